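test_that("world generation is deterministic down to bytes on disk", {
  cfg <- world_config(seed = 42)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate_world(cfg, dir = d1)
  generate_world(cfg, dir = d2)
  f1 <- list.files(d1, recursive = TRUE)
  f2 <- list.files(d2, recursive = TRUE)
  expect_identical(sort(f1, method = "radix"), sort(f2, method = "radix"))
  for (f in f1)
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), info = f)
  # different seeds differ
  d3 <- withr::local_tempdir()
  generate_world(world_config(seed = 43), dir = d3)
  expect_false(identical(unname(tools::md5sum(file.path(d1, "manifest.json"))),
                         unname(tools::md5sum(file.path(d3, "manifest.json")))))
})

test_that("worlds survive a write/read round trip", {
  w <- generate_world(world_config(seed = 8))
  d <- withr::local_tempdir()
  write_world(w, d)
  back <- read_world(d)
  expect_equal(names(back$systems), names(w$systems))
  for (nm in names(w$systems)) {
    expect_equal(names(back$systems[[nm]]$members), names(w$systems[[nm]]$members))
    for (m in names(w$systems[[nm]]$members))
      expect_true(networks_equal(back$systems[[nm]]$members[[m]],
                                 w$systems[[nm]]$members[[m]]))
  }
  expect_equal(as.matrix(back$env), as.matrix(w$env), tolerance = 1e-9)
  expect_equal(back$abundances, w$abundances, tolerance = 1e-9)
  expect_equal(length(back$conditions), 5L)
})

test_that("manifest reachable sets match the expansion engine on every cell", {
  w <- generate_world(world_config(seed = 13))
  grid <- run_grid(w$systems, w$conditions)
  expected <- w$manifest$expected_scopes
  expect_setequal(colnames(grid$values), names(expected))
  for (cell in names(expected)) {
    got <- rownames(grid$values)[grid$values[, cell] == 1]
    expect_identical(got, sort(unlist(expected[[cell]]) %||% character(0),
                               method = "radix"),
                     info = cell)
  }
})

test_that("planted gap-fill artifacts are exactly the filtered ids", {
  for (seed in c(2, 9)) {
    w <- generate_world(world_config(seed = seed))
    filt <- filter_gapfill_artifacts(run_grid(w$systems, w$conditions))
    planted <- vapply(w$manifest$artifacts, `[[`, character(1), "metabolite")
    expect_setequal(filt$removed, planted)
    expect_length(filt$removed, w$config$mag_only_artifact_count)
  }
})

test_that("planted cooperation-only metabolites are recovered; none with split = 0", {
  w0 <- generate_world(world_config(seed = 21, crossfeeding_split = 0))
  expect_equal(nrow(w0$manifest$cooperation_only), 0L)
  for (sys in w0$systems) {
    if (sys$scale != "genome_resolved") next
    res <- cooperation_potential(sys, w0$conditions$basal_medium)
    expect_equal(res$cooperation_only, character(0), info = sys$site)
  }

  w <- generate_world(world_config(seed = 22))
  coop <- w$manifest$cooperation_only
  expect_gt(nrow(coop), 0L)
  tiers <- metascope:::TIER_CONDITIONS
  for (sys in w$systems) {
    if (sys$scale != "genome_resolved") next
    for (cond_name in names(w$conditions)) {
      res <- cooperation_potential(sys, w$conditions[[cond_name]])
      sel <- coop$site == sys$site &
        vapply(coop$tier, function(t) cond_name %in% tiers[[t]], logical(1))
      expect_setequal(res$cooperation_only, coop$metabolite[sel])
    }
  }
})

test_that("planted interchangeable producers are alternatives for their product", {
  w <- generate_world(world_config(seed = 30))
  red <- w$manifest$redundancy
  expect_gt(length(red), 0L)
  checked <- 0L
  for (r in red) {
    if (r$tier != "basal") next
    sys <- w$systems[[paste(r$site, "genome_resolved", sep = "|")]]
    s <- enumerate_solutions(sys, w$conditions$basal_medium, r$end_product)
    expect_equal(s$k, 1L)
    expect_setequal(unlist(s$solutions), r$holders)
    expect_equal(s$alternative, sort(r$holders, method = "radix"))
    subst <- substitutable_groups(s)
    expect_equal(subst[[1]], sort(r$holders, method = "radix"))
    checked <- checked + 1L
    if (checked >= 3L) break
  }
  expect_gt(checked, 0L)
})

test_that("planted splits force two-member minimal communities for tail products", {
  w <- generate_world(world_config(seed = 31))
  splits <- Filter(function(s) s$tier == "basal", w$manifest$splits)
  expect_gt(length(splits), 0L)
  for (sp in splits[seq_len(min(3, length(splits)))]) {
    sys <- w$systems[[paste(sp$site, "genome_resolved", sep = "|")]]
    tail_last <- sp$tail_products[[length(sp$tail_products)]]
    s <- enumerate_solutions(sys, w$conditions$basal_medium, tail_last)
    expect_equal(s$k, 2L)
    expect_true(any(vapply(s$solutions, function(sol)
      setequal(sol, c(sp$head_organism, sp$tail_organism)), logical(1))))
  }
})

test_that("the metagenome strictly extends the community via unbinned pathways", {
  w <- generate_world(world_config(seed = 6))
  for (site in w$manifest$sites) {
    meta <- w$systems[[paste(site, "metagenome", sep = "|")]]
    mags <- w$systems[[paste(site, "genome_resolved", sep = "|")]]
    sc_meta <- as.character(community_scope(meta, w$conditions$all_amino_acids))
    sc_mag <- as.character(community_scope(mags, w$conditions$all_amino_acids))
    # MAG-side extras are exactly the planted artifacts
    art <- vapply(w$manifest$artifacts, `[[`, character(1), "metabolite")
    expect_true(all(setdiff(sc_mag, sc_meta) %in% art))
  }
  # at least one site has metagenome-only (unbinned) products
  extra <- vapply(w$manifest$sites, function(site) {
    meta <- w$systems[[paste(site, "metagenome", sep = "|")]]
    mags <- w$systems[[paste(site, "genome_resolved", sep = "|")]]
    length(setdiff(as.character(community_scope(meta, w$conditions$all_amino_acids)),
                   as.character(community_scope(mags, w$conditions$all_amino_acids))))
  }, numeric(1))
  expect_gt(sum(extra), 0)
})

test_that("invalid configurations are rejected", {
  expect_error(world_config(n_sites = 0), "positive")
  expect_error(world_config(crossfeeding_split = 1.5), "probabilities")
  expect_error(world_config(organisms_min = 10, organisms_max = 5), "exceeds")
  expect_error(world_config(redundancy_level = 9, organisms_min = 8,
                            organisms_max = 8), "redundancy_level")
  expect_error(world_config(n_planted_associated_groups = 50), "planted")
  expect_error(generate_world(world_config(universe_size = 20)), "universe")
})
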