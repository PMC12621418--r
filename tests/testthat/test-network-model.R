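test_that("reaction and network constructors enforce their invariants", {
  expect_error(reaction("", "A", "B"), "non-empty")
  expect_error(reaction("r", character(0), "B"), "reactant")
  expect_error(reaction("r", "A", character(0)), "product")
  r <- reaction("r", c("B", "A", "A"), "B")   # overlap and duplicates allowed
  expect_equal(r$reactants, c("A", "B"))
  expect_equal(r$products, "B")

  expect_error(metabolic_network("n", list(reaction("r1", "A", "B"),
                                           reaction("r1", "B", "C"))),
               "duplicate")
  empty <- metabolic_network("empty")
  expect_equal(n_reactions(empty), 0L)
  expect_equal(empty$metabolites, character(0))
  expect_equal(as.character(expansion_scope(empty, c("A", "B"))), character(0))

  net <- metabolic_network("n", list(reaction("r1", c("A", "B"), "C")))
  expect_setequal(net$metabolites, c("A", "B", "C"))
})

test_that("directed view splits reversible reactions into two rules", {
  mk <- function(rev) metabolic_network("n", list(
    reaction("r1", "A", "B", rev[1]),
    reaction("r2", "B", "C", rev[2]),
    reaction("r3", "C", "D", rev[3]),
    reaction("r4", "D", "E", rev[4])
  ))
  for (rev in list(c(F, F, F, F), c(T, T, F, F), c(T, T, T, T))) {
    rules <- directed_view(mk(rev))
    expect_length(rules, sum(!rev) + 2L * sum(rev))
  }
  rules <- directed_view(metabolic_network("n", list(reaction("r", "A", "B", TRUE))))
  expect_equal(rules[[1]]$inputs, "A")
  expect_equal(rules[[2]]$inputs, "B")
  expect_equal(rules[[2]]$outputs, "A")
})

test_that("expansion follows chains and blocks on unavailable co-substrates", {
  fx <- make_fixture_suite()
  expect_equal(as.character(expansion_scope(fx$chain$network, fx$chain$seeds)),
               fx$chain$expected$scope)
  expect_equal(as.character(expansion_scope(fx$blocked$network, fx$blocked$seeds)),
               fx$blocked$expected$scope)
  # inclusive convention keeps the seeds
  expect_setequal(as.character(expansion_scope(fx$chain$network, "A",
                                               include_seeds = TRUE)),
                  c("A", "B", "C"))
  # seeds absent from the network are inert
  expect_equal(as.character(expansion_scope(fx$chain$network, c("A", "ZZ"))),
               c("B", "C"))
})

test_that("the exclusive convention reports seeds only when regenerated", {
  net <- metabolic_network("n", list(reaction("r1", "A", "B"),
                                     reaction("r2", "B", c("A", "C"))))
  sc <- as.character(expansion_scope(net, "A"))
  expect_setequal(sc, c("A", "B", "C"))   # A regenerated by r2
  net2 <- metabolic_network("n", list(reaction("r1", "A", "B")))
  expect_equal(as.character(expansion_scope(net2, "A")), "B")
})

test_that("scope equals the naive rescan oracle and is order-invariant", {
  for (seed in 1:20) {
    net <- random_network(seed, n_reactions = 40, n_mets = 25)
    seeds <- sprintf("m%02d", sample(25, 4))
    got <- as.character(expansion_scope(net, seeds))
    expect_identical(got, oracle_scope(net, seeds), info = paste("seed", seed))
    got_inc <- as.character(expansion_scope(net, seeds, include_seeds = TRUE))
    expect_identical(got_inc, oracle_scope(net, seeds, include_seeds = TRUE))
  }
  # order invariance: >= 10 shuffles of a fixed network
  net <- random_network(99, n_reactions = 60, n_mets = 30)
  seeds <- c("m01", "m05", "m09")
  ref <- as.character(expansion_scope(net, seeds))
  for (i in 1:10) {
    set.seed(1000 + i)
    shuffled <- metabolic_network(net$id, sample(unname(net$reactions)))
    expect_identical(as.character(expansion_scope(shuffled, seeds)), ref)
  }
})

test_that("scope is monotone in seeds and reactions, and a fixpoint", {
  for (seed in 1:10) {
    net <- random_network(seed + 200, n_reactions = 35, n_mets = 20)
    set.seed(seed)
    s1 <- sprintf("m%02d", sample(20, 3))
    s2 <- union(s1, sprintf("m%02d", sample(20, 3)))
    sc1 <- as.character(expansion_scope(net, s1))
    sc2 <- as.character(expansion_scope(net, s2))
    expect_true(all(sc1 %in% union(sc2, s2)))

    # adding a reaction never shrinks the scope
    bigger <- metabolic_network(net$id, c(unname(net$reactions),
      list(reaction("extra", sample(net$metabolites, 1), "new_met"))))
    expect_true(all(sc1 %in% as.character(expansion_scope(bigger, s1))))

    # fixpoint stability: seeding with scope + seeds fires nothing new
    again <- as.character(expansion_scope(net, union(s1, sc1),
                                          include_seeds = TRUE))
    expect_setequal(again, union(s1, sc1))
  }
})

test_that("SBML round-trips preserve the reaction set exactly", {
  net <- random_network(7, n_reactions = 50, n_mets = 30)
  path <- withr::local_tempfile(fileext = ".sbml")
  write_sbml(net, path)
  back <- parse_sbml(path)
  expect_true(networks_equal(net, back))
  expect_equal(back$id, net$id)
  # and a second round trip is byte-stable
  path2 <- withr::local_tempfile(fileext = ".sbml")
  write_sbml(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("SBML parsing handles empty models, skipped reactions, bad XML", {
  p <- withr::local_tempfile(fileext = ".sbml")
  write_sbml(metabolic_network("empty"), p)
  net <- parse_sbml(p)
  expect_equal(n_reactions(net), 0L)
  expect_equal(length(net$metabolites), 0L)

  # a reaction lacking products is skipped with a warning and counted
  writeLines(c(
    '<?xml version="1.0"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">',
    '<model id="m"><listOfSpecies><species id="A"/><species id="B"/><species id="orphan"/></listOfSpecies>',
    '<listOfReactions>',
    '<reaction id="ok" reversible="false">',
    '<listOfReactants><speciesReference species="A"/></listOfReactants>',
    '<listOfProducts><speciesReference species="B"/></listOfProducts></reaction>',
    '<reaction id="broken" reversible="false">',
    '<listOfReactants><speciesReference species="A"/></listOfReactants></reaction>',
    '</listOfReactions></model></sbml>'), p)
  expect_warning(net <- parse_sbml(p), "broken")
  expect_equal(n_reactions(net), 1L)
  rep <- attr(net, "parse_report")
  expect_equal(rep$skipped_reactions, "broken")
  expect_equal(rep$n_species_dropped, 1L)   # orphan

  writeLines("<sbml><model>", p)
  expect_error(parse_sbml(p), "XML")
})

test_that("the tabular dialect matches SBML content and validates tokens", {
  net <- random_network(11, n_reactions = 25, n_mets = 15)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  sbml <- withr::local_tempfile(fileext = ".sbml")
  write_network_table(net, tsv)
  write_sbml(net, sbml)
  expect_true(networks_equal(parse_network_table(tsv, id = net$id),
                             parse_sbml(sbml)))

  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("r1\tA,B\tC\tirrev"), p)
  n <- parse_network_table(p)
  expect_equal(n$reactions$r1$reactants, c("A", "B"))
  expect_false(n$reactions$r1$reversible)

  writeLines(c("r1\tA\tB\tirrev", "r1\tB\tC\tirrev"), p)
  expect_error(parse_network_table(p), "duplicate")
  writeLines(c("r1\tA\tB\tsometimes"), p)
  expect_error(parse_network_table(p), "reversibility")
  writeLines(c("r1\tA\t\tirrev", "r2\tA\tB\trev"), p)
  expect_warning(n <- parse_network_table(p), "skipped")
  expect_equal(names(n$reactions), "r2")
})

test_that("seed files read as plain lists or SBML species lists", {
  p <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# medium", "GLC", "  WATER ", "", "Pi"), p)
  expect_equal(read_seed_file(p), c("GLC", "Pi", "WATER"))
  cond <- seed_condition("m", c("GLC", "WATER", "Pi"))
  p2 <- withr::local_tempfile(fileext = ".sbml")
  write_condition_sbml(cond, p2)
  expect_equal(read_seed_file(p2), c("GLC", "Pi", "WATER"))
})
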