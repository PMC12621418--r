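test_that("target filtering partitions by full-community producibility", {
  fx <- make_fixture_suite()$handoff
  tg <- filter_targets(fx$system, fx$condition, c("B", "C", "nope", "A"))
  expect_setequal(tg$producible, c("B", "C"))
  # a seed is unproducible under the exclusive convention unless regenerated
  expect_true("A" %in% tg$unproducible)
  expect_true("nope" %in% tg$unproducible)
  expect_error(filter_targets(fx$system, fx$condition, character(0)), "empty")
  meta <- system_spec("s", "metagenome",
                      list(metabolic_network("n", list(reaction("r", "A", "B")))))
  expect_error(filter_targets(meta, fx$condition, "B"), "genome-resolved")
})

test_that("forced hand-offs and single producers give the expected minima", {
  fx <- make_fixture_suite()
  h <- fx$handoff
  expect_equal(solve_minimum(h$system, h$condition, "C")$k, 2L)
  expect_equal(solve_minimum(h$system, h$condition, "B")$k, 1L)
  s <- enumerate_solutions(h$system, h$condition, "C")
  expect_equal(solution_key(s$solutions), solution_key(h$expected$mincom$solutions))
  expect_equal(s$mc_ks_percent, 100)
})

test_that("the interchangeable-producer instance classifies essential vs alternative", {
  fx <- make_fixture_suite()$interchangeable
  s <- enumerate_solutions(fx$system, fx$condition, fx$targets)
  expect_equal(s$k, fx$expected$k)
  expect_equal(solution_key(s$solutions), solution_key(fx$expected$solutions))
  expect_equal(s$essential, fx$expected$essential)
  expect_equal(s$alternative, fx$expected$alternative)
  expect_equal(s$mc_ks_percent, 100 * 4 / 5)
  subst <- substitutable_groups(s)
  expect_equal(length(subst), 1L)
  expect_equal(subst[[1]], fx$expected$substitutable[[1]])
})

test_that("the 12-member redundancy instance enumerates all 8 solutions", {
  fx <- make_fixture_suite()$enum12
  s <- enumerate_solutions(fx$system, fx$condition, fx$targets)
  expect_equal(s$k, 3L)
  expect_equal(length(s$solutions), 8L)
  expect_equal(s$essential, character(0))
  oracle <- oracle_mincom(fx$system, fx$condition$seeds, fx$targets)
  expect_equal(solution_key(s$solutions), solution_key(oracle$solutions))
  subst <- substitutable_groups(s)
  expect_equal(solution_key(unclass(subst)),
               solution_key(fx$expected$substitutable))
  expect_equal(s$mc_ks_percent, 50)
})

test_that("solver matches the exhaustive oracle on random communities", {
  for (seed in 1:12) {
    sys <- random_community(seed + 50, n_members = sample(5:8, 1),
                            n_chains = 5, chain_len = 4)
    cond <- seed_condition("m", c("s1", "s2"))
    full <- as.character(community_scope(sys, cond))
    if (length(full) < 2) next
    set.seed(seed)
    targets <- sample(full, min(3, length(full)))
    oracle <- oracle_mincom(sys, cond$seeds, targets)
    got <- enumerate_solutions(sys, cond, targets)
    expect_equal(got$k, oracle$k, info = paste("seed", seed))
    expect_equal(solution_key(got$solutions), solution_key(oracle$solutions),
                 info = paste("seed", seed))
    expect_equal(got$essential, oracle$essential, info = paste("seed", seed))
    expect_equal(got$alternative, oracle$alternative, info = paste("seed", seed))
  }
})

test_that("every enumerated solution is minimal and essentials are bottlenecks", {
  for (seed in c(3, 17, 31)) {
    sys <- random_community(seed, n_members = 7, n_chains = 6)
    cond <- seed_condition("m", c("s1", "s2"))
    full <- as.character(community_scope(sys, cond))
    if (length(full) < 3) next
    set.seed(seed)
    targets <- sample(full, 3)
    s <- enumerate_solutions(sys, cond, targets)
    for (sol in s$solutions) {
      expect_true(all(targets %in% oracle_community_scope(sys$members[sol],
                                                          cond$seeds)))
      for (m in sol) {
        rest <- setdiff(sol, m)
        left <- if (length(rest)) oracle_community_scope(sys$members[rest],
                                                         cond$seeds) else character(0)
        expect_false(all(targets %in% left))
      }
    }
    # removing an essential member from the FULL community breaks coverage
    for (e in s$essential) {
      rest <- sys$members[setdiff(names(sys$members), e)]
      expect_false(all(targets %in% oracle_community_scope(rest, cond$seeds)))
    }
    expect_equal(s$mc_ks_percent == 100, length(s$solutions) == 1L)
  }
})

test_that("substitutable classes agree with a brute-force swap test", {
  for (seed in c(7, 21)) {
    sys <- random_community(seed, n_members = 7, n_chains = 6)
    cond <- seed_condition("m", c("s1", "s2"))
    full <- as.character(community_scope(sys, cond))
    if (length(full) < 3) next
    set.seed(seed)
    targets <- sample(full, 3)
    s <- enumerate_solutions(sys, cond, targets)
    subst <- substitutable_groups(s)
    keys <- solution_key(s$solutions)
    swap_ok <- function(a, b) {
      for (sol in s$solutions) {
        if (a %in% sol &&
            !(paste(sort(c(setdiff(sol, a), b), method = "radix"),
                    collapse = "|") %in% keys)) return(FALSE)
        if (b %in% sol &&
            !(paste(sort(c(setdiff(sol, b), a), method = "radix"),
                    collapse = "|") %in% keys)) return(FALSE)
      }
      TRUE
    }
    # members inside one class are pairwise swappable
    for (cl in subst)
      if (length(cl) > 1)
        for (i in seq_len(length(cl) - 1))
          expect_true(swap_ok(cl[i], cl[i + 1]))
    # essential members never appear in classes
    expect_false(any(unlist(subst) %in% s$essential))
    # all-essential instances give an empty partition
    if (!length(s$alternative)) expect_length(subst, 0)
  }
})

test_that("enumeration respects the solution cap and suppresses classification", {
  fx <- make_fixture_suite()$enum12
  s <- enumerate_solutions(fx$system, fx$condition, fx$targets, cap = 3)
  expect_true(s$partial)
  expect_null(s$key_species)
  expect_error(substitutable_groups(s), "truncated")
  expect_error(abundance_summary(s, c(a = 1)), "truncated")
})

test_that("abundance summaries add up and report missing members", {
  fx <- make_fixture_suite()$interchangeable
  s <- enumerate_solutions(fx$system, fx$condition, fx$targets)
  ab <- c(e1 = 1.5, e2 = 2.0, e3 = 0.5, p1 = 1.0, p2 = 0.25)
  sm <- abundance_summary(s, ab)
  expect_equal(sm$key_species_abundance, 5.25)
  expect_equal(sm$essential_abundance, 4.0)
  expect_equal(nrow(sm$per_member), 5L)
  expect_equal(abundance_summary(s, ab * 0)$key_species_abundance, 0)
  expect_error(abundance_summary(s, ab[-1]), "e1")
})
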