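# Independent oracles and random-instance generators used across the suite.
# The oracles deliberately avoid the package's counter-propagation engine:
# scope is computed by naively rescanning every rule until nothing changes,
# and minimal communities by exhaustive search over all member subsets.

# Naive repeated-rescan fixpoint over directed rules.
oracle_scope_rules <- function(rules, seeds, include_seeds = FALSE) {
  avail <- unique(as.character(seeds))
  produced <- character(0)
  repeat {
    changed <- FALSE
    for (r in rules) {
      if (all(r$inputs %in% avail)) {
        produced <- union(produced, r$outputs)
        if (!all(r$outputs %in% avail)) {
          avail <- union(avail, r$outputs)
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  out <- if (include_seeds) avail else produced
  sort(unique(out), method = "radix")
}

oracle_scope <- function(network, seeds, include_seeds = FALSE) {
  oracle_scope_rules(directed_view(network), seeds, include_seeds)
}

# Pooled-community oracle scope: concatenate every member's directed rules.
oracle_community_scope <- function(members, seeds) {
  rules <- unlist(lapply(members, directed_view), recursive = FALSE)
  oracle_scope_rules(rules, seeds)
}

# Random Boolean network; reaction sides drawn uniformly from a small
# metabolite universe.
random_network <- function(seed, n_reactions = 30, n_mets = 20, p_rev = 0.3,
                           id = NULL) {
  set.seed(seed)
  mets <- sprintf("m%02d", seq_len(n_mets))
  rxns <- lapply(seq_len(n_reactions), function(i) {
    reactants <- sample(mets, sample(1:3, 1))
    products <- sample(mets, sample(1:3, 1))
    reaction(sprintf("r%03d", i), reactants, products,
             reversible = stats::runif(1) < p_rev)
  })
  metabolic_network(id %||% sprintf("rand%d", seed), rxns)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random multi-member community rooted in seeds: pathway chains handed out
# reaction-by-reaction to random members, so cross-feeding arises naturally.
random_community <- function(seed, n_members = 6, n_chains = 6,
                             chain_len = 4, seeds = c("s1", "s2"),
                             site = "toy") {
  set.seed(seed)
  member_rxns <- replicate(n_members, list(), simplify = FALSE)
  met_counter <- 0L
  for (ch in seq_len(n_chains)) {
    prev <- sample(seeds, 1)
    for (step in seq_len(sample(2:chain_len, 1))) {
      met_counter <- met_counter + 1L
      out <- sprintf("x%03d", met_counter)
      m <- sample(n_members, 1)
      member_rxns[[m]] <- c(member_rxns[[m]], list(
        reaction(sprintf("c%d_s%d", ch, step), prev, out)))
      prev <- out
    }
  }
  members <- lapply(seq_len(n_members), function(i) {
    rxns <- member_rxns[[i]]
    if (!length(rxns))
      rxns <- list(reaction(sprintf("idle%d", i), "unreachable_in",
                            sprintf("idle_out%d", i)))
    metabolic_network(sprintf("org%02d", i), rxns)
  })
  system_spec(site, "genome_resolved", members)
}

# Exhaustive minimal-community oracle over all 2^n member subsets.
oracle_mincom <- function(system, seeds, targets) {
  ids <- names(system$members)
  n <- length(ids)
  covers <- function(sel) {
    all(targets %in% oracle_community_scope(system$members[sel], seeds))
  }
  for (size in seq_len(n)) {
    sols <- Filter(covers, utils::combn(ids, size, simplify = FALSE))
    if (length(sols)) {
      key <- sort(unique(unlist(sols)), method = "radix")
      essential <- sort(Reduce(intersect, sols), method = "radix")
      return(list(k = size, solutions = sols, key_species = key,
                  essential = essential,
                  alternative = setdiff(key, essential)))
    }
  }
  NULL
}

# Canonical form of a solution list for set comparison.
solution_key <- function(solutions) {
  sort(unname(vapply(solutions, function(s)
    paste(sort(s, method = "radix"), collapse = "|"), character(1))),
    method = "radix")
}

# Unique-row count by an independent hashing route (serialize each row).
oracle_unique_rows <- function(mat) {
  length(unique(apply(mat, 1L, function(r) paste(r, collapse = "\r"))))
}
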