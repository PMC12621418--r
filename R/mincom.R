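# Exact minimal-community selection over Boolean metabolic networks.
#
# The solver is self-contained and exact: iterative deepening over subset
# sizes with two sound pruning steps — contribution pruning (members none of
# whose reactions fire in the full-community expansion cannot help cover any
# target) and forced-member detection (a member whose removal from the full
# community breaks coverage belongs to every solution). Candidate subsets
# are checked with a compiled integer-indexed cover test rather than by
# materializing pooled networks.

subset_scope <- function(members, seeds) {
  net <- if (length(members) == 1L) members[[1L]] else merge_networks(members)
  expansion_scope(net, seeds)
}

covers <- function(members, seeds, targets) {
  all(targets %in% subset_scope(members, seeds))
}

# Compile a system + seed set into flat integer rule tables for fast
# repeated cover checks over member subsets.
compile_cover_checker <- function(members, seeds, targets) {
  inputs <- list(); outputs <- list(); owner <- integer(0)
  for (i in seq_along(members)) {
    for (rule in directed_view(members[[i]])) {
      inputs[[length(inputs) + 1L]] <- rule$inputs
      outputs[[length(outputs) + 1L]] <- rule$outputs
      owner <- c(owner, i)
    }
  }
  universe <- unique(c(unlist(inputs, use.names = FALSE),
                       unlist(outputs, use.names = FALSE), seeds, targets))
  in_idx <- lapply(inputs, match, table = universe)
  out_idx <- lapply(outputs, match, table = universe)
  need0 <- lengths(in_idx)
  n_mets <- length(universe)
  consumers <- vector("list", n_mets)
  for (r in seq_along(in_idx))
    for (m in in_idx[[r]]) consumers[[m]] <- c(consumers[[m]], r)
  seed_idx <- match(unique(seeds), universe)
  target_idx <- match(targets, universe)

  # covers(): counter-propagation fixpoint restricted to active members'
  # rules, with early exit once every target has been produced
  function(active) {       # active: logical over members
    rule_on <- active[owner]
    need <- need0
    avail <- logical(n_mets)
    produced <- logical(n_mets)
    remaining <- length(target_idx)
    queue <- seed_idx
    avail[queue] <- TRUE
    while (length(queue)) {
      m <- queue[[1L]]
      queue <- queue[-1L]
      for (r in consumers[[m]]) {
        if (!rule_on[r]) next
        need[r] <- need[r] - 1L
        if (need[r] == 0L) {
          for (o in out_idx[[r]]) {
            if (!produced[o] && o %in% target_idx) remaining <- remaining - 1L
            produced[o] <- TRUE
            if (!avail[o]) {
              avail[o] <- TRUE
              queue <- c(queue, o)
            }
          }
          if (remaining == 0L) return(TRUE)
        }
      }
    }
    remaining == 0L
  }
}

#' Partition requested targets by community producibility
#'
#' Targets not producible by the full community under the given seeds can
#' never be covered by any subset; they are excluded from solving and
#' reported separately.
#'
#' @param system A genome-resolved `msc_system`.
#' @param condition An `msc_condition` (the basal medium in the canonical
#'   protocol).
#' @param requested Character vector of target metabolite ids (non-empty).
#' @return List of class `msc_targets` with `site`, `condition`,
#'   `requested`, `producible`, `unproducible`.
#' @export
filter_targets <- function(system, condition, requested) {
  if (system$scale != "genome_resolved")
    stop2("minimal communities require a genome-resolved system")
  requested <- sort_ids(requested)
  if (!length(requested)) stop2("requested target set is empty")
  full <- as.character(community_scope(system, condition))
  producible <- intersect(requested, full)
  structure(list(site = system$site, condition = condition$name,
                 requested = requested,
                 producible = producible,
                 unproducible = setdiff(requested, producible)),
            class = "msc_targets")
}

#' @export
print.msc_targets <- function(x, ...) {
  cat(sprintf("<targets at %s under '%s': %d requested, %d producible, %d unproducible>\n",
              x$site, x$condition, length(x$requested), length(x$producible),
              length(x$unproducible)))
  invisible(x)
}

# Members that can contribute: at least one of their reactions fires during
# the full-community expansion. Others are provably useless for coverage.
contributing_members <- function(system, seeds) {
  comm <- merge_networks(system$members, id = "full")
  scope <- expansion_scope(comm, seeds)
  fired <- attr(scope, "fired")
  prov <- attr(comm, "provenance")
  carriers <- unique(unlist(prov[fired], use.names = FALSE))
  system$members[intersect(names(system$members), carriers)]
}

# Shared search state: candidates, forced members, compiled checker.
mincom_setup <- function(system, condition, targets) {
  targets <- sort_ids(targets)
  if (!length(targets)) stop2("empty target set")
  seeds <- condition$seeds
  if (!covers(system$members, seeds, targets))
    stop2("internal error: targets not producible by the full community; ",
          "run filter_targets() first")
  cand <- contributing_members(system, seeds)
  ids <- names(cand)
  check <- compile_cover_checker(cand, seeds, targets)
  n <- length(ids)
  all_on <- rep(TRUE, n)
  forced <- logical(n)
  for (i in seq_len(n)) {
    act <- all_on; act[i] <- FALSE
    if (!check(act)) forced[i] <- TRUE    # removal breaks coverage
  }
  list(ids = ids, check = check, forced = forced, targets = targets)
}

# Iterate over subsets of `free` of size k2 (with `forced` always active),
# calling fun(subset_indices) for each covering subset; stops early when
# fun returns FALSE.
scan_size <- function(st, k2, fun) {
  n <- length(st$ids)
  base <- st$forced
  free <- which(!st$forced)
  if (k2 == 0L) {
    if (st$check(base)) return(fun(integer(0)))
    return(TRUE)
  }
  if (length(free) < k2) return(TRUE)
  for (s in utils::combn(free, k2, simplify = FALSE)) {
    act <- base; act[s] <- TRUE
    if (st$check(act)) {
      if (!fun(s)) return(FALSE)
    }
  }
  TRUE
}

#' Minimum community size for a target set
#'
#' Finds the smallest number of member networks whose pooled (mixed-bag)
#' scope covers all targets. Exact: members that contribute no fired rule
#' are excluded, members whose removal from the full community breaks
#' coverage are forced into every solution, and the remaining subsets are
#' searched in increasing size. Deterministic: candidates are scanned in
#' sorted id order and the first witness at the minimum size is returned.
#'
#' @param system A genome-resolved `msc_system`.
#' @param condition An `msc_condition`.
#' @param targets Character vector of target ids, all producible by the
#'   full community (see [filter_targets()]).
#' @return List with `k` (minimum size) and `witness` (sorted member ids of
#'   one minimal community).
#' @export
solve_minimum <- function(system, condition, targets) {
  st <- mincom_setup(system, condition, targets)
  n_free <- sum(!st$forced)
  for (k2 in 0:n_free) {
    witness <- NULL
    scan_size(st, k2, function(s) { witness <<- s; FALSE })
    if (!is.null(witness))
      return(list(k = sum(st$forced) + k2,
                  witness = sort_ids(st$ids[c(which(st$forced), witness)])))
  }
  stop2("internal error: contributing members do not cover the targets")
}

#' Enumerate all minimal communities
#'
#' All member subsets of the minimum cardinality `k` whose pooled scope
#' covers the targets, with the key-species classification:
#' \describe{
#'   \item{key species}{union of all solutions;}
#'   \item{essential syntrophic organisms}{members of every solution
#'     (producibility bottlenecks);}
#'   \item{alternative syntrophic organisms}{members of some but not all
#'     solutions (functional redundancy).}
#' }
#' `mc_ks_percent = 100 * k / |key species|`; 100% means a unique, rigid
#' consortium.
#'
#' @inheritParams solve_minimum
#' @param k Minimum community size from [solve_minimum()]; recomputed when
#'   missing.
#' @param cap Maximum number of solutions to enumerate; beyond it the
#'   result is flagged partial and the classification is suppressed.
#' @return An object of class `msc_solutions` with `site`, `condition`,
#'   `targets`, `k`, `solutions` (list of sorted id vectors),
#'   `key_species`, `essential`, `alternative`, `mc_ks_percent`,
#'   `partial`.
#' @export
enumerate_solutions <- function(system, condition, targets, k = NULL,
                                cap = 10000L) {
  st <- mincom_setup(system, condition, targets)
  targets <- st$targets
  if (is.null(k)) {
    n_free <- sum(!st$forced)
    k <- NULL
    for (k2 in 0:n_free) {
      found <- FALSE
      scan_size(st, k2, function(s) { found <<- TRUE; FALSE })
      if (found) { k <- sum(st$forced) + k2; break }
    }
    if (is.null(k))
      stop2("internal error: contributing members do not cover the targets")
  }
  k2 <- k - sum(st$forced)
  if (k2 < 0L)
    stop2("k is smaller than the number of forced members; not minimal")
  forced_ids <- st$ids[st$forced]
  solutions <- list()
  partial <- FALSE
  scan_size(st, k2, function(s) {
    if (length(solutions) >= cap) { partial <<- TRUE; return(FALSE) }
    solutions[[length(solutions) + 1L]] <<- sort_ids(c(forced_ids, st$ids[s]))
    TRUE
  })
  if (partial) {
    key <- essential <- alternative <- NULL
    mc_ks <- NA_real_
  } else {
    key <- sort_ids(unlist(solutions, use.names = FALSE))
    essential <- sort_ids(Reduce(intersect, solutions))
    alternative <- setdiff(key, essential)
    mc_ks <- 100 * k / length(key)
  }
  structure(list(site = system$site, condition = condition$name,
                 targets = targets, k = k, solutions = solutions,
                 key_species = key, essential = essential,
                 alternative = alternative, mc_ks_percent = mc_ks,
                 partial = partial),
            class = "msc_solutions")
}

#' @export
print.msc_solutions <- function(x, ...) {
  if (x$partial) {
    cat(sprintf("<minimal communities at %s: k = %d, enumeration truncated>\n",
                x$site, x$k))
  } else {
    cat(sprintf(
      "<minimal communities at %s: k = %d, %d solution(s), %d key species (%d essential, %d alternative), MC:KS = %.1f%%>\n",
      x$site, x$k, length(x$solutions), length(x$key_species),
      length(x$essential), length(x$alternative), x$mc_ks_percent))
  }
  invisible(x)
}

#' Group alternative organisms into substitutable classes
#'
#' Two alternative syntrophic organisms are interchangeable when swapping
#' one for the other maps every solution containing either onto another
#' valid solution (the "OR" groups of the power-graph summary). Classes are
#' the connected components of the pairwise-interchangeability graph;
#' essential members are excluded and singleton classes are allowed.
#'
#' @param solutions An `msc_solutions` with classification available.
#' @return An object of class `msc_substitutable`: list of character
#'   vectors (the classes, each sorted), sorted by first member.
#' @export
substitutable_groups <- function(solutions) {
  if (isTRUE(solutions$partial))
    stop2("classification suppressed (enumeration truncated); cannot group")
  alt <- solutions$alternative
  if (!length(alt)) return(structure(list(), class = "msc_substitutable"))
  sol_keys <- vapply(solutions$solutions, function(s)
    paste(sort_ids(s), collapse = "|"), character(1))
  is_solution <- function(s) paste(sort_ids(s), collapse = "|") %in% sol_keys
  swap_ok <- function(a, b) {
    for (s in solutions$solutions) {
      if (a %in% s && !is_solution(c(setdiff(s, a), b))) return(FALSE)
      if (b %in% s && !is_solution(c(setdiff(s, b), a))) return(FALSE)
    }
    TRUE
  }
  n <- length(alt)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    if (swap_ok(alt[i], alt[j])) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  classes <- unname(split(alt, roots))
  classes <- lapply(classes, sort_ids)
  classes <- classes[order(vapply(classes, `[`, character(1), 1L), method = "radix")]
  structure(classes, class = "msc_substitutable")
}

#' @export
print.msc_substitutable <- function(x, ...) {
  cat(sprintf("<%d substitutable class(es)>\n", length(x)))
  for (cl in x) cat("  {", paste(cl, collapse = ", "), "}\n")
  invisible(x)
}

#' Cumulative relative abundance of key species
#'
#' @param solutions An `msc_solutions` with classification available.
#' @param abundances Named numeric vector of relative abundances (percent)
#'   covering at least every key species.
#' @return List with `key_species_abundance`, `essential_abundance`, and
#'   `per_member` (data.frame member/role/abundance).
#' @export
abundance_summary <- function(solutions, abundances) {
  if (isTRUE(solutions$partial))
    stop2("classification suppressed (enumeration truncated)")
  missing <- setdiff(solutions$key_species, names(abundances))
  if (length(missing))
    stop2("missing abundance for member(s): ", paste(missing, collapse = ", "))
  per <- data.frame(
    member = solutions$key_species,
    role = ifelse(solutions$key_species %in% solutions$essential,
                  "essential", "alternative"),
    abundance = as.numeric(abundances[solutions$key_species])
  )
  list(key_species_abundance = sum(per$abundance),
       essential_abundance = sum(per$abundance[per$role == "essential"]),
       per_member = per)
}

#' Serialize a solution set to JSON
#' @param solutions An `msc_solutions`.
#' @param path Output path.
#' @param substitutable Optional `msc_substitutable` to include.
#' @return `path`, invisibly.
#' @export
write_solutions_json <- function(solutions, path, substitutable = NULL) {
  x <- unclass(solutions)
  x$solutions <- lapply(x$solutions, as.character)
  if (!is.null(substitutable))
    x$substitutable_classes <- lapply(unclass(substitutable), as.character)
  write_json_canonical(x, path)
}
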