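#' Directed rule view of a network
#'
#' Compiles the reaction set into directed firing rules for network
#' expansion. Each irreversible reaction contributes one rule
#' (reactants -> products); each reversible reaction contributes two, one
#' per direction, which fire independently. The rule count is therefore
#' `n_irreversible + 2 * n_reversible`.
#'
#' @param network An `msc_network`.
#' @return An object of class `msc_rules`: a list of rules, each with
#'   `inputs`, `outputs`, `reaction_id` and `direction` ("fwd"/"rev").
#' @export
directed_view <- function(network) {
  rules <- vector("list", 0L)
  for (r in network$reactions) {
    rules[[length(rules) + 1L]] <-
      list(inputs = r$reactants, outputs = r$products,
           reaction_id = r$id, direction = "fwd")
    if (r$reversible) {
      rules[[length(rules) + 1L]] <-
        list(inputs = r$products, outputs = r$reactants,
             reaction_id = r$id, direction = "rev")
    }
  }
  structure(rules, class = "msc_rules")
}

#' Network expansion: the producible scope of a seed set
#'
#' Computes the least fixpoint of the Boolean firing rule "a directed rule
#' fires once all of its inputs are available; its outputs then become
#' available", starting from the seed metabolites. This is the standard
#' network-expansion (scope) semantics: concentration-free, flux-free pure
#' reachability.
#'
#' By default the returned scope excludes the seeds themselves unless a
#' fired rule regenerates them, so scope sizes count synthesized compounds
#' only; set `include_seeds = TRUE` for the inclusive convention.
#'
#' Seeds absent from the network are permitted and inert. The result is
#' deterministic, independent of reaction order, and monotone in both the
#' seed set and the reaction set.
#'
#' @param network An `msc_network` (or a precompiled `msc_rules` object).
#' @param seeds Character vector of available metabolite ids.
#' @param include_seeds Include seed ids in the returned scope?
#' @return Sorted character vector of producible metabolite ids. The
#'   `fired` attribute lists the reaction ids of all rules that fired,
#'   used downstream for member-contribution pruning.
#' @examples
#' net <- metabolic_network("toy", list(
#'   reaction("r1", "A", "B"),
#'   reaction("r2", "B", "C")
#' ))
#' expansion_scope(net, "A")  # "B" "C"
#' @export
expansion_scope <- function(network, seeds, include_seeds = FALSE) {
  rules <- if (inherits(network, "msc_rules")) network else directed_view(network)
  seeds <- unique(as.character(seeds))
  n_rules <- length(rules)
  if (n_rules == 0L) {
    out <- if (include_seeds) sort_ids(seeds) else character(0)
    attr(out, "fired") <- character(0)
    return(out)
  }

  inputs <- lapply(rules, `[[`, "inputs")
  outputs <- lapply(rules, `[[`, "outputs")
  universe <- unique(c(unlist(inputs, use.names = FALSE),
                       unlist(outputs, use.names = FALSE), seeds))
  n_mets <- length(universe)
  in_idx <- lapply(inputs, match, table = universe)
  out_idx <- lapply(outputs, match, table = universe)

  # classic counter propagation: need[r] = unmet inputs of rule r
  need <- lengths(in_idx)
  consumers <- vector("list", n_mets)   # met index -> rule indices using it
  for (r in seq_len(n_rules)) {
    for (m in in_idx[[r]]) consumers[[m]] <- c(consumers[[m]], r)
  }

  available <- logical(n_mets)
  produced <- logical(n_mets)
  fired <- logical(n_rules)
  queue <- match(seeds, universe)
  available[queue] <- TRUE

  while (length(queue)) {
    m <- queue[[1L]]
    queue <- queue[-1L]
    for (r in consumers[[m]]) {
      need[r] <- need[r] - 1L
      if (need[r] == 0L) {
        fired[r] <- TRUE
        for (o in out_idx[[r]]) {
          produced[o] <- TRUE
          if (!available[o]) {
            available[o] <- TRUE
            queue <- c(queue, o)
          }
        }
      }
    }
  }

  keep <- if (include_seeds) available else produced
  out <- sort_ids(universe[keep])
  attr(out, "fired") <- unique(vapply(rules[fired], `[[`, character(1),
                                      "reaction_id"))
  out
}
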