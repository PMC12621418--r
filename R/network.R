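#' Construct a Boolean reaction
#'
#' A reaction in the stoichiometry-free formalism: a set of reactant
#' identifiers, a set of product identifiers, and a reversibility flag.
#' Stoichiometric coefficients are deliberately absent; producibility is a
#' reachability (Boolean) question, not a flux question.
#'
#' @param id Non-empty reaction identifier.
#' @param reactants Character vector of metabolite ids (non-empty set).
#' @param products Character vector of metabolite ids (non-empty set).
#' @param reversible Logical; reversible reactions may fire in either
#'   direction independently.
#' @return An object of class `msc_reaction`.
#' @examples
#' reaction("r1", c("A", "B"), "C")
#' @export
reaction <- function(id, reactants, products, reversible = FALSE) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop2("reaction id must be a non-empty string")
  reactants <- sort_ids(reactants)
  products <- sort_ids(products)
  if (length(reactants) == 0L || any(!nzchar(reactants)))
    stop2("reaction '", id, "': reactant set must be non-empty")
  if (length(products) == 0L || any(!nzchar(products)))
    stop2("reaction '", id, "': product set must be non-empty")
  structure(
    list(id = id, reactants = reactants, products = products,
         reversible = isTRUE(reversible)),
    class = "msc_reaction"
  )
}

#' Construct a metabolic network
#'
#' A network is a set of Boolean reactions; its metabolite set is derived as
#' the union of all reactant and product ids. A network with zero reactions
#' is legal and has an empty scope under any seed set.
#'
#' @param id Network identifier (a site id or a MAG id).
#' @param reactions List of [reaction()] objects with unique ids.
#' @return An object of class `msc_network` with elements `id`, `reactions`
#'   (named list) and `metabolites` (sorted character vector).
#' @export
metabolic_network <- function(id, reactions = list()) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop2("network id must be a non-empty string")
  if (length(reactions)) {
    ok <- vapply(reactions, inherits, logical(1), "msc_reaction")
    if (!all(ok)) stop2("all elements of `reactions` must be reaction objects")
    rids <- vapply(reactions, `[[`, character(1), "id")
    if (anyDuplicated(rids))
      stop2("duplicate reaction ids: ",
            paste(unique(rids[duplicated(rids)]), collapse = ", "))
    names(reactions) <- rids
    reactions <- reactions[order_ids(rids)]
  }
  mets <- sort_ids(unlist(lapply(reactions, function(r) c(r$reactants, r$products)),
                          use.names = FALSE))
  structure(list(id = id, reactions = reactions, metabolites = mets),
            class = "msc_network")
}

#' @export
print.msc_network <- function(x, ...) {
  nrev <- sum(vapply(x$reactions, `[[`, logical(1), "reversible"))
  cat(sprintf("<metabolic network '%s': %d reactions (%d reversible), %d metabolites>\n",
              x$id, length(x$reactions), nrev, length(x$metabolites)))
  invisible(x)
}

#' @export
print.msc_reaction <- function(x, ...) {
  arrow <- if (x$reversible) "<->" else "->"
  cat(sprintf("%s: %s %s %s\n", x$id,
              paste(x$reactants, collapse = " + "), arrow,
              paste(x$products, collapse = " + ")))
  invisible(x)
}

#' Number of reactions in a network
#' @param network An `msc_network`.
#' @return Integer count.
#' @export
n_reactions <- function(network) length(network$reactions)

#' Test two networks for equality of reaction content
#'
#' Networks are equal when their reaction sets agree as sets of
#' (reactants, products, reversible) triples with matching ids.
#'
#' @param a,b `msc_network` objects.
#' @return Logical.
#' @export
networks_equal <- function(a, b) {
  key <- function(n) sort(vapply(n$reactions, reaction_key, character(1),
                                 USE.NAMES = FALSE), method = "radix")
  identical(key(a), key(b))
}

# Canonical content key of a reaction (id-free variant used for unions).
reaction_content_key <- function(r) {
  paste(paste(r$reactants, collapse = ","),
        paste(r$products, collapse = ","),
        if (r$reversible) "rev" else "irrev", sep = "|")
}

reaction_key <- function(r) paste(r$id, reaction_content_key(r), sep = "|")

#' Pool member networks into a single mixed-bag network
#'
#' Community ("superorganism") semantics: all reactions of all members are
#' pooled into one network, ignoring cell boundaries. Reactions identical in
#' content across members are merged; provenance (which members carry each
#' pooled reaction) is retained in the `provenance` attribute.
#'
#' @param members List of `msc_network` objects.
#' @param id Identifier for the pooled network.
#' @return An `msc_network` whose `provenance` attribute maps each pooled
#'   reaction id to the member ids carrying it.
#' @export
merge_networks <- function(members, id = "community") {
  stopifnot(length(members) >= 1L)
  seen <- new.env(parent = emptyenv())
  pooled <- list()
  prov <- list()
  for (m in members) {
    for (r in m$reactions) {
      k <- reaction_content_key(r)
      if (is.null(seen[[k]])) {
        rid <- r$id
        # reaction ids may clash across members with different content
        if (!is.null(pooled[[rid]])) rid <- paste(m$id, rid, sep = "__")
        seen[[k]] <- rid
        r2 <- r; r2$id <- rid
        pooled[[rid]] <- r2
        prov[[rid]] <- m$id
      } else {
        rid <- seen[[k]]
        prov[[rid]] <- unique(c(prov[[rid]], m$id))
      }
    }
  }
  net <- metabolic_network(id, unname(pooled))
  attr(net, "provenance") <- prov[names(net$reactions)]
  net
}
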