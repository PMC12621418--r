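#' Declare a simulated system
#'
#' A system is one site's metabolic model at one of two scales: a single
#' community-wide metagenome network (`metagenome`), or a collection of
#' genome-resolved member networks, one per MAG (`genome_resolved`).
#'
#' @param site Site identifier.
#' @param scale `"metagenome"` or `"genome_resolved"`.
#' @param members List of `msc_network` objects with unique ids; length 1
#'   when `scale = "metagenome"`.
#' @return An object of class `msc_system`.
#' @export
system_spec <- function(site, scale = c("metagenome", "genome_resolved"),
                        members) {
  scale <- match.arg(scale)
  if (length(members) < 1L) stop2("a system needs at least one member network")
  if (scale == "metagenome" && length(members) != 1L)
    stop2("a metagenome-scale system has exactly one member network")
  ids <- vapply(members, `[[`, character(1), "id")
  if (anyDuplicated(ids))
    stop2("duplicate member ids: ",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(members) <- ids
  members <- members[order_ids(ids)]
  structure(list(site = site, scale = scale, members = members),
            class = "msc_system")
}

#' @export
print.msc_system <- function(x, ...) {
  cat(sprintf("<system '%s' (%s): %d member network(s)>\n",
              x$site, x$scale, length(x$members)))
  invisible(x)
}

sim_id <- function(site, scale, condition) paste(site, scale, condition, sep = "|")

#' Individual scopes of a system's members
#'
#' Each member's scope is computed independently with [expansion_scope()]:
#' what each organism could synthesize on its own from the condition's
#' seeds, without any cross-feeding.
#'
#' @param system An `msc_system`.
#' @param condition An `msc_condition`.
#' @param include_seeds Passed to [expansion_scope()].
#' @return Named list mapping member id to its sorted scope.
#' @export
individual_scopes <- function(system, condition, include_seeds = FALSE) {
  lapply(system$members, function(m)
    as.character(expansion_scope(m, condition$seeds, include_seeds)))
}

#' Mixed-bag community scope
#'
#' The scope of the pooled union of all member networks ("superorganism"
#' semantics): every reaction of every member is available to the
#' community, so the result is the upper bound of what cross-feeding
#' interactions could make producible. It is a superset of every
#' individual member scope.
#'
#' @inheritParams individual_scopes
#' @return Sorted character vector of producible metabolite ids (with the
#'   `fired` attribute of [expansion_scope()]).
#' @export
community_scope <- function(system, condition, include_seeds = FALSE) {
  net <- if (length(system$members) == 1L) system$members[[1L]]
         else merge_networks(system$members, id = paste0(system$site, "_community"))
  expansion_scope(net, condition$seeds, include_seeds)
}

#' Cooperation potential of a genome-resolved system
#'
#' Assembles, for one system and condition, the community scope, the
#' individual member scopes, and the cooperation-only set: metabolites in
#' the community scope but in no individual scope, i.e. producible only
#' through putative cross-feeding ("added value" of the community).
#'
#' @inheritParams individual_scopes
#' @return An object of class `msc_scope_result` with elements `site`,
#'   `scale`, `condition`, `community_scope`, `per_member_scopes`,
#'   `cooperation_only`.
#' @export
cooperation_potential <- function(system, condition, include_seeds = FALSE) {
  if (system$scale != "genome_resolved")
    stop2("cooperation_potential() requires a genome-resolved system")
  per_member <- individual_scopes(system, condition, include_seeds)
  comm <- as.character(community_scope(system, condition, include_seeds))
  coop <- setdiff(comm, unique(unlist(per_member, use.names = FALSE)))
  structure(list(site = system$site, scale = system$scale,
                 condition = condition$name,
                 community_scope = comm,
                 per_member_scopes = per_member,
                 cooperation_only = sort_ids(coop)),
            class = "msc_scope_result")
}

#' @export
print.msc_scope_result <- function(x, ...) {
  cat(sprintf("<scope result %s/%s under '%s': community %d, cooperation-only %d>\n",
              x$site, x$scale, x$condition,
              length(x$community_scope), length(x$cooperation_only)))
  invisible(x)
}

#' Serialize a scope result to JSON
#' @param result An `msc_scope_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scope_result <- function(result, path) {
  write_json_canonical(unclass(result), path)
}
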