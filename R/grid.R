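#' Run the full simulation grid
#'
#' Computes one scope per (system, condition) cell — the canonical design is
#' 6 sites x 2 scales x 5 conditions = 60 simulations — and assembles the
#' binary producibility matrix: rows are metabolites (the union of all
#' scopes), columns are simulations, entries are 1 when the metabolite is in
#' that simulation's scope.
#'
#' @param systems List of `msc_system` objects; (site, scale) pairs must be
#'   unique.
#' @param conditions List of `msc_condition` objects (or an
#'   `msc_condition_library`).
#' @param include_seeds Scope convention; recorded in the matrix metadata.
#' @return An object of class `msc_matrix`: list with `values` (binary
#'   matrix, rownames metabolite ids, colnames simulation ids),
#'   `columns` (data.frame of sim_id/site/scale/condition), `convention`,
#'   and `scope_sizes` (per-cell scope sizes).
#' @export
run_grid <- function(systems, conditions, include_seeds = FALSE) {
  conditions <- unclass(conditions)
  cells <- expand.grid(sys = seq_along(systems), cond = seq_along(conditions),
                       KEEP.OUT.ATTRS = FALSE)
  ids <- mapply(function(i, j) sim_id(systems[[i]]$site, systems[[i]]$scale,
                                      conditions[[j]]$name),
                cells$sys, cells$cond)
  if (anyDuplicated(ids))
    stop2("duplicate simulation cell(s): ",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))

  scopes <- vector("list", nrow(cells))
  for (k in seq_len(nrow(cells))) {
    sys <- systems[[cells$sys[k]]]
    cond <- conditions[[cells$cond[k]]]
    scopes[[k]] <- as.character(community_scope(sys, cond, include_seeds))
  }
  names(scopes) <- ids

  rows <- sort_ids(unlist(scopes, use.names = FALSE))
  values <- matrix(0L, nrow = length(rows), ncol = length(ids),
                   dimnames = list(rows, ids))
  for (k in seq_along(scopes)) values[scopes[[k]], k] <- 1L

  columns <- data.frame(
    sim_id = ids,
    site = vapply(cells$sys, function(i) systems[[i]]$site, character(1)),
    scale = vapply(cells$sys, function(i) systems[[i]]$scale, character(1)),
    condition = vapply(cells$cond, function(j) conditions[[j]]$name, character(1)),
    stringsAsFactors = FALSE
  )
  structure(list(values = values, columns = columns,
                 convention = if (include_seeds) "seeds_included" else "seeds_excluded",
                 scope_sizes = lengths(scopes)),
            class = "msc_matrix")
}

#' @export
print.msc_matrix <- function(x, ...) {
  cat(sprintf("<producibility matrix: %d metabolites x %d simulations (%s)>\n",
              nrow(x$values), ncol(x$values), x$convention))
  invisible(x)
}

#' Remove gap-fill artifacts from a producibility matrix
#'
#' Metabolites predicted producible in at least one genome-resolved
#' (MAG-collection) simulation but in no metagenome simulation are treated
#' as artifacts of gap-filling during MAG network reconstruction and
#' removed. The operation is idempotent.
#'
#' @param matrix An `msc_matrix` containing both scales; with a single
#'   scale the matrix is returned unchanged with a warning.
#' @return List with `matrix` (filtered `msc_matrix`) and `removed`
#'   (character vector of removed metabolite ids).
#' @export
filter_gapfill_artifacts <- function(matrix) {
  scales <- unique(matrix$columns$scale)
  if (!all(c("metagenome", "genome_resolved") %in% scales)) {
    warn2("matrix has a single scale; gap-fill artifact filter is a no-op")
    return(list(matrix = matrix, removed = character(0)))
  }
  mag_cols <- matrix$columns$sim_id[matrix$columns$scale == "genome_resolved"]
  metag_cols <- matrix$columns$sim_id[matrix$columns$scale == "metagenome"]
  v <- matrix$values
  artifact <- rowSums(v[, mag_cols, drop = FALSE]) > 0 &
    rowSums(v[, metag_cols, drop = FALSE]) == 0
  removed <- rownames(v)[artifact]
  matrix$values <- v[!artifact, , drop = FALSE]
  list(matrix = matrix, removed = removed)
}

#' Collapse matrix rows into metabolite groups
#'
#' Metabolites with identical producibility vectors across all simulations
#' are collapsed into one metabolite group (a unique binary vector). Groups
#' are named `g0001`, `g0002`, ... after sorting by (vector as bit-string,
#' then first member id), which makes group ids reproducible.
#'
#' @param matrix A filtered `msc_matrix`.
#' @return An object of class `msc_groups`: list of groups, each with
#'   `id`, `members`, `vector` (named 0/1 integer vector over simulations);
#'   the `columns` attribute carries the matrix column metadata.
#' @export
collapse_groups <- function(matrix) {
  v <- matrix$values
  key <- apply(v, 1L, paste, collapse = "")
  split_members <- split(rownames(v), key)
  first_member <- vapply(split_members, function(m) sort_ids(m)[1L], character(1))
  ord <- order(names(split_members), first_member, method = "radix")
  split_members <- split_members[ord]
  groups <- vector("list", length(split_members))
  for (i in seq_along(split_members)) {
    members <- sort_ids(split_members[[i]])
    groups[[i]] <- list(id = sprintf("g%04d", i), members = members,
                        vector = v[members[1L], ])
  }
  names(groups) <- vapply(groups, `[[`, character(1), "id")
  structure(groups, class = "msc_groups", columns = matrix$columns,
            convention = matrix$convention)
}

#' @export
print.msc_groups <- function(x, ...) {
  sizes <- lengths(lapply(x, `[[`, "members"))
  cat(sprintf("<%d metabolite groups over %d metabolites (largest %d, singletons %d)>\n",
              length(x), sum(sizes), if (length(sizes)) max(sizes) else 0L,
              sum(sizes == 1L)))
  invisible(x)
}

#' Group producibility vectors as a matrix
#' @param groups An `msc_groups` object.
#' @return Binary matrix, groups x simulations.
#' @export
group_matrix <- function(groups) {
  do.call(rbind, lapply(groups, `[[`, "vector"))
}

#' Core metabolites of one scale
#'
#' Metabolites producible in every (site, condition) combination of the
#' given scale.
#'
#' @param matrix An `msc_matrix` (typically filtered).
#' @param scale `"metagenome"` or `"genome_resolved"`.
#' @return Sorted character vector of metabolite ids.
#' @export
core_metabolites <- function(matrix, scale = c("metagenome", "genome_resolved")) {
  scale <- match.arg(scale)
  cols <- matrix$columns$sim_id[matrix$columns$scale == scale]
  if (!length(cols)) stop2("matrix has no '", scale, "' columns")
  v <- matrix$values[, cols, drop = FALSE]
  sort_ids(rownames(v)[rowSums(v) == length(cols)])
}

#' Write a producibility matrix as TSV
#' @param matrix An `msc_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(matrix, path) {
  df <- data.frame(metabolite = rownames(matrix$values), matrix$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a metabolite group table as TSV
#' @param groups An `msc_groups` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_groups_tsv <- function(groups, path) {
  df <- data.frame(
    group = names(groups),
    size = vapply(groups, function(g) length(g$members), integer(1)),
    members = vapply(groups, function(g) paste(g$members, collapse = ","), character(1)),
    vector = vapply(groups, function(g) paste(g$vector, collapse = ""), character(1))
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
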