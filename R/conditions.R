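# Canonical condition sizes: basal medium plus its four extensions.
CANONICAL_CONDITION_SIZES <- c(
  basal_medium = 43L,
  simple_sugars = 50L,
  complex_sugars = 64L,
  non_sulfured_amino_acids = 61L,
  all_amino_acids = 63L
)

#' Construct a seed condition
#'
#' A named set of seed metabolites used to initialize network expansion.
#' The canonical design uses a basal medium (inorganic nutrients, metal
#' ions, coenzymes) contained in every other condition, extended with
#' simple sugars, complex sugars (soil organic matter), the eighteen
#' non-sulfur amino acids, or all twenty amino acids.
#'
#' @param name Condition name.
#' @param seeds Character vector of metabolite ids.
#' @param parent Optional name of the condition this one extends.
#' @param placeholders Optional character vector flagging member ids that
#'   stand in for compounds not identified by name in the source tables.
#' @return An object of class `msc_condition`.
#' @export
seed_condition <- function(name, seeds, parent = NULL, placeholders = character(0)) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop2("condition name must be a non-empty string")
  structure(list(name = name, seeds = sort_ids(seeds), parent = parent,
                 placeholders = sort_ids(placeholders)),
            class = "msc_condition")
}

#' @export
print.msc_condition <- function(x, ...) {
  cat(sprintf("<seed condition '%s': %d seeds%s%s>\n", x$name,
              length(x$seeds),
              if (!is.null(x$parent)) paste0(", extends ", x$parent) else "",
              if (length(x$placeholders))
                sprintf(", %d placeholder ids", length(x$placeholders)) else ""))
  invisible(x)
}

#' Extend a parent condition with additional seeds
#'
#' Union semantics: the new condition's seed set is the parent's seeds plus
#' the additions (overlap permitted).
#'
#' @param name Name of the new condition.
#' @param parent A `msc_condition`, or `NULL` for a stand-alone condition.
#' @param additions Character vector of metabolite ids to add.
#' @return An `msc_condition`.
#' @export
build_condition <- function(name, parent = NULL, additions = character(0)) {
  base <- if (is.null(parent)) character(0) else parent$seeds
  seed_condition(name, c(base, additions),
                 parent = if (is.null(parent)) NULL else parent$name,
                 placeholders = if (is.null(parent)) character(0) else parent$placeholders)
}

#' Load a condition library from a YAML file
#'
#' The file lists conditions in order; each entry has a `name` and either
#' explicit `members` or a `parent` (defined earlier in the file) plus
#' `additions`. Member entries are plain ids or maps
#' `{id: ..., placeholder: true}` flagging compounds whose exact identity
#' is not given by name in the source tables.
#'
#' Validation: names unique; parents known; for the five canonical
#' condition names, sizes must equal 43/50/64/61/63, the basal medium must
#' be contained in each extension, and the all/non-sulfur amino-acid
#' conditions must differ by exactly the two sulfur amino acids.
#'
#' @param path Path to the YAML library; defaults to the packaged canonical
#'   library.
#' @return An object of class `msc_condition_library`: a named list of
#'   `msc_condition` objects with a `provenance` attribute.
#' @export
load_condition_library <- function(path = system.file("extdata", "condition_library.yaml",
                                                      package = "metascope")) {
  doc <- yaml::read_yaml(path)
  entries <- doc$conditions %||% stop2("no `conditions` entry in '", path, "'")
  lib <- list()
  for (e in entries) {
    nm <- e$name %||% stop2("condition without a name in '", path, "'")
    if (!is.null(lib[[nm]])) stop2("duplicated condition name '", nm, "'")
    parse_members <- function(xs) {
      ids <- character(0); ph <- character(0)
      for (x in xs %||% list()) {
        if (is.character(x)) ids <- c(ids, x)
        else {
          ids <- c(ids, x$id)
          if (isTRUE(x$placeholder)) ph <- c(ph, x$id)
        }
      }
      list(ids = ids, placeholders = ph)
    }
    if (!is.null(e$parent)) {
      parent <- lib[[e$parent]] %||%
        stop2("condition '", nm, "' extends unknown parent '", e$parent, "'")
      add <- parse_members(e$additions)
      cond <- seed_condition(nm, c(parent$seeds, add$ids), parent = e$parent,
                             placeholders = c(parent$placeholders, add$placeholders))
    } else {
      mem <- parse_members(e$members)
      cond <- seed_condition(nm, mem$ids, placeholders = mem$placeholders)
    }
    lib[[nm]] <- cond
  }
  lib <- structure(lib, class = "msc_condition_library",
                   provenance = doc$provenance %||% path)
  validate_condition_library(lib)
  lib
}

#' Validate a condition library against the canonical design invariants
#'
#' @param library An `msc_condition_library`.
#' @return `library`, invisibly; errors list every violated invariant.
#' @export
validate_condition_library <- function(library) {
  problems <- character(0)
  sizes <- CANONICAL_CONDITION_SIZES
  for (nm in intersect(names(sizes), names(library))) {
    got <- length(library[[nm]]$seeds)
    if (got != sizes[[nm]])
      problems <- c(problems, sprintf("'%s' has %d seeds, expected %d",
                                      nm, got, sizes[[nm]]))
  }
  basal <- library[["basal_medium"]]
  if (!is.null(basal)) {
    for (nm in setdiff(intersect(names(sizes), names(library)), "basal_medium")) {
      missing <- setdiff(basal$seeds, library[[nm]]$seeds)
      if (length(missing))
        problems <- c(problems, sprintf("'%s' does not contain the basal medium (missing %d ids)",
                                        nm, length(missing)))
    }
  }
  if (all(c("all_amino_acids", "non_sulfured_amino_acids") %in% names(library))) {
    aa <- library[["all_amino_acids"]]$seeds
    ns <- library[["non_sulfured_amino_acids"]]$seeds
    if (length(setdiff(ns, aa)))
      problems <- c(problems, "'non_sulfured_amino_acids' is not a subset of 'all_amino_acids'")
    d <- setdiff(aa, ns)
    if (length(d) != 2L)
      problems <- c(problems, sprintf(
        "all_amino_acids \\ non_sulfured_amino_acids has %d elements (%s), expected the 2 sulfur amino acids",
        length(d), paste(d, collapse = ", ")))
  }
  if (length(problems))
    stop2("condition library validation failed:\n  - ",
          paste(problems, collapse = "\n  - "))
  invisible(library)
}

#' @export
print.msc_condition_library <- function(x, ...) {
  cat(sprintf("<condition library: %d conditions>\n", length(x)))
  for (cond in x)
    cat(sprintf("  %-26s %3d seeds\n", cond$name, length(cond$seeds)))
  invisible(x)
}

#' Write a condition's seed set as an SBML species list
#'
#' Interoperability export for external scope tools that accept seeds as
#' SBML files.
#'
#' @param condition An `msc_condition`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_condition_sbml <- function(condition, path) {
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<sbml xmlns="%s" level="3" version="1">', SBML_NS),
    sprintf('  <model id="%s">', condition$name),
    '    <listOfSpecies>',
    sprintf('      <species id="%s"/>', condition$seeds),
    '    </listOfSpecies>',
    '  </model>',
    '</sbml>'
  )
  writeLines(lines, path)
  invisible(path)
}
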