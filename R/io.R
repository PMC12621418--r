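SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"

#' Read a metabolic network from SBML
#'
#' Reads the Level 3 subset used by this package: `listOfSpecies`,
#' `listOfReactions` with `listOfReactants`/`listOfProducts` species
#' references, and the `reversible` attribute. Stoichiometric coefficients
#' are discarded (Boolean semantics). Species never referenced by a
#' reaction are dropped (their count is recorded in the parse report);
#' boundary/exchange species are kept as ordinary metabolites. Reactions
#' missing a reactant or product side are skipped with a warning.
#'
#' @param path Path to an SBML file.
#' @param id Network id; defaults to the SBML model id, else the file name.
#' @return An `msc_network`; the `parse_report` attribute records
#'   `n_species_dropped` and `skipped_reactions`.
#' @export
parse_sbml <- function(path, id = NULL) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    stop2("malformed XML in '", path, "': ", conditionMessage(e)))
  xml2::xml_ns_strip(doc)
  model <- xml2::xml_find_first(doc, ".//model")
  if (inherits(model, "xml_missing"))
    stop2("no <model> element in '", path, "'")
  if (is.null(id)) {
    id <- xml2::xml_attr(model, "id")
    if (is.na(id) || !nzchar(id))
      id <- sub("\\.[^.]*$", "", basename(path))
  }

  species <- xml2::xml_attr(
    xml2::xml_find_all(model, ".//listOfSpecies/species"), "id")

  rxn_nodes <- xml2::xml_find_all(model, ".//listOfReactions/reaction")
  reactions <- list()
  skipped <- character(0)
  for (node in rxn_nodes) {
    rid <- xml2::xml_attr(node, "id")
    rev <- identical(tolower(xml2::xml_attr(node, "reversible")), "true")
    reac <- xml2::xml_attr(
      xml2::xml_find_all(node, "./listOfReactants/speciesReference"), "species")
    prod <- xml2::xml_attr(
      xml2::xml_find_all(node, "./listOfProducts/speciesReference"), "species")
    if (length(reac) == 0L || length(prod) == 0L) {
      skipped <- c(skipped, rid)
      next
    }
    reactions[[length(reactions) + 1L]] <- reaction(rid, reac, prod, rev)
  }
  if (length(skipped))
    warn2("skipped ", length(skipped),
          " reaction(s) with an empty reactant or product side in '",
          basename(path), "': ", paste(skipped, collapse = ", "))

  net <- metabolic_network(id, reactions)
  n_dropped <- length(setdiff(species, net$metabolites))
  attr(net, "parse_report") <- list(
    path = path,
    n_species_listed = length(species),
    n_species_dropped = n_dropped,
    skipped_reactions = skipped
  )
  net
}

#' Write a metabolic network as SBML
#'
#' Emits the same Level 3 subset that [parse_sbml()] reads, so that
#' parse/write/parse round-trips reproduce the reaction set exactly.
#' Output is deterministic (species and reactions in sorted id order).
#'
#' @param network An `msc_network`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sbml <- function(network, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<sbml xmlns="%s" level="3" version="1">', SBML_NS),
    sprintf('  <model id="%s">', esc(network$id)),
    '    <listOfSpecies>',
    sprintf('      <species id="%s"/>', esc(network$metabolites)),
    '    </listOfSpecies>',
    '    <listOfReactions>'
  )
  for (r in network$reactions) {
    lines <- c(lines,
      sprintf('      <reaction id="%s" reversible="%s">', esc(r$id),
              if (r$reversible) "true" else "false"),
      '        <listOfReactants>',
      sprintf('          <speciesReference species="%s"/>', esc(r$reactants)),
      '        </listOfReactants>',
      '        <listOfProducts>',
      sprintf('          <speciesReference species="%s"/>', esc(r$products)),
      '        </listOfProducts>',
      '      </reaction>')
  }
  lines <- c(lines, '    </listOfReactions>', '  </model>', '</sbml>')
  writeLines(lines, path)
  invisible(path)
}

#' Read a metabolic network from the tabular dialect
#'
#' Tab-separated file with one row per reaction and columns
#' `id`, `reactants` (comma-joined), `products` (comma-joined),
#' `reversible` (one of `rev`/`irrev`/`true`/`false`). A header row is
#' optional and detected by the literal column names.
#'
#' @param path Path to a TSV file.
#' @param id Network id; defaults to the file name without extension.
#' @return An `msc_network` (same contract as [parse_sbml()]).
#' @export
parse_network_table <- function(path, id = NULL) {
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  raw <- utils::read.delim(path, header = FALSE, colClasses = "character",
                           strip.white = TRUE, blank.lines.skip = TRUE)
  if (ncol(raw) != 4L)
    stop2("expected 4 tab-separated columns in '", path, "', found ", ncol(raw))
  names(raw) <- c("id", "reactants", "products", "reversible")
  if (nrow(raw) && identical(tolower(raw$id[1]), "id")) raw <- raw[-1L, , drop = FALSE]
  if (anyDuplicated(raw$id))
    stop2("duplicate reaction id(s) in '", path, "': ",
          paste(unique(raw$id[duplicated(raw$id)]), collapse = ", "))

  split_ids <- function(x) {
    out <- strsplit(x, ",", fixed = TRUE)[[1]]
    out <- trimws(out)
    out[nzchar(out)]
  }
  rev_map <- c(rev = TRUE, reversible = TRUE, "true" = TRUE,
               irrev = FALSE, irreversible = FALSE, "false" = FALSE)

  reactions <- list()
  skipped <- character(0)
  for (i in seq_len(nrow(raw))) {
    tok <- tolower(raw$reversible[i])
    if (!tok %in% names(rev_map))
      stop2("unknown reversibility token '", raw$reversible[i],
            "' for reaction '", raw$id[i], "'")
    reac <- split_ids(raw$reactants[i])
    prod <- split_ids(raw$products[i])
    if (length(reac) == 0L || length(prod) == 0L) {
      skipped <- c(skipped, raw$id[i])
      next
    }
    reactions[[length(reactions) + 1L]] <-
      reaction(raw$id[i], reac, prod, rev_map[[tok]])
  }
  if (length(skipped))
    warn2("skipped ", length(skipped),
          " reaction(s) with an empty reactant or product side in '",
          basename(path), "': ", paste(skipped, collapse = ", "))
  net <- metabolic_network(id, reactions)
  attr(net, "parse_report") <- list(path = path, n_species_dropped = 0L,
                                    skipped_reactions = skipped)
  net
}

#' Write a metabolic network in the tabular dialect
#' @param network An `msc_network`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_network_table <- function(network, path) {
  rows <- vapply(network$reactions, function(r) {
    paste(r$id, paste(r$reactants, collapse = ","),
          paste(r$products, collapse = ","),
          if (r$reversible) "rev" else "irrev", sep = "\t")
  }, character(1))
  writeLines(c("id\treactants\tproducts\treversible", unname(rows)), path)
  invisible(path)
}

#' Read a seed list
#'
#' Plain text (one metabolite id per line, `#` comments allowed) or an SBML
#' file whose species list is taken as the seed set.
#'
#' @param path File path.
#' @return Sorted character vector of metabolite ids.
#' @export
read_seed_file <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) && grepl("<?xml|<sbml", first, fixed = FALSE)) {
    doc <- xml2::read_xml(path)
    xml2::xml_ns_strip(doc)
    ids <- xml2::xml_attr(xml2::xml_find_all(doc, ".//species"), "id")
    return(sort_ids(ids))
  }
  x <- readLines(path, warn = FALSE)
  x <- trimws(sub("#.*$", "", x))
  sort_ids(x[nzchar(x)])
}
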