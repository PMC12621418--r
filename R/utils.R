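# Internal helpers shared across modules.

# Locale-independent sort; file outputs and group ids must not depend on LC_COLLATE.
sort_ids <- function(x) sort(unique(as.character(x)), method = "radix")

# Stable sort without dropping duplicates.
order_ids <- function(x) order(x, method = "radix")

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)

warn2 <- function(...) warning(..., call. = FALSE)

# Canonical JSON writer used for all serialized artifacts so that identical
# inputs yield byte-identical files.
write_json_canonical <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

# md5 of an R object via its canonical JSON serialization.
object_hash <- function(x) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  write_json_canonical(x, tf)
  unname(tools::md5sum(tf))
}
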