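#' Compact identifiers ("system:value")
#'
#' Entities in a linkset are identified by CURIE-style strings of the form
#' `"system:value"`, e.g. `"ncbigene:4204"` or `"chembl.compound:CHEMBL25"`.
#' The system prefix is a short datasource label and must not contain `":"`
#' or whitespace; the value is everything after the first `":"` and may itself
#' contain colons. Comparison anywhere in the package is exact, case-sensitive
#' string equality on this canonical rendering.
#'
#' @param system Datasource prefix, e.g. `"ncbigene"`.
#' @param value Local identifier within that system.
#' @return `identifier()` returns the canonical `"system:value"` string;
#'   `id_system()` and `id_value()` split a canonical string back into its
#'   parts; `is_curie()` reports whether a string contains a `":"` separator.
#' @examples
#' identifier("ncbigene", "4204")
#' id_system("ncbigene:4204")
#' id_value("chembl.compound:CHEMBL25")
#' is_curie("MECP2")
#' @export
identifier <- function(system, value) {
  system <- as.character(system)
  value <- as.character(value)
  bad <- !nzchar(system) | grepl("[:[:space:]]", system)
  if (any(bad)) {
    abort(sprintf("invalid identifier system: %s",
                  paste(unique(system[bad]), collapse = ", ")))
  }
  if (any(!nzchar(value))) abort("identifier value must be non-empty")
  paste0(system, ":", value)
}

#' @rdname identifier
#' @param id Canonical identifier string(s).
#' @export
id_system <- function(id) sub(":.*$", "", id)

#' @rdname identifier
#' @export
id_value <- function(id) sub("^[^:]*:", "", id)

#' @rdname identifier
#' @export
is_curie <- function(id) grepl(":", id, fixed = TRUE)

# Fixed rendering of an identifier set: lexically sorted, comma-joined,
# bracketed, no spaces. Used verbatim in the XGMML "identifiers" att.
render_id_set <- function(ids) {
  paste0("[", paste(sort(unique(ids)), collapse = ","), "]")
}

parse_id_set <- function(s) {
  s <- sub("^\\[", "", sub("\\]$", "", s))
  if (!nzchar(s)) return(character())
  strsplit(s, ",", fixed = TRUE)[[1]]
}
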