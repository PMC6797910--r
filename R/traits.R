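#' Read a per-taxon trait table
#'
#' Reads a two-column TSV (`taxon`, `value`, with header; `#` comment lines
#' allowed).  Depth records in meters can be mapped onto the log10 scale used
#' for habitat-depth analyses.
#'
#' @param path Path to the TSV file.
#' @param transform `"none"` (default) or `"log10_depth"`, which maps each
#'   value `v` (meters, > 0) to `log10(v)`.
#' @return A tibble with columns `taxon` (character) and `value` (double).
#' @export
read_trait_table <- function(path, transform = c("none", "log10_depth")) {
  transform <- match.arg(transform)
  tb <- readr::read_tsv(path, comment = "#", col_types = readr::cols(
    taxon = readr::col_character(),
    value = readr::col_double()
  ))
  if (!all(c("taxon", "value") %in% names(tb)))
    stop("trait table must have header columns 'taxon' and 'value'",
         call. = FALSE)
  if (anyDuplicated(tb$taxon))
    stop("duplicate taxon in trait table: ",
         paste(unique(tb$taxon[duplicated(tb$taxon)]), collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(tb$value)))
    stop("non-numeric or non-finite trait value for taxon: ",
         paste(tb$taxon[!is.finite(tb$value)], collapse = ", "), call. = FALSE)
  if (transform == "log10_depth") {
    if (any(tb$value <= 0))
      stop("nonpositive depth for taxon: ",
           paste(tb$taxon[tb$value <= 0], collapse = ", "),
           "; depths must be > 0 m under log10_depth", call. = FALSE)
    tb$value <- log10(tb$value)
  }
  tibble::as_tibble(tb[, c("taxon", "value")])
}

# Accept either the tibble form or a named numeric vector.
as_trait_vector <- function(traits) {
  if (is.data.frame(traits)) {
    stopifnot(all(c("taxon", "value") %in% names(traits)))
    tv <- setNames(as.numeric(traits$value), traits$taxon)
  } else if (is.numeric(traits) && !is.null(names(traits))) {
    tv <- traits
  } else {
    stop("traits must be a (taxon, value) data frame or a named numeric vector",
         call. = FALSE)
  }
  if (anyDuplicated(names(tv))) stop("duplicate taxa in traits", call. = FALSE)
  if (any(!is.finite(tv))) stop("non-finite trait values", call. = FALSE)
  tv
}
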