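#' Parse and render canonical variant keys
#'
#' A variant key is the compact string `"chrom-pos-ref-alt"` used throughout
#' star-allele translation tables, e.g. `"19-41356379-A-C"` for the CYP2A6
#' TATA-box promoter variant. Positions are 1-based and ref/alt follow VCF
#' conventions, so anchored indels such as `"2-234668879-C-CAT"` (the UGT1A1
#' promoter TA insertion) are valid keys.
#'
#' `parse_variant_key()` turns a character vector of keys into a tibble;
#' `render_variant_key()` is its inverse, so
#' `render_variant_key(parse_variant_key(x)) == x`.
#'
#' @param x Character vector of variant keys.
#' @return `parse_variant_key()`: a tibble with columns `chrom`, `pos`
#'   (integer), `ref`, `alt`. `render_variant_key()`: a character vector.
#' @examples
#' parse_variant_key("19-41356379-A-C")
#' render_variant_key(parse_variant_key(c("1-5-A-T", "2-234668879-C-CAT")))
#' @export
parse_variant_key <- function(x) {
  m <- str_match(x, "^([^-]+)-([0-9]+)-([ACGTNacgtn]+)-([ACGTNacgtn]+)$")
  bad <- is.na(m[, 1])
  if (any(bad)) {
    abort(paste0("malformed variant key(s): ",
                 paste(unique(x[bad]), collapse = ", ")),
          class = "pgx_validation_error")
  }
  out <- tibble(
    chrom = m[, 2],
    pos   = as.integer(m[, 3]),
    ref   = toupper(m[, 4]),
    alt   = toupper(m[, 5])
  )
  if (any(out$ref == out$alt)) {
    abort("variant key with identical ref and alt",
          class = "pgx_validation_error")
  }
  if (any(out$pos < 1L)) {
    abort("variant key with non-positive position",
          class = "pgx_validation_error")
  }
  out
}

#' @rdname parse_variant_key
#' @export
render_variant_key <- function(x) {
  stopifnot(is.data.frame(x))
  paste(x$chrom, x$pos, x$ref, x$alt, sep = "-")
}

#' Parse a star-allele name into base name and copy count
#'
#' Duplication and multiplication suffixes follow a strict grammar: a base
#' allele name followed by an optional `"x"` plus an integer, e.g. `"*7x3"`
#' (three tandem copies of CYP2E1*7). Combination/hybrid names such as
#' `"*36x2+*10"` are treated as atomic: the suffix is only parsed when it
#' terminates the full name, so `"*36x2+*10"` has `copies = 1`.
#'
#' @param name Character vector of allele names.
#' @return A tibble with columns `name`, `base` (name without the terminal
#'   copy suffix) and `copies` (integer, 1 when no suffix).
#' @examples
#' parse_allele_name(c("*4", "*1x2", "*7x3", "*36x2+*10"))
#' @export
parse_allele_name <- function(name) {
  m <- str_match(name, "^(.+?)x([0-9]+)$")
  copies <- ifelse(is.na(m[, 1]), 1L, as.integer(m[, 3]))
  base <- ifelse(is.na(m[, 1]), name, m[, 2])
  tibble(name = name, base = base, copies = copies)
}

# numeric core used for canonical diplotype ordering ("*36x2+*10" -> 36)
allele_numeric_core <- function(name) {
  m <- str_match(name, "\\*([0-9]+)")
  as.numeric(m[, 2])
}
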