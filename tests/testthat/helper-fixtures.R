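# Builders for in-code fixtures shared across test files.

suppressPackageStartupMessages({
  library(dplyr)
  library(tibble)
})

# small variant table: sites x samples from a compact spec
# calls: list of lists(chrom, pos, ref, alt, sample, gt = c(a, b), ad = c(r, a))
toy_variant_table <- function(calls, samples = NULL) {
  rows <- lapply(calls, function(cl) {
    tibble(
      chrom = cl$chrom %||% "1", pos = cl$pos, ref = cl$ref %||% "A",
      alt = cl$alt %||% "T", sample = cl$sample,
      gt_1 = cl$gt[1], gt_2 = cl$gt[2],
      phased = cl$phased %||% FALSE,
      ad_ref = if (!is.null(cl$ad)) cl$ad[1] else NA_integer_,
      ad_alt = if (!is.null(cl$ad)) cl$ad[2] else NA_integer_
    )
  })
  variant_table(bind_rows(rows), samples = samples)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# write a minimal VCF text file; records: list of lists(chrom, pos, ref, alt,
# gts = named character vector sample -> "0/1" or "0/1:10,5")
write_toy_vcf <- function(records, samples, path = tempfile(fileext = ".vcf"),
                          format = "GT:AD") {
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body <- vapply(records, function(r) {
    cells <- vapply(samples, function(s) {
      r$gts[[s]] %||% "./."
    }, character(1))
    paste(c(r$chrom %||% "1", r$pos, ".", r$ref %||% "A", r$alt %||% "T",
            ".", "PASS", ".", format, cells), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  path
}

# brute-force per-site concordance oracle: explicit loops, no shared code
# with genotype_concordance()
oracle_concordance <- function(test, truth, samples) {
  to_map <- function(t) {
    m <- list()
    for (i in seq_len(nrow(t))) {
      key <- paste(t$chrom[i], t$pos[i], t$ref[i], t$alt[i], t$sample[i])
      m[[key]] <- c(t$gt_1[i], t$gt_2[i])
    }
    m
  }
  ta <- to_map(as_tibble(test))
  tb <- to_map(as_tibble(truth))
  sites <- unique(rbind(as_tibble(test)[c("chrom", "pos", "ref", "alt")],
                        as_tibble(truth)[c("chrom", "pos", "ref", "alt")]))
  out <- list()
  for (s in samples) {
    compared <- 0; matches <- 0; fp <- 0; fn <- 0
    for (i in seq_len(nrow(sites))) {
      key <- paste(sites$chrom[i], sites$pos[i], sites$ref[i], sites$alt[i], s)
      ga <- if (!is.null(ta[[key]])) ta[[key]] else c(0L, 0L)
      gb <- if (!is.null(tb[[key]])) tb[[key]] else c(0L, 0L)
      if (any(is.na(ga)) || any(is.na(gb))) next
      compared <- compared + 1
      if (identical(sort(ga), sort(gb))) matches <- matches + 1
      if (sum(ga) > 0 && sum(gb) == 0) fp <- fp + 1
      if (sum(ga) == 0 && sum(gb) > 0) fn <- fn + 1
    }
    out[[s]] <- tibble(sample = s, sites_compared = compared,
                       matches = matches,
                       overall_concordance = matches / compared,
                       false_positive_count = fp, false_negative_count = fn)
  }
  bind_rows(out)
}

# small depth matrix over arbitrary positions
toy_depth_matrix <- function(pos, depths, chrom = "1") {
  df <- tibble(chrom = chrom, pos = as.integer(pos))
  for (s in names(depths)) df[[s]] <- depths[[s]]
  depth_matrix(df)
}

# write a translation-table TSV from a tibble-like spec
write_toy_translation <- function(rows, path = tempfile(fileext = ".tsv")) {
  readr::write_tsv(rows, path)
  path
}

# deterministic deletion-heavy cohort truth (75% of samples carry *0):
# 10 hom-deleted, 20 het, 10 diploid
mk_gstt1_del_cohort <- function(lib_factor = 1) {
  truth <- tibble(
    sample = sprintf("S%03d", 1:40),
    allele_1 = c(rep("*0", 10), rep("*0", 20), rep("*A", 10)),
    allele_2 = c(rep("*0", 10), rep("*A", 20), rep("*A", 10)),
    lib_factor = lib_factor
  )
  truth$diplotype <- mapply(function(a, b) render_diplotype(a, b, "*A"),
                            truth$allele_1, truth$allele_2, USE.NAMES = FALSE)
  attr(truth, "gene") <- "GSTT1"
  truth
}
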