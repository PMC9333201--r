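#' Construct a multi-sample variant table
#'
#' The package's working representation of a multi-sample variant call set is
#' a long tibble: one row per (site, sample) with a non-missing record.
#' Columns are `chrom`, `pos` (1-based), `ref`, `alt`, `sample`, `gt_1`,
#' `gt_2` (allele indices, 0 = ref, 1 = alt, `NA` = missing), `phased`
#' (logical) and optional allelic depths `ad_ref`, `ad_alt`. The complete
#' sample list (including samples that are reference-homozygous everywhere)
#' is kept in the `samples` attribute.
#'
#' @param df A data frame with the columns above.
#' @param samples Optional character vector of all sample ids; defaults to
#'   the ids present in `df`.
#' @return A tibble of class `pgx_variant_table`, sites sorted by
#'   (chrom, pos, ref, alt).
#' @export
variant_table <- function(df, samples = NULL) {
  needed <- c("chrom", "pos", "ref", "alt", "sample", "gt_1", "gt_2")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    abort(paste0("variant table missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "pgx_validation_error")
  }
  if (!"phased" %in% names(df)) df$phased <- FALSE
  if (!"ad_ref" %in% names(df)) df$ad_ref <- NA_integer_
  if (!"ad_alt" %in% names(df)) df$ad_alt <- NA_integer_
  ad <- c(df$ad_ref, df$ad_alt)
  if (any(!is.na(ad) & ad < 0)) {
    abort("allelic depths must be nonnegative", class = "pgx_validation_error")
  }
  out <- df |>
    as_tibble() |>
    mutate(pos = as.integer(.data$pos)) |>
    arrange(.data$chrom, .data$pos, .data$ref, .data$alt, .data$sample)
  samples <- samples %||% unique(df$sample)
  if (anyDuplicated(samples)) {
    abort("sample ids must be unique", class = "pgx_validation_error")
  }
  attr(out, "samples") <- samples
  class(out) <- unique(c("pgx_variant_table", class(out)))
  out
}

vt_samples <- function(t) attr(t, "samples") %||% unique(t$sample)

#' Read a target BED file
#'
#' BED intervals are 0-based, half-open; a 1-based position `p` falls in
#' interval `[start, end)` when `start < p <= end`.
#'
#' @param path Path to a 3+ column BED file (no header).
#' @return A tibble with columns `chrom`, `start`, `end`.
#' @export
read_bed <- function(path) {
  bed <- readr::read_tsv(path, col_names = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_guess()))
  if (ncol(bed) < 3) {
    abort("BED file needs at least 3 columns", class = "pgx_validation_error")
  }
  tibble(chrom = as.character(bed[[1]]), start = as.integer(bed[[2]]),
         end = as.integer(bed[[3]]))
}

in_regions <- function(chrom, pos, regions) {
  if (is.null(regions)) return(rep(TRUE, length(pos)))
  hit <- rep(FALSE, length(pos))
  for (i in seq_len(nrow(regions))) {
    hit <- hit | (chrom == regions$chrom[i] &
                    pos > regions$start[i] & pos <= regions$end[i])
  }
  hit
}

#' Read a multi-sample VCF into a variant table
#'
#' Parses a VCF 4.x file (via `vcfR`), honoring the GT and AD format fields,
#' and optionally restricts to target regions. Sites with more than one ALT
#' allele are retained and flagged in the `multiallelic` column so that
#' [drop_multiallelic()] can remove them before comparison.
#'
#' @param path VCF file path (plain text or bgzipped).
#' @param regions Optional BED-style tibble (`chrom`, `start`, `end`;
#'   0-based half-open) from [read_bed()].
#' @return A `pgx_variant_table` with an extra logical column `multiallelic`.
#' @export
read_variant_table <- function(path, regions = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (!nrow(fix)) {
    abort("VCF contains no variant records", class = "pgx_validation_error")
  }
  if (ncol(v@gt) < 2) {
    abort("VCF has no sample columns", class = "pgx_validation_error")
  }
  pos <- as.integer(fix$POS)
  key <- paste(fix$CHROM)
  unsorted <- unlist(tapply(pos, factor(key, levels = unique(key)),
                            function(p) any(diff(p) < 0)))
  if (any(unsorted)) {
    abort("VCF is not position-sorted", class = "pgx_validation_error")
  }

  gt <- vcfR::extract.gt(v, element = "GT")
  ad <- tryCatch(vcfR::extract.gt(v, element = "AD"),
                 error = function(e) NULL)
  samples <- colnames(gt)
  multi <- str_detect(fix$ALT, ",")

  recs <- map(seq_len(nrow(fix)), function(i) {
    alts <- str_split(fix$ALT[i], ",")[[1]]
    g <- gt[i, ]
    present <- !is.na(g) & !g %in% c(".", "./.", ".|.")
    if (!any(present)) return(NULL)
    gsub_g <- g[present]
    phased <- str_detect(gsub_g, "\\|")
    parts <- str_split(gsub_g, "[/|]")
    a1 <- suppressWarnings(as.integer(map_chr(parts, 1)))
    a2 <- suppressWarnings(as.integer(map_chr(parts, ~ .x[min(2, length(.x))])))
    ad_ref <- ad_alt <- rep(NA_integer_, sum(present))
    if (!is.null(ad)) {
      adv <- ad[i, present]
      adp <- str_split(adv, ",")
      ad_ref <- suppressWarnings(as.integer(map_chr(adp, 1)))
      ad_alt <- suppressWarnings(
        as.integer(map_chr(adp, ~ if (length(.x) > 1) .x[2] else NA_character_)))
    }
    tibble(chrom = fix$CHROM[i], pos = pos[i], ref = fix$REF[i],
           alt = alts[[1]], sample = samples[present],
           gt_1 = a1, gt_2 = a2, phased = phased,
           ad_ref = ad_ref, ad_alt = ad_alt,
           multiallelic = multi[i] | a1 > 1 | a2 > 1)
  })
  out <- bind_rows(recs)
  keep <- in_regions(out$chrom, out$pos, regions)
  out <- out[keep, , drop = FALSE]
  variant_table(out, samples = samples)
}

#' Merge two variant tables
#'
#' Takes the union of sites; a sample absent at a site keeps an implicit
#' missing record (interpreted downstream as reference-homozygous). Sample
#' id sets must be disjoint.
#'
#' @param a,b Variant tables.
#' @return A merged `pgx_variant_table`.
#' @export
merge_variant_tables <- function(a, b) {
  shared <- intersect(vt_samples(a), vt_samples(b))
  if (length(shared)) {
    abort(paste0("overlapping sample ids: ", paste(shared, collapse = ", ")),
          class = "pgx_validation_error")
  }
  variant_table(bind_rows(as_tibble(a), as_tibble(b)),
                samples = c(vt_samples(a), vt_samples(b)))
}

#' Remove multiallelic sites
#'
#' Drops every record at a (chrom, pos) that carries more than one distinct
#' ALT allele across samples or records, and any record flagged
#' `multiallelic` at read time. After filtering, every retained site has
#' exactly one ALT.
#'
#' @param t A variant table.
#' @return A biallelic-only `pgx_variant_table`.
#' @export
drop_multiallelic <- function(t) {
  flagged <- if ("multiallelic" %in% names(t)) {
    filter(t, .data$multiallelic) |> distinct(.data$chrom, .data$pos)
  } else {
    tibble(chrom = character(), pos = integer())
  }
  multi_alt <- as_tibble(t) |>
    distinct(.data$chrom, .data$pos, .data$alt) |>
    count(.data$chrom, .data$pos) |>
    filter(.data$n > 1) |>
    select("chrom", "pos")
  bad <- bind_rows(flagged, multi_alt) |> distinct()
  out <- anti_join(as_tibble(t), bad, by = c("chrom", "pos"))
  variant_table(out, samples = vt_samples(t))
}

is_indel <- function(ref, alt) nchar(ref) != nchar(alt)

gt_key <- function(gt_1, gt_2) {
  paste(pmin(gt_1, gt_2), pmax(gt_1, gt_2), sep = "/")
}

#' Per-sample genotype concordance between two call sets
#'
#' Compares each shared sample's genotypes over the union of variant sites
#' (optionally restricted to target regions). A site missing from one table
#' for a sample is treated as reference-homozygous; half-missing genotypes
#' (one allele unknown) are excluded from the compared-site denominator.
#' False positives are sites where the test call is non-reference and the
#' truth is reference/absent; false negatives the converse. Sites are split
#' into SNVs and indels by `nchar(ref) != nchar(alt)`.
#'
#' @param test,truth Biallelic variant tables sharing at least one sample id.
#' @param regions Optional BED-style tibble restricting compared sites.
#' @return A tibble of class `pgx_concordance_report`, one row per shared
#'   sample, with a `cohort_mean` attribute.
#' @export
genotype_concordance <- function(test, truth, regions = NULL) {
  shared <- intersect(vt_samples(test), vt_samples(truth))
  if (!length(shared)) {
    abort("no shared samples between test and truth",
          class = "pgx_validation_error")
  }
  prep <- function(t) {
    as_tibble(t) |>
      filter(.data$sample %in% shared,
             in_regions(.data$chrom, .data$pos, regions)) |>
      select("chrom", "pos", "ref", "alt", "sample", "gt_1", "gt_2")
  }
  a <- prep(test)
  b <- prep(truth)
  sites <- distinct(bind_rows(a, b), .data$chrom, .data$pos, .data$ref,
                    .data$alt)
  full <- tidyr::crossing(sites, sample = shared) |>
    left_join(mutate(a, rec_test = TRUE),
              by = c("chrom", "pos", "ref", "alt", "sample")) |>
    left_join(mutate(b, rec_truth = TRUE),
              by = c("chrom", "pos", "ref", "alt", "sample"),
              suffix = c("_test", "_truth"))
  # a record present in one table but with an unknown allele is half-missing
  # and excluded from the denominator; an absent record is hom-ref
  half_missing <- with(full,
    (!is.na(rec_test) & (is.na(gt_1_test) | is.na(gt_2_test))) |
      (!is.na(rec_truth) & (is.na(gt_1_truth) | is.na(gt_2_truth))))
  hm_by_sample <- full[half_missing, , drop = FALSE] |>
    count(sample = .data$sample, name = "half_missing_excluded")
  full <- full[!half_missing, , drop = FALSE]
  full <- full |>
    mutate(
      gt_1_test = tidyr::replace_na(.data$gt_1_test, 0L),
      gt_2_test = tidyr::replace_na(.data$gt_2_test, 0L),
      gt_1_truth = tidyr::replace_na(.data$gt_1_truth, 0L),
      gt_2_truth = tidyr::replace_na(.data$gt_2_truth, 0L)
    ) |>
    mutate(
      indel = is_indel(.data$ref, .data$alt),
      match = gt_key(.data$gt_1_test, .data$gt_2_test) ==
        gt_key(.data$gt_1_truth, .data$gt_2_truth),
      nonref_test = .data$gt_1_test + .data$gt_2_test > 0,
      nonref_truth = .data$gt_1_truth + .data$gt_2_truth > 0
    )
  report <- full |>
    group_by(sample = .data$sample) |>
    summarize(
      sites_compared = n(),
      matches = sum(.data$match),
      overall_concordance = mean(.data$match),
      snv_concordance = ifelse(sum(!.data$indel) > 0,
                               mean(.data$match[!.data$indel]), NA_real_),
      indel_concordance = ifelse(sum(.data$indel) > 0,
                                 mean(.data$match[.data$indel]), NA_real_),
      false_positive_count = sum(.data$nonref_test & !.data$nonref_truth),
      false_negative_count = sum(!.data$nonref_test & .data$nonref_truth),
      .groups = "drop"
    ) |>
    left_join(hm_by_sample, by = "sample") |>
    mutate(half_missing_excluded =
             tidyr::replace_na(.data$half_missing_excluded, 0L))
  attr(report, "cohort_mean") <- mean(report$overall_concordance)
  attr(report, "site_union") <- nrow(sites)
  attr(report, "per_sample_nonmissing") <-
    c(test = nrow(a), truth = nrow(b))
  class(report) <- c("pgx_concordance_report", class(report))
  report
}

#' Flag samples with low genotype concordance
#'
#' Returns the ids of samples whose overall concordance falls below a
#' threshold — the signature of sample swaps or labeling errors, which show
#' up as one outlier far below the cohort mean.
#'
#' @param report A [genotype_concordance()] report.
#' @param threshold Concordance threshold in (0, 1); default 0.90.
#' @return Sorted character vector of flagged sample ids.
#' @export
flag_discordant_samples <- function(report, threshold = 0.90) {
  stopifnot(threshold >= 0, threshold < 1)  # 0 is vacuous: nothing flagged
  sort(report$sample[report$overall_concordance < threshold])
}

#' Write a variant table as a minimal VCF
#'
#' Emits a VCF 4.2 body with GT and AD fields, suitable for re-reading with
#' [read_variant_table()]. Missing samples at a site are written as `0/0`.
#'
#' @param t A variant table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variant_vcf <- function(t, path) {
  samples <- vt_samples(t)
  sites <- distinct(as_tibble(t), .data$chrom, .data$pos, .data$ref,
                    .data$alt) |>
    arrange(.data$chrom, .data$pos, .data$ref, .data$alt)
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body <- map_chr(seq_len(nrow(sites)), function(i) {
    s <- sites[i, ]
    recs <- filter(as_tibble(t), .data$chrom == s$chrom, .data$pos == s$pos,
                   .data$ref == s$ref, .data$alt == s$alt)
    cells <- map_chr(samples, function(sm) {
      r <- filter(recs, .data$sample == sm)
      if (!nrow(r)) return("0/0:.,.")
      sep <- if (isTRUE(r$phased[1])) "|" else "/"
      gt <- paste(r$gt_1[1], r$gt_2[1], sep = sep)
      ad <- if (is.na(r$ad_ref[1])) ".,." else paste(r$ad_ref[1], r$ad_alt[1],
                                                    sep = ",")
      paste0(gt, ":", ad)
    })
    paste(c(s$chrom, s$pos, ".", s$ref, s$alt, ".", "PASS", ".", "GT:AD",
            cells), collapse = "\t")
  })
  writeLines(c(header, body), path)
  invisible(path)
}
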