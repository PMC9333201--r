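#' Read a per-base depth-of-coverage matrix
#'
#' The depth file is tab-separated with a header `chrom pos <sample1>
#' <sample2> ...` and 1-based positions (matching VCF coordinates; the BED
#' used to restrict it remains 0-based half-open). Positions outside the
#' target intervals are dropped with a warning.
#'
#' @param path Depth TSV path.
#' @param bed Target intervals (`chrom`, `start`, `end`; 0-based half-open),
#'   or `NULL` to keep all rows.
#' @return A tibble of class `pgx_depth_matrix`: `chrom`, `pos`, then one
#'   numeric depth column per sample (file order preserved).
#' @export
read_depth_matrix <- function(path, bed = NULL) {
  d <- read_pgx_tsv(path, readr::cols(chrom = readr::col_character(),
                                      .default = readr::col_character()))
  if (!all(c("chrom", "pos") %in% names(d))) {
    abort("depth file needs 'chrom' and 'pos' columns",
          class = "pgx_validation_error")
  }
  samples <- setdiff(names(d), c("chrom", "pos"))
  if (!length(samples)) {
    abort("depth file has no sample columns", class = "pgx_validation_error")
  }
  for (s in c("pos", samples)) {
    v <- suppressWarnings(as.numeric(d[[s]]))
    if (any(is.na(v) & !is.na(d[[s]]))) {
      abort(paste0("non-numeric values in column '", s, "'"),
            class = "pgx_validation_error")
    }
    d[[s]] <- v
  }
  d$pos <- as.integer(d$pos)
  depth_matrix(d, bed = bed)
}

#' @rdname read_depth_matrix
#' @param df A data frame with `chrom`, `pos` and sample depth columns.
#' @export
depth_matrix <- function(df, bed = NULL) {
  samples <- setdiff(names(df), c("chrom", "pos"))
  vals <- as.matrix(df[samples])
  if (any(vals < 0, na.rm = TRUE)) {
    abort("depths must be nonnegative", class = "pgx_validation_error")
  }
  if (!is.null(bed)) {
    keep <- in_regions(df$chrom, df$pos, bed)
    if (!any(keep)) {
      abort("no targeted positions: depth file and BED do not intersect",
            class = "pgx_io_error")
    }
    if (any(!keep)) {
      warn(paste0("dropping ", sum(!keep),
                  " depth positions outside target intervals"))
    }
    df <- df[keep, , drop = FALSE]
  }
  out <- as_tibble(df) |> arrange(.data$chrom, .data$pos)
  attr(out, "samples") <- samples
  class(out) <- unique(c("pgx_depth_matrix", class(out)))
  out
}

dm_samples <- function(d) attr(d, "samples") %||%
  setdiff(names(d), c("chrom", "pos"))

dm_values <- function(d) as.matrix(as_tibble(d)[dm_samples(d)])

#' Coverage summary of a depth matrix
#'
#' Computes the arithmetic mean depth over all targeted base-sample cells,
#' per-sample means, and the fraction of cells at or above each depth
#' threshold (uniformity). Fractions are monotone non-increasing in the
#' threshold by construction.
#'
#' @param d A depth matrix.
#' @param thresholds Positive depth thresholds (default `c(30, 100)`).
#' @return An object of class `pgx_coverage_summary`: a list with
#'   `mean_depth`, a `per_sample` tibble, and a `uniformity` tibble
#'   (`threshold`, `fraction`). Has a [tidy()] method.
#' @export
coverage_summary <- function(d, thresholds = c(30, 100)) {
  stopifnot(all(thresholds > 0))
  vals <- dm_values(d)
  if (!length(vals)) {
    abort("empty depth matrix", class = "pgx_validation_error")
  }
  out <- list(
    mean_depth = mean(vals),
    per_sample = tibble(sample = dm_samples(d),
                        mean_depth = colMeans(vals)),
    uniformity = tibble(threshold = sort(thresholds),
                        fraction = map_dbl(sort(thresholds),
                                           ~ mean(vals >= .x)))
  )
  class(out) <- "pgx_coverage_summary"
  out
}

#' @export
tidy.pgx_coverage_summary <- function(x, ...) {
  bind_rows(
    tibble(metric = "mean_depth", threshold = NA_real_, value = x$mean_depth),
    mutate(x$uniformity, metric = "fraction_at_least", value = .data$fraction,
           .keep = "unused")
  ) |> select("metric", "threshold", "value")
}

#' @export
print.pgx_coverage_summary <- function(x, ...) {
  cat(sprintf("Coverage: mean %.1fx over %d samples\n",
              x$mean_depth, nrow(x$per_sample)))
  for (i in seq_len(nrow(x$uniformity))) {
    cat(sprintf("  >= %gx: %.1f%%\n", x$uniformity$threshold[i],
                100 * x$uniformity$fraction[i]))
  }
  invisible(x)
}

#' Control-gene statistics for intra-sample depth normalization
#'
#' The per-sample location statistic (median) of depth over the control
#' locus. The median is robust to focal CNVs inside the control gene.
#' Samples with a zero statistic are marked unusable.
#'
#' @param d A depth matrix that covers the control locus.
#' @param control_gene Control gene symbol (default `"VDR"`); its interval is
#'   taken from [pgx_gene_models()] unless `region` is given.
#' @param region Optional tibble (`chrom`, `start`, `end`, 1-based inclusive)
#'   overriding the registry interval.
#' @return A tibble of class `pgx_control_stats`: `sample`, `control_stat`,
#'   `usable`; the control gene symbol is kept as an attribute.
#' @export
compute_control_statistics <- function(d, control_gene = "VDR",
                                       region = NULL) {
  if (is.null(region)) {
    gm <- gene_model(control_gene)
    region <- tibble(chrom = gm$chrom, start = gm$gene_start,
                     end = gm$gene_end)
  }
  rows <- as_tibble(d)$chrom == region$chrom &
    as_tibble(d)$pos >= region$start & as_tibble(d)$pos <= region$end
  if (!any(rows)) {
    abort(paste0("control region (", control_gene,
                 ") absent from depth matrix"),
          class = "pgx_validation_error")
  }
  vals <- dm_values(d)[rows, , drop = FALSE]
  stat <- unname(apply(vals, 2, median))
  out <- tibble(sample = dm_samples(d), control_stat = stat,
                usable = stat > 0)
  attr(out, "control_gene") <- control_gene
  class(out) <- c("pgx_control_stats", class(out))
  out
}

#' Copy-number profiles by control-gene and cohort normalization
#'
#' Converts per-base depth to copy number in two steps. Intra-sample: each
#' depth is scaled by the sample's control-gene statistic,
#' `cn_raw(s, p) = 2 * depth(s, p) / control_stat(s)`, which removes
#' library-size differences. Inter-sample (required for targeted capture,
#' where probe efficiency varies by position): each position's cohort
#' reference — the median of `cn_raw` at `p` over a designated sample set —
#' is rescaled to 2, `cn(s, p) = cn_raw(s, p) * 2 / ref(p)`. With
#' `cohort_mode = "all_samples"` the reference uses every usable sample;
#' with `"no_sv_samples"` it uses only samples declared free of structural
#' variation in the gene — essential when deletion carriers are the cohort
#' majority (e.g. GSTT1), where the all-sample median itself sits on a
#' deleted copy state.
#'
#' Positions with zero depth in more than half of the samples are masked
#' (capture dropouts), as are positions whose cohort reference is not
#' positive. Copy numbers are reported unrounded.
#'
#' @param d A depth matrix covering the gene (and pseudogene) region.
#' @param gene Gene symbol (must be in [pgx_gene_models()]).
#' @param control_stats Output of [compute_control_statistics()].
#' @param cohort_mode `"all_samples"` or `"no_sv_samples"`.
#' @param no_sv_ids Sample ids known to carry no SV in `gene`; required for
#'   `"no_sv_samples"`.
#' @return A long tibble of class `pgx_cn_profile`: `sample`, `chrom`, `pos`,
#'   `region`, `cn`, `masked`, with normalization provenance in attributes.
#' @export
copy_number_profile <- function(d, gene, control_stats,
                                cohort_mode = c("all_samples",
                                                "no_sv_samples"),
                                no_sv_ids = NULL) {
  cohort_mode <- match.arg(cohort_mode)
  gm <- gene_model(gene)
  dt <- as_tibble(d)
  in_gene <- dt$chrom == gm$chrom & dt$pos >= gm$gene_start &
    dt$pos <= gm$gene_end
  in_pseudo <- !is.na(gm$pseudo_start) & dt$chrom == gm$chrom &
    dt$pos >= gm$pseudo_start & dt$pos <= gm$pseudo_end
  rows <- in_gene | in_pseudo
  if (!any(rows)) {
    abort(paste0("gene region ", gene, " absent from depth matrix"),
          class = "pgx_validation_error")
  }
  region <- ifelse(in_gene[rows], "gene", "pseudogene")
  pos <- dt$pos[rows]
  chrom <- dt$chrom[rows]
  vals <- dm_values(d)[rows, , drop = FALSE]

  samples <- dm_samples(d)
  cs <- control_stats[match(samples, control_stats$sample), ]
  if (any(is.na(cs$control_stat))) {
    abort("control statistics missing for some samples",
          class = "pgx_validation_error")
  }
  usable <- cs$usable
  if (any(!usable)) {
    warn(paste0("excluding sample(s) with zero control statistic: ",
                paste(samples[!usable], collapse = ", ")))
    samples <- samples[usable]
    vals <- vals[, usable, drop = FALSE]
    cs <- cs[usable, ]
  }

  cn_raw <- sweep(vals, 2, 2 / cs$control_stat, `*`)
  masked <- rowMeans(vals == 0) > 0.5

  ref_set <- if (cohort_mode == "no_sv_samples") {
    if (is.null(no_sv_ids) || !length(intersect(no_sv_ids, samples))) {
      abort("cohort_mode = 'no_sv_samples' needs a non-empty no_sv_ids set",
            class = "pgx_validation_error")
    }
    intersect(no_sv_ids, samples)
  } else {
    samples
  }
  ref <- apply(cn_raw[, samples %in% ref_set, drop = FALSE], 1, median)
  masked <- masked | !(is.finite(ref) & ref > 0)
  scale <- ifelse(masked, NA_real_, 2 / ref)
  cn <- sweep(cn_raw, 1, scale, `*`)

  out <- tibble(
    sample = rep(samples, each = length(pos)),
    chrom = rep(chrom, times = length(samples)),
    pos = rep(pos, times = length(samples)),
    region = rep(region, times = length(samples)),
    cn = as.vector(cn),
    masked = rep(masked, times = length(samples))
  )
  attr(out, "gene") <- gene
  attr(out, "control_gene") <- attr(control_stats, "control_gene") %||% "VDR"
  attr(out, "cohort_mode") <- cohort_mode
  attr(out, "normalization") <- "per-position cohort median rescaled to 2"
  class(out) <- c("pgx_cn_profile", class(out))
  out
}

#' Allele-fraction profile of a sample over a gene region
#'
#' For every non-reference-homozygous site with allelic depths, the fraction
#' of reads supporting the alternate allele, `alt / (ref + alt)`. Ratios
#' near 1/3, 1/2, 2/3, or 3/4 discriminate copy configurations (a 1:3 ratio
#' at total copy number 4 indicates a triplicated haplotype). Sites with
#' missing AD or zero total depth are skipped and counted.
#'
#' @param t A variant table with AD fields.
#' @param sample Sample id; `NULL` keeps all samples.
#' @param gene Optional gene symbol restricting sites to the registry region.
#' @return A tibble of class `pgx_af_profile`: `sample`, `chrom`, `pos`,
#'   `ref`, `alt`, `fraction`; skipped-site count in attribute `skipped`.
#' @export
allele_fraction_profile <- function(t, sample = NULL, gene = NULL) {
  tt <- as_tibble(t)
  if (!is.null(sample)) tt <- filter(tt, .data$sample %in% !!sample)
  if (!is.null(gene)) {
    gm <- gene_model(gene)
    tt <- filter(tt, .data$chrom == gm$chrom, .data$pos >= gm$gene_start,
                 .data$pos <= gm$gene_end)
  }
  tt <- filter(tt, .data$gt_1 + .data$gt_2 > 0)
  skipped <- sum(is.na(tt$ad_ref) | is.na(tt$ad_alt) |
                   (tt$ad_ref + tt$ad_alt) == 0)
  tt <- filter(tt, !is.na(.data$ad_ref), !is.na(.data$ad_alt),
               .data$ad_ref + .data$ad_alt > 0)
  out <- tt |>
    mutate(fraction = .data$ad_alt / (.data$ad_ref + .data$ad_alt)) |>
    select("sample", "chrom", "pos", "ref", "alt", "fraction")
  attr(out, "skipped") <- skipped
  class(out) <- c("pgx_af_profile", class(out))
  out
}
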