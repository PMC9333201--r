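#' Packaged phenotype tables
#'
#' `pgx_activity_table()` loads per-allele function labels and activity
#' values (normal 1, decreased 0.5 or 0.25, no function 0, per CPIC) for the
#' nine genes with a CPIC genotype-phenotype table. `pgx_phenotype_bins()`
#' loads the score-to-label bins for the activity-score genes (CYP2C9,
#' CYP2D6, DPYD); a score `s` maps to the label whose bin satisfies
#' `lower < s <= upper`. `pgx_phenotype_pairs()` loads the unordered
#' function-pair to label maps used by the remaining six genes. All three
#' ship as editable TSVs so alternative guideline releases can be swapped
#' without code change.
#'
#' @param path Optional path overriding the packaged file.
#' @return A tibble.
#' @export
pgx_activity_table <- function(path = NULL) {
  path <- path %||% pgx_extdata("allele_functions.tsv")
  read_pgx_tsv(path, readr::cols(gene = readr::col_character(),
                                 allele = readr::col_character(),
                                 `function` = readr::col_character(),
                                 activity_value = readr::col_double()))
}

#' @rdname pgx_activity_table
#' @export
pgx_phenotype_bins <- function(path = NULL) {
  path <- path %||% pgx_extdata("phenotype_bins.tsv")
  read_pgx_tsv(path, readr::cols(gene = readr::col_character(),
                                 label = readr::col_character(),
                                 lower = readr::col_double(),
                                 upper = readr::col_double()))
}

#' @rdname pgx_activity_table
#' @export
pgx_phenotype_pairs <- function(path = NULL) {
  path <- path %||% pgx_extdata("phenotype_pairs.tsv")
  read_pgx_tsv(path, readr::cols(.default = readr::col_character()))
}

#' Genes with a supported genotype-phenotype translation
#'
#' Nine genes carry a CPIC genotype-phenotype table: three use activity
#' scores (CYP2C9, CYP2D6, DPYD) and six use direct diplotype-to-phenotype
#' maps. SLCO1B1 is reported as transporter function (poor to increased
#' function); the others as metabolizer status (poor to ultrarapid).
#'
#' @return Character vector of gene symbols.
#' @export
pgx_phenotype_genes <- function() {
  c("CYP2B6", "CYP2C19", "CYP2C9", "CYP2D6", "CYP3A5", "DPYD",
    "SLCO1B1", "TPMT", "UGT1A1")
}

score_genes <- function() c("CYP2C9", "CYP2D6", "DPYD")

split_diplotype <- function(diplotype) {
  parts <- str_split(diplotype, "/")[[1]]
  if (length(parts) != 2) {
    abort(paste0("malformed diplotype string: ", diplotype),
          class = "pgx_validation_error")
  }
  str_trim(parts)
}

allele_activity <- function(gene, allele, activity) {
  parsed <- parse_allele_name(allele)
  row <- filter(activity, .data$gene == !!gene,
                .data$allele == parsed$base)
  if (!nrow(row)) {
    return(list(value = NA_real_, `function` = NA_character_,
                reason = paste0(allele, " absent from activity table")))
  }
  fn <- row$`function`[1]
  if (fn %in% c("unknown", "uncertain", "unassigned") ||
      is.na(row$activity_value[1])) {
    return(list(value = NA_real_, `function` = fn,
                reason = paste0(allele, " has ", fn, " function")))
  }
  # a duplicated allele contributes once per copy
  list(value = row$activity_value[1] * parsed$copies, `function` = fn,
       reason = NA_character_)
}

#' Activity score of a diplotype
#'
#' The activity score is the sum of the values assigned to both alleles:
#' fully functional alleles contribute 1, decreased-function alleles 0.5 (or
#' 0.25), and nonfunctional alleles 0. A copy suffix `xN` multiplies the
#' allele's value by N. The score is undefined (`NA`) when either allele has
#' unknown/uncertain function or is absent from the activity table; the
#' reason is attached as an attribute.
#'
#' @param gene One of `CYP2C9`, `CYP2D6`, `DPYD`.
#' @param diplotype Diplotype string, e.g. `"*1/*4"`.
#' @param activity Activity table (default packaged).
#' @return A single numeric score, or `NA` with a `reason` attribute.
#' @examples
#' activity_score("CYP2D6", "*1/*1")   # 2
#' activity_score("CYP2D6", "*4/*5")   # 0
#' @export
activity_score <- function(gene, diplotype, activity = pgx_activity_table()) {
  if (!gene %in% score_genes()) {
    abort(paste0("activity scores are defined for ",
                 paste(score_genes(), collapse = ", "), "; not ", gene),
          class = "pgx_validation_error")
  }
  alleles <- split_diplotype(diplotype)
  parts <- map(alleles, ~ allele_activity(gene, .x, activity))
  vals <- map_dbl(parts, "value")
  if (anyNA(vals)) {
    out <- NA_real_
    attr(out, "reason") <- paste(stats::na.omit(map_chr(parts, "reason")),
                                 collapse = "; ")
    return(out)
  }
  sum(vals)
}

#' Predict the CPIC phenotype of a diplotype
#'
#' Activity-score genes map the score through the gene's bins; the other
#' supported genes look up the unordered pair of allele function labels.
#' Any allele with unknown/uncertain/unassigned function forces an
#' `Indeterminate` phenotype, as does an `"Indeterminate"` diplotype.
#' Genes without a packaged genotype-phenotype table return the label
#' `"no phenotype table"` rather than an error, so 27-gene batch calling can
#' phenotype the supported nine.
#'
#' @param gene Gene symbol.
#' @param diplotype Diplotype string (or `"Indeterminate"`).
#' @param activity,bins,pairs Packaged tables (overridable).
#' @param strict If `TRUE`, unsupported genes raise an error listing the
#'   supported set (single-gene mode); if `FALSE` (default) they return a
#'   `"no phenotype table"` row.
#' @return A one-row tibble: `gene`, `diplotype`, `activity_score`,
#'   `phenotype`.
#' @examples
#' predict_phenotype("CYP2D6", "*1/*4")
#' predict_phenotype("CYP2B6", "*6/*8")
#' @export
predict_phenotype <- function(gene, diplotype,
                              activity = pgx_activity_table(),
                              bins = pgx_phenotype_bins(),
                              pairs = pgx_phenotype_pairs(),
                              strict = FALSE) {
  if (!gene %in% pgx_phenotype_genes()) {
    if (strict) {
      abort(paste0("no genotype-phenotype table for ", gene,
                   "; supported genes: ",
                   paste(pgx_phenotype_genes(), collapse = ", ")),
            class = "pgx_validation_error")
    }
    return(tibble(gene = gene, diplotype = diplotype,
                  activity_score = NA_real_, phenotype = "no phenotype table"))
  }
  if (identical(diplotype, "Indeterminate")) {
    return(tibble(gene = gene, diplotype = diplotype,
                  activity_score = NA_real_, phenotype = "Indeterminate"))
  }
  alleles <- split_diplotype(diplotype)
  infos <- map(alleles, ~ allele_activity(gene, .x, activity))
  fns <- map_chr(infos, function(x) x[["function"]] %||% NA_character_)
  if (anyNA(fns) || any(fns %in% c("unknown", "uncertain", "unassigned"))) {
    return(tibble(gene = gene, diplotype = diplotype,
                  activity_score = NA_real_, phenotype = "Indeterminate"))
  }

  if (gene %in% score_genes()) {
    score <- activity_score(gene, diplotype, activity)
    if (is.na(score)) {
      label <- "Indeterminate"
    } else {
      b <- filter(bins, .data$gene == !!gene,
                  score > .data$lower, score <= .data$upper)
      label <- if (nrow(b)) b$label[1] else "Indeterminate"
    }
    return(tibble(gene = gene, diplotype = diplotype,
                  activity_score = ifelse(is.na(score), NA_real_, score),
                  phenotype = label))
  }

  pair <- sort(fns)
  hit <- filter(pairs, .data$gene == !!gene,
                .data$func_a == pair[1], .data$func_b == pair[2])
  if (!nrow(hit)) {
    hit <- filter(pairs, .data$gene == !!gene,
                  .data$func_a == pair[2], .data$func_b == pair[1])
  }
  label <- if (nrow(hit)) hit$label[1] else "Indeterminate"
  tibble(gene = gene, diplotype = diplotype, activity_score = NA_real_,
         phenotype = label)
}

#' Phenotype a table of diplotype calls
#'
#' Batch wrapper over [predict_phenotype()]: adds `phenotype` and
#' `activity_score` columns to a diplotype call table (e.g. from
#' [assign_diplotype()] or a TSV call set).
#'
#' @param calls A tibble with `gene` and `diplotype` columns.
#' @inheritParams predict_phenotype
#' @return The input with `activity_score` and `phenotype` columns added.
#' @export
predict_phenotypes <- function(calls, activity = pgx_activity_table(),
                               bins = pgx_phenotype_bins(),
                               pairs = pgx_phenotype_pairs()) {
  res <- map(seq_len(nrow(calls)), function(i) {
    predict_phenotype(calls$gene[i], calls$diplotype[i],
                      activity = activity, bins = bins, pairs = pairs)
  })
  res <- bind_rows(res)
  calls$activity_score <- res$activity_score
  calls$phenotype <- res$phenotype
  calls
}
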