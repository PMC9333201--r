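#' Load a diplotype comparison ledger
#'
#' The ledger records the documented adjustments applied before diplotype
#' comparison, every entry with a reason string:
#' \itemize{
#'   \item `ignored_alleles`: alleles treated as previously unreported
#'     (newly added to nomenclature after the comparator was genotyped); each
#'     maps to a comparison surrogate allele, and mismatches caused purely by
#'     the substitution are not counted;
#'   \item `adjustments`: per-sample/per-gene fixes, currently
#'     `drop_duplicated_allele` for cell-line trisomy artifacts (a
#'     `*2/*2/*4` call is compared as `*2/*4`);
#'   \item `equivalences`: notation rewrites (e.g. legacy `"(*36+)10"` for
#'     `"*36+*10"`);
#'   \item `excluded_samples`: samples removed from comparison entirely
#'     (e.g. a sample-swap detected by [flag_discordant_samples()]).
#' }
#'
#' @param path YAML ledger path, or `NULL` for an empty ledger.
#' @return A list of class `pgx_comparison_ledger`.
#' @export
load_comparison_ledger <- function(path = NULL) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  ledger <- list(
    ignored_alleles = raw$ignored_alleles %||% list(),
    adjustments = raw$adjustments %||% list(),
    equivalences = raw$equivalences %||% list(),
    excluded_samples = raw$excluded_samples %||% list()
  )
  check_reason <- function(entries, what) {
    for (e in entries) {
      if (is.null(e$reason) || !nzchar(e$reason)) {
        abort(paste0("every ", what, " ledger entry needs a reason"),
              class = "pgx_validation_error")
      }
    }
  }
  check_reason(ledger$ignored_alleles, "ignored_alleles")
  check_reason(ledger$adjustments, "adjustments")
  check_reason(ledger$equivalences, "equivalences")
  check_reason(ledger$excluded_samples, "excluded_samples")
  class(ledger) <- "pgx_comparison_ledger"
  ledger
}

empty_ledger <- function() load_comparison_ledger(NULL)

#' Normalize diplotype calls for comparison
#'
#' Applies, in order: notation equivalences; per-sample/gene trisomy
#' adjustments (dropping one duplicated allele from a triple call); ignored
#' -allele surrogate substitution; and canonical allele ordering.
#'
#' @param calls A tibble with `sample`, `gene`, `diplotype` columns.
#' @param ledger A `pgx_comparison_ledger` (default empty: normalization is
#'   then canonical ordering only).
#' @return `calls` with a `diplotype_norm` column added and excluded samples
#'   removed.
#' @export
normalize_for_comparison <- function(calls, ledger = empty_ledger()) {
  excluded <- map_chr(ledger$excluded_samples,
                      ~ .x$sample %||% NA_character_)
  out <- filter(calls, !.data$sample %in% excluded)

  norm_one <- function(sample, gene, diplotype) {
    if (identical(diplotype, "Indeterminate") || is.na(diplotype)) {
      return(diplotype)
    }
    for (eq in ledger$equivalences) {
      if (identical(eq$gene %||% gene, gene)) {
        diplotype <- gsub(eq$from, eq$to, diplotype, fixed = TRUE)
      }
    }
    parts <- str_trim(str_split(diplotype, "/")[[1]])
    for (adj in ledger$adjustments) {
      if (identical(adj$action, "drop_duplicated_allele") &&
          identical(adj$sample, sample) && identical(adj$gene, gene) &&
          length(parts) > 2) {
        dup <- parts[duplicated(parts)]
        if (length(dup)) parts <- parts[-match(dup[1], parts)]
      }
    }
    for (ig in ledger$ignored_alleles) {
      if (identical(ig$gene %||% gene, gene)) {
        parts[parts == ig$allele] <- ig$surrogate %||% ig$allele
      }
    }
    if (length(parts) == 2) {
      paste(order_alleles(parts[1], parts[2]), collapse = "/")
    } else {
      paste(sort(parts), collapse = "/")
    }
  }
  out$diplotype_norm <- map_chr(seq_len(nrow(out)), function(i) {
    norm_one(out$sample[i], out$gene[i], out$diplotype[i])
  })
  out
}

categorize_discrepancy <- function(note_a, note_b) {
  notes <- tolower(paste(note_a %||% "", note_b %||% ""))
  dplyr::case_when(
    str_detect(notes, "untargeted|not targeted|outside.*target") ~
      "untargeted_variant",
    str_detect(notes, "phas") ~ "phasing",
    str_detect(notes, "variant call|genotyping error|missed variant") ~
      "variant_calling",
    str_detect(notes, "sv|copy|duplicat|delet|hybrid|indeterminate") ~
      "sv_interpretation",
    TRUE ~ "other"
  )
}

#' Diplotype concordance between two call sets
#'
#' Compares diplotypes over the shared (sample, gene) keys after ledger
#' normalization. Equality is string equality of the normalized diplotype —
#' whole-diplotype matches, no partial credit. Each mismatch is categorized
#' from the evidence notes supplied with the calls (columns `note`, when
#' present): untargeted variant, phasing, variant calling, SV
#' interpretation, or other.
#'
#' @param set_a,set_b Call tibbles with `sample`, `gene`, `diplotype` and
#'   optional `note` columns.
#' @param ledger A comparison ledger (default empty).
#' @return An object of class `pgx_diplotype_concordance`: list with
#'   `total`, `concordant`, `rate`, and a `discrepancies` tibble.
#' @export
diplotype_concordance <- function(set_a, set_b, ledger = empty_ledger()) {
  a <- normalize_for_comparison(set_a, ledger)
  b <- normalize_for_comparison(set_b, ledger)
  if (!"note" %in% names(a)) a$note <- NA_character_
  if (!"note" %in% names(b)) b$note <- NA_character_
  j <- inner_join(
    select(a, "sample", "gene", a_call = "diplotype_norm", a_note = "note"),
    select(b, "sample", "gene", b_call = "diplotype_norm", b_note = "note"),
    by = c("sample", "gene")
  )
  if (!nrow(j)) {
    abort("no shared (sample, gene) keys between call sets",
          class = "pgx_validation_error")
  }
  j <- mutate(j, concordant = .data$a_call == .data$b_call)
  disc <- j |>
    filter(!.data$concordant) |>
    mutate(category = categorize_discrepancy(.data$a_note, .data$b_note)) |>
    select("sample", "gene", "a_call", "b_call", "category")
  out <- list(
    total = nrow(j),
    concordant = sum(j$concordant),
    rate = mean(j$concordant),
    discrepancies = disc
  )
  class(out) <- "pgx_diplotype_concordance"
  out
}

#' @export
print.pgx_diplotype_concordance <- function(x, ...) {
  cat(sprintf("Diplotype concordance: %.1f%% (%d/%d)\n", 100 * x$rate,
              x$concordant, x$total))
  if (nrow(x$discrepancies)) {
    print(count(x$discrepancies, .data$category))
  }
  invisible(x)
}

#' @export
tidy.pgx_diplotype_concordance <- function(x, ...) x$discrepancies

#' @export
glance.pgx_diplotype_concordance <- function(x, ...) {
  tibble(total = x$total, concordant = x$concordant, rate = x$rate,
         n_discrepancies = nrow(x$discrepancies))
}

#' Phenotype concordance between two call sets
#'
#' Compares phenotype labels over shared (sample, gene) keys; mismatches
#' where one side is `Indeterminate` (typically a newly called allele of
#' unknown function flipping the phenotype) are annotated as such.
#'
#' @param set_a,set_b Tibbles with `sample`, `gene`, `phenotype` columns.
#' @param ledger A comparison ledger (sample exclusions honored).
#' @return An object of class `pgx_phenotype_concordance`: list with
#'   `total`, `concordant`, `rate`, and a `discrepancies` tibble carrying an
#'   `indeterminate_involved` flag.
#' @export
phenotype_concordance <- function(set_a, set_b, ledger = empty_ledger()) {
  excluded <- map_chr(ledger$excluded_samples,
                      ~ .x$sample %||% NA_character_)
  a <- filter(set_a, !.data$sample %in% excluded)
  b <- filter(set_b, !.data$sample %in% excluded)
  j <- inner_join(
    select(a, "sample", "gene", a_phen = "phenotype"),
    select(b, "sample", "gene", b_phen = "phenotype"),
    by = c("sample", "gene")
  )
  if (!nrow(j)) {
    abort("no shared (sample, gene) keys between call sets",
          class = "pgx_validation_error")
  }
  j <- mutate(j, concordant = .data$a_phen == .data$b_phen)
  disc <- j |>
    filter(!.data$concordant) |>
    mutate(indeterminate_involved = .data$a_phen == "Indeterminate" |
             .data$b_phen == "Indeterminate") |>
    select("sample", "gene", "a_phen", "b_phen", "indeterminate_involved")
  out <- list(total = nrow(j), concordant = sum(j$concordant),
              rate = mean(j$concordant), discrepancies = disc)
  class(out) <- "pgx_phenotype_concordance"
  out
}

#' @export
print.pgx_phenotype_concordance <- function(x, ...) {
  cat(sprintf("Phenotype concordance: %.1f%% (%d/%d)\n", 100 * x$rate,
              x$concordant, x$total))
  invisible(x)
}

#' Read a call set TSV
#'
#' @param path TSV with columns `sample`, `gene`, `diplotype` and optionally
#'   `phenotype`, `note`.
#' @return A tibble.
#' @export
read_call_set <- function(path) {
  read_pgx_tsv(path, readr::cols(.default = readr::col_character()))
}
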