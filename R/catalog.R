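#' Load a star-allele translation table
#'
#' A translation table maps defining-variant sets to star-allele names for one
#' or more genes. The input is tab-separated with a header and columns
#' `gene`, `allele`, `defining_variants` (comma-separated variant keys, empty
#' for the reference and for purely structural alleles), `function`, `sv_tag`
#' (`none`, `del`, `dup`, `mult`, or `hyb`) and `is_reference`.
#'
#' Validation enforces the catalog invariants: allele names unique within a
#' gene, exactly one reference allele per gene with an empty defining set and
#' no SV tag, and (when the gene is in [pgx_gene_models()]) every defining
#' variant inside the gene or pseudogene region.
#'
#' @param path Path to a TSV file. Defaults to the packaged allele-definition
#'   table; its variant positions are synthetic (illustrative hg19-like
#'   coordinates) except the ones printed in primary literature.
#' @param genes Optional character vector restricting to a subset of genes.
#' @return A tibble of class `pgx_translation_table` with one row per allele:
#'   `gene`, `allele`, `base`, `copies`, `function`, `sv_tag`, `is_reference`,
#'   and `defining_variants` (list-column of variant-key tibbles).
#' @examples
#' tt <- load_translation_table(genes = "UGT2B17")
#' tt$allele
#' @export
load_translation_table <- function(path = NULL, genes = NULL) {
  path <- path %||% pgx_extdata("star_allele_definitions.synthetic.tsv")
  raw <- read_pgx_tsv(path, readr::cols(.default = readr::col_character()))
  needed <- c("gene", "allele", "defining_variants", "function", "sv_tag")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols)) {
    abort(paste0("translation table missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "pgx_validation_error")
  }
  if (!"is_reference" %in% names(raw)) {
    # fall back to the catalog convention: reference = empty set, no SV tag
    raw$is_reference <- as.character(raw$defining_variants %in% c(NA, "") &
                                       raw$sv_tag %in% c(NA, "none"))
  }
  if (!is.null(genes)) raw <- filter(raw, .data$gene %in% genes)

  tab <- raw |>
    mutate(
      sv_tag = ifelse(is.na(.data$sv_tag), "none", .data$sv_tag),
      `function` = ifelse(is.na(.data$`function`), "unassigned",
                          .data$`function`),
      is_reference = as.logical(.data$is_reference),
      defining_variants = map(.data$defining_variants, function(v) {
        if (is.na(v) || !nzchar(str_trim(v))) {
          return(tibble(chrom = character(), pos = integer(),
                        ref = character(), alt = character()))
        }
        parse_variant_key(str_trim(str_split(v, ",")[[1]]))
      })
    ) |>
    left_join(parse_allele_name(unique(raw$allele)),
              by = c(allele = "name")) |>
    select("gene", "allele", "base", "copies", "function", "sv_tag",
           "is_reference", "defining_variants")

  bad_fun <- setdiff(tab$`function`, allele_function_levels())
  if (length(bad_fun)) {
    abort(paste0("unknown function label(s): ", paste(bad_fun, collapse = ", ")),
          class = "pgx_validation_error")
  }
  bad_tag <- setdiff(tab$sv_tag, c("none", "del", "dup", "mult", "hyb"))
  if (length(bad_tag)) {
    abort(paste0("unknown sv_tag(s): ", paste(bad_tag, collapse = ", ")),
          class = "pgx_validation_error")
  }

  for (g in unique(tab$gene)) {
    sub <- filter(tab, .data$gene == g)
    if (anyDuplicated(sub$allele)) {
      abort(paste0(g, ": duplicate allele name(s): ",
                   paste(sub$allele[duplicated(sub$allele)], collapse = ", ")),
            class = "pgx_validation_error")
    }
    if (sum(sub$is_reference) != 1L) {
      abort(paste0(g, ": expected exactly one reference allele"),
            class = "pgx_validation_error")
    }
    ref_row <- sub[sub$is_reference, ]
    if (nrow(ref_row$defining_variants[[1]]) > 0 || ref_row$sv_tag != "none") {
      abort(paste0(g, ": reference allele must have an empty defining set ",
                   "and sv_tag 'none'"),
            class = "pgx_validation_error")
    }
    gm <- gene_model(g, required = FALSE)
    if (!is.null(gm)) {
      vars <- bind_rows(sub$defining_variants)
      if (nrow(vars)) {
        in_gene <- vars$pos >= gm$gene_start & vars$pos <= gm$gene_end
        in_pseudo <- !is.na(gm$pseudo_start) &
          vars$pos >= gm$pseudo_start & vars$pos <= gm$pseudo_end
        if (any(!(in_gene | in_pseudo))) {
          abort(paste0(g, ": defining variant outside the gene/pseudogene ",
                       "region: ",
                       paste(render_variant_key(vars[!(in_gene | in_pseudo), ]),
                             collapse = ", ")),
                class = "pgx_validation_error")
        }
      }
    }
    mult <- sub$sv_tag == "mult"
    if (any(mult & sub$copies < 3L)) {
      abort(paste0(g, ": sv_tag 'mult' implies copy count >= 3"),
            class = "pgx_validation_error")
    }
  }

  class(tab) <- c("pgx_translation_table", class(tab))
  tab
}

allele_function_levels <- function() {
  c("normal", "decreased", "no_function", "increased", "unknown",
    "uncertain", "unassigned")
}

#' @rdname load_translation_table
#' @export
pgx_translation_tables <- function(genes = NULL) {
  load_translation_table(genes = genes)
}

reference_allele <- function(table, gene) {
  sub <- filter(table, .data$gene == !!gene, .data$is_reference)
  if (!nrow(sub)) {
    abort(paste0("no reference allele for gene ", gene),
          class = "pgx_validation_error")
  }
  sub$allele[[1]]
}

#' Load the 59-gene panel catalog
#'
#' Reads the panel description (one row per targeted pharmacogene) with its
#' probe footprint in kilobases, capture design (`Exon` or `Custom`), mean
#' per-batch coverage, and per-gene counts of CPIC gene-drug pairs, CPIC
#' level-A pairs and FDA-labeled pairs. The packaged fixture describes the
#' 59-gene clinical pharmacogenomics capture panel.
#'
#' @param path Path to a TSV panel file; default is the packaged catalog.
#' @return A tibble of class `pgx_panel_catalog`.
#' @examples
#' nrow(load_panel_catalog())
#' @export
load_panel_catalog <- function(path = NULL) {
  path <- path %||% pgx_extdata("panel_genes.tsv")
  cat <- read_pgx_tsv(path, readr::cols(
    gene = readr::col_character(),
    chrom = readr::col_character(),
    design = readr::col_character(),
    `function` = readr::col_character(),
    .default = readr::col_double()
  ))
  count_cols <- c("cpic_pairs", "cpic_a_pairs", "fda_pairs")
  missing_cols <- setdiff(c("gene", "probe_kb", "design", count_cols),
                          names(cat))
  if (length(missing_cols)) {
    abort(paste0("panel catalog missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "pgx_validation_error")
  }
  for (cc in count_cols) {
    v <- cat[[cc]]
    if (any(is.na(v)) || any(v < 0) || any(v != round(v))) {
      abort(paste0("malformed count column '", cc,
                   "': counts must be nonnegative integers"),
            class = "pgx_validation_error")
    }
  }
  if (any(is.na(cat$probe_kb)) || any(cat$probe_kb <= 0)) {
    abort("probe_kb must be positive", class = "pgx_validation_error")
  }
  if (anyDuplicated(cat$gene)) {
    abort("duplicate gene rows in panel catalog",
          class = "pgx_validation_error")
  }
  class(cat) <- c("pgx_panel_catalog", class(cat))
  cat
}

#' Summarize guideline coverage of a panel catalog
#'
#' Sums the per-gene counts of CPIC gene-drug pairs, CPIC level-A pairs, and
#' FDA-labeled pairs over the whole panel. Sums are computed by enumeration
#' over rows (and are therefore invariant to row order). The CPIC level-A
#' column sum counts every gene-drug pair once per gene; guideline texts that
#' deduplicate multi-gene guidelines can print a smaller total, so that row
#' carries a cautionary note.
#'
#' @param catalog A panel catalog from [load_panel_catalog()].
#' @return A tibble with columns `guideline` (`cpic`, `cpic_a`, `fda`),
#'   `pairs` (integer sum) and `note`.
#' @examples
#' summarize_guideline_coverage(load_panel_catalog())
#' @export
summarize_guideline_coverage <- function(catalog) {
  if (!nrow(catalog)) {
    abort("empty panel catalog", class = "pgx_validation_error")
  }
  tibble(
    guideline = c("cpic", "cpic_a", "fda"),
    pairs = c(sum(catalog$cpic_pairs), sum(catalog$cpic_a_pairs),
              sum(catalog$fda_pairs)),
    note = c(NA_character_,
             "raw per-gene column sum; multi-gene guidelines not deduplicated",
             NA_character_)
  )
}

#' Load the star-allele catalog observed across call sets
#'
#' Reads the per-gene catalog of star alleles observed in a study: the
#' reference allele, the comma-separated list of reported alleles (structural
#' alleles annotated with a parenthesised `del`/`dup`/`hyb` tag), and the
#' subset not reported by earlier publications (`None` when empty).
#'
#' @param path TSV path; default is the packaged 27-gene catalog.
#' @return A long tibble of class `pgx_allele_catalog` with one row per
#'   (gene, allele): columns `gene`, `allele`, `sv_tag` (`none` unless the
#'   entry carried a structural annotation), `is_reference`, `novel`.
#' @examples
#' cat27 <- load_allele_catalog()
#' summarize_allele_catalog(cat27)
#' @export
load_allele_catalog <- function(path = NULL) {
  path <- path %||% pgx_extdata("star_allele_catalog.tsv")
  raw <- read_pgx_tsv(path, readr::cols(.default = readr::col_character()))
  if (anyDuplicated(raw$gene)) {
    abort("duplicate gene symbol across translation tables",
          class = "pgx_validation_error")
  }
  parse_entries <- function(x) {
    if (is.na(x) || x == "None") return(character())
    str_trim(str_split(x, ",")[[1]])
  }
  long <- raw |>
    mutate(reported = map(.data$alleles_reported, parse_entries),
           novel_list = map(.data$alleles_not_previously_reported,
                            parse_entries)) |>
    select("gene", "reference", "reported", "novel_list") |>
    unnest("reported") |>
    mutate(
      sv_tag = str_match(.data$reported, "\\((del|dup|hyb)\\)")[, 2],
      sv_tag = ifelse(is.na(.data$sv_tag), "none", .data$sv_tag),
      allele = str_trim(str_remove(.data$reported, "\\s*\\((del|dup|hyb)\\)")),
      is_reference = .data$allele == .data$reference,
      novel = map2_lgl(.data$allele, .data$novel_list, ~ .x %in% .y)
    ) |>
    select("gene", "allele", "sv_tag", "is_reference", "novel")

  # entries listed only in the not-previously-reported column (catalogs can
  # disagree in spelling between the two columns; both are preserved)
  extra <- raw |>
    mutate(novel_list = map(.data$alleles_not_previously_reported,
                            parse_entries),
           reported = map(.data$alleles_reported, parse_entries)) |>
    transmute(.data$gene,
              only_novel = map2(.data$novel_list, .data$reported, setdiff)) |>
    unnest("only_novel")
  attr(long, "novel_only_entries") <- extra
  class(long) <- c("pgx_allele_catalog", class(long))
  long
}

#' @importFrom purrr map2_lgl
NULL

#' Summarize a star-allele catalog by enumeration
#'
#' Counts, by direct enumeration over catalog rows (never from stored
#' constants): the unique alleles reported, the structural-variant-defined
#' alleles and the genes carrying them, and the alleles (and genes) flagged as
#' not previously reported. Novel-allele entries present only in the
#' not-previously-reported column (spelling variants preserved from the
#' source) are counted via the column itself.
#'
#' @param catalog An allele catalog from [load_allele_catalog()].
#' @return A one-row tibble with columns `unique_alleles`, `sv_alleles`,
#'   `sv_genes`, `novel_alleles`, `novel_genes`.
#' @export
summarize_allele_catalog <- function(catalog) {
  if (nrow(distinct(catalog, .data$gene, .data$allele)) != nrow(catalog)) {
    abort("duplicate (gene, allele) entries", class = "pgx_validation_error")
  }
  novel_only <- attr(catalog, "novel_only_entries") %||%
    tibble(gene = character(), only_novel = character())
  novel_in_reported <- filter(catalog, .data$novel)
  n_novel <- nrow(novel_in_reported) + nrow(novel_only)
  novel_genes <- length(union(novel_in_reported$gene, novel_only$gene))
  sv <- filter(catalog, .data$sv_tag != "none")
  tibble(
    unique_alleles = nrow(catalog),
    sv_alleles = nrow(sv),
    sv_genes = n_distinct(sv$gene),
    novel_alleles = n_novel,
    novel_genes = novel_genes
  )
}
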