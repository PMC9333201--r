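#' Split a sample's variants into two haplotypes
#'
#' Produces one haplotype pair per sample for the variants falling in the
#' gene region. In `"passthrough"` mode the input genotypes must be phased
#' (`|` separators): allele 1 of every phased genotype goes to copy 1.
#' In `"match"` mode, homozygous-alternate variants are placed on both
#' copies and the heterozygous variants are assigned by exhaustive search
#' over the \eqn{2^{k-1}} phase configurations, choosing the one that (1)
#' minimizes the number of variants not explained by each copy's best
#' catalog allele, then (2) maximizes the size of the largest fully-matched
#' allele — so variants that jointly define one catalog allele land cis,
#' and variants defining two distinct single-variant alleles land trans.
#' Ties break deterministically on the enumeration order.
#'
#' @param t A variant table.
#' @param gene Gene symbol.
#' @param mode `"match"` (catalog-guided phaser, default) or
#'   `"passthrough"` (requires phased input).
#' @param table Translation table for the gene.
#' @param max_het Heterozygous-site cap for exhaustive search; above it a
#'   greedy assignment is used (default 12).
#' @return A tibble of class `pgx_haplotypes`: `sample`, `hap` (1 or 2),
#'   `chrom`, `pos`, `ref`, `alt` — one row per variant carried.
#' @export
phase_variants <- function(t, gene, mode = c("match", "passthrough"),
                           table = pgx_translation_tables(gene),
                           max_het = 12L) {
  mode <- match.arg(mode)
  gm <- gene_model(gene)
  tt <- as_tibble(t) |>
    filter(.data$chrom == gm$chrom, .data$pos >= gm$gene_start,
           .data$pos <= gm$gene_end, .data$gt_1 + .data$gt_2 > 0)
  samples <- vt_samples(t)
  def_sets <- gene_defining_sets(table, gene)

  out <- map(samples, function(s) {
    sub <- filter(tt, .data$sample == s)
    if (!nrow(sub)) {
      return(tibble(sample = character(), hap = integer(),
                    chrom = character(), pos = integer(),
                    ref = character(), alt = character()))
    }
    keys <- render_variant_key(sub)
    hom <- sub$gt_1 == 1L & sub$gt_2 == 1L
    if (mode == "passthrough") {
      if (any(!sub$phased)) {
        abort(paste0("sample ", s, " has unphased genotypes; use ",
                     "mode = 'match' for catalog-guided phasing"),
              class = "pgx_validation_error")
      }
      hap1 <- keys[sub$gt_1 == 1L]
      hap2 <- keys[sub$gt_2 == 1L]
    } else {
      het_keys <- keys[!hom]
      assign <- phase_by_catalog(het_keys, keys[hom], def_sets, max_het)
      hap1 <- c(keys[hom], het_keys[assign == 1L])
      hap2 <- c(keys[hom], het_keys[assign == 2L])
    }
    hap_tbl <- function(h, idx) {
      if (!length(h)) {
        return(tibble(sample = character(), hap = integer(),
                      chrom = character(), pos = integer(),
                      ref = character(), alt = character()))
      }
      bind_cols(tibble(sample = s, hap = idx), parse_variant_key(h))
    }
    bind_rows(hap_tbl(hap1, 1L), hap_tbl(hap2, 2L))
  })
  out <- bind_rows(out)
  attr(out, "samples") <- samples
  attr(out, "gene") <- gene
  attr(out, "mode") <- mode
  class(out) <- c("pgx_haplotypes", class(out))
  out
}

# defining sets (character vectors of keys) for matchable alleles of a gene;
# SV-tagged alleles are excluded from direct haplotype matching
gene_defining_sets <- function(table, gene) {
  sub <- filter(table, .data$gene == !!gene, .data$sv_tag == "none",
                !.data$is_reference)
  sets <- map(sub$defining_variants, render_variant_key)
  names(sets) <- sub$allele
  keep(sets, ~ length(.x) > 0)
}

# exhaustive phase search; returns 1/2 assignment per het variant
phase_by_catalog <- function(het_keys, hom_keys, def_sets, max_het = 12L) {
  k <- length(het_keys)
  if (k == 0) return(integer())
  score <- function(assign) {
    h1 <- c(hom_keys, het_keys[assign == 1L])
    h2 <- c(hom_keys, het_keys[assign == 2L])
    best <- function(h) {
      sizes <- map_int(def_sets, function(ds) {
        if (all(ds %in% h)) length(ds) else 0L
      })
      if (length(sizes)) max(sizes) else 0L
    }
    b1 <- best(h1)
    b2 <- best(h2)
    # variants on a copy not covered by its best allele are unexplained
    unexplained <- (length(h1) - b1) + (length(h2) - b2)
    c(unexplained, -max(b1, b2))
  }
  if (k <= max_het) {
    # fix the first het variant on copy 1 (haplotype labels are arbitrary)
    configs <- expand.grid(rep(list(1:2), max(k - 1, 0)))
    best_assign <- NULL
    best_score <- c(Inf, Inf)
    for (i in seq_len(max(nrow(configs), 1))) {
      assign <- c(1L, if (k > 1) as.integer(configs[i, ]))
      sc <- score(assign)
      if (sc[1] < best_score[1] ||
          (sc[1] == best_score[1] && sc[2] < best_score[2])) {
        best_score <- sc
        best_assign <- assign
      }
    }
    best_assign
  } else {
    # greedy: seed copy 1 with the largest fully-present defining set
    present <- keep(def_sets, ~ all(.x %in% c(het_keys, hom_keys)))
    assign <- rep(2L, k)
    if (length(present)) {
      top <- present[[which.max(map_int(present, length))]]
      assign[het_keys %in% top] <- 1L
    } else {
      assign[1] <- 1L
    }
    assign
  }
}

#' Match a haplotype's variants to catalog star alleles
#'
#' Candidate alleles are those whose entire defining-variant set is carried
#' by the haplotype, ranked most-specific first (largest defining set), then
#' function-altering before unknown/uncertain/unassigned function, then
#' lexically. An empty candidate list yields the gene's reference allele.
#' SV-tagged alleles are never matched from variants alone; they are
#' substituted by [assign_diplotype()] using copy-number evidence.
#'
#' @param haplotype Character vector of variant keys carried by one copy.
#' @param table Translation table.
#' @param gene Gene symbol.
#' @return A tibble `allele`, `n_defining`, `function`, ranked; row 1 is the
#'   best match.
#' @export
match_alleles <- function(haplotype, table, gene) {
  sub <- filter(table, .data$gene == !!gene, .data$sv_tag == "none")
  cand <- sub |>
    mutate(keys = map(.data$defining_variants, render_variant_key),
           n_defining = map_int(.data$keys, length),
           hit = map_lgl(.data$keys, ~ length(.x) > 0 &&
                           all(.x %in% haplotype))) |>
    filter(.data$hit)
  if (!nrow(cand)) {
    ref <- filter(sub, .data$is_reference)
    return(tibble(allele = ref$allele, n_defining = 0L,
                  `function` = ref$`function`))
  }
  cand |>
    mutate(fn_known = !.data$`function` %in% c("unknown", "uncertain",
                                               "unassigned")) |>
    arrange(desc(.data$n_defining), desc(.data$fn_known), .data$allele) |>
    select("allele", "n_defining", "function")
}

#' Canonical diplotype ordering and rendering
#'
#' Alleles are ordered by the numeric core of their base name (`"*4"` before
#' `"*41"`; `"*36x2+*10"` orders by 36), copy-suffixed forms by their base
#' allele then copy count, and non-numeric names reference-first then
#' lexically. `render_diplotype()` joins the ordered pair with `/`;
#' indeterminate calls render as `"Indeterminate"`.
#'
#' @param allele_1,allele_2 Allele names.
#' @param reference Optional reference allele name (sorted first among
#'   non-numeric names).
#' @return `order_alleles()`: character vector of length 2;
#'   `render_diplotype()`: a single string.
#' @export
order_alleles <- function(allele_1, allele_2, reference = NULL) {
  key <- function(a) {
    core <- allele_numeric_core(a)
    copies <- parse_allele_name(a)$copies
    is_ref <- !is.null(reference) && a == reference
    list(core = core, copies = copies, is_ref = is_ref, name = a)
  }
  k1 <- key(allele_1)
  k2 <- key(allele_2)
  lt <- function(a, b) {
    if (!is.na(a$core) && !is.na(b$core)) {
      if (a$core != b$core) return(a$core < b$core)
      if (a$copies != b$copies) return(a$copies < b$copies)
      return(a$name <= b$name)
    }
    if (!is.na(a$core)) return(TRUE)   # numeric cores before named alleles
    if (!is.na(b$core)) return(FALSE)
    if (a$is_ref != b$is_ref) return(a$is_ref)
    a$name <= b$name
  }
  if (lt(k1, k2)) c(allele_1, allele_2) else c(allele_2, allele_1)
}

#' @rdname order_alleles
#' @param call A one-row diplotype call (or `allele_1`/`allele_2` strings).
#' @param indeterminate Logical; if `TRUE` renders `"Indeterminate"`.
#' @export
render_diplotype <- function(allele_1, allele_2, reference = NULL,
                             indeterminate = FALSE) {
  if (isTRUE(indeterminate)) return("Indeterminate")
  paste(order_alleles(allele_1, allele_2, reference), collapse = "/")
}

# expected allele fraction of a haplotype carrying `c` of `total` copies
copy_split_candidates <- function(total) {
  splits <- list()
  for (c1 in seq_len(total - 1)) {
    splits[[length(splits) + 1]] <- c(c1, total - c1)
  }
  splits
}

# choose the copy split (c1, c2) best supported by het-site allele fractions.
# Sites attributable to one copy (its matched allele's defining variants)
# constrain that copy; other het sites (haplotype-private passengers, whose
# phase is arbitrary) constrain the split through the better-fitting copy.
resolve_copy_split <- function(total, af, hap1_keys, hap2_keys, tol = 0.12) {
  het <- filter(af, .data$fraction > 0.02, .data$fraction < 0.98)
  if (!nrow(het)) {
    return(list(split = NULL, residual = NA_real_, evidence = 0L))
  }
  keys <- render_variant_key(het)
  site_owner <- ifelse(keys %in% hap1_keys & !keys %in% hap2_keys, 1L,
                       ifelse(keys %in% hap2_keys & !keys %in% hap1_keys, 2L,
                              NA_integer_))
  best <- NULL
  best_res <- Inf
  for (sp in copy_split_candidates(total)) {
    expected <- sp / total
    res <- map_dbl(seq_len(nrow(het)), function(i) {
      f <- het$fraction[i]
      if (!is.na(site_owner[i])) {
        abs(f - expected[site_owner[i]])
      } else {
        min(abs(f - expected))
      }
    })
    r <- mean(res)
    if (r < best_res - 1e-12) {
      best_res <- r
      best <- sp
    }
  }
  list(split = best, residual = best_res, evidence = nrow(het),
       consistent = best_res <= tol)
}

attach_copy_suffix <- function(allele, copies) {
  if (copies <= 1L) return(allele)
  paste0(allele, "x", copies)
}

#' Assign final diplotypes from haplotypes, SV calls, and allele fractions
#'
#' Integrates the three evidence layers per sample:
#' \itemize{
#'   \item normal copy state: the top-ranked catalog allele of each copy;
#'   \item heterozygous whole-gene deletion: one copy is replaced by the
#'     gene's deletion allele and the remaining variants are matched as a
#'     single copy; homozygous deletion yields the deletion allele twice;
#'   \item duplication/multiplication (total copy plateau 3 or 4): the extra
#'     copies are attributed via heterozygous-site allele fractions (a copy
#'     carrying `c` of `T` total copies shows fraction `c/T`, so a 1:3 ratio
#'     at plateau 4 resolves `*7/*7x3` against `*7x2/*7x2`); with no
#'     fraction evidence the extra copies go to the reference-most allele
#'     and the call is flagged low-confidence;
#'   \item hybrid classes: the registered hybrid allele replaces the copy
#'     carrying its embedded allele (or the reference-most copy when the
#'     hybrid contributes no observable variants);
#'   \item indeterminate SV call, or allele fractions contradicting the copy
#'     plateau beyond tolerance: the diplotype is Indeterminate.
#' }
#'
#' @param haps A `pgx_haplotypes` tibble from [phase_variants()].
#' @param sv A `pgx_sv_calls` tibble from [classify_sv()] (one row per
#'   sample), or `NULL` to assume a normal copy state.
#' @param af A `pgx_af_profile` from [allele_fraction_profile()], or `NULL`.
#' @param table Translation table.
#' @param gene Gene symbol.
#' @param af_tol Allele-fraction consistency tolerance (default 0.12,
#'   matching binomial noise at depth >= 100x).
#' @return A tibble of class `pgx_diplotype_calls`: `sample`, `gene`,
#'   `allele_1`, `allele_2`, `diplotype`, `sv_class`, `indeterminate`,
#'   `confidence`, `note`.
#' @export
assign_diplotype <- function(haps, sv = NULL, af = NULL, table,
                             gene = attr(haps, "gene"), af_tol = 0.12) {
  samples <- attr(haps, "samples") %||% unique(haps$sample)
  reg <- sv_class_registry(gene)
  ref_allele <- reference_allele(table, gene)

  rows <- map(samples, function(s) {
    sv_row <- if (!is.null(sv)) filter(sv, .data$sample == s) else NULL
    sv_class <- if (!is.null(sv_row) && nrow(sv_row)) sv_row$sv_class[1] else "normal"
    sv_ind <- !is.null(sv_row) && nrow(sv_row) && sv_row$indeterminate[1]
    meta <- filter(reg, .data$class == sv_class)
    if (!nrow(meta)) sv_ind <- TRUE

    if (sv_ind) {
      return(tibble(sample = s, gene = gene, allele_1 = NA_character_,
                    allele_2 = NA_character_, diplotype = "Indeterminate",
                    sv_class = sv_class, indeterminate = TRUE,
                    confidence = "low",
                    note = "SV call indeterminate or unregistered"))
    }

    h <- filter(as_tibble(haps), .data$sample == s)
    hap1 <- render_variant_key(filter(h, .data$hap == 1L))
    hap2 <- render_variant_key(filter(h, .data$hap == 2L))
    m1 <- match_alleles(hap1, table, gene)
    m2 <- match_alleles(hap2, table, gene)
    a1 <- m1$allele[1]
    a2 <- m2$allele[1]
    af_s <- if (!is.null(af)) filter(af, .data$sample == s) else
      tibble(fraction = numeric(), chrom = character(), pos = integer(),
             ref = character(), alt = character())
    confidence <- "high"
    note <- NA_character_
    kind <- meta$kind[1]
    total <- meta$total_copies[1]

    if (kind == "del_hom") {
      a1 <- a2 <- meta$sv_allele[1]
    } else if (kind == "del_het") {
      union_keys <- union(hap1, hap2)
      a1 <- match_alleles(union_keys, table, gene)$allele[1]
      a2 <- meta$sv_allele[1]
    } else if (kind == "partial_del" || kind == "partial_dup") {
      union_keys <- union(hap1, hap2)
      a1 <- match_alleles(setdiff(union_keys, character()), table,
                          gene)$allele[1]
      a2 <- meta$sv_allele[1]
    } else if (kind == "hyb") {
      hyb <- filter(hybrid_registry(), .data$gene == !!gene,
                    .data$allele == meta$sv_allele[1])
      embedded <- hyb$embedded[1]
      emb_keys <- if (!is.na(embedded)) {
        render_variant_key(
          filter(table, .data$gene == !!gene,
                 .data$allele == embedded)$defining_variants[[1]])
      } else character()
      hit1 <- length(emb_keys) && all(emb_keys %in% hap1)
      hit2 <- length(emb_keys) && all(emb_keys %in% hap2)
      if (hit2 && !hit1) {
        a2 <- meta$sv_allele[1]
      } else if (hit1 && !hit2) {
        a1 <- meta$sv_allele[1]
      } else {
        # hybrid contributes no distinguishing variants: replace the
        # reference-most copy
        if (m1$n_defining[1] <= m2$n_defining[1]) {
          a1 <- meta$sv_allele[1]
        } else {
          a2 <- meta$sv_allele[1]
        }
      }
    } else if (kind %in% c("dup", "mult")) {
      keys1 <- defining_keys_of(table, gene, a1)
      keys2 <- defining_keys_of(table, gene, a2)
      split <- resolve_copy_split(total, af_s,
                                  intersect(keys1, hap1),
                                  intersect(keys2, hap2), tol = af_tol)
      if (is.null(split$split)) {
        # no het evidence: extra copies to the reference-most allele
        ord <- order_alleles(a1, a2, ref_allele)
        extra <- total - 2L
        if (ord[1] == a1) {
          a1 <- attach_copy_suffix(a1, 1L + extra)
        } else {
          a2 <- attach_copy_suffix(a2, 1L + extra)
        }
        confidence <- "low"
        note <- "no heterozygous-site allele fractions; duplication attributed to reference-most allele"
      } else if (!isTRUE(split$consistent)) {
        return(tibble(sample = s, gene = gene, allele_1 = NA_character_,
                      allele_2 = NA_character_, diplotype = "Indeterminate",
                      sv_class = sv_class, indeterminate = TRUE,
                      confidence = "low",
                      note = sprintf(
                        "allele fractions inconsistent with copy plateau %d (residual %.2f)",
                        total, split$residual)))
      } else {
        # orient the split: sites owned by copy 1 pin its copy count
        sp <- split$split
        owner1 <- intersect(keys1, hap1)
        orient_res <- function(order_sp) {
          if (!length(owner1) || !nrow(af_s)) return(0)
          f <- af_s$fraction[render_variant_key(af_s) %in% owner1]
          if (!length(f)) return(0)
          mean(abs(f - order_sp[1] / total))
        }
        if (orient_res(sp) > orient_res(rev(sp))) sp <- rev(sp)
        a1 <- attach_copy_suffix(a1, sp[1])
        a2 <- attach_copy_suffix(a2, sp[2])
      }
    }

    dip <- render_diplotype(a1, a2, ref_allele)
    ord <- order_alleles(a1, a2, ref_allele)
    tibble(sample = s, gene = gene, allele_1 = ord[1], allele_2 = ord[2],
           diplotype = dip, sv_class = sv_class, indeterminate = FALSE,
           confidence = confidence, note = note)
  })
  out <- bind_rows(rows)
  class(out) <- c("pgx_diplotype_calls", class(out))
  out
}

defining_keys_of <- function(table, gene, allele) {
  row <- filter(table, .data$gene == !!gene, .data$allele == !!allele)
  if (!nrow(row)) return(character())
  render_variant_key(row$defining_variants[[1]])
}
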