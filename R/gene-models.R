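#' Built-in gene models for simulation and copy-number analysis
#'
#' Registry of the pharmacogene loci the package simulates and genotypes:
#' hg19-style gene intervals, the paralogous pseudogene interval for genes
#' with hybrid alleles (CYP2D6/CYP2D7, CYP2B6/CYP2B7), the grid stride used
#' when simulating per-base depth (coarser than 1 bp to keep desk-scale
#' cohorts light), and control-locus eligibility. VDR is the default control
#' locus for intra-sample depth normalization: it is large and has a very low
#' rate of whole-gene deletion/duplication polymorphism.
#'
#' @return A tibble with one row per modeled gene.
#' @examples
#' pgx_gene_models()
#' @export
pgx_gene_models <- function() {
  tribble(
    ~gene,      ~chrom, ~gene_start, ~gene_end,  ~pseudo_start, ~pseudo_end, ~stride, ~control_eligible,
    "CYP2D6",   "22",   42522501L,   42526883L,  42536213L,     42540576L,   25L,     FALSE,
    "CYP2E1",   "10",   135340866L,  135352620L, NA_integer_,   NA_integer_, 50L,     FALSE,
    "GSTT1",    "22",   24376141L,   24384284L,  NA_integer_,   NA_integer_, 40L,     FALSE,
    "GSTM1",    "1",    110230418L,  110236367L, NA_integer_,   NA_integer_, 30L,     FALSE,
    "UGT2B17",  "4",    69402902L,   69434245L,  NA_integer_,   NA_integer_, 150L,    FALSE,
    "CYP2A6",   "19",   41349443L,   41356700L,  NA_integer_,   NA_integer_, 35L,     FALSE,
    "CYP2B6",   "19",   41497204L,   41524301L,  41525300L,     41552300L,   130L,    FALSE,
    "UGT1A1",   "2",    234665000L,  234682000L, NA_integer_,   NA_integer_, 85L,     FALSE,
    "UGT2B15",  "4",    69508596L,   69536668L,  NA_integer_,   NA_integer_, 140L,    FALSE,
    "SLC22A2",  "6",    160637000L,  160679000L, NA_integer_,   NA_integer_, 200L,    FALSE,
    "VDR",      "12",   48235320L,   48298814L,  NA_integer_,   NA_integer_, 300L,    TRUE
  )
}

gene_model <- function(gene, required = TRUE) {
  gm <- filter(pgx_gene_models(), .data$gene == !!gene)
  if (!nrow(gm)) {
    if (required) {
      abort(paste0("no built-in gene model for ", gene),
            class = "pgx_validation_error")
    }
    return(NULL)
  }
  gm
}

# position grid used for simulated depth; gene region then pseudogene region
gene_position_grid <- function(gene) {
  gm <- gene_model(gene)
  pos <- seq(gm$gene_start, gm$gene_end, by = gm$stride)
  out <- tibble(chrom = gm$chrom, pos = as.integer(pos), region = "gene")
  if (!is.na(gm$pseudo_start)) {
    ppos <- seq(gm$pseudo_start, gm$pseudo_end, by = gm$stride)
    out <- bind_rows(out, tibble(chrom = gm$chrom, pos = as.integer(ppos),
                                 region = "pseudogene"))
  }
  out
}

# fractional coordinate within its region, in [0, 1]
region_fraction <- function(pos, region, gm) {
  start <- ifelse(region == "gene", gm$gene_start, gm$pseudo_start)
  end <- ifelse(region == "gene", gm$gene_end, gm$pseudo_end)
  (pos - start) / (end - start)
}

# ---------------------------------------------------------------------------
# Per-haplotype copy-number templates. A template gives the contribution of
# one haplotype to the *observed* copy-number track over the gene (and, if
# modeled, pseudogene) span. Hybrid templates place a single breakpoint at a
# fixed fraction of the span: the converted segment's reads align to the
# pseudogene, so the gene track loses a copy and the pseudogene track gains
# one over the mirrored window.
hap_template_segments <- function(kind) {
  seg <- function(region, f0, f1, cn) tibble(region = region, f0 = f0, f1 = f1, cn = cn)
  switch(kind,
    ref    = bind_rows(seg("gene", 0, 1, 1), seg("pseudogene", 0, 1, 1)),
    del    = bind_rows(seg("gene", 0, 1, 0), seg("pseudogene", 0, 1, 1)),
    del3p  = bind_rows(seg("gene", 0, 0.5, 1), seg("gene", 0.5, 1, 0),
                       seg("pseudogene", 0, 1, 1)),
    dup2   = bind_rows(seg("gene", 0, 1, 2), seg("pseudogene", 0, 1, 1)),
    dup3   = bind_rows(seg("gene", 0, 1, 3), seg("pseudogene", 0, 1, 1)),
    dup5p  = bind_rows(seg("gene", 0, 0.4, 2), seg("gene", 0.4, 1, 1),
                       seg("pseudogene", 0, 1, 1)),
    hyb36_10 = bind_rows(seg("gene", 0, 0.85, 2), seg("gene", 0.85, 1, 1),
                         seg("pseudogene", 0, 0.85, 1),
                         seg("pseudogene", 0.85, 1, 2)),
    hyb36x2_10 = bind_rows(seg("gene", 0, 0.85, 3), seg("gene", 0.85, 1, 1),
                           seg("pseudogene", 0, 0.85, 1),
                           seg("pseudogene", 0.85, 1, 3)),
    hyb68_4 = bind_rows(seg("gene", 0, 0.15, 2), seg("gene", 0.15, 1, 1),
                        seg("pseudogene", 0, 0.15, 1),
                        seg("pseudogene", 0.15, 1, 2)),
    hyb29  = bind_rows(seg("gene", 0, 0.5, 0), seg("gene", 0.5, 1, 1),
                       seg("pseudogene", 0, 0.5, 2),
                       seg("pseudogene", 0.5, 1, 1)),
    abort(paste0("unknown haplotype template kind: ", kind),
          class = "pgx_validation_error")
  )
}

# haplotype template kind for one allele of a gene
allele_hap_kind <- function(gene, allele) {
  parsed <- parse_allele_name(allele)
  hyb <- hybrid_registry()
  hit <- filter(hyb, .data$gene == !!gene, .data$allele == !!allele)
  if (nrow(hit)) return(hit$kind)
  if (gene == "CYP2E1" && parsed$base == "*S1") return("dup5p")
  if (gene == "SLC22A2" && parsed$base == "*S2") return("del3p")
  if (is_deletion_allele(gene, allele)) return("del")
  if (parsed$copies == 2L) return("dup2")
  if (parsed$copies == 3L) return("dup3")
  if (parsed$copies > 3L) {
    abort("copy counts above 3 are not modeled", class = "pgx_validation_error")
  }
  "ref"
}

# registry of gene-specific hybrid alleles: template kind, the SV class they
# induce (heterozygous with a reference-like allele), and the conventional
# allele embedded in the hybrid arrangement (whose defining variants are
# observable), if any
hybrid_registry <- function() {
  tribble(
    ~gene,     ~allele,       ~kind,         ~class,         ~embedded,
    "CYP2D6",  "*36+*10",     "hyb36_10",    "hyb_36_10",    "*10",
    "CYP2D6",  "*36x2+*10",   "hyb36x2_10",  "hyb_36x2_10",  "*10",
    "CYP2D6",  "*68+*4",      "hyb68_4",     "hyb_68_4",     "*4",
    "CYP2B6",  "*29",         "hyb29",       "hyb_29",       NA_character_
  )
}

deletion_allele_name <- function(gene, partial = FALSE) {
  tab <- tribble(
    ~gene,     ~whole, ~partial_name,
    "CYP2D6",  "*5",   NA_character_,
    "CYP2A6",  "*4",   NA_character_,
    "GSTT1",   "*0",   NA_character_,
    "GSTM1",   "*0",   NA_character_,
    "UGT2B17", "*2",   NA_character_,
    "UGT2B15", "*S1",  NA_character_,
    "SLC22A2", "*S1",  "*S2"
  )
  hit <- filter(tab, .data$gene == !!gene)
  if (!nrow(hit)) {
    abort(paste0("no deletion allele registered for ", gene),
          class = "pgx_validation_error")
  }
  if (partial) hit$partial_name else hit$whole
}

is_deletion_allele <- function(gene, allele) {
  tab <- tryCatch(deletion_allele_name(gene), error = function(e) NA_character_)
  ptab <- tryCatch(deletion_allele_name(gene, partial = TRUE),
                   error = function(e) NA_character_)
  allele %in% stats::na.omit(c(tab, ptab)) &&
    !(gene == "SLC22A2" && allele == "*S2")  # *S2 handled as partial template
}

#' Structural-variant class registry
#'
#' Per-gene registry of the diplotype-level structural-variant classes the
#' SVM classifier distinguishes. Each class carries its `kind` (how the
#' genotyper interprets it), the total gene copy number plateau where
#' applicable, and for hybrid classes the substituted allele name.
#'
#' @param gene Gene symbol.
#' @return A tibble with columns `gene`, `class`, `kind`, `total_copies`,
#'   `sv_allele`, `hap_a`, `hap_b` (haplotype template kinds used when
#'   simulating training examples of the class).
#' @examples
#' sv_class_registry("CYP2D6")$class
#' @export
sv_class_registry <- function(gene) {
  all <- tribble(
    ~gene,      ~class,         ~kind,        ~total_copies, ~sv_allele,  ~hap_a,       ~hap_b,
    "CYP2A6",   "normal",       "normal",     2L,  NA_character_, "ref",        "ref",
    "CYP2A6",   "del_het",      "del_het",    1L,  "*4",          "del",        "ref",
    "CYP2A6",   "del_hom",      "del_hom",    0L,  "*4",          "del",        "del",
    "CYP2A6",   "dup",          "dup",        3L,  NA_character_, "dup2",       "ref",
    "CYP2B6",   "normal",       "normal",     2L,  NA_character_, "ref",        "ref",
    "CYP2B6",   "hyb_29",       "hyb",        2L,  "*29",         "hyb29",      "ref",
    "CYP2D6",   "normal",       "normal",     2L,  NA_character_, "ref",        "ref",
    "CYP2D6",   "del_het",      "del_het",    1L,  "*5",          "del",        "ref",
    "CYP2D6",   "del_hom",      "del_hom",    0L,  "*5",          "del",        "del",
    "CYP2D6",   "dup",          "dup",        3L,  NA_character_, "dup2",       "ref",
    "CYP2D6",   "hyb_36_10",    "hyb",        3L,  "*36+*10",     "hyb36_10",   "ref",
    "CYP2D6",   "hyb_36x2_10",  "hyb",        4L,  "*36x2+*10",   "hyb36x2_10", "ref",
    "CYP2D6",   "hyb_68_4",     "hyb",        3L,  "*68+*4",      "hyb68_4",    "ref",
    "CYP2E1",   "normal",       "normal",     2L,  NA_character_, "ref",        "ref",
    "CYP2E1",   "dup",          "dup",        3L,  NA_character_, "dup2",       "ref",
    "CYP2E1",   "mult",         "mult",       4L,  NA_character_, "dup3",       "ref",
    "CYP2E1",   "dup_S1",       "partial_dup", 2L, "*S1",         "dup5p",      "ref",
    "GSTM1",    "normal",       "normal",     2L,  NA_character_, "ref",        "ref",
    "GSTM1",    "del_het",      "del_het",    1L,  "*0",          "del",        "ref",
    "GSTM1",    "del_hom",      "del_hom",    0L,  "*0",          "del",        "del",
    "GSTM1",    "dup",          "dup",        3L,  NA_character_, "dup2",       "ref",
    "GSTT1",    "normal",       "normal",     2L,  NA_character_, "ref",        "ref",
    "GSTT1",    "del_het",      "del_het",    1L,  "*0",          "del",        "ref",
    "GSTT1",    "del_hom",      "del_hom",    0L,  "*0",          "del",        "del",
    "SLC22A2",  "normal",       "normal",     2L,  NA_character_, "ref",        "ref",
    "SLC22A2",  "del_het",      "del_het",    1L,  "*S1",         "del",        "ref",
    "SLC22A2",  "del_hom",      "del_hom",    0L,  "*S1",         "del",        "del",
    "SLC22A2",  "del_partial",  "partial_del", 2L, "*S2",         "del3p",      "ref",
    "UGT2B15",  "normal",       "normal",     2L,  NA_character_, "ref",        "ref",
    "UGT2B15",  "del_het",      "del_het",    1L,  "*S1",         "del",        "ref",
    "UGT2B15",  "del_hom",      "del_hom",    0L,  "*S1",         "del",        "del",
    "UGT2B17",  "normal",       "normal",     2L,  NA_character_, "ref",        "ref",
    "UGT2B17",  "del_het",      "del_het",    1L,  "*2",          "del",        "ref",
    "UGT2B17",  "del_hom",      "del_hom",    0L,  "*2",          "del",        "del"
  )
  out <- filter(all, .data$gene == !!gene)
  if (!nrow(out)) {
    abort(paste0("no SV classes registered for ", gene),
          class = "pgx_validation_error")
  }
  out
}

#' Map a structural allele to its diplotype-level SV class
#'
#' Gives the class the classifier is expected to report for a sample carrying
#' the allele heterozygously with a copy-neutral allele; used to score class
#' recall in simulation studies.
#'
#' @param gene Gene symbol.
#' @param allele Allele name (e.g. `"*5"`, `"*1x2"`, `"*36+*10"`).
#' @return A single class label.
#' @export
allele_sv_class <- function(gene, allele) {
  k <- allele_hap_kind(gene, allele)
  reg <- sv_class_registry(gene)
  hit <- filter(reg, .data$hap_a == !!k, .data$hap_b == "ref")
  if (!nrow(hit)) {
    abort(paste0("allele ", allele, " does not map to a registered SV class ",
                 "for ", gene),
          class = "pgx_validation_error")
  }
  hit$class[[1]]
}

# diplotype truth -> SV class, by summing haplotype templates and matching
# against the per-class expected tracks
diplotype_sv_class <- function(gene, allele_1, allele_2) {
  kinds <- sort(c(allele_hap_kind(gene, allele_1),
                  allele_hap_kind(gene, allele_2)))
  reg <- sv_class_registry(gene)
  reg_kinds <- map_chr(seq_len(nrow(reg)), function(i) {
    paste(sort(c(reg$hap_a[i], reg$hap_b[i])), collapse = "|")
  })
  key <- paste(kinds, collapse = "|")
  hit <- which(reg_kinds == key)
  if (length(hit)) return(reg$class[hit[1]])
  # fall back on total gene-wide plateau (e.g. dup2 + dup2 -> mult plateau 4)
  total <- sum(map_int(kinds, function(k) {
    segs <- filter(hap_template_segments(k), .data$region == "gene")
    as.integer(round(sum(segs$cn * (segs$f1 - segs$f0))))
  }))
  plateau <- filter(reg, .data$kind %in% c("normal", "del_het", "del_hom",
                                           "dup", "mult"),
                    .data$total_copies == total)
  if (nrow(plateau)) return(plateau$class[[1]])
  abort(paste0("no SV class matches diplotype ", allele_1, "/", allele_2,
               " for ", gene),
        class = "pgx_validation_error")
}

#' Expected copy-number track for a diplotype
#'
#' Sums the two haplotype copy-number templates over the gene (and
#' pseudogene) position grid. This is the noise-free track the simulator
#' scales depth by, and the template simulation studies validate recovered
#' profiles against.
#'
#' @param gene Gene symbol.
#' @param allele_1,allele_2 Star-allele names.
#' @return A tibble with columns `chrom`, `pos`, `region`, `cn`.
#' @examples
#' head(expected_cn_track("GSTT1", "*A", "*0"))
#' @export
expected_cn_track <- function(gene, allele_1, allele_2) {
  gm <- gene_model(gene)
  grid <- gene_position_grid(gene)
  frac <- region_fraction(grid$pos, grid$region, gm)
  cn <- rep(0, nrow(grid))
  for (allele in c(allele_1, allele_2)) {
    segs <- hap_template_segments(allele_hap_kind(gene, allele))
    for (i in seq_len(nrow(segs))) {
      sel <- grid$region == segs$region[i] &
        frac >= segs$f0[i] & (frac < segs$f1[i] | segs$f1[i] == 1)
      cn[sel] <- cn[sel] + segs$cn[i]
    }
  }
  mutate(grid, cn = cn)
}

# per-position gene copy count contributed by one haplotype (for allelic
# depth simulation and AF interpretation)
hap_copies_at <- function(gene, allele, pos) {
  gm <- gene_model(gene)
  segs <- filter(hap_template_segments(allele_hap_kind(gene, allele)),
                 .data$region == "gene")
  frac <- (pos - gm$gene_start) / (gm$gene_end - gm$gene_start)
  out <- rep(0L, length(pos))
  for (i in seq_len(nrow(segs))) {
    sel <- frac >= segs$f0[i] & (frac < segs$f1[i] | segs$f1[i] == 1)
    out[sel] <- out[sel] + as.integer(segs$cn[i])
  }
  out
}
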