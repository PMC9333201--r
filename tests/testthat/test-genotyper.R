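tt <- pgx_translation_tables()
b6 <- dplyr::filter(pgx_gene_models(), gene == "CYP2B6")

# CYP2B6 synthetic-position shorthand used below:
#   v516 = 19-41512841-G-T (in *6 and *9), v785 = 19-41515263-A-G (*6, *4)
v516 <- list(chrom = "19", pos = 41512841L, ref = "G", alt = "T")
v785 <- list(chrom = "19", pos = 41515263L, ref = "A", alt = "G")

test_that("homozygous variants appear on both haplotypes", {
  t <- toy_variant_table(list(
    c(v516, list(sample = "s1", gt = c(1L, 1L)))
  ))
  h <- phase_variants(t, "CYP2B6", mode = "match", table = tt)
  expect_equal(sort(h$hap), c(1L, 2L))
})

test_that("catalog-guided phasing places joint definers cis, distinct definers trans", {
  # brute-force rationale: v516+v785 jointly define *6, so cis leaves no
  # variant unexplained with a larger matched allele than any trans split
  t_cis <- toy_variant_table(list(
    c(v516, list(sample = "s1", gt = c(0L, 1L))),
    c(v785, list(sample = "s1", gt = c(0L, 1L)))
  ))
  h <- phase_variants(t_cis, "CYP2B6", mode = "match", table = tt)
  expect_equal(length(unique(h$hap)), 1L)   # both on one copy
  best <- match_alleles(render_variant_key(h), tt, "CYP2B6")
  expect_equal(best$allele[1], "*6")

  # two variants defining two distinct single-variant alleles go trans:
  # *9 (v516) and *8 (19-41512869-A-G)
  v8 <- list(chrom = "19", pos = 41512869L, ref = "A", alt = "G")
  t_trans <- toy_variant_table(list(
    c(v516, list(sample = "s1", gt = c(0L, 1L))),
    c(v8, list(sample = "s1", gt = c(0L, 1L)))
  ))
  h2 <- phase_variants(t_trans, "CYP2B6", mode = "match", table = tt)
  expect_equal(sort(unique(h2$hap)), c(1L, 2L))

  # passthrough requires phased input
  expect_error(phase_variants(t_cis, "CYP2B6", mode = "passthrough",
                              table = tt),
               class = "pgx_validation_error")
})

test_that("allele matching ranks specific and function-altering alleles first", {
  # empty haplotype -> reference allele
  expect_equal(match_alleles(character(), tt, "CYP2D6")$allele[1], "*1")

  # the single printed promoter variant identifies CYP2A6*9
  expect_equal(match_alleles("19-41356379-A-C", tt, "CYP2A6")$allele[1],
               "*9")

  # UGT1A1 haplotype with the *80 SNV and the *28 promoter indel:
  # the two-variant combination allele outranks both singletons
  h <- c("2-234665782-C-T", "2-234668879-C-CAT")
  ranked <- match_alleles(h, tt, "UGT1A1")
  expect_equal(ranked$allele[1], "*80+*28")
  expect_true(all(c("*80", "*28") %in% ranked$allele))

  # result independent of variant input order
  expect_equal(match_alleles(rev(h), tt, "UGT1A1"), ranked)
})

test_that("diplotype rendering uses canonical ordering", {
  expect_equal(render_diplotype("*4", "*1"), "*1/*4")
  expect_equal(render_diplotype("*41", "*36x2+*10"), "*36x2+*10/*41")
  expect_equal(render_diplotype("*7x3", "*7"), "*7/*7x3")
  expect_equal(render_diplotype("*0", "*A", reference = "*A"), "*0/*A")
  expect_equal(render_diplotype(NA, NA, indeterminate = TRUE),
               "Indeterminate")
})

test_that("assignment integrates SV classes and deletion alleles", {
  mk_haps <- function(keys1 = character(), keys2 = character(), s = "s1",
                      gene = "CYP2D6") {
    empty <- tibble::tibble(sample = character(), hap = integer(),
                            chrom = character(), pos = integer(),
                            ref = character(), alt = character())
    rows <- dplyr::bind_rows(
      empty,
      if (length(keys1)) dplyr::bind_cols(tibble::tibble(sample = s, hap = 1L),
                                          parse_variant_key(keys1)),
      if (length(keys2)) dplyr::bind_cols(tibble::tibble(sample = s, hap = 2L),
                                          parse_variant_key(keys2))
    )
    attr(rows, "samples") <- s
    attr(rows, "gene") <- gene
    rows
  }
  sv_row <- function(cls, ind = FALSE) {
    tibble::tibble(sample = "s1", sv_class = cls, margin = 1, dist = 0,
                   indeterminate = ind)
  }

  # no variants, normal SV -> homozygous reference
  calls <- assign_diplotype(mk_haps(), sv_row("normal"), NULL, tt,
                            gene = "CYP2D6")
  expect_equal(calls$diplotype, "*1/*1")

  # UGT2B17 homozygous deletion -> *2/*2
  calls2 <- assign_diplotype(mk_haps(gene = "UGT2B17"), sv_row("del_hom"),
                             NULL, tt, gene = "UGT2B17")
  expect_equal(calls2$diplotype, "*2/*2")

  # CYP2D6 *4 variants at cn 1: het deletion gives *4/*5
  k4 <- "22-42524947-C-T"
  calls3 <- assign_diplotype(mk_haps(k4, k4), sv_row("del_het"), NULL, tt,
                             gene = "CYP2D6")
  expect_equal(calls3$diplotype, "*4/*5")

  # indeterminate SV propagates
  calls4 <- assign_diplotype(mk_haps(), sv_row("normal", ind = TRUE), NULL,
                             tt, gene = "CYP2D6")
  expect_equal(calls4$diplotype, "Indeterminate")
  expect_true(calls4$indeterminate)
})

test_that("copy plateaus resolve 1:3 vs 2:2 from allele fractions", {
  gm <- dplyr::filter(pgx_gene_models(), gene == "CYP2E1")
  k7 <- "10-135341011-T-A"
  haps <- function(extra1 = NULL, extra2 = NULL) {
    rows <- dplyr::bind_rows(
      dplyr::bind_cols(tibble::tibble(sample = "s1", hap = 1L),
                       parse_variant_key(c(k7, extra1))),
      dplyr::bind_cols(tibble::tibble(sample = "s1", hap = 2L),
                       parse_variant_key(c(k7, extra2)))
    )
    attr(rows, "samples") <- "s1"
    attr(rows, "gene") <- "CYP2E1"
    rows
  }
  sv <- tibble::tibble(sample = "s1", sv_class = "mult", margin = 1,
                       dist = 0, indeterminate = FALSE)
  af_at <- function(p1, f1, p2, f2) {
    af <- tibble::tibble(
      sample = "s1", chrom = gm$chrom,
      pos = as.integer(c(135341011, p1, p2)),
      ref = c("T", "A", "A"), alt = c("A", "G", "G"),
      fraction = c(1, f1, f2)
    )
    af
  }
  p1 <- "10-135343000-A-G"; p2 <- "10-135344000-A-G"

  # passenger fractions 0.25 / 0.75 at plateau 4 -> *7/*7x3
  c13 <- assign_diplotype(haps(p1, p2), sv,
                          af_at(135343000, 0.25, 135344000, 0.75), tt,
                          gene = "CYP2E1")
  expect_equal(c13$diplotype, "*7/*7x3")

  # passenger fractions 0.5 / 0.5 -> *7x2/*7x2
  c22 <- assign_diplotype(haps(p1, p2), sv,
                          af_at(135343000, 0.5, 135344000, 0.5), tt,
                          gene = "CYP2E1")
  expect_equal(c22$diplotype, "*7x2/*7x2")

  # fractions contradicting the plateau beyond tolerance -> Indeterminate
  bad <- assign_diplotype(haps(p1, p2), sv,
                          af_at(135343000, 0.1, 135344000, 0.9), tt,
                          gene = "CYP2E1")
  expect_equal(bad$diplotype, "Indeterminate")
})

test_that("reference-only input yields the homozygous reference diplotype", {
  for (g in c("CYP2D6", "GSTT1", "UGT2B17")) {
    empty <- toy_variant_table(list(
      list(chrom = "Z", pos = 1L, sample = "s1", gt = c(0L, 0L))
    ), samples = "s1")
    h <- phase_variants(empty, g, table = tt)
    calls <- assign_diplotype(h, NULL, NULL, tt, gene = g)
    ref <- pgxstar:::reference_allele(tt, g)
    expect_equal(calls$diplotype, paste0(ref, "/", ref))
  }
})
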