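test_that("simulated depth is deterministic, mean-calibrated, and cn-scaled", {
  cfg <- sim_config(n_samples = 10, seed = 17, mixture = c("*A/*A" = 1))
  d1 <- simulate_depth(cfg, "GSTT1")
  d2 <- simulate_depth(cfg, "GSTT1")
  expect_identical(tibble::as_tibble(d1), tibble::as_tibble(d2))

  # deterministic limit: no dispersion, flat capture, unit libraries
  cfg0 <- sim_config(n_samples = 3, seed = 1, dispersion = 0,
                     capture_sd = 0, library_sd = 0,
                     mixture = c("*A/*A" = 1))
  d0 <- simulate_depth(cfg0, "GSTT1")
  vals <- as.matrix(tibble::as_tibble(d0)[, -(1:2)])
  expect_true(all(vals == 250))

  # empirical mean within 2% of configured mean for >= 1e5 cells
  cfgm <- sim_config(n_samples = 300, seed = 23, mixture = c("*A/*A" = 1))
  dm <- simulate_depth(cfgm, "GSTT1")
  cells <- as.matrix(tibble::as_tibble(dm)[, -(1:2)])
  expect_gt(length(cells), 1e5)
  expect_equal(mean(cells), 250, tolerance = 0.02)

  # heterozygous whole-gene deletion: gene-region mean ~ half the control
  cfgd <- sim_config(n_samples = 40, seed = 29, mixture = c("*A/*0" = 1))
  dd <- simulate_depth(cfgd, "GSTT1")
  dt <- tibble::as_tibble(dd)
  gm <- dplyr::filter(pgx_gene_models(), gene == "GSTT1")
  in_gene <- dt$chrom == gm$chrom & dt$pos >= gm$gene_start &
    dt$pos <= gm$gene_end
  gene_mean <- mean(as.matrix(dt[in_gene, -(1:2)]))
  ctrl_mean <- mean(as.matrix(dt[!in_gene, -(1:2)]))
  expect_equal(gene_mean / ctrl_mean, 0.5, tolerance = 0.05)
})

test_that("expected copy-number tracks match the class templates", {
  # averaging simulated profiles recovers the declared template per class
  for (cls_allele in list(c("GSTT1", "*0"), c("CYP2D6", "*36+*10"),
                          c("CYP2E1", "*7x3"))) {
    g <- cls_allele[1]; al <- cls_allele[2]
    ref <- pgxstar:::reference_allele(pgx_translation_tables(g), g)
    track <- expected_cn_track(g, ref, al)
    mix <- setNames(1, paste(al, ref, sep = "/"))
    cfg <- sim_config(n_samples = 100, seed = 31, mixture = mix,
                      capture_sd = 0, library_sd = 0)
    d <- simulate_depth(cfg, g)
    dt <- tibble::as_tibble(d)
    keyed <- dplyr::semi_join(dt, track, by = c("chrom", "pos"))
    est <- rowMeans(as.matrix(keyed[, -(1:2)])) / (250 / 2)
    expect_equal(est, track$cn, tolerance = 0.1)
  }
})

test_that("allelic depths follow carrying/total copy binomials", {
  tt <- pgx_translation_tables()
  af_of <- function(mix, gene, key, n = 60) {
    cfg <- sim_config(n_samples = n, seed = 41, mixture = mix)
    sim <- simulate_cohort(gene, cfg)
    af <- allele_fraction_profile(sim$variants, gene = gene)
    af$fraction[render_variant_key(af) == key]
  }

  # *1/*1 truth -> no non-reference sites at defining positions
  cfg <- sim_config(n_samples = 10, seed = 43, n_passengers = 0,
                    mixture = c("*1/*1" = 1))
  sim <- simulate_cohort("CYP2E1", cfg)
  expect_equal(nrow(sim$variants), 0L)

  # het single-variant allele at a diploid locus: fraction ~ 0.5
  f_het <- af_of(c("*1/*7" = 1), "CYP2E1", "10-135341011-T-A")
  expect_equal(mean(f_het), 0.5, tolerance = 0.03)

  # *7/*7x3: defining sites are carried by all four copies (fraction 1);
  # the 1:3 signature lives on haplotype-private passenger sites
  cfg13 <- sim_config(n_samples = 40, seed = 47, mixture = c("*7/*7x3" = 1))
  sim13 <- simulate_cohort("CYP2E1", cfg13)
  af13 <- allele_fraction_profile(sim13$variants, gene = "CYP2E1")
  def <- af13$fraction[af13$pos == 135341011]
  expect_equal(mean(def), 1, tolerance = 0.01)
  pass <- af13$fraction[af13$pos != 135341011]
  expect_gt(length(pass), 20)
  # passengers cluster at 1/4 and 3/4, never near 1/2
  expect_true(all(abs(pass - 0.25) < 0.12 | abs(pass - 0.75) < 0.12))
})

test_that("training sets are reproducible and span the class registry", {
  a <- make_training_set("CYP2A6", n_per_class = 3, seed = 51)
  b <- make_training_set("CYP2A6", n_per_class = 3, seed = 51)
  expect_identical(a$features, b$features)
  expect_identical(a$labels, b$labels)
  expect_equal(length(a$labels), 4 * 3)

  two <- make_training_set("GSTT1", classes = c("normal", "del_het"),
                           n_per_class = 3, seed = 52)
  expect_equal(length(two$labels), 6L)

  expect_error(make_training_set("GSTT1", classes = "warp_drive"),
               class = "pgx_validation_error")
})

test_that("the 19 cataloged SV alleles map onto registered classes", {
  cat27 <- load_allele_catalog()
  sv <- dplyr::filter(cat27, sv_tag != "none")
  expect_equal(nrow(sv), 19L)
  classes <- purrr::map2_chr(sv$gene, sv$allele, allele_sv_class)
  expect_true(all(nzchar(classes)))
  # dup/del/hyb annotations land in the matching class kinds
  kinds <- purrr::map2_chr(sv$gene, sv$allele, function(g, a) {
    reg <- sv_class_registry(g)
    reg$kind[reg$class == allele_sv_class(g, a)]
  })
  expect_true(all(kinds[sv$sv_tag == "del"] %in% c("del_het", "partial_del")))
  expect_true(all(kinds[sv$sv_tag == "hyb"] == "hyb"))
  expect_true(all(kinds[sv$sv_tag == "dup"] %in%
                    c("dup", "mult", "partial_dup")))
})
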