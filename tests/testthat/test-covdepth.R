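test_that("depth files are restricted to targets and validated", {
  p <- tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(chrom = "1", pos = 1:100,
                                  s1 = 50, s2 = 60), p)
  bed <- tibble::tibble(chrom = "1", start = 0L, end = 60L)
  expect_warning(d <- read_depth_matrix(p, bed), "outside target")
  expect_equal(nrow(d), 60L)
  expect_equal(length(attr(d, "samples")), 2L)

  bed_far <- tibble::tibble(chrom = "2", start = 0L, end = 60L)
  expect_error(read_depth_matrix(p, bed_far), class = "pgx_io_error")

  p2 <- tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\ts1", "1\t5\tnot_a_number"), p2)
  expect_error(read_depth_matrix(p2), class = "pgx_validation_error")
})

test_that("coverage summary computes means and monotone uniformity", {
  d <- toy_depth_matrix(1:50, list(s1 = rep(274, 50), s2 = rep(274, 50)))
  cs <- coverage_summary(d, thresholds = c(30, 100))
  expect_equal(cs$mean_depth, 274)
  expect_equal(cs$uniformity$fraction, c(1, 1))

  d2 <- toy_depth_matrix(1:40, list(s1 = rep(c(10, 50), 20)))
  cs2 <- coverage_summary(d2, thresholds = 30)
  expect_equal(cs2$uniformity$fraction, 0.5)

  # seeded negative-binomial matrix: empirical mean near target, fractions
  # monotone in threshold
  set.seed(5)
  nb <- matrix(rnbinom(20000, mu = 250, size = 10), ncol = 10)
  d3 <- toy_depth_matrix(seq_len(nrow(nb)),
                         setNames(asplit(nb, 2), paste0("s", 1:10)))
  cs3 <- coverage_summary(d3, thresholds = c(10, 30, 100, 200, 300))
  expect_equal(cs3$mean_depth, 250, tolerance = 0.02)
  expect_true(all(diff(cs3$uniformity$fraction) <= 0))

  expect_error(coverage_summary(d[0, ]), class = "pgx_validation_error")
})

test_that("control statistics are per-sample medians over the control gene", {
  gm <- dplyr::filter(pgx_gene_models(), gene == "VDR")
  pos <- seq(gm$gene_start, gm$gene_start + 4, by = 1)
  d <- toy_depth_matrix(pos, list(s1 = rep(100, 5),
                                  s2 = c(80, 80, 100, 120, 120),
                                  s3 = rep(0, 5)),
                        chrom = gm$chrom)
  cs <- compute_control_statistics(d)
  expect_equal(cs$control_stat, c(100, 100, 0))
  expect_equal(cs$usable, c(TRUE, TRUE, FALSE))

  d_far <- toy_depth_matrix(1:5, list(s1 = rep(100, 5)))
  expect_error(compute_control_statistics(d_far),
               class = "pgx_validation_error")
})

test_that("copy-number normalization recovers diploid and deleted states", {
  # gene depth equal to control depth everywhere -> cn 2 at every position
  cfg <- sim_config(n_samples = 6, dispersion = 0, capture_sd = 0,
                    library_sd = 0, seed = 3,
                    mixture = c("*A/*A" = 1))
  sim_d <- simulate_depth(cfg, "GSTT1")
  cs <- compute_control_statistics(sim_d)
  prof <- copy_number_profile(sim_d, "GSTT1", cs)
  expect_equal(range(prof$cn[!prof$masked]), c(2, 2), tolerance = 1e-9)

  # one sample at half the cohort depth over the whole gene -> cn 1
  gm <- dplyr::filter(pgx_gene_models(), gene == "GSTT1")
  vdr <- dplyr::filter(pgx_gene_models(), gene == "VDR")
  gpos <- seq(gm$gene_start, gm$gene_start + 99, 1)
  cpos <- seq(vdr$gene_start, vdr$gene_start + 99, 1)
  df <- tibble::tibble(
    chrom = c(rep(gm$chrom, 100), rep(vdr$chrom, 100)),
    pos = c(gpos, cpos),
    s1 = c(rep(50, 100), rep(100, 100)),   # het deletion
    s2 = c(rep(100, 100), rep(100, 100)),
    s3 = c(rep(100, 100), rep(100, 100)),
    s4 = c(rep(100, 100), rep(100, 100))
  )
  d <- depth_matrix(df)
  cs2 <- compute_control_statistics(d)
  prof2 <- copy_number_profile(d, "GSTT1", cs2)
  m <- prof2 |> dplyr::group_by(sample) |>
    dplyr::summarize(cn = mean(cn[!masked]))
  expect_equal(m$cn[m$sample == "s1"], 1, tolerance = 1e-9)
  expect_equal(m$cn[m$sample == "s2"], 2, tolerance = 1e-9)
})

test_that("inter-sample normalization is invariant to library rescaling", {
  cfg <- sim_config(n_samples = 8, seed = 21, mixture = c("*A/*0" = 0.5,
                                                          "*A/*A" = 0.5))
  d <- simulate_depth(cfg, "GSTT1")
  base <- copy_number_profile(d, "GSTT1", compute_control_statistics(d))

  d2 <- tibble::as_tibble(d)
  d2[["S001"]] <- d2[["S001"]] * 7.3   # rescale one sample's whole row
  d2 <- depth_matrix(d2)
  scaled <- copy_number_profile(d2, "GSTT1", compute_control_statistics(d2))
  expect_equal(scaled$cn, base$cn, tolerance = 1e-9)
  expect_equal(scaled$masked, base$masked)
})

test_that("no-SV cohort mode rescues a deletion-dominated cohort", {
  # 40 samples: 10 hom-deleted, 20 het, 10 diploid (75% carry the deletion)
  cfg <- sim_config(n_samples = 40, seed = 33)
  truth <- mk_gstt1_del_cohort()
  d <- simulate_depth(cfg, "GSTT1", truth)
  cs <- compute_control_statistics(d)
  diploid <- truth$sample[truth$diplotype == "*A/*A"]
  het <- truth$sample[truth$diplotype == "*0/*A"]

  good <- copy_number_profile(d, "GSTT1", cs, cohort_mode = "no_sv_samples",
                              no_sv_ids = diploid)
  gm <- good |> dplyr::filter(!masked) |> dplyr::group_by(sample) |>
    dplyr::summarize(cn = mean(cn))
  expect_equal(mean(gm$cn[gm$sample %in% diploid]), 2, tolerance = 0.15)
  expect_equal(mean(gm$cn[gm$sample %in% het]), 1, tolerance = 0.15)

  bad <- copy_number_profile(d, "GSTT1", cs, cohort_mode = "all_samples")
  bm <- bad |> dplyr::filter(!masked) |> dplyr::group_by(sample) |>
    dplyr::summarize(cn = mean(cn))
  # the all-sample reference sits on a deleted copy state, inflating
  # diploid samples far above 2
  expect_gt(mean(bm$cn[bm$sample %in% diploid]), 3)

  expect_error(copy_number_profile(d, "GSTT1", cs,
                                   cohort_mode = "no_sv_samples"),
               class = "pgx_validation_error")
})

test_that("allele fractions follow alt/(ref+alt) and skip empty sites", {
  gm <- dplyr::filter(pgx_gene_models(), gene == "CYP2E1")
  t <- toy_variant_table(list(
    list(chrom = gm$chrom, pos = gm$gene_start + 10, sample = "s1",
         gt = c(0L, 1L), ad = c(10L, 10L)),
    list(chrom = gm$chrom, pos = gm$gene_start + 20, sample = "s1",
         gt = c(1L, 1L), ad = c(25L, 75L)),
    list(chrom = gm$chrom, pos = gm$gene_start + 30, sample = "s1",
         gt = c(0L, 1L), ad = c(0L, 0L))
  ))
  af <- allele_fraction_profile(t, "s1", gene = "CYP2E1")
  expect_equal(af$fraction, c(0.5, 0.75))
  expect_equal(attr(af, "skipped"), 1L)
})
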