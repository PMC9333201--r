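test_that("VCF reading honors BED regions, boundaries, and multiallelic flags", {
  samples <- c("s1", "s2")
  path <- write_toy_vcf(list(
    list(pos = 100, gts = c(s1 = "0/1:10,10", s2 = "0/0:20,0")),
    list(pos = 150, gts = c(s1 = "1/1:0,22", s2 = "0/1:9,11")),
    list(pos = 300, gts = c(s1 = "0/1:12,13", s2 = "0/0:25,0"))
  ), samples)

  # BED covering two of three sites; [99,100) retains pos 100 (half-open)
  bed <- tibble::tibble(chrom = "1", start = c(99L, 140L), end = c(100L, 160L))
  vt <- read_variant_table(path, bed)
  expect_setequal(unique(vt$pos), c(100L, 150L))

  full <- read_variant_table(path)
  expect_equal(length(unique(full$pos)), 3L)
  expect_equal(vt_samples <- attr(full, "samples"), samples)

  # two ALT alleles: retained at read time, flagged multiallelic
  path2 <- write_toy_vcf(list(
    list(pos = 100, alt = "T,G", gts = c(s1 = "1/2:5,5", s2 = "0/1:10,10")),
    list(pos = 200, gts = c(s1 = "0/1:8,9", s2 = "0/0:15,0"))
  ), samples)
  vt2 <- read_variant_table(path2)
  expect_true(any(vt2$multiallelic[vt2$pos == 100]))
  expect_false(any(vt2$multiallelic[vt2$pos == 200]))

  # sample-less VCF errors
  path3 <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO"), collapse = "\t"),
               paste(c("1", "100", ".", "A", "T", ".", ".", "."),
                     collapse = "\t")), path3)
  expect_error(read_variant_table(path3), class = "pgx_validation_error")

  # unsorted VCF errors
  path4 <- write_toy_vcf(list(
    list(pos = 300, gts = c(s1 = "0/1:1,1", s2 = "0/0:2,0")),
    list(pos = 100, gts = c(s1 = "0/1:1,1", s2 = "0/0:2,0"))
  ), samples)
  expect_error(read_variant_table(path4), class = "pgx_validation_error")
})

test_that("merging takes the site union and rejects overlapping samples", {
  a <- toy_variant_table(list(
    list(pos = 10, sample = "a1", gt = c(0L, 1L)),
    list(pos = 20, sample = "a1", gt = c(1L, 1L))
  ))
  b <- toy_variant_table(list(
    list(pos = 10, sample = "b1", gt = c(0L, 1L))
  ))
  m <- merge_variant_tables(a, b)
  expect_setequal(attr(m, "samples"), c("a1", "b1"))
  expect_setequal(unique(m$pos), c(10L, 20L))
  # site private to a has no record for b's sample (implicit hom-ref)
  expect_equal(nrow(dplyr::filter(m, pos == 20, sample == "b1")), 0L)

  empty <- variant_table(a[0, ], samples = "zz")
  m2 <- merge_variant_tables(a, empty)
  expect_equal(nrow(m2), nrow(a))

  expect_error(merge_variant_tables(a, a), class = "pgx_validation_error")
})

test_that("multiallelic removal keeps exactly one ALT per retained site", {
  t <- toy_variant_table(list(
    list(pos = 10, alt = "T", sample = "s1", gt = c(0L, 1L)),
    list(pos = 20, alt = "T", sample = "s1", gt = c(0L, 1L)),
    list(pos = 20, alt = "G", sample = "s2", gt = c(0L, 1L)),
    list(pos = 30, alt = "T", sample = "s2", gt = c(1L, 1L))
  ), samples = c("s1", "s2"))
  f <- drop_multiallelic(t)
  # two records at the same pos with different ALTs are both removed
  expect_setequal(unique(f$pos), c(10L, 30L))

  # all-biallelic table is unchanged
  clean <- toy_variant_table(list(
    list(pos = 10, sample = "s1", gt = c(0L, 1L)),
    list(pos = 20, sample = "s1", gt = c(1L, 1L))
  ))
  expect_equal(nrow(drop_multiallelic(clean)), nrow(clean))
})

test_that("concordance matches direct counts on worked examples", {
  s <- c("s1")
  ten_sites <- lapply(1:10, function(i) {
    list(pos = i * 10, sample = "s1", gt = c(0L, 1L))
  })
  truth <- toy_variant_table(ten_sites, samples = s)
  test <- toy_variant_table(ten_sites[-1], samples = s)  # misses one het

  r <- genotype_concordance(test, truth)
  expect_equal(r$false_negative_count, 1L)
  expect_equal(r$overall_concordance, 0.9)
  expect_equal(r$sites_compared, 10L)

  # identical tables: concordance exactly 1, no fp/fn
  r2 <- genotype_concordance(truth, truth)
  expect_equal(r2$overall_concordance, 1.0)
  expect_equal(r2$false_positive_count + r2$false_negative_count, 0L)

  expect_error(genotype_concordance(truth, toy_variant_table(list(
    list(pos = 10, sample = "other", gt = c(0L, 1L))
  ))), class = "pgx_validation_error")
})

test_that("concordance equals the brute-force oracle on random toy tables", {
  set.seed(42)
  samples <- paste0("s", 1:5)
  for (rep in 1:5) {
    mk <- function() {
      calls <- list()
      for (p in sample(1:20, 12)) {
        for (s in samples) {
          if (runif(1) < 0.6) next
          gt <- sample(list(c(0L, 1L), c(1L, 1L)), 1)[[1]]
          calls[[length(calls) + 1]] <-
            list(pos = p * 7, sample = s, gt = gt,
                 ref = "A", alt = sample(c("T", "TG"), 1))
        }
      }
      toy_variant_table(calls, samples = samples)
    }
    a <- mk(); b <- mk()
    got <- genotype_concordance(a, b)
    want <- oracle_concordance(a, b, samples)
    got <- got[match(want$sample, got$sample), ]
    expect_equal(got$sites_compared, want$sites_compared)
    expect_equal(got$overall_concordance, want$overall_concordance)
    expect_equal(got$false_positive_count, want$false_positive_count)
    expect_equal(got$false_negative_count, want$false_negative_count)

    # swapping test and truth swaps fp/fn and preserves concordance
    rev <- genotype_concordance(b, a)
    rev <- rev[match(got$sample, rev$sample), ]
    expect_equal(rev$overall_concordance, got$overall_concordance)
    expect_equal(rev$false_positive_count, got$false_negative_count)
    expect_equal(rev$false_negative_count, got$false_positive_count)
  }
})

test_that("a 5% perturbed cohort lands near 95% mean concordance", {
  set.seed(7)
  samples <- paste0("s", 1:4)
  calls <- list()
  for (p in 1:250) {
    for (s in samples) {
      calls[[length(calls) + 1]] <- list(pos = p * 3, sample = s,
                                         gt = c(0L, 1L))
    }
  }
  truth <- toy_variant_table(calls, samples = samples)
  flip <- runif(length(calls)) < 0.05
  perturbed <- calls
  for (i in which(flip)) perturbed[[i]]$gt <- c(1L, 1L)
  test <- toy_variant_table(perturbed, samples = samples)
  r <- genotype_concordance(test, truth)
  expect_equal(attr(r, "cohort_mean"), 1 - mean(flip), tolerance = 1e-12)
  expect_equal(attr(r, "cohort_mean"), 0.95, tolerance = 0.05)
})

test_that("half-missing genotypes leave the compared denominator", {
  t1 <- toy_variant_table(list(
    list(pos = 10, sample = "s1", gt = c(0L, 1L)),
    list(pos = 20, sample = "s1", gt = c(NA_integer_, 1L)),
    list(pos = 30, sample = "s1", gt = c(1L, 1L))
  ))
  t2 <- toy_variant_table(list(
    list(pos = 10, sample = "s1", gt = c(0L, 1L)),
    list(pos = 20, sample = "s1", gt = c(0L, 1L)),
    list(pos = 30, sample = "s1", gt = c(1L, 1L))
  ))
  r <- genotype_concordance(t1, t2)
  expect_equal(r$sites_compared, 2L)
  expect_equal(r$half_missing_excluded, 1L)
  expect_equal(r$overall_concordance, 1.0)
})

test_that("discordant-sample flagging separates a swap-like outlier", {
  report <- tibble::tibble(
    sample = c("ok1", "swap", "ok2"),
    overall_concordance = c(0.963, 0.767, 0.958)
  )
  class(report) <- c("pgx_concordance_report", class(report))
  expect_equal(flag_discordant_samples(report, 0.90), "swap")
  expect_equal(flag_discordant_samples(report, 0.5), character())
  expect_equal(flag_discordant_samples(report, 0), character())
})
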