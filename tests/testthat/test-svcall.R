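# build a synthetic cn profile object directly (no depth simulation)
mk_profile <- function(gene, cn_by_sample, mask_fn = NULL) {
  grid <- pgxstar:::gene_position_grid(gene)
  rows <- lapply(names(cn_by_sample), function(s) {
    cn <- cn_by_sample[[s]]
    stopifnot(length(cn) %in% c(1L, nrow(grid)))
    tibble::tibble(sample = s, chrom = grid$chrom, pos = grid$pos,
                   region = grid$region,
                   cn = if (length(cn) == 1) rep(cn, nrow(grid)) else cn,
                   masked = FALSE)
  })
  out <- dplyr::bind_rows(rows)
  if (!is.null(mask_fn)) out$masked <- mask_fn(out)
  attr(out, "gene") <- gene
  class(out) <- c("pgx_cn_profile", class(out))
  out
}

test_that("featurization bins profiles with masking-aware imputation", {
  p <- mk_profile("GSTT1", list(s1 = 2))
  f <- featurize_profile(p, bin_bp = 500)
  expect_true(all(abs(pgxstar:::feature_matrix(f) - 2) < 1e-12))

  # first half cn 2, second half cn 1, two bins -> (2, 1)
  gm <- dplyr::filter(pgx_gene_models(), gene == "GSTT1")
  span <- gm$gene_end - gm$gene_start
  grid <- pgxstar:::gene_position_grid("GSTT1")
  cn <- ifelse(grid$pos <= gm$gene_start + span / 2, 2, 1)
  p2 <- mk_profile("GSTT1", list(s1 = cn))
  f2 <- featurize_profile(p2, bin_bp = ceiling((span + 1) / 2))
  expect_equal(as.numeric(pgxstar:::feature_matrix(f2)), c(2, 1),
               tolerance = 0.05)

  # fully masked middle bin imputed from flanking bins
  third <- span / 3
  mask_mid <- function(d) d$pos > gm$gene_start + third &
    d$pos <= gm$gene_start + 2 * third
  cn3 <- ifelse(mask_mid(tibble::tibble(pos = grid$pos)), 99, 2)
  p3 <- mk_profile("GSTT1", list(s1 = cn3), mask_fn = mask_mid)
  f3 <- featurize_profile(p3, bin_bp = ceiling((span + 1) / 3))
  expect_equal(as.numeric(pgxstar:::feature_matrix(f3)), c(2, 2, 2),
               tolerance = 1e-9)

  expect_error(featurize_profile(p, bin_bp = 1e7),
               class = "pgx_validation_error")
})

test_that("training validates inputs and memorizes separable classes", {
  p <- mk_profile("GSTT1", as.list(setNames(c(2, 2, 2, 1, 1, 1),
                                            paste0("s", 1:6))))
  f <- featurize_profile(p, bin_bp = 2000)
  labels <- rep(c("normal", "del_het"), each = 3)
  m <- train_sv_classifier(f, labels, seed = 1)
  expect_equal(m$training_accuracy, 1.0)

  pred <- classify_sv(m, f)
  expect_equal(pred$sv_class, labels)
  expect_false(any(pred$indeterminate))

  expect_error(train_sv_classifier(f, rep("normal", 6)),
               class = "pgx_validation_error")
  expect_error(train_sv_classifier(f, c("a", "a", "a", "b", "b", "c")),
               class = "pgx_validation_error")
  expect_error(classify_sv(m, f[, 1:3]), class = "pgx_validation_error")
})

test_that("whole-gene deletion and normal patterns classify correctly", {
  ts <- make_training_set("CYP2D6", n_per_class = 10, seed = 5)
  m <- train_sv_classifier(ts$features, ts$labels, seed = 5)
  expect_equal(m$training_accuracy, 1.0)

  grid <- pgxstar:::gene_position_grid("CYP2D6")
  del <- ifelse(grid$region == "gene", 1, 2)
  probe <- mk_profile("CYP2D6", list(n1 = 2, d1 = del))
  pred <- classify_sv(m, featurize_profile(probe))
  expect_equal(pred$sv_class[pred$sample == "n1"], "normal")
  expect_equal(pred$sv_class[pred$sample == "d1"], "del_het")
})

test_that("profiles matching no trained class fall to Indeterminate", {
  ts <- make_training_set("CYP2D6", n_per_class = 10, seed = 5)
  m <- train_sv_classifier(ts$features, ts$labels, seed = 5)
  gm <- dplyr::filter(pgx_gene_models(), gene == "CYP2D6")
  grid <- pgxstar:::gene_position_grid("CYP2D6")
  mid <- (gm$gene_start + gm$gene_end) / 2
  # novel partial deletion: 3' half of the gene at cn 1
  cn <- ifelse(grid$region == "gene" & grid$pos > mid, 1, 2)
  probe <- mk_profile("CYP2D6", list(x1 = cn))
  pred <- classify_sv(m, featurize_profile(probe))
  expect_true(pred$indeterminate[1])
})

test_that("shuffled labels collapse held-out accuracy to near chance", {
  withr::with_seed(9, {
    ts <- make_training_set("CYP2D6", n_per_class = 12, seed = 9)
    idx <- sample(length(ts$labels))
    train_i <- idx[seq_len(floor(length(idx) * 0.7))]
    test_i <- setdiff(idx, train_i)
    shuffled <- sample(ts$labels[train_i])
    # guarantee >= 3 per class survives shuffling
    m <- train_sv_classifier(ts$features[train_i, ], shuffled, seed = 9)
    pred <- classify_sv(m, ts$features[test_i, ])
    acc <- mean(pred$sv_class == ts$labels[test_i])
    expect_lt(acc, 0.5)  # 7 classes; informed accuracy is ~1.0
  })
})

test_that("held-out accuracy on an informative training split is >= 0.99", {
  ts <- make_training_set("CYP2D6", n_per_class = 20, seed = 13)
  eval <- make_training_set("CYP2D6", n_per_class = 10, seed = 14)
  m <- train_sv_classifier(ts$features, ts$labels, seed = 13)
  pred <- classify_sv(m, eval$features)
  expect_gte(mean(pred$sv_class == eval$labels), 0.99)
})

test_that("classifier fits expose tidy and glance summaries", {
  ts <- make_training_set("GSTT1", n_per_class = 5, seed = 2)
  m <- train_sv_classifier(ts$features, ts$labels, seed = 2)
  td <- tidy(m)
  expect_setequal(td$class, c("normal", "del_het", "del_hom"))
  g <- glance(m)
  expect_equal(g$n_classes, 3L)
  expect_equal(g$training_accuracy, 1.0)
})
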