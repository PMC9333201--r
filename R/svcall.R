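#' Bin a copy-number profile into a fixed-length feature vector
#'
#' Averages copy number in fixed-width genomic bins over the gene (and, when
#' modeled, pseudogene) span, one feature vector per sample. Masked positions
#' are excluded from bin means; a bin left empty is imputed from the mean of
#' its flanking non-empty bins (nearest bin at the ends). Copy-number
#' profiles are near-piecewise-constant, so coarse bins preserve the SV
#' signal while suppressing per-base noise.
#'
#' @param p A `pgx_cn_profile` from [copy_number_profile()].
#' @param bin_bp Bin width in base pairs (default 500).
#' @return A tibble of class `pgx_cn_features`: `sample` plus numeric columns
#'   `f1 ... fK`; bin metadata in attribute `bins`.
#' @export
featurize_profile <- function(p, bin_bp = 500) {
  stopifnot(bin_bp > 0)
  gene <- attr(p, "gene")
  gm <- gene_model(gene)
  spans <- tibble(region = "gene", start = gm$gene_start, end = gm$gene_end)
  if (!is.na(gm$pseudo_start)) {
    spans <- bind_rows(spans, tibble(region = "pseudogene",
                                     start = gm$pseudo_start,
                                     end = gm$pseudo_end))
  }
  bins <- spans |>
    rowwise() |>
    reframe(region = .data$region,
            bin_start = seq(.data$start, .data$end, by = bin_bp)) |>
    mutate(bin_end = pmin(.data$bin_start + bin_bp - 1,
                          spans$end[match(.data$region, spans$region)]),
           bin = dplyr::row_number())
  if (diff(range(as_tibble(p)$pos)) + 1 < bin_bp) {
    abort("profile shorter than one bin", class = "pgx_validation_error")
  }

  pt <- as_tibble(p) |> filter(!.data$masked)
  assign_bin <- function(pos, region) {
    idx <- rep(NA_integer_, length(pos))
    for (i in seq_len(nrow(bins))) {
      sel <- region == bins$region[i] & pos >= bins$bin_start[i] &
        pos <= bins$bin_end[i]
      idx[sel] <- bins$bin[i]
    }
    idx
  }
  pt$bin <- assign_bin(pt$pos, pt$region)
  means <- pt |>
    filter(!is.na(.data$bin)) |>
    group_by(.data$sample, .data$bin) |>
    summarize(cn = mean(.data$cn), .groups = "drop")

  samples <- sort(unique(as_tibble(p)$sample))
  wide <- tidyr::crossing(sample = samples, bin = bins$bin) |>
    left_join(means, by = c("sample", "bin")) |>
    arrange(.data$sample, .data$bin)

  impute_row <- function(v) {
    if (!anyNA(v)) return(v)
    if (all(is.na(v))) {
      abort("profile has no usable positions", class = "pgx_validation_error")
    }
    idx <- which(is.na(v))
    ok <- which(!is.na(v))
    for (i in idx) {
      left <- ok[ok < i]
      right <- ok[ok > i]
      neigh <- c(if (length(left)) v[max(left)], if (length(right)) v[min(right)])
      v[i] <- mean(neigh)
    }
    v
  }
  mat <- matrix(wide$cn, nrow = length(samples), byrow = TRUE,
                dimnames = list(samples, paste0("f", bins$bin)))
  mat <- t(apply(mat, 1, impute_row))
  out <- as_tibble(mat, rownames = "sample")
  attr(out, "bins") <- bins
  attr(out, "gene") <- gene
  attr(out, "bin_bp") <- bin_bp
  class(out) <- c("pgx_cn_features", class(out))
  out
}

feature_matrix <- function(features) {
  as.matrix(as_tibble(features)[setdiff(names(features), "sample")])
}

#' Train a one-vs-rest SVM structural-variant classifier
#'
#' Fits one binary support vector machine per structural-variant class
#' against the rest, on binned copy-number feature vectors; the multiclass
#' decision is the largest one-vs-rest decision value. The kernel is RBF:
#' copy-number plateaus are ordered along a line, so an interior class
#' (e.g. a heterozygous deletion at CN 1, between homozygous deletion at 0
#' and diploid at 2) cannot be cut from "the rest" by any single linear
#' hyperplane, while the RBF machine carves the bounded region around the
#' plateau directly. The model also stores
#' per-class centroids and a calibration quantile of standardized training
#' distances, used by [classify_sv()] to refuse profiles unlike any trained
#' class (the Indeterminate escape hatch for novel SVs).
#'
#' @param features A `pgx_cn_features` tibble (or plain tibble with a
#'   `sample` column and numeric features).
#' @param labels Character vector of class labels, one per row; at least two
#'   classes with three examples each.
#' @param seed Integer seed (training is deterministic given it).
#' @param cost SVM cost parameter.
#' @param calibration_quantile Quantile of training distances used as the
#'   novelty threshold (default 0.995).
#' @return An object of class `pgx_sv_classifier` with [tidy()], [glance()]
#'   and [classify_sv()] methods.
#' @export
train_sv_classifier <- function(features, labels, seed = 1L, cost = 10,
                                calibration_quantile = 0.995) {
  x <- feature_matrix(features)
  labels <- as.character(labels)
  stopifnot(nrow(x) == length(labels))
  classes <- sort(unique(labels))
  if (length(classes) < 2) {
    abort("need at least two classes to train", class = "pgx_validation_error")
  }
  counts <- table(labels)
  if (any(counts < 3)) {
    abort("need at least three examples per class",
          class = "pgx_validation_error")
  }

  machines <- withr::with_seed(seed, {
    lapply(classes, function(cl) {
      y <- factor(ifelse(labels == cl, "yes", "no"), levels = c("yes", "no"))
      e1071::svm(x, y, kernel = "radial", cost = cost, scale = FALSE,
                 probability = FALSE)
    })
  })
  names(machines) <- classes

  centroids <- t(vapply(classes, function(cl) {
    colMeans(x[labels == cl, , drop = FALSE])
  }, numeric(ncol(x))))
  # per-class spread: count noise grows with the copy-number level, so each
  # class is calibrated against its own training distances; the floor guards
  # against degenerate (noise-free) features and absorbs cross-cohort
  # normalization wobble at typical panel depths
  feat_sd <- t(vapply(classes, function(cl) {
    resid_cl <- sweep(x[labels == cl, , drop = FALSE], 2,
                      centroids[match(cl, classes), ], `-`)
    pmax(apply(resid_cl, 2, stats::sd), 0.15)
  }, numeric(ncol(x))))
  class_dist <- function(xm, cl) {
    i <- match(cl, classes)
    sqrt(rowSums(sweep(sweep(xm, 2, centroids[i, ], `-`), 2,
                       feat_sd[i, ], `/`)^2))
  }
  dist_threshold <- vapply(classes, function(cl) {
    d_cl <- class_dist(x[labels == cl, , drop = FALSE], cl)
    as.numeric(quantile(d_cl, calibration_quantile)) * 1.5
  }, numeric(1))

  model <- structure(list(
    classes = classes,
    machines = machines,
    centroids = centroids,
    feat_sd = feat_sd,
    dist_threshold = dist_threshold,
    n_features = ncol(x),
    feature_names = colnames(x),
    gene = attr(features, "gene"),
    seed = seed
  ), class = "pgx_sv_classifier")

  pred <- classify_sv(model, features)
  model$training_accuracy <- mean(pred$sv_class == labels)
  model
}

sv_decision_values <- function(m, x) {
  out <- vapply(m$classes, function(cl) {
    p <- predict(m$machines[[cl]], x, decision.values = TRUE)
    dvm <- attr(p, "decision.values")
    # orient so positive always means "this class"
    if (colnames(dvm)[1] == "yes/no") dvm[, 1] else -dvm[, 1]
  }, numeric(nrow(x)))
  if (nrow(x) == 1) {
    out <- matrix(out, nrow = 1, dimnames = list(NULL, m$classes))
  }
  out
}

#' Classify structural-variant configurations
#'
#' Applies a trained one-vs-rest classifier to copy-number feature vectors.
#' A sample is called `indeterminate` when its top one-vs-rest decision value
#' is negative (no machine claims it) or its standardized distance to the
#' winning class centroid exceeds the model's calibration threshold — the
#' behavior expected for novel SVs absent from the class registry.
#'
#' @param m A `pgx_sv_classifier`.
#' @param features A `pgx_cn_features` tibble with the training feature
#'   layout.
#' @return A tibble of class `pgx_sv_calls`: `sample`, `sv_class`, `margin`
#'   (top decision value), `dist` (standardized centroid distance),
#'   `indeterminate`.
#' @export
classify_sv <- function(m, features) {
  x <- feature_matrix(features)
  if (ncol(x) != m$n_features) {
    abort(sprintf("feature length %d does not match training length %d",
                  ncol(x), m$n_features),
          class = "pgx_validation_error")
  }
  dv <- sv_decision_values(m, x)
  if (is.null(dim(dv))) dv <- matrix(dv, nrow = 1,
                                     dimnames = list(NULL, m$classes))
  best <- max.col(dv, ties.method = "first")
  margin <- dv[cbind(seq_len(nrow(x)), best)]
  cent <- m$centroids[best, , drop = FALSE]
  sds <- m$feat_sd[best, , drop = FALSE]
  dist <- sqrt(rowSums(((x - cent) / sds)^2))
  out <- tibble(
    sample = as_tibble(features)$sample,
    sv_class = m$classes[best],
    margin = margin,
    dist = dist,
    indeterminate = margin < 0 | dist > m$dist_threshold[best]
  )
  class(out) <- c("pgx_sv_calls", class(out))
  out
}

#' @export
print.pgx_sv_classifier <- function(x, ...) {
  cat(sprintf("One-vs-rest linear SVM for %s: %d classes, %d features\n",
              x$gene %||% "unspecified gene", length(x$classes), x$n_features))
  cat("  classes:", paste(x$classes, collapse = ", "), "\n")
  if (!is.null(x$training_accuracy)) {
    cat(sprintf("  training accuracy: %.3f\n", x$training_accuracy))
  }
  invisible(x)
}

#' @export
tidy.pgx_sv_classifier <- function(x, ...) {
  tibble(
    class = x$classes,
    n_support_vectors = map_int(x$machines, ~ .x$tot.nSV),
    centroid_gene_cn = round(rowMeans(x$centroids), 2)
  )
}

#' @export
glance.pgx_sv_classifier <- function(x, ...) {
  tibble(
    gene = x$gene %||% NA_character_,
    n_classes = length(x$classes),
    n_features = x$n_features,
    training_accuracy = x$training_accuracy %||% NA_real_,
    max_dist_threshold = max(x$dist_threshold)
  )
}
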