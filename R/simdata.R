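#' Simulation configuration
#'
#' Bundles the knobs of the synthetic-cohort generator. Defaults emulate the
#' targeted-capture regime the pipeline is designed for: mean on-target
#' depth 250x with negative-binomial overdispersion (dispersion 0.1, i.e.
#' per-base coefficient of variation around 0.33 at 250x), per-position
#' capture efficiency drawn once per cohort from a log-normal with sdlog
#' 0.2, per-sample library-size factors log-normal with sdlog 0.2, and two
#' haplotype-private passenger heterozygous variants per sample (emulating
#' suballele variation, which is what makes same-allele copy configurations
#' such as 1:3 vs 2:2 distinguishable by allele fraction).
#'
#' @param n_samples Number of samples.
#' @param mixture Named numeric vector of diplotype weights, names
#'   `"alleleA/alleleB"`; `NULL` defers to per-call defaults.
#' @param mean_depth Mean on-target depth for a diploid position.
#' @param dispersion Negative-binomial dispersion (0 = deterministic).
#' @param capture_sd sdlog of per-position capture efficiency (0 = uniform).
#' @param library_sd sdlog of per-sample library-size factors.
#' @param n_passengers Haplotype-private passenger het variants per sample.
#' @param seed Integer seed; every derived dataset is reproducible from it.
#' @return A list of class `pgx_sim_config`.
#' @export
sim_config <- function(n_samples = 50L, mixture = NULL, mean_depth = 250,
                       dispersion = 0.1, capture_sd = 0.2, library_sd = 0.2,
                       n_passengers = 2L, seed = 1L) {
  stopifnot(mean_depth > 0, dispersion >= 0, n_samples >= 1)
  if (!is.null(mixture)) {
    stopifnot(abs(sum(mixture) - 1) < 1e-8)
  }
  structure(list(n_samples = as.integer(n_samples), mixture = mixture,
                 mean_depth = mean_depth, dispersion = dispersion,
                 capture_sd = capture_sd, library_sd = library_sd,
                 n_passengers = as.integer(n_passengers),
                 seed = as.integer(seed)),
            class = "pgx_sim_config")
}

# default diplotype mixtures per gene: allele frequencies loosely shaped on
# diverse-cohort reports (deletion alleles common for GSTT1/GSTM1/UGT2B17)
default_mixture <- function(gene) {
  switch(gene,
    CYP2D6 = c("*1/*1" = 0.18, "*1/*2" = 0.14, "*1/*4" = 0.10,
               "*2/*41" = 0.08, "*4/*10" = 0.07, "*1/*10" = 0.08,
               "*1/*5" = 0.07, "*4/*5" = 0.04, "*1/*2x2" = 0.06,
               "*1x2/*4" = 0.04, "*1/*36+*10" = 0.06,
               "*10/*36+*10" = 0.04, "*1/*36x2+*10" = 0.04,
               "*1/*68+*4" = 0.04, "*5/*5" = 0.02, "*17/*29" = 0.04),
    CYP2E1 = c("*1/*1" = 0.38, "*1/*5" = 0.10, "*1/*7" = 0.14,
               "*7/*7" = 0.06, "*1/*7x2" = 0.08, "*7/*7x2" = 0.04,
               "*7/*7x3" = 0.06, "*7x2/*7x2" = 0.06, "*1/*S1" = 0.08),
    GSTT1 = c("*A/*A" = 0.25, "*A/*0" = 0.45, "*0/*0" = 0.30),
    GSTM1 = c("*A/*A" = 0.20, "*A/*B" = 0.10, "*A/*0" = 0.40,
              "*0/*0" = 0.25, "*A/*Ax2" = 0.05),
    UGT2B17 = c("*1/*1" = 0.30, "*1/*2" = 0.45, "*2/*2" = 0.25),
    CYP2A6 = c("*1/*1" = 0.50, "*1/*2" = 0.12, "*1/*9" = 0.14,
               "*1/*4" = 0.12, "*4/*9" = 0.04, "*1/*1x2" = 0.08),
    CYP2B6 = c("*1/*1" = 0.40, "*1/*6" = 0.25, "*6/*6" = 0.10,
               "*1/*9" = 0.08, "*6/*9" = 0.05, "*1/*29" = 0.12),
    abort(paste0("no default mixture for ", gene),
          class = "pgx_validation_error")
  )
}

#' Draw ground-truth diplotypes and library factors for a cohort
#'
#' @param cfg A [sim_config()].
#' @param gene Gene symbol.
#' @return A tibble of class `pgx_sim_truth`: `sample`, `allele_1`,
#'   `allele_2`, `diplotype`, `sv_class`, `lib_factor`, `no_sv`.
#' @export
simulate_truth <- function(cfg, gene) {
  mixture <- cfg$mixture %||% default_mixture(gene)
  table <- pgx_translation_tables(gene)
  ref <- reference_allele(table, gene)
  withr::with_seed(cfg$seed, {
    dips <- sample(names(mixture), cfg$n_samples, replace = TRUE,
                   prob = mixture)
    # mean-one library factors so configured mean depth is the cell mean
    lib <- rlnorm(cfg$n_samples, meanlog = -cfg$library_sd^2 / 2,
                  sdlog = cfg$library_sd)
    out <- tibble(
      sample = sprintf("S%03d", seq_len(cfg$n_samples)),
      allele_1 = map_chr(str_split(dips, "/"), 1),
      allele_2 = map_chr(str_split(dips, "/"), 2),
      lib_factor = lib
    ) |>
      mutate(
        diplotype = map2_chr(.data$allele_1, .data$allele_2,
                             ~ render_diplotype(.x, .y, ref)),
        sv_class = map2_chr(.data$allele_1, .data$allele_2,
                            ~ diplotype_sv_class(gene, .x, .y)),
        no_sv = .data$sv_class == "normal"
      )
    attr(out, "gene") <- gene
    attr(out, "seed") <- cfg$seed
    class(out) <- c("pgx_sim_truth", class(out))
    out
  })
}

#' @importFrom purrr map2_chr
NULL

#' Simulate a targeted-capture depth matrix
#'
#' Per-cell depth is an overdispersed count with mean
#' `mean_depth * lib_factor(s) * efficiency(p) * cn(s, p) / 2`, where the
#' copy-number track comes from each sample's true diplotype (via the
#' haplotype templates) and the control locus is simulated copy-neutral
#' (cn 2). With `dispersion = 0` the matrix is the deterministic mean.
#' Repeated runs with the same config are bit-identical.
#'
#' @param cfg A [sim_config()].
#' @param gene Gene symbol.
#' @param truth Output of [simulate_truth()] (regenerated when `NULL`).
#' @return A `pgx_depth_matrix` covering the gene (+ pseudogene) grid and
#'   the VDR control grid; the seed is kept in attribute `seed`.
#' @export
simulate_depth <- function(cfg, gene, truth = NULL) {
  truth <- truth %||% simulate_truth(cfg, gene)
  grid <- bind_rows(
    gene_position_grid(gene),
    mutate(gene_position_grid("VDR"), region = "control")
  )
  n_pos <- nrow(grid)
  n_s <- nrow(truth)

  cn <- matrix(2, nrow = n_pos, ncol = n_s)
  for (i in seq_len(n_s)) {
    track <- expected_cn_track(gene, truth$allele_1[i], truth$allele_2[i])
    cn[grid$region != "control", i] <- track$cn
  }

  withr::with_seed(cfg$seed + 1000L, {
    eff <- if (cfg$capture_sd > 0) {
      rlnorm(n_pos, meanlog = -cfg$capture_sd^2 / 2, sdlog = cfg$capture_sd)
    } else {
      rep(1, n_pos)
    }
    mu <- sweep(cn / 2 * cfg$mean_depth * eff, 2, truth$lib_factor, `*`)
    depth <- if (cfg$dispersion > 0) {
      matrix(rnbinom(n_pos * n_s, mu = mu, size = 1 / cfg$dispersion),
             nrow = n_pos)
    } else {
      mu
    }
  })
  df <- bind_cols(tibble(chrom = grid$chrom, pos = grid$pos),
                  as_tibble(setNames(as.data.frame(depth), truth$sample)))
  out <- depth_matrix(df)
  attr(out, "seed") <- cfg$seed
  attr(out, "gene") <- gene
  out
}

# passenger position pool: on-grid gene positions not used by any catalog
# defining variant
passenger_positions <- function(gene, table) {
  gm <- gene_model(gene)
  grid <- filter(gene_position_grid(gene), .data$region == "gene")
  used <- bind_rows(filter(table, .data$gene == !!gene)$defining_variants)
  setdiff(grid$pos, used$pos)
}

#' Simulate a multi-sample variant table for a truth set
#'
#' Each sample's genotypes carry the defining variants of its two alleles
#' (hybrids contribute their embedded conventional allele; deletion
#' haplotypes contribute nothing, so remaining variants appear hemizygous
#' i.e. homozygous in the diploid representation). Allelic depths at each
#' site are binomial with success probability `carrying copies / total
#' copies` at the site, read depth taken from the simulated depth matrix at
#' the nearest grid position. `n_passengers` haplotype-private passenger het
#' variants per sample make same-base-allele copy configurations resolvable
#' from allele fractions.
#'
#' @param truth A `pgx_sim_truth`.
#' @param table Translation table for the gene.
#' @param depth A simulated depth matrix.
#' @param cfg The [sim_config()] used for the cohort.
#' @return A `pgx_variant_table` (unphased, with AD fields).
#' @export
simulate_variant_table <- function(truth, table, depth,
                                   cfg = sim_config()) {
  gene <- attr(truth, "gene")
  dm <- as_tibble(depth)
  gm <- gene_model(gene)
  gene_rows <- dm$chrom == gm$chrom & dm$pos >= gm$gene_start &
    dm$pos <= gm$gene_end
  dpos <- dm$pos[gene_rows]
  pool <- passenger_positions(gene, table)

  site_depth <- function(sample, pos) {
    col <- dm[[sample]][gene_rows]
    idx <- map_int(pos, ~ which.min(abs(dpos - .x)))
    pmax(round(col[idx]), 1)
  }

  hyb <- hybrid_registry()
  allele_keys <- function(allele) {
    parsed <- parse_allele_name(allele)
    hit <- filter(hyb, .data$gene == !!gene, .data$allele == !!allele)
    lookup <- if (nrow(hit)) {
      if (is.na(hit$embedded[1])) return(tibble(chrom = character(),
                                                pos = integer(),
                                                ref = character(),
                                                alt = character()))
      hit$embedded[1]
    } else {
      parsed$base
    }
    row <- filter(table, .data$gene == !!gene, .data$allele == lookup)
    if (!nrow(row)) {
      abort(paste0("unknown allele name: ", allele),
            class = "pgx_validation_error")
    }
    row$defining_variants[[1]]
  }

  recs <- withr::with_seed(cfg$seed + 2000L, {
    map(seq_len(nrow(truth)), function(i) {
      s <- truth$sample[i]
      alleles <- c(truth$allele_1[i], truth$allele_2[i])
      hap_sites <- map(alleles, allele_keys)
      # copy count contributed by each haplotype at its variant positions
      out <- list()
      all_sites <- bind_rows(
        mutate(hap_sites[[1]], hap = 1L),
        mutate(hap_sites[[2]], hap = 2L)
      )
      # passengers: private to one physical chromosome
      if (cfg$n_passengers > 0 && length(pool) >= cfg$n_passengers) {
        ppos <- sample(pool, cfg$n_passengers)
        phap <- sample(1:2, cfg$n_passengers, replace = TRUE)
        all_sites <- bind_rows(all_sites,
                               tibble(chrom = gm$chrom,
                                      pos = as.integer(ppos),
                                      ref = "A", alt = "G", hap = phap))
      }
      if (!nrow(all_sites)) return(NULL)
      cn1 <- hap_copies_at(gene, alleles[1], all_sites$pos)
      cn2 <- hap_copies_at(gene, alleles[2], all_sites$pos)
      carrying <- ifelse(all_sites$hap == 1L, cn1, cn2)
      # variants shared by both haplotypes (same site, both alleles)
      key <- render_variant_key(all_sites)
      agg <- tibble(key = key, chrom = all_sites$chrom,
                    pos = all_sites$pos, ref = all_sites$ref,
                    alt = all_sites$alt, carrying = carrying,
                    total = cn1 + cn2) |>
        group_by(.data$key, .data$chrom, .data$pos, .data$ref, .data$alt,
                 .data$total) |>
        summarize(carrying = sum(.data$carrying), n_haps = n(),
                  .groups = "drop") |>
        filter(.data$carrying > 0, .data$total > 0)
      if (!nrow(agg)) return(NULL)
      nd <- site_depth(s, agg$pos)
      alt_reads <- rbinom(nrow(agg), nd, pmin(agg$carrying / agg$total, 1))
      gt_hom <- agg$carrying >= agg$total
      tibble(chrom = agg$chrom, pos = agg$pos, ref = agg$ref, alt = agg$alt,
             sample = s,
             gt_1 = ifelse(gt_hom, 1L, 0L), gt_2 = 1L,
             phased = FALSE,
             ad_ref = as.integer(nd - alt_reads),
             ad_alt = as.integer(alt_reads))
    })
  })
  empty <- tibble(chrom = character(), pos = integer(), ref = character(),
                  alt = character(), sample = character(), gt_1 = integer(),
                  gt_2 = integer(), phased = logical(), ad_ref = integer(),
                  ad_alt = integer())
  variant_table(bind_rows(empty, bind_rows(recs)), samples = truth$sample)
}

#' Simulate a labeled structural-variant training set
#'
#' Generates `n_per_class` cohort members per registered SV class for a gene
#' (class recipes are the haplotype-template pairs of
#' [sv_class_registry()]), runs the standard normalization (control-gene
#' statistics, copy-number profile with all-sample cohort reference over a
#' class-balanced cohort), and returns binned features plus labels, ready
#' for [train_sv_classifier()]. Reproducible under `seed`.
#'
#' @param gene Gene symbol.
#' @param classes Class labels to include; default all registered classes.
#' @param n_per_class Examples per class (default 30).
#' @param cfg Base [sim_config()]; its `n_samples`/`mixture` are ignored.
#' @param seed Integer seed.
#' @param bin_bp Feature bin width.
#' @return A list with `features` (a `pgx_cn_features` tibble), `labels`
#'   (character), and `truth`.
#' @export
make_training_set <- function(gene, classes = NULL, n_per_class = 30L,
                              cfg = sim_config(), seed = 1L, bin_bp = 500) {
  reg <- sv_class_registry(gene)
  classes <- classes %||% reg$class
  bad <- setdiff(classes, reg$class)
  if (length(bad)) {
    abort(paste0("unregistered SV class(es) for ", gene, ": ",
                 paste(bad, collapse = ", ")),
          class = "pgx_validation_error")
  }
  sub <- reg[match(classes, reg$class), ]

  # build a truth table directly from the class recipes
  n <- length(classes) * n_per_class
  truth <- withr::with_seed(seed, {
    tibble(
      sample = sprintf("T%04d", seq_len(n)),
      class = rep(classes, each = n_per_class),
      lib_factor = rlnorm(n, -cfg$library_sd^2 / 2, cfg$library_sd)
    )
  })
  # representative diplotype per class: template haplotype kinds mapped back
  # to allele names
  kind_allele <- function(kind) {
    switch(kind,
      ref = reference_allele(pgx_translation_tables(gene), gene),
      del = deletion_allele_name(gene),
      del3p = deletion_allele_name(gene, partial = TRUE),
      dup2 = attach_copy_suffix(
        reference_allele(pgx_translation_tables(gene), gene), 2L),
      dup3 = attach_copy_suffix(
        reference_allele(pgx_translation_tables(gene), gene), 3L),
      dup5p = "*S1",
      hyb36_10 = "*36+*10",
      hyb36x2_10 = "*36x2+*10",
      hyb68_4 = "*68+*4",
      hyb29 = "*29"
    )
  }
  truth$allele_1 <- map_chr(truth$class,
                            ~ kind_allele(sub$hap_a[match(.x, sub$class)]))
  truth$allele_2 <- map_chr(truth$class,
                            ~ kind_allele(sub$hap_b[match(.x, sub$class)]))
  attr(truth, "gene") <- gene

  tcfg <- cfg
  tcfg$seed <- as.integer(seed)
  d <- simulate_depth(tcfg, gene, truth)
  cs <- compute_control_statistics(d)
  no_sv <- truth$sample[truth$class == "normal"]
  prof <- if (length(no_sv)) {
    copy_number_profile(d, gene, cs, cohort_mode = "no_sv_samples",
                        no_sv_ids = no_sv)
  } else {
    copy_number_profile(d, gene, cs, cohort_mode = "all_samples")
  }
  feats <- featurize_profile(prof, bin_bp = bin_bp)
  labels <- truth$class[match(as_tibble(feats)$sample, truth$sample)]
  list(features = feats, labels = labels, truth = truth)
}

#' Simulate a complete cohort for one gene
#'
#' Convenience wrapper producing the three pipeline inputs (depth matrix,
#' variant table, truth ledger) from one config.
#'
#' @param gene Gene symbol.
#' @param cfg A [sim_config()].
#' @return A list with `truth`, `depth`, `variants`,
#'   `table` (the translation table used).
#' @export
simulate_cohort <- function(gene, cfg = sim_config()) {
  table <- pgx_translation_tables(gene)
  truth <- simulate_truth(cfg, gene)
  depth <- simulate_depth(cfg, gene, truth)
  variants <- simulate_variant_table(truth, table, depth, cfg)
  list(truth = truth, depth = depth, variants = variants, table = table)
}
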