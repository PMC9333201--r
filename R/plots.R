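#' Plot a copy-number profile
#'
#' One panel per sample: per-position copy number over the gene (and
#' pseudogene) span, the visual evidence behind SV calls — whole-gene
#' deletions sit at 1 or 0, duplications at 3+, hybrids show a step at the
#' conversion breakpoint.
#'
#' @param object A `pgx_cn_profile`.
#' @param samples Optional subset of sample ids.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pgx_cn_profile <- function(object, samples = NULL, ...) {
  d <- as_tibble(object) |> filter(!.data$masked)
  if (!is.null(samples)) d <- filter(d, .data$sample %in% samples)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pos, y = .data$cn,
                                  colour = .data$region)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6) +
    ggplot2::geom_hline(yintercept = 2, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::facet_wrap(~sample) +
    ggplot2::labs(x = "position (bp)", y = "copy number",
                  title = paste0(attr(object, "gene") %||% "", " copy number"),
                  subtitle = paste0("normalization: ",
                                    attr(object, "cohort_mode") %||% "")) +
    ggplot2::theme_minimal()
}

#' Plot an allele-fraction profile
#'
#' Alt-allele read fractions at non-reference sites; guide lines at 1/4,
#' 1/3, 1/2, 2/3 and 3/4 mark the fractions expected from common copy
#' configurations (e.g. a 1:3 duplication shows sites at 0.25/0.75).
#'
#' @param object A `pgx_af_profile`.
#' @param samples Optional subset of sample ids.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pgx_af_profile <- function(object, samples = NULL, ...) {
  d <- as_tibble(object)
  if (!is.null(samples)) d <- filter(d, .data$sample %in% samples)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pos, y = .data$fraction)) +
    ggplot2::geom_point(size = 1, alpha = 0.8) +
    ggplot2::geom_hline(yintercept = c(0.25, 1 / 3, 0.5, 2 / 3, 0.75),
                        linetype = "dotted", colour = "grey50") +
    ggplot2::ylim(0, 1) +
    ggplot2::facet_wrap(~sample) +
    ggplot2::labs(x = "position (bp)", y = "alt allele fraction") +
    ggplot2::theme_minimal()
}

#' Plot per-sample genotype concordance
#'
#' Overall concordance per sample with the cohort mean; outliers far below
#' the mean are the signature of sample swaps.
#'
#' @param object A `pgx_concordance_report`.
#' @param threshold Flagging threshold drawn as a reference line.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pgx_concordance_report <- function(object, threshold = 0.90, ...) {
  d <- as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$sample,
                                                     .data$overall_concordance),
                                  y = .data$overall_concordance)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = attr(object, "cohort_mean"),
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = threshold, colour = "firebrick",
                        linetype = "dotted") +
    ggplot2::coord_flip(ylim = c(min(d$overall_concordance) * 0.95, 1)) +
    ggplot2::labs(x = NULL, y = "genotype concordance") +
    ggplot2::theme_minimal()
}
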