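#' QQ plot of association p-values
#'
#' Observed against expected -log10 p-values, separately per cis/trans
#' class; early departure of the cis curve from the diagonal is the usual
#' signature that cis effects are easier to detect.
#'
#' @param assocs Association tibble with `p` and `class` columns.
#' @return A ggplot object.
#' @export
plot_qq <- function(assocs) {
  df <- dplyr::mutate(
    dplyr::arrange(dplyr::group_by(tibble::as_tibble(assocs), .data$class),
                   .data$p),
    expected = -log10(stats::ppoints(dplyr::n())),
    observed = -log10(.data$p)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$expected, .data$observed,
                                   colour = .data$class)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::labs(x = expression(Expected ~ -log[10](p)),
                  y = expression(Observed ~ -log[10](p)),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.eqtl_scan <- function(object, ...) plot_qq(object)

#' Density of the reference allelic ratio
#'
#' The mapping-bias diagnostic: sites with ratio above 0.51 are shown in
#' red, below 0.49 in blue, the near-balanced band in grey.
#'
#' @param x An `ase_ratio_summary` from [allelic_ratio_distribution()], or
#'   a count tibble to summarize first.
#' @return A ggplot object.
#' @export
plot_allelic_ratio <- function(x) {
  if (!inherits(x, "ase_ratio_summary")) x <- allelic_ratio_distribution(x)
  df <- tibble::tibble(ratio = x$ratios)
  df$band <- cut(df$ratio, c(-Inf, 0.49, 0.51, Inf),
                 labels = c("< 0.49", "0.49-0.51", "> 0.51"))
  ggplot2::ggplot(df, ggplot2::aes(.data$ratio, fill = .data$band)) +
    ggplot2::geom_histogram(breaks = seq(0, 1, 0.02)) +
    ggplot2::scale_fill_manual(
      values = c("< 0.49" = "#4575b4", "0.49-0.51" = "grey60",
                 "> 0.51" = "#d73027"), drop = FALSE
    ) +
    ggplot2::labs(x = "reference allelic ratio", y = "sites",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.ase_ratio_summary <- function(object, ...) plot_allelic_ratio(object)

#' Pleiotropy histogram
#'
#' Counts of eQTL per genes-per-eQTL bin, cis and trans side by side.
#'
#' @param pleio Result of [pleiotropy_summary()].
#' @return A ggplot object.
#' @export
plot_pleiotropy <- function(pleio) {
  ggplot2::ggplot(pleio$bins,
                  ggplot2::aes(.data$bin, .data$n_snps, fill = .data$class)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "associated genes per eQTL", y = "eQTL count",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Hotspot map
#'
#' Genes-per-eQTL along the genome; SNPs above the hotspot threshold are
#' highlighted.
#'
#' @param pleio Result of [pleiotropy_summary()].
#' @param hotspot_min Highlight SNPs with more genes than this (default 3).
#' @return A ggplot object.
#' @export
plot_hotspots <- function(pleio, hotspot_min = 3) {
  df <- dplyr::bind_rows(
    dplyr::mutate(pleio$hotspots, hotspot = TRUE)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$pos / 1e6, .data$n_genes,
                                   colour = .data$class)) +
    ggplot2::geom_point() +
    ggplot2::facet_grid(.data$class ~ .data$chrom, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "associated genes") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
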