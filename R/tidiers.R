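# broom-style tidiers and ggplot2 autoplot methods for the result types.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an association scan
#'
#' The scan tables are already one-row-per-SNP; `tidy()` strips the
#' result class so the output is a plain tibble.
#'
#' @param x A `gwas_result` or `gweis_result`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.gwas_result <- function(x, ...) {
  tibble::as_tibble(unclass_result(x))
}

#' @rdname tidy.gwas_result
#' @export
tidy.gweis_result <- function(x, ...) {
  tibble::as_tibble(unclass_result(x))
}

unclass_result <- function(x) {
  class(x) <- setdiff(class(x), c("gwas_result", "gweis_result",
                                  "prs_profile", "weight_table",
                                  "model_comparison", "improvement_report"))
  x
}

#' One-row summary of an association scan
#'
#' Reports the scan size and the genomic-control inflation of its
#' p-values (both test types for an interaction scan).
#'
#' @param x A `gwas_result` or `gweis_result`.
#' @param ... Unused.
#' @return A one-row tibble with `n`, `n_snps`, `n_ok`, `lambda_gc`
#'   (and `lambda_gc_joint` for GWEIS), `lambda_1000`, `min_p`.
#' @export
glance.gwas_result <- function(x, ...) {
  n <- attr(x, "n")
  infl <- genomic_inflation(x$p[x$status == "ok"], n)
  tibble::tibble(
    n = n, n_snps = nrow(x), n_ok = sum(x$status == "ok"),
    lambda_gc = infl$lambda_gc, lambda_1000 = infl$lambda_1000,
    min_p = min(x$p, na.rm = TRUE)
  )
}

#' @rdname glance.gwas_result
#' @export
glance.gweis_result <- function(x, ...) {
  n <- attr(x, "n")
  ok <- x$status == "ok"
  gxe <- genomic_inflation(x$p_gxe[ok], n)
  joint <- genomic_inflation(x$p_joint[ok & !is.na(x$p_joint)], n)
  tibble::tibble(
    n = n, n_snps = nrow(x), n_ok = sum(ok),
    robust = attr(x, "robust"),
    lambda_gc = gxe$lambda_gc, lambda_1000 = gxe$lambda_1000,
    lambda_gc_joint = joint$lambda_gc,
    min_p_gxe = min(x$p_gxe, na.rm = TRUE),
    min_p_joint = min(x$p_joint, na.rm = TRUE)
  )
}

#' Tidy / summarise a model comparison
#'
#' @param x A `model_comparison`.
#' @param ... Unused.
#' @return `tidy()`: the comparison as a plain tibble with the term
#'   sets flattened to `+`-separated strings. `glance()`: the numeric
#'   summary columns only.
#' @export
tidy.model_comparison <- function(x, ...) {
  out <- tibble::as_tibble(unclass_result(x))
  out$terms_null <- vapply(out$terms_null, paste, "", collapse = " + ")
  out$terms_full <- vapply(out$terms_full, paste, "", collapse = " + ")
  out
}

#' @rdname tidy.model_comparison
#' @export
glance.model_comparison <- function(x, ...) {
  tibble::as_tibble(unclass_result(x))[, c("r2_null", "r2_full",
                                           "incremental_r2", "lrt_stat",
                                           "lrt_df", "lrt_p", "n")]
}

#' Manhattan plot of an association scan
#'
#' @param object A `gwas_result` or `gweis_result`.
#' @param test For GWEIS results, which p-value to plot: `"gxe"`
#'   (default) or `"joint"`.
#' @param threshold Genome-wide significance line (default 5e-8).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gwas_result <- function(object, threshold = 5e-8, ...) {
  manhattan_plot(object, "p", threshold)
}

#' @rdname autoplot.gwas_result
#' @export
autoplot.gweis_result <- function(object, test = c("gxe", "joint"),
                                  threshold = 5e-8, ...) {
  test <- match.arg(test)
  manhattan_plot(object, paste0("p_", test), threshold)
}

manhattan_plot <- function(res, p_col, threshold) {
  d <- tibble::as_tibble(unclass_result(res))
  d <- d[!is.na(d[[p_col]]), ]
  d$chr <- factor(d$chr, levels = unique(d$chr))
  d <- dplyr::group_by(d, .data$chr)
  d <- dplyr::mutate(d, x = dplyr::cur_group_id() * 1e9 + .data$bp)
  d <- dplyr::ungroup(d)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x,
                                  y = -log10(.data[[p_col]]),
                                  colour = .data$chr)) +
    ggplot2::geom_point(size = 0.6, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = -log10(threshold), linetype = 2) +
    ggplot2::scale_x_continuous(breaks = NULL) +
    ggplot2::labs(x = "chromosome", y = expression(-log[10](p))) +
    ggplot2::theme_minimal()
}

#' Quantile-quantile plot of a p-value vector
#'
#' @param pvals Numeric vector of p-values.
#' @return A ggplot object with the uniform reference diagonal.
#' @export
plot_qq <- function(pvals) {
  p <- sort(pvals[!is.na(pvals)])
  d <- tibble::tibble(expected = -log10(stats::ppoints(length(p))),
                      observed = -log10(p))
  ggplot2::ggplot(d, ggplot2::aes(.data$expected, .data$observed)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::labs(x = expression(expected ~ -log[10](p)),
                  y = expression(observed ~ -log[10](p))) +
    ggplot2::theme_minimal()
}

#' Distribution of polygenic scores
#'
#' @param object A `prs_profile`.
#' @param ... Unused.
#' @return A ggplot histogram of the standardised scores.
#' @export
autoplot.prs_profile <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(unclass_result(object)),
                  ggplot2::aes(.data$score_std)) +
    ggplot2::geom_histogram(bins = 40) +
    ggplot2::labs(x = "standardised PRS", y = "count") +
    ggplot2::theme_minimal()
}

#' Heatmap of variance explained across traits and weighting schemes
#'
#' Renders an [improvement_report()] as a traits-by-schemes tile map
#' with the percentage of variance explained printed in each cell,
#' starred by LRT significance.
#'
#' @param object An `improvement_report`.
#' @param value Column to fill by (default `"incremental_r2"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.improvement_report <- function(object, value = "incremental_r2",
                                        ...) {
  d <- tibble::as_tibble(unclass_result(object))
  d$label <- sprintf("%.2f%%%s", 100 * d[[value]],
                     ifelse(is.na(d$lrt_p), "",
                            ifelse(d$lrt_p < 0.01, "**",
                                   ifelse(d$lrt_p < 0.05, "*", ""))))
  ggplot2::ggplot(d, ggplot2::aes(.data$scheme, .data$trait_id,
                                  fill = .data[[value]])) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick") +
    ggplot2::labs(x = "weighting scheme", y = "trait",
                  fill = value) +
    ggplot2::theme_minimal()
}
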