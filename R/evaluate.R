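# Incremental-prediction evaluation: nested regression models compared
# by variance explained beyond covariates, likelihood-ratio tests,
# permutation empirical p-values and Benjamini-Hochberg FDR adjustment.

gaussian_loglik <- function(resid, n) {
  s2 <- sum(resid^2) / n   # ML variance
  -n / 2 * (log(2 * pi * s2) + 1)
}

nagelkerke_r2 <- function(fit_full, fit_null, n) {
  llf <- as.numeric(stats::logLik(fit_full))
  lln <- as.numeric(stats::logLik(fit_null))
  cox <- 1 - exp(2 * (lln - llf) / n)
  cox / (1 - exp(2 * lln / n))
}

#' Compare nested prediction models for a phenotype
#'
#' Fits a null and a full regression model, both containing the
#' covariates, with the full model's predictor set strictly containing
#' the null's. For quantitative traits the models are ordinary least
#' squares and variance explained is reported as the model R-squared
#' minus the covariate-only R-squared, i.e. the fraction attributable to
#' the (PRS) terms themselves. For binary traits logistic regression is
#' used with Nagelkerke pseudo-R-squared. The improvement is tested with
#' a likelihood-ratio test `2 * (ll_full - ll_null)` on the parameter
#' difference.
#'
#' @param data Data frame holding the phenotype, all predictor terms and
#'   covariates.
#' @param phenotype Phenotype column name (numeric, or 0/1 for
#'   `family = "binomial"`).
#' @param terms_null Character vector of predictor columns in the null
#'   model (beyond covariates); may be empty.
#' @param terms_full Character vector of predictor columns in the full
#'   model; must strictly contain `terms_null`.
#' @param covariates Covariate column names included in both models.
#' @param family `"gaussian"` (default) or `"binomial"`.
#' @param trait_id Optional label carried into the output.
#' @return A one-row tibble of class `model_comparison` with `trait_id`,
#'   `scheme` (NA here; set by callers), `r2_null`, `r2_full`,
#'   `incremental_r2`, `lrt_stat`, `lrt_df`, `lrt_p`, `n`, and the term
#'   sets as list columns.
#' @examples
#' d <- tibble::tibble(y = rnorm(50), x1 = rnorm(50), x2 = rnorm(50))
#' fit_comparison(d, "y", "x1", c("x1", "x2"))
#' @export
fit_comparison <- function(data, phenotype, terms_null, terms_full,
                           covariates = character(),
                           family = c("gaussian", "binomial"),
                           trait_id = phenotype) {
  family <- match.arg(family)
  terms_null <- unique(terms_null)
  terms_full <- unique(terms_full)
  if (!all(terms_null %in% terms_full)) {
    stop("`terms_full` must contain `terms_null`", call. = FALSE)
  }
  # identical term sets are allowed as a degenerate comparison
  # (lrt_stat 0 on 0 df, p = 1)
  need <- unique(c(phenotype, terms_full, covariates))
  miss <- setdiff(need, names(data))
  if (length(miss) > 0) {
    stop("column(s) not in `data`: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  d <- data[stats::complete.cases(data[, need, drop = FALSE]), need,
            drop = FALSE]
  n <- nrow(d)

  form <- function(terms) {
    rhs <- c("1", covariates, terms)
    stats::as.formula(paste(phenotype, "~", paste(rhs, collapse = " + ")))
  }

  if (family == "gaussian") {
    f_cov <- stats::lm(form(character()), data = d)
    f_null <- stats::lm(form(terms_null), data = d)
    f_full <- stats::lm(form(terms_full), data = d)
    r2_cov <- summary(f_cov)$r.squared
    r2_null <- summary(f_null)$r.squared - r2_cov
    r2_full <- summary(f_full)$r.squared - r2_cov
    ll_null <- gaussian_loglik(stats::resid(f_null), n)
    ll_full <- gaussian_loglik(stats::resid(f_full), n)
    df <- length(stats::coef(f_full)) - length(stats::coef(f_null))
  } else {
    f_cov <- stats::glm(form(character()), data = d, family = stats::binomial())
    f_null <- stats::glm(form(terms_null), data = d, family = stats::binomial())
    f_full <- stats::glm(form(terms_full), data = d, family = stats::binomial())
    if (!f_full$converged ||
        any(abs(stats::predict(f_full, type = "link")) > 20)) {
      warning("possible separation in the logistic fit")
    }
    r2_null <- nagelkerke_r2(f_null, f_cov, n)
    r2_full <- nagelkerke_r2(f_full, f_cov, n)
    ll_null <- as.numeric(stats::logLik(f_null))
    ll_full <- as.numeric(stats::logLik(f_full))
    df <- f_null$df.residual - f_full$df.residual
  }

  lrt <- max(0, 2 * (ll_full - ll_null))
  out <- tibble::tibble(
    trait_id = trait_id, scheme = NA_character_,
    r2_null = r2_null, r2_full = r2_full,
    incremental_r2 = r2_full - r2_null,
    lrt_stat = lrt, lrt_df = df,
    lrt_p = if (df > 0) stats::pchisq(lrt, df, lower.tail = FALSE) else 1,
    empirical_p = NA_real_, fdr_p = NA_real_, n = n,
    terms_null = list(terms_null), terms_full = list(terms_full)
  )
  structure(out, class = c("model_comparison", class(out)), family = family)
}

#' Permutation empirical p-value for a PRS association
#'
#' Measures the association of one PRS term with the phenotype given
#' covariates (the partial t-test of the term in an OLS fit), then
#' permutes the phenotype `n_perm` times against the intact
#' (PRS, covariates) design and reports
#' `(1 + #\{permuted p <= observed p\}) / (n_perm + 1)`.
#'
#' @param data Data frame with the phenotype, PRS term and covariates.
#' @param phenotype Phenotype column name.
#' @param prs_term PRS column name.
#' @param covariates Covariate column names.
#' @param n_perm Number of permutations (>= 100; default 10000).
#' @param seed Integer seed for the permutation stream.
#' @return Tibble with `observed_p`, `empirical_p`, `n_perm` and
#'   `n_smaller` (count of permutations at least as extreme).
#' @examples
#' d <- tibble::tibble(y = rnorm(100), prs = rnorm(100))
#' permutation_empirical_p(d, "y", "prs", n_perm = 200, seed = 1)
#' @export
permutation_empirical_p <- function(data, phenotype, prs_term,
                                    covariates = character(),
                                    n_perm = 10000, seed = 1L) {
  if (n_perm < 100) stop("`n_perm` must be >= 100", call. = FALSE)
  need <- unique(c(phenotype, prs_term, covariates))
  d <- data[stats::complete.cases(data[, need, drop = FALSE]), need,
            drop = FALSE]
  y <- as.numeric(d[[phenotype]])
  if (stats::var(y) == 0) stop("phenotype is constant", call. = FALSE)
  n <- length(y)
  X <- cbind(1, as.matrix(d[, c(covariates, prs_term), drop = FALSE]))
  storage.mode(X) <- "double"
  k <- ncol(X)
  j <- k   # PRS term is the last column
  qx <- qr(X)
  XtXinv_jj <- chol2inv(qr.R(qx))[j, j]

  term_p <- function(Y) {
    # Y: n x r matrix of responses; partial t-test p of column j, vectorised
    B <- qr.coef(qx, Y)
    resid <- Y - X %*% B
    rss <- colSums(resid^2)
    sigma2 <- rss / (n - k)
    tstat <- B[j, ] / sqrt(sigma2 * XtXinv_jj)
    2 * stats::pt(-abs(tstat), df = n - k)
  }

  obs_p <- term_p(matrix(y, ncol = 1))
  set.seed(as.integer(seed))
  n_smaller <- 0L
  chunk <- 2000L
  done <- 0L
  while (done < n_perm) {
    r <- min(chunk, n_perm - done)
    Yp <- matrix(0, n, r)
    for (c in seq_len(r)) Yp[, c] <- y[sample.int(n)]
    n_smaller <- n_smaller + sum(term_p(Yp) <= obs_p)
    done <- done + r
  }
  tibble::tibble(
    observed_p = obs_p,
    empirical_p = (1 + n_smaller) / (n_perm + 1),
    n_perm = as.integer(n_perm),
    n_smaller = as.integer(n_smaller)
  )
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up FDR adjustment of a p-value vector; adjusted values are
#' monotone in the input ranks and bounded by 1.
#'
#' @param pvals Numeric vector of p-values in (0, 1].
#' @return Numeric vector of BH-adjusted p-values, same order as input.
#' @examples
#' fdr_adjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
fdr_adjust <- function(pvals) {
  if (length(pvals) == 0) stop("empty p-value vector", call. = FALSE)
  ok <- !is.na(pvals)
  if (any(pvals[ok] <= 0 | pvals[ok] > 1)) {
    stop("p-values must be in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Summarise model comparisons across traits and weighting schemes
#'
#' Collects [fit_comparison()] results into one table with the
#' percentage predictive improvement
#' `incremental_r2 / r2_null * 100`, and BH-adjusts the LRT p-values
#' within each weighting scheme (the adjustment family).
#'
#' @param comparisons A list of `model_comparison` rows, or a tibble
#'   binding them, with `scheme` filled in by the caller.
#' @return A tibble of class `improvement_report`: `trait_id`, `scheme`,
#'   `r2_null`, `r2_full`, `incremental_r2`, `improvement_pct`, `lrt_p`,
#'   `empirical_p`, `fdr_p`, `n`.
#' @export
improvement_report <- function(comparisons) {
  tab <- if (is.data.frame(comparisons)) {
    tibble::as_tibble(comparisons)
  } else {
    dplyr::bind_rows(comparisons)
  }
  tab <- dplyr::mutate(
    tab,
    improvement_pct = dplyr::if_else(.data$r2_null > 0,
                                     .data$incremental_r2 / .data$r2_null * 100,
                                     NA_real_)
  )
  tab <- dplyr::mutate(
    tab,
    fdr_p = stats::ave(.data$lrt_p,
                       dplyr::coalesce(.data$scheme, "all"),
                       FUN = function(p) stats::p.adjust(p, method = "BH"))
  )
  cols <- c("trait_id", "scheme", "r2_null", "r2_full", "incremental_r2",
            "improvement_pct", "lrt_p", "empirical_p", "fdr_p", "n")
  out <- tab[, intersect(cols, names(tab)), drop = FALSE]
  structure(out, class = c("improvement_report", class(out)))
}
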