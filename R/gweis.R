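# Per-SNP association engines: the additive scan (ordinary least squares
# with classical standard errors) and the interaction scan, which fits
# Y ~ 1 + G + E + GxE + covariates per SNP and reports Huber-White
# (sandwich) robust standard errors, the 1-df Wald test of the GxE term
# and the 2-df joint Wald test of (G, GxE). The robust covariance guards
# the interaction test against residual variance that changes with the
# exposure (heteroscedasticity), which otherwise inflates type-I error.

# Align a phenotype/covariate table to the panel's samples by iid and
# extract the model ingredients. Listwise deletion over the requested
# columns happens here; per-SNP deletion (missing dosages) in the loop.
align_model_data <- function(panel, data, phenotype, exposure = NULL,
                             covariates = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (!"iid" %in% names(data)) stop("`data` must have an `iid` column", call. = FALSE)
  need <- c(phenotype, exposure, covariates)
  miss_col <- setdiff(need, names(data))
  if (length(miss_col) > 0) {
    stop("column(s) not in `data`: ", paste(miss_col, collapse = ", "),
         call. = FALSE)
  }
  idx <- match(panel$samples$iid, data$iid)
  keep <- which(!is.na(idx))
  d <- data[idx[keep], , drop = FALSE]
  complete <- stats::complete.cases(d[, need, drop = FALSE])
  keep <- keep[complete]
  d <- d[complete, , drop = FALSE]
  if (length(keep) < 2) stop("fewer than 2 usable samples after joining", call. = FALSE)
  list(
    rows = keep,
    y = as.numeric(d[[phenotype]]),
    E = if (!is.null(exposure)) as.numeric(d[[exposure]]) else NULL,
    C = if (length(covariates) > 0) {
      as.matrix(dplyr::mutate(d[, covariates, drop = FALSE],
                              dplyr::across(dplyr::everything(), as.numeric)))
    } else NULL
  )
}

log10p_from_chisq <- function(stat, df) {
  stats::pchisq(stat, df, lower.tail = FALSE, log.p = TRUE) / log(10)
}

#' Genome-wide additive association scan
#'
#' Per SNP, ordinary least squares of the phenotype on the effect-allele
#' dosage plus covariates, with classical standard errors and t-based
#' p-values. Samples with a missing dosage are dropped per SNP
#' (listwise); monomorphic SNPs are flagged and get no p-value.
#'
#' @param panel A `genotype_panel`.
#' @param data Data frame with an `iid` column plus the phenotype and
#'   covariate columns, joined to the panel samples by `iid`.
#' @param phenotype Name of the phenotype column.
#' @param covariates Character vector of covariate column names (may be
#'   empty).
#' @return A tibble of class `gwas_result`: one row per SNP with `snp`,
#'   `chr`, `bp`, `a1`, `a2`, `n_used`, `beta`, `se`, `p`, `log10_p`
#'   and `status` (`"ok"` or `"monomorphic"`). `a1` is the effect allele.
#' @examples
#' study <- simulate_study(sim_config(n_samples = 300, n_snps = 30, seed = 5))
#' res <- run_gwas(study$panel, study$data, "phenotype", c("age", "sex"))
#' head(res)
#' @export
run_gwas <- function(panel, data, phenotype, covariates = character()) {
  md <- align_model_data(panel, data, phenotype, covariates = covariates)
  dos <- panel$dosages[md$rows, , drop = FALSE]
  m <- ncol(dos)
  y <- md$y
  Fixed <- cbind(`(Intercept)` = rep(1, length(y)), md$C)

  beta <- se <- p <- rep(NA_real_, m)
  n_used <- integer(m)
  status <- rep("ok", m)

  for (j in seq_len(m)) {
    g <- as.numeric(dos[, j])
    ok <- !is.na(g)
    n_used[j] <- sum(ok)
    gj <- g[ok]
    if (stats::var(gj) == 0) { status[j] <- "monomorphic"; next }
    X <- cbind(Fixed[ok, , drop = FALSE], g = gj)
    yk <- y[ok]
    k <- ncol(X)
    XtX <- crossprod(X)
    R <- tryCatch(chol(XtX), error = function(e) NULL)
    if (is.null(R)) { status[j] <- "singular"; next }
    XtXinv <- chol2inv(R)
    b <- drop(XtXinv %*% crossprod(X, yk))
    e <- yk - drop(X %*% b)
    sigma2 <- sum(e^2) / (n_used[j] - k)
    beta[j] <- b[k]
    se[j] <- sqrt(sigma2 * XtXinv[k, k])
    p[j] <- 2 * stats::pt(-abs(beta[j] / se[j]), df = n_used[j] - k)
  }

  out <- dplyr::bind_cols(
    panel$snps[, c("snp", "chr", "bp", "a1", "a2")],
    tibble::tibble(n_used = n_used, beta = beta, se = se, p = p,
                   log10_p = log10(p), status = status)
  )
  structure(out, class = c("gwas_result", class(out)),
            n = length(y), phenotype = phenotype)
}

#' Genome-wide by environment interaction scan (GWEIS)
#'
#' Per SNP, fits the full model
#' `Y ~ 1 + G + E + GxE + covariates` by least squares and computes a
#' Huber-White sandwich covariance
#' `V = (X'X)^-1 X' diag(e^2) X (X'X)^-1` (HC0; HC1 multiplies by
#' `n/(n - k)`). Reports robust standard errors for all three genetic
#' model terms, the 1-df Wald p-value of the interaction coefficient,
#' and the 2-df joint Wald statistic `b' S^-1 b` for
#' `b = (beta_G, beta_GxE)` with `S` their 2x2 robust covariance block,
#' referred to a chi-square distribution with 2 df — the test of a SNP's
#' combined main and interaction contribution against both being zero.
#'
#' @inheritParams run_gwas
#' @param exposure Name of the exposure column (a count such as a
#'   stressful-life-events tally; entered on its raw scale).
#' @param robust `"HC0"` (default) or `"HC1"`.
#' @param classical Also report classical (model-based) standard errors
#'   and p-values for the interaction term, for contrast with the robust
#'   ones (default FALSE).
#' @return A tibble of class `gweis_result`: per SNP `snp`, `chr`, `bp`,
#'   `a1`, `a2`, `n_used`, `beta_g`, `se_g`, `beta_e`, `se_e`,
#'   `beta_gxe`, `se_gxe`, `p_gxe`, `log10_p_gxe`, `chi2_joint`,
#'   `p_joint`, `log10_p_joint`, `status`, plus `se_gxe_classical` /
#'   `p_gxe_classical` when `classical = TRUE`. Robust variant and
#'   sample size are attached as attributes.
#' @examples
#' study <- simulate_study(sim_config(n_samples = 300, n_snps = 30, seed = 6))
#' res <- run_gweis(study$panel, study$data, "phenotype", "exposure",
#'                  c("age", "sex"))
#' head(res)
#' @export
run_gweis <- function(panel, data, phenotype, exposure,
                      covariates = character(),
                      robust = c("HC0", "HC1"), classical = FALSE) {
  robust <- match.arg(robust)
  md <- align_model_data(panel, data, phenotype, exposure, covariates)
  if (stats::var(md$E) == 0) {
    stop("exposure is constant across samples: G and GxE are collinear",
         call. = FALSE)
  }
  dos <- panel$dosages[md$rows, , drop = FALSE]
  m <- ncol(dos)
  y <- md$y
  E <- md$E
  Fixed <- cbind(`(Intercept)` = 1, E = E, md$C)

  cols <- c("beta_g", "se_g", "beta_e", "se_e", "beta_gxe", "se_gxe",
            "p_gxe", "chi2_joint", "p_joint", "se_gxe_classical",
            "p_gxe_classical")
  res <- matrix(NA_real_, m, length(cols), dimnames = list(NULL, cols))
  log10_gxe <- log10_joint <- rep(NA_real_, m)
  n_used <- integer(m)
  status <- rep("ok", m)

  for (j in seq_len(m)) {
    g <- as.numeric(dos[, j])
    ok <- !is.na(g)
    n_used[j] <- sum(ok)
    gj <- g[ok]
    if (stats::var(gj) == 0) { status[j] <- "monomorphic"; next }
    X <- cbind(Fixed[ok, , drop = FALSE], g = gj, gxe = gj * E[ok])
    k <- ncol(X)
    if (n_used[j] <= k + 5) { status[j] <- "insufficient_n"; next }
    ig <- k - 1L
    ii <- k
    XtX <- crossprod(X)
    R <- tryCatch(chol(XtX), error = function(e) NULL)
    if (is.null(R)) { status[j] <- "singular"; next }
    XtXinv <- chol2inv(R)
    yk <- y[ok]
    b <- drop(XtXinv %*% crossprod(X, yk))
    e <- yk - drop(X %*% b)

    meat <- crossprod(X * e)
    V <- XtXinv %*% meat %*% XtXinv
    if (robust == "HC1") V <- V * n_used[j] / (n_used[j] - k)

    res[j, "beta_g"] <- b[ig]
    res[j, "beta_e"] <- b[2L]
    res[j, "beta_gxe"] <- b[ii]
    res[j, "se_g"] <- sqrt(V[ig, ig])
    res[j, "se_e"] <- sqrt(V[2L, 2L])
    res[j, "se_gxe"] <- sqrt(V[ii, ii])
    z2 <- (b[ii] / res[j, "se_gxe"])^2
    res[j, "p_gxe"] <- stats::pchisq(z2, 1, lower.tail = FALSE)
    log10_gxe[j] <- log10p_from_chisq(z2, 1)

    S <- V[c(ig, ii), c(ig, ii)]
    detS <- S[1, 1] * S[2, 2] - S[1, 2]^2
    if (!is.finite(detS) || detS <= 0) {
      status[j] <- "singular_joint"
    } else {
      bb <- b[c(ig, ii)]
      chi2 <- (bb[1]^2 * S[2, 2] - 2 * bb[1] * bb[2] * S[1, 2] +
                 bb[2]^2 * S[1, 1]) / detS
      res[j, "chi2_joint"] <- chi2
      res[j, "p_joint"] <- stats::pchisq(chi2, 2, lower.tail = FALSE)
      log10_joint[j] <- log10p_from_chisq(chi2, 2)
    }

    if (classical) {
      sigma2 <- sum(e^2) / (n_used[j] - k)
      sec <- sqrt(sigma2 * XtXinv[ii, ii])
      res[j, "se_gxe_classical"] <- sec
      res[j, "p_gxe_classical"] <-
        stats::pchisq((b[ii] / sec)^2, 1, lower.tail = FALSE)
    }
  }

  keep_cols <- if (classical) cols else setdiff(cols, c("se_gxe_classical",
                                                        "p_gxe_classical"))
  out <- dplyr::bind_cols(
    panel$snps[, c("snp", "chr", "bp", "a1", "a2")],
    tibble::tibble(n_used = n_used),
    tibble::as_tibble(res[, keep_cols, drop = FALSE]),
    tibble::tibble(log10_p_gxe = log10_gxe, log10_p_joint = log10_joint,
                   status = status)
  )
  structure(out, class = c("gweis_result", class(out)),
            n = length(y), robust = robust, phenotype = phenotype,
            exposure = exposure)
}

#' Genomic-control inflation of a p-value vector
#'
#' `lambda_gc` is the median of the implied 1-df chi-square statistics
#' divided by the null median 0.4549364 (qchisq(0.5, 1)). `lambda_1000`
#' standardises it to an effective sample size of 1000 under the
#' quantitative-trait convention
#' `1 + (lambda_gc - 1) * 1000 / n`.
#'
#' @param pvals Numeric vector of p-values in (0, 1].
#' @param n Sample size behind the scan.
#' @return Tibble with `lambda_gc`, `lambda_1000`, `n_effective` and
#'   `n_tests`.
#' @examples
#' genomic_inflation(runif(1000), n = 5000)
#' @export
genomic_inflation <- function(pvals, n) {
  pvals <- pvals[!is.na(pvals)]
  if (length(pvals) == 0) stop("no non-missing p-values", call. = FALSE)
  if (any(pvals <= 0 | pvals > 1)) stop("p-values must be in (0, 1]", call. = FALSE)
  chisq <- stats::qchisq(pvals, df = 1, lower.tail = FALSE)
  lambda <- stats::median(chisq) / stats::qchisq(0.5, df = 1)
  tibble::tibble(
    lambda_gc = lambda,
    lambda_1000 = 1 + (lambda - 1) * 1000 / n,
    n_effective = as.integer(n),
    n_tests = length(pvals)
  )
}

#' Bonferroni genome-wide significance threshold
#'
#' `alpha / (n_snps * n_tests_per_snp)`, the threshold used when a scan
#' is repeated over several exposure measures or test types.
#'
#' @param n_snps Number of SNPs tested.
#' @param n_tests_per_snp Number of scans/measures per SNP (default 1).
#' @param alpha Family-wise error level (default 0.05).
#' @return The per-test significance threshold.
#' @examples
#' bonferroni_threshold(560351, 3)    # ~2.97e-8
#' bonferroni_threshold(1009208, 2)   # ~2.47e-8
#' @export
bonferroni_threshold <- function(n_snps, n_tests_per_snp = 1, alpha = 0.05) {
  if (n_snps < 1 || n_tests_per_snp < 1) {
    stop("counts must be >= 1", call. = FALSE)
  }
  alpha / (n_snps * n_tests_per_snp)
}
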