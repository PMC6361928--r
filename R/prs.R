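# Polygenic risk scoring from association summary statistics:
# greedy LD clumping, weight tables under three weighting schemes
# (additive main effect, GxE interaction effect, or their combined joint
# effect), PLINK --score style target scoring with mean imputation of
# missing dosages, and a p-value threshold grid search.

#' Greedy LD clumping of summary statistics
#'
#' Repeatedly takes the smallest-p unclaimed SNP with `p <= p1` as an
#' index SNP and removes all unclaimed SNPs on the same chromosome
#' within `window_kb` of it whose dosage correlation with the index
#' satisfies `r^2 >= r2_threshold` in the reference panel. Ties in p are
#' broken by (chromosome, position), making the result independent of
#' input row order. Summary SNPs absent from the reference are dropped
#' with a warning.
#'
#' @param sumstats Data frame with columns `snp`, `chr`, `bp` and a
#'   p-value column named by `p_col`.
#' @param reference A `genotype_panel` providing the LD reference.
#' @param r2_threshold Squared-correlation threshold (default 0.1).
#' @param window_kb Window half-width in kilobases (default 250).
#' @param p1 Index-SNP p-value ceiling (default 1).
#' @param p_col Name of the p-value column (default `"p"`).
#' @return The retained (index SNP) rows of `sumstats`, ordered by
#'   selection.
#' @examples
#' study <- simulate_study(sim_config(n_samples = 200, n_snps = 40,
#'                                    ld_rho = 0.8, seed = 8))
#' gw <- run_gwas(study$panel, study$data, "phenotype")
#' nrow(clump(gw, study$panel))
#' @export
clump <- function(sumstats, reference, r2_threshold = 0.1, window_kb = 250,
                  p1 = 1, p_col = "p") {
  stopifnot(inherits(reference, "genotype_panel"))
  need <- c("snp", "chr", "bp", p_col)
  miss <- setdiff(need, names(sumstats))
  if (length(miss) > 0) {
    stop("`sumstats` lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  ss <- tibble::as_tibble(sumstats)
  in_ref <- ss$snp %in% reference$snps$snp
  if (!any(in_ref)) stop("no sumstats SNPs found in the reference panel", call. = FALSE)
  if (any(!in_ref)) {
    warning(sum(!in_ref), " SNP(s) absent from the reference were dropped")
    ss <- ss[in_ref, , drop = FALSE]
  }
  p <- ss[[p_col]]
  eligible <- !is.na(p) & p <= p1
  ss <- ss[eligible, , drop = FALSE]
  p <- p[eligible]
  if (nrow(ss) == 0) stop("no SNP passes the `p1` ceiling", call. = FALSE)

  ord <- order(p, ss$chr, ss$bp)
  dos_idx <- match(ss$snp, reference$snps$snp)
  claimed <- rep(FALSE, nrow(ss))
  keep <- integer(0)
  window_bp <- window_kb * 1000

  for (i in ord) {
    if (claimed[i]) next
    claimed[i] <- TRUE
    keep <- c(keep, i)
    cand <- which(!claimed & ss$chr == ss$chr[i] &
                    abs(ss$bp - ss$bp[i]) <= window_bp)
    if (length(cand) == 0) next
    gi <- reference$dosages[, dos_idx[i]]
    r <- suppressWarnings(
      stats::cor(gi, reference$dosages[, dos_idx[cand], drop = FALSE],
                 use = "pairwise.complete.obs"))
    r2 <- as.numeric(r)^2
    r2[is.na(r2)] <- 0
    claimed[cand[r2 >= r2_threshold]] <- TRUE
  }
  ss[keep, , drop = FALSE]
}

#' Build a PRS weight table from scan results
#'
#' Maps association results onto per-SNP weights under a named scheme:
#' `"additive"` uses the additive effect and its p-value (a
#' [run_gwas()] table); `"gxe"` uses the interaction coefficient and its
#' robust 1-df p; `"joint"` uses the combined per-allele effect
#' `beta_g + beta_gxe` ranked by the 2-df joint p (the natural combined
#' effect of one effect allele at one exposure unit).
#'
#' @param records A `gwas_result` (for `"additive"`) or `gweis_result`
#'   (for `"gxe"`/`"joint"`) tibble.
#' @param scheme `"additive"`, `"gxe"` or `"joint"`.
#' @return A tibble of class `weight_table` with `snp`, `chr`, `bp`,
#'   `effect_allele`, `weight`, `select_p` and `scheme`; SNPs without a
#'   usable estimate are dropped.
#' @examples
#' study <- simulate_study(sim_config(n_samples = 300, n_snps = 30, seed = 6))
#' gx <- run_gweis(study$panel, study$data, "phenotype", "exposure")
#' build_weights(gx, "gxe")
#' @export
build_weights <- function(records, scheme = c("additive", "gxe", "joint")) {
  scheme <- match.arg(scheme)
  need <- switch(scheme,
                 additive = c("beta", "p"),
                 gxe = c("beta_gxe", "p_gxe"),
                 joint = c("beta_g", "beta_gxe", "p_joint"))
  miss <- setdiff(need, names(records))
  if (length(miss) > 0) {
    stop("records lack column(s) required for scheme '", scheme, "': ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  w <- switch(scheme,
              additive = records$beta,
              gxe = records$beta_gxe,
              joint = records$beta_g + records$beta_gxe)
  sp <- records[[need[length(need)]]]
  out <- tibble::tibble(
    snp = records$snp, chr = records$chr, bp = records$bp,
    effect_allele = records$a1, weight = w, select_p = sp,
    scheme = scheme
  )
  out <- out[!is.na(out$weight) & !is.na(out$select_p), , drop = FALSE]
  structure(out, class = c("weight_table", class(out)))
}

is_strand_ambiguous <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Score target genotypes with a PRS weight table
#'
#' Computes `score_i = sum_j weight_j * dosage_ij` over the SNPs whose
#' `select_p` passes the threshold, with the dosage counted on the
#' weight's effect allele (flipped as `2 - dosage` when the effect
#' allele is the target panel's other allele). Strand-ambiguous SNPs
#' (A/T, C/G) and allele mismatches are dropped with a warning. Missing
#' dosages are imputed as `2 x` the effect-allele frequency observed in
#' the target panel. Scores are the PLINK `--score ... sum` convention
#' (sums, not averages); a standardised version is also returned.
#'
#' @param target A `genotype_panel` to score.
#' @param weights A `weight_table` (or any data frame with `snp`,
#'   `effect_allele`, `weight`, `select_p`).
#' @param p_threshold Keep SNPs with `select_p <= p_threshold`
#'   (default 1).
#' @return A tibble of class `prs_profile` with `fid`, `iid`, `score`,
#'   `score_std` and attributes `n_snps_used` and `p_threshold`.
#' @examples
#' study <- simulate_study(sim_config(n_samples = 300, n_snps = 30, seed = 6))
#' gw <- run_gwas(study$panel, study$data, "phenotype")
#' prs_score(study$panel, build_weights(gw, "additive"))
#' @export
prs_score <- function(target, weights, p_threshold = 1) {
  stopifnot(inherits(target, "genotype_panel"))
  need <- c("snp", "effect_allele", "weight", "select_p")
  miss <- setdiff(need, names(weights))
  if (length(miss) > 0) {
    stop("`weights` lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  w <- weights[!is.na(weights$select_p) & weights$select_p <= p_threshold, ,
               drop = FALSE]
  if (nrow(w) == 0) {
    stop("no SNP passes p_threshold = ", p_threshold, call. = FALSE)
  }
  idx <- match(w$snp, target$snps$snp)
  found <- !is.na(idx)
  if (!any(found)) stop("no weight SNPs found in the target panel", call. = FALSE)
  if (any(!found)) {
    warning(sum(!found), " weight SNP(s) absent from the target were dropped")
    w <- w[found, , drop = FALSE]
    idx <- idx[found]
  }
  a1 <- target$snps$a1[idx]
  a2 <- target$snps$a2[idx]
  ambiguous <- is_strand_ambiguous(a1, a2)
  same <- w$effect_allele == a1
  flip <- w$effect_allele == a2
  usable <- (same | flip) & !ambiguous
  if (!any(usable)) stop("no allele-matched SNPs to score", call. = FALSE)
  if (any(!usable)) {
    warning(sum(!usable),
            " SNP(s) dropped (strand-ambiguous or allele mismatch)")
    w <- w[usable, , drop = FALSE]
    idx <- idx[usable]
    same <- same[usable]
  }

  dos <- target$dosages[, idx, drop = FALSE]
  storage.mode(dos) <- "double"
  # orient onto the effect allele
  flip_cols <- which(!same)
  if (length(flip_cols) > 0) {
    dos[, flip_cols] <- 2 - dos[, flip_cols]
  }
  if (anyNA(dos)) {
    eaf <- colMeans(dos, na.rm = TRUE) / 2
    for (jj in which(colSums(is.na(dos)) > 0)) {
      dos[is.na(dos[, jj]), jj] <- 2 * eaf[jj]
    }
  }
  score <- unname(drop(dos %*% w$weight))
  sdv <- stats::sd(score)
  out <- tibble::tibble(
    fid = target$samples$fid, iid = target$samples$iid,
    score = score,
    score_std = if (sdv > 0) (score - mean(score)) / sdv else score * 0
  )
  structure(out, class = c("prs_profile", class(out)),
            n_snps_used = nrow(w), p_threshold = p_threshold,
            scheme = if ("scheme" %in% names(w)) w$scheme[1] else NA_character_)
}

#' P-value threshold grid search for a PRS
#'
#' Scores the target at each threshold of a fixed grid and reports the
#' incremental variance in a phenotype explained beyond covariates, the
#' PRSice-style "best-fit" search.
#'
#' @param target A `genotype_panel`.
#' @param weights A `weight_table`.
#' @param data Data frame with `iid`, the phenotype and covariates.
#' @param phenotype Phenotype column name.
#' @param covariates Covariate column names (may be empty).
#' @param grid Numeric vector of thresholds (default
#'   `c(5e-8, 1e-5, 1e-3, 0.01, 0.05, 0.1, 0.5, 1)`).
#' @return Tibble with one row per usable threshold: `p_threshold`,
#'   `n_snps_used`, `incremental_r2`, `p`, and `best` flagging the
#'   largest incremental r-squared.
#' @export
prs_threshold_grid <- function(target, weights, data, phenotype,
                               covariates = character(),
                               grid = c(5e-8, 1e-5, 1e-3, 0.01, 0.05,
                                        0.1, 0.5, 1)) {
  rows <- purrr::map(grid, function(th) {
    prof <- tryCatch(prs_score(target, weights, th), error = function(e) NULL)
    if (is.null(prof)) return(NULL)
    d <- dplyr::inner_join(prof, data, by = "iid")
    cmp <- fit_comparison(d, phenotype, terms_null = character(),
                          terms_full = "score_std", covariates = covariates)
    tibble::tibble(p_threshold = th,
                   n_snps_used = attr(prof, "n_snps_used"),
                   incremental_r2 = cmp$incremental_r2,
                   p = cmp$lrt_p)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) stop("no threshold produced a usable score", call. = FALSE)
  out$best <- seq_len(nrow(out)) == which.max(out$incremental_r2)
  out
}
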