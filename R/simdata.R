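#' Simulation configuration for a synthetic GWEIS study
#'
#' Bundles every knob of the synthetic-data generator: cohort and panel
#' size, allele-frequency range, LD structure, the genetic architecture of
#' the phenotype (additive and SNP-by-exposure interaction variance
#' fractions), the exposure model (a count-valued measure such as a
#' stressful-life-events tally, optionally partly heritable so that
#' gene-environment correlation can be switched on), covariate effects,
#' and exposure-dependent residual heteroscedasticity.
#'
#' Variance fractions `var_additive` and `var_gxe` are expressed relative
#' to a unit-variance genetic-plus-residual core of the phenotype: the
#' realised additive and interaction components are rescaled to have
#' exactly those sample variances and the residual standard deviation is
#' set to `sqrt(1 - var_additive - var_gxe)` before the exposure main
#' effect, covariate effects and any heteroscedastic inflation are added
#' on top.
#'
#' @param n_samples Number of individuals.
#' @param n_snps Number of biallelic SNPs.
#' @param maf_range Length-2 numeric in (0, 0.5]; per-SNP effect-allele
#'   frequencies are drawn uniformly from this interval.
#' @param n_causal_additive Number of SNPs with additive main effects.
#' @param n_causal_gxe Number of SNPs with SNP-by-exposure interaction
#'   effects (disjoint from the additive causal set).
#' @param var_additive Fraction of the phenotypic core variance explained
#'   by additive effects.
#' @param var_gxe Fraction of the phenotypic core variance explained by
#'   interaction effects. `var_additive + var_gxe` must be < 1.
#' @param beta_E Exposure main effect, in phenotype SD per exposure unit.
#' @param exposure_h2 Fraction in [0, 1) of exposure liability variance
#'   that is genetic; 0 makes the exposure independent of genotype.
#' @param exposure_mean Expected exposure count (Poisson mean of the
#'   quantile-mapped counts).
#' @param n_exposure_snps Number of SNPs feeding the exposure liability
#'   when `exposure_h2 > 0`.
#' @param hetero_factor Multiplier >= 0: residual SD is
#'   `sigma0 * (1 + hetero_factor * E)`, so 0 gives homoscedastic noise.
#' @param beta_covar Effect per standardised covariate column on the
#'   phenotype.
#' @param ld_block_size SNPs per LD block; latent haplotype correlation
#'   is restarted at block (and chromosome) boundaries.
#' @param ld_rho Adjacent-SNP latent haplotype correlation in [0, 1).
#' @param n_chr Number of chromosomes the panel is spread across.
#' @param bp_spacing Base pairs between adjacent SNPs (positions are
#'   1-based and restart on each chromosome).
#' @param seed Integer seed; identical configs give bit-identical output.
#'
#' @return An object of class `sim_config` (a named list).
#' @examples
#' cfg <- sim_config(n_samples = 200, n_snps = 50, seed = 1)
#' panel <- simulate_genotypes(cfg)
#' @export
sim_config <- function(n_samples = 2000,
                       n_snps = 5000,
                       maf_range = c(0.05, 0.5),
                       n_causal_additive = 20,
                       n_causal_gxe = 20,
                       var_additive = 0.1,
                       var_gxe = 0.02,
                       beta_E = 0.2,
                       exposure_h2 = 0,
                       exposure_mean = 2,
                       n_exposure_snps = 200,
                       hetero_factor = 0,
                       beta_covar = 0.1,
                       ld_block_size = 10,
                       ld_rho = 0,
                       n_chr = 5,
                       bp_spacing = 5000,
                       seed = 1L) {
  cfg <- list(
    n_samples = as.integer(n_samples), n_snps = as.integer(n_snps),
    maf_range = as.numeric(maf_range),
    n_causal_additive = as.integer(n_causal_additive),
    n_causal_gxe = as.integer(n_causal_gxe),
    var_additive = var_additive, var_gxe = var_gxe, beta_E = beta_E,
    exposure_h2 = exposure_h2, exposure_mean = exposure_mean,
    n_exposure_snps = as.integer(n_exposure_snps),
    hetero_factor = hetero_factor, beta_covar = beta_covar,
    ld_block_size = as.integer(ld_block_size), ld_rho = ld_rho,
    n_chr = as.integer(n_chr), bp_spacing = as.integer(bp_spacing),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (length(cfg$maf_range) != 2 || any(!is.finite(cfg$maf_range)) ||
      cfg$maf_range[1] <= 0 || cfg$maf_range[2] > 0.5 ||
      cfg$maf_range[1] > cfg$maf_range[2]) {
    stop("`maf_range` must lie within (0, 0.5] with min <= max", call. = FALSE)
  }
  if (cfg$n_samples < 2) stop("`n_samples` must be >= 2", call. = FALSE)
  if (cfg$n_snps < 1) stop("`n_snps` must be >= 1", call. = FALSE)
  if (cfg$var_additive < 0 || cfg$var_gxe < 0 ||
      cfg$var_additive + cfg$var_gxe >= 1) {
    stop("`var_additive + var_gxe` must be in [0, 1)", call. = FALSE)
  }
  if (cfg$n_causal_additive + cfg$n_causal_gxe > cfg$n_snps) {
    stop("causal SNP counts exceed `n_snps`", call. = FALSE)
  }
  if (cfg$exposure_h2 < 0 || cfg$exposure_h2 >= 1) {
    stop("`exposure_h2` must be in [0, 1)", call. = FALSE)
  }
  if (cfg$hetero_factor < 0) stop("`hetero_factor` must be >= 0", call. = FALSE)
  if (cfg$ld_rho < 0 || cfg$ld_rho >= 1) {
    stop("`ld_rho` must be in [0, 1)", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", x$n_samples, " samples x ", x$n_snps, " SNPs\n", sep = "")
  cat("  architecture: var_additive=", x$var_additive, " (", x$n_causal_additive,
      " SNPs), var_gxe=", x$var_gxe, " (", x$n_causal_gxe, " SNPs)\n", sep = "")
  cat("  exposure: mean=", x$exposure_mean, ", h2=", x$exposure_h2,
      ", beta_E=", x$beta_E, ", hetero_factor=", x$hetero_factor, "\n", sep = "")
  cat("  LD: block=", x$ld_block_size, ", rho=", x$ld_rho,
      "; seed=", x$seed, "\n", sep = "")
  invisible(x)
}

# Non-strand-ambiguous allele pairs (no A/T, no C/G): orientation of the
# effect allele is then always resolvable when matching external weights.
.allele_pairs <- matrix(c("A", "G", "A", "C", "T", "G", "T", "C",
                          "G", "A", "C", "A", "G", "T", "C", "T"),
                        ncol = 2, byrow = TRUE)

#' Simulate a biallelic genotype panel
#'
#' Draws unphased genotypes in Hardy-Weinberg proportions. Each SNP's
#' effect-allele frequency is uniform on `maf_range`. Linkage
#' disequilibrium is generated haplotype-wise: within each block of
#' `ld_block_size` SNPs two latent AR(1) Gaussian vectors (adjacent
#' correlation `ld_rho`) are thresholded at the allele-frequency quantile,
#' and the two haplotypes are summed to a dosage in \{0, 1, 2\}. Blocks
#' (and chromosomes) restart the latent process, so LD never crosses a
#' chromosome boundary. No missing genotypes are generated.
#'
#' @param config A [sim_config()].
#' @return A `genotype_panel`: a list with `dosages` (integer
#'   `n_samples x n_snps` matrix, effect-allele counts), `snps` (tibble
#'   with `snp`, `chr`, `bp`, `a1`, `a2`, `freq`; `a1` is the effect
#'   allele and `freq` its generating frequency) and `samples` (tibble
#'   with `fid`, `iid`).
#' @examples
#' panel <- simulate_genotypes(sim_config(n_samples = 100, n_snps = 20, seed = 7))
#' dim(panel$dosages)
#' @export
simulate_genotypes <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_samples
  m <- config$n_snps

  freq <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  pair_idx <- sample.int(nrow(.allele_pairs), m, replace = TRUE)

  n_chr <- max(1L, min(config$n_chr, m))
  snps_per_chr <- ceiling(m / n_chr)
  chr <- as.character(((seq_len(m) - 1L) %/% snps_per_chr) + 1L)
  bp <- (((seq_len(m) - 1L) %% snps_per_chr) + 1L) * config$bp_spacing

  # block id; restart at chromosome starts so LD respects chromosomes
  within_chr <- ((seq_len(m) - 1L) %% snps_per_chr)
  block <- paste0(chr, "_", within_chr %/% max(1L, config$ld_block_size))

  thresh <- stats::qnorm(freq)
  dos <- matrix(0L, n, m)
  rho <- config$ld_rho
  for (b in unique(block)) {
    idx <- which(block == b)
    k <- length(idx)
    h1 <- matrix(stats::rnorm(n * k), n, k)
    h2 <- matrix(stats::rnorm(n * k), n, k)
    if (rho > 0 && k > 1) {
      w <- sqrt(1 - rho^2)
      for (j in 2:k) {
        h1[, j] <- rho * h1[, j - 1] + w * h1[, j]
        h2[, j] <- rho * h2[, j - 1] + w * h2[, j]
      }
    }
    th <- rep(thresh[idx], each = n)
    dos[, idx] <- (h1 < th) + (h2 < th)
  }
  storage.mode(dos) <- "integer"

  snp_id <- sprintf("snp_%s_%d", chr, bp)
  colnames(dos) <- snp_id
  samples <- tibble::tibble(fid = sprintf("F%04d", seq_len(n)),
                            iid = sprintf("I%04d", seq_len(n)))
  rownames(dos) <- samples$iid
  snps <- tibble::tibble(
    snp = snp_id, chr = chr, bp = as.integer(bp),
    a1 = .allele_pairs[pair_idx, 1], a2 = .allele_pairs[pair_idx, 2],
    freq = freq
  )
  new_genotype_panel(dos, snps, samples)
}

new_genotype_panel <- function(dosages, snps, samples) {
  stopifnot(nrow(snps) == ncol(dosages), nrow(samples) == nrow(dosages))
  dimnames(dosages) <- list(samples$iid, snps$snp)
  structure(list(dosages = dosages, snps = snps, samples = samples),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("<genotype_panel> ", nrow(x$dosages), " samples x ", ncol(x$dosages),
      " SNPs, ", length(unique(x$snps$chr)), " chromosome(s), ",
      sum(is.na(x$dosages)), " missing dosages\n", sep = "")
  invisible(x)
}

#' Subset a genotype panel
#'
#' @param x A `genotype_panel`.
#' @param samples Optional integer/logical index or character vector of
#'   `iid`s to keep.
#' @param snps Optional integer/logical index or character vector of SNP
#'   ids to keep.
#' @param ... Unused.
#' @return A `genotype_panel` restricted to the requested rows/columns.
#' @export
subset_panel <- function(x, samples = NULL, snps = NULL, ...) {
  stopifnot(inherits(x, "genotype_panel"))
  si <- seq_len(nrow(x$dosages))
  vi <- seq_len(ncol(x$dosages))
  if (!is.null(samples)) {
    si <- if (is.character(samples)) match(samples, x$samples$iid) else si[samples]
    if (anyNA(si)) stop("unknown sample id(s)", call. = FALSE)
  }
  if (!is.null(snps)) {
    vi <- if (is.character(snps)) match(snps, x$snps$snp) else vi[snps]
    if (anyNA(vi)) stop("unknown SNP id(s)", call. = FALSE)
  }
  new_genotype_panel(x$dosages[si, vi, drop = FALSE],
                     x$snps[vi, , drop = FALSE],
                     x$samples[si, , drop = FALSE])
}

# standardise dosage columns to mean 0, variance 1 (monomorphic -> 0)
standardise_dosages <- function(dos) {
  mu <- colMeans(dos)
  sdv <- apply(dos, 2, stats::sd)
  sdv[sdv == 0] <- Inf
  sweep(sweep(dos, 2, mu, "-"), 2, sdv, "/")
}

#' Simulate a count-valued exposure, optionally heritable
#'
#' Builds a latent Gaussian liability as `sqrt(exposure_h2)` times a
#' standardised polygenic score over a random SNP subset plus
#' `sqrt(1 - exposure_h2)` times independent noise, then maps the
#' liability through its normal quantiles onto a Poisson(`exposure_mean`)
#' count scale. With `exposure_h2 = 0` the exposure is independent of
#' genotype; with `exposure_h2 > 0` the generator induces
#' gene-environment correlation of controlled magnitude.
#'
#' @param panel A `genotype_panel`.
#' @param config A [sim_config()]; uses `exposure_h2`, `exposure_mean`,
#'   `n_exposure_snps` and draws from stream `seed + 1`.
#' @return Integer vector of counts (length `n_samples`) with attributes
#'   `exposure_snps` (SNP ids in the liability), `genetic_score` (the
#'   standardised true score) and `h2` (the configured fraction).
#' @examples
#' cfg <- sim_config(n_samples = 500, n_snps = 100, exposure_h2 = 0.2, seed = 3)
#' e <- simulate_exposure(simulate_genotypes(cfg), cfg)
#' mean(e)
#' @export
simulate_exposure <- function(panel, config) {
  validate_sim_config(config)
  stopifnot(inherits(panel, "genotype_panel"))
  set.seed(config$seed + 1L)
  n <- nrow(panel$dosages)
  h2 <- config$exposure_h2

  k <- min(config$n_exposure_snps, ncol(panel$dosages))
  idx <- sample.int(ncol(panel$dosages), k)
  gs <- standardise_dosages(panel$dosages[, idx, drop = FALSE])
  score <- rowSums(gs) / sqrt(k)
  score <- as.numeric(scale(score))

  liability <- sqrt(h2) * score + sqrt(1 - h2) * stats::rnorm(n)
  # monotone quantile map: liability rank -> Poisson count scale
  u <- stats::pnorm(liability / stats::sd(liability))
  counts <- stats::qpois(u, lambda = config$exposure_mean)

  structure(as.integer(counts),
            exposure_snps = panel$snps$snp[idx],
            genetic_score = score,
            h2 = h2)
}

#' Simulate covariates for a synthetic cohort
#'
#' Generates an age-like continuous covariate and a binary sex covariate,
#' the standard nuisance terms of an association scan.
#'
#' @param n Number of samples.
#' @param seed Integer seed.
#' @return Tibble with columns `age` (Normal(50, 10)) and `sex` (0/1).
#' @export
simulate_covariates <- function(n, seed = 1L) {
  set.seed(as.integer(seed) + 2L)
  tibble::tibble(age = stats::rnorm(n, 50, 10),
                 sex = stats::rbinom(n, 1, 0.5))
}

#' Simulate a quantitative phenotype under the full interaction model
#'
#' Generates `Y = sum(beta_G * G_std) + beta_E * E +
#' sum(beta_GxE * G_std * E) + covariate effects + eps` with
#' `eps ~ Normal(0, sigma0 * (1 + hetero_factor * E))`. Causal SNPs for
#' the additive and interaction components are disjoint random subsets;
#' raw effects are standard normal and each component is rescaled so its
#' realised sample variance equals exactly `var_additive` (resp.
#' `var_gxe`), with `sigma0 = sqrt(1 - var_additive - var_gxe)`.
#' Genotypes are standardised before effects are applied so the variance
#' fractions are interpretable; raw dosages are untouched.
#'
#' @param panel A `genotype_panel`.
#' @param exposure Numeric vector of exposure counts, length `n_samples`.
#' @param covariates Optional data frame of numeric covariate columns
#'   (standardised internally before the per-column effect `beta_covar`
#'   is applied); `NULL` for none.
#' @param config A [sim_config()]; draws from stream `seed + 2`.
#' @return A list with `phenotype` (numeric vector) and `truth`, a list
#'   recording the causal SNP ids and scaled effect sizes
#'   (`additive_snps`, `beta_additive`, `gxe_snps`, `beta_gxe`),
#'   `beta_E`, `beta_covar` and `sigma0`.
#' @examples
#' cfg <- sim_config(n_samples = 300, n_snps = 60, n_causal_additive = 5,
#'                   n_causal_gxe = 5, seed = 9)
#' panel <- simulate_genotypes(cfg)
#' e <- simulate_exposure(panel, cfg)
#' y <- simulate_phenotype(panel, e, NULL, cfg)
#' length(y$phenotype)
#' @export
simulate_phenotype <- function(panel, exposure, covariates = NULL, config) {
  validate_sim_config(config)
  stopifnot(inherits(panel, "genotype_panel"))
  n <- nrow(panel$dosages)
  if (length(exposure) != n) {
    stop("`exposure` length must equal the panel sample count", call. = FALSE)
  }
  if (!is.null(covariates) && nrow(covariates) != n) {
    stop("`covariates` rows must equal the panel sample count", call. = FALSE)
  }
  set.seed(config$seed + 2L)
  m <- ncol(panel$dosages)

  causal <- sample.int(m, config$n_causal_additive + config$n_causal_gxe)
  add_idx <- causal[seq_len(config$n_causal_additive)]
  gxe_idx <- setdiff(causal, add_idx)

  rescale_to <- function(component, target_var) {
    v <- stats::var(component)
    if (v == 0 || target_var == 0) return(list(x = component * 0, s = 0))
    s <- sqrt(target_var / v)
    list(x = component * s, s = s)
  }

  beta_add <- beta_gxe <- numeric(0)
  A <- I <- numeric(n)
  if (length(add_idx) > 0 && config$var_additive > 0) {
    Gs <- standardise_dosages(panel$dosages[, add_idx, drop = FALSE])
    beta_add <- stats::rnorm(length(add_idx))
    comp <- rescale_to(as.numeric(Gs %*% beta_add), config$var_additive)
    A <- comp$x
    beta_add <- beta_add * comp$s
  }
  if (length(gxe_idx) > 0 && config$var_gxe > 0) {
    Gs <- standardise_dosages(panel$dosages[, gxe_idx, drop = FALSE])
    beta_gxe <- stats::rnorm(length(gxe_idx))
    comp <- rescale_to(as.numeric((Gs * exposure) %*% beta_gxe), config$var_gxe)
    I <- comp$x
    beta_gxe <- beta_gxe * comp$s
  }

  Ceff <- numeric(n)
  if (!is.null(covariates) && ncol(covariates) > 0 && config$beta_covar != 0) {
    Cs <- scale(as.matrix(covariates))
    Cs[is.nan(Cs)] <- 0
    Ceff <- as.numeric(Cs %*% rep(config$beta_covar, ncol(Cs)))
  }

  sigma0 <- sqrt(max(0, 1 - config$var_additive - config$var_gxe))
  eps <- stats::rnorm(n, 0, sigma0 * (1 + config$hetero_factor * exposure))
  y <- A + config$beta_E * exposure + I + Ceff + eps

  list(
    phenotype = as.numeric(y),
    truth = list(
      additive_snps = panel$snps$snp[add_idx], beta_additive = beta_add,
      gxe_snps = panel$snps$snp[gxe_idx], beta_gxe = beta_gxe,
      beta_E = config$beta_E, beta_covar = config$beta_covar, sigma0 = sigma0
    )
  )
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper running [simulate_genotypes()],
#' [simulate_exposure()], [simulate_covariates()] and
#' [simulate_phenotype()] in that fixed order from one configuration, so
#' a whole cohort is reproducible from a single seed.
#'
#' @param config A [sim_config()].
#' @param covariates Logical; generate age/sex covariates (default TRUE).
#' @return A list with `panel`, `data` (tibble with `fid`, `iid`,
#'   `phenotype`, `exposure` and covariate columns) and `truth`.
#' @examples
#' study <- simulate_study(sim_config(n_samples = 200, n_snps = 50, seed = 2))
#' head(study$data)
#' @export
simulate_study <- function(config, covariates = TRUE) {
  panel <- simulate_genotypes(config)
  exposure <- simulate_exposure(panel, config)
  covar <- if (covariates) simulate_covariates(config$n_samples, config$seed) else NULL
  ph <- simulate_phenotype(panel, exposure, covar, config)
  data <- tibble::tibble(
    fid = panel$samples$fid, iid = panel$samples$iid,
    phenotype = ph$phenotype, exposure = as.integer(exposure)
  )
  if (!is.null(covar)) data <- dplyr::bind_cols(data, covar)
  list(panel = panel, data = data, truth = ph$truth,
       exposure_truth = attributes(exposure))
}

#' Write a synthetic study to PLINK-compatible files
#'
#' Emits the genotype panel as a PLINK 1.x bed/bim/fam triplet plus
#' whitespace-delimited phenotype, covariate and exposure tables with the
#' `FID IID value` header convention, so the fixture round-trips through
#' [read_plink()] and [read_study_table()].
#'
#' @param panel A `genotype_panel`.
#' @param exposure Numeric exposure vector (or NULL to skip).
#' @param phenotype Numeric phenotype vector (or NULL to skip).
#' @param covariates Data frame of covariates (or NULL to skip).
#' @param out_prefix Path prefix; files `<prefix>.bed/.bim/.fam` and
#'   `<prefix>.pheno/.covar/.exposure` are created.
#' @return Invisibly, the character vector of files written.
#' @export
write_fixture <- function(panel, exposure = NULL, phenotype = NULL,
                          covariates = NULL, out_prefix) {
  n <- nrow(panel$dosages)
  for (v in list(exposure, phenotype)) {
    if (!is.null(v) && length(v) != n) {
      stop("fixture component lengths must match the panel", call. = FALSE)
    }
  }
  if (!is.null(covariates) && nrow(covariates) != n) {
    stop("fixture component lengths must match the panel", call. = FALSE)
  }
  written <- write_plink(panel, out_prefix)
  key <- tibble::tibble(FID = panel$samples$fid, IID = panel$samples$iid)
  emit <- function(df, ext) {
    path <- paste0(out_prefix, ext)
    readr::write_delim(df, path, delim = " ")
    path
  }
  if (!is.null(phenotype)) {
    written <- c(written, emit(dplyr::mutate(key, PHENO = phenotype), ".pheno"))
  }
  if (!is.null(exposure)) {
    written <- c(written, emit(dplyr::mutate(key, EXPOSURE = exposure), ".exposure"))
  }
  if (!is.null(covariates)) {
    written <- c(written, emit(dplyr::bind_cols(key, covariates), ".covar"))
  }
  invisible(written)
}
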