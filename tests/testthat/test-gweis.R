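test_that("single-SNP GWAS equals the closed-form regression slope", {
  g <- c(0L, 1L, 2L, 1L, 0L, 2L, 1L, 1L)
  y <- c(0.2, 1.1, 2.3, 0.9, -0.1, 2.7, 1.4, 1.0)
  panel <- make_panel(matrix(g, ncol = 1))
  data <- tibble::tibble(iid = panel$samples$iid, y = y)
  res <- run_gwas(panel, data, "y")
  slope <- sum((g - mean(g)) * (y - mean(y))) / sum((g - mean(g))^2)
  expect_equal(res$beta, slope, tolerance = 1e-12)
  fit <- lm(y ~ g)
  expect_equal(res$se, summary(fit)$coefficients["g", 2], tolerance = 1e-12)
  expect_equal(res$p, summary(fit)$coefficients["g", 4], tolerance = 1e-12)
})

test_that("an orthogonal covariate leaves the additive estimate unchanged", {
  set.seed(51)
  n <- 60
  g <- sample(0:2, n, TRUE)
  y <- 0.3 * g + rnorm(n)
  z <- rnorm(n)
  z <- resid(lm(z ~ g))   # exactly orthogonal to the dosage
  panel <- make_panel(matrix(as.integer(g), ncol = 1))
  d <- tibble::tibble(iid = panel$samples$iid, y = y, z = z)
  b0 <- run_gwas(panel, d, "y")$beta
  b1 <- run_gwas(panel, d, "y", "z")$beta
  expect_equal(b0, b1, tolerance = 1e-10)
})

test_that("GWAS p-values are calibrated under the null", {
  cfg <- sim_config(n_samples = 500, n_snps = 2000, var_additive = 0,
                    var_gxe = 0, beta_E = 0, seed = 52)
  study <- simulate_study(cfg, covariates = FALSE)
  res <- run_gwas(study$panel, study$data, "phenotype")
  rate <- mean(res$p < 0.05, na.rm = TRUE)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 2000))
})

test_that("sandwich covariance matches brute-force and sandwich::vcovHC", {
  # explicit matrix-product oracle on 10 samples, no covariates
  set.seed(53)
  g <- c(0L, 1L, 2L, 0L, 1L, 2L, 1L, 0L, 2L, 1L)
  E <- rpois(10, 2)
  y <- 0.5 * g + 0.2 * E + 0.1 * g * E + rnorm(10, 0, 0.5 + 0.2 * E)
  panel <- make_panel(matrix(g, ncol = 1))
  d <- tibble::tibble(iid = panel$samples$iid, y = y, E = E)
  res <- run_gweis(panel, d, "y", "E")

  X <- cbind(1, E, g, g * E)   # column order of the fitted model
  XtXinv <- solve(t(X) %*% X)
  b <- XtXinv %*% t(X) %*% y
  e <- as.numeric(y - X %*% b)
  V <- XtXinv %*% (t(X) %*% diag(e^2) %*% X) %*% XtXinv
  expect_equal(res$beta_g, b[3], tolerance = 1e-10)
  expect_equal(res$beta_e, b[2], tolerance = 1e-10)
  expect_equal(res$beta_gxe, b[4], tolerance = 1e-10)
  expect_equal(res$se_g, sqrt(V[3, 3]), tolerance = 1e-10)
  expect_equal(res$se_gxe, sqrt(V[4, 4]), tolerance = 1e-10)
  bb <- b[c(3, 4)]
  S <- V[c(3, 4), c(3, 4)]
  expect_equal(res$chi2_joint, drop(t(bb) %*% solve(S) %*% bb),
               tolerance = 1e-8)

  # library oracle with covariates, both robust variants, 50 samples
  skip_if_not_installed("sandwich")
  cfg <- sim_config(n_samples = 50, n_snps = 5, var_additive = 0.2,
                    var_gxe = 0.1, n_causal_additive = 2, n_causal_gxe = 2,
                    hetero_factor = 0.4, seed = 54)
  study <- simulate_study(cfg)
  for (variant in c("HC0", "HC1")) {
    res <- run_gweis(study$panel, study$data, "phenotype", "exposure",
                     c("age", "sex"), robust = variant)
    for (j in 1:5) {
      dd <- study$data
      dd$g <- as.numeric(study$panel$dosages[, j])
      fit <- lm(phenotype ~ g + exposure + I(g * exposure) + age + sex,
                data = dd)
      Vo <- sandwich::vcovHC(fit, type = variant)
      expect_equal(res$beta_gxe[j], coef(fit)[["I(g * exposure)"]],
                   tolerance = 1e-8)
      expect_equal(res$se_gxe[j],
                   sqrt(Vo["I(g * exposure)", "I(g * exposure)"]),
                   tolerance = 1e-8)
      expect_equal(res$se_g[j], sqrt(Vo["g", "g"]), tolerance = 1e-8)
    }
  }
})

test_that("degenerate SNPs and exposures are handled", {
  dos <- cbind(rep(1L, 30), sample(0:2, 30, TRUE))
  panel <- make_panel(dos)
  d <- tibble::tibble(iid = panel$samples$iid, y = rnorm(30),
                      E = rpois(30, 2), Ec = rep(2, 30))
  res <- run_gweis(panel, d, "y", "E")
  expect_equal(res$status[1], "monomorphic")
  expect_true(is.na(res$p_gxe[1]))
  expect_equal(res$status[2], "ok")
  expect_error(run_gweis(panel, d, "y", "Ec"), "collinear")
})

test_that("the GxE p-value is invariant to affine exposure rescaling", {
  study <- shared_study()
  d <- study$data
  d$E2 <- 3 * d$exposure + 5
  r1 <- run_gweis(study$panel, d, "phenotype", "exposure", c("age", "sex"))
  r2 <- run_gweis(study$panel, d, "phenotype", "E2", c("age", "sex"))
  expect_equal(r1$p_gxe, r2$p_gxe, tolerance = 1e-8)
  expect_equal(r1$beta_gxe, r2$beta_gxe * 3, tolerance = 1e-8)
})

test_that("robust and classical SEs agree under homoscedastic noise", {
  cfg <- sim_config(n_samples = 3000, n_snps = 150, var_additive = 0,
                    var_gxe = 0, hetero_factor = 0, seed = 55)
  study <- simulate_study(cfg)
  res <- run_gweis(study$panel, study$data, "phenotype", "exposure",
                   c("age", "sex"), classical = TRUE)
  ratio <- res$se_gxe / res$se_gxe_classical
  expect_lt(abs(median(ratio) - 1), 0.05)
})

test_that("GxE and joint p-values are uniform under the homoscedastic null", {
  cfg <- sim_config(n_samples = 800, n_snps = 5000, var_additive = 0,
                    var_gxe = 0, hetero_factor = 0, beta_E = 0.2, seed = 56)
  study <- simulate_study(cfg)
  res <- run_gweis(study$panel, study$data, "phenotype", "exposure",
                   c("age", "sex"))
  expect_gt(ks.test(res$p_gxe, "punif")$p.value, 0.01)
  expect_gt(ks.test(res$p_joint, "punif")$p.value, 0.01)
})

test_that("the 2-df joint test absorbs a pure main effect", {
  cfg <- sim_config(n_samples = 1500, n_snps = 200, var_additive = 0.3,
                    n_causal_additive = 30, var_gxe = 0, seed = 57)
  study <- simulate_study(cfg)
  res <- run_gweis(study$panel, study$data, "phenotype", "exposure",
                   c("age", "sex"))
  # restrict to causal SNPs whose realised main effect is non-trivial
  # (drawn effects near zero give the 2-df test nothing to absorb)
  strong <- study$truth$additive_snps[abs(study$truth$beta_additive) > 0.08]
  at_causal <- res[res$snp %in% strong, ]
  expect_gt(length(strong), 5)
  expect_gt(mean(at_causal$p_joint < at_causal$p_gxe), 0.9)
})

test_that("GxE power is non-decreasing in the interaction variance", {
  power_at <- function(vg, seed) {
    cfg <- sim_config(n_samples = 2000, n_snps = 30, var_additive = 0,
                      var_gxe = vg, n_causal_gxe = 30,
                      n_causal_additive = 0, seed = seed)
    study <- simulate_study(cfg, covariates = FALSE)
    res <- run_gweis(study$panel, study$data, "phenotype", "exposure")
    mean(res$p_gxe < 0.05, na.rm = TRUE)
  }
  pw <- sapply(c(0, 0.2, 0.8), power_at, seed = 58)
  expect_true(all(diff(pw) > 0))
  expect_lt(pw[1], 0.1)
  expect_gt(pw[3], 0.5)
})

test_that("genomic inflation follows its closed forms", {
  expect_equal(genomic_inflation(rep(0.5, 100), n = 1000)$lambda_gc, 1,
               tolerance = 1e-12)
  # lambda_1000 closed form: lambda 1.10 at n = 5000 -> 1.02
  lam <- genomic_inflation(rep(pchisq(0.4549364 * 1.10, 1, lower.tail = FALSE),
                               10), n = 5000)
  expect_equal(lam$lambda_gc, 1.10, tolerance = 1e-6)
  expect_equal(lam$lambda_1000, 1.02, tolerance = 1e-6)
  set.seed(59)
  u <- runif(1e5)
  expect_lt(abs(genomic_inflation(u, n = 1000)$lambda_gc - 1), 0.03)
  expect_error(genomic_inflation(numeric(0), 10), "no non-missing")
  expect_error(genomic_inflation(c(0.5, 0), 10), "0, 1")
})

test_that("Bonferroni thresholds follow alpha/(snps x measures)", {
  expect_equal(bonferroni_threshold(100, 1), 5e-4, tolerance = 1e-15)
  expect_equal(bonferroni_threshold(560351, 3), 0.05 / 1681053,
               tolerance = 1e-15)
  expect_error(bonferroni_threshold(0, 1), ">= 1")
})
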