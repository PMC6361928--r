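test_that("clumping keeps singletons and resolves perfect LD by p-value", {
  g <- sample(0:2, 50, TRUE)
  panel <- make_panel(cbind(g, g, sample(0:2, 50, TRUE)),
                      bp = c(1000, 2000, 3000))
  ss <- tibble::tibble(snp = panel$snps$snp, chr = "1",
                       bp = panel$snps$bp, p = c(0.01, 0.002, 0.5))
  out <- clump(ss, panel, r2_threshold = 0.5, window_kb = 250)
  # s2 (p = .002) indexes and claims its perfect-LD twin s1; s3 survives
  expect_setequal(out$snp, c("s02", "s03"))
  single <- clump(ss[1, ], panel, r2_threshold = 0.5, window_kb = 250)
  expect_equal(single$snp, "s01")
})

test_that("greedy clumping matches the brute-force oracle on 20-SNP instances", {
  for (seed in 1:4) {
    cfg <- sim_config(n_samples = 150, n_snps = 20, ld_rho = 0.7,
                      ld_block_size = 5, n_chr = 2, bp_spacing = 100000,
                      n_causal_additive = 4, n_causal_gxe = 4, seed = seed)
    study <- simulate_study(cfg)
    gw <- run_gwas(study$panel, study$data, "phenotype")
    kept <- clump(gw, study$panel, r2_threshold = 0.2, window_kb = 250,
                  p1 = 0.9)
    oracle <- brute_clump(gw, study$panel, 0.2, 250, 0.9)
    expect_setequal(kept$snp, oracle)
  }
})

test_that("the clumped set is invariant to input row order", {
  study <- shared_study()
  gw <- run_gwas(study$panel, study$data, "phenotype")
  k1 <- clump(gw, study$panel, r2_threshold = 0.2)
  set.seed(60)
  k2 <- clump(gw[sample(nrow(gw)), ], study$panel, r2_threshold = 0.2)
  expect_setequal(k1$snp, k2$snp)
})

test_that("clumping validates inputs", {
  study <- shared_study()
  gw <- run_gwas(study$panel, study$data, "phenotype")
  other <- gw
  other$snp <- paste0("zz", seq_len(nrow(other)))
  expect_error(clump(other, study$panel), "no sumstats SNPs")
  mixed <- gw
  mixed$snp[1:10] <- paste0("zz", 1:10)
  expect_warning(clump(mixed, study$panel), "dropped")
  expect_error(clump(gw, study$panel, p1 = 1e-300), "p1")
})

test_that("weight tables map scheme to effect and selection p", {
  study <- shared_study()
  gw <- run_gwas(study$panel, study$data, "phenotype", c("age", "sex"))
  gx <- run_gweis(study$panel, study$data, "phenotype", "exposure",
                  c("age", "sex"))
  wa <- build_weights(gw, "additive")
  expect_equal(wa$weight, gw$beta[!is.na(gw$beta)])
  expect_equal(wa$select_p, gw$p[!is.na(gw$p)])
  wg <- build_weights(gx, "gxe")
  expect_equal(wg$select_p, gx$p_gxe[!is.na(gx$p_gxe)])
  wj <- build_weights(gx, "joint")
  expect_equal(wj$weight, (gx$beta_g + gx$beta_gxe)[!is.na(gx$beta_g)])
  # declared combination rule: beta_g + beta_gxe cancels when opposite
  fake <- gx[1, ]
  fake$beta_g <- 0.1
  fake$beta_gxe <- -0.1
  expect_equal(build_weights(fake, "joint")$weight, 0)
  expect_error(build_weights(gw, "gxe"), "beta_gxe")
})

test_that("scoring counts effect alleles and respects allele orientation", {
  dos <- matrix(c(0L, 1L, 2L, 2L, 0L, 1L), ncol = 2)
  panel <- make_panel(dos, a1 = c("A", "T"), a2 = c("G", "C"))
  w <- tibble::tibble(snp = c("s01", "s02"), effect_allele = c("A", "T"),
                      weight = c(1, 1), select_p = c(0.5, 0.5))
  prof <- prs_score(panel, w)
  expect_equal(prof$score, rowSums(dos))
  # relabelling a SNP's alleles in the panel (A1<->A2, dosage -> 2-dosage)
  # leaves all scores unchanged: the scorer re-orients onto the effect allele
  dos_f <- dos
  dos_f[, 2] <- 2L - dos_f[, 2]
  panel_f <- make_panel(dos_f, a1 = c("A", "C"), a2 = c("G", "T"))
  prof_f <- prs_score(panel_f, w)
  expect_equal(prof_f$score, prof$score)
  # negating a weight and pointing it at the other allele shifts the raw
  # score by a constant (-2w per SNP) and leaves the standardised score
  w_swap <- w
  w_swap$effect_allele <- c("G", "C")
  w_swap$weight <- -w$weight
  prof_swap <- prs_score(panel, w_swap)
  expect_equal(prof_swap$score, prof$score - 2 * sum(w$weight))
  expect_equal(prof_swap$score_std, prof$score_std)
})

test_that("ambiguous and mismatched SNPs are dropped with a warning", {
  dos <- matrix(c(0L, 1L, 2L, 2L, 0L, 1L, 1L, 1L, 0L), ncol = 3)
  panel <- make_panel(dos, a1 = c("A", "A", "C"), a2 = c("G", "T", "A"))
  w <- tibble::tibble(snp = c("s01", "s02", "s03"),
                      effect_allele = c("A", "A", "G"),
                      weight = c(1, 1, 1), select_p = rep(0.5, 3))
  expect_warning(prof <- prs_score(panel, w), "dropped")
  expect_equal(attr(prof, "n_snps_used"), 1L)   # s02 ambiguous, s03 mismatch
  expect_equal(prof$score, dos[, 1])
})

test_that("missing dosages are imputed at twice the allele frequency", {
  dos <- matrix(c(2L, 2L, 0L, NA), ncol = 1)
  panel <- make_panel(dos)
  w <- tibble::tibble(snp = "s01", effect_allele = "A", weight = 1,
                      select_p = 0.5)
  prof <- prs_score(panel, w)
  expect_equal(prof$score[4], 2 * mean(c(2, 2, 0)) / 2)
})

test_that("scoring is linear and monotone in the threshold", {
  study <- shared_study()
  gw <- run_gwas(study$panel, study$data, "phenotype")
  gx <- run_gweis(study$panel, study$data, "phenotype", "exposure")
  w1 <- build_weights(gw, "additive")
  w2 <- build_weights(gx, "gxe")
  stopifnot(identical(w1$snp, w2$snp))
  w12 <- w1
  w12$weight <- w1$weight + w2$weight
  s1 <- prs_score(study$panel, w1)$score
  s2 <- prs_score(study$panel, w2)$score
  s12 <- prs_score(study$panel, w12)$score
  expect_equal(s12, s1 + s2, tolerance = 1e-10)

  used <- sapply(c(1e-4, 0.01, 0.1, 0.5, 1), function(th) {
    p <- tryCatch(prs_score(study$panel, w1, th),
                  error = function(e) NULL)
    if (is.null(p)) 0L else attr(p, "n_snps_used")
  })
  expect_true(all(diff(used) >= 0))
  expect_error(prs_score(study$panel, w1, 1e-300), "no SNP passes")
})

test_that("an additive PRS transfers to held-out samples", {
  cfg <- sim_config(n_samples = 1600, n_snps = 400, var_additive = 0.2,
                    var_gxe = 0, n_causal_additive = 20, n_causal_gxe = 0,
                    seed = 61)
  study <- simulate_study(cfg)
  train <- subset_panel(study$panel, samples = 1:800)
  test <- subset_panel(study$panel, samples = 801:1600)
  gw <- run_gwas(train, study$data[1:800, ], "phenotype", c("age", "sex"))
  wt <- build_weights(clump(gw, train), "additive")
  prof <- prs_score(test, wt)
  ct <- cor.test(prof$score, study$data$phenotype[801:1600])
  expect_gt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.01)
})

test_that("the threshold grid reports incremental fit per cutoff", {
  study <- shared_study()
  gw <- run_gwas(study$panel, study$data, "phenotype", c("age", "sex"))
  wt <- build_weights(clump(gw, study$panel), "additive")
  grid <- prs_threshold_grid(study$panel, wt, study$data, "phenotype",
                             c("age", "sex"), grid = c(0.05, 0.5, 1))
  expect_equal(nrow(grid), 3)
  expect_equal(sum(grid$best), 1L)
  expect_true(all(diff(grid$n_snps_used) >= 0))
})
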