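# Shared small fixtures, built once per test run.

# tiny hand-buildable panel: explicit dosages, one chromosome
make_panel <- function(dosages, bp = NULL, chr = NULL, a1 = NULL, a2 = NULL) {
  n <- nrow(dosages)
  m <- ncol(dosages)
  snps <- tibble::tibble(
    snp = sprintf("s%02d", seq_len(m)),
    chr = if (is.null(chr)) rep("1", m) else chr,
    bp = if (is.null(bp)) as.integer(seq_len(m) * 1000) else as.integer(bp),
    a1 = if (is.null(a1)) rep("A", m) else a1,
    a2 = if (is.null(a2)) rep("G", m) else a2,
    freq = colMeans(dosages, na.rm = TRUE) / 2
  )
  storage.mode(dosages) <- "integer"
  colnames(dosages) <- snps$snp
  gweis:::new_genotype_panel(
    dosages, snps,
    tibble::tibble(fid = sprintf("F%03d", seq_len(n)),
                   iid = sprintf("I%03d", seq_len(n)))
  )
}

# a moderate study reused by several files (additive + GxE signal)
shared_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_samples = 600, n_snps = 150, var_additive = 0.15,
                        var_gxe = 0.05, n_causal_additive = 10,
                        n_causal_gxe = 10, ld_rho = 0.4, beta_E = 0.2,
                        seed = 101)
      cache <<- simulate_study(cfg)
    }
    cache
  }
})

# independent brute-force clumper used as oracle: literal restatement of
# the greedy definition, recomputing everything from scratch each round
brute_clump <- function(ss, panel, r2_threshold, window_kb, p1, p_col = "p") {
  ss <- ss[!is.na(ss[[p_col]]) & ss[[p_col]] <= p1, ]
  remaining <- ss
  kept <- character(0)
  while (nrow(remaining) > 0) {
    o <- order(remaining[[p_col]], remaining$chr, remaining$bp)
    idx <- remaining[o[1], ]
    kept <- c(kept, idx$snp)
    drop <- logical(nrow(remaining))
    for (i in seq_len(nrow(remaining))) {
      row <- remaining[i, ]
      if (row$snp == idx$snp) { drop[i] <- TRUE; next }
      if (row$chr != idx$chr) next
      if (abs(row$bp - idx$bp) > window_kb * 1000) next
      r2 <- cor(panel$dosages[, match(idx$snp, panel$snps$snp)],
                panel$dosages[, match(row$snp, panel$snps$snp)])^2
      if (!is.na(r2) && r2 >= r2_threshold) drop[i] <- TRUE
    }
    remaining <- remaining[!drop, ]
  }
  kept
}

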