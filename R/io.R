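# Table readers/writers for the pipeline's interchange formats and the
# end-to-end pipeline runner. All tables are whitespace- or
# tab-delimited text with conventional uppercase headers (FID IID ...,
# SNP CHR BP A1 A2 ...); internally columns use lowercase names.

#' Read a study table
#'
#' Reads one of the pipeline's tabular inputs, validates its schema and
#' returns a typed tibble with lowercase column names. Sample-keyed
#' kinds (`phenotype`, `covariate`, `exposure`) require `FID` and `IID`
#' columns and unique (FID, IID) keys; `sumstats` requires the
#' association-scan header (`SNP CHR BP A1 A2 N BETA SE P` or its GWEIS
#' analogue with `BETA_G ... P_JOINT`); `weights` requires
#' `SNP A1 WEIGHT P`. Tab- and whitespace-delimited files parse
#' identically.
#'
#' @param path File path.
#' @param kind One of `"phenotype"`, `"covariate"`, `"exposure"`,
#'   `"sumstats"`, `"weights"`.
#' @return A tibble; sample-keyed kinds get `fid`/`iid` columns,
#'   sumstats/weights get the package's internal column names
#'   (`snp`, `chr`, `bp`, `a1`, `a2`, `beta_g`, ..., or `snp`,
#'   `effect_allele`, `weight`, `select_p`).
#' @export
read_study_table <- function(path, kind = c("phenotype", "covariate",
                                            "exposure", "sumstats",
                                            "weights")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                           check.names = FALSE)
  tab <- tibble::as_tibble(tab)

  if (kind %in% c("phenotype", "covariate", "exposure")) {
    if (!all(c("FID", "IID") %in% names(tab))) {
      stop(kind, " table must have FID and IID columns", call. = FALSE)
    }
    names(tab)[match(c("FID", "IID"), names(tab))] <- c("fid", "iid")
    tab$fid <- as.character(tab$fid)
    tab$iid <- as.character(tab$iid)
    key <- paste(tab$fid, tab$iid)
    if (anyDuplicated(key)) {
      stop("duplicated sample key(s) in ", kind, " table", call. = FALSE)
    }
    if (ncol(tab) < 3) {
      stop(kind, " table needs at least one value column", call. = FALSE)
    }
    names(tab)[-(1:2)] <- tolower(names(tab)[-(1:2)])
    return(tab)
  }

  if (kind == "weights") {
    need <- c("SNP", "A1", "WEIGHT", "P")
    miss <- setdiff(need, names(tab))
    if (length(miss) > 0) {
      stop("weights table lacks column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    return(tibble::tibble(snp = as.character(tab$SNP),
                          effect_allele = as.character(tab$A1),
                          weight = as.numeric(tab$WEIGHT),
                          select_p = as.numeric(tab$P)))
  }

  # sumstats: GWAS or GWEIS layout
  base <- c("SNP", "CHR", "BP", "A1", "A2", "N")
  gweis_cols <- c("BETA_G", "SE_G", "BETA_E", "SE_E", "BETA_GXE", "SE_GXE",
                  "P_GXE", "CHI2_JOINT", "P_JOINT")
  gwas_cols <- c("BETA", "SE", "P")
  miss_base <- setdiff(base, names(tab))
  if (length(miss_base) > 0) {
    stop("sumstats table lacks column(s): ",
         paste(miss_base, collapse = ", "), call. = FALSE)
  }
  is_gweis <- all(gweis_cols %in% names(tab))
  is_gwas <- all(gwas_cols %in% names(tab))
  if (!is_gweis && !is_gwas) {
    stop("sumstats table matches neither the GWAS (BETA SE P) nor the ",
         "GWEIS (BETA_G ... P_JOINT) schema", call. = FALSE)
  }
  keep <- c(base, if (is_gweis) gweis_cols else gwas_cols)
  out <- tab[, keep, drop = FALSE]
  names(out) <- c("snp", "chr", "bp", "a1", "a2", "n_used",
                  if (is_gweis) tolower(gweis_cols) else c("beta", "se", "p"))
  out$snp <- as.character(out$snp)
  out$chr <- as.character(out$chr)
  out$bp <- as.integer(out$bp)
  tibble::as_tibble(out)
}

#' Write association summary statistics
#'
#' Writes a [run_gwas()] table with header `SNP CHR BP A1 A2 N BETA SE
#' P`, or a [run_gweis()] table with header `SNP CHR BP A1 A2 N BETA_G
#' SE_G BETA_E SE_E BETA_GXE SE_GXE P_GXE CHI2_JOINT P_JOINT`,
#' tab-delimited. A1 is always the effect allele.
#'
#' @param x A `gwas_result` or `gweis_result` tibble.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_sumstats <- function(x, path) {
  if (all(c("beta_g", "p_joint") %in% names(x))) {
    cols <- c("snp", "chr", "bp", "a1", "a2", "n_used", "beta_g", "se_g",
              "beta_e", "se_e", "beta_gxe", "se_gxe", "p_gxe",
              "chi2_joint", "p_joint")
    hdr <- c("SNP", "CHR", "BP", "A1", "A2", "N", "BETA_G", "SE_G",
             "BETA_E", "SE_E", "BETA_GXE", "SE_GXE", "P_GXE",
             "CHI2_JOINT", "P_JOINT")
  } else if ("beta" %in% names(x)) {
    cols <- c("snp", "chr", "bp", "a1", "a2", "n_used", "beta", "se", "p")
    hdr <- c("SNP", "CHR", "BP", "A1", "A2", "N", "BETA", "SE", "P")
  } else {
    stop("`x` is neither a GWAS nor a GWEIS result table", call. = FALSE)
  }
  out <- as.data.frame(x[, cols])
  names(out) <- hdr
  readr::write_tsv(out, path)
  invisible(path)
}

#' Write a PRS weight table (`SNP A1 WEIGHT P`, tab-delimited)
#'
#' @param x A `weight_table`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_weights <- function(x, path) {
  out <- data.frame(SNP = x$snp, A1 = x$effect_allele, WEIGHT = x$weight,
                    P = x$select_p)
  readr::write_tsv(out, path)
  invisible(path)
}

#' Write PRS profiles (`FID IID SCORE N_SNPS`, tab-delimited)
#'
#' @param x A `prs_profile`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_profiles <- function(x, path) {
  out <- data.frame(FID = x$fid, IID = x$iid, SCORE = x$score,
                    N_SNPS = attr(x, "n_snps_used"))
  readr::write_tsv(out, path)
  invisible(path)
}

pipeline_defaults <- function() {
  list(
    seed = 1L,
    out_prefix = "gweis_demo",
    simulate = list(),          # sim_config() overrides
    gweis = list(robust = "HC0"),
    prs = list(r2_threshold = 0.1, window_kb = 250, p_threshold = 1),
    evaluate = list(n_perm = 1000)
  )
}

merge_config <- function(defaults, user, where = "config") {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown ", where, " key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  utils::modifyList(defaults, user)
}

#' Run the full synthetic GWEIS pipeline from one configuration
#'
#' Simulates a cohort, splits it into equal discovery and target halves,
#' runs the additive scan and the interaction scan on the discovery
#' half, builds clumped weight tables under the three weighting schemes
#' (additive, gxe, joint), scores the target half, and evaluates
#' incremental prediction: each score alone against covariates, the
#' additive-plus-interaction combination over the additive score, and
#' the combination against the joint-weighted score. All stage outputs
#' are written under the configured prefix together with a JSON
#' provenance sidecar; given the same config and seed the files are
#' reproducible byte-for-byte.
#'
#' @param config Path to a YAML file or a named list with any of the
#'   blocks `seed`, `out_prefix`, `simulate` (overrides for
#'   [sim_config()]), `gweis` (`robust`), `prs` (`r2_threshold`,
#'   `window_kb`, `p_threshold`) and `evaluate` (`n_perm`). Unknown
#'   keys are rejected.
#' @param out_dir Directory for outputs (created if needed); the
#'   config's `out_prefix` is interpreted relative to it.
#' @return Invisibly, a list with the in-memory stage results
#'   (`gwas`, `gweis`, `weights`, `profiles`, `report`) and the vector
#'   of files written.
#' @examples
#' \donttest{
#' res <- run_pipeline(list(simulate = list(n_samples = 400, n_snps = 200),
#'                          evaluate = list(n_perm = 200)),
#'                     out_dir = tempdir())
#' }
#' @export
run_pipeline <- function(config, out_dir = ".") {
  if (is.character(config)) {
    if (!file.exists(config)) {
      stop("config file not found: ", config, call. = FALSE)
    }
    config <- yaml::read_yaml(config)
  }
  cfg <- merge_config(pipeline_defaults(), config)
  cfg$gweis <- merge_config(pipeline_defaults()$gweis, cfg$gweis, "gweis")
  cfg$prs <- merge_config(pipeline_defaults()$prs, cfg$prs, "prs")
  cfg$evaluate <- merge_config(pipeline_defaults()$evaluate, cfg$evaluate,
                               "evaluate")
  sim_args <- cfg$simulate
  sim_args$seed <- cfg$seed
  scfg <- do.call(sim_config, sim_args)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  prefix <- file.path(out_dir, cfg$out_prefix)
  files <- character(0)
  put <- function(p) { files <<- c(files, p); p }

  message("simulate: ", scfg$n_samples, " samples x ", scfg$n_snps, " SNPs")
  study <- simulate_study(scfg)
  covars <- intersect(c("age", "sex"), names(study$data))

  n <- scfg$n_samples
  disc_idx <- seq_len(n %/% 2)
  targ_idx <- setdiff(seq_len(n), disc_idx)
  disc <- subset_panel(study$panel, samples = disc_idx)
  targ <- subset_panel(study$panel, samples = targ_idx)
  disc_data <- study$data[disc_idx, ]
  targ_data <- study$data[targ_idx, ]

  message("scan: additive GWAS and GWEIS on the discovery half")
  gw <- run_gwas(disc, disc_data, "phenotype", covars)
  gx <- run_gweis(disc, disc_data, "phenotype", "exposure", covars,
                  robust = cfg$gweis$robust)
  write_sumstats(gw, put(paste0(prefix, "_gwas.sumstats")))
  write_sumstats(gx, put(paste0(prefix, "_gweis.sumstats")))

  message("prs: clump, weight and score the target half")
  schemes <- c("additive", "gxe", "joint")
  src <- list(additive = gw, gxe = gx, joint = gx)
  pcol <- c(additive = "p", gxe = "p_gxe", joint = "p_joint")
  weights <- list()
  profiles <- list()
  scored <- targ_data
  for (s in schemes) {
    kept <- clump(src[[s]], disc, r2_threshold = cfg$prs$r2_threshold,
                  window_kb = cfg$prs$window_kb, p_col = pcol[[s]])
    wt <- build_weights(kept, s)
    weights[[s]] <- wt
    write_weights(wt, put(paste0(prefix, "_", s, ".weights")))
    prof <- prs_score(targ, wt, cfg$prs$p_threshold)
    profiles[[s]] <- prof
    write_profiles(prof, put(paste0(prefix, "_", s, ".profile")))
    scored[[paste0("prs_", s)]] <- prof$score_std
  }

  message("evaluate: nested models, permutations, FDR")
  single <- purrr::map(schemes, function(s) {
    cmp <- fit_comparison(scored, "phenotype", character(),
                          paste0("prs_", s), covars,
                          trait_id = "phenotype")
    cmp$scheme <- s
    emp <- permutation_empirical_p(scored, "phenotype", paste0("prs_", s),
                                   covars, n_perm = cfg$evaluate$n_perm,
                                   seed = cfg$seed)
    cmp$empirical_p <- emp$empirical_p
    cmp
  })
  combo_over_add <- fit_comparison(scored, "phenotype", "prs_additive",
                                   c("prs_additive", "prs_gxe"), covars,
                                   trait_id = "phenotype")
  combo_over_add$scheme <- "additive+gxe_over_additive"
  combo_over_joint <- fit_comparison(scored, "phenotype", "prs_joint",
                                     c("prs_joint", "prs_additive", "prs_gxe"),
                                     covars, trait_id = "phenotype")
  combo_over_joint$scheme <- "additive+gxe_over_joint"

  report <- improvement_report(c(single, list(combo_over_add,
                                              combo_over_joint)))
  readr::write_csv(as.data.frame(report), put(paste0(prefix, "_report.csv")))

  provenance <- list(
    package = "gweis",
    version = as.character(utils::packageVersion("gweis")),
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), "seed")],
    sim_config = unclass(scfg),
    n_discovery = length(disc_idx),
    n_target = length(targ_idx)
  )
  jsonlite::write_json(provenance, put(paste0(prefix, "_provenance.json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(gwas = gw, gweis = gx, weights = weights,
                 profiles = profiles, report = report, files = files))
}
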