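# PLINK 1.x binary genotype I/O.
#
# bed layout: 3 magic bytes 0x6c 0x1b 0x01 (SNP-major), then per SNP
# ceiling(n/4) bytes, 4 samples per byte, sample 1 in the lowest 2 bits.
# 2-bit codes (counting the A1 allele): 00 = hom A1 (dosage 2),
# 01 = missing, 10 = het (1), 11 = hom A2 (0).

.bed_magic <- as.raw(c(0x6c, 0x1b, 0x01))
.code_to_dosage <- c(2L, NA_integer_, 1L, 0L)   # indexed by code + 1

#' Read a PLINK 1.x bed/bim/fam fileset
#'
#' Unpacks a SNP-major PLINK binary fileset into a `genotype_panel`.
#' Dosages count the A1 allele of the bim file (column 5), which is
#' treated as the effect allele throughout; the PLINK missing code maps
#' to `NA`. Positions are 1-based.
#'
#' @param prefix Path prefix: `<prefix>.bed`, `<prefix>.bim` and
#'   `<prefix>.fam` must all exist.
#' @return A `genotype_panel`; the `freq` column holds the observed
#'   effect-allele frequency (ignoring missing calls).
#' @examples
#' cfg <- sim_config(n_samples = 20, n_snps = 5, seed = 4)
#' panel <- simulate_genotypes(cfg)
#' pre <- file.path(tempdir(), "demo")
#' write_plink(panel, pre)
#' identical(read_plink(pre)$dosages, panel$dosages)
#' @export
read_plink <- function(prefix) {
  paths <- paste0(prefix, c(".bed", ".bim", ".fam"))
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    stop("missing PLINK file(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  bim <- utils::read.table(paths[2], header = FALSE, colClasses = "character")
  if (ncol(bim) != 6) stop("bim file must have 6 columns", call. = FALSE)
  names(bim) <- c("chr", "snp", "cm", "bp", "a1", "a2")
  fam <- utils::read.table(paths[3], header = FALSE, colClasses = "character")
  if (ncol(fam) != 6) stop("fam file must have 6 columns", call. = FALSE)
  n <- nrow(fam)
  m <- nrow(bim)

  raw <- readBin(paths[1], "raw", n = file.size(paths[1]))
  if (length(raw) < 3 || !identical(raw[1:3], .bed_magic)) {
    stop("not a SNP-major PLINK 1.x bed file (bad magic bytes)", call. = FALSE)
  }
  bpr <- ceiling(n / 4)
  expected <- 3 + bpr * m
  if (length(raw) != expected) {
    stop(sprintf("bed payload is %d bytes but %d expected (3 + %d x %d)",
                 length(raw), expected, bpr, m), call. = FALSE)
  }
  bytes <- as.integer(raw[-(1:3)])
  # expand each byte into its 4 two-bit codes, sample-fastest
  codes <- rbind(bytes %% 4L,
                 (bytes %/% 4L) %% 4L,
                 (bytes %/% 16L) %% 4L,
                 bytes %/% 64L)
  dos <- matrix(.code_to_dosage[codes + 1L], nrow = 4L * bpr)[seq_len(n), ,
                                                             drop = FALSE]
  dim(dos) <- c(n, m)
  storage.mode(dos) <- "integer"

  freq <- colMeans(dos, na.rm = TRUE) / 2
  snp_id <- bim$snp
  colnames(dos) <- snp_id
  rownames(dos) <- fam[[2]]
  new_genotype_panel(
    dos,
    tibble::tibble(snp = snp_id, chr = bim$chr, bp = as.integer(bim$bp),
                   a1 = bim$a1, a2 = bim$a2, freq = freq),
    tibble::tibble(fid = fam[[1]], iid = fam[[2]])
  )
}

#' Write a genotype panel as PLINK 1.x bed/bim/fam
#'
#' @param panel A `genotype_panel`.
#' @param prefix Output path prefix.
#' @return Invisibly, the three file paths written.
#' @export
write_plink <- function(panel, prefix) {
  stopifnot(inherits(panel, "genotype_panel"))
  dos <- panel$dosages
  n <- nrow(dos)
  m <- ncol(dos)
  bpr <- ceiling(n / 4)

  # dosage -> 2-bit code: 2->0, NA->1, 1->2, 0->3
  code <- matrix(0L, 4L * bpr, m)   # pad bits beyond n are zero-filled
  d <- dos
  cd <- matrix(NA_integer_, n, m)
  cd[!is.na(d) & d == 2L] <- 0L
  cd[is.na(d)] <- 1L
  cd[!is.na(d) & d == 1L] <- 2L
  cd[!is.na(d) & d == 0L] <- 3L
  if (anyNA(cd)) stop("dosages must be 0, 1, 2 or NA", call. = FALSE)
  code[seq_len(n), ] <- cd

  i4 <- seq(1L, 4L * bpr, by = 4L)
  bytes <- code[i4, , drop = FALSE] +
    4L * code[i4 + 1L, , drop = FALSE] +
    16L * code[i4 + 2L, , drop = FALSE] +
    64L * code[i4 + 3L, , drop = FALSE]

  bed <- paste0(prefix, ".bed")
  con <- file(bed, "wb")
  on.exit(close(con))
  writeBin(.bed_magic, con)
  writeBin(as.raw(bytes), con)

  bim <- paste0(prefix, ".bim")
  utils::write.table(
    data.frame(panel$snps$chr, panel$snps$snp, 0L, panel$snps$bp,
               panel$snps$a1, panel$snps$a2),
    bim, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)

  fam <- paste0(prefix, ".fam")
  utils::write.table(
    data.frame(panel$samples$fid, panel$samples$iid, 0L, 0L, 0L, -9L),
    fam, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)

  invisible(c(bed, bim, fam))
}
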