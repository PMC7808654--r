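## Readers/writers for summary statistics, LD-score files, PLINK
## panels and results, plus cross-study SNP harmonization.

VALID_ALLELES <- c("A", "C", "G", "T")

# fread with transparent gzip support via a connection (no extra
# decompression dependency).
fread_auto <- function(path) {
  if (grepl("\\.gz$", path)) {
    con <- gzfile(path, "r")
    on.exit(close(con))
    data.table::fread(text = readLines(con), header = TRUE,
                      data.table = FALSE, showProgress = FALSE)
  } else {
    data.table::fread(path, header = TRUE, data.table = FALSE,
                      showProgress = FALSE)
  }
}

#' Read an LDSC-style summary-statistics file
#'
#' Whitespace-delimited text with a header containing at least SNP,
#' A1, A2, Z (optional N); transparently gzip-readable.  Rows with
#' missing or non-finite z-scores are dropped and counted (attribute
#' \code{"n_dropped"}).
#'
#' @param path File path.
#' @return A data frame (class \code{"sumstats"}) with columns
#'   snp_id, a1, a2, z and, when present, n.
#' @export
read_sumstats <- function(path) {
  dt <- fread_auto(path)
  names(dt) <- toupper(names(dt))
  need <- c("SNP", "A1", "A2", "Z")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop(sprintf("sumstats file %s lacks required column(s): %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  out <- data.frame(snp_id = as.character(dt$SNP),
                    a1 = toupper(as.character(dt$A1)),
                    a2 = toupper(as.character(dt$A2)),
                    z = suppressWarnings(as.numeric(dt$Z)),
                    stringsAsFactors = FALSE)
  if ("N" %in% names(dt)) out$n <- as.numeric(dt$N)
  keep <- is.finite(out$z)
  dropped <- sum(!keep)
  out <- out[keep, , drop = FALSE]
  if (anyDuplicated(out$snp_id))
    stop(sprintf("duplicated SNP id in %s (e.g. %s)", path,
                 out$snp_id[anyDuplicated(out$snp_id)][1L]),
         call. = FALSE)
  if (!all(out$a1 %in% VALID_ALLELES) || !all(out$a2 %in% VALID_ALLELES))
    stop("alleles must be one of A, C, G, T", call. = FALSE)
  rownames(out) <- NULL
  attr(out, "n_dropped") <- dropped
  class(out) <- c("sumstats", "data.frame")
  out
}

#' Read an LD-score file
#'
#' Tab-separated with header CHR, SNP, BP, L2 and optionally
#' L2_<category> columns (gzip-readable), as written by
#' [write_ldscores()] and interoperable with LDSC-style
#' \code{.l2.ldscore} files.
#'
#' @param path File path.
#' @return An \code{"ldscore_table"} data frame.
#' @export
read_ldscores <- function(path) {
  dt <- fread_auto(path)
  need <- c("CHR", "SNP", "BP", "L2")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop(sprintf("ldscore file lacks column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  out <- data.frame(snp_id = as.character(dt$SNP),
                    chrom = as.character(dt$CHR), bp = as.integer(dt$BP),
                    ldscore = as.numeric(dt$L2), stringsAsFactors = FALSE)
  for (cc in grep("^L2_", names(dt), value = TRUE))
    out[[sub("^L2_", "ldscore_", cc)]] <- as.numeric(dt[[cc]])
  class(out) <- c("ldscore_table", "data.frame")
  out
}

#' Write an LD-score table
#'
#' @param ld An \code{"ldscore_table"} data frame.
#' @param path Output path (\code{.gz} suffix compresses).
#' @return \code{path}, invisibly.
#' @export
write_ldscores <- function(ld, path) {
  out <- data.frame(CHR = ld$chrom, SNP = ld$snp_id, BP = ld$bp,
                    L2 = ld$ldscore)
  for (cc in grep("^ldscore_", names(ld), value = TRUE))
    out[[sub("^ldscore_", "L2_", cc)]] <- ld[[cc]]
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Read a SNP annotation file
#'
#' Two-column tab-separated (SNP, CATEGORY) with header.
#'
#' @param path File path.
#' @return Named character vector mapping snp_id to category.
#' @export
read_annot <- function(path) {
  dt <- fread_auto(path)
  if (ncol(dt) < 2L) stop("annotation file needs two columns",
                          call. = FALSE)
  stats::setNames(as.character(dt[[2L]]), as.character(dt[[1L]]))
}

#' Merge and harmonize two summary-statistics sets with LD scores
#'
#' Inner-joins the two studies and the LD scores on SNP id, aligns
#' study 2's alleles to study 1's (sign-flipping z when the alleles
#' are swapped, directly or after strand complementation), drops
#' strand-ambiguous SNPs (A/T, C/G) and irreconcilable allele pairs,
#' and returns the analysis-ready [snp_table()].  Per-rule drop counts
#' are attached as attribute \code{"harmonize_counts"}.
#'
#' @param s1,s2 \code{"sumstats"} data frames (see [read_sumstats()]).
#' @param ld An \code{"ldscore_table"} (file- or panel-derived).
#' @param annot Optional named vector mapping snp_id to category;
#'   requires per-category LD-score columns in \code{ld}.
#' @return A [snp_table()].
#' @export
merge_and_harmonize <- function(s1, s2, ld, annot = NULL) {
  ids <- intersect(intersect(s1$snp_id, s2$snp_id), ld$snp_id)
  if (!length(ids)) stop("no SNPs shared across inputs", call. = FALSE)
  i1 <- s1[match(ids, s1$snp_id), ]
  i2 <- s2[match(ids, s2$snp_id), ]
  il <- ld[match(ids, ld$snp_id), ]

  amb <- is_ambiguous(i1$a1, i1$a2) | is_ambiguous(i2$a1, i2$a2)
  same <- i2$a1 == i1$a1 & i2$a2 == i1$a2
  swap <- i2$a1 == i1$a2 & i2$a2 == i1$a1
  c1 <- unname(COMPLEMENT[i1$a1]); c2 <- unname(COMPLEMENT[i1$a2])
  strand <- i2$a1 == c1 & i2$a2 == c2
  strand_swap <- i2$a1 == c2 & i2$a2 == c1
  flip <- swap | strand_swap
  ok <- !amb & (same | swap | strand | strand_swap)
  mismatch <- !amb & !ok

  z2 <- ifelse(flip, -i2$z, i2$z)
  counts <- c(shared = length(ids), ambiguous = sum(amb),
              allele_mismatch = sum(mismatch), flipped = sum(flip & ok),
              kept = sum(ok))
  if (sum(ok) < 2L) stop("fewer than 2 SNPs after harmonization",
                         call. = FALSE)
  keep <- which(ok)
  annot_vec <- NULL; ld_annot <- NULL
  if (!is.null(annot)) {
    if (!all(ids[keep] %in% names(annot)))
      stop("annotation does not cover all merged SNPs", call. = FALSE)
    annot_vec <- unname(annot[ids[keep]])
    cols <- paste0("ldscore_", sort(unique(annot_vec)))
    if (!all(cols %in% names(il)))
      stop("LD-score table lacks per-category columns for the annotation",
           call. = FALSE)
    ld_annot <- as.matrix(il[keep, cols, drop = FALSE])
    colnames(ld_annot) <- sub("^ldscore_", "", cols)
  }
  out <- snp_table(ids[keep], il$chrom[keep], il$bp[keep],
                   i1$z[keep], z2[keep], il$ldscore[keep],
                   annot = annot_vec, ld_annot = ld_annot)
  attr(out, "harmonize_counts") <- counts
  out
}

#' Write the results table and a metadata sidecar
#'
#' Emits \code{<prefix>.results.tsv} (parameter, estimate, se, z, p;
#' full double precision so a read round-trips losslessly) and
#' \code{<prefix>.meta.yaml} describing the design, jackknife
#' convention, software version and seed.  Output bytes are
#' deterministic given identical inputs.
#'
#' @param result A \code{"gecko_result"} from [summarize_fit()] or
#'   [gecko_analyze()].
#' @param prefix Output path prefix.
#' @param config Optional configuration list echoed in the sidecar.
#' @param seed Optional seed echoed in the sidecar.
#' @return Paths of the written files, invisibly.
#' @export
write_results <- function(result, prefix, config = NULL, seed = NULL) {
  stopifnot(inherits(result, "gecko_result"))
  tsv <- paste0(prefix, ".results.tsv")
  tab <- result$table
  for (cc in c("estimate", "se", "z", "p"))
    tab[[cc]] <- sprintf("%.17g", tab[[cc]])
  utils::write.table(tab, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  meta <- list(
    software = paste0("gecko ",
                      as.character(utils::packageVersion("gecko"))),
    design = list(n1 = result$design$n1, n2 = result$design$n2,
                  ns = result$design$ns),
    rho_e_identifiable = result$rho_e_identifiable,
    jackknife = result$jackknife, loglik = result$loglik,
    converged = result$converged)
  if (!is.null(result$note)) meta$note <- result$note
  if (!is.null(config)) meta$config <- config
  if (!is.null(seed)) meta$seed <- seed
  yml <- paste0(prefix, ".meta.yaml")
  writeLines(yaml::as.yaml(meta), yml)
  invisible(c(results = tsv, metadata = yml))
}

#' Read back a written results table
#'
#' @param path Path to a \code{.results.tsv} file.
#' @return Data frame with numeric estimate, se, z, p.
#' @export
read_results <- function(path) {
  out <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  for (cc in c("estimate", "se", "z", "p")) out[[cc]] <- as.numeric(out[[cc]])
  out
}

#' Read a PLINK 1 binary genotype fileset
#'
#' Reads \code{prefix.bed} / \code{prefix.bim} / \code{prefix.fam}
#' (SNP-major bed layout) into a [genotype_panel()]; missing genotypes
#' become NA.  Dosages count copies of the A1 allele.
#'
#' @param prefix Path prefix of the fileset.
#' @return A [genotype_panel()].
#' @export
read_plink <- function(prefix) {
  bim <- data.table::fread(paste0(prefix, ".bim"), header = FALSE,
                           data.table = FALSE, showProgress = FALSE)
  names(bim) <- c("chrom", "snp_id", "cm", "bp", "a1", "a2")[seq_len(ncol(bim))]
  fam <- data.table::fread(paste0(prefix, ".fam"), header = FALSE,
                           data.table = FALSE, showProgress = FALSE)
  n <- nrow(fam); m <- nrow(bim)
  raw <- readBin(paste0(prefix, ".bed"), "raw",
                 n = 3 + ceiling(n / 4) * m)
  if (length(raw) < 3 || raw[1L] != as.raw(0x6c) || raw[2L] != as.raw(0x1b))
    stop("not a PLINK .bed file", call. = FALSE)
  if (raw[3L] != as.raw(0x01))
    stop("only SNP-major .bed files are supported", call. = FALSE)
  body <- raw[-(1:3)]
  bps <- ceiling(n / 4)
  if (length(body) != bps * m)
    stop("truncated .bed file", call. = FALSE)
  # 2-bit codes per genotype: 00 = 2 copies of A1, 10 = 1, 11 = 0,
  # 01 = missing.  Decode via a 256 x 4 lookup table.
  codes <- as.integer(body)
  lut <- matrix(0L, 256L, 4L)
  dec <- c(`0` = 2L, `1` = NA_integer_, `2` = 1L, `3` = 0L)
  for (b in 0:255) {
    q <- bitwAnd(bitwShiftR(b, c(0L, 2L, 4L, 6L)), 3L)
    lut[b + 1L, ] <- dec[as.character(q)]
  }
  geno <- matrix(NA_integer_, n, m)
  sel <- seq_len(n)
  for (j in seq_len(m)) {
    bytes <- codes[((j - 1L) * bps + 1L):(j * bps)]
    g <- t(lut[bytes + 1L, , drop = FALSE])
    geno[, j] <- g[sel]
  }
  genotype_panel(geno, snp_id = bim$snp_id, chrom = bim$chrom,
                 bp = bim$bp, a1 = bim$a1, a2 = bim$a2)
}
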