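## Reference-panel QC and windowed LD-score computation.

#' Reference genotype panel
#'
#' @param geno Numeric matrix, individuals x SNPs, dosages in
#'   \{0, 1, 2\} (NA allowed; missing genotypes are mean-imputed at
#'   standardization time).
#' @param snp_id,chrom,bp,a1,a2 Per-SNP metadata; positions must be
#'   sortable within chromosome (the constructor sorts).
#' @return An object of class \code{"genotype_panel"}: the dosage
#'   matrix plus per-SNP metadata including allele frequency and an
#'   exact Hardy-Weinberg p-value computed from the genotype counts.
#' @export
genotype_panel <- function(geno, snp_id, chrom, bp, a1 = NULL, a2 = NULL) {
  geno <- as.matrix(geno)
  m <- ncol(geno)
  stopifnot(length(snp_id) == m, length(chrom) == m, length(bp) == m)
  if (is.null(a1)) a1 <- rep("A", m)
  if (is.null(a2)) a2 <- rep("G", m)
  ord <- order(as.character(chrom), bp)
  geno <- geno[, ord, drop = FALSE]
  freq <- colMeans(geno, na.rm = TRUE) / 2
  maf <- pmin(freq, 1 - freq)
  hwe <- hwe_exact_p(geno)
  snp <- data.frame(snp_id = as.character(snp_id)[ord],
                    chrom = as.character(chrom)[ord],
                    bp = as.integer(bp)[ord],
                    a1 = as.character(a1)[ord], a2 = as.character(a2)[ord],
                    maf = maf, hwe_p = hwe, stringsAsFactors = FALSE)
  structure(list(geno = geno, snp = snp, n_ref = nrow(geno)),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("genotype panel: %d individuals x %d SNPs, %d chromosome(s)\n",
              x$n_ref, nrow(x$snp), length(unique(x$snp$chrom))))
  invisible(x)
}

# Exact Hardy-Weinberg test p-value per SNP (two-sided, summing all
# heterozygote configurations no more probable than the observed one).
hwe_exact_p <- function(geno) {
  apply(geno, 2L, function(g) {
    g <- g[!is.na(g)]
    n_aa <- sum(g == 0); n_ab <- sum(g == 1); n_bb <- sum(g == 2)
    hwe_exact_p1(n_ab, min(n_aa, n_bb) * 2 + n_ab, 2L * length(g))
  })
}

# obs_het heterozygotes, n_rare copies of the rarer allele, n_total
# allele copies.
hwe_exact_p1 <- function(obs_het, n_rare, n_total) {
  if (n_rare == 0 || n_rare == n_total) return(1)
  hets <- seq.int(n_rare %% 2L, n_rare, by = 2L)
  # log P(het count) up to a constant, via log-factorials
  n <- n_total / 2
  lp <- vapply(hets, function(h) {
    rare_hom <- (n_rare - h) / 2
    com_hom <- n - h - rare_hom
    h * log(2) - lfactorial(h) - lfactorial(rare_hom) - lfactorial(com_hom)
  }, numeric(1))
  pr <- exp(lp - max(lp)); pr <- pr / sum(pr)
  obs <- which(hets == obs_het)
  sum(pr[pr <= pr[obs] * (1 + 1e-12)])
}

#' Quality-control filter for a genotype panel
#'
#' Removes SNPs with minor allele frequency below \code{maf_min}, with
#' exact Hardy-Weinberg p-value below \code{hwe_p_min}, or with
#' strand-ambiguous allele pairs (A/T or C/G).  The defaults mirror the
#' standard GWAS filters (MAF < 5\%, HWE p < 0.001, drop ambiguous).
#'
#' @param panel A [genotype_panel()].
#' @param maf_min Minimum minor allele frequency.
#' @param hwe_p_min Minimum HWE p-value.
#' @param drop_ambiguous Drop A/T and C/G SNPs.
#' @return The filtered panel; attribute \code{"qc_counts"} reports the
#'   number removed by each filter.
#' @export
qc_panel <- function(panel, maf_min = 0.05, hwe_p_min = 0.001,
                     drop_ambiguous = TRUE) {
  stopifnot(inherits(panel, "genotype_panel"))
  s <- panel$snp
  bad_maf <- s$maf < maf_min
  bad_hwe <- s$hwe_p < hwe_p_min
  bad_amb <- if (drop_ambiguous) is_ambiguous(s$a1, s$a2)
             else rep(FALSE, nrow(s))
  keep <- !(bad_maf | bad_hwe | bad_amb)
  if (!any(keep)) stop("no SNPs left after QC", call. = FALSE)
  out <- structure(list(geno = panel$geno[, keep, drop = FALSE],
                        snp = s[keep, , drop = FALSE],
                        n_ref = panel$n_ref), class = "genotype_panel")
  rownames(out$snp) <- NULL
  attr(out, "qc_counts") <- c(maf = sum(bad_maf), hwe = sum(bad_hwe),
                              ambiguous = sum(bad_amb),
                              kept = sum(keep))
  out
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

is_ambiguous <- function(a1, a2) {
  unname(COMPLEMENT[a1] == a2)
}

#' Standardize a dosage matrix
#'
#' Columns are centered and scaled to population variance 1
#' (denominator n), so \code{crossprod(x)/n} is the correlation matrix
#' and a self-regression z-score is exactly \code{sqrt(n)}.  Missing
#' dosages are mean-imputed per SNP first.
#'
#' @param geno Numeric matrix, individuals x SNPs.
#' @return The standardized matrix.
#' @export
standardize_genotypes <- function(geno) {
  if (anyNA(geno)) {
    mu <- colMeans(geno, na.rm = TRUE)
    idx <- which(is.na(geno), arr.ind = TRUE)
    geno[idx] <- mu[idx[, 2L]]
  }
  n <- nrow(geno)
  x <- scale(geno) * sqrt(n / (n - 1))
  if (any(!is.finite(x)))
    stop("monomorphic SNP cannot be standardized; run qc_panel first",
         call. = FALSE)
  x
}

# Same convention for a single vector.
standardize_vector <- function(y) {
  yc <- y - mean(y)
  s2 <- sum(yc^2) / length(y)
  if (s2 <= 0) stop("cannot standardize a constant vector",
                    call. = FALSE)
  yc / sqrt(s2)
}

#' Windowed LD scores from a reference panel
#'
#' For each SNP j, sums squared sample correlations \eqn{r_{ij}^2} over
#' all SNPs i on the same chromosome with \eqn{|bp_i - bp_j| \le}
#' \code{window_bp}, including i = j, so an isolated SNP has LD score
#' 1.  With \code{adjusted = TRUE} each \eqn{r^2} is replaced by the
#' small-sample-unbiased \eqn{r^2 - (1 - r^2)/(n_{ref} - 2)} and the
#' summed score floored at 1; use the adjusted estimator when the panel
#' is a small external reference, the unadjusted one when LD is
#' computed in-sample.
#'
#' @param panel A [genotype_panel()].
#' @param window_bp Window half-width in base pairs (default 1 Mb).
#' @param adjusted Use the bias-adjusted r-squared estimator.
#' @param chunk Number of SNPs per crossproduct block (speed knob).
#' @return A data frame (class \code{"ldscore_table"}) with columns
#'   snp_id, chrom, bp, ldscore.
#' @export
compute_ld_scores <- function(panel, window_bp = 1e6, adjusted = FALSE,
                              chunk = 512L) {
  stopifnot(inherits(panel, "genotype_panel"), window_bp >= 0)
  n <- panel$n_ref
  if (adjusted && n <= 2) stop("adjusted estimator needs n_ref > 2",
                               call. = FALSE)
  scores <- ld_score_engine(panel, window_bp, adjusted, chunk,
                            annot = NULL)
  out <- data.frame(snp_id = panel$snp$snp_id, chrom = panel$snp$chrom,
                    bp = panel$snp$bp, ldscore = scores$total,
                    stringsAsFactors = FALSE)
  class(out) <- c("ldscore_table", "data.frame")
  out
}

#' Annotation-stratified windowed LD scores
#'
#' Per-category LD score \eqn{l_{jk}} sums \eqn{r_{ij}^2} over window
#' neighbours i belonging to category k.  For a partitioning annotation
#' the per-category columns add up exactly to the total (unadjusted
#' estimator).
#'
#' @inheritParams compute_ld_scores
#' @param annot Per-SNP category: either a character vector aligned
#'   with the panel SNPs or a named vector / two-column data frame
#'   (snp_id, category) covering every panel SNP.
#' @return An \code{"ldscore_table"} data frame with the total
#'   \code{ldscore} column plus one \code{ldscore_<category>} column
#'   per category.
#' @export
compute_stratified_ld_scores <- function(panel, annot, window_bp = 1e6,
                                         adjusted = FALSE, chunk = 512L) {
  stopifnot(inherits(panel, "genotype_panel"))
  ids <- panel$snp$snp_id
  if (is.data.frame(annot)) {
    annot <- stats::setNames(as.character(annot[[2L]]),
                             as.character(annot[[1L]]))
  }
  if (!is.null(names(annot))) {
    if (!all(ids %in% names(annot)))
      stop("annotation does not cover all panel SNPs", call. = FALSE)
    annot <- unname(annot[ids])
  }
  stopifnot(length(annot) == ncol(panel$geno))
  annot <- as.character(annot)
  if (anyNA(annot))
    stop("annotation does not cover all panel SNPs (NA category)",
         call. = FALSE)
  scores <- ld_score_engine(panel, window_bp, adjusted, chunk, annot)
  out <- data.frame(snp_id = ids, chrom = panel$snp$chrom,
                    bp = panel$snp$bp, ldscore = scores$total,
                    stringsAsFactors = FALSE)
  for (k in colnames(scores$by_annot))
    out[[paste0("ldscore_", k)]] <- scores$by_annot[, k]
  class(out) <- c("ldscore_table", "data.frame")
  out
}

# Shared chunked crossproduct engine.  Positions are sorted within
# chromosome; the window is symmetric, same-chromosome, |d| <= window.
ld_score_engine <- function(panel, window_bp, adjusted, chunk, annot) {
  n <- panel$n_ref
  x <- standardize_genotypes(panel$geno)
  m <- ncol(x)
  cats <- if (!is.null(annot)) sort(unique(annot)) else NULL
  total <- numeric(m)
  by_annot <- if (!is.null(cats))
    matrix(0, m, length(cats), dimnames = list(NULL, cats))
  for (chr in unique(panel$snp$chrom)) {
    cols <- which(panel$snp$chrom == chr)
    bp <- panel$snp$bp[cols]
    lo <- findInterval(bp - window_bp, bp, left.open = TRUE) + 1L
    hi <- findInterval(bp + window_bp, bp)
    for (start in seq(1L, length(cols), by = chunk)) {
      jj <- start:min(start + chunk - 1L, length(cols))
      rows <- lo[jj[1L]]:hi[jj[length(jj)]]
      r <- crossprod(x[, cols[rows], drop = FALSE],
                     x[, cols[jj], drop = FALSE]) / n
      r2 <- r * r
      if (adjusted) r2 <- r2 - (1 - r2) / (n - 2)
      # windowed sums via cumulative sums down the neighbour axis
      cs <- matrix(apply(r2, 2L, cumsum), nrow = nrow(r2))
      pick <- function(csm) {
        top <- csm[cbind(hi[jj] - rows[1L] + 1L, seq_along(jj))]
        bot <- ifelse(lo[jj] > rows[1L],
                      csm[cbind(pmax(lo[jj] - rows[1L], 1L), seq_along(jj))],
                      0)
        top - bot
      }
      total[cols[jj]] <- pick(cs)
      if (!is.null(cats)) {
        arow <- annot[cols[rows]]
        for (k in cats) {
          mask <- as.numeric(arow == k)
          by_annot[cols[jj], k] <-
            pick(matrix(apply(r2 * mask, 2L, cumsum), nrow = nrow(r2)))
        }
      }
    }
  }
  if (adjusted) total <- pmax(total, 1)
  list(total = total, by_annot = by_annot)
}
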