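#' Merged per-SNP analysis table
#'
#' The container consumed by [gecko_fit()]: one row per SNP after
#' harmonization of the two summary-statistics sets with the LD scores,
#' sorted by (chromosome, position).  For annotation-stratified fits it
#' additionally carries the category of each SNP and the per-category
#' LD scores \eqn{l_{jk}} (sums of \eqn{r^2} restricted to window
#' neighbours in category k), which must add up to the total LD score
#' when the categories partition the SNP set.
#'
#' @param snp_id Character vector of unique SNP identifiers.
#' @param chrom Chromosome labels.
#' @param bp 1-based base-pair positions.
#' @param z1,z2 Marginal z-scores for trait 1 / trait 2.
#' @param ldscore Total LD score per SNP (>= 0; values below 1 are
#'   tolerated and clamped only in the weights, see [snp_weight()]).
#' @param annot Optional per-SNP category (character or factor).
#' @param ld_annot Optional numeric matrix (m x K) of per-category LD
#'   scores with column names naming the categories.
#'
#' @return An object of class \code{"snp_table"}: a list with the
#'   per-SNP data frame \code{snp}, per-category LD-score matrix
#'   \code{ld_annot} (or NULL), total SNP count \code{m}, category
#'   names \code{categories} and per-category counts \code{m_by_annot}.
#' @export
snp_table <- function(snp_id, chrom, bp, z1, z2, ldscore,
                      annot = NULL, ld_annot = NULL) {
  m <- length(snp_id)
  if (m < 2L) stop("need at least 2 SNPs", call. = FALSE)
  stopifnot(length(chrom) == m, length(bp) == m, length(z1) == m,
            length(z2) == m, length(ldscore) == m)
  if (anyDuplicated(snp_id)) stop("duplicated SNP ids", call. = FALSE)
  if (!all(is.finite(z1)) || !all(is.finite(z2)))
    stop("non-finite z-scores", call. = FALSE)
  if (!all(is.finite(ldscore)) || any(ldscore < 0))
    stop("LD scores must be finite and non-negative", call. = FALSE)
  snp <- data.frame(snp_id = as.character(snp_id),
                    chrom = as.character(chrom),
                    bp = as.integer(bp), z1 = as.numeric(z1),
                    z2 = as.numeric(z2), ldscore = as.numeric(ldscore),
                    stringsAsFactors = FALSE)
  ord <- order(snp$chrom, snp$bp)
  snp <- snp[ord, , drop = FALSE]
  rownames(snp) <- NULL

  categories <- "all"
  m_by_annot <- m
  if (!is.null(annot)) {
    stopifnot(length(annot) == m)
    annot <- as.character(annot)[ord]
    categories <- sort(unique(annot))
    snp$annot <- annot
    m_by_annot <- as.numeric(table(factor(annot, levels = categories)))
    if (any(m_by_annot < 2L))
      stop("every annotation category needs at least 2 SNPs",
           call. = FALSE)
  }
  if (!is.null(ld_annot)) {
    ld_annot <- as.matrix(ld_annot)[ord, , drop = FALSE]
    stopifnot(nrow(ld_annot) == m)
    if (is.null(colnames(ld_annot)))
      stop("ld_annot needs category column names", call. = FALSE)
    if (!is.null(annot)) {
      if (!setequal(colnames(ld_annot), categories))
        stop("ld_annot columns must match annotation categories",
             call. = FALSE)
      ld_annot <- ld_annot[, categories, drop = FALSE]
    } else {
      categories <- colnames(ld_annot)
    }
    if (any(ld_annot < 0)) stop("negative per-category LD score",
                                call. = FALSE)
  } else if (!is.null(annot)) {
    stop("annotated tables need per-category LD scores (ld_annot)",
         call. = FALSE)
  }
  structure(list(snp = snp, ld_annot = ld_annot, m = m,
                 categories = categories, m_by_annot = m_by_annot),
            class = "snp_table")
}

#' @export
print.snp_table <- function(x, ...) {
  cat(sprintf("snp_table: %d SNPs, %d chromosome(s)", x$m,
              length(unique(x$snp$chrom))))
  if (length(x$categories) > 1L)
    cat(sprintf(", %d annotation categories (%s)",
                length(x$categories),
                paste(x$categories, collapse = ", ")))
  cat("\n")
  print(utils::head(x$snp, 4L))
  if (x$m > 4L) cat(sprintf("... and %d more rows\n", x$m - 4L))
  invisible(x)
}

# m x K matrix of per-category LD scores (single column = total).
ld_matrix <- function(table) {
  if (is.null(table$ld_annot))
    matrix(table$snp$ldscore, ncol = 1L,
           dimnames = list(NULL, table$categories))
  else table$ld_annot
}
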