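## Statistical core: the marginal z-score model and its weighted
## composite log-likelihood.
##
## For SNP j the pair of marginal z-scores is modelled as bivariate
## normal with mean zero and covariance
##
##   Sigma_j = sum_k (l_{jk}/m_k) [[h2_1k n1, rg_k sqrt(n1 n2)],
##                                 [rg_k sqrt(n1 n2), h2_2k n2]]
##           + [[1, c], [c, 1]],     c = rho * ns / sqrt(n1 n2),
##
## and the composite log-likelihood is sum_j w_j log phi2(z_j; 0,
## Sigma_j) with w_j = 1 / max(l_j, 1).  All heavy computation runs on
## an aggregated sufficient-statistic form: SNPs (or bins of SNPs
## sharing an LD score) contribute only their weight sums and weighted
## second moments of (z1, z2), which is exact because Sigma_j depends
## on j only through the LD scores.

LOG2PI <- log(2 * base::pi)

#' Per-SNP marginal covariance of the z-score pair
#'
#' Evaluates the model covariance of \eqn{(z_{1j}, z_{2j})}: a genetic
#' term scaled by the SNP's (per-category) LD scores plus a residual
#' intercept whose off-diagonal \eqn{\rho n_s/\sqrt{n_1 n_2}} absorbs
#' phenotypic covariance among overlapping individuals.
#'
#' @param params A [cov_params()] object (K categories).
#' @param design A [study_design()] object.
#' @param record A list or one-row data frame with element
#'   \code{ldscore} (total LD score) and, for stratified parameters,
#'   \code{ldscore_by_annot} (length-K vector of per-category scores).
#' @param m_by_annot SNP count per category (scalar m when K = 1).
#' @return A 2x2 symmetric matrix (class \code{"matrix"}).
#' @examples
#' per_snp_covariance(cov_params(0.5, 0.5, 0.1, 0.2),
#'                    study_design(1000, 1000, 1000),
#'                    list(ldscore = 100), m_by_annot = 1000)
#' @export
per_snp_covariance <- function(params, design, record, m_by_annot) {
  K <- n_categories(params)
  l <- if (K == 1L) {
    if (is.null(record$ldscore)) stop("record$ldscore missing",
                                      call. = FALSE)
    record$ldscore
  } else {
    if (is.null(record$ldscore_by_annot) ||
        length(record$ldscore_by_annot) != K)
      stop("record lacks a per-category LD score for every category",
           call. = FALSE)
    as.numeric(record$ldscore_by_annot)
  }
  stopifnot(length(m_by_annot) == K, all(m_by_annot >= 1))
  s <- l / m_by_annot
  n1 <- design$n1; n2 <- design$n2
  c0 <- params$rho * design$ns / sqrt(n1 * n2)
  a <- 1 + sum(s * params$h2_1) * n1
  d <- 1 + sum(s * params$h2_2) * n2
  b <- c0 + sum(s * params$rho_g) * sqrt(n1 * n2)
  sigma <- matrix(c(a, b, b, d), 2L, 2L)
  if (a <= 0 || a * d - b * b <= 0)
    stop("inadmissible parameters: per-SNP covariance not positive definite",
         call. = FALSE)
  sigma
}

#' Composite-likelihood SNP weight
#'
#' The weight of SNP j in the composite likelihood is the reciprocal of
#' its LD score, \eqn{w_j = 1/l_j}, which down-weights SNPs whose
#' marginal likelihood duplicates information carried by neighbours in
#' LD.  An LD score is at least 1 by construction (the self term), so
#' noisy reference estimates below 1 are clamped to 1 before inverting;
#' this stops single SNPs from dominating the objective.
#'
#' @param ldscore Numeric vector of LD scores (>= 0).
#' @return Numeric vector of weights in (0, 1].
#' @examples
#' snp_weight(c(1, 5, 0.4))  # 1, 0.2, 1
#' @export
snp_weight <- function(ldscore) {
  if (any(!is.finite(ldscore))) stop("non-finite LD score", call. = FALSE)
  if (any(ldscore < 0)) stop("negative LD score", call. = FALSE)
  1 / pmax(ldscore, 1)
}

#' Weighted composite log-likelihood
#'
#' Evaluates \eqn{\sum_j w_j \log \phi_2(z_{1j}, z_{2j}; 0, \Sigma_j)}
#' over the SNP table, with \eqn{\phi_2} the bivariate normal density,
#' \eqn{\Sigma_j} from [per_snp_covariance()] and weights from
#' [snp_weight()].  When all LD scores equal 1 (independent SNPs) the
#' weights are all 1 and this is the exact joint log-likelihood.
#'
#' @param table A [snp_table()].
#' @param params A [cov_params()]; for stratified parameters the table
#'   must carry per-category LD scores.
#' @param design A [study_design()].
#' @return Scalar log-likelihood.
#' @export
composite_loglik <- function(table, params, design) {
  agg <- agg_from_table(table)
  sig <- agg_sigma(agg, params, design)
  bad <- which(sig$a <= 0 | sig$det <= 0)
  if (length(bad))
    stop(sprintf(
      "inadmissible parameters: covariance not positive definite at SNP index %d",
      bad[1L]), call. = FALSE)
  agg_loglik_sig(agg, sig)
}

## ---- internal aggregated representation -------------------------------

# Exact aggregation: one "bin" per SNP. s: m x K matrix l_jk / m_k;
# W = w_j; M** = w_j * second moments of (z1, z2).
agg_from_table <- function(table) {
  ld <- ld_matrix(table)
  w <- snp_weight(table$snp$ldscore)
  z1 <- table$snp$z1; z2 <- table$snp$z2
  structure(list(
    s = sweep(ld, 2L, table$m_by_annot, "/"),
    W = w, M11 = w * z1 * z1, M12 = w * z1 * z2, M22 = w * z2 * z2,
    m = table$m, m_by_annot = table$m_by_annot,
    categories = table$categories), class = "gecko_agg")
}

# Collapse an exact aggregate into nbins LD-score bins (single-category
# only).  Bins group SNPs with near-identical LD scores; within a bin
# Sigma_j is evaluated at the weight-averaged l, an approximation that
# vanishes as nbins grows and is validated against the exact path in
# the test suite.
agg_bin <- function(agg, nbins) {
  if (ncol(agg$s) != 1L)
    stop("LD-score binning supports single-category models only",
         call. = FALSE)
  if (nbins >= length(agg$W)) return(agg)
  l <- agg$s[, 1L]
  br <- unique(stats::quantile(l, probs = seq(0, 1, length.out = nbins + 1L)))
  idx <- findInterval(l, br, rightmost.closed = TRUE, all.inside = TRUE)
  W <- rowsum_vec(agg$W, idx)
  sw <- rowsum_vec(agg$W * l, idx) / W   # weight-averaged l/m per bin
  structure(list(
    s = matrix(sw, ncol = 1L, dimnames = list(NULL, agg$categories)),
    W = W, M11 = rowsum_vec(agg$M11, idx),
    M12 = rowsum_vec(agg$M12, idx), M22 = rowsum_vec(agg$M22, idx),
    m = agg$m, m_by_annot = agg$m_by_annot,
    categories = agg$categories), class = "gecko_agg")
}

rowsum_vec <- function(x, g) {
  out <- rowsum(x, g, reorder = TRUE)
  as.numeric(out)
}

# Sigma_j entries (a, b, d), determinant included, as bin-length vectors.
agg_sigma <- function(agg, params, design) {
  n1 <- design$n1; n2 <- design$n2
  c0 <- params$rho * design$ns / sqrt(n1 * n2)
  a <- 1 + as.numeric(agg$s %*% (params$h2_1 * n1))
  d <- 1 + as.numeric(agg$s %*% (params$h2_2 * n2))
  b <- c0 + as.numeric(agg$s %*% (params$rho_g * sqrt(n1 * n2)))
  list(a = a, b = b, d = d, det = a * d - b * b, c0 = c0)
}

agg_loglik_sig <- function(agg, sig) {
  q <- (sig$d * agg$M11 - 2 * sig$b * agg$M12 + sig$a * agg$M22) / sig$det
  sum(-agg$W * LOG2PI - 0.5 * agg$W * log(sig$det) - 0.5 * q)
}

# Objective used by the optimizers: -Inf outside the admissible set.
agg_loglik <- function(agg, params, design) {
  sig <- agg_sigma(agg, params, design)
  if (any(sig$a <= 0) || any(sig$det <= 0)) return(-Inf)
  agg_loglik_sig(agg, sig)
}

# Log-likelihood over a set of (rho_g, rho) candidates with the
# heritabilities held fixed: only the off-diagonal of Sigma varies, so
# all candidates are evaluated in one matrix pass (single category).
scan_offdiag_ll <- function(agg, params, design, rg, rho) {
  n1 <- design$n1; n2 <- design$n2; sq <- sqrt(n1 * n2)
  a <- 1 + agg$s[, 1L] * params$h2_1 * n1
  d <- 1 + agg$s[, 1L] * params$h2_2 * n2
  c0 <- rho * design$ns / sq
  B <- outer(agg$s[, 1L] * sq, rg) +
    matrix(c0, length(a), length(rg), byrow = TRUE)
  det <- a * d - B * B
  det[det <= 0] <- NA_real_
  q <- (d * agg$M11 + a * agg$M22 - 2 * B * agg$M12) / det
  out <- colSums(-agg$W * LOG2PI - 0.5 * agg$W * log(det) - 0.5 * q)
  out[is.na(out)] <- -Inf
  out
}
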