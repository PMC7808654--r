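## Simulation harness: synthetic genotypes with block LD, bivariate
## SNP effects, correlated environmental noise under the three overlap
## designs, marginal z-scores, and scenario-level calibration metrics.

#' LD structure of a synthetic genotype panel
#'
#' @param kind \code{"blocks"} (contiguous blocks of SNPs with
#'   equicorrelated latent Gaussians under a copula) or
#'   \code{"independent"}.
#' @param block_size SNPs per LD block.
#' @param within_block_corr Latent pairwise correlation inside a block,
#'   in [0, 1).
#' @param maf_range Minor-allele-frequency interval for the simulated
#'   SNPs, within (0, 0.5].
#' @param bp_spacing Base pairs between adjacent SNPs (default 10 kb,
#'   so a 1 Mb window spans 100 neighbours on each side).
#' @return A list of class \code{"ld_structure"}.
#' @export
ld_structure <- function(kind = c("blocks", "independent"),
                         block_size = 50L, within_block_corr = 0.6,
                         maf_range = c(0.05, 0.5), bp_spacing = 1e4) {
  kind <- match.arg(kind)
  stopifnot(block_size >= 1L, within_block_corr >= 0,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2], bp_spacing >= 1)
  if (within_block_corr >= 1)
    stop("within_block_corr must be < 1", call. = FALSE)
  if (kind == "independent") { block_size <- 1L; within_block_corr <- 0 }
  structure(list(kind = kind, block_size = as.integer(block_size),
                 within_block_corr = within_block_corr,
                 maf_range = maf_range, bp_spacing = bp_spacing),
            class = "ld_structure")
}

#' Simulate a genotype panel
#'
#' Draws dosages per SNP from Binomial(2, maf) through a Gaussian
#' copula whose latent variables are equicorrelated within contiguous
#' blocks, giving a block-LD pattern with an LD-score spread comparable
#' to array data.  Deterministic given \code{seed}.
#'
#' @param n Individuals.
#' @param m SNPs.
#' @param ld An [ld_structure()].
#' @param seed Integer seed (set only when non-NULL).
#' @return A [genotype_panel()] on one synthetic chromosome.
#' @export
simulate_genotypes <- function(n, m, ld = ld_structure(), seed = NULL) {
  stopifnot(n >= 2, m >= 1, inherits(ld, "ld_structure"))
  if (!is.null(seed)) set.seed(seed)
  maf <- stats::runif(m, ld$maf_range[1], ld$maf_range[2])
  r <- ld$within_block_corr
  lat <- matrix(stats::rnorm(n * m), n, m)
  if (r > 0 && ld$block_size > 1L) {
    blk <- rep(seq_len(ceiling(m / ld$block_size)),
               each = ld$block_size, length.out = m)
    shared <- matrix(stats::rnorm(n * max(blk)), n, max(blk))
    lat <- sqrt(r) * shared[, blk, drop = FALSE] + sqrt(1 - r) * lat
  }
  # Binomial(2, maf) quantile coding of the latent Gaussian: dosage
  # counts the thresholds exceeded at the (1-f)^2 and 1-f^2 quantiles.
  t1 <- stats::qnorm((1 - maf)^2)
  t2 <- stats::qnorm(1 - maf^2)
  geno <- (sweep(lat, 2L, t1, ">") + sweep(lat, 2L, t2, ">")) * 1L
  genotype_panel(geno, snp_id = sprintf("rs%06d", seq_len(m)),
                 chrom = rep("1", m),
                 bp = seq_len(m) * ld$bp_spacing)
}

# 2x2-covariance Gaussian draws, tolerating zero marginal variances.
rmvn2 <- function(n, v1, v2, cv) {
  z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
  if (v1 <= 0) {
    x1 <- numeric(n)
    x2 <- sqrt(max(v2, 0)) * z2
  } else {
    x1 <- sqrt(v1) * z1
    res <- v2 - cv^2 / v1
    x2 <- (cv / sqrt(v1)) * z1 + sqrt(max(res, 0)) * z2
  }
  cbind(x1, x2)
}

#' Simulate per-SNP effect-size pairs
#'
#' Effects for SNP j in category k are i.i.d. bivariate normal with
#' covariance \eqn{(1/m_k)} [[h2_1k, rho_gk], [rho_gk, h2_2k]], so the
#' summed genetic variance per trait equals the (per-category)
#' heritability in expectation.
#'
#' @param truth A [cov_params()] (K categories).
#' @param m Total SNP count.
#' @param m_by_annot Per-category SNP counts (defaults to m for K = 1).
#' @param annot Optional per-SNP category index (1..K) aligning SNPs
#'   with categories; defaults to contiguous groups of sizes
#'   \code{m_by_annot}.
#' @param seed Integer seed (set only when non-NULL).
#' @return An m x 2 matrix of (beta1, beta2).
#' @export
simulate_effects <- function(truth, m, m_by_annot = m, annot = NULL,
                             seed = NULL) {
  stopifnot(inherits(truth, "cov_params"))
  K <- n_categories(truth)
  stopifnot(length(m_by_annot) == K, sum(m_by_annot) == m)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(annot)) annot <- rep.int(seq_len(K), m_by_annot)
  stopifnot(length(annot) == m)
  beta <- matrix(0, m, 2L)
  for (k in seq_len(K)) {
    idx <- which(annot == k)
    beta[idx, ] <- rmvn2(length(idx), truth$h2_1[k] / m_by_annot[k],
                         truth$h2_2[k] / m_by_annot[k],
                         truth$rho_g[k] / m_by_annot[k])
  }
  beta
}

# Row indices of the two studies in a panel of N individuals: study 2
# reuses the last ns rows of study 1.
design_rows <- function(design, N) {
  need <- design$n1 + design$n2 - design$ns
  if (N < need)
    stop(sprintf("panel has %d individuals; design needs %d", N, need),
         call. = FALSE)
  list(rows1 = seq_len(design$n1),
       rows2 = seq.int(design$n1 - design$ns + 1L,
                       design$n1 - design$ns + design$n2))
}

#' Simulate the two phenotypes
#'
#' Builds \eqn{y_d = X_d \beta_d + \epsilon_d} on standardized
#' genotypes: individuals measured for both traits get residual pairs
#' with covariance [[1 - h2_1, rho_e], [rho_e, 1 - h2_2]], everyone
#' else independent normals with the marginal variances.  Both
#' phenotypes are centered and standardized before return, matching
#' how z-scores are defined.
#'
#' @param x Standardized genotype matrix (individuals x SNPs) covering
#'   \code{n1 + n2 - ns} rows; study 1 takes the first \code{n1} rows
#'   and study 2 the last \code{n2} (so the shared \code{ns} rows are
#'   the overlap).
#' @param effects m x 2 effect matrix from [simulate_effects()].
#' @param truth A [cov_params()]; the environmental covariance is
#'   \code{truth$rho - sum(truth$rho_g)}.
#' @param design A [study_design()].
#' @param seed Integer seed (set only when non-NULL).
#' @return A list with standardized vectors \code{y1}, \code{y2} and
#'   the study row indices \code{rows1}, \code{rows2}.
#' @export
simulate_phenotypes <- function(x, effects, truth, design, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rw <- design_rows(design, nrow(x))
  h1 <- sum(truth$h2_1); h2 <- sum(truth$h2_2)
  rho_e <- truth$rho - sum(truth$rho_g)
  if (design$ns == 0 && rho_e != 0)
    warning("rho_e has no effect with ns = 0 (disjoint samples)")
  g1 <- drop(x[rw$rows1, , drop = FALSE] %*% effects[, 1L])
  g2 <- drop(x[rw$rows2, , drop = FALSE] %*% effects[, 2L])
  eps <- sim_residuals(design, h1, h2, rho_e)
  list(y1 = standardize_vector(g1 + eps$e1),
       y2 = standardize_vector(g2 + eps$e2),
       rows1 = rw$rows1, rows2 = rw$rows2)
}

# Residual vectors with the overlap block correlated.
sim_residuals <- function(design, h1, h2, rho_e) {
  n1 <- design$n1; n2 <- design$n2; ns <- design$ns
  e1 <- stats::rnorm(n1, sd = sqrt(max(1 - h1, 0)))
  e2 <- stats::rnorm(n2, sd = sqrt(max(1 - h2, 0)))
  if (ns > 0) {
    sh <- rmvn2(ns, 1 - h1, 1 - h2, rho_e)
    e1[seq.int(n1 - ns + 1L, n1)] <- sh[, 1L]
    e2[seq_len(ns)] <- sh[, 2L]
  }
  list(e1 = e1, e2 = e2)
}

#' Marginal z-scores from standardized data
#'
#' \eqn{z_j = x_j^\top y / \sqrt{n}} for each standardized genotype
#' column, i.e. the score statistic of the per-SNP univariate
#' regression.
#'
#' @param x Standardized genotype matrix (n x m).
#' @param y Standardized phenotype vector (length n).
#' @return Numeric vector of m z-scores.
#' @export
compute_zscores <- function(x, y) {
  n <- length(y)
  stopifnot(nrow(x) == n)
  if (abs(mean(y)) > 1e-8 || abs(sum(y^2) / n - 1) > 1e-6)
    stop("phenotype must be centered and standardized", call. = FALSE)
  cm <- colMeans(x)
  if (max(abs(cm)) > 1e-8)
    stop("genotype columns must be centered and standardized",
         call. = FALSE)
  drop(crossprod(x, y)) / sqrt(n)
}

#' One end-to-end simulation replicate
#'
#' Simulates effects and phenotypes on a fixed panel and returns the
#' pair of marginal z-score vectors.
#'
#' @param x Standardized genotype matrix covering the design (see
#'   [simulate_phenotypes()]).
#' @param truth A [cov_params()].
#' @param design A [study_design()].
#' @param m_by_annot,annot Passed to [simulate_effects()].
#' @param seed Integer seed (set only when non-NULL).
#' @return List with \code{z1}, \code{z2}, \code{effects}.
#' @export
simulate_study <- function(x, truth, design, m_by_annot = ncol(x),
                           annot = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  beta <- simulate_effects(truth, ncol(x), m_by_annot, annot)
  ph <- simulate_phenotypes(x, beta, truth, design)
  list(z1 = compute_zscores(x[ph$rows1, , drop = FALSE], ph$y1),
       z2 = compute_zscores(x[ph$rows2, , drop = FALSE], ph$y2),
       effects = beta)
}
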