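## Maximization of the weighted composite log-likelihood.
##
## EM treats each SNP's z-score pair as z_j = g_j + r_j with latent
## genetic part g_j ~ N(0, sum_k s_jk G_k), s_jk = l_jk/m_k,
## G_k = [[h2_1k n1, rg_k sqrt(n1 n2)], [., h2_2k n2]], and residual
## r_j ~ N(0, [[1, c], [c, 1]]), c = rho ns / sqrt(n1 n2).  The E-step
## needs only weighted second moments of z per LD-score bin; the
## M-step for each G_k is the closed-form weighted Gaussian update and
## is exact, so the objective cannot decrease.  The residual update
## keeps the unit diagonal fixed and refreshes only c; the simple
## weighted-moment update is used first and, if it ever fails to
## improve the objective, c is re-solved by a guarded 1-d line search,
## keeping the whole sweep monotone.

#' Fitting options
#'
#' @param max_em_iter Maximum EM sweeps.
#' @param em_tol Convergence threshold on the relative change of the
#'   weighted composite log-likelihood between EM sweeps.
#' @param max_nr_iter Maximum Newton-Raphson polish iterations
#'   (0 disables the polish).
#' @param nr_tol Supremum-norm gradient threshold for the polish.
#' @param init Initial parameters: \code{"auto"} (weighted-moment
#'   start, deterministic) or a [cov_params()] object.
#' @param constrain Project parameters back into the admissible region
#'   after every M-step (heritabilities in \code{[0, h_max]},
#'   per-category \code{|rho_g| <= sqrt(h2_1 h2_2)}, residual
#'   correlation \code{|c| <= c_max}).
#' @param seed Integer seed, used only if randomized restarts are ever
#'   requested; the default fit is deterministic.
#' @param h_max Soft upper bound for heritabilities; estimates may
#'   exceed 1 by sampling noise, so the default leaves 0.25 slack.
#' @param c_max Bound keeping the residual matrix positive definite.
#' @param agg_bins Number of LD-score bins for the aggregated
#'   likelihood (single-category models only).  \code{Inf} means exact
#'   per-SNP evaluation; a few hundred bins give estimates
#'   indistinguishable from exact at a fraction of the cost and are
#'   used by the jackknife and the simulation harness.
#' @return A list of class \code{"fit_options"}.
#' @export
fit_options <- function(max_em_iter = 1000L, em_tol = 1e-6,
                        max_nr_iter = 50L, nr_tol = 1e-6,
                        init = "auto", constrain = TRUE, seed = NULL,
                        h_max = 1.25, c_max = 0.999, agg_bins = Inf) {
  stopifnot(em_tol > 0, nr_tol > 0, max_em_iter >= 1, max_nr_iter >= 0,
            h_max > 0, c_max > 0, c_max < 1, agg_bins >= 2)
  structure(list(max_em_iter = as.integer(max_em_iter), em_tol = em_tol,
                 max_nr_iter = as.integer(max_nr_iter), nr_tol = nr_tol,
                 init = init, constrain = isTRUE(constrain), seed = seed,
                 h_max = h_max, c_max = c_max, agg_bins = agg_bins),
            class = "fit_options")
}

## ---- parameter bookkeeping -------------------------------------------

# Project onto the admissible region; returns params + active flags.
project_params <- function(params, design, h_max = 1.25, c_max = 0.999) {
  flags <- character(0)
  h1 <- pmin(pmax(params$h2_1, 0), h_max)
  h2 <- pmin(pmax(params$h2_2, 0), h_max)
  if (any(h1 != params$h2_1) || any(h2 != params$h2_2))
    flags <- c(flags, "h2")
  bound <- sqrt(h1 * h2)
  rg <- pmin(pmax(params$rho_g, -bound), bound)
  if (any(rg != params$rho_g)) flags <- c(flags, "rho_g")
  rho <- params$rho
  if (design$ns > 0) {
    cmax_rho <- c_max * sqrt(design$n1 * design$n2) / design$ns
    if (abs(rho) > cmax_rho) {
      rho <- sign(rho) * cmax_rho
      flags <- c(flags, "rho")
    }
  } else {
    rho <- sum(rg)  # structural tie: c = 0, rho_e unidentified
  }
  list(params = cov_params(h1, h2, rg, rho, params$categories),
       flags = unique(flags))
}

# Free-parameter vector: (h2_1, h2_2, rho_g) per category, plus rho
# when ns > 0 (with ns = 0 rho is tied to sum(rho_g)).
pack_params <- function(params, design) {
  th <- c(params$h2_1, params$h2_2, params$rho_g)
  if (design$ns > 0) th <- c(th, params$rho)
  th
}

unpack_params <- function(theta, design, categories) {
  K <- length(categories)
  h1 <- theta[seq_len(K)]
  h2 <- theta[K + seq_len(K)]
  rg <- theta[2L * K + seq_len(K)]
  rho <- if (design$ns > 0) theta[3L * K + 1L] else sum(rg)
  new_cov_params(h1, h2, rg, rho, categories)
}

# Deterministic weighted-moment initialization in the interior.
init_params_auto <- function(agg, design) {
  K <- length(agg$categories)
  Wtot <- sum(agg$W)
  ssum <- as.numeric(agg$s %*% rep(1, K))
  Ws <- sum(agg$W * ssum)
  h1 <- (sum(agg$M11) - Wtot) / (design$n1 * Ws)
  h2 <- (sum(agg$M22) - Wtot) / (design$n2 * Ws)
  h1 <- min(max(h1, 1e-3), 1); h2 <- min(max(h2, 1e-3), 1)
  frac <- agg$m_by_annot / agg$m
  rho <- 0
  if (design$ns > 0) {
    rho <- (sum(agg$M12) / Wtot) * sqrt(design$n1 * design$n2) / design$ns
    cmax <- 0.9 * sqrt(design$n1 * design$n2) / design$ns
    rho <- min(max(rho, -cmax), cmax)
  }
  cov_params(h1 * frac, h2 * frac, rep(0, K), rho, agg$categories)
}

## ---- EM ---------------------------------------------------------------

# One EM sweep on the aggregated data.  Returns updated (projected)
# parameters; guarded so the objective never decreases (up to a hard
# fixed-point stall, reported via attribute "stalled").
em_step_agg <- function(agg, design, params, h_max = 1.25,
                        c_max = 0.999, constrain = TRUE) {
  n1 <- design$n1; n2 <- design$n2; sq <- sqrt(n1 * n2)
  sig <- agg_sigma(agg, params, design)
  if (any(sig$a <= 0) || any(sig$det <= 0))
    stop("em_step: inadmissible starting parameters", call. = FALSE)
  ll0 <- agg_loglik_sig(agg, sig)
  i11 <- sig$d / sig$det; i22 <- sig$a / sig$det; i12 <- -sig$b / sig$det
  W <- agg$W; M11 <- agg$M11; M12 <- agg$M12; M22 <- agg$M22
  K <- length(agg$categories)

  h1n <- numeric(K); h2n <- numeric(K); rgn <- numeric(K)
  for (k in seq_len(K)) {
    sk <- agg$s[, k]
    G11 <- params$h2_1[k] * n1; G22 <- params$h2_2[k] * n2
    G12 <- params$rho_g[k] * sq
    A11 <- sk * (G11 * i11 + G12 * i12)
    A12 <- sk * (G11 * i12 + G12 * i22)
    A21 <- sk * (G12 * i11 + G22 * i12)
    A22 <- sk * (G12 * i12 + G22 * i22)
    V11 <- sk * G11 - (A11 * sk * G11 + A12 * sk * G12)
    V12 <- sk * G12 - (A11 * sk * G12 + A12 * sk * G22)
    V22 <- sk * G22 - (A21 * sk * G12 + A22 * sk * G22)
    T11 <- W * V11 + A11 * A11 * M11 + 2 * A11 * A12 * M12 + A12 * A12 * M22
    T12 <- W * V12 + A11 * A21 * M11 + (A11 * A22 + A12 * A21) * M12 +
      A12 * A22 * M22
    T22 <- W * V22 + A21 * A21 * M11 + 2 * A21 * A22 * M12 + A22 * A22 * M22
    pos <- sk > 0
    Dk <- sum(W[pos])
    h1n[k] <- sum(T11[pos] / sk[pos]) / Dk / n1
    h2n[k] <- sum(T22[pos] / sk[pos]) / Dk / n2
    rgn[k] <- sum(T12[pos] / sk[pos]) / Dk / sq
  }

  rho_new <- sum(rgn)
  if (design$ns > 0) {
    # residual moment update for c with the unit diagonal held fixed
    Mt11 <- sig$a - 1; Mt22 <- sig$d - 1; Mt12 <- sig$b - sig$c0
    B11 <- Mt11 * i11 + Mt12 * i12; B12 <- Mt11 * i12 + Mt12 * i22
    B21 <- Mt12 * i11 + Mt22 * i12; B22 <- Mt12 * i12 + Mt22 * i22
    Vt12 <- Mt12 - (B11 * Mt12 + B12 * Mt22)
    Sg12 <- W * Vt12 + B11 * B21 * M11 + (B11 * B22 + B12 * B21) * M12 +
      B12 * B22 * M22
    Err12 <- M12 - (B11 * M12 + B12 * M22) - (B21 * M11 + B22 * M12) + Sg12
    c_new <- sum(Err12) / sum(W)
    rho_new <- c_new * sq / design$ns
  }

  cand <- cov_params(h1n, h2n, rgn, rho_new, agg$categories)
  if (constrain)
    cand <- project_params(cand, design, h_max, c_max)$params

  ll1 <- agg_loglik(agg, cand, design)
  if (ll1 >= ll0) return(cand)

  # moment c-update (or projection) overshot: re-solve c by line search
  if (design$ns > 0) {
    cmax <- c_max * sq / design$ns
    hold <- cand
    opt <- stats::optimize(function(r) {
      hold$rho <- r
      agg_loglik(agg, hold, design)
    }, interval = c(-cmax, cmax), maximum = TRUE, tol = 1e-10)
    if (opt$objective >= ll1) {
      cand$rho <- opt$maximum
      ll1 <- opt$objective
    }
    if (ll1 >= ll0) return(cand)
  }
  # last resort: step-halve toward the current parameters
  th0 <- pack_params(params, design); th1 <- pack_params(cand, design)
  for (i in seq_len(25L)) {
    th1 <- (th0 + th1) / 2
    cand <- unpack_params(th1, design, agg$categories)
    if (agg_loglik(agg, cand, design) >= ll0) return(cand)
  }
  structure(params, stalled = TRUE)
}

#' One EM update of the covariance parameters
#'
#' Runs a single expectation-maximization sweep of the weighted
#' composite likelihood: the E-step computes weighted conditional
#' second moments of the latent genetic and residual components of
#' each z-score pair, the M-step refreshes the per-category genetic
#' covariance matrices in closed form and the residual cross term with
#' the unit diagonal held fixed.  The weighted objective never
#' decreases.
#'
#' @param table A [snp_table()].
#' @param design A [study_design()].
#' @param params Current [cov_params()] (must be admissible).
#' @return Updated [cov_params()].
#' @export
em_step <- function(table, design, params) {
  em_step_agg(agg_from_table(table), design, params)
}

## ---- Newton-Raphson polish -------------------------------------------

# Damped Newton ascent on the free-parameter vector using the
# analytic gradient and Hessian (see score.R); falls back to gradient
# ascent when the Hessian is not negative definite.  Steps are
# accepted only if the objective does not decrease.
nr_polish_agg <- function(agg, design, params, options) {
  f <- function(th) agg_loglik(agg, unpack_params(th, design,
                                                  agg$categories), design)
  th <- pack_params(params, design)
  ll <- f(th)
  iters <- 0L
  gnorm <- Inf
  for (it in seq_len(options$max_nr_iter)) {
    iters <- it
    sc <- agg_score(agg, unpack_params(th, design, agg$categories),
                    design)
    if (is.null(sc) || !all(is.finite(sc$grad))) break
    g <- sc$grad
    gnorm <- max(abs(g))
    if (gnorm <= options$nr_tol) break
    dir <- NULL
    ev <- tryCatch(eigen(sc$hess, symmetric = TRUE,
                         only.values = TRUE)$values,
                   error = function(e) NA)
    if (all(is.finite(ev)) && max(ev) < 0)
      dir <- tryCatch(drop(solve(sc$hess, -g)), error = function(e) NULL)
    if (is.null(dir)) dir <- g / gnorm  # indefinite: gradient ascent
    lam <- 1; improved <- FALSE
    while (lam > 1e-10) {
      cand <- th + lam * dir
      llc <- f(cand)
      if (is.finite(llc) && llc > ll) {
        th <- cand; ll <- llc; improved <- TRUE; break
      }
      lam <- lam / 2
    }
    if (!improved) break
  }
  out <- unpack_params(th, design, agg$categories)
  if (options$constrain)
    out <- project_params(out, design, options$h_max, options$c_max)$params
  structure(out, nr_iter = iters, grad_norm = gnorm)
}

#' Newton-Raphson refinement of near-optimal parameters
#'
#' Polishes an EM solution with damped Newton steps on the weighted
#' composite log-likelihood (finite-difference derivatives); each step
#' is accepted only if the objective does not decrease, with a
#' gradient-ascent fallback when the Hessian is indefinite.
#'
#' @inheritParams em_step
#' @param options A [fit_options()] object.
#' @return Refined [cov_params()].
#' @export
nr_polish <- function(table, design, params, options = fit_options()) {
  nr_polish_agg(agg_from_table(table), design, params, options)
}

## ---- top-level fit ----------------------------------------------------

gecko_fit_agg <- function(agg, design, options) {
  if (all(agg$M11 == 0) && all(agg$M22 == 0))
    stop("degenerate input: all z-scores are zero", call. = FALSE)
  K <- length(agg$categories)
  if (length(agg$W) < 3L * K + (design$ns > 0))
    stop("fewer SNPs than free parameters", call. = FALSE)
  if (is.finite(options$agg_bins) && K == 1L)
    agg <- agg_bin(agg, as.integer(options$agg_bins))

  params <- if (identical(options$init, "auto"))
    init_params_auto(agg, design)
  else {
    stopifnot(inherits(options$init, "cov_params"))
    init <- options$init
    if (design$ns == 0) init$rho <- sum(init$rho_g)
    project_params(init, design, options$h_max, options$c_max)$params
  }

  ll <- agg_loglik(agg, params, design)
  if (!is.finite(ll))
    stop("initial parameters inadmissible", call. = FALSE)
  trace <- ll
  converged <- FALSE
  em_iter <- 0L
  for (it in seq_len(options$max_em_iter)) {
    em_iter <- it
    new <- em_step_agg(agg, design, params, options$h_max, options$c_max,
                       options$constrain)
    stalled <- isTRUE(attr(new, "stalled"))
    params <- new
    ll_new <- agg_loglik(agg, params, design)
    trace <- c(trace, ll_new)
    if (stalled || abs(ll_new - ll) <= options$em_tol * (abs(ll) + 1)) {
      converged <- TRUE
      ll <- ll_new
      break
    }
    ll <- ll_new
  }

  nr_iter <- 0L
  if (options$max_nr_iter > 0L) {
    polished <- nr_polish_agg(agg, design, params, options)
    nr_iter <- attr(polished, "nr_iter")
    ll_pol <- agg_loglik(agg, polished, design)
    if (is.finite(ll_pol) && ll_pol >= ll) {  # keep the larger objective
      params <- polished
      ll <- ll_pol
    }
  }

  # The likelihood is nearly flat jointly in (rho_g, rho) and can
  # carry shallow side modes at small m.  A coarse scan of that plane
  # (holding the heritabilities, on binned statistics for speed)
  # followed by an exact re-polish rescues fits stranded in the wrong
  # mode; at realistic SNP counts the scan almost never fires.
  if (options$max_nr_iter > 0L && K == 1L) {
    scan_agg <- if (length(agg$W) > 400L) agg_bin(agg, 400L) else agg
    for (round in 1:2) {
      bnd <- sqrt(max(params$h2_1 * params$h2_2, 1e-6))
      rg_grid <- seq(-bnd, bnd, length.out = 41L)
      if (design$ns > 0) {
        cmax <- options$c_max * sqrt(design$n1 * design$n2) / design$ns
        rho_grid <- seq(-cmax, cmax, length.out = 101L)
        combos <- expand.grid(rg = rg_grid, rho = rho_grid)
      } else {
        combos <- data.frame(rg = rg_grid, rho = rg_grid)
      }
      scan_ll <- scan_offdiag_ll(scan_agg, params, design,
                                 combos$rg, combos$rho)
      cur <- agg_loglik(scan_agg, params, design)
      best <- which.max(scan_ll)
      if (!is.finite(scan_ll[best]) || scan_ll[best] <= cur + 1e-10)
        break
      cand <- params
      cand$rho_g <- combos$rg[best]; cand$rho <- combos$rho[best]
      ll_cand <- agg_loglik(agg, cand, design)
      repol <- nr_polish_agg(agg, design, cand, options)
      ll_rep <- agg_loglik(agg, repol, design)
      moved <- FALSE
      if (is.finite(ll_rep) && ll_rep > max(ll, ll_cand)) {
        params <- repol; ll <- ll_rep; moved <- TRUE
      } else if (is.finite(ll_cand) && ll_cand > ll) {
        params <- cand; ll <- ll_cand; moved <- TRUE
      }
      if (!moved) break
    }
  }

  proj <- project_params(params, design, options$h_max, options$c_max)
  boundary <- proj$flags
  # flags for estimates sitting on a constraint boundary
  eps <- 1e-8
  if (any(params$h2_1 <= eps) || any(params$h2_2 <= eps) ||
      any(params$h2_1 >= options$h_max - eps) ||
      any(params$h2_2 >= options$h_max - eps))
    boundary <- unique(c(boundary, "h2"))
  if (any(abs(abs(params$rho_g) -
              sqrt(params$h2_1 * params$h2_2)) <= eps))
    boundary <- unique(c(boundary, "rho_g"))

  structure(list(params = params,
                 derived = derived_quantities(params, design),
                 loglik = ll, n_iter = c(em = em_iter, nr = nr_iter),
                 converged = converged, boundary_flags = boundary,
                 em_trace = trace, design = design, options = options,
                 categories = agg$categories),
            class = "gecko_fit")
}

#' Fit the bivariate covariance model to a SNP table
#'
#' Maximizes the weighted composite log-likelihood over
#' (per-category) heritabilities, genetic covariances and the total
#' phenotypic covariance \eqn{\rho}, by EM with a Newton-Raphson
#' polish.  With \code{ns = 0} the residual cross term is structurally
#' zero, so \eqn{\rho} is tied to \eqn{\rho_g} and the environmental
#' covariance is not estimated.  The fit is deterministic given its
#' inputs.
#'
#' @param table A [snp_table()]; stratified fits require per-category
#'   LD scores (see [fit_stratified()]).
#' @param design A [study_design()].
#' @param options A [fit_options()] object.
#' @return A list of class \code{"gecko_fit"} with elements
#'   \code{params} ([cov_params()] at the optimum), \code{derived}
#'   (rho_e, gamma_g, gamma_e), \code{loglik}, \code{n_iter},
#'   \code{converged}, \code{boundary_flags}, and the per-sweep
#'   objective \code{em_trace}.
#' @seealso [block_jackknife()] for standard errors,
#'   [gecko_analyze()] for the full pipeline.
#' @export
gecko_fit <- function(table, design, options = fit_options()) {
  stopifnot(inherits(table, "snp_table"), inherits(design, "study_design"))
  gecko_fit_agg(agg_from_table(table), design, options)
}

#' Annotation-stratified fit
#'
#' Fits one genetic covariance component per annotation category (the
#' categories must partition the SNP set and per-category LD scores
#' must be present), reporting per-category estimates alongside their
#' totals.  A single-category table reduces exactly to [gecko_fit()].
#'
#' @inheritParams gecko_fit
#' @return A \code{"gecko_fit"} object with per-category parameters.
#' @export
fit_stratified <- function(table, design, options = fit_options()) {
  if (is.null(table$ld_annot))
    stop("stratified fit needs per-category LD scores in the table",
         call. = FALSE)
  gecko_fit(table, design, options)
}

#' @export
print.gecko_fit <- function(x, ...) {
  cat(sprintf("composite-likelihood fit: loglik = %.4f, %d EM + %d NR iterations%s\n",
              x$loglik, x$n_iter[["em"]], x$n_iter[["nr"]],
              if (x$converged) "" else " (NOT converged)"))
  print(x$params)
  d <- x$derived
  if (d$identifiable)
    cat(sprintf("derived: rho_e = %.4g, gamma_g = %.4g, gamma_e = %.4g\n",
                d$rho_e, d$gamma_g, d$gamma_e))
  else
    cat(sprintf("derived: gamma_g = %.4g; rho_e/gamma_e not identifiable (ns = 0)\n",
                d$gamma_g))
  if (length(x$boundary_flags))
    cat("boundary flags:", paste(x$boundary_flags, collapse = ", "), "\n")
  invisible(x)
}
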