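## Scenario-level calibration harness: replicate loops, bias/MSE/type-I
## metrics with Monte-Carlo standard errors, and the named simulation
## presets (truth grids at reduced default scale).

#' The three canonical study designs
#'
#' Sample compositions used throughout the calibration studies: one
#' study measuring both traits on 2,938 individuals; two separate
#' studies of 1,500 and 1,438; or two studies of 2,000 and 1,938
#' sharing 1,000 individuals.
#'
#' @param name One of \code{"one_study"}, \code{"two_study"},
#'   \code{"overlap"}.
#' @return A [study_design()].
#' @export
design_preset <- function(name = c("one_study", "two_study", "overlap")) {
  switch(match.arg(name),
         one_study = study_design(2938, 2938, 2938),
         two_study = study_design(1500, 1438, 0),
         overlap = study_design(2000, 1938, 1000))
}

#' Simulation scenario specification
#'
#' @param design A [study_design()].
#' @param truth True [cov_params()] (per-category for stratified
#'   scenarios; \code{truth$rho - sum(truth$rho_g)} is the
#'   environmental covariance).
#' @param ld An [ld_structure()].
#' @param m SNP count.
#' @param reps Replicates.
#' @param seed Integer seed; the panel, every replicate and any
#'   reference panel derive their streams from it, so scenarios
#'   sharing a seed (and m, design, truth shape) see identical data —
#'   which is what makes misspecification comparisons paired.
#' @param misspec Optional list: \code{ld_mismatch = TRUE} computes
#'   the LD scores used for fitting from an independently simulated
#'   reference panel; \code{ns_override = k} fits with a wrong overlap
#'   count while simulating under the true one.
#' @param annot_frac For stratified scenarios, per-category SNP
#'   fractions (summing to 1); categories are assigned to whole LD
#'   blocks so per-category LD scores are non-trivial.
#' @param window_bp LD-score window (base pairs).
#' @param do_jackknife Compute jackknife SEs and Wald p-values per
#'   replicate (needed for type-I-error/power metrics).
#' @param n_blocks Jackknife block count.
#' @param agg_bins LD-score bins for the fast fit path (see
#'   [fit_options()]).
#' @return A list of class \code{"scenario_spec"}.
#' @export
scenario_spec <- function(design, truth, ld = ld_structure(),
                          m = 20000L, reps = 100L, seed = 1L,
                          misspec = list(), annot_frac = NULL,
                          window_bp = 1e6, do_jackknife = TRUE,
                          n_blocks = 200L, agg_bins = 400L) {
  stopifnot(inherits(design, "study_design"),
            inherits(truth, "cov_params"), reps >= 1, m >= 10)
  K <- n_categories(truth)
  if (K > 1L) {
    if (is.null(annot_frac) || length(annot_frac) != K ||
        abs(sum(annot_frac) - 1) > 1e-8)
      stop("stratified scenarios need annot_frac summing to 1",
           call. = FALSE)
  }
  structure(list(design = design, truth = truth, ld = ld,
                 m = as.integer(m), reps = as.integer(reps),
                 seed = as.integer(seed), misspec = misspec,
                 annot_frac = annot_frac, window_bp = window_bp,
                 do_jackknife = isTRUE(do_jackknife),
                 n_blocks = as.integer(n_blocks), agg_bins = agg_bins),
            class = "scenario_spec")
}

# Batched effect + phenotype + z-score simulation for all replicates
# of a single-category scenario (one large BLAS product instead of a
# per-replicate loop).  Returns m x reps z matrices for both traits.
simulate_zscores_batch <- function(x, truth, design, reps) {
  m <- ncol(x)
  h1 <- sum(truth$h2_1); h2 <- sum(truth$h2_2)
  rg <- sum(truth$rho_g); rho_e <- truth$rho - rg
  u1 <- matrix(stats::rnorm(m * reps), m, reps)
  u2 <- matrix(stats::rnorm(m * reps), m, reps)
  if (h1 > 0) {
    B1 <- sqrt(h1 / m) * u1
    B2 <- (rg / m) / sqrt(h1 / m) * u1 +
      sqrt(max(h2 - rg^2 / h1, 0) / m) * u2
  } else {
    B1 <- 0 * u1
    B2 <- sqrt(h2 / m) * u2
  }
  rw <- design_rows(design, nrow(x))
  n1 <- design$n1; n2 <- design$n2; ns <- design$ns
  E1 <- matrix(stats::rnorm(n1 * reps, sd = sqrt(max(1 - h1, 0))), n1, reps)
  E2 <- matrix(stats::rnorm(n2 * reps, sd = sqrt(max(1 - h2, 0))), n2, reps)
  if (ns > 0) {
    za <- matrix(stats::rnorm(ns * reps), ns, reps)
    zb <- matrix(stats::rnorm(ns * reps), ns, reps)
    v1 <- max(1 - h1, 0); v2 <- max(1 - h2, 0)
    if (v1 > 0) {
      ea <- sqrt(v1) * za
      eb <- (rho_e / sqrt(v1)) * za + sqrt(max(v2 - rho_e^2 / v1, 0)) * zb
    } else {
      ea <- 0 * za; eb <- sqrt(v2) * zb
    }
    E1[seq.int(n1 - ns + 1L, n1), ] <- ea
    E2[seq_len(ns), ] <- eb
  }
  Y1 <- scale(x[rw$rows1, , drop = FALSE] %*% B1 + E1) *
    sqrt(n1 / (n1 - 1))
  Y2 <- scale(x[rw$rows2, , drop = FALSE] %*% B2 + E2) *
    sqrt(n2 / (n2 - 1))
  list(Z1 = crossprod(x[rw$rows1, , drop = FALSE], Y1) / sqrt(n1),
       Z2 = crossprod(x[rw$rows2, , drop = FALSE], Y2) / sqrt(n2))
}

# Minimal exact aggregate straight from vectors (harness fast path).
agg_make <- function(l, z1, z2, m, s_annot = NULL, m_by_annot = m,
                     categories = "all") {
  w <- snp_weight(l)
  s <- if (is.null(s_annot))
    matrix(l / m, ncol = 1L, dimnames = list(NULL, categories))
  else s_annot
  structure(list(s = s, W = w, M11 = w * z1 * z1, M12 = w * z1 * z2,
                 M22 = w * z2 * z2, m = m, m_by_annot = m_by_annot,
                 categories = categories), class = "gecko_agg")
}

# Single-entry cache of the scenario panel (standardized matrix and
# in-sample LD scores).  Panels are deterministic given (N, m, LD
# structure, seed), so scenarios sharing those — e.g. the three study
# designs drawn from one pool of individuals — reuse one panel, as a
# fixed-panel calibration study should.
.panel_cache <- new.env(parent = emptyenv())

scenario_panel <- function(N, m, ld, seed, window_bp) {
  key <- paste(N, m, ld$kind, ld$block_size, ld$within_block_corr,
               paste(ld$maf_range, collapse = "_"), ld$bp_spacing,
               seed, sep = ":")
  if (!identical(.panel_cache$key, key)) {
    set.seed(seed)
    panel <- simulate_genotypes(N, m, ld)
    .panel_cache$key <- key
    .panel_cache$panel <- panel
    .panel_cache$x <- standardize_genotypes(panel$geno)
    .panel_cache$ld_by_window <- list()
  }
  wkey <- sprintf("w%g", window_bp)
  if (is.null(.panel_cache$ld_by_window[[wkey]]))
    .panel_cache$ld_by_window[[wkey]] <-
      compute_ld_scores(.panel_cache$panel, window_bp = window_bp)
  list(panel = .panel_cache$panel, x = .panel_cache$x,
       ld = .panel_cache$ld_by_window[[wkey]])
}

#' Run a simulation scenario
#'
#' Simulates a fixed genotype panel, computes in-sample (or, under LD
#' mismatch, reference-panel) LD scores once, then per replicate
#' simulates summary statistics, fits the model and (optionally)
#' computes jackknife Wald p-values.  Returns per-replicate estimates
#' plus aggregated metrics with Monte-Carlo standard errors.
#'
#' @param spec A [scenario_spec()].
#' @param options [fit_options()] template for the fits (the
#'   scenario's \code{agg_bins} is applied on top).
#' @return A list of class \code{"gecko_scenario"}: \code{estimates}
#'   (one row per converged replicate), \code{metrics} (see
#'   [scenario_metrics()]), \code{n_fail}, \code{flagged} (more than
#'   5\% failed replicates), and the panel LD-score summary.
#' @export
run_scenario <- function(spec, options = fit_options()) {
  stopifnot(inherits(spec, "scenario_spec"))
  design <- spec$design
  N <- design$n1 + design$n2 - design$ns
  K <- n_categories(spec$truth)
  pd <- scenario_panel(N, spec$m, spec$ld, spec$seed, spec$window_bp)
  panel <- pd$panel
  x <- pd$x

  annot <- NULL
  m_by_annot <- spec$m
  if (K > 1L) {
    set.seed(spec$seed + 2L)
    nb <- ceiling(spec$m / spec$ld$block_size)
    blk_cat <- sample.int(K, nb, replace = TRUE, prob = spec$annot_frac)
    annot <- rep(blk_cat, each = spec$ld$block_size)[seq_len(spec$m)]
    m_by_annot <- tabulate(annot, nbins = K)
  }

  # LD scores for fitting: in-sample, or from an independent reference
  # panel under LD mismatch (weights and model LD scores both follow).
  ld_panel <- panel
  if (isTRUE(spec$misspec$ld_mismatch)) {
    set.seed(spec$seed + 999983L)
    ld_panel <- simulate_genotypes(N, spec$m, spec$ld)
  }
  if (K > 1L) {
    lt <- compute_stratified_ld_scores(
      ld_panel, stats::setNames(spec$truth$categories[annot],
                                ld_panel$snp$snp_id),
      window_bp = spec$window_bp)
    l_tot <- lt$ldscore
    s_annot <- sweep(as.matrix(lt[, paste0("ldscore_",
                                           spec$truth$categories)]),
                     2L, m_by_annot, "/")
    colnames(s_annot) <- spec$truth$categories
  } else if (isTRUE(spec$misspec$ld_mismatch)) {
    l_tot <- compute_ld_scores(ld_panel,
                               window_bp = spec$window_bp)$ldscore
    s_annot <- NULL
  } else {
    l_tot <- pd$ld$ldscore
    s_annot <- NULL
  }

  fit_design <- design
  if (!is.null(spec$misspec$ns_override))
    fit_design <- study_design(design$n1, design$n2,
                               spec$misspec$ns_override)
  opts <- options
  if (K == 1L) opts$agg_bins <- spec$agg_bins
  jk <- jackknife_spec(n_blocks = spec$n_blocks)
  blocks <- block_ids(spec$m, spec$n_blocks)

  # replicate data (batched for the single-category path)
  set.seed(spec$seed + 1L)
  if (K == 1L) {
    zz <- simulate_zscores_batch(x, spec$truth, design, spec$reps)
  }

  rows <- vector("list", spec$reps)
  n_fail <- 0L
  for (r in seq_len(spec$reps)) {
    if (K == 1L) {
      z1 <- zz$Z1[, r]; z2 <- zz$Z2[, r]
    } else {
      set.seed(spec$seed + 1000L + r)
      sim <- simulate_study(x, spec$truth, design, m_by_annot, annot)
      z1 <- sim$z1; z2 <- sim$z2
    }
    agg <- agg_make(l_tot, z1, z2, spec$m, s_annot, m_by_annot,
                    spec$truth$categories)
    res <- tryCatch({
      fit <- gecko_fit_agg(agg, fit_design, opts)
      est <- fit_param_vector(fit$params, fit_design)
      out <- c(est, converged = as.numeric(fit$converged))
      if (spec$do_jackknife) {
        jkr <- jackknife_core(agg, blocks, fit_design, fit, jk, opts)
        wt <- wald_test(est[names(jkr$se)], jkr$se)
        names(wt$p) <- paste0("p_", names(jkr$se))
        out <- c(out, stats::setNames(jkr$se, paste0("se_", names(jkr$se))),
                 wt$p)
      }
      out
    }, error = function(e) NULL)
    if (is.null(res)) n_fail <- n_fail + 1L else rows[[r]] <- res
  }
  est <- as.data.frame(do.call(rbind, rows[!vapply(rows, is.null,
                                                   logical(1))]))
  structure(list(spec = spec, estimates = est,
                 metrics = scenario_metrics(est, spec$truth, fit_design),
                 n_fail = n_fail,
                 flagged = n_fail > 0.05 * spec$reps,
                 ldscore_summary = summary(l_tot)),
            class = "gecko_scenario")
}

#' Aggregate per-replicate estimates into calibration metrics
#'
#' @param est Data frame of per-replicate estimates (and, when
#'   available, p-values) as produced by [run_scenario()].
#' @param truth True [cov_params()].
#' @param design The design used for fitting (determines whether
#'   rho_e rows exist).
#' @param alphas Nominal levels for rejection rates.
#' @return A data frame with one row per tracked quantity: truth,
#'   mean, bias, MSE, their Monte-Carlo SEs, and (when p-values are
#'   present) rejection rates at each nominal level with binomial SEs.
#'   Rejection rates equal the empirical type I error when the
#'   corresponding true value is zero, and raw power otherwise.
#' @export
scenario_metrics <- function(est, truth, design,
                             alphas = c(0.05, 0.005)) {
  tv <- c(h2_1 = sum(truth$h2_1), h2_2 = sum(truth$h2_2),
          rho_g = sum(truth$rho_g))
  if (design$ns > 0)
    tv <- c(tv, rho_e = truth$rho - sum(truth$rho_g))
  R <- nrow(est)
  out <- lapply(names(tv), function(p) {
    if (!p %in% names(est)) return(NULL)
    e <- est[[p]]
    err <- e - tv[[p]]
    row <- data.frame(parameter = p, truth = tv[[p]], n_reps = R,
                      mean = mean(e), mc_se_mean = stats::sd(e) / sqrt(R),
                      bias = mean(err), mse = mean(err^2),
                      mc_se_mse = stats::sd(err^2) / sqrt(R))
    pcol <- paste0("p_", p)
    if (pcol %in% names(est)) {
      for (a in alphas) {
        rate <- mean(est[[pcol]] < a)
        row[[sprintf("reject_%g", a)]] <- rate
        row[[sprintf("mc_se_reject_%g", a)]] <-
          sqrt(rate * (1 - rate) / R)
      }
    }
    row
  })
  do.call(rbind, out)
}

#' @export
print.gecko_scenario <- function(x, ...) {
  s <- x$spec
  cat(sprintf(
    "scenario: m = %d, reps = %d (failed %d)%s, design n1/n2/ns = %g/%g/%g\n",
    s$m, s$reps, x$n_fail, if (x$flagged) " [FLAGGED]" else "",
    s$design$n1, s$design$n2, s$design$ns))
  print(x$metrics, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Power at a fixed empirical type I error
#'
#' Instead of rejecting at the nominal cutoff, the threshold is the
#' empirical \code{alpha}-quantile of p-values from matched null
#' replicates, so methods with different calibration are compared at
#' the same realized type I error.
#'
#' @param p_alt P-values under the alternative.
#' @param p_null P-values from matched null replicates.
#' @param alpha Target type I error rate.
#' @return Power (fraction of alternative p-values at or below the
#'   empirical threshold), with the threshold as attribute.
#' @export
power_at_fixed_alpha <- function(p_alt, p_null, alpha = 0.05) {
  stopifnot(length(p_null) > 0, length(p_alt) > 0)
  thr <- stats::quantile(p_null, probs = alpha, type = 1, names = FALSE)
  structure(mean(p_alt <= thr), threshold = thr)
}

#' Named simulation presets
#'
#' The four calibration settings as scenario grids: (I) genetic
#' covariance swept from -0.4 to 0.4 by 0.05 at environmental
#' covariance in \{-0.1, 0, 0.1\}, one-study design; (II) the roles
#' swapped; (III) the sweep across the three study designs (the
#' environmental covariance held at 0.1 where identifiable during the
#' genetic sweep, and the genetic covariance at 0.1 during the
#' environmental sweep, which only runs for designs with overlap);
#' (IV) two annotation categories with the functional category's
#' genetic covariance swept from -0.2 to 0.2 by 0.025 and the other
#' held at 0, heritability 0.25 per category.  Heritability is 0.5
#' per trait throughout.  Defaults are desk-scale (m = 20,000 SNPs,
#' 100 replicates) and overridable to full scale.
#'
#' @param setting \code{"I"}, \code{"II"}, \code{"III"} or \code{"IV"}.
#' @param m,reps,seed,ld,do_jackknife Passed to [scenario_spec()].
#' @param thin Keep every \code{thin}-th point of each sweep (1 = the
#'   full grid).
#' @return A named list of [scenario_spec()] objects.
#' @export
scenario_preset <- function(setting = c("I", "II", "III", "IV"),
                            m = 20000L, reps = 100L, seed = 1L,
                            ld = ld_structure(), do_jackknife = FALSE,
                            thin = 1L) {
  setting <- match.arg(setting)
  sweep_g <- seq(-0.4, 0.4, by = 0.05)
  sweep_g <- sweep_g[seq(1, length(sweep_g), by = thin)]
  specs <- list()
  add <- function(name, design, truth, frac = NULL) {
    specs[[name]] <<- scenario_spec(design, truth, ld = ld, m = m,
                                    reps = reps, seed = seed,
                                    annot_frac = frac,
                                    do_jackknife = do_jackknife)
  }
  one <- design_preset("one_study"); two <- design_preset("two_study")
  ovl <- design_preset("overlap")
  if (setting == "I") {
    for (re in c(-0.1, 0, 0.1)) for (rg in sweep_g)
      add(sprintf("I_re%+.2f_rg%+.2f", re, rg), one,
          cov_params(0.5, 0.5, rg, rg + re))
  } else if (setting == "II") {
    for (rg in c(-0.1, 0, 0.1)) for (re in sweep_g)
      add(sprintf("II_rg%+.2f_re%+.2f", rg, re), one,
          cov_params(0.5, 0.5, rg, rg + re))
  } else if (setting == "III") {
    for (nm in c("one_study", "two_study", "overlap")) {
      d <- design_preset(nm)
      re_fix <- if (d$ns > 0) 0.1 else 0
      for (rg in sweep_g)
        add(sprintf("III_%s_rg%+.2f", nm, rg), d,
            cov_params(0.5, 0.5, rg, rg + re_fix))
      if (d$ns > 0)
        for (re in sweep_g)
          add(sprintf("III_%s_re%+.2f", nm, re), d,
              cov_params(0.5, 0.5, 0.1, 0.1 + re))
    }
  } else {
    frac <- c(functional = 0.457, background = 0.543)
    sweep_f <- seq(-0.2, 0.2, by = 0.025)
    sweep_f <- sweep_f[seq(1, length(sweep_f), by = thin)]
    for (nm in c("one_study", "two_study", "overlap")) {
      d <- design_preset(nm)
      re_fix <- if (d$ns > 0) 0.1 else 0
      for (rg in sweep_f)
        add(sprintf("IV_%s_rgf%+.3f", nm, rg), d,
            cov_params(c(0.25, 0.25), c(0.25, 0.25), c(rg, 0),
                       rg + re_fix,
                       categories = names(frac)), frac = unname(frac))
      if (d$ns > 0)
        for (re in sweep_g)
          add(sprintf("IV_%s_re%+.2f", nm, re), d,
              cov_params(c(0.25, 0.25), c(0.25, 0.25), c(0.05, 0),
                         0.05 + re, categories = names(frac)),
              frac = unname(frac))
    }
  }
  specs
}
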