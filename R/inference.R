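## Block-jackknife standard errors and Wald tests.
##
## Contiguous blocks of SNPs (in chromosome/position order) are deleted
## one at a time and the model is refit, warm-started at the full-data
## optimum.  Per-parameter SEs use the delete-one jackknife formula;
## derived quantities (rho_e, gamma_g, gamma_e) are jackknifed as
## transformed per-block estimates rather than via the delta method.

#' Jackknife specification
#'
#' @param n_blocks Number of contiguous SNP blocks (default 200, the
#'   convention of LD-score-regression-style methods).
#' @param warm_start Start every delete-one-block refit at the
#'   full-data optimum and ascend with damped Newton steps on the
#'   analytic score (default); cold starts rerun the full EM + polish
#'   and are available for validation.
#' @param max_iter Iteration budget per warm-started refit.
#' @param grad_tol Supremum-norm gradient threshold at which a warm
#'   refit counts as converged (the implied parameter error is orders
#'   of magnitude below the jackknife dispersion).
#' @return A list of class \code{"jackknife_spec"}.
#' @export
jackknife_spec <- function(n_blocks = 200L, warm_start = TRUE,
                           max_iter = 50L, grad_tol = 1e-3) {
  stopifnot(n_blocks >= 2L, max_iter >= 1L, grad_tol > 0)
  structure(list(n_blocks = as.integer(n_blocks),
                 warm_start = isTRUE(warm_start),
                 max_iter = as.integer(max_iter), grad_tol = grad_tol),
            class = "jackknife_spec")
}

# Contiguous block ids for m SNPs, sizes differing by at most 1.
block_ids <- function(m, n_blocks) {
  sizes <- rep(m %/% n_blocks, n_blocks) +
    (seq_len(n_blocks) <= m %% n_blocks)
  rep.int(seq_len(n_blocks), sizes)
}

# Named vector of reported quantities for one parameter set.
fit_param_vector <- function(params, design) {
  K <- length(params$h2_1)
  d <- derived_quantities(params, design)
  out <- c(h2_1 = sum(params$h2_1), h2_2 = sum(params$h2_2),
           rho_g = sum(params$rho_g))
  if (K > 1L) {
    pc <- c(params$rho_g, params$h2_1, params$h2_2)
    names(pc) <- c(paste0("rho_g_", params$categories),
                   paste0("h2_1_", params$categories),
                   paste0("h2_2_", params$categories))
    out <- c(out, pc)
  }
  out <- c(out, gamma_g = d$gamma_g)
  if (design$ns > 0)
    out <- c(out, rho = params$rho, rho_e = d$rho_e, gamma_e = d$gamma_e)
  out
}

# Per-(block x bin) sufficient-statistic arrays for fast deletion.
jackknife_binned_stats <- function(agg, blocks, nbins) {
  l <- agg$s[, 1L]
  br <- unique(stats::quantile(l, probs = seq(0, 1, length.out = nbins + 1L)))
  bin <- findInterval(l, br, rightmost.closed = TRUE, all.inside = TRUE)
  nb <- max(bin)
  idx <- (blocks - 1L) * nb + bin
  lev <- seq_len(max(blocks) * nb)
  acc <- function(x) {
    out <- numeric(length(lev))
    s <- rowsum(x, idx, reorder = TRUE)
    out[as.integer(rownames(s))] <- s
    matrix(out, nrow = max(blocks), ncol = nb, byrow = TRUE)
  }
  st <- list(W = acc(agg$W), WS = acc(agg$W * l), M11 = acc(agg$M11),
             M12 = acc(agg$M12), M22 = acc(agg$M22), nbins = nb)
  st$full <- lapply(st[c("W", "WS", "M11", "M12", "M22")], colSums)
  st
}

agg_from_binned_stats <- function(st, drop_block, agg) {
  b <- drop_block
  W <- st$full$W - st$W[b, ]
  pos <- W > 0
  s <- (st$full$WS - st$WS[b, ])[pos] / W[pos]
  structure(list(
    s = matrix(s, ncol = 1L, dimnames = list(NULL, agg$categories)),
    W = W[pos],
    M11 = (st$full$M11 - st$M11[b, ])[pos],
    M12 = (st$full$M12 - st$M12[b, ])[pos],
    M22 = (st$full$M22 - st$M22[b, ])[pos],
    m = agg$m, m_by_annot = agg$m_by_annot,
    categories = agg$categories), class = "gecko_agg")
}

# Quasi-Newton ascent with the Hessian frozen at the full-data
# optimum; falls back to full Newton when no frozen Hessian is
# available or progress stalls.
warm_refit <- function(agg_b, design, init, Hfull, options) {
  if (is.null(Hfull))
    return(nr_polish_agg(agg_b, design, init, options))
  cats <- agg_b$categories
  th <- pack_params(init, design)
  f <- function(t) agg_loglik(agg_b, unpack_params(t, design, cats),
                              design)
  ll <- f(th)
  gnorm <- Inf
  dS <- sigma_derivs(agg_b, design)
  for (it in seq_len(options$max_nr_iter)) {
    sc <- agg_score(agg_b, unpack_params(th, design, cats), design,
                    hessian = FALSE, dS = dS)
    if (is.null(sc) || !all(is.finite(sc$grad))) break
    gnorm <- max(abs(sc$grad))
    if (gnorm <= options$nr_tol) break
    dir <- drop(solve(Hfull, -sc$grad))
    lam <- 1; improved <- FALSE
    while (lam > 1e-10) {
      llc <- f(th + lam * dir)
      if (is.finite(llc) && llc > ll) {
        th <- th + lam * dir; ll <- llc; improved <- TRUE; break
      }
      lam <- lam / 2
    }
    if (!improved)
      return(nr_polish_agg(agg_b, design,
                           unpack_params(th, design, cats), options))
  }
  structure(unpack_params(th, design, cats), grad_norm = gnorm)
}

# Row subset of an exact aggregate (multi-category path).
agg_drop_rows <- function(agg, rows) {
  keep <- setdiff(seq_along(agg$W), rows)
  structure(list(s = agg$s[keep, , drop = FALSE], W = agg$W[keep],
                 M11 = agg$M11[keep], M12 = agg$M12[keep],
                 M22 = agg$M22[keep], m = agg$m,
                 m_by_annot = agg$m_by_annot,
                 categories = agg$categories), class = "gecko_agg")
}

#' Block-jackknife standard errors
#'
#' Deletes each contiguous SNP block in turn, refits the model
#' (warm-started at the full-data optimum by default), and returns the
#' jackknife standard error for every reported quantity:
#' \deqn{SE = \sqrt{(B-1)/B \sum_b (\theta_{(-b)} - \bar\theta)^2}.}
#' The SNP count entering the per-SNP variance scale (\code{m}) is held
#' at its full-data value across refits so delete-block estimates stay
#' on a common scale.  Refits that fail to converge are excluded and
#' counted; more than 10\% exclusions is an error.
#'
#' @param table A [snp_table()].
#' @param design A [study_design()].
#' @param full_fit The full-data [gecko_fit()] result.
#' @param spec A [jackknife_spec()].
#' @param options [fit_options()] used for the refits; defaults to the
#'   options of \code{full_fit}.  For single-category models the refits
#'   run on binned LD-score sufficient statistics (see
#'   [fit_options()]'s \code{agg_bins}; a default of 400 bins is used
#'   here when the full fit was exact), which makes 200 refits cheap.
#' @return A list of class \code{"gecko_jackknife"} with elements
#'   \code{se} (named vector), \code{estimates} (B x P matrix of
#'   delete-block values), \code{n_fail}, \code{spec}.
#' @export
block_jackknife <- function(table, design, full_fit,
                            spec = jackknife_spec(),
                            options = full_fit$options) {
  stopifnot(inherits(full_fit, "gecko_fit"))
  if (!full_fit$converged)
    warning("jackknifing a non-converged full fit")
  m <- table$m
  if (m < spec$n_blocks)
    stop("more blocks than SNPs", call. = FALSE)
  agg <- agg_from_table(table)
  blocks <- block_ids(m, spec$n_blocks)
  jackknife_core(agg, blocks, design, full_fit, spec, options)
}

# Work-horse shared with the simulation harness: jackknife on an
# exact aggregate with given per-SNP block ids.
jackknife_core <- function(agg, blocks, design, full_fit, spec,
                           options) {
  refit_opts <- options
  Hfull <- NULL
  if (spec$warm_start) {
    # Warm refits skip EM entirely: near the full-data optimum EM
    # moves by tiny damped steps (the missing-information fraction is
    # close to 1 at GWAS signal sizes), whereas Newton on the analytic
    # score lands on the delete-block optimum in a few iterations.
    # The Hessian is frozen at the full-data optimum (deleting one of
    # B blocks perturbs it by O(1/B)), so each refit iteration needs
    # only the analytic gradient.  Validated against cold starts in
    # the test suite.
    sc <- agg_score(agg, full_fit$params, design)
    if (!is.null(sc)) {
      ev <- eigen(sc$hess, symmetric = TRUE, only.values = TRUE)$values
      if (all(is.finite(ev)) && max(ev) < 0) Hfull <- sc$hess
    }
    refit_opts$max_nr_iter <- spec$max_iter
    refit_opts$nr_tol <- spec$grad_tol
  }
  K <- length(agg$categories)
  binned <- K == 1L
  if (binned) {
    nb <- if (is.finite(options$agg_bins)) as.integer(options$agg_bins)
          else 400L
    st <- jackknife_binned_stats(agg, blocks, nb)
  }

  ests <- NULL
  fails <- 0L
  for (b in seq_len(spec$n_blocks)) {
    agg_b <- if (binned) agg_from_binned_stats(st, b, agg)
             else agg_drop_rows(agg, which(blocks == b))
    params_b <- if (spec$warm_start) {
      p <- tryCatch(
        warm_refit(agg_b, design, full_fit$params, Hfull, refit_opts),
        error = function(e) NULL)
      if (!is.null(p) && attr(p, "grad_norm") > spec$grad_tol) p <- NULL
      p
    } else {
      fb <- tryCatch(gecko_fit_agg(agg_b, design, refit_opts),
                     error = function(e) NULL)
      if (!is.null(fb) && fb$converged) fb$params else NULL
    }
    if (is.null(params_b)) {
      fails <- fails + 1L
      next
    }
    v <- fit_param_vector(params_b, design)
    ests <- rbind(ests, v)
  }
  if (fails > 0.1 * spec$n_blocks)
    stop(sprintf("jackknife: %d of %d block refits failed", fails,
                 spec$n_blocks), call. = FALSE)
  B <- nrow(ests)
  ctr <- sweep(ests, 2L, colMeans(ests))
  se <- sqrt((B - 1) / B * colSums(ctr^2))
  structure(list(se = se, estimates = ests, n_fail = fails, spec = spec),
            class = "gecko_jackknife")
}

#' Two-sided Wald test
#'
#' @param estimate Point estimate(s).
#' @param se Standard error(s), >= 0.
#' @return A list with \code{z} and two-sided \code{p}; degenerate
#'   zero-SE cases give p = 0 (estimate != 0) or p = 1 (estimate = 0)
#'   and are flagged through attribute \code{"degenerate"}.
#' @examples
#' wald_test(0.1, 0.02)  # z = 5
#' @export
wald_test <- function(estimate, se) {
  stopifnot(length(estimate) == length(se), all(se >= 0, na.rm = TRUE))
  z <- estimate / se
  p <- 2 * stats::pnorm(-abs(z))
  deg <- se == 0
  p[deg & estimate != 0] <- 0
  p[deg & estimate == 0] <- 1
  z[deg] <- ifelse(estimate[deg] == 0, 0, Inf * sign(estimate[deg]))
  out <- list(z = z, p = p)
  if (any(deg, na.rm = TRUE)) attr(out, "degenerate") <- which(deg)
  out
}

#' Assemble estimates, standard errors and p-values
#'
#' Combines a full-data fit with jackknife SEs into the final results
#' table.  With no overlapping individuals the environmental rows are
#' omitted entirely (not silently NA) and the result carries an
#' explicit not-identifiable marker.
#'
#' @param full_fit A [gecko_fit()] result.
#' @param ses A [block_jackknife()] result (or named SE vector).
#' @param design The [study_design()].
#' @return A list of class \code{"gecko_result"}: data frame
#'   \code{table} (parameter, estimate, se, z, p), \code{design},
#'   \code{rho_e_identifiable}, \code{jackknife} metadata.
#' @export
summarize_fit <- function(full_fit, ses, design) {
  se <- if (inherits(ses, "gecko_jackknife")) ses$se else ses
  est <- fit_param_vector(full_fit$params, design)
  common <- intersect(names(est), names(se))
  if (!length(common)) stop("no overlapping parameter names",
                            call. = FALSE)
  est <- est[common]; se <- se[common]
  wt <- wald_test(est, se)
  tab <- data.frame(parameter = common, estimate = unname(est),
                    se = unname(se), z = unname(wt$z), p = unname(wt$p),
                    stringsAsFactors = FALSE)
  structure(list(
    table = tab, design = design,
    rho_e_identifiable = design$ns > 0,
    note = if (design$ns == 0)
      "rho_e/gamma_e not identifiable: no overlapping individuals (ns = 0)"
    else NULL,
    jackknife = if (inherits(ses, "gecko_jackknife"))
      list(n_blocks = ses$spec$n_blocks, warm_start = ses$spec$warm_start,
           n_fail = ses$n_fail,
           convention = "delete-one contiguous SNP blocks in (chrom, bp) order")
    else NULL,
    loglik = full_fit$loglik, converged = full_fit$converged),
    class = "gecko_result")
}

#' @export
print.gecko_result <- function(x, digits = 4, ...) {
  cat("genetic/environmental covariance estimates\n")
  print(x$design)
  print(format(x$table, digits = digits), row.names = FALSE)
  if (!is.null(x$note)) cat("note:", x$note, "\n")
  if (!is.null(x$jackknife))
    cat(sprintf("SEs: block jackknife, %d blocks (%s)\n",
                x$jackknife$n_blocks, x$jackknife$convention))
  invisible(x)
}

#' One-call analysis pipeline
#'
#' Fits the model, runs the block jackknife and assembles the results
#' table.
#'
#' @inheritParams gecko_fit
#' @param jackknife A [jackknife_spec()].
#' @return A \code{"gecko_result"} object.
#' @export
gecko_analyze <- function(table, design, options = fit_options(),
                          jackknife = jackknife_spec()) {
  fit <- gecko_fit(table, design, options)
  jk <- block_jackknife(table, design, fit, jackknife, options)
  summarize_fit(fit, jk, design)
}
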