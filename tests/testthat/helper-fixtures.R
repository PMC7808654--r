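# Shared fixture builders: everything is generated in code at test
# time.

# z-score table drawn directly from the marginal model (bypassing
# genotypes), handy for oracle checks where the model is the truth.
model_table <- function(params, design, l, seed = 1) {
  set.seed(seed)
  m <- length(l)
  z <- matrix(NA_real_, m, 2)
  for (j in seq_len(m)) {
    S <- per_snp_covariance(params, design, list(ldscore = l[j]), m)
    z[j, ] <- drop(rnorm(2) %*% chol(S))
  }
  snp_table(sprintf("snp%04d", seq_len(m)), rep("1", m),
            seq_len(m) * 1000L, z[, 1], z[, 2], l)
}

random_ldscores <- function(m, seed) {
  set.seed(seed)
  1 + rgamma(m, shape = 2, scale = 5)
}

# Maximum of the composite log-likelihood over a parameter grid:
# coarse global pass (step 0.05) followed by a 0.01-step local
# refinement around the coarse argmax.
grid_max_loglik <- function(table, design, h_range = c(0, 1),
                            r_range = c(-0.5, 0.5)) {
  agg <- gecko:::agg_from_table(table)
  eval_grid <- function(h1s, h2s, rgs, rhos) {
    best <- -Inf; arg <- NULL
    for (h1 in h1s) for (h2 in h2s) for (rg in rgs) {
      if (abs(rg) > sqrt(h1 * h2)) next
      for (rho in rhos) {
        if (design$ns == 0 && rho != rg) next
        ll <- gecko:::agg_loglik(agg, cov_params(h1, h2, rg, rho),
                                 design)
        if (is.finite(ll) && ll > best) {
          best <- ll; arg <- c(h1, h2, rg, rho)
        }
      }
    }
    list(max = best, arg = arg)
  }
  co <- eval_grid(seq(h_range[1], h_range[2], by = 0.05),
                  seq(h_range[1], h_range[2], by = 0.05),
                  seq(r_range[1], r_range[2], by = 0.05),
                  if (design$ns == 0) seq(r_range[1], r_range[2], by = 0.05)
                  else seq(r_range[1], r_range[2], by = 0.05))
  a <- co$arg
  fine <- function(x, lo, hi) seq(max(lo, x - 0.05), min(hi, x + 0.05),
                                  by = 0.01)
  fi <- eval_grid(fine(a[1], h_range[1], h_range[2]),
                  fine(a[2], h_range[1], h_range[2]),
                  fine(a[3], r_range[1], r_range[2]),
                  fine(a[4], r_range[1], r_range[2]))
  list(max = max(co$max, fi$max),
       arg = if (fi$max >= co$max) fi$arg else co$arg)
}

# Small genotype panel + standardized matrix, cached per session.
small_panel_cache <- new.env(parent = emptyenv())

cached_panel <- function(n, m, seed, ld = ld_structure()) {
  key <- sprintf("p_%d_%d_%d_%s", n, m, seed, ld$kind)
  if (is.null(small_panel_cache[[key]])) {
    p <- simulate_genotypes(n, m, ld, seed = seed)
    small_panel_cache[[key]] <-
      list(panel = p, x = gecko:::standardize_genotypes(p$geno),
           ld = compute_ld_scores(p))
  }
  small_panel_cache[[key]]
}
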