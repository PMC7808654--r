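# Synthetic genotypes, effects, phenotypes, z-scores and the scenario
# harness.

test_that("genotype simulation is deterministic and respects the LD structure", {
  p1 <- simulate_genotypes(100, 200, ld_structure(), seed = 5)
  p2 <- simulate_genotypes(100, 200, ld_structure(), seed = 5)
  expect_identical(p1$geno, p2$geno)
  expect_error(ld_structure(within_block_corr = 1), "< 1")

  # independent SNPs: mean |r| across pairs matches the null
  # expectation E|r| ~ sqrt(2/(pi n)) for sample correlations
  set.seed(3)
  p <- simulate_genotypes(400, 100, ld_structure("independent"),
                          seed = 11)
  x <- gecko:::standardize_genotypes(p$geno)
  r <- crossprod(x) / (nrow(x) - 1)
  rr <- abs(r[upper.tri(r)])
  expect_lt(abs(mean(rr) - sqrt(2 / (pi * 400))),
            3 * sd(rr) / sqrt(length(rr)))

  # block structure raises within-block correlation far above that
  pb <- simulate_genotypes(400, 100, ld_structure(block_size = 50,
                                                  within_block_corr = 0.6),
                           seed = 11)
  xb <- gecko:::standardize_genotypes(pb$geno)
  rb <- crossprod(xb[, 1:50]) / 399
  expect_gt(mean(abs(rb[upper.tri(rb)])), 0.2)
})

test_that("effect sizes have the prescribed bivariate moments", {
  m <- 2e5
  truth <- cov_params(0.5, 0.3, 0.12, 0.2)
  b <- simulate_effects(truth, m, seed = 7)
  S <- crossprod(sweep(b, 2, colMeans(b))) / (m - 1) * m
  expect_equal(S[1, 1], 0.5, tolerance = 3 * sqrt(2 / m) * 0.5 + 0.01)
  expect_equal(S[2, 2], 0.3, tolerance = 3 * sqrt(2 / m) * 0.3 + 0.01)
  expect_equal(S[1, 2], 0.12, tolerance = 0.01)

  # zero-variance marginal
  b0 <- simulate_effects(cov_params(0, 0.3, 0, 0), m = 1000, seed = 8)
  expect_true(all(b0[, 1] == 0))

  # degenerate correlation: rho_g at its bound makes effects colinear
  bd <- simulate_effects(cov_params(0.4, 0.4, 0.4, 0.4), m = 5e4,
                         seed = 9)
  expect_gt(cor(bd[, 1], bd[, 2]), 0.999)
})

test_that("phenotypes decompose into genetic and residual variance", {
  cp <- cached_panel(300, 500, seed = 29)
  des <- study_design(300, 300, 300)
  truth <- cov_params(0.4, 0.4, 0.1, 0.25)
  set.seed(33)
  gvar <- replicate(100, {
    b <- simulate_effects(truth, 500)
    drop(var(cp$x[, , drop = FALSE] %*% b[, 1]))
  })
  expect_lt(abs(mean(gvar) - 0.4), 3 * sd(gvar) / sqrt(100))

  # overlap individuals: phenotypic correlation ~ rho_g + rho_e
  set.seed(34)
  pc <- replicate(60, {
    b <- simulate_effects(truth, 500)
    ph <- simulate_phenotypes(cp$x, b, truth, des)
    cor(ph$y1, ph$y2)
  })
  expect_lt(abs(mean(pc) - 0.25), 3 * sd(pc) / sqrt(60))

  expect_warning(
    simulate_phenotypes(cp$x[1:200, ], simulate_effects(truth, 500),
                        truth, study_design(100, 100, 0), seed = 1),
    "no effect")
})

test_that("z-scores follow their definition and null distribution", {
  cp <- cached_panel(500, 100, seed = 47)
  # self-regression: y equal to a standardized SNP column gives z = sqrt(n)
  y <- gecko:::standardize_vector(cp$x[, 10])
  z <- compute_zscores(cp$x, y)
  expect_equal(z[10], sqrt(500) * drop(cor(cp$x[, 10], y)),
               tolerance = 1e-8)
  expect_equal(z[10], sqrt(500), tolerance = 1e-6)

  # null phenotype: z approximately standard normal across many SNPs
  pnull <- simulate_genotypes(400, 10000, ld_structure("independent"),
                              seed = 53)
  xnull <- gecko:::standardize_genotypes(pnull$geno)
  set.seed(54)
  ynull <- gecko:::standardize_vector(rnorm(400))
  znull <- compute_zscores(xnull, ynull)
  expect_gt(ks.test(znull, "pnorm")$p.value, 0.01)

  expect_error(compute_zscores(cp$x, rep(0, 500)), "standardized")
  expect_error(compute_zscores(cp$x, rnorm(500) + 5), "standardized")
})

test_that("scenarios are reproducible and expose calibrated metrics", {
  sp <- scenario_spec(study_design(400, 400, 400),
                      cov_params(0.5, 0.5, 0.1, 0.2), m = 1500,
                      reps = 8, seed = 77, do_jackknife = TRUE,
                      n_blocks = 50)
  s1 <- run_scenario(sp)
  s2 <- run_scenario(sp)
  expect_identical(s1$estimates, s2$estimates)
  expect_true(all(c("parameter", "truth", "mean", "bias", "mse",
                    "mc_se_mse", "reject_0.05") %in%
                    names(s1$metrics)))
  expect_true(all(s1$metrics$mse >= 0))
  expect_true(all(c("p_rho_g", "p_rho_e") %in% names(s1$estimates)))
})

test_that("reference-panel LD scores (LD mismatch) preserve unbiasedness", {
  base <- scenario_spec(study_design(600, 600, 600),
                        cov_params(0.5, 0.5, 0.1, 0.2), m = 3000L,
                        reps = 40L, seed = 515L, do_jackknife = FALSE)
  mis <- base
  mis$misspec <- list(ld_mismatch = TRUE)
  sc <- run_scenario(mis)
  met <- sc$metrics
  rg <- met[met$parameter == "rho_g", ]
  expect_lt(abs(rg$mean - rg$truth), 3 * rg$mc_se_mean + 1e-3)
  # the mismatch scenario really used different LD scores than the
  # in-sample ones, but the same replicate data (paired seeds)
  sc0 <- run_scenario(base)
  expect_false(isTRUE(all.equal(sc0$ldscore_summary, sc$ldscore_summary)))
})

test_that("power at a fixed empirical type I error uses the null quantile", {
  set.seed(99)
  p_null <- runif(200)
  p_alt <- rbeta(200, 0.3, 1)
  pw <- power_at_fixed_alpha(p_alt, p_null, alpha = 0.05)
  thr <- quantile(p_null, 0.05, type = 1, names = FALSE)
  expect_equal(as.numeric(pw), mean(p_alt <= thr))
  # a stronger signal can only raise power at the same threshold
  p_alt2 <- p_alt / 10
  expect_gte(as.numeric(power_at_fixed_alpha(p_alt2, p_null)),
             as.numeric(pw))
})

test_that("scenario presets encode the published truth grids", {
  pre <- scenario_preset("I", m = 500, reps = 2, thin = 4)
  expect_equal(length(pre), 3 * 5)  # 3 env values x thinned sweep
  rg <- sapply(pre, function(s) sum(s$truth$rho_g))
  expect_true(all(range(rg) == c(-0.4, 0.4)))

  pre3 <- scenario_preset("III", m = 500, reps = 2, thin = 8)
  designs <- unique(sapply(pre3, function(s) s$design$ns))
  expect_setequal(designs, c(2938, 0, 1000))

  pre4 <- scenario_preset("IV", m = 500, reps = 2, thin = 8)
  k2 <- sapply(pre4, function(s) gecko:::n_categories(s$truth))
  expect_true(all(k2 == 2))
  # functional-category sweep spans -0.2..0.2, background held at 0
  rgs <- sapply(pre4, function(s) s$truth$rho_g[2])
  expect_true(all(rgs %in% c(0)))
})
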