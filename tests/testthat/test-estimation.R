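# EM + Newton-Raphson maximization of the composite likelihood.

test_that("fit attains the grid maximum on small tables", {
  for (seed in 1:5) {
    set.seed(seed)
    m <- sample(20:30, 1)
    des <- list(study_design(500, 500, 500),
                study_design(500, 400, 0))[[1 + seed %% 2]]
    tab <- model_table(cov_params(0.5, 0.4, 0.1,
                                  if (des$ns > 0) 0.2 else 0.1),
                       des, random_ldscores(m, seed + 50), seed = seed)
    fit <- gecko_fit(tab, des, fit_options())
    oracle <- grid_max_loglik(tab, des)
    expect_gte(fit$loglik, oracle$max - 1e-9)
  }
})

test_that("the EM trace never decreases", {
  for (seed in c(2, 8)) {
    des <- study_design(800, 800, 800)
    tab <- model_table(cov_params(0.5, 0.5, 0.15, 0.25), des,
                       random_ldscores(200, seed), seed = seed)
    fit <- gecko_fit(tab, des, fit_options(max_nr_iter = 0))
    expect_true(all(diff(fit$em_trace) >= -1e-8 * (abs(fit$loglik) + 1)))
  }
})

test_that("em_step is a fixed point at the optimum and structural with ns = 0", {
  des <- study_design(700, 700, 700)
  tab <- model_table(cov_params(0.5, 0.5, 0.1, 0.2), des,
                     random_ldscores(300, 4), seed = 14)
  # polish hard so we sit at a stationary point of the exact objective
  fit <- gecko_fit(tab, des, fit_options(em_tol = 1e-12,
                                         max_em_iter = 5000,
                                         nr_tol = 1e-9))
  stepped <- em_step(tab, des, fit$params)
  expect_equal(unlist(stepped[c("h2_1", "h2_2", "rho_g", "rho")]),
               unlist(fit$params[c("h2_1", "h2_2", "rho_g", "rho")]),
               tolerance = 1e-6)

  # no overlap: the residual cross term stays structurally zero, so
  # rho is tied to rho_g by the update
  des0 <- study_design(700, 600, 0)
  tab0 <- model_table(cov_params(0.5, 0.5, 0.1, 0.1), des0,
                      random_ldscores(300, 5), seed = 15)
  out <- em_step(tab0, des0, cov_params(0.4, 0.4, 0.05, 0.05))
  expect_identical(out$rho, sum(out$rho_g))
})

test_that("degenerate inputs are rejected", {
  des <- study_design(100, 100, 100)
  tab <- snp_table(c("a", "b", "c"), rep("1", 3), 1:3, rep(0, 3),
                   rep(0, 3), rep(1, 3))
  expect_error(gecko_fit(tab, des), "zero")
})

test_that("Newton polish converges to the grid optimum and is stationary", {
  # enough SNPs (and partial overlap) for a well-behaved interior
  # optimum
  des <- study_design(600, 500, 300)
  tab <- model_table(cov_params(0.4, 0.4, 0.15, 0.2), des,
                     random_ldscores(600, 12), seed = 35)
  # polish from a short EM run, per the operation's contract
  start <- gecko_fit(tab, des, fit_options(max_em_iter = 20,
                                           max_nr_iter = 0))$params
  polished <- nr_polish(tab, des, start,
                        fit_options(nr_tol = 1e-8, max_nr_iter = 200))
  ll <- composite_loglik(tab, polished, des)
  # reference optimum from an exhaustive independent run of the whole
  # pipeline at tight tolerances
  ref <- gecko_fit(tab, des, fit_options(em_tol = 1e-12,
                                         max_em_iter = 5000,
                                         nr_tol = 1e-10))
  expect_gte(ll, ref$loglik - 1e-6)

  # gradient at the returned parameters honours the tolerance
  agg <- gecko:::agg_from_table(tab)
  g <- gecko:::agg_score(agg, polished, des)$grad
  expect_lte(max(abs(g)), 1e-6)

  # starting exactly at a maximizer yields a zero step
  again <- nr_polish(tab, des, polished,
                     fit_options(nr_tol = 1e-8, max_nr_iter = 200))
  expect_equal(unlist(again[c("h2_1", "h2_2", "rho_g", "rho")]),
               unlist(polished[c("h2_1", "h2_2", "rho_g", "rho")]),
               tolerance = 1e-7)
})

test_that("binned and exact likelihood aggregation agree", {
  des <- study_design(900, 900, 900)
  tab <- model_table(cov_params(0.5, 0.5, 0.1, 0.2), des,
                     random_ldscores(3000, 11), seed = 41)
  fe <- gecko_fit(tab, des, fit_options(agg_bins = Inf))
  fb <- gecko_fit(tab, des, fit_options(agg_bins = 400))
  expect_equal(unlist(fb$params[c("h2_1", "h2_2", "rho_g", "rho")]),
               unlist(fe$params[c("h2_1", "h2_2", "rho_g", "rho")]),
               tolerance = 5e-3)
})

test_that("single-category stratified fit reduces to the plain fit", {
  des <- study_design(800, 800, 800)
  tab <- model_table(cov_params(0.5, 0.5, 0.1, 0.2), des,
                     random_ldscores(150, 13), seed = 27)
  tab_s <- snp_table(tab$snp$snp_id, tab$snp$chrom, tab$snp$bp,
                     tab$snp$z1, tab$snp$z2, tab$snp$ldscore,
                     annot = rep("all", tab$m),
                     ld_annot = matrix(tab$snp$ldscore,
                                       dimnames = list(NULL, "all")))
  f1 <- gecko_fit(tab, des, fit_options(agg_bins = Inf))
  f2 <- fit_stratified(tab_s, des, fit_options(agg_bins = Inf))
  expect_identical(unlist(f1$params[c("h2_1", "h2_2", "rho_g", "rho")]),
                   unlist(f2$params[c("h2_1", "h2_2", "rho_g", "rho")]))
  expect_error(fit_stratified(tab, des), "per-category")
})

test_that("stratified fit recovers per-category genetic covariances", {
  # two annotation categories with genetic covariance only in the
  # first; estimates should straddle the truths within 3 MC SEs
  frac <- c(a = 0.5, b = 0.5)
  truth <- cov_params(c(0.25, 0.25), c(0.25, 0.25), c(0.05, 0),
                      0.15, categories = names(frac))
  sp <- scenario_spec(design_preset("one_study"), truth, m = 3000,
                      reps = 25, seed = 91, annot_frac = unname(frac),
                      do_jackknife = FALSE)
  sc <- run_scenario(sp)
  est <- sc$estimates
  for (cat_truth in list(c("rho_g_a", 0.05), c("rho_g_b", 0))) {
    e <- est[[cat_truth[1]]]
    tval <- as.numeric(cat_truth[2])
    expect_lt(abs(mean(e) - tval), 3 * sd(e) / sqrt(length(e)) + 1e-3)
  }
  # totals behave like the genome-wide parameters
  expect_lt(abs(mean(est$rho_g) - 0.05),
            3 * sd(est$rho_g) / sqrt(nrow(est)) + 1e-3)
})

test_that("a null second trait reduces to a univariate heritability fit", {
  # trait 2 carries no signal; trait 1's h2 estimate matches the
  # univariate LD-score model within Monte-Carlo error
  cp <- cached_panel(600, 2500, seed = 71)
  des <- study_design(600, 600, 600)
  truth <- cov_params(0.4, 0, 0, 0)
  ests <- replicate(20, {
    sim <- simulate_study(cp$x, truth, des)
    agg <- gecko:::agg_make(cp$ld$ldscore, sim$z1, sim$z2, 2500)
    fit <- gecko:::gecko_fit_agg(agg, des, fit_options())
    sum(fit$params$h2_1)
  })
  expect_lt(abs(mean(ests) - 0.4), 3 * sd(ests) / sqrt(length(ests)))
})
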