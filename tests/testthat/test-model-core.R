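# The marginal covariance model, SNP weights and the composite
# log-likelihood.

test_that("per-SNP covariance reproduces hand arithmetic and limits", {
  des <- study_design(1000, 1000, 1000)
  S <- per_snp_covariance(cov_params(0.5, 0.5, 0.1, 0.2), des,
                          list(ldscore = 100), m_by_annot = 1000)
  expect_equal(S, matrix(c(51, 10.2, 10.2, 51), 2), tolerance = 1e-12)

  # all signal terms vanish -> identity
  S0 <- per_snp_covariance(cov_params(0, 0, 0, 0), des,
                           list(ldscore = 37), m_by_annot = 1000)
  expect_equal(S0, diag(2))

  # without overlap the residual off-diagonal is structurally zero
  des0 <- study_design(1500, 1438, 0)
  S_no <- per_snp_covariance(cov_params(0.5, 0.5, 0, 0.4), des0,
                             list(ldscore = 50), m_by_annot = 1000)
  expect_identical(S_no[1, 2], 0)
})

test_that("per-SNP covariance is linear in the variance parameters", {
  des <- study_design(800, 600, 300)
  rec <- list(ldscore = 40)
  th_a <- cov_params(0.3, 0.2, 0.05, 0.1)
  th_b <- cov_params(0.1, 0.25, -0.02, 0.05)
  th_ab <- cov_params(0.4, 0.45, 0.03, 0.15)
  th_0 <- cov_params(0, 0, 0, 0)
  lhs <- per_snp_covariance(th_a, des, rec, 500) +
    per_snp_covariance(th_b, des, rec, 500) -
    per_snp_covariance(th_0, des, rec, 500)
  expect_equal(lhs, per_snp_covariance(th_ab, des, rec, 500),
               tolerance = 1e-12)
})

test_that("stratified covariance with equal categories matches unstratified", {
  des <- study_design(900, 900, 400)
  l <- 60
  rec_u <- list(ldscore = l)
  rec_s <- list(ldscore = l, ldscore_by_annot = c(25, 35))
  p_u <- cov_params(0.4, 0.3, 0.08, 0.15)
  # per-category parameters proportional to category SNP counts, LD
  # scores summing to the total
  mks <- c(400, 600)
  p_s <- cov_params(0.4 * mks / 1000, 0.3 * mks / 1000,
                    0.08 * mks / 1000, 0.15)
  # equal per-SNP contributions require l_k/m_k = l/m
  rec_s$ldscore_by_annot <- l * mks / 1000
  expect_equal(per_snp_covariance(p_s, des, rec_s, mks),
               per_snp_covariance(p_u, des, rec_u, 1000),
               tolerance = 1e-12)
})

test_that("SNP weights invert the LD score with clamping at 1", {
  expect_equal(snp_weight(1), 1)
  expect_equal(snp_weight(5), 0.2)
  expect_equal(snp_weight(0.4), 1)  # noisy reference estimate below 1
  expect_error(snp_weight(-1), "negative")
  expect_error(snp_weight(NaN), "finite")
})

test_that("composite log-likelihood matches closed forms for independent SNPs", {
  des <- study_design(50, 50, 0)
  p0 <- cov_params(0, 0, 0, 0)
  tab <- snp_table(c("a", "b"), c("1", "1"), c(1, 2), c(0, 0), c(0, 0),
                   c(1, 1))
  expect_equal(composite_loglik(tab, p0, des), -2 * log(2 * pi),
               tolerance = 1e-12)

  set.seed(31)
  m <- 60
  z1 <- rnorm(m); z2 <- rnorm(m)
  tab2 <- snp_table(sprintf("s%02d", 1:m), rep("1", m), 1:m, z1, z2,
                    rep(1, m))
  manual <- sum(-log(2 * pi) - (z1^2 + z2^2) / 2)
  expect_equal(composite_loglik(tab2, p0, des), manual,
               tolerance = 1e-10)

  # with all l_j = 1 and arbitrary admissible parameters the composite
  # likelihood equals the exact independent-SNP joint log-likelihood
  p1 <- cov_params(0.4, 0.3, 0.1, 0.1)
  S <- per_snp_covariance(p1, des, list(ldscore = 1), m)
  Si <- solve(S)
  manual1 <- sum(-log(2 * pi) - 0.5 * log(det(S)) -
                   0.5 * (Si[1, 1] * z1^2 + 2 * Si[1, 2] * z1 * z2 +
                            Si[2, 2] * z2^2))
  expect_equal(composite_loglik(tab2, p1, des), manual1,
               tolerance = 1e-10)
})

test_that("inadmissible parameters are reported with the offending SNP", {
  des <- study_design(1000, 1000, 1000)
  tab <- snp_table(c("a", "b"), c("1", "1"), c(1, 2), c(0.5, 1),
                   c(0.2, -1), c(1, 1))
  # |rho * ns / sqrt(n1 n2)| >= 1 makes the residual matrix singular
  expect_error(composite_loglik(tab, cov_params(0, 0, 0, 1.5), des),
               "positive definite at SNP index")
})

test_that("swapping the two traits transposes the model", {
  set.seed(12)
  m <- 40
  l <- random_ldscores(m, 7)
  des <- study_design(700, 500, 300)
  des_sw <- study_design(500, 700, 300)
  p <- cov_params(0.45, 0.25, 0.07, 0.12)
  p_sw <- cov_params(0.25, 0.45, 0.07, 0.12)
  rec <- list(ldscore = l[1])
  expect_equal(per_snp_covariance(p_sw, des_sw, rec, m),
               t(per_snp_covariance(p, des, rec, m))[2:1, 2:1],
               tolerance = 1e-12)
  tab <- model_table(p, des, l, seed = 5)
  tab_sw <- snp_table(tab$snp$snp_id, tab$snp$chrom, tab$snp$bp,
                      tab$snp$z2, tab$snp$z1, tab$snp$ldscore)
  expect_equal(composite_loglik(tab_sw, p_sw, des_sw),
               composite_loglik(tab, p, des), tolerance = 1e-10)
})

test_that("duplicating every SNP record leaves the objective unchanged", {
  # duplicated genotypes double each LD score and halve each weight,
  # so the weighted objective (and hence its maximizer) is identical
  m <- 20
  l <- random_ldscores(m, 3)
  des <- study_design(400, 400, 400)
  tab <- model_table(cov_params(0.5, 0.5, 0.1, 0.2), des, l, seed = 9)
  z1 <- tab$snp$z1; z2 <- tab$snp$z2
  tab_dup <- snp_table(sprintf("d%03d", 1:(2 * m)), rep("1", 2 * m),
                       1:(2 * m), rep(z1, each = 2), rep(z2, each = 2),
                       rep(2 * tab$snp$ldscore, each = 2))
  for (p in list(cov_params(0.5, 0.5, 0.1, 0.2),
                 cov_params(0.3, 0.6, -0.1, 0),
                 cov_params(0.1, 0.1, 0, 0.05)))
    expect_equal(composite_loglik(tab_dup, p, des),
                 composite_loglik(tab, p, des), tolerance = 1e-9)
})

test_that("derived quantities follow their definitions and identifiability", {
  des <- study_design(1000, 1000, 500)
  d <- derived_quantities(cov_params(0.5, 0.5, 0.1, 0.2), des)
  expect_equal(d$rho_e, 0.1)
  expect_equal(d$gamma_g, 0.2)
  d2 <- derived_quantities(cov_params(0.5, 0.5, 0, 0.25), des)
  expect_equal(d2$gamma_e, 0.5)
  # ns = 0: environmental quantities are structurally unavailable
  d0 <- derived_quantities(cov_params(0.5, 0.5, 0.1, 0.1),
                           study_design(1000, 900, 0))
  expect_false(d0$identifiable)
  expect_true(is.na(d0$rho_e) && is.na(d0$gamma_e))
})

test_that("analytic score matches numerical derivatives", {
  skip_if_not_installed("pracma")
  set.seed(44)
  m <- 80
  l <- random_ldscores(m, 21)
  for (des in list(study_design(900, 800, 400),
                   study_design(900, 800, 0))) {
    tab <- model_table(cov_params(0.4, 0.3, 0.1, 0.15), des, l,
                       seed = 22)
    agg <- gecko:::agg_from_table(tab)
    p <- cov_params(0.35, 0.28, 0.06, if (des$ns > 0) 0.11 else 0.06)
    th <- gecko:::pack_params(p, des)
    f <- function(t)
      gecko:::agg_loglik(agg, gecko:::unpack_params(t, des, "all"), des)
    sc <- gecko:::agg_score(agg, p, des)
    expect_equal(sc$grad, pracma::grad(f, th), tolerance = 1e-6)
    expect_equal(sc$hess, pracma::hessian(f, th), tolerance = 1e-4)
  }
})
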