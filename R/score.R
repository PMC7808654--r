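## Analytic gradient and Hessian of the weighted composite
## log-likelihood on the aggregated representation.
##
## With Sigma_b = [[a, b], [b, d]] affine in the free parameters and
## per-bin weighted moments Mw_b, the objective is
##   ll = sum_b [ -W log 2pi - (W/2) log det Sigma - (1/2) tr(Sigma^-1 Mw) ],
## so with u_i = Sigma^-1 dSigma/dtheta_i,
##   d ll / dtheta_i  = sum_b [ -(W/2) tr(u_i) + (1/2) tr(u_i Sigma^-1 Mw) ]
##   d2 ll / di dj    = sum_b [ (W/2) tr(u_i u_j)
##                              - (1/2) tr((u_i u_j + u_j u_i) Sigma^-1 Mw) ].
## Every term is 2x2 algebra vectorized over bins, which makes Newton
## refits in the jackknife cheap and exact.

# Per-parameter dSigma entries as bin-length vectors (alpha = d a,
# beta = d b, delta = d d).  Parameter order matches pack_params().
sigma_derivs <- function(agg, design) {
  K <- length(agg$categories)
  n1 <- design$n1; n2 <- design$n2; sq <- sqrt(n1 * n2)
  nb <- length(agg$W)
  zero <- numeric(nb)
  out <- list()
  for (k in seq_len(K))
    out[[k]] <- list(alpha = agg$s[, k] * n1, beta = zero, delta = zero)
  for (k in seq_len(K))
    out[[K + k]] <- list(alpha = zero, beta = zero,
                         delta = agg$s[, k] * n2)
  for (k in seq_len(K))
    out[[2L * K + k]] <- list(alpha = zero, beta = agg$s[, k] * sq,
                              delta = zero)
  if (design$ns > 0)
    out[[3L * K + 1L]] <- list(alpha = zero,
                               beta = rep(design$ns / sq, nb),
                               delta = zero)
  out
}

# Gradient and (optionally) Hessian at params; NULL if inadmissible.
# dS (from sigma_derivs) is parameter-free and can be precomputed.
agg_score <- function(agg, params, design, hessian = TRUE, dS = NULL) {
  sig <- agg_sigma(agg, params, design)
  if (any(sig$a <= 0) || any(sig$det <= 0)) return(NULL)
  i11 <- sig$d / sig$det; i22 <- sig$a / sig$det; i12 <- -sig$b / sig$det
  W <- agg$W; M11 <- agg$M11; M12 <- agg$M12; M22 <- agg$M22
  if (is.null(dS)) dS <- sigma_derivs(agg, design)
  P <- length(dS)

  # u_i = Sigma^-1 dSigma_i (2x2 per bin) and Sigma^-1 Mw
  U <- lapply(dS, function(d) list(
    u11 = i11 * d$alpha + i12 * d$beta,
    u12 = i11 * d$beta + i12 * d$delta,
    u21 = i12 * d$alpha + i22 * d$beta,
    u22 = i12 * d$beta + i22 * d$delta))
  C11 <- i11 * M11 + i12 * M12; C12 <- i11 * M12 + i12 * M22
  C21 <- i12 * M11 + i22 * M12; C22 <- i12 * M12 + i22 * M22

  grad <- vapply(U, function(u) {
    sum(-W / 2 * (u$u11 + u$u22) +
          0.5 * (u$u11 * C11 + u$u12 * C21 + u$u21 * C12 + u$u22 * C22))
  }, numeric(1))
  if (!hessian) return(list(grad = grad, hess = NULL))

  H <- matrix(0, P, P)
  for (i in seq_len(P)) for (j in i:P) {
    ui <- U[[i]]; uj <- U[[j]]
    # v = u_i u_j per bin
    v11 <- ui$u11 * uj$u11 + ui$u12 * uj$u21
    v12 <- ui$u11 * uj$u12 + ui$u12 * uj$u22
    v21 <- ui$u21 * uj$u11 + ui$u22 * uj$u21
    v22 <- ui$u21 * uj$u12 + ui$u22 * uj$u22
    # w = u_j u_i per bin
    w11 <- uj$u11 * ui$u11 + uj$u12 * ui$u21
    w12 <- uj$u11 * ui$u12 + uj$u12 * ui$u22
    w21 <- uj$u21 * ui$u11 + uj$u22 * ui$u21
    w22 <- uj$u21 * ui$u12 + uj$u22 * ui$u22
    tr_uij <- v11 + v22
    tr_vC <- (v11 + w11) * C11 + (v12 + w12) * C21 +
      (v21 + w21) * C12 + (v22 + w22) * C22
    H[i, j] <- H[j, i] <- sum(W / 2 * tr_uij - 0.5 * tr_vC)
  }
  list(grad = grad, hess = H)
}
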