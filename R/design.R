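#' Study design: sample composition of the two GWASs
#'
#' Records the sample sizes of the two studies and the number of
#' individuals measured for both traits.  The overlap count \code{ns}
#' drives the residual (intercept) term of the per-SNP z-score
#' covariance: its off-diagonal is \eqn{\rho n_s / \sqrt{n_1 n_2}}, so
#' with \code{ns = 0} the total phenotypic covariance \eqn{\rho} (and
#' hence the environmental covariance \eqn{\rho_e}) is not identifiable.
#'
#' @param n1 Number of individuals measured for trait 1.
#' @param n2 Number of individuals measured for trait 2.
#' @param ns Number of individuals measured for both traits
#'   (\code{0 <= ns <= min(n1, n2)}).
#'
#' @return An object of class \code{"study_design"}: a list with
#'   elements \code{n1}, \code{n2}, \code{ns}.
#' @examples
#' study_design(2938, 2938, 2938)  # one-study design
#' study_design(1500, 1438, 0)    # two separate studies
#' study_design(2000, 1938, 1000) # partial overlap
#' @export
study_design <- function(n1, n2, ns = 0L) {
  n1 <- as.numeric(n1); n2 <- as.numeric(n2); ns <- as.numeric(ns)
  stopifnot(length(n1) == 1L, length(n2) == 1L, length(ns) == 1L,
            is.finite(n1), is.finite(n2), is.finite(ns))
  if (n1 < 1 || n2 < 1)
    stop("study sizes n1 and n2 must be >= 1", call. = FALSE)
  if (ns < 0 || ns > min(n1, n2))
    stop("overlap ns must satisfy 0 <= ns <= min(n1, n2)", call. = FALSE)
  structure(list(n1 = n1, n2 = n2, ns = ns), class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf("study design: n1 = %g, n2 = %g, overlap ns = %g (%s)\n",
              x$n1, x$n2, x$ns,
              if (x$ns == 0) "no overlap; rho_e not identifiable"
              else if (x$ns == x$n1 && x$ns == x$n2) "complete overlap"
              else "partial overlap"))
  invisible(x)
}

#' Covariance-component parameters of the bivariate model
#'
#' Holds the free parameters of the marginal z-score model: per-category
#' heritabilities of the two traits, per-category genetic covariances,
#' and the total phenotypic covariance \eqn{\rho = \rho_g + \rho_e}.
#' The environmental covariance is always derived as
#' \eqn{\rho_e = \rho - \rho_g} (see [derived_quantities()]), never a
#' free parameter, which makes its non-identifiability at \code{ns = 0}
#' structural.
#'
#' @param h2_1,h2_2 Heritability of trait 1 / trait 2; scalar for the
#'   single-component model or a vector with one entry per annotation
#'   category.  All entries must be >= 0.
#' @param rho_g Genetic covariance, same shape as the heritabilities.
#' @param rho Total phenotypic covariance \eqn{\rho_g + \rho_e}
#'   (scalar; \code{rho_g} means the per-category sum).  Defaults to
#'   \code{sum(rho_g)}, i.e. \eqn{\rho_e = 0}.
#' @param categories Optional character vector of category names.
#'
#' @return An object of class \code{"cov_params"}.
#' @examples
#' cov_params(0.5, 0.5, rho_g = 0.1, rho = 0.2)
#' cov_params(c(0.25, 0.25), c(0.25, 0.25), rho_g = c(0.05, 0),
#'            rho = 0.15, categories = c("functional", "background"))
#' @export
cov_params <- function(h2_1, h2_2, rho_g, rho = sum(rho_g),
                       categories = NULL) {
  h2_1 <- as.numeric(h2_1); h2_2 <- as.numeric(h2_2)
  rho_g <- as.numeric(rho_g); rho <- as.numeric(rho)
  K <- length(h2_1)
  stopifnot(length(h2_2) == K, length(rho_g) == K, length(rho) == 1L,
            all(is.finite(c(h2_1, h2_2, rho_g, rho))))
  if (any(h2_1 < 0) || any(h2_2 < 0))
    stop("heritabilities must be non-negative", call. = FALSE)
  if (is.null(categories)) {
    categories <- if (K == 1L) "all" else paste0("cat", seq_len(K))
  }
  stopifnot(length(categories) == K)
  structure(list(h2_1 = h2_1, h2_2 = h2_2, rho_g = rho_g, rho = rho,
                 categories = as.character(categories)),
            class = "cov_params")
}

#' @export
print.cov_params <- function(x, ...) {
  K <- length(x$h2_1)
  cat("covariance parameters", if (K > 1) sprintf("(%d categories)", K),
      "\n")
  tab <- data.frame(category = x$categories, h2_1 = x$h2_1,
                    h2_2 = x$h2_2, rho_g = x$rho_g)
  print(tab, row.names = FALSE)
  cat(sprintf("totals: h2_1 = %.4g, h2_2 = %.4g, rho_g = %.4g, rho = %.4g\n",
              sum(x$h2_1), sum(x$h2_2), sum(x$rho_g), x$rho))
  invisible(x)
}

n_categories <- function(params) length(params$h2_1)

# Unvalidated constructor for optimizer internals: intermediate
# iterates may step outside the admissible box and are policed by the
# likelihood (-Inf) and the final projection instead.
new_cov_params <- function(h2_1, h2_2, rho_g, rho, categories) {
  structure(list(h2_1 = h2_1, h2_2 = h2_2, rho_g = rho_g, rho = rho,
                 categories = categories), class = "cov_params")
}

#' Derived covariance and correlation quantities
#'
#' Converts the free parameters (heritabilities, genetic covariance,
#' total covariance \eqn{\rho}) into the quantities usually reported:
#' the environmental covariance \eqn{\rho_e = \rho - \rho_g}, the
#' genetic correlation
#' \eqn{\gamma_g = \rho_g / \sqrt{h_1^2 h_2^2}}, and the environmental
#' correlation \eqn{\gamma_e = \rho_e / \sqrt{(1 - h_1^2)(1 - h_2^2)}}.
#' Totals (sums over annotation categories) are used throughout.
#'
#' With no overlapping individuals (\code{ns = 0}) the data carry no
#' information on \eqn{\rho}, so \code{rho_e} and \code{gamma_e} are
#' returned as \code{NA} with attribute \code{identifiable = FALSE}.
#'
#' @param params A [cov_params()] object.
#' @param design A [study_design()] object.
#' @return A list with elements \code{rho_e}, \code{gamma_g},
#'   \code{gamma_e} and logical \code{identifiable} (whether the
#'   environmental components are identifiable under \code{design}).
#' @examples
#' derived_quantities(cov_params(0.5, 0.5, 0.1, rho = 0.2),
#'                    study_design(1000, 1000, 1000))
#' @export
derived_quantities <- function(params, design) {
  stopifnot(inherits(params, "cov_params"), inherits(design, "study_design"))
  h1 <- sum(params$h2_1); h2 <- sum(params$h2_2)
  rg <- sum(params$rho_g)
  identifiable <- design$ns > 0
  rho_e <- if (identifiable) params$rho - rg else NA_real_
  gamma_g <- if (h1 * h2 > 0) rg / sqrt(h1 * h2) else NA_real_
  gamma_e <- if (identifiable && (1 - h1) * (1 - h2) > 0)
    rho_e / sqrt((1 - h1) * (1 - h2)) else NA_real_
  list(rho_e = rho_e, gamma_g = gamma_g, gamma_e = gamma_e,
       identifiable = identifiable)
}
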