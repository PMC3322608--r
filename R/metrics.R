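# Model-quality metrics consumed by every decision algorithm.

#' Crystallographic R factor with optimal linear scaling
#'
#' Computes \eqn{R = \sum_{hkl} |F_{obs} - m F_{calc}| / \sum_{hkl} F_{obs}}
#' where the scale factor \eqn{m} between the calculated and observed
#' amplitudes is chosen to minimize the absolute residual. The residual is
#' convex in \eqn{m}, so the scale is located by golden-section search
#' (tolerance 1e-8).
#'
#' @param obs Numeric vector of observed structure-factor amplitudes.
#' @param calc Numeric vector of calculated amplitudes, same length.
#' @return The R factor, a non-negative fraction; 0 iff the two sets are
#'   proportional.
#' @examples
#' r_factor(c(10, 20, 30), c(10, 20, 30))   # 0
#' r_factor(c(10, 20, 30), c(5, 10, 15))    # 0, scale m = 2 absorbs the factor
#' r_factor(c(10, 20, 30), c(10, 20, 40))
#' @export
r_factor <- function(obs, calc) {
  if (length(obs) == 0L || length(obs) != length(calc)) {
    abort("`obs` and `calc` must be non-empty vectors of equal length.",
          class = "xrefine_invalid_input")
  }
  if (!all(is.finite(obs)) || !all(is.finite(calc))) {
    abort("amplitudes must be finite.", class = "xrefine_invalid_input")
  }
  if (sum(obs) <= 0) {
    abort("all-zero (or negative-sum) observed amplitudes.",
          class = "xrefine_invalid_input")
  }
  if (sum(calc) <= 0) return(1)
  # normalize the calculated set first so the search always runs on the
  # same bracket regardless of the input scale
  cs <- calc * (sum(obs) / sum(calc))
  resid <- function(m) sum(abs(obs - m * cs))
  pos <- cs > 0
  hi <- if (any(pos)) 2 * max(obs[pos] / cs[pos], 1) else 1
  m <- golden_section(resid, 0, hi, tol = 1e-8)
  resid(m) / sum(obs)
}

# Golden-section minimizer for a unimodal function on [lo, hi].
golden_section <- function(f, lo, hi, tol = 1e-8) {
  phi <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c <- b - phi * (b - a)
  d <- a + phi * (b - a)
  fc <- f(c); fd <- f(d)
  while (b - a > tol) {
    if (fc <= fd) {
      b <- d; d <- c; fd <- fc
      c <- b - phi * (b - a); fc <- f(c)
    } else {
      a <- c; c <- d; fc <- fd
      d <- a + phi * (b - a); fd <- f(d)
    }
  }
  (a + b) / 2
}

#' Estimated standard deviation of R_free
#'
#' \eqn{\sigma(R_{free}) = R_{free} / \sqrt{2 N_{test}}} where
#' \eqn{N_{test}} is the number of test-set reflections.
#'
#' @param r_free Free R factor (fraction).
#' @param n_test Number of test-set reflections (>= 1).
#' @export
sigma_r_free <- function(r_free, n_test) {
  check_number(r_free, "r_free", lower = 0)
  n_test <- check_count(n_test, "n_test", lower = 1)
  r_free / sqrt(2 * n_test)
}

#' Expected R_free for a converged unbiased refinement
#'
#' \eqn{R_{free,unb} = R \times R_{ratio}}.
#'
#' @param r Working R factor (fraction).
#' @param r_ratio Expected R_free/R ratio for a converged refinement (>= 1).
#' @export
expected_r_free <- function(r, r_ratio) {
  check_number(r, "r", lower = 0)
  check_number(r_ratio, "r_ratio", lower = 1)
  r * r_ratio
}

#' Z score of R_free against its unbiased expectation
#'
#' \eqn{Z(R_{free}) = (R_{free,unb} - R_{free}) / \sigma(R_{free})}.
#' The terms are ordered so the score is positive when the model is better
#' (lower \eqn{R_{free}}) than expected.
#'
#' @param r_free Observed free R factor.
#' @param r_free_unb Expected free R factor.
#' @param sigma Standard deviation of R_free; must be positive. A zero
#'   sigma raises a classed condition (`xrefine_undefined_z`): callers are
#'   expected to treat the Z score as unavailable and use their fallbacks.
#' @export
z_r_free <- function(r_free, r_free_unb, sigma) {
  check_number(r_free, "r_free", lower = 0)
  check_number(r_free_unb, "r_free_unb", lower = 0)
  check_number(sigma, "sigma", lower = 0)
  if (sigma == 0) {
    abort("sigma(R_free) is zero; Z(R_free) is undefined.",
          class = "xrefine_undefined_z")
  }
  (r_free_unb - r_free) / sigma
}

#' Default estimator of the expected R_free/R ratio
#'
#' The classical unrestrained data-to-parameter approximation
#' \eqn{[(N_{obs} + N_{par}) / (N_{obs} - N_{par})]^{1/2}}. Every consumer
#' of the ratio also accepts an externally supplied value, so a more
#' elaborate restrained-refinement estimate can be injected.
#'
#' @param n_obs Number of observations (working reflections).
#' @param n_param_eff Effective number of model parameters; must be
#'   strictly smaller than `n_obs`.
#' @export
estimate_r_ratio <- function(n_obs, n_param_eff) {
  n_obs <- check_count(n_obs, "n_obs", lower = 1)
  check_number(n_param_eff, "n_param_eff", lower = 0)
  if (n_obs <= n_param_eff) {
    abort("`n_obs` must exceed `n_param_eff`.", class = "xrefine_invalid_input")
  }
  sqrt((n_obs + n_param_eff) / (n_obs - n_param_eff))
}

#' Root-mean-square Z score
#'
#' r.m.s. of restraint-normalized deviations; a value near 1 means the
#' deviations match the spread of the restraint library.
#'
#' @param z_values Non-empty numeric vector of per-restraint Z scores.
#' @export
rmsz <- function(z_values) {
  if (length(z_values) == 0L || !all(is.finite(z_values))) {
    abort("`z_values` must be a non-empty finite vector.",
          class = "xrefine_invalid_input")
  }
  sqrt(mean(z_values^2))
}

#' Per-refinement statistics bundle
#'
#' One row of the metric bundle every selection algorithm consumes:
#' R, R_free, their restraint-weighted variants, geometry r.m.s. Z scores,
#' the free likelihood (lower is better) and the test-set size.
#'
#' @param label Refinement-condition label.
#' @param r,r_free Working and free R factors, fractions in [0, 1.5].
#' @param r_weighted,r_free_weighted Weighted R factors (optional, `NA` when
#'   the engine does not report them).
#' @param rmsz_bond,rmsz_angle Geometry r.m.s. Z scores (>= 0).
#' @param ll_free Free likelihood score; lower is better.
#' @param n_test_reflections Test-set size (>= 0).
#' @return A one-row tibble of class `model_stats` (rows of several calls
#'   can be bound into a candidate table for [pick()]).
#' @export
model_stats <- function(label, r, r_free,
                        r_weighted = NA_real_, r_free_weighted = NA_real_,
                        rmsz_bond = NA_real_, rmsz_angle = NA_real_,
                        ll_free = NA_real_, n_test_reflections = 0L) {
  check_number(r, "r", lower = 0, upper = 1.5)
  check_number(r_free, "r_free", lower = 0, upper = 1.5)
  if (!is.na(rmsz_bond)) check_number(rmsz_bond, "rmsz_bond", lower = 0)
  if (!is.na(rmsz_angle)) check_number(rmsz_angle, "rmsz_angle", lower = 0)
  n_test_reflections <- check_count(n_test_reflections, "n_test_reflections")
  out <- tibble::tibble(
    label = as.character(label), r = r, r_free = r_free,
    r_weighted = r_weighted, r_free_weighted = r_free_weighted,
    rmsz_bond = rmsz_bond, rmsz_angle = rmsz_angle,
    ll_free = ll_free, n_test_reflections = n_test_reflections
  )
  class(out) <- c("model_stats", class(out))
  out
}

#' Baseline quality metrics of the starting model
#'
#' The cutoff-defining quantities established before any re-refinement:
#' header R factors, recalculated R factors, the expected R_free/R ratio
#' and derived expectation/Z values, geometry baselines, the Wilson B
#' factor and the free-set bias flag. TLS-stage R factors (measured right
#' after resetting B factors, during TLS refinement) are carried optionally
#' for cutoff selection in TLS-model optimization.
#'
#' @param r_head,r_free_head R factors from the deposited header (`NA` when
#'   absent; they are never defaulted).
#' @param r_calc,r_free_calc Recalculated R factors of the stripped model.
#' @param r_ratio Expected R_free/R ratio (>= 1).
#' @param r_free_unb_calc Expected R_free; defaults to `r_calc * r_ratio`.
#' @param sigma_r_free_calc Standard deviation of R_free,calc.
#' @param z_r_free_calc Z score of R_free,calc (`NA` when undefined).
#' @param rmsz_bond_calc,rmsz_angle_calc Baseline geometry scores.
#' @param b_wilson Wilson B factor in square Angstrom.
#' @param r_tls,r_free_tls TLS-stage R factors (optional).
#' @param free_set_biased Bias flag for the free set.
#' @return A list of class `baseline_metrics`.
#' @export
baseline_metrics <- function(r_calc, r_free_calc, r_ratio,
                             r_head = NA_real_, r_free_head = NA_real_,
                             r_free_unb_calc = NULL,
                             sigma_r_free_calc = NA_real_,
                             z_r_free_calc = NA_real_,
                             rmsz_bond_calc = NA_real_,
                             rmsz_angle_calc = NA_real_,
                             b_wilson = NA_real_,
                             r_tls = NA_real_, r_free_tls = NA_real_,
                             free_set_biased = FALSE) {
  check_number(r_calc, "r_calc", lower = 0)
  check_number(r_free_calc, "r_free_calc", lower = 0)
  check_number(r_ratio, "r_ratio", lower = 1)
  if (!is.na(sigma_r_free_calc)) {
    check_number(sigma_r_free_calc, "sigma_r_free_calc", lower = 0)
  }
  structure(list(
    r_head = r_head, r_free_head = r_free_head,
    r_calc = r_calc, r_free_calc = r_free_calc,
    r_ratio = r_ratio,
    r_free_unb_calc = r_free_unb_calc %||% (r_calc * r_ratio),
    sigma_r_free_calc = sigma_r_free_calc,
    z_r_free_calc = z_r_free_calc,
    rmsz_bond_calc = rmsz_bond_calc, rmsz_angle_calc = rmsz_angle_calc,
    b_wilson = b_wilson, r_tls = r_tls, r_free_tls = r_free_tls,
    free_set_biased = isTRUE(free_set_biased)
  ), class = "baseline_metrics")
}

#' @export
print.baseline_metrics <- function(x, ...) {
  cat("Baseline metrics\n")
  cat(sprintf("  R_calc = %.4f  R_free,calc = %.4f  R_ratio = %.4f\n",
              x$r_calc, x$r_free_calc, x$r_ratio))
  cat(sprintf("  R_free,unb,calc = %.4f  Z(R_free,calc) = %s\n",
              x$r_free_unb_calc,
              ifelse(is.na(x$z_r_free_calc), "undefined",
                     sprintf("%.2f", x$z_r_free_calc))))
  cat(sprintf("  free set biased: %s\n", x$free_set_biased))
  invisible(x)
}
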