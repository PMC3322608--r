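# B-factor parameterization selection: reflections-per-atom routing and
# the Hamilton R-factor ratio test chain used to arbitrate between a
# simple and a more complex displacement model.

#' Route the B-factor parameterization by data density
#'
#' Anisotropic B factors need nine parameters per atom, isotropic four,
#' and one overall B factor only three, so the choice is driven by the
#' number of reflections per atom (RPA):
#' \itemize{
#'   \item RPA > 18: the anisotropic parameters are at least twofold
#'     overdetermined — use anisotropic B factors outright;
#'   \item 13.5 < RPA <= 18: contest anisotropic against isotropic
#'     (both trial refinements start from B factors reset to the Wilson B);
#'   \item 3 <= RPA <= 13.5: isotropic B factors;
#'   \item RPA < 3: optimize TLS first, then contest isotropic (with
#'     tight B restraints) against one overall B factor;
#'   \item if TLS cannot be used in that last regime, fall back to
#'     isotropic B factors.
#' }
#'
#' @param rpa Reflections per atom (>= 0).
#' @param tls_usable Can TLS be used (relevant only when RPA < 3)?
#' @return A list of class `parameterization_route` with `route` and the
#'   per-atom parameter counts of the simple/complex models in play.
#' @export
route_parameterization <- function(rpa, tls_usable = TRUE) {
  check_number(rpa, "rpa", lower = 0)
  if (rpa > 18) {
    route <- "aniso"; simple <- 9L; complex <- 9L
  } else if (rpa > 13.5) {
    route <- "contest_aniso_vs_iso"; simple <- 4L; complex <- 9L
  } else if (rpa >= 3) {
    route <- "iso"; simple <- 4L; complex <- 4L
  } else if (isTRUE(tls_usable)) {
    route <- "contest_iso_vs_overall"; simple <- 3L; complex <- 4L
  } else {
    route <- "iso_fallback"; simple <- 4L; complex <- 4L
  }
  structure(list(route = route,
                 params_per_atom_simple = simple,
                 params_per_atom_complex = complex),
            class = "parameterization_route")
}

#' Hamilton-test inputs
#'
#' The Hamilton R-factor ratio test needs the degrees of freedom of both
#' models, which depend on the effective number of restraints — the raw
#' restraint count multiplied by an unknown weight. Rather than guessing
#' the weight, a range of weights `w1` (basic restraints, present in both
#' models) and `w2` (extra restraints of the complex model) is scanned and
#' every combination is tested.
#'
#' @param r_free_w_simple,r_free_w_complex Weighted free R factors.
#' @param n_obs Number of observations.
#' @param n_params_simple,n_params_complex Model parameter counts
#'   (`n_params_complex > n_params_simple`).
#' @param n_restraints_base Restraints shared by both models.
#' @param n_restraints_extra Extra restraints of the complex model.
#' @param w1_grid,w2_grid Weight grids in [0, 1]; default 0 to 1 in steps
#'   of 0.1 (121 tests).
#' @param alpha Significance level of each test (default 0.05).
#' @export
hamilton_input <- function(r_free_w_simple, r_free_w_complex, n_obs,
                           n_params_simple, n_params_complex,
                           n_restraints_base, n_restraints_extra,
                           w1_grid = seq(0, 1, by = 0.1),
                           w2_grid = seq(0, 1, by = 0.1),
                           alpha = 0.05) {
  check_number(r_free_w_simple, "r_free_w_simple", lower = 0)
  check_number(r_free_w_complex, "r_free_w_complex", lower = 0)
  if (n_params_complex <= n_params_simple) {
    abort("the complex model must have more parameters than the simple one.",
          class = "xrefine_invalid_input")
  }
  if (length(w1_grid) == 0L || length(w2_grid) == 0L) {
    abort("weight grids must be non-empty.", class = "xrefine_invalid_input")
  }
  list(r_free_w_simple = r_free_w_simple,
       r_free_w_complex = r_free_w_complex,
       n_obs = check_count(n_obs, "n_obs", lower = 1),
       n_params_simple = check_count(n_params_simple, "n_params_simple"),
       n_params_complex = check_count(n_params_complex, "n_params_complex"),
       n_restraints_base = check_count(n_restraints_base, "n_restraints_base"),
       n_restraints_extra = check_count(n_restraints_extra, "n_restraints_extra"),
       w1_grid = w1_grid, w2_grid = w2_grid,
       alpha = check_number(alpha, "alpha", lower = 1e-12, upper = 0.5))
}

#' Fraction of acceptable Hamilton tests over the weight grid
#'
#' For each weight combination `(w1, w2)` the free degrees of freedom of
#' the complex model are `f = n_obs - n_params_complex +
#' w1 n_restraints_base + w2 n_restraints_extra` and the hypothesis
#' dimension is `b = (n_params_complex - n_params_simple) -
#' w2 n_restraints_extra`, floored at 1 to keep the F quantile defined.
#' The test is acceptable (the complex model is justified) iff
#' `R_free,w,simple / R_free,w,complex > [(b/f) F(alpha; b, f) + 1]^(1/2)`.
#' Grid points with `f <= 0` count as not acceptable: an under-determined
#' complex model cannot be justified.
#'
#' @param inp A [hamilton_input()].
#' @return Fraction of acceptable tests in [0, 1].
#' @export
hamilton_acceptance_fraction <- function(inp) {
  if (inp$r_free_w_complex <= 0) {
    abort("`r_free_w_complex` must be positive.", class = "xrefine_invalid_input")
  }
  ratio <- inp$r_free_w_simple / inp$r_free_w_complex
  grid <- expand.grid(w1 = inp$w1_grid, w2 = inp$w2_grid)
  f <- inp$n_obs - inp$n_params_complex +
    grid$w1 * inp$n_restraints_base + grid$w2 * inp$n_restraints_extra
  b <- pmax(1, (inp$n_params_complex - inp$n_params_simple) -
              grid$w2 * inp$n_restraints_extra)
  ok <- f > 0
  crit <- rep(Inf, nrow(grid))
  crit[ok] <- sqrt((b[ok] / f[ok]) * qf(1 - inp$alpha, b[ok], f[ok]) + 1)
  mean(ratio > crit)
}

#' Select between a simple and a complex B-factor model
#'
#' The decision chain:
#' \enumerate{
#'   \item if the weighted free R factor of the complex model is higher
#'     than the simple model's, use the simple model (no Hamilton tests
#'     are run);
#'   \item run Hamilton tests over the whole weight grid; below 30%
#'     acceptable use the simple model, above 95% use the complex model
#'     (both strict, so the 30--95% band falls through);
#'   \item in the inconclusive band, look for overrefinement of the
#'     complex model: use the simple model if `Z(R_free)_complex < -3.0`;
#'     when Z is unavailable, use the simple model if
#'     `R_free,complex - R_complex` exceeds 4 percentage points
#'     (anisotropic complex model) or 6 (isotropic); finally use the
#'     simple model if that gap is more than twice the simple model's
#'     gap. Otherwise the complex model is adopted.
#' }
#'
#' @param simple,complex [model_stats()] rows for the two models.
#' @param inp A [hamilton_input()]; ignored if `acceptance_fraction` is
#'   supplied.
#' @param z_complex `Z(R_free)` of the complex model, or `NULL`/`NA` when
#'   it cannot be computed (R_ratio unavailable or sigma zero).
#' @param complex_kind `"aniso"` or `"iso"`: the complex model's kind,
#'   selecting the 4% or 6% gap cutoff.
#' @param acceptance_fraction Optional externally computed acceptance
#'   fraction (bypasses the Hamilton grid).
#' @return A list of class `bselect_decision` with `choice` (`"simple"`
#'   or `"complex"`), `acceptance_fraction`, and `steps`, the trace of
#'   rules evaluated.
#' @export
bselect <- function(simple, complex, inp = NULL, z_complex = NULL,
                    complex_kind = c("aniso", "iso"),
                    acceptance_fraction = NULL) {
  complex_kind <- match.arg(complex_kind)
  steps <- character()
  decide <- function(choice, frac) {
    structure(list(choice = choice, acceptance_fraction = frac,
                   steps = steps), class = "bselect_decision")
  }

  # (i) weighted free R comparison
  if (complex$r_free_weighted > simple$r_free_weighted) {
    steps <- c(steps, "weighted_r_free_higher")
    return(decide("simple", NA_real_))
  }
  steps <- c(steps, "weighted_r_free_ok")

  # (ii) Hamilton band
  frac <- acceptance_fraction %||% hamilton_acceptance_fraction(inp)
  if (frac < 0.30) {
    steps <- c(steps, "hamilton_below_30")
    return(decide("simple", frac))
  }
  if (frac > 0.95) {
    steps <- c(steps, "hamilton_above_95")
    return(decide("complex", frac))
  }
  steps <- c(steps, "hamilton_inconclusive")

  # (iii) overrefinement checks on the complex model
  if (!is.null(z_complex) && !is.na(z_complex)) {
    if (z_complex < -3.0) {
      steps <- c(steps, "z_complex_too_low")
      return(decide("simple", frac))
    }
    steps <- c(steps, "z_complex_ok")
  } else {
    cutoff <- if (complex_kind == "aniso") 0.04 else 0.06
    if ((complex$r_free - complex$r) > cutoff) {
      steps <- c(steps, "gap_exceeds_cutoff")
      return(decide("simple", frac))
    }
    steps <- c(steps, "gap_within_cutoff")
  }
  if ((complex$r_free - complex$r) > 2.0 * (simple$r_free - simple$r)) {
    steps <- c(steps, "gap_ratio_exceeded")
    return(decide("simple", frac))
  }
  steps <- c(steps, "no_overrefinement")
  decide("complex", frac)
}

#' @export
print.bselect_decision <- function(x, ...) {
  cat(sprintf("B-factor model choice: %s", x$choice))
  if (!is.na(x$acceptance_fraction)) {
    cat(sprintf(" (%.1f%% of Hamilton tests acceptable)",
                100 * x$acceptance_fraction))
  }
  cat("\n  steps:", paste(x$steps, collapse = " -> "), "\n")
  invisible(x)
}

#' @exportS3Method generics::glance
glance.bselect_decision <- function(x, ...) {
  tibble::tibble(choice = x$choice,
                 acceptance_fraction = x$acceptance_fraction,
                 n_steps = length(x$steps))
}
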