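# R_free test-set management: validation, creation, bias detection and
# baseline adjustment. Proper handling of the cross-validation set is a
# precondition for every later decision that compares R_free values.

free_set_decision <- function(action, fraction_free, n_free,
                              biased = FALSE, baseline_r_free = NA_real_,
                              protocol = "normal") {
  structure(list(action = action, fraction_free = fraction_free,
                 n_free = n_free, biased = isTRUE(biased),
                 baseline_r_free = baseline_r_free, protocol = protocol),
            class = "free_set_decision")
}

#' @export
print.free_set_decision <- function(x, ...) {
  cat(sprintf("Free-set decision: %s (%d reflections, %.2f%%)\n",
              x$action, x$n_free, 100 * x$fraction_free))
  cat(sprintf("  biased: %s  protocol: %s\n", x$biased, x$protocol))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.free_set_decision <- function(x, ...) {
  tibble::tibble(action = x$action, n_free = x$n_free,
                 fraction_free = x$fraction_free, biased = x$biased,
                 baseline_r_free = x$baseline_r_free, protocol = x$protocol)
}

#' Validate an existing R_free set
#'
#' If the flagged test set is larger than the work set, the two are
#' swapped first. The (possibly swapped) test set is then rejected if it
#' contains more than 25% of all reflections or fewer than 500
#' reflections; both comparisons are strict, so boundary values are kept.
#'
#' @param n_total Total number of reflections.
#' @param n_free Number of reflections flagged free.
#' @return A `free_set_decision` with action `"keep"`,
#'   `"swap_then_keep"` or `"reject"`.
#' @export
validate_free_set <- function(n_total, n_free) {
  n_total <- check_count(n_total, "n_total", lower = 1)
  n_free <- check_count(n_free, "n_free")
  if (n_free > n_total) {
    abort("`n_free` cannot exceed `n_total`.", class = "xrefine_invalid_input")
  }
  swapped <- n_free > n_total - n_free
  kept <- if (swapped) n_total - n_free else n_free
  if (kept > 0.25 * n_total || kept < 500L) {
    return(free_set_decision("reject", kept / n_total, kept))
  }
  free_set_decision(if (swapped) "swap_then_keep" else "keep",
                    kept / n_total, kept)
}

#' Create a new R_free set
#'
#' A fresh test set targets 5% of the reflections. If that yields fewer
#' than 1000 reflections the fraction is raised just far enough to reach
#' 1000, capped at 10%. Selection is uniform without replacement and
#' reproducible from the seed. A newly created set is always flagged
#' biased: the "free" reflections were part of the original refinement.
#'
#' @param n_total Total number of reflections.
#' @param seed Integer seed for the selection.
#' @return A list with `flags` (integer vector of length `n_total`,
#'   1 = free) and `decision`, a `free_set_decision` with
#'   action `"created"` and `biased = TRUE`.
#' @export
create_free_set <- function(n_total, seed) {
  n_total <- check_count(n_total, "n_total", lower = 1)
  n_free <- ceiling(0.05 * n_total)
  if (n_free < 1000L) {
    n_free <- min(1000L, floor(0.10 * n_total))
  }
  n_free <- max(1L, as.integer(n_free))
  idx <- withr::with_seed(seed, sample.int(n_total, n_free))
  flags <- integer(n_total)
  flags[idx] <- 1L
  list(flags = flags,
       decision = free_set_decision("created", n_free / n_total, n_free,
                                    biased = TRUE))
}

#' Test whether the recalculated R_free is biased
#'
#' R_free,calc is treated as biased — i.e. the test set was plausibly used
#' in the original refinement — if any of the following hold:
#' \enumerate{
#'   \item a new test set was just created;
#'   \item R_free,calc < R_calc;
#'   \item Z(R_free,calc) > 10.0 (far better than its unbiased
#'     expectation);
#'   \item the recalculated R_free - R gap is much smaller than the
#'     header gap: R_free,calc - R_calc < 0.33 (R_free,head - R_head).
#' }
#' Condition 4 is skipped when the header R values are unavailable.
#'
#' @param base A [baseline_metrics()] object.
#' @param set_was_created Was the free set newly created?
#' @return Logical bias flag.
#' @export
assess_bias <- function(base, set_was_created = FALSE) {
  if (isTRUE(set_was_created)) return(TRUE)
  if (base$r_free_calc < base$r_calc) return(TRUE)
  if (!is.na(base$z_r_free_calc) && base$z_r_free_calc > 10.0) return(TRUE)
  if (!is.na(base$r_free_head) && !is.na(base$r_head)) {
    if ((base$r_free_calc - base$r_calc) <
        0.33 * (base$r_free_head - base$r_head)) {
      return(TRUE)
    }
  }
  FALSE
}

#' Baseline adjustments for a biased free set
#'
#' A biased R_free,calc is not usable as a baseline: the expected value
#' R_free,unb,calc replaces it, and the refinement protocol is adapted by
#' resetting atomic B factors to the Wilson B and extending the cycle
#' count (the `reset_b_and_extend` protocol, consumed by
#' [assign_cycles()] via the `new_free_set` context flag).
#'
#' @param biased Logical bias flag (from [assess_bias()]).
#' @param base A [baseline_metrics()] object.
#' @return A `free_set_decision` carrying the baseline R_free to use and
#'   the protocol.
#' @export
baseline_adjustments <- function(biased, base) {
  if (isTRUE(biased)) {
    free_set_decision("keep", NA_real_, NA_integer_, biased = TRUE,
                      baseline_r_free = base$r_free_unb_calc,
                      protocol = "reset_b_and_extend")
  } else {
    free_set_decision("keep", NA_real_, NA_integer_, biased = FALSE,
                      baseline_r_free = base$r_free_calc,
                      protocol = "normal")
  }
}
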