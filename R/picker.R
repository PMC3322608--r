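# Selection of the optimal refinement from a candidate set, with
# overfitting guards tied to the quality of the starting structure.

#' Establish picker cutoff values
#'
#' R cutoffs come from the stage the candidates originate from: the
#' TLS-stage R factors for TLS-model optimization, the recalculated
#' baseline R factors otherwise. When the free set is biased the
#' unbiased expectation replaces R_free,calc. Geometry cutoffs default to
#' 1.0 but are relaxed to the baseline r.m.s. Z values when those exceed
#' 1.0 (a model that started with loose geometry is not required to
#' tighten it).
#'
#' @param base A [baseline_metrics()] object.
#' @param source `"general"` or `"tls_opt"`.
#' @return A list of class `picker_cutoffs`.
#' @export
establish_cutoffs <- function(base, source = c("general", "tls_opt")) {
  source <- match.arg(source)
  if (source == "tls_opt") {
    if (is.na(base$r_tls) || is.na(base$r_free_tls)) {
      abort("TLS-stage R factors are required for tls_opt cutoffs.",
            class = "xrefine_invalid_input")
    }
    r_co <- base$r_tls
    r_free_co <- base$r_free_tls
  } else {
    r_co <- base$r_calc
    r_free_co <- if (base$free_set_biased) base$r_free_unb_calc else base$r_free_calc
  }
  structure(list(
    r_co = r_co, r_free_co = r_free_co,
    rmsz_bond_co = max(1.0, base$rmsz_bond_calc, na.rm = TRUE),
    rmsz_angle_co = max(1.0, base$rmsz_angle_calc, na.rm = TRUE),
    source = source
  ), class = "picker_cutoffs")
}

#' Maximum allowed R_free for one refinement condition
#'
#' Three stages, applied in order: the expectation plus noise band
#' `m = r_i R_ratio + 3.5 sigma_i`; a cap `m = min(m, r_i + 0.06)` so the
#' R_free - R gap never grows beyond six percentage points; and a floor
#' `m = max(m, (R_free,co / R_co) r_i)` so structures that started with a
#' high R_free/R ratio are not rejected wholesale. When the expectation
#' term is unavailable (no R_ratio, or sigma undefined), the cap branch
#' alone provides the bound before the floor is applied.
#'
#' @param r_i Working R factor of the candidate.
#' @param r_ratio Expected R_free/R ratio, or `NA` when unavailable.
#' @param sigma_i sigma(R_free) of the candidate, or `NA`.
#' @param cut A `picker_cutoffs` object.
#' @export
r_free_max <- function(r_i, r_ratio, sigma_i, cut) {
  check_number(r_i, "r_i", lower = 0)
  if (cut$r_co <= 0) {
    abort("R_co must be positive.", class = "xrefine_invalid_input")
  }
  if (!is.na(r_ratio) && !is.na(sigma_i) && sigma_i > 0) {
    m <- r_i * r_ratio + 3.5 * sigma_i
    m <- min(m, r_i + 0.06)
  } else {
    m <- r_i + 0.06
  }
  max(m, (cut$r_free_co / cut$r_co) * r_i)
}

#' Pick the optimal refinement from a candidate set
#'
#' Each candidate is rejected if any metric exceeds the preset limits:
#' r.m.s. Z(bond) or Z(angle) above its cutoff, R_free above the
#' per-candidate maximum ([r_free_max()]), or R_free above the baseline
#' cutoff. For models in the `vlow`/`xlow` categories the R_free - R gap
#' may additionally not exceed twice the baseline gap. Among the
#' survivors, the candidates with the lowest free likelihood and the
#' lowest R_free are located; if they differ, the one with the higher
#' `Z(R_free)` wins (an undefined Z loses). Exact ties resolve to the
#' lower R_free, then to input order. An empty survivor set is a valid
#' outcome (`chosen = NA`): the caller adapts, e.g. by falling back to
#' automatic weighting.
#'
#' @param candidates A `model_stats` tibble (one row per refinement
#'   condition; bind rows of [model_stats()]).
#' @param cut A `picker_cutoffs` object.
#' @param r_ratio Expected R_free/R ratio, or `NA` when unavailable.
#' @param category Optional [assign_category()] result; the extra gap test
#'   applies when its name is `vlow` or `xlow`.
#' @return A list of class `picker_selection`: `chosen` (label or `NA`),
#'   `candidates` (per-candidate table with limits, Z scores and rejection
#'   reasons) and the cutoffs used.
#' @export
pick <- function(candidates, cut, r_ratio = NA_real_, category = NULL) {
  if (!is.data.frame(candidates) || nrow(candidates) == 0L) {
    abort("`candidates` must be a non-empty model_stats table.",
          class = "xrefine_invalid_input")
  }
  gap_test <- !is.null(category) && category$name %in% c("vlow", "xlow")

  n <- nrow(candidates)
  sigma_i <- rfmax <- z <- rep(NA_real_, n)
  reasons <- vector("list", n)
  for (i in seq_len(n)) {
    ci <- candidates[i, ]
    if (ci$n_test_reflections >= 1L) {
      sigma_i[i] <- sigma_r_free(ci$r_free, ci$n_test_reflections)
    }
    rfmax[i] <- r_free_max(ci$r, r_ratio, sigma_i[i], cut)
    if (!is.na(r_ratio) && !is.na(sigma_i[i]) && sigma_i[i] > 0) {
      z[i] <- (ci$r * r_ratio - ci$r_free) / sigma_i[i]
    }
    why <- character()
    if (!is.na(ci$rmsz_bond) && ci$rmsz_bond > cut$rmsz_bond_co) {
      why <- c(why, "rmsz_bond_above_cutoff")
    }
    if (!is.na(ci$rmsz_angle) && ci$rmsz_angle > cut$rmsz_angle_co) {
      why <- c(why, "rmsz_angle_above_cutoff")
    }
    if (ci$r_free > rfmax[i]) why <- c(why, "r_free_above_max")
    if (ci$r_free > cut$r_free_co) why <- c(why, "r_free_above_baseline")
    if (gap_test && (ci$r_free - ci$r) > 2.0 * (cut$r_free_co - cut$r_co)) {
      why <- c(why, "gap_above_twice_baseline")
    }
    reasons[[i]] <- why
  }
  tab <- dplyr::mutate(tibble::as_tibble(candidates),
                       sigma_r_free = sigma_i, r_free_max = rfmax,
                       z_r_free = z,
                       rejected = vapply(reasons, length, 1L) > 0L,
                       reasons = reasons)

  surv <- which(!tab$rejected)
  chosen <- NA_character_
  if (length(surv) > 0L) {
    ll <- tab$ll_free[surv]
    best_ll <- surv[order(ll, tab$r_free[surv])][1L]
    best_rf <- surv[order(tab$r_free[surv])][1L]
    if (best_ll == best_rf) {
      chosen <- tab$label[best_ll]
    } else {
      z2 <- tab$z_r_free[c(best_ll, best_rf)]
      z2[is.na(z2)] <- -Inf            # an undefined Z loses the comparison
      pair <- c(best_ll, best_rf)
      if (z2[1L] == z2[2L]) {
        ord <- order(tab$r_free[pair], pair)  # tie: lower R_free, then input order
        chosen <- tab$label[pair[ord[1L]]]
      } else {
        chosen <- tab$label[pair[which.max(z2)]]
      }
    }
  }
  structure(list(chosen = chosen, candidates = tab, cutoffs = cut,
                 r_ratio = r_ratio),
            class = "picker_selection")
}

#' @export
print.picker_selection <- function(x, ...) {
  if (is.na(x$chosen)) {
    cat("Picker: no candidate passed the limits.\n")
  } else {
    cat(sprintf("Picker: chose '%s' out of %d candidates (%d rejected).\n",
                x$chosen, nrow(x$candidates), sum(x$candidates$rejected)))
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.picker_selection <- function(x, ...) {
  dplyr::mutate(
    dplyr::select(x$candidates, "label", "r", "r_free", "rmsz_bond",
                  "rmsz_angle", "ll_free", "sigma_r_free", "r_free_max",
                  "z_r_free", "rejected", "reasons"),
    chosen = .data$label == (x$chosen %||% NA_character_) &
      !is.na(x$chosen))
}

#' @exportS3Method generics::glance
glance.picker_selection <- function(x, ...) {
  tibble::tibble(chosen = x$chosen,
                 n_candidates = nrow(x$candidates),
                 n_rejected = sum(x$candidates$rejected),
                 r_free_co = x$cutoffs$r_free_co,
                 r_co = x$cutoffs$r_co)
}

#' Plot a picker selection
#'
#' Candidate R and R_free against the per-candidate R_free maximum and
#' the baseline cutoffs; rejected candidates are greyed.
#'
#' @param object A `picker_selection`.
#' @param ... Unused.
#' @method autoplot picker_selection
#' @export
autoplot.picker_selection <- function(object, ...) {
  tab <- tidy(object)
  long <- tidyr::pivot_longer(tab, c("r", "r_free"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$label, y = .data$value,
                                     shape = .data$metric,
                                     colour = .data$rejected)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_point(data = tab,
                        mapping = ggplot2::aes(x = .data$label,
                                               y = .data$r_free_max),
                        shape = 95, size = 6, colour = "grey40",
                        inherit.aes = FALSE) +
    ggplot2::geom_hline(yintercept = object$cutoffs$r_free_co,
                        linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "black",
                                            `TRUE` = "grey65")) +
    ggplot2::labs(x = "refinement condition", y = "R factor",
                  colour = "rejected", shape = NULL) +
    ggplot2::theme_minimal()
}
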