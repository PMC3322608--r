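# The pipeline state machine. All reciprocal-space work is delegated to
# an abstract refinement engine; this module owns the decisions: baseline
# reproduction with its escalation ladder, twin policy, TLS planning,
# strategy assembly, candidate selection, rebuilding dispatch and change
# classification. Every branch taken is recorded in a decision report.

#' An abstract refinement engine
#'
#' The contract a refinement backend must satisfy. All four operations
#' must be deterministic for fixed inputs and settings. `model` is opaque
#' to the pipeline and is passed back to the engine unchanged.
#'
#' @param calculate `function(model, settings)`: compute statistics
#'   without refinement; returns a [model_stats()] row. Settings may
#'   include `tls` (logical), `twin` (logical) and `b_reset` (numeric
#'   target for resetting atomic B factors).
#' @param refine `function(model, settings)`: restrained refinement;
#'   returns `list(model, stats)`. Settings include `weight` (restraint
#'   weight, `NA` = automatic), `cycles`, `tls`, `twin`, `jelly_body`.
#' @param rigid_body `function(model, settings)`: rigid-body refinement;
#'   returns `list(model, stats)`.
#' @param tls_refine `function(model, tls_model, settings)`: TLS
#'   refinement; returns `list(model, stats)`.
#' @export
refinement_engine <- function(calculate, refine, rigid_body, tls_refine) {
  for (f in list(calculate, refine, rigid_body, tls_refine)) {
    if (!is.function(f)) {
      abort("all engine operations must be functions.",
            class = "xrefine_invalid_input")
    }
  }
  structure(list(calculate = calculate, refine = refine,
                 rigid_body = rigid_body, tls_refine = tls_refine),
            class = "refinement_engine")
}

# decision report ----------------------------------------------------------

new_report <- function() {
  structure(list(trace = tibble::tibble(step = integer(),
                                        decision = character(),
                                        inputs = character(),
                                        outcome = character(),
                                        rule = character()),
                 status = "running"),
            class = "decision_report")
}

trace_add <- function(report, decision, inputs, outcome, rule) {
  report$trace <- dplyr::bind_rows(report$trace, tibble::tibble(
    step = nrow(report$trace) + 1L,
    decision = decision,
    inputs = as.character(inputs),
    outcome = as.character(outcome),
    rule = rule
  ))
  report
}

#' @export
print.decision_report <- function(x, ...) {
  cat(sprintf("Decision report: %s (%d decision points)\n",
              x$status, nrow(x$trace)))
  print(x$trace, n = nrow(x$trace))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.decision_report <- function(x, ...) x$trace

#' @exportS3Method generics::glance
glance.decision_report <- function(x, ...) {
  tibble::tibble(status = x$status, n_decisions = nrow(x$trace))
}

#' Serialize a decision report to JSON
#'
#' Byte-stable serialization: two runs with identical inputs and seed
#' produce identical strings.
#'
#' @param x A `decision_report`.
#' @export
report_json <- function(x) {
  jsonlite::toJSON(list(status = x$status, trace = x$trace),
                   dataframe = "rows", auto_unbox = TRUE, digits = NA,
                   pretty = TRUE)
}

# baseline reproduction ----------------------------------------------------

#' Reproduce the deposited R factor
#'
#' Recalculates R for the stripped model and tries to reproduce the
#' header value before any real refinement:
#' \enumerate{
#'   \item the TLS ambiguity (are the deposited B factors total or
#'     residual?) is resolved by evaluating with and without the header
#'     TLS model and keeping the lower R_calc;
#'   \item while `R_calc - R_head` exceeds 5 percentage points an
#'     escalation ladder runs, in order: evaluation with twin target
#'     functions (only when the externally detected twin fraction exceeds
#'     5%), rigid-body refinement (10 cycles, 15 for legacy models), and
#'     5 cycles of TLS refinement with the header tensors (possible
#'     tensor corruption); a rung's result is kept when it lowers R_calc,
#'     and an engine failure at a rung is recorded while the ladder
#'     continues;
#'   \item a remaining gap above 10 percentage points means something is
#'     inherently wrong with the entry and the pipeline stops.
#' }
#'
#' @param engine A [refinement_engine()].
#' @param model Opaque model object for the engine.
#' @param header Header list (see [extract_header()]); `r_head` must be
#'   present or the run aborts with status `aborted_no_r_head`.
#' @param twin_fraction_external Twin fraction from external analysis of
#'   the data (fraction, not percent).
#' @param legacy Is this a pre-1990 model?
#' @param r_ratio Expected R_free/R ratio for the baseline (`NA` =
#'   estimate unavailable).
#' @param report Optional `decision_report` to append to.
#' @return A list of class `baseline_result`: `status` (`"completed"`,
#'   `"aborted_no_r_head"` or `"aborted_unreproducible"`), `baseline`
#'   (a [baseline_metrics()] or `NULL`), `model`, `report`.
#' @export
reproduce_baseline <- function(engine, model, header,
                               twin_fraction_external = 0,
                               legacy = FALSE, r_ratio = NA_real_,
                               report = new_report()) {
  finish <- function(status, baseline = NULL) {
    report$status <- status
    structure(list(status = status, baseline = baseline, model = model,
                   report = report),
              class = "baseline_result")
  }
  if (is.na(header$r_head)) {
    report <- trace_add(report, "baseline_r_head", "r_head=NA",
                        "aborted_no_r_head", "abort_no_r_factor")
    return(finish("aborted_no_r_head"))
  }

  use_tls <- FALSE
  if (length(header$tls_groups) > 0L) {
    s_with <- engine$calculate(model, list(tls = TRUE))
    s_without <- engine$calculate(model, list(tls = FALSE))
    use_tls <- s_with$r < s_without$r
    stats <- if (use_tls) s_with else s_without
    report <- trace_add(report, "tls_ambiguity",
                        sprintf("r_with=%.4f r_without=%.4f",
                                s_with$r, s_without$r),
                        if (use_tls) "b_factors_residual" else "b_factors_total",
                        "tls_ambiguity_lowest_r")
  } else {
    stats <- engine$calculate(model, list(tls = FALSE))
    report <- trace_add(report, "tls_ambiguity", "no_header_tls",
                        "b_factors_total", "tls_ambiguity_lowest_r")
  }

  gap <- function() stats$r - header$r_head
  try_rung <- function(name, fn) {
    res <- tryCatch(fn(), error = function(e) e)
    if (inherits(res, "error")) {
      report <<- trace_add(report, paste0("ladder_", name), sprintf("gap=%.4f", gap()),
                           "engine_failure", "ladder_continue_on_failure")
      return(invisible(NULL))
    }
    new_stats <- if (is.data.frame(res)) res else res$stats
    adopted <- new_stats$r < stats$r
    if (adopted) {
      stats <<- new_stats
      if (!is.data.frame(res) && !is.null(res$model)) model <<- res$model
    }
    report <<- trace_add(report, paste0("ladder_", name),
                         sprintf("r=%.4f", new_stats$r),
                         if (adopted) "adopted" else "not_adopted",
                         paste0("ladder_", name))
    invisible(NULL)
  }

  if (gap() > 0.05) {
    if (twin_fraction_external > 0.05) {
      try_rung("twin", function() engine$calculate(model, list(tls = use_tls,
                                                               twin = TRUE)))
    } else {
      report <- trace_add(report, "ladder_twin",
                          sprintf("twin_fraction=%.3f", twin_fraction_external),
                          "skipped_low_twin_fraction", "twin_gate_5pct")
    }
  }
  if (gap() > 0.05) {
    cyc <- assign_cycles(cycle_context("rigid_reproduce", legacy = legacy))
    try_rung("rigid_body", function() engine$rigid_body(model, list(cycles = cyc)))
  }
  if (gap() > 0.05 && length(header$tls_groups) > 0L) {
    cyc <- assign_cycles(cycle_context("tls_reproduce"))
    try_rung("tls", function() engine$tls_refine(model, header$tls_groups,
                                                 list(cycles = cyc)))
  }

  if (gap() > 0.10) {
    report <- trace_add(report, "baseline_gap",
                        sprintf("gap=%.4f", gap()),
                        "aborted_unreproducible", "abort_gap_10pct")
    return(finish("aborted_unreproducible"))
  }
  report <- trace_add(report, "baseline_gap", sprintf("gap=%.4f", gap()),
                      "reproduced", "gap_within_10pct")

  sigma <- if (stats$n_test_reflections >= 1L) {
    sigma_r_free(stats$r_free, stats$n_test_reflections)
  } else NA_real_
  z <- if (!is.na(r_ratio) && !is.na(sigma) && sigma > 0) {
    z_r_free(stats$r_free, stats$r * r_ratio, sigma)
  } else NA_real_
  base <- baseline_metrics(
    r_calc = stats$r, r_free_calc = stats$r_free,
    r_ratio = if (is.na(r_ratio)) 1 else r_ratio,
    r_head = header$r_head, r_free_head = header$r_free_head,
    sigma_r_free_calc = sigma, z_r_free_calc = z,
    rmsz_bond_calc = stats$rmsz_bond, rmsz_angle_calc = stats$rmsz_angle
  )
  report$status <- "completed"
  finish("completed", base)
}

# twin policy --------------------------------------------------------------

#' Decide whether to refine with twin target functions
#'
#' Gated on the external twin-fraction estimate: only when it exceeds 5%
#' is the engine's twin-operator analysis consulted. Twin refinement is
#' then used iff at least one operator has `R_merge < 44%` (strict) and a
#' twin fraction above 7%.
#'
#' @param sfcheck_fraction Twin fraction from external data analysis.
#' @param engine_twin_ops Tibble of engine-detected twin operators with
#'   columns `r_merge` and `fraction` (both fractions in [0, 1]); only
#'   consulted when the gate passes.
#' @return Logical: refine with twin target functions?
#' @export
twin_policy <- function(sfcheck_fraction, engine_twin_ops = NULL) {
  check_number(sfcheck_fraction, "sfcheck_fraction", lower = 0, upper = 1)
  if (sfcheck_fraction <= 0.05) return(FALSE)
  if (is.null(engine_twin_ops) || nrow(engine_twin_ops) == 0L) return(FALSE)
  any(engine_twin_ops$r_merge < 0.44 & engine_twin_ops$fraction > 0.07)
}

# TLS planning -------------------------------------------------------------

#' Plan the TLS model
#'
#' Atomic B factors are reset to the Wilson B (or the mean model B at
#' resolutions of 4 Angstrom or worse), giving the TLS-stage reference
#' values R_TLS / R_free,TLS. Candidate TLS parameterizations are then
#' assembled — a simple one-group-per-chain model, the header TLS model
#' when present, and any user-supplied models — each refined by the
#' engine, and judged by [pick()] with TLS-stage cutoffs. TLS is adopted
#' only if the chosen candidate *decreases* R_free relative to
#' R_free,TLS (strict).
#'
#' @param engine A [refinement_engine()].
#' @param model Opaque model object.
#' @param header Header list (header TLS model candidate).
#' @param chains Character vector of chain identifiers (per-chain
#'   candidate).
#' @param user_models Named list of additional TLS models.
#' @param resolution Data resolution in Angstrom.
#' @param b_wilson Wilson B factor.
#' @param mean_b Mean model B factor (reset target at >= 4 Angstrom).
#' @param base A [baseline_metrics()] (updated with the TLS-stage R
#'   factors in the returned value).
#' @param r_ratio Expected R_free/R ratio.
#' @param legacy Legacy model flag (cycle counts).
#' @return List of class `tls_plan`: `use_tls`, `tls_model` (name or
#'   `NA`), `b_reset_target`, `selection` (the picker result), `base`
#'   (baseline with `r_tls`/`r_free_tls` filled in).
#' @export
plan_tls <- function(engine, model, header, chains = "A",
                     user_models = list(), resolution = 2.0,
                     b_wilson = NA_real_, mean_b = NA_real_,
                     base = NULL, r_ratio = NA_real_, legacy = FALSE) {
  b_reset <- if (resolution >= 4) mean_b else b_wilson
  ref <- engine$calculate(model, list(tls = FALSE, b_reset = b_reset))
  base$r_tls <- ref$r
  base$r_free_tls <- ref$r_free

  candidates <- list(per_chain = list(kind = "per_chain", chains = chains))
  if (length(header$tls_groups) > 0L) {
    candidates$header <- list(kind = "header", groups = header$tls_groups)
  }
  for (nm in names(user_models)) candidates[[nm]] <- user_models[[nm]]

  cyc <- assign_cycles(cycle_context("tls_optimize", legacy = legacy))
  stats <- NULL
  models <- list()
  for (nm in names(candidates)) {
    res <- tryCatch(
      engine$tls_refine(model, candidates[[nm]],
                        list(cycles = cyc, b_reset = b_reset)),
      error = function(e) NULL)
    if (is.null(res)) next
    s <- res$stats
    s$label <- nm
    stats <- dplyr::bind_rows(stats, s)
    models[[nm]] <- res$model
  }
  if (is.null(stats) || nrow(stats) == 0L) {
    return(structure(list(use_tls = FALSE, tls_model = NA_character_,
                          b_reset_target = b_reset, selection = NULL,
                          base = base),
                     class = "tls_plan"))
  }
  cut <- establish_cutoffs(base, "tls_opt")
  sel <- pick(stats, cut, r_ratio = r_ratio)
  use <- FALSE
  chosen <- NA_character_
  if (!is.na(sel$chosen)) {
    chosen_rf <- stats$r_free[stats$label == sel$chosen][[1L]]
    use <- chosen_rf < base$r_free_tls   # adoption requires a decrease
    if (use) chosen <- sel$chosen
  }
  structure(list(use_tls = use, tls_model = chosen,
                 b_reset_target = b_reset, selection = sel, base = base,
                 model = if (use) models[[chosen]] else model),
            class = "tls_plan")
}

# change classification ----------------------------------------------------

CHANGE_METRICS <- c("r_free", "z_rama", "z_rotamer", "z_packing_coarse",
                    "z_packing_fine", "bumps", "hbond_unsat")

#' Classify the change between two models
#'
#' Per-metric better/same/worse verdicts over the seven model-quality
#' metrics: R_free (band: twice its standard deviation), the four
#' normality Z scores — Ramachandran, rotamer, coarse and fine packing —
#' (band 0.1, higher is better), the bump count (band 10) and the count
#' of unsatisfied hydrogen-bond donors/acceptors (band 2); for the last
#' three, fewer is better.
#'
#' @param before,after Named lists or one-row data frames with entries
#'   `r_free`, `z_rama`, `z_rotamer`, `z_packing_coarse`,
#'   `z_packing_fine`, `bumps`, `hbond_unsat`.
#' @param sigma_r_free sigma(R_free) used for the R_free band.
#' @return Tibble with `metric`, `delta`, `verdict`.
#' @export
classify_change <- function(before, after, sigma_r_free) {
  if (length(setdiff(CHANGE_METRICS, names(before))) > 0L ||
      length(setdiff(CHANGE_METRICS, names(after))) > 0L) {
    abort("both metric sets must be complete.", class = "xrefine_invalid_input")
  }
  band <- c(r_free = 2 * sigma_r_free, z_rama = 0.1, z_rotamer = 0.1,
            z_packing_coarse = 0.1, z_packing_fine = 0.1,
            bumps = 10, hbond_unsat = 2)
  higher_better <- c(r_free = FALSE, z_rama = TRUE, z_rotamer = TRUE,
                     z_packing_coarse = TRUE, z_packing_fine = TRUE,
                     bumps = FALSE, hbond_unsat = FALSE)
  delta <- vapply(CHANGE_METRICS,
                  function(m) as.numeric(after[[m]]) - as.numeric(before[[m]]),
                  numeric(1))
  verdict <- ifelse(abs(delta) <= band[CHANGE_METRICS], "same",
                    ifelse((delta > 0) == higher_better[CHANGE_METRICS],
                           "better", "worse"))
  tibble::tibble(metric = CHANGE_METRICS, delta = unname(delta),
                 verdict = unname(verdict))
}

# full pipeline ------------------------------------------------------------

#' Run the full decision pipeline
#'
#' Sequences the whole optimization: reflection sanitation, free-set
#' validation/creation and bias handling, baseline reproduction, category
#' and strategy assembly (twin policy, B-factor route, TLS plan, cycle
#' counts), restraint-weight re-refinement with candidate selection,
#' rebuilding dispatch (water pruning always; peptide-flip and side-chain
#' stages only for the atomic/high/medium/low categories), final
#' refinement with the chosen weight and one grid step to either side (or
#' automatic weighting when re-refinement selection failed), and change
#' classification. Deterministic for a fixed engine, inputs and seed.
#'
#' @param engine A [refinement_engine()].
#' @param inputs List with `reflections` (reflection table), `model`
#'   (opaque), `header`, `resolution`, `n_atoms`, `twin_fraction`,
#'   `twin_operators` (tibble or `NULL`), `b_wilson`, `mean_b`, `chains`,
#'   `r_ratio`, `waters` (tibble with `id`, `score`, or `NULL`),
#'   `linked_water_ids`, `residues`/`links`/`altlocs`/`ss` for rebuild
#'   selection, `findings` (validation findings or `NULL`),
#'   `quality_before`/`quality_after` (optional metric sets for change
#'   classification).
#' @param config Optional [category_config()].
#' @param seed Integer seed (free-set creation).
#' @return List of class `pipeline_result`: `report` (decision report),
#'   `final_selection`, `rerefine_selection`, `baseline`, `category`,
#'   `verdict` (change classification or `NULL`), `model`.
#' @export
run_pipeline <- function(engine, inputs, config = category_config(),
                         seed = 1L) {
  report <- new_report()

  # 1. reflection sanitation
  san <- sanitize_reflections(inputs$reflections)
  refl <- san$reflections
  report <- trace_add(report, "sanitize_reflections",
                      sprintf("n_in=%d", nrow(inputs$reflections)),
                      sprintf("n_out=%d neg_amp=%d sigma_reset=%d",
                              nrow(refl),
                              san$log$n_rejected_negative_amplitudes,
                              san$log$n_sigma_reset),
                      "reflection_sanitation")

  # 2. free set
  n_total <- nrow(refl)
  n_free <- sum(refl$free_flag == 1L, na.rm = TRUE)
  set_was_created <- FALSE
  if (n_free > 0L) {
    fsd <- validate_free_set(n_total, n_free)
    report <- trace_add(report, "validate_free_set",
                        sprintf("n_total=%d n_free=%d", n_total, n_free),
                        fsd$action, "free_set_bounds")
    if (fsd$action == "reject") {
      created <- create_free_set(n_total, seed)
      refl$free_flag <- created$flags
      fsd <- created$decision
      set_was_created <- TRUE
      report <- trace_add(report, "create_free_set",
                          sprintf("n_total=%d", n_total),
                          sprintf("n_free=%d", fsd$n_free),
                          "free_set_creation")
    }
  } else {
    created <- create_free_set(n_total, seed)
    refl$free_flag <- created$flags
    fsd <- created$decision
    set_was_created <- TRUE
    report <- trace_add(report, "create_free_set",
                        sprintf("n_total=%d", n_total),
                        sprintf("n_free=%d", fsd$n_free),
                        "free_set_creation")
  }

  # 3. baseline reproduction
  legacy <- !is.na(inputs$header$deposition_year) &&
    inputs$header$deposition_year < 1990L
  bres <- reproduce_baseline(engine, inputs$model, inputs$header,
                             twin_fraction_external = inputs$twin_fraction %||% 0,
                             legacy = legacy,
                             r_ratio = inputs$r_ratio %||% NA_real_,
                             report = report)
  report <- bres$report
  if (bres$status != "completed") {
    return(structure(list(report = report, final_selection = NULL,
                          rerefine_selection = NULL, baseline = NULL,
                          category = NULL, verdict = NULL,
                          model = bres$model),
                     class = "pipeline_result"))
  }
  base <- bres$baseline
  model <- bres$model

  # 4. free-set bias
  biased <- assess_bias(base, set_was_created)
  base$free_set_biased <- biased
  adj <- baseline_adjustments(biased, base)
  report <- trace_add(report, "free_set_bias",
                      sprintf("created=%s z=%.2f", set_was_created,
                              base$z_r_free_calc %||% NA_real_),
                      sprintf("biased=%s protocol=%s", biased, adj$protocol),
                      "free_set_bias_rules")

  # 5. category
  rpa <- reflections_per_atom(n_total, inputs$n_atoms)
  category <- assign_category(inputs$resolution, rpa, config)
  report <- trace_add(report, "assign_category",
                      sprintf("resolution=%.2f rpa=%.2f",
                              inputs$resolution, rpa),
                      category$name, "category_table")

  # 6. twin policy
  twin <- twin_policy(inputs$twin_fraction %||% 0, inputs$twin_operators)
  report <- trace_add(report, "twin_policy",
                      sprintf("fraction=%.3f", inputs$twin_fraction %||% 0),
                      if (twin) "twin_targets" else "no_twin", "twin_gates")

  # 7. B-factor route + TLS plan
  route <- route_parameterization(rpa, tls_usable = inputs$tls_usable %||% TRUE)
  report <- trace_add(report, "route_parameterization",
                      sprintf("rpa=%.2f", rpa), route$route, "rpa_routing")
  use_tls <- FALSE
  if (route$route != "aniso") {
    plan <- plan_tls(engine, model, inputs$header,
                     chains = inputs$chains %||% "A",
                     user_models = inputs$user_tls %||% list(),
                     resolution = inputs$resolution,
                     b_wilson = inputs$b_wilson %||% NA_real_,
                     mean_b = inputs$mean_b %||% NA_real_,
                     base = base, r_ratio = base$r_ratio, legacy = legacy)
    base <- plan$base
    use_tls <- plan$use_tls
    if (use_tls) model <- plan$model
    report <- trace_add(report, "plan_tls",
                        sprintf("candidates=%s",
                                if (is.null(plan$selection)) 0L
                                else nrow(plan$selection$candidates)),
                        if (use_tls) sprintf("tls:%s", plan$tls_model)
                        else "no_tls", "tls_adoption_requires_decrease")
  } else {
    report <- trace_add(report, "plan_tls", "route=aniso", "skipped",
                        "aniso_route_no_tls")
  }

  # 8. cycles
  aniso <- route$route == "aniso"
  cyc <- assign_cycles(cycle_context("rerefine", legacy = legacy,
                                     tls_in_use = use_tls,
                                     new_free_set = biased,
                                     anisotropic = aniso))
  report <- trace_add(report, "assign_cycles",
                      sprintf("legacy=%s tls=%s new_free=%s aniso=%s",
                              legacy, use_tls, biased, aniso),
                      cyc, "cycle_rules")

  # 9. re-refinement over the weight grid
  cut <- establish_cutoffs(base, "general")
  weights <- category$weight_grid
  stats <- NULL
  models <- list()
  for (k in seq_along(weights)) {
    res <- engine$refine(model, list(weight = weights[[k]], cycles = cyc,
                                     tls = use_tls, twin = twin,
                                     jelly_body = category$jelly_body))
    s <- res$stats
    s$label <- sprintf("w%02d", k)
    stats <- dplyr::bind_rows(stats, s)
    models[[s$label]] <- res$model
  }
  sel <- pick(stats, cut, r_ratio = base$r_ratio, category = category)
  report <- trace_add(report, "pick_rerefine",
                      sprintf("n_candidates=%d", nrow(stats)),
                      if (is.na(sel$chosen)) "none" else sel$chosen,
                      "picker")

  auto_weight <- is.na(sel$chosen)
  if (auto_weight) {
    # keep rebuilding from the original model; final refinement falls
    # back to automatic restraint weighting
    rebuilt_from <- model
    chosen_weight <- NA_real_
  } else {
    rebuilt_from <- models[[sel$chosen]]
    chosen_weight <- weights[[match(sel$chosen, stats$label)]]
  }

  # 10. rebuilding dispatch
  if (!is.null(inputs$waters)) {
    cf <- centrifuge(inputs$waters, inputs$linked_water_ids %||% character())
    report <- trace_add(report, "centrifuge",
                        sprintf("n_waters=%d", nrow(inputs$waters)),
                        sprintf("removed=%d", nrow(cf$removed)),
                        "centrifuge_cutoff")
  }
  rebuild <- category$name %in% c("atomic", "high", "medium", "low")
  if (rebuild && !is.null(inputs$residues)) {
    elig <- rebuild_candidates(inputs$residues, inputs$links,
                               inputs$altlocs, inputs$ss)
    report <- trace_add(report, "rebuild_selection",
                        sprintf("n_residues=%d", nrow(elig)),
                        sprintf("pepflip=%d sidechain=%d",
                                sum(elig$pepflip_eligible),
                                sum(elig$sidechain_eligible)),
                        "rebuild_negative_selection")
    if (!is.null(inputs$findings)) {
      tasks <- validation_tasks(inputs$findings, elig)
      report <- trace_add(report, "validation_tasks",
                          sprintf("n_findings=%d", nrow(inputs$findings)),
                          sprintf("n_tasks=%d", nrow(tasks)),
                          "validation_positive_selection")
    }
  } else {
    report <- trace_add(report, "rebuild_selection", category$name,
                        "skipped_low_resolution_category",
                        "rebuild_category_gate")
  }

  # 11. final refinement: chosen weight plus one grid step either side,
  #     or automatic weighting on selection failure
  if (auto_weight) {
    final_weights <- NA_real_
    labels <- "auto"
  } else {
    k <- match(sel$chosen, stats$label)
    ks <- unique(pmin(pmax(c(k - 1L, k, k + 1L), 1L), length(weights)))
    final_weights <- weights[ks]
    labels <- sprintf("final_w%02d", ks)
  }
  fstats <- NULL
  fmodels <- list()
  for (k in seq_along(final_weights)) {
    res <- engine$refine(rebuilt_from,
                         list(weight = final_weights[[k]], cycles = cyc,
                              tls = use_tls, twin = twin,
                              jelly_body = category$jelly_body))
    s <- res$stats
    s$label <- labels[[k]]
    fstats <- dplyr::bind_rows(fstats, s)
    fmodels[[s$label]] <- res$model
  }
  fsel <- pick(fstats, cut, r_ratio = base$r_ratio, category = category)
  report <- trace_add(report, "pick_final",
                      sprintf("weights=%s",
                              if (auto_weight) "auto"
                              else paste(sprintf("%.3g", final_weights),
                                         collapse = ",")),
                      if (is.na(fsel$chosen)) "none" else fsel$chosen,
                      if (auto_weight) "final_auto_weighting"
                      else "final_weight_bracket")

  # 12. change classification
  verdict <- NULL
  if (!is.null(inputs$quality_before) && !is.null(inputs$quality_after)) {
    verdict <- classify_change(inputs$quality_before, inputs$quality_after,
                               base$sigma_r_free_calc)
    n_better <- sum(verdict$verdict == "better")
    n_worse <- sum(verdict$verdict == "worse")
    report <- trace_add(report, "classify_change",
                        sprintf("sigma=%.4f", base$sigma_r_free_calc),
                        sprintf("better=%d same=%d worse=%d", n_better,
                                sum(verdict$verdict == "same"), n_worse),
                        "change_bands")
  }

  report$status <- "completed"
  final_model <- if (!is.na(fsel$chosen)) fmodels[[fsel$chosen]] else rebuilt_from
  structure(list(report = report, final_selection = fsel,
                 rerefine_selection = sel, baseline = base,
                 category = category, verdict = verdict,
                 model = final_model, chosen_weight = chosen_weight),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("Pipeline %s\n", x$report$status))
  if (!is.null(x$rerefine_selection)) {
    cat(sprintf("  re-refinement choice: %s\n",
                x$rerefine_selection$chosen %||% "none"))
  }
  if (!is.null(x$final_selection)) {
    cat(sprintf("  final choice: %s\n", x$final_selection$chosen %||% "none"))
  }
  invisible(x)
}
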