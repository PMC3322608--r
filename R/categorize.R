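# Resolution / data-density categories and refinement cycle assignment.

# Default restraint-weight search spaces per category. The number of
# weights shrinks with resolution: at high resolution the data can
# discriminate between many weights, at very low resolution only automatic
# weighting is sensible. Grids are log-spaced and overridable via
# category_config().
default_weight_grids <- function() {
  logspace <- function(hi, lo, n) exp(seq(log(hi), log(lo), length.out = n))
  list(
    atomic = logspace(5, 0.01, 7),
    high   = logspace(5, 0.01, 7),
    medium = logspace(2, 0.01, 5),
    low    = logspace(1, 0.01, 4),
    vlow   = logspace(0.5, 0.01, 3),
    xlow   = NA_real_              # automatic weighting only
  )
}

default_b_weight_grids <- function() {
  logspace <- function(hi, lo, n) exp(seq(log(hi), log(lo), length.out = n))
  list(
    atomic = logspace(4, 0.5, 5),
    high   = logspace(4, 0.5, 5),
    medium = logspace(3, 0.5, 4),
    low    = logspace(2, 0.5, 3),
    vlow   = logspace(1.5, 0.5, 2),
    xlow   = NA_real_
  )
}

#' Category configuration
#'
#' Weight search spaces per category, overridable from a YAML-style list
#' (e.g. `yaml::read_yaml()` output with elements `weight_grids` and/or
#' `b_weight_grids`, each a named list of numeric vectors).
#'
#' @param overrides Optional named list of overrides.
#' @return List with `weight_grids` and `b_weight_grids`.
#' @export
category_config <- function(overrides = NULL) {
  cfg <- list(weight_grids = default_weight_grids(),
              b_weight_grids = default_b_weight_grids())
  if (!is.null(overrides)) {
    for (slot in intersect(names(overrides), names(cfg))) {
      for (nm in names(overrides[[slot]])) {
        cfg[[slot]][[nm]] <- as.numeric(overrides[[slot]][[nm]])
      }
    }
  }
  cfg
}

#' Assign a structure-model category
#'
#' Categories drive the restraint-weight search spaces, jelly-body use and
#' rebuilding eligibility. The reflections-per-atom (RPA) rule takes
#' precedence over data resolution: models with very few data per atom are
#' treated as (very) low resolution regardless of the nominal resolution.
#' Resolution bins are half-open `[lower, upper)`:
#' atomic < 1.20, high [1.20, 1.70), medium [1.70, 2.80), low [2.80, 3.50),
#' vlow [3.50, 5.00), xlow >= 5.00 Angstrom; RPA < 1.0 forces xlow and
#' 1.0 <= RPA < 2.5 forces vlow.
#'
#' @param resolution Data resolution in Angstrom.
#' @param reflections_per_atom Number of X-ray reflections per atom.
#' @param config Optional [category_config()].
#' @return A list of class `refine_category` with `name`, `jelly_body`,
#'   `weight_grid` and `b_weight_grid`.
#' @export
assign_category <- function(resolution, reflections_per_atom,
                            config = category_config()) {
  check_number(resolution, "resolution", lower = 1e-6)
  check_number(reflections_per_atom, "reflections_per_atom", lower = 0)
  name <-
    if (reflections_per_atom < 1.0) "xlow"
    else if (reflections_per_atom < 2.5) "vlow"
    else if (resolution >= 5.00) "xlow"
    else if (resolution >= 3.50) "vlow"
    else if (resolution >= 2.80) "low"
    else if (resolution >= 1.70) "medium"
    else if (resolution >= 1.20) "high"
    else "atomic"
  structure(list(
    name = name,
    jelly_body = name %in% c("vlow", "xlow"),
    weight_grid = config$weight_grids[[name]],
    b_weight_grid = config$b_weight_grids[[name]]
  ), class = "refine_category")
}

#' @export
print.refine_category <- function(x, ...) {
  cat(sprintf("Category '%s' (jelly-body: %s, %d restraint weights)\n",
              x$name, x$jelly_body, length(x$weight_grid)))
  invisible(x)
}

#' Reflections per atom
#'
#' @param n_reflections Number of reflections.
#' @param n_atoms Number of atoms (>= 1).
#' @export
reflections_per_atom <- function(n_reflections, n_atoms) {
  check_number(n_reflections, "n_reflections", lower = 0)
  n_atoms <- check_count(n_atoms, "n_atoms", lower = 1)
  n_reflections / n_atoms
}

#' Refinement cycle context
#'
#' @param task One of `"rigid_reproduce"`, `"tls_reproduce"`,
#'   `"tls_optimize"`, `"tls_final"`, `"rerefine"`,
#'   `"b_model_iso_vs_aniso"`, `"b_weight_opt"`.
#' @param legacy Model predates 1990?
#' @param tls_in_use Will TLS models be used?
#' @param new_free_set Was a new free set created (biased baseline)?
#' @param anisotropic Anisotropic atomic B factors (excludes TLS)?
#' @export
cycle_context <- function(task, legacy = FALSE, tls_in_use = FALSE,
                          new_free_set = FALSE, anisotropic = FALSE) {
  tasks <- c("rigid_reproduce", "tls_reproduce", "tls_optimize", "tls_final",
             "rerefine", "b_model_iso_vs_aniso", "b_weight_opt")
  if (!is.character(task) || length(task) != 1L || !(task %in% tasks)) {
    abort("unknown refinement task.", class = "xrefine_invalid_input")
  }
  if (isTRUE(anisotropic) && isTRUE(tls_in_use)) {
    abort("anisotropic B factors exclude TLS.", class = "xrefine_invalid_input")
  }
  list(task = task, legacy = isTRUE(legacy), tls_in_use = isTRUE(tls_in_use),
       new_free_set = isTRUE(new_free_set), anisotropic = isTRUE(anisotropic))
}

#' Assign the number of refinement cycles
#'
#' Empirical cycle counts per refinement task. Re-refinement uses 20
#' cycles by default, 30 when a new free set was created, 40 with
#' anisotropic B factors, and 50/60 for legacy (pre-1990) models
#' (60 anisotropic); five extra cycles are added when no TLS model is in
#' use (applied to the 20- and 30-cycle bases). Rigid-body reproduction
#' uses 10 cycles (15 legacy); TLS reproduction and final TLS update use
#' 5; TLS-model optimization uses 10 (15 legacy); deciding between
#' isotropic and anisotropic B factors uses 50; B-restraint weight
#' optimization uses 10 with TLS, 15 without.
#'
#' @param ctx A [cycle_context()].
#' @return Integer cycle count.
#' @export
assign_cycles <- function(ctx) {
  switch(ctx$task,
    rigid_reproduce = if (ctx$legacy) 15L else 10L,
    tls_reproduce = 5L,
    tls_optimize = if (ctx$legacy) 15L else 10L,
    tls_final = 5L,
    rerefine = {
      if (ctx$legacy) {
        if (ctx$anisotropic) 60L else 50L
      } else if (ctx$anisotropic) {
        40L
      } else {
        base <- if (ctx$new_free_set) 30L else 20L
        base + (if (ctx$tls_in_use) 0L else 5L)
      }
    },
    b_model_iso_vs_aniso = 50L,
    b_weight_opt = if (ctx$tls_in_use) 10L else 15L,
    abort("unknown refinement task.", class = "xrefine_invalid_input")
  )
}
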