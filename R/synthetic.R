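# Synthetic generators for every input class: reflection data with
# plantable defects, a deterministic simulated refinement engine with a
# known optimal restraint weight, and density maps with waters planted in
# peaks and in flat solvent. These exist so that every decision path of
# the pipeline can be exercised and asserted against planted ground truth
# without any external program or download.

#' Synthetic study profile
#'
#' Bundles every parameter of the synthetic generators. Defaults describe
#' a routine medium-resolution case: a 2.0 Angstrom dataset with about
#' 2000 unique reflections over 500 atoms (4 reflections per atom), a
#' true R of 0.18 with a 0.04 R_free - R gap, 5% relative amplitude
#' noise, and an engine response whose free R factor is convex in the log
#' restraint weight.
#'
#' @param n_reflections Approximate number of unique reflections.
#' @param resolution Resolution limit in Angstrom.
#' @param n_atoms Number of atoms in the model.
#' @param true_r Converged working R factor of the engine.
#' @param r_free_gap R_free - R gap at convergence.
#' @param noise_sd Relative sigma of the amplitudes.
#' @param seed Base seed; all generators derive their streams from it.
#' @param b_wilson Wilson B factor (amplitude falloff and B-reset target).
#' @param n_test Test-set size reported by the engine.
#' @param opt_weight The restraint weight at which the engine's R_free is
#'   minimal (the planted optimum).
#' @param curvature Curvature of R_free in log-weight around the optimum.
#' @param rmsz_base,rmsz_slope Bond r.m.s. Z at the tightest weight and
#'   its increase per log-weight unit as restraints loosen.
#' @param tls_gain Decrease of R_free when TLS refinement is used
#'   (negative values make TLS hurt, so the plan declines it).
#' @param baseline_r R_calc of the starting model before any ladder rung.
#' @param rung_gains Named numeric: decrease of R_calc delivered by the
#'   `twin`, `rigid` and `tls` baseline-ladder rungs.
#' @param defect_negative_amplitudes,defect_zero_sigma Planted defect
#'   counts for sanitation tests.
#' @param defect_extra_dataset Append a duplicate second dataset?
#' @export
synthetic_profile <- function(n_reflections = 2000, resolution = 2.0,
                              n_atoms = 500, true_r = 0.18,
                              r_free_gap = 0.04, noise_sd = 0.05,
                              seed = 1L, b_wilson = 30,
                              n_test = 1000L,
                              opt_weight = 0.3, curvature = 0.004,
                              rmsz_base = 0.4, rmsz_slope = 0.12,
                              tls_gain = 0.01,
                              baseline_r = NULL,
                              rung_gains = c(twin = 0.0, rigid = 0.0,
                                             tls = 0.0),
                              defect_negative_amplitudes = 0L,
                              defect_zero_sigma = 0L,
                              defect_extra_dataset = FALSE) {
  structure(list(
    n_reflections = n_reflections, resolution = resolution,
    n_atoms = n_atoms, true_r = true_r, r_free_gap = r_free_gap,
    noise_sd = noise_sd, seed = as.integer(seed), b_wilson = b_wilson,
    n_test = as.integer(n_test),
    opt_weight = opt_weight, curvature = curvature,
    rmsz_base = rmsz_base, rmsz_slope = rmsz_slope,
    tls_gain = tls_gain,
    baseline_r = baseline_r %||% (true_r + 0.02),
    rung_gains = rung_gains,
    defect_negative_amplitudes = as.integer(defect_negative_amplitudes),
    defect_zero_sigma = as.integer(defect_zero_sigma),
    defect_extra_dataset = isTRUE(defect_extra_dataset)
  ), class = "synthetic_profile")
}

#' Generate a synthetic reflection dataset
#'
#' Enumerates the unique Miller indices of a P1 toy cell sized to yield
#' roughly `n_reflections` reflections at the profile's resolution, draws
#' intensities from a Wilson-like exponential distribution attenuated by
#' the Wilson B factor, converts to amplitudes, assigns relative sigmas,
#' and flags a 5% free set. Defects (negative amplitudes, zero sigmas, a
#' duplicated second dataset) are planted on request for sanitation
#' tests.
#'
#' @param profile A [synthetic_profile()].
#' @return A reflection table; attribute `lattice` holds the cell.
#' @export
gen_reflections <- function(profile) {
  d <- profile$resolution
  # half-sphere count ~ (4/3) pi (a/d)^3 / 2 for a cubic P1 cell
  a <- d * (2 * profile$n_reflections * 3 / (4 * pi))^(1 / 3)
  lat <- lattice(a, a, a)
  uniq <- unique_reflections(lat, d)
  n <- nrow(uniq)
  refl <- withr::with_seed(profile$seed, {
    s2 <- inv_d2(lat, uniq$h, uniq$k, uniq$l)
    intensity <- rexp(n) * exp(-profile$b_wilson * s2 / 2)
    value <- sqrt(intensity)
    sigma <- pmax(profile$noise_sd * value, 1e-6)
    free <- integer(n)
    free[sample.int(n, max(1L, round(0.05 * n)))] <- 1L
    out <- reflection_table(uniq$h, uniq$k, uniq$l, value, sigma,
                            kind = "amplitude", free_flag = free,
                            dataset_id = "1")
    if (profile$defect_negative_amplitudes > 0L) {
      idx <- sample.int(n, profile$defect_negative_amplitudes)
      out$value[idx] <- -abs(out$value[idx]) - 1e-6
    }
    if (profile$defect_zero_sigma > 0L) {
      ok <- which(out$value >= 0)
      idx <- sample(ok, min(profile$defect_zero_sigma, length(ok)))
      out$sigma[idx] <- 0
    }
    if (profile$defect_extra_dataset) {
      dup <- out
      dup$dataset_id <- "2"
      out <- dplyr::bind_rows(out, dup)
    }
    out
  })
  attr(refl, "lattice") <- lat
  refl
}

#' A deterministic simulated refinement engine
#'
#' Implements the [refinement_engine()] contract with closed-form
#' responses so selection algorithms can be asserted against planted
#' ground truth: R_free is a convex quadratic in the log restraint
#' weight with its minimum at `opt_weight`; the bond/angle r.m.s. Z
#' grows linearly in log-weight as restraints loosen; TLS refinement
#' shifts R_free by `-tls_gain`; the baseline ladder rungs lower R_calc
#' by the configured `rung_gains`. All responses are pure functions of
#' the model state and settings, so the engine is deterministic by
#' construction.
#'
#' The opaque model state is a list: `r` (current working R),
#' `tls_applied`, `rungs_applied`.
#'
#' @param profile A [synthetic_profile()].
#' @return A [refinement_engine()].
#' @export
simulated_engine <- function(profile) {
  p <- profile
  gap <- p$r_free_gap

  stats_for <- function(r, rmsz_b = p$rmsz_base, rmsz_a = p$rmsz_base,
                        label = "calc") {
    model_stats(label = label, r = r, r_free = r + gap,
                r_weighted = r, r_free_weighted = r + gap,
                rmsz_bond = rmsz_b, rmsz_angle = rmsz_a,
                ll_free = 1e4 * (r + gap), n_test_reflections = p$n_test)
  }

  calculate <- function(model, settings = list()) {
    r <- model$r %||% p$baseline_r
    if (isTRUE(settings$tls)) r <- r - p$tls_gain
    if (isTRUE(settings$twin)) r <- r - (p$rung_gains[["twin"]] %||% 0)
    if (!is.null(settings$b_reset)) r <- r + 0.005  # B reset perturbs R slightly
    stats_for(r)
  }

  rigid_body <- function(model, settings = list()) {
    r <- (model$r %||% p$baseline_r) - (p$rung_gains[["rigid"]] %||% 0)
    model$r <- min(model$r %||% p$baseline_r, r)
    list(model = model, stats = stats_for(r))
  }

  tls_refine <- function(model, tls_model, settings = list()) {
    kind <- if (is.list(tls_model) && !is.null(tls_model$kind)) tls_model$kind
            else "header"
    base_r <- (model$r %||% p$baseline_r) + 0.005   # from the B-reset state
    # the per-chain model is the planted best TLS candidate; a negative
    # tls_gain makes every candidate worse than the reference
    gain <- if (identical(kind, "per_chain")) p$tls_gain else p$tls_gain / 2
    gain <- gain + (p$rung_gains[["tls"]] %||% 0)
    model$tls_applied <- TRUE
    list(model = model, stats = stats_for(base_r - gain, label = kind))
  }

  refine <- function(model, settings = list()) {
    w <- settings$weight
    r0 <- p$true_r
    if (is.null(w) || is.na(w)) {
      # automatic weighting lands near, but not at, the optimum
      rf <- r0 + gap + p$curvature * 0.25
      rz <- p$rmsz_base + p$rmsz_slope * 0.5
    } else {
      lw <- log(w / p$opt_weight)
      rf <- r0 + gap + p$curvature * lw^2
      rz <- p$rmsz_base + p$rmsz_slope * max(0, log(w / 0.01))
    }
    if (isTRUE(settings$tls)) rf <- rf - p$tls_gain / 2
    model$r <- rf - gap
    list(model = model,
         stats = model_stats(label = "refined", r = rf - gap, r_free = rf,
                             r_weighted = rf - gap, r_free_weighted = rf,
                             rmsz_bond = rz, rmsz_angle = rz,
                             ll_free = 1e4 * rf,
                             n_test_reflections = p$n_test))
  }

  refinement_engine(calculate = calculate, refine = refine,
                    rigid_body = rigid_body, tls_refine = tls_refine)
}

#' Generate a synthetic density map with planted waters
#'
#' A Gaussian-sum density over a toy orthogonal grid: strong peaks with a
#' water centred in each (the "real" waters) plus waters placed in flat
#' solvent (the spurious ones). The intended class of every water is
#' recorded so pruning decisions can be checked against ground truth.
#'
#' @param profile A [synthetic_profile()].
#' @param n_peak_waters,n_flat_waters Waters planted in peaks / in flat
#'   solvent.
#' @param peak_height Peak density amplitude (flat background is 0.05).
#' @param grid_n Grid points per axis.
#' @param spacing Grid spacing in Angstrom.
#' @return List with `map` (a [grid_map()]) and `waters` (an
#'   [atom_table()] with columns `id` and `intended` =
#'   `"peak"`/`"solvent"` appended).
#' @export
gen_map_and_waters <- function(profile, n_peak_waters = 6L,
                               n_flat_waters = 6L, peak_height = 1.0,
                               grid_n = 32L, spacing = 0.8) {
  withr::with_seed(profile$seed + 1L, {
    ext <- (grid_n - 1L) * spacing
    margin <- 3
    place <- function(n) {
      cbind(runif(n, margin, ext - margin), runif(n, margin, ext - margin),
            runif(n, margin, ext - margin))
    }
    peaks <- place(n_peak_waters)
    flats <- place(n_flat_waters)
    ax <- (seq_len(grid_n) - 1L) * spacing
    vals <- array(0.05, dim = c(grid_n, grid_n, grid_n))
    for (i in seq_len(n_peak_waters)) {
      dx2 <- outer(outer((ax - peaks[i, 1])^2, (ax - peaks[i, 2])^2, "+"),
                   (ax - peaks[i, 3])^2, "+")
      vals <- vals + peak_height * exp(-dx2 / (2 * 0.8^2))
    }
    pos <- rbind(peaks, flats)
    n <- nrow(pos)
    waters <- atom_table(
      name = "O", element = "O", residue = "HOH", chain = "W",
      resno = seq_len(n), x = pos[, 1], y = pos[, 2], z = pos[, 3],
      occupancy = 1, b_factor = 20
    )
    waters$id <- sprintf("W/%d/O", waters$resno)
    waters$intended <- rep(c("peak", "solvent"),
                           c(n_peak_waters, n_flat_waters))
    list(map = grid_map(vals, origin = c(0, 0, 0),
                        spacing = rep(spacing, 3)),
         waters = waters)
  })
}

#' Assemble full synthetic pipeline inputs
#'
#' Builds everything [run_pipeline()] consumes from one profile: the
#' reflection table, an opaque starting model, a header whose R value
#' matches the profile's baseline, geometry for rebuilding selection and
#' quality metrics for change classification.
#'
#' @param profile A [synthetic_profile()].
#' @return An inputs list for [run_pipeline()].
#' @export
gen_pipeline_inputs <- function(profile) {
  refl <- gen_reflections(profile)
  header <- empty_header()
  header$r_head <- profile$baseline_r
  header$r_free_head <- profile$baseline_r + profile$r_free_gap
  header$deposition_year <- 2005L
  residues <- tibble::tibble(chain = "A", resno = 1:20,
                             resname = rep("ALA", 20))
  mw <- gen_map_and_waters(profile)
  scored <- score_waters(mw$map, mw$waters)
  quality_before <- list(r_free = profile$baseline_r + profile$r_free_gap,
                         z_rama = -1.3, z_rotamer = -1.2,
                         z_packing_coarse = -0.24, z_packing_fine = -0.97,
                         bumps = 108, hbond_unsat = 43)
  quality_after <- list(r_free = profile$true_r + profile$r_free_gap,
                        z_rama = -0.61, z_rotamer = -0.24,
                        z_packing_coarse = -0.12, z_packing_fine = -0.70,
                        bumps = 82, hbond_unsat = 37)
  list(
    reflections = refl,
    model = list(r = NULL),
    header = header,
    resolution = profile$resolution,
    n_atoms = profile$n_atoms,
    twin_fraction = 0,
    twin_operators = NULL,
    b_wilson = profile$b_wilson,
    mean_b = profile$b_wilson,
    chains = "A",
    r_ratio = 1 + profile$r_free_gap / profile$true_r,
    waters = scored,
    linked_water_ids = character(),
    residues = residues,
    links = NULL, altlocs = NULL, ss = NULL,
    findings = tibble::tibble(chain = "A", resno = c(3L, 7L),
                              restype = c("ASN", "THR"),
                              issue = c("hn_flip", "chirality")),
    quality_before = quality_before,
    quality_after = quality_after
  )
}

#' Score a set of waters against a map
#'
#' Convenience wrapper: one [density_fit()] call per water.
#'
#' @param map A [grid_map()].
#' @param waters An [atom_table()] with an `id` column.
#' @return `waters` with a `score` column.
#' @export
score_waters <- function(map, waters) {
  waters$score <- vapply(seq_len(nrow(waters)), function(i) {
    density_fit(map, waters[i, , drop = FALSE])$score
  }, numeric(1))
  waters
}
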