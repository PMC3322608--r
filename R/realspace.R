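# Real-space density-fit scoring and the decisions that consume it:
# water pruning and rebuilding candidate selection.

#' Default per-element atom radii (Angstrom)
#'
#' Small van der Waals-like table used by [density_fit()]; any element
#' not listed falls back to the `default` entry. Override by passing a
#' named vector.
#' @export
default_atom_radii <- function() {
  c(C = 1.7, N = 1.55, O = 1.52, S = 1.8, P = 1.8, H = 1.2, default = 1.7)
}

#' A gridded density volume
#'
#' A minimal orthogonal-grid density container: an origin, per-axis grid
#' spacing and a 3-D array of density values (the layout CCP4-convention
#' maps reduce to after axis ordering).
#'
#' @param values 3-D numeric array of density values.
#' @param origin Cartesian origin (Angstrom) of the first grid point.
#' @param spacing Grid spacing per axis (Angstrom), all positive.
#' @export
grid_map <- function(values, origin = c(0, 0, 0), spacing = c(1, 1, 1)) {
  if (!is.array(values) || length(dim(values)) != 3L) {
    abort("`values` must be a 3-D array.", class = "xrefine_invalid_input")
  }
  if (!all(is.finite(values))) {
    abort("map values must be finite.", class = "xrefine_invalid_input")
  }
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (any(spacing <= 0)) {
    abort("grid spacing must be positive.", class = "xrefine_invalid_input")
  }
  structure(list(values = values, origin = rep_len(as.numeric(origin), 3L),
                 spacing = spacing),
            class = "grid_map")
}

#' @export
print.grid_map <- function(x, ...) {
  cat(sprintf("Density grid %s, spacing (%.2f, %.2f, %.2f) A\n",
              paste(dim(x$values), collapse = " x "),
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' Weighted mean density fit of a group of atoms
#'
#' Scores how well a group of atoms sits in the density:
#' \deqn{fit = \frac{\sum_a w_a \sum_g t(x_g) \rho(x_g)}
#'                  {\sum_a w_a \sum_g t(x_g)}}
#' summing over the grid points \eqn{x_g} around each atom, with a linear
#' taper \eqn{t(x) = \max(0, 1 - |x - x_a| / r_{atom})} and atom weight
#' \eqn{w_a = occ_a / (1 + U_a)} where \eqn{U_a = B_a / 8\pi^2} is the
#' mean-square displacement: mobile, partial-occupancy atoms count less.
#' Scores are evaluated on grid points directly (no interpolation). The
#' taper is pluggable via `taper`.
#'
#' @param map A [grid_map()].
#' @param atoms An [atom_table()] (positions, occupancy, b_factor,
#'   element used).
#' @param radius_table Named per-element radius vector
#'   (see [default_atom_radii()]).
#' @param taper Function of (distance, radius) returning weights in
#'   [0, 1]; the default is the linear taper.
#' @return A list of class `fit_score` with `score` and `n_grid_points`.
#' @export
density_fit <- function(map, atoms, radius_table = default_atom_radii(),
                        taper = function(d, r) pmax(0, 1 - d / r)) {
  if (!inherits(map, "grid_map")) {
    abort("`map` must be a grid_map.", class = "xrefine_invalid_input")
  }
  if (nrow(atoms) == 0L) {
    abort("no atoms to score.", class = "xrefine_invalid_input")
  }
  dims <- dim(map$values)
  num <- 0; den <- 0; n_pts <- 0L
  for (i in seq_len(nrow(atoms))) {
    el <- toupper(trimws(atoms$element[[i]]))
    r_atom <- radius_table[[el]] %||% radius_table[["default"]]
    pos <- c(atoms$x[[i]], atoms$y[[i]], atoms$z[[i]])
    u <- atoms$b_factor[[i]] / (8 * pi^2)
    w_a <- atoms$occupancy[[i]] / (1 + u)
    # grid-index bounding box around the atom
    lo <- pmax(1L, ceiling((pos - r_atom - map$origin) / map$spacing) + 1L)
    hi <- pmin(dims, floor((pos + r_atom - map$origin) / map$spacing) + 1L)
    if (any(lo > hi)) next
    ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
    gx <- map$origin[1] + (ix - 1) * map$spacing[1]
    gy <- map$origin[2] + (iy - 1) * map$spacing[2]
    gz <- map$origin[3] + (iz - 1) * map$spacing[3]
    d2 <- outer(outer((gx - pos[1])^2, (gy - pos[2])^2, "+"),
                (gz - pos[3])^2, "+")
    tt <- taper(sqrt(d2), r_atom)
    inside <- tt > 0
    if (!any(inside)) next
    rho <- map$values[ix, iy, iz, drop = FALSE]
    num <- num + w_a * sum(tt[inside] * rho[inside])
    den <- den + w_a * sum(tt[inside])
    n_pts <- n_pts + sum(inside)
  }
  if (n_pts == 0L || den == 0) {
    abort("no grid point within any atom radius; fit undefined.",
          class = "xrefine_undefined_fit")
  }
  structure(list(score = num / den, n_grid_points = n_pts),
            class = "fit_score")
}

#' Prune waters by density fit
#'
#' Waters with a weighted mean density fit below the resolution-independent
#' cutoff 0.37 (on the normalized 2mFo-DFc map scale the cutoff was
#' calibrated for, chosen to minimize false-positive deletions) are
#' removed; waters involved in LINK records are never touched.
#'
#' @param waters Tibble with one row per water carrying at least `id` and
#'   `score` (its [density_fit()] score).
#' @param linked_water_ids Character vector of water ids involved in LINKs.
#' @param cutoff Density-fit cutoff (default 0.37, strict `<`).
#' @return List with `kept` and `removed` tibbles.
#' @export
centrifuge <- function(waters, linked_water_ids = character(),
                       cutoff = 0.37) {
  if (!is.data.frame(waters)) {
    abort("`waters` must be a tibble with `id` and `score`.",
          class = "xrefine_invalid_input")
  }
  if (nrow(waters) == 0L) {
    return(list(kept = waters, removed = waters))
  }
  remove <- waters$score < cutoff & !(waters$id %in% linked_water_ids)
  list(kept = waters[!remove, , drop = FALSE],
       removed = waters[remove, , drop = FALSE])
}

#' Mark residues in the middle of secondary-structure elements
#'
#' A residue is a "middle" residue when both flanking residues share its
#' helix or strand state.
#'
#' @param states Character vector of per-residue states along a chain,
#'   e.g. `"H"` (helix), `"E"` (strand), anything else = other.
#' @return Character vector: `"helix_mid"`, `"strand_mid"` or `"other"`.
#' @export
ss_middle <- function(states) {
  n <- length(states)
  out <- rep("other", n)
  if (n < 3L) return(out)
  for (i in 2:(n - 1L)) {
    if (states[i] %in% c("H", "E") &&
        states[i - 1L] == states[i] && states[i + 1L] == states[i]) {
      out[i] <- if (states[i] == "H") "helix_mid" else "strand_mid"
    }
  }
  out
}

#' Per-stage rebuilding eligibility
#'
#' Rebuilding is comprehensive by default: every residue is considered.
#' Negative selection then excludes residues for which unsupervised
#' rebuilding is too risky or pointless: peptide flipping skips residues
#' whose backbone N or O is in a LINK and residues in the middle of
#' helices or strands; side-chain rebuilding skips side chains involved
#' in LINKs and side chains with multiple conformations.
#'
#' @param residues Tibble with `chain`, `resno` (and optionally
#'   `resname`).
#' @param links Tibble of link end points with `chain`, `resno`, `atom`
#'   (atom name at the linked end); may be empty.
#' @param altlocs Tibble with `chain`, `resno` for residues whose side
#'   chain has multiple conformations; may be empty.
#' @param ss Character vector (per residue, aligned with `residues`) of
#'   `"helix_mid"`, `"strand_mid"` or `"other"`; defaults to all
#'   `"other"`.
#' @return `residues` with logical columns `pepflip_eligible` and
#'   `sidechain_eligible`.
#' @export
rebuild_candidates <- function(residues,
                               links = NULL, altlocs = NULL, ss = NULL) {
  n <- nrow(residues)
  ss <- ss %||% rep("other", n)
  if (length(ss) != n) {
    abort("`ss` must align with `residues`.", class = "xrefine_invalid_input")
  }
  rkey <- paste(residues$chain, residues$resno, sep = "/")
  bb_linked <- rep(FALSE, n)
  sc_linked <- rep(FALSE, n)
  if (!is.null(links) && nrow(links) > 0L) {
    lkey <- paste(links$chain, links$resno, sep = "/")
    bb <- trimws(links$atom) %in% c("N", "O")
    bb_linked <- rkey %in% lkey[bb]
    sc_linked <- rkey %in% lkey[!bb]
  }
  multi <- rep(FALSE, n)
  if (!is.null(altlocs) && nrow(altlocs) > 0L) {
    multi <- rkey %in% paste(altlocs$chain, altlocs$resno, sep = "/")
  }
  dplyr::mutate(tibble::as_tibble(residues),
                pepflip_eligible = !bb_linked & !(ss %in% c("helix_mid", "strand_mid")),
                sidechain_eligible = !sc_linked & !multi)
}

# The validation-driven fix-up tasks are positively selected, but only
# for the enumerated residue types per issue kind.
VALIDATION_TASK_TYPES <- list(
  hn_flip = c("HIS", "ASN", "GLN"),
  chi2_flip = c("ASP", "GLU", "PHE", "TYR"),
  arg_ne_swap = "ARG",
  chirality = c("THR", "ILE", "VAL", "LEU")
)

#' Turn validation findings into rebuilding tasks
#'
#' Positive selection from a validation report: flip His/Asn/Gln side
#' chains to improve hydrogen bonding (`hn_flip`), flip
#' Asp/Glu/Phe/Tyr side chains to standardize the chi-2 angle (chi-3 for
#' Glu; `chi2_flip`), unswap mixed-up N-epsilon atoms in Arg
#' (`arg_ne_swap`), and fix administrative chirality errors in the C-beta
#' atom of Thr/Ile/Val and the C-gamma atom of Leu (`chirality`).
#' Findings on other residue types produce no task; findings with an
#' unknown issue kind are skipped with a warning. The negative selectors
#' of [rebuild_candidates()] still apply: tasks on side-chain-excluded
#' residues are dropped.
#'
#' @param findings Tibble with `chain`, `resno`, `restype` and `issue`.
#' @param eligibility Optional [rebuild_candidates()] output; when given,
#'   only `sidechain_eligible` residues produce tasks.
#' @return Tibble of tasks: `chain`, `resno`, `restype`, `task`.
#' @export
validation_tasks <- function(findings, eligibility = NULL) {
  if (nrow(findings) == 0L) {
    return(tibble::tibble(chain = character(), resno = integer(),
                          restype = character(), task = character()))
  }
  unknown <- !(findings$issue %in% names(VALIDATION_TASK_TYPES))
  if (any(unknown)) {
    warn(paste("skipping unknown issue kind(s):",
               paste(unique(findings$issue[unknown]), collapse = ", ")))
  }
  keep <- !unknown &
    mapply(function(issue, restype) {
      !is.na(issue) && issue %in% names(VALIDATION_TASK_TYPES) &&
        toupper(restype) %in% VALIDATION_TASK_TYPES[[issue]]
    }, findings$issue, findings$restype)
  out <- findings[keep, , drop = FALSE]
  if (!is.null(eligibility)) {
    ekey <- paste(eligibility$chain, eligibility$resno, sep = "/")
    ok <- eligibility$sidechain_eligible
    out <- out[paste(out$chain, out$resno, sep = "/") %in% ekey[ok], ,
               drop = FALSE]
  }
  tibble::tibble(chain = out$chain, resno = out$resno,
                 restype = out$restype, task = out$issue)
}

#' Plot a density-map section with waters
#'
#' A single z-section of the map with water positions overlaid, coloured
#' by kept/removed status if a [centrifuge()] result is given.
#'
#' @param object A `grid_map`.
#' @param z_index Section index along the third axis (default: middle).
#' @param waters Optional tibble with `x`, `y` (and `removed`) columns.
#' @param ... Unused.
#' @method autoplot grid_map
#' @export
autoplot.grid_map <- function(object, z_index = NULL, waters = NULL, ...) {
  dims <- dim(object$values)
  z_index <- z_index %||% ceiling(dims[3] / 2)
  df <- expand.grid(
    x = object$origin[1] + (seq_len(dims[1]) - 1) * object$spacing[1],
    y = object$origin[2] + (seq_len(dims[2]) - 1) * object$spacing[2]
  )
  df$density <- as.vector(object$values[, , z_index])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                        fill = .data$density)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (A)", y = "y (A)") +
    ggplot2::theme_minimal()
  if (!is.null(waters)) {
    p <- p + ggplot2::geom_point(
      data = waters,
      mapping = ggplot2::aes(x = .data$x, y = .data$y),
      inherit.aes = FALSE, colour = "red", shape = 4, size = 2
    )
  }
  p
}
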