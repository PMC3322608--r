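# Reflection-data standardization and sanity checks.

#' Build a reflection table
#'
#' A reflection table is a tibble with one Miller-indexed observation per
#' row: integer indices `h`, `k`, `l`, the measured `value` (amplitude or
#' intensity, engine units), its `sigma` (or `NA`), the `kind` of the
#' value (`"amplitude"` or `"intensity"`), an integer `free_flag`
#' (`NA` when absent) and a `dataset_id`.
#'
#' @param h,k,l Integer Miller indices; (0,0,0) is not a reflection.
#' @param value Measured amplitudes or intensities.
#' @param sigma Standard deviations, `NA` when not measured.
#' @param kind `"amplitude"` or `"intensity"`, recycled.
#' @param free_flag Integer free-set flag (1 = free), `NA` when absent.
#' @param dataset_id Dataset identifier, recycled.
#' @export
reflection_table <- function(h, k, l, value, sigma = NA_real_,
                             kind = "amplitude", free_flag = NA_integer_,
                             dataset_id = "1") {
  out <- tibble::tibble(
    h = as.integer(h), k = as.integer(k), l = as.integer(l),
    value = as.numeric(value), sigma = as.numeric(sigma),
    kind = as.character(kind), free_flag = as.integer(free_flag),
    dataset_id = as.character(dataset_id)
  )
  if (any(out$h == 0L & out$k == 0L & out$l == 0L)) {
    abort("(0,0,0) is not a valid reflection.", class = "xrefine_invalid_input")
  }
  if (!all(out$kind %in% c("amplitude", "intensity"))) {
    abort("`kind` must be 'amplitude' or 'intensity'.",
          class = "xrefine_invalid_input")
  }
  out
}

#' Sanitize a reflection table
#'
#' Applies the standardization rules used before refinement:
#' \itemize{
#'   \item only the first dataset (in file order) is retained;
#'   \item reflections with negative values are rejected if they are
#'     amplitudes but kept if they are intensities (weak intensities are
#'     legitimately negative after background subtraction);
#'   \item if all sigma values are identical they carry no information and
#'     are declared unusable for scaling;
#'   \item individual sigma values of 0.0 are reset to the highest sigma
#'     in the dataset.
#' }
#'
#' @param records A reflection table (see [reflection_table()]).
#' @return A list with `reflections` (the sanitized table) and `log`, a
#'   one-row tibble with counts: `n_rejected_negative_amplitudes`,
#'   `sigmas_usable`, `n_sigma_reset`, `datasets_dropped`.
#' @export
sanitize_reflections <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0L) {
    abort("`records` must be a non-empty reflection table.",
          class = "xrefine_invalid_input")
  }
  first_id <- records$dataset_id[[1L]]
  datasets_dropped <- dplyr::n_distinct(records$dataset_id) - 1L
  out <- dplyr::filter(records, .data$dataset_id == first_id)

  neg_amp <- out$kind == "amplitude" & out$value < 0
  n_neg <- sum(neg_amp)
  out <- out[!neg_amp, , drop = FALSE]
  if (nrow(out) == 0L) {
    abort("all reflections were rejected during sanitation.",
          class = "xrefine_empty_dataset")
  }

  sig <- out$sigma
  known <- sig[!is.na(sig)]
  # exact equality on purpose: the values come from a file, not arithmetic
  sigmas_usable <- length(known) > 0L && length(unique(known)) > 1L
  n_reset <- 0L
  if (sigmas_usable) {
    zero <- !is.na(sig) & sig == 0
    n_reset <- sum(zero)
    if (n_reset > 0L) out$sigma[zero] <- max(known)
  }

  list(
    reflections = out,
    log = tibble::tibble(
      n_rejected_negative_amplitudes = n_neg,
      sigmas_usable = sigmas_usable,
      n_sigma_reset = n_reset,
      datasets_dropped = datasets_dropped
    )
  )
}

# lattice geometry ---------------------------------------------------------

#' Describe a crystal lattice
#'
#' @param a,b,c Cell edges in Angstrom.
#' @param alpha,beta,gamma Cell angles in degrees.
#' @param ops List of 3x3 integer matrices: the point-group rotations
#'   acting on Miller indices (identity only for point group 1). Friedel
#'   mates are always merged in addition to these.
#' @export
lattice <- function(a, b, c, alpha = 90, beta = 90, gamma = 90,
                    ops = list(diag(3))) {
  for (v in c(a, b, c)) check_number(v, "cell edge", lower = 1e-6)
  for (v in c(alpha, beta, gamma)) check_number(v, "cell angle", lower = 1e-3, upper = 179.999)
  structure(list(a = a, b = b, c = c, alpha = alpha, beta = beta,
                 gamma = gamma, ops = ops),
            class = "xrefine_lattice")
}

# 1/d^2 for Miller index triples in a general (triclinic) cell.
inv_d2 <- function(lat, h, k, l) {
  ca <- cos(lat$alpha * pi / 180); cb <- cos(lat$beta * pi / 180)
  cg <- cos(lat$gamma * pi / 180)
  sa <- sin(lat$alpha * pi / 180); sb <- sin(lat$beta * pi / 180)
  sg <- sin(lat$gamma * pi / 180)
  V2 <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (V2 <= 0) abort("degenerate cell.", class = "xrefine_invalid_input")
  (h^2 * sa^2 / lat$a^2 + k^2 * sb^2 / lat$b^2 + l^2 * sg^2 / lat$c^2 +
     2 * k * l * (cb * cg - ca) / (lat$b * lat$c) +
     2 * l * h * (cg * ca - cb) / (lat$c * lat$a) +
     2 * h * k * (ca * cb - cg) / (lat$a * lat$b)) / V2
}

# Canonical representative of the orbit of (h,k,l) under the point group
# plus Friedel inversion: the lexicographically largest image.
canonical_hkl <- function(lat, hkl) {
  ops <- c(lat$ops, lapply(lat$ops, function(m) -m))
  imgs <- vapply(ops, function(m) as.integer(m %*% hkl), integer(3))
  best <- imgs[, 1L]
  for (j in seq_len(ncol(imgs))[-1L]) {
    x <- imgs[, j]
    if (x[1] > best[1] ||
        (x[1] == best[1] && (x[2] > best[2] ||
                             (x[2] == best[2] && x[3] > best[3])))) {
      best <- x
    }
  }
  best
}

#' Enumerate the symmetry-unique reflections inside a resolution sphere
#'
#' @param lat A [lattice()].
#' @param d_min Resolution limit in Angstrom.
#' @return Tibble of unique `h`, `k`, `l` (Friedel pairs merged).
#' @export
unique_reflections <- function(lat, d_min) {
  check_number(d_min, "d_min", lower = 1e-6)
  smax2 <- 1 / d_min^2
  hmax <- floor(lat$a / d_min) + 1L
  kmax <- floor(lat$b / d_min) + 1L
  lmax <- floor(lat$c / d_min) + 1L
  grid <- expand.grid(h = -hmax:hmax, k = -kmax:kmax, l = -lmax:lmax)
  keep <- inv_d2(lat, grid$h, grid$k, grid$l) <= smax2 + 1e-12
  grid <- grid[keep & !(grid$h == 0 & grid$k == 0 & grid$l == 0), ]
  canon <- t(apply(as.matrix(grid), 1L, function(v) canonical_hkl(lat, v)))
  dplyr::distinct(tibble::tibble(h = as.integer(canon[, 1]),
                                 k = as.integer(canon[, 2]),
                                 l = as.integer(canon[, 3])))
}

#' Data completeness inside the resolution sphere
#'
#' Fraction of the theoretically possible symmetry-unique reflections
#' (Friedel pairs merged) that are present in the data.
#'
#' @param records Reflection table.
#' @param lat A [lattice()].
#' @param d_min Resolution limit in Angstrom.
#' @return Fraction in [0, 1].
#' @export
completeness <- function(records, lat, d_min) {
  uniq <- unique_reflections(lat, d_min)
  if (nrow(records) == 0L) return(0)
  canon <- t(apply(as.matrix(records[, c("h", "k", "l")]), 1L,
                   function(v) canonical_hkl(lat, v)))
  obs <- dplyr::distinct(tibble::tibble(h = as.integer(canon[, 1]),
                                        k = as.integer(canon[, 2]),
                                        l = as.integer(canon[, 3])))
  nrow(dplyr::inner_join(obs, uniq, by = c("h", "k", "l"))) / nrow(uniq)
}

# structure-factor mmCIF I/O -----------------------------------------------

#' Read a structure-factor mmCIF file
#'
#' Parses `_refln` loops: Miller indices, measured amplitudes (or
#' intensities when amplitudes are not given), sigma values, the free-set
#' status column, and a dataset identifier (`crystal_id`/`diffrn_id` or
#' the `data_` block name). Accepted status dialects: `o`/`f` characters
#' (`f` = free), or integer flags, where the minority class is taken as
#' the free set (ties resolve to flag 0 = free).
#'
#' @param path Path to an (uncompressed) structure-factor mmCIF file.
#' @return A reflection table; attribute `free_value` records which raw
#'   flag value was interpreted as free.
#' @export
read_sf_cif <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  blocks <- parse_cif_loops(lines)
  refln <- NULL
  for (b in blocks) {
    if (any(grepl("^_refln[._]", b$tags))) { refln <- b; break }
  }
  if (is.null(refln)) {
    abort("no _refln loop found.", class = "xrefine_invalid_input")
  }
  tag <- function(suffixes) {
    for (s in suffixes) {
      i <- match(TRUE, tolower(refln$tags) == tolower(s))
      if (!is.na(i)) return(i)
    }
    NA_integer_
  }
  col <- function(i) if (is.na(i)) NULL else refln$values[[i]]
  num <- function(x) {
    if (is.null(x)) return(NULL)
    suppressWarnings(as.numeric(ifelse(x %in% c("?", "."), NA, x)))
  }
  h <- num(col(tag("_refln.index_h"))); k <- num(col(tag("_refln.index_k")))
  l <- num(col(tag("_refln.index_l")))
  if (is.null(h) || is.null(k) || is.null(l)) {
    abort("missing Miller-index columns.", class = "xrefine_invalid_input")
  }
  f <- num(col(tag(c("_refln.F_meas_au", "_refln.F_meas"))))
  sf <- num(col(tag(c("_refln.F_meas_sigma_au", "_refln.F_sigma",
                      "_refln.F_meas_sigma"))))
  im <- num(col(tag(c("_refln.intensity_meas", "_refln.F_squared_meas"))))
  si <- num(col(tag(c("_refln.intensity_sigma", "_refln.F_squared_sigma"))))
  if (!is.null(f) && any(!is.na(f))) {
    value <- f; sigma <- if (is.null(sf)) NA_real_ else sf; kind <- "amplitude"
  } else if (!is.null(im)) {
    value <- im; sigma <- if (is.null(si)) NA_real_ else si; kind <- "intensity"
  } else {
    abort("no amplitude or intensity column.", class = "xrefine_invalid_input")
  }
  status <- col(tag(c("_refln.status", "_refln.pdbx_r_free_flag")))
  free_flag <- rep(NA_integer_, length(h))
  free_value <- NA_character_
  if (!is.null(status)) {
    st <- status[!(status %in% c("?", "."))]
    if (all(st %in% c("o", "f"))) {
      free_flag <- ifelse(status == "f", 1L,
                          ifelse(status == "o", 0L, NA_integer_))
      free_value <- "f"
    } else {
      stn <- suppressWarnings(as.integer(status))
      tb <- sort(table(stn))
      if (length(tb) >= 2L) {
        cand <- names(tb)[tb == tb[[1L]]]
        fv <- if ("0" %in% cand) 0L else as.integer(cand[[1L]])
        free_flag <- ifelse(is.na(stn), NA_integer_,
                            ifelse(stn == fv, 1L, 0L))
        free_value <- as.character(fv)
      } else {
        free_flag <- ifelse(is.na(stn), NA_integer_, 0L)
      }
    }
  }
  ds <- col(tag(c("_refln.crystal_id", "_refln.diffrn_id")))
  dataset_id <- if (is.null(ds)) refln$block else ds
  out <- reflection_table(h, k, l, value, sigma, kind, free_flag, dataset_id)
  attr(out, "free_value") <- free_value
  out
}

# Minimal CIF loop reader: returns a list of loops, each with the data
# block name, its tags and one character vector of values per tag.
parse_cif_loops <- function(lines) {
  loops <- list()
  block <- "data"
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    ln <- lines[[i]]
    if (grepl("^data_", ln)) block <- sub("^data_", "", ln)
    if (identical(ln, "loop_")) {
      i <- i + 1L
      tags <- character()
      while (i <= n && grepl("^_", lines[[i]])) {
        tags <- c(tags, strsplit(lines[[i]], "[[:space:]]+")[[1L]][1L])
        i <- i + 1L
      }
      rows <- character()
      while (i <= n && nzchar(lines[[i]]) && !grepl("^(_|loop_|data_|#)", lines[[i]])) {
        rows <- c(rows, lines[[i]])
        i <- i + 1L
      }
      if (length(tags) > 0L && length(rows) > 0L) {
        toks <- strsplit(paste(rows, collapse = " "), "[[:space:]]+")[[1L]]
        toks <- toks[nzchar(toks)]
        if (length(toks) %% length(tags) == 0L) {
          m <- matrix(toks, ncol = length(tags), byrow = TRUE)
          loops[[length(loops) + 1L]] <-
            list(block = block, tags = tags,
                 values = lapply(seq_along(tags), function(j) m[, j]))
        }
      }
    } else {
      i <- i + 1L
    }
  }
  loops
}

#' Write a reflection table as structure-factor mmCIF
#'
#' Emits a `_refln` loop in the same dialect [read_sf_cif()] accepts,
#' with `o`/`f` status flags.
#'
#' @param records Reflection table.
#' @param path Output path.
#' @export
write_sf_cif <- function(records, path) {
  kind <- records$kind[[1L]]
  vtag <- if (kind == "amplitude") "_refln.F_meas_au" else "_refln.intensity_meas"
  stag <- if (kind == "amplitude") "_refln.F_meas_sigma_au" else "_refln.intensity_sigma"
  status <- ifelse(is.na(records$free_flag), "o",
                   ifelse(records$free_flag == 1L, "f", "o"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "data_xrefine",
    "loop_",
    "_refln.crystal_id",
    "_refln.index_h", "_refln.index_k", "_refln.index_l",
    vtag, stag, "_refln.status"
  ), con)
  writeLines(sprintf("%s %d %d %d %.6g %s %s",
                     records$dataset_id, records$h, records$k, records$l,
                     records$value,
                     ifelse(is.na(records$sigma), "?",
                            sprintf("%.6g", records$sigma)),
                     status), con)
  invisible(path)
}
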