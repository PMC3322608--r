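# Independent oracles and fixture builders. These reimplement the
# decision rules longhand (loops, no shared code with the package
# internals) so the optimized implementations can be checked against
# them.

# Least-absolute-residual scale by brute-force grid scan, refined twice.
oracle_r_factor <- function(obs, calc) {
  resid <- function(m) sum(abs(obs - m * calc))
  lo <- 0
  hi <- 2 * max(obs / pmax(calc, 1e-9), 1)
  for (pass in 1:3) {
    grid <- seq(lo, hi, length.out = 20001)
    vals <- vapply(grid, resid, numeric(1))
    k <- which.min(vals)
    lo <- grid[max(1, k - 1)]
    hi <- grid[min(length(grid), k + 1)]
  }
  resid((lo + hi) / 2) / sum(obs)
}

# Longhand per-grid-point Hamilton evaluation (explicit double loop).
oracle_hamilton <- function(inp) {
  n_ok <- 0L
  n_tot <- 0L
  for (w1 in inp$w1_grid) {
    for (w2 in inp$w2_grid) {
      n_tot <- n_tot + 1L
      f <- inp$n_obs - inp$n_params_complex +
        w1 * inp$n_restraints_base + w2 * inp$n_restraints_extra
      if (f <= 0) next
      b <- (inp$n_params_complex - inp$n_params_simple) -
        w2 * inp$n_restraints_extra
      if (b < 1) b <- 1
      crit <- sqrt((b / f) * qf(1 - inp$alpha, b, f) + 1)
      if (inp$r_free_w_simple / inp$r_free_w_complex > crit) {
        n_ok <- n_ok + 1L
      }
    }
  }
  n_ok / n_tot
}

# Exhaustive filter + argmin reimplementation of the candidate selection.
oracle_pick <- function(candidates, cut, r_ratio = NA_real_,
                        category_name = NULL) {
  n <- nrow(candidates)
  keep <- logical(n)
  z <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    r <- candidates$r[i]
    rf <- candidates$r_free[i]
    nt <- candidates$n_test_reflections[i]
    sig <- if (nt >= 1) rf / sqrt(2 * nt) else NA_real_
    if (!is.na(r_ratio) && !is.na(sig) && sig > 0) {
      m <- r * r_ratio + 3.5 * sig
      if (m > r + 0.06) m <- r + 0.06
      z[i] <- (r * r_ratio - rf) / sig
    } else {
      m <- r + 0.06
    }
    floor_m <- (cut$r_free_co / cut$r_co) * r
    if (m < floor_m) m <- floor_m
    ok <- TRUE
    if (candidates$rmsz_bond[i] > cut$rmsz_bond_co) ok <- FALSE
    if (candidates$rmsz_angle[i] > cut$rmsz_angle_co) ok <- FALSE
    if (rf > m) ok <- FALSE
    if (rf > cut$r_free_co) ok <- FALSE
    if (!is.null(category_name) && category_name %in% c("vlow", "xlow") &&
        (rf - r) > 2 * (cut$r_free_co - cut$r_co)) {
      ok <- FALSE
    }
    keep[i] <- ok
  }
  surv <- which(keep)
  if (length(surv) == 0L) return(NA_character_)
  a <- surv[which.min(candidates$ll_free[surv])]
  b <- surv[which.min(candidates$r_free[surv])]
  if (a == b) return(candidates$label[a])
  za <- if (is.na(z[a])) -Inf else z[a]
  zb <- if (is.na(z[b])) -Inf else z[b]
  if (za == zb) {
    pair <- c(a, b)
    pair <- pair[order(candidates$r_free[pair], pair)]
    return(candidates$label[pair[1]])
  }
  candidates$label[if (za > zb) a else b]
}

# Randomized candidate sets with occasional degenerate test-set sizes.
random_candidates <- function(n) {
  r <- runif(n, 0.15, 0.30)
  tibble::tibble(
    label = sprintf("c%02d", seq_len(n)),
    r = r,
    r_free = r + runif(n, -0.01, 0.09),
    r_weighted = r, r_free_weighted = r,
    rmsz_bond = runif(n, 0.2, 1.6),
    rmsz_angle = runif(n, 0.2, 1.6),
    ll_free = runif(n, 1000, 2000),
    n_test_reflections = sample(c(0L, sample(200:3000, n, TRUE)), n)
  )
}

random_cutoffs <- function() {
  r_calc <- runif(1, 0.18, 0.28)
  base <- baseline_metrics(
    r_calc = r_calc,
    r_free_calc = r_calc + runif(1, 0.01, 0.06),
    r_ratio = runif(1, 1.0, 1.3),
    rmsz_bond_calc = runif(1, 0.4, 1.5),
    rmsz_angle_calc = runif(1, 0.4, 1.5)
  )
  establish_cutoffs(base, "general")
}

# Minimal baseline for picker/cutoff tests.
toy_baseline <- function(r_calc = 0.20, r_free_calc = 0.24, r_ratio = 1.15,
                         ...) {
  baseline_metrics(r_calc = r_calc, r_free_calc = r_free_calc,
                   r_ratio = r_ratio, ...)
}

# One model_stats row with permissive defaults.
stats_row <- function(label = "x", r = 0.20, r_free = 0.24,
                      r_free_weighted = r_free, rmsz_bond = 0.8,
                      rmsz_angle = 0.8, ll_free = 1000,
                      n_test = 1000L) {
  model_stats(label = label, r = r, r_free = r_free,
              r_weighted = r, r_free_weighted = r_free_weighted,
              rmsz_bond = rmsz_bond, rmsz_angle = rmsz_angle,
              ll_free = ll_free, n_test_reflections = n_test)
}

# Engine whose baseline-ladder rungs leave R unchanged (for abort-gap
# probing) built from a planted R_calc - R_head gap.
stalled_engine_inputs <- function(gap) {
  p <- synthetic_profile(baseline_r = 0.20 + gap,
                         rung_gains = c(twin = 0, rigid = 0, tls = 0),
                         tls_gain = 0)
  header <- empty_header()
  header$r_head <- 0.20
  list(engine = simulated_engine(p), header = header,
       model = list(r = NULL))
}
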