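# Parameterization routing, Hamilton grid tests against a longhand
# oracle, and the bselect decision chain.

test_that("data-density routing follows the printed RPA regimes", {
  expect_equal(route_parameterization(18.1)$route, "aniso")
  expect_equal(route_parameterization(18.0)$route, "contest_aniso_vs_iso")
  expect_equal(route_parameterization(15)$route, "contest_aniso_vs_iso")
  expect_equal(route_parameterization(13.5)$route, "iso")
  expect_equal(route_parameterization(5)$route, "iso")
  expect_equal(route_parameterization(3)$route, "iso")
  expect_equal(route_parameterization(2.9)$route, "contest_iso_vs_overall")
  expect_equal(route_parameterization(2.9, tls_usable = FALSE)$route,
               "iso_fallback")
  # parameters per atom: 9 anisotropic, 4 isotropic, 3 overall-B
  r <- route_parameterization(15)
  expect_equal(r$params_per_atom_simple, 4L)
  expect_equal(r$params_per_atom_complex, 9L)
  r <- route_parameterization(2)
  expect_equal(r$params_per_atom_simple, 3L)
  expect_equal(r$params_per_atom_complex, 4L)
})

test_that("hamilton acceptance fraction: degenerate ratios", {
  inp_eq <- hamilton_input(0.22, 0.22, 50000, 4000, 9000, 3000, 1000)
  expect_equal(hamilton_acceptance_fraction(inp_eq), 0)

  inp_huge <- hamilton_input(2.2, 0.22, 50000, 4000, 9000, 3000, 1000)
  expect_equal(hamilton_acceptance_fraction(inp_huge), 1)
})

test_that("hamilton acceptance matches the longhand per-grid-point oracle", {
  toy <- hamilton_input(0.235, 0.225, 30000, 4000, 9000, 2500, 800,
                        w1_grid = c(0, 0.5, 1), w2_grid = c(0, 0.5, 1))
  expect_equal(hamilton_acceptance_fraction(toy), oracle_hamilton(toy))

  withr::with_seed(101, {
    for (rep in 1:100) {
      n_obs <- sample(2000:60000, 1)
      n_s <- sample(500:5000, 1)
      n_c <- n_s + sample(500:8000, 1)
      inp <- hamilton_input(
        r_free_w_simple = runif(1, 0.18, 0.30),
        r_free_w_complex = runif(1, 0.18, 0.30),
        n_obs = n_obs, n_params_simple = n_s, n_params_complex = n_c,
        n_restraints_base = sample(0:6000, 1),
        n_restraints_extra = sample(0:4000, 1),
        w1_grid = seq(0, 1, by = 0.25), w2_grid = seq(0, 1, by = 0.25)
      )
      expect_equal(hamilton_acceptance_fraction(inp), oracle_hamilton(inp))
    }
  })
})

test_that("hamilton fraction is monotone in the R ratio and ignores duplicate grid points", {
  mk <- function(rs) hamilton_input(rs, 0.22, 30000, 4000, 9000, 2500, 800)
  fr <- vapply(seq(0.20, 0.30, by = 0.01),
               function(rs) hamilton_acceptance_fraction(mk(rs)), numeric(1))
  expect_true(all(diff(fr) >= 0))

  base <- hamilton_input(0.24, 0.22, 30000, 4000, 9000, 2500, 800,
                         w1_grid = c(0, 0.5, 1), w2_grid = c(0, 1))
  dup <- hamilton_input(0.24, 0.22, 30000, 4000, 9000, 2500, 800,
                        w1_grid = c(0, 0, 0.5, 0.5, 1, 1),
                        w2_grid = c(0, 0, 1, 1))
  expect_equal(hamilton_acceptance_fraction(base),
               hamilton_acceptance_fraction(dup))
})

test_that("under-determined grid points count as not acceptable", {
  # n_obs barely above the complex parameter count: w1 = w2 = 0 gives
  # f < 0 and must not crash nor count as acceptable
  inp <- hamilton_input(2.0, 0.2, 5000, 2000, 5100, 3000, 500,
                        w1_grid = c(0, 1), w2_grid = c(0, 1))
  frac <- hamilton_acceptance_fraction(inp)
  expect_lte(frac, 0.75)
  expect_equal(frac, oracle_hamilton(inp))
})

test_that("bselect step (i): a higher weighted free R rejects the complex model", {
  dec <- bselect(stats_row(r_free_weighted = 0.230),
                 stats_row(r_free_weighted = 0.231),
                 complex_kind = "aniso")
  expect_equal(dec$choice, "simple")
  expect_true(is.na(dec$acceptance_fraction))  # no Hamilton test was run

  withr::with_seed(5, {
    for (rep in 1:50) {
      s <- stats_row(r_free_weighted = runif(1, 0.2, 0.3))
      c <- stats_row(r_free_weighted = s$r_free_weighted + runif(1, 1e-6, 0.05))
      expect_equal(bselect(s, c, complex_kind = "iso")$choice, "simple")
    }
  })
})

test_that("bselect step (ii): the 30/95% band is strict on both sides", {
  s <- stats_row(r = 0.20, r_free = 0.22)
  c <- stats_row(r = 0.19, r_free = 0.215, r_free_weighted = 0.215)
  # force step (iii) toward 'complex' (benign gap, high Z)
  expect_equal(bselect(s, c, z_complex = 1, acceptance_fraction = 0.299)$choice,
               "simple")
  expect_equal(bselect(s, c, z_complex = 1, acceptance_fraction = 0.30)$choice,
               "complex")  # falls through to step (iii), which passes
  # force step (iii) toward 'simple' and confirm > 95% short-circuits
  bad_c <- stats_row(r = 0.19, r_free = 0.26, r_free_weighted = 0.215)
  expect_equal(bselect(s, bad_c, z_complex = -5,
                       acceptance_fraction = 0.96)$choice, "complex")
  expect_equal(bselect(s, bad_c, z_complex = -5,
                       acceptance_fraction = 0.95)$choice, "simple")
})

test_that("bselect step (iii): Z score, gap cutoffs and the 2x gap ratio", {
  s <- stats_row(r = 0.20, r_free = 0.23)   # simple gap 3 points
  mid <- 0.5

  # Z too low
  c1 <- stats_row(r = 0.19, r_free = 0.225, r_free_weighted = 0.22)
  expect_equal(bselect(s, c1, z_complex = -3.1,
                       acceptance_fraction = mid)$choice, "simple")
  expect_equal(bselect(s, c1, z_complex = -2.9,
                       acceptance_fraction = mid)$choice, "complex")

  # Z unavailable: 4% cutoff for anisotropic, strict
  c2 <- stats_row(r = 0.190, r_free = 0.231, r_free_weighted = 0.22)
  expect_equal(bselect(s, c2, z_complex = NA, complex_kind = "aniso",
                       acceptance_fraction = mid)$choice, "simple")
  c3 <- stats_row(r = 0.190, r_free = 0.2299, r_free_weighted = 0.22)
  expect_equal(bselect(s, c3, z_complex = NA, complex_kind = "aniso",
                       acceptance_fraction = mid)$choice, "complex")
  # 6% cutoff for isotropic: the 4.1-point gap is fine there
  expect_equal(bselect(s, c2, z_complex = NA, complex_kind = "iso",
                       acceptance_fraction = mid)$choice, "complex")

  # the 2.0x gap-ratio test catches a complex gap twice the simple gap
  s2 <- stats_row(r = 0.20, r_free = 0.215)  # gap 1.5 points
  c4 <- stats_row(r = 0.190, r_free = 0.2201, r_free_weighted = 0.21)
  expect_equal(bselect(s2, c4, z_complex = 1,
                       acceptance_fraction = mid)$choice, "simple")
  c5 <- stats_row(r = 0.190, r_free = 0.2199, r_free_weighted = 0.21)
  expect_equal(bselect(s2, c5, z_complex = 1,
                       acceptance_fraction = mid)$choice, "complex")
})
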