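# Baseline reproduction ladder, twin policy, TLS planning, change
# classification and the end-to-end pipeline.

test_that("no ladder rung runs when the gap is within five points", {
  si <- stalled_engine_inputs(gap = 0.03)
  res <- reproduce_baseline(si$engine, si$model, si$header)
  expect_equal(res$status, "completed")
  expect_false(any(grepl("^ladder_(rigid|tls)", res$report$trace$decision)))
  expect_false(any(res$report$trace$outcome == "adopted"))
})

test_that("a 7-point gap with high twin fraction tries the twin rung first", {
  p <- synthetic_profile(baseline_r = 0.27,
                         rung_gains = c(twin = 0.05, rigid = 0, tls = 0),
                         tls_gain = 0)
  header <- empty_header(); header$r_head <- 0.20
  res <- reproduce_baseline(simulated_engine(p), list(r = NULL), header,
                            twin_fraction_external = 0.06)
  tr <- res$report$trace
  twin_step <- tr$step[tr$decision == "ladder_twin"]
  rigid_step <- tr$step[tr$decision == "ladder_rigid_body"]
  expect_length(twin_step, 1L)
  expect_equal(tr$outcome[tr$decision == "ladder_twin"], "adopted")
  # twin brought the gap to 2 points, so the rigid rung never ran
  expect_length(rigid_step, 0L)
  expect_equal(res$status, "completed")
})

test_that("low twin fractions gate the twin rung off entirely", {
  si <- stalled_engine_inputs(gap = 0.07)
  res <- reproduce_baseline(si$engine, si$model, si$header,
                            twin_fraction_external = 0.04)
  tr <- res$report$trace
  expect_equal(tr$outcome[tr$decision == "ladder_twin"],
               "skipped_low_twin_fraction")
  # gap of 7 points survives every rung but stays under 10: completed
  expect_equal(res$status, "completed")
})

test_that("a terminal gap above ten points aborts as unreproducible", {
  for (gap in c(0.105, 0.2)) {
    si <- stalled_engine_inputs(gap)
    res <- reproduce_baseline(si$engine, si$model, si$header,
                              twin_fraction_external = 0)
    expect_equal(res$status, "aborted_unreproducible")
    expect_null(res$baseline)
  }
  si <- stalled_engine_inputs(0.0995)  # ten points is not "more than" ten
  expect_equal(reproduce_baseline(si$engine, si$model, si$header)$status,
               "completed")
})

test_that("a missing header R factor aborts before anything else", {
  si <- stalled_engine_inputs(0.0)
  si$header$r_head <- NA_real_
  res <- reproduce_baseline(si$engine, si$model, si$header)
  expect_equal(res$status, "aborted_no_r_head")
  expect_equal(nrow(res$report$trace), 1L)
})

test_that("an engine failure at a rung is recorded and the ladder continues", {
  p <- synthetic_profile(baseline_r = 0.27, tls_gain = 0,
                         rung_gains = c(twin = 0, rigid = 0.05, tls = 0))
  eng <- simulated_engine(p)
  eng_fail <- refinement_engine(
    calculate = function(model, settings = list()) {
      if (isTRUE(settings$twin)) stop("twin targets unsupported")
      eng$calculate(model, settings)
    },
    refine = eng$refine, rigid_body = eng$rigid_body,
    tls_refine = eng$tls_refine
  )
  header <- empty_header(); header$r_head <- 0.20
  res <- reproduce_baseline(eng_fail, list(r = NULL), header,
                            twin_fraction_external = 0.08)
  tr <- res$report$trace
  expect_equal(tr$outcome[tr$decision == "ladder_twin"], "engine_failure")
  expect_equal(tr$outcome[tr$decision == "ladder_rigid_body"], "adopted")
  expect_equal(res$status, "completed")
})

test_that("twin policy requires the gate and strict operator criteria", {
  ops <- function(r_merge, fraction) {
    tibble::tibble(r_merge = r_merge, fraction = fraction)
  }
  expect_false(twin_policy(0.04, ops(0.10, 0.50)))   # gate closed
  expect_true(twin_policy(0.10, ops(0.43, 0.08)))
  expect_false(twin_policy(0.10, ops(0.44, 0.08)))   # strict < 44%
  expect_false(twin_policy(0.10, ops(0.43, 0.07)))   # strict > 7%
  expect_true(twin_policy(0.10, ops(c(0.80, 0.30), c(0.02, 0.10))))
  expect_false(twin_policy(0.10, NULL))
})

test_that("TLS planning adopts only a strict R_free decrease", {
  base <- toy_baseline()
  header <- empty_header()

  good <- plan_tls(simulated_engine(synthetic_profile(tls_gain = 0.01)),
                   list(r = 0.20), header, chains = c("A", "B"),
                   base = base, r_ratio = 1.15)
  expect_true(good$use_tls)
  expect_equal(good$tls_model, "per_chain")
  expect_equal(good$base$r_tls, 0.205, tolerance = 1e-12)

  # TLS makes things worse: declined
  bad <- plan_tls(simulated_engine(synthetic_profile(tls_gain = -0.01)),
                  list(r = 0.20), header, base = base, r_ratio = 1.15)
  expect_false(bad$use_tls)

  # no decrease at all (gain exactly zero) is not adopted either
  flat <- plan_tls(simulated_engine(synthetic_profile(tls_gain = 0)),
                   list(r = 0.20), header, base = base, r_ratio = 1.15)
  expect_false(flat$use_tls)
})

test_that("the B reset target switches to the mean B at 4 Angstrom", {
  base <- toy_baseline()
  eng <- simulated_engine(synthetic_profile())
  hi <- plan_tls(eng, list(r = 0.2), empty_header(), resolution = 2.0,
                 b_wilson = 30, mean_b = 45, base = base)
  expect_equal(hi$b_reset_target, 30)
  lo <- plan_tls(eng, list(r = 0.2), empty_header(), resolution = 4.2,
                 b_wilson = 30, mean_b = 45, base = base)
  expect_equal(lo$b_reset_target, 45)
})

test_that("change classification bands match the traffic-light rules", {
  before <- list(r_free = 0.240, z_rama = -1.3, z_rotamer = -1.2,
                 z_packing_coarse = -0.24, z_packing_fine = -0.97,
                 bumps = 108, hbond_unsat = 43)
  same <- before
  same$r_free <- 0.239   # within 2 sigma = 0.008
  v <- classify_change(before, same, sigma_r_free = 0.004)
  expect_true(all(v$verdict == "same"))

  after <- before
  after$bumps <- before$bumps - 11
  after$z_rama <- before$z_rama + 0.15
  after$hbond_unsat <- before$hbond_unsat + 3
  v <- classify_change(before, after, sigma_r_free = 0.004)
  expect_equal(v$verdict[v$metric == "bumps"], "better")
  expect_equal(v$verdict[v$metric == "z_rama"], "better")
  expect_equal(v$verdict[v$metric == "hbond_unsat"], "worse")

  after$bumps <- before$bumps - 10    # boundary: still "same"
  v <- classify_change(before, after, sigma_r_free = 0.004)
  expect_equal(v$verdict[v$metric == "bumps"], "same")
})

test_that("change classification is antisymmetric", {
  withr::with_seed(55, {
    for (rep in 1:25) {
      a <- list(r_free = runif(1, 0.2, 0.3), z_rama = rnorm(1),
                z_rotamer = rnorm(1), z_packing_coarse = rnorm(1),
                z_packing_fine = rnorm(1), bumps = sample(0:200, 1),
                hbond_unsat = sample(0:80, 1))
      b <- list(r_free = runif(1, 0.2, 0.3), z_rama = rnorm(1),
                z_rotamer = rnorm(1), z_packing_coarse = rnorm(1),
                z_packing_fine = rnorm(1), bumps = sample(0:200, 1),
                hbond_unsat = sample(0:80, 1))
      fwd <- classify_change(a, b, 0.004)$verdict
      rev <- classify_change(b, a, 0.004)$verdict
      expect_equal(rev, dplyr::recode(fwd, better = "worse",
                                      worse = "better", same = "same"))
    }
  })
})

test_that("the nominal pipeline visits every decision point exactly once", {
  p <- synthetic_profile()
  res <- run_pipeline(simulated_engine(p), gen_pipeline_inputs(p), seed = 1L)
  expect_equal(res$report$status, "completed")
  expected <- c("sanitize_reflections", "validate_free_set",
                "create_free_set", "tls_ambiguity", "baseline_gap",
                "free_set_bias", "assign_category", "twin_policy",
                "route_parameterization", "plan_tls", "assign_cycles",
                "pick_rerefine", "centrifuge", "rebuild_selection",
                "validation_tasks", "pick_final", "classify_change")
  expect_setequal(res$report$trace$decision, expected)
  expect_equal(anyDuplicated(res$report$trace$decision), 0L)
})

test_that("pipelines are deterministic: identical seeds, identical reports", {
  p <- synthetic_profile(seed = 42)
  inputs <- gen_pipeline_inputs(p)
  r1 <- run_pipeline(simulated_engine(p), inputs, seed = 7L)
  r2 <- run_pipeline(simulated_engine(p), inputs, seed = 7L)
  expect_identical(as.character(report_json(r1$report)),
                   as.character(report_json(r2$report)))
})

test_that("very-low-resolution categories skip the rebuilding stages", {
  p <- synthetic_profile(resolution = 4.0, n_reflections = 400,
                         n_atoms = 300)
  inputs <- gen_pipeline_inputs(p)
  res <- run_pipeline(simulated_engine(p), inputs, seed = 1L)
  expect_equal(res$category$name, "vlow")
  tr <- res$report$trace
  expect_true("centrifuge" %in% tr$decision)  # water pruning always runs
  expect_equal(tr$outcome[tr$decision == "rebuild_selection"],
               "skipped_low_resolution_category")
  expect_false("validation_tasks" %in% tr$decision)
})

test_that("an improving engine never triggers the auto-weighting fallback", {
  for (seed in 1:10) {
    p <- synthetic_profile(seed = seed)
    res <- run_pipeline(simulated_engine(p), gen_pipeline_inputs(p),
                        seed = seed)
    expect_false(is.na(res$rerefine_selection$chosen))
    expect_false(any(res$report$trace$rule == "final_auto_weighting"))
  }
})
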