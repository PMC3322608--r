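# Density-fit scoring properties, water pruning and rebuilding
# selection.

uniform_map <- function(value = 1, n = 16, spacing = 0.8) {
  grid_map(array(value, dim = c(n, n, n)), spacing = rep(spacing, 3))
}

center_atom <- function(n = 16, spacing = 0.8) {
  mid <- (n - 1) * spacing / 2
  atom_table("O", "O", "HOH", "W", 1, mid, mid, mid)
}

test_that("the fit of any atom set to a uniform map is the map value", {
  for (c0 in c(0.25, 1, 7.5)) {
    fs <- density_fit(uniform_map(c0), center_atom())
    expect_equal(fs$score, c0, tolerance = 1e-12)
  }
  atoms <- dplyr::bind_rows(center_atom(),
                            atom_table("C", "C", "LIG", "A", 1, 3, 3, 3,
                                       b_factor = 80, occupancy = 0.5))
  expect_equal(density_fit(uniform_map(2), atoms)$score, 2, tolerance = 1e-12)
})

test_that("density_fit is linear in the map", {
  p <- synthetic_profile(seed = 9)
  mw <- gen_map_and_waters(p, n_peak_waters = 3, n_flat_waters = 2)
  atoms <- mw$waters[1, ]
  base <- density_fit(mw$map, atoms)$score
  for (k in c(0.5, 3, 11)) {
    scaled <- grid_map(k * mw$map$values, mw$map$origin, mw$map$spacing)
    expect_equal(density_fit(scaled, atoms)$score, k * base,
                 tolerance = 1e-9)
  }
  zero <- grid_map(0 * mw$map$values, mw$map$origin, mw$map$spacing)
  expect_equal(density_fit(zero, atoms)$score, 0, tolerance = 1e-12)
})

test_that("density_fit is invariant under rigid translation of map plus atoms", {
  p <- synthetic_profile(seed = 13)
  mw <- gen_map_and_waters(p, n_peak_waters = 2, n_flat_waters = 1)
  atoms <- mw$waters
  base <- density_fit(mw$map, atoms)$score
  shift <- c(5.25, -3.5, 1.75)
  moved_map <- grid_map(mw$map$values, mw$map$origin + shift, mw$map$spacing)
  moved_atoms <- dplyr::mutate(atoms, x = x + shift[1], y = y + shift[2],
                               z = z + shift[3])
  expect_equal(density_fit(moved_map, moved_atoms)$score, base,
               tolerance = 1e-9)
})

test_that("density_fit matches a longhand double-loop summation", {
  # single atom centred in a synthetic Gaussian peak
  n <- 12; spacing <- 0.7
  ax <- (seq_len(n) - 1) * spacing
  pos <- c(3.9, 3.6, 4.2)
  vals <- array(0, dim = c(n, n, n))
  for (i in 1:n) for (j in 1:n) for (k in 1:n) {
    d2 <- (ax[i] - pos[1])^2 + (ax[j] - pos[2])^2 + (ax[k] - pos[3])^2
    vals[i, j, k] <- exp(-d2 / 2)
  }
  map <- grid_map(vals, spacing = rep(spacing, 3))
  atom <- atom_table("O", "O", "HOH", "W", 1, pos[1], pos[2], pos[3],
                     occupancy = 0.8, b_factor = 25)
  got <- density_fit(map, atom)

  r_atom <- 1.52
  num <- 0; den <- 0; npts <- 0
  for (i in 1:n) for (j in 1:n) for (k in 1:n) {
    d <- sqrt((ax[i] - pos[1])^2 + (ax[j] - pos[2])^2 + (ax[k] - pos[3])^2)
    t <- max(0, 1 - d / r_atom)
    if (t > 0) {
      w <- 0.8 / (1 + 25 / (8 * pi^2))
      num <- num + w * t * vals[i, j, k]
      den <- den + w * t
      npts <- npts + 1
    }
  }
  expect_equal(got$score, num / den, tolerance = 1e-12)
  expect_equal(got$n_grid_points, npts)
})

test_that("no grid point in range raises the undefined-fit signal", {
  far <- atom_table("O", "O", "HOH", "W", 1, 500, 500, 500)
  expect_error(density_fit(uniform_map(), far),
               class = "xrefine_undefined_fit")
})

test_that("water pruning is strict at the cutoff and honours LINKs", {
  waters <- tibble::tibble(id = c("w1", "w2", "w3"),
                           score = c(0.369, 0.370, 0.10))
  res <- centrifuge(waters)
  expect_equal(res$removed$id, c("w1", "w3"))
  expect_equal(res$kept$id, "w2")

  linked <- centrifuge(waters, linked_water_ids = "w3")
  expect_equal(linked$removed$id, "w1")
  expect_true("w3" %in% linked$kept$id)

  empty <- centrifuge(waters[0, ])
  expect_equal(nrow(empty$kept), 0L)
  expect_equal(nrow(empty$removed), 0L)
})

test_that("removal count shrinks monotonically as the cutoff is lowered", {
  withr::with_seed(23, {
    waters <- tibble::tibble(id = sprintf("w%03d", 1:100),
                             score = runif(100, 0, 1))
    removed <- vapply(seq(1.0, 0, by = -0.05), function(co) {
      nrow(centrifuge(waters, cutoff = co)$removed)
    }, numeric(1))
    expect_true(all(diff(removed) <= 0))
  })
})

test_that("planted peak/solvent waters separate on either side of the cutoff", {
  p <- synthetic_profile(seed = 4)
  mw <- gen_map_and_waters(p)
  scored <- score_waters(mw$map, mw$waters)
  expect_true(min(scored$score[scored$intended == "peak"]) >
                max(scored$score[scored$intended == "solvent"]))
  res <- centrifuge(scored)
  expect_setequal(res$removed$intended, "solvent")
  expect_setequal(res$kept$intended, "peak")
})

test_that("secondary-structure middles require matching flanks", {
  expect_equal(ss_middle(c("H", "H", "H", "H", "C")),
               c("other", "helix_mid", "helix_mid", "other", "other"))
  expect_equal(ss_middle(c("E", "E", "E")), c("other", "strand_mid", "other"))
  expect_equal(ss_middle(c("C", "C")), c("other", "other"))
})

test_that("rebuilding eligibility applies the negative selectors", {
  residues <- tibble::tibble(chain = "A", resno = 1:5,
                             resname = c("ALA", "ASN", "SER", "GLU", "LYS"))
  links <- tibble::tibble(chain = "A", resno = c(2L, 3L),
                          atom = c("O", "OG"))
  altlocs <- tibble::tibble(chain = "A", resno = 4L)
  ss <- c("other", "other", "other", "other", "helix_mid")
  elig <- rebuild_candidates(residues, links, altlocs, ss)

  expect_false(elig$pepflip_eligible[2])    # backbone O linked
  expect_true(elig$sidechain_eligible[2])
  expect_true(elig$pepflip_eligible[3])     # side-chain link only
  expect_false(elig$sidechain_eligible[3])
  expect_false(elig$sidechain_eligible[4])  # altloc side chain
  expect_false(elig$pepflip_eligible[5])    # helix middle
  expect_true(elig$pepflip_eligible[1])     # unremarkable: fully eligible
  expect_true(elig$sidechain_eligible[1])

  bare <- rebuild_candidates(residues)
  expect_true(all(bare$pepflip_eligible))
  expect_true(all(bare$sidechain_eligible))
})

test_that("validation findings map to tasks only for the enumerated types", {
  findings <- tibble::tibble(
    chain = "A", resno = c(12L, 40L, 7L, 9L),
    restype = c("ASN", "TRP", "THR", "GLU"),
    issue = c("hn_flip", "hn_flip", "chirality", "chi2_flip")
  )
  tasks <- validation_tasks(findings)
  expect_equal(nrow(tasks), 3L)              # Trp is not enumerated
  expect_false(40L %in% tasks$resno)

  # negative selector wins over the positive selection
  elig <- rebuild_candidates(
    tibble::tibble(chain = "A", resno = c(7L, 9L, 12L)),
    links = tibble::tibble(chain = "A", resno = 7L, atom = "OG1")
  )
  gated <- validation_tasks(findings, elig)
  expect_false(7L %in% gated$resno)
  expect_true(all(c(9L, 12L) %in% gated$resno))

  expect_warning(validation_tasks(
    tibble::tibble(chain = "A", resno = 1L, restype = "ALA",
                   issue = "teleport")), "unknown")
})
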