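# Stripper removal rules, header extraction and the PDB round trip.

toy_atoms <- function() {
  dplyr::bind_rows(
    atom_table("N", "N", "ALA", "A", 1, 0, 0, 0),
    atom_table("CA", "C", "ALA", "A", 1, 1.5, 0, 0),
    atom_table("HA", "H", "ALA", "A", 1, 1.5, 1, 0),
    atom_table("CB", "C", "ALA", "A", 1, 2, 1, 1, occupancy = 0.009),
    atom_table("O", "O", "HOH", "W", 101, 5, 5, 5),
    atom_table("C1", "C", "UNL", "B", 2, 8, 0, 0),
    atom_table("N", "N", "UNK", "C", 3, 9, 0, 0),
    atom_table("CA", "C", "UNK", "C", 3, 10, 0, 0),
    atom_table("CB", "C", "UNK", "C", 3, 11, 0, 0),
    atom_table("CG", "C", "UNK", "C", 3, 12, 0, 0),
    atom_table("X1", "X", "LIG", "D", 4, 13, 0, 0),
    atom_table("UNX", "", "UNX", "E", 5, 14, 0, 0)
  )
}

test_that("stripping applies each removal rule exactly once", {
  res <- strip_model(toy_atoms())
  kept <- paste(res$atoms$residue, res$atoms$name)
  expect_false("ALA HA" %in% kept)           # explicit hydrogen
  expect_false("ALA CB" %in% kept)           # occupancy 0.009 < 0.01
  expect_false("UNL C1" %in% kept)           # unknown ligand
  expect_true("UNK CB" %in% kept)            # up to C-beta is kept
  expect_false("UNK CG" %in% kept)           # beyond C-beta removed
  expect_false("LIG X1" %in% kept)           # element X
  expect_false("UNX UNX" %in% kept)
  expect_true("HOH O" %in% kept)             # waters are never stripped
  expect_equal(res$log$n_hydrogen, 1L)
  expect_equal(res$log$n_low_occupancy, 1L)
  expect_equal(res$log$n_unk_sidechain, 1L)

  # occupancy exactly 0.01 is kept (strict inequality)
  at <- atom_table(c("CA", "CB"), "C", "ALA", "A", 1, 1:2, 0, 0,
                   occupancy = c(0.01, 0.009))
  out <- strip_model(at)
  expect_equal(out$atoms$name, "CA")
})

test_that("hydrogens are inferred from names when the element is missing", {
  at <- dplyr::bind_rows(
    atom_table("CA", "", "ALA", "A", 1, 0, 0, 0),
    atom_table("1HB", "", "ALA", "A", 1, 1, 0, 0),
    atom_table("HG21", "", "THR", "A", 2, 2, 0, 0)
  )
  out <- strip_model(at)
  expect_equal(out$atoms$name, "CA")
  expect_equal(out$log$n_hydrogen, 2L)
})

test_that("inter-symmetry LINKs are dropped and distances blanked", {
  header <- empty_header()
  header$links <- tibble::tibble(
    atom1 = c("A/1/ND2", "A/5/O"), atom2 = c("B/9/C1", "C/2/ZN"),
    inter_symmetry = c(FALSE, TRUE), distance = c(1.45, 2.1)
  )
  res <- strip_model(atom_table("CA", "C", "ALA", "A", 1, 0, 0, 0), header)
  expect_equal(nrow(res$header$links), 1L)
  expect_equal(res$header$links$atom1, "A/1/ND2")
  expect_true(is.na(res$header$links$distance))   # field blanked, record kept
  expect_equal(res$log$n_links_dropped, 1L)
})

test_that("stripping is idempotent", {
  once <- strip_model(toy_atoms())
  twice <- strip_model(once$atoms, once$header)
  expect_identical(twice$atoms, once$atoms)
  expect_equal(sum(unlist(twice$log[1, 1:7])), 0L)
})

test_that("header extraction reads R values and leaves absences absent", {
  txt <- c(
    "HEADER    HYDROLASE                               12-JAN-05   1ABC",
    "REMARK   3   R VALUE            (WORKING SET) : 0.198",
    "REMARK   3   FREE R VALUE                     : 0.243",
    "REMARK   3   SOLVENT MODEL : MASK"
  )
  hdr <- extract_header(txt)
  expect_equal(hdr$r_head, 0.198)
  expect_equal(hdr$r_free_head, 0.243)
  expect_equal(hdr$solvent_model, "MASK")
  expect_equal(hdr$deposition_year, 2005L)

  bare <- extract_header("ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00 20.00           C")
  expect_true(is.na(bare$r_head))
  expect_true(is.na(bare$r_free_head))
  expect_length(bare$tls_groups, 0L)
})

test_that("TLS groups parse selections and tensors; malformed blocks warn", {
  txt <- c(
    "REMARK   3  TLS DETAILS",
    "REMARK   3   TLS GROUP : 1",
    "REMARK   3    RESIDUE RANGE :   A     1        A    120",
    "REMARK   3    T11:   0.0100 T22:   0.0200",
    "REMARK   3    T33:   0.0300 T12:   0.0040",
    "REMARK   3    T13:   0.0050 T23:   0.0060",
    "REMARK   3    L11:   1.1000 L22:   1.2000",
    "REMARK   3    L33:   1.3000 L12:   0.1000",
    "REMARK   3    L13:   0.2000 L23:   0.3000",
    "REMARK   3    S11:   0.0100 S12:   0.0200 S13:   0.0300",
    "REMARK   3    S21:   0.0400 S22:   0.0500 S23:   0.0600",
    "REMARK   3    S31:   0.0700 S32:   0.0800 S33:   0.0900"
  )
  hdr <- extract_header(txt)
  expect_length(hdr$tls_groups, 1L)
  g <- hdr$tls_groups[[1]]
  expect_match(g$selection, "A\\s+1\\s+A\\s+120")
  expect_equal(g$t[1, 1], 0.01)
  expect_equal(g$t[1, 2], 0.004)   # symmetric completion
  expect_equal(g$t[2, 1], 0.004)
  expect_equal(g$l[3, 3], 1.3)
  expect_equal(g$s[3, 1], 0.07)

  malformed <- c("REMARK   3   TLS GROUP : 1",
                 "REMARK   3    RESIDUE RANGE :   A 1 A 120")
  expect_warning(hdr2 <- extract_header(malformed), "TLS")
  expect_length(hdr2$tls_groups, 0L)
})

test_that("LINK records round-trip through parsing with symmetry detection", {
  link_intra <- sprintf("%-80s", paste0(
    "LINK         ND2 ASN A 112                C1  NAG B   1     1555   1555  1.45"))
  link_inter <- sprintf("%-80s", paste0(
    "LINK         O   HOH W   5                ZN  ZN  C   1     1555   2565  2.10"))
  hdr <- extract_header(c(link_intra, link_inter))
  expect_equal(nrow(hdr$links), 2L)
  expect_equal(hdr$links$inter_symmetry, c(FALSE, TRUE))
})

test_that("write/read round trip preserves the stripped atom multiset", {
  res <- strip_model(toy_atoms())
  path <- withr::local_tempfile(fileext = ".pdb")
  write_model(res$atoms, path)
  back <- read_model(path)
  key <- function(a) sort(paste(a$residue, a$chain, a$resno, trimws(a$name)))
  expect_equal(key(back$atoms), key(res$atoms))
  expect_equal(back$atoms$occupancy[order(back$atoms$resno)],
               res$atoms$occupancy[order(res$atoms$resno)],
               tolerance = 0.005)
  # stripping what was already stripped changes nothing
  again <- strip_model(back$atoms, back$header)
  expect_equal(nrow(again$atoms), nrow(res$atoms))
})
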