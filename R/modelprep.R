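# Coordinate-file stripping and header metadata extraction. Atoms live in
# a tibble (one row per atom); header metadata (R factors, TLS groups,
# LINK/SSBOND connectivity, solvent model, deposition year) in a list.

WATER_RESIDUES <- c("HOH", "WAT", "DOD", "H2O")
BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

#' Build an atom table
#'
#' @param name Atom names (e.g. `"CA"`).
#' @param element Element symbols; empty strings trigger name-based
#'   inference during stripping (legacy files lacking element columns).
#' @param residue Residue names.
#' @param chain Chain identifiers.
#' @param resno Residue sequence numbers.
#' @param x,y,z Coordinates in Angstrom.
#' @param occupancy Occupancies in [0, 1].
#' @param b_factor Isotropic B factors in square Angstrom.
#' @param altloc Alternate-location indicators (`""` when absent).
#' @export
atom_table <- function(name, element, residue, chain, resno, x, y, z,
                       occupancy = 1, b_factor = 20, altloc = "") {
  tibble::tibble(
    name = as.character(name), element = as.character(element),
    residue = as.character(residue), chain = as.character(chain),
    resno = as.integer(resno),
    x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
    occupancy = as.numeric(occupancy), b_factor = as.numeric(b_factor),
    is_water = as.character(residue) %in% WATER_RESIDUES,
    altloc = as.character(altloc)
  )
}

# Element inference for legacy files: strip leading digits; hydrogen and
# deuterium when the remaining name starts with H/D, else the first
# alphabetic character(s).
infer_element <- function(name) {
  core <- sub("^[0-9']+", "", trimws(name))
  first <- substr(core, 1L, 1L)
  ifelse(first %in% c("H", "D"), "H", first)
}

#' Strip a model for refinement
#'
#' Applies the removal rules that make a deposited model safe for
#' automated restraint generation and refinement:
#' \enumerate{
#'   \item explicit H (and D) atoms;
#'   \item atoms with occupancy < 0.01 (strict);
#'   \item superfluous carbohydrate O atoms, supplied as an external
#'     detection list (`extra_oxygens`, atom row indices or keys) — a
#'     no-op when absent;
#'   \item unknown ligands (residue UNL);
#'   \item side-chain atoms beyond C-beta for unknown residues (UNK);
#'   \item inter-symmetry LINK and SSBOND records (dropped), and distance
#'     fields of remaining LINK records (blanked);
#'   \item unknown atoms (residue UNX);
#'   \item atoms of element X (no scattering factors can be assigned).
#' }
#' Water oxygens are never removed here; water pruning is a real-space
#' decision.
#'
#' @param atoms An [atom_table()].
#' @param header A header list as returned by [extract_header()].
#' @param extra_oxygens Character vector of atom keys
#'   (`"chain/resno/name"`) detected as superfluous carbohydrate oxygens
#'   by an external tool.
#' @return List with `atoms`, `header` (LINK/SSBOND edited) and
#'   `log` (one-row tibble of per-rule removal counts).
#' @export
strip_model <- function(atoms, header = empty_header(),
                        extra_oxygens = character()) {
  elem <- ifelse(nzchar(trimws(atoms$element)), toupper(trimws(atoms$element)),
                 infer_element(atoms$name))
  key <- paste(atoms$chain, atoms$resno, trimws(atoms$name), sep = "/")

  is_h <- elem %in% c("H", "D")
  low_occ <- !is_h & atoms$occupancy < 0.01
  carb_o <- !is_h & !low_occ & key %in% extra_oxygens
  unl <- atoms$residue == "UNL" & !(is_h | low_occ | carb_o)
  unk_side <- atoms$residue == "UNK" &
    !(trimws(atoms$name) %in% c(BACKBONE_ATOMS, "CB")) &
    !(is_h | low_occ | carb_o | unl)
  unx <- atoms$residue == "UNX" &
    !(is_h | low_occ | carb_o | unl | unk_side)
  elx <- elem == "X" & !(is_h | low_occ | carb_o | unl | unk_side | unx)

  drop <- is_h | low_occ | carb_o | unl | unk_side | unx | elx
  kept <- atoms[!drop, , drop = FALSE]
  if (nrow(kept) == 0L) {
    abort("no atoms left after stripping.", class = "xrefine_empty_model")
  }

  n_links_dropped <- 0L
  n_ssbond_dropped <- 0L
  if (!is.null(header$links) && nrow(header$links) > 0L) {
    inter <- header$links$inter_symmetry
    n_links_dropped <- sum(inter)
    header$links <- header$links[!inter, , drop = FALSE]
    header$links$distance <- NA_real_   # distance fields are blanked
  }
  if (!is.null(header$ssbonds) && nrow(header$ssbonds) > 0L) {
    inter <- header$ssbonds$inter_symmetry
    n_ssbond_dropped <- sum(inter)
    header$ssbonds <- header$ssbonds[!inter, , drop = FALSE]
  }

  list(
    atoms = kept, header = header,
    log = tibble::tibble(
      n_hydrogen = sum(is_h), n_low_occupancy = sum(low_occ),
      n_carb_oxygen = sum(carb_o), n_unl = sum(unl),
      n_unk_sidechain = sum(unk_side), n_unx = sum(unx),
      n_element_x = sum(elx),
      n_links_dropped = n_links_dropped,
      n_ssbonds_dropped = n_ssbond_dropped
    )
  )
}

#' @rdname extract_header
#' @export
empty_header <- function() {
  list(r_head = NA_real_, r_free_head = NA_real_,
       tls_groups = list(),
       solvent_model = NA_character_,
       links = tibble::tibble(atom1 = character(), atom2 = character(),
                              inter_symmetry = logical(),
                              distance = numeric()),
       ssbonds = tibble::tibble(atom1 = character(), atom2 = character(),
                                inter_symmetry = logical()),
       deposition_year = NA_integer_)
}

#' Extract refinement metadata from PDB-format text
#'
#' Parses REMARK 3 R factors (working and free), REMARK 3 TLS group
#' selections and tensors, the solvent-model line, LINK and SSBOND
#' connectivity (with inter-symmetry detection from the symmetry-operator
#' columns) and the deposition year from the HEADER record. Absent fields
#' are `NA`, never defaulted. A malformed TLS block yields an empty
#' `tls_groups` with a warning: refinement then simply proceeds without a
#' header TLS model.
#'
#' @param pdb_text Character vector of PDB-format lines (or a single
#'   string with newlines).
#' @return A header list: `r_head`, `r_free_head`, `tls_groups` (each a
#'   list with `selection` and a 3x3+3x3+3x3 `t`/`l`/`s` tensor set),
#'   `solvent_model`, `links`, `ssbonds`, `deposition_year`.
#' @export
extract_header <- function(pdb_text) {
  lines <- unlist(strsplit(pdb_text, "\n", fixed = TRUE))
  hdr <- empty_header()

  grab_number <- function(pattern) {
    m <- grep(pattern, lines, value = TRUE)
    if (length(m) == 0L) return(NA_real_)
    v <- sub(".*:\\s*", "", m[[1L]])
    suppressWarnings(as.numeric(sub("[^0-9.Ee+-].*$", "", trimws(v))))
  }
  hdr$r_head <- grab_number("^REMARK   3.*R VALUE.*\\(WORKING SET\\)\\s*:")
  if (is.na(hdr$r_head)) {
    hdr$r_head <- grab_number("^REMARK   3.*R VALUE\\s+\\(WORKING SET, NO CUTOFF\\)\\s*:")
  }
  hdr$r_free_head <- grab_number("^REMARK   3.*FREE R VALUE\\s*:")

  sm <- grep("^REMARK   3.*SOLVENT MODEL", lines, value = TRUE)
  if (length(sm) > 0L) {
    hdr$solvent_model <- trimws(sub(".*:\\s*", "", sm[[1L]]))
  }

  hd <- grep("^HEADER", lines, value = TRUE)
  if (length(hd) > 0L) {
    date <- substr(hd[[1L]], 51L, 59L)
    yy <- suppressWarnings(as.integer(substr(trimws(date), 8L, 9L)))
    if (!is.na(yy)) {
      hdr$deposition_year <- if (yy < 50L) 2000L + yy else 1900L + yy
    }
  }

  hdr$tls_groups <- tryCatch(parse_tls_groups(lines), error = function(e) {
    warn("malformed TLS block in REMARK 3; ignoring header TLS model.")
    list()
  })
  hdr$links <- parse_link_records(lines)
  hdr$ssbonds <- parse_ssbond_records(lines)
  hdr
}

# REMARK 3 TLS details: "TLS GROUP :", "RESIDUE RANGE :", and T/L/S tensor
# lines like "T11: 0.1 T22: 0.2".
parse_tls_groups <- function(lines) {
  r3 <- lines[grepl("^REMARK   3", lines)]
  starts <- grep("TLS GROUP\\s*:", r3)
  if (length(starts) == 0L) return(list())
  bounds <- c(starts, length(r3) + 1L)
  groups <- list()
  for (g in seq_along(starts)) {
    blk <- r3[starts[g]:(bounds[g + 1L] - 1L)]
    sel <- grep("(RESIDUE RANGE|SELECTION)\\s*:", blk, value = TRUE)
    selection <- trimws(sub(".*:\\s*", "", sel))
    tensor <- function(prefix) {
      vals <- matrix(NA_real_, 3L, 3L)
      for (i in 1:3) for (j in 1:3) {
        tag <- paste0(prefix, i, j)
        ln <- grep(paste0("\\b", tag, "\\s*:"), blk, value = TRUE)
        if (length(ln) > 0L) {
          v <- sub(paste0(".*", tag, "\\s*:\\s*"), "", ln[[1L]])
          vals[i, j] <- as.numeric(strsplit(trimws(v), "\\s+")[[1L]][1L])
        }
      }
      # symmetric tensors are printed as upper triangles
      for (i in 1:3) for (j in 1:3) {
        if (is.na(vals[i, j]) && !is.na(vals[j, i])) vals[i, j] <- vals[j, i]
      }
      vals
    }
    t_t <- tensor("T"); t_l <- tensor("L"); t_s <- tensor("S")
    if (all(is.na(t_t)) && all(is.na(t_l))) {
      stop("TLS group without tensors")
    }
    groups[[g]] <- list(selection = selection, t = t_t, l = t_l, s = t_s)
  }
  groups
}

# LINK records: atom fields at fixed columns; symmetry operators in
# columns 60-65 and 67-72; a trailing numeric field is the link distance.
parse_link_records <- function(lines) {
  lk <- lines[grepl("^LINK", lines)]
  if (length(lk) == 0L) {
    return(empty_header()$links)
  }
  lk <- formatC(lk, width = 80, flag = "-")
  atom1 <- paste(trimws(substr(lk, 22, 22)), trimws(substr(lk, 23, 26)),
                 trimws(substr(lk, 13, 16)), sep = "/")
  atom2 <- paste(trimws(substr(lk, 52, 52)), trimws(substr(lk, 53, 56)),
                 trimws(substr(lk, 43, 46)), sep = "/")
  sym1 <- trimws(substr(lk, 60, 65))
  sym2 <- trimws(substr(lk, 67, 72))
  inter <- (nzchar(sym1) & sym1 != "1555") | (nzchar(sym2) & sym2 != "1555")
  dist <- suppressWarnings(as.numeric(trimws(substr(lk, 74, 80))))
  tibble::tibble(atom1 = atom1, atom2 = atom2, inter_symmetry = inter,
                 distance = dist)
}

parse_ssbond_records <- function(lines) {
  sb <- lines[grepl("^SSBOND", lines)]
  if (length(sb) == 0L) {
    return(empty_header()$ssbonds)
  }
  sb <- formatC(sb, width = 80, flag = "-")
  atom1 <- paste(trimws(substr(sb, 16, 16)), trimws(substr(sb, 18, 21)),
                 "SG", sep = "/")
  atom2 <- paste(trimws(substr(sb, 30, 30)), trimws(substr(sb, 32, 35)),
                 "SG", sep = "/")
  sym1 <- trimws(substr(sb, 60, 65))
  sym2 <- trimws(substr(sb, 67, 72))
  inter <- (nzchar(sym1) & sym1 != "1555") | (nzchar(sym2) & sym2 != "1555")
  tibble::tibble(atom1 = atom1, atom2 = atom2, inter_symmetry = inter)
}

#' Read a PDB file into an atom table and header
#'
#' Coordinates are parsed with \pkg{bio3d}; header records (REMARK 3,
#' TLS, LINK, SSBOND, HEADER) are parsed from the raw text.
#'
#' @param path Path to a PDB file.
#' @return List with `atoms` ([atom_table()]) and `header`.
#' @export
read_model <- function(path) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  atoms <- atom_table(
    name = at$elety,
    element = ifelse(is.na(at$elesy), "", at$elesy),
    residue = at$resid, chain = at$chain, resno = at$resno,
    x = at$x, y = at$y, z = at$z,
    occupancy = ifelse(is.na(at$o), 1, at$o),
    b_factor = ifelse(is.na(at$b), 0, at$b),
    altloc = ifelse(is.na(at$alt), "", at$alt)
  )
  header <- extract_header(readLines(path, warn = FALSE))
  list(atoms = atoms, header = header)
}

#' Write an atom table (plus LINK/SSBOND records) as PDB format
#'
#' @param atoms An [atom_table()].
#' @param path Output path.
#' @param header Optional header list; surviving LINK records are written
#'   back (with blanked distance fields).
#' @export
write_model <- function(atoms, path, header = NULL) {
  lines <- character()
  if (!is.null(header) && nrow(header$links) > 0L) {
    lines <- c(lines, vapply(seq_len(nrow(header$links)), function(i) {
      p1 <- strsplit(header$links$atom1[[i]], "/")[[1L]]
      p2 <- strsplit(header$links$atom2[[i]], "/")[[1L]]
      sprintf("LINK        %-4s     LIG %1s%4s                %-4s     LIG %1s%4s",
              p1[3], p1[1], p1[2], p2[3], p2[1], p2[2])
    }, character(1)))
  }
  hetero <- atoms$is_water | atoms$residue %in% c("UNL", "UNX")
  lines <- c(lines, sprintf(
    "%-6s%5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    ifelse(hetero, "HETATM", "ATOM"),
    seq_len(nrow(atoms)),
    ifelse(nchar(atoms$name) < 4L, paste0(" ", atoms$name), atoms$name),
    substr(paste0(atoms$altloc, " "), 1L, 1L),
    atoms$residue, atoms$chain, atoms$resno,
    atoms$x, atoms$y, atoms$z, atoms$occupancy, atoms$b_factor,
    toupper(atoms$element)
  ), "END")
  writeLines(lines, path)
  invisible(path)
}
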