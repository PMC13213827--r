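# Structure parsing and ligand discovery. Coordinates and SEQRES come from
# bio3d; header records that bio3d does not expose (HEADER date, EXPDTA,
# REMARK 2/3 quality metrics, SEQADV, LINK, REMARK 600 peculiarities) are
# read from the raw lines.

.water_codes <- c("HOH", "DOD", "WAT")

.standard_residues <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL",
  "DA", "DC", "DG", "DT", "DU", "A", "C", "G", "U", "I"
)

# Elements the chemistry model handles without flagging; metals are not in it.
.supported_elements <- c("H", "C", "N", "O", "P", "S", "F", "CL", "BR", "I",
                         "B", "SE")

# Monoisotopic-free standard atomic weights (g/mol), enough to cover organic
# ligands plus the metals commonly seen in PDB hetero-groups. Unknown elements
# contribute zero weight (the ligand is flagged UNSUPPORTED_ELEMENT anyway).
.atomic_masses <- c(
  H = 1.008, D = 2.014, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  NA. = 22.990, MG = 24.305, P = 30.974, S = 32.06, CL = 35.45, K = 39.098,
  CA = 40.078, MN = 54.938, FE = 55.845, CO = 58.933, NI = 58.693,
  CU = 63.546, ZN = 65.38, AS = 74.922, SE = 78.971, BR = 79.904,
  MO = 95.95, RU = 101.07, PD = 106.42, AG = 107.87, CD = 112.41,
  I = 126.904, PT = 195.084, AU = 196.967, HG = 200.592, B = 10.81,
  SI = 28.085, AL = 26.982, LI = 6.94, W = 183.84, V = 50.942
)

.element_mass <- function(elesy) {
  key <- toupper(trimws(elesy))
  key[key == "NA"] <- "NA."
  m <- .atomic_masses[key]
  m[is.na(m)] <- 0
  unname(m)
}

#' One-line descriptions of ligand skip reasons
#'
#' @return Named character vector mapping each skip-reason code to a
#'   human-readable description.
#' @export
skip_reason_catalog <- function() {
  c(
    MISSING_ATOMS_ANNOTATED = "header metadata annotates missing atoms for this component",
    COVALENT_LINK = "LINK record joins a ligand atom to a polymer atom",
    UNSUPPORTED_ELEMENT = "ligand contains an element outside the supported organic set",
    FORMULA_MISMATCH = "observed element counts disagree with the reference formula",
    METADATA_PECULIARITY = "header metadata annotates a peculiarity for this component",
    POLYMER_LIGAND = "component code is a standard amino acid or nucleotide"
  )
}

#' Parse a PDB structure
#'
#' Reads a structure from PDB-format text (a file path, a single string, or a
#' character vector of lines). Chain sequences are taken from SEQRES when
#' present, otherwise from the ATOM records; the ATOM-derived sequence is kept
#' alongside for binding-site indexing. All non-water HETATM groups are
#' collected as candidate ligands.
#'
#' @param x Path to a PDB file, or PDB text.
#' @return A `structure_record`: list with `structure_id`, `chains` (named
#'   list; each has `chain_id`, `atoms`, `residues`, `seq_atom`, `seq_seqres`,
#'   `one_letter`), `het_groups` (list of atom data frames keyed
#'   `het:chain:resno`), `seqadv_entries`, `link_records`,
#'   `metadata_peculiarities`, `resolution`, `r_factor`, `r_free`,
#'   `experimental_method`, `deposition_date`.
#' @export
parse_structure <- function(x) {
  lines <- .as_pdb_lines(x)
  if (length(lines) == 0L || all(!nzchar(trimws(lines)))) {
    stop("empty structure text", call. = FALSE)
  }
  .check_coordinate_records(lines)

  pdbfile <- tempfile(fileext = ".pdb")
  on.exit(unlink(pdbfile), add = TRUE)
  writeLines(lines, pdbfile)
  pdb <- suppressWarnings(bio3d::read.pdb(pdbfile, verbose = FALSE))

  atoms <- pdb$atom
  poly <- atoms[atoms$type == "ATOM", , drop = FALSE]
  if (nrow(poly) == 0L) {
    stop("structure contains zero polymer chains", call. = FALSE)
  }

  header <- .parse_header(lines)
  seqres <- .parse_seqres(lines)

  chains <- lapply(sort(unique(poly$chain)), function(ch) {
    ca <- poly[poly$chain == ch, , drop = FALSE]
    resno_order <- unique(ca$resno)
    res3 <- vapply(resno_order,
                   function(rn) ca$resid[ca$resno == rn][1], character(1))
    seq_atom <- paste(.aa_one(res3), collapse = "")
    seq_seqres <- if (!is.null(seqres[[ch]])) {
      paste(.aa_one(seqres[[ch]]), collapse = "")
    } else {
      NA_character_
    }
    list(
      chain_id = ch,
      atoms = ca[, c("elety", "resid", "resno", "x", "y", "z", "elesy")],
      residues = data.frame(resid = res3, resno = resno_order,
                            stringsAsFactors = FALSE),
      seq_atom = seq_atom,
      seq_seqres = seq_seqres,
      one_letter = if (!is.na(seq_seqres)) seq_seqres else seq_atom
    )
  })
  names(chains) <- vapply(chains, `[[`, character(1), "chain_id")

  het <- atoms[atoms$type == "HETATM" & !(atoms$resid %in% .water_codes), ,
               drop = FALSE]
  het_groups <- list()
  if (nrow(het) > 0L) {
    key <- paste(het$resid, het$chain, het$resno, sep = ":")
    het_groups <- split(het[, c("elety", "resid", "chain", "resno",
                                "x", "y", "z", "elesy")], key)
    het_groups <- het_groups[unique(key)]
  }

  seqadv <- .parse_seqadv(lines)
  bad_chain <- setdiff(seqadv$chain, names(chains))
  if (length(bad_chain) > 0L) {
    warning("SEQADV entries reference unknown chain(s): ",
            paste(bad_chain, collapse = ", "))
    seqadv <- seqadv[seqadv$chain %in% names(chains), , drop = FALSE]
  }

  structure(
    list(
      structure_id = header$structure_id,
      chains = chains,
      het_groups = het_groups,
      seqadv_entries = seqadv,
      link_records = .parse_link(lines),
      metadata_peculiarities = .parse_peculiarities(lines),
      resolution = header$resolution,
      r_factor = header$r_factor,
      r_free = header$r_free,
      experimental_method = header$experimental_method,
      deposition_date = header$deposition_date
    ),
    class = "structure_record"
  )
}

#' @export
print.structure_record <- function(x, ...) {
  cat("<structure_record>", x$structure_id, "\n")
  cat("  chains:", paste(names(x$chains), collapse = ", "),
      " het groups:", length(x$het_groups), "\n")
  cat("  resolution:", if (is.na(x$resolution)) "-" else x$resolution,
      " method:", if (is.na(x$experimental_method)) "-" else x$experimental_method, "\n")
  invisible(x)
}

.as_pdb_lines <- function(x) {
  if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    return(readLines(x, warn = FALSE))
  }
  if (length(x) == 1L && grepl("\n", x)) {
    return(strsplit(x, "\n", fixed = TRUE)[[1]])
  }
  as.character(x)
}

.check_coordinate_records <- function(lines) {
  coord <- grep("^(ATOM|HETATM)", lines)
  for (i in coord) {
    ln <- lines[i]
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                         substr(ln, 39, 46),
                                         substr(ln, 47, 54))))
    if (anyNA(xyz)) {
      stop("unparseable coordinate record at line ", i, ": ", trimws(ln),
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

.aa_one <- function(res3) {
  one <- suppressWarnings(bio3d::aa321(res3))
  one[is.na(one) | !(one %in% LETTERS)] <- "X"
  one
}

.parse_header <- function(lines) {
  hdr <- grep("^HEADER", lines, value = TRUE)
  structure_id <- NA_character_
  deposition_date <- as.Date(NA)
  if (length(hdr) > 0L) {
    id <- trimws(substr(hdr[1], 63, 66))
    if (nzchar(id)) structure_id <- id
    dt <- trimws(substr(hdr[1], 51, 59))
    if (nzchar(dt)) deposition_date <- .parse_pdb_date(dt)
  }
  if (is.na(structure_id)) structure_id <- "XXXX"

  res_line <- grep("^REMARK   2 RESOLUTION", lines, value = TRUE)
  resolution <- NA_real_
  if (length(res_line) > 0L) {
    m <- regmatches(res_line[1],
                    regexpr("[0-9]+\\.?[0-9]*(?=[[:space:]]+ANGSTROM)",
                            res_line[1], perl = TRUE))
    if (length(m) > 0L) resolution <- as.numeric(m)
  }

  r_factor <- .remark3_value(lines, "R VALUE[[:space:]]+\\(WORKING SET\\)")
  r_free <- .remark3_value(lines, "^REMARK   3   FREE R VALUE[[:space:]]*:",
                           anchored = TRUE)

  exp_line <- grep("^EXPDTA", lines, value = TRUE)
  experimental_method <- if (length(exp_line) > 0L) {
    trimws(substr(exp_line[1], 11, nchar(exp_line[1])))
  } else {
    NA_character_
  }

  list(structure_id = structure_id, deposition_date = deposition_date,
       resolution = resolution, r_factor = r_factor, r_free = r_free,
       experimental_method = experimental_method)
}

# DD-MMM-YY with English month abbreviations, independent of locale
.parse_pdb_date <- function(dt) {
  parts <- strsplit(toupper(dt), "-", fixed = TRUE)[[1]]
  if (length(parts) != 3L) return(as.Date(NA))
  months <- c("JAN", "FEB", "MAR", "APR", "MAY", "JUN",
              "JUL", "AUG", "SEP", "OCT", "NOV", "DEC")
  m <- match(parts[2], months)
  day <- suppressWarnings(as.integer(parts[1]))
  yy <- suppressWarnings(as.integer(parts[3]))
  if (is.na(m) || is.na(day) || is.na(yy)) return(as.Date(NA))
  year <- if (yy <= 68L) 2000L + yy else 1900L + yy
  as.Date(sprintf("%04d-%02d-%02d", year, m, day))
}

.remark3_value <- function(lines, pattern, anchored = FALSE) {
  pat <- if (anchored) pattern else paste0("^REMARK   3.*", pattern)
  ln <- grep(pat, lines, value = TRUE)
  if (length(ln) == 0L) return(NA_real_)
  m <- regmatches(ln[1], regexpr("[0-9]+\\.[0-9]+", ln[1]))
  if (length(m) == 0L) NA_real_ else as.numeric(m)
}

.parse_seqres <- function(lines) {
  sr <- grep("^SEQRES", lines, value = TRUE)
  if (length(sr) == 0L) return(list())
  chain <- substr(sr, 12, 12)
  out <- lapply(unique(chain), function(ch) {
    toks <- unlist(strsplit(trimws(substr(sr[chain == ch], 20, 70)), "[ ]+"))
    toks[nzchar(toks)]
  })
  names(out) <- unique(chain)
  out
}

.parse_seqadv <- function(lines) {
  sa <- grep("^SEQADV", lines, value = TRUE)
  data.frame(
    chain = substr(sa, 17, 17),
    position = suppressWarnings(as.integer(substr(sa, 19, 22))),
    modeled_residue = trimws(substr(sa, 13, 15)),
    reference_residue = trimws(substr(sa, 40, 42)),
    comment = trimws(substr(sa, 50, pmax(nchar(sa), 50))),
    stringsAsFactors = FALSE
  )
}

.parse_link <- function(lines) {
  lk <- grep("^LINK", lines, value = TRUE)
  data.frame(
    atom1 = trimws(substr(lk, 13, 16)),
    res1 = trimws(substr(lk, 18, 20)),
    chain1 = substr(lk, 22, 22),
    resno1 = suppressWarnings(as.integer(substr(lk, 23, 26))),
    atom2 = trimws(substr(lk, 43, 46)),
    res2 = trimws(substr(lk, 48, 50)),
    chain2 = substr(lk, 52, 52),
    resno2 = suppressWarnings(as.integer(substr(lk, 53, 56))),
    stringsAsFactors = FALSE
  )
}

# REMARK 600 free text: first token that looks like a component code names the
# hetero-group, the remainder is the issue description.
.parse_peculiarities <- function(lines) {
  rem <- grep("^REMARK 600", lines, value = TRUE)
  rem <- trimws(substr(rem, 12, vapply(rem, nchar, integer(1))))
  rem <- rem[nzchar(rem) & !(toupper(rem) %in% c("HETEROGEN"))]
  if (length(rem) == 0L) {
    return(data.frame(het_code = character(), issue = character(),
                      stringsAsFactors = FALSE))
  }
  toks <- strsplit(rem, "[ ]+")
  data.frame(
    het_code = vapply(toks, `[`, character(1), 1L),
    issue = vapply(toks, function(t) paste(t[-1], collapse = " "), character(1)),
    stringsAsFactors = FALSE
  )
}

#' Extract candidate ligands with consistency checks
#'
#' Builds one ligand record per non-water hetero-group with descriptors
#' computed from the atoms present in the file. Problems never remove a
#' ligand; they are encoded as skip reasons: header peculiarities
#' (`MISSING_ATOMS_ANNOTATED` when the annotation mentions missing atoms,
#' otherwise `METADATA_PECULIARITY`), covalent linkage to the polymer
#' (`COVALENT_LINK`), elements outside the supported organic set
#' (`UNSUPPORTED_ELEMENT`), element counts disagreeing with a reference
#' formula (`FORMULA_MISMATCH`), and standard residues appearing as
#' hetero-groups (`POLYMER_LIGAND`).
#'
#' @param s A `structure_record`.
#' @param ref_formulas Optional named character vector or two-column data
#'   frame (`het_code`, `formula`) of reference formulas such as
#'   `"C10 H16 N5 O13 P3"`; hydrogens are ignored in the comparison since
#'   they are usually absent from coordinates.
#' @return A data frame of class `ligand_inventory`: `structure_id`,
#'   `het_code`, `chain_id`, `residue_number`, `heavy_atom_count`,
#'   `molecular_weight`, `covalent`, `skip_reasons` (semicolon-joined, empty
#'   when clean).
#' @export
extract_ligands <- function(s, ref_formulas = NULL) {
  stopifnot(inherits(s, "structure_record"))
  if (length(s$het_groups) == 0L) {
    out <- data.frame(structure_id = character(), het_code = character(),
                      chain_id = character(), residue_number = integer(),
                      heavy_atom_count = integer(), molecular_weight = numeric(),
                      covalent = logical(), skip_reasons = character(),
                      stringsAsFactors = FALSE)
    class(out) <- c("ligand_inventory", "data.frame")
    return(out)
  }
  ref <- .ref_formula_counts(ref_formulas)

  rows <- lapply(s$het_groups, function(g) {
    het_code <- g$resid[1]
    chain_id <- g$chain[1]
    resno <- g$resno[1]
    elem <- toupper(trimws(g$elesy))
    heavy <- !(elem %in% c("H", "D"))
    reasons <- character()

    pec <- s$metadata_peculiarities
    pec <- pec[pec$het_code == het_code, , drop = FALSE]
    if (nrow(pec) > 0L) {
      if (any(grepl("MISSING", toupper(pec$issue)))) {
        reasons <- c(reasons, "MISSING_ATOMS_ANNOTATED")
      }
      if (any(!grepl("MISSING", toupper(pec$issue)))) {
        reasons <- c(reasons, "METADATA_PECULIARITY")
      }
    }

    covalent <- .is_covalently_linked(s, het_code, chain_id, resno)
    if (covalent) reasons <- c(reasons, "COVALENT_LINK")

    if (any(!(elem %in% .supported_elements))) {
      reasons <- c(reasons, "UNSUPPORTED_ELEMENT")
    }

    if (!is.null(ref[[het_code]])) {
      obs <- table(elem[heavy])
      expect <- ref[[het_code]]
      expect <- expect[!(names(expect) %in% c("H", "D"))]
      same <- length(obs) == length(expect) &&
        setequal(names(obs), names(expect)) &&
        all(obs[names(expect)] == expect)
      if (!same) reasons <- c(reasons, "FORMULA_MISMATCH")
    }

    if (het_code %in% .standard_residues) {
      reasons <- c(reasons, "POLYMER_LIGAND")
    }

    data.frame(
      structure_id = s$structure_id,
      het_code = het_code,
      chain_id = chain_id,
      residue_number = resno,
      heavy_atom_count = sum(heavy),
      molecular_weight = sum(.element_mass(elem)),
      covalent = covalent,
      skip_reasons = paste(unique(reasons), collapse = ";"),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  class(out) <- c("ligand_inventory", "data.frame")
  out
}

.ref_formula_counts <- function(ref_formulas) {
  if (is.null(ref_formulas)) return(list())
  if (is.data.frame(ref_formulas)) {
    v <- ref_formulas[[2]]
    names(v) <- ref_formulas[[1]]
    ref_formulas <- v
  }
  lapply(as.list(ref_formulas), function(f) {
    toks <- strsplit(trimws(f), "[ ]+")[[1]]
    counts <- as.integer(sub("^[A-Za-z]+", "", toks))
    counts[is.na(counts)] <- 1L
    names(counts) <- toupper(sub("[0-9]+$", "", toks))
    tapply(counts, names(counts), sum)
  })
}

.is_covalently_linked <- function(s, het_code, chain_id, resno) {
  lk <- s$link_records
  if (nrow(lk) == 0L) return(FALSE)
  is_poly <- function(res, ch, rn) {
    !is.na(ch) & ch %in% names(s$chains) &
      mapply(function(cc, rr) {
        !is.na(rr) && !is.null(s$chains[[cc]]) && rr %in% s$chains[[cc]]$residues$resno
      }, ch, rn) &
      res %in% .standard_residues
  }
  side1 <- lk$res1 == het_code & lk$chain1 == chain_id & lk$resno1 == resno
  side2 <- lk$res2 == het_code & lk$chain2 == chain_id & lk$resno2 == resno
  any(side1 & is_poly(lk$res2, lk$chain2, lk$resno2)) ||
    any(side2 & is_poly(lk$res1, lk$chain1, lk$resno1))
}

#' Compute the binding site of a ligand
#'
#' A polymer residue belongs to the site when at least one of its atoms lies
#' within `cutoff` angstroms of at least one ligand heavy atom. The default
#' cutoff is the 3.25-angstrom radius of a 6.5-angstrom-diameter sphere around
#' each ligand heavy atom; it is configurable because radius conventions vary.
#'
#' @param s A `structure_record`.
#' @param het_code,chain_id,residue_number Identify the ligand instance
#'   (a `het:chain:resno` group of `s`).
#' @param cutoff Distance cutoff in angstroms (> 0).
#' @return A `binding_site`: list with `ligand_ref`, `cutoff`, `residues`
#'   (data frame `chain_id`, `residue_number`), and `sequence_positions`
#'   (per-chain integer indices into the ATOM-derived chain sequence).
#' @export
find_binding_site <- function(s, het_code, chain_id, residue_number,
                              cutoff = 3.25) {
  stopifnot(inherits(s, "structure_record"), cutoff > 0)
  key <- paste(het_code, chain_id, residue_number, sep = ":")
  g <- s$het_groups[[key]]
  if (is.null(g)) {
    stop("no hetero-group ", key, " in structure ", s$structure_id,
         call. = FALSE)
  }
  heavy <- g[!(toupper(trimws(g$elesy)) %in% c("H", "D")), , drop = FALSE]
  if (nrow(heavy) == 0L) {
    stop("degenerate ligand with zero heavy atoms: ", key, call. = FALSE)
  }
  lig_xyz <- as.matrix(heavy[, c("x", "y", "z")])

  res_rows <- list()
  seq_pos <- list()
  for (ch in names(s$chains)) {
    chain <- s$chains[[ch]]
    axyz <- as.matrix(chain$atoms[, c("x", "y", "z")])
    # min distance of each polymer atom to any ligand heavy atom
    d2 <- apply(lig_xyz, 1, function(p) {
      (axyz[, 1] - p[1])^2 + (axyz[, 2] - p[2])^2 + (axyz[, 3] - p[3])^2
    })
    d2 <- matrix(d2, nrow = nrow(axyz))
    within <- .row_mins(d2) <= cutoff^2
    hit_resno <- sort(unique(chain$atoms$resno[within]))
    if (length(hit_resno) > 0L) {
      res_rows[[ch]] <- data.frame(chain_id = ch, residue_number = hit_resno,
                                   stringsAsFactors = FALSE)
      seq_pos[[ch]] <- match(hit_resno, chain$residues$resno)
    }
  }
  residues <- if (length(res_rows) > 0L) {
    do.call(rbind, c(res_rows, list(make.row.names = FALSE)))
  } else {
    data.frame(chain_id = character(), residue_number = integer(),
               stringsAsFactors = FALSE)
  }
  structure(
    list(
      ligand_ref = list(structure_id = s$structure_id, het_code = het_code,
                        chain_id = chain_id, residue_number = residue_number),
      cutoff = cutoff,
      residues = residues,
      sequence_positions = seq_pos
    ),
    class = "binding_site"
  )
}

# row-wise minimum of a numeric matrix
.row_mins <- function(m) {
  if (ncol(m) == 1L) return(m[, 1])
  do.call(pmin, as.data.frame(m))
}

#' Write a ligand inventory as TSV
#'
#' @param inventory A `ligand_inventory` data frame.
#' @param path Output file path.
#' @export
write_ligand_inventory <- function(inventory, path) {
  utils::write.table(inventory, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
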