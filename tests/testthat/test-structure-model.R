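# Ligand discovery, consistency flags, and binding-site geometry.

# Minimal hand-built PDB with a 3-residue chain; hetero-groups are appended
# per test. Coordinates put residue CA atoms 3.8 A apart on the x axis.
base_pdb <- function(extra = character()) {
  c(
    "HEADER    SYNTHETIC COMPLEX                       12-MAR-05   1ABC",
    "EXPDTA    X-RAY DIFFRACTION",
    "REMARK   2 RESOLUTION.    1.80 ANGSTROMS.",
    "REMARK   3   R VALUE            (WORKING SET) : 0.185",
    "REMARK   3   FREE R VALUE                     : 0.221",
    "SEQRES   1 A    3  ALA GLY SER",
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00 20.00           C",
    "ATOM      2  CA  GLY A   2       3.800   0.000   0.000  1.00 20.00           C",
    "ATOM      3  CA  SER A   3       7.600   0.000   0.000  1.00 20.00           C",
    extra,
    "END"
  )
}

het_line <- function(serial, name, resid, resno, x, y, z, elem) {
  sprintf("HETATM%5d  %-3s %-3s A%4d    %8.3f%8.3f%8.3f  1.00 30.00          %2s",
          serial, name, resid, resno, x, y, z, elem)
}

# ATP heavy-atom composition C10 N5 O13 P3; the expected count of 31 is
# derived by counting the non-hydrogen atom records appended to the fixture.
atp_lines <- function() {
  elems <- c(rep("C", 10), rep("N", 5), rep("O", 13), rep("P", 3))
  vapply(seq_along(elems), function(k) {
    het_line(100 + k, paste0(elems[k], k), "ATP", 201, 50 + 3 * k, 50, 0,
             elems[k])
  }, character(1))
}

test_that("parsing recovers chains, header fields, and hetero-groups", {
  s <- parse_structure(base_pdb(atp_lines()))
  expect_equal(s$structure_id, "1ABC")
  expect_equal(names(s$chains), "A")
  expect_equal(s$chains$A$one_letter, "AGS")
  expect_equal(s$resolution, 1.8)
  expect_equal(s$r_factor, 0.185)
  expect_equal(s$r_free, 0.221)
  expect_equal(s$experimental_method, "X-RAY DIFFRACTION")
  expect_equal(s$deposition_date, as.Date("2005-03-12"))
  expect_length(s$het_groups, 1L)
})

test_that("degenerate structure text is rejected with a clear error", {
  expect_error(parse_structure(""), "empty")
  expect_error(parse_structure(base_pdb(
    "HETATM  999  C1  LIG A 301      bad       1.0     2.0  1.00 30.00           C"
  )), "line")
})

test_that("ATP group yields 31 heavy atoms and no skip reasons", {
  atp <- atp_lines()
  n_heavy_expected <- length(atp)  # independent count of atom records
  expect_equal(n_heavy_expected, 31L)
  ligs <- extract_ligands(parse_structure(base_pdb(atp)))
  expect_equal(nrow(ligs), 1L)
  expect_equal(ligs$heavy_atom_count, 31L)
  expect_equal(ligs$skip_reasons, "")
  expect_false(ligs$covalent)
  # molecular weight of the heavy atoms present (no hydrogens in the file)
  mw_expected <- 10 * 12.011 + 5 * 14.007 + 13 * 15.999 + 3 * 30.974
  expect_equal(ligs$molecular_weight, mw_expected, tolerance = 1e-9)
})

test_that("consistency problems become skip reasons, never failures", {
  fe <- het_line(101, "FE1", "FEX", 202, 60, 60, 0, "FE")
  lig <- c(
    het_line(110, "C1", "LIG", 203, 0, 3.0, 0, "C"),
    het_line(111, "O1", "LIG", 203, 0, 40, 0, "O")
  )
  link <- "LINK         C1  LIG A 203                 CA  ALA A   1"
  rem <- "REMARK 600 LIG MISSING ATOMS IN DENSITY"
  s <- parse_structure(base_pdb(c(fe, lig, link, rem)))
  ligs <- extract_ligands(s)
  expect_equal(nrow(ligs), 2L)
  fe_row <- ligs[ligs$het_code == "FEX", ]
  expect_match(fe_row$skip_reasons, "UNSUPPORTED_ELEMENT")
  lig_row <- ligs[ligs$het_code == "LIG", ]
  expect_true(lig_row$covalent)
  expect_match(lig_row$skip_reasons, "COVALENT_LINK")
  expect_match(lig_row$skip_reasons, "MISSING_ATOMS_ANNOTATED")
})

test_that("reference formula disagreement is flagged", {
  lig <- c(het_line(110, "C1", "LIG", 203, 0, 3.0, 0, "C"),
           het_line(111, "O1", "LIG", 203, 0, 40, 0, "O"))
  s <- parse_structure(base_pdb(lig))
  ok <- extract_ligands(s, ref_formulas = c(LIG = "C1 O1"))
  expect_equal(ok$skip_reasons, "")
  bad <- extract_ligands(s, ref_formulas = c(LIG = "C2 O1"))
  expect_match(bad$skip_reasons, "FORMULA_MISMATCH")
})

test_that("water is never a ligand and polymer components are flagged", {
  hoh <- het_line(120, "O", "HOH", 301, 90, 90, 0, "O")
  ala <- c(het_line(121, "N1", "ALA", 302, 80, 80, 0, "N"),
           het_line(122, "C2", "ALA", 302, 82, 80, 0, "C"))
  s <- parse_structure(base_pdb(c(hoh, ala)))
  ligs <- extract_ligands(s)
  expect_equal(nrow(ligs), 1L)  # only the ALA het group; HOH excluded
  expect_match(ligs$skip_reasons, "POLYMER_LIGAND")
})

test_that("binding-site membership follows the distance cutoff exactly", {
  # ligand atom at the origin-residue CA +3.0 on y; CA of residue 1 at origin
  near <- het_line(110, "C1", "LIG", 203, 3.0, 0, 0, "C")
  s <- parse_structure(base_pdb(near))
  bs <- find_binding_site(s, "LIG", "A", 203, cutoff = 3.25)
  expect_true(1 %in% bs$residues$residue_number)  # 3.0 <= 3.25

  far <- het_line(110, "C1", "LIG", 203, 3.5, 10, 0, "C")
  s2 <- parse_structure(base_pdb(far))
  bs2 <- find_binding_site(s2, "LIG", "A", 203, cutoff = 3.25)
  expect_equal(nrow(bs2$residues), 0L)

  # union over ligand atoms: residue within cutoff of the second atom only
  two <- c(het_line(110, "C1", "LIG", 203, 50, 50, 0, "C"),
           het_line(111, "C2", "LIG", 203, 7.6, 3.0, 0, "C"))
  s3 <- parse_structure(base_pdb(two))
  bs3 <- find_binding_site(s3, "LIG", "A", 203, cutoff = 3.25)
  expect_equal(bs3$residues$residue_number, 3L)
  expect_equal(bs3$sequence_positions$A, 3L)
})

test_that("binding sites are invariant under rigid motion", {
  spec <- scenario_spec(11)
  g <- generate_structure(spec, 1)
  s <- parse_structure(g$pdb)
  lig <- extract_ligands(s)[1, ]
  bs <- find_binding_site(s, lig$het_code, lig$chain_id, lig$residue_number)

  # rotate all coordinates 90 degrees about z and translate
  rot <- function(lines) {
    vapply(lines, function(ln) {
      if (!grepl("^(ATOM|HETATM)", ln)) return(ln)
      x <- as.numeric(substr(ln, 31, 38)); y <- as.numeric(substr(ln, 39, 46))
      z <- as.numeric(substr(ln, 47, 54))
      xyz <- c(-y + 11.5, x - 3.2, z + 7.9)
      paste0(substr(ln, 1, 30), sprintf("%8.3f%8.3f%8.3f", xyz[1], xyz[2], xyz[3]),
             substr(ln, 55, nchar(ln)))
    }, character(1), USE.NAMES = FALSE)
  }
  s2 <- parse_structure(rot(g$pdb))
  bs2 <- find_binding_site(s2, lig$het_code, lig$chain_id, lig$residue_number)
  expect_equal(bs$residues, bs2$residues)
  expect_equal(bs$sequence_positions, bs2$sequence_positions)
})

test_that("degenerate and unknown ligands raise errors", {
  s <- parse_structure(base_pdb(atp_lines()))
  expect_error(find_binding_site(s, "XXX", "A", 999), "no hetero-group")
  expect_error(find_binding_site(s, "ATP", "A", 201, cutoff = -1))
})

test_that("ligand inventory round-trips through its TSV writer", {
  s <- parse_structure(base_pdb(atp_lines()))
  inv <- extract_ligands(s)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ligand_inventory(inv, path)
  back <- read.delim(path, stringsAsFactors = FALSE)
  expect_equal(back$het_code, inv$het_code)
  expect_equal(back$heavy_atom_count, inv$heavy_atom_count)
})
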