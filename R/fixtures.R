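# Synthetic-scenario generator. Each scenario plants structures, molecules
# and bioactivity tables whose correct pipeline outputs (ligand inventory,
# binding sites, alignment statistics, molecule match levels, cascade winner
# and deciding step, variant handling) are derivable in closed form at
# generation time, so end-to-end runs can be checked exactly with no
# external data.
#
# Geometry: extended-chain backbone along the x axis (3.8 A consecutive CA
# spacing, side chains reduced to CB stubs on the -y side); binding-site
# contact atoms sit 3.0 A above the CA of each planted site residue, all
# other ligand atoms are parked far from the chain. Hit sequences derive
# from the chain sequence by controlled edits (interior substitutions,
# terminal extensions), which keeps the optimal local alignment full-length
# and its statistics predictable.

.aa20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

.aa_three <- c(
  A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE", G = "GLY",
  H = "HIS", I = "ILE", K = "LYS", L = "LEU", M = "MET", N = "ASN",
  P = "PRO", Q = "GLN", R = "ARG", S = "SER", T = "THR", V = "VAL",
  W = "TRP", Y = "TYR"
)

.pdb_months <- c("JAN", "FEB", "MAR", "APR", "MAY", "JUN",
                 "JUL", "AUG", "SEP", "OCT", "NOV", "DEC")

.scenario_steps <- c("SINGLE", "SEQUENCE", "MOLECULE", "MUTATIONS",
                     "TARGET_TYPE", "DATAPOINTS", "TIEBREAK", "DUMMY",
                     "EMPTY", "SEQADV", "VARIANT", "UNDEFINED_VARIANT")

.scenario_features <- c("none", "covalent", "metal", "remark600_missing",
                        "remark600_other", "water", "polymer")

#' The built-in small-molecule library of the scenario generator
#'
#' Five families, each with the SMILES of the base molecule, an atom-order
#' permuted copy (level 5), and where chemically meaningful an enantiomer
#' (level 3), a tautomer (level 1), a protonation variant (level 2), and an
#' unrelated partner (level 0), plus the heavy-atom element list used to
#' write HETATM records.
#'
#' @return Named list of family descriptions.
#' @export
fixture_ligand_library <- function() {
  list(
    LG1 = list(  # L-alanine: chiral
      smiles = "C[C@@H](N)C(=O)O",
      same = "OC(=O)[C@@H](C)N",
      enantiomer = "C[C@H](N)C(=O)O",
      unrelated = "c1ccccc1O",
      elements = c("C", "C", "C", "N", "O", "O")
    ),
    LG2 = list(  # acetone: keto/enol pair
      smiles = "CC(C)=O",
      same = "O=C(C)C",
      tautomer = "CC(=C)O",
      unrelated = "CCN",
      elements = c("C", "C", "C", "O")
    ),
    LG3 = list(  # acetic acid: protonation variant
      smiles = "CC(=O)O",
      same = "OC(C)=O",
      protomer = "CC(=O)[O-]",
      unrelated = "CCCl",
      elements = c("C", "C", "O", "O")
    ),
    LG4 = list(  # (R)-2-butanol: chiral
      smiles = "C[C@H](O)CC",
      same = "CC[C@@H](O)C",
      enantiomer = "C[C@@H](O)CC",
      unrelated = "c1ccncc1",
      elements = c("C", "C", "C", "C", "O")
    ),
    LG5 = list(  # L-serine: chiral
      smiles = "C([C@@H](N)C(=O)O)O",
      same = "OC[C@@H](N)C(O)=O",
      enantiomer = "C([C@H](N)C(=O)O)O",
      unrelated = "CCSC",
      elements = c("C", "C", "C", "N", "O", "O", "O")
    )
  )
}

#' Describe a synthetic linking scenario
#'
#' @param seed Integer seed; everything downstream is a deterministic
#'   function of the seed and the parameters below.
#' @param n_structures Number of structures to plant.
#' @param chain_length_range Inclusive residue-count range for chains.
#' @param n_site_residues Binding-site residues planted per main ligand.
#' @param cutoff Binding-site cutoff the geometry is built for.
#' @return A `scenario_spec` list.
#' @export
scenario_spec <- function(seed, n_structures = 3,
                          chain_length_range = c(30, 50),
                          n_site_residues = 3, cutoff = 3.25) {
  stopifnot(length(seed) == 1L, is.finite(seed),
            n_structures >= 1L, chain_length_range[1] >= 12L)
  structure(list(seed = as.integer(seed), n_structures = n_structures,
                 chain_length_range = chain_length_range,
                 n_site_residues = n_site_residues, cutoff = cutoff),
            class = "scenario_spec")
}

# Deterministic full plan for the scenario: sequences, sites, mutations,
# targets, molecules, dates, and the expected (truth) values.
.scenario_plan <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(spec$seed)

  lib <- fixture_ligand_library()
  plans <- vector("list", spec$n_structures)
  dummy_used <- FALSE
  for (i in seq_len(spec$n_structures)) {
    L <- sample(spec$chain_length_range[1]:spec$chain_length_range[2], 1)
    aa <- sample(.aa20, L, replace = TRUE)
    interior <- 3:(L - 2)
    site <- sort(sample(interior, spec$n_site_residues))
    free <- setdiff(interior, site)
    # stride-5 rotation spreads step types; the single shared dummy accession
    # can only carry one component sequence, so at most one dummy-bearing
    # blueprint per scenario
    step <- .scenario_steps[((i - 1L) * 5L + spec$seed) %% length(.scenario_steps) + 1L]
    if (step %in% c("DUMMY", "EMPTY")) {
      if (isTRUE(dummy_used)) step <- "TIEBREAK" else dummy_used <- TRUE
    }
    feature <- .scenario_features[(i + spec$seed) %% length(.scenario_features) + 1L]
    family_name <- names(lib)[(i - 1L) %% length(lib) + 1L]
    fam <- lib[[family_name]]
    # chiral families for MOLECULE scenarios (need an enantiomer)
    if (step == "MOLECULE" && is.null(fam$enantiomer)) {
      family_name <- "LG1"
      fam <- lib$LG1
    }
    mut_out <- sample(free, 1)
    mut_out2 <- sample(setdiff(free, mut_out), 1)
    mut_in <- sample(site, 1)
    adv_pos <- sample(setdiff(free, c(mut_out, mut_out2)), 1)
    dep_year <- 2001L + (i * 2L + spec$seed) %% 18L
    doc_year <- 2001L + (i * 3L + spec$seed + 5L) %% 18L

    plans[[i]] <- list(
      index = i,
      structure_id = sprintf("S%03d", i),
      chain_id = "A",
      L = L, aa = aa, site = site, step = step, feature = feature,
      family_name = family_name, fam = fam,
      mut_out = mut_out, mut_out2 = mut_out2, mut_in = mut_in,
      adv_pos = adv_pos,
      dep_date = as.Date(sprintf("%d-%02d-%02d", dep_year,
                                 1L + (i + spec$seed) %% 12L,
                                 1L + (i * 5L + spec$seed) %% 28L)),
      doc_date = as.Date(sprintf("%d-%02d-%02d", doc_year,
                                 1L + (i * 7L + spec$seed) %% 12L,
                                 1L + (i * 3L + spec$seed) %% 28L)),
      resolution = round(1.5 + 0.1 * ((i + spec$seed) %% 15L), 2),
      r_factor = 0.18, r_free = 0.22,
      targets = NULL  # filled below
    )
    plans[[i]]$targets <- .plan_targets(plans[[i]], spec)
  }
  plans
}

# substitute a different residue at a position (deterministic cyclic pick)
.other_aa <- function(res) {
  .aa20[(match(res, .aa20)) %% length(.aa20) + 1L]
}

.mutate_seq <- function(aa, positions) {
  for (p in positions) aa[p] <- .other_aa(aa[p])
  paste(aa, collapse = "")
}

# Target blueprints for one structure. Each target records its hit sequence,
# molecule relation, expected alignment statistics (closed form: controlled
# interior edits keep the optimal local alignment full-length), expected
# mutation counts against the pair's site, and data-point count.
.plan_targets <- function(p, spec) {
  L <- p$L
  base <- 1000L * p$index
  chain_seq <- paste(p$aa, collapse = "")
  exact <- function(acc, type = "SINGLE PROTEIN", n_dp = 2L, mol = "same",
                    variant = NA_character_) {
    list(acc = sprintf("CHEMBL%d", acc), type = type,
         component = chain_seq, variant = variant, n_dp = n_dp, mol = mol,
         identity = 100, alen = L, hlen = L, nmut = 0L, from_seqadv = FALSE)
  }
  mut1 <- function(acc, pos, in_site, type = "SINGLE PROTEIN", n_dp = 2L,
                   mol = "same") {
    list(acc = sprintf("CHEMBL%d", acc), type = type,
         component = .mutate_seq(p$aa, pos), variant = NA_character_,
         n_dp = n_dp, mol = mol, identity = 100 * (L - 1) / L, alen = L,
         hlen = L, nmut = if (in_site) 1L else 0L, from_seqadv = FALSE)
  }
  extended <- function(acc, flank = 5L, type = "SINGLE PROTEIN", n_dp = 2L,
                       mol = "same") {
    fl <- function(n) paste(sample(.aa20, n, replace = TRUE), collapse = "")
    list(acc = sprintf("CHEMBL%d", acc), type = type,
         component = paste0(fl(flank), chain_seq, fl(flank)),
         variant = NA_character_, n_dp = n_dp, mol = mol,
         identity = 100, alen = L, hlen = L + 2L * flank, nmut = 0L,
         from_seqadv = FALSE)
  }

  switch(p$step,
    SINGLE = list(exact(base + 10L)),
    SEQUENCE = list(exact(base + 10L),
                    mut1(base + 20L, p$mut_out, in_site = FALSE)),
    MOLECULE = list(exact(base + 10L, mol = "same"),
                    exact(base + 20L, mol = "enantiomer")),
    MUTATIONS = list(mut1(base + 10L, p$mut_out, in_site = FALSE),
                     mut1(base + 20L, p$mut_in, in_site = TRUE)),
    TARGET_TYPE = list(exact(base + 10L),
                       exact(base + 20L, type = "PROTEIN FAMILY")),
    DATAPOINTS = list(extended(base + 10L, n_dp = 5L),
                      extended(base + 20L, n_dp = 2L)),
    TIEBREAK = list(exact(base + 10L), exact(base + 20L)),
    DUMMY = list(exact(base + 10L), exact(612545L)),
    EMPTY = list(exact(612545L)),
    SEQADV = {
      # T2's component equals the SEQADV-adjusted chain; its best alignment
      # is the adjusted one and carries the SEQADV flag
      adv_aa <- p$aa
      adv_aa[p$adv_pos] <- .other_aa(adv_aa[p$adv_pos])
      t2 <- list(acc = sprintf("CHEMBL%d", base + 20L),
                 type = "SINGLE PROTEIN",
                 component = paste(adv_aa, collapse = ""),
                 variant = NA_character_, n_dp = 2L, mol = "same",
                 identity = 100, alen = L, hlen = L, nmut = 0L,
                 from_seqadv = TRUE)
      list(exact(base + 10L), t2)
    },
    VARIANT = {
      # component diverges (two out-of-site substitutions) but every assay
      # carries the exact chain as variant sequence
      t1 <- exact(base + 10L, variant = chain_seq)
      t1$component <- .mutate_seq(p$aa, c(p$mut_out, p$mut_out2))
      t1$hlen <- L
      t1
      list(t1)
    },
    UNDEFINED_VARIANT = list(exact(base + 10L,
                                   variant = "UNDEFINED MUTATION")),
    stop("unknown scenario step ", p$step)
  )
}

# expected deciding step per blueprint and mode
.expected_decision <- function(step, mode) {
  if (mode == "binding") {
    switch(step,
      SINGLE = , VARIANT = , UNDEFINED_VARIANT = "SINGLE",
      SEQUENCE = "SEQUENCE", MOLECULE = "MOLECULE", MUTATIONS = "MUTATIONS",
      TARGET_TYPE = "TARGET_TYPE", DATAPOINTS = "DATAPOINTS",
      TIEBREAK = "TIEBREAK", DUMMY = "DUMMY", EMPTY = "DUMMY",
      SEQADV = "SEQADV")
  } else {
    switch(step,
      SINGLE = , VARIANT = , UNDEFINED_VARIANT = "SINGLE",
      SEQUENCE = "SEQUENCE",
      MOLECULE = , MUTATIONS = , DATAPOINTS = , TIEBREAK = "TIEBREAK",
      TARGET_TYPE = "TARGET_TYPE", DUMMY = "DUMMY", EMPTY = "DUMMY",
      SEQADV = "SEQADV")
  }
}

.mol_level_expected <- c(same = 5L, enantiomer = 3L, protomer = 2L,
                         tautomer = 1L, unrelated = 0L)

.fmt_pdb_atom <- function(serial, name, resid, chain, resno, x, y, z, elem,
                          het = FALSE) {
  rec <- if (het) "HETATM" else "ATOM  "
  name_f <- if (nchar(elem) == 2L) sprintf("%-4s", name) else sprintf(" %-3s", name)
  sprintf("%s%5d %s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rec, serial, name_f, resid, chain, resno, x, y, z, 1, 20,
          toupper(elem))
}

#' Generate one synthetic structure of a scenario
#'
#' Writes a syntactically valid PDB text for structure `index`: header with
#' deposition date and quality remarks, SEQRES, extended-chain ATOM records,
#' the main HETATM ligand placed so its binding site at the configured
#' cutoff is exactly the planted residue set, and the scenario's optional
#' SEQADV / LINK / REMARK 600 / extra hetero-group records. Byte-identical
#' for identical specs.
#'
#' @param spec A `scenario_spec`.
#' @param index Structure index in `1:spec$n_structures`.
#' @return List with `pdb` (character vector of lines) and `truth` (expected
#'   ligand inventory, binding-site residue numbers, chain sequence).
#' @export
generate_structure <- function(spec, index) {
  plan <- .scenario_plan(spec)
  stopifnot(index >= 1L, index <= length(plan))
  .render_structure(plan[[index]], spec)
}

.render_structure <- function(p, spec) {
  L <- p$L
  id <- p$structure_id
  dep <- sprintf("%02d-%s-%02d",
                 as.integer(format(p$dep_date, "%d")),
                 .pdb_months[as.integer(format(p$dep_date, "%m"))],
                 as.integer(format(p$dep_date, "%Y")) %% 100L)
  lines <- c(
    sprintf("HEADER    %-40s%9s   %4s", "SYNTHETIC COMPLEX", dep, id),
    "EXPDTA    X-RAY DIFFRACTION",
    sprintf("REMARK   2 RESOLUTION.    %.2f ANGSTROMS.", p$resolution),
    sprintf("REMARK   3   R VALUE            (WORKING SET) : %.3f", p$r_factor),
    sprintf("REMARK   3   FREE R VALUE                     : %.3f", p$r_free)
  )
  if (p$feature == "remark600_missing") {
    lines <- c(lines, sprintf("REMARK 600 %s MISSING ATOMS ANNOTATED IN METADATA",
                              p$family_name))
  }
  if (p$feature == "remark600_other") {
    lines <- c(lines, sprintf("REMARK 600 %s UNUSUAL COORDINATION GEOMETRY",
                              p$family_name))
  }

  res3 <- unname(.aa_three[p$aa])
  for (r in seq_len(ceiling(L / 13))) {
    idx <- ((r - 1) * 13 + 1):min(r * 13, L)
    lines <- c(lines, sprintf("SEQRES %3d %s %4d  %s", r, p$chain_id, L,
                              paste(sprintf("%-3s", res3[idx]), collapse = " ")))
  }
  if (p$step == "SEQADV") {
    ref3 <- .aa_three[[.other_aa(p$aa[p$adv_pos])]]
    lines <- c(lines, sprintf(
      "SEQADV %-4s %3s %s %4d  %-4s %-9s %3s %5d %s",
      id, res3[p$adv_pos], p$chain_id, p$adv_pos, "UNP", "P99999",
      ref3, p$adv_pos, "ENGINEERED MUTATION"))
  }

  serial <- 0L
  atom <- function(name, resid, chain, resno, x, y, z, elem, het = FALSE) {
    serial <<- serial + 1L
    .fmt_pdb_atom(serial, name, resid, chain, resno, x, y, z, elem, het)
  }
  for (i in seq_len(L)) {
    x <- 3.8 * (i - 1)
    lines <- c(lines,
      atom("N", res3[i], p$chain_id, i, x - 1.2, -0.8, 0, "N"),
      atom("CA", res3[i], p$chain_id, i, x, 0, 0, "C"),
      atom("C", res3[i], p$chain_id, i, x + 1.2, -0.8, 0, "C"),
      atom("O", res3[i], p$chain_id, i, x + 1.3, -2.0, 0, "O"))
    if (p$aa[i] != "G") {
      lines <- c(lines, atom("CB", res3[i], p$chain_id, i, x, -1.5, 0, "C"))
    }
  }

  # main ligand: one contact atom 3.0 A above each planted site CA, the rest
  # parked far from the chain
  elems <- p$fam$elements
  lig_resno <- 201L
  for (k in seq_along(elems)) {
    nm <- paste0(elems[k], k)
    if (k <= length(p$site)) {
      x <- 3.8 * (p$site[k] - 1)
      lines <- c(lines, atom(nm, p$family_name, p$chain_id, lig_resno,
                             x, 3.0, 0, elems[k], het = TRUE))
    } else {
      lines <- c(lines, atom(nm, p$family_name, p$chain_id, lig_resno,
                             5.0 * k, 30.0, 0, elems[k], het = TRUE))
    }
  }

  extra <- NULL
  if (p$feature == "covalent") {
    extra <- list(het = "LGX", elements = c("C", "C", "O"))
  } else if (p$feature == "metal") {
    extra <- list(het = "FEX", elements = c("FE"))
  } else if (p$feature == "polymer") {
    extra <- list(het = "ALA", elements = c("N", "C", "C", "O", "C"))
  }
  if (!is.null(extra)) {
    for (k in seq_along(extra$elements)) {
      lines <- c(lines, atom(paste0(extra$elements[k], k), extra$het,
                             p$chain_id, 202L, 5.0 * k, 40.0, 0,
                             extra$elements[k], het = TRUE))
    }
  }
  if (p$feature == "covalent") {
    lines <- c(lines, sprintf(
      "LINK        %-4s %3s %s%4d                %-4s %3s %s%4d",
      "C1", "LGX", p$chain_id, 202L, "CA", res3[1], p$chain_id, 1L))
  }
  if (p$feature == "water") {
    lines <- c(lines,
      atom("O", "HOH", p$chain_id, 301L, -10, 40, 0, "O", het = TRUE),
      atom("O", "HOH", p$chain_id, 302L, -15, 40, 0, "O", het = TRUE))
  }
  lines <- c(lines, "END")

  truth_ligands <- data.frame(
    structure_id = id,
    het_code = p$family_name,
    chain_id = p$chain_id,
    residue_number = lig_resno,
    heavy_atom_count = length(elems),
    molecular_weight = sum(.element_mass(elems)),
    covalent = FALSE,
    skip_reasons = if (p$feature == "remark600_missing") {
      "MISSING_ATOMS_ANNOTATED"
    } else if (p$feature == "remark600_other") {
      "METADATA_PECULIARITY"
    } else {
      ""
    },
    stringsAsFactors = FALSE
  )
  if (!is.null(extra)) {
    truth_ligands <- rbind(truth_ligands, data.frame(
      structure_id = id, het_code = extra$het, chain_id = p$chain_id,
      residue_number = 202L,
      heavy_atom_count = length(extra$elements),
      molecular_weight = sum(.element_mass(extra$elements)),
      covalent = p$feature == "covalent",
      skip_reasons = switch(p$feature,
                            covalent = "COVALENT_LINK",
                            metal = "UNSUPPORTED_ELEMENT",
                            polymer = "POLYMER_LIGAND"),
      stringsAsFactors = FALSE
    ))
  }

  list(
    pdb = lines,
    truth = list(
      structure_id = id,
      chain_seq = paste(p$aa, collapse = ""),
      site_residues = p$site,
      ligands = truth_ligands,
      resolution = p$resolution,
      dep_date = p$dep_date
    )
  )
}

#' Generate the bioactivity table of a scenario
#'
#' Emits the assay/target/molecule/value rows realizing the scenario's
#' planted targets, including dummy-target rows, SEQADV decoys, variant
#' sequences (including the unusable UNDEFINED MUTATION label), and
#' molecules at each planted match level.
#'
#' @param spec A `scenario_spec`.
#' @return List with `activities` (data frame), `het_smiles` (named SMILES
#'   vector for the HET codes used), and `truth` (per structure-ligand pair:
#'   expected candidates, winner and deciding step in both modes, expected
#'   variant origins, timeline year).
#' @export
generate_bioactivities <- function(spec) {
  plan <- .scenario_plan(spec)
  lib <- fixture_ligand_library()

  rows <- list()
  truth <- list()
  for (p in plan) {
    cand <- data.frame(
      target_accession = vapply(p$targets, `[[`, character(1), "acc"),
      cov_id = vapply(p$targets, function(t) {
        (t$identity / 100) * 1.0
      }, numeric(1)),
      molecule_level = vapply(p$targets, function(t) {
        .mol_level_expected[[t$mol]]
      }, integer(1)),
      n_site_mutations = vapply(p$targets, `[[`, integer(1), "nmut"),
      n_unique_datapoints = vapply(p$targets, `[[`, integer(1), "n_dp"),
      from_seqadv = vapply(p$targets, `[[`, logical(1), "from_seqadv"),
      quality = vapply(p$targets, function(t) {
        dq <- abs(1 - t$alen / p$L)
        dh <- abs(1 - t$alen / t$hlen)
        if (t$identity >= 95 && dq <= 0.05 && dh <= 0.05) "GOLD"
        else if (t$identity >= 95 && dq <= 0.10) "SILVER"
        else if (t$identity >= 80) "BRONZE" else "NONE"
      }, character(1)),
      stringsAsFactors = FALSE
    )
    # survivors of the SEQADV/dummy discards, ordered by the cascade keys,
    # give the expected winner without replaying the cascade logic
    surv <- cand[!cand$from_seqadv & cand$target_accession != DUMMY_TARGET, ,
                 drop = FALSE]
    pick_winner <- function(active_molecule) {
      if (nrow(surv) == 0L) return(NA_character_)
      zero <- rep(0L, nrow(surv))
      ml <- if (active_molecule) surv$molecule_level else zero
      nm <- if (active_molecule) surv$n_site_mutations else zero
      dp <- if (active_molecule) surv$n_unique_datapoints else zero
      ord <- order(-round(surv$cov_id, 6), -ml, nm, -dp,
                   as.numeric(sub("CHEMBL", "", surv$target_accession)))
      surv$target_accession[ord[1]]
    }

    variant_origin <- vapply(p$targets, function(t) {
      if (!is.na(t$variant) && toupper(t$variant) != "UNDEFINED MUTATION") {
        "VARIANT"
      } else {
        "COMPONENT"
      }
    }, character(1))

    for (ti in seq_along(p$targets)) {
      t <- p$targets[[ti]]
      smiles <- switch(t$mol,
        same = p$fam$same, enantiomer = p$fam$enantiomer,
        tautomer = p$fam$tautomer, protomer = p$fam$protomer,
        unrelated = p$fam$unrelated)
      if (is.null(smiles)) {
        stop("family ", p$family_name, " has no '", t$mol, "' molecule")
      }
      for (k in seq_len(t$n_dp)) {
        rows[[length(rows) + 1L]] <- data.frame(
          assay_id = sprintf("A%03d_%s_%d", p$index, t$acc, k),
          target_accession = t$acc,
          target_type = t$type,
          component_sequence = t$component,
          variant_sequence = t$variant,
          canonical_smiles = smiles,
          standard_type = "IC50",
          standard_value = 10 * k,
          standard_units = "nM",
          pchembl_value = round(8 - log10(10 * k / 1e9) - 9, 2),
          doc_date = as.character(p$doc_date),
          data_validity_comment = "",
          stringsAsFactors = FALSE
        )
      }
    }

    truth[[p$structure_id]] <- list(
      structure_id = p$structure_id,
      het_code = p$family_name,
      chain_id = p$chain_id,
      step = p$step,
      candidates = cand,
      winner_binding = pick_winner(active_molecule = TRUE),
      decided_binding = .expected_decision(p$step, "binding"),
      winner_target = pick_winner(active_molecule = FALSE),
      decided_target = .expected_decision(p$step, "target"),
      variant_origin = stats::setNames(variant_origin,
                                       vapply(p$targets, `[[`, character(1), "acc")),
      year = max(as.integer(format(p$dep_date, "%Y")),
                 as.integer(format(p$doc_date, "%Y")))
    )
  }

  het_used <- unique(vapply(plan, `[[`, character(1), "family_name"))
  het_smiles <- vapply(lib[het_used], `[[`, character(1), "smiles")
  names(het_smiles) <- het_used

  list(
    activities = do.call(rbind, c(rows, list(make.row.names = FALSE))),
    het_smiles = het_smiles,
    truth = truth
  )
}

#' Generate a complete scenario
#'
#' Bundles [generate_structure()] for all structures with
#' [generate_bioactivities()]; optionally writes the files (PDB per
#' structure, activity TSV, SMILES dictionary, truth JSON) to a directory.
#'
#' @param spec A `scenario_spec`.
#' @param dir Optional output directory.
#' @return List with `structures` (parsed-ready PDB line vectors),
#'   `activities`, `het_smiles`, `truth` (structure- and pair-level).
#' @export
generate_scenario <- function(spec, dir = NULL) {
  n <- spec$n_structures
  str_out <- lapply(seq_len(n), function(i) generate_structure(spec, i))
  act <- generate_bioactivities(spec)
  out <- list(
    structures = lapply(str_out, `[[`, "pdb"),
    structure_truth = lapply(str_out, `[[`, "truth"),
    activities = act$activities,
    het_smiles = act$het_smiles,
    pair_truth = act$truth
  )
  names(out$structures) <- vapply(out$structure_truth, `[[`, character(1),
                                  "structure_id")
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (sid in names(out$structures)) {
      writeLines(out$structures[[sid]], file.path(dir, paste0(sid, ".pdb")))
    }
    utils::write.table(out$activities, file.path(dir, "activities.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(paste(out$het_smiles, names(out$het_smiles)),
               file.path(dir, "het_smiles.smi"))
    jsonlite::write_json(
      list(structures = out$structure_truth, pairs = out$pair_truth),
      file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA,
      force = TRUE)
  }
  out
}
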