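# Independent oracles and fixture builders shared across the suite.

# ---- brute-force winner oracle: lexicographic sort over the cascade keys ----

oracle_type_rank <- function(type) {
  r <- match(toupper(type),
             c("SINGLE PROTEIN", "PROTEIN COMPLEX", "PROTEIN FAMILY"))
  r[is.na(r)] <- 4L
  r
}

oracle_cascade_winner <- function(cand, mode) {
  surv <- cand[!cand$from_seqadv & cand$target_accession != "CHEMBL612545", ,
               drop = FALSE]
  if (nrow(surv) == 0L) return(NA_character_)
  n <- nrow(surv)
  binding <- mode == "binding"
  ml <- if (binding) ifelse(is.na(surv$molecule_level), -1, surv$molecule_level) else rep(0, n)
  nm <- if (binding) ifelse(is.na(surv$n_site_mutations), Inf, surv$n_site_mutations) else rep(0, n)
  dp <- if (binding) ifelse(is.na(surv$n_unique_datapoints), -1, surv$n_unique_datapoints) else rep(0, n)
  num <- as.numeric(sub("^CHEMBL", "", surv$target_accession))
  ord <- order(-round(surv$cov_id, 6), -ml, nm,
               oracle_type_rank(surv$target_type), -dp, num)
  surv$target_accession[ord[1]]
}

random_candidate_set <- function(max_n = 8L) {
  n <- sample.int(max_n, 1)
  accs <- c(sample(setdiff(1:500, 612545), n - 1),
            if (runif(1) < 0.25) 612545 else sample(setdiff(501:999, 612545), 1))
  accs <- sample(accs, n)
  target_candidates(
    target_accession = sprintf("CHEMBL%d", accs),
    target_type = sample(c("SINGLE PROTEIN", "PROTEIN COMPLEX",
                           "PROTEIN FAMILY", "ORGANISM", "CELL-LINE"),
                         n, replace = TRUE),
    cov_id = sample(c(0.6, 0.8, 0.9, 0.95, 1.0), n, replace = TRUE),
    molecule_level = sample(0:5, n, replace = TRUE),
    n_site_mutations = sample(0:3, n, replace = TRUE),
    n_unique_datapoints = sample(1:5, n, replace = TRUE),
    from_seqadv = runif(n) < 0.15
  )
}

# ---- random alignment statistics for the equation suite ----

random_alignment_stats <- function() {
  qlen <- sample(50:600, 1)
  hlen <- sample(50:900, 1)
  alen <- sample(20:min(qlen, hlen), 1)
  alignment_record(
    query_id = "q", hit_id = "h",
    identity = round(runif(1, 40, 100), 2),
    alignment_length = alen, query_length = qlen, hit_length = hlen,
    coverage_query = round(runif(1, 10, 100), 2)
  )
}

# ---- random linear hetero-alkanes: always valid, reversible token order ----

random_chain_tokens <- function(len = NULL) {
  if (is.null(len)) len <- sample(4:12, 1)
  tokens <- character(len)
  prev_hetero <- TRUE  # force a carbon start
  for (i in seq_len(len)) {
    tok <- if (prev_hetero) "C" else sample(c("C", "C", "C", "N", "O"), 1)
    prev_hetero <- tok %in% c("N", "O")
    tokens[i] <- tok
  }
  if (tokens[len] %in% c("N", "O") && len > 1 && tokens[len - 1] != "C") {
    tokens[len] <- "C"
  }
  tokens
}

# ---- RDKit as an independent canonicalization oracle ----

rdkit_match_levels <- function(pairs) {
  # pairs: data.frame(smiles_a, smiles_b); returns integer levels computed
  # with an entirely separate toolkit and an independent layer-truncation
  script <- '
import sys, json
from rdkit import Chem
from rdkit.Chem.inchi import MolToInchi, MolToInchiKey

def trunc(inchi, keep):
    toks = inchi.split("/")
    out = toks[:2]
    for t in toks[2:]:
        if t[:1] in keep:
            out.append(t)
        else:
            break
    return "/".join(out)

def forms(smi):
    m = Chem.MolFromSmiles(smi)
    frags = Chem.GetMolFrags(m, asMols=True)
    m = max(frags, key=lambda f: f.GetNumHeavyAtoms())
    inchi = MolToInchi(m)
    return {
        "key": MolToInchiKey(m),
        "chiral": Chem.MolToSmiles(m, isomericSmiles=True),
        "achiral": Chem.MolToSmiles(m, isomericSmiles=False),
        "th": trunc(inchi, ("c", "h")),
        "tc": trunc(inchi, ("c",)),
    }

def level(a, b):
    if a["key"] == b["key"]: return 5
    if a["chiral"] == b["chiral"]: return 4
    if a["achiral"] == b["achiral"]: return 3
    if a["th"] == b["th"]: return 2
    if a["tc"] == b["tc"]: return 1
    return 0

pairs = json.load(sys.stdin)
print(json.dumps([level(forms(a), forms(b)) for a, b in pairs]))
'
  sf <- tempfile(fileext = ".py")
  writeLines(script, sf)
  on.exit(unlink(sf))
  input <- jsonlite::toJSON(unname(Map(c, pairs$smiles_a, pairs$smiles_b)))
  out <- suppressWarnings(
    system2("python", sf, input = as.character(input), stdout = TRUE,
            stderr = FALSE)
  )
  as.integer(jsonlite::fromJSON(out[length(out)]))
}

python_rdkit_available <- function() {
  nzchar(Sys.which("python")) &&
    suppressWarnings(system2("python", c("-c", shQuote("import rdkit")),
                             stdout = FALSE, stderr = FALSE)) == 0
}

# ---- scenario recovery check used by the end-to-end tests ----

check_scenario <- function(seed, tol = 1e-9) {
  failures <- character()
  note <- function(...) failures <<- c(failures, paste0(...))

  spec <- scenario_spec(seed)
  sc <- generate_scenario(spec)
  structures <- lapply(sc$structures, parse_structure)
  pl <- run_pipeline(structures, sc$activities, sc$het_smiles)

  # ligand inventories incl. skip reasons and descriptors
  truth_lig <- do.call(rbind, lapply(sc$structure_truth, `[[`, "ligands"))
  got_lig <- pl$binding$ligand_rows
  ord_t <- order(truth_lig$structure_id, truth_lig$het_code)
  ord_g <- order(got_lig$structure_id, got_lig$het_code)
  tl <- truth_lig[ord_t, ]; gl <- got_lig[ord_g, ]
  if (!identical(nrow(tl), nrow(gl))) {
    note("seed ", seed, ": ligand row count ", nrow(gl), " != ", nrow(tl))
  } else {
    for (cl in c("het_code", "chain_id", "residue_number",
                 "heavy_atom_count", "covalent", "skip_reasons")) {
      if (!identical(unname(as.vector(tl[[cl]])), unname(as.vector(gl[[cl]])))) {
        note("seed ", seed, ": ligand column ", cl, " mismatch")
      }
    }
    if (max(abs(tl$molecular_weight - gl$molecular_weight)) > 1e-6) {
      note("seed ", seed, ": molecular weight mismatch")
    }
  }

  for (sid in names(sc$pair_truth)) {
    tr <- sc$pair_truth[[sid]]
    stru <- sc$structure_truth[[which(vapply(sc$structure_truth, `[[`,
                                             character(1), "structure_id") == sid)]]
    # binding site recovery
    site <- pl$binding$sites[[paste(sid, tr$het_code, tr$chain_id, sep = ":")]]
    if (!identical(sort(site$residues$residue_number),
                   as.integer(sort(stru$site_residues)))) {
      note("seed ", seed, " ", sid, ": site residues mismatch")
    }
    # winners + deciding steps, both modes
    w <- pl$binding$winners
    row <- w[w$structure_id == sid & !is.na(w$het_code) &
               w$het_code == tr$het_code, ]
    if (!identical(row$winner, tr$winner_binding) ||
        !identical(row$decided_at, tr$decided_binding)) {
      note("seed ", seed, " ", sid, ": binding winner/step mismatch (",
           row$winner, "/", row$decided_at, " vs ",
           tr$winner_binding, "/", tr$decided_binding, ")")
    }
    wt <- pl$target$winners
    rowt <- wt[wt$structure_id == sid, ]
    if (!identical(rowt$winner, tr$winner_target) ||
        !identical(rowt$decided_at, tr$decided_target)) {
      note("seed ", seed, " ", sid, ": target winner/step mismatch")
    }
    # candidate attributes: cov_id, molecule level, mutations, data points,
    # SEQADV flags, quality of the best alignment
    idx <- which(vapply(seq_len(nrow(w)), function(k) {
      w$structure_id[k] == sid && !is.na(w$het_code[k]) &&
        w$het_code[k] == tr$het_code
    }, logical(1)))
    cand <- pl$binding$candidates[[idx]]
    tc <- tr$candidates
    cand <- cand[order(cand$target_accession), ]
    tc <- tc[order(tc$target_accession), ]
    if (!identical(cand$target_accession, tc$target_accession)) {
      note("seed ", seed, " ", sid, ": candidate set mismatch")
    } else {
      if (max(abs(cand$cov_id - tc$cov_id)) > tol) {
        note("seed ", seed, " ", sid, ": cov_id mismatch")
      }
      if (!identical(cand$molecule_level, tc$molecule_level)) {
        note("seed ", seed, " ", sid, ": molecule level mismatch")
      }
      if (!identical(cand$n_site_mutations, tc$n_site_mutations)) {
        note("seed ", seed, " ", sid, ": site mutation count mismatch")
      }
      if (!identical(cand$n_unique_datapoints, tc$n_unique_datapoints)) {
        note("seed ", seed, " ", sid, ": data point count mismatch")
      }
      if (!identical(cand$from_seqadv, tc$from_seqadv)) {
        note("seed ", seed, " ", sid, ": seqadv flag mismatch")
      }
    }
    # quality tier and variant handling, from the activity rows
    act <- pl$binding$activity_rows
    act <- act[act$structure_id == sid & !is.na(act$het_code) &
                 act$het_code == tr$het_code, ]
    for (acc in tc$target_accession) {
      arow <- act[act$target_accession == acc, ][1, ]
      if (!identical(arow$quality, tc$quality[tc$target_accession == acc])) {
        note("seed ", seed, " ", sid, " ", acc, ": quality mismatch")
      }
      if (!identical(arow$variant_origin, unname(tr$variant_origin[acc]))) {
        note("seed ", seed, " ", sid, " ", acc, ": variant origin mismatch")
      }
    }
  }

  # growth timeline: per-structure later-date years
  tl_expect <- table(vapply(sc$pair_truth, `[[`, numeric(1), "year"))
  tl_got <- growth_timeline(pl$tables$FULL)
  if (!identical(as.integer(names(tl_expect)), tl_got$year) ||
      !identical(as.integer(tl_expect), tl_got$new_complexes)) {
    note("seed ", seed, ": growth timeline mismatch")
  }
  failures
}
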