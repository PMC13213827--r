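---
title: "Linking protein-ligand structures to bioactivity records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking protein-ligand structures to bioactivity records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

Structure-based modelling needs training data that pairs a modelled
protein-ligand complex with a measured affinity for the *same* protein and
the *same* molecule. Neither side of that pairing is trivial: a structure
file records a construct that may be truncated, tagged, or mutated relative
to the assayed protein, and the registered molecule may be a salt, a
different protonation state, or a different stereoisomer of the modelled
ligand. bioactlink automates the pairing with explicit, auditable quality
descriptors at every step, so that downstream users can subset by evidence
strength rather than trust a single opaque join.

```{r setup}
library(bioactlink)
```

## Ligand discovery and consistency flags

`parse_structure()` reads PDB text (coordinates and SEQRES through bio3d;
HEADER, EXPDTA, REMARK 2/3, SEQADV, LINK and REMARK 600 records from the
raw lines). `extract_ligands()` then produces one row per non-water
hetero-group. Problems never drop a ligand; they are annotated as *skip
reasons* (`skip_reason_catalog()`): metadata peculiarities such as
annotated missing atoms, covalent linkage to the polymer via LINK records,
elements outside the supported organic set (H, C, N, O, P, S, F, Cl, Br,
I, B, Se - metals deliberately excluded), disagreement with a reference
formula, and standard residues appearing as hetero-groups. Molecular
weight and the heavy-atom count are computed from the atoms actually
present in the file, not from an idealized formula, so incomplete groups
report what was modelled.

`find_binding_site()` returns every polymer residue with at least one atom
within a cutoff of any ligand heavy atom. The default cutoff is 3.25
angstroms - the literal radius of a 6.5-angstrom-*diameter* sphere. Site
definitions in the field often quote 6.5 angstroms as a radius instead, so
the cutoff is an explicit parameter rather than a constant; every
downstream count (site residues, site mutations) inherits it.

## Molecule correspondence: five levels

`mol_forms()` canonicalizes molecules through OpenBabel (the `obabel`
executable) into six representations: standard InChI, InChIKey, canonical
SMILES with and without stereochemistry, and the InChI truncated after the
hydrogen and after the atom-connection layer. `match_level()` grades a
pair as the *highest* level whose equality criterion holds:

| level | criterion |
|------:|-----------|
| 5 | identical InChIKey |
| 4 | identical canonical SMILES with stereochemistry |
| 3 | identical canonical SMILES without stereochemistry |
| 2 | identical InChI truncated after the hydrogen layer |
| 1 | identical InChI truncated after the atom-connection layer |
| 0 | none of the above |

Levels 5 and 4 both mean "the same molecule" (they can disagree only in
canonicalization corner cases, and reporting the highest satisfied level
makes such pairs score 5). Level 3 captures stereochemically distinct
molecules such as enantiomer pairs; levels 2 and 1 capture *potentially*
identical molecules - protonation variants share everything through the
hydrogen layer, tautomers share the connectivity but differ in hydrogen
placement. Two conventions worth stating because descriptions of the
layer assignment vary: here level 2 means cut after the *hydrogen* layer
and level 1 cut after the *atom-connection* layer; and registered salts
are reduced to their largest covalently connected component before
canonicalization, while charges are otherwise preserved (no protonation
normalization beyond what standard InChI itself performs).

```{r}
forms <- mol_forms(c("C[C@@H](N)C(=O)O", "C[C@H](N)C(=O)O"),
                   id = c("L-ala", "D-ala"))
match_level(forms[1, ], forms[2, ])   # enantiomers: level 3
```

## Sequence matching and the CovId score

`align_sequences()` computes a Smith-Waterman local alignment with affine
gaps (BLOSUM62, gap open 11, extend 1 - the defaults of the standard
protein search tool). Identity is the fraction of identical aligned
columns over the alignment length; query coverage is the fraction of
query residues that appear in the alignment (gap-free count). Matches
below 80 percent identity are flagged sub-threshold and never become
candidate links. Precomputed alignments in the standard 12-column tabular
hit format are accepted through `read_alignment_hits()` as an alternative
to the internal aligner.

Identity alone favors short, trivially perfect local matches, so
`score_match()` combines it with coverage:

$$\mathrm{CovId} = \frac{\mathrm{Identity}}{100} \times
  \left|\frac{\mathrm{Cov}_{\mathrm{match+query}}}{100}\right|$$

and two relative length discrepancies,

$$D_{\mathrm{match+query}} = \left|1 -
  \frac{\mathrm{length(alignment)}}{\mathrm{length(query)}}\right|,\qquad
  D_{\mathrm{match+hit}} = \left|1 -
  \frac{\mathrm{length(alignment)}}{\mathrm{length(hit)}}\right|$$

which feed three quality tiers with inclusive bounds: **Gold** (identity
>= 95, both discrepancies <= 0.05: the assayed construct and the modelled
chain are essentially the same protein at the same length), **Silver**
(identity >= 95, query discrepancy <= 0.10: the modelled chain is covered
but the registry sequence may be much longer, e.g. a polyprotein), and
**Bronze** (identity >= 80). Tier classification compares values rounded
to nine decimals so that exact threshold cases, which are common with
round sequence lengths, are not pushed over an inclusive bound by binary
floating-point representation; the stored scores themselves are never
rounded.

One numerical guard deserves explanation: the internal aligner returns
the single best local alignment for *every* sequence pair, including
unrelated ones, and a chance four-residue exact match is "100 percent
identity". A database search tool would never report such a hit
(significance filtering); `link_bioactivities()` therefore applies a raw
alignment-score floor (`min_score`, default 70) before a match can become
a candidate link. With BLOSUM62 this corresponds to roughly a dozen
aligned residues of genuine similarity; genuinely related chains of
typical domain length score in the hundreds.

## Variants, SEQADV, and mutation counting

Assays may record a *variant sequence* - the actual mutated construct
measured. `resolve_assay_sequence()` uses it in place of the target's
component sequence whenever it exists, with one exception: the literal
annotation `UNDEFINED MUTATION` carries no usable sequence, so such
assays fall back to the component. A consequence of matching against the
variant is that a structure mutation consistent with the assay variant is
*not* a mutation: `count_site_mutations()` sees agreeing residues.

Mutations are counted as alignment columns whose query position lies in
the binding site and whose residues differ; site positions aligned to a
gap count as differences, while site positions outside the local
alignment span are not counted (the alignment makes no claim about them).

SEQADV records document where the modelled sequence deviates from its
database reference. `seqadv_adjusted_sequence()` reconstructs the
reference-like sequence, and matches built from it are computed and
flagged `from_seqadv` - useful for diagnosis, but by definition they
describe residues *absent from the model*, so the selection cascade
discards them before anything else.

## The selection cascade

Several targets can match one structure. `run_cascade()` reduces the
candidates for a structure-ligand pair (binding mode) or a structure
(target mode) to one winner, in a fixed order: discard SEQADV-built
matches; discard the dummy target `CHEMBL612545` (a container of
heterogeneous unchecked data); keep the highest CovId; keep the best
molecule match level; keep the fewest binding-site mutations; prefer
target types SINGLE PROTEIN > PROTEIN COMPLEX > PROTEIN FAMILY; keep the
most unique activity data points; finally keep the lowest accession
number. The three ligand-dependent steps are skipped in target mode.

Three interpretation choices were genuinely open and are resolved as
follows. The type step is skipped only when *no* candidate bears one of
the three preferred labels; when some do, candidates with the best-ranked
present label are kept (the alternative reading - skip unless all labels
are identical - would make the step a near-no-op). CovId values are
compared after rounding to six decimals, so platform-dependent last-bit
differences cannot decide a winner. "Unique activity data points" is
made precise as distinct (assay, activity type, value, units) tuples.

Every removal is attributed to its step in a `CascadeAudit`; `decided_at`
is the last step that strictly shrank the candidate set (`SINGLE` for
singleton inputs that win). When the SEQADV discard itself is that last
step the audit reports `SEQADV` - the published step vocabulary has no
separate label for this case, and folding it into the dummy step would
misattribute the removal.

## Assembling the linked tables

`merge_outputs()` performs a full outer join of the ligand inventory
(keyed by structure, HET code, chain), the structure-quality rows (keyed
by structure), and the activity links, with two merge indicators:
`merge_ligand_structure` (`both` / `ligand_only` / `structure_only`, plus
`neither` for activity rows whose binding chain has no ligand/structure
row - the published indicator vocabulary has no value for this real case)
and `merge_activity` (`present` / `absent`). `build_variant()` derives
the four table variants: all candidates per pair (`FULL`), all candidates
per structure (`TARGET`), and the cascade-winner-only subsets
(`FILTERED`, `TARGET_FILTERED`), where a pair that loses all its activity
rows keeps a single representative with a blank activity block.

The optional density-support score is a pass-through numeric column
(convention: -1 encodes "not computable"); no density computation is
performed. `growth_timeline()` dates each linked complex by the later of
structure deposition and bioactivity document date and reports yearly and
cumulative counts. `apply_quality_filters()` implements conjunctive
subsetting (skip-reason whitelist, density range, resolution bound,
duplicate collapse, validity-comment removal, molecule-level floor,
identity floor, site-mutation cap, quality-tier floor); a row lacking a
field an active criterion needs is removed by that criterion, which is
how non-crystallographic structures drop out of density-filtered subsets.

## The synthetic-scenario generator

`generate_scenario()` plants structures, molecules and bioactivity tables
whose correct pipeline outputs are known in closed form:

* Chains are extended (3.8-angstrom CA spacing along one axis, CB stubs);
  binding-site contact atoms sit 3.0 angstroms above the CA of each
  planted site residue, everything else is parked far away. At the
  default cutoff the recovered site is exactly the planted set.
* Hit sequences derive from the chain by controlled edits - interior
  substitutions (placed at least two residues from either end, so the
  optimal local alignment provably stays full-length and identity equals
  the edit count) and terminal extensions (which change only the hit
  length). This is what makes expected CovId, D metrics and tiers exact
  closed forms rather than re-runs of the aligner.
* The molecule library (`fixture_ligand_library()`) carries five families
  with atom-order permuted copies, enantiomers, a keto/enol tautomer
  pair, a protonation variant, and unrelated partners - one planted pair
  per match level.
* Each structure realizes one cascade blueprint (single candidate,
  sequence-decided, molecule-decided, mutation-decided, type-decided,
  data-point-decided, tiebreak, dummy-target cases, a SEQADV decoy, and
  the two variant-sequence cases), with the expected winner derived from
  a sort-based oracle independent of `run_cascade()`.

Default scenario size is 3 structures with 30-50 residue chains and 3
site residues; the end-to-end suite replays 50 seeded scenarios, and the
cascade is additionally checked against the brute-force oracle on 1000
random candidate sets per mode. These sizes give full blueprint coverage
(the twelve blueprints rotate with the seed) while keeping a complete run
in the order of a minute.

What passing these tests shows - and what it does not: the scenarios
exercise the full record flow (parsing, flags, geometry, alignment
statistics, canonicalization, cascade, assembly) with exact expected
values, but their geometry is idealized, their sequences are random
rather than homologous families, and their alignments are designed to be
unambiguous. Real data adds conformational complexity, genuinely
ambiguous alignments, malformed records, and chemistry at the edges of
the canonicalization model; results on real archives should be inspected
through the audit tables and quality tiers, which exist for exactly that
purpose.

## Known limitations

* Effective assay sequences are pooled per target before alignment; in a
  target whose assays mix variant and non-variant annotations, the
  candidate's best match may come from either sequence. The planted
  scenarios keep variant annotations uniform per target; per-assay match
  granularity is a natural extension.
* mmCIF input, multi-model (NMR/cryo-EM) handling beyond the first model,
  enhanced stereochemistry, metal-organic bond models and tautomer
  enumeration are out of scope.
* Bond perception from coordinates is delegated to the chemistry backend;
  for structure-side molecules the supported route is a HET-code-to-SMILES
  dictionary, as in `run_pipeline(..., het_smiles = ...)`.
* The covalent-ligand flag is reported, but covalent complexes are linked
  like any others; no covalent-specific chemistry is attempted.
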