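# Outer-join assembly, variants, timeline, and quality-filter queries.

lig_rows <- function() {
  data.frame(
    structure_id = c("S001", "S001", "S002"),
    het_code = c("LG1", "LG2", "LG1"),
    chain_id = "A",
    residue_number = 201L,
    heavy_atom_count = c(6L, 4L, 6L),
    molecular_weight = 80,
    covalent = FALSE,
    skip_reasons = c("", "COVALENT_LINK", ""),
    stringsAsFactors = FALSE
  )
}

str_rows <- function() {
  data.frame(
    structure_id = c("S001", "S003"),
    resolution = c(2.0, 2.9),
    r_factor = 0.2, r_free = 0.25,
    experimental_method = "X-RAY DIFFRACTION",
    deposition_date = as.Date(c("2004-05-01", "2010-01-01")),
    density_score = c(0.9, -1),
    stringsAsFactors = FALSE
  )
}

act_rows <- function() {
  data.frame(
    structure_id = "S001", het_code = "LG1", chain_id = "A",
    assay_id = c("A1", "A1", "A2"),
    target_accession = c("CHEMBL10", "CHEMBL20", "CHEMBL10"),
    target_type = "SINGLE PROTEIN",
    canonical_smiles = "CCO",
    standard_type = "IC50", standard_value = c(10, 10, 20),
    standard_units = "nM", pchembl_value = 8,
    doc_date = "2006-07-01", data_validity_comment = "",
    variant_origin = "COMPONENT",
    identity = c(100, 90, 100), coverage = 100,
    cov_id = c(1, 0.9, 1), d_query = 0, d_hit = 0,
    quality = c("GOLD", "BRONZE", "GOLD"),
    molecule_level = 5L, n_site_mutations = 0L,
    from_seqadv = FALSE, match_chain = "A",
    stringsAsFactors = FALSE
  )
}

test_that("the merge is a full outer join with correct indicators", {
  m <- merge_outputs(lig_rows(), str_rows(), act_rows())
  # S001/LG1 has 3 activity rows, S001/LG2 none, S002 no structure row,
  # S003 no ligand rows
  expect_equal(nrow(m), 3 + 1 + 1 + 1)
  lg2 <- m[m$structure_id == "S001" & m$het_code == "LG2", ]
  expect_equal(lg2$merge_ligand_structure, "both")
  expect_equal(lg2$merge_activity, "absent")
  s2 <- m[m$structure_id == "S002", ]
  expect_equal(s2$merge_ligand_structure, "ligand_only")
  s3 <- m[m$structure_id == "S003", ]
  expect_equal(s3$merge_ligand_structure, "structure_only")
  expect_true(all(m$merge_activity[m$structure_id == "S001" &
                                     m$het_code == "LG1"] == "present"))
  # no input information dropped
  expect_true(all(lig_rows()$het_code %in% m$het_code))
  expect_true(all(str_rows()$structure_id %in% m$structure_id))
})

test_that("disjoint keys simply concatenate and conflicts error", {
  lig <- lig_rows()[1, ]
  str2 <- str_rows()[2, , drop = FALSE]
  m <- merge_outputs(lig, str2, NULL)
  expect_equal(nrow(m), 2L)

  dup <- rbind(lig_rows(), transform(lig_rows()[1, ], molecular_weight = 99))
  expect_error(merge_outputs(dup, str_rows(), NULL), "duplicate conflicting")
})

test_that("filtered variants keep only cascade winners per pair", {
  m <- merge_outputs(lig_rows(), str_rows(), act_rows())
  winners <- data.frame(structure_id = "S001", het_code = "LG1",
                        chain_id = "A", winner = "CHEMBL10",
                        stringsAsFactors = FALSE)
  attr(winners, "mode") <- "binding"
  f <- build_variant(m, "FILTERED", winners)
  act <- f[f$merge_activity == "present", ]
  expect_true(all(act$target_accession == "CHEMBL10"))
  expect_equal(nrow(act), 2L)   # CHEMBL20's row removed
  # idempotent and a subset of FULL
  expect_equal(nrow(build_variant(f, "FILTERED", winners)), nrow(f))
  expect_true(nrow(f) <= nrow(m))
  expect_identical(build_variant(m, "FULL"), m)
})

test_that("a pair whose only match loses keeps a blank activity block", {
  m <- merge_outputs(lig_rows(), str_rows(), act_rows())
  winners <- data.frame(structure_id = "S001", het_code = "LG1",
                        chain_id = "A", winner = NA_character_,
                        stringsAsFactors = FALSE)
  attr(winners, "mode") <- "binding"
  f <- build_variant(m, "FILTERED", winners)
  pair <- f[f$structure_id == "S001" & !is.na(f$het_code) &
              f$het_code == "LG1", ]
  expect_equal(nrow(pair), 1L)
  expect_equal(pair$merge_activity, "absent")
  expect_true(is.na(pair$target_accession))
  expect_equal(pair$merge_ligand_structure, "both")
})

test_that("variant/mode mismatches are configuration errors", {
  m <- merge_outputs(lig_rows(), str_rows(), act_rows())
  winners <- data.frame(structure_id = "S001", winner = "CHEMBL10",
                        stringsAsFactors = FALSE)
  attr(winners, "mode") <- "target"
  expect_error(build_variant(m, "FILTERED", winners), "mode")
  expect_error(build_variant(m, "FILTERED"), "required")
  t <- build_variant(m, "TARGET")
  expect_false("molecule_level" %in% names(t))
  expect_false("n_site_mutations" %in% names(t))
})

test_that("the growth timeline dates complexes by the later date", {
  rows <- data.frame(
    structure_id = c("S1", "S2", "S3", "S3"),
    het_code = "LG1",
    merge_activity = "present",
    deposition_date = as.Date(c("2005-01-01", "2006-03-01", "2004-01-01",
                                "2004-01-01")),
    doc_date = as.Date(c("2004-06-01", "2006-01-01", "2008-02-01",
                         "2008-02-01")),
    stringsAsFactors = FALSE
  )
  tl <- growth_timeline(rows)
  expect_equal(tl$year, c(2005L, 2006L, 2008L))
  expect_equal(tl$new_complexes, c(1L, 1L, 1L))
  expect_equal(tl$cumulative, c(1L, 2L, 3L))
  expect_equal(nrow(growth_timeline(rows[0, ])), 0L)

  rows$deposition_date[1] <- NA
  rows$doc_date[1] <- NA
  expect_warning(tl2 <- growth_timeline(rows), "excluded")
  expect_equal(sum(tl2$new_complexes), 2L)
})

test_that("quality filters are conjunctive, monotone, and validated", {
  m <- merge_outputs(lig_rows(), str_rows(), act_rows())
  expect_identical(apply_quality_filters(m, list()), m)

  res <- apply_quality_filters(m, list(resolution_max = 2.5))
  expect_true(all(res$resolution <= 2.5, na.rm = TRUE))
  expect_true(all(!is.na(res$resolution)))

  # conjunction: a row passing one criterion but failing another is removed
  both <- apply_quality_filters(m, list(identity_min = 95,
                                        site_mutation_max = 0))
  expect_true(all(both$identity >= 95))
  one <- m[1, ]; one$identity <- 99; one$n_site_mutations <- 1L
  expect_equal(nrow(apply_quality_filters(one, list(identity_min = 95,
                                                    site_mutation_max = 0))),
               0L)

  # a density criterion removes rows without a usable density score
  dens <- apply_quality_filters(m, list(density_min = 0, density_max = 1.2))
  expect_true(all(dens$density_score >= 0))

  sk <- apply_quality_filters(m, list(skip_reasons_allowed = character()))
  expect_true(all(sk$skip_reasons == ""))

  q <- apply_quality_filters(m, list(quality_min = "SILVER"))
  expect_true(all(q$quality == "GOLD"))

  expect_error(apply_quality_filters(m, list(nonsense = 1)), "unknown")

  # adding criteria never increases the row count; order never matters
  c1 <- list(resolution_max = 2.5)
  c2 <- list(resolution_max = 2.5, quality_min = "BRONZE")
  expect_lte(nrow(apply_quality_filters(m, c2)),
             nrow(apply_quality_filters(m, c1)))
  expect_equal(apply_quality_filters(m, c2),
               apply_quality_filters(m, rev(c2)))
})

test_that("duplicate activity tuples collapse when requested", {
  m <- merge_outputs(lig_rows(), str_rows(), act_rows())
  # A1/CHEMBL10/10nM and A2/CHEMBL10/20nM differ; add a true duplicate
  extra <- m[m$merge_activity == "present", ][1, ]
  m2 <- rbind(m, extra)
  dedup <- apply_quality_filters(m2, list(remove_duplicates = TRUE))
  expect_equal(nrow(dedup), nrow(m))
})
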