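# Alignment statistics, CovId / length-discrepancy scoring, quality tiers,
# variant resolution, and binding-site mutation counting.

rand_seq <- function(n) paste(sample(c("A", "C", "D", "E", "F", "G", "H",
                                       "I", "K", "L", "M", "N", "P", "Q",
                                       "R", "S", "T", "V", "W", "Y"),
                                     n, replace = TRUE), collapse = "")

test_that("self- and substring alignments give the expected statistics", {
  set.seed(1)
  q <- rand_seq(50)
  a <- align_sequences(q, q)
  expect_equal(a$identity, 100)
  expect_equal(a$coverage_query, 100)
  expect_equal(a$alignment_length, 50L)
  s <- score_match(a)
  expect_equal(s$cov_id, 1)
  expect_equal(s$d_query, 0)
  expect_equal(s$d_hit, 0)
  expect_equal(s$quality, "GOLD")

  hit <- paste0(rand_seq(180), q, rand_seq(170))
  q40 <- substr(q, 1, 40)
  a2 <- align_sequences(q40, hit)
  expect_equal(a2$identity, 100)
  expect_equal(a2$coverage_query, 100)
  expect_equal(a2$hit_length, 400L)
})

test_that("one interior mismatch in 100 residues gives identity 99", {
  set.seed(2)
  q <- rand_seq(100)
  hit <- q
  substr(hit, 50, 50) <- if (substr(q, 50, 50) == "A") "G" else "A"
  a <- align_sequences(q, hit)
  expect_equal(a$identity, 99)
  expect_equal(a$alignment_length, 100L)
  expect_equal(nrow(a$substitutions), 1L)
  expect_equal(a$substitutions$query_pos, 50L)
})

test_that("score_match reproduces the defining arithmetic", {
  a <- alignment_record("q", "h", identity = 95, alignment_length = 90,
                        query_length = 100, hit_length = 500,
                        coverage_query = 50)
  s <- score_match(a)
  expect_equal(s$cov_id, 0.475)
  expect_equal(s$d_query, 0.10)
  expect_equal(s$d_hit, 0.82)
})

test_that("quality tiers respect the inclusive thresholds", {
  mk <- function(identity, alen, qlen, hlen) {
    score_match(alignment_record("q", "h", identity, alen, qlen, hlen,
                                 coverage_query = 100))$quality
  }
  expect_equal(mk(96, 100, 100, 104), "GOLD")
  expect_equal(mk(96, 92, 100, 500), "SILVER")   # d_query 0.08, d_hit fails
  expect_equal(mk(85, 100, 100, 100), "BRONZE")
  expect_equal(mk(79, 100, 100, 100), "NONE")
  # boundary cases sit inside their tier
  expect_equal(mk(95, 95, 100, 100), "GOLD")     # identity 95, d exactly 0.05
  expect_equal(mk(95, 90, 100, 500), "SILVER")   # d_query exactly 0.10
  expect_equal(mk(80, 60, 100, 100), "BRONZE")   # identity exactly 80
  expect_equal(mk(94.999, 95, 100, 100), "BRONZE")
})

test_that("cov_id is monotone in identity and coverage", {
  base <- alignment_record("q", "h", 90, 80, 100, 100, coverage_query = 80)
  for (k in 1:20) {
    up_id <- base; up_id$identity <- base$identity + k / 4
    up_cov <- base; up_cov$coverage_query <- base$coverage_query + k / 2
    expect_gte(score_match(up_id)$cov_id, score_match(base)$cov_id)
    expect_gte(score_match(up_cov)$cov_id, score_match(base)$cov_id)
  }
})

test_that("variant sequences override components except UNDEFINED MUTATION", {
  comp <- "MKTAYIAKQR"
  expect_equal(resolve_assay_sequence("MKTAYIAKQV", comp)$origin, "VARIANT")
  expect_equal(resolve_assay_sequence("UNDEFINED MUTATION", comp)$origin,
               "COMPONENT")
  expect_equal(resolve_assay_sequence(NA, comp)$origin, "COMPONENT")
  expect_equal(resolve_assay_sequence(NA, comp)$sequence, comp)
})

test_that("site mutation counting sees only binding-site columns", {
  spec <- scenario_spec(23)
  g <- generate_structure(spec, 1)
  s <- parse_structure(g$pdb)
  lig <- extract_ligands(s)[1, ]
  site <- find_binding_site(s, lig$het_code, lig$chain_id, lig$residue_number)
  q <- s$chains$A$seq_atom
  site_pos <- site$sequence_positions$A

  expect_equal(count_site_mutations(align_sequences(q, q), site, "A"), 0L)

  mut_in <- q
  p_in <- site_pos[1]
  substr(mut_in, p_in, p_in) <- if (substr(q, p_in, p_in) == "W") "Y" else "W"
  expect_equal(count_site_mutations(align_sequences(q, mut_in), site, "A"), 1L)

  mut_out <- q
  p_out <- setdiff(seq(3, nchar(q) - 2), site_pos)[1]
  substr(mut_out, p_out, p_out) <- if (substr(q, p_out, p_out) == "W") "Y" else "W"
  expect_equal(count_site_mutations(align_sequences(q, mut_out), site, "A"), 0L)

  # a structure mutation matched against a variant carrying the same
  # mutation: sequences agree, so nothing is recorded
  expect_equal(count_site_mutations(align_sequences(mut_in, mut_in), site, "A"),
               0L)
  expect_error(count_site_mutations(align_sequences(q, q), site, "B"),
               "chain")
})

test_that("empty sequences are rejected", {
  expect_error(align_sequences("", "MKT"), "empty")
  expect_error(align_sequences("MKT", ""), "empty")
})

test_that("tabular alignment hits round-trip into scored records", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste(c("q1", "h1", "97.5", "200", "5", "0", "1", "200",
                     "31", "230", "1e-50", "400"), collapse = "\t"), path)
  hits <- read_alignment_hits(path, c(q1 = 210L), c(h1 = 240L))
  expect_length(hits, 1L)
  a <- hits[[1]]
  expect_equal(a$identity, 97.5)
  expect_equal(a$coverage_query, 100 * 200 / 210)
  s <- score_match(a)
  expect_equal(s$d_query, abs(1 - 200 / 210))
  expect_equal(s$d_hit, abs(1 - 200 / 240))
  expect_error(read_alignment_hits(path, c(zz = 10L), c(h1 = 240L)),
               "missing sequence lengths")
})
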