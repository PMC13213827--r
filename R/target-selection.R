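# Best-target selection. Candidates for one structure (target mode) or one
# structure-ligand pair (binding mode) are reduced to a single winner by a
# fixed cascade; every removal is attributed to a step for the audit trail.

#' The dummy target accession removed unconditionally
#'
#' This registry target aggregates heterogeneous, unchecked data and is never
#' an acceptable winner.
#' @export
DUMMY_TARGET <- "CHEMBL612545"

.type_rank <- function(type) {
  r <- match(toupper(type),
             c("SINGLE PROTEIN", "PROTEIN COMPLEX", "PROTEIN FAMILY"))
  r[is.na(r)] <- 4L
  r
}

.target_numeric <- function(accession) {
  n <- suppressWarnings(as.numeric(sub("^CHEMBL", "", accession)))
  if (anyNA(n)) {
    stop("target accession(s) not of the form CHEMBL<integer>: ",
         paste(accession[is.na(n)], collapse = ", "), call. = FALSE)
  }
  n
}

#' Build a candidate table for the selection cascade
#'
#' @param target_accession Accessions of the form `CHEMBL<integer>`.
#' @param target_type Registry type label (`SINGLE PROTEIN`, `PROTEIN
#'   COMPLEX`, `PROTEIN FAMILY`, or anything else).
#' @param cov_id Coverage-weighted identity of each candidate's best
#'   alignment.
#' @param molecule_level Molecule match level 0-5 (`NA` in target mode).
#' @param n_site_mutations Binding-site mutation count (`NA` in target mode).
#' @param n_unique_datapoints Distinct activity tuples linked to the
#'   candidate (`NA` in target mode).
#' @param from_seqadv Whether the best match was built from a SEQADV-adjusted
#'   sequence.
#' @return A `target_candidates` data frame.
#' @export
target_candidates <- function(target_accession, target_type, cov_id,
                              molecule_level = NA_integer_,
                              n_site_mutations = NA_integer_,
                              n_unique_datapoints = NA_integer_,
                              from_seqadv = FALSE) {
  out <- data.frame(
    target_accession = as.character(target_accession),
    target_numeric = .target_numeric(target_accession),
    target_type = as.character(target_type),
    cov_id = as.numeric(cov_id),
    molecule_level = as.integer(rep_len(molecule_level, length(target_accession))),
    n_site_mutations = as.integer(rep_len(n_site_mutations, length(target_accession))),
    n_unique_datapoints = as.integer(rep_len(n_unique_datapoints, length(target_accession))),
    from_seqadv = as.logical(rep_len(from_seqadv, length(target_accession))),
    stringsAsFactors = FALSE
  )
  class(out) <- c("target_candidates", "data.frame")
  out
}

#' Run the best-target filter cascade
#'
#' Applies, in order: discard SEQADV-built matches; discard the dummy target;
#' keep the highest `cov_id` (compared after rounding to 6 decimals); keep
#' the highest molecule match level (binding mode only); keep the fewest
#' binding-site mutations (binding mode only); prefer target types in the
#' order SINGLE PROTEIN > PROTEIN COMPLEX > PROTEIN FAMILY, skipping the step
#' when no candidate bears any of the three labels; keep the most unique
#' activity data points (binding mode only); finally keep the lowest
#' accession number. The result is deterministic and independent of input
#' order.
#'
#' @param candidates A `target_candidates` data frame (may have zero rows).
#' @param mode `"binding"` (all steps) or `"target"` (molecule, mutation and
#'   data-point steps skipped).
#' @return List with `winner` (accession or `NA`), and `audit`: `decided_at`
#'   (`SINGLE`, `SEQADV`, `DUMMY`, `SEQUENCE`, `MOLECULE`, `MUTATIONS`,
#'   `TARGET_TYPE`, `DATAPOINTS`, `TIEBREAK`, or `NA` for empty input),
#'   `removals` (data frame `target_accession`, `removed_by`), `winner`.
#' @export
run_cascade <- function(candidates, mode = c("binding", "target")) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(candidates))
  n_input <- nrow(candidates)
  removals <- data.frame(target_accession = character(),
                         removed_by = character(), stringsAsFactors = FALSE)
  if (n_input == 0L) {
    return(list(winner = NA_character_,
                audit = list(decided_at = NA_character_, removals = removals,
                             winner = NA_character_)))
  }
  if (anyDuplicated(candidates$target_accession)) {
    stop("duplicate candidate accessions: ",
         paste(unique(candidates$target_accession[
           duplicated(candidates$target_accession)]), collapse = ", "),
         call. = FALSE)
  }

  cur <- candidates
  decided_at <- "SINGLE"
  drop_rows <- function(keep, step) {
    if (any(!keep)) {
      removals <<- rbind(removals, data.frame(
        target_accession = cur$target_accession[!keep],
        removed_by = step, stringsAsFactors = FALSE))
      cur <<- cur[keep, , drop = FALSE]
      decided_at <<- step
    }
  }

  drop_rows(!cur$from_seqadv, "SEQADV")
  if (nrow(cur) > 0L) drop_rows(cur$target_accession != DUMMY_TARGET, "DUMMY")

  if (nrow(cur) > 1L) {
    cov <- round(cur$cov_id, 6)
    drop_rows(cov == max(cov), "SEQUENCE")
  }
  if (mode == "binding" && nrow(cur) > 1L) {
    ml <- ifelse(is.na(cur$molecule_level), -1L, cur$molecule_level)
    drop_rows(ml == max(ml), "MOLECULE")
  }
  if (mode == "binding" && nrow(cur) > 1L) {
    nm <- ifelse(is.na(cur$n_site_mutations), .Machine$integer.max,
                 cur$n_site_mutations)
    drop_rows(nm == min(nm), "MUTATIONS")
  }
  if (nrow(cur) > 1L) {
    rank <- .type_rank(cur$target_type)
    if (any(rank < 4L)) drop_rows(rank == min(rank), "TARGET_TYPE")
  }
  if (mode == "binding" && nrow(cur) > 1L) {
    dp <- ifelse(is.na(cur$n_unique_datapoints), -1L, cur$n_unique_datapoints)
    drop_rows(dp == max(dp), "DATAPOINTS")
  }
  if (nrow(cur) > 1L) {
    drop_rows(cur$target_numeric == min(cur$target_numeric), "TIEBREAK")
  }

  winner <- if (nrow(cur) == 1L) cur$target_accession else NA_character_
  if (n_input == 1L && !is.na(winner)) decided_at <- "SINGLE"
  list(winner = winner,
       audit = list(decided_at = decided_at, removals = removals,
                    winner = winner))
}

#' Keep the best alignment among several for one candidate pair
#'
#' Maximal `cov_id`; ties broken by higher identity, then longer alignment,
#' then lexicographically smallest hit id.
#'
#' @param alignments Non-empty list of `alignment_result` objects.
#' @return The selected `alignment_result`.
#' @export
select_best_alignment <- function(alignments) {
  if (length(alignments) == 0L) {
    stop("no alignments to select from", call. = FALSE)
  }
  covid <- vapply(alignments, function(a) score_match(a)$cov_id, numeric(1))
  ident <- vapply(alignments, `[[`, numeric(1), "identity")
  alen <- vapply(alignments, `[[`, numeric(1), "alignment_length")
  hid <- vapply(alignments, `[[`, character(1), "hit_id")
  ord <- order(-round(covid, 6), -ident, -alen, hid)
  alignments[[ord[1]]]
}

#' Aggregate cascade audits into per-step counts
#'
#' One row per deciding step with the number of cases decided there, plus
#' one row per step with the number of candidates it removed.
#'
#' @param results List of `run_cascade()` results.
#' @return List of two data frames, `decided` and `removed`.
#' @export
cascade_audit_counts <- function(results) {
  decided <- table(vapply(results, function(r) {
    d <- r$audit$decided_at
    if (is.na(d)) "EMPTY" else d
  }, character(1)))
  removed_all <- do.call(rbind, lapply(results, function(r) r$audit$removals))
  removed <- if (is.null(removed_all) || nrow(removed_all) == 0L) {
    table(character())
  } else {
    table(removed_all$removed_by)
  }
  list(
    decided = data.frame(step = names(decided), n = as.integer(decided),
                         stringsAsFactors = FALSE),
    removed = data.frame(step = names(removed), n = as.integer(removed),
                         stringsAsFactors = FALSE)
  )
}
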