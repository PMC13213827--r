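# Five-level molecule correspondence grading between structure-derived and
# registry-derived small molecules. Level 5 = identical standard InChIKey,
# 4 = identical canonical SMILES with stereo, 3 = identical canonical SMILES
# without stereo, 2 = identical InChI truncated after the hydrogen layer,
# 1 = identical InChI truncated after the atom-connection layer, 0 = no match.

#' Compute all canonical representations of molecules
#'
#' Canonicalizes each molecule (largest covalently connected component; input
#' atom order is irrelevant) and derives the six representations used for
#' correspondence grading: standard InChI, InChIKey, canonical SMILES with and
#' without stereochemistry, and the InChI truncated after the hydrogen and
#' after the atom-connection layer.
#'
#' @param smiles Character vector of SMILES strings.
#' @param id Optional identifiers, recycled against `smiles`.
#' @return A data frame of class `mol_forms` with columns `id`, `input`,
#'   `smiles_chiral`, `smiles_achiral`, `inchi`, `inchi_key`, `inchi_trunc_h`,
#'   `inchi_trunc_c`.
#' @examples
#' \dontrun{
#' mol_forms(c("CCO", "C[C@@H](N)C(=O)O"))
#' }
#' @export
mol_forms <- function(smiles, id = NULL) {
  stopifnot(is.character(smiles))
  if (is.null(id)) id <- as.character(seq_along(smiles))
  id <- rep_len(as.character(id), length(smiles))

  inchi <- ob_convert(smiles, "inchi")
  bad <- which(is.na(inchi) & !is.na(smiles) & nzchar(smiles))
  if (length(bad) > 0L) {
    stop("molecule(s) could not be sanitized/canonicalized: ",
         paste0(id[bad], " ('", smiles[bad], "')", collapse = ", "),
         call. = FALSE)
  }
  forms <- data.frame(
    id             = id,
    input          = smiles,
    smiles_chiral  = ob_convert(smiles, "can"),
    smiles_achiral = ob_convert(smiles, "can_achiral"),
    inchi          = inchi,
    inchi_key      = ob_convert(smiles, "inchikey"),
    stringsAsFactors = FALSE
  )
  forms$inchi_trunc_h <- vapply(forms$inchi, truncate_inchi,
                                character(1), cut_after = "hydrogen")
  forms$inchi_trunc_c <- vapply(forms$inchi, truncate_inchi,
                                character(1), cut_after = "connection")
  class(forms) <- c("mol_forms", "data.frame")
  forms
}

#' Truncate a standard InChI after a named layer
#'
#' Keeps the version prefix and formula, plus the atom-connection (`/c`) layer
#' for `cut_after = "connection"` and additionally the hydrogen (`/h`) layer
#' for `cut_after = "hydrogen"`. When the named layer is absent the truncation
#' happens at the last earlier layer that is present.
#'
#' @param inchi A standard InChI string (must begin with `InChI=`).
#' @param cut_after `"formula"`, `"connection"`, or `"hydrogen"`.
#' @return The truncated InChI string.
#' @export
truncate_inchi <- function(inchi, cut_after = c("hydrogen", "connection", "formula")) {
  cut_after <- match.arg(cut_after)
  stopifnot(is.character(inchi), length(inchi) == 1L)
  if (is.na(inchi)) return(NA_character_)
  if (!startsWith(inchi, "InChI=")) {
    stop("malformed InChI (missing 'InChI=' prefix): ", inchi, call. = FALSE)
  }
  tokens <- strsplit(inchi, "/", fixed = TRUE)[[1]]
  if (length(tokens) < 2L) return(inchi)
  keep_prefixes <- switch(cut_after,
    formula    = character(),
    connection = "c",
    hydrogen   = c("c", "h")
  )
  kept <- tokens[1:2]  # version prefix + molecular formula
  for (tok in tokens[-(1:2)]) {
    if (substr(tok, 1, 1) %in% keep_prefixes) kept <- c(kept, tok) else break
  }
  paste(kept, collapse = "/")
}

#' Grade the correspondence of two molecules
#'
#' Returns the highest level on the five-level scale whose equality criterion
#' holds between the two sets of canonical forms: 5 identical InChIKey,
#' 4 identical chiral canonical SMILES, 3 identical achiral canonical SMILES,
#' 2 identical InChI truncated after the hydrogen layer, 1 identical InChI
#' truncated after the atom-connection layer, 0 otherwise.
#'
#' @param a,b Single-row `mol_forms` data frames (or rows thereof).
#' @return Integer match level in `0:5`.
#' @export
match_level <- function(a, b) {
  stopifnot(nrow(a) == 1L, nrow(b) == 1L)
  eq <- function(x, y) !is.na(x) && !is.na(y) && x == y
  if (eq(a$inchi_key, b$inchi_key)) return(5L)
  if (eq(a$smiles_chiral, b$smiles_chiral)) return(4L)
  if (eq(a$smiles_achiral, b$smiles_achiral)) return(3L)
  if (eq(a$inchi_trunc_h, b$inchi_trunc_h)) return(2L)
  if (eq(a$inchi_trunc_c, b$inchi_trunc_c)) return(1L)
  0L
}

# Which representation decided a given level (for reporting).
.match_level_repr <- c("none", "inchi_trunc_c", "inchi_trunc_h",
                       "smiles_achiral", "smiles_chiral", "inchi_key")

#' Cross-grade two sets of molecules
#'
#' Computes the match level for every pair of one molecule from `a` and one
#' from `b`.
#'
#' @param a,b `mol_forms` data frames.
#' @return A data frame with columns `id_a`, `id_b`, `level`,
#'   `matched_representation`.
#' @export
match_table <- function(a, b) {
  stopifnot(inherits(a, "mol_forms"), inherits(b, "mol_forms"))
  grid <- expand.grid(i = seq_len(nrow(a)), j = seq_len(nrow(b)))
  level <- mapply(function(i, j) match_level(a[i, ], b[j, ]), grid$i, grid$j)
  data.frame(
    id_a = a$id[grid$i],
    id_b = b$id[grid$j],
    level = as.integer(level),
    matched_representation = .match_level_repr[as.integer(level) + 1L],
    stringsAsFactors = FALSE
  )
}

#' Read molecules from a SMILES file
#'
#' Whitespace-separated SMILES-and-title lines; molecules without a title get
#' their line number as id.
#'
#' @param path Path to a `.smi` file.
#' @return A `mol_forms` data frame.
#' @export
read_smiles_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "[ \t]+")
  smiles <- vapply(parts, `[`, character(1), 1L)
  id <- vapply(seq_along(parts), function(i) {
    if (length(parts[[i]]) > 1L) parts[[i]][2L] else as.character(i)
  }, character(1))
  mol_forms(smiles, id = id)
}
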