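# OpenBabel-backed canonicalization. All conversions are batched: one obabel
# process per output format, however many molecules are in the request. A
# package-level cache keyed by (smiles, format) makes repeated form lookups
# (the common case when scoring many activity rows against few ligands) free.

.chem_cache <- new.env(parent = emptyenv())

#' Locate the OpenBabel executable
#'
#' @return Path to `obabel`, or an error if it is not on the PATH.
#' @keywords internal
ob_executable <- function() {
  path <- Sys.which("obabel")
  if (!nzchar(path)) {
    stop("OpenBabel executable 'obabel' not found on PATH; ",
         "molecule canonicalization is unavailable.", call. = FALSE)
  }
  unname(path)
}

# Output format -> obabel arguments. "can" is OpenBabel's canonical SMILES;
# the -xi output option strips isotope and stereo annotations, giving the
# achiral canonical form. "-r" keeps only the largest covalently connected
# component, so registered salts compare equal to the bound species.
.ob_format_args <- list(
  can      = c("-ocan"),
  can_achiral = c("-ocan", "-xi"),
  inchi    = c("-oinchi", "-xt"),
  inchikey = c("-oinchikey", "-xt")
)

#' Batched SMILES conversion through OpenBabel
#'
#' Converts a vector of SMILES strings to one output representation in a
#' single external call. Failed molecules come back as `NA`.
#'
#' @param smiles Character vector of SMILES strings.
#' @param format One of `"can"`, `"can_achiral"`, `"inchi"`, `"inchikey"`.
#' @return Character vector parallel to `smiles`.
#' @keywords internal
ob_convert <- function(smiles, format = c("can", "can_achiral", "inchi", "inchikey")) {
  format <- match.arg(format)
  if (length(smiles) == 0L) return(character())
  stopifnot(is.character(smiles))

  out <- rep(NA_character_, length(smiles))
  keys <- paste0(format, "\r", smiles)
  hit <- vapply(keys, function(k) !is.null(.chem_cache[[k]]), logical(1))
  out[hit] <- vapply(keys[hit], function(k) .chem_cache[[k]], character(1))
  todo <- which(!hit & !is.na(smiles) & nzchar(smiles))
  if (length(todo) == 0L) return(out)

  infile <- tempfile(fileext = ".smi")
  outfile <- tempfile(fileext = ".txt")
  on.exit(unlink(c(infile, outfile)), add = TRUE)
  # Titles m<i> carry the input index through obabel, which silently drops
  # molecules it cannot read.
  writeLines(paste(smiles[todo], paste0("m", seq_along(todo))), infile)
  args <- c(infile, "-ismi", .ob_format_args[[format]], "-r", "-O", outfile)
  status <- suppressWarnings(
    system2(ob_executable(), args, stdout = FALSE, stderr = FALSE)
  )
  if (status != 0L || !file.exists(outfile)) {
    stop("obabel conversion to '", format, "' failed (exit status ", status, ")",
         call. = FALSE)
  }
  res <- readLines(outfile, warn = FALSE)
  res <- res[nzchar(trimws(res))]
  for (line in res) {
    parts <- strsplit(trimws(line), "[ \t]+")[[1]]
    if (length(parts) < 2L) next
    title <- parts[length(parts)]
    if (!grepl("^m[0-9]+$", title)) next
    i <- as.integer(sub("^m", "", title))
    if (i >= 1L && i <= length(todo)) {
      value <- paste(parts[-length(parts)], collapse = " ")
      out[todo[i]] <- value
    }
  }
  for (j in todo) {
    if (!is.na(out[j])) .chem_cache[[keys[j]]] <- out[j]
  }
  out
}
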