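# Sequence data model and IUPAC-aware base operations.
#
# Coordinates are 0-based half-open everywhere in this package; only
# human-readable reports use 1-based inclusive positions.

IUPAC_ALPHABET <- c("A", "C", "G", "T", "R", "Y", "S", "W",
                    "K", "M", "B", "D", "H", "V", "N")

# concrete base sets denoted by each IUPAC symbol
.iupac_sets <- local({
  m <- Biostrings::IUPAC_CODE_MAP[IUPAC_ALPHABET]
  lapply(strsplit(unname(m), ""), identity) |> stats::setNames(IUPAC_ALPHABET)
})

# 15 x 15 logical lookup: do the base sets of two symbols intersect?
.iupac_compat <- local({
  n <- length(IUPAC_ALPHABET)
  mat <- matrix(FALSE, n, n, dimnames = list(IUPAC_ALPHABET, IUPAC_ALPHABET))
  for (a in IUPAC_ALPHABET)
    for (b in IUPAC_ALPHABET)
      mat[a, b] <- length(intersect(.iupac_sets[[a]], .iupac_sets[[b]])) > 0L
  mat
})

# 15 x 15 logical lookup: is the base set of the row symbol a subset of the
# column symbol's set?  Used for the conservative enzyme-site rule: an
# ambiguous sequence base is cut only if every concrete resolution matches.
.iupac_subset <- local({
  n <- length(IUPAC_ALPHABET)
  mat <- matrix(FALSE, n, n, dimnames = list(IUPAC_ALPHABET, IUPAC_ALPHABET))
  for (a in IUPAC_ALPHABET)
    for (b in IUPAC_ALPHABET)
      mat[a, b] <- all(.iupac_sets[[a]] %in% .iupac_sets[[b]])
  mat
})

#' Create a sequence record
#'
#' A `SequenceRecord` is an identified DNA sequence: a template, an amplicon
#' or a reference haplotype. Residues are normalized to uppercase IUPAC DNA
#' (`U` mapped to `T`); gap characters (`-`) are stripped with a warning, as
#' downstream coordinate arithmetic assumes ungapped residues. Any other
#' symbol is rejected.
#'
#' @param id Record identifier (unique within a run).
#' @param residues DNA string over the IUPAC alphabet.
#' @param description Free-text description (FASTA header remainder).
#' @return An object of class `dmcc_seq` with fields `id`, `description`,
#'   `residues` and `length`.
#' @examples
#' seq_record("q1", "acgtn")
#' @export
seq_record <- function(id, residues, description = "") {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  residues <- normalize_residues(residues, id = id)
  structure(
    list(id = id, description = description,
         residues = residues, length = nchar(residues)),
    class = "dmcc_seq"
  )
}

#' @export
print.dmcc_seq <- function(x, ...) {
  cat(sprintf("<dmcc_seq> %s%s  (%d nt)\n", x$id,
              if (nzchar(x$description)) paste0(" ", x$description) else "",
              x$length))
  head_nt <- substr(x$residues, 1L, 60L)
  cat(" ", head_nt, if (x$length > 60L) "..." else "", "\n", sep = "")
  invisible(x)
}

# Normalize residues; error (naming id and 1-based position) on non-IUPAC
# symbols.  Exposed internally; seq_record() and read_fasta() both use it.
normalize_residues <- function(residues, id = "<sequence>") {
  stopifnot(is.character(residues), length(residues) == 1L)
  residues <- toupper(residues)
  residues <- chartr("U", "T", residues)
  if (grepl("-", residues, fixed = TRUE)) {
    warning(sprintf("record '%s': gap characters stripped on input", id),
            call. = FALSE)
    residues <- gsub("-", "", residues, fixed = TRUE)
  }
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  bad <- which(!(chars %in% IUPAC_ALPHABET))
  if (length(bad) > 0L) {
    stop(sprintf(
      "record '%s': non-IUPAC symbol '%s' at position %d",
      id, chars[bad[1]], bad[1]), call. = FALSE)
  }
  residues
}

# internal: character vector of residues
seq_chars <- function(x) {
  strsplit(if (inherits(x, "dmcc_seq")) x$residues else x, "", fixed = TRUE)[[1]]
}

as_residues <- function(x) {
  if (inherits(x, "dmcc_seq")) x$residues else normalize_residues(x)
}

#' Read sequences from a FASTA file
#'
#' Reads a (possibly multi-record, line-wrapped, LF or CRLF) FASTA file and
#' returns normalized [seq_record()] objects in file order. Residues are
#' uppercased with `U` mapped to `T`; gaps are stripped with a warning;
#' any other non-IUPAC symbol is a parse error naming the record and
#' position. Duplicate ids are rejected.
#'
#' @param path Path to a FASTA file.
#' @return A named list of `dmcc_seq` records, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no sequences in FASTA file: ", path, call. = FALSE)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  descs <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L)
    stop("duplicate sequence id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  recs <- vector("list", length(set))
  for (i in seq_along(set)) {
    recs[[i]] <- seq_record(ids[i], as.character(set[[i]]), descs[i])
  }
  stats::setNames(recs, ids)
}

#' Write sequence records to a FASTA file
#'
#' @param records A `dmcc_seq` record or list of records.
#' @param path Output path.
#' @param width Line-wrap width (default 60 columns).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  if (inherits(records, "dmcc_seq")) records <- list(records)
  seqs <- Biostrings::BStringSet(vapply(records, `[[`, "", "residues"))
  names(seqs) <- vapply(records, function(r) {
    if (nzchar(r$description)) paste(r$id, r$description) else r$id
  }, "")
  Biostrings::writeXStringSet(seqs, path, width = width)
  invisible(path)
}

#' Read accession and residues from a GenBank flat file
#'
#' Minimal reader for registry reference sequences: extracts the ACCESSION
#' token and the ORIGIN residues only; all other fields are ignored.
#'
#' @param path Path to a GenBank flat file (single record).
#' @return A `dmcc_seq` whose id is the accession.
#' @export
read_genbank_origin <- function(path) {
  if (!file.exists(path)) stop("GenBank file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  acc_line <- grep("^ACCESSION", lines, value = TRUE)
  acc <- if (length(acc_line) > 0L) {
    strsplit(trimws(sub("^ACCESSION", "", acc_line[1])), "\\s+")[[1]][1]
  } else {
    tools::file_path_sans_ext(basename(path))
  }
  ori <- grep("^ORIGIN", lines)
  if (length(ori) == 0L) stop("no ORIGIN section in ", path, call. = FALSE)
  end <- grep("^//", lines)
  end <- end[end > ori[1]]
  body <- lines[(ori[1] + 1L):(if (length(end)) end[1] - 1L else length(lines))]
  residues <- gsub("[0-9 /]", "", paste(body, collapse = ""))
  seq_record(acc, residues, description = "GenBank ORIGIN")
}

#' Reverse complement of an IUPAC DNA string
#'
#' Uses the full IUPAC complement table (R<->Y, S<->S, W<->W, K<->M, B<->V,
#' D<->H, N<->N); length is preserved and `revcomp(revcomp(x)) == x`.
#'
#' @param x A DNA string or `dmcc_seq` record.
#' @return A character string (the reverse complement). For a `dmcc_seq`
#'   input, a `dmcc_seq` with id suffixed `_rc` is returned.
#' @examples
#' revcomp("AGGATGGAACTGTTCATGAATGAA")
#' @export
revcomp <- function(x) {
  if (inherits(x, "dmcc_seq")) {
    rc <- revcomp(x$residues)
    return(seq_record(paste0(x$id, "_rc"), rc, x$description))
  }
  x <- normalize_residues(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Do two IUPAC symbols denote intersecting base sets?
#'
#' `TRUE` iff the set of concrete bases denoted by `observed` intersects the
#' set denoted by `pattern` (e.g. `R` = \{A,G\} and `W` = \{A,T\} share `A`).
#' Vectorized over both arguments.
#'
#' @param observed Single-character IUPAC symbol(s).
#' @param pattern Single-character IUPAC symbol(s).
#' @return Logical vector.
#' @examples
#' iupac_match("A", "N")  # TRUE
#' iupac_match("A", "Y")  # FALSE
#' @export
iupac_match <- function(observed, pattern) {
  observed <- toupper(observed)
  pattern <- toupper(pattern)
  if (!all(observed %in% IUPAC_ALPHABET))
    stop("non-IUPAC symbol in 'observed'", call. = FALSE)
  if (!all(pattern %in% IUPAC_ALPHABET))
    stop("non-IUPAC symbol in 'pattern'", call. = FALSE)
  .iupac_compat[cbind(observed, pattern)]
}
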