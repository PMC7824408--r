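# Restriction enzyme model and in silico digestion.
#
# Ambiguity policy: a degenerate base in the MOTIF matches by IUPAC base
# sets, but a degenerate base in the SEQUENCE is conservative — a site is
# reported only if every concrete resolution of the observed symbol is
# contained in the motif symbol's set.  Low-quality Sanger positions (N)
# therefore never create phantom cuts.

#' Define a restriction enzyme
#'
#' @param name Enzyme name (e.g. `"DraI"`).
#' @param recognition IUPAC recognition motif, length >= 4.
#' @param cut_offset Position of the top-strand cut within the recognition
#'   site, `0 <= cut_offset <= nchar(recognition)` (DraI: 3, i.e. TTT^AAA).
#' @param palindromic Is the recognition site its own reverse complement?
#'   Non-palindromic enzymes are also searched on the reverse strand.
#' @return An object of class `dmcc_enzyme`.
#' @examples
#' enzyme("DraI", "TTTAAA", 3)
#' @export
enzyme <- function(name, recognition, cut_offset, palindromic = NULL) {
  recognition <- normalize_residues(recognition, id = name)
  if (nchar(recognition) < 4L)
    stop("recognition motif must be >= 4 nt", call. = FALSE)
  stopifnot(cut_offset >= 0L, cut_offset <= nchar(recognition))
  is_pal <- identical(revcomp(recognition), recognition)
  if (is.null(palindromic)) palindromic <- is_pal
  if (palindromic && !is_pal)
    stop(sprintf("enzyme '%s' declared palindromic but %s is not its own reverse complement",
                 name, recognition), call. = FALSE)
  structure(list(name = name, recognition = recognition,
                 cut_offset = as.integer(cut_offset),
                 palindromic = palindromic),
            class = "dmcc_enzyme")
}

#' The DraI enzyme (TTT^AAA), REBASE semantics
#' @return A `dmcc_enzyme` for DraI.
#' @export
enzyme_drai <- function() enzyme("DraI", "TTTAAA", 3L, palindromic = TRUE)

#' @export
print.dmcc_enzyme <- function(x, ...) {
  rec <- paste0(substr(x$recognition, 1, x$cut_offset), "^",
                substr(x$recognition, x$cut_offset + 1, nchar(x$recognition)))
  cat(sprintf("<dmcc_enzyme> %s  %s%s\n", x$name, rec,
              if (x$palindromic) "  (palindromic)" else ""))
  invisible(x)
}

# strict window match used for site scanning: every sequence symbol's base
# set must be a subset of the corresponding motif symbol's set
strict_profile <- function(seq_chars_v, motif_chars) {
  n <- length(seq_chars_v)
  m <- length(motif_chars)
  if (n < m) return(logical(0))
  starts <- seq_len(n - m + 1L)
  ok <- rep(TRUE, n - m + 1L)
  for (j in seq_len(m)) {
    ok <- ok & .iupac_subset[cbind(seq_chars_v[starts + j - 1L],
                                   motif_chars[j])]
  }
  ok
}

#' Find restriction sites on a sequence
#'
#' Reports every position where the recognition motif matches, including
#' overlapping occurrences. For non-palindromic enzymes the reverse-strand
#' motif is also searched, with positions reported on the forward strand.
#'
#' @param seq A `dmcc_seq` record (or DNA string); must be ungapped.
#' @param enz A [enzyme()].
#' @return Sorted integer vector of 0-based site start positions (empty
#'   when there are no sites).
#' @examples
#' find_sites(seq_record("s", "GGTTTAAACC"), enzyme_drai())  # 2
#' @export
find_sites <- function(seq, enz) {
  stopifnot(inherits(enz, "dmcc_enzyme"))
  chars <- seq_chars(seq)
  motif <- seq_chars(enz$recognition)
  hits <- which(strict_profile(chars, motif)) - 1L
  if (!enz$palindromic) {
    rc_motif <- seq_chars(revcomp(enz$recognition))
    hits <- union(hits, which(strict_profile(chars, rc_motif)) - 1L)
  }
  sort(unique(as.integer(hits)))
}

#' Digest a sequence in silico
#'
#' Cuts the (linear, ungapped) sequence at `site + cut_offset` for every
#' recognition site; duplicate cut positions collapse. Fragments tile the
#' sequence exactly and carry coordinates so SNPs can later be located
#' within fragments.
#'
#' @param seq A `dmcc_seq` record (or DNA string).
#' @param enz A [enzyme()].
#' @return An object of class `dmcc_digest` with fields `sequence_id`,
#'   `enzyme_name`, `cut_positions` (sorted) and `fragments` (data frame
#'   with `index`, `start`, `end`, `length` in 5'->3' order).
#' @examples
#' digest(seq_record("s", "GGTTTAAACC"), enzyme_drai())
#' @export
digest <- function(seq, enz) {
  id <- if (inherits(seq, "dmcc_seq")) seq$id else "<sequence>"
  len <- if (inherits(seq, "dmcc_seq")) seq$length else nchar(as_residues(seq))
  sites <- find_sites(seq, enz)
  cuts <- sort(unique(sites + enz$cut_offset))
  cuts <- cuts[cuts > 0L & cuts < len]
  bounds <- c(0L, cuts, len)
  fragments <- data.frame(
    index = seq_len(length(bounds) - 1L) - 1L,
    start = bounds[-length(bounds)],
    end = bounds[-1],
    stringsAsFactors = FALSE)
  fragments$length <- fragments$end - fragments$start
  structure(list(sequence_id = id, enzyme_name = enz$name,
                 cut_positions = cuts, fragments = fragments),
            class = "dmcc_digest")
}

#' @export
print.dmcc_digest <- function(x, ...) {
  cat(sprintf("<dmcc_digest> %s with %s: %d cut(s)\n",
              x$sequence_id, x$enzyme_name, length(x$cut_positions)))
  cat("  fragments (5'->3'):", paste(x$fragments$length, collapse = ", "), "\n")
  invisible(x)
}

#' Gel-visible fragment sizes of a digest
#'
#' Filters out fragments too small to resolve on a gel and returns the
#' remaining sizes in descending (ladder) order. The full [digest()] result
#' stays available unfiltered.
#'
#' @param result A `dmcc_digest`.
#' @param min_visible Minimum resolvable fragment length in nt (default 15,
#'   below which bands are not resolved on 7.5% polyacrylamide).
#' @return Integer vector of fragment lengths `>= min_visible`, descending.
#'   When every fragment is below the threshold, an empty vector carrying
#'   attribute `all_below_min = TRUE` is returned with a warning.
#' @export
visible_fragments <- function(result, min_visible = 15L) {
  stopifnot(inherits(result, "dmcc_digest"), min_visible >= 0L)
  lens <- as.integer(sort(
    result$fragments$length[result$fragments$length >= min_visible],
    decreasing = TRUE))
  if (length(lens) == 0L) {
    warning(sprintf("all fragments of '%s' are below min_visible = %d nt",
                    result$sequence_id, min_visible), call. = FALSE)
    attr(lens, "all_below_min") <- TRUE
  }
  lens
}
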