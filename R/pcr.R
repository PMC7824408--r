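# Primer-site localization, in silico amplification and trimming to the
# classical H2-E2 window.  No indels are modeled in primer annealing:
# Sanger-consensus errors near primer ends are overwhelmingly substitutions,
# and the footprint arithmetic stays exact.

#' Create a primer
#'
#' @param name Primer name (e.g. `"COI_Seq-F"`, `"H2"`).
#' @param sequence IUPAC DNA string, written 5'->3'. Primers shorter than
#'   10 nt are rejected as unreliable anchors.
#' @return An object of class `dmcc_primer`.
#' @export
primer <- function(name, sequence) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  sequence <- normalize_residues(sequence, id = name)
  if (nchar(sequence) < 10L)
    stop(sprintf("primer '%s' is %d nt; primers must be >= 10 nt",
                 name, nchar(sequence)), call. = FALSE)
  structure(list(name = name, sequence = sequence), class = "dmcc_primer")
}

#' @export
print.dmcc_primer <- function(x, ...) {
  cat(sprintf("<dmcc_primer> %s  5'-%s-3'  (%d nt)\n",
              x$name, x$sequence, nchar(x$sequence)))
  invisible(x)
}

# Vectorized mismatch profile: number of IUPAC-incompatible positions for
# every alignment of `pattern_chars` against `template_chars` (both character
# vectors).  Returns an integer vector over start offsets 0 .. n-m.
mismatch_profile <- function(template_chars, pattern_chars) {
  n <- length(template_chars)
  m <- length(pattern_chars)
  if (n < m) return(integer(0))
  starts <- seq_len(n - m + 1L)
  mm <- integer(n - m + 1L)
  for (j in seq_len(m)) {
    mm <- mm + !.iupac_compat[cbind(template_chars[starts + j - 1L],
                                    pattern_chars[j])]
  }
  mm
}

#' Locate primer annealing sites on a template
#'
#' Scans both strands of a template for the primer: the primer sequence on
#' the plus strand and its reverse complement on the minus strand. A hit is
#' any ungapped placement with at most `max_mismatch` IUPAC-incompatible
#' positions (degenerate symbols match by base-set intersection). Indels are
#' not modeled.
#'
#' @param template A `dmcc_seq` record (or DNA string).
#' @param primer A [primer()] object.
#' @param max_mismatch Maximum number of mismatching positions (default 1).
#' @return A data frame with columns `primer_name`, `strand` (`"+"`/`"-"`),
#'   `start`, `end` (0-based half-open footprint on the forward strand) and
#'   `mismatches`, sorted by `start` then strand. A template shorter than
#'   the primer yields an empty result with a warning.
#' @export
find_primer_sites <- function(template, primer, max_mismatch = 1L) {
  stopifnot(inherits(primer, "dmcc_primer"), max_mismatch >= 0L)
  tchars <- seq_chars(template)
  pchars <- seq_chars(primer$sequence)
  m <- length(pchars)
  empty <- data.frame(primer_name = character(), strand = character(),
                      start = integer(), end = integer(),
                      mismatches = integer(), stringsAsFactors = FALSE)
  if (length(tchars) < m) {
    warning(sprintf("template shorter than primer '%s'; no sites searched",
                    primer$name), call. = FALSE)
    return(empty)
  }
  hits <- empty
  for (strand in c("+", "-")) {
    probe <- if (strand == "+") pchars else seq_chars(revcomp(primer$sequence))
    mm <- mismatch_profile(tchars, probe)
    keep <- which(mm <= max_mismatch)
    if (length(keep) > 0L) {
      hits <- rbind(hits, data.frame(
        primer_name = primer$name, strand = strand,
        start = keep - 1L, end = keep - 1L + m,
        mismatches = mm[keep], stringsAsFactors = FALSE))
    }
  }
  hits <- hits[order(hits$start, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Amplify a template in silico with a primer pair
#'
#' Emits one amplicon for every (forward-primer plus-strand hit,
#' reverse-primer minus-strand hit) pair that is correctly oriented
#' (`fwd.start < rev.end`) and no longer than `max_product`. Templates are
#' treated as linear, even when the source is a circular mitogenome: the
#' COI-COII locus never spans the origin.
#'
#' @param template A `dmcc_seq` record.
#' @param fwd,rev [primer()] objects (forward and reverse, both 5'->3').
#' @param max_mismatch Maximum mismatches per primer footprint (default 1).
#' @param max_product Maximum product length in nt (default 2000).
#' @return A list of `dmcc_amplicon` objects sorted by length ascending,
#'   each with fields `template_id`, `start`, `end`, `sequence`,
#'   `fwd_primer`, `rev_primer`, `length`. When no amplicon is possible,
#'   an empty list carrying a `diagnosis` attribute that names the failing
#'   primer(s).
#' @export
amplify <- function(template, fwd, rev, max_mismatch = 1L, max_product = 2000L) {
  stopifnot(inherits(template, "dmcc_seq"),
            inherits(fwd, "dmcc_primer"), inherits(rev, "dmcc_primer"))
  if (max_product <= nchar(fwd$sequence) + nchar(rev$sequence))
    stop("max_product must exceed the combined primer length", call. = FALSE)
  fhits <- find_primer_sites(template, fwd, max_mismatch)
  rhits <- find_primer_sites(template, rev, max_mismatch)
  fhits <- fhits[fhits$strand == "+", , drop = FALSE]
  rhits <- rhits[rhits$strand == "-", , drop = FALSE]
  if (nrow(fhits) == 0L || nrow(rhits) == 0L) {
    missing <- c(if (nrow(fhits) == 0L) fwd$name,
                 if (nrow(rhits) == 0L) rev$name)
    out <- list()
    attr(out, "diagnosis") <- sprintf(
      "no amplicon: no %s-strand site for primer(s) %s",
      paste(ifelse(missing == fwd$name, "+", "-"), collapse = "/"),
      paste(missing, collapse = ", "))
    attr(out, "failed_primers") <- missing
    return(out)
  }
  products <- list()
  for (i in seq_len(nrow(fhits))) {
    for (j in seq_len(nrow(rhits))) {
      s <- fhits$start[i]; e <- rhits$end[j]
      len <- e - s
      if (s < e && len <= max_product) {
        products[[length(products) + 1L]] <- structure(list(
          template_id = template$id, start = s, end = e,
          sequence = substr(template$residues, s + 1L, e),
          fwd_primer = fwd$name, rev_primer = rev$name,
          length = len), class = "dmcc_amplicon")
      }
    }
  }
  if (length(products) == 0L) {
    out <- list()
    attr(out, "diagnosis") <-
      "no amplicon: primer sites found but no correctly oriented pair within max_product"
    attr(out, "failed_primers") <- character(0)
    return(out)
  }
  products[order(vapply(products, `[[`, 0L, "length"))]
}

#' @export
print.dmcc_amplicon <- function(x, ...) {
  cat(sprintf("<dmcc_amplicon> %s [%d, %d)  %d bp  (%s x %s)\n",
              x$template_id, x$start, x$end, x$length,
              x$fwd_primer, x$rev_primer))
  invisible(x)
}

#' Trim a sequence precisely to the H2-E2 window
#'
#' Locates the H2-side and E2-side primer footprints in either orientation
#' of the input and returns the sub-sequence from the start of the upstream
#' (H2) footprint to the end of the downstream (E2) footprint, INCLUSIVE of
#' both primer sequences — the physical H2-E2 amplicon that the classical
#' DmCC test digests, so fragment sizes stay comparable to gel patterns.
#' Output is always reported in the orientation with H2 on the plus strand.
#' Trimming is idempotent and orientation-insensitive.
#'
#' @param seq A `dmcc_seq` record (an extended amplicon in either
#'   orientation, or a sequence already equal to the window).
#' @param h2,e2 [primer()] objects bounding the window.
#' @param max_mismatch Maximum mismatches per footprint (default 1).
#' @return A `dmcc_seq` holding the trimmed window (same id, description
#'   annotated). Errors if either primer is not found (naming it) or if
#'   multiple candidate windows exist (listing them; no silent choice).
#' @export
trim_to_window <- function(seq, h2, e2, max_mismatch = 1L) {
  stopifnot(inherits(seq, "dmcc_seq"),
            inherits(h2, "dmcc_primer"), inherits(e2, "dmcc_primer"))
  windows <- list()
  for (orient in c("fwd", "rev")) {
    s <- if (orient == "fwd") seq else
      seq_record(seq$id, revcomp(seq$residues), seq$description)
    hh <- find_primer_sites(s, h2, max_mismatch)
    eh <- find_primer_sites(s, e2, max_mismatch)
    hh <- hh[hh$strand == "+", , drop = FALSE]
    eh <- eh[eh$strand == "-", , drop = FALSE]
    if (nrow(hh) == 0L || nrow(eh) == 0L) next
    for (i in seq_len(nrow(hh))) for (j in seq_len(nrow(eh))) {
      if (hh$start[i] < eh$end[j]) {
        windows[[length(windows) + 1L]] <- list(
          orient = orient, start = hh$start[i], end = eh$end[j],
          residues = substr(s$residues, hh$start[i] + 1L, eh$end[j]))
      }
    }
  }
  if (length(windows) == 0L) {
    # diagnose which primer is missing, checking both orientations
    h_any <- nrow(find_primer_sites(seq, h2, max_mismatch)) > 0L
    e_any <- nrow(find_primer_sites(seq, e2, max_mismatch)) > 0L
    missing <- c(if (!h_any) h2$name, if (!e_any) e2$name)
    if (length(missing) == 0L) missing <- "an oriented H2..E2 pair"
    stop(sprintf("window not found in '%s': missing %s",
                 seq$id, paste(missing, collapse = " and ")), call. = FALSE)
  }
  # windows identical in residues collapse to one (e.g. palindromic pads)
  uniq <- !duplicated(vapply(windows, `[[`, "", "residues"))
  windows <- windows[uniq]
  if (length(windows) > 1L) {
    desc <- vapply(windows, function(w)
      sprintf("%s[%d,%d)", w$orient, w$start, w$end), "")
    stop(sprintf("multiple candidate H2-E2 windows in '%s': %s",
                 seq$id, paste(desc, collapse = ", ")), call. = FALSE)
  }
  w <- windows[[1]]
  seq_record(seq$id, w$residues,
             description = trimws(paste(seq$description, "[trimmed H2-E2]")))
}
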