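# Lineage, haplotype and subspecies calling; SNP reporting; structure
# annotation of the trimmed COI-COII window.

#' Classify evolutionary lineage from trimmed-window length
#'
#' The length class of the trimmed H2-E2 amplicon stands in for the agarose
#' band of the classical test: the unique lineage whose (inclusive) bin
#' contains the length is returned, `"UNRESOLVED"` when no bin matches.
#'
#' @param trimmed_length Length of the trimmed H2-E2 window in nt (> 0).
#' @param reg A `dmcc_registry` (supplies `lineage_bins`).
#' @return One of `"A"`, `"M"`, `"C"`, `"O"`, `"UNRESOLVED"`.
#' @export
classify_lineage <- function(trimmed_length, reg) {
  stopifnot(inherits(reg, "dmcc_registry"), trimmed_length > 0)
  for (ln in names(reg$lineage_bins)) {
    b <- reg$lineage_bins[[ln]]
    if (trimmed_length >= b[1] && trimmed_length <= b[2]) return(ln)
  }
  "UNRESOLVED"
}

# per-fragment tolerance: max(absolute_bp, relative * expected)
fragment_tolerance <- function(expected, tol) {
  pmax(tol$absolute_bp, tol$relative * expected)
}

#' Match an observed fragment pattern against the registry
#'
#' A haplotype matches iff it has the same visible-fragment count and, after
#' pairing fragments in descending order (the way ladder lanes are read on a
#' gel), every `|observed - expected|` is within
#' `max(absolute_bp, relative * expected)`. Among matches the minimal summed
#' absolute deviation wins; an exact tie is broken alphabetically and
#' flagged `AMBIGUOUS_TIE`. With no match the call is `NOVEL` with flag
#' `NOVEL_PATTERN`, and the distance to the nearest registry pattern is
#' reported for diagnostics (unpaired fragments count their full size).
#'
#' @param observed_sizes Descending vector of visible fragment lengths, as
#'   produced by [visible_fragments()] with the registry's `min_visible`.
#' @param reg A `dmcc_registry`.
#' @return A list with `haplotype` (name or `"NOVEL"`), `record` (the
#'   matched `dmcc_haplotype` or `NULL`), `distance` (nt), `fragment_deltas`
#'   (signed observed - expected, for the matched or nearest entry), `flags`
#'   (character subset of `AMBIGUOUS_TIE`, `NOVEL_PATTERN`) and
#'   `nearest` (nearest entry name, for NOVEL calls).
#' @export
match_pattern <- function(observed_sizes, reg) {
  stopifnot(inherits(reg, "dmcc_registry"))
  observed_sizes <- as.integer(observed_sizes)
  if (length(observed_sizes) == 0L)
    stop("empty observed fragment pattern: nothing visible to match",
         call. = FALSE)
  if (any(diff(observed_sizes) > 0L))
    observed_sizes <- sort(observed_sizes, decreasing = TRUE)
  matches <- list()
  nearest_name <- NA_character_
  nearest_dist <- Inf
  nearest_deltas <- NULL
  for (h in reg$haplotypes) {
    exp_sizes <- h$expected_sizes
    k <- min(length(observed_sizes), length(exp_sizes))
    deltas_k <- observed_sizes[seq_len(k)] - exp_sizes[seq_len(k)]
    # diagnostic distance: paired deviations plus full size of unpaired bands
    diag_dist <- sum(abs(deltas_k)) +
      sum(observed_sizes[seq_len(length(observed_sizes)) > k]) +
      sum(exp_sizes[seq_len(length(exp_sizes)) > k])
    if (diag_dist < nearest_dist ||
        (diag_dist == nearest_dist && is.na(nearest_name))) {
      nearest_dist <- diag_dist
      nearest_name <- h$name
      nearest_deltas <- deltas_k
    }
    if (length(observed_sizes) != length(exp_sizes)) next
    tol <- fragment_tolerance(exp_sizes, reg$tolerance)
    if (all(abs(deltas_k) <= tol)) {
      matches[[h$name]] <- list(record = h, distance = sum(abs(deltas_k)),
                                deltas = deltas_k)
    }
  }
  if (length(matches) == 0L) {
    return(list(haplotype = "NOVEL", record = NULL,
                distance = nearest_dist,
                fragment_deltas = nearest_deltas,
                flags = "NOVEL_PATTERN", nearest = nearest_name))
  }
  dists <- vapply(matches, `[[`, 0, "distance")
  best_d <- min(dists)
  best <- sort(names(dists)[dists == best_d])  # alphabetical tie-break
  flags <- if (length(best) > 1L) "AMBIGUOUS_TIE" else character(0)
  chosen <- matches[[best[1]]]
  list(haplotype = best[1], record = chosen$record,
       distance = chosen$distance, fragment_deltas = chosen$deltas,
       flags = flags, nearest = best[1])
}

#' Detect SNPs and indels against a reference haplotype sequence
#'
#' Globally aligns the trimmed window to the reference (end-to-end;
#' match +1, mismatch -1, affine gaps costing 4 to open plus 1 per gapped
#' position) and walks the alignment columns, emitting substitutions and
#' merged indel runs in 0-based reference coordinates. By the DmCC rule,
#' these differences never by themselves change a haplotype name — they are
#' reported alongside the fragment-pattern call.
#'
#' @param trimmed A `dmcc_seq` (trimmed H2-E2 window).
#' @param reference A `dmcc_seq` or IUPAC string (reference window), or
#'   `NULL` when the called haplotype has no reference — then an empty
#'   result with a `note` attribute is returned, never an error.
#' @param match,mismatch,gap_opening,gap_extension Alignment scores.
#' @return A data frame with columns `pos` (0-based reference position; for
#'   insertions, the reference position before which the bases insert),
#'   `type` (`SNP`, `INS`, `DEL`), `ref`, `alt`, `length`.
#' @export
detect_snps <- function(trimmed, reference,
                        match = 1, mismatch = -1,
                        gap_opening = 4, gap_extension = 1) {
  empty <- data.frame(pos = integer(), type = character(),
                      ref = character(), alt = character(),
                      length = integer(), stringsAsFactors = FALSE)
  if (is.null(reference)) {
    attr(empty, "note") <- "no reference sequence for the called haplotype"
    return(empty)
  }
  qry <- as_residues(trimmed)
  ref <- as_residues(reference)
  if (identical(qry, ref)) return(empty)
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = match, mismatch = mismatch, baseOnly = FALSE, type = "DNA")
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(qry), subject = Biostrings::DNAString(ref),
    type = "global", substitutionMatrix = mat,
    gapOpening = gap_opening, gapExtension = gap_extension)
  pch <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sch <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  out <- empty
  refpos <- 0L
  run_type <- ""
  run_start <- 0L
  run_ref <- character(0)
  run_alt <- character(0)
  flush_run <- function() {
    if (run_type == "") return()
    out[nrow(out) + 1L, ] <<- list(
      pos = run_start, type = run_type,
      ref = if (run_type == "INS") "-" else paste(run_ref, collapse = ""),
      alt = if (run_type == "DEL") "-" else paste(run_alt, collapse = ""),
      length = max(length(run_ref), length(run_alt)))
    run_type <<- ""
    run_ref <<- character(0)
    run_alt <<- character(0)
  }
  for (i in seq_along(pch)) {
    p <- pch[i]; s <- sch[i]
    if (s != "-" && p != "-") {
      flush_run()
      if (p != s) {
        out[nrow(out) + 1L, ] <- list(pos = refpos, type = "SNP",
                                      ref = s, alt = p, length = 1L)
      }
      refpos <- refpos + 1L
    } else if (s == "-") {          # insertion in the query
      if (run_type != "INS") { flush_run(); run_type <- "INS"; run_start <- refpos }
      run_alt <- c(run_alt, p)
    } else {                        # deletion from the reference
      if (run_type != "DEL") { flush_run(); run_type <- "DEL"; run_start <- refpos }
      run_ref <- c(run_ref, s)
      refpos <- refpos + 1L
    }
  }
  flush_run()
  out
}

#' Annotate the structural organization of a trimmed window
#'
#' Locates the structural elements of the COI-COII intergenic region
#' (3' end of COI, tRNA-Leu, the non-coding Q fragment, 5' end of COII) by
#' best local alignment of registry element exemplars against the trimmed
#' window. Elements aligning below the identity threshold are omitted with
#' a note.
#'
#' @param trimmed A `dmcc_seq` (trimmed H2-E2 window).
#' @param reg A `dmcc_registry` whose `elements` field holds exemplar
#'   sequences.
#' @param min_identity Minimum percent identity over the aligned span for
#'   an element to be reported (default 0.8).
#' @return A data frame with columns `element`, `start`, `end` (0-based
#'   half-open on the trimmed window), `identity`, ordered by `start`;
#'   omitted elements are listed in the `omitted` attribute. Empty (with a
#'   warning) when nothing can be located or the registry has no exemplars.
#' @export
annotate_structure <- function(trimmed, reg, min_identity = 0.8) {
  stopifnot(inherits(reg, "dmcc_registry"))
  empty <- data.frame(element = character(), start = integer(),
                      end = integer(), identity = numeric(),
                      stringsAsFactors = FALSE)
  if (is.null(reg$elements) || length(reg$elements) == 0L) {
    warning("registry provides no element exemplars; empty annotation",
            call. = FALSE)
    return(empty)
  }
  qry <- Biostrings::DNAString(as_residues(trimmed))
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = 2, mismatch = -3, baseOnly = FALSE, type = "DNA")
  rows <- list()
  omitted <- character(0)
  for (el in names(reg$elements)) {
    exemplar <- Biostrings::DNAString(normalize_residues(reg$elements[[el]], el))
    aln <- Biostrings::pairwiseAlignment(
      pattern = exemplar, subject = qry, type = "local",
      substitutionMatrix = mat, gapOpening = 5, gapExtension = 2)
    span <- Biostrings::subject(aln)
    ident <- Biostrings::pid(aln, type = "PID2") / 100
    covered <- Biostrings::nchar(aln) / length(exemplar)
    if (ident >= min_identity && covered >= 0.3) {
      rows[[el]] <- data.frame(
        element = el,
        start = as.integer(Biostrings::start(span) - 1L),
        end = as.integer(Biostrings::end(span)),
        identity = round(ident, 4), stringsAsFactors = FALSE)
    } else {
      omitted <- c(omitted, el)
    }
  }
  if (length(rows) == 0L) {
    warning("no structural element could be located", call. = FALSE)
    attr(empty, "omitted") <- omitted
    return(empty)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$start), , drop = FALSE]
  # resolve overlaps deterministically: keep the higher-identity element
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))[-1]) {
    prev <- max(which(keep[seq_len(i - 1L)]))
    if (out$start[i] < out$end[prev]) {
      if (out$identity[i] > out$identity[prev]) keep[prev] <- FALSE
      else keep[i] <- FALSE
    }
  }
  dropped <- out$element[!keep]
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "omitted") <- c(omitted, dropped)
  out
}
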