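# Shared fixtures and independent oracles.  Oracles deliberately avoid the
# package's own matching code: complement/base-set tables are written out by
# hand, site scanning goes through perl regex lookahead on concrete motif
# expansions, and primer scanning is a naive per-position loop.

# hand-written IUPAC base sets (independent of the package tables)
ORACLE_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

# hand-written complement pairs
ORACLE_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A",
                       R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
                       B = "V", V = "B", D = "H", H = "D", N = "N")

oracle_revcomp <- function(x) {
  chars <- strsplit(x, "")[[1]]
  paste(rev(unname(ORACLE_COMPLEMENT[chars])), collapse = "")
}

rand_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# set-intersection lookup precomputed from the hand-written table (keeps the
# naive scan below independent of the package yet fast enough to run)
ORACLE_COMPAT <- local({
  syms <- names(ORACLE_SETS)
  m <- matrix(FALSE, length(syms), length(syms), dimnames = list(syms, syms))
  for (a in syms) for (b in syms)
    m[a, b] <- length(intersect(ORACLE_SETS[[a]], ORACLE_SETS[[b]])) > 0L
  m
})

# naive O(n*m) per-position primer scan on both strands
oracle_primer_scan <- function(template, primer_seq, max_mm) {
  tch <- strsplit(template, "")[[1]]
  rows <- list()
  for (strand in c("+", "-")) {
    probe <- if (strand == "+") primer_seq else oracle_revcomp(primer_seq)
    pch <- strsplit(probe, "")[[1]]
    m <- length(pch)
    if (length(tch) < m) next
    for (s in 0:(length(tch) - m)) {
      mm <- sum(!ORACLE_COMPAT[cbind(tch[s + seq_len(m)], pch)])
      if (mm <= max_mm)
        rows[[length(rows) + 1L]] <- data.frame(
          strand = strand, start = s, mismatches = mm,
          stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(strand = character(), start = integer(),
                      mismatches = integer(), stringsAsFactors = FALSE))
  hits <- do.call(rbind, rows)
  hits[order(hits$start, hits$strand), , drop = FALSE]
}

# expand a degenerate motif into its concrete resolutions
oracle_expand_motif <- function(motif) {
  sets <- ORACLE_SETS[strsplit(motif, "")[[1]]]
  apply(do.call(expand.grid, c(sets, stringsAsFactors = FALSE)), 1,
        paste, collapse = "")
}

# overlapping site scan via perl lookahead; 0-based positions.  For
# non-palindromic motifs the reverse-strand motif is scanned too, with
# positions reported on the forward strand (the digestion contract).
oracle_find_sites <- function(seq, motif) {
  probes <- unique(c(motif, oracle_revcomp(motif)))
  sites <- integer(0)
  for (probe in probes) {
    for (concrete in oracle_expand_motif(probe)) {
      m <- gregexpr(paste0("(?=", concrete, ")"), seq, perl = TRUE)[[1]]
      if (m[1] != -1L) sites <- c(sites, as.integer(m) - 1L)
    }
  }
  sort(unique(sites))
}

# full digest oracle: sites -> cuts -> fragment lengths 5'->3'
oracle_digest_lengths <- function(seq, motif, cut_offset) {
  len <- nchar(seq)
  cuts <- oracle_find_sites(seq, motif) + cut_offset
  cuts <- sort(unique(cuts[cuts > 0L & cuts < len]))
  diff(c(0L, cuts, len))
}

# one shared synthetic registry for the whole suite (built once)
fixture_registry <- local({
  reg <- NULL
  function() {
    if (is.null(reg)) reg <<- make_registry(42)
    reg
  }
})

write_temp_fasta <- function(lines) {
  path <- withr::local_tempfile(fileext = ".fasta",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
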