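# Deterministic synthetic COI-COII-like fixtures: templates, registries and
# mitogenome-scale stand-ins, so every pipeline stage is testable offline.
#
# Background composition is uniform over {A,C,G,T}; any segment that would
# introduce an unplanted recognition site or a spurious primer hit is
# redrawn, so the emitted truth record is exact by construction.

# run code under a seed, preserving the caller's RNG state
with_preserved_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# random segment guaranteed free of the motif
random_dna_clean <- function(n, motif = "TTTAAA", max_tries = 200L) {
  for (i in seq_len(max_tries)) {
    s <- random_dna(n)
    if (!grepl(motif, s, fixed = TRUE)) return(s)
  }
  stop("could not draw a motif-free segment of length ", n, call. = FALSE)
}

#' Specification of one synthetic COI-COII-like template
#'
#' The synthetic window mirrors the structural organization of the real
#' intergenic region: an H2 footprint, a 3' stub of COI, tRNA-Leu, the
#' non-coding Q fragment (which carries the planted DraI sites), a 5' stub
#' of COII and the E2 footprint. With `include_extended_pads` the window is
#' embedded in COI/COII pads carrying the outer sequencing primers, giving
#' an extended amplicon (820 bp under the defaults).
#'
#' @param seed Integer seed; the same spec always yields the same template.
#' @param haplotype Optional registry haplotype name. When given, the
#'   window is that entry's `reference_sequence` with `snps` applied
#'   (copy mode); otherwise a fresh window is assembled from the registry's
#'   element exemplars (assembly mode).
#' @param window_length Trimmed H2-E2 window length in nt (assembly mode;
#'   default 600).
#' @param planted_drai_offsets 0-based window offsets at which `TTTAAA` is
#'   written (assembly mode); must fall in the Q region and be >= 6 apart.
#' @param snps List of `list(pos, alt)` single-base substitutions applied
#'   to the window (0-based window coordinates); they must not touch primer
#'   footprints and must leave the recognition-site set unchanged.
#' @param include_extended_pads Add COI/COII pads with the outer primer
#'   sites so that trimming is exercised (default TRUE).
#' @param pad_length Length of each pad in nt (default 110; with the
#'   600 nt default window the extended amplicon is 820 bp).
#' @param fill `"random"` (redrawable background after Q; default) or
#'   `"exemplar"` (COII 5' stub copied from the registry exemplar, so
#'   structure annotation can recover it).
#' @return An object of class `dmcc_synth_spec`.
#' @export
synth_spec <- function(seed, haplotype = NULL, window_length = 600L,
                       planted_drai_offsets = c(160L, 330L),
                       snps = list(), include_extended_pads = TRUE,
                       pad_length = 110L, fill = c("random", "exemplar")) {
  fill <- match.arg(fill)
  planted_drai_offsets <- sort(as.integer(planted_drai_offsets))
  if (length(planted_drai_offsets) > 1L &&
      any(diff(planted_drai_offsets) < 6L))
    stop("planted DraI sites overlap", call. = FALSE)
  structure(list(seed = as.integer(seed), haplotype = haplotype,
                 window_length = as.integer(window_length),
                 planted_drai_offsets = planted_drai_offsets,
                 snps = snps, include_extended_pads = include_extended_pads,
                 pad_length = as.integer(pad_length), fill = fill),
            class = "dmcc_synth_spec")
}

# fixed window geometry (assembly mode): H2 | COI3' | tRNA-Leu | Q | fill | E2'
SYNTH_GEOM <- list(coi3 = 60L, trna = 70L, q = 250L)

q_region <- function(h2_len) {
  start <- h2_len + SYNTH_GEOM$coi3 + SYNTH_GEOM$trna
  c(start, start + SYNTH_GEOM$q)
}

#' Generate a synthetic template with its truth record
#'
#' Deterministic in `spec$seed`. The truth record carries everything the
#' pipeline is expected to recover: window coordinates on the template,
#' expected cut offsets and fragment lengths, the expected haplotype call
#' (copy mode) and the planted SNPs.
#'
#' @param spec A [synth_spec()].
#' @param reg A `dmcc_registry` supplying primers, enzyme, exemplars and
#'   (copy mode) the reference window.
#' @param id Sequence id for the template (default `"synth"`).
#' @return List with `template` (a `dmcc_seq`) and `truth` (a list with
#'   `window_start`, `window_end`, `window_length`, `lineage`, `haplotype`,
#'   `cut_offsets`, `fragments`, `visible_sizes`, `snps`).
#' @export
make_template <- function(spec, reg, id = "synth") {
  stopifnot(inherits(spec, "dmcc_synth_spec"), inherits(reg, "dmcc_registry"))
  with_preserved_seed(spec$seed, build_template(spec, reg, id))
}

build_template <- function(spec, reg, id) {
  h2 <- reg$primers$H2; e2 <- reg$primers$E2
  motif <- reg$enzyme$recognition
  if (!is.null(spec$haplotype)) {
    h <- reg$haplotypes[[spec$haplotype]]
    if (is.null(h) || is.null(h$reference_sequence))
      stop("registry has no reference sequence for haplotype '",
           spec$haplotype, "'", call. = FALSE)
    window <- h$reference_sequence
    expected_hap <- h$name
  } else {
    window <- assemble_window(spec, reg)
    expected_hap <- NULL
  }
  sites0 <- find_sites(window, reg$enzyme)
  window <- apply_planted_snps(window, spec$snps, sites0,
                               nchar(h2$sequence), nchar(e2$sequence),
                               reg$enzyme)
  planted_snps <- attr(window, "planted_snps")
  attr(window, "planted_snps") <- NULL

  L <- nchar(window)
  if (spec$include_extended_pads) {
    fwd_out <- reg$primers[["COI_Seq-F"]]
    rev_out <- reg$primers[["COII_Seq-R"]]
    if (is.null(fwd_out) || is.null(rev_out))
      stop("registry lacks the outer primers COI_Seq-F/COII_Seq-R needed ",
           "for extended pads", call. = FALSE)
    template_res <- add_pads(window, spec$pad_length, fwd_out, rev_out,
                             reg, motif)
    win_start <- spec$pad_length
  } else {
    template_res <- window
    win_start <- 0L
  }
  template <- seq_record(id, template_res, "synthetic COI-COII-like template")

  d <- digest(seq_record(paste0(id, "_win"), window), reg$enzyme)
  vis <- suppressWarnings(visible_fragments(d, reg$min_visible))
  truth <- list(
    sample_id = id,
    window_start = win_start, window_end = win_start + L,
    window_length = L,
    lineage = classify_lineage(L, reg),
    haplotype = expected_hap %||% "NOVEL",
    cut_offsets = d$cut_positions,
    fragments = d$fragments$length,
    visible_sizes = as.integer(vis),
    snps = planted_snps)
  list(template = template, truth = truth)
}

# assembly mode: build a fresh window from registry exemplars
assemble_window <- function(spec, reg, max_tries = 200L) {
  h2 <- reg$primers$H2; e2 <- reg$primers$E2
  motif <- reg$enzyme$recognition
  els <- reg$elements
  need <- c("COI_3prime", "tRNA_Leu", "Q_fragment")
  if (is.null(els) || !all(need %in% names(els)))
    stop("assembly mode needs registry element exemplars: ",
         paste(need, collapse = ", "), call. = FALSE)
  h2_len <- nchar(h2$sequence); e2_len <- nchar(e2$sequence)
  qr <- q_region(h2_len)
  offs <- spec$planted_drai_offsets
  if (length(offs) > 0L &&
      (any(offs < qr[1]) || any(offs + nchar(motif) > qr[2])))
    stop(sprintf("planted DraI offsets must lie in the Q region [%d, %d)",
                 qr[1], qr[2] - nchar(motif) + 1L), call. = FALSE)
  fixed_len <- h2_len + SYNTH_GEOM$coi3 + SYNTH_GEOM$trna + SYNTH_GEOM$q + e2_len
  fill_len <- spec$window_length - fixed_len
  if (fill_len < 20L)
    stop("window_length too short for the synthetic geometry (need >= ",
         fixed_len + 20L, " nt)", call. = FALSE)
  q_seq <- seq_chars(substr(els[["Q_fragment"]], 1L, SYNTH_GEOM$q))
  for (o in offs) {
    rel <- o - qr[1]
    q_seq[rel + seq_len(nchar(motif))] <- seq_chars(motif)
  }
  head_part <- paste0(h2$sequence,
                      substr(els[["COI_3prime"]], 1L, SYNTH_GEOM$coi3),
                      substr(els[["tRNA_Leu"]], 1L, SYNTH_GEOM$trna),
                      paste(q_seq, collapse = ""))
  for (i in seq_len(max_tries)) {
    fill <- if (spec$fill == "exemplar") {
      ex <- els[["COII_5prime"]]
      if (is.null(ex) || nchar(ex) < fill_len)
        stop("COII_5prime exemplar absent or shorter than the fill (",
             fill_len, " nt)", call. = FALSE)
      substr(ex, 1L, fill_len)
    } else random_dna_clean(fill_len, motif)
    window <- paste0(head_part, fill, revcomp(e2$sequence))
    sites <- find_sites(window, reg$enzyme)
    if (!identical(sites, as.integer(offs))) {
      if (spec$fill == "exemplar")
        stop("exemplar fill introduces an unplanted recognition site; ",
             "impossible spec", call. = FALSE)
      next
    }
    if (window_primers_unique(window, reg)) return(window)
    if (spec$fill == "exemplar")
      stop("exemplar fill creates a spurious primer site; impossible spec",
           call. = FALSE)
  }
  stop("could not assemble a clean synthetic window after ", max_tries,
       " attempts", call. = FALSE)
}

# exactly one H2 (+) footprint at the start and one E2 (-) at the end
window_primers_unique <- function(window, reg) {
  L <- nchar(window)
  hh <- find_primer_sites(window, reg$primers$H2, 1L)
  eh <- find_primer_sites(window, reg$primers$E2, 1L)
  hp <- hh[hh$strand == "+", , drop = FALSE]
  em <- eh[eh$strand == "-", , drop = FALSE]
  nrow(hp) == 1L && hp$start[1] == 0L &&
    nrow(em) == 1L && em$end[1] == L
}

# apply pattern-neutral planted SNPs; returns window with attr planted_snps
apply_planted_snps <- function(window, snps, sites0, h2_len, e2_len, enz) {
  out <- data.frame(pos = integer(), ref = character(), alt = character(),
                    stringsAsFactors = FALSE)
  if (length(snps) == 0L) { attr(window, "planted_snps") <- out; return(window) }
  chars <- seq_chars(window)
  L <- length(chars)
  msz <- nchar(enz$recognition)
  forbidden <- c(seq_len(h2_len),                      # H2 footprint (1-based)
                 (L - e2_len + 1L):L,                  # E2 footprint
                 unlist(lapply(sites0, function(s) s + seq_len(msz))))
  for (sn in snps) {
    pos <- as.integer(sn$pos); alt <- toupper(sn$alt)
    if ((pos + 1L) %in% forbidden)
      stop("planted SNP at ", pos, " overlaps a primer footprint or a ",
           "planted recognition site", call. = FALSE)
    ref <- chars[pos + 1L]
    if (identical(ref, alt))
      stop("planted SNP at ", pos, " does not change the base", call. = FALSE)
    chars[pos + 1L] <- alt
    out[nrow(out) + 1L, ] <- list(pos = pos, ref = ref, alt = alt)
  }
  mutated <- paste(chars, collapse = "")
  if (!identical(find_sites(mutated, enz), sites0))
    stop("planted SNPs alter the recognition-site set; impossible spec",
         call. = FALSE)
  attr(mutated, "planted_snps") <- out
  mutated
}

# wrap the window in COI/COII pads carrying the outer primers
add_pads <- function(window, pad_length, fwd_out, rev_out, reg, motif,
                     max_tries = 200L) {
  flen <- nchar(fwd_out$sequence); rlen <- nchar(rev_out$sequence)
  if (pad_length < flen + 6L || pad_length < rlen + 6L)
    stop("pad_length must exceed the outer primer length by >= 6 nt",
         call. = FALSE)
  for (i in seq_len(max_tries)) {
    left <- paste0(fwd_out$sequence, random_dna_clean(pad_length - flen, motif))
    right <- paste0(random_dna_clean(pad_length - rlen, motif),
                    revcomp(rev_out$sequence))
    template <- paste0(left, window, right)
    if (template_clean(template, window, pad_length, reg, motif))
      return(template)
  }
  stop("could not draw clean extended pads after ", max_tries, " attempts",
       call. = FALSE)
}

# no unplanted recognition sites anywhere; every primer hits exactly once
template_clean <- function(template, window, pad_length, reg, motif) {
  win_sites <- find_sites(window, reg$enzyme) + pad_length
  if (!identical(find_sites(template, reg$enzyme), win_sites)) return(FALSE)
  L <- nchar(template)
  for (nm in c("H2", "E2", "COI_Seq-F", "COII_Seq-R")) {
    p <- reg$primers[[nm]]
    if (is.null(p)) next
    hits <- find_primer_sites(template, p, 1L)
    want_strand <- if (nm %in% c("E2", "COII_Seq-R")) "-" else "+"
    if (nrow(hits) != 1L || hits$strand[1] != want_strand) return(FALSE)
  }
  TRUE
}

#' Generate a synthetic haplotype registry
#'
#' Builds `n_haplotypes` synthetic haplotype entries with distinct visible
#' fragment patterns (pairwise separated by more than twice the matching
#' tolerance), each with a self-consistent reference window; lineages C and
#' A are populated (Z-prefixed entries carry lineage A, following DmCC
#' convention). The registry also carries element exemplars, synthetic
#' H2/E2 primers (the originally published DmCC primer sequences are user
#' data and must be supplied in real registries) and the real outer
#' sequencing primers COI_Seq-F / COII_Seq-R.
#'
#' @param seed Integer seed.
#' @param n_haplotypes Number of entries (2 to 12, default 5; at the
#'   default the entry names mirror the classical reference panel C1, C2,
#'   C3, A2, Z1).
#' @return A validated `dmcc_registry`.
#' @export
make_registry <- function(seed, n_haplotypes = 5L) {
  stopifnot(n_haplotypes >= 2L, n_haplotypes <= 12L)
  with_preserved_seed(seed, build_registry(n_haplotypes))
}

build_registry <- function(n, max_tries = 200L) {
  enz <- enzyme_drai()
  motif <- enz$recognition
  # synthetic H2/E2 anchors; E2 is drawn so its reverse complement cannot
  # seed a recognition site across the window's right junction
  h2 <- primer("H2", random_dna_clean(20L, motif))
  repeat {
    e2_seq <- random_dna_clean(20L, motif)
    rc1 <- substr(revcomp(e2_seq), 1L, 1L)
    if (rc1 %in% c("C", "G")) break
  }
  e2 <- primer("E2", e2_seq)
  primers <- list(
    "H2" = h2, "E2" = e2,
    "COI_Seq-F" = primer("COI_Seq-F", "ACCACCTCTAGATCATTCACATTT"),
    "COII_Seq-R" = primer("COII_Seq-R", "AGGATGGAACTGTTCATGAATGAA"))
  # shared element exemplars; the fixed head concatenation must be clean
  for (i in seq_len(max_tries)) {
    elements <- c(
      COI_3prime = random_dna_clean(SYNTH_GEOM$coi3, motif),
      tRNA_Leu = random_dna_clean(SYNTH_GEOM$trna, motif),
      Q_fragment = random_dna_clean(SYNTH_GEOM$q, motif),
      COII_5prime = random_dna_clean(400L, motif))
    head_concat <- paste0(h2$sequence, elements[["COI_3prime"]],
                          elements[["tRNA_Leu"]], elements[["Q_fragment"]])
    if (!grepl(motif, head_concat, fixed = TRUE)) break
    if (i == max_tries) stop("could not draw clean element exemplars",
                             call. = FALSE)
  }
  lineage_bins <- list(C = c(500L, 760L), A = c(770L, 1020L))
  tolerance <- list(absolute_bp = 3L, relative = 0.02)
  min_visible <- 15L
  n_c <- ceiling(n * 0.6)
  names_panel <- c("C1", "C2", "C3", "A2", "Z1")
  labels <- c(C1 = "synthetic ligustica-like", C2 = "synthetic carnica-like")

  stub <- structure(list(primers = primers, enzyme = enz,
                         lineage_bins = lineage_bins,
                         tolerance = tolerance, min_visible = min_visible,
                         elements = elements, haplotypes = list()),
                    class = "dmcc_registry")
  haps <- list()
  patterns <- list()
  qr <- q_region(nchar(h2$sequence))
  for (i in seq_len(n)) {
    is_c <- i <= n_c
    idx <- if (is_c) i else i - n_c
    nm <- if (n == 5L) names_panel[i] else
      paste0(if (is_c) "C" else "A", idx)
    lineage <- if (is_c) "C" else "A"
    L <- if (is_c) 560L + 30L * idx else 800L + 30L * idx
    n_sites <- 1L + (i %% 3L)
    placed <- FALSE
    for (attempt in seq_len(max_tries)) {
      offs <- sort(sample(seq(qr[1] + 5L, qr[2] - nchar(motif) - 5L), n_sites))
      if (length(offs) > 1L && any(diff(offs) < 30L)) next
      spec <- synth_spec(seed = sample.int(2^20, 1L), haplotype = NULL,
                         window_length = L, planted_drai_offsets = offs,
                         include_extended_pads = FALSE)
      window <- tryCatch(assemble_window(spec, stub),
                         error = function(e) NULL)
      if (is.null(window)) next
      d <- digest(seq_record(nm, window), enz)
      vis <- suppressWarnings(visible_fragments(d, min_visible))
      if (length(vis) == 0L) next
      if (pattern_too_close(vis, patterns, tolerance)) next
      haps[[nm]] <- haplotype_record(
        nm, lineage, if (nm %in% names(labels)) labels[[nm]] else "", vis,
        reference_sequence = window)
      patterns[[nm]] <- vis
      placed <- TRUE
      break
    }
    if (!placed)
      stop("cannot place a distinct pattern for entry ", i, " of ", n,
           call. = FALSE)
  }
  registry(primers = primers, enzyme = enz, lineage_bins = lineage_bins,
           haplotypes = unname(haps), tolerance = tolerance,
           min_visible = min_visible, elements = elements)
}

# is a candidate pattern within 2x tolerance of an existing one?
pattern_too_close <- function(vis, patterns, tol) {
  for (p in patterns) {
    if (length(p) != length(vis)) next
    lim <- 2 * pmax(tol$absolute_bp, tol$relative * p)
    if (all(abs(vis - p) <= lim)) return(TRUE)
  }
  FALSE
}

#' Generate a synthetic mitogenome-scale template
#'
#' A mitogenome-sized random background with one extended COI-COII-like
#' locus embedded, following the geometry of the real locus (820 bp
#' extended amplicon under the defaults). This is a synthetic stand-in for
#' a complete reference mitogenome, intended for exercising in silico PCR
#' at template scale; it does not mimic real A. mellifera base composition.
#'
#' @param seed Integer seed.
#' @param reg A `dmcc_registry`; the embedded locus is assembled from the
#'   registry's element exemplars at the default geometry (600 nt H2-E2
#'   window, 110 nt COI/COII pads).
#' @param genome_length Total length in nt (default 16343, mitogenome
#'   scale).
#' @param locus_start 0-based position of the extended locus (default
#'   3000).
#' @return List with `genome` (a `dmcc_seq`) and `truth` (the embedded
#'   template's truth record, coordinates shifted to the genome, plus
#'   `amplicon_start`, `amplicon_end`, `amplicon_length`).
#' @export
make_mitogenome <- function(seed, reg, genome_length = 16343L,
                            locus_start = 3000L) {
  stopifnot(inherits(reg, "dmcc_registry"))
  with_preserved_seed(seed, {
    tpl <- build_template(synth_spec(seed = seed), reg, id = "locus")
    ext_len <- tpl$template$length
    stopifnot(locus_start + ext_len <= genome_length)
    for (i in seq_len(200L)) {
      left_bg <- random_dna(locus_start)
      right_bg <- random_dna(genome_length - locus_start - ext_len)
      genome <- paste0(left_bg, tpl$template$residues, right_bg)
      ok <- TRUE
      for (nm in c("H2", "E2", "COI_Seq-F", "COII_Seq-R")) {
        p <- reg$primers[[nm]]
        if (is.null(p)) next
        if (nrow(find_primer_sites(genome, p, 1L)) != 1L) { ok <- FALSE; break }
      }
      if (ok) {
        truth <- tpl$truth
        truth$window_start <- truth$window_start + locus_start
        truth$window_end <- truth$window_end + locus_start
        truth$amplicon_start <- locus_start
        truth$amplicon_end <- locus_start + ext_len
        truth$amplicon_length <- ext_len
        return(list(
          genome = seq_record("synthetic_mitogenome", genome,
                              "synthetic C-lineage mitogenome stand-in"),
          truth = truth))
      }
    }
    stop("could not draw a clean mitogenome background", call. = FALSE)
  })
}

#' Write a batch of synthetic fixtures to disk
#'
#' Generates a registry and `n` extended templates (each copied from a
#' random registry entry with a few pattern-neutral planted SNPs), writing
#' `samples.fasta`, per-sample truth records in `truth.json` and
#' `registry.yaml` under `out_dir`.
#'
#' @param seed Integer seed.
#' @param n Number of samples.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with `registry`, `templates` and `truths`.
#' @export
write_fixtures <- function(seed, n, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  reg <- make_registry(seed)
  batch <- with_preserved_seed(seed + 1L, {
    lapply(seq_len(n), function(i) {
      synth_sample(reg, sample_seed = sample.int(2^28, 1L),
                   id = sprintf("sample%02d", i))
    })
  })
  templates <- lapply(batch, `[[`, "template")
  truths <- lapply(batch, `[[`, "truth")
  write_fasta(templates, file.path(out_dir, "samples.fasta"))
  write_registry(reg, file.path(out_dir, "registry.yaml"))
  jsonlite::write_json(truths, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(registry = reg, templates = templates, truths = truths))
}

# one extended sample copied from a random registry entry, with 0-3
# pattern-neutral SNPs planted at safe positions
synth_sample <- function(reg, sample_seed, id, n_snps = NULL) {
  with_preserved_seed(sample_seed, {
    hap <- sample(names(reg$haplotypes), 1L)
    ref <- reg$haplotypes[[hap]]$reference_sequence
    if (is.null(n_snps)) n_snps <- sample(0:3, 1L)
    snps <- draw_neutral_snps(ref, reg, n_snps)
    spec <- synth_spec(seed = sample.int(2^28, 1L), haplotype = hap,
                       snps = snps)
    make_template(spec, reg, id = id)
  })
}

# draw single-base substitutions that keep the recognition-site set intact
draw_neutral_snps <- function(ref, reg, n_snps, max_tries = 200L) {
  if (n_snps == 0L) return(list())
  enz <- reg$enzyme
  msz <- nchar(enz$recognition)
  L <- nchar(ref)
  sites <- find_sites(ref, enz)
  h2_len <- nchar(reg$primers$H2$sequence)
  e2_len <- nchar(reg$primers$E2$sequence)
  forbidden <- unique(c(seq_len(h2_len) - 1L, (L - e2_len):(L - 1L),
                        unlist(lapply(sites, function(s) s + 0:(msz - 1L)))))
  chars <- seq_chars(ref)
  snps <- list()
  taken <- integer(0)
  for (k in seq_len(n_snps)) {
    for (i in seq_len(max_tries)) {
      pos <- sample.int(L, 1L) - 1L
      if (pos %in% forbidden || pos %in% taken) next
      alt <- sample(setdiff(c("A", "C", "G", "T"), chars[pos + 1L]), 1L)
      cand <- chars
      cand[pos + 1L] <- alt
      if (!identical(find_sites(paste(cand, collapse = ""), enz), sites)) next
      chars <- cand
      snps[[length(snps) + 1L]] <- list(pos = pos, alt = alt)
      taken <- c(taken, pos)
      break
    }
  }
  snps
}
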