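# The haplotype registry: primers, enzyme, lineage length bins, matching
# tolerance and reference haplotype patterns.  YAML on disk, validated in
# full (including per-haplotype digest self-consistency) at load time.

LINEAGES <- c("A", "M", "C", "O")

#' Build a haplotype record
#'
#' @param name Haplotype name (e.g. `C1`, `C2`, `A2`, `Z1`).
#' @param lineage One of `A`, `M`, `C`, `O` (Z-prefixed haplotypes carry
#'   lineage A by DmCC convention).
#' @param subspecies_label Free text, e.g. `"A. m. carnica"`; may be empty.
#' @param expected_sizes Descending vector of gel-visible fragment lengths.
#' @param reference_sequence Optional trimmed H2-E2 IUPAC string.
#' @param accession Optional source accession token.
#' @return An object of class `dmcc_haplotype`.
#' @export
haplotype_record <- function(name, lineage, subspecies_label = "",
                             expected_sizes,
                             reference_sequence = NULL, accession = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!lineage %in% LINEAGES)
    stop(sprintf("haplotype '%s': lineage must be one of %s", name,
                 paste(LINEAGES, collapse = "/")), call. = FALSE)
  expected_sizes <- as.integer(expected_sizes)
  if (length(expected_sizes) == 0L || any(expected_sizes <= 0L))
    stop(sprintf("haplotype '%s': expected_sizes must be non-empty and positive",
                 name), call. = FALSE)
  if (is.unsorted(rev(expected_sizes), strictly = FALSE) ||
      any(diff(expected_sizes) > 0L))
    stop(sprintf("haplotype '%s': expected_sizes must be descending", name),
         call. = FALSE)
  if (!is.null(reference_sequence))
    reference_sequence <- normalize_residues(reference_sequence, id = name)
  structure(list(name = name, lineage = lineage,
                 subspecies_label = subspecies_label %||% "",
                 expected_sizes = expected_sizes,
                 reference_sequence = reference_sequence,
                 accession = accession),
            class = "dmcc_haplotype")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assemble a registry object
#'
#' Usually reached through [load_registry()]; exposed so the synthetic
#' fixture generator can build registries in memory. Runs full validation,
#' including the per-haplotype self-consistency check: digesting each
#' `reference_sequence` with the registry enzyme and applying
#' [visible_fragments()] at the registry `min_visible` must reproduce
#' `expected_sizes` exactly.
#'
#' @param primers Named list of [primer()] objects; must include `H2`
#'   and `E2`.
#' @param enzyme A [enzyme()] (DraI for the classical test).
#' @param lineage_bins Named list mapping lineage to an inclusive
#'   `c(lo, hi)` length interval for the trimmed H2-E2 amplicon.
#' @param haplotypes List of [haplotype_record()]s.
#' @param tolerance List with `absolute_bp` (nt) and `relative` (fraction);
#'   per-fragment tolerance is `max(absolute_bp, relative * expected)`.
#' @param min_visible Gel visibility threshold in nt.
#' @param elements Optional named character vector of element exemplar
#'   sequences (`tRNA_Leu`, `Q_fragment`, ...) for structure annotation.
#' @return An object of class `dmcc_registry`.
#' @export
registry <- function(primers, enzyme, lineage_bins, haplotypes,
                     tolerance = list(absolute_bp = 3L, relative = 0.02),
                     min_visible = 15L, elements = NULL) {
  stopifnot(inherits(enzyme, "dmcc_enzyme"))
  if (!all(vapply(primers, inherits, TRUE, "dmcc_primer")))
    stop("all registry primers must be primer() objects", call. = FALSE)
  if (!all(c("H2", "E2") %in% names(primers)))
    stop("registry primers must include H2 and E2", call. = FALSE)
  # lineage bins: known letters, inclusive, non-overlapping
  for (ln in names(lineage_bins)) {
    if (!ln %in% LINEAGES)
      stop("unknown lineage in lineage_bins: ", ln, call. = FALSE)
    b <- lineage_bins[[ln]]
    if (length(b) != 2L || b[1] > b[2])
      stop("lineage_bins[", ln, "] must be c(lo, hi) with lo <= hi",
           call. = FALSE)
  }
  if (length(lineage_bins) > 1L) {
    ord <- order(vapply(lineage_bins, `[`, 0, 1))
    bins <- lineage_bins[ord]
    for (i in seq_len(length(bins) - 1L)) {
      if (bins[[i]][2] >= bins[[i + 1L]][1])
        stop(sprintf("lineage_bins overlap: %s and %s",
                     names(bins)[i], names(bins)[i + 1L]), call. = FALSE)
    }
  }
  nms <- vapply(haplotypes, `[[`, "", "name")
  if (anyDuplicated(nms))
    stop("duplicate haplotype name(s): ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  reg <- structure(list(
    primers = primers, enzyme = enzyme,
    lineage_bins = lapply(lineage_bins, as.integer),
    haplotypes = stats::setNames(haplotypes, nms),
    tolerance = list(absolute_bp = as.integer(tolerance$absolute_bp %||% 3L),
                     relative = as.numeric(tolerance$relative %||% 0.02)),
    min_visible = as.integer(min_visible),
    elements = elements), class = "dmcc_registry")
  check_registry_consistency(reg)
  reg
}

# digest each reference_sequence and compare with expected_sizes
check_registry_consistency <- function(reg) {
  for (h in reg$haplotypes) {
    if (is.null(h$reference_sequence)) next
    d <- digest(seq_record(h$name, h$reference_sequence), reg$enzyme)
    got <- suppressWarnings(visible_fragments(d, reg$min_visible))
    if (!identical(as.integer(got), h$expected_sizes))
      stop(sprintf(
        paste0("registry self-consistency failure for haplotype '%s': ",
               "digest of reference gives [%s], expected_sizes are [%s]"),
        h$name, paste(got, collapse = ", "),
        paste(h$expected_sizes, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.dmcc_registry <- function(x, ...) {
  cat(sprintf("<dmcc_registry> %d haplotype(s), enzyme %s, primers: %s\n",
              length(x$haplotypes), x$enzyme$name,
              paste(names(x$primers), collapse = ", ")))
  for (h in x$haplotypes)
    cat(sprintf("  %-6s %s  [%s]  %s\n", h$name, h$lineage,
                paste(h$expected_sizes, collapse = ", "),
                h$subspecies_label))
  invisible(x)
}

#' Load and validate a haplotype registry from YAML
#'
#' The YAML schema has top-level keys `primers` (name: sequence), `enzyme`
#' (`name`, `recognition`, `cut_offset`, `palindromic`), `lineage_bins`
#' (lineage: `[lo, hi]`, inclusive), `tolerance` (`absolute_bp`,
#' `relative`), `min_visible`, optional `elements` (name: sequence) and
#' `haplotypes` (list of `name`, `lineage`, `subspecies_label`,
#' `expected_sizes`, optional `reference_sequence`, optional `accession`).
#' All validation of [registry()] runs, including reference-digest
#' self-consistency; failures abort naming the offending entry.
#'
#' @param path Path to the YAML registry file.
#' @return A validated `dmcc_registry`.
#' @export
load_registry <- function(path) {
  if (!file.exists(path)) stop("registry file not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  for (key in c("primers", "enzyme", "lineage_bins", "haplotypes")) {
    if (is.null(y[[key]]))
      stop("registry schema violation: missing top-level key '", key, "'",
           call. = FALSE)
  }
  primers <- mapply(primer, names(y$primers), unlist(y$primers),
                    SIMPLIFY = FALSE)
  enz <- enzyme(y$enzyme$name, y$enzyme$recognition, y$enzyme$cut_offset,
                y$enzyme$palindromic)
  haps <- lapply(y$haplotypes, function(h) {
    if (is.null(h$name) || is.null(h$lineage) || is.null(h$expected_sizes))
      stop("registry schema violation: each haplotype needs name, lineage ",
           "and expected_sizes", call. = FALSE)
    haplotype_record(h$name, h$lineage, h$subspecies_label %||% "",
                     h$expected_sizes, h$reference_sequence, h$accession)
  })
  elements <- if (!is.null(y$elements)) unlist(y$elements) else NULL
  registry(primers = primers, enzyme = enz,
           lineage_bins = y$lineage_bins, haplotypes = haps,
           tolerance = y$tolerance %||% list(absolute_bp = 3L, relative = 0.02),
           min_visible = y$min_visible %||% 15L,
           elements = elements)
}

#' Write a registry to YAML
#'
#' Inverse of [load_registry()]; the written file reloads to an identical
#' registry.
#'
#' @param reg A `dmcc_registry`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_registry <- function(reg, path) {
  stopifnot(inherits(reg, "dmcc_registry"))
  y <- list(
    primers = lapply(reg$primers, `[[`, "sequence"),
    enzyme = list(name = reg$enzyme$name,
                  recognition = reg$enzyme$recognition,
                  cut_offset = reg$enzyme$cut_offset,
                  palindromic = reg$enzyme$palindromic),
    lineage_bins = lapply(reg$lineage_bins, as.integer),
    tolerance = reg$tolerance,
    min_visible = reg$min_visible,
    haplotypes = lapply(unname(reg$haplotypes), function(h) {
      out <- list(name = h$name, lineage = h$lineage,
                  subspecies_label = h$subspecies_label,
                  expected_sizes = as.integer(h$expected_sizes))
      if (!is.null(h$reference_sequence))
        out$reference_sequence <- h$reference_sequence
      if (!is.null(h$accession)) out$accession <- h$accession
      out
    }))
  if (!is.null(reg$elements)) y$elements <- as.list(reg$elements)
  yaml::write_yaml(y, path)
  invisible(path)
}
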