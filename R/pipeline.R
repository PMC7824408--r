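# End-to-end DmCC pipeline: trim -> lineage -> digest -> visible fragments
# -> pattern match -> SNPs (-> structure), one TSV row per input record,
# plus a virtual gel of all sample lanes next to the registry references.

#' Pipeline run configuration
#'
#' @param fasta Input FASTA path (Sanger consensus amplicons or templates).
#' @param registry Registry YAML path, or a loaded `dmcc_registry`.
#' @param out Report TSV path, or `NULL` to skip writing.
#' @param gel Gel output path, or `NULL` to skip the gel.
#' @param gel_format `"svg"` or `"text"`.
#' @param max_mismatch Mismatch allowance for primer footprints (default 1).
#' @param min_visible Override of the registry gel-visibility threshold
#'   (`NULL` keeps the registry value); echoed in the report header.
#' @param tolerance_absolute_bp,tolerance_relative Overrides of the
#'   registry matching tolerance (`NULL` keeps registry values).
#' @param annotate_structure Also run structure annotation per sample.
#' @return An object of class `dmcc_run_config`.
#' @export
run_config <- function(fasta, registry, out = NULL, gel = NULL,
                       gel_format = c("svg", "text"), max_mismatch = 1L,
                       min_visible = NULL, tolerance_absolute_bp = NULL,
                       tolerance_relative = NULL,
                       annotate_structure = FALSE) {
  structure(list(fasta = fasta, registry = registry, out = out, gel = gel,
                 gel_format = match.arg(gel_format),
                 max_mismatch = as.integer(max_mismatch),
                 min_visible = min_visible,
                 tolerance_absolute_bp = tolerance_absolute_bp,
                 tolerance_relative = tolerance_relative,
                 annotate_structure = isTRUE(annotate_structure)),
            class = "dmcc_run_config")
}

# apply config overrides to a loaded registry, collecting echo lines
apply_overrides <- function(reg, config) {
  echoes <- character(0)
  if (!is.null(config$min_visible)) {
    reg$min_visible <- as.integer(config$min_visible)
    echoes <- c(echoes, paste0("min_visible=", reg$min_visible))
  }
  if (!is.null(config$tolerance_absolute_bp)) {
    reg$tolerance$absolute_bp <- as.integer(config$tolerance_absolute_bp)
    echoes <- c(echoes, paste0("tolerance_absolute_bp=",
                               reg$tolerance$absolute_bp))
  }
  if (!is.null(config$tolerance_relative)) {
    reg$tolerance$relative <- as.numeric(config$tolerance_relative)
    echoes <- c(echoes, paste0("tolerance_relative=", reg$tolerance$relative))
  }
  list(registry = reg, echoes = echoes)
}

#' Genotype one sequence record
#'
#' Runs the per-sample half of the pipeline: trim to the H2-E2 window,
#' classify lineage by trimmed length, digest, read the visible ladder,
#' match the fragment pattern, and (when the matched entry carries a
#' reference) report SNPs. A failed trim yields a call flagged `NO_WINDOW`
#' rather than an error, so batch runs continue past bad records.
#'
#' @param record A `dmcc_seq`.
#' @param reg A `dmcc_registry`.
#' @param max_mismatch Primer-footprint mismatch allowance (default 1).
#' @param annotate Also run [annotate_structure()].
#' @return A `dmcc_call` list: `sample_id`, `trimmed` (a `dmcc_seq` or
#'   `NULL`), `trimmed_length`, `lineage`, `haplotype`, `subspecies_label`,
#'   `distance`, `fragment_deltas`, `visible_sizes`, `snps` (data frame),
#'   `flags`, `structure` (data frame or `NULL`), `error` (message or
#'   `NA`).
#' @export
call_sample <- function(record, reg, max_mismatch = 1L, annotate = FALSE) {
  stopifnot(inherits(record, "dmcc_seq"), inherits(reg, "dmcc_registry"))
  call <- structure(list(
    sample_id = record$id, trimmed = NULL, trimmed_length = NA_integer_,
    lineage = "UNRESOLVED", haplotype = NA_character_,
    subspecies_label = "", distance = NA_real_,
    fragment_deltas = integer(0), visible_sizes = integer(0),
    snps = detect_snps(record, NULL), flags = character(0),
    structure = NULL, error = NA_character_), class = "dmcc_call")
  trimmed <- tryCatch(
    trim_to_window(record, reg$primers$H2, reg$primers$E2, max_mismatch),
    error = function(e) e)
  if (inherits(trimmed, "error")) {
    call$flags <- "NO_WINDOW"
    call$error <- conditionMessage(trimmed)
    return(call)
  }
  call$trimmed <- trimmed
  call$trimmed_length <- trimmed$length
  call$lineage <- classify_lineage(trimmed$length, reg)
  d <- digest(trimmed, reg$enzyme)
  vis <- suppressWarnings(visible_fragments(d, reg$min_visible))
  call$visible_sizes <- vis
  if (length(vis) == 0L) {
    call$haplotype <- "NOVEL"
    call$flags <- c(call$flags, "NOVEL_PATTERN")
    return(call)
  }
  m <- match_pattern(vis, reg)
  call$haplotype <- m$haplotype
  call$distance <- m$distance
  call$fragment_deltas <- m$fragment_deltas
  call$flags <- c(call$flags, m$flags)
  if (!is.null(m$record)) {
    call$subspecies_label <- m$record$subspecies_label
    if (m$record$lineage != call$lineage)
      call$flags <- c(call$flags, "LINEAGE_CONFLICT")
    call$snps <- detect_snps(trimmed, m$record$reference_sequence)
  }
  if (annotate)
    call$structure <- suppressWarnings(annotate_structure(trimmed, reg))
  call
}

#' @export
print.dmcc_call <- function(x, ...) {
  cat(sprintf("<dmcc_call> %s: lineage %s, haplotype %s%s\n", x$sample_id,
              x$lineage, x$haplotype %||% "NA",
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]")
              else ""))
  if (length(x$visible_sizes))
    cat("  visible fragments:", paste(x$visible_sizes, collapse = ", "), "\n")
  if (nrow(x$snps))
    cat("  SNPs/indels:", nrow(x$snps), "\n")
  invisible(x)
}

# format the SNP data frame for the report: 1-based pos:ref>alt, ";"-joined
format_snps <- function(snps) {
  if (is.null(snps) || nrow(snps) == 0L) return("")
  paste(vapply(seq_len(nrow(snps)), function(i) {
    sprintf("%d:%s>%s", snps$pos[i] + 1L, snps$ref[i], snps$alt[i])
  }, ""), collapse = ";")
}

calls_to_table <- function(calls) {
  data.frame(
    sample_id = vapply(calls, `[[`, "", "sample_id"),
    trimmed_length = vapply(calls, `[[`, NA_integer_, "trimmed_length"),
    lineage = vapply(calls, `[[`, "", "lineage"),
    haplotype = vapply(calls, function(c) c$haplotype %||% NA_character_, ""),
    subspecies = vapply(calls, `[[`, "", "subspecies_label"),
    distance = vapply(calls, `[[`, NA_real_, "distance"),
    fragment_lengths_desc = vapply(calls, function(c)
      paste(c$visible_sizes, collapse = ","), ""),
    n_snps = vapply(calls, function(c) nrow(c$snps), 0L),
    snps = vapply(calls, function(c) format_snps(c$snps), ""),
    flags = vapply(calls, function(c) paste(c$flags, collapse = ","), ""),
    stringsAsFactors = FALSE)
}

write_report <- function(calls, path, echoes = character(0)) {
  tab <- calls_to_table(calls)
  con <- file(path, open = "wb")   # binary: stable LF line endings
  on.exit(close(con))
  if (length(echoes) > 0L)
    writeLines(paste0("# override ", echoes), con, sep = "\n")
  writeLines(paste(colnames(tab), collapse = "\t"), con, sep = "\n")
  for (i in seq_len(nrow(tab))) {
    row <- unlist(lapply(tab[i, ], function(v)
      if (is.numeric(v) && !is.na(v) && v == as.integer(v))
        format(as.integer(v)) else format(v)))
    row[is.na(tab[i, ])] <- "NA"
    writeLines(paste(row, collapse = "\t"), con, sep = "\n")
  }
  invisible(path)
}

# reference + sample lanes mirroring the published virtual-gel layout:
# a C2-pattern ladder first (when present), then all registry references,
# then the samples
build_gel_lanes <- function(calls, reg) {
  lanes <- list()
  c2 <- grep("^C2", names(reg$haplotypes), value = TRUE)
  if (length(c2) > 0L)
    lanes[[length(lanes) + 1L]] <- gel_lane(
      paste0(c2[1], " ladder"), reg$haplotypes[[c2[1]]]$expected_sizes,
      is_ladder = TRUE)
  for (h in reg$haplotypes)
    lanes[[length(lanes) + 1L]] <- gel_lane(h$name, h$expected_sizes,
                                            is_ladder = TRUE)
  for (call in calls) {
    if (length(call$visible_sizes) == 0L) next
    lanes[[length(lanes) + 1L]] <- gel_lane(call$sample_id,
                                            call$visible_sizes)
  }
  lanes
}

#' Run the full in silico DmCC pipeline
#'
#' For every record in the input FASTA: trim to the H2-E2 window, classify
#' lineage, digest with the registry enzyme, match the visible fragment
#' pattern, report SNPs against the matched reference, and (optionally)
#' annotate structure. Per-sample failures never abort the run; they are
#' flagged (`NO_WINDOW`) in their report row. The report has one TSV row
#' per input record, and the gel shows all sample lanes beside the registry
#' reference lanes.
#'
#' @param config A [run_config()].
#' @return A list with `calls` (list of `dmcc_call`), `table` (the report
#'   as a data frame), `report` (TSV path or `NULL`), `gel` (path or
#'   `NULL`), and `exit_status` (0 when every sample produced a call —
#'   NOVEL counts as a call — 1 when some samples failed).
#' @export
run_dmcc <- function(config) {
  stopifnot(inherits(config, "dmcc_run_config"))
  reg <- if (inherits(config$registry, "dmcc_registry")) config$registry
         else load_registry(config$registry)
  ov <- apply_overrides(reg, config)
  reg <- ov$registry
  records <- read_fasta(config$fasta)
  calls <- lapply(records, call_sample, reg = reg,
                  max_mismatch = config$max_mismatch,
                  annotate = config$annotate_structure)
  stopifnot(length(calls) == length(records))  # one row per input, always
  if (!is.null(config$out)) write_report(calls, config$out, ov$echoes)
  gel_doc <- NULL
  if (!is.null(config$gel)) {
    lanes <- build_gel_lanes(calls, reg)
    gel_doc <- render_gel(lanes, gel_params(min_visible = reg$min_visible),
                          format = config$gel_format)
    con <- file(config$gel, open = "wb")
    writeChar(gel_doc, con, eos = NULL)
    close(con)
  }
  failed <- vapply(calls, function(c) "NO_WINDOW" %in% c$flags, TRUE)
  list(calls = calls, table = calls_to_table(calls),
       report = config$out, gel = config$gel,
       exit_status = if (any(failed)) 1L else 0L)
}
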