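# small hand-built registry used for matcher behaviour tests
mini_registry <- function(tol_abs = 5L, tol_rel = 0.02,
                          dup_pattern = FALSE) {
  haps <- list(
    haplotype_record("HA", "C", "alpha-like", c(400L, 150L, 50L)),
    haplotype_record("HB", "A", "beta-like", c(700L, 120L)))
  if (dup_pattern)
    haps <- c(haps, list(haplotype_record("HC", "C", "", c(400L, 150L, 50L))))
  registry(
    primers = list(H2 = primer("H2", "ACGTACGTACGTACGTACGT"),
                   E2 = primer("E2", "TGCATGCATGCATGCATGCA")),
    enzyme = enzyme_drai(),
    lineage_bins = list(C = c(500L, 650L), A = c(651L, 900L)),
    haplotypes = haps,
    tolerance = list(absolute_bp = tol_abs, relative = tol_rel),
    min_visible = 15L)
}

test_that("registry load validates schema, duplicates and self-consistency", {
  reg <- fixture_registry()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_registry(reg, path)
  back <- load_registry(path)
  expect_equal(names(back$haplotypes), names(reg$haplotypes))
  for (nm in names(reg$haplotypes))
    expect_equal(back$haplotypes[[nm]]$expected_sizes,
                 reg$haplotypes[[nm]]$expected_sizes)
  expect_equal(back$primers$H2$sequence, reg$primers$H2$sequence)

  # tamper with one entry's expected_sizes -> load error naming the entry
  y <- yaml::read_yaml(path)
  y$haplotypes[[2]]$expected_sizes[1] <- y$haplotypes[[2]]$expected_sizes[1] + 40L
  bad <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(y, bad)
  expect_error(load_registry(bad),
               paste0("self-consistency.*", y$haplotypes[[2]]$name))

  # duplicate names
  y2 <- yaml::read_yaml(path)
  y2$haplotypes[[2]]$name <- y2$haplotypes[[1]]$name
  y2$haplotypes[[2]]$reference_sequence <- y2$haplotypes[[1]]$reference_sequence
  y2$haplotypes[[2]]$expected_sizes <- y2$haplotypes[[1]]$expected_sizes
  dup <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(y2, dup)
  expect_error(load_registry(dup), "duplicate haplotype name")

  # missing top-level key
  y3 <- yaml::read_yaml(path)
  y3$enzyme <- NULL
  nk <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(y3, nk)
  expect_error(load_registry(nk), "missing top-level key 'enzyme'")
})

test_that("the shipped example registry loads and is self-consistent", {
  path <- system.file("extdata", "example_registry.yaml", package = "dmcc")
  reg <- load_registry(path)
  expect_gte(length(reg$haplotypes), 5L)
  expect_true(all(c("H2", "E2", "COI_Seq-F", "COII_Seq-R") %in%
                    names(reg$primers)))
})

test_that("lineage classification uses inclusive bins", {
  reg <- mini_registry()
  expect_equal(classify_lineage(560, reg), "C")
  expect_equal(classify_lineage(10, reg), "UNRESOLVED")
  expect_equal(classify_lineage(650, reg), "C")   # inclusive upper edge
  expect_equal(classify_lineage(651, reg), "A")
  expect_equal(classify_lineage(901, reg), "UNRESOLVED")
})

test_that("pattern matching: identity, tolerance, distance and NOVEL", {
  reg <- mini_registry(tol_abs = 5L)
  m <- match_pattern(c(400L, 150L, 50L), reg)
  expect_equal(m$haplotype, "HA")
  expect_equal(m$distance, 0)
  expect_length(m$flags, 0L)

  # each fragment perturbed by +2 within absolute tolerance 5
  m2 <- match_pattern(c(402L, 152L, 52L), reg)
  expect_equal(m2$haplotype, "HA")
  expect_equal(m2$distance, 2 * 3)
  expect_equal(m2$fragment_deltas, c(2L, 2L, 2L))

  # one extra fragment relative to every entry -> NOVEL
  m3 <- match_pattern(c(400L, 150L, 50L, 20L), reg)
  expect_equal(m3$haplotype, "NOVEL")
  expect_true("NOVEL_PATTERN" %in% m3$flags)
  expect_equal(m3$nearest, "HA")
  expect_equal(m3$distance, 20)   # the unpaired extra band

  # same count, out of tolerance -> NOVEL with the summed deviation
  m4 <- match_pattern(c(430L, 150L, 50L), reg)
  expect_equal(m4$haplotype, "NOVEL")
  expect_equal(m4$distance, 30)

  expect_error(match_pattern(integer(0), reg), "empty observed")
})

test_that("exact ties break alphabetically and carry AMBIGUOUS_TIE", {
  reg <- mini_registry(dup_pattern = TRUE)
  m <- match_pattern(c(400L, 150L, 50L), reg)
  expect_equal(m$haplotype, "HA")   # HA < HC
  expect_true("AMBIGUOUS_TIE" %in% m$flags)
})

test_that("SNP detection reports substitutions and indel runs in reference coordinates", {
  reg <- fixture_registry()
  ref <- reg$haplotypes$C1$reference_sequence

  expect_equal(nrow(detect_snps(seq_record("q", ref), ref)), 0L)

  # planted substitution at 0-based position 137
  chars <- strsplit(ref, "")[[1]]
  old <- chars[138]
  chars[138] <- setdiff(c("A", "C", "G", "T"), old)[1]
  snps <- detect_snps(seq_record("q", paste(chars, collapse = "")), ref)
  expect_equal(nrow(snps), 1L)
  expect_equal(snps$pos, 137L)
  expect_equal(snps$type, "SNP")
  expect_equal(snps$ref, old)
  expect_equal(snps$alt, chars[138])

  # planted 3-nt deletion: removing reference bases 201..203 (1-based)
  del <- paste0(substr(ref, 1, 200), substr(ref, 204, nchar(ref)))
  rows <- detect_snps(seq_record("q", del), ref)
  expect_equal(nrow(rows), 1L)
  expect_equal(rows$type, "DEL")
  expect_equal(rows$length, 3L)
  expect_equal(rows$pos, 200L)
  expect_equal(rows$ref, substr(ref, 201, 203))

  # planted insertion; the aligner may report an equivalent shifted
  # placement, so assert that removing the reported run restores the
  # reference rather than the exact inserted string
  ins <- paste0(substr(ref, 1, 300), "GGCC", substr(ref, 301, nchar(ref)))
  rows2 <- detect_snps(seq_record("q", ins), ref)
  expect_equal(rows2$type, "INS")
  expect_equal(rows2$length, 4L)
  restored <- paste0(substr(ins, 1, rows2$pos),
                     substr(ins, rows2$pos + 5L, nchar(ins)))
  expect_equal(restored, ref)

  # no reference: empty result with a note, never an error
  none <- detect_snps(seq_record("q", ref), NULL)
  expect_equal(nrow(none), 0L)
  expect_match(attr(none, "note"), "no reference")
})

test_that("structure annotation recovers elements at construction coordinates", {
  reg <- fixture_registry()
  w <- make_template(synth_spec(3, fill = "exemplar",
                                include_extended_pads = FALSE),
                     reg, id = "w")$template
  ann <- annotate_structure(w, reg)
  h2_len <- nchar(reg$primers$H2$sequence)
  expect_equal(ann$element[1:3], c("COI_3prime", "tRNA_Leu", "Q_fragment"))
  expect_equal(ann$start[1], h2_len)
  expect_equal(ann$end[1], h2_len + 60L)
  expect_equal(ann$start[2], h2_len + 60L)
  expect_equal(ann$end[2], h2_len + 130L)
  expect_equal(ann$start[3], h2_len + 130L)
  expect_equal(ann$end[3], h2_len + 380L)
  expect_true(all(diff(ann$start) > 0))
  # non-overlap invariant
  expect_true(all(ann$start[-1] >= ann$end[-nrow(ann)]))
})

test_that("an element replaced by random sequence is omitted; mutated elements are still found", {
  reg <- fixture_registry()
  w <- make_template(synth_spec(3, fill = "exemplar",
                                include_extended_pads = FALSE),
                     reg, id = "w")$template
  h2_len <- nchar(reg$primers$H2$sequence)
  withr::local_seed(61)
  chars <- strsplit(w$residues, "")[[1]]
  # replace the Q fragment span with random bases (no accidental sites)
  repeat {
    cand <- chars
    cand[(h2_len + 130L + 1L):(h2_len + 380L)] <-
      strsplit(rand_dna(250), "")[[1]]
    if (length(find_sites(paste(cand, collapse = ""), reg$enzyme)) == 0L) break
  }
  noq <- seq_record("noq", paste(cand, collapse = ""))
  ann <- annotate_structure(noq, reg)
  expect_false("Q_fragment" %in% ann$element)
  expect_true("Q_fragment" %in% attr(ann, "omitted"))
  expect_true(all(c("COI_3prime", "tRNA_Leu") %in% ann$element))

  # 10% substitutions in tRNA-Leu, identity threshold 0.8 -> still located
  mut <- chars
  span <- (h2_len + 60L + 1L):(h2_len + 130L)
  picks <- sample(span, 7)
  for (p in picks) mut[p] <- setdiff(c("A", "C", "G", "T"), mut[p])[1]
  ann2 <- annotate_structure(seq_record("mut", paste(mut, collapse = "")), reg)
  trna <- ann2[ann2$element == "tRNA_Leu", ]
  expect_equal(nrow(trna), 1L)
  expect_lte(abs(trna$start - (h2_len + 60L)), 3L)
  expect_lte(abs(trna$end - (h2_len + 130L)), 3L)
})
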