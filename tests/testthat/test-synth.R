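test_that("template generation is deterministic and its truth is oracle-exact", {
  reg <- fixture_registry()
  spec <- synth_spec(seed = 7, planted_drai_offsets = c(160L, 330L))
  a <- make_template(spec, reg, id = "t")
  b <- make_template(spec, reg, id = "t")
  expect_identical(a$template$residues, b$template$residues)
  expect_identical(a$truth, b$truth)

  # cut arithmetic: planted offsets + cut offset 3
  expect_equal(a$truth$cut_offsets, c(163L, 333L))
  window <- substr(a$template$residues, a$truth$window_start + 1,
                   a$truth$window_end)
  expect_equal(a$truth$fragments, oracle_digest_lengths(window, "TTTAAA", 3L))
  expect_equal(sum(a$truth$fragments), a$truth$window_length)
  expect_equal(a$truth$visible_sizes,
               sort(a$truth$fragments[a$truth$fragments >= reg$min_visible],
                    decreasing = TRUE))
})

test_that("the generator never emits unplanted recognition sites", {
  reg <- fixture_registry()
  withr::local_seed(67)
  for (i in 1:20) {
    n_sites <- sample(1:3, 1)
    offs <- sort(sample(seq(160L, 380L, by = 12L), n_sites))
    if (n_sites > 1 && any(diff(offs) < 6L)) next
    tpl <- make_template(synth_spec(seed = 1000L + i,
                                    planted_drai_offsets = offs), reg)
    sites <- find_sites(tpl$template, reg$enzyme)
    expect_equal(sites, offs + tpl$truth$window_start,
                 info = paste("seed", 1000L + i))
  }
})

test_that("impossible specs are rejected", {
  reg <- fixture_registry()
  expect_error(synth_spec(1, planted_drai_offsets = c(100L, 103L)),
               "overlap")
  expect_error(make_template(synth_spec(1, planted_drai_offsets = 10L), reg),
               "Q region")
  expect_error(make_template(synth_spec(1, window_length = 300L), reg),
               "too short")
  expect_error(
    make_template(synth_spec(1, haplotype = "C2",
                             snps = list(list(pos = 2L, alt = "G"))), reg),
    "primer footprint|recognition site")
})

test_that("planted SNPs are recorded in the truth and recovered by detect_snps", {
  reg <- fixture_registry()
  ref <- reg$haplotypes$C3$reference_sequence
  snps <- dmcc:::with_preserved_seed(71,
    dmcc:::draw_neutral_snps(ref, reg, 3L))
  expect_length(snps, 3L)
  tpl <- make_template(synth_spec(5, haplotype = "C3", snps = snps), reg)
  expect_equal(nrow(tpl$truth$snps), 3L)
  trimmed <- trim_to_window(tpl$template, reg$primers$H2, reg$primers$E2)
  found <- detect_snps(trimmed, ref)
  expect_equal(found$pos, sort(tpl$truth$snps$pos))
  expect_equal(found$alt,
               tpl$truth$snps$alt[order(tpl$truth$snps$pos)])
  # pattern-neutral: the haplotype call is unchanged
  m <- match_pattern(visible_fragments(digest(trimmed, reg$enzyme),
                                       reg$min_visible), reg)
  expect_equal(m$haplotype, "C3")
})

test_that("synthetic registries have separated, self-consistent patterns", {
  reg <- make_registry(99)
  expect_length(reg$haplotypes, 5L)
  pats <- lapply(reg$haplotypes, `[[`, "expected_sizes")
  nms <- names(pats)
  for (i in seq_along(pats)) for (j in seq_len(i - 1L)) {
    a <- pats[[i]]; b <- pats[[j]]
    if (length(a) != length(b)) next
    lim <- 2 * pmax(reg$tolerance$absolute_bp, reg$tolerance$relative * b)
    expect_false(all(abs(a - b) <= lim), info = paste(nms[i], nms[j]))
  }
  # digest of each reference reproduces its expected sizes
  for (h in reg$haplotypes) {
    d <- digest(seq_record(h$name, h$reference_sequence), reg$enzyme)
    expect_equal(visible_fragments(d, reg$min_visible), h$expected_sizes)
    # lineage bin agrees with the entry lineage
    expect_equal(classify_lineage(nchar(h$reference_sequence), reg),
                 h$lineage)
  }
  expect_error(make_registry(1, n_haplotypes = 1L), "n_haplotypes")
})

test_that("the synthetic mitogenome carries exactly one extended locus", {
  reg <- fixture_registry()
  mg <- make_mitogenome(13, reg)
  expect_equal(mg$genome$length, 16343L)
  expect_equal(mg$truth$amplicon_length, 820L)
  amps <- amplify(mg$genome, reg$primers[["COI_Seq-F"]],
                  reg$primers[["COII_Seq-R"]])
  expect_length(amps, 1L)
  expect_equal(amps[[1]]$start, mg$truth$amplicon_start)
  expect_equal(amps[[1]]$length, 820L)
  # determinism
  mg2 <- make_mitogenome(13, reg)
  expect_identical(mg$genome$residues, mg2$genome$residues)
})

test_that("write_fixtures emits FASTA, truth JSON and registry that reload", {
  dir <- withr::local_tempdir()
  out <- write_fixtures(seed = 21, n = 3, out_dir = dir)
  expect_true(file.exists(file.path(dir, "samples.fasta")))
  expect_true(file.exists(file.path(dir, "truth.json")))
  expect_true(file.exists(file.path(dir, "registry.yaml")))
  reg <- load_registry(file.path(dir, "registry.yaml"))
  recs <- read_fasta(file.path(dir, "samples.fasta"))
  truths <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_length(recs, 3L)
  expect_length(truths, 3L)
  expect_equal(vapply(truths, function(t) t$sample_id, ""),
               vapply(recs, `[[`, "", "id"), ignore_attr = TRUE)
})
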