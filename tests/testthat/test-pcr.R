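coi_f <- primer("COI_Seq-F", "ACCACCTCTAGATCATTCACATTT")
coii_r <- primer("COII_Seq-R", "AGGATGGAACTGTTCATGAATGAA")

# deterministic clean background with a payload planted at a given offset
plant <- function(background_n, payloads, seed = 1) {
  withr::local_seed(seed, .local_envir = parent.frame())
  repeat {
    chars <- strsplit(rand_dna(background_n), "")[[1]]
    for (p in payloads)
      chars[p$at + seq_len(nchar(p$seq))] <- strsplit(p$seq, "")[[1]]
    template <- paste(chars, collapse = "")
    seqs <- vapply(payloads, `[[`, "", "seq")
    ok <- all(vapply(unique(seqs), function(s)
      nrow(oracle_primer_scan(template, s, 1L)) == sum(seqs == s), TRUE))
    if (ok) return(template)
  }
}

test_that("a planted primer site is recovered exactly", {
  tpl <- plant(50, list(list(seq = coi_f$sequence, at = 13)))
  hits <- find_primer_sites(seq_record("t", tpl), coi_f, max_mismatch = 0)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$strand, "+")
  expect_equal(hits$start, 13L)
  expect_equal(hits$end, 37L)
  expect_equal(hits$mismatches, 0L)
})

test_that("the mismatch threshold is a sharp boundary", {
  tpl <- plant(50, list(list(seq = coi_f$sequence, at = 13)))
  mutated <- coi_f$sequence
  substr(mutated, 5, 5) <- if (substr(mutated, 5, 5) == "A") "C" else "A"
  p1 <- primer("mut", mutated)
  expect_equal(nrow(find_primer_sites(seq_record("t", tpl), p1, 0)), 0L)
  hits <- find_primer_sites(seq_record("t", tpl), p1, 1)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$mismatches, 1L)
})

test_that("multiple planted sites are all reported, sorted by start", {
  tpl <- plant(80, list(list(seq = coi_f$sequence, at = 5),
                        list(seq = coi_f$sequence, at = 40)), seed = 3)
  hits <- find_primer_sites(seq_record("t", tpl), coi_f, 0)
  expect_equal(hits$start, c(5L, 40L))
})

test_that("find_primer_sites agrees with the naive per-position oracle", {
  withr::local_seed(17)
  for (i in 1:12) {
    n <- sample(60:2000, 1)
    tpl <- rand_dna(n)
    mm <- sample(0:2, 1)
    got <- find_primer_sites(seq_record("t", tpl), coii_r, mm)
    want <- oracle_primer_scan(tpl, coii_r$sequence, mm)
    expect_equal(got$start, want$start, info = paste("case", i))
    expect_equal(got$strand, want$strand, info = paste("case", i))
    expect_equal(got$mismatches, want$mismatches, info = paste("case", i))
  }
})

test_that("a template shorter than the primer warns and yields no hits", {
  expect_warning(hits <- find_primer_sites(seq_record("t", "ACGTACGTAC"),
                                           coi_f, 1),
                 "shorter than")
  expect_equal(nrow(hits), 0L)
})

test_that("amplification of a planted 1000-nt template yields the 820 bp product", {
  tpl <- plant(1000, list(list(seq = coi_f$sequence, at = 100),
                          list(seq = oracle_revcomp(coii_r$sequence),
                               at = 896)), seed = 7)
  amps <- amplify(seq_record("t", tpl), coi_f, coii_r, max_mismatch = 0)
  expect_length(amps, 1L)
  expect_equal(amps[[1]]$length, 820L)
  expect_equal(amps[[1]]$start, 100L)
  expect_equal(amps[[1]]$end, 920L)
  expect_equal(amps[[1]]$sequence, substr(tpl, 101, 920))
})

test_that("a missing reverse site is diagnosed by primer name", {
  tpl <- plant(300, list(list(seq = coi_f$sequence, at = 30)), seed = 9)
  amps <- amplify(seq_record("t", tpl), coi_f, coii_r)
  expect_length(amps, 0L)
  expect_match(attr(amps, "diagnosis"), "COII_Seq-R")
  expect_equal(attr(amps, "failed_primers"), "COII_Seq-R")
})

test_that("all forward/reverse hit pairs are enumerated, sorted by length", {
  withr::local_seed(23)
  # two forward sites, one reverse site
  repeat {
    chars <- strsplit(rand_dna(700), "")[[1]]
    chars[50 + 1:24] <- strsplit(coi_f$sequence, "")[[1]]
    chars[300 + 1:24] <- strsplit(coi_f$sequence, "")[[1]]
    chars[600 + 1:24] <- strsplit(oracle_revcomp(coii_r$sequence), "")[[1]]
    tpl <- paste(chars, collapse = "")
    if (nrow(oracle_primer_scan(tpl, coi_f$sequence, 0)) == 2L &&
        nrow(oracle_primer_scan(tpl, coii_r$sequence, 0)) == 1L) break
  }
  amps <- amplify(seq_record("t", tpl), coi_f, coii_r, max_mismatch = 0)
  expect_length(amps, 2L)
  lens <- vapply(amps, `[[`, 0L, "length")
  expect_equal(lens, sort(lens))
  expect_equal(sort(vapply(amps, `[[`, 0L, "start")), c(50L, 300L))
  # slice-equality invariant
  for (a in amps)
    expect_equal(a$sequence, substr(tpl, a$start + 1, a$end))
})

test_that("trimming recovers a planted H2-E2 window exactly and is idempotent", {
  reg <- fixture_registry()
  tpl <- make_template(synth_spec(seed = 31, pad_length = 54), reg, id = "w")
  truth <- tpl$truth
  window <- substr(tpl$template$residues, truth$window_start + 1,
                   truth$window_end)
  expect_equal(nchar(window), 600L)
  trimmed <- trim_to_window(tpl$template, reg$primers$H2, reg$primers$E2)
  expect_equal(trimmed$residues, window)
  # fixed point
  again <- trim_to_window(trimmed, reg$primers$H2, reg$primers$E2)
  expect_equal(again$residues, trimmed$residues)
  # orientation-insensitive: reverse-complemented input, same window out
  rc_in <- seq_record("w_rc", revcomp(tpl$template$residues))
  rc_trim <- trim_to_window(rc_in, reg$primers$H2, reg$primers$E2)
  expect_equal(rc_trim$residues, window)
})

test_that("trim failures are explicit: missing primer and ambiguous windows", {
  reg <- fixture_registry()
  withr::local_seed(37)
  expect_error(
    trim_to_window(seq_record("bad", rand_dna(400)),
                   reg$primers$H2, reg$primers$E2),
    "window not found.*H2.*E2")
  # duplicate the window -> two distinct candidate windows -> hard error
  tpl <- make_template(synth_spec(seed = 41), reg, id = "w")$template
  doubled <- seq_record("dd", paste0(tpl$residues, tpl$residues))
  expect_error(trim_to_window(doubled, reg$primers$H2, reg$primers$E2),
               "multiple candidate")
})
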