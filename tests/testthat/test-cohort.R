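test_that("depth-corrected frequencies follow the stated combining rule", {
  # one patient, clones A:3 and B:1
  one <- rbind(cohort_row("P1", "(CAG)47", 3L), cohort_row("P1", "(CAG)46", 1L))
  f1 <- depth_corrected_frequencies(one)
  expect_equal(f1$overall_pct[f1$pattern == "(CAG)47"], 75)
  expect_equal(f1$overall_pct[f1$pattern == "(CAG)46"], 25)

  # two patients: {A:1} and {A:1, B:1} -> A 75%, B 25% (equal patient weight)
  two <- rbind(cohort_row("P1", "(CAG)47", 1L),
               cohort_row("P2", "(CAG)47", 1L),
               cohort_row("P2", "(CAG)46", 1L))
  f2 <- depth_corrected_frequencies(two)
  expect_equal(f2$overall_pct[f2$pattern == "(CAG)47"], 75)
  expect_equal(f2$overall_pct[f2$pattern == "(CAG)46"], 25)
})

test_that("depth-corrected frequencies always sum to 100", {
  set.seed(707)
  for (i in 1:20) {
    n_pat <- sample(2:6, 1)
    rows <- do.call(rbind, lapply(seq_len(n_pat), function(j) {
      n_seq <- sample(1:5, 1)
      do.call(rbind, lapply(seq_len(n_seq), function(k)
        cohort_row(sprintf("P%d", j), format_notation(random_pattern()),
                   sample(1:20, 1))))
    }))
    expect_equal(sum(depth_corrected_frequencies(rows)$overall_pct), 100,
                 tolerance = 1e-9)
  }
})

test_that("mean allele size is the clone-weighted mean with threshold filtering", {
  df <- rbind(cohort_row("P1", "(CAG)48", 2L), cohort_row("P1", "(CAG)47", 2L))
  expect_equal(mean_allele_size(df, "P1", "pathogenic", "total"), 47.5)

  single <- cohort_row("P1", "(CAG)50", 1L)
  expect_equal(mean_allele_size(single, "P1", "pathogenic", "total"), 50)

  # sub-threshold pathogenic clones (slippage artefacts) are excluded
  with_slip <- rbind(cohort_row("P1", "(CAG)48", 9L),
                     cohort_row("P1", "(CAG)20", 1L))
  expect_equal(mean_allele_size(with_slip, "P1", "pathogenic", "total"), 48)
  expect_error(mean_allele_size(cohort_row("P1", "(CAG)20", 5L), "P1",
                                "pathogenic", "total"),
               "at or above")
  expect_error(mean_allele_size(df, "P2", "pathogenic", "total"), "no .* clones")
})

test_that("mean allele size matches a brute-force weighted mean", {
  set.seed(808)
  for (i in 1:30) {
    n_seq <- sample(2:5, 1)
    pats <- replicate(n_seq, random_pattern(), simplify = FALSE)
    counts <- sample(1:10, n_seq, replace = TRUE)
    df <- do.call(rbind, lapply(seq_len(n_seq), function(k)
      cohort_row("P1", format_notation(pats[[k]]), counts[k],
                 allele_label = "normal")))
    # brute force: replicate each clone and average
    totals <- rep(vapply(pats, total_repeats, 0L), counts)
    longests <- rep(vapply(pats, longest_pure_run, 0L), counts)
    expect_equal(mean_allele_size(df, "P1", "normal", "total"), mean(totals))
    expect_equal(mean_allele_size(df, "P1", "normal", "longest"),
                 mean(longests))
    expect_lte(mean_allele_size(df, "P1", "normal", "longest"),
               mean_allele_size(df, "P1", "normal", "total"))
  }
})

test_that("a single interrupted clone is an artifact suspect, not interruption", {
  lone <- rbind(cohort_row("P7", "(CAG)48", 18L),
                cohort_row("P7", "(CAG)35(CAT)(CAG)(CAT)(CAG)12", 1L))
  st <- patient_interruption_status(lone, "P7")
  expect_false(st$interrupted)
  expect_true(st$artifact_suspect)
  expect_identical(st$n_interrupted_clones, 1L)

  # all pathogenic clones interrupted: clearly an interrupted allele
  real <- rbind(cohort_row("P1", "(CAG)51(CAT)(CAG)(CAT)(CAG)10", 4L),
                cohort_row("P1", "(CAG)53(CAT)(CAG)(CAT)(CAG)10", 3L))
  expect_true(interrupted_patient_flag(real, "P1"))

  pure <- cohort_row("P9", "(CAG)44", 10L)
  st2 <- patient_interruption_status(pure, "P9")
  expect_false(st2$interrupted)
  expect_false(st2$artifact_suspect)

  # two interrupted clones pass the default threshold even in a deep library
  pair <- rbind(cohort_row("P2", "(CAG)48", 30L),
                cohort_row("P2", "(CAG)40(CAT)(CAG)(CAT)(CAG)10", 2L))
  expect_true(interrupted_patient_flag(pair, "P2"))
})

test_that("transmission events carry size and interruption labels", {
  # interrupted allele contracting to a pure tract on maternal transmission
  ev <- classify_transmission(53, TRUE, 48, FALSE)
  expect_setequal(ev$labels, c("contraction", "interruption_loss"))
  expect_identical(ev$delta_total, -5L)

  ev2 <- classify_transmission(47, FALSE, 50, FALSE)
  expect_setequal(ev2$labels, "expansion")
  expect_identical(ev2$delta_total, 3L)

  ev3 <- classify_transmission(48, FALSE, 48, FALSE)
  expect_setequal(ev3$labels, "stable_length")
  expect_identical(ev3$delta_total, 0L)

  expect_error(classify_transmission(0, FALSE, 48, FALSE), "positive")
})

test_that("transmission classification is antisymmetric under parent/child swap", {
  set.seed(909)
  for (i in 1:50) {
    a <- sample(39:80, 1); b <- sample(39:80, 1)
    ia <- sample(c(TRUE, FALSE), 1); ib <- sample(c(TRUE, FALSE), 1)
    fwd <- classify_transmission(a, ia, b, ib)
    rev <- classify_transmission(b, ib, a, ia)
    expect_identical(fwd$delta_total, -rev$delta_total)
    expect_identical("expansion" %in% fwd$labels, "contraction" %in% rev$labels)
    expect_identical("interruption_loss" %in% fwd$labels,
                     "interruption_gain" %in% rev$labels)
  }
})

test_that("threshold tally matches a hand count in both conventions", {
  df <- rbind(
    cohort_row("P1", "(CAG)47", 5L),                          # pure, above
    cohort_row("P1", "(CAG)30", 1L, allele_label = "normal"), # pure, below
    cohort_row("P2", "(CAG)40(CAT)(CAG)(CAT)(CAG)10", 2L),    # int, above (52)
    cohort_row("P2", "(CAG)12(CAT)(CAG)(CAT)(CAG)14", 4L,     # int, below (29)
               allele_label = "normal"),
    cohort_row("P2", "(CAG)47", 3L)                           # duplicate of P1's
  )
  tt <- threshold_tally(df)
  # distinct sequences: 4 unique (the two (CAG)47 rows collapse)
  expect_identical(sum(tt$distinct$counts), 4)
  expect_identical(tt$distinct$counts["uninterrupted", "at_or_above"], 1)
  expect_identical(tt$distinct$counts["uninterrupted", "below_threshold"], 1)
  expect_identical(tt$distinct$counts["interrupted", "at_or_above"], 1)
  expect_identical(tt$distinct$counts["interrupted", "below_threshold"], 1)
  # clone-weighted: 15 clones total
  expect_identical(sum(tt$weighted$counts), 15)
  expect_identical(tt$weighted$counts["uninterrupted", "at_or_above"], 8)
  expect_equal(tt$weighted$row_pct["interrupted", "below_threshold"],
               100 * 4 / 6)

  all_above <- rbind(cohort_row("P1", "(CAG)47", 5L),
                     cohort_row("P2", "(CAG)40", 2L))
  tt2 <- threshold_tally(all_above)
  expect_equal(tt2$distinct$row_pct["uninterrupted", "at_or_above"], 100)
})

test_that("cohort summary JSON is written and re-readable", {
  df <- rbind(cohort_row("P1", "(CAG)47", 5L),
              cohort_row("P1", "(CAG)30", 1L, allele_label = "normal"))
  tmp <- tempfile(fileext = ".json")
  write_cohort_summary(df, tmp)
  report <- jsonlite::read_json(tmp)
  expect_identical(report$n_patients, 1L)
  expect_identical(report$n_clones, 6L)
})

test_that("cohort TSV round-trips through read/write with schema checks", {
  df <- rbind(cohort_row("P1", "(CAG)47", 5L, onset_age = 40, sized_repeat = 44),
              cohort_row("P1", "(CAG)30", 1L, allele_label = "normal",
                         onset_age = 40, sized_repeat = 44))
  tmp <- tempfile(fileext = ".tsv")
  write_cohort(df, tmp)
  back <- read_cohort(tmp)
  expect_equal(back$pattern, df$pattern)
  expect_equal(back$n_clones, df$n_clones)

  bad <- df
  bad$allele_label[1] <- "upper"
  expect_error(validate_cohort(bad), "allele_label")
  bad2 <- df[, setdiff(names(df), "onset_age")]
  expect_error(validate_cohort(bad2), "missing column")
  bad3 <- df
  bad3$pattern[2] <- "(CAG)x"
  expect_error(validate_cohort(bad3), "row 2")
})
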