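test_that("pure tandem arrays are recovered exactly", {
  h <- find_tandem_repeats(paste(rep("ACGATTGGCTAAGCTTACGA", 4),
                                 collapse = ""), min_score = 30)
  expect_equal(nrow(h), 1L)
  expect_equal(h$period, 20L)
  expect_equal(h$copy_number, 4.0)
  expect_equal(h$identity, 100)
  expect_equal(h$consensus, "ACGATTGGCTAAGCTTACGA")
  expect_equal(c(h$start, h$end), c(1L, 80L))
  expect_error(find_tandem_repeats(""), "empty")
})

test_that("a short motif planted in random background is pinpointed", {
  set.seed(7)
  bg1 <- paste(sample(c("A", "C", "G", "T"), 150, TRUE), collapse = "")
  bg2 <- paste(sample(c("A", "C", "G", "T"), 120, TRUE), collapse = "")
  seqn <- paste0(bg1, strrep("ACG", 20), bg2)
  h <- find_tandem_repeats(seqn, min_score = 30)
  h <- h[h$score == max(h$score), ][1, ]
  expect_equal(h$period, 3L)
  expect_equal(h$consensus, "ACG")
  # span may rope in a few chance-matching background bases, never more
  expect_lt(abs(h$copy_number - 20), 1)
  expect_lte(abs(h$start - 151L), 2L)
})

test_that("mutated control-region arrays are found at the published threshold", {
  cr <- generate_control_region(seed = 101)
  hits <- find_tandem_repeats(cr$seq, min_score = 30)
  for (i in seq_len(nrow(cr$truth))) {
    tr <- cr$truth[i, ]
    match_hit <- hits[abs(hits$period - tr$period) <= 2, ]
    expect_gte(nrow(match_hit), 1L)
    # locus agrees with the planted array
    expect_lte(abs(match_hit$start[1] - tr$start), tr$period)
  }
})

test_that("reported scores are reproducible by re-aligning the span", {
  set.seed(19)
  for (i in 1:5) {
    cr <- generate_control_region(seed = 200 + i, cr_length = 900L,
                                  cr_repeats = list(list(period = 25L,
                                                         copies = 6L,
                                                         mutation = 0.05)))
    hits <- find_tandem_repeats(cr$seq, min_score = 30)
    for (j in seq_len(nrow(hits)))
      expect_equal(rescore_hit(cr$seq, hits[j, ]), hits$score[j])
  }
})

test_that("detector matches the exhaustive (period, phase) oracle on short sequences", {
  set.seed(37)
  for (i in 1:12) {
    p <- sample(3:12, 1)
    copies <- sample(3:6, 1)
    mut <- sample(c(0, 0.03, 0.05), 1)
    pad <- sample(5:15, 1)
    bg <- paste(sample(c("A", "C", "G", "T"), pad, TRUE), collapse = "")
    arr <- generate_control_region(seed = 500 + i,
                                   cr_length = p * copies + 2L * pad + 2L,
                                   cr_repeats = list(list(period = p,
                                                          copies = copies,
                                                          mutation = mut)))
    seqn <- arr$seq
    expect_lte(nchar(seqn), 200L)
    ora <- oracle_best_repeat(seqn, pmax = 20)
    det <- find_tandem_repeats(seqn, min_score = 30, period_range = c(2, 20))
    if (ora$score >= 30) {
      expect_gte(nrow(det), 1L)
      expect_gte(max(det$score), ora$score)
    }
  }
})

test_that("detection is rotation-invariant on circular sequences", {
  cr <- generate_control_region(seed = 61, cr_length = 600L,
                                cr_repeats = list(list(period = 20L,
                                                       copies = 5L,
                                                       mutation = 0)))
  base <- find_tandem_repeats(cr$seq, min_score = 30, circular = TRUE)
  rot <- paste0(substr(cr$seq, 301, 600), substr(cr$seq, 1, 300))
  moved <- find_tandem_repeats(rot, min_score = 30, circular = TRUE)
  expect_equal(nrow(base), nrow(moved))
  expect_equal(sort(base$period), sort(moved$period))
  expect_equal(sort(base$score), sort(moved$score))
})

test_that("repeat_report restricts to the control region unless told otherwise", {
  rec <- generate_genome(synthetic_genome_spec(seed = 71))
  cr_feat <- rec$features[rec$features$feature_class == "CR", ]
  rep_cr <- repeat_report(rec, min_score = 30)
  expect_true(all(rep_cr$region == "CR"))
  # CR-relative coordinates stay inside the CR span
  cr_len <- cr_feat$stop - cr_feat$start + 1L
  expect_true(all(rep_cr$start >= 1 & rep_cr$end <= cr_len))
  truth <- attr(rec, "truth")$repeats
  expect_true(all(vapply(truth$period, function(p)
    any(abs(rep_cr$period - p) <= 2), logical(1))))
  # repeat-free CR gives an empty table
  clean <- generate_genome(synthetic_genome_spec(seed = 72,
                                                 cr_repeats = list()))
  expect_equal(nrow(repeat_report(clean, min_score = 30)), 0L)
  # genome-wide flag labels out-of-CR hits
  gw <- repeat_report(rec, min_score = 30, genome_wide = TRUE)
  expect_true(all(gw$region %in% c("CR", "genome")))
  no_cr <- mitogenome_record("x", gene_feature("g", "tRNA", "+", 1, 10),
                             sequence = strrep("ACGT", 5))
  expect_error(repeat_report(no_cr), "no CR")
})
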