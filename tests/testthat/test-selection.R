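test_that("NG86 counting matches its textbook examples", {
  # identical sequences: no differences, omega undefined
  r0 <- ng86_pair(c("ATG", "CCA", "GGT"), c("ATG", "CCA", "GGT"))
  expect_equal(r0$pS, 0)
  expect_equal(r0$pN, 0)
  expect_true(is.na(r0$omega))
  expect_equal(r0$S + r0$N, 9)
  # one synonymous third-position change in an all-Lys pair:
  # each AAA/AAG carries 1/3 synonymous site (stop-excluded), so S = 1
  r1 <- ng86_pair(c("AAA", "AAA", "AAA"), c("AAA", "AAA", "AAG"),
                  correct = FALSE)
  expect_equal(r1$S, 1)
  expect_equal(r1$N, 8)
  expect_equal(r1$pS, 1)
  expect_equal(r1$pN, 0)
  expect_error(ng86_pair(c("ATG"), c("ATG", "AAA")), "length")
})

test_that("NG86 agrees with the exhaustive pathway oracle on random pairs", {
  set.seed(43)
  for (i in 1:40) {
    a <- random_sense_codons(30)
    b <- a
    nmut <- sample(1:12, 1)
    for (m in seq_len(nmut)) {
      j <- sample(30, 1)
      b[j] <- random_sense_codons(1)
    }
    ours <- ng86_pair(a, b, correct = FALSE)
    ora <- oracle_ng86(a, b)
    expect_equal(ours$S, ora$S, tolerance = 1e-12)
    expect_equal(ours$N, ora$N, tolerance = 1e-12)
    expect_equal(ours$Sd, ora$Sd, tolerance = 1e-12)
    expect_equal(ours$Nd, ora$Nd, tolerance = 1e-12)
    # symmetry in the arguments
    rev_ <- ng86_pair(b, a, correct = FALSE)
    expect_equal(ours$pS, rev_$pS)
    expect_equal(ours$pN, rev_$pN)
  }
})

test_that("Jukes-Cantor correction applies below saturation and warns above", {
  expect_equal(jc_correct(0), 0)
  expect_equal(jc_correct(0.1), -0.75 * log(1 - 0.4 / 3))
  expect_true(is.na(jc_correct(0.8)))
  a <- rep("AAA", 4); b <- c("AAG", "AAG", "AAG", "AAG")
  expect_warning(ng86_pair(a, b, correct = TRUE), "saturated")
})

test_that("omega dial of the evolver is recovered by NG86", {
  estimate_omega <- function(omega_true, seeds) {
    vals <- vapply(seeds, function(sd) {
      set.seed(sd)
      body <- paste(random_sense_codons(498), collapse = "")
      rec <- one_gene_record(paste0("ATG", body, "TAA"))
      fam <- evolve_family(rec, evolver_spec("(a:0.08,b:0.08,c:0.001);",
                                             omega = omega_true,
                                             seed = sd))
      aln <- fam$alignments[["GENE1"]]
      ng86_pair(aln["a", ], aln["b", ])$omega
    }, numeric(1))
    mean(vals, na.rm = TRUE)
  }
  expect_lt(abs(estimate_omega(0.2, 1:8) - 0.2), 0.15)
  expect_lt(abs(estimate_omega(1.0, 9:16) - 1.0), 0.15)
})

test_that("foreground screen flags planted sites and stays quiet on neutral data", {
  # planted: background monomorphic, foreground carries 5 nonsynonymous
  # states of its own
  set.seed(53)
  cods <- random_sense_codons(60)
  aln <- rbind(bg1 = cods, bg2 = cods, bg3 = cods, fg = cods)
  planted <- c(4L, 13L, 27L, 41L, 58L)
  code <- vert_mito_code()
  for (j in planted) {
    repeat {
      cand <- random_sense_codons(1)
      if (code[[cand]] != code[[cods[j]]]) break
    }
    aln["fg", j] <- cand
  }
  res <- sitewise_screen(list(gene = aln), foreground = "fg", p0 = 0.01)
  expect_gte(res$flagged, 4L)
  idx <- as.integer(strsplit(res$flagged_codons, ",")[[1]])
  expect_true(all(idx %in% planted))
  # foreground identical to background: nothing flagged
  res0 <- sitewise_screen(list(gene = rbind(a = cods, b = cods, c = cods,
                                            fg = cods)), foreground = "fg")
  expect_equal(res0$flagged, 0L)
  expect_error(sitewise_screen(list(g = aln), foreground = "nope"),
               "not in alignment")
})

test_that("neutral evolution rarely produces enrichment calls", {
  flags <- 0L; genes <- 0L
  for (rep_i in 1:20) {
    rec <- multi_gene_record(k = 5L, codons_per_gene = 80L,
                             seed = 600 + rep_i)
    fam <- evolve_family(rec, evolver_spec(
      "((fg:0.04,b1:0.04):0.01,b2:0.05,b3:0.05);",
      omega = 1, seed = 600 + rep_i))
    res <- sitewise_screen(fam$alignments, foreground = "fg")
    flags <- flags + sum(res$enriched)
    genes <- genes + nrow(res)
  }
  expect_lte(flags / genes, 0.05)
})

test_that("per-gene dN/dS table covers shared genes of a family", {
  rec <- generate_genome(synthetic_genome_spec(seed = 81))
  fam <- evolve_family(rec, evolver_spec("(a:0.03,b:0.03,c:0.001);",
                                         omega = 0.3, seed = 5))
  tab <- dnds_table(fam$records[["a"]], fam$records[["b"]])
  expect_equal(nrow(tab), 13L)
  expect_true(all(tab$dS >= 0, na.rm = TRUE))
  expect_true(all(tab$omega >= 0, na.rm = TRUE))
})
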