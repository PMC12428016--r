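test_that("codon extraction handles complete and incomplete stops and strands", {
  rec <- one_gene_record("ATGAAATAA")
  cx <- extract_codons(rec, rec$features[1, ])
  expect_equal(cx$codons, c("ATG", "AAA", "TAA"))
  expect_equal(cx$stop_codon, "TAA")
  expect_true(is.na(cx$incomplete_stop))
  # light-strand gene read from the reverse complement
  rec_l <- one_gene_record("ATGAAATAG", strand = "-", stop_codon = "TAG")
  cx_l <- extract_codons(rec_l, rec_l$features[1, ])
  expect_equal(cx_l$codons, c("ATG", "AAA", "TAG"))
  expect_equal(cx_l$stop_codon, "TAG")
  # 691 bp gene: 230 complete codons + trailing T flagged as T(AA)
  set.seed(5)
  body <- paste(random_sense_codons(229), collapse = "")
  rec_i <- one_gene_record(paste0("ATG", body, "T"), stop_codon = "T(AA)")
  cx_i <- extract_codons(rec_i, rec_i$features[1, ])
  expect_equal(nchar(paste0("ATG", body, "T")), 691L)
  expect_equal(cx_i$n_codons, 230L)
  expect_equal(cx_i$incomplete_stop, "T(AA)")
  # internal stop warns with its codon index
  rec_s <- one_gene_record("ATGTAAAAATAA")
  expect_warning(extract_codons(rec_s, rec_s$features[1, ]), "codon 2")
  expect_error(extract_codons(rec_s, list(feature_class = "tRNA")),
               "not a PCG")
})

test_that("start/stop tabulation on the synthetic default matches its template", {
  rec <- generate_genome(synthetic_genome_spec(seed = 13))
  ss <- tabulate_start_stop(rec)
  expect_equal(nrow(ss), 13L)
  expect_equal(sum(ss$start_codon == "ATG"), 12L)
  expect_equal(ss$start_codon[ss$gene == "COX1"], "GTG")
  expect_equal(ss$stop_codon[ss$gene == "ND6"], "TAG")
  expect_equal(ss$stop_codon[ss$gene == "COX2"], "T(AA)")
  expect_equal(ss$stop_codon[ss$gene == "ND4"], "T(AA)")
  expect_equal(sum(ss$stop_codon == "TAA"), 9L)
  # degenerate input: a gene with no recognized stop
  rec_n <- one_gene_record("ATGAAACCC")
  expect_warning(tabulate_start_stop(rec_n), "no recognized stop")
})

test_that("RSCU sums to family degeneracy and hits the degeneracy bound", {
  fam <- codon_families()
  # equal usage in every family -> all RSCU 1
  eq <- setNames(rep(7, nrow(fam)), fam$codon)
  expect_true(all(abs(rscu(eq)$rscu - 1) < 1e-12))
  # 4-fold family concentrated on one codon -> RSCU 4,0,0,0
  cc <- setNames(c(8, 0, 0, 0), c("GTT", "GTC", "GTA", "GTG"))
  val <- rscu(cc)
  expect_equal(val$rscu[val$codon == "GTT"], 4)
  expect_equal(sum(val$rscu[val$aa == "V"]), 4)
  # random usage tables: family sums equal degeneracy (property)
  set.seed(17)
  for (i in 1:25) {
    counts <- setNames(rpois(nrow(fam), lambda = runif(1, 0.5, 20)),
                       fam$codon)
    r <- rscu(counts)
    sums <- tapply(r$rscu, r$aa, sum)
    degs <- tapply(r$degeneracy, r$aa, unique)
    used <- tapply(r$count, r$aa, sum) > 0
    expect_equal(as.numeric(sums[used]), as.numeric(degs[used]))
    expect_true(all(is.na(sums[!used])))
  }
  # independent oracle on a small fixed table: family-mean arithmetic
  toy <- setNames(rep(0, nrow(fam)), fam$codon)
  toy[c("TTT", "TTC")] <- c(6, 2)          # Phe
  toy[c("GCT", "GCC", "GCA", "GCG")] <- c(1, 1, 1, 5)  # Ala
  r <- rscu(toy)
  expect_equal(r$rscu[r$codon == "TTT"], 6 / ((6 + 2) / 2))
  expect_equal(r$rscu[r$codon == "GCG"], 5 / ((1 + 1 + 1 + 5) / 4))
})

test_that("ENc spans its bounds and matches a direct Wright evaluation", {
  fam <- codon_families()
  # uniform usage approaches the code's ceiling of 60 sense-codon
  # equivalents (and never exceeds 61)
  big <- setNames(rep(10000, nrow(fam)), fam$codon)
  expect_lt(abs(enc(big) - 60), 0.1)
  expect_lte(enc(big), 61)
  # one codon per family -> the floor: 12 + 6 + 2 = 20 families
  one <- setNames(rep(0, nrow(fam)), fam$codon)
  for (a in unique(fam$aa)) one[fam$codon[fam$aa == a][1]] <- 50
  expect_equal(enc(one), 20)
  # independent brute-force evaluation on a fixed small table
  set.seed(23)
  counts <- setNames(rpois(nrow(fam), 9) + 1, fam$codon)
  Fk <- tapply(seq_len(nrow(fam)), fam$aa, function(ix) {
    n <- sum(counts[ix]); p <- counts[ix] / n
    (n * sum(p^2) - 1) / (n - 1)
  })
  deg <- tapply(fam$degeneracy, fam$aa, unique)
  expected <- sum(vapply(c(2, 4, 6), function(k)
    sum(deg == k) / mean(Fk[deg == k]), numeric(1)))
  expect_equal(enc(counts), expected)
  # ENc in [20, 61] on random tables; concentration lowers it
  for (i in 1:20) {
    counts <- setNames(rpois(nrow(fam), runif(1, 1, 15)) + 1, fam$codon)
    e0 <- enc(counts)
    expect_gte(e0, 20); expect_lte(e0, 61)
    # mean-preserving concentration within the Leu family
    leu <- fam$codon[fam$aa == "L"]
    conc <- counts
    tot <- sum(conc[leu])
    conc[leu] <- c(tot - 5, 1, 1, 1, 1, 1)
    expect_lt(enc(conc), e0 + 1e-9)
  }
  expect_error(enc(setNames(rep(0, nrow(fam)), fam$codon)), "insufficient")
})

test_that("codon bookkeeping reconciles with coordinate lengths", {
  rec <- generate_genome(synthetic_genome_spec(seed = 29))
  cut <- codon_usage_table(rec)
  v <- validate_annotation(rec)
  n_complete_stops <- sum(cut$start_stop$stop_codon %in% mito_stop_codons())
  expect_equal(3L * cut$total_codons + 3L * n_complete_stops +
                 cut$incomplete_stop_nt,
               v$pcg_length_sum)
  # whole-record ENc lies in the admissible band
  expect_gte(cut$enc, 20); expect_lte(cut$enc, 61)
  # strong codon bias lowers ENc relative to the unbiased generator
  biased <- generate_genome(synthetic_genome_spec(seed = 29,
                                                  codon_bias = 0.08))
  expect_lt(codon_usage_table(biased)$enc, cut$enc)
})
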