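tbl1 <- pleopoldi_annotation()

test_that("published feature table parses into 38 ordered features", {
  f <- tbl1$features
  expect_equal(nrow(f), 38L)
  expect_equal(sum(f$feature_class == "PCG"), 13L)
  expect_equal(sum(f$feature_class == "tRNA"), 22L)
  expect_equal(sum(f$feature_class == "rRNA"), 2L)
  expect_equal(sum(f$feature_class == "CR"), 1L)
  expect_equal(tbl1$genome_length, 17504L)
  # thousands separators stripped: ND5 row
  nd5 <- f[f$name == "ND5", ]
  expect_equal(c(nd5$start, nd5$stop), c(11975L, 13810L))
  expect_equal(nd5$stop - nd5$start + 1L, 1836L)
  # D-loop mapped to CR with heavy strand assumed
  expect_equal(f$feature_class[f$name == "D-loop"], "CR")
})

test_that("parser rejects malformed tables with informative errors", {
  expect_error(parse_feature_table("Name\tType\tStrand\tStart\tStop"),
               "no features")
  expect_error(parse_feature_table(c("Name\tType\tStrand\tStart\tStop",
                                     "ND1\tPCG\t+\tabc\t3841\t\t\tATG/TAA")),
               "malformed coordinate.*ND1")
  expect_error(parse_feature_table(c("Name\tType\tStrand\tStart\tStop",
                                     "ND1\tmystery\t+\t1\t10")),
               "unknown feature class")
})

test_that("validator reproduces published spacers and flags inconsistent rows", {
  v <- validate_annotation(tbl1)
  per <- v$per_feature
  spacer <- function(nm) per$intergenic[per$name == nm]
  expect_equal(spacer("ND2"), -1L)       # abuts tRNA-Trp at 5103
  expect_equal(spacer("ATP8"), -10L)     # overlaps ATP6
  expect_equal(spacer("COX1"), 6L)
  expect_equal(spacer("tRNA-Val"), 19L)
  # strand tally over the 37 gene rows (CR excluded)
  expect_equal(v$strand_tally, c(heavy = 28L, light = 9L))
  # declared-vs-computed length conflicts, including the ATP6 row where
  # coordinates give 684 against a printed 683
  expect_setequal(v$length_discrepancies$name,
                  c("ATP6", "tRNA-Ser", "tRNA-Glu", "tRNA-Pro", "D-loop"))
  glu <- per[per$name == "tRNA-Glu", ]
  expect_equal(glu$computed_length, 79L)
  expect_equal(glu$declared_length, 69L)
  # coordinate-computed PCG sum vs the printed length column's sum
  expect_equal(v$pcg_length_sum, 11435L)
  expect_equal(v$pcg_declared_sum, 11434L)
  # printed spacer column disagrees with coordinates on exactly these rows
  expect_setequal(v$intergenic_discrepancies$name,
                  c("tRNA-Asn", "tRNA-Ser", "ND6", "tRNA-Thr", "tRNA-Pro"))
  # all other rows match the printed spacer column exactly
  consistent <- per[per$intergenic_ok & !is.na(per$declared_intergenic), ]
  expect_true(all(consistent$intergenic == consistent$declared_intergenic))
  expect_gte(nrow(consistent), 30L)
})

test_that("extract_region slices, reverse-complements and wraps the origin", {
  rec <- mitogenome_record("t", gene_feature("g", "CR", "+", 1, 4),
                           sequence = "ATGC")
  expect_identical(extract_region(rec, list(start = 1, stop = 3, strand = "+")),
                   "ATG")
  expect_identical(extract_region(rec, list(start = 1, stop = 3, strand = "-")),
                   "CAT")
  expect_identical(extract_region(rec, list(start = 4, stop = 2, strand = "+")),
                   "CAT")
  # strand - is revcomp of strand + for arbitrary slices
  set.seed(3)
  s <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
  r2 <- mitogenome_record("r", gene_feature("g", "CR", "+", 1, 60),
                          sequence = s)
  for (span in list(c(5, 20), c(1, 60), c(33, 34))) {
    plus <- extract_region(r2, list(start = span[1], stop = span[2], strand = "+"))
    minus <- extract_region(r2, list(start = span[1], stop = span[2], strand = "-"))
    expect_identical(revcomp(plus), minus)
  }
})

test_that("FASTA and GenBank writers round-trip a synthetic record", {
  rec <- generate_genome(synthetic_genome_spec(seed = 9))
  fa <- tempfile(fileext = ".fasta")
  write_fasta_seq(tolower(rec$sequence), rec$record_id, fa)
  expect_identical(read_fasta_seq(fa), rec$sequence)  # uppercased on read
  gb <- tempfile(fileext = ".gb")
  write_genbank_flat(rec, gb)
  back <- read_genbank_flat(gb)
  expect_identical(back$sequence, rec$sequence)
  for (col in c("name", "feature_class", "strand", "start", "stop"))
    expect_equal(back$features[[col]], rec$features[[col]])
})

test_that("GenBank reader flags origin-wrapping join() features", {
  feats <- rbind(
    gene_feature("tRNA-Phe", "tRNA", "+", 3, 10),
    gene_feature("D-loop", "CR", "+", 11, 2))  # wraps 11..12,1..2
  rec <- mitogenome_record("wrap", feats, sequence = "ACGTACGTACGT")
  gb <- tempfile(fileext = ".gb")
  write_genbank_flat(rec, gb)
  back <- read_genbank_flat(gb)
  dl <- back$features[back$features$name == "D-loop", ]
  expect_lt(dl$stop, dl$start)   # wrapping flagged by stop < start
  expect_equal(c(dl$start, dl$stop), c(11L, 2L))
  expect_identical(extract_region(back, dl), "GTAC")
  # multi-record files are rejected
  two <- tempfile()
  writeLines(c(readLines(gb), readLines(gb)), two)
  expect_error(read_genbank_flat(two), "multi-record")
})
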