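#!/usr/bin/env Rscript
# Stage 6: pairwise NG86 dN/dS screen and foreground-specific
# substitution scan.
#
# Finding: on families evolved from a synthetic root, NG86 recovers the
# evolver's dN/dS dial (omega 0.2 here estimated near 0.2 per gene,
# purifying-selection territory), and the foreground screen flags
# planted foreground-specific nonsynonymous codons while staying quiet
# on neutral data. The published per-gene selected-site counts (ND1:1,
# ND4:1, ND5:3, COXI:6, COXII:3) rest on an unstated method and dataset
# and are not a reproduction target; this stage reports the same
# gene -> flagged-sites layout from transparent counting instead.

suppressPackageStartupMessages(library(mitoray))
dir.create("results", showWarnings = FALSE)

root <- generate_genome(synthetic_genome_spec(seed = 1))
fam <- evolve_family(root, evolver_spec("(focal:0.05,sister:0.05,o:0.001);",
                                        omega = 0.2, seed = 2))
tab <- dnds_table(fam$records[["focal"]], fam$records[["sister"]])
cat("Per-gene NG86 between the focal genome and its sister:\n")
print(tab, row.names = FALSE)
write.table(tab, "results/06_dnds.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("\nMedian omega across genes: %.3f (evolver dial: 0.2)\n",
            median(tab$omega, na.rm = TRUE)))

# foreground screen across a 4-taxon family
fam4 <- evolve_family(root, evolver_spec(
  "((fg:0.03,b1:0.03):0.01,b2:0.04,b3:0.04);", omega = 1, seed = 3))
scr <- sitewise_screen(fam4$alignments, foreground = "fg")
cat("\nForeground-specific substitution screen (neutral family):\n")
print(scr[, c("gene", "eligible_codons", "flagged", "p_value", "enriched")],
      row.names = FALSE)
write.table(scr, "results/06_screen.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("written: results/06_dnds.tsv, results/06_screen.tsv\n")
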