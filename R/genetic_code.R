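#' The vertebrate mitochondrial genetic code
#'
#' Codon-to-amino-acid map for NCBI translation table 2, the code used by
#' all vertebrate mitochondria. It differs from the standard code in three
#' ways: \code{ATA} encodes Met (not Ile), \code{TGA} encodes Trp (not
#' stop), and \code{AGA}/\code{AGG} are stops (not Arg). The stop set is
#' therefore \code{TAA, TAG, AGA, AGG} and there are 60 sense codons.
#'
#' @return Named character vector of length 64 mapping codon (e.g. "ATG")
#'   to one-letter amino acid, with "*" for stop codons.
#' @export
#' @examples
#' code <- vert_mito_code()
#' code[["ATA"]]  # "M"
#' code[["TGA"]]  # "W"
vert_mito_code <- function() {
  .mito_code_env$code
}

#' Synonymous-family partition of the vertebrate mitochondrial code
#'
#' Groups the 60 sense codons of translation table 2 into synonymous
#' families. Under this code there are 12 two-fold families (Phe, Tyr,
#' His, Gln, Asn, Lys, Asp, Glu, Cys, Trp, Met, Ile), 6 four-fold families
#' (Val, Pro, Thr, Ala, Arg, Gly) and 2 six-fold families (Leu, Ser);
#' no amino acid is encoded by a single codon and none is three-fold.
#'
#' @return A data.frame with columns \code{codon}, \code{aa} (one-letter),
#'   and \code{degeneracy} (2, 4 or 6), one row per sense codon.
#' @export
codon_families <- function() {
  .mito_code_env$families
}

#' Stop codons of the vertebrate mitochondrial code
#' @return Character vector \code{c("TAA","TAG","AGA","AGG")}.
#' @export
mito_stop_codons <- function() c("TAA", "TAG", "AGA", "AGG")

.mito_code_env <- new.env(parent = emptyenv())

.build_mito_code <- function() {
  bases <- c("T", "C", "A", "G")
  # first codon position varies slowest: TTT, TTC, TTA, TTG, TCT, ...
  codons <- paste0(rep(bases, each = 16L),
                   rep(rep(bases, each = 4L), times = 4L),
                   rep(bases, times = 16L))
  # standard-code amino acids in TCAG order, then the three table-2 edits
  aa <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",   # Txx
    "LLLLPPPPHHQQRRRR",   # Cxx
    "IIIMTTTTNNKKSSRR",   # Axx
    "VVVVAAAADDEEGGGG"),  # Gxx
    "")[[1]]
  names(aa) <- codons
  aa[["ATA"]] <- "M"
  aa[["TGA"]] <- "W"
  aa[["AGA"]] <- "*"
  aa[["AGG"]] <- "*"
  sense <- names(aa)[aa != "*"]
  deg <- table(aa[sense])
  fam <- data.frame(
    codon = sense,
    aa = unname(aa[sense]),
    degeneracy = as.integer(deg[aa[sense]]),
    stringsAsFactors = FALSE
  )
  fam <- fam[order(fam$aa, fam$codon), ]
  rownames(fam) <- NULL
  .mito_code_env$code <- aa
  .mito_code_env$families <- fam
  invisible(NULL)
}
.build_mito_code()

#' Translate codons under the vertebrate mitochondrial code
#'
#' @param codons Character vector of 3-mers (uppercase DNA).
#' @return Character vector of one-letter amino acids ("*" for stops,
#'   NA for codons containing non-ACGT characters).
#' @export
translate_mito <- function(codons) {
  code <- vert_mito_code()
  out <- unname(code[codons])
  out
}

#' Reverse complement of a DNA string
#'
#' @param seq Single character string over A/C/G/T/N (case preserved as
#'   uppercase on output).
#' @return The reverse complement string.
#' @export
revcomp <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  x <- chartr("ACGTNacgtn", "TGCANTGCAN", seq)
  paste(rev(strsplit(x, "", fixed = TRUE)[[1]]), collapse = "")
}

# split a sequence string into a character vector of single bases
seq_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

# split an in-frame coding string into complete codons (trailing 1-2 nt dropped)
split_codons <- function(seq) {
  n <- nchar(seq)
  k <- n %/% 3L
  if (k == 0L) return(character(0))
  substring(seq, 3L * seq_len(k) - 2L, 3L * seq_len(k))
}
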