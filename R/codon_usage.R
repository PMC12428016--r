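#' Extract codons from a protein-coding gene
#'
#' Obtains the coding-strand sequence of a PCG (light-strand genes are
#' reverse-complemented), splits it into complete codons, and records any
#' trailing 1-2 nucleotides as an incomplete stop codon in the customary
#' notation: a trailing "T" is reported as \code{"T(AA)"}, a trailing
#' \code{"TA"} as \code{"TA(A)"} -- such stops are completed to TAA by
#' post-transcriptional polyadenylation and are excluded from codon
#' counts. Internal stop codons trigger a warning listing their 1-based
#' codon positions.
#'
#' @param record A \code{mitogenome_record} with sequence.
#' @param feature A PCG row of the record's feature table.
#' @return List with \code{codons} (character vector of complete codons),
#'   \code{n_codons}, \code{start_codon}, \code{stop_codon} (the terminal
#'   complete codon when it is a stop, else NA), \code{incomplete_stop}
#'   ("T(AA)"/"TA(A)" or NA), and \code{trailing_nt} (0, 1 or 2).
#' @export
extract_codons <- function(record, feature) {
  if (!identical(feature$feature_class, "PCG"))
    stop("feature is not a PCG")
  s <- extract_region(record, feature)
  if (nchar(s) < 3L) stop("coding sequence shorter than one codon")
  codons <- split_codons(s)
  trailing <- nchar(s) %% 3L
  incomplete <- NA_character_
  if (trailing == 1L) {
    tail_nt <- substr(s, nchar(s), nchar(s))
    incomplete <- paste0(tail_nt, "(AA)")
  } else if (trailing == 2L) {
    tail_nt <- substr(s, nchar(s) - 1L, nchar(s))
    incomplete <- paste0(tail_nt, "(A)")
  }
  stops <- mito_stop_codons()
  last <- codons[length(codons)]
  stop_codon <- NA_character_
  if (trailing == 0L && last %in% stops) stop_codon <- last
  internal <- which(codons[-length(codons)] %in% stops)
  if (length(internal))
    warning("internal stop codon(s) in ", feature$name, " at codon ",
            paste(internal, collapse = ", "))
  list(
    codons = codons, n_codons = length(codons),
    start_codon = codons[1L], stop_codon = stop_codon,
    incomplete_stop = incomplete, trailing_nt = trailing
  )
}

#' Tabulate start and stop codons across all protein-coding genes
#'
#' @param record A \code{mitogenome_record} with sequence and annotated
#'   PCGs.
#' @return data.frame: gene, strand, start_codon, stop_codon (a complete
#'   stop, an incomplete "T(AA)"-style entry, or "none" with a warning).
#' @export
tabulate_start_stop <- function(record) {
  pcg <- record$features[record$features$feature_class == "PCG", ,
                         drop = FALSE]
  if (!nrow(pcg)) stop("record has no PCG features")
  rows <- lapply(seq_len(nrow(pcg)), function(i) {
    cx <- extract_codons(record, pcg[i, ])
    stop_out <- if (!is.na(cx$incomplete_stop)) cx$incomplete_stop
      else if (!is.na(cx$stop_codon)) cx$stop_codon
      else "none"
    if (identical(stop_out, "none"))
      warning("no recognized stop codon in ", pcg$name[i])
    data.frame(gene = pcg$name[i], strand = pcg$strand[i],
               start_codon = cx$start_codon, stop_codon = stop_out,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Count codon usage over the protein-coding genes of a record
#'
#' Counts every complete codon of every PCG on its coding strand. Stop
#' codons (complete terminal stops and any internal ones) are tallied
#' under their own entries but carry no RSCU; incomplete stops contribute
#' nothing. Start codons are counted as ordinary codons (a GTG start
#' falls in the Val family), with starts tabulated separately by
#' \code{\link{tabulate_start_stop}}.
#'
#' @param record A \code{mitogenome_record} with sequence.
#' @param exclude_stops Drop the 4 stop codons from the returned counts
#'   (default TRUE, the convention for RSCU/ENc input).
#' @return Named integer vector of counts over codons.
#' @export
codon_counts <- function(record, exclude_stops = TRUE) {
  pcg <- record$features[record$features$feature_class == "PCG", ,
                         drop = FALSE]
  if (!nrow(pcg)) stop("record has no PCG features")
  all_codons <- unlist(lapply(seq_len(nrow(pcg)), function(i)
    extract_codons(record, pcg[i, ])$codons))
  lv <- names(vert_mito_code())
  counts <- table(factor(all_codons, levels = lv))
  counts <- stats::setNames(as.integer(counts), lv)
  if (exclude_stops) counts <- counts[setdiff(lv, mito_stop_codons())]
  counts
}

#' Relative synonymous codon usage
#'
#' RSCU of codon c is its count divided by the mean count over its
#' synonymous family under the vertebrate mitochondrial code; 1 means no
#' bias, and values sum to the family degeneracy within each used family.
#' Families with zero total usage get NA.
#'
#' @param counts Named numeric vector of codon counts (stop codons, if
#'   present, are ignored).
#' @return data.frame: codon, aa, degeneracy, count, rscu.
#' @export
#' @examples
#' cc <- setNames(c(8, 0, 0, 0), c("GTT", "GTC", "GTA", "GTG"))
#' rscu(cc)$rscu  # 4, 0, 0, 0
rscu <- function(counts) {
  fam <- codon_families()
  fam$count <- ifelse(is.na(counts[fam$codon]), 0, counts[fam$codon])
  totals <- tapply(fam$count, fam$aa, sum)
  fam$rscu <- ifelse(totals[fam$aa] > 0,
                     fam$count * fam$degeneracy / totals[fam$aa],
                     NA_real_)
  rownames(fam) <- NULL
  fam
}

#' Effective number of codons (ENc)
#'
#' Wright-style summary of codon-usage bias. For each amino-acid family
#' with total usage n >= 2 the codon homozygosity is
#' \deqn{F = (n \sum p_i^2 - 1)/(n - 1)}
#' and ENc sums, over degeneracy classes k, (number of k-fold families) /
#' mean(F_k). Under the vertebrate mitochondrial code the classes are 12
#' two-fold, 6 four-fold and 2 six-fold families (no single-codon amino
#' acid, no three-fold family), so uniform usage gives the code's ceiling
#' of 60 -- slightly below the 61 familiar from the standard code -- and
#' one-codon-per-family usage gives the floor of 20. A family with usage
#' but undefined F (n < 2), or an unused family, is imputed the observed
#' mean F of its degeneracy class; if an entire class is missing its mean
#' F is taken from the expectation under the overall F of computable
#' families. The result is clamped to at most 61.
#'
#' @param counts Named numeric vector of sense-codon counts.
#' @return ENc value in [20, 61].
#' @export
enc <- function(counts) {
  fam <- codon_families()
  fam$count <- ifelse(is.na(counts[fam$codon]), 0, counts[fam$codon])
  sp <- split(fam, fam$aa)
  deg <- vapply(sp, function(d) d$degeneracy[1L], integer(1))
  Fhat <- vapply(sp, function(d) {
    n <- sum(d$count)
    if (n < 2) return(NA_real_)
    p <- d$count / n
    (n * sum(p^2) - 1) / (n - 1)
  }, numeric(1))
  if (all(is.na(Fhat))) stop("insufficient usage: no family with n >= 2")
  classes <- sort(unique(deg))
  total <- 0
  global_mean <- mean(Fhat, na.rm = TRUE)
  for (k in classes) {
    fk <- Fhat[deg == k]
    nk <- length(fk)
    mk <- mean(fk, na.rm = TRUE)
    if (is.nan(mk)) mk <- global_mean
    if (mk <= 0) mk <- 1 / k   # guard: F can hit 0 on tiny balanced n
    total <- total + nk / mk
  }
  min(total, 61)
}

#' Full codon-usage table for a mitogenome
#'
#' Bundles codon counts, RSCU, per-gene start/stop codons, whole-record
#' ENc and per-gene ENc (where computable) for one record.
#'
#' @param record A \code{mitogenome_record} with sequence.
#' @return List of class \code{codon_usage_table}: \code{counts},
#'   \code{rscu} (data.frame), \code{start_stop} (data.frame),
#'   \code{enc} (whole set of PCGs pooled), \code{enc_per_gene}
#'   (named numeric, NA where a gene's usage is too sparse),
#'   \code{total_codons}, \code{incomplete_stop_nt}.
#' @export
codon_usage_table <- function(record) {
  pcg <- record$features[record$features$feature_class == "PCG", ,
                         drop = FALSE]
  counts <- codon_counts(record)
  per_gene <- vapply(seq_len(nrow(pcg)), function(i) {
    cx <- extract_codons(record, pcg[i, ])
    lv <- setdiff(names(vert_mito_code()), mito_stop_codons())
    gc <- table(factor(cx$codons[cx$codons %in% lv], levels = lv))
    tryCatch(enc(stats::setNames(as.integer(gc), lv)),
             error = function(e) NA_real_)
  }, numeric(1))
  names(per_gene) <- pcg$name
  trailing <- vapply(seq_len(nrow(pcg)), function(i)
    extract_codons(record, pcg[i, ])$trailing_nt, integer(1))
  out <- list(
    counts = counts,
    rscu = rscu(counts),
    start_stop = tabulate_start_stop(record),
    enc = enc(counts),
    enc_per_gene = per_gene,
    total_codons = sum(counts),
    incomplete_stop_nt = sum(trailing)
  )
  class(out) <- "codon_usage_table"
  out
}

#' @export
print.codon_usage_table <- function(x, ...) {
  cat("<codon_usage_table>\n")
  cat("  total codons (sense): ", x$total_codons,
      "; incomplete-stop nt: ", x$incomplete_stop_nt, "\n", sep = "")
  cat(sprintf("  ENc (all PCGs pooled): %.2f; per-gene mean: %.2f\n",
              x$enc, mean(x$enc_per_gene, na.rm = TRUE)))
  top <- x$rscu[order(-x$rscu$rscu), ][1:5, c("codon", "aa", "rscu")]
  cat("  most preferred codons:\n")
  print(top, row.names = FALSE)
  invisible(x)
}

#' Write an RSCU table
#' @param cut A \code{codon_usage_table}.
#' @param path Output TSV path.
#' @export
write_rscu_table <- function(cut, path) {
  utils::write.table(cut$rscu, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
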