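#' Base composition and strand-skew profile of a sequence
#'
#' Counts A/C/G/T over a region and derives the strand-asymmetry
#' statistics used throughout mitogenome descriptions:
#' \deqn{AT\,skew = (A - T)/(A + T), \quad GC\,skew = (G - C)/(G + C).}
#' N bases are tallied separately and excluded from every denominator;
#' percentages are over counted (non-N) bases only, so A+C+G+T fractions
#' sum to 100. Skews are stored at full precision; rendering to the
#' two decimals customarily printed is left to the report layer.
#'
#' @param seq Non-empty nucleotide string over A/C/G/T/N (case-insensitive).
#' @return An object of class \code{composition_profile}: list with
#'   \code{counts} (named integer A,C,G,T), \code{n_count}, \code{pct}
#'   (named percentages), \code{at_content}, \code{gc_content} (percent),
#'   \code{at_skew}, \code{gc_skew} (NA when a denominator is zero).
#' @export
#' @examples
#' p <- composition_profile("GGGC")
#' p$gc_skew  # (3 - 1) / 4 = 0.5
composition_profile <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (nchar(seq) == 0L) stop("empty sequence")
  seq <- toupper(seq)
  bad <- regexpr("[^ACGTN]", seq)
  if (bad > 0L)
    stop("non-IUPAC character '", substr(seq, bad, bad),
         "' at position ", bad)
  v <- utf8ToInt(seq)
  counts <- c(A = sum(v == 65L), C = sum(v == 67L),
              G = sum(v == 71L), T = sum(v == 84L))
  n_count <- sum(v == 78L)
  .profile_from_counts(counts, n_count)
}

.profile_from_counts <- function(counts, n_count = 0L) {
  tot <- sum(counts)
  pct <- if (tot > 0) 100 * counts / tot else counts * NA_real_
  at <- counts[["A"]] + counts[["T"]]
  gc <- counts[["G"]] + counts[["C"]]
  structure(list(
    counts = counts, n_count = as.integer(n_count), pct = pct,
    at_content = if (tot > 0) 100 * at / tot else NA_real_,
    gc_content = if (tot > 0) 100 * gc / tot else NA_real_,
    at_skew = if (at > 0) (counts[["A"]] - counts[["T"]]) / at else NA_real_,
    gc_skew = if (gc > 0) (counts[["G"]] - counts[["C"]]) / gc else NA_real_
  ), class = "composition_profile")
}

#' @export
print.composition_profile <- function(x, ...) {
  cat("<composition_profile> ", sum(x$counts), " bases",
      if (x$n_count) paste0(" (+", x$n_count, " N)"), "\n", sep = "")
  cat(sprintf("  A: %.2f%%  C: %.2f%%  G: %.2f%%  T: %.2f%%\n",
              x$pct[["A"]], x$pct[["C"]], x$pct[["G"]], x$pct[["T"]]))
  cat(sprintf("  AT content: %.2f%%  AT skew: %s  GC skew: %s\n",
              x$at_content, format_skew(x$at_skew), format_skew(x$gc_skew)))
  invisible(x)
}

# two-decimal display with round-half-even, as printed in report tables
format_skew <- function(x) {
  if (is.na(x)) return("NA")
  sprintf("%.2f", round(x, 2))
}

#' Strand skews of a composition profile
#'
#' @param profile A \code{composition_profile}.
#' @return Named numeric \code{c(at_skew=, gc_skew=)}; a skew is NA (with
#'   a warning) when its denominator is zero.
#' @export
skew_stats <- function(profile) {
  if (is.na(profile$at_skew) || is.na(profile$gc_skew))
    warning("skew undefined for zero denominator")
  c(at_skew = profile$at_skew, gc_skew = profile$gc_skew)
}

#' Composition arithmetic from printed percentages
#'
#' Recomputes AT/GC content and skews from a published base-percentage
#' breakdown (e.g. "A: 32.32, T: 24.41, C: 12.84, G: 30.42"), exactly as
#' the skew formulas apply to fractions. Used to audit printed tables:
#' for the P. leopoldi whole-genome percentages this yields AT content
#' 56.73, AT skew 0.1394 and GC skew +0.406 -- the latter positive even
#' though the publication reports -0.40, an internal sign inconsistency
#' (consistent with a C/G label swap) that \code{gc_sign_consistent}
#' exposes; the arithmetic is reproduced, never silently corrected.
#'
#' @param pct Named numeric with entries A, C, G, T (percent).
#' @param reported_gc_skew Optional published GC-skew value to check the
#'   sign against.
#' @return List with \code{at_content}, \code{gc_content}, \code{at_skew},
#'   \code{gc_skew}, and (when \code{reported_gc_skew} is given)
#'   \code{gc_sign_consistent}.
#' @export
composition_from_percent <- function(pct, reported_gc_skew = NULL) {
  stopifnot(all(c("A", "C", "G", "T") %in% names(pct)))
  at <- pct[["A"]] + pct[["T"]]
  gc <- pct[["G"]] + pct[["C"]]
  out <- list(
    at_content = at, gc_content = gc,
    at_skew = (pct[["A"]] - pct[["T"]]) / at,
    gc_skew = (pct[["G"]] - pct[["C"]]) / gc
  )
  if (!is.null(reported_gc_skew))
    out$gc_sign_consistent <-
      sign(out$gc_skew) == sign(reported_gc_skew)
  out
}

#' Sliding-window composition over a circular genome
#'
#' @param record A \code{mitogenome_record} with sequence.
#' @param window Window size in bp (>= 1, <= genome length).
#' @param step Step in bp (>= 1).
#' @return data.frame with one row per window: \code{start} (1-based),
#'   \code{at_content}, \code{gc_content}, \code{at_skew}, \code{gc_skew}.
#'   Windows wrap the circular origin, so every start position up to the
#'   genome length is covered.
#' @export
windowed_skew <- function(record, window, step) {
  if (is.na(record$sequence)) stop("record has no sequence")
  L <- record$genome_length
  if (window < 1L || step < 1L) stop("window and step must be >= 1")
  if (window > L) stop("window larger than genome")
  starts <- seq.int(1L, L, by = step)
  seq2 <- paste0(record$sequence, substr(record$sequence, 1L, window))
  rows <- lapply(starts, function(s) {
    p <- composition_profile(substr(seq2, s, s + window - 1L))
    data.frame(start = s, at_content = p$at_content,
               gc_content = p$gc_content,
               at_skew = p$at_skew, gc_skew = p$gc_skew)
  })
  do.call(rbind, rows)
}

#' Per-region composition report for a mitogenome
#'
#' One composition row for the whole genome and for each feature class
#' present (PCG, tRNA, rRNA, CR), with class sequences formed by
#' concatenating the coding-strand sequence of every member feature.
#'
#' @param record A \code{mitogenome_record} with sequence.
#' @return data.frame: region, length_bp, pct A/C/G/T, at_content,
#'   gc_content, at_skew, gc_skew.
#' @export
composition_report <- function(record) {
  if (is.na(record$sequence)) stop("record has no sequence")
  regions <- list(whole_genome = record$sequence)
  for (cls in c("PCG", "tRNA", "rRNA", "CR")) {
    rows <- record$features[record$features$feature_class == cls, ,
                            drop = FALSE]
    if (!nrow(rows)) next
    regions[[cls]] <- paste(
      vapply(seq_len(nrow(rows)),
             function(i) extract_region(record, rows[i, ]), character(1)),
      collapse = "")
  }
  out <- lapply(names(regions), function(nm) {
    p <- composition_profile(regions[[nm]])
    data.frame(region = nm, length_bp = sum(p$counts) + p$n_count,
               A = p$pct[["A"]], C = p$pct[["C"]],
               G = p$pct[["G"]], T = p$pct[["T"]],
               at_content = p$at_content, gc_content = p$gc_content,
               at_skew = p$at_skew, gc_skew = p$gc_skew,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
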