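# Tandem repeat detection: seed (recurring k-mer spacings) and extend
# (gapless wraparound alignment against the phased consensus). Scoring
# follows the customary tandem-repeat weights: match +2, mismatch -7;
# hits below the configured minimum alignment score are discarded.

# integer encoding A=1 C=2 G=3 T=4 (N and others = NA)
encode_dna <- function(seq) {
  v <- utf8ToInt(toupper(seq))
  out <- rep(NA_integer_, length(v))
  out[v == 65L] <- 1L; out[v == 67L] <- 2L
  out[v == 71L] <- 3L; out[v == 84L] <- 4L
  out
}
decode_dna <- function(code) {
  c("A", "C", "G", "T")[code]
}

# column-majority consensus of x (integer codes) phased at period p,
# anchored so that position i maps to column ((i - 1) %% p) + 1.
# ties broken by base order A < C < G < T (deterministic).
phase_consensus <- function(x, p) {
  col <- ((seq_along(x) - 1L) %% p) + 1L
  cons <- integer(p)
  for (j in seq_len(p)) {
    xs <- x[col == j]
    xs <- xs[!is.na(xs)]
    if (!length(xs)) { cons[j] <- 1L; next }
    tab <- tabulate(xs, 4L)
    cons[j] <- which.max(tab)   # which.max takes first on ties = A<C<G<T
  }
  cons
}

# per-position match/mismatch score of x against the tiled consensus
tile_scores <- function(x, cons, match = 2, mismatch = -7) {
  p <- length(cons)
  tiled <- cons[((seq_along(x) - 1L) %% p) + 1L]
  sc <- ifelse(!is.na(x) & x == tiled, match, mismatch)
  sc
}

# maximal-scoring contiguous subarray (Kadane); returns start, end, score
max_subarray <- function(sc) {
  best <- -Inf; best_s <- 1L; best_e <- 0L
  cur <- 0; cur_s <- 1L
  for (i in seq_along(sc)) {
    if (cur <= 0) { cur <- sc[i]; cur_s <- i } else cur <- cur + sc[i]
    if (cur > best) { best <- cur; best_s <- cur_s; best_e <- i }
  }
  list(start = best_s, end = best_e, score = best)
}

# consensus of x phased at period p with phase anchored at position
# `anchor` (anchor maps to column 1)
anchored_consensus <- function(x, p, anchor) {
  off <- ((anchor - 1L) %% p)
  col <- (((seq_along(x) - 1L) - off) %% p) + 1L
  cons <- integer(p)
  for (j in seq_len(p)) {
    xs <- x[col == j]
    xs <- xs[!is.na(xs)]
    if (!length(xs)) { cons[j] <- 1L; next }
    tab <- tabulate(xs, 4L)
    cons[j] <- which.max(tab)   # which.max takes first on ties = A<C<G<T
  }
  list(cons = cons, col = col)
}

# score one candidate (window x, period p, seed position within window):
# the motif is seeded from the two aligned copies at the seed, the best
# span is found by maximal-scoring subarray, then the consensus is
# refitted by column majority over that span and rescored (two rounds)
score_candidate <- function(x, p, seed_at = 1L, match = 2, mismatch = -7) {
  n <- length(x)
  # initial motif: majority over the copies starting at the seed
  seed_end <- min(n, seed_at + 2L * p - 1L)
  init <- anchored_consensus(x[seed_at:seed_end], p, 1L)$cons
  off <- ((seed_at - 1L) %% p)
  col <- (((seq_along(x) - 1L) - off) %% p) + 1L
  sc <- ifelse(!is.na(x) & x == init[col], match, mismatch)
  hit <- max_subarray(sc)
  # refine: refit the consensus by column majority over the current best
  # span (phase anchored at its start), rescore the window, re-extend
  for (round in 1:2) {
    if (hit$end < hit$start) break
    cons_r <- anchored_consensus(x[hit$start:hit$end], p, 1L)$cons
    off2 <- ((hit$start - 1L) %% p)
    col2 <- (((seq_along(x) - 1L) - off2) %% p) + 1L
    sc2 <- ifelse(!is.na(x) & x == cons_r[col2], match, mismatch)
    hit2 <- max_subarray(sc2)
    if (hit2$start == hit$start && hit2$end == hit$end) { hit <- hit2; break }
    hit <- hit2
  }
  if (hit$end < hit$start)
    return(list(start = 1L, end = 0L, score = -Inf, consensus = integer(p)))
  # final self-consistent consensus + score for the reported span, with
  # column 1 of the consensus at the span start
  xs <- x[hit$start:hit$end]
  cons <- anchored_consensus(xs, p, 1L)$cons
  tiled <- cons[((seq_along(xs) - 1L) %% p) + 1L]
  score <- sum(ifelse(!is.na(xs) & xs == tiled, match, mismatch))
  list(start = hit$start, end = hit$end, score = score, consensus = cons)
}

#' Find tandem repeats in a nucleotide sequence
#'
#' Seed-and-extend detector for tandem repeats. Candidate periods are
#' proposed from the spacing histogram of recurring k-mers (k = 5);
#' each candidate locus is extended by aligning the surrounding sequence,
#' without gaps, against its period-phased column-majority consensus
#' (match +2, mismatch -7 by default), keeping the maximal-scoring span.
#' Hits scoring below \code{min_score} are discarded; overlapping hits of
#' the same locus are reduced to the best-scoring period; results are
#' sorted by start. Copy number is the (fractional) span length divided
#' by the period.
#'
#' @param seq Nucleotide string (length >= 2 x smallest period sought).
#' @param min_score Minimum alignment score to report a repeat
#'   (default 30, the threshold used for published control-region scans).
#' @param period_range Integer pair: smallest and largest period tried.
#' @param match,mismatch Alignment weights; the gap weight of the
#'   published tool (-7) is implicit in the gapless model.
#' @param circular Treat the sequence as circular: seeds and extension may
#'   wrap the origin, and a hit crossing it is reported with
#'   \code{end > length(seq)} coordinates reduced modulo the length.
#' @return data.frame of class \code{tandem_repeat_hits}: start, end
#'   (1-based inclusive), period, copy_number, score, identity (percent),
#'   consensus.
#' @export
find_tandem_repeats <- function(seq, min_score = 30L,
                                period_range = c(2L, 500L),
                                match = 2, mismatch = -7,
                                circular = FALSE) {
  if (!nzchar(seq)) stop("empty sequence")
  L0 <- nchar(seq)
  pad <- 0L
  if (circular) {
    pad <- min(L0, period_range[2] * 2L)
    seq <- paste0(seq, substr(seq, 1L, pad))
  }
  x <- encode_dna(seq)
  L <- length(x)
  k <- 5L
  pmin_ <- max(2L, period_range[1]); pmax_ <- min(period_range[2], L %/% 2L)
  if (pmax_ < pmin_) return(.empty_hits())
  # k-mer seeds: positions of each 5-mer; spacings between consecutive
  # occurrences propose (period, locus) candidates
  if (L >= k) {
    km <- substring(seq, 1:(L - k + 1L), k:L)
    ord <- order(km)
    kms <- km[ord]
    runs <- rle(kms)
    cand <- new.env(parent = emptyenv())
    pos_sorted <- ord
    idx <- cumsum(runs$lengths)
    starts_i <- c(1L, head(idx, -1L) + 1L)
    seeds <- list()
    for (r in seq_along(runs$lengths)) {
      if (runs$lengths[r] < 2L) next
      pos <- sort(pos_sorted[starts_i[r]:idx[r]])
      d <- diff(pos)
      keep <- d >= pmin_ & d <= pmax_
      if (any(keep))
        seeds[[length(seeds) + 1L]] <-
          cbind(pos = pos[-length(pos)][keep], per = d[keep])
    }
    if (!length(seeds)) return(.finish_hits(.empty_hits(), L0, circular))
    sm <- do.call(rbind, seeds)
  } else return(.finish_hits(.empty_hits(), L0, circular))
  # bucket seeds into coarse loci per period and keep well-supported ones
  sdf <- data.frame(pos = sm[, "pos"], per = sm[, "per"],
                    buck = sm[, "pos"] %/% 64L)
  agg <- stats::aggregate(pos ~ per + buck, data = sdf, FUN = min)
  agg$n <- stats::aggregate(pos ~ per + buck, data = sdf, FUN = length)$pos
  # spurious background spacings rarely recur within a locus; genuine
  # tandem arrays seed the same (period, locus) many times
  agg <- agg[agg$n >= 2L | agg$per <= 12L, , drop = FALSE]
  hits <- list()
  seen <- character(0)
  for (i in seq_len(nrow(agg))) {
    p <- agg$per[i]
    anchor <- agg$pos[i]
    key <- paste(p, anchor %/% max(p, 32L))
    if (key %in% seen) next
    seen <- c(seen, key)
    # window: a generous neighborhood around the anchor
    w0 <- max(1L, anchor - 2L * p)
    w1 <- min(L, anchor + 20L * p + 4L * k)
    res <- score_candidate(x[w0:w1], p, seed_at = anchor - w0 + 1L,
                           match = match, mismatch = mismatch)
    if (res$score < min_score) next
    s <- w0 + res$start - 1L; e <- w0 + res$end - 1L
    span <- e - s + 1L
    if (span < 1.8 * p) next
    xs <- x[s:e]
    tiled <- res$consensus[((seq_along(xs) - 1L) %% p) + 1L]
    ident <- 100 * mean(xs == tiled, na.rm = TRUE)
    hits[[length(hits) + 1L]] <- data.frame(
      start = s, end = e, period = p,
      copy_number = span / p,
      score = res$score, identity = ident,
      consensus = paste(decode_dna(res$consensus), collapse = ""),
      stringsAsFactors = FALSE)
  }
  out <- if (length(hits)) do.call(rbind, hits) else .empty_hits()
  out <- .dedupe_hits(out)
  .finish_hits(out, L0, circular)
}

.empty_hits <- function() {
  data.frame(start = integer(0), end = integer(0), period = integer(0),
             copy_number = numeric(0), score = numeric(0),
             identity = numeric(0), consensus = character(0),
             stringsAsFactors = FALSE)
}

# reduce heavily overlapping hits of one locus to a single period:
# the best score wins, except that a fundamental (smaller) period beats
# its own harmonics when it scores comparably: a true harmonic's
# fundamental explains almost the same span, while a spurious
# sub-period of a genuine long repeat scores far below it
.dedupe_hits <- function(h) {
  if (nrow(h) < 2L) return(h)
  pref <- order(-h$score, h$period, h$start)
  keep <- rep(TRUE, nrow(h))
  for (i in pref) {
    if (!keep[i]) next
    for (j in seq_len(nrow(h))) {
      if (j == i || !keep[j]) next
      ov <- min(h$end[i], h$end[j]) - max(h$start[i], h$start[j]) + 1L
      shorter <- min(h$end[i] - h$start[i], h$end[j] - h$start[j]) + 1L
      if (ov <= 0.5 * shorter) next
      harmonic_of_j <- h$period[i] %% h$period[j] == 0L &&
        h$period[i] > h$period[j] && h$score[j] >= 0.7 * h$score[i]
      if (harmonic_of_j) keep[i] <- FALSE else keep[j] <- FALSE
      if (!keep[i]) break
    }
  }
  h <- h[keep, , drop = FALSE]
  h[order(h$start), , drop = FALSE]
}

.finish_hits <- function(h, L0, circular) {
  if (circular && nrow(h)) {
    # drop duplicates living entirely in the pad; reduce wrapped coords
    h <- h[h$start <= L0, , drop = FALSE]
    h$end <- ifelse(h$end > L0, h$end - L0, h$end)
  }
  class(h) <- c("tandem_repeat_hits", class(h))
  h
}

#' Tandem repeats of the annotated control region
#'
#' Scans the control region (CR / D-loop) of a record and reports hits in
#' CR-relative coordinates (1 = first CR base), supporting cross-species
#' control-region layout tables. With \code{genome_wide = TRUE} the whole
#' genome is scanned too and hits are labelled by region.
#'
#' @param record A \code{mitogenome_record} with sequence and an annotated
#'   CR feature.
#' @param min_score Minimum alignment score (default 30).
#' @param genome_wide Also scan outside the CR.
#' @param ... Passed to \code{\link{find_tandem_repeats}}.
#' @return data.frame of hits with columns of
#'   \code{\link{find_tandem_repeats}} plus \code{region} ("CR" or
#'   "genome") ; CR hits use CR-relative coordinates.
#' @export
repeat_report <- function(record, min_score = 30L, genome_wide = FALSE, ...) {
  cr <- record$features[record$features$feature_class == "CR", , drop = FALSE]
  if (!nrow(cr)) stop("no CR feature annotated")
  cr_seq <- extract_region(record, cr[1L, ])
  hits <- find_tandem_repeats(cr_seq, min_score = min_score, ...)
  if (nrow(hits)) hits$region <- "CR"
  else hits$region <- character(0)
  if (genome_wide) {
    gw <- find_tandem_repeats(record$sequence, min_score = min_score,
                              circular = record$circular, ...)
    if (nrow(gw)) {
      gw$region <- "genome"
      hits <- rbind(hits, gw)
    }
  }
  hits
}
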