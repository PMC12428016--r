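# Nei-Gojobori (1986) dN/dS counting under the vertebrate mitochondrial
# code, plus a transparent foreground-specific substitution screen. The
# classic equal-pathway-weighting variant is used throughout: synonymous
# site fractions count only mutations that do not create a stop codon,
# and multi-difference codon pairs average synonymous / nonsynonymous
# step counts over all minimal mutational pathways, pathways through
# stop codons excluded.

.ng86_env <- new.env(parent = emptyenv())

# synonymous-site count s(c) per codon: at each position, the fraction of
# non-stop single-base changes that preserve the amino acid; n = 3 - s,
# so S + N = 3 per codon
.ng86_sites <- function() {
  if (!is.null(.ng86_env$sites)) return(.ng86_env$sites)
  code <- vert_mito_code()
  bases <- c("A", "C", "G", "T")
  sense <- names(code)[code != "*"]
  s <- stats::setNames(numeric(length(sense)), sense)
  for (cd in sense) {
    ch <- seq_chars(cd)
    tot <- 0
    for (pos in 1:3) {
      alt_syn <- 0L; alt_valid <- 0L
      for (b in setdiff(bases, ch[pos])) {
        mut <- ch; mut[pos] <- b
        mc <- paste(mut, collapse = "")
        if (code[[mc]] == "*") next
        alt_valid <- alt_valid + 1L
        if (code[[mc]] == code[[cd]]) alt_syn <- alt_syn + 1L
      }
      tot <- tot + if (alt_valid > 0L) alt_syn / alt_valid else 0
    }
    s[[cd]] <- tot
  }
  .ng86_env$sites <- s
  s
}

# average synonymous/nonsynonymous substitutions between two sense codons
# over all minimal pathways (stop-passing pathways excluded; if every
# pathway is blocked, all are used)
.ng86_path <- function(c1, c2) {
  code <- vert_mito_code()
  ch1 <- seq_chars(c1); ch2 <- seq_chars(c2)
  diffs <- which(ch1 != ch2)
  k <- length(diffs)
  if (k == 0L) return(c(sd = 0, nd = 0))
  perms <- switch(as.character(k),
    "1" = list(diffs),
    "2" = list(diffs, rev(diffs)),
    "3" = {
      p <- list()
      for (i in 1:3) for (j in 1:3) for (l in 1:3)
        if (length(unique(c(i, j, l))) == 3L)
          p[[length(p) + 1L]] <- diffs[c(i, j, l)]
      p
    })
  step_counts <- function(order_, allow_stops) {
    cur <- ch1; sd_ <- 0; nd_ <- 0
    for (pos in order_) {
      nxt <- cur; nxt[pos] <- ch2[pos]
      aa_from <- code[[paste(cur, collapse = "")]]
      aa_to <- code[[paste(nxt, collapse = "")]]
      if (aa_to == "*" && !allow_stops) return(NULL)
      if (aa_from == aa_to) sd_ <- sd_ + 1 else nd_ <- nd_ + 1
      cur <- nxt
    }
    c(sd = sd_, nd = nd_)
  }
  res <- lapply(perms, step_counts, allow_stops = FALSE)
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res)) res <- lapply(perms, step_counts, allow_stops = TRUE)
  m <- do.call(rbind, res)
  colMeans(m)
}

# 60x60 lookup of pathway-averaged (sd, nd) between sense codons
.ng86_pair_table <- function() {
  if (!is.null(.ng86_env$pair_sd)) return(NULL)
  sense <- names(.ng86_sites())
  n <- length(sense)
  sd_m <- matrix(0, n, n, dimnames = list(sense, sense))
  nd_m <- matrix(0, n, n, dimnames = list(sense, sense))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    v <- .ng86_path(sense[i], sense[j])
    sd_m[i, j] <- sd_m[j, i] <- v[["sd"]]
    nd_m[i, j] <- nd_m[j, i] <- v[["nd"]]
  }
  .ng86_env$pair_sd <- sd_m
  .ng86_env$pair_nd <- nd_m
  invisible(NULL)
}

# Jukes-Cantor multiple-hit correction of a proportion
jc_correct <- function(p) {
  ifelse(p < 0.75, -0.75 * log(1 - 4 * p / 3), NA_real_)
}

#' Pairwise dN/dS by the Nei-Gojobori (1986) method
#'
#' Counts synonymous (S) and nonsynonymous (N) sites averaged over the
#' two sequences, pathway-averaged synonymous (Sd) and nonsynonymous
#' (Nd) differences, the proportions pS = Sd/S and pN = Nd/N, optional
#' Jukes-Cantor corrected distances dS and dN, and omega = dN/dS. Codons
#' containing gaps, N, or a stop in either sequence are pairwise-deleted.
#' S + N = 3 x (number of comparable codons).
#'
#' @param codons_a,codons_b Equal-length character vectors of codons.
#' @param correct Apply the Jukes-Cantor correction
#'   d = -3/4 log(1 - 4p/3); a proportion >= 3/4 leaves the distance NA
#'   with a warning (saturation).
#' @param flag_threshold Per-codon nonsynonymous difference count at or
#'   above which a codon index is listed in \code{flagged_codons}.
#' @return List of class \code{dnds_result}: \code{n_codons}
#'   (comparable), \code{S}, \code{N}, \code{Sd}, \code{Nd}, \code{pS},
#'   \code{pN}, \code{dS}, \code{dN}, \code{omega} (NA when the
#'   denominator is 0), \code{flagged_codons} (1-based indices).
#' @export
ng86_pair <- function(codons_a, codons_b, correct = TRUE,
                      flag_threshold = 2) {
  if (length(codons_a) != length(codons_b))
    stop("codon lists differ in length")
  sites <- .ng86_sites()
  .ng86_pair_table()
  ok <- codons_a %in% names(sites) & codons_b %in% names(sites)
  a <- codons_a[ok]; b <- codons_b[ok]
  if (!length(a)) stop("no comparable codons")
  s_a <- sites[a]; s_b <- sites[b]
  S <- (sum(s_a) + sum(s_b)) / 2
  N <- 3 * length(a) - S
  ii <- cbind(match(a, rownames(.ng86_env$pair_sd)),
              match(b, colnames(.ng86_env$pair_sd)))
  sd_per <- .ng86_env$pair_sd[ii]
  nd_per <- .ng86_env$pair_nd[ii]
  Sd <- sum(sd_per); Nd <- sum(nd_per)
  pS <- if (S > 0) Sd / S else NA_real_
  pN <- if (N > 0) Nd / N else NA_real_
  if (correct) {
    dS <- jc_correct(pS); dN <- jc_correct(pN)
    if ((is.na(dS) && !is.na(pS) && pS >= 0.75) ||
        (is.na(dN) && !is.na(pN) && pN >= 0.75))
      warning("substitution proportion >= 3/4: distance saturated, left NA")
  } else {
    dS <- pS; dN <- pN
  }
  omega <- if (!is.na(dS) && !is.na(dN) && dS > 0) dN / dS else NA_real_
  structure(list(
    n_codons = length(a), S = S, N = N, Sd = Sd, Nd = Nd,
    pS = pS, pN = pN, dS = dS, dN = dN, omega = omega,
    flagged_codons = which(ok)[nd_per >= flag_threshold]
  ), class = "dnds_result")
}

#' @export
print.dnds_result <- function(x, ...) {
  cat("<dnds_result> ", x$n_codons, " codons\n", sep = "")
  cat(sprintf("  S = %.2f  N = %.2f  Sd = %.2f  Nd = %.2f\n",
              x$S, x$N, x$Sd, x$Nd))
  cat(sprintf("  pS = %.4f  pN = %.4f  dS = %s  dN = %s  omega = %s\n",
              x$pS, x$pN, format(x$dS, digits = 4),
              format(x$dN, digits = 4), format(x$omega, digits = 4)))
  invisible(x)
}

# split aligned DNA strings into a taxa x codon matrix
codon_alignment <- function(seqs) {
  lens <- unique(nchar(seqs))
  if (length(lens) != 1L) stop("aligned sequences differ in length")
  k <- lens %/% 3L
  m <- matrix(unlist(lapply(seqs, split_codons)), nrow = length(seqs),
              ncol = k, byrow = TRUE)
  rownames(m) <- names(seqs)
  m
}

#' Foreground-specific nonsynonymous substitution screen
#'
#' Flags codon positions where a designated foreground sequence carries a
#' nonsynonymous state that no background sequence has, while the
#' background itself is monomorphic at the amino-acid level -- a minimal,
#' fully specified analogue of branch-specific positive-selection site
#' screens. A per-gene binomial enrichment test compares the gene's flag
#' count against a baseline rate (by default the pooled rate over the
#' genes supplied), upper tail.
#'
#' @param alignments A single codon alignment (taxa x codon character
#'   matrix or named character vector of equal-length aligned DNA
#'   strings) or a named list of them, one per gene. >= 3 sequences each.
#' @param foreground Sequence (taxon) name present in every alignment.
#' @param p0 Baseline flag rate for the binomial test; default = pooled
#'   flagged / eligible over all supplied genes.
#' @param alpha Significance level used for the \code{enriched} verdict.
#' @return data.frame, one row per gene: gene, eligible_codons (background
#'   aa-monomorphic, no gaps), flagged (count), flagged_codons
#'   (comma-separated 1-based indices), p_value, enriched.
#' @export
sitewise_screen <- function(alignments, foreground, p0 = NULL,
                            alpha = 0.05) {
  if (!is.list(alignments) || is.data.frame(alignments))
    alignments <- list(gene = alignments)
  scan_gene <- function(aln) {
    if (!is.matrix(aln)) aln <- codon_alignment(aln)
    if (nrow(aln) < 3L) stop("need >= 3 sequences")
    if (!foreground %in% rownames(aln))
      stop("foreground '", foreground, "' not in alignment")
    code <- vert_mito_code()
    aa <- matrix(code[aln], nrow = nrow(aln),
                 dimnames = dimnames(aln))
    bg <- aa[setdiff(rownames(aa), foreground), , drop = FALSE]
    fg <- aa[foreground, ]
    mono <- apply(bg, 2L, function(col)
      !anyNA(col) && !any(col == "*") && length(unique(col)) == 1L)
    eligible <- which(mono & !is.na(fg) & fg != "*")
    flagged <- eligible[fg[eligible] != bg[1L, eligible]]
    list(m = length(eligible), x = length(flagged), idx = flagged)
  }
  scans <- lapply(alignments, scan_gene)
  if (is.null(p0)) {
    M <- sum(vapply(scans, `[[`, numeric(1), "m"))
    X <- sum(vapply(scans, `[[`, numeric(1), "x"))
    p0 <- if (M > 0) X / M else 0
  }
  rows <- lapply(names(scans), function(g) {
    sc <- scans[[g]]
    pv <- if (sc$m > 0 && p0 > 0 && p0 < 1)
      stats::binom.test(sc$x, sc$m, p0, alternative = "greater")$p.value
    else if (sc$x == 0) 1 else NA_real_
    data.frame(gene = g, eligible_codons = sc$m, flagged = sc$x,
               flagged_codons = paste(sc$idx, collapse = ","),
               p_value = pv, enriched = !is.na(pv) && pv < alpha,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-gene pairwise dN/dS table for two mitogenomes
#'
#' Runs \code{\link{ng86_pair}} gene-by-gene on the shared PCGs of two
#' records (genes matched by canonical label, sequences compared codon
#' -wise without realignment -- intended for equal-length orthologues such
#' as synthetic families).
#'
#' @param rec_a,rec_b \code{mitogenome_record}s with sequence.
#' @param correct Jukes-Cantor correction flag.
#' @return data.frame: gene, n_codons, dS, dN, omega, flagged_codons.
#' @export
dnds_table <- function(rec_a, rec_b, correct = TRUE) {
  pa <- rec_a$features[rec_a$features$feature_class == "PCG", , drop = FALSE]
  pb <- rec_b$features[rec_b$features$feature_class == "PCG", , drop = FALSE]
  shared <- intersect(.canon_label(pa$name), .canon_label(pb$name))
  rows <- lapply(shared, function(g) {
    fa <- pa[.canon_label(pa$name) == g, ][1L, ]
    fb <- pb[.canon_label(pb$name) == g, ][1L, ]
    ca <- extract_codons(rec_a, fa)$codons
    cb <- extract_codons(rec_b, fb)$codons
    k <- min(length(ca), length(cb))
    r <- ng86_pair(ca[seq_len(k)], cb[seq_len(k)], correct = correct)
    data.frame(gene = g, n_codons = r$n_codons, dS = r$dS, dN = r$dN,
               omega = r$omega,
               flagged_codons = paste(r$flagged_codons, collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
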