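# Independent oracles used across the suite. Each one recomputes a
# quantity by a different route than the package implementation:
# brute-force enumeration, closed forms, or a third-party code table.

# --- genetic code: independent source via Biostrings --------------------
oracle_mito_code <- function() {
  gc <- Biostrings::getGeneticCode("2")      # vertebrate mitochondrial
  names(gc) <- chartr("U", "T", names(gc))
  gc
}

# --- NG86: pathway-enumeration oracle ------------------------------------
# counts synonymous/nonsynonymous sites and differences by explicit
# enumeration, independently of the package's lookup tables
.oracle_cache <- new.env(parent = emptyenv())

oracle_ng86 <- function(codons_a, codons_b) {
  code <- oracle_mito_code()
  bases <- c("A", "C", "G", "T")
  site_s <- function(cd) {
    ch <- strsplit(cd, "")[[1]]
    tot <- 0
    for (pos in 1:3) {
      syn <- 0; valid <- 0
      for (b in bases[bases != ch[pos]]) {
        m <- ch; m[pos] <- b
        mc <- paste(m, collapse = "")
        if (code[[mc]] == "*") next
        valid <- valid + 1
        if (code[[mc]] == code[[cd]]) syn <- syn + 1
      }
      tot <- tot + if (valid > 0) syn / valid else 0
    }
    tot
  }
  path_sd_nd <- function(c1, c2) {
    ch1 <- strsplit(c1, "")[[1]]; ch2 <- strsplit(c2, "")[[1]]
    diffs <- which(ch1 != ch2)
    if (!length(diffs)) return(c(0, 0))
    perms <- if (length(diffs) == 1) list(diffs)
      else if (length(diffs) == 2) list(diffs, rev(diffs))
      else unlist(lapply(seq_len(6), function(i) NULL), use.names = FALSE)
    if (length(diffs) == 3) {
      perms <- list()
      for (pp in list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1),
                      c(3,1,2), c(3,2,1)))
        perms[[length(perms) + 1]] <- diffs[pp]
    }
    walk <- function(ord, allow) {
      cur <- ch1; sd_ <- 0; nd_ <- 0
      for (pos in ord) {
        nxt <- cur; nxt[pos] <- ch2[pos]
        a1 <- code[[paste(cur, collapse = "")]]
        a2 <- code[[paste(nxt, collapse = "")]]
        if (a2 == "*" && !allow) return(NULL)
        if (a1 == a2) sd_ <- sd_ + 1 else nd_ <- nd_ + 1
        cur <- nxt
      }
      c(sd_, nd_)
    }
    res <- Filter(Negate(is.null), lapply(perms, walk, allow = FALSE))
    if (!length(res)) res <- lapply(perms, walk, allow = TRUE)
    colMeans(do.call(rbind, res))
  }
  site_s_cached <- function(cd) {
    key <- paste0("s_", cd)
    v <- .oracle_cache[[key]]
    if (is.null(v)) { v <- site_s(cd); .oracle_cache[[key]] <- v }
    v
  }
  path_cached <- function(c1, c2) {
    key <- paste0("p_", c1, c2)
    v <- .oracle_cache[[key]]
    if (is.null(v)) { v <- path_sd_nd(c1, c2); .oracle_cache[[key]] <- v }
    v
  }
  sense <- names(code)[code != "*"]
  ok <- codons_a %in% sense & codons_b %in% sense
  a <- codons_a[ok]; b <- codons_b[ok]
  S <- (sum(vapply(a, site_s_cached, numeric(1))) +
        sum(vapply(b, site_s_cached, numeric(1)))) / 2
  N <- 3 * length(a) - S
  dd <- vapply(seq_along(a), function(i) path_cached(a[i], b[i]), numeric(2))
  list(S = S, N = N, Sd = sum(dd[1, ]), Nd = sum(dd[2, ]),
       pS = sum(dd[1, ]) / S, pN = sum(dd[2, ]) / N)
}

# random sense-codon sampler for oracle comparisons
random_sense_codons <- function(n) {
  sense <- setdiff(names(vert_mito_code())[vert_mito_code() != "*"], NULL)
  sample(sense, n, replace = TRUE)
}

# --- tandem repeats: exhaustive (period, phase) scorer -------------------
# best score over all periods, scanning the whole sequence with a
# whole-sequence majority consensus per period and a maximal-scoring
# subarray -- an independent, exhaustive counterpart of the seeded
# detector for short sequences
oracle_best_repeat <- function(seq, pmax = nchar(seq) %/% 2,
                               match = 2, mismatch = -7) {
  x <- match(strsplit(toupper(seq), "")[[1]], c("A", "C", "G", "T"))
  best <- list(score = -Inf, period = NA)
  for (p in 2:pmax) {
    col <- ((seq_along(x) - 1) %% p) + 1
    cons <- integer(p)
    for (j in 1:p) {
      tb <- tabulate(x[col == j], 4)
      cons[j] <- which.max(tb)
    }
    sc <- ifelse(x == cons[col], match, mismatch)
    # Kadane
    cur <- 0; bst <- -Inf; s0 <- 1; bs <- 1; be <- 0
    for (i in seq_along(sc)) {
      if (cur <= 0) { cur <- sc[i]; s0 <- i } else cur <- cur + sc[i]
      if (cur > bst) { bst <- cur; bs <- s0; be <- i }
    }
    if (bst > best$score && (be - bs + 1) >= 1.8 * p)
      best <- list(score = bst, period = p, start = bs, end = be)
  }
  best
}

# re-score a reported hit: align its span against its own consensus
rescore_hit <- function(seq, hit, match = 2, mismatch = -7) {
  span <- substr(seq, hit$start, hit$end)
  x <- strsplit(toupper(span), "")[[1]]
  cons <- strsplit(hit$consensus, "")[[1]]
  tiled <- cons[((seq_along(x) - 1) %% hit$period) + 1]
  sum(ifelse(x == tiled, match, mismatch))
}

# --- phylogeny: additive matrices from random trees ----------------------
random_additive_case <- function(ntaxa, seed) {
  set.seed(seed)
  tr <- ape::rtree(ntaxa, br = function(n) runif(n, 0.2, 1))
  dm <- ape::cophenetic.phylo(tr)
  dm <- dm[sort(rownames(dm)), sort(colnames(dm))]
  list(tree = tr, dm = dm)
}

# K2P closed form from transition/transversion proportions
k2p_closed_form <- function(P, Q) {
  0.5 * log(1 / (1 - 2 * P - Q)) + 0.25 * log(1 / (1 - 2 * Q))
}

# --- small record builders ----------------------------------------------
# single-PCG record around a given coding-strand sequence
one_gene_record <- function(coding, strand = "+", id = "toy",
                            start_codon = "ATG", stop_codon = "TAA") {
  seqn <- if (strand == "-") mitoray::revcomp(coding) else coding
  feat <- gene_feature("GENE1", "PCG", strand, 1L, nchar(coding),
                       start_codon = start_codon, stop_codon = stop_codon)
  mitogenome_record(id, feat, sequence = seqn)
}

# record with k equal-length PCGs laid end to end (for screen tests)
multi_gene_record <- function(k = 5L, codons_per_gene = 100L, seed = 1L,
                              id = "multi") {
  set.seed(seed)
  pieces <- character(k)
  feats <- list()
  pos <- 1L
  for (i in seq_len(k)) {
    body <- paste(random_sense_codons(codons_per_gene - 2L), collapse = "")
    coding <- paste0("ATG", body, "TAA")
    feats[[i]] <- gene_feature(paste0("G", i), "PCG", "+", pos,
                               pos + nchar(coding) - 1L,
                               start_codon = "ATG", stop_codon = "TAA")
    pieces[i] <- coding
    pos <- pos + nchar(coding)
  }
  mitogenome_record(id, do.call(rbind, feats),
                    sequence = paste(pieces, collapse = ""))
}
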