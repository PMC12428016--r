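# Synthetic mitogenome generator and tree-guided sequence evolver: the
# clean-room control for every analysis stage. Generated records carry
# the canonical vertebrate gene order and strand layout, class-specific
# base composition, configurable codon-usage bias, and a control region
# with planted tandem repeats; families of records are evolved along a
# guide tree with configurable transition bias and dN/dS.

.default_composition <- function() {
  list(
    # class-specific A/C/G/T fractions emulating a strongly A-rich,
    # C-poor heavy strand (whole-genome and rRNA values follow the
    # published P. leopoldi profile; tRNA reuses the genome-wide profile)
    PCG  = c(A = 0.3232, C = 0.1284, G = 0.3042, T = 0.2441),
    tRNA = c(A = 0.3232, C = 0.1284, G = 0.3042, T = 0.2441),
    rRNA = c(A = 0.3563, C = 0.2598, G = 0.1727, T = 0.2112),
    CR   = c(A = 0.3355, C = 0.2430, G = 0.1224, T = 0.2992)
  )
}

# the published gene template: order, class, strand, computed length and
# codon annotations, from the packaged feature table
.pleopoldi_template <- function() {
  rec <- pleopoldi_annotation()
  f <- rec$features
  data.frame(
    name = f$name, feature_class = f$feature_class, strand = f$strand,
    length = feature_length(f$start, f$stop, rec$genome_length),
    start_codon = f$start_codon, stop_codon = f$stop_codon,
    stringsAsFactors = FALSE
  )
}

#' Specification for a synthetic mitogenome
#'
#' Collects the dials of \code{\link{generate_genome}}. The defaults
#' reproduce the structure every analysis stage assumes: the canonical
#' vertebrate gene order with its 28 heavy- and 9 light-strand genes,
#' class-specific A-rich base composition, per-gene lengths equal to the
#' published coordinate-computed lengths (including the two genes ending
#' in incomplete stop codons), and a control region carrying one 128 bp
#' and one 20 bp tandem-repeat array.
#'
#' @param seed Integer seed governing all randomness.
#' @param template "pleopoldi" for the full 38-feature layout, or "plain"
#'   for a single unannotated-composition genome (one CR-class feature
#'   spanning it) of length \code{genome_length}.
#' @param genome_length Length for \code{template = "plain"}.
#' @param composition Named list of A/C/G/T fraction vectors per feature
#'   class (PCG, tRNA, rRNA, CR); each must sum to 1.
#' @param codon_bias NULL for composition-driven (weak-bias) codon
#'   sampling, or a positive Dirichlet concentration: per-family codon
#'   weights are drawn once per genome from Dirichlet(concentration);
#'   small values (e.g. 0.1) give strongly biased usage and low ENc.
#' @param cr_length Control-region length in bp.
#' @param cr_repeats List of planted repeat specs, each
#'   \code{list(period =, copies =, mutation =)}; defaults plant a
#'   128 bp x 4 and a 20 bp x 6 array at 5 percent per-base mutation.
#' @param spacer Intergenic spacer in bp inserted between features.
#' @return List of class \code{synthetic_genome_spec}.
#' @export
synthetic_genome_spec <- function(seed = 1L,
                                  template = c("pleopoldi", "plain"),
                                  genome_length = 17000L,
                                  composition = .default_composition(),
                                  codon_bias = NULL,
                                  cr_length = 1811L,
                                  cr_repeats = list(
                                    list(period = 128L, copies = 4L,
                                         mutation = 0.05),
                                    list(period = 20L, copies = 6L,
                                         mutation = 0.05)),
                                  spacer = 0L) {
  template <- match.arg(template)
  for (cls in names(composition)) {
    fr <- composition[[cls]]
    # printed profiles round to two decimals, so allow slight drift and
    # renormalize
    if (abs(sum(fr) - 1) > 0.02)
      stop("composition fractions for ", cls, " must sum to 1")
    if (any(fr < 0)) stop("negative composition fraction")
    composition[[cls]] <- fr / sum(fr)
  }
  structure(list(seed = as.integer(seed), template = template,
                 genome_length = as.integer(genome_length),
                 composition = composition, codon_bias = codon_bias,
                 cr_length = as.integer(cr_length),
                 cr_repeats = cr_repeats, spacer = as.integer(spacer)),
            class = "synthetic_genome_spec")
}

.random_dna <- function(n, probs) {
  paste(sample(names(probs), n, replace = TRUE, prob = probs),
        collapse = "")
}

# sample k sense codons; either composition-driven (3 iid bases,
# stop codons rejected) or family-biased (Dirichlet weights per family)
.sample_codons <- function(k, probs, bias_weights = NULL) {
  if (k <= 0L) return(character(0))
  if (is.null(bias_weights)) {
    stops <- mito_stop_codons()
    out <- character(0)
    while (length(out) < k) {
      need <- k - length(out)
      b <- matrix(sample(names(probs), 3L * (need + 4L), replace = TRUE,
                         prob = probs), ncol = 3L)
      cand <- paste0(b[, 1L], b[, 2L], b[, 3L])
      out <- c(out, cand[!cand %in% stops])
    }
    out[seq_len(k)]
  } else {
    sample(names(bias_weights), k, replace = TRUE, prob = bias_weights)
  }
}

# Dirichlet draw of per-codon weights: amino acids weighted by their
# degeneracy (so every family is exercised), codons within a family by a
# Dirichlet(alpha) draw
.dirichlet_codon_weights <- function(alpha) {
  fam <- codon_families()
  w <- numeric(nrow(fam))
  for (a in unique(fam$aa)) {
    ix <- which(fam$aa == a)
    g <- stats::rgamma(length(ix), shape = alpha)
    if (sum(g) == 0) g[sample.int(length(g), 1L)] <- 1
    w[ix] <- (g / sum(g)) * length(ix)
  }
  stats::setNames(w / sum(w), fam$codon)
}

# build one tandem repeat array: motif repeated with per-copy per-base
# point mutations
.plant_repeat <- function(period, copies, mutation, probs) {
  motif <- seq_chars(.random_dna(period, probs))
  bases <- c("A", "C", "G", "T")
  arr <- character(0)
  for (i in seq_len(copies)) {
    cp <- motif
    nm <- stats::rbinom(1L, period, mutation)
    if (nm > 0L) {
      pos <- sample.int(period, nm)
      for (p in pos) cp[p] <- sample(setdiff(bases, cp[p]), 1L)
    }
    arr <- c(arr, cp)
  }
  list(motif = paste(motif, collapse = ""),
       seq = paste(arr, collapse = ""))
}

.build_control_region <- function(cr_length, cr_repeats, probs) {
  arrays <- lapply(cr_repeats, function(rp)
    .plant_repeat(rp$period, rp$copies, rp$mutation, probs))
  arr_len <- vapply(arrays, function(a) nchar(a$seq), numeric(1))
  bg_total <- cr_length - sum(arr_len)
  if (bg_total < length(arrays) + 1L)
    stop("cr_length too small for the planted repeats")
  # split background into n_arrays + 1 chunks around the arrays
  kck <- length(arrays) + 1L
  cuts <- if (kck > 1L)
    sort(sample.int(bg_total - kck, kck - 1L)) + seq_len(kck - 1L)
  else integer(0)
  chunk_len <- diff(c(0L, cuts, bg_total))
  cr <- .random_dna(chunk_len[1L], probs)
  starts <- integer(length(arrays))
  for (ai in seq_along(arrays)) {
    starts[ai] <- nchar(cr) + 1L
    cr <- paste0(cr, arrays[[ai]]$seq, .random_dna(chunk_len[ai + 1L], probs))
  }
  truth <- data.frame(
    start = starts,
    period = vapply(cr_repeats, function(r) as.numeric(r$period), numeric(1)),
    copies = vapply(cr_repeats, function(r) as.numeric(r$copies), numeric(1)),
    motif = vapply(arrays, `[[`, character(1), "motif"),
    stringsAsFactors = FALSE)
  list(seq = cr, truth = truth)
}

#' Generate a synthetic control region with planted tandem repeats
#'
#' Stand-alone access to the control-region model of
#' \code{\link{generate_genome}}: an AT-rich composition-sampled
#' background with the given repeat arrays planted at random, seeded
#' loci.
#'
#' @param cr_length Total length in bp.
#' @param cr_repeats List of \code{list(period =, copies =, mutation =)}
#'   specs (defaults as in \code{\link{synthetic_genome_spec}}).
#' @param composition A/C/G/T fraction vector (defaults to the CR
#'   profile).
#' @param seed Integer seed.
#' @return List: \code{seq} (the CR string) and \code{truth} (data.frame
#'   start / period / copies / motif of the planted arrays).
#' @export
generate_control_region <- function(cr_length = 1811L,
                                    cr_repeats = list(
                                      list(period = 128L, copies = 4L,
                                           mutation = 0.05),
                                      list(period = 20L, copies = 6L,
                                           mutation = 0.05)),
                                    composition = NULL, seed = 1L) {
  set.seed(seed)
  if (is.null(composition)) composition <- .default_composition()$CR
  composition <- composition / sum(composition)
  .build_control_region(as.integer(cr_length), cr_repeats, composition)
}

#' Generate a synthetic mitogenome
#'
#' Emits a circular \code{\link{mitogenome_record}} under the given spec,
#' together with ground-truth annotations. Protein-coding genes start
#' with their template start codon (ATG, or GTG where the template says
#' so), end with their template stop -- emitting a trailing "T" or "TA"
#' for incomplete stops -- and contain no internal stop codons;
#' light-strand genes are inserted reverse-complemented. tRNA and rRNA
#' regions follow their class composition. The control region is
#' composition-sampled with the spec's repeat arrays planted at distinct
#' loci. Generated declared lengths always equal computed lengths, so
#' \code{\link{validate_annotation}} reports zero discrepancies: the
#' generator is the clean-room control.
#'
#' @param spec A \code{\link{synthetic_genome_spec}}.
#' @return A \code{mitogenome_record} with attribute \code{truth}: list
#'   with \code{repeats} (data.frame of planted arrays in CR-relative
#'   coordinates: start, period, copies, motif) and \code{codon_weights}
#'   (when codon bias was drawn).
#' @export
generate_genome <- function(spec = synthetic_genome_spec()) {
  set.seed(spec$seed)
  comp <- spec$composition
  if (spec$template == "plain") {
    seqn <- .random_dna(spec$genome_length, comp$CR)
    feats <- gene_feature("region", "CR", "+", 1L, spec$genome_length,
                          declared_length = spec$genome_length)
    rec <- mitogenome_record(sprintf("synthetic-plain-%d", spec$seed),
                             feats, sequence = seqn)
    attr(rec, "truth") <- list(repeats = NULL)
    return(rec)
  }
  tmpl <- .pleopoldi_template()
  tmpl$length[tmpl$feature_class == "CR"] <- spec$cr_length
  bias_w <- if (!is.null(spec$codon_bias))
    .dirichlet_codon_weights(spec$codon_bias) else NULL
  pieces <- character(nrow(tmpl))
  truth_rep <- NULL
  for (i in seq_len(nrow(tmpl))) {
    cls <- tmpl$feature_class[i]
    L <- tmpl$length[i]
    if (cls == "PCG") {
      tail_nt <- L %% 3L
      n_codons <- L %/% 3L
      stop_c <- tmpl$stop_codon[i]
      has_complete_stop <- tail_nt == 0L && !grepl("(", stop_c, fixed = TRUE)
      n_body <- n_codons - 1L - as.integer(has_complete_stop)
      if (n_body < 0L) stop("gene ", tmpl$name[i], " too short for template")
      body <- .sample_codons(n_body, comp$PCG, bias_w)
      coding <- paste0(tmpl$start_codon[i], paste(body, collapse = ""))
      if (has_complete_stop) coding <- paste0(coding, stop_c)
      if (tail_nt == 1L) coding <- paste0(coding, "T")
      if (tail_nt == 2L) coding <- paste0(coding, "TA")
      pieces[i] <- if (tmpl$strand[i] == "-") revcomp(coding) else coding
    } else if (cls == "CR") {
      crg <- .build_control_region(spec$cr_length, spec$cr_repeats, comp$CR)
      truth_rep <- crg$truth
      pieces[i] <- crg$seq
    } else {
      pieces[i] <- .random_dna(L, comp[[cls]])
    }
    if (spec$spacer > 0L && i < nrow(tmpl))
      pieces[i] <- paste0(pieces[i], .random_dna(spec$spacer, comp$tRNA))
  }
  lens <- nchar(pieces)
  starts <- cumsum(c(1L, lens[-length(lens)]))
  stops <- starts + tmpl$length - 1L
  feats <- do.call(rbind, lapply(seq_len(nrow(tmpl)), function(i)
    gene_feature(tmpl$name[i], tmpl$feature_class[i], tmpl$strand[i],
                 starts[i], stops[i], declared_length = tmpl$length[i],
                 start_codon = tmpl$start_codon[i],
                 stop_codon = tmpl$stop_codon[i])))
  rec <- mitogenome_record(sprintf("synthetic-%d", spec$seed), feats,
                           sequence = paste(pieces, collapse = ""))
  attr(rec, "truth") <- list(repeats = truth_rep,
                             codon_weights = bias_w)
  rec
}

# ---- tree-guided evolution --------------------------------------------------

#' Specification for the sequence evolver
#'
#' @param tree Guide tree: an \code{ape::phylo} object or a Newick
#'   string, with branch lengths in expected nucleotide substitution
#'   attempts per site.
#' @param kappa Transition/transversion rate ratio of the proposal
#'   process (default 1: symmetric proposals, matching the assumptions of
#'   the counting estimators the evolver is used to calibrate).
#' @param omega Probability that a proposed nonsynonymous change in a
#'   protein-coding gene is accepted (dN/dS dial); synonymous proposals
#'   are always accepted, proposals creating stop codons always rejected.
#' @param seed Integer seed.
#' @return List of class \code{evolver_spec}.
#' @export
evolver_spec <- function(tree, kappa = 1, omega = 1, seed = 1L) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  if (is.null(tree$edge.length)) stop("guide tree needs branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch length")
  structure(list(tree = tree, kappa = kappa, omega = omega,
                 seed = as.integer(seed)),
            class = "evolver_spec")
}

# kappa-weighted single-base proposal; bases coded A=1 C=2 G=3 T=4;
# transitions A<->G (1,3) and C<->T (2,4)
.propose_base <- function(base, kappa) {
  ti <- c(3L, 4L, 1L, 2L)[base]
  tv <- list(c(2L, 4L), c(1L, 3L), c(2L, 4L), c(1L, 3L))[[base]]
  w <- c(kappa, 1, 1)
  sample(c(ti, tv), 1L, prob = w)
}

# evolve an integer-coded nucleotide vector along one branch (K2P-style)
.evolve_noncoding <- function(x, b, kappa) {
  n_ev <- stats::rpois(1L, b * length(x))
  if (n_ev == 0L) return(x)
  pos <- sample.int(length(x), n_ev, replace = TRUE)
  for (p in pos) x[p] <- .propose_base(x[p], kappa)
  x
}

# evolve a codon vector (character) along one branch under the
# proposal-acceptance omega model
.evolve_coding <- function(codons, b, kappa, omega) {
  code <- vert_mito_code()
  n_sites <- 3L * length(codons)
  n_ev <- stats::rpois(1L, b * n_sites)
  if (n_ev == 0L) return(codons)
  sites <- sample.int(n_sites, n_ev, replace = TRUE)
  for (s in sites) {
    ci <- (s - 1L) %/% 3L + 1L
    pos <- (s - 1L) %% 3L + 1L
    ch <- seq_chars(codons[ci])
    old_code <- match(ch[pos], c("A", "C", "G", "T"))
    new_base <- c("A", "C", "G", "T")[.propose_base(old_code, kappa)]
    ch2 <- ch; ch2[pos] <- new_base
    cand <- paste(ch2, collapse = "")
    if (code[[cand]] == "*") next
    if (code[[cand]] != code[[codons[ci]]] && stats::runif(1L) > omega) next
    codons[ci] <- cand
  }
  codons
}

# decompose a record into evolvable segments in genome order
.segmentize <- function(record) {
  f <- record$features
  L <- record$genome_length
  segs <- list()
  covered <- rep(FALSE, L)
  pcg <- which(f$feature_class == "PCG")
  for (i in pcg) {
    coding <- extract_region(record, f[i, ])
    k <- nchar(coding) %/% 3L
    segs[[length(segs) + 1L]] <- list(
      type = "coding", name = f$name[i], strand = f$strand[i],
      start = f$start[i], stop = f$stop[i],
      codons = split_codons(coding),
      trailing = substr(coding, 3L * k + 1L, nchar(coding)))
    covered[f$start[i]:f$stop[i]] <- TRUE
  }
  # everything not inside a PCG evolves under the noncoding model
  run <- rle(covered)
  ends <- cumsum(run$lengths)
  starts <- c(1L, head(ends, -1L) + 1L)
  for (r in seq_along(run$values)) {
    if (run$values[r]) next
    segs[[length(segs) + 1L]] <- list(
      type = "noncoding", start = starts[r], stop = ends[r],
      bases = encode_dna(substr(record$sequence, starts[r], ends[r])))
  }
  segs
}

.assemble <- function(segs, L) {
  chars <- rep("A", L)
  for (sg in segs) {
    s <- if (sg$type == "coding") {
      cs <- paste0(paste(sg$codons, collapse = ""), sg$trailing)
      if (sg$strand == "-") revcomp(cs) else cs
    } else paste(decode_dna(sg$bases), collapse = "")
    substr_span <- sg$start:sg$stop
    chars[substr_span] <- seq_chars(s)
  }
  paste(chars, collapse = "")
}

#' Evolve a family of mitogenomes along a guide tree
#'
#' Starting from a root record, evolves every region independently along
#' the guide tree: protein-coding genes under a codon-level
#' proposal-acceptance model with dN/dS dial \code{omega} (proposals
#' creating stop codons are rejected; nonsynonymous proposals accepted
#' with probability omega), all other positions under a K2P-style
#' nucleotide model with transition bias \code{kappa}. No indel process:
#' the true alignment of the leaves is the trivial one.
#'
#' @param root A \code{mitogenome_record} with sequence (e.g. from
#'   \code{\link{generate_genome}}).
#' @param espec An \code{\link{evolver_spec}}.
#' @return List: \code{records} (named list of leaf
#'   \code{mitogenome_record}s), \code{sequences} (named character
#'   vector of leaf genome strings, a ready-made whole-genome
#'   alignment), \code{alignments} (named list per PCG of taxa x codon
#'   character matrices), \code{tree} (the guide \code{phylo}).
#' @export
evolve_family <- function(root, espec) {
  if (is.na(root$sequence)) stop("root record has no sequence")
  set.seed(espec$seed)
  tree <- espec$tree
  ntip <- length(tree$tip.label)
  if (ntip < 3L) stop("guide tree needs >= 3 leaves")
  root_segs <- .segmentize(root)
  root_node <- ntip + 1L
  node_state <- vector("list", ntip + tree$Nnode)
  node_state[[root_node]] <- root_segs
  # preorder traversal
  tre2 <- stats::reorder(tree, "cladewise")
  edges <- tre2$edge
  edge_len <- tre2$edge.length
  for (e in seq_len(nrow(edges))) {
    par <- edges[e, 1L]; child <- edges[e, 2L]
    b <- edge_len[e]
    segs <- node_state[[par]]
    segs <- lapply(segs, function(sg) {
      if (sg$type == "coding")
        sg$codons <- .evolve_coding(sg$codons, b, espec$kappa, espec$omega)
      else
        sg$bases <- .evolve_noncoding(sg$bases, b, espec$kappa)
      sg
    })
    node_state[[child]] <- segs
  }
  leaves <- stats::setNames(seq_len(ntip), tree$tip.label)
  seqs <- vapply(leaves, function(nd)
    .assemble(node_state[[nd]], root$genome_length), character(1))
  records <- lapply(names(seqs), function(tax)
    mitogenome_record(tax, root$features, sequence = seqs[[tax]]))
  names(records) <- names(seqs)
  pcg_names <- vapply(Filter(function(s) s$type == "coding", root_segs),
                      `[[`, character(1), "name")
  alignments <- lapply(pcg_names, function(g) {
    m <- do.call(rbind, lapply(names(leaves), function(tax) {
      sg <- Filter(function(s) s$type == "coding" &&
                     identical(s$name, g), node_state[[leaves[[tax]]]])[[1]]
      sg$codons
    }))
    rownames(m) <- names(leaves)
    m
  })
  names(alignments) <- pcg_names
  list(records = records, sequences = seqs, alignments = alignments,
       tree = tree)
}
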