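# Distance-based phylogeny: hand-written p / Kimura two-parameter
# distances with pairwise deletion, neighbor joining (via ape's
# agglomeration, with negative branch lengths clamped), nonparametric
# bootstrap over alignment columns, and outgroup-rooted monophyly tests.

#' Pairwise distance matrix from an alignment
#'
#' Computes p-distances or Kimura two-parameter (K2P) distances between
#' all pairs of aligned sequences. Columns where either sequence carries
#' a gap ("-") or N are deleted pairwise. K2P uses the transition (P)
#' and transversion (Q) proportions:
#' \deqn{d = \tfrac12 \ln\frac{1}{1-2P-Q} + \tfrac14 \ln\frac{1}{1-2Q}.}
#' A saturated pair (log argument <= 0) or a pair with zero comparable
#' columns is an error.
#'
#' @param alignment Named character vector of equal-length aligned DNA
#'   strings, or a taxa x site character matrix.
#' @param model "p" or "K2P".
#' @return Symmetric numeric matrix with taxon dimnames, zero diagonal,
#'   and attribute \code{model}.
#' @export
pairwise_distances <- function(alignment, model = c("p", "K2P")) {
  model <- match.arg(model)
  m <- .aln_matrix(alignment)
  n <- nrow(m)
  if (n < 2L) stop("need >= 2 taxa")
  labs <- rownames(m)
  d <- matrix(0, n, n, dimnames = list(labs, labs))
  purines <- c("A", "G")
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    a <- m[i, ]; b <- m[j, ]
    ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
    if (!any(ok)) stop("no comparable columns for pair ",
                       labs[i], " / ", labs[j])
    a <- a[ok]; b <- b[ok]
    diff <- a != b
    if (model == "p") {
      d[i, j] <- d[j, i] <- mean(diff)
    } else {
      ti <- diff & ((a %in% purines) == (b %in% purines))
      P <- mean(ti); Q <- mean(diff & !ti)
      arg1 <- 1 - 2 * P - Q; arg2 <- 1 - 2 * Q
      if (arg1 <= 0 || arg2 <= 0)
        stop("K2P distance saturated for pair ", labs[i], " / ", labs[j])
      d[i, j] <- d[j, i] <- 0.5 * log(1 / arg1) + 0.25 * log(1 / arg2)
    }
  }
  attr(d, "model") <- model
  d
}

.aln_matrix <- function(alignment) {
  if (is.matrix(alignment)) return(alignment)
  lens <- unique(nchar(alignment))
  if (length(lens) != 1L) stop("aligned sequences differ in length")
  m <- matrix(unlist(strsplit(toupper(alignment), "", fixed = TRUE)),
              nrow = length(alignment), byrow = TRUE)
  rownames(m) <- names(alignment)
  m
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Q-criterion agglomeration (exact on additive matrices).
#' Negative branch lengths -- an artefact NJ can produce on noisy
#' matrices -- are clamped to zero with the deficit moved to the adjacent
#' branch, preserving leaf-to-leaf path lengths where possible.
#'
#' @param dm Symmetric distance matrix with taxon dimnames (>= 3 taxa,
#'   complete: no NA).
#' @return An unrooted \code{ape::phylo} tree.
#' @export
neighbor_joining <- function(dm) {
  if (anyNA(dm)) stop("incomplete distance matrix")
  if (nrow(dm) < 3L) stop("need >= 3 taxa")
  # deterministic tie-breaking: agglomerate with taxa in label order
  ord <- order(rownames(dm))
  tree <- ape::nj(dm[ord, ord])
  if (any(tree$edge.length < 0)) {
    # move each negative length onto its sibling/parent edge
    for (e in which(tree$edge.length < 0)) {
      deficit <- tree$edge.length[e]
      tree$edge.length[e] <- 0
      parent <- tree$edge[e, 1L]
      sib <- which(tree$edge[, 1L] == parent)
      sib <- setdiff(sib, e)
      if (length(sib))
        tree$edge.length[sib[1L]] <- tree$edge.length[sib[1L]] + deficit
    }
    tree$edge.length[tree$edge.length < 0] <- 0
  }
  tree
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree on
#' each replicate, and reports for every internal bipartition of the
#' full-data tree the fraction of replicates containing it. These are
#' nonparametric bootstrap proportions, not posterior probabilities.
#'
#' @param alignment As in \code{\link{pairwise_distances}}.
#' @param model "p" or "K2P".
#' @param replicates Number of bootstrap replicates (>= 1).
#' @param seed Integer seed; resampling is reproducible given it.
#' @return The NJ tree (\code{ape::phylo}) on the full alignment with
#'   \code{node.label} set to support proportions in [0, 1] (root label
#'   empty).
#' @export
bootstrap_support <- function(alignment, model = c("p", "K2P"),
                              replicates = 100L, seed = 1L) {
  model <- match.arg(model)
  m <- .aln_matrix(alignment)
  main <- neighbor_joining(pairwise_distances(m, model))
  set.seed(seed)
  ncol_ <- ncol(m)
  reps <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    idx <- sample.int(ncol_, ncol_, replace = TRUE)
    reps[[r]] <- neighbor_joining(pairwise_distances(m[, idx, drop = FALSE],
                                                     model))
  }
  counts <- ape::prop.clades(main, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  main$node.label <- counts / replicates
  main
}

#' Test monophyly of a taxon set after outgroup rooting
#'
#' Roots the tree on the outgroup and asks whether the given taxa form a
#' complete clade.
#'
#' @param tree An \code{ape::phylo} tree containing all labels.
#' @param taxa Character vector of ingroup labels (subset of leaves,
#'   excluding the outgroup).
#' @param outgroup Single leaf label to root on.
#' @return List: \code{monophyletic} (logical) and \code{clade_taxa}
#'   (leaves of the smallest clade containing \code{taxa} in the rooted
#'   tree -- equal to \code{taxa} iff monophyletic).
#' @export
is_monophyletic <- function(tree, taxa, outgroup) {
  labs <- tree$tip.label
  unknown <- setdiff(c(taxa, outgroup), labs)
  if (length(unknown)) stop("unknown label(s): ",
                            paste(unknown, collapse = ", "))
  if (outgroup %in% taxa) stop("outgroup must not be in taxa")
  rooted <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  if (length(taxa) <= 1L)
    return(list(monophyletic = TRUE, clade_taxa = taxa))
  mono <- ape::is.monophyletic(rooted, taxa)
  mrca <- ape::getMRCA(rooted, taxa)
  clade <- ape::extract.clade(rooted, mrca)$tip.label
  list(monophyletic = mono, clade_taxa = clade)
}

#' Read an aligned FASTA file
#' @param path FASTA with equal-length aligned sequences.
#' @return Named character vector of uppercase sequences.
#' @export
read_alignment <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  stats::setNames(toupper(as.character(set)), names(set))
}

#' Write a PHYLIP-style distance matrix
#' @param dm Distance matrix.
#' @param path Output path.
#' @export
write_phylip_dm <- function(dm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(dm)), con)
  for (i in seq_len(nrow(dm)))
    writeLines(paste0(sprintf("%-10s", rownames(dm)[i]),
                      paste(sprintf("%.6f", dm[i, ]), collapse = " ")), con)
  invisible(path)
}
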