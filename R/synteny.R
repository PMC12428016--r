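# Gene-order (synteny) comparison across circular mitogenomes:
# canonical label vocabulary, rotation-normalized signed orders, and
# breakpoint counting on shared genes.

# synonym map for the cross-database label chaos; duplicated tRNAs
# (Leu, Ser) are disambiguated afterwards by coordinate rank
.canon_label <- function(x) {
  y <- toupper(gsub("[ _]", "", x))
  y <- sub("^TRN([A-Z])$", "TRNA-\\1", y)
  swaps <- c(
    "COXI" = "COX1", "COI" = "COX1", "COXII" = "COX2", "COII" = "COX2",
    "COXIII" = "COX3", "COIII" = "COX3",
    "CYTB" = "CYTB", "CYB" = "CYTB", "COB" = "CYTB",
    "12SRRNA" = "RRNS", "16SRRNA" = "RRNL", "12S" = "RRNS", "16S" = "RRNL",
    "DLOOP" = "CR", "D-LOOP" = "CR"
  )
  ifelse(y %in% names(swaps), swaps[y], y)
}

#' Signed gene order of a mitogenome
#'
#' The rotation-normalized, signed (strand-carrying) circular gene order
#' of a record: labels are canonicalized (COXI -> COX1, 12S rRNA -> RRNS,
#' ...), duplicate tRNA labels (the two Leu and two Ser genes) are
#' disambiguated by coordinate rank ("#1", "#2"), the CR is dropped
#' (gene-order comparisons concern genes), and the circle is rotated to
#' start at tRNA-Phe when present, else at the lexicographically minimal
#' label.
#'
#' @param record A \code{mitogenome_record} with >= 1 feature.
#' @return Object of class \code{gene_order}: list with \code{record_id},
#'   \code{labels} (character), \code{strands} (+/-) in circular order.
#' @export
gene_order <- function(record) {
  f <- record$features
  if (is.null(f) || nrow(f) < 1L) stop("record has no features")
  f <- f[f$feature_class != "CR", , drop = FALSE]
  lab <- .canon_label(f$name)
  dup <- names(which(table(lab) > 1L))
  for (d in dup) {
    ix <- which(lab == d)
    ix <- ix[order(f$start[ix])]
    lab[ix] <- paste0(d, "#", seq_along(ix))
  }
  if (anyDuplicated(lab)) stop("unresolvable duplicate gene labels")
  anchor <- grep("^TRNA-PHE", lab)
  rot <- if (length(anchor)) anchor[1L] else which(lab == min(lab))[1L]
  idx <- c(rot:length(lab), seq_len(rot - 1L))
  structure(list(record_id = record$record_id,
                 labels = lab[idx], strands = f$strand[idx]),
            class = "gene_order")
}

#' @export
print.gene_order <- function(x, ...) {
  cat("<gene_order> ", x$record_id, " (", length(x$labels), " genes)\n",
      sep = "")
  cat("  ", paste0(x$labels, "(", x$strands, ")", collapse = " "), "\n",
      sep = "")
  invisible(x)
}

# unordered circular adjacencies of a label sequence
.adjacencies <- function(labels) {
  n <- length(labels)
  if (n < 2L) return(character(0))
  nxt <- c(labels[-1L], labels[1L])
  a <- pmin(labels, nxt); b <- pmax(labels, nxt)
  paste(a, b, sep = "|")
}

#' Compare two circular gene orders
#'
#' Restricts both orders to their shared gene set, then counts
#' breakpoints: circular gene adjacencies (unordered neighbor pairs)
#' present in one order but not the other. Strand changes are tallied
#' separately -- a gene flipped in place contributes no breakpoint, one
#' strand disagreement. Orders are declared \code{identical} when both
#' the rotation-normalized label sequence and all strands agree.
#'
#' @param a,b \code{gene_order} objects.
#' @return List of class \code{synteny_comparison}: \code{pair},
#'   \code{shared} (gene labels), \code{breakpoints} (integer),
#'   \code{strand_disagreements} (labels), \code{identical} (logical).
#' @export
compare_orders <- function(a, b) {
  shared <- intersect(a$labels, b$labels)
  if (!length(shared)) stop("disjoint gene sets")
  ka <- a$labels[a$labels %in% shared]
  kb <- b$labels[b$labels %in% shared]
  adj_a <- .adjacencies(ka)
  adj_b <- .adjacencies(kb)
  bp <- length(setdiff(adj_a, adj_b))
  sa <- a$strands[match(shared, a$labels)]
  sb <- b$strands[match(shared, b$labels)]
  flips <- shared[sa != sb]
  # rotation-normalize the restricted sequences to a common anchor
  rot_to <- function(v, g) { i <- match(g, v); c(v[i:length(v)], v[seq_len(i - 1L)]) }
  anchor <- shared[order(shared)][1L]
  ident <- identical(rot_to(ka, anchor), rot_to(kb, anchor)) &&
    length(flips) == 0L
  structure(list(
    pair = c(a$record_id, b$record_id), shared = shared,
    breakpoints = bp, strand_disagreements = flips,
    identical = ident
  ), class = "synteny_comparison")
}

#' @export
print.synteny_comparison <- function(x, ...) {
  cat("<synteny_comparison> ", x$pair[1], " vs ", x$pair[2], "\n", sep = "")
  cat("  shared genes: ", length(x$shared),
      "; breakpoints: ", x$breakpoints,
      "; strand disagreements: ", length(x$strand_disagreements),
      "; identical: ", x$identical, "\n", sep = "")
  invisible(x)
}

#' Pairwise synteny matrix for a set of records
#'
#' @param records List of \code{mitogenome_record}s (>= 2).
#' @return List with \code{breakpoints} (symmetric integer matrix),
#'   \code{identical} (logical matrix), \code{orders} (list of
#'   \code{gene_order}), and \code{layout} (data.frame, one row per
#'   genome, columns the ordered strand-marked gene labels of the first
#'   record -- the tabular analogue of a gene-arrangement figure).
#' @export
synteny_matrix <- function(records) {
  if (length(records) < 2L) stop("need >= 2 records")
  orders <- lapply(records, gene_order)
  ids <- vapply(orders, function(o) o$record_id, character(1))
  n <- length(orders)
  bp <- matrix(0L, n, n, dimnames = list(ids, ids))
  idm <- matrix(TRUE, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    cmp <- compare_orders(orders[[i]], orders[[j]])
    bp[i, j] <- bp[j, i] <- cmp$breakpoints
    idm[i, j] <- idm[j, i] <- cmp$identical
  }
  width <- max(vapply(orders, function(o) length(o$labels), integer(1)))
  layout <- do.call(rbind, lapply(orders, function(o) {
    marked <- paste0(o$labels, "(", o$strands, ")")
    length(marked) <- width
    as.data.frame(as.list(marked), col.names = paste0("g", seq_len(width)))
  }))
  rownames(layout) <- ids
  list(breakpoints = bp, identical = idm, orders = orders, layout = layout)
}
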