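#' Full characterization of one or more mitogenomes
#'
#' Orchestrates the whole desk-scale characterization: annotation
#' validation, per-region composition and skews, codon usage (start/stop
#' table, RSCU, ENc), control-region tandem repeats, and -- when several
#' records are supplied -- the cross-record analyses: gene-order synteny
#' matrix, whole-genome distance matrix, neighbor-joining tree with
#' bootstrap support, monophyly verdict, and a per-gene dN/dS table
#' against a designated reference. Every number in the report is produced
#' by one module function; the report layer only assembles (and, in
#' \code{print}, rounds for display).
#'
#' @param records A \code{mitogenome_record} or list of them. Records
#'   without sequence get annotation-only reports.
#' @param ingroup Optional character vector of record ids whose monophyly
#'   (after rooting on \code{outgroup}) should be assessed.
#' @param outgroup Optional record id used to root the tree.
#' @param reference Record id used as the focal genome of the dN/dS
#'   table (default: the first record).
#' @param min_repeat_score Minimum tandem-repeat alignment score.
#' @param bootstrap_replicates Bootstrap replicates for tree support
#'   (0 disables bootstrapping).
#' @param seed Seed for the bootstrap resampling.
#' @param strict Turn validator discrepancies into errors (off by
#'   default: published tables are allowed to disagree with their own
#'   coordinates and are reported, not censored).
#' @return List of class \code{characterization_report}: \code{per_record}
#'   (named list with validation, composition, codon_usage, repeats) and,
#'   for >= 2 sequenced records, \code{synteny}, \code{distances},
#'   \code{tree}, \code{monophyly}, \code{dnds}. Per-stage errors are
#'   collected under \code{errors} and do not abort independent stages.
#' @export
characterize <- function(records, ingroup = NULL, outgroup = NULL,
                         reference = NULL, min_repeat_score = 30L,
                         bootstrap_replicates = 100L, seed = 1L,
                         strict = FALSE) {
  if (inherits(records, "mitogenome_record")) records <- list(records)
  ids <- vapply(records, function(r) r$record_id, character(1))
  names(records) <- ids
  errors <- list()
  note <- function(stage, e) errors[[stage]] <<- conditionMessage(e)
  per_record <- lapply(records, function(rec) {
    out <- list()
    out$validation <- tryCatch(validate_annotation(rec),
                               error = function(e) { note(paste0("validate:", rec$record_id), e); NULL })
    if (strict && !is.null(out$validation) &&
        nrow(out$validation$length_discrepancies) > 0L)
      stop("strict mode: declared/computed length discrepancies in ",
           rec$record_id)
    if (!is.na(rec$sequence)) {
      out$composition <- tryCatch(composition_report(rec),
                                  error = function(e) { note(paste0("composition:", rec$record_id), e); NULL })
      out$codon_usage <- tryCatch(codon_usage_table(rec),
                                  error = function(e) { note(paste0("codon:", rec$record_id), e); NULL })
      out$repeats <- tryCatch(repeat_report(rec, min_score = min_repeat_score),
                              error = function(e) { note(paste0("repeats:", rec$record_id), e); NULL })
    }
    out
  })
  report <- list(per_record = per_record, errors = errors)
  seq_recs <- records[!vapply(records, function(r) is.na(r$sequence),
                              logical(1))]
  if (length(records) >= 2L)
    report$synteny <- tryCatch(synteny_matrix(records),
                               error = function(e) { note("synteny", e); NULL })
  if (length(seq_recs) >= 3L) {
    aln <- vapply(seq_recs, function(r) r$sequence, character(1))
    if (length(unique(nchar(aln))) == 1L) {
      report$distances <- tryCatch(pairwise_distances(aln, "K2P"),
                                   error = function(e) { note("distances", e); NULL })
      if (!is.null(report$distances)) {
        report$tree <- tryCatch({
          if (bootstrap_replicates > 0L)
            bootstrap_support(aln, "K2P",
                              replicates = bootstrap_replicates, seed = seed)
          else neighbor_joining(report$distances)
        }, error = function(e) { note("tree", e); NULL })
      }
      if (!is.null(report$tree) && !is.null(ingroup) && !is.null(outgroup))
        report$monophyly <- tryCatch(
          is_monophyletic(report$tree, ingroup, outgroup),
          error = function(e) { note("monophyly", e); NULL })
    } else {
      errors[["distances"]] <- "records differ in length; supply aligned sequences"
      report$errors <- errors
    }
  }
  if (length(seq_recs) >= 2L) {
    ref <- if (is.null(reference)) names(seq_recs)[1L] else reference
    others <- setdiff(names(seq_recs), ref)
    report$dnds <- tryCatch({
      tabs <- lapply(others, function(id) {
        t <- dnds_table(seq_recs[[ref]], seq_recs[[id]])
        t$pair <- paste(ref, id, sep = " vs ")
        t
      })
      do.call(rbind, tabs)
    }, error = function(e) { note("dnds", e); NULL })
  }
  report$errors <- errors
  class(report) <- "characterization_report"
  report
}

#' @export
print.characterization_report <- function(x, ...) {
  cat("<characterization_report> ", length(x$per_record), " record(s)\n",
      sep = "")
  for (id in names(x$per_record)) {
    pr <- x$per_record[[id]]
    v <- pr$validation
    if (is.null(v)) next
    cat("-- ", id, ": ", v$genome_length, " bp; ", sep = "")
    cc <- v$class_counts
    cat(paste(names(cc), as.integer(cc), sep = ":", collapse = " "),
        "; strands H", v$strand_tally[["heavy"]], "/L",
        v$strand_tally[["light"]], "\n", sep = "")
    if (!is.null(pr$codon_usage))
      cat(sprintf("   ENc %.2f over %d codons; ", pr$codon_usage$enc,
                  pr$codon_usage$total_codons))
    if (!is.null(pr$composition)) {
      wg <- pr$composition[pr$composition$region == "whole_genome", ]
      cat(sprintf("AT %.2f%%, AT skew %s, GC skew %s",
                  wg$at_content, format_skew(wg$at_skew),
                  format_skew(wg$gc_skew)))
    }
    if (!is.null(pr$codon_usage) || !is.null(pr$composition)) cat("\n")
    if (!is.null(pr$repeats) && nrow(pr$repeats))
      cat("   CR repeats: ",
          paste(sprintf("period %d x %.1f", pr$repeats$period,
                        pr$repeats$copy_number), collapse = "; "),
          "\n", sep = "")
  }
  if (!is.null(x$monophyly))
    cat("-- ingroup monophyletic: ", x$monophyly$monophyletic, "\n",
        sep = "")
  if (length(x$errors))
    cat("-- stage errors: ", paste(names(x$errors), collapse = ", "),
        "\n", sep = "")
  invisible(x)
}

#' Serialize a characterization report to a directory
#'
#' Writes a JSON bundle (full precision) plus per-table TSVs and a
#' manifest. Two runs with identical inputs and seed produce identical
#' bundles.
#'
#' @param report A \code{characterization_report}.
#' @param dir Output directory (created if missing).
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  put_tsv <- function(df, name) {
    path <- file.path(dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <<- c(files, name)
  }
  bundle <- list()
  for (id in names(report$per_record)) {
    pr <- report$per_record[[id]]
    safe <- gsub("[^A-Za-z0-9._-]", "_", id)
    if (!is.null(pr$validation)) {
      put_tsv(pr$validation$per_feature,
              paste0(safe, "_validation.tsv"))
      bundle[[id]]$genome_length <- pr$validation$genome_length
      bundle[[id]]$strand_tally <- as.list(pr$validation$strand_tally)
      bundle[[id]]$class_counts <- as.list(pr$validation$class_counts)
      bundle[[id]]$pcg_length_sum <- pr$validation$pcg_length_sum
    }
    if (!is.null(pr$composition))
      put_tsv(pr$composition, paste0(safe, "_composition.tsv"))
    if (!is.null(pr$codon_usage)) {
      put_tsv(pr$codon_usage$rscu, paste0(safe, "_rscu.tsv"))
      put_tsv(pr$codon_usage$start_stop, paste0(safe, "_codons.tsv"))
      bundle[[id]]$enc <- pr$codon_usage$enc
      bundle[[id]]$total_codons <- pr$codon_usage$total_codons
    }
    if (!is.null(pr$repeats))
      put_tsv(as.data.frame(pr$repeats), paste0(safe, "_repeats.tsv"))
  }
  if (!is.null(report$synteny)) {
    put_tsv(as.data.frame(report$synteny$breakpoints), "synteny_breakpoints.tsv")
    put_tsv(report$synteny$layout, "synteny_layout.tsv")
  }
  if (!is.null(report$distances))
    write_phylip_dm(report$distances, file.path(dir, "distances.phy"))
  if (!is.null(report$tree))
    ape::write.tree(report$tree, file.path(dir, "tree.nwk"))
  if (!is.null(report$dnds)) put_tsv(report$dnds, "dnds.tsv")
  if (!is.null(report$monophyly))
    bundle$monophyly <- report$monophyly
  jsonlite::write_json(bundle, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(sort(c(files, "report.json")),
             file.path(dir, "MANIFEST"))
  invisible(dir)
}
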