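#' Construct a gene feature
#'
#' One annotated feature of a mitogenome: a protein-coding gene (PCG),
#' tRNA, rRNA, or the control region (CR / D-loop). Coordinates are
#' 1-based inclusive on the heavy (+) strand as deposited; a feature may
#' wrap the circular origin, in which case \code{stop < start}.
#'
#' @param name Feature label, e.g. "ND5" or "tRNA-Phe".
#' @param feature_class One of "PCG", "tRNA", "rRNA", "CR".
#' @param strand "+" (heavy) or "-" (light).
#' @param start,stop 1-based inclusive coordinates.
#' @param declared_length Length in bp as printed in the source table, or NA.
#' @param start_codon,stop_codon Codon annotations for PCGs; the stop may be
#'   an incomplete form such as "T(AA)" or "TA(A)". NA when absent.
#' @param anticodon tRNA anticodon 3-mer or NA.
#' @return A one-row data.frame of class \code{gene_feature} fields (used
#'   rowwise inside a \code{mitogenome_record} feature table).
#' @export
gene_feature <- function(name, feature_class, strand, start, stop,
                         declared_length = NA_integer_,
                         start_codon = NA_character_,
                         stop_codon = NA_character_,
                         anticodon = NA_character_) {
  feature_class <- match.arg(feature_class, c("PCG", "tRNA", "rRNA", "CR"))
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  start <- as.integer(start); stop <- as.integer(stop)
  if (is.na(start) || is.na(stop) || start < 1L || stop < 1L)
    stop("coordinates must be positive integers")
  if (feature_class == "PCG" && (is.na(start_codon) || is.na(stop_codon)))
    stop("PCG features require start and stop codon annotations")
  data.frame(
    name = name, feature_class = feature_class, strand = strand,
    start = start, stop = stop,
    declared_length = as.integer(declared_length),
    start_codon = start_codon, stop_codon = stop_codon,
    anticodon = anticodon, stringsAsFactors = FALSE
  )
}

#' Construct a mitogenome record
#'
#' A circular mitochondrial genome: an optional nucleotide sequence plus an
#' ordered feature table. Features may exist without sequence
#' (annotation-only mode, e.g. when working from a printed feature table).
#'
#' @param record_id Identifier string.
#' @param features A data.frame of features as built by rows of
#'   \code{\link{gene_feature}}; sorted by start coordinate on construction.
#' @param sequence Nucleotide string over A/C/G/T/N, or NA for
#'   annotation-only records.
#' @param genome_length Genome length in bp; required when no sequence is
#'   given, otherwise derived from the sequence.
#' @param circular Logical; mitogenomes are circular by default.
#' @return An object of class \code{mitogenome_record}.
#' @export
mitogenome_record <- function(record_id, features, sequence = NA_character_,
                              genome_length = NULL, circular = TRUE) {
  has_seq <- !is.na(sequence)
  if (has_seq) {
    sequence <- toupper(sequence)
    bad <- regexpr("[^ACGTN]", sequence)
    if (bad > 0L)
      stop("non-IUPAC character in sequence at position ", bad)
    genome_length <- nchar(sequence)
  } else if (is.null(genome_length)) {
    stop("genome_length required for annotation-only records")
  }
  if (!is.null(features) && nrow(features)) {
    features <- features[order(features$start), , drop = FALSE]
    rownames(features) <- NULL
  }
  structure(
    list(record_id = record_id, sequence = sequence,
         features = features, genome_length = as.integer(genome_length),
         circular = circular),
    class = "mitogenome_record"
  )
}

#' @export
print.mitogenome_record <- function(x, ...) {
  cat("<mitogenome_record> ", x$record_id, "\n", sep = "")
  cat("  length: ", x$genome_length, " bp",
      if (x$circular) " (circular)" else "", "\n", sep = "")
  cat("  sequence: ", if (is.na(x$sequence)) "absent (annotation-only)"
      else "present", "\n", sep = "")
  if (!is.null(x$features)) {
    tab <- table(x$features$feature_class)
    cat("  features: ", nrow(x$features), " (",
        paste(names(tab), as.integer(tab), sep = ":", collapse = ", "),
        ")\n", sep = "")
  }
  invisible(x)
}

.strip_int <- function(x) {
  # printed tables use thousands separators ("11,975"); strip and parse
  suppressWarnings(as.integer(gsub("[, ]", "", x)))
}

#' Parse a printed mitogenome feature table
#'
#' Reads a tab-delimited table in the published layout
#' (Name / Type / Strand / Start / Stop / Intergenic / Length / Codons)
#' into an annotation-only \code{\link{mitogenome_record}}. Thousands
#' separators in coordinates are tolerated; a "D-loop" type or name is
#' mapped to feature class CR; the CR row may leave strand blank (heavy
#' assumed). The printed Intergenic and Length columns are retained as
#' declared values for later validation, never trusted for arithmetic.
#'
#' @param table_text The table as a single string or character vector of
#'   lines, header included.
#' @param record_id Identifier for the resulting record.
#' @param genome_length Total genome length in bp; defaults to the maximum
#'   stop coordinate.
#' @return An annotation-only \code{mitogenome_record} whose
#'   \code{features} table carries extra columns \code{declared_intergenic}
#'   and row order as printed.
#' @export
parse_feature_table <- function(table_text, record_id = "feature_table",
                                genome_length = NULL) {
  lines <- if (length(table_text) == 1L)
    strsplit(table_text, "\n", fixed = TRUE)[[1]] else table_text
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 1L) stop("no features: empty table")
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  if (!grepl("name", header[1], ignore.case = TRUE))
    stop("header row not found (expected first column 'Name')")
  body <- lines[-1]
  if (!length(body)) stop("no features: empty table body")
  rows <- lapply(seq_along(body), function(i) {
    f <- strsplit(body[[i]], "\t", fixed = TRUE)[[1]]
    length(f) <- 8L
    f[is.na(f)] <- ""
    name <- trimws(f[1])
    type <- trimws(f[2])
    cls <- switch(toupper(type),
      "PCG" = "PCG", "CDS" = "PCG", "TRNA" = "tRNA", "RRNA" = "rRNA",
      "CR" = "CR", "D-LOOP" = "CR",
      stop("unknown feature class '", type, "' in row ", i, " (", name, ")"))
    if (grepl("^D-?loop$", name, ignore.case = TRUE)) cls <- "CR"
    strand <- trimws(f[3])
    if (strand == "") strand <- "+"
    if (strand == "−") strand <- "-"   # unicode minus in typeset tables
    start <- .strip_int(f[4]); stop_ <- .strip_int(f[5])
    if (is.na(start) || is.na(stop_) || start < 1L || stop_ < 1L)
      stop("malformed coordinate in row ", i, " (", name, "): '",
           f[4], "' / '", f[5], "'")
    ig <- .strip_int(f[6])
    len <- .strip_int(f[7])
    codons <- trimws(f[8])
    sc <- NA_character_; ec <- NA_character_
    if (cls == "PCG") {
      if (!grepl("/", codons, fixed = TRUE))
        stop("PCG row ", i, " (", name, ") lacks start/stop codon annotation")
      parts <- strsplit(codons, "/", fixed = TRUE)[[1]]
      sc <- trimws(parts[1]); ec <- trimws(parts[2])
    }
    cbind(
      gene_feature(name, cls, strand, start, stop_, declared_length = len,
                   start_codon = sc, stop_codon = ec),
      data.frame(declared_intergenic = ig)
    )
  })
  feats <- do.call(rbind, rows)
  if (is.null(genome_length)) genome_length <- max(feats$stop)
  mitogenome_record(record_id, feats, genome_length = genome_length)
}

#' Load the packaged published annotation table
#'
#' The feature table of the Potamotrygon leopoldi mitogenome (GenBank
#' OR896919) as published: 37 gene rows plus the D-loop, with the printed
#' intergenic-spacer and length columns retained for validation. The
#' printed table contains several internal inconsistencies between its
#' coordinates and its length/spacer columns; \code{\link{validate_annotation}}
#' flags them all.
#'
#' @return An annotation-only \code{mitogenome_record} of 38 features,
#'   genome length 17,504 bp.
#' @export
pleopoldi_annotation <- function() {
  path <- system.file("extdata", "pleopoldi_annotation.tsv", package = "mitoray",
                      mustWork = TRUE)
  parse_feature_table(readLines(path), record_id = "OR896919",
                      genome_length = 17504L)
}

#' Published whole-genome composition values
#'
#' The printed base-composition percentages and summary values reported
#' for the P. leopoldi mitogenome (whole genome, rRNA, control region,
#' protein-coding genes), packaged so the report layer can reproduce the
#' published arithmetic without the deposited sequence.
#'
#' @return A nested list mirroring the published values.
#' @export
pleopoldi_printed_composition <- function() {
  path <- system.file("extdata", "pleopoldi_printed_composition.json",
                      package = "mitoray", mustWork = TRUE)
  jsonlite::read_json(path, simplifyVector = TRUE)
}

# ---- sequence I/O -----------------------------------------------------------

#' Read a single DNA sequence from FASTA
#'
#' @param path FASTA file with exactly one record.
#' @return Uppercase sequence string.
#' @export
read_fasta_seq <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) != 1L) stop("expected a single FASTA record, found ", length(set))
  s <- toupper(as.character(set[[1]]))
  if (nchar(s) == 0L) stop("zero-length sequence")
  s
}

#' Write a sequence to FASTA
#' @param seq Sequence string.
#' @param id Record id for the header.
#' @param path Output path.
#' @export
write_fasta_seq <- function(seq, id, path) {
  x <- Biostrings::DNAStringSet(seq)
  names(x) <- id
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

#' Write a mitogenome record as a minimal GenBank flat file
#'
#' Emits LOCUS/FEATURES/ORIGIN sections with CDS, tRNA, rRNA and D-loop
#' features in 1-based inclusive coordinates; light-strand features use
#' \code{complement()}, origin-wrapping features \code{join()}. The writer
#' is bit-stable given a fixed record.
#'
#' @param record A \code{mitogenome_record} with sequence.
#' @param path Output path.
#' @export
write_genbank_flat <- function(record, path) {
  if (is.na(record$sequence)) stop("record has no sequence")
  con <- file(path, "w")
  on.exit(close(con))
  L <- record$genome_length
  writeLines(sprintf(
    "LOCUS       %s %d bp    DNA     circular     %s",
    record$record_id, L, "VRT"), con)
  writeLines(sprintf("DEFINITION  %s mitochondrion, complete genome.",
                     record$record_id), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     source          1..%d", L), con)
  key_of <- c(PCG = "CDS", tRNA = "tRNA", rRNA = "rRNA", CR = "D-loop")
  for (i in seq_len(nrow(record$features))) {
    f <- record$features[i, ]
    loc <- if (f$stop < f$start)
      sprintf("join(%d..%d,1..%d)", f$start, L, f$stop)
    else sprintf("%d..%d", f$start, f$stop)
    if (f$strand == "-") loc <- sprintf("complement(%s)", loc)
    writeLines(sprintf("     %-15s %s", key_of[[f$feature_class]], loc), con)
    writeLines(sprintf("                     /gene=\"%s\"", f$name), con)
    if (!is.na(f$start_codon))
      writeLines(sprintf("                     /note=\"codons=%s/%s\"",
                         f$start_codon, f$stop_codon), con)
  }
  writeLines("ORIGIN", con)
  s <- tolower(record$sequence)
  pos <- seq(1L, nchar(s), by = 60L)
  for (p in pos) {
    chunk <- substr(s, p, min(p + 59L, nchar(s)))
    blocks <- substring(chunk, seq(1L, nchar(chunk), 10L),
                        pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    writeLines(sprintf("%9d %s", p, paste(blocks, collapse = " ")), con)
  }
  writeLines("//", con)
  invisible(path)
}

#' Read a minimal single-record GenBank flat file
#'
#' Parses the dialect emitted by \code{\link{write_genbank_flat}} (and the
#' common subset of real flat files): one circular record with CDS / tRNA /
#' rRNA / D-loop features, \code{complement()} for light-strand genes and
#' \code{join(a..L,1..b)} for features wrapping the origin (flagged by
#' \code{stop < start} in the resulting table). Coordinates are kept
#' 1-based inclusive.
#'
#' @param path GenBank flat file with exactly one record.
#' @return A \code{mitogenome_record}.
#' @export
read_genbank_flat <- function(path) {
  lines <- readLines(path)
  ends <- grep("^//", lines)
  if (length(ends) > 1L) stop("multi-record GenBank file not supported")
  id <- sub("^LOCUS\\s+(\\S+).*$", "\\1", lines[grep("^LOCUS", lines)[1]])
  ori <- grep("^ORIGIN", lines)[1]
  if (is.na(ori)) stop("no ORIGIN section")
  seq_lines <- lines[(ori + 1L):(if (length(ends)) ends[1] - 1L else length(lines))]
  sequence <- toupper(gsub("[^acgtnACGTN]", "", paste(seq_lines, collapse = "")))
  if (nchar(sequence) == 0L) stop("zero-length sequence")
  feat_start <- grep("^FEATURES", lines)[1]
  block <- lines[(feat_start + 1L):(ori - 1L)]
  key_re <- "^\\s{5}(\\S+)\\s+(.+)$"
  is_key <- grepl(key_re, block) & !grepl("^\\s{21}", block)
  idx <- which(is_key)
  cls_of <- c(CDS = "PCG", tRNA = "tRNA", rRNA = "rRNA", "D-loop" = "CR")
  feats <- list()
  for (k in seq_along(idx)) {
    line <- block[idx[k]]
    key <- sub(key_re, "\\1", line)
    if (!key %in% names(cls_of)) next
    loc <- sub(key_re, "\\2", line)
    to <- if (k < length(idx)) idx[k + 1L] - 1L else length(block)
    quals <- block[(idx[k] + 1L):to]
    strand <- if (grepl("complement(", loc, fixed = TRUE)) "-" else "+"
    nums <- as.integer(regmatches(loc, gregexpr("[0-9]+", loc))[[1]])
    if (grepl("join(", loc, fixed = TRUE) && length(nums) >= 4L) {
      start <- nums[1]; stop_ <- nums[4]   # wraps origin: stop < start
    } else {
      start <- nums[1]; stop_ <- nums[2]
    }
    gene <- quals[grep("/gene=", quals, fixed = TRUE)[1]]
    name <- if (is.na(gene)) paste0(key, "_", k)
      else sub('.*?/gene="([^"]*)".*', "\\1", gene)
    sc <- NA_character_; ec <- NA_character_
    note <- quals[grep("codons=", quals, fixed = TRUE)[1]]
    if (!is.na(note)) {
      cod <- sub('.*codons=([^"]*)".*', "\\1", note)
      parts <- strsplit(cod, "/", fixed = TRUE)[[1]]
      sc <- parts[1]; ec <- parts[2]
    }
    cls <- cls_of[[key]]
    if (cls == "PCG" && (is.na(sc) || is.na(ec))) { sc <- "ATG"; ec <- "TAA" }
    feats[[length(feats) + 1L]] <-
      gene_feature(name, cls, strand, start, stop_,
                   start_codon = sc, stop_codon = ec)
  }
  mitogenome_record(id, do.call(rbind, feats), sequence = sequence)
}

# ---- coordinate arithmetic --------------------------------------------------

# computed length of a feature on a circular genome (wrap when stop < start)
feature_length <- function(start, stop, genome_length) {
  ifelse(stop >= start, stop - start + 1L, genome_length - start + 1L + stop)
}

#' Extract a feature's sequence from a record
#'
#' 1-based inclusive slice of the genome; light-strand (-) features are
#' returned reverse-complemented so the result reads 5'->3' on the coding
#' strand; features wrapping the circular origin (stop < start) are
#' concatenated across it.
#'
#' @param record A \code{mitogenome_record} with sequence.
#' @param feature One row of the record's feature table (or any list with
#'   \code{start}, \code{stop}, \code{strand}).
#' @return Nucleotide string.
#' @export
extract_region <- function(record, feature) {
  if (is.na(record$sequence)) stop("record has no sequence")
  L <- record$genome_length
  start <- feature$start; stop_ <- feature$stop
  if (start > L || stop_ > L) {
    if (!record$circular) stop("coordinates beyond genome length on a non-circular record")
    start <- ((start - 1L) %% L) + 1L
    stop_ <- ((stop_ - 1L) %% L) + 1L
  }
  s <- if (stop_ >= start) substr(record$sequence, start, stop_)
  else {
    if (!record$circular)
      stop("wrapping feature on a non-circular record")
    paste0(substr(record$sequence, start, L), substr(record$sequence, 1L, stop_))
  }
  if (identical(feature$strand, "-")) revcomp(s) else s
}

#' Validate a mitogenome annotation against its own coordinates
#'
#' Recomputes every feature length from coordinates, the intergenic spacer
#' to the next feature (negative values denote overlap), strand tallies by
#' feature class, and flags every row whose declared length or declared
#' intergenic spacer disagrees with the coordinate arithmetic. Computed
#' values are authoritative for all downstream statistics; declared values
#' are only reported. The published P. leopoldi table trips several of
#' these flags (tRNA-Glu, tRNA-Pro, the second tRNA-Ser, ATP6, D-loop and
#' five spacer entries); a clean synthetic record trips none.
#'
#' @param record A \code{mitogenome_record} (sequence optional).
#' @return An object of class \code{validation_report}: a list with
#'   \code{per_feature} (data.frame: name, class, strand, start, stop,
#'   computed_length, declared_length, length_ok, intergenic,
#'   declared_intergenic, intergenic_ok), \code{overlaps},
#'   \code{length_discrepancies}, \code{intergenic_discrepancies},
#'   \code{strand_tally}, \code{class_counts}, \code{pcg_length_sum}
#'   (computed), \code{pcg_declared_sum}, and \code{genome_length}.
#' @export
validate_annotation <- function(record) {
  f <- record$features
  if (is.null(f) || nrow(f) < 1L) stop("record has no features")
  L <- record$genome_length
  n <- nrow(f)
  comp_len <- feature_length(f$start, f$stop, L)
  # circular spacer: from each feature to the next by start order; the last
  # wraps to the first
  nxt <- c(2:n, 1L)
  raw_gap <- f$start[nxt] - f$stop - 1L
  raw_gap[n] <- (f$start[1L] + L) - f$stop[n] - 1L
  has_decl_ig <- "declared_intergenic" %in% names(f)
  decl_ig <- if (has_decl_ig) f$declared_intergenic else rep(NA_integer_, n)
  decl_len <- f$declared_length
  length_ok <- is.na(decl_len) | decl_len == comp_len
  ig_ok <- is.na(decl_ig) | decl_ig == raw_gap
  per <- data.frame(
    name = f$name, feature_class = f$feature_class, strand = f$strand,
    start = f$start, stop = f$stop,
    computed_length = comp_len, declared_length = decl_len,
    length_ok = length_ok,
    intergenic = raw_gap, declared_intergenic = decl_ig,
    intergenic_ok = ig_ok, stringsAsFactors = FALSE
  )
  gene_rows <- f$feature_class != "CR"
  strand_tally <- table(factor(f$strand[gene_rows], levels = c("+", "-")))
  out <- list(
    record_id = record$record_id,
    genome_length = L,
    per_feature = per,
    overlaps = per[per$intergenic < 0L,
                   c("name", "intergenic"), drop = FALSE],
    length_discrepancies = per[!per$length_ok, , drop = FALSE],
    intergenic_discrepancies = per[!per$intergenic_ok, , drop = FALSE],
    strand_tally = c(heavy = unname(strand_tally[["+"]]),
                     light = unname(strand_tally[["-"]])),
    class_counts = table(factor(f$feature_class,
                                levels = c("PCG", "tRNA", "rRNA", "CR"))),
    pcg_length_sum = sum(comp_len[f$feature_class == "PCG"]),
    pcg_declared_sum = sum(decl_len[f$feature_class == "PCG"], na.rm = TRUE)
  )
  class(out) <- "validation_report"
  out
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report> ", x$record_id, " (", x$genome_length, " bp)\n",
      sep = "")
  cc <- x$class_counts
  cat("  features: ", paste(names(cc), as.integer(cc), sep = ":",
                            collapse = ", "), "\n", sep = "")
  cat("  gene strands: heavy ", x$strand_tally[["heavy"]], ", light ",
      x$strand_tally[["light"]], "\n", sep = "")
  cat("  PCG length sum: ", x$pcg_length_sum, " bp (computed); ",
      x$pcg_declared_sum, " bp (declared)\n", sep = "")
  cat("  length discrepancies: ", nrow(x$length_discrepancies),
      "; spacer discrepancies: ", nrow(x$intergenic_discrepancies),
      "; overlaps: ", nrow(x$overlaps), "\n", sep = "")
  invisible(x)
}

#' Write a feature table in the published layout
#'
#' @param record A \code{mitogenome_record}.
#' @param path Output path (TSV).
#' @export
write_feature_table <- function(record, path) {
  f <- record$features
  rep <- validate_annotation(record)
  codons <- ifelse(is.na(f$start_codon), "-",
                   paste0(f$start_codon, "/", f$stop_codon))
  tab <- data.frame(
    Name = f$name, Type = f$feature_class, Strand = f$strand,
    Start = f$start, Stop = f$stop,
    Intergenic = rep$per_feature$intergenic,
    Length = rep$per_feature$computed_length,
    Codons = codons, stringsAsFactors = FALSE
  )
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
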