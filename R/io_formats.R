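#' Construct a time-course expression matrix
#'
#' Bundles a genes x samples abundance matrix (FPKM or simulated
#' equivalents) with per-sample zeitgeber time, replicate and condition
#' annotation, validating the invariants every downstream stage relies on.
#'
#' @param values numeric matrix, genes in rows, samples in columns;
#'   non-negative abundances.
#' @param gene_ids character vector of unique gene identifiers, one per row.
#' @param samples data.frame with columns `sample_id`, `zt` (hours in
#'   [0, 24)), `replicate` (positive integer) and `condition` (label such
#'   as "CV", "GF", "WT", "KO"), one row per column of `values`.
#' @return An object of class `TimeCourseMatrix`: a list with elements
#'   `values`, `gene_ids` and `samples`.
#' @export
time_course_matrix <- function(values, gene_ids, samples) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("expression values must be numeric")
  if (anyNA(values)) stop("missing values are not permitted in expression matrices")
  if (any(values < 0)) stop("expression values must be non-negative")
  gene_ids <- as.character(gene_ids)
  if (length(gene_ids) != nrow(values))
    stop("gene_ids length does not match matrix rows")
  dup <- gene_ids[duplicated(gene_ids)]
  if (length(dup))
    stop("duplicate gene id(s): ", paste(unique(dup), collapse = ", "))
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  need <- c("sample_id", "zt", "replicate", "condition")
  miss <- setdiff(need, names(samples))
  if (length(miss))
    stop("sample annotation lacks column(s): ", paste(miss, collapse = ", "))
  if (nrow(samples) != ncol(values))
    stop("annotation describes ", nrow(samples), " samples but matrix has ",
         ncol(values), " columns")
  if (any(samples$zt < 0 | samples$zt >= 24))
    stop("zeitgeber times must lie in [0, 24)")
  if (any(samples$replicate < 1 | samples$replicate != round(samples$replicate)))
    stop("replicate must be a positive integer")
  key <- paste(samples$zt, samples$replicate, samples$condition)
  if (anyDuplicated(key))
    stop("duplicate (zt, replicate, condition) triplet in sample annotation")
  if (length(unique(samples$zt)) < 2)
    stop("at least 2 distinct timepoints are required")
  rownames(values) <- gene_ids
  colnames(values) <- samples$sample_id
  structure(list(values = values, gene_ids = gene_ids, samples = samples),
            class = "TimeCourseMatrix")
}

#' @export
print.TimeCourseMatrix <- function(x, ...) {
  cat("TimeCourseMatrix:", nrow(x$values), "genes x", ncol(x$values), "samples\n")
  cat("  timepoints (ZT):", paste(sort(unique(x$samples$zt)), collapse = ", "), "\n")
  cat("  conditions:", paste(unique(x$samples$condition), collapse = ", "), "\n")
  invisible(x)
}

#' Read a tab-separated expression table
#'
#' First column is the gene id, remaining columns are numeric abundances;
#' the header row carries sample ids.  Column order is preserved.
#'
#' @param path path to the TSV file.
#' @param sample_annotations data.frame with `sample_id`, `zt`, `replicate`,
#'   `condition`, one row per expression column, in file column order (rows
#'   are matched to columns by `sample_id` when all ids are present,
#'   otherwise positionally).
#' @return A [time_course_matrix()] object.
#' @export
read_expression_table <- function(path, sample_annotations) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("expression table needs a gene id column plus samples")
  gene_ids <- as.character(tab[[1]])
  vals <- tab[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1]
      stop("non-numeric value in column '", names(vals)[j], "' row ",
           if (is.na(bad)) "?" else bad)
    }
  }
  vals <- as.matrix(vals)
  ann <- as.data.frame(sample_annotations, stringsAsFactors = FALSE)
  if (nrow(ann) != ncol(vals))
    stop("annotation lists ", nrow(ann), " samples but table has ",
         ncol(vals), " sample columns")
  if (all(colnames(vals) %in% ann$sample_id))
    ann <- ann[match(colnames(vals), ann$sample_id), , drop = FALSE]
  time_course_matrix(vals, gene_ids, ann)
}

#' Write a time-course matrix back to TSV
#'
#' Inverse of [read_expression_table()]; the sample annotation is written
#' alongside as `<path>` plus `samples_path` when given.
#'
#' @param tcm a `TimeCourseMatrix`.
#' @param path output TSV path.
#' @param samples_path optional path for the sample annotation TSV.
#' @export
write_expression_table <- function(tcm, path, samples_path = NULL) {
  stopifnot(inherits(tcm, "TimeCourseMatrix"))
  out <- data.frame(gene_id = tcm$gene_ids, tcm$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(samples_path))
    utils::write.table(tcm$samples, samples_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(path)
}

#' Construct an interval set
#'
#' Genomic intervals in the 0-based half-open (BED) convention; carries
#' aligned ChIP-seq reads and motif sites alike.
#'
#' @param records data.frame with columns `chrom`, `start`, `end` and
#'   optionally `name`, `score`, `strand`.
#' @return An object of class `IntervalSet` with elements `records` and
#'   `total_count`.
#' @export
interval_set <- function(records) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (nrow(records)) {
    stopifnot(all(c("chrom", "start", "end") %in% names(records)))
    bad <- which(records$start >= records$end)
    if (length(bad))
      stop("interval with start >= end at record ", bad[1])
    if (any(records$start < 0)) stop("negative interval start")
  } else {
    records <- data.frame(chrom = character(), start = integer(),
                          end = integer(), stringsAsFactors = FALSE)
  }
  structure(list(records = records, total_count = nrow(records)),
            class = "IntervalSet")
}

#' @export
print.IntervalSet <- function(x, ...) {
  cat("IntervalSet:", x$total_count, "intervals on",
      length(unique(x$records$chrom)), "sequence(s)\n")
  invisible(x)
}

#' Read a BED3+ file
#'
#' Track and comment lines (`track`, `browser`, `#`) are tolerated.
#' Coordinates are kept 0-based half-open.
#'
#' @param path path to a BED file.
#' @return An [interval_set()].
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(lines)
  data_lines <- lines[keep]
  if (!length(data_lines)) return(interval_set(data.frame()))
  fields <- strsplit(data_lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    stop("BED line ", which(keep)[which(nf < 3)[1]], " has fewer than 3 fields")
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- as.integer(vapply(fields, `[[`, "", 2L))
  end <- as.integer(vapply(fields, `[[`, "", 3L))
  bad <- which(start >= end)
  if (length(bad))
    stop("malformed interval (start >= end) at line ", which(keep)[bad[1]])
  rec <- data.frame(chrom = chrom, start = start, end = end,
                    stringsAsFactors = FALSE)
  if (max(nf) >= 4) rec$name <- vapply(fields, function(f) if (length(f) >= 4) f[[4]] else NA_character_, "")
  if (max(nf) >= 5) rec$score <- suppressWarnings(as.numeric(vapply(fields, function(f) if (length(f) >= 5) f[[5]] else NA_character_, "")))
  if (max(nf) >= 6) rec$strand <- vapply(fields, function(f) if (length(f) >= 6) f[[6]] else NA_character_, "")
  interval_set(rec)
}

#' Write an interval set as BED
#'
#' @param iset an `IntervalSet`.
#' @param path output path.
#' @export
write_bed <- function(iset, path) {
  stopifnot(inherits(iset, "IntervalSet"))
  rec <- iset$records
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(rec))
  utils::write.table(rec[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene models from a refFlat-like TSV
#'
#' Columns: gene_id, chrom, strand, txStart, txEnd (0-based).  The
#' transcription start site is `txStart` on the '+' strand and `txEnd` on
#' the '-' strand.
#'
#' @param path TSV path with a header row.
#' @return data.frame with columns `gene_id`, `chrom`, `strand`, `tss`,
#'   `txStart`, `txEnd`.
#' @export
read_gene_models <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "strand", "txStart", "txEnd")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("gene model table lacks column(s): ",
                         paste(miss, collapse = ", "))
  gene_models(tab$gene_id, tab$chrom, tab$strand, tab$txStart, tab$txEnd)
}

#' Build a validated gene-model table
#'
#' @param gene_id,chrom,strand,txStart,txEnd parallel vectors.
#' @return data.frame as in [read_gene_models()].
#' @export
gene_models <- function(gene_id, chrom, strand, txStart, txEnd) {
  strand <- as.character(strand)
  bad <- which(!strand %in% c("+", "-"))
  if (length(bad))
    stop("unknown strand symbol '", strand[bad[1]], "' for gene ",
         gene_id[bad[1]])
  txStart <- as.integer(txStart); txEnd <- as.integer(txEnd)
  if (any(txStart < 0)) stop("negative txStart")
  tss <- ifelse(strand == "+", txStart, txEnd)
  data.frame(gene_id = as.character(gene_id), chrom = as.character(chrom),
             strand = strand, tss = tss, txStart = txStart, txEnd = txEnd,
             stringsAsFactors = FALSE)
}

#' Write gene models as a refFlat-like TSV
#' @param models gene model data.frame.
#' @param path output path.
#' @export
write_gene_models <- function(models, path) {
  utils::write.table(models[, c("gene_id", "chrom", "strand", "txStart", "txEnd")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: term id, description, then member gene ids, tab-separated.
#' Duplicate members within a line are deduplicated; duplicate term ids
#' across lines are an error (ambiguous collection).
#'
#' @param path GMT path.
#' @return An object of class `GeneSetCollection`: a list with `sets`
#'   (named list of character vectors) and `descriptions` (named character).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    stop("GMT line ", which(nf < 3)[1], " has fewer than 3 fields")
  ids <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(ids))
    stop("duplicate term id in GMT: ", ids[duplicated(ids)][1])
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- ids
  desc <- vapply(fields, `[[`, "", 2L)
  names(desc) <- ids
  gene_set_collection(sets, desc)
}

#' Build a gene-set collection from a named list
#' @param sets named list of character vectors (term id -> members).
#' @param descriptions optional named character vector of term descriptions.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  if (any(lengths(sets) == 0)) stop("empty gene set in collection")
  sets <- lapply(sets, function(s) unique(as.character(s)))
  if (is.null(descriptions)) {
    descriptions <- stats::setNames(rep("", length(sets)), names(sets))
  }
  structure(list(sets = sets, descriptions = descriptions),
            class = "GeneSetCollection")
}

#' @export
print.GeneSetCollection <- function(x, ...) {
  cat("GeneSetCollection:", length(x$sets), "sets, median size",
      stats::median(lengths(x$sets)), "\n")
  invisible(x)
}

#' Write a gene-set collection as GMT
#' @param collection a `GeneSetCollection`.
#' @param path output path.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(id) {
    paste(c(id, collection$descriptions[[id]], collection$sets[[id]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

# GRanges view of an IntervalSet (internal): BED 0-based half-open ->
# 1-based closed at this single boundary.
.as_granges <- function(x) {
  rec <- if (inherits(x, "IntervalSet")) x$records else x
  GenomicRanges::GRanges(
    seqnames = rec$chrom,
    ranges = IRanges::IRanges(start = rec$start + 1L, end = rec$end),
    strand = if ("strand" %in% names(rec) && !anyNA(rec$strand)) rec$strand else "*")
}
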