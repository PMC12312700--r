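#' Promoter windows around the TSS
#'
#' The promoter is the strand-oriented window from `upstream` bp before to
#' `downstream` bp after the transcription start site: on '+' genes
#' `[tss - upstream, tss + downstream)`, on '-' genes the reflected
#' `[tss - downstream, tss + upstream)`.  Windows are clipped at
#' coordinate 0 with a warning.
#'
#' @param models gene model data.frame from [gene_models()].
#' @param upstream,downstream extent in bp (default 1500/500, the histone
#'   acetylation quantification window).
#' @return data.frame: gene_id, chrom, start, end, strand (0-based
#'   half-open).
#' @export
make_promoter_windows <- function(models, upstream = 1500, downstream = 500) {
  start <- ifelse(models$strand == "+", models$tss - upstream,
                  models$tss - downstream)
  end <- ifelse(models$strand == "+", models$tss + downstream,
                models$tss + upstream)
  clipped <- start < 0
  if (any(clipped)) {
    warning(sum(clipped), " promoter window(s) clipped at coordinate 0")
    start[clipped] <- 0L
  }
  data.frame(gene_id = models$gene_id, chrom = models$chrom,
             start = as.integer(start), end = as.integer(end),
             strand = models$strand, stringsAsFactors = FALSE)
}

#' Promoter windows for motif mapping (-900..+100)
#'
#' @inheritParams make_promoter_windows
#' @export
motif_promoter_windows <- function(models) {
  make_promoter_windows(models, upstream = 900, downstream = 100)
}

#' Count promoter reads per gene per timepoint
#'
#' A read counts for a window when it overlaps it by at least 1 bp (each
#' read counted once per window; a read may hit several windows).  Raw
#' counts are scaled by the timepoint's total aligned reads to reads per
#' million.
#'
#' @param reads named list of [interval_set()], one per timepoint.
#' @param windows promoter windows from [make_promoter_windows()].
#' @return object of class `promoter_signal`: list with `gene_id`,
#'   `signal` (genes x timepoints normalized matrix), `raw` (counts),
#'   `totals` (reads per timepoint).
#' @export
count_promoter_signal <- function(reads, windows) {
  stopifnot(is.list(reads), length(reads) >= 1)
  wgr <- GenomicRanges::GRanges(
    seqnames = windows$chrom,
    ranges = IRanges::IRanges(start = windows$start + 1L, end = windows$end))
  raw <- sapply(names(reads), function(tp) {
    iset <- reads[[tp]]
    if (iset$total_count == 0)
      stop("timepoint ", tp, " has zero total reads")
    GenomicRanges::countOverlaps(wgr, .as_granges(iset), ignore.strand = TRUE)
  })
  raw <- matrix(raw, nrow = nrow(windows),
                dimnames = list(windows$gene_id, names(reads)))
  totals <- vapply(reads, `[[`, 0, "total_count")
  signal <- sweep(raw, 2, totals, "/") * 1e6
  structure(list(gene_id = windows$gene_id, signal = signal, raw = raw,
                 totals = totals),
            class = "promoter_signal")
}

#' @export
print.promoter_signal <- function(x, ...) {
  cat("promoter_signal:", nrow(x$signal), "genes x", ncol(x$signal),
      "timepoints; library sizes", paste(x$totals, collapse = "/"), "\n")
  invisible(x)
}

#' Relative amplitude of a promoter signal track
#'
#' `(max - min) / max` across timepoints; 0 for constant and for all-zero
#' tracks.
#'
#' @param track numeric vector over timepoints, a genes x timepoints
#'   matrix, or a `promoter_signal` object.
#' @return numeric scalar or per-gene vector in [0, 1].
#' @export
promoter_rel_amp <- function(track) {
  if (inherits(track, "promoter_signal")) track <- track$signal
  if (is.matrix(track)) {
    mx <- apply(track, 1, max); mn <- apply(track, 1, min)
    return(ifelse(mx > 0, (mx - mn) / mx, 0))
  }
  if (length(track) < 2) stop("need at least 2 timepoints")
  mx <- max(track)
  if (mx <= 0) return(0)
  (mx - min(track)) / mx
}

#' Split genes by promoter acetylation amplitude
#'
#' `high` when the relative amplitude exceeds the cutoff, `low` otherwise
#' (the boundary value goes to `low`).  Default cutoff 0.466; 0.5 is the
#' documented alternative preset.
#'
#' @param tracks a `promoter_signal` object, or a named numeric vector of
#'   relative amplitudes.
#' @param cutoff amplitude cutoff.
#' @return list with `low` and `high` gene id vectors and the `rel_amp`
#'   vector used.
#' @export
amp_cutoff_split <- function(tracks, cutoff = 0.466) {
  if (inherits(tracks, "promoter_signal")) {
    ra <- promoter_rel_amp(tracks)
    ids <- tracks$gene_id
  } else {
    ra <- tracks
    ids <- names(tracks)
    if (is.null(ids)) ids <- as.character(seq_along(ra))
  }
  list(low = ids[ra <= cutoff], high = ids[ra > cutoff], rel_amp = ra)
}

#' Write a promoter signal table as TSV
#'
#' Columns: gene_id, one normalized signal column per timepoint, rel_amp,
#' amp_class.
#'
#' @param sig a `promoter_signal` object.
#' @param path output path.
#' @param cutoff amplitude cutoff for the class column.
#' @export
write_promoter_signal <- function(sig, path, cutoff = 0.466) {
  ra <- promoter_rel_amp(sig)
  out <- data.frame(gene_id = sig$gene_id, sig$signal,
                    rel_amp = ra,
                    amp_class = ifelse(ra > cutoff, "high", "low"),
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
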