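#' Map motif sites to gene promoters
#'
#' A gene carries a motif when at least one site of that motif overlaps
#' its promoter window by >= 1 bp (a site spanning two windows counts for
#' both genes).  Site records must carry the motif id in the `name` field.
#'
#' @param sites an [interval_set()] of motif sites (BED name = motif id).
#' @param windows promoter windows, typically [motif_promoter_windows()].
#' @return named list: motif id -> character vector of gene ids.
#' @export
genes_with_motif <- function(sites, windows) {
  rec <- sites$records
  if (!"name" %in% names(rec) || anyNA(rec$name))
    stop("motif sites must carry a motif id in the name field")
  wgr <- GenomicRanges::GRanges(
    seqnames = windows$chrom,
    ranges = IRanges::IRanges(start = windows$start + 1L, end = windows$end))
  sgr <- .as_granges(sites)
  hits <- GenomicRanges::findOverlaps(sgr, wgr, ignore.strand = TRUE)
  if (!length(hits)) return(stats::setNames(list(), character()))
  df <- data.frame(motif = rec$name[S4Vectors::queryHits(hits)],
                   gene = windows$gene_id[S4Vectors::subjectHits(hits)],
                   stringsAsFactors = FALSE)
  lapply(split(df$gene, df$motif), unique)
}

#' Fisher-exact motif enrichment over a gene list
#'
#' For each motif the four counts are reported as classically defined:
#' x1 = list genes with the motif, x2 = list genes without, z1 = universe
#' (genome) genes with the motif, z2 = universe genes without.  The 2x2
#' table actually tested contrasts the list against the rest of the
#' universe (background = universe minus list), which keeps the margins
#' independent; both the raw counts and the tested table's odds ratio are
#' returned.  P-values are Fisher's exact (two-sided by default) with
#' Benjamini-Hochberg FDR across motifs.
#'
#' @param list_genes gene ids of interest (subset of `universe_genes`).
#' @param universe_genes all genes considered.
#' @param motif_gene_sets named list: motif id -> gene ids with the motif.
#' @param alternative "two.sided" (default) or "greater".
#' @return data.frame: motif_id, x1, x2, z1, z2, odds_ratio, p, fdr.
#' @export
fisher_enrichment <- function(list_genes, universe_genes, motif_gene_sets,
                              alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  if (!length(list_genes) || !length(universe_genes))
    stop("empty gene list or universe")
  universe_genes <- unique(universe_genes)
  list_genes <- unique(list_genes)
  if (length(setdiff(list_genes, universe_genes)))
    stop("gene list is not a subset of the universe")
  N <- length(universe_genes)
  n <- length(list_genes)
  rows <- lapply(names(motif_gene_sets), function(m) {
    withm <- intersect(motif_gene_sets[[m]], universe_genes)
    x1 <- length(intersect(list_genes, withm))
    x2 <- n - x1
    z1 <- length(withm)
    z2 <- N - z1
    a <- x1; b <- x2; cc <- z1 - x1; d <- z2 - x2
    tab <- matrix(c(a, cc, b, d), 2)
    p <- stats::fisher.test(tab, alternative = alternative)$p.value
    orat <- if (b * cc == 0) {
      if (a * d == 0) NA_real_ else Inf
    } else (a * d) / (b * cc)
    data.frame(motif_id = m, x1 = x1, x2 = x2, z1 = z1, z2 = z2,
               odds_ratio = orat, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  out[order(out$p), ]
}

#' Motifs uniquely enriched in one of two gene clusters
#'
#' A motif is uniquely enriched in cluster 1 when its FDR is below the
#' threshold there and at or above it in cluster 2 (and vice versa).
#'
#' @param enrich1,enrich2 [fisher_enrichment()] tables over the same
#'   motifs.
#' @param fdr_threshold significance threshold (default 0.05).
#' @return list with `only1` and `only2` motif id vectors.
#' @export
uniquely_enriched <- function(enrich1, enrich2, fdr_threshold = 0.05) {
  f1 <- stats::setNames(enrich1$fdr, enrich1$motif_id)
  f2 <- stats::setNames(enrich2$fdr, enrich2$motif_id)
  motifs <- intersect(names(f1), names(f2))
  list(only1 = motifs[f1[motifs] < fdr_threshold & f2[motifs] >= fdr_threshold],
       only2 = motifs[f2[motifs] < fdr_threshold & f1[motifs] >= fdr_threshold])
}

#' Read position weight matrices in MEME minimal format
#'
#' Parses `MOTIF` blocks with their letter-probability matrices; the
#' background letter frequencies line is honoured when present, else a
#' uniform background is used.  A pseudocount is mixed in so no
#' probability is exactly zero.
#'
#' @param path MEME minimal format file.
#' @param pseudocount mixed into each position (default 1e-4).
#' @return list of PWMs: each a list with `motif_id`, `matrix` (positions
#'   x 4, columns A,C,G,T) and `background`.
#' @export
read_meme <- function(path, pseudocount = 1e-4) {
  lines <- readLines(path)
  bg <- rep(0.25, 4)
  bgi <- grep("^Background letter frequencies", lines)
  if (length(bgi)) {
    toks <- strsplit(trimws(lines[bgi[1] + 1]), "\\s+")[[1]]
    bg <- as.numeric(toks[c(2, 4, 6, 8)])
  }
  starts <- grep("^MOTIF", lines)
  pwms <- list()
  for (s in starts) {
    id <- strsplit(trimws(lines[s]), "\\s+")[[1]][2]
    h <- grep("^letter-probability matrix", lines[s:length(lines)])[1] + s - 1
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[h]))
    m <- do.call(rbind, lapply(lines[(h + 1):(h + w)], function(l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
    pwms[[id]] <- pwm(id, m, bg, pseudocount)
  }
  pwms
}

#' Build a validated position weight matrix
#'
#' @param motif_id motif identifier.
#' @param matrix positions x 4 base probability matrix (columns A,C,G,T).
#' @param background length-4 background base probabilities.
#' @param pseudocount mixed in to avoid exact zeros.
#' @export
pwm <- function(motif_id, matrix, background = rep(0.25, 4),
                pseudocount = 1e-4) {
  matrix <- as.matrix(matrix)
  stopifnot(ncol(matrix) == 4, all(matrix >= 0))
  matrix <- (matrix + pseudocount) / (1 + 4 * pseudocount)
  if (any(abs(rowSums(matrix) - 1) > 1e-6))
    stop("PWM rows must each sum to 1")
  background <- background / sum(background)
  colnames(matrix) <- c("A", "C", "G", "T")
  structure(list(motif_id = motif_id, matrix = matrix,
                 background = background), class = "pwm")
}

# reverse-complement of a PWM: reverse positions, swap A<->T and C<->G
.revcomp_pwm <- function(p) {
  m <- p$matrix[rev(seq_len(nrow(p$matrix))), c("T", "G", "C", "A"),
                drop = FALSE]
  colnames(m) <- c("A", "C", "G", "T")
  list(matrix = m, background = p$background[c(4, 3, 2, 1)])
}

#' Scan sequences for motif sites above a likelihood-ratio threshold
#'
#' At every placement on both strands the likelihood ratio is the product
#' over positions of `p_motif(base)/p_background(base)`; placements with
#' LR above the threshold are reported as 0-based half-open intervals
#' (score = log LR).  `N` bases force the LR to 0 at overlapping
#' placements.
#'
#' @param sequences named character vector of sequences, or a
#'   `Biostrings::DNAStringSet`.
#' @param pwm a [pwm()] object.
#' @param lr_threshold sites with LR strictly above this are reported
#'   (default 500).
#' @return an [interval_set()] with name = motif id, score = log LR,
#'   strand.
#' @export
pwm_scan <- function(sequences, pwm, lr_threshold = 500) {
  if (inherits(sequences, "DNAStringSet")) {
    nm <- names(sequences)
    sequences <- as.character(sequences)
    names(sequences) <- nm
  }
  if (is.null(names(sequences)))
    names(sequences) <- paste0("seq", seq_along(sequences))
  w <- nrow(pwm$matrix)
  logthr <- log(lr_threshold)
  strands <- list(`+` = pwm, `-` = .revcomp_pwm(pwm))
  rec <- list()
  for (nm in names(sequences)) {
    code <- match(strsplit(toupper(sequences[[nm]]), "")[[1]],
                  c("A", "C", "G", "T"))
    L <- length(code)
    if (L < w) next
    for (st in names(strands)) {
      p <- strands[[st]]
      lw <- log(p$matrix) - rep(log(p$background), each = w)
      scores <- numeric(L - w + 1)
      for (k in seq_len(w)) {
        v <- lw[k, code[k:(L - w + k)]]
        v[is.na(v)] <- -Inf                     # N base: LR = 0
        scores <- scores + v
      }
      hit <- which(unname(scores) > logthr)
      if (length(hit))
        rec[[length(rec) + 1]] <- data.frame(
          chrom = nm, start = hit - 1L, end = hit - 1L + w,
          name = pwm$motif_id, score = unname(scores[hit]), strand = st,
          row.names = NULL, stringsAsFactors = FALSE)
    }
  }
  interval_set(if (length(rec)) do.call(rbind, rec) else data.frame())
}
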