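#' Hypergeometric over-representation analysis
#'
#' For each term the upper-tail hypergeometric probability of observing at
#' least the overlap between the gene list and the term's universe
#' members, with Benjamini-Hochberg FDR across terms.  The gene ratio is
#' the number of list genes in the term divided by the list size.
#'
#' @param list_genes gene ids of interest (subset of `universe`).
#' @param universe background gene ids.
#' @param collection a [gene_set_collection()].
#' @return data.frame: term_id, description, k (list genes in term),
#'   K (universe genes in term), n (list size), N (universe size),
#'   gene_ratio, p, fdr; ordered by p.
#' @export
ora <- function(list_genes, universe, collection) {
  stopifnot(inherits(collection, "GeneSetCollection"))
  universe <- unique(universe)
  list_genes <- unique(list_genes)
  if (length(setdiff(list_genes, universe)))
    stop("gene list is not a subset of the universe")
  N <- length(universe); n <- length(list_genes)
  rows <- lapply(names(collection$sets), function(id) {
    members <- intersect(collection$sets[[id]], universe)
    K <- length(members)
    if (K == 0) {
      warning("term ", id, " has no universe members; skipped")
      return(NULL)
    }
    k <- length(intersect(list_genes, members))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = id, description = collection$descriptions[[id]],
               k = k, K = K, n = n, N = N, gene_ratio = k / n, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no term has universe members")
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  out[order(out$p), ]
}

#' Cohen's kappa between two gene sets over a universe
#'
#' Each set is a binary rater over the universe; `pr_a` is the fraction of
#' genes on which the raters agree, `pr_e` the chance agreement from the
#' marginals, and `kappa = (pr_a - pr_e)/(1 - pr_e)`.  Identical sets give
#' kappa 1 (including two identical constant raters, where pr_e = 1);
#' constant-but-different raters give kappa 0 with a warning.
#'
#' @param term_a_members,term_b_members gene id vectors (subsets of
#'   `universe`).
#' @param universe gene id vector, non-empty.
#' @return list: term ids left NA, `kappa`, `pr_a`, `pr_e`.
#' @export
kappa_score <- function(term_a_members, term_b_members, universe) {
  if (!length(universe)) stop("universe must be non-empty")
  a <- universe %in% term_a_members
  b <- universe %in% term_b_members
  pr_a <- mean(a == b)
  pa <- mean(a); pb <- mean(b)
  pr_e <- pa * pb + (1 - pa) * (1 - pb)
  if (pr_e >= 1) {
    k <- 1                                  # both raters constant and equal
  } else {
    k <- (pr_a - pr_e) / (1 - pr_e)
  }
  constant <- (pa %in% c(0, 1)) && (pb %in% c(0, 1))
  if (constant && pa != pb)
    warning("constant but different raters; kappa 0")
  list(kappa = k, pr_a = pr_a, pr_e = pr_e)
}

#' Kappa-score term similarity network
#'
#' Significant terms become nodes; undirected edges link pairs whose
#' kappa score reaches the threshold; functional groups are the connected
#' components.  Node size metadata is the term's mapped-gene count.
#'
#' @param ora_table an [ora()] result (or data.frame with term_id and the
#'   significance column).
#' @param collection the [gene_set_collection()] the terms came from.
#' @param universe gene universe for the kappa computation.
#' @param kappa_threshold minimum kappa for an edge (default 0.4).
#' @param sig_threshold admission threshold on the significance column
#'   (default 0.05).
#' @param sig_column "fdr" (default) or "p".
#' @return list: `nodes` (data.frame term_id, component, mapped_genes),
#'   `edges` (data.frame term_a, term_b, kappa), `kappa_threshold`.
#' @export
kappa_network <- function(ora_table, collection, universe,
                          kappa_threshold = 0.4, sig_threshold = 0.05,
                          sig_column = c("fdr", "p")) {
  sig_column <- match.arg(sig_column)
  terms <- ora_table$term_id[ora_table[[sig_column]] <= sig_threshold]
  members <- lapply(terms, function(id)
    intersect(collection$sets[[id]], universe))
  names(members) <- terms
  edges <- NULL
  if (length(terms) >= 2) {
    cmb <- utils::combn(terms, 2)
    kap <- apply(cmb, 2, function(pr)
      kappa_score(members[[pr[1]]], members[[pr[2]]], universe)$kappa)
    keep <- kap >= kappa_threshold
    if (any(keep))
      edges <- data.frame(term_a = cmb[1, keep], term_b = cmb[2, keep],
                          kappa = kap[keep], stringsAsFactors = FALSE)
  }
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(terms), name = terms)
  if (!is.null(edges))
    g <- igraph::add_edges(g, rbind(match(edges$term_a, terms),
                                    match(edges$term_b, terms)))
  comp <- if (length(terms)) igraph::components(g)$membership else integer()
  nodes <- data.frame(term_id = terms,
                      component = as.integer(comp),
                      mapped_genes = lengths(members),
                      stringsAsFactors = FALSE)
  if (is.null(edges))
    edges <- data.frame(term_a = character(), term_b = character(),
                        kappa = numeric(), stringsAsFactors = FALSE)
  list(nodes = nodes, edges = edges, kappa_threshold = kappa_threshold)
}
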