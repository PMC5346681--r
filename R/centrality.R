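#' Degree centrality of every gene
#'
#' Degree is the number of distinct interaction partners of a gene in the
#' network. Genes declared but isolated have degree 0.
#'
#' @param network an `interaction_network`
#' @return an object of class `centrality_scores`: list with `metric`
#'   (`"degree"`) and `scores`, a named non-negative vector over all network
#'   genes
#' @export
degree_scores <- function(network) {
  g <- as_igraph(network)
  s <- igraph::degree(g, loops = FALSE)
  structure(list(metric = "degree", scores = s[network$genes]),
            class = "centrality_scores")
}

#' Betweenness centrality of every gene
#'
#' For gene i, betweenness is the sum over unordered gene pairs \{j, k\}
#' (j, k both distinct from i) of the fraction of shortest j--k paths that
#' pass through i:
#' \deqn{BC_i = \sum_{j<k} g_{jk}(i) / g_{jk}}
#' where \eqn{g_{jk}} is the number of shortest paths between j and k and
#' \eqn{g_{jk}(i)} the number of those passing through i. Pairs in different
#' connected components contribute 0. Scores are unnormalized raw
#' pair-fraction sums (any constant normalization would leave the within-
#' network ranking unchanged). Computed by Brandes' exact algorithm for
#' unweighted graphs.
#'
#' @param network an `interaction_network`
#' @return a `centrality_scores` object with `metric = "betweenness"`
#' @export
betweenness_scores <- function(network) {
  g <- as_igraph(network)
  s <- igraph::betweenness(g, directed = FALSE, weights = NULL, normalized = FALSE)
  structure(list(metric = "betweenness", scores = s[network$genes]),
            class = "centrality_scores")
}

#' @export
print.centrality_scores <- function(x, ...) {
  cat(sprintf("centrality_scores (%s) over %d genes; range [%g, %g]\n",
              x$metric, length(x$scores), min(x$scores), max(x$scores)))
  invisible(x)
}

#' Rank genes by a centrality score
#'
#' Orders genes best-first by descending score with a fully deterministic tie
#' rule: `"lexicographic"` (default) breaks tied scores by gene identifier in
#' C-locale order; `"random_seeded"` shuffles tied genes with a caller-supplied
#' seed, so the same seed always reproduces the same order.
#'
#' @param scores a `centrality_scores` object
#' @param tie_rule `"lexicographic"` or `"random_seeded"`
#' @param seed integer; required when `tie_rule = "random_seeded"`
#' @return an object of class `gene_ranking`: list with `metric`, `order`
#'   (genes best first), `scores` (named, in ranking order), `tie_rule`,
#'   and `seed`
#' @export
rank_genes <- function(scores, tie_rule = c("lexicographic", "random_seeded"),
                       seed = NULL) {
  stopifnot(inherits(scores, "centrality_scores"))
  tie_rule <- match.arg(tie_rule)
  s <- scores$scores
  genes <- names(s)
  n <- length(s)
  if (tie_rule == "lexicographic") {
    ord <- order(-s, genes, method = "radix")
  } else {
    if (is.null(seed)) {
      stop("tie_rule 'random_seeded' requires a `seed`", call. = FALSE)
    }
    shuffle <- with_seed(seed, sample.int(n))
    ord <- order(-s, shuffle, method = "radix")
  }
  structure(
    list(metric = scores$metric, order = genes[ord], scores = s[ord],
         tie_rule = tie_rule, seed = seed),
    class = "gene_ranking"
  )
}

#' @export
print.gene_ranking <- function(x, ...) {
  cat(sprintf("gene_ranking (%s, %s ties): %d genes; top: %s\n",
              x$metric, x$tie_rule, length(x$order),
              paste(utils::head(x$order, 5L), collapse = ", ")))
  invisible(x)
}

#' Write a ranking as TSV (gene, score, rank)
#'
#' Rank is 1-based with the best-ranked gene first.
#'
#' @param ranking a `gene_ranking`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_ranking <- function(ranking, path) {
  stopifnot(inherits(ranking, "gene_ranking"))
  df <- data.frame(gene = ranking$order, score = unname(ranking$scores),
                   rank = seq_along(ranking$order), stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
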