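#' Randomly remove a fraction of interactions
#'
#' Retains a uniformly random edge subset of size
#' `|E| - round(fraction_removed * |E|)`. The gene universe is unchanged:
#' genes whose every interaction is removed stay in the network with degree
#' zero, so downstream confusion-table denominators remain comparable across
#' removal fractions.
#'
#' @param network an `interaction_network`
#' @param fraction_removed fraction of edges to remove, in \[0, 1\]
#' @param seed integer RNG seed
#' @return a down-sampled `interaction_network` over the same genes
#' @export
downsample_edges <- function(network, fraction_removed, seed = 1L) {
  stopifnot(inherits(network, "interaction_network"))
  if (fraction_removed < 0 || fraction_removed > 1) {
    stop("`fraction_removed` must be in [0, 1]", call. = FALSE)
  }
  m <- n_edges(network)
  keep_n <- m - round(fraction_removed * m)
  keep <- with_seed(seed, sort(sample.int(m, keep_n)))
  interaction_network(network$edges[keep, , drop = FALSE], genes = network$genes)
}

#' Prediction stability under network incompleteness
#'
#' Emulates incomplete interactome maps by removing increasing fractions of
#' interactions at random, re-ranking genes by degree in the remaining
#' network, and recomputing recall, accuracy and specificity at a fixed
#' evaluation cutoff. Each (removal fraction, replicate) cell is seeded
#' deterministically from `seed` and the cell indices, so a profile is exactly
#' reproducible.
#'
#' @param network an `interaction_network`
#' @param positives a `gene_set` of gold-standard genes; must be a subset of
#'   the network's genes
#' @param fractions_removed removal fractions to test (default 0 to 0.9 by 0.1)
#' @param replicates independent removal realizations per fraction (default 10)
#' @param eval_fraction top-ranked fraction used as the prediction cutoff
#'   (default 0.10)
#' @param metric centrality used for re-ranking (`"degree"`, the fast,
#'   robust choice; `"betweenness"` also supported)
#' @param seed integer master seed
#' @return a data frame of class `robustness_profile` with columns
#'   `fraction_removed`, `replicate`, `n_edges`, `recall`, `accuracy`,
#'   `specificity`; attributes `eval_fraction` and `seed`
#' @export
robustness_profile <- function(network, positives,
                               fractions_removed = seq(0, 0.9, by = 0.1),
                               replicates = 10L, eval_fraction = 0.10,
                               metric = c("degree", "betweenness"),
                               seed = 1L) {
  stopifnot(inherits(network, "interaction_network"), inherits(positives, "gene_set"))
  metric <- match.arg(metric)
  if (!all(positives$ids %in% network$genes)) {
    stop("positives are not a subset of the network genes; ",
         "apply restrict_to_network() first", call. = FALSE)
  }
  score_fun <- if (metric == "degree") degree_scores else betweenness_scores
  rows <- list()
  for (i in seq_along(fractions_removed)) {
    f <- fractions_removed[i]
    for (j in seq_len(replicates)) {
      sub_seed <- derive_seed(seed, i, j)
      sub <- downsample_edges(network, f, seed = sub_seed)
      rk <- rank_genes(score_fun(sub), tie_rule = "lexicographic")
      m <- suppressMessages(classification_metrics(
        confusion_at_fraction(rk, positives, eval_fraction)))
      rows[[length(rows) + 1L]] <- data.frame(
        fraction_removed = f, replicate = j, n_edges = n_edges(sub),
        recall = m[["recall"]], accuracy = m[["accuracy"]],
        specificity = m[["specificity"]])
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "eval_fraction") <- eval_fraction
  attr(out, "seed") <- as.integer(seed)
  attr(out, "metric") <- metric
  class(out) <- c("robustness_profile", "data.frame")
  out
}

#' Write a robustness profile as TSV
#' @param profile a `robustness_profile`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_profile <- function(profile, path) {
  utils::write.table(as.data.frame(profile), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
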