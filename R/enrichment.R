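#' Permutation null for top-fraction recovery
#'
#' Benchmarks a centrality ranking against random orderings of the same gene
#' universe. In each of `n_perm` permutations the genes are uniformly randomly
#' ranked and the number of positives recovered in the top
#' `floor(fraction * N)` block is recorded. Fold enrichment is the observed
#' recovered proportion divided by the mean proportion under the null, and
#' the empirical p-value uses the add-one estimator
#' \eqn{p = (1 + \#\{null \ge observed\}) / (n_{perm} + 1)},
#' which can never report exactly zero.
#'
#' @inheritParams confusion_at_fraction
#' @param fraction top-ranked fraction used as the prediction cutoff
#'   (default 0.10)
#' @param n_perm number of random rankings (default 1000)
#' @param seed integer RNG seed; recorded in the result
#' @return an object of class `enrichment_result`: list with `fraction`,
#'   `observed_recovery`, `observed_proportion`, `null_mean_recovery`,
#'   `null_mean_proportion`, `null_sd_recovery`, `fold_enrichment`,
#'   `p_empirical`, `n_perm`, `seed`, and the raw `null_recoveries` vector
#' @export
permutation_null <- function(ranking, positives, fraction = 0.10,
                             n_perm = 1000L, seed = 1L) {
  stopifnot(inherits(ranking, "gene_ranking"), n_perm >= 1L)
  pos <- if (inherits(positives, "gene_set")) positives$ids else as.character(positives)
  if (length(pos) == 0L) {
    stop("`positives` is empty; recovered proportions are undefined", call. = FALSE)
  }
  cc <- confusion_at_fraction(ranking, positives, fraction)
  obs <- cc$TP
  n <- length(ranking$order)
  k <- floor_fraction(fraction, n)
  is_pos <- ranking$order %in% pos
  null_rec <- with_seed(seed, {
    vapply(seq_len(n_perm),
           function(b) sum(is_pos[sample.int(n, k)]),
           integer(1))
  })
  np <- length(pos)
  null_mean <- mean(null_rec)
  obs_prop <- obs / np
  null_prop <- null_mean / np
  structure(
    list(fraction = fraction,
         observed_recovery = obs,
         observed_proportion = obs_prop,
         null_mean_recovery = null_mean,
         null_mean_proportion = null_prop,
         null_sd_recovery = stats::sd(null_rec),
         fold_enrichment = if (null_prop > 0) obs_prop / null_prop else NA_real_,
         p_empirical = (1 + sum(null_rec >= obs)) / (n_perm + 1),
         n_perm = as.integer(n_perm),
         seed = as.integer(seed),
         null_recoveries = null_rec),
    class = "enrichment_result"
  )
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(paste0("enrichment at top %.0f%%: recovered %d positives ",
                     "(null mean %.2f); fold = %.3g, empirical p = %.4g ",
                     "(%d permutations, seed %d)\n"),
              100 * x$fraction, x$observed_recovery, x$null_mean_recovery,
              x$fold_enrichment, x$p_empirical, x$n_perm, x$seed))
  invisible(x)
}

#' Serialize an enrichment result to JSON
#'
#' Writes all summary fields (not the raw null recoveries) as a JSON record.
#'
#' @param result an `enrichment_result`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_enrichment <- function(result, path) {
  stopifnot(inherits(result, "enrichment_result"))
  out <- result[setdiff(names(result), "null_recoveries")]
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
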