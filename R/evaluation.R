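#' Confusion counts at a top-fraction threshold
#'
#' The first `floor(fraction * N)` genes of the ranking are treated as
#' predicted positives; the gold-standard genes (restricted to the network)
#' are the positive class and all remaining network genes the negative class.
#'
#' @param ranking a `gene_ranking`
#' @param positives a `gene_set` or character vector; must be a subset of the
#'   ranked genes -- apply [restrict_to_network()] first
#' @param fraction threshold fraction in \[0, 1\]
#' @return an object of class `confusion_counts`: list with integer `TP`,
#'   `FP`, `TN`, `FN` and `threshold_fraction`
#' @export
confusion_at_fraction <- function(ranking, positives, fraction) {
  stopifnot(inherits(ranking, "gene_ranking"))
  pos <- if (inherits(positives, "gene_set")) positives$ids else as.character(positives)
  if (fraction < 0 || fraction > 1) stop("`fraction` must be in [0, 1]", call. = FALSE)
  if (!all(pos %in% ranking$order)) {
    stop("positives are not a subset of the ranked genes; ",
         "apply restrict_to_network() before evaluation", call. = FALSE)
  }
  n <- length(ranking$order)
  k <- floor_fraction(fraction, n)
  top <- ranking$order[seq_len(k)]
  tp <- sum(top %in% pos)
  np <- length(pos)
  structure(
    list(TP = tp, FP = k - tp, FN = np - tp, TN = n - k - (np - tp),
         threshold_fraction = fraction),
    class = "confusion_counts"
  )
}

#' Recall, accuracy and specificity from confusion counts
#'
#' recall = TP/(TP+FN); accuracy = (TP+TN)/(TP+FP+TN+FN);
#' specificity = TN/(TN+FP). A metric whose denominator is zero is reported
#' as `NA` (undefined) with a note, never silently as 0.
#'
#' @param counts a `confusion_counts` object
#' @param positives_total optional integer: use this as the recall denominator
#'   instead of the within-network positive count (TP+FN). Useful for
#'   cross-network comparison on a common denominator, e.g. the full
#'   gold-standard size.
#' @return named numeric vector `c(recall, accuracy, specificity)`
#' @export
classification_metrics <- function(counts, positives_total = NULL) {
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- counts$TP; fp <- counts$FP; tn <- counts$TN; fn <- counts$FN
  rec_den <- if (is.null(positives_total)) tp + fn else positives_total
  recall <- if (rec_den > 0) tp / rec_den else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  total <- tp + fp + tn + fn
  acc <- if (total > 0) (tp + tn) / total else NA_real_
  if (anyNA(c(recall, spec, acc))) {
    message("a metric denominator is zero; reporting NA for the affected metric")
  }
  c(recall = recall, accuracy = acc, specificity = spec)
}

#' Threshold-sweep evaluation curve
#'
#' Computes confusion counts and metrics at each threshold fraction,
#' sweeping from excluding everything to including the whole ranking
#' (default: 1% steps from 0 to 100%).
#'
#' @inheritParams confusion_at_fraction
#' @param fractions ascending numeric vector of threshold fractions in \[0, 1\]
#' @param positives_total optional common recall denominator
#'   (see [classification_metrics()])
#' @return a data frame of class `evaluation_curve` with columns `fraction`,
#'   `TP`, `FP`, `TN`, `FN`, `recall`, `accuracy`, `specificity`; attributes
#'   `positives_n` and `genes_n`
#' @export
evaluation_curve <- function(ranking, positives, fractions = seq(0, 1, by = 0.01),
                             positives_total = NULL) {
  if (is.unsorted(fractions)) stop("`fractions` must be ascending", call. = FALSE)
  rows <- lapply(fractions, function(f) {
    cc <- confusion_at_fraction(ranking, positives, f)
    m <- suppressMessages(classification_metrics(cc, positives_total))
    data.frame(fraction = f, TP = cc$TP, FP = cc$FP, TN = cc$TN, FN = cc$FN,
               recall = m[["recall"]], accuracy = m[["accuracy"]],
               specificity = m[["specificity"]])
  })
  out <- do.call(rbind, rows)
  pos <- if (inherits(positives, "gene_set")) positives$ids else as.character(positives)
  attr(out, "positives_n") <- length(pos)
  attr(out, "genes_n") <- length(ranking$order)
  class(out) <- c("evaluation_curve", "data.frame")
  out
}

#' Write an evaluation curve as TSV
#' @param curve an `evaluation_curve`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_curve <- function(curve, path) {
  utils::write.table(as.data.frame(curve), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
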