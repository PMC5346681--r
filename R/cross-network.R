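#' Relative ranks of genes across networks
#'
#' A gene's relative rank in a network is its rank position divided by the
#' total number of genes in that network, so values lie in (0, 1\] and smaller
#' means more central. Because it is scale-free, relative ranks are comparable
#' across networks of different sizes. A gene absent from a network gets `NA`.
#'
#' @param rankings named list of `gene_ranking` objects, one per network
#' @param genes character vector of focal genes (rows of the output)
#' @return a data frame with column `gene` plus one numeric column per network
#'   label; `NA` marks absence from that network
#' @export
relative_ranks <- function(rankings, genes) {
  stopifnot(length(rankings) > 0L, !is.null(names(rankings)),
            all(nzchar(names(rankings))))
  genes <- as.character(genes)
  cols <- lapply(rankings, function(rk) {
    stopifnot(inherits(rk, "gene_ranking"))
    rel <- seq_along(rk$order) / length(rk$order)
    names(rel) <- rk$order
    unname(rel[genes])
  })
  out <- data.frame(gene = genes, stringsAsFactors = FALSE)
  for (lab in names(rankings)) out[[lab]] <- cols[[lab]]
  out
}

#' Write a relative-rank table as TSV (explicit NA for absence)
#' @param table a data frame from [relative_ranks()]
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_relative_ranks <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Overlap of a focal network's top-k genes with other networks
#'
#' Takes the `k` best-ranked genes of the focal network and reports how many
#' are present in at least one other network, and which of them are also
#' centrally ranked elsewhere (relative rank at or below `low_rank_cut` in at
#' least one other network) versus centrally ranked only in the focal network.
#'
#' @param focal the focal network's `gene_ranking`
#' @param others named list of `gene_ranking` objects for the other networks
#' @param k number of top focal genes to consider (default 100)
#' @param low_rank_cut relative-rank threshold below which a gene counts as
#'   centrally ranked in another network (default 0.10); always reported in
#'   the result
#' @return an object of class `topk_overlap`: list with `top_genes`,
#'   `shared_any` (count present in >= 1 other network), `shared_genes`,
#'   `low_elsewhere` (top genes also centrally ranked in another network),
#'   `focal_only_low` (shared genes centrally ranked only in the focal
#'   network), `k`, `low_rank_cut`
#' @export
top_k_overlap <- function(focal, others, k = 100L, low_rank_cut = 0.10) {
  stopifnot(inherits(focal, "gene_ranking"))
  if (k > length(focal$order)) {
    stop("`k` exceeds the number of genes in the focal network", call. = FALSE)
  }
  top <- focal$order[seq_len(k)]
  if (length(others) == 0L) {
    res <- list(top_genes = top, shared_any = 0L, shared_genes = character(0),
                low_elsewhere = character(0), focal_only_low = character(0),
                k = as.integer(k), low_rank_cut = low_rank_cut)
    return(structure(res, class = "topk_overlap"))
  }
  stopifnot(!is.null(names(others)), all(nzchar(names(others))))
  rel <- relative_ranks(others, top)
  relmat <- as.matrix(rel[, -1L, drop = FALSE])
  present <- rowSums(!is.na(relmat)) > 0L
  low <- rowSums(!is.na(relmat) & relmat <= low_rank_cut) > 0L
  structure(
    list(top_genes = top,
         shared_any = sum(present),
         shared_genes = top[present],
         low_elsewhere = top[low],
         focal_only_low = top[present & !low],
         k = as.integer(k),
         low_rank_cut = low_rank_cut),
    class = "topk_overlap"
  )
}

#' @export
print.topk_overlap <- function(x, ...) {
  cat(sprintf(paste0("top-%d overlap: %d/%d present in >=1 other network; ",
                     "%d also ranked in the top %.0f%% elsewhere ",
                     "(relative-rank cut %.2f)\n"),
              x$k, x$shared_any, x$k, length(x$low_elsewhere),
              100 * x$low_rank_cut, x$low_rank_cut))
  invisible(x)
}

#' Serialize a top-k overlap summary to JSON
#' @param overlap a `topk_overlap`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_overlap <- function(overlap, path) {
  stopifnot(inherits(overlap, "topk_overlap"))
  jsonlite::write_json(unclass(overlap), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}
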