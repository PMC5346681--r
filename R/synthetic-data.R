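# Synthetic data with the statistical structure the pipeline assumes:
# heavy-tailed PPI-like networks, hub-biased positive gene sets, and mutation
# tables with a planted rate difference. Everything is seeded and
# reproducible.

#' Generate a synthetic scale-free interaction network
#'
#' Two generative models are offered. `"preferential_attachment"`
#' (Barabasi-Albert) grows the network one gene at a time, attaching each new
#' gene to `m` existing genes with probability proportional to their current
#' degree; for `n` genes this yields exactly `2n - 3` edges at `m = 2`
#' (each of the `n - 2` later genes contributes `m` attachments, plus the one
#' initial edge). `"configuration_model"` draws a degree sequence from a
#' discrete power law `P(k) ~ k^-gamma` on `k >= min_degree` and wires a
#' simple graph realizing it; self-loops and multi-edges are avoided by
#' construction and the graph is simplified as a safeguard. Both produce the
#' heavy-tailed degree distributions characteristic of protein interactomes.
#'
#' @param n_genes number of genes
#' @param model `"preferential_attachment"` (default) or
#'   `"configuration_model"`
#' @param m attachments per new gene (preferential attachment; default 2)
#' @param gamma power-law exponent of the degree distribution
#'   (configuration model; default 2.5)
#' @param min_degree minimum degree (configuration model; default 1)
#' @param seed integer RNG seed
#' @return an `interaction_network` with gene identifiers `g0001, g0002, ...`
#' @export
generate_network <- function(n_genes,
                             model = c("preferential_attachment", "configuration_model"),
                             m = 2L, gamma = 2.5, min_degree = 1L, seed = 1L) {
  model <- match.arg(model)
  stopifnot(n_genes >= 3L)
  width <- max(4L, nchar(as.character(n_genes)))
  ids <- sprintf(paste0("g%0", width, "d"), seq_len(n_genes))
  if (model == "preferential_attachment") {
    g <- with_seed(seed, igraph::sample_pa(n_genes, m = m, directed = FALSE))
  } else {
    g <- with_seed(seed, {
      degs <- sample_powerlaw_degrees(n_genes, gamma, min_degree)
      wire_degree_sequence(degs)
    })
  }
  em <- igraph::as_edgelist(g, names = FALSE)
  interaction_network(cbind(ids[em[, 1L]], ids[em[, 2L]]), genes = ids)
}

# Discrete power-law degree sample with even sum (required for wiring).
sample_powerlaw_degrees <- function(n, gamma, min_degree) {
  kmax <- max(min_degree + 1L, floor(sqrt(n)))
  ks <- min_degree:kmax
  p <- ks^(-gamma)
  degs <- sample(ks, n, replace = TRUE, prob = p / sum(p))
  if (sum(degs) %% 2L == 1L) degs[1L] <- degs[1L] + 1L
  degs
}

# Wire a simple graph for a degree sequence, retrying with perturbed
# sequences when the one drawn is not realizable as a simple graph.
wire_degree_sequence <- function(degs, max_retries = 20L) {
  for (attempt in seq_len(max_retries)) {
    g <- tryCatch(
      igraph::sample_degseq(degs, method = "fast.heur.simple"),
      error = function(e) NULL
    )
    if (!is.null(g)) {
      if (attempt > 1L) {
        message(sprintf("degree sequence realized after %d retries", attempt - 1L))
      }
      return(igraph::simplify(g))
    }
    # decrement the largest degree: the usual cause is an infeasible tail
    degs[which.max(degs)] <- max(1L, max(degs) - 1L)
    if (sum(degs) %% 2L == 1L) degs[which.max(degs)] <- degs[which.max(degs)] + 1L
  }
  stop("could not realize a simple graph for the drawn degree sequence",
       call. = FALSE)
}

#' Plant a positive gene set with tunable hub bias
#'
#' Samples `n_positives` genes without replacement with sampling weight
#' `(degree + 1)^beta`. `beta = 0` gives a uniform draw; larger `beta`
#' concentrates the positives on hubs, emulating the premise that
#' highly connected genes are enriched for disease genes. The `+1` keeps
#' isolated genes sampleable.
#'
#' @param network an `interaction_network`
#' @param n_positives number of genes to plant
#' @param beta hub-bias exponent (>= 0; default 0 = unbiased)
#' @param seed integer RNG seed
#' @return a `gene_set` labelled with the bias used
#' @export
plant_positives <- function(network, n_positives, beta = 0, seed = 1L) {
  stopifnot(inherits(network, "interaction_network"),
            n_positives <= n_genes(network), beta >= 0)
  deg <- degree_scores(network)$scores
  w <- (deg + 1)^beta
  ids <- with_seed(seed, sample(network$genes, n_positives, prob = w))
  gene_set(ids, label = sprintf("planted(beta=%g)", beta))
}

#' Generate a synthetic mutation table
#'
#' For each cancer label, every (gene, sample) pair mutates independently:
#' positives with probability `planted_rate`, all other genes with
#' `baseline_rate`. One record per mutated pair is emitted, in the minimal
#' MAF dialect used by [read_maf()]. The per-cancer total sample count is
#' attached as the `total_samples` attribute so frequencies use the true
#' denominator even when some samples carry no mutations.
#'
#' @param genes character vector of gene identifiers
#' @param positives a `gene_set` or character vector of elevated-rate genes
#' @param n_samples samples per cancer type (default 100)
#' @param baseline_rate per-sample mutation probability of background genes
#'   (default 0.01)
#' @param planted_rate per-sample mutation probability of positive genes
#'   (default 0.10; must be >= `baseline_rate`)
#' @param cancer_types character vector of cancer labels (default `"SYNTH"`)
#' @param seed integer RNG seed
#' @return a data frame of mutation records (`gene`, `sample`, `cancer_type`,
#'   `variant_class`) with attribute `total_samples`
#' @export
generate_mutations <- function(genes, positives, n_samples = 100L,
                               baseline_rate = 0.01, planted_rate = 0.10,
                               cancer_types = "SYNTH", seed = 1L) {
  pos <- if (inherits(positives, "gene_set")) positives$ids else as.character(positives)
  stopifnot(planted_rate >= baseline_rate,
            baseline_rate >= 0, planted_rate <= 1)
  rate <- ifelse(genes %in% pos, planted_rate, baseline_rate)
  recs <- with_seed(seed, {
    out <- list()
    for (ct in cancer_types) {
      barcodes <- sprintf("%s-S%04d", ct, seq_len(n_samples))
      n_mut <- stats::rbinom(length(genes), n_samples, rate)
      gi <- rep.int(seq_along(genes), n_mut)
      if (length(gi) > 0L) {
        hit <- unlist(lapply(n_mut[n_mut > 0L],
                             function(k) sample.int(n_samples, k)),
                      use.names = FALSE)
        out[[ct]] <- data.frame(gene = genes[gi], sample = barcodes[hit],
                                cancer_type = ct,
                                variant_class = "Missense_Mutation",
                                stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, out)
  })
  if (is.null(recs)) {
    recs <- data.frame(gene = character(0), sample = character(0),
                       cancer_type = character(0), variant_class = character(0),
                       stringsAsFactors = FALSE)
  }
  rownames(recs) <- NULL
  attr(recs, "total_samples") <- stats::setNames(
    rep(as.integer(n_samples), length(cancer_types)), cancer_types)
  recs
}

#' Write mutation records as a minimal MAF file
#'
#' Emits the three standard columns (`Hugo_Symbol`, `Tumor_Sample_Barcode`,
#' `Variant_Classification`), one file per cancer type, plus a provenance
#' JSON beside it.
#'
#' @param records data frame of mutation records for a single cancer type
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_maf <- function(records, path) {
  cts <- unique(records$cancer_type)
  if (length(cts) > 1L) {
    stop("`records` spans multiple cancer types; write one file per type",
         call. = FALSE)
  }
  out <- data.frame(Hugo_Symbol = records$gene,
                    Tumor_Sample_Barcode = records$sample,
                    Variant_Classification = records$variant_class,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  ts <- attr(records, "total_samples")
  total <- if (!is.null(ts) && length(cts) == 1L && cts %in% names(ts)) ts[[cts]] else NA
  write_provenance(path, list(cancer_type = if (length(cts) == 1L) cts else NA,
                              n_records = nrow(records),
                              total_samples = total))
  invisible(path)
}
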