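#' Compare gold-standard recovery across networks
#'
#' Runs the full comparative benchmark for each supplied network and each
#' centrality metric: restrict the gold-standard set to the network, rank
#' genes, sweep the threshold for recall/accuracy/specificity curves, and
#' compute permutation-null fold enrichment at the prediction cutoff. The
#' summary table ranks networks by recall at the cutoff (then accuracy).
#'
#' @param networks named list of `interaction_network` objects
#' @param gold a `gene_set` of gold-standard genes (e.g. CGC)
#' @param metrics centralities to rank by (default degree and betweenness)
#' @param fractions threshold grid for the evaluation curves (default 1%
#'   steps from 0 to 100%)
#' @param enrich_fraction prediction cutoff for enrichment and the summary
#'   (default 0.10)
#' @param n_perm permutations for the enrichment null (default 1000)
#' @param seed integer master seed
#' @param out_dir optional directory; when given, per-network curve TSVs,
#'   enrichment JSONs, a summary TSV and a provenance JSON are written there
#' @return list with `curves` (nested by network then metric), `enrichment`
#'   (likewise), `rankings`, and `summary` (data frame, one row per
#'   network x metric, sorted best first)
#' @export
run_compare <- function(networks, gold,
                        metrics = c("degree", "betweenness"),
                        fractions = seq(0, 1, by = 0.01),
                        enrich_fraction = 0.10, n_perm = 1000L, seed = 1L,
                        out_dir = NULL) {
  stopifnot(length(networks) >= 1L, !is.null(names(networks)),
            all(nzchar(names(networks))), inherits(gold, "gene_set"))
  metrics <- match.arg(metrics, c("degree", "betweenness"), several.ok = TRUE)
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  curves <- list(); enrich <- list(); rankings <- list(); rows <- list()
  for (lab in names(networks)) {
    net <- networks[[lab]]
    pos <- restrict_to_network(net, gold)
    if (length(pos$ids) == 0L) {
      stop("no gold-standard genes present in network '", lab, "'", call. = FALSE)
    }
    for (metric in metrics) {
      sc <- if (metric == "degree") degree_scores(net) else betweenness_scores(net)
      rk <- rank_genes(sc, tie_rule = "lexicographic")
      cv <- evaluation_curve(rk, pos, fractions)
      en <- permutation_null(rk, pos, fraction = enrich_fraction,
                             n_perm = n_perm,
                             seed = derive_seed(seed, match(lab, names(networks)),
                                                match(metric, metrics)))
      curves[[lab]][[metric]] <- cv
      enrich[[lab]][[metric]] <- en
      rankings[[lab]][[metric]] <- rk
      cc <- confusion_at_fraction(rk, pos, enrich_fraction)
      m <- suppressMessages(classification_metrics(cc))
      rows[[length(rows) + 1L]] <- data.frame(
        network = lab, metric = metric,
        n_genes = n_genes(net), n_edges = n_edges(net),
        n_positives = length(pos$ids),
        recall_at_cutoff = m[["recall"]],
        accuracy_at_cutoff = m[["accuracy"]],
        specificity_at_cutoff = m[["specificity"]],
        fold_enrichment = en$fold_enrichment,
        p_empirical = en$p_empirical,
        stringsAsFactors = FALSE)
      if (!is.null(out_dir)) {
        write_curve(cv, file.path(out_dir, sprintf("curve_%s_%s.tsv", lab, metric)))
        write_enrichment(en, file.path(out_dir, sprintf("enrichment_%s_%s.json", lab, metric)))
      }
    }
  }
  summary <- do.call(rbind, rows)
  summary <- summary[order(-summary$recall_at_cutoff, -summary$accuracy_at_cutoff), ]
  rownames(summary) <- NULL
  if (!is.null(out_dir)) {
    utils::write.table(summary, file.path(out_dir, "summary.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_provenance(file.path(out_dir, "summary.tsv"),
                     list(stage = "compare", networks = names(networks),
                          metrics = metrics, enrich_fraction = enrich_fraction,
                          n_perm = n_perm, seed = seed))
  }
  list(curves = curves, enrichment = enrich, rankings = rankings,
       summary = summary)
}

#' Run the full benchmarking pipeline
#'
#' Composes all stages: cross-network comparison ([run_compare()]),
#' edge-removal robustness profiling of a focal network, relative-rank /
#' top-k overlap analysis of the focal network's top genes against the other
#' networks, and -- when mutation records are supplied -- per-cancer rank-sum
#' comparison of mutation frequencies between the focal network's top- and
#' bottom-ranked genes. The mutation stage is skipped with a notice when no
#' records are given.
#'
#' @inheritParams run_compare
#' @param focal label of the focal network (default: the first)
#' @param mutation_records optional data frame of mutation records
#'   (see [read_maf()] / [generate_mutations()])
#' @param total_samples optional named vector of per-cancer sample totals
#' @param robustness_fractions removal fractions for the robustness stage
#' @param replicates removal replicates per fraction
#' @param k top-k size for overlap and mutation group comparison (capped at
#'   half the focal network size so top and bottom groups cannot overlap)
#' @param low_rank_cut relative-rank cut for the overlap stage
#' @return list with `compare`, `robustness`, `overlap`, `relative_ranks`,
#'   and `mutation` (`NULL` when skipped) components
#' @export
run_full <- function(networks, gold, focal = names(networks)[1L],
                     mutation_records = NULL, total_samples = NULL,
                     metrics = c("degree", "betweenness"),
                     robustness_fractions = seq(0, 0.9, by = 0.1),
                     replicates = 10L, enrich_fraction = 0.10,
                     n_perm = 1000L, k = 100L, low_rank_cut = 0.10,
                     seed = 1L, out_dir = NULL) {
  stopifnot(focal %in% names(networks))
  cmp <- run_compare(networks, gold, metrics = metrics,
                     enrich_fraction = enrich_fraction, n_perm = n_perm,
                     seed = seed, out_dir = out_dir)
  focal_net <- networks[[focal]]
  pos <- restrict_to_network(focal_net, gold)
  prof <- robustness_profile(focal_net, pos,
                             fractions_removed = robustness_fractions,
                             replicates = replicates,
                             eval_fraction = enrich_fraction,
                             seed = derive_seed(seed, 101L))
  focal_rk <- cmp$rankings[[focal]][["degree"]]
  k_use <- min(k, floor(length(focal_rk$order) / 2))
  others <- lapply(cmp$rankings[setdiff(names(networks), focal)],
                   function(x) x[["degree"]])
  ov <- top_k_overlap(focal_rk, others, k = k_use, low_rank_cut = low_rank_cut)
  rel <- relative_ranks(lapply(cmp$rankings, function(x) x[["degree"]]),
                        ov$top_genes)
  mut <- NULL
  if (is.null(mutation_records)) {
    message("no mutation records supplied; mutation stage skipped")
  } else {
    tab <- mutation_frequency(mutation_records, total_samples)
    top <- focal_rk$order[seq_len(k_use)]
    n_f <- length(focal_rk$order)
    bottom <- focal_rk$order[seq.int(n_f - k_use + 1L, n_f)]
    tests <- lapply(names(tab$samples_per_cancer), function(ct) {
      compare_rank_groups(tab, top, bottom, ct)
    })
    names(tests) <- names(tab$samples_per_cancer)
    mut <- list(table = tab, tests = tests, top = top, bottom = bottom)
  }
  if (!is.null(out_dir)) {
    write_profile(prof, file.path(out_dir, sprintf("robustness_%s.tsv", focal)))
    write_overlap(ov, file.path(out_dir, sprintf("overlap_%s.json", focal)))
    write_relative_ranks(rel, file.path(out_dir, sprintf("relative_ranks_%s.tsv", focal)))
    if (!is.null(mut)) {
      write_frequency_matrix(mut$table, file.path(out_dir, "mutation_frequency.tsv"))
      jsonlite::write_json(mut$tests, file.path(out_dir, "mutation_tests.json"),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
    }
    write_provenance(file.path(out_dir, "run_full"),
                     list(stage = "full", focal = focal, k = k_use,
                          low_rank_cut = low_rank_cut,
                          robustness_fractions = robustness_fractions,
                          replicates = replicates, seed = seed))
  }
  list(compare = cmp, robustness = prof, overlap = ov, relative_ranks = rel,
       mutation = mut)
}
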