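#' Read somatic mutation records from a MAF-like file
#'
#' Parses the minimal MAF dialect: a tab-delimited table whose header contains
#' at least a gene column (`Hugo_Symbol`, falling back to `Entrez_Gene_Id`),
#' `Tumor_Sample_Barcode` and `Variant_Classification`. Any further columns
#' are ignored. TCGA MAFs are per-cancer files, so the cancer-type label is
#' supplied by the caller.
#'
#' @param path path to the MAF file
#' @param cancer_type label attached to every record (e.g. `"LUAD"`)
#' @param exclude_silent drop records whose `Variant_Classification` is
#'   `"Silent"` (off by default: every call counts as a mutation)
#' @return a data frame of mutation records with columns `gene`, `sample`,
#'   `cancer_type`, `variant_class`
#' @export
read_maf <- function(path, cancer_type, exclude_silent = FALSE) {
  if (!file.exists(path)) stop("MAF file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          comment.char = "#", stringsAsFactors = FALSE,
                          colClasses = "character", check.names = FALSE)
  gene_col <- if ("Hugo_Symbol" %in% names(df)) "Hugo_Symbol"
              else if ("Entrez_Gene_Id" %in% names(df)) "Entrez_Gene_Id"
              else stop("MAF is missing required column Hugo_Symbol (or Entrez_Gene_Id)",
                        call. = FALSE)
  for (col in c("Tumor_Sample_Barcode", "Variant_Classification")) {
    if (!col %in% names(df)) {
      stop("MAF is missing required column ", col, call. = FALSE)
    }
  }
  rec <- data.frame(gene = df[[gene_col]],
                    sample = df[["Tumor_Sample_Barcode"]],
                    cancer_type = rep(cancer_type, nrow(df)),
                    variant_class = df[["Variant_Classification"]],
                    stringsAsFactors = FALSE)
  if (exclude_silent) {
    silent <- rec$variant_class == "Silent"
    if (any(silent)) {
      message(sprintf("%s: dropped %d Silent record(s)", basename(path), sum(silent)))
    }
    rec <- rec[!silent, , drop = FALSE]
  }
  rec
}

#' Per-gene, per-cancer mutation frequency
#'
#' Mutation frequency of a gene in a cancer type is the number of samples with
#' at least one mutation call for that gene divided by the total number of
#' samples in that cancer; multiple records of one gene in one sample count
#' once.
#'
#' @param records data frame of mutation records (`gene`, `sample`,
#'   `cancer_type` columns), e.g. from [read_maf()] or [generate_mutations()]
#' @param total_samples optional named integer vector of total sample counts
#'   per cancer type. When `NULL`, totals are inferred as the number of
#'   distinct sample barcodes observed per cancer (a lower bound, since
#'   samples with no mutations leave no records).
#' @return an object of class `mutation_table`: list with `freq` (data frame
#'   `gene`, `cancer_type`, `n_mutated`, `frequency`) and `samples_per_cancer`
#' @export
mutation_frequency <- function(records, total_samples = NULL) {
  stopifnot(all(c("gene", "sample", "cancer_type") %in% names(records)))
  if (is.null(total_samples) && !is.null(attr(records, "total_samples"))) {
    total_samples <- attr(records, "total_samples")
  }
  uniq <- unique(records[, c("gene", "sample", "cancer_type")])
  observed <- tapply(uniq$sample, uniq$cancer_type,
                     function(x) length(unique(x)))
  if (is.null(total_samples)) {
    totals <- observed
  } else {
    totals <- total_samples
    missing_ct <- setdiff(names(observed), names(totals))
    if (length(missing_ct) > 0L) {
      stop("`total_samples` lacks cancer type(s): ",
           paste(missing_ct, collapse = ", "), call. = FALSE)
    }
    low <- names(observed)[observed > totals[names(observed)]]
    if (length(low) > 0L) {
      stop("`total_samples` is below the observed distinct sample count for: ",
           paste(low, collapse = ", "), call. = FALSE)
    }
  }
  counts <- stats::aggregate(sample ~ gene + cancer_type, data = uniq,
                             FUN = function(x) length(unique(x)))
  names(counts)[names(counts) == "sample"] <- "n_mutated"
  counts$frequency <- counts$n_mutated / as.numeric(totals[counts$cancer_type])
  counts <- counts[order(counts$cancer_type, counts$gene, method = "radix"), ]
  rownames(counts) <- NULL
  structure(list(freq = counts,
                 samples_per_cancer = as.integer(totals) |>
                   stats::setNames(names(totals))),
            class = "mutation_table")
}

#' @export
print.mutation_table <- function(x, ...) {
  cat(sprintf("mutation_table: %d gene x cancer frequencies over %d cancer type(s)\n",
              nrow(x$freq), length(x$samples_per_cancer)))
  invisible(x)
}

#' Look up mutation frequencies for a gene list
#'
#' Genes with no mutation record in the given cancer type have frequency 0.
#'
#' @param table a `mutation_table`
#' @param genes character vector of genes
#' @param cancer_type single cancer-type label present in the table
#' @return numeric vector of frequencies, one per gene
#' @export
frequency_of <- function(table, genes, cancer_type) {
  stopifnot(inherits(table, "mutation_table"))
  if (!cancer_type %in% names(table$samples_per_cancer)) {
    stop("unknown cancer type: ", cancer_type, call. = FALSE)
  }
  sub <- table$freq[table$freq$cancer_type == cancer_type, ]
  f <- stats::setNames(sub$frequency, sub$gene)
  out <- f[as.character(genes)]
  out[is.na(out)] <- 0
  unname(out)
}

#' Rank-sum comparison of mutation frequencies between two gene groups
#'
#' Compares the mutation-frequency distributions of two gene lists (typically
#' the top-100 and bottom-100 ranked genes of a network) in one cancer type
#' with the Wilcoxon rank-sum (Mann-Whitney) test. Genes absent from the
#' table count as frequency 0. The default alternative is one-sided
#' (`top > bottom`), matching the directional hypothesis that centrally
#' ranked genes are mutated more often; exact p-values are used for small
#' untied samples and the normal approximation with tie correction otherwise.
#'
#' @param table a `mutation_table`
#' @param top character vector of top-ranked genes
#' @param bottom character vector of bottom-ranked genes
#' @param cancer_type cancer type to compare within
#' @param alternative `"greater"` (default), `"two.sided"` or `"less"`
#' @return list with `statistic` (Mann-Whitney W for top vs bottom),
#'   `p_value`, `alternative`, `n_top`, `n_bottom`, `cancer_type`,
#'   `degenerate` (TRUE when every frequency is identical)
#' @export
compare_rank_groups <- function(table, top, bottom, cancer_type,
                                alternative = c("greater", "two.sided", "less")) {
  alternative <- match.arg(alternative)
  if (length(top) == 0L || length(bottom) == 0L) {
    stop("both gene lists must be nonempty", call. = FALSE)
  }
  x <- frequency_of(table, top, cancer_type)
  y <- frequency_of(table, bottom, cancer_type)
  if (length(unique(c(x, y))) == 1L) {
    message("all frequencies are identical; rank-sum comparison is degenerate (p = 1)")
    return(list(statistic = length(x) * length(y) / 2, p_value = 1,
                alternative = alternative, n_top = length(x),
                n_bottom = length(y), cancer_type = cancer_type,
                degenerate = TRUE))
  }
  wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = alternative))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       alternative = alternative, n_top = length(x), n_bottom = length(y),
       cancer_type = cancer_type, degenerate = FALSE)
}

#' Write a gene x cancer-type frequency matrix as TSV
#'
#' @param table a `mutation_table`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_frequency_matrix <- function(table, path) {
  stopifnot(inherits(table, "mutation_table"))
  wide <- stats::reshape(table$freq[, c("gene", "cancer_type", "frequency")],
                         idvar = "gene", timevar = "cancer_type",
                         direction = "wide")
  names(wide) <- sub("^frequency\\.", "", names(wide))
  wide[is.na(wide)] <- 0
  wide <- wide[order(wide$gene, method = "radix"), ]
  utils::write.table(wide, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
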