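#' Construct an undirected interaction network
#'
#' Builds a simple undirected network over gene identifiers from a two-column
#' edge table, applying the standard interactome cleaning rules: self-loops are
#' dropped and redundant records -- duplicate rows and (a,b)/(b,a) mirror
#' pairs -- are collapsed to a single undirected edge. Identifiers are opaque
#' case-sensitive strings (typically NCBI Entrez IDs); no identifier
#' validation or mapping is attempted.
#'
#' @param edges two-column character matrix or data frame of interacting gene
#'   pairs; zero rows give an empty network. Columns beyond the first two are
#'   ignored.
#' @param genes optional character vector of gene identifiers to declare in
#'   addition to edge endpoints (allows isolated, degree-zero genes). By
#'   default the gene universe is the union of edge endpoints.
#' @return an object of class `interaction_network`: a list with `genes`
#'   (sorted unique identifiers), `edges` (two-column character matrix,
#'   each row lexicographically ordered, rows sorted), and `dropped`
#'   (counts of removed self-loops and redundant records).
#' @examples
#' net <- interaction_network(rbind(c("A", "B"), c("B", "A"), c("C", "C")))
#' n_edges(net)  # 1: the mirror pair collapses, the self-loop is dropped
#' @export
interaction_network <- function(edges, genes = NULL) {
  if (is.data.frame(edges)) edges <- as.matrix(edges)
  if (is.null(edges) || length(edges) == 0L || nrow(edges) == 0L) {
    edges <- matrix(character(0), ncol = 2L)
  }
  if (ncol(edges) < 2L) stop("`edges` must have at least two columns", call. = FALSE)
  a <- as.character(edges[, 1L])
  b <- as.character(edges[, 2L])
  if (anyNA(a) || anyNA(b) || any(!nzchar(a)) || any(!nzchar(b))) {
    stop("edge endpoints must be non-empty identifiers", call. = FALSE)
  }
  self <- a == b
  lo <- pmin(a, b)[!self]
  hi <- pmax(a, b)[!self]
  key <- paste(lo, hi, sep = "\r")
  dup <- duplicated(key)
  lo <- lo[!dup]
  hi <- hi[!dup]
  ord <- order(lo, hi, method = "radix")
  em <- cbind(lo[ord], hi[ord])
  colnames(em) <- c("gene_a", "gene_b")
  all_genes <- sort(unique(c(em[, 1L], em[, 2L], as.character(genes))), method = "radix")
  structure(
    list(genes = all_genes, edges = em,
         dropped = c(self_loops = sum(self), redundant = sum(dup))),
    class = "interaction_network"
  )
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf("interaction_network: %d genes, %d interactions\n",
              n_genes(x), n_edges(x)))
  invisible(x)
}

#' Number of genes / edges in a network
#' @param network an `interaction_network`
#' @return integer count
#' @export
n_genes <- function(network) length(network$genes)

#' @rdname n_genes
#' @export
n_edges <- function(network) nrow(network$edges)

#' Convert a network to an igraph object
#'
#' @param network an `interaction_network`
#' @return an undirected simple [igraph::igraph] graph over all declared genes
#'   (isolated genes included as degree-zero vertices)
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "interaction_network"))
  igraph::graph_from_data_frame(
    d = as.data.frame(network$edges, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = network$genes, stringsAsFactors = FALSE)
  )
}

#' Read an interaction network from a plain-text edge list
#'
#' Parses a whitespace- or delimiter-separated two-column edge list (extra
#' columns, e.g. evidence scores, are ignored with a note -- the networks are
#' treated as unweighted). Self-loops and redundant interactions are removed
#' as in [interaction_network()], and the number of dropped records is
#' reported via [message()].
#'
#' @param path path to the edge-list file
#' @param comment_prefix lines starting with this prefix are skipped
#' @param delimiter field separator; `NULL` (default) splits on runs of
#'   whitespace
#' @return an `interaction_network`
#' @export
read_edge_list <- function(path, comment_prefix = "#", delimiter = NULL) {
  if (!file.exists(path)) stop("edge-list file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), comment_prefix)
  lineno <- which(keep)
  lines <- trimws(lines[keep])
  if (length(lines) == 0L) {
    return(interaction_network(matrix(character(0), ncol = 2L)))
  }
  fields <- if (is.null(delimiter)) strsplit(lines, "[ \t]+") else strsplit(lines, delimiter, fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 2L)) {
    bad <- lineno[which(nf < 2L)[1L]]
    stop(sprintf("line %d of %s has fewer than 2 columns", bad, path), call. = FALSE)
  }
  if (any(nf > 2L)) {
    message(sprintf("%s: ignoring columns beyond the first two on %d line(s)",
                    basename(path), sum(nf > 2L)))
  }
  em <- cbind(vapply(fields, `[[`, "", 1L), vapply(fields, `[[`, "", 2L))
  net <- interaction_network(em)
  if (sum(net$dropped) > 0L) {
    message(sprintf("%s: dropped %d self-loop(s) and %d redundant record(s)",
                    basename(path), net$dropped[["self_loops"]],
                    net$dropped[["redundant"]]))
  }
  net
}

#' Write a cleaned network as a canonical edge list
#'
#' Emits tab-separated, lexicographically ordered pairs in sorted row order,
#' so that two equal networks always produce byte-identical files.
#'
#' @param network an `interaction_network`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_edge_list <- function(network, path) {
  stopifnot(inherits(network, "interaction_network"))
  utils::write.table(network$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Construct a gene set
#'
#' @param ids character vector of gene identifiers; duplicates are collapsed
#' @param label free-text name for the set (e.g. `"CGC"`)
#' @return an object of class `gene_set` with sorted unique `ids` and `label`
#' @export
gene_set <- function(ids, label = "") {
  ids <- trimws(as.character(ids))
  ids <- sort(unique(ids[nzchar(ids)]), method = "radix")
  structure(list(ids = ids, label = label), class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("gene_set%s: %d genes\n",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              length(x$ids)))
  invisible(x)
}

#' Read a gene set from a one-identifier-per-line file
#'
#' Surrounding whitespace is trimmed and duplicate identifiers collapsed;
#' lines starting with `#` are skipped. An empty file yields an empty set
#' with a warning.
#'
#' @param path path to the gene-list file
#' @param label name for the set; defaults to the file name
#' @return a `gene_set`
#' @export
read_gene_set <- function(path, label = basename(path)) {
  if (!file.exists(path)) stop("gene-set file not found: ", path, call. = FALSE)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  gs <- gene_set(lines, label = label)
  if (length(gs$ids) == 0L) warning("gene set '", label, "' is empty", call. = FALSE)
  gs
}

#' Write a gene set, one identifier per line
#' @param gs a `gene_set`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_gene_set <- function(gs, path) {
  stopifnot(inherits(gs, "gene_set"))
  writeLines(gs$ids, path)
  invisible(path)
}

#' Restrict a gene set to the genes present in a network
#'
#' Gold-standard genes are meaningful positives only within the network that
#' contains them; the remaining network genes act as negative controls.
#' This returns the intersection of the set with the network's gene universe.
#'
#' @param network an `interaction_network`
#' @param gs a `gene_set`
#' @return a `gene_set` containing only genes present in the network
#' @export
restrict_to_network <- function(network, gs) {
  stopifnot(inherits(network, "interaction_network"), inherits(gs, "gene_set"))
  gene_set(intersect(gs$ids, network$genes), label = gs$label)
}
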