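# Shared fixtures: toy graphs, random-network builder, and an igraph-free
# brute-force betweenness oracle based on BFS shortest-path counting.

toy_path <- function() interaction_network(rbind(c("A", "B"), c("B", "C")))

toy_star <- function() {
  interaction_network(rbind(c("h", "x"), c("h", "y"), c("h", "z")))
}

toy_cycle4 <- function() {
  interaction_network(rbind(c("A", "B"), c("B", "C"), c("C", "D"), c("A", "D")))
}

# Erdos-Renyi-style random simple network over n labelled genes.
random_network <- function(n, p, seed) {
  set.seed(seed)
  ids <- sprintf("v%02d", seq_len(n))
  pairs <- t(utils::combn(n, 2))
  keep <- stats::runif(nrow(pairs)) < p
  interaction_network(cbind(ids[pairs[keep, 1]], ids[pairs[keep, 2]]),
                      genes = ids)
}

# BFS from one source on an adjacency matrix: geodesic distances and
# shortest-path counts to every vertex.
bfs_counts <- function(adj, s) {
  n <- nrow(adj)
  dist <- rep(Inf, n)
  sigma <- numeric(n)
  dist[s] <- 0
  sigma[s] <- 1
  frontier <- s
  while (length(frontier) > 0) {
    nxt <- integer(0)
    for (v in frontier) {
      for (w in which(adj[v, ] > 0)) {
        if (is.infinite(dist[w])) {
          dist[w] <- dist[v] + 1
          nxt <- c(nxt, w)
        }
        if (dist[w] == dist[v] + 1) sigma[w] <- sigma[w] + sigma[v]
      }
    }
    frontier <- unique(nxt)
  }
  list(dist = dist, sigma = sigma)
}

# Brute-force betweenness: for every unordered pair {j,k} and interior vertex
# i, a shortest j-k path runs through i iff d(j,i) + d(i,k) = d(j,k), and the
# number of such paths is sigma_j(i) * sigma_i(k).
brute_force_betweenness <- function(network) {
  n <- length(network$genes)
  adj <- matrix(0L, n, n, dimnames = list(network$genes, network$genes))
  if (nrow(network$edges) > 0) {
    adj[network$edges] <- 1L
    adj[network$edges[, c(2, 1), drop = FALSE]] <- 1L
  }
  bfs <- lapply(seq_len(n), function(s) bfs_counts(adj, s))
  bc <- stats::setNames(numeric(n), network$genes)
  if (n < 3) return(bc)
  for (j in 1:(n - 1)) {
    for (k in (j + 1):n) {
      djk <- bfs[[j]]$dist[k]
      if (is.infinite(djk)) next
      gjk <- bfs[[j]]$sigma[k]
      for (i in seq_len(n)) {
        if (i == j || i == k) next
        if (bfs[[j]]$dist[i] + bfs[[i]]$dist[k] == djk) {
          bc[i] <- bc[i] + bfs[[j]]$sigma[i] * bfs[[i]]$sigma[k] / gjk
        }
      }
    }
  }
  bc
}
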