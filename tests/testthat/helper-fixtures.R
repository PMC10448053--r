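# small fixtures built in code; no files on disk

tiny_table <- function(counts = NULL, groups = NULL) {
  if (is.null(counts))
    counts <- matrix(c(5L, 3L, 2L,
                       1L, 4L, 0L,
                       2L, 2L, 6L), nrow = 3, byrow = TRUE,
                     dimnames = list(paste0("OTU", 1:3),
                                     paste0("s", 1:3)))
  md <- tibble::tibble(sample_id = colnames(counts),
                       group = groups %||% rep("all", ncol(counts)))
  otu_table(counts, md)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_table <- function(n_taxa, n_samples, seed, groups = NULL,
                         lambda = 8) {
  set.seed(seed)
  m <- matrix(rpois(n_taxa * n_samples, lambda), n_taxa, n_samples,
              dimnames = list(sprintf("OTU%03d", seq_len(n_taxa)),
                              sprintf("s%03d", seq_len(n_samples))))
  # ensure no all-zero sample or taxon
  m[1, colSums(m) == 0] <- 1L
  m <- m[rowSums(m) > 0, , drop = FALSE]
  md <- tibble::tibble(sample_id = colnames(m),
                       group = groups %||% rep("all", ncol(m)))
  otu_table(m, md)
}

# graph fixtures
path_graph <- function(n) igraph::make_ring(n, circular = FALSE)
star_graph <- function(leaves)
  igraph::make_star(leaves + 1, mode = "undirected", center = 1)

# natural-connectivity oracle via matrix exponential trace
natcon_expm_oracle <- function(g) {
  N <- igraph::vcount(g)
  if (N == 0) return(0)
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  A[A != 0] <- 1; diag(A) <- 0
  E <- as.matrix(Matrix::expm(Matrix::Matrix(A)))
  log(sum(diag(E)) / N)
}

# exhaustive shortest-path oracle (Floyd-Warshall) for APL/diameter
dist_oracle <- function(g) {
  n <- igraph::vcount(g)
  d <- matrix(Inf, n, n); diag(d) <- 0
  el <- igraph::as_edgelist(g, names = FALSE)
  for (k in seq_len(nrow(el))) {
    d[el[k, 1], el[k, 2]] <- 1; d[el[k, 2], el[k, 1]] <- 1
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

# betweenness oracle: enumerate all shortest paths by DFS (n small)
betweenness_oracle <- function(g) {
  n <- igraph::vcount(g)
  adj <- lapply(seq_len(n), function(i)
    as.integer(igraph::neighbors(g, i)))
  d <- dist_oracle(g)
  btw <- numeric(n)
  all_paths <- function(from, to, len) {
    # all simple paths of exactly shortest length
    out <- list()
    walk <- function(path) {
      v <- path[length(path)]
      if (v == to && length(path) == len + 1) {
        out[[length(out) + 1]] <<- path
        return(invisible())
      }
      if (length(path) > len) return(invisible())
      for (w in adj[[v]])
        if (!(w %in% path)) walk(c(path, w))
    }
    walk(from)
    out
  }
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    if (!is.finite(d[s, t])) next
    paths <- all_paths(s, t, d[s, t])
    sigma <- length(paths)
    if (sigma == 0) next
    inner <- table(unlist(lapply(paths, function(p)
      p[-c(1, length(p))])))
    if (length(inner))
      btw[as.integer(names(inner))] <-
        btw[as.integer(names(inner))] + as.numeric(inner) / sigma
  }
  btw
}

# enumerate all set partitions of 1..n as membership vectors
.all_partitions <- function(n) {
  out <- list()
  recurse <- function(mem, next_label) {
    i <- length(mem) + 1
    if (i > n) {
      out[[length(out) + 1]] <<- mem
      return(invisible())
    }
    for (l in seq_len(next_label))
      recurse(c(mem, l), max(next_label, l + 1))
  }
  recurse(integer(0), 1)
  out
}

# ANOSIM R oracle: direct formula, independent ranking code path
anosim_R_oracle <- function(D, groups) {
  D <- as.matrix(D)
  ut <- upper.tri(D)
  r <- rank(D[ut])
  same <- outer(groups, groups, "==")[ut]
  (mean(r[!same]) - mean(r[same])) / (length(r) / 2)
}
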