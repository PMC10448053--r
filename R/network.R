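#' Spearman correlation matrix across taxa
#'
#' Tie-corrected (average-rank) Spearman correlation between all pairs of
#' taxa across samples, with p-values from the t approximation
#' \eqn{t = \rho\sqrt{(n-2)/(1-\rho^2)}}. Zero-variance taxa are dropped
#' with a warning (their correlations are undefined).
#'
#' @param x An `otu_table` (typically rarefied, one habitat).
#' @param taxa Taxon ids to correlate (e.g. from [abundance_filter()]);
#'   default all taxa of `x`.
#' @return A list: `rho` and `p` (symmetric matrices, NA diagonal),
#'   `taxa` (ids retained), `n_samples`.
#' @export
spearman_matrix <- function(x, taxa = NULL) {
  if (is.null(taxa)) taxa <- rownames(x$counts)
  stopifnot(all(taxa %in% rownames(x$counts)))
  n <- n_samples(x)
  if (n < 4) stop("need >= 4 samples for correlation inference")
  cts <- x$counts[taxa, , drop = FALSE]
  keep <- apply(cts, 1, function(v) stats::var(v) > 0)
  if (any(!keep))
    warning(sum(!keep), " zero-variance taxon/taxa dropped")
  cts <- cts[keep, , drop = FALSE]
  rho <- stats::cor(t(cts), method = "spearman")
  r <- pmin(pmax(rho, -1), 1)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(r) >= 1 - 1e-12] <- 0
  diag(rho) <- NA_real_
  diag(p) <- NA_real_
  list(rho = rho, p = p, taxa = rownames(cts), n_samples = n)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' False-discovery-rate adjusted p-values:
#' \eqn{q_{(i)} = \min_{j \ge i} p_{(j)} m / j}, computed with
#' [stats::p.adjust()].
#'
#' @param p Numeric vector of p-values in [0, 1] (NA passed through).
#' @return Adjusted q-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' Build a thresholded co-occurrence network
#'
#' Edges connect taxon pairs with |Spearman rho| strictly above
#' `rho_min` and BH-adjusted q strictly below `q_max` (BH applied over
#' all tested pairs of this network). Nodes passing the abundance filter
#' but gaining no edge are retained and flagged `isolated`. SRB flags
#' and phylum labels are attached as node attributes when provided.
#'
#' @param x An `otu_table` for one habitat (rarefied).
#' @param taxa Taxa to include; default [abundance_filter()] at
#'   `filter_threshold` on the table's relative abundances.
#' @param rho_min Absolute correlation threshold (default 0.6).
#' @param q_max Adjusted-p threshold (default 0.01).
#' @param filter_threshold Abundance-filter threshold used when `taxa`
#'   is NULL (default 1e-4, i.e. 0.01%).
#' @param filter_mode Passed to [abundance_filter()].
#' @param annotations Optional tibble (`taxon_id`, `is_srb`).
#' @param taxonomy Optional tibble (`taxon_id`, `lineage`); the phylum
#'   slot of the lineage is attached to nodes.
#' @return A `cooccurrence_network`: `graph` (igraph, undirected,
#'   simple; edge attrs `rho`, `p`, `q`, `sign`; vertex attrs `is_srb`,
#'   `phylum`, `isolated`), `edges` (tibble), `nodes` (tibble),
#'   `thresholds`, `n_pairs_tested`.
#' @export
cooccurrence_network <- function(x, taxa = NULL, rho_min = 0.6,
                                 q_max = 0.01, filter_threshold = 1e-4,
                                 filter_mode = "mean",
                                 annotations = NULL, taxonomy = NULL) {
  if (is.null(taxa))
    taxa <- abundance_filter(to_relative(x), filter_threshold,
                             mode = filter_mode)
  sm <- spearman_matrix(x, taxa)
  build_network(sm$rho, sm$p, rho_min = rho_min, q_max = q_max,
                annotations = annotations, taxonomy = taxonomy)
}

#' @rdname cooccurrence_network
#' @param rho,p Symmetric correlation and p-value matrices over the same
#'   taxa (dimnames required), e.g. from [spearman_matrix()].
#' @export
build_network <- function(rho, p, rho_min = 0.6, q_max = 0.01,
                          annotations = NULL, taxonomy = NULL) {
  stopifnot(identical(dim(rho), dim(p)),
            identical(rownames(rho), rownames(p)))
  ids <- rownames(rho)
  ut <- which(upper.tri(rho), arr.ind = TRUE)
  p_vec <- p[upper.tri(p)]
  q_vec <- bh_adjust(p_vec)
  rho_vec <- rho[upper.tri(rho)]
  sel <- !is.na(rho_vec) & abs(rho_vec) > rho_min & q_vec < q_max
  edges <- tibble::tibble(
    from = ids[ut[sel, 1]], to = ids[ut[sel, 2]],
    rho = rho_vec[sel], p = p_vec[sel], q = q_vec[sel],
    sign = ifelse(rho_vec[sel] >= 0, "positive", "negative"))
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = ids, stringsAsFactors = FALSE))
  igraph::V(g)$is_srb <- .srb_flags(ids, annotations)
  phylum <- rep(NA_character_, length(ids))
  if (!is.null(taxonomy)) {
    idx <- match(ids, taxonomy$taxon_id)
    phylum <- lineage_rank(taxonomy$lineage[idx], 2L)
  }
  igraph::V(g)$phylum <- phylum
  igraph::V(g)$isolated <- igraph::degree(g) == 0
  nodes <- tibble::tibble(taxon_id = ids,
                          is_srb = igraph::V(g)$is_srb,
                          phylum = phylum,
                          isolated = igraph::V(g)$isolated)
  structure(list(graph = g, edges = edges, nodes = nodes,
                 thresholds = c(rho_min = rho_min, q_max = q_max),
                 n_pairs_tested = sum(!is.na(rho_vec))),
            class = "cooccurrence_network")
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  cat("<cooccurrence_network> ", nrow(x$nodes), " nodes (",
      sum(!x$nodes$isolated), " connected), ", nrow(x$edges),
      " edges; |rho| > ", x$thresholds[["rho_min"]], ", q < ",
      x$thresholds[["q_max"]], "\n", sep = "")
  invisible(x)
}

#' Global topology of a co-occurrence network
#'
#' Density 2E/(N(N-1)); mean degree 2E/N; clustering coefficient = mean
#' of local clustering coefficients with degree-<2 nodes contributing 0;
#' average path length and diameter over connected pairs only; Louvain
#' modularity (seeded, so tie-breaking is reproducible).
#'
#' @param net A `cooccurrence_network` (or bare igraph).
#' @param seed Seed for Louvain tie-breaking.
#' @return One-row tibble: `n_nodes`, `n_nodes_connected`, `n_edges`,
#'   `density`, `mean_degree`, `clustering_coefficient`,
#'   `average_path_length`, `diameter`, `modularity`, `n_modules`.
#' @export
global_topology <- function(net, seed = 1L) {
  g <- if (inherits(net, "cooccurrence_network")) net$graph else net
  N <- igraph::vcount(g); E <- igraph::ecount(g)
  if (N == 0)
    return(tibble::tibble(n_nodes = 0L, n_nodes_connected = 0L,
                          n_edges = 0L, density = NA_real_,
                          mean_degree = NA_real_,
                          clustering_coefficient = NA_real_,
                          average_path_length = NA_real_,
                          diameter = NA_real_, modularity = NA_real_,
                          n_modules = 0L))
  loc <- igraph::transitivity(g, type = "local", isolates = "zero")
  loc[is.na(loc)] <- 0
  apl <- if (E > 0) igraph::mean_distance(g) else NA_real_
  diam <- if (E > 0) igraph::diameter(g, unconnected = TRUE) else NA_real_
  if (E > 0) {
    old <- .save_seed(); on.exit(.restore_seed(old))
    set.seed(seed)
    comm <- igraph::cluster_louvain(g)
    mod <- igraph::modularity(comm)
    n_mod <- length(unique(igraph::membership(comm)))
  } else {
    mod <- NA_real_; n_mod <- N
  }
  tibble::tibble(
    n_nodes = N,
    n_nodes_connected = sum(igraph::degree(g) > 0),
    n_edges = E,
    density = if (N > 1) 2 * E / (N * (N - 1)) else NA_real_,
    mean_degree = 2 * E / N,
    clustering_coefficient = mean(loc),
    average_path_length = apl,
    diameter = diam,
    modularity = mod,
    n_modules = n_mod)
}

#' Node-level topology of a co-occurrence network
#'
#' Degree; unnormalised shortest-path betweenness; closeness computed
#' within each node's component as (n_c - 1) / sum of distances
#' (singletons get 0); eigenvector centrality of the largest component,
#' max-normalised to 1 (nodes outside it get 0). Edge weights are
#' ignored throughout — the graph is treated as unweighted and unsigned.
#'
#' @param net A `cooccurrence_network` (or bare igraph).
#' @return Tibble: `taxon_id`, `is_srb`, `degree`, `betweenness`,
#'   `closeness`, `eigenvector`, `module`.
#' @export
node_topology <- function(net) {
  g <- if (inherits(net, "cooccurrence_network")) net$graph else net
  N <- igraph::vcount(g)
  deg <- unname(igraph::degree(g))
  btw <- unname(igraph::betweenness(g, weights = NA))
  comp <- igraph::components(g)
  d <- igraph::distances(g, weights = NA)
  clo <- vapply(seq_len(N), function(i) {
    members <- which(comp$membership == comp$membership[i])
    if (length(members) < 2) return(0)
    (length(members) - 1) / sum(d[i, setdiff(members, i)])
  }, numeric(1))
  eig <- rep(0, N)
  if (igraph::ecount(g) > 0) {
    big <- which.max(comp$csize)
    sub_ids <- which(comp$membership == big)
    sub <- igraph::induced_subgraph(g, sub_ids)
    # dense leading eigenvector (deterministic, unlike ARPACK)
    A <- igraph::as_adjacency_matrix(sub, sparse = FALSE)
    A[A != 0] <- 1
    es <- eigen(A, symmetric = TRUE)
    ev <- abs(es$vectors[, 1])
    eig[sub_ids] <- ev / max(ev)
  }
  is_srb <- if (!is.null(igraph::V(g)$is_srb)) igraph::V(g)$is_srb
            else rep(FALSE, N)
  tibble::tibble(taxon_id = igraph::V(g)$name, is_srb = is_srb,
                 degree = as.integer(deg), betweenness = btw,
                 closeness = clo, eigenvector = eig)
}

#' Compare SRB vs other nodes on node-level topology
#'
#' Two-sided Wilcoxon rank-sum tests of degree, betweenness, closeness
#' and eigenvector centrality between SRB-flagged nodes and the rest,
#' with group medians.
#'
#' @param net A `cooccurrence_network`, or a [node_topology()] tibble.
#' @return Tibble: `metric`, `median_srb`, `median_other`, `statistic`,
#'   `p_value`.
#' @export
compare_srb_topology <- function(net) {
  nt <- if (inherits(net, "cooccurrence_network")) node_topology(net)
        else net
  if (!any(nt$is_srb)) stop("no SRB nodes in network")
  if (all(nt$is_srb)) stop("no non-SRB nodes in network")
  purrr::map_dfr(
    c("degree", "betweenness", "closeness", "eigenvector"),
    function(metric) {
      xs <- nt[[metric]][nt$is_srb]
      ys <- nt[[metric]][!nt$is_srb]
      w <- wilcoxon_rank_sum(xs, ys)
      tibble::tibble(metric = metric,
                     median_srb = w$median_x,
                     median_other = w$median_y,
                     statistic = w$statistic,
                     p_value = w$p_value)
    })
}

#' Export a co-occurrence network
#'
#' Writes the edge list and node table as TSV and the graph as GraphML
#' (Gephi-compatible).
#'
#' @param net A `cooccurrence_network`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix, default `"network"`.
#' @return Paths of the written files, invisibly.
#' @export
write_network <- function(net, dir, prefix = "network") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ep <- file.path(dir, paste0(prefix, "_edges.tsv"))
  np <- file.path(dir, paste0(prefix, "_nodes.tsv"))
  gp <- file.path(dir, paste0(prefix, ".graphml"))
  readr::write_tsv(dplyr::mutate(net$edges, dplyr::across(
    dplyr::where(is.numeric), ~signif(.x, 6))), ep)
  nodes <- dplyr::left_join(net$nodes,
                            dplyr::select(node_topology(net), -"is_srb"),
                            by = "taxon_id")
  readr::write_tsv(dplyr::mutate(nodes, dplyr::across(
    dplyr::where(is.numeric), ~signif(.x, 6))), np)
  g <- net$graph
  igraph::V(g)$phylum <- ifelse(is.na(igraph::V(g)$phylum), "",
                                igraph::V(g)$phylum)
  igraph::write_graph(g, gp, format = "graphml")
  invisible(c(edges = ep, nodes = np, graphml = gp))
}

#' @rdname tidy.neutral_fit
#' @method tidy cooccurrence_network
#' @export
tidy.cooccurrence_network <- function(x, ...) x$edges

#' @rdname tidy.neutral_fit
#' @method glance cooccurrence_network
#' @export
glance.cooccurrence_network <- function(x, ...) global_topology(x)

#' Degree-coloured network summary plot
#'
#' A quick diagnostic layout of the network (Fruchterman-Reingold,
#' seeded) with SRB nodes highlighted. For publication-grade figures
#' export GraphML via [write_network()] and use Gephi.
#'
#' @param object A `cooccurrence_network`.
#' @param seed Layout seed.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cooccurrence_network
#' @export
autoplot.cooccurrence_network <- function(object, seed = 1L, ...) {
  g <- object$graph
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  xy <- igraph::layout_with_fr(g)
  nodes <- dplyr::mutate(object$nodes, x = xy[, 1], y = xy[, 2],
                         degree = igraph::degree(g))
  el <- igraph::as_edgelist(g, names = FALSE)
  segs <- tibble::tibble(x = xy[el[, 1], 1], y = xy[el[, 1], 2],
                         xend = xy[el[, 2], 1], yend = xy[el[, 2], 2])
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = segs,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend,
                                       yend = .data$yend),
                          colour = "grey80", linewidth = 0.2) +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     size = .data$degree,
                                     colour = .data$is_srb)) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "#d73027"),
                                 labels = c("other", "SRB"),
                                 name = NULL) +
    ggplot2::scale_size_continuous(range = c(0.5, 4)) +
    ggplot2::theme_void()
}
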