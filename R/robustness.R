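#' Natural connectivity of a graph
#'
#' \deqn{\bar\lambda = \ln\!\Big(\frac{1}{N}\sum_{i=1}^{N} e^{\lambda_i}\Big)}
#' where \eqn{\lambda_i} are the eigenvalues of the simple (unweighted,
#' undirected) adjacency matrix. A spectral measure of the redundancy of
#' closed walks: it never increases when an edge is removed, which makes
#' it a well-behaved robustness score under node/edge loss. Computed with
#' an overflow-safe log-sum-exp; all `N` nodes count, including isolated
#' ones. The empty graph returns 0 by convention.
#'
#' @param g An igraph (or a `cooccurrence_network`).
#' @return Natural connectivity, a scalar >= 0 for any graph containing
#'   at least its self-walks (0 for edgeless graphs).
#' @export
natural_connectivity <- function(g) {
  if (inherits(g, "cooccurrence_network")) g <- g$graph
  N <- igraph::vcount(g)
  if (N == 0) return(0)
  if (igraph::ecount(g) == 0) return(0)
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE, type = "both")
  A[A != 0] <- 1
  diag(A) <- 0
  lam <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  mx <- max(lam)
  mx + log(sum(exp(lam - mx))) - log(N)
}

#' Keystone-removal robustness simulation
#'
#' Repeatedly deletes a growing proportion of the SRB (keystone) node
#' set, or an equally sized random draw of non-SRB nodes as control, and
#' scores each induced subgraph by natural connectivity, the fraction of
#' original nodes still carrying at least one edge, and the average
#' degree. For proportion f the removal count is `round(f * n_SRB)`
#' (half away from zero); the "other" scheme samples the same count from
#' non-SRB nodes only. Each (scheme, proportion, repetition) cell draws
#' from its own child seed, so any subset of the experiment can be
#' reproduced independently.
#'
#' @param net A `cooccurrence_network` whose nodes carry `is_srb` flags
#'   (or an igraph with a logical `is_srb` vertex attribute).
#' @param proportions Removal proportions in (0, 1], default
#'   `seq(0.1, 1, 0.1)`.
#' @param repetitions Repetitions per proportion, default 50.
#' @param seed Master integer seed.
#' @return A `robustness_trajectory`: `records` (tibble: `scheme`,
#'   `proportion`, `repetition`, `n_removed`, `natural_connectivity`,
#'   `remaining_node_fraction`, `average_degree`), `baseline` (intact
#'   metrics), `n_srb`, `n_nodes`.
#' @export
remove_nodes <- function(net, proportions = seq(0.1, 1, 0.1),
                         repetitions = 50, seed = 1L) {
  g <- if (inherits(net, "cooccurrence_network")) net$graph else net
  stopifnot(all(proportions > 0 & proportions <= 1), repetitions >= 1)
  is_srb <- igraph::V(g)$is_srb
  if (is.null(is_srb)) stop("network lacks is_srb node flags")
  srb_pool <- which(is_srb)
  other_pool <- which(!is_srb)
  if (!length(srb_pool)) stop("no SRB nodes to remove")
  N0 <- igraph::vcount(g)

  score <- function(keep) {
    sub <- igraph::induced_subgraph(g, keep)
    nk <- igraph::vcount(sub)
    tibble::tibble(
      natural_connectivity = natural_connectivity(sub),
      remaining_node_fraction =
        if (nk) sum(igraph::degree(sub) > 0) / N0 else 0,
      average_degree =
        if (nk) 2 * igraph::ecount(sub) / nk else 0)
  }

  grid <- tidyr::expand_grid(scheme = c("srb", "other"),
                             proportion = proportions,
                             repetition = seq_len(repetitions))
  old <- .save_seed(); on.exit(.restore_seed(old))
  records <- purrr::pmap_dfr(grid, function(scheme, proportion,
                                            repetition) {
    k <- .round_half_away(proportion * length(srb_pool))
    pool <- if (scheme == "srb") srb_pool else other_pool
    if (k > length(pool))
      stop("removal count ", k, " exceeds ", scheme, " pool size ",
           length(pool))
    idx <- which(grid$scheme == scheme &
                 grid$proportion == proportion &
                 grid$repetition == repetition)
    set.seed(.child_seed(seed, idx))
    removed <- if (k > 0) sample(pool, k) else integer(0)
    dplyr::bind_cols(
      tibble::tibble(scheme = scheme, proportion = proportion,
                     repetition = repetition, n_removed = k),
      score(setdiff(seq_len(N0), removed)))
  })
  structure(list(records = records,
                 baseline = score(seq_len(N0)),
                 n_srb = length(srb_pool), n_nodes = N0),
            class = "robustness_trajectory")
}

.round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Summarise a robustness trajectory
#'
#' Per-scheme OLS slope of natural connectivity on removal proportion
#' (pooled over repetitions) and per-(scheme, proportion) mean +- SD
#' tables for plotting.
#'
#' @param traj A `robustness_trajectory`.
#' @return A list: `slopes` (tibble: `scheme`, `slope`, `intercept`,
#'   `r`, `p_value`, `n`), `by_proportion` (tibble of means and SDs of
#'   all three metrics).
#' @export
summarize_trajectory <- function(traj) {
  rec <- traj$records
  if (length(unique(rec$proportion)) < 2)
    stop("need >= 2 proportions to fit a slope")
  slopes <- rec |>
    dplyr::group_by(.data$scheme) |>
    dplyr::group_modify(function(d, key)
      ols_fit(d$proportion, d$natural_connectivity)) |>
    dplyr::ungroup()
  by_prop <- rec |>
    dplyr::group_by(.data$scheme, .data$proportion) |>
    dplyr::summarise(dplyr::across(
      c("natural_connectivity", "remaining_node_fraction",
        "average_degree"),
      list(mean = mean, sd = stats::sd)), .groups = "drop")
  list(slopes = slopes, by_proportion = by_prop)
}

#' @export
print.robustness_trajectory <- function(x, ...) {
  s <- summarize_trajectory(x)
  cat("<robustness_trajectory> ", x$n_srb, " SRB of ", x$n_nodes,
      " nodes; slopes of natural connectivity:\n", sep = "")
  print(as.data.frame(s$slopes[, c("scheme", "slope")]),
        row.names = FALSE)
  invisible(x)
}

#' @rdname tidy.neutral_fit
#' @method tidy robustness_trajectory
#' @export
tidy.robustness_trajectory <- function(x, ...) x$records

#' @rdname tidy.neutral_fit
#' @method glance robustness_trajectory
#' @export
glance.robustness_trajectory <- function(x, ...) {
  s <- summarize_trajectory(x)
  tidyr::pivot_wider(s$slopes[, c("scheme", "slope")],
                     names_from = "scheme", values_from = "slope",
                     names_prefix = "slope_")
}

#' Natural-connectivity decay plot
#'
#' Mean natural connectivity (+- SD ribbon) against removal proportion,
#' one curve per removal scheme, with the pooled OLS regression lines.
#'
#' @param object A `robustness_trajectory`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot robustness_trajectory
#' @export
autoplot.robustness_trajectory <- function(object, ...) {
  s <- summarize_trajectory(object)
  d <- s$by_proportion
  ggplot2::ggplot(d, ggplot2::aes(x = .data$proportion,
                                  y = .data$natural_connectivity_mean,
                                  colour = .data$scheme,
                                  fill = .data$scheme)) +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = .data$natural_connectivity_mean -
        .data$natural_connectivity_sd,
      ymax = .data$natural_connectivity_mean +
        .data$natural_connectivity_sd),
      alpha = 0.15, colour = NA) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.6) +
    ggplot2::scale_colour_manual(
      values = c(srb = "#d73027", other = "grey40"),
      aesthetics = c("colour", "fill"), name = "removed") +
    ggplot2::labs(x = "proportion of SRB-set size removed",
                  y = "natural connectivity") +
    ggplot2::theme_minimal()
}
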