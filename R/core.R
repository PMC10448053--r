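#' Rank taxa by occupancy, then abundance
#'
#' The abundance-occupancy core ranking: occupancy descending, ties
#' broken by mean relative abundance descending, remaining ties by
#' taxon id (so the order is deterministic).
#'
#' @param view A `rel_abund`.
#' @return Tibble: `rank`, `taxon_id`, `occupancy`, `mean_abundance`.
#' @export
rank_by_occupancy <- function(view) {
  tx <- dplyr::arrange(view$taxa,
                       dplyr::desc(.data$occupancy),
                       dplyr::desc(.data$mean_abundance),
                       .data$taxon_id)
  dplyr::mutate(
    dplyr::select(tx, "taxon_id", "occupancy", "mean_abundance"),
    rank = dplyr::row_number(), .before = 1)
}

#' Cumulative beta-diversity contribution curve
#'
#' For each rank r along an occupancy-ranked taxon list, the share of the
#' Bray-Curtis numerator carried by the top-r taxa, averaged over all
#' sample pairs:
#' \deqn{c_r = \mathrm{mean}_{(j,k)} \frac{\sum_{i \le r} |x_{ij}-x_{ik}|}
#'   {\sum_{i} |x_{ij}-x_{ik}|}}
#' The denominator is fixed at the full-community numerator, which makes
#' the curve monotone non-decreasing with \eqn{c_{last} = 1}. Pairs of
#' identical samples (zero numerator) are skipped with a warning.
#'
#' @param x An `otu_table`.
#' @param ranked Taxon ranking from [rank_by_occupancy()] (or a character
#'   vector covering all taxa of `x`).
#' @return Tibble: `rank`, `taxon_id`, `contribution` (\eqn{c_r}).
#' @export
contribution_curve <- function(x, ranked = NULL) {
  if (is.null(ranked)) ranked <- rank_by_occupancy(to_relative(x))
  ids <- if (is.character(ranked)) ranked else ranked$taxon_id
  if (!setequal(ids, rownames(x$counts)))
    stop("`ranked` must cover exactly the taxa of the table")
  cts <- x$counts[ids, , drop = FALSE]
  S <- ncol(cts)
  pairs <- utils::combn(S, 2)
  # numerator |x_ij - x_ik| per taxon (rows) per pair (cols)
  num <- abs(cts[, pairs[1, ], drop = FALSE] -
             cts[, pairs[2, ], drop = FALSE])
  denom <- colSums(num)
  keep <- denom > 0
  if (any(!keep))
    warning(sum(!keep), " identical sample pair(s) skipped")
  if (!any(keep)) stop("all sample pairs identical")
  shares <- apply(num[, keep, drop = FALSE], 2, cumsum) /
    rep(denom[keep], each = nrow(cts))
  shares <- matrix(shares, nrow = nrow(cts))
  tibble::tibble(rank = seq_along(ids), taxon_id = ids,
                 contribution = unname(rowMeans(shares)))
}

#' Core-set stopping rule on a contribution curve
#'
#' Finds the last rank whose step adds at least `threshold` relative gain
#' to the cumulative contribution: with gains
#' \eqn{g_r = (c_{r+1} - c_r)/c_r}, the stopping rank is
#' \eqn{r^* = 1 + \max\{r : g_r \ge threshold\}} (the "last 2% increase"
#' rule at the default threshold), or 1 if no step reaches it.
#'
#' @param curve Output of [contribution_curve()] (or a numeric vector of
#'   \eqn{c_r}).
#' @param threshold Relative-gain cutoff in (0, 1), default 0.02.
#' @return The stopping rank r* (integer).
#' @export
select_core <- function(curve, threshold = 0.02) {
  stopifnot(threshold > 0, threshold < 1)
  c_r <- if (is.numeric(curve)) curve else curve$contribution
  L <- length(c_r)
  if (L < 2) return(L)
  gains <- (c_r[-1] - c_r[-L]) / c_r[-L]
  hits <- which(gains >= threshold)
  if (!length(hits)) return(1L)
  as.integer(min(L, 1L + max(hits)))
}

#' Summarise a core taxon set
#'
#' Reports the core's share of taxa, its mean per-sample share of
#' sequences, and SRB representation inside versus outside the core.
#' Fractions are computed in exact arithmetic and reported as
#' percentages.
#'
#' @param core Character vector of core taxon ids (subset of the table's
#'   taxa).
#' @param x An `otu_table`.
#' @param annotations Optional tibble (`taxon_id`, `is_srb`); taxa absent
#'   from it count as non-SRB.
#' @return One-row tibble: `n_core`, `n_taxa`, `core_pct_of_taxa`,
#'   `core_pct_of_sequences` (mean over samples of core reads / total
#'   reads, x100), `n_srb_core`, `n_srb_total`, `srb_pct_in_core`,
#'   `srb_pct_overall`.
#' @export
summarize_core <- function(core, x, annotations = NULL) {
  stopifnot(all(core %in% rownames(x$counts)))
  n_core <- length(unique(core))
  n_tax <- n_taxa(x)
  core_reads <- colSums(x$counts[unique(core), , drop = FALSE])
  total_reads <- colSums(x$counts)
  seq_pct <- mean(core_reads / total_reads) * 100
  is_srb <- .srb_flags(rownames(x$counts), annotations)
  names(is_srb) <- rownames(x$counts)
  n_srb_core <- sum(is_srb[unique(core)])
  n_srb_total <- sum(is_srb)
  tibble::tibble(
    n_core = n_core, n_taxa = n_tax,
    core_pct_of_taxa = n_core / n_tax * 100,
    core_pct_of_sequences = seq_pct,
    n_srb_core = n_srb_core, n_srb_total = n_srb_total,
    srb_pct_in_core = if (n_core > 0) n_srb_core / n_core * 100 else NA_real_,
    srb_pct_overall = n_srb_total / n_tax * 100)
}

.srb_flags <- function(taxa, annotations) {
  if (is.null(annotations)) return(rep(FALSE, length(taxa)))
  idx <- match(taxa, annotations$taxon_id)
  flags <- annotations$is_srb[idx]
  flags[is.na(flags)] <- FALSE
  flags
}

#' Abundance-occupancy core microbiome selection
#'
#' End-to-end core identification: rank taxa occupancy-then-abundance,
#' score each rank by its cumulative contribution to beta diversity
#' ([contribution_curve()]), stop at the last rank adding at least
#' `threshold` relative gain ([select_core()]), and summarise the chosen
#' core ([summarize_core()]).
#'
#' @param x An `otu_table` (one habitat, typically rarefied).
#' @param threshold Relative-gain stopping threshold, default 0.02.
#' @param annotations Optional SRB annotation tibble.
#' @return A `core_selection`: `curve` (ranked tibble with
#'   `contribution` and `in_core`), `r_star`, `core_ids`, `summary`,
#'   `threshold`.
#' @export
core_microbiome <- function(x, threshold = 0.02, annotations = NULL) {
  view <- to_relative(x)
  ranked <- rank_by_occupancy(view)
  curve <- contribution_curve(x, ranked)
  r_star <- select_core(curve, threshold)
  curve <- dplyr::mutate(
    dplyr::left_join(curve,
                     dplyr::select(ranked, "taxon_id", "occupancy",
                                   "mean_abundance"),
                     by = "taxon_id"),
    in_core = .data$rank <= r_star)
  core_ids <- curve$taxon_id[curve$in_core]
  structure(list(curve = curve, r_star = r_star, core_ids = core_ids,
                 summary = summarize_core(core_ids, x, annotations),
                 threshold = threshold),
            class = "core_selection")
}

#' @export
print.core_selection <- function(x, ...) {
  s <- x$summary
  cat("<core_selection> ", s$n_core, " of ", s$n_taxa, " taxa (",
      sprintf("%.2f", s$core_pct_of_taxa), "% of taxa, ",
      sprintf("%.2f", s$core_pct_of_sequences), "% of sequences)\n",
      sep = "")
  invisible(x)
}

#' @rdname tidy.neutral_fit
#' @method tidy core_selection
#' @export
tidy.core_selection <- function(x, ...) x$curve

#' @rdname tidy.neutral_fit
#' @method glance core_selection
#' @export
glance.core_selection <- function(x, ...)
  dplyr::mutate(x$summary, r_star = x$r_star,
                threshold = x$threshold)

#' Contribution-curve plot of a core selection
#'
#' @param object A `core_selection`.
#' @param ... Unused.
#' @return A ggplot of cumulative beta-diversity contribution against
#'   rank, with the stopping rank marked.
#' @method autoplot core_selection
#' @export
autoplot.core_selection <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = .data$rank,
                               y = .data$contribution)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$r_star,
                        linetype = "dashed", colour = "#d73027") +
    ggplot2::labs(x = "occupancy rank",
                  y = "cumulative contribution to beta diversity",
                  subtitle = sprintf("core = top %d taxa", object$r_star)) +
    ggplot2::theme_minimal()
}
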