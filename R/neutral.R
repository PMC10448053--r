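#' Sloan neutral-model occupancy curve
#'
#' Expected occurrence frequency of a taxon with metacommunity mean
#' relative abundance `p` in a local community of size `N` with migration
#' rate `m` and detection limit `d`:
#' \deqn{F(p) = 1 - I_d(N m p,\; N m (1 - p))}
#' where \eqn{I_d} is the regularised incomplete Beta function (the Beta
#' CDF at `d`). Under neutral drift-with-immigration the local relative
#' abundance of the taxon is Beta-distributed with those shapes; the
#' taxon is detected whenever its abundance exceeds the detection limit.
#'
#' @param p Mean relative abundance(s) in (0, 1).
#' @param m Migration rate, > 0. Larger `m` couples local communities
#'   more tightly to the source.
#' @param N Local community size (reads per sample), > 0.
#' @param d Detection limit in relative-abundance units (0 < d < 1),
#'   typically 1/N after rarefaction.
#' @return Predicted occupancy in [0, 1], vectorised over `p`.
#' @export
predicted_occupancy <- function(p, m, N, d) {
  stopifnot(m > 0, N > 0, d > 0, d < 1)
  if (any(p <= 0) || any(p >= 1)) stop("p must be in (0, 1)")
  a <- N * m * p
  b <- N * m * (1 - p)
  if (any(a <= 0) || any(b <= 0)) stop("Beta shapes must be positive")
  1 - stats::pbeta(d, a, b)
}

#' Fit the Sloan neutral community model
#'
#' Estimates the migration rate `m` by least squares of observed taxon
#' occupancies against [predicted_occupancy()] across taxa, with
#' community size `N` fixed at the mean sample depth and detection limit
#' `d` at the smallest observed non-zero relative abundance. A 95% Wilson
#' score band (with n = number of samples) around the fitted curve
#' partitions taxa into `neutral` (inside), `above` and `below`; the
#' ratio #neutral / (#above + #below) summarises the balance of
#' stochastic to deterministic assembly. The binomial pure-sampling
#' competitor is fitted alongside and both models are scored by a
#' Gaussian-residual AIC (lower is better).
#'
#' The 1-D least-squares problem is solved by a coarse grid over
#' \eqn{\log m} followed by Brent refinement within the bracketing
#' interval, which is robust to the local minima a single-start Newton
#' step can fall into.
#'
#' @param view A `rel_abund` (from [to_relative()]), ideally on a
#'   rarefied table.
#' @param d Detection limit override; default smallest non-zero fraction.
#' @param N Community size override; default mean sample depth.
#' @param m_bounds Search interval for m (default `c(1e-6, 1e3)`).
#' @param conf Band coverage (default 0.95).
#' @return A `neutral_fit` object; see [tidy.neutral_fit()] /
#'   [glance.neutral_fit()]. Fields: `m`, `N`, `d`, `r_squared`, `taxa`
#'   (per-taxon tibble with predictions, band, partition), `counts`
#'   (partition tally), `ratio` (stochastic:deterministic),
#'   `aic_neutral`, `aic_binomial`, `n_samples`.
#' @export
fit_neutral_model <- function(view, d = NULL, N = NULL,
                              m_bounds = c(1e-6, 1e3), conf = 0.95) {
  stopifnot(inherits(view, "rel_abund"))
  if (is.null(N)) N <- view$mean_depth
  fr <- view$fractions
  if (is.null(d)) d <- min(fr[fr > 0])
  tx <- view$taxa
  use <- tx$mean_abundance > 0 & tx$mean_abundance < 1
  if (all(tx$occupancy[use] == 1))
    stop("degenerate data: every taxon occupies every sample")
  if (sum(use & tx$occupancy > 0 & tx$occupancy < 1) < 20)
    warning("fewer than 20 taxa with intermediate occupancy; ",
            "fit may be unstable")
  p <- tx$mean_abundance[use]
  obs <- tx$occupancy[use]

  ss <- function(logm) {
    pred <- predicted_occupancy(p, exp(logm), N, d)
    sum((obs - pred)^2)
  }
  grid <- seq(log(m_bounds[1]), log(m_bounds[2]), length.out = 61)
  vals <- vapply(grid, ss, numeric(1))
  i <- which.min(vals)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  opt <- stats::optimize(ss, c(lo, hi), tol = 1e-10)
  m_hat <- exp(opt$minimum)

  pred <- predicted_occupancy(p, m_hat, N, d)
  ss_res <- sum((obs - pred)^2)
  ss_tot <- sum((obs - mean(obs))^2)
  r2 <- 1 - ss_res / ss_tot

  band <- .wilson_band(pred, view$n_samples, conf)
  partition <- dplyr::case_when(
    obs > band$upper ~ "above",
    obs < band$lower ~ "below",
    TRUE ~ "neutral")

  # binomial (pure random sampling) competitor, no free parameter
  pred_bin <- .binomial_occupancy(p, N, d)
  ss_bin <- sum((obs - pred_bin)^2)
  n <- length(obs)
  aic_neutral <- n * log(ss_res / n) + 2 * 1
  aic_binomial <- n * log(ss_bin / n) + 2 * 0

  taxa <- tibble::tibble(
    taxon_id = tx$taxon_id[use],
    mean_abundance = p,
    occupancy_obs = obs,
    occupancy_pred = pred,
    lower95 = band$lower,
    upper95 = band$upper,
    partition = partition)
  counts <- c(neutral = sum(partition == "neutral"),
              above = sum(partition == "above"),
              below = sum(partition == "below"))
  ratio <- if (counts[["above"]] + counts[["below"]] > 0)
    counts[["neutral"]] / (counts[["above"]] + counts[["below"]])
  else Inf
  structure(list(m = m_hat, N = N, d = d, r_squared = r2,
                 taxa = taxa, counts = counts, ratio = ratio,
                 aic_neutral = aic_neutral, aic_binomial = aic_binomial,
                 ss_res = ss_res, ss_binomial = ss_bin,
                 n_samples = view$n_samples, conf = conf,
                 convergence = list(objective = opt$objective,
                                    log_m = opt$minimum)),
            class = "neutral_fit")
}

# Wilson score interval around a predicted proportion, clipped to [0,1]
.wilson_band <- function(p_hat, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  denom <- 1 + z^2 / n
  centre <- (p_hat + z^2 / (2 * n)) / denom
  half <- z * sqrt(p_hat * (1 - p_hat) / n + z^2 / (4 * n^2)) / denom
  list(lower = pmax(0, centre - half), upper = pmin(1, centre + half))
}

.binomial_occupancy <- function(p, N, d) {
  Nr <- round(N)
  thr <- max(0, round(Nr * d) - 1)
  1 - stats::pbinom(thr, Nr, p)
}

#' Binomial pure-sampling occupancy model
#'
#' Predicted occupancy when local communities are plain multinomial
#' samples of the source (no drift, no parameter): the probability that
#' a taxon with source abundance `p` is seen at or above the detection
#' limit in `N` reads, \eqn{1 - \mathrm{BinomCDF}(\lceil Nd\rceil - 1; N, p)}.
#' Serves as the null competitor for the neutral model's AIC comparison.
#'
#' @inheritParams fit_neutral_model
#' @return Tibble: `taxon_id`, `mean_abundance`, `occupancy_obs`,
#'   `occupancy_pred`; attribute `"ss_res"` carries the residual sum of
#'   squares.
#' @export
fit_binomial_model <- function(view, d = NULL, N = NULL) {
  stopifnot(inherits(view, "rel_abund"))
  if (is.null(N)) N <- view$mean_depth
  fr <- view$fractions
  if (is.null(d)) d <- min(fr[fr > 0])
  tx <- view$taxa
  use <- tx$mean_abundance > 0 & tx$mean_abundance < 1
  pred <- .binomial_occupancy(tx$mean_abundance[use], N, d)
  out <- tibble::tibble(taxon_id = tx$taxon_id[use],
                        mean_abundance = tx$mean_abundance[use],
                        occupancy_obs = tx$occupancy[use],
                        occupancy_pred = pred)
  attr(out, "ss_res") <- sum((out$occupancy_obs - pred)^2)
  out
}

#' Bootstrap AIC comparison of the neutral and binomial models
#'
#' Resamples taxa with replacement `n_boot` times; on each resample both
#' models are refitted and scored by the Gaussian-residual AIC
#' \eqn{n \ln(SS/n) + 2k} (k = 1 for the neutral model's migration rate,
#' k = 0 for the parameter-free binomial). Lower AIC indicates the
#' better-supported model.
#'
#' @inheritParams fit_neutral_model
#' @param n_boot Number of bootstrap replicates (default 1000).
#' @param seed Integer seed.
#' @return A list: `replicates` (tibble: `replicate`, `aic_neutral`,
#'   `aic_binomial`), `summary` (tibble with means and 2.5/97.5%
#'   quantiles per model), `n_failed` refits.
#' @export
bootstrap_aic <- function(view, n_boot = 1000, seed = 1L,
                          d = NULL, N = NULL) {
  stopifnot(inherits(view, "rel_abund"), n_boot >= 1)
  if (is.null(N)) N <- view$mean_depth
  fr <- view$fractions
  if (is.null(d)) d <- min(fr[fr > 0])
  tx <- view$taxa
  use <- tx$mean_abundance > 0 & tx$mean_abundance < 1
  p_all <- tx$mean_abundance[use]
  obs_all <- tx$occupancy[use]
  n <- length(p_all)

  fit_once <- function(p, obs) {
    ss <- function(logm)
      sum((obs - predicted_occupancy(p, exp(logm), N, d))^2)
    grid <- seq(log(1e-6), log(1e3), length.out = 31)
    vals <- vapply(grid, ss, numeric(1))
    i <- which.min(vals)
    opt <- stats::optimize(ss, c(grid[max(1, i - 1)],
                                 grid[min(length(grid), i + 1)]),
                           tol = 1e-8)
    ss_neu <- opt$objective
    ss_bin <- sum((obs - .binomial_occupancy(p, N, d))^2)
    c(n * log(ss_neu / n) + 2, n * log(ss_bin / n))
  }

  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  res <- matrix(NA_real_, n_boot, 2)
  failed <- 0L
  for (b in seq_len(n_boot)) {
    idx <- if (n_boot == 1) seq_len(n) else sample(n, replace = TRUE)
    r <- tryCatch(fit_once(p_all[idx], obs_all[idx]),
                  error = function(e) NULL)
    if (is.null(r)) failed <- failed + 1L else res[b, ] <- r
  }
  if (failed > 0.1 * n_boot)
    stop(failed, " of ", n_boot, " bootstrap refits failed")
  reps <- tibble::tibble(replicate = seq_len(n_boot),
                         aic_neutral = res[, 1],
                         aic_binomial = res[, 2])
  long <- tidyr::pivot_longer(reps, -"replicate",
                              names_to = "model", values_to = "aic")
  summ <- dplyr::summarise(
    dplyr::group_by(long, .data$model),
    mean = mean(.data$aic, na.rm = TRUE),
    lower = stats::quantile(.data$aic, 0.025, na.rm = TRUE),
    upper = stats::quantile(.data$aic, 0.975, na.rm = TRUE),
    .groups = "drop")
  list(replicates = reps, summary = summ, n_failed = failed)
}

#' @export
print.neutral_fit <- function(x, ...) {
  cat("<neutral_fit> m =", signif(x$m, 4),
      " R2 =", signif(x$r_squared, 4),
      " N =", signif(x$N, 6), " d =", signif(x$d, 4), "\n")
  cat("  partition:", paste(names(x$counts), x$counts, collapse = ", "),
      " ratio =", signif(x$ratio, 4), "\n")
  cat("  AIC neutral =", signif(x$aic_neutral, 6),
      " binomial =", signif(x$aic_binomial, 6), "\n")
  invisible(x)
}

#' Tidy / summarise a neutral-model fit
#'
#' `tidy()` returns the per-taxon table (abundance, observed and
#' predicted occupancy, 95% band, partition); `glance()` a one-row model
#' summary.
#'
#' @param x A `neutral_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy neutral_fit
#' @export
tidy.neutral_fit <- function(x, ...) x$taxa

#' @rdname tidy.neutral_fit
#' @method glance neutral_fit
#' @export
glance.neutral_fit <- function(x, ...) {
  tibble::tibble(m = x$m, N = x$N, d = x$d, r_squared = x$r_squared,
                 n_taxa = nrow(x$taxa), n_samples = x$n_samples,
                 n_neutral = x$counts[["neutral"]],
                 n_above = x$counts[["above"]],
                 n_below = x$counts[["below"]],
                 ratio = x$ratio,
                 aic_neutral = x$aic_neutral,
                 aic_binomial = x$aic_binomial)
}

#' Occupancy-abundance plot of a neutral fit
#'
#' Each point is a taxon at its log10 mean relative abundance and
#' observed occupancy, coloured by partition; the solid line is the
#' fitted neutral curve and dashed lines its 95% band.
#'
#' @param object A `neutral_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot neutral_fit
#' @export
autoplot.neutral_fit <- function(object, ...) {
  df <- dplyr::arrange(object$taxa, .data$mean_abundance)
  ggplot2::ggplot(df, ggplot2::aes(x = log10(.data$mean_abundance))) +
    ggplot2::geom_point(ggplot2::aes(y = .data$occupancy_obs,
                                     colour = .data$partition),
                        size = 0.8, alpha = 0.7) +
    ggplot2::geom_line(ggplot2::aes(y = .data$occupancy_pred),
                       colour = "grey30") +
    ggplot2::geom_line(ggplot2::aes(y = .data$lower95),
                       colour = "grey55", linetype = "dashed") +
    ggplot2::geom_line(ggplot2::aes(y = .data$upper95),
                       colour = "grey55", linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(neutral = "#4575b4",
                                            above = "#d73027",
                                            below = "#fc8d59")) +
    ggplot2::labs(x = "log10 mean relative abundance",
                  y = "occupancy",
                  colour = NULL,
                  subtitle = sprintf("m = %.3g, R² = %.2f, ratio = %.2f",
                                     object$m, object$r_squared,
                                     object$ratio)) +
    ggplot2::theme_minimal()
}
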