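#' Alpha diversity per sample
#'
#' Richness S (taxa detected), Shannon H (natural log by default, the
#' Shannon-Wiener convention) and Pielou evenness J = H / ln(S). J is
#' undefined (NA) for samples with fewer than two taxa.
#'
#' @param x An `otu_table`.
#' @param log_base Base of the Shannon logarithm (default `exp(1)`).
#' @return Tibble: `sample_id`, `group`, `richness`, `shannon`, `pielou`.
#' @export
alpha_diversity <- function(x, log_base = exp(1)) {
  tibble::tibble(
    sample_id = colnames(x$counts),
    group = x$metadata$group,
    richness = apply(x$counts, 2, richness),
    shannon = apply(x$counts, 2, shannon, log_base = log_base),
    pielou = apply(x$counts, 2, pielou_evenness, log_base = log_base))
}

#' Shannon diversity of one count vector
#'
#' \eqn{H = -\sum_i f_i \log f_i} over taxa with \eqn{f_i > 0}, where
#' \eqn{f_i} is the relative abundance.
#'
#' @param counts Non-negative count (or abundance) vector, not all zero.
#' @param log_base Logarithm base, default natural.
#' @return H, a non-negative scalar.
#' @export
shannon <- function(counts, log_base = exp(1)) {
  if (any(counts < 0)) stop("negative counts")
  total <- sum(counts)
  if (total == 0) stop("all-zero count vector")
  f <- counts[counts > 0] / total
  -sum(f * log(f, base = log_base))
}

#' @rdname shannon
#' @export
richness <- function(counts) sum(counts > 0)

#' @rdname shannon
#' @export
pielou_evenness <- function(counts, log_base = exp(1)) {
  s <- richness(counts)
  if (s <= 1) return(NA_real_)
  shannon(counts, log_base) / log(s, base = log_base)
}

#' Bray-Curtis dissimilarity matrix
#'
#' \eqn{D_{jk} = \sum_i |x_{ij} - x_{ik}| / \sum_i (x_{ij} + x_{ik})},
#' computed with [vegan::vegdist()]. Symmetric, zero-diagonal, bounded in
#' [0, 1].
#'
#' @param x An `otu_table` with at least two samples and no all-zero
#'   samples.
#' @return A symmetric sample-by-sample matrix.
#' @export
bray_curtis <- function(x) {
  if (n_samples(x) < 2) stop("need >= 2 samples")
  if (any(colSums(x$counts) == 0))
    stop("all-zero sample present; Bray-Curtis undefined")
  as.matrix(vegan::vegdist(t(x$counts), method = "bray"))
}

#' Principal coordinates analysis
#'
#' Classical metric scaling (double-centring of -D^2/2, eigen
#' decomposition). Negative eigenvalues, which arise when D is not
#' Euclidean-embeddable (Bray-Curtis typically is not), are reported
#' as-is; no Cailliez/Lingoes correction is applied.
#'
#' @param D Symmetric distance matrix (e.g. from [bray_curtis()]).
#' @param k Number of axes to return (default 2).
#' @return A list: `coordinates` (tibble: `sample_id`, `axis1`, ...,
#'   plus eigenvalue shares as attribute), `eigenvalues` (all of them),
#'   `variance_explained` (share of the positive eigenvalue total per
#'   returned axis).
#' @export
pcoa_axes <- function(D, k = 2) {
  D <- as.matrix(D)
  fit <- stats::cmdscale(stats::as.dist(D), k = min(k, nrow(D) - 1),
                         eig = TRUE)
  pts <- fit$points
  if (ncol(pts) < k)
    warning("only ", ncol(pts), " axes available; k truncated")
  coords <- tibble::as_tibble(pts, .name_repair = "minimal")
  names(coords) <- paste0("axis", seq_len(ncol(coords)))
  coords <- dplyr::bind_cols(
    tibble::tibble(sample_id = rownames(D)), coords)
  pos <- sum(fit$eig[fit$eig > 0])
  list(coordinates = coords,
       eigenvalues = fit$eig,
       variance_explained = fit$eig[seq_len(ncol(pts))] / pos)
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based test of group separation on a distance matrix:
#' \eqn{R = (\bar r_B - \bar r_W) / (M/2)} with ranks taken over all
#' \eqn{M = n(n-1)/2} pairwise distances. Significance by permutation of
#' group labels; when the number of distinct label arrangements is at
#' most `exact_limit` they are enumerated exhaustively instead and the
#' p-value is exact.
#'
#' @param D Symmetric distance matrix with sample ids as dimnames.
#' @param groups Group label per sample (same order as `D`), >= 2 groups
#'   with >= 2 samples each.
#' @param n_perm Number of label permutations (default 999).
#' @param seed Integer seed for the permutations.
#' @param exact_limit Enumerate exhaustively when the number of distinct
#'   arrangements is below this (default 10000); set 0 to disable.
#' @return Tibble: `statistic` (R), `p_value`, `n_perm`, `method`
#'   (`"exact"` or `"permutation"`).
#' @export
anosim_test <- function(D, groups, n_perm = 999, seed = 1L,
                        exact_limit = 10000) {
  D <- as.matrix(D)
  n <- nrow(D)
  groups <- as.character(groups)
  stopifnot(length(groups) == n)
  tab <- table(groups)
  if (length(tab) < 2) stop("need >= 2 groups")
  if (any(tab < 2)) stop("every group needs >= 2 samples")

  ut <- upper.tri(D)
  r <- rank(D[ut])
  M <- length(r)
  same <- outer(groups, groups, "==")[ut]
  R_of <- function(same_vec)
    (mean(r[!same_vec]) - mean(r[same_vec])) / (M / 2)
  R_obs <- R_of(same)

  n_arr <- .n_arrangements(tab)
  if (!is.na(n_arr) && n_arr <= exact_limit && exact_limit > 0) {
    perms <- .enumerate_assignments(groups)
    R_all <- vapply(perms, function(g)
      R_of(outer(g, g, "==")[ut]), numeric(1))
    p <- mean(R_all >= R_obs - 1e-12)
    return(tibble::tibble(statistic = R_obs, p_value = p,
                          n_perm = length(R_all), method = "exact"))
  }
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  R_perm <- vapply(seq_len(n_perm), function(i) {
    g <- sample(groups)
    R_of(outer(g, g, "==")[ut])
  }, numeric(1))
  p <- (1 + sum(R_perm >= R_obs - 1e-12)) / (1 + n_perm)
  tibble::tibble(statistic = R_obs, p_value = p, n_perm = n_perm,
                 method = "permutation")
}

# number of distinct group-label arrangements (multinomial coefficient)
.n_arrangements <- function(tab) {
  v <- exp(lgamma(sum(tab) + 1) - sum(lgamma(tab + 1)))
  if (!is.finite(v)) NA_real_ else round(v)
}

# enumerate all distinct assignments of the multiset of labels
.enumerate_assignments <- function(groups) {
  labs <- sort(unique(groups))
  n <- length(groups)
  out <- list()
  recurse <- function(remaining_pos, counts, assignment) {
    if (!length(remaining_pos)) {
      out[[length(out) + 1]] <<- assignment
      return(invisible())
    }
    pos <- remaining_pos[1]
    for (l in labs[counts > 0]) {
      counts2 <- counts; counts2[l] <- counts2[l] - 1
      assignment[pos] <- l
      recurse(remaining_pos[-1], counts2, assignment)
    }
  }
  counts <- table(factor(groups, levels = labs))
  counts <- stats::setNames(as.integer(counts), labs)
  recurse(seq_len(n), counts, character(n))
  out
}

#' Standardised effect size of mean nearest-taxon distance (SES.MNTD)
#'
#' Per sample, MNTD is the mean patristic distance from each present
#' taxon to its nearest present relative; the null distribution shuffles
#' tip labels across the tree (`"taxa.labels"` null) and
#' \eqn{SES = (obs - \bar{null}) / sd(null)}. Negative SES.MNTD indicates
#' phylogenetic clustering beyond chance. Computation is delegated to
#' [picante::ses.mntd()], the standard implementation.
#'
#' @param x An `otu_table` whose taxa all appear as tree tips.
#' @param tree Rooted [ape::phylo] with branch lengths.
#' @param n_null Number of null randomisations (default 999).
#' @param seed Integer seed.
#' @param abundance_weighted Weight MNTD by abundances (default FALSE).
#' @return Tibble: `sample_id`, `group`, `n_taxa`, `mntd_obs`,
#'   `null_mean`, `null_sd`, `ses_mntd` (NA where undefined: < 2 taxa or
#'   zero null sd), `n_null`.
#' @export
ses_mntd <- function(x, tree, n_null = 999, seed = 1L,
                     abundance_weighted = FALSE) {
  missing <- setdiff(rownames(x$counts), tree$tip.label)
  if (length(missing))
    stop("taxa absent from tree: ", paste(utils::head(missing, 3),
                                          collapse = ", "))
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  dis <- stats::cophenetic(tree)
  samp <- t(x$counts)
  single <- nrow(samp) == 1
  if (single) {                       # picante needs >= 2 distinct rows
    samp <- samp[c(1, 1), , drop = FALSE]
    rownames(samp) <- c(rownames(samp)[1], ".dup")
  }
  res <- picante::ses.mntd(samp, dis, null.model = "taxa.labels",
                           abundance.weighted = abundance_weighted,
                           runs = n_null)
  if (single) res <- res[1, , drop = FALSE]
  tibble::tibble(
    sample_id = rownames(res),
    group = x$metadata$group[match(rownames(res),
                                   x$metadata$sample_id)],
    n_taxa = res$ntaxa,
    mntd_obs = res$mntd.obs,
    null_mean = res$mntd.rand.mean,
    null_sd = res$mntd.rand.sd,
    ses_mntd = dplyr::if_else(res$ntaxa >= 2 & res$mntd.rand.sd > 0,
                              res$mntd.obs.z, NA_real_),
    n_null = n_null)
}

#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Exact enumeration when both samples are small and tie-free, otherwise
#' the tie-corrected normal approximation — the default behaviour of
#' [stats::wilcox.test()], surfaced as a tidy one-row tibble.
#'
#' @param x,y Numeric vectors, both non-empty.
#' @return Tibble: `statistic` (Mann-Whitney U for `x`), `p_value`,
#'   `median_x`, `median_y`, `method`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  stopifnot(length(x) > 0, length(y) > 0)
  if (length(unique(c(x, y))) == 1)
    return(tibble::tibble(statistic = length(x) * length(y) / 2,
                          p_value = 1, median_x = stats::median(x),
                          median_y = stats::median(y), method = "degenerate"))
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- !ties && (length(x) + length(y)) <= 20
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = !exact))
  tibble::tibble(statistic = unname(wt$statistic), p_value = wt$p.value,
                 median_x = stats::median(x), median_y = stats::median(y),
                 method = if (exact) "exact" else "normal-approx")
}

#' Ordinary least-squares fit of y on x
#'
#' Slope, intercept, Pearson r and the t-test p-value for the slope, via
#' [stats::lm()]. Used for the abundance-diversity regressions and the
#' robustness-trajectory slopes.
#'
#' @param x,y Numeric vectors, length >= 3, with `var(x) > 0`.
#' @return Tibble: `slope`, `intercept`, `r`, `p_value`, `n`.
#' @export
ols_fit <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::var(x) == 0) stop("var(x) = 0; slope undefined")
  fit <- stats::lm(y ~ x)
  s <- summary(fit)
  tibble::tibble(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r = stats::cor(x, y),
                 p_value = s$coefficients[2, 4],
                 n = length(x))
}
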