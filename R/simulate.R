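#' Simulate a community assembled under the Sloan neutral model
#'
#' Generates an OTU table whose occupancy-abundance structure follows the
#' stationary approximation the Sloan fit assumes: a metacommunity with
#' log-normal relative abundances \eqn{p_i}, and for every sample an
#' independent Beta draw of each taxon's local relative abundance with
#' shape parameters \eqn{(N m p_i,\; N m (1 - p_i))}, renormalised across
#' taxa and converted to reads by a multinomial draw at depth `n_reads`.
#' Small `m` (migration rate) makes local communities drift far from the
#' source, lowering occupancy of rare taxa; large `m` pins every sample to
#' the source composition.
#'
#' @param n_taxa Number of taxa in the source community.
#' @param n_samples Number of local communities (samples).
#' @param n_reads Sequencing depth per sample.
#' @param m Migration rate, > 0.
#' @param sigma_log Standard deviation of log source abundances
#'   (log-normal metacommunity; default 2, a typically long-tailed
#'   amplicon abundance distribution).
#' @param seed Integer seed; the same seed reproduces the table exactly.
#' @param group Group label written into the sample metadata.
#' @return An `otu_table` with attribute `"source_abundance"` holding the
#'   true \eqn{p_i} used.
#' @export
simulate_neutral_table <- function(n_taxa, n_samples, n_reads, m,
                                   sigma_log = 2, seed = 1L,
                                   group = "sim") {
  stopifnot(n_taxa >= 2, n_samples >= 1, n_reads >= 1)
  if (m <= 0) stop("m must be > 0")
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  p <- stats::rlnorm(n_taxa, meanlog = 0, sdlog = sigma_log)
  p <- p / sum(p)
  a <- n_reads * m * p
  b <- n_reads * m * (1 - p)
  if (any(a <= 0) || any(b <= 0))
    stop("Beta shape parameters must be positive; check m, n_reads, p")
  counts <- matrix(0L, n_taxa, n_samples,
                   dimnames = list(sprintf("OTU%04d", seq_len(n_taxa)),
                                   sprintf("%s_s%03d", group,
                                           seq_len(n_samples))))
  for (j in seq_len(n_samples)) {
    frac <- stats::rbeta(n_taxa, a, b)
    s <- sum(frac)
    frac <- if (s > 0) frac / s else rep(1 / n_taxa, n_taxa)
    counts[, j] <- stats::rmultinom(1, n_reads, frac)[, 1]
  }
  ot <- otu_table(counts,
                  tibble::tibble(sample_id = colnames(counts),
                                 group = group))
  attr(ot, "source_abundance") <-
    stats::setNames(p, rownames(counts))
  ot
}

#' Simulate an OTU table with block/hub correlation structure
#'
#' Builds a latent Gaussian factor model: taxa are partitioned into
#' blocks sharing a block factor (pairwise latent correlation
#' `rho_block`), plus `n_hubs` "keystone" taxa, each the centre of its own
#' star: the hub loads heavily (0.97) on a private factor and
#' `hub_degree_multiplier * (block_size - 1)` satellite taxa load at
#' 0.85, so the hub-satellite latent correlation (~0.82) survives the
#' rank-correlation attenuation of count sampling and clears a 0.6 edge
#' threshold, while satellite-satellite correlation (~0.72 latent,
#' weaker after attenuation) mostly does not — hubs end up with several
#' times the degree of other nodes. The factor construction is positive
#' semi-definite by design. Latent Gaussians are mapped through their
#' CDF to log-normal abundance quantiles; structured taxa (blocks, hubs,
#' satellites) get a higher log-mean than noise taxa, emulating the
#' empirical pattern that network-forming and keystone taxa are drawn
#' from the abundant fraction of the community. Reads are sampled
#' multinomially per sample. Hubs are labelled SRB.
#'
#' @param n_taxa Total number of taxa; must accommodate the blocks, hubs
#'   and satellites (remaining taxa are independent noise).
#' @param n_samples Number of samples.
#' @param n_reads Reads per sample.
#' @param rho_block Latent within-block correlation, |rho| < 1.
#' @param n_blocks,block_size Block layout (default 8 blocks of 6 taxa).
#' @param n_hubs Number of hub (SRB-labelled) taxa, default 4.
#' @param hub_degree_multiplier Satellites per hub, as a multiple of
#'   `block_size - 1` (default 3, i.e. 15 satellites per hub).
#' @param sigma_log Log-sd of marginal abundances (default 1.5).
#' @param seed Integer seed.
#' @param group Group label for sample metadata.
#' @return A list: `table` (the `otu_table`), `truth` (tibble of
#'   ground-truth edges: `taxon_a`, `taxon_b`, `latent_rho`, `type` in
#'   `{"within_block","hub_satellite"}`), `annotations` (tibble
#'   `taxon_id`, `is_srb` with hubs flagged), `hub_ids`.
#' @export
simulate_structured_table <- function(n_taxa, n_samples, n_reads,
                                      rho_block = 0.9,
                                      n_blocks = 8, block_size = 6,
                                      n_hubs = 4,
                                      hub_degree_multiplier = 3,
                                      sigma_log = 1.5, seed = 1L,
                                      group = "sim") {
  stopifnot(n_samples >= 4, n_reads >= 1, abs(rho_block) < 1)
  n_sat <- n_hubs * round(hub_degree_multiplier * (block_size - 1))
  n_struct <- n_blocks * block_size + n_hubs + n_sat
  if (n_taxa < n_struct)
    stop("n_taxa too small: need at least ", n_struct,
         " for the requested blocks/hubs")
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)

  ids <- sprintf("OTU%04d", seq_len(n_taxa))
  # loadings matrix L (taxa x factors); latent x = L f + sqrt(1-|L|^2) eps
  n_fac <- n_blocks + n_hubs
  L <- matrix(0, n_taxa, n_fac)
  block_of <- rep(NA_integer_, n_taxa)
  idx <- 1
  if (rho_block < 0)
    stop("negative rho_block is not supported by the factor construction")
  lb <- sqrt(rho_block)                  # block loading
  for (b in seq_len(n_blocks)) {
    rows <- idx:(idx + block_size - 1)
    L[rows, b] <- lb
    block_of[rows] <- b
    idx <- idx + block_size
  }
  hub_rows <- integer(0)
  l_hub <- 0.97; l_sat <- 0.85
  sat_per_hub <- if (n_hubs > 0) n_sat / n_hubs else 0
  for (h in seq_len(n_hubs)) {
    hub <- idx; idx <- idx + 1
    L[hub, n_blocks + h] <- l_hub
    hub_rows <- c(hub_rows, hub)
    if (sat_per_hub > 0) {
      sats <- idx:(idx + sat_per_hub - 1)
      L[sats, n_blocks + h] <- l_sat
      idx <- idx + sat_per_hub
    }
  }
  resid_sd <- sqrt(pmax(0, 1 - rowSums(L^2)))

  f <- matrix(stats::rnorm(n_samples * n_fac), n_fac, n_samples)
  z <- L %*% f + resid_sd * matrix(stats::rnorm(n_taxa * n_samples),
                                   n_taxa, n_samples)
  u <- stats::pnorm(z)
  meanlog <- stats::rnorm(n_taxa, 0, 1)       # per-taxon abundance scale
  meanlog[seq_len(n_struct)] <- meanlog[seq_len(n_struct)] + 3
  ab <- stats::qlnorm(pmin(pmax(u, 1e-12), 1 - 1e-12),
                      meanlog = meanlog, sdlog = sigma_log)
  counts <- matrix(0L, n_taxa, n_samples,
                   dimnames = list(ids,
                                   sprintf("%s_s%03d", group,
                                           seq_len(n_samples))))
  for (j in seq_len(n_samples))
    counts[, j] <- stats::rmultinom(1, n_reads, ab[, j] / sum(ab[, j]))[, 1]

  # ground-truth edges: latent correlation L L' (off-diagonal) >= 0.6
  latent <- L %*% t(L)
  truth <- NULL
  pairs <- which(upper.tri(latent) & abs(latent) >= 0.6 - 1e-9,
                 arr.ind = TRUE)
  if (nrow(pairs)) {
    i <- pairs[, 1]; j <- pairs[, 2]
    type <- dplyr::case_when(
      !is.na(block_of[i]) & block_of[i] == block_of[j] ~ "within_block",
      i %in% hub_rows | j %in% hub_rows ~ "hub_satellite",
      TRUE ~ "satellite_satellite")
    truth <- tibble::tibble(taxon_a = ids[i], taxon_b = ids[j],
                            latent_rho = latent[pairs], type = type)
  } else {
    truth <- tibble::tibble(taxon_a = character(), taxon_b = character(),
                            latent_rho = double(), type = character())
  }
  ann <- tibble::tibble(taxon_id = ids,
                        is_srb = seq_len(n_taxa) %in% hub_rows)
  list(table = otu_table(counts,
                         tibble::tibble(sample_id = colnames(counts),
                                        group = group)),
       truth = truth, annotations = ann, hub_ids = ids[hub_rows])
}

#' Simulate a pure-birth phylogeny
#'
#' Yule (pure-birth) tree with `n_tips` labelled tips. When
#' `clustered_tips` is given, those labels are forced into a single
#' monophyletic clade by grafting a separate pure-birth subtree onto one
#' tip of a backbone tree — useful for constructing communities that are
#' phylogenetically clustered by design (negative SES.MNTD).
#'
#' @param n_tips Number of tips (>= 2).
#' @param clustered_tips Optional character vector of tip labels (length
#'   >= 2, <= n_tips - 1) to place in one clade. Remaining tips are
#'   labelled `t1 ... t<k>` unless `tip_labels` is supplied.
#' @param tip_labels Optional labels for all tips (clustered labels are
#'   drawn from these if both are given).
#' @param seed Integer seed.
#' @return A rooted [ape::phylo] with branch lengths.
#' @export
simulate_tree <- function(n_tips, clustered_tips = NULL,
                          tip_labels = NULL, seed = 1L) {
  if (n_tips < 2) stop("n_tips must be >= 2")
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  if (is.null(tip_labels)) tip_labels <- paste0("t", seq_len(n_tips))
  stopifnot(length(tip_labels) == n_tips, !anyDuplicated(tip_labels))
  if (is.null(clustered_tips)) {
    tr <- ape::rphylo(n_tips, birth = 1, death = 0)
    tr$tip.label <- tip_labels
    return(tr)
  }
  k <- length(clustered_tips)
  stopifnot(k >= 2, k <= n_tips - 1, all(clustered_tips %in% tip_labels))
  rest <- setdiff(tip_labels, clustered_tips)
  backbone <- ape::rphylo(length(rest) + 1, birth = 1, death = 0)
  backbone$tip.label <- c(rest, "GRAFT")
  clade <- ape::rphylo(k, birth = 1, death = 0)
  # shrink the clade so its tips sit close together relative to backbone
  clade$edge.length <- clade$edge.length /
    max(ape::node.depth.edgelength(clade)) * 0.2
  clade$tip.label <- clustered_tips
  tr <- ape::bind.tree(backbone, clade,
                       where = which(backbone$tip.label == "GRAFT"))
  tr
}
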