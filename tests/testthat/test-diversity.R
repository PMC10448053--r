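test_that("shannon, richness and evenness match their definitions", {
  expect_equal(shannon(c(25, 25, 25, 25)), log(4))
  expect_equal(shannon(c(10, 0, 0)), 0)
  f <- c(0.1, 0.2, 0.3, 0.4)
  expect_equal(shannon(1:4), -sum(f * log(f)))
  expect_error(shannon(c(0, 0)), "all-zero")
  expect_equal(pielou_evenness(c(5, 5, 5)), 1)
  expect_lt(pielou_evenness(c(9, 1)), pielou_evenness(c(5, 5)))
  expect_equal(richness(c(3, 0, 7)), 2)
  expect_true(is.na(pielou_evenness(c(4, 0))))
  # H <= ln(S), equality iff uniform (random cases)
  set.seed(1)
  for (i in 1:20) {
    v <- rpois(10, 5) + (i == 1)
    v[1] <- v[1] + 1
    expect_lte(shannon(v), log(richness(v)) + 1e-12)
  }
  # cross-check against vegan on a random vector
  set.seed(2); v <- rpois(15, 10) + 1
  expect_equal(shannon(v), as.numeric(vegan::diversity(v)))
})

test_that("bray-curtis matches hand values and stays in bounds", {
  ot <- tiny_table(matrix(c(2L, 2L, 1L, 3L), 2,
                          dimnames = list(c("a", "b"), c("s1", "s2"))))
  D <- bray_curtis(ot)
  expect_equal(D["s1", "s2"], 0.25)
  # identical and disjoint samples
  id <- tiny_table(matrix(c(1L, 2L, 1L, 2L), 2,
                          dimnames = list(c("a", "b"), c("s1", "s2"))))
  expect_equal(bray_curtis(id)["s1", "s2"], 0)
  dj <- tiny_table(matrix(c(3L, 0L, 0L, 5L), 2,
                          dimnames = list(c("a", "b"), c("s1", "s2"))))
  expect_equal(bray_curtis(dj)["s1", "s2"], 1)
  # properties on a random table
  D2 <- bray_curtis(random_table(25, 8, seed = 3))
  expect_true(all(D2 >= 0 & D2 <= 1))
  expect_equal(D2, t(D2))
  expect_true(all(diag(D2) == 0))
})

test_that("pcoa reconstructs euclidean configurations and simplex geometry", {
  # points on a line: recovered distances match input to 1e-8
  x <- c(0, 1, 3, 7, 12)
  D <- as.matrix(dist(x))
  dimnames(D) <- list(paste0("s", 1:5), paste0("s", 1:5))
  # k above the rank is truncated, with a warning
  warns <- testthat::capture_warnings(ord <- pcoa_axes(D, k = 4))
  expect_true(any(grepl("truncated", warns)))
  rec <- as.matrix(dist(as.matrix(ord$coordinates[, -1])))
  expect_lt(max(abs(rec - D)), 1e-8)
  # equidistant triple: two equal positive eigenvalues
  D3 <- matrix(1, 3, 3) - diag(3)
  dimnames(D3) <- list(paste0("s", 1:3), paste0("s", 1:3))
  ord3 <- pcoa_axes(D3, k = 2)
  eig <- ord3$eigenvalues[1:2]
  expect_gt(min(eig), 0)
  expect_equal(eig[1], eig[2])
  # duplicated sample lands on coincident coordinates
  x2 <- c(0, 0, 2, 5)
  D4 <- as.matrix(dist(x2))
  dimnames(D4) <- list(paste0("s", 1:4), paste0("s", 1:4))
  co <- as.matrix(pcoa_axes(D4, k = 2)$coordinates[, -1])
  expect_lt(max(abs(co[1, ] - co[2, ])), 1e-6)
})

test_that("anosim matches oracles, vegan, and its exact mode", {
  # perfectly separated groups give R = 1
  x <- c(0, 0.1, 0.2, 5, 5.1, 5.2)
  D <- as.matrix(dist(x))
  dimnames(D) <- list(paste0("s", 1:6), paste0("s", 1:6))
  g <- rep(c("a", "b"), each = 3)
  res <- anosim_test(D, g, seed = 1)
  expect_equal(res$statistic, 1)
  # R statistic equals the independent direct-formula oracle and vegan's
  set.seed(4)
  ot <- random_table(20, 8, seed = 5)
  D2 <- bray_curtis(ot)
  g2 <- rep(c("a", "b"), each = 4)
  r_obs <- anosim_test(D2, g2, seed = 2)$statistic
  expect_equal(r_obs, anosim_R_oracle(D2, g2))
  van <- vegan::anosim(as.dist(D2), g2, permutations = 9)
  expect_equal(r_obs, unname(van$statistic))
  # exact mode equals brute-force enumeration on 4 samples
  D4 <- as.matrix(dist(c(0, 1, 10, 11)))
  dimnames(D4) <- list(paste0("s", 1:4), paste0("s", 1:4))
  g4 <- c("a", "a", "b", "b")
  ex <- anosim_test(D4, g4)
  expect_equal(ex$method, "exact")
  expect_equal(ex$n_perm, 6)   # choose(4,2) distinct arrangements
  R_all <- apply(t(combn(4, 2)), 1, function(idx) {
    gg <- rep("b", 4); gg[idx] <- "a"
    anosim_R_oracle(D4, gg)
  })
  expect_equal(ex$p_value, mean(R_all >= ex$statistic - 1e-12))
  # null: shuffled labels on unstructured distances give mean R near 0
  set.seed(9)
  Dn <- as.matrix(dist(rnorm(8)))
  dimnames(Dn) <- list(paste0("s", 1:8), paste0("s", 1:8))
  Rs <- replicate(200, anosim_R_oracle(Dn, sample(rep(c("a", "b"), 4))))
  expect_lt(abs(mean(Rs)), 0.05)
  # group of size 1 rejected
  expect_error(anosim_test(D4, c("a", "b", "b", "b")), ">= 2 samples")
})

test_that("ses.mntd flags degenerate communities and detects clustering", {
  tree <- simulate_tree(16, clustered_tips = paste0("t", 1:5), seed = 3)
  # community confined to the shallow clade: negative SES
  cts <- matrix(0L, 16, 3, dimnames = list(paste0("t", 1:16),
                                           paste0("s", 1:3)))
  cts[1:5, ] <- 5L
  clustered <- otu_table(cts)
  res <- ses_mntd(clustered, tree, n_null = 99, seed = 1)
  expect_true(all(res$ses_mntd < 0))
  # saturated community: shuffling cannot change MNTD -> undefined
  full <- otu_table(matrix(2L, 16, 2,
                           dimnames = list(paste0("t", 1:16),
                                           c("s1", "s2"))))
  res2 <- ses_mntd(full, tree, n_null = 29, seed = 1)
  expect_true(all(is.na(res2$ses_mntd)))
  # sample with < 2 taxa flagged undefined
  one <- matrix(0L, 16, 2, dimnames = list(paste0("t", 1:16),
                                           c("s1", "s2")))
  one[1, 1] <- 4L
  one[3:8, 2] <- 2L
  res3 <- ses_mntd(otu_table(one), tree, n_null = 29, seed = 1)
  expect_true(is.na(res3$ses_mntd[res3$sample_id == "s1"]))
  expect_false(is.na(res3$ses_mntd[res3$sample_id == "s2"]))
  # unstructured communities have SES centred near zero
  set.seed(8)
  big <- simulate_tree(40, seed = 17)
  zs <- vapply(1:25, function(i) {
    m <- matrix(0L, 40, 1, dimnames = list(big$tip.label, "s1"))
    m[sample(40, 12), 1] <- 1L
    ses_mntd(otu_table(m), big, n_null = 49, seed = i)$ses_mntd
  }, numeric(1))
  expect_lt(abs(mean(zs)), 0.3)
})

test_that("wilcoxon test covers exact, tie and degenerate regimes", {
  w <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(w$p_value, 0.1)
  expect_true(w$statistic %in% c(0, 9))
  expect_equal(w$method, "exact")
  # identical multisets: p = 1
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(3, 1, 2))$p_value, 1)
  # constant data degenerate
  expect_equal(wilcoxon_rank_sum(rep(2, 4), rep(2, 5))$p_value, 1)
  # shifting y further decreases p
  set.seed(3); x <- rnorm(12); y <- rnorm(12)
  p1 <- wilcoxon_rank_sum(x, y + 1)$p_value
  p2 <- wilcoxon_rank_sum(x, y + 3)$p_value
  expect_lt(p2, p1)
  # agrees with stats::wilcox.test in the tie-corrected regime
  xt <- c(1, 2, 2, 3, 5, 7); yt <- c(2, 3, 3, 6, 8, 9, 9)
  ref <- suppressWarnings(wilcox.test(xt, yt, exact = FALSE))
  expect_equal(wilcoxon_rank_sum(xt, yt)$p_value, ref$p.value)
})

test_that("ols_fit recovers exact lines and rejects degenerate x", {
  f <- suppressWarnings(ols_fit(1:10, 2 * (1:10) + 1))
  expect_equal(f$slope, 2)
  expect_equal(f$intercept, 1)
  expect_equal(f$r, 1)
  # independent noise: |r| small
  set.seed(5)
  f2 <- ols_fit(rnorm(1000), rnorm(1000))
  expect_lt(abs(f2$r), 0.1)
  # duplicating points leaves the slope unchanged
  x <- c(1, 2, 4, 8); y <- c(0.5, 1.1, 2.3, 3.9)
  expect_equal(ols_fit(c(x, x), c(y, y))$slope, ols_fit(x, y)$slope)
  expect_error(ols_fit(rep(1, 5), 1:5), "var\\(x\\)")
})
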