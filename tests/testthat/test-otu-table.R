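test_that("TSV round trip preserves counts and identifiers", {
  ot <- tiny_table()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_otu_table(ot, path)
  back <- read_otu_table(path, metadata = ot$metadata)
  expect_identical(back$counts, ot$counts)
  expect_identical(taxon_ids(back), taxon_ids(ot))
  expect_identical(sample_ids(back), sample_ids(ot))
})

test_that("validation rejects malformed tables", {
  m <- matrix(1:4, 2, dimnames = list(c("a", "a"), c("s1", "s2")))
  expect_error(otu_table(m), "duplicate taxon id: a")
  m2 <- matrix(c(1, -1, 2, 3), 2,
               dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(otu_table(m2), "non-negative")
  m3 <- matrix(c(1, 0.5, 2, 3), 2,
               dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(otu_table(m3), "integer")
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("taxon_id\ts1\ts2", "a\t1\tx", "b\t2\t3"), path)
  expect_error(read_otu_table(path), "non-numeric count")
})

test_that("median depth uses the lower-median convention", {
  mk <- function(sums) {
    m <- matrix(as.integer(sums), nrow = 1,
                dimnames = list("a", paste0("s", seq_along(sums))))
    otu_table(m)
  }
  expect_identical(median_depth(mk(c(5, 7, 9))), 7L)
  expect_identical(median_depth(mk(c(4, 8))), 4L)
  expect_identical(median_depth(mk(1883)), 1883L)
})

test_that("rarefaction conserves depth, subsets counts, drops shallow samples", {
  ot <- random_table(30, 10, seed = 4, lambda = 20)
  r <- rarefy(ot, depth = 100, seed = 9)
  expect_true(all(colSums(r$counts) == 100))
  expect_true(all(r$counts <= ot$counts[rownames(r$counts),
                                        colnames(r$counts)]))
  expect_true(all(rowSums(r$counts) > 0))
  # deterministic under seed
  r2 <- rarefy(ot, depth = 100, seed = 9)
  expect_identical(r$counts, r2$counts)
  # sample below depth is dropped with a warning
  m <- ot$counts; m[, 1] <- 0L; m[1, 1] <- 3L
  shallow <- otu_table(m, ot$metadata)
  expect_warning(rs <- rarefy(shallow, depth = 100, seed = 1),
                 "below depth")
  expect_false("s001" %in% sample_ids(rs))
  # depth above every sample total errors
  expect_error(rarefy(ot, depth = 10000), "no samples retained")
  # depth equal to total returns the sample unchanged
  one <- otu_table(matrix(c(3L, 7L), 2,
                          dimnames = list(c("a", "b"), "s1")))
  expect_identical(rarefy(one, depth = 10, seed = 1)$counts, one$counts)
})

test_that("relative view normalises columns and computes occupancy", {
  ot <- tiny_table(matrix(c(2L, 2L, 0L, 4L), 2,
                          dimnames = list(c("a", "b"),
                                          c("s1", "s2"))))
  v <- to_relative(ot)
  expect_equal(unname(v$fractions[, 1]), c(0.5, 0.5))
  expect_equal(colSums(v$fractions), c(s1 = 1, s2 = 1))
  expect_equal(v$taxa$occupancy, c(0.5, 1))
  # all-zero sample rejected
  bad <- otu_table(matrix(c(1L, 0L), 1,
                          dimnames = list("a", c("s1", "s2"))))
  expect_error(to_relative(bad), "all-zero sample")
})

test_that("abundance filter is strict and monotone in the threshold", {
  ot <- random_table(40, 12, seed = 2)
  v <- to_relative(ot)
  # strictness: a taxon exactly at threshold is excluded
  thr <- v$taxa$mean_abundance[5]
  expect_false(v$taxa$taxon_id[5] %in% abundance_filter(v, thr))
  # threshold 0 keeps every detected taxon
  expect_setequal(abundance_filter(v, 0), v$taxa$taxon_id)
  # monotone: raising the threshold never adds taxa
  thrs <- sort(runif(5, 0, 0.05))
  sets <- lapply(thrs, function(t) abundance_filter(v, t))
  for (i in seq_len(length(sets) - 1))
    expect_true(all(sets[[i + 1]] %in% sets[[i]]))
  # sum mode: shares summed over samples rather than averaged
  expect_setequal(abundance_filter(v, 0.5, mode = "sum"),
                  v$taxa$taxon_id[rowSums(v$fractions) > 0.5])
})

test_that("taxonomy/annotation/tree readers validate their inputs", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("taxon_id\tlineage",
               "a\tk__Bacteria; p__Proteobacteria; c__Delta",
               "b\tk__Bacteria"), tf)
  tx <- read_taxonomy(tf)
  expect_equal(lineage_rank(tx$lineage, 2),
               c("Proteobacteria", NA))
  af <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("taxon_id\tis_srb", "a\t1", "b\t0"), af)
  ann <- read_annotations(af)
  expect_identical(ann$is_srb, c(TRUE, FALSE))
  tr <- simulate_tree(6, seed = 1)
  np <- withr::local_tempfile(fileext = ".nwk")
  write_phylo_tree(tr, np)
  back <- read_phylo_tree(np)
  expect_setequal(back$tip.label, tr$tip.label)
})
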