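#' Construct an OTU table
#'
#' An `otu_table` couples a non-negative integer count matrix (taxa in rows,
#' samples in columns) with per-sample metadata, usually a habitat label.
#' It is the universal input of the pipeline: rarefaction, diversity,
#' neutral-model fitting, core selection and network inference all start
#' from it.
#'
#' @param counts Integer matrix, taxa x samples, with unique rownames
#'   (taxon ids) and colnames (sample ids). A data frame whose first column
#'   holds taxon ids is also accepted.
#' @param metadata Data frame with columns `sample_id` and `group`; every
#'   sample in `counts` must appear. If `NULL`, all samples are assigned
#'   group `"all"`.
#' @return An object of class `otu_table` with elements `counts` (integer
#'   matrix) and `metadata` (tibble: `sample_id`, `group`).
#' @examples
#' m <- matrix(c(5L, 0L, 3L, 2L, 1L, 4L), nrow = 3,
#'             dimnames = list(paste0("OTU", 1:3), c("s1", "s2")))
#' ot <- otu_table(m)
#' n_taxa(ot)
#' @export
otu_table <- function(counts, metadata = NULL) {
  if (is.data.frame(counts)) {
    ids <- as.character(counts[[1]])
    counts <- as.matrix(counts[, -1, drop = FALSE])
    rownames(counts) <- ids
  }
  if (!is.matrix(counts)) stop("`counts` must be a matrix or data frame")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("`counts` must have taxon rownames and sample colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate taxon id: ",
         rownames(counts)[duplicated(rownames(counts))][1])
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample id: ",
         colnames(counts)[duplicated(colnames(counts))][1])
  if (!is.numeric(counts) || anyNA(counts) || any(!is.finite(counts)))
    stop("counts must be finite numbers")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(counts != round(counts))) stop("counts must be integers")
  storage.mode(counts) <- "integer"

  if (is.null(metadata)) {
    metadata <- tibble::tibble(sample_id = colnames(counts), group = "all")
  } else {
    metadata <- tibble::as_tibble(metadata)
    if (!all(c("sample_id", "group") %in% names(metadata)))
      stop("`metadata` needs columns `sample_id` and `group`")
    missing <- setdiff(colnames(counts), metadata$sample_id)
    if (length(missing))
      stop("samples missing from metadata: ",
           paste(missing, collapse = ", "))
    metadata <- metadata[match(colnames(counts), metadata$sample_id), ]
  }
  structure(list(counts = counts, metadata = metadata),
            class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat("<otu_table> ", nrow(x$counts), " taxa x ", ncol(x$counts),
      " samples; groups: ",
      paste(unique(x$metadata$group), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @rdname otu_table
#' @param x An `otu_table`.
#' @export
n_taxa <- function(x) nrow(x$counts)

#' @rdname otu_table
#' @export
n_samples <- function(x) ncol(x$counts)

#' @rdname otu_table
#' @export
taxon_ids <- function(x) rownames(x$counts)

#' @rdname otu_table
#' @export
sample_ids <- function(x) colnames(x$counts)

#' Subset an otu_table to one sample group
#'
#' @param x An `otu_table`.
#' @param group Group label to keep.
#' @param drop_empty_taxa Drop taxa with all-zero rows in the subset
#'   (default `TRUE`).
#' @return An `otu_table` restricted to the samples of `group`.
#' @export
subset_group <- function(x, group, drop_empty_taxa = TRUE) {
  keep <- x$metadata$sample_id[x$metadata$group == group]
  if (!length(keep)) stop("no samples in group '", group, "'")
  counts <- x$counts[, keep, drop = FALSE]
  if (drop_empty_taxa) counts <- counts[rowSums(counts) > 0, , drop = FALSE]
  otu_table(counts, x$metadata[x$metadata$sample_id %in% keep, ])
}

#' Read / write OTU tables
#'
#' TSV layout: first column `taxon_id`, remaining columns one per sample,
#' tab separated with a header row. BIOM 2.1 is supported when the
#' `biomformat` package is installed.
#'
#' @param path File path.
#' @param format `"tsv"` or `"biom"`.
#' @param metadata Optional sample metadata data frame (see [otu_table()]).
#' @return [read_otu_table()] returns an `otu_table`;
#'   [write_otu_table()] returns `path` invisibly.
#' @export
read_otu_table <- function(path, format = c("tsv", "biom"),
                           metadata = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("reading BIOM requires the `biomformat` package")
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix")
    return(otu_table(m, metadata))
  }
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = "character")
  ids <- df[[1]]
  cells <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop("non-numeric count at row ", bad[1], " (taxon ", ids[bad[1]],
         "), column ", colnames(cells)[bad[2]])
  }
  dimnames(num) <- list(ids, colnames(cells))
  otu_table(num, metadata)
}

#' @rdname read_otu_table
#' @param x An `otu_table`.
#' @export
write_otu_table <- function(x, path) {
  df <- tibble::as_tibble(x$counts, rownames = "taxon_id")
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read sample metadata, taxonomy, and SRB annotation tables
#'
#' All three are two(ish)-column TSVs with a header row:
#' metadata = `sample_id`, `group`; taxonomy = `taxon_id`, `lineage`
#' (ranks separated by `"; "`, coarse to fine); annotations = `taxon_id`,
#' `is_srb` (0/1). Taxa absent from the annotation file are treated as
#' non-SRB downstream.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_metadata <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = "c"))
  if (!all(c("sample_id", "group") %in% names(df)))
    stop("metadata must have columns sample_id, group")
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in metadata")
  df
}

#' @rdname read_metadata
#' @export
read_taxonomy <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = "c"))
  if (!all(c("taxon_id", "lineage") %in% names(df)))
    stop("taxonomy must have columns taxon_id, lineage")
  if (anyDuplicated(df$taxon_id)) stop("duplicate taxon_id in taxonomy")
  df
}

#' @rdname read_metadata
#' @export
read_annotations <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("taxon_id", "is_srb") %in% names(df)))
    stop("annotations must have columns taxon_id, is_srb")
  if (anyDuplicated(df$taxon_id)) stop("duplicate taxon_id in annotations")
  dplyr::mutate(df, is_srb = as.logical(as.integer(.data$is_srb)))
}

#' Extract a named rank from lineage strings
#'
#' Lineages use the `"d__...; p__...; c__..."` convention or plain
#' `"; "`-separated ranks. `lineage_rank` pulls the requested 1-based rank
#' (2 = phylum under the domain-first convention), returning `NA` where
#' the lineage is too short.
#'
#' @param lineage Character vector of lineage strings.
#' @param rank Integer rank position (default 2, the phylum slot).
#' @return Character vector.
#' @export
lineage_rank <- function(lineage, rank = 2L) {
  parts <- strsplit(lineage, ";\\s*")
  vapply(parts, function(p) {
    if (length(p) < rank) return(NA_character_)
    sub("^[a-z]__", "", trimws(p[[rank]]))
  }, character(1))
}

#' Median sequencing depth of an OTU table
#'
#' The median of per-sample read totals, used as the default rarefaction
#' depth. With an even number of samples the *lower* of the two middle
#' values is returned so the depth is always an achievable integer count.
#'
#' @param x An `otu_table`.
#' @return A positive integer.
#' @export
median_depth <- function(x) {
  if (n_samples(x) < 1) stop("empty table")
  sums <- sort(colSums(x$counts))
  as.integer(sums[ceiling(length(sums) / 2)])
}

#' Rarefy an OTU table to even depth
#'
#' Subsamples each sample's reads without replacement (multivariate
#' hypergeometric) down to `depth`. Samples with fewer than `depth` reads
#' are dropped with a warning; taxa left with all-zero rows are dropped.
#' The same `seed` always yields the same table.
#'
#' @param x An `otu_table`.
#' @param depth Target reads per sample; defaults to [median_depth()].
#' @param seed Integer seed.
#' @return A rarefied `otu_table` whose column sums all equal `depth`.
#' @export
rarefy <- function(x, depth = median_depth(x), seed = 1L) {
  stopifnot(depth >= 1)
  sums <- colSums(x$counts)
  keep <- sums >= depth
  if (!any(keep)) stop("no samples retained at depth ", depth)
  if (any(!keep))
    warning(sum(!keep), " sample(s) below depth ", depth, " dropped: ",
            paste(colnames(x$counts)[!keep], collapse = ", "))
  counts <- x$counts[, keep, drop = FALSE]
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  # vegan warns heuristically when the smallest nonzero count exceeds 1;
  # counts here are validated integers, so muffle that specific warning
  rar <- withCallingHandlers(
    t(vegan::rrarefy(t(counts), depth)),
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  rar <- rar[rowSums(rar) > 0, , drop = FALSE]
  storage.mode(rar) <- "integer"
  otu_table(rar, x$metadata[x$metadata$sample_id %in% colnames(rar), ])
}

#' Relative-abundance view of an OTU table
#'
#' Converts counts to per-sample fractions and summarises each taxon by
#' its mean relative abundance \eqn{p_i} (mean of per-sample fractions)
#' and its occupancy (fraction of samples where it is detected). These two
#' per-taxon quantities drive the neutral-model fit and the
#' abundance-occupancy core ranking.
#'
#' @param x An `otu_table` with no all-zero samples.
#' @return A `rel_abund` object: `fractions` (taxa x samples matrix whose
#'   columns sum to 1), `taxa` (tibble: `taxon_id`, `mean_abundance`,
#'   `occupancy`), `n_samples`, and `mean_depth` (mean reads per sample,
#'   kept for the neutral model's community-size parameter).
#' @export
to_relative <- function(x) {
  sums <- colSums(x$counts)
  if (any(sums == 0))
    stop("all-zero sample(s): ",
         paste(colnames(x$counts)[sums == 0], collapse = ", "))
  fr <- sweep(x$counts, 2, sums, "/")
  taxa <- tibble::tibble(
    taxon_id = rownames(fr),
    mean_abundance = unname(rowMeans(fr)),
    occupancy = unname(rowMeans(x$counts > 0)))
  structure(list(fractions = fr, taxa = taxa,
                 n_samples = ncol(fr), mean_depth = mean(sums)),
            class = "rel_abund")
}

#' @export
print.rel_abund <- function(x, ...) {
  cat("<rel_abund> ", nrow(x$fractions), " taxa x ", x$n_samples,
      " samples (mean depth ", signif(x$mean_depth, 6), ")\n", sep = "")
  invisible(x)
}

#' Abundance filter for network construction
#'
#' Keeps taxa whose relative abundance across all samples exceeds
#' `threshold` (strictly). Low-abundance taxa with very few non-zero
#' observations otherwise generate spurious rank correlations.
#' `mode = "mean"` (default) compares the mean per-sample fraction to the
#' threshold; `mode = "sum"` compares the raw sum of per-sample fractions.
#'
#' @param view A `rel_abund`.
#' @param threshold Fraction, default `1e-4` (0.01%).
#' @param mode `"mean"` or `"sum"`.
#' @return Character vector of retained taxon ids.
#' @export
abundance_filter <- function(view, threshold = 1e-4,
                             mode = c("mean", "sum")) {
  mode <- match.arg(mode)
  stopifnot(threshold >= 0)
  share <- if (mode == "mean") view$taxa$mean_abundance
           else rowSums(view$fractions)
  view$taxa$taxon_id[share > threshold]
}

#' Read / write phylogenetic trees (Newick)
#'
#' Thin wrappers over [ape::read.tree()] / [ape::write.tree()] that check
#' the properties downstream phylogenetic analyses need: unique tip
#' labels and non-negative branch lengths.
#'
#' @param path File path.
#' @return [read_phylo_tree()] returns an [ape::phylo] object.
#' @export
read_phylo_tree <- function(path) {
  tr <- ape::read.tree(path)
  if (anyDuplicated(tr$tip.label)) stop("duplicate tip labels in tree")
  if (!is.null(tr$edge.length) && any(tr$edge.length < 0))
    stop("negative branch lengths in tree")
  tr
}

#' @rdname read_phylo_tree
#' @param tree An [ape::phylo] object.
#' @export
write_phylo_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

# RNG bookkeeping: functions that take an explicit seed must not disturb
# the caller's random stream.
.save_seed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# deterministic child-seed derivation (kept below .Machine$integer.max)
.child_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + index * 16807) %% 2147483629)
}
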