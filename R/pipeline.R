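#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis. Defaults follow
#' the conventional settings of habitat-contrast amplicon studies:
#' rarefaction to the median depth, 0.01% abundance filter, |rho| > 0.6
#' with BH q < 0.01 edges, 0.02 core stopping threshold, 999
#' permutations, 1,000 bootstrap replicates, removal proportions
#' 10-100% with 50 repetitions.
#'
#' @param otu Path to the OTU count TSV (or an `otu_table`).
#' @param metadata Path to sample metadata TSV (ignored when `otu` is
#'   already an `otu_table` carrying metadata).
#' @param taxonomy,annotations,tree Optional paths (taxonomy TSV, SRB
#'   annotation TSV, Newick tree) or pre-read objects.
#' @param out_dir Output directory.
#' @param depth `"median"` or an integer rarefaction depth.
#' @param filter_threshold,filter_mode Abundance filter settings.
#' @param rho_min,q_max Network edge thresholds.
#' @param core_threshold Core stopping threshold.
#' @param n_boot Bootstrap replicates for the AIC comparison.
#' @param n_perm ANOSIM permutations.
#' @param n_null SES.MNTD null randomisations.
#' @param proportions,repetitions Robustness removal grid.
#' @param seed Master seed; every stochastic stage derives a child seed
#'   from it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(otu, metadata = NULL, taxonomy = NULL,
                            annotations = NULL, tree = NULL,
                            out_dir = "oceanet_out",
                            depth = "median",
                            filter_threshold = 1e-4,
                            filter_mode = "mean",
                            rho_min = 0.6, q_max = 0.01,
                            core_threshold = 0.02,
                            n_boot = 1000, n_perm = 999, n_null = 999,
                            proportions = seq(0.1, 1, 0.1),
                            repetitions = 50, seed = 1L) {
  cfg <- list(otu = otu, metadata = metadata, taxonomy = taxonomy,
              annotations = annotations, tree = tree, out_dir = out_dir,
              depth = depth, filter_threshold = filter_threshold,
              filter_mode = filter_mode, rho_min = rho_min,
              q_max = q_max, core_threshold = core_threshold,
              n_boot = n_boot, n_perm = n_perm, n_null = n_null,
              proportions = proportions, repetitions = repetitions,
              seed = as.integer(seed))
  for (f in c("otu", "metadata", "taxonomy", "annotations", "tree"))
    if (is.character(cfg[[f]]) && !file.exists(cfg[[f]]))
      stop("config path does not exist: ", cfg[[f]])
  structure(cfg, class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Rarefies the input table, then per habitat group: alpha diversity,
#' neutral-model fit with bootstrap AIC, core-microbiome selection,
#' co-occurrence network with topology tables, and (when SRB
#' annotations are present) the SRB-removal robustness simulation.
#' Across groups it computes Bray-Curtis PCoA, ANOSIM, and — when a tree
#' is supplied — SES.MNTD with between-group Wilcoxon tests. All outputs
#' are written as TSV/JSON under `out_dir` together with a manifest
#' recording parameters, seeds and input checksums; reruns with an
#' identical config are byte-identical.
#'
#' @param config A [pipeline_config()].
#' @return The manifest (list), invisibly; outputs on disk.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_file <- file.path(cfg$out_dir, "run.log")
  logger <- function(...) {
    msg <- paste0("[", paste(...), "]")
    cat(msg, "\n", file = log_file, append = TRUE)
  }
  stage <- function(name, expr) {
    logger("stage", name)
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ",
           conditionMessage(e), call. = FALSE))
  }
  unlink(log_file)

  # ---- load inputs -------------------------------------------------
  meta <- if (is.character(cfg$metadata)) read_metadata(cfg$metadata)
          else cfg$metadata
  ot <- stage("read", {
    if (inherits(cfg$otu, "otu_table")) cfg$otu
    else read_otu_table(cfg$otu, metadata = meta)
  })
  ann <- if (is.character(cfg$annotations))
    read_annotations(cfg$annotations) else cfg$annotations
  taxn <- if (is.character(cfg$taxonomy))
    read_taxonomy(cfg$taxonomy) else cfg$taxonomy
  tree <- if (is.character(cfg$tree)) read_phylo_tree(cfg$tree)
          else cfg$tree
  if (is.null(ann))
    warning("no SRB annotations supplied; SRB comparisons and ",
            "robustness simulation skipped")

  # ---- rarefaction -------------------------------------------------
  depth <- if (identical(cfg$depth, "median")) median_depth(ot)
           else as.integer(cfg$depth)
  rar <- stage("rarefy", rarefy(ot, depth, seed = .child_seed(cfg$seed, 1)))
  write_otu_table(rar, file.path(cfg$out_dir, "rarefied_otu_table.tsv"))

  groups <- unique(rar$metadata$group)

  # ---- cross-group diversity --------------------------------------
  alpha <- stage("alpha", alpha_diversity(rar))
  .write_tsv6(alpha, file.path(cfg$out_dir, "alpha_diversity.tsv"))

  D <- stage("beta", bray_curtis(rar))
  ord <- pcoa_axes(D, k = 2)
  .write_tsv6(ord$coordinates, file.path(cfg$out_dir, "pcoa_axes.tsv"))
  anosim_res <- NULL
  if (length(groups) >= 2 && all(table(rar$metadata$group) >= 2)) {
    anosim_res <- stage("anosim",
      anosim_test(D, rar$metadata$group, n_perm = cfg$n_perm,
                  seed = .child_seed(cfg$seed, 2)))
    .write_tsv6(anosim_res, file.path(cfg$out_dir, "anosim.tsv"))
  }
  if (!is.null(tree)) {
    sm <- stage("ses_mntd",
      ses_mntd(rar, tree, n_null = cfg$n_null,
               seed = .child_seed(cfg$seed, 3)))
    .write_tsv6(sm, file.path(cfg$out_dir, "ses_mntd.tsv"))
  }

  # ---- per-group stages -------------------------------------------
  summary_json <- list()
  for (gi in seq_along(groups)) {
    grp <- groups[gi]
    sub <- subset_group(rar, grp)
    view <- to_relative(sub)
    tag <- gsub("[^A-Za-z0-9_.-]", "_", grp)

    nf <- stage(paste0("neutral/", grp), fit_neutral_model(view))
    .write_tsv6(tidy(nf),
                file.path(cfg$out_dir, paste0("neutral_", tag, ".tsv")))
    boot <- stage(paste0("aic/", grp),
      bootstrap_aic(view, n_boot = cfg$n_boot,
                    seed = .child_seed(cfg$seed, 10 + gi)))

    core <- stage(paste0("core/", grp),
      core_microbiome(sub, threshold = cfg$core_threshold,
                      annotations = ann))
    .write_tsv6(tidy(core),
                file.path(cfg$out_dir, paste0("core_", tag, ".tsv")))

    net <- stage(paste0("network/", grp),
      cooccurrence_network(sub, rho_min = cfg$rho_min,
                           q_max = cfg$q_max,
                           filter_threshold = cfg$filter_threshold,
                           filter_mode = cfg$filter_mode,
                           annotations = ann, taxonomy = taxn))
    write_network(net, cfg$out_dir, prefix = paste0("network_", tag))
    gt <- global_topology(net, seed = .child_seed(cfg$seed, 20 + gi))
    .write_tsv6(gt,
                file.path(cfg$out_dir,
                          paste0("topology_global_", tag, ".tsv")))

    grp_summary <- list(
      neutral = as.list(glance(nf)),
      aic_bootstrap = as.list(boot$summary),
      core = as.list(glance(core)),
      network = as.list(gt))

    if (!is.null(ann) && any(net$nodes$is_srb) &&
        !all(net$nodes$is_srb)) {
      cmp <- stage(paste0("srb_topology/", grp),
                   compare_srb_topology(net))
      .write_tsv6(cmp,
                  file.path(cfg$out_dir,
                            paste0("srb_topology_", tag, ".tsv")))
      rob <- stage(paste0("robustness/", grp),
        remove_nodes(net, proportions = cfg$proportions,
                     repetitions = cfg$repetitions,
                     seed = .child_seed(cfg$seed, 30 + gi)))
      .write_tsv6(tidy(rob),
                  file.path(cfg$out_dir,
                            paste0("robustness_", tag, ".tsv")))
      st <- summarize_trajectory(rob)
      .write_tsv6(st$slopes,
                  file.path(cfg$out_dir,
                            paste0("robustness_slopes_", tag, ".tsv")))
      grp_summary$robustness_slopes <- as.list(
        stats::setNames(st$slopes$slope, st$slopes$scheme))
    } else if (!is.null(ann)) {
      warning("group '", grp, "': no (or only) SRB nodes in network; ",
              "SRB comparison and robustness skipped")
    }
    summary_json[[grp]] <- grp_summary
  }

  manifest <- list(
    package = "oceanet",
    version = as.character(utils::packageVersion("oceanet")),
    seed = cfg$seed,
    depth = depth,
    parameters = cfg[c("filter_threshold", "filter_mode", "rho_min",
                       "q_max", "core_threshold", "n_boot", "n_perm",
                       "n_null", "proportions", "repetitions")],
    groups = as.list(groups),
    inputs = .input_checksums(cfg),
    anosim = if (!is.null(anosim_res)) as.list(anosim_res) else NULL,
    summary = summary_json)
  jsonlite::write_json(manifest,
                       file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  logger("done")
  invisible(manifest)
}

.write_tsv6 <- function(df, path) {
  df <- dplyr::mutate(df, dplyr::across(dplyr::where(is.double),
                                        ~signif(.x, 6)))
  readr::write_tsv(df, path)
}

.input_checksums <- function(cfg) {
  out <- list()
  for (f in c("otu", "metadata", "taxonomy", "annotations", "tree"))
    if (is.character(cfg[[f]]))
      out[[f]] <- unname(tools::md5sum(cfg[[f]]))
  out
}
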