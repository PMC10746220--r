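#' Assemble and validate a pipeline run configuration
#'
#' Accepts a YAML file path or a named list. Unset thresholds default to
#' the values the individual stage functions document (2.5 Mbp length
#' screen, 0.90 eukaryotic fraction, 500-KO reference filter, 0.05
#' selection p, 75/25 split, Sidak alpha 0.05, 90th percentile, 0.70 rho
#' cutoff, 99% ANI collapse).
#'
#' @param config YAML path or named list of paths and thresholds.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  defaults <- list(min_length_bp = 2.5e6, min_euk_fraction = 0.90,
                   min_kos = 500, p_threshold = 0.05, n_trees = 500,
                   split_fraction = 0.25, alpha = 0.05, percentile = 90,
                   rho_min = 0.70, ani_collapse = 99, seed = 1,
                   out_dir = "eukmag_out")
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  required <- c("bins_tsv", "domains_tsv", "quality_tsv", "counts_tsv",
                "lengths_tsv", "totals_tsv", "ref_ko_tsv",
                "ref_labels_tsv", "mag_domains_tsv", "env_tsv",
                "tree_nwk", "focal_txt", "base_txt")
  missing <- setdiff(required, names(config))
  if (length(missing))
    stop("config missing entries: ", paste(missing, collapse = ", "))
  for (nm in required) {
    if (!file.exists(config[[nm]]))
      stop("input file not found (", nm, "): ", config[[nm]])
  }
  structure(config, class = "run_config")
}

#' Run every pipeline stage on configured inputs
#'
#' Executes the five desk-scale stages in order - bin screening, abundance
#' normalisation, trophic scoring, co-occurrence network, phylogenetic
#' diversity - writing one TSV per stage plus a provenance manifest
#' (versions, seed, thresholds, per-stage record counts) to the output
#' directory. Stages share no hidden state; each is just the exported
#' stage function applied to files. A failing stage aborts with the stage
#' name in the error.
#'
#' @param config A [run_config()] (or something coercible to one).
#' @return Invisibly, the manifest list.
#' @export
run_all <- function(config) {
  cfg <- run_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  counts <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
  }

  screen <- stage("screen", {
    bins <- read_cols_tsv(cfg$bins_tsv, c("bin_id", "contig_id"), "bins")
    doms <- read_cols_tsv(cfg$domains_tsv,
                          c("contig_id", "domain", "length"), "domains")
    qual <- read_cols_tsv(cfg$quality_tsv, "bin_id", "quality")
    screen_bin_table(bins, doms, qual, cfg$min_length_bp,
                     cfg$min_euk_fraction)
  })
  utils::write.table(screen, file.path(cfg$out_dir, "screen.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  counts$screen <- c(bins = nrow(screen), euk_pass = sum(screen$euk_pass))

  cpm_mat <- stage("abundance", abundance_from_files(
    cfg$counts_tsv, cfg$lengths_tsv, cfg$totals_tsv, metric = "cpm"))
  write_matrix_tsv(unclass(cpm_mat), file.path(cfg$out_dir, "cpm.tsv"),
                   id_column = "mag_id")
  counts$abundance <- c(mags = nrow(cpm_mat), samples = ncol(cpm_mat))

  trophic <- stage("trophic", {
    refs <- read_ko_profiles(cfg$ref_ko_tsv)
    lab_tab <- read_cols_tsv(cfg$ref_labels_tsv,
                             c("entity_id", "trophic_mode"), "labels")
    labels <- stats::setNames(lab_tab$trophic_mode, lab_tab$entity_id)
    queries <- if (!is.null(cfg$query_ko_tsv))
      read_ko_profiles(cfg$query_ko_tsv) else refs
    trophic_pipeline(refs, labels, queries, min_kos = cfg$min_kos,
                     p_threshold = cfg$p_threshold,
                     n_trees = cfg$n_trees,
                     split_fraction = cfg$split_fraction,
                     seed = cfg$seed)
  })
  utils::write.table(trophic$score_table,
                     file.path(cfg$out_dir, "ko_scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(trophic$scores,
                     file.path(cfg$out_dir, "trophic_scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  counts$trophic <- c(entities_scored = nrow(trophic$scores),
                      selected_kos = trophic$selection$n_selected,
                      held_out_accuracy = trophic$model$accuracy)

  network <- stage("network", {
    dom_tab <- read_cols_tsv(cfg$mag_domains_tsv,
                             c("mag_id", "domain"), "MAG domains")
    domains <- stats::setNames(dom_tab$domain, dom_tab$mag_id)
    ani <- if (!is.null(cfg$ani_tsv))
      ani_matrix(read_matrix_tsv(cfg$ani_tsv, table_spec("ani"))) else
        NULL
    net <- build_network(unclass(cpm_mat), domains, ani,
                         edge_filter_config(cfg$alpha, cfg$percentile,
                                            cfg$rho_min,
                                            cfg$ani_collapse),
                         seed = cfg$seed)
    env <- read_matrix_tsv(cfg$env_tsv,
                           table_spec("env", allow_missing = TRUE))
    memb <- net$communities$membership
    node_for <- function(m)
      if (!is.null(net$collapse) && m %in% names(net$collapse$mapping))
        net$collapse$mapping[[m]] else m
    nodes <- vapply(rownames(cpm_mat), node_for, character(1))
    keep <- nodes %in% names(memb)
    comm_sum <- NULL
    if (any(keep)) {
      grp <- memb[nodes[keep]]
      comm_sum <- rowsum(unclass(cpm_mat)[keep, , drop = FALSE], grp)
      rownames(comm_sum) <- paste0("community_", rownames(comm_sum))
    }
    env_cor <- if (!is.null(comm_sum))
      env_correlation(comm_sum, env) else NULL
    list(net = net, env_cor = env_cor)
  })
  edges <- network$net$edges
  utils::write.table(edges, file.path(cfg$out_dir, "edges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  memb <- network$net$communities$membership
  utils::write.table(
    data.frame(node = names(memb), community = as.integer(memb)),
    file.path(cfg$out_dir, "communities.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  if (length(network$net$connectedness))
    write_matrix_tsv(network$net$connectedness,
                     file.path(cfg$out_dir, "connectedness.tsv"),
                     id_column = "community")
  if (!is.null(network$env_cor))
    utils::write.table(network$env_cor,
                       file.path(cfg$out_dir, "env_correlations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  counts$network <- c(edges = nrow(edges),
                      communities = length(unique(memb)),
                      modularity = network$net$communities$modularity)

  pd <- stage("pd", pd_from_files(cfg$tree_nwk, cfg$focal_txt,
                                  cfg$base_txt))
  utils::write.table(pd, file.path(cfg$out_dir, "pd.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  counts$pd <- c(metrics = nrow(pd))

  manifest <- list(
    package = "eukmag",
    version = as.character(utils::packageVersion("eukmag")),
    seed = cfg$seed,
    thresholds = cfg[c("min_length_bp", "min_euk_fraction", "min_kos",
                       "p_threshold", "n_trees", "split_fraction",
                       "alpha", "percentile", "rho_min", "ani_collapse")],
    stages = counts)
  jsonlite::write_json(manifest,
                       file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Write a complete synthetic input set for a demonstration run
#'
#' Generates, with one seed, every file [run_all()] consumes: toy bins
#' (down-scaled so the fixture stays small, with the length threshold
#' scaled alongside), a trophic reference panel, read counts with planted
#' community structure, MAG domain tags, an ANI matrix with one
#' near-identical pair, environmental covariates and a random tree with
#' focal/base leaf sets.
#'
#' @param dir Output directory.
#' @param seed Integer seed.
#' @param n_refs_per_mode,n_kos Panel size controls.
#' @return A `run_config`-ready named list (paths plus matched
#'   thresholds).
#' @export
write_demo_inputs <- function(dir, seed = 1, n_refs_per_mode = 40,
                              n_kos = 300) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  toy <- make_toy_bins(file.path(dir, "bins"), n_bins = 6, scale = 0.01,
                       seed = seed)
  panel <- make_trophic_panel(n_refs_per_mode = n_refs_per_mode,
                              n_kos = n_kos,
                              n_informative = round(n_kos / 5),
                              seed = seed)
  ref_ko_tsv <- file.path(dir, "ref_kos.tsv")
  write_ko_profiles(panel$profiles, ref_ko_tsv)
  ref_labels_tsv <- file.path(dir, "ref_labels.tsv")
  utils::write.table(
    data.frame(entity_id = names(panel$labels),
               trophic_mode = unname(panel$labels)),
    ref_labels_tsv, sep = "\t", quote = FALSE, row.names = FALSE)

  sim <- make_abundance_matrix(seed = seed)
  set.seed(seed + 1)
  lengths_bp <- round(stats::runif(nrow(sim$cpm), 1e6, 8e6))
  totals <- round(stats::runif(ncol(sim$cpm), 5e6, 5e7))
  X <- matrix(stats::rpois(length(sim$cpm), sim$cpm / 200),
              nrow(sim$cpm), dimnames = dimnames(sim$cpm))
  counts_df <- data.frame(
    mag_id = rep(rownames(X), ncol(X)),
    sample_id = rep(colnames(X), each = nrow(X)),
    reads = as.vector(X))
  counts_tsv <- file.path(dir, "counts.tsv")
  lengths_tsv <- file.path(dir, "lengths.tsv")
  totals_tsv <- file.path(dir, "totals.tsv")
  utils::write.table(counts_df, counts_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(mag_id = rownames(X),
                                length_bp = lengths_bp),
                     lengths_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(sample_id = colnames(X),
                                total_reads = totals),
                     totals_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  mags <- rownames(sim$cpm)
  domain <- ifelse(seq_along(mags) %% 2 == 1, "eukaryote", "prokaryote")
  mag_domains_tsv <- file.path(dir, "mag_domains.tsv")
  utils::write.table(data.frame(mag_id = mags, domain = domain),
                     mag_domains_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ani <- diag(100, length(mags))
  dimnames(ani) <- list(mags, mags)
  ani[1, 2] <- ani[2, 1] <- 99.5
  ani_tsv <- file.path(dir, "ani.tsv")
  write_matrix_tsv(ani, ani_tsv, id_column = "mag_id")

  env_tsv <- file.path(dir, "env.tsv")
  write_matrix_tsv(as.matrix(sim$env), env_tsv, id_column = "sample_id")

  set.seed(seed + 2)
  tree <- ape::rtree(8)
  tree_nwk <- file.path(dir, "tree.nwk")
  ape::write.tree(tree, tree_nwk)
  focal_txt <- file.path(dir, "focal.txt")
  base_txt <- file.path(dir, "base.txt")
  writeLines(tree$tip.label[1:3], focal_txt)
  writeLines(tree$tip.label[4:8], base_txt)

  list(bins_tsv = toy$paths$bins_tsv,
       domains_tsv = toy$paths$domains_tsv,
       quality_tsv = toy$paths$quality_tsv,
       min_length_bp = toy$min_length_bp,
       counts_tsv = counts_tsv, lengths_tsv = lengths_tsv,
       totals_tsv = totals_tsv, ref_ko_tsv = ref_ko_tsv,
       ref_labels_tsv = ref_labels_tsv,
       mag_domains_tsv = mag_domains_tsv, ani_tsv = ani_tsv,
       env_tsv = env_tsv, tree_nwk = tree_nwk, focal_txt = focal_txt,
       base_txt = base_txt, min_kos = 50, n_trees = 200, seed = seed)
}
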