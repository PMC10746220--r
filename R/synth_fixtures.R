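#' Generate a labelled synthetic trophic reference panel
#'
#' Emulates the structure of a curated reference transcriptome panel:
#' three trophic modes, a block of mode-informative KOs that occur with
#' probability `occ_in_mode` inside their mode and `occ_out_mode`
#' elsewhere, and background KOs present everywhere with probability
#' `background_occ`. Informative KOs are assigned to modes round-robin.
#' Fully deterministic for a given seed.
#'
#' @param n_refs_per_mode References per mode.
#' @param n_kos Total number of KOs.
#' @param n_informative Number of mode-informative KOs (<= `n_kos`).
#' @param occ_in_mode,occ_out_mode,background_occ Occurrence
#'   probabilities.
#' @param seed Integer seed.
#' @return List with `matrix` (0/1, entities x KOs), `labels` (named),
#'   `profiles` (named list of KO sets) and `info` (per-KO data frame:
#'   `ko`, `informative`, `mode`).
#' @export
make_trophic_panel <- function(n_refs_per_mode = 300, n_kos = 2000,
                               n_informative = 300, occ_in_mode = 0.9,
                               occ_out_mode = 0.1, background_occ = 0.5,
                               seed = 11) {
  stopifnot(n_informative <= n_kos,
            all(c(occ_in_mode, occ_out_mode, background_occ) >= 0),
            all(c(occ_in_mode, occ_out_mode, background_occ) <= 1))
  if (n_informative > 0 && occ_in_mode == occ_out_mode)
    warning("occ_in_mode equals occ_out_mode: informative KOs carry ",
            "no signal")
  modes <- c("heterotroph", "phototroph", "mixotroph")
  set.seed(seed)
  labels <- rep(modes, each = n_refs_per_mode)
  ids <- sprintf("ref_%s_%03d", substr(labels, 1, 3),
                 stats::ave(seq_along(labels), labels, FUN = seq_along))
  kos <- sprintf("K%05d", seq_len(n_kos))
  ko_mode <- rep(NA_character_, n_kos)
  if (n_informative > 0)
    ko_mode[seq_len(n_informative)] <-
      modes[(seq_len(n_informative) - 1L) %% 3L + 1L]
  prob <- matrix(background_occ, length(ids), n_kos)
  for (j in which(!is.na(ko_mode)))
    prob[, j] <- ifelse(labels == ko_mode[j], occ_in_mode, occ_out_mode)
  mat <- matrix(stats::rbinom(length(prob), 1L, prob), nrow(prob),
                dimnames = list(ids, kos))
  profiles <- lapply(seq_len(nrow(mat)), function(i) kos[mat[i, ] == 1L])
  names(profiles) <- ids
  list(matrix = mat, labels = stats::setNames(labels, ids),
       profiles = profiles,
       info = data.frame(ko = kos, informative = !is.na(ko_mode),
                         mode = ko_mode, stringsAsFactors = FALSE))
}

#' Generate a synthetic abundance matrix with planted communities
#'
#' Members of each planted community share a lognormal latent abundance
#' trajectory across samples, perturbed by independent Gaussian noise on
#' the log scale; background MAGs follow independent lognormal
#' trajectories. Environmental covariates are monotone (linear on the
#' log-latent scale) transforms of the community latents plus noise. The
#' matrix is column-normalised to counts per million so it carries the
#' same compositional structure as a real CPM table.
#'
#' @param n_samples Number of samples (a warning is issued below 10).
#' @param n_communities Number of planted communities.
#' @param community_size MAGs per community.
#' @param n_background Independent background MAGs.
#' @param noise_sd Log-scale member noise standard deviation.
#' @param env_noise_sd Noise added to environmental covariates.
#' @param seed Integer seed.
#' @return List with `cpm` (MAG x sample, attribute `metric = "CPM"`),
#'   `truth` (named integer: planted community per MAG, 0 for
#'   background), `env` (sample x covariate data frame, one covariate per
#'   community) and `latent`.
#' @export
make_abundance_matrix <- function(n_samples = 60, n_communities = 2,
                                  community_size = 8, n_background = 10,
                                  noise_sd = 0.2, env_noise_sd = 0.2,
                                  seed = 3) {
  stopifnot(n_communities >= 1, community_size >= 1, noise_sd >= 0)
  if (n_samples < 10)
    warning("fewer than 10 samples: correlation estimates will be ",
            "unstable")
  set.seed(seed)
  latent <- matrix(stats::rnorm(n_communities * n_samples),
                   n_communities, n_samples)
  mags <- c(sprintf("mag_c%d_%02d", rep(seq_len(n_communities),
                                        each = community_size),
                    rep(seq_len(community_size), n_communities)),
            if (n_background > 0) sprintf("mag_bg_%02d",
                                          seq_len(n_background)))
  truth <- c(rep(seq_len(n_communities), each = community_size),
             rep(0L, n_background))
  names(truth) <- mags
  vals <- matrix(0, length(mags), n_samples,
                 dimnames = list(mags, sprintf("s%02d",
                                               seq_len(n_samples))))
  for (i in seq_along(mags)) {
    vals[i, ] <- if (truth[i] > 0)
      exp(latent[truth[i], ] + stats::rnorm(n_samples, sd = noise_sd))
    else exp(stats::rnorm(n_samples))
  }
  cpm_mat <- sweep(vals, 2, colSums(vals), "/") * 1e6
  attr(cpm_mat, "metric") <- "CPM"
  env <- as.data.frame(lapply(seq_len(n_communities), function(cc)
    latent[cc, ] + stats::rnorm(n_samples, sd = env_noise_sd)))
  colnames(env) <- sprintf("env_%d", seq_len(n_communities))
  rownames(env) <- colnames(cpm_mat)
  list(cpm = cpm_mat, truth = truth, env = env, latent = latent)
}

#' Generate toy bins with contig sequences and quality metrics
#'
#' Emits a small set of genome bins whose sizes and eukaryotic-content
#' fractions straddle the screening thresholds, always including one bin
#' exactly at the 2.5 Mbp length boundary and one exactly at 90%
#' eukaryotic content. Random contig sequences, per-contig domain calls
#' and a quality table are written as plain FASTA/TSV.
#'
#' @param out_dir Output directory (created if needed).
#' @param n_bins Number of bins (>= 4; the first four are the boundary
#'   and pass/fail archetypes).
#' @param scale Multiplier on bin sizes; 1 gives real Mbp-scale bins,
#'   smaller values give faster fixtures with the same boundary
#'   structure relative to `2.5e6 * scale`.
#' @param seed Integer seed.
#' @return Invisibly, a list with `bins`, `domains`, `quality` data
#'   frames and the file paths written (`fasta`, `bins_tsv`,
#'   `domains_tsv`, `quality_tsv`), plus `min_length_bp` (the scaled
#'   length threshold).
#' @export
make_toy_bins <- function(out_dir, n_bins = 6, scale = 1, seed = 42) {
  stopifnot(n_bins >= 4, scale > 0)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  min_len <- round(2.5e6 * scale)
  # archetypes: pass; fail length (exact boundary); fail fraction (exact
  # 90%); fail both; then random bins around the thresholds
  sizes <- c(round(1.2 * min_len), min_len, round(1.2 * min_len),
             round(0.8 * min_len))
  fracs <- c(0.95, 0.99, 0.90, 0.50)
  if (n_bins > 4) {
    sizes <- c(sizes, round(stats::runif(n_bins - 4, 0.7, 1.5) * min_len))
    fracs <- c(fracs, round(stats::runif(n_bins - 4, 0.80, 1.0), 2))
  }
  bins <- domains <- quality <- NULL
  seqs <- character(0); seq_ids <- character(0)
  alphabet <- c("A", "C", "G", "T")
  for (b in seq_len(n_bins)) {
    bin_id <- sprintf("bin_%02d", b)
    euk_len <- round(sizes[b] * fracs[b])
    contig_lens <- c(euk_len, sizes[b] - euk_len)
    contig_dom <- c("eukaryote", "prokaryote")
    keep <- contig_lens > 0
    contig_lens <- contig_lens[keep]; contig_dom <- contig_dom[keep]
    cids <- sprintf("%s_ctg%d", bin_id, seq_along(contig_lens))
    for (ci in seq_along(cids)) {
      seqs <- c(seqs, paste(sample(alphabet, contig_lens[ci],
                                   replace = TRUE), collapse = ""))
      seq_ids <- c(seq_ids, cids[ci])
    }
    bins <- rbind(bins, data.frame(bin_id = bin_id, contig_id = cids,
                                   stringsAsFactors = FALSE))
    domains <- rbind(domains, data.frame(
      contig_id = cids, domain = contig_dom, length = contig_lens,
      stringsAsFactors = FALSE))
    quality <- rbind(quality, data.frame(
      bin_id = bin_id,
      busco_completeness = round(stats::runif(1, 5, 95), 1),
      checkm_completeness = round(stats::runif(1, 50, 99), 1),
      checkm_contamination = round(stats::runif(1, 0, 12), 1),
      n50 = round(stats::runif(1, 1e4, 5e5)),
      stringsAsFactors = FALSE))
  }
  fasta <- file.path(out_dir, "contigs.fasta")
  write_fasta(data.frame(id = seq_ids, sequence = seqs,
                         stringsAsFactors = FALSE), fasta)
  paths <- list(fasta = fasta,
                bins_tsv = file.path(out_dir, "bins.tsv"),
                domains_tsv = file.path(out_dir, "domains.tsv"),
                quality_tsv = file.path(out_dir, "quality.tsv"))
  utils::write.table(bins, paths$bins_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(domains, paths$domains_tsv, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(quality, paths$quality_tsv, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(list(bins = bins, domains = domains, quality = quality,
                 paths = paths, min_length_bp = min_len))
}
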