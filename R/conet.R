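#' Spearman correlations between all MAG pairs
#'
#' Computes the Spearman rank correlation and its (asymptotic,
#' midrank-tied) two-sided p-value for every unordered pair of MAGs
#' across samples. Pairs sharing fewer than `min_shared` samples with
#' values in both MAGs are reported with missing rho and p.
#'
#' @param mat MAG x sample numeric matrix (e.g. a CPM matrix).
#' @param min_shared Minimum number of shared non-missing samples.
#' @return Data frame of class `correlation_result`: `mag_i`, `mag_j`,
#'   `rho`, `p`, `n_shared`.
#' @export
spearman_all_pairs <- function(mat, min_shared = 3L) {
  stopifnot(is.matrix(mat))
  if (nrow(mat) < 2L) stop("need at least two MAGs")
  ids <- rownames(mat)
  if (is.null(ids)) ids <- paste0("mag", seq_len(nrow(mat)))
  pairs <- utils::combn(nrow(mat), 2)
  res <- apply(pairs, 2, function(ij) {
    xi <- mat[ij[1], ]; xj <- mat[ij[2], ]
    ok <- !is.na(xi) & !is.na(xj)
    if (sum(ok) < min_shared) return(c(NA_real_, NA_real_, sum(ok)))
    ct <- suppressWarnings(stats::cor.test(xi[ok], xj[ok],
                                           method = "spearman",
                                           exact = FALSE))
    c(unname(ct$estimate), ct$p.value, sum(ok))
  })
  out <- data.frame(mag_i = ids[pairs[1, ]], mag_j = ids[pairs[2, ]],
                    rho = res[1, ], p = res[2, ], n_shared = res[3, ],
                    stringsAsFactors = FALSE)
  class(out) <- c("correlation_result", "data.frame")
  out
}

#' Sidak-corrected p-value cutoff
#'
#' For `n` simultaneous tests at family-wise level `alpha`, a test is
#' retained when its raw p-value falls below `1 - (1 - alpha)^(1/n)`.
#'
#' @param alpha Family-wise significance level.
#' @param n_comparisons Number of comparisons (>= 1).
#' @return The per-comparison p-value threshold.
#' @export
sidak_cutoff <- function(alpha, n_comparisons) {
  stopifnot(alpha >= 0, alpha < 1)
  if (any(n_comparisons < 1)) stop("n_comparisons must be >= 1")
  1 - (1 - alpha)^(1 / n_comparisons)
}

#' Edge filter configuration
#'
#' @param alpha Family-wise significance for the Sidak stage.
#' @param percentile Percentile (0-100) of surviving absolute rho that
#'   edges must reach.
#' @param rho_min Final absolute correlation threshold (strict).
#' @param ani_collapse ANI percentage at which near-identical MAGs are
#'   collapsed.
#' @return List of class `edge_filter_config`.
#' @export
edge_filter_config <- function(alpha = 0.05, percentile = 90,
                               rho_min = 0.70, ani_collapse = 99) {
  stopifnot(alpha > 0, alpha < 1, percentile >= 0, percentile <= 100,
            rho_min >= 0, rho_min <= 1)
  structure(list(alpha = alpha, percentile = percentile,
                 rho_min = rho_min, ani_collapse = ani_collapse),
            class = "edge_filter_config")
}

#' Filter correlation pairs into network edges
#'
#' Applies the staged filter: (1) keep pairs with raw p below the Sidak
#' cutoff for the number of testable comparisons; (2) keep pairs whose
#' absolute rho reaches the `percentile` quantile of the survivors'
#' absolute rho; (3) keep pairs with absolute rho strictly above
#' `rho_min`; (4) drop prokaryote-prokaryote pairs, retaining only
#' eukaryote-eukaryote and eukaryote-prokaryote interactions. Stage
#' counts are recorded in the `stage_counts` attribute.
#'
#' @param corr A [spearman_all_pairs()] result.
#' @param cfg An [edge_filter_config()].
#' @param domains Named character vector mapping each MAG id to
#'   `"eukaryote"` or `"prokaryote"`.
#' @return Data frame of surviving edges (`mag_i`, `mag_j`, `rho`, `p`)
#'   with attributes `stage_counts` and `rho_percentile_cut`.
#' @export
filter_edges <- function(corr, cfg = edge_filter_config(), domains) {
  stopifnot(inherits(corr, "correlation_result"))
  tested <- corr[!is.na(corr$p), , drop = FALSE]
  n_comp <- nrow(tested)
  if (!n_comp) stop("no testable pairs")
  cut_p <- sidak_cutoff(cfg$alpha, n_comp)
  s1 <- tested[tested$p < cut_p, , drop = FALSE]
  q <- if (nrow(s1)) stats::quantile(abs(s1$rho), cfg$percentile / 100,
                                     names = FALSE) else NA_real_
  s2 <- s1[abs(s1$rho) >= q, , drop = FALSE]
  s3 <- s2[abs(s2$rho) > cfg$rho_min, , drop = FALSE]
  if (!missing(domains) && !is.null(domains)) {
    missing_dom <- setdiff(unique(c(s3$mag_i, s3$mag_j)), names(domains))
    if (length(missing_dom))
      stop("MAG(s) without a domain tag: ",
           paste(missing_dom, collapse = ", "))
    prok_prok <- domains[s3$mag_i] == "prokaryote" &
      domains[s3$mag_j] == "prokaryote"
    s4 <- s3[!prok_prok, , drop = FALSE]
  } else s4 <- s3
  rownames(s4) <- NULL
  attr(s4, "stage_counts") <- c(tested = n_comp, sidak = nrow(s1),
                                percentile = nrow(s2),
                                rho_min = nrow(s3), domain = nrow(s4))
  attr(s4, "sidak_cutoff") <- cut_p
  attr(s4, "rho_percentile_cut") <- q
  s4
}

#' Collapse near-identical MAGs into ANI cluster nodes
#'
#' MAG pairs that are both highly similar (ANI at or above
#' `ani_threshold`) and strongly correlated (absolute rho strictly above
#' `rho_min` on an edge of the list) are merged into single cluster
#' nodes (connected components of that relation). Edges internal to a
#' cluster are removed; parallel edges between the resulting nodes keep
#' the member-pair edge of maximum absolute rho.
#'
#' @param edges Edge data frame (`mag_i`, `mag_j`, `rho`, ...).
#' @param ani An [ani_matrix()] (may cover a subset of MAGs; pairs absent
#'   from it are never merged).
#' @param ani_threshold,rho_min Merge thresholds.
#' @return List with `mapping` (named character: MAG id -> node id;
#'   cluster nodes are named after their lexicographically first member),
#'   `members` (list per cluster node) and `edges` (reduced edge frame).
#' @export
collapse_ani_clusters <- function(edges, ani, ani_threshold = 99,
                                  rho_min = 0.70) {
  mags <- unique(c(edges$mag_i, edges$mag_j))
  in_ani <- edges$mag_i %in% rownames(ani) & edges$mag_j %in% rownames(ani)
  ani_vals <- rep(NA_real_, nrow(edges))
  if (any(in_ani))
    ani_vals[in_ani] <- unclass(ani)[cbind(edges$mag_i[in_ani],
                                           edges$mag_j[in_ani])]
  merge_edge <- !is.na(ani_vals) & ani_vals >= ani_threshold &
    abs(edges$rho) > rho_min
  g <- igraph::graph_from_data_frame(
    edges[merge_edge, c("mag_i", "mag_j"), drop = FALSE],
    directed = FALSE, vertices = data.frame(name = mags))
  comp <- igraph::components(g)$membership
  groups <- split(names(comp), comp)
  node_of <- character(0)
  members <- list()
  for (grp in groups) {
    nm <- min(grp)
    node_of[grp] <- nm
    if (length(grp) > 1L) members[[nm]] <- sort(grp)
  }
  u <- node_of[edges$mag_i]
  v <- node_of[edges$mag_j]
  keep <- u != v
  red <- edges[keep, , drop = FALSE]
  red$node_i <- pmin(u[keep], v[keep])
  red$node_j <- pmax(u[keep], v[keep])
  ord <- order(red$node_i, red$node_j, -abs(red$rho))
  red <- red[ord, , drop = FALSE]
  dup <- duplicated(red[, c("node_i", "node_j")])
  red <- red[!dup, , drop = FALSE]
  rownames(red) <- NULL
  list(mapping = node_of, members = members, edges = red)
}

#' Detect communities by modularity optimisation
#'
#' Builds an undirected graph weighted by absolute rho and partitions it
#' with multilevel (Louvain) modularity maximisation. The node order is
#' shuffled deterministically from the seed so repeated runs agree.
#'
#' @param edges Edge data frame; node columns are `node_i`/`node_j` if
#'   present, else `mag_i`/`mag_j`; weights from `|rho|`.
#' @param nodes Optional full node set (isolated nodes become singleton
#'   communities).
#' @param seed Integer seed.
#' @param positive_only If `TRUE`, drop negative-rho edges first.
#' @return List with `membership` (named integer), `modularity` (Q) and
#'   `graph` (the igraph object).
#' @export
detect_communities <- function(edges, nodes = NULL, seed = 1,
                               positive_only = FALSE) {
  ucol <- if ("node_i" %in% names(edges)) "node_i" else "mag_i"
  vcol <- if ("node_j" %in% names(edges)) "node_j" else "mag_j"
  if (positive_only) edges <- edges[edges$rho > 0, , drop = FALSE]
  all_nodes <- unique(c(edges[[ucol]], edges[[vcol]], nodes))
  set.seed(seed)
  all_nodes <- sample(all_nodes)
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges[[ucol]], to = edges[[vcol]],
               weight = abs(edges$rho)),
    directed = FALSE, vertices = data.frame(name = all_nodes))
  if (igraph::ecount(g) == 0) {
    memb <- stats::setNames(seq_along(all_nodes), all_nodes)
    return(list(membership = memb, modularity = 0, graph = g))
  }
  set.seed(seed)
  cl <- igraph::cluster_louvain(g, weights = igraph::E(g)$weight)
  memb <- igraph::membership(cl)
  list(membership = stats::setNames(as.integer(memb), names(memb)),
       modularity = igraph::modularity(cl), graph = g)
}

#' Within- and between-community connectedness
#'
#' Diagonal entries give, per community, the realized fraction of all
#' possible within-community links: the number of edges among members
#' divided by `n_x * (n_x - 1) / 2`. Off-diagonal entries count, under
#' the default `"distinct-nodes"` rule, each MAG of either community the
#' first time it is linked to the other community — the number of
#' distinct members of the union incident to at least one cross-community
#' edge — divided by the size of the larger community. The alternative
#' `"edges"` rule divides the raw cross-edge count by the same
#' denominator.
#'
#' @param edges Edge data frame (`node_i`/`node_j` or `mag_i`/`mag_j`).
#' @param communities Named membership vector covering every node.
#' @param between `"distinct-nodes"` (default) or `"edges"`.
#' @return Symmetric numeric matrix C, one row/column per community.
#' @export
connectedness <- function(edges, communities,
                          between = c("distinct-nodes", "edges")) {
  between <- match.arg(between)
  ucol <- if ("node_i" %in% names(edges)) "node_i" else "mag_i"
  vcol <- if ("node_j" %in% names(edges)) "node_j" else "mag_j"
  u <- as.character(edges[[ucol]]); v <- as.character(edges[[vcol]])
  miss <- setdiff(unique(c(u, v)), names(communities))
  if (length(miss))
    stop("node(s) without a community: ", paste(miss, collapse = ", "))
  comms <- sort(unique(communities))
  k <- length(comms)
  n <- vapply(comms, function(cc) sum(communities == cc), numeric(1))
  C <- matrix(0, k, k, dimnames = list(comms, comms))
  cu <- communities[u]; cv <- communities[v]
  for (a in seq_len(k)) {
    within <- sum(cu == comms[a] & cv == comms[a])
    denom <- n[a] * (n[a] - 1) / 2
    if (denom == 0) {
      warning("singleton community ", comms[a],
              ": within-connectedness set to 0")
      C[a, a] <- 0
    } else C[a, a] <- within / denom
  }
  if (k > 1) for (a in seq_len(k - 1)) for (b in (a + 1):k) {
    cross <- (cu == comms[a] & cv == comms[b]) |
      (cu == comms[b] & cv == comms[a])
    val <- if (between == "distinct-nodes")
      length(unique(c(u[cross], v[cross]))) else sum(cross)
    C[a, b] <- C[b, a] <- val / max(n[a], n[b])
  }
  C
}

#' Community-environment Spearman correlations
#'
#' Correlates each community's summed abundance profile with each
#' environmental variable (pairwise-complete), then applies a Bonferroni
#' adjustment over all comparisons actually made. Pairs with fewer than
#' three complete observations are reported as missing.
#'
#' @param community_abund Community x sample matrix (e.g. summed CPM).
#' @param env Sample x variable data frame or matrix; rows matched to
#'   `community_abund` columns by name.
#' @param alpha Significance level on the adjusted p-value.
#' @return Data frame: `community`, `variable`, `rho`, `p`, `p_adjusted`,
#'   `significant`, `n`.
#' @export
env_correlation <- function(community_abund, env, alpha = 0.01) {
  stopifnot(is.matrix(community_abund))
  env <- as.data.frame(env)
  shared <- intersect(colnames(community_abund), rownames(env))
  if (length(shared) < 3)
    stop("fewer than three samples shared between abundance and ",
         "environment tables")
  ab <- community_abund[, shared, drop = FALSE]
  ev <- env[shared, , drop = FALSE]
  grid <- expand.grid(community = rownames(ab), variable = colnames(ev),
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    x <- ab[grid$community[i], ]
    y <- ev[[grid$variable[i]]]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 3) return(c(NA_real_, NA_real_, sum(ok)))
    ct <- suppressWarnings(stats::cor.test(x[ok], y[ok],
                                           method = "spearman",
                                           exact = FALSE))
    c(unname(ct$estimate), ct$p.value, sum(ok))
  })
  res <- do.call(rbind, res)
  grid$rho <- res[, 1]; grid$p <- res[, 2]; grid$n <- res[, 3]
  n_tests <- sum(!is.na(grid$p))
  grid$p_adjusted <- pmin(1, grid$p * n_tests)
  grid$significant <- !is.na(grid$p_adjusted) & grid$p_adjusted < alpha
  grid
}

#' Build the full co-occurrence network from a CPM matrix
#'
#' Runs [spearman_all_pairs()], [filter_edges()], optionally
#' [collapse_ani_clusters()], then [detect_communities()] and
#' [connectedness()].
#'
#' @param cpm_matrix MAG x sample abundance matrix.
#' @param domains Named domain vector per MAG.
#' @param ani Optional [ani_matrix()] for the collapse step.
#' @param cfg An [edge_filter_config()].
#' @param seed Integer seed for community detection.
#' @param positive_only Drop negative-rho edges before community
#'   detection.
#' @return List with `correlations`, `edges`, `collapse`, `communities`,
#'   `connectedness`.
#' @export
build_network <- function(cpm_matrix, domains, ani = NULL,
                          cfg = edge_filter_config(), seed = 1,
                          positive_only = FALSE) {
  corr <- spearman_all_pairs(cpm_matrix)
  edges <- filter_edges(corr, cfg, domains)
  collapse <- NULL
  if (!is.null(ani) && nrow(edges)) {
    collapse <- collapse_ani_clusters(edges, ani, cfg$ani_collapse,
                                      cfg$rho_min)
    edges_for_graph <- collapse$edges
  } else edges_for_graph <- edges
  comm <- detect_communities(edges_for_graph, seed = seed,
                             positive_only = positive_only)
  C <- if (length(comm$membership))
    connectedness(edges_for_graph, comm$membership) else
      matrix(0, 0, 0)
  list(correlations = corr, edges = edges, collapse = collapse,
       communities = comm, connectedness = C)
}
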