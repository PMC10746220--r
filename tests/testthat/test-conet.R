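test_that("Spearman pairs respect rank invariance and the rank-formula oracle", {
  set.seed(2)
  x <- runif(12)
  mat <- rbind(a = x, b = exp(3 * x), c = -x,
               d = runif(12))
  res <- spearman_all_pairs(mat)
  get <- function(i, j)
    res$rho[(res$mag_i == i & res$mag_j == j) |
              (res$mag_i == j & res$mag_j == i)]
  expect_equal(get("a", "b"), 1)     # monotone transform
  expect_equal(get("a", "c"), -1)    # reversed ranks
  expect_equal(get("a", "d"), oracle_spearman(mat["a", ], mat["d", ]))

  # small 5-sample pair against the explicit rank computation
  m5 <- rbind(u = c(3, 1, 4, 1, 5), v = c(9, 2, 6, 5, 3))
  r5 <- spearman_all_pairs(m5)
  expect_equal(r5$rho, oracle_spearman(m5["u", ], m5["v", ]))

  expect_error(spearman_all_pairs(mat[1, , drop = FALSE]), "two MAGs")

  # pairs sharing too few samples are reported missing
  mat_na <- rbind(a = c(1, 2, NA, NA, NA), b = c(2, 1, NA, NA, NA))
  expect_true(is.na(spearman_all_pairs(mat_na)$rho))
})

test_that("the Sidak cutoff matches its closed form over a grid", {
  expect_equal(sidak_cutoff(0.05, 1), 0.05)
  expect_equal(sidak_cutoff(0, 10), 0)
  expect_equal(sidak_cutoff(0.05, 10), 1 - 0.95^0.1)
  for (alpha in c(0.01, 0.05, 0.1))
    for (n in c(1, 2, 10, 100, 4950, 1e6))
      expect_equal(sidak_cutoff(alpha, n), 1 - (1 - alpha)^(1 / n),
                   tolerance = 1e-15)
  expect_error(sidak_cutoff(0.05, 0), ">= 1")
})

test_that("edge filtering applies its stages in order", {
  corr <- data.frame(
    mag_i = c("e1", "e1", "p1", "e2"),
    mag_j = c("e2", "p1", "p2", "p2"),
    rho = c(0.99, 0.95, 0.92, 0.30),
    p = c(0.5, 1e-8, 1e-8, 1e-8),
    n_shared = 10)
  class(corr) <- c("correlation_result", "data.frame")
  domains <- c(e1 = "eukaryote", e2 = "eukaryote",
               p1 = "prokaryote", p2 = "prokaryote")
  cfg <- edge_filter_config(percentile = 0)
  out <- filter_edges(corr, cfg, domains)
  # high-rho pair dies at the Sidak stage; prok-prok dies at domain stage;
  # low-rho pair dies at the 0.70 stage
  expect_equal(nrow(out), 1)
  expect_equal(out$mag_i, "e1")
  expect_equal(out$mag_j, "p1")
  counts <- attr(out, "stage_counts")
  expect_true(all(diff(counts) <= 0))  # cascade never adds edges
  expect_equal(unname(counts["tested"]), 4)
})

test_that("a planted correlated block survives the filter exactly", {
  set.seed(8)
  n_s <- 40
  latent <- rnorm(n_s)
  block <- t(sapply(1:5, function(i) latent + rnorm(n_s, sd = 0.05)))
  noise <- matrix(rnorm(15 * n_s), 15)
  mat <- rbind(block, noise)
  rownames(mat) <- c(paste0("blk", 1:5), paste0("bg", 1:15))
  corr <- spearman_all_pairs(mat)
  domains <- setNames(rep("eukaryote", 20), rownames(mat))
  out <- filter_edges(corr, edge_filter_config(percentile = 0), domains)
  got <- sort(paste(out$mag_i, out$mag_j))
  want <- apply(combn(paste0("blk", 1:5), 2), 2, paste, collapse = " ")
  expect_equal(got, sort(want))
})

test_that("near-identical strongly-correlated MAGs collapse into cluster nodes", {
  ids <- c("A", "B", "C", "D")
  ani <- matrix(95, 4, 4, dimnames = list(ids, ids))
  diag(ani) <- 100
  ani["A", "B"] <- ani["B", "A"] <- 99.5
  ani["B", "C"] <- ani["C", "B"] <- 99.3
  edges <- data.frame(mag_i = c("A", "B", "A", "C"),
                      mag_j = c("B", "C", "D", "D"),
                      rho = c(0.9, 0.85, 0.8, 0.75))
  col <- collapse_ani_clusters(edges, ani_matrix(ani))
  # chain A~B, B~C all qualify: one 3-member cluster named after A
  expect_equal(sort(col$members$A), c("A", "B", "C"))
  expect_equal(unname(col$mapping[c("A", "B", "C", "D")]),
               c("A", "A", "A", "D"))
  # intra-cluster edges removed; parallel A-D/C-D edges keep max |rho|
  expect_equal(nrow(col$edges), 1)
  expect_equal(col$edges$rho, 0.8)

  # high ANI with weak correlation does not merge
  edges2 <- data.frame(mag_i = "A", mag_j = "B", rho = 0.3)
  col2 <- collapse_ani_clusters(edges2, ani_matrix(ani))
  expect_length(col2$members, 0)
  expect_equal(nrow(col2$edges), 1)
})

test_that("community detection resolves cliques, singletons and complete graphs", {
  # two 5-cliques joined by a single bridge
  cl <- function(prefix) t(combn(paste0(prefix, 1:5), 2))
  ed <- rbind(cl("a"), cl("b"), c("a1", "b1"))
  edges <- data.frame(mag_i = ed[, 1], mag_j = ed[, 2], rho = 0.9)
  com <- detect_communities(edges, seed = 1)
  expect_equal(length(unique(com$membership)), 2)
  expect_length(unique(com$membership[paste0("a", 1:5)]), 1)
  expect_length(unique(com$membership[paste0("b", 1:5)]), 1)
  expect_gt(com$modularity, 0.3)

  lonely <- detect_communities(edges[0, ], nodes = c("x", "y", "z"))
  expect_equal(length(unique(lonely$membership)), 3)
  expect_equal(lonely$modularity, 0)

  full <- t(combn(paste0("n", 1:6), 2))
  com_full <- detect_communities(
    data.frame(mag_i = full[, 1], mag_j = full[, 2], rho = 0.8),
    seed = 1)
  expect_equal(length(unique(com_full$membership)), 1)

  # determinism under the seed
  com2 <- detect_communities(edges, seed = 1)
  expect_identical(com$membership[order(names(com$membership))],
                   com2$membership[order(names(com2$membership))])
})

test_that("connectedness matches hand counts on small communities", {
  tri <- t(combn(c("x1", "x2", "x3"), 2))
  edges <- data.frame(mag_i = tri[, 1], mag_j = tri[, 2], rho = 0.9)
  comm <- setNames(rep(1, 3), c("x1", "x2", "x3"))
  expect_equal(unname(connectedness(edges, comm)[1, 1]), 1)

  edges4 <- data.frame(mag_i = c("y1", "y2"), mag_j = c("y2", "y3"),
                       rho = 0.8)
  comm4 <- setNames(rep(1, 4), paste0("y", 1:4))
  expect_equal(unname(connectedness(edges4, comm4)[1, 1]), 2 / 6)

  # x (3 nodes), y (5 nodes), cross edges touching 2 of x and 1 of y
  edges_xy <- data.frame(mag_i = c("x1", "x2"), mag_j = c("y1", "y1"),
                         rho = 0.9)
  comm_xy <- setNames(c(rep(1, 3), rep(2, 5)),
                      c(paste0("x", 1:3), paste0("y", 1:5)))
  C <- suppressWarnings(connectedness(edges_xy, comm_xy))
  expect_equal(C["1", "2"], 3 / 5)
  expect_equal(C["2", "1"], 3 / 5)  # symmetric
  # raw edge-count alternative
  C2 <- connectedness(edges_xy, comm_xy, between = "edges")
  expect_equal(C2["1", "2"], 2 / 5)

  single <- setNames(c(1, 2, 2), c("a", "b", "c"))
  expect_warning(
    Cs <- connectedness(data.frame(mag_i = "b", mag_j = "c", rho = 0.9),
                        single), "singleton")
  expect_equal(Cs["1", "1"], 0)
})

test_that("connectedness agrees with the exhaustive oracle and ignores labels", {
  set.seed(12)
  for (i in 1:40) {
    n <- sample(4:8, 1)
    edges <- random_edge_frame(n)
    if (!nrow(edges)) next
    comm <- setNames(sample(1:3, n, replace = TRUE), paste0("v", 1:n))
    C <- suppressWarnings(connectedness(edges, comm))
    O <- suppressWarnings(oracle_connectedness(edges, comm))
    expect_equal(C, O)
    expect_true(all(diag(C) >= 0 & diag(C) <= 1))
    # relabeling nodes leaves the matrix unchanged
    relab <- setNames(paste0("w", seq_len(n)), paste0("v", seq_len(n)))
    edges2 <- data.frame(mag_i = relab[edges$mag_i],
                         mag_j = relab[edges$mag_j], rho = edges$rho)
    comm2 <- setNames(comm, relab[names(comm)])
    expect_equal(unname(suppressWarnings(connectedness(edges2, comm2))),
                 unname(C))
  }
})

test_that("environment correlations are Bonferroni-adjusted", {
  set.seed(3)
  samples <- paste0("s", 1:20)
  ab <- matrix(runif(40), 2, dimnames = list(c("c1", "c2"), samples))
  env <- data.frame(temp = ab["c1", ] * 2 + 1,
                    depth = runif(20), row.names = samples)
  out <- env_correlation(ab, env)
  expect_equal(out$rho[out$community == "c1" & out$variable == "temp"], 1)
  n_tests <- sum(!is.na(out$p))
  expect_equal(out$p_adjusted, pmin(1, out$p * n_tests))
  # a single comparison keeps its raw p
  out1 <- env_correlation(ab[1, , drop = FALSE],
                          env[, "depth", drop = FALSE])
  expect_equal(out1$p_adjusted, out1$p)
  # 10 comparisons at raw p = 0.004 would adjust to 0.04: not significant
  expect_false(min(1, 0.004 * 10) < 0.01)
  expect_error(env_correlation(ab[, 1:2], env[1:2, ]), "three")
})
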