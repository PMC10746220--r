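# shared helpers: tiny oracles kept independent of package internals

# brute-force Spearman rho via the rank formula on midranks
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# exhaustive connectedness on an explicit edge list (independent count)
oracle_connectedness <- function(edges, communities,
                                 between = "distinct-nodes") {
  comms <- sort(unique(communities))
  k <- length(comms)
  C <- matrix(0, k, k, dimnames = list(comms, comms))
  for (a in seq_len(k)) for (b in seq_len(k)) {
    mem_a <- names(communities)[communities == comms[a]]
    mem_b <- names(communities)[communities == comms[b]]
    if (a == b) {
      cnt <- 0
      if (length(mem_a) >= 2) {
        prs <- utils::combn(sort(mem_a), 2)
        for (i in seq_len(ncol(prs)))
          cnt <- cnt + any((edges$mag_i == prs[1, i] &
                              edges$mag_j == prs[2, i]) |
                             (edges$mag_i == prs[2, i] &
                                edges$mag_j == prs[1, i]))
      }
      denom <- length(mem_a) * (length(mem_a) - 1) / 2
      C[a, a] <- if (denom > 0) cnt / denom else 0
    } else {
      touched <- character(0)
      cnt <- 0
      for (i in seq_len(nrow(edges))) {
        u <- edges$mag_i[i]; v <- edges$mag_j[i]
        cross <- (u %in% mem_a && v %in% mem_b) ||
          (u %in% mem_b && v %in% mem_a)
        if (cross) {
          cnt <- cnt + 1
          touched <- union(touched, c(u, v))
        }
      }
      val <- if (between == "distinct-nodes") length(touched) else cnt
      C[a, b] <- val / max(length(mem_a), length(mem_b))
    }
  }
  C
}

# random undirected graph as an edge data frame
random_edge_frame <- function(n_nodes, p_edge = 0.4) {
  nodes <- paste0("v", seq_len(n_nodes))
  prs <- utils::combn(nodes, 2)
  keep <- stats::runif(ncol(prs)) < p_edge
  data.frame(mag_i = prs[1, keep], mag_j = prs[2, keep],
             rho = stats::runif(sum(keep), 0.5, 1),
             stringsAsFactors = FALSE)
}

toy_tree <- function() ape::read.tree(text = "((A:1,B:2):1,C:4);")
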