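test_that("eukaryotic screening applies strict length and fraction thresholds", {
  pass <- screen_eukaryotic_bin(bin_record("b1", 3e6, 2.85e6))
  expect_true(pass$pass)
  expect_length(pass$reasons, 0)

  short <- screen_eukaryotic_bin(bin_record("b2", 2.4e6, 2.376e6))
  expect_false(short$pass)
  expect_match(short$reasons, "length", all = FALSE)

  boundary <- screen_eukaryotic_bin(bin_record("b3", 3e6, 2.7e6))
  expect_false(boundary$pass)  # fraction exactly 0.90 fails strictly
  at_len <- screen_eukaryotic_bin(bin_record("b4", 2.5e6, 2.5e6))
  expect_false(at_len$pass)    # length exactly 2.5 Mbp fails strictly

  expect_error(screen_eukaryotic_bin(bin_record("b5", 0, 0)), "zero")
})

test_that("screening is monotone in eukaryotic length", {
  set.seed(1)
  for (i in 1:25) {
    total <- runif(1, 2e6, 4e6)
    euks <- sort(runif(2, 0, total))
    lo <- screen_eukaryotic_bin(bin_record("x", total, euks[1]))$pass
    hi <- screen_eukaryotic_bin(bin_record("x", total, euks[2]))$pass
    expect_false(lo && !hi)
  }
})

test_that("completeness tiers follow the strict thresholds", {
  expect_equal(tier_eukaryotic_completeness(87), "EUK_HIGH")
  expect_equal(tier_eukaryotic_completeness(15), "EUK_REPORTED")
  expect_equal(tier_eukaryotic_completeness(10), "EUK_CANDIDATE")
  expect_equal(tier_eukaryotic_completeness(30), "EUK_REPORTED")
  expect_error(tier_eukaryotic_completeness(101), "0, 100")

  expect_equal(tier_prokaryotic_quality(95, 2), "PROK_HQ")
  expect_equal(tier_prokaryotic_quality(80, 8), "PROK_MQ")
  expect_equal(tier_prokaryotic_quality(80, 12), "DISCARD")
  # exactly 90% completeness with low contamination falls to MQ
  expect_equal(tier_prokaryotic_quality(90, 2), "PROK_MQ")
  expect_equal(tier_prokaryotic_quality(74.9, 2), "DISCARD")
})

test_that("dereplication single-links at the ANI threshold and scores representatives", {
  ids <- c("A", "B", "C")
  ani <- matrix(100, 3, 3, dimnames = list(ids, ids))
  ani["A", "B"] <- ani["B", "A"] <- 99.5
  ani["B", "C"] <- ani["C", "B"] <- 99.2
  ani["A", "C"] <- ani["C", "A"] <- 98.0
  q <- data.frame(bin_id = ids, completeness = c(96, 99, 50),
                  contamination = c(1, 4, 1), n50 = c(1e5, 1e5, 1e4))
  d <- dereplicate(q, ani_matrix(ani))
  expect_length(d$clusters, 1)
  expect_setequal(d$clusters[[1]], ids)

  # below threshold: singletons
  ani2 <- matrix(c(100, 98.9, 98.9, 100), 2,
                 dimnames = list(c("A", "B"), c("A", "B")))
  d2 <- dereplicate(q[1:2, ], ani_matrix(ani2))
  expect_length(d2$clusters, 2)

  # representative by score: S1 = 96-5+2.5 = 93.5 beats S2 = 99-20+2.5
  ani3 <- matrix(c(100, 99.5, 99.5, 100), 2,
                 dimnames = list(c("A", "B"), c("A", "B")))
  d3 <- dereplicate(q[1:2, ], ani_matrix(ani3))
  expect_equal(unname(d3$scores), c(93.5, 81.5))
  expect_equal(d3$representatives, "A")

  expect_error(dereplicate(q, ani_matrix(ani2)), "missing")
})

test_that("dereplication partitions the input and ignores row order", {
  set.seed(7)
  n <- 12
  ids <- sprintf("g%02d", 1:n)
  ani <- matrix(runif(n * n, 95, 100), n, dimnames = list(ids, ids))
  ani <- (ani + t(ani)) / 2
  diag(ani) <- 100
  q <- data.frame(bin_id = ids, completeness = runif(n, 60, 100),
                  contamination = runif(n, 0, 10),
                  n50 = runif(n, 1e4, 1e6))
  d <- dereplicate(q, ani_matrix(ani))
  expect_setequal(unlist(d$clusters), ids)
  expect_equal(sum(lengths(d$clusters)), n)  # partition, no duplicates
  for (k in seq_along(d$clusters))
    expect_true(d$representatives[k] %in% d$clusters[[k]])

  perm <- sample(n)
  d2 <- dereplicate(q[perm, ], ani_matrix(ani))
  expect_equal(d2$clusters, d$clusters)
  expect_equal(d2$representatives, d$representatives)
})

test_that("percent-identity levels match the published bands and deepen monotonically", {
  expect_equal(assign_taxonomic_level(96), "species")
  expect_equal(assign_taxonomic_level(85), "genus")
  expect_equal(assign_taxonomic_level(30), "none")
  # shared boundaries belong to the shallower level
  expect_equal(assign_taxonomic_level(c(95, 80, 65, 50)),
               c("genus", "family", "order", "class"))
  depth <- c(none = 0, class = 1, order = 2, family = 3, genus = 4,
             species = 5)
  lv <- assign_taxonomic_level(seq(0, 100, by = 0.5))
  expect_true(all(diff(depth[lv]) >= 0))
})

test_that("taxonomy-report descent follows the max-percent child above 8%", {
  chain <- taxon_node("root", "root", 100, list(
    taxon_node("phy", "phylum", 60, list(
      taxon_node("gen", "genus", 9, list(
        taxon_node("sp", "species", 3)))))))
  expect_equal(select_taxon_from_report(chain)$name, "gen")
  expect_equal(select_taxon_from_report(chain, rule = "first")$name,
               "phy")

  flat <- taxon_node("root", "root", 100, list(
    taxon_node("a", "phylum", 7), taxon_node("b", "phylum", 8)))
  expect_equal(select_taxon_from_report(flat)$name, "root")

  strain <- taxon_node("root", "root", 100, list(
    taxon_node("s", "strain", 50, list(taxon_node("x", "isolate", 40)))))
  expect_equal(select_taxon_from_report(strain)$name, "s")

  low <- taxon_node("root", "root", 5)
  expect_warning(res <- select_taxon_from_report(low), "root")
  expect_equal(res$name, "root")
})

test_that("screen_bin_table aggregates contig lengths and tiers bins", {
  bins <- data.frame(bin_id = c("b1", "b1", "b2"),
                     contig_id = c("c1", "c2", "c3"))
  domains <- data.frame(contig_id = c("c1", "c2", "c3"),
                        domain = c("eukaryote", "prokaryote", "eukaryote"),
                        length = c(2.9e6, 0.1e6, 2e6))
  quality <- data.frame(bin_id = c("b1", "b2"),
                        busco_completeness = c(45, NA),
                        checkm_completeness = c(NA, 95),
                        checkm_contamination = c(NA, 2))
  out <- screen_bin_table(bins, domains, quality)
  expect_equal(out$total_length, c(3e6, 2e6))
  expect_equal(out$euk_pass, c(TRUE, FALSE))
  expect_equal(out$tier, c("EUK_HIGH", "PROK_HQ"))
})
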