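test_that("reference filter keeps profiles at the 500-KO boundary", {
  mk <- function(n) sprintf("K%05d", seq_len(n))
  profiles <- list(a = mk(499), b = mk(500), c = mk(600))
  out <- filter_references(profiles)
  expect_equal(names(out$kept), c("b", "c"))
  expect_equal(out$removed, "a")
  expect_error(filter_references(list(a = mk(10))), "500")
  out2 <- filter_references(list(a = mk(10), b = mk(20)), min_kos = 15)
  expect_equal(out2$removed, "a")
})

test_that("the g-transform is the documented piecewise map", {
  expect_equal(g_transform(0.9), 0.9)
  expect_equal(g_transform(0.1), -0.4)
  expect_equal(g_transform(0.5), 0)
  expect_equal(g_transform(0), -0.5)
  expect_equal(g_transform(1), 1)
  a <- seq(0, 1, by = 0.01)
  expect_true(all(diff(g_transform(a)) >= 0))        # monotone
  expect_true(all(g_transform(a) >= -0.5 & g_transform(a) <= 1))
  expect_error(g_transform(1.2))
})

test_that("per-KO mode scores are g of the occurrence ratios", {
  profiles <- list(h1 = "K00001", h2 = "K00001", h3 = character(0),
                   h4 = character(0), h5 = character(0),
                   p1 = "K00001", p2 = character(0),
                   m1 = "K00001", m2 = "K00001")
  labels <- c(rep("heterotroph", 5), rep("phototroph", 2),
              rep("mixotroph", 2))
  tab <- ko_mode_scores(profiles, labels, kos = "K00001")
  expect_equal(tab$a_het, 0.4)
  expect_equal(tab$h, -(0.5 - 0.4))
  expect_equal(tab$a_photo, 0.5)
  expect_equal(tab$p, 0)
  expect_equal(tab$a_mixo, 1)
  expect_equal(tab$m, 1)
  expect_error(ko_mode_scores(profiles[1:5], labels[1:5]),
               "zero references")
})

test_that("an absent KO rare among heterotroph references scores +0.4", {
  # 10 heterotroph references, the KO present in exactly one (a = 0.1)
  profiles <- c(
    setNames(c(list("K00042"), rep(list(character(0)), 9)),
             paste0("h", 1:10)),
    list(p1 = "K00042", p2 = character(0), m1 = "K00042",
         m2 = character(0)))
  labels <- c(rep("heterotroph", 10), "phototroph", "phototroph",
              "mixotroph", "mixotroph")
  tab <- ko_mode_scores(profiles, labels, kos = "K00042")
  expect_equal(tab$h, -0.4)
  s <- score_entity(character(0), tab)   # KO absent from the entity
  expect_equal(s$H, 0.4)
})

test_that("entity scores are antisymmetric under presence complement", {
  set.seed(9)
  panel <- make_trophic_panel(n_refs_per_mode = 10, n_kos = 50,
                              n_informative = 12, seed = 9)
  tab <- ko_mode_scores(panel$profiles, panel$labels)
  kos <- tab$ko
  present <- sample(kos, 20)
  s1 <- score_entity(present, tab)
  s2 <- score_entity(setdiff(kos, present), tab)
  expect_equal(s1$H, -s2$H)
  expect_equal(s1$P, -s2$P)
  expect_equal(s1$M, -s2$M)
  # all-present entity sums the raw scores
  expect_equal(score_entity(kos, tab)$H, sum(tab$h))
  expect_error(score_entity("K00001", tab[0, ]), "empty")
})

test_that("the heterotrophy index follows its two branches", {
  expect_equal(h_index(120, 20, 0), 100)
  expect_equal(h_index(100, 0, 200), 0.5)       # damped branch, /M
  expect_equal(h_index(50, 50, 500), 0)          # H = P gives 0
  expect_equal(h_index(20, 120, 0), -100)        # sign follows H - P
  # |index| non-increasing in M inside the damped branch
  v <- h_index(100, 0, c(160, 200, 400))
  expect_true(all(diff(abs(v)) <= 0))
  # branch boundary: margin exactly reached triggers damping
  expect_equal(h_index(100, 0, 150), 100 / 150)
  # quadratic reading preserved behind the flag
  expect_equal(h_index(30, 10, 0, form = "quadratic"), 400)
  expect_equal(h_index(10, 30, 0, form = "quadratic"), -400)
})

test_that("index bands are descriptive only", {
  expect_equal(classify_with_index(c(-200, 0, 200)),
               c("phototroph-like", "intermediate", "heterotroph-like"))
})

test_that("feature selection finds separating KOs and skips noise", {
  panel <- make_trophic_panel(n_refs_per_mode = 60, n_kos = 250,
                              n_informative = 30, occ_in_mode = 1,
                              occ_out_mode = 0, seed = 7)
  # add a constant all-present KO and a coin-flip KO
  x <- cbind(panel$matrix, K09998 = 1L,
             K09999 = rbinom(nrow(panel$matrix), 1, 0.5))
  sel <- vita_select(x, panel$labels, n_trees = 300, seed = 7)
  informative <- panel$info$ko[panel$info$informative]
  expect_true(all(informative %in% sel$selected))
  expect_false("K09998" %in% sel$selected)  # zero-variance feature
  expect_true(all(sel$p_value >= 0 & sel$p_value <= 1))
  expect_true(all(sel$selected %in% colnames(x)))
  # determinism under the seed
  sel2 <- vita_select(x, panel$labels, n_trees = 300, seed = 7)
  expect_identical(sel$importance, sel2$importance)
  expect_identical(sel$selected, sel2$selected)
  expect_error(vita_select(x, rep("heterotroph", nrow(x))), "two classes")
})

test_that("uninformative KOs are rarely selected across seeds", {
  hits <- 0L
  for (s in 1:10) {
    panel <- make_trophic_panel(n_refs_per_mode = 40, n_kos = 120,
                                n_informative = 15, seed = 100 + s)
    sel <- vita_select(panel$matrix, panel$labels, n_trees = 200,
                      seed = s)
    noise <- panel$info$ko[!panel$info$informative]
    # fraction of pure-noise KOs passing selection stays near alpha
    hits <- hits + (mean(noise %in% sel$selected) > 0.15)
  }
  expect_lte(hits, 1L)
})

test_that("the forest memorises its training set and collapses under label permutation", {
  panel <- make_trophic_panel(n_refs_per_mode = 60, n_kos = 200,
                              n_informative = 45, seed = 11)
  fit <- train_trophic_rf(panel$matrix, panel$labels, seed = 11)
  expect_true(all(c("model", "accuracy") %in% names(fit)))
  # training set duplicated as test set: perfect recall
  pred <- predict(fit, lapply(rownames(panel$matrix), function(id)
    colnames(panel$matrix)[panel$matrix[id, ] == 1]) |>
      setNames(rownames(panel$matrix)))
  train_ids <- setdiff(rownames(panel$matrix), fit$test_ids)
  expect_equal(mean(pred[train_ids] ==
                      panel$labels[train_ids]), 1.0)
  # permuted labels: held-out accuracy near chance for 3 classes
  set.seed(42)
  perm <- sample(panel$labels)
  names(perm) <- names(panel$labels)
  fitp <- train_trophic_rf(panel$matrix, perm, seed = 11)
  expect_lt(abs(fitp$accuracy - 1 / 3), 0.15)
  # a singleton class is swallowed whole by the test split
  xs <- panel$matrix[1:7, ]
  expect_error(train_trophic_rf(
    xs, c(rep("heterotroph", 3), rep("phototroph", 3), "mixotroph"),
    seed = 1), "absent")
})

test_that("the full trophic pipeline is reproducible under a fixed seed", {
  panel <- make_trophic_panel(n_refs_per_mode = 30, n_kos = 150,
                              n_informative = 30, seed = 4)
  run <- function() trophic_pipeline(panel$profiles, panel$labels,
                                     panel$profiles[1:6], min_kos = 10,
                                     n_trees = 150, seed = 4)
  r1 <- run(); r2 <- run()
  expect_identical(r1$selection$selected, r2$selection$selected)
  expect_identical(r1$scores, r2$scores)
  expect_true(all(c("H", "P", "M", "H_ind", "rf_class", "band") %in%
                    names(r1$scores)))
})
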