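#' Filter reference profiles by KO richness
#'
#' Reference transcriptomes with fewer than `min_kos` present KEGG
#' Orthologs carry too little signal to anchor occurrence ratios and are
#' removed; profiles with exactly `min_kos` are retained.
#'
#' @param profiles Named list of KO identifier vectors.
#' @param min_kos Minimum number of present KOs (inclusive).
#' @return List with `kept` (filtered profiles) and `removed` (ids).
#' @export
filter_references <- function(profiles, min_kos = 500) {
  stopifnot(is.list(profiles), !is.null(names(profiles)))
  n <- lengths(profiles)
  keep <- n >= min_kos
  if (!any(keep))
    stop("no reference profile has at least ", min_kos, " present KOs")
  list(kept = profiles[keep], removed = names(profiles)[!keep])
}

#' Convert KO profiles to a presence/absence matrix
#'
#' @param profiles Named list of KO identifier vectors.
#' @param kos Optional fixed KO universe (column order); defaults to the
#'   sorted union of all present KOs.
#' @return Integer 0/1 matrix, entities in rows, KOs in columns.
#' @export
profiles_to_matrix <- function(profiles, kos = NULL) {
  if (is.null(kos)) kos <- sort(unique(unlist(profiles, use.names = FALSE)))
  mat <- matrix(0L, length(profiles), length(kos),
                dimnames = list(names(profiles), kos))
  for (i in seq_along(profiles)) {
    hit <- intersect(profiles[[i]], kos)
    mat[i, hit] <- 1L
  }
  mat
}

# internal: stratified two-way split of indices by label
stratified_halves <- function(labels) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    half <- ceiling(length(idx) / 2)
    fold[idx[seq_len(half)]] <- 1L
    fold[idx[-seq_len(half)]] <- 2L
  }
  fold
}

#' Hold-out permutation-importance feature selection
#'
#' Selects KOs predictive of the class labels by cross-validated
#' permutation importance: the data are split into two stratified halves,
#' a random forest grown on each half scores permutation importance on the
#' other, and the two importance vectors are averaged. Because unimportant
#' features scatter symmetrically around zero under this scheme, a null
#' distribution is formed by mirroring the non-positive importances around
#' zero; each feature's empirical p-value is its exceedance probability
#' under that null, and features with `p < p_threshold` are selected.
#'
#' @param x Presence/absence matrix (entities x KOs) with column names.
#' @param labels Factor or character vector of class labels, one per row.
#' @param p_threshold Selection threshold on the empirical p-value
#'   (strict).
#' @param n_trees Trees per forest.
#' @param seed Integer seed; the whole procedure is deterministic given
#'   it.
#' @return A list of class `feature_selection` with `importance`,
#'   `p_value` (both named by KO), `selected` (character vector) and
#'   `n_selected`.
#' @export
vita_select <- function(x, labels, p_threshold = 0.05, n_trees = 500,
                        seed = 1) {
  stopifnot(is.matrix(x), !is.null(colnames(x)),
            nrow(x) == length(labels))
  labels <- factor(labels)
  if (nlevels(labels) < 2L)
    stop("feature selection needs at least two classes")
  set.seed(seed)
  fold <- stratified_halves(labels)
  dat <- as.data.frame(x)
  dat$.class <- labels
  imp <- matrix(0, ncol(x), 2, dimnames = list(colnames(x), NULL))
  for (k in 1:2) {
    w <- as.numeric(fold == k)  # grow on fold k, score on the other
    fit <- ranger::ranger(
      dependent.variable.name = ".class", data = dat,
      num.trees = n_trees, importance = "permutation",
      case.weights = w, holdout = TRUE, replace = FALSE,
      sample.fraction = mean(w), seed = seed + k, num.threads = 1)
    imp[, k] <- fit$variable.importance[colnames(x)]
  }
  importance <- rowMeans(imp)
  nonpos <- importance[importance <= 0]
  null <- c(nonpos, -nonpos[nonpos < 0])
  if (!length(null)) null <- 0
  p <- vapply(importance, function(v) (1 + sum(null >= v)) /
                (1 + length(null)), numeric(1))
  selected <- names(importance)[p < p_threshold]
  structure(list(importance = importance, p_value = p,
                 selected = selected, n_selected = length(selected)),
            class = "feature_selection")
}

#' Train a trophic-mode random forest
#'
#' Grows a classification forest on a stratified 75/25 train/test split of
#' the labelled presence/absence matrix (restricted beforehand to the
#' selected KOs) and reports held-out accuracy. A coarse out-of-bag grid
#' over the number of candidate features per split stands in for a full
#' hyperparameter search.
#'
#' @param x Presence/absence matrix restricted to selected KOs.
#' @param labels Class labels, one per row.
#' @param split_fraction Fraction of entities held out for testing.
#' @param n_trees Trees in the forest.
#' @param seed Integer seed.
#' @param tune If `TRUE`, pick `mtry` from a small grid by out-of-bag
#'   error; otherwise use the square-root default.
#' @return A list of class `trophic_rf`: `model` (ranger fit on the
#'   training split), `accuracy` (held-out), `test_ids`, `kos`
#'   (feature universe), `mtry`.
#' @export
train_trophic_rf <- function(x, labels, split_fraction = 0.25,
                             n_trees = 500, seed = 1, tune = FALSE) {
  stopifnot(is.matrix(x), !is.null(colnames(x)),
            nrow(x) == length(labels), split_fraction > 0,
            split_fraction < 1)
  labels <- factor(labels)
  set.seed(seed)
  test <- unlist(lapply(levels(labels), function(cl) {
    idx <- which(labels == cl)
    idx[sample.int(length(idx),
                   max(1L, floor(split_fraction * length(idx))))]
  }))
  train <- setdiff(seq_len(nrow(x)), test)
  if (!all(levels(labels) %in% unique(labels[train])))
    stop("a class is absent from the training split")
  dat <- as.data.frame(x)
  dat$.class <- labels
  p <- ncol(x)
  mtry_grid <- if (tune)
    unique(pmax(1L, c(floor(sqrt(p) / 2), floor(sqrt(p)),
                      2L * floor(sqrt(p))))) else
    max(1L, floor(sqrt(p)))
  fits <- lapply(mtry_grid, function(m)
    ranger::ranger(dependent.variable.name = ".class",
                   data = dat[train, , drop = FALSE],
                   num.trees = n_trees, mtry = m, seed = seed,
                   num.threads = 1))
  oob <- vapply(fits, `[[`, numeric(1), "prediction.error")
  best <- which.min(oob)
  model <- fits[[best]]
  pred <- stats::predict(model, dat[test, , drop = FALSE],
                         num.threads = 1)$predictions
  acc <- mean(pred == labels[test])
  structure(list(model = model, accuracy = acc,
                 test_ids = rownames(x)[test], kos = colnames(x),
                 mtry = mtry_grid[best], oob_error = oob[best],
                 classes = levels(labels)),
            class = "trophic_rf")
}

#' Predict trophic mode for KO profiles
#'
#' @param object A [train_trophic_rf()] fit.
#' @param profiles Named list of KO identifier vectors (KOs outside the
#'   model's feature universe are ignored; missing ones count as absent).
#' @param ... Unused.
#' @return Named character vector of predicted classes.
#' @export
predict.trophic_rf <- function(object, profiles, ...) {
  x <- profiles_to_matrix(profiles, kos = object$kos)
  pred <- stats::predict(object$model, as.data.frame(x),
                         num.threads = 1)$predictions
  stats::setNames(as.character(pred), names(profiles))
}

#' The occurrence-ratio transform g
#'
#' Maps a KO's within-mode occurrence ratio `a = K / n` to a score:
#' `g(a) = a` when `a > 0.5`, otherwise `-(0.5 - a)`. A KO present in
#' fewer than half the references of a mode is thus scored negatively
#' (characteristically absent) without valuing absence over presence:
#' the range is `[-0.5, 0]` for `a <= 0.5` and `(0.5, 1]` for `a > 0.5`.
#'
#' @param a Occurrence ratio(s) in [0, 1].
#' @return Transformed score(s).
#' @export
g_transform <- function(a) {
  stopifnot(all(a >= 0 & a <= 1))
  ifelse(a > 0.5, a, -(0.5 - a))
}

#' Per-KO trophic-mode scores from labelled references
#'
#' For every KO and each trophic mode, the occurrence ratio
#' `a_mode = K_mode / n_mode` (references of that mode containing the KO
#' over all references of the mode) is computed and passed through
#' [g_transform()], yielding the per-KO scores h (heterotrophy),
#' p (phototrophy) and m (mixotrophy).
#'
#' @param profiles Named list of KO identifier vectors (the references).
#' @param labels Named or positional vector of modes, one of
#'   `"heterotroph"`, `"phototroph"`, `"mixotroph"`, per reference.
#' @param kos KO universe to score (e.g. the vita-selected set); defaults
#'   to all KOs seen in the references.
#' @return Data frame of class `trophic_score_table` with columns `ko`,
#'   `h`, `p`, `m`, `a_het`, `a_photo`, `a_mixo`, `K_het`, `K_photo`,
#'   `K_mixo`, and attributes `n_het`, `n_photo`, `n_mixo`.
#' @export
ko_mode_scores <- function(profiles, labels, kos = NULL) {
  stopifnot(length(profiles) == length(labels))
  modes <- c(het = "heterotroph", photo = "phototroph",
             mixo = "mixotroph")
  bad <- setdiff(unique(labels), modes)
  if (length(bad))
    stop("unknown trophic mode label(s): ", paste(bad, collapse = ", "))
  n_mode <- vapply(modes, function(m) sum(labels == m), numeric(1))
  if (any(n_mode == 0))
    stop("mode(s) with zero references: ",
         paste(modes[n_mode == 0], collapse = ", "))
  mat <- profiles_to_matrix(profiles, kos = kos)
  K <- matrix(0, ncol(mat), length(modes),
              dimnames = list(colnames(mat), names(modes)))
  for (i in seq_along(modes))
    K[, i] <- colSums(mat[labels == modes[i], , drop = FALSE])
  a <- sweep(K, 2, n_mode, "/")
  out <- data.frame(ko = colnames(mat),
                    h = g_transform(a[, "het"]),
                    p = g_transform(a[, "photo"]),
                    m = g_transform(a[, "mixo"]),
                    a_het = a[, "het"], a_photo = a[, "photo"],
                    a_mixo = a[, "mixo"],
                    K_het = K[, "het"], K_photo = K[, "photo"],
                    K_mixo = K[, "mixo"],
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "n_het") <- n_mode[["het"]]
  attr(out, "n_photo") <- n_mode[["photo"]]
  attr(out, "n_mixo") <- n_mode[["mixo"]]
  class(out) <- c("trophic_score_table", "data.frame")
  out
}

#' Composite trophic scores for one entity
#'
#' Sums the per-KO mode scores over the whole scored KO set with a
#' presence sign: a present KO contributes its score as-is, an absent KO
#' contributes the negated score. An absent KO that is also rare among
#' heterotroph references (say `a = 0.1`, so `h_k = -0.4`) therefore
#' contributes `-1 * (-0.4) = +0.4` towards heterotrophy: its absence is
#' evidence in favour of the mode it is characteristically absent from.
#'
#' @param present_kos Character vector of KOs present in the entity.
#' @param table A [ko_mode_scores()] table.
#' @return List with `H`, `P`, `M` (numeric sums).
#' @export
score_entity <- function(present_kos, table) {
  stopifnot(inherits(table, "trophic_score_table"))
  if (!nrow(table)) stop("empty trophic score table")
  s <- ifelse(table$ko %in% present_kos, 1, -1)
  list(H = sum(s * table$h), P = sum(s * table$p), M = sum(s * table$m))
}

#' Composite heterotrophy index
#'
#' Collapses the three mode scores to a single scale running from
#' phototroph-like (negative) to heterotroph-like (positive). The default
#' `"linear"` form reads the index numerator as
#' `sign(H - P) * sqrt((H - P)^2) = H - P`; when the mixotrophy score
#' dominates (`M - max(H, P) >= mixo_margin`, default margin 50) the
#' difference is damped by dividing by M. The `"quadratic"` form
#' substitutes `sign(H - P) * (H - P)^2` as the numerator.
#'
#' @param H,P,M Mode scores from [score_entity()].
#' @param mixo_margin Margin on `M - max(H, P)` that triggers the damped
#'   branch.
#' @param form `"linear"` (default) or `"quadratic"`.
#' @return The index value (vectorised over H, P, M).
#' @export
h_index <- function(H, P, M, mixo_margin = 50,
                    form = c("linear", "quadratic")) {
  form <- match.arg(form)
  base <- if (form == "linear") H - P else sign(H - P) * (H - P)^2
  damped <- M - pmax(H, P) >= mixo_margin
  ifelse(damped, base / M, base)
}

#' Descriptive band for a heterotrophy index value
#'
#' Reporting aid only: maps index values to phototroph-like, intermediate
#' or heterotroph-like bands. It never overrides the random-forest class.
#'
#' @param h_ind Index value(s).
#' @param cutoffs Two ascending numbers bounding the intermediate band.
#' @return Character vector of bands.
#' @export
classify_with_index <- function(h_ind, cutoffs = c(-50, 50)) {
  stopifnot(length(cutoffs) == 2L, cutoffs[1] <= cutoffs[2])
  ifelse(h_ind < cutoffs[1], "phototroph-like",
         ifelse(h_ind > cutoffs[2], "heterotroph-like", "intermediate"))
}

#' End-to-end trophic scoring of entities against a reference panel
#'
#' Convenience wrapper: filters references, selects KOs, fits the forest,
#' builds the score table on the selected KOs, then scores and classifies
#' each query entity.
#'
#' @param ref_profiles,ref_labels Labelled reference KO profiles.
#' @param query_profiles Named list of KO profiles to score.
#' @param min_kos,p_threshold,n_trees,split_fraction,seed See the
#'   component functions.
#' @return List with `selection`, `model`, `score_table` and `scores` (a
#'   data frame: entity, H, P, M, H_ind, rf_class, band).
#' @export
trophic_pipeline <- function(ref_profiles, ref_labels, query_profiles,
                             min_kos = 500, p_threshold = 0.05,
                             n_trees = 500, split_fraction = 0.25,
                             seed = 1) {
  flt <- filter_references(ref_profiles, min_kos)
  labels <- ref_labels[names(flt$kept)]
  x <- profiles_to_matrix(flt$kept)
  sel <- vita_select(x, labels, p_threshold, n_trees, seed)
  if (!sel$n_selected) stop("no KOs selected")
  xs <- x[, sel$selected, drop = FALSE]
  model <- train_trophic_rf(xs, labels, split_fraction, n_trees, seed)
  tab <- ko_mode_scores(flt$kept, labels, kos = sel$selected)
  hpm <- lapply(query_profiles, score_entity, table = tab)
  H <- vapply(hpm, `[[`, numeric(1), "H")
  P <- vapply(hpm, `[[`, numeric(1), "P")
  M <- vapply(hpm, `[[`, numeric(1), "M")
  hi <- h_index(H, P, M)
  scores <- data.frame(entity = names(query_profiles), H = H, P = P,
                       M = M, H_ind = hi,
                       rf_class = predict(model, query_profiles),
                       band = classify_with_index(hi),
                       stringsAsFactors = FALSE, row.names = NULL)
  list(selection = sel, model = model, score_table = tab,
       scores = scores)
}
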