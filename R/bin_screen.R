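#' Construct a genome bin record
#'
#' Bundles the per-bin quantities used by the screening and tiering rules:
#' total assembly length, the summed length of contigs domain-called
#' eukaryotic, and completeness/contamination estimates.
#'
#' @param bin_id Bin identifier.
#' @param total_length Total bin length in bp.
#' @param euk_length Summed length (bp) of contigs called eukaryotic.
#' @param busco_completeness,busco_duplication BUSCO percentages (0-100).
#' @param checkm_completeness,checkm_contamination CheckM percentages.
#' @param n50 Assembly N50 in bp.
#' @param contig_ids Optional contig membership.
#' @return An object of class `bin_record`.
#' @export
bin_record <- function(bin_id, total_length, euk_length = 0,
                       busco_completeness = NA_real_,
                       busco_duplication = NA_real_,
                       checkm_completeness = NA_real_,
                       checkm_contamination = NA_real_,
                       n50 = NA_real_, contig_ids = character()) {
  stopifnot(length(bin_id) == 1L, total_length >= 0,
            euk_length >= 0, euk_length <= total_length)
  pct <- c(busco_completeness, busco_duplication,
           checkm_completeness, checkm_contamination)
  pct <- pct[!is.na(pct)]
  if (length(pct) && (any(pct < 0) || any(pct > 100)))
    stop("percentages must lie in [0, 100] for bin ", bin_id)
  structure(list(bin_id = as.character(bin_id),
                 total_length = total_length, euk_length = euk_length,
                 busco_completeness = busco_completeness,
                 busco_duplication = busco_duplication,
                 checkm_completeness = checkm_completeness,
                 checkm_contamination = checkm_contamination,
                 n50 = n50, contig_ids = contig_ids),
            class = "bin_record")
}

#' Screen a bin as a putative eukaryotic MAG
#'
#' A candidate passes when its total length strictly exceeds
#' `min_length_bp` (default 2.5 Mbp, modelled on the smallest known
#' eukaryotic genome) and its eukaryotic fraction by length strictly
#' exceeds `min_euk_fraction` (default 0.90). Both comparisons are strict;
#' bins exactly at a threshold fail that criterion.
#'
#' @param bin A [bin_record()].
#' @param min_length_bp Minimum total length, exclusive (bp).
#' @param min_euk_fraction Minimum eukaryotic length fraction, exclusive.
#' @return A list with `pass` (logical) and `reasons` (character vector of
#'   violated criteria, empty on pass).
#' @export
screen_eukaryotic_bin <- function(bin, min_length_bp = 2.5e6,
                                  min_euk_fraction = 0.90) {
  stopifnot(inherits(bin, "bin_record"))
  if (bin$total_length == 0) stop("bin ", bin$bin_id, " has zero length")
  reasons <- character()
  if (!(bin$total_length > min_length_bp))
    reasons <- c(reasons, sprintf(
      "total length %d bp not greater than %d bp",
      as.integer(bin$total_length), as.integer(min_length_bp)))
  frac <- bin$euk_length / bin$total_length
  if (!(frac > min_euk_fraction))
    reasons <- c(reasons, sprintf(
      "eukaryotic fraction %.4f not greater than %.2f",
      frac, min_euk_fraction))
  list(pass = length(reasons) == 0L, reasons = reasons,
       euk_fraction = frac)
}

#' Tier a eukaryotic MAG by BUSCO completeness
#'
#' Strictly greater than 30% complete is the highly complete tier used for
#' downstream trophic and network analyses; strictly greater than 10% is
#' reported; anything else remains a candidate.
#'
#' @param busco_completeness BUSCO completeness percentage in [0, 100].
#' @return `"EUK_HIGH"`, `"EUK_REPORTED"` or `"EUK_CANDIDATE"`.
#' @export
tier_eukaryotic_completeness <- function(busco_completeness) {
  if (is.na(busco_completeness) || busco_completeness < 0 ||
      busco_completeness > 100)
    stop("BUSCO completeness must lie in [0, 100]")
  if (busco_completeness > 30) "EUK_HIGH"
  else if (busco_completeness > 10) "EUK_REPORTED"
  else "EUK_CANDIDATE"
}

#' Tier a prokaryotic MAG by CheckM completeness and contamination
#'
#' High quality: completeness > 90% and contamination < 5%. Medium
#' quality: completeness in [75, 90] band (closed at 75) with
#' contamination < 10%. Everything else is discarded. A bin at exactly 90%
#' completeness with low contamination falls to the medium tier.
#'
#' @param completeness,contamination CheckM percentages in [0, 100].
#' @return `"PROK_HQ"`, `"PROK_MQ"` or `"DISCARD"`.
#' @export
tier_prokaryotic_quality <- function(completeness, contamination) {
  if (is.na(completeness) || completeness < 0 || completeness > 100 ||
      is.na(contamination) || contamination < 0 || contamination > 100)
    stop("completeness and contamination must lie in [0, 100]")
  if (completeness > 90 && contamination < 5) "PROK_HQ"
  else if (completeness >= 75 && contamination < 10) "PROK_MQ"
  else "DISCARD"
}

#' Construct and validate an ANI matrix
#'
#' @param mat Square numeric matrix of pairwise average nucleotide
#'   identities in percent, with genome ids as dimnames.
#' @return The validated matrix, class `ani_matrix`.
#' @export
ani_matrix <- function(mat) {
  stopifnot(is.matrix(mat), nrow(mat) == ncol(mat),
            !is.null(rownames(mat)),
            identical(rownames(mat), colnames(mat)))
  if (any(abs(diag(mat) - 100) > 1e-9))
    stop("ANI matrix diagonal must be 100")
  if (any(abs(mat - t(mat)) > 1e-9))
    stop("ANI matrix must be symmetric")
  if (any(mat < 0 | mat > 100)) stop("ANI values must lie in [0, 100]")
  structure(mat, class = c("ani_matrix", class(mat)))
}

#' Representative score for dereplication
#'
#' `S = completeness - 5 * contamination + 0.5 * log10(N50)`, a reduced
#' form of the dRep scoring used to pick one representative genome per
#' ANI cluster. Coefficients are arguments so users can re-weight them.
#'
#' @param completeness,contamination Percentages.
#' @param n50 Assembly N50 (bp); must be positive.
#' @param w_completeness,w_contamination,w_n50 Term weights.
#' @return Numeric score (vectorised).
#' @export
derep_score <- function(completeness, contamination, n50,
                        w_completeness = 1, w_contamination = 5,
                        w_n50 = 0.5) {
  stopifnot(all(n50 > 0))
  w_completeness * completeness - w_contamination * contamination +
    w_n50 * log10(n50)
}

#' Dereplicate genomes by ANI single-linkage clustering
#'
#' Genomes joined by pairwise ANI at or above `ani_threshold` (default
#' 99%) form clusters (connected components, i.e. single linkage). Within
#' each cluster the representative is the member maximising
#' [derep_score()], with ties broken by larger total length then by
#' lexicographic genome id.
#'
#' @param quality Data frame with columns `bin_id`, `completeness`,
#'   `contamination`, `n50` and optionally `total_length`.
#' @param ani An [ani_matrix()] covering every `bin_id`.
#' @param ani_threshold Clustering threshold in percent (inclusive).
#' @return A list with `clusters` (list of member-id vectors, each sorted;
#'   clusters ordered by first member), `representatives` (character
#'   vector, one per cluster), `membership` (named cluster index per
#'   genome) and `scores` (named numeric).
#' @export
dereplicate <- function(quality, ani, ani_threshold = 99) {
  stopifnot(is.data.frame(quality),
            all(c("bin_id", "completeness", "contamination", "n50") %in%
                  names(quality)))
  ids <- as.character(quality$bin_id)
  if (anyDuplicated(ids)) stop("duplicate bin_id in quality table")
  missing <- setdiff(ids, rownames(ani))
  if (length(missing))
    stop("genome(s) missing from ANI matrix: ",
         paste(missing, collapse = ", "))
  a <- unclass(ani)[ids, ids, drop = FALSE]
  adj <- a >= ani_threshold
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership[ids]
  total_length <- if ("total_length" %in% names(quality))
    quality$total_length else rep(0, nrow(quality))
  scores <- derep_score(quality$completeness, quality$contamination,
                        quality$n50)
  names(scores) <- ids
  names(total_length) <- ids
  members <- split(ids, comp)
  members <- lapply(members, sort)
  members <- members[order(vapply(members, `[`, character(1), 1L))]
  reps <- vapply(members, function(m) {
    ord <- order(-scores[m], -total_length[m], m)
    m[ord[1]]
  }, character(1))
  membership <- integer(length(ids))
  names(membership) <- ids
  for (k in seq_along(members)) membership[members[[k]]] <- k
  list(clusters = unname(members), representatives = unname(reps),
       membership = membership, scores = scores)
}

#' Assign a taxonomic level from percent identity
#'
#' Percent-identity bands for best-hit taxonomic level estimation:
#' species (95, 100]; genus (80, 95]; family (65, 80]; order (50, 65];
#' class (30, 50]; no assignment at or below 30. Bands are lower-exclusive
#' so shared boundary values belong to the shallower level.
#'
#' @param percent_identity Numeric vector in [0, 100].
#' @return Character vector of `"species"`, `"genus"`, `"family"`,
#'   `"order"`, `"class"` or `"none"`.
#' @export
assign_taxonomic_level <- function(percent_identity) {
  if (any(is.na(percent_identity)) || any(percent_identity < 0) ||
      any(percent_identity > 100))
    stop("percent identity must lie in [0, 100]")
  cut_points <- c(30, 50, 65, 80, 95)
  levels <- c("none", "class", "order", "family", "genus", "species")
  idx <- findInterval(percent_identity, cut_points, left.open = FALSE) + 1L
  # findInterval with left.open = FALSE puts x == cutpoint into the upper
  # bin; the bands are lower-exclusive, so boundary values step back down.
  at_bound <- percent_identity %in% cut_points
  idx[at_bound] <- idx[at_bound] - 1L
  levels[idx]
}

#' Construct a taxonomy-report node
#'
#' Node of a cumulative-mapping taxonomy report: `percent_mapped` is the
#' percentage of mappings at or below the node, so it is monotone
#' non-increasing from root to leaves.
#'
#' @param name Scientific name.
#' @param rank Rank string (e.g. `"phylum"`, `"strain"`).
#' @param percent_mapped Cumulative mapped percentage.
#' @param children List of child `taxon_node`s.
#' @param taxon_id Optional integer taxon identifier.
#' @return An object of class `taxon_node`.
#' @export
taxon_node <- function(name, rank, percent_mapped, children = list(),
                       taxon_id = NA_integer_) {
  stopifnot(percent_mapped >= 0, percent_mapped <= 100)
  for (ch in children) {
    stopifnot(inherits(ch, "taxon_node"))
    if (ch$percent_mapped > percent_mapped + 1e-9)
      stop("child '", ch$name, "' has percent_mapped above parent '",
           name, "'")
  }
  structure(list(name = name, rank = rank,
                 percent_mapped = percent_mapped, children = children,
                 taxon_id = taxon_id),
            class = "taxon_node")
}

#' Select a taxon from a cumulative taxonomy report
#'
#' Descends from the root, at each step to the child with the greatest
#' `percent_mapped` whose value strictly exceeds `min_percent` (default
#' 8%), stopping when no child qualifies or a strain-rank node is reached.
#' The default `"deepest"` rule returns the last node visited; the
#' alternative `"first"` rule returns the first non-root node on that path
#' exceeding the threshold.
#'
#' @param root A [taxon_node()].
#' @param min_percent Mapping percentage a node must exceed.
#' @param rule `"deepest"` (default) or `"first"`.
#' @return The selected `taxon_node`.
#' @export
select_taxon_from_report <- function(root, min_percent = 8,
                                     rule = c("deepest", "first")) {
  rule <- match.arg(rule)
  stopifnot(inherits(root, "taxon_node"))
  if (root$percent_mapped <= min_percent) {
    warning("root mapping ", root$percent_mapped,
            "% does not exceed ", min_percent, "%; returning root")
    return(root)
  }
  node <- root
  first_hit <- NULL
  repeat {
    if (identical(node$rank, "strain")) break
    if (!length(node$children)) break
    pct <- vapply(node$children, `[[`, numeric(1), "percent_mapped")
    best <- which.max(pct)
    if (pct[best] <= min_percent) break
    node <- node$children[[best]]
    if (is.null(first_hit)) first_hit <- node
  }
  if (rule == "first" && !is.null(first_hit)) first_hit else node
}

#' Screen a table of bins and tier the results
#'
#' Convenience wrapper applying [screen_eukaryotic_bin()],
#' [tier_eukaryotic_completeness()] and [tier_prokaryotic_quality()] to a
#' full bin table built from membership, domain-call and quality files.
#'
#' @param bins Data frame (`bin_id`, `contig_id`).
#' @param domains Data frame (`contig_id`, `domain` in
#'   `{eukaryote, prokaryote, unknown}`), with `length` per contig.
#' @param quality Data frame (`bin_id`, `busco_completeness`,
#'   `checkm_completeness`, `checkm_contamination`).
#' @param min_length_bp,min_euk_fraction Screening thresholds.
#' @return Data frame: one row per bin with lengths, eukaryotic fraction,
#'   screen outcome and tier.
#' @export
screen_bin_table <- function(bins, domains, quality,
                             min_length_bp = 2.5e6,
                             min_euk_fraction = 0.90) {
  stopifnot(all(c("bin_id", "contig_id") %in% names(bins)),
            all(c("contig_id", "domain", "length") %in% names(domains)))
  dom <- domains[match(bins$contig_id, domains$contig_id), ]
  if (anyNA(dom$length))
    stop("contig(s) missing from domain table: ",
         paste(utils::head(bins$contig_id[is.na(dom$length)], 3),
               collapse = ", "))
  total <- tapply(dom$length, bins$bin_id, sum)
  euk <- tapply(dom$length * (dom$domain == "eukaryote"), bins$bin_id, sum)
  ids <- names(total)
  out <- data.frame(bin_id = ids, total_length = as.numeric(total),
                    euk_length = as.numeric(euk),
                    stringsAsFactors = FALSE)
  out$euk_fraction <- out$euk_length / out$total_length
  res <- lapply(seq_len(nrow(out)), function(i) {
    b <- bin_record(out$bin_id[i], out$total_length[i], out$euk_length[i])
    screen_eukaryotic_bin(b, min_length_bp, min_euk_fraction)
  })
  out$euk_pass <- vapply(res, `[[`, logical(1), "pass")
  out$reasons <- vapply(res, function(r)
    paste(r$reasons, collapse = "; "), character(1))
  if (!missing(quality) && !is.null(quality)) {
    q <- quality[match(ids, quality$bin_id), ]
    out$tier <- vapply(seq_len(nrow(out)), function(i) {
      if (out$euk_pass[i]) {
        bc <- q$busco_completeness[i]
        if (is.na(bc)) "EUK_CANDIDATE" else
          tier_eukaryotic_completeness(bc)
      } else {
        cc <- q$checkm_completeness[i]
        ct <- q$checkm_contamination[i]
        if (is.na(cc) || is.na(ct)) "DISCARD" else
          tier_prokaryotic_quality(cc, ct)
      }
    }, character(1))
  }
  rownames(out) <- NULL
  out
}
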