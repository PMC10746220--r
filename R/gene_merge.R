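#' Build an exon table
#'
#' @param contig Contig name (recycled).
#' @param start,end 1-based inclusive coordinates.
#' @param strand `"+"` or `"-"` (recycled).
#' @param source `"AB_INITIO"` or `"EVIDENCE"` (recycled).
#' @return Data frame with one row per exon.
#' @export
exon_table <- function(contig, start, end, strand = "+",
                       source = "AB_INITIO") {
  if (any(end < start))
    stop("exon end before start at interval [",
         start[which(end < start)[1]], ", ", end[which(end < start)[1]], "]")
  n <- length(start)
  data.frame(contig = rep_len(contig, n), start = as.integer(start),
             end = as.integer(end), strand = rep_len(strand, n),
             source = rep_len(source, n), stringsAsFactors = FALSE)
}

#' Do two exons correspond?
#'
#' Correspondence between an ab initio exon and a protein-evidence exon is
#' same-strand coordinate overlap of at least `min_overlap` bp (default 1).
#'
#' @param a,b Single-row exon data frames (or lists with `contig`,
#'   `start`, `end`, `strand`).
#' @param min_overlap Minimum overlap in bp.
#' @return Logical.
#' @export
exon_correspondence <- function(a, b, min_overlap = 1L) {
  if (!identical(as.character(a$contig), as.character(b$contig)))
    stop("exons on different contigs: ", a$contig, " vs ", b$contig)
  if (!identical(as.character(a$strand), as.character(b$strand)))
    return(FALSE)
  ov <- min(a$end, b$end) - max(a$start, b$start) + 1L
  ov >= min_overlap
}

#' Build a gene locus from two exon tracks
#'
#' @param locus_id Locus identifier.
#' @param ab_exons Ab initio exon table.
#' @param ev_exons Protein-evidence exon table (may be empty).
#' @return A list of class `gene_locus`.
#' @export
gene_locus <- function(locus_id, ab_exons, ev_exons = exon_table(
  character(), integer(), integer())[0, ]) {
  for (d in list(ab_exons, ev_exons)) {
    if (!nrow(d)) next
    if (length(unique(d$contig)) > 1L || length(unique(d$strand)) > 1L)
      stop("locus ", locus_id, ": exons span multiple contigs or strands")
    d <- d[order(d$start), ]
    if (nrow(d) > 1L && any(d$start[-1] <= d$end[-nrow(d)]))
      stop("locus ", locus_id, ": overlapping exons within one track")
  }
  both <- rbind(ab_exons, ev_exons)
  if (nrow(both) && (length(unique(both$contig)) > 1L ||
                     length(unique(both$strand)) > 1L))
    stop("locus ", locus_id, ": tracks disagree on contig or strand")
  sort_exons <- function(d) {
    d <- d[order(d$start), , drop = FALSE]; rownames(d) <- NULL; d
  }
  structure(list(locus_id = locus_id, ab_exons = sort_exons(ab_exons),
                 ev_exons = sort_exons(ev_exons)),
            class = "gene_locus")
}

# internal: correspondence matrix between two exon tables
correspondence_matrix <- function(a, b, min_overlap = 1L) {
  if (!nrow(a) || !nrow(b))
    return(matrix(FALSE, nrow(a), nrow(b)))
  outer(seq_len(nrow(a)), seq_len(nrow(b)), Vectorize(function(i, j) {
    exon_correspondence(a[i, ], b[j, ], min_overlap)
  }))
}

# internal: coalesce overlapping intervals by union; EVIDENCE provenance
# wins when members disagree
coalesce_exons <- function(d) {
  d <- d[order(d$start, d$end), , drop = FALSE]
  if (nrow(d) < 2L) { rownames(d) <- NULL; return(d) }
  keep <- d[1, , drop = FALSE]
  for (i in 2:nrow(d)) {
    last <- nrow(keep)
    if (d$start[i] <= keep$end[last]) {
      keep$end[last] <- max(keep$end[last], d$end[i])
      if (d$source[i] == "EVIDENCE") keep$source[last] <- "EVIDENCE"
    } else {
      keep <- rbind(keep, d[i, ])
    }
  }
  rownames(keep) <- NULL
  keep
}

#' Merge ab initio and protein-evidence exon structures for one locus
#'
#' The ab initio exon set is the base prediction of the locus structure.
#' If protein-evidence exons exist and the total exon counts of the two
#' tracks agree at ratio `min(|ab|, |ev|) / max(|ab|, |ev|) >=
#' agreement_min` (default 0.70), interior ab initio exons lacking a
#' corresponding evidence exon are removed; the first and last ab initio
#' exons of the locus are never removed. Evidence exons lacking a
#' corresponding ab initio exon are then added (also, by default, when the
#' agreement test fails; `strict = TRUE` suppresses additions in that
#' case). The result is re-sorted and overlapping exons are coalesced by
#' interval union, with evidence provenance retained.
#'
#' @param locus A [gene_locus()].
#' @param agreement_min Exon-count agreement ratio required for the
#'   deletion step.
#' @param min_overlap Correspondence overlap (bp), see
#'   [exon_correspondence()].
#' @param strict If `TRUE`, evidence-only exons are only added when the
#'   agreement test passes.
#' @return A list of class `merged_locus` with `locus_id`, `exons` (with
#'   per-exon `source` provenance) and `agreement_ratio` (`NA` when there
#'   are no evidence exons).
#' @export
merge_locus <- function(locus, agreement_min = 0.70, min_overlap = 1L,
                        strict = FALSE) {
  stopifnot(inherits(locus, "gene_locus"))
  ab <- locus$ab_exons
  ev <- locus$ev_exons
  if (!nrow(ev)) {
    out <- ab
    rownames(out) <- NULL
    return(structure(list(locus_id = locus$locus_id, exons = out,
                          agreement_ratio = NA_real_),
                     class = "merged_locus"))
  }
  if (!nrow(ab)) {
    out <- ev
    out$source <- "EVIDENCE"
    rownames(out) <- NULL
    return(structure(list(locus_id = locus$locus_id, exons = out,
                          agreement_ratio = NA_real_),
                     class = "merged_locus"))
  }
  ratio <- min(nrow(ab), nrow(ev)) / max(nrow(ab), nrow(ev))
  corr <- correspondence_matrix(ab, ev, min_overlap)
  ab_has <- apply(corr, 1, any)
  ev_has <- apply(corr, 2, any)
  if (ratio >= agreement_min) {
    protected <- seq_len(nrow(ab)) %in% c(1L, nrow(ab))
    keep_ab <- ab_has | protected
  } else {
    keep_ab <- rep(TRUE, nrow(ab))
  }
  kept <- ab[keep_ab, , drop = FALSE]
  kept$source <- "AB_INITIO"
  add_ev <- ratio >= agreement_min || !strict
  if (add_ev && any(!ev_has)) {
    extra <- ev[!ev_has, , drop = FALSE]
    extra$source <- "EVIDENCE"
    kept <- rbind(kept, extra)
  }
  merged <- coalesce_exons(kept)
  structure(list(locus_id = locus$locus_id, exons = merged,
                 agreement_ratio = ratio),
            class = "merged_locus")
}

#' Merge two GFF3 exon tracks locus by locus
#'
#' Reads ab initio and protein-evidence GFF3 files, pairs loci by id
#' (loci present in only one track pass through), merges each with
#' [merge_locus()], and optionally writes the merged structures to GFF3.
#'
#' @param ab_path,ev_path Input GFF3 paths.
#' @param out_path Optional output GFF3 path.
#' @param agreement_min,min_overlap,strict Passed to [merge_locus()].
#' @return Named list of `merged_locus` objects, invisibly when
#'   `out_path` is given.
#' @export
merge_gff3_tracks <- function(ab_path, ev_path, out_path = NULL,
                              agreement_min = 0.70, min_overlap = 1L,
                              strict = FALSE) {
  ab <- read_gff3_exons(ab_path, track_label = "AB_INITIO")
  ev <- read_gff3_exons(ev_path, track_label = "EVIDENCE")
  ids <- sort(union(names(ab), names(ev)))
  empty <- exon_table(character(), integer(), integer())[0, ]
  merged <- lapply(ids, function(id) {
    loc <- gene_locus(id,
                      if (id %in% names(ab)) ab[[id]] else empty,
                      if (id %in% names(ev)) ev[[id]] else empty)
    merge_locus(loc, agreement_min, min_overlap, strict)
  })
  names(merged) <- ids
  if (!is.null(out_path)) {
    loci <- lapply(merged, `[[`, "exons")
    write_gff3_exons(loci, out_path)
    return(invisible(merged))
  }
  merged
}
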