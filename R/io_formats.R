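#' Table specification for validated TSV input
#'
#' A lightweight description of a tabular input: its name (used in error
#' messages), the columns that must be present, the delimiter, and whether
#' missing values are permitted in numeric cells.
#'
#' @param name Short name of the table, used in error messages.
#' @param required_columns Character vector of column names that must be
#'   present exactly once.
#' @param delimiter Field delimiter; tab by default, comma accepted.
#' @param allow_missing Logical; if `TRUE`, `NA` cells are tolerated in
#'   numeric columns.
#' @return An object of class `table_spec`.
#' @export
table_spec <- function(name, required_columns = character(),
                       delimiter = "\t", allow_missing = FALSE) {
  stopifnot(is.character(name), length(name) == 1L,
            delimiter %in% c("\t", ","))
  structure(list(name = name, required_columns = required_columns,
                 delimiter = delimiter, allow_missing = allow_missing),
            class = "table_spec")
}

#' Read a FASTA file into a sequence collection
#'
#' Wraps [Biostrings::readBStringSet()] and validates that headers are
#' unique. Line wrapping is irrelevant: wrapped and unwrapped records with
#' the same residues are read identically.
#'
#' @param path Path to a FASTA file (nucleotide or amino acid).
#' @return A data frame of class `seq_collection` with columns `id`,
#'   `sequence` and `length` (in residues), in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  if (file.size(path) == 0) stop("empty FASTA file: ", path)
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) stop("no records in FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(seqs))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate FASTA header(s): ", paste(dup, collapse = ", "))
  out <- data.frame(id = ids, sequence = as.character(seqs),
                    length = Biostrings::width(seqs),
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("seq_collection", "data.frame")
  out
}

#' Write a sequence collection to FASTA
#'
#' @param x A `seq_collection` (or any data frame with `id` and `sequence`
#'   columns).
#' @param path Output path.
#' @param width Line-wrap width in residues.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 60L) {
  stopifnot(all(c("id", "sequence") %in% names(x)))
  set <- Biostrings::BStringSet(x$sequence)
  names(set) <- x$id
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

#' Read exon features from a GFF3 file, grouped by locus
#'
#' Imports a GFF3 track via [rtracklayer::import()], keeps `exon` (and
#' `CDS`, if no `exon` features exist) rows, and groups them by their
#' `Parent` attribute. Coordinates are GFF3 1-based inclusive and are
#' preserved verbatim.
#'
#' @param path Path to a GFF3 file.
#' @param track_label Optional label recorded in the `source` column of the
#'   returned exons (defaults to the GFF3 source column).
#' @return A named list; one element per locus, each a data frame with
#'   columns `contig`, `start`, `end`, `strand`, `source`, sorted by
#'   `start`.
#' @export
read_gff3_exons <- function(path, track_label = NULL) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  keep <- type == "exon"
  if (!any(keep)) keep <- type == "CDS"
  gr <- gr[keep]
  if (length(gr) == 0L) stop("no exon/CDS features in GFF3 file: ", path)
  parent <- gr$Parent
  if (is.null(parent))
    stop("exon feature(s) missing a Parent attribute in ", path)
  n_par <- S4Vectors::elementNROWS(parent)
  if (any(n_par == 0L))
    stop("exon feature(s) missing a Parent attribute in ", path)
  locus <- vapply(parent, `[[`, character(1), 1L)
  src <- if (is.null(track_label)) as.character(gr$source) else
    rep(track_label, length(gr))
  df <- data.frame(
    contig = as.character(GenomicRanges::seqnames(gr)),
    start  = GenomicRanges::start(gr),
    end    = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    source = src,
    stringsAsFactors = FALSE)
  out <- split(df, locus)
  lapply(out, function(d) {
    d <- d[order(d$start), , drop = FALSE]
    rownames(d) <- NULL
    d
  })
}

#' Write exon lists to GFF3
#'
#' Emits one `gene` feature plus its `exon` children per locus, with
#' `ID`/`Parent` attributes, via [rtracklayer::export()].
#'
#' @param loci Named list of exon data frames as returned by
#'   [read_gff3_exons()].
#' @param path Output path.
#' @param source Value for the GFF3 source column; if `NULL` the per-exon
#'   `source` column is used.
#' @return `path`, invisibly.
#' @export
write_gff3_exons <- function(loci, path, source = NULL) {
  stopifnot(is.list(loci), length(loci) > 0L, !is.null(names(loci)))
  rows <- lapply(names(loci), function(id) {
    d <- loci[[id]]
    src <- if (is.null(source)) d$source else rep(source, nrow(d))
    gene <- data.frame(contig = d$contig[1], start = min(d$start),
                       end = max(d$end), strand = d$strand[1],
                       source = src[1], type = "gene",
                       ID = id, Parent = NA_character_)
    ex <- data.frame(contig = d$contig, start = d$start, end = d$end,
                     strand = d$strand, source = src, type = "exon",
                     ID = sprintf("%s.exon%d", id, seq_len(nrow(d))),
                     Parent = id)
    rbind(gene, ex)
  })
  tab <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = tab$contig,
    ranges = IRanges::IRanges(start = tab$start, end = tab$end),
    strand = tab$strand)
  gr$source <- tab$source
  gr$type <- tab$type
  gr$ID <- tab$ID
  gr$Parent <- ifelse(is.na(tab$Parent), NA_character_, tab$Parent)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a labeled numeric matrix from TSV
#'
#' The first column holds row labels; the header holds column labels. Cells
#' must parse as numbers; `NA`/empty cells are rejected unless the spec
#' permits missing values. Ragged rows and duplicate row labels are errors.
#'
#' @param path Path to the delimited file.
#' @param spec A [table_spec()]; controls delimiter and missing-value
#'   policy.
#' @return A numeric matrix with `dimnames` from the file.
#' @export
read_matrix_tsv <- function(path, spec = table_spec("matrix")) {
  if (!file.exists(path)) stop(spec$name, " file not found: ", path)
  nf <- utils::count.fields(path, sep = spec$delimiter, quote = "")
  if (length(unique(nf)) > 1L) {
    lines <- readLines(path)
    bad <- which(nf != nf[1])[1]
    lab <- strsplit(lines[bad], spec$delimiter, fixed = TRUE)[[1]][1]
    stop(spec$name, ": ragged row '", lab, "' (line ", bad, ")")
  }
  tab <- utils::read.table(path, sep = spec$delimiter, header = TRUE,
                           check.names = FALSE, quote = "",
                           colClasses = "character",
                           stringsAsFactors = FALSE)
  rl <- tab[[1]]
  if (anyDuplicated(rl))
    stop(spec$name, ": duplicate row label(s): ",
         paste(unique(rl[duplicated(rl)]), collapse = ", "))
  body <- tab[, -1, drop = FALSE]
  mat <- matrix(NA_real_, nrow = nrow(body), ncol = ncol(body),
                dimnames = list(rl, colnames(body)))
  for (j in seq_len(ncol(body))) {
    cell <- body[[j]]
    is_na <- is.na(cell) | cell == "" | cell == "NA"
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(!is_na & is.na(num))
    if (length(bad))
      stop(spec$name, ": non-numeric cell at row '", rl[bad[1]],
           "', column '", colnames(body)[j], "': '", cell[bad[1]], "'")
    if (any(is_na) && !spec$allow_missing)
      stop(spec$name, ": missing value at row '", rl[which(is_na)[1]],
           "', column '", colnames(body)[j], "'")
    mat[, j] <- num
  }
  mat
}

#' Write a labeled numeric matrix to TSV
#'
#' @param mat Numeric matrix with dimnames.
#' @param path Output path.
#' @param id_column Header for the row-label column.
#' @param delimiter Field delimiter.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(mat, path, id_column = "id", delimiter = "\t") {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_column
  utils::write.table(df, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a newick tree, requiring branch lengths
#'
#' Wraps [ape::read.tree()] and checks that every edge carries a branch
#' length (phylogenetic diversity is undefined without them) and that leaf
#' labels are unique. A degenerate single-leaf tree `"A:5;"` is supported.
#'
#' @param path Path to a newick file.
#' @return An [ape::read.tree()] `phylo` object.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("newick file not found: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  m <- regmatches(txt, regexec(
    "^\\s*([^():,;\\s]+):([0-9.eE+-]+)\\s*;\\s*$", txt))[[1]]
  if (length(m) == 3L) {
    # single-leaf degenerate tree; ape cannot parse it directly
    tr <- structure(list(edge = matrix(c(2L, 1L), nrow = 1),
                         edge.length = as.numeric(m[3]),
                         tip.label = m[2], Nnode = 1L),
                    class = "phylo")
    return(tr)
  }
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("could not parse newick file: ", path)
  if (is.null(tr$edge.length) || length(tr$edge.length) != nrow(tr$edge) ||
      anyNA(tr$edge.length))
    stop("newick tree is missing branch lengths: ", path)
  if (anyDuplicated(tr$tip.label))
    stop("duplicate leaf labels in newick tree: ", path)
  tr
}

#' Total branch length of a tree
#'
#' @param tree A `phylo` object with branch lengths.
#' @return Sum of all edge lengths (the root edge, if any, excluded).
#' @export
total_branch_length <- function(tree) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  sum(tree$edge.length)
}

#' Read KEGG Ortholog profiles from long or wide tables
#'
#' Long format: two columns (entity id, KO id), one row per present KO, as
#' emitted by kofamscan-style annotators. Wide format: first column entity
#' id, remaining columns one KO each with 0/1 presence. The format is
#' auto-detected from the header.
#'
#' @param path Path to a TSV file.
#' @param format `"auto"`, `"long"` or `"wide"`.
#' @param delimiter Field delimiter.
#' @return A named list of character vectors: per entity, the set of
#'   present KO identifiers (`K` followed by five digits).
#' @export
read_ko_profiles <- function(path, format = c("auto", "long", "wide"),
                             delimiter = "\t") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("KO table not found: ", path)
  tab <- utils::read.table(path, sep = delimiter, header = TRUE,
                           check.names = FALSE, quote = "",
                           stringsAsFactors = FALSE)
  if (format == "auto") {
    ko_cols <- grepl("^K[0-9]{5}$", colnames(tab))
    format <- if (ncol(tab) == 2L && !any(ko_cols)) "long" else
      if (sum(ko_cols) == ncol(tab) - 1L) "wide" else "long"
  }
  if (format == "long") {
    if (ncol(tab) < 2L) stop("long KO table needs two columns")
    ids <- as.character(tab[[1]])
    kos <- as.character(tab[[2]])
    validate_ko_ids(kos)
    profiles <- lapply(split(kos, ids), function(k) sort(unique(k)))
  } else {
    ids <- as.character(tab[[1]])
    kos <- colnames(tab)[-1]
    validate_ko_ids(kos)
    if (anyDuplicated(ids)) stop("duplicate entity ids in wide KO table")
    mat <- as.matrix(tab[, -1, drop = FALSE]) != 0
    profiles <- lapply(seq_along(ids), function(i) sort(kos[mat[i, ]]))
    names(profiles) <- ids
  }
  profiles
}

validate_ko_ids <- function(kos) {
  bad <- unique(kos[!grepl("^K[0-9]{5}$", kos)])
  if (length(bad))
    stop("malformed KO identifier(s): ", paste(utils::head(bad, 3),
                                               collapse = ", "))
  invisible(TRUE)
}

#' Write KEGG Ortholog profiles as a long TSV
#'
#' @param profiles Named list of KO identifier vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ko_profiles <- function(profiles, path) {
  df <- data.frame(
    entity_id = rep(names(profiles), lengths(profiles)),
    ko_id = unlist(profiles, use.names = FALSE),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# internal: read a simple two-or-more column TSV with required columns
read_cols_tsv <- function(path, required, name = "table", delimiter = "\t") {
  if (!file.exists(path)) stop(name, " file not found: ", path)
  tab <- utils::read.table(path, sep = delimiter, header = TRUE,
                           check.names = FALSE, quote = "",
                           stringsAsFactors = FALSE)
  missing <- setdiff(required, colnames(tab))
  if (length(missing))
    stop(name, ": missing required column(s): ",
         paste(missing, collapse = ", "))
  tab
}
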