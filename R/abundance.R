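#' Assemble a read-count table
#'
#' Holds the three quantities RPKM is defined over: X, the reads recruited
#' per MAG and sample; l, MAG length in kb; and N, total trimmed reads per
#' sample in millions. Lengths arrive in bp and totals in reads; the
#' conversion to kb and millions happens here.
#'
#' @param counts Data frame (`mag_id`, `sample_id`, `reads`).
#' @param lengths Data frame (`mag_id`, `length_bp`).
#' @param totals Data frame (`sample_id`, `total_reads`).
#' @return A list of class `read_count_table`: `X` (MAG x sample integer
#'   matrix), `l_kb` (named), `N_million` (named).
#' @export
read_count_table <- function(counts, lengths, totals) {
  stopifnot(all(c("mag_id", "sample_id", "reads") %in% names(counts)),
            all(c("mag_id", "length_bp") %in% names(lengths)),
            all(c("sample_id", "total_reads") %in% names(totals)))
  if (anyDuplicated(lengths$mag_id)) stop("duplicate mag_id in lengths")
  if (anyDuplicated(totals$sample_id)) stop("duplicate sample_id in totals")
  if (any(counts$reads < 0) || anyNA(counts$reads))
    stop("read counts must be finite and non-negative")
  mags <- as.character(lengths$mag_id)
  samples <- as.character(totals$sample_id)
  unknown <- setdiff(unique(counts$mag_id), mags)
  if (length(unknown))
    stop("mag_id without a length: ", paste(unknown, collapse = ", "))
  unknown <- setdiff(unique(counts$sample_id), samples)
  if (length(unknown))
    stop("sample_id without a read total: ",
         paste(unknown, collapse = ", "))
  X <- matrix(0, length(mags), length(samples),
              dimnames = list(mags, samples))
  X[cbind(match(counts$mag_id, mags),
          match(counts$sample_id, samples))] <- counts$reads
  l_kb <- stats::setNames(lengths$length_bp / 1e3, mags)
  N_million <- stats::setNames(totals$total_reads / 1e6, samples)
  if (any(l_kb <= 0)) stop("MAG lengths must be positive")
  if (any(N_million <= 0)) stop("per-sample read totals must be positive")
  structure(list(X = X, l_kb = l_kb, N_million = N_million),
            class = "read_count_table")
}

#' Reads per kilobase million (RPKM)
#'
#' `RPKM(i, s) = X(i, s) / (l_i * N_s)` with X the reads recruited to MAG
#' i in sample s, l_i the MAG length in kb and N_s the total trimmed reads
#' in sample s in millions.
#'
#' @param rc A [read_count_table()].
#' @return A MAG x sample numeric matrix with attribute `metric = "RPKM"`.
#' @export
rpkm <- function(rc) {
  stopifnot(inherits(rc, "read_count_table"))
  vals <- rc$X / outer(rc$l_kb, rc$N_million)
  structure(vals, metric = "RPKM")
}

#' Counts per million (CPM)
#'
#' Normalises an RPKM matrix so every sample (column) sums to one million:
#' `CPM(i, s) = RPKM(i, s) / sum_j RPKM(j, s) * 1e6`. Samples recruiting
#' no reads at all yield an all-zero column with a warning rather than an
#' error, since poorly-recruiting samples are routine in environmental
#' surveys.
#'
#' @param rpkm_matrix Matrix produced by [rpkm()] (attribute
#'   `metric = "RPKM"`).
#' @return A MAG x sample matrix with attribute `metric = "CPM"`; each
#'   non-empty column sums to 1e6.
#' @export
cpm <- function(rpkm_matrix) {
  metric <- attr(rpkm_matrix, "metric")
  if (is.null(metric) || metric != "RPKM")
    stop("cpm() expects an RPKM matrix (attribute metric = \"RPKM\")")
  if (any(rpkm_matrix < 0)) stop("negative RPKM values")
  totals <- colSums(rpkm_matrix)
  empty <- totals == 0
  if (any(empty)) {
    warning("sample(s) with zero total RPKM left as all-zero columns: ",
            paste(colnames(rpkm_matrix)[empty], collapse = ", "))
    totals[empty] <- 1  # avoid 0/0; columns are all zero anyway
  }
  vals <- sweep(rpkm_matrix, 2, totals, "/") * 1e6
  structure(vals, metric = "CPM")
}

#' Compute an abundance matrix from count TSV files
#'
#' @param counts_path,lengths_path,totals_path Input TSV paths with the
#'   column layouts documented in [read_count_table()].
#' @param metric `"cpm"` (default) or `"rpkm"`.
#' @param out_path Optional path to write the matrix as TSV.
#' @return The abundance matrix (invisibly when `out_path` is given).
#' @export
abundance_from_files <- function(counts_path, lengths_path, totals_path,
                                 metric = c("cpm", "rpkm"),
                                 out_path = NULL) {
  metric <- match.arg(metric)
  rc <- read_count_table(
    read_cols_tsv(counts_path, c("mag_id", "sample_id", "reads"), "counts"),
    read_cols_tsv(lengths_path, c("mag_id", "length_bp"), "lengths"),
    read_cols_tsv(totals_path, c("sample_id", "total_reads"), "totals"))
  out <- rpkm(rc)
  if (metric == "cpm") out <- cpm(out)
  if (!is.null(out_path)) {
    write_matrix_tsv(unclass(out), out_path, id_column = "mag_id")
    return(invisible(out))
  }
  out
}
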