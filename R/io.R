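#' Write a synthetic dataset to disk
#'
#' Emits the generator's outputs in the plain-text formats the pipeline
#' reads back: expression TSV (rows = genes), PSI TSV (rows = events,
#' `NA` for missing), event metadata TSV with BED-style 0-based
#' half-open coordinates, clinical TSV, FASTA sequence windows, and a
#' peak BED.
#'
#' @param dir output directory (created if absent).
#' @param expr genes x samples matrix (optional).
#' @param psi_data list from [generate_psi()] (optional).
#' @param clinical data.frame from [generate_survival()] (optional).
#' @param seq_data list from [generate_sequences_and_peaks()] (optional).
#' @return `dir`, invisibly.
#' @export
write_sim_dataset <- function(dir, expr = NULL, psi_data = NULL,
                              clinical = NULL, seq_data = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(expr)) write_matrix_tsv(expr, file.path(dir, "expression.tsv"))
  if (!is.null(psi_data)) {
    write_matrix_tsv(psi_data$psi, file.path(dir, "psi.tsv"))
    utils::write.table(psi_data$meta, file.path(dir, "events.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(psi_data$truth, file.path(dir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(clinical))
    utils::write.table(clinical, file.path(dir, "clinical.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(seq_data)) {
    write_fasta(c(seq_data$regulated, seq_data$control),
                file.path(dir, "windows.fa"))
    if (!is.null(seq_data$peaks))
      utils::write.table(
        data.frame(chrom = seq_data$peaks$seq_id,
                   start = seq_data$peaks$start, end = seq_data$peaks$end,
                   name = seq_data$peaks$factor),
        file.path(dir, "peaks.bed"), sep = "\t", quote = FALSE,
        row.names = FALSE, col.names = FALSE)
  }
  invisible(dir)
}

#' Write / read a named numeric matrix as TSV
#'
#' First column `id` holds row names; `NA` encodes missing values.
#'
#' @param m matrix with dimnames.
#' @param path file path.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @return `read_matrix_tsv`: the numeric matrix.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write sequences as FASTA
#'
#' @param seqs named character vector.
#' @param path file path.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' @param path file path.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(ss), names(ss))
}

#' Read a BED3+ file as a 0-based half-open interval data.frame
#'
#' @param path file path.
#' @param one_based set `TRUE` for 1-based closed input coordinates
#'   (converted at the boundary).
#' @return data.frame with chrom, start, end and any extra columns as
#'   name/score/strand.
#' @export
read_bed <- function(path, one_based = FALSE) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  names(df) <- cols[seq_len(min(ncol(df), 6))]
  if (one_based) df$start <- df$start - 1L
  df
}

#' Read a simple PWM text file
#'
#' One record per matrix: a `>name` header line followed by four
#' whitespace-separated rows (A, C, G, T) of probabilities.
#'
#' @param path file path.
#' @return named list of 4 x L probability matrices.
#' @export
read_pwm_file <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^>", lines)
  if (length(heads) == 0) stop("no PWM records in ", path)
  out <- list()
  for (i in seq_along(heads)) {
    lo <- heads[i] + 1L
    hi <- if (i < length(heads)) heads[i + 1] - 1L else length(lines)
    rows <- lapply(lines[lo:hi], function(l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
    if (length(rows) != 4) stop("PWM record must have 4 rows")
    m <- do.call(rbind, rows)
    rownames(m) <- c("A", "C", "G", "T")
    out[[sub("^>\\s*", "", lines[heads[i]])]] <- m
  }
  out
}
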