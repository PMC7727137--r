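#' Read and write 10x-style MatrixMarket triplets
#'
#' A count matrix directory in the 10x dialect holds `matrix.mtx` (integer
#' coordinate MatrixMarket, features as rows, cells as columns),
#' `barcodes.tsv` (one cell barcode per line) and `features.tsv` (tab-
#' separated, no header; first column feature id, second column feature name).
#'
#' @param counts A genes-by-cells sparse matrix (coercible to `dgCMatrix`)
#'   with feature and barcode dimnames.
#' @param dir Directory to write into (created if missing).
#' @return `write_tenx` returns `dir` invisibly; `read_tenx` returns a
#'   `dgCMatrix` with feature rownames and barcode colnames.
#' @export
write_tenx <- function(counts, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(colnames(m), file.path(dir, "barcodes.tsv"))
  write.table(data.frame(id = rownames(m), name = rownames(m)),
              file.path(dir, "features.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(dir)
}

#' @rdname write_tenx
#' @export
read_tenx <- function(dir) {
  m <- as(Matrix::readMM(file.path(dir, "matrix.mtx")), "CsparseMatrix")
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  feats <- read.table(file.path(dir, "features.tsv"), sep = "\t",
                      header = FALSE, stringsAsFactors = FALSE)
  if (nrow(feats) != nrow(m) || length(barcodes) != ncol(m))
    stop("matrix dimensions do not match barcodes/features files")
  dimnames(m) <- list(feats[[1L]], barcodes)
  as(m, "dMatrix")
}

#' Write a paired set of barcode-read FASTQ files
#'
#' R1 carries cell barcode + UMI (default 16 + 12 nt), R2 the cDNA sequence
#' that may contain a flanked CellTag. Records are paired by order and share
#' read ids.
#'
#' @param reads Data frame with columns `cell_barcode`, `umi`, `sequence`.
#' @param r1,r2 Output FASTQ paths (`.gz` suffix enables compression).
#' @return Invisibly, a list with the two paths.
#' @export
write_tag_fastq <- function(reads, r1, r2) {
  stopifnot(all(c("cell_barcode", "umi", "sequence") %in% names(reads)))
  ids <- sprintf("read%07d", seq_len(nrow(reads)))
  s1 <- Biostrings::DNAStringSet(paste0(reads$cell_barcode, reads$umi))
  s2 <- Biostrings::DNAStringSet(reads$sequence)
  names(s1) <- names(s2) <- ids
  q1 <- Biostrings::PhredQuality(strrep("I", Biostrings::width(s1)))
  q2 <- Biostrings::PhredQuality(strrep("I", Biostrings::width(s2)))
  Biostrings::writeQualityScaledXStringSet(
    Biostrings::QualityScaledDNAStringSet(s1, q1), r1,
    compress = grepl("\\.gz$", r1))
  Biostrings::writeQualityScaledXStringSet(
    Biostrings::QualityScaledDNAStringSet(s2, q2), r2,
    compress = grepl("\\.gz$", r2))
  invisible(list(r1 = r1, r2 = r2))
}

#' @rdname write_tag_fastq
#' @param bc_len,umi_len Lengths of the cell barcode and UMI in R1.
#' @return `read_tag_fastq` returns a data frame of
#'   (`cell_barcode`, `umi`, `sequence`).
#' @export
read_tag_fastq <- function(r1, r2, bc_len = 16L, umi_len = 12L) {
  x1 <- Biostrings::readDNAStringSet(r1, format = "fastq")
  x2 <- Biostrings::readDNAStringSet(r2, format = "fastq")
  if (length(x1) != length(x2))
    stop("R1 and R2 contain different numbers of records")
  s1 <- unname(as.character(x1))
  data.frame(
    cell_barcode = substr(s1, 1L, bc_len),
    umi = substr(s1, bc_len + 1L, bc_len + umi_len),
    sequence = unname(as.character(x2)),
    stringsAsFactors = FALSE
  )
}

#' Write and read per-cell tag signatures
#'
#' Signatures are stored as a two-column TSV (`cell_id`, comma-joined sorted
#' tags) with a header line.
#'
#' @param signatures Named list of character vectors (cell id -> tag set).
#' @param path Output TSV path.
#' @export
write_signatures <- function(signatures, path) {
  df <- data.frame(
    cell_id = names(signatures),
    tags = vapply(signatures, function(t) paste(sort(t), collapse = ","),
                  character(1)),
    stringsAsFactors = FALSE
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_signatures
#' @export
read_signatures <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   colClasses = "character")
  sigs <- strsplit(df$tags, ",", fixed = TRUE)
  names(sigs) <- df$cell_id
  sigs
}
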