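#' Extract motif-anchored CellTags from barcode reads
#'
#' Scans each read for `motif_prefix + <tag_length bases> + motif_suffix` and
#' emits one (cell_barcode, umi, tag) triple per matching read. The leftmost
#' match wins when a read contains several. Reads without a match are
#' counted and skipped; tags containing `N` are tallied separately and
#' skipped.
#'
#' @param reads Data frame with columns `cell_barcode`, `umi`, `sequence`
#'   (as returned by [emit_reads()] or [read_tag_fastq()]).
#' @param motif_prefix,motif_suffix Non-empty flanking motifs.
#' @param tag_length Tag length in bases (default 8).
#' @return Data frame (`cell_barcode`, `umi`, `tag`) with attributes
#'   `n_no_match` and `n_ambiguous_base` (reads skipped for each reason).
#' @export
extract_tags <- function(reads, motif_prefix = "GGT", motif_suffix = "GAATTC",
                         tag_length = 8L) {
  stopifnot(nzchar(motif_prefix), nzchar(motif_suffix), tag_length >= 1L)
  pattern <- paste0(motif_prefix,
                    "([ACGTN]{", as.integer(tag_length), "})",
                    motif_suffix)
  m <- regexpr(pattern, reads$sequence, perl = TRUE)
  hit <- m > 0L
  start <- m[hit] + nchar(motif_prefix)
  tags <- substr(reads$sequence[hit], start, start + tag_length - 1L)
  has_n <- grepl("N", tags, fixed = TRUE)
  out <- data.frame(cell_barcode = reads$cell_barcode[hit][!has_n],
                    umi = reads$umi[hit][!has_n],
                    tag = tags[!has_n],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_no_match") <- sum(!hit)
  attr(out, "n_ambiguous_base") <- sum(has_n)
  out
}

#' Collapse tag triples into a cells-by-tags UMI count matrix
#'
#' Reads with identical (cell, UMI, tag) collapse to one molecule; the matrix
#' entry is the number of distinct UMIs supporting that tag in that cell.
#'
#' @param triples Data frame (`cell_barcode`, `umi`, `tag`).
#' @return Sparse `dgCMatrix`, cells (rows) by tags (columns).
#' @export
count_tags <- function(triples) {
  if (nrow(triples) == 0L)
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(0L, 0L)))
  mol <- unique(triples[, c("cell_barcode", "umi", "tag")])
  cells <- sort(unique(mol$cell_barcode))
  tags <- sort(unique(mol$tag))
  m <- Matrix::sparseMatrix(
    i = match(mol$cell_barcode, cells),
    j = match(mol$tag, tags),
    x = rep(1, nrow(mol)),
    dims = c(length(cells), length(tags)),
    dimnames = list(cells, tags)
  )
  ## duplicate (i,j) entries sum on construction -> UMI counts
  m
}

#' Per-cell Hamming-distance error correction of tag counts
#'
#' Within each cell, a tag whose UMI count is less than half that of another
#' tag at Hamming distance `<= hamming_radius` is merged into the more
#' abundant tag (counts added). Candidate recipients are searched in
#' decreasing count order, ties broken toward the lexicographically smaller
#' tag. Correction is per-cell so distinct clones' tags are never merged
#' across cells. Radius 0 is the identity.
#'
#' @param mat Cells-by-tags count matrix from [count_tags()].
#' @param hamming_radius 0 or 1.
#' @return Corrected matrix, same shape (all-zero tag columns retained).
#' @export
correct_tags <- function(mat, hamming_radius = 1L) {
  stopifnot(hamming_radius %in% c(0L, 1L))
  if (hamming_radius == 0L || nrow(mat) == 0L) return(mat)
  tm <- as(Matrix::t(mat), "CsparseMatrix")   # tags x cells for column access
  tagnames <- rownames(tm)
  p <- tm@p
  for (cell in seq_len(ncol(tm))) {
    idx <- if (p[cell + 1L] > p[cell]) (p[cell] + 1L):p[cell + 1L] else integer(0)
    if (length(idx) < 2L) next
    tags <- tagnames[tm@i[idx] + 1L]
    counts <- tm@x[idx]
    merged <- merge_cell_tags(tags, counts)
    if (!identical(merged, counts)) tm@x[idx] <- merged
  }
  out <- Matrix::t(tm)
  out <- as(Matrix::drop0(out), "CsparseMatrix")
  ## keep original tag universe as columns for shape stability
  out
}

## Greedy per-cell merge: visit tags in increasing count (lexicographic tag
## order on ties); merge a tag into the best eligible recipient (count
## strictly more than double, Hamming distance <= 1), preferring the highest
## count then the lexicographically smaller tag. Returns updated counts
## aligned with `tags` (merged donors set to 0).
merge_cell_tags <- function(tags, counts) {
  d <- hamming_matrix(tags)
  cur <- counts
  ord <- order(cur, tags)              # ascending count, lexicographic ties
  for (i in ord) {
    if (cur[i] == 0) next
    cand <- which(d[i, ] <= 1L & seq_along(tags) != i & cur > 2 * cur[i])
    if (!length(cand)) next
    best <- cand[order(-cur[cand], tags[cand])][1L]
    cur[best] <- cur[best] + cur[i]
    cur[i] <- 0
  }
  cur
}

#' Filter tag counts and binarize into per-cell tag signatures
#'
#' Entries below `min_umi` UMIs are zeroed, non-whitelist tags dropped (when
#' a whitelist is given), and cells left with no tag removed. The surviving
#' support is the per-cell tag signature.
#'
#' @param mat Cells-by-tags count matrix.
#' @param min_umi Minimum UMIs supporting a (cell, tag) entry (default 2).
#' @param whitelist Optional character vector of legitimate tag sequences.
#' @return List with `counts` (filtered count matrix), `binary` (pattern
#'   matrix of the same shape) and `signatures` (named list cell -> sorted
#'   tag set).
#' @export
filter_and_binarize <- function(mat, min_umi = 2, whitelist = NULL) {
  stopifnot(min_umi >= 1)
  m <- as(mat, "CsparseMatrix")
  m@x[m@x < min_umi] <- 0
  m <- Matrix::drop0(m)
  if (!is.null(whitelist))
    m <- m[, colnames(m) %in% whitelist, drop = FALSE]
  keep <- Matrix::rowSums(m) > 0
  m <- m[keep, , drop = FALSE]
  m <- m[, Matrix::colSums(m) > 0, drop = FALSE]
  if (nrow(m) == 0L)
    warning("no cells retain any tag after filtering")
  binary <- as(m > 0, "lMatrix")
  sigs <- matrix_signatures(m)
  list(counts = m, binary = binary, signatures = sigs)
}

## Per-cell sorted tag sets from the nonzero support of a cells-by-tags
## matrix, in row order; cells with no tags get character(0).
matrix_signatures <- function(m) {
  if (nrow(m) == 0L || ncol(m) == 0L)
    return(stats::setNames(rep(list(character(0)), nrow(m)), rownames(m)))
  mm <- as(as(m, "CsparseMatrix"), "TsparseMatrix")
  f <- factor(rownames(m)[mm@i + 1L], levels = rownames(m))
  sigs <- split(as.character(colnames(m)[mm@j + 1L]), f)
  lapply(sigs, sort)
}

#' Summarize per-cell tag statistics, optionally across two timepoints
#'
#' Reports the minimum, mean and maximum number of distinct tags per cell and
#' the tags-per-cell histogram. Given a second matrix, also counts the cells
#' at each timepoint whose full tag signature is matched by at least one cell
#' at the other timepoint (the "tagged with the same CellTags" count).
#'
#' @param mat Cells-by-tags count matrix (nonzero entries define signatures).
#' @param mat2 Optional second timepoint's matrix.
#' @return List with `n_cells`, `min`, `mean`, `max`, `histogram`, and for
#'   two matrices `shared_cells` (per timepoint) and `shared_total`.
#' @export
tag_stats <- function(mat, mat2 = NULL) {
  per_cell <- Matrix::rowSums(mat > 0)
  out <- list(
    n_cells = nrow(mat),
    min = if (length(per_cell)) min(per_cell) else NA_real_,
    mean = if (length(per_cell)) mean(per_cell) else NA_real_,
    max = if (length(per_cell)) max(per_cell) else NA_real_,
    histogram = table(per_cell)
  )
  if (!is.null(mat2)) {
    key <- function(m) vapply(matrix_signatures(m), paste, character(1),
                              collapse = ",")
    k1 <- key(mat)
    k2 <- key(mat2)
    out$shared_cells <- c(timepoint1 = sum(k1 %in% k2),
                          timepoint2 = sum(k2 %in% k1))
    out$shared_total <- sum(out$shared_cells)
  }
  out
}
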