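#' Library-size normalize and log-transform counts
#'
#' Each cell's counts are scaled to a common total (`target_sum`) and
#' log1p-transformed: `log(1 + count / cell_total * target_sum)`. Cells with
#' zero total are dropped with a warning.
#'
#' @param counts Genes-by-cells count matrix (sparse or dense).
#' @param target_sum Post-scaling total per cell (default 1e4).
#' @return Sparse `dgCMatrix` of normalized log values, genes by cells.
#' @export
normalize_log <- function(counts, target_sum = 1e4) {
  m <- as(as(counts, "CsparseMatrix"), "dMatrix")
  totals <- Matrix::colSums(m)
  if (any(totals == 0)) {
    warning(sum(totals == 0), " all-zero cell(s) dropped")
    m <- m[, totals > 0, drop = FALSE]
    totals <- totals[totals > 0]
  }
  norm <- m %*% Matrix::Diagonal(x = target_sum / totals)
  norm@x <- log1p(norm@x)
  dimnames(norm) <- dimnames(m)
  norm
}

#' Select highly variable genes by mean-binned normalized dispersion
#'
#' Per-gene dispersion (variance / mean) is computed on normalized data,
#' genes are placed into 20 equal-frequency bins of mean expression, and
#' dispersions are z-scored within each bin. Mode `"count"` takes the
#' `n_top` genes by normalized dispersion; mode `"threshold"` keeps genes
#' with mean inside `mean_bounds` and normalized dispersion at least
#' `min_disp`.
#'
#' @param normalized Genes-by-cells normalized matrix from
#'   [normalize_log()].
#' @param n_top Number of genes in `"count"` mode (default 2000).
#' @param mean_bounds Inclusive mean-expression bounds in `"threshold"`
#'   mode (default `c(0.0125, 3)`).
#' @param min_disp Minimum normalized dispersion in `"threshold"` mode.
#' @param mode `"count"` or `"threshold"`.
#' @param n_bins Number of mean bins (default 20).
#' @return Character vector of selected gene names. The full per-gene table
#'   is attached as attribute `"stats"`.
#' @export
select_hvg <- function(normalized, n_top = 2000, mean_bounds = c(0.0125, 3),
                       min_disp = 0.5, mode = c("count", "threshold"),
                       n_bins = 20L) {
  mode <- match.arg(mode)
  mu <- Matrix::rowMeans(normalized)
  ex2 <- Matrix::rowMeans(normalized^2)
  n <- ncol(normalized)
  v <- (ex2 - mu^2) * n / (n - 1)
  disp <- ifelse(mu > 0, v / mu, 0)
  expressed <- mu > 0
  bins <- rep(NA_integer_, length(mu))
  if (any(expressed)) {
    qs <- unique(quantile(mu[expressed], probs = seq(0, 1, length.out = n_bins + 1)))
    bins[expressed] <- as.integer(cut(mu[expressed], breaks = qs,
                                      include.lowest = TRUE))
  }
  zdisp <- rep(0, length(mu))
  for (b in unique(bins[!is.na(bins)])) {
    idx <- which(bins == b)
    s <- sd(disp[idx])
    zdisp[idx] <- if (is.na(s) || s < 1e-12) 0 else
      (disp[idx] - mean(disp[idx])) / s
  }
  stats_df <- data.frame(gene = rownames(normalized), mean = mu,
                         dispersion = disp, dispersion_norm = zdisp,
                         stringsAsFactors = FALSE)
  if (mode == "count") {
    cand <- which(expressed)
    take <- cand[order(-zdisp[cand], rownames(normalized)[cand])]
    sel <- rownames(normalized)[sort(take[seq_len(min(n_top, length(take)))])]
  } else {
    sel <- rownames(normalized)[expressed &
                                  mu >= mean_bounds[1] & mu <= mean_bounds[2] &
                                  zdisp >= min_disp]
  }
  attr(sel, "stats") <- stats_df
  sel
}

#' Scale selected genes and embed cells by PCA
#'
#' Genes are z-scored across cells (values clipped at `clip` standard
#' deviations), and cells are embedded with exact PCA. Component signs are
#' fixed by the convention that each component's largest-magnitude gene
#' loading is positive; explained-variance shares are reported. The (PC1,
#' PC3) pair is the conventional reprogramming-axis scatter.
#'
#' @param normalized Genes-by-cells normalized matrix.
#' @param genes Genes to use (e.g. from [select_hvg()]).
#' @param n_components Number of components (default 20; reduced with a
#'   warning if the data have lower rank).
#' @param clip Clipping bound for scaled values (default 10).
#' @return List with `embedding` (cells x components), `loadings` (genes x
#'   components), `var_explained` (shares) and `genes`.
#' @export
scale_and_pca <- function(normalized, genes, n_components = 20L, clip = 10) {
  x <- as.matrix(normalized[genes, , drop = FALSE])
  mu <- rowMeans(x)
  sdev <- apply(x, 1L, sd)
  sdev[sdev < 1e-12] <- 1
  z <- (x - mu) / sdev
  z[z > clip] <- clip
  z[z < -clip] <- -clip
  zc <- t(z)                                   # cells x genes
  rank_max <- min(dim(zc)) - 1L
  if (n_components > rank_max) {
    warning("n_components reduced to rank ", rank_max)
    n_components <- rank_max
  }
  pc <- prcomp(zc, center = TRUE, scale. = FALSE, rank. = n_components)
  flip <- vapply(seq_len(n_components), function(j) {
    l <- pc$rotation[, j]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  emb <- sweep(pc$x[, seq_len(n_components), drop = FALSE], 2L, flip, "*")
  load <- sweep(pc$rotation[, seq_len(n_components), drop = FALSE], 2L, flip, "*")
  list(embedding = emb, loadings = load,
       var_explained = pc$sdev^2 / sum(pc$sdev^2),
       genes = genes)
}

#' Score cells against a gene signature
#'
#' The score is the mean normalized expression over the signature's genes
#' present in the matrix. Missing genes are reported; if none is present
#' this is an error.
#'
#' @param normalized Genes-by-cells normalized matrix.
#' @param gene_set Character vector of gene names.
#' @return Named numeric vector of per-cell scores.
#' @export
score_signature <- function(normalized, gene_set) {
  present <- intersect(gene_set, rownames(normalized))
  if (!length(present))
    stop("no signature gene present in the matrix: ",
         paste(gene_set, collapse = ", "))
  missing <- setdiff(gene_set, present)
  if (length(missing))
    message("signature genes absent from matrix: ",
            paste(missing, collapse = ", "))
  scores <- Matrix::colMeans(normalized[present, , drop = FALSE])
  names(scores) <- colnames(normalized)
  scores
}

#' Call the HSPC program High/Low from signature scores
#'
#' The threshold is the midpoint of the deterministic two-group 1-D split
#' minimizing within-group variance over all cut points (an exhaustive scan;
#' no random initialization). Cells scoring above the threshold are `High`.
#' Constant scores give all-`Low` with a warning.
#'
#' @param scores Named numeric vector of per-cell signature scores.
#' @return List with `labels` (named `"High"`/`"Low"` vector), `threshold`
#'   and `group_means`.
#' @export
call_hspc_program <- function(scores) {
  stopifnot(length(scores) >= 2L)
  s <- sort(scores)
  n <- length(s)
  if (max(s) - min(s) < 1e-12) {
    warning("constant scores; all cells called Low")
    labels <- rep("Low", n)
    names(labels) <- names(scores)
    return(list(labels = labels, threshold = Inf,
                group_means = c(Low = mean(s), High = NA_real_)))
  }
  cs <- cumsum(s)
  cs2 <- cumsum(s^2)
  k <- seq_len(n - 1L)
  ssw_left <- cs2[k] - cs[k]^2 / k
  ssw_right <- (cs2[n] - cs2[k]) - (cs[n] - cs[k])^2 / (n - k)
  ssw <- ssw_left + ssw_right
  ## only cuts between strictly different values are real splits
  valid <- s[k] < s[k + 1L]
  ssw[!valid] <- Inf
  kbest <- which.min(ssw)
  threshold <- unname((s[kbest] + s[kbest + 1L]) / 2)
  labels <- ifelse(scores > threshold, "High", "Low")
  names(labels) <- names(scores)
  list(labels = labels, threshold = threshold,
       group_means = c(Low = mean(scores[labels == "Low"]),
                       High = mean(scores[labels == "High"])))
}

#' Assign per-cell (or per-cluster) type labels from marker sets
#'
#' Each marker set is scored per cell ([score_signature()]), scores are
#' z-scored across cells per type, and each cell takes the argmax type. The
#' margin between best and second-best z-score is reported; margins below
#' `min_margin` are flagged low-confidence. When a cluster partition is
#' supplied, each cluster additionally receives the majority vote of its
#' cells' calls (figure legends annotate clusters, not cells).
#'
#' @param normalized Genes-by-cells normalized matrix.
#' @param marker_sets Named list of marker gene vectors (pairwise distinct),
#'   e.g. [state_marker_sets()].
#' @param clusters Optional named vector: cell id -> cluster id.
#' @param min_margin Low-confidence margin threshold (default 0.1).
#' @return Data frame with `cell_id`, `type`, `margin`, `confident`, and
#'   when `clusters` is given, `cluster` and `cluster_type`.
#' @export
assign_cell_type <- function(normalized, marker_sets, clusters = NULL,
                             min_margin = 0.1) {
  stopifnot(!any(duplicated(lapply(marker_sets, sort))))
  sc <- vapply(marker_sets, function(g) score_signature(normalized, g),
               numeric(ncol(normalized)))
  z <- scale(sc)
  z[is.nan(z)] <- 0
  best <- max.col(z, ties.method = "first")
  margin <- vapply(seq_len(nrow(z)), function(i) {
    o <- sort(z[i, ], decreasing = TRUE)
    if (length(o) > 1L) o[1L] - o[2L] else Inf
  }, numeric(1))
  ## no marker evidence at all -> never confident
  margin[rowSums(sc) == 0] <- 0
  out <- data.frame(cell_id = colnames(normalized),
                    type = names(marker_sets)[best],
                    margin = margin,
                    confident = margin >= min_margin,
                    stringsAsFactors = FALSE)
  if (!is.null(clusters)) {
    out$cluster <- unname(clusters[out$cell_id])
    maj <- vapply(split(out$type, out$cluster), function(tt) {
      tab <- sort(table(tt), decreasing = TRUE)
      names(tab)[1L]
    }, character(1))
    out$cluster_type <- unname(maj[as.character(out$cluster)])
  }
  out
}

#' Rank-sum differential expression with log-fold-change threshold
#'
#' Per gene, a two-sided Wilcoxon rank-sum test compares the two cell groups
#' on normalized data: exact by exhaustive enumeration of group assignments
#' when that is cheap (at most `max_exact` splits, ties handled by
#' midranks), otherwise the normal approximation with tie and continuity
#' correction. The average log fold change is
#' `log(mean(expm1(A)) + 1) - log(mean(expm1(B)) + 1)` (natural log).
#' P-values are Benjamini-Hochberg adjusted across tested genes; a gene
#' passes iff adjusted p <= `alpha` and avg logFC >= `lfc_min`.
#'
#' @param normalized Genes-by-cells normalized matrix.
#' @param cells_a,cells_b Cell ids of the two groups (>= 3 each).
#' @param alpha Adjusted-p threshold (default 0.01).
#' @param lfc_min Minimum average log fold change (default 1).
#' @param max_exact Enumerate the exact permutation null when
#'   `choose(nA + nB, nA)` is at most this (default 10000).
#' @return Data frame (`gene`, `avg_logFC`, `statistic` (Mann-Whitney U of
#'   group A), `p_val`, `p_val_adj`, `pass`).
#' @export
rank_sum_deg <- function(normalized, cells_a, cells_b,
                         alpha = 0.01, lfc_min = 1, max_exact = 10000) {
  stopifnot(length(cells_a) >= 3L, length(cells_b) >= 3L)
  a <- as.matrix(normalized[, cells_a, drop = FALSE])
  b <- as.matrix(normalized[, cells_b, drop = FALSE])
  na <- ncol(a)
  nb <- ncol(b)
  nn <- na + nb
  x <- cbind(a, b)
  mu <- na * nb / 2
  offs <- na * (na + 1) / 2
  if (choose(nn, na) <= max_exact) {
    splits <- utils::combn(nn, na)
    res <- apply(x, 1L, function(row) {
      r <- rank(row)
      u_obs <- sum(r[seq_len(na)]) - offs
      u_all <- colSums(matrix(r[splits], nrow = na)) - offs
      c(u = u_obs, p = mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9))
    })
    u <- res["u", ]
    p <- res["p", ]
  } else {
    stats <- apply(x, 1L, function(row) {
      r <- rank(row)
      u <- sum(r[seq_len(na)]) - offs
      ties <- rle(sort(row))$lengths
      tie_term <- sum(ties^3 - ties)
      sigma2 <- na * nb / 12 * ((nn + 1) - tie_term / (nn * (nn - 1)))
      c(u = u, sigma2 = sigma2)
    })
    u <- stats["u", ]
    sigma2 <- stats["sigma2", ]
    z <- numeric(length(u))
    pos <- sigma2 > 0
    ## continuity-corrected normal approximation (matches wilcox.test)
    z[pos] <- (abs(u[pos] - mu) - 0.5) / sqrt(sigma2[pos])
    z[z < 0] <- 0
    p <- ifelse(pos, 2 * pnorm(-z), 1)
    p <- pmin(p, 1)
  }
  lfc <- log(rowMeans(expm1(a)) + 1) - log(rowMeans(expm1(b)) + 1)
  padj <- p.adjust(p, method = "BH")
  data.frame(gene = rownames(normalized),
             avg_logFC = lfc, statistic = u,
             p_val = p, p_val_adj = padj,
             pass = padj <= alpha & lfc >= lfc_min,
             stringsAsFactors = FALSE)
}

#' Cluster gene profiles by average-linkage correlation distance
#'
#' Genes are clustered on `1 - Pearson correlation` between their expression
#' profiles with average-linkage agglomeration and cut into `k` clusters.
#' Constant profiles (undefined correlation) take distance 1 to every other
#' gene, with a message. Cluster ids are renumbered by first appearance in
#' the dendrogram's leaf order.
#'
#' @param normalized Genes-by-cells normalized matrix.
#' @param genes Genes to cluster (at least `k`).
#' @param k Number of clusters (default 3).
#' @return List with `clusters` (named integer vector), `order` (leaf order
#'   of gene names) and `hclust` (the tree).
#' @export
hierarchical_gene_clusters <- function(normalized, genes, k = 3L) {
  stopifnot(length(genes) >= k)
  x <- as.matrix(normalized[genes, , drop = FALSE])
  cc <- suppressWarnings(cor(t(x)))
  if (anyNA(cc)) {
    message("constant gene profile(s); correlation distance set to 1")
    cc[is.na(cc)] <- 0
  }
  diag(cc) <- 1
  d <- as.dist(1 - cc)
  hc <- hclust(d, method = "average")
  raw <- cutree(hc, k = k)
  leaf <- hc$labels[hc$order]
  remap <- unique(raw[leaf])
  clusters <- match(raw, remap)
  names(clusters) <- names(raw)
  list(clusters = clusters, order = leaf, hclust = hc)
}
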