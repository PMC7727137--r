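make_counts <- function(n_genes = 50, n_cells = 40, seed = 1, mu = 2) {
  set.seed(seed)
  m <- matrix(rnbinom(n_genes * n_cells, mu = mu, size = 2),
              n_genes, n_cells,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("c%03d", seq_len(n_cells))))
  Matrix::Matrix(m, sparse = TRUE)
}

test_that("normalization rescales cells to the target sum on the log scale", {
  counts <- make_counts()
  norm <- normalize_log(counts, target_sum = 1e4)
  expect_equal(unname(Matrix::colSums(expm1(as.matrix(norm)))),
               rep(1e4, ncol(counts)), tolerance = 1e-9)
  expect_true(all(as.matrix(norm)[as.matrix(counts) == 0] == 0))
  ## a cell whose total equals target_sum keeps log1p of raw counts
  c2 <- counts
  c2[, 1] <- 0
  c2[1:10, 1] <- 1000                     # total = 1e4 = target_sum
  norm2 <- normalize_log(c2, target_sum = 1e4)
  expect_equal(as.numeric(norm2[1:10, 1]), rep(log1p(1000), 10))
})

test_that("normalization is invariant to integer scaling of a cell", {
  counts <- make_counts()
  scaled <- counts
  scaled[, 3] <- scaled[, 3] * 7
  expect_equal(as.numeric(normalize_log(counts)[, 3]),
               as.numeric(normalize_log(scaled)[, 3]))
})

test_that("all-zero cells are dropped with a warning", {
  counts <- make_counts()
  counts[, 5] <- 0
  expect_warning(norm <- normalize_log(counts), "all-zero")
  expect_equal(ncol(norm), ncol(counts) - 1L)
})

test_that("variance-inflated genes are always selected; mean bounds apply", {
  set.seed(2)
  n_cells <- 300
  base <- matrix(rpois(200 * n_cells, 5), 200, n_cells,
                 dimnames = list(sprintf("g%03d", 1:200),
                                 sprintf("c%03d", seq_len(n_cells))))
  ## same mean, 10x variance: a two-point mixture around 5
  base["g001", ] <- 5 + sample(c(-1, 1), n_cells, TRUE) * 7
  base["g001", base["g001", ] < 0] <- 0
  norm <- Matrix::Matrix(log1p(base), sparse = TRUE)  # bypass depth scaling
  sel <- select_hvg(norm, n_top = 20)
  expect_true("g001" %in% sel)

  stats_df <- attr(select_hvg(norm, n_top = 20), "stats")
  high_mean <- stats_df$gene[stats_df$mean > 3][1]
  selB <- select_hvg(norm, mode = "threshold", mean_bounds = c(0.0125, 3),
                     min_disp = -Inf)
  expect_false(high_mean %in% selB)
  expect_true(all(stats_df$mean[match(selB, stats_df$gene)] <= 3))
})

test_that("equal-distribution genes yield a full, unbiased count-mode panel", {
  counts <- make_counts(n_genes = 100, n_cells = 200, seed = 3)
  norm <- normalize_log(counts)
  sel <- select_hvg(norm, n_top = 60)
  expect_length(sel, 60)
})

test_that("PCA embedding has fixed signs, ranked variance and duplicates map together", {
  set.seed(4)
  n <- 120
  dominant <- rnorm(n, sd = 8)
  x <- rbind(outer(rep(1, 30), dominant) + rnorm(30 * n),
             matrix(rnorm(20 * n), 20, n))
  dimnames(x) <- list(sprintf("g%02d", 1:50), sprintf("c%03d", 1:n))
  x[, 2] <- x[, 1]                       # duplicated cell
  norm <- Matrix::Matrix(x, sparse = TRUE)
  pca <- scale_and_pca(norm, rownames(x), n_components = 5)
  expect_gt(pca$var_explained[1], max(pca$var_explained[-1]))
  expect_equal(pca$embedding[1, ], pca$embedding[2, ])
  ## sign convention: largest-magnitude loading positive
  for (j in 1:5) {
    l <- pca$loadings[, j]
    expect_gt(l[which.max(abs(l))], 0)
  }
  ## scaled view is standardized over fitting cells
  z <- (as.matrix(norm) - rowMeans(as.matrix(norm))) /
    apply(as.matrix(norm), 1, sd)
  expect_lt(max(abs(rowMeans(z))), 1e-6)
  expect_lt(max(abs(apply(z, 1, sd) - 1)), 1e-6)
})

test_that("states separate in PC space on simulated three-state data", {
  cfg <- test_config(n_cells_day1 = 450L)
  states <- rep(c("matNeu", "MPP", "MEP"), each = 150)
  counts <- simulate_expression(states, cfg, seed = 21)
  norm <- normalize_log(counts)
  hvg <- select_hvg(norm, n_top = 120)
  pca <- scale_and_pca(norm, hvg, n_components = 20)
  ## nearest-centroid classifier on the 20 PCs
  centroids <- apply(pca$embedding, 2, tapply, states, mean)
  d <- as.matrix(dist(rbind(centroids, pca$embedding)))[-(1:3), 1:3]
  pred <- rownames(centroids)[max.col(-d)]
  expect_gte(mean(pred == states), 0.95)
})

test_that("signature scores are means over present genes, with hard error when absent", {
  counts <- make_counts(n_genes = 10, n_cells = 5)
  norm <- normalize_log(counts)
  expect_equal(unname(score_signature(norm, "g001")),
               unname(as.numeric(norm["g001", ])))
  sc <- score_signature(norm, c("g001", "g002"))
  expect_equal(unname(sc),
               unname(as.numeric((norm["g001", ] + norm["g002", ]) / 2)))
  expect_error(score_signature(norm, c("nope1", "nope2")), "nope1")
  zero <- norm
  zero["g001", ] <- 0
  expect_equal(unname(score_signature(zero, "g001")), rep(0, 5))
})

test_that("the High/Low cut is the variance-minimizing split and behaves invariantly", {
  s <- c(a = 0, b = 0, c = 0, d = 10, e = 10)
  call <- call_hspc_program(s)
  expect_equal(call$threshold, 5)
  expect_equal(sum(call$labels == "High"), 2)
  ## translation invariance
  call2 <- call_hspc_program(s + 3.7)
  expect_equal(call2$threshold, call$threshold + 3.7)
  expect_identical(call2$labels, call$labels)
  ## order and duplication invariance
  call3 <- call_hspc_program(s[c(4, 2, 5, 1, 3)])
  expect_equal(call3$threshold, call$threshold)
  call4 <- call_hspc_program(c(s, s))
  expect_equal(call4$threshold, call$threshold)
  expect_warning(c5 <- call_hspc_program(c(x = 1, y = 1)), "constant")
  expect_true(all(c5$labels == "Low"))
})

test_that("High/Low calls recover the planted program states", {
  cfg <- test_config(n_cells_day1 = 700L)
  states <- sample(c("matNeu", "immNeu", "preNeu", "GMP", "CMP", "MPP", "MEP"),
                   700, replace = TRUE)
  counts <- simulate_expression(states, cfg, seed = 8)
  norm <- normalize_log(counts)
  call <- call_hspc_program(score_signature(norm, marker_signatures()$HSPC))
  truth <- ifelse(states %in% c("MPP", "GMP", "CMP", "MEP"), "High", "Low")
  expect_gte(mean(call$labels == truth), 0.95)
})

test_that("marker typing follows the strongest z-scored signature", {
  cfg <- test_config(n_cells_day1 = 300L)
  states <- rep(c("MEP", "matNeu", "GMP"), each = 100)
  counts <- simulate_expression(states, cfg, seed = 9)
  norm <- normalize_log(counts)
  ty <- assign_cell_type(norm, state_marker_sets()[c("MEP", "matNeu", "GMP")])
  expect_gte(mean(ty$type == states), 0.9)
  ## a cell expressing only the MEP markers among all marker genes
  mk <- unique(unlist(state_marker_sets()))
  solo <- norm
  solo[mk, 1] <- 0
  solo[c("Car1", "Hba-a1"), 1] <- max(norm)
  ty1 <- assign_cell_type(solo, state_marker_sets())
  expect_equal(ty1$type[1], "MEP")
  ## an all-zero cell is low-confidence
  z <- norm
  z[, 2] <- 0
  ty2 <- assign_cell_type(z, state_marker_sets())
  expect_false(ty2$confident[2])
})

test_that("rank-sum p-values agree with the exhaustive permutation oracle", {
  set.seed(10)
  for (sizes in list(c(3, 3), c(4, 4), c(5, 8))) {
    n <- sum(sizes)
    x <- matrix(c(rpois(10 * sizes[1], 3), rpois(10 * sizes[2], 6)),
                nrow = 10,
                dimnames = list(sprintf("g%02d", 1:10),
                                sprintf("c%02d", 1:n)))
    norm <- Matrix::Matrix(x, sparse = TRUE)
    a <- colnames(x)[seq_len(sizes[1])]
    b <- colnames(x)[sizes[1] + seq_len(sizes[2])]
    deg <- rank_sum_deg(norm, a, b)
    for (g in rownames(x)) {
      p_or <- oracle_perm_ranksum_p(x[g, a], x[g, b])
      expect_lt(abs(deg$p_val[deg$gene == g] - p_or) / p_or, 0.1)
    }
  }
})

test_that("the classic 3-vs-3 toy gives exact two-sided p of 0.1", {
  norm <- Matrix::Matrix(matrix(c(1, 2, 3, 4, 5, 6), 1,
                                dimnames = list("g1", paste0("c", 1:6))),
                         sparse = TRUE)
  deg <- rank_sum_deg(norm, paste0("c", 1:3), paste0("c", 4:6))
  expect_equal(deg$p_val, 0.1)
  expect_equal(deg$p_val,
               oracle_perm_ranksum_p(c(1, 2, 3), c(4, 5, 6)))
})

test_that("DEG pass flags respect both thresholds and BH monotonicity", {
  set.seed(12)
  n <- 60
  counts <- matrix(rnbinom(400 * 2 * n, mu = 3, size = 2), 400, 2 * n,
                   dimnames = list(sprintf("g%03d", 1:400),
                                   sprintf("c%03d", seq_len(2 * n))))
  counts["g001", seq_len(n)] <- rnbinom(n, mu = 12, size = 2)  # 4x shift
  norm <- normalize_log(Matrix::Matrix(counts, sparse = TRUE))
  norm["g002", ] <- 2                     # zero variance in both groups
  a <- colnames(counts)[seq_len(n)]
  b <- colnames(counts)[n + seq_len(n)]
  deg <- rank_sum_deg(norm, a, b)
  expect_true(deg$pass[deg$gene == "g001"])
  expect_equal(deg$p_val[deg$gene == "g002"], 1)
  expect_true(all(deg$p_val_adj >= deg$p_val - 1e-12))
  o <- order(deg$p_val)
  expect_true(all(diff(deg$p_val_adj[o]) >= -1e-12))
  ## the pass set shrinks as alpha decreases
  deg_strict <- rank_sum_deg(norm, a, b, alpha = 1e-6)
  expect_true(all(deg$gene[deg_strict$pass] %in% deg$gene[deg$pass]))
  ## pass requires the fold-change side too
  counts2 <- counts
  counts2["g003", n + seq_len(n)] <- rnbinom(n, mu = 12, size = 2)  # B-high
  norm2 <- normalize_log(Matrix::Matrix(counts2, sparse = TRUE))
  deg2 <- rank_sum_deg(norm2, a, b)
  expect_false(deg2$pass[deg2$gene == "g003"])   # logFC < 0 for A vs B
})

test_that("gene clustering recovers planted blocks and honors trivial cuts", {
  set.seed(13)
  n <- 150
  programs <- matrix(rnorm(3 * n), 3, n)
  genes <- sprintf("g%03d", 1:45)
  block <- rep(1:3, each = 15)
  x <- matrix(0, 45, n, dimnames = list(genes, sprintf("c%03d", 1:n)))
  for (i in 1:45) x[i, ] <- 2 * programs[block[i], ] + rnorm(n, sd = 0.4)
  norm <- Matrix::Matrix(x, sparse = TRUE)
  hc <- hierarchical_gene_clusters(norm, genes, k = 3)
  expect_gte(ari(hc$clusters, block), 0.9)
  ## two perfectly correlated genes co-cluster at any k < |genes|
  y <- x
  y["g002", ] <- 2 * y["g001", ] + 1
  hc2 <- hierarchical_gene_clusters(Matrix::Matrix(y, sparse = TRUE),
                                    genes, k = 10)
  expect_equal(hc2$clusters[["g001"]], hc2$clusters[["g002"]])
  ## k = |genes| gives singletons
  hc3 <- hierarchical_gene_clusters(norm, genes[1:5], k = 5)
  expect_equal(sort(unname(hc3$clusters)), 1:5)
  ## constant profile handled by convention
  z <- x
  z["g001", ] <- 3
  expect_message(hierarchical_gene_clusters(Matrix::Matrix(z, sparse = TRUE),
                                            genes, k = 3),
                 "constant")
})
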