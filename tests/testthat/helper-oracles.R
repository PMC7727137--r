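# Independent oracles used to validate the package's implementations on
# small inputs. These deliberately use different primitives (utils::adist,
# dense loops, exhaustive enumeration) than the implementations they check.

# All-pairs Hamming distance via adist with insertions/deletions disabled.
oracle_hamming <- function(a, b) {
  utils::adist(a, b, costs = list(ins = 1000, del = 1000, sub = 1))
}

# Brute-force per-cell Hamming merge at radius 1: repeatedly merge the
# lowest-count tag (lexicographic ties) that has a neighbor at distance <= 1
# with more than twice its count, into its highest-count such neighbor
# (lexicographically smaller on ties), until no merge applies.
oracle_hamming_merge <- function(tags, counts) {
  names(counts) <- tags
  repeat {
    live <- names(counts)[counts > 0]
    if (length(live) < 2L) break
    d <- oracle_hamming(live, live)
    done <- TRUE
    ord <- live[order(counts[live], live)]
    for (a in ord) {
      nb <- live[d[match(a, live), ] <= 1 & live != a &
                   counts[live] > 2 * counts[[a]]]
      if (length(nb)) {
        b <- nb[order(-counts[nb], nb)][1L]
        counts[[b]] <- counts[[b]] + counts[[a]]
        counts[[a]] <- 0
        done <- FALSE
        break
      }
    }
    if (done) break
  }
  counts
}

# Brute-force kNN edge set (sorted pair strings) with ties broken by index.
oracle_knn_edges <- function(emb, k) {
  n <- nrow(emb)
  pairs <- character(0)
  for (i in seq_len(n)) {
    d2 <- colSums((t(emb) - emb[i, ])^2)
    d2[i] <- Inf
    nb <- order(d2)[seq_len(k)]
    pairs <- c(pairs, paste(pmin(i, nb), pmax(i, nb)))
  }
  sort(unique(pairs))
}

# Brute-force all-pairs Jaccard matcher: for every day-7 cell, scan every
# day-1 cell; returns per day-7 cell the best similarity and the day-1 cells
# achieving it.
oracle_jaccard_match <- function(sigs1, sigs7, jaccard_min) {
  lapply(sigs7, function(s7) {
    j <- vapply(sigs1, function(s1)
      length(intersect(s1, s7)) / length(union(s1, s7)), numeric(1))
    best <- max(j)
    if (best < jaccard_min)
      list(best = NA_real_, cells = character(0))
    else
      list(best = best, cells = names(sigs1)[j == best])
  })
}

# Exhaustive-permutation two-sided rank-sum p-value (midranks for ties).
oracle_perm_ranksum_p <- function(x, y) {
  na <- length(x)
  vals <- c(x, y)
  r <- rank(vals)
  mu <- na * (length(vals) - na) / 2
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  splits <- utils::combn(length(vals), na)
  u_all <- apply(splits, 2L, function(ix) sum(r[ix]) - na * (na + 1) / 2)
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

# Adjusted Rand index (mclust is an independent implementation).
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# Small fast simulation config for unit tests.
test_config <- function(...) {
  args <- list(...)
  defaults <- list(n_cells_day1 = 200L, n_genes = 400L, seed = 42L)
  do.call(sim_config, utils::modifyList(defaults, args))
}

# Run the expression -> clustering stack used by several tests.
analyze_embedding <- function(counts, n_hvg = 150, n_pcs = 20, k = 15,
                              resolution = 1, seed = 1) {
  norm <- normalize_log(counts)
  hvg <- select_hvg(norm, n_top = n_hvg)
  pca <- scale_and_pca(norm, hvg, n_components = n_pcs)
  g <- knn_graph(pca$embedding, k = k)
  part <- cluster_graph_partition(g, resolution = resolution, seed = seed)
  list(norm = norm, pca = pca, graph = g, partition = part)
}
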