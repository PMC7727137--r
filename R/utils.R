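#' @importFrom stats uniroot qpois runif dpois rpois rnbinom rlnorm rnorm
#'   prcomp hclust cutree as.dist cor pnorm p.adjust quantile var sd
#' @importFrom methods as is
#' @importFrom utils write.table read.table head
NULL

NUC <- c("A", "C", "G", "T")

## Zero-truncated Poisson with a target *truncated* mean.
## Solves lambda / (1 - exp(-lambda)) = mean, then samples by inverse CDF
## conditional on X >= 1. mean must be > 1 (mean -> 1 collapses to all ones).
ztpois_lambda <- function(mean) {
  stopifnot(mean >= 1)
  if (mean <= 1 + 1e-9) return(1e-9)
  uniroot(function(l) l / (1 - exp(-l)) - mean,
          interval = c(1e-9, mean * 10), tol = 1e-10)$root
}

rztpois <- function(n, mean, max = Inf) {
  lam <- ztpois_lambda(mean)
  p0 <- dpois(0, lam)
  x <- qpois(p0 + runif(n) * (1 - p0), lam)
  x[x < 1L] <- 1L           # guard against numeric edge at p0
  pmin(x, max)
}

## Random fixed-length nucleotide strings; `unique` retries until distinct.
## When n covers most of the 4^width sequence space, rejection sampling
## degenerates (coupon collector), so the space is enumerated instead.
random_nt <- function(n, width, unique = FALSE) {
  space <- 4^width
  if (unique && n > space)
    stop("cannot draw ", n, " distinct sequences of width ", width)
  if (unique && n > 0.25 * space && width <= 10) {
    grid <- do.call(expand.grid, rep(list(NUC), width))
    all_seqs <- do.call(paste0, grid)
    return(sample(all_seqs, n))
  }
  draw <- function(k) {
    m <- matrix(sample(NUC, k * width, replace = TRUE), nrow = k)
    apply(m, 1L, paste0, collapse = "")
  }
  s <- draw(n)
  if (unique) {
    while (anyDuplicated(s)) {
      dup <- duplicated(s)
      s[dup] <- draw(sum(dup))
    }
  }
  s
}

## Pairwise Hamming distances between equal-length strings (small sets).
hamming_matrix <- function(tags) {
  k <- length(tags)
  if (k == 0L) return(matrix(0L, 0L, 0L))
  chars <- matrix(unlist(strsplit(tags, "", fixed = TRUE), use.names = FALSE),
                  ncol = k)
  d <- matrix(0L, k, k, dimnames = list(tags, tags))
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      d[i, j] <- d[j, i] <- sum(chars[, i] != chars[, j])
    }
  }
  d
}

## Substitute bases at a per-base error rate; errors pick one of the 3 other bases.
mutate_seq <- function(seqs, error_rate) {
  if (error_rate <= 0) return(seqs)
  chars <- strsplit(seqs, "", fixed = TRUE)
  lens <- lengths(chars)
  flat <- unlist(chars, use.names = FALSE)
  hit <- runif(length(flat)) < error_rate
  if (any(hit)) {
    repl <- sample(NUC, sum(hit), replace = TRUE)
    same <- repl == flat[hit]
    while (any(same)) {
      repl[same] <- sample(NUC, sum(same), replace = TRUE)
      same <- repl == flat[hit]
    }
    flat[hit] <- repl
  }
  vapply(split(flat, rep.int(seq_along(lens), lens)),
         paste0, character(1), collapse = "")
}

## Deterministic per-stage seeds fanned out from one global seed.
stage_seed <- function(seed, stage) {
  offsets <- c(clones = 101L, reprogram = 211L, expression = 307L,
               reads = 401L, analysis = 503L, partition = 601L)
  if (!stage %in% names(offsets)) stop("unknown stage: ", stage)
  (as.integer(seed) + offsets[[stage]]) %% .Machine$integer.max
}

`%||%` <- function(a, b) if (is.null(a)) b else a
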