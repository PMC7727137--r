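#' Default state-transition graphs for chemical-cocktail reprogramming
#'
#' `default_transition_graph()` encodes the reprogramming routes observed
#' among neutrophil-derived cells: mature neutrophils revert to immature and
#' (skipping a stage) preneutrophils; immature neutrophils to preneutrophils
#' or MEP; preneutrophils mostly directly to MPP, with minority routes into
#' GMP and MEP; GMP to CMP; CMP to MPP or MEP; MPP to MEP.
#'
#' `full_transition_graph()` extends it with the non-neutrophil day-1
#' lineages (eosinophil, macrophage, basophil, erythrocyte, T cell), all of
#' which reprogram into MPP.
#'
#' `fate_transition_graph()` is the preset for fate-map (Sankey) cohorts:
#' every successfully reprogrammed clone of every lineage lands in an
#' HSPC-program state, so the planted lineage contribution among induced
#' HSPC-high cells equals the initial lineage composition in expectation.
#'
#' @return Named list: for each source state, a named numeric vector of
#'   target-state probabilities summing to 1.
#' @export
default_transition_graph <- function() {
  list(
    matNeu = c(immNeu = 0.6, preNeu = 0.4),
    immNeu = c(preNeu = 0.8, MEP = 0.2),
    preNeu = c(MPP = 0.7, GMP = 0.2, MEP = 0.1),
    GMP = c(CMP = 1),
    CMP = c(MPP = 0.6, MEP = 0.4),
    MPP = c(MEP = 1)
  )
}

#' @rdname default_transition_graph
#' @export
full_transition_graph <- function() {
  c(default_transition_graph(),
    list(eosinophil = c(MPP = 1), macrophage = c(MPP = 1),
         basophil = c(MPP = 1), erythrocyte = c(MPP = 1),
         Tcell = c(MPP = 1)))
}

#' @rdname default_transition_graph
#' @export
fate_transition_graph <- function() {
  neu <- c(MPP = 0.7, GMP = 0.2, CMP = 0.05, MEP = 0.05)
  list(matNeu = neu, immNeu = neu, preNeu = neu,
       eosinophil = c(MPP = 1), macrophage = c(MPP = 1),
       basophil = c(MPP = 1), erythrocyte = c(MPP = 1),
       Tcell = c(MPP = 1))
}

#' Default day-1 state composition
#'
#' Lineage proportions follow the observed contributions of initial lineages
#' to induced HSPC-program cells: 43% neutrophil (split over the three
#' maturation stages), 30% eosinophil, 15% macrophage, 6% basophil,
#' 3% erythrocyte and 3% T cell.
#'
#' @return Named numeric vector over day-1 states, summing to 1.
#' @export
default_initial_composition <- function() {
  c(matNeu = 0.25, immNeu = 0.10, preNeu = 0.08,
    eosinophil = 0.30, macrophage = 0.15, basophil = 0.06,
    erythrocyte = 0.03, Tcell = 0.03)
}

#' Simulation configuration for a two-timepoint barcoded cohort
#'
#' Bundles and validates every knob of the synthetic-data generator. The
#' defaults emulate the study conditions of a CellTag reprogramming
#' experiment: 1 to 40 eight-nucleotide tags per cell with mean 2, two
#' timepoints (day 1 and day 7), seven hematopoietic cell states with
#' marker-gene expression shifts, and a reprogramming transition graph over
#' those states.
#'
#' @param n_cells_day1 Number of day-1 cells.
#' @param n_genes Size of the gene universe (marker genes included).
#' @param tag_pool_size Number of distinct tags in the lentiviral pool.
#' @param tags_per_cell_mean Mean of the zero-truncated Poisson tag count
#'   per cell (default 2).
#' @param tags_per_cell_max Hard cap on tags per cell (default 40).
#' @param tag_length Tag length in nucleotides (default 8).
#' @param motif_prefix,motif_suffix Constant sequences flanking the tag in
#'   the transcript (defaults `"GGT"` / `"GAATTC"`, the v1 construct
#'   convention; configurable).
#' @param clone_size_day1_mean Mean day-1 cells per clone (zero-truncated
#'   Poisson; cells expand briefly before the day-1 harvest).
#' @param day7_cells_per_clone_mean Mean day-7 cells per clone.
#' @param umis_per_tag_mean,reads_per_umi_mean Depth model: zero-truncated
#'   Poisson UMIs per (cell, tag) molecule and reads per UMI.
#' @param read_length R2 read length; must fit prefix + tag + suffix.
#' @param seq_error_rate Per-base substitution probability on R2 reads.
#' @param tag_dropout Per-(cell, tag) probability that a tag is not
#'   observed in that cell (models tag silencing/dropout; default 0).
#' @param initial_composition Named vector of day-1 state fractions.
#' @param transition_graph Named list mapping each day-1 state to a named
#'   probability vector over day-7 states (one-hop fate draw per clone).
#' @param reprogram_fraction Probability that a clone transitions at all;
#'   with probability `1 - reprogram_fraction` it self-loops (reprogramming
#'   failure).
#' @param dispersion Negative-binomial dispersion of counts (variance =
#'   mu + dispersion * mu^2); 0 gives the Poisson limit.
#' @param marker_fold Fold elevation of a state's own marker genes.
#' @param program_fold Fold elevation of the HSPC program genes in
#'   HSPC-program states and of neutrophil identity genes in neutrophil
#'   states.
#' @param state_block_genes,state_block_fold Size and fold elevation of the
#'   exclusive block of background genes each state over-expresses (cell
#'   states differ by broad programs, not only diagnostic markers).
#' @param lib_size_meanlog,lib_size_sdlog Log-normal library-size model.
#' @param seed Integer seed; all generator stages derive their streams
#'   from it.
#' @return Object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_cells_day1 = 2000,
                       n_genes = 400,
                       tag_pool_size = 65536,
                       tags_per_cell_mean = 2,
                       tags_per_cell_max = 40,
                       tag_length = 8,
                       motif_prefix = "GGT",
                       motif_suffix = "GAATTC",
                       clone_size_day1_mean = 2,
                       day7_cells_per_clone_mean = 2,
                       umis_per_tag_mean = 4,
                       reads_per_umi_mean = 2,
                       read_length = 40,
                       seq_error_rate = 0.01,
                       tag_dropout = 0,
                       initial_composition = default_initial_composition(),
                       transition_graph = full_transition_graph(),
                       reprogram_fraction = 0.7,
                       dispersion = 0.25,
                       marker_fold = 10,
                       program_fold = 6,
                       state_block_genes = 25L,
                       state_block_fold = 8,
                       lib_size_meanlog = log(2500),
                       lib_size_sdlog = 0.3,
                       seed = 1L) {
  cfg <- list(n_cells_day1 = as.integer(n_cells_day1),
              n_genes = as.integer(n_genes),
              tag_pool_size = as.integer(tag_pool_size),
              tags_per_cell_mean = tags_per_cell_mean,
              tags_per_cell_max = as.integer(tags_per_cell_max),
              tag_length = as.integer(tag_length),
              motif_prefix = motif_prefix, motif_suffix = motif_suffix,
              clone_size_day1_mean = clone_size_day1_mean,
              day7_cells_per_clone_mean = day7_cells_per_clone_mean,
              umis_per_tag_mean = umis_per_tag_mean,
              reads_per_umi_mean = reads_per_umi_mean,
              read_length = as.integer(read_length),
              seq_error_rate = seq_error_rate,
              tag_dropout = tag_dropout,
              initial_composition = initial_composition,
              transition_graph = transition_graph,
              reprogram_fraction = reprogram_fraction,
              dispersion = dispersion,
              marker_fold = marker_fold,
              program_fold = program_fold,
              state_block_genes = as.integer(state_block_genes),
              state_block_fold = state_block_fold,
              lib_size_meanlog = lib_size_meanlog,
              lib_size_sdlog = lib_size_sdlog,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_cells_day1 >= 1, cfg$n_genes >= 1, cfg$tag_pool_size >= 1,
            cfg$tags_per_cell_mean >= 1, cfg$tags_per_cell_max >= 1,
            cfg$tag_length >= 1)
  probs <- c(cfg$seq_error_rate, cfg$tag_dropout, cfg$reprogram_fraction,
             cfg$initial_composition, unlist(cfg$transition_graph))
  if (any(probs < 0 | probs > 1))
    stop("all fractions and probabilities must lie in [0, 1]")
  if (abs(sum(cfg$initial_composition) - 1) > 1e-9)
    stop("initial_composition must sum to 1")
  rowsums <- vapply(cfg$transition_graph, sum, numeric(1))
  if (any(abs(rowsums - 1) > 1e-9))
    stop("per-state transition probabilities must sum to 1")
  missing <- setdiff(names(cfg$initial_composition), names(cfg$transition_graph))
  if (length(missing))
    stop("day-1 states absent from the transition graph: ",
         paste(missing, collapse = ", "))
  if (nchar(cfg$motif_prefix) + cfg$tag_length + nchar(cfg$motif_suffix) >
      cfg$read_length)
    stop("motif_prefix + tag + motif_suffix does not fit in read_length")
  invisible(cfg)
}

#' Assign clones and tag sets to day-1 cells
#'
#' Cells are grouped into clones (clone sizes zero-truncated Poisson); each
#' clone receives a tag set sampled independently from the tag pool, with the
#' per-clone tag count drawn from a zero-truncated Poisson with the
#' configured mean, clipped to `[1, tags_per_cell_max]`. All cells of a clone
#' carry an identical tag set. A warning is emitted when the expected number
#' of tag collisions between distinct clones is high (collisions are a
#' realistic confounder and are allowed).
#'
#' @param config A [sim_config()].
#' @return List with `cells` (data frame `cell_id`, `clone_id`), `clone_tags`
#'   (named list clone -> tag set) and `tag_pool`.
#' @export
simulate_clones <- function(config) {
  validate_sim_config(config)
  set.seed(stage_seed(config$seed, "clones"))
  n <- config$n_cells_day1
  sizes <- integer(0)
  while (sum(sizes) < n)
    sizes <- c(sizes, rztpois(max(16L, ceiling(n / config$clone_size_day1_mean)),
                              config$clone_size_day1_mean))
  sizes <- sizes[cumsum(sizes) - sizes < n]
  sizes[length(sizes)] <- n - sum(sizes[-length(sizes)])
  n_clones <- length(sizes)

  ## clones are only confusable when their tag sets coincide; in practice
  ## that means two single-tag clones drawing the same tag
  lam <- ztpois_lambda(config$tags_per_cell_mean)
  p1 <- lam * exp(-lam) / (1 - exp(-lam))
  exp_collisions <- choose(p1 * n_clones, 2) / config$tag_pool_size
  if (exp_collisions > max(1, 0.01 * n_clones))
    warning(sprintf(
      "expected identical-tag-set clone collisions (%.1f) are high relative to %d clones; consider a larger tag_pool_size",
      exp_collisions, n_clones))

  pool <- random_nt(config$tag_pool_size, config$tag_length, unique = TRUE)
  n_tags <- rztpois(n_clones, config$tags_per_cell_mean,
                    max = config$tags_per_cell_max)
  clone_ids <- sprintf("clone%05d", seq_len(n_clones))
  clone_tags <- lapply(seq_len(n_clones), function(i)
    sort(sample(pool, n_tags[i], replace = FALSE)))
  names(clone_tags) <- clone_ids

  cells <- data.frame(
    cell_id = sprintf("d1_%05d", seq_len(n)),
    clone_id = rep(clone_ids, sizes),
    stringsAsFactors = FALSE
  )
  list(cells = cells, clone_tags = clone_tags, tag_pool = pool)
}

#' Draw day-7 fates by walking the transition graph
#'
#' Each traced clone takes a single hop: with probability
#' `reprogram_fraction` its day-7 state is drawn from the transition graph's
#' edge distribution for its day-1 state, otherwise it self-loops
#' (reprogramming failure).
#'
#' @param day1_states Character vector of day-1 states (one per clone).
#' @param transition_graph Named list of named probability vectors.
#' @param reprogram_fraction Probability that a clone transitions at all.
#' @param seed Integer seed.
#' @return Character vector of day-7 states, same length and order.
#' @export
simulate_reprogramming <- function(day1_states, transition_graph,
                                   reprogram_fraction = 1, seed = 1L) {
  unknown <- setdiff(unique(day1_states), names(transition_graph))
  if (length(unknown))
    stop("unknown state label(s) in transition graph: ",
         paste(unknown, collapse = ", "))
  set.seed(stage_seed(seed, "reprogram"))
  out <- day1_states
  go <- runif(length(day1_states)) < reprogram_fraction
  for (s in unique(day1_states[go])) {
    idx <- which(go & day1_states == s)
    edges <- transition_graph[[s]]
    out[idx] <- sample(names(edges), length(idx), replace = TRUE, prob = edges)
  }
  out
}

## Build the per-state relative expression profile matrix (genes x states).
## Baseline gene means are drawn once (log-normal); marker genes are
## multiplied by marker_fold in their own state and program genes by
## program_fold in the states carrying the program. Each state additionally
## receives an exclusive block of `state_block_genes` filler genes elevated
## state_block_fold-fold: cell states differ by broad expression programs,
## not only by their two diagnostic markers.
state_mean_matrix <- function(config, states) {
  sigs <- marker_signatures()
  lin <- lineage_marker_sets()
  needed <- unique(c(unlist(sigs), unlist(lin)))
  n_fill <- config$n_genes - length(needed)
  if (n_fill < 0)
    stop("n_genes too small for the marker gene universe (need >= ",
         length(needed), ")")
  genes <- c(needed, sprintf("Gene%04d", seq_len(n_fill)))
  base <- rlnorm(length(genes), meanlog = log(0.3), sdlog = 0.8)
  names(base) <- genes
  profiles <- matrix(rep(base, length(states)), ncol = length(states),
                     dimnames = list(genes, states))
  marker_of <- c(sigs[intersect(states, names(sigs))],
                 lin[intersect(states, names(lin))])
  for (s in names(marker_of)) {
    mk <- marker_of[[s]]
    absent <- setdiff(mk, genes)
    if (length(absent))
      stop("marker gene absent from gene universe: ",
           paste(absent, collapse = ", "))
    profiles[mk, s] <- profiles[mk, s] * config$marker_fold
  }
  hspc_states <- intersect(states, HSPC_STATES)
  profiles[sigs$HSPC, hspc_states] <-
    profiles[sigs$HSPC, hspc_states] * config$program_fold
  neu_states <- intersect(states, NEUTROPHIL_STATES)
  profiles[sigs$neutrophil, neu_states] <-
    profiles[sigs$neutrophil, neu_states] * config$program_fold
  ## exclusive per-state program blocks over the filler genes (assigned in
  ## sorted state order so the mapping is stable across cohorts)
  if (n_fill > 0 && config$state_block_genes > 0) {
    fillers <- genes[(length(needed) + 1L):length(genes)]
    block_states <- sort(states)
    bs <- min(config$state_block_genes,
              floor(length(fillers) / length(block_states)))
    if (bs > 0) {
      for (si in seq_along(block_states)) {
        blk <- fillers[((si - 1L) * bs + 1L):(si * bs)]
        profiles[blk, block_states[si]] <-
          profiles[blk, block_states[si]] * config$state_block_fold
      }
    }
  }
  profiles
}

#' Simulate a count matrix for labelled cells
#'
#' Counts are negative-binomial around per-state mean profiles (marker genes
#' elevated over a shared baseline) with log-normal library sizes.
#'
#' @param states Character vector of per-cell state labels; names (if any)
#'   become cell ids.
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @param profiles Optional precomputed genes-by-states profile matrix (so
#'   both timepoints share one baseline).
#' @return Sparse `dgCMatrix`, genes by cells.
#' @export
simulate_expression <- function(states, config, seed = config$seed,
                                profiles = NULL) {
  set.seed(stage_seed(seed, "expression"))
  if (is.null(profiles))
    profiles <- state_mean_matrix(config, unique(states))
  miss <- setdiff(unique(states), colnames(profiles))
  if (length(miss))
    stop("no expression profile for state(s): ", paste(miss, collapse = ", "))
  n <- length(states)
  libs <- rlnorm(n, config$lib_size_meanlog, config$lib_size_sdlog)
  size <- 1 / max(config$dispersion, 1e-8)
  p <- sweep(profiles, 2L, colSums(profiles), "/")
  counts <- matrix(0L, nrow(profiles), n,
                   dimnames = list(rownames(profiles),
                                   names(states) %||% sprintf("cell%05d", seq_len(n))))
  for (s in unique(states)) {
    idx <- which(states == s)
    mu <- outer(p[, s], libs[idx])
    counts[, idx] <- rnbinom(length(mu), size = size, mu = mu)
  }
  as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
}

#' Realize tag reads as a paired-read table
#'
#' For each observed (cell, tag) pair, UMIs and reads per UMI are drawn from
#' zero-truncated Poisson depth models; each R2 read carries
#' `motif_prefix + tag + motif_suffix` at a random offset, padded with random
#' bases to `read_length`, with per-base substitution errors at
#' `seq_error_rate`.
#'
#' @param assignment Data frame with columns `cell_barcode` and `tag`, one
#'   row per (cell, tag) pair.
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return Data frame (`cell_barcode`, `umi`, `sequence`), one row per read.
#' @export
emit_reads <- function(assignment, config, seed = config$seed) {
  validate_sim_config(config)
  set.seed(stage_seed(seed, "reads"))
  if (nrow(assignment) == 0L)
    return(data.frame(cell_barcode = character(0), umi = character(0),
                      sequence = character(0)))
  n_umis <- rztpois(nrow(assignment), config$umis_per_tag_mean)
  mol <- data.frame(
    cell_barcode = rep(assignment$cell_barcode, n_umis),
    tag = rep(assignment$tag, n_umis),
    stringsAsFactors = FALSE
  )
  mol$umi <- random_nt(nrow(mol), 12L)
  n_reads <- rztpois(nrow(mol), config$reads_per_umi_mean)
  reads <- mol[rep(seq_len(nrow(mol)), n_reads), , drop = FALSE]

  construct <- paste0(config$motif_prefix, reads$tag, config$motif_suffix)
  clen <- nchar(config$motif_prefix) + config$tag_length +
    nchar(config$motif_suffix)
  pad <- config$read_length - clen
  left <- if (pad > 0) sample.int(pad + 1L, nrow(reads), replace = TRUE) - 1L
          else integer(nrow(reads))
  draw_pad <- function(k)
    if (k > 0) paste(sample(NUC, k, replace = TRUE), collapse = "") else ""
  lpad <- vapply(left, draw_pad, character(1))
  rpad <- vapply(pad - left, draw_pad, character(1))
  seqs <- paste0(lpad, construct, rpad)
  ## in the real construct the tag's flanks are fixed vector sequence that
  ## cannot spoof the motif anchor; redraw any padding that creates a
  ## spurious leftmost match so error-free reads extract their true tag
  pattern <- paste0(config$motif_prefix,
                    "([ACGTN]{", config$tag_length, "})", config$motif_suffix)
  for (iter in seq_len(50L)) {
    m <- regexpr(pattern, seqs, perl = TRUE)
    start <- as.integer(m) + nchar(config$motif_prefix)
    got <- substr(seqs, start, start + config$tag_length - 1L)
    bad <- which(m < 0L | got != reads$tag)
    if (!length(bad)) break
    lpad[bad] <- vapply(left[bad], draw_pad, character(1))
    rpad[bad] <- vapply(pad - left[bad], draw_pad, character(1))
    seqs[bad] <- paste0(lpad[bad], construct[bad], rpad[bad])
  }
  seqs <- mutate_seq(seqs, config$seq_error_rate)
  out <- data.frame(cell_barcode = reads$cell_barcode, umi = reads$umi,
                    sequence = seqs, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Simulate a reprogramming-trajectory cohort with transitional cells
#'
#' Models the induced (day-7) cohort in which reprogramming is caught in
#' flight: each clone starts from a neutrophil maturation stage and performs
#' a multi-step walk along the transition graph; each of its cells is a
#' snapshot at a uniformly random position along that walk, with cells
#' falling inside an edge expressed as a blend of the two endpoint state
#' profiles. The traversed state pairs are the planted adjacencies a
#' cluster-graph trajectory analysis should recover.
#'
#' @param config A [sim_config()]; the transition graph must cover the
#'   start-state composition.
#' @param n_cells Number of cells in the cohort.
#' @param start_composition Composition of clone start states (default the
#'   three neutrophil stages, mature-skewed).
#' @param max_steps Maximum walk length in transitions (default 4).
#' @param seed Integer seed (defaults to the config's).
#' @return List with `cells` (data frame `cell_id`, `clone_id`, `state`
#'   (nearest state), `src`, `tgt`, `blend`), `counts` (genes x cells),
#'   `traversed` (data frame of planted state adjacencies `from`, `to`) and
#'   `config`.
#' @export
simulate_trajectory_cohort <- function(config = sim_config(),
                                       n_cells = 1500,
                                       start_composition = c(matNeu = 0.5,
                                                             immNeu = 0.3,
                                                             preNeu = 0.2),
                                       max_steps = 4L,
                                       seed = config$seed) {
  graph <- config$transition_graph
  unknown <- setdiff(names(start_composition), names(graph))
  if (length(unknown))
    stop("start state(s) missing from transition graph: ",
         paste(unknown, collapse = ", "))
  set.seed(stage_seed(seed, "reprogram") + 7L)
  n_clones <- max(2L, round(n_cells / config$day7_cells_per_clone_mean))
  walks <- lapply(seq_len(n_clones), function(i) {
    s <- sample(names(start_composition), 1L, prob = start_composition)
    path <- s
    for (step in seq_len(max_steps)) {
      edges <- graph[[path[length(path)]]]
      if (is.null(edges)) break
      path <- c(path, sample(names(edges), 1L, prob = edges))
    }
    path
  })
  sizes <- rztpois(n_clones, config$day7_cells_per_clone_mean)
  total <- sum(sizes)
  clone_of <- rep(seq_len(n_clones), sizes)
  pos <- runif(total)                      # position along each cell's walk
  src <- character(total)
  tgt <- character(total)
  blend <- numeric(total)
  for (c_i in seq_len(total)) {
    path <- walks[[clone_of[c_i]]]
    l <- length(path) - 1L
    if (l == 0L) {
      src[c_i] <- tgt[c_i] <- path[1L]
      blend[c_i] <- 0
    } else {
      x <- pos[c_i] * l
      k <- pmin(floor(x), l - 1L)
      src[c_i] <- path[k + 1L]
      tgt[c_i] <- path[k + 2L]
      b <- x - k
      ## stage-wise conversion: cells dwell at states and cross edges
      ## quickly, so mid-edge density is thinned while bridges remain
      blend[c_i] <- b^3 / (b^3 + (1 - b)^3)
    }
  }
  state <- ifelse(blend < 0.5, src, tgt)
  ids <- sprintf("tc_%05d", seq_len(total))

  all_states <- unique(c(unlist(lapply(walks, identity)), names(graph)))
  set.seed(stage_seed(seed, "expression") + 7L)
  profiles <- state_mean_matrix(config, all_states)
  p <- sweep(profiles, 2L, colSums(profiles), "/")
  mu_rel <- p[, src, drop = FALSE] * rep(1 - blend, each = nrow(p)) +
    p[, tgt, drop = FALSE] * rep(blend, each = nrow(p))
  libs <- rlnorm(total, config$lib_size_meanlog, config$lib_size_sdlog)
  mu <- sweep(mu_rel, 2L, libs / colSums(mu_rel), "*")
  size <- 1 / max(config$dispersion, 1e-8)
  counts <- matrix(rnbinom(length(mu), size = size, mu = mu),
                   nrow(mu), ncol(mu), dimnames = list(rownames(p), ids))
  traversed <- unique(do.call(rbind, lapply(walks, function(path) {
    if (length(path) < 2L) return(NULL)
    data.frame(from = path[-length(path)], to = path[-1L],
               stringsAsFactors = FALSE)
  })))
  traversed <- traversed[traversed$from != traversed$to, , drop = FALSE]
  rownames(traversed) <- NULL
  list(cells = data.frame(cell_id = ids,
                          clone_id = sprintf("clone%05d", clone_of),
                          state = state, src = src, tgt = tgt, blend = blend,
                          stringsAsFactors = FALSE),
       counts = as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix"),
       traversed = traversed,
       config = config)
}

#' Simulate a complete two-timepoint barcoded reprogramming experiment
#'
#' Composes [simulate_clones()], [simulate_reprogramming()] and
#' [simulate_expression()] into a full cohort with ground truth: day-1 cells
#' with lineage states, clonal tag sets, day-7 descendants with reprogrammed
#' states, observed per-cell tag signatures (after optional tag dropout) and
#' genes-by-cells count matrices for both timepoints.
#'
#' @param config A [sim_config()].
#' @param expression Logical; simulate count matrices (set `FALSE` for
#'   tag-only studies, where only clone structure is needed).
#' @return Object of class `sim_experiment`: list with `cells_day1`,
#'   `cells_day7` (data frames: `cell_id`, `cell_barcode`, `clone_id`,
#'   `state`, `lineage`, and for day 7 `hspc_truth`), `clones` (per-clone
#'   truth), `signatures` (`day1`/`day7` named lists of observed tag sets;
#'   cells that lost every tag are absent), `counts` (`day1`/`day7` sparse
#'   matrices or `NULL`), and `config`.
#' @export
simulate_experiment <- function(config = sim_config(), expression = TRUE) {
  validate_sim_config(config)
  cl <- simulate_clones(config)
  cells1 <- cl$cells
  clone_ids <- names(cl$clone_tags)
  n_clones <- length(clone_ids)

  ## plant the composition exactly (largest-remainder apportionment at the
  ## clone level, then shuffle) so configured contributions are the truth
  ## rather than one multinomial draw from it
  set.seed(stage_seed(config$seed, "clones") + 1L)
  comp <- config$initial_composition
  quota <- comp * n_clones
  n_per <- floor(quota)
  rem <- n_clones - sum(n_per)
  if (rem > 0) {
    top_up <- order(quota - n_per, decreasing = TRUE)[seq_len(rem)]
    n_per[top_up] <- n_per[top_up] + 1L
  }
  clone_state <- sample(rep(names(comp), n_per))
  names(clone_state) <- clone_ids
  cells1$state <- unname(clone_state[cells1$clone_id])
  cells1$lineage <- state_to_lineage(cells1$state)

  day7_state <- simulate_reprogramming(unname(clone_state),
                                       config$transition_graph,
                                       config$reprogram_fraction,
                                       seed = config$seed)
  names(day7_state) <- clone_ids

  set.seed(stage_seed(config$seed, "clones") + 2L)
  n7 <- rztpois(n_clones, config$day7_cells_per_clone_mean)
  cells7 <- data.frame(
    cell_id = sprintf("d7_%05d", seq_len(sum(n7))),
    clone_id = rep(clone_ids, n7),
    stringsAsFactors = FALSE
  )
  cells7$state <- unname(day7_state[cells7$clone_id])
  cells7$lineage <- state_to_lineage(unname(clone_state[cells7$clone_id]))
  cells7$hspc_truth <- ifelse(cells7$state %in% HSPC_STATES, "High", "Low")

  barcodes <- random_nt(nrow(cells1) + nrow(cells7), 16L, unique = TRUE)
  cells1$cell_barcode <- barcodes[seq_len(nrow(cells1))]
  cells7$cell_barcode <- barcodes[nrow(cells1) + seq_len(nrow(cells7))]

  observe <- function(cells) {
    sigs <- cl$clone_tags[cells$clone_id]
    names(sigs) <- cells$cell_id
    if (config$tag_dropout > 0) {
      sigs <- lapply(sigs, function(t) t[runif(length(t)) >= config$tag_dropout])
      sigs <- sigs[lengths(sigs) > 0L]
    }
    sigs
  }
  set.seed(stage_seed(config$seed, "clones") + 3L)
  signatures <- list(day1 = observe(cells1), day7 = observe(cells7))

  counts <- NULL
  if (expression) {
    all_states <- unique(c(cells1$state, cells7$state))
    set.seed(stage_seed(config$seed, "expression"))
    profiles <- state_mean_matrix(config, all_states)
    s1 <- cells1$state; names(s1) <- cells1$cell_id
    s7 <- cells7$state; names(s7) <- cells7$cell_id
    counts <- list(
      day1 = simulate_expression(s1, config, seed = config$seed,
                                 profiles = profiles),
      day7 = simulate_expression(s7, config, seed = config$seed + 1L,
                                 profiles = profiles)
    )
  }

  clones <- data.frame(
    clone_id = clone_ids,
    day1_state = unname(clone_state),
    day7_state = unname(day7_state),
    lineage = state_to_lineage(unname(clone_state)),
    n_tags = lengths(cl$clone_tags),
    tags = vapply(cl$clone_tags, paste, character(1), collapse = ","),
    n_day1 = as.integer(table(factor(cells1$clone_id, levels = clone_ids))),
    n_day7 = as.integer(table(factor(cells7$clone_id, levels = clone_ids))),
    stringsAsFactors = FALSE
  )
  rownames(clones) <- NULL

  structure(list(cells_day1 = cells1, cells_day7 = cells7, clones = clones,
                 clone_tags = cl$clone_tags, signatures = signatures,
                 counts = counts, config = config),
            class = "sim_experiment")
}

#' @export
print.sim_experiment <- function(x, ...) {
  cat("sim_experiment:", nrow(x$cells_day1), "day-1 cells,",
      nrow(x$cells_day7), "day-7 cells,", nrow(x$clones), "clones\n")
  cat("  states day 7:",
      paste(sprintf("%s=%d", names(table(x$cells_day7$state)),
                    table(x$cells_day7$state)), collapse = " "), "\n")
  invisible(x)
}

#' Expand observed signatures into a (cell_barcode, tag) assignment table
#'
#' @param sim A [simulate_experiment()] result.
#' @param timepoint `"day1"` or `"day7"`.
#' @return Data frame (`cell_id`, `cell_barcode`, `tag`).
#' @export
tag_assignment <- function(sim, timepoint = c("day1", "day7")) {
  timepoint <- match.arg(timepoint)
  sigs <- sim$signatures[[timepoint]]
  cells <- if (timepoint == "day1") sim$cells_day1 else sim$cells_day7
  bc <- cells$cell_barcode
  names(bc) <- cells$cell_id
  data.frame(
    cell_id = rep(names(sigs), lengths(sigs)),
    cell_barcode = rep(unname(bc[names(sigs)]), lengths(sigs)),
    tag = unlist(sigs, use.names = FALSE),
    stringsAsFactors = FALSE
  )
}
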