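test_that("config validation rejects inconsistent study designs", {
  expect_error(sim_config(initial_composition = c(matNeu = 0.5, MPP = 0.4)),
               "sum to 1")
  expect_error(sim_config(transition_graph = list(matNeu = c(immNeu = 0.5)),
                          initial_composition = c(matNeu = 1)),
               "sum to 1")
  expect_error(sim_config(initial_composition = c(unknownState = 1)),
               "absent from the transition graph")
  expect_error(sim_config(seq_error_rate = 1.5), "\\[0, 1\\]")
  expect_error(sim_config(read_length = 10), "does not fit")
})

test_that("tags per cell follow the truncated-Poisson law with mean 2, max 40", {
  cfg <- test_config(n_cells_day1 = 10000L, clone_size_day1_mean = 1)
  ## 10,000 single-cell clones genuinely saturate the 8-mer pool; the
  ## collision warning is expected at this scale
  cl <- suppressWarnings(simulate_clones(cfg))
  per_cell <- lengths(cl$clone_tags)[cl$cells$clone_id]
  expect_gte(mean(per_cell), 1.8)
  expect_lte(mean(per_cell), 2.2)
  expect_lte(max(per_cell), 40)
  expect_gte(min(per_cell), 1)
})

test_that("the truncated tag-count distribution collapses to 1 at its floor", {
  cfg <- test_config(tags_per_cell_mean = 1)
  cl <- simulate_clones(cfg)
  expect_true(all(lengths(cl$clone_tags) == 1L))
})

test_that("cells of one clone carry identical tag sets", {
  cfg <- test_config()
  cl <- simulate_clones(cfg)
  sizes <- table(cl$cells$clone_id)
  big <- names(sizes)[sizes >= 2][1]
  members <- cl$cells$cell_id[cl$cells$clone_id == big]
  sim <- simulate_experiment(cfg)
  sets <- sim$signatures$day1[intersect(members, names(sim$signatures$day1))]
  expect_true(all(vapply(sets, identical, logical(1), y = sets[[1]])))
})

test_that("a self-loop-only transition graph leaves states unchanged", {
  states <- rep(c("matNeu", "MPP"), 50)
  g <- list(matNeu = c(matNeu = 1), MPP = c(MPP = 1))
  expect_identical(simulate_reprogramming(states, g, 1, seed = 1), states)
})

test_that("unknown day-1 states are a hard error", {
  expect_error(simulate_reprogramming("whale", default_transition_graph(), 1),
               "unknown state")
})

test_that("one-hop fates match configured edge probabilities", {
  n <- 10000
  out <- simulate_reprogramming(rep("matNeu", n), default_transition_graph(),
                                reprogram_fraction = 1, seed = 3)
  p_pre <- default_transition_graph()$matNeu[["preNeu"]]
  sd3 <- 3 * sqrt(p_pre * (1 - p_pre) / n)
  expect_lt(abs(mean(out == "preNeu") - p_pre), sd3)

  out2 <- simulate_reprogramming(rep("preNeu", n), default_transition_graph(),
                                 reprogram_fraction = 1, seed = 4)
  p_mpp <- default_transition_graph()$preNeu[["MPP"]]   # 0.7
  expect_equal(p_mpp, 0.7)
  expect_lt(abs(mean(out2 == "MPP") - p_mpp),
            3 * sqrt(p_mpp * (1 - p_mpp) / n))
})

test_that("day-7 composition is the push-forward of day 1 through the graph", {
  n <- 10000
  comp <- c(matNeu = 0.5, immNeu = 0.3, preNeu = 0.2)
  g <- default_transition_graph()
  states1 <- sample(names(comp), n, replace = TRUE, prob = comp)
  states7 <- simulate_reprogramming(states1, g, 1, seed = 9)
  targets <- unique(unlist(lapply(g, names)))
  push <- stats::setNames(numeric(length(targets)), targets)
  for (s in names(comp)) {
    for (t in names(g[[s]]))
      push[t] <- push[t] + comp[[s]] * g[[s]][[t]]
  }
  push <- push[push > 0]
  obs <- table(factor(states7, levels = names(push)))
  chi <- suppressWarnings(chisq.test(obs, p = push / sum(push)))
  expect_gt(chi$p.value, 0.001)
})

test_that("counts approach the Poisson limit as dispersion vanishes", {
  cfg <- test_config(dispersion = 1e-8, lib_size_sdlog = 0)
  states <- rep("MPP", 2000)
  counts <- simulate_expression(states, cfg, seed = 5)
  m <- Matrix::rowMeans(counts)
  v <- apply(as.matrix(counts), 1L, var)
  keep <- m > 0.5
  expect_lt(median(abs(v[keep] / m[keep] - 1)), 0.15)
})

test_that("configured marker shifts are visible in simulated counts", {
  cfg <- test_config(lib_size_sdlog = 0.1)
  states <- rep(c("MPP", "matNeu"), each = 500)
  counts <- simulate_expression(states, cfg, seed = 6)
  gfi1 <- as.numeric(counts["Gfi1", ])
  tt <- t.test(gfi1[states == "MPP"], gfi1[states == "matNeu"])
  expect_gt(tt$statistic, 0)
  expect_lt(tt$p.value, 1e-6)
  norm <- normalize_log(counts)
  hspc <- score_signature(norm, marker_signatures()$HSPC)
  expect_gt(mean(hspc[states == "MPP"]), mean(hspc[states == "matNeu"]))
})

test_that("a marker gene missing from the universe is a named hard error", {
  cfg <- test_config()
  profiles <- clonotrace:::state_mean_matrix(cfg, c("MPP"))
  expect_error(simulate_expression(rep("unknownState", 5), cfg,
                                   profiles = profiles),
               "unknownState")
})

test_that("emitted reads are valid paired FASTQ with intact constructs at error 0", {
  cfg <- test_config(n_cells_day1 = 50L, seq_error_rate = 0)
  sim <- simulate_experiment(cfg, expression = FALSE)
  ta <- tag_assignment(sim, "day1")
  reads <- emit_reads(ta, cfg)
  expect_true(all(grepl(paste0("GGT[ACGT]{8}GAATTC"), reads$sequence)))
  tags_seen <- regmatches(reads$sequence,
                          regexpr("GGT[ACGT]{8}GAATTC", reads$sequence))
  tags_seen <- substr(tags_seen, 4, 11)
  expect_true(all(tags_seen %in% unlist(sim$clone_tags)))

  r1 <- tempfile(fileext = ".fastq"); r2 <- tempfile(fileext = ".fastq")
  write_tag_fastq(reads, r1, r2)
  lines <- readLines(r1)
  expect_equal(length(lines) %% 4, 0)
  expect_true(all(startsWith(lines[seq(1, length(lines), 4)], "@")))
  expect_true(all(startsWith(lines[seq(3, length(lines), 4)], "+")))
  expect_equal(nchar(lines[seq(2, length(lines), 4)]),
               nchar(lines[seq(4, length(lines), 4)]))
  back <- read_tag_fastq(r1, r2)
  expect_equal(back, reads)
})

test_that("per-base errors corrupt tags at the closed-form binomial rate", {
  cfg <- test_config(n_cells_day1 = 60L, seq_error_rate = 0.01,
                     read_length = 17L)   # construct fills the read: fixed offset
  sim <- simulate_experiment(cfg, expression = FALSE)
  ta <- tag_assignment(sim, "day1")
  reads <- emit_reads(ta, cfg)
  ## at read_length 17 the tag always occupies positions 4..11
  obs_tag <- substr(reads$sequence, 4, 11)
  ## a read's true tag is its cell's tag with minimal Hamming distance
  cell_tags <- split(ta$tag, ta$cell_barcode)
  corrupted <- mapply(function(cb, ot) {
    cand <- cell_tags[[cb]]
    d <- as.integer(oracle_hamming(ot, cand))
    min(d) > 0
  }, reads$cell_barcode, obs_tag)
  p_expect <- 1 - (1 - 0.01)^8
  n <- nrow(reads)
  expect_lt(abs(mean(corrupted) - p_expect),
            3 * sqrt(p_expect * (1 - p_expect) / n))
})

test_that("all reads of a single tagged cell share its barcode", {
  cfg <- test_config(n_cells_day1 = 1L, tags_per_cell_mean = 1,
                     clone_size_day1_mean = 1)
  sim <- simulate_experiment(cfg, expression = FALSE)
  ta <- tag_assignment(sim, "day1")
  reads <- emit_reads(ta, cfg)
  expect_equal(length(unique(reads$cell_barcode)), 1L)
  expect_identical(unique(reads$cell_barcode), ta$cell_barcode[1])
})

test_that("generator output is byte-identical across runs with one seed", {
  cfg <- test_config(n_cells_day1 = 80L)
  s1 <- simulate_experiment(cfg)
  s2 <- simulate_experiment(cfg)
  expect_identical(s1$cells_day7, s2$cells_day7)
  expect_identical(s1$clone_tags, s2$clone_tags)
  expect_identical(as.matrix(s1$counts$day1), as.matrix(s2$counts$day1))
  r1 <- emit_reads(tag_assignment(s1, "day1"), cfg)
  r2 <- emit_reads(tag_assignment(s2, "day1"), cfg)
  expect_identical(r1, r2)
})

test_that("trajectory cohorts traverse only planted adjacencies", {
  cfg <- test_config()
  tc <- simulate_trajectory_cohort(cfg, n_cells = 300, seed = 2)
  g <- cfg$transition_graph
  legal <- unlist(lapply(names(g), function(s) paste(s, names(g[[s]]))))
  expect_true(all(paste(tc$traversed$from, tc$traversed$to) %in% legal))
  ## blends index real edges of each cell's walk
  mid <- tc$cells[tc$cells$src != tc$cells$tgt, ]
  expect_true(all(paste(mid$src, mid$tgt) %in% legal))
  expect_true(all(tc$cells$blend >= 0 & tc$cells$blend <= 1))
})
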