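#' Default pipeline configuration
#'
#' Returns the full per-stage parameter tree driving [run_pipeline()].
#' Unknown keys in a user config are rejected; the effective (merged)
#' config is echoed into the output directory.
#'
#' @param seed Global seed; every stage derives its random stream from it.
#' @return Nested list of stage parameter blocks.
#' @export
pipeline_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    simulate = list(enabled = TRUE, n_cells_day1 = 600L, n_genes = 400L,
                    tag_pool_size = 65536L, tags_per_cell_mean = 2,
                    tags_per_cell_max = 40L, seq_error_rate = 0.005,
                    tag_dropout = 0),
    extract = list(motif_prefix = "GGT", motif_suffix = "GAATTC",
                   tag_length = 8L, hamming_radius = 1L, min_umi = 2L),
    clones = list(method = "jaccard", jaccard_min = 0.7),
    annotate = list(target_sum = 1e4, n_hvg = 2000L, n_pcs = 20L),
    fate = list(restrict = "High"),
    trajectory = list(k = 15L, resolution = 1, c_min = 0.05,
                      query = c("matNeu", "MPP"))
  )
}

merge_config <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ",
         paste0(path, unknown, collapse = ", "))
  for (k in names(user)) {
    defaults[[k]] <- if (is.list(defaults[[k]]) && is.list(user[[k]]))
      merge_config(defaults[[k]], user[[k]], paste0(path, k, "."))
    else user[[k]]
  }
  defaults
}

#' Run the lineage-tracing pipeline end to end
#'
#' Executes simulate (optional) -> extract -> clones -> annotate -> fate ->
#' trajectory -> report, writing every stage's tables under `out_dir`
#' together with the effective config and a manifest of output checksums.
#' Outputs are byte-identical across reruns with the same config and seed.
#' A failing stage aborts with the stage named and leaves a `FAILED` marker
#' in the output directory.
#'
#' @param config A config list (see [pipeline_config()]), a path to a YAML
#'   file with the same structure, or `NULL` for defaults.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the output directory path.
#' @export
run_pipeline <- function(config = NULL, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(pipeline_config(), config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(cfg, file.path(out_dir, "config_effective.yaml"))

  stage <- function(name, fun) {
    tryCatch(fun(), error = function(e) {
      writeLines(paste("FAILED at stage:", name, "-", conditionMessage(e)),
                 file.path(out_dir, "FAILED"))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  ## ---- simulate -------------------------------------------------------
  sim <- NULL
  if (isTRUE(cfg$simulate$enabled)) {
    sim <- stage("simulate", function() {
      sc <- sim_config(n_cells_day1 = cfg$simulate$n_cells_day1,
                       n_genes = cfg$simulate$n_genes,
                       tag_pool_size = cfg$simulate$tag_pool_size,
                       tags_per_cell_mean = cfg$simulate$tags_per_cell_mean,
                       tags_per_cell_max = cfg$simulate$tags_per_cell_max,
                       seq_error_rate = cfg$simulate$seq_error_rate,
                       tag_dropout = cfg$simulate$tag_dropout,
                       motif_prefix = cfg$extract$motif_prefix,
                       motif_suffix = cfg$extract$motif_suffix,
                       tag_length = cfg$extract$tag_length,
                       seed = cfg$seed)
      s <- simulate_experiment(sc)
      for (tp in c("day1", "day7")) {
        reads <- emit_reads(tag_assignment(s, tp), sc,
                            seed = sc$seed + ifelse(tp == "day7", 1L, 0L))
        write_tag_fastq(reads,
                        file.path(out_dir, paste0(tp, "_R1.fastq")),
                        file.path(out_dir, paste0(tp, "_R2.fastq")))
        write_tenx(s$counts[[tp]], file.path(out_dir, paste0("counts_", tp)))
      }
      write.table(s$cells_day1, file.path(out_dir, "truth_cells_day1.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(s$cells_day7, file.path(out_dir, "truth_cells_day7.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(s$clones, file.path(out_dir, "truth_clones.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      s
    })
  }

  ## ---- extract --------------------------------------------------------
  sigs <- stage("extract", function() {
    out <- list()
    mats <- list()
    for (tp in c("day1", "day7")) {
      reads <- read_tag_fastq(file.path(out_dir, paste0(tp, "_R1.fastq")),
                              file.path(out_dir, paste0(tp, "_R2.fastq")))
      triples <- extract_tags(reads, cfg$extract$motif_prefix,
                              cfg$extract$motif_suffix,
                              cfg$extract$tag_length)
      mat <- correct_tags(count_tags(triples), cfg$extract$hamming_radius)
      fb <- filter_and_binarize(mat, min_umi = cfg$extract$min_umi)
      write_signatures(fb$signatures,
                       file.path(out_dir, paste0("signatures_", tp, ".tsv")))
      out[[tp]] <- fb$signatures
      mats[[tp]] <- fb$counts
    }
    ts <- tag_stats(mats$day1, mats$day7)
    stats_df <- data.frame(
      metric = c("cells_day1", "cells_day7", "tags_min", "tags_mean",
                 "tags_max", "shared_day1", "shared_day7", "shared_total"),
      value = c(nrow(mats$day1), nrow(mats$day7),
                min(tag_stats(mats$day1)$min, tag_stats(mats$day7)$min),
                mean(c(Matrix::rowSums(mats$day1 > 0),
                       Matrix::rowSums(mats$day7 > 0))),
                max(tag_stats(mats$day1)$max, tag_stats(mats$day7)$max),
                ts$shared_cells[["timepoint1"]],
                ts$shared_cells[["timepoint2"]], ts$shared_total))
    write.table(stats_df, file.path(out_dir, "tag_stats.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    hist_both <- table(c(Matrix::rowSums(mats$day1 > 0),
                         Matrix::rowSums(mats$day7 > 0)))
    hist_df <- data.frame(n_tags = names(hist_both),
                          n_cells = as.integer(hist_both))
    write.table(hist_df, file.path(out_dir, "tag_histogram.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    out
  })

  ## map cell barcodes back to cell ids when truth is available
  if (!is.null(sim)) {
    bc2id <- c(with(sim$cells_day1, stats::setNames(cell_id, cell_barcode)),
               with(sim$cells_day7, stats::setNames(cell_id, cell_barcode)))
    for (tp in c("day1", "day7"))
      names(sigs[[tp]]) <- unname(bc2id[names(sigs[[tp]])])
  }

  ## ---- clones ---------------------------------------------------------
  ct <- stage("clones", function() {
    ct <- match_clones(sigs$day1, sigs$day7, method = cfg$clones$method,
                       jaccard_min = cfg$clones$jaccard_min)
    write.table(ct$clones, file.path(out_dir, "clones.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(ct$members, file.path(out_dir, "clone_members.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    ct
  })

  ## ---- annotate -------------------------------------------------------
  ann <- stage("annotate", function() {
    counts7 <- read_tenx(file.path(out_dir, "counts_day7"))
    norm7 <- normalize_log(counts7, cfg$annotate$target_sum)
    hvg <- select_hvg(norm7, n_top = cfg$annotate$n_hvg)
    pca7 <- scale_and_pca(norm7, hvg, n_components = cfg$annotate$n_pcs)
    hspc <- score_signature(norm7, marker_signatures()$HSPC)
    call <- call_hspc_program(hspc)
    types <- assign_cell_type(norm7, state_marker_sets())
    labels <- data.frame(cell_id = colnames(norm7),
                         hspc_score = unname(hspc),
                         hspc_call = unname(call$labels[colnames(norm7)]),
                         type = types$type, margin = types$margin,
                         stringsAsFactors = FALSE)
    write.table(labels, file.path(out_dir, "labels_day7.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    pca_df <- data.frame(cell_id = rownames(pca7$embedding),
                         pca7$embedding)
    write.table(pca_df, file.path(out_dir, "pca_day7.csv"),
                sep = ",", quote = FALSE, row.names = FALSE)
    list(norm7 = norm7, pca7 = pca7, labels = labels,
         threshold = call$threshold)
  })

  ## ---- fate -----------------------------------------------------------
  fm <- stage("fate", function() {
    day1_lab <- if (!is.null(sim)) {
      stats::setNames(sim$cells_day1$lineage, sim$cells_day1$cell_id)
    } else {
      lab <- read.table(file.path(out_dir, "truth_cells_day1.tsv"),
                        sep = "\t", header = TRUE, stringsAsFactors = FALSE)
      stats::setNames(lab$lineage, lab$cell_id)
    }
    ## cover every annotated day-7 cell; cells without a recovered tag
    ## signature are untraced
    lin <- assign_initial_lineage(ct, day1_lab,
                                  day7_cells = ann$labels$cell_id)
    grp <- stats::setNames(ann$labels$hspc_call, ann$labels$cell_id)
    fm <- fate_map(lin, grp, restrict_to = cfg$fate$restrict)
    if (fm$n_selected > 0 && sum(fm$counts) != fm$n_selected)
      stop("fate-map cell conservation check failed")
    cdf <- as.data.frame(fm$counts, stringsAsFactors = FALSE)
    fr_all <- as.data.frame(fm$fractions_overall, stringsAsFactors = FALSE)
    names(fr_all)[names(fr_all) == "Freq"] <- "fraction_overall"
    cdf <- merge(cdf, fr_all, by = c("lineage", "group"))
    fr <- as.data.frame(fm$fractions, stringsAsFactors = FALSE)
    if (nrow(fr)) {
      names(fr) <- c("lineage", "group", "fraction_traced")
      cdf <- merge(cdf, fr, by = c("lineage", "group"), all.x = TRUE)
    } else cdf$fraction_traced <- NA_real_
    cdf <- cdf[order(cdf$group, -cdf$Freq), ]
    names(cdf)[names(cdf) == "Freq"] <- "count"
    write.table(cdf, file.path(out_dir, "fate_map.csv"),
                sep = ",", quote = FALSE, row.names = FALSE)
    sankey <- list(
      nodes = unique(c(paste0("day1:", cdf$lineage),
                       paste0("day7:", cdf$group))),
      links = lapply(seq_len(nrow(cdf)), function(r)
        list(source = paste0("day1:", cdf$lineage[r]),
             target = paste0("day7:", cdf$group[r]),
             value = cdf$count[r]))
    )
    jsonlite::write_json(sankey, file.path(out_dir, "sankey.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    fm
  })

  ## ---- trajectory -----------------------------------------------------
  stage("trajectory", function() {
    emb <- ann$pca7$embedding
    g <- knn_graph(emb, k = min(cfg$trajectory$k, nrow(emb) - 1L))
    part <- cluster_graph_partition(g, resolution = cfg$trajectory$resolution,
                                    seed = cfg$seed)
    cg <- paga_connectivity(g, part)
    types <- assign_cell_type(ann$norm7, state_marker_sets(),
                              clusters = part)
    cl_types <- stats::setNames(
      types$cluster_type[!duplicated(types$cluster)],
      as.character(types$cluster[!duplicated(types$cluster)]))
    rep <- trajectory_report(cg, cl_types, c_min = cfg$trajectory$c_min,
                             query = cfg$trajectory$query)
    write.table(data.frame(cell_id = names(part), cluster = unname(part)),
                file.path(out_dir, "clusters.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(cg$edges, file.path(out_dir, "cluster_graph.csv"),
                sep = ",", quote = FALSE, row.names = FALSE)
    write.table(rep$edges, file.path(out_dir, "trajectory_edges.csv"),
                sep = ",", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(query = rep$query,
           paths = if (is.data.frame(rep$paths)) rep$paths else list()),
      file.path(out_dir, "paths.json"), auto_unbox = TRUE, pretty = TRUE)
    invisible(NULL)
  })

  ## ---- report + manifest ---------------------------------------------
  stage("report", function() make_report(out_dir))
  files <- sort(setdiff(list.files(out_dir, recursive = TRUE),
                        "manifest.json"))
  manifest <- list(seed = cfg$seed, config = cfg,
                   checksums = as.list(tools::md5sum(
                     file.path(out_dir, files))))
  names(manifest$checksums) <- files
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' Assemble a human-readable run report
#'
#' Reads the stage tables present in a pipeline output directory and writes
#' `report.md` summarizing lineage contribution fractions, the tags-per-cell
#' histogram with min/mean/max, matched-cell counts per timepoint, the
#' labelled cluster-graph edge list and the parameter echo. Every number is
#' taken verbatim from the emitted CSV/TSVs.
#'
#' @param out_dir A [run_pipeline()] output directory (at least one stage
#'   output must be present).
#' @return Invisibly, the path to `report.md`.
#' @export
make_report <- function(out_dir) {
  have <- function(f) file.exists(file.path(out_dir, f))
  if (!any(vapply(c("tag_stats.tsv", "fate_map.csv", "trajectory_edges.csv",
                    "config_effective.yaml"), have, logical(1))))
    stop("no stage output found in ", out_dir)
  lines <- c("# Lineage-tracing pipeline report", "")
  if (have("tag_stats.tsv")) {
    ts <- read.table(file.path(out_dir, "tag_stats.tsv"), sep = "\t",
                     header = TRUE)
    lines <- c(lines, "## Tag statistics", "",
               sprintf("- %s: %s", ts$metric, signif(ts$value, 6)), "")
  }
  if (have("tag_histogram.tsv")) {
    th <- read.table(file.path(out_dir, "tag_histogram.tsv"), sep = "\t",
                     header = TRUE)
    lines <- c(lines, "## Tags-per-cell histogram", "",
               "| tags | cells |", "|---|---|",
               sprintf("| %s | %d |", th$n_tags, th$n_cells), "")
  }
  if (have("fate_map.csv")) {
    fmd <- read.table(file.path(out_dir, "fate_map.csv"), sep = ",",
                      header = TRUE)
    lines <- c(lines, "## Fate map (initial lineage contributions)", "",
               "| lineage | group | count | fraction (traced) |",
               "|---|---|---|---|",
               sprintf("| %s | %s | %d | %s |", fmd$lineage, fmd$group,
                       fmd$count,
                       ifelse(is.na(fmd$fraction_traced), "-",
                              sprintf("%.3f", fmd$fraction_traced))), "")
  }
  if (have("trajectory_edges.csv")) {
    te <- read.table(file.path(out_dir, "trajectory_edges.csv"), sep = ",",
                     header = TRUE)
    lines <- c(lines, "## Trajectory edges", "",
               "| clusters | types | connectivity | skip |", "|---|---|---|---|",
               sprintf("| %d-%d | %s-%s | %.3f | %s |", te$i, te$j,
                       te$type_i, te$type_j, te$connectivity, te$skip), "")
  }
  if (have("config_effective.yaml")) {
    lines <- c(lines, "## Parameters", "", "```yaml",
               readLines(file.path(out_dir, "config_effective.yaml")), "```")
  }
  path <- file.path(out_dir, "report.md")
  writeLines(lines, path)
  invisible(path)
}
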