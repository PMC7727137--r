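## Jaccard similarities between two lists of tag sets, via sparse binary
## matrices over the union tag universe. Returns a sparse matrix
## |sigs1| x |sigs2| holding similarities at the nonzero intersections.
jaccard_cross <- function(sigs1, sigs2) {
  tags <- sort(unique(c(unlist(sigs1, use.names = FALSE),
                        unlist(sigs2, use.names = FALSE))))
  mk <- function(sigs) Matrix::sparseMatrix(
    i = rep(seq_along(sigs), lengths(sigs)),
    j = match(unlist(sigs, use.names = FALSE), tags),
    x = 1,
    dims = c(length(sigs), length(tags)),
    dimnames = list(names(sigs), tags)
  )
  a <- mk(sigs1)
  b <- mk(sigs2)
  inter <- a %*% Matrix::t(b)
  inter <- as(inter, "TsparseMatrix")
  s1 <- lengths(sigs1)
  s2 <- lengths(sigs2)
  jac <- inter@x / (s1[inter@i + 1L] + s2[inter@j + 1L] - inter@x)
  Matrix::sparseMatrix(i = inter@i + 1L, j = inter@j + 1L, x = jac,
                       dims = dim(inter),
                       dimnames = list(names(sigs1), names(sigs2)))
}

#' Match cells across timepoints into clones by tag-set similarity
#'
#' Day-1 cells are first grouped into clones: in `"exact"` mode, cells with
#' an identical tag set; in `"jaccard"` mode, connected components of the
#' day-1 similarity graph at `Jaccard >= jaccard_min`. Each day-7 cell then
#' links to the day-1 clone with the highest maximum Jaccard similarity
#' (which must reach `jaccard_min`; in exact mode the signature must be
#' identical), ties broken toward the larger day-1 clone, then toward the
#' lexicographically smaller clone signature. Keeping the day-7 side out of
#' the component construction prevents a tag collision from fusing two
#' distinct clones.
#'
#' Clone ids are assigned by the lexicographic order of each clone's
#' canonical signature (union of its day-1 members' tags), so they are
#' stable under any input cell order.
#'
#' @param day1_signatures,day7_signatures Named lists: cell id -> non-empty
#'   character vector of tags.
#' @param method `"jaccard"` or `"exact"`.
#' @param jaccard_min Minimum Jaccard similarity for a link (default 0.7).
#' @return Object of class `clone_table`: list with `clones` (data frame
#'   `clone_id`, `tags`, `n_day1`, `n_day7`), `members` (data frame
#'   `cell_id`, `timepoint`, `clone_id`, `similarity`) and `unmatched`
#'   (day-7 cell ids with no eligible link).
#' @export
match_clones <- function(day1_signatures, day7_signatures,
                         method = c("jaccard", "exact"), jaccard_min = 0.7) {
  method <- match.arg(method)
  stopifnot(all(lengths(day1_signatures) > 0),
            all(lengths(day7_signatures) > 0))
  n1 <- length(day1_signatures)

  ## --- group day-1 cells into clones
  if (method == "exact") {
    keys <- vapply(day1_signatures, function(t) paste(sort(t), collapse = ","),
                   character(1))
    comp <- match(keys, sort(unique(keys)))
  } else {
    jac11 <- jaccard_cross(day1_signatures, day1_signatures)
    jt <- as(jac11, "TsparseMatrix")
    keep <- jt@x >= jaccard_min & jt@i < jt@j
    g <- igraph::graph_from_data_frame(
      data.frame(from = jt@i[keep] + 1L, to = jt@j[keep] + 1L),
      directed = FALSE,
      vertices = data.frame(name = seq_len(n1))
    )
    comp <- igraph::components(g)$membership
  }

  ## canonical signature per clone (union of members' tags) -> stable ids
  clone_sets <- lapply(split(seq_len(n1), comp), function(ix)
    sort(unique(unlist(day1_signatures[ix], use.names = FALSE))))
  canon <- vapply(clone_sets, paste, character(1), collapse = ",")
  ord <- order(canon)
  clone_of_comp <- integer(length(canon))
  clone_of_comp[ord] <- seq_along(canon)      # comp index -> clone rank
  clone_ids <- sprintf("clone_%05d", seq_along(canon))
  day1_clone <- clone_ids[clone_of_comp[comp]]
  clone_tags_str <- character(length(canon))
  clone_tags_str[clone_of_comp] <- canon
  clone_sizes <- as.integer(table(factor(day1_clone, levels = clone_ids)))

  ## per-day-1-member similarity to the clone signature
  sets_by_id <- vector("list", length(canon))
  sets_by_id[clone_of_comp] <- clone_sets
  sim1 <- vapply(seq_len(n1), function(i) {
    s <- day1_signatures[[i]]
    cs <- sets_by_id[[match(day1_clone[i], clone_ids)]]
    length(intersect(s, cs)) / length(union(s, cs))
  }, numeric(1))

  ## --- assign day-7 cells
  jac17 <- jaccard_cross(day1_signatures, day7_signatures)
  jt <- as(jac17, "TsparseMatrix")
  if (method == "exact") {
    k1 <- vapply(day1_signatures, function(t) paste(sort(t), collapse = ","),
                 character(1))
    k7 <- vapply(day7_signatures, function(t) paste(sort(t), collapse = ","),
                 character(1))
    ok <- k1[jt@i + 1L] == k7[jt@j + 1L]
  } else {
    ok <- jt@x >= jaccard_min
  }
  links <- data.frame(day7 = jt@j[ok] + 1L,
                      clone = day1_clone[jt@i + 1L][ok],
                      jac = jt@x[ok])
  assign7 <- rep(NA_character_, length(day7_signatures))
  sim7 <- rep(NA_real_, length(day7_signatures))
  if (nrow(links)) {
    ## best link per (day7, clone): the maximum Jaccard
    agg <- stats::aggregate(jac ~ day7 + clone, data = links, FUN = max)
    agg$size <- clone_sizes[match(agg$clone, clone_ids)]
    agg$sig <- clone_tags_str[match(agg$clone, clone_ids)]
    ## pick per day-7 cell: max jac, then larger clone, then lexicographic sig
    agg <- agg[order(agg$day7, -agg$jac, -agg$size, agg$sig), ]
    first <- !duplicated(agg$day7)
    assign7[agg$day7[first]] <- agg$clone[first]
    sim7[agg$day7[first]] <- agg$jac[first]
  }

  members <- rbind(
    data.frame(cell_id = names(day1_signatures), timepoint = "day1",
               clone_id = day1_clone, similarity = sim1,
               stringsAsFactors = FALSE),
    data.frame(cell_id = names(day7_signatures)[!is.na(assign7)],
               timepoint = rep("day7", sum(!is.na(assign7))),
               clone_id = assign7[!is.na(assign7)],
               similarity = sim7[!is.na(assign7)],
               stringsAsFactors = FALSE)
  )
  rownames(members) <- NULL
  n_day7 <- as.integer(table(factor(members$clone_id[members$timepoint == "day7"],
                                    levels = clone_ids)))
  clones <- data.frame(clone_id = clone_ids, tags = clone_tags_str,
                       n_day1 = clone_sizes, n_day7 = n_day7,
                       stringsAsFactors = FALSE)
  structure(list(clones = clones, members = members,
                 unmatched = names(day7_signatures)[is.na(assign7)],
                 method = method, jaccard_min = jaccard_min),
            class = "clone_table")
}

#' @export
print.clone_table <- function(x, ...) {
  cat("clone_table:", nrow(x$clones), "clones;",
      sum(x$members$timepoint == "day1"), "day-1 cells;",
      sum(x$members$timepoint == "day7"), "day-7 cells matched;",
      length(x$unmatched), "day-7 cells unmatched\n")
  invisible(x)
}

#' Assign each matched day-7 cell its clone's initial lineage
#'
#' The initial lineage is the majority label among the clone's day-1
#' members; ties give `"ambiguous"`; day-7 cells without a matched clone (or
#' whose clone has no labelled day-1 member) are `"untraced"`.
#'
#' @param clone_table A [match_clones()] result.
#' @param day1_labels Named character vector: day-1 cell id -> lineage label.
#' @param day7_cells Optional character vector of day-7 cell ids the result
#'   should cover (defaults to the matched plus unmatched cells of
#'   `clone_table`).
#' @return Named character vector: day-7 cell id -> initial lineage.
#' @export
assign_initial_lineage <- function(clone_table, day1_labels,
                                   day7_cells = NULL) {
  mem <- clone_table$members
  d1 <- mem[mem$timepoint == "day1", ]
  if (anyNA(day1_labels[d1$cell_id]))
    stop("every day-1 clone member needs a label")
  clone_lineage <- vapply(split(day1_labels[d1$cell_id], d1$clone_id),
                          function(lab) {
    tab <- sort(table(lab), decreasing = TRUE)
    if (length(tab) > 1L && tab[1L] == tab[2L]) "ambiguous" else names(tab)[1L]
  }, character(1))
  d7 <- mem[mem$timepoint == "day7", ]
  if (is.null(day7_cells))
    day7_cells <- c(d7$cell_id, clone_table$unmatched)
  out <- rep("untraced", length(day7_cells))
  names(out) <- day7_cells
  hit <- d7$cell_id %in% day7_cells
  lin <- clone_lineage[d7$clone_id[hit]]
  lin[is.na(lin)] <- "untraced"
  out[d7$cell_id[hit]] <- lin
  out
}

#' Tabulate the clonal fate map from initial lineages to induced groups
#'
#' Counts the selected day-7 cells by initial lineage and induced group.
#' Fractions are normalized per induced group over traced, unambiguous cells
#' (`"ambiguous"` and `"untraced"` are tabulated but excluded); fractions
#' over all selected cells are reported alongside.
#'
#' @param initial_lineage Named vector (day-7 cell id -> lineage) from
#'   [assign_initial_lineage()].
#' @param induced_group Named vector (day-7 cell id -> group label, e.g. the
#'   HSPC-program call).
#' @param restrict_to Optional group label(s) to keep (e.g. `"High"`);
#'   `NULL` keeps all groups.
#' @return Object of class `fate_map`: list with `counts` (lineage x group
#'   matrix), `fractions` (excluding ambiguous/untraced),
#'   `fractions_overall` (including them) and `n_selected`.
#' @export
fate_map <- function(initial_lineage, induced_group, restrict_to = NULL) {
  cells <- intersect(names(initial_lineage), names(induced_group))
  grp <- induced_group[cells]
  lin <- initial_lineage[cells]
  if (!is.null(restrict_to)) {
    keep <- grp %in% restrict_to
    grp <- grp[keep]
    lin <- lin[keep]
  }
  if (!length(grp)) {
    warning("no day-7 cells selected; empty fate map")
    return(structure(list(counts = table(character(0), character(0)),
                          fractions = NULL, fractions_overall = NULL,
                          n_selected = 0L), class = "fate_map"))
  }
  counts <- table(lineage = lin, group = grp)
  traced <- !(rownames(counts) %in% c("ambiguous", "untraced"))
  fr <- counts
  fr[] <- 0
  tot_traced <- colSums(counts[traced, , drop = FALSE])
  fr[traced, ] <- sweep(counts[traced, , drop = FALSE], 2L, tot_traced, "/")
  fr_all <- sweep(counts, 2L, colSums(counts), "/")
  structure(list(counts = counts,
                 fractions = fr[traced, , drop = FALSE],
                 fractions_overall = fr_all,
                 n_selected = length(grp)),
            class = "fate_map")
}

#' @export
print.fate_map <- function(x, ...) {
  cat("fate_map over", x$n_selected, "day-7 cells\n")
  if (!is.null(x$fractions)) {
    cat("fractions (traced, unambiguous):\n")
    print(round(x$fractions, 3))
  }
  invisible(x)
}

#' Partition day-1 cells into reprogrammed / not reprogrammed / untraced
#'
#' A day-1 cell is `reprogrammed` iff its clone contains at least one day-7
#' cell in the success set; `not_reprogrammed` iff the clone has day-7
#' members but none succeeds; `untraced` otherwise (no matched day-7
#' member).
#'
#' @param clone_table A [match_clones()] result.
#' @param day7_success Character vector of day-7 cell ids counted as
#'   reprogramming successes (e.g. HSPC-program High cells).
#' @return Named character vector over day-1 cells.
#' @export
classify_reprogrammable <- function(clone_table, day7_success) {
  mem <- clone_table$members
  d7 <- mem[mem$timepoint == "day7", ]
  has7 <- unique(d7$clone_id)
  success <- unique(d7$clone_id[d7$cell_id %in% day7_success])
  d1 <- mem[mem$timepoint == "day1", ]
  out <- ifelse(d1$clone_id %in% success, "reprogrammed",
                ifelse(d1$clone_id %in% has7, "not_reprogrammed", "untraced"))
  names(out) <- d1$cell_id
  out
}
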