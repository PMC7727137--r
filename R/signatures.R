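#' Default gene-signature sets for hematopoietic reprogramming analysis
#'
#' Returns the named gene lists used throughout the package:
#'
#' * `HSPC`: the ten-gene stem/progenitor program
#'   (Ly6e, Lmo2, Hoxa9, Runx1, Cd34, Gfi1, Egfl7, Myl10, Ctsg, Prtn3).
#' * `neutrophil`: neutrophil identity genes (S100a6, S100a11, Ly6c2, Samsn1).
#' * One two-gene marker set per cell state: mature neutrophils (Itgam, Mmp9),
#'   immature neutrophils (Gal, Gngt2), preneutrophils (Ctsg, Elane),
#'   GMP (Ifitm1, Gata2), CMP (Ctsc, Prss34), MPP (Gfi1, Prtn2) and
#'   MEP (Car1, Hba-a1).
#'
#' Note `Prtn2` is the printed MPP marker symbol; it may be a typo for
#' `Prtn3`, so the default keeps the printed symbol and treats it as a
#' distinct gene.
#'
#' @return Named list of character vectors. The state marker sets are the
#'   elements named after states (`matNeu`, `immNeu`, `preNeu`, `GMP`,
#'   `CMP`, `MPP`, `MEP`).
#' @export
marker_signatures <- function() {
  list(
    HSPC = c("Ly6e", "Lmo2", "Hoxa9", "Runx1", "Cd34",
             "Gfi1", "Egfl7", "Myl10", "Ctsg", "Prtn3"),
    neutrophil = c("S100a6", "S100a11", "Ly6c2", "Samsn1"),
    matNeu = c("Itgam", "Mmp9"),
    immNeu = c("Gal", "Gngt2"),
    preNeu = c("Ctsg", "Elane"),
    GMP = c("Ifitm1", "Gata2"),
    CMP = c("Ctsc", "Prss34"),
    MPP = c("Gfi1", "Prtn2"),
    MEP = c("Car1", "Hba-a1")
  )
}

#' @rdname marker_signatures
#' @details `state_marker_sets()` returns only the seven per-state marker
#'   sets, the form expected by [assign_cell_type()].
#' @export
state_marker_sets <- function() {
  marker_signatures()[c("matNeu", "immNeu", "preNeu", "GMP", "CMP", "MPP", "MEP")]
}

## Extra day-1 lineage markers used only by the simulator's expression model
## so that non-neutrophil lineages are transcriptionally distinct.
lineage_marker_sets <- function() {
  list(
    eosinophil  = c("Prg2", "Epx"),
    macrophage  = c("Adgre1", "Csf1r"),
    basophil    = c("Mcpt8", "Cd200r3"),
    erythrocyte = c("Hba-a2", "Alas2"),
    Tcell       = c("Cd3e", "Cd3d")
  )
}

## States whose transcriptome carries the HSPC program.
HSPC_STATES <- c("MPP", "GMP", "CMP", "MEP")
NEUTROPHIL_STATES <- c("matNeu", "immNeu", "preNeu")

## Map a day-1 state to its lineage label (neutrophil maturation stages
## collapse to "neutrophil"; every other state is its own lineage).
state_to_lineage <- function(states) {
  ifelse(states %in% NEUTROPHIL_STATES, "neutrophil", states)
}

#' Write and read signature files
#'
#' Signature files are two-column TSVs (`name`, comma-joined gene list) with
#' a header.
#'
#' @param signatures Named list of character vectors.
#' @param path File path.
#' @export
write_signature_file <- function(signatures, path) {
  df <- data.frame(name = names(signatures),
                   genes = vapply(signatures, paste, character(1),
                                  collapse = ","),
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_signature_file
#' @export
read_signature_file <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  sets <- strsplit(df$genes, ",", fixed = TRUE)
  names(sets) <- df$name
  sets
}
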