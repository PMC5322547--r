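#' Tally a repertoire by homeobox class
#'
#' Exact counts per canonical class (plus `"Others"`) from an annotation
#' data.frame or a repertoire table with a `class` column.
#'
#' @param x data.frame with a `class` column
#' @return named integer vector over the eleven canonical classes and
#'   `"Others"`, with attribute `"total"`
#' @export
tallyByClass <- function(x) {
  cls <- x$class
  levels <- c(HOMEOBOX_CLASSES, "Others")
  unknown <- setdiff(unique(cls), levels)
  if (length(unknown))
    stop("unknown class label(s): ", paste(unknown, collapse = ", "))
  counts <- vapply(levels, function(l) sum(cls == l), 0L)
  attr(counts, "total") <- sum(counts)
  counts
}

#' Number of canonical classes represented
#'
#' Counts how many of the eleven canonical metazoan classes have at least
#' one gene; `"Others"` is excluded.
#'
#' @param tally named counts from [tallyByClass()]
#' @return integer in 0..11
#' @export
classesPresent <- function(tally) {
  sum(tally[HOMEOBOX_CLASSES] >= 1)
}

#' Count evolutionarily novel genes
#'
#' With an `is_novel` column (pipeline annotations after [callNovel()]),
#' counts flagged genes. On a repertoire table without that column, a gene
#' is novel when its family is undetermined (`"n.d."`) or is a
#' lineage-specific clade label rather than an ancient family.
#'
#' @param x annotation data.frame or repertoire table
#' @return integer count
#' @export
countNovelGenes <- function(x) {
  if (!is.null(x$is_novel) && !all(is.na(x$is_novel)))
    return(sum(x$is_novel, na.rm = TRUE))
  sum(x$family == "n.d." | grepl("Clade", x$family))
}

#' Count genes assigned to lineage-specific clades
#'
#' Counts repertoire genes whose family column names one of the clades in
#' the clade table, plus the members of the clade-restricted engrailed and
#' Hmx duplicate groups. Clade labels referenced by the repertoire but
#' absent from the clade table raise an error.
#'
#' @param x repertoire table (class/family/gene_name columns)
#' @param cladeTable clade table as in [loadFixtureTables()]`$clades`
#' @param duplicateMembers gene names belonging to the engrailed and Hmx
#'   duplicate groups listed in the clade table
#' @return integer count
#' @export
countCladeGenes <- function(x, cladeTable = loadFixtureTables()$clades,
                            duplicateMembers = c(engrailed = "En2",
                                                 Hmx = "Hmx1")) {
  labels <- paste(cladeTable$class, cladeTable$clade)
  # repertoire spells the NKL and CUT clades with their own capitalization
  norm <- toupper(gsub("[ _]", "", labels))
  famLabels <- unique(x$family[grepl("Clade", x$family)])
  famNorm <- toupper(gsub("[ _]", "", famLabels))
  missing <- famLabels[!famNorm %in% norm]
  if (length(missing))
    stop("clade(s) referenced but undefined: ",
         paste(missing, collapse = ", "))
  inClade <- sum(x$family %in% famLabels)
  dups <- 0L
  for (grp in names(duplicateMembers)) {
    if (any(cladeTable$clade == grp))
      dups <- dups + sum(x$gene_name %in% duplicateMembers[[grp]])
  }
  inClade + dups
}

#' Number of clades in a clade table
#'
#' @param cladeTable clade table as in [loadFixtureTables()]`$clades`
#' @return integer row count
#' @export
countClades <- function(cladeTable = loadFixtureTables()$clades) {
  nrow(cladeTable)
}

#' Per-species totals of a class-count table
#'
#' Sums the per-class rows (excluding any printed total row) for each
#' species column of a class-count comparison table.
#'
#' @param classCounts table as in [loadFixtureTables()]`$classCounts`
#' @return named numeric vector of column sums per species
#' @export
speciesTotals <- function(classCounts = loadFixtureTables()$classCounts) {
  rows <- classCounts$class != "Number of genes"
  cols <- setdiff(names(classCounts), "class")
  vapply(cols, function(cl) sum(classCounts[rows, cl]), 0)
}
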