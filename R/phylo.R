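#' p-distance matrix from aligned homeodomains
#'
#' Pairwise fraction of differing columns over columns where neither
#' sequence is gapped. Pairs with fewer than 30 comparable columns are
#' flagged in the `"flagged"` attribute.
#'
#' @param alignment `AAStringSet` or named character vector of equal-length
#'   aligned sequences (gap character `-`)
#' @return symmetric numeric matrix with zero diagonal; attribute
#'   `"flagged"` holds a two-column matrix of low-overlap pairs (labels)
#' @export
pdistanceMatrix <- function(alignment) {
  nm <- names(alignment)
  seqs <- as.character(alignment)
  if (!is.null(nm)) names(seqs) <- nm
  if (length(seqs) < 2) stop("need at least two sequences")
  if (length(unique(nchar(seqs))) != 1) stop("unequal sequence lengths")
  if (is.null(names(seqs))) names(seqs) <- paste0("s", seq_along(seqs))
  mat <- do.call(rbind, strsplit(seqs, ""))
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  flagged <- NULL
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      comp <- mat[i, ] != "-" & mat[j, ] != "-"
      nc <- sum(comp)
      dij <- if (nc == 0) 1 else mean(mat[i, comp] != mat[j, comp])
      d[i, j] <- d[j, i] <- dij
      if (nc < 30)
        flagged <- rbind(flagged, c(names(seqs)[i], names(seqs)[j]))
    }
  }
  attr(d, "flagged") <- flagged
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor-joining ([ape::nj()]) with input validation; on
#' additive matrices this recovers the generating topology exactly. The
#' returned tree is unrooted and Newick-serializable
#' ([ape::write.tree()]).
#'
#' @param dm symmetric nonnegative distance matrix with zero diagonal and
#'   at least three labelled taxa
#' @return an unrooted `phylo` tree
#' @export
njTree <- function(dm) {
  dm <- as.matrix(dm)
  if (nrow(dm) < 3) stop("need at least three taxa")
  if (any(!is.finite(dm))) stop("non-finite distances")
  if (max(abs(dm - t(dm))) > 1e-12) stop("distance matrix must be symmetric")
  ape::nj(stats::as.dist(dm))
}

# character matrix (sequences x columns) from aligned sequences
.alnMatrix <- function(alignment) {
  nm <- names(alignment)
  seqs <- as.character(alignment)
  if (!is.null(nm)) names(seqs) <- nm
  if (is.null(names(seqs))) names(seqs) <- paste0("s", seq_along(seqs))
  m <- do.call(rbind, strsplit(seqs, ""))
  rownames(m) <- names(seqs)
  m
}

#' Bootstrap support for neighbor-joining clades
#'
#' Resamples alignment columns with replacement, rebuilds the p-distance
#' neighbor-joining tree, and counts how often each clade of the full-data
#' tree recurs. Seeded and reproducible.
#'
#' @param alignment aligned sequences as for [pdistanceMatrix()]
#' @param nReps number of bootstrap replicates (>= 1)
#' @param seed integer seed
#' @return list with `tree` (the full-data `phylo`) and `support`
#'   (percent support for each internal node, in `phylo` node order)
#' @export
bootstrapSupport <- function(alignment, nReps = 1000, seed = 1) {
  stopifnot(nReps >= 1)
  m <- .alnMatrix(alignment)
  build <- function(x) njTree(.pdistFromMatrix(x))
  tree <- build(m)
  set.seed(seed)
  counts <- ape::boot.phylo(tree, m, build, B = nReps, quiet = TRUE)
  list(tree = tree, support = 100 * counts / nReps)
}

# p-distance on a character matrix (no flagging; used in bootstrap loop)
.pdistFromMatrix <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      comp <- m[i, ] != "-" & m[j, ] != "-"
      d[i, j] <- d[j, i] <- if (!any(comp)) 1
                            else mean(m[i, comp] != m[j, comp])
    }
  }
  d
}

#' Bootstrap support for a specific clade
#'
#' Convenience accessor: percent of replicates containing the clade whose
#' members are `tips`, taken from a [bootstrapSupport()] result.
#'
#' @param bs result of [bootstrapSupport()]
#' @param tips tip labels defining the clade
#' @return support percent (NA if the tips are not monophyletic in the
#'   full-data tree)
#' @export
cladeSupport <- function(bs, tips) {
  tree <- bs$tree
  labs <- tree$tip.label
  pp <- ape::prop.part(tree)  # tip sets per internal node, node order
  for (i in seq_along(pp)) {
    set <- labs[pp[[i]]]
    # unrooted tree: a clade is a bipartition, so accept the complement too
    if (setequal(set, tips) || setequal(set, setdiff(labs, tips)))
      return(unname(bs$support[i]))
  }
  NA_real_
}

#' Most specific taxon spanning a set of species
#'
#' Lowest common ancestor over the lineage lists of the member species:
#' the most specific taxon whose lineage contains every member. Used to
#' date the origin of a clade from its taxonomic distribution.
#'
#' @param species character vector of member species
#' @param taxa a [TaxonMap-class]
#' @return single taxon label
#' @export
taxonomicDistribution <- function(species, taxa) {
  stopifnot(is(taxa, "TaxonMap"), length(species) >= 1)
  unknown <- setdiff(species, taxonSpecies(taxa))
  if (length(unknown))
    stop("unknown species: ", paste(unknown, collapse = ", "))
  lins <- lapply(unique(species), lineageOf, x = taxa)
  cand <- lins[[1]]
  for (t in cand) {
    if (all(vapply(lins, function(l) t %in% l, TRUE))) return(t)
  }
  stop("lineages share no common taxon")  # unreachable for valid TaxonMap
}

#' Is a taxon nested within (or equal to) another?
#'
#' @param taxon taxon label to test
#' @param within enclosing taxon label
#' @param taxa a [TaxonMap-class]
#' @return logical
#' @export
taxonWithin <- function(taxon, within, taxa) {
  if (identical(taxon, within)) return(TRUE)
  for (lin in taxa@lineages) {
    i <- match(taxon, lin); j <- match(within, lin)
    if (!is.na(i) && !is.na(j)) return(i < j)
  }
  FALSE
}

#' Flag evolutionarily novel genes
#'
#' A gene is novel when its family is undetermined (`"n.d."`), when it is
#' assigned to a clade whose taxonomic distribution lies within the
#' Lophotrochozoa, or when it belongs to the lophotrochozoan-restricted
#' engrailed / Hmx duplicate groups.
#'
#' @param annotations annotation data.frame from [classifyHits()]
#' @param cladeTable clade table with columns `class`, `clade`,
#'   `taxonomic_distribution` (default: the packaged transcription)
#' @param taxa a [TaxonMap-class] used to interpret distributions
#' @return `annotations` with `is_novel` filled in
#' @export
callNovel <- function(annotations,
                      cladeTable = loadFixtureTables()$clades,
                      taxa = readTaxonMap()) {
  cladeLabel <- paste(cladeTable$class, cladeTable$clade)
  dist <- setNames(cladeTable$taxonomic_distribution, cladeLabel)
  lophClade <- function(clades) {
    if (is.na(clades)) return(FALSE)
    for (cl in strsplit(clades, ";", fixed = TRUE)[[1]]) {
      if (cl %in% c("ANTP_NKL engrailed", "ANTP_NKL Hmx")) return(TRUE)
      if (cl == "TALE Clade VI/VII") return(TRUE)  # both molluscan
      d <- dist[cl]
      # distribution may be a compound label; test its components
      if (!is.na(d)) {
        parts <- strsplit(d, " ", fixed = TRUE)[[1]]
        if (any(vapply(parts, taxonWithin, TRUE,
                       within = "Lophotrochozoa", taxa = taxa)))
          return(TRUE)
      }
    }
    FALSE
  }
  annotations$is_novel <- annotations$family == "n.d." |
    vapply(annotations$clade, lophClade, TRUE)
  annotations
}
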