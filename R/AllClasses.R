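#' Position-specific scoring profile for the homeodomain
#'
#' Log-odds profile over the 60 canonical homeodomain columns (or a variant
#' with neutral insertion columns), built from a gapless seed alignment by
#' [buildProfile()]. Scores are in bits relative to a background
#' amino-acid distribution.
#'
#' @slot scores numeric matrix, 21 rows (20 canonical residues plus a
#'   neutral "X" row of zeros) by one column per profile position.
#' @slot background named numeric vector of 20 background frequencies
#'   summing to one.
#' @slot pseudocount positive weight of the background-proportional
#'   pseudocounts used when the profile was built.
#'
#' @seealso [buildProfile()], [profileScan()], [consensusScore()]
#' @exportClass HomeodomainProfile
setClass("HomeodomainProfile",
  representation(scores = "matrix", background = "numeric",
                 pseudocount = "numeric"))

setValidity("HomeodomainProfile", function(object) {
  msg <- character()
  if (!identical(rownames(object@scores), c(AA20, "X")))
    msg <- c(msg, "score rows must be the 20 canonical residues plus X")
  if (any(!is.finite(object@scores)))
    msg <- c(msg, "log-odds scores must be finite")
  if (length(object@background) != 20 ||
      abs(sum(object@background) - 1) > 1e-8)
    msg <- c(msg, "background must be 20 frequencies summing to 1")
  if (length(object@pseudocount) != 1 || object@pseudocount < 0)
    msg <- c(msg, "pseudocount must be a single nonnegative number")
  if (length(msg)) msg else TRUE
})

setMethod("show", "HomeodomainProfile", function(object) {
  cat("HomeodomainProfile with", ncol(object@scores), "columns\n")
  cat("  pseudocount weight:", object@pseudocount, "\n")
  cat("  consensus score:", round(consensusScore(object), 2), "bits\n")
})

#' @describeIn HomeodomainProfile number of profile columns
#' @param x a `HomeodomainProfile`
#' @export
profileWidth <- function(x) ncol(x@scores)

#' Maximum attainable profile score
#'
#' Sum of the per-column maxima of the log-odds matrix: the score of the
#' profile consensus against itself, an upper bound on the score of any
#' sequence window.
#'
#' @param profile a [HomeodomainProfile-class] object
#' @return a single numeric score in bits
#' @export
consensusScore <- function(profile) {
  stopifnot(is(profile, "HomeodomainProfile"))
  sum(apply(profile@scores[AA20, , drop = FALSE], 2, max))
}

#' Species-to-lineage taxonomy map
#'
#' Maps each species to its ordered lineage, from the species itself up to a
#' shared root taxon (e.g. Bilateria). Used to date clade origins: the
#' taxonomic distribution of a clade is the most specific taxon containing
#' all its member species ([taxonomicDistribution()]).
#'
#' @slot lineages named list; each element is a character vector ordered
#'   from most specific (the species) to most general (the common root).
#'
#' @seealso [readTaxonMap()], [taxonomicDistribution()]
#' @exportClass TaxonMap
setClass("TaxonMap", representation(lineages = "list"))

setValidity("TaxonMap", function(object) {
  lin <- object@lineages
  msg <- character()
  if (length(lin) == 0 || is.null(names(lin)) || any(names(lin) == ""))
    msg <- c(msg, "lineages must be a named, non-empty list")
  if (any(vapply(lin, length, 0L) == 0))
    msg <- c(msg, "every lineage must be non-empty")
  roots <- vapply(lin, function(x) x[length(x)], "")
  if (length(unique(roots)) > 1)
    msg <- c(msg, "all lineages must end in a common root")
  if (length(msg)) msg else TRUE
})

setMethod("show", "TaxonMap", function(object) {
  cat("TaxonMap for", length(object@lineages), "species; root:",
      object@lineages[[1]][length(object@lineages[[1]])], "\n")
})

#' @describeIn TaxonMap species names in the map
#' @param x a `TaxonMap`
#' @export
taxonSpecies <- function(x) names(x@lineages)

#' @describeIn TaxonMap lineage for one species
#' @param species single species name
#' @export
lineageOf <- function(x, species) {
  if (!species %in% names(x@lineages))
    stop("unknown species: ", species)
  x@lineages[[species]]
}

#' Construct a taxonomy map from lineages
#'
#' @param lineages named list of character lineages (most specific first)
#' @return a [TaxonMap-class] object
#' @export
TaxonMap <- function(lineages) new("TaxonMap", lineages = lineages)
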