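#' Read a protein FASTA file
#'
#' Reads protein sequences, uppercases them, and validates the alphabet
#' (20 canonical residues plus `X`). The description line is parsed into an
#' id (first whitespace-delimited token) and an optional species tag using
#' the `id|species` dialect; a species side table can be supplied instead.
#'
#' @param path path to a FASTA file
#' @param species optional named character vector mapping id to species;
#'   overrides any `id|species` header tags
#' @return an [Biostrings::AAStringSet] named by id, with a `species`
#'   metadata column (NA where unknown)
#' @export
readProteinFasta <- function(path, species = NULL) {
  stopifnot(file.exists(path))
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0) {
    warning("empty FASTA file: ", path)
    out <- Biostrings::AAStringSet()
    mcols(out) <- S4Vectors::DataFrame(species = character(0))
    return(out)
  }
  desc <- names(raw)
  ids <- vapply(strsplit(desc, "[ \t|]+"), `[`, "", 1L)
  hasPipe <- grepl("|", desc, fixed = TRUE)
  sp <- ifelse(hasPipe, trimws(sub("^[^|]*\\|", "", desc)), NA_character_)
  if (anyDuplicated(ids))
    stop("duplicate ids in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(as.character(raw))
  bad <- !grepl(paste0("^[", paste(AA20, collapse = ""), "X]+$"), seqs)
  if (any(bad))
    stop("invalid residues in sequence(s): ",
         paste(ids[bad], collapse = ", "))
  out <- Biostrings::AAStringSet(seqs)
  names(out) <- ids
  if (!is.null(species)) sp <- unname(species[ids])
  mcols(out) <- S4Vectors::DataFrame(species = sp)
  out
}

#' Write proteins to FASTA
#'
#' Inverse of [readProteinFasta()]: ids (and species, where present, as
#' `id|species`) form the headers.
#'
#' @param x an `AAStringSet` with optional `species` metadata column
#' @param path output path
#' @return `path`, invisibly
#' @export
writeProteinFasta <- function(x, path) {
  out <- x
  sp <- if (!is.null(mcols(x)$species)) mcols(x)$species else NA
  nm <- ifelse(is.na(sp), names(x), paste0(names(x), "|", sp))
  names(out) <- nm
  Biostrings::writeXStringSet(out, path)
  invisible(path)
}

#' Drop short protein records
#'
#' Keeps records whose sequence is strictly longer than `minLen`. The
#' default of 40 mirrors the candidate-assembly rule that incomplete
#' database records of 40 residues or fewer are discarded.
#'
#' @param x an `AAStringSet`
#' @param minLen minimum exclusive length (records of exactly `minLen`
#'   residues are dropped)
#' @return the filtered `AAStringSet`, input order preserved
#' @export
lengthFilter <- function(x, minLen = 40) {
  stopifnot(minLen >= 0)
  x[Biostrings::width(x) > minLen]
}

#' Read gene models from a 6-column TSV
#'
#' The interchange format is a tab-separated table with header
#' `gene_id, scaffold, start, end, strand, is_homeobox`, coordinates
#' 0-based half-open. Internally models are held as a
#' [GenomicRanges::GRanges] (1-based closed) with a dense 0-based `rank`
#' per scaffold reflecting gene-model order along the scaffold.
#'
#' @param path path to the TSV
#' @return `GRanges` with metadata columns `gene_id`, `is_homeobox`, `rank`
#' @export
readGeneModels <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "scaffold", "start", "end", "strand", "is_homeobox")
  if (!all(need %in% names(df)))
    stop("gene-model TSV must have columns: ", paste(need, collapse = ", "))
  if (any(df$start >= df$end)) stop("gene models must satisfy start < end")
  if (!all(df$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  geneModels(df$gene_id, df$scaffold, df$start + 1L, df$end,
             df$strand, as.logical(df$is_homeobox))
}

#' Build a gene-model GRanges
#'
#' @param gene_id,scaffold,start,end,strand,is_homeobox parallel vectors;
#'   coordinates 1-based closed
#' @return `GRanges` with `gene_id`, `is_homeobox` and per-scaffold `rank`
#' @export
geneModels <- function(gene_id, scaffold, start, end, strand, is_homeobox) {
  gr <- GenomicRanges::GRanges(scaffold, IRanges::IRanges(start, end),
                               strand = strand)
  mcols(gr)$gene_id <- gene_id
  mcols(gr)$is_homeobox <- is_homeobox
  gr <- gr[order(as.character(seqnames(gr)), GenomicRanges::start(gr))]
  rk <- unlist(lapply(split(seq_along(gr), as.character(seqnames(gr))),
                      function(i) seq_along(i) - 1L), use.names = FALSE)
  mcols(gr)$rank <- rk
  gr
}

#' Write gene models to the 6-column TSV interchange format
#'
#' @param gr gene-model `GRanges` from [geneModels()]
#' @param path output path
#' @return `path`, invisibly
#' @export
writeGeneModels <- function(gr, path) {
  df <- data.frame(gene_id = mcols(gr)$gene_id,
                   scaffold = as.character(seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   strand = as.character(strand(gr)),
                   is_homeobox = mcols(gr)$is_homeobox)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a genes-by-stages expression matrix
#'
#' Expects a TSV whose header row names the ordered developmental stages and
#' whose first column holds gene ids; values are nonnegative expression
#' levels (RPKM).
#'
#' @param path path to the TSV
#' @return numeric matrix, genes in rows, stages in columns
#' @export
readExpressionMatrix <- function(path) {
  df <- read.delim(path, row.names = 1, check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df)
  if (any(m < 0)) stop("expression values must be nonnegative")
  m
}

#' Describe an ordered developmental stage series
#'
#' @param stages character vector of stage names in developmental order
#' @param trochophore index (or contiguous indices) of the trochophore
#'   stage block within `stages`
#' @return a `stage_map` list used by [categorizeStage()] and friends
#' @export
stageMap <- function(stages, trochophore) {
  stopifnot(length(stages) >= 1, all(trochophore %in% seq_along(stages)),
            all(diff(sort(trochophore)) == 1))
  structure(list(stages = stages, trochophore = sort(trochophore)),
            class = "stage_map")
}

#' Default oyster-like developmental stage series
#'
#' Ten ordered stages from egg to juvenile with the trochophore as the
#' single mid-developmental (candidate phylotypic) stage.
#'
#' @return a `stage_map`
#' @export
defaultStages <- function() {
  stageMap(c("egg", "two_cell", "morula", "blastula", "gastrula",
             "trochophore", "d_larva", "umbo_larva", "pediveliger",
             "juvenile"), trochophore = 6)
}

#' Read a species-to-lineage taxonomy TSV
#'
#' Two columns: `species` and `lineage` (semicolon-separated, most specific
#' taxon first, ending at the shared root).
#'
#' @param path path to the TSV; defaults to the packaged lophotrochozoan map
#' @return a [TaxonMap-class]
#' @export
readTaxonMap <- function(path = system.file("extdata",
    "taxonomy_lophotrochozoa.tsv", package = "homeokit")) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  TaxonMap(setNames(strsplit(df$lineage, ";", fixed = TRUE), df$species))
}

#' Load the packaged repertoire tables
#'
#' Machine-readable transcriptions of the published Pacific oyster homeobox
#' tables: the full classified repertoire (class, family, gene name, gene
#' model), the per-class counts for five bilaterian species, and the list
#' of lophotrochozoan-specific clades with taxonomic distribution and
#' bootstrap support (`NA` where no monophyletic support was obtained).
#'
#' @return list with elements `repertoire`, `classCounts`, `clades`
#' @export
loadFixtureTables <- function() {
  f <- function(x) {
    p <- system.file("extdata", x, package = "homeokit")
    if (p == "" || !file.exists(p)) stop("missing packaged fixture: ", x)
    read.delim(p, check.names = FALSE, stringsAsFactors = FALSE)
  }
  list(repertoire = f("table1_oyster_repertoire.tsv"),
       classCounts = f("table2_class_counts.tsv"),
       clades = f("table3_novel_clades.tsv"))
}
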