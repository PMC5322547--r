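#' Simulation specification
#'
#' Bundles every knob of the seeded generators: proteome composition
#' ([genProteome()]), scaffold layout ([genScaffoldMap()]) and stage-series
#' expression ([genExpressionMatrix()]). All generators are pure functions
#' of the spec: the same seed yields byte-identical output.
#'
#' @param seed integer RNG seed
#' @param genesPerFamily planted genes per exemplar family (default 2:
#'   56 genes across all eleven classes)
#' @param novelGenes data.frame(`feature`, `base_family`, `count`) of
#'   clade-motif genes to plant; features are `NKL_I` (terminal KEKR),
#'   `PRD_VI` (SPQQVRS), `TALE_VI` (QVKK), `TALE_VII` (PADRE),
#'   `En_loph` (C at 23), `Hmx_loph` (H at 10). NULL plants one of each.
#' @param decoys number of random decoy proteins (default 200)
#' @param decoyLength decoy length (default 300, uniform composition)
#' @param noiseRate per-residue substitution probability applied to
#'   planted genes (default 0); diagnostic positions keep their planted
#'   state with probability 0.5 when selected
#' @param novelDivergence extra substitution rate applied to the
#'   homeodomain of clade-motif genes (default 0.25)
#' @param motifProb probability a gene of a companion-domain class carries
#'   its companion motif (default 1)
#' @param layout named list of integer vectors: for each scaffold, the
#'   numbers of non-homeobox gene models between consecutive homeobox
#'   genes (an empty vector plants a lone gene). NULL uses a default mix
#'   of pairs, a triple and singletons.
#' @param layoutPad non-homeobox models padding each scaffold end
#' @param window linkage window used to define planted cluster truth
#' @param stages a `stage_map` for the expression series
#' @param nOld,nNovel numbers of old and novel genes in the expression
#'   series (defaults 60 and 0)
#' @param oldCatProbs,novelCatProbs optional length-3 proportions of the
#'   group peaking early / at trochophore / late, planted as an exact
#'   composition; NULL draws peak stages uniformly over all stages
#' @param baseline baseline expression level (RPKM, default 10)
#' @param fold peak fold-change (>= 1, default 4)
#' @param cv coefficient of variation of the multiplicative log-normal
#'   noise (default 0.2)
#' @return a `sim_spec` list
#' @export
simSpec <- function(seed = 1, genesPerFamily = 2, novelGenes = NULL,
                    decoys = 200, decoyLength = 300, noiseRate = 0,
                    novelDivergence = 0.25, motifProb = 1,
                    layout = NULL, layoutPad = 6, window = 5,
                    stages = defaultStages(), nOld = 60, nNovel = 0,
                    oldCatProbs = NULL, novelCatProbs = NULL,
                    baseline = 10, fold = 4, cv = 0.2) {
  stopifnot(fold >= 1, cv >= 0, noiseRate >= 0, noiseRate <= 1,
            decoys >= 0, genesPerFamily >= 0)
  if (is.null(novelGenes))
    novelGenes <- data.frame(
      feature = c("NKL_I", "PRD_VI", "TALE_VI", "TALE_VII", "En_loph",
                  "Hmx_loph"),
      base_family = c("Msx", "Otx", "Meis", "Pbx", "En", "Nk5/Hmx"),
      count = 1L, stringsAsFactors = FALSE)
  if (is.null(layout))
    layout <- list(scaffold_1 = c(0L), scaffold_2 = c(3L),
                   scaffold_3 = c(6L), scaffold_4 = integer(0),
                   scaffold_5 = c(0L, 2L), scaffold_6 = c(1L, 7L))
  structure(list(seed = seed, genesPerFamily = genesPerFamily,
                 novelGenes = novelGenes, decoys = decoys,
                 decoyLength = decoyLength, noiseRate = noiseRate,
                 novelDivergence = novelDivergence, motifProb = motifProb,
                 layout = layout, layoutPad = layoutPad, window = window,
                 stages = stages, nOld = nOld, nNovel = nNovel,
                 oldCatProbs = oldCatProbs, novelCatProbs = novelCatProbs,
                 baseline = baseline, fold = fold, cv = cv),
            class = "sim_spec")
}

# substitute residues at `rate`; positions in `protect` keep their planted
# state with probability 0.5 when selected for substitution
.mutateSeq <- function(chars, rate, protect = integer(0)) {
  if (rate <= 0) return(chars)
  hit <- which(runif(length(chars)) < rate)
  for (i in hit) {
    if (i %in% protect && runif(1) < 0.5) next
    chars[i] <- sample(setdiff(AA20, chars[i]), 1)
  }
  chars
}

.randomFlank <- function(range) {
  paste(sample(AA20, sample(range[1]:range[2], 1), replace = TRUE),
        collapse = "")
}

#' Generate a proteome with planted homeodomains
#'
#' Plants, for each exemplar family, genes carrying the family homeodomain
#' with its class-diagnostic features (position-50 residue, TALE or HNF
#' insertion, companion motif in the N-terminal flank), plus clade-motif
#' genes (terminal KEKR, SPQQVRS, QVKK, PADRE, C23 engrailed, H10 Hmx),
#' embedded in random flanks among uniform-composition decoy proteins.
#' Fully determined by the seed.
#'
#' @param spec a [simSpec()]
#' @param references exemplar table (default the packaged set)
#' @param motifLibrary motif table (default the packaged set)
#' @return list with `proteins` (`AAStringSet`) and `truth` (data.frame:
#'   `id`, `class`, `family`, `clade`, `insertion`, `hd_start`, `hd_end`,
#'   `is_novel`)
#' @export
genProteome <- function(spec, references = defaultFamilyExemplars(),
                        motifLibrary = defaultMotifLibrary()) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  classMotifs <- motifLibrary[motifLibrary$kind == "class", ]
  companions <- setNames(classMotifs$sequence, classMotifs$asserts)
  padre <- motifLibrary$sequence[motifLibrary$motif == "PADRE"]
  featureClade <- c(NKL_I = "ANTP_NKL Clade I", PRD_VI = "PRD Clade VI",
                    TALE_VI = "TALE Clade VI", TALE_VII = "TALE Clade VI/VII",
                    En_loph = "ANTP_NKL engrailed", Hmx_loph = "ANTP_NKL Hmx")
  seqs <- character(0); truth <- NULL
  plant <- function(id, family, feature = NA_character_) {
    ref <- references[references$family == family, ]
    cls <- ref$class
    hd <- strsplit(ref$sequence, "")[[1]]
    protect <- 50L
    clade <- NA_character_
    if (!is.na(feature)) {
      hd <- .mutateSeq(hd, spec$novelDivergence, protect = protect)
      hd[50] <- strsplit(ref$sequence, "")[[1]][50]
      if (feature == "En_loph") { hd[23] <- "C"; protect <- c(protect, 23L) }
      if (feature == "Hmx_loph") { hd[10] <- "H"; protect <- c(protect, 10L) }
      clade <- unname(featureClade[feature])
    }
    hd <- .mutateSeq(hd, spec$noiseRate, protect = protect)
    insertion <- "none"
    if (cls == "TALE") {
      hd <- append(hd, sample(AA20, 3, replace = TRUE), after = 23)
      insertion <- "tale_3aa"
    } else if (cls == "HNF") {
      hd <- append(hd, sample(AA20, 4, replace = TRUE), after = 39)
      insertion <- "hnf_helix23"
    }
    nflank <- .randomFlank(c(30, 120))
    if (cls %in% names(companions) && runif(1) < spec$motifProb) {
      mot <- .mutateSeq(strsplit(companions[[cls]], "")[[1]], spec$noiseRate)
      at <- sample(0:nchar(nflank), 1)
      nflank <- paste0(substr(nflank, 1, at), paste(mot, collapse = ""),
                       substr(nflank, at + 1, nchar(nflank)))
    }
    pre <- nflank
    if (!is.na(feature) && feature %in% c("TALE_VI", "TALE_VII")) {
      spacer <- .randomFlank(c(0, 20))
      pre <- paste0(nflank,
                    paste(.mutateSeq(strsplit(padre, "")[[1]],
                                     spec$noiseRate), collapse = ""),
                    spacer)
    }
    body <- paste(hd, collapse = "")
    if (!is.na(feature) && feature == "TALE_VI") body <- paste0(body, "QVKK")
    if (!is.na(feature) && feature == "PRD_VI") body <- paste0(body, "SPQQVRS")
    cflank <- .randomFlank(c(20, 80))
    tail <- if (!is.na(feature) && feature == "NKL_I") "KEKR" else ""
    seq <- paste0(pre, body, cflank, tail)
    truth <<- rbind(truth, data.frame(
      id = id, class = cls, family = family, clade = clade,
      insertion = insertion, hd_start = nchar(pre) + 1L,
      hd_end = nchar(pre) + length(hd), is_novel = !is.na(feature),
      stringsAsFactors = FALSE))
    seqs[id] <<- seq
  }
  for (f in seq_len(nrow(references))) {
    fam <- references$family[f]
    famId <- gsub("[^A-Za-z0-9]", "_", fam)
    for (g in seq_len(spec$genesPerFamily))
      plant(sprintf("%s_g%d", famId, g), fam)
  }
  ng <- spec$novelGenes
  for (i in seq_len(nrow(ng))) {
    for (g in seq_len(ng$count[i]))
      plant(sprintf("novel_%s_g%d", ng$feature[i], g), ng$base_family[i],
            feature = ng$feature[i])
  }
  for (d in seq_len(spec$decoys))
    seqs[sprintf("decoy_%03d", d)] <-
      paste(sample(AA20, spec$decoyLength, replace = TRUE), collapse = "")
  proteins <- Biostrings::AAStringSet(seqs)
  mcols(proteins) <- S4Vectors::DataFrame(
    species = rep("Crassostrea gigas", length(proteins)))
  list(proteins = proteins, truth = truth)
}

#' Generate a scaffold map with planted homeobox clusters
#'
#' Lays out homeobox genes separated by the specified numbers of
#' non-homeobox gene models on each scaffold, padded with non-homeobox
#' models at both ends; coordinates are consistent with ranks. The truth
#' table groups homeobox genes into the clusters implied by the spec's
#' linkage window.
#'
#' @param spec a [simSpec()]
#' @return list with `map` (gene-model `GRanges`) and `truth` (data.frame:
#'   `gene_id`, `scaffold`, `rank`, `cluster`)
#' @export
genScaffoldMap <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed + 1L)
  rows <- NULL; truth <- NULL
  for (sc in names(spec$layout)) {
    gaps <- spec$layout[[sc]]
    nHb <- if (length(gaps)) length(gaps) + 1L else 1L
    flags <- rep(FALSE, spec$layoutPad)
    for (k in seq_len(nHb)) {
      flags <- c(flags, TRUE)
      if (k <= length(gaps)) flags <- c(flags, rep(FALSE, gaps[k]))
    }
    flags <- c(flags, rep(FALSE, spec$layoutPad))
    ids <- sprintf("%s_m%d", sc, seq_along(flags))
    ids[flags] <- sprintf("%s_hb%d", sc, seq_len(sum(flags)))
    start <- (seq_along(flags) - 1L) * 1500L + 1L
    rows <- rbind(rows, data.frame(
      gene_id = ids, scaffold = sc, start = start, end = start + 999L,
      strand = sample(c("+", "-"), length(flags), replace = TRUE),
      is_homeobox = flags, stringsAsFactors = FALSE))
    hbIdx <- which(flags)
    grp <- cumsum(c(TRUE, if (length(gaps)) gaps > spec$window
                          else logical(0)))
    truth <- rbind(truth, data.frame(
      gene_id = ids[hbIdx], scaffold = sc, rank = hbIdx - 1L,
      cluster = paste0(sc, "_c", grp), stringsAsFactors = FALSE))
  }
  map <- geneModels(rows$gene_id, rows$scaffold, rows$start, rows$end,
                    rows$strand, rows$is_homeobox)
  list(map = map, truth = truth)
}

#' Generate a stage-series expression matrix with planted peaks
#'
#' Each gene receives mean `baseline * fold` at its planted peak stage and
#' `baseline` elsewhere, under mean-preserving multiplicative log-normal
#' noise with the given coefficient of variation. Peak stages are drawn
#' uniformly over stages; when early/trochophore/late category
#' proportions are supplied, the group's category composition is planted
#' exactly (largest-remainder rounding, shuffled across genes) and the
#' stage is drawn uniformly within the category's stage block.
#'
#' @param spec a [simSpec()]
#' @return list with `matrix` (genes x stages) and `truth` (data.frame:
#'   `gene`, `is_novel`, `peak_index`, `peak_stage`, `category`)
#' @export
genExpressionMatrix <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed + 2L)
  st <- spec$stages
  nStages <- length(st$stages)
  tr <- st$trochophore
  blocks <- list(early = seq_len(min(tr) - 1), trochophore = tr,
                 late = if (max(tr) < nStages) (max(tr) + 1):nStages
                        else integer(0))
  # exact composition by largest-remainder rounding, shuffled over genes
  groupCats <- function(nGenes, catProbs) {
    raw <- nGenes * catProbs / sum(catProbs)
    counts <- floor(raw)
    extra <- order(raw - counts, decreasing = TRUE)
    counts[extra[seq_len(nGenes - sum(counts))]] <-
      counts[extra[seq_len(nGenes - sum(counts))]] + 1
    sample(rep(names(blocks), counts))
  }
  stageIn <- function(cat) {
    b <- blocks[[cat]]
    if (!length(b)) stop("category '", cat, "' has no stages")
    as.integer(if (length(b) == 1) b else sample(b, 1))
  }
  groupPeaks <- function(nGenes, catProbs) {
    if (nGenes == 0) return(integer(0))
    if (is.null(catProbs)) return(sample.int(nStages, nGenes, replace = TRUE))
    vapply(groupCats(nGenes, catProbs), stageIn, 0L)
  }
  n <- spec$nOld + spec$nNovel
  novel <- c(rep(FALSE, spec$nOld), rep(TRUE, spec$nNovel))
  peaks <- c(groupPeaks(spec$nOld, spec$oldCatProbs),
             groupPeaks(spec$nNovel, spec$novelCatProbs))
  sigma <- sqrt(log(1 + spec$cv^2))
  means <- matrix(spec$baseline, n, nStages)
  means[cbind(seq_len(n), peaks)] <- spec$baseline * spec$fold
  noise <- matrix(exp(rnorm(n * nStages, -sigma^2 / 2, sigma)), n, nStages)
  m <- means * noise
  rownames(m) <- sprintf("%s_%03d", ifelse(novel, "novel", "old"),
                         seq_len(n))
  colnames(m) <- st$stages
  truth <- data.frame(gene = rownames(m), is_novel = novel,
                      peak_index = peaks, peak_stage = st$stages[peaks],
                      category = categorizeStage(peaks, st),
                      stringsAsFactors = FALSE)
  list(matrix = m, truth = truth)
}
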