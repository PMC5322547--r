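#' Build a homeodomain scoring profile from a seed alignment
#'
#' Computes per-column log-odds (bits) from a gapless 60-column alignment
#' with background-proportional additive pseudocounts:
#' `log2(((count + w * bg) / (n + w)) / bg)` for pseudocount weight `w` and
#' background frequency `bg`.
#'
#' @param alignment `AAStringSet` or character vector; at least two
#'   sequences of equal length (canonically 60)
#' @param background named vector of 20 background frequencies (default
#'   uniform)
#' @param pseudocount pseudocount weight (default 1)
#' @return a [HomeodomainProfile-class]
#' @export
buildProfile <- function(alignment, background = setNames(rep(1/20, 20), AA20),
                         pseudocount = 1) {
  seqs <- as.character(alignment)
  if (length(seqs) < 1) stop("alignment must contain sequences")
  W <- unique(nchar(seqs))
  if (length(W) != 1) stop("ragged alignment: unequal sequence lengths")
  background <- background[AA20]
  chars <- do.call(rbind, strsplit(seqs, ""))
  counts <- apply(chars, 2, function(col) {
    tabulate(factor(col, levels = AA20), nbins = 20)
  })
  n <- length(seqs)
  freq <- sweep(counts + pseudocount * background, 2, n + pseudocount, "/")
  scores <- log2(sweep(freq, 1, background, "/"))
  rownames(scores) <- AA20
  scores <- rbind(scores, X = rep(0, W))  # unknown residue is neutral
  new("HomeodomainProfile", scores = scores, background = background,
      pseudocount = pseudocount)
}

#' Default homeodomain profile
#'
#' Profile built from the packaged synthetic family-exemplar alignment
#' ([defaultFamilyExemplars()]).
#'
#' @return a [HomeodomainProfile-class]
#' @export
defaultProfile <- function() {
  buildProfile(defaultFamilyExemplars()$sequence)
}

# offset layouts of the scan variants: protein offsets (0-based, relative
# to window start) of the 60 canonical columns, skipping neutral insertion
# columns. TALE: 3 residues between helices 1 and 2 (after canonical 23);
# HNF: 4 residues between helices 2 and 3 (after canonical 39).
.scanVariants <- function() {
  list(none = list(offs = 0:59, width = 60L),
       tale_3aa = list(offs = c(0:22, 26:62), width = 63L),
       hnf_helix23 = list(offs = c(0:38, 43:63), width = 64L))
}

.emptyHits <- function() {
  data.frame(protein_id = character(0), start = integer(0), end = integer(0),
             score = numeric(0), method = character(0),
             insertion = character(0), stringsAsFactors = FALSE)
}

# greedy non-overlap selection: best score first, ties by earlier start,
# then by preference order of the `pref` column values
.selectNonOverlapping <- function(cand, prefLevels) {
  ord <- order(-cand$score, cand$start, match(cand$pref, prefLevels))
  cand <- cand[ord, , drop = FALSE]
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    ok <- TRUE
    if (any(keep)) {
      k <- cand[keep, , drop = FALSE]
      ok <- all(cand$start[i] > k$end | cand$end[i] < k$start)
    }
    keep[i] <- ok
  }
  cand[keep, , drop = FALSE]
}

#' Scan proteins with a homeodomain profile
#'
#' Slides the 60-column profile, a 63-column TALE variant (three neutral
#' insertion columns after canonical position 23) and a 64-column HNF
#' variant (four neutral columns between helices 2 and 3) over every
#' window of each protein, and reports non-overlapping hits scoring at
#' least `threshold` bits, best-scoring first within each protein. The
#' `insertion` field records which variant won.
#'
#' @param proteins `AAStringSet` (named) or single character sequence
#' @param profile a [HomeodomainProfile-class] with 60 columns
#' @param threshold minimum score in bits (default 15)
#' @return hit data.frame with columns `protein_id`, `start`, `end`
#'   (1-based closed), `score`, `method`, `insertion`, and a `column_map`
#'   list column giving the protein position of each canonical column
#' @export
profileScan <- function(proteins, profile, threshold = 15) {
  stopifnot(is(profile, "HomeodomainProfile"), is.finite(threshold))
  if (is.character(proteins)) proteins <- Biostrings::AAStringSet(proteins)
  if (is.null(names(proteins)))
    names(proteins) <- paste0("seq", seq_along(proteins))
  M <- profile@scores
  variants <- .scanVariants()
  res <- list(); maps <- list()
  for (p in seq_along(proteins)) {
    seq <- as.character(proteins[[p]])
    n <- nchar(seq)
    idx <- match(strsplit(seq, "")[[1]], rownames(M))
    cand <- NULL
    for (v in names(variants)) {
      W <- variants[[v]]$width; offs <- variants[[v]]$offs
      if (n < W) next
      starts <- seq_len(n - W + 1L)
      sc <- numeric(length(starts))
      for (j in seq_len(60)) sc <- sc + M[idx[starts + offs[j]], j]
      hit <- which(sc >= threshold)
      if (length(hit))
        cand <- rbind(cand, data.frame(start = starts[hit],
                                       end = starts[hit] + W - 1L,
                                       score = sc[hit], pref = v,
                                       stringsAsFactors = FALSE))
    }
    if (is.null(cand)) next
    sel <- .selectNonOverlapping(cand, names(variants))
    for (i in seq_len(nrow(sel))) {
      v <- sel$pref[i]
      cmap <- sel$start[i] + variants[[v]]$offs
      res[[length(res) + 1L]] <- data.frame(
        protein_id = names(proteins)[p], start = sel$start[i],
        end = sel$end[i], score = sel$score[i], method = "profile",
        insertion = v, stringsAsFactors = FALSE)
      maps[[length(maps) + 1L]] <- cmap
    }
  }
  if (!length(res)) {
    out <- .emptyHits(); out$column_map <- list(); return(out)
  }
  out <- do.call(rbind, res)
  out$column_map <- maps
  out <- out[order(out$protein_id, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# map canonical query columns to protein positions from one local alignment
.alignmentColumnMap <- function(aln, queryLen) {
  pat <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  qpos <- Biostrings::start(Biostrings::subject(aln)) - 1L
  ppos <- Biostrings::start(Biostrings::pattern(aln)) - 1L
  map <- rep(NA_integer_, queryLen)
  for (k in seq_along(pat)) {
    if (pat[k] != "-") ppos <- ppos + 1L
    if (sub[k] != "-") {
      qpos <- qpos + 1L
      if (pat[k] != "-") map[qpos] <- ppos
    }
  }
  map
}

# classify an insertion from gaps in the canonical column map
.insertionFromMap <- function(map) {
  gap <- function(a, b) if (!is.na(map[a]) && !is.na(map[b]))
    map[b] - map[a] - 1L else 0L
  if (gap(23, 24) == 3L) "tale_3aa"
  else if (gap(39, 40) >= 3L) "hnf_helix23"
  else "none"
}

#' Scan proteins by local alignment against homeodomain queries
#'
#' Smith–Waterman local alignment (via [Biostrings::pairwiseAlignment()])
#' of each protein against a set of 60-residue homeodomain queries. A hit
#' is kept when its score reaches `scoreFrac` of the query's self-score
#' (or a fixed `threshold` if supplied); overlapping hits on a protein are
#' reduced to non-overlapping intervals keeping the best score.
#'
#' @param proteins `AAStringSet` of proteins (named)
#' @param queries named `AAStringSet`/character of 60-residue homeodomains
#' @param substitutionMatrix substitution matrix name or matrix
#'   (default BLOSUM62)
#' @param gapOpening,gapExtension gap penalties (positive costs)
#' @param scoreFrac fraction of the query self-score used as the per-query
#'   acceptance threshold (default 0.6)
#' @param threshold optional fixed score threshold overriding `scoreFrac`
#' @return hit data.frame in the same shape as [profileScan()], with
#'   `method = "similarity"` and a `query` column
#' @export
similarityScan <- function(proteins, queries,
                           substitutionMatrix = "BLOSUM62",
                           gapOpening = 10, gapExtension = 4,
                           scoreFrac = 0.6, threshold = NULL) {
  if (is.character(proteins)) proteins <- Biostrings::AAStringSet(proteins)
  if (is.character(queries)) queries <- Biostrings::AAStringSet(queries)
  mcols(proteins) <- NULL  # pairwiseAlignment drops them with a warning
  mcols(queries) <- NULL
  stopifnot(length(queries) >= 1)
  if (is.null(names(proteins)))
    names(proteins) <- paste0("seq", seq_along(proteins))
  if (is.null(names(queries)))
    names(queries) <- paste0("query", seq_along(queries))
  if (is.character(substitutionMatrix)) {
    mat <- get(data(list = substitutionMatrix,
                    package = "Biostrings", envir = environment()))
  } else mat <- substitutionMatrix
  rows <- list(); maps <- list()
  for (q in seq_along(queries)) {
    qseq <- strsplit(as.character(queries[[q]]), "")[[1]]
    qlen <- length(qseq)
    self <- sum(mat[cbind(qseq, qseq)])
    thr <- if (is.null(threshold)) scoreFrac * self else threshold
    aln <- Biostrings::pairwiseAlignment(
      pattern = proteins, subject = queries[[q]], type = "local",
      substitutionMatrix = mat, gapOpening = gapOpening,
      gapExtension = gapExtension)
    sc <- Biostrings::score(aln)
    for (p in which(sc >= thr)) {
      a <- aln[p]
      map <- .alignmentColumnMap(a, qlen)
      rows[[length(rows) + 1L]] <- data.frame(
        protein_id = names(proteins)[p],
        start = Biostrings::start(Biostrings::pattern(a)),
        end = Biostrings::end(Biostrings::pattern(a)),
        score = sc[p], method = "similarity",
        insertion = .insertionFromMap(map),
        query = names(queries)[q], stringsAsFactors = FALSE)
      maps[[length(maps) + 1L]] <- map
    }
  }
  if (!length(rows)) {
    out <- .emptyHits(); out$query <- character(0)
    out$column_map <- list(); return(out)
  }
  out <- do.call(rbind, rows)
  out$column_map <- maps
  # reduce to non-overlapping intervals per protein, best score first
  keep <- logical(nrow(out))
  for (pid in unique(out$protein_id)) {
    i <- which(out$protein_id == pid)
    ord <- i[order(-out$score[i], out$start[i], out$query[i])]
    sel <- integer(0)
    for (j in ord) {
      if (!length(sel) ||
          all(out$start[j] > out$end[sel] | out$end[j] < out$start[sel]))
        sel <- c(sel, j)
    }
    keep[sel] <- TRUE
  }
  out <- out[keep, , drop = FALSE]
  out <- out[order(out$protein_id, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge hit lists from the two detectors
#'
#' Union of two hit lists; two hits on the same protein whose intervals
#' overlap by more than `overlapFrac` of the shorter interval are collapsed
#' into one record keeping the higher-scoring hit's coordinates and score
#' and recording both methods. Equal-score ties prefer the earlier start,
#' then the profile method.
#'
#' @param a,b hit data.frames from [profileScan()] / [similarityScan()]
#' @param overlapFrac overlap fraction of the shorter interval above which
#'   two hits are considered redundant (default 0.5)
#' @return merged hit data.frame sorted by (`protein_id`, `start`)
#' @export
mergeHits <- function(a, b, overlapFrac = 0.5) {
  cols <- c("protein_id", "start", "end", "score", "method", "insertion")
  norm <- function(x) {
    x <- x[, c(cols, "column_map"), drop = FALSE]
    x
  }
  all <- rbind(norm(a), norm(b))
  if (nrow(all) == 0) { all$methods <- character(0); return(all) }
  out <- NULL
  for (pid in unique(all$protein_id)) {
    h <- all[all$protein_id == pid, , drop = FALSE]
    ord <- order(-h$score, h$start, match(h$method, c("profile", "similarity")))
    h <- h[ord, , drop = FALSE]
    kept <- h[0, , drop = FALSE]
    methods <- list()
    for (i in seq_len(nrow(h))) {
      ov <- FALSE
      if (nrow(kept)) {
        inter <- pmax(0, pmin(h$end[i], kept$end) -
                         pmax(h$start[i], kept$start) + 1)
        shorter <- pmin(h$end[i] - h$start[i] + 1,
                        kept$end - kept$start + 1)
        j <- which(inter / shorter > overlapFrac)
        if (length(j)) {
          j <- j[1]
          methods[[j]] <- union(methods[[j]],
                                strsplit(h$method[i], ",")[[1]])
          ov <- TRUE
        }
      }
      if (!ov) {
        kept <- rbind(kept, h[i, , drop = FALSE])
        methods[[nrow(kept)]] <- strsplit(h$method[i], ",")[[1]]
      }
    }
    kept$method <- vapply(methods, function(m)
      paste(sort(unique(m)), collapse = ","), "")
    out <- rbind(out, kept)
  }
  out <- out[order(out$protein_id, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write hits to TSV
#'
#' @param hits hit data.frame
#' @param path output path
#' @return `path`, invisibly
#' @export
writeHits <- function(hits, path) {
  df <- hits[, c("protein_id", "start", "end", "score", "method",
                 "insertion")]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
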