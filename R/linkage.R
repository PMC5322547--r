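#' Detect linked homeobox gene clusters on scaffolds
#'
#' Two homeobox genes on the same scaffold belong to the same cluster when
#' at most `window` non-homeobox gene models lie strictly between them in
#' gene-model order (rank), extended transitively. Singleton homeobox
#' genes are reported as size-1 clusters. Scaffold ends truncate the
#' window naturally.
#'
#' @param map gene-model `GRanges` from [geneModels()] /
#'   [readGeneModels()] with `gene_id`, `is_homeobox`, `rank` columns
#' @param window maximum number of intervening non-homeobox gene models
#'   (default 5, the five-gene-model rule)
#' @return data.frame with one row per cluster: `cluster_id`, `scaffold`,
#'   `n`, `span_start`, `span_end` and a `members` list column of gene ids
#'   in rank order
#' @export
findLinkedClusters <- function(map, window = 5) {
  stopifnot(window >= 1)
  mc <- mcols(map)
  if (is.null(mc$gene_id) || is.null(mc$is_homeobox))
    stop("map must carry gene_id and is_homeobox columns")
  out <- NULL
  members <- list()
  cid <- 0L
  for (sc in unique(as.character(seqnames(map)))) {
    i <- which(as.character(seqnames(map)) == sc)
    i <- i[order(mcols(map)$rank[i])]
    hb <- i[mcols(map)$is_homeobox[i]]
    if (!length(hb)) next
    ranks <- mcols(map)$rank[hb]
    # new cluster whenever more than `window` models intervene
    brk <- c(TRUE, diff(ranks) - 1 > window)
    grp <- cumsum(brk)
    for (g in unique(grp)) {
      j <- hb[grp == g]
      cid <- cid + 1L
      out <- rbind(out, data.frame(
        cluster_id = cid, scaffold = sc, n = length(j),
        span_start = min(GenomicRanges::start(map)[j]),
        span_end = max(GenomicRanges::end(map)[j]),
        stringsAsFactors = FALSE))
      members[[cid]] <- mcols(map)$gene_id[j]
    }
  }
  if (is.null(out))
    out <- data.frame(cluster_id = integer(0), scaffold = character(0),
                      n = integer(0), span_start = integer(0),
                      span_end = integer(0))
  out$members <- members[seq_len(nrow(out))]
  out[order(out$scaffold, out$span_start), , drop = FALSE]
}

#' Summarize clustering extent
#'
#' @param clusters cluster data.frame from [findLinkedClusters()]
#' @return list with `size_histogram` (named counts of clusters by size),
#'   `n_genes`, `n_clustered` and `fraction_clustered` (fraction of
#'   homeobox genes in clusters of two or more)
#' @export
clusteringSummary <- function(clusters) {
  sizes <- clusters$n
  nGenes <- sum(sizes)
  nClustered <- sum(sizes[sizes >= 2])
  list(size_histogram = table(sizes),
       n_genes = nGenes,
       n_clustered = nClustered,
       fraction_clustered = if (nGenes == 0) 0 else nClustered / nGenes)
}
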