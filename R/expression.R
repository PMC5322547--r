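#' Normalize expression per gene by its peak
#'
#' Divides every gene's row by its row maximum so that the peak stage
#' equals 1. All-zero rows are left unchanged and flagged in the
#' `"zero_rows"` attribute. Idempotent.
#'
#' @param m genes-by-stages matrix of nonnegative values
#' @return normalized matrix with attribute `"zero_rows"` (gene names)
#' @export
normalizePerGene <- function(m) {
  if (any(m < 0)) stop("expression values must be nonnegative")
  mx <- apply(m, 1, max)
  zero <- mx == 0
  out <- m
  out[!zero, ] <- m[!zero, , drop = FALSE] / mx[!zero]
  attr(out, "zero_rows") <- rownames(m)[zero]
  out
}

#' Temporal category of a stage index
#'
#' Stages before the trochophore block are `"early"`, stages inside it
#' `"trochophore"`, stages after it `"late"`.
#'
#' @param stageIndex integer index into the stage series
#' @param stages a `stage_map` from [stageMap()]
#' @return one of `"early"`, `"trochophore"`, `"late"`
#' @export
categorizeStage <- function(stageIndex, stages = defaultStages()) {
  stopifnot(inherits(stages, "stage_map"))
  if (any(stageIndex < 1 | stageIndex > length(stages$stages)))
    stop("stage index out of range")
  tr <- stages$trochophore
  ifelse(stageIndex < min(tr), "early",
         ifelse(stageIndex > max(tr), "late", "trochophore"))
}

#' Peak-stage assignment per gene
#'
#' The peak is the argmax across stages; ties are broken by the earliest
#' stage. All-zero genes get peak stage and category `"undetermined"`
#' (peak index `NA`) and are excluded from downstream tallies with a
#' warning.
#'
#' @param m genes-by-stages matrix
#' @param stages a `stage_map`
#' @param is_novel optional named (or parallel) logical novelty flags
#' @return data.frame with `gene`, `peak_stage`, `peak_index`, `category`,
#'   `is_novel`
#' @export
peakStage <- function(m, stages = defaultStages(), is_novel = NA) {
  stopifnot(ncol(m) == length(stages$stages))
  if (is.null(rownames(m))) rownames(m) <- paste0("g", seq_len(nrow(m)))
  if (length(is_novel) == 1) is_novel <- rep(is_novel, nrow(m))
  if (!is.null(names(is_novel))) is_novel <- is_novel[rownames(m)]
  peak <- apply(m, 1, which.max)  # which.max takes the earliest on ties
  zero <- apply(m, 1, max) == 0
  cat <- categorizeStage(peak, stages)
  stage <- stages$stages[peak]
  peak <- as.integer(peak)
  cat[zero] <- "undetermined"
  stage[zero] <- "undetermined"
  peak[zero] <- NA_integer_
  if (any(zero))
    warning(sum(zero), " all-zero gene(s) set to 'undetermined'")
  data.frame(gene = rownames(m), peak_stage = stage, peak_index = peak,
             category = cat, is_novel = unname(is_novel),
             stringsAsFactors = FALSE)
}

#' Heatmap row order by peak stage
#'
#' Genes sorted by peak index ascending, ties alphabetically. Optionally
#' renders the normalized matrix with `pheatmap` (cosmetic; requires the
#' suggested package).
#'
#' @param m genes-by-stages matrix
#' @param assignments data.frame from [peakStage()]
#' @param render draw a heatmap (default FALSE)
#' @return character vector of gene names in display order
#' @export
heatmapOrder <- function(m, assignments, render = FALSE) {
  ord <- assignments$gene[order(assignments$peak_index, assignments$gene)]
  if (render && requireNamespace("pheatmap", quietly = TRUE)) {
    pheatmap::pheatmap(normalizePerGene(m)[ord, , drop = FALSE],
                       cluster_rows = FALSE, cluster_cols = FALSE)
  }
  ord
}

#' Old-versus-novel peak-category contingency table
#'
#' Cross-tabulates peak categories (early / trochophore / late) against
#' gene age (old vs novel). `"undetermined"` genes are excluded; the count
#' of exclusions is reported as an attribute. A table whose genes all fall
#' in one category is passed through with a warning.
#'
#' @param assignments data.frame from [peakStage()] with `is_novel` set
#' @return 2x3 integer matrix (rows `old`, `novel`; columns `early`,
#'   `trochophore`, `late`) with attribute `"n_excluded"`
#' @export
buildContingency <- function(assignments) {
  if (nrow(assignments) == 0) stop("no assignments")
  if (any(is.na(assignments$is_novel)))
    stop("is_novel must be set for every gene")
  keep <- !is.na(assignments$category) &
    assignments$category != "undetermined"
  a <- assignments[keep, , drop = FALSE]
  tab <- matrix(0L, 2, 3,
                dimnames = list(c("old", "novel"),
                                c("early", "trochophore", "late")))
  for (cat in colnames(tab)) {
    tab["old", cat] <- sum(!a$is_novel & a$category == cat)
    tab["novel", cat] <- sum(a$is_novel & a$category == cat)
  }
  if (sum(colSums(tab) > 0) == 1)
    warning("all genes peak in a single temporal category")
  attr(tab, "n_excluded") <- sum(!keep)
  tab
}

#' Pearson chi-square test of independence
#'
#' Computes the Pearson statistic `sum((O - E)^2 / E)` with expected
#' counts from the row/column margins after dropping all-zero rows and
#' columns; the p-value is the upper tail of the chi-square distribution
#' with `(r-1)(c-1)` degrees of freedom. When any expected count is below
#' 5 a warning flag is set and a margin-preserving Monte-Carlo p-value
#' (`nPerm` simulated tables via [stats::r2dtable()]) is reported
#' alongside the asymptotic one.
#'
#' @param table matrix of nonnegative integer counts, at least 2x2 after
#'   dropping all-zero rows/columns
#' @param nPerm Monte-Carlo replicates used when small cells are present
#'   (default 10000); set to 0 to skip
#' @param seed seed for the Monte-Carlo draw (default 1)
#' @return object of class `contingency_result`: `table`, `expected`,
#'   `statistic`, `df`, `p.value`, `p.mc` (NA unless computed),
#'   `small_cell_warning`
#' @export
chiSquareTest <- function(table, nPerm = 10000, seed = 1) {
  tab <- as.matrix(table)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be nonnegative integers")
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2 || ncol(tab) < 2)
    stop("table must be at least 2x2 after dropping empty rows/columns")
  n <- sum(tab)
  E <- outer(rowSums(tab), colSums(tab)) / n
  X2 <- sum((tab - E)^2 / E)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  p <- pchisq(X2, df, lower.tail = FALSE)
  small <- any(E < 5)
  pmc <- NA_real_
  if (small && nPerm > 0) {
    set.seed(seed)
    sims <- r2dtable(nPerm, rowSums(tab), colSums(tab))
    x2s <- vapply(sims, function(s) sum((s - E)^2 / E), 0)
    pmc <- (1 + sum(x2s >= X2 - 1e-12)) / (nPerm + 1)
  }
  structure(list(table = tab, expected = E, statistic = X2, df = df,
                 p.value = p, p.mc = pmc, small_cell_warning = small),
            class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  cat("Pearson chi-square test of independence\n")
  print(x$table)
  cat(sprintf("X-squared = %.4f, df = %d, p-value = %.6g\n",
              x$statistic, x$df, x$p.value))
  if (x$small_cell_warning)
    cat(sprintf("warning: expected count < 5 in some cell; Monte-Carlo p = %.4g\n",
                x$p.mc))
  invisible(x)
}

#' Egg-timer (hourglass) expression analysis
#'
#' Full temporal analysis: per-gene normalization, peak assignment,
#' early/trochophore/late categorization and the old-versus-novel
#' chi-square comparison.
#'
#' @param m genes-by-stages expression matrix
#' @param is_novel named or parallel logical novelty flags
#' @param stages a `stage_map`
#' @param ... passed to [chiSquareTest()]
#' @return list with `assignments`, `contingency`, `test`
#' @export
hourglassAnalysis <- function(m, is_novel, stages = defaultStages(), ...) {
  norm <- normalizePerGene(m)
  assign <- peakStage(norm, stages, is_novel)
  tab <- buildContingency(assign)
  list(assignments = assign, contingency = tab,
       test = chiSquareTest(tab, ...))
}
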