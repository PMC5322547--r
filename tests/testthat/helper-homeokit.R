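# Shared helpers for the homeokit test suite.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# deterministic random amino-acid string
randomAA <- function(n, seed) {
  set.seed(seed)
  paste(sample(AA20, n, replace = TRUE), collapse = "")
}

# write FASTA lines verbatim and return the path
writeFastaLines <- function(lines) {
  path <- tempfile(fileext = ".fa")
  writeLines(lines, path)
  path
}

# consensus string of a HomeodomainProfile: per-column best residue
profileConsensus <- function(profile) {
  sc <- profile@scores[AA20, , drop = FALSE]
  paste(AA20[apply(sc, 2, which.max)], collapse = "")
}

# upper-tail chi-square probability by numerical integration: an oracle
# independent of pchisq() and chisq.test()
chisqUpperTail <- function(q, df) {
  stats::integrate(function(x) x^(df / 2 - 1) * exp(-x / 2),
                   q, Inf, rel.tol = 1e-12)$value /
    (2^(df / 2) * gamma(df / 2))
}

# does an unrooted phylo tree contain the bipartition splitting `tips`
# from the rest?
hasBipartition <- function(tree, tips) {
  labs <- tree$tip.label
  pp <- ape::prop.part(tree)
  for (part in pp) {
    set <- labs[part]
    if (setequal(set, tips) || setequal(set, setdiff(labs, tips)))
      return(TRUE)
  }
  FALSE
}

# cluster membership as a canonical partition (sorted list of sorted
# character vectors), for comparing clusterings irrespective of labels
canonicalPartition <- function(members) {
  parts <- lapply(unname(members), function(x) sort(as.character(x)))
  parts[order(vapply(parts, `[`, "", 1L))]
}

# partition of planted truth (gene_id grouped by cluster label)
truthPartition <- function(truth) {
  canonicalPartition(split(truth$gene_id, truth$cluster))
}
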