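test_that("buildProfile log-odds match a hand-computed three-sequence oracle", {
  p <- buildProfile(c("AA", "AC", "CC"))
  # column 1: A twice, C once, n = 3, pseudocount 1, background 1/20
  bg <- 1 / 20
  expect_equal(unname(p@scores["A", 1]), log2(((2 + bg) / 4) / bg))
  expect_equal(unname(p@scores["C", 1]), log2(((1 + bg) / 4) / bg))
  expect_equal(unname(p@scores["G", 1]), log2((bg / 4) / bg))  # unseen
  # column 2 mirrors column 1 with A and C swapped
  expect_equal(unname(p@scores["C", 2]), unname(p@scores["A", 1]))
  expect_equal(unname(p@scores["A", 2]), unname(p@scores["C", 1]))
  expect_identical(profileWidth(p), 2L)
})

test_that("with a vanishing pseudocount a unanimous column scores log2(20)", {
  p <- buildProfile(c("MK", "MK"), pseudocount = 1e-9)
  expect_equal(consensusScore(p), 2 * log2(20), tolerance = 1e-6)
})

test_that("buildProfile rejects ragged or empty alignments", {
  expect_error(buildProfile(c("AA", "ACD")))
  expect_error(buildProfile(character(0)))
})

test_that("profileScan finds a planted consensus at the exact offset", {
  prof <- defaultProfile()
  cons <- profileConsensus(prof)
  flank <- randomAA(37, 101)
  protein <- Biostrings::AAStringSet(c(
    planted = paste0(flank, cons, randomAA(55, 102))))
  hits <- profileScan(protein, prof)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$start, 38L)
  expect_identical(hits$end, 38L + 59L)
  expect_identical(hits$insertion, "none")
  expect_equal(hits$score, consensusScore(prof))
  # the stored column map sends canonical positions to protein positions
  expect_identical(hits$column_map[[1]], 38:97)
})

test_that("no window can out-score the profile consensus", {
  prof <- defaultProfile()
  set.seed(42)
  proteins <- Biostrings::AAStringSet(
    setNames(vapply(1:20, function(i)
      paste(sample(AA20, 150, replace = TRUE), collapse = ""), ""),
      paste0("r", 1:20)))
  hits <- profileScan(proteins, prof, threshold = -1e6)
  expect_true(all(hits$score <= consensusScore(prof) + 1e-9))
})

test_that("proteins shorter than the homeodomain yield no profile hits", {
  prof <- defaultProfile()
  protein <- Biostrings::AAStringSet(c(short = randomAA(59, 7)))
  expect_identical(nrow(profileScan(protein, prof)), 0L)
})

test_that("the TALE insertion variant is detected and mapped around", {
  prof <- defaultProfile()
  cons <- profileConsensus(prof)
  hd <- paste0(substr(cons, 1, 23), "WWW", substr(cons, 24, 60))
  protein <- Biostrings::AAStringSet(c(
    tale = paste0(randomAA(30, 201), hd, randomAA(30, 202))))
  hits <- profileScan(protein, prof)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$insertion, "tale_3aa")
  expect_identical(hits$end - hits$start + 1L, 63L)
  # canonical position 24 maps past the three inserted residues
  expect_identical(residueAt(hits[1, ], protein[[1]], 24),
                   substr(cons, 24, 24))
  expect_identical(residueAt(hits[1, ], protein[[1]], 23),
                   substr(cons, 23, 23))
})

test_that("the HNF insertion variant is detected between helices 2 and 3", {
  prof <- defaultProfile()
  cons <- profileConsensus(prof)
  hd <- paste0(substr(cons, 1, 39), "WWWW", substr(cons, 40, 60))
  protein <- Biostrings::AAStringSet(c(
    hnf = paste0(randomAA(25, 301), hd, randomAA(25, 302))))
  hits <- profileScan(protein, prof)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$insertion, "hnf_helix23")
  expect_identical(hits$end - hits$start + 1L, 64L)
  expect_identical(residueAt(hits[1, ], protein[[1]], 40),
                   substr(cons, 40, 40))
})

test_that("similarityScan recovers an exact substring at its self-score", {
  query <- Biostrings::AAStringSet(c(q1 = randomAA(60, 501)))
  protein <- Biostrings::AAStringSet(c(
    target = paste0(randomAA(40, 502), as.character(query[[1]]),
                    randomAA(40, 503))))
  hits <- similarityScan(protein, query)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$start, 41L)
  expect_identical(hits$end, 100L)
  data("BLOSUM62", package = "Biostrings", envir = environment())
  chars <- strsplit(as.character(query[[1]]), "")[[1]]
  selfScore <- sum(BLOSUM62[cbind(chars, chars)])
  expect_equal(hits$score, selfScore)
})

test_that("similarityScan ignores proteins below the score fraction", {
  query <- Biostrings::AAStringSet(c(q1 = randomAA(60, 601)))
  protein <- Biostrings::AAStringSet(c(noise = randomAA(200, 602)))
  expect_identical(nrow(similarityScan(protein, query)), 0L)
})

test_that("mergeHits collapses overlapping hits keeping the best score", {
  a <- data.frame(protein_id = "p", start = 10L, end = 69L, score = 30,
                  method = "profile", insertion = "none",
                  stringsAsFactors = FALSE)
  a$column_map <- list(10:69)
  b <- data.frame(protein_id = "p", start = 12L, end = 71L, score = 28,
                  method = "similarity", insertion = "none",
                  stringsAsFactors = FALSE)
  b$column_map <- list(12:71)
  m <- mergeHits(a, b)
  expect_identical(nrow(m), 1L)
  expect_equal(m$score, 30)
  expect_identical(m$start, 10L)
  expect_true(grepl("profile", m$method) && grepl("similarity", m$method))
  # merging is symmetric and idempotent
  m2 <- mergeHits(b, a)
  expect_identical(m2$start, m$start)
  expect_equal(m2$score, m$score)
  expect_identical(nrow(mergeHits(m, m[0, ])), 1L)
})

test_that("disjoint hits survive merging untouched", {
  a <- data.frame(protein_id = c("p", "p"), start = c(10L, 200L),
                  end = c(69L, 259L), score = c(20, 25),
                  method = "profile", insertion = "none",
                  stringsAsFactors = FALSE)
  a$column_map <- list(10:69, 200:259)
  b <- a[0, ]
  m <- mergeHits(a, b)
  expect_identical(nrow(m), 2L)
  expect_identical(m$start, c(10L, 200L))
})

test_that("merged hits never overlap more than the collapse fraction", {
  set.seed(9)
  mk <- function(n) {
    st <- sort(sample(1:400, n))
    df <- data.frame(protein_id = "p", start = st, end = st + 59L,
                     score = runif(n, 15, 40), method = "profile",
                     insertion = "none", stringsAsFactors = FALSE)
    df$column_map <- lapply(st, function(s) s:(s + 59L))
    df
  }
  m <- mergeHits(mk(8), mk(6))
  if (nrow(m) > 1) {
    for (i in seq_len(nrow(m) - 1)) {
      ov <- max(0, min(m$end[i], m$end[i + 1]) -
                  max(m$start[i], m$start[i + 1]) + 1)
      shorter <- min(m$end[i] - m$start[i], m$end[i + 1] - m$start[i + 1]) + 1
      expect_lte(ov / shorter, 0.5)
    }
  }
  # idempotence on the merged set
  expect_identical(nrow(mergeHits(m, m[0, ])), nrow(m))
})

test_that("hit TSV export keeps the interval and score columns", {
  prof <- defaultProfile()
  protein <- Biostrings::AAStringSet(c(
    planted = paste0(randomAA(20, 801), profileConsensus(prof),
                     randomAA(20, 802))))
  hits <- profileScan(protein, prof)
  path <- tempfile(fileext = ".tsv")
  writeHits(hits, path)
  df <- read.delim(path)
  expect_identical(df$protein_id, "planted")
  expect_identical(df$start, hits$start)
  expect_identical(df$end, hits$end)
})
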