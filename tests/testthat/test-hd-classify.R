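# helper: plant a homeodomain (optionally with extra N-terminal payload)
# and scan it, returning the hit plus the protein
plantAndScan <- function(hd, nflank = randomAA(30, 9001),
                         cflank = randomAA(30, 9002), tail = "") {
  protein <- Biostrings::AAStringSet(c(x = paste0(nflank, hd, cflank, tail)))
  hits <- profileScan(protein, defaultProfile())
  stopifnot(nrow(hits) == 1)
  list(hit = hits[1, ], protein = protein)
}

test_that("residueAt reads canonical positions through the column map", {
  ex <- defaultFamilyExemplars()
  seq60 <- ex$sequence[1]
  ps <- plantAndScan(seq60)
  expect_identical(residueAt(ps$hit, ps$protein[[1]], 1),
                   substr(seq60, 1, 1))
  expect_identical(residueAt(ps$hit, ps$protein[[1]], 50),
                   substr(seq60, 50, 50))
  expect_identical(residueAt(ps$hit, ps$protein[[1]], 60),
                   substr(seq60, 60, 60))
  expect_error(residueAt(ps$hit, ps$protein[[1]], 61))
})

test_that("a TALE insertion with a TALE residue 50 calls the TALE class", {
  ex <- defaultFamilyExemplars()
  seq60 <- ex$sequence[ex$class == "TALE"][1]
  hd <- paste0(substr(seq60, 1, 23), "WWW", substr(seq60, 24, 60))
  ps <- plantAndScan(hd)
  call <- applyClassRules(ps$hit, ps$protein[[1]])
  expect_identical(call$class, "TALE")
  expect_true(any(grepl("tale_3aa", call$evidence)))
})

test_that("a helix-2/3 insertion calls the HNF class", {
  ex <- defaultFamilyExemplars()
  seq60 <- ex$sequence[ex$class == "HNF"][1]
  hd <- paste0(substr(seq60, 1, 39), "WWWW", substr(seq60, 40, 60))
  ps <- plantAndScan(hd)
  call <- applyClassRules(ps$hit, ps$protein[[1]])
  expect_identical(call$class, "HNF")
})

test_that("companion motifs are found in the flanks, none in a bare domain", {
  ml <- defaultMotifLibrary()
  paired <- ml$sequence[ml$motif == "Paired"]
  ex <- defaultFamilyExemplars()
  seq60 <- ex$sequence[ex$family == "Arx"]
  ps <- plantAndScan(seq60, nflank = paste0(randomAA(10, 9101), paired,
                                            randomAA(10, 9102)))
  found <- detectCompanionMotifs(ps$protein[[1]], ps$hit)
  expect_true("Paired" %in% found$motif)
  expect_true(all(found$identity >= 0.8))
  bare <- plantAndScan(seq60)
  expect_identical(nrow(detectCompanionMotifs(bare$protein[[1]], bare$hit)),
                   0L)
})

test_that("a single companion motif drives the class call", {
  ml <- defaultMotifLibrary()
  ex <- defaultFamilyExemplars()
  for (cls in c("CUT", "PROS", "ZF", "LIM", "POU", "CERS")) {
    fams <- ex$family[ex$class == cls]
    motif <- ml$sequence[ml$asserts == cls][1]
    ps <- plantAndScan(ex$sequence[ex$family == fams[1]],
                       nflank = paste0(randomAA(15, 9200), motif,
                                       randomAA(15, 9201)))
    mh <- detectCompanionMotifs(ps$protein[[1]], ps$hit)
    call <- applyClassRules(ps$hit, ps$protein[[1]], motifHits = mh)
    expect_identical(call$class, cls)
  }
})

test_that("conflicting companion motifs demote the gene to Others", {
  ml <- defaultMotifLibrary()
  ex <- defaultFamilyExemplars()
  paired <- ml$sequence[ml$motif == "Paired"]
  lim <- ml$sequence[ml$motif == "LIM"]
  ps <- plantAndScan(ex$sequence[ex$family == "Arx"],
                     nflank = paste0(randomAA(5, 9301), paired,
                                     randomAA(5, 9302), lim,
                                     randomAA(5, 9303)))
  ann <- classifyHits(rbind(ps$hit), ps$protein)
  expect_identical(ann$class, "Others")
})

test_that("lysine at canonical 50 separates SINE from Paired-motif genes", {
  ex <- defaultFamilyExemplars()
  ml <- defaultMotifLibrary()
  sixFam <- ex$family[ex$class == "SINE"][1]
  expect_identical(substr(ex$sequence[ex$family == sixFam], 50, 50), "K")
  ps <- plantAndScan(ex$sequence[ex$family == sixFam])
  ann <- classifyHits(rbind(ps$hit), ps$protein)
  expect_identical(ann$class, "SINE")
  expect_identical(ann$family, sixFam)
  # Gsc also has K50 but carries a Paired domain: stays PRD
  paired <- ml$sequence[ml$motif == "Paired"]
  expect_identical(substr(ex$sequence[ex$family == "Gsc"], 50, 50), "K")
  ps2 <- plantAndScan(ex$sequence[ex$family == "Gsc"],
                      nflank = paste0(randomAA(12, 9401), paired,
                                      randomAA(12, 9402)))
  ann2 <- classifyHits(rbind(ps2$hit), ps2$protein)
  expect_identical(ann2$class, "PRD")
  expect_identical(ann2$family, "Gsc")
})

test_that("assignFamilyNearest scores identity over canonical columns", {
  ex <- defaultFamilyExemplars()
  fam <- ex$family[1]
  seq60 <- ex$sequence[1]
  ps <- plantAndScan(seq60)
  res <- assignFamilyNearest(ps$hit, ps$protein[[1]])
  expect_identical(res$family, fam)
  expect_equal(res$identity, 1)
  # two substitutions out of sixty -> 58/60
  chars <- strsplit(seq60, "")[[1]]
  alt <- setdiff(AA20, chars[c(5, 30)])
  chars[5] <- alt[1]; chars[30] <- alt[2]
  ps2 <- plantAndScan(paste(chars, collapse = ""))
  res2 <- assignFamilyNearest(ps2$hit, ps2$protein[[1]])
  expect_identical(res2$family, fam)
  expect_equal(res2$identity, 58 / 60)
})

test_that("sequences below the identity floor stay family-undetermined", {
  ex <- defaultFamilyExemplars()
  seq60 <- ex$sequence[1]
  # mutate 40 of 60 positions: identity to the source drops to 1/3
  set.seed(77)
  chars <- strsplit(seq60, "")[[1]]
  idx <- sample(60, 40)
  for (i in idx) chars[i] <- sample(setdiff(AA20, chars[i]), 1)
  diverged <- paste(chars, collapse = "")
  protein <- Biostrings::AAStringSet(c(x = paste0(randomAA(30, 9501),
                                                  diverged,
                                                  randomAA(30, 9502))))
  hit <- data.frame(protein_id = "x", start = 31L, end = 90L, score = 0,
                    method = "similarity", insertion = "none",
                    stringsAsFactors = FALSE)
  hit$column_map <- list(31:90)
  res <- assignFamilyNearest(hit[1, ], protein[[1]])
  expect_identical(res$family, "n.d.")
  expect_lt(res$identity, 0.55)
})

test_that("clade motifs are each detected on a planted carrier", {
  ex <- defaultFamilyExemplars()
  ml <- defaultMotifLibrary()
  padre <- ml$sequence[ml$motif == "PADRE"]
  cladeOf <- function(ps) detectCladeMotifs(ps$protein[[1]], ps$hit)$clade
  # terminal KEKR
  ps <- plantAndScan(ex$sequence[ex$family == "Msx"], tail = "KEKR")
  expect_true("ANTP_NKL Clade I" %in% cladeOf(ps))
  # SPQQVRS after the domain
  ps <- plantAndScan(ex$sequence[ex$family == "Otx"],
                     cflank = paste0("SPQQVRS", randomAA(20, 9601)))
  expect_true("PRD Clade VI" %in% cladeOf(ps))
  # QVKK after the domain
  ps <- plantAndScan(ex$sequence[ex$family == "Meis"],
                     cflank = paste0("QVKK", randomAA(20, 9602)))
  expect_true("TALE Clade VI" %in% cladeOf(ps))
  # PADRE upstream of the domain
  ps <- plantAndScan(ex$sequence[ex$family == "Pbx"],
                     nflank = paste0(randomAA(10, 9603), padre,
                                     randomAA(5, 9604)))
  expect_true("TALE Clade VI/VII" %in% cladeOf(ps))
  # cysteine at canonical 23
  en <- strsplit(ex$sequence[ex$family == "En"], "")[[1]]
  en[23] <- "C"
  ps <- plantAndScan(paste(en, collapse = ""))
  expect_true("ANTP_NKL engrailed" %in% cladeOf(ps))
  # histidine at canonical 10
  hmx <- strsplit(ex$sequence[ex$family == "Nk5/Hmx"], "")[[1]]
  hmx[10] <- "H"
  ps <- plantAndScan(paste(hmx, collapse = ""))
  expect_true("ANTP_NKL Hmx" %in% cladeOf(ps))
  # a plain exemplar carries none of them
  ps <- plantAndScan(ex$sequence[ex$family == "Cdx"])
  expect_length(cladeOf(ps), 0)
})

test_that("classification is deterministic", {
  s <- simSpec(seed = 19, genesPerFamily = 1, decoys = 10)
  pg <- genProteome(s)
  hits <- profileScan(pg$proteins, defaultProfile())
  a1 <- classifyHits(hits, pg$proteins)
  a2 <- classifyHits(hits, pg$proteins)
  expect_identical(a1, a2)
})

test_that("a noiseless planted proteome is classified without error", {
  s <- simSpec(seed = 23, genesPerFamily = 1, decoys = 30)
  pg <- genProteome(s)
  hits <- profileScan(pg$proteins, defaultProfile())
  ann <- classifyHits(hits, pg$proteins)
  ann <- callNovel(ann)
  truth <- pg$truth
  merged <- merge(ann, truth, by.x = "protein_id", by.y = "id")
  expect_identical(nrow(merged), nrow(truth))  # every planted gene scanned
  expect_true(all(merged$class.x == merged$class.y))
  expect_true(all(merged$is_novel.x == merged$is_novel.y))
})

test_that("annotations export to TSV with their class and family calls", {
  s <- simSpec(seed = 29, genesPerFamily = 1, decoys = 0, novelGenes =
                 data.frame(feature = "NKL_I", base_family = "Msx",
                            count = 1L))
  pg <- genProteome(s)
  hits <- profileScan(pg$proteins, defaultProfile())
  ann <- classifyHits(hits, pg$proteins)
  path <- tempfile(fileext = ".tsv")
  writeAnnotations(ann, path)
  df <- read.delim(path)
  expect_identical(sort(df$protein_id), sort(ann$protein_id))
  expect_true(all(c("class", "family", "clade") %in% names(df)))
})
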