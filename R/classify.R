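#' Packaged family-exemplar homeodomains
#'
#' A synthetic stand-in reference set: one 60-residue homeodomain exemplar
#' per gene family, spanning the eleven metazoan classes, carrying the
#' diagnostic features used by the classifier (position-50 residue by
#' class, no reserved residues at positions 10 and 23). Real exemplars from
#' curated alignments can be substituted via the `references` arguments.
#'
#' @return data.frame with columns `family`, `class`, `sequence`
#' @export
defaultFamilyExemplars <- function() {
  p <- system.file("extdata", "family_exemplars_synthetic.tsv",
                   package = "homeokit")
  read.delim(p, stringsAsFactors = FALSE)
}

#' Packaged companion-motif library
#'
#' Synthetic stand-in consensus sequences for the companion domains that
#' diagnose homeobox classes outside the homeodomain (Paired, LIM,
#' POU-specific, SIX, CUT, PROS, zinc-finger, CERS) plus the ~87-residue
#' PADRE region N-terminal to the homeodomain of molluscan TALE clades
#' VI/VII. Each motif carries the class or clade it asserts and a minimum
#' identity threshold. The library is an editable TSV; user-supplied
#' profiles can replace it.
#'
#' @return data.frame with columns `motif`, `asserts`, `kind`,
#'   `min_identity`, `sequence`
#' @export
defaultMotifLibrary <- function() {
  p <- system.file("extdata", "motif_library_synthetic.tsv",
                   package = "homeokit")
  read.delim(p, stringsAsFactors = FALSE)
}

#' Residue at a canonical homeodomain column
#'
#' @param hit a single hit (one row of a hit data.frame, or a list with a
#'   `column_map` entry)
#' @param protein the protein sequence (character or `AAStringSet` element)
#' @param canonicalPos canonical column, 1–60
#' @return single residue character, or `"-"` for a gapped column
#' @export
residueAt <- function(hit, protein, canonicalPos) {
  if (canonicalPos < 1 || canonicalPos > 60)
    stop("canonical position must be in 1..60")
  map <- if (is.data.frame(hit)) hit$column_map[[1]] else hit$column_map
  pos <- map[canonicalPos]
  if (is.na(pos)) return("-")
  substr(as.character(protein), pos, pos)
}

# best-identity windows of `motif` within regions of `pchars`
# (list of c(from, to)); returns NULL or c(start, end, identity)
.bestMotifWindow <- function(pchars, motif, regions) {
  mchars <- strsplit(motif, "")[[1]]
  L <- length(mchars)
  best <- NULL
  for (r in regions) {
    from <- r[1]; to <- r[2]
    if (is.na(from) || to - from + 1 < L) next
    starts <- from:(to - L + 1)
    idx <- outer(starts - 1L, seq_len(L), "+")
    eq <- matrix(pchars[idx], nrow = length(starts)) ==
      matrix(mchars, nrow = length(starts), ncol = L, byrow = TRUE)
    ident <- rowMeans(eq)
    k <- which.max(ident)
    if (is.null(best) || ident[k] > best[3])
      best <- c(starts[k], starts[k] + L - 1L, ident[k])
  }
  best
}

#' Detect companion-domain motifs outside the homeodomain
#'
#' Scans the protein regions flanking the hit interval for each motif in
#' the library and reports motifs whose best window reaches the motif's
#' identity threshold.
#'
#' @param protein protein sequence (character)
#' @param hit single hit row (for the interval to exclude)
#' @param motifLibrary motif table as in [defaultMotifLibrary()]
#' @return data.frame with columns `motif`, `asserts`, `kind`, `start`,
#'   `end`, `identity` (zero rows when nothing is found)
#' @export
detectCompanionMotifs <- function(protein, hit,
                                  motifLibrary = defaultMotifLibrary()) {
  seq <- as.character(protein)
  pchars <- strsplit(seq, "")[[1]]
  n <- length(pchars)
  s <- if (is.data.frame(hit)) hit$start[1] else hit$start
  e <- if (is.data.frame(hit)) hit$end[1] else hit$end
  regions <- list(c(1L, s - 1L), c(e + 1L, n))
  out <- NULL
  for (i in seq_len(nrow(motifLibrary))) {
    b <- .bestMotifWindow(pchars, motifLibrary$sequence[i], regions)
    if (!is.null(b) && b[3] >= motifLibrary$min_identity[i])
      out <- rbind(out, data.frame(motif = motifLibrary$motif[i],
                                   asserts = motifLibrary$asserts[i],
                                   kind = motifLibrary$kind[i],
                                   start = b[1], end = b[2],
                                   identity = b[3],
                                   stringsAsFactors = FALSE))
  }
  if (is.null(out))
    out <- data.frame(motif = character(0), asserts = character(0),
                      kind = character(0), start = integer(0),
                      end = integer(0), identity = numeric(0))
  out
}

#' Detect clade-diagnostic motifs
#'
#' Checks the short conserved signatures of the lophotrochozoan-specific
#' clades: a C-terminal KEKR (ANTP NKL Clade I), an SPQQVRS substring
#' (PRD Clade VI), a QVKK substring (TALE Clade VI), a cysteine at
#' canonical position 23 (lophotrochozoan engrailed paralogs), a histidine
#' at position 10 (mollusk-specific Hmx duplicates), and a PADRE-profile
#' match in the region N-terminal to the homeodomain (TALE Clades VI/VII).
#'
#' @param protein protein sequence (character)
#' @param hit single hit row with a `column_map`
#' @param motifLibrary motif table providing the PADRE profile
#' @return data.frame with columns `clade`, `evidence`
#' @export
detectCladeMotifs <- function(protein, hit,
                              motifLibrary = defaultMotifLibrary()) {
  seq <- as.character(protein)
  out <- NULL
  add <- function(clade, evidence)
    rbind(out, data.frame(clade = clade, evidence = evidence,
                          stringsAsFactors = FALSE))
  if (endsWith(seq, "KEKR"))
    out <- add("ANTP_NKL Clade I", "terminal KEKR")
  if (grepl("SPQQVRS", seq, fixed = TRUE))
    out <- add("PRD Clade VI", "SPQQVRS substring")
  if (grepl("QVKK", seq, fixed = TRUE))
    out <- add("TALE Clade VI", "QVKK substring")
  if (residueAt(hit, seq, 23) == "C")
    out <- add("ANTP_NKL engrailed", "C at canonical 23")
  if (residueAt(hit, seq, 10) == "H")
    out <- add("ANTP_NKL Hmx", "H at canonical 10")
  padre <- motifLibrary[motifLibrary$motif == "PADRE", , drop = FALSE]
  if (nrow(padre)) {
    s <- if (is.data.frame(hit)) hit$start[1] else hit$start
    pchars <- strsplit(seq, "")[[1]]
    L <- nchar(padre$sequence[1])
    region <- list(c(max(1L, s - L - 40L), s - 1L))
    b <- .bestMotifWindow(pchars, padre$sequence[1], region)
    if (!is.null(b) && b[3] >= padre$min_identity[1])
      out <- add("TALE Clade VI/VII",
                 sprintf("PADRE match at %d-%d (%.2f)", b[1], b[2], b[3]))
  }
  if (is.null(out))
    out <- data.frame(clade = character(0), evidence = character(0))
  out
}

#' Default class-assignment rules
#'
#' Ordered diagnostic rules: the TALE three-residue loop extension together
#' with I/A/G at position 50; the HNF helix-2/3 insertion; companion
#' domains asserting their classes; K at position 50 (SINE, or Gsc/Mix of
#' PRD, resolved by family assignment); H at position 50 (Cux). Unmatched
#' hits fall through to nearest-family resolution.
#'
#' @return list of rules (name, priority, predicates, asserts)
#' @export
defaultClassRules <- function() {
  rule <- function(name, priority, predicates, asserts)
    list(name = name, priority = priority, predicates = predicates,
         asserts = asserts)
  companions <- c(Paired = "PRD", LIM = "LIM", POU_specific = "POU",
                  SIX = "SINE", CUT = "CUT", PROS = "PROS", ZF = "ZF",
                  CERS = "CERS")
  rules <- list(
    rule("tale_insertion_res50", 1,
         list(list(kind = "insertion", descriptor = "tale_3aa"),
              list(kind = "residue_at", pos = 50,
                   residues = c("I", "A", "G"))),
         list(class = "TALE")),
    rule("hnf_helix23_insertion", 2,
         list(list(kind = "insertion", descriptor = "hnf_helix23")),
         list(class = "HNF")))
  pr <- 3
  for (m in names(companions)) {
    rules[[length(rules) + 1L]] <-
      rule(paste0("companion_", m), pr,
           list(list(kind = "companion_motif", motif = m)),
           list(class = unname(companions[m])))
    pr <- pr + 1
  }
  rules[[length(rules) + 1L]] <-
    rule("residue50_K", pr,
         list(list(kind = "residue_at", pos = 50, residues = "K")),
         list(class = "SINE", candidate = TRUE))
  rules[[length(rules) + 1L]] <-
    rule("residue50_H", pr + 1,
         list(list(kind = "residue_at", pos = 50, residues = "H")),
         list(class = "CUT", candidate = TRUE))
  rules
}

#' Apply class rules to one hit
#'
#' Evaluates the rules in priority order and returns the first match,
#' logging every fired predicate. Two companion motifs asserting different
#' classes are contradictory: the call becomes `"Others"` with conflict
#' evidence.
#'
#' @param hit single hit row
#' @param protein protein sequence
#' @param rules rule list from [defaultClassRules()]
#' @param motifHits companion-motif detections for this hit
#'   ([detectCompanionMotifs()])
#' @return list with `class` (or NA when no rule fires), `rule`,
#'   `candidate`, `evidence` (character vector)
#' @export
applyClassRules <- function(hit, protein, rules = defaultClassRules(),
                            motifHits = NULL) {
  if (is.null(motifHits)) motifHits <- detectCompanionMotifs(protein, hit)
  classMotifs <- motifHits[motifHits$kind == "class", , drop = FALSE]
  if (length(unique(classMotifs$asserts)) > 1) {
    return(list(class = "Others", rule = "conflict", candidate = FALSE,
                evidence = paste0("conflict:",
                  paste(sort(unique(classMotifs$asserts)), collapse = "/"))))
  }
  ins <- if (is.data.frame(hit)) hit$insertion[1] else hit$insertion
  rules <- rules[order(vapply(rules, `[[`, 0, "priority"))]
  for (r in rules) {
    ev <- character(0)
    ok <- TRUE
    for (p in r$predicates) {
      if (p$kind == "insertion") {
        if (identical(ins, p$descriptor))
          ev <- c(ev, paste0("insertion:", ins))
        else { ok <- FALSE; break }
      } else if (p$kind == "residue_at") {
        res <- residueAt(hit, protein, p$pos)
        if (res %in% p$residues)
          ev <- c(ev, paste0("residue", p$pos, ":", res))
        else { ok <- FALSE; break }
      } else if (p$kind == "companion_motif") {
        m <- classMotifs[classMotifs$motif == p$motif, , drop = FALSE]
        if (nrow(m))
          ev <- c(ev, sprintf("motif:%s@%d-%d(%.2f)", m$motif[1],
                              m$start[1], m$end[1], m$identity[1]))
        else { ok <- FALSE; break }
      } else stop("unknown predicate kind: ", p$kind)
    }
    if (ok)
      return(list(class = r$asserts$class, rule = r$name,
                  candidate = isTRUE(r$asserts$candidate), evidence = ev))
  }
  list(class = NA_character_, rule = NA_character_, candidate = FALSE,
       evidence = character(0))
}

#' Nearest-family assignment by homeodomain identity
#'
#' Percent identity over the canonical columns against every reference
#' exemplar; returns the best-matching family, or `"n.d."` when the best
#' identity falls below `floor`. Ties are broken alphabetically with a
#' warning.
#'
#' @param hit single hit row with `column_map`
#' @param protein protein sequence
#' @param references exemplar table ([defaultFamilyExemplars()] shape)
#' @param floor identity floor below which the family is undetermined
#' @return list with `family`, `identity`, `class` (reference class of the
#'   assigned family, NA for `"n.d."`)
#' @export
assignFamilyNearest <- function(hit, protein,
                                references = defaultFamilyExemplars(),
                                floor = 0.55) {
  stopifnot(nrow(references) >= 1)
  map <- if (is.data.frame(hit)) hit$column_map[[1]] else hit$column_map
  pchars <- strsplit(as.character(protein), "")[[1]]
  res <- ifelse(is.na(map), "-", pchars[ifelse(is.na(map), 1L, map)])
  ident <- vapply(references$sequence, function(ref) {
    rchars <- strsplit(ref, "")[[1]]
    comparable <- res != "-"
    if (!any(comparable)) return(0)
    mean(res[comparable] == rchars[comparable])
  }, 0)
  best <- max(ident)
  if (best < floor)
    return(list(family = "n.d.", identity = best, class = NA_character_))
  top <- which(ident == best)
  if (length(top) > 1) {
    top <- top[order(references$family[top])]
    warning("family tie at identity ", round(best, 3), ": ",
            paste(references$family[top], collapse = ", "),
            "; keeping ", references$family[top[1]])
  }
  k <- top[1]
  list(family = references$family[k], identity = unname(best),
       class = references$class[k])
}

#' Classify homeodomain hits into classes, families and clades
#'
#' Runs the full rule engine on every hit: companion-motif detection,
#' ordered class rules, nearest-family assignment (restricted to the
#' called class where one was determined; position-50 K candidates are
#' disambiguated between SINE and the K50 PRD families Gsc/Mix by family
#' identity), and clade-motif detection. Every fired rule is logged in the
#' `evidence` column.
#'
#' @param hits hit data.frame ([mergeHits()] output or either scanner's)
#' @param proteins named `AAStringSet` the hits refer to
#' @param references family exemplar table
#' @param motifLibrary companion/clade motif table
#' @param rules class rule list
#' @param identityFloor floor for family assignment (default 0.55)
#' @return annotation data.frame: `gene_name`, `protein_id`, `class`,
#'   `family`, `clade`, `identity`, `is_novel` (NA until [callNovel()]),
#'   `evidence`
#' @export
classifyHits <- function(hits, proteins,
                         references = defaultFamilyExemplars(),
                         motifLibrary = defaultMotifLibrary(),
                         rules = defaultClassRules(),
                         identityFloor = 0.55) {
  n <- nrow(hits)
  out <- data.frame(gene_name = character(n), protein_id = character(n),
                    class = character(n), family = character(n),
                    clade = NA_character_, identity = NA_real_,
                    is_novel = NA, evidence = character(n),
                    stringsAsFactors = FALSE)
  multi <- table(hits$protein_id)
  for (i in seq_len(n)) {
    pid <- hits$protein_id[i]
    protein <- as.character(proteins[[pid]])
    hit <- hits[i, , drop = FALSE]
    motifs <- detectCompanionMotifs(protein, hit, motifLibrary)
    call <- applyClassRules(hit, protein, rules, motifs)
    ev <- call$evidence
    refs <- references
    if (!is.na(call$class) && call$class != "Others") {
      if (call$rule == "residue50_K") {
        # SINE vs Gsc/Mix: both carry K50; family identity decides
        k50 <- vapply(references$sequence, function(s)
          substr(s, 50, 50) == "K", TRUE)
        refs <- references[k50, , drop = FALSE]
      } else if (any(references$class == call$class)) {
        refs <- references[references$class == call$class, , drop = FALSE]
      }
    }
    fam <- assignFamilyNearest(hit, protein, refs, identityFloor)
    cls <- call$class
    if (is.na(cls)) {
      cls <- if (!is.na(fam$class)) fam$class else "Others"
      if (!is.na(fam$class))
        ev <- c(ev, paste0("nearest_family_class:", fam$class))
    } else if (call$candidate && !is.na(fam$class) && fam$class != cls) {
      ev <- c(ev, paste0("candidate_reassigned:", cls, "->", fam$class))
      cls <- fam$class
    }
    ev <- c(ev, sprintf("family:%s(%.3f)", fam$family, fam$identity))
    clades <- detectCladeMotifs(protein, hit, motifLibrary)
    if (nrow(clades))
      ev <- c(ev, paste0("clade:", clades$evidence))
    out$gene_name[i] <- if (multi[pid] > 1)
      paste0(pid, ".", sum(hits$protein_id[seq_len(i)] == pid)) else pid
    out$protein_id[i] <- pid
    out$class[i] <- cls
    out$family[i] <- fam$family
    out$clade[i] <- if (nrow(clades))
      paste(unique(clades$clade), collapse = ";") else NA_character_
    out$identity[i] <- fam$identity
    out$evidence[i] <- paste(ev, collapse = "; ")
  }
  out
}

#' Write annotations to TSV
#'
#' @param annotations annotation data.frame from [classifyHits()]
#' @param path output path
#' @return `path`, invisibly
#' @export
writeAnnotations <- function(annotations, path) {
  write.table(annotations, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
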