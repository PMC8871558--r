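params <- detectionParams()

test_that("column profiles follow the conservation definition", {
  m <- matrix("A", nrow = 10, ncol = 2,
              dimnames = list(paste0("t", 1:10), NULL))
  m[8:10, 2] <- "S"
  prof <- profileColumns(proteinAlignment(m), params)
  expect_equal(prof$majorityFraction, c(1.0, 0.7))
  expect_equal(prof$conserved, c(TRUE, FALSE))   # 7/10 < 0.8
  expect_equal(prof$majorityResidue, c("A", "A"))
})

test_that("column profiles match a brute-force tally on random alignments", {
  set.seed(21)
  for (k in 1:50) {
    aln <- randomAlignment(nTaxa = sample(3:8, 1), nCols = sample(5:40, 1),
                           gapProb = 0.2)
    prof <- profileColumns(aln, params)
    oracle <- oracleProfiles(aln, params)
    expect_equal(prof$majorityFraction, oracle$majorityFraction)
    expect_equal(prof$gapFraction, oracle$gapFraction)
    expect_equal(prof$conserved, oracle$conserved)
  }
})

test_that("indel candidates are the maximal constant-gap-set runs", {
  ungapped <- randomAlignment(4, 30, gapProb = 0)
  expect_equal(nrow(findIndelCandidates(ungapped)), 0L)

  aln <- plantedAlignment(paste0("t", 1:4), c("t3", "t4"), 10:11, nCols = 30)
  cands <- findIndelCandidates(aln)
  expect_equal(nrow(cands), 1L)
  expect_equal(cands$start, 10L)
  expect_equal(cands$end, 11L)
  expect_equal(cands$length, 2L)
  expect_setequal(cands$gapTaxa[[1]], c("t3", "t4"))
  expect_setequal(cands$residueTaxa[[1]], c("t1", "t2"))
})

test_that("candidate enumeration equals exhaustive interval search", {
  set.seed(22)
  for (k in 1:50) {
    aln <- randomAlignment(nTaxa = sample(3:8, 1), nCols = sample(20:120, 1),
                           gapProb = 0.12)
    got <- findIndelCandidates(aln)
    want <- oracleCandidates(aln)
    expect_equal(nrow(got), length(want))
    for (i in seq_along(want)) {
      expect_equal(got$start[i], want[[i]]$start)
      expect_equal(got$end[i], want[[i]]$end)
      expect_setequal(got$gapTaxa[[i]], want[[i]]$gapTaxa)
    }
  }
})

test_that("flank assessment applies the conserved-window rule", {
  # 3 conserved columns left of the indel, plenty right: must fail (3 < 5)
  taxa <- paste0("t", 1:6)
  m <- matrix(sample(AA20, 6 * 60, replace = TRUE), nrow = 6,
              dimnames = list(taxa, NULL))
  base <- sample(AA20, 60, replace = TRUE)
  m[, 31:60] <- rep(base[31:60], each = 6)          # right flank conserved
  m[, c(5, 12, 18)] <- rep(base[c(5, 12, 18)], each = 6)  # 3 conserved left
  for (j in setdiff(1:19, c(5, 12, 18)))            # scramble the rest
    m[, j] <- sample(AA20, 6, replace = FALSE)
  m[c("t5", "t6"), 20:21] <- "-"
  aln <- proteinAlignment(m)
  prof <- profileColumns(aln, params)
  cand <- findIndelCandidates(aln)[1, ]
  fl <- assessFlanks(cand, prof, params)
  expect_equal(fl$left, 3L)
  expect_false(fl$pass)

  # fully conserved surround passes
  aln2 <- plantedAlignment(taxa, c("t5", "t6"), 20:21, nCols = 60)
  fl2 <- assessFlanks(findIndelCandidates(aln2)[1, ],
                      profileColumns(aln2, params), params)
  expect_true(fl2$pass)
})

test_that("flank counts equal brute-force window tallies", {
  set.seed(23)
  for (k in 1:50) {
    aln <- randomAlignment(nTaxa = sample(4:8, 1), nCols = sample(30:120, 1),
                           gapProb = 0.1)
    prof <- profileColumns(aln, params)
    cands <- findIndelCandidates(aln)
    if (!nrow(cands)) next
    i <- sample(nrow(cands), 1)
    got <- assessFlanks(cands[i, ], prof, params)
    want <- oracleFlanks(cands$start[i], cands$end[i], prof$conserved, params)
    expect_equal(got[c("left", "right", "pass")],
                 want[c("left", "right", "pass")])
  }
})

test_that("specificity assignment follows the clade rules", {
  sc <- gliresScenario()
  part <- sc$partition
  taxa <- alnTaxa(part)
  castor <- cladeMembers(part, "suborder", "Castorimorpha")

  cand <- data.frame(start = 10L, end = 10L, length = 1L)
  cand$gapTaxa <- I(list(castor))
  cand$residueTaxa <- I(list(setdiff(taxa, castor)))
  p2 <- detectionParams(minCarriers = 2)
  spec <- classifySpecificity(cand[1, ], part, p2, taxaPresent = taxa)
  expect_equal(spec$label, "Castorimorpha")
  expect_equal(spec$level, "suborder")
  expect_setequal(spec$carriers, castor)
  expect_length(spec$exceptions, 0L)

  # two taxa from different suborders: no clade passes
  pair <- c("Mus_musculus", "Cavia_porcellus")
  cand2 <- cand
  cand2$gapTaxa <- I(list(pair))
  cand2$residueTaxa <- I(list(setdiff(taxa, pair)))
  expect_null(classifySpecificity(cand2[1, ], part, p2, taxaPresent = taxa))
})

test_that("specificity matches exhaustive (clade, side) scoring", {
  sc <- gliresScenario()
  part <- sc$partition
  taxa <- alnTaxa(part)
  set.seed(24)
  p <- gliresDetectionParams()
  for (k in 1:60) {
    side <- sample(taxa, sample(2:20, 1))
    cand <- data.frame(start = 1L, end = 1L, length = 1L)
    cand$gapTaxa <- I(list(side))
    cand$residueTaxa <- I(list(setdiff(taxa, side)))
    got <- suppressMessages(
      classifySpecificity(cand[1, ], part, p, taxaPresent = taxa))
    want <- oracleSpecificity(side, setdiff(taxa, side), taxa, part, p)
    if (is.null(want)) expect_null(got)
    else expect_equal(paste(got$level, got$label), want)
  }
})

test_that("polarity is read off unanimous outgroup states and flips on swap", {
  sc <- gliresScenario()
  part <- sc$partition
  taxa <- alnTaxa(part)
  og <- outgroupTaxa(part)
  lago <- cladeMembers(part, "order", "Lagomorpha")

  mk <- function(gapTaxa) {
    cand <- data.frame(start = 1L, end = 1L, length = 1L)
    cand$gapTaxa <- I(list(gapTaxa))
    cand$residueTaxa <- I(list(setdiff(taxa, gapTaxa)))
    cand[1, ]
  }
  # everyone but the carriers gapped (outgroups gapped) -> insertion
  expect_equal(inferPolarity(mk(setdiff(taxa, lago)), part, lago, params),
               "insertion")
  # carriers gapped, outgroups with residues -> deletion
  expect_equal(inferPolarity(mk(lago), part, lago, params), "deletion")
  # no outgroup present -> undetermined with a warning
  cand <- data.frame(start = 1L, end = 1L, length = 1L)
  cand$gapTaxa <- I(list(lago))
  cand$residueTaxa <- I(list(setdiff(taxa, c(lago, og))))
  expect_warning(pol <- inferPolarity(cand[1, ], part, lago, params),
                 class = "csiNoOutgroupWarning")
  expect_equal(pol, "undetermined")
})

test_that("reference coordinates follow the displayed-region convention", {
  taxa <- paste0("t", 1:6)
  # indel = single column 11 (1-based), fully conserved elsewhere
  aln <- plantedAlignment(taxa, c("t5", "t6"), 11, nCols = 40)
  expect_equal(mapToReferenceCoords(aln, 11L, 11L, "t1", params), c(6L, 16L))

  # 3 extra gap columns in the reference upstream shift nothing
  m <- alnMatrix(aln)
  m2 <- cbind(matrix("-", 6, 3), m)
  m2[2:6, 1:3] <- matrix(rep(sample(AA20, 3), each = 5), nrow = 5)
  m2 <- `rownames<-`(m2, taxa)
  aln2 <- proteinAlignment(m2)
  expect_equal(mapToReferenceCoords(aln2, 14L, 14L, "t1", params), c(6L, 16L))

  # reference gapped across the whole region errors
  m3 <- alnMatrix(aln)
  m3["t6", ] <- m3["t1", ]
  m3["t1", ] <- "-"
  aln3 <- proteinAlignment(m3)
  expect_error(mapToReferenceCoords(aln3, 11L, 11L, "t1", params),
               class = "csiReferenceError")
})

test_that("coordinate mapping matches a gap-aware oracle on random cases", {
  set.seed(25)
  for (k in 1:50) {
    aln <- randomAlignment(nTaxa = 6, nCols = sample(40:120, 1),
                           gapProb = 0.08)
    cands <- findIndelCandidates(aln)
    if (!nrow(cands)) next
    i <- sample(nrow(cands), 1)
    ref <- sample(cands$residueTaxa[[i]], 1)
    got <- tryCatch(
      mapToReferenceCoords(aln, cands$start[i], cands$end[i], ref, params),
      error = function(e) NULL)
    want <- oracleRefCoords(aln, cands$start[i], cands$end[i], ref, params)
    if (is.null(got)) expect_true(any(is.na(want)))
    else expect_equal(got, unname(want))
  }
})

test_that("query regions are clipped ungapped slices of the reference", {
  taxa <- paste0("t", 1:4)
  aln <- plantedAlignment(taxa, c("t3", "t4"), 100:101, nCols = 250)
  refSeq <- paste(alnMatrix(aln)["t1", ], collapse = "")
  expect_equal(extractQueryRegion(aln, 100L, 101L, "t1", flankAa = 60),
               substr(refSeq, 40, 161))
  # near the start: clipped at residue 1
  aln2 <- plantedAlignment(taxa, c("t3", "t4"), 10, nCols = 250)
  ref2 <- paste(alnMatrix(aln2)["t1", ], collapse = "")
  expect_equal(suppressWarnings(
    extractQueryRegion(aln2, 10L, 10L, "t1", flankAa = 60)),
    substr(ref2, 1, 70))
})

test_that("detection recovers a planted insertion and rejects ragged decoys", {
  sc <- gliresScenario()
  p <- gliresDetectionParams()
  plan <- data.frame(level = "suborder", clade = "Hystricomorpha",
                     position = 150L, length = 1L, kind = "insertion")
  fam <- evolveFamily(sc, simulationParams(substitution = 0.01), plan,
                      seed = 99, id = "fam")
  calls <- detectCsis(fam$alignment, sc$partition, p)
  expect_length(calls, 1L)
  expect_equal(calls[[1]]@length, 1L)
  expect_equal(calls[[1]]@polarity, "insertion")
  expect_equal(calls[[1]]@cladeLabel, "Hystricomorpha")

  planR <- transform(plan, decoy = "ragged")
  famR <- evolveFamily(sc, simulationParams(substitution = 0.01), planR,
                       seed = 99, id = "famR")
  expect_length(detectCsis(famR$alignment, sc$partition, p), 0L)

  ungapped <- randomAlignment(4, 120, gapProb = 0)
  part4 <- cladePartition(
    levels = list(group = c(t1 = "A", t2 = "A", t3 = "B", t4 = "B")),
    candidateClades = data.frame(level = "group", label = c("A", "B")))
  expect_length(detectCsis(ungapped, part4), 0L)
})
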