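test_that("concatenation lays out blocks with gap fill and a partition map", {
  a1 <- proteinAlignment(c(t1 = "ACDEF", t2 = "ACDEF", t3 = "AC-EF"), "p1")
  a2 <- proteinAlignment(c(t1 = "GHIKLMN", t2 = "GHIKLMN"), "p2")
  sm <- concatenateAlignments(list(a1, a2), taxa = c("t1", "t2", "t3"))
  expect_equal(alnWidth(sm), 12L)
  expect_equal(sm@partitionMap$start, c(1L, 6L))
  expect_equal(sm@partitionMap$end, c(5L, 12L))
  expect_equal(unname(alnMatrix(sm)["t3", 6:12]), rep("-", 7))

  back <- splitSupermatrix(sm)
  expect_identical(alnMatrix(back$p1), alnMatrix(a1))
  expect_identical(alnMatrix(back$p2), alnMatrix(a2))

  expect_error(concatenateAlignments(list(a1, a1)), class = "csiInputError")
})

test_that("concatenate/split round-trips random alignment sets", {
  set.seed(41)
  for (k in 1:10) {
    alns <- lapply(1:4, function(i)
      randomAlignment(nTaxa = sample(3:6, 1), nCols = sample(10:40, 1),
                      gapProb = 0.05, id = paste0("prot", i)))
    taxa <- unique(unlist(lapply(alns, alnTaxa)))
    sm <- concatenateAlignments(alns, taxa)
    back <- splitSupermatrix(sm)
    for (a in alns)
      expect_identical(alnMatrix(back[[a@id]])[alnTaxa(a), ], alnMatrix(a))
  }
})

test_that("trimming removes long nonconserved runs and ragged block ends", {
  tp <- trimParams()
  taxa <- paste0("t", 1:10)
  # fully identical matrix: nothing trimmed
  m <- matrix(rep(sample(AA20, 40, replace = TRUE), each = 10), nrow = 10,
              dimnames = list(taxa, NULL))
  sm <- new("Supermatrix", taxa = taxa, seqs = m,
            partitionMap = data.frame(protein = "p", start = 1L, end = 40L))
  out <- trimBlocks(sm, tp)
  expect_equal(alnWidth(out$supermatrix), 40L)
  expect_equal(out$report, data.frame(start = 1L, end = 40L))

  # a 9-column run at majority fraction 0.4 exceeds the max run of 8
  m2 <- m
  for (j in 16:24) m2[, j] <- c(rep("A", 4), rep("C", 3), rep("D", 3))
  sm2 <- new("Supermatrix", taxa = taxa, seqs = m2,
             partitionMap = data.frame(protein = "p", start = 1L, end = 40L))
  out2 <- trimBlocks(sm2, tp)
  expect_equal(nrow(out2$report), 2L)
  expect_equal(out2$report$end[1], 15L)
  expect_equal(out2$report$start[2], 25L)
  expect_equal(alnWidth(out2$supermatrix), 31L)
})

test_that("trimming matches a rule-by-rule oracle on random matrices", {
  set.seed(42)
  tp <- trimParams()
  for (k in 1:50) {
    nt <- 6L
    m <- matrix(sample(c(AA20, "-"), nt * 200,
                       prob = c(rep(0.3, 4), rep(0.02, 16), 0.05),
                       replace = TRUE),
                nrow = nt, dimnames = list(paste0("t", 1:nt), NULL))
    sm <- new("Supermatrix", taxa = rownames(m), seqs = m,
              partitionMap = data.frame(protein = "p", start = 1L,
                                        end = 200L))
    out <- suppressWarnings(trimBlocks(sm, tp))
    kept <- unlist(mapply(seq.int, out$report$start, out$report$end,
                          SIMPLIFY = FALSE))
    if (is.null(kept)) kept <- integer()
    expect_equal(as.integer(kept), oracleTrimKeep(m, tp))
  }
})

test_that("trimming and coverage filtering are idempotent", {
  set.seed(43)
  m <- matrix(sample(c(AA20, "-"), 6 * 300, prob = c(rep(0.4, 3),
                                                     rep(0.01, 17), 0.08),
                     replace = TRUE),
              nrow = 6, dimnames = list(paste0("t", 1:6), NULL))
  sm <- new("Supermatrix", taxa = rownames(m), seqs = m,
            partitionMap = data.frame(protein = "p", start = 1L, end = 300L))
  # seed a fully conserved backbone so trimming retains blocks
  keepCols <- sample(300, 150)
  vals <- m[1, keepCols]
  vals[vals == "-"] <- "A"
  m[, keepCols] <- rep(vals, each = 6)
  sm <- new("Supermatrix", taxa = rownames(m), seqs = m,
            partitionMap = data.frame(protein = "p", start = 1L, end = 300L))
  once <- trimBlocks(sm, trimParams())$supermatrix
  expect_gt(alnWidth(once), 0L)
  twice <- trimBlocks(once, trimParams())$supermatrix
  expect_identical(alnMatrix(twice), alnMatrix(once))

  cov1 <- filterSiteCoverage(sm, 0.8)
  cov2 <- filterSiteCoverage(cov1, 0.8)
  expect_identical(alnMatrix(cov2), alnMatrix(cov1))
})

test_that("site-coverage filtering drops exactly the low-coverage columns", {
  taxa <- paste0("t", 1:20)
  base <- sample(AA20, 3, replace = TRUE)
  m <- matrix(rep(base, each = 20), nrow = 20, dimnames = list(taxa, NULL))
  m[1, 2] <- "-"            # coverage 0.95: retained at threshold 0.95
  m[1:2, 3] <- "-"          # coverage 0.90: removed
  sm <- new("Supermatrix", taxa = taxa, seqs = m,
            partitionMap = data.frame(protein = "p", start = 1L, end = 3L))
  out <- filterSiteCoverage(sm, 0.95)
  expect_equal(alnWidth(out), 2L)
  expect_equal(unname(alnMatrix(out)[1, ]), c(base[1], "-"))

  # counting oracle on random matrices
  set.seed(44)
  for (k in 1:20) {
    sm2 <- new("Supermatrix", taxa = paste0("t", 1:8),
               seqs = alnMatrix(randomAlignment(8, 50, gapProb = 0.2)),
               partitionMap = data.frame(protein = "p", start = 1L,
                                         end = 50L))
    thr <- runif(1, 0.5, 1)
    keepOracle <- which(vapply(seq_len(50), function(j)
      sum(alnMatrix(sm2)[, j] != "-") / 8 >= thr, TRUE))
    expect_identical(alnMatrix(filterSiteCoverage(sm2, thr)),
                     alnMatrix(sm2)[, keepOracle, drop = FALSE])
  }
})
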