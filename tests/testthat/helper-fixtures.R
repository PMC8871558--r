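# Fixture builders and independent brute-force oracles shared by the unit
# and acceptance tests. Oracles re-derive each quantity from its definition
# (per-column tallies, exhaustive interval search, rule-by-rule filters)
# without calling the implementation under test.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

randomAlignment <- function(nTaxa = 6, nCols = 60, gapProb = 0.1,
                            id = "rand") {
  repeat {
    m <- matrix(sample(AA20, nTaxa * nCols, replace = TRUE), nrow = nTaxa,
                dimnames = list(paste0("t", seq_len(nTaxa)), NULL))
    gaps <- matrix(runif(nTaxa * nCols) < gapProb, nrow = nTaxa)
    m[gaps] <- "-"
    if (all(colSums(m != "-") > 0L)) break
  }
  proteinAlignment(m, id = id)
}

# conserved flanks + an indel planted for `gapped` taxa at columns cols
plantedAlignment <- function(taxa, gapped, cols, nCols = 120) {
  base <- sample(AA20, nCols, replace = TRUE)
  m <- matrix(rep(base, each = length(taxa)), nrow = length(taxa),
              dimnames = list(taxa, NULL))
  m[gapped, cols] <- "-"
  proteinAlignment(m, id = "planted")
}

# ---- oracles ---------------------------------------------------------------

# per-column conservation tally, written as an explicit loop
oracleProfiles <- function(aln, params) {
  m <- alnMatrix(aln)
  out <- data.frame(column = integer(), majorityFraction = numeric(),
                    gapFraction = numeric(), conserved = logical())
  for (j in seq_len(ncol(m))) {
    counts <- integer(0)
    gaps <- 0L
    for (i in seq_len(nrow(m))) {
      ch <- m[i, j]
      if (ch == "-") gaps <- gaps + 1L
      else if (ch != "X") counts[ch] <- (if (is.na(counts[ch])) 0L else counts[ch]) + 1L
    }
    frac <- if (length(counts)) max(counts) / sum(counts) else 0
    gf <- gaps / nrow(m)
    out <- rbind(out, data.frame(
      column = j, majorityFraction = frac, gapFraction = gf,
      conserved = frac >= params@conservationThreshold &&
        gf <= params@maxColumnGapFraction))
  }
  out
}

# exhaustive interval search for maximal constant-gap-set runs
oracleCandidates <- function(aln) {
  m <- alnMatrix(aln)
  L <- ncol(m)
  key <- function(j) paste(which(m[, j] == "-"), collapse = ",")
  found <- list()
  for (a in seq_len(L)) {
    if (!nzchar(key(a))) next
    if (a > 1 && key(a - 1) == key(a)) next      # not maximal to the left
    b <- a
    while (b < L && key(b + 1L) == key(a)) b <- b + 1L
    found[[length(found) + 1L]] <- list(start = a, end = b,
                                        gapTaxa = rownames(m)[m[, a] == "-"])
  }
  found
}

# explicit window tallies for flank conservation
oracleFlanks <- function(start, end, conserved, params) {
  L <- length(conserved)
  left <- 0L
  for (j in seq_len(L))
    if (j < start && j >= start - params@flankWindow && conserved[j])
      left <- left + 1L
  right <- 0L
  for (j in seq_len(L))
    if (j > end && j <= end + params@flankWindow && conserved[j])
      right <- right + 1L
  list(left = left, right = right,
       pass = left >= params@minConservedFlank &&
              right >= params@minConservedFlank)
}

# exhaustive (clade, side) scoring for specificity classification
oracleSpecificity <- function(gapTaxa, residueTaxa, taxaPresent, partition,
                              params) {
  cc <- candidateClades(partition)
  og <- outgroupTaxa(partition)
  best <- NULL
  bestSize <- Inf
  tied <- FALSE
  for (i in seq_len(nrow(cc))) {
    members <- intersect(cladeMembers(partition, cc$level[i], cc$label[i]),
                         taxaPresent)
    if (!length(members)) next
    minCar <- params@cladeMinCarriers[cc$label[i]]
    if (length(minCar) != 1 || is.na(minCar)) minCar <- params@minCarriers
    for (side in list(gapTaxa, residueTaxa)) {
      ogIn <- sum(side %in% intersect(og, taxaPresent))
      ogAll <- sum(taxaPresent %in% og)
      if (ogAll > 0 && ogIn / ogAll >= params@outgroupUnanimity) next
      if (length(intersect(side, members)) <
          length(members) - params@maxExceptions) next
      if (length(setdiff(side, c(members, og))) > params@maxForeign) next
      if (length(side) < minCar) next
      sz <- length(members)
      idTag <- paste(cc$level[i], cc$label[i])
      if (sz < bestSize) { best <- idTag; bestSize <- sz; tied <- FALSE }
      else if (sz == bestSize && !identical(best, idTag)) tied <- TRUE
    }
  }
  if (is.null(best) || tied) NULL else best
}

# gap-aware coordinate mapping computed column by column
oracleRefCoords <- function(aln, start, end, refTaxon, params) {
  prof <- profileColumns(aln, params)
  consIdx <- which(prof$conserved)
  left <- rev(consIdx[consIdx < start])[seq_len(params@minConservedFlank)]
  right <- consIdx[consIdx > end][seq_len(params@minConservedFlank)]
  lo <- suppressWarnings(min(c(left[!is.na(left)], start)))
  hi <- suppressWarnings(max(c(right[!is.na(right)], end)))
  ref <- alnMatrix(aln)[refTaxon, ]
  pos <- 0L; refStart <- NA; refEnd <- NA
  for (j in seq_along(ref)) {
    if (ref[j] != "-") {
      pos <- pos + 1L
      if (j >= lo && is.na(refStart)) refStart <- pos
      if (j <= hi) refEnd <- pos
    }
  }
  c(refStart, refEnd)
}

# rule-by-rule conserved-block trimming on a character matrix
oracleTrimKeep <- function(m, params) {
  L <- ncol(m)
  cls <- integer(L)
  for (j in seq_len(L)) {
    col <- m[, j]
    if (!params@allowGapColumns && any(col == "-")) { cls[j] <- 0L; next }
    resid <- col[col != "-"]
    if (!length(resid)) { cls[j] <- 0L; next }
    frac <- max(table(resid)) / nrow(m)
    cls[j] <- if (frac >= params@highThreshold) 2L
              else if (frac > params@conservedThreshold) 1L else 0L
  }
  keep <- rep(TRUE, L)
  j <- 1L
  while (j <= L) {
    if (cls[j] == 0L) {
      k <- j
      while (k < L && cls[k + 1L] == 0L) k <- k + 1L
      if (k - j + 1L > params@maxNonconservedRun) keep[j:k] <- FALSE
      j <- k + 1L
    } else j <- j + 1L
  }
  kept <- logical(L)
  j <- 1L
  while (j <= L) {
    if (keep[j]) {
      k <- j
      while (k < L && keep[k + 1L]) k <- k + 1L
      block <- j:k
      hc <- block[cls[block] == 2L]
      if (length(hc)) {
        block <- min(hc):max(hc)
        if (length(block) >= params@minBlockLength) kept[block] <- TRUE
      }
      j <- k + 1L
    } else j <- j + 1L
  }
  which(kept)
}

# random resolved tree with strictly positive branch lengths
randomPhylo <- function(nLeaves) {
  tr <- ape::rtree(nLeaves, rooted = FALSE,
                   tip.label = paste0("t", seq_len(nLeaves)))
  tr$edge.length <- runif(length(tr$edge.length), 0.2, 1.5)
  tr
}
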