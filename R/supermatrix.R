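#' Construct trimming parameters
#'
#' @param conservedThreshold,highThreshold,maxNonconservedRun,minBlockLength,allowGapColumns,minSiteCoverage
#'   see [TrimParams-class].
#' @return a validated [TrimParams-class].
#' @export
trimParams <- function(conservedThreshold = 0.5, highThreshold = 0.85,
                       maxNonconservedRun = 8L, minBlockLength = 10L,
                       allowGapColumns = FALSE, minSiteCoverage = 0.95) {
  new("TrimParams", conservedThreshold = conservedThreshold,
      highThreshold = highThreshold,
      maxNonconservedRun = as.integer(maxNonconservedRun),
      minBlockLength = as.integer(minBlockLength),
      allowGapColumns = allowGapColumns, minSiteCoverage = minSiteCoverage)
}

#' Concatenate per-protein alignments into a supermatrix
#'
#' Protein blocks are laid out in input order over the supplied taxon order;
#' taxa missing from a protein are filled with gaps across its block. The
#' partition map records each protein's column interval so the inputs can be
#' recovered by [splitSupermatrix()].
#'
#' @param alignments list of [ProteinAlignment-class]; distinct ids required.
#' @param taxa ordered union taxon list; defaults to the union of the
#'   alignments' taxa in first-seen order.
#' @return a [Supermatrix-class].
#' @export
concatenateAlignments <- function(alignments, taxa = NULL) {
  if (!length(alignments))
    csiStop("csiEmptyInputError", "no alignments supplied")
  ids <- vapply(alignments, function(a) a@id, "")
  if (anyDuplicated(ids))
    csiStop("csiInputError", sprintf("duplicate protein id '%s'",
                                     ids[duplicated(ids)][1L]))
  taxa <- taxa %||% unique(unlist(lapply(alignments, alnTaxa)))
  extra <- setdiff(unlist(lapply(alignments, alnTaxa)), taxa)
  if (length(extra))
    csiStop("csiUnknownTaxonError",
            sprintf("alignment taxon '%s' absent from taxon list", extra[1L]))
  widths <- vapply(alignments, alnWidth, 0L)
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  m <- matrix("-", nrow = length(taxa), ncol = sum(widths),
              dimnames = list(taxa, NULL))
  for (i in seq_along(alignments)) {
    a <- alignments[[i]]
    m[alnTaxa(a), starts[i]:ends[i]] <- a@seqs
  }
  new("Supermatrix", taxa = taxa, seqs = m,
      partitionMap = data.frame(protein = ids, start = starts, end = ends))
}

#' Split a supermatrix back into per-protein alignments
#'
#' Inverse of [concatenateAlignments()] up to gap-fill: taxa whose block is
#' entirely gapped are dropped from that protein's alignment.
#'
#' @param sm a [Supermatrix-class].
#' @return named list of [ProteinAlignment-class].
#' @export
splitSupermatrix <- function(sm) {
  stopifnot(is(sm, "Supermatrix"))
  pm <- sm@partitionMap
  out <- lapply(seq_len(nrow(pm)), function(i) {
    block <- sm@seqs[, seqRange(pm$start[i], pm$end[i]), drop = FALSE]
    present <- rowSums(block != "-") > 0L
    new("ProteinAlignment", id = pm$protein[i],
        seqs = block[present, , drop = FALSE])
  })
  names(out) <- pm$protein
  out
}

# Column classes for trimming: 0 = nonconserved, 1 = conserved, 2 = highly
# conserved. Majority-identity fraction is taken over all rows.
classifyColumns <- function(m, params) {
  vapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    if (!params@allowGapColumns && any(col == "-")) return(0L)
    resid <- col[col != "-"]
    if (!length(resid)) return(0L)
    frac <- max(table(resid)) / nrow(m)
    if (frac >= params@highThreshold) 2L
    else if (frac > params@conservedThreshold) 1L
    else 0L
  }, 0L)
}

#' Trim poorly conserved blocks from a supermatrix
#'
#' A simplified conserved-block trimmer in the tradition of Gblocks: columns
#' are classified as nonconserved, conserved or highly conserved by
#' majority-identity fraction (gap-containing columns are nonconserved unless
#' \code{allowGapColumns}); runs of more than \code{maxNonconservedRun}
#' consecutive nonconserved columns are removed; residual blocks are trimmed
#' at both ends to highly conserved columns and kept only when at least
#' \code{minBlockLength} long. The partition map is remapped to the kept
#' columns and the report makes every kept interval auditable.
#'
#' @param sm a [Supermatrix-class].
#' @param params a [TrimParams-class].
#' @return list with \code{supermatrix} (trimmed) and \code{report}
#'   (data.frame of kept column intervals in original coordinates).
#' @export
trimBlocks <- function(sm, params = trimParams()) {
  stopifnot(is(sm, "Supermatrix"), is(params, "TrimParams"))
  L <- ncol(sm@seqs)
  cls <- classifyColumns(sm@seqs, params)
  keep <- rep(TRUE, L)
  # rule 1: drop long nonconserved runs
  r <- rle(cls == 0L)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  for (i in seq_along(r$values))
    if (r$values[i] && r$lengths[i] > params@maxNonconservedRun)
      keep[starts[i]:ends[i]] <- FALSE
  # rules 2-3: per residual block, trim ends to highly conserved, then length
  kept <- integer(0)
  report <- list()
  r2 <- rle(keep)
  e2 <- cumsum(r2$lengths); s2 <- e2 - r2$lengths + 1L
  for (i in seq_along(r2$values)) {
    if (!r2$values[i]) next
    block <- s2[i]:e2[i]
    hc <- block[cls[block] == 2L]
    if (!length(hc)) next
    block <- seqRange(min(hc), max(hc))
    if (length(block) < params@minBlockLength) next
    kept <- c(kept, block)
    report[[length(report) + 1L]] <- data.frame(start = min(block),
                                                end = max(block))
  }
  report <- if (length(report)) do.call(rbind, report)
            else data.frame(start = integer(), end = integer())
  if (!length(kept))
    csiWarn("csiEmptyResultWarning", "all columns trimmed away")
  newSm <- subsetColumns(sm, kept)
  list(supermatrix = newSm, report = report)
}

# Rebuild a supermatrix keeping the given (sorted) original columns,
# remapping the partition intervals; proteins left empty get zero-width
# intervals removed.
subsetColumns <- function(sm, cols) {
  pm <- sm@partitionMap
  m <- sm@seqs[, cols, drop = FALSE]
  if (length(cols)) {
    counts <- vapply(seq_len(nrow(pm)), function(i)
      sum(cols >= pm$start[i] & cols <= pm$end[i]), 0L)
  } else counts <- rep(0L, nrow(pm))
  keepP <- counts > 0L
  ends <- cumsum(counts[keepP]); starts <- ends - counts[keepP] + 1L
  new("Supermatrix", taxa = sm@taxa, seqs = m,
      partitionMap = data.frame(protein = pm$protein[keepP],
                                start = starts, end = ends))
}

#' Filter supermatrix columns by site coverage
#'
#' Drops every column whose non-gap fraction is below \code{minCoverage}
#' (the published pipeline eliminates positions with less than 95% site
#' coverage).
#'
#' @param sm a [Supermatrix-class].
#' @param minCoverage fraction in (0, 1].
#' @return a [Supermatrix-class].
#' @export
filterSiteCoverage <- function(sm, minCoverage = 0.95) {
  stopifnot(is(sm, "Supermatrix"))
  if (minCoverage <= 0 || minCoverage > 1)
    csiStop("csiInputError", "minCoverage must be in (0, 1]")
  cov <- colSums(sm@seqs != "-") / nrow(sm@seqs)
  subsetColumns(sm, which(cov >= minCoverage))
}
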