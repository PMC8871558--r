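#' Construct detection parameters
#'
#' Defaults encode the published screening rules: at least 5 conserved columns
#' within the 45 columns flanking the indel on each side, a conserved column
#' being one where at least 80% of the non-gap, non-X rows share the majority
#' residue with at most 10% gaps; at least 3 carrier taxa (indels present in
#' only 1-2 isolated species are not reliable markers); at most one clade
#' member lacking the signature; no foreign carriers.
#'
#' @param flankWindow,minConservedFlank,conservationThreshold,maxColumnGapFraction
#'   column-conservation and flank rules; see [DetectionParams-class].
#' @param minCarriers,maxExceptions,maxForeign specificity rules.
#' @param cladeMinCarriers named vector of per-clade-label \code{minCarriers}
#'   overrides.
#' @param outgroupUnanimity outgroup fraction required to call polarity.
#' @return a validated [DetectionParams-class].
#' @export
detectionParams <- function(flankWindow = 45L, minConservedFlank = 5L,
                            conservationThreshold = 0.8,
                            maxColumnGapFraction = 0.1,
                            minCarriers = 3L, maxExceptions = 1L,
                            maxForeign = 0L, cladeMinCarriers = numeric(),
                            outgroupUnanimity = 0.9) {
  new("DetectionParams",
      flankWindow = as.integer(flankWindow),
      minConservedFlank = as.integer(minConservedFlank),
      conservationThreshold = conservationThreshold,
      maxColumnGapFraction = maxColumnGapFraction,
      minCarriers = as.integer(minCarriers),
      maxExceptions = as.integer(maxExceptions),
      maxForeign = as.integer(maxForeign),
      cladeMinCarriers = cladeMinCarriers,
      outgroupUnanimity = outgroupUnanimity)
}

#' Detection profile for the packaged Glires taxonomy
#'
#' Default parameters with the per-clade carrier minimum lowered to 2 for
#' Castorimorpha, whose sequenced membership is only two species.
#'
#' @param ... overrides passed on to [detectionParams()].
#' @return a [DetectionParams-class].
#' @export
gliresDetectionParams <- function(...) {
  detectionParams(cladeMinCarriers = c(Castorimorpha = 2), ...)
}

#' Per-column conservation profile
#'
#' For each alignment column, reports the majority residue and its fraction
#' among non-gap, non-X rows, the gap fraction over all rows, and whether the
#' column counts as conserved (majority fraction at least
#' \code{conservationThreshold} and gap fraction at most
#' \code{maxColumnGapFraction}).
#'
#' @param aln a [ProteinAlignment-class].
#' @param params a [DetectionParams-class].
#' @return data.frame with columns \code{column} (1-based),
#'   \code{majorityResidue} (NA if no informative rows),
#'   \code{majorityFraction}, \code{gapFraction}, \code{conserved}.
#' @export
profileColumns <- function(aln, params = detectionParams()) {
  stopifnot(is(aln, "ProteinAlignment"), is(params, "DetectionParams"))
  m <- aln@seqs
  n <- nrow(m)
  prof <- lapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    gaps <- sum(col == "-")
    informative <- col[col != "-" & col != "X"]
    if (!length(informative)) {
      res <- NA_character_; frac <- 0
    } else {
      tab <- table(informative)
      # deterministic tie-break: alphabetically first among maxima
      res <- names(tab)[tab == max(tab)][1L]
      frac <- max(tab) / length(informative)
    }
    data.frame(column = j, majorityResidue = res, majorityFraction = frac,
               gapFraction = gaps / n)
  })
  prof <- do.call(rbind, prof)
  prof$conserved <- prof$majorityFraction >= params@conservationThreshold &
    prof$gapFraction <= params@maxColumnGapFraction
  prof
}

#' Enumerate fixed-length indel candidates
#'
#' Finds every maximal run of consecutive columns sharing one constant,
#' nonempty, proper gap-taxon set: the taxa gapped across all columns of the
#' interval. Ragged patterns, where the gap set changes inside the run, yield
#' several shorter candidates, never one merged candidate.
#'
#' @param aln a [ProteinAlignment-class].
#' @return data.frame with columns \code{start}, \code{end} (1-based
#'   inclusive), \code{length}, and list-columns \code{gapTaxa},
#'   \code{residueTaxa}; ordered by \code{start}.
#' @export
findIndelCandidates <- function(aln) {
  stopifnot(is(aln, "ProteinAlignment"))
  m <- aln@seqs
  gap <- m == "-"
  # fingerprint the gap pattern of each column; maximal runs of one pattern
  keys <- apply(gap, 2L, function(g) paste(which(g), collapse = ","))
  runs <- rle(keys)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- nzchar(runs$values)   # nonempty gap set (proper by validity)
  if (!any(keep))
    return(data.frame(start = integer(), end = integer(), length = integer(),
                      gapTaxa = I(list()), residueTaxa = I(list())))
  starts <- starts[keep]; ends <- ends[keep]; vals <- runs$values[keep]
  taxa <- rownames(m)
  gapTaxa <- lapply(vals, function(v)
    taxa[as.integer(strsplit(v, ",", fixed = TRUE)[[1L]])])
  data.frame(start = starts, end = ends, length = ends - starts + 1L,
             gapTaxa = I(gapTaxa),
             residueTaxa = I(lapply(gapTaxa, function(g) setdiff(taxa, g))))
}

#' Flank-conservation assessment of one candidate
#'
#' Counts conserved columns within \code{flankWindow} columns to the left of
#' the candidate start and to the right of its end (indel columns excluded,
#' windows clipped at the alignment edges). The candidate passes when both
#' counts reach \code{minConservedFlank}; unflanked indels are not reliable
#' markers.
#'
#' @param cand one candidate row of [findIndelCandidates()] (or any list with
#'   \code{start}, \code{end}).
#' @param profiles output of [profileColumns()] on the same alignment.
#' @param params a [DetectionParams-class].
#' @return list with \code{left}, \code{right} conserved counts and
#'   \code{pass}.
#' @export
assessFlanks <- function(cand, profiles, params = detectionParams()) {
  L <- nrow(profiles)
  leftCols <- seqRange(max(1L, cand$start - params@flankWindow), cand$start - 1L)
  rightCols <- seqRange(cand$end + 1L, min(L, cand$end + params@flankWindow))
  left <- sum(profiles$conserved[leftCols])
  right <- sum(profiles$conserved[rightCols])
  list(left = left, right = right,
       pass = left >= params@minConservedFlank &&
              right >= params@minConservedFlank)
}

#' Classify the clade specificity of a candidate
#'
#' Tests each side of the indel (the gapped taxa and the residue-bearing
#' taxa) against every candidate clade of the partition: a (side, clade) pair
#' passes when the side contains all clade members present in the alignment
#' up to \code{maxExceptions}, carries at most \code{maxForeign} non-clade,
#' non-outgroup taxa, and contains at least the clade's minimum carrier count.
#' Among passing pairs the smallest (most specific) clade is assigned; a tie
#' between distinct clades of equal size is rejected as ambiguous.
#'
#' @param cand one row of [findIndelCandidates()].
#' @param partition a [CladePartition-class]; alignment taxa must be a subset
#'   of the partition's taxa.
#' @param params a [DetectionParams-class].
#' @param taxaPresent taxa present in the source alignment (defaults to the
#'   union of the candidate's two sides).
#' @return \code{NULL} when rejected, otherwise a list with \code{level},
#'   \code{label}, \code{carriers}, \code{exceptions}, \code{foreign} and
#'   \code{side} (\code{"gap"} or \code{"residue"}).
#' @export
classifySpecificity <- function(cand, partition, params = detectionParams(),
                                taxaPresent = NULL) {
  stopifnot(is(partition, "CladePartition"))
  cc <- partition@candidateClades
  if (!nrow(cc))
    csiStop("csiConfigError", "partition declares no candidate clades")
  gapTaxa <- unlist(cand$gapTaxa)
  residueTaxa <- unlist(cand$residueTaxa)
  taxaPresent <- taxaPresent %||% c(gapTaxa, residueTaxa)
  unknown <- setdiff(taxaPresent, partition@taxa)
  if (length(unknown))
    csiStop("csiUnknownTaxonError",
            sprintf("alignment taxon '%s' absent from partition", unknown[1L]))
  og <- partition@outgroups
  ogPresent <- intersect(og, taxaPresent)
  # a side sharing the (near-)unanimous outgroup state is plesiomorphic:
  # its taxa hold the ancestral state, so it cannot support a synapomorphy
  sideOk <- function(side)
    !length(ogPresent) ||
      length(intersect(side, ogPresent)) / length(ogPresent) <
        params@outgroupUnanimity
  passing <- list()
  for (i in seq_len(nrow(cc))) {
    lv <- cc$level[i]; lb <- cc$label[i]
    members <- intersect(cladeMembers(partition, lv, lb), taxaPresent)
    if (!length(members)) next
    minCar <- as.integer(params@cladeMinCarriers[lb] %|NA|% params@minCarriers)
    for (sideName in c("gap", "residue")) {
      side <- if (sideName == "gap") gapTaxa else residueTaxa
      if (!sideOk(side)) next
      carriers <- intersect(side, members)
      if (length(carriers) < length(members) - params@maxExceptions) next
      foreign <- setdiff(side, c(members, og))
      if (length(foreign) > params@maxForeign) next
      if (length(side) < minCar) next
      passing[[length(passing) + 1L]] <- list(
        level = lv, label = lb, size = length(members),
        carriers = carriers, exceptions = setdiff(members, side),
        foreign = foreign, side = sideName)
    }
  }
  if (!length(passing)) return(NULL)
  sizes <- vapply(passing, `[[`, 0L, "size")
  best <- passing[sizes == min(sizes)]
  labels <- unique(vapply(best, function(x) paste(x$level, x$label), ""))
  if (length(labels) > 1L) {
    message(sprintf(
      "ambiguous specificity at columns %d-%d: clades %s tie at size %d; rejected",
      cand$start, cand$end, paste(labels, collapse = " / "), min(sizes)))
    return(NULL)
  }
  best[[1L]][c("level", "label", "carriers", "exceptions", "foreign", "side")]
}

# vectorized "x if not NA else y" for scalar lookups
`%|NA|%` <- function(x, y) if (length(x) != 1L || is.na(x)) y else x

#' Infer indel polarity from outgroup states
#'
#' When at least \code{outgroupUnanimity} of the outgroup taxa present in the
#' alignment carry residues across the indel columns and the carriers are
#' gapped, the event was a deletion in the carriers' common ancestor; in the
#' mirrored situation it was an insertion; mixed outgroup states leave the
#' polarity undetermined (homoplasy cannot be excluded).
#'
#' @param cand one row of [findIndelCandidates()].
#' @param partition a [CladePartition-class].
#' @param carriers the carrier taxa from [classifySpecificity()].
#' @param params a [DetectionParams-class].
#' @return \code{"insertion"}, \code{"deletion"} or \code{"undetermined"}.
#' @export
inferPolarity <- function(cand, partition, carriers,
                          params = detectionParams()) {
  gapTaxa <- unlist(cand$gapTaxa)
  residueTaxa <- unlist(cand$residueTaxa)
  og <- intersect(partition@outgroups, c(gapTaxa, residueTaxa))
  if (!length(og)) {
    csiWarn("csiNoOutgroupWarning",
            "no outgroup taxon present; polarity undetermined")
    return("undetermined")
  }
  residFrac <- length(intersect(og, residueTaxa)) / length(og)
  if (residFrac >= params@outgroupUnanimity && all(carriers %in% gapTaxa))
    return("deletion")
  if ((1 - residFrac) >= params@outgroupUnanimity &&
      all(carriers %in% residueTaxa))
    return("insertion")
  "undetermined"
}

# Columns of the displayed region: the indel plus the minConservedFlank
# nearest conserved columns on each side (clipped at the alignment edges).
displayedRegionColumns <- function(start, end, profiles, params) {
  consLeft <- which(profiles$conserved[seqRange(1L, start - 1L)])
  consRight <- which(profiles$conserved) # global indices handled below
  leftPick <- utils::tail(consLeft, params@minConservedFlank)
  rightAll <- consRight[consRight > end]
  rightPick <- utils::head(rightAll, params@minConservedFlank)
  lo <- if (length(leftPick)) min(leftPick) else start
  hi <- if (length(rightPick)) max(rightPick) else end
  c(lo, hi)
}

#' Map an indel to ungapped reference coordinates
#'
#' Returns the 1-based residue interval of the reference sequence spanning
#' the displayed region: the indel columns plus the \code{minConservedFlank}
#' nearest conserved columns on each side. Gap columns of the reference do
#' not advance its residue counter, so inserting gap-only columns upstream
#' changes nothing.
#'
#' @param aln a [ProteinAlignment-class].
#' @param start,end indel alignment columns (1-based inclusive).
#' @param referenceTaxon reference taxon identifier.
#' @param params a [DetectionParams-class].
#' @param profiles optional precomputed [profileColumns()] output.
#' @return length-2 integer vector, 1-based inclusive residue interval.
#' @export
mapToReferenceCoords <- function(aln, start, end, referenceTaxon,
                                 params = detectionParams(),
                                 profiles = NULL) {
  stopifnot(is(aln, "ProteinAlignment"))
  if (!referenceTaxon %in% alnTaxa(aln))
    csiStop("csiUnknownTaxonError",
            sprintf("reference taxon '%s' not in alignment", referenceTaxon))
  profiles <- profiles %||% profileColumns(aln, params)
  region <- displayedRegionColumns(start, end, profiles, params)
  ref <- aln@seqs[referenceTaxon, ]
  isRes <- ref != "-"
  if (!any(isRes[seqRange(region[1L], region[2L])]))
    csiStop("csiReferenceError", sprintf(
      "reference '%s' is gapped across the entire displayed region (columns %d-%d)",
      referenceTaxon, region[1L], region[2L]))
  cumRes <- cumsum(isRes)
  refStart <- (if (region[1L] > 1L) cumRes[region[1L] - 1L] else 0L) + 1L
  refEnd <- cumRes[region[2L]]
  c(refStart, refEnd)
}

#' Extract the ungapped query region around an indel
#'
#' Returns the reference sequence's ungapped residues covering the indel
#' region plus \code{flankAa} residues on each side, clipped at the sequence
#' ends - the query one would submit to an external homology search to
#' verify group specificity. The published protocol uses flanks of 50-100
#' residues; values outside that range are accepted but flagged.
#'
#' @inheritParams mapToReferenceCoords
#' @param flankAa residues per side (default 60).
#' @return single character string.
#' @export
extractQueryRegion <- function(aln, start, end, referenceTaxon,
                               flankAa = 60L) {
  stopifnot(is(aln, "ProteinAlignment"))
  if (!referenceTaxon %in% alnTaxa(aln))
    csiStop("csiUnknownTaxonError",
            sprintf("reference taxon '%s' not in alignment", referenceTaxon))
  if (flankAa < 50L || flankAa > 100L)
    csiWarn("csiFlankRangeWarning",
            "flankAa outside the conventional 50-100 residue range")
  ref <- aln@seqs[referenceTaxon, ]
  isRes <- ref != "-"
  cumRes <- cumsum(isRes)
  degapped <- paste(ref[isRes], collapse = "")
  if (!nchar(degapped))
    csiStop("csiReferenceError",
            sprintf("reference '%s' has no residues", referenceTaxon))
  before <- if (start > 1L) cumRes[start - 1L] else 0L
  upto <- cumRes[end]
  if (upto >= before + 1L) { a <- before + 1L; b <- upto }      # ref has residues in the indel
  else { a <- before + 1L; b <- before }                        # ref gapped: empty core
  qs <- max(1L, a - flankAa)
  qe <- min(nchar(degapped), b + flankAa)
  substr(degapped, qs, qe)
}

# Crisp-boundary rule: a fixed-length shared indel requires every gap-side
# taxon to resume residues immediately outside the interval (where the
# alignment extends that far). Ragged patterns, whose gap runs extend past a
# candidate's boundary for some taxa, are discarded here.
hasCrispBoundaries <- function(aln, cand) {
  gapTaxa <- unlist(cand$gapTaxa)
  m <- aln@seqs
  ok <- TRUE
  if (cand$start > 1L)
    ok <- ok && all(m[gapTaxa, cand$start - 1L] != "-")
  if (cand$end < ncol(m))
    ok <- ok && all(m[gapTaxa, cand$end + 1L] != "-")
  ok
}

#' Detect conserved signature indels in one alignment
#'
#' The full screening pipeline: enumerate fixed-length indel candidates,
#' discard candidates without crisp shared boundaries (ragged patterns),
#' keep those flanked by conserved regions, classify clade specificity with
#' exception tolerance, infer insertion/deletion polarity from the outgroup
#' states, and map each accepted signature to reference coordinates.
#'
#' @param aln a [ProteinAlignment-class] whose taxa are a subset of the
#'   partition's taxa.
#' @param partition a [CladePartition-class].
#' @param params a [DetectionParams-class].
#' @param referenceTaxon taxon anchoring reported coordinates; by default the
#'   first alignment row (preferring carriers) without gaps in the displayed
#'   flanks.
#' @param flankAa query-region flank width in residues (default 60).
#' @return list of [CSICall-class] objects, sorted by start column.
#' @examples
#' sc <- generateScenario(nFamilies = 2, seed = 1)
#' calls <- detectCsis(sc$families[[1]], sc$partition, gliresDetectionParams())
#' @export
detectCsis <- function(aln, partition, params = detectionParams(),
                       referenceTaxon = NULL, flankAa = 60L) {
  stopifnot(is(aln, "ProteinAlignment"), is(partition, "CladePartition"))
  unknown <- setdiff(alnTaxa(aln), partition@taxa)
  if (length(unknown))
    csiStop("csiUnknownTaxonError",
            sprintf("alignment taxon '%s' absent from partition", unknown[1L]))
  profiles <- profileColumns(aln, params)
  cands <- findIndelCandidates(aln)
  calls <- list()
  for (i in seq_len(nrow(cands))) {
    cand <- cands[i, ]
    if (!hasCrispBoundaries(aln, cand)) next
    fl <- assessFlanks(cand, profiles, params)
    if (!fl$pass) next
    spec <- classifySpecificity(cand, partition, params,
                                taxaPresent = alnTaxa(aln))
    if (is.null(spec)) next
    pol <- inferPolarity(cand, partition, spec$carriers, params)
    ref <- referenceTaxon %||%
      chooseReference(aln, cand, spec$carriers, profiles, params)
    if (is.null(ref)) next
    refRange <- mapToReferenceCoords(aln, cand$start, cand$end, ref,
                                     params, profiles)
    qr <- suppressWarnings(
      extractQueryRegion(aln, cand$start, cand$end, ref, flankAa))
    calls[[length(calls) + 1L]] <- new("CSICall",
      proteinId = aln@id, start = cand$start, end = cand$end,
      length = cand$length, cladeLevel = spec$level, cladeLabel = spec$label,
      carriers = spec$carriers, exceptions = spec$exceptions,
      foreign = spec$foreign, gapTaxa = unlist(cand$gapTaxa),
      polarity = pol, flankLeft = as.integer(fl$left),
      flankRight = as.integer(fl$right), referenceTaxon = ref,
      referenceRange = as.integer(refRange), queryRegion = qr)
  }
  calls[order(vapply(calls, function(x) x@start, 0L))]
}

# Default reference: the first taxon (carriers preferred, alignment order)
# with residues throughout the displayed region outside the indel columns.
chooseReference <- function(aln, cand, carriers, profiles, params) {
  region <- displayedRegionColumns(cand$start, cand$end, profiles, params)
  flankCols <- setdiff(seqRange(region[1L], region[2L]),
                       seqRange(cand$start, cand$end))
  m <- aln@seqs
  ok <- function(tx) all(m[tx, flankCols] != "-")
  for (tx in intersect(rownames(m), carriers)) if (ok(tx)) return(tx)
  for (tx in rownames(m)) if (ok(tx)) return(tx)
  NULL
}

#' Tabulate CSI calls
#'
#' Flattens a list of [CSICall-class] objects into the tab-separated report
#' layout: one row per CSI with protein, clade, size, type, reference range,
#' carriers and exceptions.
#'
#' @param calls list of [CSICall-class] (as returned by [detectCsis()]),
#'   or a list of such lists (e.g. one per protein family).
#' @return data.frame, zero rows when no calls.
#' @export
csiTable <- function(calls) {
  if (length(calls) && is.list(calls[[1]]) && !is(calls[[1]], "CSICall"))
    calls <- unlist(calls, recursive = FALSE)
  if (!length(calls))
    return(data.frame(protein = character(), clade = character(),
                      level = character(), sizeAa = integer(),
                      type = character(), start = integer(), end = integer(),
                      refStart = integer(), refEnd = integer(),
                      referenceTaxon = character(), carriers = character(),
                      exceptions = character(), foreign = character()))
  do.call(rbind, lapply(calls, function(x) data.frame(
    protein = x@proteinId, clade = x@cladeLabel, level = x@cladeLevel,
    sizeAa = x@length,
    type = switch(x@polarity, insertion = "Ins", deletion = "Del", "Indet"),
    start = x@start, end = x@end,
    refStart = x@referenceRange[1L], refEnd = x@referenceRange[2L],
    referenceTaxon = x@referenceTaxon,
    carriers = paste(x@carriers, collapse = ","),
    exceptions = paste(x@exceptions, collapse = ","),
    foreign = paste(x@foreign, collapse = ","))))
}
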