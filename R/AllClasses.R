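#' @import methods
NULL

#' Gapped protein multiple sequence alignment
#'
#' The substrate of every stage of the package: a rectangular, gapped
#' amino-acid alignment keyed by taxon identifier. Sequences are stored as a
#' character matrix with one single-letter cell per column; row names are the
#' taxon identifiers (conventionally \code{Genus_species}). The alphabet is
#' the 20 standard residues, \code{X} (unknown) and \code{-} (gap).
#'
#' Validity requires at least one row and column, unique taxon identifiers,
#' alphabet compliance, and that no column consists entirely of gaps.
#'
#' @slot id single protein-family identifier.
#' @slot seqs character matrix, rows = taxa, columns = alignment columns.
#' @seealso [readAlignment()], [writeAlignment()], [proteinAlignment()]
#' @export
setClass("ProteinAlignment",
  representation(id = "character", seqs = "matrix"))

setValidity("ProteinAlignment", function(object) {
  m <- object@seqs
  if (length(object@id) != 1L) return("'id' must be a single string")
  if (!is.character(m) || nrow(m) < 1L || ncol(m) < 1L)
    return("alignment must have >= 1 taxon and >= 1 column")
  if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
    return("taxon identifiers must be present and unique")
  bad <- !(m %in% ALN_ALPHABET)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    return(sprintf("invalid symbol '%s' in row '%s', column %d",
                   m[idx[1L], idx[2L]], rownames(m)[idx[1L]], idx[2L]))
  }
  allGap <- which(colSums(m != "-") == 0L)
  if (length(allGap))
    return(sprintf("column %d consists entirely of gaps", allGap[1L]))
  TRUE
})

#' Hierarchical clade partition of a taxon set
#'
#' Maps taxon identifiers to clade labels at named taxonomic levels (order,
#' suborder, family, ...), designates outgroup taxa (never assignable as CSI
#' carriers) and lists the candidate clades eligible for specificity
#' assignment. Taxa missing from a level's mapping are treated as unplaced at
#' that level.
#'
#' @slot taxa character vector of all taxon identifiers.
#' @slot levels named list; each element a named character vector taxon -> label.
#' @slot outgroups character vector, subset of \code{taxa}.
#' @slot candidateClades data.frame with columns \code{level}, \code{label}.
#' @seealso [loadCladePartition()], [cladeMembers()]
#' @export
setClass("CladePartition",
  representation(taxa = "character", levels = "list",
                 outgroups = "character", candidateClades = "data.frame"))

setValidity("CladePartition", function(object) {
  if (anyDuplicated(object@taxa)) return("duplicate taxon identifiers")
  if (!all(object@outgroups %in% object@taxa))
    return("outgroups must be a subset of taxa")
  for (lv in names(object@levels)) {
    map <- object@levels[[lv]]
    if (!is.character(map) || is.null(names(map)))
      return(sprintf("level '%s' must be a named character vector", lv))
    unknown <- setdiff(names(map), object@taxa)
    if (length(unknown))
      return(sprintf("level '%s' maps unknown taxon '%s'", lv, unknown[1L]))
  }
  cc <- object@candidateClades
  if (!all(c("level", "label") %in% names(cc)))
    return("candidateClades needs 'level' and 'label' columns")
  for (i in seq_len(nrow(cc))) {
    lv <- cc$level[i]; lb <- cc$label[i]
    if (!lv %in% names(object@levels))
      return(sprintf("candidate clade level '%s' not defined", lv))
    members <- names(object@levels[[lv]])[object@levels[[lv]] == lb]
    if (!length(members))
      return(sprintf("candidate clade %s/%s has no members", lv, lb))
    if (length(intersect(members, object@outgroups)))
      return(sprintf("candidate clade %s/%s overlaps the outgroup set", lv, lb))
  }
  TRUE
})

#' Tuning parameters for CSI detection
#'
#' Operationalizes the published screening rules: an indel qualifies when it
#' is of fixed length across carriers, flanked on both sides by at least
#' \code{minConservedFlank} conserved columns within \code{flankWindow}
#' columns, shared by at least \code{minCarriers} taxa, specific to one
#' candidate clade up to \code{maxExceptions} missing members and at most
#' \code{maxForeign} non-clade, non-outgroup carriers.
#'
#' @slot flankWindow columns inspected on each side of an indel (default 45).
#' @slot minConservedFlank conserved columns required per side (default 5).
#' @slot conservationThreshold fraction of non-gap, non-X rows sharing the
#'   majority residue for a column to count as conserved (default 0.8).
#' @slot maxColumnGapFraction maximum gap fraction of a conserved column
#'   (default 0.1).
#' @slot minCarriers minimum taxa sharing the indel (default 3).
#' @slot maxExceptions clade members allowed to lack the CSI (default 1).
#' @slot maxForeign non-clade, non-outgroup taxa allowed to share it (default 0).
#' @slot cladeMinCarriers named numeric vector of per-clade-label overrides of
#'   \code{minCarriers} (e.g. a two-member suborder); default empty.
#' @slot outgroupUnanimity outgroup fraction required to call polarity
#'   (default 0.9).
#' @seealso [detectionParams()], [detectCsis()]
#' @export
setClass("DetectionParams",
  representation(flankWindow = "integer", minConservedFlank = "integer",
                 conservationThreshold = "numeric",
                 maxColumnGapFraction = "numeric",
                 minCarriers = "integer", maxExceptions = "integer",
                 maxForeign = "integer", cladeMinCarriers = "numeric",
                 outgroupUnanimity = "numeric"))

setValidity("DetectionParams", function(object) {
  if (object@minConservedFlank < 1L ||
      object@flankWindow < object@minConservedFlank)
    return("need flankWindow >= minConservedFlank >= 1")
  if (object@conservationThreshold <= 0 || object@conservationThreshold > 1)
    return("conservationThreshold must be in (0, 1]")
  if (object@maxColumnGapFraction < 0 || object@maxColumnGapFraction > 1)
    return("maxColumnGapFraction must be in [0, 1]")
  if (object@minCarriers < 1L) return("minCarriers must be >= 1")
  if (object@maxExceptions < 0L || object@maxForeign < 0L)
    return("maxExceptions and maxForeign must be >= 0")
  if (object@outgroupUnanimity <= 0 || object@outgroupUnanimity > 1)
    return("outgroupUnanimity must be in (0, 1]")
  TRUE
})

#' A detected conserved signature indel
#'
#' One accepted signature: the indel's alignment columns, length, assigned
#' clade, carrier and exception taxa, inferred polarity, flank-conservation
#' report and reference-sequence coordinates.
#'
#' Column coordinates are 1-based inclusive alignment columns. Reference
#' coordinates are 1-based inclusive ungapped residue positions in the
#' reference taxon's sequence, spanning the displayed region (indel plus the
#' required conserved flank columns on each side).
#'
#' @slot proteinId protein-family identifier of the source alignment.
#' @slot start,end first/last alignment column of the indel (1-based inclusive).
#' @slot length indel length in amino acids (\code{end - start + 1}).
#' @slot cladeLevel,cladeLabel the assigned candidate clade.
#' @slot carriers clade members sharing the indel.
#' @slot exceptions clade members lacking it (at most \code{maxExceptions}).
#' @slot foreign non-clade, non-outgroup taxa sharing it.
#' @slot gapTaxa taxa gapped across the indel columns.
#' @slot polarity \code{"insertion"}, \code{"deletion"} or \code{"undetermined"}.
#' @slot flankLeft,flankRight conserved-column counts in the two flank windows.
#' @slot referenceTaxon taxon whose sequence anchors reported coordinates.
#' @slot referenceRange length-2 integer, displayed-region residue interval.
#' @slot queryRegion ungapped reference sequence covering the indel and its
#'   flanking residues (for external homology searches).
#' @seealso [detectCsis()], [renderSignature()]
#' @export
setClass("CSICall",
  representation(proteinId = "character", start = "integer", end = "integer",
                 length = "integer", cladeLevel = "character",
                 cladeLabel = "character", carriers = "character",
                 exceptions = "character", foreign = "character",
                 gapTaxa = "character", polarity = "character",
                 flankLeft = "integer", flankRight = "integer",
                 referenceTaxon = "character", referenceRange = "integer",
                 queryRegion = "character"))

#' Dash-notation signature figure
#'
#' A plain-text excerpt of an alignment around a CSI in the style of
#' published signature files: the reference residues on the top line, every
#' other row showing \code{-} where identical to the top line, the residue
#' letter where different and a space where gapped; rows grouped into labelled
#' clade blocks (carriers first, then other in-group clades, then outgroups);
#' the indel columns highlighted.
#'
#' @slot title figure title.
#' @slot displayStart,displayEnd displayed alignment columns (1-based inclusive).
#' @slot highlightStart,highlightEnd highlighted indel columns.
#' @slot rows data.frame with columns \code{group}, \code{taxon}, \code{text};
#'   the first row is the reference and contains no dashes.
#' @slot identityGlyph glyph used for identity with the top line.
#' @seealso [renderSignature()], [signatureSlice()]
#' @export
setClass("SignatureFigure",
  representation(title = "character", displayStart = "integer",
                 displayEnd = "integer", highlightStart = "integer",
                 highlightEnd = "integer", rows = "data.frame",
                 identityGlyph = "character"))

setValidity("SignatureFigure", function(object) {
  r <- object@rows
  if (!all(c("group", "taxon", "text") %in% names(r)))
    return("rows needs 'group', 'taxon', 'text' columns")
  w <- unique(nchar(r$text))
  if (length(w) != 1L) return("rendered strings must have equal length")
  if (w != object@displayEnd - object@displayStart + 1L)
    return("rendered width must match the display interval")
  if (object@highlightStart < object@displayStart ||
      object@highlightEnd > object@displayEnd)
    return("highlight span must lie within the display interval")
  if (length(r$text) && grepl(object@identityGlyph, r$text[1L], fixed = TRUE))
    return("top row must not contain the identity glyph")
  TRUE
})

#' Concatenated multi-protein supermatrix
#'
#' Per-protein alignment blocks concatenated over a common taxon set, with a
#' partition map recording each protein's column interval (1-based inclusive).
#' Taxa missing from a protein are gap-filled across its block.
#'
#' @slot taxa ordered taxon identifiers (matrix row names).
#' @slot seqs character matrix as in [ProteinAlignment-class] (all-gap
#'   columns permitted here, unlike single alignments).
#' @slot partitionMap data.frame with columns \code{protein}, \code{start},
#'   \code{end}; intervals disjoint and covering all columns.
#' @seealso [concatenateAlignments()], [trimBlocks()], [filterSiteCoverage()]
#' @export
setClass("Supermatrix",
  representation(taxa = "character", seqs = "matrix",
                 partitionMap = "data.frame"))

setValidity("Supermatrix", function(object) {
  m <- object@seqs
  if (!identical(rownames(m), object@taxa)) return("row names must equal taxa")
  pm <- object@partitionMap
  if (!all(c("protein", "start", "end") %in% names(pm)))
    return("partitionMap needs 'protein', 'start', 'end' columns")
  if (ncol(m) == 0L) {
    if (nrow(pm) && any(pm$end >= pm$start)) return("non-empty interval in empty matrix")
    return(TRUE)
  }
  covered <- unlist(mapply(seqRange, pm$start, pm$end, SIMPLIFY = FALSE))
  if (anyDuplicated(covered)) return("partition intervals overlap")
  if (!setequal(covered, seq_len(ncol(m))))
    return("partition intervals must cover all columns")
  TRUE
})

#' Gblocks-style trimming parameters
#'
#' Column-classification thresholds and block rules for [trimBlocks()],
#' mirroring the documented defaults of the classic conserved-block trimmer:
#' a column is \emph{conserved} when its majority-identity fraction strictly
#' exceeds \code{conservedThreshold}, \emph{highly conserved} at
#' \code{>= highThreshold}; gap-containing columns are nonconserved unless
#' \code{allowGapColumns}. Runs of more than \code{maxNonconservedRun}
#' nonconserved columns are removed, residual blocks are trimmed to highly
#' conserved ends and kept only at length \code{>= minBlockLength}.
#'
#' @slot conservedThreshold default 0.5 (strictly exceeded).
#' @slot highThreshold default 0.85.
#' @slot maxNonconservedRun default 8.
#' @slot minBlockLength default 10.
#' @slot allowGapColumns default FALSE.
#' @slot minSiteCoverage default 0.95 (used by [filterSiteCoverage()]).
#' @seealso [trimParams()]
#' @export
setClass("TrimParams",
  representation(conservedThreshold = "numeric", highThreshold = "numeric",
                 maxNonconservedRun = "integer", minBlockLength = "integer",
                 allowGapColumns = "logical", minSiteCoverage = "numeric"))

setValidity("TrimParams", function(object) {
  if (object@conservedThreshold <= 0 || object@conservedThreshold > 1 ||
      object@highThreshold <= 0 || object@highThreshold > 1 ||
      object@minSiteCoverage <= 0 || object@minSiteCoverage > 1)
    return("thresholds must be in (0, 1]")
  if (object@maxNonconservedRun < 1L || object@minBlockLength < 1L)
    return("run/block lengths must be >= 1")
  TRUE
})

#' Pairwise distance matrix with effective site counts
#'
#' Symmetric matrix of Poisson-corrected amino-acid distances together with
#' the number of pairwise-ungapped columns each estimate is based on.
#'
#' @slot taxa taxon identifiers (dimnames of both matrices).
#' @slot d symmetric nonnegative distance matrix, zero diagonal.
#' @slot sharedSites integer matrix of pairwise-ungapped column counts.
#' @seealso [poissonDistance()], [neighborJoining()]
#' @export
setClass("DistanceMatrix",
  representation(taxa = "character", d = "matrix", sharedSites = "matrix"))

setValidity("DistanceMatrix", function(object) {
  d <- object@d
  if (!identical(rownames(d), object@taxa) ||
      !identical(colnames(d), object@taxa))
    return("dimnames must equal taxa")
  if (any(!is.finite(d))) return("distances must be finite")
  if (any(abs(d - t(d)) > 1e-12)) return("matrix must be symmetric")
  if (any(diag(d) != 0)) return("diagonal must be zero")
  if (any(d < 0)) return("distances must be nonnegative")
  TRUE
})
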