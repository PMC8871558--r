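#' Taxon identifiers of an object
#' @param x a ProteinAlignment, CladePartition, Supermatrix or DistanceMatrix.
#' @return character vector of taxon identifiers.
#' @export
setGeneric("alnTaxa", function(x) standardGeneric("alnTaxa"))

#' Number of alignment columns
#' @param x a ProteinAlignment or Supermatrix.
#' @return integer column count.
#' @export
setGeneric("alnWidth", function(x) standardGeneric("alnWidth"))

#' Underlying character matrix of an alignment-like object
#' @param x a ProteinAlignment, Supermatrix or SignatureFigure.
#' @return character matrix (rows = taxa).
#' @export
setGeneric("alnMatrix", function(x) standardGeneric("alnMatrix"))

#' @rdname alnTaxa
#' @export
setMethod("alnTaxa", "ProteinAlignment", function(x) rownames(x@seqs))
#' @rdname alnTaxa
#' @export
setMethod("alnTaxa", "CladePartition", function(x) x@taxa)
#' @rdname alnTaxa
#' @export
setMethod("alnTaxa", "Supermatrix", function(x) x@taxa)
#' @rdname alnTaxa
#' @export
setMethod("alnTaxa", "DistanceMatrix", function(x) x@taxa)

#' @rdname alnWidth
#' @export
setMethod("alnWidth", "ProteinAlignment", function(x) ncol(x@seqs))
#' @rdname alnWidth
#' @export
setMethod("alnWidth", "Supermatrix", function(x) ncol(x@seqs))

#' @rdname alnMatrix
#' @export
setMethod("alnMatrix", "ProteinAlignment", function(x) x@seqs)
#' @rdname alnMatrix
#' @export
setMethod("alnMatrix", "Supermatrix", function(x) x@seqs)

setMethod("show", "ProteinAlignment", function(object) {
  cat(sprintf("ProteinAlignment '%s': %d taxa x %d columns\n",
              object@id, nrow(object@seqs), ncol(object@seqs)))
  tx <- rownames(object@seqs)
  shown <- utils::head(tx, 4L)
  cat("  taxa:", paste(shown, collapse = ", "),
      if (length(tx) > 4L) sprintf("... (+%d)", length(tx) - 4L) else "", "\n")
})

setMethod("show", "CladePartition", function(object) {
  cat(sprintf("CladePartition: %d taxa, %d levels (%s), %d outgroups\n",
              length(object@taxa), length(object@levels),
              paste(names(object@levels), collapse = ", "),
              length(object@outgroups)))
  cc <- object@candidateClades
  cat(sprintf("  %d candidate clades: %s\n", nrow(cc),
              paste(utils::head(cc$label, 6L), collapse = ", ")))
})

setMethod("show", "CSICall", function(object) {
  cat(sprintf("CSICall: %d aa %s in '%s', columns %d-%d\n",
              object@length,
              switch(object@polarity, insertion = "Ins", deletion = "Del",
                     "indel (polarity undetermined)"),
              object@proteinId, object@start, object@end))
  cat(sprintf("  specific for %s '%s' (%d carriers", object@cladeLevel,
              object@cladeLabel, length(object@carriers)))
  if (length(object@exceptions))
    cat(sprintf("; lacking in %s", paste(object@exceptions, collapse = ", ")))
  cat(")\n")
  cat(sprintf("  reference %s residues %d-%d; flanks %d/%d conserved columns\n",
              object@referenceTaxon, object@referenceRange[1L],
              object@referenceRange[2L], object@flankLeft, object@flankRight))
})

setMethod("show", "Supermatrix", function(object) {
  cat(sprintf("Supermatrix: %d taxa x %d columns, %d partitions\n",
              length(object@taxa), ncol(object@seqs),
              nrow(object@partitionMap)))
})

setMethod("show", "DetectionParams", function(object) {
  cat(sprintf(paste0(
    "DetectionParams: flank %d/%d (threshold %.2f, max gap %.2f), ",
    "carriers >= %d, exceptions <= %d, foreign <= %d\n"),
    object@minConservedFlank, object@flankWindow,
    object@conservationThreshold, object@maxColumnGapFraction,
    object@minCarriers, object@maxExceptions, object@maxForeign))
  if (length(object@cladeMinCarriers))
    cat("  per-clade min carriers:",
        paste(names(object@cladeMinCarriers), object@cladeMinCarriers,
              sep = "=", collapse = ", "), "\n")
})

setMethod("show", "DistanceMatrix", function(object) {
  cat(sprintf("DistanceMatrix: %d taxa, mean distance %.4f\n",
              length(object@taxa),
              mean(object@d[upper.tri(object@d)])))
})
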