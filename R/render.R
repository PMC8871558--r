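#' Render a signature figure for a CSI
#'
#' Produces the classic signature-file excerpt: the reference residues on the
#' top line; every other row showing the identity glyph where identical to
#' the top line, the residue letter where different, and a space where
#' gapped; rows grouped into labelled blocks (carriers first, then the other
#' in-group clades at the assigned level, then the outgroups); the indel
#' columns highlighted.
#'
#' The rendering is lossless: [signatureSlice()] reconstructs the original
#' alignment slice byte-for-byte.
#'
#' @param csi a [CSICall-class] derived from \code{aln}.
#' @param aln the source [ProteinAlignment-class].
#' @param partition the [CladePartition-class] used for detection.
#' @param displayFlank columns shown on each side of the indel (default 20),
#'   clipped at the alignment bounds.
#' @param ascii use \code{"."} instead of \code{"-"} as the identity glyph
#'   (strict-ASCII mode avoiding dash ambiguity).
#' @return a [SignatureFigure-class].
#' @export
renderSignature <- function(csi, aln, partition, displayFlank = 20L,
                            ascii = FALSE) {
  stopifnot(is(csi, "CSICall"), is(aln, "ProteinAlignment"),
            is(partition, "CladePartition"))
  if (!identical(csi@proteinId, aln@id) ||
      !all(c(csi@referenceTaxon, csi@carriers) %in% alnTaxa(aln)) ||
      csi@end > alnWidth(aln))
    csiStop("csiConsistencyError",
            "CSI call does not belong to this alignment")
  glyph <- if (ascii) "." else "-"
  ds <- max(1L, csi@start - as.integer(displayFlank))
  de <- min(alnWidth(aln), csi@end + as.integer(displayFlank))
  cols <- seqRange(ds, de)
  m <- aln@seqs[, cols, drop = FALSE]

  refTx <- csi@referenceTaxon
  top <- m[refTx, ]
  renderRow <- function(chars) {
    out <- chars
    out[chars == "-"] <- " "
    ident <- chars != "-" & top != "-" & chars == top
    out[ident] <- glyph
    paste(out, collapse = "")
  }
  topText <- paste(ifelse(top == "-", " ", top), collapse = "")

  taxa <- alnTaxa(aln)
  lvMap <- partition@levels[[csi@cladeLevel]]
  og <- intersect(taxa, partition@outgroups)
  carrierBlock <- c(refTx, setdiff(intersect(taxa, csi@carriers), refTx))
  carrierBlock <- unique(c(refTx, carrierBlock))
  rest <- setdiff(taxa, c(carrierBlock, og))
  restLabel <- function(tx) {
    lb <- unname(lvMap[tx])
    ifelse(is.na(lb), "Other", lb)
  }
  ordered <- c(carrierBlock,
               rest[order(restLabel(rest), match(rest, taxa))], og)
  groups <- vapply(ordered, function(tx) {
    if (tx %in% carrierBlock) csi@cladeLabel
    else if (tx %in% og) "Outgroup"
    else restLabel(tx)
  }, "")
  texts <- vapply(ordered, function(tx) {
    if (tx == refTx) topText else renderRow(m[tx, ])
  }, "")
  rows <- data.frame(group = unname(groups), taxon = ordered,
                     text = unname(texts), row.names = NULL)
  new("SignatureFigure",
      title = sprintf("%d aa %s in %s, specific for %s", csi@length,
                      switch(csi@polarity, insertion = "insertion",
                             deletion = "deletion", "indel"),
                      csi@proteinId, csi@cladeLabel),
      displayStart = ds, displayEnd = de,
      highlightStart = csi@start, highlightEnd = csi@end,
      rows = rows, identityGlyph = glyph)
}

#' Reconstruct the alignment slice from a signature figure
#'
#' Inverse of [renderSignature()]: decodes the dash/space notation back into
#' the original gapped alignment characters.
#'
#' @param fig a [SignatureFigure-class].
#' @return character matrix (rows = taxa of the figure, in figure order).
#' @export
signatureSlice <- function(fig) {
  stopifnot(is(fig, "SignatureFigure"))
  topChars <- strsplit(fig@rows$text[1L], "")[[1L]]
  top <- ifelse(topChars == " ", "-", topChars)
  out <- t(vapply(seq_len(nrow(fig@rows)), function(i) {
    chars <- strsplit(fig@rows$text[i], "")[[1L]]
    dec <- chars
    dec[chars == " "] <- "-"
    dec[chars == fig@identityGlyph] <- top[chars == fig@identityGlyph]
    dec
  }, character(nchar(fig@rows$text[1L]))))
  rownames(out) <- fig@rows$taxon
  out[1L, ] <- top
  out
}

#' Format a signature figure as text lines
#'
#' @param fig a [SignatureFigure-class].
#' @return character vector of lines (title, column ruler, highlight marks,
#'   grouped rows separated by blank lines).
#' @export
formatSignature <- function(fig) {
  stopifnot(is(fig, "SignatureFigure"))
  nameW <- max(nchar(fig@rows$taxon), nchar("taxon")) + 2L
  header <- sprintf("%-*s%d..%d", nameW, "", fig@displayStart, fig@displayEnd)
  mark <- rep(" ", fig@displayEnd - fig@displayStart + 1L)
  mark[seqRange(fig@highlightStart - fig@displayStart + 1L,
                fig@highlightEnd - fig@displayStart + 1L)] <- "^"
  lines <- c(fig@title, header)
  lastGroup <- NULL
  for (i in seq_len(nrow(fig@rows))) {
    g <- fig@rows$group[i]
    if (!identical(g, lastGroup)) {
      lines <- c(lines, "", sprintf("[%s]", g))
      lastGroup <- g
    }
    lines <- c(lines, sprintf("%-*s%s", nameW, fig@rows$taxon[i],
                              fig@rows$text[i]))
  }
  c(lines, sprintf("%-*s%s", nameW, "", paste(mark, collapse = "")))
}

#' Write a signature figure to a plain-text or HTML file
#'
#' @param fig a [SignatureFigure-class].
#' @param path output path.
#' @param format \code{"text"} or \code{"html"} (a minimal
#'   \code{<pre>}-wrapped page with the indel span emphasised).
#' @return \code{path}, invisibly.
#' @export
writeSignature <- function(fig, path, format = c("text", "html")) {
  format <- match.arg(format)
  lines <- formatSignature(fig)
  if (format == "html") {
    esc <- function(x) gsub("<", "&lt;", gsub("&", "&amp;", x, fixed = TRUE),
                            fixed = TRUE)
    lines <- c("<!DOCTYPE html>", "<html><body>",
               sprintf("<h3>%s</h3>", esc(fig@title)),
               "<pre>", esc(lines[-1L]), "</pre>", "</body></html>")
  }
  tryCatch(writeLines(lines, path), error = function(e)
    csiStop("csiIOError", sprintf("cannot write %s", path)))
  invisible(path)
}

setMethod("show", "SignatureFigure", function(object) {
  cat(formatSignature(object), sep = "\n")
})
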