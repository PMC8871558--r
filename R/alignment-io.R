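#' Construct a ProteinAlignment from sequence strings
#'
#' @param seqs named character vector of equal-length gapped sequences, or a
#'   character matrix of single letters with taxon row names.
#' @param id protein-family identifier.
#' @return a validated [ProteinAlignment-class].
#' @examples
#' proteinAlignment(c(Mus_musculus = "ACDEF", Rattus_rattus = "AC-EF"), "demo")
#' @export
proteinAlignment <- function(seqs, id = "alignment") {
  if (is.matrix(seqs)) {
    m <- seqs
  } else {
    if (!length(seqs))
      csiStop("csiEmptyInputError", "no sequences supplied")
    if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
      csiStop("csiShapeError", "sequences must be named by taxon")
    widths <- nchar(seqs)
    if (length(unique(widths)) != 1L)
      csiStop("csiShapeError", sprintf(
        "rows have unequal lengths: '%s' has %d columns, '%s' has %d",
        names(seqs)[1L], widths[1L],
        names(seqs)[which(widths != widths[1L])[1L]],
        widths[widths != widths[1L]][1L]))
    m <- matrix(unlist(strsplit(toupper(seqs), "", fixed = TRUE)),
                nrow = length(seqs), byrow = TRUE,
                dimnames = list(names(seqs), NULL))
  }
  m[m == "."] <- "-"
  validateAlignmentMatrix(m)
  new("ProteinAlignment", id = as.character(id), seqs = m)
}

# Shared validation that raises the classed errors named by the I/O contract
# (the S4 validity method repeats the checks but reports generically).
validateAlignmentMatrix <- function(m) {
  if (nrow(m) < 1L || ncol(m) < 1L)
    csiStop("csiEmptyInputError", "alignment has no rows or no columns")
  if (anyDuplicated(rownames(m)))
    csiStop("csiShapeError", sprintf("duplicate taxon identifier '%s'",
                                     rownames(m)[duplicated(rownames(m))][1L]))
  bad <- !(m %in% ALN_ALPHABET)
  if (any(bad)) {
    idx <- which(matrix(bad, nrow = nrow(m)), arr.ind = TRUE)[1L, ]
    csiStop("csiAlphabetError", sprintf(
      "invalid symbol '%s' in row '%s', column %d",
      m[idx[1L], idx[2L]], rownames(m)[idx[1L]], idx[2L]))
  }
  allGap <- which(colSums(m != "-") == 0L)
  if (length(allGap))
    csiStop("csiShapeError",
            sprintf("column %d consists entirely of gaps", allGap[1L]))
  invisible(m)
}

#' Read a protein multiple sequence alignment
#'
#' Reads gapped amino-acid alignments in FASTA or Clustal format. Lowercase
#' residues are normalized to uppercase and \code{.} gaps to \code{-}.
#' \code{format = "auto"} detects the format from the file content (a leading
#' \code{>} record means FASTA, a \code{CLUSTAL} header means Clustal).
#'
#' @param path input file path.
#' @param format one of \code{"auto"}, \code{"fasta"}, \code{"clustal"}.
#' @param id protein-family identifier; defaults to the file base name.
#' @return a validated [ProteinAlignment-class].
#' @export
readAlignment <- function(path, format = c("auto", "fasta", "clustal"),
                          id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path))
    csiStop("csiIOError", sprintf("file not found: %s", path))
  id <- id %||% sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  content <- lines[nzchar(trimws(lines))]
  if (!length(content))
    csiStop("csiEmptyInputError", sprintf("empty alignment file: %s", path))
  if (format == "auto") {
    format <- if (startsWith(content[1L], ">")) "fasta"
              else if (grepl("^CLUSTAL", content[1L], ignore.case = TRUE))
                "clustal"
              else csiStop("csiParseError", sprintf(
                "cannot detect alignment format of %s", path))
  }
  if (format == "fasta") {
    if (!startsWith(content[1L], ">"))
      csiStop("csiParseError", sprintf("%s is not FASTA", path))
    set <- Biostrings::readBStringSet(path)
    if (!length(set))
      csiStop("csiEmptyInputError", sprintf("no FASTA records in %s", path))
    seqs <- as.character(set)
    # taxon identifier = first whitespace-delimited token of the header
    names(seqs) <- vapply(strsplit(names(set), "[ \t]+"), `[`, "", 1L)
  } else {
    seqs <- tryCatch({
      maln <- Biostrings::readAAMultipleAlignment(path, format = "clustal")
      set <- methods::as(maln, "AAStringSet")
      structure(vapply(seq_along(set), function(i)
        as.character(set[[i]]), ""), names = names(set))
    }, error = function(e) csiStop("csiShapeError", sprintf(
      "failed to parse Clustal file %s: %s", path, conditionMessage(e))))
    return(proteinAlignment(seqs, id = id))
  }
  proteinAlignment(seqs, id = id)
}

#' Write a protein multiple sequence alignment
#'
#' Emits FASTA (wrapped at 60 columns) or Clustal format; the output is
#' re-readable by [readAlignment()] into an equal alignment.
#'
#' @param aln a [ProteinAlignment-class].
#' @param path output file path.
#' @param format \code{"fasta"} or \code{"clustal"}.
#' @return \code{path}, invisibly.
#' @export
writeAlignment <- function(aln, path, format = c("fasta", "clustal")) {
  stopifnot(is(aln, "ProteinAlignment"))
  format <- match.arg(format)
  if (nrow(aln@seqs) == 0L)
    csiStop("csiEmptyInputError", "alignment has no taxa")
  seqs <- apply(aln@seqs, 1L, paste, collapse = "")
  out <- tryCatch(file(path, "w"), error = function(e)
    csiStop("csiIOError", sprintf("cannot open %s for writing", path)),
    warning = function(w)
    csiStop("csiIOError", sprintf("cannot open %s for writing", path)))
  on.exit(close(out))
  if (format == "fasta") {
    for (tx in names(seqs)) {
      writeLines(paste0(">", tx), out)
      body <- substring(seqs[[tx]],
                        seq(1L, nchar(seqs[[tx]]), 60L),
                        pmin(seq(1L, nchar(seqs[[tx]]), 60L) + 59L,
                             nchar(seqs[[tx]])))
      writeLines(body, out)
    }
  } else {
    writeLines(c("CLUSTAL W (2.1) multiple sequence alignment", "", ""), out)
    width <- max(nchar(names(seqs))) + 4L
    L <- alnWidth(aln)
    cons <- vapply(seq_len(L), function(j) {
      col <- aln@seqs[, j]
      if (all(col != "-") && length(unique(col)) == 1L) "*" else " "
    }, "")
    for (s in seq(1L, L, 60L)) {
      e <- min(s + 59L, L)
      for (tx in names(seqs))
        writeLines(sprintf("%-*s%s", width, tx, substr(seqs[[tx]], s, e)), out)
      writeLines(c(sprintf("%-*s%s", width, "",
                           paste(cons[s:e], collapse = "")), ""), out)
    }
  }
  invisible(path)
}

#' Load a hierarchical clade-partition configuration
#'
#' Reads a YAML configuration with three sections: \code{levels} (level name
#' to a mapping of clade label to member taxa, or taxon to label), \code{outgroups}
#' (taxa never assignable as CSI carriers) and \code{candidate_clades}
#' (list of \code{level}/\code{label} pairs eligible for specificity
#' assignment). The packaged example \code{glires_partition.yaml} encodes the
#' Glires/Rodentia taxonomy used throughout the package.
#'
#' @param path YAML configuration file.
#' @return a validated [CladePartition-class].
#' @examples
#' cfg <- system.file("extdata", "glires_partition.yaml", package = "CSIscan")
#' loadCladePartition(cfg)
#' @export
loadCladePartition <- function(path) {
  if (!file.exists(path))
    csiStop("csiIOError", sprintf("file not found: %s", path))
  cfg <- tryCatch(yaml::read_yaml(path), error = function(e)
    csiStop("csiConfigError", sprintf("cannot parse %s: %s", path,
                                      conditionMessage(e))))
  for (sec in c("levels", "outgroups", "candidate_clades"))
    if (is.null(cfg[[sec]]))
      csiStop("csiConfigError", sprintf("missing '%s' section in %s", sec, path))
  levels <- lapply(cfg$levels, function(level) {
    # each level: clade label -> vector of member taxa
    maps <- unlist(lapply(names(level), function(lb) {
      members <- as.character(unlist(level[[lb]]))
      structure(rep(lb, length(members)), names = members)
    }))
    if (anyDuplicated(names(maps)))
      csiStop("csiConfigError", sprintf(
        "taxon '%s' assigned to two clades within one level",
        names(maps)[duplicated(names(maps))][1L]))
    maps
  })
  # duplicate clade label within one level
  for (lv in names(cfg$levels))
    if (anyDuplicated(names(cfg$levels[[lv]])))
      csiStop("csiConfigError", sprintf(
        "duplicate clade label '%s' within level '%s'",
        names(cfg$levels[[lv]])[duplicated(names(cfg$levels[[lv]]))][1L], lv))
  taxa <- as.character(cfg$taxa %||% unique(unlist(lapply(levels, names))))
  outgroups <- as.character(unlist(cfg$outgroups))
  unknown <- setdiff(outgroups, taxa)
  if (length(unknown))
    csiStop("csiUnknownTaxonError",
            sprintf("outgroup '%s' not among the declared taxa", unknown[1L]))
  cc <- do.call(rbind, lapply(cfg$candidate_clades, function(x)
    data.frame(level = x$level, label = x$label)))
  for (i in seq_len(nrow(cc))) {
    if (!cc$level[i] %in% names(levels))
      csiStop("csiConfigError", sprintf("candidate clade level '%s' undefined",
                                        cc$level[i]))
    members <- names(levels[[cc$level[i]]])[levels[[cc$level[i]]] == cc$label[i]]
    if (!length(members))
      csiStop("csiUnknownTaxonError", sprintf(
        "candidate clade %s/%s has no member taxa", cc$level[i], cc$label[i]))
    missing <- setdiff(members, taxa)
    if (length(missing))
      csiStop("csiUnknownTaxonError", sprintf(
        "taxon '%s' in candidate clade %s/%s absent from taxa",
        missing[1L], cc$level[i], cc$label[i]))
    if (length(intersect(members, outgroups)))
      csiStop("csiConfigError", sprintf(
        "taxon '%s' is both an outgroup and a member of %s/%s",
        intersect(members, outgroups)[1L], cc$level[i], cc$label[i]))
  }
  new("CladePartition", taxa = taxa, levels = levels,
      outgroups = outgroups, candidateClades = cc)
}

#' Construct a CladePartition in code
#'
#' @param levels named list; each element a named character vector mapping
#'   taxon to clade label at that level.
#' @param outgroups outgroup taxon identifiers.
#' @param candidateClades data.frame with columns \code{level}, \code{label}.
#' @param taxa all taxon identifiers; defaults to every taxon named in
#'   \code{levels} plus the outgroups.
#' @return a validated [CladePartition-class].
#' @export
cladePartition <- function(levels, outgroups = character(),
                           candidateClades, taxa = NULL) {
  taxa <- taxa %||% unique(c(unlist(lapply(levels, names)), outgroups))
  new("CladePartition", taxa = taxa, levels = levels,
      outgroups = as.character(outgroups),
      candidateClades = candidateClades)
}

#' Members of one clade at one level
#'
#' @param partition a [CladePartition-class].
#' @param level level name (e.g. \code{"suborder"}).
#' @param label clade label (e.g. \code{"Myomorpha"}).
#' @return character vector of member taxa (empty, with a warning, for an
#'   unknown level or label).
#' @export
cladeMembers <- function(partition, level, label) {
  stopifnot(is(partition, "CladePartition"))
  map <- partition@levels[[level]]
  if (is.null(map)) {
    csiWarn("csiUnknownCladeWarning", sprintf("unknown level '%s'", level))
    return(character())
  }
  members <- names(map)[map == label]
  if (!length(members))
    csiWarn("csiUnknownCladeWarning",
            sprintf("no taxa labelled '%s' at level '%s'", label, level))
  members
}

#' Outgroup taxa of a partition
#' @param partition a [CladePartition-class].
#' @return character vector.
#' @export
outgroupTaxa <- function(partition) {
  stopifnot(is(partition, "CladePartition"))
  partition@outgroups
}

#' Candidate clades of a partition
#' @param partition a [CladePartition-class].
#' @return data.frame with columns \code{level}, \code{label}.
#' @export
candidateClades <- function(partition) {
  stopifnot(is(partition, "CladePartition"))
  partition@candidateClades
}

#' Restrict an alignment to a subset of taxa
#'
#' Columns left entirely gapped by the subsetting are dropped with a warning.
#'
#' @param aln a [ProteinAlignment-class].
#' @param taxa taxa to keep (order preserved from \code{taxa}).
#' @return a [ProteinAlignment-class].
#' @export
subsetTaxa <- function(aln, taxa) {
  stopifnot(is(aln, "ProteinAlignment"))
  missing <- setdiff(taxa, alnTaxa(aln))
  if (length(missing))
    csiStop("csiUnknownTaxonError",
            sprintf("taxon '%s' not in alignment", missing[1L]))
  m <- aln@seqs[taxa, , drop = FALSE]
  allGap <- colSums(m != "-") == 0L
  if (any(allGap)) {
    csiWarn("csiAllGapColumnWarning", sprintf(
      "dropping %d column(s) left all-gap after subsetting", sum(allGap)))
    m <- m[, !allGap, drop = FALSE]
  }
  new("ProteinAlignment", id = aln@id, seqs = m)
}
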