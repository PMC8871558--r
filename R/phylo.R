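#' Poisson-corrected pairwise distances
#'
#' For each taxon pair, the mismatch fraction \eqn{p} over pairwise-ungapped
#' columns is corrected as \eqn{d = -\ln(1 - p)}. Every pair must share at
#' least one ungapped column. \code{X} counts as a mismatch to every residue.
#'
#' @param sm a [Supermatrix-class] (or [ProteinAlignment-class]).
#' @return a [DistanceMatrix-class] with per-pair effective column counts.
#' @export
poissonDistance <- function(sm) {
  m <- if (is(sm, "Supermatrix") || is(sm, "ProteinAlignment")) sm@seqs
       else csiStop("csiInputError", "need a Supermatrix or ProteinAlignment")
  taxa <- rownames(m)
  n <- length(taxa)
  d <- matrix(0, n, n, dimnames = list(taxa, taxa))
  shared <- matrix(0L, n, n, dimnames = list(taxa, taxa))
  diag(shared) <- as.integer(rowSums(m != "-"))
  gap <- m == "-"
  for (i in seqRange(1L, n - 1L)) for (j in seqRange(i + 1L, n)) {
    both <- !gap[i, ] & !gap[j, ]
    ns <- sum(both)
    if (ns == 0L)
      csiStop("csiCoverageError", sprintf(
        "taxa '%s' and '%s' share no ungapped columns", taxa[i], taxa[j]))
    mism <- m[i, both] != m[j, both] | m[i, both] == "X" | m[j, both] == "X"
    p <- sum(mism) / ns
    dij <- -log(1 - p)
    d[i, j] <- d[j, i] <- dij
    shared[i, j] <- shared[j, i] <- ns
  }
  new("DistanceMatrix", taxa = taxa, d = d, sharedSites = shared)
}

#' Neighbor-joining tree
#'
#' Standard neighbor joining (Q-criterion agglomeration, via
#' \code{\link[ape]{nj}}) on a distance matrix; negative branch lengths are
#' clamped to zero with a message. The result is unrooted.
#'
#' @param dm a [DistanceMatrix-class] or a plain symmetric numeric matrix
#'   with dimnames.
#' @return an unrooted \code{\link[ape]{read.tree}}-style \code{phylo} tree.
#' @export
neighborJoining <- function(dm) {
  d <- if (is(dm, "DistanceMatrix")) dm@d else as.matrix(dm)
  if (nrow(d) < 3L)
    csiStop("csiInputError", "neighbor joining needs at least 3 taxa")
  tree <- ape::nj(d)
  neg <- tree$edge.length < 0
  if (any(neg)) {
    message(sprintf("clamped %d negative branch length(s) to 0", sum(neg)))
    tree$edge.length[neg] <- 0
  }
  tree
}

# Canonical key of one bipartition of `tips`: the sorted side not containing
# the alphabetically first tip.
bipartitionKey <- function(side, tips) {
  anchor <- min(tips)
  if (anchor %in% side) side <- setdiff(tips, side)
  paste(sort(side), collapse = "|")
}

#' Internal-edge bipartitions of a tree
#'
#' Each internal edge splits the taxon set in two; the split is reported as a
#' canonical string key (the sorted side not containing the alphabetically
#' first tip). Trivial splits (single tips) are excluded.
#'
#' @param tree a \code{phylo} tree (rooted or unrooted).
#' @return character vector of bipartition keys.
#' @export
treeBipartitions <- function(tree) {
  tips <- tree$tip.label
  n <- length(tips)
  parts <- ape::prop.part(tree)
  keys <- vapply(parts, function(idx) bipartitionKey(tips[idx], tips), "")
  sizes <- vapply(parts, length, 0L)
  unique(keys[sizes > 1L & sizes < n - 1L & nzchar(keys)])
}

#' Neighbor-joining tree with bootstrap support
#'
#' Resamples supermatrix columns with replacement \code{nReps} times,
#' rebuilds the tree from Poisson-corrected distances for each replicate, and
#' annotates every internal edge of the full-data tree with the percentage of
#' replicate trees containing its bipartition. Seeded and reproducible:
#' identical seeds give identical supports.
#'
#' @param sm a [Supermatrix-class].
#' @param nReps bootstrap replicates (>= 1).
#' @param seed integer RNG seed.
#' @return an unrooted \code{phylo} tree whose \code{node.label} holds
#'   supports in [0, 100] on internal nodes (\code{""} elsewhere).
#' @export
bootstrapSupport <- function(sm, nReps = 100L, seed = 1L) {
  stopifnot(is(sm, "Supermatrix"))
  if (nReps < 1L) csiStop("csiInputError", "nReps must be >= 1")
  full <- neighborJoining(poissonDistance(sm))
  refKeys <- treeBipartitions(full)
  counts <- setNames(numeric(length(refKeys)), refKeys)
  L <- ncol(sm@seqs)
  set.seed(seed)
  for (r in seq_len(nReps)) {
    cols <- sample.int(L, L, replace = TRUE)
    rep.sm <- new("Supermatrix", taxa = sm@taxa,
                  seqs = sm@seqs[, cols, drop = FALSE],
                  partitionMap = data.frame(protein = "resampled", start = 1L,
                                            end = L))
    repTree <- neighborJoining(poissonDistance(rep.sm))
    hits <- intersect(refKeys, treeBipartitions(repTree))
    counts[hits] <- counts[hits] + 1
  }
  support <- 100 * counts / nReps
  annotateSupports(full, support)
}

# Write a support map (bipartition key -> percentage) onto node labels.
annotateSupports <- function(tree, support) {
  tips <- tree$tip.label
  n <- length(tips)
  nNode <- tree$Nnode
  labels <- character(nNode)
  parts <- ape::prop.part(tree)   # parts[[k]] = tips under internal node n+k
  for (k in seq_len(nNode)) {
    side <- tips[parts[[k]]]
    sz <- length(side)
    if (sz <= 1L || sz >= n - 1L) { labels[k] <- ""; next }  # trivial split
    key <- bipartitionKey(side, tips)
    labels[k] <- if (key %in% names(support))
      format(support[[key]], trim = TRUE) else ""
  }
  tree$node.label <- labels
  tree
}

#' Root a tree on a designated outgroup
#'
#' Places the root at the midpoint of the edge subtending the outgroup leaf.
#' Bootstrap supports are preserved on the corresponding bipartitions
#' (recomputed from the unrooted support map, which rooting cannot change).
#'
#' @param tree a \code{phylo} tree (optionally with support node labels).
#' @param outgroup outgroup taxon identifier (a tip of \code{tree}).
#' @return a rooted \code{phylo} tree; the outgroup is a child of the root.
#' @export
rootTree <- function(tree, outgroup) {
  if (!outgroup %in% tree$tip.label)
    csiStop("csiInputError", sprintf("unknown taxon '%s'", outgroup))
  supports <- supportMap(tree)
  tip <- which(tree$tip.label == outgroup)
  edge <- which(tree$edge[, 2L] == tip)
  len <- tree$edge.length[edge]
  rooted <- phytools::reroot(tree, tip, position = len / 2)
  annotateSupports(rooted, supports)
}

# Extract bipartition key -> support from node labels (empty map if none).
supportMap <- function(tree) {
  if (is.null(tree$node.label)) return(setNames(numeric(), character()))
  tips <- tree$tip.label
  parts <- ape::prop.part(tree)
  keys <- vapply(parts, function(idx) bipartitionKey(tips[idx], tips), "")
  val <- suppressWarnings(as.numeric(tree$node.label))
  ok <- !is.na(val)
  setNames(val[ok], keys[ok])
}

#' Read and write newick trees
#'
#' Thin wrappers over \code{\link[ape]{read.tree}} and
#' \code{\link[ape]{write.tree}} with a structural pre-check that reports the
#' character position of unbalanced parentheses or a missing terminal
#' semicolon. Internal node labels carry bootstrap supports.
#'
#' @param text newick string (or \code{file}).
#' @param file file to read from / write to.
#' @param tree a \code{phylo} tree.
#' @return \code{readNewick}: a \code{phylo} tree. \code{writeNewick}: the
#'   newick string, invisibly when written to a file.
#' @export
readNewick <- function(text = NULL, file = NULL) {
  if (is.null(text)) {
    if (is.null(file)) csiStop("csiInputError", "supply 'text' or 'file'")
    text <- paste(readLines(file, warn = FALSE), collapse = "")
  }
  chars <- strsplit(text, "")[[1L]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (depth < 0L)
      csiStop("csiParseError",
              sprintf("unbalanced ')' at position %d", i))
  }
  if (depth != 0L)
    csiStop("csiParseError", sprintf(
      "unbalanced '(': %d unclosed at end of input", depth))
  if (!grepl(";\\s*$", text))
    csiStop("csiParseError",
            sprintf("missing ';' at position %d", length(chars)))
  tree <- tryCatch(ape::read.tree(text = text), error = function(e)
    csiStop("csiParseError", conditionMessage(e)))
  if (is.null(tree))
    csiStop("csiParseError", "not a parseable newick string")
  tree
}

#' @rdname readNewick
#' @export
writeNewick <- function(tree, file = NULL) {
  txt <- ape::write.tree(tree)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' Desk-scale supermatrix phylogeny pipeline
#'
#' Concatenates per-protein alignments, trims poorly conserved blocks,
#' applies the site-coverage filter, and builds a bootstrap-supported
#' neighbor-joining tree from Poisson-corrected distances, rooted on the
#' designated outgroup. Deterministic: the same inputs and seed give a
#' byte-identical newick string.
#'
#' @param alignments list of [ProteinAlignment-class].
#' @param outgroup taxon used to root the final tree (NULL leaves it unrooted).
#' @param nReps bootstrap replicates.
#' @param seed integer RNG seed.
#' @param trim a [TrimParams-class].
#' @param taxa optional ordered taxon list for concatenation.
#' @return list with \code{tree} (\code{phylo}), \code{supermatrix} (the
#'   filtered [Supermatrix-class]) and \code{trimReport}.
#' @export
supermatrixTree <- function(alignments, outgroup = NULL, nReps = 100L,
                            seed = 1L, trim = trimParams(), taxa = NULL) {
  sm <- concatenateAlignments(alignments, taxa = taxa)
  tr <- trimBlocks(sm, trim)
  sm2 <- filterSiteCoverage(tr$supermatrix, trim@minSiteCoverage)
  tree <- bootstrapSupport(sm2, nReps = nReps, seed = seed)
  if (!is.null(outgroup)) tree <- rootTree(tree, outgroup)
  list(tree = tree, supermatrix = sm2, trimReport = tr$report)
}
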