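#' Simulation parameters
#'
#' Conditions for the synthetic protein-family generator. Defaults emulate
#' the study conditions of the CSI screen: families of single-copy proteins
#' a few hundred residues long over a 35-taxon Glires-like tree, per-branch
#' substitution noise at most a few percent per site, and half the sites
#' constrained (never substituted) so that conserved flanks exist.
#'
#' @param families number of protein families (default 50).
#' @param length ancestral sequence length in residues (default 300; must be
#'   at least twice the flank window plus the largest indel).
#' @param substitution per-site, per-branch substitution probability in
#'   [0, 1) (default 0.05, the upper end of realistic desk-scale noise).
#' @param conservedFraction fraction of sites never substituted (default 0.5).
#' @param lossProb probability that a planted event carries one secondarily
#'   lacking lineage, the \emph{Jaculus jaculus} pattern (default 0.1).
#' @param raggedProb probability that a family carries a ragged-length decoy
#'   (default 0.15).
#' @param homoplasyProb probability that a family carries a homoplastic decoy
#'   (identical-coordinate indel planted independently on one non-clade
#'   terminal branch; default 0.15).
#' @return a list of class \code{"SimulationParams"}.
#' @export
simulationParams <- function(families = 50L, length = 300L,
                             substitution = 0.05, conservedFraction = 0.5,
                             lossProb = 0.1, raggedProb = 0.15,
                             homoplasyProb = 0.15) {
  if (substitution < 0 || substitution >= 1)
    csiStop("csiInputError", "substitution must be in [0, 1)")
  if (conservedFraction < 0 || conservedFraction > 1)
    csiStop("csiInputError", "conservedFraction must be in [0, 1]")
  if (length < 2L * 45L + 30L)
    csiStop("csiInputError",
            "sequence length too short for flank windows plus an indel")
  structure(list(families = as.integer(families), length = as.integer(length),
                 substitution = substitution,
                 conservedFraction = conservedFraction, lossProb = lossProb,
                 raggedProb = raggedProb, homoplasyProb = homoplasyProb),
            class = "SimulationParams")
}

# ---- the Glires-like species scenario -------------------------------------

gliresTaxonomy <- function() {
  list(
    Muridae = c("Mus_musculus", "Rattus_norvegicus", "Rattus_rattus",
                "Apodemus_speciosus", "Arvicanthis_niloticus"),
    Cricetidae = c("Mesocricetus_auratus", "Cricetulus_griseus",
                   "Peromyscus_leucopus", "Microtus_ochrogaster",
                   "Ondatra_zibethicus"),
    Spalacidae = c("Nannospalax_galili", "Rhizomys_pruinosus"),
    Dipodoidea = "Jaculus_jaculus",
    Castorimorpha = c("Castor_canadensis", "Dipodomys_ordii"),
    Sciuromorpha = c("Ictidomys_tridecemlineatus", "Marmota_marmota",
                     "Sciurus_vulgaris", "Urocitellus_parryii", "Glis_glis",
                     "Graphiurus_murinus"),
    Hystricomorpha = c("Cavia_porcellus", "Chinchilla_lanigera",
                       "Octodon_degus", "Heterocephalus_glaber",
                       "Fukomys_damarensis"),
    Lagomorpha = c("Oryctolagus_cuniculus", "Lepus_europaeus",
                   "Sylvilagus_floridanus", "Ochotona_princeps"),
    Primates = c("Homo_sapiens", "Pan_troglodytes", "Macaca_mulatta"),
    Scandentia = "Tupaia_chinensis",
    Dermoptera = "Galeopterus_variegatus")
}

gliresNewick <- function() {
  tx <- gliresTaxonomy()
  cl <- function(members, bl) paste0(
    "(", paste0(members, ":", bl, collapse = ","), ")")
  muroidea <- paste0("(", cl(tx$Muridae, 0.06), ":0.05,",
                     cl(tx$Cricetidae, 0.06), ":0.05):0.03,",
                     cl(tx$Spalacidae, 0.08), ":0.05")
  myomorpha <- paste0("((", muroidea, "):0.04,", tx$Dipodoidea, ":0.14)")
  rodentia <- paste0("(((", myomorpha, ":0.05,",
                     cl(tx$Castorimorpha, 0.1), ":0.07):0.03,",
                     cl(tx$Hystricomorpha, 0.08), ":0.06):0.02,",
                     cl(tx$Sciuromorpha, 0.07), ":0.06)")
  glires <- paste0("(", rodentia, ":0.05,", cl(tx$Lagomorpha, 0.09), ":0.08)")
  euarchonta <- paste0("((", cl(tx$Primates, 0.04), ":0.04,",
                       tx$Dermoptera, ":0.09):0.02,",
                       tx$Scandentia, ":0.1)")
  paste0("(", glires, ":0.06,", euarchonta, ":0.06);")
}

#' The packaged Glires-like species scenario
#'
#' A fixed 35-taxon labelled species tree (30 Glires: the four Rodentia
#' suborders with nested Myomorpha families, plus Lagomorpha; and five
#' Euarchonta outgroups), together with the matching hierarchical clade
#' partition. Clades are monophyletic on the tree.
#'
#' @return list with \code{tree} (a \code{phylo}), \code{partition}
#'   (a [CladePartition-class]) and \code{outgroups}.
#' @export
gliresScenario <- function() {
  tx <- gliresTaxonomy()
  lab <- function(groups) {
    out <- unlist(lapply(names(groups), function(g)
      structure(rep(g, length(groups[[g]])), names = groups[[g]])))
    out
  }
  myo <- c(tx$Muridae, tx$Cricetidae, tx$Spalacidae, tx$Dipodoidea)
  rodentia <- c(myo, tx$Castorimorpha, tx$Sciuromorpha, tx$Hystricomorpha)
  glires <- c(rodentia, tx$Lagomorpha)
  levels <- list(
    grandorder = lab(list(Glires = glires,
                          Euarchonta = c(tx$Primates, tx$Scandentia,
                                         tx$Dermoptera))),
    order = lab(list(Rodentia = rodentia, Lagomorpha = tx$Lagomorpha,
                     Primates = tx$Primates, Scandentia = tx$Scandentia,
                     Dermoptera = tx$Dermoptera)),
    suborder = lab(list(Myomorpha = myo, Castorimorpha = tx$Castorimorpha,
                        Sciuromorpha = tx$Sciuromorpha,
                        Hystricomorpha = tx$Hystricomorpha)),
    superfamily = lab(list(Muroidea = c(tx$Muridae, tx$Cricetidae,
                                        tx$Spalacidae))),
    family = lab(tx[c("Muridae", "Cricetidae", "Spalacidae", "Dipodoidea")]))
  outgroups <- c(tx$Primates, tx$Scandentia, tx$Dermoptera)
  cc <- data.frame(
    level = c("grandorder", "order", "order", "suborder", "suborder",
              "suborder", "suborder", "superfamily", "family", "family"),
    label = c("Glires", "Rodentia", "Lagomorpha", "Myomorpha",
              "Castorimorpha", "Sciuromorpha", "Hystricomorpha", "Muroidea",
              "Muridae", "Cricetidae"))
  partition <- cladePartition(levels, outgroups, cc)
  tree <- readNewick(gliresNewick())
  list(tree = tree, partition = partition, outgroups = outgroups)
}

# ---- evolution engine ------------------------------------------------------

# Substitute: each position in `sites` mutates independently with prob p to a
# uniformly drawn different residue. Returns list(seq, nSub).
mutateBranch <- function(seq, sites, p) {
  if (!length(sites) || p <= 0) return(list(seq = seq, nSub = 0L))
  hit <- sites[stats::runif(length(sites)) < p]
  for (s in hit) {
    seq[s] <- sample(setdiff(AA_LETTERS, seq[s]), 1L)
  }
  list(seq = seq, nSub = length(hit))
}

# Simulate tip sequences down `tree` from `root` sequence; `free` are the
# unconstrained site indices. Returns list(tips = named list, nSub, nTrials).
simulateTips <- function(tree, root, free, p) {
  nTip <- length(tree$tip.label)
  rootNode <- nTip + 1L
  seqs <- vector("list", nTip + tree$Nnode)
  seqs[[rootNode]] <- root
  nSub <- 0L; nTrials <- 0L
  ord <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(ord$edge))) {
    parent <- ord$edge[e, 1L]; child <- ord$edge[e, 2L]
    res <- mutateBranch(seqs[[parent]], free, p)
    seqs[[child]] <- res$seq
    nSub <- nSub + res$nSub
    nTrials <- nTrials + length(free)
  }
  tips <- seqs[seq_len(nTip)]
  names(tips) <- tree$tip.label
  list(tips = tips, nSub = nSub, nTrials = nTrials)
}

#' Evolve one protein family with planted indels
#'
#' Draws a root sequence uniformly over the 20 residues, applies per-branch
#' substitutions at the nominal rate (constrained sites never substituted),
#' and applies each indel plan on the target clade's ancestral branch: an
#' insertion adds columns gapped outside the clade, a deletion gaps the clade
#' across existing columns. Loss taxa have the event reverted on their
#' terminal branch. Decoys are applied as flagged: a homoplastic decoy copies
#' the event onto one non-clade, non-outgroup terminal branch; a ragged decoy
#' plants the event with lengths differing among clade members. The true
#' alignment is emitted directly (no realignment step).
#'
#' @param scenario a scenario list from [gliresScenario()].
#' @param params a [simulationParams()] object.
#' @param plans data.frame of indel plans with columns \code{level},
#'   \code{clade}, \code{position} (ancestral coordinate), \code{length},
#'   \code{kind} (\code{"insertion"}/\code{"deletion"}), and optionally
#'   \code{lossTaxa} (comma-separated), \code{decoy} (\code{"none"},
#'   \code{"homoplastic"}, \code{"ragged"}), \code{extraTaxon}.
#' @param seed integer RNG seed.
#' @param id protein-family identifier.
#' @return list with \code{alignment} (a [ProteinAlignment-class]),
#'   \code{truth} (data.frame with final alignment coordinates),
#'   \code{nSubstitutions} and \code{nTrials} (for rate checks).
#' @export
evolveFamily <- function(scenario, params = simulationParams(), plans = NULL,
                         seed = 1L, id = "family") {
  set.seed(seed)
  tree <- scenario$tree
  partition <- scenario$partition
  taxa <- tree$tip.label
  L <- params$length
  if (is.null(plans))
    plans <- data.frame(level = character(), clade = character(),
                        position = integer(), length = integer(),
                        kind = character())
  if (nrow(plans)) {
    if (is.null(plans$lossTaxa)) plans$lossTaxa <- ""
    if (is.null(plans$decoy)) plans$decoy <- "none"
    if (is.null(plans$extraTaxon)) plans$extraTaxon <- ""
    bad <- plans$position < 1L | plans$position + plans$length > L
    if (any(bad))
      csiStop("csiPlanError", sprintf(
        "plan %d: position %d + length %d exceeds sequence bounds",
        which(bad)[1L], plans$position[which(bad)[1L]],
        plans$length[which(bad)[1L]]))
    if (any(plans$length < 1L))
      csiStop("csiPlanError", "indel length must be >= 1")
  }
  nCons <- round(params$conservedFraction * L)
  conserved <- sort(sample.int(L, nCons))
  free <- setdiff(seq_len(L), conserved)
  root <- sample(AA_LETTERS, L, replace = TRUE)
  sim <- simulateTips(tree, root, free, params$substitution)
  tips <- sim$tips

  # carriers per plan (in ancestral-coordinate space)
  planInfo <- lapply(seq_len(nrow(plans)), function(i) {
    p <- plans[i, ]
    members <- intersect(cladeMembers(partition, p$level, p$clade), taxa)
    loss <- if (nzchar(p$lossTaxa))
      strsplit(p$lossTaxa, ",", fixed = TRUE)[[1L]] else character()
    if (length(setdiff(loss, members)))
      csiStop("csiPlanError", "loss taxa must belong to the target clade")
    carriers <- setdiff(members, loss)
    extra <- if (identical(p$decoy, "homoplastic")) {
      if (nzchar(p$extraTaxon)) p$extraTaxon else
        sample(setdiff(taxa, c(members, partition@outgroups)), 1L)
    } else character()
    ragged <- identical(p$decoy, "ragged")
    # ragged: half the carriers take length len, the rest len + 1
    longSet <- if (ragged)
      carriers[seq_len(ceiling(length(carriers) / 2))] else character()
    list(kind = p$kind, position = p$position, length = p$length,
         clade = p$clade, level = p$level, carriers = carriers,
         loss = loss, extra = if (length(extra)) extra else character(),
         ragged = ragged, longSet = longSet, decoy = p$decoy)
  })

  # column layout: base columns 1..L plus inserted blocks (footprint length)
  layout <- lapply(seq_len(L), function(j) list(type = "base", pos = j))
  insPlans <- which(vapply(planInfo, function(x) x$kind == "insertion", TRUE))
  if (length(insPlans)) {
    ord <- insPlans[order(vapply(planInfo[insPlans], `[[`, 0L, "position"),
                          decreasing = TRUE)]
    for (i in ord) {
      info <- planInfo[[i]]
      foot <- info$length + as.integer(info$ragged)
      at <- which(vapply(layout, function(c)
        c$type == "base" && c$pos == info$position, TRUE))
      block <- lapply(seq_len(foot), function(k)
        list(type = "ins", plan = i, offset = k))
      layout <- append(layout, block, after = at)
    }
  }
  nColsF <- length(layout)

  # inserted residues: drawn at the event ancestor, then one extra round of
  # per-carrier substitution noise within the subtree
  insResid <- lapply(planInfo, function(info) {
    if (info$kind != "insertion") return(NULL)
    foot <- info$length + as.integer(info$ragged)
    anc <- sample(AA_LETTERS, foot, replace = TRUE)
    carr <- c(info$carriers, info$extra)
    out <- lapply(carr, function(tx)
      mutateBranch(anc, seq_len(foot), params$substitution)$seq)
    names(out) <- carr
    out
  })

  m <- matrix("-", nrow = length(taxa), ncol = nColsF,
              dimnames = list(taxa, NULL))
  types <- vapply(layout, `[[`, "", "type")
  basePos <- vapply(layout, function(c) if (c$type == "base") c$pos else NA_integer_, 0L)
  baseIdx <- which(types == "base")
  for (tx in taxa) m[tx, baseIdx] <- tips[[tx]][basePos[baseIdx]]

  for (i in seq_along(planInfo)) {
    info <- planInfo[[i]]
    if (info$kind == "deletion") {
      delLen <- function(tx) info$length +
        as.integer(info$ragged && tx %in% info$longSet)
      for (tx in c(info$carriers, info$extra)) {
        cols <- basePos %in% seqRange(info$position,
                                      info$position + delLen(tx) - 1L)
        m[tx, which(cols)] <- "-"
      }
    } else {
      insCols <- which(types == "ins" &
                       vapply(layout, function(c)
                         !is.null(c$plan) && c$plan == i, TRUE))
      offsets <- vapply(layout[insCols], `[[`, 0L, "offset")
      for (tx in c(info$carriers, info$extra)) {
        width <- info$length + as.integer(info$ragged && tx %in% info$longSet)
        use <- insCols[offsets <= width]
        m[tx, use] <- insResid[[i]][[tx]][offsets[offsets <= width]]
      }
    }
  }

  truth <- do.call(rbind, lapply(seq_along(planInfo), function(i) {
    info <- planInfo[[i]]
    foot <- info$length + as.integer(info$ragged)
    if (info$kind == "insertion") {
      cols <- which(types == "ins" & vapply(layout, function(c)
        !is.null(c$plan) && c$plan == i, TRUE))
    } else {
      cols <- which(basePos %in% seqRange(info$position,
                                          info$position + foot - 1L))
    }
    data.frame(family = id, start = min(cols), end = max(cols),
               length = info$length, kind = info$kind, level = info$level,
               clade = info$clade,
               losses = paste(info$loss, collapse = ","),
               decoy = info$decoy)
  }))
  if (is.null(truth))
    truth <- data.frame(family = character(), start = integer(),
                        end = integer(), length = integer(),
                        kind = character(), level = character(),
                        clade = character(), losses = character(),
                        decoy = character())
  aln <- new("ProteinAlignment", id = id, seqs = m)
  validObject(aln)
  list(alignment = aln, truth = truth,
       nSubstitutions = sim$nSub, nTrials = sim$nTrials)
}

#' Generate a full synthetic study: families, truth table, partition, tree
#'
#' Builds the packaged 35-taxon Glires-like scenario and simulates
#' \code{nFamilies} protein families, each carrying 0-2 planted
#' clade-ancestral indel events across clade levels plus ragged and
#' homoplastic decoys at the configured frequencies; some events carry one
#' secondarily lacking lineage. Everything needed to run [detectCsis()]
#' end-to-end is returned. Deterministic under a fixed seed.
#'
#' @param nFamilies number of families (default \code{params$families}).
#' @param params a [simulationParams()] object.
#' @param seed integer RNG seed.
#' @return list with \code{families} (list of [ProteinAlignment-class]),
#'   \code{truth} (data.frame), \code{partition}, \code{tree}.
#' @export
generateScenario <- function(nFamilies = NULL, params = simulationParams(),
                             seed = 1L) {
  scenario <- gliresScenario()
  partition <- scenario$partition
  nFamilies <- as.integer(nFamilies %||% params$families)
  if (nFamilies < 1L) csiStop("csiInputError", "nFamilies must be >= 1")
  set.seed(seed)
  famSeeds <- sample.int(.Machine$integer.max, nFamilies)
  cc <- partition@candidateClades
  # plantable clades: enough members that one exception still leaves the
  # per-clade carrier minimum (Castorimorpha covered by its shipped profile)
  sizes <- vapply(seq_len(nrow(cc)), function(i)
    length(cladeMembers(partition, cc$level[i], cc$label[i])), 0L)
  cladeSets <- lapply(seq_len(nrow(cc)), function(i)
    cladeMembers(partition, cc$level[i], cc$label[i]))
  # a carrier set coinciding with a *different* candidate clade's membership
  # is irreducibly ambiguous (e.g. Myomorpha minus its sole Dipodoidea
  # lineage equals Muroidea); such events are not planted as truth
  confusable <- function(carrierSet, ownIdx)
    any(vapply(seq_along(cladeSets), function(j)
      j != ownIdx && setequal(cladeSets[[j]], carrierSet), TRUE))
  L <- params$length
  margin <- 50L    # keeps every event clear of the edges and of each other
  families <- vector("list", nFamilies)
  truths <- vector("list", nFamilies)
  for (f in seq_len(nFamilies)) {
    nEvents <- sample(0:2, 1L, prob = c(0.3, 0.5, 0.2))
    nSlots <- nEvents + 2L   # reserve slots for possible decoys
    positions <- margin + (seq_len(nSlots) - 1L) * ((L - 2L * margin) %/% nSlots) +
      sample.int(20L, nSlots) - 10L
    slot <- 0L
    plans <- list()
    addPlan <- function(decoy) {
      slot <<- slot + 1L
      eligible <- seq_len(nrow(cc))
      if (decoy == "homoplastic") {
        # needs a non-clade, non-outgroup terminal branch to plant on
        eligible <- eligible[vapply(eligible, function(i)
          length(setdiff(partition@taxa,
                         c(cladeSets[[i]], partition@outgroups))) > 0L, TRUE)]
      }
      ci <- sample(eligible, 1L)
      members <- cladeSets[[ci]]
      len <- sample(1:5, 1L, prob = c(0.4, 0.25, 0.15, 0.1, 0.1))
      kind <- sample(c("insertion", "deletion"), 1L)
      loss <- ""
      if (decoy == "none" && stats::runif(1) < params$lossProb &&
          sizes[ci] >= 4L) {
        okLoss <- Filter(function(tx) !confusable(setdiff(members, tx), ci),
                         members)
        if (length(okLoss)) loss <- sample(okLoss, 1L)
      }
      extra <- ""
      if (decoy == "homoplastic") {
        pool <- setdiff(partition@taxa, c(members, partition@outgroups))
        okExtra <- Filter(function(tx) !confusable(c(members, tx), ci), pool)
        extra <- sample(okExtra, 1L)
      }
      plans[[length(plans) + 1L]] <<- data.frame(
        level = cc$level[ci], label = cc$label[ci], position = positions[slot],
        length = len, kind = kind, lossTaxa = loss, decoy = decoy,
        extraTaxon = extra)
    }
    for (k in seqRange(1L, nEvents)) addPlan("none")
    if (stats::runif(1) < params$raggedProb) addPlan("ragged")
    if (stats::runif(1) < params$homoplasyProb) addPlan("homoplastic")
    plans <- if (length(plans)) do.call(rbind, plans) else NULL
    if (!is.null(plans)) names(plans)[names(plans) == "label"] <- "clade"
    fam <- evolveFamily(scenario, params, plans, seed = famSeeds[f],
                        id = sprintf("family%03d", f))
    families[[f]] <- fam$alignment
    truths[[f]] <- fam$truth
  }
  truth <- do.call(rbind, truths)
  list(families = families, truth = truth, partition = partition,
       tree = scenario$tree)
}

#' Score detection output against the simulation truth table
#'
#' A call matches a truth record when it has the same family, overlapping
#' columns, the same length and the same clade label. Precision is computed
#' over all calls and recall over non-decoy truth records (decoy records are
#' planted distractors that a correct detector must not call). With zero
#' calls, precision is reported as 1.0 with a zero-denominator flag.
#'
#' @param calls data.frame as from [csiTable()], with a \code{family} column
#'   (see \code{family} argument), or a named list of per-family call lists.
#' @param truth truth data.frame from [generateScenario()].
#' @return list with \code{precision}, \code{recall},
#'   \code{polarityAccuracy} (over matched pairs), \code{confusion}
#'   (per-clade table of planted vs recovered counts),
#'   \code{zeroDenominator} flags.
#' @export
scoreDetection <- function(calls, truth) {
  if (is.list(calls) && !is.data.frame(calls)) {
    tabs <- lapply(names(calls), function(f) {
      tb <- csiTable(calls[[f]])
      if (nrow(tb)) tb$family <- f
      tb
    })
    calls <- do.call(rbind, tabs[vapply(tabs, nrow, 0L) > 0L])
    if (is.null(calls)) calls <- data.frame()
  }
  positives <- truth[truth$decoy == "none", , drop = FALSE]
  nCalls <- if (nrow(calls)) nrow(calls) else 0L
  matchedCalls <- logical(nCalls)
  matchedTruth <- logical(nrow(positives))
  polarityHits <- logical(0)
  if (nCalls) {
    for (t in seq_len(nrow(positives))) {
      tr <- positives[t, ]
      hit <- which(!matchedCalls &
                   calls$family == tr$family &
                   calls$clade == tr$clade &
                   calls$sizeAa == tr$length &
                   calls$start <= tr$end & calls$end >= tr$start)
      if (length(hit)) {
        matchedCalls[hit[1L]] <- TRUE
        matchedTruth[t] <- TRUE
        polarityHits <- c(polarityHits, identical(
          calls$type[hit[1L]], c(insertion = "Ins", deletion = "Del")[tr$kind][[1L]]))
      }
    }
  }
  zeroCalls <- nCalls == 0L
  zeroTruth <- nrow(positives) == 0L
  precision <- if (zeroCalls) 1.0 else mean(matchedCalls)
  recall <- if (zeroTruth) 1.0 else mean(matchedTruth)
  polarityAccuracy <- if (length(polarityHits)) mean(polarityHits) else NA_real_
  confusion <- if (nrow(positives))
    stats::aggregate(matchedTruth,
                     by = list(clade = positives$clade),
                     FUN = function(x) c(planted = length(x),
                                         recovered = sum(x)))
  else data.frame()
  list(precision = precision, recall = recall,
       polarityAccuracy = polarityAccuracy, confusion = confusion,
       zeroDenominator = c(calls = zeroCalls, truth = zeroTruth))
}
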