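#' Simulation parameters
#'
#' Bundles the knobs of the synthetic index-hopping benchmark.  The
#' defaults describe the reference scenario: 4 sites of 6 samples plus 4
#' blank index combinations, 50 species carrying 3 ASVs each (150 genuine
#' ASVs), mean sequencing depth 5e4 reads per sample, a 2% per-read hop
#' probability and 50 spurious single-observation error ASVs.
#'
#' @param nSites number of sites (groups).
#' @param samplesPerSite samples per site.
#' @param nBlanks unused index combinations (blank samples).
#' @param nSpecies number of true species.
#' @param asvsPerSpecies intragenomic/intraspecific ASVs per species;
#'   `nSpecies * asvsPerSpecies` genuine ASVs in total.
#' @param meanDepth expected reads per used sample.
#' @param abundanceLogmean,abundanceLogsd lognormal parameters of
#'   species relative abundance (log scale).
#' @param occupancy probability a species occurs at a site.
#' @param nestedSites if `TRUE`, site communities are nested subsets of a
#'   fixed species ranking (poorer sites inside richer ones) instead of
#'   independent occupancy draws.
#' @param pJump per-read probability of hopping to another index
#'   combination (used or blank, uniform over destinations).
#' @param nErrorAsvs number of spurious sequencing-error ASVs injected,
#'   each in exactly one combination.
#' @param errorReadP geometric parameter of spurious read counts
#'   (`reads = 1 + Geometric(p)`): most errors are tiny, a heavy tail
#'   exists.
#' @param dWithin,dBetween,seqLength sequence-simulation targets: maximum
#'   intra-species and minimum inter-species p-distance, and alignment
#'   length.
#' @param seed RNG seed (mandatory for any stochastic call).
#' @return a `SimParams` list.
#' @export
simParams <- function(nSites = 4, samplesPerSite = 6, nBlanks = 4,
                      nSpecies = 50, asvsPerSpecies = 3,
                      meanDepth = 5e4, abundanceLogmean = 0,
                      abundanceLogsd = 1.5, occupancy = 0.6,
                      nestedSites = FALSE, pJump = 0.02,
                      nErrorAsvs = 50, errorReadP = 0.3,
                      dWithin = 0.01, dBetween = 0.08, seqLength = 400,
                      seed = 42) {
  p <- list(
    nSites = .assertCount(nSites, "nSites"),
    samplesPerSite = .assertCount(samplesPerSite, "samplesPerSite"),
    nBlanks = .assertCount(nBlanks, "nBlanks"),
    nSpecies = .assertCount(nSpecies, "nSpecies"),
    asvsPerSpecies = .assertCount(asvsPerSpecies, "asvsPerSpecies"),
    meanDepth = as.numeric(meanDepth),
    abundanceLogmean = as.numeric(abundanceLogmean),
    abundanceLogsd = as.numeric(abundanceLogsd),
    occupancy = .assertProb(occupancy, "occupancy"),
    nestedSites = isTRUE(nestedSites),
    pJump = .assertProb(pJump, "pJump"),
    nErrorAsvs = .assertCount(nErrorAsvs, "nErrorAsvs", min = 0L),
    errorReadP = .assertProb(errorReadP, "errorReadP"),
    dWithin = as.numeric(dWithin),
    dBetween = as.numeric(dBetween),
    seqLength = .assertCount(seqLength, "seqLength"),
    seed = .assertCount(seed, "seed", min = 0L))
  if (p$meanDepth <= 0) .inputError("meanDepth must be positive")
  class(p) <- "SimParams"
  p
}

.asvIds <- function(params) {
  sprintf("ASV_s%03d_a%d",
          rep(seq_len(params$nSpecies), each = params$asvsPerSpecies),
          rep(seq_len(params$asvsPerSpecies), times = params$nSpecies))
}

.sampleMeta <- function(params) {
  sites <- sprintf("Site%d", seq_len(params$nSites))
  used <- data.frame(
    sample_id = sprintf("%s_S%d",
                        rep(sites, each = params$samplesPerSite),
                        rep(seq_len(params$samplesPerSite),
                            times = params$nSites)),
    is_blank = FALSE,
    group = rep(sites, each = params$samplesPerSite))
  blanks <- data.frame(
    sample_id = sprintf("Blank%d", seq_len(params$nBlanks)),
    is_blank = TRUE, group = NA_character_)
  rbind(used, blanks)
}

#' Simulate a site-structured true community table
#'
#' Species occupy sites with probability `occupancy` (or as nested
#' subsets of an abundance ranking when `nestedSites = TRUE`); all ASVs
#' of an occupying species are present at that site.  Within a sample,
#' expected reads are proportional to lognormal species abundance times
#' the sample depth, realised as independent Poisson draws per cell.
#' Blank samples receive zero true reads.
#'
#' @param params a [simParams()] list.
#' @param seed RNG seed (defaults to `params$seed`).
#' @return an [ObservationTable-class] of genuine observations only.
#' @export
simulateCommunity <- function(params, seed = params$seed) {
  stopifnot(inherits(params, "SimParams"))
  set.seed(seed)
  meta <- .sampleMeta(params)
  asvs <- .asvIds(params)
  spOf <- rep(seq_len(params$nSpecies), each = params$asvsPerSpecies)
  abund <- stats::rlnorm(length(asvs), params$abundanceLogmean,
                         params$abundanceLogsd)
  if (params$nestedSites) {
    spTot <- tapply(abund, spOf, sum)
    ranking <- order(spTot, decreasing = TRUE)
    quotas <- round(seq(params$nSpecies,
                        max(2, round(params$nSpecies * params$occupancy)),
                        length.out = params$nSites))
    occ <- vapply(seq_len(params$nSites), function(k) {
      seq_len(params$nSpecies) %in% ranking[seq_len(quotas[k])]
    }, logical(params$nSpecies))
  } else {
    occ <- matrix(stats::rbinom(params$nSpecies * params$nSites, 1,
                                params$occupancy) == 1,
                  nrow = params$nSpecies)
  }
  rows <- list()
  used <- meta[!meta$is_blank, ]
  for (i in seq_len(nrow(used))) {
    site <- match(used$group[i], sprintf("Site%d", seq_len(params$nSites)))
    inSample <- occ[spOf, site]
    if (!any(inSample)) next
    lambda <- abund * inSample
    lambda <- lambda / sum(lambda) * params$meanDepth
    reads <- stats::rpois(length(asvs), lambda)
    keep <- reads > 0
    if (any(keep)) {
      rows[[length(rows) + 1L]] <- data.frame(
        asv_id = asvs[keep], sample_id = used$sample_id[i],
        reads = reads[keep])
    }
  }
  if (length(rows) == 0) {
    .preconditionError("simulated community is empty; raise occupancy ",
                       "or meanDepth")
  }
  ObservationTable(do.call(rbind, rows), meta)
}

#' Inject tag-jumped (index-hopped) reads
#'
#' Every genuine read independently hops with probability `pJump` to a
#' uniformly chosen other index combination, used or blank.  Origin cells
#' are decremented; destination cells that were empty become new
#' observations labelled `tagjump`.  Total reads are conserved exactly.
#'
#' @param table an [ObservationTable-class] of true observations.
#' @param pJump per-read hop probability.
#' @param seed RNG seed.
#' @return list with `table` (the observed [ObservationTable-class]) and
#'   `truth` (a [SimTruth-class] labelling every observation).
#' @export
injectTagJumps <- function(table, pJump, seed) {
  stopifnot(methods::is(table, "ObservationTable"))
  pJump <- .assertProb(pJump, "pJump")
  set.seed(seed)
  obs <- observations(table)
  combos <- sampleData(table)$sample_id
  nC <- length(combos)
  if (nC < 2) .preconditionError("need at least 2 index combinations")
  hopped <- stats::rbinom(nrow(obs), obs$reads, pJump)
  recv <- list()
  for (i in which(hopped > 0)) {
    dests <- combos[combos != obs$sample_id[i]]
    cnt <- as.vector(stats::rmultinom(1, hopped[i],
                                      rep(1, nC - 1)))
    nz <- cnt > 0
    if (any(nz)) {
      recv[[length(recv) + 1L]] <- data.frame(
        asv_id = obs$asv_id[i], sample_id = dests[nz], reads = cnt[nz])
    }
  }
  origin <- data.frame(asv_id = obs$asv_id, sample_id = obs$sample_id,
                       stay = obs$reads - hopped,
                       true_reads = obs$reads)
  received <- if (length(recv) > 0) {
    r <- do.call(rbind, recv)
    agg <- stats::aggregate(reads ~ asv_id + sample_id, data = r,
                            FUN = sum)
    agg
  } else {
    data.frame(asv_id = character(), sample_id = character(),
               reads = integer())
  }
  key <- function(d) .obsKey(d$asv_id, d$sample_id)
  allKeys <- union(key(origin), key(received))
  stay <- stats::setNames(origin$stay, key(origin))[allKeys]
  stay[is.na(stay)] <- 0
  got <- stats::setNames(received$reads, key(received))[allKeys]
  got[is.na(got)] <- 0
  trueR <- stats::setNames(origin$true_reads, key(origin))[allKeys]
  trueR[is.na(trueR)] <- 0
  parts <- strsplit(allKeys, "\r", fixed = TRUE)
  labels <- data.frame(
    asv_id = vapply(parts, `[`, character(1), 1),
    sample_id = vapply(parts, `[`, character(1), 2),
    reads = as.integer(stay + got),
    label = ifelse(trueR > 0, "genuine", "tagjump"),
    hopped_in = as.integer(got),
    true_reads = as.integer(trueR))
  labels <- labels[labels$reads > 0, , drop = FALSE]
  rownames(labels) <- NULL
  newTab <- ObservationTable(
    labels[, c("asv_id", "sample_id", "reads")], sampleData(table))
  truth <- methods::new("SimTruth", labels = labels,
                        params = list(pJump = pJump, seed = seed))
  list(table = newTab, truth = truth)
}

#' Inject spurious sequencing-error ASVs
#'
#' Adds `nErrorAsvs` novel ASVs, each observed in exactly one index
#' combination (blanks included) with `1 + Geometric(errorReadP)` reads,
#' labelled `seqerror`.  The blank/used split of the destinations is
#' stratified at its expected proportion
#' (`round(nErrorAsvs * nBlanks / nCombos)` errors land in blanks);
#' within each stratum placement is uniform.  The stratification makes
#' the blank-threshold derivation exercisable at every seed instead of
#' failing on the binomial lower tail.
#'
#' @param table an [ObservationTable-class].
#' @param nErrorAsvs number of error ASVs to add.
#' @param errorReadP geometric parameter of the read counts.
#' @param seed RNG seed.
#' @param truth optional [SimTruth-class] to extend (from
#'   [injectTagJumps()]); if `NULL` a fresh truth labelling all existing
#'   observations `genuine` is created.
#' @return list with `table` and `truth` as in [injectTagJumps()].
#' @export
injectSeqErrors <- function(table, nErrorAsvs, errorReadP, seed,
                            truth = NULL) {
  stopifnot(methods::is(table, "ObservationTable"))
  nErrorAsvs <- .assertCount(nErrorAsvs, "nErrorAsvs", min = 0L)
  errorReadP <- .assertProb(errorReadP, "errorReadP")
  set.seed(seed)
  if (is.null(truth)) {
    obs <- observations(table)
    truth <- methods::new("SimTruth", labels = data.frame(
      asv_id = obs$asv_id, sample_id = obs$sample_id, reads = obs$reads,
      label = rep("genuine", nrow(obs)), hopped_in = 0L,
      true_reads = obs$reads), params = list())
  }
  if (nErrorAsvs == 0) return(list(table = table, truth = truth))
  meta <- sampleData(table)
  combos <- meta$sample_id
  # Stratified blank/used allocation: the number of error ASVs landing in
  # blanks is fixed at its expectation (placement within each stratum is
  # uniform), so the blank-calibration machinery downstream is exercised
  # at every seed rather than in ~9 seeds out of 10.
  blanks <- meta$sample_id[meta$is_blank]
  nB <- round(nErrorAsvs * length(blanks) / length(combos))
  toBlank <- seq_len(nErrorAsvs) %in% sample.int(nErrorAsvs, nB)
  dest <- character(nErrorAsvs)
  if (nB > 0) dest[toBlank] <- sample(blanks, nB, replace = TRUE)
  if (nB < nErrorAsvs) {
    dest[!toBlank] <- sample(setdiff(combos, blanks),
                             nErrorAsvs - nB, replace = TRUE)
  }
  add <- data.frame(
    asv_id = sprintf("ERR_%03d", seq_len(nErrorAsvs)),
    sample_id = dest,
    reads = 1L + stats::rgeom(nErrorAsvs, errorReadP))
  obs <- rbind(observations(table)[, c("asv_id", "sample_id", "reads")],
               add)
  labels <- rbind(truth@labels,
                  data.frame(asv_id = add$asv_id,
                             sample_id = add$sample_id,
                             reads = add$reads, label = "seqerror",
                             hopped_in = 0L, true_reads = 0L))
  rownames(labels) <- NULL
  list(table = ObservationTable(obs, sampleData(table)),
       truth = methods::new("SimTruth", labels = labels,
                            params = c(truth@params,
                                       list(nErrorAsvs = nErrorAsvs,
                                            errorReadP = errorReadP))))
}

#' @rdname SimTruth-accessors
#' @export
setMethod("truthLabels", "SimTruth", function(x) x@labels)

#' Accessors for SimTruth
#' @param x a [SimTruth-class].
#' @return `truthLabels()` the per-observation label data.frame;
#'   `simulationParams()` the parameter list.
#' @name SimTruth-accessors
NULL

#' @rdname SimTruth-accessors
#' @export
setMethod("simulationParams", "SimTruth", function(x) x@params)

setMethod("show", "SimTruth", function(object) {
  tab <- table(object@labels$label)
  cat("SimTruth:", nrow(object@labels), "labelled observations (",
      paste(names(tab), as.integer(tab), collapse = ", "), ")\n")
})

#' Simulate a species-structured alignment and tree
#'
#' Builds an alignment in which the intra/inter-species distance
#' separation is guaranteed by construction and verified before return:
#' species receive random codes over a shared set of diagnostic
#' positions (2.5x the `ceiling(dBetween * length)` differences
#' required), resampled until every species pair differs at >=
#' `dBetween * length` positions; within-species ASVs carry at most
#' `floor(dWithin * length / 2)` substitutions confined to
#' non-diagnostic positions, bounding every intra-species pairwise
#' p-distance by `dWithin` while never eroding the inter-species floor.
#' The returned rooted tree has one clade per species with branch
#' lengths matching the realised mutation fractions.
#'
#' @param nSpecies,asvsPerSpecies species count and ASVs per species.
#' @param dWithin maximum intra-species pairwise p-distance.
#' @param dBetween minimum inter-species pairwise p-distance.
#' @param length alignment length in columns.
#' @param seed RNG seed.
#' @return list with `alignment` (an [ape::DNAbin] matrix), `tree`
#'   (rooted [ape::phylo]), and `partition` (named character: ASV id ->
#'   species id, the ground-truth clustering).
#' @export
simulateSequences <- function(nSpecies = 20, asvsPerSpecies = 3,
                              dWithin = 0.01, dBetween = 0.08,
                              length = 400, seed = 42) {
  nSpecies <- .assertCount(nSpecies, "nSpecies")
  asvsPerSpecies <- .assertCount(asvsPerSpecies, "asvsPerSpecies")
  length <- .assertCount(length, "length")
  needB <- ceiling(dBetween * length)   # required pairwise differences
  mW <- floor(dWithin * length / 2)
  # shared diagnostic positions: random species codes differ at ~3/4 of
  # them, so 2.5x the requirement leaves a wide verified margin
  P <- ceiling(2.5 * needB)
  if (P + mW > length || needB > length) {
    .inputError("infeasible divergence: need ", P, " diagnostic + ", mW,
                " variable positions in an alignment of length ", length)
  }
  set.seed(seed)
  bases <- c("a", "c", "g", "t")
  root <- sample(bases, length, replace = TRUE)
  perm <- sample.int(length)
  diagPos <- perm[seq_len(P)]
  free <- perm[seq(P + 1, length)]
  codes <- NULL
  for (attempt in seq_len(100)) {
    codes <- matrix(sample(bases, nSpecies * P, replace = TRUE),
                    nrow = nSpecies)
    if (nSpecies == 1) break
    dmin <- min(vapply(seq_len(nSpecies - 1), function(i) {
      min(vapply(seq(i + 1, nSpecies), function(j)
        sum(codes[i, ] != codes[j, ]), numeric(1)))
    }, numeric(1)))
    if (dmin >= needB) break
    codes <- NULL
  }
  if (is.null(codes)) {
    .inputError("could not realise the requested inter-species ",
                "divergence; lower dBetween or raise length")
  }
  rotate <- function(b) bases[(match(b, bases)) %% 4 + 1]
  seqs <- list()
  partition <- character(0)
  stemLen <- numeric(nSpecies)
  for (k in seq_len(nSpecies)) {
    anc <- root
    anc[diagPos] <- codes[k, ]
    stemLen[k] <- sum(anc != root) / length
    for (a in seq_len(asvsPerSpecies)) {
      s <- anc
      if (mW > 0 && a > 1) {
        pos <- sample(free, mW)
        s[pos] <- rotate(s[pos])
      }
      id <- sprintf("ASV_s%03d_a%d", k, a)
      seqs[[id]] <- s
      partition[id] <- sprintf("SP%03d", k)
    }
  }
  aln <- ape::as.DNAbin(do.call(rbind, seqs))
  tipLen <- function(a) if (a == 1) 0 else mW / length
  clade <- vapply(seq_len(nSpecies), function(k) {
    tips <- sprintf("ASV_s%03d_a%d", k, seq_len(asvsPerSpecies))
    if (asvsPerSpecies == 1) {
      sprintf("%s:%g", tips, stemLen[k])
    } else {
      sprintf("(%s):%g",
              paste(sprintf("%s:%g", tips,
                            vapply(seq_len(asvsPerSpecies), tipLen,
                                   numeric(1))), collapse = ","),
              stemLen[k])
    }
  }, character(1))
  # fold the species clades into a zero-length ladder so the root is
  # binary (rooted in the ape sense); patristic distances are unchanged
  txt <- if (nSpecies == 1) {
    paste0("(", clade, ");")
  } else {
    acc <- clade[1]
    if (nSpecies > 2) {
      for (k in seq(2, nSpecies - 1)) {
        acc <- sprintf("(%s,%s):0", acc, clade[k])
      }
    }
    sprintf("(%s,%s);", acc, clade[nSpecies])
  }
  tree <- ape::read.tree(text = txt)
  list(alignment = aln, tree = tree, partition = partition)
}

#' Score a filtering rule against simulation ground truth
#'
#' Compares the observations retained by a filter with the generative
#' labels: tag-jump sensitivity (fraction of `tagjump` observations
#' removed), genuine specificity (fraction of `genuine` observations
#' retained) and error sensitivity (fraction of `seqerror` observations
#' removed), plus the full confusion table.
#'
#' @param truth a [SimTruth-class] for the simulated table.
#' @param filtered the [ObservationTable-class] returned by the filter;
#'   must be a subset of the truth observations.
#' @param minReads additionally report genuine retention restricted to
#'   observations with `true` reads strictly above `minReads` (e.g. the
#'   derived read threshold), as `genuineSpecificityAbove`.
#' @return list of class `FilterScore` with elements
#'   `tagjumpSensitivity`, `genuineSpecificity`, `errorSensitivity`,
#'   `genuineSpecificityAbove`, `minReads` and `confusion` (label x
#'   removed/retained counts).
#' @export
scoreFilter <- function(truth, filtered, minReads = 0) {
  stopifnot(methods::is(truth, "SimTruth"),
            methods::is(filtered, "ObservationTable"))
  lb <- truth@labels
  tk <- .obsKey(lb$asv_id, lb$sample_id)
  fo <- observations(filtered)
  fk <- .obsKey(fo$asv_id, fo$sample_id)
  alien <- setdiff(fk, tk)
  if (length(alien) > 0) {
    .inputError("filtered table contains observations absent from ",
                "truth: ", gsub("\r", " / ", alien[1], fixed = TRUE))
  }
  removed <- !(tk %in% fk)
  confusion <- table(label = lb$label,
                     status = ifelse(removed, "removed", "retained"))
  frac <- function(lab, rem) {
    sel <- lb$label == lab
    if (!any(sel)) return(NA_real_)
    if (rem) mean(removed[sel]) else mean(!removed[sel])
  }
  gAbove <- {
    sel <- lb$label == "genuine" & lb$reads > minReads
    if (any(sel)) mean(!removed[sel]) else NA_real_
  }
  structure(list(
    tagjumpSensitivity = frac("tagjump", TRUE),
    genuineSpecificity = frac("genuine", FALSE),
    errorSensitivity = frac("seqerror", TRUE),
    genuineSpecificityAbove = gAbove,
    minReads = minReads,
    confusion = confusion), class = "FilterScore")
}

#' @export
print.FilterScore <- function(x, ...) {
  cat("FilterScore\n")
  cat(sprintf("  tag-jump sensitivity : %.3f\n", x$tagjumpSensitivity))
  cat(sprintf("  genuine specificity  : %.3f\n", x$genuineSpecificity))
  if (!is.na(x$genuineSpecificityAbove)) {
    cat(sprintf("  genuine specificity (reads > %g): %.3f\n",
                x$minReads, x$genuineSpecificityAbove))
  }
  cat(sprintf("  error sensitivity    : %.3f\n", x$errorSensitivity))
  print(x$confusion)
  invisible(x)
}

#' Simulate a complete benchmark dataset
#'
#' Orchestrates [simulateCommunity()], [injectTagJumps()],
#' [injectSeqErrors()] and [simulateSequences()] with seeds derived from
#' `params$seed`.  Error-ASV sequences are generated as single
#' substitutions of a random genuine ASV (at a position free of every
#' species block) and attached to the tree as near-zero-length sisters of
#' their parent, so downstream clustering and tree operations remain
#' defined for any error ASV that survives filtering.
#'
#' @param params a [simParams()] list.
#' @return list with `table` (observed [ObservationTable-class]),
#'   `truth` ([SimTruth-class]), `alignment` ([ape::DNAbin]), `tree`
#'   (rooted [ape::phylo] covering genuine and error ASVs), `partition`
#'   (true species assignment of genuine ASVs) and `params`.
#' @export
simulateDataset <- function(params = simParams()) {
  stopifnot(inherits(params, "SimParams"))
  true <- simulateCommunity(params, seed = params$seed)
  tj <- injectTagJumps(true, params$pJump, seed = params$seed + 1L)
  se <- injectSeqErrors(tj$table, params$nErrorAsvs, params$errorReadP,
                        seed = params$seed + 2L, truth = tj$truth)
  seqres <- simulateSequences(params$nSpecies, params$asvsPerSpecies,
                              params$dWithin, params$dBetween,
                              params$seqLength, seed = params$seed + 3L)
  if (params$nErrorAsvs > 0) {
    seqres <- .attachErrorAsvs(seqres,
                               sprintf("ERR_%03d",
                                       seq_len(params$nErrorAsvs)),
                               params, seed = params$seed + 4L)
  }
  truth <- se$truth
  truth@params <- c(unclass(params))
  list(table = se$table, truth = truth, alignment = seqres$alignment,
       tree = seqres$tree, partition = seqres$partition, params = params)
}

# Give each error ASV a sequence one substitution away from a random
# genuine parent ASV, and graft it onto the tree as a near-zero-length
# sister of that parent (string-level graft on the Newick text, which
# keeps the parent's patristic position unchanged).
.attachErrorAsvs <- function(seqres, errorIds, params, seed) {
  set.seed(seed)
  aln <- as.character(seqres$alignment)
  genuine <- rownames(aln)
  L <- ncol(aln)
  bases <- c("a", "c", "g", "t")
  newRows <- list()
  nwk <- ape::write.tree(seqres$tree)
  eps <- 1e-4
  for (e in errorIds) {
    parent <- sample(genuine, 1)
    s <- aln[parent, ]
    pos <- sample.int(L, 1)
    s[pos] <- sample(setdiff(bases, s[pos]), 1)
    newRows[[e]] <- s
    # replace "parent:len" with "(parent:eps,e:eps):len"
    pat <- paste0("(?<![A-Za-z0-9_])", parent, ":([0-9.eE+-]+)")
    rep <- sprintf("(%s:%g,%s:%g):\\1", parent, eps, e, eps)
    nwk <- sub(pat, rep, nwk, perl = TRUE)
  }
  aln2 <- rbind(aln, do.call(rbind, newRows))
  rownames(aln2) <- c(genuine, errorIds)
  list(alignment = ape::as.DNAbin(aln2), tree = ape::read.tree(text = nwk),
       partition = seqres$partition)
}
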