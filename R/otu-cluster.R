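#' Pairwise p-distances from an aligned FASTA
#'
#' Uncorrected proportion distances with pairwise deletion: for each pair
#' of sequences, alignment columns where either sequence carries a gap or
#' an ambiguity are skipped and the distance is mismatches over compared
#' columns.  Computed with [ape::dist.dna()] (`model = "raw"`,
#' `pairwise.deletion = TRUE`); a Jukes-Cantor correction is available via
#' `model = "JC69"`.
#'
#' @param alignment path to an aligned FASTA file, or an
#'   [ape::DNAbin] object.
#' @param model `"raw"` (p-distance, default) or `"JC69"`.
#' @return symmetric numeric matrix of distances with ASV ids as
#'   dimnames.
#' @export
pairwiseDistances <- function(alignment, model = c("raw", "JC69")) {
  model <- match.arg(model)
  if (is.character(alignment)) {
    if (!file.exists(alignment)) {
      .inputError("file not found: ", alignment)
    }
    alignment <- ape::read.FASTA(alignment)
  }
  if (!inherits(alignment, "DNAbin")) {
    .inputError("alignment must be a FASTA path or a DNAbin object")
  }
  lens <- if (is.matrix(alignment)) rep(ncol(alignment), nrow(alignment))
          else lengths(alignment)
  if (length(unique(lens)) > 1) {
    .inputError("ragged alignment: sequence lengths ",
                paste(unique(lens), collapse = ", "))
  }
  d <- as.matrix(ape::dist.dna(alignment, model = model,
                               pairwise.deletion = TRUE))
  if (anyNA(d)) {
    bad <- which(is.na(d) | is.nan(d), arr.ind = TRUE)[1, ]
    .inputError("no comparable columns between ",
                rownames(d)[bad[1]], " and ", colnames(d)[bad[2]])
  }
  d
}

#' Complete-linkage OTU clustering at a fixed cutoff
#'
#' Agglomerative complete-linkage clustering cut so that no cluster
#' contains a pair of members farther apart than `cutoff`: clusters whose
#' merge height would exceed the cutoff are never formed, which is exactly
#' the "maximum pairwise distance within an OTU <= cutoff" semantics of a
#' barcoding-gap threshold.  Merges are fully deterministic: at each step
#' the closest pair is merged, and equal-distance candidates are ordered
#' by the lexicographically smallest member labels of the two clusters, so
#' the partition is invariant to the input label order.
#'
#' @param dm symmetric distance matrix (or `dist`) with ASV-id dimnames.
#' @param cutoff maximum within-OTU pairwise distance (default 0.03, the
#'   3% barcoding gap).
#' @return An [OtuAssignment-class].  OTU ids are `OTU_<smallest member
#'   ASV id>`; representatives default to that smallest member until
#'   [chooseRepresentatives()] replaces them by the most abundant one.
#' @examples
#' d <- matrix(c(0, .01, .05, .01, 0, .05, .05, .05, 0), 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' otuMapping(clusterCompleteLinkage(d))
#' @export
clusterCompleteLinkage <- function(dm, cutoff = 0.03) {
  if (inherits(dm, "dist")) dm <- as.matrix(dm)
  if (!is.matrix(dm) || nrow(dm) != ncol(dm)) {
    .inputError("dm must be a square distance matrix")
  }
  labels <- rownames(dm)
  if (is.null(labels) || anyDuplicated(labels)) {
    .inputError("dm needs unique rownames (ASV ids)")
  }
  if (any(!is.finite(dm)) || any(abs(dm - t(dm)) > 1e-12) ||
      any(diag(dm) != 0)) {
    .inputError("dm must be finite, symmetric, with zero diagonal")
  }
  n <- length(labels)
  clusters <- as.list(labels)        # members of each live cluster
  minLab <- labels                   # lexicographic anchor per cluster
  D <- dm                            # complete-linkage cluster distances
  while (length(clusters) > 1) {
    offdiag <- D
    diag(offdiag) <- Inf
    m <- min(offdiag)
    if (m > cutoff) break
    cand <- which(offdiag == m, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    keys <- apply(cand, 1, function(ij) {
      k <- .lexSort(c(minLab[ij[1]], minLab[ij[2]]))
      paste(k, collapse = "\r")
    })
    pick <- cand[order(method = "radix", keys)[1], ]
    i <- pick[1]; j <- pick[2]
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    minLab[i] <- .lexSort(c(minLab[i], minLab[j]))[1]
    newd <- pmax(D[i, ], D[j, ])
    D[i, ] <- newd
    D[, i] <- newd
    D[i, i] <- 0
    clusters[[j]] <- NULL
    minLab <- minLab[-j]
    D <- D[-j, -j, drop = FALSE]
  }
  mapping <- character(0)
  for (k in seq_along(clusters)) {
    otu <- paste0("OTU_", minLab[k])
    mapping[clusters[[k]]] <- otu
  }
  mapping <- mapping[labels]
  reps <- vapply(split(names(mapping), mapping),
                 function(m) .lexSort(m)[1], character(1))
  methods::new("OtuAssignment", mapping = mapping,
               representative = reps, cutoff = cutoff)
}

#' Accessors for OtuAssignment
#' @param x an [OtuAssignment-class].
#' @return `otuMapping()` the named ASV-to-OTU character vector;
#'   `otuRepresentatives()` the named OTU-to-representative-ASV vector.
#' @name OtuAssignment-accessors
NULL

#' @rdname OtuAssignment-accessors
#' @export
setMethod("otuMapping", "OtuAssignment", function(x) x@mapping)

#' @rdname OtuAssignment-accessors
#' @export
setMethod("otuRepresentatives", "OtuAssignment",
          function(x) x@representative)

setMethod("show", "OtuAssignment", function(object) {
  cat("OtuAssignment:", length(object@mapping), "ASVs in",
      length(object@representative), "OTUs (cutoff",
      object@cutoff, ")\n")
})

#' Choose abundance-based OTU representatives
#'
#' Sets each OTU's representative to the member ASV with the highest
#' total read count in `table`; ASVs absent from the table count zero and
#' ties go to the lexicographically smallest ASV id.
#'
#' @param assignment an [OtuAssignment-class].
#' @param table an [ObservationTable-class].
#' @return The assignment with representatives replaced.
#' @export
chooseRepresentatives <- function(assignment, table) {
  stopifnot(methods::is(assignment, "OtuAssignment"),
            methods::is(table, "ObservationTable"))
  obs <- observations(table)
  totals <- tapply(as.numeric(obs$reads), obs$asv_id, sum)
  mapping <- assignment@mapping
  reps <- vapply(split(names(mapping), mapping), function(members) {
    members <- .lexSort(members)
    tot <- totals[members]
    tot[is.na(tot)] <- 0
    members[which.max(tot)]     # first max -> lexicographic tie-break
  }, character(1))
  methods::initialize(assignment, representative = reps)
}

#' Aggregate an observation table to an OTU community matrix
#'
#' @param table an [ObservationTable-class]; every ASV must be mapped.
#' @param assignment an [OtuAssignment-class].
#' @return integer matrix, samples (all samples in the metadata) by OTUs;
#'   cell = summed member-ASV reads.  Total reads are conserved exactly.
#' @export
aggregateToOtus <- function(table, assignment) {
  stopifnot(methods::is(table, "ObservationTable"),
            methods::is(assignment, "OtuAssignment"))
  obs <- observations(table)
  unmapped <- setdiff(unique(obs$asv_id), names(assignment@mapping))
  if (length(unmapped) > 0) {
    .inputError("ASVs without OTU assignment: ",
                paste(utils::head(unmapped, 5), collapse = ", "))
  }
  samples <- sampleData(table)$sample_id
  otus <- .lexSort(unique(assignment@mapping))
  cm <- matrix(0L, nrow = length(samples), ncol = length(otus),
               dimnames = list(samples, otus))
  otu <- assignment@mapping[obs$asv_id]
  agg <- tapply(as.numeric(obs$reads),
                list(obs$sample_id, otu), sum)
  agg[is.na(agg)] <- 0
  cm[rownames(agg), colnames(agg)] <- as.integer(agg)
  cm
}

#' Collapse an ASV tree to one representative tip per OTU
#'
#' Prunes every tip that is not an OTU representative, suppresses the
#' resulting degree-2 internal nodes (branch lengths summed) and renames
#' the surviving tips to their OTU ids.  Patristic distances between the
#' surviving representatives are preserved.
#'
#' @param tree a rooted [ape::phylo] tree, or a path to a Newick file.
#' @param assignment an [OtuAssignment-class]; every representative must
#'   be a tip of the tree, and at least two OTUs are required (a one-tip
#'   tree has no phylogenetic-diversity surface).
#' @return rooted [ape::phylo] tree with OTU ids as tip labels.
#' @export
collapseTree <- function(tree, assignment) {
  if (is.character(tree)) {
    if (!file.exists(tree)) .inputError("file not found: ", tree)
    tree <- ape::read.tree(tree)
  }
  stopifnot(inherits(tree, "phylo"),
            methods::is(assignment, "OtuAssignment"))
  reps <- assignment@representative
  miss <- setdiff(unname(reps), tree$tip.label)
  if (length(miss) > 0) {
    .inputError("representatives missing from tree: ",
                paste(utils::head(miss, 5), collapse = ", "))
  }
  if (length(reps) < 2) {
    .preconditionError("need at least two OTUs to build an OTU tree")
  }
  pruned <- ape::keep.tip(tree, unname(reps))
  pruned$tip.label <- names(reps)[match(pruned$tip.label, reps)]
  pruned
}
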