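.asCommunityMatrix <- function(cm) {
  if (!is.matrix(cm)) .inputError("community matrix must be a matrix")
  if (is.null(rownames(cm)) || is.null(colnames(cm))) {
    .inputError("community matrix needs sample rownames and OTU colnames")
  }
  if (any(cm < 0)) .inputError("community matrix has negative cells")
  cm
}

#' Per-sample OTU richness
#'
#' @param cm community matrix, samples x OTUs (counts or
#'   presence-absence).
#' @return named integer vector: number of OTUs with reads > 0 per
#'   sample.
#' @export
richness <- function(cm) {
  cm <- .asCommunityMatrix(cm)
  rowSums(cm > 0)
}

.tipEdgePaths <- function(tree) {
  # list of root-path edge indices for each tip, in tip.label order
  parent <- integer(max(tree$edge))
  edgeOf <- integer(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  edgeOf[tree$edge[, 2]] <- seq_len(nrow(tree$edge))
  root <- ape::Ntip(tree) + 1L
  lapply(seq_len(ape::Ntip(tree)), function(tip) {
    path <- integer(0)
    v <- tip
    while (v != root) {
      path <- c(path, edgeOf[v])
      v <- parent[v]
    }
    path
  })
}

#' Faith's phylogenetic diversity
#'
#' PD of a sample is the sum of branch lengths of the minimal subtree
#' connecting its present OTUs.  By default the path to the root is
#' included (the convention of the classic implementation), so a
#' single-OTU sample has PD equal to its root-path length; with
#' `includeRoot = FALSE` the subtree is rooted at the MRCA of the present
#' tips and a single-OTU sample has PD 0.  Empty samples have PD 0.
#'
#' @param cm community matrix, samples x OTUs.
#' @param tree rooted [ape::phylo] with branch lengths; every OTU column
#'   must be a tip.
#' @param includeRoot logical (default `TRUE`).
#' @return named numeric vector of per-sample PD in branch-length units.
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
#' cm <- rbind(s1 = c(A = 1, B = 1, C = 0))
#' faithPd(cm, tr)  # 3
#' @export
faithPd <- function(cm, tree, includeRoot = TRUE) {
  cm <- .asCommunityMatrix(cm)
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) .inputError("tree must be rooted")
  if (is.null(tree$edge.length)) .inputError("tree has no branch lengths")
  miss <- setdiff(colnames(cm), tree$tip.label)
  if (length(miss) > 0) {
    .inputError("OTUs missing from tree: ",
                paste(utils::head(miss, 5), collapse = ", "))
  }
  paths <- .tipEdgePaths(tree)
  names(paths) <- tree$tip.label
  vapply(rownames(cm), function(s) {
    present <- colnames(cm)[cm[s, ] > 0]
    if (length(present) == 0) return(0)
    tipPaths <- paths[present]
    edges <- unique(unlist(tipPaths))
    if (!includeRoot) {
      shared <- Reduce(intersect, tipPaths)   # root-to-MRCA edges
      edges <- setdiff(edges, shared)
    }
    sum(tree$edge.length[edges])
  }, numeric(1))
}

#' Sequencing-depth residual correction of a diversity index
#'
#' Fits an ordinary least-squares line `diversity ~ depth` and returns the
#' residuals: the part of a sample's diversity not explained by how many
#' reads it received.  A positive residual means the sample is more
#' diverse than its sequencing depth predicts.  Scaled (z-scored)
#' residuals are returned alongside the raw ones.
#'
#' @param values per-sample diversity (richness, PD, ...).
#' @param depths per-sample total reads; must vary across samples.
#' @param onConstantDepth `"error"` (default) or `"center"` (fall back to
#'   mean-centering when the depths are all equal and a slope is
#'   undefined).
#' @return data.frame with columns `raw` and `scaled` (mean 0, unit
#'   variance; all zero when the raw residuals are constant).
#' @export
depthResiduals <- function(values, depths,
                           onConstantDepth = c("error", "center")) {
  onConstantDepth <- match.arg(onConstantDepth)
  if (length(values) != length(depths)) {
    .inputError("values and depths must have equal length")
  }
  if (length(values) < 3) .preconditionError("need at least 3 samples")
  if (any(depths <= 0)) .inputError("depths must be positive")
  if (stats::var(depths) == 0) {
    if (onConstantDepth == "error") {
      .preconditionError("constant sequencing depth: slope undefined ",
                         "(use onConstantDepth = \"center\")")
    }
    raw <- values - mean(values)
  } else {
    raw <- unname(stats::resid(stats::lm(values ~ depths)))
  }
  s <- stats::sd(raw)
  # residuals that are zero up to OLS round-off must not be inflated
  # into unit-variance noise by the standardisation
  tol <- 1e-10 * max(abs(values), 1)
  scaled <- if (s <= tol) raw * 0 else (raw - mean(raw)) / s
  out <- data.frame(raw = raw, scaled = scaled)
  rownames(out) <- names(values)
  out
}

.betaTriple <- function(sor, sim) {
  c(beta_sor = sor, beta_sim = sim, beta_sne = sor - sim)
}

#' Pairwise Sorensen beta-diversity partition (Baselga)
#'
#' For two samples with `a` shared OTUs and `b`, `c` exclusive OTUs:
#' total dissimilarity `beta_sor = (b + c) / (2a + b + c)`, turnover
#' `beta_sim = min(b, c) / (a + min(b, c))` (Simpson dissimilarity) and
#' nestedness-resultant `beta_sne = beta_sor - beta_sim`.
#'
#' @param pa community matrix, samples x OTUs; converted to
#'   presence-absence (`> 0`) internally.
#' @param i,j row names or indices of the two distinct samples.
#' @return named numeric vector `beta_sor`, `beta_sim`, `beta_sne`.
#' @export
betaPairwise <- function(pa, i, j) {
  pa <- .asCommunityMatrix(pa) > 0
  x <- pa[i, ]
  y <- pa[j, ]
  a <- sum(x & y)
  b <- sum(x & !y)
  c_ <- sum(!x & y)
  if (a + b + c_ == 0) {
    .preconditionError("both samples are empty: dissimilarity undefined")
  }
  m <- min(b, c_)
  sim <- if (a + m == 0) 0 else m / (a + m)
  .betaTriple((b + c_) / (2 * a + b + c_), sim)
}

#' Multi-site Sorensen beta-diversity partition (Baselga)
#'
#' With `S_i` the richness of site i, `S_T` the pooled richness and
#' `b_ij` the number of OTUs present in site i but not j (sums over
#' unordered pairs):
#' `beta_SIM = sum(min) / (core + sum(min))` and
#' `beta_SOR = (sum(min) + sum(max)) / (2 * core + sum(min) + sum(max))`
#' where `core = sum(S_i) - S_T`; `beta_SNE = beta_SOR - beta_SIM`.
#'
#' @param pa community matrix, samples x OTUs (>= 2 samples, at least one
#'   present OTU).
#' @return named numeric vector `beta_sor`, `beta_sim`, `beta_sne`.
#' @export
betaMultisite <- function(pa) {
  pa <- .asCommunityMatrix(pa) > 0
  if (nrow(pa) < 2) .preconditionError("need at least 2 samples")
  if (sum(pa) == 0) .preconditionError("all samples are empty")
  Si <- rowSums(pa)
  ST <- sum(colSums(pa) > 0)
  core <- sum(Si) - ST
  sumMin <- 0
  sumMax <- 0
  n <- nrow(pa)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      bij <- sum(pa[i, ] & !pa[j, ])
      bji <- sum(pa[j, ] & !pa[i, ])
      sumMin <- sumMin + min(bij, bji)
      sumMax <- sumMax + max(bij, bji)
    }
  }
  sim <- if (core + sumMin == 0) 0 else sumMin / (core + sumMin)
  sor <- if (2 * core + sumMin + sumMax == 0) 0 else
    (sumMin + sumMax) / (2 * core + sumMin + sumMax)
  .betaTriple(sor, sim)
}

#' Resampled multi-site beta partition per group
#'
#' For each group (site/area), repeatedly draws `nSites` samples without
#' replacement and records the multi-site partition of the draw; the
#' spread of the draws describes within-group beta diversity.  Groups
#' smaller than `nSites` are resampled at their own size, with a warning.
#'
#' @param pa community matrix, samples x OTUs.
#' @param groups group label per row of `pa`.
#' @param nSites number of samples per draw (default 20).
#' @param nIter number of draws per group (default 1000).
#' @param seed RNG seed; fixed seed gives identical draws.
#' @param meanPairwise if `TRUE`, record the mean of all pairwise
#'   partitions of the draw instead of the multi-site statistic.
#' @return named list (one element per group, in lexicographic order) of
#'   data.frames with columns `beta_sor`, `beta_sim`, `beta_sne` and
#'   attributes `n_sites`, `n_iter`, `seed`.
#' @export
betaResample <- function(pa, groups, nSites = 20, nIter = 1000,
                         seed = NULL, meanPairwise = FALSE) {
  pa <- .asCommunityMatrix(pa)
  groups <- as.character(groups)
  if (length(groups) != nrow(pa)) {
    .inputError("groups must have one label per sample row")
  }
  nIter <- .assertCount(nIter, "nIter")
  nSites <- .assertCount(nSites, "nSites", min = 2L)
  if (!is.null(seed)) set.seed(seed)
  out <- list()
  for (g in .lexSort(unique(groups))) {
    idx <- which(groups == g)
    if (length(idx) == 0) .preconditionError("empty group: ", g)
    ns <- nSites
    if (length(idx) < nSites) {
      warning("group ", g, " has ", length(idx), " samples < nSites = ",
              nSites, "; resampling at group size", call. = FALSE)
      ns <- length(idx)
    }
    draws <- matrix(NA_real_, nrow = nIter, ncol = 3)
    for (it in seq_len(nIter)) {
      take <- idx[sample.int(length(idx), ns)]
      draws[it, ] <- if (meanPairwise) {
        sub <- pa[take, , drop = FALSE]
        prs <- utils::combn(ns, 2)
        rowMeans(apply(prs, 2, function(p)
          betaPairwise(sub, p[1], p[2])))
      } else {
        betaMultisite(pa[take, , drop = FALSE])
      }
    }
    df <- as.data.frame(draws)
    names(df) <- c("beta_sor", "beta_sim", "beta_sne")
    attr(df, "group") <- g
    attr(df, "n_sites") <- ns
    attr(df, "n_iter") <- nIter
    attr(df, "seed") <- seed
    out[[g]] <- df
  }
  out
}

#' Exclusive and shared OTU counts across groups
#'
#' Counts, for every non-empty combination of groups (a Venn region),
#' the OTUs present in exactly that set of groups.  Region counts sum to
#' the pooled richness; `exclusive` extracts the single-group regions.
#'
#' @param pa community matrix, samples x OTUs.
#' @param groups group label per sample row; at most 6 groups.
#' @return list with `exclusive` (named integer per group), `regions`
#'   (named integer per group combination, names joined with `&`) and
#'   `pooledRichness`.
#' @export
exclusiveOtus <- function(pa, groups) {
  pa <- .asCommunityMatrix(pa) > 0
  groups <- as.character(groups)
  if (length(groups) != nrow(pa)) {
    .inputError("groups must have one label per sample row")
  }
  gs <- .lexSort(unique(groups))
  if (length(gs) > 6) {
    .inputError("more than 6 groups: Venn region enumeration capped")
  }
  G <- t(vapply(gs, function(g)
    colSums(pa[groups == g, , drop = FALSE]) > 0,
    logical(ncol(pa))))
  present <- colSums(G) > 0
  pattern <- apply(G[, present, drop = FALSE], 2, function(col)
    paste(gs[col], collapse = "&"))
  regions <- table(pattern)
  regions <- stats::setNames(as.integer(regions), names(regions))
  exclusive <- stats::setNames(integer(length(gs)), gs)
  hit <- intersect(gs, names(regions))
  exclusive[hit] <- regions[hit]
  list(exclusive = exclusive, regions = regions,
       pooledRichness = sum(present))
}
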