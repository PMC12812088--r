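# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: the hinge rule is re-derived from sorted order
# statistics, the multi-site partition from explicit set arithmetic, and
# small-n clustering from exhaustive partition enumeration.

# Tukey hinges by the five-number-summary rule: hinge depth
# (floor((n + 1) / 2) + 1) / 2, averaging the two bracketing order
# statistics when the depth is fractional.
bruteHinges <- function(x) {
  x <- sort(x)
  n <- length(x)
  d <- (floor((n + 1) / 2) + 1) / 2
  at <- function(k) mean(c(x[floor(k)], x[ceiling(k)]))
  c(lower = at(d), upper = at(n + 1 - d))
}

bruteTukeySplit <- function(x) {
  h <- bruteHinges(x)
  fence <- h[["upper"]] + 1.5 * (h[["upper"]] - h[["lower"]])
  list(outliers = x[x > fence], body = x[x <= fence], fence = fence)
}

# Baselga multi-site partition via explicit per-site OTU sets.
bruteMultisite <- function(pa) {
  sets <- apply(pa > 0, 1, which, simplify = FALSE)
  ST <- length(Reduce(union, sets))
  Si <- lengths(sets)
  core <- sum(Si) - ST
  sumMin <- 0
  sumMax <- 0
  n <- length(sets)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      bij <- length(setdiff(sets[[i]], sets[[j]]))
      bji <- length(setdiff(sets[[j]], sets[[i]]))
      sumMin <- sumMin + min(bij, bji)
      sumMax <- sumMax + max(bij, bji)
    }
  }
  sim <- if (core + sumMin == 0) 0 else sumMin / (core + sumMin)
  sor <- if (2 * core + sumMin + sumMax == 0) 0 else
    (sumMin + sumMax) / (2 * core + sumMin + sumMax)
  c(sor = sor, sim = sim, sne = sor - sim)
}

# All set partitions of seq_len(n) (Bell-number enumeration, n <= 8).
enumeratePartitions <- function(n) {
  if (n == 1) return(list(list(1L)))
  out <- list()
  for (p in enumeratePartitions(n - 1)) {
    for (k in seq_along(p)) {
      q <- p
      q[[k]] <- c(q[[k]], n)
      out[[length(out) + 1L]] <- q
    }
    out[[length(out) + 1L]] <- c(p, list(n))
  }
  out
}

# Does a partition (list of integer index vectors) satisfy the
# max-pairwise-distance bound?
partitionFeasible <- function(partition, dm, cutoff) {
  all(vapply(partition, function(cl) {
    if (length(cl) < 2) return(TRUE)
    max(dm[cl, cl]) <= cutoff
  }, logical(1)))
}

# Canonical form of a partition given as a membership vector, for
# comparing partitions irrespective of cluster labels.
canonicalPartition <- function(membership) {
  unname(split(names(membership), membership)) |>
    lapply(sort) |>
    (\(x) x[order(vapply(x, `[`, character(1), 1))])()
}

# A toy observation table with hand-set statistics columns (bypasses
# computeStats so blank readprop/norm values can be crafted exactly).
tableWithStats <- function(obs, samples) {
  methods::new("ObservationTable", obs = obs, samples = samples)
}

# A table whose blank-only unique observations have exactly the given
# read counts: one private ASV per value in one blank sample, plus an
# anchor ASV spread over two used samples so the table is non-trivial.
blankErrorTable <- function(blankReads, extraBlankObs = NULL) {
  obs <- data.frame(
    asv_id = c(sprintf("err%02d", seq_along(blankReads)), "keep", "keep"),
    sample_id = c(rep("B1", length(blankReads)), "s1", "s2"),
    reads = c(blankReads, 500, 500))
  if (!is.null(extraBlankObs)) obs <- rbind(obs, extraBlankObs)
  samples <- data.frame(
    sample_id = c("B1", "B2", "s1", "s2"),
    is_blank = c(TRUE, TRUE, FALSE, FALSE),
    group = c(NA, NA, "g1", "g1"))
  ObservationTable(obs, samples)
}

# Random presence-absence matrix guaranteeing no all-empty row pair.
randomPA <- function(nSamples, nOtus, p = 0.5) {
  repeat {
    pa <- matrix(rbinom(nSamples * nOtus, 1, p), nrow = nSamples,
                 dimnames = list(sprintf("s%d", seq_len(nSamples)),
                                 sprintf("o%d", seq_len(nOtus))))
    if (sum(pa) > 0) return(pa)
  }
}
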