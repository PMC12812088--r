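#' Tukey outlier split of a numeric vector
#'
#' Splits values into a high-side outlier set and a body using the Tukey
#' five-number-summary hinges (hinge depth `(floor((n+1)/2) + 1) / 2`,
#' averaging when fractional, as in [stats::fivenum()] and the classic
#' boxplot statistics) and the upper fence
#' `upper hinge + 1.5 * (upper hinge - lower hinge)`.  Outliers are values
#' strictly above the fence; low-side outliers are deliberately ignored --
#' for read counts only the high side is meaningful, and the tag-jump
#' thresholds are minima of high-side outlier sets.
#'
#' @param values non-empty numeric vector (ties allowed).
#' @return list with `outliers`, `body`, `lowerHinge`, `upperHinge`,
#'   `upperFence`.  `outliers` and `body` partition the input multiset.
#' @examples
#' tukeyOutliers(c(1, 2, 3, 4, 100))
#' @export
tukeyOutliers <- function(values) {
  if (length(values) == 0) .inputError("tukeyOutliers: empty input")
  if (!is.numeric(values) || anyNA(values)) {
    .inputError("tukeyOutliers: values must be numeric and non-missing")
  }
  fn <- stats::fivenum(values)
  lower <- fn[2L]
  upper <- fn[4L]
  fence <- upper + 1.5 * (upper - lower)
  hi <- values > fence
  list(outliers = values[hi], body = values[!hi],
       lowerHinge = lower, upperHinge = upper, upperFence = fence)
}

.requireStats <- function(table) {
  if (!hasStats(table)) {
    .preconditionError("per-observation statistics absent; ",
                       "run computeStats() first")
  }
}

.requireBlanks <- function(table) {
  if (length(blankSamples(table)) == 0) {
    .preconditionError("no blank samples flagged in metadata; ",
                       "threshold derivation needs blanks")
  }
}

#' Derive the sequencing-error read-count threshold (filter 1)
#'
#' Collects the read counts of observations whose ASV occurs in exactly
#' one sample (`readprop = 1`) and whose single sample is a blank.  Such
#' reads cannot be tag jumps (they exist nowhere else) and are treated as
#' sequencing errors.  High-side Tukey outliers are removed and the
#' maximum of the remaining body is returned as the cutoff: keeping the
#' outliers would eliminate too many real observations downstream.
#'
#' @param table an [ObservationTable-class] with statistics computed.
#' @param minBlankErrors minimum number of qualifying blank-only
#'   observations required for a data-driven threshold (default 5; a
#'   guard, not a biological constant).
#' @return list with `tReads` (integer cutoff) and `provenance` (values,
#'   hinges, fence, outlier/body split).
#' @export
deriveSeqErrorThreshold <- function(table, minBlankErrors = 5) {
  stopifnot(methods::is(table, "ObservationTable"))
  .requireStats(table)
  .requireBlanks(table)
  obs <- table@obs
  nPer <- stats::ave(obs$reads, obs$asv_id, FUN = length)
  qual <- nPer == 1L & obs$sample_id %in% blankSamples(table)
  vals <- obs$reads[qual]
  if (length(vals) < minBlankErrors) {
    .preconditionError(
      "only ", length(vals), " blank-only unique observations (need >= ",
      minBlankErrors, "); supply a manual read threshold instead")
  }
  split <- tukeyOutliers(as.numeric(vals))
  list(tReads = max(split$body),
       provenance = c(list(values = as.numeric(vals),
                           n = length(vals),
                           threshold = max(split$body)),
                      split[c("outliers", "body", "lowerHinge",
                              "upperHinge", "upperFence")]))
}

#' Apply the sequencing-error filter
#'
#' Removes observations in scope whose read count falls at or below the
#' cutoff.  The comparison is inclusive by default (`reads <= tReads`
#' removed): the cutoff is the largest known error, so a strict rule would
#' let errors of exactly that size survive.  Set `strict = TRUE` for the
#' literal strictly-below reading.
#'
#' @param table an [ObservationTable-class].
#' @param tReads the read-count cutoff.
#' @param scope which samples to filter: `"nonblanks"`, `"blanks"` or
#'   `"all"`.
#' @param strict logical; if `TRUE` only `reads < tReads` are removed.
#' @return The filtered table; out-of-scope observations untouched.
#' @export
applySeqErrorFilter <- function(table, tReads,
                                scope = c("nonblanks", "blanks", "all"),
                                strict = FALSE) {
  stopifnot(methods::is(table, "ObservationTable"))
  scope <- match.arg(scope)
  obs <- table@obs
  inScope <- switch(scope,
    all = rep(TRUE, nrow(obs)),
    blanks = obs$sample_id %in% blankSamples(table),
    nonblanks = !(obs$sample_id %in% blankSamples(table)))
  fails <- if (strict) obs$reads < tReads else obs$reads <= tReads
  methods::initialize(table, obs = obs[!(inScope & fails), , drop = FALSE])
}

#' Derive the tag-jump thresholds (filter 2)
#'
#' From the blank observations that survive filter 1, takes the high-side
#' Tukey outliers of the `readprop` column and of the `norm` column
#' independently; each threshold is the minimum of its outlier set.  The
#' rationale: abundant ASVs hop many reads, so hopped observations can
#' carry many reads yet only a tiny share of the ASV's total
#' (small readprop) and far fewer reads than an equal spread would give
#' (norm near -1); the least extreme blank outlier marks how far genuine
#' observations may stray.
#'
#' @param table an [ObservationTable-class] with statistics present and
#'   filter 1 already applied to the blank samples.
#' @param minBlankErrors minimum number of remaining blank observations.
#' @return list with `tReadprop`, `tNorm` and `provenance` for each.
#' @export
deriveTagjumpThresholds <- function(table, minBlankErrors = 5) {
  stopifnot(methods::is(table, "ObservationTable"))
  .requireStats(table)
  .requireBlanks(table)
  obs <- table@obs
  blank <- obs[obs$sample_id %in% blankSamples(table), , drop = FALSE]
  if (nrow(blank) < minBlankErrors) {
    .preconditionError(
      "only ", nrow(blank), " blank observations after filter 1 (need >= ",
      minBlankErrors, "); supply manual tag-jump thresholds instead")
  }
  one <- function(vals, what) {
    split <- tukeyOutliers(vals)
    if (length(split$outliers) == 0) {
      .preconditionError(
        "no high-side outliers in blank ", what, " values; the ",
        "data-driven rule is undefined -- supply a manual threshold")
    }
    c(list(values = vals, n = length(vals),
           threshold = min(split$outliers)),
      split[c("outliers", "body", "lowerHinge", "upperHinge",
              "upperFence")])
  }
  pr <- one(blank$readprop, "readprop")
  pn <- one(blank$norm, "norm")
  list(tReadprop = pr$threshold, tNorm = pn$threshold,
       provenance = list(readprop = pr, norm = pn))
}

#' Apply the conditional tag-jump filter
#'
#' An observation is retained iff it passes at least one threshold:
#' `readprop > tReadprop` OR `norm > tNorm` (strict, disjunctive).  Only
#' non-blank samples are filtered.
#'
#' @param table an [ObservationTable-class] with statistics present.
#' @param tReadprop read-proportion cutoff.
#' @param tNorm divergence cutoff.
#' @return The filtered table.
#' @export
applyTagjumpFilter <- function(table, tReadprop, tNorm) {
  stopifnot(methods::is(table, "ObservationTable"))
  .requireStats(table)
  obs <- table@obs
  inScope <- !(obs$sample_id %in% blankSamples(table))
  keep <- !inScope | obs$readprop > tReadprop | obs$norm > tNorm
  methods::initialize(table, obs = obs[keep, , drop = FALSE])
}

#' Run the full blank-informed two-stage filter
#'
#' Executes, in order: statistic computation on the raw table; derivation
#' of the sequencing-error cutoff from blank-only unique observations;
#' filter 1 on blanks; derivation of the tag-jump cutoffs from the
#' surviving blank observations; filter 1 on non-blank samples; the
#' conditional tag-jump filter on non-blank samples; and finally removal
#' of the blank samples from the output.
#'
#' @param table an [ObservationTable-class] with blanks flagged.
#' @param minBlankErrors guard on the number of blank observations
#'   backing each derivation (default 5).
#' @param filter1Strict if `TRUE`, filter 1 removes `reads < tReads`
#'   instead of `reads <= tReads`.
#' @param recomputeStatsAfterFilter1 if `TRUE`, readprop/exprop/norm are
#'   recomputed after filter 1 on blanks, before threshold derivation and
#'   filter 2 (the alternative reading; default `FALSE`, a single up-front
#'   computation).
#' @return list with `filtered` (the decontaminated table, blanks
#'   dropped), `thresholds` (a [FilterThresholds-class]) and `report`
#'   (a data.frame of observation/read counts after every step).
#' @examples
#' \donttest{
#' sim <- simulateDataset(simParams(seed = 1))
#' res <- runBlankFilter(sim$table)
#' res$thresholds
#' res$report
#' }
#' @export
runBlankFilter <- function(table, minBlankErrors = 5,
                           filter1Strict = FALSE,
                           recomputeStatsAfterFilter1 = FALSE) {
  stopifnot(methods::is(table, "ObservationTable"))
  .requireBlanks(table)
  steps <- list()
  note <- function(name, tab) {
    steps[[length(steps) + 1L]] <<- data.frame(
      step = name, n_obs = nObservations(tab), n_reads = totalReads(tab))
  }
  tab <- computeStats(table)
  note("input", tab)
  d1 <- deriveSeqErrorThreshold(tab, minBlankErrors)
  tab <- applySeqErrorFilter(tab, d1$tReads, scope = "blanks",
                             strict = filter1Strict)
  note("filter1_blanks", tab)
  if (recomputeStatsAfterFilter1) tab <- computeStats(tab)
  d2 <- deriveTagjumpThresholds(tab, minBlankErrors)
  tab <- applySeqErrorFilter(tab, d1$tReads, scope = "nonblanks",
                             strict = filter1Strict)
  note("filter1_nonblanks", tab)
  tab <- applyTagjumpFilter(tab, d2$tReadprop, d2$tNorm)
  note("filter2_nonblanks", tab)
  blanks <- blankSamples(tab)
  obs <- tab@obs[!(tab@obs$sample_id %in% blanks), , drop = FALSE]
  smp <- tab@samples[!tab@samples$is_blank, , drop = FALSE]
  rownames(smp) <- NULL
  tab <- methods::new("ObservationTable", obs = obs, samples = smp)
  note("drop_blanks", tab)
  thresholds <- methods::new("FilterThresholds",
    tReads = as.numeric(d1$tReads),
    tReadprop = d2$tReadprop,
    tNorm = d2$tNorm,
    provenance = list(seq_error = d1$provenance,
                      readprop = d2$provenance$readprop,
                      norm = d2$provenance$norm,
                      settings = list(
                        minBlankErrors = minBlankErrors,
                        filter1Strict = filter1Strict,
                        recomputeStatsAfterFilter1 =
                          recomputeStatsAfterFilter1)))
  report <- do.call(rbind, steps)
  message(sprintf(
    "blank filter: tReads = %g, tReadprop = %.9g, tNorm = %.9g",
    thresholds@tReads, thresholds@tReadprop, thresholds@tNorm))
  list(filtered = tab, thresholds = thresholds, report = report)
}

#' @rdname FilterThresholds-accessors
#' @export
setMethod("thresholdReads", "FilterThresholds", function(x) x@tReads)

#' @rdname FilterThresholds-accessors
#' @export
setMethod("thresholdReadprop", "FilterThresholds", function(x) x@tReadprop)

#' @rdname FilterThresholds-accessors
#' @export
setMethod("thresholdNorm", "FilterThresholds", function(x) x@tNorm)

#' Accessors for FilterThresholds
#' @param x a [FilterThresholds-class].
#' @return The corresponding cutoff, or the provenance list.
#' @name FilterThresholds-accessors
NULL

#' @rdname FilterThresholds-accessors
#' @export
setMethod("provenance", "FilterThresholds", function(x) x@provenance)

setMethod("show", "FilterThresholds", function(object) {
  cat("FilterThresholds\n")
  cat(sprintf("  tReads    : %g (max of blank-only unique reads, %d values, fence %.4g)\n",
              object@tReads, object@provenance$seq_error$n,
              object@provenance$seq_error$upperFence))
  cat(sprintf("  tReadprop : %.9g (min outlier of %d blank readprops)\n",
              object@tReadprop, object@provenance$readprop$n))
  cat(sprintf("  tNorm     : %.9g (min outlier of %d blank norms)\n",
              object@tNorm, object@provenance$norm$n))
})

#' Replay threshold provenance
#'
#' Recomputes the three cutoffs from the value vectors stored in a
#' [FilterThresholds-class] provenance record.  The replay must reproduce
#' the thresholds bit-exactly; it is the audit trail for the derivation.
#'
#' @param thresholds a [FilterThresholds-class].
#' @return named numeric vector `c(tReads, tReadprop, tNorm)`.
#' @export
replayThresholds <- function(thresholds) {
  stopifnot(methods::is(thresholds, "FilterThresholds"))
  pv <- thresholds@provenance
  c(tReads = max(tukeyOutliers(pv$seq_error$values)$body),
    tReadprop = min(tukeyOutliers(pv$readprop$values)$outliers),
    tNorm = min(tukeyOutliers(pv$norm$values)$outliers))
}
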