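#' @import methods
NULL

#' ObservationTable: a long-format metabarcoding count table
#'
#' Container for per-observation records of a metabarcoding experiment.
#' An observation is one (ASV, sample) cell with a strictly positive read
#' count; zero cells are never materialised.  Sample metadata flags which
#' index combinations are blanks (unused tag pairs) and optionally assigns
#' a group (site) label.  After [computeStats()] each observation
#' additionally carries `readprop` (its share of the ASV's total reads),
#' `exprop` (the equal-share expectation, 1 / number of observations of the
#' ASV) and `norm` (the relative divergence `(readprop - exprop) / exprop`).
#'
#' @slot obs data.frame with columns `asv_id`, `sample_id`, `reads`
#'   (positive integers) and, once computed, `readprop`, `exprop`, `norm`.
#' @slot samples data.frame with columns `sample_id`, `is_blank` (logical)
#'   and `group` (character, `NA` allowed).
#'
#' @seealso [ObservationTable()] for construction, [computeStats()],
#'   [runBlankFilter()]
#' @export
setClass("ObservationTable",
  slots = c(obs = "data.frame", samples = "data.frame"))

setValidity("ObservationTable", function(object) {
  obs <- object@obs
  smp <- object@samples
  need <- c("asv_id", "sample_id", "reads")
  if (!all(need %in% names(obs))) {
    return(paste("obs must have columns", paste(need, collapse = ", ")))
  }
  if (!all(c("sample_id", "is_blank", "group") %in% names(smp))) {
    return("samples must have columns sample_id, is_blank, group")
  }
  if (nrow(obs) > 0) {
    if (!is.numeric(obs$reads) || anyNA(obs$reads)) {
      return("reads must be numeric and non-missing")
    }
    if (any(obs$reads < 1) || any(obs$reads != round(obs$reads))) {
      return("reads must be positive integers (zero cells are dropped)")
    }
    key <- .obsKey(obs$asv_id, obs$sample_id)
    if (anyDuplicated(key)) {
      dup <- key[duplicated(key)][1L]
      return(paste0("duplicate (asv_id, sample_id) pair: ",
                    gsub("\r", " / ", dup, fixed = TRUE)))
    }
    if (!all(obs$sample_id %in% smp$sample_id)) {
      miss <- setdiff(obs$sample_id, smp$sample_id)
      return(paste("observations reference samples absent from metadata:",
                   paste(utils::head(miss, 5), collapse = ", ")))
    }
  }
  if (anyDuplicated(smp$sample_id)) {
    return("sample_ids must be unique")
  }
  if (!is.logical(smp$is_blank) || anyNA(smp$is_blank)) {
    return("is_blank must be logical and non-missing")
  }
  TRUE
})

#' FilterThresholds: the three blank-derived cutoffs
#'
#' Holds the sequencing-error read-count cutoff (`tReads`), the tag-jump
#' read-proportion cutoff (`tReadprop`) and the tag-jump divergence cutoff
#' (`tNorm`), together with full derivation provenance: for each threshold
#' the blank-observation values it was derived from, the Tukey hinges,
#' the upper fence and the outlier/body split.  Replaying the provenance
#' with [replayThresholds()] reproduces the thresholds bit-exactly.
#'
#' @slot tReads numeric(1), filter-1 cutoff in reads.
#' @slot tReadprop numeric(1), filter-2 proportion cutoff in (0, 1].
#' @slot tNorm numeric(1), filter-2 divergence cutoff, >= -1.
#' @slot provenance list with elements `seq_error`, `readprop`, `norm`.
#' @export
setClass("FilterThresholds",
  slots = c(tReads = "numeric", tReadprop = "numeric", tNorm = "numeric",
            provenance = "list"))

setValidity("FilterThresholds", function(object) {
  if (length(object@tReads) != 1L || object@tReads < 0) {
    return("tReads must be a single non-negative number")
  }
  if (length(object@tReadprop) != 1L ||
      object@tReadprop <= 0 || object@tReadprop > 1) {
    return("tReadprop must lie in (0, 1]")
  }
  if (length(object@tNorm) != 1L || object@tNorm < -1) {
    return("tNorm must be >= -1")
  }
  TRUE
})

#' OtuAssignment: ASV-to-OTU map with one representative per OTU
#'
#' @slot mapping named character; names are ASV ids, values OTU ids.
#' @slot representative named character; names are OTU ids, values the
#'   member ASV chosen to represent the OTU (highest total reads by
#'   default, see [chooseRepresentatives()]).
#' @slot cutoff numeric(1), the complete-linkage distance cutoff (default
#'   0.03, the barcoding gap).
#' @export
setClass("OtuAssignment",
  slots = c(mapping = "character", representative = "character",
            cutoff = "numeric"))

setValidity("OtuAssignment", function(object) {
  m <- object@mapping
  r <- object@representative
  if (is.null(names(m)) || anyDuplicated(names(m))) {
    return("mapping must be named by unique ASV ids")
  }
  if (!setequal(unique(m), names(r))) {
    return("representative must cover exactly the OTU ids in mapping")
  }
  ok <- vapply(names(r), function(o) m[[r[[o]]]] == o, logical(1))
  if (!all(ok)) {
    return("each representative must be a member of its OTU")
  }
  if (length(object@cutoff) != 1L || object@cutoff < 0) {
    return("cutoff must be a single non-negative number")
  }
  TRUE
})

#' SimTruth: generative labels for a simulated observation table
#'
#' One row per observation of the simulated table, labelled `genuine`
#' (a real community cell, possibly with hopped reads mixed in),
#' `tagjump` (a cell created entirely by index hopping) or `seqerror`
#' (an injected spurious single-observation ASV).
#'
#' @slot labels data.frame with columns `asv_id`, `sample_id`, `reads`,
#'   `label`, `hopped_in` (reads received by hopping), `true_reads`
#'   (reads originating in that cell before hopping).
#' @slot params list, the simulation parameters ([simParams()]).
#' @export
setClass("SimTruth",
  slots = c(labels = "data.frame", params = "list"))

setValidity("SimTruth", function(object) {
  lb <- object@labels
  need <- c("asv_id", "sample_id", "reads", "label", "hopped_in",
            "true_reads")
  if (!all(need %in% names(lb))) {
    return(paste("labels must have columns", paste(need, collapse = ", ")))
  }
  if (nrow(lb) > 0 &&
      !all(lb$label %in% c("genuine", "tagjump", "seqerror"))) {
    return("labels must be genuine, tagjump or seqerror")
  }
  TRUE
})
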