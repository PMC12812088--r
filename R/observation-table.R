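#' Construct an ObservationTable
#'
#' Builds the long-format container from an observation data.frame and,
#' optionally, sample metadata.  Zero-read rows are dropped; counts are
#' coerced to integer; samples present in the observations but absent from
#' the metadata default to non-blank with no group.
#'
#' @param obs data.frame with columns `asv_id`, `sample_id`, `reads`.
#'   Extra statistic columns (`readprop`, `exprop`, `norm`) are kept.
#' @param samples optional data.frame with columns `sample_id`,
#'   `is_blank` and optionally `group`.  Samples listed here but carrying
#'   no observation (e.g. empty blanks) are retained in the metadata.
#' @return An [ObservationTable-class] object.
#' @examples
#' obs <- data.frame(asv_id = c("a", "a", "b"),
#'                   sample_id = c("s1", "s2", "s1"),
#'                   reads = c(90, 10, 5))
#' tab <- ObservationTable(obs)
#' nObservations(tab)
#' @export
ObservationTable <- function(obs, samples = NULL) {
  obs <- as.data.frame(obs)
  if (!all(c("asv_id", "sample_id", "reads") %in% names(obs))) {
    .inputError("obs needs columns asv_id, sample_id, reads")
  }
  if (nrow(obs) > 0) {
    if (!is.numeric(obs$reads) || anyNA(obs$reads)) {
      .inputError("reads must be numeric and non-missing")
    }
    if (any(obs$reads < 0)) .inputError("negative read counts")
    if (any(obs$reads != round(obs$reads))) {
      .inputError("read counts must be whole numbers")
    }
    obs$asv_id <- as.character(obs$asv_id)
    obs$sample_id <- as.character(obs$sample_id)
    obs <- obs[obs$reads > 0, , drop = FALSE]
    obs$reads <- as.integer(round(obs$reads))
    key <- .obsKey(obs$asv_id, obs$sample_id)
    if (anyDuplicated(key)) {
      dup <- key[duplicated(key)][1L]
      .inputError("duplicate (asv_id, sample_id) pair: ",
                  gsub("\r", " / ", dup, fixed = TRUE))
    }
    rownames(obs) <- NULL
  }
  if (is.null(samples)) {
    samples <- data.frame(sample_id = character(), is_blank = logical(),
                          group = character())
  }
  samples <- as.data.frame(samples)
  if (!"sample_id" %in% names(samples)) {
    .inputError("samples needs a sample_id column")
  }
  samples$sample_id <- as.character(samples$sample_id)
  if (!"is_blank" %in% names(samples)) samples$is_blank <- FALSE
  samples$is_blank <- .parseLogical(samples$is_blank)
  if (!"group" %in% names(samples)) samples$group <- NA_character_
  samples$group <- as.character(samples$group)
  samples <- samples[, c("sample_id", "is_blank", "group")]
  extra <- setdiff(unique(obs$sample_id), samples$sample_id)
  if (length(extra) > 0) {
    samples <- rbind(samples,
                     data.frame(sample_id = extra, is_blank = FALSE,
                                group = NA_character_))
  }
  rownames(samples) <- NULL
  methods::new("ObservationTable", obs = obs, samples = samples)
}

.parseLogical <- function(x) {
  if (is.logical(x)) return(x)
  out <- tolower(as.character(x)) %in% c("1", "true", "t", "yes")
  bad <- !(tolower(as.character(x)) %in%
             c("0", "1", "true", "false", "t", "f", "yes", "no"))
  if (any(bad)) .inputError("is_blank values must be 0/1/true/false")
  out
}

#' Accessors for ObservationTable
#'
#' @param x an [ObservationTable-class].
#' @return `observations()` the observation data.frame; `sampleData()` the
#'   sample metadata; `nObservations()` the number of (ASV, sample) cells;
#'   `totalReads()` the grand total read count; `blankSamples()` the blank
#'   sample ids; `hasStats()` whether readprop/exprop/norm are present.
#' @name ObservationTable-accessors
NULL

#' @rdname ObservationTable-accessors
#' @export
setMethod("observations", "ObservationTable", function(x) x@obs)

#' @rdname ObservationTable-accessors
#' @export
setMethod("sampleData", "ObservationTable", function(x) x@samples)

#' @rdname ObservationTable-accessors
#' @export
setMethod("nObservations", "ObservationTable", function(x) nrow(x@obs))

#' @rdname ObservationTable-accessors
#' @export
setMethod("totalReads", "ObservationTable",
          function(x) sum(as.numeric(x@obs$reads)))

#' @rdname ObservationTable-accessors
#' @export
setMethod("blankSamples", "ObservationTable",
          function(x) x@samples$sample_id[x@samples$is_blank])

#' @rdname ObservationTable-accessors
#' @export
setMethod("hasStats", "ObservationTable",
          function(x) all(c("readprop", "exprop", "norm") %in%
                            names(x@obs)))

setMethod("show", "ObservationTable", function(object) {
  cat("ObservationTable with", nrow(object@obs), "observations\n")
  cat("  ASVs:    ", length(unique(object@obs$asv_id)), "\n")
  cat("  samples: ", nrow(object@samples), "(",
      sum(object@samples$is_blank), "blank )\n")
  cat("  reads:   ", format(totalReads(object), big.mark = ","), "\n")
  cat("  stats:   ", if (hasStats(object)) "computed" else "absent", "\n")
})

#' Read an observation table from TSV
#'
#' Long layout expects header columns `asv_id`, `sample_id`, `reads`.
#' Wide layout expects a first column `asv_id` and one column of counts
#' per sample; zero cells are dropped when melting.
#'
#' @param path path to a tab-separated file.
#' @param layout `"long"` or `"wide"`.
#' @param samplesPath optional path to a sample-metadata TSV with columns
#'   `sample_id`, `is_blank` (0/1/true/false) and optionally `group`.
#' @return An [ObservationTable-class].
#' @export
readObservationTable <- function(path, layout = c("long", "wide"),
                                 samplesPath = NULL) {
  layout <- match.arg(layout)
  if (!file.exists(path)) .inputError("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = NA)
  if (layout == "long") {
    if (!all(c("asv_id", "sample_id", "reads") %in% names(raw))) {
      .inputError("long table needs columns asv_id, sample_id, reads: ",
                  path)
    }
    if (!is.numeric(raw$reads)) {
      .inputError("non-numeric read counts in ", path)
    }
    obs <- raw[, c("asv_id", "sample_id", "reads")]
  } else {
    if (names(raw)[1] != "asv_id") {
      .inputError("wide table must have first column asv_id: ", path)
    }
    counts <- raw[, -1, drop = FALSE]
    if (!all(vapply(counts, is.numeric, logical(1)))) {
      .inputError("non-numeric read counts in ", path)
    }
    obs <- data.frame(
      asv_id = rep(raw$asv_id, times = ncol(counts)),
      sample_id = rep(names(counts), each = nrow(raw)),
      reads = unlist(counts, use.names = FALSE))
  }
  samples <- NULL
  if (!is.null(samplesPath)) {
    if (!file.exists(samplesPath)) {
      .inputError("file not found: ", samplesPath)
    }
    samples <- utils::read.table(samplesPath, header = TRUE, sep = "\t",
                                 stringsAsFactors = FALSE)
  }
  ObservationTable(obs, samples)
}

#' Write an observation table (long layout) and its sample metadata
#'
#' @param table an [ObservationTable-class].
#' @param path output TSV path for the long table.
#' @param samplesPath optional output TSV path for the sample metadata.
#' @return `path`, invisibly.
#' @export
writeObservationTable <- function(table, path, samplesPath = NULL) {
  stopifnot(methods::is(table, "ObservationTable"))
  utils::write.table(observations(table), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(samplesPath)) {
    utils::write.table(sampleData(table), samplesPath, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Compute per-observation statistics (readprop, exprop, norm)
#'
#' For every observation of every ASV: `readprop` is the share of the
#' ASV's total reads held by that observation (blank samples included in
#' the denominator by default -- the same table the thresholds are derived
#' from); `exprop = 1 / n` where `n` is the number of observations of the
#' ASV, i.e. the proportion expected were the reads spread equally; and
#' `norm = (readprop - exprop) / exprop`, the relative divergence from
#' that expectation.  `norm` is near -1 for observations holding far fewer
#' reads than the equal share -- the signature of a hopped read packet.
#'
#' @param table an [ObservationTable-class].
#' @return The table with `readprop`, `exprop` and `norm` columns filled.
#'   Recomputation on its own output yields identical values.
#' @examples
#' tab <- ObservationTable(data.frame(asv_id = c("a", "a"),
#'                                    sample_id = c("s1", "s2"),
#'                                    reads = c(90, 10)))
#' observations(computeStats(tab))
#' @export
computeStats <- function(table) {
  stopifnot(methods::is(table, "ObservationTable"))
  obs <- table@obs
  if (nrow(obs) == 0) .preconditionError("empty observation table")
  tot <- stats::ave(as.numeric(obs$reads), obs$asv_id, FUN = sum)
  n <- stats::ave(obs$reads, obs$asv_id, FUN = length)
  obs$readprop <- obs$reads / tot
  obs$exprop <- 1 / n
  obs$norm <- (obs$readprop - obs$exprop) / obs$exprop
  methods::initialize(table, obs = obs)
}

#' Drop ASVs below a taxonomic identity threshold
#'
#' Removes all observations of ASVs whose best-hit percent identity to the
#' target clade falls strictly below `minIdentity` (default 84, the
#' empirical clade boundary for the COI fragment).
#'
#' @param table an [ObservationTable-class].
#' @param taxonomy data.frame with columns `asv_id` and `identity`
#'   (percentage in \[0, 100\]); one row per ASV.
#' @param minIdentity numeric threshold; ASVs with `identity <
#'   minIdentity` are removed (strict comparison).
#' @param missing policy for ASVs without a taxonomy record: `"error"`
#'   (default), `"drop"` or `"keep"`.
#' @return The filtered [ObservationTable-class]; retained observations
#'   are untouched.
#' @export
filterByIdentity <- function(table, taxonomy, minIdentity = 84,
                             missing = c("error", "drop", "keep")) {
  stopifnot(methods::is(table, "ObservationTable"))
  missing <- match.arg(missing)
  taxonomy <- as.data.frame(taxonomy)
  if (!all(c("asv_id", "identity") %in% names(taxonomy))) {
    .inputError("taxonomy needs columns asv_id, identity")
  }
  if (anyDuplicated(taxonomy$asv_id)) {
    .inputError("taxonomy must have one record per ASV")
  }
  if (nrow(taxonomy) > 0 &&
      (any(taxonomy$identity < 0) || any(taxonomy$identity > 100))) {
    .inputError("identity must lie in [0, 100]")
  }
  obs <- table@obs
  id <- taxonomy$identity[match(obs$asv_id, taxonomy$asv_id)]
  unknown <- is.na(id)
  if (any(unknown) && missing == "error") {
    .inputError("ASVs without taxonomy record: ",
                paste(utils::head(unique(obs$asv_id[unknown]), 5),
                      collapse = ", "))
  }
  keep <- !is.na(id) & id >= minIdentity
  if (missing == "keep") keep[unknown] <- TRUE
  methods::initialize(table, obs = obs[keep, , drop = FALSE])
}
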