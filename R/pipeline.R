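#' Default pipeline configuration
#'
#' Returns the full configuration list for [runPipeline()] with the
#' standard settings: all four stages enabled on a simulated dataset,
#' identity filter off (simulated ASVs have no taxonomy), 3% clustering
#' cutoff, and group resampling of 20 sites x 1000 iterations.
#'
#' @param ... named overrides of the defaults (nested lists are merged
#'   per field).
#' @return configuration list.
#' @export
defaultConfig <- function(...) {
  cfg <- list(
    stages = c("simulate", "filter", "cluster", "diversity"),
    seed = 42,
    sim = list(),                 # overrides for simParams()
    input = list(table = NULL, samples = NULL, alignment = NULL,
                 tree = NULL, taxonomy = NULL),
    filter = list(minBlankErrors = 5, filter1Strict = FALSE,
                  recomputeStatsAfterFilter1 = FALSE,
                  minIdentity = 84),
    cluster = list(cutoff = 0.03, model = "raw"),
    diversity = list(nSites = 20, nIter = 1000,
                     meanPairwise = FALSE, includeRoot = TRUE))
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(cfg[[nm]]) && is.list(over[[nm]])) {
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    } else {
      cfg[[nm]] <- over[[nm]]
    }
  }
  cfg
}

.writeJson <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
}

#' Run the simulate - filter - cluster - diversity pipeline
#'
#' Executes the enabled stages in order with a single configuration and
#' writes every artifact (tables, thresholds, OTU map, community matrix,
#' trees, diversity outputs, resolved configuration and a machine-readable
#' run report) under `outDir`.  With identical configuration and seed the
#' written artifacts are byte-identical across runs; stage wall-clock
#' times are therefore kept in the returned report object only, not in
#' the serialized `report.json`.
#'
#' @param config configuration list from [defaultConfig()], or a path to
#'   a YAML file with the same structure.  When the `simulate` stage is
#'   disabled, `input$table`/`input$samples` (long TSV + metadata TSV)
#'   and, for later stages, `input$alignment` / `input$tree` must point
#'   to existing files.
#' @param outDir output directory (created if needed).
#' @return the run report: per-stage observation/ASV/OTU/read counts,
#'   derived thresholds, filter score (when ground truth exists) and
#'   stage timings.
#' @examples
#' \donttest{
#' rep <- runPipeline(defaultConfig(seed = 7,
#'                                  diversity = list(nIter = 50)),
#'                    outDir = tempfile())
#' rep$stages$filter$thresholds
#' }
#' @export
runPipeline <- function(config = defaultConfig(), outDir) {
  if (is.character(config)) {
    if (!file.exists(config)) .inputError("config file not found: ",
                                          config)
    config <- do.call(defaultConfig, yaml::read_yaml(config))
  }
  if (missing(outDir) || is.null(outDir)) {
    .inputError("outDir is required")
  }
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  report <- list(package = "jumpsieve",
                 version = as.character(utils::packageVersion("jumpsieve")),
                 stages = list())
  timings <- c()
  tick <- function(expr) {
    t0 <- proc.time()[["elapsed"]]
    value <- force(expr)
    list(value = value, secs = proc.time()[["elapsed"]] - t0)
  }
  yaml::write_yaml(.configForYaml(config), file.path(outDir, "config.yaml"))

  stages <- config$stages
  table <- NULL; truth <- NULL; alignment <- NULL; tree <- NULL

  if ("simulate" %in% stages) {
    st <- tick({
      params <- do.call(simParams, c(config$sim,
                                     if (is.null(config$sim$seed))
                                       list(seed = config$seed)))
      simulateDataset(params)
    })
    sim <- st$value
    table <- sim$table; truth <- sim$truth
    alignment <- sim$alignment; tree <- sim$tree
    writeObservationTable(table, file.path(outDir, "obs.tsv"),
                          file.path(outDir, "meta.tsv"))
    utils::write.table(truthLabels(truth),
                       file.path(outDir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    ape::write.FASTA(alignment, file.path(outDir, "asvs.aln.fasta"))
    ape::write.tree(tree, file.path(outDir, "asvs.nwk"))
    .writeJson(unclass(sim$params), file.path(outDir, "params.json"))
    report$stages$simulate <- list(
      n_obs = nObservations(table),
      n_asvs = length(unique(observations(table)$asv_id)),
      n_samples = nrow(sampleData(table)),
      n_blanks = length(blankSamples(table)),
      n_reads = totalReads(table))
    timings["simulate"] <- st$secs
  } else {
    if (is.null(config$input$table)) {
      .preconditionError("stage filter: no simulate stage and no ",
                         "input$table provided")
    }
    table <- readObservationTable(config$input$table, "long",
                                  config$input$samples)
    if (!is.null(config$input$alignment)) {
      alignment <- ape::read.FASTA(config$input$alignment)
    }
    if (!is.null(config$input$tree)) {
      tree <- ape::read.tree(config$input$tree)
    }
  }

  filtered <- table
  if ("filter" %in% stages) {
    st <- tick({
      if (!is.null(config$input$taxonomy)) {
        tax <- utils::read.table(config$input$taxonomy, header = TRUE,
                                 sep = "\t", stringsAsFactors = FALSE)
        table <- filterByIdentity(table, tax,
                                  config$filter$minIdentity)
      }
      runBlankFilter(table,
                     minBlankErrors = config$filter$minBlankErrors,
                     filter1Strict = config$filter$filter1Strict,
                     recomputeStatsAfterFilter1 =
                       config$filter$recomputeStatsAfterFilter1)
    })
    res <- st$value
    filtered <- res$filtered
    writeObservationTable(filtered, file.path(outDir, "filtered.tsv"))
    .writeJson(list(tReads = thresholdReads(res$thresholds),
                    tReadprop = thresholdReadprop(res$thresholds),
                    tNorm = thresholdNorm(res$thresholds)),
               file.path(outDir, "thresholds.json"))
    utils::write.table(res$report, file.path(outDir, "filter_steps.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$stages$filter <- list(
      steps = res$report,
      thresholds = list(tReads = thresholdReads(res$thresholds),
                        tReadprop = thresholdReadprop(res$thresholds),
                        tNorm = thresholdNorm(res$thresholds)),
      n_obs = nObservations(filtered),
      n_asvs = length(unique(observations(filtered)$asv_id)),
      n_reads = totalReads(filtered))
    if (!is.null(truth)) {
      score <- scoreFilter(truth, filtered,
                           minReads = thresholdReads(res$thresholds))
      report$stages$filter$score <- score
    }
    timings["filter"] <- st$secs
  }

  cm <- NULL; otuTree <- NULL
  if ("cluster" %in% stages) {
    if (is.null(alignment)) {
      .preconditionError("stage cluster: no alignment available; ",
                         "enable simulate or set input$alignment")
    }
    st <- tick({
      keepIds <- unique(observations(filtered)$asv_id)
      aln <- alignment[intersect(labels(alignment), keepIds), ]
      dm <- pairwiseDistances(aln, model = config$cluster$model)
      assignment <- clusterCompleteLinkage(dm, config$cluster$cutoff)
      assignment <- chooseRepresentatives(assignment, filtered)
      list(assignment = assignment,
           cm = aggregateToOtus(filtered, assignment),
           otuTree = if (!is.null(tree))
             collapseTree(tree, assignment))
    })
    assignment <- st$value$assignment
    cm <- st$value$cm
    otuTree <- st$value$otuTree
    map <- data.frame(asv_id = names(otuMapping(assignment)),
                      otu_id = unname(otuMapping(assignment)))
    map$is_representative <-
      otuRepresentatives(assignment)[map$otu_id] == map$asv_id
    utils::write.table(map[order(map$otu_id, map$asv_id), ],
                       file.path(outDir, "otu_map.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(data.frame(sample_id = rownames(cm), cm,
                                  check.names = FALSE),
                       file.path(outDir, "otu_matrix.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if (!is.null(otuTree)) {
      ape::write.tree(otuTree, file.path(outDir, "otus.nwk"))
    }
    report$stages$cluster <- list(
      n_asvs = length(otuMapping(assignment)),
      n_otus = length(otuRepresentatives(assignment)),
      cutoff = config$cluster$cutoff,
      n_reads = sum(as.numeric(cm)))
    timings["cluster"] <- st$secs
  }

  if ("diversity" %in% stages) {
    if (is.null(cm)) {
      .preconditionError("stage diversity: no community matrix; ",
                         "enable the cluster stage")
    }
    st <- tick({
      rich <- richness(cm)
      depth <- rowSums(cm)
      alpha <- data.frame(sample_id = rownames(cm), richness = rich,
                          depth = depth)
      pd <- NULL
      if (!is.null(otuTree)) {
        pd <- faithPd(cm, otuTree,
                      includeRoot = config$diversity$includeRoot)
        alpha$pd <- pd
      }
      resR <- depthResiduals(rich, depth)
      alpha$residual_richness_raw <- resR$raw
      alpha$residual_richness <- resR$scaled
      if (!is.null(pd)) {
        resP <- depthResiduals(pd, depth)
        alpha$residual_pd_raw <- resP$raw
        alpha$residual_pd <- resP$scaled
      }
      groups <- sampleData(filtered)$group[
        match(rownames(cm), sampleData(filtered)$sample_id)]
      pairs <- utils::combn(nrow(cm), 2)
      pw <- t(apply(pairs, 2, function(p) betaPairwise(cm, p[1], p[2])))
      pw <- data.frame(sample_i = rownames(cm)[pairs[1, ]],
                       sample_j = rownames(cm)[pairs[2, ]], pw)
      multi <- lapply(split(seq_len(nrow(cm)), groups), function(idx)
        as.list(betaMultisite(cm[idx, , drop = FALSE])))
      draws <- betaResample(cm, groups,
                            nSites = config$diversity$nSites,
                            nIter = config$diversity$nIter,
                            seed = config$seed,
                            meanPairwise = config$diversity$meanPairwise)
      venn <- exclusiveOtus(cm, groups)
      list(alpha = alpha, pw = pw, multi = multi, draws = draws,
           venn = venn)
    })
    dv <- st$value
    utils::write.table(dv$alpha, file.path(outDir, "alpha.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(dv$pw, file.path(outDir, "beta_pairwise.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    .writeJson(dv$multi, file.path(outDir, "beta_multisite.json"))
    drawsLong <- do.call(rbind, lapply(names(dv$draws), function(g)
      data.frame(group = g, iter = seq_len(nrow(dv$draws[[g]])),
                 dv$draws[[g]])))
    utils::write.table(drawsLong,
                       file.path(outDir, "resample_draws.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    .writeJson(list(exclusive = as.list(dv$venn$exclusive),
                    regions = as.list(dv$venn$regions),
                    pooled_richness = dv$venn$pooledRichness),
               file.path(outDir, "venn.json"))
    report$stages$diversity <- list(
      n_samples = nrow(cm),
      mean_richness = mean(dv$alpha$richness),
      mean_pd = if (!is.null(dv$alpha$pd)) mean(dv$alpha$pd),
      pooled_richness = dv$venn$pooledRichness,
      multisite = dv$multi)
    timings["diversity"] <- st$secs
  }

  .writeJson(.reportForJson(report), file.path(outDir, "report.json"))
  report$timings_s <- as.list(timings)
  invisible(report)
}

# drop non-deterministic / non-serialisable bits before writing
.reportForJson <- function(report) {
  if (!is.null(report$stages$filter$score)) {
    sc <- report$stages$filter$score
    report$stages$filter$score <- list(
      tagjump_sensitivity = sc$tagjumpSensitivity,
      genuine_specificity = sc$genuineSpecificity,
      error_sensitivity = sc$errorSensitivity,
      genuine_specificity_above_threshold = sc$genuineSpecificityAbove)
  }
  report
}

.configForYaml <- function(config) {
  rapply(config, function(x) x, how = "replace")
}
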