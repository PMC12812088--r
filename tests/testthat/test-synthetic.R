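smallParams <- function(...) {
  simParams(nSites = 2, samplesPerSite = 3, nBlanks = 2, nSpecies = 10,
            asvsPerSpecies = 2, meanDepth = 2000, nErrorAsvs = 10, ...)
}

test_that("community simulation honours occupancy, blanks and the seed", {
  p <- smallParams(occupancy = 1, seed = 3)
  tab <- simulateCommunity(p)
  obs <- observations(tab)
  meta <- sampleData(tab)
  # saturation: every ASV appears at every site (union over site samples)
  for (g in unique(na.omit(meta$group))) {
    inSite <- unique(obs$asv_id[obs$sample_id %in%
                                  meta$sample_id[meta$group == g]])
    expect_length(inSite, p$nSpecies * p$asvsPerSpecies)
  }
  # blanks carry no true reads
  expect_false(any(obs$sample_id %in% blankSamples(tab)))
  expect_equal(length(blankSamples(tab)), 2L)
  # reproducibility and seed sensitivity
  expect_equal(observations(simulateCommunity(p)), obs)
  expect_false(identical(
    observations(simulateCommunity(p, seed = 4)), obs))
})

test_that("nested site mode yields strictly nested species pools", {
  p <- smallParams(nestedSites = TRUE, occupancy = 0.4, seed = 8)
  tab <- simulateCommunity(p)
  obs <- observations(tab)
  meta <- sampleData(tab)
  species <- function(g) unique(sub("_a\\d+$", "",
    obs$asv_id[obs$sample_id %in% meta$sample_id[meta$group %in% g]]))
  s1 <- species("Site1")
  s2 <- species("Site2")
  expect_true(all(s2 %in% s1))
  expect_gt(length(s1), length(s2))
})

test_that("tag-jump injection conserves reads and labels correctly", {
  p <- smallParams(seed = 12)
  true <- simulateCommunity(p)
  for (s in c(1, 2, 3)) {
    tj <- injectTagJumps(true, 0.05, seed = s)
    expect_equal(totalReads(tj$table), totalReads(true))
    lb <- truthLabels(tj$truth)
    expect_equal(sum(lb$reads), totalReads(true))
    expect_true(all(lb$label %in% c("genuine", "tagjump")))
    # tagjump rows are pure hops; genuine rows existed before hopping
    expect_true(all(lb$true_reads[lb$label == "tagjump"] == 0))
    expect_true(all(lb$true_reads[lb$label == "genuine"] > 0))
    expect_true(all(lb$reads == lb$hopped_in |
                      lb$label == "genuine"))
  }
  # identity at zero hop probability
  same <- injectTagJumps(true, 0, seed = 1)
  expect_equal(observations(same$table), observations(true))
  expect_false(any(truthLabels(same$truth)$label == "tagjump"))
  # saturation: with certain hopping no read stays at its origin
  all_ <- injectTagJumps(true, 1, seed = 1)
  lbAll <- truthLabels(all_$truth)
  expect_true(all(lbAll$reads == lbAll$hopped_in))
  expect_equal(sum(lbAll$reads), totalReads(true))
})

test_that("hopped reads reaching blanks match the binomial expectation", {
  p <- smallParams(seed = 2)
  true <- simulateCommunity(p)
  total <- totalReads(true)
  nCombos <- nrow(sampleData(true))
  nBlanks <- length(blankSamples(true))
  pJump <- 0.03
  pBlank <- pJump * nBlanks / (nCombos - 1)
  draws <- vapply(1:30, function(s) {
    tj <- injectTagJumps(true, pJump, seed = 1000 + s)
    lb <- truthLabels(tj$truth)
    sum(lb$hopped_in[lb$sample_id %in% blankSamples(true)])
  }, numeric(1))
  expected <- total * pBlank
  mcSE <- sqrt(total * pBlank * (1 - pBlank)) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - expected), 3 * mcSE)
})

test_that("error injection adds unique single-sample ASVs", {
  p <- smallParams(seed = 15)
  tab <- simulateCommunity(p)
  se <- injectSeqErrors(tab, 10, 0.3, seed = 16)
  obs <- observations(se$table)
  errRows <- obs[grepl("^ERR_", obs$asv_id), ]
  expect_equal(nrow(errRows), 10L)
  expect_equal(anyDuplicated(errRows$asv_id), 0L)
  # exactly one observation each: readprop is 1 after stats
  st <- observations(computeStats(se$table))
  expect_true(all(st$readprop[grepl("^ERR_", st$asv_id)] == 1))
  lb <- truthLabels(se$truth)
  expect_equal(sum(lb$label == "seqerror"), 10L)
  # identity case
  none <- injectSeqErrors(tab, 0, 0.3, seed = 1)
  expect_equal(observations(none$table), observations(tab))
})

test_that("error read counts follow the shifted geometric mean", {
  p <- smallParams(seed = 18)
  tab <- simulateCommunity(p)
  reads <- unlist(lapply(1:40, function(s) {
    se <- injectSeqErrors(tab, 25, 0.3, seed = 3000 + s)
    obs <- observations(se$table)
    obs$reads[grepl("^ERR_", obs$asv_id)]
  }))
  expect_equal(mean(reads), 1 / 0.3, tolerance = 0.08)
})

test_that("sequence simulation separates species by construction", {
  sq <- simulateSequences(nSpecies = 6, asvsPerSpecies = 3,
                          dWithin = 0.01, dBetween = 0.08,
                          length = 400, seed = 5)
  dm <- pairwiseDistances(sq$alignment)
  sameSp <- outer(sq$partition[rownames(dm)],
                  sq$partition[colnames(dm)], "==")
  offdiag <- !diag(nrow(dm))
  expect_lt(max(dm[sameSp & offdiag]), 0.03)
  expect_gt(min(dm[!sameSp]), 0.03)
  expect_true(ape::is.rooted(sq$tree))
  expect_setequal(sq$tree$tip.label, rownames(dm))

  # single-ASV species must come back as singletons
  solo <- simulateSequences(nSpecies = 5, asvsPerSpecies = 1,
                            length = 300, seed = 6)
  m <- otuMapping(clusterCompleteLinkage(
    pairwiseDistances(solo$alignment), 0.03))
  expect_length(unique(m), 5L)

  # byte-level reproducibility
  a1 <- simulateSequences(nSpecies = 4, seed = 9)
  a2 <- simulateSequences(nSpecies = 4, seed = 9)
  expect_identical(as.character(a1$alignment),
                   as.character(a2$alignment))
  expect_identical(ape::write.tree(a1$tree), ape::write.tree(a2$tree))

  expect_error(simulateSequences(nSpecies = 10, dBetween = 0.5,
                                 length = 100),
               class = "jumpsieve_input_error")
})

test_that("filter scoring tallies the confusion table exactly", {
  labels <- data.frame(
    asv_id = c("g1", "g2", "g3", "t1", "t2", "e1"),
    sample_id = "s1",
    reads = c(50L, 20L, 5L, 3L, 2L, 1L),
    label = c("genuine", "genuine", "genuine", "tagjump", "tagjump",
              "seqerror"),
    hopped_in = c(0L, 0L, 0L, 3L, 2L, 0L),
    true_reads = c(50L, 20L, 5L, 0L, 0L, 0L))
  truth <- methods::new("SimTruth", labels = labels, params = list())
  meta <- data.frame(sample_id = "s1", is_blank = FALSE, group = NA)
  keep <- function(ids) ObservationTable(
    labels[labels$asv_id %in% ids, c("asv_id", "sample_id", "reads")],
    meta)

  sAll <- scoreFilter(truth, keep(labels$asv_id))
  expect_equal(sAll$tagjumpSensitivity, 0)
  expect_equal(sAll$genuineSpecificity, 1)
  sNone <- scoreFilter(truth, keep(character(0)))
  expect_equal(sNone$tagjumpSensitivity, 1)
  expect_equal(sNone$genuineSpecificity, 0)
  expect_equal(sNone$errorSensitivity, 1)

  # hand tally: keep g1, g2, t1 -> 1/2 tagjump removed, 2/3 genuine kept
  s <- scoreFilter(truth, keep(c("g1", "g2", "t1")), minReads = 10)
  expect_equal(s$tagjumpSensitivity, 0.5)
  expect_equal(s$genuineSpecificity, 2 / 3)
  expect_equal(s$errorSensitivity, 1)
  expect_equal(s$genuineSpecificityAbove, 1)  # g1, g2 above 10 reads
  expect_equal(as.vector(s$confusion["genuine", c("removed",
                                                  "retained")]),
               c(1, 2))

  alien <- ObservationTable(data.frame(asv_id = "zz", sample_id = "s1",
                                       reads = 1), meta)
  expect_error(scoreFilter(truth, alien), "absent",
               class = "jumpsieve_input_error")
})

test_that("the default benchmark scenario is well-posed", {
  sim <- simulateDataset(simParams())
  tab <- sim$table
  expect_equal(nrow(sampleData(tab)), 28L)
  expect_equal(length(blankSamples(tab)), 4L)
  obs <- observations(tab)
  # blanks are nonempty and the derivation preconditions hold
  expect_gt(sum(obs$sample_id %in% blankSamples(tab)), 0)
  st <- computeStats(tab)
  expect_no_error(deriveSeqErrorThreshold(st))
  # truth covers the table exactly
  lb <- truthLabels(sim$truth)
  expect_equal(sort(paste(lb$asv_id, lb$sample_id)),
               sort(paste(obs$asv_id, obs$sample_id)))
  expect_equal(sum(lb$reads), totalReads(tab))
})
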