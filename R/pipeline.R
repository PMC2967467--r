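# End-to-end orchestration: simulate -> SL -> graphs -> metrics -> group
# statistics, with plain-TSV outputs and a reproducible run manifest.

.groupMeanSync <- function(matrices, groups, group) {
  sel <- matrices[groups == group]
  m <- Reduce(`+`, lapply(sel, syncValues)) / length(sel)
  syncMatrix(m)
}

.summaryRow <- function(roiSet, parameter, patient, control) {
  tt <- stats::t.test(patient, control, var.equal = TRUE)
  data.frame(roi_set = roiSet, parameter = parameter,
             mean_patient = mean(patient), sd_patient = stats::sd(patient),
             mean_control = mean(control), sd_control = stats::sd(control),
             t = unname(tt$statistic), p = tt$p.value,
             stringsAsFactors = FALSE)
}

#' Run the full synchronization-graph pipeline
#'
#' Simulates (or accepts) a two-group cohort, computes every subject's
#' synchronization matrix, sweeps binary graphs over threshold (T) and
#' mean-degree (K) grids with surrogate-corrected small-world metrics,
#' and compares the groups: a summary table of S, gamma and lambda (the
#' latter two at `summaryK`), per-level t statistics, a cluster-based
#' permutation test across the K grid, and the pairwise regional
#' synchronization difference map aggregated by lobe blocks.  The
#' analysis is run for each requested ROI set — all regions and,
#' optionally, the set excluding the cerebellum.
#'
#' All randomness derives from `config`'s master seed, so rerunning with
#' the same configuration is bit-identical; no timestamps are written.
#'
#' @param config a [CohortConfig-class].
#' @param registry ROI registry covering the config's regions (default
#'   the bundled atlas).
#' @param outDir optional output directory; when given, all results are
#'   written as TSV/text files (fail-fast; no partial rewriting logic).
#' @param subjects optional precomputed cohort (list of
#'   [RegionalTimeSeries-class]); when NULL the cohort is simulated from
#'   `config`.
#' @param params an [SlParams-class].
#' @param tLevels,kLevels threshold and mean-degree grids.
#' @param nSurrogates rewired surrogates per subject and level.
#' @param nPermutations Monte-Carlo permutations for the cluster test.
#' @param alpha uncorrected significance level for the regional map.
#' @param clusterMetric metrics column the cluster test runs on
#'   (default `"lambda"`).
#' @param summaryK mean degree at which the summary table reports gamma
#'   and lambda (must be on `kLevels`).
#' @param excludeCerebellarSet if TRUE (default) the analysis is repeated
#'   on the ROI set without cerebellar regions.
#' @return A list with `subjects`, `syncMatrices`, `groups`, `metrics`
#'   (long data.frame over ROI sets, modes and levels), `summary`
#'   (Table-style data.frame), `clusterTest` (per ROI set), `regionalMap`,
#'   `blockCounts`, `manifest`.
#' @export
runPipeline <- function(config, registry = aalRegistry(), outDir = NULL,
                        subjects = NULL, params = slParams(),
                        tLevels = seq(0.01, 0.05, by = 0.01),
                        kLevels = 5:15, nSurrogates = 50L,
                        nPermutations = 5000L, alpha = 0.05,
                        clusterMetric = "lambda", summaryK = 10,
                        excludeCerebellarSet = TRUE) {
  stopifnot(is(config, "CohortConfig"))
  regions <- names(config@blockMap)
  if (!all(regions %in% registry$region))
    stop("registry does not cover the configured regions")
  if (!summaryK %in% kLevels)
    stop("'summaryK' must be one of 'kLevels'")
  if (is.null(subjects))
    subjects <- simulateCohort(config)
  groups <- vapply(subjects, subjectGroup, character(1))

  syncs <- lapply(subjects, slMatrix, params = params)

  registry <- registry[match(regions, registry$region), , drop = FALSE]
  roiSets <- list(all = regions)
  if (excludeCerebellarSet && any(registry$cerebellum))
    roiSets$noCerebellum <- regions[!registry$cerebellum]

  metricsAll <- list()
  summaryAll <- list()
  clusterTests <- list()
  for (si in seq_along(roiSets)) {
    setName <- names(roiSets)[si]
    labs <- roiSets[[si]]
    sub <- lapply(syncs, function(m)
      syncMatrix(syncValues(m)[labs, labs, drop = FALSE]))
    S <- vapply(sub, globalSyncMean, numeric(1))
    mk <- cohortMetrics(sub, groups, mode = "K", levels = kLevels,
                        nSurrogates = nSurrogates,
                        seed = config@seed + 100000L * si)
    mt <- cohortMetrics(sub, groups, mode = "T", levels = tLevels,
                        nSurrogates = nSurrogates,
                        seed = config@seed + 100000L * si + 50000L)
    m <- rbind(mk, mt)
    m$roi_set <- setName
    metricsAll[[setName]] <- m

    atK <- mk[mk$level == summaryK, ]
    pat <- atK$group == "patient"
    summaryAll[[setName]] <- rbind(
      .summaryRow(setName, "S", S[groups == "patient"],
                  S[groups == "control"]),
      .summaryRow(setName, "gamma", atK$gamma[pat], atK$gamma[!pat]),
      .summaryRow(setName, "lambda", atK$lambda[pat], atK$lambda[!pat]))

    byLevel <- metricByLevel(mk, clusterMetric)
    clusterTests[[setName]] <- clusterPermutationTest(
      byLevel$patient, byLevel$control, levels = sort(unique(mk$level)),
      nPermutations = nPermutations, seed = config@seed + 99991L)
  }
  metrics <- do.call(rbind, metricsAll)
  rownames(metrics) <- NULL
  summary <- do.call(rbind, summaryAll)
  rownames(summary) <- NULL

  regionalMap <- regionalDifferenceMap(syncs[groups == "patient"],
                                       syncs[groups == "control"],
                                       alpha = alpha)
  blockCounts <- blockSummary(regionalMap, registry)

  manifest <- list(
    package = "SLgraph",
    version = as.character(utils::packageVersion("SLgraph")),
    seed = config@seed, n_control = config@nControl,
    n_patient = config@nPatient, n_regions = length(regions),
    n_timepoints = config@nTimepoints,
    sl_lag = params@lag, sl_dim = params@dim, sl_theiler = params@theiler,
    sl_pref = params@pref, t_levels = tLevels, k_levels = kLevels,
    n_surrogates = nSurrogates, n_permutations = nPermutations,
    alpha = alpha, summary_k = summaryK,
    roi_sets = names(roiSets), cluster_metric = clusterMetric)

  result <- list(subjects = subjects, syncMatrices = syncs,
                 groups = groups, metrics = metrics, summary = summary,
                 clusterTests = clusterTests, regionalMap = regionalMap,
                 blockCounts = blockCounts, manifest = manifest)
  if (!is.null(outDir))
    .writePipelineOutputs(result, registry, outDir)
  invisible(result)
}

.writePipelineOutputs <- function(result, registry, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  syncDir <- file.path(outDir, "sync")
  dir.create(syncDir, showWarnings = FALSE)
  for (id in names(result$syncMatrices))
    writeSyncMatrix(result$syncMatrices[[id]],
                    file.path(syncDir, paste0(id, "_sl.tsv")))
  for (g in unique(result$groups))
    writeSyncMatrix(.groupMeanSync(result$syncMatrices, result$groups, g),
                    file.path(outDir, paste0("group_mean_sl_", g, ".tsv")))
  utils::write.table(result$metrics, file.path(outDir, "metrics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(result$summary, file.path(outDir, "summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (setName in names(result$clusterTests)) {
    ct <- result$clusterTests[[setName]]
    txt <- utils::capture.output(print(ct))
    writeLines(txt, file.path(outDir,
                              paste0("cluster_test_", setName, ".txt")))
    .writeKeyValue(list(max_stat = ct$maxStat, p_value = ct$pValue,
                        n_permutations = ct$nPermutations,
                        exhaustive = ct$exhaustive, df = ct$df,
                        threshold = ct$threshold),
                   file.path(outDir,
                             paste0("cluster_test_", setName, ".kv")))
  }
  utils::write.table(result$regionalMap$signs,
                     file.path(outDir, "regional_diff_signs.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  utils::write.table(result$blockCounts,
                     file.path(outDir, "block_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  .writeKeyValue(result$manifest, file.path(outDir, "run_manifest.kv"))
  invisible(outDir)
}
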