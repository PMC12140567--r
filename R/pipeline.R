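#' Configuration for a full multiplex analysis run
#'
#' @param modalityPaths Named vector modality -> input table path (omit when
#'   a cohort object is passed to \code{\link{runAnalysis}} directly).
#' @param atlas A \linkS4class{RoiAtlas}, or one of \code{"DK68"} /
#'   \code{"Destrieux148"}.
#' @param comparisons List of 2-long character vectors, each a (groupA,
#'   groupB) pair; differences are reported as A minus B.
#' @param measures Multiplex measures to test.
#' @param thresholds Strictly increasing sweep inside (0, 1); default the
#'   densities 0.40 to 0.70 in steps of 0.05.
#' @param thresholdMode \code{"density"} or \code{"absolute"}.
#' @param nPermutations Permutations per test (default 5000, minimum 100).
#' @param fdrQ FDR level for nodal results (default 0.05).
#' @param seed Master seed; each comparison gets the child seed
#'   \code{seed + 10007 * comparison_index} so independent comparisons never
#'   share a permutation stream.
#' @param outputDir Directory for CSV/JSON outputs (created if missing);
#'   \code{NULL} suppresses writing.
#' @return A validated list of class \code{"RunConfig"}.
#' @export
runConfig <- function(modalityPaths = NULL, atlas = "DK68",
                      comparisons,
                      measures = c("global_mpc", "nodal_mpc",
                                   "global_overlapping_degree"),
                      thresholds = seq(0.40, 0.70, by = 0.05),
                      thresholdMode = c("density", "absolute"),
                      nPermutations = 5000L, fdrQ = 0.05, seed = 1L,
                      outputDir = NULL) {
  thresholdMode <- match.arg(thresholdMode)
  if (is.character(atlas))
    atlas <- switch(atlas, DK68 = dkAtlas(),
                    Destrieux148 = destrieuxAtlas(),
                    stop("unknown atlas '", atlas, "'"))
  if (!is.list(comparisons)) comparisons <- list(comparisons)
  stopifnot(all(lengths(comparisons) == 2L))
  if (any(diff(thresholds) <= 0) || any(thresholds <= 0) ||
      any(thresholds >= 1))
    stop("thresholds must be strictly increasing within (0, 1)")
  if (nPermutations < 100L) stop("nPermutations must be >= 100")
  measures <- match.arg(measures, several.ok = TRUE)
  structure(list(modalityPaths = modalityPaths, atlas = atlas,
                 comparisons = comparisons, measures = measures,
                 thresholds = thresholds, thresholdMode = thresholdMode,
                 nPermutations = as.integer(nPermutations), fdrQ = fdrQ,
                 seed = as.integer(seed), outputDir = outputDir),
            class = "RunConfig")
}

#' Run the full multiplex analysis
#'
#' Orchestrates residualize -> group correlation -> threshold sweep -> supra
#' assembly -> multiplex measures -> permutation comparison -> FDR for every
#' configured (comparison, measure, threshold) cell, and (optionally) writes
#' per-group-per-threshold measure CSVs, one comparison CSV per group pair,
#' and a JSON manifest recording the seed derivation, package version, and
#' the analysis conventions in force (threshold mode, negative-edge removal,
#' FDR family). A rerun with the same config reproduces every output
#' bit-identically.
#'
#' @param config A \code{\link{runConfig}}.
#' @param cohort Optional \linkS4class{CohortTable}; when \code{NULL} the
#'   cohort is read from \code{config$modalityPaths}.
#' @return (Invisibly) list with \code{measures} (data.frame of nodal
#'   measures per group and threshold), \code{comparisons} (named list of
#'   comparison data.frames), and \code{manifest}.
#' @export
runAnalysis <- function(config, cohort = NULL) {
  stopifnot(inherits(config, "RunConfig"))
  if (is.null(cohort)) {
    if (is.null(config$modalityPaths))
      stop("stage input: no cohort given and no modalityPaths in config")
    cohort <- tryCatch(readCohort(config$modalityPaths, config$atlas),
                       error = function(e)
                         stop("stage cohort_io: ", conditionMessage(e),
                              call. = FALSE))
  }
  groupsNeeded <- unique(unlist(config$comparisons))
  cohorts <- tryCatch(splitByGroup(cohort, groupsNeeded),
                      error = function(e)
                        stop("stage cohort_io: ", conditionMessage(e),
                             call. = FALSE))

  # descriptive per-group measures at every threshold (full-group pipeline,
  # residualized on the whole analysis sample)
  resid <- tryCatch(residualizeCohort(cohort),
                    error = function(e)
                      stop("stage residualization: ", conditionMessage(e),
                           call. = FALSE))
  measureRows <- list()
  for (g in groupsNeeded) {
    sub <- resid[, colData(resid)$group == g]
    layersW <- lapply(modalities(sub), function(m)
      groupCorrelation(t(assay(sub, m)), m, g))
    names(layersW) <- modalities(sub)
    for (d in config$thresholds) {
      bin <- lapply(layersW, thresholdBinarize, d = d,
                    mode = config$thresholdMode)
      net <- buildSupra(bin, threshold = d,
                        thresholdMode = config$thresholdMode)
      mm <- multiplexMeasures(net)
      measureRows[[length(measureRows) + 1L]] <-
        cbind(group = g, threshold = d, mm$nodal,
              global_mpc = mm$global_mpc,
              global_overlapping_degree = mm$global_overlapping_degree)
    }
  }
  measureTab <- do.call(rbind, measureRows)

  comparisonTabs <- list()
  for (ci in seq_along(config$comparisons)) {
    pair <- config$comparisons[[ci]]
    childSeed <- (config$seed + 10007L * ci) %% .Machine$integer.max
    rows <- list()
    for (meas in config$measures)
      for (d in config$thresholds)
        rows[[length(rows) + 1L]] <- tryCatch(
          permutationTest(cohorts[[pair[1L]]], cohorts[[pair[2L]]],
                          measure = meas, d = d,
                          mode = config$thresholdMode,
                          nPerm = config$nPermutations, seed = childSeed,
                          fdrQ = config$fdrQ),
          error = function(e)
            stop("stage group_comparison (", pair[1L], " vs ", pair[2L],
                 ", ", meas, ", d = ", d, "): ", conditionMessage(e),
                 call. = FALSE))
    comparisonTabs[[paste(pair, collapse = "_vs_")]] <- do.call(rbind, rows)
  }

  manifest <- list(
    package = "multiplexSCN",
    version = as.character(utils::packageVersion("multiplexSCN")),
    seed = config$seed,
    child_seed_rule = "seed + 10007 * comparison_index",
    atlas = atlasName(config$atlas),
    n_regions = nRegions(config$atlas),
    modalities = modalities(cohort),
    groups = vapply(groupsNeeded, function(g) ncol(cohorts[[g]]), 0L),
    thresholds = config$thresholds,
    threshold_mode = config$thresholdMode,
    negative_edges = "set to zero before thresholding",
    edge_rounding = "round half away from zero of d * n(n-1)/2",
    tie_break = "stable (-weight, i, j) lexicographic",
    coupling = "C = identity, strength 1",
    isolated_nodes = "MPC defined as 0 when overlapping degree is 0",
    fdr_family = "regions within one (comparison, measure, threshold)",
    residualization = "pooled over the compared pair, fitted once",
    n_permutations = config$nPermutations,
    fdr_q = config$fdrQ)

  if (!is.null(config$outputDir)) {
    dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
    for (g in groupsNeeded) for (d in config$thresholds) {
      sub <- measureTab[measureTab$group == g & measureTab$threshold == d, ]
      utils::write.csv(sub, file.path(config$outputDir,
        sprintf("measures_%s_d%0.2f.csv", g, d)), row.names = FALSE)
    }
    for (nm in names(comparisonTabs))
      utils::write.csv(comparisonTabs[[nm]],
        file.path(config$outputDir, paste0("comparison_", nm, ".csv")),
        row.names = FALSE)
    jsonlite::write_json(manifest,
      file.path(config$outputDir, "manifest.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(measures = measureTab, comparisons = comparisonTabs,
                 manifest = manifest))
}

#' Human-readable table of significant regions
#'
#' Collapses nodal comparison results into a table of FDR-significant
#' regions grouped by the direction of the group difference, with hemisphere
#' and lobe tags from the atlas.
#'
#' @param comparison A comparison data.frame from \code{\link{runAnalysis}} /
#'   \code{\link{permutationTest}}, or a path to one of the written
#'   comparison CSVs.
#' @param atlas The \linkS4class{RoiAtlas} the analysis used.
#' @return data.frame with columns region, hemisphere, lobe, direction
#'   (\code{"A > B"} / \code{"A < B"}), threshold, diff, p, p_fdr; zero rows
#'   (with header) when nothing is significant.
#' @export
reportRegions <- function(comparison, atlas) {
  if (is.character(comparison))
    comparison <- utils::read.csv(comparison, stringsAsFactors = FALSE)
  stopifnot(is(atlas, "RoiAtlas"))
  nodal <- comparison[comparison$measure == "nodal_mpc" &
                        comparison$significant %in% TRUE, , drop = FALSE]
  empty <- data.frame(region = character(), hemisphere = character(),
                      lobe = character(), direction = character(),
                      threshold = numeric(), diff = numeric(),
                      p = numeric(), p_fdr = numeric())
  if (!nrow(nodal)) return(empty)
  unknown <- setdiff(nodal$node, regions(atlas))
  if (length(unknown))
    stop("unknown region(s) in comparison table: ",
         paste(unknown, collapse = ", "))
  lob <- lobes(atlas)
  hemi <- sub("-.*$", "", nodal$node)
  hemi[!hemi %in% c("lh", "rh")] <- NA_character_
  out <- data.frame(region = nodal$node, hemisphere = hemi,
                    lobe = unname(lob[nodal$node]),
                    direction = ifelse(nodal$diff > 0, "A > B", "A < B"),
                    threshold = nodal$threshold, diff = nodal$diff,
                    p = nodal$p, p_fdr = nodal$p_fdr)
  out[order(out$direction, out$lobe, out$region), , drop = FALSE]
}
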