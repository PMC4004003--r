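#' @include AllClasses.R
NULL

#' Run the full e-nose analysis pipeline
#'
#' Executes the complete workflow on a dataset: D_ave feature extraction,
#' covariance PCA on all samples, exhaustive dispersion-ratio pair search
#' (regular and/or absolute-value variant), class-centroid Mahalanobis tables
#' for the (1, 2) baseline pair and for the selected pair, and PNN spread
#' grid search with confusion matrices for both branches. The baseline branch
#' is always reported alongside the selected branch so the two component
#' choices can be compared on any input.
#'
#' @param input an [ENoseDataset-class], or a CSV path read with `dialect`.
#' @param synth name of a [scenarioConfig()] preset, used when `input` is
#'   NULL.
#' @param seed integer seed for the synthetic generator (ignored for file
#'   input).
#' @param dialect CSV dialect for file input.
#' @param variant `"improved"` (default), `"regular"`, or `"both"`; the
#'   selection branch uses the improved table when both are computed.
#' @param pair `"auto"` (use the Wilks-selected pair) or an explicit pair of
#'   distinct 1-based component indices.
#' @param kernel PNN kernel.
#' @param spreadGrid PNN spread grid (default [defaultSpreadGrid()]).
#' @param nTrain training samples per class for the ordered split
#'   (default 15).
#' @param outDir if non-NULL, write all tables (CSV) and a JSON report there.
#' @return a list bundle with elements `classes`, `features`, `pca`
#'   (eigenvalues, explained variance), `wilks` (per-variant
#'   [WilksReport-class]), `selectedPair`, `separation` (per-branch centroid
#'   + distance tables), `pnn` (per-branch grid results and confusion
#'   matrices), and `provenance`.
#' @export
runPipeline <- function(input = NULL, synth = "default", seed = NA_integer_,
                        dialect = c("long", "wide"),
                        variant = c("improved", "regular", "both"),
                        pair = "auto",
                        kernel = c("dot_product", "euclidean"),
                        spreadGrid = defaultSpreadGrid(),
                        nTrain = 15L, outDir = NULL) {
  variant <- match.arg(variant)
  kernel <- match.arg(kernel)
  dialect <- match.arg(dialect)
  if (!identical(pair, "auto")) {
    pair <- as.integer(pair)
    if (length(pair) != 2L || anyNA(pair) || pair[1L] == pair[2L] ||
        any(pair < 1L))
      stop("config error: 'pair' must be \"auto\" or two distinct 1-based indices")
  }

  ds <- if (is(input, "ENoseDataset")) input
        else if (is.character(input)) readResponseCSV(input, dialect)
        else if (is.null(input)) enoseScenario(synth, seed = seed)
        else stop("config error: 'input' must be a dataset, a path, or NULL")

  fm <- extractFeatures(ds)
  model <- fitPCA(fm)
  sm <- pcaTransform(model, fm)

  variants <- if (variant == "both") c("regular", "improved") else variant
  reports <- lapply(variants, function(v) pairSearch(sm, variant = v))
  names(reports) <- variants
  selReport <- reports[[if ("improved" %in% variants) "improved" else "regular"]]
  selected <- if (identical(pair, "auto")) selReport@bestPair else pair

  branches <- list(baseline = c(1L, 2L), selected = selected)
  separation <- lapply(branches, function(pc) {
    cs <- classCentroids(selectComponents(sm, pc))
    list(pair = pc, centroids = cs,
         distances = pairwiseMahalanobis(cs))
  })

  split <- trainTestSplit(classLabels(sm), nTrain = nTrain)
  pnn <- lapply(branches, function(pc) {
    s2 <- scoreValues(selectComponents(sm, pc))
    lab <- as.character(classLabels(sm))
    gs <- spreadGridSearch(s2[split$train, , drop = FALSE], lab[split$train],
                           s2[split$test, , drop = FALSE], lab[split$test],
                           grid = spreadGrid, kernel = kernel)
    ev <- evaluatePNN(gs$model, s2[split$test, , drop = FALSE],
                      lab[split$test])
    list(pair = pc, grid = gs$results, spread = gs$spread,
         confusion = ev$confusion, accuracy = ev$accuracy,
         accuracyPct = ev$accuracyPct)
  })

  bundle <- list(
    classes = classNames(ds),
    dataset = ds,
    features = fm,
    pca = list(
      model = model,
      eigenvalues = model@eigenvalues,
      explainedPct = list(
        baseline = explainedVariancePct(model@eigenvalues, c(1L, 2L)),
        selected = explainedVariancePct(model@eigenvalues, selected))),
    wilks = reports,
    selectedPair = selected,
    separation = separation,
    pnn = pnn,
    provenance = list(
      seed = if (is.na(seed)) NULL else as.integer(seed),
      config = list(synth = if (is.null(input)) synth else NULL,
                    variant = variant, pair = if (identical(pair, "auto"))
                      "auto" else pair,
                    kernel = kernel, spreadGrid = spreadGrid,
                    nTrain = as.integer(nTrain)),
      package = as.character(utils::packageVersion("enoseWilks")))
  )
  if (!is.null(outDir)) writePipelineReport(bundle, outDir)
  bundle
}

#' Write a pipeline report bundle to disk
#'
#' Writes feature and score CSVs, per-variant Wilks tables, separation and
#' confusion tables for both branches, and a `results.json` summary with the
#' shared schema `{classes, tables, provenance}`. Percentages are printed to
#' 2 decimals, dispersion ratios and distances to 4 in the JSON summary;
#' CSVs keep full precision.
#'
#' @param bundle result of [runPipeline()].
#' @param outDir output directory, created if needed.
#' @return `outDir`, invisibly.
#' @export
writePipelineReport <- function(bundle, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  writeFeatureCSV(bundle$features, file.path(outDir, "features.csv"))
  sm <- pcaTransform(bundle$pca$model, bundle$features)
  writeScoresCSV(sm, file.path(outDir, "scores.csv"))
  for (v in names(bundle$wilks))
    utils::write.csv(wilksTable(bundle$wilks[[v]]),
                     file.path(outDir, paste0("wilks_", v, ".csv")),
                     row.names = FALSE)
  for (b in names(bundle$separation)) {
    sep <- bundle$separation[[b]]
    utils::write.csv(as.data.frame(sep$distances),
                     file.path(outDir, paste0("mahalanobis_", b, ".csv")))
    utils::write.csv(as.data.frame(bundle$pnn[[b]]$confusion),
                     file.path(outDir, paste0("confusion_", b, ".csv")))
    utils::write.csv(bundle$pnn[[b]]$grid,
                     file.path(outDir, paste0("pnn_grid_", b, ".csv")),
                     row.names = FALSE)
  }
  tables <- list(
    explained_variance_pct = lapply(bundle$pca$explainedPct,
                                    function(x) round(x, 2)),
    wilks = lapply(bundle$wilks, function(r) list(
      variant = r@variant,
      ratios = cbind(r@table$i, r@table$j, round(r@table$lambda, 4)),
      best_pair = r@bestPair,
      best_value = round(r@bestValue, 4),
      above_one = r@table[r@table$lambda > 1, c("i", "j")])),
    selected_pair = bundle$selectedPair,
    mahalanobis = lapply(bundle$separation, function(s)
      round(s$distances, 4)),
    pnn = lapply(bundle$pnn, function(p) list(
      pair = p$pair, spread = p$spread,
      grid = transform(p$grid,
                       train_acc = round(train_acc, 2),
                       test_acc = round(test_acc, 2)),
      confusion = p$confusion,
      accuracy_pct = p$accuracyPct))
  )
  report <- list(classes = bundle$classes, tables = tables,
                 provenance = bundle$provenance)
  jsonlite::write_json(report, file.path(outDir, "results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(outDir)
}

#' One-line text summary of a pipeline bundle
#'
#' @param bundle result of [runPipeline()].
#' @return character vector of summary lines, invisibly; also printed.
#' @export
summarizePipeline <- function(bundle) {
  sel <- bundle$selectedPair
  lines <- c(
    sprintf("classes: %s", paste(bundle$classes, collapse = ", ")),
    sprintf("selected pair: (PC%d, PC%d)", sel[1L], sel[2L]),
    sprintf("explained variance: baseline %.2f%%, selected %.2f%%",
            bundle$pca$explainedPct$baseline,
            bundle$pca$explainedPct$selected),
    sprintf("PNN test accuracy: baseline %.2f%% (spread %g), selected %.2f%% (spread %g)",
            bundle$pnn$baseline$accuracyPct, bundle$pnn$baseline$spread,
            bundle$pnn$selected$accuracyPct, bundle$pnn$selected$spread))
  cat(lines, sep = "\n")
  invisible(lines)
}
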