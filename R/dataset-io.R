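#' @include AllClasses.R
NULL

# Full-precision numeric formatting so CSV round-trips are bit-exact.
.fmtNum <- function(x) sprintf("%.17g", x)

#' Read an e-nose response CSV
#'
#' Reads a dataset of G/G0 response curves from CSV in one of two dialects:
#'
#' * `long`: columns `sample_id, class_label, sensor, t, value` — one row per
#'   reading, `sensor` a 1-based integer, `t` in seconds. The sampling
#'   interval is inferred from the time column and must be constant (within
#'   1e-9) across the dataset.
#' * `wide`: columns `sample_id, class_label, sensor, v1..v{n_time}` — one row
#'   per (sample, sensor) curve; the sampling interval is assumed to be 1 s.
#'
#' Sample order is first appearance in the file; class order is first
#' appearance across samples.
#'
#' @param path path to a CSV file (comma separator, header row, '.' decimal).
#' @param dialect `"long"` or `"wide"`.
#' @return an [ENoseDataset-class].
#' @seealso [writeResponseCSV()]
#' @export
readResponseCSV <- function(path, dialect = c("long", "wide")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (dialect == "long") .readLong(df) else .readWide(df)
}

.readLong <- function(df) {
  need <- c("sample_id", "class_label", "sensor", "t", "value")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("format error: missing column(s): ", paste(miss, collapse = ", "))
  if (any(df$value <= 0))
    stop("value error: non-positive response ratio in input")
  ids <- unique(df$sample_id)
  sensors <- sort(unique(df$sensor))
  if (!identical(as.integer(sensors), seq_along(sensors)))
    stop("format error: sensor indices must be 1..n_sensors")
  times <- sort(unique(df$t))
  if (length(times) < 2L)
    stop("format error: at least 2 time points required")
  dts <- diff(times)
  if (max(dts) - min(dts) > 1e-9)
    stop("dialect error: non-constant time step in 't' column")
  dt <- dts[1L]
  nS <- length(sensors); nT <- length(times); nK <- length(ids)
  arr <- array(NA_real_, dim = c(nS, nT, nK))
  ki <- match(df$sample_id, ids)
  si <- match(df$sensor, sensors)
  ti <- match(df$t, times)
  arr[cbind(si, ti, ki)] <- df$value
  if (anyNA(arr))
    stop("format error: incomplete sensor/time grid for at least one sample")
  lab <- df$class_label[match(ids, df$sample_id)]
  ENoseDataset(arr, ids, lab, dt = dt)
}

.readWide <- function(df) {
  need <- c("sample_id", "class_label", "sensor")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("format error: missing column(s): ", paste(miss, collapse = ", "))
  vcols <- grep("^v[0-9]+$", names(df), value = TRUE)
  if (length(vcols) < 2L)
    stop("format error: wide dialect needs value columns v1..v{n_time}")
  vcols <- vcols[order(as.integer(sub("^v", "", vcols)))]
  vals <- as.matrix(df[, vcols])
  if (any(vals <= 0))
    stop("value error: non-positive response ratio in input")
  ids <- unique(df$sample_id)
  sensors <- sort(unique(df$sensor))
  if (!identical(as.integer(sensors), seq_along(sensors)))
    stop("format error: sensor indices must be 1..n_sensors")
  nS <- length(sensors); nT <- length(vcols); nK <- length(ids)
  arr <- array(NA_real_, dim = c(nS, nT, nK))
  ki <- match(df$sample_id, ids)
  si <- match(df$sensor, sensors)
  for (r in seq_len(nrow(df))) arr[si[r], , ki[r]] <- vals[r, ]
  if (anyNA(arr))
    stop("format error: incomplete sensor set for at least one sample")
  lab <- df$class_label[match(ids, df$sample_id)]
  ENoseDataset(arr, ids, lab, dt = 1)
}

#' Write an e-nose response CSV
#'
#' Inverse of [readResponseCSV()]: values are written at full double
#' precision, so a write/read round trip reproduces the dataset exactly.
#' The wide dialect assumes dt = 1 s and refuses other intervals.
#'
#' @param ds an [ENoseDataset-class], non-empty.
#' @param path output file path.
#' @param dialect `"long"` or `"wide"`.
#' @return `path`, invisibly.
#' @export
writeResponseCSV <- function(ds, path, dialect = c("long", "wide")) {
  dialect <- match.arg(dialect)
  stopifnot(is(ds, "ENoseDataset"))
  if (nSamples(ds) == 0L) stop("cannot write an empty dataset")
  nS <- nSensors(ds); nT <- nTimePoints(ds); nK <- nSamples(ds)
  lab <- as.character(ds@classLabels)
  if (dialect == "long") {
    tgrid <- ds@dt * seq_len(nT)
    df <- data.frame(
      sample_id = rep(ds@sampleIds, each = nS * nT),
      class_label = rep(lab, each = nS * nT),
      sensor = rep(rep(seq_len(nS), times = nT), times = nK),
      t = .fmtNum(rep(rep(tgrid, each = nS), times = nK)),
      value = .fmtNum(as.vector(ds@responses)),
      stringsAsFactors = FALSE
    )
  } else {
    if (abs(ds@dt - 1) > 1e-12)
      stop("dialect error: wide dialect assumes dt = 1 s")
    rows <- vector("list", nK)
    for (k in seq_len(nK)) {
      m <- ds@responses[, , k]
      rows[[k]] <- data.frame(
        sample_id = ds@sampleIds[k],
        class_label = lab[k],
        sensor = seq_len(nS),
        matrix(.fmtNum(m), nrow = nS,
               dimnames = list(NULL, paste0("v", seq_len(nT)))),
        stringsAsFactors = FALSE, check.names = FALSE
      )
    }
    df <- do.call(rbind, rows)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a feature matrix CSV
#'
#' Columns: `sample_id, class_label, s1..s{n_sensors}`.
#'
#' @param fm a [FeatureMatrix-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeFeatureCSV <- function(fm, path) {
  stopifnot(is(fm, "FeatureMatrix"))
  v <- fm@values
  df <- data.frame(
    sample_id = fm@sampleIds,
    class_label = as.character(fm@classLabels),
    matrix(.fmtNum(v), nrow = nrow(v),
           dimnames = list(NULL, paste0("s", seq_len(ncol(v))))),
    stringsAsFactors = FALSE, check.names = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a feature matrix CSV
#'
#' @param path CSV written by [writeFeatureCSV()].
#' @return a [FeatureMatrix-class].
#' @export
readFeatureCSV <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample_id", "class_label")
  if (!all(need %in% names(df)))
    stop("format error: missing sample_id/class_label columns")
  scols <- grep("^s[0-9]+$", names(df), value = TRUE)
  scols <- scols[order(as.integer(sub("^s", "", scols)))]
  FeatureMatrix(as.matrix(df[, scols, drop = FALSE]),
                df$sample_id, df$class_label)
}

#' Write a score matrix CSV
#'
#' Columns: `sample_id, class_label, pc{i}...` for the retained components.
#'
#' @param sm a [ScoreMatrix-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeScoresCSV <- function(sm, path) {
  stopifnot(is(sm, "ScoreMatrix"))
  v <- sm@scores
  df <- data.frame(
    sample_id = sm@sampleIds,
    class_label = as.character(sm@classLabels),
    matrix(.fmtNum(v), nrow = nrow(v),
           dimnames = list(NULL, paste0("pc", sm@componentIds))),
    stringsAsFactors = FALSE, check.names = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a score matrix CSV
#'
#' @param path CSV written by [writeScoresCSV()].
#' @return a [ScoreMatrix-class].
#' @export
readScoresCSV <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  pcols <- grep("^pc[0-9]+$", names(df), value = TRUE)
  if (!length(pcols) || !all(c("sample_id", "class_label") %in% names(df)))
    stop("format error: score CSV needs sample_id, class_label, pc<i> columns")
  ids <- as.integer(sub("^pc", "", pcols))
  ord <- order(ids)
  new("ScoreMatrix",
      scores = as.matrix(df[, pcols[ord], drop = FALSE]),
      sampleIds = df$sample_id,
      classLabels = factor(df$class_label, levels = unique(df$class_label)),
      componentIds = ids[ord])
}
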