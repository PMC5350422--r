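#' Write a fingerprint matrix as CSV
#'
#' Samples x points matrix with the retention-time grid as header row and
#' sample ids in the first column.
#'
#' @param X samples x points matrix (or a [FingerprintSet-class]).
#' @param grid retention-time grid (ignored when `X` is a FingerprintSet).
#' @param file output path.
#' @return Invisibly, `file`.
#' @export
writeFingerprintCSV <- function(X, grid = NULL, file) {
  if (is(X, "FingerprintSet")) {
    grid <- rtGrid(X)
    X <- fingerprintMatrix(X)
  }
  df <- data.frame(sample_id = rownames(X), X, check.names = FALSE)
  colnames(df) <- c("sample_id", format(grid, trim = TRUE, digits = 15))
  write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' Read a fingerprint matrix CSV
#'
#' Counterpart of [writeFingerprintCSV()]: validates the header (first
#' column `sample_id`, remaining columns a numeric strictly increasing
#' grid), rejects ragged or non-numeric rows with the offending line number,
#' and returns the matrix with its grid.
#'
#' @param file input path.
#' @return list with `X` (samples x points, rownames = sample ids) and
#'   `grid`.
#' @export
readFingerprintCSV <- function(file) {
  header <- strsplit(readLines(file, n = 1), ",")[[1]]
  header <- gsub('^"|"$', "", header)
  if (header[1] != "sample_id")
    stop("malformed header in ", file, ": first column must be 'sample_id'")
  grid <- suppressWarnings(as.numeric(header[-1]))
  if (any(is.na(grid)) || (length(grid) > 1 && any(diff(grid) <= 0)))
    stop("malformed header in ", file,
         ": columns must be a strictly increasing numeric grid")
  df <- read.csv(file, check.names = FALSE, colClasses = "character")
  if (ncol(df) != length(grid) + 1)
    stop("ragged rows in ", file)
  vals <- suppressWarnings(
    vapply(seq_len(nrow(df)), function(i) as.numeric(unlist(df[i, -1])),
           numeric(length(grid))))
  bad <- which(colSums(is.na(vals)) > 0)
  if (length(bad))
    stop("non-numeric cell in ", file, " at data line ", bad[1])
  X <- t(vals)
  rownames(X) <- df$sample_id
  list(X = X, grid = grid)
}

#' Read an activities CSV
#'
#' Expects columns `sample_id` and `activity`.
#'
#' @param file input path.
#' @return named numeric vector of activities.
#' @export
readActivitiesCSV <- function(file) {
  df <- read.csv(file)
  if (!all(c("sample_id", "activity") %in% colnames(df)))
    stop("activities file needs columns sample_id, activity: ", file)
  if (any(is.na(suppressWarnings(as.numeric(df$activity)))))
    stop("non-numeric activity at data line ",
         which(is.na(suppressWarnings(as.numeric(df$activity))))[1],
         " in ", file)
  setNames(as.numeric(df$activity), df$sample_id)
}

#' Read a fingerprint panel from files
#'
#' Assembles a [FingerprintSet-class] from the matrix CSV, a metadata CSV
#' (`sample_id`, `batch`, extraction columns) and optionally an activities
#' CSV. Samples present in the matrix but missing from activities raise a
#' join error naming the sample.
#'
#' @param matrixFile path to the fingerprint matrix CSV.
#' @param metadataFile path to the metadata CSV.
#' @param activitiesFile optional path to the activities CSV.
#' @return A [FingerprintSet-class].
#' @export
readPanel <- function(matrixFile, metadataFile, activitiesFile = NULL) {
  m <- readFingerprintCSV(matrixFile)
  meta <- read.csv(metadataFile)
  if (!all(c("sample_id", "batch") %in% colnames(meta)))
    stop("metadata file needs columns sample_id, batch")
  missing <- setdiff(rownames(m$X), meta$sample_id)
  if (length(missing))
    stop("no metadata for sample(s): ", paste(missing, collapse = ", "))
  meta <- meta[match(rownames(m$X), meta$sample_id), ]
  acts <- NULL
  if (!is.null(activitiesFile)) {
    acts <- readActivitiesCSV(activitiesFile)
    missing <- setdiff(rownames(m$X), names(acts))
    if (length(missing))
      stop("no activity value for sample(s): ",
           paste(missing, collapse = ", "))
  }
  sd <- meta[setdiff(colnames(meta), c("sample_id", "batch"))]
  if (!is.null(acts)) sd$activity <- unname(acts[rownames(m$X)])
  FingerprintSet(m$X, m$grid, sampleIds = rownames(m$X),
                 batchIds = meta$batch, sampleData = sd)
}

#' Published reference panel: CD80 activities of 72 herbal extracts
#'
#' The per-sample immunomodulatory activities (% change of CD80 expression
#' on THP-1 cells relative to the untreated control, delta% scale) of a
#' published panel of 72 Radix Astragali extracts in three batches of 24,
#' shipped as a plain-text fixture. These are measured reference values used
#' for desk-scale metric checks, not synthetic data.
#'
#' @return data.frame with columns `sample`, `batch`, `activity`.
#' @export
referenceActivities <- function() {
  read.csv(system.file("extdata", "ra_cd80_activities.csv",
                       package = "qparfp"))
}

#' Published reference test set: actual and predicted CD80 activities
#'
#' The 24-sample external test set of the same published panel, with the
#' measured activity and the predictions of the plain-PLS and EN-PLS models
#' (all on the 100 + delta% scale, i.e. 100 means no change against the
#' untreated control; these values equal 100 plus the delta% activities of
#' [referenceActivities()]).
#'
#' @return data.frame with columns `number`, `act`, `pls_pred`,
#'   `enpls_pred`.
#' @export
referenceTestSet <- function() {
  read.csv(system.file("extdata", "ra_cd80_testset.csv",
                       package = "qparfp"))
}
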