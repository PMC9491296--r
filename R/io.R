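.delimFor <- function(path) {
  if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
}

#' Read a time-course matrix from delimited text
#'
#' Rows are timepoints, columns are components. CSV or TSV is chosen from
#' the file extension (.tsv/.txt = tab). An optional header row supplies
#' component labels; otherwise labels C01, C02, ... are generated. Ragged
#' rows, non-numeric cells and missing values are errors that name the
#' offending location. A matrix with fewer rows than columns triggers an
#' orientation warning (timepoints are expected to outnumber components).
#'
#' @param path file path.
#' @return numeric T x C matrix with component labels as colnames.
#' @export
readTimeCourses <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- .delimFor(path)
  first <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1L]]
  hasHeader <- any(is.na(suppressWarnings(as.numeric(first))))
  df <- utils::read.table(path, header = hasHeader, sep = sep,
                          colClasses = "character", check.names = FALSE)
  if (ncol(df) < 2L) stop("need at least 2 columns in ", path)
  if (nrow(df) < 10L) stop("need at least 10 rows in ", path)
  m <- matrix(NA_real_, nrow(df), ncol(df))
  for (j in seq_len(ncol(df))) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    bad <- which(!is.finite(v))
    if (length(bad))
      stop(sprintf("non-numeric or missing value at row %d, column %d of %s",
                   bad[1L], j, path))
    m[, j] <- v
  }
  colnames(m) <- if (hasHeader) colnames(df)
                 else sprintf("C%02d", seq_len(ncol(m)))
  if (nrow(m) <= ncol(m))
    warning("fewer rows (timepoints) than columns (components) in ", path,
            ": check the matrix orientation")
  m
}

#' Write / read a labelled square matrix
#'
#' Round-trips a matrix (e.g. a connectivity or comparison map) through
#' delimited text with full double precision: labels are kept exactly
#' (quoted, so commas survive) and values to better than 1e-12.
#'
#' @param m numeric matrix with dimnames.
#' @param path file path; extension selects the delimiter.
#' @return \code{readMatrix} returns the matrix; \code{writeMatrix} its
#'   path, invisibly.
#' @export
writeMatrix <- function(m, path) {
  if (length(m) == 0L) stop("refusing to write an empty matrix")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("matrix must carry dimnames")
  ch <- matrix(ifelse(is.na(m), "NA", sprintf("%.17g", m)), nrow(m))
  df <- data.frame(label = rownames(m), ch, check.names = FALSE)
  colnames(df) <- c("label", colnames(m))
  utils::write.table(df, path, sep = .delimFor(path), row.names = FALSE,
                     qmethod = "double")
  invisible(path)
}

#' @rdname writeMatrix
#' @export
readMatrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- .delimFor(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, colClasses = "character",
                          strip.white = TRUE)
  labels <- df[[1L]]
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  dimnames(m) <- list(labels, colnames(df)[-1L])
  m
}

#' Read / write a subject manifest
#'
#' A manifest is delimited text with header \code{subject_id,group,path};
#' paths are resolved relative to the manifest's directory when not
#' absolute.
#'
#' @param path manifest file path.
#' @param requireTwoGroups error unless exactly two group labels occur.
#' @return data.frame with columns subject_id, group, path.
#' @export
readManifest <- function(path, requireTwoGroups = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = .delimFor(path),
                          colClasses = "character", check.names = FALSE)
  need <- c("subject_id", "group", "path")
  if (!all(need %in% colnames(df)))
    stop("manifest must have columns subject_id, group, path")
  if (anyDuplicated(df$subject_id)) stop("duplicate subject ids in manifest")
  if (requireTwoGroups && length(unique(df$group)) != 2L)
    stop("manifest must contain exactly two groups, found: ",
         paste(unique(df$group), collapse = ", "))
  base <- dirname(path)
  abs <- grepl("^(/|[A-Za-z]:)", df$path)
  df$path[!abs] <- file.path(base, df$path[!abs])
  missing <- !file.exists(df$path)
  if (any(missing))
    stop("manifest points to missing file(s): ",
         paste(utils::head(df$path[missing], 3L), collapse = ", "))
  df[need]
}

#' Load a cohort from a manifest
#'
#' @param manifestPath path to a manifest (see [readManifest()]).
#' @param domains optional character vector of per-component domains.
#' @return an [FncCohort-class].
#' @export
readCohort <- function(manifestPath, domains = character()) {
  mf <- readManifest(manifestPath)
  tcs <- lapply(mf$path, readTimeCourses)
  labels <- colnames(tcs[[1L]])
  tcs <- lapply(tcs, function(m) { colnames(m) <- NULL; m })
  new("FncCohort", timecourses = tcs, subjectId = mf$subject_id,
      group = mf$group, componentLabels = labels,
      domains = as.character(domains))
}

#' Write a cohort as per-subject files plus a manifest
#'
#' @param cohort an [FncCohort-class].
#' @param dir output directory (created if needed).
#' @param sep delimiter for the time-course files.
#' @return path of the written manifest, invisibly.
#' @export
writeCohort <- function(cohort, dir, sep = ",") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (sep == ",") "csv" else "tsv"
  files <- sprintf("%s.%s", subjectIds(cohort), ext)
  for (s in seq_len(nSubjects(cohort))) {
    m <- timeCourses(cohort, s)
    colnames(m) <- componentLabels(cohort)
    utils::write.table(format(m, digits = 17, trim = TRUE, scientific = FALSE),
                       file.path(dir, files[s]), sep = sep,
                       row.names = FALSE, quote = FALSE)
  }
  mf <- data.frame(subject_id = subjectIds(cohort),
                   group = unname(subjectGroups(cohort)), path = files)
  mfPath <- file.path(dir, "manifest.csv")
  utils::write.table(mf, mfPath, sep = ",", row.names = FALSE, quote = FALSE)
  if (length(domains(cohort)))
    utils::write.table(data.frame(component = componentLabels(cohort),
                                  domain = domains(cohort)),
                       file.path(dir, "domains.csv"), sep = ",",
                       row.names = FALSE, quote = FALSE)
  invisible(mfPath)
}
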