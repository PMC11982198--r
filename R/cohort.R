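#' Canonical WDBC feature names
#'
#' The 30 continuous cell-nucleus features of the Wisconsin Diagnostic
#' Breast Cancer (WDBC) data in canonical column order: the ten base
#' measurements (radius, texture, perimeter, area, smoothness, compactness,
#' concavity, concave points, symmetry, fractal_dimension), each as the
#' per-image mean, standard error ("se") and worst (mean of the three
#' largest values).
#'
#' @return Character vector of length 30.
#' @export
#' @examples
#' wdbc_feature_names()[1:5]
wdbc_feature_names <- function() {
  base <- c("radius", "texture", "perimeter", "area", "smoothness",
            "compactness", "concavity", "concave points", "symmetry",
            "fractal_dimension")
  as.vector(vapply(c("mean", "se", "worst"),
                   function(s) paste(base, s, sep = "_"), character(10)))
}

# accepted alternative spellings seen in circulating copies of the data
.wdbc_aliases <- c("texture_worse" = "texture_worst",
                   "concave_points_mean"  = "concave points_mean",
                   "concave_points_se"    = "concave points_se",
                   "concave_points_worst" = "concave points_worst")

.canonicalise_names <- function(x) {
  hit <- match(x, names(.wdbc_aliases))
  x[!is.na(hit)] <- .wdbc_aliases[hit[!is.na(hit)]]
  x
}

#' Construct a labelled cohort
#'
#' A labelled cohort is the training-side container: a numeric feature
#' matrix with named columns, a benign/malignant label per record, and
#' opaque record identifiers. Labels are kept as a factor so they can
#' never silently enter the feature matrix.
#'
#' @param features Numeric matrix (records x features) with unique column
#'   names; no missing values allowed.
#' @param labels Character or factor with values in
#'   `c("benign", "malignant")`, one per record.
#' @param record_ids Optional character vector of identifiers; defaults to
#'   the row index.
#' @return An object of class `labeled_cohort` with elements `features`,
#'   `labels` and `record_ids`.
#' @export
labeled_cohort <- function(features, labels, record_ids = NULL) {
  features <- as.matrix(features)
  if (!is.numeric(features)) stop("features must be numeric")
  n <- nrow(features); p <- ncol(features)
  if (n < 1L) stop("no records")
  if (p < 1L) stop("no features")
  if (is.null(colnames(features)) || anyDuplicated(colnames(features)))
    stop("features must have unique column names")
  bad <- which(!is.finite(features), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("missing or non-finite value at row %d, column '%s'",
                 bad[1L, 1L], colnames(features)[bad[1L, 2L]]))
  labels <- as.character(labels)
  if (length(labels) != n) stop("labels must have one entry per record")
  unknown <- setdiff(unique(labels), c("benign", "malignant"))
  if (length(unknown) > 0L)
    stop(sprintf("unknown label code: '%s'", unknown[1L]))
  if (is.null(record_ids)) record_ids <- as.character(seq_len(n))
  record_ids <- as.character(record_ids)
  if (length(record_ids) != n) stop("record_ids must have one entry per record")
  structure(list(features = features,
                 labels = factor(labels, levels = c("benign", "malignant")),
                 record_ids = record_ids),
            class = "labeled_cohort")
}

#' @export
print.labeled_cohort <- function(x, ...) {
  cat(sprintf("Labelled cohort: %d records x %d features (%d benign, %d malignant)\n",
              nrow(x$features), ncol(x$features),
              sum(x$labels == "benign"), sum(x$labels == "malignant")))
  invisible(x)
}

#' @export
dim.labeled_cohort <- function(x) dim(x$features)

#' Read a WDBC-style data file
#'
#' Supports the two file dialects in which the Wisconsin Diagnostic Breast
#' Cancer data circulates: the raw UCI flat file (32 comma-separated
#' fields per line, no header: ID, diagnosis `M`/`B`, then 30 floats in
#' canonical order) and a headered CSV (feature names plus a `diagnosis`
#' column, optional `id` column). The dialect is auto-detected from the
#' presence of a header unless forced.
#'
#' @param path Path to the file.
#' @param dialect One of `"auto"`, `"uci_raw"`, `"headered_csv"`.
#' @return A [labeled_cohort] with `M` decoded as malignant and `B` as
#'   benign; record order as in the file.
#' @export
load_wdbc <- function(path, dialect = c("auto", "uci_raw", "headered_csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L || !nzchar(trimws(first))) stop("no records")
  if (dialect == "auto") {
    # header lines carry feature names; data lines are id + code + numbers
    dialect <- if (grepl("diagnosis", first, fixed = TRUE))
      "headered_csv" else "uci_raw"
  }
  if (dialect == "uci_raw") .load_wdbc_raw(path) else .load_wdbc_csv(path)
}

.load_wdbc_raw <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("no records")
  fields <- strsplit(lines, ",", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 32L))
    stop(sprintf("row %d has %d fields, expected 32",
                 which(nf != 32L)[1L], nf[nf != 32L][1L]))
  ids <- vapply(fields, `[[`, character(1), 1L)
  codes <- vapply(fields, `[[`, character(1), 2L)
  feat <- matrix(NA_real_, length(lines), 30L,
                 dimnames = list(NULL, wdbc_feature_names()))
  for (i in seq_along(fields)) {
    v <- suppressWarnings(as.numeric(fields[[i]][3:32]))
    if (anyNA(v))
      stop(sprintf("missing or non-numeric value at row %d, column '%s'",
                   i, wdbc_feature_names()[which(is.na(v))[1L]]))
    feat[i, ] <- v
  }
  labeled_cohort(feat, .decode_diagnosis(codes), ids)
}

.load_wdbc_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("no records")
  names(df) <- .canonicalise_names(names(df))
  if (!"diagnosis" %in% names(df)) stop("headered CSV must have a 'diagnosis' column")
  ids <- if ("id" %in% names(df)) as.character(df[["id"]])
         else as.character(seq_len(nrow(df)))
  codes <- as.character(df[["diagnosis"]])
  fdf <- df[, setdiff(names(df), c("id", "diagnosis")), drop = FALSE]
  for (j in seq_along(fdf)) {
    v <- suppressWarnings(as.numeric(fdf[[j]]))
    if (anyNA(v))
      stop(sprintf("missing or non-numeric value at row %d, column '%s'",
                   which(is.na(v))[1L], names(fdf)[j]))
    fdf[[j]] <- v
  }
  feat <- as.matrix(fdf)
  canon <- wdbc_feature_names()
  if (all(canon %in% colnames(feat))) feat <- feat[, canon, drop = FALSE]
  labeled_cohort(feat, .decode_diagnosis(codes), ids)
}

.decode_diagnosis <- function(codes) {
  out <- c(M = "malignant", B = "benign",
           malignant = "malignant", benign = "benign")[codes]
  if (anyNA(out))
    stop(sprintf("unknown label code: '%s'", codes[which(is.na(out))[1L]]))
  unname(out)
}

#' The bundled Wisconsin Diagnostic Breast Cancer cohort
#'
#' Loads the plain-text copy of the public WDBC data shipped with the
#' package (569 records, 30 features, 357 benign / 212 malignant). The
#' data are stored as headered CSV in consecutive parts; this reassembles
#' them and parses the result through [load_wdbc()].
#'
#' @return A [labeled_cohort] with 569 records.
#' @export
#' @examples
#' wdbc_cohort()
wdbc_cohort <- function() {
  parts <- sort(list.files(system.file("extdata", package = "driftguard"),
                           pattern = "^wdbc_part[0-9]+\\.csv$", full.names = TRUE))
  if (length(parts) == 0L) stop("bundled WDBC data not found")
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp))
  header <- readLines(parts[1L], n = 1L)
  body <- unlist(lapply(parts, function(f) readLines(f, warn = FALSE)[-1L]))
  writeLines(c(header, body), tmp)
  load_wdbc(tmp, dialect = "headered_csv")
}

#' Write a labelled cohort as headered CSV
#'
#' @param cohort A [labeled_cohort].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  stopifnot(inherits(cohort, "labeled_cohort"))
  df <- data.frame(id = cohort$record_ids,
                   diagnosis = ifelse(cohort$labels == "malignant", "M", "B"),
                   check.names = FALSE)
  feats <- as.data.frame(cohort$features, check.names = FALSE)
  # %.17g keeps the text form faithful to the double, so both dialects of
  # one cohort parse back to identical matrices
  feats[] <- lapply(feats, function(v) sprintf("%.17g", v))
  utils::write.csv(cbind(df, feats), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# internal: check a feature matrix against an expected ordered name set
.check_feature_names <- function(m, expected) {
  if (is.null(colnames(m)) || !identical(colnames(m), expected)) {
    if (!is.null(colnames(m)) && setequal(colnames(m), expected))
      return(m[, expected, drop = FALSE])
    stop("feature columns do not match the model's feature names")
  }
  m
}
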