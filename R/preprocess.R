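# population standard deviation (divisor n), fixed for bit-reproducibility
.sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

#' Prune multicollinear features
#'
#' Removes redundant features by a deterministic greedy scan in column
#' order: a feature is dropped iff its absolute Pearson correlation with
#' any already-retained feature exceeds `threshold`. On the WDBC cohort at
#' the default threshold this removes nine features (perimeter/area
#' mean, se and worst, radius_worst, texture_worst, concave points_mean)
#' and retains 21.
#'
#' @param cohort A [labeled_cohort].
#' @param threshold Absolute Pearson correlation bound (default 0.9).
#' @return A list with `cohort` (the pruned [labeled_cohort]) and `prune`,
#'   a `prune_result` holding `retained`, `removed` and `threshold`.
#' @export
prune_collinear <- function(cohort, threshold = 0.9) {
  stopifnot(inherits(cohort, "labeled_cohort"))
  x <- cohort$features
  if (nrow(x) < 2L) stop("need at least 2 records to compute correlations")
  sds <- apply(x, 2, .sd_pop)
  if (any(sds == 0))
    stop(sprintf("constant feature '%s': correlation undefined",
                 colnames(x)[which(sds == 0)[1L]]))
  cm <- abs(stats::cor(x))
  retained <- integer(0)
  for (j in seq_len(ncol(x))) {
    if (length(retained) == 0L || all(cm[j, retained] <= threshold))
      retained <- c(retained, j)
  }
  removed <- setdiff(seq_len(ncol(x)), retained)
  pruned <- labeled_cohort(x[, retained, drop = FALSE], cohort$labels,
                           cohort$record_ids)
  prune <- structure(list(retained = colnames(x)[retained],
                          removed = colnames(x)[removed],
                          threshold = threshold),
                     class = "prune_result")
  list(cohort = pruned, prune = prune)
}

#' @export
print.prune_result <- function(x, ...) {
  cat(sprintf("Multicollinearity pruning (|r| > %g): %d retained, %d removed\n",
              x$threshold, length(x$retained), length(x$removed)))
  if (length(x$removed) > 0L)
    cat("removed:", paste(x$removed, collapse = ", "), "\n")
  invisible(x)
}

#' SMOTE oversampling of a minority class
#'
#' Generates synthetic minority records by interpolation: each synthetic
#' row is `x_i + g * (x_nn - x_i)` for a uniformly chosen minority row
#' `x_i`, one of its `k_neighbors` nearest minority neighbours `x_nn`
#' (Euclidean distance), and `g` uniform on \[0, 1\]. Only the synthetic
#' rows are returned.
#'
#' @param minority Numeric matrix of minority-class records.
#' @param target_count Desired total minority count after oversampling.
#' @param k_neighbors Number of nearest neighbours to interpolate towards
#'   (default 5, the original SMOTE setting).
#' @param seed Integer seed; the operation is reproducible given the seed.
#' @return Matrix of `target_count - nrow(minority)` synthetic rows (0 rows
#'   when the class already has `target_count` records).
#' @export
smote_oversample <- function(minority, target_count, k_neighbors = 5L,
                             seed = 1L) {
  minority <- as.matrix(minority)
  n <- nrow(minority)
  if (target_count < n)
    stop(sprintf("target_count (%d) below current minority count (%d)",
                 target_count, n))
  if (n < k_neighbors + 1L)
    stop(sprintf("need at least k_neighbors + 1 = %d minority records, have %d",
                 k_neighbors + 1L, n))
  n_syn <- target_count - n
  out <- matrix(numeric(0), 0L, ncol(minority),
                dimnames = list(NULL, colnames(minority)))
  if (n_syn == 0L) return(out)
  d <- as.matrix(stats::dist(minority))
  diag(d) <- Inf
  nn <- t(apply(d, 1L, function(r) order(r)[seq_len(k_neighbors)]))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  base <- sample.int(n, n_syn, replace = TRUE)
  pick <- sample.int(k_neighbors, n_syn, replace = TRUE)
  gap <- stats::runif(n_syn)
  syn <- minority[base, , drop = FALSE] +
    gap * (minority[nn[cbind(base, pick)], , drop = FALSE] -
             minority[base, , drop = FALSE])
  rownames(syn) <- NULL
  syn
}

#' Fit a z-score scaler
#'
#' Stores per-feature mean and population standard deviation (divisor n)
#' so that the transformed training matrix has column mean 0 and SD 1
#' exactly, and any later record can be mapped into the same scaled space.
#'
#' @param x Numeric matrix with named columns; at least 2 rows.
#' @return A `scaler_model` with named `means` and `sds`.
#' @export
fit_scaler <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 rows to fit a scaler")
  if (is.null(colnames(x))) stop("matrix must have column names")
  means <- colMeans(x)
  sds <- apply(x, 2, .sd_pop)
  if (any(sds == 0))
    stop(sprintf("zero-variance column '%s'", colnames(x)[which(sds == 0)[1L]]))
  scaler_model(means, sds)
}

scaler_model <- function(means, sds) {
  stopifnot(length(means) == length(sds), all(sds > 0))
  structure(list(means = means, sds = sds), class = "scaler_model")
}

#' Apply or invert a fitted scaler
#'
#' @param scaler A `scaler_model` from [fit_scaler()].
#' @param x Numeric matrix whose column names match the scaler's features.
#' @return The transformed (or back-transformed) matrix.
#' @export
scale_transform <- function(scaler, x) {
  stopifnot(inherits(scaler, "scaler_model"))
  x <- .check_feature_names(as.matrix(x), names(scaler$means))
  sweep(sweep(x, 2, scaler$means), 2, scaler$sds, "/")
}

#' @rdname scale_transform
#' @export
scale_inverse <- function(scaler, x) {
  stopifnot(inherits(scaler, "scaler_model"))
  x <- .check_feature_names(as.matrix(x), names(scaler$means))
  sweep(sweep(x, 2, scaler$sds, "*"), 2, scaler$means, "+")
}

#' Run the full training-cohort preparation chain
#'
#' Reproduces the standard preparation for one-class training on a
#' labelled diagnostic cohort: multicollinearity pruning (on the original
#' labelled records), SMOTE oversampling of the minority class up to the
#' majority count (on unscaled pruned features), label removal, then
#' z-score standardisation of the combined matrix. On the WDBC cohort this
#' yields a 714 x 21 scaled training matrix.
#'
#' @param cohort A [labeled_cohort].
#' @param threshold Pruning correlation bound (default 0.9).
#' @param k_neighbors SMOTE neighbour count (default 5).
#' @param seed Integer seed for the SMOTE draw.
#' @return A list with `matrix` (the prepared scaled training matrix),
#'   `model` (a `preprocess_model`: prune result + scaler, the contract
#'   for transforming deployment-time records), `prune`, and
#'   `n_synthetic`.
#' @export
prepare <- function(cohort, threshold = 0.9, k_neighbors = 5L, seed = 1L) {
  stopifnot(inherits(cohort, "labeled_cohort"))
  pr <- prune_collinear(cohort, threshold)
  x <- pr$cohort$features
  counts <- table(pr$cohort$labels)
  syn <- NULL
  if (counts[["benign"]] != counts[["malignant"]]) {
    mino_lab <- if (counts[["benign"]] < counts[["malignant"]]) "benign" else "malignant"
    mino <- x[pr$cohort$labels == mino_lab, , drop = FALSE]
    syn <- smote_oversample(mino, target_count = max(counts),
                            k_neighbors = k_neighbors, seed = seed)
  }
  full <- rbind(x, syn)
  scaler <- fit_scaler(full)
  model <- structure(list(prune = pr$prune, scaler = scaler),
                     class = "preprocess_model")
  list(matrix = scale_transform(scaler, full),
       model = model,
       prune = pr$prune,
       n_synthetic = if (is.null(syn)) 0L else nrow(syn))
}

#' @export
print.preprocess_model <- function(x, ...) {
  cat(sprintf("Preprocess model: %d retained features, z-score scaler\n",
              length(x$prune$retained)))
  invisible(x)
}

#' Transform new records into a model's scaled feature space
#'
#' Selects the retained features by name (extra columns are ignored;
#' missing ones are an error) and applies the stored scaling statistics.
#'
#' @param model A `preprocess_model` from [prepare()] or [read_model()].
#' @param records Numeric matrix or data frame of raw-feature records.
#' @return Matrix in the scaled feature space, columns in model order.
#' @export
transform_new <- function(model, records) {
  stopifnot(inherits(model, "preprocess_model"))
  records <- as.matrix(records)
  feats <- model$prune$retained
  miss <- setdiff(feats, colnames(records))
  if (length(miss) > 0L)
    stop(sprintf("records are missing required feature '%s'", miss[1L]))
  scale_transform(model$scaler, records[, feats, drop = FALSE])
}

# save/restore the caller's RNG state around seeded operations
.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
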