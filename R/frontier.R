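# decision values within this band of zero are treated as lying on the
# frontier itself: free support vectors sit at decision 0 at the optimum
# and land at +/- ~1e-9 under the solver's KKT tolerance
.MARGIN_TOL <- 1e-6

new_frontier_model <- function(gamma, nu, support_vectors, dual_coefs, rho,
                               feature_names) {
  stopifnot(gamma > 0, nu > 0, nu <= 1,
            nrow(support_vectors) >= 1L,
            length(dual_coefs) == nrow(support_vectors),
            all(dual_coefs >= 0),
            ncol(support_vectors) == length(feature_names))
  colnames(support_vectors) <- feature_names
  structure(list(gamma = gamma, nu = nu,
                 support_vectors = support_vectors,
                 dual_coefs = dual_coefs, rho = rho,
                 feature_names = feature_names),
            class = "frontier_model")
}

#' Fit a one-class SVM frontier
#'
#' Solves the Schoelkopf nu-OCSVM with an RBF kernel
#' `K(x, x') = exp(-gamma * ||x - x'||^2)` on a standardised training
#' matrix, via the libsvm quadratic-programming solver (through
#' \pkg{e1071}). The returned model is self-sufficient: it stores the
#' support vectors, nonnegative dual weights normalised to sum to 1 (each
#' bounded by `1/(nu * n)`), the offset `rho` on the same scale, and the
#' kernel width, so decision values can be evaluated from the stored
#' fields alone.
#'
#' @param x Scaled numeric training matrix (records x features) with
#'   column names; must contain only finite values.
#' @param nu Expected outlier fraction in (0, 1\]; upper-bounds the
#'   fraction of training records outside the frontier and lower-bounds
#'   the support-vector fraction. Default 0.01.
#' @param gamma Either `"one_over_p"` (default; kernel width `1/p`, the
#'   automatic scaling appropriate for unit-variance features) or a
#'   positive number.
#' @param tolerance Solver KKT termination tolerance.
#' @return A `frontier_model`.
#' @export
fit_frontier <- function(x, nu = 0.01, gamma = "one_over_p",
                         tolerance = 1e-7) {
  x <- as.matrix(x)
  if (!all(is.finite(x))) stop("training matrix contains non-finite values")
  if (nrow(x) < 2L) stop("need at least 2 training records")
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  stopifnot(nu > 0, nu <= 1)
  g <- if (identical(gamma, "one_over_p")) 1 / ncol(x) else {
    if (!is.numeric(gamma) || gamma <= 0) stop("gamma must be 'one_over_p' or a positive number")
    as.numeric(gamma)
  }
  fit <- e1071::svm(x, y = NULL, type = "one-classification",
                    kernel = "radial", gamma = g, nu = nu,
                    scale = FALSE, tolerance = tolerance)
  if (is.null(fit$SV) || nrow(fit$SV) == 0L)
    stop("solver returned no support vectors")
  n <- nrow(x)
  # libsvm scales the one-class dual so that sum(alpha) = nu * n with
  # alpha_i <= 1; renormalise to the textbook convention sum(alpha) = 1,
  # alpha_i <= 1/(nu n); rho scales identically so the sign is unchanged
  scl <- nu * n
  new_frontier_model(gamma = g, nu = nu,
                     support_vectors = unname(as.matrix(fit$SV)),
                     dual_coefs = as.numeric(fit$coefs) / scl,
                     rho = fit$rho / scl,
                     feature_names = colnames(x))
}

#' @export
print.frontier_model <- function(x, ...) {
  cat(sprintf("One-class SVM frontier: %d support vectors, %d features, nu = %g, gamma = %g\n",
              nrow(x$support_vectors), length(x$feature_names), x$nu, x$gamma))
  invisible(x)
}

#' Evaluate the frontier decision function
#'
#' Computes the signed decision value
#' `sum_i alpha_i exp(-gamma ||x - sv_i||^2) - rho` for each record from
#' the model's stored fields. Non-negative values are inside the frontier.
#'
#' @param model A `frontier_model`.
#' @param records Matrix of records in the model's scaled feature space,
#'   columns matching `model$feature_names`.
#' @return Numeric vector of decision values.
#' @export
decision_values <- function(model, records) {
  stopifnot(inherits(model, "frontier_model"))
  records <- as.matrix(records)
  if (is.null(colnames(records)) && ncol(records) == length(model$feature_names))
    colnames(records) <- model$feature_names
  records <- .check_feature_names(records, model$feature_names)
  sv <- model$support_vectors
  d2 <- outer(rowSums(records^2), rowSums(sv^2), "+") - 2 * records %*% t(sv)
  d2[d2 < 0] <- 0   # guard tiny negative round-off
  drop(exp(-model$gamma * d2) %*% model$dual_coefs) - model$rho
}

#' Classify records against the frontier
#'
#' A record is an inlier iff its decision value is non-negative; the
#' boundary itself counts as inside. Decision values within a small
#' numerical band of zero (`margin_tol`) are resolved as on-the-frontier
#' inliers, because free support vectors sit exactly on the zero level set
#' at the optimum and acquire sign jitter at the solver's tolerance.
#'
#' @param model A `frontier_model`.
#' @param records Matrix in the model's scaled feature space.
#' @param margin_tol Half-width of the numerical zero band (default 1e-6).
#' @return A data frame with columns `decision` (raw value) and `label`
#'   (factor, `inlier`/`outlier`).
#' @export
classify <- function(model, records, margin_tol = .MARGIN_TOL) {
  dec <- decision_values(model, records)
  lab <- ifelse(dec >= -margin_tol, "inlier", "outlier")
  data.frame(decision = dec,
             label = factor(lab, levels = c("inlier", "outlier")))
}

#' Decision-value grid for a two-feature frontier
#'
#' Evaluates the decision function over a Cartesian grid, for contour
#' plots of the frontier (the zero level set) of a model trained on
#' exactly two features.
#'
#' @param model A `frontier_model` with exactly 2 features.
#' @param x_range,y_range Length-2 numeric ranges for the two features,
#'   in scaled units.
#' @param resolution Number of grid points per axis (default 100).
#' @return A list with `x`, `y` (axis coordinates) and `z` (a
#'   `resolution` x `resolution` matrix of decision values, rows indexed
#'   by `x`), suitable for [graphics::contour()].
#' @export
decision_grid <- function(model, x_range, y_range, resolution = 100L) {
  stopifnot(inherits(model, "frontier_model"))
  if (length(model$feature_names) != 2L)
    stop("decision_grid requires a model trained on exactly 2 features")
  stopifnot(length(x_range) == 2L, length(y_range) == 2L, resolution >= 2L)
  xs <- seq(x_range[1L], x_range[2L], length.out = resolution)
  ys <- seq(y_range[1L], y_range[2L], length.out = resolution)
  pts <- cbind(rep(xs, times = resolution), rep(ys, each = resolution))
  colnames(pts) <- model$feature_names
  z <- matrix(decision_values(model, pts), resolution, resolution)
  list(x = xs, y = ys, z = z)
}

#' Write a decision grid as a plain long-format table
#'
#' @param grid A grid from [decision_grid()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_grid_csv <- function(grid, path) {
  df <- data.frame(x = rep(grid$x, times = length(grid$y)),
                   y = rep(grid$y, each = length(grid$x)),
                   decision = as.vector(grid$z))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
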