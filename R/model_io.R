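.MODEL_FORMAT_VERSION <- "1.0"

#' Write a fitted drift-detection model to a JSON file
#'
#' Serialises the preprocessing contract (retained feature names,
#' per-feature scaling statistics) together with the fitted one-class
#' frontier (support vectors, dual weights, offset, kernel width) as
#' self-describing JSON. All numeric fields are written at full double
#' precision so that a read-back model reproduces decision values exactly.
#'
#' @param preprocess A `preprocess_model` from [prepare()].
#' @param frontier A `frontier_model` from [fit_frontier()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @seealso [read_model()]
#' @export
write_model <- function(preprocess, frontier, path) {
  stopifnot(inherits(preprocess, "preprocess_model"),
            inherits(frontier, "frontier_model"))
  if (!identical(preprocess$prune$retained, frontier$feature_names))
    stop("preprocess and frontier disagree on feature names")
  obj <- list(
    format_version = .MODEL_FORMAT_VERSION,
    retained_features = preprocess$prune$retained,
    scaler = list(means = unname(preprocess$scaler$means),
                  sds = unname(preprocess$scaler$sds)),
    frontier = list(gamma = frontier$gamma,
                    nu = frontier$nu,
                    support_vectors = unname(frontier$support_vectors),
                    dual_coefs = unname(frontier$dual_coefs),
                    rho = frontier$rho)
  )
  # 17 significant digits: the shortest length at which every IEEE double
  # survives a text round-trip exactly
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' Read a drift-detection model from a JSON file
#'
#' @param path Path to a file written by [write_model()].
#' @return A list with elements `preprocess` (class `preprocess_model`)
#'   and `frontier` (class `frontier_model`).
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) stop(sprintf("cannot parse model file: %s",
                                                   conditionMessage(e))))
  if (is.null(obj$format_version))
    stop("model file has no format_version field")
  if (!identical(as.character(obj$format_version), .MODEL_FORMAT_VERSION))
    stop(sprintf("model format version '%s' not supported (expected '%s')",
                 obj$format_version, .MODEL_FORMAT_VERSION))
  need <- c("retained_features", "scaler", "frontier")
  miss <- setdiff(need, names(obj))
  if (length(miss) > 0L)
    stop(sprintf("model file missing field '%s'", miss[1L]))
  for (f in c("means", "sds"))
    if (is.null(obj$scaler[[f]])) stop(sprintf("model file missing scaler field '%s'", f))
  for (f in c("gamma", "nu", "support_vectors", "dual_coefs", "rho"))
    if (is.null(obj$frontier[[f]]))
      stop(sprintf("model file missing frontier field '%s'", f))

  feats <- as.character(obj$retained_features)
  scaler <- scaler_model(stats::setNames(as.numeric(obj$scaler$means), feats),
                         stats::setNames(as.numeric(obj$scaler$sds), feats))
  prune <- structure(list(retained = feats, removed = character(0),
                          threshold = NA_real_),
                     class = "prune_result")
  pre <- structure(list(prune = prune, scaler = scaler),
                   class = "preprocess_model")
  sv <- obj$frontier$support_vectors
  if (is.list(sv)) sv <- do.call(rbind, lapply(sv, as.numeric))
  sv <- matrix(as.numeric(sv), ncol = length(feats),
               dimnames = list(NULL, feats))
  fr <- new_frontier_model(gamma = as.numeric(obj$frontier$gamma),
                           nu = as.numeric(obj$frontier$nu),
                           support_vectors = sv,
                           dual_coefs = as.numeric(obj$frontier$dual_coefs),
                           rho = as.numeric(obj$frontier$rho),
                           feature_names = feats)
  list(preprocess = pre, frontier = fr)
}
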