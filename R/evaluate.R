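#' Score simulated cohorts and tabulate inlier rates
#'
#' Classifies every record of each drifted cohort against the frontier
#' and reports, per noise level, the inlier/outlier counts and the
#' percentage classified as inliers. Rising inlier rates across noisier
#' drifted cohorts indicate growing overlap with the training population.
#'
#' @param model A `frontier_model`.
#' @param cohorts List of `drift_cohort` objects (see [simulate_drift()]).
#' @return A `drift_report`: a data frame with columns `noise_frac`,
#'   `n_total`, `n_inliers`, `n_outliers`, `proportion_inliers` (percent).
#' @export
evaluate_cohorts <- function(model, cohorts) {
  stopifnot(inherits(model, "frontier_model"))
  rows <- lapply(cohorts, function(co) {
    if (nrow(co$features) == 0L) stop("empty cohort")
    cl <- classify(model, co$features)
    n <- nrow(co$features)
    k <- sum(cl$label == "inlier")
    data.frame(noise_frac = co$noise_frac, n_total = n,
               n_inliers = k, n_outliers = n - k,
               proportion_inliers = 100 * k / n)
  })
  out <- if (length(rows) == 0L)
    data.frame(noise_frac = numeric(0), n_total = integer(0),
               n_inliers = integer(0), n_outliers = integer(0),
               proportion_inliers = numeric(0))
  else do.call(rbind, rows)
  class(out) <- c("drift_report", "data.frame")
  out
}

#' @export
print.drift_report <- function(x, ...) {
  cat(format_drift_report(x), sep = "\n")
  invisible(x)
}

#' Render a drift report as an aligned plain-text table
#'
#' @param report A `drift_report` from [evaluate_cohorts()].
#' @return Character vector of table lines.
#' @export
format_drift_report <- function(report) {
  hdr <- c("Noise level (%)", "Records classified as inliers",
           "Proportion classified as inliers (%)")
  rows <- cbind(format(100 * report$noise_frac),
                format(report$n_inliers),
                sprintf("%.2f", report$proportion_inliers))
  w <- pmax(nchar(hdr), if (nrow(report)) apply(nchar(rows), 2, max) else 0L)
  pad <- function(v) paste(mapply(formatC, v, width = w), collapse = "  ")
  c(pad(hdr), if (nrow(report)) apply(rows, 1, pad))
}

#' Write a drift report as JSON
#'
#' @param report A `drift_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(as.data.frame(report), path, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Monitor a record stream for population drift
#'
#' Flags each incoming record as inlier or outlier against the frontier
#' and raises an alert whenever the outlier count within the trailing
#' window of `window` records exceeds the one-sided binomial critical
#' value for the no-drift outlier rate `nu_ref` at level `alert_alpha`
#' (i.e. the count `c` with `P(Bin(window, nu_ref) > c) <= alert_alpha`).
#' Windows that are not yet full never alert.
#'
#' @param model A `frontier_model`.
#' @param records Matrix of records in the model's scaled feature space,
#'   in arrival order.
#' @param window Window length W in records (default 100).
#' @param nu_ref Expected outlier fraction under no drift (default the
#'   model's `nu`).
#' @param alert_alpha One-sided significance level for the alert
#'   (default 0.01).
#' @return A list with `flags` (factor inlier/outlier per record),
#'   `alerts` (data frame: `index` of the record completing an alerting
#'   window, `outlier_frac` in that window), `critical` (the critical
#'   count) and the monitor settings.
#' @export
monitor_stream <- function(model, records, window = 100L,
                           nu_ref = model$nu, alert_alpha = 0.01) {
  stopifnot(inherits(model, "frontier_model"),
            window >= 1L, alert_alpha > 0, alert_alpha < 1,
            nu_ref >= 0, nu_ref <= 1)
  cl <- classify(model, records)
  out <- cl$label == "outlier"
  n <- length(out)
  crit <- stats::qbinom(1 - alert_alpha, window, nu_ref)
  alerts <- data.frame(index = integer(0), outlier_frac = numeric(0))
  if (n >= window) {
    cum <- cumsum(out)
    counts <- cum[window:n] - c(0, cum)[seq.int(1L, n - window + 1L)]
    hit <- which(counts > crit)
    alerts <- data.frame(index = hit + window - 1L,
                         outlier_frac = counts[hit] / window)
  }
  list(flags = cl$label, alerts = alerts, critical = crit,
       window = as.integer(window), nu_ref = nu_ref,
       alert_alpha = alert_alpha)
}
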