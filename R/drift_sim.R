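#' Specify a drifted-population simulation
#'
#' Parameters of the drifted-cohort simulator: cohorts are centred on the
#' real training records attaining the minimum and maximum of an anchor
#' feature, offset further outward along that feature by `offset_sd`
#' training standard deviations, with independent Gaussian noise of SD
#' `noise_frac` (as a fraction of the per-feature training SD) added to
#' every feature. All quantities are expressed in the scaled feature
#' space, where every feature's training SD is 1.
#'
#' @param anchor_feature Feature along which the population drifts
#'   (default `"radius_mean"`).
#' @param offset_sd Outward offset in training-SD units (default 0.4).
#' @param noise_fracs Noise SDs as fractions of the training SD (default
#'   `c(0.05, 0.10, 0.30)`).
#' @param n_per_side Records per side (low/high) per noise level
#'   (default 5000, i.e. 10000 records per level).
#' @param seed Integer seed.
#' @return A `drift_spec` list.
#' @export
drift_spec <- function(anchor_feature = "radius_mean", offset_sd = 0.4,
                       noise_fracs = c(0.05, 0.10, 0.30),
                       n_per_side = 5000L, seed = 1L) {
  stopifnot(offset_sd >= 0, all(noise_fracs >= 0), n_per_side >= 1L)
  structure(list(anchor_feature = anchor_feature, offset_sd = offset_sd,
                 noise_fracs = noise_fracs,
                 n_per_side = as.integer(n_per_side),
                 seed = as.integer(seed)),
            class = "drift_spec")
}

#' Locate the drifted-population centres
#'
#' Finds the full training rows attaining the minimum and maximum of the
#' anchor feature and offsets only that coordinate outward by
#' `offset_sd`: the low centre is the minimising row with `offset_sd`
#' subtracted from its anchor value, the high centre the maximising row
#' with `offset_sd` added. Ties at the extremum are broken by first
#' occurrence.
#'
#' @param x Prepared (scaled) training matrix with named columns.
#' @param anchor_feature Name of the anchor feature.
#' @param offset_sd Offset in scaled units (training SDs).
#' @return A list with numeric vectors `low` and `high` (one coordinate
#'   per feature).
#' @export
find_anchors <- function(x, anchor_feature = "radius_mean", offset_sd = 0.4) {
  x <- as.matrix(x)
  if (!anchor_feature %in% colnames(x))
    stop(sprintf("anchor feature '%s' not present", anchor_feature))
  a <- x[, anchor_feature]
  low <- x[which.min(a), ]
  high <- x[which.max(a), ]
  low[anchor_feature] <- low[anchor_feature] - offset_sd
  high[anchor_feature] <- high[anchor_feature] + offset_sd
  list(low = low, high = high)
}

#' Simulate drifted patient cohorts
#'
#' For each noise level, draws `n_per_side` records around each of the
#' low and high centres from [find_anchors()]: record = centre +
#' `noise_frac * z` with `z` independent standard Gaussian per feature
#' (the anchor coordinate included). In the scaled space the per-feature
#' training SD is 1, so `noise_frac` is directly the noise SD.
#'
#' @param x Prepared (scaled) training matrix.
#' @param spec A [drift_spec()].
#' @return A list of `drift_cohort` objects, one per noise level, each
#'   with elements `features` (matrix in scaled space), `side` (factor
#'   low/high per record) and `noise_frac`.
#' @export
simulate_drift <- function(x, spec) {
  stopifnot(inherits(spec, "drift_spec"))
  x <- as.matrix(x)
  anchors <- find_anchors(x, spec$anchor_feature, spec$offset_sd)
  p <- ncol(x)
  old <- .save_rng(); on.exit(.restore_rng(old))
  lapply(seq_along(spec$noise_fracs), function(k) {
    eps <- spec$noise_fracs[k]
    # stage seed per level so levels are independent and individually
    # reproducible; kept below 2^31
    set.seed((spec$seed + 104729 * k) %% 2147483647)
    m <- spec$n_per_side
    centre <- rbind(matrix(anchors$low, m, p, byrow = TRUE),
                    matrix(anchors$high, m, p, byrow = TRUE))
    noise <- eps * matrix(stats::rnorm(2 * m * p), 2 * m, p)
    feats <- centre + noise
    colnames(feats) <- colnames(x)
    structure(list(features = feats,
                   side = factor(rep(c("low", "high"), each = m),
                                 levels = c("low", "high")),
                   noise_frac = eps),
              class = "drift_cohort")
  })
}

#' @export
print.drift_cohort <- function(x, ...) {
  cat(sprintf("Drift cohort: %d records (noise %g x training SD)\n",
              nrow(x$features), x$noise_frac))
  invisible(x)
}

#' Write simulated cohorts to CSV
#'
#' One row per simulated record, with `side` and `noise_frac` metadata
#' columns followed by the scaled feature values.
#'
#' @param cohorts List of `drift_cohort` objects from [simulate_drift()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_drift_csv <- function(cohorts, path) {
  dfs <- lapply(cohorts, function(co) {
    cbind(data.frame(side = as.character(co$side),
                     noise_frac = co$noise_frac),
          as.data.frame(co$features, check.names = FALSE))
  })
  utils::write.csv(do.call(rbind, dfs), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read simulated cohorts from CSV
#'
#' @param path CSV written by [write_drift_csv()].
#' @return List of `drift_cohort` objects, one per distinct noise level,
#'   in order of appearance.
#' @export
read_drift_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("side", "noise_frac") %in% names(df)))
    stop("drift CSV must have 'side' and 'noise_frac' columns")
  levels_seen <- unique(df$noise_frac)
  lapply(levels_seen, function(eps) {
    sub <- df[df$noise_frac == eps, , drop = FALSE]
    feats <- as.matrix(sub[, setdiff(names(sub), c("side", "noise_frac")),
                           drop = FALSE])
    structure(list(features = feats,
                   side = factor(sub$side, levels = c("low", "high")),
                   noise_frac = eps),
              class = "drift_cohort")
  })
}
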