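#' Specify a synthetic labelled cohort
#'
#' Describes a two-class cohort generator emulating the structure of the
#' WDBC data: independent Gaussian base features with class-dependent
#' means, plus planted blocks of near-collinear child features, all
#' shifted to be positive (the real features are positive geometric
#' measurements). Child features are built as
#' `r * standardised(parent) + sqrt(1 - r^2) * residual`, which gives the
#' block its target population correlation exactly.
#'
#' @param n_benign,n_malignant Class record counts (defaults 357 / 212,
#'   the WDBC class imbalance).
#' @param base_features Character vector of independent base feature
#'   names.
#' @param collinear_blocks List of blocks, each a list with `parent` (a
#'   base feature name), `children` (new feature names) and `r` (target
#'   population correlation, in (0, 1)).
#' @param class_shift Named numeric vector: per-feature malignant-minus-
#'   benign mean separation in SD units (unnamed features shift 0).
#' @param latent_loadings Named numeric vector of loadings in \[0, 1) on a
#'   shared per-record latent severity factor: base feature j is
#'   `l_j * L + sqrt(1 - l_j^2) * e_j`, giving within-class correlation
#'   `l_j * l_k` between loaded features (unnamed features load 0). This
#'   emulates the strong common size/severity factor of real cell-nucleus
#'   measurements, which makes records extreme on one feature jointly
#'   extreme on the correlated ones.
#' @param latent_df Degrees of freedom of the latent factor's Student-t
#'   distribution, standardised to unit variance (`Inf`, the default,
#'   gives a Gaussian factor). Low values give the factor heavy tails, so
#'   sample extremes stand clear of the bulk the way extremes of real
#'   skewed morphometric features do.
#' @param feature_order Optional character vector giving the column order
#'   of the output (must be a permutation of base + child names); default
#'   base features followed by children.
#' @param anchor_feature Feature intended as the drift anchor (metadata).
#' @param positive_shift Constant added to every feature so all values
#'   are positive (default 10 SD units; a constant shift preserves all
#'   correlations exactly).
#' @param seed Integer seed.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_benign = 357L, n_malignant = 212L,
                           base_features = sprintf("feat_%02d", 1:10),
                           collinear_blocks = list(),
                           class_shift = c(feat_01 = 2),
                           latent_loadings = numeric(0),
                           latent_df = Inf,
                           feature_order = NULL,
                           anchor_feature = base_features[1L],
                           positive_shift = 10,
                           seed = 1L) {
  stopifnot(n_benign >= 1L, n_malignant >= 1L, length(base_features) >= 1L)
  children <- unlist(lapply(collinear_blocks, `[[`, "children"))
  all_feats <- c(base_features, children)
  if (anyDuplicated(all_feats)) stop("duplicate feature names")
  for (b in collinear_blocks) {
    if (!b$parent %in% base_features)
      stop(sprintf("block parent '%s' is not a base feature", b$parent))
    if (!is.numeric(b$r) || b$r <= 0 || b$r >= 1)
      stop(sprintf("infeasible correlation target %s for parent '%s'",
                   format(b$r), b$parent))
  }
  if (is.null(feature_order)) feature_order <- all_feats
  if (!setequal(feature_order, all_feats) ||
      length(feature_order) != length(all_feats))
    stop("feature_order must be a permutation of all feature names")
  if (!anchor_feature %in% all_feats) stop("unknown anchor feature")
  if (length(latent_loadings) > 0 &&
      (any(latent_loadings < 0) || any(latent_loadings >= 1)))
    stop("latent loadings must lie in [0, 1)")
  if (!is.numeric(latent_df) || latent_df <= 2)
    stop("latent_df must exceed 2 (finite variance required)")
  structure(list(n_benign = as.integer(n_benign),
                 n_malignant = as.integer(n_malignant),
                 base_features = base_features,
                 collinear_blocks = collinear_blocks,
                 class_shift = class_shift,
                 latent_loadings = latent_loadings,
                 latent_df = latent_df,
                 feature_order = feature_order,
                 anchor_feature = anchor_feature,
                 positive_shift = positive_shift,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic labelled cohort
#'
#' Draws a cohort from a [synthetic_spec()]: benign records first, then
#' malignant. Base feature j is N(0, 1) for benign and
#' N(class_shift_j, 1) for malignant; each collinear child is
#' `r * z_parent + sqrt(1 - r^2) * e` with `z_parent` the parent
#' standardised by its analytic mixture moments and `e` standard
#' Gaussian, so the child-parent population correlation equals `r`.
#' Finally `positive_shift` is added to every feature.
#'
#' @param spec A [synthetic_spec()].
#' @return A [labeled_cohort].
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n_b <- spec$n_benign; n_m <- spec$n_malignant
  n <- n_b + n_m
  w_m <- n_m / n; w_b <- n_b / n
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(spec$seed)
  shifts <- stats::setNames(rep(0, length(spec$base_features)),
                            spec$base_features)
  known <- intersect(names(spec$class_shift), spec$base_features)
  shifts[known] <- spec$class_shift[known]
  loads <- stats::setNames(rep(0, length(spec$base_features)),
                           spec$base_features)
  kl <- intersect(names(spec$latent_loadings), spec$base_features)
  loads[kl] <- spec$latent_loadings[kl]
  latent <- if (is.finite(spec$latent_df)) {
    stats::rt(n, spec$latent_df) / sqrt(spec$latent_df / (spec$latent_df - 2))
  } else stats::rnorm(n)
  base <- matrix(stats::rnorm(n * length(spec$base_features)), n,
                 dimnames = list(NULL, spec$base_features))
  base <- sweep(base, 2, sqrt(1 - loads^2), "*") + outer(latent, loads)
  mal <- seq.int(n_b + 1L, n)
  base[mal, ] <- sweep(base[mal, , drop = FALSE], 2, shifts, "+")
  cols <- as.data.frame(base, check.names = FALSE)
  for (b in spec$collinear_blocks) {
    s <- shifts[[b$parent]]
    mix_mean <- w_m * s
    mix_sd <- sqrt(1 + w_b * w_m * s^2)
    z_par <- (base[, b$parent] - mix_mean) / mix_sd
    for (ch in b$children)
      cols[[ch]] <- b$r * z_par + sqrt(1 - b$r^2) * stats::rnorm(n)
  }
  feats <- as.matrix(cols)[, spec$feature_order, drop = FALSE] +
    spec$positive_shift
  labeled_cohort(feats, rep(c("benign", "malignant"), c(n_b, n_m)))
}

#' WDBC-shaped synthetic preset
#'
#' Convenience generator for a cohort with the 30 canonical WDBC feature
#' names and class counts (357 benign, 212 malignant), in which the nine
#' features that multicollinearity pruning removes from the real data
#' (perimeter/area mean, se and worst, radius_worst, texture_worst,
#' concave points_mean) are planted as collinear children (target
#' r = 0.95) of features that are retained. Pruning at threshold 0.9
#' therefore removes exactly those nine names, and the full pipeline is
#' exercisable offline with the same shapes as on the real data.
#' Malignant records have larger radius, texture, compactness and
#' concavity means, so the anchor feature (`radius_mean`) separates the
#' classes. Size- and shape-related features load on a shared latent
#' severity factor (moderate pairwise correlations, as in the real
#' measurements), so records extreme on the anchor are jointly extreme
#' on the correlated features and the drift anchors sit at the periphery
#' of the training cloud.
#'
#' @param seed Integer seed.
#' @return A [labeled_cohort] with 569 records and 30 features.
#' @export
generate_wdbc_shaped <- function(seed = 1L) {
  canon <- wdbc_feature_names()
  planted <- c("perimeter_mean", "area_mean", "concave points_mean",
               "perimeter_se", "area_se", "radius_worst", "texture_worst",
               "perimeter_worst", "area_worst")
  base <- setdiff(canon, planted)
  blocks <- list(
    list(parent = "radius_mean",
         children = c("perimeter_mean", "area_mean", "radius_worst",
                      "perimeter_worst", "area_worst"), r = 0.95),
    list(parent = "concavity_mean", children = "concave points_mean", r = 0.95),
    list(parent = "radius_se", children = c("perimeter_se", "area_se"), r = 0.95),
    list(parent = "texture_mean", children = "texture_worst", r = 0.95)
  )
  spec <- synthetic_spec(
    n_benign = 357L, n_malignant = 212L,
    base_features = base,
    collinear_blocks = blocks,
    class_shift = c(radius_mean = 2, texture_mean = 1,
                    compactness_mean = 1, concavity_mean = 1.5),
    latent_loadings = c(radius_mean = 0.9, radius_se = 0.8,
                        compactness_mean = 0.65, concavity_mean = 0.65,
                        compactness_se = 0.5, concavity_se = 0.5,
                        smoothness_worst = 0.5, compactness_worst = 0.65,
                        concavity_worst = 0.65,
                        "concave points_worst" = 0.65,
                        symmetry_worst = 0.45),
    latent_df = 4,
    feature_order = canon,
    positive_shift = 15,
    anchor_feature = "radius_mean",
    seed = seed)
  generate_cohort(spec)
}
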