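test_that("greedy pruning matches an independent brute-force scan", {
  for (seed in c(2, 17, 31)) {
    set.seed(seed)
    n <- 120
    base <- matrix(rnorm(n * 5), n, 5)
    # plant a correlated block: columns 6-8 are noisy copies of 1-2
    x <- cbind(base,
               base[, 1] + rnorm(n, sd = 0.1),
               base[, 2] + rnorm(n, sd = 0.1),
               base[, 1] + rnorm(n, sd = 0.05))
    colnames(x) <- sprintf("c%02d", 1:8)
    co <- labeled_cohort(x, rep(c("benign", "malignant"), length.out = n))
    got <- prune_collinear(co, threshold = 0.9)
    ref <- prune_ref(x, 0.9)
    expect_identical(got$prune$retained, ref$retained)
    expect_identical(got$prune$removed, ref$removed)
    # partition invariant
    expect_setequal(c(got$prune$retained, got$prune$removed), colnames(x))
    # no retained pair exceeds the threshold (full pairwise recomputation)
    kept <- got$cohort$features
    cm <- abs(cor(kept))
    expect_lte(max(cm[upper.tri(cm)]), 0.9)
  }
})

test_that("pruning edge cases: exact duplicates, independence, constants", {
  set.seed(4)
  x <- matrix(rnorm(200), 100, 2, dimnames = list(NULL, c("a", "b")))
  co <- labeled_cohort(x, rep("benign", 100))
  expect_length(prune_collinear(co, 0.9)$prune$removed, 0L)

  dup <- cbind(x, a_copy = x[, "a"])
  co2 <- labeled_cohort(dup, rep("benign", 100))
  expect_identical(prune_collinear(co2, 0.9)$prune$removed, "a_copy")

  cst <- cbind(x, flat = rep(1, 100))
  co3 <- labeled_cohort(cst, rep("benign", 100))
  expect_error(prune_collinear(co3, 0.9), "constant feature 'flat'")
})

test_that("SMOTE produces the required counts and stays on kNN segments", {
  set.seed(8)
  mino <- matrix(rnorm(20 * 3, mean = 5), 20, 3,
                 dimnames = list(NULL, c("p", "q", "r")))
  syn <- smote_oversample(mino, target_count = 32, k_neighbors = 4, seed = 99)
  expect_equal(nrow(syn), 12L)
  expect_identical(colnames(syn), colnames(mino))
  # every synthetic row lies on a segment to a true k nearest neighbour
  for (i in seq_len(nrow(syn)))
    expect_true(smote_row_ok(syn[i, ], mino, k = 4))
  # coordinate-wise convex hull bound against all candidate segments is
  # implied by segment membership; also check reproducibility
  expect_identical(syn,
                   smote_oversample(mino, target_count = 32,
                                    k_neighbors = 4, seed = 99))
  expect_false(identical(syn,
                         smote_oversample(mino, target_count = 32,
                                          k_neighbors = 4, seed = 100)))
})

test_that("SMOTE degenerate and error cases", {
  mino <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, c("a", "b", "c")))
  expect_equal(nrow(smote_oversample(mino, target_count = 10, seed = 1)), 0L)
  expect_error(smote_oversample(mino, target_count = 5, seed = 1),
               "below current")
  expect_error(smote_oversample(mino[1:4, ], target_count = 10,
                                k_neighbors = 5, seed = 1),
               "at least k_neighbors")
})

test_that("scaler standardises to mean 0 / SD 1 and round-trips", {
  set.seed(12)
  x <- matrix(rexp(400, rate = 0.2), 100, 4,
              dimnames = list(NULL, paste0("v", 1:4)))
  sc <- fit_scaler(x)
  z <- scale_transform(sc, x)
  expect_lt(max(abs(colMeans(z))), 1e-9)
  sd_pop <- function(v) sqrt(mean((v - mean(v))^2))
  expect_lt(max(abs(apply(z, 2, sd_pop) - 1)), 1e-9)
  # probe rows at mu and mu +/- sigma map to 0 and +/- 1
  probe <- rbind(sc$means, sc$means + sc$sds, sc$means - sc$sds)
  colnames(probe) <- names(sc$means)
  expect_equal(unname(scale_transform(sc, probe)),
               rbind(rep(0, 4), rep(1, 4), rep(-1, 4)), tolerance = 1e-12)
  # inverse transform round-trip
  expect_equal(scale_inverse(sc, z), x, tolerance = 1e-12)
})

test_that("scaler rejects zero-variance columns and name mismatches", {
  x <- cbind(a = rnorm(50), b = rep(2, 50))
  expect_error(fit_scaler(x), "zero-variance column 'b'")
  sc <- fit_scaler(cbind(a = rnorm(50), b = rnorm(50)))
  bad <- cbind(a = rnorm(5), z = rnorm(5))
  expect_error(scale_transform(sc, bad), "do not match")
})

test_that("prepare chains prune, SMOTE, label removal and scaling", {
  co <- generate_wdbc_shaped(seed = 21)
  prep <- prepare(co, seed = 7)
  expect_equal(dim(prep$matrix), c(2L * 357L, 21L))
  expect_equal(prep$n_synthetic, 357L - 212L)
  # planted redundant features are absent from the prepared columns
  expect_false(any(c("perimeter_mean", "area_worst") %in%
                     colnames(prep$matrix)))
  # scaler features equal retained features, same order
  expect_identical(names(prep$model$scaler$means), prep$prune$retained)
  # bitwise reproducibility
  expect_identical(prep$matrix, prepare(co, seed = 7)$matrix)
})

test_that("prepare adds no rows to an already balanced cohort", {
  co <- tiny_cohort(n_benign = 20, n_malignant = 20, p = 3, seed = 30)
  prep <- prepare(co, seed = 1)
  expect_equal(prep$n_synthetic, 0L)
  expect_equal(nrow(prep$matrix), 40L)
})

test_that("transform_new applies the training contract to raw records", {
  co <- generate_wdbc_shaped(seed = 2)
  prep <- prepare(co, seed = 3)
  z <- transform_new(prep$model, co$features)   # full 30-feature input
  expect_identical(colnames(z), prep$prune$retained)
  # same records transformed by hand
  byhand <- scale_transform(prep$model$scaler,
                            co$features[, prep$prune$retained])
  expect_equal(z, byhand, tolerance = 0)
  expect_error(transform_new(prep$model, co$features[, 1:3]),
               "missing required feature")
})
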