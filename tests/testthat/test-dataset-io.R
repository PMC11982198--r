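# writes a cohort in the raw UCI dialect (32 unnamed comma-separated fields)
write_uci_raw <- function(cohort, path) {
  stopifnot(ncol(cohort$features) == 30L)
  codes <- ifelse(cohort$labels == "malignant", "M", "B")
  lines <- vapply(seq_len(nrow(cohort$features)), function(i) {
    paste(c(cohort$record_ids[i], codes[i],
            format(cohort$features[i, ], digits = 17, trim = TRUE,
                   scientific = FALSE)), collapse = ",")
  }, character(1))
  writeLines(lines, path)
}

test_that("bundled WDBC cohort has the known shape and class counts", {
  co <- wdbc_cohort()
  expect_s3_class(co, "labeled_cohort")
  expect_equal(nrow(co$features), 569L)
  expect_equal(ncol(co$features), 30L)
  expect_equal(unname(table(co$labels)[["benign"]]), 357L)
  expect_equal(unname(table(co$labels)[["malignant"]]), 212L)
  expect_identical(colnames(co$features), wdbc_feature_names())
  # deterministic with record order preserved
  expect_identical(co$features, wdbc_cohort()$features)
})

test_that("the two file dialects parse one dataset identically", {
  co <- generate_wdbc_shaped(seed = 11)
  raw <- tempfile(fileext = ".data"); csv <- tempfile(fileext = ".csv")
  write_uci_raw(co, raw)
  write_cohort_csv(co, csv)
  a <- load_wdbc(raw, dialect = "uci_raw")
  b <- load_wdbc(csv, dialect = "headered_csv")
  expect_equal(a$features, b$features, tolerance = 1e-15)
  expect_identical(a$labels, b$labels)
  # auto-detection picks the right dialect for both
  expect_equal(load_wdbc(raw)$features, a$features, tolerance = 0)
  expect_equal(load_wdbc(csv)$features, b$features, tolerance = 0)
  unlink(c(raw, csv))
})

test_that("alias spellings of feature names are canonicalised on input", {
  co <- tiny_cohort(p = 2, prefix = "x")
  colnames(co$features) <- c("texture_worse", "radius_mean")
  csv <- tempfile(fileext = ".csv")
  write_cohort_csv(co, csv)
  got <- load_wdbc(csv, dialect = "headered_csv")
  expect_true("texture_worst" %in% colnames(got$features))
  expect_false("texture_worse" %in% colnames(got$features))
  unlink(csv)
})

test_that("malformed inputs fail loudly with located errors", {
  f <- tempfile()
  writeLines(character(0), f)
  expect_error(load_wdbc(f), "no records")

  writeLines("1,M,3.2,4.1", f)
  expect_error(load_wdbc(f, dialect = "uci_raw"), "expected 32")

  co <- generate_wdbc_shaped(seed = 3)
  write_uci_raw(co, f)
  lines <- readLines(f)
  parts <- strsplit(lines[5], ",")[[1]]; parts[4] <- ""
  lines[5] <- paste(parts, collapse = ",")
  writeLines(lines, f)
  expect_error(load_wdbc(f, dialect = "uci_raw"), "row 5.*texture_mean")

  write_uci_raw(co, f)
  lines <- readLines(f)
  lines[2] <- sub("^([^,]*),[MB],", "\\1,Q,", lines[2])
  writeLines(lines, f)
  expect_error(load_wdbc(f, dialect = "uci_raw"), "unknown label code: 'Q'")
  unlink(f)
})

test_that("cohort invariants are enforced by the constructor", {
  m <- matrix(1:6, 3, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(labeled_cohort(m, c("benign", "odd", "benign")), "unknown label")
  m2 <- m; m2[2, 1] <- NA
  expect_error(labeled_cohort(m2, rep("benign", 3)), "row 2.*'a'")
  colnames(m) <- c("a", "a")
  expect_error(labeled_cohort(m, rep("benign", 3)), "unique")
  expect_error(labeled_cohort(matrix(numeric(0), 0, 2,
                                     dimnames = list(NULL, c("a", "b"))),
                              character(0)), "no records")
})

test_that("model JSON round-trips to identical decision values", {
  co <- tiny_cohort(n_benign = 30, n_malignant = 18, p = 3, seed = 5)
  prep <- prepare(co, seed = 9)
  fm <- fit_frontier(prep$matrix, nu = 0.1)
  path <- tempfile(fileext = ".json")
  write_model(prep$model, fm, path)
  back <- read_model(path)
  set.seed(1)
  probe <- matrix(rnorm(20 * 3), 20, 3,
                  dimnames = list(NULL, fm$feature_names))
  expect_identical(decision_values(back$frontier, probe),
                   decision_values(fm, probe))
  expect_identical(back$frontier$dual_coefs, fm$dual_coefs)
  expect_identical(back$frontier$rho, fm$rho)
  expect_identical(back$preprocess$scaler$means, prep$model$scaler$means)
  expect_identical(back$preprocess$scaler$sds, prep$model$scaler$sds)
  unlink(path)
})

test_that("corrupt or mismatched model files are rejected", {
  co <- tiny_cohort(seed = 6)
  prep <- prepare(co, seed = 2)
  fm <- fit_frontier(prep$matrix, nu = 0.2)
  path <- tempfile(fileext = ".json")
  write_model(prep$model, fm, path)

  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$frontier$rho <- NULL
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  expect_error(read_model(path), "missing frontier field 'rho'")

  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$frontier$rho <- fm$rho; obj$format_version <- "99.0"
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  expect_error(read_model(path), "version")

  writeLines(substr(paste(readLines(path), collapse = ""), 1, 50), path)
  expect_error(read_model(path))
  unlink(path)
})

test_that("a hand-built one-support-vector model evaluates the kernel expansion", {
  path <- tempfile(fileext = ".json")
  writeLines('{
    "format_version": "1.0",
    "retained_features": ["u", "v"],
    "scaler": {"means": [0, 0], "sds": [1, 1]},
    "frontier": {"gamma": 0.5, "nu": 0.5,
                 "support_vectors": [[1.0, 2.0]],
                 "dual_coefs": [1.0], "rho": 0.3}
  }', path)
  m <- read_model(path)$frontier
  sv <- matrix(c(1, 2), 1, 2, dimnames = list(NULL, c("u", "v")))
  # at the support vector the kernel is 1, so decision = alpha * 1 - rho
  expect_equal(decision_values(m, sv), 1 - 0.3, tolerance = 1e-15)
  far <- sv + c(3, -4)  # squared distance 25
  expect_equal(decision_values(m, far), exp(-0.5 * 25) - 0.3,
               tolerance = 1e-15)
  unlink(path)
})
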