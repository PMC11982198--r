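# Independent reference implementations used as oracles. These are kept
# deliberately naive (explicit loops, textbook formulas) and separate from
# the package's vectorised code paths.

# Pearson correlation from the textbook formula
pearson_ref <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# greedy multicollinearity scan, loop form
prune_ref <- function(x, threshold) {
  retained <- integer(0)
  for (j in seq_len(ncol(x))) {
    conflict <- FALSE
    for (r in retained) {
      if (abs(pearson_ref(x[, j], x[, r])) > threshold) { conflict <- TRUE; break }
    }
    if (!conflict) retained <- c(retained, j)
  }
  list(retained = colnames(x)[retained],
       removed = colnames(x)[setdiff(seq_len(ncol(x)), retained)])
}

# exhaustive k nearest neighbours (Euclidean), excluding the point itself
knn_ref <- function(x, i, k) {
  d <- apply(x, 1, function(r) sqrt(sum((r - x[i, ])^2)))
  d[i] <- Inf
  order(d)[seq_len(k)]
}

# does synthetic row s lie on the segment between some minority row and
# one of its true k nearest neighbours?
smote_row_ok <- function(s, minority, k) {
  for (i in seq_len(nrow(minority))) {
    for (j in knn_ref(minority, i, k)) {
      v <- minority[j, ] - minority[i, ]
      w <- s - minority[i, ]
      piv <- which.max(abs(v))
      if (abs(v[piv]) < 1e-12) next
      g <- w[piv] / v[piv]
      if (g >= -1e-9 && g <= 1 + 1e-9 &&
          max(abs(w - g * v)) < 1e-8 * max(1, max(abs(minority))))
        return(TRUE)
    }
  }
  FALSE
}

# RBF kernel expansion, scalar loop form
decision_ref <- function(model, x) {
  out <- numeric(nrow(x))
  for (q in seq_len(nrow(x))) {
    acc <- 0
    for (i in seq_len(nrow(model$support_vectors))) {
      d2 <- sum((x[q, ] - model$support_vectors[i, ])^2)
      acc <- acc + model$dual_coefs[i] * exp(-model$gamma * d2)
    }
    out[q] <- acc - model$rho
  }
  out
}

# small labelled cohort with independent Gaussian features
tiny_cohort <- function(n_benign = 25, n_malignant = 15, p = 4, seed = 1,
                        prefix = "f") {
  set.seed(seed)
  n <- n_benign + n_malignant
  feats <- matrix(rnorm(n * p, mean = 10), n, p,
                  dimnames = list(NULL, paste0(prefix, seq_len(p))))
  labeled_cohort(feats, rep(c("benign", "malignant"), c(n_benign, n_malignant)))
}
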