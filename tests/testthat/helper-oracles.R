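# Independent oracles used to cross-check the implementation. These stay
# deliberately naive: explicit formulas, no shared code with R/.

# OLS by the normal equations, (X'X)^{-1} X'y.
ols_normal_equations <- function(design, response) {
  x <- cbind(1, as.matrix(design))
  solve(t(x) %*% x, t(x) %*% response)[, 1]
}

# Closed-form leave-one-out residuals for linear least squares:
# e_i / (1 - h_ii).
loocv_hat_matrix <- function(design, response) {
  x <- cbind(1, as.matrix(design))
  h <- diag(x %*% solve(t(x) %*% x) %*% t(x))
  fit <- x %*% solve(t(x) %*% x, t(x) %*% response)
  e <- response - fit[, 1]
  response - e / (1 - h)  # held-out predictions
}

# Brute-force pooled confusion counting, element by element.
confusion_brute_force <- function(reference, predicted) {
  counts <- c(tpc = 0L, fnc = 0L, tnc = 0L, fpc = 0L)
  for (i in seq_along(reference)) {
    rp <- reference[i] != "poor"
    pp <- predicted[i] != "poor"
    key <- if (rp && pp) "tpc" else if (rp && !pp) "fnc"
    else if (!rp && !pp) "tnc" else "fpc"
    counts[key] <- counts[key] + 1L
  }
  counts
}

# Kappa straight from its definition over an explicit cross-table.
kappa_brute_force <- function(reference, predicted) {
  labels <- unique(c(reference, predicted))
  n <- length(reference)
  po <- mean(reference == predicted)
  pe <- 0
  for (l in labels) {
    pe <- pe + mean(reference == l) * mean(predicted == l)
  }
  if (po == 1) 1 else (po - pe) / (1 - pe)
}

# A small random cohort-shaped design for regression property tests.
random_design <- function(n, p, seed) {
  set.seed(seed)
  as.data.frame(matrix(rnorm(n * p), n, p,
                       dimnames = list(NULL, paste0("x", seq_len(p)))))
}
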