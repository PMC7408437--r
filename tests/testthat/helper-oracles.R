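# Independent oracles used across the suite.  These deliberately reuse
# nothing from the package's vectorized implementations: plain loops over
# genes with stats::t.test / stats::aov.

# naive re-evaluation of the tumor-specificity criteria, gene by gene
naive_select <- function(expr, labels, target, min_fold = 2, max_p = 1e-5) {
  others <- setdiff(unique(labels), target)
  sel <- vapply(seq_len(nrow(expr)), function(i) {
    x <- expr[i, ]
    all(vapply(others, function(o) {
      a <- x[labels == target]; b <- x[labels == o]
      fold <- 2^(mean(a) - mean(b))
      p <- stats::t.test(a, b)$p.value
      fold > min_fold && p < max_p
    }, logical(1)))
  }, logical(1))
  rownames(expr)[sel]
}

# naive re-evaluation of the DE criteria (up and down panels)
naive_de <- function(expr, labels, uhr = "UHR", min_fold = 1.5, max_p = 1e-3) {
  res <- t(vapply(seq_len(nrow(expr)), function(i) {
    x <- expr[i, ]
    a <- x[labels == uhr]; b <- x[labels != uhr]
    c(fold = 2^(mean(a) - mean(b)), p = stats::t.test(a, b)$p.value)
  }, c(fold = 0, p = 0)))
  list(up = rownames(expr)[res[, "fold"] > min_fold & res[, "p"] < max_p],
       down = rownames(expr)[1 / res[, "fold"] > min_fold & res[, "p"] < max_p])
}

# hand product-limit estimator (loop over distinct event times)
naive_km <- function(time, event, horizon) {
  s <- 1
  for (t in sort(unique(time[event == 1]))) {
    if (t > horizon) break
    at_risk <- sum(time >= t)
    d <- sum(time == t & event == 1)
    s <- s * (1 - d / at_risk)
  }
  s
}

# a nonnegative matrix with a planted, well-separated 2x2 block structure
planted_block_matrix <- function(m = 20, n = 15, sep = 2) {
  rows <- sort(rep(1:2, length.out = m))
  cols <- sort(rep(1:2, length.out = n))
  base <- matrix(stats::runif(m * n, 0.5, 1.5), m, n)
  X <- base + sep * outer(rows, cols, "==")
  expr <- t(X)  # genes x samples orientation
  dimnames(expr) <- list(sprintf("g%03d", seq_len(n)), sprintf("s%03d", seq_len(m)))
  list(expr = expr, rows = rows, cols = cols)
}
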