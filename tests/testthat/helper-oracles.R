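# Independent brute-force oracles, coded from the definitions with plain
# loops and never calling the implementation under test.

oracle_index1 <- function(t, y) {
  k <- length(t)
  total <- 0
  for (j in 1:(k - 1)) total <- total + (y[j + 1] - y[j]) / (t[j + 1] - t[j])
  total / (k - 1)
}

oracle_index2 <- function(t, y) {
  k <- length(t)
  total <- 0
  for (j in 1:(k - 1)) total <- total + (t[j + 1] - t[j]) * (y[j] + y[j + 1]) / 2
  total / (k - 1)
}

oracle_index3 <- function(y) {
  k <- length(y)
  m <- sum(y) / k
  ss <- 0
  for (j in 1:k) ss <- ss + (y[j] - m)^2
  sqrt(ss / (k - 1)) / m
}

oracle_index4 <- function(t, y) {
  num <- 0; den <- 0
  for (j in seq_along(t)) { num <- num + t[j] * y[j]; den <- den + t[j] }
  num / den
}

oracle_index5 <- function(y) y[length(y)]

# AUC by exhaustive pair counting, ties worth 1/2
oracle_auc <- function(scores, labels) {
  cs <- scores[labels == 1]; ct <- scores[labels == 0]
  total <- 0
  for (a in cs) for (b in ct) {
    total <- total + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  total / (length(cs) * length(ct))
}

# one-tailed exact McNemar tail by explicit binomial summation
oracle_mcnemar_tail <- function(b, cc) {
  n <- b + cc
  if (n == 0) return(1.0)
  total <- 0
  for (x in b:n) total <- total + choose(n, x) * 0.5^n
  total
}

# simple random series generator for property tests
random_series <- function(k = NULL) {
  if (is.null(k)) k <- sample(2:10, 1)
  t <- sort(runif(k, 40, 80))
  while (any(diff(t) < 1e-4)) t <- sort(runif(k, 40, 80))
  y <- rnorm(k, 2, 1)
  if (abs(mean(y)) < 0.15) y <- y + 1  # keep the CV oracle well-conditioned
  list(t = t, y = y)
}
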