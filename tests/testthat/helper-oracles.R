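# Independent oracles, deliberately written without reference to the package
# implementations they check.

# plain dynamic-programming DTW (symmetric step, |a-b| cost, no window)
dp_dtw <- function(a, b) {
  n <- length(a); m <- length(b)
  D <- matrix(Inf, n + 1, m + 1)
  D[1, 1] <- 0
  for (i in 2:(n + 1))
    for (j in 2:(m + 1))
      D[i, j] <- abs(a[i - 1] - b[j - 1]) +
        min(D[i - 1, j - 1], D[i - 1, j], D[i, j - 1])
  D[n + 1, m + 1]
}

# exhaustive recursion over every warping path (tiny sequences only)
enum_dtw <- function(a, b) {
  rec <- function(i, j) {
    cost <- abs(a[i] - b[j])
    if (i == 1 && j == 1) return(cost)
    best <- Inf
    if (i > 1 && j > 1) best <- min(best, rec(i - 1, j - 1))
    if (i > 1) best <- min(best, rec(i - 1, j))
    if (j > 1) best <- min(best, rec(i, j - 1))
    cost + best
  }
  rec(length(a), length(b))
}

# two-tailed exact binomial p-value by direct enumeration of outcome
# probabilities no more likely than the observed one
enum_binom_two_tailed <- function(x, n, p0) {
  probs <- stats::dbinom(0:n, n, p0)
  sum(probs[probs <= probs[x + 1] * (1 + 1e-7)])
}

# classical MDS straight from the definition (for cross-checking)
oracle_cmds <- function(d, k) stats::cmdscale(as.dist(d), k = k)
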