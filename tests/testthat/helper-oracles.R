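# Independent oracles used across the suite. Deliberately naive: they share
# no code path with the package internals they check.

# full pairwise-distance sort (O(n^2)) giving the k-th and 2k-th radii
brute_radii <- function(X, k, periodic = FALSE) {
  n <- nrow(X)
  r_k <- r_2k <- numeric(n)
  for (i in seq_len(n)) {
    d <- apply(X[-i, , drop = FALSE], 1, function(p) {
      dd <- X[i, ] - p
      if (periodic) {
        dd <- abs(dd)
        dd <- pmin(dd, 1 - dd)
      }
      sqrt(sum(dd^2))
    })
    d <- sort(d)
    r_k[i] <- d[k]
    r_2k[i] <- d[2 * k]
  }
  list(r_k = r_k, r_2k = r_2k)
}

# periodic distance by exhaustive enumeration of all 3^m image shifts
image_distance <- function(a, b) {
  m <- length(a)
  shifts <- as.matrix(expand.grid(rep(list(c(-1, 0, 1)), m)))
  min(apply(shifts, 1, function(s) sqrt(sum((a - (b + s))^2))))
}

# log likelihood of local estimates at dimension D (direct product form)
loglik_fsa <- function(D, delta, k) sum(log(dfsa(delta, D, k)))

# half-Cauchy cdf
phalf_cauchy <- function(q) 2 * atan(q) / pi
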