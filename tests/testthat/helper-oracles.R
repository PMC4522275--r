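# Independent oracles used across test files.

# Brute-force grid search for 2-endmember NNLS: minimizes
# ||a1 s1 + a2 s2 - x||^2 over a non-negative grid. Vectorized through the
# quadratic expansion of the SSE so a 1e-3 step stays affordable.
grid_nnls_sse <- function(S, x, step = 1e-3, amax = 1) {
  stopifnot(nrow(S) == 2)
  g11 <- sum(S[1, ]^2); g22 <- sum(S[2, ]^2); g12 <- sum(S[1, ] * S[2, ])
  c1 <- sum(S[1, ] * x); c2 <- sum(S[2, ] * x); xx <- sum(x^2)
  a <- seq(0, amax, by = step)
  q1 <- a^2 * g11 - 2 * a * c1
  q2 <- a^2 * g22 - 2 * a * c2
  M <- outer(q1, q2, "+") + 2 * g12 * outer(a, a) + xx
  idx <- arrayInd(which.min(M), dim(M))
  list(sse = min(M), coef = c(a[idx[1]], a[idx[2]]))
}

# Exhaustive Mann-Whitney: enumerates every assignment of the pooled
# values into groups of the observed sizes, computes the U statistic of
# group A for each, and derives the two-sided p for the observed U with
# the same tail-doubling convention R uses.
mw_enum_p <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  combs <- utils::combn(length(pooled), na)
  u_of <- function(ix) {
    ga <- pooled[ix]; gb <- pooled[-ix]
    sum(outer(ga, gb, ">")) + 0.5 * sum(outer(ga, gb, "=="))
  }
  u_all <- apply(combs, 2, u_of)
  u_obs <- sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  nm <- na * length(b)
  p <- if (u_obs > nm / 2) 2 * mean(u_all >= u_obs) else 2 * mean(u_all <= u_obs)
  min(1, p)
}

# Greedy matching of detected centroids to true centroids within max_d px;
# returns the fraction of true cells matched.
match_centroid_fraction <- function(detected, truth, max_d = 3) {
  if (nrow(detected) == 0 || nrow(truth) == 0) return(0)
  used <- rep(FALSE, nrow(detected))
  matched <- 0L
  for (i in seq_len(nrow(truth))) {
    d2 <- (detected$y - truth$y[i])^2 + (detected$x - truth$x[i])^2
    d2[used] <- Inf
    j <- which.min(d2)
    if (d2[j] <= max_d^2) { used[j] <- TRUE; matched <- matched + 1L }
  }
  matched / nrow(truth)
}
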