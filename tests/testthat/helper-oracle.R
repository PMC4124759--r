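# Brute-force oracle for the weighted re-encoding, independent of the
# package implementation: every pairwise correlation is recomputed from the
# raw 0/1 columns with the closed-form phi expression, and the per-protein
# group arithmetic is spelled out feature by feature.

oracle_phi <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  den2 <- (n * sx - sx^2) * (n * sy - sy^2)
  if (den2 <= 0) return(0)  # zero-variance convention
  (n * sum(x * y) - sx * sy) / sqrt(den2)
}

oracle_weighted <- function(X) {
  X <- unclass(X)
  n <- nrow(X); p <- ncol(X)
  W <- matrix(NA_real_, n, p)
  for (i in seq_len(n)) {
    for (g in c(0, 1)) {
      members <- which(X[i, ] == g)
      if (length(members) == 0) next
      if (length(members) == 1) { W[i, members] <- 0.5; next }
      w <- numeric(length(members))
      for (a in seq_along(members)) {
        for (b in seq_along(members)) {
          if (a == b) next
          ja <- members[a]; jb <- members[b]
          cc <- if (ja == jb) 1 else oracle_phi(X[, ja], X[, jb])
          w[a] <- w[a] + cc
        }
      }
      denom <- sum(w)
      if (abs(denom) < 1e-12) {
        W[i, members] <- 0.5 / length(members)
      } else {
        for (a in seq_along(members)) {
          W[i, members[a]] <- 0.5 * w[a] / denom
        }
      }
    }
  }
  W
}

random_binary_matrix <- function(n, p, density) {
  matrix(rbinom(n * p, 1L, density), n, p,
         dimnames = list(sprintf("P%03d", seq_len(n)),
                         sprintf("IPR%03d", seq_len(p))))
}
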