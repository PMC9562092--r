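# Independently coded brute-force oracles. These deliberately share no code
# with the package implementations they check.

# Floyd-Warshall all-pairs shortest paths on a direct-length matrix.
oracle_floyd_warshall <- function(D0) {
  n <- nrow(D0)
  D <- D0
  diag(D) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
      }
    }
  }
  D
}

oracle_cpl <- function(D) {
  vals <- c()
  n <- nrow(D)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && is.finite(D[i, j])) vals <- c(vals, D[i, j])
    }
  }
  mean(vals)
}

oracle_ge <- function(D) {
  tot <- 0
  n <- nrow(D)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && is.finite(D[i, j]) && D[i, j] > 0) tot <- tot + 1 / D[i, j]
    }
  }
  tot / (n * (n - 1))
}

# Naive triple-loop directed weighted clustering (cube-root triangle
# intensity, reciprocal-corrected denominator).
oracle_cc <- function(W) {
  n <- nrow(W)
  A <- (W > 0) * 1
  out <- numeric(n)
  for (i in seq_len(n)) {
    t_i <- 0
    for (j in seq_len(n)) {
      for (h in seq_len(n)) {
        t_i <- t_i + (W[i, j]^(1/3) + W[j, i]^(1/3)) *
          (W[i, h]^(1/3) + W[h, i]^(1/3)) *
          (W[j, h]^(1/3) + W[h, j]^(1/3))
      }
    }
    t_i <- t_i / 2
    k_tot <- sum(A[i, ]) + sum(A[, i])
    recip <- sum(A[i, ] * A[, i])
    den <- k_tot * (k_tot - 1) - 2 * recip
    out[i] <- if (den > 0) t_i / den else 0
  }
  out
}

# Naive directed local efficiency: per node, Floyd-Warshall on the
# neighbor-induced subgraph with 1/w lengths.
oracle_le <- function(W) {
  n <- nrow(W)
  A <- (W > 0) * 1
  out <- numeric(n)
  for (i in seq_len(n)) {
    nbrs <- which(A[i, ] + A[, i] > 0)
    k_tot <- sum(A[i, ]) + sum(A[, i])
    recip <- sum(A[i, ] * A[, i])
    den <- k_tot * (k_tot - 1) - 2 * recip
    if (length(nbrs) < 2 || den <= 0) next
    sub <- W[nbrs, nbrs, drop = FALSE]
    L <- ifelse(sub > 0, 1 / sub, Inf)
    diag(L) <- Inf
    D <- oracle_floyd_warshall(L)
    s <- 0
    for (jj in seq_along(nbrs)) {
      for (hh in seq_along(nbrs)) {
        if (jj == hh) next
        j <- nbrs[jj]; h <- nbrs[hh]
        d1 <- if (is.finite(D[jj, hh]) && D[jj, hh] > 0) 1 / D[jj, hh] else 0
        d2 <- if (is.finite(D[hh, jj]) && D[hh, jj] > 0) 1 / D[hh, jj] else 0
        s <- s + (A[i, j] + A[j, i]) * (A[i, h] + A[h, i]) * (d1 + d2)
      }
    }
    out[i] <- (s / 2) / den
  }
  out
}

# Linear exhaustive percolation scan (no bisection).
oracle_percolation_tau <- function(W) {
  ws <- sort(unique(W[W > 0]))
  if (length(ws) == 0) return(0)
  giant <- function(thr) {
    A <- W >= thr
    reach <- (A | t(A))
    n <- nrow(A)
    comp <- rep(0L, n)
    cid <- 0L
    for (v in seq_len(n)) {
      if (comp[v] > 0) next
      cid <- cid + 1L
      queue <- v
      comp[v] <- cid
      while (length(queue) > 0) {
        u <- queue[1]; queue <- queue[-1]
        nb <- which(reach[u, ] & comp == 0L)
        comp[nb] <- cid
        queue <- c(queue, nb)
      }
    }
    max(tabulate(comp))
  }
  base <- giant(ws[1])
  tau <- ws[1]
  for (thr in ws) {
    if (giant(thr) < base) break
    tau <- thr
  }
  tau
}

# Frequency-pair-by-frequency-pair PSI for one channel pair.
oracle_psi_pair <- function(Karr, freqs, df, band, i, j) {
  idx <- which(freqs >= band[1] & freqs < band[2] &
                 (freqs + df) >= band[1] & (freqs + df) < band[2])
  idx <- idx[idx + 1 <= length(freqs)]
  tot <- 0
  for (k in idx) {
    tot <- tot + Im(Conj(Karr[i, j, k]) * Karr[i, j, k + 1])
  }
  tot
}

# Random directed weighted graph (no self-loops).
random_digraph <- function(n, p = 0.4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  W <- matrix(stats::runif(n * n), n, n) * (matrix(stats::runif(n * n), n, n) < p)
  diag(W) <- 0
  W
}
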