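# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths.

# D' from explicit 2x2 haplotype contingency counting.
oracle_dprime <- function(hapA, hapB) {
  stopifnot(!anyNA(hapA), !anyNA(hapB))
  n11 <- sum(hapA == 1 & hapB == 1)
  n10 <- sum(hapA == 1 & hapB == 0)
  n01 <- sum(hapA == 0 & hapB == 1)
  n00 <- sum(hapA == 0 & hapB == 0)
  n <- n11 + n10 + n01 + n00
  pA <- (n11 + n10) / n
  pB <- (n11 + n01) / n
  pAB <- n11 / n
  D <- pAB - pA * pB
  if (pA %in% c(0, 1) || pB %in% c(0, 1) || D == 0) return(0)
  dmax <- if (D > 0) min(pA * (1 - pB), (1 - pA) * pB)
          else max(-pA * pB, -(1 - pA) * (1 - pB))
  if (dmax == 0) return(0)
  D / dmax
}

# Exhaustive complete-linkage distance between two SNP index sets.
oracle_cluster_distance <- function(idxA, idxB, H, mode = "magnitude") {
  worst <- -Inf
  for (i in idxA) for (j in idxB) {
    dp <- oracle_dprime(H[, i], H[, j])
    d <- if (mode == "magnitude") 1 - abs(dp) else 1 - dp
    if (d > worst) worst <- d
  }
  worst
}

# Quadratic-time reference for adjacency-constrained clustering of one
# chromosome: rebuilds the full adjacent-distance list from scratch at every
# step; leftmost minimum merges.
oracle_ld_cluster <- function(H, n_snps, target, mode = "magnitude") {
  cl <- lapply(seq_len(n_snps), identity)
  while (length(cl) > target) {
    d <- vapply(seq_len(length(cl) - 1L), function(j) {
      oracle_cluster_distance(cl[[j]], cl[[j + 1L]], H, mode)
    }, numeric(1))
    j <- which.min(d)
    cl[[j]] <- c(cl[[j]], cl[[j + 1L]])
    cl[[j + 1L]] <- NULL
  }
  cl
}

# Naive double-loop genomic relationship matrix from raw 0/1/2 dosages.
oracle_grm <- function(X) {
  p <- colMeans(X) / 2
  keep <- p > 0 & p < 1
  X <- X[, keep, drop = FALSE]; p <- p[keep]
  denom <- 2 * sum(p * (1 - p))
  n <- nrow(X)
  G <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in i:n) {
    v <- sum((X[i, ] - 2 * p) * (X[j, ] - 2 * p)) / denom
    G[i, j] <- v; G[j, i] <- v
  }
  G
}

# Dense-matrix restricted log-likelihood for y ~ N(Xb, sg2 G + se2 I),
# evaluated directly with solve() and determinants (no eigen shortcut).
oracle_reml_ll <- function(sg2, se2, y, X, G) {
  V <- sg2 * G + diag(se2, length(y))
  cV <- chol(V)
  Vi <- chol2inv(cV)
  XVX <- t(X) %*% Vi %*% X
  b <- solve(XVX, t(X) %*% Vi %*% y)
  r <- y - X %*% b
  -0.5 * (2 * sum(log(diag(cV))) +
            determinant(XVX, logarithm = TRUE)$modulus[1] +
            drop(t(r) %*% Vi %*% r))
}

# Grid + golden refinement REML over h2 in (0, 1), using the dense oracle
# likelihood only.
oracle_reml_h2 <- function(y, X, G, vp = NULL) {
  if (is.null(vp)) vp <- stats::var(y)
  f <- function(h2) oracle_reml_ll(h2 * vp, (1 - h2) * vp, y, X, G)
  # profile out total variance at each h2 by 1-D optimisation
  g <- function(h2) {
    o <- stats::optimize(function(s) f2(h2, s), c(vp * 0.05, vp * 20), maximum = TRUE,
                         tol = 1e-10)
    o$objective
  }
  f2 <- function(h2, s) oracle_reml_ll(h2 * s, (1 - h2) * s, y, X, G)
  o <- stats::optimize(g, c(1e-6, 1 - 1e-6), maximum = TRUE, tol = 1e-8)
  o$maximum
}
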