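# Genomic relationship matrix, REML variance components by eigendecomposition
# + 1-D profile likelihood over the variance ratio, BLUP of genetic values and
# marker-effect back-solutions.

#' Build a genomic relationship matrix from a dosage design
#'
#' G = M M' / (2 * sum p_j (1 - p_j)). In `"vanraden1"` mode (default) M is
#' centered only (x_ij - 2 p_j); in `"paper_literal"` mode M is centered and
#' scaled by sqrt(2 p_j (1 - p_j)), with the same denominator, which
#' double-scales relative to either standard construction but is retained for
#' faithfulness to sources that print it. Fixed columns are dropped before
#' construction.
#'
#' @param m a `diplotype_matrix` or plain 0/1/2 dosage matrix (individuals x
#'   markers)
#' @param mode `"vanraden1"` or `"paper_literal"`
#' @param p optional allele frequencies used for centering/scaling; computed
#'   from `m` if omitted (supply training-set frequencies to build test-row
#'   relatedness consistently)
#' @return N x N symmetric matrix with attributes `"mode"`, `"denom"` (the
#'   scaling constant 2 sum p(1-p)) and `"p"`
#' @export
build_grm <- function(m, mode = c("vanraden1", "paper_literal"), p = NULL) {
  mode <- match.arg(mode)
  std <- if (mode == "vanraden1") "centered" else "centered_scaled"
  M <- standardize_dosage(m, mode = std, p = p)
  pk <- attr(M, "p")
  denom <- 2 * sum(pk * (1 - pk))
  if (denom <= 0) stop("degenerate scaling constant: all alleles fixed")
  G <- tcrossprod(M) / denom
  attr(G, "mode") <- mode
  attr(G, "denom") <- denom
  attr(G, "p") <- pk
  G
}

#' Ridge-stabilize a relationship matrix
#'
#' Adds `ridge` to the diagonal only when the minimum eigenvalue falls below
#' `tol`, so that downstream inversions are well posed. The decision is
#' recorded in the `"ridged"` attribute.
#'
#' @param G symmetric relationship matrix
#' @param tol eigenvalue threshold below which stabilization triggers
#' @param ridge diagonal increment
#' @return G, possibly with `ridge` added to the diagonal
#' @export
stabilize_grm <- function(G, tol = 1e-8, ridge = 1e-6) {
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  ridged <- min(ev) < tol
  if (ridged) G <- G + diag(ridge, nrow(G))
  attr(G, "ridged") <- ridged
  G
}

#' Fixed-effect design for carcass-trait models
#'
#' Intercept, sex as an indicator and slaughter age as a linear covariate.
#'
#' @param pheno data.frame with `sex` (two-level) and `age` columns
#' @return model matrix with full column rank
#' @export
fixed_design <- function(pheno) {
  X <- stats::model.matrix(~ sex + age, data = transform(pheno, sex = factor(sex)))
  if (qr(X)$rank < ncol(X)) stop("fixed-effect design is rank deficient")
  X
}

#' Align a phenotype vector and fixed-effect design with a genotyped panel
#'
#' @param pheno phenotype data.frame with `id`, `sex`, `age` and trait columns
#' @param trait name of the trait column
#' @param ids individual ids in the order of the relationship matrix
#' @return list with `y`, `X`, `ids` restricted to individuals having the
#'   trait, sex and age recorded
#' @export
mixed_model_spec <- function(pheno, trait, ids) {
  rows <- match(ids, pheno$id)
  keep <- !is.na(rows)
  sub <- pheno[rows[keep], , drop = FALSE]
  ok <- !is.na(sub[[trait]]) & !is.na(sub$sex) & !is.na(sub$age)
  sub <- sub[ok, , drop = FALSE]
  list(y = sub[[trait]], X = fixed_design(sub), ids = sub$id)
}

# Profiled REML log-likelihood at variance ratio lambda = sg2/se2, in the
# eigenbasis of G. Returns the loglik and the profiled estimates.
.reml_profile <- function(lambda, d, yt, Xt, n, p) {
  w <- lambda * d + 1
  iw <- 1 / w
  XtW <- Xt * iw
  XWX <- crossprod(Xt, XtW)
  XWy <- crossprod(XtW, yt)
  b <- solve(XWX, XWy)
  r <- yt - Xt %*% b
  rss <- sum(r * r * iw)
  se2 <- rss / (n - p)
  ll <- -0.5 * ((n - p) * log(se2) + sum(log(w)) +
                  determinant(XWX, logarithm = TRUE)$modulus[1] + (n - p))
  list(ll = as.numeric(ll), b = b, se2 = se2, r = r)
}

# Unprofiled restricted loglik at (sg2, se2); used for the observed
# information / standard errors.
.reml_ll2 <- function(sg2, se2, d, yt, Xt, n, p) {
  v <- sg2 * d + se2
  if (any(v <= 0)) return(-Inf)
  iv <- 1 / v
  XtV <- Xt * iv
  XVX <- crossprod(Xt, XtV)
  b <- solve(XVX, crossprod(XtV, yt))
  r <- yt - Xt %*% b
  -0.5 * (sum(log(v)) + determinant(XVX, logarithm = TRUE)$modulus[1] +
            sum(r * r * iv))
}

#' REML estimation of genetic and residual variance
#'
#' Fits y ~ N(Xb, G sg2 + I se2) by restricted maximum likelihood. Because
#' there is a single genomic component, the restricted likelihood is profiled
#' to one dimension in the ratio lambda = sg2/se2 using the eigendecomposition
#' of G, searched by staged grid refinement (the best restricted
#' log-likelihood is non-decreasing across stages) and polished with Brent's
#' method to |delta log-lik| below `tol`. Boundary estimates are clamped at
#' zero. Standard errors come from the observed information of the
#' two-parameter restricted likelihood; heritability h2 = sg2 / (sg2 + se2).
#'
#' @param y numeric response vector (n >= 30 recommended)
#' @param X fixed-effect design matrix (full column rank)
#' @param G relationship matrix aligned with `y`
#' @param tol convergence tolerance on the restricted log-likelihood
#' @param lambda_range search range for log10(lambda)
#' @return a `variance_estimate`: list with `sg2`, `se2`, `h2`, `se_sg2`,
#'   `se_se2`, `se_h2`, `loglik`, `iterations`, `converged`, `trace`
#'   (best-so-far log-likelihood per refinement stage) and the eigen pair of
#'   G for reuse by [blup_gebv()]
#' @export
reml_fit <- function(y, X, G, tol = 1e-8, lambda_range = c(-6, 6)) {
  y <- as.numeric(y); X <- as.matrix(X)
  n <- length(y); p <- ncol(X)
  stopifnot(nrow(X) == n, nrow(G) == n)
  eg <- eigen(G, symmetric = TRUE)
  d <- pmax(eg$values, 0) # clamp numerically negative eigenvalues
  U <- eg$vectors
  yt <- crossprod(U, y)
  Xt <- crossprod(U, X)
  evals <- 0L
  f <- function(loglam) {
    evals <<- evals + 1L
    .reml_profile(10^loglam, d, yt, Xt, n, p)$ll
  }
  # staged grid refinement; best loglik is non-decreasing by construction
  lo <- lambda_range[1]; hi <- lambda_range[2]
  trace <- numeric(0)
  best <- NA_real_
  for (stage in 1:4) {
    grid <- seq(lo, hi, length.out = 21)
    vals <- vapply(grid, f, numeric(1))
    i <- which.max(vals)
    best <- if (length(trace)) max(vals[i], best) else vals[i]
    trace <- c(trace, best)
    step <- grid[2] - grid[1]
    lo <- grid[i] - step; hi <- grid[i] + step
  }
  opt <- stats::optimize(f, lower = lo, upper = hi, maximum = TRUE, tol = 1e-10)
  ll0 <- f(lambda_range[1] - 6) # effectively lambda -> 0 (pure noise)
  at_boundary <- opt$objective <= ll0 + tol
  if (at_boundary) {
    lam <- 0
    prof <- .reml_profile(0, d, yt, Xt, n, p)
    ll <- prof$ll
  } else {
    lam <- 10^opt$maximum
    prof <- .reml_profile(lam, d, yt, Xt, n, p)
    ll <- prof$ll
  }
  trace <- c(trace, max(trace, ll))
  se2 <- prof$se2
  sg2 <- lam * se2
  h2 <- if (sg2 + se2 > 0) sg2 / (sg2 + se2) else 0
  # observed information at the optimum (finite differences)
  se_sg2 <- se_se2 <- se_h2 <- NA_real_
  if (!at_boundary && se2 > 1e-10) tryCatch({
    h <- c(sg2, se2) * 1e-4 + 1e-10
    ll2 <- function(a, b) .reml_ll2(a, b, d, yt, Xt, n, p)
    H <- matrix(NA_real_, 2, 2)
    f0 <- ll2(sg2, se2)
    H[1, 1] <- (ll2(sg2 + h[1], se2) - 2 * f0 + ll2(sg2 - h[1], se2)) / h[1]^2
    H[2, 2] <- (ll2(sg2, se2 + h[2]) - 2 * f0 + ll2(sg2, se2 - h[2])) / h[2]^2
    H[1, 2] <- H[2, 1] <- (ll2(sg2 + h[1], se2 + h[2]) - ll2(sg2 + h[1], se2 - h[2]) -
                             ll2(sg2 - h[1], se2 + h[2]) + ll2(sg2 - h[1], se2 - h[2])) /
      (4 * h[1] * h[2])
    V <- tryCatch(solve(-H), error = function(e) NULL)
    if (!is.null(V) && all(diag(V) > 0)) {
      se_sg2 <- sqrt(V[1, 1]); se_se2 <- sqrt(V[2, 2])
      gr <- c(se2, -sg2) / (sg2 + se2)^2 # delta method for h2
      vh <- drop(t(gr) %*% V %*% gr)
      if (vh > 0) se_h2 <- sqrt(vh)
    }
  }, error = function(e) NULL)
  structure(list(sg2 = sg2, se2 = se2, h2 = h2,
                 se_sg2 = se_sg2, se_se2 = se_se2, se_h2 = se_h2,
                 loglik = ll, iterations = evals,
                 converged = TRUE, at_boundary = at_boundary, trace = trace,
                 eigen = list(values = d, vectors = U)),
            class = "variance_estimate")
}

#' @export
print.variance_estimate <- function(x, ...) {
  cat(sprintf("REML variance components: sg2 = %.4g, se2 = %.4g, h2 = %.3f (SE %.3f)\n",
              x$sg2, x$se2, x$h2, x$se_h2))
  cat(sprintf("  restricted loglik %.4f after %d evaluations%s\n", x$loglik,
              x$iterations, if (x$at_boundary) " (boundary: sg2 = 0)" else ""))
  invisible(x)
}

#' BLUP of fixed effects, genetic values and GEBVs
#'
#' Solves the mixed model at the REML estimates: b-hat by generalized least
#' squares, g-hat = sg2 G V^-1 (y - X b-hat) with V = G sg2 + I se2. GEBVs of
#' training individuals are g-hat; for new individuals with relatedness rows
#' G_new to the training set, GEBV = G_new %*% alpha where alpha =
#' sg2 V^-1 (y - X b-hat) (equivalently G_new G^-1 g-hat, or M_new u-hat via
#' [backsolve_marker_effects()]).
#'
#' @param y,X,G as passed to [reml_fit()]
#' @param fit the `variance_estimate` returned by [reml_fit()] on the same
#'   inputs
#' @param G_new optional matrix of relatedness rows (new individuals x
#'   training individuals) for out-of-sample GEBVs
#' @return a `blup_solution`: list with `b`, `ghat`, `alpha`, `gebv`
#'   (training GEBVs) and `gebv_new` when `G_new` is supplied
#' @export
blup_gebv <- function(y, X, G, fit, G_new = NULL) {
  if (!inherits(fit, "variance_estimate")) stop("fit must come from reml_fit()")
  if (!fit$converged) stop("REML fit did not converge")
  d <- fit$eigen$values; U <- fit$eigen$vectors
  v <- fit$sg2 * d + fit$se2
  if (any(v <= 0)) stop("singular V: sg2 and se2 both zero")
  yt <- crossprod(U, y); Xt <- crossprod(U, as.matrix(X))
  iv <- 1 / v
  XVX <- crossprod(Xt, Xt * iv)
  b <- solve(XVX, crossprod(Xt * iv, yt))
  rt <- drop(yt - Xt %*% b)
  alpha <- fit$sg2 * drop(U %*% (rt * iv)) # sg2 * V^-1 (y - Xb)
  ghat <- drop(U %*% (d * fit$sg2 * (rt * iv)))  # G %*% alpha in eigenbasis
  out <- list(b = drop(b), ghat = ghat, alpha = alpha, gebv = ghat)
  if (!is.null(G_new)) out$gebv_new <- drop(as.matrix(G_new) %*% alpha)
  structure(out, class = "blup_solution")
}

#' Back-solve haplotype-allele (marker) effects from genetic values
#'
#' u-hat = s * M' G^-1 g-hat. With `scale = "vanraden1"`, s = 1 / (2 sum
#' p_j (1 - p_j)) — the constant G was built with — so that M u-hat
#' reproduces g-hat exactly when G was built from the same M. The
#' `"paper_n"` variant divides by the number of individuals instead.
#'
#' @param M centered dosage design (as returned by [standardize_dosage()],
#'   carrying its `"p"` attribute), the matrix G was built from
#' @param G relationship matrix (invertible; see [stabilize_grm()])
#' @param ghat genetic values from [blup_gebv()]
#' @param scale `"vanraden1"` or `"paper_n"`
#' @return vector of per-column marker/allele effects
#' @export
backsolve_marker_effects <- function(M, G, ghat, scale = c("vanraden1", "paper_n")) {
  scale <- match.arg(scale)
  M <- as.matrix(M)
  if (nrow(M) != nrow(G)) stop("M and G refer to different individuals")
  s <- if (scale == "vanraden1") {
    p <- attr(M, "p")
    if (is.null(p)) stop("M carries no allele-frequency attribute; use standardize_dosage()")
    1 / (2 * sum(p * (1 - p)))
  } else 1 / nrow(M)
  # centered GRMs are singular (the ones vector is in the null space), but
  # ghat lies in the range of G, so the pseudo-inverse solves exactly
  eg <- eigen(as.matrix(G), symmetric = TRUE)
  pos <- eg$values > max(eg$values) * 1e-10
  Ginv_g <- eg$vectors[, pos, drop = FALSE] %*%
    (crossprod(eg$vectors[, pos, drop = FALSE], ghat) / eg$values[pos])
  s * drop(crossprod(M, Ginv_g))
}
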