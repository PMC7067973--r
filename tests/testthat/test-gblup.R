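test_that("build_grm matches the naive double-loop construction", {
  set.seed(31)
  X <- matrix(rbinom(50 * 200, 2, runif(200, 0.1, 0.9)), 50, 200, byrow = TRUE)
  G <- build_grm(X)
  expect_lt(max(abs(G - oracle_grm(X))), 1e-10)
  expect_lt(max(abs(G - t(G))), 1e-12)
  expect_equal(attr(G, "mode"), "vanraden1")
})

test_that("grm degenerate and exchangeability properties hold", {
  # all dosages at exactly 2p gives the zero matrix
  X <- matrix(1, 10, 5) # p = 0.5, x = 2p = 1 everywhere -> centered all zero
  X[1, 1] <- 0; X[2, 1] <- 2 # keep one column segregating
  G <- build_grm(X)
  expect_true(all(abs(G[3:10, 3:10]) < 1e-12))
  # a duplicated individual has identical rows/columns
  set.seed(5)
  Xr <- matrix(rbinom(20 * 60, 2, 0.4), 20, 60)
  Xr[2, ] <- Xr[1, ]
  Gr <- build_grm(Xr)
  expect_equal(Gr[1, ], Gr[2, ])
  expect_equal(Gr[, 1], Gr[, 2])
  # all columns fixed is an error
  expect_error(build_grm(matrix(2, 5, 4)), "degenerate")
})

test_that("paper-literal mode scales the standardized design by the same constant", {
  set.seed(9)
  X <- matrix(rbinom(30 * 50, 2, 0.5), 30, 50)
  Gp <- build_grm(X, "paper_literal")
  Ms <- standardize_dosage(X, "centered_scaled")
  p <- attr(Ms, "p")
  expect_equal(unname(Gp), unname(tcrossprod(Ms) / (2 * sum(p * (1 - p)))),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("grm diagonal averages one for simulated unrelated individuals", {
  set.seed(41)
  X <- matrix(rbinom(500 * 800, 2, runif(800, 0.1, 0.9)), 500, 800, byrow = TRUE)
  G <- build_grm(X)
  expect_lt(abs(mean(diag(G)) - 1), 0.1)
})

test_that("stabilize_grm ridges only near-singular matrices", {
  G1 <- diag(5)
  expect_false(attr(stabilize_grm(G1), "ridged"))
  G2 <- matrix(1, 4, 4) # rank 1
  G2s <- stabilize_grm(G2)
  expect_true(attr(G2s, "ridged"))
  expect_gt(min(eigen(G2s, symmetric = TRUE, only.values = TRUE)$values), 0)
})

# shared mid-sized simulated dataset for REML/BLUP checks
gblup_sim <- function(n = 300, m = 600, h2 = 0.4, seed = 1) {
  set.seed(seed)
  X <- matrix(rbinom(n * m, 2, runif(m, 0.1, 0.9)), n, m, byrow = TRUE)
  G <- build_grm(X)
  M <- standardize_dosage(X, "centered")
  beta <- rnorm(m) / sqrt(m)
  g_true <- drop(M %*% beta)
  g_true <- g_true * sqrt(h2 / max(var(g_true), 1e-12))
  sex <- rbinom(n, 1, 0.5)
  age <- runif(n, 24, 36)
  y <- 5 + 0.5 * sex + 0.05 * age + g_true +
    rnorm(n, 0, sqrt(max(1 - h2, 1e-12)))
  Xf <- cbind(1, sex, age)
  list(y = y, Xf = Xf, G = G, M = M, X = X, g_true = g_true)
}

test_that("REML recovers heritability and detects its absence", {
  # pure-noise boundary: 10-replicate average at n = 500
  h2_null <- vapply(1:10, function(i) {
    d0 <- gblup_sim(n = 500, m = 600, h2 = 0, seed = 100 + i)
    reml_fit(d0$y, d0$Xf, d0$G)$h2
  }, numeric(1))
  expect_lte(mean(h2_null), 0.05)
  h2_sig <- vapply(1:5, function(i) {
    d1 <- gblup_sim(n = 300, m = 600, h2 = 0.4, seed = 200 + i)
    reml_fit(d1$y, d1$Xf, d1$G)$h2
  }, numeric(1))
  expect_lt(abs(mean(h2_sig) - 0.4), 0.1)
})

test_that("REML agrees with lme4 on an equivalent random-intercept model", {
  skip_if_not_installed("lme4")
  set.seed(77)
  n_grp <- 40; per <- 8; n <- n_grp * per
  grp <- rep(seq_len(n_grp), each = per)
  Z <- outer(grp, seq_len(n_grp), "==") + 0
  G <- tcrossprod(Z) # g ~ N(0, sg2 ZZ') is a random intercept per group
  x <- rnorm(n)
  y <- 1 + 0.5 * x + rep(rnorm(n_grp, 0, sqrt(2)), each = per) + rnorm(n)
  fit <- reml_fit(y, cbind(1, x), G)
  lfit <- lme4::lmer(y ~ x + (1 | grp), REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(lfit))
  expect_equal(fit$sg2, vc$vcov[1], tolerance = 1e-4)
  expect_equal(fit$se2, vc$vcov[2], tolerance = 1e-4)
  expect_equal(fit$h2, vc$vcov[1] / sum(vc$vcov), tolerance = 1e-4)
})

test_that("REML maximum matches the dense-matrix likelihood oracle", {
  d <- gblup_sim(n = 120, m = 300, h2 = 0.4, seed = 9)
  fit <- reml_fit(d$y, d$Xf, d$G)
  # the eigen-profile loglik at the optimum equals the dense computation
  dense <- oracle_reml_ll(fit$sg2, fit$se2, d$y, d$Xf, d$G)
  expect_equal(fit$loglik, dense, tolerance = 1e-6)
  # no (sg2, se2) in a surrounding grid beats the claimed optimum
  for (f1 in c(0.8, 1.25)) for (f2 in c(0.8, 1.25)) {
    ll <- oracle_reml_ll(fit$sg2 * f1, fit$se2 * f2, d$y, d$Xf, d$G)
    expect_lte(ll, dense + 1e-6)
  }
})

test_that("the best restricted log-likelihood never decreases across refinement", {
  d <- gblup_sim(n = 150, m = 300, h2 = 0.3, seed = 13)
  fit <- reml_fit(d$y, d$Xf, d$G)
  expect_true(all(diff(fit$trace) >= -1e-12))
  expect_true(fit$converged)
  expect_gt(fit$iterations, 0)
})

test_that("BLUP degenerate cases: no genetic variance and exact fixed effects", {
  d <- gblup_sim(n = 100, m = 200, h2 = 0.4, seed = 21)
  fit0 <- reml_fit(d$y, d$Xf, d$G)
  fit0$sg2 <- 0; fit0$se2 <- 1; fit0$h2 <- 0
  sol0 <- blup_gebv(d$y, d$Xf, d$G, fit0)
  expect_true(all(abs(sol0$ghat) < 1e-12))
  # y = Xb exactly: ghat ~ 0 and b recovered
  b_true <- c(2, -1, 0.3)
  y_exact <- drop(d$Xf %*% b_true)
  fit_e <- reml_fit(y_exact, d$Xf, d$G)
  sol_e <- blup_gebv(y_exact, d$Xf, d$G, fit_e)
  expect_lt(max(abs(sol_e$ghat)), 1e-6)
  expect_equal(unname(sol_e$b), b_true, tolerance = 1e-6)
})

test_that("marker back-solutions reproduce genetic values and held-out GEBVs", {
  d <- gblup_sim(n = 150, m = 400, h2 = 0.5, seed = 33)
  tr <- 1:120; te <- 121:150
  p_tr <- colMeans(d$X[tr, , drop = FALSE]) / 2
  keep <- p_tr > 0 & p_tr < 1
  M <- sweep(d$X[, keep, drop = FALSE], 2, 2 * p_tr[keep], "-")
  attr(M, "p") <- p_tr[keep]
  denom <- 2 * sum(p_tr[keep] * (1 - p_tr[keep]))
  G_tr <- tcrossprod(M[tr, ]) / denom
  G_new <- M[te, ] %*% t(M[tr, ]) / denom
  fit <- reml_fit(d$y[tr], d$Xf[tr, ], G_tr)
  sol <- blup_gebv(d$y[tr], d$Xf[tr, ], G_tr, fit, G_new = G_new)
  M_tr <- M[tr, , drop = FALSE]; attr(M_tr, "p") <- p_tr[keep]
  u <- backsolve_marker_effects(M_tr, G_tr, sol$ghat)
  # M u-hat = g-hat on the training side
  expect_lt(max(abs(M_tr %*% u - sol$ghat)), 1e-8)
  # held-out GEBV via G_new G^-1 g-hat equals M_new u-hat
  expect_lt(max(abs(M[te, ] %*% u - sol$gebv_new)), 1e-8)
  # permuting individuals permutes g-hat but leaves u-hat unchanged
  perm <- sample(length(tr))
  Mp <- M_tr[perm, , drop = FALSE]; attr(Mp, "p") <- p_tr[keep]
  up <- backsolve_marker_effects(Mp, G_tr[perm, perm], sol$ghat[perm])
  expect_equal(up, u, tolerance = 1e-8)
  # the paper-literal divisor variant is a pure rescaling of the same vector
  un <- backsolve_marker_effects(M_tr, G_tr, sol$ghat, scale = "paper_n")
  expect_equal(un, u * denom / length(tr), tolerance = 1e-10)
})

test_that("one-column designs give effects proportional to the column", {
  set.seed(3)
  x <- rbinom(40, 2, 0.5)
  M <- cbind(x - mean(x))
  attr(M, "p") <- mean(x) / 2
  G <- tcrossprod(M) / (2 * attr(M, "p") * (1 - attr(M, "p")))
  G <- stabilize_grm(G)
  ghat <- rnorm(40)
  u <- backsolve_marker_effects(M, G, ghat)
  expect_equal(length(u), 1)
  expect_true(is.finite(u))
})
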