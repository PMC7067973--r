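test_that("precorrect removes sex and age exactly and leaves orthogonal residuals", {
  set.seed(2)
  ph <- tiny_pheno(n = 1000)
  # trait uncorrelated with sex/age: corrected ~ centered trait
  r <- precorrect(ph, "CWT")
  expect_gt(cor(r, ph$CWT), 0.99)
  # residuals orthogonal to age and the sex indicator
  expect_lt(abs(sum(r * ph$age)), 1e-6)
  expect_lt(abs(sum(r * (ph$sex == "M"))), 1e-6)
  expect_lt(abs(sum(r)), 1e-6)
  # trait = 2 * age exactly vanishes after correction
  ph$CWT <- 2 * ph$age
  expect_lt(max(abs(precorrect(ph, "CWT"))), 1e-8)
})

test_that("precorrect fitted on a training subset applies train coefficients everywhere", {
  ph <- tiny_pheno(n = 200, seed = 4)
  tr <- ph$id[1:150]
  r <- precorrect(ph, "CWT", train_ids = tr)
  fit <- lm(CWT ~ factor(sex) + age, data = ph[ph$id %in% tr, ])
  manual <- ph$CWT - predict(fit, newdata = transform(ph, sex = factor(sex)))
  expect_equal(unname(r), unname(manual), tolerance = 1e-10)
})

test_that("kfold_plan partitions individuals into near-equal seeded folds", {
  ids <- sprintf("i%02d", 1:10)
  plan <- kfold_plan(ids, folds = 5, repeats = 1, seed = 3)
  expect_equal(unname(table(plan$fold)), rep(2L, 5) , ignore_attr = TRUE)
  expect_setequal(plan$id, ids)
  # same seed, same plan; each id tested exactly `repeats` times
  p1 <- kfold_plan(ids, 5, 5, seed = 11)
  p2 <- kfold_plan(ids, 5, 5, seed = 11)
  expect_identical(p1, p2)
  expect_true(all(table(p1$id) == 5))
  for (r in 1:5) expect_setequal(p1$id[p1$rep == r], ids)
  # uneven sizes differ by at most one
  p3 <- kfold_plan(sprintf("x%d", 1:13), 5, 1, seed = 1)
  expect_lte(diff(range(table(p3$fold))), 1)
})

test_that("paired_ttest matches the reference t distribution and is antisymmetric", {
  set.seed(6)
  a <- 0.4 + rnorm(25, 0, 0.03)
  b <- a - 0.02 + rnorm(25, 0, 0.01)
  res <- paired_ttest(a, b)
  ref <- t.test(a, b, paired = TRUE)
  expect_equal(res$t, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(res$p, ref$p.value, tolerance = 1e-10)
  swapped <- paired_ttest(b, a)
  expect_equal(swapped$t, -res$t, tolerance = 1e-12)
  expect_equal(swapped$p, res$p, tolerance = 1e-12)
  # identical vectors are the degenerate zero-variance case
  deg <- paired_ttest(a, a)
  expect_true(deg$degenerate)
  expect_equal(deg$t, 0)
  expect_error(paired_ttest(a, a - 0.1), "zero variance")
  expect_error(paired_ttest(a[1:2], a[1:2] + rnorm(2)), "at least 3")
})

test_that("forward_split honors the inclusive cutoff and rejects empty sides", {
  ph <- data.frame(id = c("a", "b", "c"), sex = "F", age = 30,
                   birth_date = c("2011-12-31", "2012-01-01", "2012-06-01"),
                   CWT = 1:3)
  sp <- forward_split(ph, "2012-01-01")
  expect_equal(sp$train, "a")
  expect_setequal(sp$test, c("b", "c")) # born on the cutoff goes to test
  expect_error(forward_split(ph, "2030-01-01"), "2030")
  expect_error(forward_split(ph, "2000-01-01"), "before")
})

# small end-to-end dataset reused by the CV tests
cv_dataset <- function(seed = 5, n = 250, h2 = 0.4) {
  nq <- if (h2 > 0) 25 else 0
  cfg <- sim_config(n_individuals = n, n_chr = 1, n_snps_per_chr = 400,
                    n_qtl = nq, h2 = h2, seed = seed)
  simulate_dataset(cfg)
}

test_that("cross_validate recovers signal and the permutation null collapses", {
  sim <- cv_dataset()
  des <- marker_design(sim$genotypes, "snp")
  plan <- kfold_plan(sim$genotypes$ids, folds = 5, repeats = 1, seed = 9)
  res <- cross_validate(des, sim$pheno, "CWT", plan)
  expect_true(all(is.na(res$error)))
  expect_true(all(res$accuracy > 0.2)) # real signal at h2 = 0.4
  expect_true(all(res$accuracy >= -1 & res$accuracy <= 1))
  expect_true(all(res$n_test > 2))
  # permuted phenotypes: mean accuracy near zero
  ph0 <- sim$pheno
  set.seed(10)
  ph0$CWT <- sample(ph0$CWT)
  res0 <- cross_validate(des, ph0, "CWT", plan)
  expect_lt(abs(mean(res0$accuracy)), 2 / sqrt(50) * 1.5)
})

test_that("training fits are bit-identical when test phenotypes are perturbed", {
  sim <- cv_dataset(seed = 8, n = 150)
  des <- marker_design(sim$genotypes, "snp")
  plan <- kfold_plan(sim$genotypes$ids, folds = 5, repeats = 1, seed = 2)
  res1 <- cross_validate(des, sim$pheno, "CWT", plan, keep_details = TRUE)
  ph2 <- sim$pheno
  fold1_ids <- plan$id[plan$fold == 1]
  set.seed(99)
  sel <- ph2$id %in% fold1_ids
  ph2$CWT[sel] <- ph2$CWT[sel] + rnorm(sum(sel), 0, 3)
  res2 <- cross_validate(des, ph2, "CWT", plan, keep_details = TRUE)
  d1 <- attr(res1, "details")[["1.1"]]
  d2 <- attr(res2, "details")[["1.1"]]
  expect_identical(d1$fit, d2$fit) # REML/BLUP untouched by test phenotypes
  expect_identical(d1$train_ids, d2$train_ids)
  # but the fold-1 accuracy itself changes (the perturbation is real)
  expect_false(isTRUE(all.equal(res1$accuracy[1], res2$accuracy[1])))
})

test_that("forward validation runs and underperforms CV under allele-frequency drift", {
  wins <- 0L
  for (s in 1:3) {
    cfg <- sim_config(n_individuals = 250, n_chr = 1, n_snps_per_chr = 400,
                      n_qtl = 25, seed = 40 + s, founder_drift = 3)
    sim <- simulate_dataset(cfg)
    des <- marker_design(sim$genotypes, "snp")
    fwd <- forward_validate(des, sim$pheno, "CWT", "2012-01-01")
    plan <- kfold_plan(sim$genotypes$ids, folds = 5, repeats = 1, seed = s)
    cv <- cross_validate(des, sim$pheno, "CWT", plan)
    if (mean(cv$accuracy) >= fwd$accuracy) wins <- wins + 1L
    expect_true(is.finite(fwd$accuracy))
  }
  expect_gte(wins, 2) # majority of replicates
})

test_that("whole-data pre-correction mode is available and differs from fold-safe mode", {
  sim <- cv_dataset(seed = 12, n = 150)
  des <- marker_design(sim$genotypes, "snp")
  plan <- kfold_plan(sim$genotypes$ids, folds = 5, repeats = 1, seed = 3)
  r1 <- cross_validate(des, sim$pheno, "CWT", plan, precorrect_mode = "within_fold")
  r2 <- cross_validate(des, sim$pheno, "CWT", plan, precorrect_mode = "whole_data")
  expect_false(identical(r1$accuracy, r2$accuracy))
  expect_lt(max(abs(r1$accuracy - r2$accuracy)), 0.2) # same data, small shift
})

test_that("summarize_accuracy aggregates by method with standard errors", {
  res <- data.frame(trait = "CWT", method = rep(c("a", "b"), each = 4),
                    rep = 1, fold = rep(1:4, 2),
                    accuracy = c(0.4, 0.5, 0.45, 0.55, NA, 0.3, 0.35, 0.25),
                    n_test = 10, h2 = 0.4, error = NA)
  s <- summarize_accuracy(res)
  expect_equal(s$mean_accuracy[s$method == "a"], 0.475)
  expect_equal(s$n_failed[s$method == "b"], 1)
  expect_equal(s$se[s$method == "a"], sd(c(0.4, 0.5, 0.45, 0.55)) / 2)
})
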