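# Prediction-accuracy evaluation: phenotype pre-correction, repeated k-fold
# cross-validation, forward (temporal) validation and paired comparisons.

#' Pre-correct a phenotype for sex and slaughter age
#'
#' Residuals of an ordinary least-squares fit of the trait on intercept, sex
#' and age. When `train_ids` is given the regression coefficients are
#' estimated on those individuals only and applied to everyone (the
#' leakage-safe mode used inside cross-validation); otherwise the fit uses
#' all complete rows.
#'
#' @param pheno phenotype data.frame (`id`, `sex`, `age`, trait columns)
#' @param trait trait column name
#' @param train_ids optional ids used to estimate the correction
#' @return numeric vector aligned with the rows of `pheno` (NA where the
#'   trait, sex or age is missing)
#' @export
precorrect <- function(pheno, trait, train_ids = NULL) {
  ok <- !is.na(pheno[[trait]]) & !is.na(pheno$sex) & !is.na(pheno$age)
  fit_rows <- if (is.null(train_ids)) ok else ok & pheno$id %in% train_ids
  if (sum(fit_rows) < 4L) stop("too few complete rows to fit the correction")
  dat <- data.frame(y = pheno[[trait]], sex = factor(pheno$sex), age = pheno$age)
  fit <- stats::lm(y ~ sex + age, data = dat[fit_rows, , drop = FALSE])
  out <- rep(NA_real_, nrow(pheno))
  out[ok] <- dat$y[ok] - stats::predict(fit, newdata = dat[ok, , drop = FALSE])
  out
}

#' Repeated k-fold cross-validation plan
#'
#' For each repeat, a fresh seeded shuffle of the individuals is split into
#' `folds` test sets of near-equal size (sizes differ by at most 1); within a
#' repeat the folds partition all individuals.
#'
#' @param ids individual identifiers
#' @param folds number of folds (default 5)
#' @param repeats number of repeats (default 5)
#' @param seed integer seed; the same seed reproduces the same plan
#' @return a `fold_plan` data.frame with columns `rep`, `fold`, `id`
#' @export
kfold_plan <- function(ids, folds = 5, repeats = 5, seed = 1) {
  n <- length(ids)
  if (n < folds) stop("fewer individuals than folds")
  rows <- list()
  for (r in seq_len(repeats)) {
    set.seed(seed + r - 1L)
    perm <- sample(ids)
    fold <- sort(rep(seq_len(folds), length.out = n))
    rows[[r]] <- data.frame(rep = r, fold = fold, id = perm)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("fold_plan", "data.frame")
  out
}

#' Build a marker design for prediction
#'
#' Produces the raw individuals x markers dosage matrix a GBLUP model is fit
#' from: either per-SNP alternate-allele dosages (`"snp"`) or haplotype-allele
#' diplotype dosages for a given block partition (`"hap"`). Missing SNP
#' dosages are mean-imputed per SNP at this encoding step only.
#'
#' @param g a `phased_genotypes` object
#' @param method `"snp"` or `"hap"`
#' @param partition a `block_partition` (required for `"hap"`)
#' @param label optional method tag carried into results
#' @return list with `X` (dosage matrix), `ids`, `label`
#' @export
marker_design <- function(g, method = c("snp", "hap"), partition = NULL,
                          label = NULL) {
  method <- match.arg(method)
  if (method == "snp") {
    X <- geno_dosage(g)
    if (anyNA(X)) {
      mu <- colMeans(X, na.rm = TRUE)
      idx <- which(is.na(X), arr.ind = TRUE)
      X[idx] <- mu[idx[, 2]]
    }
    lab <- if (is.null(label)) "snp" else label
  } else {
    if (is.null(partition)) stop("hap design needs a block partition")
    cat_ <- enumerate_alleles(g, partition)
    dm <- encode_diplotypes(g, cat_)
    X <- dm$X
    lab <- if (is.null(label))
      paste0("hap_", partition$method, "_", format(partition$k)) else label
  }
  list(X = X, ids = g$ids, label = lab)
}

# One train/test evaluation shared by CV and forward validation. Allele
# frequencies, centering, REML and the phenotype correction all come from the
# training individuals only (unless precorrect_mode = "whole_data").
.evaluate_split <- function(design, pheno, trait, train_ids, test_ids,
                            precorrect_mode, grm_mode) {
  prows <- pheno[match(design$ids, pheno$id), , drop = FALSE]
  complete <- !is.na(prows[[trait]]) & !is.na(prows$sex) & !is.na(prows$age)
  tr <- which(design$ids %in% train_ids & complete)
  te <- which(design$ids %in% test_ids & complete)
  if (length(te) < 3L) stop("test set too small after phenotype alignment")
  X <- design$X
  p_tr <- colMeans(X[tr, , drop = FALSE]) / 2
  keep <- p_tr > 0 & p_tr < 1
  M <- sweep(X[, keep, drop = FALSE], 2L, 2 * p_tr[keep], "-")
  if (grm_mode == "paper_literal")
    M <- sweep(M, 2L, sqrt(2 * p_tr[keep] * (1 - p_tr[keep])), "/")
  denom <- 2 * sum(p_tr[keep] * (1 - p_tr[keep]))
  G_tr <- tcrossprod(M[tr, , drop = FALSE]) / denom
  G_new <- M[te, , drop = FALSE] %*% t(M[tr, , drop = FALSE]) / denom
  y_tr <- prows[[trait]][tr]
  Xf_tr <- fixed_design(prows[tr, , drop = FALSE])
  fit <- reml_fit(y_tr, Xf_tr, G_tr)
  sol <- blup_gebv(y_tr, Xf_tr, G_tr, fit, G_new = G_new)
  corr_ids <- if (precorrect_mode == "within_fold") design$ids[tr] else NULL
  ycorr <- precorrect(prows, trait, train_ids = corr_ids)
  # a boundary fit (sg2 = 0) predicts a constant: no predictive ability
  acc <- if (stats::sd(sol$gebv_new) == 0) 0 else stats::cor(sol$gebv_new, ycorr[te])
  list(accuracy = acc, n_test = length(te), h2 = fit$h2,
       fit = list(b = sol$b, sg2 = fit$sg2, se2 = fit$se2,
                  loglik = fit$loglik, ghat = sol$ghat),
       train_ids = design$ids[tr])
}

#' Cross-validated prediction accuracy of a GBLUP design
#'
#' For every (repeat, fold) of the plan: variance components are estimated by
#' REML on the training individuals only, test GEBVs are predicted from their
#' relatedness to the training set, and accuracy is the Pearson correlation
#' between test GEBVs and pre-corrected test phenotypes. Allele frequencies,
#' centering and (by default) the sex/age correction are all estimated on the
#' training side of each fold, so test phenotypes never leak into training.
#'
#' @param design a design from [marker_design()]
#' @param pheno phenotype data.frame
#' @param trait trait column name
#' @param plan a `fold_plan` from [kfold_plan()]
#' @param precorrect_mode `"within_fold"` (leakage-safe, default) or
#'   `"whole_data"`
#' @param grm_mode GRM construction, see [build_grm()]
#' @param keep_details if TRUE, attach per-fold training fits (used by
#'   leakage diagnostics)
#' @return data.frame with one row per (repeat, fold): `trait`, `method`,
#'   `rep`, `fold`, `accuracy`, `n_test`, `h2`; failed folds are flagged in
#'   the `error` column and excluded from summaries
#' @export
cross_validate <- function(design, pheno, trait, plan,
                           precorrect_mode = c("within_fold", "whole_data"),
                           grm_mode = "vanraden1", keep_details = FALSE) {
  precorrect_mode <- match.arg(precorrect_mode)
  combos <- unique(plan[, c("rep", "fold")])
  rows <- list(); details <- list()
  for (i in seq_len(nrow(combos))) {
    r <- combos$rep[i]; f <- combos$fold[i]
    test_ids <- plan$id[plan$rep == r & plan$fold == f]
    train_ids <- plan$id[plan$rep == r & plan$fold != f]
    res <- tryCatch(
      .evaluate_split(design, pheno, trait, train_ids, test_ids,
                      precorrect_mode, grm_mode),
      error = function(e) e)
    if (inherits(res, "error")) {
      rows[[i]] <- data.frame(trait = trait, method = design$label, rep = r,
                              fold = f, accuracy = NA_real_, n_test = NA_integer_,
                              h2 = NA_real_, error = conditionMessage(res))
    } else {
      rows[[i]] <- data.frame(trait = trait, method = design$label, rep = r,
                              fold = f, accuracy = res$accuracy,
                              n_test = res$n_test, h2 = res$h2, error = NA_character_)
      if (keep_details) details[[paste(r, f, sep = ".")]] <-
        res[c("fit", "train_ids")]
    }
  }
  out <- do.call(rbind, rows)
  if (keep_details) attr(out, "details") <- details
  out
}

#' Temporal train/test split by birth date
#'
#' Test individuals are those born on or after the cutoff; the rest train the
#' model.
#'
#' @param pheno phenotype data.frame with a parseable `birth_date` column
#' @param cutoff cutoff date (ISO 8601 string or Date)
#' @return list with `train` and `test` id vectors (both non-empty)
#' @export
forward_split <- function(pheno, cutoff) {
  bd <- as.Date(pheno$birth_date)
  if (anyNA(bd)) stop("unparseable birth dates")
  cutoff <- as.Date(cutoff)
  test <- pheno$id[bd >= cutoff]
  train <- pheno$id[bd < cutoff]
  if (!length(test)) stop("no individuals born on/after ", format(cutoff))
  if (!length(train)) stop("no individuals born before ", format(cutoff))
  list(train = train, test = test)
}

#' Forward-validation accuracy of a GBLUP design
#'
#' Single temporal split: older animals train, younger animals are predicted;
#' otherwise identical to one cross-validation fold.
#'
#' @inheritParams cross_validate
#' @param cutoff birth-date cutoff passed to [forward_split()]
#' @return one-row data.frame like [cross_validate()]'s output
#' @export
forward_validate <- function(design, pheno, trait, cutoff,
                             precorrect_mode = c("within_fold", "whole_data"),
                             grm_mode = "vanraden1") {
  precorrect_mode <- match.arg(precorrect_mode)
  sp <- forward_split(pheno, cutoff)
  res <- .evaluate_split(design, pheno, trait, sp$train, sp$test,
                         precorrect_mode, grm_mode)
  data.frame(trait = trait, method = design$label, rep = NA_integer_,
             fold = NA_integer_, accuracy = res$accuracy, n_test = res$n_test,
             h2 = res$h2, error = NA_character_)
}

#' Paired t-test on per-fold accuracies
#'
#' Two-sided paired t-test comparing two methods' accuracy vectors paired by
#' (repeat, fold). When every pairwise difference is exactly zero the test is
#' degenerate and (t = 0, p = 1) is returned with a flag; a constant nonzero
#' difference (zero variance) is an error.
#'
#' @param a,b equal-length (>= 3) accuracy vectors
#' @return list with `t`, `p`, `df`, `degenerate`
#' @export
paired_ttest <- function(a, b) {
  if (length(a) != length(b)) stop("accuracy vectors must have equal length")
  d <- a - b
  d <- d[!is.na(d)]
  n <- length(d)
  if (n < 3L) stop("need at least 3 paired accuracies")
  sdd <- stats::sd(d)
  if (sdd <= 1e-12 * max(abs(mean(d)), 1)) {
    if (all(d == 0)) return(list(t = 0, p = 1, df = n - 1L, degenerate = TRUE))
    stop("zero variance of nonzero differences: degenerate paired t-test")
  }
  tstat <- mean(d) / (sdd / sqrt(n))
  list(t = tstat, p = 2 * stats::pt(abs(tstat), df = n - 1L, lower.tail = FALSE),
       df = n - 1L, degenerate = FALSE)
}

#' Mean accuracy and its standard error per method
#'
#' @param results rows from [cross_validate()] (possibly several methods
#'   bound together)
#' @return data.frame with `method`, `mean_accuracy`, `se`, `n_folds`,
#'   `n_failed`
#' @export
summarize_accuracy <- function(results) {
  out <- do.call(rbind, lapply(split(results, results$method), function(d) {
    ok <- !is.na(d$accuracy)
    data.frame(method = d$method[1],
               mean_accuracy = mean(d$accuracy[ok]),
               se = stats::sd(d$accuracy[ok]) / sqrt(sum(ok)),
               n_folds = sum(ok), n_failed = sum(!ok))
  }))
  rownames(out) <- NULL
  out
}
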