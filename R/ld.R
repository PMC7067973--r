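# Linkage disequilibrium: D-prime between phased loci and the
# complete-linkage distance between SNP clusters used by block clustering.

# Vectorised D' from frequencies. pA, pB may be vectors/matrices conformable
# with pAB. Convention: monomorphic locus or D == 0 gives D' = 0.
.dprime_from_freqs <- function(pA, pB, pAB) {
  D <- pAB - pA * pB
  dmax_pos <- pmin(pA * (1 - pB), (1 - pA) * pB)
  dmax_neg <- pmax(-pA * pB, -(1 - pA) * (1 - pB))
  dmax <- ifelse(D > 0, dmax_pos, dmax_neg)
  dp <- ifelse(D == 0 | dmax == 0, 0, D / dmax)
  mono <- pA <= 0 | pA >= 1 | pB <= 0 | pB >= 1
  dp[mono] <- 0
  dp
}

#' Pairwise D-prime between two phased loci
#'
#' Computes the normalised linkage-disequilibrium coefficient D' from two
#' binary haplotype vectors: D = pAB - pA * pB, scaled by its sign-dependent
#' maximum given the allele frequencies. Haplotypes with a missing value at
#' either locus are excluded pairwise. By convention D' = 0 when D = 0 or
#' when either locus is monomorphic in the retained haplotypes.
#'
#' @param hapA,hapB binary (0/1/NA) vectors of equal length, one entry per
#'   haplotype in the population.
#' @return An object of class `pair_ld`: a list with `pA`, `pB`, `pAB`, `D`,
#'   `Dmax`, `Dprime` and `n_haplotypes` (informative haplotypes used).
#' @export
pair_dprime <- function(hapA, hapB) {
  if (length(hapA) != length(hapB))
    stop("haplotype vectors must have equal length")
  keep <- !is.na(hapA) & !is.na(hapB)
  a <- hapA[keep]; b <- hapB[keep]
  n <- length(a)
  if (n < 2L) stop("fewer than 2 informative haplotypes")
  pA <- mean(a); pB <- mean(b); pAB <- mean(a * b)
  D <- pAB - pA * pB
  if (D > 0) {
    dmax <- min(pA * (1 - pB), (1 - pA) * pB)
  } else if (D < 0) {
    dmax <- max(-pA * pB, -(1 - pA) * (1 - pB))
  } else dmax <- 0
  dp <- if (D == 0 || dmax == 0 || pA %in% c(0, 1) || pB %in% c(0, 1)) 0 else D / dmax
  structure(list(pA = pA, pB = pB, pAB = pAB, D = D, Dmax = dmax,
                 Dprime = dp, n_haplotypes = n),
            class = "pair_ld")
}

#' LD distance between two SNPs
#'
#' The clustering distance between two loci, `1 - D'`. The default
#' `"magnitude"` mode uses |D'|, which is invariant to arbitrary ref/alt
#' relabelling; `"signed"` mode uses the signed D' literally.
#'
#' @param hapA,hapB binary haplotype vectors as in [pair_dprime()]
#' @param mode `"magnitude"` (default) or `"signed"`
#' @return distance in [0, 1] (signed mode can reach 2)
#' @export
snp_distance <- function(hapA, hapB, mode = c("magnitude", "signed")) {
  mode <- match.arg(mode)
  dp <- pair_dprime(hapA, hapB)$Dprime
  if (mode == "magnitude") 1 - abs(dp) else 1 - dp
}

# All cross-pair D' between two column index sets of a haplotype matrix with
# no missing entries, via one cross-product: pAB[i, j] = mean(HA[, i] * HB[, j]).
.dprime_cross <- function(H, ia, ib) {
  n <- nrow(H)
  HA <- H[, ia, drop = FALSE]; HB <- H[, ib, drop = FALSE]
  pA <- colMeans(HA); pB <- colMeans(HB)
  pAB <- crossprod(HA, HB) / n
  .dprime_from_freqs(outer(pA, rep(1, length(pB))),
                     outer(rep(1, length(pA)), pB),
                     pAB)
}

#' Complete-linkage LD distance between two SNP clusters
#'
#' The distance between two clusters of SNPs is the maximum of `1 - D'` over
#' all cross-cluster SNP pairs (complete linkage). For singleton sets this
#' reduces to [snp_distance()].
#'
#' @param idxA,idxB disjoint, non-empty sets of SNP column indices into `g`
#' @param g a `phased_genotypes` object
#' @param mode distance convention, as in [snp_distance()]
#' @return the maximum pairwise distance
#' @export
cluster_distance <- function(idxA, idxB, g, mode = c("magnitude", "signed")) {
  mode <- match.arg(mode)
  if (length(idxA) == 0L || length(idxB) == 0L) stop("empty index set")
  if (length(intersect(idxA, idxB))) stop("index sets must be disjoint")
  H <- g$H
  sub <- H[, c(idxA, idxB), drop = FALSE]
  if (!anyNA(sub)) {
    dp <- .dprime_cross(H, idxA, idxB)
    if (mode == "magnitude") return(max(1 - abs(dp)))
    return(max(1 - dp))
  }
  # missing data: fall back to pairwise-complete scalar computation
  worst <- -Inf
  for (i in idxA) for (j in idxB) {
    d <- snp_distance(H[, i], H[, j], mode = mode)
    if (d > worst) worst <- d
  }
  worst
}

#' D-prime between physically adjacent SNPs along the map
#'
#' Diagnostic/CLI helper: computes D' for every adjacent SNP pair within each
#' chromosome.
#'
#' @param g a `phased_genotypes` object
#' @return data.frame with `chrom`, `pos1`, `pos2`, `dprime`
#' @export
adjacent_dprime <- function(g) {
  out <- lapply(unique(g$map$chrom), function(ch) {
    idx <- which(g$map$chrom == ch)
    if (length(idx) < 2L) return(NULL)
    dp <- vapply(seq_len(length(idx) - 1L), function(k) {
      pair_dprime(g$H[, idx[k]], g$H[, idx[k + 1L]])$Dprime
    }, numeric(1))
    data.frame(chrom = ch,
               pos1 = g$map$pos[idx[-length(idx)]],
               pos2 = g$map$pos[idx[-1L]],
               dprime = dp)
  })
  do.call(rbind, out)
}

#' Squared correlation (r2) between adjacent SNP genotypes
#'
#' Simulator diagnostic only: mean r-squared of adjacent SNP pairs, computed
#' from haplotype alleles. Not used as a clustering metric.
#'
#' @param g a `phased_genotypes` object
#' @return mean adjacent r2 (NA pairs dropped)
#' @export
mean_adjacent_r2 <- function(g) {
  r2 <- unlist(lapply(unique(g$map$chrom), function(ch) {
    idx <- which(g$map$chrom == ch)
    if (length(idx) < 2L) return(NULL)
    vapply(seq_len(length(idx) - 1L), function(k) {
      a <- g$H[, idx[k]]; b <- g$H[, idx[k + 1L]]
      keep <- !is.na(a) & !is.na(b)
      if (stats::sd(a[keep]) == 0 || stats::sd(b[keep]) == 0) return(NA_real_)
      stats::cor(a[keep], b[keep])^2
    }, numeric(1))
  }))
  mean(r2, na.rm = TRUE)
}
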