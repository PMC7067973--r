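# Haplotype-allele enumeration per block and the individuals x alleles
# diplotype dosage design (the mixed model's marker matrix).

# Haplotype strings of every phased haplotype over a block's SNP columns.
# Missing entries are either imputed to the most frequent compatible complete
# haplotype ("impute_frequent") or rejected ("strict").
.block_strings <- function(H, cols, missing = "impute_frequent") {
  sub <- H[, cols, drop = FALSE]
  if (anyNA(sub)) {
    if (missing == "strict") stop("missing haplotype entries within a block")
    bad <- which(rowSums(is.na(sub)) > 0L)
    good <- sub[-bad, , drop = FALSE]
    if (nrow(good) == 0L) stop("no complete haplotype to impute from in block")
    good_str <- do.call(paste0, as.data.frame(good))
    freq_tab <- sort(table(good_str), decreasing = TRUE)
    for (r in bad) {
      row <- sub[r, ]
      obs <- !is.na(row)
      # most frequent complete haplotype matching the observed entries
      cand <- names(freq_tab)
      if (any(obs)) {
        pat <- vapply(cand, function(s) {
          v <- as.integer(strsplit(s, "", fixed = TRUE)[[1]])
          all(v[obs] == row[obs])
        }, logical(1))
        cand <- cand[pat]
      }
      if (!length(cand)) cand <- names(freq_tab)[1] # no compatible: commonest
      sub[r, ] <- as.integer(strsplit(cand[1], "", fixed = TRUE)[[1]])
    }
  }
  do.call(paste0, as.data.frame(sub))
}

#' Enumerate haplotype alleles per block
#'
#' For every block of a partition, lists the distinct haplotype strings
#' (concatenated 0/1 over the block's SNPs) observed among the 2N phased
#' haplotypes, with their empirical frequencies. Alleles are ordered by
#' descending frequency, ties broken by the haplotype string, so column
#' order downstream is deterministic.
#'
#' @param g a `phased_genotypes` object
#' @param p a `block_partition` built on the same SNP map
#' @param missing `"impute_frequent"` (assign haplotypes with missing entries
#'   to the most frequent compatible complete haplotype) or `"strict"` (error)
#' @return an `allele_catalog`: list with `blocks` (per-block data.frames of
#'   `haplotype`, `freq`) and the partition
#' @export
enumerate_alleles <- function(g, p, missing = c("impute_frequent", "strict")) {
  missing <- match.arg(missing)
  members <- block_members(p)
  if (any(unlist(members) > ncol(g$H))) stop("partition references SNPs absent from g")
  blocks <- lapply(members, function(cols) {
    s <- .block_strings(g$H, cols, missing)
    tab <- table(s)
    df <- data.frame(haplotype = names(tab), freq = as.numeric(tab) / length(s))
    df[order(-df$freq, df$haplotype), , drop = FALSE]
  })
  structure(list(blocks = blocks, partition = p), class = "allele_catalog")
}

#' @export
print.allele_catalog <- function(x, ...) {
  na <- vapply(x$blocks, nrow, integer(1))
  cat(sprintf("allele_catalog: %d blocks, %d alleles (%.2f per block)\n",
              length(na), sum(na), mean(na)))
  invisible(x)
}

#' Encode individuals as haplotype-allele dosages
#'
#' Builds the N x H diplotype design: entry (i, j) is the number of copies
#' (0, 1 or 2) of haplotype allele j carried by individual i. Within every
#' block the dosages of an individual sum to exactly 2 (one per phased
#' haplotype).
#'
#' @param g the `phased_genotypes` the catalog was built from
#' @param catalog an `allele_catalog`
#' @param missing missing-data policy, as in [enumerate_alleles()]
#' @return a `diplotype_matrix`: list with `X` (N x H dosage matrix), `ids`,
#'   `block` (block index of each column), `allele` (haplotype string of each
#'   column) and `freq` (per-allele frequency among the 2N haplotypes)
#' @export
encode_diplotypes <- function(g, catalog, missing = c("impute_frequent", "strict")) {
  missing <- match.arg(missing)
  members <- block_members(catalog$partition)
  n <- length(g$ids)
  odd <- seq(1L, 2L * n, by = 2L)
  cols <- list(); block_of <- integer(0); allele_of <- character(0)
  for (b in seq_along(members)) {
    al <- catalog$blocks[[b]]$haplotype
    s <- .block_strings(g$H, members[[b]], missing)
    idx <- match(s, al)
    if (anyNA(idx)) stop("haplotype not present in allele catalog (block ", b, ")")
    m <- matrix(0, n, length(al))
    i1 <- cbind(seq_len(n), idx[odd])
    i2 <- cbind(seq_len(n), idx[odd + 1L])
    m[i1] <- m[i1] + 1
    m[i2] <- m[i2] + 1
    cols[[b]] <- m
    block_of <- c(block_of, rep.int(b, length(al)))
    allele_of <- c(allele_of, al)
  }
  X <- do.call(cbind, cols)
  rownames(X) <- g$ids
  structure(list(X = X, ids = g$ids, block = block_of, allele = allele_of,
                 freq = colSums(X) / (2 * n)),
            class = "diplotype_matrix")
}

#' @export
print.diplotype_matrix <- function(x, ...) {
  cat(sprintf("diplotype_matrix: %d individuals x %d haplotype alleles in %d blocks\n",
              nrow(x$X), ncol(x$X), length(unique(x$block))))
  invisible(x)
}

#' Haplotype-allele frequencies of a diplotype design
#'
#' p_j = sum_i x_ij / (2N), the allele's own frequency (frequencies within a
#' block sum to 1).
#'
#' @param m a `diplotype_matrix`
#' @return numeric vector of per-column allele frequencies
#' @export
allele_frequencies <- function(m) colSums(m$X) / (2 * nrow(m$X))

#' Standardize a dosage design by allele frequency
#'
#' Centers each dosage column by twice its allele frequency, x_ij - 2 p_j
#' (`"centered"`), optionally also dividing by sqrt(2 p_j (1 - p_j))
#' (`"centered_scaled"`). Fixed columns (p_j of 0 or 1) carry no information
#' and are dropped; the count is recorded in the `"dropped_fixed"` attribute.
#'
#' @param m a `diplotype_matrix`, or a plain dosage matrix (individuals x
#'   markers with entries 0/1/2)
#' @param mode `"centered"` or `"centered_scaled"`
#' @param p optional allele frequencies; computed from the dosages if omitted
#' @return numeric matrix with attributes `"p"` (frequencies of the retained
#'   columns) and `"dropped_fixed"` (number of fixed columns removed)
#' @export
standardize_dosage <- function(m, mode = c("centered", "centered_scaled"), p = NULL) {
  mode <- match.arg(mode)
  X <- if (inherits(m, "diplotype_matrix")) m$X else as.matrix(m)
  if (is.null(p)) p <- colMeans(X) / 2
  keep <- p > 0 & p < 1
  X <- X[, keep, drop = FALSE]; p <- p[keep]
  M <- sweep(X, 2L, 2 * p, "-")
  if (mode == "centered_scaled")
    M <- sweep(M, 2L, sqrt(2 * p * (1 - p)), "/")
  attr(M, "p") <- p
  attr(M, "dropped_fixed") <- sum(!keep)
  M
}

#' Summary statistics of a block partition and its allele catalog
#'
#' The per-method descriptive statistics reported for a haplotype set: block
#' count, total and mean alleles, mean/min/max SNPs per block.
#'
#' @param p a `block_partition`
#' @param catalog the matching `allele_catalog`
#' @return data.frame with one row of summary statistics
#' @export
partition_summary <- function(p, catalog) {
  na <- vapply(catalog$blocks, nrow, integer(1))
  ns <- p$blocks$n_snps
  data.frame(n_blocks = nrow(p$blocks),
             total_alleles = sum(na),
             mean_snps = mean(ns),
             mean_alleles = mean(na),
             min_snps = min(ns),
             max_snps = max(ns))
}
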