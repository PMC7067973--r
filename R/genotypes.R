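#' Construct a phased-genotype container
#'
#' Bundles a SNP map with the phased haplotypes of a diploid panel. The
#' haplotype matrix `H` holds one row per haplotype (rows `2i - 1` and `2i`
#' are the two phased haplotypes of individual `i`) and one column per SNP,
#' with entries 0 (reference), 1 (alternate) or `NA` (missing).
#'
#' @param map data.frame with columns `chrom`, `pos` (1-based bp), `id`,
#'   `ref`, `alt`, ordered by (chrom, pos); positions must be strictly
#'   increasing within each chromosome.
#' @param ids character vector of individual identifiers (unique).
#' @param H integer/numeric matrix of dimension `2 * length(ids)` x
#'   `nrow(map)` with entries in \{0, 1, NA\}.
#' @return An object of class `phased_genotypes` with elements `map`, `ids`,
#'   `H`.
#' @export
phased_genotypes <- function(map, ids, H) {
  stopifnot(is.data.frame(map),
            all(c("chrom", "pos", "id", "ref", "alt") %in% names(map)))
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("individual ids must be unique")
  H <- as.matrix(H)
  if (nrow(H) != 2L * length(ids))
    stop("H must have two rows (haplotypes) per individual")
  if (ncol(H) != nrow(map))
    stop("H must have one column per SNP in the map")
  bad <- !(H %in% c(0L, 1L)) & !is.na(H)
  if (any(bad)) stop("haplotype entries must be 0, 1 or NA")
  # duplicated sites are tolerated here (QC deduplicates them); order must
  # still be non-decreasing within chromosome
  for (ch in unique(map$chrom)) {
    p <- map$pos[map$chrom == ch]
    if (any(diff(p) < 0))
      stop("positions must be sorted within chromosome ", ch)
  }
  structure(list(map = map, ids = ids, H = H), class = "phased_genotypes")
}

#' @export
print.phased_genotypes <- function(x, ...) {
  cat(sprintf("phased_genotypes: %d individuals, %d SNPs on %d chromosome(s)\n",
              length(x$ids), nrow(x$map), length(unique(x$map$chrom))))
  miss <- mean(is.na(x$H))
  cat(sprintf("  missing haplotype entries: %.3f%%\n", 100 * miss))
  invisible(x)
}

#' Number of individuals in a phased panel
#' @param g a `phased_genotypes` object
#' @return integer count
#' @export
n_individuals <- function(g) length(g$ids)

#' Per-individual genotype dosages (0/1/2 copies of the alternate allele)
#'
#' Sums the two phased haplotypes of each individual; a genotype is `NA`
#' when either haplotype is missing at that SNP.
#'
#' @param g a `phased_genotypes` object
#' @return numeric matrix, individuals x SNPs, rownames = individual ids
#' @export
geno_dosage <- function(g) {
  n <- length(g$ids)
  D <- g$H[seq(1L, 2L * n, by = 2L), , drop = FALSE] +
       g$H[seq(2L, 2L * n, by = 2L), , drop = FALSE]
  rownames(D) <- g$ids
  colnames(D) <- g$map$id
  D
}

#' Subset a phased panel by individuals and/or SNPs
#'
#' @param g a `phased_genotypes` object
#' @param individuals indices or ids of individuals to keep (default all)
#' @param snps column indices of SNPs to keep (default all)
#' @return a `phased_genotypes` object
#' @export
subset_genotypes <- function(g, individuals = NULL, snps = NULL) {
  if (is.null(individuals)) individuals <- seq_along(g$ids)
  if (is.character(individuals)) individuals <- match(individuals, g$ids)
  if (anyNA(individuals)) stop("unknown individual id")
  if (is.null(snps)) snps <- seq_len(nrow(g$map))
  hap_rows <- as.vector(rbind(2L * individuals - 1L, 2L * individuals))
  phased_genotypes(g$map[snps, , drop = FALSE],
                   g$ids[individuals],
                   g$H[hap_rows, snps, drop = FALSE])
}
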