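# Haplotype block construction: fixed SNP count, fixed physical length,
# and adjacency-constrained agglomerative clustering on D'-based LD.

.new_partition <- function(blocks, method, k, dropped = integer(0)) {
  blocks <- blocks[order(match(blocks$chrom, unique(blocks$chrom)),
                         blocks$first), , drop = FALSE]
  rownames(blocks) <- NULL
  blocks$block_id <- seq_len(nrow(blocks))
  structure(list(blocks = blocks, method = method, k = k, dropped = dropped),
            class = "block_partition")
}

#' @export
print.block_partition <- function(x, ...) {
  cat(sprintf("block_partition (%s, k = %s): %d blocks, %d SNPs (%d dropped)\n",
              x$method, format(x$k), nrow(x$blocks),
              sum(x$blocks$n_snps), length(x$dropped)))
  invisible(x)
}

#' SNP indices of every block in a partition
#' @param p a `block_partition`
#' @return list of integer vectors, one per block
#' @export
block_members <- function(p) {
  mapply(seq.int, p$blocks$first, p$blocks$last, SIMPLIFY = FALSE)
}

.block_row <- function(map, first, last, chrom) {
  data.frame(chrom = chrom, first = first, last = last,
             n_snps = last - first + 1L,
             start_pos = map$pos[first], end_pos = map$pos[last])
}

#' Haplotype blocks of a fixed number of SNPs
#'
#' Partitions each chromosome into consecutive runs of exactly `k` SNPs. The
#' final run of fewer than `k` SNPs is handled by `remainder_policy`:
#' `"short_block"` keeps it as a smaller block, `"drop"` excludes those SNPs
#' (listed in the result), `"merge_last"` appends them to the last full block.
#'
#' @param map SNP map data.frame (`chrom`, `pos`, ...) ordered by position
#' @param k SNPs per block (>= 2), typically 5, 10, 20 or 50
#' @param remainder_policy one of `"short_block"`, `"drop"`, `"merge_last"`
#' @return a `block_partition`
#' @export
blocks_by_count <- function(map, k,
                            remainder_policy = c("short_block", "drop", "merge_last")) {
  remainder_policy <- match.arg(remainder_policy)
  stopifnot(k >= 2, nrow(map) > 0)
  rows <- list(); dropped <- integer(0)
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    n <- length(idx)
    nfull <- n %/% k
    rem <- n %% k
    if (nfull == 0L) {
      # chromosome shorter than one block
      if (remainder_policy == "drop") { dropped <- c(dropped, idx); next }
      rows[[length(rows) + 1L]] <- .block_row(map, idx[1], idx[n], ch)
      next
    }
    firsts <- idx[seq(1L, by = k, length.out = nfull)]
    lasts <- firsts + k - 1L
    if (rem > 0L) {
      tail_idx <- idx[(nfull * k + 1L):n]
      if (remainder_policy == "drop") {
        dropped <- c(dropped, tail_idx)
      } else if (remainder_policy == "short_block") {
        firsts <- c(firsts, tail_idx[1]); lasts <- c(lasts, tail_idx[rem])
      } else { # merge_last
        lasts[nfull] <- tail_idx[rem]
      }
    }
    for (b in seq_along(firsts))
      rows[[length(rows) + 1L]] <- .block_row(map, firsts[b], lasts[b], ch)
  }
  if (!length(rows)) stop("no blocks produced; all SNPs dropped")
  .new_partition(do.call(rbind, rows), "count", k, dropped)
}

#' Target physical window length for a given mean block size
#'
#' The genome-wide mean SNP spacing (total genome length divided by total SNP
#' count) multiplied by `k`, so that length-based windows contain `k` SNPs on
#' average. Genome length is the sum over chromosomes of (max position - min
#' position + 1).
#'
#' @param map SNP map data.frame
#' @param k target mean SNPs per block
#' @return window length in bp
#' @export
target_window_length <- function(map, k) {
  stopifnot(nrow(map) > 0, k > 0)
  span <- sum(tapply(map$pos, map$chrom, function(p) max(p) - min(p) + 1))
  span / nrow(map) * k
}

#' Haplotype blocks of a fixed physical length
#'
#' Tiles each chromosome with half-open windows `[start, start + window)`
#' anchored at the chromosome's first SNP position; every SNP falls in
#' exactly one window and empty windows are omitted, so blocks contain one or
#' more SNPs.
#'
#' @param map SNP map data.frame
#' @param window window length in bp (> 0)
#' @return a `block_partition` (its `k` field stores the window length)
#' @export
blocks_by_length <- function(map, window) {
  stopifnot(window > 0, nrow(map) > 0)
  rows <- list()
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    pos <- map$pos[idx]
    win <- floor((pos - pos[1]) / window)
    for (w in unique(win)) {
      sel <- idx[win == w]
      rows[[length(rows) + 1L]] <- .block_row(map, sel[1], sel[length(sel)], ch)
    }
  }
  .new_partition(do.call(rbind, rows), "length", window)
}

#' Apportion a genome-wide cluster count to chromosomes
#'
#' The global target number of clusters, K = round(total SNPs / k), is split
#' across chromosomes proportionally to their SNP counts by the
#' largest-remainder rule, with every chromosome receiving at least one
#' cluster.
#'
#' @param map SNP map data.frame
#' @param k mean SNPs per cluster (>= 2)
#' @return named integer vector of per-chromosome cluster counts summing to K
#' @export
allocate_cluster_counts <- function(map, k) {
  stopifnot(k >= 2)
  n_by_chr <- table(factor(map$chrom, levels = unique(map$chrom)))
  total <- sum(n_by_chr)
  K <- max(1L, as.integer(round(total / k)))
  if (K < length(n_by_chr))
    stop("target cluster count ", K, " is smaller than the number of chromosomes")
  share <- K * as.numeric(n_by_chr) / total
  alloc <- floor(share)
  rem <- share - alloc
  short <- K - sum(alloc)
  if (short > 0) {
    bump <- order(rem, decreasing = TRUE)[seq_len(short)]
    alloc[bump] <- alloc[bump] + 1L
  }
  # enforce >= 1 per chromosome, taking from the largest allocations
  while (any(alloc < 1L)) {
    need <- which.min(alloc); give <- which.max(alloc)
    alloc[need] <- alloc[need] + 1L; alloc[give] <- alloc[give] - 1L
  }
  alloc <- as.integer(alloc)
  if (any(alloc > as.integer(n_by_chr)))
    stop("a chromosome was allocated more clusters than it has SNPs")
  stats::setNames(alloc, names(n_by_chr))
}

# Agglomerative adjacency-constrained clustering of one chromosome's SNPs.
# Returns list(first, last, merge_log). Clusters are contiguous index runs;
# the linear list of adjacent-cluster distances is the source of truth for
# the minimum search; ties break leftmost (which.min).
.cluster_chromosome <- function(g, idx, target, mode) {
  nc <- length(idx)
  first <- idx; last <- idx
  log_rows <- list()
  if (nc <= target) {
    return(list(first = first, last = last,
                merge_log = data.frame(chrom = character(0), left_first = integer(0),
                                       left_last = integer(0), right_first = integer(0),
                                       right_last = integer(0), distance = numeric(0))))
  }
  d <- vapply(seq_len(nc - 1L), function(j) {
    cluster_distance(seq.int(first[j], last[j]),
                     seq.int(first[j + 1L], last[j + 1L]), g, mode = mode)
  }, numeric(1))
  while (length(first) > target) {
    j <- which.min(d) # leftmost minimum
    log_rows[[length(log_rows) + 1L]] <-
      c(first[j], last[j], first[j + 1L], last[j + 1L], d[j])
    # merge clusters j and j+1
    last[j] <- last[j + 1L]
    first <- first[-(j + 1L)]; last <- last[-(j + 1L)]
    # rebuild the affected adjacent distances by direct recomputation
    new_d <- numeric(0)
    if (j > 1L)
      new_d <- cluster_distance(seq.int(first[j - 1L], last[j - 1L]),
                                seq.int(first[j], last[j]), g, mode = mode)
    right_d <- numeric(0)
    if (j < length(first))
      right_d <- cluster_distance(seq.int(first[j], last[j]),
                                  seq.int(first[j + 1L], last[j + 1L]), g, mode = mode)
    d <- c(if (j > 2L) d[seq_len(j - 2L)], new_d, right_d,
           if (j + 1L < length(d)) d[seq.int(j + 2L, length(d))])
  }
  ml <- if (length(log_rows)) {
    m <- do.call(rbind, log_rows)
    data.frame(left_first = as.integer(m[, 1]), left_last = as.integer(m[, 2]),
               right_first = as.integer(m[, 3]), right_last = as.integer(m[, 4]),
               distance = m[, 5])
  } else {
    data.frame(left_first = integer(0), left_last = integer(0),
               right_first = integer(0), right_last = integer(0),
               distance = numeric(0))
  }
  list(first = first, last = last, merge_log = ml)
}

#' Haplotype blocks by adjacency-constrained hierarchical clustering on LD
#'
#' Agglomerative complete-linkage clustering of each chromosome's SNPs where
#' only physically adjacent SNPs or clusters may merge, so clusters remain
#' contiguous, non-overlapping runs. Starting from singletons, the minimum of
#' the linear list of adjacent-cluster distances (1 - D', complete linkage)
#' is merged repeatedly; each merge removes the three affected list entries
#' and inserts the two recomputed distances to the new cluster's neighbours.
#' Merging stops when the chromosome reaches its share of the genome-wide
#' cluster target K = round(total SNPs / k) (see
#' [allocate_cluster_counts()]). Ties break to the leftmost pair.
#'
#' @param g a QC-filtered `phased_genotypes` object
#' @param k target mean SNPs per cluster (>= 2)
#' @param mode D' distance convention, see [snp_distance()]
#' @return a `block_partition` with an additional `merge_log` element: one
#'   row per merge with the two merged runs and the merge distance
#' @export
blocks_by_ld_clustering <- function(g, k, mode = c("magnitude", "signed")) {
  mode <- match.arg(mode)
  stopifnot(k >= 2)
  map <- g$map
  alloc <- allocate_cluster_counts(map, k)
  rows <- list(); logs <- list()
  for (ch in names(alloc)) {
    idx <- which(map$chrom == ch)
    res <- .cluster_chromosome(g, idx, alloc[[ch]], mode)
    for (b in seq_along(res$first))
      rows[[length(rows) + 1L]] <- .block_row(map, res$first[b], res$last[b], ch)
    if (nrow(res$merge_log)) {
      res$merge_log$chrom <- ch
      logs[[length(logs) + 1L]] <- res$merge_log
    }
  }
  p <- .new_partition(do.call(rbind, rows), "ld_cluster", k)
  p$merge_log <- if (length(logs)) do.call(rbind, logs) else NULL
  p
}

#' Validate the structural laws of a block partition
#'
#' Checks contiguity, non-overlap, chromosome respect and SNP conservation
#' (members plus the explicit drop list cover every SNP exactly once).
#' Called by tests; errors on the first violated law.
#'
#' @param p a `block_partition`
#' @param map the SNP map the partition was built from
#' @return TRUE invisibly
#' @export
validate_partition <- function(p, map) {
  b <- p$blocks
  if (any(b$first > b$last)) stop("block with first > last")
  if (any(map$chrom[b$first] != b$chrom) || any(map$chrom[b$last] != b$chrom))
    stop("block spans outside its chromosome")
  covered <- unlist(block_members(p))
  if (anyDuplicated(covered)) stop("overlapping blocks")
  all_idx <- sort(c(covered, p$dropped))
  if (!identical(all_idx, seq_len(nrow(map))))
    stop("SNP conservation violated: blocks + dropped != all SNPs")
  for (i in seq_len(nrow(b))) {
    ch <- map$chrom[seq.int(b$first[i], b$last[i])]
    if (length(unique(ch)) != 1L) stop("block crosses a chromosome boundary")
  }
  invisible(TRUE)
}
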