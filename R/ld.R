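## Pairwise r2 on genotype dosages (composite LD), windowed LD pruning, and
## binned LD-decay curves with resampling confidence intervals.

#' Squared correlation (r2) between two dosage vectors
#'
#' Composite LD: the squared Pearson correlation of genotype dosages over
#' pairwise-complete entries. No phase information is used.
#'
#' @param x,y Equal-length dosage vectors (0/1/2/NA).
#' @return r2 in [0, 1], or NA if fewer than two complete pairs remain or
#'   either vector is constant on the complete subset (never 0 for the
#'   degenerate case).
#' @examples
#' ld_r2(c(0, 1, 2, 0), c(0, 1, 1, 1))
#' @export
ld_r2 <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2) return(NA_real_)
  x <- x[ok]; y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)^2
}

#' Windowed greedy LD pruning
#'
#' Slides a window of \code{window} markers by \code{step} along each
#' chromosome; within a window, for every pair with r2 above
#' \code{r2_max} the later (right-hand) marker is removed and the earlier
#' kept. Passes repeat until a full pass removes nothing, so the result is
#' idempotent and deterministic.
#'
#' @param g N x M dosage matrix with markers sorted by (chrom, bp).
#' @param map Marker map aligned with the columns of \code{g}.
#' @param window Window size in markers (default 50).
#' @param step Window increment in markers (default 5).
#' @param r2_max r2 threshold (default 0.1).
#' @return Character vector of retained marker ids in map order.
#' @export
ld_prune <- function(g, map, window = 50, step = 5, r2_max = 0.1) {
  if (window < 2) stop("window must be >= 2")
  g <- check_geno(g)
  map <- check_map(map)
  keep <- rep(TRUE, ncol(g))
  names(keep) <- colnames(g)
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    idx <- idx[order(map$bp[idx])]
    repeat {
      removed <- FALSE
      alive <- idx[keep[idx]]
      if (length(alive) < 2) break
      starts <- seq(1, length(alive), by = step)
      for (s in starts) {
        win <- alive[s:min(s + window - 1, length(alive))]
        win <- win[keep[win]]
        if (length(win) < 2) next
        cc <- suppressWarnings(stats::cor(g[, win, drop = FALSE],
                                          use = "pairwise.complete.obs"))
        r2 <- cc^2
        for (a in seq_len(length(win) - 1)) {
          if (!keep[win[a]]) next
          for (b in seq(a + 1, length(win))) {
            if (!keep[win[b]]) next
            v <- r2[a, b]
            if (!is.na(v) && v > r2_max) {
              keep[win[b]] <- FALSE
              removed <- TRUE
            }
          }
        }
      }
      if (!removed) break
    }
  }
  colnames(g)[keep]
}

#' LD decay curve with subsample resampling
#'
#' For each of \code{reps} replicates, \code{n_draw} samples are drawn
#' without replacement and r2 is computed for every intra-chromosome marker
#' pair within \code{max_bp}. Pairs are binned by physical distance into
#' bins of width \code{bin_bp} centred at multiples of \code{bin_bp}
#' starting at \code{bin_bp} (so the first bin spans
#' [\code{bin_bp/2}, \code{3 bin_bp/2}) with the lower endpoint included).
#' Per bin the replicate means are averaged; the confidence band is the
#' empirical 2.5/97.5 percentile across replicates.
#'
#' @param g N x M dosage matrix.
#' @param map Marker map.
#' @param max_bp Maximum pair distance (default 1e6).
#' @param bin_bp Bin width (default 1000).
#' @param n_draw Samples per replicate (default 5).
#' @param reps Number of replicates (default 50).
#' @param seed Integer seed.
#' @return data.frame(bin_center_bp, mean_r2, ci_low, ci_high, n_pairs);
#'   empty bins carry n_pairs = 0 and NA means.
#' @export
ld_decay <- function(g, map, max_bp = 1e6, bin_bp = 1000, n_draw = 5,
                     reps = 50, seed = 1) {
  g <- check_geno(g)
  map <- check_map(map)
  if (n_draw > nrow(g)) stop("n_draw exceeds sample count")
  ## enumerate intra-chromosome pairs within max_bp once
  pi1 <- integer(0); pi2 <- integer(0); pd <- numeric(0)
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    idx <- idx[order(map$bp[idx])]
    bp <- map$bp[idx]
    j <- 1L
    for (a in seq_along(idx)) {
      b <- a + 1L
      while (b <= length(idx) && bp[b] - bp[a] <= max_bp) {
        pi1 <- c(pi1, idx[a]); pi2 <- c(pi2, idx[b])
        pd <- c(pd, bp[b] - bp[a])
        b <- b + 1L
      }
    }
  }
  centers <- seq(bin_bp, max_bp, by = bin_bp)
  half <- bin_bp / 2
  bin_of <- floor((pd - half) / bin_bp) + 1L   # lower endpoint included
  bin_of[pd < half | bin_of > length(centers)] <- NA_integer_
  set.seed(seed)
  binmeans <- matrix(NA_real_, reps, length(centers))
  for (r in seq_len(reps)) {
    rows <- sample(nrow(g), n_draw)
    sub <- g[rows, , drop = FALSE]
    r2 <- vapply(seq_along(pi1), function(k) ld_r2(sub[, pi1[k]], sub[, pi2[k]]),
                 numeric(1))
    for (bidx in seq_along(centers)) {
      v <- r2[!is.na(bin_of) & bin_of == bidx]
      v <- v[!is.na(v)]
      if (length(v)) binmeans[r, bidx] <- mean(v)
    }
  }
  n_pairs <- vapply(seq_along(centers),
                    function(bidx) sum(!is.na(bin_of) & bin_of == bidx),
                    integer(1))
  data.frame(
    bin_center_bp = centers,
    mean_r2 = colMeans(binmeans, na.rm = TRUE),
    ci_low = apply(binmeans, 2, function(x)
      if (all(is.na(x))) NA_real_ else stats::quantile(x, 0.025, na.rm = TRUE)),
    ci_high = apply(binmeans, 2, function(x)
      if (all(is.na(x))) NA_real_ else stats::quantile(x, 0.975, na.rm = TRUE)),
    n_pairs = n_pairs)
}
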