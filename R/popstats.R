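## Per-individual inbreeding coefficients, pairwise inbreeding-adjusted
## Hudson F_ST with moving-block jackknife errors, and inbreeding-bin tables.

#' Per-individual inbreeding coefficients from excess homozygosity
#'
#' F_i = 1 - O_het(i) / E_het(i), where O_het is the observed heterozygote
#' count and E_het the Hardy-Weinberg expectation under pooled allele
#' frequencies, summed over the markers non-missing in individual i.
#' Negative values indicate heterozygote excess. When the pooled frequencies
#' are estimated from the data itself (the default), the per-marker expected
#' heterozygosity uses Nei's small-sample correction
#' \code{2 p (1-p) 2n/(2n-1)}, which removes the O(1/n) downward bias of the
#' plug-in estimate; frequencies supplied externally are taken as population
#' values and used uncorrected.
#'
#' @param g N x M dosage matrix (the pooled set of groups).
#' @param pooled_freqs Optional vector of pooled allele frequencies; default
#'   computed from \code{g}.
#' @return Named numeric vector of per-individual F (NA with a warning for
#'   individuals with zero expected heterozygosity).
#' @export
inbreeding_f <- function(g, pooled_freqs = NULL) {
  g <- check_geno(g)
  if (is.null(pooled_freqs)) {
    p <- allele_freqs(g)
    n2 <- 2 * marker_n(g)
    eh <- 2 * p * (1 - p) * ifelse(n2 > 1, n2 / (n2 - 1), 1)
  } else {
    p <- pooled_freqs
    if (length(p) != ncol(g)) stop("pooled_freqs length must match markers")
    eh <- 2 * p * (1 - p)
  }
  obs <- !is.na(g)
  o_het <- rowSums(g == 1, na.rm = TRUE)
  e_het <- obs %*% eh
  f <- 1 - o_het / as.vector(e_het)
  if (any(e_het == 0)) {
    warning("individuals with zero expected heterozygosity; F set to NA")
    f[e_het == 0] <- NA_real_
  }
  stats::setNames(f, rownames(g))
}

#' Pairwise Hudson-style F_ST with inbreeding adjustment
#'
#' Ratio-of-sums estimator: per marker the numerator is
#' \code{(p1 - p2)^2} minus each group's sampling variance of the allele
#' frequency estimate, and the denominator is
#' \code{p1 (1 - p2) + p2 (1 - p1)}. With \code{inbreed_adjust} the sampling
#' variance of p-hat in group j uses \code{Var = p(1-p)(1+F_j)/(2 n_j)},
#' with F_j the group's mean inbreeding coefficient estimated against the
#' pooled frequencies of both groups - inbreeding inflates the variance of
#' frequency estimates and, uncorrected, biases F_ST upward. The standard
#' error comes from a moving-block jackknife over contiguous marker blocks.
#'
#' @param g1,g2 Dosage matrices over the same marker set.
#' @param inbreed_adjust Apply the (1+F) correction (default TRUE).
#' @param n_blocks Jackknife blocks (default 553); 0 skips the jackknife.
#' @return An object of class \code{fst_result}: list(estimate, se,
#'   block_values, n_blocks, n_markers_used, f1, f2).
#' @export
fst_pair <- function(g1, g2, inbreed_adjust = TRUE, n_blocks = 553) {
  g1 <- check_geno(g1); g2 <- check_geno(g2)
  if (ncol(g1) != ncol(g2)) stop("marker sets differ")
  if (nrow(g1) < 2 || nrow(g2) < 2) stop("need >= 2 samples per group")
  p1 <- allele_freqs(g1); p2 <- allele_freqs(g2)
  n1 <- marker_n(g1); n2 <- marker_n(g2)
  f1 <- f2 <- 0
  if (inbreed_adjust) {
    pool <- rbind(g1, g2)
    fp <- allele_freqs(pool)
    f1 <- mean(inbreeding_f(g1, pooled_freqs = fp), na.rm = TRUE)
    f2 <- mean(inbreeding_f(g2, pooled_freqs = fp), na.rm = TRUE)
    ## pooled freqs here are plug-in estimates over both groups; the group-F
    ## bias from that is O(1/(2(n1+n2))) and immaterial for the correction
  }
  ## unbiased estimate of the sampling variance of p-hat under inbreeding:
  ## E[p(1-p)-hat] = p(1-p) (1 - (1+F)/(2n))  =>  divide by (2n - (1+F))
  c1 <- p1 * (1 - p1) * (1 + f1) / (2 * n1 - (1 + f1))
  c2 <- p2 * (1 - p2) * (1 + f2) / (2 * n2 - (1 + f2))
  num <- (p1 - p2)^2 - c1 - c2
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  use <- is.finite(num) & is.finite(den) & den > 0
  if (!any(use)) {
    warning("F_ST undefined: no polymorphic markers")
    return(structure(list(estimate = NA_real_, se = NA_real_,
                          block_values = numeric(0), n_blocks = 0,
                          n_markers_used = 0, f1 = f1, f2 = f2),
                     class = "fst_result"))
  }
  num <- num[use]; den <- den[use]
  est <- sum(num) / sum(den)
  se <- NA_real_; bv <- numeric(0)
  if (n_blocks >= 2 && length(num) >= n_blocks) {
    jk <- block_jackknife_se(num, den, n_blocks = n_blocks)
    se <- jk$se; bv <- jk$block_values
  }
  structure(list(estimate = est, se = se, block_values = bv,
                 n_blocks = length(bv), n_markers_used = length(num),
                 f1 = f1, f2 = f2),
            class = "fst_result")
}

#' @export
print.fst_result <- function(x, ...) {
  cat("Hudson F_ST estimate:", format(x$estimate, digits = 4))
  if (is.finite(x$se)) cat("  (block-jackknife se ", format(x$se, digits = 3),
                           ", ", x$n_blocks, " blocks)", sep = "")
  cat("\n")
  invisible(x)
}

#' Moving-block jackknife standard error of a ratio-of-sums statistic
#'
#' Markers are partitioned, in map order, into \code{n_blocks} contiguous
#' blocks of (near-)equal size. For each block j the statistic is recomputed
#' with the block deleted, theta_(-j) = sum(num[-j]) / sum(den[-j]), and
#' se^2 = (B-1)/B * sum((theta_(-j) - mean)^2).
#'
#' @param num,den Per-marker numerator and denominator contributions.
#' @param n_blocks Number of blocks (>= 2).
#' @return list(se, block_values = the delete-one-block estimates).
#' @export
block_jackknife_se <- function(num, den, n_blocks) {
  if (n_blocks < 2) stop("n_blocks must be >= 2")
  m <- length(num)
  stopifnot(length(den) == m, m >= n_blocks)
  block <- cut(seq_len(m), breaks = n_blocks, labels = FALSE)
  bn <- tapply(num, block, sum)
  bd <- tapply(den, block, sum)
  ## merge any zero-denominator block into its neighbour
  zero <- which(bd == 0)
  if (length(zero)) {
    warning("blocks with zero denominator merged into neighbours")
    for (z in zero) {
      tgt <- if (z > 1) z - 1 else z + 1
      bn[tgt] <- bn[tgt] + bn[z]; bd[tgt] <- bd[tgt] + bd[z]
    }
    bn <- bn[-zero]; bd <- bd[-zero]
  }
  B <- length(bn)
  sn <- sum(bn); sd_ <- sum(bd)
  theta <- (sn - bn) / (sd_ - bd)
  se <- sqrt((B - 1) / B * sum((theta - mean(theta))^2))
  list(se = se, block_values = as.numeric(theta))
}

#' Bin per-group inbreeding coefficients into the standard table
#'
#' Counts and percentages of individuals per F bin and group, with bins
#' (-0.05, 0.00], (0.00, 0.05], (0.05, 0.10], (0.10, 0.15], (0.15, 0.20].
#' Percentages are count / group size * 100, rounded half-up to 2 decimals.
#' Individuals outside every bin are reported in an overflow row.
#'
#' @param F_by_group Named list of per-individual F vectors, one per group.
#' @return list(counts, percentages) matrices (bins + overflow) x groups.
#' @export
bin_f_table <- function(F_by_group) {
  breaks <- c(-0.05, 0.00, 0.05, 0.10, 0.15, 0.20)
  labs <- c("(-0.05,0.00]", "(0.00,0.05]", "(0.05,0.10]", "(0.10,0.15]",
            "(0.15,0.20]")
  groups <- names(F_by_group)
  counts <- matrix(0L, length(labs) + 1, length(groups),
                   dimnames = list(c(labs, "outside"), groups))
  pct <- counts * 0
  for (j in seq_along(groups)) {
    f <- F_by_group[[j]]
    f <- f[!is.na(f)]
    b <- cut(f, breaks = breaks, labels = labs)
    counts[seq_along(labs), j] <- as.integer(table(b))
    counts["outside", j] <- sum(is.na(b))
    if (length(f))
      pct[, j] <- round_half_up(counts[, j] / length(f) * 100, 2)
  }
  list(counts = counts, percentages = pct)
}
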