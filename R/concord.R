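## Cluster-versus-surname concordance: contingency tables and the Mantel
## permutation test on co-membership distance matrices.

#' Cross-tabulate genetic groups against surname origins
#'
#' @param group_of,origin_of Equal-length label vectors over the same
#'   samples (no missing values).
#' @param digits Decimals for row percentages (rounded half-up), default 2.
#' @return An object of class \code{concordance_table}: list(counts,
#'   row_pct, row_totals).
#' @export
contingency <- function(group_of, origin_of, digits = 2) {
  if (length(group_of) != length(origin_of))
    stop("labelings must cover the same samples")
  if (anyNA(group_of) || anyNA(origin_of)) {
    bad <- which(is.na(group_of) | is.na(origin_of))
    stop("missing labels for samples: ", paste(bad, collapse = ", "))
  }
  counts <- table(group = group_of, origin = origin_of)
  totals <- rowSums(counts)
  pct <- round_half_up(sweep(counts, 1, totals, "/") * 100, digits)
  structure(list(counts = unclass(counts), row_pct = unclass(pct),
                 row_totals = totals),
            class = "concordance_table")
}

#' @export
print.concordance_table <- function(x, ...) {
  m <- matrix(paste0(x$counts, " (", x$row_pct, "%)"),
              nrow(x$counts), ncol(x$counts),
              dimnames = dimnames(x$counts))
  print(cbind(m, total = x$row_totals), quote = FALSE)
  invisible(x)
}

#' Co-membership distance from a categorical labeling
#'
#' d(i, j) = 0 if samples i and j carry the same label, 1 otherwise - a
#' metric (it satisfies the triangle inequality) that turns a clustering
#' into a distance matrix for the Mantel test.
#'
#' @param labels Label vector (>= 3 samples, no missing).
#' @return Symmetric 0/1 matrix with zero diagonal.
#' @export
labels_to_distance <- function(labels) {
  if (length(labels) < 3) stop("need >= 3 samples")
  if (anyNA(labels)) stop("missing labels")
  d <- outer(labels, labels, FUN = "!=") * 1
  diag(d) <- 0
  rownames(d) <- colnames(d) <- names(labels)
  d
}

#' Mantel permutation test between two distance matrices
#'
#' r is the Pearson correlation over the strictly-upper-triangle entries;
#' the p-value is \code{(1 + count(perm r >= observed r)) / (n_perm + 1)}
#' under simultaneous row/column permutation of the second matrix, so p is
#' never 0 and its floor is \code{1/(n_perm + 1)}. Delegates the
#' permutation machinery to \code{vegan::mantel}, whose conventions match.
#'
#' @param d1,d2 Symmetric matrices, zero diagonal, equal dimension >= 3.
#' @param n_perm Number of permutations (default 9999).
#' @param seed Optional integer seed.
#' @return list(r, p, n_perm).
#' @export
mantel_test <- function(d1, d2, n_perm = 9999, seed = NULL) {
  d1 <- as.matrix(d1); d2 <- as.matrix(d2)
  if (!all(dim(d1) == dim(d2)) || nrow(d1) < 3)
    stop("matrices must be equal-dimension, >= 3 samples")
  for (d in list(d1, d2)) {
    if (any(abs(d - t(d)) > 1e-8)) stop("distance matrices must be symmetric")
    if (any(abs(diag(d)) > 1e-12)) stop("distance matrices must have zero diagonal")
  }
  if (stats::sd(d1[upper.tri(d1)]) == 0 || stats::sd(d2[upper.tri(d2)]) == 0)
    stop("constant distance matrix: Mantel r undefined")
  if (!is.null(seed)) set.seed(seed)
  mt <- vegan::mantel(stats::as.dist(d1), stats::as.dist(d2),
                      method = "pearson", permutations = n_perm)
  list(r = unname(mt$statistic), p = unname(mt$signif), n_perm = n_perm)
}
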