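## PCA with drop-one-in projection and F_ST-based neighbour-joining
## consensus trees.

#' Principal component analysis of genotype dosages
#'
#' Each marker is centred by its mean dosage and scaled by
#' \code{sqrt(2 p (1-p))} (the binomial standard deviation at the estimated
#' allele frequency); missing dosages are imputed to the marker mean.
#' Monomorphic markers are dropped. Coordinates are the left singular
#' vectors scaled by the singular values; eigenvalues are those of the
#' sample covariance across markers, sorted descending.
#'
#' @param g N x M dosage matrix (>= 2 samples).
#' @param n_pc Number of components to return (default 10, capped).
#' @return list(coords = N x n_pc matrix, eigenvalues, ids).
#' @export
pca_genotypes <- function(g, n_pc = 10) {
  g <- check_geno(g)
  if (nrow(g) < 2) stop("need >= 2 samples")
  p <- allele_freqs(g)
  keep <- !is.na(p) & p > 0 & p < 1
  if (sum(keep) < 2) stop("fewer than 2 polymorphic markers")
  g <- g[, keep, drop = FALSE]
  p <- p[keep]
  x <- sweep(g, 2, 2 * p)
  x[is.na(x)] <- 0
  x <- sweep(x, 2, sqrt(2 * p * (1 - p)), "/")
  n_pc <- min(n_pc, nrow(g) - 1, ncol(g))
  sv <- svd(x, nu = n_pc, nv = 0)
  coords <- sv$u * rep(sv$d[seq_len(n_pc)], each = nrow(g))
  rownames(coords) <- rownames(g)
  colnames(coords) <- paste0("PC", seq_len(n_pc))
  list(coords = coords, eigenvalues = sv$d^2 / ncol(g), ids = rownames(g))
}

#' Drop-one-in PCA projection of query samples
#'
#' To keep unequal group sizes from distorting the component axes, each
#' query sample is dropped, alone, into the reference set: PCA is rerun on
#' reference + that one query and the query's coordinates on the first two
#' components are recorded. Axis signs are aligned across runs by
#' maximising the correlation of the reference coordinates with the
#' reference-only PCA; near-degenerate alignments (|correlation| < 0.8) are
#' flagged. Per-reference-sample mean coordinates across runs are returned
#' as a stability readout.
#'
#' @param reference,queries Dosage matrices over the same marker set.
#' @return list(query_coords = n_query x 2, ref_mean_coords, ref_coords =
#'   reference-only PCA coordinates, flagged = logical per query).
#' @export
drop_one_in <- function(reference, queries) {
  reference <- check_geno(reference); queries <- check_geno(queries)
  if (ncol(reference) != ncol(queries)) stop("marker sets differ")
  base <- pca_genotypes(reference, n_pc = 2)
  nq <- nrow(queries)
  qc <- matrix(NA_real_, nq, 2,
               dimnames = list(rownames(queries), c("PC1", "PC2")))
  acc <- matrix(0, nrow(reference), 2)
  flagged <- logical(nq)
  for (i in seq_len(nq)) {
    qrow <- queries[i, , drop = FALSE]
    rownames(qrow) <- ".query."            # avoid id clashes with references
    comb <- rbind(reference, qrow)
    run <- pca_genotypes(comb, n_pc = 2)
    ref_idx <- seq_len(nrow(reference))
    for (j in 1:2) {
      cc <- stats::cor(base$coords[, j], run$coords[ref_idx, j])
      if (!is.finite(cc) || abs(cc) < 0.8) flagged[i] <- TRUE
      s <- if (!is.finite(cc) || cc >= 0) 1 else -1
      run$coords[, j] <- run$coords[, j] * s
    }
    qc[i, ] <- run$coords[nrow(comb), ]
    acc <- acc + run$coords[ref_idx, ]
  }
  list(query_coords = qc, ref_mean_coords = acc / nq,
       ref_coords = base$coords, flagged = flagged)
}

#' Neighbour-joining tree from a distance matrix
#'
#' Saitou-Nei neighbour joining (via \code{ape::nj}); negative branch
#' lengths, which can arise from sampling noise, are clamped to zero with
#' the deficit transferred to the adjacent branch so path lengths are
#' preserved where possible.
#'
#' @param d Symmetric matrix with zero diagonal, >= 3 taxa.
#' @return An \code{ape::phylo} unrooted tree.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3) stop("need >= 3 taxa")
  if (any(abs(d - t(d)) > 1e-8)) stop("distance matrix must be symmetric")
  if (any(abs(diag(d)) > 1e-12)) stop("distance matrix must have zero diagonal")
  tr <- ape::nj(stats::as.dist(d))
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    child <- tr$edge[e, 2]
    adj <- which(tr$edge[, 1] == child)   # edges below the clamped one
    if (length(adj))
      tr$edge.length[adj] <- tr$edge.length[adj] + tr$edge.length[e]
    tr$edge.length[e] <- 0
  }
  tr
}

#' F_ST bootstrap consensus tree over populations
#'
#' Per replicate, \code{n_per_pop} samples are drawn without replacement
#' from each population, all pairwise inbreeding-adjusted Hudson F_ST
#' values are computed, and a neighbour-joining tree is built. The
#' majority-rule (> 50 percent) consensus over replicates is returned with
#' per-internal-edge support equal to the fraction of replicate trees
#' containing the bipartition. Replicates with any undefined F_ST are
#' skipped and counted.
#'
#' @param groups Named list of dosage matrices, one per population, over a
#'   shared marker set.
#' @param n_per_pop Samples drawn per population per replicate (default 5).
#' @param reps Replicates (default 1000).
#' @param seed Integer seed.
#' @param inbreed_adjust Passed to \code{\link{fst_pair}}.
#' @return An object of class \code{consensus_tree}: list(tree =
#'   \code{ape::phylo} with support as node labels, support, newick,
#'   n_used, n_skipped).
#' @export
fst_bootstrap_consensus <- function(groups, n_per_pop = 5, reps = 1000,
                                    seed = 1, inbreed_adjust = TRUE) {
  stopifnot(is.list(groups), length(groups) >= 3)
  pops <- names(groups)
  if (any(vapply(groups, nrow, 0) < n_per_pop))
    stop("every population needs >= n_per_pop samples")
  set.seed(seed)
  trees <- vector("list", reps)
  skipped <- 0L
  for (r in seq_len(reps)) {
    sub <- lapply(groups, function(gg)
      gg[sample(nrow(gg), n_per_pop), , drop = FALSE])
    d <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
    bad <- FALSE
    for (i in seq_len(length(pops) - 1)) {
      for (j in seq(i + 1, length(pops))) {
        fij <- fst_pair(sub[[i]], sub[[j]], inbreed_adjust = inbreed_adjust,
                        n_blocks = 0)$estimate
        if (!is.finite(fij)) { bad <- TRUE; break }
        d[i, j] <- d[j, i] <- fij
      }
      if (bad) break
    }
    if (bad) { skipped <- skipped + 1L; next }
    trees[[r]] <- nj_tree(d)
  }
  trees <- trees[!vapply(trees, is.null, TRUE)]
  if (!length(trees)) stop("no usable replicates")
  class(trees) <- "multiPhylo"
  cons <- ape::consensus(trees, p = 0.5)
  supp <- ape::prop.clades(cons, trees, rooted = FALSE) / length(trees)
  cons$node.label <- format(round(supp, 3))
  structure(list(tree = cons, support = supp,
                 newick = ape::write.tree(cons),
                 n_used = length(trees), n_skipped = skipped),
            class = "consensus_tree")
}

#' @export
print.consensus_tree <- function(x, ...) {
  cat("Majority-rule consensus over", x$n_used, "replicate F_ST NJ trees",
      if (x$n_skipped) paste0("(", x$n_skipped, " skipped)"), "\n")
  cat(x$newick, "\n")
  invisible(x)
}
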