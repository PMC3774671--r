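## Maximum-likelihood EM admixture estimation, replicate-run alignment,
## run-consistency Mantel checks, K selection and majority group assignment.

#' Binomial admixture log-likelihood
#'
#' Each individual i has ancestry proportions Q[i, ] over K clusters with
#' cluster allele frequencies P; its dosage at marker m is Binomial(2, f_im)
#' with f_im = sum_k Q[i,k] P[k,m]. The log-likelihood is
#' sum_im [ g_im log f_im + (2 - g_im) log(1 - f_im) ] over non-missing
#' dosages (the binomial coefficient, constant in Q and P, is omitted).
#'
#' @param g N x M dosage matrix.
#' @param Q N x K row-stochastic matrix.
#' @param P K x M frequency matrix in (0, 1).
#' @return The log-likelihood (0 if every dosage is missing).
#' @export
admix_loglik <- function(g, Q, P) {
  Q <- as.matrix(Q); P <- as.matrix(P)
  if (nrow(g) != nrow(Q) || ncol(g) != ncol(P) || ncol(Q) != nrow(P))
    stop("dimension mismatch between g, Q and P")
  f <- Q %*% P
  ll <- g * log(f) + (2 - g) * log(1 - f)
  sum(ll[!is.na(ll)])
}

#' Fit the admixture model by EM
#'
#' Maximum-likelihood estimation of ancestry proportions Q and cluster
#' allele frequencies P by the standard admixture EM updates. Q is
#' initialised from flat Dirichlet draws, P from observed allele frequencies
#' plus jitter; replicate runs differ only by seed. The likelihood is
#' non-decreasing across iterations (asserted); iteration stops when the
#' gain drops below \code{tol} or after \code{max_iter} accelerated cycles
#' (each cycle is two EM updates plus a squared extrapolation, SQUAREM,
#' accepted only when it does not lower the likelihood). Markers should be
#' LD-pruned beforehand.
#'
#' Initialisation: \code{init = "kmeans"} (default) seeds the clusters from
#' a k-means partition of the top principal components - cluster allele
#' frequencies for P, soft one-hot memberships for Q - which starts EM near
#' a good basin; \code{init = "random"} uses flat Dirichlet Q and observed
#' frequencies plus jitter for P. Both are deterministic given the seed.
#'
#' @param g N x M dosage matrix.
#' @param K Number of clusters (1 <= K <= N).
#' @param seed Integer seed.
#' @param max_iter Maximum accelerated cycles (default 500).
#' @param tol Log-likelihood convergence tolerance (default 1e-4).
#' @param init "kmeans" or "random".
#' @return An object of class \code{admix_fit}: list(Q, P, loglik_trace,
#'   K, seed, converged).
#' @export
admix_fit <- function(g, K, seed = 1, max_iter = 500, tol = 1e-4,
                      init = c("kmeans", "random")) {
  g <- check_geno(g)
  init <- match.arg(init)
  n <- nrow(g); m <- ncol(g)
  if (K < 1) stop("K must be >= 1")
  if (K > n) stop("K must not exceed the sample count")
  set.seed(seed)
  pm <- allele_freqs(g)
  if (init == "kmeans" && K > 1) {
    pc <- pca_genotypes(g, n_pc = min(max(K + 2, 4), n - 1))
    km <- stats::kmeans(pc$coords, centers = K, nstart = 10)
    Q0 <- matrix(0.2 / (K - 1), n, K)
    Q0[cbind(seq_len(n), km$cluster)] <- 0.8
    P0 <- t(vapply(seq_len(K), function(k)
      colMeans(g[km$cluster == k, , drop = FALSE], na.rm = TRUE) / 2,
      numeric(m)))
    P0[is.na(P0)] <- matrix(pm, K, m, byrow = TRUE)[is.na(P0)]
  } else {
    Q0 <- rdirichlet(n, rep(1, K))
    P0 <- matrix(rep(pm, each = K), K, m) +
      matrix(stats::runif(K * m, -0.05, 0.05), K, m)
  }
  P0 <- pmin(pmax(P0, 1e-6), 1 - 1e-6)
  res <- .admix_em_cpp(g, Q0, P0, as.integer(max_iter), tol)
  Q <- res$Q; P <- res$P
  dimnames(Q) <- list(rownames(g), paste0("K", seq_len(K)))
  dimnames(P) <- list(paste0("K", seq_len(K)), colnames(g))
  structure(list(Q = Q, P = P, loglik_trace = res$trace, K = K, seed = seed,
                 converged = res$converged),
            class = "admix_fit")
}

#' @export
print.admix_fit <- function(x, ...) {
  cat("Admixture EM fit: K =", x$K, ", N =", nrow(x$Q), ", M =", ncol(x$P),
      "\n")
  cat("log-likelihood:", format(utils::tail(x$loglik_trace, 1)),
      "after", length(x$loglik_trace), "iterations",
      if (x$converged) "(converged)" else "(max_iter reached)", "\n")
  invisible(x)
}

#' @export
summary.admix_fit <- function(object, ...) {
  grp <- assign_majority(object$Q)
  cat("Admixture EM fit (K =", object$K, ")\n")
  cat("Cluster sizes by majority assignment:\n")
  print(table(grp$group))
  cat("Mean ancestry proportions:\n")
  print(round(colMeans(object$Q), 4))
  invisible(object)
}

#' @export
coef.admix_fit <- function(object, ...) object$Q

#' @export
logLik.admix_fit <- function(object, ...) {
  val <- utils::tail(object$loglik_trace, 1)
  attr(val, "df") <- (nrow(object$Q) * (object$K - 1) +
                        object$K * ncol(object$P))
  class(val) <- "logLik"
  val
}

#' @export
plot.admix_fit <- function(x, order_by = NULL, ...) {
  Q <- x$Q
  if (!is.null(order_by)) Q <- Q[order(order_by, -Q[, 1]), , drop = FALSE]
  graphics::barplot(t(Q), col = grDevices::hcl.colors(x$K, "Dark 3"),
                    border = NA, space = 0, xaxt = "n",
                    ylab = "ancestry proportion", ...)
  invisible(x)
}

#' Align replicate admixture runs by column permutation
#'
#' Label-switching correction: for each run the column permutation of Q (and
#' row permutation of P) maximising the Frobenius inner product with the
#' first run's Q is chosen, exhaustively over the K! permutations (K <= 8).
#'
#' @param fits List of \code{admix_fit} objects with equal K and N.
#' @return list(fits = aligned fits, permutations = list of integer vectors).
#' @export
align_runs <- function(fits) {
  stopifnot(length(fits) >= 1)
  K <- fits[[1]]$K
  if (any(vapply(fits, function(f) f$K, 0) != K))
    stop("all runs must share K")
  if (K > 8) stop("exhaustive alignment limited to K <= 8")
  perms <- all_permutations(K)
  ref <- fits[[1]]$Q
  out <- vector("list", length(fits))
  pused <- vector("list", length(fits))
  for (i in seq_along(fits)) {
    Q <- fits[[i]]$Q
    scores <- apply(perms, 1, function(pp) sum(ref * Q[, pp, drop = FALSE]))
    best <- perms[which.max(scores), ]
    f <- fits[[i]]
    f$Q <- f$Q[, best, drop = FALSE]
    f$P <- f$P[best, , drop = FALSE]
    colnames(f$Q) <- paste0("K", seq_len(K))
    rownames(f$P) <- paste0("K", seq_len(K))
    out[[i]] <- f
    pused[[i]] <- best
  }
  list(fits = out, permutations = pused)
}

#' Consistency of replicate runs via Mantel tests
#'
#' For every pair of aligned runs, a Mantel permutation test is applied to
#' the Euclidean distance matrices of the individuals' ancestry vectors.
#'
#' @param fits List of aligned \code{admix_fit} objects (>= 2).
#' @param n_perm Permutations per test (default 9999).
#' @param seed Integer seed.
#' @return data.frame(run1, run2, r, p).
#' @export
run_consistency <- function(fits, n_perm = 9999, seed = 1) {
  if (length(fits) < 2) stop("need at least two runs")
  dd <- lapply(fits, function(f) as.matrix(stats::dist(f$Q)))
  res <- list()
  k <- 1
  for (i in seq_len(length(fits) - 1)) {
    for (j in seq(i + 1, length(fits))) {
      mt <- mantel_test(dd[[i]], dd[[j]], n_perm = n_perm,
                        seed = derive_seed(seed, i * 100 + j))
      res[[k]] <- data.frame(run1 = i, run2 = j, r = mt$r, p = mt$p)
      k <- k + 1
    }
  }
  do.call(rbind, res)
}

#' Select the number of clusters K
#'
#' Returns the candidate K with the highest mean final log-likelihood across
#' replicate runs (the ML analogue of choosing the highest mean estimated
#' ln P(Data)); ties go to the smaller K.
#'
#' @param fits_by_k Named list mapping each candidate K (as a name or in the
#'   fits) to a list of \code{admix_fit} objects.
#' @return The selected K (integer).
#' @export
select_k <- function(fits_by_k) {
  if (!length(fits_by_k)) stop("empty candidate map")
  ks <- vapply(fits_by_k, function(fl) fl[[1]]$K, 0)
  mean_ll <- vapply(fits_by_k, function(fl)
    mean(vapply(fl, function(f) utils::tail(f$loglik_trace, 1), 0)), 0)
  ord <- order(-mean_ll, ks)
  as.integer(ks[ord[1]])
}

#' Assign individuals to groups by relative majority
#'
#' Each individual is labelled with the cluster of its largest ancestry
#' proportion; exact ties are broken by the lowest column index and flagged.
#'
#' @param Q N x K row-stochastic matrix.
#' @return data.frame(sample_id, group, tie).
#' @export
assign_majority <- function(Q) {
  Q <- as.matrix(Q)
  idx <- max.col(Q, ties.method = "first")
  rmax <- Q[cbind(seq_len(nrow(Q)), idx)]
  tie <- rowSums(Q == rmax) > 1
  labs <- colnames(Q)
  if (is.null(labs)) labs <- paste0("K", seq_len(ncol(Q)))
  data.frame(sample_id = if (is.null(rownames(Q)))
    as.character(seq_len(nrow(Q))) else rownames(Q),
    group = labs[idx], tie = tie, stringsAsFactors = FALSE)
}
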