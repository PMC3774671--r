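## Internal helpers shared across modules.

#' popstructr: population substructure inference from SNP genotypes
#'
#' Simulation-verified estimators for admixture, differentiation,
#' inbreeding, segment sharing and concordance in structured human cohorts.
#' @useDynLib popstructr, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @keywords internal
"_PACKAGE"

## Dirichlet draws used for individual ancestry scatter and EM initialisation.
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  x / rowSums(x)
}

## round() in R is banker's rounding; printed tables use half-up.
round_half_up <- function(x, digits = 2) {
  s <- 10^digits
  floor(x * s + 0.5) / s
}

## Truncation (not rounding) to `digits` decimals, e.g. 252/273 -> 92.30%.
trunc_digits <- function(x, digits = 2) {
  s <- 10^digits
  trunc(x * s) / s
}

## All permutations of 1..k (k small; used for run alignment, k <= 8).
all_permutations <- function(k) {
  if (k == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(k - 1L)
  out <- vector("list", k)
  for (pos in seq_len(k)) {
    block <- matrix(0L, nrow(sub), k)
    block[, pos] <- k
    block[, -pos] <- sub
    out[[pos]] <- block
  }
  do.call(rbind, out)
}

## Validate a genotype matrix: samples x markers, values {0,1,2,NA}.
check_geno <- function(g) {
  if (!is.matrix(g)) stop("genotypes must be a matrix (samples x markers)")
  v <- g[!is.na(g)]
  if (length(v) && !all(v %in% c(0, 1, 2)))
    stop("genotype dosages must be 0, 1, 2 or NA")
  if (is.null(rownames(g))) rownames(g) <- sprintf("S%04d", seq_len(nrow(g)))
  if (is.null(colnames(g))) colnames(g) <- sprintf("snp%06d", seq_len(ncol(g)))
  if (anyDuplicated(rownames(g))) stop("duplicate sample ids")
  if (anyDuplicated(colnames(g))) stop("duplicate marker ids")
  g
}

## Validate a marker map: data.frame(marker, chrom, bp, cM), sorted, cM
## non-decreasing within chromosome.
check_map <- function(map, require_cm = FALSE) {
  need <- c("marker", "chrom", "bp")
  if (!is.data.frame(map) || !all(need %in% names(map)))
    stop("map must be a data.frame with columns marker, chrom, bp (and optionally cM)")
  if (anyDuplicated(paste(map$chrom, map$bp))) stop("duplicate (chrom, bp) in map")
  if (require_cm && is.null(map$cM)) stop("map must carry genetic positions (cM)")
  if (!is.null(map$cM)) {
    bad <- tapply(map$cM, map$chrom, function(x) any(diff(x) < 0))
    if (any(unlist(bad))) stop("cM must be non-decreasing within chromosome")
  }
  map
}

## Allele frequency of the counted allele, per marker, NA-aware.
allele_freqs <- function(g) colMeans(g, na.rm = TRUE) / 2

## Per-marker count of non-missing individuals.
marker_n <- function(g) colSums(!is.na(g))

## Deterministic child seeds below 2^31 derived from one user seed.
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000003L) * 1009L + as.integer(offset) %% 100003L
}
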