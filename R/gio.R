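## PLINK-text genotype I/O, genetic-map interpolation, and the study's
## marker/sample quality-control filters.

#' Read genotypes from PLINK text files (.ped/.map)
#'
#' The .ped file must carry the six leading columns (FID IID PAT MAT SEX
#' PHENO) followed by two allele columns per marker; the .map file the four
#' standard columns (chrom, marker id, cM, bp). Allele codes must be one of
#' A, C, G, T or 0 (missing). Dosages count copies of A1, defined as the
#' first non-missing allele encountered in file order for that marker;
#' "0 0" becomes NA.
#'
#' @param ped_path,map_path Paths to the .ped and .map files.
#' @return A list with \code{genotypes} (N x M dosage matrix), \code{map}
#'   (data.frame marker, chrom, bp, cM), \code{alleles} (M x 2 character
#'   matrix, A1 then A2) and \code{fam} (the six leading .ped columns).
#' @export
read_plink_text <- function(ped_path, map_path) {
  if (!file.exists(ped_path)) stop("ped file not found: ", ped_path)
  if (!file.exists(map_path)) stop("map file not found: ", map_path)
  mp <- utils::read.table(map_path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("chrom", "marker", "cM", "bp"))
  map <- data.frame(marker = as.character(mp$marker),
                    chrom = as.character(mp$chrom),
                    bp = as.integer(mp$bp), cM = as.numeric(mp$cM),
                    stringsAsFactors = FALSE)
  m <- nrow(map)
  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  n <- length(lines)
  fam <- matrix(NA_character_, n, 6)
  g <- matrix(NA_integer_, n, m)
  a1 <- rep(NA_character_, m)
  a2 <- rep(NA_character_, m)
  ok <- c("A", "C", "G", "T", "0")
  for (i in seq_len(n)) {
    f <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(f) != 6 + 2 * m)
      stop("ped line ", i, ": expected ", 6 + 2 * m, " fields, found ",
           length(f))
    fam[i, ] <- f[1:6]
    al <- f[-(1:6)]
    if (!all(al %in% ok))
      stop("ped line ", i, ": allele codes outside {A,C,G,T,0}")
    aA <- al[seq(1, 2 * m, 2)]
    aB <- al[seq(2, 2 * m, 2)]
    miss <- aA == "0" | aB == "0"
    new1 <- is.na(a1) & !miss
    a1[new1] <- aA[new1]
    new2 <- is.na(a2) & !miss & aB != a1
    a2[new2] <- aB[new2]
    new2b <- is.na(a2) & !miss & aA != a1
    a2[new2b] <- aA[new2b]
    d <- (aA == a1) + (aB == a1)
    d[miss] <- NA_integer_
    g[i, ] <- d
  }
  colnames(fam) <- c("fid", "iid", "pat", "mat", "sex", "pheno")
  fam <- as.data.frame(fam, stringsAsFactors = FALSE)
  ids <- fam$iid
  if (anyDuplicated(ids)) ids <- paste(fam$fid, fam$iid, sep = "_")
  dimnames(g) <- list(ids, map$marker)
  list(genotypes = g, map = map, alleles = cbind(A1 = a1, A2 = a2),
       fam = fam)
}

#' Write genotypes to PLINK text files (.ped/.map)
#'
#' Inverse of \code{\link{read_plink_text}}: dosages of A1 become allele
#' pairs (2 -> "A1 A1", 1 -> "A1 A2", 0 -> "A2 A2", NA -> "0 0").
#'
#' @param g N x M dosage matrix.
#' @param map Marker map data.frame (marker, chrom, bp, cM).
#' @param ped_path,map_path Output paths.
#' @param alleles Optional M x 2 character matrix (A1, A2); defaults to
#'   "A"/"G" for every marker.
#' @param fam Optional data.frame of the six leading .ped columns.
#' @return Invisibly, the two paths.
#' @export
write_plink_text <- function(g, map, ped_path, map_path, alleles = NULL,
                             fam = NULL) {
  g <- check_geno(g)
  map <- check_map(map)
  if (ncol(g) != nrow(map)) stop("marker count mismatch between g and map")
  m <- ncol(g)
  if (is.null(alleles)) alleles <- cbind(rep("A", m), rep("G", m))
  if (is.null(fam))
    fam <- data.frame(fid = rownames(g), iid = rownames(g), pat = 0, mat = 0,
                      sex = 0, pheno = -9)
  cm <- if (is.null(map$cM)) rep(0, m) else map$cM
  utils::write.table(data.frame(map$chrom, map$marker, cm, map$bp),
                     map_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  con <- file(ped_path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(g))) {
    d <- g[i, ]
    aA <- ifelse(is.na(d), "0", ifelse(d >= 1, alleles[, 1], alleles[, 2]))
    aB <- ifelse(is.na(d), "0", ifelse(d == 2, alleles[, 1], alleles[, 2]))
    geno <- as.vector(rbind(aA, aB))
    writeLines(paste(c(unlist(fam[i, ]), geno), collapse = " "), con)
  }
  invisible(c(ped_path, map_path))
}

#' Interpolate genetic positions from physical positions
#'
#' Linear interpolation of cM between flanking reference points per
#' chromosome; outside the reference hull, extrapolation continues the
#' boundary segment's slope. Output is monotone when the references are.
#'
#' @param map Marker map (marker, chrom, bp).
#' @param reference_points data.frame(chrom, bp, cM) with at least two
#'   strictly increasing points per chromosome present in the map.
#' @return The map with its cM column replaced by interpolated values.
#' @export
interpolate_cm <- function(map, reference_points) {
  map <- check_map(map)
  rp <- reference_points
  stopifnot(all(c("chrom", "bp", "cM") %in% names(rp)))
  out <- rep(NA_real_, nrow(map))
  for (ch in unique(map$chrom)) {
    r <- rp[rp$chrom == ch, ]
    if (nrow(r) < 2)
      stop("chromosome without >=2 reference points: ", ch)
    r <- r[order(r$bp), ]
    if (any(diff(r$bp) <= 0) || any(diff(r$cM) <= 0))
      stop("reference points must be strictly increasing on chromosome ", ch)
    idx <- which(map$chrom == ch)
    x <- map$bp[idx]
    y <- stats::approx(r$bp, r$cM, xout = x, rule = 2)$y
    k <- nrow(r)
    lo <- x < r$bp[1]
    hi <- x > r$bp[k]
    slope1 <- (r$cM[2] - r$cM[1]) / (r$bp[2] - r$bp[1])
    slopek <- (r$cM[k] - r$cM[k - 1]) / (r$bp[k] - r$bp[k - 1])
    y[lo] <- r$cM[1] + slope1 * (x[lo] - r$bp[1])
    y[hi] <- r$cM[k] + slopek * (x[hi] - r$bp[k])
    out[idx] <- y
  }
  map$cM <- out
  map
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact conditional test: given the observed allele counts, the
#' p-value is the sum of probabilities of all heterozygote counts whose
#' conditional probability does not exceed that of the observed count.
#'
#' @param n_AA,n_Aa,n_aa Non-negative integer genotype counts.
#' @return A p-value in (0, 1].
#' @examples
#' hwe_exact_p(5, 0, 5)   # strong heterozygote deficit
#' @export
hwe_exact_p <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stop("genotype counts must be non-negative")
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop("total count must be >= 1")
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n - nA
  hmax <- min(nA, na)
  h <- seq(nA %% 2, hmax, by = 2)           # parity fixed by allele count
  ## P(h het | nA, n) proportional to n! 2^h / (nAA! h! naa!)
  logp <- lgamma(n + 1) - lgamma((nA - h) / 2 + 1) - lgamma(h + 1) -
    lgamma((na - h) / 2 + 1) + h * log(2)
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  obs <- pr[match(n_Aa, h)]
  min(1, sum(pr[pr <= obs * (1 + 1e-9)]))
}

#' Method-of-moments relatedness estimates (PI_HAT) for all sample pairs
#'
#' IBS-based moment estimator of the IBD-sharing coefficient PI_HAT =
#' P(IBD=1)/2 + P(IBD=2): observed IBS0/1/2 counts per pair are equated with
#' their expectations under the pooled allele frequencies.
#'
#' @param g N x M dosage matrix.
#' @return data.frame(id1, id2, pi_hat) for all unordered pairs.
#' @export
pi_hat <- function(g) {
  g <- check_geno(g)
  n <- nrow(g)
  if (n < 2) return(data.frame(id1 = character(), id2 = character(),
                               pi_hat = numeric()))
  p <- allele_freqs(g)
  keep <- is.finite(p) & p > 0 & p < 1
  g <- g[, keep, drop = FALSE]
  A0 <- (!is.na(g) & g == 0) + 0
  A1 <- (!is.na(g) & g == 1) + 0
  A2 <- (!is.na(g) & g == 2) + 0
  V <- (A0 + A1 + A2) %*% t(A0 + A1 + A2)        # pairwise valid markers
  N2 <- A0 %*% t(A0) + A1 %*% t(A1) + A2 %*% t(A2)
  N0 <- A0 %*% t(A2) + A2 %*% t(A0)
  N1 <- V - N0 - N2
  M <- ncol(g)
  ## unbiased frequency moments from allele counts x of a (factorial
  ## moments), removing the small-sample bias of plug-in p-hat powers
  x <- colSums(g, na.rm = TRUE)
  a <- 2 * marker_n(g)
  y <- a - x
  d4 <- a * (a - 1) * (a - 2) * (a - 3)
  d3 <- a * (a - 1) * (a - 2)
  p2q2 <- x * (x - 1) * y * (y - 1) / d4
  p3q <- x * (x - 1) * (x - 2) * y / d4
  pq3 <- x * y * (y - 1) * (y - 2) / d4
  p4 <- x * (x - 1) * (x - 2) * (x - 3) / d4
  q4 <- y * (y - 1) * (y - 2) * (y - 3) / d4
  p2q <- x * (x - 1) * y / d3
  pq2 <- x * y * (y - 1) / d3
  p3 <- x * (x - 1) * (x - 2) / d3
  q3 <- y * (y - 1) * (y - 2) / d3
  e0 <- sum(2 * p2q2) / M
  e1_0 <- sum(4 * p3q + 4 * pq3) / M
  e2_0 <- sum(p4 + q4 + 4 * p2q2) / M
  e1_1 <- sum(2 * p2q + 2 * pq2) / M
  e2_1 <- sum(p3 + q3 + p2q + pq2) / M
  ids <- rownames(g)
  pairs <- which(upper.tri(V), arr.ind = TRUE)
  f0 <- N0[pairs] / V[pairs]; f1 <- N1[pairs] / V[pairs]
  f2 <- N2[pairs] / V[pairs]
  P0 <- pmin(pmax(f0 / e0, 0), 1)
  P1 <- pmin(pmax((f1 - P0 * e1_0) / e1_1, 0), 1)
  P2 <- pmin(pmax((f2 - P0 * e2_0 - P1 * e2_1) / 1, 0), 1)
  tot <- P0 + P1 + P2
  P1 <- P1 / tot; P2 <- P2 / tot
  data.frame(id1 = ids[pairs[, 1]], id2 = ids[pairs[, 2]],
             pi_hat = P1 / 2 + P2, stringsAsFactors = FALSE)
}

#' Prune related samples down to second-cousin level
#'
#' Flags pairs with PI_HAT above the threshold and greedily removes one
#' member per flagged pair: the member with the lower call rate, ties broken
#' by keeping the lexicographically smaller id. No retained pair exceeds the
#' threshold.
#'
#' @param g N x M dosage matrix.
#' @param threshold PI_HAT threshold in (0, 1); default 0.05, above the
#'   expected second-cousin sharing of ~0.03.
#' @return Character vector of retained sample ids (original order).
#' @export
relatedness_prune <- function(g, threshold = 0.05) {
  g <- check_geno(g)
  if (nrow(g) < 2) return(rownames(g))
  ph <- pi_hat(g)
  flagged <- ph[ph$pi_hat > threshold, , drop = FALSE]
  call_rate <- rowMeans(!is.na(g))
  kept <- rownames(g)
  while (nrow(flagged) > 0) {
    pair <- flagged[order(-flagged$pi_hat, flagged$id1, flagged$id2), ][1, ]
    drop <- if (call_rate[pair$id1] < call_rate[pair$id2]) pair$id1
    else if (call_rate[pair$id2] < call_rate[pair$id1]) pair$id2
    else max(pair$id1, pair$id2)
    kept <- setdiff(kept, drop)
    flagged <- flagged[flagged$id1 != drop & flagged$id2 != drop, ,
                       drop = FALSE]
  }
  rownames(g)[rownames(g) %in% kept]
}

#' Marker and sample quality control
#'
#' Applies, in this order: (1) sample call rate >= \code{sample_call};
#' (2) marker-type filter - autosomes only and removal of A/T and G/C
#' (strand-ambiguous) markers when allele codes are available; (3) marker
#' call rate >= \code{marker_call}; (4) minor allele frequency filter
#' (markers with MAF <= \code{maf} removed); (5) exact Hardy-Weinberg test
#' (markers with p < \code{hwe_p} removed). The filter order is recorded in
#' the report. Filters are idempotent on their own output.
#'
#' @param g N x M dosage matrix.
#' @param map Marker map.
#' @param sample_call,marker_call,maf,hwe_p Thresholds (defaults 0.97, 0.98,
#'   0.05, 1e-3).
#' @param alleles Optional M x 2 allele matrix enabling the A/T-G/C rule.
#' @param autosomes Character vector of autosomal chromosome labels; markers
#'   on other chromosomes are removed. NULL disables the rule.
#' @return list(genotypes, map, report) where report is a data.frame(rule,
#'   kind, removed) in application order.
#' @export
qc_filter <- function(g, map, sample_call = 0.97, marker_call = 0.98,
                      maf = 0.05, hwe_p = 1e-3, alleles = NULL,
                      autosomes = as.character(1:22)) {
  g <- check_geno(g)
  map <- check_map(map)
  if (ncol(g) != nrow(map)) stop("marker count mismatch between g and map")
  report <- data.frame(rule = character(), kind = character(),
                       removed = integer(), stringsAsFactors = FALSE)
  note <- function(rule, kind, removed)
    rbind(report, data.frame(rule = rule, kind = kind, removed = removed))

  cr <- rowMeans(!is.na(g))
  keep_s <- cr >= sample_call
  report <- note("sample_call_rate", "sample", sum(!keep_s))
  g <- g[keep_s, , drop = FALSE]

  keep_m <- rep(TRUE, ncol(g))
  if (!is.null(autosomes)) keep_m <- map$chrom %in% autosomes
  if (!is.null(alleles)) {
    pair <- paste0(pmin(alleles[, 1], alleles[, 2]),
                   pmax(alleles[, 1], alleles[, 2]))
    keep_m <- keep_m & !(pair %in% c("AT", "CG"))
  }
  report <- note("marker_type", "marker", sum(!keep_m))
  g <- g[, keep_m, drop = FALSE]; map <- map[keep_m, , drop = FALSE]

  mcr <- colMeans(!is.na(g))
  keep_m <- mcr >= marker_call
  report <- note("marker_call_rate", "marker", sum(!keep_m))
  g <- g[, keep_m, drop = FALSE]; map <- map[keep_m, , drop = FALSE]

  p <- allele_freqs(g)
  m_af <- pmin(p, 1 - p)
  keep_m <- !is.na(m_af) & m_af > maf
  report <- note("maf", "marker", sum(!keep_m))
  g <- g[, keep_m, drop = FALSE]; map <- map[keep_m, , drop = FALSE]

  hp <- vapply(seq_len(ncol(g)), function(j) {
    x <- g[, j]
    hwe_exact_p(sum(x == 2, na.rm = TRUE), sum(x == 1, na.rm = TRUE),
                sum(x == 0, na.rm = TRUE))
  }, numeric(1))
  keep_m <- hp >= hwe_p
  report <- note("hwe", "marker", sum(!keep_m))
  g <- g[, keep_m, drop = FALSE]; map <- map[keep_m, , drop = FALSE]

  if (ncol(g) == 0) warning("all markers removed by QC")
  list(genotypes = g, map = map, report = report)
}
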