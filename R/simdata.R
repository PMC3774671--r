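## Synthetic cohort generator: Balding-Nichols ancestral panels, admixed
## inbred genotypes with phased truth haplotypes, planted ROH/IBD segments,
## and surname labels concordant with genetic groups.

#' Simulate ancestral allele-frequency panels under the Balding-Nichols model
#'
#' Draws a shared set of ancestral ("base") allele frequencies and, for each
#' of \code{n_pops} populations, per-SNP frequencies from the Beta
#' distribution \code{Beta(p(1-c)/c, (1-p)(1-c)/c)} whose variance around the
#' base frequency \code{p} equals \code{c p(1-p)}; \code{c} is the
#' population's differentiation (F_ST) parameter.
#'
#' @param n_snps Number of SNPs (>= 1).
#' @param n_pops Number of ancestral populations.
#' @param fst_params Numeric vector of length \code{n_pops}; each in (0, 1).
#' @param seed Integer seed; identical seeds give identical panels.
#' @param base_range Range from which base frequencies are drawn uniformly,
#'   bounded away from 0 and 1 (default \code{c(0.05, 0.95)}).
#' @param base_freqs Optional vector of base frequencies to use instead of
#'   drawing them (length \code{n_snps}); enables hierarchical drift by
#'   feeding one panel's population frequencies back in as the base.
#' @return An object of class \code{ancestral_panel}: a list with
#'   \code{base_freqs} (length M), \code{pop_freqs} (K x M matrix, clipped to
#'   \code{[1e-6, 1 - 1e-6]}) and \code{fst_params}.
#' @examples
#' pan <- simulate_panel(100, 2, c(0.05, 0.1), seed = 1)
#' dim(pan$pop_freqs)
#' @export
simulate_panel <- function(n_snps, n_pops, fst_params, seed,
                           base_range = c(0.05, 0.95), base_freqs = NULL) {
  if (n_snps < 1) stop("n_snps must be >= 1")
  if (length(fst_params) != n_pops)
    stop("fst_params must have one entry per population")
  if (any(!is.finite(fst_params)) || any(fst_params <= 0) || any(fst_params >= 1))
    stop("each fst_param must be finite and in (0, 1)")
  set.seed(seed)
  p <- if (is.null(base_freqs)) {
    stats::runif(n_snps, base_range[1], base_range[2])
  } else {
    if (length(base_freqs) != n_snps) stop("base_freqs must have length n_snps")
    pmin(pmax(base_freqs, 1e-6), 1 - 1e-6)
  }
  pop_freqs <- matrix(NA_real_, n_pops, n_snps)
  for (k in seq_len(n_pops)) {
    c_k <- fst_params[k]
    pop_freqs[k, ] <- stats::rbeta(n_snps, p * (1 - c_k) / c_k,
                                   (1 - p) * (1 - c_k) / c_k)
  }
  pop_freqs <- pmin(pmax(pop_freqs, 1e-6), 1 - 1e-6)
  structure(list(base_freqs = p, pop_freqs = pop_freqs,
                 fst_params = fst_params),
            class = "ancestral_panel")
}

#' Simulate admixed, possibly inbred genotypes with phased truth
#'
#' Each individual i carries ancestry proportions \code{Q_true[i, ]} over the
#' panel's populations, giving a per-SNP dose frequency
#' \code{p_im = sum_k Q[i,k] pop_freqs[k,m]}. Genotypes are built from two
#' haplotypes: the first allele is Bernoulli(p_im); with probability
#' \code{F_true[i]} the second allele copies the first (autozygosity),
#' otherwise it is an independent Bernoulli(p_im) draw. This yields genotype
#' probabilities \code{(1-p)^2 + Fp(1-p)}, \code{2p(1-p)(1-F)},
#' \code{p^2 + Fp(1-p)} - inbreeding as excess homozygosity over the
#' Hardy-Weinberg baseline. The truth haplotypes are retained so segment
#' scanners have an exact phased target.
#'
#' @param panel An \code{ancestral_panel}.
#' @param Q_true N x K row-stochastic matrix of true ancestry proportions.
#' @param F_true Per-individual inbreeding coefficient in [0, 1] (length N
#'   or scalar).
#' @param seed Integer seed.
#' @param sample_ids Optional sample ids (default \code{S0001, ...}).
#' @return A list with \code{genotypes} (N x M dosage matrix of the
#'   panel-frequency allele) and \code{truth}, an object of class
#'   \code{sim_truth} holding \code{Q_true}, \code{F_true}, the two phased
#'   haplotype matrices \code{hap1}/\code{hap2}, and the seed.
#' @export
simulate_genotypes <- function(panel, Q_true, F_true, seed, sample_ids = NULL) {
  stopifnot(inherits(panel, "ancestral_panel"))
  Q_true <- as.matrix(Q_true)
  if (ncol(Q_true) != nrow(panel$pop_freqs))
    stop("Q_true columns must match the panel's population count")
  if (any(abs(rowSums(Q_true) - 1) > 1e-9))
    stop("rows of Q_true must sum to 1")
  n <- nrow(Q_true)
  m <- ncol(panel$pop_freqs)
  F_true <- rep_len(F_true, n)
  if (any(F_true < 0 | F_true > 1))
    stop("F_true must lie in [0, 1] for generation")
  set.seed(seed)
  p <- Q_true %*% panel$pop_freqs                       # N x M dose freqs
  hap1 <- matrix(as.integer(stats::runif(n * m) < p), n, m)
  ## autozygosity mask: F_true varies by row, runif matrix fills by column
  copy <- matrix(stats::runif(n * m), n, m) < matrix(F_true, n, m)
  hap2_new <- matrix(as.integer(stats::runif(n * m) < p), n, m)
  hap2 <- ifelse(copy, hap1, hap2_new)
  g <- hap1 + hap2
  ids <- if (is.null(sample_ids)) sprintf("S%04d", seq_len(n)) else sample_ids
  snps <- sprintf("snp%06d", seq_len(m))
  dimnames(g) <- dimnames(hap1) <- dimnames(hap2) <- list(ids, snps)
  truth <- structure(list(Q_true = Q_true, F_true = F_true,
                          hap1 = hap1, hap2 = hap2,
                          planted_segments = empty_segments(),
                          surname_origin = NULL,
                          generations = NA_integer_, seed = seed),
                     class = "sim_truth")
  list(genotypes = g, truth = truth)
}

## Empty segment table shared by generator and scanners.
empty_segments <- function() {
  data.frame(kind = character(), carrier = character(), carrier2 = character(),
             chrom = character(), start_bp = integer(), end_bp = integer(),
             n_snps = integer(), cm_length = numeric(), truncated = logical(),
             stringsAsFactors = FALSE)
}

## rbind segment tables whose optional columns (cm_drawn) may differ.
bind_segments <- function(a, b) {
  if (!nrow(a)) return(b)
  if (!nrow(b)) return(a)
  cols <- union(names(a), names(b))
  for (cl in setdiff(cols, names(a))) a[[cl]] <- NA
  for (cl in setdiff(cols, names(b))) b[[cl]] <- NA
  rbind(a[cols], b[cols])
}

#' Build a regular synthetic marker map
#'
#' Markers are evenly spaced along \code{n_chrom} chromosomes at
#' \code{spacing_bp} with genetic positions at a constant
#' \code{cm_per_mb} centimorgans per megabase.
#'
#' @param n_snps Total marker count.
#' @param n_chrom Number of chromosomes the markers are spread over.
#' @param spacing_bp Physical distance between adjacent markers.
#' @param cm_per_mb Recombination rate (cM/Mb), default 1.
#' @return A data.frame with columns marker, chrom, bp, cM.
#' @export
make_marker_map <- function(n_snps, n_chrom = 4, spacing_bp = 25000,
                            cm_per_mb = 1) {
  per <- rep(n_snps %/% n_chrom, n_chrom)
  if (n_snps %% n_chrom) per[seq_len(n_snps %% n_chrom)] <-
      per[seq_len(n_snps %% n_chrom)] + 1L
  chrom <- rep(as.character(seq_len(n_chrom)), per)
  idx <- unlist(lapply(per, seq_len))
  bp <- as.integer(idx * spacing_bp)
  data.frame(marker = sprintf("snp%06d", seq_len(n_snps)), chrom = chrom,
             bp = bp, cM = bp * cm_per_mb * 1e-6, stringsAsFactors = FALSE)
}

#' Plant homozygous (ROH) or shared (IBD) segments with exponential lengths
#'
#' Segment genetic lengths follow Haldane's model for the descent of an
#' ancestral chromosome chunk over g meioses: Exponential with mean
#' \code{1/(2g)} Morgans, i.e. \code{100/(2g)} cM. \code{mode = "roh"}
#' overwrites the carrier's genotypes inside the interval with homozygous
#' calls (second haplotype copies the first); \code{mode = "ibd"} copies the
#' carrier's two haplotypes (hence genotypes) onto a second individual inside
#' the interval. Segments whose drawn length overruns the chromosome are
#' truncated at the chromosome end and flagged.
#'
#' @param genotypes N x M dosage matrix.
#' @param map Marker map (cM required, non-decreasing within chromosome).
#' @param g Generations since the common ancestor (>= 1).
#' @param mode "roh" or "ibd".
#' @param n_segments Number of segments to plant.
#' @param seed Integer seed.
#' @param haplotypes Optional list(hap1, hap2) of phased truth matrices; kept
#'   consistent with the planted genotypes and returned updated.
#' @return A list with updated \code{genotypes}, the planted \code{segments}
#'   table (chrom, start/end bp, n_snps, cm_length, truncated, carriers) and,
#'   if supplied, updated \code{haplotypes}.
#' @export
plant_segments <- function(genotypes, map, g, mode = c("roh", "ibd"),
                           n_segments, seed, haplotypes = NULL) {
  mode <- match.arg(mode)
  genotypes <- check_geno(genotypes)
  map <- check_map(map, require_cm = TRUE)
  if (g < 1) stop("g must be >= 1")
  bad <- tapply(map$cM, map$chrom, function(x) any(diff(x) <= 0))
  if (any(unlist(bad))) stop("map cM must be strictly increasing within chromosome")
  set.seed(seed)
  chroms <- unique(map$chrom)
  span <- vapply(chroms, function(ch) {
    x <- map$cM[map$chrom == ch]; max(x) - min(x)
  }, numeric(1))
  n <- nrow(genotypes)
  segs <- vector("list", n_segments)
  mean_cm <- 100 / (2 * g)
  for (s in seq_len(n_segments)) {
    ch <- sample(chroms, 1, prob = span)
    sub <- map[map$chrom == ch, ]
    len <- stats::rexp(1, rate = 1 / mean_cm)
    start_cm <- stats::runif(1, min(sub$cM), max(sub$cM))
    end_cm <- start_cm + len
    truncated <- end_cm > max(sub$cM)
    if (truncated) end_cm <- max(sub$cM)
    inside <- which(sub$cM >= start_cm & sub$cM <= end_cm)
    carrier <- sample(n, 1)
    carrier2 <- if (mode == "ibd") sample(setdiff(seq_len(n), carrier), 1) else NA
    if (length(inside)) {
      cols <- match(sub$marker[inside], colnames(genotypes))
      cols <- cols[!is.na(cols)]
      if (mode == "roh") {
        if (!is.null(haplotypes)) {
          haplotypes$hap2[carrier, cols] <- haplotypes$hap1[carrier, cols]
          genotypes[carrier, cols] <- 2L * haplotypes$hap1[carrier, cols]
        } else {
          het <- which(genotypes[carrier, cols] == 1L)
          genotypes[carrier, cols[het]] <-
            2L * as.integer(stats::runif(length(het)) < 0.5)
        }
      } else {
        genotypes[carrier2, cols] <- genotypes[carrier, cols]
        if (!is.null(haplotypes)) {
          haplotypes$hap1[carrier2, cols] <- haplotypes$hap1[carrier, cols]
          haplotypes$hap2[carrier2, cols] <- haplotypes$hap2[carrier, cols]
        }
      }
    }
    segs[[s]] <- data.frame(
      kind = mode, carrier = rownames(genotypes)[carrier],
      carrier2 = if (is.na(carrier2)) NA_character_ else rownames(genotypes)[carrier2],
      chrom = ch,
      start_bp = if (length(inside)) min(sub$bp[inside]) else NA_integer_,
      end_bp = if (length(inside)) max(sub$bp[inside]) else NA_integer_,
      n_snps = length(inside), cm_length = end_cm - start_cm,
      cm_drawn = len, truncated = truncated, stringsAsFactors = FALSE)
  }
  out <- list(genotypes = genotypes, segments = do.call(rbind, segs))
  if (!is.null(haplotypes)) out$haplotypes <- haplotypes
  out
}

#' Assign surname-origin labels concordant with genetic groups
#'
#' With probability \code{concordance} an individual's surname origin equals
#' its group's canonical origin; otherwise the origin is drawn uniformly from
#' the remaining origins (which may include "Unclassified").
#'
#' @param group_of Character/factor vector of group labels.
#' @param concordance Probability in [0, 1] of the canonical origin.
#' @param origins Character vector of possible origins (non-empty).
#' @param seed Integer seed.
#' @param canonical Optional named character vector mapping each group to its
#'   canonical origin; default maps the i-th distinct group to origins[i].
#' @return Character vector of surname origins, same length as group_of.
#' @export
assign_surnames <- function(group_of, concordance, origins, seed,
                            canonical = NULL) {
  if (!length(origins)) stop("origins must be non-empty")
  if (concordance < 0 || concordance > 1) stop("concordance must be in [0, 1]")
  groups <- unique(as.character(group_of))
  if (is.null(canonical)) {
    if (length(origins) < length(groups))
      stop("need at least one origin per group for the default canonical map")
    canonical <- stats::setNames(origins[seq_along(groups)], groups)
  }
  set.seed(seed)
  vapply(as.character(group_of), function(gr) {
    canon <- canonical[[gr]]
    if (stats::runif(1) < concordance) canon
    else if (length(origins) == 1L) canon
    else sample(setdiff(origins, canon), 1)
  }, character(1), USE.NAMES = FALSE)
}

## Default study conditions: three groups of 138/63/72 individuals admixed
## over six ancestral components, group-mean ancestry mirroring the reported
## composition (Arabian 69% in the second group, African 17% in the third,
## West Asian 56% and European 12% in the first), group mean inbreeding
## 0.025742 / 0.04226 / 0.00274.
default_components <- function() {
  c("Arabian", "African", "Brahui", "Druze", "Kalash", "European")
}

#' @rdname simulate_cohort
#' @export
default_group_ancestry <- function() {
  comp <- default_components()
  A <- rbind(
    Kuwait_P = c(Arabian = 0.27, African = 0.05, Brahui = 0.20,
                 Druze = 0.20, Kalash = 0.16, European = 0.12),
    Kuwait_S = c(Arabian = 0.69, African = 0.03, Brahui = 0.08,
                 Druze = 0.10, Kalash = 0.05, European = 0.05),
    Kuwait_B = c(Arabian = 0.40, African = 0.17, Brahui = 0.12,
                 Druze = 0.15, Kalash = 0.08, European = 0.08))
  A[, comp]
}

#' Simulate the full demonstration cohort
#'
#' Generates a three-group admixed cohort (default sizes 138/63/72) over six
#' Balding-Nichols ancestral panels at continental-scale differentiation,
#' with group-specific inbreeding, optional one-hot reference individuals
#' per ancestral population (emulating a diversity-panel merge), planted
#' ROH/IBD segments under Haldane's exponential length model, and
#' concordant-but-noisy surname labels.
#'
#' @param group_sizes Integer vector of group sizes.
#' @param group_ancestry Groups x components row-stochastic matrix of mean
#'   ancestry; default \code{default_group_ancestry()}.
#' @param group_f Mean inbreeding coefficient per group; individual F values
#'   are Exponential with these means (clipped at 0.5).
#' @param fst_params Differentiation of each ancestral panel.
#' @param n_snps Marker count.
#' @param dirichlet_conc Concentration of individual ancestry around the
#'   group mean (higher = tighter); the group mean is preserved exactly in
#'   expectation.
#' @param n_ref_per_pop Reference (unadmixed, F = 0) individuals per
#'   ancestral population appended after the cohort; 0 to disable.
#' @param generations Generations since common ancestor for planted segments.
#' @param n_roh,n_ibd Number of planted ROH / IBD segments (0 disables).
#' @param concordance Surname-group concordance probability (default 0.7).
#' @param map Optional marker map; default \code{make_marker_map(n_snps)}.
#' @param seed Integer seed.
#' @return A list with \code{genotypes}, \code{map}, \code{truth}
#'   (class \code{sim_truth}, including group labels, surname origins and
#'   planted segments), \code{panel}, and \code{ref_ids}.
#' @export
simulate_cohort <- function(group_sizes = c(138, 63, 72),
                            group_ancestry = default_group_ancestry(),
                            group_f = c(0.025742, 0.04226, 0.00274),
                            fst_params = c(0.08, 0.15, 0.08, 0.08, 0.10, 0.10),
                            n_snps = 5000,
                            dirichlet_conc = 50,
                            n_ref_per_pop = 0,
                            generations = 6,
                            n_roh = 0, n_ibd = 0,
                            concordance = 0.7,
                            map = NULL,
                            seed = 1) {
  K <- ncol(group_ancestry)
  stopifnot(length(group_sizes) == nrow(group_ancestry),
            length(group_f) == length(group_sizes),
            length(fst_params) == K)
  panel <- simulate_panel(n_snps, K, fst_params, seed = derive_seed(seed, 1))
  set.seed(derive_seed(seed, 2))
  groups <- rep(rownames(group_ancestry), group_sizes)
  Q <- do.call(rbind, lapply(seq_along(group_sizes), function(i) {
    qi <- rdirichlet(group_sizes[i], group_ancestry[i, ] * dirichlet_conc)
    ## the stated group-level mixes are the study conditions: rescale the
    ## draws (IPF on the simplex) so the realised group mean matches exactly
    for (it in 1:100) {
      qi <- qi * rep(group_ancestry[i, ] / colMeans(qi), each = nrow(qi))
      qi <- qi / rowSums(qi)
      if (max(abs(colMeans(qi) - group_ancestry[i, ])) < 1e-9) break
    }
    qi
  }))
  Fv <- unlist(lapply(seq_along(group_sizes), function(i) {
    pmin(stats::rexp(group_sizes[i], rate = 1 / group_f[i]), 0.5)
  }))
  if (n_ref_per_pop > 0) {
    Qref <- diag(K)[rep(seq_len(K), each = n_ref_per_pop), , drop = FALSE]
    Q <- rbind(Q, Qref)
    Fv <- c(Fv, rep(0, n_ref_per_pop * K))
    groups <- c(groups, paste0("REF_", rep(colnames(group_ancestry),
                                           each = n_ref_per_pop)))
  }
  colnames(Q) <- colnames(group_ancestry)
  sim <- simulate_genotypes(panel, Q, Fv, seed = derive_seed(seed, 3))
  g <- sim$genotypes
  truth <- sim$truth
  truth$group <- groups
  ref_ids <- rownames(g)[grepl("^REF_", groups)]
  if (is.null(map)) map <- make_marker_map(n_snps)
  segs <- empty_segments()
  hap <- list(hap1 = truth$hap1, hap2 = truth$hap2)
  if (n_roh > 0) {
    pr <- plant_segments(g, map, generations, "roh", n_roh,
                         seed = derive_seed(seed, 4), haplotypes = hap)
    g <- pr$genotypes; hap <- pr$haplotypes; segs <- bind_segments(segs, pr$segments)
  }
  if (n_ibd > 0) {
    pi <- plant_segments(g, map, generations, "ibd", n_ibd,
                         seed = derive_seed(seed, 5), haplotypes = hap)
    g <- pi$genotypes; hap <- pi$haplotypes; segs <- bind_segments(segs, pi$segments)
  }
  truth$hap1 <- hap$hap1; truth$hap2 <- hap$hap2
  truth$planted_segments <- segs
  truth$generations <- generations
  cohort_mask <- !grepl("^REF_", groups)
  origins <- c("Persian", "Saudi tribe", "Bedouin", "Unclassified")
  canonical <- stats::setNames(origins[seq_len(nrow(group_ancestry))],
                               rownames(group_ancestry))
  surn <- rep(NA_character_, length(groups))
  surn[cohort_mask] <- assign_surnames(groups[cohort_mask], concordance,
                                       origins, seed = derive_seed(seed, 6),
                                       canonical = canonical)
  truth$surname_origin <- surn
  truth$seed <- seed
  list(genotypes = g, map = map, truth = truth, panel = panel,
       ref_ids = ref_ids)
}

#' Write a simulated cohort's ground truth to TSV files
#'
#' Writes a truth table (sample_id, group, F_true, surname_origin) and a
#' BED-like planted-segment table (chrom, start_bp, end_bp, carriers, cM).
#'
#' @param cohort Result of \code{simulate_cohort}.
#' @param truth_path,segments_path Output TSV paths.
#' @return Invisibly, the two paths.
#' @export
write_truth <- function(cohort, truth_path, segments_path) {
  tr <- cohort$truth
  df <- data.frame(sample_id = rownames(cohort$genotypes),
                   group = tr$group, F_true = tr$F_true,
                   surname_origin = tr$surname_origin,
                   stringsAsFactors = FALSE)
  utils::write.table(df, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(tr$planted_segments, segments_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(truth_path, segments_path))
}
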