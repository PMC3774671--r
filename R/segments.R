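## ROH scanning on genotypes, deterministic IBD detection on phased
## haplotypes, per-carrier segment summaries, and the exponential
## generations-to-common-ancestor estimator.

## Maximal runs over a marker block satisfying sliding count constraints.
## feas_het/feas_mis are 0/1 vectors; returns matrix of (start, end) indices
## of all maximal feasible windows (<= max_het hets, <= max_mis missing).
maximal_runs <- function(het, mis, max_het, max_mis) {
  n <- length(het)
  if (n == 0) return(matrix(integer(0), 0, 2))
  ch <- 0L; cm <- 0L
  R <- integer(n)   # R[l] = max feasible right end starting at l
  r <- 0L
  for (ll in seq_len(n)) {
    if (r < ll - 1L) { r <- ll - 1L; ch <- 0L; cm <- 0L }
    while (r < n && ch + het[r + 1L] <= max_het && cm + mis[r + 1L] <= max_mis) {
      r <- r + 1L
      ch <- ch + het[r]; cm <- cm + mis[r]
    }
    R[ll] <- r
    ch <- ch - het[ll]; cm <- cm - mis[ll]
  }
  keep <- which(c(TRUE, R[-1] > R[-n]))
  runs <- cbind(start = keep, end = R[keep])
  runs[runs[, 2] >= runs[, 1], , drop = FALSE]
}

#' Scan for runs of homozygosity
#'
#' Per individual and chromosome, finds maximal marker runs containing at
#' most \code{max_het} heterozygous and \code{max_mis} missing calls, with
#' no inter-marker gap above \code{max_gap_bp}; runs are reported only if
#' they span at least \code{min_bp} and contain at least \code{min_snps}
#' markers. Overlapping candidate runs are resolved left-to-right so one
#' individual's reported segments never overlap. Defaults follow the
#' standard chip-density parameterisation: 500 kb, 25 SNPs, 1 heterozygote,
#' 5 missing, 100 kb gap.
#'
#' @param g N x M dosage matrix.
#' @param map Marker map with cM (markers sorted by chrom, bp).
#' @param min_bp Minimum physical span (default 5e5).
#' @param min_snps Minimum marker count (default 25).
#' @param max_het Heterozygote allowance (default 1).
#' @param max_mis Missing-call allowance (default 5).
#' @param max_gap_bp Maximum gap between consecutive markers (default 1e5).
#' @param exclude Optional data.frame(chrom, start_bp, end_bp) of intervals
#'   (e.g. centromeres) whose markers are dropped before scanning.
#' @return Segment data.frame (kind = "roh", carrier, chrom, start_bp,
#'   end_bp, n_snps, cm_length).
#' @export
roh_scan <- function(g, map, min_bp = 5e5, min_snps = 25, max_het = 1,
                     max_mis = 5, max_gap_bp = 1e5, exclude = NULL) {
  g <- check_geno(g)
  map <- check_map(map, require_cm = TRUE)
  if (!is.null(exclude)) {
    drop <- rep(FALSE, nrow(map))
    for (r in seq_len(nrow(exclude)))
      drop <- drop | (map$chrom == exclude$chrom[r] &
                        map$bp >= exclude$start_bp[r] &
                        map$bp <= exclude$end_bp[r])
    map <- map[!drop, , drop = FALSE]
    g <- g[, !drop, drop = FALSE]
  }
  segs <- list(); k <- 1
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    if (any(diff(map$bp[idx]) <= 0)) stop("map not sorted by bp on chromosome ", ch)
    gap_break <- which(diff(map$bp[idx]) > max_gap_bp)
    blocks <- split(idx, cumsum(seq_along(idx) %in% (gap_break + 1)))
    for (blk in blocks) {
      if (length(blk) < min_snps) next
      bp <- map$bp[blk]; cm <- map$cM[blk]
      for (i in seq_len(nrow(g))) {
        x <- g[i, blk]
        het <- as.integer(!is.na(x) & x == 1)
        mis <- as.integer(is.na(x))
        runs <- maximal_runs(het, mis, max_het, max_mis)
        if (!nrow(runs)) next
        span <- bp[runs[, 2]] - bp[runs[, 1]]
        nsnp <- runs[, 2] - runs[, 1] + 1L
        ok <- span >= min_bp & nsnp >= min_snps
        runs <- runs[ok, , drop = FALSE]
        if (!nrow(runs)) next
        last_end <- 0L
        for (r in seq_len(nrow(runs))) {
          ## left-to-right non-overlap: trim a run that overhangs the
          ## previous one and re-check the reporting thresholds
          s0 <- max(runs[r, 1], last_end + 1L)
          if (s0 > runs[r, 2]) next
          if (bp[runs[r, 2]] - bp[s0] < min_bp ||
              runs[r, 2] - s0 + 1L < min_snps) next
          runs[r, 1] <- s0
          last_end <- runs[r, 2]
          segs[[k]] <- data.frame(
            kind = "roh", carrier = rownames(g)[i], carrier2 = NA_character_,
            chrom = ch, start_bp = bp[runs[r, 1]], end_bp = bp[runs[r, 2]],
            n_snps = runs[r, 2] - runs[r, 1] + 1L,
            cm_length = cm[runs[r, 2]] - cm[runs[r, 1]],
            truncated = FALSE, stringsAsFactors = FALSE)
          k <- k + 1
        }
      }
    }
  }
  if (length(segs)) do.call(rbind, segs) else empty_segments()
}

## Merge runs of exact haplotype match across isolated mismatches while the
## mismatch rate stays within 1 per 100 SNPs.
match_runs <- function(match, rate = 0.01) {
  n <- length(match)
  out <- list()
  r <- rle(match)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  seg_start <- NA_integer_; seg_end <- NA_integer_; mm <- 0L
  flush <- function() {
    if (!is.na(seg_start)) out[[length(out) + 1]] <<- c(seg_start, seg_end)
  }
  for (i in seq_along(r$values)) {
    if (r$values[i]) {
      if (is.na(seg_start)) { seg_start <- starts[i]; seg_end <- ends[i]; mm <- 0L }
      else { seg_end <- ends[i] }
    } else {
      len_if <- if (is.na(seg_start)) 0L else ends[i] - seg_start + 1L
      if (!is.na(seg_start) && r$lengths[i] == 1L &&
          (mm + 1L) <= floor(len_if * rate)) {
        mm <- mm + 1L          # absorb a single mismatch
      } else {
        flush(); seg_start <- NA_integer_; mm <- 0L
      }
    }
  }
  flush()
  if (length(out)) do.call(rbind, out) else matrix(integer(0), 0, 2)
}

#' Detect IBD segments between two phased individuals
#'
#' Deterministic scan on phased haplotypes: maximal marker intervals where
#' at least one haplotype of individual A exactly matches one of B, allowing
#' up to one mismatch per 100 SNPs for genotyping error. Overlapping
#' intervals from the four haplotype pairings are merged. Intervals of
#' genetic length at least \code{min_cm} are reported.
#'
#' @param hapA,hapB 2 x M 0/1 matrices (the two phased haplotypes of each
#'   individual).
#' @param map Marker map with cM.
#' @param min_cm Minimum genetic length in cM (default 1).
#' @param ids Character vector of the two carrier ids.
#' @return Segment data.frame (kind = "ibd").
#' @export
ibd_scan <- function(hapA, hapB, map, min_cm = 1.0,
                     ids = c("A", "B")) {
  hapA <- as.matrix(hapA); hapB <- as.matrix(hapB)
  if (ncol(hapA) != ncol(hapB) || ncol(hapA) != nrow(map))
    stop("haplotype and map lengths differ")
  map <- check_map(map, require_cm = TRUE)
  segs <- list(); k <- 1
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    bp <- map$bp[idx]; cm <- map$cM[idx]
    ## a segment must be carried by one haplotype pairing; keep each
    ## pairing's runs that already reach min_cm, then merge overlaps so the
    ## same tract found on both haplotypes is reported once
    iv <- matrix(integer(0), 0, 2)
    for (a in 1:2) for (b in 1:2) {
      m <- hapA[a, idx] == hapB[b, idx]
      runs <- match_runs(m)
      if (nrow(runs)) {
        long <- cm[runs[, 2]] - cm[runs[, 1]] >= min_cm
        iv <- rbind(iv, runs[long, , drop = FALSE])
      }
    }
    if (!nrow(iv)) next
    iv <- iv[order(iv[, 1], iv[, 2]), , drop = FALSE]
    merged <- list(iv[1, ])
    for (r in seq_len(nrow(iv))[-1]) {
      last <- merged[[length(merged)]]
      if (iv[r, 1] <= last[2])
        merged[[length(merged)]] <- c(last[1], max(last[2], iv[r, 2]))
      else merged[[length(merged) + 1]] <- iv[r, ]
    }
    for (mv in merged) {
      len <- cm[mv[2]] - cm[mv[1]]
      if (len >= min_cm) {
        segs[[k]] <- data.frame(
          kind = "ibd", carrier = ids[1], carrier2 = ids[2], chrom = ch,
          start_bp = bp[mv[1]], end_bp = bp[mv[2]],
          n_snps = mv[2] - mv[1] + 1L, cm_length = len, truncated = FALSE,
          stringsAsFactors = FALSE)
        k <- k + 1
      }
    }
  }
  if (length(segs)) do.call(rbind, segs) else empty_segments()
}

#' Scan all sample pairs for IBD segments
#'
#' @param hap1,hap2 N x M phased haplotype matrices (rows = individuals).
#' @param map Marker map with cM.
#' @param min_cm Minimum genetic length (default 1 cM).
#' @return Combined segment data.frame over all unordered pairs.
#' @export
ibd_scan_all <- function(hap1, hap2, map, min_cm = 1.0) {
  n <- nrow(hap1)
  ids <- rownames(hap1)
  if (is.null(ids)) ids <- sprintf("S%04d", seq_len(n))
  out <- list(); k <- 1
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      s <- ibd_scan(rbind(hap1[i, ], hap2[i, ]), rbind(hap1[j, ], hap2[j, ]),
                    map, min_cm = min_cm, ids = ids[c(i, j)])
      if (nrow(s)) { out[[k]] <- s; k <- k + 1 }
    }
  }
  if (length(out)) do.call(rbind, out) else empty_segments()
}

#' Summarise a segment set per carrier and cohort-wide
#'
#' Per carrier: total cM, number of segments, counts of segments >= 2 cM and
#' >= 10 cM, longest segment, and F_seg = total cM / genome_cm. Cohort-wide
#' (for IBD sets): the fraction of individuals sharing at least one segment
#' of >= 10 cM with at least one other individual, expressed as a
#' percentage either truncated (default, matching printed two-decimal
#' truncation conventions) or rounded to 2 decimals.
#'
#' @param segs Segment data.frame.
#' @param genome_cm Total genome genetic length in cM (> 0).
#' @param cohort_ids Optional full id set for the cohort fraction (ids with
#'   no segments count in the denominator).
#' @param pct_convention "truncate" or "round".
#' @return list(per_carrier = data.frame, n_segments, frac_ge2,
#'   pct_with_ge10).
#' @export
summarize_segments <- function(segs, genome_cm, cohort_ids = NULL,
                               pct_convention = c("truncate", "round")) {
  pct_convention <- match.arg(pct_convention)
  if (genome_cm <= 0) stop("genome_cm must be > 0")
  if (!nrow(segs)) {
    return(list(per_carrier = data.frame(), n_segments = 0L,
                frac_ge2 = NA_real_, pct_with_ge10 = NA_real_))
  }
  carriers <- unique(c(segs$carrier, stats::na.omit(segs$carrier2)))
  per <- do.call(rbind, lapply(carriers, function(id) {
    s <- segs[segs$carrier == id |
                (!is.na(segs$carrier2) & segs$carrier2 == id), , drop = FALSE]
    data.frame(carrier = id, total_cm = sum(s$cm_length),
               n_segments = nrow(s),
               n_ge2 = sum(s$cm_length >= 2), n_ge10 = sum(s$cm_length >= 10),
               longest_cm = max(s$cm_length),
               f_seg = sum(s$cm_length) / genome_cm,
               stringsAsFactors = FALSE)
  }))
  frac_ge2 <- sum(segs$cm_length >= 2) / nrow(segs)
  ids <- if (is.null(cohort_ids)) carriers else cohort_ids
  with10 <- per$carrier[per$n_ge10 >= 1]
  pct <- length(intersect(ids, with10)) / length(ids) * 100
  pct <- if (pct_convention == "truncate") trunc_digits(pct, 2)
  else round_half_up(pct, 2)
  list(per_carrier = per, n_segments = nrow(segs), frac_ge2 = frac_ge2,
       pct_with_ge10 = pct)
}

#' Estimate generations since the common ancestor from segment lengths
#'
#' Under Haldane's recombination model the genetic length of a segment
#' inherited intact from an ancestor g generations back is Exponential with
#' mean 1/(2g) Morgans = 100/(2g) cM. Detection truncates at \code{min_cm};
#' by the memorylessness of the exponential, lengths minus \code{min_cm}
#' are Exponential with the same mean, so the method-of-moments estimate is
#' g-hat = 100 / (2 (mean(lengths) - min_cm)).
#'
#' @param lengths_cm Segment lengths in cM (all >= min_cm; n >= 10).
#' @param min_cm Detection threshold the lengths were subject to (default 1).
#' @return list(g = rounded integer estimate, g_raw = raw estimate,
#'   mean_excess_cm).
#' @export
fit_generations <- function(lengths_cm, min_cm = 1.0) {
  lengths_cm <- lengths_cm[!is.na(lengths_cm)]
  if (length(lengths_cm) < 10) stop("need at least 10 segment lengths")
  if (any(lengths_cm < min_cm)) stop("lengths below the stated min_cm")
  ex <- mean(lengths_cm) - min_cm
  if (ex <= 0) stop("mean length does not exceed min_cm; estimate undefined")
  g_raw <- 100 / (2 * ex)
  list(g = as.integer(round(g_raw)), g_raw = g_raw, mean_excess_cm = ex)
}
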