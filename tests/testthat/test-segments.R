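test_that("ROH scanner honours all four run constraints", {
  map <- make_marker_map(400, n_chrom = 1, spacing_bp = 25000)

  # an all-heterozygous individual carries no runs
  g <- matrix(1L, 1, 400, dimnames = list("HET", map$marker))
  expect_equal(nrow(roh_scan(g, map)), 0L)

  # a planted homozygous tract is recovered as one covering segment
  set.seed(91)
  x <- sample(c(0L, 1L, 2L), 400, replace = TRUE,
              prob = c(0.3, 0.45, 0.25))
  x[100:160] <- sample(c(0L, 2L), 61, replace = TRUE)   # ~1.5 Mb, 61 SNPs
  g2 <- matrix(x, 1, 400, dimnames = list("A", map$marker))
  segs <- roh_scan(g2, map)
  expect_gte(nrow(segs), 1)
  planted <- c(map$bp[100], map$bp[160])
  overlap <- max(0, min(segs$end_bp, planted[2]) -
                   max(segs$start_bp, planted[1]))
  expect_gte(overlap / diff(planted), 0.9)

  # every reported segment satisfies the thresholds (post-hoc invariant)
  expect_true(all(segs$end_bp - segs$start_bp >= 5e5))
  expect_true(all(segs$n_snps >= 25))

  # segments of one individual never overlap
  if (nrow(segs) > 1) {
    o <- order(segs$start_bp)
    expect_true(all(segs$start_bp[o][-1] > segs$end_bp[o][-nrow(segs)]))
  }
})

test_that("two interior heterozygotes split a tract as hand-traced", {
  map <- make_marker_map(200, n_chrom = 1, spacing_bp = 25000)
  # homozygous background with hets at markers 60 and 120
  x <- rep(2L, 200)
  x[c(60, 120)] <- 1L
  g <- matrix(x, 1, 200, dimnames = list("A", map$marker))
  segs <- roh_scan(g, map)
  # hand trace: with a 1-het allowance, the left-to-right maximal runs are
  # [1, 119] (containing the het at 60) and [120, 200]; both pass 500 kb/25
  expect_equal(nrow(segs), 2L)
  expect_equal(segs$start_bp[1], map$bp[1])
  expect_equal(segs$end_bp[1], map$bp[119])
  expect_equal(segs$start_bp[2], map$bp[120])
  expect_equal(segs$end_bp[2], map$bp[200])

  # with a 100 kb gap rule, a 150 kb marker gap breaks any run
  map2 <- map
  map2$bp[101:200] <- map2$bp[101:200] + 150000L
  g3 <- matrix(rep(0L, 200), 1, 200, dimnames = list("A", map2$marker))
  segs3 <- roh_scan(g3, map2)
  expect_equal(nrow(segs3), 2L)
})

test_that("IBD scanner finds planted shared haplotypes with sharp bounds", {
  map <- make_marker_map(1200, n_chrom = 1, spacing_bp = 25000)  # 30 cM
  pan <- simulate_panel(1200, 1, 0.05, seed = 92)
  sim <- simulate_genotypes(pan, matrix(1, 2, 1), 0, seed = 93)
  hapA <- rbind(sim$truth$hap1[1, ], sim$truth$hap2[1, ])
  hapB <- rbind(sim$truth$hap1[2, ], sim$truth$hap2[2, ])

  # identical individuals: one segment spanning the chromosome
  whole <- ibd_scan(hapA, hapA, map, min_cm = 1)
  expect_equal(nrow(whole), 1L)
  expect_equal(whole$start_bp, map$bp[1])
  expect_equal(whole$end_bp, map$bp[1200])

  # a planted 12 cM copy is recovered with < 0.5 cM boundary error
  idx <- 300:780   # 12 cM at 25 kb per marker, 1 cM/Mb
  hapB2 <- hapB
  hapB2[1, idx] <- hapA[1, idx]
  segs <- ibd_scan(hapA, hapB2, map, min_cm = 1)
  expect_equal(nrow(segs), 1L)
  expect_lt(abs(segs$start_bp * 1e-6 - map$cM[300]), 0.5)
  expect_lt(abs(segs$cm_length - 12), 1)

  # symmetry in the two carriers
  rev <- ibd_scan(hapB2, hapA, map, min_cm = 1)
  expect_equal(rev$start_bp, segs$start_bp)
  expect_equal(rev$end_bp, segs$end_bp)

  # independent pairs at min_cm = 10: essentially never a hit
  hits <- 0
  for (r in 1:10) {
    s2 <- simulate_genotypes(pan, matrix(1, 2, 1), 0, seed = 200 + r)
    hA <- rbind(s2$truth$hap1[1, ], s2$truth$hap2[1, ])
    hB <- rbind(s2$truth$hap1[2, ], s2$truth$hap2[2, ])
    hits <- hits + nrow(ibd_scan(hA, hB, map, min_cm = 10))
  }
  expect_lte(hits, 1)
})

test_that("segment summaries follow the printed conventions", {
  seg1 <- data.frame(kind = "ibd", carrier = "a", carrier2 = "b",
                     chrom = "1", start_bp = 1L, end_bp = 2L, n_snps = 10L,
                     cm_length = 10, truncated = FALSE)
  s <- summarize_segments(seg1, genome_cm = 100)
  expect_equal(s$per_carrier$f_seg, c(0.1, 0.1))   # both carriers share it

  # 252 of 273 individuals flagged prints as 92.30 (truncated, not rounded)
  ids <- sprintf("P%03d", 1:273)
  segs <- do.call(rbind, lapply(1:126, function(i)
    data.frame(kind = "ibd", carrier = ids[2 * i - 1], carrier2 = ids[2 * i],
               chrom = "1", start_bp = 1L, end_bp = 2L, n_snps = 5L,
               cm_length = 11, truncated = FALSE)))
  sc <- summarize_segments(segs, genome_cm = 3500, cohort_ids = ids)
  expect_equal(sc$pct_with_ge10, trunc(252 / 273 * 10000) / 100)
  expect_equal(sc$pct_with_ge10, 92.30)

  # totals are additive over disjoint segment sets
  sa <- summarize_segments(seg1, 100)
  twice <- summarize_segments(rbind(seg1, seg1), 100)
  expect_equal(twice$per_carrier$total_cm, 2 * sa$per_carrier$total_cm)
  expect_equal(summarize_segments(seg1[0, ], 100)$n_segments, 0L)
})

test_that("generations estimator inverts Haldane's exponential model", {
  # untruncated mean 25 cM: g = 100 / (2 * 25) = 2 exactly
  lens <- rep(25, 20)
  expect_equal(fit_generations(lens, min_cm = 0)$g_raw, 2)

  # 2000 draws at the 6-generation mean round back to 6
  set.seed(94)
  draws <- stats::rexp(2000, rate = 12 / 100)
  expect_equal(fit_generations(draws, min_cm = 0)$g, 6L)

  # memorylessness: truncation at 1 cM leaves the estimate unchanged
  tr <- draws[draws >= 1]
  expect_lt(abs(fit_generations(tr, min_cm = 1)$g_raw -
                  fit_generations(draws, min_cm = 0)$g_raw), 0.5)

  # rounding recovery across the generation range seen in such cohorts
  for (gg in c(4, 6, 9)) {
    d <- stats::rexp(2000, rate = 2 * gg / 100)
    expect_lte(abs(fit_generations(d, min_cm = 0)$g - gg), 1)
  }

  expect_error(fit_generations(rep(2, 5), min_cm = 0), "at least 10")
  expect_error(fit_generations(rep(1, 20), min_cm = 1), "undefined")
})
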