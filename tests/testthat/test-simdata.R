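test_that("Balding-Nichols panel matches the Beta moments", {
  # Var(p_k) = c p (1-p): at c = 0.1, p = 0.5 the variance is 0.025
  pan <- simulate_panel(1e5, 1, 0.1, seed = 3,
                        base_freqs = rep(0.5, 1e5))
  v <- stats::var(pan$pop_freqs[1, ])
  expect_lt(abs(v - 0.025), 0.001)
  expect_lt(abs(mean(pan$pop_freqs[1, ]) - 0.5), 0.005)

  # c -> 0 limit: population frequencies collapse onto the base frequencies
  pan0 <- simulate_panel(5000, 1, 1e-5, seed = 4)
  expect_lt(max(abs(pan0$pop_freqs[1, ] - pan0$base_freqs)), 0.05)

  # determinism
  a <- simulate_panel(500, 2, c(0.05, 0.2), seed = 9)
  b <- simulate_panel(500, 2, c(0.05, 0.2), seed = 9)
  expect_identical(a, b)

  expect_error(simulate_panel(100, 1, 1.2, seed = 1), "fst_param")
  expect_error(simulate_panel(100, 1, NaN, seed = 1), "fst_param")
})

test_that("genotype generator follows the inbreeding-adjusted HW law", {
  pan <- simulate_panel(10000, 2, c(0.1, 0.1), seed = 11)
  Q <- rbind(c(1, 0), c(1, 0), c(0.5, 0.5), c(1, 0))
  sim <- simulate_genotypes(pan, Q, c(1, 0, 0, 0.3), seed = 12)
  g <- sim$genotypes

  # F = 1: no heterozygous calls at all
  expect_equal(sum(g[1, ] == 1), 0)

  # genotypes equal the sum of the retained truth haplotypes
  expect_equal(g, sim$truth$hap1 + sim$truth$hap2)

  # one-hot individual at F = 0: genotype class totals match pop 1's HW law
  p <- pan$pop_freqs[1, ]
  o_het <- sum(g[2, ] == 1)
  e_het <- sum(2 * p * (1 - p))
  sd_het <- sqrt(sum(2 * p * (1 - p) * (1 - 2 * p * (1 - p))))
  expect_lt(abs(o_het - e_het) / sd_het, 4)
  o_hom <- sum(g[2, ] == 2)
  e_hom <- sum(p^2)
  expect_lt(abs(o_hom - e_hom) / sqrt(sum(p^2 * (1 - p^2))), 4)

  # F = 0.3 suppresses heterozygosity by the factor (1 - F)
  o_het_f <- sum(g[4, ] == 1)
  expect_lt(abs(o_het_f - 0.7 * e_het) / sd_het, 4)

  # F = 0 at p = 0.5: het fraction about one half
  pan5 <- simulate_panel(5000, 1, 0.01, seed = 5, base_freqs = rep(0.5, 5000))
  pan5$pop_freqs[1, ] <- 0.5
  s5 <- simulate_genotypes(pan5, matrix(1, 1, 1), 0, seed = 6)
  expect_lt(abs(mean(s5$genotypes == 1) - 0.5), 0.03)

  expect_error(simulate_genotypes(pan, matrix(1, 2, 1), 0, seed = 1),
               "population count")
})

test_that("planted segment lengths follow the Haldane exponential model", {
  map <- make_marker_map(4000, n_chrom = 4, spacing_bp = 25000)
  g <- matrix(1L, 4, 4000,
              dimnames = list(paste0("S", 1:4), map$marker))

  # g generations => mean length 100 / (2g) cM; KS test on the drawn lengths
  pl <- plant_segments(g, map, g = 6, mode = "roh", n_segments = 2000,
                       seed = 21)
  expect_equal(nrow(pl$segments), 2000)
  ks <- stats::ks.test(pl$segments$cm_drawn, "pexp", rate = 12 / 100)
  expect_gt(ks$p.value, 0.01)
  expect_lt(abs(mean(pl$segments$cm_drawn) - 100 / 12), 0.5)

  # g = 50: mean 1 cM, exponential tail beyond 10 cM is ~ e^-10
  pl50 <- plant_segments(g, map, g = 50, mode = "roh", n_segments = 2000,
                         seed = 22)
  expect_lte(sum(pl50$segments$cm_drawn >= 10), 2)

  # every marker inside a planted ROH interval is non-heterozygous
  one <- plant_segments(g, map, g = 4, mode = "roh", n_segments = 20,
                        seed = 23)
  for (s in seq_len(nrow(one$segments))) {
    seg <- one$segments[s, ]
    if (seg$n_snps == 0) next
    cols <- map$marker[map$chrom == seg$chrom &
                         map$bp >= seg$start_bp & map$bp <= seg$end_bp]
    expect_false(any(one$genotypes[seg$carrier, cols] == 1L))
  }

  # ibd mode copies the carrier's genotypes onto the second carrier
  two <- plant_segments(g, map, g = 4, mode = "ibd", n_segments = 5,
                        seed = 24)
  for (s in seq_len(nrow(two$segments))) {
    seg <- two$segments[s, ]
    if (seg$n_snps == 0) next
    cols <- map$marker[map$chrom == seg$chrom &
                         map$bp >= seg$start_bp & map$bp <= seg$end_bp]
    expect_equal(two$genotypes[seg$carrier, cols],
                 two$genotypes[seg$carrier2, cols])
  }

  # truncation at the chromosome end is flagged
  short_map <- make_marker_map(100, n_chrom = 1, spacing_bp = 25000)
  pls <- plant_segments(g[, 1:100], short_map, g = 2, mode = "roh",
                        n_segments = 50, seed = 25)
  expect_true(any(pls$segments$truncated))
  expect_true(all(pls$segments$cm_length <= max(short_map$cM)))
})

test_that("surname assignment is concordant at the requested rate", {
  grp <- rep(c("A", "B", "C"), each = 100)
  orig <- c("oa", "ob", "oc", "Unclassified")

  # concordance 1: contingency table is diagonal
  s1 <- assign_surnames(grp, 1, orig, seed = 31)
  expect_equal(unname(s1[grp == "A"]), rep("oa", 100))
  expect_equal(unname(table(grp, s1)["B", "ob"]), 100)

  # concordance 0.6: expected diagonal count 60 per group (binomial CI)
  s6 <- assign_surnames(grp, 0.6, orig, seed = 32)
  canon <- c(A = "oa", B = "ob", C = "oc")
  for (gname in names(canon)) {
    d <- sum(s6[grp == gname] == canon[[gname]])
    expect_gte(d, stats::qbinom(0.001, 100, 0.6))
    expect_lte(d, stats::qbinom(0.999, 100, 0.6))
  }

  # determinism and errors
  expect_identical(assign_surnames(grp, 0.7, orig, seed = 5),
                   assign_surnames(grp, 0.7, orig, seed = 5))
  expect_error(assign_surnames(grp, 0.5, character(0), seed = 1),
               "non-empty")
})

test_that("the cohort generator is reproducible and matches its conditions", {
  a <- simulate_cohort(group_sizes = c(20, 10, 10), n_snps = 600,
                       map = make_marker_map(600), seed = 77)
  b <- simulate_cohort(group_sizes = c(20, 10, 10), n_snps = 600,
                       map = make_marker_map(600), seed = 77)
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$truth$surname_origin, b$truth$surname_origin)

  # Q rows sum to one; group means hit the configured ancestry exactly
  expect_true(all(abs(rowSums(a$truth$Q_true) - 1) < 1e-9))
  gm <- colMeans(a$truth$Q_true[a$truth$group == "Kuwait_B", ])
  expect_lt(max(abs(gm - default_group_ancestry()["Kuwait_B", ])), 1e-6)
})

test_that("pairwise Hudson F_ST converges to the shared drift parameter", {
  tp <- make_two_pops(n1 = 60, n2 = 60, m = 5e4, fst = 0.05, seed = 41)
  est <- fst_pair(tp$g1, tp$g2, inbreed_adjust = FALSE, n_blocks = 0)$estimate
  expect_lt(abs(est - 0.05) / 0.05, 0.2)
})
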