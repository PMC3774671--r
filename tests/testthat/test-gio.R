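test_that("PLINK text round-trip is the identity on dosages, ids and map", {
  set.seed(51)
  g <- matrix(sample(c(0L, 1L, 2L, NA), 60, replace = TRUE,
                     prob = c(.3, .3, .3, .1)), 6, 10,
              dimnames = list(paste0("ID", 1:6), sprintf("m%02d", 1:10)))
  map <- data.frame(marker = sprintf("m%02d", 1:10), chrom = "1",
                    bp = seq(1000, 10000, by = 1000), cM = (1:10) / 100)
  ped <- tempfile(fileext = ".ped"); mp <- tempfile(fileext = ".map")
  write_plink_text(g, map, ped, mp)
  rt <- read_plink_text(ped, mp)
  # A1 is the first-seen allele, which may flip the counted allele for
  # markers whose first non-missing call is homozygous-reference
  flip <- rt$alleles[, "A1"] == "G"
  expect_equal(unname(rt$genotypes[, !flip]), unname(g[, !flip]))
  expect_equal(unname(2L - rt$genotypes[, flip]), unname(g[, flip]))
  expect_equal(rownames(rt$genotypes), rownames(g))
  expect_equal(rt$map$bp, map$bp)
  expect_equal(rt$map$marker, map$marker)
})

test_that("toy .ped/.map fixture parses to the expected dosage matrix", {
  ped <- tempfile(fileext = ".ped"); mp <- tempfile(fileext = ".map")
  writeLines(c("F1 I1 0 0 1 -9 A A A G C C",
               "F2 I2 0 0 2 -9 A G G G C T"), ped)
  writeLines(c("1\tsnp1\t0\t100", "1\tsnp2\t0\t200", "1\tsnp3\t0\t300"), mp)
  rt <- read_plink_text(ped, mp)
  expect_equal(dim(rt$genotypes), c(2L, 3L))
  expect_equal(sum(is.na(rt$genotypes)), 0L)
  # dosages of the first-seen allele: snp1 A, snp2 A, snp3 C
  expect_equal(unname(rt$genotypes["I1", ]), c(2L, 1L, 2L))
  expect_equal(unname(rt$genotypes["I2", ]), c(1L, 0L, 1L))

  writeLines(c("F1 I1 0 0 1 -9 A A A G"), ped)
  expect_error(read_plink_text(ped, mp), "line 1")
  writeLines(c("F1 I1 0 0 1 -9 A A A G X C"), ped)
  expect_error(read_plink_text(ped, mp), "allele codes")
})

test_that("cM interpolation is linear inside and slope-clamped outside", {
  map <- data.frame(marker = c("a", "b", "c", "d"), chrom = "1",
                    bp = c(500000L, 1000000L, 1500000L, 2000000L))
  refs <- data.frame(chrom = "1", bp = c(0, 1e6), cM = c(0, 1))
  out <- interpolate_cm(map, refs)
  expect_equal(out$cM, c(0.5, 1, 1.5, 2))  # midpoint + boundary-slope beyond

  # a marker exactly at a reference gets that reference cM
  refs2 <- data.frame(chrom = "1", bp = c(5e5, 1e6, 3e6), cM = c(1, 4, 5))
  out2 <- interpolate_cm(map, refs2)
  expect_equal(out2$cM[1], 1)
  expect_equal(out2$cM[2], 4)

  # random monotone references: output is monotone and inside the hull
  set.seed(52)
  for (r in 1:20) {
    bps <- sort(sample(1e6, 5))
    cms <- sort(stats::runif(5, 0, 10))
    rr <- data.frame(chrom = "1", bp = bps, cM = cms)
    mm <- data.frame(marker = paste0("x", 1:30), chrom = "1",
                     bp = sort(sample(seq(min(bps), max(bps)), 30)))
    oo <- interpolate_cm(mm, rr)
    expect_true(all(diff(oo$cM) >= -1e-12))
    expect_true(all(oo$cM >= min(cms) - 1e-12 & oo$cM <= max(cms) + 1e-12))
  }

  expect_error(interpolate_cm(data.frame(marker = "z", chrom = "2", bp = 1L),
                              refs), "chromosome")
})

test_that("exact HWE test agrees with the enumeration oracle", {
  # two diploids, two of each allele: het counts 0 (prob 1/3) and 2 (2/3)
  expect_equal(hwe_exact_p(0, 2, 0), 1.0)
  expect_equal(hwe_exact_p(1, 0, 1), hwe_oracle(1, 0, 1))

  expect_equal(hwe_exact_p(5, 0, 5), hwe_oracle(5, 0, 5))

  set.seed(53)
  for (r in 1:200) {
    n <- sample(1:50, 1)
    nAA <- sample(0:n, 1)
    nAa <- sample(0:(n - nAA), 1)
    naa <- n - nAA - nAa
    p <- hwe_exact_p(nAA, nAa, naa)
    expect_gt(p, 0)
    expect_lte(p, 1)
    expect_equal(p, hwe_oracle(nAA, nAa, naa), tolerance = 1e-12)
  }
  expect_error(hwe_exact_p(-1, 0, 1), "non-negative")
})

test_that("QC filters apply in the documented order with audited counts", {
  set.seed(54)
  n <- 10; m <- 12
  g <- matrix(sample(c(0L, 1L, 2L), n * m, replace = TRUE), n, m,
              dimnames = list(paste0("S", 1:n), paste0("m", 1:m)))
  g[, 1] <- 1L                    # all-heterozygous: HWE-extreme, MAF 0.5
  g[, 2] <- 0L                                    # monomorphic -> MAF rule
  g[10, 2:10] <- NA                               # sample 10: 25% missing
  map <- data.frame(marker = paste0("m", 1:m),
                    chrom = c(rep("1", 10), "X", "1"),
                    bp = c(seq(1e5, 1e6, length.out = 10), 5e5, 2e6))
  alle <- cbind(rep("A", m), rep("G", m))
  alle[12, ] <- c("A", "T")                       # strand-ambiguous
  # the low-call sample is removed before the HWE test sees the marker, so
  # the exact p is that of 9 heterozygotes in 9 diploids (0.0105); the rule
  # is exercised at a 0.02 threshold
  qc <- qc_filter(g, map, alleles = alle, hwe_p = 0.02)
  rep_ <- qc$report
  expect_equal(rep_$rule,
               c("sample_call_rate", "marker_type", "marker_call_rate",
                 "maf", "hwe"))
  expect_equal(rep_$removed[rep_$rule == "sample_call_rate"], 1L)  # S10
  expect_equal(rep_$removed[rep_$rule == "marker_type"], 2L)       # X + A/T
  expect_false("m2" %in% qc$map$marker)                            # MAF
  expect_false("m1" %in% qc$map$marker)                            # HWE

  # removed counts sum to the input/output differences
  expect_equal(sum(rep_$removed[rep_$kind == "marker"]),
               ncol(g) - ncol(qc$genotypes))
  expect_equal(sum(rep_$removed[rep_$kind == "sample"]),
               nrow(g) - nrow(qc$genotypes))

  # idempotence on its own output
  qc2 <- qc_filter(qc$genotypes, qc$map)
  expect_equal(sum(qc2$report$removed), 0L)
})

test_that("relatedness pruning flags duplicates and parent-offspring", {
  # unrelated samples: nobody removed at the default threshold (the moment
  # estimator's sampling noise needs a dense marker set to sit below 0.05)
  pan_u <- simulate_panel(15000, 1, 0.05, seed = 56)
  sim_u <- simulate_genotypes(pan_u, matrix(1, 10, 1), 0, seed = 57)
  expect_equal(relatedness_prune(sim_u$genotypes),
               rownames(sim_u$genotypes))

  g <- sim_u$genotypes

  # exact duplicate: PI_HAT ~ 1, one of the two removed
  gdup <- rbind(g, DUP = g[1, ])
  ph <- pi_hat(gdup)
  expect_gt(ph$pi_hat[ph$id1 == "S0001" & ph$id2 == "DUP"], 0.9)
  kept <- relatedness_prune(gdup)
  expect_equal(length(kept), nrow(gdup) - 1L)
  # call rates are equal, so the lexicographically larger id (S0001) goes
  expect_false("S0001" %in% kept)
  expect_true("DUP" %in% kept)

  # parent-offspring construction: child shares one haplotype with parent
  set.seed(58)
  child <- sim_u$truth$hap1[1, ] +
    rbinom(ncol(g), 1, pan_u$pop_freqs[1, ])
  names(child) <- colnames(g)
  gpo <- rbind(g, CHILD = child)
  php <- pi_hat(gpo)
  expect_gt(php$pi_hat[php$id1 == "S0001" & php$id2 == "CHILD"], 0.3)
  expect_lt(length(relatedness_prune(gpo)), nrow(gpo))
})
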