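test_that("PCA separates populations and treats duplicates identically", {
  tp <- make_two_pops(n1 = 25, n2 = 25, m = 1500, fst = 0.2, seed = 101)
  g <- rbind(tp$g1, tp$g2)
  pc <- pca_genotypes(g)

  # eigenvalues are non-negative and sorted descending
  expect_true(all(pc$eigenvalues >= -1e-10))
  expect_true(all(diff(pc$eigenvalues) <= 1e-10))

  # PC1 splits the two populations with zero overlap
  a <- pc$coords[1:25, 1]; b <- pc$coords[26:50, 1]
  expect_true(max(a) < min(b) || max(b) < min(a))

  # a duplicated sample lands on identical coordinates
  gd <- rbind(g, DUP = g[1, ])
  pcd <- pca_genotypes(gd)
  expect_equal(unname(pcd$coords["DUP", ]), unname(pcd$coords[1, ]),
               tolerance = 1e-8)

  # sample order only flips signs
  ord <- sample(nrow(g))
  pco <- pca_genotypes(g[ord, ])
  for (j in 1:2) {
    cc <- stats::cor(pco$coords[match(rownames(g), rownames(g)[ord]), j],
                     pc$coords[, j])
    expect_gt(abs(cc), 0.999)
  }

  expect_error(pca_genotypes(matrix(c(0, 0, 2, 2), 2, 2)), "polymorphic")
})

test_that("drop-one-in projection places queries with their population", {
  # three well-separated populations so both PC axes carry structure and
  # the sign alignment is unambiguous
  km <- make_k_pops(K = 3, n_per = 40, m = 600, fst = 0.25, seed = 102)
  ref <- km$g
  qQ <- matrix(c(1, 0, 0), 10, 3, byrow = TRUE)  # queries from population 1
  qs <- simulate_genotypes(km$panel, qQ, 0, seed = 103,
                           sample_ids = paste0("QRY", 1:10))$genotypes
  din <- drop_one_in(ref, qs)

  # queries land inside population 1's bounding box (slightly padded)
  p1 <- din$ref_coords[km$pop == 1, , drop = FALSE]
  pad <- 0.5 * apply(p1, 2, function(x) diff(range(x)))
  inside <- sum(din$query_coords[, 1] > min(p1[, 1]) - pad[1] &
                  din$query_coords[, 1] < max(p1[, 1]) + pad[1] &
                  din$query_coords[, 2] > min(p1[, 2]) - pad[2] &
                  din$query_coords[, 2] < max(p1[, 2]) + pad[2])
  expect_gte(inside, 9)

  # reference coordinates are stable across runs (about 1 percent RMS)
  rms <- sqrt(mean((din$ref_mean_coords - din$ref_coords)^2))
  scale <- sqrt(mean(din$ref_coords^2))
  expect_lt(rms / scale, 0.02)

  # a query identical to a reference sample reproduces its coordinates
  din2 <- drop_one_in(ref, ref[1, , drop = FALSE])
  expect_equal(unname(din2$query_coords[1, ]),
               unname(din2$ref_coords[1, ]), tolerance = 0.05)
})

test_that("neighbour joining reproduces additive distances exactly", {
  # 4-taxon tree ((A:1,B:2):1.5,C:3,D:4); path distances are additive
  d <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  d["A", "B"] <- d["B", "A"] <- 3
  d["A", "C"] <- d["C", "A"] <- 1 + 1.5 + 3
  d["A", "D"] <- d["D", "A"] <- 1 + 1.5 + 4
  d["B", "C"] <- d["C", "B"] <- 2 + 1.5 + 3
  d["B", "D"] <- d["D", "B"] <- 2 + 1.5 + 4
  d["C", "D"] <- d["D", "C"] <- 7
  tr <- nj_tree(d)
  expect_equal(unname(as.matrix(stats::cophenetic(tr))[rownames(d),
                                                       rownames(d)]),
               unname(d))

  # three taxa: the unique unrooted topology
  tr3 <- nj_tree(d[1:3, 1:3])
  expect_equal(ape::Ntip(tr3), 3L)

  # random additive matrices from random trees are recovered exactly
  set.seed(104)
  for (r in 1:10) {
    nt <- sample(5:8, 1)
    rt <- ape::rtree(nt, rooted = FALSE)
    dd <- as.matrix(stats::cophenetic(rt))
    rec <- nj_tree(dd)
    expect_equal(ape::dist.topo(ape::unroot(rt), rec), 0,
                 ignore_attr = TRUE)
  }

  # an ultrametric matrix gives a topology consistent with UPGMA
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  du <- as.matrix(stats::cophenetic(hc))
  tru <- nj_tree(du)
  upg <- ape::as.phylo(hc)
  expect_equal(ape::dist.topo(ape::unroot(upg), tru), 0, ignore_attr = TRUE)

  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2, 2)), "3 taxa")
  dm <- d; dm[1, 2] <- 99
  expect_error(nj_tree(dm), "symmetric")
})

test_that("F_ST bootstrap consensus recovers a known drift topology", {
  # hierarchical drift: (P1,P2) vs (P3,P4), strong split, weak tips
  m <- 1500
  top <- simulate_panel(m, 2, c(0.15, 0.15), seed = 105)
  tips12 <- simulate_panel(m, 2, c(0.03, 0.03), seed = 106,
                           base_freqs = top$pop_freqs[1, ])
  tips34 <- simulate_panel(m, 2, c(0.03, 0.03), seed = 107,
                           base_freqs = top$pop_freqs[2, ])
  pan <- top
  pan$pop_freqs <- rbind(tips12$pop_freqs, tips34$pop_freqs)
  pan$fst_params <- rep(0.03, 4)
  Q <- diag(4)[rep(1:4, each = 12), ]
  sim <- simulate_genotypes(pan, Q, 0, seed = 108)
  groups <- split(seq_len(48), rep(1:4, each = 12))
  gl <- lapply(groups, function(ix) sim$genotypes[ix, , drop = FALSE])
  names(gl) <- paste0("P", 1:4)

  ct <- fst_bootstrap_consensus(gl, n_per_pop = 5, reps = 60, seed = 109)
  expect_true(all(ct$support >= 0 & ct$support <= 1))
  # the (P1,P2)|(P3,P4) bipartition should appear with high support
  cons <- ct$tree
  expect_equal(ape::Ntip(cons), 4L)
  internal <- ct$support[!is.na(ct$support)]
  expect_gt(max(internal), 0.9)

  # a single replicate is its own consensus with full support
  ct1 <- fst_bootstrap_consensus(gl, n_per_pop = 5, reps = 1, seed = 110)
  expect_true(all(ct1$support[!is.na(ct1$support)] == 1))
})
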