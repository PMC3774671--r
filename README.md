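# popstructr

Population-substructure inference from genome-wide SNP genotypes, built for
cohorts assembled from a few recent source populations — the setting of the
Arabian Peninsula, where genetic groups are weakly differentiated (pairwise
F_ST ~ 0.005–0.01), consanguinity is common, and family-name lineage gives
an external check on genetic clusters. Everything is verified by parameter
recovery on a seeded synthetic-data generator with known truth.

## What it computes

- **Admixture proportions** by maximum-likelihood EM under the binomial
  admixture model g<sub>im</sub> ~ Bin(2, Σ<sub>k</sub> Q<sub>ik</sub>P<sub>km</sub>),
  with SQUAREM acceleration, CLUMPP-style alignment of replicate runs,
  Mantel run-consistency checks, likelihood-based selection of K, and
  relative-majority group assignment.
- **Pairwise F_ST** (Hudson ratio-of-sums) with an inbreeding adjustment —
  the sampling variance of each allele-frequency estimate uses
  p(1−p)(1+F)/(2n) — and moving-block jackknife standard errors
  (553 blocks by default).
- **Inbreeding coefficients** F = 1 − O<sub>het</sub>/E<sub>het</sub>
  against pooled allele frequencies, with small-sample-corrected expected
  heterozygosity, plus the standard binned distribution table.
- **Runs of homozygosity** (500 kb / 25 SNPs / ≤1 het / ≤5 missing /
  ≤100 kb gap scan) and **IBD segments** via a deterministic scan on phased
  haplotypes, with per-carrier summaries and a method-of-moments estimator
  of generations to the common ancestor under Haldane's model
  (segment length ~ Exp(mean 1/(2g) Morgans)).
- **PCA** with √(2p(1−p)) scaling and a *drop-one-in* projection that keeps
  unequal group sizes from distorting the axes; **neighbour-joining
  consensus trees** over bootstrap-resampled F_ST matrices.
- **Cluster-vs-surname concordance**: contingency tables and the Mantel
  permutation test on co-membership distances.
- **LD**: composite r², 50/5/0.1 windowed pruning, and 1 kb-binned decay
  curves with resampled 95% bands.
- **Synthetic cohorts**: Balding–Nichols ancestral panels, admixed and
  inbred individuals with retained truth haplotypes, planted ROH/IBD
  segments, concordant-but-noisy surname labels, PLINK-text output.

## Worked example

```r
library(popstructr)
coh <- simulate_cohort(group_sizes = c(60, 40, 40), n_snps = 4000,
                       group_f = c(0.026, 0.042, 0.003),
                       map = make_marker_map(4000), n_ibd = 40,
                       generations = 6, seed = 7)
g <- coh$genotypes; grp <- coh$truth$group

gl <- split.data.frame(g, grp)
fst_pair(gl$Kuwait_P, gl$Kuwait_S, n_blocks = 200)
#> Hudson F_ST estimate: 0.008807  (block-jackknife se 0.000494, 200 blocks)
```

The two most differentiated groups sit at F_ST ≈ 0.009 — the weak but real
stratification this kind of cohort shows, enough to inflate false positives
in a naive association study.

```r
round(tapply(inbreeding_f(g), grp, mean), 4)
#> Kuwait_B Kuwait_P Kuwait_S
#>   0.0037   0.0196   0.0725
```

The endogamous group (Kuwait_S) ranks far above the out-marrying group
(Kuwait_B), as generated. Absolute levels shift away from the generating
means (0.042 / 0.026 / 0.003) because the estimator measures homozygosity
against *pooled* frequencies: a group diverged from the pooled baseline
reads high, a broadly admixed group reads low — the Wahlund-type behaviour
any pooled-frequency F estimator has.

```r
fit_generations(coh$truth$planted_segments$cm_drawn, min_cm = 0)$g_raw
#> [1] 7.49   # 40 planted segments drawn at g = 6; rounds to 7 at this n
mt <- mantel_test(labels_to_distance(grp),
                  labels_to_distance(coh$truth$surname_origin),
                  n_perm = 9999, seed = 1)
#> Mantel r = 0.360, p = 0.0001 (9999 permutations)
```

With only 40 segments the generations estimate is coarse (7.5 vs the
generating 6); at 2,000 segments it recovers the integer exactly. The
Mantel p-value of 1e-4 is the exact permutation floor (1/(9999+1)) —
surname origins generated at 70% concordance are unambiguously associated
with the genetic groups.

The full pipeline (QC → prune → admixture → F_ST/F → segments → PCA/tree →
concordance → LD decay) runs from one config:

```r
res <- run_all(run_config(out_dir = "demo_run", seed = 1))
```

writing TSV/Newick outputs and a hash manifest under `demo_run/`.

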