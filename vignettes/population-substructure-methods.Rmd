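---
title: "Models and methods for population-substructure inference"
author: "popstructr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for population-substructure inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popstructr)
```

# Scope

popstructr dissects fine-scale substructure in an admixed human cohort from
genome-wide SNP genotypes. The motivating setting is a Gulf-peninsula
population assembled from a few historical source populations (Arabian
tribes, Persian settlers, Bedouin nomads, with African and European
contributions), where group differentiation is weak (pairwise F_ST of order
0.005-0.01), consanguinity is common, and surname lineage provides an
external labeling to validate genetic clusters against. Every estimator in
the package is paired with a seeded generator that simulates data *with
known truth* under the same model assumptions, so correctness is established
by parameter recovery rather than by comparison to an external program.

# The synthetic cohort generator

## Allele frequencies: the Balding-Nichols model

Ancestral panel frequencies are simulated hierarchically. A base frequency
$p_m \sim \mathrm{Uniform}(0.05, 0.95)$ is drawn per SNP, and each ancestral
population $k$ receives

$$p_{km} \sim \mathrm{Beta}\!\left(p_m\frac{1-c_k}{c_k},\;
(1-p_m)\frac{1-c_k}{c_k}\right),$$

whose mean is $p_m$ and whose variance is $c_k\,p_m(1-p_m)$. The parameter
$c_k$ is the population's differentiation from the shared ancestor, and the
pairwise Hudson F_ST between two populations simulated at the same $c$
converges to $c$ — this is the calibration the F_ST recovery tests rely on.
Frequencies are clipped to $[10^{-6}, 1-10^{-6}]$.

The demonstration cohort uses six ancestral components (Arabian, African,
Brahui-like, Druze-like, Kalash-like, European) at $c$ between 0.08 and
0.15. These are continental-scale values: the African panel is the most
diverged (0.15), the Middle-Eastern panels the least (0.08), roughly
matching the spread seen among diversity-panel reference populations.

## Individuals: admixture, inbreeding, phase

Individual $i$ has ancestry proportions $q_i$ (row-stochastic over the $K$
components) and inbreeding coefficient $F_i$. Its dose frequency at SNP $m$
is $f_{im} = \sum_k q_{ik} p_{km}$, and the genotype is built from two
haplotypes: allele one is Bernoulli($f_{im}$); allele two copies allele one
with probability $F_i$ (autozygosity) and is otherwise an independent
Bernoulli($f_{im}$) draw. This reproduces the excess-homozygosity law

$$P(0) = (1-f)^2 + F f(1-f),\quad P(1) = 2f(1-f)(1-F),\quad
P(2) = f^2 + F f(1-f).$$

The two haplotypes are retained as ground truth so that the IBD scanner has
an exact phased target; no statistical phasing is performed anywhere.

The default cohort mirrors the study conditions: three groups of 138, 63
and 72 individuals whose group-mean ancestries put 56% of combined
West-Asian weight and 12% European weight in the first group, 69% Arabian
weight in the second, and 17% African weight in the third. Individual
ancestries scatter around the group mean as Dirichlet draws with
concentration 50 (per-component standard deviation of about 0.05, similar
to the within-group spread visible in model-based clustering of such
cohorts). Because the group-level mixes *are* the stated conditions, the
draws are rescaled (iterative proportional fitting on the simplex) so each
realised group mean matches its target exactly; the scatter is preserved.
Group-mean inbreeding defaults to 0.0257 / 0.0423 / 0.0027; individual $F$
values are exponential with those means (clipped at 0.5), giving the
right-skewed distribution seen in consanguineous cohorts. Negative
estimated $F$ arises from estimator noise on low-$F$ individuals, not from
the generator: the generator never simulates heterozygote excess, matching
the interpretation of negative coefficients as an estimation-side signal of
out-marriage.

Surname origins are assigned canonically per group with probability 0.7
(the concordance level is a free choice; printed cluster-by-surname tables
in this setting show strong but imperfect diagonal dominance, and 0.7
reproduces that qualitative structure) and uniformly among the remaining
origins otherwise.

## Planted segments

ROH and IBD segments are planted with genetic lengths drawn from Haldane's
model: a chromosome chunk inherited intact through $g$ meioses has
exponential length with mean $1/(2g)$ Morgans, i.e. $100/(2g)$ cM. ROH mode
rewrites the carrier's second haplotype to equal the first inside the
interval; IBD mode copies both haplotypes (hence genotypes) onto a second
carrier. Drawn lengths that overrun the chromosome are truncated and
flagged, and the pre-truncation length is recorded so distributional tests
can use the exact exponential law.

## What the generator does not emulate

No coalescent recombination structure, no mutation model, no background LD
(markers are exchangeable given the panel frequencies), no genotyping error
by default, and no X chromosome. Passing recovery tests therefore show that
the estimators are correct *under the stated model*, not that they are
robust to real-data artefacts such as batch effects, LD leakage through
pruning thresholds, or platform-specific missingness.

# Estimators

## Admixture by maximum-likelihood EM

Genotypes are modelled as $g_{im} \sim \mathrm{Binomial}(2, f_{im})$ with
$f = QP$. The EM updates are the standard allele-responsibility form;
the log-likelihood is asserted non-decreasing at every recorded step.
Because plain EM crawls along the nearly flat ridge that mixes similar
components, the implementation wraps each pair of EM steps in a SQUAREM
squared-extrapolation with a monotonicity guard (an extrapolated state is
accepted only if its likelihood is at least that of the single EM step);
`max_iter` counts these accelerated cycles, default 500, with convergence
declared when the gain drops below `tol` = 1e-4.

Initialisation matters at this scale: the default seeds clusters from a
k-means partition of the top principal components (cluster allele
frequencies for $P$, 0.8/0.2 soft one-hot memberships for $Q$), which
starts the EM inside the right basin; a flat-Dirichlet random
initialisation is available and is what replicate-run consistency checks
exercise. Replicate runs differ only by seed. Label switching across runs
is undone by exhaustively choosing, per run, the column permutation of $Q$
maximising the Frobenius inner product with the first run ($K \le 8$), the
same alignment task CLUMPP performs; aligned runs are then merged by
averaging. $K$ is selected as the candidate maximising the mean final
log-likelihood across replicates (the ML analogue of the mean estimated
ln P(Data) rule), with ties to the smaller $K$; note that in-sample
likelihood is non-decreasing in $K$, so on weakly structured data the rule
can plateau — the package returns the argmax and leaves the judgement to
the analyst, as the original criterion does.

Unsupervised EM on admixed-only data cannot name its components. The
analysis that motivates this package merged reference populations into the
run and read components off the references; `simulate_cohort` therefore
supports appending unadmixed reference individuals per ancestral panel
(default 30 in the recovery harnesses, a typical diversity-panel population
size), and group-mean ancestry is reported on the component each reference
panel anchors.

## F_ST with inbreeding adjustment

The pairwise estimator is the Hudson-style ratio of sums: per marker,

$$\mathrm{num}_m = (\hat p_1 - \hat p_2)^2 - \widehat{\mathrm{Var}}(\hat p_1)
 - \widehat{\mathrm{Var}}(\hat p_2),\qquad
\mathrm{den}_m = \hat p_1(1-\hat p_2) + \hat p_2(1-\hat p_1),$$

with the estimate $\sum_m \mathrm{num}_m / \sum_m \mathrm{den}_m$
(ratio-of-sums is robust to rare markers). Inbreeding inflates the
sampling variance of $\hat p$ by $(1+F)$; the adjusted correction uses the
unbiased form $\hat p(1-\hat p)(1+\hat F)/(2n - (1+\hat F))$, with the
group's $\hat F$ estimated against the pooled frequencies of both groups.
Under Balding-Nichols truth the estimator converges to the generating $c$,
which is how the recovery acceptance check is calibrated. Standard errors
come from a moving-block jackknife: markers are cut into contiguous
map-order blocks (553 by default), the ratio-of-sums is recomputed with
each block deleted, and $\mathrm{se}^2 = \frac{B-1}{B}\sum_j(\theta_{(-j)} -
\bar\theta)^2$.

## Inbreeding coefficients

$F_i = 1 - O_i/E_i$, observed over expected heterozygosity on the markers
non-missing in individual $i$, with pooled frequencies across the whole
cohort (not per group, so that group differences in frequency do not absorb
the inbreeding signal). When the pooled frequencies are estimated from the
sample itself, each marker's expected heterozygosity uses Nei's unbiased
form $2\hat p(1-\hat p)\,2n/(2n-1)$; without this the estimate is biased
low by roughly $(1+F)/(2n)$, which at 63 individuals would be an
appreciable fraction of the mean levels of interest (0.003-0.04).

## ROH and IBD segments

The ROH scanner finds, per individual and chromosome, maximal marker runs
containing at most 1 heterozygote and 5 missing calls, with no adjacent
gap above 100 kb; runs qualify if they span at least 500 kb and 25 SNPs.
Overlapping maximal candidates are resolved left to right, trimming a
candidate at the previous segment's end and re-checking the thresholds, so
one individual's segments never overlap. An optional exclusion list (e.g.
centromeres, which are absent from synthetic genomes) masks markers before
scanning.

The IBD scanner is deterministic and works on phased haplotypes: for each
of the four haplotype pairings of two individuals it finds maximal exact
match runs, absorbing isolated single-site mismatches at up to 1 per 100
SNPs (genotyping error allowance); runs reaching `min_cm` (default 1 cM)
are kept per pairing and overlapping intervals across pairings are merged
so a tract shared on both haplotypes is reported once. This replaces the
HMM-based phased-inference pipeline of the original analysis — the largest
deliberate methodological substitution in the package. It is justified
because the generator provides truth phase and every downstream summary
(length distributions, per-individual totals, the generations fit) depends
only on the segment intervals; the cost is that the scanner is not
applicable to unphased real data.

Per-carrier summaries report totals, counts at the $\ge$ 2 cM and
$\ge$ 10 cM thresholds (closed thresholds; the printed tallies do not state
open vs closed, and $\ge$ is used), the longest segment, and
$F_{seg}$ = total cM / genome cM. Cohort percentages default to
*truncation* at two decimals because the worked number they mirror
(252/273 printed as 92.30%) is truncated, not rounded; rounding is
available as an option.

The generations-to-common-ancestor estimator inverts Haldane's model by
method of moments on detected lengths: lengths observed above a detection
threshold $\ell_0$ are, by memorylessness, $\ell_0$ plus an exponential
with the same mean, so $\hat g = 100 / (2(\bar\ell - \ell_0))$, returned
raw and rounded.

## PCA, drop-one-in, and consensus trees

PCA centres each marker at its mean dosage, scales by
$\sqrt{2\hat p(1-\hat p)}$, imputes missing dosages to the mean, and takes
the SVD. The drop-one-in procedure protects the axes from unequal group
sizes: each query individual is added alone to the reference set, the PCA
is rerun, and the query's first two coordinates are recorded; axis signs
are anchored to the reference-only PCA by correlation of reference
coordinates, with |r| < 0.8 flagged as a near-degenerate alignment. Mean
reference coordinates across runs are returned as a stability readout.

Trees are built from pairwise inbreeding-adjusted F_ST matrices by
Saitou-Nei neighbour joining (negative branch lengths are clamped to zero
with the deficit moved to the adjacent branch). The consensus procedure
draws 5 samples per population per replicate, rebuilds the F_ST NJ tree
1000 times, and reports the majority-rule (> 50%) consensus with per-edge
support equal to the bipartition frequency; majority rule is the
conventional default when the original figure reports support bands
without naming its consensus rule. One subsample per population per
replicate is shared across all pairs in that replicate.

## Concordance

Cluster-vs-surname agreement uses a cross-tabulation with half-up rounded
row percentages (printed tables mix one- and two-decimal precision, so the
precision is a parameter) and a Mantel permutation test. Categorical
labelings become co-membership distances (0 within a label, 1 across),
which makes the perfect-concordance floor exact: with identical matrices
the observed $r = 1$ can only be tied, never beaten, so
$p = (1 + \#\{r_{perm} \ge r\})/(n_{perm}+1) = 1/(n_{perm}+1)$, e.g.
$10^{-4}$ at 9999 permutations. The permutation machinery is delegated to
`vegan::mantel`, whose conventions (upper-triangle Pearson r, +1 p-value)
match.

## LD

$r^2$ is the squared Pearson correlation of dosages (composite LD, no
phase), undefined — never zero — for monomorphic vectors. Pruning slides a
50-marker window in steps of 5 and greedily removes the right-hand member
of any pair with $r^2 > 0.1$, repeating until stable, which makes the
result deterministic and idempotent; the left-most marker of an offending
pair is kept (the tie-break is unspecified in the source description).
Decay curves draw 5 samples without replacement, 50 times, compute $r^2$
for all intra-chromosome pairs within 1 Mb, and bin by distance into 1 kb
bins whose lower endpoint is included (a pair at exactly 950 bp belongs to
the 1 kb bin spanning 950-1050); the band is the empirical 2.5/97.5
percentile across replicates.

# Quality control

Filters run in a fixed, audited order: sample call rate $\ge$ 0.97 →
marker-type (autosomes only; A/T and G/C strand-ambiguous markers dropped)
→ marker call rate $\ge$ 0.98 → MAF (markers with MAF $\le$ 0.05 removed —
aggressive, but it is the stated rule) → exact Hardy-Weinberg test
($p < 10^{-3}$ removed). The source lists the rules without an order; this
order removes bad samples before marker statistics are computed and
reports a per-rule removal count so any ordering effect is auditable. The
HWE test is the plain two-sided exact conditional test (no mid-p), the
field standard for SNP QC. Relatedness pruning estimates PLINK-style
PI_HAT by IBS method-of-moments with unbiased factorial-moment frequency
estimates and greedily drops one member per flagged pair (lower call rate
first, then the lexicographically larger id) until no retained pair
exceeds the threshold (default 0.05, above expected second-cousin
sharing). PI_HAT has sampling noise of about 0.03 at 5,000 markers, so
meaningful thresholding needs dense marker sets — tens of thousands of
markers, as in real chip data.

# Numerical and design choices

- Frequencies are clipped to $[10^{-6}, 1-10^{-6}]$ and ancestry weights
  to $\ge 10^{-12}$ before renormalisation, keeping likelihoods finite.
- Majority assignment breaks exact ties toward the lowest cluster index
  and flags them.
- `interpolate_cm` is linear between reference points and continues the
  boundary slope outside them, preserving monotonicity.
- The dosage convention counts copies of the first-seen allele in .ped
  file order ("0 0" is missing); PLINK dialects differ here, and the
  convention is documented in the reader.
- Seeds: every public generator and resampling routine takes an explicit
  seed; the pipeline derives per-stage seeds from one master seed, so a
  config reproduces byte-identical outputs.

# Problem sizes

The recovery analyses are dimensioned for a single desktop core: F_ST
recovery uses 20 replicates of 50,000 SNPs at the study's 138/63
sample split; admixture recovery uses 5,000 pruned-scale markers, the
273-member three-group cohort plus 30 reference individuals per panel, and
two aligned EM replicates; inbreeding recovery uses 20,000 SNPs; the
generations fit uses 2,000 segment lengths. The demonstration pipeline
runs a reduced marker set by default; all sizes are arguments.

# Known limitations

- The IBD scanner requires phase and is therefore a truth-recovery tool
  for simulated cohorts, not a replacement for HMM phasing/IBD inference
  on real genotypes.
- Unsupervised EM admixture at weak differentiation mildly compresses
  large ancestry components and inflates small ones (simplex-boundary
  noise): at the default recovery scale the bias is under one percentage
  point on a 17% component and 2-3 points on a 69% component. More markers
  shrink it.
- Model selection by in-sample likelihood cannot penalise overfitting K;
  it matches the original selection rule, not modern cross-validation
  practice.
- The pipeline's admixture stage on unanchored cohort data labels clusters
  arbitrarily; naming components requires reference panels.
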