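---
title: "Detecting dysregulated ceRNA crosstalk between pathways"
author: "cePathways maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting dysregulated ceRNA crosstalk between pathways}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cePathways)
```

## The model

Competing endogenous RNAs (ceRNAs) are transcripts that share microRNA
binding sites and therefore co-regulate one another by competing for a
common miRNA pool. When that competition is active, the transcripts
co-express; when it collapses — for example in a tumour where the shared
miRNAs are inactivated — the co-expression collapses with it. The package
asks this question not for individual gene pairs but for *pairs of
biological pathways*: which pathway pairs gain or lose ceRNA-mediated
co-regulation between two conditions?

The analysis has four stages.

**1. The ceRNA relationship change network.** Genes are connected when they
share significantly more miRNA-family binding sites than expected. For
genes $x$ and $y$ with family sets $F(x)$ and $F(y)$ inside a universe of
$N$ actively expressed families, the overlap $k = |F(x) \cap F(y)|$ is
scored with the upper-tail hypergeometric probability of drawing at least
$k$ shared families, and Benjamini–Hochberg correction is applied across
all tested pairs (edges at $q < 0.05$). Each edge carries the per-condition
Pearson co-expression $\rho_{normal}$ and $\rho_{tumor}$ and their change
$\Delta\rho = \rho_{tumor} - \rho_{normal}$: negative $\Delta\rho$ is a
ceRNA relationship loss, positive a gain. Before testing, genes must be
expressed (abundance $\ge 1$ in strictly more than 80% of all samples),
miRNA families must be moderately expressed (mean abundance strictly
between 0.01 and 100 — outside this window competition is implausible:
too rare to matter or too abundant to saturate), and genes must retain at
least 6 binding-site families within the active universe.

**2. Direct pathway-pair screening.** For a pathway $P$, every network
neighbour $y$ is scored by $\theta_P(y) = \sum_{x \in P} \Delta\rho(x,y)$
over the edges $(x,y)$. Neighbours are split by sign (losses ranked most
negative first, gains most positive first) and walked with a weighted
running sum against a second pathway $Q$: a gene in $Q$ adds
$|\theta|/N_R$ (with $N_R$ the total $|\theta|$ over $Q$ genes in the
sublist), any other gene subtracts $1/(N - N_H)$. The enrichment score
(CES) is the maximum absolute deviation of this running sum — the weighted
Kolmogorov–Smirnov form familiar from gene-set enrichment analysis, which
keeps mid-list clusters from scoring high. Significance comes from
permuting which ranked positions carry $Q$ membership (2,000 label
permutations by default); the p-value is the fraction of permutations
scoring at least the observed CES, so $p = 0$ is attainable. Calls require
CES > 0.6 and B-H $q < 0.01$, computed within each direction.

**3. Indirect pathway-pair screening.** A gene $z$ two hops from $P$
through a mediator $y$ is an indirect partner of $x \in P$ when
$(x,y)$ and $(y,z)$ are edges, the pair $(x,z)$ is *not* itself an edge,
and $\Delta\rho(x,y)$, $\Delta\rho(y,z)$, $\Delta\rho(x,z)$ agree in sign
(a change that does not propagate coherently along the chain is not
mediated competition). Then
$\kappa_P(z) = \sum_x \Delta\rho(x,z)$ over qualifying $x$, with
$\Delta\rho(x,z)$ computed from expression directly. The CES/permutation
machinery is reused on the $\kappa$ ranking. Because mediated signals are
weaker and noisier, significance uses the ForwardStop rule on the pooled,
ascending p-values within each direction: reject the largest prefix $k$
whose running mean of $-\log(1 - p_i)$ stays at or below $\alpha = 0.01$.
No CES cutoff is applied to indirect calls.

**4. Minimal mediators.** For a called indirect pair, each candidate
mediator covers the pathway genes at the ends of the chains it mediates.
The smallest set of mediators covering every involved pathway gene is a
minimum set cover, solved exactly by branch and bound on the equivalent
integer program (one binary variable per mediator, one covering constraint
per pathway gene). Since minimum covers are usually not unique, the solver
is re-run under random permutations of the mediator precedence and the
distinct optimal covers are aggregated; their union is the
minimally-mediating gene set. Enrichment of that set in a reference list
(tumour suppressors, oncogenes) is assessed against random draws of the
same size from a background gene pool.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `min_abundance`, `min_fraction` | 1, 0.8 | expressed-gene filter (abundance units, fraction of all samples; strict `>`) |
| `mirna_lo`, `mirna_hi` | 0.01, 100 | active-miRNA window on the mean abundance (strict on both sides) |
| `min_sites` | 6 | minimum binding-site families per gene within the active universe |
| `overlap_q` | 0.05 | B-H cutoff for the hypergeometric overlap |
| `n_perm` | 2000 | gene-label permutations per enrichment test |
| `ces_cutoff` | 0.6 | minimum CES for a direct call (an empirical default corresponding to the top 5% of a reference score distribution; data-dependent and deliberately configurable) |
| `q_cutoff` | 0.01 | B-H cutoff on direct permutation p-values |
| `min_Q_overlap` | 5 | enrichment gate: Q genes required in P's ranking before testing |
| `alpha_forwardstop` | 0.01 | ForwardStop level for indirect calls |
| `mediator_n_perm` | 1000 | solver-input permutations when aggregating minimum covers |
| `enrichment_trials` | 100 | random draws for mediator-set enrichment |

## Decisions where the design was open

* **Running-sum increments.** "Proportional to the score" admits several
  weightings; the package uses the weighted Kolmogorov–Smirnov form (hit:
  $|\theta|/N_R$; miss: $1/(N-N_H)$), the concrete scheme of the method the
  weighting is borrowed from.
* **Orientation.** $CES_P(Q) \ne CES_Q(P)$: both orientations are scored
  and a pair is reported when either passes, with both sets of statistics
  emitted. This favours recall while keeping the evidence visible.
* **Multiple testing across directions.** Losses and gains are corrected
  separately (B-H for direct, ForwardStop for indirect), mirroring the
  separate treatment of the two signs throughout.
* **The enrichment gate** is a minimum count of Q genes in P's ranking
  (default 5): the screening stage needs a cheap, explicit notion of
  "Q present in the neighbourhood" before a permutation test is spent.
* **Indirect exclusions.** Pairs $(x,z)$ that are themselves edges carry
  direct evidence and are excluded from $\kappa$, keeping the direct and
  indirect analyses on disjoint gene-pair evidence; $z$ is required to lie
  outside $P$. A $\Delta\rho$ of exactly 0 fails the sign-consistency
  condition (zero is neither gain nor loss).
* **No per-pair permutation streams.** Under gene-label permutation the
  null CES distribution depends only on the weight sequence and the hit
  count, so the screens compute one null per (pathway, direction, hit
  count) — statistically identical to per-pair permutation, deterministic
  (streams derive from the master seed by stable string hashing), and far
  cheaper.
* **Set cover, not a literal constraint system.** Mediator minimisation
  is formulated with the standard covering constraints of the minimum
  set cover problem (one binary variable per mediator, coverage of every
  involved pathway gene), which is exactly the problem class the task
  reduces to.
  Pathway genes no mediator can cover are pruned with a report rather than
  failing the instance.

## Numerical choices

Boundary cases are strict everywhere they are stated as strict: a gene
expressed in exactly 80% of samples is dropped; a family with mean
abundance exactly 100 is inactive. Undefined correlations (zero variance
within a condition) drop the affected edges or partners with a logged
count — they are never coerced to $\rho = 0$, which would masquerade as
evidence of absent co-expression. Permutation p-values carry no $+1$
smoothing, so a pair scoring above all permutations reports $p = 0$, and
ForwardStop clamps $p \le 1 - 10^{-15}$ before the logarithm. Ties in
rankings break by gene identifier; result tables order by $q$, then CES
descending, then pathway names; all of this makes full pipeline output
byte-reproducible under a fixed master seed.

## What the synthetic generator emulates

The generator (`simulateCernaStudy()`) produces the complete input bundle:
a genes-by-samples abundance matrix for two matched 50-sample conditions,
a family-level miRNA matrix, a gene-to-family target table, and a pathway
collection (20 disjoint pathways of 10 genes by default, 150 families of
which 120 sit inside the active window).

Planted structure targets the statistical features the pipeline consumes,
not the kinetics that produce them. A planted direct pair loads the genes
of both pathways on a shared Gaussian latent factor in exactly one
condition, with the loading set so the within-group log-abundance
correlation equals the requested effect size; the pair shares a dedicated
block of miRNA families, asymmetrically (Q carries the full block, each P
gene a random half) so that P–Q overlaps are significant while P's own
genes do not flood P's neighbourhood ranking as high-weight misses. A
planted chain routes the factor through dedicated mediator genes with
per-side family blocks that never cross, so the pathway pair co-expresses
sign-consistently along every chain yet cannot form a single direct edge.
Fifteen independent-expression decoy genes per block populate the
rankings with realistic low-score misses.

Background genes draw their family sets uniformly, which makes the
hypergeometric overlap test exactly calibrated on background pairs, and
half of them form co-targeting modules — 4-gene cliques sharing a
10-family block with independent expression — giving a sparse background
network whose $\Delta\rho$ is pure noise. Earlier designs that generated
background overlap through heavy-tailed family popularity were discarded:
a liberal overlap-test null interacts with B-H (planted signal raises the
rejection threshold and floods the network with background edges only
when signal is present), which destabilises both calibration and
recovery.

What the generator does **not** emulate: count noise (abundances are
log-normal, not negative binomial), mass-action miRNA titration,
overlapping pathways, correlated pathway membership and annotation bias,
3'UTR isoform effects, or batch structure. Passing the planted-recovery
and null-calibration suites therefore demonstrates that the statistics
recover the structure they model under clean conditions — not that real
tumour data meet those conditions.

## Problem sizes used by the test-suite

The calibration suite runs 50 replicate null studies (20 pathways,
200 genes, 50 samples per condition, 500 permutations) and checks that
direct calls stay within twice the nominal error budget and that
ForwardStop rejects nothing in at least 95% of replicates. The recovery
suite plants one direct loss and one mediated loss chain (effect 0.8) in
each of 20 replicate studies and requires each to surface as the top call
in at least 90% of them. Exact-oracle suites compare the running-sum score
against brute-force prefix evaluation (1,000 random lists), the two-hop
ranking against exhaustive triple enumeration (100 networks of up to 40
nodes), the cover solver against exhaustive search (200 instances of up
to 25 mediators), and the overlap test against direct summation of the
hypergeometric mass for every universe size up to 12.

## Known limitations

ForwardStop rejects some prefix whenever the smallest pooled p-value is
at most $1 - e^{-\alpha}$; with permutation granularity $1/n_{perm}$ this
makes the indirect screen sensitive to the number of hypotheses it pools,
and large collections with many weak candidate pairs will need more
permutations for stable behaviour near the boundary. The mediator ILP is
solved exactly, so pathological instances (hundreds of near-symmetric
mediators) can be slow — real and simulated instances here solve in
milliseconds, and the aggregation bound is checked against exhaustive
enumeration only on small instances. Sample pairing is carried as
metadata but the correlation statistics are unpaired, matching the
method's use of matched cohorts without a paired estimator.
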