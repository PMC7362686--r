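---
title: "Methods: multi-informant network congruency and binarization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-informant network congruency and binarization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netcongruency)
```

This vignette documents the statistical model behind `netcongruency`, the
parameters that matter, the numerical conventions adopted where the
methodological literature leaves a choice open, and what the synthetic
classroom generator does and does not establish about real data.

## The measurement setting

One classroom of $n$ consented children is described by three adjacency
matrices on a single roster whose order is canonical for everything:

* **Child report** — a directed binary matrix $N$, $N_{ij} = 1$ when child
  $i$ nominated child $j$ as someone they most like to play with.
* **Teacher report** — a symmetric ordinal matrix $R$,
  $R_{ij} \in \{0,\dots,4\}$, the teacher's rating of how much the pair
  plays together (0 = never, 4 = always). Teacher instruments rate the
  *pair*, so $R$ is stored symmetric; the package flags, rather than
  silently repairs, asymmetric input (an explicit `symmetrize` option
  averages and logs).
* **Researcher report** — a symmetric count matrix $F$ accumulated over
  $T$ time-sampling cycles; $F_{ij}$ is the number of cycles in which the
  pair was coded interacting. Children can be unavailable (absent,
  bathroom, asleep), so per-child availability counts accompany $F$.

All statistics run over the $n(n-1)$ **ordered** off-diagonal dyads: for
$n = 16$ that is 240, the unit of analysis. The diagonal is stored as zero
but treated as undefined; every operation masks it. Symmetric matrices are
kept mirrored so that a directed network can be compared with an
undirected one without discarding directionality: the undirected network
simply contributes each pair's value twice. Nonconsented children are
excluded before matrices are built, so the effective classroom size
$n_\text{eff}$ — the denominator of the chance threshold below — always
equals the matrix dimension.

## Binary transformation

Inferential network models typically require 0/1 ties, and the threshold
choice is an analyst decision this package makes explicit and auditable.
Three families are implemented.

**Rating cutoff.** Tie iff $R_{ij} \ge c$. The comparison is inclusive
("at or above"); $c = 0$ degenerately ties everything.

**Ratio thresholds.** Define $r_{ij} = F_{ij} / \sum_{k \ne i} F_{ik}$,
child $i$'s share of interaction budget directed at $j$ (rows with a zero
budget are left all-zero and reported). Tie from $i$ to $j$ iff
$r_{ij} \ge t$ with

* chance level $t = 1/(n_\text{eff} - 1)$ (6.7\% at $n_\text{eff}=16$):
  the share one classmate receives under uniform spreading;
* twice-chance $t = 2/(n_\text{eff} - 1)$; and
* a fixed share, conventionally 5\%.

Which of chance and fixed-5\% is more stringent depends on classroom size;
they coincide at $n_\text{eff} = 21$. Row normalization breaks the
symmetry of $F$, so ratio-thresholded networks are **directed**; no
automatic symmetrization is applied, since any OR/AND rule is a further
modeling choice.

**Frequency thresholds.** Computed on the distribution of $F_{ij}$ over
all $\binom{n}{2}$ unordered pairs, *including* zero-count pairs — with
roughly half of all pairs ever observed interacting, a median of 1 is only
obtained when zeros count. The half-median rule ties pairs **strictly
above** half the median (on integer counts with median 1 this is exactly
"observed at least once"); percentile rules use the inclusive comparison.
Percentiles are **nearest-rank** (the $\lceil qm/100 \rceil$-th order
statistic), so cutoffs are always observed integer frequencies; an
interpolated percentile could return non-achievable fractional cutoffs and
the published cutoffs in this literature are integers.

Two invariants are property-tested: tightening any threshold can only
shrink the tie set (density monotone non-increasing), and every scheme
commutes with node relabeling.

## Congruency statistics

**Graph correlation and QAP.** The observed statistic for a pair of
networks is the Pearson correlation of their paired off-diagonal cells.
Because dyads sharing a child are dependent, cell-wise permutation is
invalid; the Quadratic Assignment Procedure instead draws uniform random
node permutations $\pi$ and recomputes the correlation against
$B_{\pi(i)\pi(j)}$ — the classic full-matrix Mantel/Krackhardt form
(semi-partialling variants belong to multivariate QAP regression, which is
out of scope). With $M$ permutations (default 10,000) the upper-tail
p-value is $(1 + \#\{r_\pi \ge r_\text{obs}\})/(1 + M)$: the add-one
convention keeps Monte-Carlo tests valid and ties count toward rejection,
the conservative choice. Both one-sided and two-sided (on $|r|$) p-values
are reported, the one-sided being the headline since congruency hypotheses
are directional. Floating-point ties are compared with a $10^{-12}$
guard. `qap_exact()` enumerates all $n!$ permutations for $n \le 8$ and
anchors the Monte-Carlo implementation in tests; a calibration suite
checks the empirical type-I error at $\alpha = 0.05$ on independent
Bernoulli(0.3) networks of 16 nodes.

**Jaccard.** For binary networks, $J = C/(A+B+C)$ with $C$ the ordered
dyads tied in both networks and $A, B$ those tied in exactly one;
absent–absent dyads are excluded (present-tie Jaccard, not the simple
matching coefficient) but reported, and $J := 0$ when no tie exists in
either network. For independent networks of matched density $d$ the
components give $\mathbb{E}J \approx d/(2-d)$, so J inflates with density;
`jaccard()` therefore returns the full decomposition and
`congruency_grid()` publishes densities alongside.

**The grid.** `congruency_grid()` crosses teacher cutoffs
(default $\{1,2,3\}$; 4 is excluded by default because "always play"
ratings are rare) with researcher schemes (default: three ratio, three
frequency) and reports QAP and Jaccard for the three informant pairs plus
the original-network QAP. Per-comparison seeds are derived
deterministically from one top-level seed, so reports are byte-identical
across reruns. A derived network can be degenerate — a cutoff of 0 ties
every dyad, leaving the correlation undefined; the grid records `NA` for
that cell with a message rather than aborting, while the underlying
primitives raise an error for degenerate direct calls.

## Validity bootstrap

Per-child totals (in-strength of nominations; total rating score; total
observed interactions) are correlated with outcome scores. With $n = 16$
children, normal-theory intervals are fragile, so 95\% CIs are
**percentile bootstrap** over case resamples of children (default 1,000),
the simplest method consistent with reporting "bootstrap CIs"; BCa adds
assumptions not needed here. Pearson correlation is the default, Spearman
an option. Resamples where either vector collapses to a constant (possible
at $n = 16$) are redrawn and counted. Significance is read from whether
the CI excludes 0. Coverage at the study scale ($n = 16$, true
$r = 0.6$) is checked by simulation in the acceptance suite; percentile
intervals for a correlation are known to undercover slightly at this $n$,
and the observed coverage (~0.93) sits within the accepted 0.92–0.98
band.

## The synthetic classroom generator

The generator exists so every pipeline stage is testable end-to-end and so
recovery of a known truth can be measured. Its latent state is a
play-group partition (default 4 groups of 4) with a dyadic **affinity**:
the per-cycle probability that a pair interacts, `within_group_affinity`
(0.25) inside groups and `between_group_affinity` (0.018) across, each
jittered on the logit scale (sd 0.3) to avoid an unrealistically
two-valued truth.

The three instruments are then drawn **conditionally independently** given
the affinity:

* **counts** — per cycle, each child is available with probability 0.72;
  each available unordered pair interacts with probability equal to its
  affinity. Hence $\mathbb{E}F_{ij} = T\,p_\text{avail}^2\,a_{ij}$, a
  closed form the tests verify, and no count can exceed the pair's joint
  availability;
* **ratings** — affinity plus $\mathcal N(0, 0.08^2)$ noise, cut at
  $(0, 0.08, 0.16, 0.30)$ into $\{0,\dots,4\}$;
* **nominations** — directed Bernoulli with
  $\text{logit}^{-1}(-2.8 + 8\,a_{ij})$.

Defaults were calibrated once, from the closed-form expectations above
and a small simulation check, to land on the study conditions the package
emulates — nomination density near 11\%, rating grand mean near 1.35,
pair-count mean near 1.47 over 44 cycles — and are not revisited;
`calibration_summary()` prints a generated classroom's descriptives next
to those reference values. The per-cycle dyadic Bernoulli process
simplifies the real roster-scan protocol (one focal child observed at a
time): it preserves the count marginals and the availability censoring
that ratio thresholds are designed to absorb, which is what the analysis
pipeline exercises. It does **not** model focal-child sampling artifacts,
teacher biases (seating, salience, teacher–child relationship),
correlated informant errors, negative-interaction networks, or day-to-day
nonstationarity. Consequently, passing recovery tests show the pipeline's
statistics behave correctly under the assumed measurement model — they do
not certify congruency levels in real classrooms, where informant errors
are plausibly correlated and the latent structure richer than play
groups.

Two recovery properties are exercised at the defaults: twice-chance
binarized counts recover the thresholded latent ties (Jaccard well above
0.6, averaged over seeds), and pairwise informant congruency (QAP $r$)
decreases monotonically as the configured informant noise grows.

## Numerical conventions and problem sizes

Inclusive ($\ge$) comparisons for ratio and rating thresholds versus
strict ($>$) for half-median follow the defining phrases of each rule;
with integer counts and a median of 1 the two conventions coincide.
Heterogeneous per-child availability is a config option left homogeneous
by default. Hypothesis-test simulations in the test suite use the sizes
stated with each check: 9,999 permutations against the exhaustive oracle
on 5-node networks, 500 replicates for type-I calibration at 999
permutations, 300 replicates for bootstrap coverage, 50 seeds for the
synthetic congruency and noise-monotonicity checks; these were chosen as
the smallest sizes at which the binomial error of the check is well below
the tolerance being asserted.

```{r example}
cls <- generate_classroom(synthetic_config(seed = 1))
calibration_summary(cls)
```
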