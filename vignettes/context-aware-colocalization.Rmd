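---
title: "Context-aware Markov chain models for annotation colocalization"
author: "ContextColoc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Context-aware Markov chain models for annotation colocalization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ContextColoc)
```

## The problem

Given two genome annotations — a *query* $Q$ (say, ChIP-seq peaks for an
epigenetic mark) and a *reference* $R$ (say, a family of repeats) — we want to
know whether they colocalize more (or less) than chance would predict.  Two
statistics are standard: the number of overlaps
$$K(R, Q) = \#\{\text{intervals of } R \text{ intersecting some interval of } Q\}$$
and the number of shared bases
$$B(R, Q) = \#\{\text{positions covered by both } R \text{ and } Q\}.$$
Both are large by accident whenever both annotations are large, so a null
model for the query is needed.  A further, subtler problem is confounding:
two annotations can look associated merely because both avoid assembly gaps,
or both prefer GC-rich sequence.  This package addresses both problems at
once.

## The null model

An annotation is a set of half-open intervals $[b, e)$ on $\{0, \dots, L-1\}$,
each pair separated by at least one base, or equivalently a binary sequence
$Q_0, \dots, Q_{L-1}$.  A *genome context* is a map
$\phi : \{0, \dots, L-1\} \to \Lambda$ assigning each position one of a
finite set of class labels; the positions where $\phi$ changes are *class
boundaries* (there are $c$ of them).

The null model generates the query by a two-state Markov chain whose
transition matrix depends on the local context class: with
$T : \Lambda \to \mathbb{R}^{2\times2}$,
$$\Pr[(S_{-1}, S_0, \dots, S_{L-1}) = (s_{-1}, \dots, s_{L-1})]
  = \pi_{s_{-1}} \prod_{i=0}^{L-1} T(\phi(i))_{s_{i-1}, s_i},$$
where $\pi$ is the stationary distribution of $T(\phi(0))$, in closed form
$\pi = \bigl(T_{10},\ 1 - T_{00}\bigr) / (1 - T_{00} + T_{10})$.
State 1 at position $i$ means "position $i$ is covered".  Interval and gap
lengths are geometric within a class, with class-specific means — so a
context with, e.g., gap/non-gap or GC-bin classes lets the null reproduce a
query's different densities in different genomic strata, and intervals may
freely span class boundaries.

The per-class matrices are *trained from the query itself*: for each class
$\lambda$, count the transitions
$c_{\lambda, s, s'} = 1 + \sum_{i=1}^{L-1}
  \mathbf{1}\bigl(\phi(i) = \lambda,\ Q_{i-1} = s,\ Q_i = s'\bigr)$
and row-normalize.  The pseudocount 1 (configurable via the `pseudocount`
argument of `trainChain()`) keeps all probabilities strictly positive.  Two
conventions worth making explicit, because the formula decides them:

* a transition is attributed to the class of its *destination* position
  $\phi(i)$, so at a class boundary the pair $(Q_{i-1}, Q_i)$ counts toward
  the class being entered;
* the sum starts at $i = 1$: the virtual step from $S_{-1}$ to $S_0$ is never
  counted, $S_{-1}$ exists only through the stationary initial distribution.

Training is done in run-length arithmetic over the query's interval list and
the context's run list, so it costs $O(|Q| + c)$, independent of $L$, and
counts are pooled across chromosomes.  Chromosomes are generated
independently, each starting from the stationary distribution of the class
at its own position 0.

Significance is reported through the Z-score
$Z = (A_{\mathrm{obs}} - \mathrm{E}[A]) / \sqrt{\mathrm{Var}[A]}$ and the
normal-approximation tails $1 - \Phi(Z)$ (enrichment) and $\Phi(Z)$
(depletion), where the mean and variance are *exact* under the null; only
the distributional shape is approximated.

## Exact moments via two-sided interval summaries

Both $K$ and $B$ are *separable*: a sum over reference intervals of
contributions that depend only on the query states inside each interval
(the overlap indicator for $K$; the number of covered positions for $B$).
The engine computes exact means and variances of any such statistic with a
small algebra of per-interval summaries.

For a span $[i, j)$ the *two-sided plumbus* stores, for each pair of
boundary states $(x, y) = (S_{i-1}, S_{j-1})$:
$$\mu(x,y) = \mathrm{E}[v \mid x, y], \qquad
  \sigma^2(x,y) = \mathrm{Var}[v \mid x, y], \qquad
  \Psi(x \to y) = \Pr[S_{j-1} = y \mid S_{i-1} = x],$$
where $v$ is the span's contribution.  Three facts make this work:

1. **Markov splicing.** Given the state at a shared boundary, the two sides
   are conditionally independent, so two adjacent summaries merge by summing
   out the boundary state: means add with weights
   $w_m \propto \Psi_L(x \to m)\,\Psi_R(m \to y)$, and variances combine by
   the conditional-variance decomposition (law of total variance).  The
   merge (`combinePlumbus()`) is $O(1)$ and associative.
2. **Constant-time pieces within a class.** For a single-class span the
   $n$-step matrix has the closed form
   $T^n = \Pi + (1 - a - b)^n (I - \Pi)$ ($a = T_{01}$, $b = T_{10}$, $\Pi$
   the stationary projector), and the all-zero-stretch probability is
   $T_{x0} T_{00}^{\,n-1}$.  Gap summaries ($\mu \equiv 0$) and
   overlap-statistic interval summaries need only these, one factor per
   same-class run.
3. **Doubling for shared bases.** A $B$-interval summary equals the fold of
   single-position summaries.  Within one class the summary depends only on
   the run length, so summaries for lengths $2^0, 2^1, \dots$ are built once
   per class (cached per chromosome pass) and combined along the binary
   representation of each run length: $O(\log t)$ merges for a run of
   length $t$.

A chromosome is processed by folding, strictly left to right, the
alternating gap/interval summaries, then removing the boundary conditioning
with the initial distribution ($p_{x,y} = \pi_x \Psi(x \to y)$,
`finalizePlumbus()`).  Genome totals are sums over chromosomes.  The merge
count is $O(|R| + c)$ for $K$ and $O((|R| + c)\log t)$ for $B$; it is
exposed as `combineCalls` on every `MomentResult` so the scaling is a
testable property, not a claim.  A left fold (rather than a balanced tree)
was chosen because it is simpler, has the same complexity, and keeps the
per-chromosome state a single summary.

## Exact mode

`exactNullPmf()` computes the full null PMF by a dynamic program that
carries the joint distribution of (state at the current boundary, statistic
so far): gap steps multiply by the span's $\Psi$; for $K$ each reference
interval branches on overlap/no-overlap using the same conditional
probabilities as the moment engine; for $B$ the program advances one base at
a time inside reference intervals.  Per-chromosome PMFs are convolved
directly (supports are small wherever exact mode is sensible, so FFT is
unnecessary).  Cost is quadratic — in $|R|$ for $K$, in the total reference
length for $B$ (guarded at $10^4$ bases).

Exact mode doubles as the user-facing recommendation for small references:
the normal approximation's extreme upper tail is too light when $K$ is a sum
of a few hundred dependent indicators, so normal p-values there are smaller
than the exact ones.  `colocTest()` warns below 500 reference intervals
(configurable).  Exact-mode tail p-values are inclusive,
$\Pr[A' \ge A_{\mathrm{obs}}]$.

As a third, fully independent route, `bruteForcePmf()` enumerates all
$2^{L+1}$ state sequences of a tiny chromosome and accumulates the model
probability of each.  It shares no code path with either engine beyond the
transition matrices themselves, and it is the correctness authority in the
test suite: on 200 random instances ($L \le 14$, up to 3 classes, up to 3
reference intervals, strictly positive random chains) both the moment
engine and both exact DPs must agree with enumeration to $10^{-9}$, for
both statistics.

## Contexts

* `readContext()` reads BED4 (column 4 = label); positions covered by no
  record receive a caller-chosen default label (`"background"`), so running
  with no context file at all is identical to a one-class context — the
  plain Markov chain null is the degenerate case, and the test suite checks
  the two runs agree bit for bit.
* `relativeContext()` builds the two-class inside/outside context from a
  superset reference $R_2$; `differentialColocTest()` uses it to measure
  enrichment of $Q$ in $R_1 \subseteq R_2$ *relative to* $R_2$: inside
  $R_2$ the trained chain reflects the query's behaviour across all of
  $R_2$, so only a preference of $Q$ for $R_1$ beyond its general affinity
  for $R_2$ registers as enrichment.
* `gcContext()` tiles the genome into fixed windows (default 1 kbp), labels
  windows that are at least half N with a gap class, and bins the remaining
  windows by GC fraction.  Two conventions had to be fixed because no
  standard exists: GC fraction is computed over the *non-N* bases of the
  window, and bin $k$ covers $[k/n, (k+1)/n)$ with GC $= 1$ clamped into
  the top bin (so with two bins, GC $= 0.5$ falls in the upper bin).
  Five bins plus the gap class is the default stratification.

## Numerical choices

All probability arithmetic is in plain double precision; two-state chains
are well conditioned and the quantities are probabilities and bounded
means, so no log-space machinery is needed.  Specific policies:

* $(1 - a - b)^n$ is computed by direct powering with $|1 - a - b|$ clamped
  to 1; entries of $T^n$ are clamped into $[0, 1]$.
* Merged variances are clamped at 0 from below (roundoff can produce
  $-10^{-16}$-scale values); transition matrices whose rows miss 1 by more
  than $10^{-8}$ are rejected up front.
* Unreachable boundary-state pairs ($\Psi = 0$) carry sentinel zero
  mean/variance (sentinel $\mu = 1$ for the overlap summary's conditioning
  on an impossible all-zero event) and receive zero weight in every merge,
  avoiding 0/0 without branching the formulas.
* The degenerate stationary case ($T_{00} = 1$, $T_{10} = 0$) is defined as
  $\pi = (1, 0)$; it cannot arise from pseudocounted training.
* A zero null variance (e.g. an empty reference) yields a result with
  status `"degenerate"` and omitted p-values rather than a guessed Z.
* Log-scale p-values use `pnorm(..., log.p = TRUE)`, so $|Z| > 38$ reports
  a finite log10 tail while the linear-scale value prints 0.

## The generative sampler and the synthetic benchmark

`sampleAnnotation()` draws from the null by alternating geometric sojourn
times (re-drawn at class boundaries, which is exact by memorylessness), so
sampling costs $O(\text{switches} + c)$ rather than $O(L)$.  It is the
Monte-Carlo arm of the validation: empirical transition frequencies,
coverage, and the moments of $K$ and $B$ over repeated draws must match the
analytic values.

`synthAnnotation()` builds the fixed-length-interval annotations used in
the validation experiments: exactly $n$ intervals of length $\ell$,
configuration drawn uniformly among all valid placements via the
stars-and-bars construction (sorted uniform draws over the free space),
deterministic given a seed.  This emulates the synthetic design on which
the method family is conventionally benchmarked — a large chromosome, a
dense fixed-length query, references from 200 to 20\,000 intervals — at
desk scale.  What it does *not* emulate about real annotations: interval
lengths are constant rather than heavy-tailed, placements are uniform
rather than clustered, and there is no correlation between query and
reference beyond what the null induces.  Passing tests on these fixtures
therefore validate the *mathematics* (moments, PMFs, calibration under the
model), not the biological adequacy of the Markov null for any particular
data set.

## Validation experiments and their sizes

The suite (`tests/testthat/test-acceptance.R`) and the reproduction script
(`scripts/acceptance.R`) run the same experiments; sizes were chosen so the
whole battery completes in a few minutes on one CPU while keeping every
check statistically meaningful:

* **Analytic anchor.** The enrichment p-value at $Z = 3$ must equal
  $1 - \Phi(3) = 0.00135$ to five decimals.
* **Oracle equivalence.** 200 random tiny instances ($L \le 14$) against
  brute-force enumeration, tolerance $10^{-9}$, both statistics, all three
  computational routes.
* **Medium-scale consistency.** $L = 10^5$, six-segment three-class
  context, $|R|$ up to 300: exact-PMF mean/variance vs. the moment engine.
* **Type-I calibration.** A chain trained from a 200-interval query at
  $L = 10^5$ generates 2\,000 replicate queries; p-values are computed
  under that same chain's exact moments.  The rejection rate at
  $\alpha = 0.05$ must land in $[0.03, 0.07]$ and empirical moments within
  4 standard errors of the analytic ones.  This design isolates the
  p-value transform: the generator and the null coincide by construction.
  (The variant that re-trains the chain on every replicate — the full
  pipeline as applied to real data — is measurably *conservative*, with a
  rejection rate near 0.01–0.02 at this scale, because the re-estimated
  transition probabilities absorb each replicate's realized coverage.
  That conservatism is a property of plug-in nulls generally, worth knowing
  when interpreting borderline p-values.)
* **Parameter recovery.** A single-class chain with mean interval 20 bp and
  mean gap 50 bp, sampled at $L = 10^7$ and re-trained, must be recovered
  within 1% relative error per entry.  The density was chosen so each
  transition type is observed about $10^5$ times, making the 1% bound a
  $>3\sigma$ property; a sparse chain (mean gap in the kilobases) would
  put the sampling error itself near 1% and turn the check into a coin
  flip.
* **Complexity.** Merge counts for $|R| \in \{200, 2000, 20000\}$
  (length-500 intervals, $L = 2 \times 10^7$): log–log slope within
  $[0.9, 1.1]$ for $K$, and for $B$ bounded by a constant times
  $(|R| + c)\log_2 t$.
* **Small-reference conservatism.** 50 instances at $|R| = 200$
  ($L = 10^6$, 500-interval query, 25% coverage — the benchmark density):
  at the first support point with $Z \ge 3$ the exact tail must be at
  least the normal tail in $\ge 90\%$ of instances.  This is the
  qualitative fact behind the exact-mode recommendation.

## Limitations

* P-values rest on the normal approximation of an exact-moment null;
  the shape error is only controlled empirically (and exact mode exists
  for the regime where it is known to matter).
* Contexts are categorical; quantitative covariates must be discretized
  (as `gcContext()` does).
* The chain is first-order: interval and gap lengths are geometric within
  a class, which underweights heavy-tailed length distributions seen in
  some real annotation types.
* Only the query is modeled as random; the reference is fixed, and the
  roles are not exchangeable.
* Strand is ignored throughout.
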