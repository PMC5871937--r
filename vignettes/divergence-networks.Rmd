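---
title: "Divergence profiles and column networks for structured-RNA alignments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Divergence profiles and column networks for structured-RNA alignments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnadivnet)
```

## The problem

tRNAs are charged with their amino acid by aminoacyl-tRNA synthetases,
which recognize specific nucleotide positions — identity determinants —
within the tRNA body. Locating such positions from sequence compendia is
a statistical problem with two complementary faces: finding columns of a
multiple alignment whose nucleotide distribution is *specific to a
subclass* (an amino-acid class within a domain of life), and finding
columns that *depend on each other* within the molecule (stem pairs,
tertiary contacts, compensatory clusters). `rnadivnet` implements one
estimator for each face, plus the synthetic ground-truth generator used
to calibrate both.

Nothing in the package is tRNA-specific beyond convenience defaults:
column labels are opaque strings, and the canonical tRNA numbering
(`trna_standard_labels()`) is shipped as an optional map, never assumed.

## The divergence statistic

Each column *i* is a categorical variable over the five states
$(a, c, g, u, \text{gap})$. Writing $q_i$ for its distribution over the
whole alignment and $p_{ij}$ for its distribution within subclass $j$,
the importance of column *i* for subclass *j* is the Jensen–Shannon
divergence

$$
l_{ij} = \tfrac12\, d(p_{ij}, m_{ij}) + \tfrac12\, d(q_i, m_{ij}),
\qquad m_{ij} = \tfrac12 (p_{ij} + q_i),
$$

with $d(x,y) = \sum_k x(k)\,\log x(k)/y(k)$ and $0 \log 0 = 0$. The
mixture $m_{ij}$ is the only smoothing in the estimator: it removes every
zero-denominator term, so no pseudocounts are needed (a Laplace
`pseudocount` argument exists for very small strata, default 0).

**Units.** All divergences use log base 2, so $l \in [0, 1]$ bits, the
maximum is attained exactly at disjoint supports, and $\sqrt{l}$ is a
proper metric. The conventional significance cutoff of 0.2 is applied on
this scale. A caveat worth stating plainly: the literature quoting that
cutoff rarely states its log base, so the packaged default (0.2 bits,
strict inequality, ties do not exceed) is a declared convention, not a
reproduction — it is a tunable parameter of `importance_profile()`.

**Reference population.** $q_i$ is computed over the full alignment by
default, even when the selector fixes both the amino-acid class and the
domain of life. Whether the natural comparison population is the whole
compendium or the domain-of-life subset is genuinely ambiguous in
practice; `reference = "domain"` switches to the subset.

**Gaps.** The gap state is counted as a fifth state by default — it is a
bookkeeping convenience that makes variable-region columns visible to the
statistic — and can be excluded (`include_gap = FALSE`), in which case
nucleotide frequencies renormalize over non-gap rows per column.

## The permutation null

Observed $l_{ij}$ values must be separated from sampling noise: even
under label independence, a finite stratum of size $k$ has
$l_{ij} > 0$. The null redraws the stratum membership uniformly at fixed
size $k$ (equivalently, permutes the class-label vector over rows),
recomputes $l^{*}_{ij}$ for every column, and repeats `null_reps` times.
Per-column quantiles at 0.95 / 0.99 / 0.999 are reported;
`exceeds_null` uses the 0.99 quantile, a fixed convention chosen because
no standard level exists for this statistic — all three quantiles are
emitted so users can apply their own. The production default is
`null_reps = 1e5` (the point at which the null quantiles are stable to
the third digit); the test suite and the acceptance script run 1e4 and
2000 replicates respectively, which only widens quantile noise and is
noted where it matters.

No multiple-testing correction is applied across columns: the fixed
cutoff plus the per-column null is the calling device, and the package
keeps that contract.

Second-order structure — signal at a column that is high but *not*
class-specific, e.g. driven by base-pairing — can be probed with
`conditional_profile()`, which conditions every other column on a chosen
state at an anchor column. The package deliberately stops at the
computation: no thresholding rule is imposed on conditional profiles,
because none is established; interpretation is left to the analyst.

## Classification against a reference list

`classify_determinants()` reproduces the standard literature-comparison
table. Given a reference list of experimentally established determinants
(plain text, one label per line, pair notation `3-70` expanding to both
members — note `-1` is a label, not a pair), every column receives
exactly one status: **confirmed** (in the list, above cutoff),
**low significance** (in the list, at or below cutoff), **suggested**
(above cutoff, not in the list), or unremarkable. An example list for
bacterial Gly tRNAs ships in
`inst/extdata/gly_bac_reference_determinants.txt`.

## The column network

The second estimator treats columns as nodes of a Bayesian network
(a probabilistic DAG): an edge means probabilistic dependence, absence
of an edge conditional independence; edge direction carries no causal
meaning. Local models are multinomial with the four nucleotide states.
Gap handling differs from the divergence module by design: a gap is
missing data here, so each family (child plus parents) is fit on its
complete-case rows — sparse insertion columns act as rare events in
correspondingly reduced datasets — and columns whose gap fraction
exceeds `gap_threshold` (default 0.5) are excluded from the node set
with a logged report, since majority-gap columns carry more alignment
artifact than signal.

**Score.** "MDL" is concretized as penalized maximum log-likelihood,

$$
\text{score}(G) = \sum_{v} \Big[ -\ell\ell(v \mid \mathrm{pa}(v))
  + w \cdot \tfrac{k_v}{2}\, \log N_v \Big],
$$

with $k_v$ the free-parameter count $(r_v - 1)\prod_{u \in \mathrm{pa}(v)} r_u$,
$N_v$ the family's complete-case rows, natural logs, and lower scores
better. `penalty_weight` $w$ (default 1, the BIC-equivalent form) is the
underfitting knob: larger values prune harder, and the default errs
toward underfitting so that a retained edge is trustworthy.

**Search.** Greedy hill-climbing over single-edge additions, deletions
and reversals, best-improvement acceptance, ties broken by enumeration
order (parent index, then child index) for determinism, stopping at a
local optimum; acyclicity is enforced at every step and `max_parents`
(default 4) bounds table sizes — an artifact constraint, not a modeling
claim. Restart 1 starts from the empty graph; further restarts start
from seeded random DAGs with edge probability $2/(p-1)$. The best local
optimum over all restarts wins. On four nodes the search provably
reaches the global optimum of all 543 DAGs in ≥95% of trials (tested
against exhaustive enumeration); beyond that, no global claim is made.

**Edge strengths.** The strength of an edge is the exponentiated score
delta from deleting it with everything else fixed — a likelihood-ratio
style quantity comparable within one network only. Because the score is
a penalized (not marginal) likelihood, this is an approximation to a
Bayesian marginal-likelihood ratio, stated as such. At realistic sample
sizes the raw ratio overflows double precision (deltas of thousands of
nats), so the edges table carries both `strength` (may be `Inf`) and
`log10_strength`; printing and DOT labels use the log10 form.

**Class node.** The subclass variable can enter as an ordinary
multinomial node (`include_class_node = TRUE`), conventionally labeled
`"100"` so it cannot collide with position labels; edges touching it
read as class-association.

`to_cpdag()` reduces a learned DAG to its Markov equivalence class
(skeleton + v-structures, orientations propagated by the standard
closure rules), which is the honest granularity at which learned edge
directions should be read.

## The synthetic world

`synthetic_spec()` states the generator's world; `generate_alignment()`
draws from it, returning the alignment plus a ground-truth record
(including each planted determinant's closed-form expected JSD against
the pooled distribution, computed from the planted parameters). The
defaults are one fixed choice of a realistic desk-scale world, made once:

- 5 amino-acid classes × 400 sequences = 2000 rows — the size at which
  class strata remain in the hundreds, as in real per-class subsets;
- 76 columns, matching the canonical tRNA length;
- a 7-pair stem block at complementarity 0.95 (real acceptor stems pair
  near-perfectly, with occasional non-canonical pairs); an optional
  `wobble` fraction adds g–u pairs, default 0;
- one determinant column per class with within-class frequency 0.97 on
  one state (real identity determinants are near-invariant within their
  class), giving an expected JSD of 0.32 bits against the pooled
  distribution;
- four invariant columns, and a 4-column variable region at 60% gaps.

What the generator does **not** model, on purpose: phylogenetic
correlation between rows. Rows are exchangeable, so a green calibration
test establishes that the statistic and its null behave correctly under
the stated model — not that real tRNA compendia, which carry phylogenetic
autocorrelation, meet the null's independence assumptions. On real data
the permutation null is anti-conservative to an unknown degree; this is
intrinsic to label-permutation nulls on phylogenetically related
sequences and is the main caveat for interpretation.

## Numerical and degenerate-input conventions

- Residues normalize on load: case-folded, `t`→`u`, `.`→`-`; anything
  else (ambiguity codes, modified-base symbols) is rejected with
  row/column coordinates. Real compendia curate such symbols before
  import; the loader refuses to guess.
- Empty strata and empty-support columns are errors, not NAs: a
  distribution over zero rows is undefined and silently propagating it
  would poison downstream calls.
- A hill-climbing move must improve the score by more than 1e-9 to be
  accepted, so floating-point ties terminate the climb.
- All-constant inputs return the empty network with a message rather
  than an error — a legitimate degenerate answer.
- Every stochastic step (generator, permutation null, restarts) flows
  from one integer seed per entry point; repeated runs are
  byte-identical, which the suite asserts end to end.

## Known limitations

- The divergence and network modules read gaps differently (fifth state
  vs missing data); both conventions are documented and deliberate, but
  profiles and networks over gap-rich regions are not directly
  comparable.
- Hill-climbing guarantees are local beyond 4 nodes; planted-structure
  recovery is demonstrated at desk scale (34 columns), not proven.
- The 0.2-bit cutoff inherits the literature's unstated log base; treat
  cross-study comparisons of absolute divergences with care.
- No phylogenetic correction (see above); no alignment construction; no
  secondary/tertiary structure prediction.
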