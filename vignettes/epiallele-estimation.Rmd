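---
title: "Estimating epiallele frequencies under conversion and sequencing error"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating epiallele frequencies under conversion and sequencing error}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epifreq)
```

## The statistical model

A bisulphite amplicon read covering $n$ CpG sites carries a methylation
pattern $\mathbf{k} \in \{0,1\}^n$ (0 unmethylated, 1 methylated).  The
sample defines a distribution $\theta$ over the $2^n$ patterns, indexed so
that $k-1$ is the binary reading of the pattern (leftmost site = most
significant bit); this makes index order and lexicographic string order
coincide, which is how all tables in the package are sorted.

Two error processes distort what is sequenced.  Incomplete bisulphite
conversion leaves an unmethylated cytosine unconverted with probability
$\varepsilon$, so it registers as methylated; conversion never affects
methylated cytosines, so this error is strictly $0 \to 1$.  Sequencing
then flips the registered state of site $s$ in either direction with
probability $\eta_s$.  Per site, the conditional probability of
registering state $\ell_s$ given true state $k_s$ is the row-stochastic
matrix

$$E_s =
\begin{pmatrix} 1-\varepsilon & \varepsilon \\ 0 & 1 \end{pmatrix}
\begin{pmatrix} 1-\eta_s & \eta_s \\ \eta_s & 1-\eta_s \end{pmatrix},$$

conversion first, read error second — the same order in which the
physical processes act, and the order the simulator uses.  Sites are
corrupted independently, so the pattern-level misclassification matrix is
the Kronecker product $M = E_1 \otimes \cdots \otimes E_n$ and a read
drawn from $\theta$ registers as pattern $\ell$ with probability
$\phi_\ell = \sum_k \theta_k M_{k\ell}$.  Reads are independent, so the
observed counts $y$ are multinomial in $\phi$ and the log-likelihood is

$$L(\theta \mid y) = \sum_k y_k \log\Big(\sum_j \theta_j M_{jk}\Big),
\qquad \theta \in S = \Big\{\theta : \theta_k \ge 0,\ \sum_k \theta_k = 1\Big\}.$$

`estimate_patterns()` maximises $L$ over $S$.  The maximiser is unique,
and observed patterns whose estimate is *identically zero* are reported
as spurious: the fit explains every one of their reads as error acting on
other patterns.  Inverting $M$ on the naive proportions $y/N$ does not
work — $M$ maps $S$ onto a strictly smaller simplex, and realistic data
(with many zero counts) sit on parts of the boundary that the shrunken
simplex excludes, so the inverted estimate has negative components.
`inversion_estimate()` exists to demonstrate exactly this.

### Model assumptions

* $\varepsilon$ is homogeneous across sites and known (estimated
  externally, e.g. from non-CpG cytosines or unmethylated spike-ins);
  the package does not estimate it.
* Sequencing error is symmetric ($0\to1$ and $1\to0$ equally likely at a
  site) but may vary by site, e.g. degrading towards read ends.
* Sites are corrupted independently given the true pattern; reads are
  independent (no differential PCR amplification of epialleles).
* Every read covers all $n$ sites; reads with missing pattern positions
  are out of scope.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `epsilon` | — | non-conversion probability, unitless in $[0,1)$; order $10^{-2}$ in practice |
| `eta` | — | per-site read error, unitless in $[0,0.5)$; scalar is broadcast to all sites; a warning is issued above 0.1 |
| `mode` | `"fast"` | `"fast"` restricts the support to observed patterns; `"slow"` searches all $2^n$ |
| `tol` | `1e-10` | stop when the log-likelihood gains fewer nats than this per EM sweep |
| `max_iter` | `1e5` | EM sweep cap per optimisation stage |
| `zero_tol` | `1e-5` | components below this after convergence become boundary-snap *candidates* |

The estimates are insensitive to `tol` well before the default; the
default is chosen so that components genuinely converging to zero have
decayed far below `zero_tol` when iteration stops.  `zero_tol` only
nominates candidates — whether a candidate is zeroed is decided by
likelihood comparison, never by magnitude.  This matters because real
fits can have components that are tiny (down to $10^{-5}$–$10^{-4}$) yet
genuinely positive: zeroing them measurably lowers the likelihood.

## The optimiser and the boundary

The EM iteration
$\theta_j \leftarrow \theta_j \sum_k y_k M_{jk} / (N \phi_k)$
is the natural fixed-point scheme for this likelihood: it preserves the
simplex, increases $L$ monotonically, and leaves exact zeros exact — so
the same routine optimises over any restricted support.  Because the
constrained MLE is unique, the result is start-independent; the default
start is the additively smoothed $(y_j + \tfrac12)/(N + m/2)$ over the
$m$ searched patterns, strictly interior as EM requires.

EM converges into the boundary only asymptotically, so a converged
interior solution is *refined*: all components below `zero_tol` are set
to zero — jointly first, then singly — the remaining mass is renormalised
and re-optimised over the reduced support, and the boundary point is
adopted whenever its likelihood is not lower than the current one (ties
within $10^{-9}$ nats prefer the boundary, i.e. the more parsimonious
support).  Adoption can create new candidates, so the step repeats until
no candidate passes.  Re-optimising after snapping (rather than only
renormalising) is a deliberate choice: it makes the comparison a fair
one between maximised likelihoods on the two supports.

Degenerate inputs behave sensibly: with $\varepsilon = \eta = 0$, $M$ is
the identity, one EM sweep lands exactly on $\hat\theta = y/N$ and
nothing is snapped (zeroing an observed pattern would give $-\infty$).
For $n = 1$ the model collapses to a binomial with a $2\times2$ error
matrix, and the estimator reproduces the closed-form inverted-and-clipped
binomial MLE.  The slow mode is refused for $n > 8$ (the search space
grows as $2^n$) unless forced, and the fast mode warns beyond ~200
observed patterns.

### A note on zero-calls near the boundary

The spurious/real call is a statement that the *exact* MLE lies on the
boundary.  Components whose removal costs only $\sim 10^{-2}$ nats of
log-likelihood are near-ties: any optimiser whose convergence accuracy
is coarser than that cost will report such components as zero and call
the pattern spurious, while an exact optimiser keeps them positive.
`epifreq` resolves the ambiguity by always comparing *re-optimised*
likelihoods at the stated $10^{-9}$ tie tolerance, and the bundled tests
verify the resulting fits against a $10^5$-point random search of the
simplex and against random EM restarts ($10^{-5}$ componentwise
agreement).  Users comparing against other implementations should expect
disagreement precisely (and only) on patterns in this near-tie regime —
the package's diagnostic is the likelihood audit: re-fit with the
disputed pattern forced to zero and compare `logLik()`.  On the bundled
six-site dataset, one 1-read pattern sits at $7\times10^{-5}$ with a
0.012-nat cost of removal; the bundled eight-site amplicon has one at
$3\times10^{-5}$ costing 0.001 nats.  Classification at any threshold
$K \ge 10^{-4}$ is unaffected by which way such patterns are called.

## What the simulator does and does not emulate

`simulate_reads()` draws $N_{\mathrm{read}}$ true patterns from $\theta$
(multinomial) and corrupts each read site by site — non-conversion with
probability $\varepsilon$ on unmethylated sites, then a symmetric flip
with probability $\eta_s$ — retaining each read's latent true pattern so
that simulation studies have exact spurious/real ground truth.  This is
distributionally identical to one multinomial draw from $\phi = \theta M$
(available as `method = "multinomial"`), and the test suite checks the
two routes against each other.  `truncate_distribution()` builds sparse
"true" distributions by flooring and renormalising (renormalisation is
our choice; a distribution must sum to one).

The simulator reproduces exactly the error structure the estimator
assumes — which is the point: passing recovery tests demonstrates
correctness of the inference, not robustness to model misspecification.
Real data additionally contain PCR amplification bias, read-quality
variation correlated along reads, non-homogeneous conversion rates and
incomplete reads; none of these are simulated, so simulation results say
nothing about them.

The bundled reference datasets are `table1_fixture()` — a six-site locus,
$N = 2000$, $\varepsilon = 0.005$,
$\eta = (0.008, 0.006, 0.006, 0.006, 0.006, 0.008)$, 6 true epialleles,
24 observed patterns — and `table2_fixture()`, a real honey-bee amplicon
($n = 8$, $N = 1793$, 36 observed patterns, conventionally analysed with
$\varepsilon = 0.01$, $\eta = 0.02$).

## Evaluation

With known truth (simulations), `classify_at_threshold()` declares a
pattern spurious when its statistic — the estimate $\hat\theta_i$ or the
naive $y_i/N$ — is $\le K$, and counts TP/FP/TN/FN over observed
patterns only (a tie at $K$ is declared spurious).  `tpr_fpr_curve()`
sweeps a closed grid containing 0, 1 and every distinct statistic value,
so the step functions are exact; TPR and FPR are non-decreasing in $K$
by construction.  This is a benchmarking classifier, not a hypothesis
test: patterns are not independent and $K$ has no p-value calibration,
which is why the package exposes it for evaluation rather than
inference.

## Problem sizes in the test suite

The suite exercises exhaustive encode/decode checks to $n = 10$, dense
matrix oracles to $n = 8$, Dirichlet random searches of $10^5$ points at
$n \le 3$, goodness-of-fit simulations of $10^6$ reads at $n \le 3$, and
ten recovery replicates of $10^5$ reads at $n = 6$ — sizes chosen to make
every oracle exact or statistically decisive while keeping a full run in
the order of a minute.

## Known limitations

* No uncertainty quantification on $\hat\theta$ (no standard errors,
  intervals or posteriors); the spurious call is a point-estimate
  statement.
* $\varepsilon$ and $\eta$ must be supplied; misspecifying them biases
  the estimates, particularly $\eta$ (both spurious and real patterns
  respond to it).
* Reads with missing sites are ignored by design; pattern extraction
  from alignments is upstream of this package.
* Near-boundary zero-calls are sensitive to optimiser accuracy in any
  implementation; see the note above for how this package makes the
  call reproducible.
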