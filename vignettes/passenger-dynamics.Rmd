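---
title: "Passenger mutation dynamics during tumor clonal expansion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Passenger mutation dynamics during tumor clonal expansion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(passengr)
```

## The model

`passengr` studies neutral (passenger) mutation accumulation during the
clonal expansion of a tumor. The population is a continuous-time multi-type
branching process: every cell divides at rate $b$ (per day) and dies at rate
$d$, independently of the mutations it carries — passengers are selectively
neutral by definition. At each division, with probability $u$ one daughter
cell acquires a new, never-seen-before mutation (infinite-allele
assumption) and founds a new *type*. The process starts from a single
founder cell (type 0) and is studied conditional on reaching a final size
of $M$ cells.

Two parameter combinations matter:

* the **death–birth ratio** $\delta = d/b$, which is also the extinction
  probability of a single cell's lineage. Everything about frequencies,
  fixation and tree shapes depends on the rates only through $\delta$; $b$
  merely sets the clock. The package requires $\delta < 1$ (supercritical
  growth) — every closed form carries a $1-\delta$ denominator.
* the **passenger mutation probability** $u$ per division. The default
  $u = 0.015$ is the product of a typical point mutation rate per division
  ($\sim 5\cdot10^{-10}$) and the exome length ($\sim 3\cdot10^7$ bp), i.e.
  it counts exome-wide passengers. The default $b = 0.25$/day is a typical
  colorectal value; $\delta$ in tumors plausibly ranges from $\sim0.72$
  (fast-growing metastases) to $\sim0.99$–$0.999$ (slow early lesions).

Mutations whose lineage never dies out are called **successful** and are
labeled $k = 1, 2, \dots$ by order of appearance. The closed-form layer
provides, among others:

* fixation probability $\rho_k = [u/(u - \log\delta)]^k$
  (`fixation_probability()`), with an independent quadrature cross-check
  integrating over the Poisson-distributed population size at appearance
  (`fixation_probability_integral()`);
* the eventual-frequency law $F_k(\alpha) = 1 - [1 -
  \log(1-\alpha(1-\delta))/u]^{-k}$ (`frequency_cdf()`), its density,
  median, and the conditional law given the origin size $z$;
* backward-looking estimators of the population size when an observed
  mutation arose, $\hat z_{\rm ML} = -1/\log(1-\alpha(1-\delta))$
  (`zhat_ml()`, `zhat_map()`);
* the expected cumulative spectrum: $\bar m_s(\alpha) =
  u(1-\alpha)/((1-\delta)\alpha)$ subclonal mutations above cell fraction
  $\alpha$, $\bar m_c = \delta u/(1-\delta)$ clonal passengers
  (`expected_subclonal()`, `expected_clonal()`, `theory_table()`).

### Phylogenies of the first three successful mutations

Type 0 plus the first three successful mutations can form six rooted
topologies, from the star (all three arise on the founder background) to
the linear chain (each arises in the previous one's lineage).
`tree_probabilities()` evaluates their closed-form likelihoods from
$\rho_1$, $\rho_2$ and the conditional mean subclonal fractions
$\mathrm{sub}_1, \mathrm{sub}_2$ obtained by quadrature. Fast growth
($\delta \approx 0.7$) makes the star tree dominant; slow growth
($\delta \approx 0.99$) the chain — tree shape is informative about
$\delta$ independently of mutation counts.

These formulas rest on two approximations: the probability that a later
mutation arises within an earlier one's lineage is taken equal to that
lineage's eventual mean fraction, and one conditional-independence step
$P(B\mid A\cap C) \approx P(B\mid C)$. They are accurate to a percent or
two but *not* exact; the simulator (below) resolves the residual error, and
the test suite deliberately documents where the difference is larger than
Monte Carlo noise at 2,000 runs (notably the star and the two
single-branch topologies at $\delta = 0.72$). The six values are therefore
*not* renormalized to sum to 1 (they sum to within 1% of it for the
$\delta$ range of interest); `normalize = TRUE` gives a rescaled
convenience view only.

## The simulator

`simulate_clone_genealogy()` is an exact Gillespie simulation written at
the *clone* level: cells within a clone are exchangeable, so it suffices to
track clone sizes and sample the clone hit by each birth/death event
proportional to its size (a Fenwick tree makes that $O(\log\,\#\text{clones})$
per event; the core is compiled). This is orders of magnitude cheaper than
cell-level simulation and has exactly the same law. Each new clone records
its parent, origin time, and the total population size $z$ just before it
appeared. Runs stop at extinction, at `stop_size` cells, or at a
`max_events` safety cap (reported as `"truncated"`, never silently).

Event waiting times are drawn (exponential with rate $N(b+d)$) so origin
times are available; all summary statistics are size-indexed, and
`track_time = FALSE` skips the draws, which is flagged in the output.

### Deciding "successful" and "fixed" at a finite stop size

A run stops at $M$ cells, but success and fixation are statements about
$t \to \infty$. The package resolves them *exactly* using the limit law of
the supercritical linear birth–death process: each of the $m$ cells
currently carrying a mutation leaves a surviving lineage independently with
probability $1 - \delta$, and each surviving lineage's long-run size weight
is Exp(1) on a common scale. Drawing $S_m \sim \mathrm{Bin}(m, 1-\delta)$
and $S_{nc} \sim \mathrm{Bin}(M - m, 1-\delta)$ once per mutation gives,
coherently from the same draw:

* successful $\iff S_m \ge 1$ (probability $1-\delta^m$);
* fixed $\iff$ successful and $S_{nc} = 0$ (probability $\delta^{M-m}$);
* eventual frequency $= 1$ if fixed, otherwise
  $\mathrm{Beta}(S_m, S_{nc})$.

`classify_successful()` reports both the frequency at stop
($m/M$) and this eventual-frequency projection. The distinction matters
for slow growth: at $\delta = 0.99$ and $M = 5{,}000$ clone fractions have
not yet stabilized, and only the eventual projection is comparable to the
analytic eventual-frequency law. In a pure birth process ($d = 0$) the
classification degenerates correctly: every extant mutation is successful
and none ever fixes, because the founder cell is immortal.

Default problem sizes are chosen so that validation runs on a laptop-class
budget: ensembles use `stop_size` 5,000 and 2,000 surviving runs (the
event count per surviving run grows like $M(1+\delta)/(1-\delta)$, so
$\delta = 0.99$ dominates the cost at roughly $10^6$ events per run).
Collection conditions on survival (probability $1-\delta$ per attempt) and,
for tree statistics, on at least three successful mutations; attempts are
capped at ten times the expected number, with an explicit error beyond.
One root seed set before collection makes a whole ensemble reproducible;
runs are collected sequentially from that single stream.

## Fitting the allele-fraction spectrum

For a diploid tumor with heterozygous mutations and no loss of
heterozygosity, allele fraction is half the cell fraction, so the expected
number of mutations with allele fraction in $(\alpha, 0.25]$ is

$$ a\left(\frac{1}{\alpha} - \frac{1}{0.25}\right), \qquad
   a = \frac{u}{2(1-\delta)}. $$

The pipeline mirrors how such data are analyzed in practice:

1. `filter_samples()`: keep near-diploid (ploidy in $[1.8, 2.2]$, closed
   interval) and high-purity ($\ge 0.70$, inclusive) samples, with an audit
   trail of exclusions. Missing metadata excludes a sample, it never
   crashes the cohort.
2. `correct_allele_fraction()`: divide observed fractions by purity;
   corrected values above 0.5 are flagged as potentially clonal/aneuploid
   but retained (the window removes them).
3. `cumulative_curve()`: inside the window $[0.12, 0.25]$ (lower edge:
   detection power; upper edge: clonality risk), at each observed fraction
   count the mutations *strictly* above it and $\le 0.25$. Strict
   inequality fixes tie behavior: duplicated fractions do not count each
   other.
4. `fit_neutral_model()`: ordinary least squares of the counts on
   $1/\alpha - 4$ *through the origin* (the form vanishes at
   $\alpha = 0.25$), with a $t$-based 95% CI on the slope and $R^2 = 1 -
   SS_{res}/SS_{tot}$ about the mean count. $R^2$ for a through-origin fit
   is convention-dependent; this choice makes a flat curve score 0 and is
   stated so results are reproducible.
5. `delta_from_fit()`: $\delta = 1 - u/(2a)$ for an assumed $u$; values of
   $a < u/2$ are reported as an error (no valid $\delta$ — evidence
   against a neutral spectrum at that $u$). Two coefficient conventions
   circulate for this spectrum ($u/(1-\delta)$ vs $u/(2(1-\delta))$); the
   package adopts $a = u/(2(1-\delta))$ throughout, which is the one
   consistent with converting a median MSS coefficient of $a = 2.86$ into
   $\delta = 0.997$ at $u = 0.015$.

`classify_msi()` separates hypermutated (MSI) from stable (MSS) samples by
total mutation burden; the threshold is configurable with a default of 500
exome mutations (the usual bimodal split), strict inequality for the MSI
call. It never enters any quantitative result in this package.

### The synthetic generator

`generate_synthetic_table()` stands in for real cohort data (the package
deliberately ships no patient data). It emulates exactly the sampling
layers the model predicts plus the sequencing readout:

* mutation count Poisson with mean $\bar m_s(\alpha_{\min})$;
* cell fractions by inverse transform from the spectrum density
  $\propto 1/\alpha^2$ on $[\alpha_{\min}, 1]$;
* allele fraction $= \text{purity} \cdot \text{cell fraction}/2$
  (diploid, heterozygous, defaults purity 0.85 — a typical passing-sample
  average — and depth 100, exome-like);
* read counts Binomial at Poisson per-site depth.

What it does **not** emulate: copy-number change and LOH, subclonal
drivers, variant-calling errors and power loss near the detection limit,
shared trunk mutations across samples, and over-dispersed sequencing
noise. Passing end-to-end tests on these tables therefore demonstrates
internal consistency of generator + pipeline under the model's own
assumptions, not robustness to real-data artifacts.

### A caveat the test suite documents deliberately

The cumulative curve's evaluation points share one Poisson realization of
the in-window mutation count, so neighboring counts are strongly
correlated and the *residual-based* slope SE of the least-squares fit
understates the replicate-to-replicate spread of $a$ — by around a factor
of seven at $a = 2.5$, where a typical sample has only $\sim 11$ in-window
mutations. A coverage simulation in the test suite computes this
directly: nominal-95% CIs cover the generating $\delta^\*$ in far fewer
than 95% of replicates when $\delta^\*$ is large (coverage falls from
$\sim$0.9 at $\delta^\* = 0.97$, where sparse curves make the CI wide, to
$\sim$0.2 at $\delta^\* = 0.997$), and the corresponding check is left
failing by design rather than silenced. The point estimate of $a$ is
nearly unbiased; it is only
the naive CI that is optimistic. Users who need calibrated uncertainty for
single-sample fits should bootstrap over mutations rather than trust the
regression CI; the regression CI is retained because it is the field's
customary output for this fit.

Also of note: at $u = 0.015$ the model itself predicts only
$a(1/0.12 - 4) \approx 4.3 a$ mutations in the fitting window, so for
$\delta^\* \lesssim 0.97$ ($a \le 0.25$) most samples do not even yield
the two points a fit needs. Coverage statistics are therefore computed
over replicates with a valid fit.

## Numerical choices

* Quadrature uses `stats::integrate` at `rel.tol = 1e-10`. The fixation
  integral over origin sizes runs on $(0, \infty)$ with a log-space
  integrand; the mean-fraction integrals $\int_0^1 \alpha g_k\,d\alpha$
  are evaluated under the substitution $\alpha = 1 - e^{-t}$, which
  removes the integrable endpoint singularity that appears at
  $\delta = 0$ and avoids cancellation at large $t$.
* $\delta = 0$ is handled as an exact limit (fixation 0, expected clonal
  count 0, uniform $z{=}1$ law) — $\log 0$ is never evaluated.
* $\delta \ge 1$ is rejected at construction, once, in
  `branching_params()`.
* Tree probabilities outside $[0,1]$ by more than $10^{-12}$ raise an
  error rather than being clipped; within that slack they are clipped.
* Filter boundaries are inclusive (ploidy $[1.8, 2.2]$, purity
  $\ge 0.70$); cumulative counts use strict $>$ with $\le$ at the 0.25
  cutoff; the MSI call uses strict $>$.
* Cell fractions and allele fractions are never mixed in one column:
  column and argument names carry the distinction, and only
  `allele_count_in_window()` plus the cohort pipeline speak allele
  fractions (the diploid factor 2 is fixed there).

## Known limitations

* The tree likelihoods cover only the first three successful mutations;
  no inference of trees from observed data is attempted.
* No LOH, copy-number change, drivers, spatial structure, or
  growth-plateau phase; the model is pure exponential-phase neutral
  evolution. The closed-form median of the first mutations' frequency law
  is used as-is; near-boundary rounding of published summaries (e.g.
  "below 5%" vs a computed 5.3% at $\delta = 0.72$) is not asserted.
* Derivation-only intermediates of the theory (per-lineage exponential
  limits, the $\beta[1,i]$ law, the recursive ladder behind the spectrum)
  have no runtime representation; only their closed-form consequences do.
* The simulator's successful/fixed calls are exact in law but are still
  Monte Carlo draws at a finite stop; a larger `stop_size` sharpens
  per-run frequencies but not the Bernoulli classification itself.
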