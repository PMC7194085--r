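---
title: "Composition-heterogeneous phylogenetic inference with codon-degenerate recoding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Composition-heterogeneous phylogenetic inference with codon-degenerate recoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Two evolutionary artifacts routinely mislead phylogenetic inference from
deep protein-coding alignments. First, synonymous substitutions are
unconstrained at the protein level and accumulate fast; third codon
positions saturate, and what survives of their signal is dominated by base
composition rather than history. Second, base (or amino-acid) composition
itself drifts between lineages; when two non-sister lineages converge on a
similar composition, models that assume one stationary composition for the
whole tree read that convergence as shared ancestry ("compositional
attraction") and can resolve the wrong topology with full support.

degenphy implements the two complementary remedies and the diagnostics
around them:

* **Codon-degenerate recoding** replaces each codon by the minimal IUPAC
  ambiguity pattern covering its synonymous codon family, so synonymous
  point substitutions become literally invisible to the likelihood (the
  recoded symbols enter Felsenstein pruning as ambiguity partials, never as
  a reduced alphabet).
* **Tree-heterogeneous composition models**: `CV1` (one composition vector,
  the classical homogeneous case), `NDCH-k` (k vectors painted onto nodes,
  the paint sampled), and `NDCH2` (one vector per node, shrunk toward the
  empirical composition by a Dirichlet prior whose concentration is itself
  sampled).

## The model

The substitution process on the branch leading into node $v$ is a
reversible rate matrix $Q^{(v)}_{ij} = R_{ij}\,\pi^{(v)}_j$ built from
shared symmetric exchangeabilities $R$ and the composition vector
$\pi^{(v)}$ attached to $v$; the root's vector weights the root partials.
Every branch's $Q$ is rescaled so that $-\sum_i \pi^{(v)}_i Q^{(v)}_{ii}=1$,
keeping branch lengths in expected substitutions per site under each local
composition. Among-site rate variation is a discrete gamma mixture with
equal category weights; categories are represented by their conditional
means (not medians), renormalised to mean one, with $k=4$ by default (the
standard default of the reference software; the category count is not
stated in the source analyses).

Under `CV1` the likelihood is root-invariant (reversibility); under
`NDCH`/`NDCH2` it deliberately is not — node-attached compositions define a
directional process, which is the point.

### Priors

* branch lengths: iid exponential, mean 0.1 (tunable);
* topology: uniform over labelled topologies;
* exchangeabilities and `CV1`/`NDCH` compositions: flat Dirichlet;
* gamma shape: uniform on (0, 20];
* `NDCH2`: $\pi_v \sim \mathrm{Dirichlet}(c\,\hat\pi)$ independently per
  node, with $\hat\pi$ the empirical alignment composition and
  $c \sim \mathrm{Exponential}(\text{mean }100)$. The source analyses say
  only that the concentration is "sampled"; the exponential hyperprior with
  mean 100 weakly favours near-homogeneity and lets the data pull node
  vectors apart — with $S=4$ and $c=100$ the per-entry prior standard
  deviation is about 0.04.

## Sampling, and what a chain can and cannot do

The sampler is single-move Metropolis–Hastings: NNI on internal edges,
per-branch length multipliers, a log-scale window on the gamma shape,
centred Dirichlet proposals for exchangeabilities and compositions
(proposals falling below a floor of $10^{-6}$ per entry are rejected — a
symmetric truncation that preserves detailed balance), an NDCH node
reassignment move, a log-scale walk on $c$, and two structural moves:

* a **jolt** — NNI coupled with a fresh draw of the rearranged internal
  branch from its prior and, under `NDCH2`, of the two incident node
  compositions from their Dirichlet prior. The proposal densities cancel
  against the prior, leaving a pure likelihood-ratio acceptance.
* a **conditional-prior composition redraw** (`NDCH2` only) — one node's
  vector resampled from $\mathrm{Dirichlet}(c\,\hat\pi)$. Without it the
  joint prior on $(c, \pi_1..\pi_{2n-1})$ is a funnel that a centred random
  walk cannot traverse, and even prior-only moments come out wrong.

An honest limitation, measured rather than assumed: at realistic data
sizes (thousands of sites) the topology posterior is nearly degenerate and
the valleys between topology basins are hundreds of log-likelihood units
deep; no simple-move chain crosses them (jolt proposals from a stuck state
land 150+ units below it). The package therefore treats *replicate runs*
as the unit of inference, exactly as the reference workflow does when its
runs disagree: `replicate_analysis()` runs several chains, estimates each
run's marginal likelihood from its stationary tail, takes the best run as
the reference and pools the runs whose modal topology agrees with it,
flagging (not fatally) any disagreement via the ASDSF < 0.01 and
|Δ log-marginal| < 10 convergence rule. For `NDCH2` on few taxa the runs
start from *distinct enumerated topologies* with topology moves suppressed
for the first 20% of iterations, so the run set is guaranteed to
characterise every basin and the marginal likelihood does the ranking; the
homogeneous `CV1` runs keep free random starts, since a homogeneous chain's
early drift toward the compositionally attractive tree is itself the
behaviour under study.

## Marginal likelihood

`estimate_marginal_likelihood()` is a stabilised harmonic-mean estimator: a
working prior $w(\theta)$ is fitted to the post-burn-in draws (independent
gamma surrogates for branch lengths, gamma shape and $c$; Dirichlet
surrogates for simplex blocks), and
$1/\hat m = \tfrac1n\sum_i w(\theta_i)/[L(\theta_i)\pi(\theta_i)]$.
Fitted concentrations are doubled ("shrink"), giving the working prior
lighter tails than the posterior so the importance weights stay bounded;
the estimator is unbiased for any normalised $w$, so shrinking trades a
little variance inflation for robustness. Draws are conditioned on the
modal *rooted* topology class (so branch-length blocks align exactly,
keyed by the clade below each edge) and the estimate subtracts that class's
log posterior mass, which restores the total marginal exactly. The
standard error is a nonparametric bootstrap over draws. The estimator is
validated against the analytic Dirichlet-multinomial marginal of a
conjugate toy; zero-variance blocks raise an error rather than silently
degenerating.

## Posterior-predictive composition test

`x2_statistic()` is the classical taxon-by-state homogeneity statistic,
counting unambiguous core symbols only (gaps, missing and IUPAC codes are
excluded, not fractionally allocated — switchable in principle, but the
exclusion keeps observed and simulated counts exactly comparable).
`posterior_predictive_pvalue()` simulates one replicate per posterior draw
with the same dimensions and the same missing-data mask as the observed
matrix and reports the tail area $\Pr(X^2_{rep} \ge X^2_{obs})$; ties count
toward the tail (conservative), and $p \ge 0.05$ is read as model fit.

## The monophyly screen (GGI) and the AU test

Constraint topologies on named groups are enumerated exhaustively
($(2g-5)!!$ of them; 15 for five groups). Each constraint is fitted by a
hill-climb entirely inside the package: within-constraint NNI (a
rearrangement is admitted only if every group stays monophyletic *and* the
group-level backbone still matches the constraint), Brent line search per
branch, bounded search on the gamma shape, cycled to a $10^{-4}$ log-unit
tolerance from `n_starts` random within-group resolutions. Per-site
log-likelihoods of the fitted constraints feed the multiscale RELL
bootstrap: at each scale $r \in \{0.5,\dots,1.4\}$, `n_reps` resamples of
$\lfloor r\,n\rceil$ columns are scored, best-count proportions are
probit-transformed and regressed on $(\sqrt r, 1/\sqrt r)$ by weighted
least squares with binomial-variance weights, and
$p_{AU} = 1 - \Phi(d - c)$. Degenerate proportion vectors (0 or 1 at every
scale) clamp $p$ to 0/1 with an explicit flag. A gene passes the screen
when at least one constraint has $p \ge 0.05$ ("equal or greater").

## The synthetic-data generator

`simulate_alignment()` evolves states down the tree with the same
branch-to-composition convention as the likelihood engine, gamma rates
drawn per site, per-gene taxon dropout masking whole gene-by-taxon cells
(default emulation target: 9.5% missing gene sequences, the level of the
motivating data set). Codon mode evolves whole codons under a rate matrix
with single-nucleotide moves in which synonymous changes are multiplied by
`omega_syn` — a deliberate simplification (not a full codon model) that is
sufficient to reproduce the third-position saturation artifact: at
`omega_syn = 8`, third-position divergence plateaus near 0.75 while
degenerate-recoded divergence keeps rising with branch length.

`make_attraction_scenario()` is the package's core adversarial world: four
groups on `((A,B),(C,D))`, tips of the non-sister groups B and D given a
GC-rich composition (convex mixture with weight `bias_strength`), long
terminal branches (0.8) into the biased tips versus 0.2 elsewhere and a 0.1
internal branch, gamma shape 1. The numbers were fixed once, during design,
to make the mechanism express itself at 5,000 sites: under the homogeneous
model the attraction tree beats the truth by ~30 log-marginal units, under
`NDCH2` the truth wins by ~15–20. A five-group variant was tried and
rejected: with three unbiased lineages sharing one composition the
"attractive" grouping is no longer unique, so the scenario's recorded
wrong split would not be the one a homogeneous analysis actually finds.

What a green contrast experiment establishes: that on data generated with
convergent composition bias on non-sister lineages, the homogeneous model
confidently supports the biased grouping while the node-heterogeneous model
recovers the generating topology. What it does not establish: anything
about real mitochondrial alignments (no alignment error, no indels, no
among-gene rate or composition differences beyond dropout, no heterotachy,
taxon counts far below real data sets).

## Numerical choices

* pruning is in C++ over unique site patterns with per-pattern rescaling;
  compressed and uncompressed likelihoods agree to $10^{-9}$;
* reversible matrix exponentials use the symmetrised eigendecomposition,
  the general (codon-mode) case a Padé approximation;
* consensus trees keep splits with pooled frequency strictly above the
  cutoff (a split at exactly 0.5 is excluded);
* ASDSF uses the two-point sample standard deviation with an inclusion
  threshold of 0.1 (common practice; unstated in the source analyses);
* the convergence thresholds are ASDSF < 0.01 and < 10 natural-log units
  of marginal likelihood;
* coordinates are 0-based half-open internally, 1-based in messages;
  missing (`?`) and gap (`-`) are both fully ambiguous to the likelihood
  but distinguished by the curation reports.

## Known limitations

* No Metropolis coupling; topology mixing at scale relies on the
  replicate-run design described above.
* Marginal likelihoods condition on the modal topology class; the reported
  posterior mass of that class is part of the result and should be read
  alongside the estimate.
* The GGI hill-climb is a local search; `n_starts` (default 20, mirroring
  standard practice) is the only defence against local optima.
* Amino-acid analyses use empirical exchangeability matrices (bundled via
  phangorn, or any PAML-format file, e.g. a user-supplied stmtREV); the
  package does not estimate 190 amino-acid exchangeabilities by MCMC.
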