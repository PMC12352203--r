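---
title: "Profiling intrinsic disorder and missense pathogenicity with DisorderMap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling intrinsic disorder and missense pathogenicity with DisorderMap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(DisorderMap)
```

## The analysis

Intrinsically disordered protein regions (IDPRs) are functional segments that
lack a stable three-dimensional structure. A recurring observation in
structural bioinformatics is that missense substitutions falling inside such
regions tend to be predicted benign, while substitutions in well-folded cores
tend to be predicted damaging. DisorderMap packages that analysis as a
reusable per-residue track pipeline for a single protein chain:

1. **Consensus disorder.** Several per-residue disorder predictors are
   averaged into a mean disorder profile (MDP), with the per-residue sample
   standard deviation as an error band. A residue counts as disordered when
   its score is at least 0.5, the percentage of predicted disordered residues
   (PPDR) summarises a track, and the protein is binned as highly ordered
   (PPDR < 10%), moderately disordered (10% <= PPDR < 30%) or highly
   disordered (PPDR >= 30%).
2. **Pathogenicity aggregation.** A table of per-substitution pathogenicity
   scores in [0, 1] (the AlphaMissense UniProt-substitution dialect) is
   collapsed to a per-residue mean over all recorded alternates at each
   position. Scores below 0.34 are likely benign, scores above 0.564 likely
   pathogenic, and the closed interval between the cutoffs is ambiguous, so
   the three classes partition [0, 1].
3. **Correlation.** The per-residue pathogenicity means are smoothed with a
   centered 10-residue moving mean and regressed on the raw MDP with the
   exponential decay `y = a * exp(-b * x) + c`, reporting
   `R^2 = 1 - SS_res / SS_tot`.
4. **Region calculus.** Maximal threshold runs on any track yield typed
   1-based inclusive regions: disordered regions at threshold 0.5 on the MDP,
   droplet-promoting regions (DPRs) at threshold 0.60 on a FuzDrop-style
   droplet-probability track. A protein with an overall phase-separation
   probability (pLLPS) of at least 0.60 is a droplet driver; below that, a
   protein with DPRs is a droplet client.
5. **Composition.** Amino-acid enrichment and depletion against a background
   composition via the fractional difference
   `(C_x - C_background) / C_background`, with resampling-based significance
   and Bonferroni correction over the 20 codes, presented in TOP-IDP order
   (C most order-promoting to P most disorder-promoting).
6. **Networks and structures.** Edge-list summaries (average node degree
   `2E/N`, average local clustering) and B-factor repainting of a structure
   model with any per-residue track.

## A worked synthetic run

Every input format can be generated with known ground truth, so the whole
pipeline runs offline:

```{r example}
cfg <- simulationConfig(seed = 1)
sq  <- genSequence(cfg)
dis <- genDisorderTracks(cfg)
am  <- genPathogenicity(cfg, dis$latent, sq)

mdp <- computeMdp(dis$tracks)$mdp
ppdr(mdp)
pr  <- perResidueMean(am, length(sq))
res <- correlateDisorderPathogenicity(mdp, pr)
res$fit
```

The planted decay parameters are `a = 0.6, b = 4, c = 0.2`; the fit recovers
them through six noisy pseudo-predictors and 19 noisy variant scores per
residue.

## Model and parameter choices

**Exponential-decay form.** The decay is fitted with a free offset `c`
because smoothed pathogenicity plateaus above zero in real proteins: even
maximally disordered regions keep a benign-but-nonzero mean score. The
two-parameter form (`c = 0`) is available via `offsetTerm = FALSE` for
sensitivity analysis. The decay rate is constrained non-negative -- the model
encodes "pathogenicity decays with disorder", and an unconstrained sign flip
would silently change the hypothesis.

**R-squared.** `rSquared()` implements the plain coefficient of
determination with no degrees-of-freedom adjustment; some presentations call
this "adjusted" while printing the unadjusted formula, so the function name
avoids the word entirely.

**Smoothing convention.** The moving mean covers offsets
`-ceiling(w/2)+1 .. floor(w/2)` (for the default `w = 10`: -4 to +5),
truncating at the chain ends and skipping missing values. Even windows have
no symmetric centering; this convention is stated explicitly and used
everywhere so results are reproducible to the bit. Smoothing is applied to
the pathogenicity track only; the disorder axis stays raw (a `smoothX` flag
exists for sensitivity checks). With `w = 1` smoothing is the identity, which
the tests exploit for permutation invariance.

**Fitting.** Levenberg-Marquardt (via minpack.lm) from the deterministic
start `a0 = max(y) - min(y)`, `b0 = 1`, `c0 = min(y)`, tolerances 1e-12 and
up to 1000 iterations. On noiseless model data this recovers parameters to
machine precision; identical inputs give bit-identical results. A constant
response collapses to the offset with `R^2 = 0` and a warning; if the
optimiser ever fails structurally, a direct Nelder-Mead pass on the residual
sum of squares is returned with `converged = FALSE` rather than an error.

**Class boundaries.** Both pathogenicity cutoffs map to the ambiguous class
(closed interval) and the PPDR boundaries are left-closed
(10 is moderate, 30 is high), choices that are property-tested to partition
their domains with no gaps or overlaps.

**Droplet regions.** The 0.60 threshold is inclusive ("0.60 or higher").
The minimum DPR length defaults to 5 residues: published droplet-promoting
regions are rarely shorter, single-residue threshold crossings are almost
always noise, and the parameter is exposed for users who want raw runs
(`minLength = 1`).

**Composition significance.** Per iteration the query composition is
bootstrapped (a multinomial draw of the query's length from its observed
frequencies -- exactly equivalent to resampling residues with replacement)
and a background pseudo-sample of `backgroundN = 3000` residues is drawn
from the background frequencies. The test statistic divides the difference
of the two bootstrap means by the *null* standard deviation estimated from
the background bootstrap alone, scaled for both sample sizes:
`sqrt(var_bg * (1 + backgroundN / n_query))`. Two properties motivated this
form. First, the bootstrap-distribution variance must not be divided by the
iteration count: the bootstrap spread estimates the sampling variance of a
frequency, and shrinking it with iterations would make any fixed composition
difference arbitrarily significant. Second, estimating the null variance
from the query side couples the denominator to the query's own random
deviation (binomial variance tracks the mean), which inflates the family-wise
error; taking it from the background restores calibration. Measured over
1000 null replicates (query drawn from the background itself) the
family-wise significance rate at `alpha = 0.05` with Bonferroni m = 20 is
about 0.02-0.03, and a planted two-fold enrichment at query length 500 is
flagged in >= 95% of seeds. A percentile alternative
(`method = "bootstrap_ci"`) is provided; it shares the query-coupling
caveat and is intended for effect-size exploration rather than calibrated
testing.

**Backgrounds.** The curated ordered/disordered background sets used by
composition-profiling web services are not redistributable, so the package
ships one clearly labelled *synthetic* globular-protein background
(`background_synthetic_globular.csv`); all tests use synthetic backgrounds,
and any user CSV with `code, freq` columns can be supplied.

**Protein-level pathogenicity mean.** Averaging all substitutions and
averaging the per-residue means differ when residues carry unequal entry
counts. Both are computed; the per-variant mean is the headline value and a
message flags any disagreement beyond 1e-9 relative.

**Network statistics.** Clustering uses the unweighted graph after score
thresholding; degree-0/1 nodes contribute zero to the mean rather than being
excluded, matching the common convention of network tools. Expected-edge
counts and interaction-enrichment p-values are deliberately out of scope:
they depend on a database-wide degree-preserving null that cannot be
reproduced from an edge list.

**Structure repainting.** Repainting replaces only columns 61-66 of
`ATOM`/`HETATM` records (fixed two-decimal, value x 100), leaving every
other byte of the file untouched; this is why the writer operates on the
text records directly instead of going through a structure object
round-trip, which would reformat coordinates. mmCIF models can be read (the
confidence track comes from the B-factor column of the representative atom,
CA with first-atom fallback) but repainted output is PDB only.

## The synthetic generator

The generator is the package's study-condition definition, not a test dial.
Defaults emulate a CYP1B1-like protein: length 543; six pseudo-predictors;
latent disorder built as a Gaussian random walk smoothed with a 21-residue
window, standardised and squashed through a logistic map (scale 2), which
produces smooth profiles spanning [0, 1] like real predictor output;
predictor noise sd 0.05; 19 substitutions per residue with scores
`a * exp(-b * latent) + c` plus noise sd 0.1, clipped to [0, 1]; three
planted droplet regions at 1-14, 295-322 and 367-377 with droplet
probabilities `0.60 + U(0, 0.35)` inside and `U(0, 0.55)` outside; overall
pLLPS 0.3692; and a uniform random 56-node, 268-edge graph with weights in
the 900-1000 confidence band. The latent profile is shared between the
disorder and pathogenicity generators, so the planted coupling is exact at
the latent level and noise enters only at observation level -- this is what
makes parameter recovery a clean acceptance surface. Clipping bias is
negligible at the default parameters (`a + c = 0.8`, scores rarely touch the
bounds). One master seed fans out to fixed per-generator substreams.

What the generator does *not* emulate: the score distribution of any real
pathogenicity predictor, the error correlation structure of real disorder
predictors (they share training data; the pseudo-predictors are
conditionally independent), residue-type-dependent disorder propensity, and
degree heterogeneity of real interaction networks. Passing the recovery
tests therefore demonstrates that the pipeline's arithmetic is correct under
the planted model, not that any biological conclusion transfers to a real
protein.

## Problem sizes and determinism

The test suite and the acceptance script size their simulations to run in a
few minutes on one core: 100 seeds for end-to-end decay-rate recovery at
full protein length, 1000 replicates for the composition null, 1000 random
tracks (length 60) against the quadratic run-enumeration oracle, 200 random
graphs (up to 30 nodes) against the cubic triangle oracle, and 1e5 draws for
the partition properties. All randomness flows from explicit seeds; the
pipeline writes an input-checksum manifest next to its JSON report so a run
is reproducible from (inputs, config, seed).

## Limitations

- External predictor outputs are consumed, never recomputed; results are
  only as good as the supplied tracks and tables.
- Single chains only: no assemblies, no indels or frameshifts (missense
  substitutions only), no non-standard residues beyond an `X` marker.
- The published per-protein numbers that depend on full external tables
  (protein-wide mean pathogenicity, predictor-specific PPDRs, the real
  decay-fit R^2) cannot be reproduced from shipped data; the package instead
  proves the machinery on planted ground truth and on the published
  per-variant worked values.
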