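---
title: "Reverse-complement equivariant networks: model, pipeline and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reverse-complement equivariant networks: model, pipeline and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rcnets)
```

## The problem

Double-stranded DNA has no preferred reading direction: a transcription
factor binding site is the same biological object whether it is read on the
forward strand or as its reverse complement (RC) on the other strand. A
sequence classifier that scores a sequence and its reverse complement
differently is therefore making a distinction that has no physical meaning,
and in low-data regimes it wastes capacity learning (imperfectly) a symmetry
that could be built in. `rcnets` builds convolutional classifiers that are
*exactly* RC-symmetric, combines them with Monte Carlo (Bayesian) dropout,
and surrounds them with the tooling needed to study the approach end to end:
a motif-injection simulator with ground truth, a hidden Markov model
pipeline that turns recombination-rate tracks into hotspot/coldspot training
data, and motif scanning/enrichment/harvesting utilities.

## The symmetry and the layer algebra

A sequence of length $N$ is one-hot encoded as a $4 \times N$ matrix $X$
with channel order A, C, G, T. With this order, the RC group action on the
input is a flip of both axes:

$$\mathrm{RC}(X)_{ij} = X_{-i,-j},$$

where a negative index counts from the opposite end (the complement of base
$i$ is base $5-i$ precisely because of the A,C,G,T ordering). Every hidden
tensor $T \in \mathbb{R}^{C \times L}$ carries the same action: reverse the
filter axis and the spatial axis. A layer $F$ is *equivariant* when
$F(\mathrm{RC}_{\mathrm{in}}(X)) = \mathrm{RC}_{\mathrm{out}}(F(X))$;
a network of equivariant layers ending in an RC-invariant head is exactly
strand-symmetric, for every parameter setting, trained or not.

The constructions, and what makes each equivariant:

* **Tied convolution.** A bank of $n_f$ filters $W \in \mathbb{R}^{4 \times
  f_l \times n_f}$ is constrained by $W_{m,n,i} = W_{-m,-n,-i}$: filter
  $n_f{+}1{-}i$ is the channel-and-position flip of filter $i$. Biases are
  mirrored, $b_i = b_{n_f+1-i}$ (the bias tie is required for equivariance
  even though it is easy to overlook when biases are dropped from the
  algebra "for simplicity"). The package stores only the free half
  (`symmetrize()` expands it), so the tie holds *bitwise* after every
  optimizer step and gradients flow through the symmetrization by
  construction. This is why `n_f` must be even: an odd count would need a
  self-symmetric middle filter that is never used in practice and is
  rejected with an error.
* **Spatial max-pooling** (`spatial_max_pool`) with stride equal to pool
  width commutes with the flip whenever the pool width divides the spatial
  length; the standalone operation enforces divisibility strictly.
* **RC orbit pooling** (`rc_orbit_pool`) reduces each orbit
  $\{(i,j), (-i,-j)\}$ with max, sum or mean, halving the tensor. After it,
  RC acts as the identity, so everything downstream (dense layers, softmax)
  is automatically invariant. This is the package's chosen route to an
  invariant head; RC-equivariant dense layers are not implemented because
  orbit pooling makes them unnecessary.
* **Equivariant dropout** (`sample_mask(..., equivariant = TRUE)`) draws one
  Bernoulli indicator per orbit and copies it to both members, so the mask
  satisfies $\epsilon_{ij} = \epsilon_{-i,-j}$ exactly and dropout commutes
  with the flip. Masks are sampled once per training batch and shared across
  the batch; at prediction time $K$ masks are sampled up front and shared
  across all test sequences, which makes the Monte Carlo predictor a fixed,
  deterministic, exactly RC-symmetric function.
* **Activations.** ELU is the default; SReLU ($\max(z,-1)$) and ReLU are
  available. On shallow genomic networks the hard sparsity of ReLU tends to
  stall convergence, which is why the default is ELU.

## The network family and training

`network_config()` declares a single-convolution-block stack:

conv($n_f{=}16$, $f_l{=}12$, ELU) → equivariant dropout ($p_{\mathrm{keep}}
{=}0.7$) → RC orbit max-pool → spatial max-pool ($p_l{=}8$) → global spatial
max → dense(2) → softmax.

This is the smallest architecture exercising every construction above, and
it is the default used by tests and the CLI. Configuration covers
equivariant vs free filters, Bayesian vs deterministic dropout, dropout
placement before or after orbit pooling, orbit-pool mode (max/sum/avg), L2
strength, and optimizer hyperparameters. Deeper stacks are out of scope:
the package's subject is the symmetry algebra and its consequences, which
one block exhibits fully.

Two numerical choices deserve a note:

* **Partial final pool window.** Because a global spatial max immediately
  follows the spatial pool, `maxpool → global max` equals `global max`
  exactly; the network therefore allows the final pool window to be shorter
  than $p_l$ when $p_l$ does not divide the conv output length. This is safe
  only downstream of orbit pooling (where RC is already the identity), which
  is where it sits. The standalone `spatial_max_pool()` keeps the strict
  divisibility error.
* **Inverted dropout scaling.** Masked activations are divided by
  $p_{\mathrm{keep}}$ during training and during Monte Carlo prediction, so
  $p_{\mathrm{keep}} = 1$ reduces exactly to no dropout and expected
  activation scales are stable. The source formulation leaves the rescaling
  convention unstated; any fixed convention is self-consistent, and this one
  makes the limits exact. `predict_weight_avg()` (a single unmasked pass) is
  then the conventional-dropout test-time procedure. One consequence worth
  knowing: in this one-block architecture the difference between test-time
  conventions is close to a monotone rescaling of the single pooled feature
  vector, so rank-based metrics (AUROC) are nearly blind to it — accuracy at
  a fixed threshold is where test-time procedures genuinely differ. The
  package reports both predictors so users can measure either.

Training is plain mini-batch gradient descent (optional heavy-ball momentum,
off by default) on softmax cross-entropy plus an L2 penalty on free
convolution and dense weights (not biases), with hand-derived gradients
checked against finite differences in the test suite. The output layer uses
a custom initialization — dense weights all 1, biases $(1, -1)$ — which
empirically sits near the optimum for two-class problems of this kind and
speeds convergence. A side effect: a *fresh* model's two scores differ by a
constant, so its conv filters receive zero gradient until the dense rows
separate; the dense layer learns first, then shapes the filters.

## The simulator

`simulate_dataset()` emulates a two-binding-protein regulatory architecture:
labels are drawn first (Bernoulli 0.5), then each of two PWMs is injected
independently into a uniform i.i.d. background with probability 0.4 (label
1) or 0.2 (label 0), each instance sampled from its PWM,
reverse-complemented with probability 1/2 and placed uniformly at random.
Defaults are 40 000 sequences of length 1000. Injections may overlap — the
later one overwrites, and both are logged — because no collision rule is
part of the design being emulated; the injection log is exact ground truth
for every non-overwritten instance. The bundled `toy_pwms()` (a sharp
10-mer, consensus ACGGTAGCAT, and a degenerate 8-mer) stand in for external
database matrices, which users can load with `read_jaspar_pfm()`.

What the simulator does *not* emulate: background composition structure
(CpG islands, repeats), motif position preferences, or dependence between
the two motifs. Passing tests on simulated data therefore demonstrate the
correctness of the machinery and the attainability of the planted signal,
not performance on real genomes.

A useful property of this generative design is that the label depends on
the sequence only through the two injection indicators. The Bayes-optimal
AUROC is therefore computable: for per-motif injection probabilities
$(p_1, p_0)$ the indicator pair is $\mathrm{Binom}(2, p_1)$ vs
$\mathrm{Binom}(2, p_0)$, giving e.g. $\approx 0.855$ at $(0.6, 0.1)$ and
$\approx 0.623$ at $(0.3, 0.15)$ — ceilings that no classifier, however
good, can exceed on such data. The test suite's learning checks are read
against these ceilings.

## The hotspot pipeline

Meiotic recombination rates (cM/Mb) along the genome are segmented into
"hot" and "not hot" with a two-state hidden Markov model with exponential
emission densities parameterized by their means, fitted by Viterbi training
(hard EM): decode with `viterbi()` (log space), re-estimate each state's
mean as the sample mean of its assigned rates, re-estimate transitions from
path counts with add-one smoothing, repeat until the path stabilizes.
Identifiability is fixed by the convention mean(hot) > mean(cold), enforced
by swapping. Rates of exactly 0 are floored at $10^{-6}$ cM/Mb before
likelihood evaluation: the exponential density is positive at 0, but a
state capturing only zeros would degenerate the mean re-estimate. Decoding
is validated against exhaustive path enumeration ($n \le 12$), and
parameter recovery is tested at means 10.5 / 0.5 cM/Mb — values on the
scale of observed hot-region medians.

Hot runs are merged into intervals (`call_hotspots`); intervals longer than
4 kb are discarded as poorly localized, and a 1 kb window centred at
$\lfloor (start+end)/2 \rfloor$ is extracted (`extract_center`), dropping
windows with unspecified bases. Matched controls (`match_coldspot`) are
found by a greedy search outward from each hotspot: candidate 1 kb windows
at 1 kb steps, alternating sides, out to 300 kb, accepting the first window
within 0.10 GC (absolute difference of fractions; a relative mode is
provided behind a flag since "within 10% GC" is ambiguous), with mean rate
below 0.5 cM/Mb, no N, and no overlap with hot intervals or previously
claimed coldspots. The candidate ordering (outward, alternating, first
acceptable) is this package's concretization of a greedy search; it makes
the result deterministic. GC matching exists so that GC content — elevated
in hotspots by GC-biased gene conversion — cannot serve as a proxy label.
Coordinates are BED-style 0-based half-open throughout, including the
0-based `position` argument of `inject()`.

## Motif tools

`scan_count()` counts occurrences of degenerate patterns over
{A,C,G,T,N} with overlaps allowed, on both strands by default (a position
matching the pattern and its reverse complement at once is counted once);
it is cross-checked against a brute-force position-by-position oracle.
Counts are *occurrences*, not sequences-containing: published count tables
for short submotifs exceed the number of sequences, which forces this
convention. `enrich()` reports the hot/cold occurrence-count ratio — the
convention that reproduces the published enrichment columns to their
printed precision — plus a two-sided exact binomial test (null proportion =
hot sequence share) with Bonferroni correction; a classical 2×2 odds ratio
is available behind a flag. The binomial construction is a documented
convention: the exact test behind the published p-values is not
reconstructible from the source text, so those p-values are not asserted
anywhere.

`harvest_motifs()` recovers motifs from a trained model: for one
representative of each RC-tied filter pair, it records each sequence's
maximal first-layer activation and position, keeps the top scorers (the
smaller of `top_k` and the upper `activation_quantile` tail), extracts the
length-$f_l$ subsequence under each maximum — reverse-complemented when the
tied partner fired harder — and stacks them into a PWM with pseudocount 1.
Pseudocount and selection rule are package choices; the harvesting idea
(subsequences driving first-layer activations, aligned by construction)
is the method under study. `information_content()` and
`pwm_to_consensus()` render harvested PWMs in the degenerate-pattern style,
and `pwm_match_correlation()` scores recovery against a reference PWM by
best-offset/strand mean column correlation over informative columns.

## Problem sizes and determinism

The test suite runs everything at desk scale, chosen so the full suite
completes in minutes on one CPU while still exercising each claim: layer
equivariance on 100 random draws; exact RC symmetry on 100 random models ×
100 sequences (forward and $K{=}16$ MC); Viterbi against enumeration on 50
random tracks of length ≤ 12 and recovery on $10^4$ windows; the simulator
contract at its full default size (40 000 × 1000); learning checks on 4000
sequences of length 200 trained 10 epochs; and the test-time-procedure
comparison over 10 seeded runs. All randomness flows through explicit
integer seeds; fixed seeds give bit-identical datasets, models and
predictions on a given platform.

## Known limitations

* Only the two-element RC group; no larger symmetry groups, no 2D
  convolutions, dilation or same-padding.
* One convolutional block; the published multi-layer topologies and their
  hyperparameter searches are out of scope, so absolute published accuracy
  tables are not reproduced here.
* The simulator's background is i.i.d.; real-genome confounders are only
  addressed via the GC-matching of the hotspot pipeline.
* Viterbi training is hard EM: it optimizes the joint (path, data)
  likelihood, not the marginal likelihood; forward–backward posterior
  decoding is not provided.
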