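---
title: "Interface co-evolution profiles and interaction confidence scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interface co-evolution profiles and interaction confidence scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coevnet)
```

## The problem

High-throughput protein-protein interaction screens carry substantial
false-positive and false-negative rates, and most candidate interactions have
no experimentally solved complex structure. When two query proteins can be
threaded onto a template complex family, the putative binding interface they
inherit can itself be interrogated: interacting protein families co-evolve at
their interfaces, so residue pairs in contact across the interface show
correlated substitution patterns that non-interacting pairs do not. `coevnet`
turns that signal into a calibrated confidence score for a candidate
interaction, in three steps:

1. **Simulated co-evolution.** Real families rarely contain enough solved,
   aligned interacting homolog pairs to estimate interface correlations
   directly. Starting from the few known complexes of a family, a Markov
   chain Monte Carlo sampler generates artificial interacting homolog pairs:
   contacting residue pairs are resampled from a paired residue distribution,
   non-contacting residues drift under BLOSUM62, and proposals are accepted
   or rejected by their joint fitness against the two family profiles.
2. **Tree-structured interface profiles.** From the simulated pairs, two
   spanning-tree graphical models over the interface columns are learned by
   maximum-mutual-information (Chow--Liu) structure learning: a *positive*
   tree from the co-evolved pairs and a *negative* tree from the same pairs
   with the partner protein shuffled. A candidate interface is scored by its
   log-likelihood under each tree; the gap `L+ - L-` is the co-evolution
   signal.
3. **Logistic confidence.** Alignment features from the upstream threading
   stage and the interface features are combined by a penalized logistic
   model,
   `logit(p) = alpha + b1'X1 + b2'X2 + bi*Yi + b_plus*L+ + b_minus*L-`,
   where `X1`, `X2` are each protein's sequence score, secondary-structure
   score, and length, and `Yi` is the interface size. The output `p` in
   (0, 1) is the interaction confidence; `p >= 0.6` (boundary inclusive) is
   called high confidence.

## The simulation model

Each family chain starts at one seed complex and performs, per step:

* **Contact moves.** `ceiling(0.05 * n_contacts)` contacts are chosen
  uniformly without replacement. For each, a fair coin fixes one side and the
  other side is resampled from the conditional of the 20x20 paired residue
  distribution given the fixed residue. Each contact is treated
  independently.
* **Background moves.** `ceiling(0.05 * n_noncontact)` non-contacting
  positions per protein are resampled from a conditional substitution
  distribution derived from BLOSUM62 by inverting its half-bit log-odds:
  `P(b | a) proportional to background_b * 2^(S(a,b)/2)`, row-normalized.
  The background defaults to the BLOSUM62 marginal frequencies.
* **Selection.** The proposed pair's joint fitness is the sum of the two
  profile scores (per-column log-odds in bits; gaps contribute a fixed
  penalty, default -4 bits). The move is accepted with probability
  `min(1, exp(delta_fitness / temperature))`, temperature 1 bit by default.

The per-step mutation fractions (5% of contacts, 5% of non-contacting
residues) and the per-seed sample counts (1,000 per seed complex, 2,500 for
single-seed families) are the model's study conditions and are the package
defaults. Burn-in (500 steps) and thinning (10) are implementation defaults
chosen so that small families pass the window-mean convergence check
(`check_convergence()`: the last two windows of the fitness trace must agree
to half a pooled standard deviation); a failed check warns and flags the
sample set rather than failing, since a long-but-slow chain still yields
usable samples.

Gap columns are immutable: the sampler neither creates nor removes gaps, and
contacts with a gap on either side are excluded from the move set. Indel
events and phylogeny-aware evolution are out of scope.

### Exactness of the acceptance rule

The resampling proposal is asymmetric (the conditional depends on the
current state), so the plain fitness-only rule — which mirrors the described
procedure and is the default — does not exactly preserve the Boltzmann
distribution `pi(x) proportional to exp(fitness(x) / T)`. For stationarity
testing the sampler has an optional exact mode (`hastings = TRUE`) that
multiplies the acceptance ratio by the proposal ratio of the *sampled move
label* (the selected positions and coin choices). Because the label
distribution is state-independent, each labelled kernel is reversible with
respect to `pi`, and a mixture of reversible kernels is reversible: the
corrected chain targets `pi` exactly. The test suite verifies this by full
enumeration of a 16-state toy family (2 proteins x 2 columns over a
two-letter alphabet, one contact): the enumerated kernel's stationary vector
equals the Boltzmann law to machine precision, and 40,000 sampled states land
within total-variation 0.05 of it. One caveat: when several selected
contacts share an alignment column, the replayed reverse-label probability
can differ from the true reverse conditional; the correction is exact for
disjoint moves, which is the overwhelmingly common case at 5% mutation
fractions.

### The paired residue distribution

The contact-pair distribution is estimated from the family's own aligned
interface observations with pseudocount 1 per cell
(`(count + 1) / (total + 400)`), or loaded from a whitespace 20x20 matrix
file. When a generated family carries a paired alignment (`msa_pairs`), those
pairs can be counted too — a small seed set alone is too sparse to carry
coupling into the simulation.

## Tree profiles

Interface nodes are the union of both proteins' interface columns, labelled
`A<col>` / `B<col>`. Structure learning maximizes the sum of pairwise mutual
information over spanning trees (Chow--Liu), which is the
maximum-likelihood tree-structured model; spanning trees keep learning and
inference exact and cheap, whereas loopy models would need approximate
inference with poorly controlled behaviour. Determinism is guaranteed by
sorting candidate edges in canonical node order before Kruskal's algorithm
(ties break toward earlier edges) and rooting at the first node in canonical
order. Canonical order is protein tag then *numeric* column index — the
deterministic stand-in for a lexicographic rule that would misorder column 10
before column 2.

Tables use a 21-symbol alphabet (20 residues plus gap) with pseudocount 0.5
per cell, so gapped query interfaces remain scorable with finite
log-likelihoods. Node marginals are taken as projections of the
pseudocounted edge joints, which makes the factorization exactly
root-invariant; the test suite checks this numerically, along with exhaustive
normalization (`sum over all 21^n assignments of 2^loglik = 1`) for small
trees.

The negative tree is learned from the same simulated pairs after permuting
the B-halves by a random derangement. This preserves both proteins' marginal
column distributions while destroying exactly the inter-protein correlations
the positive tree captures. Whether the original method's background model
was built this way is not documented; the derangement is this package's
choice of background, not an inference about the original. Likelihood scores
are passed to the classifier unnormalized — with both trees over the same
nodes, any length effect is absorbed by the classifier weights.

## Confidence classifier

`confidence_model()` maximizes the L2-penalized logistic likelihood
(intercept unpenalized) by damped Newton-Raphson on standardized features to
gradient tolerance 1e-10; the standardization parameters are stored in the
model so prediction is self-contained. The penalty (strength 1 by default) is
needed because `L+` and `L-` are nearly collinear on well-behaved families.
`L+` and `L-` enter as scalars — one tree per class — with scalar
coefficients. Evaluation reports ROC curves (thresholds swept over distinct
scores, AUC by trapezoid, equal to the tie-corrected Mann-Whitney statistic)
and stratified k-fold cross-validation (default 5-fold) with globally
balanced fold sizes. `association_test()` compares predicted and reference
binary labels by Fisher's exact test with a Haldane-corrected odds ratio.

## The synthetic benchmark

`generate_family()` draws families from a generating model whose coupling is
a mixture of a copy channel and independence: at each true contact the
B-residue copies the (alphabet-permuted) A-residue with probability
`coupling_strength`, otherwise both are uniform; background columns are
independent and uniform. The mixture was chosen because its per-contact
mutual information has a closed form (`coupling_mi()`), giving the tests
analytic oracles. Default conditions: 30 + 30 columns, 8 contacts, coupling
0.9, a 60-pair family alignment, 5 seed complexes, and a 100/100
positive/negative benchmark — sizes that keep a full desk run within a few
minutes on one CPU.

`sample_labeled_benchmark()` pushes everything through the real pipeline:
MCMC simulation, tree learning, and feature extraction. Alignment features
are deliberately uninformative (profile scores and noise are identically
distributed across classes), so benchmark discrimination isolates the
interface features. What passing benchmarks show is that the chain
transmits contact coupling into the learned trees and that the classifier
converts the likelihood gap into ranking; what they cannot show is
performance on real interactomes — real families have phylogenetic
structure, indels, non-uniform backgrounds, and contact maps inferred from
noisy threading, none of which the generator imitates.

Two stochastic checks deserve a note on protocol. The no-signal null
(coupling 0) has a pooled 5-fold CV AUC whose sampling standard error at
100/100 pairs is about 0.04, so a single draw breaches a +/-0.05 band about
one time in five even when everything is correct; the null is therefore
measured as the mean over five replicate benchmarks. Likewise,
coefficient-recovery checks ("all 10 coefficients within 3 standard errors")
fail ~3% of the time per dataset by construction, so they are asserted over
three independent simulations with at least two required to pass fully.

## Numerical choices and degenerate inputs

* Profile probabilities: `(count + pc * background) / (n_nongap + pc)`;
  pseudocount 1 and uniform background by default, background replaceable.
  An all-gap column falls back to the background with a warning; an empty
  MSA is an error.
* Contact maps validate 1-based bounds on input and deduplicate; a
  coordinate-derived map uses a representative-atom cutoff of 8 Angstroms by
  default (configurable; co-evolution is detectable out to 10-12 Angstroms,
  but contacts drive proposals while longer-range correlation is the tree's
  job).
* Mutation counts use ceilings so any positive fraction mutates at least one
  position on small interfaces.
* Zero requested samples yields a valid empty sample set; a single sample
  cannot be deranged (error); trees need two or more samples unless there is
  a single node.
* All randomness flows through seeds carried in parameter objects; reruns
  with the same seeds are bit-identical, and output files carry provenance
  headers (package version, seed, config hash).

## Problem sizes used in the automated checks

The test suite and the acceptance script run entirely on generated data:
16-state chain enumeration with 40,000 sampled states; 100 replicates of
5,000-sample structure recovery on a 6-node chain; the default 100/100
benchmark plus five null replicates; 5,000-row logistic recovery; and
exhaustive 21^3 tree enumeration. These sizes were picked to keep the whole
battery in the low minutes on a single CPU while leaving comfortable margins
on every statistical threshold.
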