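# coevnet

Confidence scoring for candidate protein–protein interactions from
interface co-evolution.

High-throughput interaction screens are noisy, and most candidate pairs have
no solved complex structure. When a candidate pair can be aligned onto a
template complex family, the binding interface it inherits can be tested for
the signature that distinguishes genuinely interacting families: correlated
substitution patterns between residues in contact across the interface.
`coevnet` builds a family-specific statistical model of that signature and
turns it into a probability that a candidate pair interacts.

The method has three parts:

1. **Simulated co-evolution (MCMC).** Starting from the family's seed
   complexes, artificial interacting homolog pairs are sampled: at each step
   5% of the interface contacts are mutated by fixing one side at random and
   resampling the partner from a paired residue distribution
   `P(a, b)`, 5% of non-contacting residues mutate independently under a
   BLOSUM62-derived conditional, and the proposal is accepted with
   probability `min(1, exp(Δfitness / T))`, where fitness is the summed
   position-specific profile score of the two sequences. 1,000 pairs are
   collected per seed complex (2,500 for single-seed families).
2. **Tree-structured interface profiles.** Over the interface columns, two
   spanning-tree graphical models are learned by maximum mutual-information
   (Chow–Liu) structure learning: a *positive* tree from the simulated
   interacting pairs, and a *negative* (background) tree from the same pairs
   with partner proteins shuffled by a derangement. A candidate interface
   assignment `x` is scored by its tree log-likelihoods `L+` and `L−`:
   `log2 P(x) = log2 P(x_root) + Σ_edges log2 P(x_child | x_parent)`.
3. **Logistic confidence.** Features are combined as

   `logit(p) = α + β₁ᵀX₁ + β₂ᵀX₂ + β_i·Y_i + β₊·L₊ + β₋·L₋`

   where `X₁`, `X₂` are each protein's alignment features (sequence score,
   secondary-structure score, length) supplied by the upstream threading
   stage, and `Y_i` is the interface size. The model is fitted with an L2
   penalty on standardized features; `p ≥ 0.6` is called high confidence.
   Evaluation is by ROC curves and stratified 5-fold cross-validation.

A synthetic-family generator with analytic ground truth (contact coupling is
a copy-channel/independence mixture with closed-form mutual information)
makes the whole pipeline testable without any external data.

## Worked example

Fit an interface profile for a synthetic family and score a labeled
benchmark end to end:

```r
library(coevnet)

spec <- generator_spec(n_cols_a = 20, n_cols_b = 20, n_contacts = 5,
                       coupling_strength = 0.9, n_msa = 50, n_seed_pairs = 2,
                       n_positive_pairs = 40, n_negative_pairs = 40, rng_seed = 42)
gen <- generate_family(spec)
fam <- gen$family
fam
#> Family 'synthetic-c0.90-k20-seed42': 2 seed pair(s), alignments 20 + 20 columns, 5 contacts

pd  <- estimate_pair_distribution(fam, pairs = c(fam$seed_pairs, fam$msa_pairs))
fit <- interface_profile(fam, mcmc_params(rng_seed = 43), pair_dist = pd)
summary(fit)
#> Interface co-evolution profile for family 'synthetic-c0.90-k20-seed42'
#>   nodes: 10   simulated pairs: 2000   acceptance rate: 0.400   converged: TRUE
#>   mean edge MI (bits): positive 0.628, negative 0.206
#>   positive tree edges (MI in bits):
#>     A1 - A5  0.229
#>     A1 - B4  0.918
#>     A5 - A17  0.227
#>     A5 - B15  0.978
#>     B4 - B17  0.226
#>     A17 - B18  0.893
#>     B17 - A10  0.984
#>     B18 - A4  0.235
#>     A4 - B7  0.963
```

The five edges with ~0.9–1.0 bits of mutual information are exactly the
family's five true contacts; the weaker edges stitch the remaining columns
into a spanning tree. The negative tree's residual MI (0.206 bits) is the
background level after shuffling.

```r
d <- sample_labeled_benchmark(spec, mcmc_params(rng_seed = 43))
model <- confidence_model(d)
model
#> Logistic confidence model (n = 80, lambda = 1)
#>   alpha = 0.1569
#>    seq_score_a     ss_score_a          len_a    seq_score_b     ss_score_b
#>        -0.0751         0.0659         0.0000         0.0881        -0.0654
#>          len_b interface_size         l_plus        l_minus
#>         0.0000         0.0000         3.3378        -1.1306

cross_validate(d, k = 5, rng_seed = 44)
#> 5-fold cross-validation (1 repeat(s))
#>   mean fold AUC = 0.9938 (sd 0.0140); pooled AUC = 0.9925

p <- predict(model, d[c(1, 41), ])   # one true positive, one negative
round(p, 3)
#>     1    41
#> 0.997 0.115
classify_high_confidence(p)
#>     1    41
#>  TRUE FALSE
```

The classifier puts essentially all its weight on the interface features
(`l_plus`, `l_minus`) — the alignment features are uninformative in the
synthetic benchmark by design — and separates coupled from uncoupled pairs
almost perfectly.

The same flow works from the shell via the bundled CLI
(`inst/cli/coevnet.R`): `simulate`, `build-profile`, `score`, `train`,
`predict`, `evaluate`, `simulate-fixture`, and `pipeline` subcommands read
and write the package's FASTA/TSV/JSON formats.

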