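# Synthetic families with analytic ground truth. Contact coupling is a
# mixture of a copy channel (through a fixed random permutation of the
# alphabet) with independence, so the per-contact mutual information has a
# closed form; background columns are independent and uniform.

#' Specification for the synthetic family generator
#'
#' @param n_cols_a,n_cols_b Alignment lengths (default 30 + 30).
#' @param n_contacts Number of interface contacts (default 8); at most
#'   `min(n_cols_a, n_cols_b)`.
#' @param coupling_strength Mixing weight in `[0, 1]`: with this probability
#'   the B-residue at a contact copies the (alphabet-permuted) A-residue,
#'   otherwise it is drawn independently and uniformly (default 0.9).
#' @param alphabet_size Number of residue symbols used, 2..20 (default 20).
#' @param n_positive_pairs,n_negative_pairs Benchmark class sizes (default
#'   100 each).
#' @param n_msa Size of the generated paired family alignment used to build
#'   profiles and estimate the contact-pair distribution (default 60).
#' @param n_seed_pairs Number of seed complexes (default 5).
#' @param rng_seed Integer seed (default 1).
#' @return An object of class `coev_generator_spec`.
#' @export
generator_spec <- function(n_cols_a = 30, n_cols_b = 30, n_contacts = 8,
                           coupling_strength = 0.9, alphabet_size = 20,
                           n_positive_pairs = 100, n_negative_pairs = 100,
                           n_msa = 60, n_seed_pairs = 5, rng_seed = 1) {
  stopifnot(n_cols_a >= 1, n_cols_b >= 1,
            n_contacts >= 1, n_contacts <= min(n_cols_a, n_cols_b),
            coupling_strength >= 0, coupling_strength <= 1,
            alphabet_size >= 2, alphabet_size <= 20,
            n_positive_pairs >= 0, n_negative_pairs >= 0,
            n_msa >= 2, n_seed_pairs >= 1)
  structure(list(n_cols_a = as.integer(n_cols_a), n_cols_b = as.integer(n_cols_b),
                 n_contacts = as.integer(n_contacts),
                 coupling_strength = coupling_strength,
                 alphabet_size = as.integer(alphabet_size),
                 n_positive_pairs = as.integer(n_positive_pairs),
                 n_negative_pairs = as.integer(n_negative_pairs),
                 n_msa = as.integer(n_msa),
                 n_seed_pairs = as.integer(n_seed_pairs),
                 rng_seed = as.integer(rng_seed)),
            class = "coev_generator_spec")
}

#' Analytic per-contact mutual information of the coupling model
#'
#' For the mixture copy channel with uniform marginals over `k` symbols and
#' coupling `c`, the joint puts mass `(c + (1 - c)/k) / k` on each of the `k`
#' matched cells and `(1 - c) / k^2` elsewhere; the MI (bits) follows in
#' closed form from those entropies.
#'
#' @param coupling_strength Coupling in `[0, 1]`.
#' @param alphabet_size Number of symbols `k`.
#' @return MI in bits.
#' @export
coupling_mi <- function(coupling_strength, alphabet_size) {
  k <- alphabet_size; c <- coupling_strength
  p1 <- (c + (1 - c) / k) / k          # matched cell
  p0 <- (1 - c) / k^2                  # unmatched cell
  term <- function(p, m) if (p > 0) m * p * log2(p * k^2) else 0
  term(p1, k) + term(p0, k * (k - 1))
}

# Draw n sequence pairs (integer code matrices) from the generating model.
.gen_draw <- function(truth, n, coupled) {
  k <- truth$alphabet_size
  a <- matrix(sample.int(k, n * truth$n_cols_a, replace = TRUE),
              nrow = n, ncol = truth$n_cols_a)
  b <- matrix(sample.int(k, n * truth$n_cols_b, replace = TRUE),
              nrow = n, ncol = truth$n_cols_b)
  if (coupled && truth$coupling_strength > 0) {
    for (i in seq_len(nrow(truth$contacts))) {
      ca <- truth$contacts[i, 1]; cb <- truth$contacts[i, 2]
      copy <- stats::runif(n) < truth$coupling_strength
      b[copy, cb] <- truth$sigma[a[copy, ca]]
    }
  }
  list(a = a, b = b)
}

.codes_mat_to_pairs <- function(d) {
  lapply(seq_len(nrow(d$a)), function(i) {
    aligned_pair(codes_to_seq(d$a[i, ]), codes_to_seq(d$b[i, ]))
  })
}

#' Generate a synthetic family with known ground truth
#'
#' Draws seed complexes and a paired family alignment from the coupled
#' generating model, builds per-protein profiles from the alignment, and
#' returns the family together with the generating structure (true contacts,
#' alphabet permutation, analytic per-contact MI).
#'
#' @param spec A [generator_spec()].
#' @return List with elements `family` (a [family_seed()], whose `msa_pairs`
#'   holds the paired alignment) and `truth` (class `coev_ground_truth`:
#'   `contacts`, `sigma`, `coupling_strength`, `alphabet_size`, `n_cols_a`,
#'   `n_cols_b`, `analytic_mi`).
#' @export
generate_family <- function(spec) {
  stopifnot(inherits(spec, "coev_generator_spec"))
  set.seed(spec$rng_seed)
  cols_a <- sort(sample.int(spec$n_cols_a, spec$n_contacts))
  cols_b <- sort(sample.int(spec$n_cols_b, spec$n_contacts))
  contacts <- cbind(cols_a, cols_b)
  truth <- structure(list(contacts = contacts,
                          sigma = sample.int(spec$alphabet_size),
                          coupling_strength = spec$coupling_strength,
                          alphabet_size = spec$alphabet_size,
                          n_cols_a = spec$n_cols_a, n_cols_b = spec$n_cols_b,
                          analytic_mi = coupling_mi(spec$coupling_strength,
                                                    spec$alphabet_size)),
                     class = "coev_ground_truth")
  msa <- .gen_draw(truth, spec$n_msa, coupled = TRUE)
  seeds <- .gen_draw(truth, spec$n_seed_pairs, coupled = TRUE)
  msa_a <- apply(msa$a, 1, codes_to_seq)
  msa_b <- apply(msa$b, 1, codes_to_seq)
  fam <- family_seed(.codes_mat_to_pairs(seeds),
                     contact_map(contacts, spec$n_cols_a, spec$n_cols_b),
                     build_profile(msa_a, pseudocount = 1),
                     build_profile(msa_b, pseudocount = 1),
                     id = sprintf("synthetic-c%.2f-k%d-seed%d",
                                  spec$coupling_strength, spec$alphabet_size,
                                  spec$rng_seed),
                     msa_pairs = .codes_mat_to_pairs(msa))
  list(family = fam, truth = truth)
}

#' Generate a labeled benchmark through the full pipeline
#'
#' Builds a synthetic family, fits its interface profile
#' ([interface_profile()]: MCMC simulation then tree learning), then draws
#' positive query pairs from the coupled generating model and negative query
#' pairs from the independence model, assembling each row's features through
#' [extract_features()]. Alignment features are per-protein profile scores
#' (sequence score), standard-normal noise (secondary-structure score), and
#' the alignment lengths, identically distributed in both classes: the
#' discriminative signal enters only through the interface features.
#'
#' @param spec A [generator_spec()].
#' @param params MCMC parameters; by default [mcmc_params()] seeded from
#'   `spec$rng_seed`.
#' @param regularization Unused here; retained so callers can carry one
#'   settings object.
#' @return Data frame in the labeled-dataset schema (`pair_id`, `label`,
#'   features). Attributes `truth`, `family`, and `fit` (the
#'   `coev_interface_profile`) carry the generating model and fitted profile.
#' @export
sample_labeled_benchmark <- function(spec, params = NULL, regularization = 1) {
  stopifnot(inherits(spec, "coev_generator_spec"))
  empty <- data.frame(pair_id = character(0), label = integer(0),
                      seq_score_a = numeric(0), ss_score_a = numeric(0),
                      len_a = numeric(0), seq_score_b = numeric(0),
                      ss_score_b = numeric(0), len_b = numeric(0),
                      interface_size = integer(0), l_plus = numeric(0),
                      l_minus = numeric(0), stringsAsFactors = FALSE)
  if (spec$n_positive_pairs == 0L && spec$n_negative_pairs == 0L) return(empty)
  gen <- generate_family(spec)
  fam <- gen$family; truth <- gen$truth
  if (is.null(params)) {
    params <- mcmc_params(rng_seed = (spec$rng_seed + 1L) %% .Machine$integer.max)
  }
  pd <- estimate_pair_distribution(fam, pairs = c(fam$seed_pairs, fam$msa_pairs))
  fit <- interface_profile(fam, params, pair_dist = pd)
  set.seed((spec$rng_seed + 2L) %% .Machine$integer.max)
  n_pos <- spec$n_positive_pairs; n_neg <- spec$n_negative_pairs
  draws <- list(if (n_pos > 0) .gen_draw(truth, n_pos, coupled = TRUE),
                if (n_neg > 0) .gen_draw(truth, n_neg, coupled = FALSE))
  labels <- c(rep(1L, n_pos), rep(0L, n_neg))
  cm <- fam$contact_map
  rows <- vector("list", n_pos + n_neg)
  idx <- 0L
  for (d in seq_along(draws)) {
    dr <- draws[[d]]
    if (is.null(dr)) next
    for (i in seq_len(nrow(dr$a))) {
      idx <- idx + 1L
      assignment <- stats::setNames(
        AA21[c(dr$a[i, cm$interface_cols_a], dr$b[i, cm$interface_cols_b])],
        interface_nodes(cm))
      rec <- list(pair_id = sprintf("pair%03d", idx),
                  seq_score_a = profile_score(dr$a[i, ], fam$profile_a),
                  ss_score_a = stats::rnorm(1),
                  len_a = truth$n_cols_a,
                  seq_score_b = profile_score(dr$b[i, ], fam$profile_b),
                  ss_score_b = stats::rnorm(1),
                  len_b = truth$n_cols_b)
      rows[[idx]] <- extract_features(rec, assignment, fit)
    }
  }
  out <- do.call(rbind, rows)
  out <- cbind(out[, "pair_id", drop = FALSE], label = labels,
               out[, setdiff(names(out), "pair_id")])
  attr(out, "truth") <- truth
  attr(out, "family") <- fam
  attr(out, "fit") <- fit
  out
}
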