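# Simulated interface co-evolution: artificial interacting homolog pairs are
# generated from each seed complex by mutation + stochastic selection.
# Contacting residue pairs are resampled from the conditional of a paired
# residue distribution (one side fixed by a fair coin), non-contacting
# residues independently via a BLOSUM62-derived conditional; proposals are
# accepted by a Metropolis rule on the joint profile fitness.

#' MCMC sampling parameters
#'
#' @param contact_mutation_fraction Fraction of interface contacts mutated per
#'   step (default 0.05); the number mutated is `ceiling(fraction * n)`.
#' @param noncontact_mutation_fraction Fraction of non-contacting (mutable)
#'   residues mutated per step in each protein (default 0.05).
#' @param temperature Selection temperature in score (bit) units; acceptance
#'   probability is `min(1, exp(delta_fitness / temperature))`.
#' @param n_samples_per_seed Samples collected per seed complex (default
#'   1000).
#' @param n_samples_single_seed Samples collected when the family has exactly
#'   one seed complex (default 2500).
#' @param burn_in Steps discarded at the start of each chain.
#' @param thinning Keep every `thinning`-th state after burn-in.
#' @param rng_seed Integer seed; `NULL` leaves the RNG state untouched.
#' @param hastings If `TRUE`, the acceptance ratio includes the proposal
#'   ratio of the sampled move (exact Metropolis-Hastings); by default the
#'   plain fitness-only rule is used, mirroring the described procedure.
#' @return An object of class `coev_mcmc_params`.
#' @export
mcmc_params <- function(contact_mutation_fraction = 0.05,
                        noncontact_mutation_fraction = 0.05,
                        temperature = 1,
                        n_samples_per_seed = 1000,
                        n_samples_single_seed = 2500,
                        burn_in = 500,
                        thinning = 10,
                        rng_seed = NULL,
                        hastings = FALSE) {
  stopifnot(contact_mutation_fraction >= 0, contact_mutation_fraction <= 1,
            noncontact_mutation_fraction >= 0, noncontact_mutation_fraction <= 1,
            temperature > 0, n_samples_per_seed >= 0,
            n_samples_single_seed >= 0, burn_in >= 0, thinning >= 1)
  structure(list(contact_mutation_fraction = contact_mutation_fraction,
                 noncontact_mutation_fraction = noncontact_mutation_fraction,
                 temperature = temperature,
                 n_samples_per_seed = as.integer(n_samples_per_seed),
                 n_samples_single_seed = as.integer(n_samples_single_seed),
                 burn_in = as.integer(burn_in),
                 thinning = as.integer(thinning),
                 rng_seed = rng_seed,
                 hastings = isTRUE(hastings)),
            class = "coev_mcmc_params")
}

#' Paired residue distribution at interface contacts
#'
#' A 20 x 20 joint distribution over `(residue_a, residue_b)` at a contact,
#' with the two conditionals used by the mutation proposal.
#'
#' @param joint 20 x 20 non-negative matrix (normalized internally; must sum
#'   to a positive value).
#' @return An object of class `coev_pair_dist` with `joint`,
#'   `cond_b_given_a` (rows: fixed A residue), `cond_a_given_b` (rows: fixed
#'   B residue).
#' @export
pair_distribution <- function(joint) {
  m <- as.matrix(joint)
  if (!all(dim(m) == c(N_AA, N_AA))) stop("joint must be 20 x 20", call. = FALSE)
  if (any(!is.finite(m)) || any(m < 0)) stop("joint must be non-negative and finite", call. = FALSE)
  tot <- sum(m)
  if (tot <= 0) stop("joint has no mass", call. = FALSE)
  m <- m / tot
  dimnames(m) <- list(AA20, AA20)
  norm_rows <- function(x) {
    rs <- rowSums(x)
    zero <- rs == 0
    x[zero, ] <- 1 / N_AA
    rs[zero] <- 1
    x / rs
  }
  structure(list(joint = m,
                 cond_b_given_a = norm_rows(m),
                 cond_a_given_b = norm_rows(t(m))),
            class = "coev_pair_dist")
}

#' @export
print.coev_pair_dist <- function(x, ...) {
  cat("Contact-pair residue distribution (20 x 20)\n")
  cat(sprintf("  mass on diagonal: %.3f; max cell: %.4f\n",
              sum(diag(x$joint)), max(x$joint)))
  invisible(x)
}

#' Estimate the contact-pair residue distribution from a family
#'
#' Counts ordered residue pairs `(a, b)` over every contact of the family's
#' contact map and every supplied aligned pair, then applies a pseudocount:
#' `joint[r, s] = (count + pseudocount) / (total + 400 * pseudocount)`.
#' Contact observations where either side is a gap are skipped (with a
#' warning).
#'
#' @param family A [family_seed()].
#' @param pseudocount Non-negative pseudocount per cell; must be positive if
#'   any cell is unobserved.
#' @param pairs Aligned pairs to count over; defaults to the family's seed
#'   pairs. Pass `c(family$seed_pairs, family$msa_pairs)` to include a full
#'   paired family alignment.
#' @return A [pair_distribution()].
#' @export
estimate_pair_distribution <- function(family, pseudocount = 1, pairs = NULL) {
  stopifnot(inherits(family, "coev_family"))
  if (is.null(pairs)) pairs <- family$seed_pairs
  contacts <- family$contact_map$contacts
  if (nrow(contacts) == 0L) stop("family has no contacts", call. = FALSE)
  counts <- matrix(0, N_AA, N_AA, dimnames = list(AA20, AA20))
  skipped <- 0L
  for (p in pairs) {
    ca <- .check_codes(seq_to_codes(p$seq_a), "seq_a")
    cb <- .check_codes(seq_to_codes(p$seq_b), "seq_b")
    ra <- ca[contacts[, 1]]
    rb <- cb[contacts[, 2]]
    ok <- ra != GAP_CODE & rb != GAP_CODE
    skipped <- skipped + sum(!ok)
    if (any(ok)) {
      idx <- cbind(ra[ok], rb[ok])
      for (i in seq_len(nrow(idx))) counts[idx[i, 1], idx[i, 2]] <- counts[idx[i, 1], idx[i, 2]] + 1
    }
  }
  if (skipped > 0L) warning(sprintf("%d contact observation(s) skipped (gap on one side)", skipped))
  if (pseudocount == 0 && any(counts == 0)) {
    stop("pseudocount must be > 0 when some residue pairs are unobserved", call. = FALSE)
  }
  pair_distribution((counts + pseudocount) / (sum(counts) + 400 * pseudocount))
}

# Per-chain mutation context: which contacts and which non-contact positions
# are mutable given the seed's (immutable) gap pattern.
.mutation_ctx <- function(codes_a, codes_b, cm) {
  contacts <- cm$contacts
  usable <- contacts[, 1] %in% which(codes_a != GAP_CODE) &
    contacts[, 2] %in% which(codes_b != GAP_CODE)
  iface_a <- cm$interface_cols_a
  iface_b <- cm$interface_cols_b
  nc_a <- setdiff(which(codes_a != GAP_CODE), iface_a)
  nc_b <- setdiff(which(codes_b != GAP_CODE), iface_b)
  list(contacts = contacts[usable, , drop = FALSE], nc_a = nc_a, nc_b = nc_b)
}

# One mutation proposal on integer-coded state. Returns the proposed state,
# the natural-log forward/reverse proposal probabilities of the sampled move
# label (selected positions + coin choices), and the selections themselves.
.propose <- function(a, b, ctx, fc, fnc, pdist, subst) {
  lqf <- 0; lqr <- 0
  nc_sel_a <- integer(0); nc_sel_b <- integer(0); c_sel <- integer(0)
  n_c <- nrow(ctx$contacts)
  if (fc > 0 && n_c > 0L) {
    m <- min(n_c, as.integer(ceiling(fc * n_c)))
    c_sel <- if (m == n_c) seq_len(n_c) else sample.int(n_c, m)
    for (k in c_sel) {
      i <- ctx$contacts[k, 1]; j <- ctx$contacts[k, 2]
      if (stats::runif(1) < 0.5) {            # fix A, resample B
        cond <- pdist$cond_b_given_a[a[i], ]
        old <- b[j]
        new <- sample.int(N_AA, 1L, prob = cond)
        b[j] <- new
        lqf <- lqf + log(cond[[new]]); lqr <- lqr + log(cond[[old]])
      } else {                                # fix B, resample A
        cond <- pdist$cond_a_given_b[b[j], ]
        old <- a[i]
        new <- sample.int(N_AA, 1L, prob = cond)
        a[i] <- new
        lqf <- lqf + log(cond[[new]]); lqr <- lqr + log(cond[[old]])
      }
    }
  }
  if (fnc > 0) {
    if (length(ctx$nc_a) > 0L) {
      k <- min(length(ctx$nc_a), as.integer(ceiling(fnc * length(ctx$nc_a))))
      nc_sel_a <- ctx$nc_a[sample.int(length(ctx$nc_a), k)]
      for (i in nc_sel_a) {
        row <- subst[a[i], ]
        old <- a[i]
        new <- sample.int(N_AA, 1L, prob = row)
        a[i] <- new
        lqf <- lqf + log(row[[new]]); lqr <- lqr + log(subst[new, old])
      }
    }
    if (length(ctx$nc_b) > 0L) {
      k <- min(length(ctx$nc_b), as.integer(ceiling(fnc * length(ctx$nc_b))))
      nc_sel_b <- ctx$nc_b[sample.int(length(ctx$nc_b), k)]
      for (j in nc_sel_b) {
        row <- subst[b[j], ]
        old <- b[j]
        new <- sample.int(N_AA, 1L, prob = row)
        b[j] <- new
        lqf <- lqf + log(row[[new]]); lqr <- lqr + log(subst[new, old])
      }
    }
  }
  list(a = a, b = b, log_q_forward = lqf, log_q_reverse = lqr,
       contacts_selected = c_sel,
       noncontacts_selected_a = nc_sel_a, noncontacts_selected_b = nc_sel_b)
}

#' Propose one co-evolution mutation step
#'
#' Selects `ceiling(fraction * n)` contacts uniformly without replacement;
#' for each, fixes one side by a fair coin and resamples the other from the
#' paired distribution's conditional given the fixed residue. Independently,
#' `ceiling(fraction * n)` non-contacting positions per protein are resampled
#' from the substitution conditional given their current residue. Gap
#' positions are immutable and never proposed.
#'
#' @param pair An [aligned_pair()] conforming to `contact_map`.
#' @param contact_map A [contact_map()].
#' @param pair_dist A [pair_distribution()].
#' @param params An [mcmc_params()] (only the two mutation fractions are
#'   used).
#' @param subst 20 x 20 row-stochastic substitution conditional; defaults to
#'   [blosum_conditional()].
#' @return The proposed [aligned_pair()], with attributes
#'   `contacts_mutated` (row indices into the usable contact list),
#'   `noncontacts_mutated_a` / `_b` (column indices), and
#'   `log_q_forward` / `log_q_reverse` (natural-log proposal probabilities of
#'   the sampled move).
#' @export
propose_mutation <- function(pair, contact_map, pair_dist,
                             params = mcmc_params(),
                             subst = blosum_conditional()) {
  stopifnot(inherits(contact_map, "coev_contact_map"),
            inherits(pair_dist, "coev_pair_dist"))
  a <- .check_codes(seq_to_codes(pair$seq_a), "seq_a")
  b <- .check_codes(seq_to_codes(pair$seq_b), "seq_b")
  if (length(a) != contact_map$length_a || length(b) != contact_map$length_b) {
    stop("pair lengths do not match the contact map", call. = FALSE)
  }
  ctx <- .mutation_ctx(a, b, contact_map)
  pr <- .propose(a, b, ctx, params$contact_mutation_fraction,
                 params$noncontact_mutation_fraction, pair_dist, subst)
  out <- aligned_pair(codes_to_seq(pr$a), codes_to_seq(pr$b))
  attr(out, "contacts_mutated") <- pr$contacts_selected
  attr(out, "noncontacts_mutated_a") <- pr$noncontacts_selected_a
  attr(out, "noncontacts_mutated_b") <- pr$noncontacts_selected_b
  attr(out, "log_q_forward") <- pr$log_q_forward
  attr(out, "log_q_reverse") <- pr$log_q_reverse
  out
}

#' Joint fitness of an aligned pair
#'
#' Sum of the two per-protein profile scores.
#'
#' @param pair An [aligned_pair()].
#' @param profile_a,profile_b [build_profile()] objects.
#' @return Numeric score in bits.
#' @export
joint_fitness <- function(pair, profile_a, profile_b) {
  profile_score(pair$seq_a, profile_a) + profile_score(pair$seq_b, profile_b)
}

#' Metropolis acceptance decision
#'
#' Accepts with probability
#' `min(1, exp((fitness_proposed - fitness_current) / temperature +
#' log_proposal_ratio))`.
#'
#' @param fitness_current,fitness_proposed Joint fitness scores (bits).
#' @param temperature Positive selection temperature (bits).
#' @param log_proposal_ratio Natural-log Hastings correction
#'   `log q(x | x') - log q(x' | x)`; 0 for the plain fitness-only rule.
#' @return Logical.
#' @export
mcmc_accept <- function(fitness_current, fitness_proposed, temperature,
                        log_proposal_ratio = 0) {
  if (temperature <= 0) stop("temperature must be positive", call. = FALSE)
  log_alpha <- (fitness_proposed - fitness_current) / temperature + log_proposal_ratio
  if (log_alpha >= 0) TRUE else stats::runif(1) < exp(log_alpha)
}

# Profile lookup tables with a 21st gap row, so fitness is a single indexed sum.
.profile_lut <- function(profile) {
  rbind(profile$log_odds, rep(profile$gap_penalty, ncol(profile$log_odds)))
}

#' Generate artificial interacting homolog pairs by MCMC
#'
#' Runs one independent chain per seed complex, started at that seed. After
#' `burn_in` steps, every `thinning`-th state is emitted until
#' `n_samples_per_seed` samples are collected per chain
#' (`n_samples_single_seed` when the family has exactly one seed). Chains are
#' pooled into a single sample set.
#'
#' @param family A [family_seed()].
#' @param params An [mcmc_params()].
#' @param pair_dist A [pair_distribution()]; by default estimated from the
#'   family's seed pairs (plus `family$msa_pairs` when present).
#' @param subst Substitution conditional for non-contacting positions;
#'   defaults to [blosum_conditional()].
#' @return An object of class `coev_samples`: integer-coded sample matrices
#'   `a` (n x length_a) and `b`, per-chain `fitness_trace` and
#'   `accepted_trace`, `acceptance_rate`, `params`, and a `converged` flag
#'   from [check_convergence()] (a non-converged chain warns, it does not
#'   fail).
#' @export
run_mcmc <- function(family, params = mcmc_params(), pair_dist = NULL,
                     subst = blosum_conditional()) {
  stopifnot(inherits(family, "coev_family"), inherits(params, "coev_mcmc_params"))
  if (is.null(pair_dist)) {
    pairs <- c(family$seed_pairs, family$msa_pairs)
    pair_dist <- estimate_pair_distribution(family, pairs = pairs)
  }
  if (!is.null(params$rng_seed)) set.seed(params$rng_seed)
  n_seeds <- length(family$seed_pairs)
  n_target <- if (n_seeds == 1L) params$n_samples_single_seed else params$n_samples_per_seed
  lut_a <- .profile_lut(family$profile_a)
  lut_b <- .profile_lut(family$profile_b)
  cols_a <- seq_len(ncol(lut_a)); cols_b <- seq_len(ncol(lut_b))
  fitness_of <- function(a, b) {
    sum(lut_a[cbind(a, cols_a)]) + sum(lut_b[cbind(b, cols_b)])
  }
  all_a <- vector("list", n_seeds); all_b <- vector("list", n_seeds)
  traces <- vector("list", n_seeds); acc_traces <- vector("list", n_seeds)
  n_acc <- 0L; n_steps_total <- 0L; converged <- TRUE
  for (chain in seq_len(n_seeds)) {
    seed <- family$seed_pairs[[chain]]
    a <- .check_codes(seq_to_codes(seed$seq_a))
    b <- .check_codes(seq_to_codes(seed$seq_b))
    ctx <- .mutation_ctx(a, b, family$contact_map)
    fit <- fitness_of(a, b)
    n_steps <- params$burn_in + n_target * params$thinning
    if (n_target == 0L) n_steps <- 0L
    trace <- numeric(n_steps); acc <- logical(n_steps)
    out_a <- matrix(0L, nrow = n_target, ncol = length(a))
    out_b <- matrix(0L, nrow = n_target, ncol = length(b))
    emitted <- 0L
    for (step in seq_len(n_steps)) {
      pr <- .propose(a, b, ctx, params$contact_mutation_fraction,
                     params$noncontact_mutation_fraction, pair_dist, subst)
      fit_prop <- fitness_of(pr$a, pr$b)
      lqr <- if (params$hastings) pr$log_q_reverse - pr$log_q_forward else 0
      if (mcmc_accept(fit, fit_prop, params$temperature, lqr)) {
        a <- pr$a; b <- pr$b; fit <- fit_prop; acc[step] <- TRUE
      }
      trace[step] <- fit
      if (step > params$burn_in &&
          (step - params$burn_in) %% params$thinning == 0L) {
        emitted <- emitted + 1L
        out_a[emitted, ] <- a
        out_b[emitted, ] <- b
      }
    }
    all_a[[chain]] <- out_a; all_b[[chain]] <- out_b
    traces[[chain]] <- trace; acc_traces[[chain]] <- acc
    n_acc <- n_acc + sum(acc); n_steps_total <- n_steps_total + n_steps
    # diagnostic window: wide enough that autocorrelated window means settle
    w <- min(2000L, floor(n_steps / 2))
    if (w >= 2L && !check_convergence(trace, w, 0.5)) converged <- FALSE
  }
  if (!converged) warning("MCMC convergence check failed for at least one chain")
  structure(list(a = do.call(rbind, all_a), b = do.call(rbind, all_b),
                 fitness_trace = traces, accepted_trace = acc_traces,
                 acceptance_rate = if (n_steps_total > 0) n_acc / n_steps_total else NA_real_,
                 params = params, converged = converged,
                 family_id = family$id),
            class = "coev_samples")
}

#' @export
print.coev_samples <- function(x, ...) {
  cat(sprintf("MCMC sample set: %d pairs (%d + %d columns), acceptance rate %.3f, converged: %s\n",
              nrow(x$a), ncol(x$a), ncol(x$b),
              x$acceptance_rate, x$converged))
  invisible(x)
}

#' Convert a sample set to aligned pairs
#'
#' @param samples A `coev_samples` object.
#' @return List of [aligned_pair()] objects.
#' @export
as_aligned_pairs <- function(samples) {
  stopifnot(inherits(samples, "coev_samples"))
  lapply(seq_len(nrow(samples$a)), function(i) {
    aligned_pair(codes_to_seq(samples$a[i, ]), codes_to_seq(samples$b[i, ]))
  })
}

#' Window-mean convergence check for a fitness trace
#'
#' Compares the means of the last two non-overlapping windows: converged when
#' their absolute difference is at most `tolerance` times the pooled standard
#' deviation of the two windows.
#'
#' @param fitness_trace Numeric trace; must have length at least `2 * window`.
#' @param window Window length.
#' @param tolerance Multiple of the pooled standard deviation allowed.
#' @return Logical.
#' @export
check_convergence <- function(fitness_trace, window = 500, tolerance = 0.5) {
  n <- length(fitness_trace)
  if (n < 2 * window) stop("trace shorter than two windows", call. = FALSE)
  last <- fitness_trace[(n - window + 1):n]
  prev <- fitness_trace[(n - 2 * window + 1):(n - window)]
  pooled <- sqrt((stats::var(last) + stats::var(prev)) / 2)
  abs(mean(last) - mean(prev)) <= tolerance * pooled
}
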