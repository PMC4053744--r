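# Shared fixture builders. Everything is generated in code at test time.

AA20_T <- coevnet::aa_alphabet()
AA21_T <- c(AA20_T, "-")

# A 20x20 contact-pair distribution supported on {A, V}: P(same) = p_same
# split over (A,A) and (V,V), the rest over (A,V) and (V,A).
av_pair_dist <- function(p_same = 0.8) {
  m <- matrix(0, 20, 20, dimnames = list(AA20_T, AA20_T))
  m["A", "A"] <- p_same / 2; m["V", "V"] <- p_same / 2
  m["A", "V"] <- (1 - p_same) / 2; m["V", "A"] <- (1 - p_same) / 2
  pair_distribution(m)
}

# Row-stochastic substitution conditional supported on {A, V}.
av_subst <- function(stay = 0.7) {
  m <- matrix(1 / 20, 20, 20, dimnames = list(AA20_T, AA20_T))
  m["A", ] <- 0; m["V", ] <- 0
  m["A", "A"] <- stay; m["A", "V"] <- 1 - stay
  m["V", "V"] <- stay; m["V", "A"] <- 1 - stay
  m
}

# Profile over an L-column alignment with P(A) = p_a and P(V) = 1 - p_a in
# every column (uniform background), built directly so tests control the
# column probabilities exactly.
av_profile <- function(L, p_a = 0.7) {
  bg <- coevnet::uniform_background()
  probs <- matrix(0, 20, L, dimnames = list(AA20_T, NULL))
  probs["A", ] <- p_a; probs["V", ] <- 1 - p_a
  structure(list(log_odds = log2(probs / bg), background = bg,
                 pseudocount = 0, gap_penalty = -4),
            class = "coev_seq_profile")
}

# Toy family: 2 proteins x 2 columns over {A, V}, one contact A2-B1.
# Non-contact columns are A1 and B2. 16 enumerable joint states.
toy_family <- function(p_a = 0.7, n_seeds = 1) {
  cm <- contact_map(matrix(c(2L, 1L), ncol = 2), 2, 2)
  seeds <- rep(list(aligned_pair("AA", "AA")), n_seeds)
  if (n_seeds > 1) seeds[[2]] <- aligned_pair("VV", "VV")
  family_seed(seeds, cm, av_profile(2, p_a), av_profile(2, p_a), id = "toy")
}

# Random tree over n nodes with random (strictly positive) tables.
random_tree <- function(n_nodes, seed) {
  set.seed(seed)
  nodes <- sort(sprintf("A%d", sample(1:50, n_nodes)))
  rdist <- function(k) { w <- stats::rgamma(k, 1) + 0.05; w / sum(w) }
  marginal <- stats::setNames(rdist(21), AA21_T)
  edges <- if (n_nodes >= 2) {
    data.frame(parent = nodes[c(1, seq_len(max(0, n_nodes - 2)) + 1)][seq_len(n_nodes - 1)],
               child = nodes[-1], stringsAsFactors = FALSE)
  } else data.frame(parent = character(0), child = character(0))
  cpts <- lapply(seq_len(nrow(edges)), function(e) {
    m <- t(vapply(1:21, function(i) rdist(21), numeric(21)))
    dimnames(m) <- list(AA21_T, AA21_T)
    m
  })
  names(cpts) <- if (nrow(edges)) paste(edges$parent, edges$child, sep = "->") else character(0)
  structure(list(nodes = nodes, edges = edges, root = nodes[1],
                 marginal = marginal, cpts = cpts,
                 mi = stats::setNames(rep(NA_real_, nrow(edges)), names(cpts)),
                 pseudocount = 0.5, n_samples = 0L),
            class = "coev_tree")
}

# All 21^n assignments over the given nodes, as a code matrix.
enumerate_assignments <- function(nodes) {
  g <- do.call(expand.grid, rep(list(1:21), length(nodes)))
  m <- as.matrix(g)
  colnames(m) <- nodes
  m
}

# Brute-force joint probability of a code assignment under a tree's
# factorization, computed directly from the tables (independent of
# tree_loglik's arithmetic).
brute_tree_prob <- function(codes, tree) {
  p <- tree$marginal[[codes[[tree$root]]]]
  if (nrow(tree$edges)) {
    for (e in seq_len(nrow(tree$edges))) {
      p <- p * tree$cpts[[e]][codes[[tree$edges$parent[e]]],
                              codes[[tree$edges$child[e]]]]
    }
  }
  p
}

# Samples from a 6-node chain of noisy copy channels over a k-letter
# sub-alphabet: root uniform, each next node copies its neighbour with
# probability `stay`, otherwise uniform over the other k-1 letters.
chain_samples <- function(n, nodes, k = 4, stay = 0.7) {
  x <- matrix(0L, n, length(nodes), dimnames = list(NULL, nodes))
  x[, 1] <- sample.int(k, n, replace = TRUE)
  for (j in 2:length(nodes)) {
    copy <- stats::runif(n) < stay
    x[, j] <- ifelse(copy, x[, j - 1],
                     1L + (x[, j - 1] - 1L + sample.int(k - 1, n, replace = TRUE)) %% k)
  }
  x
}

# Small labeled dataset with a known signal in l_plus / l_minus.
sim_logistic_data <- function(n, beta, alpha = 0, seed = 1) {
  set.seed(seed)
  x <- matrix(stats::rnorm(n * 9), n, 9)
  colnames(x) <- c("seq_score_a", "ss_score_a", "len_a",
                   "seq_score_b", "ss_score_b", "len_b",
                   "interface_size", "l_plus", "l_minus")
  eta <- alpha + drop(x %*% beta)
  y <- stats::rbinom(n, 1, stats::plogis(eta))
  data.frame(pair_id = sprintf("p%d", seq_len(n)), label = y, x,
             stringsAsFactors = FALSE)
}
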