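# Helpers to build a coev_samples object directly from code matrices.
samples_from_codes <- function(a, b) {
  structure(list(a = a, b = b, fitness_trace = list(), accepted_trace = list(),
                 acceptance_rate = NA_real_, params = NULL, converged = NA),
            class = "coev_samples")
}

test_that("mutual information matches the brute-force double sum", {
  set.seed(5)
  x <- cbind(A1 = sample.int(21, 50, replace = TRUE),
             B2 = sample.int(21, 50, replace = TRUE))
  for (pc in c(0.5, 1)) {
    joint <- matrix(pc, 21, 21)
    for (i in 1:50) joint[x[i, 1], x[i, 2]] <- joint[x[i, 1], x[i, 2]] + 1
    joint <- joint / sum(joint)
    pi <- rowSums(joint); pj <- colSums(joint)
    brute <- 0
    for (r in 1:21) for (s in 1:21) {
      if (joint[r, s] > 0) brute <- brute + joint[r, s] * log2(joint[r, s] / (pi[r] * pj[s]))
    }
    expect_equal(mutual_information(x, "A1", "B2", pc), brute, tolerance = 1e-12)
  }
  expect_error(mutual_information(x, "A1", "Z9"), "unknown node")
})

test_that("mutual information separates independent and copied columns", {
  # plug-in MI has upward bias ~ (I-1)(J-1) / (2 n ln 2); n is chosen so the
  # bias sits well below the thresholds asserted here
  set.seed(6)
  n <- 40000
  ind <- cbind(A1 = sample.int(21, n, replace = TRUE),
               B1 = sample.int(21, n, replace = TRUE))
  expect_lt(mutual_information(ind, "A1", "B1", 0.5), 0.01)
  # uniform 2-symbol copy channel carries exactly 1 bit
  z <- sample(c(1L, 18L), n, replace = TRUE)
  cop <- cbind(A1 = z, B1 = z)
  expect_equal(mutual_information(cop, "A1", "B1", 1e-9), 1, tolerance = 0.02)
})

test_that("learn_tree recovers forced and chain structures deterministically", {
  # 2 nodes: the single possible edge, CPT = pseudocounted conditionals
  set.seed(8)
  x2 <- cbind(A1 = sample.int(3, 40, replace = TRUE),
              B1 = sample.int(3, 40, replace = TRUE))
  tr2 <- learn_tree(x2, pseudocount = 0.5)
  expect_equal(nrow(tr2$edges), 1)
  expect_equal(tr2$root, "A1")
  cnt <- table(factor(x2[, 1], levels = 1:21), factor(x2[, 2], levels = 1:21))
  want_row3 <- (cnt[3, ] + 0.5) / (sum(cnt[3, ]) + 21 * 0.5)
  expect_equal(unname(tr2$cpts[[1]][3, ]), unname(as.numeric(want_row3)),
               tolerance = 1e-12)

  # known 6-node chain with strong couplings is recovered exactly
  nodes <- c("A1", "A2", "B1", "B2", "B3", "B4")
  set.seed(13)
  x <- chain_samples(5000, nodes, k = 4, stay = 0.75)
  tr <- learn_tree(x, pseudocount = 0.5)
  got <- sort(paste(pmin(tr$edges$parent, tr$edges$child),
                    pmax(tr$edges$parent, tr$edges$child)))
  want <- sort(c("A1 A2", "A2 B1", "B1 B2", "B2 B3", "B3 B4"))
  expect_equal(got, want)

  # permuting sample order leaves the learned tree bit-identical
  perm <- sample(nrow(x))
  tr_p <- learn_tree(x[perm, ], pseudocount = 0.5)
  expect_identical(tr_p$edges, tr$edges)
  expect_identical(tr_p$cpts, tr$cpts)

  # degenerate node counts
  expect_error(learn_tree(x[, integer(0), drop = FALSE]), "no interface nodes")
  one <- learn_tree(x[, 1, drop = FALSE])
  expect_equal(length(one$nodes), 1)
  expect_equal(nrow(one$edges), 0)
  expect_equal(sum(one$marginal), 1, tolerance = 1e-9)
})

test_that("learned trees satisfy the normalization invariants", {
  set.seed(30)
  for (rep in 1:5) {
    n_nodes <- sample(2:6, 1)
    x <- matrix(sample.int(21, 200 * n_nodes, replace = TRUE), 200, n_nodes)
    colnames(x) <- paste0(sample(c("A", "B"), n_nodes, TRUE), sample(99, n_nodes))
    tr <- learn_tree(x, pseudocount = 0.5)
    expect_equal(nrow(tr$edges), n_nodes - 1)
    expect_equal(sum(tr$marginal), 1, tolerance = 1e-9)
    for (cpt in tr$cpts) expect_equal(unname(rowSums(cpt)), rep(1, 21), tolerance = 1e-9)
  }
})

test_that("Chow-Liu tree attains the maximum spanning-tree MI weight", {
  # brute force over all spanning trees of <= 5 nodes via Pruefer sequences
  set.seed(31)
  for (rep in 1:3) {
    n <- sample(3:5, 1)
    nodes <- paste0("A", seq_len(n))
    x <- chain_samples(80, nodes, k = 3, stay = sample(c(0.4, 0.7), 1))
    x <- x[, sample(n)]  # shuffle columns so the chain is not in order
    tr <- learn_tree(x, pseudocount = 0.5)
    w <- matrix(0, n, n, dimnames = list(colnames(x), colnames(x)))
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      w[i, j] <- w[j, i] <- mutual_information(x, colnames(x)[i], colnames(x)[j], 0.5)
    }
    got_weight <- sum(vapply(seq_len(nrow(tr$edges)), function(e) {
      w[tr$edges$parent[e], tr$edges$child[e]]
    }, 0))
    # enumerate all n^(n-2) labelled trees
    best <- -Inf
    pruefer <- as.matrix(do.call(expand.grid, rep(list(seq_len(n)), n - 2)))
    for (r in seq_len(nrow(pruefer))) {
      seq_ <- pruefer[r, ]
      degree <- rep(1L, n) + tabulate(seq_, n)
      edges <- matrix(0L, 0, 2)
      s <- seq_
      for (v in s) {
        leaf <- min(which(degree == 1L))
        edges <- rbind(edges, c(leaf, v))
        degree[leaf] <- degree[leaf] - 1L
        degree[v] <- degree[v] - 1L
      }
      edges <- rbind(edges, which(degree == 1L))
      weight <- sum(w[edges])
      best <- max(best, weight)
    }
    expect_equal(got_weight, best, tolerance = 1e-9)
  }
})

test_that("derangement shuffling preserves marginals and destroys coupling", {
  set.seed(14)
  n <- 30000
  z <- sample.int(20, n, replace = TRUE)
  noise <- stats::runif(n) < 0.9
  a <- cbind(z, sample.int(20, n, replace = TRUE))
  b <- cbind(ifelse(noise, z, sample.int(20, n, replace = TRUE)),
             sample.int(20, n, replace = TRUE))
  s <- samples_from_codes(a, b)
  cm <- contact_map(rbind(c(1, 1)), 2, 2)
  x_pos <- interface_assignments(s, cm)
  expect_gt(mutual_information(x_pos, "A1", "B1", 0.5), 0.5)
  neg <- build_negative_samples(s, rng_seed = 3)
  # A-halves untouched, B marginals preserved
  expect_identical(neg$a, s$a)
  expect_equal(sort(neg$b[, 1]), sort(s$b[, 1]))
  x_neg <- interface_assignments(neg, cm)
  expect_lt(mutual_information(x_neg, "A1", "B1", 0.5), 0.02)

  # two samples: the swap is the only derangement
  s2 <- samples_from_codes(a[1:2, ], b[1:2, ])
  n2 <- build_negative_samples(s2)
  expect_identical(n2$b, b[c(2, 1), ])
  expect_error(build_negative_samples(samples_from_codes(a[1, , drop = FALSE],
                                                         b[1, , drop = FALSE])),
               "derangement")
})

test_that("tree log-likelihood equals brute-force factorization and normalizes", {
  for (n_nodes in 1:3) {
    tr <- random_tree(n_nodes, seed = 40 + n_nodes)
    grid <- enumerate_assignments(tr$nodes)
    ll <- vapply(seq_len(nrow(grid)), function(i) tree_loglik(grid[i, ], tr), 0)
    brute <- vapply(seq_len(nrow(grid)), function(i) brute_tree_prob(grid[i, ], tr), 0)
    expect_equal(2^ll, brute, tolerance = 1e-12)
    expect_equal(sum(2^ll), 1, tolerance = 1e-9)
  }
  # single-node tree with uniform residue marginal (no gap mass)
  tr1 <- random_tree(1, seed = 1)
  tr1$marginal[] <- c(rep(1 / 20, 20), 0)
  expect_equal(tree_loglik(stats::setNames("C", tr1$nodes), tr1), log2(1 / 20),
               tolerance = 1e-12)
  expect_error(tree_loglik(stats::setNames("u", tr1$nodes), tr1), "alphabet")
  expect_error(tree_loglik(c(Z9 = "A"), tr1), "cover")
})

test_that("re-rooting leaves the tree likelihood invariant", {
  # learn the same joint with different column orders so the root changes,
  # then compare likelihoods of identical assignments
  set.seed(50)
  nodes <- c("A1", "A2", "B7")
  x <- chain_samples(400, nodes, k = 4, stay = 0.7)
  tr_a <- learn_tree(x, pseudocount = 0.5)
  x2 <- x; colnames(x2) <- c("B7", "A2", "A1")  # relabel so root differs
  tr_b <- learn_tree(x2, pseudocount = 0.5)
  for (i in 1:20) {
    codes <- stats::setNames(sample.int(21, 3, replace = TRUE), nodes)
    codes2 <- stats::setNames(codes[c("B7", "A2", "A1")], c("A1", "A2", "B7"))
    ll_a <- tree_loglik(codes, tr_a)
    ll_b <- tree_loglik(codes2, tr_b)
    expect_equal(ll_a, ll_b, tolerance = 1e-9)
  }
})

test_that("interface scoring uses both trees and tolerates all-gap input", {
  tr <- random_tree(3, seed = 77)
  pp <- profile_pair(tr, tr)
  a <- stats::setNames(c("A", "-", "W"), tr$nodes)
  s <- score_interface(a, pp)
  expect_equal(unname(s["L_plus"]), unname(s["L_minus"]))
  gaps <- stats::setNames(rep("-", 3), tr$nodes)
  expect_true(all(is.finite(score_interface(gaps, pp))))
  tr2 <- random_tree(4, seed = 78)
  expect_error(profile_pair(tr, tr2), "node set")
})

test_that("samples from the positive tree score higher under it than the negative", {
  set.seed(60)
  n <- 1000
  z <- sample.int(5, n, replace = TRUE)
  stay <- stats::runif(n) < 0.85
  a <- cbind(z)
  b <- cbind(ifelse(stay, z, sample.int(5, n, replace = TRUE)))
  s <- samples_from_codes(a, b)
  cm <- contact_map(rbind(c(1, 1)), 1, 1)
  pos <- learn_tree(interface_assignments(s, cm), 0.5)
  neg <- learn_tree(interface_assignments(build_negative_samples(s, 4), cm), 0.5)
  pp <- profile_pair(pos, neg)
  draws <- simulate(pos, nsim = 500, seed = 61)
  delta <- vapply(seq_len(nrow(draws)), function(i) {
    sc <- score_interface(draws[i, ], pp)
    sc[["L_plus"]] - sc[["L_minus"]]
  }, 0)
  expect_gt(mean(delta), 0)
})

test_that("tree models and profile pairs round-trip through JSON", {
  set.seed(70)
  nodes <- c("A1", "A3", "B2")
  x <- chain_samples(200, nodes, k = 4, stay = 0.7)
  tr <- learn_tree(x, pseudocount = 0.5)
  path <- withr::local_tempfile(fileext = ".json")
  write_tree_json(tr, path)
  back <- read_tree_json(path)
  expect_equal(back$nodes, tr$nodes)
  expect_equal(back$edges, tr$edges)
  expect_equal(back$marginal, tr$marginal, tolerance = 1e-12)
  expect_equal(back$cpts, tr$cpts, tolerance = 1e-12)
  codes <- stats::setNames(c("A", "C", "-"), nodes)
  expect_equal(tree_loglik(codes, back), tree_loglik(codes, tr), tolerance = 1e-12)

  cm <- contact_map(rbind(c(1, 2), c(3, 2)), 3, 2)
  pp <- profile_pair(tr, tr, family_id = "fam1",
                     contact_map = cm)
  pq <- withr::local_tempfile(fileext = ".json")
  write_profile_pair_json(pp, pq)
  back_pp <- read_profile_pair_json(pq)
  expect_equal(back_pp$family_id, "fam1")
  expect_equal(back_pp$contact_map$contacts, cm$contacts)
  expect_equal(score_interface(codes, back_pp), score_interface(codes, pp),
               tolerance = 1e-12)
})
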