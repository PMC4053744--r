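# Spanning-tree graphical models over interface columns. Structure is the
# maximum-weight spanning tree under pairwise mutual information (Chow-Liu);
# node/edge tables are pseudocounted over the 21-symbol alphabet (20 residues
# plus gap) so gapped query interfaces remain scorable.

# Canonical node order: protein A before B, columns ascending. Deterministic
# root and tie-break order for structure learning.
.node_order <- function(nodes) {
  p <- .node_parts(nodes)
  order(p$tag, p$col)
}

#' Extract interface assignments from a sample set
#'
#' Builds the matrix of interface residues (integer codes 1..21, gap = 21)
#' with one row per sample and one column per interface node of the contact
#' map, in canonical node order.
#'
#' @param samples A `coev_samples` object from [run_mcmc()].
#' @param cm The family's [contact_map()].
#' @return Integer matrix with interface node ids as column names.
#' @export
interface_assignments <- function(samples, cm) {
  stopifnot(inherits(samples, "coev_samples"), inherits(cm, "coev_contact_map"))
  m <- cbind(samples$a[, cm$interface_cols_a, drop = FALSE],
             samples$b[, cm$interface_cols_b, drop = FALSE])
  colnames(m) <- interface_nodes(cm)
  m
}

# Coerce an assignment container (named character vector, named code vector,
# or 1-row matrix) to integer codes named by node.
.assignment_codes <- function(assignment) {
  if (is.matrix(assignment)) assignment <- assignment[1, ]
  nms <- names(assignment)
  if (is.null(nms)) stop("assignment must be named by interface node id", call. = FALSE)
  if (is.character(assignment)) {
    codes <- match(toupper(assignment), AA21)
    if (anyNA(codes)) {
      bad <- nms[which(is.na(codes))[1]]
      stop(sprintf("assignment at node %s holds a symbol outside the 21-letter alphabet", bad),
           call. = FALSE)
    }
  } else {
    codes <- as.integer(assignment)
    if (anyNA(codes) || any(codes < 1L) || any(codes > N_SYM)) {
      stop("assignment codes must be integers in 1..21", call. = FALSE)
    }
  }
  stats::setNames(codes, nms)
}

# Pseudocounted 21 x 21 joint over two columns of a code matrix.
.joint_table <- function(x, i, j, pseudocount) {
  counts <- matrix(0, N_SYM, N_SYM)
  t <- table(factor(x[, i], levels = 1:N_SYM), factor(x[, j], levels = 1:N_SYM))
  counts <- counts + as.matrix(t)
  p <- counts + pseudocount
  p / sum(p)
}

#' Mutual information between two interface columns
#'
#' MI in bits of the pseudocounted empirical joint distribution over the
#' 21-symbol alphabet.
#'
#' @param x Assignment matrix from [interface_assignments()] (or any integer
#'   code matrix with node ids as column names).
#' @param node_i,node_j Node ids (or column indices).
#' @param pseudocount Non-negative pseudocount per joint cell (default 0.5).
#' @return Non-negative numeric, bits.
#' @export
mutual_information <- function(x, node_i, node_j, pseudocount = 0.5) {
  if (nrow(x) < 1L) stop("at least one sample required", call. = FALSE)
  idx <- function(node) {
    if (is.character(node)) {
      k <- match(node, colnames(x))
      if (is.na(k)) stop(sprintf("unknown node id '%s'", node), call. = FALSE)
      k
    } else as.integer(node)
  }
  p <- .joint_table(x, idx(node_i), idx(node_j), pseudocount)
  pi <- rowSums(p); pj <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log2(p[nz] / outer(pi, pj)[nz]))
}

#' Learn a spanning-tree graphical model over interface columns
#'
#' Chow-Liu structure learning: the maximum-weight spanning tree under
#' pairwise mutual information, with deterministic tie-breaking (candidate
#' edges sorted by canonical node order) and the root fixed at the first node
#' in canonical order. Node marginals and edge conditional tables are
#' pseudocounted empirical frequencies over the 21-symbol alphabet.
#'
#' @param x Assignment matrix from [interface_assignments()].
#' @param pseudocount Pseudocount per table cell (default 0.5).
#' @return An object of class `coev_tree`: `nodes`, `edges` (data frame
#'   `parent`, `child`, directed away from `root`), `root`, `marginal`
#'   (21-vector for the root), `cpts` (named list of 21 x 21 row-stochastic
#'   matrices, rows = parent symbol), `mi` (edge MI weights), `pseudocount`,
#'   `n_samples`.
#' @export
learn_tree <- function(x, pseudocount = 0.5) {
  if (ncol(x) == 0L) stop("no interface nodes", call. = FALSE)
  if (is.null(colnames(x))) stop("assignment matrix must have node-id column names", call. = FALSE)
  nodes <- colnames(x)
  ord <- .node_order(nodes)
  x <- x[, ord, drop = FALSE]
  nodes <- nodes[ord]
  n_nodes <- length(nodes)
  if (nrow(x) < 2L && n_nodes > 1L) stop("at least two samples required", call. = FALSE)
  root <- nodes[1]
  # With edges present the node marginal is the projection of the
  # pseudocounted 21x21 edge joints, so marginal * CPT reproduces the same
  # pairwise table whichever endpoint is the parent (root-invariant
  # factorization). A single-node tree uses the plain pseudocounted counts.
  marg <- function(col, edge_consistent) {
    cnt <- tabulate(x[, col], nbins = N_SYM)
    if (edge_consistent) {
      stats::setNames((cnt + N_SYM * pseudocount) /
                        (nrow(x) + N_SYM^2 * pseudocount), AA21)
    } else {
      stats::setNames((cnt + pseudocount) / (nrow(x) + N_SYM * pseudocount), AA21)
    }
  }
  if (n_nodes == 1L) {
    return(structure(list(nodes = nodes, edges = data.frame(parent = character(0), child = character(0)),
                          root = root, marginal = marg(1, FALSE), cpts = list(), mi = numeric(0),
                          pseudocount = pseudocount, n_samples = nrow(x)),
                     class = "coev_tree"))
  }
  # candidate edges in canonical order; Kruskal on -MI with stable ties
  cand <- which(upper.tri(matrix(0, n_nodes, n_nodes)), arr.ind = TRUE)
  cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
  w <- vapply(seq_len(nrow(cand)), function(k) {
    mutual_information(x, cand[k, 1], cand[k, 2], pseudocount)
  }, 0)
  sel <- order(-w, cand[, 1], cand[, 2])
  parent_ds <- seq_len(n_nodes)
  find <- function(i) { while (parent_ds[i] != i) i <- parent_ds[i]; i }
  chosen <- integer(0)
  for (k in sel) {
    ri <- find(cand[k, 1]); rj <- find(cand[k, 2])
    if (ri != rj) {
      parent_ds[ri] <- rj
      chosen <- c(chosen, k)
      if (length(chosen) == n_nodes - 1L) break
    }
  }
  adj <- vector("list", n_nodes)
  for (k in chosen) {
    i <- cand[k, 1]; j <- cand[k, 2]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  # direct edges away from the root (BFS)
  parent <- rep(NA_integer_, n_nodes)
  visited <- logical(n_nodes); visited[1] <- TRUE
  queue <- 1L
  order_bfs <- integer(0)
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    order_bfs <- c(order_bfs, v)
    for (u in sort(adj[[v]])) {
      if (!visited[u]) { visited[u] <- TRUE; parent[u] <- v; queue <- c(queue, u) }
    }
  }
  child_idx <- order_bfs[-1]
  edges <- data.frame(parent = nodes[parent[child_idx]], child = nodes[child_idx],
                      stringsAsFactors = FALSE)
  cpts <- vector("list", length(child_idx))
  mi_e <- numeric(length(child_idx))
  for (e in seq_along(child_idx)) {
    ci <- child_idx[e]; pi_ <- parent[ci]
    jt <- .joint_table(x, pi_, ci, 0) * nrow(x) + pseudocount  # counts + pc
    cpt <- jt / rowSums(jt)
    dimnames(cpt) <- list(AA21, AA21)
    cpts[[e]] <- cpt
    mi_e[e] <- mutual_information(x, pi_, ci, pseudocount)
  }
  names(cpts) <- paste(edges$parent, edges$child, sep = "->")
  names(mi_e) <- names(cpts)
  structure(list(nodes = nodes, edges = edges, root = root,
                 marginal = marg(1, TRUE), cpts = cpts, mi = mi_e,
                 pseudocount = pseudocount, n_samples = nrow(x)),
            class = "coev_tree")
}

#' @export
print.coev_tree <- function(x, ...) {
  cat(sprintf("Interface tree model: %d nodes, root %s, pseudocount %g (learned from %d samples)\n",
              length(x$nodes), x$root, x$pseudocount, x$n_samples))
  if (nrow(x$edges)) {
    cat("  edges:", paste(sprintf("%s-%s", x$edges$parent, x$edges$child), collapse = " "), "\n")
  }
  invisible(x)
}

#' Background-shuffled negative sample set
#'
#' Keeps the A-sequences in order and permutes the B-sequences by a random
#' derangement, destroying inter-protein correlations while preserving both
#' proteins' marginal column distributions.
#'
#' @param samples A `coev_samples` object with at least 2 samples.
#' @param rng_seed Optional integer seed.
#' @return A `coev_samples` object.
#' @export
build_negative_samples <- function(samples, rng_seed = NULL) {
  stopifnot(inherits(samples, "coev_samples"))
  n <- nrow(samples$a)
  if (n < 2L) stop("at least two samples are required for a derangement", call. = FALSE)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  if (n == 2L) {
    perm <- c(2L, 1L)
  } else {
    repeat {
      perm <- sample.int(n)
      if (all(perm != seq_len(n))) break
    }
  }
  out <- samples
  out$b <- samples$b[perm, , drop = FALSE]
  out$fitness_trace <- list(); out$accepted_trace <- list()
  out
}

#' Tree log-likelihood of an interface assignment
#'
#' `log2 P(x) = log2 marginal[root][x_root] + sum over edges of
#' log2 CPT[x_parent, x_child]`.
#'
#' @param assignment Named character (or code) vector covering exactly the
#'   tree's nodes; symbols from the 20 residues plus `'-'`.
#' @param tree A [learn_tree()] object.
#' @return Log-likelihood in bits.
#' @export
tree_loglik <- function(assignment, tree) {
  stopifnot(inherits(tree, "coev_tree"))
  codes <- .assignment_codes(assignment)
  if (!setequal(names(codes), tree$nodes)) {
    stop("assignment must cover exactly the tree's nodes", call. = FALSE)
  }
  ll <- log2(tree$marginal[[codes[[tree$root]]]])
  if (nrow(tree$edges)) {
    for (e in seq_len(nrow(tree$edges))) {
      cpt <- tree$cpts[[e]]
      ll <- ll + log2(cpt[codes[[tree$edges$parent[e]]], codes[[tree$edges$child[e]]]])
    }
  }
  unname(ll)
}

#' Positive/negative interface profile pair
#'
#' Bundles the tree learned from simulated interacting pairs ("positive")
#' with the tree learned from background-shuffled pairs ("negative").
#'
#' @param positive,negative [learn_tree()] objects over the same node set.
#' @param family_id Family identifier.
#' @param contact_map Optional [contact_map()] retained so query pairs can be
#'   mapped to interface nodes.
#' @return An object of class `coev_profile_pair`.
#' @export
profile_pair <- function(positive, negative, family_id = "family",
                         contact_map = NULL) {
  stopifnot(inherits(positive, "coev_tree"), inherits(negative, "coev_tree"))
  if (!setequal(positive$nodes, negative$nodes)) {
    stop("positive and negative trees must share the same node set", call. = FALSE)
  }
  structure(list(positive = positive, negative = negative,
                 family_id = family_id, contact_map = contact_map),
            class = "coev_profile_pair")
}

#' Score an interface against the positive and negative trees
#'
#' @param assignment Named symbol vector over the trees' nodes.
#' @param pp A [profile_pair()] (or `coev_interface_profile` fit).
#' @return Named numeric vector `c(L_plus = ..., L_minus = ...)`.
#' @export
score_interface <- function(assignment, pp) {
  if (inherits(pp, "coev_interface_profile")) pp <- pp$profile_pair
  stopifnot(inherits(pp, "coev_profile_pair"))
  c(L_plus = tree_loglik(assignment, pp$positive),
    L_minus = tree_loglik(assignment, pp$negative))
}

#' Simulate assignments from a tree model
#'
#' Ancestral sampling: the root symbol from the root marginal, then each
#' child from its conditional table given the sampled parent.
#'
#' @param object A `coev_tree`.
#' @param nsim Number of assignments.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return Character matrix (`nsim` rows, nodes as columns).
#' @export
simulate.coev_tree <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n_nodes <- length(object$nodes)
  out <- matrix(0L, nrow = nsim, ncol = n_nodes,
                dimnames = list(NULL, object$nodes))
  ridx <- match(object$root, object$nodes)
  out[, ridx] <- sample.int(N_SYM, nsim, replace = TRUE, prob = object$marginal)
  if (nrow(object$edges)) {
    for (e in seq_len(nrow(object$edges))) {
      pidx <- match(object$edges$parent[e], object$nodes)
      cidx <- match(object$edges$child[e], object$nodes)
      cpt <- object$cpts[[e]]
      for (i in seq_len(nsim)) {
        out[i, cidx] <- sample.int(N_SYM, 1L, prob = cpt[out[i, pidx], ])
      }
    }
  }
  m <- matrix(AA21[out], nrow = nsim, dimnames = dimnames(out))
  m
}

# JSON serialization of tree models and profile pairs -------------------------

.tree_to_list <- function(tree) {
  list(nodes = tree$nodes,
       root = tree$root,
       edges = lapply(seq_len(nrow(tree$edges)),
                      function(e) list(parent = tree$edges$parent[e],
                                       child = tree$edges$child[e])),
       marginal = unname(tree$marginal),
       cpts = lapply(tree$cpts, function(m) lapply(seq_len(nrow(m)), function(i) unname(m[i, ]))),
       mi = as.list(tree$mi),
       pseudocount = tree$pseudocount,
       n_samples = tree$n_samples)
}

.tree_from_list <- function(obj) {
  edges <- if (length(obj$edges)) {
    data.frame(parent = vapply(obj$edges, `[[`, "", "parent"),
               child = vapply(obj$edges, `[[`, "", "child"),
               stringsAsFactors = FALSE)
  } else data.frame(parent = character(0), child = character(0))
  cpts <- lapply(obj$cpts, function(rows) {
    m <- do.call(rbind, lapply(rows, as.numeric))
    dimnames(m) <- list(AA21, AA21)
    m
  })
  structure(list(nodes = unlist(obj$nodes), edges = edges, root = obj$root,
                 marginal = stats::setNames(as.numeric(obj$marginal), AA21),
                 cpts = cpts,
                 mi = stats::setNames(as.numeric(unlist(obj$mi)), names(obj$mi)),
                 pseudocount = obj$pseudocount, n_samples = obj$n_samples),
            class = "coev_tree")
}

#' Write / read tree models and profile pairs as JSON
#'
#' @param tree A `coev_tree`; `pp` a [profile_pair()].
#' @param path File path.
#' @return Readers return the reconstructed object.
#' @export
write_tree_json <- function(tree, path) {
  jsonlite::write_json(.tree_to_list(tree), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_tree_json
#' @export
read_tree_json <- function(path) {
  .tree_from_list(jsonlite::read_json(path, simplifyVector = FALSE))
}

#' @rdname write_tree_json
#' @export
write_profile_pair_json <- function(pp, path) {
  stopifnot(inherits(pp, "coev_profile_pair"))
  obj <- list(family_id = pp$family_id,
              positive = .tree_to_list(pp$positive),
              negative = .tree_to_list(pp$negative))
  if (!is.null(pp$contact_map)) {
    cm <- pp$contact_map
    obj$contact_map <- list(contacts = lapply(seq_len(nrow(cm$contacts)),
                                              function(i) as.list(unname(cm$contacts[i, ]))),
                            length_a = cm$length_a, length_b = cm$length_b)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_tree_json
#' @export
read_profile_pair_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  cm <- NULL
  if (!is.null(obj$contact_map)) {
    m <- do.call(rbind, lapply(obj$contact_map$contacts, function(p) as.integer(unlist(p))))
    cm <- contact_map(m, obj$contact_map$length_a, obj$contact_map$length_b)
  }
  profile_pair(.tree_from_list(obj$positive), .tree_from_list(obj$negative),
               family_id = obj$family_id, contact_map = cm)
}
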