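# Top-level model fit: simulate co-evolved homolog pairs for a family and
# learn the positive/negative interface tree profiles from them.

#' Fit an interface co-evolution profile for a family
#'
#' Runs the MCMC co-evolution simulation ([run_mcmc()]) from the family's
#' seed complexes, pools the sampled interacting pairs, builds a
#' background-shuffled copy by derangement of the B-halves
#' ([build_negative_samples()]), and learns a positive and a negative
#' spanning-tree model over the interface columns ([learn_tree()]).
#'
#' @param family A [family_seed()].
#' @param params An [mcmc_params()].
#' @param pair_dist Optional [pair_distribution()]; estimated from the family
#'   when `NULL`.
#' @param tree_pseudocount Pseudocount for tree marginals/CPTs (default 0.5).
#' @param subst Non-contact substitution conditional (default
#'   [blosum_conditional()]).
#' @param keep_samples Retain the pooled sample set in the fit (default
#'   `FALSE`).
#' @return An object of class `coev_interface_profile` with elements
#'   `profile_pair` ([profile_pair()]), `family_id`, `n_samples`,
#'   `acceptance_rate`, `converged`, `params`, `fitness_trace`, and
#'   optionally `samples`.
#' @seealso [predict.coev_interface_profile()], [score_interface()],
#'   [confidence_model()]
#' @export
interface_profile <- function(family, params = mcmc_params(), pair_dist = NULL,
                              tree_pseudocount = 0.5,
                              subst = blosum_conditional(),
                              keep_samples = FALSE) {
  stopifnot(inherits(family, "coev_family"))
  if (interface_size(family$contact_map) == 0L) {
    stop("family has no interface columns: no interface model can be learned",
         call. = FALSE)
  }
  samples <- run_mcmc(family, params, pair_dist = pair_dist, subst = subst)
  if (nrow(samples$a) < 2L) {
    stop("at least two MCMC samples are required to learn the trees", call. = FALSE)
  }
  pos_x <- interface_assignments(samples, family$contact_map)
  neg <- build_negative_samples(samples)
  neg_x <- interface_assignments(neg, family$contact_map)
  pp <- profile_pair(learn_tree(pos_x, tree_pseudocount),
                     learn_tree(neg_x, tree_pseudocount),
                     family_id = family$id,
                     contact_map = family$contact_map)
  structure(list(profile_pair = pp,
                 family_id = family$id,
                 n_samples = nrow(samples$a),
                 acceptance_rate = samples$acceptance_rate,
                 converged = samples$converged,
                 params = params,
                 fitness_trace = samples$fitness_trace,
                 samples = if (keep_samples) samples else NULL),
            class = "coev_interface_profile")
}

#' @export
print.coev_interface_profile <- function(x, ...) {
  cat(sprintf("Interface co-evolution profile for family '%s'\n", x$family_id))
  cat(sprintf("  %d interface nodes; %d simulated pairs; acceptance rate %.3f; converged: %s\n",
              length(x$profile_pair$positive$nodes), x$n_samples,
              x$acceptance_rate, x$converged))
  invisible(x)
}

#' @method summary coev_interface_profile
#' @export
summary.coev_interface_profile <- function(object, ...) {
  pos <- object$profile_pair$positive
  neg <- object$profile_pair$negative
  out <- list(family_id = object$family_id,
              n_nodes = length(pos$nodes),
              n_samples = object$n_samples,
              acceptance_rate = object$acceptance_rate,
              converged = object$converged,
              positive_edges = pos$edges,
              positive_mi = pos$mi,
              negative_mi = neg$mi,
              mean_positive_mi = if (length(pos$mi)) mean(pos$mi) else NA_real_,
              mean_negative_mi = if (length(neg$mi)) mean(neg$mi) else NA_real_)
  class(out) <- "summary.coev_interface_profile"
  out
}

#' @export
print.summary.coev_interface_profile <- function(x, ...) {
  cat(sprintf("Interface co-evolution profile for family '%s'\n", x$family_id))
  cat(sprintf("  nodes: %d   simulated pairs: %d   acceptance rate: %.3f   converged: %s\n",
              x$n_nodes, x$n_samples, x$acceptance_rate, x$converged))
  cat(sprintf("  mean edge MI (bits): positive %.3f, negative %.3f\n",
              x$mean_positive_mi, x$mean_negative_mi))
  if (nrow(x$positive_edges)) {
    cat("  positive tree edges (MI in bits):\n")
    for (e in seq_len(nrow(x$positive_edges))) {
      cat(sprintf("    %s - %s  %.3f\n", x$positive_edges$parent[e],
                  x$positive_edges$child[e], x$positive_mi[e]))
    }
  }
  invisible(x)
}

#' Score interfaces with a fitted profile
#'
#' @param object A `coev_interface_profile` fit.
#' @param newdata A named assignment vector, a list of assignments, a
#'   character/code matrix with node-id columns, or a list/data frame of
#'   aligned pairs (`seq_a`, `seq_b`) mapped through the family contact map.
#' @param ... Unused.
#' @return Data frame with columns `L_plus`, `L_minus`, `delta`
#'   (`L_plus - L_minus`).
#' @export
predict.coev_interface_profile <- function(object, newdata, ...) {
  assigns <- .as_assignment_list(newdata, object$profile_pair)
  s <- t(vapply(assigns, function(a) score_interface(a, object$profile_pair),
                c(L_plus = 0, L_minus = 0)))
  out <- as.data.frame(s)
  out$delta <- out$L_plus - out$L_minus
  out
}

.as_assignment_list <- function(newdata, pp) {
  nodes <- pp$positive$nodes
  if (is.matrix(newdata)) {
    return(lapply(seq_len(nrow(newdata)), function(i) newdata[i, ]))
  }
  if (is.data.frame(newdata) && all(c("seq_a", "seq_b") %in% names(newdata))) {
    if (is.null(pp$contact_map)) {
      stop("profile pair carries no contact map; supply assignments directly",
           call. = FALSE)
    }
    return(lapply(seq_len(nrow(newdata)), function(i) {
      interface_assignment(list(seq_a = newdata$seq_a[i], seq_b = newdata$seq_b[i]),
                           pp$contact_map)
    }))
  }
  if (is.list(newdata) && !is.null(newdata$seq_a) && !is.null(newdata$seq_b)) {
    if (is.null(pp$contact_map)) {
      stop("profile pair carries no contact map; supply assignments directly",
           call. = FALSE)
    }
    return(list(interface_assignment(newdata, pp$contact_map)))
  }
  if (is.list(newdata) && length(newdata) && !is.null(names(newdata[[1]]))) {
    return(newdata)
  }
  if (!is.null(names(newdata)) && setequal(names(newdata), nodes)) {
    return(list(newdata))
  }
  stop("newdata must be an assignment, a list of assignments, a node matrix, or aligned pairs",
       call. = FALSE)
}

#' Simulate interface assignments from the fitted positive tree
#'
#' @param object A `coev_interface_profile` fit.
#' @param nsim Number of assignments to draw.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return Character matrix of sampled assignments (nodes as columns).
#' @export
simulate.coev_interface_profile <- function(object, nsim = 1, seed = NULL, ...) {
  simulate.coev_tree(object$profile_pair$positive, nsim = nsim, seed = seed)
}

#' Plot the MCMC fitness traces of a fitted profile
#'
#' @param x A `coev_interface_profile` fit.
#' @param ... Passed to [graphics::plot()].
#' @method plot coev_interface_profile
#' @export
plot.coev_interface_profile <- function(x, ...) {
  if (!length(x$fitness_trace)) {
    stop("no fitness trace recorded", call. = FALSE)
  }
  tr <- x$fitness_trace
  ylim <- range(unlist(tr))
  graphics::plot(tr[[1]], type = "l", xlab = "MCMC step",
                 ylab = "joint fitness (bits)", ylim = ylim,
                 main = sprintf("MCMC fitness, family '%s'", x$family_id), ...)
  if (length(tr) > 1) {
    for (k in 2:length(tr)) graphics::lines(tr[[k]], col = k)
  }
  invisible(x)
}
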