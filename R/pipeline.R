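# Orchestration: batch interface scoring and the end-to-end pipeline
# (simulate -> build profile -> score -> train -> predict -> evaluate),
# with file outputs carrying provenance headers.

#' Score a table of query pairs against a fitted profile
#'
#' For every query row the aligned pair is mapped through the family contact
#' map to its interface assignment and scored against the positive and
#' negative trees. Malformed rows (wrong length, illegal characters) are
#' skipped with a warning and counted.
#'
#' @param pp A [profile_pair()] (with contact map) or
#'   `coev_interface_profile` fit.
#' @param queries Data frame with columns `pair_id`, `seq_a`, `seq_b`.
#' @return Data frame with columns `pair_id`, `interface_size`, `l_plus`,
#'   `l_minus`, one row per valid query in input order; attribute `n_skipped`
#'   counts dropped rows.
#' @export
score_queries <- function(pp, queries) {
  if (inherits(pp, "coev_interface_profile")) pp <- pp$profile_pair
  stopifnot(inherits(pp, "coev_profile_pair"))
  if (is.null(pp$contact_map)) stop("profile pair carries no contact map", call. = FALSE)
  need <- c("pair_id", "seq_a", "seq_b")
  if (!all(need %in% names(queries))) {
    stop("queries must have columns pair_id, seq_a, seq_b", call. = FALSE)
  }
  yi <- interface_size(pp$contact_map)
  out <- data.frame(pair_id = character(0), interface_size = integer(0),
                    l_plus = numeric(0), l_minus = numeric(0),
                    stringsAsFactors = FALSE)
  n_skipped <- 0L
  for (i in seq_len(nrow(queries))) {
    res <- tryCatch({
      a <- interface_assignment(list(seq_a = queries$seq_a[i],
                                     seq_b = queries$seq_b[i]),
                                pp$contact_map)
      s <- score_interface(a, pp)
      data.frame(pair_id = queries$pair_id[i], interface_size = yi,
                 l_plus = unname(s["L_plus"]), l_minus = unname(s["L_minus"]),
                 stringsAsFactors = FALSE)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning(sprintf("query row %d (%s) skipped: %s", i,
                      queries$pair_id[i], conditionMessage(res)))
      n_skipped <- n_skipped + 1L
    } else {
      out <- rbind(out, res)
    }
  }
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Write a family seed bundle to a directory
#'
#' Emits `seeds.fasta` (records A1, B1, A2, B2, ...), `contacts.tsv`,
#' `msa_a.fasta`, `msa_b.fasta` — the formats [read_family_seed()] reads.
#' The family must carry `msa_pairs` (or the seed pairs are reused as the
#' MSAs).
#'
#' @param family A [family_seed()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_family_dir <- function(family, dir) {
  stopifnot(inherits(family, "coev_family"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seqs <- character(0)
  for (k in seq_along(family$seed_pairs)) {
    p <- family$seed_pairs[[k]]
    seqs <- c(seqs, stats::setNames(c(p$seq_a, p$seq_b),
                                    sprintf("seed%d_%s", k, c("A", "B"))))
  }
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs),
                              file.path(dir, "seeds.fasta"))
  ct <- family$contact_map$contacts
  writeLines(c("# col_a\tcol_b (1-based)",
               sprintf("%d\t%d", ct[, 1], ct[, 2])),
             file.path(dir, "contacts.tsv"))
  msa <- if (!is.null(family$msa_pairs)) family$msa_pairs else family$seed_pairs
  Biostrings::writeXStringSet(
    Biostrings::BStringSet(stats::setNames(vapply(msa, `[[`, "", "seq_a"),
                                           sprintf("msa%d", seq_along(msa)))),
    file.path(dir, "msa_a.fasta"))
  Biostrings::writeXStringSet(
    Biostrings::BStringSet(stats::setNames(vapply(msa, `[[`, "", "seq_b"),
                                           sprintf("msa%d", seq_along(msa)))),
    file.path(dir, "msa_b.fasta"))
  invisible(dir)
}

.pipeline_defaults <- function() {
  list(rng_seed = 1L, cutoff = 0.6, regularization = 1,
       cv_folds = 5L, cv_repeats = 1L, generator = list(), mcmc = list())
}

#' Run the end-to-end pipeline on a synthetic benchmark
#'
#' Stages: generate a synthetic family, fit the interface profile by MCMC +
#' tree learning, assemble the labeled benchmark through the scoring path,
#' train the logistic confidence model, cross-validate it, and write
#' predictions plus a machine-readable run report. A failing stage aborts
#' with the stage named; files are written atomically (a `.partial` file is
#' left behind if writing itself fails mid-way).
#'
#' @param config A YAML path or a list with any of: `rng_seed`, `cutoff`,
#'   `regularization`, `cv_folds`, `cv_repeats`, `generator` (fields of
#'   [generator_spec()]), `mcmc` (fields of [mcmc_params()]).
#' @param out_dir Output directory; receives `profile_pair.json`,
#'   `model.json`, `dataset.tsv`, `predictions.tsv`, `report.json`.
#' @return Invisibly, a list with `report`, `dataset`, `model`, `cv`,
#'   `predictions`, and the output paths.
#' @export
coev_pipeline <- function(config = list(), out_dir = tempfile("coevnet_run_")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(.pipeline_defaults(), config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(force(expr), error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  write_atomic <- function(writer, obj, path) {
    partial <- paste0(path, ".partial")
    writer(obj, partial)
    file.rename(partial, path)
    path
  }
  spec <- stage("simulate-fixture", do.call(generator_spec,
                c(cfg$generator, list(rng_seed = cfg$rng_seed))))
  params <- stage("simulate", do.call(mcmc_params,
                  c(cfg$mcmc, list(rng_seed = (cfg$rng_seed + 1L) %% .Machine$integer.max))))
  dataset <- stage("build-profile",
                   sample_labeled_benchmark(spec, params = params))
  fit <- attr(dataset, "fit")
  model <- stage("train", confidence_model(dataset, cfg$regularization))
  cv <- stage("evaluate", cross_validate(dataset, k = cfg$cv_folds,
                                         n_repeats = cfg$cv_repeats,
                                         rng_seed = (cfg$rng_seed + 3L) %% .Machine$integer.max,
                                         regularization = cfg$regularization))
  p <- stage("predict", predict(model, dataset))
  predictions <- data.frame(pair_id = dataset$pair_id, label = dataset$label,
                            confidence = p,
                            high_confidence = as.integer(classify_high_confidence(p, cfg$cutoff)),
                            stringsAsFactors = FALSE)
  paths <- list(
    profile_pair = write_atomic(write_profile_pair_json, fit$profile_pair,
                                file.path(out_dir, "profile_pair.json")),
    model = write_atomic(write_model_json, model, file.path(out_dir, "model.json")),
    dataset = write_atomic(function(o, p) write_dataset_tsv(o, p, seed = cfg$rng_seed),
                           dataset, file.path(out_dir, "dataset.tsv")),
    predictions = write_atomic(function(o, p) .write_tsv(o, p, seed = cfg$rng_seed,
                                                         config = cfg),
                               predictions, file.path(out_dir, "predictions.tsv")))
  report <- list(package_version = as.character(utils::packageVersion("coevnet")),
                 rng_seed = cfg$rng_seed,
                 generator = unclass(spec),
                 mcmc = unclass(params)[c("contact_mutation_fraction",
                                          "noncontact_mutation_fraction",
                                          "temperature", "n_samples_per_seed",
                                          "n_samples_single_seed", "burn_in",
                                          "thinning", "hastings")],
                 n_samples = fit$n_samples,
                 acceptance_rate = fit$acceptance_rate,
                 mcmc_converged = fit$converged,
                 cutoff = cfg$cutoff,
                 regularization = cfg$regularization,
                 cv = list(k = cv$k, n_repeats = cv$n_repeats,
                           mean_fold_auc = cv$mean_auc, sd_fold_auc = cv$sd_auc,
                           pooled_auc = mean(cv$pooled_auc)),
                 n_high_confidence = sum(predictions$high_confidence))
  rp <- file.path(out_dir, "report.json")
  jsonlite::write_json(report, paste0(rp, ".partial"), auto_unbox = TRUE, digits = NA)
  file.rename(paste0(rp, ".partial"), rp)
  paths$report <- rp
  invisible(list(report = report, dataset = dataset, model = model, cv = cv,
                 predictions = predictions, paths = paths, profile = fit))
}
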