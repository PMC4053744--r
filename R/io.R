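# File formats: FASTA (Biostrings), contacts TSV, profile/tree/model JSON,
# paired-distribution matrices, labeled-dataset TSV. All column indices in
# files are 1-based; '#' starts a comment line in TSV formats.

.read_tsv_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  list(lines = lines[keep], rows = which(keep))
}

#' Read an interface contacts file
#'
#' Two tab- (or whitespace-) separated 1-based integer columns per line;
#' `#` comment lines allowed.
#'
#' @param path Path to the contacts TSV.
#' @param length_a,length_b Alignment lengths used for bounds checking.
#' @return A [contact_map()].
#' @export
read_contacts <- function(path, length_a, length_b) {
  tl <- .read_tsv_lines(path)
  if (length(tl$lines) == 0L) {
    return(contact_map(matrix(integer(0), ncol = 2), length_a, length_b))
  }
  parts <- strsplit(trimws(tl$lines), "\\s+")
  m <- matrix(NA_integer_, nrow = length(parts), ncol = 2)
  for (i in seq_along(parts)) {
    p <- suppressWarnings(as.integer(parts[[i]]))
    if (length(p) != 2L || anyNA(p)) {
      stop(sprintf("contacts file %s line %d: expected two integers", path, tl$rows[i]),
           call. = FALSE)
    }
    if (p[1] < 1L || p[1] > length_a || p[2] < 1L || p[2] > length_b) {
      stop(sprintf("contacts file %s row %d: contact (%d, %d) out of range for lengths (%d, %d)",
                   path, i, p[1], p[2], length_a, length_b), call. = FALSE)
    }
    m[i, ] <- p
  }
  contact_map(m, length_a, length_b)
}

#' Read a family seed bundle from disk
#'
#' The seed FASTA holds an even number of records ordered A1, B1, A2, B2, ...;
#' the contacts TSV holds 1-based column index pairs; `msa_paths` names the
#' two aligned FASTA/A2M files the per-protein profiles are built from.
#'
#' @param fasta_path Seed complex FASTA (aligned, gaps allowed).
#' @param contacts_tsv_path Contacts TSV path.
#' @param msa_paths Character vector of length 2: MSA paths for proteins A
#'   and B.
#' @param pseudocount,background,gap_penalty Passed to [build_profile()].
#' @param id Family identifier; defaults to the FASTA file stem.
#' @return A [family_seed()].
#' @export
read_family_seed <- function(fasta_path, contacts_tsv_path, msa_paths,
                             pseudocount = 1, background = uniform_background(),
                             gap_penalty = -4, id = NULL) {
  recs <- as.character(Biostrings::readBStringSet(fasta_path))
  if (length(recs) == 0L || length(recs) %% 2L != 0L) {
    stop(sprintf("seed FASTA %s must hold an even, positive number of records (A1,B1,A2,B2,...); found %d",
                 fasta_path, length(recs)), call. = FALSE)
  }
  n_seed <- length(recs) / 2L
  la <- nchar(recs[1]); lb <- nchar(recs[2])
  seed_pairs <- vector("list", n_seed)
  for (k in seq_len(n_seed)) {
    a <- recs[2L * k - 1L]; b <- recs[2L * k]
    if (nchar(a) != la || nchar(b) != lb) {
      stop(sprintf("seed FASTA record '%s'/'%s': lengths (%d, %d) do not match the first pair (%d, %d)",
                   names(recs)[2L * k - 1L], names(recs)[2L * k],
                   nchar(a), nchar(b), la, lb), call. = FALSE)
    }
    seed_pairs[[k]] <- aligned_pair(a, b)
  }
  cm <- read_contacts(contacts_tsv_path, la, lb)
  msa_a <- as.character(Biostrings::readBStringSet(msa_paths[[1]]))
  msa_b <- as.character(Biostrings::readBStringSet(msa_paths[[2]]))
  if (length(unique(nchar(msa_a))) > 1L || (length(msa_a) && nchar(msa_a[1]) != la)) {
    stop(sprintf("MSA %s has column count inconsistent with the seed alignment (%d)",
                 msa_paths[[1]], la), call. = FALSE)
  }
  if (length(unique(nchar(msa_b))) > 1L || (length(msa_b) && nchar(msa_b[1]) != lb)) {
    stop(sprintf("MSA %s has column count inconsistent with the seed alignment (%d)",
                 msa_paths[[2]], lb), call. = FALSE)
  }
  pa <- build_profile(msa_a, pseudocount, background, gap_penalty)
  pb <- build_profile(msa_b, pseudocount, background, gap_penalty)
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(fasta_path))
  family_seed(seed_pairs, cm, pa, pb, id = id)
}

#' Write / read a profile model as JSON
#'
#' Schema: `{"background": [20], "columns": [[20] ...], "pseudocount": x,
#' "gap_penalty": g}` where `columns` holds per-column log-odds in
#' [aa_alphabet()] order.
#'
#' @param profile A [build_profile()] object.
#' @param path Output path.
#' @return `write_profile_json` returns `path` invisibly; `read_profile_json`
#'   returns the profile.
#' @export
write_profile_json <- function(profile, path) {
  stopifnot(inherits(profile, "coev_seq_profile"))
  obj <- list(background = unname(profile$background),
              columns = lapply(seq_len(ncol(profile$log_odds)),
                               function(j) unname(profile$log_odds[, j])),
              pseudocount = profile$pseudocount,
              gap_penalty = profile$gap_penalty)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_profile_json
#' @export
read_profile_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  lo <- if (is.matrix(obj$columns)) t(obj$columns) else
    matrix(unlist(obj$columns), nrow = N_AA)
  dimnames(lo) <- list(AA20, NULL)
  structure(list(log_odds = lo,
                 background = stats::setNames(as.numeric(obj$background), AA20),
                 pseudocount = obj$pseudocount,
                 gap_penalty = obj$gap_penalty),
            class = "coev_seq_profile")
}

#' Read / write a 20 x 20 contact-pair residue distribution
#'
#' Whitespace-separated matrix with a header row and header column of
#' amino-acid letters.
#'
#' @param path File path.
#' @param dist A [pair_distribution()] object (for writing).
#' @return `read_pair_distribution` returns a [pair_distribution()].
#' @export
read_pair_distribution <- function(path) {
  m <- as.matrix(utils::read.table(path, header = TRUE, row.names = 1,
                                   check.names = FALSE))
  pair_distribution(m[AA20, AA20])
}

#' @rdname read_pair_distribution
#' @export
write_pair_distribution <- function(dist, path) {
  stopifnot(inherits(dist, "coev_pair_dist"))
  utils::write.table(format(dist$joint, digits = 17), path, quote = FALSE,
                     sep = "\t", col.names = NA)
  invisible(path)
}

# Provenance header written at the top of package TSV outputs.
.provenance <- function(seed = NULL, config = NULL) {
  h <- sprintf("# coevnet %s",
               as.character(utils::packageVersion("coevnet")))
  if (!is.null(seed)) h <- paste0(h, " seed=", seed)
  if (!is.null(config)) {
    tf <- tempfile(); on.exit(unlink(tf))
    writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, force = TRUE), tf)
    h <- paste0(h, " config_md5=", unname(tools::md5sum(tf)))
  }
  h
}

.write_tsv <- function(df, path, seed = NULL, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.provenance(seed, config), con)
  utils::write.table(df, con, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}

.read_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}

#' Write / read a labeled feature dataset
#'
#' Columns: `pair_id`, `label`, `seq_score_a`, `ss_score_a`, `len_a`,
#' `seq_score_b`, `ss_score_b`, `len_b`, `interface_size`, `l_plus`,
#' `l_minus`. Query tables use the same schema minus `label`.
#'
#' @param data Data frame in the dataset schema.
#' @param path File path.
#' @param seed Optional seed recorded in the provenance header.
#' @return `read_dataset_tsv` returns a data frame.
#' @export
write_dataset_tsv <- function(data, path, seed = NULL) {
  .write_tsv(data, path, seed = seed)
}

#' @rdname write_dataset_tsv
#' @export
read_dataset_tsv <- function(path) {
  .read_tsv(path)
}

#' Write MCMC samples as interleaved FASTA plus a fitness trace
#'
#' Records alternate A/B halves of each sampled pair
#' (`>sample<k>_A`, `>sample<k>_B`). The trace TSV (same stem, `.trace.tsv`)
#' has columns `chain`, `step`, `fitness`, `accepted`.
#'
#' @param samples A `coev_samples` object from [run_mcmc()].
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_samples_fasta <- function(samples, path) {
  stopifnot(inherits(samples, "coev_samples"))
  n <- nrow(samples$a)
  seqs <- character(2L * n)
  nms <- character(2L * n)
  for (i in seq_len(n)) {
    seqs[2L * i - 1L] <- codes_to_seq(samples$a[i, ])
    seqs[2L * i] <- codes_to_seq(samples$b[i, ])
    nms[2L * i - 1L] <- sprintf("sample%d_A", i)
    nms[2L * i] <- sprintf("sample%d_B", i)
  }
  x <- Biostrings::BStringSet(stats::setNames(seqs, nms))
  Biostrings::writeXStringSet(x, path)
  tr <- do.call(rbind, lapply(seq_along(samples$fitness_trace), function(k) {
    data.frame(chain = k,
               step = seq_along(samples$fitness_trace[[k]]),
               fitness = samples$fitness_trace[[k]],
               accepted = as.integer(samples$accepted_trace[[k]]))
  }))
  .write_tsv(tr, sub("\\.[^.]*$", ".trace.tsv", path),
             seed = samples$params$rng_seed)
  invisible(path)
}

#' Read interleaved A/B sample FASTA back into a sample set
#'
#' @param path FASTA path written by [write_samples_fasta()].
#' @return A `coev_samples` object (without traces).
#' @export
read_samples_fasta <- function(path) {
  recs <- as.character(Biostrings::readBStringSet(path))
  if (length(recs) %% 2L != 0L) stop("sample FASTA must hold A/B record pairs", call. = FALSE)
  n <- length(recs) / 2L
  a <- do.call(rbind, unname(lapply(recs[seq(1L, by = 2L, length.out = n)],
                                    function(s) .check_codes(seq_to_codes(s)))))
  b <- do.call(rbind, unname(lapply(recs[seq(2L, by = 2L, length.out = n)],
                                    function(s) .check_codes(seq_to_codes(s)))))
  structure(list(a = a, b = b, fitness_trace = list(), accepted_trace = list(),
                 acceptance_rate = NA_real_, params = NULL, converged = NA),
            class = "coev_samples")
}
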