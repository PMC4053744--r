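# Domain types for interacting-protein families: aligned sequence pairs,
# interface contact maps in alignment coordinates, position-specific profiles.

#' Aligned sequence pair
#'
#' A pair of amino-acid sequences in the alignment coordinates of their two
#' family alignments. Only the 20 standard residues plus the gap character
#' `'-'` are allowed.
#'
#' @param seq_a,seq_b Aligned amino-acid strings for protein A and protein B.
#' @return An object of class `coev_aligned_pair` with elements `seq_a`,
#'   `seq_b`, `length_a`, `length_b`.
#' @export
aligned_pair <- function(seq_a, seq_b) {
  ca <- .check_codes(seq_to_codes(seq_a), "seq_a")
  cb <- .check_codes(seq_to_codes(seq_b), "seq_b")
  structure(list(seq_a = unname(toupper(seq_a)), seq_b = unname(toupper(seq_b)),
                 length_a = length(ca), length_b = length(cb)),
            class = "coev_aligned_pair")
}

#' @export
print.coev_aligned_pair <- function(x, ...) {
  cat(sprintf("Aligned sequence pair: A (%d cols), B (%d cols)\n",
              x$length_a, x$length_b))
  cat(" A:", x$seq_a, "\n B:", x$seq_b, "\n")
  invisible(x)
}

#' Interface contact map
#'
#' The set of inter-protein residue contacts at a binding interface, as pairs
#' of 1-based alignment column indices `(col_a, col_b)`. The interface columns
#' of each protein are the projections of the contact set.
#'
#' @param contacts Two-column integer matrix or data frame; column 1 indexes
#'   protein A's alignment, column 2 protein B's. Duplicate pairs are dropped.
#' @param length_a,length_b Column counts of the two family alignments.
#' @return An object of class `coev_contact_map` with elements `contacts`
#'   (m x 2 integer matrix), `interface_cols_a`, `interface_cols_b`,
#'   `length_a`, `length_b`.
#' @export
contact_map <- function(contacts, length_a, length_b) {
  m <- as.matrix(contacts)
  if (length(m) == 0L) m <- matrix(integer(0), ncol = 2)
  if (ncol(m) != 2L) stop("contacts must have exactly two columns", call. = FALSE)
  storage.mode(m) <- "integer"
  if (anyNA(m)) stop("contacts contain non-integer entries", call. = FALSE)
  for (i in seq_len(nrow(m))) {
    if (m[i, 1] < 1L || m[i, 1] > length_a || m[i, 2] < 1L || m[i, 2] > length_b) {
      stop(sprintf("contact row %d: (%d, %d) out of range for alignments of length %d and %d",
                   i, m[i, 1], m[i, 2], length_a, length_b), call. = FALSE)
    }
  }
  m <- unique(m)
  dimnames(m) <- list(NULL, c("col_a", "col_b"))
  structure(list(contacts = m,
                 interface_cols_a = sort(unique(m[, 1])),
                 interface_cols_b = sort(unique(m[, 2])),
                 length_a = as.integer(length_a),
                 length_b = as.integer(length_b)),
            class = "coev_contact_map")
}

#' @export
print.coev_contact_map <- function(x, ...) {
  cat(sprintf("Interface contact map: %d contacts, %d + %d interface columns (alignments %d + %d)\n",
              nrow(x$contacts), length(x$interface_cols_a),
              length(x$interface_cols_b), x$length_a, x$length_b))
  invisible(x)
}

#' Interface size
#'
#' Number of interface positions: the count of distinct interface columns in
#' protein A plus those in protein B. This is the `Yi` feature of the
#' confidence classifier.
#'
#' @param cm A [contact_map()].
#' @return Non-negative integer.
#' @export
interface_size <- function(cm) {
  stopifnot(inherits(cm, "coev_contact_map"))
  length(cm$interface_cols_a) + length(cm$interface_cols_b)
}

#' Interface node identifiers
#'
#' Node ids of the interface graphical model: one node per interface column,
#' tagged by protein (`"A<col>"` / `"B<col>"`), in canonical order (protein A
#' first, columns ascending).
#'
#' @param cm A [contact_map()].
#' @return Character vector of node ids.
#' @export
interface_nodes <- function(cm) {
  stopifnot(inherits(cm, "coev_contact_map"))
  c(if (length(cm$interface_cols_a)) paste0("A", cm$interface_cols_a),
    if (length(cm$interface_cols_b)) paste0("B", cm$interface_cols_b))
}

# Split a node id into tag and column.
.node_parts <- function(nodes) {
  list(tag = substr(nodes, 1, 1),
       col = as.integer(substring(nodes, 2)))
}

#' Family seed bundle
#'
#' Seed complexes of a template family: one or more aligned sequence pairs
#' sharing a contact map (interfaces pre-aligned), plus per-protein
#' position-specific profiles.
#'
#' @param seed_pairs List of [aligned_pair()] objects (at least one).
#' @param contact_map A [contact_map()] shared by all seeds.
#' @param profile_a,profile_b [build_profile()] objects for the two proteins.
#' @param id Optional family identifier string.
#' @param msa_pairs Optional list of additional aligned pairs (for example the
#'   full paired family alignment) usable when estimating the contact-pair
#'   residue distribution.
#' @return An object of class `coev_family`.
#' @export
family_seed <- function(seed_pairs, contact_map, profile_a, profile_b,
                        id = "family", msa_pairs = NULL) {
  if (inherits(seed_pairs, "coev_aligned_pair")) seed_pairs <- list(seed_pairs)
  if (length(seed_pairs) < 1L) stop("at least one seed pair is required", call. = FALSE)
  stopifnot(inherits(contact_map, "coev_contact_map"),
            inherits(profile_a, "coev_seq_profile"),
            inherits(profile_b, "coev_seq_profile"))
  for (i in seq_along(seed_pairs)) {
    p <- seed_pairs[[i]]
    if (!inherits(p, "coev_aligned_pair")) stop("seed_pairs must be aligned_pair objects", call. = FALSE)
    if (p$length_a != contact_map$length_a || p$length_b != contact_map$length_b) {
      stop(sprintf("seed pair %d has lengths (%d, %d); family requires (%d, %d)",
                   i, p$length_a, p$length_b,
                   contact_map$length_a, contact_map$length_b), call. = FALSE)
    }
  }
  if (ncol(profile_a$log_odds) != contact_map$length_a ||
      ncol(profile_b$log_odds) != contact_map$length_b) {
    stop("profile column counts do not match the family alignment lengths", call. = FALSE)
  }
  structure(list(seed_pairs = seed_pairs, contact_map = contact_map,
                 profile_a = profile_a, profile_b = profile_b,
                 id = id, msa_pairs = msa_pairs),
            class = "coev_family")
}

#' @export
print.coev_family <- function(x, ...) {
  cat(sprintf("Family '%s': %d seed pair(s), alignments %d + %d columns, %d contacts\n",
              x$id, length(x$seed_pairs), x$contact_map$length_a,
              x$contact_map$length_b, nrow(x$contact_map$contacts)))
  invisible(x)
}

#' Build a position-specific log-odds profile from a multiple alignment
#'
#' Column probabilities are pseudocounted residue frequencies,
#' `(count + pseudocount * background) / (n_nongap + pseudocount)`, with gaps
#' excluded from the counts; log-odds are `log2(prob / background)`. A column
#' consisting only of gaps falls back to the background distribution (with a
#' warning).
#'
#' @param msa Character vector of aligned sequences (equal lengths), or an
#'   `XStringSet`.
#' @param pseudocount Positive pseudocount mass (may be 0, in which case
#'   unobserved residues get `-Inf` log-odds).
#' @param background Residue background frequencies; default uniform.
#' @param gap_penalty Score contribution (bits) of a gap column when scoring a
#'   sequence against the profile.
#' @return An object of class `coev_seq_profile` with elements `log_odds`
#'   (20 x L matrix, rows residues), `background`, `pseudocount`,
#'   `gap_penalty`.
#' @export
build_profile <- function(msa, pseudocount = 1, background = uniform_background(),
                          gap_penalty = -4) {
  if (methods::is(msa, "XStringSet")) msa <- as.character(msa)
  msa <- as.character(msa)
  if (length(msa) == 0L) stop("empty MSA", call. = FALSE)
  if (pseudocount < 0) stop("pseudocount must be >= 0", call. = FALSE)
  background <- .check_background(background)
  codes <- lapply(msa, function(s) .check_codes(seq_to_codes(s), "MSA sequence"))
  L <- length(codes[[1]])
  if (any(vapply(codes, length, 1L) != L)) {
    stop("MSA sequences have unequal lengths", call. = FALSE)
  }
  cm <- do.call(rbind, codes)        # n x L integer codes
  probs <- matrix(0, nrow = N_AA, ncol = L, dimnames = list(AA20, NULL))
  all_gap <- logical(L)
  for (j in seq_len(L)) {
    col <- cm[, j]
    col <- col[col != GAP_CODE]
    if (length(col) == 0L) {
      all_gap[j] <- TRUE
      probs[, j] <- background
    } else {
      cnt <- tabulate(col, nbins = N_AA)
      probs[, j] <- (cnt + pseudocount * background) / (length(col) + pseudocount)
    }
  }
  if (any(all_gap)) {
    warning(sprintf("%d all-gap column(s) fall back to the background distribution",
                    sum(all_gap)))
  }
  structure(list(log_odds = log2(probs / background),
                 background = background,
                 pseudocount = pseudocount,
                 gap_penalty = gap_penalty),
            class = "coev_seq_profile")
}

#' @export
print.coev_seq_profile <- function(x, ...) {
  cat(sprintf("Position-specific profile: %d columns, pseudocount %g, gap penalty %g bits\n",
              ncol(x$log_odds), x$pseudocount, x$gap_penalty))
  invisible(x)
}

#' Score a sequence against a profile
#'
#' Sum over columns of the profile log-odds of the residue at each column;
#' gap columns contribute the profile's fixed `gap_penalty`.
#'
#' @param sequence Aligned amino-acid string with length equal to the profile
#'   column count, or an integer code vector.
#' @param profile A [build_profile()] object.
#' @param gap_penalty Override the profile's stored gap penalty.
#' @return Numeric score in bits.
#' @export
profile_score <- function(sequence, profile, gap_penalty = profile$gap_penalty) {
  stopifnot(inherits(profile, "coev_seq_profile"))
  codes <- if (is.character(sequence)) .check_codes(seq_to_codes(sequence)) else as.integer(sequence)
  L <- ncol(profile$log_odds)
  if (length(codes) != L) {
    stop(sprintf("sequence length %d does not match profile column count %d",
                 length(codes), L), call. = FALSE)
  }
  gap <- codes == GAP_CODE
  s <- sum(gap) * gap_penalty
  if (any(!gap)) {
    s <- s + sum(profile$log_odds[cbind(codes[!gap], which(!gap))])
  }
  s
}

#' Contact map from residue coordinates
#'
#' Declares a contact between alignment column `i` of protein A and column `j`
#' of protein B when the Euclidean distance between their representative
#' coordinates is at most `cutoff_angstrom`.
#'
#' @param coords_a,coords_b Data frames or matrices with one representative
#'   3D coordinate per residue: either columns `x`, `y`, `z` (rows taken as
#'   columns 1..n) or columns `col`, `x`, `y`, `z`.
#' @param cutoff_angstrom Distance cutoff in Angstroms (default 8).
#' @param length_a,length_b Alignment lengths; default the largest residue
#'   index present.
#' @return A [contact_map()] (possibly empty).
#' @export
contact_map_from_coords <- function(coords_a, coords_b, cutoff_angstrom = 8,
                                    length_a = NULL, length_b = NULL) {
  if (cutoff_angstrom <= 0) stop("cutoff must be positive", call. = FALSE)
  pa <- .parse_coords(coords_a)
  pb <- .parse_coords(coords_b)
  la <- if (is.null(length_a)) max(c(pa$col, 0L)) else length_a
  lb <- if (is.null(length_b)) max(c(pb$col, 0L)) else length_b
  if (nrow(pa$xyz) == 0L || nrow(pb$xyz) == 0L) {
    return(contact_map(matrix(integer(0), ncol = 2), max(la, 1L), max(lb, 1L)))
  }
  d2 <- outer(rowSums(pa$xyz^2), rowSums(pb$xyz^2), "+") - 2 * pa$xyz %*% t(pb$xyz)
  hit <- which(d2 <= cutoff_angstrom^2 + 1e-9, arr.ind = TRUE)
  contact_map(cbind(pa$col[hit[, 1]], pb$col[hit[, 2]]), la, lb)
}

.parse_coords <- function(coords) {
  m <- as.data.frame(coords)
  if (all(c("x", "y", "z") %in% names(m))) {
    col <- if ("col" %in% names(m)) as.integer(m$col) else seq_len(nrow(m))
    xyz <- as.matrix(m[, c("x", "y", "z")])
  } else if (ncol(m) == 3L) {
    col <- seq_len(nrow(m))
    xyz <- as.matrix(m)
  } else if (ncol(m) >= 4L) {
    col <- as.integer(m[[1]])
    xyz <- as.matrix(m[, 2:4])
  } else {
    stop("coordinates must provide x, y, z (optionally a residue column index)",
         call. = FALSE)
  }
  storage.mode(xyz) <- "double"
  list(col = col, xyz = xyz)
}

#' Interface residue assignment from an aligned pair
#'
#' Extracts the residues at the interface columns of a contact map from an
#' aligned sequence pair, keyed by interface node id.
#'
#' @param pair An [aligned_pair()] (or list with `seq_a`, `seq_b`).
#' @param cm A [contact_map()].
#' @return Named character vector over [interface_nodes()].
#' @export
interface_assignment <- function(pair, cm) {
  stopifnot(inherits(cm, "coev_contact_map"))
  ca <- .check_codes(seq_to_codes(pair$seq_a), "seq_a")
  cb <- .check_codes(seq_to_codes(pair$seq_b), "seq_b")
  if (length(ca) != cm$length_a || length(cb) != cm$length_b) {
    stop("pair lengths do not match the contact map", call. = FALSE)
  }
  stats::setNames(AA21[c(ca[cm$interface_cols_a], cb[cm$interface_cols_b])],
                  interface_nodes(cm))
}
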