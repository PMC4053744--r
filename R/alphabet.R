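# Amino-acid alphabet shared across the package.
#
# Symbols are encoded internally as integers 1..21: the 20 standard residues
# in alphabetical one-letter order, then the alignment gap '-' as state 21.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
GAP_CHAR <- "-"
AA21 <- c(AA20, GAP_CHAR)
N_AA <- 20L
N_SYM <- 21L
GAP_CODE <- 21L

# BLOSUM62 background residue frequencies (Henikoff & Henikoff marginals),
# in AA20 order. Used to invert the substitution matrix into a conditional
# mutation distribution.
.blosum62_bg <- c(
  A = 0.074, C = 0.025, D = 0.054, E = 0.054, F = 0.047,
  G = 0.074, H = 0.026, I = 0.068, K = 0.058, L = 0.099,
  M = 0.025, N = 0.045, P = 0.039, Q = 0.034, R = 0.052,
  S = 0.057, T = 0.051, V = 0.073, W = 0.013, Y = 0.032)

#' Amino-acid alphabet used by coevnet
#'
#' @return Character vector of the 20 standard one-letter residue codes, in
#'   alphabetical order. The gap symbol `"-"` is appended as a 21st state in
#'   all tree models.
#' @export
aa_alphabet <- function() AA20

#' Uniform residue background
#'
#' @return Named numeric 20-vector, each entry 1/20.
#' @export
uniform_background <- function() {
  stats::setNames(rep(1 / N_AA, N_AA), AA20)
}

#' BLOSUM62 background residue frequencies
#'
#' The marginal residue frequencies underlying the BLOSUM62 substitution
#' matrix, renormalized to sum to 1.
#'
#' @return Named numeric 20-vector in [aa_alphabet()] order.
#' @export
blosum62_background <- function() {
  .blosum62_bg / sum(.blosum62_bg)
}

# Encode an aligned amino-acid string to integer codes (1..21).
# Unknown characters yield NA.
seq_to_codes <- function(s) {
  match(strsplit(toupper(s), "", fixed = TRUE)[[1]], AA21)
}

codes_to_seq <- function(codes) {
  paste(AA21[codes], collapse = "")
}

.check_codes <- function(codes, what = "sequence") {
  if (anyNA(codes)) {
    bad <- which(is.na(codes))[1]
    stop(sprintf("%s contains a character outside the 20-letter alphabet plus '-' at position %d",
                 what, bad), call. = FALSE)
  }
  codes
}

# The BLOSUM62 score matrix restricted to the 20 standard residues, AA20 order.
blosum62_scores <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      m <- e$BLOSUM62[AA20, AA20]
      cache <<- m
    }
    cache
  }
})

#' Conditional substitution distribution derived from BLOSUM62
#'
#' Inverts the BLOSUM62 log-odds scores into a conditional mutation
#' distribution: `P(b | a)` is proportional to `background[b] * 2^(S(a,b)/2)`
#' (BLOSUM62 scores are log-odds in half-bit units), row-normalized. Row `a`
#' is the distribution that a residue currently in state `a` is resampled
#' from when a non-contacting position is mutated.
#'
#' @param background Named numeric 20-vector of residue background
#'   frequencies; defaults to the BLOSUM62 marginals.
#' @return A 20 x 20 row-stochastic matrix with residues as dimnames; rows are
#'   the current residue, columns the proposed residue.
#' @export
blosum_conditional <- function(background = blosum62_background()) {
  background <- .check_background(background)
  s <- blosum62_scores()
  w <- sweep(2^(s / 2), 2, background, "*")
  w / rowSums(w)
}

.check_background <- function(background) {
  if (length(background) != N_AA || any(!is.finite(background)) || any(background <= 0)) {
    stop("background must be a strictly positive numeric 20-vector", call. = FALSE)
  }
  background <- background / sum(background)
  if (is.null(names(background))) names(background) <- AA20
  background[AA20]
}
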