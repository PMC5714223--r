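#' Pairwise alignment HMM parameters
#'
#' The three-state model (ALN, INS1, INS2) is parameterised by a 3x3
#' transition matrix, a 4x4 joint emission table for the ALN state over
#' \code{A,C,G,U} x \code{A,C,G,U}, and a length-4 single-residue
#' emission table shared by the two insert states.
#'
#' @param transition 3x3 row-stochastic matrix, rows/cols ordered
#'   ALN, INS1, INS2; \code{transition[s, t]} is the probability of
#'   moving from state \code{s} to state \code{t}.
#' @param emission_pair 4x4 nonnegative table summing to 1.
#' @param emission_single Length-4 nonnegative table summing to 1.
#' @return An object of class \code{hmm_parameters}.
#' @export
hmm_parameters <- function(transition, emission_pair, emission_single) {
  stopifnot(is.matrix(transition), all(dim(transition) == c(3L, 3L)),
            is.matrix(emission_pair), all(dim(emission_pair) == c(4L, 4L)),
            is.numeric(emission_single), length(emission_single) == 4L)
  if (any(transition < 0) || any(emission_pair < 0) ||
      any(emission_single < 0))
    stop("HMM parameters must be nonnegative")
  if (any(abs(rowSums(transition) - 1) > 1e-12))
    stop("transition rows must sum to 1")
  if (abs(sum(emission_pair) - 1) > 1e-12)
    stop("pair emission table must sum to 1")
  if (abs(sum(emission_single) - 1) > 1e-12)
    stop("single emission table must sum to 1")
  structure(list(transition = transition, emission_pair = emission_pair,
                 emission_single = emission_single),
            class = "hmm_parameters")
}

#' Default pairwise alignment HMM parameters
#'
#' A documented stand-in parameter set: sticky ALN state (self-transition
#' 0.95), symmetric gap opening (0.025 each), gap extension 0.75, and a
#' match emission favouring identical nucleotides 5:1 over mismatches.
#' The tables are symmetric, so swapping the two sequences transposes
#' the posterior matrices. All values are overridable through
#' [hmm_parameters()].
#'
#' @return An \code{hmm_parameters} object.
#' @export
default_hmm_parameters <- function() {
  tr <- matrix(c(0.95, 0.025, 0.025,
                 0.24, 0.75, 0.01,
                 0.24, 0.01, 0.75),
               nrow = 3, byrow = TRUE,
               dimnames = list(c("ALN", "INS1", "INS2"),
                               c("ALN", "INS1", "INS2")))
  ep <- matrix(1 / 32, 4, 4,
               dimnames = list(c("A", "C", "G", "U"), c("A", "C", "G", "U")))
  diag(ep) <- 5 / 32
  hmm_parameters(tr, ep, stats::setNames(rep(0.25, 4),
                                         c("A", "C", "G", "U")))
}

#' Posterior co-incidence and aligned probabilities for a sequence pair
#'
#' Runs the forward-backward algorithm on the three-state pair HMM. Two
#' positions are co-incident when they are aligned or when one lies in an
#' insert run immediately following an aligned position; the co-incidence
#' posterior sums the ALN, INS1 and INS2 state posteriors at \code{(i,k)},
#' while the aligned posterior keeps the ALN term only. An optional
#' structural match score \code{rho} multiplies the ALN terms of both
#' recursions as a prior; both returned matrices share the normaliser
#' (the total path weight), which absorbs the global scale of \code{rho}.
#' Omitting \code{rho} is equivalent to an all-ones prior.
#'
#' @param x,y [rna_sequence()] objects.
#' @param params An [hmm_parameters()] object.
#' @param rho Optional \code{N_x} x \code{N_y} matrix of strictly
#'   positive match scores.
#' @param identity Logical; when \code{TRUE} (default) the pairwise
#'   identity of the posterior-decoded alignment is computed and stored.
#' @return An object of class \code{coincidence_posteriors} with fields
#'   \code{coincidence}, \code{aligned} (both \code{N_x} x \code{N_y}),
#'   \code{identity} and \code{logZ}.
#' @export
compute_posteriors <- function(x, y, params = default_hmm_parameters(),
                               rho = NULL, identity = TRUE) {
  stopifnot(inherits(x, "rna_sequence"), inherits(y, "rna_sequence"),
            inherits(params, "hmm_parameters"))
  if (!is.null(rho)) {
    if (!is.matrix(rho) || nrow(rho) != x$length || ncol(rho) != y$length)
      stop("rho must be an N_x by N_y matrix")
    if (any(rho <= 0)) stop("rho entries must be strictly positive")
  }
  res <- .hmm_posteriors_cpp(encode_rna(x$residues), encode_rna(y$residues),
                             params$transition, params$emission_pair,
                             params$emission_single, rho)
  post <- structure(list(coincidence = res$coincidence,
                         aligned = res$aligned,
                         identity = NA_real_, logZ = res$logZ),
                    class = "coincidence_posteriors")
  if (identity) post$identity <- pairwise_identity(post, x, y)
  post
}

#' @export
print.coincidence_posteriors <- function(x, ...) {
  cat("<coincidence_posteriors> ", nrow(x$coincidence), " x ",
      ncol(x$coincidence), ", identity ",
      formatC(x$identity, digits = 3, format = "f"), "\n", sep = "")
  invisible(x)
}

#' Pairwise sequence identity from decoded alignment posteriors
#'
#' Decodes the aligned-posterior matrix with a maximum expected accuracy
#' dynamic program (maximising the summed aligned posterior over monotone
#' alignments, gap score 0) and reports the fraction of alignment columns
#' in which both residues are present and identical. The denominator is
#' the full decoded alignment length, including gap columns (terminal
#' gaps included).
#'
#' @param post A [compute_posteriors()] result.
#' @param x,y The two [rna_sequence()] objects the posteriors refer to.
#' @return Identity in \code{[0, 1]}.
#' @export
pairwise_identity <- function(post, x, y) {
  stopifnot(inherits(post, "coincidence_posteriors"))
  dec <- .nw_decode_cpp(post$aligned)
  m <- dec$matches
  rx <- strsplit(x$residues, "")[[1]]
  ry <- strsplit(y$residues, "")[[1]]
  n_ident <- if (nrow(m)) sum(rx[m[, 1]] == ry[m[, 2]]) else 0L
  # alignment length = matched columns + unmatched residues of each side
  len <- nrow(m) + (x$length - nrow(m)) + (y$length - nrow(m))
  if (len == 0L) return(0)
  n_ident / len
}
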