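#' Per-position pairing-state profile
#'
#' Summarises a base-pair probability matrix as, for every position
#' \code{i}, the probability of pairing downstream
#' (\code{p_down = sum_(j>i) P(i,j)}), upstream
#' (\code{p_up = sum_(j<i) P(j,i)}), and of being unpaired
#' (\code{p_unpaired = 1 - p_down - p_up}). The three components sum to
#' one at every position.
#'
#' @param p A [pair_probability_matrix()].
#' @return An object of class \code{pairing_state_profile} with numeric
#'   fields \code{p_down}, \code{p_up}, \code{p_unpaired}.
#' @export
pairing_state_profile <- function(p) {
  stopifnot(inherits(p, "pair_probability_matrix"))
  down <- rowSums(p$p)
  up <- colSums(p$p)
  unp <- 1 - down - up
  if (any(unp < -1e-9)) stop("pair probability matrix invariant violated")
  structure(list(p_down = pmin(pmax(down, 0), 1),
                 p_up = pmin(pmax(up, 0), 1),
                 p_unpaired = pmin(pmax(unp, 0), 1)),
            class = "pairing_state_profile")
}

#' Match-score weights
#'
#' @param alpha1 Weight on agreement of pairing direction (both
#'   downstream-paired or both upstream-paired).
#' @param alpha2 Weight on agreement of being unpaired.
#' @param alpha3 Additive offset controlling the score ratio between
#'   aligned positions of unlike and like pairing state.
#' @return An object of class \code{match_score_params}.
#' @export
match_score_params <- function(alpha1, alpha2, alpha3) {
  stopifnot(alpha1 >= 0, alpha2 >= 0, alpha3 >= 0)
  structure(list(alpha1 = alpha1, alpha2 = alpha2, alpha3 = alpha3),
            class = "match_score_params")
}

#' Default match-score weights
#'
#' The shipped defaults (alpha1 = 1.0, alpha2 = 0.8, alpha3 = 0.5)
#' weight agreement of pairing direction slightly above agreement of
#' being unpaired, with a moderate offset that tolerates paired/unpaired
#' mismatches at stem-loop boundaries. Setting alpha1 = alpha2 = 1 and
#' alpha3 = 0 recovers the PMcomp-style score.
#'
#' @return A [match_score_params()] object.
#' @export
default_match_params <- function() match_score_params(1.0, 0.8, 0.5)

#' Structural match score between all position pairs of two sequences
#'
#' \deqn{\rho(i,k) = \alpha_1(\sqrt{P_<(i) P_<(k)} + \sqrt{P_>(i) P_>(k)})
#'   + \alpha_2 \sqrt{P_\circ(i) P_\circ(k)} + \alpha_3}
#' where \eqn{P_<}, \eqn{P_>}, \eqn{P_\circ} are the downstream-paired,
#' upstream-paired and unpaired probabilities of the two profiles.
#'
#' @param a,b [pairing_state_profile()] objects for the two sequences.
#' @param params A [match_score_params()] object.
#' @return \code{N_a} x \code{N_b} matrix of nonnegative match scores.
#' @export
match_score_matrix <- function(a, b, params = default_match_params()) {
  stopifnot(inherits(a, "pairing_state_profile"),
            inherits(b, "pairing_state_profile"),
            inherits(params, "match_score_params"))
  params$alpha1 * (sqrt(outer(a$p_down, b$p_down)) +
                   sqrt(outer(a$p_up, b$p_up))) +
    params$alpha2 * sqrt(outer(a$p_unpaired, b$p_unpaired)) +
    params$alpha3
}

#' Pairing proclivity mapped from a homolog
#'
#' Maps the base-pair probabilities of sequence \code{n} onto the
#' coordinates of sequence \code{m} through the pairwise co-incidence
#' posteriors:
#' \deqn{P^{(n\to m)}(i,j) = \sum_{k<l} P^n(k,l)\, P(i \sim k)\, P(j \sim l)}
#' restricted to candidate indices whose co-incidence probability is at
#' least \code{cutoff} (an approximation that prunes negligible terms;
#' \code{cutoff = 0} gives the exact sum).
#'
#' @param p_n [pair_probability_matrix()] of the source sequence \code{n}.
#' @param post_mn [compute_posteriors()] result for the pair
#'   \code{(m, n)}, i.e. co-incidence rows indexed by \code{m} positions.
#' @param cutoff Candidate-set threshold in \code{[0, 1)}; co-incidence
#'   entries below it are excluded (default 0.01, inclusive at the
#'   threshold).
#' @return Strictly upper-triangular \code{N_m} x \code{N_m} matrix.
#' @export
proclivity <- function(p_n, post_mn, cutoff = 0.01) {
  stopifnot(inherits(p_n, "pair_probability_matrix"),
            inherits(post_mn, "coincidence_posteriors"),
            cutoff >= 0, cutoff < 1)
  co <- post_mn$coincidence
  if (ncol(co) != p_n$n)
    stop("posterior and pair-probability dimensions disagree")
  if (cutoff > 0) co[co < cutoff] <- 0
  m <- co %*% p_n$p %*% t(co)
  m[lower.tri(m, diag = TRUE)] <- 0
  m
}

#' Extrinsic information for a target sequence
#'
#' Identity-weighted sum of the pairing proclivities mapped in from
#' every other sequence, normalised so the largest entry is one:
#' \deqn{\tilde P^m = \alpha^m \sum_{n \ne m} (1 - \psi_{m,n})\,
#'   P^{(n\to m)}}
#' Distant homologs (low identity \eqn{\psi}) contribute more: they
#' carry independent structural evidence. When the weighted sum is
#' identically zero (a single sequence, or all homologs identical), the
#' zero matrix is returned; it is neutral under the partition function's
#' \code{1 + kappa * P} multiplier.
#'
#' @param proclivities List of \code{N_m} x \code{N_m} [proclivity()]
#'   matrices, one per non-target sequence.
#' @param identities Numeric vector of pairwise identities
#'   \eqn{\psi_{m,n}} aligned with \code{proclivities}.
#' @return An object of class \code{extrinsic_matrix} with fields
#'   \code{p} (max-normalised matrix) and \code{alpha} (the normaliser;
#'   \code{NA} for the zero matrix).
#' @export
extrinsic_information <- function(proclivities, identities) {
  stopifnot(is.list(proclivities), length(proclivities) == length(identities),
            all(identities >= 0), all(identities <= 1))
  if (!length(proclivities)) stop("no homolog proclivities supplied")
  n <- nrow(proclivities[[1]])
  acc <- matrix(0, n, n)
  for (t in seq_along(proclivities))
    acc <- acc + (1 - identities[t]) * proclivities[[t]]
  mx <- max(acc)
  if (mx <= 0)
    return(structure(list(p = matrix(0, n, n), alpha = NA_real_),
                     class = "extrinsic_matrix"))
  structure(list(p = acc / mx, alpha = 1 / mx), class = "extrinsic_matrix")
}

#' @export
print.extrinsic_matrix <- function(x, ...) {
  cat("<extrinsic_matrix> n = ", nrow(x$p),
      if (is.na(x$alpha)) " (zero / neutral)" else "", "\n", sep = "")
  invisible(x)
}
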