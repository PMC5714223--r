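#' Maximum expected accuracy structure
#'
#' Finds the non-crossing structure maximising
#' \deqn{\sum_{(i,j) \in S} 2 P(i,j) + \sum_{i\ \mathrm{unpaired}} P(i)}
#' where \eqn{P(i)} is the unpaired probability, via a Nussinov-style
#' dynamic program. The pair weight of 2 and unpaired weight of 1 are
#' fixed. Ties break toward the structure with fewer pairs, then toward
#' the smallest partner index, so the output is deterministic.
#'
#' @param p A [pair_probability_matrix()].
#' @param min_hairpin Minimum hairpin size; candidate pairs must satisfy
#'   \code{j - i > min_hairpin} (default 3).
#' @return A [secondary_structure()]; its attribute \code{"objective"}
#'   carries the attained objective value.
#' @export
mea_structure <- function(p, min_hairpin = 3L) {
  stopifnot(inherits(p, "pair_probability_matrix"))
  q <- unpaired_probabilities(p)
  res <- .mea_dp_cpp(p$p, q, as.integer(min_hairpin))
  s <- secondary_structure(p$n, res$pairs, min_hairpin = min_hairpin)
  attr(s, "objective") <- res$objective
  s
}

#' Structure from thresholded pair probabilities
#'
#' Keeps every pair with probability strictly above \code{t}; conflicts
#' (an index claimed by two kept pairs) are resolved greedily by
#' descending probability. For \code{t >= 0.5} the result is conflict-free
#' by construction, since each position's total pairing probability is at
#' most one. Crossing pairs are permitted (the CT writer accepts them;
#' the dot-bracket writer does not).
#'
#' @param p A [pair_probability_matrix()].
#' @param t Threshold in \code{(0, 1]} (default 0.5).
#' @return A [secondary_structure()].
#' @export
threshold_structure <- function(p, t = 0.5) {
  stopifnot(inherits(p, "pair_probability_matrix"), t > 0, t <= 1)
  idx <- which(p$p > t, arr.ind = TRUE)
  if (!nrow(idx)) return(secondary_structure(p$n, min_hairpin = 0L))
  pr <- p$p[idx]
  ord <- order(-pr, idx[, 1], idx[, 2])
  idx <- idx[ord, , drop = FALSE]
  used <- logical(p$n)
  keep <- logical(nrow(idx))
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]
    if (!used[i] && !used[j]) {
      keep[r] <- TRUE
      used[i] <- used[j] <- TRUE
    }
  }
  secondary_structure(p$n, idx[keep, , drop = FALSE], min_hairpin = 0L)
}
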