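#' Configuration for the joint folding-and-alignment pipeline
#'
#' @param iterations Number of coupling iterations (default 3). Zero
#'   gives a single-pass pipeline: sequence-only alignment posteriors,
#'   plain thermodynamic folding, then MSA and structure prediction.
#' @param match_params [match_score_params()]; default (1.0, 0.8, 0.5).
#' @param kappa Weight of the extrinsic term in the partition function
#'   (default 10; 0 disables the structure channel).
#' @param coincidence_cutoff Candidate-set threshold for the proclivity
#'   sum (default 0.01).
#' @param mode Structure prediction mode, \code{"mea"} or
#'   \code{"threshold"}.
#' @param threshold Pair-probability threshold for
#'   \code{mode = "threshold"} (default 0.5).
#' @param energy_model An [energy_model()].
#' @param hmm An [hmm_parameters()] object.
#' @param consistency_min Sparsity floor applied to the aligned
#'   posteriors before the consistency transform's matrix products
#'   (default 0.001).
#' @return An object of class \code{homofold_config}.
#' @export
homofold_config <- function(iterations = 3L,
                         match_params = default_match_params(),
                         kappa = 10,
                         coincidence_cutoff = 0.01,
                         mode = c("mea", "threshold"),
                         threshold = 0.5,
                         energy_model = default_energy_model(),
                         hmm = default_hmm_parameters(),
                         consistency_min = 0.001) {
  mode <- match.arg(mode)
  stopifnot(iterations >= 0, kappa >= 0,
            coincidence_cutoff >= 0, coincidence_cutoff < 1,
            threshold > 0, threshold <= 1,
            inherits(match_params, "match_score_params"),
            inherits(energy_model, "energy_model"),
            inherits(hmm, "hmm_parameters"))
  structure(list(iterations = as.integer(iterations),
                 match_params = match_params, kappa = kappa,
                 coincidence_cutoff = coincidence_cutoff, mode = mode,
                 threshold = threshold, energy_model = energy_model,
                 hmm = hmm, consistency_min = consistency_min),
            class = "homofold_config")
}

# internal: canonical key for the unordered pair m < n
pair_key <- function(m, n) paste0(min(m, n), "|", max(m, n))

# internal: posteriors for pair (m, n) oriented with rows = m positions
oriented_post <- function(state, m, n) {
  p <- state$post[[pair_key(m, n)]]
  if (m < n) return(p)
  structure(list(coincidence = t(p$coincidence), aligned = t(p$aligned),
                 identity = p$identity, logZ = p$logZ),
            class = "coincidence_posteriors")
}

#' Initialise the pipeline state
#'
#' The initial pass computes alignment posteriors from sequence alone
#' (no structural prior) and base-pair probabilities from thermodynamics
#' alone (no extrinsic information). Pairwise identities are computed
#' here, from the sequence-only decoded alignments, and held fixed
#' through the iterations so the extrinsic weighting stays stable.
#'
#' @param seqs A [sequence_set()]; every sequence must be at least 4 nt
#'   (shorter sequences cannot fold above the hairpin minimum).
#' @param cfg A [homofold_config()].
#' @return An object of class \code{homofold_state} holding per-sequence
#'   \code{pairprobs}, per-pair \code{post}, the identity matrix
#'   \code{psi}, and the \code{iteration} counter.
#' @export
homofold_init <- function(seqs, cfg = homofold_config()) {
  stopifnot(inherits(seqs, "sequence_set"), inherits(cfg, "homofold_config"))
  H <- length(seqs)
  lens <- vapply(seqs$sequences, function(s) s$length, integer(1))
  if (any(lens < 4L))
    stop("all sequences must be at least 4 nt (folding is degenerate ",
         "below the hairpin minimum)")
  pairprobs <- lapply(seqs$sequences, pair_probabilities,
                      model = cfg$energy_model)
  post <- list()
  psi <- diag(1, H)
  if (H >= 2L) {
    for (m in seq_len(H - 1L)) for (n in (m + 1L):H) {
      p <- compute_posteriors(seqs[[m]], seqs[[n]], cfg$hmm)
      post[[pair_key(m, n)]] <- p
      psi[m, n] <- psi[n, m] <- p$identity
    }
  }
  structure(list(seqs = seqs, pairprobs = pairprobs, post = post,
                 psi = psi, iteration = 0L),
            class = "homofold_state")
}

#' @export
print.homofold_state <- function(x, ...) {
  cat("<homofold_state> H = ", length(x$seqs), ", iteration ",
      x$iteration, "\n", sep = "")
  invisible(x)
}

#' One coupling iteration
#'
#' Executes, in order: (a) a structural match score for every sequence
#' pair from the current base-pair probabilities; (b) re-estimation of
#' the alignment posteriors with that score as a prior; (c) extrinsic
#' information for every sequence from the current base-pair
#' probabilities of its homologs and the just-updated posteriors; (d)
#' re-estimation of every sequence's base-pair probabilities with the
#' extrinsic term. All extrinsic matrices are formed before any pair
#' probabilities are replaced.
#'
#' @param state A [homofold_init()] result.
#' @param cfg A [homofold_config()].
#' @return The updated \code{homofold_state} (iteration counter + 1).
#' @export
iterate_once <- function(state, cfg = homofold_config()) {
  stopifnot(inherits(state, "homofold_state"), inherits(cfg, "homofold_config"))
  seqs <- state$seqs
  H <- length(seqs)
  profiles <- lapply(state$pairprobs, pairing_state_profile)
  if (H >= 2L) {
    for (m in seq_len(H - 1L)) for (n in (m + 1L):H) {
      rho <- match_score_matrix(profiles[[m]], profiles[[n]],
                                cfg$match_params)
      p <- compute_posteriors(seqs[[m]], seqs[[n]], cfg$hmm, rho = rho,
                              identity = FALSE)
      p$identity <- state$post[[pair_key(m, n)]]$identity
      state$post[[pair_key(m, n)]] <- p
    }
    exts <- vector("list", H)
    for (m in seq_len(H)) {
      others <- setdiff(seq_len(H), m)
      procs <- lapply(others, function(n)
        proclivity(state$pairprobs[[n]], oriented_post(state, m, n),
                   cfg$coincidence_cutoff))
      exts[[m]] <- extrinsic_information(procs, state$psi[m, others])
    }
    state$pairprobs <- lapply(seq_len(H), function(m)
      pair_probabilities(seqs[[m]], cfg$energy_model,
                         extrinsic = exts[[m]], kappa = cfg$kappa))
  }
  state$iteration <- state$iteration + 1L
  state
}

#' Run the full joint folding-and-alignment pipeline
#'
#' Initialises the state, performs \code{cfg$iterations} coupling
#' passes, then computes the consistency-transformed progressive
#' multiple sequence alignment and per-sequence structure predictions
#' from the final state. With a single input sequence the alignment
#' step is skipped. The pipeline has no source of randomness; repeated
#' runs on the same inputs are identical.
#'
#' @param seqs A [sequence_set()].
#' @param cfg A [homofold_config()].
#' @return A list with elements \code{state} (final \code{homofold_state}),
#'   \code{alignment} ([multiple_alignment()] or \code{NULL} for H = 1)
#'   and \code{structures} (list of [secondary_structure()], input
#'   order).
#' @export
homofold <- function(seqs, cfg = homofold_config()) {
  state <- homofold_init(seqs, cfg)
  if (cfg$iterations > 0L)
    for (it in seq_len(cfg$iterations)) state <- iterate_once(state, cfg)
  alignment <- if (length(seqs) >= 2L) compute_msa(state, cfg) else NULL
  structures <- lapply(state$pairprobs, function(p) {
    if (cfg$mode == "mea") mea_structure(p)
    else threshold_structure(p, cfg$threshold)
  })
  list(state = state, alignment = alignment, structures = structures)
}
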