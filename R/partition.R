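#' Simplified nearest-neighbour energy model
#'
#' The partition function sums, over all non-crossing canonical
#' structures, a product of equilibrium factors: one \code{pair_weight}
#' per pair, a loop factor per loop (hairpin, bulge, internal, or a
#' linear multibranch cost), and a \code{stack} factor when two pairs are
#' directly adjacent. Canonical pairs are \code{AU, UA, GC, CG, GU, UG};
#' every other pair has weight zero. The model is deliberately small and
#' fully pluggable: the algorithmic contribution of the package is the
#' exchange of information between folding and alignment, which is
#' agnostic to the particular thermodynamic table.
#'
#' @param pair_weight 4x4 nonnegative matrix over \code{A,C,G,U}; entries
#'   for non-canonical pairs must be 0.
#' @param stack 6x6 nonnegative matrix of stacking factors indexed by
#'   pair type in the order \code{AU, UA, GC, CG, GU, UG} (outer pair by
#'   inner pair).
#' @param hairpin,bulge,internal Functions mapping unpaired-length to a
#'   nonnegative loop factor.
#' @param m_init,m_branch,m_unpaired Multibranch loop factors: per loop,
#'   per inner branch, and per unpaired loop nucleotide.
#' @param min_hairpin Minimum unpaired nucleotides in a hairpin (>= 3).
#' @param max_internal Maximum total unpaired length of a two-loop.
#' @return An object of class \code{energy_model}.
#' @export
energy_model <- function(pair_weight, stack, hairpin, bulge, internal,
                         m_init, m_branch, m_unpaired,
                         min_hairpin = 3L, max_internal = 30L) {
  stopifnot(is.matrix(pair_weight), all(dim(pair_weight) == c(4L, 4L)),
            is.matrix(stack), all(dim(stack) == c(6L, 6L)),
            is.function(hairpin), is.function(bulge), is.function(internal),
            m_init >= 0, m_branch >= 0, m_unpaired >= 0,
            min_hairpin >= 3L, max_internal >= 0L)
  if (any(pair_weight < 0) || any(stack < 0))
    stop("energy-model factors must be nonnegative")
  canon <- canonical_mask()
  if (any(pair_weight[!canon] != 0))
    stop("non-canonical pairs must have weight 0")
  structure(list(pair_weight = pair_weight, stack = stack,
                 hairpin = hairpin, bulge = bulge, internal = internal,
                 m_init = m_init, m_branch = m_branch,
                 m_unpaired = m_unpaired,
                 min_hairpin = as.integer(min_hairpin),
                 max_internal = as.integer(max_internal)),
            class = "energy_model")
}

# internal: logical 4x4 mask of canonical pairs (A,C,G,U order)
canonical_mask <- function() {
  m <- matrix(FALSE, 4, 4)
  idx <- rbind(c(1, 4), c(4, 1), c(3, 2), c(2, 3), c(3, 4), c(4, 3))
  m[idx] <- TRUE
  m
}

# internal: pair-type index AU=1,UA=2,GC=3,CG=4,GU=5,UG=6; 0 otherwise
pair_type_index <- function(a, b) {
  key <- paste0(c("A", "C", "G", "U")[a], c("A", "C", "G", "U")[b])
  match(key, c("AU", "UA", "GC", "CG", "GU", "UG"), nomatch = 0L)
}

#' Default toy energy model
#'
#' Equilibrium factors chosen to reproduce the qualitative shape of RNA
#' thermodynamics: GC > AU > GU pair strength, stacking as the dominant
#' stabilising term, and loop factors that decay with loop length. Units
#' are dimensionless Boltzmann-like factors.
#'
#' @return An \code{energy_model} object.
#' @export
default_energy_model <- function() {
  pw <- matrix(0, 4, 4, dimnames = list(c("A", "C", "G", "U"),
                                        c("A", "C", "G", "U")))
  pw["G", "C"] <- pw["C", "G"] <- 3.0
  pw["A", "U"] <- pw["U", "A"] <- 2.0
  pw["G", "U"] <- pw["U", "G"] <- 1.0
  # stack factor grows with the strength of the participating pairs
  w6 <- c(2, 2, 3, 3, 1, 1) # AU,UA,GC,CG,GU,UG
  st <- 2 * sqrt(outer(w6, w6))
  energy_model(pair_weight = pw, stack = st,
               hairpin = function(u) 0.03 * exp(-0.3 * (u - 3)),
               bulge = function(u) 0.05 * exp(-0.5 * u),
               internal = function(u) 0.05 * exp(-0.35 * (u - 2)),
               m_init = 0.01, m_branch = 0.8, m_unpaired = 0.9)
}

# internal: precompute loop factor lookup tables for a given length
loop_tables <- function(model, n) {
  hF <- numeric(max(n + 1L, model$min_hairpin + 2L))
  us <- model$min_hairpin:max(n, model$min_hairpin)
  hF[us + 1L] <- vapply(us, model$hairpin, numeric(1))
  bF <- numeric(model$max_internal + 1L)
  if (model$max_internal >= 1L)
    bF[2:(model$max_internal + 1L)] <-
      vapply(seq_len(model$max_internal), model$bulge, numeric(1))
  iF <- numeric(model$max_internal + 1L)
  if (model$max_internal >= 2L)
    iF[3:(model$max_internal + 1L)] <-
      vapply(2:model$max_internal, model$internal, numeric(1))
  list(hairpin = hF, bulge = bF, internal = iF)
}

#' Equilibrium base-pair probabilities for one sequence
#'
#' Inside-outside computation of \code{P(i, j)}, the equilibrium
#' probability that positions \code{i < j} pair, over all non-crossing
#' canonical structures under the given [energy_model()]. When an
#' extrinsic pairing-proclivity matrix from homologs is supplied, each
#' pair's equilibrium factor is multiplied by
#' \code{1 + kappa * extrinsic(i, j)}: neutral where the extrinsic matrix
#' is zero, bounded, and monotone in the proclivity.
#'
#' @param seq An [rna_sequence()].
#' @param model An [energy_model()].
#' @param extrinsic Optional [extrinsic_information()] result (or a plain
#'   \code{N} x \code{N} matrix of values in \code{[0, 1]}).
#' @param kappa Nonnegative weight of the extrinsic term (default 10).
#' @return An object of class \code{pair_probability_matrix} with fields
#'   \code{n} and \code{p} (strictly upper-triangular matrix).
#' @export
pair_probabilities <- function(seq, model = default_energy_model(),
                               extrinsic = NULL, kappa = 10) {
  stopifnot(inherits(seq, "rna_sequence"), inherits(model, "energy_model"),
            kappa >= 0)
  n <- seq$length
  extmult <- extrinsic_multiplier(extrinsic, kappa, n)
  lt <- loop_tables(model, n)
  p <- .partition_pairprobs_cpp(encode_rna(seq$residues),
                                model$pair_weight, model$stack,
                                lt$hairpin, lt$bulge, lt$internal,
                                model$m_init, model$m_branch,
                                model$m_unpaired,
                                model$min_hairpin, model$max_internal,
                                extmult)
  pair_probability_matrix(p)
}

# internal: 1 + kappa * Ptilde as a dense matrix, or NULL for neutral
extrinsic_multiplier <- function(extrinsic, kappa, n) {
  if (is.null(extrinsic) || kappa == 0) return(NULL)
  pt <- if (inherits(extrinsic, "extrinsic_matrix")) extrinsic$p else extrinsic
  if (!is.matrix(pt) || nrow(pt) != n || ncol(pt) != n)
    stop("extrinsic matrix has wrong dimensions")
  if (any(pt < 0) || any(pt > 1 + 1e-9))
    stop("extrinsic entries must lie in [0, 1]")
  1 + kappa * pt
}

#' Pair probability matrix container
#'
#' @param p Strictly upper-triangular numeric matrix of base-pair
#'   probabilities; for every position the total pairing involvement
#'   (row plus column sums) must not exceed 1.
#' @return An object of class \code{pair_probability_matrix}.
#' @export
pair_probability_matrix <- function(p) {
  stopifnot(is.matrix(p), nrow(p) == ncol(p))
  if (any(p < 0) || any(p > 1 + 1e-9))
    stop("pair probabilities must lie in [0, 1]")
  if (any(p[lower.tri(p, diag = TRUE)] != 0))
    stop("pair probability matrix must be strictly upper-triangular")
  inv <- pair_involvement(p)
  if (any(inv > 1 + 1e-9))
    stop("pairing involvement exceeds 1 at position ",
         which.max(inv), " (", max(inv), ")")
  structure(list(n = nrow(p), p = p), class = "pair_probability_matrix")
}

# internal: per-position total pairing probability (row + column sums)
pair_involvement <- function(p) {
  if (inherits(p, "pair_probability_matrix")) p <- p$p
  rowSums(p) + colSums(p)
}

#' @export
print.pair_probability_matrix <- function(x, ...) {
  cat("<pair_probability_matrix> n = ", x$n, ", ",
      sum(x$p >= 0.01), " entries >= 0.01\n", sep = "")
  invisible(x)
}

#' Per-position unpaired probabilities
#'
#' \code{P(i) = 1 - sum_(j>i) P(i,j) - sum_(j<i) P(j,i)}, clipped to
#' \code{[0, 1]} only for violations within \code{1e-9}; larger
#' violations indicate an invalid matrix and raise an error.
#'
#' @param p A [pair_probability_matrix()].
#' @return Numeric vector of length \code{n}.
#' @export
unpaired_probabilities <- function(p) {
  stopifnot(inherits(p, "pair_probability_matrix"))
  q <- 1 - pair_involvement(p)
  if (any(q < -1e-9))
    stop("pairing involvement exceeds 1 beyond tolerance")
  pmin(pmax(q, 0), 1)
}

#' Exhaustive-enumeration oracle for base-pair probabilities
#'
#' Enumerates every non-crossing canonical structure of a short sequence,
#' weights each by the product of its loop and pair factors under the
#' same model contract as [pair_probabilities()], and forms the pair
#' marginals directly. Exponential in sequence length; refuses sequences
#' longer than \code{max_n}.
#'
#' @inheritParams pair_probabilities
#' @param max_n Hard length cap (default 16).
#' @return A [pair_probability_matrix()].
#' @export
enumerate_structures_oracle <- function(seq, model = default_energy_model(),
                                        extrinsic = NULL, kappa = 10,
                                        max_n = 16L) {
  stopifnot(inherits(seq, "rna_sequence"))
  n <- seq$length
  if (n > max_n) stop("sequence too long for enumeration (n = ", n, ")")
  enc <- encode_rna(seq$residues) + 1L
  extmult <- extrinsic_multiplier(extrinsic, kappa, n)
  if (is.null(extmult)) extmult <- matrix(1, n, n)

  canon <- canonical_mask()
  structs <- enumerate_noncrossing(enc, canon, model$min_hairpin, 1L, n)
  num <- matrix(0, n, n)
  Z <- 0
  for (s in structs) {
    w <- structure_weight(s, enc, model, extmult)
    Z <- Z + w
    if (nrow(s)) num[s] <- num[s] + w
  }
  pair_probability_matrix(num / Z)
}

# internal: list all non-crossing canonical pair sets on [i..j]
enumerate_noncrossing <- function(enc, canon, min_h, i, j) {
  if (i > j) return(list(matrix(integer(0), ncol = 2L)))
  # i unpaired
  out <- enumerate_noncrossing(enc, canon, min_h, i + 1L, j)
  # i paired with k
  ks <- seq_len(j)
  ks <- ks[ks > i + min_h]
  for (k in ks) {
    if (!canon[enc[i], enc[k]]) next
    inner <- enumerate_noncrossing(enc, canon, min_h, i + 1L, k - 1L)
    outer_ <- enumerate_noncrossing(enc, canon, min_h, k + 1L, j)
    for (si in inner) for (so in outer_)
      out[[length(out) + 1L]] <- rbind(cbind(i, k), si, so)
  }
  out
}

# internal: model weight of one structure via its loop decomposition
structure_weight <- function(pairs, enc, model, extmult) {
  if (!nrow(pairs)) return(1)
  pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  w <- 1
  for (r in seq_len(nrow(pairs)))
    w <- w * model$pair_weight[enc[pairs[r, 1]], enc[pairs[r, 2]]] *
      extmult[pairs[r, 1], pairs[r, 2]]
  # children of each pair: pairs directly nested (not inside another child)
  parent_of <- function(r) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    enclosing <- which(pairs[, 1] < i & pairs[, 2] > j)
    if (!length(enclosing)) return(0L)
    enclosing[which.max(pairs[enclosing, 1])]
  }
  par <- vapply(seq_len(nrow(pairs)), parent_of, integer(1))
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    ch <- which(par == r)
    if (!length(ch)) {
      w <- w * model$hairpin(j - i - 1L)
    } else if (length(ch) == 1L) {
      k <- pairs[ch, 1]; l <- pairs[ch, 2]
      u1 <- k - i - 1L; u2 <- j - l - 1L
      if (u1 + u2 > model$max_internal) return(0)
      f <- if (u1 == 0L && u2 == 0L) {
        model$stack[pair_type_index(enc[i], enc[j]),
                    pair_type_index(enc[k], enc[l])]
      } else if (u1 == 0L || u2 == 0L) {
        model$bulge(u1 + u2)
      } else {
        model$internal(u1 + u2)
      }
      w <- w * f
    } else {
      u <- (j - i - 1L) - sum(pairs[ch, 2] - pairs[ch, 1] + 1L)
      w <- w * model$m_init * model$m_branch^length(ch) *
        model$m_unpaired^u
    }
  }
  w
}
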