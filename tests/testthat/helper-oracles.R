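# Independent brute-force oracles and small generators shared by the
# tests. All oracles enumerate explicitly and never reuse the package's
# dynamic programs.

# Exhaustive pair-HMM path enumeration: every monotone alignment path,
# weighted by transition/emission (and rho on ALN moves) products. The
# initial move leaves the ALN state, matching the alpha_ALN(0,0) = 1
# boundary of the recursions.
hmm_path_oracle <- function(x, y, params, rho = NULL) {
  xe <- strsplit(x$residues, "")[[1]]
  ye <- strsplit(y$residues, "")[[1]]
  n1 <- length(xe); n2 <- length(ye)
  idx <- function(b) match(b, c("A", "C", "G", "U"))
  tau <- params$transition; ep <- params$emission_pair
  ie <- params$emission_single
  co <- matrix(0, n1, n2); al <- matrix(0, n1, n2); Z <- 0
  rec <- function(i, k, prev, w, visited) {
    if (i == n1 && k == n2) {
      Z <<- Z + w
      for (v in visited) {
        co[v[1], v[2]] <<- co[v[1], v[2]] + w
        if (v[3] == 1) al[v[1], v[2]] <<- al[v[1], v[2]] + w
      }
      return(invisible())
    }
    if (i < n1 && k < n2) {
      r <- if (is.null(rho)) 1 else rho[i + 1, k + 1]
      rec(i + 1, k + 1, 1,
          w * tau[prev, 1] * ep[idx(xe[i + 1]), idx(ye[k + 1])] * r,
          c(visited, list(c(i + 1, k + 1, 1))))
    }
    if (i < n1) {
      w2 <- w * tau[prev, 2] * ie[idx(xe[i + 1])]
      vis <- if (k >= 1) c(visited, list(c(i + 1, k, 2))) else visited
      rec(i + 1, k, 2, w2, vis)
    }
    if (k < n2) {
      w2 <- w * tau[prev, 3] * ie[idx(ye[k + 1])]
      vis <- if (i >= 1) c(visited, list(c(i, k + 1, 3))) else visited
      rec(i, k + 1, 3, w2, vis)
    }
  }
  rec(0, 0, 1, 1, list())
  list(coincidence = co / Z, aligned = al / Z, Z = Z)
}

# Random valid HMM parameter set (rows/tables normalised).
random_hmm_params <- function() {
  tr <- matrix(stats::runif(9, 0.05, 1), 3, 3)
  tr <- tr / rowSums(tr)
  ep <- matrix(stats::runif(16, 0.2, 1), 4, 4)
  ep <- ep / sum(ep)
  ie <- stats::runif(4, 0.2, 1)
  hmm_parameters(tr, ep, ie / sum(ie))
}

random_rna <- function(n, id = "r") {
  rna_sequence(id, paste(sample(c("A", "C", "G", "U"), n, replace = TRUE),
                         collapse = ""))
}

# Random toy energy model with positive factors.
random_energy_model <- function() {
  pw <- matrix(0, 4, 4)
  canon <- rbind(c(1, 4), c(4, 1), c(3, 2), c(2, 3), c(3, 4), c(4, 3))
  pw[canon] <- stats::runif(6, 0.5, 3)
  st <- matrix(stats::runif(36, 1, 5), 6, 6)
  h0 <- stats::runif(1, 0.01, 0.2)
  b0 <- stats::runif(1, 0.01, 0.2)
  i0 <- stats::runif(1, 0.01, 0.2)
  energy_model(pw, st,
               hairpin = function(u) h0 * exp(-0.2 * (u - 3)),
               bulge = function(u) b0 * exp(-0.4 * u),
               internal = function(u) i0 * exp(-0.3 * (u - 2)),
               m_init = stats::runif(1, 0.005, 0.05),
               m_branch = stats::runif(1, 0.5, 1),
               m_unpaired = stats::runif(1, 0.7, 1))
}

# Random pair-probability matrix with valid per-position involvement.
random_pair_matrix <- function(n, min_sep = 3L, density = 0.4) {
  p <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j - i > min_sep && stats::runif(1) < density)
      p[i, j] <- stats::runif(1)
  }
  inv <- max(rowSums(p) + colSums(p), 1)
  pair_probability_matrix(p / (inv * 1.0001))
}

# Brute-force MEA: enumerate all non-crossing structures with pair span
# > min_sep (pairs need not be canonical here) and maximise the
# objective directly.
mea_brute_force <- function(p, q, min_sep = 3L) {
  n <- length(q)
  structs <- function(i, j) {
    if (i > j) return(list(matrix(integer(0), ncol = 2)))
    out <- structs(i + 1, j)
    for (k in seq_len(j)) {
      if (k - i <= min_sep) next
      for (si in structs(i + 1, k - 1)) for (so in structs(k + 1, j))
        out[[length(out) + 1L]] <- rbind(cbind(i, k), si, so)
    }
    out
  }
  best <- -Inf
  for (s in structs(1L, n)) {
    paired <- as.vector(s)
    obj <- sum(q[setdiff(seq_len(n), paired)])
    if (nrow(s)) obj <- obj + sum(2 * p[s])
    if (obj > best) best <- obj
  }
  best
}

# A small fast family for pipeline-level tests.
small_family <- function(seed = 1L, n_seqs = 3L, ...) {
  db <- "...((((((........))))))...(((((.......)))))..."
  struct <- parse_dotbracket(db)
  bases <- homofold:::with_rng(seed + 1000L, {
    b <- sample(c("A", "C", "G", "U"), nchar(db), replace = TRUE)
    for (r in seq_len(nrow(struct$pairs))) {
      t <- sample(6L, 1L, prob = c(.15, .15, .3, .3, .05, .05))
      b[struct$pairs[r, 1]] <- homofold:::.pair_types[t, 1]
      b[struct$pairs[r, 2]] <- homofold:::.pair_types[t, 2]
    }
    b
  })
  generate_family(family_spec(paste(bases, collapse = ""), struct,
                              n_seqs = n_seqs, seed = seed, ...))
}

# Summed aligned-posterior mass on the true-alignment cells of a family.
true_cell_mass <- function(state, fam) {
  chars <- lapply(fam$alignment$rows, function(r) strsplit(r, "")[[1]])
  pos <- lapply(chars, function(cc) {
    p <- cumsum(cc != "-"); p[cc == "-"] <- NA_integer_; p
  })
  H <- length(chars)
  total <- 0
  for (m in seq_len(H - 1)) for (n in (m + 1):H) {
    both <- !is.na(pos[[m]]) & !is.na(pos[[n]])
    cells <- cbind(pos[[m]][both], pos[[n]][both])
    al <- state$post[[homofold:::pair_key(m, n)]]$aligned
    total <- total + sum(al[cells])
  }
  total
}
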