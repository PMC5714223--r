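#' Specification of a synthetic homolog family
#'
#' Homolog families are generated from a seed sequence with a known
#' structure, evolved under a star phylogeny: substitutions at paired
#' positions are pair-preserving (compensatory) with probability
#' \code{compensatory}, and indels are restricted to unpaired (loop)
#' regions so the truth structures remain well-defined. This emulates
#' the central property the pipeline exploits: secondary structure is
#' conserved to a greater extent than sequence identity.
#'
#' @param seed_seq Seed residue string or [rna_sequence()].
#' @param seed_struct [secondary_structure()] of the seed.
#' @param n_seqs Number of descendants (the family size H).
#' @param sub_rate Per-position (per-pair, for paired positions)
#'   substitution probability in \code{[0, 1]}.
#' @param compensatory Fraction of paired-position substitutions that
#'   replace the pair with a different canonical pair; the remainder
#'   mutate one side only and may destroy the pair.
#' @param indel_rate Per-unpaired-position probability of an indel
#'   event (split evenly between a deletion of that position and an
#'   insertion after it).
#' @param max_indel Maximum insertion length (uniform on
#'   \code{1..max_indel}).
#' @param seed RNG seed; generation is fully deterministic given it.
#' @param hairpin_insert Either \code{FALSE} or a descendant index that
#'   receives a whole inserted hairpin (a variable structural element)
#'   in its longest loop.
#' @param two_level When \code{TRUE}, descendants hang off two
#'   intermediate ancestors; the ancestor branches carry the full
#'   substitution rate and the leaf branches a quarter of it, giving the
#'   family a known, clearly separated two-clade topology for guide-tree
#'   tests.
#' @return An object of class \code{family_spec}.
#' @export
family_spec <- function(seed_seq, seed_struct, n_seqs = 5L,
                        sub_rate = 0.35, compensatory = 1,
                        indel_rate = 0.03, max_indel = 3L, seed = 1L,
                        hairpin_insert = FALSE, two_level = FALSE) {
  if (is.character(seed_seq)) seed_seq <- rna_sequence("seed", seed_seq)
  stopifnot(inherits(seed_seq, "rna_sequence"),
            inherits(seed_struct, "secondary_structure"),
            seed_struct$length == seed_seq$length,
            n_seqs >= 1L, sub_rate >= 0, sub_rate <= 1,
            compensatory >= 0, compensatory <= 1,
            indel_rate >= 0, indel_rate <= 1, max_indel >= 1L)
  structure(list(seed_seq = seed_seq, seed_struct = seed_struct,
                 n_seqs = as.integer(n_seqs), sub_rate = sub_rate,
                 compensatory = compensatory, indel_rate = indel_rate,
                 max_indel = as.integer(max_indel), seed = as.integer(seed),
                 hairpin_insert = hairpin_insert, two_level = two_level),
            class = "family_spec")
}

#' Parse a dot-bracket string into a secondary structure
#'
#' @param db Dot-bracket string over \code{().}; must be balanced.
#' @param min_hairpin Passed through to [secondary_structure()].
#' @return A [secondary_structure()].
#' @export
parse_dotbracket <- function(db, min_hairpin = 3L) {
  cc <- strsplit(db, "")[[1]]
  if (any(!cc %in% c("(", ")", ".")))
    stop("dot-bracket may contain only '(', ')' and '.'")
  stack <- integer(0)
  pairs <- matrix(integer(0), ncol = 2L)
  for (i in seq_along(cc)) {
    if (cc[i] == "(") stack <- c(stack, i)
    else if (cc[i] == ")") {
      if (!length(stack)) stop("unbalanced dot-bracket")
      pairs <- rbind(pairs, c(stack[length(stack)], i))
      stack <- stack[-length(stack)]
    }
  }
  if (length(stack)) stop("unbalanced dot-bracket")
  secondary_structure(length(cc), pairs, min_hairpin = min_hairpin)
}

# canonical pair types as base pairs (A,C,G,U alphabet)
.pair_types <- matrix(c("A", "U", "U", "A", "G", "C", "C", "G",
                        "G", "U", "U", "G"),
                      ncol = 2L, byrow = TRUE)

# internal: run expr under a private RNG stream seeded with `seed`
with_rng <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv())
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' A ready-made multibranch seed family specification
#'
#' Builds a ~110 nt seed with a closing stem and three hairpin arms (a
#' cloverleaf-like multibranch layout typical of small structured
#' RNAs), assigns GC-biased canonical pairs to the stems and uniform
#' bases to the loops, and wraps it in a [family_spec()].
#'
#' @param seed RNG seed determining the seed sequence (and downstream
#'   family generation).
#' @param ... Further arguments passed to [family_spec()].
#' @return A [family_spec()].
#' @export
example_family_spec <- function(seed = 1L, ...) {
  db <- paste0("....((((((((...",
               "(((((((..........)))))))", "...",
               "((((((((............))))))))", "...",
               "(((((((..........)))))))",
               "...))))))))....")
  struct <- parse_dotbracket(db)
  L <- struct$length
  bases <- with_rng(seed, {
    b <- sample(c("A", "C", "G", "U"), L, replace = TRUE)
    type_w <- c(0.15, 0.15, 0.30, 0.30, 0.05, 0.05)
    for (r in seq_len(nrow(struct$pairs))) {
      t <- sample(6L, 1L, prob = type_w)
      b[struct$pairs[r, 1]] <- .pair_types[t, 1]
      b[struct$pairs[r, 2]] <- .pair_types[t, 2]
    }
    b
  })
  family_spec(paste(bases, collapse = ""), struct, seed = seed, ...)
}

# internal: substitute bases in place; pairs_mat rows are (i, j)
mutate_bases <- function(bases, pairs_mat, unpaired_idx, rate,
                         compensatory) {
  alph <- c("A", "C", "G", "U")
  for (r in seq_len(nrow(pairs_mat))) {
    if (stats::runif(1) < rate) {
      i <- pairs_mat[r, 1]; j <- pairs_mat[r, 2]
      if (stats::runif(1) < compensatory) {
        cur <- paste0(bases[i], bases[j])
        types <- paste0(.pair_types[, 1], .pair_types[, 2])
        choice <- sample(setdiff(types, cur), 1L)
        bases[i] <- substr(choice, 1, 1)
        bases[j] <- substr(choice, 2, 2)
      } else {
        side <- sample(c(i, j), 1L)
        bases[side] <- sample(setdiff(alph, bases[side]), 1L)
      }
    }
  }
  for (i in unpaired_idx) {
    if (stats::runif(1) < rate)
      bases[i] <- sample(setdiff(alph, bases[i]), 1L)
  }
  bases
}

#' Generate a synthetic homolog family with known truth
#'
#' Evolves the seed of a [family_spec()] into \code{n_seqs} descendants
#' and records the true alignment (seed coordinates plus per-sequence
#' insertion columns) and the true structure of every descendant (seed
#' pairs that survive with canonical bases, mapped into descendant
#' coordinates, plus any inserted hairpin).
#'
#' @param spec A [family_spec()].
#' @return A list with elements \code{seqs} ([sequence_set()]),
#'   \code{alignment} (true [multiple_alignment()]), \code{structures}
#'   (list of true [secondary_structure()]), \code{identity} (realised
#'   mean pairwise identity on the true alignment) and \code{spec}.
#' @export
generate_family <- function(spec) {
  stopifnot(inherits(spec, "family_spec"))
  with_rng(spec$seed, generate_family_impl(spec))
}

generate_family_impl <- function(spec) {
  L <- spec$seed_seq$length
  seed_bases <- strsplit(spec$seed_seq$residues, "")[[1]]
  pairs_mat <- spec$seed_struct$pairs
  paired_idx <- as.vector(pairs_mat)
  unpaired_idx <- setdiff(seq_len(L), paired_idx)
  H <- spec$n_seqs
  alph <- c("A", "C", "G", "U")
  canon <- paste0(.pair_types[, 1], .pair_types[, 2])

  # two-level mode: most divergence on the two ancestor branches, so the
  # within-clade similarity clearly dominates the between-clade one
  anc <- list(seed_bases, seed_bases)
  if (isTRUE(spec$two_level)) {
    anc <- lapply(1:2, function(k)
      mutate_bases(seed_bases, pairs_mat, unpaired_idx,
                   spec$sub_rate, spec$compensatory))
  }

  kept <- matrix(TRUE, H, L)      # seed position retained in descendant
  ins <- matrix("", H, L + 1L)    # insertion after seed position i-1
  bases_d <- vector("list", H)
  extra_pairs <- vector("list", H) # inserted-hairpin pairs, seed coords
  for (d in seq_len(H)) {
    start <- if (isTRUE(spec$two_level)) {
      anc[[if (d <= ceiling(H / 2)) 1L else 2L]]
    } else seed_bases
    rate <- if (isTRUE(spec$two_level)) spec$sub_rate / 4 else spec$sub_rate
    b <- mutate_bases(start, pairs_mat, unpaired_idx, rate,
                      spec$compensatory)
    for (i in unpaired_idx) {
      if (stats::runif(1) < spec$indel_rate / 2) kept[d, i] <- FALSE
      if (stats::runif(1) < spec$indel_rate / 2) {
        len <- sample.int(spec$max_indel, 1L)
        ins[d, i + 1L] <- paste(sample(alph, len, replace = TRUE),
                                collapse = "")
      }
    }
    bases_d[[d]] <- b
    extra_pairs[[d]] <- matrix(integer(0), ncol = 2L)
  }
  hp_d <- 0L; hp_slot <- 0L; hp_len <- 0L
  hp_pair_offsets <- NULL
  if (!isFALSE(spec$hairpin_insert)) {
    hp_d <- as.integer(spec$hairpin_insert)
    stopifnot(hp_d >= 1L, hp_d <= H)
    hp <- "GGCGCGAAAGCGCC" # 5 bp stem, 4 nt loop
    hp_len <- nchar(hp)
    hp_pair_offsets <- cbind(c(1L, 2L, 3L, 4L, 5L),
                             c(14L, 13L, 12L, 11L, 10L))
    # insert into the middle of the longest unpaired run
    runs <- rle(seq_len(L) %in% unpaired_idx)
    ends <- cumsum(runs$lengths)
    longest <- which(runs$values)[which.max(runs$lengths[runs$values])]
    hp_slot <- ends[longest] - runs$lengths[longest] %/% 2L
    ins[hp_d, hp_slot + 1L] <- paste0(hp, ins[hp_d, hp_slot + 1L])
  }

  # column framework: seed columns interleaved with insertion blocks
  col_src <- list() # each: c(type = 0 seed / d > 0 insert, pos, offset)
  for (i in 0:L) {
    if (i >= 1L) col_src[[length(col_src) + 1L]] <- c(0L, i, 0L)
    for (d in seq_len(H)) {
      blk <- ins[d, i + 1L]
      if (nzchar(blk))
        for (o in seq_len(nchar(blk)))
          col_src[[length(col_src) + 1L]] <- c(d, i, o)
    }
  }
  rows <- character(H)
  maps <- vector("list", H) # seed position -> descendant position
  seqs <- vector("list", H)
  hp_start <- NA_integer_   # descendant position of the hairpin's 1st nt
  for (d in seq_len(H)) {
    chars <- character(length(col_src))
    map <- rep(NA_integer_, L)
    at <- 0L
    for (ci in seq_along(col_src)) {
      src <- col_src[[ci]]
      if (src[1] == 0L) { # seed column
        i <- src[2]
        if (kept[d, i]) {
          at <- at + 1L
          map[i] <- at
          chars[ci] <- bases_d[[d]][i]
        } else chars[ci] <- "-"
      } else if (src[1] == d) {
        at <- at + 1L
        chars[ci] <- substr(ins[d, src[2] + 1L], src[3], src[3])
        if (d == hp_d && src[2] == hp_slot && src[3] == 1L)
          hp_start <- at
      } else chars[ci] <- "-"
    }
    rows[d] <- paste(chars, collapse = "")
    maps[[d]] <- map
    res <- degap(rows[d])
    if (!nzchar(res)) stop("generation produced an empty sequence")
    seqs[[d]] <- rna_sequence(sprintf("hom%02d", d), res)
  }
  if (hp_d > 0L)
    extra_pairs[[hp_d]] <- hp_start - 1L + hp_pair_offsets

  structures <- vector("list", H)
  for (d in seq_len(H)) {
    keep_pairs <- matrix(integer(0), ncol = 2L)
    for (r in seq_len(nrow(pairs_mat))) {
      i <- pairs_mat[r, 1]; j <- pairs_mat[r, 2]
      if (is.na(maps[[d]][i]) || is.na(maps[[d]][j])) next
      bp <- paste0(bases_d[[d]][i], bases_d[[d]][j])
      if (!bp %in% canon) next # destroyed by non-compensatory mutation
      keep_pairs <- rbind(keep_pairs, c(maps[[d]][i], maps[[d]][j]))
    }
    if (nrow(extra_pairs[[d]]))
      keep_pairs <- rbind(keep_pairs, extra_pairs[[d]])
    structures[[d]] <- secondary_structure(seqs[[d]]$length, keep_pairs,
                                           min_hairpin = 0L)
  }

  msa <- multiple_alignment(vapply(seqs, function(s) s$id, character(1)),
                            rows)
  list(seqs = sequence_set(seqs), alignment = msa,
       structures = structures,
       identity = alignment_mean_identity(msa), spec = spec)
}

#' Mean pairwise identity of an alignment
#'
#' For each sequence pair: project the alignment onto the columns where
#' at least one of the two rows has a residue (the pairwise alignment,
#' including gap columns) and report identical-column fraction; the
#' returned value is the mean over all pairs.
#'
#' @param msa A [multiple_alignment()].
#' @return Mean pairwise identity in \code{[0, 1]}.
#' @export
alignment_mean_identity <- function(msa) {
  stopifnot(inherits(msa, "multiple_alignment"))
  H <- length(msa$ids)
  if (H < 2L) return(1)
  chars <- lapply(msa$rows, function(r) strsplit(r, "")[[1]])
  vals <- c()
  for (a in seq_len(H - 1L)) for (b in (a + 1L):H) {
    keep <- chars[[a]] != "-" | chars[[b]] != "-"
    ident <- chars[[a]][keep] == chars[[b]][keep] & chars[[a]][keep] != "-"
    vals <- c(vals, sum(ident) / sum(keep))
  }
  mean(vals)
}

#' Analytic expected pairwise identity under the generation model
#'
#' Exact closed-form expectation of the pairwise identity between two
#' star-phylogeny descendants, from per-site enumeration of the
#' substitution kernel (exact when \code{indel_rate = 0}; indels shift
#' the denominator slightly).
#'
#' @param spec A [family_spec()] (star phylogeny).
#' @return Expected identity in \code{[0, 1]}.
#' @export
expected_pairwise_identity <- function(spec) {
  stopifnot(inherits(spec, "family_spec"), !isTRUE(spec$two_level))
  r <- spec$sub_rate
  cmp <- spec$compensatory
  L <- spec$seed_seq$length
  bases <- strsplit(spec$seed_seq$residues, "")[[1]]
  pairs_mat <- spec$seed_struct$pairs
  unpaired_n <- L - 2L * nrow(pairs_mat)
  p_unpaired <- (1 - r)^2 + r^2 / 3

  alph <- c("A", "C", "G", "U")
  states <- expand.grid(left = alph, right = alph,
                        stringsAsFactors = FALSE)
  canon <- paste0(.pair_types[, 1], .pair_types[, 2])
  kernel <- function(s0) { # distribution over 16 states given seed pair
    pr <- numeric(16L)
    names(pr) <- paste0(states$left, states$right)
    pr[s0] <- pr[s0] + (1 - r)
    others <- setdiff(canon, s0)
    pr[others] <- pr[others] + r * cmp / 5
    l0 <- substr(s0, 1, 1); r0 <- substr(s0, 2, 2)
    for (b in setdiff(alph, l0))
      pr[paste0(b, r0)] <- pr[paste0(b, r0)] + r * (1 - cmp) / 6
    for (b in setdiff(alph, r0))
      pr[paste0(l0, b)] <- pr[paste0(l0, b)] + r * (1 - cmp) / 6
    pr
  }
  total <- unpaired_n * p_unpaired
  for (rr in seq_len(nrow(pairs_mat))) {
    s0 <- paste0(bases[pairs_mat[rr, 1]], bases[pairs_mat[rr, 2]])
    k <- kernel(s0)
    p_left <- sum(outer(k, k) *
                    outer(states$left, states$left, `==`))
    p_right <- sum(outer(k, k) *
                     outer(states$right, states$right, `==`))
    total <- total + p_left + p_right
  }
  total / L
}
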