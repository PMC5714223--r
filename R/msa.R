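#' Probabilistic consistency transformation
#'
#' Re-estimates every pairwise aligned-posterior matrix by averaging
#' two-step alignments through each sequence of the set, including the
#' two endpoint sequences themselves with identity self-posteriors:
#' \deqn{P'(i \sim k | X_m, X_n) = \frac{1}{H} \sum_{o} \sum_q
#'   P(i \sim q | X_m, X_o) P(q \sim k | X_o, X_n)}
#' For H = 2 the transform returns its input exactly. Following ProbCons,
#' the transform is applied once. Entries below \code{sparsity} are
#' dropped from the matrices entering the cross products (the direct
#' endpoint terms are kept dense), bounding the cost on larger sets.
#'
#' @param aligned Named list of aligned-posterior matrices, one per
#'   unordered sequence pair, keys \code{"m|n"} with \code{m < n} and
#'   rows indexed by \code{m} positions.
#' @param lens Integer vector of the H sequence lengths.
#' @param sparsity Entries below this value are zeroed before the
#'   matrix products (default 0.001).
#' @return Named list of transformed matrices with the same keys.
#' @export
consistency_transform <- function(aligned, lens, sparsity = 0.001) {
  H <- length(lens)
  stopifnot(H >= 2L)
  get_pair <- function(m, n) {
    key <- pair_key(m, n)
    p <- aligned[[key]]
    if (is.null(p)) stop("missing posterior matrix for pair ", key)
    if (m < n) p else t(p)
  }
  sparse <- function(p) {
    p[p < sparsity] <- 0
    p
  }
  out <- list()
  for (m in seq_len(H - 1L)) for (n in (m + 1L):H) {
    direct <- get_pair(m, n)
    acc <- 2 * direct # intermediaries o = m and o = n (identity factors)
    others <- setdiff(seq_len(H), c(m, n))
    for (o in others)
      acc <- acc + sparse(get_pair(m, o)) %*% sparse(get_pair(o, n))
    out[[pair_key(m, n)]] <- pmin(acc / H, 1)
  }
  out
}

#' Guide tree by greedy agglomeration on expected accuracy
#'
#' Pairwise similarity is the expected accuracy of the maximum expected
#' accuracy decoding of the transformed posterior matrix, normalised by
#' the shorter sequence length:
#' \code{E(m, n) = max-sum decode score / min(N_m, N_n)}. Clusters are
#' merged greedily by highest average-linkage similarity; ties break
#' toward the smallest sequence index. Average linkage makes the merge
#' scores non-increasing along the merge order.
#'
#' @param transformed A [consistency_transform()] result.
#' @param lens Integer vector of sequence lengths.
#' @return An object of class \code{guide_tree}: a list of merges, each
#'   with the member indices of the two clusters and the merge score.
#' @export
build_guide_tree <- function(transformed, lens) {
  H <- length(lens)
  stopifnot(H >= 2L)
  E <- matrix(0, H, H)
  for (m in seq_len(H - 1L)) for (n in (m + 1L):H) {
    sc <- .nw_decode_cpp(transformed[[pair_key(m, n)]])$score
    E[m, n] <- E[n, m] <- sc / min(lens[m], lens[n])
  }
  clusters <- lapply(seq_len(H), identity)
  merges <- list()
  while (length(clusters) > 1L) {
    best <- c(NA_integer_, NA_integer_)
    best_s <- -Inf
    for (a in seq_len(length(clusters) - 1L)) {
      for (b in (a + 1L):length(clusters)) {
        s <- mean(E[clusters[[a]], clusters[[b]]])
        # strict > : first-found pair wins ties; clusters are kept ordered
        # by smallest member, so this is the smallest-index tie-break
        if (s > best_s) {
          best_s <- s
          best <- c(a, b)
        }
      }
    }
    a <- best[1]; b <- best[2]
    merges[[length(merges) + 1L]] <-
      list(left = clusters[[a]], right = clusters[[b]], score = best_s)
    merged <- c(clusters[[a]], clusters[[b]])
    clusters <- c(clusters[-c(a, b)], list(merged))
    # keep clusters ordered by their smallest member for deterministic ties
    clusters <- clusters[order(vapply(clusters, min, integer(1)))]
  }
  structure(list(merges = merges), class = "guide_tree")
}

#' @export
print.guide_tree <- function(x, ...) {
  cat("<guide_tree>\n")
  for (m in x$merges)
    cat("  (", paste(m$left, collapse = ","), ") + (",
        paste(m$right, collapse = ","), ")  score ",
        formatC(m$score, digits = 4, format = "f"), "\n", sep = "")
  invisible(x)
}

# internal: alignment of one cluster as a position matrix: one row per
# member sequence (named by its index), one column per alignment column,
# entries = residue index or NA for a gap
single_profile <- function(m, len) {
  pos <- matrix(seq_len(len), nrow = 1L)
  rownames(pos) <- as.character(m)
  pos
}

# internal: merge two profiles by profile-profile DP over columns.
# Column-against-column score is the summed transformed posterior over
# all cross-cluster sequence pairs at the residues placed in the same
# column; gap columns score 0. Existing columns are kept atomic, so a
# gap once introduced is never removed.
merge_profiles <- function(pa, pb, transformed, lens) {
  ids_a <- as.integer(rownames(pa))
  ids_b <- as.integer(rownames(pb))
  ca <- ncol(pa); cb <- ncol(pb)
  S <- matrix(0, ca, cb)
  for (a in seq_along(ids_a)) {
    for (b in seq_along(ids_b)) {
      m <- ids_a[a]; n <- ids_b[b]
      P <- transformed[[pair_key(m, n)]]
      if (m > n) P <- t(P)
      # pad with a zero row/column so NA (gap) positions score 0
      Ppad <- rbind(cbind(P, 0), 0)
      ia <- pa[a, ]; ia[is.na(ia)] <- nrow(Ppad)
      ib <- pb[b, ]; ib[is.na(ib)] <- ncol(Ppad)
      S <- S + Ppad[ia, ib, drop = FALSE]
    }
  }
  dec <- .nw_decode_cpp(S)
  mm <- dec$matches
  # build the merged column order: between matched column pairs, emit
  # the unmatched columns of the first profile, then of the second
  cols <- list()
  ai <- 1L; bi <- 1L
  emit <- function(acol, bcol) {
    cols[[length(cols) + 1L]] <<- c(acol, bcol)
  }
  if (nrow(mm)) {
    for (r in seq_len(nrow(mm))) {
      while (ai < mm[r, 1]) { emit(ai, NA); ai <- ai + 1L }
      while (bi < mm[r, 2]) { emit(NA, bi); bi <- bi + 1L }
      emit(ai, bi); ai <- ai + 1L; bi <- bi + 1L
    }
  }
  while (ai <= ca) { emit(ai, NA); ai <- ai + 1L }
  while (bi <= cb) { emit(NA, bi); bi <- bi + 1L }
  merged <- matrix(NA_integer_, nrow = nrow(pa) + nrow(pb),
                   ncol = length(cols))
  rownames(merged) <- c(rownames(pa), rownames(pb))
  for (ci in seq_along(cols)) {
    acol <- cols[[ci]][1]; bcol <- cols[[ci]][2]
    if (!is.na(acol)) merged[seq_len(nrow(pa)), ci] <- pa[, acol]
    if (!is.na(bcol)) merged[nrow(pa) + seq_len(nrow(pb)), ci] <- pb[, bcol]
  }
  merged
}

#' Progressive profile alignment along a guide tree
#'
#' Merges cluster alignments in guide-tree order with a profile-profile
#' dynamic program maximising the sum, over all cross-cluster sequence
#' pairs, of the transformed posterior of the residues placed in the
#' same column (gap score 0). Alignment columns are atomic, so gaps
#' introduced at earlier merges persist.
#'
#' @param tree A [build_guide_tree()] result.
#' @param transformed A [consistency_transform()] result.
#' @param seqs The [sequence_set()].
#' @return A [multiple_alignment()] with rows in input order.
#' @export
progressive_align <- function(tree, transformed, seqs) {
  stopifnot(inherits(tree, "guide_tree"), inherits(seqs, "sequence_set"))
  lens <- vapply(seqs$sequences, function(s) s$length, integer(1))
  profiles <- lapply(seq_along(lens), function(m) single_profile(m, lens[m]))
  names(profiles) <- vapply(profiles, function(p)
    as.character(min(as.integer(rownames(p)))), character(1))
  for (mg in tree$merges) {
    ka <- as.character(min(mg$left)); kb <- as.character(min(mg$right))
    merged <- merge_profiles(profiles[[ka]], profiles[[kb]],
                             transformed, lens)
    profiles[[kb]] <- NULL
    profiles[[ka]] <- merged
  }
  pos <- profiles[[1]]
  pos <- pos[order(as.integer(rownames(pos))), , drop = FALSE]
  rows <- vapply(seq_len(nrow(pos)), function(r) {
    res <- strsplit(seqs[[as.integer(rownames(pos)[r])]]$residues, "")[[1]]
    paste(ifelse(is.na(pos[r, ]), "-", res[pos[r, ]]), collapse = "")
  }, character(1))
  multiple_alignment(seqs$ids, rows)
}

#' Final multiple sequence alignment from a pipeline state
#'
#' Applies the probabilistic consistency transformation to the final
#' aligned posteriors, builds the guide tree, and aligns progressively.
#'
#' @param state A \code{homofold_state} (after the iterations).
#' @param cfg The [homofold_config()] in use.
#' @return A [multiple_alignment()] with rows in input order.
#' @export
compute_msa <- function(state, cfg = homofold_config()) {
  stopifnot(inherits(state, "homofold_state"))
  seqs <- state$seqs
  H <- length(seqs)
  if (H < 2L) stop("an alignment needs at least two sequences")
  lens <- vapply(seqs$sequences, function(s) s$length, integer(1))
  aligned <- lapply(state$post, function(p) p$aligned)
  transformed <- consistency_transform(aligned, lens, cfg$consistency_min)
  tree <- build_guide_tree(transformed, lens)
  progressive_align(tree, transformed, seqs)
}
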