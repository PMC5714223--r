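#' Sensitivity / PPV score pair
#'
#' @param tp True positives.
#' @param ref_p Reference positives (sensitivity denominator).
#' @param pred_p Predicted positives (PPV denominator).
#' @return An object of class \code{score_pair} with fields
#'   \code{sensitivity}, \code{ppv} and the three counts. A zero
#'   denominator yields a flagged 0 (\code{flagged_zero = TRUE}).
#' @export
score_pair <- function(tp, ref_p, pred_p) {
  stopifnot(tp >= 0, ref_p >= 0, pred_p >= 0, tp <= ref_p || ref_p == 0,
            tp <= pred_p || pred_p == 0)
  structure(list(sensitivity = if (ref_p > 0) tp / ref_p else 0,
                 ppv = if (pred_p > 0) tp / pred_p else 0,
                 tp = as.integer(tp), ref_p = as.integer(ref_p),
                 pred_p = as.integer(pred_p),
                 flagged_zero = ref_p == 0 || pred_p == 0),
            class = "score_pair")
}

#' @export
print.score_pair <- function(x, ...) {
  cat("sensitivity ", formatC(x$sensitivity, digits = 4, format = "f"),
      " (", x$tp, "/", x$ref_p, "), PPV ",
      formatC(x$ppv, digits = 4, format = "f"),
      " (", x$tp, "/", x$pred_p, ")\n", sep = "")
  invisible(x)
}

# internal: set of aligned residue pairs of an alignment, as strings
# "a|i|b|k" with sequence indices a < b (positions 1-based in each
# ungapped sequence); columns where either residue is a gap contribute
# nothing
aligned_residue_pairs <- function(msa, id_order) {
  rows <- msa$rows[match(id_order, msa$ids)]
  chars <- lapply(rows, function(r) strsplit(r, "")[[1]])
  pos <- lapply(chars, function(cc) {
    p <- cumsum(cc != "-")
    p[cc == "-"] <- NA_integer_
    p
  })
  H <- length(rows)
  out <- character(0)
  for (a in seq_len(H - 1L)) for (b in (a + 1L):H) {
    both <- !is.na(pos[[a]]) & !is.na(pos[[b]])
    if (any(both))
      out <- c(out, paste0(a, "|", pos[[a]][both], "|", b, "|",
                           pos[[b]][both]))
  }
  out
}

#' Alignment accuracy against a reference alignment
#'
#' The unit of comparison is an aligned residue pair: two residues from
#' two different sequences placed in the same column, neither a gap.
#' Sensitivity is the fraction of reference pairs recovered; PPV the
#' fraction of predicted pairs present in the reference. Matching is
#' exact column co-membership; the one-position slippage rule applies
#' only to base pairs, not to alignment columns.
#'
#' @param pred,ref [multiple_alignment()] objects over the same
#'   sequences (matched by id; residues must agree after de-gapping).
#' @return A [score_pair()].
#' @export
alignment_score <- function(pred, ref) {
  stopifnot(inherits(pred, "multiple_alignment"),
            inherits(ref, "multiple_alignment"))
  if (!setequal(pred$ids, ref$ids))
    stop("alignments cover different sequence ids")
  id_order <- ref$ids
  for (id in id_order) {
    dp <- degap(pred$rows[match(id, pred$ids)])
    dr <- degap(ref$rows[match(id, ref$ids)])
    if (!identical(dp, dr))
      stop("sequence '", id, "' differs between the two alignments")
  }
  ps <- aligned_residue_pairs(pred, id_order)
  rs <- aligned_residue_pairs(ref, id_order)
  score_pair(length(intersect(ps, rs)), length(rs), length(ps))
}

#' Structure accuracy with the one-position slippage rule
#'
#' A predicted pair \code{(i, j)} is counted correct when the reference
#' contains \code{(i, j)}, \code{(i-1, j)}, \code{(i+1, j)},
#' \code{(i, j-1)} or \code{(i, j+1)}. Each reference pair can credit at
#' most one predicted pair; predictions are matched greedily in pair
#' order (sorted by \code{i}, then \code{j}).
#'
#' @param pred,ref [secondary_structure()] objects of equal length.
#' @return A [score_pair()].
#' @export
structure_score <- function(pred, ref) {
  stopifnot(inherits(pred, "secondary_structure"),
            inherits(ref, "secondary_structure"))
  if (pred$length != ref$length)
    stop("structures have different lengths")
  rp <- ref$pairs
  claimed <- logical(nrow(rp))
  key <- function(i, j) paste0(i, "_", j)
  ref_keys <- if (nrow(rp)) key(rp[, 1], rp[, 2]) else character(0)
  tp <- 0L
  pp <- pred$pairs
  if (nrow(pp)) {
    pp <- pp[order(pp[, 1], pp[, 2]), , drop = FALSE]
    for (r in seq_len(nrow(pp))) {
      i <- pp[r, 1]; j <- pp[r, 2]
      cand <- c(key(i, j), key(i - 1L, j), key(i + 1L, j),
                key(i, j - 1L), key(i, j + 1L))
      for (ck in cand) { # exact match takes precedence over slips
        hit <- which(ref_keys == ck & !claimed)
        if (length(hit)) {
          claimed[hit[1]] <- TRUE
          tp <- tp + 1L
          break
        }
      }
    }
  }
  score_pair(tp, nrow(rp), nrow(pp))
}
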