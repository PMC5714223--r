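#' RNA sequence
#'
#' A single RNA sequence with an identifier. Residues are stored as an
#' uppercase string over the unambiguous RNA alphabet \code{A,C,G,U};
#' use [read_fasta()] for normalisation of raw input (T to U, case).
#'
#' @param id Sequence identifier (non-empty string).
#' @param residues Residue string over \code{A,C,G,U}.
#' @return An object of class \code{rna_sequence} with fields \code{id},
#'   \code{residues} and \code{length}.
#' @export
rna_sequence <- function(id, residues) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.character(residues), length(residues) == 1L)
  residues <- toupper(residues)
  if (grepl("[^ACGU]", residues))
    stop("residues must be over {A,C,G,U}: offending sequence '", id, "'")
  structure(list(id = id, residues = residues, length = nchar(residues)),
            class = "rna_sequence")
}

#' @export
print.rna_sequence <- function(x, ...) {
  cat("<rna_sequence> ", x$id, " (", x$length, " nt)\n", sep = "")
  invisible(x)
}

#' Ordered set of homologous RNA sequences
#'
#' @param sequences List of [rna_sequence()] objects. Identifiers must be
#'   unique; input order is preserved by every downstream computation.
#' @return An object of class \code{sequence_set}; \code{length()} gives
#'   the number of sequences H.
#' @export
sequence_set <- function(sequences) {
  stopifnot(is.list(sequences), length(sequences) >= 1L)
  ok <- vapply(sequences, inherits, logical(1), "rna_sequence")
  if (!all(ok)) stop("all elements must be rna_sequence objects")
  ids <- vapply(sequences, function(s) s$id, character(1))
  if (anyDuplicated(ids)) stop("duplicate sequence ids: ",
                               paste(unique(ids[duplicated(ids)]),
                                     collapse = ", "))
  structure(list(sequences = sequences, ids = ids),
            class = "sequence_set")
}

#' @export
length.sequence_set <- function(x) length(x$sequences)

#' @export
`[[.sequence_set` <- function(x, i) x$sequences[[i]]

#' @export
print.sequence_set <- function(x, ...) {
  cat("<sequence_set> H =", length(x), "sequences:\n")
  for (s in x$sequences)
    cat("  ", s$id, " (", s$length, " nt)\n", sep = "")
  invisible(x)
}

#' RNA secondary structure as a set of base pairs
#'
#' @param length Sequence length the structure refers to.
#' @param pairs Two-column integer matrix of base pairs \code{(i, j)} with
#'   \code{1 <= i < j <= length}; may have zero rows. No index may occur
#'   in two pairs.
#' @param min_hairpin Minimum number of unpaired nucleotides enclosed by
#'   a hairpin; every pair must satisfy \code{j - i > min_hairpin}.
#' @return An object of class \code{secondary_structure}.
#' @export
secondary_structure <- function(length, pairs = NULL, min_hairpin = 3L) {
  stopifnot(is.numeric(length), length >= 0)
  length <- as.integer(length)
  if (is.null(pairs) || NROW(pairs) == 0L) {
    pairs <- matrix(integer(0), ncol = 2L)
  } else {
    pairs <- matrix(as.integer(pairs), ncol = 2L)
  }
  colnames(pairs) <- c("i", "j")
  if (nrow(pairs)) {
    if (any(pairs[, 1] >= pairs[, 2]))
      stop("pairs must satisfy i < j")
    if (any(pairs < 1L) || any(pairs > length))
      stop("pair indices out of range 1..", length)
    idx <- as.vector(pairs)
    if (anyDuplicated(idx))
      stop("an index occurs in more than one pair")
    if (any(pairs[, 2] - pairs[, 1] <= min_hairpin))
      stop("pair span below hairpin minimum (j - i must exceed ",
           min_hairpin, ")")
    pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  }
  structure(list(length = length, pairs = pairs), class = "secondary_structure")
}

#' @export
print.secondary_structure <- function(x, ...) {
  cat("<secondary_structure> length ", x$length, ", ",
      nrow(x$pairs), " pairs\n", sep = "")
  invisible(x)
}

#' Gapped multiple sequence alignment
#'
#' @param ids Character vector of sequence identifiers.
#' @param rows Character vector of gapped strings over \code{A,C,G,U,-},
#'   one per id, all of equal width.
#' @return An object of class \code{multiple_alignment} with fields
#'   \code{ids}, \code{rows} and \code{columns}.
#' @export
multiple_alignment <- function(ids, rows) {
  stopifnot(is.character(ids), is.character(rows),
            length(ids) == length(rows), length(ids) >= 1L)
  ids <- unname(ids)
  rows <- unname(rows)
  if (anyDuplicated(ids)) stop("duplicate ids in alignment")
  w <- nchar(rows)
  if (length(unique(w)) != 1L) stop("ragged alignment rows")
  if (any(grepl("[^ACGU-]", rows)))
    stop("alignment rows must be over {A,C,G,U,-}")
  structure(list(ids = ids, rows = rows, columns = w[1L]),
            class = "multiple_alignment")
}

#' @export
print.multiple_alignment <- function(x, ...) {
  cat("<multiple_alignment> ", length(x$ids), " sequences x ",
      x$columns, " columns\n", sep = "")
  invisible(x)
}

#' Remove gaps from an alignment row
#'
#' @param row Gapped string.
#' @return The ungapped residue string.
#' @export
degap <- function(row) gsub("-", "", row, fixed = TRUE)

# internal: encode residues as integers A,C,G,U -> 0..3
encode_rna <- function(residues) {
  m <- match(strsplit(residues, "", fixed = TRUE)[[1]],
             c("A", "C", "G", "U")) - 1L
  if (anyNA(m)) stop("non-ACGU residue in sequence")
  m
}
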