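#' Read a multi-record nucleotide FASTA file
#'
#' Records are normalised for downstream use: lowercase is uppercased and
#' \code{T} is mapped to \code{U}. Any residue outside \code{A,C,G,U}
#' after normalisation (including IUPAC ambiguity codes such as \code{N})
#' is rejected, keeping the pipeline deterministic.
#'
#' @param path Path to a FASTA file with at least one record.
#' @return A [sequence_set()] preserving record order. Identifiers are
#'   the first whitespace-delimited token of each header.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) == 0L) stop("FASTA file has no records: ", path)
  ids <- sub("\\s.*$", "", names(recs))
  if (any(!nzchar(ids))) stop("FASTA record with empty identifier")
  if (anyDuplicated(ids))
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- vector("list", length(recs))
  for (r in seq_along(recs)) {
    res <- toupper(as.character(recs[[r]]))
    res <- gsub("T", "U", res, fixed = TRUE)
    if (grepl("[^ACGU]", res)) {
      bad <- unique(strsplit(gsub("[ACGU]", "", res), "")[[1]])
      stop("unsupported characters in record '", ids[r], "': ",
           paste(bad, collapse = ""),
           " (IUPAC ambiguity codes are not supported)")
    }
    if (!nzchar(res)) stop("empty sequence in record '", ids[r], "'")
    seqs[[r]] <- rna_sequence(ids[r], res)
  }
  sequence_set(seqs)
}

#' Read a connectivity-table (CT) structure file
#'
#' Standard six-column CT: position index, base, 5' connection, 3'
#' connection, pairing partner (0 when unpaired), natural numbering.
#' Pairing columns must be reciprocal.
#'
#' @param path Path to a CT file holding one structure.
#' @return A list with elements \code{sequence} ([rna_sequence()]) and
#'   \code{structure} ([secondary_structure()]).
#' @export
read_ct <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 1L) stop("empty CT file: ", path)
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  n <- suppressWarnings(as.integer(hdr[1]))
  if (is.na(n) || n < 1L) stop("bad CT header: ", lines[1])
  id <- if (length(hdr) > 1L) paste(hdr[-1], collapse = " ") else "structure"
  if (length(lines) - 1L != n) stop("CT row count does not match header")
  fields <- strsplit(trimws(lines[-1]), "\\s+")
  idx <- as.integer(vapply(fields, `[`, character(1), 1L))
  if (!identical(idx, seq_len(n))) stop("CT index column has gaps")
  base <- toupper(vapply(fields, `[`, character(1), 2L))
  base <- gsub("T", "U", base, fixed = TRUE)
  partner <- as.integer(vapply(fields, `[`, character(1), 5L))
  if (any(is.na(partner)) || any(partner < 0L) || any(partner > n))
    stop("CT pairing column out of range")
  for (i in seq_len(n)) {
    if (partner[i] != 0L && partner[partner[i]] != i)
      stop("non-reciprocal CT pairing at position ", i)
    if (partner[i] == i) stop("self-pairing at position ", i)
  }
  pi <- which(partner != 0L & seq_len(n) < partner)
  pairs <- cbind(pi, partner[pi])
  list(sequence = rna_sequence(id, paste(base, collapse = "")),
       structure = secondary_structure(n, pairs, min_hairpin = 0L))
}

#' Write a secondary structure as CT or dot-bracket text
#'
#' Writing dot-bracket requires the structure to be non-crossing; the CT
#' writer accepts any valid pair set. [read_ct()] applied to CT output
#' round-trips the structure exactly.
#'
#' @param seq The [rna_sequence()] the structure belongs to.
#' @param s A [secondary_structure()] with \code{s$length == seq$length}.
#' @param fmt Either \code{"ct"} or \code{"dot-bracket"}.
#' @param file Optional path; when given the text is also written there.
#' @return The formatted text as a single character scalar (invisibly
#'   when \code{file} is given).
#' @export
write_structure <- function(seq, s, fmt = c("ct", "dot-bracket"),
                            file = NULL) {
  fmt <- match.arg(fmt)
  stopifnot(inherits(seq, "rna_sequence"), inherits(s, "secondary_structure"))
  if (s$length != seq$length)
    stop("structure length does not match sequence length")
  res <- strsplit(seq$residues, "")[[1]]
  if (fmt == "ct") {
    partner <- integer(s$length)
    if (nrow(s$pairs)) {
      partner[s$pairs[, 1]] <- s$pairs[, 2]
      partner[s$pairs[, 2]] <- s$pairs[, 1]
    }
    i <- seq_len(s$length)
    body <- sprintf("%5d %s %7d %5d %5d %5d", i, res, i - 1L,
                    ifelse(i == s$length, 0L, i + 1L), partner, i)
    txt <- paste(c(sprintf("%5d  %s", s$length, seq$id), body, ""),
                 collapse = "\n")
  } else {
    if (pairs_cross(s$pairs))
      stop("structure contains crossing pairs; dot-bracket cannot ",
           "represent pseudoknots")
    db <- rep(".", s$length)
    if (nrow(s$pairs)) {
      db[s$pairs[, 1]] <- "("
      db[s$pairs[, 2]] <- ")"
    }
    txt <- paste0(">", seq$id, "\n", seq$residues, "\n",
                  paste(db, collapse = ""), "\n")
  }
  if (!is.null(file)) {
    writeLines(sub("\n$", "", txt), file)
    return(invisible(txt))
  }
  txt
}

# internal: TRUE when any two pairs cross (i < k < j < l)
pairs_cross <- function(pairs) {
  np <- nrow(pairs)
  if (np < 2L) return(FALSE)
  for (a in seq_len(np - 1L)) for (b in (a + 1L):np) {
    i <- pairs[a, 1]; j <- pairs[a, 2]
    k <- pairs[b, 1]; l <- pairs[b, 2]
    if ((i < k && k < j && j < l) || (k < i && i < l && l < j))
      return(TRUE)
  }
  FALSE
}

#' Write a multiple alignment as aligned FASTA or Stockholm text
#'
#' @param msa A [multiple_alignment()].
#' @param fmt Either \code{"afa"} (aligned FASTA) or \code{"stockholm"}.
#' @param file Optional output path.
#' @return The formatted text as a character scalar.
#' @export
write_alignment <- function(msa, fmt = c("afa", "stockholm"), file = NULL) {
  fmt <- match.arg(fmt)
  stopifnot(inherits(msa, "multiple_alignment"))
  if (fmt == "afa") {
    txt <- paste0(paste0(">", msa$ids, "\n", msa$rows, collapse = "\n"),
                  "\n")
  } else {
    w <- max(nchar(msa$ids)) + 2L
    body <- sprintf(paste0("%-", w, "s%s"), msa$ids, msa$rows)
    txt <- paste(c("# STOCKHOLM 1.0", "", body, "//", ""), collapse = "\n")
  }
  if (!is.null(file)) {
    writeLines(sub("\n$", "", txt), file)
    return(invisible(txt))
  }
  txt
}

#' Read an alignment from aligned FASTA or Stockholm text
#'
#' @param path Path to the alignment file.
#' @param fmt Either \code{"afa"} or \code{"stockholm"}.
#' @return A [multiple_alignment()].
#' @export
read_alignment <- function(path, fmt = c("afa", "stockholm")) {
  fmt <- match.arg(fmt)
  if (fmt == "afa") {
    recs <- Biostrings::readBStringSet(path)
    if (length(recs) == 0L) stop("empty alignment file")
    return(multiple_alignment(sub("\\s.*$", "", names(recs)),
                              toupper(as.character(recs))))
  }
  lines <- readLines(path)
  if (!grepl("^# STOCKHOLM 1\\.0", lines[1]))
    stop("missing Stockholm 1.0 header")
  body <- lines[!grepl("^#", lines) & !grepl("^//", lines) &
                nzchar(trimws(lines))]
  if (!any(grepl("^//", lines))) stop("missing Stockholm terminator")
  parts <- strsplit(trimws(body), "\\s+")
  ids <- vapply(parts, `[`, character(1), 1L)
  rows <- vapply(parts, `[`, character(1), 2L)
  rows <- toupper(gsub("[.]", "-", rows))
  multiple_alignment(ids, rows)
}

#' Write a probability matrix as sparse triplet text
#'
#' One line per retained entry: \code{i j value} with 1-based indices.
#' Entries below \code{1e-6} are omitted, keeping dumps small and
#' human-diffable.
#'
#' @param p Numeric matrix.
#' @param file Optional output path.
#' @return The triplet text as a character scalar.
#' @export
write_prob_matrix <- function(p, file = NULL) {
  stopifnot(is.matrix(p))
  keep <- which(p >= 1e-6, arr.ind = TRUE)
  keep <- keep[order(keep[, 1], keep[, 2]), , drop = FALSE]
  lines <- sprintf("%d %d %.8g", keep[, 1], keep[, 2], p[keep])
  txt <- paste0(paste(c(sprintf("# %d %d", nrow(p), ncol(p)), lines),
                      collapse = "\n"), "\n")
  if (!is.null(file)) {
    writeLines(sub("\n$", "", txt), file)
    return(invisible(txt))
  }
  txt
}

#' Read a sparse triplet probability-matrix dump
#'
#' @param path Path to a file written by [write_prob_matrix()].
#' @return The dense numeric matrix (omitted entries are zero).
#' @export
read_prob_matrix <- function(path) {
  lines <- readLines(path)
  dims <- as.integer(strsplit(sub("^#\\s*", "", lines[1]), "\\s+")[[1]])
  p <- matrix(0, dims[1], dims[2])
  body <- lines[-1]
  body <- body[nzchar(body)]
  if (length(body)) {
    f <- strsplit(body, "\\s+")
    i <- as.integer(vapply(f, `[`, character(1), 1L))
    j <- as.integer(vapply(f, `[`, character(1), 2L))
    v <- as.numeric(vapply(f, `[`, character(1), 3L))
    p[cbind(i, j)] <- v
  }
  p
}
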