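test_that("zero rates copy the seed exactly", {
  fam <- small_family(seed = 81, n_seqs = 3, sub_rate = 0,
                      indel_rate = 0)
  expect_equal(length(fam$seqs), 3L)
  res <- vapply(fam$seqs$sequences, function(s) s$residues, character(1))
  expect_equal(res[1], res[2])
  expect_equal(res[2], res[3])
  expect_false(any(grepl("-", fam$alignment$rows, fixed = TRUE)))
  expect_equal(fam$identity, 1)
  # all structures identical to the seed's pair count
  np <- vapply(fam$structures, function(s) nrow(s$pairs), integer(1))
  expect_equal(np, rep(np[1], 3L))
})

test_that("fully compensatory evolution preserves canonical pairing", {
  canon <- c("AU", "UA", "GC", "CG", "GU", "UG")
  fam <- small_family(seed = 82, n_seqs = 4, sub_rate = 0.5,
                      compensatory = 1, indel_rate = 0.05)
  seed_pairs <- nrow(fam$spec$seed_struct$pairs)
  for (m in seq_len(4)) {
    s <- fam$structures[[m]]
    expect_equal(nrow(s$pairs), seed_pairs) # no pair destroyed
    res <- strsplit(fam$seqs[[m]]$residues, "")[[1]]
    expect_true(all(paste0(res[s$pairs[, 1]], res[s$pairs[, 2]]) %in% canon))
  }
})

test_that("generation is deterministic in the seed and varies across it", {
  a <- generate_family(example_family_spec(seed = 9))
  b <- generate_family(example_family_spec(seed = 9))
  c <- generate_family(example_family_spec(seed = 10))
  expect_identical(a$alignment$rows, b$alignment$rows)
  expect_identical(vapply(a$seqs$sequences, `[[`, character(1), "residues"),
                   vapply(b$seqs$sequences, `[[`, character(1), "residues"))
  expect_false(identical(a$alignment$rows, c$alignment$rows))
})

test_that("true alignments de-gap to the generated sequences", {
  fam <- generate_family(example_family_spec(seed = 83, indel_rate = 0.08))
  for (m in seq_along(fam$seqs$sequences))
    expect_equal(degap(fam$alignment$rows[m]), fam$seqs[[m]]$residues)
})

test_that("realised identity tracks the analytic expectation", {
  spec <- example_family_spec(seed = 84, n_seqs = 8, sub_rate = 0.35,
                              compensatory = 1, indel_rate = 0)
  fam <- generate_family(spec)
  expect_lt(abs(fam$identity - expected_pairwise_identity(spec)), 0.1)
  # higher substitution rate lowers identity but keeps pairs mappable
  spec2 <- example_family_spec(seed = 84, n_seqs = 8, sub_rate = 0.6,
                               compensatory = 1, indel_rate = 0)
  fam2 <- generate_family(spec2)
  expect_lt(fam2$identity, fam$identity)
  expect_equal(nrow(fam2$structures[[1]]$pairs),
               nrow(spec2$seed_struct$pairs))
})

test_that("structures map through the true alignment onto seed pairs", {
  fam <- generate_family(example_family_spec(seed = 85, indel_rate = 0.05))
  chars <- lapply(fam$alignment$rows, function(r) strsplit(r, "")[[1]])
  # column index of each sequence position
  colof <- lapply(chars, function(cc) which(cc != "-"))
  seed_cols <- NULL
  for (m in seq_along(fam$structures)) {
    s <- fam$structures[[m]]
    cols <- cbind(colof[[m]][s$pairs[, 1]], colof[[m]][s$pairs[, 2]])
    key <- sort(paste(cols[, 1], cols[, 2]))
    if (is.null(seed_cols)) seed_cols <- key
    else expect_equal(key, seed_cols) # same pairs in column space
  }
})

test_that("a hairpin insertion adds a private structural element", {
  spec <- example_family_spec(seed = 86, n_seqs = 3, indel_rate = 0,
                              hairpin_insert = 2L)
  fam <- generate_family(spec)
  lens <- vapply(fam$seqs$sequences, `[[`, integer(1), "length")
  expect_equal(lens[2] - lens[1], 14L)
  expect_equal(nrow(fam$structures[[2]]$pairs) -
                 nrow(fam$structures[[1]]$pairs), 5L)
  # every pair of the carrier, inserted stem included, is canonical
  res <- strsplit(fam$seqs[[2]]$residues, "")[[1]]
  pp <- fam$structures[[2]]$pairs
  expect_true(all(paste0(res[pp[, 1]], res[pp[, 2]]) %in%
                    c("AU", "UA", "GC", "CG", "GU", "UG")))
})

test_that("dot-bracket parsing validates balance", {
  s <- parse_dotbracket("((((...))))")
  expect_equal(nrow(s$pairs), 4L)
  expect_error(parse_dotbracket("((..)"), "unbalanced")
  expect_error(parse_dotbracket("(x)"), "only")
})
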