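test_that("the consistency transform is the identity for two sequences", {
  set.seed(61)
  P <- matrix(runif(30, 0, 0.5), 5, 6)
  out <- consistency_transform(list("1|2" = P), lens = c(5L, 6L),
                               sparsity = 0)
  expect_identical(out[["1|2"]], P)
})

test_that("three-sequence transform equals the averaged matrix products", {
  set.seed(62)
  P12 <- matrix(runif(6, 0, 0.4), 2, 3)
  P13 <- matrix(runif(4, 0, 0.4), 2, 2)
  P23 <- matrix(runif(6, 0, 0.4), 3, 2)
  out <- consistency_transform(list("1|2" = P12, "1|3" = P13, "2|3" = P23),
                               lens = c(2L, 3L, 2L), sparsity = 0)
  expect_equal(out[["1|2"]], (2 * P12 + P13 %*% t(P23)) / 3,
               tolerance = 1e-12)
  expect_equal(out[["1|3"]], (2 * P13 + P12 %*% P23) / 3,
               tolerance = 1e-12)
  expect_equal(out[["2|3"]], (2 * P23 + t(P12) %*% P13) / 3,
               tolerance = 1e-12)
  # sub-stochastic inputs keep entries in [0, 1]
  for (m in out) expect_true(all(m >= 0 & m <= 1))
})

test_that("guide tree merges the dominant pair first", {
  set.seed(63)
  s <- paste(sample(c("A", "C", "G", "U"), 20, TRUE), collapse = "")
  seqs <- sequence_set(list(rna_sequence("a", s), rna_sequence("b", s),
                            rna_sequence("c", paste(rev(strsplit(s, "")[[1]]),
                                                    collapse = ""))))
  cfg <- homofold_config(iterations = 0)
  st <- homofold_init(seqs, cfg)
  lens <- rep(20L, 3)
  tr <- consistency_transform(lapply(st$post, `[[`, "aligned"), lens)
  tree <- build_guide_tree(tr, lens)
  expect_equal(sort(c(tree$merges[[1]]$left, tree$merges[[1]]$right)),
               c(1L, 2L))
  # merge scores are non-increasing under average linkage
  scores <- vapply(tree$merges, `[[`, numeric(1), "score")
  expect_true(all(diff(scores) <= 1e-9))
})

test_that("two-clade families recover their generation topology", {
  fam <- generate_family(example_family_spec(seed = 64, n_seqs = 4,
                                             two_level = TRUE,
                                             sub_rate = 0.4,
                                             indel_rate = 0))
  cfg <- homofold_config(iterations = 0)
  st <- homofold_init(fam$seqs, cfg)
  lens <- vapply(fam$seqs$sequences, function(s) s$length, integer(1))
  tr <- consistency_transform(lapply(st$post, `[[`, "aligned"), lens)
  tree <- build_guide_tree(tr, lens)
  first_two <- lapply(tree$merges[1:2], function(m)
    sort(c(m$left, m$right)))
  expect_true(any(vapply(first_two, identical, logical(1), c(1L, 2L))))
  expect_true(any(vapply(first_two, identical, logical(1), c(3L, 4L))))
})

test_that("progressive alignment of identical sequences is gap-free", {
  seqs <- sequence_set(lapply(c("a", "b", "c"), function(id)
    rna_sequence(id, "GGCAAAAAGCCAA")))
  run <- homofold(seqs, homofold_config(iterations = 0))
  expect_false(any(grepl("-", run$alignment$rows, fixed = TRUE)))
  expect_equal(run$alignment$columns, 13L)
})

test_that("pairwise alignment follows a concentrated posterior register", {
  # posterior concentrated on aligning x[i] with y[i+2]
  P <- matrix(1e-6, 6, 8)
  for (i in 1:6) P[i, i + 2] <- 0.95
  out <- consistency_transform(list("1|2" = P), lens = c(6L, 8L),
                               sparsity = 0)
  tree <- build_guide_tree(out, c(6L, 8L))
  seqs <- sequence_set(list(rna_sequence("x", "ACGUAC"),
                            rna_sequence("y", "GGACGUAC")))
  msa <- progressive_align(tree, out, seqs)
  expect_equal(msa$rows[1], "--ACGUAC")
  expect_equal(msa$rows[2], "GGACGUAC")
})

test_that("alignment column counts respect their bounds", {
  fam <- small_family(seed = 65, n_seqs = 4)
  run <- homofold(fam$seqs, homofold_config(iterations = 1))
  lens <- vapply(fam$seqs$sequences, function(s) s$length, integer(1))
  expect_lte(run$alignment$columns, sum(lens))
  expect_gte(run$alignment$columns, max(lens))
  for (m in seq_along(lens))
    expect_equal(degap(run$alignment$rows[m]), fam$seqs[[m]]$residues)
})

test_that("joint estimation beats sequence-only alignment on a family", {
  fam <- small_family(seed = 66, n_seqs = 4, sub_rate = 0.4)
  full <- homofold(fam$seqs, homofold_config())
  base <- homofold(fam$seqs, homofold_config(iterations = 0))
  sens_full <- alignment_score(full$alignment, fam$alignment)$sensitivity
  sens_base <- alignment_score(base$alignment, fam$alignment)$sensitivity
  expect_gte(sens_full, sens_base - 0.02)
})
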