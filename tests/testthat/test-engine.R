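test_that("initialisation covers the degenerate and shape contracts", {
  cfg <- homofold_config()
  one <- sequence_set(list(rna_sequence("a", "GGGAAACCCAAA")))
  st <- homofold_init(one, cfg)
  expect_length(st$post, 0L)
  expect_equal(st$pairprobs[[1]]$p,
               pair_probabilities(one[[1]], cfg$energy_model)$p)

  twin <- sequence_set(list(rna_sequence("a", "GGGAAACCCAAA"),
                            rna_sequence("b", "GGGAAACCCAAA")))
  st <- homofold_init(twin, cfg)
  expect_equal(st$psi[1, 2], 1)

  set.seed(51)
  trio <- sequence_set(lapply(1:3, function(i) random_rna(30, paste0("s", i))))
  st <- homofold_init(trio, cfg)
  expect_length(st$pairprobs, 3L)
  expect_length(st$post, 3L) # pairs 1|2, 1|3, 2|3
  expect_equal(dim(st$post[["1|2"]]$coincidence), c(30L, 30L))

  short <- sequence_set(list(rna_sequence("a", "ACG")))
  expect_error(homofold_init(short, cfg), "at least 4 nt")
})

test_that("neutral coupling makes one iteration a fixed point", {
  set.seed(52)
  seqs <- sequence_set(lapply(1:3, function(i) random_rna(25, paste0("s", i))))
  cfg <- homofold_config(kappa = 0, match_params = match_score_params(0, 0, 1))
  st0 <- homofold_init(seqs, cfg)
  st1 <- iterate_once(st0, cfg)
  for (m in 1:3)
    expect_equal(st1$pairprobs[[m]]$p, st0$pairprobs[[m]]$p,
                 tolerance = 1e-14)
  for (key in names(st0$post)) {
    expect_equal(st1$post[[key]]$coincidence, st0$post[[key]]$coincidence,
                 tolerance = 1e-12)
    expect_equal(st1$post[[key]]$aligned, st0$post[[key]]$aligned,
                 tolerance = 1e-12)
  }
  expect_equal(st1$iteration, 1L)
})

test_that("an identical twin contributes zero extrinsic information", {
  seqs <- sequence_set(list(rna_sequence("a", "GGCGCAAAAAGCGCCAAA"),
                            rna_sequence("b", "GGCGCAAAAAGCGCCAAA")))
  cfg <- homofold_config()
  st <- homofold_init(seqs, cfg)
  st1 <- iterate_once(st, cfg)
  # psi = 1 zeroes the only proclivity, so folding stays intrinsic
  expect_equal(st1$pairprobs[[1]]$p, st$pairprobs[[1]]$p, tolerance = 1e-12)
})

test_that("the pipeline is deterministic end to end", {
  fam <- small_family(seed = 3, n_seqs = 3)
  cfg <- homofold_config(iterations = 2)
  a <- homofold(fam$seqs, cfg)
  b <- homofold(fam$seqs, cfg)
  expect_identical(a$alignment$rows, b$alignment$rows)
  expect_identical(lapply(a$structures, `[[`, "pairs"),
                   lapply(b$structures, `[[`, "pairs"))
  expect_identical(a$state$pairprobs[[1]]$p, b$state$pairprobs[[1]]$p)
})

test_that("zero iterations reduces to the single-pass pipeline", {
  fam <- small_family(seed = 4, n_seqs = 3)
  cfg <- homofold_config(iterations = 0)
  run <- homofold(fam$seqs, cfg)
  st <- homofold_init(fam$seqs, cfg)
  expect_equal(run$state$iteration, 0L)
  expect_identical(run$alignment$rows, compute_msa(st, cfg)$rows)
  expect_equal(run$structures[[1]]$pairs,
               mea_structure(st$pairprobs[[1]])$pairs)
})

test_that("full runs emit valid non-crossing canonical structures", {
  fam <- small_family(seed = 5, n_seqs = 4)
  run <- homofold(fam$seqs, homofold_config(iterations = 1))
  canon <- c("AU", "UA", "GC", "CG", "GU", "UG")
  for (m in seq_along(run$structures)) {
    s <- run$structures[[m]]
    expect_false(homofold:::pairs_cross(s$pairs))
    res <- strsplit(fam$seqs[[m]]$residues, "")[[1]]
    if (nrow(s$pairs))
      expect_true(all(paste0(res[s$pairs[, 1]], res[s$pairs[, 2]]) %in%
                        canon))
  }
  # alignment rows de-gap to the inputs, in input order
  for (m in seq_along(fam$seqs$sequences))
    expect_equal(degap(run$alignment$rows[m]), fam$seqs[[m]]$residues)
})

test_that("threshold mode emits only pairs above the threshold", {
  fam <- small_family(seed = 6, n_seqs = 3)
  run <- homofold(fam$seqs, homofold_config(iterations = 1,
                                          mode = "threshold",
                                          threshold = 0.5))
  for (m in seq_along(run$structures)) {
    s <- run$structures[[m]]
    if (nrow(s$pairs))
      expect_true(all(run$state$pairprobs[[m]]$p[s$pairs] > 0.5))
  }
})
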