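test_that("posteriors match exhaustive path enumeration on short pairs", {
  set.seed(11)
  for (trial in 1:6) {
    params <- if (trial <= 3) random_hmm_params() else
      default_hmm_parameters()
    x <- random_rna(sample(2:5, 1), "x")
    y <- random_rna(sample(2:5, 1), "y")
    rho <- if (trial %% 2 == 0)
      matrix(runif(x$length * y$length, 0.2, 3), x$length, y$length)
    else NULL
    o <- hmm_path_oracle(x, y, params, rho)
    r <- compute_posteriors(x, y, params, rho = rho, identity = FALSE)
    expect_lt(max(abs(o$coincidence - r$coincidence)), 1e-9)
    expect_lt(max(abs(o$aligned - r$aligned)), 1e-9)
    expect_lt(abs(log(o$Z) - r$logZ), 1e-9)
  }
})

test_that("swapping the sequences transposes the posteriors", {
  set.seed(12)
  x <- random_rna(8, "x"); y <- random_rna(6, "y")
  p <- default_hmm_parameters() # symmetric tables
  a <- compute_posteriors(x, y, p)
  b <- compute_posteriors(y, x, p)
  expect_equal(a$coincidence, t(b$coincidence), tolerance = 1e-12)
  expect_equal(a$aligned, t(b$aligned), tolerance = 1e-12)
  expect_equal(a$identity, b$identity)
})

test_that("a constant rho of 1 reproduces the no-prior posteriors", {
  set.seed(13)
  x <- random_rna(10, "x"); y <- random_rna(9, "y")
  p <- default_hmm_parameters()
  a <- compute_posteriors(x, y, p)
  b <- compute_posteriors(x, y, p,
                          rho = matrix(1, x$length, y$length))
  expect_equal(a$coincidence, b$coincidence, tolerance = 1e-14)
  expect_equal(a$aligned, b$aligned, tolerance = 1e-14)
})

test_that("a strong match-score prior pulls posterior mass to its cell", {
  set.seed(14)
  x <- random_rna(7, "x"); y <- random_rna(7, "y")
  p <- default_hmm_parameters()
  base <- compute_posteriors(x, y, p)
  rho <- matrix(1, 7, 7)
  rho[3, 4] <- 1e6
  boosted <- compute_posteriors(x, y, p, rho = rho)
  expect_gt(boosted$aligned[3, 4], base$aligned[3, 4])
  expect_gt(boosted$aligned[3, 4], 0.99)
})

test_that("posterior invariants hold on random inputs", {
  set.seed(15)
  for (trial in 1:5) {
    x <- random_rna(sample(10:40, 1), "x")
    y <- random_rna(sample(10:40, 1), "y")
    r <- compute_posteriors(x, y, default_hmm_parameters())
    expect_true(all(r$coincidence >= 0 & r$coincidence <= 1))
    expect_true(all(r$aligned <= r$coincidence + 1e-9))
    expect_true(all(rowSums(r$aligned) <= 1 + 1e-9))
    expect_true(all(colSums(r$aligned) <= 1 + 1e-9))
  }
})

test_that("forward-backward stays finite for kilobase sequences", {
  set.seed(16)
  x <- random_rna(1000, "x")
  y <- random_rna(950, "y")
  r <- compute_posteriors(x, y, default_hmm_parameters(), identity = FALSE)
  expect_true(all(is.finite(r$coincidence)))
  expect_true(all(is.finite(r$aligned)))
  expect_true(is.finite(r$logZ))
  expect_gt(max(r$aligned), 0)
})

test_that("pairwise identity follows the decoded-alignment definition", {
  p <- default_hmm_parameters()
  x <- rna_sequence("x", "ACGUACGUAC")
  same <- compute_posteriors(x, rna_sequence("y", x$residues), p)
  expect_equal(same$identity, 1)

  a <- rna_sequence("a", "AAAA")
  c4 <- rna_sequence("c", "CCCC")
  expect_equal(compute_posteriors(a, c4, p)$identity, 0)

  # one mismatch, gap-free decode: 3 identical / 4 columns
  u <- rna_sequence("u", "ACGU")
  v <- rna_sequence("v", "ACGA")
  expect_equal(compute_posteriors(u, v, p)$identity, 0.75)
})

test_that("degenerate parameters raise an error rather than NaN", {
  tr <- matrix(c(0, 1, 0,
                 0, 1, 0,
                 0, 1, 0), 3, 3, byrow = TRUE) # can never emit y
  ep <- matrix(1 / 16, 4, 4)
  pars <- hmm_parameters(tr, ep, rep(0.25, 4))
  x <- rna_sequence("x", "ACGU")
  y <- rna_sequence("y", "ACGU")
  expect_error(compute_posteriors(x, y, pars), "zero total path weight")
})
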