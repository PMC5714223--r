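test_that("pairing-state profiles are the row/column sums", {
  z <- pair_probability_matrix(matrix(0, 6, 6))
  pr <- pairing_state_profile(z)
  expect_equal(pr$p_unpaired, rep(1, 6))

  m <- matrix(0, 6, 6); m[1, 5] <- 1
  pr <- pairing_state_profile(pair_probability_matrix(m))
  expect_equal(pr$p_down[1], 1)
  expect_equal(pr$p_up[5], 1)
  expect_equal(pr$p_unpaired[c(1, 5)], c(0, 0))

  s <- rna_sequence("h", "GGGAAACCC")
  p <- enumerate_structures_oracle(s)
  pr <- pairing_state_profile(p)
  expect_equal(pr$p_down, rowSums(p$p))
  expect_equal(pr$p_up, colSums(p$p))
  expect_equal(pr$p_down + pr$p_up + pr$p_unpaired, rep(1, 9),
               tolerance = 1e-9)
})

test_that("match score reproduces its closed form and special cases", {
  unpaired <- structure(list(p_down = 0, p_up = 0, p_unpaired = 1),
                        class = "pairing_state_profile")
  down <- structure(list(p_down = 1, p_up = 0, p_unpaired = 0),
                    class = "pairing_state_profile")
  up <- structure(list(p_down = 0, p_up = 1, p_unpaired = 0),
                  class = "pairing_state_profile")
  d <- default_match_params()
  # both unpaired under the defaults: alpha2 * 1 + alpha3
  expect_equal(match_score_matrix(unpaired, unpaired, d)[1, 1], 1.3)
  # opposite pairing directions: only the offset survives
  expect_equal(match_score_matrix(down, up, d)[1, 1], 0.5)
  # PMcomp-style weights (1, 1, 0): perfect agreement scores 1
  pm <- match_score_params(1, 1, 0)
  expect_equal(match_score_matrix(down, down, pm)[1, 1], 1)
  expect_equal(match_score_matrix(unpaired, unpaired, pm)[1, 1], 1)
  expect_equal(match_score_matrix(down, up, pm)[1, 1], 0)
})

test_that("match scores stay inside their analytic bounds", {
  set.seed(31)
  d <- default_match_params()
  lo <- d$alpha3
  hi <- max(d$alpha1, d$alpha2) + d$alpha3
  for (rep in 1:20) {
    n <- sample(3:20, 1)
    mk <- function(n) {
      a <- matrix(runif(3 * n), 3)
      a <- a / rep(colSums(a), each = 3)
      structure(list(p_down = a[1, ], p_up = a[2, ], p_unpaired = a[3, ]),
                class = "pairing_state_profile")
    }
    rho <- match_score_matrix(mk(n), mk(n + 2), d)
    expect_true(all(rho >= lo - 1e-12))
    expect_true(all(rho <= hi + 1e-9))
  }
})

test_that("proclivity maps pairs through co-incidence posteriors", {
  # single certain pair, certain co-incidence: proclivity 1 at (i, j)
  pn <- matrix(0, 6, 6); pn[2, 6] <- 1
  co <- matrix(0, 5, 6)
  co[1, 2] <- 1 # i = 1 ~ k = 2
  co[4, 6] <- 1 # j = 4 ~ l = 6
  post <- structure(list(coincidence = co, aligned = co, identity = 0.5),
                    class = "coincidence_posteriors")
  out <- proclivity(pair_probability_matrix(pn), post, cutoff = 0.01)
  expect_equal(out[1, 4], 1)
  expect_equal(sum(out), 1)

  # all co-incidence below the cutoff: empty candidate sets, zero matrix
  post_lo <- structure(list(coincidence = co * 0.001, aligned = co * 0.001,
                            identity = 0.5),
                       class = "coincidence_posteriors")
  expect_equal(sum(proclivity(pair_probability_matrix(pn), post_lo,
                              cutoff = 0.01)), 0)
})

test_that("cutoff-free proclivity equals the direct triple sum", {
  set.seed(32)
  nm <- 7; nn <- 8
  pn <- matrix(0, nn, nn)
  pn[upper.tri(pn)] <- runif(nn * (nn - 1) / 2, 0, 0.2)
  pn[, ] <- pn / 2
  co <- matrix(runif(nm * nn), nm, nn)
  post <- structure(list(coincidence = co, aligned = co, identity = 0.5),
                    class = "coincidence_posteriors")
  got <- proclivity(pair_probability_matrix(pn), post, cutoff = 0)
  want <- matrix(0, nm, nm)
  for (i in seq_len(nm)) for (j in seq_len(nm)) {
    if (j <= i) next
    for (k in seq_len(nn)) for (l in seq_len(nn)) {
      if (l <= k) next
      want[i, j] <- want[i, j] + pn[k, l] * co[i, k] * co[j, l]
    }
  }
  expect_equal(got, want, tolerance = 1e-12)

  # the 0.01 cutoff is an approximation with a bounded effect
  got01 <- proclivity(pair_probability_matrix(pn), post, cutoff = 0.01)
  expect_lte(sum(abs(got - got01)), 0.01 * nm * nm)
})

test_that("extrinsic information weights, normalises and degenerates", {
  # identical sequences (psi = 1) contribute nothing
  z <- extrinsic_information(list(matrix(5, 4, 4)), identities = 1)
  expect_equal(max(z$p), 0)
  expect_true(is.na(z$alpha))

  # single entry v > 0 with psi = 0.4 normalises to exactly 1
  m <- matrix(0, 4, 4); m[1, 4] <- 0.7
  e <- extrinsic_information(list(m), identities = 0.4)
  expect_equal(e$p[1, 4], 1)
  expect_equal(e$alpha, 1 / (0.6 * 0.7))

  # three-sequence weighted sum against a direct evaluation
  m1 <- matrix(0, 3, 3); m1[1, 3] <- 0.5; m1[1, 2] <- 0.2
  m2 <- matrix(0, 3, 3); m2[1, 3] <- 0.1; m2[2, 3] <- 0.9
  e <- extrinsic_information(list(m1, m2), identities = c(0.3, 0.6))
  want <- 0.7 * m1 + 0.4 * m2
  expect_equal(e$p, want / max(want), tolerance = 1e-12)

  # permutation of the non-target sequences leaves the result unchanged
  e2 <- extrinsic_information(list(m2, m1), identities = c(0.6, 0.3))
  expect_equal(e$p, e2$p)
})
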