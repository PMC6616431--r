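test_that("AHP recovers weights from consistent matrices", {
  m3 <- matrix(1, 3, 3)
  r <- ahp_weights(m3)
  expect_equal(r$weights, rep(1 / 3, 3))
  expect_equal(r$cr, 0, tolerance = 1e-10)
  w <- c(0.5, 0.3, 0.2)
  rc <- ahp_weights(consistent_matrix(w))
  expect_equal(rc$weights, w, tolerance = 1e-10)
  expect_equal(rc$cr, 0, tolerance = 1e-10)
})

test_that("consistency ratio agrees with an independent eigen analysis", {
  set.seed(61)
  for (rep in 1:5) {
    w <- runif(7); w <- w / sum(w)
    m <- consistent_matrix(w)
    for (i in 1:6) for (j in (i + 1):7) {
      m[i, j] <- m[i, j] * exp(rnorm(1, 0, 0.2))
      m[j, i] <- 1 / m[i, j]
    }
    r <- ahp_weights(m)
    lambda <- max(Re(eigen(m, only.values = TRUE)$values))
    ri <- c(0, 0, 0.58, 0.90, 1.12, 1.24, 1.32, 1.41, 1.45, 1.49)[7]
    expect_equal(r$cr, ((lambda - 7) / 6) / ri, tolerance = 1e-8)
  }
})

test_that("AHP rejects malformed matrices", {
  m <- consistent_matrix(c(0.5, 0.3, 0.2))
  m[1, 2] <- 5
  expect_error(ahp_weights(m), "reciprocal")
  expect_error(ahp_weights(matrix(1, 2, 2)), "3x3 to 10x10")
})

test_that("consistency screening keeps only acceptable experts", {
  w <- c(0.20, 0.10, 0.24, 0.09, 0.05, 0.22, 0.10)
  clean <- generate_expert_matrices(15, w, noise = 0, seed = 62)
  acc <- screen_experts(clean)
  expect_equal(nrow(acc), 15)
  # one wildly inconsistent matrix among consistent ones is rejected alone
  bad <- consistent_matrix(w)
  bad[1, 2] <- 9; bad[2, 1] <- 1 / 9
  bad[2, 3] <- 9; bad[3, 2] <- 1 / 9
  bad[1, 3] <- 1 / 9; bad[3, 1] <- 9
  expect_gt(ahp_weights(bad)$cr, 0.1)
  acc2 <- screen_experts(c(clean[1:4], list(bad)))
  expect_equal(nrow(acc2), 4)
  expect_error(screen_experts(list(bad)), "no expert matrix passed")
})

test_that("screening with calibrated noise emulates a 15-to-11 intake", {
  # moderate noise leaves most but not all experts under CR < 0.1
  mats <- generate_expert_matrices(15,
    c(0.20, 0.10, 0.24, 0.09, 0.05, 0.22, 0.10), noise = 0.55, seed = 63)
  acc <- screen_experts(mats)
  expect_gt(nrow(acc), 5)
  expect_lt(nrow(acc), 15)
})

test_that("degenerate pools return the common weights exactly", {
  w <- c(PD = 0.20, LFI = 0.10, NDVI = 0.24, LDI = 0.09, APAI = 0.05,
         ESV = 0.22, ER = 0.10)
  acc <- matrix(rep(w, each = 11), 11, 7,
                dimnames = list(NULL, names(w)))
  mc <- monte_carlo_weights(acc, seed = 64)
  expect_equal(mc$weights$weights, w)
  expect_true(all(mc$stability$ehi_sd == 0))
})

test_that("simulated weight vectors are normalized and reproducible", {
  set.seed(65)
  acc <- matrix(abs(rnorm(11 * 7, 0.14, 0.05)), 11, 7)
  acc <- acc / rowSums(acc)
  mc1 <- monte_carlo_weights(acc, pool_size = 2000, sample_sizes = c(8, 50),
                             reps = 20, seed = 66)
  mc2 <- monte_carlo_weights(acc, pool_size = 2000, sample_sizes = c(8, 50),
                             reps = 20, seed = 66)
  expect_identical(mc1, mc2)
  expect_equal(sum(mc1$weights$weights), 1, tolerance = 1e-12)
})

test_that("EHI dispersion shrinks as the sample capacity grows", {
  w <- c(0.20, 0.10, 0.24, 0.09, 0.05, 0.22, 0.10)
  acc <- screen_experts(generate_expert_matrices(11, w, noise = 0.25,
                                                 seed = 67))
  mc <- monte_carlo_weights(acc, pool_size = 5000,
                            sample_sizes = seq(8, 400, by = 8),
                            reps = 100, seed = 68)
  s <- mc$stability
  # stabilization: dispersion at large N well below dispersion at small N
  expect_lt(mean(s$ehi_sd[s$n >= 200]), mean(s$ehi_sd[s$n <= 24]))
  # monotone decreasing trend overall
  expect_lt(coef(lm(ehi_sd ~ n, s))[2], 0)
})

test_that("small-noise elicitation recovers the underlying weights", {
  w <- c(PD = 0.20, LFI = 0.10, NDVI = 0.24, LDI = 0.09, APAI = 0.05,
         ESV = 0.22, ER = 0.10)
  mats <- generate_expert_matrices(15, w, noise = 0.1, seed = 69)
  acc <- screen_experts(mats)
  colnames(acc) <- names(w)
  mc <- monte_carlo_weights(acc, pool_size = 5000, sample_sizes = c(50, 200),
                            reps = 50, final_capacity = 200, seed = 70)
  expect_lt(max(abs(mc$weights$weights - w)), 0.02)
})

test_that("weight sets enforce the dimension structure", {
  dw <- default_weights()
  expect_equal(unname(dw$dimension_weights["pressure"]), 0.3)
  expect_equal(unname(dw$dimension_weights["state"]), 0.7)
  expect_equal(sum(dw$weights), 1)
  expect_error(weight_set(c(PD = 1)), "missing indicator")
  expect_error(weight_set(c(PD = 0.5, LFI = 0.1, NDVI = 0.24, LDI = 0.09,
                            APAI = 0.05, ESV = 0.22, ER = 0.10)),
               "sum to 1")
})
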