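test_that("sign-flip Monte-Carlo p-values match exhaustive enumeration", {
  set.seed(5)
  arr <- array(rnorm(8 * 3 * 6, sd = 1) + 0.45, dim = c(8, 3, 6))
  p_exact <- enumerate_signflip_p(arr)
  stream <- signflip_surrogates(arr, n_surrogates = 4000, seed = 2)
  ms <- stepdown_maxstat(stream, alpha = 0)   # no masking: single-iteration p
  p_mc <- as.vector(ms$p_values)
  # binomial error on p ~ sqrt(p(1-p)/n); allow 4 sigma
  tol <- 4 * sqrt(pmax(p_exact * (1 - p_exact), 0.25 / 4000) / 4000) + 1 / 4000
  expect_true(all(abs(p_mc - p_exact) <= tol + 0.25 / sqrt(4000)))
})

test_that("all-positive flips reproduce the observed map; flips shared across channels", {
  set.seed(1)
  arr <- array(rnorm(6 * 4 * 5), dim = c(6, 4, 5))
  stream <- signflip_surrogates(arr, n_surrogates = 50, seed = 3)
  M <- matrix(arr, nrow = 6)
  expect_equal(stream$observed, abs(colMeans(M)))
  expect_equal(stream$map_dim, c(4, 5))
})

test_that("step-down recovers a masked second element (constructed two-element case)", {
  # element 1 huge, element 2 moderate: with 8 units the exact max-null is
  # enumerable (p floor 2/256); element 2 only reaches significance once
  # element 1 is masked off the maximum
  set.seed(4)
  units <- cbind(10 + rnorm(8, sd = 0.3), 2 + rnorm(8, sd = 0.1))
  arr <- array(units, dim = c(8, 1, 2))
  # exact enumeration of the max statistic over both elements / element 2 only
  flips <- as.matrix(expand.grid(rep(list(c(-1, 1)), 8)))
  both <- apply(abs(flips %*% units) / 8, 1, max)
  el2 <- abs(flips %*% units[, 2]) / 8
  obs <- abs(colMeans(units))
  p1_both <- mean(both >= obs[2])       # element 2 vs max over both: not sig
  p1_el2 <- mean(el2 >= obs[2])         # element 2 alone: significant
  expect_gt(p1_both, 0.05)
  expect_lt(p1_el2, 0.05)               # exact 2/256

  stream <- signflip_surrogates(arr, n_surrogates = 4000, seed = 9)
  ms <- stepdown_maxstat(stream, alpha = 0.05)
  expect_true(ms$significant[1, 1])
  expect_true(ms$significant[1, 2])
  expect_gte(ms$iterations, 2)

  # step-down finds a superset of the single-step significances
  single <- stream$observed > quantile(stream$max_stat(1:2), 0.95)
  expect_true(all(which(single) %in% which(as.vector(ms$significant))))
})

test_that("all-zero observed maps yield nothing significant and p near 1", {
  arr <- array(0, dim = c(5, 2, 3))
  arr[, , ] <- rnorm(30) * 1e-18
  arr2 <- array(0, dim = c(5, 2, 3))
  stream <- signflip_surrogates(arr2, n_surrogates = 200, seed = 1)
  ms <- stepdown_maxstat(stream)
  expect_false(any(ms$significant))
  expect_true(all(ms$p_values == 1))
})

test_that("phase surrogates preserve per-epoch magnitude spectra exactly", {
  cfg <- fast_sim(duration = 60, sampling_rate = 120)
  rec <- generate_oddball_recording(cfg, tiny_array())
  fe <- oddball_epochs(rec)
  # a surrogate multiplies each epoch-bin coefficient by a unit phase:
  # reconstruct one surrogate by hand and compare magnitudes
  ph <- opmpipe:::phase_factors(3, fe$n_epochs, seed = 4, tag = "p1b61")
  for (s in 1:3) {
    surr <- fe$coef[, 1, 61] * ph[s, ]
    expect_equal(Mod(surr), Mod(fe$coef[, 1, 61]), tolerance = 1e-12)
  }

  # single epoch: SNR map is invariant under any phase draw
  fe1 <- fe
  fe1$coef <- fe$coef[1, , , drop = FALSE]
  fe1$n_epochs <- 1L
  st1 <- phase_surrogates(fe1, n_surrogates = 30, seed = 6)
  mx <- st1$max_stat(seq_along(st1$observed))
  expect_equal(mx, rep(max(st1$observed), 30), tolerance = 1e-9)
})

test_that("coherent lines collapse to the analytic incoherent level under phase randomization", {
  # n identical epochs with a coherent coefficient c: surrogate average power
  # E|mean(c e^{i theta})|^2 = |c|^2 / n, vs |c|^2 coherent
  n_ep <- 12
  nch <- 3
  coefs <- array(complex(real = 0), dim = c(n_ep, nch, 101))
  freq <- seq(0, 5, by = 0.05)
  i3 <- which.min(abs(freq - 3))
  coefs[, , ] <- complex(real = rnorm(length(coefs), sd = 0.2),
                         imaginary = rnorm(length(coefs), sd = 0.2))
  coefs[, , i3] <- 2 + 0i
  fe <- structure(list(coef = coefs, freq = freq, n_epochs = n_ep,
                       epoch_length = 20,
                       channels = tiny_array()[1:nch, ]),
                  class = "opm_fourier")
  ph <- opmpipe:::phase_factors(2000, n_ep, seed = 3, tag = sprintf("p1b%d", i3))
  surr_pow <- Mod(ph %*% coefs[, 1, i3] / n_ep)^2
  expect_equal(mean(surr_pow), Mod(2)^2 / n_ep, tolerance = 0.1)
  # and the observed coherent power is n times larger
  expect_equal(Mod(mean(coefs[, 1, i3]))^2 / mean(surr_pow), n_ep,
               tolerance = 0.15 * n_ep)
})

test_that("noise-only SNR is a typical draw from its phase-surrogate null", {
  set.seed(12)
  ks_ps <- vapply(1:5, function(s) {
    n_ep <- 10; nch <- 4
    freq <- seq(0, 5, by = 0.05)
    coefs <- array(complex(real = rnorm(n_ep * nch * 101),
                           imaginary = rnorm(n_ep * nch * 101)),
                   dim = c(n_ep, nch, 101))
    fe <- structure(list(coef = coefs, freq = freq, n_epochs = n_ep,
                         epoch_length = 20, channels = tiny_array()[1:nch, ]),
                    class = "opm_fourier")
    st <- phase_surrogates(fe, n_surrogates = 300, seed = 40 + s)
    mx <- st$max_stat(seq_along(st$observed))
    mean(mx >= max(st$observed))     # observed max should not be extreme
  }, numeric(1))
  expect_gt(max(ks_ps), 0.05)
  expect_gt(mean(ks_ps > 0.01), 0.6)
})

test_that("normality gate selects the right test and handles degenerate input", {
  a <- c(1, 2, 3, 4, 5)
  same <- compare_samples(a, a, paired = TRUE)
  expect_equal(same$p_value, 1)
  expect_equal(same$statistic, 0)

  # normal shift: paired t detects it
  set.seed(2)
  x <- rnorm(12); y <- x + 1 + rnorm(12, sd = 0.3)
  cmp <- compare_samples(y, x, paired = TRUE)
  expect_equal(cmp$test, "paired-t")
  expect_lt(cmp$p_value, 0.01)
  expect_equal(cmp$direction, 1)

  # grossly heavy-tailed differences (outlier contamination) push the gate
  # to the signed-rank test
  picks <- vapply(1:40, function(s) {
    set.seed(1000 + s)
    d <- rnorm(10)
    d[1] <- 25 * sign(rnorm(1))
    compare_samples(d + 5, rep(5, 10), paired = TRUE)$test
  }, character(1))
  expect_gte(mean(picks == "wilcoxon-signed-rank"), 0.9)

  # unpaired path
  u <- compare_samples(rnorm(10, 1), rnorm(12), paired = FALSE)
  expect_true(u$test %in% c("unpaired-t", "rank-sum"))
})

test_that("correlation: identity, orthogonality, hand case", {
  x <- c(0, 1, 2)
  expect_equal(correlate_samples(x, x)$r, 1)
  a <- c(1, -1, 1, -1); b <- c(1, 1, -1, -1)
  expect_equal(correlate_samples(a, b)$r, 0)
  set.seed(3)
  z <- rnorm(20)
  expect_equal(correlate_samples(z, 3 * z + 2)$r, 1, tolerance = 1e-12)
})

test_that("seeded surrogate streams are bit-reproducible", {
  arr <- array(rnorm(6 * 3 * 4), dim = c(6, 3, 4))
  s1 <- signflip_surrogates(arr, 100, seed = 7)
  s2 <- signflip_surrogates(arr, 100, seed = 7)
  expect_identical(s1$max_stat(1:12), s2$max_stat(1:12))
  r1 <- stepdown_maxstat(s1)
  r2 <- stepdown_maxstat(s2)
  expect_identical(r1$p_values, r2$p_values)
  expect_identical(r1$thresholds, r2$thresholds)
})
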