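test_that("toy base concentrations follow the declared grid and kinetics", {
  base <- toy_base_concentrations()
  expect_equal(nrow(base), 20)
  expect_equal(base$time[1], 0)
  expect_equal(base$time[20], 15)
  expect_equal(diff(base$time), rep(15 / 19, 19))
  expect_true(all(as.matrix(base[-1]) >= 0))
  # at t = 0 every curve sits at its baseline offset
  tk <- toy_kinetics()
  expect_equal(unname(unlist(base[1, -1])), tk$d)
  expect_equal(base$caffeine[1], 0)
})

test_that("sampled volumes respect truncation and the configured distribution", {
  v <- sample_volumes(2000, seed = 141)
  expect_true(all(v >= 0.05 & v <= 4))
  expect_identical(v, sample_volumes(2000, seed = 141))
  expect_false(identical(v[1:10], sample_volumes(10, seed = 142)))

  # moments of log-draws against the closed-form truncated-normal oracle
  mu <- log(0.3); s <- log(2.5)
  a <- (log(0.05) - mu) / s; b <- (log(4) - mu) / s
  Z <- pnorm(b) - pnorm(a)
  m_or <- mu + s * (dnorm(a) - dnorm(b)) / Z
  v_or <- s^2 * (1 + (a * dnorm(a) - b * dnorm(b)) / Z -
                   ((dnorm(a) - dnorm(b)) / Z)^2)
  big <- sample_volumes(1e5, seed = 143)
  expect_equal(mean(log(big)), m_or, tolerance = 0.02 * abs(m_or))
  expect_equal(sd(log(big)), sqrt(v_or), tolerance = 0.02)
})

test_that("simulation v1 draws kinetics within bounds and composes masses exactly", {
  ds <- simulate_v1(n_metabolites = 12, n_timepoints = 10, cv = 0.2, seed = 151)
  expect_equal(dim(ds$concentrations), c(10, 12))
  k <- ds$kinetics[-(1:4), ]
  expect_true(all(k$k_a >= 0 & k$k_a <= 3))
  expect_true(all(k$k_e >= 0 & k$k_e <= 3))
  expect_true(all(k$c0 >= 0 & k$c0 <= 5))
  expect_true(all(k$lag >= 0 & k$lag <= 15))
  expect_true(all(k$d >= 0 & k$d <= 3))

  # bit-identical reconstruction from stored ground-truth components
  M <- ds$concentrations * ds$epsilon
  M[, !ds$noise_mask] <- M[, !ds$noise_mask] * ds$volumes
  expect_identical(unname(as.matrix(ds$data[-1])), unname(M))

  # determinism
  expect_identical(ds$data, simulate_v1(12, 10, 0.2, seed = 151)$data)

  # toy-only data set has no appended columns
  ds4 <- simulate_v1(n_metabolites = 4, seed = 152)
  expect_equal(ncol(ds4$data), 5)

  # degenerate case: no error, constant volume => masses proportional to C
  ds0 <- simulate_v1(6, 8, cv = 0, seed = 153,
                     volume_args = list(meanlog = log(1), sdlog = 1e-12,
                                        lower = 0.999, upper = 1.001))
  pos <- ds0$concentrations > 0
  ratio <- unname(as.matrix(ds0$data[-1]))[pos] / ds0$concentrations[pos]
  expect_equal(ratio, rep(ds0$volumes[1], sum(pos)), tolerance = 1e-3)
})

test_that("simulation v2 appends strictly positive random profiles", {
  ds <- simulate_v2(n_metabolites = 30, n_timepoints = 200, cv = 0.2, seed = 161)
  newC <- ds$concentrations[, -(1:4)]
  expect_true(all(newC > 0))
  # profiles are i.i.d. per time point: no systematic time trend
  trends <- apply(newC, 2, function(x) abs(cor(x, seq_along(x))))
  expect_lt(median(trends), 0.2)

  # degenerate meta-distribution: all columns share identical moments
  meta0 <- list(mean_meanlog = log(2), mean_sdlog = 0,
                sd_meanlog = log(0.5), sd_sdlog = 0)
  dsd <- simulate_v2(n_metabolites = 20, n_timepoints = 2000, cv = 0,
                     seed = 162, meta = meta0)
  mns <- colMeans(dsd$concentrations[, -(1:4)])
  sds <- apply(dsd$concentrations[, -(1:4)], 2, sd)
  expect_equal(unname(mns), rep(2, 16), tolerance = 0.1)
  expect_equal(unname(sds), rep(0.5, 16), tolerance = 0.15)
})

test_that("simulation v3 resamples ground-truth columns without replacement", {
  gt <- synthetic_ground_truth(n_metabolites = 40, n_timepoints = 10)
  ds <- simulate_v3(n_metabolites = 20, n_timepoints = 10, cv = 0.2,
                    seed = 171, ground_truth = gt)
  gtm <- as.matrix(gt[-1])
  # appended columns are exact copies of distinct source columns (pre-noise)
  appended <- ds$concentrations[, -(1:4)]
  src <- apply(appended, 2, function(col) {
    hits <- which(colSums(abs(gtm - col)) < 1e-12)
    expect_length(hits, 1)
    hits
  })
  expect_false(anyDuplicated(src) > 0)

  # different seeds pick different subsets almost surely
  ds2 <- simulate_v3(20, 10, 0.2, seed = 172, ground_truth = gt)
  expect_false(identical(ds$concentrations, ds2$concentrations))

  expect_error(simulate_v3(60, 10, ground_truth = gt), "pool")
})

test_that("noise fraction flags only untargeted columns and recomposes masses", {
  ds <- simulate_v3(n_metabolites = 100, n_timepoints = 10, cv = 0.2, seed = 181)
  expect_identical(apply_noise_fraction(ds, 0), ds)

  noisy <- apply_noise_fraction(ds, 0.95)
  expect_equal(sum(noisy$noise_mask), 95)
  expect_false(any(noisy$noise_mask[1:4]))

  # noise columns: volume factor absent; others unchanged
  M <- noisy$concentrations * noisy$epsilon
  M[, !noisy$noise_mask] <- M[, !noisy$noise_mask] * noisy$volumes
  expect_identical(unname(as.matrix(noisy$data[-1])), unname(M))
  same <- !noisy$noise_mask
  expect_identical(as.matrix(noisy$data[-1])[, same],
                   as.matrix(ds$data[-1])[, same])

  # realized fraction is round(f_n * n) / n
  n50 <- apply_noise_fraction(ds, 0.333)
  expect_equal(sum(n50$noise_mask), round(0.333 * 100))

  # impossible fractions are rejected
  small <- simulate_v1(n_metabolites = 5, n_timepoints = 6, seed = 182)
  expect_error(apply_noise_fraction(small, 0.9), "targeted")
  expect_error(apply_noise_fraction(ds, 0.99), "0.95")
})

test_that("PQN quotient spread shrinks as the noise fraction grows", {
  f_grid <- c(0, 0.25, 0.5, 0.75, 0.95)
  cv_mean <- vapply(f_grid, function(fn) {
    cvs <- vapply(1:8, function(r) {
      ds <- simulate_v3(n_metabolites = 100, n_timepoints = 20, cv = 0.2,
                        seed = 190 + r)
      if (fn > 0) ds <- apply_noise_fraction(ds, fn)
      q <- pqn_quotients(ds$data)$quotient
      sd(q) / mean(q)
    }, numeric(1))
    mean(cvs)
  }, numeric(1))
  expect_true(all(diff(cv_mean) < 0))
})
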