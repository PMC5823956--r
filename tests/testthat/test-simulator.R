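test_that("spike generation follows the Poisson law and the epoch doubling", {
  expect_true(all(poisson_spikes(0, 10, 0.01) == 0))

  set.seed(101)
  totals <- replicate(200, sum(poisson_spikes(0.5, 120, 0.01,
                                              modulation = FALSE)))
  expect_lt(abs(mean(totals) - 60), 2)

  # epoch doubling: empirical on/off rate ratio near 2
  set.seed(102)
  on <- neuropil:::stimulus_on((seq_len(12000) - 1) * 0.01, 15)
  counts <- rowSums(replicate(400, poisson_spikes(2, 120, 0.01)))
  ratio <- mean(counts[on]) / mean(counts[!on])
  expect_lt(abs(ratio - 2), 0.1)
})

test_that("calcium dynamics match the closed-form impulse response", {
  ind <- indicator_params("gcamp6f")
  dt <- 0.01
  s <- c(1, rep(0, 1999))
  cc <- calcium_dynamics(s, ind, dt)
  t <- (seq_along(s) - 1) * dt
  expect_lt(max(abs(cc - (exp(-t / ind$tau_d) - exp(-t / ind$tau_r)))),
            1e-9)
  # peak time of the difference of exponentials
  tpk <- ind$tau_r * ind$tau_d / (ind$tau_d - ind$tau_r) *
    log(ind$tau_d / ind$tau_r)
  expect_equal(tpk, 0.0619, tolerance = 1e-2)
  expect_lt(abs((which.max(cc) - 1) * dt - tpk), dt)

  # superposition: two spikes equal the sum of shifted single responses
  s2 <- rep(0, 2000); s2[1] <- 1; s2[301] <- 1
  c2 <- calcium_dynamics(s2, ind, dt)
  expect_equal(c2, cc + c(rep(0, 300), cc[1:1700]), tolerance = 1e-12)

  expect_error(calcium_dynamics(s, ind, dt = 0.02), "rise time")
})

test_that("indicator nonlinearity saturates at the closed-form c_max", {
  ind <- indicator_params("gcamp6f", amplitude = 0.3)
  expect_equal(ind$c_max, 94.536, tolerance = 1e-4)
  expect_gt(indicator_params("gcamp6s")$c_max, 0)
  expect_equal(indicator_response(0, ind), 0)
  # the bracket reduces to d at d = 1
  expect_equal(indicator_response(1, ind), 0.3)
  # saturation: response flat beyond c_max
  expect_equal(indicator_response(ind$c_max + 50, ind),
               indicator_response(ind$c_max, ind))
  expect_error(indicator_params(p3 = 0), "undefined")
})

test_that("cell kernels are normalised doughnuts matching per-pixel evaluation", {
  spec <- cell_spec(centre = c(0, 0), sigma2 = 50)
  k <- cell_kernel(spec, c(80, 80))
  expect_equal(max(k), 1)
  # radial symmetry at rho = 0
  expect_lt(max(abs(k - t(k))), 1e-12)

  # oracle: direct per-pixel evaluation of the doughnut + soma step
  hh <- 80
  ora <- matrix(0, hh, hh)
  for (r in 1:hh) for (cc in 1:hh) {
    x <- cc - 1 - (hh - 1) / 2; y <- r - 1 - (hh - 1) / 2
    q <- (x^2 + y^2) / 50
    ora[r, cc] <- exp(-q / 2) - exp(-q)
  }
  ora <- ora / max(ora)
  ora <- ora + 0.2 * (ora > 0.5)
  ora <- ora / max(ora)
  expect_equal(k, ora, tolerance = 1e-12)

  # super-threshold region is an annulus (has a hole)
  msk <- ground_truth_mask(spec, c(80, 80), 0.5)
  expect_false(msk$mask[40, 40])
  expect_gt(mask_area(msk), 100)

  expect_error(cell_spec(sigma2 = 10, rho = 10), "positive-definite")
})

test_that("ground-truth masks shrink as the threshold rises", {
  spec <- cell_spec(sigma2 = 50)
  areas <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9), function(tm)
    mask_area(ground_truth_mask(spec, c(80, 80), tm)), 0L)
  expect_true(all(diff(areas) <= 0))
  expect_error(ground_truth_mask(spec, c(80, 80), 1.5), "exceeds")
})

test_that("background trace is a Wiener walk plus the stimulus square wave", {
  spec0 <- background_spec(eta = 0, square_amplitude = 0, initial_level = 2)
  expect_true(all(background_trace(spec0, 10, 0.01) == 2))

  # square wave alone: two levels, 0.1 apart, switching at the epoch
  sq <- background_trace(background_spec(eta = 0), 60, 0.01)
  expect_equal(sort(unique(sq)), c(1, 1.1))
  expect_equal(unique(sq[1:1500]), 1)      # first epoch: stimulus off
  expect_equal(unique(sq[1501:3000]), 1.1)

  # Wiener variance law: Var[B(T) - B(0) - square] ~ eta^2 * T
  set.seed(103)
  spec <- background_spec(square_amplitude = 0)
  finals <- replicate(500, {
    b <- background_trace(spec, 120, 0.01)
    b[length(b)] - b[1]
  })
  expect_lt(abs(var(finals) - 0.05^2 * 120), 0.15 * 0.05^2 * 120)
})

test_that("background kernel is positive and matches direct evaluation", {
  spec <- background_spec(n_gaussians = 3)
  set.seed(104)
  k <- background_kernel(spec, c(30, 30))
  expect_true(all(k > 0))
  # oracle: same draws, explicit double loop
  set.seed(104)
  mux <- runif(3, -14.5, 14.5); muy <- runif(3, -14.5, 14.5)
  s2 <- runif(3, 100, 200)
  ora <- matrix(0, 30, 30)
  for (r in 1:30) for (cc in 1:30) {
    x <- cc - 1 - 14.5; y <- r - 1 - 14.5
    ora[r, cc] <- sum(exp(-((x - mux)^2 + (y - muy)^2) / (2 * s2)))
  }
  expect_equal(k, ora, tolerance = 1e-12)

  # a single Gaussian peaks at the pixel nearest its centre
  set.seed(105)
  k1 <- background_kernel(background_spec(n_gaussians = 1), c(21, 21))
  set.seed(105)
  cx <- runif(1, -10, 10); cy <- runif(1, -10, 10)
  peak <- which(k1 == max(k1), arr.ind = TRUE)
  expect_lte(abs(peak[[1, 1]] - 1 - 10 - cy), 0.51)
  expect_lte(abs(peak[[1, 2]] - 1 - 10 - cx), 0.51)
})

test_that("rendered movies obey the Poisson mean law and are reproducible", {
  # background only: per-pixel time-means approach photon_scale * K_bg * B0
  cfg <- sim_config(cells = list(), duration = 20, frame_rate = 100,
                    background = background_spec(eta = 0,
                                                 square_amplitude = 0),
                    photon_scale = 5, seed = 42)
  out <- render(cfg)
  expected <- 5 * out$kernels$bg * 1
  got <- apply(out$movie$frames, c(1, 2), mean)
  sel <- expected >= 1
  expect_gt(sum(sel), 100)
  expect_lt(max(abs(got[sel] - expected[sel]) / expected[sel]), 0.1)

  # determinism: identical seed, identical movie
  out2 <- render(cfg)
  expect_identical(out$movie$frames, out2$movie$frames)

  # all counts are non-negative integers
  expect_true(all(out$movie$frames >= 0))
  expect_true(all(out$movie$frames == round(out$movie$frames)))
})

test_that("noise-free fluorescence is linear in the source amplitudes", {
  ind1 <- indicator_params(amplitude = 0.3)
  ind2 <- indicator_params(amplitude = 0.6)
  s <- c(1, rep(0, 199))
  f1 <- indicator_response(calcium_dynamics(s, ind1, 0.01), ind1)
  f2 <- indicator_response(calcium_dynamics(s, ind2, 0.01), ind2)
  expect_equal(f2, 2 * f1)
})

test_that("benchmark scenes carry the documented cell layout", {
  a <- benchmark_scene("A")
  b <- benchmark_scene("B")
  cc <- benchmark_scene("C")
  expect_length(a$cells, 1)
  expect_length(b$cells, 2)
  expect_length(cc$cells, 3)
  expect_equal(a$cells[[1]]$firing_rate, 0.5)
  expect_equal(a$cells[[1]]$indicator$amplitude, 0.3)
  expect_equal(b$cells[[2]]$centre, c(13, 13))
  expect_equal(b$cells[[2]]$indicator$amplitude, 2)
  expect_equal(cc$cells[[3]]$sigma2, 10)
  expect_equal(cc$cells[[3]]$centre, c(-15, -15))
  expect_equal(cc$cells[[3]]$indicator$amplitude, 4)
  expect_equal(a$duration, 120)
  expect_equal(a$frame_rate, 100)
  expect_equal(a$field_size, c(80L, 80L))
})
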