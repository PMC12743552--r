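test_that("KD is koff/kon with printed rate constants", {
  expect_equal(signif(kd_from_rates(1.1e4, 4.6e-2), 2), 4.2e-6)
  expect_equal(kd_from_rates(1, 0), 0)
  expect_equal(kd_from_rates(2, 2), 1)
  expect_error(kd_from_rates(0, 1), "positive")
  # the wild-type printed affinity (2.16 uM) rounds differently from its
  # own printed rates: koff/kon gives 2.18 uM
  wt <- vwf_bli_constants()[1, ]
  expect_equal(round(1e6 * kd_from_rates(wt$kon_Ms, wt$koff_s), 2), 2.18)
  expect_false(round(1e6 * kd_from_rates(wt$kon_Ms, wt$koff_s), 2) == 2.16)
})

test_that("simulated sensorgrams match the closed form pointwise", {
  kon <- 1.7e4; koff <- 3.7e-2; C <- 1e-6
  s <- simulate_sensorgram(kon, koff, Rmax = 1, conc = C, noise_sd = 0)
  kobs <- kon * C + koff
  req <- 1 * C / (C + koff / kon)
  assoc <- s$time_s <= 60
  expect_equal(s$response_nm[assoc],
               req * (1 - exp(-kobs * s$time_s[assoc])), tolerance = 1e-12)
  r60 <- req * (1 - exp(-kobs * 60))
  expect_equal(s$response_nm[!assoc],
               r60 * exp(-koff * (s$time_s[!assoc] - 60)), tolerance = 1e-12)
})

test_that("saturation and full-dissociation limits behave", {
  kd <- kd_from_rates(1.7e4, 3.7e-2)
  s <- simulate_sensorgram(1.7e4, 3.7e-2, Rmax = 1, conc = 1e6 * kd,
                           t_assoc_end = 2000, t_dissoc_end = 2001, dt = 10)
  expect_equal(max(s$response_nm), 1, tolerance = 1e-4)

  s2 <- simulate_sensorgram(1e4, 5e-2, Rmax = 1, conc = 1e-6,
                            t_dissoc_end = 60 + 400, dt = 1)
  expect_lt(utils::tail(s2$response_nm, 1), 1e-6)   # koff*t >> 1
})

test_that("responses scale linearly in Rmax and KD is Rmax-invariant", {
  g1 <- make_sensorgram_set(Rmax = 1, noise_sd = 0)
  g2 <- make_sensorgram_set(Rmax = 2, noise_sd = 0)
  for (i in seq_along(g1$curves))
    expect_equal(2 * g1$curves[[i]]$response_nm,
                 g2$curves[[i]]$response_nm, tolerance = 1e-12)
  f1 <- fit_langmuir_global(g1$curves)
  f2 <- fit_langmuir_global(g2$curves)
  expect_equal(f1$KD, f2$KD, tolerance = 1e-6)
})

test_that("kobs is affine in concentration with slope kon, intercept koff", {
  kon <- 2e4; koff <- 4e-2
  concs <- c(0.25, 0.5, 1, 2, 4) * 1e-6
  # recover kobs per curve by fitting a single exponential to association
  kobs_hat <- vapply(concs, function(C) {
    s <- simulate_sensorgram(kon, koff, 1, C, noise_sd = 0)
    a <- s[s$time_s <= 60, ]
    req <- max(a$response_nm)  # asymptote proxy for the regression
    fit <- minpack.lm::nlsLM(
      response_nm ~ R * (1 - exp(-k * time_s)), data = a,
      start = list(R = req, k = kon * C + koff),
      control = minpack.lm::nls.lm.control(maxiter = 300))
    stats::coef(fit)[["k"]]
  }, numeric(1))
  lm_fit <- stats::lm(kobs_hat ~ concs)
  expect_equal(unname(stats::coef(lm_fit)[2]), kon, tolerance = 1e-3)
  expect_equal(unname(stats::coef(lm_fit)[1]), koff, tolerance = 1e-3)
})

test_that("noiseless global fit recovers the generating rates", {
  gen <- make_sensorgram_set(kon = 1.7e4, koff = 3.7e-2, noise_sd = 0)
  fit <- fit_langmuir_global(gen$curves)
  expect_equal(fit$kon, 1.7e4, tolerance = 1e-3)
  expect_equal(fit$koff, 3.7e-2, tolerance = 1e-3)
  expect_identical(fit$KD, fit$koff / fit$kon)
})

test_that("model violation (two koff values) is visible in the rss", {
  good <- make_sensorgram_set(noise_sd = 0)
  fit_good <- fit_langmuir_global(good$curves)

  half <- make_sensorgram_set(koff = 3.7e-2, noise_sd = 0)
  other <- make_sensorgram_set(koff = 3.7e-1, noise_sd = 0)
  mixed <- c(half$curves[1:3], other$curves[4:6])
  fit_bad <- fit_langmuir_global(mixed)
  expect_gt(fit_bad$rss, 1e4 * max(fit_good$rss, 1e-12))
})

test_that("duplicate concentrations and bad parameters are rejected", {
  g <- make_sensorgram_set(noise_sd = 0)
  expect_error(fit_langmuir_global(c(g$curves[1], g$curves[1])), "distinct")
  expect_error(simulate_sensorgram(-1, 1, 1, 1e-6), "positive")
  expect_error(make_sensorgram_set(concentrations = c(1e-6, 1e-6)),
               "distinct")
  expect_warning(fit_langmuir_global(g$curves[1:2]), "fewer than 3")
})

test_that("sensorgram sets round-trip through CSV + manifest", {
  gen <- make_sensorgram_set(noise_sd = 0.01, seed = 3)
  dir <- withr::local_tempdir()
  write_sensorgram_set(gen$curves, dir)
  back <- read_sensorgram_set(dir)
  expect_length(back, 6)
  expect_equal(attr(back[[4]], "concentration_M"),
               attr(gen$curves[[4]], "concentration_M"))
  expect_equal(back[[2]]$response_nm, gen$curves[[2]]$response_nm)
})
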