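test_that("spring force follows the harmonic pulling model", {
  expect_equal(spring_force(0, 0), 0)
  expect_equal(spring_force(1, 0, v = 5, k = 69.48), 347.4)
  t <- seq(0, 10, by = 0.5)
  expect_equal(spring_force(t, 5 * t), rep(0, length(t)))  # tracking limit
  expect_error(spring_force(1, 0, v = -1), "positive")
})

test_that("dissociation time applies the sustained-zero rule", {
  c1 <- force_curve(0:4, c(10, 20, 30, 5, 1),
                    hbond_count = c(3, 2, 1, 0, 0),
                    buried_sasa_A2 = c(500, 300, 100, 0.5, 0.2))
  expect_equal(dissociation_time(c1), 3)

  # transient zero at t=2 rebounds; sustained zero starts at t=4
  c2 <- force_curve(0:5, rep(1, 6),
                    hbond_count = c(3, 1, 0, 1, 0, 0),
                    buried_sasa_A2 = c(500, 100, 0.1, 50, 0.1, 0.1))
  expect_equal(dissociation_time(c2), 4)

  # contacts never vanish
  c3 <- force_curve(0:3, rep(1, 4), hbond_count = c(2, 2, 1, 1),
                    buried_sasa_A2 = c(9, 9, 9, 9))
  expect_warning(expect_true(is.na(dissociation_time(c3))), "never vanish")

  # monotone non-increasing in sasa_eps
  c4 <- force_curve(0:4, rep(1, 5), hbond_count = c(1, 0, 0, 0, 0),
                    buried_sasa_A2 = c(100, 5, 2, 0.5, 0.1))
  eps <- c(0.2, 1, 3, 10)
  times <- vapply(eps, function(e) dissociation_time(c4, e), numeric(1))
  expect_true(all(diff(times) <= 0))
})

test_that("rupture force finds the pre-dissociation peak, earliest on ties", {
  tri <- force_curve(seq(0, 25, by = 0.5),
                     c(seq(0, 400, length.out = 41),
                       seq(390, 0, length.out = 10)))
  pr <- rupture_force(tri)
  expect_equal(pr$rupture_force, 400)
  expect_equal(pr$rupture_time, 20)

  twin <- force_curve(0:4, c(0, 300, 100, 300, 0))
  expect_equal(rupture_force(twin)$rupture_time, 1)  # earlier equal peak

  # peak after dissociation is ignored
  late <- force_curve(0:4, c(10, 200, 5, 500, 600),
                      hbond_count = c(2, 1, 0, 0, 0),
                      buried_sasa_A2 = c(100, 50, 0, 0, 0))
  pr2 <- rupture_force(late)
  expect_equal(pr2$rupture_force, 200)
  expect_equal(pr2$dissociation_time, 2)
})

test_that("rupture force is scale-equivariant", {
  set.seed(3)
  f <- abs(rnorm(100, 50, 10))
  cur <- force_curve(seq_along(f), f)
  base <- rupture_force(cur, smooth_window = 5)
  scaled <- force_curve(seq_along(f), 3.5 * f)
  expect_equal(rupture_force(scaled, smooth_window = 5)$rupture_force,
               3.5 * base$rupture_force)
})

test_that("adhesion frequency pools cycles per substrate", {
  cyc <- afm_cycles(data.frame(
    substrate_id = "S1", point_id = "P1", cycle_id = 1:100,
    adhered = c(rep(TRUE, 15), rep(FALSE, 85)),
    rupture_force_pN = c(rnorm(15, 40, 5), rep(NA, 85))))
  out <- adhesion_frequency(cyc)
  expect_equal(out$per_substrate$frequency_pct, 15)
  expect_true(is.na(out$sem_pct))   # one substrate, no spread estimate

  three <- make_afm_cycles(p_adhesion = c(0.2, 0.2, 0.2), seed = 1)
  s <- adhesion_frequency(three$cycles)
  expect_equal(s$n_substrates, 3)
  expect_true(s$mean_pct >= 0 && s$mean_pct <= 100)

  # identical substrates -> sem 0
  same <- afm_cycles(data.frame(
    substrate_id = rep(c("S1", "S2", "S3"), each = 5),
    point_id = "P1", cycle_id = 1:5,
    adhered = rep(c(TRUE, FALSE, FALSE, FALSE, FALSE), 3),
    rupture_force_pN = rep(c(30, NA, NA, NA, NA), 3)))
  out2 <- adhesion_frequency(same)
  expect_equal(out2$mean_pct, 20)
  expect_equal(out2$sem_pct, 0)
})

test_that("pooling all substrates reproduces the event-weighted mean", {
  gen <- make_afm_cycles(p_adhesion = c(0.1, 0.2, 0.3), seed = 9)
  out <- adhesion_frequency(gen$cycles)
  pooled <- 100 * sum(gen$cycles$adhered) / nrow(gen$cycles)
  weighted <- with(out$per_substrate,
                   sum(frequency_pct * n_cycles) / sum(n_cycles))
  expect_equal(pooled, weighted)
})

test_that("rupture-force distribution mean is binning-independent", {
  gen <- make_afm_cycles(p_adhesion = 0.5, force_mean = 40, force_sd = 6,
                         seed = 2)
  d5 <- rupture_distribution(gen$cycles, bin_width = 5)
  d2 <- rupture_distribution(gen$cycles, bin_width = 2)
  truth_mean <- mean(gen$cycles$rupture_force_pN[gen$cycles$adhered])
  expect_identical(d5$mean_force_pN, truth_mean)
  expect_identical(d2$mean_force_pN, truth_mean)
  # Xc close to the planted center
  expect_lt(abs(d5$xc_pN - 40), 1.5)

  few <- gen$cycles[gen$cycles$adhered, ][1:5, ]
  expect_error(rupture_distribution(afm_cycles(few)), "at least 20")
})

test_that("cycle tables validate the adhered/force invariant", {
  expect_error(afm_cycles(data.frame(
    substrate_id = "S1", point_id = "P1", cycle_id = 1,
    adhered = TRUE, rupture_force_pN = NA)), "carry a rupture force")
  expect_error(afm_cycles(data.frame(
    substrate_id = "S1", point_id = "P1", cycle_id = 1,
    adhered = FALSE, rupture_force_pN = 30)), "must not carry")
})

test_that("force-curve and AFM CSV round trips preserve data", {
  gen <- make_smd_curve(noise_sd = 5, seed = 4)
  p1 <- withr::local_tempfile(fileext = ".csv")
  write_force_curve(gen$curve, p1)
  back <- read_force_curve(p1)
  expect_equal(back$force_pN, gen$curve$force_pN)
  expect_equal(back$hbond_count, gen$curve$hbond_count)

  afm <- make_afm_cycles(seed = 5)
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_afm_cycles(afm$cycles, p2)
  back2 <- read_afm_cycles(p2)
  expect_equal(back2$adhered, afm$cycles$adhered)
  expect_equal(back2$rupture_force_pN, afm$cycles$rupture_force_pN)
})
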