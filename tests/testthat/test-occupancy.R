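runs_from_table <- function(tab) {
  lapply(c("run1", "run2", "run3"),
         function(cl) stats::setNames(tab[[cl]], tab$pair))
}

test_that("survival rate is the percent of frames present", {
  occ <- occupancy_matrix(list(
    data.frame(kind = "hbond", chain_a = "A", res_a = 1, resname_a = "GLY",
               chain_b = "B", res_b = 2, resname_b = "GLY",
               min_distance_A = 2.9),
    NULL, NULL, NULL, NULL)[c(1, 1, 2, 1, 2)], frame_interval_ns = 0.1)
  expect_equal(unname(survival_rates(occ)), 60)

  # all-absent and all-present rows via planted trajectories
  toy <- make_toy_complex(hb_distance = c(2.9, 2.9))
  gen <- make_trajectory(toy, occupancy = list(1, 0), n_frames = 20,
                         seed = 2)
  occ2 <- trajectory_contacts(gen$trajectory, "A", "B", saltbridge = NULL)
  sr <- survival_rates(occ2)
  expect_equal(unname(sr), 100)  # the p=0 pair never appears as a key
})

test_that("survival is invariant to frame permutation", {
  toy <- make_toy_complex(hb_distance = 2.9)
  gen <- make_trajectory(toy, occupancy = list(0.5), n_frames = 50, seed = 5)
  occ <- trajectory_contacts(gen$trajectory, "A", "B", saltbridge = NULL)
  perm <- occ
  set.seed(1)
  perm$presence <- perm$presence[, sample(ncol(perm$presence)), drop = FALSE]
  expect_equal(survival_rates(occ), survival_rates(perm))
})

test_that("planted Bernoulli occupancy is recovered within binomial bounds", {
  toy <- make_toy_complex(hb_distance = 2.9)
  n <- 10000
  gen <- make_trajectory(toy, occupancy = list(0.7), n_frames = n, seed = 42)
  occ <- trajectory_contacts(gen$trajectory, "A", "B", saltbridge = NULL)
  sr <- unname(survival_rates(occ))
  expect_identical(sr, 100 * mean(gen$truth[1, ]))  # exact vs ground truth
  expect_lt(abs(sr - 70), 3 * 100 * sqrt(0.7 * 0.3 / n))
})

test_that("run aggregation reproduces printed mean and SEM cells", {
  agg <- aggregate_runs(list(c("R1334-E1598" = 79.3),
                             c("R1334-E1598" = 59.1),
                             c("R1334-E1598" = 51.1)))
  expect_equal(round(agg$mean, 1), 63.2)
  expect_equal(round(agg$sem, 1), 8.4)

  agg2 <- aggregate_runs(list(c("D1323-R1575" = 69.9),
                              c("D1323-R1575" = 2.6),
                              c("D1323-R1575" = 87.9)))
  expect_equal(round(agg2$sem, 1), 26.0)

  same <- aggregate_runs(list(c(a = 40), c(a = 40), c(a = 40)))
  expect_equal(same$mean, 40)
  expect_equal(same$sem, 0)
})

test_that("keys absent from a run contribute explicit zeros", {
  agg <- aggregate_runs(list(c(x = 30), c(x = 60, y = 90), c(x = 30)))
  yrow <- agg[agg$pair == "y", ]
  expect_equal(unlist(yrow[, c("run1", "run2", "run3")], use.names = FALSE),
               c(0, 90, 0))
  expect_equal(yrow$mean, 30)
  expect_error(aggregate_runs(list(c(x = 1))), "SEM")
})

test_that("threshold filtering is strict and sorted by mean", {
  tab <- aggregate_runs(list(c(a = 63.2, b = 10.0, c = 9.9),
                             c(a = 63.2, b = 10.0, c = 9.9),
                             c(a = 63.2, b = 10.0, c = 9.9)))
  kept <- filter_table(tab, 10)
  expect_equal(kept$pair, "a")
  expect_true(all(filter_table(tab, 0)$pair %in% tab$pair))
  expect_equal(filter_table(tab, 0)$mean, sort(tab$mean, decreasing = TRUE))
})

test_that("heat-map matrix places means at ascending residue pairs", {
  tab <- vwf_survival_runs("hbond")
  agg <- aggregate_runs(runs_from_table(tab), kind = "hbond")
  m <- heatmap_matrix(agg)
  expect_equal(rownames(m), as.character(sort(unique(agg$res_a))))
  expect_equal(m["1334", "1598"], agg$mean[agg$pair == "R1334-E1598"])
  # row sums equal direct per-residue summation
  for (r in unique(agg$res_a))
    expect_equal(sum(m[as.character(r), ]),
                 sum(agg$mean[agg$res_a == r]))
  # degenerate cases
  expect_equal(dim(heatmap_matrix(agg[0, ])), c(0, 0))
  one <- heatmap_matrix(agg[1, ])
  expect_equal(dim(one), c(1, 1))
  expect_equal(unname(one[1, 1]), agg$mean[1])
})

test_that("bond-count series sums columns and Gaussian fitting recovers", {
  toy <- make_toy_complex(hb_distance = c(2.9, 2.9, 2.9))
  gen <- make_trajectory(toy, occupancy = list(0.9, 0.5, 0.2),
                         n_frames = 100, seed = 6)
  occ <- trajectory_contacts(gen$trajectory, "A", "B", saltbridge = NULL)
  counts <- hbond_count_series(occ)
  expect_identical(counts, as.integer(colSums(gen$truth)))

  # rounded-normal recovery
  set.seed(10)
  x <- round(rnorm(10000, 10, 2))
  fit <- fit_count_distribution(x)
  expect_lt(abs(fit$mu - 10), 0.1)
  expect_lt(abs(fit$sigma - 2), 0.1)

  # noiseless histogram exactly proportional to a Gaussian
  xs <- seq(-5, 5, by = 0.5)
  ys <- 7 * exp(-(xs - 1.2)^2 / (2 * 1.5^2))
  fit2 <- fit_gaussian(xs, ys)
  expect_lt(fit2$rss, 1e-6)
  expect_equal(fit2$mu, 1.2, tolerance = 1e-6)
  expect_equal(fit2$sigma, 1.5, tolerance = 1e-6)

  expect_error(fit_count_distribution(rep(5L, 100)), "degenerate")
  expect_error(fit_count_distribution(1:5), "at least 10")
})
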