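# Iterative scaling, symmetry-aware merging, and the quality statistics.

test_that("identity data recovers unit scales and zero B", {
  cfg <- toy_config(n_crystals = 4, wedge_width = 120, noise_scale = 0,
                    scale_range = c(1, 1), B_range = c(0, 0))
  sim <- simulate_datasets(cfg)
  fit <- fit_scales(sim$datasets, cfg$sg)
  expect_true(fit$convergence$converged)
  expect_equal(coef(fit)$k, rep(1, 4), tolerance = 1e-6)
  expect_equal(coef(fit)$B, rep(0, 4), tolerance = 1e-3)
})

test_that("a doubled crystal is fit at scale ratio 2", {
  cfg <- toy_config(n_crystals = 2, wedge_width = 360, noise_scale = 0,
                    scale_range = c(1, 1), B_range = c(0, 0))
  sim <- simulate_datasets(cfg)
  ds <- sim$datasets
  ds[[2]]$observations$intensity <- 2 * ds[[2]]$observations$intensity
  ds[[2]]$observations$sigma <- 2 * ds[[2]]$observations$sigma
  fit <- fit_scales(ds, cfg$sg)
  p <- coef(fit)
  expect_equal(p$k[2] / p$k[1], 2, tolerance = 1e-4)
})

test_that("scales and B are recovered from noisy wedges", {
  cfg <- toy_config(n_crystals = 12, wedge_width = 40, seed = 21,
                    scale_range = c(0.5, 2), B_range = c(0, 20))
  sim <- simulate_datasets(cfg)
  fit <- fit_scales(sim$datasets, cfg$sg)
  tr <- sim$truth$crystals
  k_ref <- tr$k / exp(mean(log(tr$k)))
  B_ref <- tr$B - mean(tr$B)
  p <- coef(fit)
  expect_lt(sqrt(mean((p$k / k_ref - 1)^2)), 0.05)
  expect_lt(sqrt(mean((p$B - B_ref)^2)), 2)
})

test_that("per-frame scaling fits one scale per frame, B per crystal", {
  cfg <- toy_config(n_crystals = 3, wedge_width = 90, frames_per_wedge = 3)
  sim <- simulate_datasets(cfg)
  fit <- fit_scales(sim$datasets, cfg$sg, per_frame = TRUE)
  p <- coef(fit)
  expect_gt(nrow(p), 3)
  expect_false(any(is.na(p$frame_id)))
  # one B per crystal
  expect_equal(unname(vapply(split(p$B, p$crystal_id),
                             function(b) max(b) - min(b), 0)),
               rep(0, 3))
})

test_that("a disconnected crystal graph is refused with components named", {
  cfg <- toy_config(n_crystals = 2, wedge_width = 360)
  sim <- simulate_datasets(cfg)
  ds <- sim$datasets
  # make the second crystal live in a disjoint index universe
  ds[[2]]$observations <- ds[[2]]$observations[0, ]
  extra <- observation_table(rep(20, 25), 21:45, rep(20, 25),
                             rep(10, 25), rep(1, 25), 0L, "xtal002")
  ds[[2]]$observations <- extra
  expect_error(fit_scales(ds, cfg$sg), "disconnected")
})

test_that("duplicated noiseless observations merge to R_merge 0 and
          CC1/2 1", {
  cfg <- toy_config(n_crystals = 2, wedge_width = 360, noise_scale = 0,
                    scale_range = c(1, 1), B_range = c(0, 0),
                    cell_jitter_sigma = 0, angle_jitter_sigma = 0)
  sim <- simulate_datasets(cfg)
  fit <- fit_scales(sim$datasets, cfg$sg)
  m <- merge_observations(sim$datasets, fit, cfg$sg)
  expect_equal(m$overall$R_merge, 0, tolerance = 1e-10)
  expect_equal(m$overall$cc_half, 1, tolerance = 1e-10)
})

test_that("a hand-built toy table reproduces spreadsheet R factors", {
  # two uniques in P1 (Friedel off to keep indices literal):
  # (1,0,0): I = 10, 12  -> mean 11, dev 1, 1
  # (0,1,0): I = 20, 24, 28 -> mean 24, dev 4, 0, 4
  # equal sigmas so inverse-variance means are plain means.
  # R_merge = (1+1+4+0+4) / (10+12+20+24+28) = 10/94
  # R_meas  = (2*sqrt(2/1) + 8*sqrt(3/2)) / 94
  # R_pim   = (2*sqrt(1/1) + 8*sqrt(1/2)) / 94
  obs <- observation_table(c(1, 1, 0, 0, 0), c(0, 0, 1, 1, 1),
                           c(0, 0, 0, 0, 0), c(10, 12, 20, 24, 28),
                           rep(1, 5), 0L, "t")
  ds <- list(crystal_dataset("t", unit_cell(10, 10, 10), obs))
  sg <- space_group("P1", friedel_merged = FALSE)
  m <- merge_observations(ds, NULL, sg, n_shells = 1)
  expect_equal(m$overall$R_merge, 10 / 94, tolerance = 1e-12)
  expect_equal(m$overall$R_meas,
               (2 * sqrt(2) + 8 * sqrt(3 / 2)) / 94, tolerance = 1e-12)
  expect_equal(m$overall$R_pim,
               (2 * 1 + 8 * sqrt(1 / 2)) / 94, tolerance = 1e-12)
  expect_equal(m$reflections$I[match(24, m$reflections$I)], 24)
  expect_setequal(m$reflections$multiplicity, c(2, 3))
  # sigma_merged = sqrt(1 / sum(1/sigma^2))
  expect_equal(sort(m$reflections$sigma),
               sort(c(1 / sqrt(2), 1 / sqrt(3))), tolerance = 1e-12)
})

test_that("R_pim <= R_merge <= R_meas on every shell with n >= 2", {
  cfg <- toy_config(n_crystals = 8, wedge_width = 60, seed = 13)
  sim <- simulate_datasets(cfg)
  fit <- fit_scales(sim$datasets, cfg$sg)
  m <- merge_observations(sim$datasets, fit, cfg$sg)
  sh <- m$shells[!is.na(m$shells$R_merge), ]
  expect_gt(nrow(sh), 5)
  expect_true(all(sh$R_pim <= sh$R_merge + 1e-12))
  expect_true(all(sh$R_merge <= sh$R_meas + 1e-12))
})

test_that("per-shell completeness equals brute-force ASU enumeration", {
  for (sym in c("P1", "P21", "P212121")) {
    sg <- space_group(sym)
    cfg <- toy_config(n_crystals = 5, sg = sym, wedge_width = 90,
                      cell_jitter_sigma = 0, angle_jitter_sigma = 0,
                      seed = 31)
    sim <- simulate_datasets(cfg)
    fit <- fit_scales(sim$datasets, cfg$sg)
    m <- merge_observations(sim$datasets, fit, cfg$sg)
    # brute force: map every sphere reflection to the ASU, count the
    # distinct present ones per shell, independent of merge internals
    lim <- floor(as.numeric(toy_cell())[1:3] / min(m$shells$d_min))
    grid <- as.matrix(expand.grid(-lim[1]:lim[1], -lim[2]:lim[2],
                                  -lim[3]:lim[3]))
    grid <- grid[rowSums(abs(grid)) > 0, ]
    d <- resolution_of(toy_cell(), grid)
    canon <- map_to_asu(grid, sg)
    lab <- paste(canon$h, canon$k, canon$l)
    keep <- !duplicated(lab)
    canon <- canon[keep, ]; d <- d[keep]; lab <- lab[keep]
    present <- !is_absent(as.matrix(canon[, c("h", "k", "l")]), sg)
    canon <- canon[present, ]; d <- d[present]; lab <- lab[present]
    for (i in seq_len(nrow(m$shells))) {
      sh <- m$shells[i, ]
      in_shell <- d > sh$d_min & d <= sh$d_max + 1e-9
      if (i == nrow(m$shells))
        in_shell <- in_shell | abs(d - sh$d_min) < 1e-9
      n_brute <- sum(in_shell)
      expect_equal(sh$n_possible, n_brute)
      obs_lab <- paste(m$reflections$h, m$reflections$k, m$reflections$l)
      n_obs <- sum(m$reflections$shell == i)
      expect_equal(sh$completeness, n_obs / n_brute)
      expect_true(all(obs_lab[m$reflections$shell == i] %in% lab[in_shell]))
    }
  }
})

test_that("merging is invariant to observation order and absorbs a
          constant per-crystal rescaling", {
  cfg <- toy_config(n_crystals = 4, wedge_width = 90, seed = 17)
  sim <- simulate_datasets(cfg)
  fit <- fit_scales(sim$datasets, cfg$sg)
  m1 <- merge_observations(sim$datasets, fit, cfg$sg)

  shuffled <- lapply(sim$datasets, function(ds) {
    set.seed(99)
    ds$observations <- ds$observations[sample(nrow(ds$observations)), ]
    rownames(ds$observations) <- NULL
    ds
  })
  m2 <- merge_observations(shuffled, fit_scales(shuffled, cfg$sg), cfg$sg)
  expect_equal(m1$reflections, m2$reflections, tolerance = 1e-9)
  expect_equal(m1$overall, m2$overall, tolerance = 1e-9)

  # multiply crystal 2 by c: refit absorbs it, merged set unchanged
  rescaled <- sim$datasets
  rescaled[[2]]$observations$intensity <-
    rescaled[[2]]$observations$intensity * 3.7
  rescaled[[2]]$observations$sigma <-
    rescaled[[2]]$observations$sigma * 3.7
  # the gauge (geometric-mean scale) re-distributes the constant, so the
  # merged set is unchanged up to one global factor
  m3 <- merge_observations(rescaled, fit_scales(rescaled, cfg$sg), cfg$sg)
  ratio <- m3$reflections$I / m1$reflections$I
  expect_equal(ratio, rep(3.7^(1 / 4), length(ratio)), tolerance = 1e-4)
  expect_equal(m3$overall$R_merge, m1$overall$R_merge, tolerance = 1e-4)
  expect_equal(m3$overall$cc_half, m1$overall$cc_half, tolerance = 1e-3)
})

test_that("CC1/2 over repeated seeded splits is stable", {
  cfg <- toy_config(n_crystals = 6, wedge_width = 60, seed = 23)
  sim <- simulate_datasets(cfg)
  fit <- fit_scales(sim$datasets, cfg$sg)
  m20 <- merge_observations(sim$datasets, fit, cfg$sg, n_splits = 20)
  m1 <- merge_observations(sim$datasets, fit, cfg$sg, n_splits = 1,
                           split_seed = 777)
  expect_false(is.na(m20$overall$cc_half_sd))
  expect_lt(abs(m1$overall$cc_half - m20$overall$cc_half),
            3 * m20$overall$cc_half_sd + 1e-12)
  # identical seed, identical value (determinism of the split stream)
  m1b <- merge_observations(sim$datasets, fit, cfg$sg, n_splits = 1,
                            split_seed = 777)
  expect_identical(m1$overall$cc_half, m1b$overall$cc_half)
})

test_that("empty shells report NA statistics, not zeros", {
  obs <- observation_table(c(5, 5), c(0, 0), c(0, 0), c(10, 12), c(1, 1),
                           0L, "t")
  ds <- list(crystal_dataset("t", unit_cell(10, 10, 10), obs))
  m <- merge_observations(ds, NULL, space_group("P1"), n_shells = 4,
                          d_min = 1.5, d_max = 10)
  empty <- m$shells$n_unique == 0
  expect_gt(sum(empty), 0)
  expect_true(all(is.na(m$shells$R_merge[empty])))
  expect_true(all(is.na(m$shells$cc_half[empty])))
})

test_that("anomalous CC is null without signal, strong with it, and
          refuses Friedel-merged groups", {
  sgu <- space_group("P212121", friedel_merged = FALSE)
  cfg0 <- toy_config(n_crystals = 8, wedge_width = 360, anom_fraction = 0,
                     sg = sgu, seed = 41)
  sim0 <- simulate_datasets(cfg0)
  fit0 <- fit_scales(sim0$datasets, sgu)
  cc0 <- anomalous_cc(sim0$datasets, fit0, sgu, n_shells = 4)
  n_pairs <- sum(cc0$by_shell$n_pairs)
  expect_lt(abs(cc0$overall), 3 * 2 / sqrt(n_pairs) + 0.05)

  cfg1 <- toy_config(n_crystals = 8, wedge_width = 360, anom_fraction = 0.5,
                     noise_floor = 1, noise_scale = 0.3, sg = sgu, seed = 41)
  sim1 <- simulate_datasets(cfg1)
  fit1 <- fit_scales(sim1$datasets, sgu)
  cc1 <- anomalous_cc(sim1$datasets, fit1, sgu, n_shells = 4)
  expect_gt(cc1$overall, 0.9)

  # swapping every mate negates dI in both halves: CC sign preserved
  swapped <- lapply(sim1$datasets, function(ds) {
    ds$observations[, c("h", "k", "l")] <- -ds$observations[, c("h", "k", "l")]
    ds
  })
  cc2 <- anomalous_cc(swapped, fit_scales(swapped, sgu), sgu, n_shells = 4)
  expect_gt(cc2$overall, 0.9)

  expect_error(anomalous_cc(sim1$datasets, fit1, space_group("P212121")),
               "friedel_merged = FALSE")
})
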