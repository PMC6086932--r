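test_that("model_density evaluates the annular erf model", {
  m <- geometric_model(x0 = 0, y0 = 0, r_out = 70, dr = 30, A = 1,
                       sigma = 15)
  # A = 0 gives the zero image
  m0 <- geometric_model(r_out = 70, dr = 30, A = 0, sigma = 15)
  expect_equal(model_density(m0, 10, 20), 0)
  # radial symmetry
  for (d in c(5, 33, 71, 140)) {
    expect_equal(model_density(m, d, 0), model_density(m, -d, 0))
    expect_equal(model_density(m, d, 0), model_density(m, 0, d))
  }
  # high-precision value at R = r_out: erf(30 / (sqrt(2) * 15))
  expect_equal(model_density(m, 70, 0), 2 * pnorm(2) - 1, tolerance = 1e-12)
  expect_equal(model_density(m, 70, 0), 0.954499736, tolerance = 1e-9)
})

test_that("fit_model_to_image reproduces parameters on ideal images", {
  # spot-check here; the full 20-point grid runs in test-acceptance.R
  set.seed(51)
  for (pars in list(c(70, 30), c(40, 55))) {
    m <- geometric_model(x0 = 4.2, y0 = -7.9, r_out = pars[1], dr = pars[2],
                         A = 0.8, sigma = 15)
    img <- ideal_model_image(m)
    init <- geometric_model(x0 = 0, y0 = 0, r_out = pars[1] * 1.4,
                            dr = pars[2] * 0.7, sigma = 15)
    f <- fit_model_to_image(img, init)
    expect_lt(abs(f$model$r_out - pars[1]), 1e-2)
    expect_lt(abs(f$model$dr - pars[2]), 1e-2)
    expect_lt(abs(f$model$x0 - 4.2), 1e-2)
    expect_lt(abs(f$model$y0 + 7.9), 1e-2)
  }
})

test_that("fit_site recovers synthetic rings and applies exclusion rules", {
  set.seed(52)
  fits <- replicate(25, {
    tab <- ring_site_table(n = 300)
    fit_site(tab, restarts = 1, max_r = 150)$model$r_out
  })
  expect_lt(abs(median(fits) - 70), 4)
  # exclusion: under 30 localizations
  small <- ring_site_table(n = 25)
  f <- fit_site(small)
  expect_true(f$excluded)
  expect_equal(f$reason, "few_locs")
  # coat/scission policy keeps small radii, still excludes low counts
  tiny <- ring_site_table(n = 80, r_out = 20, dr = 25, shape = "patch",
                          precision = 10)
  expect_equal(fit_site(tiny, policy = "coat_scission")$reason, "none")
  gen <- fit_site(tiny, policy = "general")
  if (gen$model$r_out < 30) expect_equal(gen$reason, "small_radius")
  expect_error(fit_site(ring_site_table(n = 4)), "5 localizations")
})

test_that("fit_site is translation-equivariant", {
  set.seed(53)
  tab <- ring_site_table(n = 200)
  v <- c(12345.6, -789.1)
  shifted <- tab
  shifted$x_nm <- shifted$x_nm + v[1]
  shifted$y_nm <- shifted$y_nm + v[2]
  set.seed(99); f1 <- fit_site(tab, restarts = 1)
  set.seed(99); f2 <- fit_site(shifted, restarts = 1)
  expect_equal(f2$model$x0 - f1$model$x0, v[1], tolerance = 1e-6)
  expect_equal(f2$model$y0 - f1$model$y0, v[2], tolerance = 1e-6)
  expect_equal(f2$model$r_out, f1$model$r_out, tolerance = 1e-6)
  expect_equal(f2$model$dr, f1$model$dr, tolerance = 1e-6)
})

test_that("radial_profile bins correctly and conserves counts", {
  one <- simple_table(42, 0)
  pr <- radial_profile(one, c(0, 0), bin_width = 5)
  expect_equal(pr$counts[pr$r_mid == 42.5], 1)   # bin [40, 45)
  expect_equal(sum(pr$counts), 1)
  # annulus-area normalization: uniform disk is flat. Aggregate the fine
  # profile into equal-area rings so every ring has ~1e4 expected counts
  # (the innermost 5-10 nm bins alone hold only ~100 draws at n = 1e5,
  # far too few for a 3% bound)
  set.seed(54)
  disk <- disk_points(1e5, c(0, 0), 200)
  pr2 <- radial_profile(disk, c(0, 0), bin_width = 10, max_r = 250)
  edges <- attr(pr2, "bin_edges")
  ring <- ceiling(10 * edges[-1]^2 / 200^2 - 1e-9)
  keep <- edges[-1] <= 200
  agg_counts <- tapply(pr2$counts[keep], ring[keep], sum)
  agg_area <- tapply(diff(pi * edges^2)[keep], ring[keep], sum)
  dens <- agg_counts / agg_area
  expect_lt(max(abs(dens / mean(dens) - 1)), 0.03)
  expect_equal(sum(pr2$counts), 1e5)
})

test_that("align_and_average centers, averages and summarizes", {
  set.seed(55)
  offsets <- rbind(c(0, 0), c(500, 0), c(-300, 800))
  locs_list <- lapply(1:3, function(i) {
    ring_site_table(n = 250, center = offsets[i, ])
  })
  fits <- lapply(locs_list, fit_site, restarts = 2)
  avg <- align_and_average(fits, locs_list)
  expect_equal(avg$summary$n_sites, 3L)
  expect_equal(avg$summary$ring_fraction, 1)
  expect_lt(abs(avg$summary$mean_r_out - 70),
            max(4, 2 * avg$summary$sem_r_out + 2))
  expect_equal(avg$summary$sem_r_out,
               avg$summary$sd_r_out / sqrt(3), tolerance = 1e-12)
  # single non-excluded site: average equals that site's centered stack
  one <- align_and_average(fits[1], locs_list[1])
  expect_equal(one$summary$n_sites, 1L)
  expect_equal(sum(one$image > 0) > 0, TRUE)
  # profile peaks near the rim center (r_out - dr/2 = 55)
  expect_lt(abs(avg$profile$r_mid[which.max(avg$profile$density)] - 55), 15)
  expect_error(align_and_average(list(structure(list(excluded = TRUE),
                                                class = "site_fit")),
                                 list(NULL)), "excluded")
})

test_that("classify_shape applies the dome/ring/patch rules", {
  prof_flat <- data.frame(r_mid = seq(2.5, 247.5, 5),
                          density = rep(1, 50))
  prof_hole <- prof_flat; prof_hole$density[1:5] <- 0.2
  mk <- function(r, dr) structure(list(mean_r_out = r, mean_dr = dr),
                                  class = "module_summary")
  # boundary dr = r_out is a patch
  expect_equal(classify_shape(mk(50, 50), prof_flat), "patch")
  # large with filled center: dome
  expect_equal(classify_shape(mk(90, 40), prof_flat), "dome")
  # large but hollow: ring, not dome
  expect_equal(classify_shape(mk(90, 40), prof_hole), "ring")
  # mid-sized with dr/r_out = 0.4: ring
  expect_equal(classify_shape(mk(70, 28), prof_hole), "ring")
})

test_that("summary_stats matches printed mean/SD/SEM arithmetic", {
  set.seed(56)
  x <- rnorm(2514, 60.8, 20.9)
  st <- summary_stats(x)
  expect_equal(st[["sem"]], st[["sd"]] / sqrt(2514))
  # the printed-precision identity: SD 20.9 at n = 2514 gives SEM 0.4
  expect_equal(round(20.9 / sqrt(2514), 1), 0.4)
  expect_equal(st[["n"]], 2514)
})

test_that("rank_sum_test matches enumeration and handles ties", {
  # exact small-sample case against full permutation enumeration
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  res <- rank_sum_test(a, b)
  expect_equal(res$method, "exact")
  pool <- c(a, b)
  combs <- combn(6, 3)
  U_all <- apply(combs, 2, function(idx) {
    sum(rank(pool)[idx]) - 3 * 4 / 2
  })
  U_obs <- res$statistic
  p_exact <- 2 * min(mean(U_all <= U_obs), mean(U_all >= U_obs))
  expect_equal(res$p_value, p_exact)
  expect_equal(res$p_value, 0.1)
  # oracle on a second asymmetric case
  a2 <- c(1.5, 9.1, 3.3, 7.7); b2 <- c(2.2, 4.4, 6.6, 8.8, 10.1)
  res2 <- rank_sum_test(a2, b2)
  pool2 <- c(a2, b2)
  combs2 <- combn(9, 4)
  U2 <- apply(combs2, 2, function(idx) sum(rank(pool2)[idx]) - 4 * 5 / 2)
  p2 <- 2 * min(mean(U2 <= res2$statistic), mean(U2 >= res2$statistic))
  expect_equal(res2$p_value, p2)
  # identical samples: p about 1 under the tie-corrected normal path
  same <- rep(1:5, 10)
  res3 <- rank_sum_test(same, same)
  expect_equal(res3$method, "normal_approximation")
  expect_gt(res3$p_value, 0.99)
  expect_error(rank_sum_test(numeric(), 1:3), "non-empty")
})
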