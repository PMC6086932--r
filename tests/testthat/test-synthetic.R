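test_that("structure_spec validates its fields", {
  expect_error(structure_spec("blob", r_out = 50, dr = 20, n_molecules = 10),
               "shape")
  expect_error(structure_spec("ring", r_out = -5, dr = 20, n_molecules = 10),
               "r_out")
  expect_error(structure_spec("patch", r_out = 50, dr = 20, n_molecules = 10),
               "dr >= r_out")
  expect_silent(structure_spec("ring", r_out = 70, dr = 30, n_molecules = 1))
})

test_that("sample_structure returns the requested count and geometry", {
  # count conservation
  s7 <- sample_structure(structure_spec("ring", r_out = 70, dr = 30,
                                        n_molecules = 7), seed = 1)
  expect_equal(nrow(s7), 7L)

  # degenerate annulus: dr -> 0+ puts every point at radius r_out
  thin <- sample_structure(structure_spec("ring", center = c(100, -50),
                                          r_out = 80, dr = 1e-9,
                                          n_molecules = 100), seed = 2)
  r <- sqrt((thin[, 1] - 100)^2 + (thin[, 2] + 50)^2)
  expect_true(all(abs(r - 80) < 1e-6))

  # dome projections stay inside the disk of radius r_out
  dome <- sample_structure(structure_spec("dome", r_out = 90, dr = 90,
                                          n_molecules = 500), seed = 3)
  expect_true(all(rowSums(dome^2) <= 90^2 + 1e-9))
})

test_that("sampled radial distributions match the analytic density", {
  # patch: uniform over the disk; KS distance against the closed-form
  # radial CDF r^2 / R^2
  set.seed(4)
  p <- sample_structure(structure_spec("patch", r_out = 40, dr = 40,
                                       n_molecules = 1e5))
  r <- sort(sqrt(rowSums(p^2)))
  ks <- max(abs(seq_along(r) / length(r) - r^2 / 40^2))
  expect_lt(ks, 0.01)

  # ring: CDF (r^2 - r_in^2) / (r_out^2 - r_in^2) on the annulus
  set.seed(5)
  g <- sample_structure(structure_spec("ring", r_out = 70, dr = 30,
                                       n_molecules = 1e5))
  r <- sort(sqrt(rowSums(g^2)))
  expect_true(all(r >= 40 - 1e-9 & r <= 70 + 1e-9))
  ks <- max(abs(seq_along(r) / length(r) - (r^2 - 40^2) / (70^2 - 40^2)))
  expect_lt(ks, 0.02)
})

test_that("emit_localizations conserves counts and records truth", {
  spec <- structure_spec("ring", r_out = 70, dr = 30, n_molecules = 50)
  man <- ground_truth_manifest(list(spec), n_frames = 200, seed = 6)
  model <- emission_model(mean_blinks = 3, background_rate = 5,
                          precision_mean = 12, precision_sd = 3)
  tab <- emit_localizations(man, model, field_nm = c(2000, 2000), seed = 7)
  sid <- attr(tab, "site_id")
  expect_equal(nrow(tab), length(sid))
  expect_true(all(tab$frame >= 1 & tab$frame <= 200))
  expect_true(all(tab$precision_nm >= 1))
  # seeded determinism: bit-identical reruns
  tab2 <- emit_localizations(man, model, field_nm = c(2000, 2000), seed = 7)
  expect_identical(tab, tab2)
  expect_error(emit_localizations(man, model, n_frames = 0), "n_frames")
})

test_that("noiseless limit returns molecule positions at the 1 nm floor", {
  spec <- structure_spec("patch", r_out = 50, dr = 50, n_molecules = 40)
  man <- ground_truth_manifest(list(spec), n_frames = 10, seed = 8)
  model <- emission_model(mean_blinks = 1, blink_gap_prob = 0,
                          precision_mean = 0, precision_sd = 0)
  tab <- emit_localizations(man, model, seed = 9)
  expect_equal(nrow(tab), 40L)
  truth <- man$molecule_positions[[1]]
  # match each record to its molecule: all within a few floor sigmas
  d <- sqrt(outer(tab$x_nm, truth[, 1], "-")^2 +
              outer(tab$y_nm, truth[, 2], "-")^2)
  expect_lt(max(apply(d, 1, min)), 6)   # 1 nm floor per axis
})

test_that("the 15 nm per-axis blur gives a 21.2 nm lateral spread", {
  spec <- structure_spec("patch", r_out = 1e-3, dr = 1e-3, n_molecules = 1e4)
  man <- ground_truth_manifest(list(spec), n_frames = 1, seed = 10)
  model <- emission_model(mean_blinks = 1, precision_mean = 15,
                          precision_sd = 0)
  tab <- emit_localizations(man, model, seed = 11)
  spread <- sqrt(mean(tab$x_nm^2 + tab$y_nm^2))
  expect_lt(abs(spread - 21.2) / 21.2, 0.02)
})

test_that("background-only tables are uniform over the field", {
  spec <- structure_spec("patch", r_out = 1, dr = 1, n_molecules = 1)
  man <- ground_truth_manifest(list(spec), n_frames = 50, seed = 12)
  man$molecule_positions[[1]] <- man$molecule_positions[[1]][0, , drop = FALSE]
  man$sites[[1]]$n_molecules <- 0L
  model <- emission_model(background_rate = 2000)
  tab <- emit_localizations(man, model, field_nm = c(4000, 4000), seed = 13)
  expect_gt(nrow(tab), 1000)
  # chi-square uniformity on a 4x4 grid at alpha = 0.01
  gx <- cut(tab$x_nm, seq(0, 4000, 1000))
  gy <- cut(tab$y_nm, seq(0, 4000, 1000))
  counts <- as.vector(table(gx, gy))
  chi <- sum((counts - mean(counts))^2 / mean(counts))
  expect_lt(chi, stats::qchisq(0.99, df = 15))
})

test_that("render_frames conserves photons and background", {
  cam <- list(pixelsize_nm = 100, width_px = 16, height_px = 16,
              background = 7)
  # empty table: per-pixel mean = background
  empty <- localization_table()
  stk <- render_frames(empty, cam, n_frames = 40, seed = 14)
  expect_equal(mean(stk), 7, tolerance = 3 / sqrt(length(stk)) * sqrt(7) / 7)
  # single blink photon conservation, noiseless
  one <- simple_table(800, 800)
  img <- render_frames(one, cam, noiseless = TRUE)[, , 1]
  expect_equal(sum(img) - 7 * 256, 1000, tolerance = 0.5)
  # two blinks 10 px apart (at pixel centers, avoiding edge ties): the two
  # brightest pixels are exactly theirs
  two <- simple_table(c(350, 1350), c(350, 350))
  img2 <- render_frames(two, cam, noiseless = TRUE)[, , 1]
  top2 <- arrayInd(order(img2, decreasing = TRUE)[1:2], dim(img2))
  expect_setequal(top2[, 1], c(4, 4))
  expect_setequal(top2[, 2], c(4, 14))
  expect_error(render_frames(one, list(pixelsize_nm = 0, width_px = 4,
                                       height_px = 4)), "pixelsize")
  expect_error(render_frames(simple_table(1e6, 0), cam), "bounds")
})

test_that("gen_gfp_stack renders linear, defocus-decaying spots", {
  layout <- list(n_slices = 9, step_nm = 50, psf_sigma_nm = 180,
                 pixelsize_nm = 100, width_px = 30, height_px = 30,
                 background = 0)
  # site at a pixel center; the peak pixel equals the amplitude up to
  # pixel integration (sigma/pixel = 1.8 gives ~3% flattening)
  one <- gen_gfp_stack(data.frame(x = 1550, y = 1550, amplitude = 300),
                       layout)
  focus <- one$data[, , one$focus_slice]
  expect_equal(which(focus == max(focus), arr.ind = TRUE)[1, ],
               c(row = 16L, col = 16L), ignore_attr = TRUE)
  expect_equal(max(focus), 300, tolerance = 0.03)
  # amplitude decays away from focus
  peaks <- apply(one$data, 3, max)
  expect_true(all(diff(peaks[1:one$focus_slice]) > 0))
  # linearity: two sites sum exactly
  a <- gen_gfp_stack(data.frame(x = 1200, y = 1500, amplitude = 300), layout)
  b <- gen_gfp_stack(data.frame(x = 1600, y = 1500, amplitude = 200), layout)
  ab <- gen_gfp_stack(data.frame(x = c(1200, 1600), y = c(1500, 1500),
                                 amplitude = c(300, 200)), layout)
  expect_equal(ab$data, a$data + b$data, tolerance = 1e-12)
  # slice bookkeeping for the downstream 7-slice projection
  big <- gen_gfp_stack(data.frame(x = 1500, y = 1500, amplitude = 10),
                       modifyList(layout, list(n_slices = 81)))
  half <- 3L
  idx <- (big$focus_slice - half):(big$focus_slice + half)
  expect_length(idx, 7L)
  expect_true(all(idx >= 1 & idx <= 81))
  expect_error(gen_gfp_stack(data.frame(x = 1, y = 1, amplitude = 1),
                             modifyList(layout, list(n_slices = 0))),
               "n_slices")
})
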