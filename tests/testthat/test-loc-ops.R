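test_that("group_localizations applies the chain rules", {
  # frames 1 and 3 (gap 1), 50 nm apart: merged
  t1 <- simple_table(c(0, 50), c(0, 0), frame = c(1L, 3L), photons = 100)
  g <- group_localizations(t1)
  expect_equal(nrow(g), 1L)
  expect_equal(g$x_nm, 25)                       # equal photons: midpoint
  expect_equal(g$frame, 1L)
  expect_equal(g$photons, 200)
  expect_equal(g$precision_nm, 10 / sqrt(2))     # inverse-variance combined
  # frames 1 and 4: gap exceeded, not merged
  t2 <- simple_table(c(0, 50), c(0, 0), frame = c(1L, 4L))
  expect_equal(nrow(group_localizations(t2)), 2L)
  # beyond the 75 nm radius: not merged
  t3 <- simple_table(c(0, 80), c(0, 0), frame = c(1L, 2L))
  expect_equal(nrow(group_localizations(t3)), 2L)
})

test_that("grouping never grows the table and is idempotent", {
  set.seed(31)
  for (rep in 1:5) {
    n <- 60
    tab <- simple_table(runif(n, 0, 2000), runif(n, 0, 2000),
                        frame = sample.int(30, n, TRUE),
                        photons = runif(n, 500, 2000))
    g1 <- group_localizations(tab)
    expect_lte(nrow(g1), nrow(tab))
    g2 <- group_localizations(g1)
    expect_equal(nrow(g2), nrow(g1))
    expect_equal(g2$x_nm, g1$x_nm, tolerance = 1e-12)
  }
})

test_that("filter_localizations keeps boundaries and counts violators", {
  tab <- simple_table(1:6 * 10, 1:6 * 10, precision = c(29, 30, 31, 10, 10, 10),
                      sigma = c(100, 100, 100, 175, 176, 100))
  out <- filter_localizations(tab)
  expect_equal(nrow(out), 4L)                    # 29/30 kept, 31 and 176 out
  # brute-force count oracle on random tables
  set.seed(32)
  for (rep in 1:5) {
    n <- 200
    tab <- simple_table(runif(n), runif(n), precision = runif(n, 0, 60),
                        sigma = runif(n, 50, 250))
    k <- sum(tab$precision_nm > 30 | tab$sigma_nm > 175)
    expect_equal(nrow(filter_localizations(tab)), n - k)
  }
  expect_error(filter_localizations(data.frame(x_nm = 1)), "precision_nm")
})

test_that("render_image normalizes, floors sigma, and localizes mass", {
  st <- render_settings(pixel_size = 5, min_sigma = 6)
  # minimum sigma rule: precision 3 renders at 6 nm
  one <- simple_table(500, 500, precision = 3)
  img <- render_image(one, st, xlim = c(400, 600), ylim = c(400, 600))
  expect_equal(sum(img), 1, tolerance = 1e-9)
  pk <- which(img == max(img), arr.ind = TRUE)[1, ]
  expect_equal(unname(pk), c(20, 20))            # pixel containing (500,500)
  # rendered width ~6 nm: compare variance against the analytic value
  xs <- 400 + (seq_len(ncol(img)) - 0.5) * 5
  v <- sum(img * outer(rep(1, 40), (xs - 500)^2)) / sum(img)
  expect_equal(sqrt(v), sqrt(6^2 + 5^2 / 12), tolerance = 0.05)
  # n interior records: sum = n
  set.seed(33)
  many <- simple_table(runif(40, 300, 700), runif(40, 300, 700),
                       precision = runif(40, 3, 20))
  img2 <- render_image(many, st, xlim = c(0, 1000), ylim = c(0, 1000))
  expect_equal(sum(img2), 40, tolerance = 1e-6)
})

test_that("drift_correct recovers injected drift and honours skip rules", {
  set.seed(34)
  nmol <- 300; nf <- 8000
  pos <- cbind(runif(nmol, 500, 4500), runif(nmol, 500, 4500))
  drift <- outer(seq_len(nf) - 1, c(50, -30) / (nf - 1))
  nb <- 6
  frame <- sample.int(nf, nmol * nb, replace = TRUE)
  frame[1:2] <- c(1L, nf)                        # pin the movie length
  id <- rep(seq_len(nmol), each = nb)
  xy <- pos[id, ] + matrix(rnorm(2 * nmol * nb, 0, 12), ncol = 2) +
    drift[frame, ]
  tab <- simple_table(xy[, 1], xy[, 2], frame = frame, precision = 12)
  dc <- drift_correct(tab)
  expect_false(dc$skipped)
  resid <- dc$drift - drift
  resid <- sweep(resid, 2, colMeans(resid))      # gauge: window 1 reference
  expect_lt(sqrt(mean(resid^2)), 5)
  # exact invertibility
  back <- dc$table
  back$x_nm <- back$x_nm + dc$drift[back$frame, 1]
  back$y_nm <- back$y_nm + dc$drift[back$frame, 2]
  expect_lt(max(abs(back$x_nm - tab$x_nm), abs(back$y_nm - tab$y_nm)), 1e-9)
  # movies under 5000 frames are never corrected
  short <- tab; short$frame <- pmin(short$frame, 3000L)
  expect_true(drift_correct(short)$skipped)
  # stationary data: skip with small_drift
  still <- simple_table(pos[id, 1] + rnorm(nmol * nb, 0, 12),
                        pos[id, 2] + rnorm(nmol * nb, 0, 12),
                        frame = frame, precision = 12)
  d0 <- drift_correct(still)
  expect_true(d0$skipped)
  expect_equal(d0$reason, "small_drift")
  expect_equal(d0$table, still)
})

test_that("estimate_channel_transform recovers homographies", {
  set.seed(35)
  pts <- cbind(runif(1000, 0, 40000), runif(1000, 0, 40000))
  # identity from identical point sets
  id <- estimate_channel_transform(pts[1:20, ], pts[1:20, ])
  expect_lt(max(abs(id$matrix - diag(3))), 1e-9)
  expect_lt(id$rms_error, 1e-6)
  # known homography + 3 nm noise: better than 10 nm anywhere in the field
  H <- rbind(c(1.01, 0.002, 30), c(-0.003, 0.99, -20), c(1e-7, -2e-7, 1))
  mov <- apply_transform(H, pts) + matrix(rnorm(2000, 0, 3), ncol = 2)
  tr <- estimate_channel_transform(pts, mov)
  grid <- as.matrix(expand.grid(seq(0, 40000, 2000), seq(0, 40000, 2000)))
  err <- sqrt(rowSums((apply_transform(tr, apply_transform(H, grid)) -
                         grid)^2))
  expect_lt(max(err), 10)
  # preconditions
  expect_error(estimate_channel_transform(pts[1:4, ], pts[1:4, ]), "5 point")
  line <- cbind(1:10, 2 * (1:10))
  expect_error(estimate_channel_transform(line, line), "collinear")
})
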