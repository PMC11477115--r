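test_that("neutrality regression recovers anchor geometries", {
  x <- seq(0.2, 0.4, length.out = 10)
  fit <- neutrality_regression(x, x)
  expect_equal(fit$slope, 1)
  expect_equal(fit$r, 1)
  expect_identical(fit$n, 10L)

  flat <- neutrality_regression(rep(0.4, 10), x)
  expect_equal(flat$slope, 0)

  expect_warning(z <- neutrality_regression(x, rep(0.3, 10)), "zero variance")
  expect_true(is.na(z$slope))
  expect_error(neutrality_regression(c(.1, .2), c(.1, .2)), "at least 3")
})

test_that("ENC-plot ratios, histogram and band fraction are consistent", {
  # a gene exactly on the curve has ratio 0
  ep0 <- enc_plot(gc3s = 0.3, enc_obs = expected_enc(0.3))
  expect_equal(ep0$data$enc_ratio, 0)

  ep <- enc_plot(gc3s = c(0.5, 0.2, 0.7), enc_obs = c(30, 40, 55))
  expect_equal(ep$data$enc_ratio[1], (60.5 - 30) / 60.5)
  expect_identical(sum(ep$histogram$count), nrow(ep$data))
  expect_true(all(diff(ep$histogram$bin_left) > 0))
  # band fraction invariant to gene order
  ep_rev <- enc_plot(gc3s = c(0.7, 0.2, 0.5), enc_obs = c(55, 40, 30))
  expect_equal(ep_rev$frac_in_band, ep$frac_in_band)
  # ratio < 0 iff the gene sits above the expected curve
  above <- enc_plot(0.5, expected_enc(0.5) + 1)
  expect_lt(above$data$enc_ratio, 0)
})

test_that("PR2 coordinates sit at parity and reflect under base swaps", {
  parity <- pr2_plot(data.frame(A3 = 10, T3 = 10, G3 = 7, C3 = 7))
  expect_equal(unlist(parity$data[c("x", "y")]), c(x = 0.5, y = 0.5))

  p <- pr2_plot(data.frame(A3 = 10, T3 = 30, G3 = 30, C3 = 10))
  expect_equal(p$data$x, 0.75)
  expect_equal(p$data$y, 0.25)
  expect_identical(unname(p$quadrants["right", "bottom"]), 1L)

  swapped <- pr2_plot(data.frame(A3 = 30, T3 = 10, G3 = 30, C3 = 10))
  expect_equal(swapped$data$y, 1 - p$data$y)
  expect_equal(swapped$data$x, p$data$x)

  expect_warning(dropped <- pr2_plot(data.frame(A3 = 0, T3 = 0, G3 = 3, C3 = 2)),
                 "dropped")
  expect_identical(nrow(dropped$data), 0L)
})

test_that("correspondence analysis matches the eigen oracle and chi-square identity", {
  m <- matrix(c(12, 3, 7,
                2, 9, 4,
                5, 6, 11), 3, 3, byrow = TRUE,
              dimnames = list(paste0("g", 1:3), paste0("c", 1:3)))
  ca <- correspondence_analysis(m)
  expect_equal(ca$inertia, brute_ca_inertia(m), tolerance = 1e-8)
  chi <- suppressWarnings(stats::chisq.test(m))$statistic
  expect_equal(ca$total_inertia, unname(chi) / sum(m), tolerance = 1e-10)
  expect_equal(sum(ca$inertia_pct), 100)
  expect_true(all(diff(ca$inertia) <= 1e-12))

  # cross-check against an independent CA implementation
  cca <- vegan::cca(m)
  expect_equal(unname(ca$inertia), unname(cca$CA$eig), tolerance = 1e-8)

  # identical rows: no variation at all
  same <- matrix(rep(c(4, 2, 6), each = 3), 3, 3,
                 dimnames = list(paste0("g", 1:3), paste0("c", 1:3)))
  ca0 <- correspondence_analysis(same)
  expect_identical(ca0$n_axes, 0L)
  expect_equal(ca0$total_inertia, 0)

  # permuting rows permutes row coordinates and leaves inertia unchanged
  perm <- c(3, 1, 2)
  cap <- correspondence_analysis(m[perm, ])
  expect_equal(cap$inertia_pct, ca$inertia_pct)
  expect_equal(abs(cap$row_coords[rownames(ca$row_coords), , drop = FALSE]),
               abs(ca$row_coords))

  # undefined entries count as zero; all-zero columns are dropped
  mna <- cbind(m, c0 = c(0, 0, 0))
  expect_message(can <- correspondence_analysis(mna), "all-zero")
  expect_equal(can$inertia, ca$inertia)
})

test_that("CA row coordinates reproduce chi-square distances between profiles", {
  set.seed(8)
  m <- matrix(stats::rpois(5 * 4, 10) + 1, 5, 4,
              dimnames = list(paste0("g", 1:5), paste0("c", 1:4)))
  ca <- correspondence_analysis(m)
  # full-rank principal coordinates preserve chi-square distances
  prof <- m / rowSums(m)
  cm <- colSums(m) / sum(m)
  d_chi <- as.matrix(stats::dist(prof %*% diag(1 / sqrt(cm))))
  d_ca <- as.matrix(stats::dist(ca$row_coords))
  expect_equal(d_ca, d_chi, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("correlation suite handles anchors, missingness and constants", {
  df <- data.frame(a = 1:10, b = (1:10)^2, c = -(1:10), d = rep(1, 10),
                   e = c(NA, 2:10))
  out <- correlation_suite(df, list(c("a", "b"), c("a", "c"), c("a", "e")))
  expect_equal(out$rho[1], 1)
  expect_equal(out$rho[2], -1)
  expect_identical(out$n[3], 9L)  # pairwise-complete

  expect_warning(cc <- correlation_suite(df, list(c("a", "d"))), "constant")
  expect_true(is.na(cc$rho))
  expect_error(correlation_suite(df, list(c("a", "nope"))), "unknown variable")

  pe <- correlation_suite(df, list(c("a", "b")), method = "pearson")
  expect_lt(pe$rho, 1)  # pearson on a convex curve is below rank correlation
})
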