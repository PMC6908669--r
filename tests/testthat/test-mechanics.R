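test_that("WLC interpolation formula: origin, midpoint value, monotonicity", {
  expect_equal(wlc_force(0, p = 0.4, Lc = 60), 0)
  # direct evaluation at x = Lc/2: F = 1.25 * kT / p
  expect_equal(wlc_force(30, p = 0.4, Lc = 60, kT = 4.114),
               1.25 * 4.114 / 0.4, tolerance = 1e-12)
  expect_equal(1.25 * 4.114 / 0.4, 12.85625)
  x <- seq(0, 0.99 * 60, length.out = 500)
  expect_true(all(diff(wlc_force(x, 0.4, 60)) > 0))
  expect_error(wlc_force(60, 0.4, 60), "extension")
})

test_that("event detection: ground truth, flat curve, dominant threshold", {
  # noise-free 3-increment curve: every rupture found within one grid step
  cv <- simulate_force_curve(noise_sd = 0, seed = 1)
  gt <- cv$metadata$ground_truth
  ev <- detect_unfolding_events(cv)
  expect_equal(nrow(ev), length(gt$lc_schedule))
  expect_true(all(abs(ev$peak_extension - gt$rupture_extensions) <= 0.2 + 1e-9))

  flat <- force_curve(seq(0.1, 10, by = 0.1), rep(0, 100))
  expect_equal(nrow(detect_unfolding_events(flat)), 0)

  # threshold above the global force range: nothing detected
  ev2 <- detect_unfolding_events(cv, drop_threshold = 1e5)
  expect_equal(nrow(ev2), 0)
})

test_that("inter-segment drops match the spec construction example", {
  # schedule [30, 50, 70] without final detachment: exactly 2 drops, each at
  # the commanded rupture force
  cv <- simulate_force_curve(lc_schedule = c(30, 50, 70), rupture_forces = 50,
                             noise_sd = 0, detach = FALSE, seed = 1)
  drops <- which(diff(cv$force) < -20)
  expect_length(drops, 2)
  expect_equal(cv$force[drops], c(50, 50), tolerance = 1)

  # degenerate schedule: single Lc, no noise -> curve equals wlc_force
  cv2 <- simulate_force_curve(lc_schedule = 40, rupture_forces = 45,
                              noise_sd = 0, detach = FALSE, seed = 1)
  expect_equal(cv2$force, wlc_force(cv2$extension, 0.4, 40), tolerance = 1e-9)
})

test_that("contour-length fitting: noise-free and noisy round trips", {
  # noise-free single segment generated at Lc = 60 recovers it to 1e-3
  cv <- simulate_force_curve(lc_schedule = 60, rupture_forces = 50,
                             noise_sd = 0, seed = 1)
  ev <- detect_unfolding_events(cv)
  fit <- fit_segment_contour_lengths(cv, ev)
  expect_equal(fit$fitted_Lc, 60, tolerance = 1e-3)

  # with the instrument's stated force accuracy (8.5 pN), Lc within 5%
  # and a true increment of 20 nm recovered within 5%
  cv2 <- simulate_force_curve(lc_schedule = c(60, 80), rupture_forces = 50,
                              noise_sd = 8.5, seed = 12)
  ev2 <- detect_unfolding_events(cv2)
  fit2 <- fit_segment_contour_lengths(cv2, ev2)
  expect_equal(nrow(fit2), 2)
  expect_true(all(abs(fit2$fitted_Lc - c(60, 80)) / c(60, 80) < 0.05))
  expect_equal(fit2$delta_Lc[2], 20, tolerance = 20 * 0.05)
})

test_that("delta-Lc histogram: pooled modes, degenerate binnings", {
  evs <- lapply(1:50, function(s) {
    cv <- simulate_force_curve(seed = s)
    suppressWarnings(
      fit_segment_contour_lengths(cv, detect_unfolding_events(cv)))
  })
  hist <- delta_lc_histogram(evs, bin_width = 5)
  # modes land in the bins containing 20, 40 and 60 nm
  top3 <- hist$center[order(-hist$count)][1:3]
  expect_setequal(top3, c(20, 40, 60))
  expect_true(all(diff(hist$center) == 5))   # empty bins retained

  one <- delta_lc_histogram(list(data.frame(delta_Lc = c(NA, 35))), 5)
  expect_equal(sum(one$count > 0), 1)
  big <- delta_lc_histogram(evs, bin_width = 500)
  expect_equal(sum(big$count > 0), 1)
})

test_that("parallel dimer stretching halves apparent increments", {
  dl <- unlist(lapply(1:10, function(s) {
    cv <- simulate_force_curve(lc_schedule = c(30, 70), dimer_parallel = TRUE,
                               seed = s)
    fit <- suppressWarnings(
      fit_segment_contour_lengths(cv, detect_unfolding_events(cv)))
    fit$delta_Lc[-1]
  }))
  expect_equal(mean(dl), 20, tolerance = 1)
  # and twice the number of unfolding peaks: 2 increments instead of 1
  cv <- simulate_force_curve(lc_schedule = c(30, 70), dimer_parallel = TRUE,
                             noise_sd = 0, seed = 1)
  expect_equal(nrow(detect_unfolding_events(cv)), 3)
})

test_that("disulfide-constrained extension bound follows interval arithmetic", {
  st <- line_structure(11, spacing = 1)   # initial N-C distance 10 A = 1 nm
  expect_equal(max_extension_bound(st, NULL), 10 * 0.365 - 1.0)
  bridges <- data.frame(residue_a = "A:3:", residue_b = "A:8:")
  expect_equal(max_extension_bound(st, bridges),
               (10 - 5) * 0.365 + 0.6 - 1.0)
  # nested bridges collapse by interval union
  nested <- data.frame(residue_a = c("A:3:", "A:4:"),
                       residue_b = c("A:8:", "A:7:"))
  expect_equal(max_extension_bound(st, nested),
               max_extension_bound(st, bridges))
  # brute-force interval enumeration oracle on random bridge sets
  set.seed(8)
  for (rep in 1:20) {
    n_b <- sample(1:4, 1)
    a <- sample(1:10, n_b, replace = TRUE)
    b <- pmin(a + sample(1:5, n_b, replace = TRUE), 11)
    keep <- b > a
    if (!any(keep)) next
    br <- data.frame(residue_a = sprintf("A:%d:", a[keep]),
                     residue_b = sprintf("A:%d:", b[keep]))
    # oracle: mark each link inside any bridge, count merged regions directly
    locked <- rep(FALSE, 10)
    for (k in seq_len(sum(keep)))
      locked[a[keep][k]:(b[keep][k] - 1)] <- TRUE
    regions <- sum(diff(c(FALSE, locked)) == 1)
    expected <- (10 - sum(locked)) * 0.365 + regions * 0.6 - 1.0
    expect_equal(max_extension_bound(st, br), expected, tolerance = 1e-12)
  }
  # monotone: adding a bridge never increases the bound
  more <- rbind(bridges, data.frame(residue_a = "A:9:", residue_b = "A:11:"))
  expect_lte(max_extension_bound(st, more), max_extension_bound(st, bridges))
  expect_error(max_extension_bound(st,
    data.frame(residue_a = "A:3:", residue_b = "B:99:")), "not found")
})

test_that("force curves round-trip through two-column files", {
  cv <- simulate_force_curve(seed = 3)
  path <- tempfile(fileext = ".txt")
  write_force_curve(cv, path)
  back <- read_force_curve(path)
  expect_equal(back$extension, cv$extension, tolerance = 1e-6)
  expect_equal(back$force, cv$force, tolerance = 1e-6)
})
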