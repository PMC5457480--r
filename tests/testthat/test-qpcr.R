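test_that("2^-ddCt reproduces hand-computed relative quantities", {
  expect_equal(delta_delta_ct(20, 18, 20, 18), 1.0)
  expect_equal(delta_delta_ct(19, 18, 20, 18), 2.0)  # one cycle = doubling
  expect_equal(delta_delta_ct(21.5, 18.0, 20.0, 17.5), 0.5)
  expect_error(delta_delta_ct(NA, 18, 20, 18), "non-finite")
  expect_error(delta_delta_ct(Inf, 18, 20, 18), "non-finite")
})

test_that("shifting both target Cts by one cycle halves the quantity", {
  set.seed(4)
  for (i in 1:20) {
    ct <- runif(4, 15, 30)
    q0 <- delta_delta_ct(ct[1], ct[2], ct[3], ct[4])
    q1 <- delta_delta_ct(ct[1] + 1, ct[2], ct[3], ct[4])
    expect_equal(q1, q0 / 2)
    # shifting the test target and origin target together cancels
    q2 <- delta_delta_ct(ct[1] + 1, ct[2], ct[3] + 1, ct[4])
    expect_equal(q2, q0)
  }
})

make_plate <- function(levels, ct_base = 25, ref_base = 20,
                       n_exp = 2, n_rep = 3, jitter = NULL) {
  markers <- sprintf("M%02d", seq_along(levels))
  rows <- list()
  k <- 1
  for (ex in seq_len(n_exp)) for (rp in seq_len(n_rep)) {
    for (smp in c("test", "origin")) {
      T_ <- if (smp == "test") levels else rep(1, length(levels))
      ct <- ct_base - log2(T_)
      if (!is.null(jitter)) ct <- ct + jitter(length(ct))
      rows[[k]] <- data.frame(marker_id = c(markers, "REF"), sample = smp,
                              target = c(rep("marker", length(levels)),
                                         "reference"),
                              experiment = ex, replicate = rp,
                              ct = c(ct, ref_base), stringsAsFactors = FALSE)
      k <- k + 1
    }
  }
  qpcr_plate(do.call(rbind, rows), markers)
}

test_that("copy profile recovers noiseless levels exactly", {
  flat <- relative_copy_profile(make_plate(rep(1, 6)))
  expect_equal(flat$R, rep(1, 6))
  step <- relative_copy_profile(make_plate(rep(c(1, 2), c(10, 11))))
  expect_equal(step$R, rep(c(1, 2), c(10, 11)))
})

test_that("replicates average on the Ct scale before ddCt", {
  markers <- "M01"
  wells <- rbind(
    data.frame(marker_id = "M01", sample = "test", target = "marker",
               experiment = 1, replicate = 1:3, ct = c(20.0, 20.2, 19.8)),
    data.frame(marker_id = "REF", sample = "test", target = "reference",
               experiment = 1, replicate = 1, ct = 18),
    data.frame(marker_id = "M01", sample = "origin", target = "marker",
               experiment = 1, replicate = 1, ct = 21),
    data.frame(marker_id = "REF", sample = "origin", target = "reference",
               experiment = 1, replicate = 1, ct = 18))
  prof <- relative_copy_profile(qpcr_plate(wells, markers))
  # mean test Ct 20.0 -> ddCt = (20-18) - (21-18) = -1 -> R = 2
  expect_equal(prof$R, 2)
})

test_that("profile is invariant to well row order", {
  plate <- make_plate(rep(c(1, 2), c(4, 4)),
                      jitter = function(n) rnorm(n, 0, 0.05))
  set.seed(6)
  shuffled <- qpcr_plate(plate$wells[sample(nrow(plate$wells)), ],
                        plate$marker_order)
  expect_equal(relative_copy_profile(shuffled),
               relative_copy_profile(plate))
})

test_that("missing reference wells are reported with their location", {
  plate <- make_plate(rep(1, 3))
  wells <- plate$wells[!(plate$wells$target == "reference" &
                           plate$wells$sample == "origin" &
                           plate$wells$experiment == 2), ]
  expect_error(relative_copy_profile(qpcr_plate(wells, plate$marker_order)),
               "origin.*experiment 2")
})

test_that("breakpoint detection nails exact steps and rejects constants", {
  bp <- detect_breakpoint(c(1, 1, 1, 2, 2))
  expect_true(bp$step_called)
  expect_equal(bp$changepoint, 3)
  expect_equal(c(bp$left_call, bp$right_call), c(1, 2))
  expect_equal(c(bp$left_level, bp$right_level), c(1, 2))

  flat <- detect_breakpoint(rep(1.3, 8))
  expect_false(flat$step_called)
  expect_true(is.na(flat$changepoint))
  expect_error(detect_breakpoint(1.0), "at least 2")
  expect_error(detect_breakpoint(c(1, -1)), "positive")
})

test_that("selected changepoint equals the independent brute-force fit", {
  set.seed(12)
  for (i in 1:50) {
    n <- sample(4:15, 1)
    j_true <- sample(1:(n - 1), 1)
    R <- 2^(c(rep(0, j_true), rep(1, n - j_true)) + rnorm(n, 0, 0.2))
    bp <- detect_breakpoint(R)
    orc <- oracle_changepoint(R)
    if (bp$step_called) {
      expect_equal(bp$changepoint, orc$j)
      expect_equal(bp$sse, orc$sse, tolerance = 1e-10)
    }
  }
})

test_that("fitted levels snap to the candidate copy ratios", {
  bp <- detect_breakpoint(c(0.96, 1.05, 0.99, 2.1, 1.94, 2.02))
  expect_equal(bp$changepoint, 3)
  expect_equal(c(bp$left_call, bp$right_call), c(1, 2))
  expect_false(bp$left_level == 1)  # raw level reported un-snapped
})

test_that("Monte-Carlo recovery at the design noise level", {
  hits <- vapply(1:60, function(s) {
    q <- simulate_qpcr_plate(qpcr_sim_config(seed = 5000 + s))
    bp <- detect_breakpoint(relative_copy_profile(q$plate))
    isTRUE(bp$changepoint == 10)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
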