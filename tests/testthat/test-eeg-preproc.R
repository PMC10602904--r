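# Preprocessing chain: re-referencing, ocular regression, epoching,
# amplitude rejection, and file IO.

toy_rec <- function(n_ch = 3, n_samp = 1000, rate = 250, seed = 1,
                    with_aux = TRUE) {
  labels <- c("Fz", "Cz", "Pz")[seq_len(n_ch)]
  types <- rep("eeg", n_ch)
  data <- withr::with_seed(seed, matrix(stats::rnorm(n_ch * n_samp, sd = 10),
                                        n_ch))
  if (with_aux) {
    aux <- withr::with_seed(seed + 1,
                            matrix(stats::rnorm(2 * n_samp, sd = 5), 2))
    data <- rbind(data, aux)
    labels <- c(labels, "M1", "M2")
    types <- c(types, "mastoid", "mastoid")
  }
  eeg_recording(data, rate, labels, types,
                events = data.frame(sample = c(100L, 400L),
                                    code = c(1L, 2L),
                                    video_id = c("vid01", "vid02")))
}

test_that("mastoid re-referencing equals per-sample subtraction", {
  rec <- toy_rec()
  out <- rereference_mastoids(rec)
  ref <- colMeans(rec$data[c("M1", "M2"), ])
  for (ch in c("Fz", "Cz", "Pz")) {   # brute-force loop oracle
    expect_equal(out$data[ch, ], rec$data[ch, ] - ref)
  }
  # zero mastoids leave data unchanged
  rec0 <- rec; rec0$data[c("M1", "M2"), ] <- 0
  expect_equal(rereference_mastoids(rec0)$data[1:3, ], rec$data[1:3, ])
  # all channels equal to the mastoid mean -> scalp all zero
  rec1 <- rec
  for (ch in 1:3) rec1$data[ch, ] <- ref
  expect_equal(max(abs(rereference_mastoids(rec1)$data[1:3, ])), 0)
  expect_error(rereference_mastoids(toy_rec(with_aux = FALSE)), "M1")
})

test_that("bandpass validates its band edges", {
  rec <- toy_rec()
  expect_error(bandpass(rec, hp_hz = 40, lp_hz = 30), "hp < lp")
  expect_error(bandpass(rec, hp_hz = 0.1, lp_hz = 200), "Nyquist")
})

test_that("ocular regression recovers known propagation factors", {
  rate <- 250; n <- 5000
  set.seed(7)
  blink <- withr::with_seed(7, {
    t <- seq_len(n)
    rowSums(vapply(c(800, 2400, 4100), function(c0) {
      150 * exp(-((t - c0) / 40)^2)
    }, numeric(n)))
  })
  noise <- withr::with_seed(8, matrix(stats::rnorm(3 * n, sd = 5), 3))
  b_true <- c(Fz = 0.12, Cz = 0.08, Pz = 0.04)
  scalp <- noise + outer(b_true, blink * 1.3)  # bipolar VEOG = 1.3 * blink
  data <- rbind(scalp,
                HEOGL = stats::rnorm(n, sd = 2),
                HEOGR = stats::rnorm(n, sd = 2),
                VEOGU = blink + stats::rnorm(n, sd = 2),
                VEOGL = -0.3 * blink + stats::rnorm(n, sd = 2))
  rec <- eeg_recording(data, rate, c("Fz", "Cz", "Pz", "HEOGL", "HEOGR",
                                     "VEOGU", "VEOGL"),
                       c(rep("eeg", 3), rep("eog", 4)))
  out <- correct_ocular(rec)
  fac <- out$meta$ocular_factors
  expect_equal(fac$b_v, unname(b_true), tolerance = 0.05)
  # corrected channels no longer track the blink
  for (ch in 1:3) {
    expect_lt(abs(stats::cor(out$data[ch, ], blink)), 0.1)
  }
  # channel orthogonal to EOG is untouched (up to regression noise)
  expect_equal(out$data["Pz", ], scalp[3, ] - b_true["Pz"] * blink * 1.3,
               tolerance = 0.3, ignore_attr = TRUE)
})

test_that("scalp channel that is an exact EOG multiple is nulled", {
  n <- 2000
  veogu <- withr::with_seed(3, stats::rnorm(n, sd = 30))
  data <- rbind(Fz = 0.5 * veogu, HEOGL = stats::rnorm(n, sd = 1e-4),
                HEOGR = stats::rnorm(n, sd = 1e-4),
                VEOGU = veogu, VEOGL = rep(0, n))
  rec <- eeg_recording(data, 250, rownames(data),
                       c("eeg", rep("eog", 4)))
  out <- correct_ocular(rec)
  expect_equal(out$meta$ocular_factors$b_v[1], 0.5, tolerance = 0.01)
  expect_lt(stats::sd(out$data["Fz", ]), 0.05 * stats::sd(data["Fz", ]))
})

test_that("zero-variance EOG yields zero factors with a warning", {
  rec <- toy_rec(with_aux = FALSE)
  data <- rbind(rec$data, matrix(0, 4, ncol(rec$data)))
  rec2 <- eeg_recording(data, rec$rate_hz,
                        c(rec$channel_labels, "HEOGL", "HEOGR", "VEOGU",
                          "VEOGL"),
                        c(rec$channel_types, rep("eog", 4)))
  expect_warning(out <- correct_ocular(rec2), "variance")
  expect_equal(out$meta$ocular_factors$b_h, c(0, 0, 0))
  expect_equal(out$data[1:3, ], rec$data)
})

test_that("epoching extracts the documented windows and flags overruns", {
  rec <- toy_rec(n_samp = 1200, rate = 250)
  ep <- epoch(rec, window_s = c(0, 2))
  expect_equal(dim(ep$epochs), c(2, 5, 500))
  # manual slice comparison (overlapping events are independent)
  expect_equal(ep$epochs[1, , ], unname(rec$data[, 100:599]))
  expect_equal(ep$epochs[2, , ], unname(rec$data[, 400:899]))
  # event too close to the end is flagged, not dropped
  rec2 <- rec
  rec2$events <- rbind(rec2$events,
                       data.frame(sample = 1100L, code = 3L,
                                  video_id = "vid03"))
  ep2 <- epoch(rec2, window_s = c(0, 2))
  expect_equal(dim(ep2$epochs)[1], 3)
  expect_equal(ep2$rejection_mask, c(FALSE, FALSE, TRUE))
  # 5 s at 500 Hz = 2500 samples per trial
  rec3 <- eeg_recording(matrix(0, 1, 4000), 500, "Cz",
                        events = data.frame(sample = 1L, code = 1L))
  expect_equal(dim(epoch(rec3, c(0, 5))$epochs)[3], 2500)
  # zero events: empty epoch set, no error
  rec4 <- rec; rec4$events <- rec$events[0, ]
  expect_equal(dim(epoch(rec4)$epochs)[1], 0)
})

test_that("amplitude rejection flags exactly the violating trials", {
  rec <- toy_rec(n_samp = 1200)
  ep <- epoch(rec, window_s = c(0, 2))
  expect_equal(sum(reject_amplitude(ep, 75)$rejection_mask), 0)
  # push one sample of trial 2 beyond the bound
  ep$epochs[2, 1, 17] <- 80
  out <- reject_amplitude(ep, 75)
  expect_equal(out$rejection_mask, c(FALSE, TRUE))
  # brute-force oracle over a random epoch set
  set.seed(11)
  eps <- array(stats::rnorm(10 * 3 * 50, sd = 40), c(10, 3, 50))
  es <- epoch_set(eps, 250, c("Fz", "Cz", "Pz"))
  out2 <- reject_amplitude(es, 75)
  oracle <- vapply(seq_len(10), function(i) any(abs(eps[i, , ]) > 75),
                   logical(1))
  expect_equal(out2$rejection_mask, oracle)
  expect_error(reject_amplitude(es, -5), "positive")
})

test_that("the full chain is deterministic and filter-before-epoch", {
  cohort <- small_cohort()
  rec <- cohort$recordings[[1]]
  ep1 <- preprocess(rec)
  ep2 <- preprocess(rec)
  expect_identical(ep1$epochs, ep2$epochs)
  # epoching a filtered continuous record equals the chain's epochs
  cont <- preprocess_continuous(rec)
  ep3 <- epoch(cont, c(0, 5))
  expect_equal(ep1$epochs, ep3$epochs)
})

test_that("BrainVision triplet round-trips data, rate, labels, events", {
  cohort <- small_cohort()
  rec <- cohort$recordings[[1]]
  base <- file.path(withr::local_tempdir(), "rec01")
  write_brainvision(rec, base)
  rec2 <- read_brainvision(paste0(base, ".vhdr"))
  expect_equal(rec2$rate_hz, rec$rate_hz)
  expect_equal(rec2$channel_labels, rec$channel_labels)
  expect_equal(rec2$events$sample, rec$events$sample)
  expect_equal(rec2$data, rec$data, tolerance = 1e-6)  # float32 storage
})
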