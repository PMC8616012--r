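test_that("baseline estimation: constant, noisy and pulsed traces", {
  bl <- estimate_baseline(rep(2.5, 5000), window = 101)
  expect_equal(bl$baseline, rep(2.5, 5000))
  expect_equal(bl$noise_sd, 0)
  set.seed(10)
  bn <- estimate_baseline(rnorm(1e5, sd = 0.01), window = 501)
  expect_lt(abs(bn$noise_sd - 0.01) / 0.01, 0.10)
  # sparse pulses (~1% duty cycle) do not drag the median baseline
  x <- rnorm(5e4, sd = 0.01)
  centers <- seq(2000, 48000, by = 5000)
  for (c0 in centers)
    x[(c0 - 20):(c0 + 20)] <- x[(c0 - 20):(c0 + 20)] +
      exp(-((-20:20)^2) / 50)
  bp <- estimate_baseline(x, window = 501)
  expect_lt(max(abs(bp$baseline)), 0.05)
  expect_error(estimate_baseline(1:10, window = 50), "longer than trace")
  expect_error(estimate_baseline(1:10, window = 2), ">= 3")
})

test_that("a single planted pulse yields one event with the planted SNR", {
  set.seed(11)
  tr <- plant_pulses(2e4, centers = 1e4, amplitude = 0.5, sigma = 10,
                     noise_sd = 0.005)
  ev <- detect_pulses(tr, k_threshold = 5, min_width = 8)
  expect_equal(nrow(ev), 1L)
  # summed-channel noise sd = sqrt(4)*0.005 = 0.01 -> snr ~ 0.5/0.01 = 50
  expect_gt(ev$snr, 35)
  expect_lt(ev$snr, 70)
  expect_true(ev$start <= 1e4 && 1e4 < ev$end)
})

test_that("pure noise yields no events; separation controls merging", {
  set.seed(12)
  tr <- plant_pulses(1e5, centers = integer(0), amplitude = numeric(0),
                     noise_sd = 0.01)
  expect_equal(nrow(detect_pulses(tr, k_threshold = 5, min_width = 8)), 0L)
  # two pulses: far apart -> 2 events, close -> merged into 1
  tr2 <- plant_pulses(2e4, centers = c(8000, 12000), amplitude = 0.5,
                      sigma = 8, noise_sd = 0.004)
  expect_equal(nrow(detect_pulses(tr2, k_threshold = 5,
                                  min_separation = 200)), 2L)
  tr3 <- plant_pulses(2e4, centers = c(9900, 10100), amplitude = 0.5,
                      sigma = 8, noise_sd = 0.004)
  expect_equal(nrow(detect_pulses(tr3, k_threshold = 5,
                                  min_separation = 400)), 1L)
  expect_error(detect_pulses(trace_set(numeric(0), numeric(0), numeric(0),
                                       numeric(0), numeric(0), 1e5)),
               "empty|length|window")
})

test_that("event integrals are additive under trace splitting", {
  tr <- plant_pulses(4e4, centers = c(9000, 30000), amplitude = 0.4,
                     sigma = 8, noise_sd = 0)
  full <- detect_pulses(tr, k_threshold = 5)
  cut <- 2e4
  ch <- tr$channels
  halves <- lapply(list(1:cut, (cut + 1):4e4), function(idx)
    trace_set(ch$IL[idx], ch$I0[idx], ch$I90[idx], ch$I135[idx],
              ch$FL[idx], sampling_rate = tr$sampling_rate))
  parts <- lapply(halves, detect_pulses, k_threshold = 5)
  expect_equal(nrow(parts[[1]]) + nrow(parts[[2]]), nrow(full))
  got <- rbind(parts[[1]], parts[[2]])
  for (col in c("IL", "I0", "I90", "I135", "Fm"))
    expect_equal(got[[col]], full[[col]], tolerance = 1e-9)
})

test_that("features invert pulses through the instrument matrix", {
  p <- data.frame(IL = 1, I0 = 1, I90 = 0, I135 = 0, Fm = 0.5)
  f <- features_from_pulses(p, diag(4), intensity_floor = 0)
  expect_equal(c(f$q, f$u, f$v, f$dop, f$F), c(1, 0, 0, 1, 0.5))
  # joint rescaling of all channels and Fm leaves every feature unchanged
  f3 <- features_from_pulses(
    data.frame(IL = 3, I0 = 3, I90 = 0, I135 = 0, Fm = 1.5),
    diag(4), intensity_floor = 0)
  expect_equal(c(f3$q, f3$u, f3$v, f3$dop, f3$F),
               c(f$q, f$u, f$v, f$dop, f$F))
  # sub-floor intensity is rejected with a count, not an error
  weak <- data.frame(IL = 1e-9, I0 = 1e-9, I90 = 0, I135 = 0, Fm = 0)
  out <- features_from_pulses(rbind(p, weak), diag(4),
                              intensity_floor = 1e-6)
  expect_equal(nrow(out), 1L)
  expect_equal(attr(out, "n_rejected"), 1L)
})

test_that("detection recall and precision hold across seeded noisy runs", {
  n_runs <- 25
  recall <- precision <- numeric(n_runs)
  for (r in seq_len(n_runs)) {
    set.seed(100 + r)
    centers <- seq(2000, 18000, by = 2300) + sample(-200:200, 7, TRUE)
    # summed-channel noise sd = 0.02; amplitudes give snr in [6, 15]
    amp <- runif(7, 0.12, 0.30)
    tr <- plant_pulses(2e4, centers, amp, sigma = 6, noise_sd = 0.01)
    ev <- detect_pulses(tr, k_threshold = 3.5, min_width = 5,
                        min_separation = 100)
    mm <- match_events(ev, centers, slack = 12)
    recall[r] <- mean(mm$found)
    precision[r] <- if (nrow(ev)) mean(mm$matched) else 1
  }
  expect_gte(mean(recall), 0.95)
  expect_gte(mean(precision), 0.95)
})

test_that("trace sets round-trip through the columnar text format", {
  set.seed(13)
  tr <- plant_pulses(500, centers = 250, amplitude = 0.3, noise_sd = 0.01,
                     sampling_rate = 12345)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_traces(tr, path)
  tr2 <- read_traces(path)
  expect_equal(tr2$sampling_rate, 12345)
  expect_equal(tr2$channels$I135, tr$channels$I135, tolerance = 1e-9)
  expect_equal(tr2$n, tr$n)
})
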