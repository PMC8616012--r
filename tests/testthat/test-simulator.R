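test_that("particle sampling is Poisson in count and seeded-deterministic", {
  cls <- particle_class("a", 0.2, 60, 0.8)
  counts <- vapply(1:20, function(s) {
    d <- experiment_design(list(cls), arrival_rate = 10, duration = 100,
                           seed = s)
    nrow(sample_particles(d))
  }, numeric(1))
  expect_true(all(abs(counts - 1000) < 4 * sqrt(1000)))
  d <- experiment_design(list(cls), arrival_rate = 20, duration = 2, seed = 99)
  expect_identical(sample_particles(d), sample_particles(d))
  expect_error(experiment_design(list(cls), arrival_rate = 1, duration = 1),
               "seed")
})

test_that("class structure propagates into the sampled population", {
  nf <- particle_class("plastic", 0.2, 60, 0.8, f_ratio_mean = 0)
  fl <- particle_class("algae", 0.2, 60, 0.8, f_ratio_mean = 0.5,
                       f_ratio_sd = 0.1)
  d <- experiment_design(list(nf, fl), arrival_rate = 100, duration = 1,
                         seed = 21)
  p <- sample_particles(d)
  expect_true(all(p$f_ratio[p$label == "plastic"] == 0))
  expect_true(all(p$f_ratio[p$label == "algae"] > 0))
  # an identity-like class (no diattenuation/retardance/depol, no jitter)
  # scatters the incident state unchanged
  id_cls <- particle_class("id", 0, 0, 1, diatt_sd = 0, ret_sd = 0,
                           depol_sd = 0)
  d2 <- experiment_design(list(id_cls), arrival_rate = 50, duration = 1,
                          seed = 22)
  p2 <- sample_particles(d2)
  expect_equal(unname(as.matrix(p2[, c("S_I", "S_Q", "S_U", "S_V")])),
               matrix(rep(c(1, 0, 1, 0), each = nrow(p2)), ncol = 4),
               tolerance = 1e-12)
})

test_that("every generated scattered Stokes vector is physical", {
  classes <- list(particle_class("a", 0.4, 120, 0.6),
                  particle_class("b", 0.1, 30, 0.95))
  d <- experiment_design(classes, arrival_rate = 200, duration = 1, seed = 23)
  p <- sample_particles(d)
  ok <- apply(p[, c("S_I", "S_Q", "S_U", "S_V")], 1, is_physical_stokes)
  expect_true(all(ok))
})

test_that("rendered traces carry the particles; empty designs give noise", {
  cls <- particle_class("a", 0.2, 60, 0.8, f_ratio_mean = 0.4,
                        f_ratio_sd = 0.1)
  d0 <- experiment_design(list(cls), arrival_rate = 0, duration = 0.2,
                          seed = 31, noise_sd = 0.01)
  tr0 <- render_traces(sample_particles(d0), d0)
  expect_equal(sd(tr0$channels$I0), 0.01, tolerance = 0.05)
  # noiseless single particle: full pipeline recovers its features
  d1 <- experiment_design(list(particle_class("a", 0.2, 60, 0.85,
                                              diatt_sd = 0, ret_sd = 0,
                                              depol_sd = 0,
                                              f_ratio_mean = 0.4,
                                              f_ratio_sd = 1e-9,
                                              amplitude_sdlog = 0)),
                          arrival_rate = 5, duration = 0.4, seed = 32,
                          noise_sd = 0)
  p1 <- sample_particles(d1)[1, , drop = FALSE]
  p1$time <- 0.2
  tr1 <- render_traces(p1, d1)
  ev <- detect_pulses(tr1, k_threshold = 5)
  expect_equal(nrow(ev), 1L)
  f <- features_from_pulses(ev, d1$instrument)
  truth <- polarization_components(as.numeric(
    p1[1, c("S_I", "S_Q", "S_U", "S_V")]))
  expect_lt(abs(f$q - truth$q), 1e-6)
  expect_lt(abs(f$u - truth$u), 1e-6)
  expect_lt(abs(f$v - truth$v), 1e-6)
  expect_lt(abs(f$F - p1$f_ratio), 1e-6)
})

test_that("overlapping arrivals are rendered additively with a warning", {
  cls <- particle_class("a", 0.1, 30, 0.9, amplitude_sdlog = 0)
  d <- experiment_design(list(cls), arrival_rate = 100, duration = 0.1,
                         seed = 33, noise_sd = 0)
  p <- sample_particles(d)[1:2, ]
  p$time <- c(0.05, 0.05005)  # closer than one transit width
  expect_warning(render_traces(p, d), "overlap")
})

test_that("benchmark presets are reproducible and structured as designed", {
  b1 <- make_benchmark_suite("ps10-family", seed = 41, n_per_class = 60)
  b2 <- make_benchmark_suite("ps10-family", seed = 41, n_per_class = 60)
  expect_identical(b1, b2)
  expect_setequal(levels(b1$label), c("PS10", "PS10-100", "SiO2", "PS10-F"))
  expect_error(make_benchmark_suite("nope", seed = 1), "unknown preset")
  # algae4: class mean F ordered P.G. > M.A. > D.S. > P.T.,
  # with the widest spread for P.G.
  a <- make_benchmark_suite("algae4", seed = 42, n_per_class = 150)
  mF <- tapply(a$F, a$label, mean)
  expect_true(mF[["P.G."]] > mF[["M.A."]] &&
              mF[["M.A."]] > mF[["D.S."]] &&
              mF[["D.S."]] > mF[["P.T."]])
  sF <- tapply(a$F, a$label, sd)
  expect_equal(names(which.max(sF)), "P.G.")
})

test_that("pipeline feature recovery is unbiased at high SNR", {
  cls <- particle_class("a", 0.25, 70, 0.8, f_ratio_mean = 0.5,
                        f_ratio_sd = 0.1, amplitude_meanlog = log(2),
                        amplitude_sdlog = 0.2)
  d <- experiment_design(list(cls), arrival_rate = 25, duration = 1,
                         seed = 51, noise_sd = 0.001)
  p <- sample_particles(d)
  # drop overlapping arrivals so each event maps to one particle
  keep <- c(TRUE, diff(p$time) > 0.002)
  p <- p[keep & rev(c(TRUE, diff(rev(p$time)) < -0.002)), ]
  tr <- suppressWarnings(render_traces(p, d))
  ev <- detect_pulses(tr, k_threshold = 5, min_separation = 50)
  f <- features_from_pulses(ev, d$instrument)
  centers <- round(p$time * d$sampling_rate)
  m <- match_events(ev, centers)
  expect_gte(mean(m$found), 0.95)
  truth_q <- p$S_Q / p$S_I
  # compare matched pairs on q and F (relative bias < 1%)
  pair <- vapply(seq_len(nrow(f)), function(i) {
    j <- which(centers >= ev$start[i] & centers < ev$end[i])[1]
    c(dq = f$q[i] - truth_q[j], dF = f$F[i] - p$f_ratio[j],
      q = truth_q[j], F = p$f_ratio[j])
  }, numeric(4))
  expect_lt(abs(mean(pair["dq", ])) / mean(abs(pair["q", ])), 0.01)
  expect_lt(abs(mean(pair["dF", ])) / mean(pair["F", ]), 0.01)
})
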