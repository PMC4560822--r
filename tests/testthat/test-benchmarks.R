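test_that("gravity data: noiseless records equal the truth oracle exactly", {
  cfg <- benchmark_config("gravity", N = 12, noise = 0, seed = 21)
  data <- generate_gravity_data(cfg)
  expect_equal(nrow(data), 12)
  expect_equal(length(ts_conditions_test(data)), 12)
  truth <- attr(data, "truth")
  for (cid in unique(data$condition)) {
    row <- data[data$condition == cid, ]
    cnd <- ts_conditions_test(data)[[cid]]
    tv <- truth$fun(cnd, sort(unique(c(0, row$time))))
    expect_equal(row$value, tv[match(row$time, sort(unique(c(0, row$time))))],
                 tolerance = 1e-9)
  }
})

test_that("a release at the circular-orbit radius keeps r constant", {
  # v0 = 1, mu = 1: circular radius r0 = mu / v0^2 = 1
  tr <- integrate_gravity(1, 0, ell = 1, mu = 1, times = seq(0, 10, 0.5))
  expect_lt(max(abs(tr$states[, 1] - 1)), 1e-6)
})

test_that("the gravity protocol mixes bound and unbound trajectories", {
  cfg <- benchmark_config("gravity", N = 40, seed = 2)
  data <- generate_gravity_data(cfg)
  r0 <- sapply(ts_conditions_test(data), function(c) c$x0[["r"]])
  # E < 0 (ellipse) iff r0 < 2 mu / v0^2 = 2 at these defaults
  expect_true(any(r0 < 2) && any(r0 > 2))
  expect_true(min(r0) < 1 && max(r0) > 1) # straddles the circular radius
})

test_that("the 5-site phosphorylation network has 32 conserved microstate ODEs", {
  net <- build_phospho_network(5)
  expect_equal(net$n_states, 32)
  expect_equal(nrow(net$transitions), 32 * 5)
  tr <- integrate_phospho(net, 1.3, seq(0, 10, 0.25))
  expect_equal(tr$status, "ok")
  tot <- rowSums(tr$states)
  expect_lt(max(abs(tot - 1)), 1e-9)
})

test_that("a 1-site network has 2 microstates and 2 transitions", {
  net <- build_phospho_network(1)
  expect_equal(net$n_states, 2)
  expect_equal(nrow(net$transitions), 2)
})

test_that("total phosphorylation matches brute-force microstate bookkeeping", {
  net <- build_phospho_network(3)
  tt <- seq(0, 6, 0.5)
  tr <- integrate_phospho(net, 2, tt)
  counts <- sapply(0:(2^3 - 1), function(s) sum(bitwAnd(bitwShiftR(s, 0:2), 1)))
  manual <- as.vector(tr$states %*% counts)
  expect_equal(tr$observable, manual, tolerance = 1e-12)
  expect_equal(tr$observable[1], 0) # unphosphorylated start
})

test_that("saturating all phosphorylation rates drives the observable to 5", {
  net <- build_phospho_network(5)
  up <- net$transitions$dir == "up"
  net$transitions$V[up] <- 1e4
  tr <- integrate_phospho(net, 1e4, seq(0, 2, 0.2),
                          control = default_control(maxsteps = 200000L))
  expect_gt(tail(tr$observable, 1), 4.9)
  expect_lte(max(tr$observable), 5 + 1e-6)
})

test_that("phosphorylation data carry 10% noise with a floor and a truth oracle", {
  cfg <- benchmark_config("phosphorylation", N = 30, seed = 8)
  data <- generate_phospho_data(cfg)
  expect_equal(nrow(data), 30)
  expect_true(all(data$sigma > 0))
  truth <- attr(data, "truth")
  cnd <- ts_conditions_test(data)[[1]]
  rows <- data[data$condition == names(ts_conditions_test(data))[1], ]
  tv <- truth$fun(cnd, c(0, rows$time))[-1, 1]
  expect_lt(max(abs(rows$value - tv) / rows$sigma), 5) # noise at stated scale
  # sigma is 10% of the value wherever that clears the floor
  big <- rows$sigma > 0.01 * diff(range(attr(data, "truth")$noiseless)) + 1e-12
  expect_equal(rows$sigma[big], 0.1 * abs(tv[big]), tolerance = 0.3)
})

test_that("the frozen rate draw makes the generator fully reproducible", {
  d1 <- generate_phospho_data(benchmark_config("phosphorylation", N = 15, seed = 4))
  d2 <- generate_phospho_data(benchmark_config("phosphorylation", N = 15, seed = 4))
  expect_identical(as.data.frame(d1), as.data.frame(d2))
  d3 <- generate_gravity_data(benchmark_config("gravity", N = 5, seed = 9))
  d4 <- generate_gravity_data(benchmark_config("gravity", N = 5, seed = 9))
  expect_identical(as.data.frame(d3), as.data.frame(d4))
})

test_that("the simple phosphorylation model saturates in time and input", {
  p <- c(A = 3, V0 = 1, w = 0.5, tau = 2, c = 0.25)
  expect_equal(simple_phospho_model(p, 0, V = 5), 0.25) # t = 0 -> c
  expect_equal(simple_phospho_model(p, 1e6, V = 1e6), 3 + 0.25,
               tolerance = 1e-6) # double saturation -> A + c
  expect_length(p, 5)
})

test_that("the glycolysis model has 7 species, 16 constants and a ~1-minute cycle", {
  m <- build_glycolysis_model()
  expect_length(m$species, 7)
  expect_length(m$constants, 16)
  tt <- seq(0, 20, 0.005)
  tr <- integrate_glycolysis(m, m$x0_cycle, tt)
  expect_equal(tr$status, "ok")
  late <- tt > 5
  per <- oscillation_period(tt[late], tr$states[late, "S1"])
  expect_gt(per, 0.8)
  expect_lt(per, 1.2)
  # oscillations are sustained, not decaying
  amp_early <- diff(range(tr$states[tt > 5 & tt < 10, "S1"]))
  amp_late <- diff(range(tr$states[tt > 15, "S1"]))
  expect_gt(amp_late, 0.5 * amp_early)
})

test_that("glycolysis data follow the single-random-time 3-species protocol", {
  cfg <- benchmark_config("glycolysis", N = 8, seed = 31)
  data <- generate_glycolysis_data(cfg)
  expect_equal(nrow(data), 24) # 3 records per condition
  expect_setequal(unique(data$variable), c("S1", "S2", "S3"))
  per_cond <- table(data$condition)
  expect_true(all(per_cond == 3))
  # one time point per condition
  tpc <- tapply(data$time, data$condition, function(t) length(unique(t)))
  expect_true(all(tpc == 1))
  # noiseless data at time ~0 would equal the initial conditions
  cfg0 <- benchmark_config("glycolysis", N = 3, noise = 0, seed = 5)
  d0 <- generate_glycolysis_data(cfg0)
  truth <- attr(d0, "truth")
  cnd <- ts_conditions_test(d0)[[1]]
  expect_equal(as.numeric(truth$fun(cnd, c(0, 1e-9))[1, ]),
               as.numeric(cnd$x0), tolerance = 1e-6)
})

test_that("out-of-sample ranges scale about the in-sample midpoints", {
  m <- build_glycolysis_model()
  r2 <- dynadapt:::scaled_ranges(m$in_ranges, 2)
  mid <- rowMeans(m$in_ranges)
  expect_equal(rowMeans(r2), pmax(mid, (r2[, 1] + r2[, 2]) / 2), tolerance = 1e-12)
  expect_true(all(r2[, 2] - r2[, 1] >= 2 * (m$in_ranges[, 2] - m$in_ranges[, 1]) - 1e-9 |
                    r2[, 1] == 1e-3))
})
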