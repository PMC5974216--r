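test_that("with-replacement synapse count inverts the pair probability", {
  expect_identical(total_synapse_count(0, 50, 50), 0L)
  expect_error(total_synapse_count(1, 50, 50), "p = 1")

  set.seed(2)
  for (i in 1:20) {
    p <- runif(1, 0.01, 0.6)
    N1 <- sample(20:500, 1); N2 <- sample(20:500, 1)
    K <- total_synapse_count(p, N1, N2)
    p_back <- 1 - (1 - 1 / (N1 * N2))^K
    # exact up to the rounding of K
    p_lo <- 1 - (1 - 1 / (N1 * N2))^(K - 0.5)
    p_hi <- 1 - (1 - 1 / (N1 * N2))^(K + 0.5)
    expect_true(p >= p_lo && p <= p_hi,
                label = sprintf("p=%.3f N=(%d,%d)", p, N1, N2))
    expect_equal(p_back, p, tolerance = 1e-2)
  }
  expect_equal(total_synapse_count(0.1, 100, 100, method = "binomial"),
               1000L)
})

test_that("empirical pair-connection probability matches p", {
  p <- 0.1; N <- 100
  K <- total_synapse_count(p, N, N)
  set.seed(77)
  reps <- 200
  hits <- 0
  for (r in 1:reps) {
    s <- sample.int(N, K, replace = TRUE)
    t <- sample.int(N, K, replace = TRUE)
    hits <- hits + length(unique((s - 1) * N + t))
  }
  expect_equal(hits / (reps * N * N), p, tolerance = 0.01)
})

test_that("instantiated synapses honour the distributions and clipping", {
  proj <- projection_spec("A", "B", K = 1e5L, weight_mean = 0.0878,
                          weight_sd = 0.00878, sign = "excitatory",
                          delay_mean = 1.5, delay_sd = 0.75)
  set.seed(10)
  s <- instantiate_connections(proj, 200, 200, h = 0.1)
  expect_equal(nrow(s), 1e5)
  se <- 0.00878 / sqrt(1e5)
  expect_lt(abs(mean(s$weight) - 0.0878), 3 * se)
  expect_lt(abs(sd(s$weight) - 0.00878), 3 * se)
  expect_gte(min(s$delay), 0.1)
  expect_true(all(abs(s$delay / 0.1 - round(s$delay / 0.1)) < 1e-9))

  # inhibitory sign flag and zero-sd degenerate draws
  pri <- projection_spec("A", "B", K = 100L, weight_mean = 0.3512,
                         sign = "inhibitory", delay_mean = 0.33)
  si <- instantiate_connections(pri, 10, 10, h = 0.1)
  expect_true(all(si$weight == -0.3512))
  expect_equal(si$delay, rep(0.3, 100))   # rounded to grid
})

test_that("multapse multiplicity matches the binomial prediction", {
  # N_pre = N_post = 3, K = 8: each ordered pair is hit Binomial(8, 1/9)
  # times; check the zero-multiplicity frequency
  set.seed(55)
  reps <- 3000
  p0 <- (1 - 1 / 9)^8
  zero <- 0
  for (r in 1:reps) {
    s <- sample.int(3, 8, replace = TRUE)
    t <- sample.int(3, 8, replace = TRUE)
    zero <- zero + 9 - length(unique((s - 1) * 3 + t))
  }
  se <- sqrt(p0 * (1 - p0) / (reps * 9))
  expect_lt(abs(zero / (reps * 9) - p0), 4 * se)
})

test_that("dc_equivalent matches arithmetic and a long simulation", {
  expect_equal(dc_equivalent(0, 0.0878, 0.5), 0)
  expect_equal(dc_equivalent(8000, 0.0878, 0.5), 0.3512)
  expect_equal(dc_equivalent(16000, 0.0878, 0.5),
               2 * dc_equivalent(8000, 0.0878, 0.5))

  # cross-check: time-averaged synaptic current of a Poisson-driven neuron
  h <- 0.1; J <- 0.0878; tau_s <- 0.5
  counts <- generate_grid_poisson(8000, h, 20000, seed = 3)
  beta <- exp(-h / tau_s); q <- tau_s * (1 - beta) / h
  I <- 0; acc <- 0
  for (c in counts) {
    I <- beta * I + q * c * J
    acc <- acc + h * I
  }
  expect_equal(acc / (length(counts) * h), 0.3512, tolerance = 0.01)
})

test_that("network scaling preserves probabilities and counts neurons", {
  # arithmetic-only config with 77,169 neurons total
  sizes <- c(20000L, 5000L, 22000L, 5500L, 5000L, 1250L, 14500L, 3919L)
  pops <- lapply(seq_along(sizes), function(i)
    population_spec(paste0("P", i), sizes[i], I_DC = 0.4))
  proj <- list(projection_spec("P1", "P2", p = 0.1, weight_mean = 0.0878,
                               sign = "excitatory", delay_mean = 1.5))
  spec <- network_spec(pops, proj)
  expect_equal(sum(sizes), 77169L)

  s1 <- scale_network(spec, 1)
  expect_equal(vapply(s1$populations, `[[`, 0L, "N"), sizes)

  s01 <- scale_network(spec, 0.1)
  tot <- sum(vapply(s01$populations, `[[`, 0L, "N"))
  expect_lt(abs(tot - 7717), 4)    # 7,717 up to per-population rounding
  expect_equal(s01$projections[[1]]$p, 0.1)

  # expected synapse count scales ~ factor^2 at fixed p
  K_full <- total_synapse_count(0.1, sizes[1], sizes[2])
  K_scaled <- total_synapse_count(0.1, s01$populations[[1]]$N,
                                  s01$populations[[2]]$N)
  expect_equal(K_scaled / K_full, 0.01, tolerance = 0.001)

  tiny <- network_spec(list(population_spec("A", 3L, I_DC = 0)), list())
  expect_error(scale_network(tiny, 0.1), "zero neurons")
})

test_that("instantiation is bit-reproducible and substreams independent", {
  spec <- tiny_net_spec()
  a <- instantiate_network(spec, h = 0.1, seed = 9)
  b <- instantiate_network(spec, h = 0.1, seed = 9)
  expect_identical(a$synapses, b$synapses)
  expect_identical(a$V0, b$V0)
  c <- instantiate_network(spec, h = 0.1, seed = 10)
  expect_false(identical(a$synapses, c$synapses))
  # initial potentials lie in [V_r, theta)
  p <- std_params()
  expect_true(all(a$V0 >= p$V_r & a$V0 < p$theta))
})

test_that("network config JSON round-trips", {
  spec <- tiny_net_spec()
  path <- tempfile(fileext = ".json")
  write_network_config(spec, path)
  back <- read_network_config(path)
  expect_equal(length(back$populations), length(spec$populations))
  expect_equal(back$populations[[1]]$nu_ext, spec$populations[[1]]$nu_ext)
  expect_equal(back$projections[[3]]$sign, "inhibitory")
  expect_equal(back$projections[[1]]$p, 0.1)
  # instantiation from the round-tripped spec is identical
  a <- instantiate_network(spec, h = 0.1, seed = 4)
  b <- instantiate_network(back, h = 0.1, seed = 4)
  expect_identical(a$synapses, b$synapses)
  unlink(path)
})

test_that("synthetic microcircuit spec is well-formed", {
  spec <- synthetic_microcircuit("dc")
  expect_length(spec$populations, 8)
  expect_equal(sum(vapply(spec$populations, `[[`, 0L, "N")), 76250L)
  nm <- vapply(spec$populations, `[[`, "", "name")
  expect_setequal(nm, c("2/3E", "2/3I", "4E", "4I", "5E", "5I", "6E", "6I"))
  # the 4E -> 2/3E feedforward projection carries doubled weight
  w <- vapply(spec$projections, function(pr)
    if (pr$pre == "4E" && pr$post == "2/3E") pr$weight_mean else NA_real_,
    numeric(1))
  expect_equal(w[!is.na(w)], 0.1756)
  ps <- synthetic_microcircuit("poisson")
  expect_equal(ps$populations[[1]]$nu_ext, 11400)
  # DC variant is the mean-current equivalent of the Poisson variant
  expect_equal(spec$populations[[1]]$I_DC,
               dc_equivalent(11400, 0.0878, 0.5))
})
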