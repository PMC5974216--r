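test_that("exact propagator matches the closed form", {
  p <- std_params()

  # identity map at h = 0
  pr0 <- exact_propagator(p, 0)
  expect_equal(pr0$alpha, 1)
  expect_equal(pr0$beta, 1)
  expect_equal(pr0$P21, 0)

  # standard parameters at h = 0.1 ms, against an independent evaluation
  # of R_m * tau_s * (e^(-h/tau_s) - e^(-h/tau_m)) / (tau_s - tau_m)
  pr <- exact_propagator(p, 0.1)
  expect_equal(pr$alpha, exp(-0.01))
  expect_equal(pr$beta, exp(-0.2))
  expect_equal(pr$P21, 40 * 0.5 * (exp(-0.2) - exp(-0.01)) / (0.5 - 10),
               tolerance = 1e-12)
  expect_equal(pr$P21, 0.36067174878144462, tolerance = 1e-12)
  expect_true(pr$P21 >= 0 && pr$alpha <= 1 && pr$beta <= 1)

  # degenerate tau_s == tau_m uses the analytic limit, continuous in tau_s
  pd <- neuron_params(tau_m = 10, tau_s = 10)
  prd <- exact_propagator(pd, 0.1)
  pd2 <- neuron_params(tau_m = 10, tau_s = 10 + 1e-5)
  prd2 <- exact_propagator(pd2, 0.1)
  expect_equal(prd$P21, prd2$P21, tolerance = 1e-4)

  expect_error(exact_propagator(p, -1), "non-negative")
  expect_error(neuron_params(tau_m = 0), "positive")
  expect_error(neuron_params(V_r = -40), "theta")
})

test_that("leak-only decay follows E_L + (V0-E_L) * alpha^k to 1e-10 mV", {
  p <- std_params()
  pr <- exact_propagator(p, 0.1)
  st <- neuron_state(-55, 0)
  for (k in 1:200) {
    st <- step_exact(st, pr, p)
    expect_lt(abs(st$V - (p$E_L + (-55 - p$E_L) * exp(-k * 0.1 / p$tau_m))),
              1e-10)
  }
})

test_that("step_exact fixed point, reset and refractoriness", {
  p <- std_params()
  pr <- exact_propagator(p, 0.1)

  st <- step_exact(neuron_state(p$E_L, 0), pr, p)
  expect_equal(st$V, p$E_L)
  expect_equal(st$I, 0)
  expect_false(attr(st, "spiked"))

  # a state whose propagated V reaches theta: spike, reset to
  # V_r = -65 mV, refractory starts
  st <- step_exact(neuron_state(p$theta, 2), pr, p, incoming_weight_sum = 1)
  expect_true(attr(st, "spiked"))
  expect_equal(st$V, -65)
  expect_equal(st$refractory_remaining, p$tau_ref)

  # while refractory, V stays clamped regardless of input
  st2 <- step_exact(st, pr, p, incoming_weight_sum = 100)
  expect_equal(st2$V, p$V_r)
  expect_false(attr(st2, "spiked"))
  expect_equal(st2$refractory_remaining, p$tau_ref - 0.1)
})

test_that("charge per synaptic event is J * tau_s", {
  p <- std_params()
  J <- 0.0878
  for (h in c(0.1, 1)) {
    # exponential backend, default q: discrete sum is exact by construction
    st <- neuron_state(p$E_L, 0)
    charge <- 0
    for (k in 1:(5000 / h)) {
      st <- step_exponential(st, p, h, if (k == 1) J else 0)
      charge <- charge + h * st$I
    }
    expect_equal(charge, J * p$tau_s, tolerance = 1e-12)
  }
  # exact backend: continuous integral of I(t) = J e^(-t/tau_s) is J tau_s;
  # the discrete I samples bound it above (left Riemann sum of a decaying
  # exponential, I sampled after the jump)
  h <- 0.1
  st <- neuron_state(p$E_L, 0)
  pr <- exact_propagator(p, h)
  charge <- 0
  for (k in 1:5000) {
    st <- step_exact(st, pr, p, if (k == 1) J else 0)
    charge <- charge + h * st$I
  }
  expect_gt(charge, J * p$tau_s)
  # trapezoid-corrected integral recovers J tau_s
  expect_equal(charge * p$tau_s * (1 - pr$beta) / h, J * p$tau_s,
               tolerance = 1e-10)
})

test_that("decay_then_add scheme uses q = beta", {
  p <- std_params()
  h <- 1
  beta <- exp(-h / p$tau_s)
  st <- step_exponential(neuron_state(p$E_L, 0), p, h, 1,
                         scheme = "decay_then_add")
  expect_equal(st$I, beta)
  st <- step_exponential(neuron_state(p$E_L, 0), p, h, 1, scheme = "charge")
  expect_equal(st$I, p$tau_s * (1 - beta) / h)
})

test_that("exponential and exact schemes agree without synaptic input", {
  p <- std_params()
  pr <- exact_propagator(p, 0.1)
  s1 <- neuron_state(-58, 0); s2 <- neuron_state(-58, 0)
  for (k in 1:50) {
    s1 <- step_exact(s1, pr, p)
    s2 <- step_exponential(s2, p, 0.1)
    expect_equal(s1$V, s2$V, tolerance = 1e-12)
  }
})

test_that("separated integration overshoots the exact single-spike response", {
  # the piecewise-constant-current scheme delivers the step's charge at the
  # start of the step, so the membrane excursion runs consistently above
  # the exact solution during the rise
  p <- std_params()
  fx <- make_fixture("single-spike-response", h = 1)
  ex <- run_single_neuron(p, "exact-grid", fx$input, 1, J = fx$J)
  sp <- run_single_neuron(p, "exponential-grid", fx$input, 1, J = fx$J)
  # the separated scheme responds one step earlier and overshoots the peak
  expect_gt(sp$trace$V_mV[1], ex$trace$V_mV[1])
  expect_gt(max(sp$trace$V_mV), max(ex$trace$V_mV))
  fx01 <- make_fixture("single-spike-response", h = 0.1)
  ex01 <- run_single_neuron(p, "exact-grid", fx01$input, 0.1, J = fx01$J)
  sp01 <- run_single_neuron(p, "exponential-grid", fx01$input, 0.1, J = fx01$J)
  expect_gt(max(sp01$trace$V_mV), max(ex01$trace$V_mV))
})

test_that("precise crossing search matches a dense-grid oracle", {
  p <- std_params()

  # already at threshold
  expect_equal(find_precise_crossing(neuron_state(p$theta, 0), p, 0.1), 0)
  # leak alone never crosses
  expect_true(is.na(find_precise_crossing(neuron_state(-55, 0), p, 0.1)))
  expect_error(find_precise_crossing(neuron_state(-55, 0), p, 0.1, tol = 0),
               "tol")

  # worked case from the closed form
  st <- neuron_state(-50.5, 2)
  tc <- find_precise_crossing(st, p, 0.1, tol = 1e-9)
  tt <- seq(0, 0.1, by = 1e-6)
  vv <- subthreshold_voltage(st, p, tt)
  expect_lt(abs(tc - tt[which(vv >= p$theta)[1]]), 2e-6)

  # property: 100 random initial conditions against the dense grid
  set.seed(31)
  for (i in 1:100) {
    st <- neuron_state(runif(1, -65, -50.01), runif(1, 0, 3))
    tc <- find_precise_crossing(st, p, 0.1, tol = 1e-7)
    vv <- subthreshold_voltage(st, p, tt)
    first <- which(vv >= p$theta)[1]
    if (is.na(tc)) {
      expect_true(is.na(first) || all(vv < p$theta))
    } else {
      expect_lt(abs(tc - tt[first]), 2e-6)
    }
  }
})

test_that("run_single_neuron is quiescent without input and deterministic", {
  p <- std_params()
  r <- run_single_neuron(p, "exact-grid", integer(1000), 0.1)
  expect_length(r$spikes, 0)
  expect_true(all(r$trace$V_mV == p$E_L))

  inp <- fixed_input()
  for (be in c("exact-grid", "exponential-grid", "exponential-fixed",
               "precise")) {
    a <- run_single_neuron(p, be, inp, 0.1)
    b <- run_single_neuron(p, be, inp, 0.1)
    expect_identical(a$spikes, b$spikes)
    expect_identical(a$trace, b$trace)
  }
  expect_error(run_single_neuron(p, "no-such-backend", inp, 0.1),
               "unknown backend")
})

test_that("C++ grid loops agree bit-exactly with the R step functions", {
  p <- std_params()
  h <- 0.1
  inp <- fixed_input(rate = 20000, duration = 50)
  pr <- exact_propagator(p, h)
  run <- run_single_neuron(p, "exact-grid", inp, h)
  st <- neuron_state(p$E_L, 0)
  for (k in seq_along(inp)) {
    st <- step_exact(st, pr, p, inp[k] * 0.0878)
    expect_identical(st$V, run$trace$V_mV[k])
  }
  run <- run_single_neuron(p, "exponential-grid", inp, h)
  st <- neuron_state(p$E_L, 0)
  for (k in seq_along(inp)) {
    st <- step_exponential(st, p, h, inp[k] * 0.0878)
    expect_identical(st$V, run$trace$V_mV[k])
  }
})

test_that("no backend violates the refractory period", {
  p <- std_params()
  inp <- fixed_input(rate = 30000, duration = 2000, seed = 5)
  for (be in names(lifbench:::.backend_codes)) {
    r <- run_single_neuron(p, be, inp, 0.1, record_trace = FALSE)
    expect_gt(length(r$spikes), 10)
    expect_true(all(diff(r$spikes) >= p$tau_ref - 1e-9), label = be)
  }
})

test_that("exponential-grid spike times converge to exact-grid as h -> 0", {
  p <- std_params()
  base <- fixed_input(rate = 10000, h = 0.1, duration = 4000, seed = 11)
  first_diff <- function(h, input) {
    a <- run_single_neuron(p, "exact-grid", input, h, record_trace = FALSE)
    b <- run_single_neuron(p, "exponential-grid", input, h,
                           record_trace = FALSE)
    abs(a$spikes[1] - b$spikes[1])
  }
  d_coarse <- first_diff(0.1, base)
  fine <- integer(length(base) * 10L)
  fine[seq(1, length(fine), by = 10L)] <- base   # same realization, h/10
  d_fine <- first_diff(0.01, fine)
  expect_lt(d_fine, d_coarse / 10 + 1e-12)
})

test_that("precise backend matches exact-grid rates and leads sub-step", {
  p <- std_params()
  inp <- fixed_input(rate = 8000, duration = 2000, seed = 9)
  pre <- run_single_neuron(p, "precise", inp, 0.1, record_trace = FALSE)
  ex <- run_single_neuron(p, "exact-grid", inp, 0.1, record_trace = FALSE)
  n <- min(length(pre$spikes), length(ex$spikes))
  expect_gt(n, 5)
  # the grid constrains spikes to the step end, so grid spikes lag precise
  d <- ex$spikes[1:n] - pre$spikes[1:n]
  expect_true(all(d > -1e-9))
})
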