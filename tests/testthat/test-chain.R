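test_that("catenary M2 closed form has the Bateman coefficients", {
  sp <- chain_spec(0.07, 0.12, 0.42, dose = 90, V = 20)
  m2 <- chain_solution(sp, "M2")
  expect_equal(nrow(m2), 3)
  expect_equal(m2$rate, c(0.07, 0.12, 0.42))
  # direct product formula, computed independently
  k <- c(0.07, 0.12, 0.42)
  coefs <- vapply(1:3, function(i) {
    0.07 * 0.12 * 90 / (prod(k[-i] - k[i]) * 20)
  }, numeric(1))
  expect_equal(m2$coef, coefs, tolerance = 1e-12)
  expect_equal(round(m2$coef, 2), c(2.16, -2.52, 0.36))
  # metabolite profiles start at zero: coefficients cancel
  expect_equal(sum(m2$coef), 0, tolerance = 1e-12)
  expect_equal(eval_exp_sum(m2, 0), 0, tolerance = 1e-12)
  # parent is monoexponential at dose/V
  d <- chain_solution(sp, "D")
  expect_equal(nrow(d), 1)
  expect_equal(d$coef, 90 / 20)
  expect_equal(d$rate, 0.07)
})

test_that("closed forms agree with the stiff integrator to 1e-8", {
  set.seed(61)
  for (i in 1:10) {
    sp <- random_chain_spec()
    tmax <- 5 / min(chain_rates(sp))
    times <- seq(0, tmax, length.out = 200)
    for (species in c("D", "M1", "M2", "M3")) {
      curve <- chain_solution(sp, species)
      prof <- simulate_ode(sp, times, species = species)
      expect_lt(rel_dev(curve, prof), 1e-8)
    }
  }
})

test_that("mass is conserved across the chain at every time", {
  set.seed(62)
  sp <- random_chain_spec()
  times <- seq(0, 4 / min(chain_rates(sp)), length.out = 100)
  total <- Reduce(`+`, lapply(c("D", "M1", "M2", "M3"), function(s) {
    eval_exp_sum(chain_solution(sp, s), times)
  }))
  expect_equal(total * sp$V, rep(sp$dose, length(times)), tolerance = 1e-10)
})

test_that("moments of the chain solution match the printed-form sums", {
  sp <- chain_spec(0.07, 0.12, 0.42, 90, 20)
  m <- moments(chain_solution(sp, "M2"))
  # coefficient-over-exponent sums, computed independently
  co <- c(2.16, -2.52, 0.36); k <- c(0.07, 0.12, 0.42)
  expect_equal(round(m$AUC, 2), round(sum(co / k), 2))
  expect_equal(round(m$AUMC, 1), round(sum(co / k^2), 1))
  expect_equal(m$MRT, 25, tolerance = 1e-12)
  # brute-force trapezoid on a long dense grid
  nm <- numeric_moments(chain_solution(sp, "M2"), tmax = 400, dt = 0.005)
  expect_equal(m$AUC, nm$AUC, tolerance = 1e-4)
  expect_equal(m$AUMC, nm$AUMC, tolerance = 1e-3)
  # monoexponential MRT is 1/k
  expect_equal(moments(exp_sum(4.5, 0.42))$MRT, 1 / 0.42, tolerance = 1e-12)
  expect_error(moments(exp_sum(c(1, 1), c(0.5, 0))), "positive decay")
})

test_that("series shortcut equals the moment MRT on random chains", {
  sp <- chain_spec(0.07, 0.12, 0.42, 90, 20)
  expect_equal(mrt_kirchhoff(c(0.07, 0.12, 0.42)),
               moments(chain_solution(sp, "M2"))$MRT, tolerance = 1e-12)
  expect_equal(mrt_kirchhoff(0.42), 1 / 0.42, tolerance = 1e-12)
  set.seed(63)
  for (i in 1:200) {
    sp <- random_chain_spec()
    k <- chain_rates(sp)
    expect_equal(mrt_kirchhoff(k), moments(chain_solution(sp, "M2"))$MRT,
                 tolerance = 1e-10)
    expect_equal(mrt_kirchhoff(k[1:2]), moments(chain_solution(sp, "M1"))$MRT,
                 tolerance = 1e-10)
  }
})

test_that("confluent solution is the limit of the distinct-rate solution", {
  base <- 0.2
  times <- seq(0, 40, by = 0.5)
  conf <- chain_solution(chain_spec(base, base, base, 90, 20), "M2",
                         degenerate_ok = TRUE)
  # triple-repeated rate collapses M2 to a single t^2 * exp term
  expect_true(any(conf$power == 2))
  expect_true(all(conf$rate == base))
  # at moderate separation the distinct-rate closed form itself approaches
  # the confluent one ...
  sp3 <- chain_spec(base, base * 1.001, base * 1.002, 90, 20)
  expect_lt(max(abs(eval_exp_sum(chain_solution(sp3, "M2"), times) -
                      eval_exp_sum(conf, times))), 5e-3)
  # ... but its coefficients diverge as 1/separation^2 and cancellation makes
  # direct evaluation unreliable below ~1e-4 separation, so the limit is
  # checked against the numerically stable integrator of the perturbed system
  prev_dev <- Inf
  for (eps in 10^-(3:6)) {
    sp <- chain_spec(base, base * (1 + eps), base * (1 + 2 * eps), 90, 20)
    prof <- simulate_ode(sp, times, species = "M2")
    dev <- max(abs(eval_exp_sum(conf, times) - prof$concentrations))
    expect_lt(dev, prev_dev + 1e-12)
    prev_dev <- dev
  }
  expect_lt(prev_dev, 1e-5)
  # confluent form also matches the integrator
  prof <- simulate_ode(chain_spec(base, base, base, 90, 20), times,
                       species = "M2")
  expect_lt(rel_dev(conf, prof), 1e-8)
  # without the flag, repeated rates are an error
  expect_error(chain_solution(chain_spec(base, base, 0.4, 90, 20), "M2"),
               "degenerate_ok")
})
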