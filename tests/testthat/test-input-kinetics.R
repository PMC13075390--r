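test_that("oral total clearance is the gut/systemic series combination", {
  expect_identical(total_clearance_oral(Inf, 527), 527)
  expect_equal(total_clearance_oral(10, 10), 5)
  # cimetidine-like gut/systemic ratio of 1.6
  cl_iv <- 600
  expect_equal(total_clearance_oral(1.6 * cl_iv, cl_iv), cl_iv / 1.625,
               tolerance = 1e-12)
  # traditional framework ignores the gut stage by construction
  expect_identical(total_clearance_oral(1.6 * cl_iv, cl_iv, "traditional"),
                   cl_iv)
  expect_equal(gut_clearance(0.5, 2000), 1000)
})

test_that("mean times add in series; rate constants combine harmonically", {
  expect_equal(mrt_oral(1, 2), 3)
  expect_equal(mrt_oral(7.3, 0), 7.3)
  # inverse-rate form matches the series rate-constant combination
  k_iv <- 0.42; k_a <- 0.07
  expect_equal(mrt_oral(1 / k_iv, 1 / k_a), 1 / k_oral(k_iv, k_a),
               tolerance = 1e-12)
  expect_equal(k_oral(0.42, 0.07), 0.06, tolerance = 1e-12)
  expect_equal(k_oral(0.3, 0.3), 0.15)
  expect_identical(k_oral(0.2, Inf), 0.2)
  # fast absorption limit
  expect_equal(k_oral(0.2, 2000), 0.2, tolerance = 1e-3)
})

test_that("flip-flop resolvability reports fold separation and slope", {
  ff <- flip_flop_check(k_a = 0.07, k_d = 0.42)
  expect_true(ff$flip_flop)
  expect_true(ff$resolvable)   # 6-fold separation
  expect_equal(ff$terminal_slope, 0.06, tolerance = 1e-12)
  close <- flip_flop_check(k_a = 0.2, k_d = 0.42)
  expect_false(close$resolvable)
  expect_true(flip_flop_check(0.2, 0.42, threshold = 2)$resolvable)
})

test_that("AUC inflation and renal-clearance depression are reciprocal", {
  expect_identical(apparent_bioavailability(0.7, 10, Inf), 0.7)
  expect_equal(apparent_bioavailability(1, 10, 90), 1 + 1 / 9,
               tolerance = 1e-12)
  expect_equal(apparent_bioavailability(0.5, 10, 10), 1)
  expect_identical(renal_clearance_route_ratio(10, Inf), 1)
  expect_equal(renal_clearance_route_ratio(10, 10), 0.5)
  expect_equal(renal_clearance_route_ratio(10, 16), 1 / (1 + 10 / 16),
               tolerance = 1e-12)
  # exact algebraic identity over random draws, and monotonicity in CL_gut
  set.seed(51)
  for (i in 1:100) {
    f <- stats::runif(1, 0.05, 1)
    cl_iv <- stats::runif(1, 1, 100)
    cl_gut <- stats::runif(1, 1, 500)
    expect_equal(apparent_bioavailability(f, cl_iv, cl_gut) *
                   renal_clearance_route_ratio(cl_iv, cl_gut),
                 f, tolerance = 1e-12)
  }
  gq <- c(5, 10, 50, 1000)
  fa <- vapply(gq, function(g) apparent_bioavailability(0.8, 10, g),
               numeric(1))
  expect_true(all(diff(fa) < 0))
})

test_that("simulated AUC ratios expose the two frameworks' divergence", {
  # the same physical inputs, two generative interpretations
  f_true <- 0.8
  k_a <- 0.1; k_d <- 0.4; v <- 5000; dose <- 100
  cl_iv <- k_d * v                      # mL/h
  cl_gut <- k_a * v * 2                 # V_gut = 2*V_body, slow input
  times <- seq(0, 400, by = 0.1)
  # traditional generative model: the one-compartment ODE of the textbook
  sp <- one_compartment_spec(k_a = k_a, k_d = k_d, F_bio = f_true,
                             dose = dose, V_body = v)
  auc_oral <- nca(simulate_ode(sp, times, route = "oral"))$AUC_inf
  auc_iv <- nca(simulate_ode(sp, times, route = "iv_bolus"))$AUC_inf
  ratio_sim <- auc_oral / auc_iv
  expect_equal(ratio_sim, f_true, tolerance = 1e-3)
  expect_equal(ratio_sim,
               apparent_bioavailability(f_true, cl_iv, cl_gut, "traditional"),
               tolerance = 1e-3)
  # series-composition generative model: oral AUC = F*Dose/CL_total with the
  # gut stage in series; the same ratio now exceeds F_true
  auc_oral_k <- f_true * dose / total_clearance_oral(cl_gut, cl_iv)
  ratio_k <- auc_oral_k / (dose / cl_iv)
  expect_equal(ratio_k, apparent_bioavailability(f_true, cl_iv, cl_gut),
               tolerance = 1e-12)
  # the two frameworks genuinely diverge for finite gut clearance
  expect_gt(ratio_k, ratio_sim + 0.5)
})

test_that("oral comparison table tags every row with both frameworks", {
  tab <- oral_comparison(CL_iv_bolus = 600, CL_gut = 960, F_true = 0.8,
                         k_a = 0.07, k_avg_iv = 0.42)
  expect_setequal(names(tab), c("quantity", "unit", "traditional", "kirchhoff"))
  expect_equal(tab$traditional[tab$quantity == "CL_total"], 600)
  expect_equal(tab$kirchhoff[tab$quantity == "CL_total"], 600 / 1.625)
  expect_equal(tab$kirchhoff[tab$quantity == "terminal_slope"], 0.06,
               tolerance = 1e-12)
  expect_error(oral_comparison(600), "CL_gut")
})
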