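test_that("hepatic series model and its limits", {
  expect_equal(hepatic_intrinsic(3, 2), 5)
  expect_equal(hepatic_intrinsic(0, 7), 7)
  # symmetric harmonic mean
  p <- hepatic_processes(1500, 1, 1500)
  expect_equal(hepatic_clearance(p)$value, 750)
  # flow-unlimited with transport: CL_int * net / (CL_int + net)
  p2 <- hepatic_processes(Inf, 1, 1000, CL_int_influx = 10,
                          CL_int_efflux = 0, transport_relevant = TRUE)
  expect_equal(hepatic_clearance(p2)$value, 1000 * 10 / 1010,
               tolerance = 1e-12)
  # flow-limited: intrinsic clearance huge -> CL_H -> Q_H
  p3 <- hepatic_processes(1500, 1, 1e12)
  expect_equal(hepatic_clearance(p3)$value, 1500, tolerance = 1e-6)
  # dropping the transport term reproduces the two-term form exactly
  p4a <- hepatic_processes(1200, 0.3, 4000)
  expect_equal(hepatic_clearance(p4a)$value,
               1200 * 0.3 * 4000 / (1200 + 0.3 * 4000), tolerance = 1e-12)
})

test_that("hepatic clearance never exceeds any rate-defining term", {
  set.seed(31)
  for (i in 1:100) {
    qh <- stats::runif(1, 500, 2000)
    fu <- stats::runif(1, 0.01, 1)
    clint <- stats::runif(1, 10, 5000)
    infl <- stats::runif(1, 10, 5000)
    effl <- stats::runif(1, 0, infl * 0.99)
    p <- hepatic_processes(qh, fu, clint, CL_int_influx = infl,
                           CL_int_efflux = effl, transport_relevant = TRUE)
    cl <- hepatic_clearance(p)$value
    expect_lte(cl, min(qh, fu * clint, fu * (infl - effl)) + 1e-9)
  }
  # equals the smallest term when the others blow up
  p <- hepatic_processes(Inf, 1, 1e12, CL_int_influx = 1e12 + 50,
                         CL_int_efflux = 1e12, transport_relevant = TRUE)
  expect_equal(hepatic_clearance(p)$value, 50, tolerance = 1e-3)
})

test_that("transport term demands influx above efflux; ECM does not", {
  expect_error(
    hepatic_processes(1500, 1, 1000, CL_int_influx = 5, CL_int_efflux = 10,
                      transport_relevant = TRUE),
    "influx > efflux")
  p <- hepatic_processes(1500, 1, 1000, CL_int_influx = 5, CL_int_efflux = 10)
  expect_equal(ecm_clearance(p), 5 * 1000 / 1010)
  # efflux zero: ECM collapses to unbound influx clearance
  p0 <- hepatic_processes(1500, 0.4, 1000, CL_int_influx = 80)
  expect_equal(ecm_clearance(p0), 0.4 * 80)
  # influx = efflux = CL_int = x, f_uB = 1 -> x/2
  px <- hepatic_processes(1500, 1, 200, CL_int_influx = 200,
                          CL_int_efflux = 200)
  expect_equal(ecm_clearance(px), 100)
  p5 <- hepatic_processes(Inf, 1, 1000, CL_int_influx = 10, CL_int_efflux = 5)
  expect_equal(ecm_clearance(p5), 10 * 1000 / 1005)
})

test_that("hepatic availability is the flow-normalized complement", {
  expect_equal(hepatic_availability(0, 1500), 1)
  expect_equal(hepatic_availability(1500, 1500), 0)
  expect_equal(hepatic_availability(750, 1500), 0.5)
  expect_error(hepatic_availability(1600, 1500), "exceed")
  expect_equal(efficiency_number(1, 1500, 1500), 1)
  expect_equal(efficiency_number(0.5, 3000, 1500), 1)
  expect_equal(efficiency_number(0.1, 150, 1500), 0.01)
})

test_that("Kp_uu curves match their steady-state oracles", {
  fh <- seq(0.05, 0.95, by = 0.05)
  # WSM: root-found well-stirred steady state
  for (f in c(0.1, 0.5, 0.9)) {
    o <- wsm_oracle(fu_clint = (1 - f) / f * 1000, q = 1000)
    expect_equal(o$F_H, f, tolerance = 1e-9)
    expect_equal(kpuu_curve("WSM", f), o$kpuu, tolerance = 1e-9)
  }
  # PTM: discretized tube at 1e4 segments; the segment model carries O(1/N)
  # bias in its own availability, so compare Kp_uu at the availability the
  # tube actually realizes
  for (f in c(0.1, 0.3, 0.5, 0.8)) {
    o <- tube_oracle(-log(f), n = 1e4)
    expect_equal(o$F_H, f, tolerance = 1e-3)
    expect_equal(kpuu_curve("PTM", o$F_H), o$kpuu, tolerance = 1e-4)
  }
  expect_equal(kpuu_curve("PTM", 0.5), (1 - 0.5) / log(2), tolerance = 1e-12)
  expect_equal(kpuu_curve("PTM", 1), 1)   # continuous limit
  # shape claims: bounded by 1, PTM above WSM, both strictly increasing
  w <- kpuu_curve("WSM", fh); ptm <- kpuu_curve("PTM", fh)
  expect_true(all(w > 0 & w <= 1))
  expect_true(all(ptm > 0 & ptm <= 1))
  expect_true(all(ptm >= w))
  expect_true(all(diff(w) > 0) && all(diff(ptm) > 0))
  expect_error(kpuu_curve("WSM", 1.2), "0, 1")
})

test_that("ECM Kp_uu matches the mass-balance solve and sits below F_H", {
  set.seed(41)
  for (i in 1:50) {
    effl <- stats::runif(1, 0, 200)
    clint <- stats::runif(1, 200, 3000)
    # uptake-limited OATP-substrate regime: membrane uptake well below the
    # total of efflux and elimination
    infl <- stats::runif(1, 1, 0.15 * (effl + clint))
    k <- kpuu_curve("ECM", CL_int_influx = infl, CL_int_efflux = effl,
                    CL_H_int = clint)
    expect_equal(k, ecm_oracle(infl, effl, clint), tolerance = 1e-10)
    # uptake-limited regime (influx < efflux + CL_int): Kp_uu below the
    # availability implied by the ECM clearance
    fu <- stats::runif(1, 0.05, 1)
    qh <- stats::runif(1, 800, 1600)
    p <- hepatic_processes(qh, fu, clint, CL_int_influx = infl,
                           CL_int_efflux = effl)
    fh <- hepatic_availability(min(ecm_clearance(p), qh), qh)
    expect_lt(k, fh + 1e-12)
  }
})

test_that("saturable clearance composes capacity, saturation and flow", {
  # V_max 100 mg/h, K_M 10 mg/L, S 10 mg/L, Q_H 90 L/h
  expect_equal(saturable_clearance(100, 10, 10, 90), 1 / (0.2 + 1 / 90),
               tolerance = 1e-12)
  # brute-force inverse sum agrees
  expect_equal(1 / saturable_clearance(100, 10, 10, 90),
               sum(1 / c(100 / 10, 100 / 10, 90)), tolerance = 1e-12)
  # flow-unlimited limit is classical Michaelis-Menten, exactly
  expect_identical(saturable_clearance(100, 10, 10, Inf), 100 / (10 + 10))
  expect_identical(saturable_clearance(100, 10, 0, Inf), 10)
  # monotone: decreasing in S, increasing in Q_H
  s <- seq(0, 50, by = 5)
  cls <- saturable_clearance(100, 10, s, 90)
  expect_true(all(diff(cls) < 0))
  q <- c(10, 30, 90, 270)
  clq <- vapply(q, function(qq) saturable_clearance(100, 10, 10, qq),
                numeric(1))
  expect_true(all(diff(clq) > 0))
  expect_error(saturable_clearance(-1, 10), "V_max")
})
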