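test_that("the viscous drop matches the Poiseuille closed form on uniform tubes", {
  cases <- list(c(L = 30, r = 1.5, Q = 120), c(L = 50, r = 2, Q = 300),
                c(L = 12, r = 0.8, Q = 40))
  for (cs in cases) {
    prof <- data.frame(s = seq(0, cs[["L"]], 0.25), r = cs[["r"]])
    got <- segment_pressure_drop(prof, cs[["Q"]])
    want <- poiseuille_R(cs[["L"]], cs[["r"]]) * cs[["Q"]]
    expect_lt(abs(got - want) / want, 1e-3)
  }
  expect_equal(segment_pressure_drop(data.frame(s = c(0, 10), r = 2), 0), 0)
  expect_error(segment_pressure_drop(data.frame(s = c(0, 10), r = 2), -5),
               class = "coroflow_domain_error")
})

test_that("a stenosed tube always drops more pressure than a uniform one", {
  s <- seq(0, 30, 0.25)
  uni <- data.frame(s = s, r = rep(1.5, length(s)))
  dis <- apply_stenosis(make_tube(L = 30, r = 1.5, spacing = 0.25),
                        stenosis_spec("tube", 15, 10, 75))
  prof <- dis$branches$tube$samples[, c("s", "r")]
  for (Q in c(10, 60, 200)) {
    expect_gt(segment_pressure_drop(prof, Q),
              segment_pressure_drop(uni, Q))
  }
})

test_that("a single tube with an outlet resistance solves in closed form", {
  tr <- make_tube(L = 30, r = 1.5)
  R_v <- poiseuille_R(30, 1.5)
  bcs <- data.frame(outlet_id = "tube", R = 0.85, p0 = 0)
  sol <- solve_flow(tr, 85, bcs)
  expect_true(sol$converged)
  expect_equal(sol$inlet_flow, 85 / (R_v + 0.85), tolerance = 1e-8)
  # linearity: without expansion losses, doubling the drive doubles the flow
  sol2 <- solve_flow(tr, 170, bcs)
  expect_equal(sol2$inlet_flow, 2 * sol$inlet_flow, tolerance = 1e-6)
})

test_that("a two-outlet linear tree matches the resistor-network oracle to 1e-6", {
  tr <- make_fork()
  Pin <- 85; Ra <- 0.9; Rb <- 1.4
  R0 <- poiseuille_R(20, 2); R1 <- poiseuille_R(25, 1.4)
  R2 <- poiseuille_R(18, 1.1)
  # independent oracle: solve the 2x2 resistor network directly
  A <- matrix(c(R0 + R1 + Ra, R0, R0, R0 + R2 + Rb), 2, 2, byrow = TRUE)
  q_exact <- solve(A, c(Pin, Pin))
  sol <- solve_flow(tr, Pin, data.frame(outlet_id = c("c1", "c2"),
                                        R = c(Ra, Rb), p0 = 0))
  got <- unname(sol$outlet_flows[c("c1", "c2")])
  expect_lt(max(abs(got - q_exact) / q_exact), 1e-6)
})

test_that("symmetric daughters carry equal flows", {
  tr <- make_fork(r1 = 1.3, r2 = 1.3, L1 = 22, L2 = 22)
  sol <- solve_flow(tr, 85, data.frame(outlet_id = c("c1", "c2"),
                                       R = c(1, 1), p0 = 0))
  expect_equal(unname(sol$outlet_flows["c1"]),
               unname(sol$outlet_flows["c2"]), tolerance = 1e-10)
})

test_that("mass is conserved at every junction and pressure is monotone", {
  for (seed in c(4, 17, 23)) {
    cs <- make_stenosed_case(seed, severity = 60)
    tr <- cs$diseased
    bc <- build_outlet_bcs(tr, cs$patient)
    sol <- solve_flow(tr, bc$inlet_pressure, bc$bcs)
    # global conservation
    expect_equal(sol$inlet_flow, sum(sol$outlet_flows), tolerance = 1e-9)
    # per-junction: parent subtree flow = own outlet + children subtree flows
    ch <- coroflow:::tree_children(tr)
    for (id in names(tr$branches)) {
      own <- if (id %in% names(sol$outlet_flows)) sol$outlet_flows[[id]] else 0
      kid <- sum(vapply(ch[[id]]$id,
                        function(k) sol$branch_flows[[k]], numeric(1)))
      expect_equal(sol$branch_flows[[id]], own + kid, tolerance = 1e-9)
    }
    # monotone non-increasing pressure along every branch, bounded by inlet
    sp <- sol$sample_pressures
    for (id in unique(sp$branch_id)) {
      p <- sp$pressure[sp$branch_id == id]
      expect_true(all(diff(p) <= 1e-9))
      expect_true(all(p <= bc$inlet_pressure + 1e-9))
    }
  }
})

test_that("the flow solution is independent of the starting point", {
  cs <- make_stenosed_case(31, severity = 80)
  bc <- build_outlet_bcs(cs$diseased, cs$patient)
  sol1 <- solve_flow(cs$diseased, bc$inlet_pressure, bc$bcs)
  init <- sol1$outlet_flows * c(4, 0.1, 2, 0.5)[seq_along(sol1$outlet_flows)]
  sol2 <- solve_flow(cs$diseased, bc$inlet_pressure, bc$bcs,
                     init_flows = init)
  expect_equal(sol1$outlet_flows, sol2$outlet_flows, tolerance = 1e-6)
})

test_that("calibration reaches the hyperemic target on a healthy tube", {
  tr <- make_tube()
  pat <- patient_record(120, 70, 16, mbp = 91.8)
  par <- hemo_params(flow_coeff = 21 / 16^0.75)
  bc <- build_outlet_bcs(tr, pat, par)
  cal <- calibrate_total_flow(tr, bc$inlet_pressure, bc$bcs, bc$target_flow,
                              params = par)
  expect_lt(abs(cal$solution$inlet_flow - 100) / 100, 1e-3)
})

test_that("severe stenosis calibrates to target with lower distal pressure", {
  cs <- make_stenosed_case(12, severity = 85)
  ffr_dis <- case_ffr(cs$diseased, cs)
  ffr_healthy <- case_ffr(cs$healthy, cs)
  expect_lt(ffr_dis, ffr_healthy)
  bc <- build_outlet_bcs(cs$diseased, cs$patient)
  cal <- calibrate_total_flow(cs$diseased, bc$inlet_pressure, bc$bcs,
                              bc$target_flow)
  expect_lt(abs(cal$solution$inlet_flow - bc$target_flow) / bc$target_flow,
            1e-3)
})

test_that("a severe lesion on the sole flow path cannot reach the target", {
  tr <- make_tube(L = 40, r = 2, spacing = 0.25)
  dis <- apply_stenosis(tr, stenosis_spec("tube", 20, 10, 90))
  pat <- patient_record(127, 74, 114)
  bc <- build_outlet_bcs(dis, pat)
  expect_error(
    calibrate_total_flow(dis, bc$inlet_pressure, bc$bcs, bc$target_flow),
    class = "coroflow_convergence_error")
})
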