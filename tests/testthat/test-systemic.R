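# Coupled wounded-plant model. Heavier fixtures (the flagship full-resolution
# run) are cached in helper-fixtures.R and shared with the acceptance suite.

coarse_cfg <- function(...) solver_config(n_cells_x = 60, n_cells_y = 24,
                                          n_times = 120, ...)

test_that("steady state: no transpiration means atmospheric equilibrium", {
  s <- make_scenario("arabidopsis_fig2", list(E = 0))
  st <- steady_state(s, coarse_cfg())
  expect_equal(max(abs(st$P_xyl)), 0)
  expect_equal(max(abs(st$P_t - s$pi_t)), 0)
})

test_that("steady state: preset mean xylem pressure brackets P0", {
  s <- make_scenario("arabidopsis_fig2")
  st <- steady_state(s, solver_config())
  expect_gt(mean(st$P_xyl), -0.3e6)
  expect_lt(mean(st$P_xyl), -0.1e6)
  # tissue in local water-potential equilibrium
  expect_equal(st$P_t[, 1], st$P_xyl + s$pi_t)
})

test_that("steady state is linear in E and fails cleanly when unclosable", {
  s1 <- make_scenario("arabidopsis_fig2", list(E = 0.5e-3))
  s2 <- make_scenario("arabidopsis_fig2", list(E = 1.0e-3))
  p1 <- steady_state(s1, coarse_cfg())$P_xyl
  p2 <- steady_state(s2, coarse_cfg())$P_xyl
  expect_equal(2 * (0 - p1), 0 - p2, tolerance = 1e-10)
  sbad <- make_scenario("arabidopsis_fig2", list(h_stem = 0))
  expect_error(steady_state(sbad, coarse_cfg()), "no steady state")
})

test_that("sustained wound: xylem equilibrates by 5 tau_xyl, tissue by ~3 tau_t", {
  s <- fig2_scenario()
  res <- fig2_run("full")
  ts <- characteristic_timescales(s)
  k5 <- which(res$times >= 5 * ts[["tau_xyl"]])[1]
  expect_lt(max(abs(res$P_xyl[k5, ])), 0.05 * abs(s$P0))   # >= 95% equilibrated
  kend <- length(res$times)
  expect_gte(res$times[kend], 2.99 * ts[["tau_t"]])
  p_mid <- res$P_t[, 50, res$mesh_y$n_cells]
  recovery <- (p_mid[kend] - p_mid[1]) / (0.75e6 - p_mid[1])
  expect_gt(recovery, 0.95)                                 # approaching 0.75 MPa
  expect_equal(res$P_t[kend, 50, res$mesh_y$n_cells], 0.75e6,
               tolerance = 2e-3)
})

test_that("water balance residual stays below 1e-6 of the largest term", {
  res <- fig2_run("full")
  wb <- water_balance(res)
  biggest <- pmax(abs(wb$wound_influx), abs(wb$stem_influx),
                  abs(wb$transpiration_efflux), abs(wb$tissue_storage_rate),
                  abs(wb$xylem_storage_rate))
  keep <- biggest > 0
  expect_true(all(abs(wb$residual[keep]) <= 1e-6 * biggest[keep]))
})

test_that("pre-wound steady state: stem influx balances transpiration", {
  s <- make_scenario("arabidopsis_fig2",
                     list(wound = list(mode = "none")))
  res <- simulate_wound_response(s, coarse_cfg(t_end = 100), mode = "full")
  wb <- water_balance(res)
  n <- nrow(wb)
  expect_equal(wb$stem_influx[n], wb$transpiration_efflux[n],
               tolerance = 1e-6)
  expect_lt(abs(wb$tissue_storage_rate[n]), 1e-8 * wb$transpiration_efflux[n])
  # unwounded run stays at the steady state for all t
  expect_lt(max(abs(sweep(res$P_xyl, 2, res$P_xyl[1, ]))), 1e-6 * abs(s$P0))
})

test_that("cumulative wound influx matches capacitance x pressure change (E = 0)", {
  s <- fig2_scenario(E = 0)
  res <- fig2_run_nontranspiring()
  wb <- water_balance(res)
  # trapezoid in time of the influx rate
  influx <- sum(diff(res$times) *
                  (wb$wound_influx[-1] + wb$wound_influx[-nrow(wb)]) / 2)
  tissue_vol <- 2 * half_spacing(s) * s$d_th * s$L
  expected <- s$c_t * (s$pi_t - (s$P0 + s$pi_t)) * tissue_vol +
    s$c_xyl * s$a_xyl * s$L * (0 - s$P0)
  expect_equal(influx, expected, tolerance = 1e-2)
})

test_that("sustained wound with E = 0 relaxes monotonically everywhere", {
  res <- fig2_run_nontranspiring()
  tolP <- 1e-9 * 0.2e6
  expect_true(all(diff(res$P_xyl) >= -tolP))
  p_mid <- res$P_t[, 30, res$mesh_y$n_cells]
  p_near <- res$P_t[, 30, 1]
  expect_true(all(diff(p_mid) >= -tolP))
  expect_true(all(diff(p_near) >= -tolP))
})

test_that("tissue_series extracts a valid transverse pressure history", {
  res <- fig2_run("full")
  fs <- tissue_series(res, x_index = 50)
  expect_s3_class(fs, "field_series")
  expect_equal(fs$mesh$n_cells, res$mesh_y$n_cells)
  expect_identical(fs$times, res$times)
  expect_equal(fs$values[1, ], res$P_t[1, 50, ])
  # and it feeds the swelling pipeline
  dil <- dilation_field(fs, res$scenario)
  expect_gt(dil$theta[length(dil$theta)], 0.95)
})

test_that("full and quasi-steady modes agree to 1% for t >= 10 tau_xyl", {
  res_a <- fig2_run("full")
  res_b <- fig2_run("quasi_steady")
  expect_identical(res_a$times, res_b$times)
  ts <- characteristic_timescales(fig2_scenario())
  keep <- res_a$times >= 10 * ts[["tau_xyl"]]
  dP <- abs(res_a$P_t[keep, , ] - res_b$P_t[keep, , ])
  expect_lt(max(dP) / abs(fig2_scenario()$P0), 0.01)
})

test_that("wounded-leaf axial flow runs from wound toward stem for t > tau_xyl", {
  res <- fig2_run("full")
  ts <- characteristic_timescales(fig2_scenario())
  keep <- res$times > ts[["tau_xyl"]]
  i_stem <- which.min(abs(res$mesh_x$centers - res$scenario$L / 2))
  # faces strictly between wound and stem; positive J = toward the stem
  expect_true(all(res$J[keep, 2:i_stem] > 0))
})

test_that("tissue 63%-recovery time scales as W^2 (R^2 > 0.999)", {
  spacings <- c(2e-4, 4e-4, 8e-4)
  t63 <- vapply(spacings, function(vs) {
    s <- make_scenario("arabidopsis_fig2", list(E = 0, vein_spacing = vs))
    res <- simulate_wound_response(s, coarse_cfg(), mode = "quasi_steady")
    tissue_recovery_time(res, frac = 0.63)
  }, numeric(1))
  fit <- stats::lm(t63 ~ I((spacings / 2)^2))
  expect_gt(summary(fit)$r.squared, 0.999)
  expect_true(all(diff(t63) > 0))
})

test_that("simulated xylem 95%-equilibration time scales as L^2", {
  teq <- vapply(c(0.01, 0.03, 0.10), function(L) {
    # scale the stem coupling with L so the pre-wound tension stays P0
    # (the "same plant, scaled up" comparison)
    s <- make_scenario("arabidopsis_fig2",
                       list(L = L, a_stem = 4e-6 * L / 0.01))
    res <- simulate_wound_response(
      s, solver_config(n_cells_x = 60, n_cells_y = 16, n_times = 160,
                       t_end = 10 * L^2 / s$kappa_xyl), mode = "full")
    dev <- apply(abs(res$P_xyl), 1, max) / abs(s$P0)
    res$times[which(dev <= 0.05)[1]]
  }, numeric(1))
  L2 <- c(0.01, 0.03, 0.10)^2
  fit <- stats::lm(teq ~ L2)
  expect_gt(summary(fit)$r.squared, 0.999)
})

test_that("depleting reservoir: switch recorded, early exhaustion warns", {
  s <- make_scenario("arabidopsis_fig2",
                     list(wound = list(mode = "depleting_reservoir",
                                       reservoir_moles = 1e-7)))
  res <- cached("fig2_depleting",
                simulate_wound_response(s, solver_config(), mode = "full"))
  expect_false(is.na(res$switch_time))
  expect_gt(res$switch_time, 0)
  s2 <- make_scenario("arabidopsis_fig2",
                      list(wound = list(mode = "depleting_reservoir",
                                        reservoir_moles = 1e-13)))
  expect_warning(
    simulate_wound_response(s2, coarse_cfg(), mode = "quasi_steady"),
    "exhausted before")
})
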