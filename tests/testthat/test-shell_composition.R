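test_that("two-state shell fraction inverts the weighted-mean energy", {
  expect_equal(as.numeric(shell_mole_fraction_simple(60.68, 60.68, 68.7)), 0)
  expect_equal(as.numeric(shell_mole_fraction_simple(68.7, 60.68, 68.7)), 1)
  mid <- (60.68 + 68.7) / 2
  expect_equal(as.numeric(shell_mole_fraction_simple(mid, 60.68, 68.7)), 0.5)
  expect_error(shell_mole_fraction_simple(65, 64, 64), "degenerate|distinct")
})

test_that("shell fraction is affine and monotone in energy, never clipped", {
  et <- seq(59, 70, by = 0.25)
  x2s <- as.numeric(shell_mole_fraction_simple(et, 60.68, 68.7))
  expect_true(all(diff(x2s) > 0))
  expect_equal(diff(x2s, differences = 2), rep(0, length(et) - 2),
               tolerance = 1e-12)
  # synergistic energies beyond the endpoints flag but keep the raw value
  syn <- shell_mole_fraction_simple(69.5, 60.68, 68.7)
  expect_gt(as.numeric(syn), 1)
  expect_true(attr(syn, "out_of_range"))
})

test_that("preferential solvation parameter carries the sign convention", {
  expect_equal(preferential_solvation_parameter(0.5, 0.5), 0)
  expect_equal(preferential_solvation_parameter(0.7, 0.3), 0.4)
  expect_equal(preferential_solvation_parameter(0.2, 0.5), -0.3)
})

test_that("a series on the ideal line has zero preference everywhere", {
  x2 <- seq(0, 1, by = 0.1)
  s <- titration_series(x2, ideal_mixture_energy(x2, 62, 68))
  sh <- shell_series(s)
  expect_equal(sh$delta_s2, rep(0, length(x2)), tolerance = 1e-12)
  expect_equal(attr(sh, "excess_extremum"), 0, tolerance = 1e-12)
  expect_equal(attr(sh, "excess_integral"), 0, tolerance = 1e-12)
})

test_that("delta_s2 vanishes at both pure-solvent endpoints", {
  for (nm in names(scenario_library())) {
    sh <- shell_series(sim_scenario(nm, grid = seq(0, 1, 0.1)))
    expect_equal(sh$delta_s2[sh$x2 == 0], 0, tolerance = 1e-12)
    expect_equal(sh$delta_s2[sh$x2 == 1], 0, tolerance = 1e-12)
  }
})

test_that("without the intersolvent complex, preference matches the two-state oracle", {
  # closed-form oracle: x2s/x1s = f2/1 (x2/x1)^m. At m = 1 the sign of
  # delta_s2 equals sign(f2/1 - 1) at every interior point; at m > 1 the
  # isotherm crosses the diagonal, so only sign agreement with the oracle
  # (not with f2/1 - 1) can hold pointwise.
  grid <- seq(0.01, 0.99, length.out = 99)
  for (f in c(0.2, 0.74, 1.5, 3)) {
    for (m in c(1, 2)) {
      params <- exchange_params(62, 68, 65, f2_1 = f, f12_1 = 0, m = m)
      s <- simulate_exchange_series(params, grid = c(0, grid, 1),
                                    noise = noise_spec(0, 1))
      sh <- shell_series(s)
      inner <- sh$x2 > 0 & sh$x2 < 1
      oracle <- two_state_x2s(sh$x2[inner], f, m) - sh$x2[inner]
      expect_equal(sh$delta_s2[inner], oracle, tolerance = 1e-9)
      if (m == 1) {
        expect_true(all(sign(sh$delta_s2[inner]) == sign(f - 1)),
                    info = sprintf("f2/1 = %g", f))
      } else {
        clear <- abs(oracle) > 1e-6  # away from the diagonal crossing
        expect_true(all(sign(sh$delta_s2[inner][clear]) ==
                          sign(oracle[clear])),
                    info = sprintf("f2/1 = %g, m = %g", f, m))
      }
    }
  }
})

test_that("shell series of a water + ethanol-like mixture prefers S1", {
  sh <- shell_series(sim_scenario("Water + EtOH", grid = seq(0, 1, 0.05)))
  inner <- sh$x2 > 0 & sh$x2 < 1
  expect_true(all(sh$delta_s2[inner] < 0))
  expect_lt(attr(sh, "delta_min")["delta_s2"], 0)
})

test_that("summary attributes locate extrema and sign crossings", {
  # construct a biphasic curve: S1-preferential then S2-preferential
  params <- scenario_library()[["Water + MeOH"]]
  sh <- shell_series(sim_scenario("Water + MeOH", grid = seq(0, 1, 0.05)))
  dmax <- attr(sh, "delta_max")
  expect_equal(unname(dmax["delta_s2"]),
               max(sh$delta_s2), tolerance = 1e-12)
  expect_true(all(attr(sh, "sign_crossings") > 0 &
                    attr(sh, "sign_crossings") < 1))
})

test_that("endpoint-only series yields zero preference at both ends", {
  s <- titration_series(c(0, 1), c(60.68, 68.7))
  expect_error(shell_series(s), NA)
  sh <- shell_series(s)
  expect_equal(sh$delta_s2, c(0, 0))
})

test_that("shell table writes the delimited interface format", {
  sh <- shell_series(sim_scenario("Benzene + MeOH", grid = seq(0, 1, 0.1)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_shell_table(sh, path)
  back <- utils::read.csv(path)
  expect_named(back, c("x2", "x2s", "delta_s2"))
  expect_equal(back$delta_s2, sh$delta_s2, tolerance = 1e-12)
})
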