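test_that("mass-transfer rate follows the geometry closed form", {
  g <- vessel_geometry(V = 1000, L = 10, D = 50, R = 1000)
  k <- kflow_from_vessel(g)
  expect_equal(k, 0.75 * (1000^2 * 50 / (1000 * 10)^2)^(1 / 3),
               tolerance = 1e-12)
  expect_equal(k, 0.5952754, tolerance = 1e-6)
  # cross-check by cubing: (4k/3)^3 == V^2 D / (RL)^2
  expect_equal((4 * k / 3)^3, 0.5, tolerance = 1e-12)

  # homogeneity: doubling V multiplies by 2^(2/3); V -> 0 vanishes
  g2 <- vessel_geometry(V = 2000, L = 10, D = 50, R = 1000)
  expect_equal(kflow_from_vessel(g2) / k, 2^(2 / 3))
  expect_equal(kflow_from_vessel(vessel_geometry(V = 1e-12, R = 1000)), 0,
               tolerance = 1e-6)
  expect_error(vessel_geometry(V = 0, R = 1000), "positive")
})

test_that("pathway variants nullify exactly the documented reactions", {
  r <- table1_rates()

  ni <- apply_pathway_variant(r, "NI")
  zeroed <- c("k_plus_4", "k_minus_4", "k_plus_6", "k_minus_6",
              "k_plus_7", "k_minus_7", "k_plus_8", "k_minus_8")
  expect_equal(unname(unclass(ni)[zeroed]), rep(0, 8))
  expect_equal(unclass(ni)[c("k_plus_1", "k_minus_1", "k_plus_2",
                             "k_plus_3", "k_minus_3")],
               unclass(r)[c("k_plus_1", "k_minus_1", "k_plus_2",
                            "k_plus_3", "k_minus_3")])

  dib <- apply_pathway_variant(r, "DIB")
  expect_equal(dib, r)  # reaction 5 is already zero in the medians

  expect_error(apply_pathway_variant(r, "XX"), "unknown")
})

test_that("solution-phase Xa:TFPI only arises through reaction 4 or
           dissociation of the quaternary complex (reverse 8)", {
  # both routes off: PI can never appear
  r48 <- nullify_reactions(table1_rates(), c(4, 8))
  tr <- simulate_flow(species_state(E = 1), r48, flow_config(k_flow = 1),
                      seq(0, 600, by = 60))
  expect_lt(max(abs(tr$PI)), 1e-12)

  # the DB variant keeps reaction 8, so a trace of PI leaks out of the
  # quaternary complex even though solution binding (reaction 4) is off;
  # it stays far below the TFPI pool
  db <- apply_pathway_variant(table1_rates(), "DB")
  tr2 <- simulate_flow(species_state(E = 1), db, flow_config(k_flow = 1),
                       seq(0, 600, by = 60))
  expect_gt(max(tr2$PI), 0)
  expect_lt(max(tr2$PI), 0.01)
})

test_that("flow derivatives reduce to static at k_flow = 0 and add only
           inflow/outflow terms", {
  set.seed(11)
  for (i in 1:10) {
    st <- random_state()
    r <- random_rates()
    expect_identical(flow_rhs(st, r, flow_config(k_flow = 0)),
                     static_rhs(st, r))
    fl <- flow_config(k_flow = 1.7, S_up = 170, I_up = 2.4)
    diffd <- flow_rhs(st, r, fl) - static_rhs(st, r)
    expect_equal(unname(diffd[c("S", "P", "I", "PI")]),
                 c(1.7 * (170 - st[["S"]]), -1.7 * st[["P"]],
                   1.7 * (2.4 - st[["I"]]), -1.7 * st[["PI"]]))
    expect_equal(unname(diffd[c("E", "ES", "EP", "EPI", "PIE")]),
                 rep(0, 5))
    # enzyme moiety untouched by flow for arbitrary states
    d <- flow_rhs(st, r, fl)
    expect_equal(sum(d[c("E", "ES", "EP", "EPI", "PIE")]), 0,
                 tolerance = 1e-12)
  }

  # pure inflow at an empty reaction zone
  d0 <- flow_rhs(species_state(), table1_rates(),
                 flow_config(k_flow = 1, S_up = 170, I_up = 2.4))
  expect_equal(unname(d0), c(0, 170, 0, 0, 0, 2.4, 0, 0, 0))
})

test_that("k_flow = 0 flow simulation equals the static simulation", {
  init <- species_state(E = 0.128, S = 170, I = 2.4)
  times <- seq(0, 720, by = 120)
  a <- simulate_static(init, table1_rates(), times)
  b <- simulate_flow(init, table1_rates(), flow_config(k_flow = 0), times)
  expect_lt(max(abs(as.matrix(a[-1]) - as.matrix(b[-1]))), 1e-8)
})

test_that("enzyme moiety stays fixed over 15 simulated minutes of flow", {
  tr <- simulate_flow(species_state(E = 1), table1_rates(),
                      flow_config(k_flow = 1), seq(0, 900, by = 60))
  ct <- conserved_totals(tr)
  expect_lt(max(abs(ct$enzyme - 1)), 1e-8)
})

test_that("functional enzyme metric is E + ES", {
  expect_equal(e_functional(species_state(E = 0.542, ES = 0.376)), 0.918)
  expect_equal(e_functional(species_state()), 0)
  expect_equal(e_functional(species_state(E = 1)), 1)
})

test_that("steady state solves the flow balance and matches the
           closed-form no-TFPI oracle", {
  ni <- apply_pathway_variant(table1_rates(), "NI")
  for (kf in c(1e-3, 1, 1e3)) {
    fl <- flow_config(k_flow = kf)
    ss <- steady_state(ni, fl, enzyme_total = 1)
    expect_lt(max(abs(flow_rhs(ss, ni, fl))), 1e-10)
    expect_equal(sum(ss[c("E", "ES", "EP", "EPI", "PIE")]), 1,
                 tolerance = 1e-8)
    oracle <- ni_steady_state_oracle(ni, kf)
    expect_lt(max(abs(ss[c("E", "S", "ES", "EP", "P")] -
                      oracle[c("E", "S", "ES", "EP", "P")])), 1e-4)
  }
})

test_that("long-horizon NI flow integration approaches the steady state", {
  ni <- apply_pathway_variant(table1_rates(), "NI")
  fl <- flow_config(k_flow = 1)
  ss <- steady_state(ni, fl, enzyme_total = 1)
  tr <- simulate_flow(species_state(E = 1), ni, fl, c(0, 5e4))
  expect_lt(max(abs(unlist(tr[2, -1]) - unname(ss))), 1e-3)
})

test_that("NI steady-state functional enzyme is nondecreasing in flow
           and reproduces the printed plateau values", {
  sw <- flow_sweep(table1_rates(), "NI")
  expect_true(all(diff(sw$E_functional_nM) >= -1e-9))
  expect_equal(sw$E_functional_nM[sw$k_flow_per_s == 1e-3], 0.755,
               tolerance = 0.01)
  expect_equal(sw$E_functional_nM[sw$k_flow_per_s == 1], 0.918,
               tolerance = 0.01)
})

test_that("product-inhibition scaling maps phi to K_D_3 and lowers the
           curves monotonically", {
  grid <- 10^seq(-3, 3, length.out = 7)
  fam <- product_inhibition_sweep(table1_rates(),
                                  phi_values = c(1, 10, 100, 1000),
                                  kflow_grid = grid)
  # phi = 1 is the plain NI sweep
  plain <- flow_sweep(table1_rates(), "NI", grid)
  expect_equal(fam$E_functional_nM[fam$phi == 1], plain$E_functional_nM,
               tolerance = 1e-9)
  # K_D_3 scales as 520/phi
  for (phi in c(1, 10, 100, 1000)) {
    r <- unclass(table1_rates())
    expect_equal(r[["k_minus_3"]] / phi / r[["k_plus_3"]], 520 / phi,
                 tolerance = 0.025)
  }
  # curves strictly ordered downward in phi at every grid point
  m <- matrix(fam$E_functional_nM, nrow = length(grid))
  for (j in 2:4) expect_true(all(m[, j] < m[, j - 1] + 1e-12))
})
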