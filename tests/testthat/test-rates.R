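test_that("standard activity shows half-saturation and the saturation limit", {
  ls <- thermo_landscape(-25, -40)
  rc <- rate_constants(ls)
  km <- michaelis_constant(ls)
  ET <- 0.01
  expect_equal(activity(ls, assay_condition(S = km, ET = ET)),
               rc$k2 * ET / 2, tolerance = 1e-12)
  # saturation: v -> k2 ET as S -> Inf
  expect_equal(activity(ls, assay_condition(S = 1e12, ET = ET)),
               rc$k2 * ET, tolerance = 1e-6)
  expect_equal(activity(ls, assay_condition(S = 0)), 0)
  expect_equal(activity(ls, assay_condition(S = 10, ET = 0)), 0)
  expect_equal(activity(ls, assay_condition(S = 10, ET = ET)),
               oracle_landscape$v_S10_ET0.01, tolerance = 1e-12)
  expect_error(activity(ls, assay_condition(S = 1, mechanism = "reversible")),
               "standard")
})

test_that("strong binding wins at low [S], weak binding at high [S]", {
  # three landscapes sharing dGT = -40 kJ/mol
  enz <- lapply(c(-25, -20, -15), thermo_landscape, dGT = -40)
  v_low <- vapply(enz, function(e) activity(e, assay_condition(S = 0.05)),
                  numeric(1))
  v_high <- vapply(enz, function(e) activity(e, assay_condition(S = 100)),
                   numeric(1))
  expect_equal(which.max(v_low), 1L)   # dG1 = -25 fastest below ~1 uM
  expect_equal(which.max(v_high), 3L)  # dG1 = -15 fastest well above 1 uM
})

test_that("activity is monotone in S and in the total driving force", {
  for (fx in generate_landscapes(50, seed = 3)) {
    ls <- fx$landscape
    S <- 10^seq(-2, 3, length.out = 30)
    v <- predict(ls, S = S)
    expect_true(all(diff(v) > 0))
  }
  # at fixed dG1, lowering dGT (more negative) raises v
  S <- 5
  v_by_dGT <- vapply(seq(-10, -70, by = -10), function(gt)
    activity(thermo_landscape(-15, gt), assay_condition(S = S)), numeric(1))
  expect_true(all(diff(v_by_dGT) > 0))
})

test_that("changing the concentration unit leaves dimensionless ratios unchanged", {
  # uM -> nM: concentrations scale by sc; the binding free energy shifts by
  # RT ln(sc) with the standard state, and the reference constants rescale as
  # k1_0 -> k1_0 sc^(alpha1-1), k2_0 -> k2_0 sc^(-alpha2), which keeps every
  # rate constant dimensionally consistent (k1, k2r in 1/(conc s) scale by
  # 1/sc; k1r, k2 in 1/s are untouched). v/(k2 ET) and Km/S are invariant.
  sc <- 1000
  a1 <- 0.4; a2 <- 0.7
  ls1 <- thermo_landscape(-18, -45, alpha1 = a1, alpha2 = a2, k1_0 = 2)
  RT <- ls1$RT
  ls2 <- thermo_landscape(-18 + RT * log(sc), -45, alpha1 = a1, alpha2 = a2,
                          k1_0 = 2 * sc^(a1 - 1), k2_0 = sc^(-a2))
  rc1 <- rate_constants(ls1)
  rc2 <- rate_constants(ls2)
  expect_equal(rc2$k1, rc1$k1 / sc, tolerance = 1e-12)
  expect_equal(rc2$k1r, rc1$k1r, tolerance = 1e-12)
  expect_equal(rc2$k2, rc1$k2, tolerance = 1e-12)
  expect_equal(rc2$k2r, rc1$k2r / sc, tolerance = 1e-12)
  S <- 3
  ET <- 0.01
  v1 <- activity(ls1, assay_condition(S = S, ET = ET))
  v2 <- activity(ls2, assay_condition(S = S * sc, ET = ET * sc))
  expect_equal(v1 / (rc1$k2 * ET), v2 / (rc2$k2 * ET * sc), tolerance = 1e-12)
  expect_equal(michaelis_constant(ls1) / S,
               michaelis_constant(ls2) / (S * sc), tolerance = 1e-12)
})

test_that("reversible net rate reduces, vanishes and changes sign correctly", {
  ls <- thermo_landscape(-20, -40)
  # irreversible limit P = 0
  expect_equal(net_rate_reversible(ls, assay_condition(S = 7, mechanism = "reversible")),
               activity(ls, assay_condition(S = 7)), tolerance = 1e-12)
  # equilibrium: P/S = exp(-dGT/RT) gives zero net rate
  S <- 1e-4
  P <- S * exp(-ls$dGT / ls$RT)
  v_eq <- net_rate_reversible(ls, assay_condition(S = S, P = P,
                                                  mechanism = "reversible"))
  scale <- abs(net_rate_reversible(ls, assay_condition(S = S, P = 0,
                                                       mechanism = "reversible")))
  expect_lt(abs(v_eq) / scale, 1e-12)
  # sign follows the total driving force at S = P
  fwd <- thermo_landscape(-20, -40)
  bwd <- thermo_landscape(-20, 40)
  cnd <- assay_condition(S = 10, P = 10, mechanism = "reversible")
  expect_gt(net_rate_reversible(fwd, cnd), 0)
  expect_lt(net_rate_reversible(bwd, cnd), 0)
  expect_equal(net_rate_reversible(ls, assay_condition(S = 0, P = 0,
                                                       mechanism = "reversible")), 0)
})

test_that("reversible net rate is antisymmetric under S<->P with role swap", {
  # swapping substrate and product, reversing dGT and swapping the roles of
  # the two steps (dG1' = dG2 reversed, alpha and k0 swapped) flips the sign
  for (fx in generate_landscapes(30, seed = 5)) {
    ls <- fx$landscape
    S <- fx$condition$S
    P <- fx$condition$P
    v <- net_rate_reversible(ls, assay_condition(S = S, P = P,
                                                 mechanism = "reversible"))
    ls_sw <- thermo_landscape(dG1 = -ls$dG2, dGT = -ls$dGT,
                              alpha1 = 1 - ls$alpha2, alpha2 = 1 - ls$alpha1,
                              k1_0 = ls$k2_0, k2_0 = ls$k1_0,
                              temperature = ls$temperature)
    v_sw <- net_rate_reversible(ls_sw, assay_condition(S = P, P = S,
                                                       mechanism = "reversible"))
    expect_equal(v_sw, -v, tolerance = 1e-12)
  }
})

test_that("reversible net rate increases with S at fixed P when dGT < 0", {
  ls <- thermo_landscape(-15, -30)
  S <- 10^seq(-2, 3, length.out = 25)
  v <- vapply(S, function(s)
    net_rate_reversible(ls, assay_condition(S = s, P = 5,
                                            mechanism = "reversible")),
    numeric(1))
  expect_true(all(diff(v) > 0))
})

test_that("inhibited rates reduce at gamma = 0 and fall with gamma", {
  ls <- thermo_landscape(-22, -40)
  v0 <- activity(ls, assay_condition(S = 10))
  for (mech in c("competitive", "uncompetitive")) {
    expect_equal(rate_inhibited(ls, assay_condition(S = 10, mechanism = mech,
                                                    gamma = 0)),
                 v0, tolerance = 1e-12)
    v_g <- vapply(c(0, 1, 5, 10, 100), function(g)
      rate_inhibited(ls, assay_condition(S = 10, mechanism = mech, gamma = g)),
      numeric(1))
    expect_true(all(diff(v_g) < 0))
  }
  expect_error(rate_inhibited(ls, assay_condition(S = 1)), "competitive")
})

test_that("reaction_rate dispatches on the mechanism tag", {
  ls <- thermo_landscape(-22, -40)
  expect_equal(reaction_rate(ls, assay_condition(S = 4)),
               activity(ls, assay_condition(S = 4)))
  cond_rev <- assay_condition(S = 4, P = 2, mechanism = "reversible")
  expect_equal(reaction_rate(ls, cond_rev), net_rate_reversible(ls, cond_rev))
  cond_ci <- assay_condition(S = 4, mechanism = "competitive", gamma = 3)
  expect_equal(reaction_rate(ls, cond_ci), rate_inhibited(ls, cond_ci))
})
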