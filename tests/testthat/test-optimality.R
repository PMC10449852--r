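test_that("closed-form optimum gives Km* = (alpha2/(1-alpha2)) [S]", {
  # symmetric coefficients: Km* = [S]
  o <- optimal_dG1_closed(S = 0.1, dGT = -40)
  expect_equal(o$Km_star, 0.1, tolerance = 1e-12)
  # general alpha1 + alpha2 = 1
  o74 <- optimal_dG1_closed(S = 10, dGT = -40, alpha1 = 0.26, alpha2 = 0.74)
  expect_equal(o74$Km_star, 0.74 / 0.26 * 10, tolerance = 1e-12)
  # half-saturation at the apex for alpha = 0.5
  ls_star <- thermo_landscape(o$dG1_star, -40)
  expect_equal(o$v_star, rate_constants(ls_star)$k2 * 0.01 / 2,
               tolerance = 1e-10)
  expect_error(optimal_dG1_closed(S = 1, dGT = -40, alpha1 = 0.3, alpha2 = 0.3),
               "optimize_numeric")
})

test_that("numeric optimizer agrees with the closed form when alpha1+alpha2=1", {
  for (a2 in c(0.3, 0.5, 0.74, 0.9)) {
    num <- optimize_numeric(S = 10, dGT = -40, alpha1 = 1 - a2, alpha2 = a2)
    cl <- optimal_dG1_closed(S = 10, dGT = -40, alpha1 = 1 - a2, alpha2 = a2)
    expect_lt(abs(num$dG1_star - cl$dG1_star), 1e-6)
    expect_equal(num$Km_star, cl$Km_star, tolerance = 1e-6)
  }
  # and across random constrained fixtures
  for (fx in generate_landscapes(20, seed = 13, constrain_alpha_sum = TRUE)) {
    ls <- fx$landscape
    S <- fx$condition$S
    num <- optimize_numeric(S = S, dGT = ls$dGT, alpha1 = ls$alpha1,
                            alpha2 = ls$alpha2, k1_0 = ls$k1_0,
                            k2_0 = ls$k2_0)
    cl <- optimal_dG1_closed(S = S, dGT = ls$dGT, alpha1 = ls$alpha1,
                             alpha2 = ls$alpha2, k1_0 = ls$k1_0,
                             k2_0 = ls$k2_0)
    expect_lt(abs(num$dG1_star - cl$dG1_star), 1e-6)
  }
})

test_that("numeric optimizer matches a dense grid-scan oracle", {
  cases <- list(
    list(S = 10, dGT = -40, a1 = 0.2, a2 = 0.2, mech = "standard", g = 0),
    list(S = 1, dGT = -25, a1 = 0.7, a2 = 0.35, mech = "standard", g = 0),
    list(S = 10, dGT = -40, a1 = 0.5, a2 = 0.5, mech = "competitive", g = 10)
  )
  for (cs in cases) {
    opt <- optimize_numeric(S = cs$S, dGT = cs$dGT, alpha1 = cs$a1,
                            alpha2 = cs$a2, mechanism = cs$mech,
                            gamma = cs$g)
    # brute-force scan, 1e5 points over the same bracket
    dG1 <- seq(cs$dGT - 60, 60, length.out = 1e5)
    RT <- 8.314e-3 * 298.15
    v <- bepmm:::.rate_kernel(dG1, cs$dGT, cs$a1, cs$a2, 1, 1, RT,
                              S = cs$S, P = 0, ET = 0.01,
                              mechanism = cs$mech, gamma = cs$g)
    step <- dG1[2] - dG1[1]
    expect_lt(abs(opt$dG1_star - dG1[which.max(v)]), step)
    expect_gte(opt$v_star, max(v) * (1 - 1e-12))
  }
})

test_that("optimizer flags a boundary solution", {
  expect_warning(
    o <- optimize_numeric(S = 10, dGT = -40, interval = c(10, 20)),
    "boundary")
  expect_true(o$boundary)
})

test_that("activity grid ridge is the Km = [S] contour for alpha = 0.5", {
  for (S in c(0.1, 10)) {
    g <- activity_grid(assay_condition(S = S), n_dG1 = 150, n_dGT = 40)
    cell <- diff(g$dG1[1:2])
    RT <- 8.314e-3 * 298.15
    # one dG1 cell corresponds to cell/(RT ln 10) in log10 Km
    expect_true(all(abs(log10(g$ridge$Km / S)) <= cell / (RT * log(10))))
    # grid values equal pointwise activity calls
    i <- c(1, 75, 150); j <- c(1, 20, 40)
    for (a in i) for (b in j) {
      ls <- thermo_landscape(g$dG1[a], g$dGT[b])
      expect_equal(g$v[a, b], activity(ls, assay_condition(S = S)),
                   tolerance = 1e-12)
    }
    # ridge matches the numeric optimizer column-wise (spot check)
    for (b in c(1, 20, 40)) {
      o <- optimize_numeric(S = S, dGT = g$dGT[b])
      expect_lt(abs(g$ridge$dG1[b] - o$dG1_star), cell)
    }
  }
  expect_error(activity_grid(assay_condition(S = 1), n_dG1 = 1), "at least 2")
  expect_error(activity_grid(assay_condition(S = 1), dG1_range = c(5, -5)))
})

test_that("refining the grid moves the ridge by less than one coarse cell", {
  S <- 1
  g1 <- activity_grid(assay_condition(S = S), n_dG1 = 100, n_dGT = 20)
  g2 <- activity_grid(assay_condition(S = S), n_dG1 = 200, n_dGT = 20)
  coarse_cell <- diff(g1$dG1[1:2])
  expect_true(all(abs(g1$ridge$dG1 - g2$ridge$dG1) < coarse_cell))
})

test_that("volcano curves are single-peaked with apex at Km = [S]", {
  for (S in c(0.1, 100)) {
    vc <- volcano_curve(S = S, dGT = -40)
    expect_true(attr(vc, "single_peaked"))
    expect_true(attr(vc, "apex_interior"))
    expect_equal(log10(attr(vc, "apex_Km") / S), 0, tolerance = 0.02)
    # half-saturation at the apex
    ls_apex <- thermo_landscape(attr(vc, "apex_dG1"), -40)
    expect_equal(attr(vc, "apex_v"),
                 rate_constants(ls_apex)$k2 * 0.01 / 2, tolerance = 1e-3)
  }
  # apex location invariant to dGT, k1_0, k2_0
  apex <- vapply(c(-20, -40, -60), function(gt)
    attr(volcano_curve(S = 1, dGT = gt), "apex_Km"), numeric(1))
  expect_true(all(abs(apex / apex[1] - 1) < 0.01))
  apex_k <- vapply(c(0.1, 1, 10), function(k0)
    attr(volcano_curve(S = 1, dGT = -40, k1_0 = k0, k2_0 = 1 / k0), "apex_Km"),
    numeric(1))
  expect_true(all(abs(apex_k / apex_k[1] - 1) < 0.01))
  expect_warning(volcano_curve(S = 1, dGT = -40,
                               dG1 = seq(20, 40, length.out = 50)),
                 "apex")
})

test_that("log k2 - log Km scaling has slope alpha2 and the predicted intercept", {
  for (a2 in c(0.5, 0.74)) {
    sr <- scaling_relation(dGT = -40, alpha1 = 1 - a2, alpha2 = a2)
    expect_equal(sr$slope, a2, tolerance = 1e-9)
    expect_gt(sr$r_squared, 0.999999)
    RT <- 8.314e-3 * 298.15
    K <- 1 / exp(a2 * -40 / RT)
    expect_equal(sr$intercept,
                 -a2 * log10((1 + K) * exp(-40 / RT)) + log10(1),
                 tolerance = 1e-9)
  }
  expect_error(scaling_relation(dG1 = 1), "at least 2")
  expect_warning(scaling_relation(alpha1 = 0.3, alpha2 = 0.3), "alpha")
})

test_that("km_to_dG1 inverts the Michaelis constant for any coefficients", {
  for (fx in generate_landscapes(50, seed = 17)) {
    ls <- fx$landscape
    km <- michaelis_constant(ls)
    dg <- km_to_dG1(km, ls$dGT, ls$alpha1, ls$alpha2, ls$k1_0, ls$k2_0)
    expect_equal(dg, ls$dG1, tolerance = 1e-8)
  }
})

test_that("inhibition optima bracket [S] about an order of magnitude apart", {
  S <- 10
  oc <- true_optimal_km("competitive", S = S, dGT = -40, gamma = 10)
  ou <- true_optimal_km("uncompetitive", S = S, dGT = -40, gamma = 10)
  expect_lt(oc$Km_star, S)   # competitive optimum below [S]
  expect_gt(ou$Km_star, S)   # uncompetitive optimum above [S]
  # candidate closed forms Km* = S/(1+gamma) and S(1+gamma), validated here
  expect_equal(oc$Km_star, S / 11, tolerance = 1e-6)
  expect_equal(ou$Km_star, S * 11, tolerance = 1e-6)
  # reversible, strongly downhill: optimum stays at Km ~ S
  orv <- true_optimal_km("reversible", S = S, dGT = -60, P = 10)
  expect_equal(log10(orv$Km_star / S), 0, tolerance = 0.05)
  # standard mechanism recovers Km* = S
  ost <- true_optimal_km("standard", S = S, dGT = -40)
  expect_equal(ost$Km_star, S, tolerance = 1e-6)
})

test_that("the Km = [S] rule never costs more than 10x across mechanisms", {
  dGT <- seq(-80, 0, by = 10)
  for (mech in c("competitive", "uncompetitive")) {
    p <- km_rule_penalty(S = 10, dGT = dGT, mechanism = mech, gamma = 10)
    expect_lt(p$max_shortfall_pct, 90)  # v_rule > v*/10 everywhere
    expect_true(all(p$table$shortfall_pct >= -1e-9))
  }
  # alpha = 0.2: rule still within 10x of the optimum
  o <- optimize_numeric(S = 10, dGT = -40, alpha1 = 0.2, alpha2 = 0.2)
  dG1_rule <- km_to_dG1(10, -40, 0.2, 0.2)
  v_rule <- activity(thermo_landscape(dG1_rule, -40, 0.2, 0.2),
                     assay_condition(S = 10))
  expect_lt(o$v_star / v_rule, 10)
})
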