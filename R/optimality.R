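## ---- optimum container ------------------------------------------------

.km_optimum <- function(dG1_star, Km_star, v_star, method, f_value,
                        boundary = FALSE, mechanism = "standard", S = NA_real_) {
  structure(
    list(dG1_star = dG1_star, Km_star = Km_star, v_star = v_star,
         method = method, denominator_f_value = f_value,
         boundary = boundary, mechanism = mechanism, S = S),
    class = "km_optimum"
  )
}

#' @export
print.km_optimum <- function(x, ...) {
  cat(sprintf("Optimal free-energy allocation (%s, %s mechanism)\n",
              x$method, x$mechanism))
  cat(sprintf("  dG1* = %.8g kJ/mol\n", x$dG1_star))
  cat(sprintf("  Km*  = %.8g uM  (substrate [S] = %g uM)\n", x$Km_star, x$S))
  cat(sprintf("  v*   = %.8g uM/s\n", x$v_star))
  if (isTRUE(x$boundary))
    cat("  NOTE: optimum lies on the search boundary\n")
  invisible(x)
}

## value of the rate-law denominator f(g1) = S g1^-a2 + g1^(1-a2)
## + k2_0 g1^a1 / (k1_0 gT^a2); minimized at the optimum (standard mechanism)
.denominator_f <- function(dG1, dGT, alpha1, alpha2, k1_0, k2_0, RT, S) {
  lg1 <- dG1 / RT
  lgT <- dGT / RT
  S * exp(-alpha2 * lg1) + exp((1 - alpha2) * lg1) +
    exp(log(k2_0) - log(k1_0) + alpha1 * lg1 - alpha2 * lgT)
}

## ---- closed form -------------------------------------------------------

#' Closed-form optimal binding free energy
#'
#' When the BEP coefficients satisfy \eqn{\alpha_1 + \alpha_2 = 1}, the
#' composite constant \eqn{K} is independent of \eqn{g_1} and the stationarity
#' condition of the rate-law denominator is explicit:
#' \eqn{[S] = g_1 ((1-\alpha_2)/\alpha_2 + (\alpha_1/\alpha_2) K)}. The
#' optimal Michaelis constant is then \eqn{K_m^* = (\alpha_2/(1-\alpha_2))
#' [S]}, which reduces to \eqn{K_m^* = [S]} for
#' \eqn{\alpha_1 = \alpha_2 = 0.5}.
#'
#' @param S Substrate concentration, uM.
#' @param dGT Total reaction free energy, kJ/mol.
#' @param alpha1,alpha2 BEP coefficients; must satisfy
#'   `alpha1 + alpha2 == 1` (otherwise use [optimize_numeric()]).
#' @param k1_0,k2_0 Reference rate constants, 1/(uM s) and 1/s.
#' @param temperature Kelvin.
#' @param ET Total enzyme concentration, uM.
#' @return A `"km_optimum"` object (`method = "closed_form"`).
#' @examples
#' optimal_dG1_closed(S = 0.1, dGT = -40)  # Km* = 0.1 uM
#' @export
optimal_dG1_closed <- function(S, dGT, alpha1 = 0.5, alpha2 = 0.5,
                               k1_0 = 1, k2_0 = 1, temperature = 298.15,
                               ET = 0.01) {
  stopifnot(S > 0)
  if (abs(alpha1 + alpha2 - 1) > 1e-9)
    stop("the closed form requires alpha1 + alpha2 = 1; ",
         "use optimize_numeric() for general BEP coefficients")
  RT <- .RGAS * temperature
  K <- k2_0 / (k1_0 * exp(alpha2 * dGT / RT))
  g1_star <- S * alpha2 / ((1 - alpha2) * (1 + K))
  dG1_star <- RT * log(g1_star)
  ls <- thermo_landscape(dG1_star, dGT, alpha1, alpha2, k1_0, k2_0, temperature)
  v_star <- activity(ls, assay_condition(S = S, ET = ET))
  f_val <- .denominator_f(dG1_star, dGT, alpha1, alpha2, k1_0, k2_0, RT, S)
  .km_optimum(dG1_star, michaelis_constant(ls), v_star,
              method = "closed_form", f_value = f_val, S = S)
}

## ---- numeric optimizer -------------------------------------------------

#' Numerical maximization of activity over the binding free energy
#'
#' One-dimensional, derivative-free (Brent) maximization of the steady-state
#' rate over \eqn{\Delta G_1} at fixed \eqn{\Delta G_T}, for any BEP
#' coefficients and any supported mechanism. The Brent result is polished by
#' one local parabolic step, and certified as a local maximum by comparing
#' against the rate at small displacements. The default search bracket is
#' `[dGT - 60, 60]` kJ/mol.
#'
#' @inheritParams optimal_dG1_closed
#' @param mechanism Rate law to maximize: `"standard"`, `"reversible"`,
#'   `"competitive"`, `"uncompetitive"`.
#' @param gamma Degree of inhibition, for the inhibited mechanisms.
#' @param P Product concentration (uM), for the reversible mechanism.
#' @param interval Search bracket on dG1 (kJ/mol); default `c(dGT - 60, 60)`.
#' @param tol Absolute tolerance on dG1, kJ/mol.
#' @return A `"km_optimum"` object (`method = "numeric"`); `boundary = TRUE`
#'   flags an optimum within tolerance of the bracket ends.
#' @examples
#' optimize_numeric(S = 10, dGT = -40)  # Km* = 10 uM
#' @export
optimize_numeric <- function(S, dGT, alpha1 = 0.5, alpha2 = 0.5,
                             k1_0 = 1, k2_0 = 1, temperature = 298.15,
                             ET = 0.01, mechanism = "standard", gamma = 0,
                             P = 0, interval = NULL, tol = 1e-9) {
  stopifnot(S >= 0, alpha1 > 0, alpha1 < 1, alpha2 > 0, alpha2 < 1)
  RT <- .RGAS * temperature
  if (is.null(interval)) interval <- c(dGT - 60, 60)
  stopifnot(length(interval) == 2L, interval[1] < interval[2])
  obj <- function(dG1)
    .rate_kernel(dG1, dGT, alpha1, alpha2, k1_0, k2_0, RT,
                 S = S, P = P, ET = ET, mechanism = mechanism, gamma = gamma)
  opt <- stats::optimize(obj, interval = interval, maximum = TRUE, tol = tol)
  x <- opt$maximum
  ## parabolic polish: vertex of the quadratic through (x-h, x, x+h)
  h <- 1e-4
  if (x - h > interval[1] && x + h < interval[2]) {
    fl <- obj(x - h); fc <- obj(x); fr <- obj(x + h)
    denom <- fl - 2 * fc + fr
    if (is.finite(denom) && denom < 0) {
      x_new <- x + h / 2 * (fl - fr) / denom
      if (abs(x_new - x) < h && obj(x_new) >= fc) x <- x_new
    }
  }
  v_star <- obj(x)
  boundary <- (x - interval[1] < 1e-6) || (interval[2] - x < 1e-6)
  if (boundary)
    warning("optimum lies on the search boundary; no interior maximum found")
  ## local-maximum certificate
  delta <- 1e-5
  if (!boundary &&
      (obj(x - delta) > v_star * (1 + 1e-9) ||
       obj(x + delta) > v_star * (1 + 1e-9)))
    warning("optimum failed the local-maximum certificate")
  ls <- thermo_landscape(x, dGT, alpha1, alpha2, k1_0, k2_0, temperature)
  f_val <- .denominator_f(x, dGT, alpha1, alpha2, k1_0, k2_0, RT, S)
  .km_optimum(x, michaelis_constant(ls), v_star, method = "numeric",
              f_value = f_val, boundary = boundary, mechanism = mechanism,
              S = S)
}

#' True optimal Km for a mechanism
#'
#' Convenience wrapper around [optimize_numeric()] using the given
#' mechanism's rate law, returning the Michaelis constant at the maximizing
#' free-energy allocation (the "solid line" of the robustness analysis).
#'
#' @inheritParams optimize_numeric
#' @return A `"km_optimum"` object.
#' @examples
#' true_optimal_km("competitive", S = 10, dGT = -40, gamma = 10)
#' @export
true_optimal_km <- function(mechanism = c("standard", "reversible",
                                          "competitive", "uncompetitive"),
                            S, dGT, gamma = 10, P = 0,
                            alpha1 = 0.5, alpha2 = 0.5, k1_0 = 1, k2_0 = 1,
                            temperature = 298.15, ET = 0.01, ...) {
  mechanism <- match.arg(mechanism)
  optimize_numeric(S = S, dGT = dGT, alpha1 = alpha1, alpha2 = alpha2,
                   k1_0 = k1_0, k2_0 = k2_0, temperature = temperature,
                   ET = ET, mechanism = mechanism, gamma = gamma, P = P, ...)
}

## ---- Km -> dG1 inversion ----------------------------------------------

#' Binding free energy realizing a target Michaelis constant
#'
#' Inverts \eqn{K_m = g_1 (1 + K(g_1))} for \eqn{\Delta G_1}. The map is
#' strictly increasing in \eqn{g_1} for any BEP coefficients, so the root is
#' unique; when \eqn{\alpha_1 + \alpha_2 = 1} the inversion is closed-form.
#'
#' @param Km Target Michaelis constant, uM.
#' @inheritParams optimal_dG1_closed
#' @return dG1 in kJ/mol.
#' @export
km_to_dG1 <- function(Km, dGT, alpha1 = 0.5, alpha2 = 0.5,
                      k1_0 = 1, k2_0 = 1, temperature = 298.15) {
  stopifnot(Km > 0)
  RT <- .RGAS * temperature
  log_c <- log(k2_0) - log(k1_0) - alpha2 * dGT / RT
  pow <- alpha1 + alpha2 - 1
  if (abs(pow) < 1e-12)
    return(RT * (log(Km) - .log1pexp(log_c)))
  fn <- function(lg) lg + .log1pexp(log_c + pow * lg) - log(Km)
  hi <- log(Km)
  lo <- hi - 10
  while (fn(lo) > 0) {
    lo <- lo - 20
    if (lo < -1e4) stop("failed to bracket the Km inversion")
  }
  root <- stats::uniroot(fn, c(lo, hi), tol = 1e-13)$root
  RT * root
}

## ---- activity grid -----------------------------------------------------

#' Activity landscape over (dG1, dGT) with its ridge
#'
#' Evaluates the rate on a uniform grid over the binding free energy
#' \eqn{\Delta G_1} (rows) and the total free energy \eqn{\Delta G_T}
#' (columns), and extracts the ridge: the maximizing \eqn{\Delta G_1} in each
#' \eqn{\Delta G_T} column (ties broken toward more negative \eqn{\Delta
#' G_1}). For the standard mechanism with symmetric BEP coefficients the
#' ridge coincides with the contour \eqn{K_m = [S]}. Cells with non-positive
#' net rate (possible for the reversible mechanism at \eqn{\Delta G_T > 0})
#' are flagged in `feasible` rather than masked.
#'
#' @param cond An [assay_condition()].
#' @param dG1_range,dGT_range Axis ranges, kJ/mol.
#' @param n_dG1,n_dGT Grid sizes (at least 2).
#' @param alpha1,alpha2,k1_0,k2_0,temperature Landscape constants shared by
#'   all grid points.
#' @return Object of class `"activity_grid"`: `dG1`, `dGT` axis vectors, rate
#'   matrix `v` (`n_dG1` x `n_dGT`, uM/s), logical matrix `feasible`, and
#'   `ridge` data frame with columns `dGT`, `dG1`, `Km`.
#' @examples
#' g <- activity_grid(assay_condition(S = 1), n_dG1 = 60, n_dGT = 50)
#' head(g$ridge)
#' @export
activity_grid <- function(cond, dG1_range = c(-60, 20), dGT_range = c(-80, 0),
                          n_dG1 = 400, n_dGT = 400,
                          alpha1 = 0.5, alpha2 = 0.5, k1_0 = 1, k2_0 = 1,
                          temperature = 298.15) {
  stopifnot(inherits(cond, "assay_condition"),
            length(dG1_range) == 2L, dG1_range[1] < dG1_range[2],
            length(dGT_range) == 2L, dGT_range[1] < dGT_range[2])
  if (n_dG1 < 2 || n_dGT < 2) stop("grid sizes must be at least 2")
  RT <- .RGAS * temperature
  dG1 <- seq(dG1_range[1], dG1_range[2], length.out = n_dG1)
  dGT <- seq(dGT_range[1], dGT_range[2], length.out = n_dGT)
  v <- matrix(NA_real_, n_dG1, n_dGT)
  for (j in seq_len(n_dGT)) {
    v[, j] <- .rate_kernel(dG1, dGT[j], alpha1, alpha2, k1_0, k2_0, RT,
                           S = cond$S, P = cond$P, ET = cond$ET,
                           mechanism = cond$mechanism, gamma = cond$gamma)
  }
  idx <- apply(v, 2, which.max)  # first index = most negative dG1 on ties
  ridge_km <- vapply(seq_len(n_dGT), function(j) {
    michaelis_constant(thermo_landscape(dG1[idx[j]], dGT[j], alpha1, alpha2,
                                        k1_0, k2_0, temperature))
  }, numeric(1))
  structure(
    list(dG1 = dG1, dGT = dGT, v = v, feasible = v > 0,
         ridge = data.frame(dGT = dGT, dG1 = dG1[idx], Km = ridge_km),
         cond = cond,
         params = list(alpha1 = alpha1, alpha2 = alpha2, k1_0 = k1_0,
                       k2_0 = k2_0, temperature = temperature)),
    class = "activity_grid"
  )
}

#' @export
print.activity_grid <- function(x, ...) {
  cat(sprintf("Activity grid (%s mechanism): %d x %d over dG1 [%g, %g], dGT [%g, %g] kJ/mol\n",
              x$cond$mechanism, length(x$dG1), length(x$dGT),
              min(x$dG1), max(x$dG1), min(x$dGT), max(x$dGT)))
  cat(sprintf("  [S] = %g uM; ridge Km range: [%.4g, %.4g] uM\n",
              x$cond$S, min(x$ridge$Km), max(x$ridge$Km)))
  invisible(x)
}

#' @describeIn activity_grid image of log10 activity with the ridge (solid)
#'   and, for reference, the `Km = S` locus (dashed).
#' @param x,... plot arguments.
#' @export
plot.activity_grid <- function(x, ...) {
  z <- log10(pmax(x$v, .Machine$double.xmin))
  graphics::image(x$dG1, x$dGT, z, col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  xlab = expression(Delta * G[1] ~ "(kJ/mol)"),
                  ylab = expression(Delta * G[T] ~ "(kJ/mol)"), ...)
  graphics::lines(x$ridge$dG1, x$ridge$dGT, lwd = 2)
  rule <- vapply(x$dGT, function(gt)
    km_to_dG1(x$cond$S, gt, x$params$alpha1, x$params$alpha2,
              x$params$k1_0, x$params$k2_0, x$params$temperature), numeric(1))
  graphics::lines(rule, x$dGT, lty = 2, lwd = 2)
  invisible(x)
}

## ---- volcano curve -----------------------------------------------------

#' Activity-versus-Km volcano curve
#'
#' Sweeps the binding free energy at fixed \eqn{\Delta G_T} and reports the
#' rate as a function of the resulting Michaelis constant. The curve is
#' single-peaked with its apex at \eqn{K_m = [S]} for symmetric BEP
#' coefficients; the apex location is invariant to \eqn{\Delta G_T} and the
#' reference rate constants.
#'
#' @inheritParams optimal_dG1_closed
#' @param dG1 Sweep over the binding free energy, kJ/mol; default 2001 points
#'   over `[dGT - 60, 60]`.
#' @return Object of class `"volcano_curve"`: a data frame with columns
#'   `dG1`, `Km`, `v` and attributes `apex_Km`, `apex_v`, `single_peaked`,
#'   `apex_interior`.
#' @examples
#' vc <- volcano_curve(S = 0.1, dGT = -40)
#' attr(vc, "apex_Km")
#' @export
volcano_curve <- function(S, dGT = -40, dG1 = NULL,
                          alpha1 = 0.5, alpha2 = 0.5, k1_0 = 1, k2_0 = 1,
                          temperature = 298.15, ET = 0.01) {
  stopifnot(S > 0)
  RT <- .RGAS * temperature
  if (is.null(dG1)) dG1 <- seq(dGT - 60, 60, length.out = 2001L)
  km <- vapply(dG1, function(g)
    michaelis_constant(thermo_landscape(g, dGT, alpha1, alpha2, k1_0, k2_0,
                                        temperature)), numeric(1))
  v <- .rate_kernel(dG1, dGT, alpha1, alpha2, k1_0, k2_0, RT,
                    S = S, P = 0, ET = ET, mechanism = "standard", gamma = 0)
  i <- which.max(v)
  s <- sign(diff(v))
  s <- s[s != 0]
  runs <- rle(s)$values
  single <- identical(runs, c(1, -1)) || identical(runs, 1) ||
    identical(runs, -1)
  interior <- i > 1L && i < length(v)
  if (!interior)
    warning("the dG1 sweep does not bracket the volcano apex")
  apex_dG1 <- dG1[i]
  apex_v <- v[i]
  apex_km <- km[i]
  if (interior) {
    # parabolic refinement past the sweep resolution
    denom <- v[i - 1] - 2 * v[i] + v[i + 1]
    if (is.finite(denom) && denom < 0) {
      h <- dG1[i] - dG1[i - 1]
      apex_dG1 <- dG1[i] + h / 2 * (v[i - 1] - v[i + 1]) / denom
      apex_v <- .rate_kernel(apex_dG1, dGT, alpha1, alpha2, k1_0, k2_0, RT,
                             S = S, P = 0, ET = ET, mechanism = "standard",
                             gamma = 0)
      apex_km <- michaelis_constant(thermo_landscape(apex_dG1, dGT, alpha1,
                                                     alpha2, k1_0, k2_0,
                                                     temperature))
    }
  }
  structure(
    data.frame(dG1 = dG1, Km = km, v = v),
    apex_Km = apex_km, apex_v = apex_v, apex_dG1 = apex_dG1,
    single_peaked = single, apex_interior = interior, S = S,
    class = c("volcano_curve", "data.frame")
  )
}

#' @describeIn volcano_curve rate against Km on a log axis, apex marked.
#' @param x,... plot arguments.
#' @export
plot.volcano_curve <- function(x, ...) {
  graphics::plot(x$Km, x$v, type = "l", log = "xy",
                 xlab = expression(K[m] ~ "(uM)"),
                 ylab = "v (uM/s)", ...)
  graphics::abline(v = attr(x, "S"), lty = 2)
  invisible(x)
}

## ---- scaling relation --------------------------------------------------

#' Scaling between the turnover constant and the Michaelis constant
#'
#' Along a sweep of the binding free energy at fixed \eqn{\Delta G_T}, the
#' BEP coupling forces \eqn{\log k_2 = \alpha_2 \log K_m - \alpha_2 \log((1 +
#' K) g_T) + \log k_2^0}: turnover and affinity cannot be improved
#' independently. The slope is exactly \eqn{\alpha_2} whenever \eqn{\alpha_1 +
#' \alpha_2 = 1} (constant \eqn{K}); otherwise the intercept drifts with
#' \eqn{K} and the fitted slope is only approximate, so per-point values of
#' \eqn{K} are included.
#'
#' @inheritParams volcano_curve
#' @param dG1 Sweep over the binding free energy, kJ/mol (length >= 2).
#' @return Object of class `"scaling_relation"`: list with the sweep data
#'   (`log10_Km`, `log10_k2`, `K`), least-squares `slope`, `intercept`,
#'   `r_squared`, and the landscape constants.
#' @examples
#' scaling_relation(dGT = -40, alpha2 = 0.74, alpha1 = 0.26)$slope
#' @export
scaling_relation <- function(dGT = -40, dG1 = seq(-40, 20, length.out = 121L),
                             alpha1 = 0.5, alpha2 = 0.5, k1_0 = 1, k2_0 = 1,
                             temperature = 298.15) {
  if (length(dG1) < 2L) stop("the dG1 sweep must contain at least 2 points")
  RT <- .RGAS * temperature
  lg1 <- dG1 / RT
  lgT <- dGT / RT
  log_K <- log(k2_0) - log(k1_0) + (alpha1 + alpha2 - 1) * lg1 - alpha2 * lgT
  log10_km <- (lg1 + .log1pexp(log_K)) / log(10)
  log10_k2 <- (log(k2_0) + alpha2 * (lg1 - lgT)) / log(10)
  fit <- stats::lm(log10_k2 ~ log10_km)
  if (abs(alpha1 + alpha2 - 1) > 1e-9)
    warning("alpha1 + alpha2 != 1: K varies along the sweep and the fitted ",
            "slope is only approximately alpha2")
  structure(
    list(data = data.frame(dG1 = dG1, log10_Km = log10_km,
                           log10_k2 = log10_k2, K = exp(log_K)),
         slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r_squared = suppressWarnings(summary(fit)$r.squared),
         alpha2 = alpha2,
         constants = list(dGT = dGT, alpha1 = alpha1, alpha2 = alpha2,
                          k1_0 = k1_0, k2_0 = k2_0,
                          temperature = temperature)),
    class = "scaling_relation"
  )
}

#' @export
print.scaling_relation <- function(x, ...) {
  cat("log10(k2) vs log10(Km) scaling along a dG1 sweep\n")
  cat(sprintf("  slope = %.9g (alpha2 = %g), intercept = %.6g, R^2 = %.9g\n",
              x$slope, x$alpha2, x$intercept, x$r_squared))
  invisible(x)
}

## ---- penalty of the Km = [S] rule --------------------------------------

#' Activity penalty of tuning Km to the substrate concentration
#'
#' For each value of the total driving force, compares the rate obtained by
#' setting \eqn{K_m = [S]} with the rate at the numerically optimal
#' \eqn{K_m} of the given mechanism. Two summaries are reported per
#' \eqn{\Delta G_T}: the one-sided shortfall
#' \eqn{(v^* - v_{rule})/v^* \times 100} and the relative difference between
#' the two activities, \eqn{2 |v^* - v_{rule}|/(v^* + v_{rule}) \times 100}
#' (symmetric, so it does not depend on which rate is the reference).
#'
#' @inheritParams optimize_numeric
#' @param dGT Vector of total free energies to scan, kJ/mol.
#' @return Object of class `"km_rule_penalty"`: per-dGT data frame (`dGT`,
#'   `Km_star`, `v_star`, `v_rule`, `shortfall_pct`, `rel_diff_pct`) plus the
#'   maxima `max_shortfall_pct` and `max_rel_diff_pct`.
#' @examples
#' p <- km_rule_penalty(S = 10, mechanism = "competitive", gamma = 10,
#'                      dGT = seq(-80, 0, by = 10))
#' p$max_rel_diff_pct
#' @export
km_rule_penalty <- function(S = 10, dGT = seq(-80, 0, by = 0.5),
                            mechanism = "competitive", gamma = 10, P = 0,
                            alpha1 = 0.5, alpha2 = 0.5, k1_0 = 1, k2_0 = 1,
                            temperature = 298.15, ET = 0.01) {
  RT <- .RGAS * temperature
  rows <- lapply(dGT, function(gt) {
    opt <- optimize_numeric(S = S, dGT = gt, alpha1 = alpha1, alpha2 = alpha2,
                            k1_0 = k1_0, k2_0 = k2_0,
                            temperature = temperature, ET = ET,
                            mechanism = mechanism, gamma = gamma, P = P)
    dG1_rule <- km_to_dG1(S, gt, alpha1, alpha2, k1_0, k2_0, temperature)
    v_rule <- .rate_kernel(dG1_rule, gt, alpha1, alpha2, k1_0, k2_0, RT,
                           S = S, P = P, ET = ET, mechanism = mechanism,
                           gamma = gamma)
    data.frame(dGT = gt, Km_star = opt$Km_star, v_star = opt$v_star,
               v_rule = v_rule,
               shortfall_pct = 100 * (opt$v_star - v_rule) / opt$v_star,
               rel_diff_pct = 200 * abs(opt$v_star - v_rule) /
                 (opt$v_star + v_rule))
  })
  tab <- do.call(rbind, rows)
  structure(
    list(table = tab,
         max_shortfall_pct = max(tab$shortfall_pct),
         max_rel_diff_pct = max(tab$rel_diff_pct),
         S = S, mechanism = mechanism, gamma = gamma, P = P),
    class = "km_rule_penalty"
  )
}

#' @export
print.km_rule_penalty <- function(x, ...) {
  cat(sprintf("Penalty of the Km = [S] rule (%s mechanism, gamma = %g, [S] = %g uM)\n",
              x$mechanism, x$gamma, x$S))
  cat(sprintf("  max shortfall vs optimum: %.4g %%\n", x$max_shortfall_pct))
  cat(sprintf("  max relative difference : %.4g %%\n", x$max_rel_diff_pct))
  invisible(x)
}
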