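#' Free-energy landscape of a two-step enzymatic reaction
#'
#' Constructs the thermodynamic description of one enzyme: the binding free
#' energy of the first step (E + S -> ES), the total free energy of the
#' reaction (S -> P), the BEP coefficients of both steps, and the reference
#' rate constants at zero driving force. The free energy of the second step is
#' always derived as `dG2 = dGT - dG1`, so the additivity constraint
#' \eqn{\Delta G_1 + \Delta G_2 = \Delta G_T} holds by construction. The
#' reverse BEP coefficient of step 1 is never stored; it is `1 - alpha1`.
#'
#' @param dG1 Free energy of E + S -> ES, kJ/mol.
#' @param dGT Total free energy of S -> P, kJ/mol.
#' @param alpha1,alpha2 BEP coefficients of steps 1 and 2, each in (0, 1).
#' @param k1_0 Reference rate constant of step 1 at zero driving force,
#'   1/(uM s).
#' @param k2_0 Reference rate constant of step 2 at zero driving force, 1/s.
#' @param temperature Absolute temperature, K. Default 298.15 K (25 C), the
#'   conventional biochemical reference.
#'
#' @return An object of class `"thermo_landscape"`: a list with the supplied
#'   fields plus derived `dG2` (kJ/mol) and `RT` (kJ/mol).
#' @examples
#' ls <- thermo_landscape(dG1 = -25, dGT = -40)
#' ls
#' coef(ls)
#' @seealso [rate_constants()], [michaelis_constant()], [activity()]
#' @export
thermo_landscape <- function(dG1, dGT, alpha1 = 0.5, alpha2 = 0.5,
                             k1_0 = 1, k2_0 = 1, temperature = 298.15) {
  stopifnot(
    is.numeric(dG1), length(dG1) == 1L, is.finite(dG1),
    is.numeric(dGT), length(dGT) == 1L, is.finite(dGT),
    is.numeric(alpha1), length(alpha1) == 1L,
    is.numeric(alpha2), length(alpha2) == 1L,
    is.numeric(k1_0), length(k1_0) == 1L,
    is.numeric(k2_0), length(k2_0) == 1L,
    is.numeric(temperature), length(temperature) == 1L
  )
  if (alpha1 <= 0 || alpha1 >= 1 || alpha2 <= 0 || alpha2 >= 1)
    stop("BEP coefficients 'alpha1' and 'alpha2' must lie strictly in (0, 1)")
  if (k1_0 <= 0 || k2_0 <= 0)
    stop("reference rate constants 'k1_0' and 'k2_0' must be positive")
  if (temperature <= 0) stop("'temperature' must be positive (K)")
  RT <- .RGAS * temperature
  dG2 <- dGT - dG1
  if (max(abs(c(dG1, dG2, dGT))) / RT > .MAX_REDUCED_DG)
    stop("free energies exceed the numerically safe range (|dG|/RT > ",
         .MAX_REDUCED_DG, "); rate constants would overflow")
  structure(
    list(dG1 = dG1, dGT = dGT, dG2 = dG2,
         alpha1 = alpha1, alpha2 = alpha2,
         k1_0 = k1_0, k2_0 = k2_0,
         temperature = temperature, RT = RT),
    class = "thermo_landscape"
  )
}

## dimensionless equilibrium factors and the composite constant
## K = k2_0 g1^(alpha1+alpha2-1) / (k1_0 gT^alpha2), all kept in log space
.landscape_logs <- function(ls) {
  log_g1 <- ls$dG1 / ls$RT
  log_gT <- ls$dGT / ls$RT
  log_K <- log(ls$k2_0) - log(ls$k1_0) +
    (ls$alpha1 + ls$alpha2 - 1) * log_g1 - ls$alpha2 * log_gT
  list(log_g1 = log_g1, log_g2 = log_gT - log_g1, log_gT = log_gT,
       log_K = log_K)
}

#' Elementary rate constants from a free-energy landscape
#'
#' Applies the BEP relation to both steps of the mechanism: each forward
#' barrier grows linearly with its driving force with slope `alpha`, the
#' reverse barrier with slope `1 - alpha`. With \eqn{g_i = \exp(\Delta
#' G_i/RT)} this gives \eqn{k_1 = k_1^0 g_1^{-\alpha_1}},
#' \eqn{k_{1r} = k_1^0 g_1^{1-\alpha_1}}, \eqn{k_2 = k_2^0 (g_1/g_T)^{\alpha_2}}
#' and \eqn{k_{2r} = k_2^0 (g_1/g_T)^{\alpha_2 - 1}}. The construction
#' guarantees microscopic reversibility per step
#' (\eqn{k_1/k_{1r} = e^{-\Delta G_1/RT}}) and the Haldane identity around the
#' cycle, \eqn{k_1 k_2/(k_{1r} k_{2r}) = e^{-\Delta G_T/RT}}.
#'
#' @param landscape A [thermo_landscape()].
#' @return An object of class `"rate_constants"`: list with `k1` (1/(uM s)),
#'   `k1r` (1/s), `k2` (1/s), `k2r` (1/(uM s)).
#' @examples
#' rc <- rate_constants(thermo_landscape(dG1 = -25, dGT = -40))
#' rc$k1 * rc$k2 / (rc$k1r * rc$k2r)  # exp(40/RT)
#' @export
rate_constants <- function(landscape) {
  stopifnot(inherits(landscape, "thermo_landscape"))
  lg <- .landscape_logs(landscape)
  lk1_0 <- log(landscape$k1_0)
  lk2_0 <- log(landscape$k2_0)
  a1 <- landscape$alpha1
  a2 <- landscape$alpha2
  k <- list(
    k1  = exp(lk1_0 - a1 * lg$log_g1),
    k1r = exp(lk1_0 + (1 - a1) * lg$log_g1),
    k2  = exp(lk2_0 + a2 * (lg$log_g1 - lg$log_gT)),
    k2r = exp(lk2_0 + (a2 - 1) * (lg$log_g1 - lg$log_gT))
  )
  if (!all(vapply(k, is.finite, logical(1))) || any(unlist(k) <= 0))
    stop("rate constants overflowed or underflowed; free energies are outside",
         " the representable range")
  structure(k, class = "rate_constants", landscape = landscape)
}

#' Michaelis constant of a landscape
#'
#' The Michaelis constant is the composite quasi-equilibrium constant
#' \eqn{K_m = (k_{1r} + k_2)/k_1}. In terms of the landscape it reduces to
#' \eqn{K_m = g_1 (1 + K)} with
#' \eqn{K = k_2^0 g_1^{\alpha_1+\alpha_2-1}/(k_1^0 g_T^{\alpha_2})};
#' the two routes agree to machine precision. Evaluated in log space.
#'
#' @inheritParams rate_constants
#' @return Km in uM (scalar).
#' @examples
#' michaelis_constant(thermo_landscape(dG1 = 0, dGT = 0))  # 2 uM
#' @export
michaelis_constant <- function(landscape) {
  stopifnot(inherits(landscape, "thermo_landscape"))
  lg <- .landscape_logs(landscape)
  km <- exp(lg$log_g1 + .log1pexp(lg$log_K))
  if (!is.finite(km))
    stop("Km overflowed; free energies are outside the representable range")
  km
}

#' @export
print.thermo_landscape <- function(x, ...) {
  cat("Two-step free-energy landscape (E + S <-> ES -> E + P)\n")
  cat(sprintf("  dG1 = %.6g kJ/mol, dG2 = %.6g kJ/mol, dGT = %.6g kJ/mol\n",
              x$dG1, x$dG2, x$dGT))
  cat(sprintf("  alpha1 = %.3g, alpha2 = %.3g (alpha1r = %.3g)\n",
              x$alpha1, x$alpha2, 1 - x$alpha1))
  cat(sprintf("  k1_0 = %.6g 1/(uM s), k2_0 = %.6g 1/s, T = %.6g K\n",
              x$k1_0, x$k2_0, x$temperature))
  cat(sprintf("  Km = %.6g uM\n", michaelis_constant(x)))
  invisible(x)
}

#' @export
print.rate_constants <- function(x, ...) {
  cat("BEP rate constants\n")
  cat(sprintf("  k1  = %.6g 1/(uM s)   k1r = %.6g 1/s\n", x$k1, x$k1r))
  cat(sprintf("  k2  = %.6g 1/s        k2r = %.6g 1/(uM s)\n", x$k2, x$k2r))
  invisible(x)
}

#' @describeIn thermo_landscape kinetic parameters implied by the landscape:
#'   the four elementary rate constants plus `Km` and `kcat` (`= k2`).
#' @param object,... method arguments.
#' @export
coef.thermo_landscape <- function(object, ...) {
  rc <- rate_constants(object)
  c(k1 = rc$k1, k1r = rc$k1r, k2 = rc$k2, k2r = rc$k2r,
    Km = michaelis_constant(object), kcat = rc$k2)
}

#' @describeIn thermo_landscape steady-state Michaelis-Menten rate at the
#'   substrate concentrations `S` (uM) and total enzyme `ET` (uM); returns a
#'   vector of rates in uM/s.
#' @param S substrate concentrations, uM.
#' @param ET total enzyme concentration, uM.
#' @export
predict.thermo_landscape <- function(object, S, ET = 0.01, ...) {
  stopifnot(is.numeric(S), all(S >= 0), ET >= 0)
  rc <- rate_constants(object)
  km <- michaelis_constant(object)
  rc$k2 * S * ET / (km + S)
}

#' Assay condition for a rate-law evaluation
#'
#' Bundles the concentrations and the mechanism under which a landscape's rate
#' is evaluated. The inhibitor is characterized only through the degree of
#' inhibition `gamma = [I]/Ki`; inhibitor concentration and Ki are never
#' stored separately.
#'
#' @param S Substrate concentration, uM.
#' @param P Product concentration, uM (used by the reversible mechanism).
#' @param ET Total enzyme concentration, uM. Default 0.01 uM.
#' @param mechanism One of `"standard"`, `"reversible"`, `"competitive"`,
#'   `"uncompetitive"`.
#' @param gamma Degree of inhibition `[I]/Ki`, dimensionless; meaningful only
#'   for the competitive and uncompetitive mechanisms.
#' @return Object of class `"assay_condition"`.
#' @examples
#' assay_condition(S = 10, mechanism = "competitive", gamma = 10)
#' @export
assay_condition <- function(S, P = 0, ET = 0.01,
                            mechanism = c("standard", "reversible",
                                          "competitive", "uncompetitive"),
                            gamma = 0) {
  mechanism <- match.arg(mechanism)
  stopifnot(is.numeric(S), length(S) == 1L, S >= 0,
            is.numeric(P), length(P) == 1L, P >= 0,
            is.numeric(ET), length(ET) == 1L, ET >= 0,
            is.numeric(gamma), length(gamma) == 1L, gamma >= 0)
  if (gamma > 0 && !mechanism %in% c("competitive", "uncompetitive"))
    warning("'gamma' is ignored for the ", mechanism, " mechanism")
  structure(list(S = S, P = P, ET = ET, mechanism = mechanism, gamma = gamma),
            class = "assay_condition")
}

#' @export
print.assay_condition <- function(x, ...) {
  cat(sprintf("Assay condition: [S] = %g uM, [P] = %g uM, [ET] = %g uM\n",
              x$S, x$P, x$ET))
  cat(sprintf("  mechanism = %s, gamma = %g\n", x$mechanism, x$gamma))
  invisible(x)
}

#' Read landscape or condition parameters from a configuration file
#'
#' JSON (`.json`) and YAML (`.yml`/`.yaml`) files are supported. Recognized
#' field names are exactly `dG1`, `dGT`, `alpha1`, `alpha2`, `k1_0`, `k2_0`,
#' `temperature` for the landscape and `S`, `P`, `ET`, `gamma`, `mechanism`
#' for the condition; both can live in the same file.
#'
#' @param path Path to the config file.
#' @return `landscape_from_config()` returns a [thermo_landscape()];
#'   `condition_from_config()` an [assay_condition()].
#' @export
landscape_from_config <- function(path) {
  cfg <- .read_config(path)
  need <- c("dG1", "dGT")
  if (!all(need %in% names(cfg)))
    stop("config file must define fields: ", paste(need, collapse = ", "))
  args <- cfg[intersect(names(cfg),
                        c("dG1", "dGT", "alpha1", "alpha2",
                          "k1_0", "k2_0", "temperature"))]
  do.call(thermo_landscape, args)
}

#' @rdname landscape_from_config
#' @export
condition_from_config <- function(path) {
  cfg <- .read_config(path)
  if (!"S" %in% names(cfg)) stop("config file must define field: S")
  args <- cfg[intersect(names(cfg), c("S", "P", "ET", "mechanism", "gamma"))]
  do.call(assay_condition, args)
}

.read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
    json = jsonlite::fromJSON(path),
    yml = ,
    yaml = yaml::read_yaml(path),
    stop("unsupported config format '", ext, "' (use .json, .yml or .yaml)")
  )
  if (!is.list(cfg)) stop("config file must contain a mapping of fields")
  cfg
}
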