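## Vectorized rate-law kernel used by the optimizer and the grid/volcano
## utilities. `dG1` may be a vector; all other parameters are scalars.
.rate_kernel <- function(dG1, dGT, alpha1, alpha2, k1_0, k2_0, RT,
                         S, P, ET, mechanism, gamma) {
  lg1 <- dG1 / RT
  lgT <- dGT / RT
  lK <- log(k2_0) - log(k1_0) + (alpha1 + alpha2 - 1) * lg1 - alpha2 * lgT
  k2 <- exp(log(k2_0) + alpha2 * (lg1 - lgT))
  km <- exp(lg1 + .log1pexp(lK))
  switch(mechanism,
    standard = k2 * S * ET / (km + S),
    competitive = k2 * S * ET / (km * (1 + gamma) + S),
    uncompetitive = k2 * S * ET / (km + (1 + gamma) * S),
    reversible = {
      k1 <- exp(log(k1_0) - alpha1 * lg1)
      k1r <- exp(log(k1_0) + (1 - alpha1) * lg1)
      k2r <- exp(log(k2_0) + (alpha2 - 1) * (lg1 - lgT))
      ET * (k1 * k2 * S - k1r * k2r * P) / (k1 * S + k2r * P + k1r + k2)
    },
    stop("unknown mechanism: ", mechanism)
  )
}

.kernel_args <- function(landscape, cond) {
  list(dGT = landscape$dGT, alpha1 = landscape$alpha1,
       alpha2 = landscape$alpha2, k1_0 = landscape$k1_0,
       k2_0 = landscape$k2_0, RT = landscape$RT,
       S = cond$S, P = cond$P, ET = cond$ET,
       mechanism = cond$mechanism, gamma = cond$gamma)
}

#' Steady-state Michaelis-Menten activity
#'
#' Evaluates \eqn{v = k_2 [S] [E_T] / (K_m + [S])} with \eqn{k_2} and
#' \eqn{K_m} derived from the landscape through the BEP relation. The
#' condition must carry the `"standard"` mechanism tag; other mechanisms are
#' dispatched by [reaction_rate()].
#'
#' @param landscape A [thermo_landscape()].
#' @param cond An [assay_condition()] with `mechanism = "standard"`.
#' @return Rate v in uM/s.
#' @examples
#' ls <- thermo_landscape(dG1 = -25, dGT = -40)
#' activity(ls, assay_condition(S = 10))
#' @export
activity <- function(landscape, cond) {
  stopifnot(inherits(landscape, "thermo_landscape"),
            inherits(cond, "assay_condition"))
  if (cond$mechanism != "standard")
    stop("activity() handles the standard mechanism only; got '",
         cond$mechanism, "'. Use reaction_rate().")
  do.call(.rate_kernel, c(list(dG1 = landscape$dG1), .kernel_args(landscape, cond)))
}

#' Net rate in the presence of the reverse reaction
#'
#' Steady-state net rate of the fully reversible two-step scheme
#' E + S <-> ES <-> E + P with BEP rate constants:
#' \deqn{v_{net} = [E_T]\frac{k_1 k_2 [S] - k_{1r} k_{2r} [P]}
#'   {k_1 [S] + k_{2r} [P] + k_{1r} + k_2}.}
#' The Haldane identity makes the rate vanish exactly at equilibrium,
#' \eqn{[P]/[S] = e^{-\Delta G_T/RT}}, and the law reduces to [activity()]
#' when \eqn{[P] = 0}.
#'
#' @param landscape A [thermo_landscape()].
#' @param cond An [assay_condition()] with `mechanism = "reversible"`.
#' @return Net rate in uM/s (negative when the reverse direction dominates).
#' @export
net_rate_reversible <- function(landscape, cond) {
  stopifnot(inherits(landscape, "thermo_landscape"),
            inherits(cond, "assay_condition"))
  if (cond$mechanism != "reversible")
    stop("net_rate_reversible() requires mechanism = 'reversible'")
  if (cond$S == 0 && cond$P == 0) return(0)
  do.call(.rate_kernel, c(list(dG1 = landscape$dG1), .kernel_args(landscape, cond)))
}

#' Rate under competitive or uncompetitive inhibition
#'
#' Textbook inhibited Michaelis-Menten forms parameterized by the degree of
#' inhibition \eqn{\gamma = [I]/K_i}: competitive inhibition rescales the
#' Michaelis constant, \eqn{v = k_2 [S] [E_T]/(K_m (1+\gamma) + [S])};
#' uncompetitive inhibition rescales the substrate term,
#' \eqn{v = k_2 [S] [E_T]/(K_m + (1+\gamma) [S])}. Both reduce to the
#' standard law at \eqn{\gamma = 0}.
#'
#' @param landscape A [thermo_landscape()].
#' @param cond An [assay_condition()] with mechanism `"competitive"` or
#'   `"uncompetitive"`.
#' @return Rate in uM/s.
#' @export
rate_inhibited <- function(landscape, cond) {
  stopifnot(inherits(landscape, "thermo_landscape"),
            inherits(cond, "assay_condition"))
  if (!cond$mechanism %in% c("competitive", "uncompetitive"))
    stop("rate_inhibited() requires mechanism 'competitive' or 'uncompetitive'")
  do.call(.rate_kernel, c(list(dG1 = landscape$dG1), .kernel_args(landscape, cond)))
}

#' Rate law dispatched on the condition's mechanism
#'
#' Single entry point used by the optimizer and grid utilities: calls
#' [activity()], [net_rate_reversible()] or [rate_inhibited()] according to
#' `cond$mechanism`.
#'
#' @inheritParams activity
#' @return Rate in uM/s.
#' @export
reaction_rate <- function(landscape, cond) {
  stopifnot(inherits(cond, "assay_condition"))
  switch(cond$mechanism,
    standard = activity(landscape, cond),
    reversible = net_rate_reversible(landscape, cond),
    competitive = ,
    uncompetitive = rate_inhibited(landscape, cond)
  )
}
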