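## ---- synthetic Km-[S] tables ---------------------------------------------

#' Default specification for the synthetic Km-[S] table
#'
#' One row per occurrence category. The entry counts and log-ratio centers
#' mirror the published wild-type dataset (980 major-metabolite entries
#' centered at -0.18 with SD 1.3; 410 cofactor entries at -0.43; 313 ATP
#' entries at -1.64). The cofactor and ATP spreads are not published directly;
#' 1.2 and 0.8 are implied by the printed fraction statistics (57% of
#' cofactor entries within one order of magnitude; 98% of ATP entries with
#' Km < [S]).
#'
#' @return Data frame with columns `label`, `n_entries`, `ratio_mu`,
#'   `ratio_sigma`, `n_substrates`.
#' @export
default_km_spec <- function() {
  data.frame(
    label = c("major_metabolite", "cofactor", "ATP"),
    n_entries = c(980L, 410L, 313L),
    ratio_mu = c(-0.18, -0.43, -1.64),
    ratio_sigma = c(1.3, 1.2, 0.8),
    n_substrates = c(25L, 5L, 1L),
    stringsAsFactors = FALSE
  )
}

## split n entries over ns substrates as evenly as possible
.split_counts <- function(n, ns) {
  base <- n %/% ns
  rem <- n %% ns
  base + c(rep(1L, rem), rep(0L, ns - rem))
}

#' Generate a synthetic Km-[S] table
#'
#' Draws a table with the statistical structure of the wild-type Km versus
#' in-vivo concentration dataset: in-vivo concentrations are log-uniform over
#' \eqn{10^{-2}} to \eqn{10^{4}} uM, per-category log-ratios are Gaussian with
#' the specified centers and spreads, and `Km = S * 10^ratio`. Occurrence
#' counts per substrate are split as evenly as possible within each category
#' and must respect the categorization thresholds (at most `low` per
#' major-metabolite substrate, between `low + 1` and `high - 1` per cofactor
#' substrate, at least `high` for the high-occurrence class); an infeasible
#' profile is an error. Fully deterministic for a fixed seed (a single
#' `rnorm`/`runif` stream in row order).
#'
#' @param spec Data frame as returned by [default_km_spec()].
#' @param seed Integer seed; the generator restores the caller's RNG state.
#' @param low,high Occurrence thresholds used for the feasibility check.
#' @return A data frame of class `"km_dataset"` with columns `substrate`,
#'   `Km` (uM), `S` (uM), `organism`, `log_ratio`.
#' @examples
#' tab <- generate_km_dataset(seed = 42)
#' nrow(tab)  # 1703
#' @export
generate_km_dataset <- function(spec = default_km_spec(), seed = 1,
                                low = 50, high = 300) {
  stopifnot(is.data.frame(spec),
            all(c("label", "n_entries", "ratio_mu", "ratio_sigma",
                  "n_substrates") %in% names(spec)),
            all(spec$n_entries >= 0), all(spec$ratio_sigma >= 0),
            all(spec$n_substrates >= 1))
  ## feasibility of the occurrence profile against the category thresholds
  for (i in seq_len(nrow(spec))) {
    counts <- .split_counts(spec$n_entries[i], spec$n_substrates[i])
    ok <- switch(spec$label[i],
      major_metabolite = all(counts <= low),
      cofactor = all(counts > low & counts < high),
      ATP = all(counts >= high),
      TRUE)
    if (!ok)
      stop("infeasible occurrence profile for category '", spec$label[i],
           "': ", spec$n_entries[i], " entries over ", spec$n_substrates[i],
           " substrates violates the occurrence thresholds")
  }
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(seed)
  organisms <- c("Escherichia coli", "Saccharomyces cerevisiae",
                 "Mus musculus")
  parts <- lapply(seq_len(nrow(spec)), function(i) {
    n <- spec$n_entries[i]
    if (n == 0L) return(NULL)
    counts <- .split_counts(n, spec$n_substrates[i])
    subs <- if (spec$label[i] == "ATP" && spec$n_substrates[i] == 1L) "ATP"
            else sprintf("%s_%02d", spec$label[i], seq_len(spec$n_substrates[i]))
    s <- 10^stats::runif(n, -2, 4)
    ratio <- stats::rnorm(n, spec$ratio_mu[i], spec$ratio_sigma[i])
    data.frame(substrate = rep(subs, counts),
               Km = s * 10^ratio, S = s,
               organism = sample(organisms, n, replace = TRUE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  if (is.null(out))
    out <- data.frame(substrate = character(0), Km = numeric(0),
                      S = numeric(0), organism = character(0))
  out$log_ratio <- if (nrow(out)) log10(out$Km / out$S) else numeric(0)
  rownames(out) <- NULL
  class(out) <- c("km_dataset", "data.frame")
  out
}

#' Write a Km-[S] table as CSV
#'
#' Writes the four data columns (`substrate`, `Km`, `S`, `organism`) in uM,
#' in a form readable by [load_km_dataset()] with `km_unit = "uM"`,
#' `s_unit = "uM"`. Byte-identical output for identical input.
#'
#' @param x A `"km_dataset"` data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_km_dataset <- function(x, path) {
  stopifnot(is.data.frame(x),
            all(c("substrate", "Km", "S", "organism") %in% names(x)))
  utils::write.csv(x[, c("substrate", "Km", "S", "organism")], path,
                   row.names = FALSE)
  invisible(path)
}

## ---- landscape/condition fixtures ----------------------------------------

#' Generate random landscape and condition fixtures
#'
#' Seeded sampler used by the property suites (Haldane identity, ridge, apex
#' and scaling checks). Free energies are uniform over the given ranges, BEP
#' coefficients uniform over `alpha_range`, reference rate constants
#' log-uniform over `k0_range`, and substrate/product concentrations
#' log-uniform over `conc_range`.
#'
#' @param n Number of fixtures (0 gives an empty list).
#' @param seed Integer seed; caller RNG state is restored.
#' @param dG1_range,dGT_range Free-energy ranges, kJ/mol (within +-100).
#' @param alpha_range BEP-coefficient range, within \[0.05, 0.95\].
#' @param k0_range Range for both reference rate constants (log-uniform).
#' @param conc_range Concentration range for S and P, uM (log-uniform).
#' @param constrain_alpha_sum If `TRUE`, sets `alpha2 = 1 - alpha1` so the
#'   closed-form optimum applies.
#' @return List of length `n`; each element has `$landscape`
#'   (a [thermo_landscape()]) and `$condition` (an [assay_condition()], with
#'   the standard mechanism).
#' @export
generate_landscapes <- function(n, seed = 1,
                                dG1_range = c(-60, 20),
                                dGT_range = c(-80, 0),
                                alpha_range = c(0.05, 0.95),
                                k0_range = c(0.1, 10),
                                conc_range = c(1e-2, 1e4),
                                constrain_alpha_sum = FALSE) {
  stopifnot(n >= 0,
            all(abs(c(dG1_range, dGT_range)) <= 100),
            alpha_range[1] >= 0.05, alpha_range[2] <= 0.95,
            all(k0_range > 0), all(conc_range > 0))
  if (n == 0L) return(list())
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(seed)
  dG1 <- stats::runif(n, dG1_range[1], dG1_range[2])
  dGT <- stats::runif(n, dGT_range[1], dGT_range[2])
  a1 <- stats::runif(n, alpha_range[1], alpha_range[2])
  a2 <- if (constrain_alpha_sum) 1 - a1
        else stats::runif(n, alpha_range[1], alpha_range[2])
  k1_0 <- exp(stats::runif(n, log(k0_range[1]), log(k0_range[2])))
  k2_0 <- exp(stats::runif(n, log(k0_range[1]), log(k0_range[2])))
  s <- exp(stats::runif(n, log(conc_range[1]), log(conc_range[2])))
  p <- exp(stats::runif(n, log(conc_range[1]), log(conc_range[2])))
  lapply(seq_len(n), function(i) {
    list(landscape = thermo_landscape(dG1[i], dGT[i], a1[i], a2[i],
                                      k1_0[i], k2_0[i]),
         condition = assay_condition(S = s[i], P = p[i]))
  })
}
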