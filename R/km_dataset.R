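## ---- loading -------------------------------------------------------------

#' Load a Km versus in-vivo substrate-concentration table
#'
#' Reads a CSV or TSV table with (at least) the columns `substrate`, `Km`,
#' `S` and `organism` (case-insensitive). Units must be declared explicitly
#' for both concentration columns — Km values from kinetics databases are
#' conventionally in mM while metabolomic concentrations are often in uM, and
#' a silent unit mixup shifts every log-ratio by 3 — and are converted to uM.
#' Rows with missing or non-positive `Km` or `S` are dropped and counted in
#' the load report. The log-ratio `log10(Km/S)` is always recomputed from the
#' converted columns, never read from the file.
#'
#' @param path CSV or TSV file (delimiter sniffed from the header line).
#' @param km_unit,s_unit Units of the `Km` and `S` columns: `"uM"`, `"mM"`
#'   or `"M"`. No defaults: they must be stated.
#' @return A data frame of class `"km_dataset"` with columns `substrate`,
#'   `Km`, `S` (both uM), `organism`, `log_ratio`, and an attribute
#'   `load_report` (list: `n_rows`, `n_kept`, `n_dropped`, `dropped_reasons`).
#' @seealso [generate_km_dataset()] for synthetic tables, [km_consistency()]
#'   for the downstream analysis.
#' @export
load_km_dataset <- function(path, km_unit = c("uM", "mM", "M"),
                            s_unit = c("uM", "mM", "M")) {
  km_unit <- match.arg(km_unit)
  s_unit <- match.arg(s_unit)
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           quote = "\"", comment.char = "")
  cols <- tolower(names(raw))
  pick <- function(nm) {
    i <- which(cols == tolower(nm))
    if (length(i) == 0L)
      stop("required column '", nm, "' is missing from ", path)
    raw[[i[1]]]
  }
  substrate <- as.character(pick("substrate"))
  organism <- as.character(pick("organism"))
  km_raw <- suppressWarnings(as.numeric(pick("Km")))
  s_raw <- suppressWarnings(as.numeric(pick("S")))
  n_unparseable <- sum((is.na(km_raw) & !is.na(pick("Km"))) |
                       (is.na(s_raw) & !is.na(pick("S"))))
  if (n_unparseable > 0)
    warning(n_unparseable, " row(s) had unparseable Km or S values")
  to_uM <- c(uM = 1, mM = 1e3, M = 1e6)
  km <- km_raw * to_uM[[km_unit]]
  s <- s_raw * to_uM[[s_unit]]
  bad_na <- is.na(km) | is.na(s)
  bad_pos <- !bad_na & (km <= 0 | s <= 0)
  keep <- !(bad_na | bad_pos)
  out <- data.frame(substrate = substrate[keep], Km = km[keep], S = s[keep],
                    organism = organism[keep],
                    log_ratio = log10(km[keep] / s[keep]),
                    stringsAsFactors = FALSE)
  attr(out, "load_report") <- list(
    n_rows = length(keep), n_kept = sum(keep), n_dropped = sum(!keep),
    dropped_reasons = c(missing_or_unparseable = sum(bad_na),
                        nonpositive = sum(bad_pos))
  )
  class(out) <- c("km_dataset", "data.frame")
  out
}

## ---- categorization -------------------------------------------------------

#' Categorize substrates by how often they occur in the dataset
#'
#' The number of entries per substrate acts as a proxy for how strongly a
#' substrate is shared between enzymes, and therefore how far in-vivo kinetics
#' may deviate from the single-enzyme Michaelis-Menten picture. Occurrence
#' counts are computed over the whole dataset; the boundary convention is:
#' at most `low` occurrences -> `"major_metabolite"`, between `low + 1` and
#' `high - 1` -> `"cofactor"`, at least `high` -> `"ATP"`.
#'
#' @param data A `"km_dataset"` (or any data frame with a `substrate` column).
#' @param low,high Occurrence thresholds; defaults 50 and 300.
#' @return Factor of labels, one per row, levels
#'   `c("major_metabolite", "cofactor", "ATP")`.
#' @export
categorize_substrates <- function(data, low = 50, high = 300) {
  stopifnot("substrate" %in% names(data), low < high)
  counts <- table(data$substrate)
  n <- as.vector(counts[data$substrate])
  lab <- ifelse(n >= high, "ATP",
                ifelse(n > low, "cofactor", "major_metabolite"))
  factor(lab, levels = c("major_metabolite", "cofactor", "ATP"))
}

## ---- Gaussian histogram fit -----------------------------------------------

#' Least-squares Gaussian fit to a histogram of log-ratios
#'
#' Bins the values at a fixed bin width (bins aligned to multiples of the
#' width) and fits \eqn{A \exp(-(x - \mu)^2 / 2\sigma^2)} to the bin counts
#' by unweighted least squares (Levenberg-Marquardt, with a Nelder-Mead
#' fallback). Sample mean and SD are always returned alongside the fit for
#' comparison. Degenerate input (all values identical) yields an `NA` fit
#' with the sample statistics intact.
#'
#' @param x Numeric values (log10 ratios); at least 10 required.
#' @param bin_width Histogram bin width in log10 units, default 0.25.
#' @return Object of class `"gaussian_fit"`: list with `mu`, `sigma`,
#'   `amplitude`, `sample_mean`, `sample_sd`, `n`, `bin_width`, `converged`,
#'   and the binned data (`mids`, `counts`).
#' @examples
#' set.seed(1)
#' fit_gaussian_histogram(rnorm(1e4, -0.18, 1.3))
#' @export
fit_gaussian_histogram <- function(x, bin_width = 0.25) {
  x <- x[is.finite(x)]
  if (length(x) < 10L)
    stop("at least 10 finite values are required for a histogram fit")
  m <- mean(x)
  s <- stats::sd(x)
  out <- list(mu = NA_real_, sigma = NA_real_, amplitude = NA_real_,
              sample_mean = m, sample_sd = s, n = length(x),
              bin_width = bin_width, converged = FALSE,
              mids = numeric(0), counts = numeric(0))
  class(out) <- "gaussian_fit"
  if (s == 0) {
    warning("degenerate input (zero variance): Gaussian fit not possible; ",
            "sample statistics returned")
    return(out)
  }
  breaks <- seq(floor(min(x) / bin_width) * bin_width,
                ceiling(max(x) / bin_width) * bin_width + bin_width / 2,
                by = bin_width)
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  df <- data.frame(mid = h$mids, count = h$counts)
  out$mids <- df$mid
  out$counts <- df$count
  start <- list(A = max(df$count), mu = m, sigma = s)
  fit <- tryCatch(
    minpack.lm::nlsLM(count ~ A * exp(-(mid - mu)^2 / (2 * sigma^2)),
                      data = df, start = start,
                      lower = c(A = 0, mu = -Inf, sigma = 1e-8),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    cf <- stats::coef(fit)
    out$mu <- unname(cf["mu"])
    out$sigma <- abs(unname(cf["sigma"]))
    out$amplitude <- unname(cf["A"])
    out$converged <- TRUE
    return(out)
  }
  ## fallback: direct least squares on (A, mu, log sigma)
  obj <- function(p) {
    pred <- p[1] * exp(-(df$mid - p[2])^2 / (2 * exp(2 * p[3])))
    sum((df$count - pred)^2)
  }
  op <- stats::optim(c(max(df$count), m, log(s)), obj,
                     control = list(maxit = 2000, reltol = 1e-12))
  out$amplitude <- op$par[1]
  out$mu <- op$par[2]
  out$sigma <- exp(op$par[3])
  out$converged <- op$convergence == 0
  out
}

#' @export
print.gaussian_fit <- function(x, ...) {
  cat(sprintf("Gaussian histogram fit (n = %d, bin width = %g)\n",
              x$n, x$bin_width))
  if (is.na(x$mu)) {
    cat("  fit unavailable (degenerate input)\n")
  } else {
    cat(sprintf("  center = %.4g, width (sigma) = %.4g, amplitude = %.4g\n",
                x$mu, x$sigma, x$amplitude))
  }
  cat(sprintf("  sample mean = %.4g, sample SD = %.4g\n",
              x$sample_mean, x$sample_sd))
  invisible(x)
}

## ---- per-category summary --------------------------------------------------

#' Per-category consistency statistics
#'
#' For each occurrence category, fits a Gaussian to the histogram of
#' \eqn{\log_{10}(K_m/[S])} and computes the fraction of entries with
#' \eqn{|\log_{10}(K_m/[S])| \le 1} (Km matches the in-vivo concentration to
#' within one order of magnitude), the fraction with \eqn{K_m < [S]}, and the
#' fraction with \eqn{\log_{10}(K_m/[S]) > 3}.
#'
#' @param data A `"km_dataset"`.
#' @param labels Factor from [categorize_substrates()]; computed if missing.
#' @param bin_width Histogram bin width for the Gaussian fits.
#' @return List with `categories` (data frame: `label`, `n_entries`,
#'   `gauss_mu`, `gauss_sigma`, `sample_mean`, `sample_sd`,
#'   `frac_within_one_order`, `frac_km_below_S`, `frac_ratio_above_3`) and
#'   `overall` (list: `n_entries`, `frac_ratio_above_3`, `n_ratio_above_3`).
#' @export
category_summary <- function(data, labels = NULL, bin_width = 0.25) {
  stopifnot(all(c("log_ratio", "substrate") %in% names(data)))
  if (is.null(labels)) labels <- categorize_substrates(data)
  stopifnot(length(labels) == nrow(data))
  lev <- levels(labels)
  rows <- lapply(lev, function(lb) {
    lr <- data$log_ratio[labels == lb]
    n <- length(lr)
    if (n == 0L) {
      return(data.frame(label = lb, n_entries = 0L, gauss_mu = NA_real_,
                        gauss_sigma = NA_real_, sample_mean = NA_real_,
                        sample_sd = NA_real_, frac_within_one_order = NA_real_,
                        frac_km_below_S = NA_real_,
                        frac_ratio_above_3 = NA_real_))
    }
    fit <- if (n >= 10L) fit_gaussian_histogram(lr, bin_width)
           else list(mu = NA_real_, sigma = NA_real_, sample_mean = mean(lr),
                     sample_sd = stats::sd(lr))
    data.frame(label = lb, n_entries = n, gauss_mu = fit$mu,
               gauss_sigma = fit$sigma, sample_mean = fit$sample_mean,
               sample_sd = fit$sample_sd,
               frac_within_one_order = mean(abs(lr) <= 1),
               frac_km_below_S = mean(lr < 0),
               frac_ratio_above_3 = mean(lr > 3))
  })
  categories <- do.call(rbind, rows)
  list(categories = categories,
       overall = list(n_entries = nrow(data),
                      frac_ratio_above_3 = mean(data$log_ratio > 3),
                      n_ratio_above_3 = sum(data$log_ratio > 3)))
}

## ---- pipeline object -------------------------------------------------------

#' Km versus in-vivo concentration consistency analysis
#'
#' The full analysis pipeline: categorizes substrates by occurrence,
#' recomputes log-ratios, fits per-category Gaussians to the log-ratio
#' histograms, and assembles the fraction statistics. This is the programmatic
#' equivalent of asking how often wild-type enzymes satisfy the optimality
#' guideline \eqn{K_m = [S]} to within an order of magnitude.
#'
#' @param data A `"km_dataset"` from [load_km_dataset()] or
#'   [generate_km_dataset()].
#' @param bin_width Histogram bin width in log10 units, default 0.25.
#' @param low,high Occurrence thresholds passed to [categorize_substrates()].
#' @return Object of class `"km_consistency"`: list with `data` (input plus a
#'   `label` column), `categories`, `overall`, `bin_width`.
#' @examples
#' tab <- generate_km_dataset(seed = 1)
#' fit <- km_consistency(tab)
#' fit
#' @export
km_consistency <- function(data, bin_width = 0.25, low = 50, high = 300) {
  stopifnot(is.data.frame(data),
            all(c("substrate", "Km", "S") %in% names(data)))
  if (any(data$Km <= 0) || any(data$S <= 0))
    stop("all Km and S values must be positive; clean the table with ",
         "load_km_dataset() first")
  data$log_ratio <- log10(data$Km / data$S)  # never trusted from the file
  labels <- categorize_substrates(data, low = low, high = high)
  summ <- category_summary(data, labels, bin_width = bin_width)
  data$label <- labels
  structure(
    list(data = data, categories = summ$categories, overall = summ$overall,
         bin_width = bin_width, thresholds = c(low = low, high = high)),
    class = "km_consistency"
  )
}

#' @export
print.km_consistency <- function(x, ...) {
  cat(sprintf("Km vs in-vivo [S] consistency analysis: %d entries, %d substrates\n",
              x$overall$n_entries, length(unique(x$data$substrate))))
  df <- x$categories
  df$gauss_mu <- round(df$gauss_mu, 3)
  df$gauss_sigma <- round(df$gauss_sigma, 3)
  df$frac_within_one_order <- round(df$frac_within_one_order, 3)
  df$frac_km_below_S <- round(df$frac_km_below_S, 3)
  print(df[, c("label", "n_entries", "gauss_mu", "gauss_sigma",
               "frac_within_one_order", "frac_km_below_S")],
        row.names = FALSE)
  cat(sprintf("Overall: %.2f%% of entries have log10(Km/[S]) > 3 (%d entries)\n",
              100 * x$overall$frac_ratio_above_3, x$overall$n_ratio_above_3))
  invisible(x)
}

#' @describeIn km_consistency the per-category statistics data frame.
#' @param object,... method arguments.
#' @export
summary.km_consistency <- function(object, ...) object$categories

#' @describeIn km_consistency fitted Gaussian centers, named by category.
#' @export
coef.km_consistency <- function(object, ...) {
  stats::setNames(object$categories$gauss_mu, object$categories$label)
}

#' @describeIn km_consistency overlaid log-ratio histograms with fitted
#'   Gaussian curves, one panel per category.
#' @param x plot argument.
#' @export
plot.km_consistency <- function(x, ...) {
  cats <- levels(x$data$label)
  old <- graphics::par(mfrow = c(1, length(cats)))
  on.exit(graphics::par(old))
  cols <- c(major_metabolite = "firebrick", cofactor = "steelblue",
            ATP = "black")
  for (lb in cats) {
    lr <- x$data$log_ratio[x$data$label == lb]
    if (length(lr) == 0L) next
    h <- graphics::hist(lr, breaks = seq(floor(min(lr)), ceiling(max(lr)),
                                         by = x$bin_width),
                        col = grDevices::adjustcolor(cols[[lb]], 0.5),
                        main = lb, xlab = expression(log[10](K[m] / "[S]")))
    row <- x$categories[x$categories$label == lb, ]
    if (!is.na(row$gauss_mu)) {
      xs <- seq(min(lr), max(lr), length.out = 200)
      graphics::lines(xs, max(h$counts) *
                        exp(-(xs - row$gauss_mu)^2 / (2 * row$gauss_sigma^2)),
                      col = cols[[lb]], lwd = 2)
    }
    graphics::abline(v = 0, lty = 2)
  }
  invisible(x)
}

#' Write a consistency report
#'
#' Writes the per-category statistics as JSON and, optionally, the per-entry
#' table (labels and log-ratios) as CSV.
#'
#' @param x A `"km_consistency"` object.
#' @param json_path Output JSON path.
#' @param csv_path Optional per-entry CSV path.
#' @return Invisibly, the list written to JSON.
#' @export
write_km_report <- function(x, json_path, csv_path = NULL) {
  stopifnot(inherits(x, "km_consistency"))
  report <- list(categories = x$categories, overall = x$overall,
                 bin_width = x$bin_width)
  jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  if (!is.null(csv_path))
    utils::write.csv(x$data, csv_path, row.names = FALSE)
  invisible(report)
}
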