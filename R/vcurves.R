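#' Weibull xylem vulnerability curve
#'
#' Constructs a two-parameter Weibull vulnerability curve (VC) describing loss
#' of xylem hydraulic conductivity with increasingly negative xylem pressure.
#' On the conductivity scale \eqn{K_s(\psi) = K_{smax} e^{-(-\psi/b)^c}}; on
#' the percent-loss scale \eqn{PLC(\psi) = 100 (1 - e^{-(-\psi/b)^c})}.
#'
#' @param b Scale parameter, MPa, entered as a positive magnitude (the curve
#'   itself lives at negative pressures).
#' @param c Shape parameter, dimensionless, > 0. Values below 1 give the
#'   "R-shaped" curves typical of cotton: rapid conductivity loss at mild
#'   tension followed by a long tail.
#' @param ksmax Maximum specific conductivity (kg m-1 s-1 MPa-1) of the flushed
#'   segment. Optional; only needed to evaluate the curve on the Ks scale.
#' @param organ `"stem"` or `"root"`.
#' @param genotype Optional genotype label.
#' @return An object of class `vulnerability_curve`.
#' @examples
#' vc <- vulnerability_curve(b = 1.55, c = 0.75, organ = "stem")
#' p50(vc)
#' @export
vulnerability_curve <- function(b, c, ksmax = NULL, organ = "stem",
                                genotype = NA_character_) {
  if (!is.numeric(b) || length(b) != 1L || !is.finite(b) || b <= 0)
    stop("'b' must be a single positive number (MPa magnitude)")
  if (!is.numeric(c) || length(c) != 1L || !is.finite(c) || c <= 0)
    stop("'c' must be a single positive number")
  if (!is.null(ksmax)) {
    if (!is.numeric(ksmax) || length(ksmax) != 1L || ksmax <= 0)
      stop("'ksmax' must be a single positive number")
  }
  organ <- match.arg(organ, c("stem", "root"))
  structure(list(b = b, c = c, ksmax = ksmax, organ = organ,
                 genotype = genotype),
            class = "vulnerability_curve")
}

#' @export
print.vulnerability_curve <- function(x, ...) {
  cat("Weibull vulnerability curve (", x$organ, ")\n", sep = "")
  if (!is.na(x$genotype)) cat("  genotype:", x$genotype, "\n")
  cat(sprintf("  b = %.4g MPa, c = %.4g", x$b, x$c))
  if (!is.null(x$ksmax)) cat(sprintf(", Ksmax = %.4g kg m-1 s-1 MPa-1", x$ksmax))
  cat(sprintf("\n  P50 = %.3f MPa\n", p50(x)))
  invisible(x)
}

#' Evaluate a vulnerability curve at given xylem pressures
#'
#' @param curve A [vulnerability_curve()].
#' @param pressure Xylem pressure(s), MPa, all <= 0.
#' @param what `"plc"`, `"ks"` or `"both"`. Requesting `"ks"` (or `"both"`)
#'   without a `ksmax` in the curve is an error.
#' @return A data.frame with columns `pressure_mpa` plus `plc` and/or `ks`.
#' @examples
#' vc <- vulnerability_curve(1.55, 0.75)
#' evaluate_vc(vc, c(0, -0.951, -1.55))
#' @export
evaluate_vc <- function(curve, pressure, what = c("plc", "ks", "both")) {
  stopifnot(inherits(curve, "vulnerability_curve"))
  what <- match.arg(what)
  if (any(!is.finite(pressure)) || any(pressure > 0))
    stop("xylem pressure must be finite and <= 0 MPa")
  frac <- exp(-((-pressure) / curve$b)^curve$c)  # retained fraction of Ksmax
  out <- data.frame(pressure_mpa = pressure, plc = 100 * (1 - frac))
  if (what %in% c("ks", "both")) {
    if (is.null(curve$ksmax))
      stop("curve has no 'ksmax'; cannot evaluate on the Ks scale")
    out$ks <- curve$ksmax * frac
  }
  if (what == "ks") out$plc <- NULL
  out
}

#' Pressure at 50% loss of conductivity
#'
#' Closed-form inversion of the Weibull PLC curve:
#' \eqn{\psi_{50} = -b (\ln 2)^{1/c}}.
#'
#' @param curve A [vulnerability_curve()].
#' @return P50 in MPa (negative).
#' @examples
#' p50(vulnerability_curve(1.55, 0.75))  # about -0.95 MPa
#' p50(vulnerability_curve(0.29, 0.59))  # about -0.16 MPa
#' @export
p50 <- function(curve) {
  stopifnot(inherits(curve, "vulnerability_curve"))
  -curve$b * log(2)^(1 / curve$c)
}

#' Fit a Weibull vulnerability curve to segment measurements
#'
#' Nonlinear least squares (Levenberg-Marquardt, [minpack.lm::nlsLM()]) with a
#' small multistart grid over (b0, c0) and box bounds, which keeps R-shaped
#' fits from collapsing into local optima. Fitting on the PLC scale estimates
#' (b, c); fitting on the Ks scale co-estimates Ksmax unless one is supplied.
#'
#' @param measurements data.frame with column `pressure_mpa` (<= 0) and either
#'   `plc` (percent) or `ks` (specific conductivity), e.g. from
#'   [read_vc_measurements()] or [gen_vc_measurements()].
#' @param scale `"plc"` (default; the scale used to parameterize the
#'   simulator) or `"ks"`.
#' @param ksmax Optional fixed Ksmax for `scale = "ks"`; if `NULL` it is
#'   co-estimated.
#' @param starts Optional data.frame of starting values with columns `b`, `c`.
#' @return An object of class `vc_fit`: `curve`, `residual_sum_squares`,
#'   `n_points`, `standard_errors`, `fit_scale`, `converged`.
#' @export
fit_vc <- function(measurements, scale = c("plc", "ks"), ksmax = NULL,
                   starts = NULL) {
  scale <- match.arg(scale)
  m <- as.data.frame(measurements)
  if (!"pressure_mpa" %in% names(m))
    stop("measurements need a 'pressure_mpa' column")
  ycol <- if (scale == "plc") "plc" else "ks"
  if (!ycol %in% names(m))
    stop("measurements need a '", ycol, "' column for scale = '", scale, "'")
  m <- m[is.finite(m$pressure_mpa) & is.finite(m[[ycol]]), , drop = FALSE]
  if (any(m$pressure_mpa > 0)) stop("xylem pressures must be <= 0 MPa")
  n <- nrow(m)
  n_par <- if (scale == "plc") 2L else if (is.null(ksmax)) 3L else 2L
  if (n < n_par + 1L) stop("need at least ", n_par + 1L, " measurements")
  if (length(unique(m$pressure_mpa)) < 2L)
    stop("non-identifiable: all measurements at the same pressure")
  if (stats::sd(m[[ycol]]) == 0)
    stop("non-identifiable: response has zero variance")

  psi <- m$pressure_mpa
  y <- m[[ycol]]
  if (is.null(starts))
    starts <- expand.grid(b = c(0.2, 1, 3), c = c(0.5, 1, 2))
  lower <- c(b = 0.01, c = 0.05)
  upper <- c(b = 20, c = 20)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    st <- list(b = starts$b[i], c = starts$c[i])
    fit <- if (scale == "plc") {
      try(minpack.lm::nlsLM(
        y ~ 100 * (1 - exp(-((-psi) / b)^c)),
        start = st, lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
    } else if (is.null(ksmax)) {
      st$ksmax <- max(y)
      try(minpack.lm::nlsLM(
        y ~ ksmax * exp(-((-psi) / b)^c),
        start = st, lower = c(lower, ksmax = 1e-9),
        upper = c(upper, ksmax = Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
    } else {
      try(minpack.lm::nlsLM(
        y ~ ksmax * exp(-((-psi) / b)^c),
        start = st, lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
    }
    if (inherits(fit, "try-error")) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best))
    stop("vulnerability-curve fit failed to converge from any start")
  fit <- best$fit
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, length(cf)))
  ks_out <- if (scale == "ks") {
    if (is.null(ksmax)) unname(cf["ksmax"]) else ksmax
  } else NULL
  organ <- if ("organ" %in% names(m)) as.character(m$organ[1]) else "stem"
  genotype <- if ("genotype" %in% names(m)) as.character(m$genotype[1]) else NA_character_
  curve <- vulnerability_curve(unname(cf["b"]), unname(cf["c"]), ksmax = ks_out,
                               organ = organ, genotype = genotype)
  structure(list(curve = curve,
                 residual_sum_squares = best$rss,
                 n_points = n,
                 standard_errors = se,
                 fit_scale = scale,
                 converged = isTRUE(fit$convInfo$isConv)),
            class = "vc_fit")
}

#' @export
print.vc_fit <- function(x, ...) {
  cat("Vulnerability-curve fit (", x$fit_scale, " scale, n = ", x$n_points,
      ")\n", sep = "")
  print(x$curve)
  cat(sprintf("  RSS = %.4g; converged: %s\n", x$residual_sum_squares,
              x$converged))
  invisible(x)
}

#' Compare fitted VC parameters across genotypes
#'
#' One-way ANOVA per parameter with Tukey HSD post-hoc pairwise comparisons at
#' a fixed significance level, the standard test for genotype differences in
#' replicate-level curve parameters.
#'
#' @param fits data.frame with a `genotype` column and one column per
#'   parameter to compare (any of `b`, `c`, `p50`), one row per biological
#'   replicate.
#' @param parameters Which parameter columns to test; defaults to all of
#'   `b`, `c`, `p50` that are present.
#' @param alpha Significance level for flagging pairs (default 0.05).
#' @return Object of class `vc_comparison`: per-parameter list with `F`,
#'   `p_value`, `tukey` (all pairs) and `flagged_pairs`.
#' @export
compare_vc_parameters <- function(fits, parameters = NULL, alpha = 0.05) {
  fits <- as.data.frame(fits)
  if (!"genotype" %in% names(fits)) stop("'fits' needs a 'genotype' column")
  if (is.null(parameters))
    parameters <- intersect(c("b", "c", "p50"), names(fits))
  if (!length(parameters)) stop("no parameter columns found")
  g <- factor(fits$genotype)
  if (nlevels(g) < 2L) stop("need at least 2 genotypes")
  if (any(table(g) < 2L)) stop("need at least 2 replicates per genotype")
  out <- lapply(parameters, function(p) {
    value <- fits[[p]]
    if (stats::var(value) == 0) {
      # all observations identical: no variance to partition
      return(list(F = 0, p_value = 1,
                  tukey = NULL,
                  flagged_pairs = character(0)))
    }
    fm <- stats::aov(value ~ g)
    an <- summary(fm)[[1]]
    tk <- stats::TukeyHSD(fm, conf.level = 1 - alpha)$g
    flagged <- rownames(tk)[tk[, "p adj"] < alpha]
    list(F = an[["F value"]][1], p_value = an[["Pr(>F)"]][1],
         tukey = tk, flagged_pairs = flagged)
  })
  names(out) <- parameters
  structure(list(results = out, alpha = alpha, n_groups = nlevels(g)),
            class = "vc_comparison")
}

#' @export
print.vc_comparison <- function(x, ...) {
  cat("Genotype comparison of VC parameters (alpha =", x$alpha, ")\n")
  for (p in names(x$results)) {
    r <- x$results[[p]]
    cat(sprintf("  %-4s F = %.3f, p = %.4g; flagged pairs: %s\n", p, r$F,
                r$p_value,
                if (length(r$flagged_pairs)) paste(r$flagged_pairs, collapse = ", ")
                else "none"))
  }
  invisible(x)
}

#' Read a vulnerability-curve measurement table
#'
#' Expects delimited text with columns `genotype`, `organ`, `segment_id`,
#' `pressure_mpa` and `ks` and/or `plc`.
#'
#' @param path File path.
#' @param sep Field separator (default comma).
#' @return data.frame of measurements.
#' @export
read_vc_measurements <- function(path, sep = ",") {
  m <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE)
  need <- c("genotype", "organ", "segment_id", "pressure_mpa")
  miss <- setdiff(need, names(m))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (!any(c("ks", "plc") %in% names(m)))
    stop("need a 'ks' or 'plc' column")
  if (any(m$pressure_mpa > 0)) stop("pressures must be <= 0 MPa")
  m
}

#' Write a table of vulnerability-curve fits
#'
#' @param fits A list of `vc_fit` objects (or a single one).
#' @param path Output file path (delimited text).
#' @param sep Field separator.
#' @return The report data.frame, invisibly.
#' @export
write_vc_fits <- function(fits, path, sep = ",") {
  if (inherits(fits, "vc_fit")) fits <- list(fits)
  rows <- lapply(fits, function(f) {
    data.frame(genotype = f$curve$genotype, organ = f$curve$organ,
               fit_scale = f$fit_scale, b = f$curve$b, c = f$curve$c,
               ksmax = if (is.null(f$curve$ksmax)) NA_real_ else f$curve$ksmax,
               p50 = p50(f$curve), rss = f$residual_sum_squares,
               n_points = f$n_points, converged = f$converged)
  })
  report <- do.call(rbind, rows)
  utils::write.table(report, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(report)
}
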