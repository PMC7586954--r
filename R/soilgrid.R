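#' Semivariance of a fitted variogram model
#'
#' @param model A `variogram_model` (or a list with `model`, `nugget`,
#'   `partial_sill`, `range`).
#' @param h Lag distance(s), m.
#' @return Semivariance at each lag. `h = 0` returns 0 (the nugget is a
#'   discontinuity at the origin).
#' @export
semivariance <- function(model, h) {
  n <- model$nugget; s <- model$partial_sill; r <- model$range
  structural <- switch(model$model,
    exponential = s * (1 - exp(-h / r)),
    spherical = ifelse(h >= r, s, s * (1.5 * h / r - 0.5 * (h / r)^3)),
    stop("unknown variogram model: ", model$model))
  ifelse(h <= 0, 0, n + structural)
}

#' Fit a variogram model to soil samples
#'
#' Bins pairwise squared half-differences of the chosen texture variable by
#' lag distance and fits the empirical semivariogram by weighted least
#' squares (weights = pair counts per bin), with a small multistart over the
#' range parameter.
#'
#' @param samples data.frame with columns `x`, `y` and the variable. If
#'   several depth layers are present, filter to one layer first; the field
#'   is interpolated independently per layer.
#' @param variable One of `"clay"`, `"sand"`, `"silt"`.
#' @param model `"exponential"` (range = e-folding distance) or
#'   `"spherical"` (range = full range).
#' @param n_bins Number of lag bins (default 12).
#' @param cutoff Maximum lag used (default half the maximum pairwise
#'   distance).
#' @return Object of class `variogram_model` with `nugget`, `partial_sill`,
#'   `range`, `model` and the `empirical` binned semivariogram.
#' @export
fit_variogram <- function(samples, variable = c("clay", "sand", "silt"),
                          model = c("exponential", "spherical"),
                          n_bins = 12, cutoff = NULL) {
  variable <- match.arg(variable)
  model <- match.arg(model)
  s <- as.data.frame(samples)
  stopifnot(all(c("x", "y", variable) %in% names(s)))
  if (nrow(s) < 10L) stop("need at least 10 samples to fit a variogram")
  v <- s[[variable]]
  d <- as.matrix(stats::dist(cbind(s$x, s$y)))
  iu <- upper.tri(d)
  h <- d[iu]
  if (length(unique(round(h, 9))) < 3L)
    stop("fewer than 3 distinct pairwise lags")
  gam <- 0.5 * outer(v, v, "-")[iu]^2
  if (stats::var(v) == 0) {
    warning("zero-variance variable: returning degenerate variogram")
    return(structure(list(model = model, nugget = 0, partial_sill = 0,
                          range = max(h) / 3, empirical = NULL),
                     class = "variogram_model"))
  }
  if (is.null(cutoff)) cutoff <- max(h) / 2
  keep <- h <= cutoff & h > 0
  bins <- cut(h[keep], breaks = seq(0, cutoff, length.out = n_bins + 1L),
              include.lowest = TRUE)
  emp <- data.frame(
    lag = tapply(h[keep], bins, mean),
    gamma = tapply(gam[keep], bins, mean),
    n = as.integer(table(bins)))
  emp <- emp[emp$n > 0 & is.finite(emp$gamma), , drop = FALSE]
  if (nrow(emp) < 3L) stop("fewer than 3 non-empty lag bins")

  vtot <- stats::var(v)
  obj <- function(par) {
    m <- list(model = model, nugget = par[1], partial_sill = par[2],
              range = par[3])
    sum(emp$n * (emp$gamma - semivariance(m, emp$lag))^2)
  }
  best <- NULL
  for (r0 in c(cutoff / 6, cutoff / 3, cutoff)) {
    fit <- try(stats::optim(c(0.1 * vtot, 0.9 * vtot, r0), obj,
                            method = "L-BFGS-B",
                            lower = c(0, 0, cutoff / 1e3),
                            upper = c(2 * vtot, 5 * vtot, 10 * cutoff)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("variogram fit failed")
  structure(list(model = model, nugget = best$par[1],
                 partial_sill = best$par[2], range = best$par[3],
                 empirical = emp),
            class = "variogram_model")
}

#' @export
print.variogram_model <- function(x, ...) {
  cat(sprintf("%s variogram: nugget %.4g, partial sill %.4g, range %.4g m\n",
              x$model, x$nugget, x$partial_sill, x$range))
  invisible(x)
}

# discretization points of a rectangular block (midpoint grid); a degenerate
# rectangle (zero width/height) collapses to fewer points
.block_points <- function(b, d) {
  gx <- if (b["xmax"] > b["xmin"])
    b["xmin"] + (seq_len(d) - 0.5) / d * (b["xmax"] - b["xmin"]) else b["xmin"]
  gy <- if (b["ymax"] > b["ymin"])
    b["ymin"] + (seq_len(d) - 0.5) / d * (b["ymax"] - b["ymin"]) else b["ymin"]
  as.matrix(expand.grid(x = gx, y = gy))
}

#' Ordinary block kriging of a soil texture variable
#'
#' Solves the ordinary kriging system (semivariogram form with a Lagrange
#' multiplier, so weights sum to 1 per block) for the average of the variable
#' over each rectangular block, using a midpoint discretization grid.
#'
#' @param samples data.frame with `x`, `y` and the variable (single depth
#'   layer). Duplicate locations are averaged before solving.
#' @param variogram A fitted [fit_variogram()] model.
#' @param variable Variable name in `samples`.
#' @param blocks data.frame with columns `xmin`, `xmax`, `ymin`, `ymax` (a
#'   zero-area rectangle kriges a point).
#' @param discretization Points per block side (default 4, i.e. a 4 x 4 grid).
#' @return Object of class `krige_result`: `predictions` (block, pred, var),
#'   `weights` (blocks x samples; each row sums to 1) and `lagrange`.
#' @export
block_krige <- function(samples, variogram, variable = "clay", blocks,
                        discretization = 4) {
  s <- as.data.frame(samples)
  stopifnot(all(c("x", "y", variable) %in% names(s)))
  blocks <- as.data.frame(blocks)
  stopifnot(all(c("xmin", "xmax", "ymin", "ymax") %in% names(blocks)))
  # deduplicate coincident sample locations (averaging), else the system is
  # singular when the nugget is zero
  key <- paste(signif(s$x, 12), signif(s$y, 12))
  if (anyDuplicated(key)) {
    s <- stats::aggregate(s[c("x", "y", variable)], list(key = key), mean)
    s$key <- NULL
  }
  n <- nrow(s)
  xy <- cbind(s$x, s$y)
  v <- s[[variable]]

  G <- matrix(0, n + 1L, n + 1L)
  if (n > 1L) {
    dmat <- as.matrix(stats::dist(xy))
    G[1:n, 1:n] <- semivariance(variogram, dmat)
  }
  G[n + 1L, 1:n] <- 1
  G[1:n, n + 1L] <- 1
  diag(G)[1:n] <- 0

  nb <- nrow(blocks)
  rhs <- matrix(0, n + 1L, nb)
  gbb <- numeric(nb)
  centers <- matrix(0, nb, 2)
  for (j in seq_len(nb)) {
    bp <- .block_points(unlist(blocks[j, c("xmin", "xmax", "ymin", "ymax")]),
                        discretization)
    centers[j, ] <- colMeans(bp)
    dd <- sqrt(outer(xy[, 1], bp[, 1], "-")^2 + outer(xy[, 2], bp[, 2], "-")^2)
    rhs[1:n, j] <- rowMeans(semivariance(variogram, dd))
    dpp <- as.matrix(stats::dist(bp))
    gbb[j] <- mean(semivariance(variogram, dpp))
    rhs[n + 1L, j] <- 1
  }
  sol <- tryCatch(solve(G, rhs), error = function(e)
    stop("singular kriging system: ", conditionMessage(e)))
  w <- t(sol[1:n, , drop = FALSE])
  mu <- sol[n + 1L, ]
  pred <- as.numeric(w %*% v)
  pvar <- pmax(0, colSums(sol[1:n, , drop = FALSE] * rhs[1:n, , drop = FALSE]) +
                 mu - gbb)
  # extrapolation warning: block centre beyond 2x the maximum nearest-sample
  # spacing from any sample
  if (n > 1L) {
    nn <- apply(dmat + diag(Inf, n), 1, min)
    dc <- sqrt(outer(centers[, 1], xy[, 1], "-")^2 +
               outer(centers[, 2], xy[, 2], "-")^2)
    far <- apply(dc, 1, min) > 2 * max(nn)
    if (any(far))
      warning(sum(far), " block(s) beyond 2x the maximum sample spacing")
  }
  structure(list(predictions = data.frame(block = seq_len(nb), pred = pred,
                                          var = pvar),
                 weights = w, lagrange = mu, variable = variable),
            class = "krige_result")
}

#' Aggregate plot-level fractions to grid cells and pick clay extremes
#'
#' Cell fractions are the means of member plots (renormalized to closure);
#' cells at or beyond the stated clay percentiles (linear interpolation
#' between order statistics, boundary values included) form the
#' high-clay / low-clay selections used to build contrasting soil parameter
#' sets.
#'
#' @param plot_values data.frame with `plot_id`, `clay`, `sand`, `silt`.
#' @param layout data.frame mapping `plot_id` to `cell_id` (optionally with a
#'   `treatment` column carried through).
#' @param lower,upper Clay percentile cutoffs (defaults 0.10 and 0.90).
#' @return List with `cells` (cell-level fractions), `high_clay` and
#'   `low_clay` (subsets of `cells`).
#' @export
aggregate_and_select_cells <- function(plot_values, layout, lower = 0.1,
                                       upper = 0.9) {
  pv <- as.data.frame(plot_values)
  ly <- as.data.frame(layout)
  stopifnot(all(c("plot_id", "clay", "sand", "silt") %in% names(pv)),
            all(c("plot_id", "cell_id") %in% names(ly)))
  m <- merge(pv, ly, by = "plot_id", all.x = TRUE)
  if (anyNA(m$cell_id))
    stop("unassigned plots: ", paste(m$plot_id[is.na(m$cell_id)], collapse = ", "))
  cells <- stats::aggregate(m[c("clay", "sand", "silt")],
                            by = list(cell_id = m$cell_id), FUN = mean)
  tot <- cells$clay + cells$sand + cells$silt
  cells$clay <- cells$clay / tot
  cells$sand <- cells$sand / tot
  cells$silt <- cells$silt / tot
  if ("treatment" %in% names(m)) {
    tr <- unique(m[c("cell_id", "treatment")])
    cells <- merge(cells, tr, by = "cell_id")
  }
  q <- stats::quantile(cells$clay, c(lower, upper), type = 7, names = FALSE)
  list(cells = cells,
       high_clay = cells[cells$clay >= q[2], , drop = FALSE],
       low_clay = cells[cells$clay <= q[1], , drop = FALSE])
}

#' Representative texture from a set of grid cells
#'
#' Mean of the cell fractions, renormalized to closure — the averaging rule
#' used to build e.g. a single "high clay" parameter set from selected cells.
#'
#' @param cells data.frame with `clay`, `sand`, `silt` columns.
#' @return Named vector of fractions summing to 1.
#' @export
representative_texture <- function(cells) {
  f <- colMeans(cells[c("clay", "sand", "silt")])
  f / sum(f)
}

#' Read a soil sample table
#'
#' Delimited text with columns `x_m`, `y_m`, `depth_top_cm`,
#' `depth_bottom_cm`, `clay`, `sand`, `silt` (fractions of 1).
#'
#' @param path File path.
#' @param sep Field separator.
#' @return data.frame with internal column names (`x`, `y`, `depth_top`,
#'   `depth_bottom`, fractions).
#' @export
read_soil_samples <- function(path, sep = ",") {
  s <- utils::read.table(path, header = TRUE, sep = sep)
  need <- c("x_m", "y_m", "depth_top_cm", "depth_bottom_cm", "clay", "sand",
            "silt")
  miss <- setdiff(need, names(s))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  out <- data.frame(x = s$x_m, y = s$y_m, depth_top = s$depth_top_cm,
                    depth_bottom = s$depth_bottom_cm, clay = s$clay,
                    sand = s$sand, silt = s$silt)
  bad <- abs(out$clay + out$sand + out$silt - 1) > 1e-6
  if (any(bad)) stop(sum(bad), " sample(s) violate fraction closure")
  if (any(out$depth_bottom <= out$depth_top))
    stop("depth_bottom must exceed depth_top")
  out
}
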