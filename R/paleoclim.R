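#' @title Oxygen-isotope time series
#' @description (age Ma, delta-18-O value) pairs with strictly increasing
#' ages; irregular spacing allowed. Benthic delta-18-O rises as global
#' climate cools, so it is an inverse palaeo-temperature proxy.
#' @slot age ages in Ma, strictly increasing.
#' @slot value delta-18-O values.
#' @export
setClass("IsotopeSeries", representation(age = "numeric", value = "numeric"))

setValidity("IsotopeSeries", function(object) {
  if (length(object@age) != length(object@value))
    return("age and value lengths differ")
  if (length(object@age) >= 2L && any(diff(object@age) <= 0))
    return("ages must be strictly increasing (no duplicates)")
  TRUE
})

#' Construct an IsotopeSeries (sorting and validating)
#' @param age,value numeric vectors of equal length.
#' @return An [IsotopeSeries-class].
#' @export
isotopeSeries <- function(age, value) {
  ord <- order(age)
  new("IsotopeSeries", age = age[ord], value = value[ord])
}

setMethod("show", "IsotopeSeries", function(object) {
  cat(sprintf("IsotopeSeries: %d points, %.2f-%.2f Ma\n",
              length(object@age), min(object@age), max(object@age)))
})

#' @describeIn IsotopeSeries-class ages (Ma)
#' @param x an `IsotopeSeries`
#' @export
seriesAges <- function(x) x@age

#' @describeIn IsotopeSeries-class values
#' @export
seriesValues <- function(x) x@value

#' @title Temperature proxy on a uniform age grid
#' @description The isotope series interpolated onto the 0.1 Myr rate-curve
#' grid and (by default) negated, so larger values mean warmer; with that
#' orientation a negative rate-proxy correlation reads "speciation faster
#' when cooler".
#' @slot age uniform grid ages (Ma, ascending).
#' @slot value proxy values.
#' @slot negated whether the isotope values were negated.
#' @export
setClass("ProxySeries",
         representation(age = "numeric", value = "numeric",
                        negated = "logical"))

setMethod("show", "ProxySeries", function(object) {
  cat(sprintf("ProxySeries: %d grid points, %.1f-%.1f Ma%s\n",
              length(object@age), min(object@age), max(object@age),
              if (object@negated) " (negated: higher = warmer)" else ""))
})

#' Load an isotope series from CSV
#'
#' Two-column dialect: first column age in millions of years, second the
#' isotope value; a header row is detected and skipped. Rows with
#' non-numeric entries are rejected with a warning naming their line
#' numbers; duplicate ages keep the first occurrence, with a warning.
#'
#' @param path CSV path.
#' @return An [IsotopeSeries-class].
#' @export
loadIsotopeSeries <- function(path) {
  raw <- read.csv(path, header = FALSE, stringsAsFactors = FALSE,
                  colClasses = "character")
  if (ncol(raw) < 2L) stop("need a two-column CSV (age, value)")
  start <- 1L
  if (is.na(suppressWarnings(as.numeric(raw[1L, 1L])))) start <- 2L  # header
  rows <- seq.int(start, nrow(raw))
  age <- suppressWarnings(as.numeric(raw[rows, 1L]))
  value <- suppressWarnings(as.numeric(raw[rows, 2L]))
  bad <- which(is.na(age) | is.na(value))
  if (length(bad))
    warning("dropping malformed row(s) at line ",
            paste(rows[bad], collapse = ", "))
  ok <- setdiff(seq_along(rows), bad)
  age <- age[ok]; value <- value[ok]
  dup <- duplicated(age)
  if (any(dup)) {
    warning("dropping ", sum(dup), " duplicate age(s)")
    age <- age[!dup]; value <- value[!dup]
  }
  if (length(age) < 3L) stop("fewer than 3 valid rows in ", path)
  isotopeSeries(age, value)
}

#' Tukey running-mean smoothing
#'
#' Centered running mean over `window` consecutive points; at the series
#' ends the window is clipped to the available points. `window = 1` is the
#' identity.
#' A running-median variant is available via `median = TRUE`.
#'
#' @param series an [IsotopeSeries-class].
#' @param window odd integer window size in points (default 5).
#' @param median use a running median instead of the mean.
#' @return A smoothed [IsotopeSeries-class] on the same ages.
#' @export
tukeySmooth <- function(series, window = 5L, median = FALSE) {
  if (window %% 2L == 0L) stop("window must be odd")
  if (window < 1L) stop("window must be >= 1")
  v <- series@value
  n <- length(v)
  half <- (window - 1L) %/% 2L
  out <- vapply(seq_len(n), function(i) {
    w <- v[max(1L, i - half):min(n, i + half)]   # window clipped at the ends
    if (median) stats::median(w) else mean(w)
  }, 0)
  new("IsotopeSeries", age = series@age, value = out)
}

#' Resample an isotope series onto the rate-curve grid
#'
#' Linear interpolation onto a uniform grid (0.1 Myr default), matching
#' the bins of the speciation-rate curves; the values are negated by
#' default to form a warmth-increasing temperature proxy. Refuses to
#' extrapolate beyond the data's age range.
#'
#' @param series an [IsotopeSeries-class] (smooth it first if desired).
#' @param span `c(age_min, age_max)` in Ma.
#' @param step grid step in Myr.
#' @param negate negate values (default TRUE).
#' @return A [ProxySeries-class].
#' @export
resampleToGrid <- function(series, span, step = 0.1, negate = TRUE) {
  stopifnot(length(span) == 2L, span[1L] <= span[2L])
  lo <- min(series@age); hi <- max(series@age)
  if (span[1L] < lo - 1e-9 || span[2L] > hi + 1e-9)
    stop(sprintf(
      "span [%g, %g] extends beyond the data range [%g, %g] by [%g, %g]",
      span[1L], span[2L], lo, hi,
      max(0, lo - span[1L]), max(0, span[2L] - hi)))
  grid <- seq(span[1L], span[2L], by = step)
  val <- approx(series@age, series@value, xout = grid, rule = 1)$y
  if (negate) val <- -val
  new("ProxySeries", age = grid, value = val, negated = negate)
}

#' Pearson product-moment correlation
#'
#' @param x,y equal-length numeric vectors (n >= 3) with nonzero variance.
#' @return The coefficient in `[-1, 1]`; zero variance is an error, not a
#'   silent zero.
#' @export
pearsonR <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 points")
  if (sd(x) == 0 || sd(y) == 0)
    stop("undefined correlation: zero variance")
  cor(x, y, method = "pearson")
}

#' Detrended cross-correlation coefficient
#'
#' rho_DCCA(s): cumulative mean-centered profiles of both series; every
#' overlapping window of `s + 1` consecutive profile points is linearly
#' detrended by least squares; the detrended covariance F2_DCCA (mean
#' residual cross-product over windows) is normalized by the two
#' detrended-fluctuation roots F_DFA. Bounded in `[-1, 1]` by
#' Cauchy-Schwarz. Robust to the non-stationarity and autocorrelation
#' that bias plain Pearson correlation on palaeo time series.
#'
#' @param x,y equal-length numeric vectors, `N >= s + 2`.
#' @param s window (box) size, `4 <= s <= N/2`.
#' @return rho_DCCA(s).
#' @export
dccaRho <- function(x, y, s) {
  N <- length(x)
  if (length(y) != N) stop("x and y must have equal length")
  s <- as.integer(s)
  if (s < 4L || s > N / 2) stop("box size s must satisfy 4 <= s <= N/2")
  if (N < s + 2L) stop("series too short for box size ", s)
  X <- cumsum(x - mean(x))
  Y <- cumsum(y - mean(y))
  t <- 0:s
  tc <- t - mean(t)
  stt <- sum(tc^2)
  nwin <- N - s
  fxy <- fxx <- fyy <- 0
  for (i in seq_len(nwin)) {
    xs <- X[i:(i + s)]
    ys <- Y[i:(i + s)]
    rx <- xs - mean(xs) - (sum(tc * xs) / stt) * tc
    ry <- ys - mean(ys) - (sum(tc * ys) / stt) * tc
    fxy <- fxy + mean(rx * ry)
    fxx <- fxx + mean(rx * rx)
    fyy <- fyy + mean(ry * ry)
  }
  if (fxx == 0 || fyy == 0)
    stop("undefined DCCA coefficient: zero detrended fluctuation")
  (fxy / nwin) / sqrt((fxx / nwin) * (fyy / nwin))
}

#' @title Distribution of per-sample correlation coefficients
#' @description One coefficient per posterior rate curve against the
#' temperature proxy, with a one-sample two-sided t-test of the mean
#' against zero. The posterior draws are not independent, so the t-test
#' p-value is reported as-is with an effective-sample-size caveat in
#' `note`.
#' @slot coef per-curve coefficients.
#' @slot method `"pearson"` or `"dcca"`.
#' @slot s DCCA box size (NA for Pearson).
#' @slot mean,se,t,p summary statistics (t and p are `NA` when the
#'   coefficient set has zero variance).
#' @slot note caveats.
#' @export
setClass("CorrelationDistribution",
         representation(coef = "numeric", method = "character", s = "numeric",
                        mean = "numeric", se = "numeric", t = "numeric",
                        p = "numeric", note = "character"))

setMethod("show", "CorrelationDistribution", function(object) {
  cat(sprintf(
    "CorrelationDistribution [%s%s]: n=%d, mean=%.4f, se=%.4g, t=%.3g, p=%.3g\n",
    object@method,
    if (object@method == "dcca") sprintf("(s=%d)", as.integer(object@s)) else "",
    length(object@coef), object@mean, object@se, object@t, object@p))
  if (nzchar(object@note)) cat("  note:", object@note, "\n")
})

#' @describeIn CorrelationDistribution-class the per-curve coefficients
#' @param x a `CorrelationDistribution`
#' @export
coefValues <- function(x) x@coef

#' Correlate every posterior rate curve with the temperature proxy
#'
#' Computes one coefficient (Pearson or rho_DCCA) per posterior rate
#' curve over the overlapping span of the curve grid and the proxy grid,
#' then a one-sample two-sided Student t-test of the coefficient mean
#' against zero. A negative mean under the warmth-increasing proxy
#' orientation means speciation rates increase with cooler temperatures.
#'
#' @param curves matrix from [rttCurves()] (samples x grid, `"age"`
#'   attribute), or a list of [RateCurve-class] on a common grid.
#' @param proxy a [ProxySeries-class] covering the curve grid overlap.
#' @param method `"pearson"` or `"dcca"`.
#' @param s DCCA box size; default `floor(N/4)` of the overlap length.
#' @return A [CorrelationDistribution-class].
#' @export
correlatePosterior <- function(curves, proxy,
                               method = c("pearson", "dcca"), s = NULL) {
  method <- match.arg(method)
  if (is.list(curves) && !is.matrix(curves)) {
    ages <- curves[[1L]]@age
    for (cv in curves)
      if (!isTRUE(all.equal(cv@age, ages)))
        stop("all curves must share one grid")
    mat <- do.call(rbind, lapply(curves, curveRates))
  } else {
    mat <- curves
    ages <- attr(curves, "age")
    if (is.null(ages)) stop("curve matrix lacks an 'age' attribute")
  }
  step <- if (length(ages) > 1L) ages[2L] - ages[1L] else 0.1
  keep <- ages >= min(proxy@age) - 1e-9 & ages <= max(proxy@age) + 1e-9
  if (sum(keep) < 3L) stop("curve/proxy overlap has fewer than 3 points")
  ages <- ages[keep]
  mat <- mat[, keep, drop = FALSE]
  pv <- approx(proxy@age, proxy@value, xout = ages)$y
  N <- length(ages)
  if (method == "dcca" && is.null(s)) s <- max(4L, floor(N / 4))
  if (method == "dcca" && (s < 4L || s > N / 2))
    stop("box size s must satisfy 4 <= s <= N/2")
  coefs <- apply(mat, 1L, function(r) {
    if (sd(r) == 0) return(NA_real_)
    # degenerate curves (e.g. exactly linear cumulative profiles) have no
    # defined coefficient; they are dropped like constant curves
    tryCatch(
      if (method == "pearson") pearsonR(r, pv) else dccaRho(r, pv, s),
      error = function(e) {
        if (grepl("undefined", conditionMessage(e))) NA_real_ else stop(e)
      })
  })
  note <- paste("posterior draws are autocorrelated; the t-test treats the",
                "coefficients as independent and overstates precision")
  nOK <- sum(!is.na(coefs))
  if (nOK < 2L || sd(coefs, na.rm = TRUE) == 0) {
    return(new("CorrelationDistribution", coef = coefs, method = method,
               s = if (method == "dcca") as.numeric(s) else NA_real_,
               mean = mean(coefs, na.rm = TRUE), se = 0,
               t = NA_real_, p = NA_real_,
               note = paste("zero-variance coefficient set: t undefined;",
                            note)))
  }
  tt <- t.test(coefs[!is.na(coefs)], mu = 0)
  if (nOK < length(coefs))
    note <- paste0(note, "; ", length(coefs) - nOK,
                   " constant curve(s) gave undefined coefficients and were dropped")
  new("CorrelationDistribution", coef = coefs, method = method,
      s = if (method == "dcca") as.numeric(s) else NA_real_,
      mean = mean(coefs, na.rm = TRUE),
      se = sd(coefs, na.rm = TRUE) / sqrt(nOK),
      t = unname(tt$statistic), p = tt$p.value, note = note)
}
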