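# Drought indices: Thornthwaite PET, SPEI, hydrological-year precipitation,
# extreme-year classification.

check_climate <- function(climate) {
  need <- c("year", "month", "tmean", "precip")
  miss <- setdiff(need, names(climate))
  if (length(miss)) stop("climate is missing columns: ", paste(miss, collapse = ", "))
  if (any(climate$precip < 0, na.rm = TRUE)) stop("precipitation must be >= 0")
  if (any(!climate$month %in% 1:12)) stop("month must be in 1..12")
  climate[order(climate$year, climate$month), ]
}

# mid-month day length (hours) from latitude via standard solar declination
day_length_hours <- function(month, latitude) {
  jday <- c(15, 45, 74, 105, 135, 166, 196, 227, 258, 288, 319, 349)[month]
  decl <- 0.409 * sin(2 * pi * jday / 365 - 1.39)
  phi <- latitude * pi / 180
  x <- pmin(1, pmax(-1, -tan(phi) * tan(decl)))
  24 * acos(x) / pi
}

#' Thornthwaite potential evapotranspiration
#'
#' Monthly PET (mm) from mean monthly temperature only, using the
#' Thornthwaite heat-index formulation with a day-length correction by
#' latitude and month. Months with tmean <= 0 degC get PET = 0 by
#' convention. The annual heat index is computed from the long-term monthly
#' normals of the supplied series.
#'
#' @param climate data.frame with columns `year`, `month`, `tmean` (degC),
#'   `precip` (mm); every year used must have all 12 months.
#' @param latitude Site latitude in degrees, within \[-60, 60\].
#' @return `climate` with an added `pet` column (mm/month).
#' @export
thornthwaite_pet <- function(climate, latitude) {
  climate <- check_climate(climate)
  if (latitude < -60 || latitude > 60)
    stop("latitude must be in [-60, 60] degrees")
  cnt <- table(climate$year)
  bad <- names(cnt)[cnt != 12L]
  if (length(bad))
    stop("incomplete years (need all 12 months): ", paste(bad, collapse = ", "))
  # heat index from monthly normals
  normals <- tapply(climate$tmean, climate$month, mean)
  I <- sum(pmax(normals, 0)[pmax(normals, 0) > 0]^1.514 / 5^1.514)
  if (I <= 0) stop("annual heat index is zero: all monthly normals <= 0 degC")
  aa <- 6.75e-7 * I^3 - 7.71e-5 * I^2 + 1.792e-2 * I + 0.49239
  ndays <- c(31, 28.25, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
  K <- day_length_hours(climate$month, latitude) / 12 * ndays[climate$month] / 30
  pet <- ifelse(climate$tmean > 0,
                16 * K * (10 * climate$tmean / I)^aa,
                0)
  climate$pet <- pet
  climate
}

# unbiased probability-weighted moments b0, b1, b2
pwm_unbiased <- function(x) {
  x <- sort(x)
  n <- length(x)
  i <- seq_len(n)
  c(b0 = mean(x),
    b1 = sum((i - 1) / (n - 1) * x) / n,
    b2 = sum((i - 1) * (i - 2) / ((n - 1) * (n - 2)) * x) / n)
}

# 3-parameter log-logistic (generalized logistic, Hosking parameterisation)
# fitted from the unbiased PWMs via L-moments
loglogistic_pwm <- function(x) {
  b <- pwm_unbiased(x)
  l1 <- b[["b0"]]
  l2 <- 2 * b[["b1"]] - b[["b0"]]
  l3 <- 6 * b[["b2"]] - 6 * b[["b1"]] + b[["b0"]]
  k <- -l3 / l2
  if (abs(k) < 1e-8) k <- 1e-8
  alpha <- l2 * sin(k * pi) / (k * pi)
  xi <- l1 - alpha * (1 / k - pi / sin(k * pi))
  c(xi = xi, alpha = alpha, kappa = k)
}

loglogistic_cdf <- function(x, par) {
  k <- par[["kappa"]]; a <- par[["alpha"]]; xi <- par[["xi"]]
  arg <- 1 - k * (x - xi) / a
  y <- ifelse(arg > 0, -log(arg) / k, if (k > 0) Inf else -Inf)
  1 / (1 + exp(-y))
}

#' Standardised Precipitation-Evapotranspiration Index
#'
#' Multiscalar drought index from the climatic water balance D = precip -
#' PET. D is summed over backward windows of `scale` months; for each
#' calendar month a 3-parameter log-logistic distribution is fitted to the
#' calibration-period window sums by unbiased probability-weighted moments,
#' and the index is the standard-normal quantile of the fitted CDF
#' (probabilities clamped to \[1e-6, 1 - 1e-6\]).
#'
#' @param climate data.frame with `year`, `month`, `tmean`, `precip`.
#' @param scale Window length in months (3, 6 or 12 typical).
#' @param latitude Site latitude (degrees) for PET.
#' @param calibration Optional year range `c(first, last)` used for fitting;
#'   defaults to all years with a complete window.
#' @return data.frame `year`, `month`, `spei` with attributes `scale` and
#'   `calibration`.
#' @export
spei <- function(climate, scale, latitude, calibration = NULL) {
  stopifnot(length(scale) == 1, scale >= 1)
  climate <- thornthwaite_pet(climate, latitude)
  if (length(unique(climate$year)) < scale / 12 + 30)
    stop("series too short to fit the index distribution")
  D <- climate$precip - climate$pet
  wsum <- zoo::rollsumr(D, k = scale, fill = NA)
  out <- data.frame(year = climate$year, month = climate$month, spei = NA_real_)
  if (is.null(calibration)) calibration <- range(climate$year)
  calib <- out$year >= calibration[1] & out$year <= calibration[2]
  for (m in 1:12) {
    idx <- which(out$month == m & !is.na(wsum))
    fit_idx <- idx[calib[idx]]
    x <- wsum[fit_idx]
    if (length(unique(x)) < 4 || stats::sd(x) < 1e-10)
      stop("degenerate water-balance distribution for calendar month ", m)
    par <- loglogistic_pwm(x)
    p <- loglogistic_cdf(wsum[idx], par)
    p <- pmin(pmax(p, 1e-6), 1 - 1e-6)
    out$spei[idx] <- stats::qnorm(p)
  }
  attr(out, "scale") <- scale
  attr(out, "calibration") <- calibration
  out
}

#' Hydrological-year precipitation
#'
#' Sums monthly precipitation from the previous September through the
#' current August; the sum is assigned to the August year. Years without a
#' complete 12-month window are omitted with a warning.
#'
#' @param climate data.frame with `year`, `month`, `precip`.
#' @return data.frame `year`, `precip` (mm per hydrological year).
#' @export
hydro_year_precip <- function(climate) {
  climate <- check_climate(climate)
  hy <- ifelse(climate$month >= 9, climate$year + 1L, climate$year)
  years <- sort(unique(hy))
  res <- lapply(years, function(y) {
    sub <- climate[hy == y, ]
    if (nrow(sub) != 12L) return(NULL)
    data.frame(year = y, precip = sum(sub$precip))
  })
  dropped <- years[vapply(res, is.null, logical(1))]
  if (length(dropped))
    warning("incomplete hydrological years omitted: ",
            paste(dropped, collapse = ", "))
  do.call(rbind, res[!vapply(res, is.null, logical(1))])
}

#' Classify dry, wet and average years from a drought index
#'
#' Takes the index values of one calendar month (default August) across
#' years and returns the `n` driest (lowest), `n` wettest (highest) and `n`
#' average years (smallest absolute value, excluding years already
#' classified dry or wet). Ties are broken by the earlier year.
#'
#' @param index data.frame from [spei()] (columns `year`, `month`, value
#'   column `spei`).
#' @param n Number of years per class, > 0.
#' @param month Calendar month whose values are ranked (default 8, August).
#' @return list with integer vectors `dry`, `wet`, `average` (sorted), and
#'   the ranked table as attribute `table`.
#' @export
classify_extreme_years <- function(index, n = 6, month = 8) {
  if (n <= 0) stop("n must be positive")
  sub <- index[index$month == month & !is.na(index$spei), ]
  if (nrow(sub) < 3 * n)
    stop("need at least 3n = ", 3 * n, " years with index values, have ",
         nrow(sub))
  dry <- sub$year[order(sub$spei, sub$year)][seq_len(n)]
  wet <- sub$year[order(-sub$spei, sub$year)][seq_len(n)]
  rest <- sub[!sub$year %in% c(dry, wet), ]
  avg <- rest$year[order(abs(rest$spei), rest$year)][seq_len(n)]
  out <- list(dry = sort(dry), wet = sort(wet), average = sort(avg))
  attr(out, "table") <- sub[order(sub$spei), c("year", "spei")]
  out
}
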