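# Basal area increments, chronologies, climate correlations and drought
# resilience indices.

#' Basal area increment series from ring widths
#'
#' Measured widths are proportionally rescaled so their cumulative sum
#' equals the bark-corrected radius `dbh/2 - bark` (single-core
#' approximation), then converted to annual basal area increments
#' `BAI_t = pi * (R_t^2 - R_{t-1}^2)` with radii in cm.
#'
#' @param rings data.frame for one tree: columns `tree_id`, `year`
#'   (consecutive), `width_mm` (>= 0), plus scalar metadata `dbh` (cm) and
#'   `bark` (cm) either as columns or via the `dbh`/`bark` arguments.
#' @param dbh,bark Optional scalar overrides (cm).
#' @return data.frame `tree_id`, `year`, `bai` (cm2/year), `radius` (cm,
#'   at end of each year).
#' @export
bai_series <- function(rings, dbh = NULL, bark = NULL) {
  stopifnot(all(c("tree_id", "year", "width_mm") %in% names(rings)))
  rings <- rings[order(rings$year), ]
  if (any(diff(rings$year) != 1))
    stop("years must be consecutive for tree ", rings$tree_id[1])
  if (any(rings$width_mm < 0)) stop("widths must be >= 0")
  if (is.null(dbh)) dbh <- rings$dbh[1]
  if (is.null(bark)) bark <- rings$bark[1]
  if (is.null(dbh) || is.null(bark)) stop("dbh and bark required")
  target <- dbh / 2 - bark
  if (target <= 0) stop("dbh/2 must exceed bark thickness")
  w_cm <- rings$width_mm / 10
  if (sum(w_cm) <= 0) stop("all ring widths are zero")
  w_cm <- w_cm * target / sum(w_cm)
  radius <- cumsum(w_cm)
  bai <- pi * (radius^2 - c(0, radius[-length(radius)])^2)
  data.frame(tree_id = rings$tree_id[1], year = rings$year, bai = bai,
             radius = radius)
}

#' Mean chronology with confidence band
#'
#' Aligns per-tree annual trait series by year and returns the per-year mean
#' with a `+/- 1.96 SEM` band over the trees present that year. Years with a
#' single tree get band width zero and are flagged.
#'
#' @param series data.frame with columns `tree_id`, `year`, and a value
#'   column named by `value`.
#' @param value Name of the value column (default "value").
#' @return data.frame `year`, `mean`, `sem`, `lower`, `upper`, `n`,
#'   `single_tree` (logical flag).
#' @export
chronology <- function(series, value = "value") {
  stopifnot(all(c("tree_id", "year", value) %in% names(series)))
  v <- series[[value]]
  years <- sort(unique(series$year))
  out <- do.call(rbind, lapply(years, function(y) {
    x <- v[series$year == y & !is.na(v)]
    n <- length(x)
    sem <- if (n > 1) stats::sd(x) / sqrt(n) else 0
    data.frame(year = y, mean = mean(x), sem = sem,
               lower = mean(x) - 1.96 * sem, upper = mean(x) + 1.96 * sem,
               n = n, single_tree = n == 1L)
  }))
  rownames(out) <- NULL
  out
}

#' Monthly climate-trait correlations over the dendro window
#'
#' Pearson correlations between an annual trait series and monthly climate
#' variables from October of the previous year through September of the
#' current year (12 window months labelled pOct..Sep). Significance is
#' assessed by a bootstrap percentile interval (resampling years in pairs)
#' excluding zero.
#'
#' @param trait data.frame `year`, `value`.
#' @param climate data.frame `year`, `month`, plus climate variable columns.
#' @param variables Character vector of climate columns to correlate
#'   (default `c("tmean", "precip")`).
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Seed for the bootstrap.
#' @param conf Confidence level (default 0.95).
#' @return data.frame `variable`, `window_month` (pOct..Sep), `r`, `lower`,
#'   `upper`, `significant`.
#' @export
climate_correlations <- function(trait, climate, variables = c("tmean", "precip"),
                                 n_boot = 1000, seed = 1, conf = 0.95) {
  stopifnot(all(c("year", "value") %in% names(trait)))
  months <- c(10:12, 1:9)
  labels <- c("pOct", "pNov", "pDec", "Jan", "Feb", "Mar", "Apr", "May",
              "Jun", "Jul", "Aug", "Sep")
  prev <- months >= 10
  res <- list()
  withr::with_seed(seed, {
    for (v in variables) {
      if (!v %in% names(climate)) stop("climate variable not found: ", v)
      for (k in seq_along(months)) {
        m <- months[k]
        cy <- if (prev[k]) climate$year + 1L else climate$year
        sub <- climate[climate$month == m, ]
        suby <- if (prev[k]) sub$year + 1L else sub$year
        idx <- match(trait$year, suby)
        ok <- !is.na(idx) & !is.na(trait$value)
        x <- trait$value[ok]
        y <- sub[[v]][idx[ok]]
        if (length(x) < 15)
          stop("fewer than 15 overlapping years for ", v, " ", labels[k])
        r <- stats::cor(x, y)
        bs <- replicate(n_boot, {
          i <- sample.int(length(x), replace = TRUE)
          suppressWarnings(stats::cor(x[i], y[i]))
        })
        qs <- stats::quantile(bs, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                              na.rm = TRUE)
        res[[length(res) + 1L]] <- data.frame(
          variable = v, window_month = labels[k], r = r,
          lower = qs[1], upper = qs[2],
          significant = qs[1] > 0 | qs[2] < 0)
      }
    }
  })
  out <- do.call(rbind, res)
  out$window_month <- factor(out$window_month, levels = labels)
  rownames(out) <- NULL
  out
}

#' Drought resistance, recovery and resilience indices
#'
#' Event-based ratios for an annual trait around a drought year: resistance
#' = Dr/PreDr, recovery = PostDr/Dr, resilience = PostDr/PreDr, where Dr is
#' the trait in the event year and PreDr/PostDr are means over the `window`
#' years before/after the event. The recovery period is the smallest m >= 1
#' with trait(event + m) >= PreDr, censored at the series end.
#'
#' @param trait data.frame `year`, `value` (annual series).
#' @param event_year Drought year (must be in the series).
#' @param window Pre/post window length in years (default 3).
#' @return one-row data.frame: `event_year`, `resistance`, `recovery`,
#'   `resilience`, `recovery_period`, `censored`.
#' @export
resilience <- function(trait, event_year, window = 3) {
  stopifnot(all(c("year", "value") %in% names(trait)))
  trait <- trait[order(trait$year), ]
  if (!event_year %in% trait$year) stop("event year not in series")
  val <- function(y) trait$value[match(y, trait$year)]
  pre_years <- (event_year - window):(event_year - 1)
  post_years <- (event_year + 1):(event_year + window)
  pre <- val(pre_years); post <- val(post_years)
  if (all(is.na(pre))) stop("no pre-event years available")
  pre_m <- mean(pre, na.rm = TRUE)
  post_m <- mean(post, na.rm = TRUE)
  dr <- val(event_year)
  if (is.na(pre_m) || pre_m == 0) stop("pre-drought mean is zero; ratios undefined")
  after <- trait[trait$year > event_year, ]
  hit <- which(after$value >= pre_m)
  censored <- length(hit) == 0L
  rp <- if (censored) NA_integer_ else as.integer(after$year[hit[1]] - event_year)
  data.frame(event_year = event_year,
             resistance = dr / pre_m,
             recovery = post_m / dr,
             resilience = post_m / pre_m,
             recovery_period = rp,
             censored = censored)
}
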