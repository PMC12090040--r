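# Seeded synthetic study generator: atmosphere, climate, tree populations,
# ring widths, cell tables and isotope series with known ground truth.
#
# The default scenario emulates a 39-year (1978-2016) multi-proxy study of
# three co-occurring Mediterranean conifers (a drought-sensitive pine with
# healthy/declining/dead individuals, a second pine with healthy/dead, and
# a healthy juniper), with planted extreme-drought years and a post-drought
# growth-decline divergence in non-healthy pines.

SPECIES <- c("pinaster", "pinea", "oxycedrus")
STATUSES <- c("healthy", "declining", "dead")

#' Atmospheric CO2 and delta13C-of-air scenario
#'
#' Smooth monotone interpolation between endpoint values: exponential in
#' time for CO2 (optionally through interior anchor points, piecewise
#' exponential), linear for air delta13C. Endpoints are matched exactly.
#'
#' @param years Integer vector of consecutive calendar years.
#' @param ca_endpoints Length-2 CO2 endpoints (ppm) for the first and last
#'   year.
#' @param d13c_endpoints Length-2 air delta13C endpoints (per mil).
#' @param ca_anchors Optional data.frame `year`, `ca` of interior anchor
#'   points the CO2 trajectory must pass through.
#' @return data.frame `year`, `ca`, `d13c_air`.
#' @export
generate_atmosphere <- function(years = 1978:2016,
                                ca_endpoints = c(335, 404),
                                d13c_endpoints = c(-7.4, -8.4),
                                ca_anchors = NULL) {
  if (!length(years)) stop("years must be non-empty")
  if (any(diff(years) <= 0)) stop("years must be strictly increasing")
  if (any(!is.finite(c(ca_endpoints, d13c_endpoints))))
    stop("endpoints must be finite")
  if (any(ca_endpoints <= 0)) stop("CO2 endpoints must be positive")
  n <- length(years)
  if (n == 1)
    return(data.frame(year = years, ca = ca_endpoints[1],
                      d13c_air = d13c_endpoints[1]))
  knots <- data.frame(year = c(years[1], years[n]),
                      ca = c(ca_endpoints[1], ca_endpoints[2]))
  if (!is.null(ca_anchors)) {
    stopifnot(all(c("year", "ca") %in% names(ca_anchors)))
    knots <- rbind(knots, ca_anchors[c("year", "ca")])
    knots <- knots[order(knots$year), ]
    if (any(diff(knots$ca) < 0)) stop("anchors must keep CO2 non-decreasing")
  }
  # exponential in time = linear interpolation of log(ca); knot values
  # matched exactly (no round-off through the log)
  ca <- exp(stats::approx(knots$year, log(knots$ca), xout = years)$y)
  hit <- match(knots$year, years)
  ca[hit[!is.na(hit)]] <- knots$ca[!is.na(hit)]
  d13c <- d13c_endpoints[1] +
    (d13c_endpoints[2] - d13c_endpoints[1]) * (years - years[1]) / (years[n] - years[1])
  data.frame(year = years, ca = ca, d13c_air = d13c)
}

#' Synthetic monthly climate with planted drought years
#'
#' Monthly temperature and precipitation built from 12 monthly means plus a
#' linear warming trend and noise (Gaussian for temperature, lognormal
#' multiplicative for precipitation so it stays positive). In planted
#' drought years, precipitation over the hydrological window (previous
#' September through current August) is scaled by `drought_factor`.
#'
#' @param years Integer year vector.
#' @param tmean_monthly,precip_monthly Length-12 monthly normals (degC,
#'   mm); defaults emulate a continental Mediterranean site (~12.3 degC,
#'   ~530 mm/yr, summer drought).
#' @param trend Warming trend in degC per decade (default 0.25).
#' @param drought_years Years whose hydrological window is dried.
#' @param drought_factor Multiplier in (0, 1] on window precipitation.
#' @param t_sd Temperature noise sd (degC).
#' @param p_sdlog Precipitation lognormal noise sdlog.
#' @param latitude Site latitude (degrees), carried as an attribute.
#' @param seed RNG seed; same seed, same series.
#' @return data.frame `year`, `month`, `tmean`, `precip` with attribute
#'   `latitude`.
#' @export
generate_climate <- function(years,
                             tmean_monthly = c(4, 5, 7.5, 9.5, 13.5, 18.5,
                                               22, 21.5, 18, 12.5, 7.5, 4.5),
                             precip_monthly = c(60, 55, 45, 55, 55, 30,
                                                12, 15, 35, 60, 70, 65),
                             trend = 0.25,
                             drought_years = integer(),
                             drought_factor = 0.4,
                             t_sd = 1.2, p_sdlog = 0.35,
                             latitude = 40.5, seed = 1) {
  stopifnot(length(tmean_monthly) == 12, length(precip_monthly) == 12)
  if (any(precip_monthly <= 0)) stop("monthly precipitation means must be positive")
  if (drought_factor <= 0 || drought_factor > 1)
    stop("drought_factor must be in (0, 1]")
  grid <- expand.grid(month = 1:12, year = years)[, c("year", "month")]
  withr::with_seed(seed, {
    tnoise <- stats::rnorm(nrow(grid), 0, t_sd)
    pnoise <- stats::rlnorm(nrow(grid), -p_sdlog^2 / 2, p_sdlog)
  })
  decade <- (grid$year - years[1]) / 10
  tmean <- tmean_monthly[grid$month] + trend * decade + tnoise
  precip <- precip_monthly[grid$month] * pnoise
  # hydrological window Sep(prev)..Aug of each planted drought year
  hy <- ifelse(grid$month >= 9, grid$year + 1L, grid$year)
  precip[hy %in% drought_years] <- precip[hy %in% drought_years] * drought_factor
  out <- data.frame(year = grid$year, month = grid$month,
                    tmean = tmean, precip = precip)
  attr(out, "latitude") <- latitude
  out
}

#' Ground-truth parameters of the synthetic study
#'
#' Encodes the scenario the generators emulate: species decline years,
#' planted drought years, a per-(species, status) true iWUE response
#' surface (piecewise linear in CO2 with a 360 ppm breakpoint plus a linear
#' drought term), baseline anatomy profiles and drought multipliers, ring
#' width parameters, and per-trait noise levels.
#'
#' True iWUE (micromol/mol):
#' `iwue_true = base + s_lo * (min(ca, brk) - 335) + s_hi * max(ca - brk, 0) - d_sens * spei`.
#'
#' @param noise List of noise parameters; set elements to 0 for noiseless
#'   generation. Defaults: delta13C additive Gaussian sd 0.15 per mil; ring
#'   width and lumen area lognormal (sdlog 0.15 / 0.25); wall thickness
#'   lognormal (sdlog 0.12).
#' @return list of class `synthetic_truth`.
#' @export
default_truth <- function(noise = list(d13c = 0.15, width_sdlog = 0.15,
                                       la_sdlog = 0.25, cwt_sdlog = 0.12)) {
  iw <- function(base, s_lo, s_hi, d_sens, brk = 360)
    list(base = base, s_lo = s_lo, s_hi = s_hi, d_sens = d_sens, brk = brk)
  an <- function(la_ew, la_lw, cwt_ew, cwt_lw, cells_per_mm, width_mm,
                 la_drought_mult = 0.6, cwt_drought_mult = 1.05,
                 width_drought_mult = 0.55, decline_rate = 0)
    list(la_ew = la_ew, la_lw = la_lw, cwt_ew = cwt_ew, cwt_lw = cwt_lw,
         cells_per_mm = cells_per_mm, width_mm = width_mm,
         la_drought_mult = la_drought_mult,
         cwt_drought_mult = cwt_drought_mult,
         width_drought_mult = width_drought_mult,
         decline_rate = decline_rate)
  truth <- list(
    decline_year_by_species = c(pinaster = 1995, pinea = 2005, oxycedrus = NA),
    drought_years = c(1986, 1989, 1995, 1999, 2005, 2012),
    iwue_response = list(
      pinaster.healthy   = iw(70, 0.896, 0.105, 4),
      pinaster.declining = iw(70, 0.392, 0.010, 2),
      pinaster.dead      = iw(70, 0.588, 0.010, 2),
      pinea.healthy      = iw(70, 0.700, 0.200, 4),
      pinea.dead         = iw(70, 1.064, 0.330, 4),
      oxycedrus.healthy  = iw(90, 0.377, 0.377, 2)
    ),
    anatomy_effects = list(
      pinaster.healthy   = an(950, 150, 2.5, 6.0, 8, 2.0),
      pinaster.declining = an(800, 140, 2.4, 5.2, 8, 1.9, decline_rate = 0.04),
      pinaster.dead      = an(750, 130, 2.3, 4.8, 8, 1.9, decline_rate = 0.07),
      pinea.healthy      = an(900, 150, 2.5, 5.5, 8, 2.0),
      pinea.dead         = an(900, 150, 2.4, 5.3, 8, 2.0, decline_rate = 0.07),
      oxycedrus.healthy  = an(180, 60, 2.2, 4.5, 40, 1.0)
    ),
    noise = noise
  )
  class(truth) <- "synthetic_truth"
  truth
}

truth_key <- function(species, status) paste(species, status, sep = ".")

#' Evaluate the true iWUE response surface
#'
#' @param truth A `synthetic_truth` object.
#' @param species,status Group identifiers.
#' @param ca CO2 (ppm).
#' @param spei August 12-month drought index values (same length as `ca` or
#'   scalar).
#' @return True iWUE (micromol/mol).
#' @export
iwue_true <- function(truth, species, status, ca, spei = 0) {
  p <- truth$iwue_response[[truth_key(species, status)]]
  if (is.null(p)) stop("no iWUE truth for ", species, " ", status)
  p$base + p$s_lo * (pmin(ca, p$brk) - 335) + p$s_hi * pmax(ca - p$brk, 0) -
    p$d_sens * spei
}

#' Generate a synthetic tree population
#'
#' Draws tree metadata around the study design: diameter, height and age
#' from per-group normals, plus ordinal mistletoe and defoliation scores.
#' Declining status exists only for the mistletoe-infected pine
#' ("pinaster"); "pinea" never carries mistletoe; dead trees are fully
#' defoliated (score 4).
#'
#' @param design data.frame `species`, `status`, `n` (counts >= 0).
#'   Default: 5 trees per the six species-status combinations (30 trees).
#' @param seed RNG seed.
#' @return data.frame of tree metadata.
#' @export
generate_population <- function(design = default_design(), seed = 1) {
  stopifnot(all(c("species", "status", "n") %in% names(design)))
  if (any(design$n < 0)) stop("counts must be >= 0")
  bad <- design$species != "pinaster" & design$status == "declining" & design$n > 0
  if (any(bad)) stop("declining status is only defined for pinaster")
  if (any(!design$species %in% SPECIES))
    stop("unknown species in design")
  # per-group metadata distributions (means, sd)
  meta <- list(
    pinaster.healthy   = list(dbh = c(54.2, 11.8), height = c(18.9, 4.5), age = c(83, 26), mist = 0:2, defol = 1),
    pinaster.declining = list(dbh = c(45.6, 3.9), height = c(16.8, 3.8), age = c(108, 47), mist = 0:3, defol = 2:3),
    pinaster.dead      = list(dbh = c(36.5, 6.1), height = c(12.2, 1.2), age = c(62, 5), mist = 0:4, defol = 4),
    pinea.healthy      = list(dbh = c(65.5, 9.2), height = c(15.2, 4.1), age = c(156, 39), mist = 0, defol = 0:1),
    pinea.dead         = list(dbh = c(64.3, 11.7), height = c(14.1, 2.8), age = c(114, 18), mist = 0, defol = 4),
    oxycedrus.healthy  = list(dbh = c(24.4, 6.7), height = c(7.8, 0.3), age = c(74, 25), mist = 0, defol = 0)
  )
  rows <- list()
  withr::with_seed(seed, {
    for (i in seq_len(nrow(design))) {
      k <- truth_key(design$species[i], design$status[i])
      m <- meta[[k]]
      if (is.null(m)) stop("no metadata model for ", k)
      n <- design$n[i]
      if (n == 0) next
      dbh <- pmax(10, stats::rnorm(n, m$dbh[1], m$dbh[2]))
      rows[[length(rows) + 1L]] <- data.frame(
        tree_id = sprintf("%s_%s_%02d", design$species[i],
                          design$status[i], seq_len(n)),
        species = design$species[i], status = design$status[i],
        dbh = dbh,
        bark = pmax(0.5, 0.04 * dbh),
        height = pmax(2, stats::rnorm(n, m$height[1], m$height[2])),
        age = pmax(40, round(stats::rnorm(n, m$age[1], m$age[2]))),
        mistletoe = if (length(m$mist) == 1) rep(m$mist, n)
                    else sample(m$mist, n, replace = TRUE),
        defoliation = if (length(m$defol) == 1) rep(m$defol, n)
                      else sample(m$defol, n, replace = TRUE)
      )
    }
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(tree_id = character(), species = character(),
               status = character(), dbh = numeric(), bark = numeric(),
               height = numeric(), age = numeric(), mistletoe = numeric(),
               defoliation = numeric())
  rownames(out) <- NULL
  out
}

#' Default study design: 5 trees per species-status combination
#' @return data.frame `species`, `status`, `n`.
#' @export
default_design <- function() {
  data.frame(
    species = c("pinaster", "pinaster", "pinaster", "pinea", "pinea", "oxycedrus"),
    status = c("healthy", "declining", "dead", "healthy", "dead", "healthy"),
    n = 5L
  )
}

#' Generate a ring-width series for one tree
#'
#' Widths start from the group baseline, respond negatively to planted
#' drought years (multiplicative `width_drought_mult`), carry lognormal
#' noise, and for non-healthy trees decay geometrically (rate per year)
#' after the species decline year. Widths are rescaled so the cumulative
#' radius equals `dbh/2 - bark`.
#'
#' @param tree One row of the population data.frame.
#' @param years Year vector (default 1978:2016).
#' @param truth `synthetic_truth` object.
#' @param seed RNG seed.
#' @return data.frame `tree_id`, `year`, `width_mm`, `dbh`, `bark` plus
#'   columns `species`, `status`.
#' @export
generate_ring_series <- function(tree, years = 1978:2016,
                                 truth = default_truth(), seed = 1) {
  p <- truth$anatomy_effects[[truth_key(tree$species, tree$status)]]
  if (is.null(p)) stop("species/status not present in truth")
  n <- length(years)
  base <- rep(p$width_mm, n)
  base[years %in% truth$drought_years] <-
    base[years %in% truth$drought_years] * p$width_drought_mult
  dy <- truth$decline_year_by_species[[tree$species]]
  if (!is.na(dy) && p$decline_rate > 0) {
    post <- years > dy
    base[post] <- base[post] * (1 - p$decline_rate)^(years[post] - dy)
  }
  sdl <- truth$noise$width_sdlog
  withr::with_seed(seed, {
    noise <- if (sdl > 0) stats::rlnorm(n, -sdl^2 / 2, sdl) else rep(1, n)
  })
  w <- base * noise
  # rescale so the reconstructed radius matches the bark-corrected dbh
  target_mm <- (tree$dbh / 2 - tree$bark) * 10
  w <- w * target_mm / sum(w)
  data.frame(tree_id = tree$tree_id, year = years, width_mm = w,
             dbh = tree$dbh, bark = tree$bark,
             species = tree$species, status = tree$status)
}

#' Generate the cell table for one annual ring
#'
#' Lays tracheids on radial files. Along the relative position x in \[0,1\]
#' lumen area decreases and wall thickness increases following a logistic
#' earlywood-to-latewood transition; in planted drought years LA over the
#' first 75% of the ring is scaled by the drought multiplier (and CWT
#' slightly raised). Cell count per file is proportional to ring width.
#'
#' @param ring One row of a ring series (needs `tree_id`, `year`,
#'   `width_mm`, `species`, `status`).
#' @param truth `synthetic_truth`.
#' @param n_files Number of radial files laid out (default 18).
#' @param drought Logical; is this ring from a planted drought year? If
#'   NULL, taken from `truth$drought_years`.
#' @param seed RNG seed.
#' @return Cell table data.frame: `tree_id`, `year`, `cell_id`, `file_id`,
#'   `position`, `la`, `ld`, `cwt_r1`, `cwt_r2`, `cwt_t1`, `cwt_t2`.
#' @export
generate_cell_table <- function(ring, truth = default_truth(), n_files = 18,
                                drought = NULL, seed = 1) {
  if (ring$width_mm <= 0) stop("ring width must be positive")
  p <- truth$anatomy_effects[[truth_key(ring$species, ring$status)]]
  if (is.null(p)) stop("species/status not present in truth")
  if (is.null(drought)) drought <- ring$year %in% truth$drought_years
  n_per_file <- max(3L, round(p$cells_per_mm * ring$width_mm))
  n <- n_per_file * n_files
  file_id <- rep(seq_len(n_files), each = n_per_file)
  within <- rep(seq_len(n_per_file), times = n_files)
  pos <- (within - 0.5) / n_per_file
  trans <- stats::plogis((pos - 0.8) / 0.05)
  la <- p$la_lw + (p$la_ew - p$la_lw) * (1 - trans)
  cwt <- p$cwt_ew + (p$cwt_lw - p$cwt_ew) * trans
  if (drought) {
    ew_part <- pos <= 0.75
    la[ew_part] <- la[ew_part] * p$la_drought_mult
    cwt[ew_part] <- cwt[ew_part] * p$cwt_drought_mult
  }
  withr::with_seed(seed, {
    if (truth$noise$la_sdlog > 0)
      la <- la * stats::rlnorm(n, -truth$noise$la_sdlog^2 / 2,
                               truth$noise$la_sdlog)
    wob <- function() if (truth$noise$cwt_sdlog > 0) {
      cwt * stats::rlnorm(n, -truth$noise$cwt_sdlog^2 / 2,
                          truth$noise$cwt_sdlog) *
        stats::runif(n, 0.95, 1.05)
    } else cwt
    out <- data.frame(tree_id = ring$tree_id, year = ring$year,
                      cell_id = paste0(file_id, "_", within),
                      file_id = file_id, position = pos,
                      la = la, ld = 2 * sqrt(la / pi),
                      cwt_r1 = wob(), cwt_r2 = wob(),
                      cwt_t1 = wob(), cwt_t2 = wob())
  })
  rownames(out) <- NULL
  out
}

#' Generate a tree-ring isotope series with known iWUE truth
#'
#' Inverts the discrimination chain exactly: from `iwue_true(ca, spei)` the
#' implied discrimination and tree delta13C are computed per year, Gaussian
#' measurement noise is added to delta13C, and (optionally) consecutive
#' k-year blocks are pooled into single records holding the block-mean
#' delta (equal ring mass assumed). A noiseless series therefore
#' round-trips through [iwue_series()] to the truth.
#'
#' @param tree One row of the population data.frame.
#' @param atm Atmosphere data.frame covering the years.
#' @param spei_aug12 data.frame `year`, `spei` (August 12-month index used
#'   by the truth surface). Missing years are treated as 0 (climatology).
#' @param truth `synthetic_truth`.
#' @param pool_every Integer block length for pooling, or NULL for annual
#'   records. Trailing years that do not fill a block are emitted as
#'   single-year records.
#' @param seed RNG seed.
#' @return data.frame `tree_id`, `year_start`, `year_end`, `d13c_tree`.
#' @export
generate_isotope_series <- function(tree, atm, spei_aug12 = NULL,
                                    truth = default_truth(),
                                    pool_every = NULL, seed = 1) {
  years <- atm$year
  sp <- if (is.null(spei_aug12)) rep(0, length(years)) else {
    v <- spei_aug12$spei[match(years, spei_aug12$year)]
    ifelse(is.na(v), 0, v)
  }
  w_true <- iwue_true(truth, tree$species, tree$status, atm$ca, sp)
  if (any(w_true <= 0 | w_true >= atm$ca / 1.6))
    stop("true iWUE outside (0, ca/1.6): unphysical generation scenario")
  delta <- iwue_to_delta(w_true, atm$ca)
  d13c <- big_delta_inverse(delta, atm$d13c_air)
  withr::with_seed(seed, {
    if (truth$noise$d13c > 0)
      d13c <- d13c + stats::rnorm(length(d13c), 0, truth$noise$d13c)
  })
  if (is.null(pool_every) || pool_every <= 1) {
    out <- data.frame(tree_id = tree$tree_id, year_start = years,
                      year_end = years, d13c_tree = d13c)
  } else {
    n_full <- floor(length(years) / pool_every)
    blocks <- list()
    for (b in seq_len(n_full)) {
      idx <- ((b - 1) * pool_every + 1):(b * pool_every)
      blocks[[b]] <- data.frame(
        tree_id = tree$tree_id, year_start = years[idx[1]],
        year_end = years[idx[length(idx)]], d13c_tree = mean(d13c[idx]))
    }
    rest <- seq_len(length(years)) > n_full * pool_every
    if (any(rest))
      blocks[[length(blocks) + 1L]] <- data.frame(
        tree_id = tree$tree_id, year_start = years[rest],
        year_end = years[rest], d13c_tree = d13c[rest])
    out <- do.call(rbind, blocks)
  }
  rownames(out) <- NULL
  out
}
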