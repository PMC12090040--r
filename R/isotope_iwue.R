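# Carbon isotope chain: VPDB delta, discrimination, intercellular CO2, iWUE.

#' Delta notation relative to a standard
#'
#' Expresses an isotope ratio relative to a reference standard (for carbon,
#' Vienna Pee Dee Belemnite) in per mil.
#'
#' @param r_sample Isotope ratio (13C/12C) of the sample. Must be > 0.
#' @param r_standard Isotope ratio of the standard. Must be > 0.
#' @return delta value in per mil: `(r_sample / r_standard - 1) * 1000`.
#' @seealso [delta_to_ratio()] for the inverse.
#' @export
#' @examples
#' delta_vpdb(0.0110, 0.0112)
delta_vpdb <- function(r_sample, r_standard) {
  if (any(!is.finite(r_sample)) || any(!is.finite(r_standard)))
    stop("isotope ratios must be finite")
  if (any(r_sample <= 0) || any(r_standard <= 0))
    stop("isotope ratios must be positive")
  (r_sample / r_standard - 1) * 1000
}

#' Invert delta notation back to a ratio
#'
#' @param delta delta value in per mil.
#' @param r_standard Ratio of the standard (> 0).
#' @return Sample isotope ratio.
#' @export
delta_to_ratio <- function(delta, r_standard) {
  if (any(r_standard <= 0)) stop("r_standard must be positive")
  r_standard * (1 + delta / 1000)
}

#' Photosynthetic carbon isotope discrimination
#'
#' Discrimination of the plant against 13C, computed from plant and air
#' delta13C:
#' `Delta13C = (d13c_air - d13c_tree) / (1 + d13c_tree / 1000)` (per mil).
#' Strictly decreasing in `d13c_tree` at fixed `d13c_air`.
#'
#' @param d13c_tree Tree-ring delta13C (per mil VPDB). Must be > -1000.
#' @param d13c_air Atmospheric delta13C (per mil VPDB).
#' @return Discrimination Delta13C in per mil.
#' @export
#' @examples
#' big_delta(-26, -8)  # 18.4805...
big_delta <- function(d13c_tree, d13c_air) {
  if (any(d13c_tree <= -1000))
    stop("d13c_tree at or below -1000 per mil is singular/unphysical")
  (d13c_air - d13c_tree) / (1 + d13c_tree / 1000)
}

#' Invert discrimination to tree delta13C
#'
#' @param delta Discrimination Delta13C (per mil).
#' @param d13c_air Atmospheric delta13C (per mil).
#' @return Tree delta13C (per mil VPDB).
#' @export
big_delta_inverse <- function(delta, d13c_air) {
  (d13c_air - delta) / (1 + delta / 1000)
}

#' Intercellular CO2 from discrimination
#'
#' Simple (linear) discrimination model: `ci = ca * (Delta - a) / (b - a)`,
#' where `a` is the fractionation during stomatal diffusion and `b` the net
#' Rubisco carboxylation fractionation, both as positive discriminations in
#' per mil.
#'
#' @param delta Discrimination Delta13C (per mil).
#' @param ca Atmospheric CO2 mole fraction (ppm), > 0.
#' @param a Diffusion fractionation (per mil), default 4.
#' @param b Carboxylation fractionation (per mil), default 27. Must exceed `a`.
#' @return ci in ppm. Values of `delta` outside `[a, b]` yield ci outside
#'   `[0, ca]`; they are returned as-is (the caller may flag them).
#' @export
ci_from_delta <- function(delta, ca, a = 4, b = 27) {
  if (b <= a) stop("b must exceed a")
  if (any(ca <= 0)) stop("ca must be positive")
  ca * (delta - a) / (b - a)
}

#' Intrinsic water-use efficiency from discrimination
#'
#' The ratio of net assimilation to stomatal conductance estimated from
#' tree-ring discrimination: `iWUE = ca * (b - Delta) / (1.6 * (b - a))`
#' (micromol CO2 per mol H2O). 1.6 is the ratio of stomatal conductance for
#' water vapour to that for CO2. Identical to `(ca - ci)/1.6` with
#' [ci_from_delta()].
#'
#' @inheritParams ci_from_delta
#' @return iWUE in micromol per mol.
#' @export
#' @examples
#' iwue(18.4805, 400)  # ~92.60
iwue <- function(delta, ca, a = 4, b = 27) {
  if (b <= a) stop("b must exceed a")
  if (any(ca <= 0)) stop("ca must be positive")
  ca * (b - delta) / (1.6 * (b - a))
}

#' Invert iWUE back to discrimination
#'
#' @param w iWUE (micromol per mol).
#' @inheritParams ci_from_delta
#' @return Discrimination Delta13C (per mil).
#' @export
iwue_to_delta <- function(w, ca, a = 4, b = 27) {
  b - 1.6 * (b - a) * w / ca
}

#' Splice two atmospheric delta13C reference segments
#'
#' Concatenates an early and a late annual delta13C-of-air series into one
#' continuous reference, the early source taking precedence up to its last
#' year. Typical use: an ice-core/compilation record spliced with a modern
#' flask record. Provenance is recorded per year.
#'
#' @param early data.frame with columns `year`, `d13c_air` (the earlier
#'   source, kept in full).
#' @param late data.frame with the same columns, starting no later than one
#'   year after `early` ends.
#' @param tol Junction disagreement (per mil) above which a warning is
#'   emitted when the two sources overlap.
#' @return data.frame with columns `year`, `d13c_air`, `source`
#'   ("early"/"late").
#' @export
splice_air_reference <- function(early, late, tol = 0.3) {
  for (d in list(early, late))
    stopifnot(is.data.frame(d), all(c("year", "d13c_air") %in% names(d)))
  early <- early[order(early$year), ]
  late <- late[order(late$year), ]
  cut <- max(early$year)
  if (min(late$year) > cut + 1)
    stop("gap between reference segments: ", cut, " to ", min(late$year))
  ov <- intersect(early$year, late$year)
  if (length(ov)) {
    d <- abs(early$d13c_air[match(ov, early$year)] -
               late$d13c_air[match(ov, late$year)])
    if (any(d > tol))
      warning("air delta13C sources disagree by up to ",
              format(max(d), digits = 3), " per mil over the overlap")
  }
  late_part <- late[late$year > cut, ]
  out <- rbind(
    data.frame(year = early$year, d13c_air = early$d13c_air, source = "early"),
    if (nrow(late_part))
      data.frame(year = late_part$year, d13c_air = late_part$d13c_air,
                 source = "late")
  )
  rownames(out) <- NULL
  out
}

#' Expand pooled isotope records to annual weighted rows
#'
#' Isotope series may contain multi-year pooled records (e.g., rings pooled
#' every 5 years for narrow-ringed trees). Each pooled record is expanded to
#' one row per covered year with the pooled value copied and weight
#' `1 / block_length`, so each original record contributes total weight 1.
#'
#' @param iso data.frame with columns `tree_id`, `year_start`, `year_end`,
#'   `d13c_tree`.
#' @return data.frame with columns `tree_id`, `year`, `d13c_tree`, `weight`.
#' @export
pool_expand <- function(iso) {
  stopifnot(all(c("tree_id", "year_start", "year_end", "d13c_tree") %in%
                  names(iso)))
  if (any(iso$year_end < iso$year_start))
    stop("invalid pooled block: year_end < year_start")
  n <- iso$year_end - iso$year_start + 1L
  out <- data.frame(
    tree_id = rep(iso$tree_id, n),
    year = unlist(Map(seq, iso$year_start, iso$year_end), use.names = FALSE),
    d13c_tree = rep(iso$d13c_tree, n),
    weight = rep(1 / n, n)
  )
  rownames(out) <- NULL
  out
}

#' Per-year iWUE series from an isotope series and atmosphere
#'
#' Expands pooled records, matches each year to its atmospheric CO2 and
#' delta13C-of-air (pooled records are evaluated against block-mean ca and
#' air delta13C, a mass balance over the pooled wood), and applies the
#' discrimination chain to produce Delta13C, ci and iWUE per tree-year.
#'
#' @param iso Isotope series data.frame (`tree_id`, `year_start`, `year_end`,
#'   `d13c_tree`).
#' @param atm Atmosphere data.frame (`year`, `ca`, `d13c_air`) covering every
#'   record year.
#' @param a,b Discrimination constants (per mil), see [iwue()].
#' @return data.frame: `tree_id`, `year`, `delta13c`, `ci`, `iwue`, `ca`,
#'   `weight`.
#' @export
iwue_series <- function(iso, atm, a = 4, b = 27) {
  stopifnot(all(c("year", "ca", "d13c_air") %in% names(atm)))
  yrs <- unlist(Map(seq, iso$year_start, iso$year_end), use.names = FALSE)
  missing_years <- setdiff(yrs, atm$year)
  if (length(missing_years))
    stop("atmosphere does not cover years: ",
         paste(sort(unique(missing_years)), collapse = ", "))
  # block-mean atmosphere per record, copied onto each expanded year
  n <- iso$year_end - iso$year_start + 1L
  rec_ca <- mapply(function(y0, y1) mean(atm$ca[atm$year >= y0 & atm$year <= y1]),
                   iso$year_start, iso$year_end)
  rec_air <- mapply(function(y0, y1)
    mean(atm$d13c_air[atm$year >= y0 & atm$year <= y1]),
    iso$year_start, iso$year_end)
  ex <- pool_expand(iso)
  ex$ca <- rep(rec_ca, n)
  d13c_air <- rep(rec_air, n)
  ex$delta13c <- big_delta(ex$d13c_tree, d13c_air)
  ex$ci <- ci_from_delta(ex$delta13c, ex$ca, a = a, b = b)
  ex$iwue <- iwue(ex$delta13c, ex$ca, a = a, b = b)
  ex[c("tree_id", "year", "delta13c", "ci", "iwue", "ca", "weight")]
}
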