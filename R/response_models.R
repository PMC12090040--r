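# Smooth-response models of iWUE against CO2 and August SPEI12 with
# health-status and period interactions; selection by AIC (ML) with REML
# refit; partial effects, derivative slopes and percent-change summaries.

#' Assemble the tree-year model frame
#'
#' Joins a per-tree iWUE panel with the August 12-month drought index and
#' the atmosphere, and labels each pine year as pre- or post-decline.
#' Species without a decline year get no period factor (single level).
#'
#' @param iwue_panel data.frame from [iwue_series()] plus `species`,
#'   `status` columns.
#' @param spei_aug12 data.frame `year`, `spei` (August values of the
#'   12-month index).
#' @param decline_years Named vector species -> decline year (NA for none).
#' @return data.frame `tree_id`, `species`, `year`, `iwue`, `ca`, `spei`,
#'   `status` (factor, reference "healthy"), `period` (factor pre/post
#'   where defined, else "pre"), `weight`.
#' @export
build_model_frame <- function(iwue_panel, spei_aug12, decline_years) {
  need <- c("tree_id", "species", "status", "year", "iwue", "ca", "weight")
  miss <- setdiff(need, names(iwue_panel))
  if (length(miss)) stop("iwue panel missing columns: ", paste(miss, collapse = ", "))
  sp <- spei_aug12$spei[match(iwue_panel$year, spei_aug12$year)]
  if (any(is.na(sp)))
    stop("drought index missing for years: ",
         paste(sort(unique(iwue_panel$year[is.na(sp)])), collapse = ", "))
  dy <- decline_years[iwue_panel$species]
  period <- ifelse(is.na(dy) | iwue_panel$year <= dy, "pre", "post")
  out <- data.frame(
    tree_id = iwue_panel$tree_id, species = iwue_panel$species,
    year = iwue_panel$year, iwue = iwue_panel$iwue, ca = iwue_panel$ca,
    spei = sp,
    status = stats::relevel(factor(iwue_panel$status), ref = "healthy"),
    period = factor(period, levels = c("pre", "post")),
    weight = iwue_panel$weight)
  out$period <- droplevels(out$period)
  out
}

# ordered-factor copies used for difference smooths; mgcv drops the first
# level of an ordered by-factor, leaving status-specific deviations from
# the global smooth
prep_frame <- function(frame) {
  frame$status <- droplevels(factor(frame$status))
  frame$status_o <- as.ordered(frame$status)
  if (!"period" %in% names(frame)) frame$period <- factor("pre")
  frame$period <- droplevels(frame$period)
  ps <- interaction(frame$period, frame$status, drop = TRUE)
  frame$ps_o <- as.ordered(ps)
  frame
}

model_formula <- function(frame, co2_by_status, spei_by, k) {
  multi_status <- nlevels(frame$status) > 1
  terms <- c(if (multi_status) "status",
             sprintf("s(ca, k = %d, bs = 'cr')", k),
             if (co2_by_status && multi_status)
               sprintf("s(ca, by = status_o, k = %d, bs = 'cr')", k),
             sprintf("s(spei, k = %d, bs = 'cr')", k))
  if (spei_by == "status" && multi_status)
    terms <- c(terms, sprintf("s(spei, by = status_o, k = %d, bs = 'cr')", k))
  if (spei_by == "period_status" && nlevels(frame$ps_o) > 1)
    terms <- c(terms, sprintf("s(spei, by = ps_o, k = %d, bs = 'cr')", k))
  stats::as.formula(paste("iwue ~", paste(terms, collapse = " + ")))
}

#' Fit a smooth-response model of iWUE
#'
#' Penalized cubic regression splines (basis dimension `k`, default 4) of
#' CO2 and drought with sum-to-zero identifiability constraints: intercept
#' + status offsets + global CO2 smooth + status-specific CO2 difference
#' smooths + global drought smooth + (optionally) period-x-status-specific
#' drought difference smooths, with weighted likelihood honouring pooled
#' record weights.
#'
#' @param frame Model frame from [build_model_frame()], one species.
#' @param co2_by_status Include status-specific CO2 difference smooths.
#' @param spei_by One of "none", "status", "period_status" for the drought
#'   difference smooths.
#' @param k Spline basis dimension (default 4).
#' @param method "ML" or "REML".
#' @return Object of class `smooth_fit`: list with the mgcv fit (`gam`),
#'   the descriptor, `aic`, `logLik`, `deviance_explained`, `edf`.
#' @export
fit_smooth_model <- function(frame, co2_by_status = TRUE,
                             spei_by = "period_status", k = 4,
                             method = c("ML", "REML")) {
  method <- match.arg(method)
  spei_by <- match.arg(spei_by, c("none", "status", "period_status"))
  frame <- prep_frame(frame)
  if (any(table(frame$status) < 10))
    stop("need at least 10 rows per status level")
  f <- model_formula(frame, co2_by_status, spei_by, k)
  fit <- mgcv::gam(f, data = frame, weights = frame$weight, method = method)
  s <- summary(fit)
  structure(list(
    gam = fit,
    descriptor = list(co2_by_status = co2_by_status, spei_by = spei_by, k = k),
    method = method,
    aic = stats::AIC(fit),
    logLik = as.numeric(stats::logLik(fit)),
    deviance_explained = s$dev.expl,
    edf = sum(fit$edf),
    frame = frame
  ), class = "smooth_fit")
}

#' @export
print.smooth_fit <- function(x, ...) {
  cat("Smooth-response fit (", x$method, ")\n", sep = "")
  cat("  terms:", deparse(stats::formula(x$gam$formula)), "\n")
  cat(sprintf("  AIC %.2f | deviance explained %.1f%% | total edf %.1f\n",
              x$aic, 100 * x$deviance_explained, x$edf))
  invisible(x)
}

#' Select among candidate smooth models by AIC
#'
#' Fits every candidate with maximum likelihood, picks the lowest AIC
#' (ties broken by fewer effective parameters), and refits the winner with
#' REML.
#'
#' @param frame Model frame (one species).
#' @param candidates list of descriptor lists with elements
#'   `co2_by_status`, `spei_by` (and optional `k`). Default: the four
#'   combinations of with/without CO2-status interaction and drought
#'   difference smooths.
#' @return The winning `smooth_fit` (REML), with the ML comparison table in
#'   attribute `selection`.
#' @export
select_model <- function(frame, candidates = NULL) {
  if (is.null(candidates))
    candidates <- list(
      list(co2_by_status = FALSE, spei_by = "none"),
      list(co2_by_status = TRUE, spei_by = "none"),
      list(co2_by_status = FALSE, spei_by = "period_status"),
      list(co2_by_status = TRUE, spei_by = "period_status"))
  fits <- list(); errs <- character()
  for (i in seq_along(candidates)) {
    d <- candidates[[i]]
    fits[[i]] <- tryCatch(
      fit_smooth_model(frame, co2_by_status = d$co2_by_status,
                       spei_by = d$spei_by,
                       k = if (is.null(d$k)) 4 else d$k, method = "ML"),
      error = function(e) {errs <<- c(errs, conditionMessage(e)); NULL})
  }
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) stop("all candidate fits failed: ", paste(errs, collapse = "; "))
  tab <- data.frame(
    candidate = which(ok),
    aic = vapply(fits[ok], `[[`, numeric(1), "aic"),
    edf = vapply(fits[ok], `[[`, numeric(1), "edf"),
    deviance_explained = vapply(fits[ok], `[[`, numeric(1), "deviance_explained"))
  best <- tab$candidate[order(tab$aic, tab$edf)][1]
  d <- candidates[[best]]
  out <- fit_smooth_model(frame, co2_by_status = d$co2_by_status,
                          spei_by = d$spei_by,
                          k = if (is.null(d$k)) 4 else d$k, method = "REML")
  attr(out, "selection") <- tab
  out
}

# newdata grid per status level with the other covariate at its frame mean
pe_newdata <- function(fit, variable, grid, status) {
  frame <- fit$frame
  nd <- data.frame(v = grid)
  names(nd) <- variable
  other <- setdiff(c("ca", "spei"), variable)
  nd[[other]] <- stats::weighted.mean(frame[[other]], frame$weight)
  nd$status <- factor(status, levels = levels(frame$status))
  nd$status_o <- factor(status, levels = levels(frame$status), ordered = TRUE)
  # period fixed at the reference level; its difference smooth contributes a
  # group-constant offset only
  lev <- levels(frame$ps_o)
  pick <- grep(paste0("\\.", status, "$"), lev, value = TRUE)
  nd$ps_o <- factor(if (length(pick)) pick[1] else lev[1],
                    levels = lev, ordered = TRUE)
  nd
}

clip_grid <- function(grid, range, what) {
  if (any(grid < range[1] | grid > range[2])) {
    warning(what, " grid clipped to the observed range [",
            format(range[1], digits = 4), ", ", format(range[2], digits = 4), "]")
    grid <- pmin(pmax(grid, range[1]), range[2])
  }
  grid
}

#' Partial effect of CO2 or drought per status
#'
#' Predictions over a grid of one predictor with the other fixed at its
#' (weight-weighted) frame mean, per status level, with pointwise
#' `+/- 1.96 SE` bands.
#'
#' @param fit `smooth_fit`.
#' @param variable "ca" or "spei".
#' @param grid Predictor values; default 100 points over the observed
#'   range. Out-of-range values are clipped with a warning.
#' @return data.frame `status`, grid column, `fit`, `se`, `lower`, `upper`.
#' @export
partial_effect <- function(fit, variable = c("ca", "spei"), grid = NULL) {
  variable <- match.arg(variable)
  frame <- fit$frame
  rng <- range(frame[[variable]])
  if (is.null(grid)) grid <- seq(rng[1], rng[2], length.out = 100)
  grid <- clip_grid(grid, rng, variable)
  out <- list()
  for (st in levels(frame$status)) {
    nd <- pe_newdata(fit, variable, grid, st)
    pr <- mgcv::predict.gam(fit$gam, newdata = nd, se.fit = TRUE)
    out[[st]] <- data.frame(status = st, v = grid, fit = as.numeric(pr$fit),
                            se = as.numeric(pr$se.fit))
  }
  out <- do.call(rbind, out)
  names(out)[names(out) == "v"] <- variable
  out$lower <- out$fit - 1.96 * out$se
  out$upper <- out$fit + 1.96 * out$se
  rownames(out) <- NULL
  out
}

#' First-derivative slopes of the smooth response
#'
#' Central finite differences of the linear predictor along one variable
#' (step `eps`, default range/1000), per status level, with delta-method
#' standard errors from the basis-difference vector and 95% pointwise
#' intervals. With the other covariate held fixed this is the derivative of
#' the variable's smooth terms, e.g. the iWUE-CO2 slope
#' (delta iWUE / delta CO2).
#'
#' @param fit `smooth_fit`.
#' @param variable "ca" or "spei".
#' @param grid Evaluation points (default 50 over the observed range).
#' @param eps Step; default predictor range / 1000.
#' @return data.frame `status`, grid column, `slope`, `se`, `lower`,
#'   `upper`.
#' @export
smooth_derivative <- function(fit, variable = c("ca", "spei"), grid = NULL,
                              eps = NULL) {
  variable <- match.arg(variable)
  frame <- fit$frame
  rng <- range(frame[[variable]])
  if (is.null(grid)) grid <- seq(rng[1], rng[2], length.out = 50)
  grid <- clip_grid(grid, rng, variable)
  if (is.null(eps)) eps <- diff(rng) / 1000
  V <- stats::vcov(fit$gam)
  out <- list()
  for (st in levels(frame$status)) {
    ndp <- pe_newdata(fit, variable, grid + eps, st)
    ndm <- pe_newdata(fit, variable, grid - eps, st)
    Xd <- (mgcv::predict.gam(fit$gam, newdata = ndp, type = "lpmatrix") -
             mgcv::predict.gam(fit$gam, newdata = ndm, type = "lpmatrix")) /
      (2 * eps)
    slope <- as.numeric(Xd %*% stats::coef(fit$gam))
    se <- sqrt(pmax(0, rowSums((Xd %*% V) * Xd)))
    out[[st]] <- data.frame(status = st, v = grid, slope = slope, se = se)
  }
  out <- do.call(rbind, out)
  names(out)[names(out) == "v"] <- variable
  out$lower <- out$slope - 1.96 * out$se
  out$upper <- out$slope + 1.96 * out$se
  rownames(out) <- NULL
  out
}

#' Predicted iWUE surface over CO2 x drought
#'
#' Full prediction grid per status level across the ranges of both
#' predictors.
#'
#' @param fit `smooth_fit`.
#' @param co2_grid,spei_grid Grids (defaults: 25 points over observed
#'   ranges).
#' @return data.frame `status`, `ca`, `spei`, `fit`, `se`.
#' @export
interaction_surface <- function(fit, co2_grid = NULL, spei_grid = NULL) {
  frame <- fit$frame
  if (is.null(co2_grid))
    co2_grid <- seq(min(frame$ca), max(frame$ca), length.out = 25)
  if (is.null(spei_grid))
    spei_grid <- seq(min(frame$spei), max(frame$spei), length.out = 25)
  out <- list()
  for (st in levels(frame$status)) {
    nd <- expand.grid(ca = co2_grid, spei = spei_grid)
    nd$status <- factor(st, levels = levels(frame$status))
    nd$status_o <- factor(st, levels = levels(frame$status), ordered = TRUE)
    lev <- levels(frame$ps_o)
    pick <- grep(paste0("\\.", st, "$"), lev, value = TRUE)
    nd$ps_o <- factor(if (length(pick)) pick[1] else lev[1],
                      levels = lev, ordered = TRUE)
    pr <- mgcv::predict.gam(fit$gam, newdata = nd, se.fit = TRUE)
    out[[st]] <- data.frame(status = st, ca = nd$ca, spei = nd$spei,
                            fit = as.numeric(pr$fit), se = as.numeric(pr$se.fit))
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Percent change in iWUE between two years
#'
#' For a fitted model: evaluates the status-level iWUE-CO2 response
#' (intercept + status + CO2 smooth terms; drought smooths excluded) at the
#' two years' CO2 values and returns `100 * (v2 - v1) / v1` per status. For
#' an annual series (`year`, `value`): the same ratio on the series values.
#'
#' @param object `smooth_fit` or data.frame `year`, `value`.
#' @param years Length-2 year pair `c(t1, t2)`.
#' @param atm Atmosphere data.frame (`year`, `ca`); required for a fit.
#' @return data.frame `status` (or "series"), `value_t1`, `value_t2`,
#'   `pct_change`.
#' @export
percent_change <- function(object, years, atm = NULL) {
  stopifnot(length(years) == 2)
  if (is.data.frame(object)) {
    v <- object$value[match(years, object$year)]
    if (any(is.na(v))) stop("years not covered by the series")
    if (v[1] <= 0) stop("baseline value <= 0: percent change undefined")
    return(data.frame(status = "series", value_t1 = v[1], value_t2 = v[2],
                      pct_change = 100 * (v[2] - v[1]) / v[1]))
  }
  stopifnot(inherits(object, "smooth_fit"), !is.null(atm))
  ca2 <- atm$ca[match(years, atm$year)]
  if (any(is.na(ca2))) stop("atmosphere does not cover the requested years")
  frame <- object$frame
  drop_terms <- grep("s\\(spei", row.names(summary(object$gam)$s.table),
                     value = TRUE)
  out <- list()
  for (st in levels(frame$status)) {
    nd <- pe_newdata(object, "ca", ca2, st)
    pr <- mgcv::predict.gam(object$gam, newdata = nd, exclude = drop_terms)
    v <- as.numeric(pr)
    if (v[1] <= 0) stop("baseline prediction <= 0 for status ", st)
    out[[st]] <- data.frame(status = st, value_t1 = v[1], value_t2 = v[2],
                            pct_change = 100 * (v[2] - v[1]) / v[1])
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
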