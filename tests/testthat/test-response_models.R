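test_that("model frame splits periods at the species decline year", {
  atm <- default_atm()
  panel <- do.call(rbind, lapply(c("a", "b", "c", "d", "e"), function(id)
    data.frame(tree_id = id, species = "pinaster", status = "healthy",
               year = atm$year, iwue = 90, ca = atm$ca, weight = 1)))
  aug <- data.frame(year = atm$year, spei = 0)
  fr <- build_model_frame(panel, aug,
                          c(pinaster = 1995, pinea = 2005, oxycedrus = NA))
  expect_equal(nrow(fr), 195)
  expect_true(all(fr$period[fr$year <= 1995] == "pre"))
  expect_true(all(fr$period[fr$year > 1995] == "post"))
  # species without decline year: single-level period
  panel$species <- "oxycedrus"
  frj <- build_model_frame(panel, aug,
                           c(pinaster = 1995, pinea = 2005, oxycedrus = NA))
  expect_equal(nlevels(frj$period), 1)
  expect_error(build_model_frame(panel, aug[-1, ],
                                 c(oxycedrus = NA)), "1978")
})

test_that("linear truth is recovered with null difference smooths", {
  fr <- plateau_frame(21, s_lo = 0.25, s_hi = c(healthy = 0.25,
                                                declining = 0.25, dead = 0.25))
  fit <- fit_smooth_model(fr, co2_by_status = TRUE, spei_by = "status",
                          method = "ML")
  dv <- smooth_derivative(fit, "ca", grid = seq(340, 400, by = 10))
  expect_true(all(dv$lower <= 0.25 + 0.03 & dv$upper >= 0.25 - 0.03))
  # status difference smooths essentially flat: curves coincide
  pe <- partial_effect(fit, "ca", grid = seq(340, 400, by = 10))
  spread <- tapply(pe$fit, pe$ca, function(x) diff(range(x)))
  expect_lt(max(spread), 2)
  # edf bounded by basis dimension, deviance beats intercept-only
  expect_true(all(summary(fit$gam)$edf <= 3 + 1e-6))
  expect_gt(fit$deviance_explained, 0)
  # REML refit keeps the term set
  refit <- fit_smooth_model(fr, co2_by_status = TRUE, spei_by = "status",
                            method = "REML")
  expect_equal(length(refit$gam$smooth), length(fit$gam$smooth))
})

test_that("AIC selection prefers the planted interaction and refits with REML", {
  hits <- vapply(1:10, function(s) {
    fr <- plateau_frame(300 + s, s_hi = c(healthy = 0.3, declining = 0,
                                          dead = 0))
    fit <- select_model(fr, candidates = list(
      list(co2_by_status = FALSE, spei_by = "none"),
      list(co2_by_status = TRUE, spei_by = "none")))
    fit$descriptor$co2_by_status
  }, logical(1))
  expect_gte(sum(hits), 8)
  fr <- plateau_frame(1)
  fit <- select_model(fr)
  expect_equal(fit$method, "REML")
  tab <- attr(fit, "selection")
  expect_true(all(diff(tab$candidate) > 0))
  # AIC reproduced from the stored likelihood and effective parameters
  ml <- fit_smooth_model(fr, co2_by_status = fit$descriptor$co2_by_status,
                         spei_by = fit$descriptor$spei_by, method = "ML")
  expect_equal(ml$aic, 2 * attr(stats::logLik(ml$gam), "df") -
                 2 * as.numeric(stats::logLik(ml$gam)), tolerance = 1e-9)
})

test_that("adding a pure-noise smooth never lowers the ML likelihood", {
  withr::with_seed(33, {
    fr <- plateau_frame(33, statuses = "healthy",
                        s_hi = c(healthy = 0.3))
    fr$spei <- stats::rnorm(nrow(fr))  # uninformative
  })
  base <- mgcv::gam(iwue ~ s(ca, k = 4, bs = "cr"), data = fr, method = "ML")
  full <- mgcv::gam(iwue ~ s(ca, k = 4, bs = "cr") + s(spei, k = 4, bs = "cr"),
                    data = fr, method = "ML")
  expect_gte(as.numeric(stats::logLik(full)) + 1e-8,
             as.numeric(stats::logLik(base)))
})

test_that("partial effects, derivatives and surfaces are mutually consistent", {
  fr <- plateau_frame(7)
  fit <- fit_smooth_model(fr, co2_by_status = TRUE, spei_by = "status")
  # single-point grid equals direct prediction
  pe1 <- partial_effect(fit, "ca", grid = 370)
  nd <- data.frame(ca = 370,
                   spei = stats::weighted.mean(fit$frame$spei, fit$frame$weight),
                   status = factor("healthy", levels = levels(fit$frame$status)),
                   status_o = factor("healthy", levels = levels(fit$frame$status),
                                     ordered = TRUE),
                   ps_o = factor("pre.healthy", levels = levels(fit$frame$ps_o),
                                 ordered = TRUE))
  direct <- as.numeric(mgcv::predict.gam(fit$gam, newdata = nd))
  expect_equal(pe1$fit[pe1$status == "healthy"], direct, tolerance = 1e-10)
  # derivative equals numeric differentiation of the partial-effect curve
  g <- seq(340, 400, by = 5)
  eps <- diff(range(fit$frame$ca)) / 1000
  dv <- smooth_derivative(fit, "ca", grid = g)
  pe_p <- partial_effect(fit, "ca", grid = g + eps)
  pe_m <- partial_effect(fit, "ca", grid = g - eps)
  num <- (pe_p$fit - pe_m$fit) / (2 * eps)
  expect_equal(dv$slope, num, tolerance = 1e-6)
  expect_true(all(dv$lower <= dv$slope & dv$slope <= dv$upper))
  # derivative integrates back to the partial effect up to a constant
  gg <- seq(min(fit$frame$ca), max(fit$frame$ca), length.out = 201)
  pec <- partial_effect(fit, "ca", grid = gg)
  dvc <- smooth_derivative(fit, "ca", grid = gg)
  h <- pec[pec$status == "healthy", ]; dh <- dvc[dvc$status == "healthy", ]
  integ <- cumsum(c(0, (dh$slope[-1] + dh$slope[-201]) / 2 * diff(gg)))
  resid <- (h$fit - h$fit[1]) - integ
  expect_lt(max(abs(resid)), 0.001 * diff(range(h$fit)))
  # surface at the mean drought value matches the CO2 partial effect
  su <- interaction_surface(fit, co2_grid = g,
                            spei_grid = stats::weighted.mean(fit$frame$spei,
                                                             fit$frame$weight))
  pe <- partial_effect(fit, "ca", grid = g)
  sh <- su[su$status == "healthy", ]
  expect_equal(sh$fit, pe$fit[pe$status == "healthy"], tolerance = 1e-10)
  # 1x1 surface grid is a scalar prediction
  s1 <- interaction_surface(fit, co2_grid = 370, spei_grid = 0)
  expect_equal(nrow(s1), nlevels(fit$frame$status))
  # out-of-range grids are clipped with a warning
  expect_warning(partial_effect(fit, "ca", grid = c(200, 370)), "clipped")
})

test_that("penalized-to-linear limit agrees with ordinary least squares", {
  fr <- plateau_frame(11, statuses = "healthy", s_hi = c(healthy = 0.3))
  g <- mgcv::gam(iwue ~ s(ca, k = 4, bs = "cr") + s(spei, k = 4, bs = "cr"),
                 data = fr, sp = c(1e9, 1e9), method = "ML")
  ols <- stats::lm(iwue ~ ca + spei, data = fr)
  grid <- data.frame(ca = c(350, 390), spei = c(-1, 1))
  expect_equal(as.numeric(mgcv::predict.gam(g, grid)),
               as.numeric(stats::predict(ols, grid)), tolerance = 1e-4)
})

test_that("percent change handles series and model predictions", {
  flat <- data.frame(year = 2000:2010, value = 7)
  expect_equal(percent_change(flat, c(2001, 2009))$pct_change, 0)
  dbl <- data.frame(year = 2000:2010, value = seq(5, 10, length.out = 11))
  expect_equal(percent_change(dbl, c(2000, 2010))$pct_change, 100)
  expect_error(percent_change(flat, c(1990, 2000)), "covered")
})
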