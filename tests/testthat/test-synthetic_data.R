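test_that("atmosphere scenario matches endpoints, anchors and monotonicity", {
  atm <- generate_atmosphere(1978:2016, c(335, 404))
  expect_equal(atm$ca[1], 335)
  expect_equal(atm$ca[39], 404)
  expect_true(all(diff(atm$ca) > 0))
  expect_true(all(diff(atm$d13c_air) < 0))
  anc <- generate_atmosphere(ca_anchors = data.frame(year = 1995, ca = 360))
  expect_equal(anc$ca[anc$year == 1995], 360)
  expect_true(all(diff(anc$ca) > 0))
  one <- generate_atmosphere(1990, c(350, 400), c(-8, -8.4))
  expect_equal(nrow(one), 1)
  expect_equal(one$ca, 350)
  expect_error(generate_atmosphere(2016:1978), "increasing")
})

test_that("climate generator plants droughts, honours zero noise and the seed", {
  dr <- c(1995, 2005)
  cl <- generate_climate(1990:2010, drought_years = dr, drought_factor = 0.4,
                         seed = 4)
  hp <- suppressWarnings(hydro_year_precip(cl))
  expect_lt(max(hp$precip[hp$year %in% dr]),
            mean(hp$precip[!hp$year %in% dr]))
  # zero trend and noise: identical Julys everywhere
  cl0 <- generate_climate(1990:2010, trend = 0, t_sd = 0, p_sdlog = 0, seed = 4)
  julys <- cl0[cl0$month == 7, ]
  expect_equal(length(unique(julys$tmean)), 1)
  expect_equal(length(unique(julys$precip)), 1)
  # bit-identical under the same seed
  expect_identical(generate_climate(1990:2010, seed = 4),
                   generate_climate(1990:2010, seed = 4))
  expect_false(identical(generate_climate(1990:2010, seed = 4),
                         generate_climate(1990:2010, seed = 5)))
  expect_error(generate_climate(1990:2010, drought_factor = 0), "0, 1")
})

test_that("population generator enforces the design and status invariants", {
  pop <- generate_population(seed = 2)
  expect_equal(nrow(pop), 30)
  expect_equal(as.integer(table(pop$species)),
               c(5L, 15L, 10L))  # oxycedrus, pinaster, pinea (alphabetical)
  expect_true(all(pop$defoliation[pop$status == "dead"] == 4))
  expect_true(all(pop$mistletoe[pop$species == "pinea"] == 0))
  expect_true(all(pop$mistletoe %in% 0:4 & pop$defoliation %in% 0:4))
  expect_true(all(pop$status[pop$species != "pinaster"] != "declining"))
  empty <- generate_population(data.frame(species = "pinea", status = "healthy",
                                          n = 0L), seed = 1)
  expect_equal(nrow(empty), 0)
  expect_error(generate_population(
    data.frame(species = "pinea", status = "declining", n = 2L)), "declining")
})

test_that("ring series decline after the species decline year and rescale to dbh", {
  truth <- default_truth()
  healthy <- tree_row("pinaster", "healthy", dbh = 50, bark = 2)
  dead <- tree_row("pinaster", "dead", dbh = 50, bark = 2)
  rh <- generate_ring_series(healthy, truth = truth, seed = 6)
  rd <- generate_ring_series(dead, truth = truth, seed = 6)
  expect_true(all(rh$width_mm > 0))
  expect_equal(sum(rh$width_mm) / 10, 50 / 2 - 2, tolerance = 1e-9)
  expect_lt(mean(rd$width_mm[rd$year > 1995]),
            mean(rh$width_mm[rh$year > 1995]))
  # drought years dent the width (noiseless comparison)
  t0 <- noiseless_truth()
  r0 <- generate_ring_series(healthy, truth = t0, seed = 1)
  expect_lt(mean(r0$width_mm[r0$year %in% t0$drought_years]),
            mean(r0$width_mm[!r0$year %in% t0$drought_years]))
  # no drought effect, no noise -> flat
  t0$anatomy_effects$pinaster.healthy$width_drought_mult <- 1
  rf <- generate_ring_series(healthy, truth = t0, seed = 1)
  expect_equal(length(unique(round(rf$width_mm, 12))), 1)
  expect_identical(generate_ring_series(healthy, truth = truth, seed = 6), rh)
})

test_that("cell tables express the intra-ring profile and drought scaling", {
  truth <- default_truth()
  ring <- data.frame(tree_id = "p", year = 1995, width_mm = 2,
                     species = "pinaster", status = "healthy")
  dry <- generate_cell_table(ring, truth, drought = TRUE, seed = 9)
  wet <- generate_cell_table(ring, truth, drought = FALSE, seed = 9)
  ew <- function(cc) mean(cc$la[cc$position <= 0.75])
  expect_lt(ew(dry), ew(wet))
  expect_equal(ew(dry) / ew(wet), 0.6, tolerance = 0.05)
  # juniper earlywood lumen ~5x smaller than pine at matched noise stream
  jr <- data.frame(tree_id = "j", year = 1995, width_mm = 2,
                   species = "oxycedrus", status = "healthy")
  jun <- generate_cell_table(jr, truth, drought = FALSE, seed = 9)
  ratio <- mean(wet$la[wet$position <= 0.5]) / mean(jun$la[jun$position <= 0.5])
  expect_equal(ratio, 950 / 180, tolerance = 0.15)
  # count proportional to width
  wide <- ring; wide$width_mm <- 4
  expect_equal(nrow(generate_cell_table(wide, truth, seed = 1)) /
                 nrow(generate_cell_table(ring, truth, seed = 1)), 2,
               tolerance = 0.05)
  expect_error(generate_cell_table(transform(ring, width_mm = 0), truth),
               "positive")
})

test_that("isotope generator pools blocks and stays within physical bounds", {
  atm <- default_atm()
  tree <- tree_row("oxycedrus", "healthy")
  iso <- generate_isotope_series(tree, atm, NULL, default_truth(),
                                 pool_every = 5, seed = 3)
  expect_equal(sum(iso$year_end > iso$year_start), 7)  # 7 five-year blocks
  expect_equal(sum(iso$year_end == iso$year_start), 4) # 4 residual years
  covered <- unlist(Map(seq, iso$year_start, iso$year_end))
  expect_equal(sort(covered), 1978:2016)
  # plateau truth: noiseless series flat above the breakpoint
  t0 <- noiseless_truth()
  t0$iwue_response$pinaster.dead$s_hi <- 0
  t0$iwue_response$pinaster.dead$d_sens <- 0
  isod <- generate_isotope_series(tree_row("pinaster", "dead"), atm, NULL, t0,
                                  seed = 1)
  iw <- iwue_series(isod, atm)
  above <- iw$iwue[atm$ca > 360]
  expect_lt(max(above) - min(above), 1e-9)
  # unphysical truth rejected
  tbad <- noiseless_truth()
  tbad$iwue_response$pinaster.dead$base <- 500
  expect_error(generate_isotope_series(tree_row("pinaster", "dead"), atm, NULL,
                                       tbad), "unphysical")
})
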