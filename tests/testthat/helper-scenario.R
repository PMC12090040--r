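# Shared fixtures, computed once per test run.

noiseless_truth <- function() {
  default_truth(noise = list(d13c = 0, width_sdlog = 0, la_sdlog = 0,
                             cwt_sdlog = 0))
}

default_atm <- function() {
  generate_atmosphere(ca_anchors = data.frame(year = 1995, ca = 360))
}

.scenario_cache <- new.env(parent = emptyenv())

# default-scenario climate + 12-month index, shared across tests
scenario_spei12 <- function() {
  if (is.null(.scenario_cache$spei12)) {
    cl <- generate_climate(1948:2016,
                           drought_years = default_truth()$drought_years,
                           seed = 11)
    .scenario_cache$climate <- cl
    .scenario_cache$spei12 <- spei(cl, 12, attr(cl, "latitude"))
  }
  .scenario_cache$spei12
}

scenario_climate <- function() {
  invisible(scenario_spei12())
  .scenario_cache$climate
}

scenario_spei_aug <- function(years = 1978:2016) {
  s <- scenario_spei12()
  s[s$month == 8 & s$year %in% years, c("year", "spei")]
}

# one synthetic tree row without drawing a population
tree_row <- function(species = "pinaster", status = "healthy",
                     dbh = 50, bark = 2, height = 18) {
  data.frame(tree_id = paste0(species, "_", status, "_01"),
             species = species, status = status, dbh = dbh, bark = bark,
             height = height, age = 80, mistletoe = 0,
             defoliation = if (status == "dead") 4 else 1)
}

# simulated tree-year model frame with piecewise-linear iWUE truth:
# slope `s_lo` below 360 ppm, per-status slope above; gaussian noise
plateau_frame <- function(seed, statuses = c("healthy", "declining", "dead"),
                          s_lo = 0.3,
                          s_hi = c(healthy = 0.3, declining = 0, dead = 0),
                          sd = 3, n_trees = 5, atm = default_atm()) {
  withr::with_seed(seed, {
    do.call(rbind, lapply(statuses, function(st) {
      ca <- rep(atm$ca, n_trees)
      spei <- stats::rnorm(length(ca))
      mu <- 70 + s_lo * (pmin(ca, 360) - 335) + s_hi[[st]] * pmax(ca - 360, 0)
      data.frame(tree_id = paste0(st, rep(seq_len(n_trees), each = length(atm$year))),
                 species = "pine", year = rep(atm$year, n_trees),
                 iwue = mu + stats::rnorm(length(ca), 0, sd),
                 ca = ca, spei = spei,
                 status = factor(st, levels = statuses),
                 period = factor("pre"), weight = 1)
    }))
  })
}

# small random cell table for oracle checks
random_cells <- function(n, seed, year = 2000, tree_id = "t1", n_files = 5) {
  withr::with_seed(seed, {
    data.frame(tree_id = tree_id, year = year,
               cell_id = paste0("c", seq_len(n)),
               file_id = sample.int(n_files, n, replace = TRUE),
               position = stats::runif(n),
               la = stats::runif(n, 50, 1200),
               ld = stats::runif(n, 5, 40),
               cwt_r1 = stats::runif(n, 1, 8), cwt_r2 = stats::runif(n, 1, 8),
               cwt_t1 = stats::runif(n, 1, 8), cwt_t2 = stats::runif(n, 1, 8))
  })
}
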