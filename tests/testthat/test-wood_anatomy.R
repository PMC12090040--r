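test_that("row selection keeps the most populated files with stable ties", {
  cells <- random_cells(200, seed = 2, n_files = 30)
  sel <- select_rows(cells)
  kept <- unique(sel$file_id)
  expect_length(kept, 20)
  cnt <- table(cells$file_id)
  expect_gte(min(cnt[as.character(kept)]),
             max(cnt[!names(cnt) %in% as.character(kept)]))
  # brute-force ranking oracle
  o <- names(sort(-cnt))
  # resolve count ties by file id like the implementation
  ord <- order(-as.vector(cnt), names(cnt))
  expect_setequal(as.character(kept), names(cnt)[ord][1:20])
  # fewer than n_min files: all kept, warning
  few <- random_cells(40, seed = 3, n_files = 10)
  expect_warning(sel2 <- select_rows(few), "keeping all")
  expect_setequal(unique(sel2$file_id), unique(few$file_id))
  expect_error(select_rows(few[0, ]), "empty")
})

test_that("Mork partition follows LD >= 4 CWT with earlywood at the boundary", {
  expect_equal(mork_classify(40, 5), "EW")
  expect_equal(mork_classify(10, 4), "LW")
  expect_equal(mork_classify(20, 5), "EW")  # boundary convention
  expect_error(mork_classify(0, 1), "positive")
})

test_that("ring aggregates equal a brute-force recomputation by sector", {
  one <- random_cells(1, seed = 5)
  one$cwt_r1 <- 4; one$cwt_r2 <- 4; one$cwt_t1 <- 6; one$cwt_t2 <- 6
  ra1 <- ring_anatomy(one)
  expect_equal(ra1$cwt_mean[ra1$sector == "whole"], 5)
  cells <- random_cells(300, seed = 6)
  ra <- ring_anatomy(cells)
  cwt <- with(cells, (cwt_r1 + cwt_r2 + cwt_t1 + cwt_t2) / 4)
  ew <- cells$ld >= 4 * cwt
  nf <- length(unique(cells$file_id))
  expect_equal(ra$la_mean[ra$sector == "EW"], mean(cells$la[ew]))
  expect_equal(ra$cwt_mean[ra$sector == "LW"], mean(cwt[!ew]))
  expect_equal(ra$n_cells[ra$sector == "whole"], nrow(cells) / nf)
  # sector partition conserves counts
  expect_equal(ra$n_total[ra$sector == "EW"] + ra$n_total[ra$sector == "LW"],
               ra$n_total[ra$sector == "whole"])
  expect_equal(ra$n_cells[ra$sector == "EW"] + ra$n_cells[ra$sector == "LW"],
               ra$n_cells[ra$sector == "whole"], tolerance = 1e-9)
  # all-earlywood ring: LW flagged empty, whole == EW
  ew_only <- cells; ew_only$ld <- 1000
  ra2 <- ring_anatomy(ew_only)
  expect_equal(ra2$n_total[ra2$sector == "LW"], 0)
  expect_true(is.na(ra2$la_mean[ra2$sector == "LW"]))
  expect_equal(ra2$la_mean[ra2$sector == "whole"], ra2$la_mean[ra2$sector == "EW"])
})

test_that("hydraulic conductivity scales as d^4, sums per cell and is additive", {
  cells <- random_cells(50, seed = 8)
  kh <- theoretical_kh(cells)
  # brute-force per-cell summation
  brute <- 0
  for (i in seq_len(nrow(cells))) {
    d <- 2 * sqrt(cells$la[i] / pi) * 1e-6
    brute <- brute + pi * d^4 / (128 * 1.002e-9)
  }
  expect_equal(kh, brute, tolerance = 1e-12)
  # doubling all diameters quadruples la and multiplies kh by 16
  cells2 <- cells; cells2$la <- 4 * cells$la
  expect_equal(theoretical_kh(cells2) / kh, 16, tolerance = 1e-12)
  expect_equal(theoretical_kh(cells[0, ]), 0)
  # additive over a disjoint split
  expect_equal(theoretical_kh(cells[1:20, ]) + theoretical_kh(cells[21:50, ]),
               kh, tolerance = 1e-12)
})

test_that("implosion safety is (T/B)^2 and larger for narrow-lumen juniper", {
  expect_equal(implosion_safety(5, 20), 0.0625)
  expect_equal(implosion_safety(10, 20) / implosion_safety(5, 20), 4)
  expect_error(implosion_safety(5, 0), "positive")
  truth <- noiseless_truth()
  pine <- generate_cell_table(
    data.frame(tree_id = "p", year = 2000, width_mm = 2,
               species = "pinaster", status = "healthy"),
    truth, drought = FALSE, seed = 1)
  jun <- generate_cell_table(
    data.frame(tree_id = "j", year = 2000, width_mm = 2,
               species = "oxycedrus", status = "healthy"),
    truth, drought = FALSE, seed = 1)
  tb2 <- function(cells) {
    ra <- ring_anatomy(cells)
    ra$tb2[ra$sector == "EW"]
  }
  expect_gt(tb2(jun), tb2(pine))
})

test_that("tracheidograms bin by relative position and match group-by means", {
  truth <- noiseless_truth()
  ring <- data.frame(tree_id = "p", year = 2000, width_mm = 2,
                     species = "pinaster", status = "healthy")
  cells <- generate_cell_table(ring, truth, drought = FALSE, seed = 1)
  tg <- tracheidogram(cells, npoints = 10)
  expect_true(all(diff(tg$la_mean) <= 1e-9))  # noiseless EW->LW decline
  # brute-force group-by on a noisy fixture
  cells2 <- random_cells(500, seed = 10)
  tg2 <- tracheidogram(cells2, npoints = 8)
  b <- pmin(floor(cells2$position * 8), 7) + 1
  for (k in c(1, 4, 8)) {
    expect_equal(tg2$la_mean[k], mean(cells2$la[b == k]))
    expect_equal(tg2$la_sem[k],
                 stats::sd(cells2$la[b == k]) / sqrt(sum(b == k)))
  }
  expect_error(tracheidogram(cells2, npoints = 1), "at least 2")
})

test_that("KS statistic equals the brute-force ECDF sup difference", {
  expect_equal(ks_compare(1:5, 1:5)$D, 0)
  expect_equal(ks_compare(1:3, 4:6)$D, 1)
  brute_D <- function(a, b) {
    g <- sort(unique(c(a, b)))
    max(abs(stats::ecdf(a)(g) - stats::ecdf(b)(g)))
  }
  withr::with_seed(12, {
    for (i in 1:50) {
      a <- stats::rnorm(sample(5:60, 1))
      b <- stats::rnorm(sample(5:60, 1), mean = stats::runif(1, -1, 1))
      kc <- ks_compare(a, b)
      expect_equal(kc$D, brute_D(a, b), tolerance = 1e-12)
      expect_true(kc$D >= 0 && kc$D <= 1)
      expect_true(kc$p >= 0 && kc$p <= 1)
      # symmetry
      expect_equal(kc$D, ks_compare(b, a)$D)
    }
  })
})

test_that("dry/average/wet profile contrasts detect the planted drought effect", {
  truth <- default_truth()
  classes <- list(dry = c(1995, 1999), average = c(1993, 1997), wet = c(1991, 2001))
  mk <- function(years, drought) {
    do.call(rbind, lapply(seq_along(years), function(i)
      generate_cell_table(
        data.frame(tree_id = "p", year = years[i], width_mm = 2,
                   species = "pinaster", status = "healthy"),
        truth, drought = drought, seed = 100 + years[i])))
  }
  cells <- rbind(mk(classes$dry, TRUE), mk(classes$average, FALSE),
                 mk(classes$wet, FALSE))
  cells$group <- "pinaster.healthy"
  res <- drought_profile_contrast(cells, classes)
  la_dw <- res[res$trait == "la" & res$contrast == "dry-wet", ]
  expect_true(la_dw$significant)
  aw <- res[res$trait == "la" & res$contrast == "average-wet", ]
  expect_lt(aw$D, la_dw$D)
  # empty class skipped with warning
  cls2 <- list(dry = classes$dry, average = classes$average, wet = 1888)
  warns <- testthat::capture_warnings(
    res2 <- drought_profile_contrast(cells, cls2))
  expect_true(all(grepl("skipped", warns)))
  expect_false(any(res2$contrast %in% c("dry-wet", "average-wet")))
})

test_that("mixed-model group comparison separates planted effects and recovers means", {
  mk_panel <- function(effect, seed) {
    withr::with_seed(seed, {
      do.call(rbind, lapply(1:3, function(g)
        do.call(rbind, lapply(1:6, function(tr) {
          re <- stats::rnorm(1, 0, 0.5)
          data.frame(tree_id = paste0("g", g, "t", tr),
                     group = paste0("G", g),
                     height = stats::runif(1, 10, 20),
                     y = 10 + effect * (g - 1) + re + stats::rnorm(30))
        }))))
    })
  }
  # strong effect (3 residual SD): all letters distinct, means recovered
  panel <- mk_panel(3, seed = 42)
  cmp <- trait_group_comparison(panel, "y")
  expect_length(unique(cmp$estimates$letter), 3)
  est <- cmp$estimates$emmean
  expect_lt(max(abs(est - c(10, 13, 16))) / 3, 0.05 * 3)  # bias < 5% of effect
  # no effect: a single shared letter in most replicates
  shared <- vapply(1:10, function(s) {
    cmp0 <- trait_group_comparison(mk_panel(0, seed = 100 + s), "y")
    length(unique(cmp0$estimates$letter)) == 1
  }, logical(1))
  expect_gte(sum(shared), 8)
})
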