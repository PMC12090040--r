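# Quantitative wood anatomy: row selection, Mork partition, ring
# aggregates, hydraulic conductivity, tracheidograms, KS contrasts and
# group comparisons.

#' Select complete tracheid rows for a ring
#'
#' Radial files (tracheid rows) are ranked by cell count, descending, and
#' the top `n_max` files are kept (ties broken by file id, ascending). If
#' fewer than `n_min` files are available all are kept with a warning. This
#' mimics the field practice of analysing the 15-20 complete rows with the
#' most tracheids per annual ring.
#'
#' @param cells Cell table for a single ring (columns incl. `file_id`).
#' @param n_min,n_max Bounds on the number of files kept (default 15, 20).
#' @return The subset of `cells` belonging to the selected files.
#' @export
select_rows <- function(cells, n_min = 15, n_max = 20) {
  if (nrow(cells) == 0) stop("empty ring: no cells to select from")
  cnt <- table(cells$file_id)
  ids <- names(cnt)[order(-as.vector(cnt), names(cnt))]
  if (length(ids) < n_min)
    warning("only ", length(ids), " radial files available (< ", n_min, "); keeping all")
  keep <- ids[seq_len(min(n_max, length(ids)))]
  cells[cells$file_id %in% keep, , drop = FALSE]
}

#' Mork earlywood/latewood classification
#'
#' A tracheid is earlywood iff its radial lumen diameter is at least four
#' times its mean cell-wall thickness (Mork ratio 4 CWT / LD <= 1);
#' boundary cells are assigned to earlywood.
#'
#' @param ld Radial lumen diameter (micron), > 0.
#' @param cwt_mean Mean cell-wall thickness (micron), >= 0.
#' @return Character vector "EW"/"LW".
#' @export
mork_classify <- function(ld, cwt_mean) {
  if (any(ld <= 0)) stop("lumen diameter must be positive")
  ifelse(ld >= 4 * cwt_mean, "EW", "LW")
}

#' Per-cell mean wall thickness
#'
#' Mean of the four measured walls (two radial, two tangential).
#' @param cells Cell table with `cwt_r1`, `cwt_r2`, `cwt_t1`, `cwt_t2`.
#' @return Numeric vector (micron).
#' @export
cell_cwt <- function(cells) {
  (cells$cwt_r1 + cells$cwt_r2 + cells$cwt_t1 + cells$cwt_t2) / 4
}

#' Theoretical hydraulic conductivity of a set of conduits
#'
#' Hagen-Poiseuille conductivity summed over cells using equivalent circle
#' diameters: `d = 2 sqrt(LA/pi)` and `KH = sum(pi d^4 / (128 eta))` with
#' diameters converted to metres and water viscosity `eta` in MPa s, so KH
#' is in m^4 MPa^-1 s^-1. Additive over disjoint cell sets.
#'
#' @param cells Cell table with `la` (micron^2), all > 0.
#' @param eta Dynamic viscosity of water (MPa s), default 1.002e-9 (20 degC).
#' @return Scalar KH (m^4 MPa^-1 s^-1); 0 for an empty cell set.
#' @export
theoretical_kh <- function(cells, eta = 1.002e-9) {
  if (nrow(cells) == 0) return(0)
  if (any(cells$la <= 0)) stop("lumen areas must be positive")
  d_m <- 2 * sqrt(cells$la / pi) * 1e-6
  sum(pi * d_m^4 / (128 * eta))
}

#' Implosion-safety ratio (T/B)^2
#'
#' Squared ratio of wall thickness T to conduit diameter B, a proxy for
#' resistance of the tracheid wall to collapse under tension.
#'
#' @param cwt_mean Wall thickness T (micron).
#' @param diameter Conduit diameter B (micron), > 0. By convention here the
#'   radial lumen diameter.
#' @return (T/B)^2, dimensionless.
#' @export
implosion_safety <- function(cwt_mean, diameter) {
  if (any(diameter <= 0)) stop("conduit diameter must be positive")
  (cwt_mean / diameter)^2
}

#' Ring-level anatomical aggregates by sector
#'
#' Computes earlywood (EW), latewood (LW) and whole-ring aggregates from a
#' (row-selected) cell table: mean wall thickness (mean of four walls, then
#' over cells), mean lumen area and radial diameter, mean cell count per
#' selected radial file (plus total count), summed theoretical hydraulic
#' conductivity and mean implosion-safety ratio. Sectors are assigned per
#' cell by [mork_classify()].
#'
#' @param cells Cell table for one ring, after [select_rows()].
#' @return data.frame with one row per sector in (EW, LW, whole); empty
#'   sectors are flagged via `n_total = 0` and NA aggregates.
#' @export
ring_anatomy <- function(cells) {
  if (nrow(cells) == 0) stop("no cells supplied")
  cwt <- cell_cwt(cells)
  sector <- mork_classify(cells$ld, cwt)
  nfiles <- length(unique(cells$file_id))
  agg <- function(idx, label) {
    sub <- cells[idx, , drop = FALSE]
    if (nrow(sub) == 0)
      return(data.frame(tree_id = cells$tree_id[1], year = cells$year[1],
                        sector = label, cwt_mean = NA_real_, la_mean = NA_real_,
                        ld_mean = NA_real_, n_cells = 0, n_total = 0L,
                        kh = 0, tb2 = NA_real_))
    cw <- cwt[idx]
    data.frame(tree_id = cells$tree_id[1], year = cells$year[1], sector = label,
               cwt_mean = mean(cw), la_mean = mean(sub$la),
               ld_mean = mean(sub$ld),
               n_cells = nrow(sub) / nfiles, n_total = nrow(sub),
               kh = theoretical_kh(sub),
               tb2 = mean(implosion_safety(cw, sub$ld)))
  }
  out <- rbind(agg(sector == "EW", "EW"),
               agg(sector == "LW", "LW"),
               agg(rep(TRUE, nrow(cells)), "whole"))
  rownames(out) <- NULL
  out
}

#' Standardized tracheidogram
#'
#' Bins cells by relative radial position into `npoints` equal half-open
#' bins `[i/n, (i+1)/n)` (last bin closed) and returns per-bin means and
#' `+/- 1.96 SEM` bands of lumen area and wall thickness.
#'
#' @param cells Cell table (possibly from many rings) with `position`, `la`
#'   and wall columns.
#' @param npoints Number of bins (>= 2).
#' @return data.frame `bin`, `position` (bin midpoint), per-trait `mean`,
#'   `sem`, `lower`, `upper` columns and `n`.
#' @export
tracheidogram <- function(cells, npoints = 20) {
  if (npoints < 2) stop("npoints must be at least 2")
  if (nrow(cells) == 0) stop("no cells supplied")
  if (any(cells$position < 0 | cells$position > 1))
    stop("relative positions must lie in [0, 1]")
  bin <- pmin(floor(cells$position * npoints), npoints - 1L) + 1L
  cwt <- cell_cwt(cells)
  out <- do.call(rbind, lapply(seq_len(npoints), function(b) {
    idx <- bin == b
    n <- sum(idx)
    stat <- function(x) {
      if (n == 0) return(c(NA_real_, NA_real_))
      m <- mean(x[idx])
      s <- if (n > 1) stats::sd(x[idx]) / sqrt(n) else 0
      c(m, s)
    }
    la <- stat(cells$la); cw <- stat(cwt)
    data.frame(bin = b, position = (b - 0.5) / npoints,
               la_mean = la[1], la_sem = la[2],
               la_lower = la[1] - 1.96 * la[2], la_upper = la[1] + 1.96 * la[2],
               cwt_mean = cw[1], cwt_sem = cw[2],
               cwt_lower = cw[1] - 1.96 * cw[2], cwt_upper = cw[1] + 1.96 * cw[2],
               n = n)
  }))
  rownames(out) <- NULL
  out
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' D is the supremum of the absolute difference between the two empirical
#' CDFs; the p value is the two-sided asymptotic one.
#'
#' @param a,b Numeric samples (non-empty).
#' @return list with `D` and `p`.
#' @export
ks_compare <- function(a, b) {
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  kt <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  list(D = unname(kt$statistic), p = unname(kt$p.value))
}

#' Intra-ring trait contrasts between dry, average and wet years
#'
#' For each group (e.g., species x health status), compares the intra-ring
#' distributions of lumen area and wall thickness between cells formed in
#' dry, average and wet years (three pairwise two-sample KS tests per
#' trait). Groups or classes with no cells are skipped with a warning.
#'
#' @param cells Cell table with `year`, `la`, wall columns and a grouping
#'   column named by `group`.
#' @param year_classes list with `dry`, `wet`, `average` year vectors, as
#'   returned by [classify_extreme_years()].
#' @param group Name of the grouping column (default "group"; use a
#'   constant column for a single group).
#' @param alpha Significance level (default 0.05).
#' @return data.frame `group`, `trait`, `contrast` (dry-average, dry-wet,
#'   average-wet), `D`, `p`, `significant`.
#' @export
drought_profile_contrast <- function(cells, year_classes, group = "group",
                                     alpha = 0.05) {
  stopifnot(group %in% names(cells))
  cells$..cwt <- cell_cwt(cells)
  classes <- list(dry = year_classes$dry, average = year_classes$average,
                  wet = year_classes$wet)
  pairs <- list(c("dry", "average"), c("dry", "wet"), c("average", "wet"))
  res <- list()
  for (g in unique(cells[[group]])) {
    sub <- cells[cells[[group]] == g, ]
    for (trait in c("la", "cwt")) {
      v <- if (trait == "la") sub$la else sub$..cwt
      vals <- lapply(classes, function(yrs) v[sub$year %in% yrs])
      for (p in pairs) {
        if (!length(vals[[p[1]]]) || !length(vals[[p[2]]])) {
          warning("empty year class for group ", g, "; contrast ",
                  paste(p, collapse = "-"), " skipped")
          next
        }
        kt <- ks_compare(vals[[p[1]]], vals[[p[2]]])
        res[[length(res) + 1L]] <- data.frame(
          group = g, trait = trait, contrast = paste(p, collapse = "-"),
          D = kt$D, p = kt$p, significant = kt$p <= alpha)
      }
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# compact letter display from a symmetric "not significantly different"
# relation; group counts are small, so maximal cliques are enumerated
# exhaustively
letter_display <- function(levels, pmat, alpha = 0.05) {
  k <- length(levels)
  same <- pmat > alpha
  diag(same) <- TRUE
  subsets <- lapply(seq_len(2^k - 1), function(s) which(bitwAnd(s, 2^(seq_len(k) - 1)) > 0))
  is_clique <- vapply(subsets, function(s) all(same[s, s]), logical(1))
  cliques <- subsets[is_clique]
  maximal <- vapply(seq_along(cliques), function(i)
    !any(vapply(cliques, function(c2)
      length(c2) > length(cliques[[i]]) && all(cliques[[i]] %in% c2), logical(1))),
    logical(1))
  groups <- cliques[maximal]
  groups <- groups[order(vapply(groups, min, integer(1)))]
  letters_out <- rep("", k)
  for (g in seq_along(groups))
    letters_out[groups[[g]]] <- paste0(letters_out[groups[[g]]], letters[g])
  stats::setNames(letters_out, levels)
}

#' Group comparison of ring-level traits with a height covariate
#'
#' Fits a linear mixed model `trait ~ group + height + (1 | tree_id)` to a
#' panel of repeated ring-level measurements, computes Tukey-adjusted
#' pairwise group contrasts via estimated marginal means, and summarises
#' them as a compact letter display (groups sharing a letter do not differ
#' at `alpha`). On a singular fit the function falls back to group means
#' from an ordinary linear model with heteroscedasticity-robust (HC3)
#' standard errors.
#'
#' @param panel data.frame with columns `tree_id`, `group`, `height`, and
#'   the trait column named by `trait`.
#' @param trait Name of the response column.
#' @param alpha Significance level for the letter display.
#' @return list: `estimates` (per-group marginal mean, SE, letter),
#'   `contrasts` (pairwise tests), `model`, `singular` flag.
#' @export
trait_group_comparison <- function(panel, trait, alpha = 0.05) {
  stopifnot(all(c("tree_id", "group", "height", trait) %in% names(panel)))
  if (length(unique(panel$group)) < 2) stop("need at least 2 groups")
  panel$group <- factor(panel$group)
  f <- stats::as.formula(paste(trait, "~ group + height + (1 | tree_id)"))
  fit <- suppressMessages(lme4::lmer(f, data = panel))
  singular <- lme4::isSingular(fit, tol = 1e-5)
  if (singular) {
    f0 <- stats::as.formula(paste(trait, "~ group + height"))
    fit <- stats::lm(f0, data = panel)
    emm <- emmeans::emmeans(fit, "group", vcov. = sandwich::vcovHC(fit, type = "HC3"))
  } else {
    emm <- emmeans::emmeans(fit, "group")
  }
  ctr <- summary(emmeans::contrast(emm, method = "pairwise", adjust = "tukey"))
  est <- summary(emm)
  lv <- as.character(est$group)
  pmat <- matrix(1, length(lv), length(lv), dimnames = list(lv, lv))
  for (i in seq_len(nrow(ctr))) {
    pr <- strsplit(as.character(ctr$contrast[i]), " - ", fixed = TRUE)[[1]]
    pr <- gsub("^\\(|\\)$", "", pr)
    pmat[pr[1], pr[2]] <- pmat[pr[2], pr[1]] <- ctr$p.value[i]
  }
  est$letter <- letter_display(lv, pmat, alpha)[lv]
  list(estimates = est, contrasts = ctr, model = fit, singular = singular)
}
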