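# Plantar pressure maps, anatomical region partitioning, and the validation
# statistics: region peak extraction, normality-gated paired comparison, and
# Pearson / Bland-Altman agreement.

#' Create a plantar pressure map
#'
#' A uniform grid of cell-centre coordinates (mm) with nonnegative pressures
#' (kPa), plus a foot-axis definition used to place the anatomical regions.
#'
#' @param df data frame with columns `x`, `y` (mm, uniform grid) and
#'   `pressure` (kPa, >= 0).
#' @param heel optional length-2 heel point overriding the estimated axis
#'   origin.
#' @param toe_direction optional length-2 unit vector overriding the
#'   estimated posterior-to-anterior axis.
#' @param side `"right"` or `"left"`; fixes which side of the axis is medial.
#' @return A tibble of class `pressure_map`.
#' @export
pressure_map <- function(df, heel = NULL, toe_direction = NULL,
                         side = c("right", "left")) {
  side <- match.arg(side)
  need <- c("x", "y", "pressure")
  if (!all(need %in% names(df))) abort("Need columns x, y, pressure.")
  if (any(df$pressure < 0)) abort("Pressures must be >= 0 kPa.")
  check_uniform <- function(v) {
    u <- sort(unique(round(v, 9)))
    if (length(u) > 1) {
      dd <- diff(u)
      if (max(dd) - min(dd) > 1e-6 * max(dd)) {
        abort("Grid spacing must be uniform per axis.")
      }
    }
  }
  check_uniform(df$x); check_uniform(df$y)
  out <- tibble::as_tibble(df[need])
  attr(out, "heel") <- heel
  attr(out, "toe_direction") <- toe_direction
  attr(out, "side") <- side
  class(out) <- c("pressure_map", class(out))
  out
}

# Pressure-weighted foot axis: origin at the heel centre (weighted centroid
# of the posterior 15% band along a provisional axis), direction toward the
# centroid of the anterior 15% band. Overridable via pressure_map() attrs.
foot_axis <- function(map) {
  on <- map[map$pressure > 0, ]
  if (nrow(on) == 0) abort("Empty footprint: no cells with positive pressure.")
  heel <- attr(map, "heel")
  dirv <- attr(map, "toe_direction")
  if (is.null(heel) || is.null(dirv)) {
    # provisional axis: principal direction of loaded cells, oriented +y-ish
    xy <- cbind(on$x, on$y)
    ctr <- colMeans(xy)
    ev <- eigen(stats::cov(xy))$vectors[, 1]
    if (ev[2] < 0 || (ev[2] == 0 && ev[1] < 0)) ev <- -ev
    t0 <- drop((xy - matrix(ctr, nrow(xy), 2, byrow = TRUE)) %*% ev)
    tr <- range(t0)
    wband <- function(sel) {
      w <- on$pressure[sel]
      c(sum(on$x[sel] * w), sum(on$y[sel] * w)) / sum(w)
    }
    post <- t0 <= tr[1] + 0.15 * diff(tr)
    ant <- t0 >= tr[2] - 0.15 * diff(tr)
    h <- wband(post); a <- wband(ant)
    if (is.null(dirv)) dirv <- (a - h) / sqrt(sum((a - h)^2))
    if (is.null(heel)) heel <- h
  }
  dirv <- dirv / sqrt(sum(dirv^2))
  # medial unit: left of the walking direction for a right foot
  med <- c(-dirv[2], dirv[1])
  if (identical(attr(map, "side"), "left")) med <- -med
  list(heel = heel, dir = dirv, medial = med)
}

#' Region scheme
#'
#' The seven-region barefoot scheme (medial heel, lateral heel, midfoot,
#' medial/middle/lateral forefoot, hallux) or the eight-region orthosis
#' scheme (midfoot split into medial and lateral). Boundary fractions are a
#' package convention and configurable: longitudinal heel/midfoot/forefoot/toe
#' cuts at 0.30/0.60/0.85 of footprint length; forefoot width cuts at
#' 0.40/0.70 medial-to-lateral.
#'
#' @param name `"SEVEN"` or `"EIGHT"`.
#' @param long_cuts length-3 increasing fractions in (0,1).
#' @param width_cuts length-2 increasing fractions in (0,1).
#' @return A `region_scheme` object with ordered `$regions`.
#' @export
region_scheme <- function(name = c("SEVEN", "EIGHT"),
                          long_cuts = c(0.30, 0.60, 0.85),
                          width_cuts = c(0.40, 0.70)) {
  name <- match.arg(toupper(name), c("SEVEN", "EIGHT"))
  if (any(diff(long_cuts) <= 0) || any(long_cuts <= 0) || any(long_cuts >= 1)) {
    abort("`long_cuts` must be increasing fractions in (0, 1).")
  }
  regions <- if (name == "SEVEN") {
    c("medial heel", "lateral heel", "midfoot", "medial forefoot",
      "middle forefoot", "lateral forefoot", "hallux")
  } else {
    c("medial heel", "lateral heel", "medial midfoot", "lateral midfoot",
      "medial forefoot", "middle forefoot", "lateral forefoot", "hallux")
  }
  structure(list(name = name, regions = regions,
                 long_cuts = long_cuts, width_cuts = width_cuts),
            class = "region_scheme")
}

#' Partition a pressure map into anatomical regions
#'
#' Longitudinal bands by fraction of footprint length along the foot axis
#' (heel, midfoot, forefoot, toes), a medial/lateral split at the axis line
#' for heel (and midfoot in the eight-region scheme), forefoot columns by
#' medial-to-lateral width fraction, and the hallux as the medial third of
#' the toe band (remaining toe cells join the adjacent forefoot columns so
#' the masks cover every loaded cell). Masks are disjoint by construction
#' and verified to cover all cells with positive pressure.
#'
#' @param map a [pressure_map()].
#' @param scheme a [region_scheme()].
#' @return The map tibble with an added `region` factor column (ordered by
#'   the scheme), `NA` outside the loaded footprint's bands.
#' @export
partition_regions <- function(map, scheme = region_scheme("SEVEN")) {
  ax <- foot_axis(map)
  on <- map$pressure > 0
  tcoord <- (map$x - ax$heel[1]) * ax$dir[1] + (map$y - ax$heel[2]) * ax$dir[2]
  mcoord <- (map$x - ax$heel[1]) * ax$medial[1] + (map$y - ax$heel[2]) * ax$medial[2]
  tr <- range(tcoord[on])
  tfrac <- (tcoord - tr[1]) / (tr[2] - tr[1])
  lc <- scheme$long_cuts
  band <- cut(pmin(pmax(tfrac, 0), 1), c(-Inf, lc, Inf),
              labels = c("heel", "midfoot", "forefoot", "toes"))
  # width fraction, medial (0) to lateral (1), within the loaded footprint of
  # the forefoot + toe bands
  fore <- on & band %in% c("forefoot", "toes")
  region <- rep(NA_character_, nrow(map))
  if (!any(fore)) abort("Footprint has no forefoot band cells.")
  wr <- range(mcoord[fore])
  wfrac <- (wr[2] - mcoord) / (wr[2] - wr[1])   # medial has the largest mcoord
  wc <- scheme$width_cuts
  heel_sel <- band == "heel"
  region[heel_sel & mcoord >= 0] <- "medial heel"
  region[heel_sel & mcoord < 0] <- "lateral heel"
  mid_sel <- band == "midfoot"
  if (scheme$name == "SEVEN") {
    region[mid_sel] <- "midfoot"
  } else {
    region[mid_sel & mcoord >= 0] <- "medial midfoot"
    region[mid_sel & mcoord < 0] <- "lateral midfoot"
  }
  fore_sel <- band == "forefoot"
  region[fore_sel & wfrac <= wc[1]] <- "medial forefoot"
  region[fore_sel & wfrac > wc[1] & wfrac <= wc[2]] <- "middle forefoot"
  region[fore_sel & wfrac > wc[2]] <- "lateral forefoot"
  toe_sel <- band == "toes"
  region[toe_sel & wfrac <= 1 / 3] <- "hallux"
  region[toe_sel & wfrac > 1 / 3 & wfrac <= wc[2]] <- "middle forefoot"
  region[toe_sel & wfrac > wc[2]] <- "lateral forefoot"
  if (any(on & is.na(region))) {
    abort("Internal error: region masks do not cover the loaded footprint.")
  }
  out <- map
  out$region <- factor(region, levels = scheme$regions)
  out$region[!on] <- NA
  attr(out, "scheme") <- scheme
  out
}

#' Peak pressure per region
#'
#' @param map a partitioned map from [partition_regions()], or a raw
#'   [pressure_map()] (partitioned with `scheme` first).
#' @param scheme region scheme used when `map` is unpartitioned.
#' @return Tibble `region`, `peak_kpa` in scheme order; empty regions get 0
#'   with a warning.
#' @export
region_peaks <- function(map, scheme = region_scheme("SEVEN")) {
  if (!"region" %in% names(map)) map <- partition_regions(map, scheme)
  sch <- attr(map, "scheme") %||% scheme
  peaks <- vapply(sch$regions, function(r) {
    v <- map$pressure[!is.na(map$region) & map$region == r]
    if (!length(v)) NA_real_ else max(v)
  }, numeric(1))
  if (anyNA(peaks)) {
    warn(sprintf("Empty region(s): %s; peak reported as 0.",
                 paste(names(peaks)[is.na(peaks)], collapse = ", ")))
    peaks[is.na(peaks)] <- 0
  }
  tibble::tibble(region = factor(sch$regions, levels = sch$regions),
                 peak_kpa = unname(peaks))
}

#' Normality-gated paired comparison of region peaks
#'
#' Tests the paired differences for normality with the Shapiro-Wilk test at
#' `alpha`; if normality is not rejected a paired t test is used, otherwise
#' the Wilcoxon matched-pairs signed-rank test (exact p for n <= 25 without
#' ties, normal approximation with continuity correction above). Two-sided
#' throughout. All-zero differences give the degenerate result p = 1 on the
#' Wilcoxon branch.
#'
#' @param a,b paired numeric vectors (e.g. measured and predicted peak
#'   pressures), length >= 3.
#' @param alpha significance level gate for the normality test (default 0.05).
#' @param test `"auto"` (the gate above), or force `"paired-t"` /
#'   `"wilcoxon"`.
#' @return One-row tibble of class `paired_comparison`: `test`,
#'   `normality_p`, `statistic`, `p_value`, `mean_difference`, `n`, `alpha`.
#' @export
compare_paired <- function(a, b, alpha = 0.05,
                           test = c("auto", "paired-t", "wilcoxon")) {
  test <- match.arg(test)
  if (length(a) != length(b)) abort("Paired samples must have equal length.")
  n <- length(a)
  if (n < 3) abort("Need at least 3 pairs.")
  d <- a - b
  if (all(d == 0)) {
    out <- tibble::tibble(test = "wilcoxon", normality_p = NA_real_,
                          statistic = NA_real_, p_value = 1,
                          mean_difference = 0, n = n, alpha = alpha)
    class(out) <- c("paired_comparison", class(out))
    return(out)
  }
  norm_p <- if (diff(range(d)) == 0) NA_real_ else shapiro.test(d)$p.value
  if (test == "auto") {
    test <- if (!is.na(norm_p) && norm_p > alpha) "paired-t" else "wilcoxon"
  }
  if (test == "paired-t") {
    tt <- t.test(a, b, paired = TRUE)
    stat <- unname(tt$statistic); p <- tt$p.value
  } else {
    wt <- suppressWarnings(
      wilcox.test(a, b, paired = TRUE, exact = n <= 25, correct = TRUE))
    stat <- unname(wt$statistic); p <- wt$p.value
  }
  out <- tibble::tibble(test = test, normality_p = norm_p, statistic = stat,
                        p_value = p, mean_difference = mean(d), n = n,
                        alpha = alpha)
  class(out) <- c("paired_comparison", class(out))
  out
}

#' Pearson correlation and Bland-Altman agreement
#'
#' Pearson product-moment correlation between measured and predicted values,
#' plus the Bland-Altman mean offset `mean(predicted - measured)` and 95%
#' limits of agreement `offset +/- 1.96 sd(differences)`.
#'
#' @param measured,predicted equal-length numeric vectors (>= 3, each with
#'   nonzero variance for the correlation).
#' @return One-row tibble of class `agreement_result`: `pearson_r`,
#'   `pearson_p`, `offset`, `loa_lower`, `loa_upper`, `n`.
#' @export
agreement <- function(measured, predicted) {
  if (length(measured) != length(predicted)) abort("Vectors must have equal length.")
  if (length(measured) < 3) abort("Need at least 3 pairs.")
  if (sd(measured) == 0 || sd(predicted) == 0) {
    abort("Zero variance: Pearson correlation undefined.")
  }
  ct <- cor.test(measured, predicted, method = "pearson")
  d <- predicted - measured
  off <- mean(d); s <- sd(d)
  out <- tibble::tibble(
    pearson_r = unname(ct$estimate), pearson_p = ct$p.value,
    offset = off, loa_lower = off - 1.96 * s, loa_upper = off + 1.96 * s,
    n = length(d)
  )
  class(out) <- c("agreement_result", class(out))
  out
}

#' Plot a pressure map
#'
#' @param object a [pressure_map()] (optionally partitioned).
#' @param ... unused.
#' @return A ggplot tile map; faceted outline colours show regions when the
#'   map is partitioned.
#' @export
autoplot.pressure_map <- function(object, ...) {
  df <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(df[df$pressure > 0, ],
                       ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$pressure)) +
    ggplot2::scale_fill_viridis_c(option = "inferno") +
    ggplot2::coord_equal() +
    ggplot2::labs(fill = "kPa", x = "x (mm)", y = "y (mm)",
                  title = "Plantar pressure") +
    ggplot2::theme_minimal()
  if ("region" %in% names(df)) {
    p <- p + ggplot2::geom_point(
      data = df[!is.na(df$region), ],
      ggplot2::aes(colour = .data$region), size = 0.3, alpha = 0.5) +
      ggplot2::labs(colour = "region")
  }
  p
}

#' Bland-Altman plot from paired vectors
#'
#' @param measured,predicted paired numeric vectors.
#' @return A ggplot with the mean-difference line and 95% limits of
#'   agreement.
#' @export
plot_bland_altman <- function(measured, predicted) {
  ag <- agreement(measured, predicted)
  df <- tibble::tibble(mean = (measured + predicted) / 2,
                       difference = predicted - measured)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean, y = .data$difference)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = ag$offset, colour = "blue") +
    ggplot2::geom_hline(yintercept = c(ag$loa_lower, ag$loa_upper),
                        linetype = "dashed") +
    ggplot2::labs(x = "mean of pair (kPa)", y = "predicted - measured (kPa)",
                  title = sprintf("Bland-Altman: offset %.1f kPa", ag$offset)) +
    ggplot2::theme_minimal()
}
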