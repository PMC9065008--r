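# Range-through diversity trajectories on a fine age grid, slope series,
# and discrete-bin boundary-crosser counts with per-capita (Foote)
# origination/extinction rates.

#' Range-through diversity trajectory
#'
#' Counts, at every grid age `t`, the lineages whose closed interval
#' `[Te, Ts]` covers `t` (ties at grid ages count as present).
#'
#' @param lifespans a `lifespan_table`.
#' @param step grid step in Myr (default 0.1).
#' @param max_age oldest grid age; defaults to `ceiling(max(Ts))`.
#' @param replicate_index stored replicate label.
#' @return data frame of class `diversity_trajectory` with descending
#'   `age` and integer `count`.
#' @export
range_through <- function(lifespans, step = 0.1, max_age = NULL,
                          replicate_index = 1L) {
  top <- if (is.null(max_age)) {
    if (nrow(lifespans)) ceiling(max(lifespans$ts)) else 1
  } else max_age
  # round away accumulated fp error so ties at grid ages are exact
  grid <- round(seq(top, 0, by = -step), 9)
  if (nrow(lifespans) == 0L) {
    counts <- integer(length(grid))
  } else {
    sts <- sort(lifespans$ts); ste <- sort(lifespans$te)
    n <- length(sts)
    # N(t) = #(ts >= t) - #(te > t)
    counts <- (n - findInterval(grid, sts, left.open = TRUE)) -
      (n - findInterval(grid, ste))
  }
  out <- data.frame(age = grid, count = as.integer(counts))
  attr(out, "replicate_index") <- replicate_index
  class(out) <- c("diversity_trajectory", "data.frame")
  out
}

#' Diversity slope series
#'
#' Difference in diversity between subsequent time samples, backwards
#' from the present: the slope at the younger age of each adjacent pair
#' is `D(younger) - D(older)` (species per grid step). Optionally reports
#' the mean slope over an age window.
#'
#' @param trajectory a `diversity_trajectory`.
#' @param window optional `c(oldest, youngest)` ages (Ma) over which to
#'   average the slope (e.g. `c(12, 0)` for the last 12 Myr).
#' @return list with `series` (data frame `age`, `slope`) and
#'   `mean_slope` (NA when no window given).
#' @export
diversity_slope <- function(trajectory, window = NULL) {
  if (nrow(trajectory) < 2L) stop("trajectory needs at least 2 points")
  age <- trajectory$age            # descending
  cnt <- trajectory$count
  slope <- cnt[-1L] - cnt[-length(cnt)]   # D(younger) - D(older)
  s_age <- age[-1L]
  mean_slope <- NA_real_
  if (!is.null(window)) {
    if (window[1L] > max(age) || window[2L] < min(age))
      stop("window outside trajectory grid")
    sel <- s_age <= window[1L] & s_age >= window[2L]
    mean_slope <- mean(slope[sel])
  }
  list(series = data.frame(age = s_age, slope = slope),
       mean_slope = mean_slope)
}

#' Boundary-crosser counts in discrete time bins
#'
#' Resolves each species' binned range (first and last appearance bins,
#' from point occurrence ages) and classifies species in every bin as
#' both-boundary crossers (`n_bt`), bottom-only crossers extinct in the
#' bin (`n_bL`), top-only crossers originating in the bin (`n_Ft`) or
#' singletons confined to the bin (`n_FL`). Extant species' ranges extend
#' through the youngest bin.
#'
#' @param table an `occurrence_table`.
#' @param replicate optional `age_replicate` resolving point ages
#'   (default: range midpoints).
#' @param bins strictly decreasing bin boundaries ending at 0.
#' @return data frame of class `binned_counts` with one row per bin
#'   (oldest first): bin bounds, the four class counts and `dt`.
#' @export
bin_occurrence_ranges <- function(table, replicate = NULL, bins) {
  bins <- as.numeric(bins)
  if (any(diff(bins) >= 0)) stop("bin boundaries must be strictly decreasing")
  nb <- length(bins) - 1L
  ages <- if (is.null(replicate)) (table$min_ma + table$max_ma) / 2
          else replicate$ages[table$occurrence_id]
  asc <- rev(bins)
  i <- findInterval(ages, asc, left.open = TRUE)
  i[i == 0L] <- 1L
  bin_of <- nb + 1L - i            # bin 1 = oldest
  sp <- factor(table$species_name)
  b_fa <- tapply(bin_of, sp, min)  # oldest bin touched
  b_la <- tapply(bin_of, sp, max)
  ext <- tapply(table$extant, sp, any)
  b_la[ext] <- nb                  # extant ranges reach the present
  counts <- matrix(0L, nb, 4L,
                   dimnames = list(NULL, c("n_bt", "n_bL", "n_Ft", "n_FL")))
  for (s in seq_along(b_fa)) {
    f <- b_fa[s]; l <- b_la[s]
    if (f == l) counts[f, "n_FL"] <- counts[f, "n_FL"] + 1L
    else {
      counts[f, "n_Ft"] <- counts[f, "n_Ft"] + 1L
      counts[l, "n_bL"] <- counts[l, "n_bL"] + 1L
      if (l > f + 1L) {
        mid <- (f + 1L):(l - 1L)
        counts[mid, "n_bt"] <- counts[mid, "n_bt"] + 1L
      }
    }
  }
  out <- data.frame(bin_old = bins[-length(bins)], bin_young = bins[-1L],
                    counts, dt = bins[-length(bins)] - bins[-1L])
  class(out) <- c("binned_counts", "data.frame")
  out
}

#' Per-capita (Foote) origination and extinction rates
#'
#' From boundary-crosser counts per bin of width `dt`:
#' `p_hat = log((n_bt + n_Ft) / n_bt) / dt` and
#' `q_hat = log((n_bt + n_bL) / n_bt) / dt`. Singletons (`n_FL`) enter
#' neither numerator nor denominator. Bins with `n_bt = 0` are flagged
#' undefined (`NA` rates), not errors.
#'
#' @param counts a `binned_counts` data frame.
#' @return the input with columns `p_hat`, `q_hat` and logical `defined`
#'   appended; class `per_capita_rates`.
#' @export
foote_rates <- function(counts) {
  defined <- counts$n_bt > 0L
  p_hat <- q_hat <- rep(NA_real_, nrow(counts))
  p_hat[defined] <- log((counts$n_bt[defined] + counts$n_Ft[defined]) /
                          counts$n_bt[defined]) / counts$dt[defined]
  q_hat[defined] <- log((counts$n_bt[defined] + counts$n_bL[defined]) /
                          counts$n_bt[defined]) / counts$dt[defined]
  out <- cbind(counts, p_hat = p_hat, q_hat = q_hat, defined = defined)
  class(out) <- c("per_capita_rates", "data.frame")
  out
}

#' Range-through diversity per discrete bin
#' @param counts a `binned_counts` data frame.
#' @return integer vector: `n_bt + n_bL + n_Ft + n_FL` per bin.
#' @export
binned_range_through <- function(counts) {
  as.integer(counts$n_bt + counts$n_bL + counts$n_Ft + counts$n_FL)
}

#' Lifespans snapped to first/last-appearance bin edges
#'
#' The resolution discrete binned data can support: each species'
#' origination is placed at the older edge of its first-appearance bin
#' and its extinction at the younger edge of its last-appearance bin
#' (0 for extant species). Used to compare the continuous range-through
#' path against the discrete-bin path on equal footing.
#'
#' @inheritParams bin_occurrence_ranges
#' @return a `lifespan_table`.
#' @export
lifespans_from_bins <- function(table, replicate = NULL, bins) {
  bins <- as.numeric(bins)
  nb <- length(bins) - 1L
  ages <- if (is.null(replicate)) (table$min_ma + table$max_ma) / 2
          else replicate$ages[table$occurrence_id]
  asc <- rev(bins)
  i <- findInterval(ages, asc, left.open = TRUE)
  i[i == 0L] <- 1L
  bin_of <- nb + 1L - i
  sp <- factor(table$species_name)
  b_fa <- tapply(bin_of, sp, min)
  b_la <- tapply(bin_of, sp, max)
  ext <- as.logical(tapply(table$extant, sp, any))
  ts <- bins[b_fa]                  # older edge of FA bin
  te <- bins[b_la + 1L]             # younger edge of LA bin
  te[ext] <- 0
  lifespan_table(levels(sp), ts, te, ext)
}
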