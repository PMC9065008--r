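# Range-through diversity, slope series, boundary-crosser counts and
# per-capita rates.

test_that("range-through counts match direct interval stabbing", {
  lf <- lifespan_table(c("a", "b"), c(10, 7), c(5, 0), c(FALSE, TRUE))
  tr <- range_through(lf, step = 1)
  expect_equal(tr$count[tr$age == 6], 2L)
  expect_equal(tr$count[tr$age == 10], 1L)
  expect_equal(tr$count[tr$age == 3], 1L)
  # ties at grid ages count as present (closed [Te, Ts])
  expect_equal(tr$count[tr$age == 5], 2L)
  expect_equal(tr$count[tr$age == 7], 2L)
  # empty table -> all-zero trajectory
  empty <- lifespan_table(character(0), numeric(0), numeric(0), logical(0))
  expect_true(all(range_through(empty, step = 1, max_age = 5)$count == 0L))
})

test_that("range-through equals a brute-force oracle on random lifespans", {
  set.seed(41)
  n <- 10000
  ts <- runif(n, 0.5, 30)
  te <- ts * runif(n)
  lf <- lifespan_table(sprintf("s%d", 1:n), ts, te, FALSE)
  tr <- range_through(lf, step = 0.5)
  brute <- vapply(tr$age, function(t) sum(te <= t & t <= ts), 0)
  expect_identical(tr$count, as.integer(brute))
})

test_that("range-through is monotone under lifespan extension", {
  set.seed(42)
  lf <- lifespan_table(sprintf("s%d", 1:200), runif(200, 5, 20),
                       runif(200, 0, 4))
  tr1 <- range_through(lf, step = 0.5)
  lf2 <- lf
  lf2$ts <- lf2$ts + runif(200, 0, 2)
  lf2$te <- pmax(lf2$te - runif(200, 0, 2), 0)
  tr2 <- range_through(lf2, step = 0.5, max_age = max(tr1$age))
  expect_true(all(tr2$count >= tr1$count))
})

test_that("diversity slopes follow the backwards-difference definition", {
  # D(3.0) = 10, D(2.9) = 12 -> slope at 2.9 is +2 per 0.1 Myr
  tr <- structure(data.frame(age = c(3.0, 2.9, 2.8),
                             count = c(10L, 12L, 12L)),
                  class = c("diversity_trajectory", "data.frame"))
  sl <- diversity_slope(tr, window = c(3, 2.8))
  expect_equal(sl$series$slope[sl$series$age == 2.9], 2)
  expect_equal(sl$mean_slope, 1)
  # constant trajectory -> all slopes zero
  cst <- structure(data.frame(age = seq(5, 0, by = -0.1), count = 7L),
                   class = c("diversity_trajectory", "data.frame"))
  expect_true(all(diversity_slope(cst)$series$slope == 0))
  # a linear ramp has constant slope equal to its increment
  ramp <- structure(data.frame(age = seq(10, 0, by = -0.1),
                               count = seq(0, 100)),
                    class = c("diversity_trajectory", "data.frame"))
  sr <- diversity_slope(ramp, window = c(10, 0))
  expect_true(all(sr$series$slope == 1))
  expect_equal(sr$mean_slope, 1)
  expect_error(diversity_slope(ramp, window = c(50, 20)), "window")
})

test_that("boundary-crosser classes follow their definitions", {
  # one species spanning bins 2-5 (ages: FA in (15,16], LA in (12,13])
  tab <- occurrence_table(data.frame(
    species_name = c("A a", "A a", "B b"),
    min_ma = c(15.5, 12.5, 14.5), max_ma = c(15.5, 12.5, 14.5)))
  counts <- bin_occurrence_ranges(tab, bins = myr_bins(17))
  # bins indexed oldest first: bin 1 = (16,17], bin 2 = (15,16] ...
  a_bt <- counts$n_bt
  expect_equal(sum(a_bt), 2L)              # species A crosses bins 3 and 4
  expect_equal(which(a_bt == 1L), c(3L, 4L))
  expect_equal(counts$n_Ft[2], 1L)         # A originates in bin 2
  expect_equal(counts$n_bL[5], 1L)         # A ends in bin 5
  expect_equal(counts$n_FL[3], 1L)         # B is a singleton in bin 3
  # range-through identity: the four classes partition presences
  expect_equal(binned_range_through(counts)[2:5], c(1L, 2L, 1L, 1L))
})

test_that("binned classification matches brute-force enumeration", {
  set.seed(43)
  n <- 1000
  fa <- runif(n, 1, 24); la <- fa * runif(n)
  tab <- occurrence_table(data.frame(
    species_name = rep(sprintf("s%d u", 1:n), 2),
    min_ma = c(fa, la), max_ma = c(fa, la)))
  bins <- myr_bins(25)
  counts <- bin_occurrence_ranges(tab, bins = bins)
  bin_of <- function(a) {
    i <- findInterval(a, rev(bins), left.open = TRUE)
    length(bins) - 1L - max(i - 1L, 0L)
  }
  nb <- length(bins) - 1L
  brute <- matrix(0L, nb, 4)
  for (s in 1:n) {
    f <- bin_of(fa[s]); l <- bin_of(la[s])
    for (b in f:l) {
      cls <- if (f == l) 4L else if (b == f) 3L else if (b == l) 2L else 1L
      brute[b, cls] <- brute[b, cls] + 1L
    }
  }
  expect_equal(counts$n_bt, brute[, 1])
  expect_equal(counts$n_bL, brute[, 2])
  expect_equal(counts$n_Ft, brute[, 3])
  expect_equal(counts$n_FL, brute[, 4])
})

test_that("Foote per-capita rates match their closed form", {
  counts <- data.frame(bin_old = 2, bin_young = 1, n_bt = 50L, n_bL = 10L,
                       n_Ft = 20L, n_FL = 5L, dt = 1)
  fr <- foote_rates(counts)
  expect_equal(fr$q_hat, log(1.2), tolerance = 1e-10)
  expect_equal(fr$p_hat, log(1.4), tolerance = 1e-10)
  # no crossers entering/leaving -> both rates zero
  z <- foote_rates(data.frame(bin_old = 2, bin_young = 1, n_bt = 30L,
                              n_bL = 0L, n_Ft = 0L, n_FL = 2L, dt = 1))
  expect_equal(z$p_hat, 0); expect_equal(z$q_hat, 0)
  # no both-crossers -> undefined, flagged, not an error
  u <- foote_rates(data.frame(bin_old = 2, bin_young = 1, n_bt = 0L,
                              n_bL = 3L, n_Ft = 1L, n_FL = 0L, dt = 1))
  expect_false(u$defined)
  expect_true(is.na(u$p_hat) && is.na(u$q_hat))
})

test_that("Foote rates track true rates on a well-sampled simulation", {
  h <- simulate_bd(sim_params(18, 3, 0.4, 0.2, seed = 3))
  occ <- simulate_preservation(h, pres_hpp(8), seed = 44)
  fr <- foote_rates(bin_occurrence_ranges(occ, bins = myr_bins(18)))
  interior <- fr$defined & fr$bin_old <= 14 & fr$bin_young >= 2 &
    fr$n_bt >= 20
  # binomial-ish standard errors: se(q_hat) ~ sqrt(n_bL)/n_bt
  se_q <- sqrt(pmax(fr$n_bL, 1)) / fr$n_bt
  se_p <- sqrt(pmax(fr$n_Ft, 1)) / fr$n_bt
  expect_gt(mean(abs(fr$q_hat[interior] - 0.2) < 2 * se_q[interior]), 0.7)
  expect_gt(mean(abs(fr$p_hat[interior] - 0.4) < 2 * se_p[interior]), 0.7)
  expect_lt(abs(mean(fr$p_hat[interior]) - 0.4), 0.12)
  expect_lt(abs(mean(fr$q_hat[interior]) - 0.2), 0.12)
})

test_that("continuous and binned range-through paths agree when snapped", {
  h <- simulate_bd(sim_params(18, 3, 0.4, 0.2, seed = 3))
  occ <- simulate_preservation(h, pres_hpp(8), seed = 45)
  bins <- myr_bins(18)
  counts <- bin_occurrence_ranges(occ, bins = bins)
  lf <- lifespans_from_bins(occ, bins = bins)
  tr <- range_through(lf, step = 0.1, max_age = 18)
  mids <- (counts$bin_old + counts$bin_young) / 2
  cont <- tr$count[match(round(mids, 9), round(tr$age, 9))]
  expect_true(all(abs(cont - binned_range_through(counts)) <= 1))
})
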