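d0 <- as.POSIXct("2023-05-01 00:00:00", tz = "UTC")

test_that("buzz_per_hour: formula, zero counts, missing when unrecorded", {
  expect_equal(buzz_per_hour(6, 12), 30)
  expect_equal(buzz_per_hour(0, 12), 0)
  expect_equal(buzz_per_hour(13, 72), 13 / 72 * 60)
  expect_true(is.na(buzz_per_hour(3, 0)))
  # linearity in count; halving recorded minutes doubles the rate
  set.seed(3)
  n <- rpois(20, 10); m <- runif(20, 1, 60)
  expect_equal(buzz_per_hour(2 * n, m), 2 * buzz_per_hour(n, m))
  expect_equal(buzz_per_hour(n, m / 2), 2 * buzz_per_hour(n, m))
})

test_that("standardize_counts divides abundance by replicates", {
  s <- data.frame(site_id = "A", period = "apr", method = "pan_trap",
                  n_replicates = c(4, 6, 2),
                  total_abundance = c(40, 0, 17),
                  flying_abundance = c(20, 0, 17))
  out <- standardize_counts(s)
  expect_equal(out$std_total, c(10, 0, 8.5))
  expect_equal(out$std_flying, c(5, 0, 8.5))
  s$n_replicates[1] <- 0
  expect_error(standardize_counts(s), "n_replicates")
})

test_that("activity_series bins events and attaches recorded minutes", {
  sched <- duty_cycle_schedule()
  ev <- data.frame(device_id = "d1", site_id = "A",
                   event_time = d0 + c(10 * 3600 + c(60, 120, 300),  # 10:0x, in window
                                       11 * 3600 + 30 * 60))        # 11:30, off-window
  act <- activity_series(ev, sched, start = d0 + 10 * 3600,
                         end = d0 + 12 * 3600,
                         devices = data.frame(device_id = "d1", site_id = "A"))
  expect_equal(nrow(act), 2L)
  expect_equal(act$buzz_count, c(3L, 1L))
  expect_equal(act$recorded_min, c(12, 12))
  expect_equal(act$buzz_per_hour, c(15, 5))
})

test_that("hourly_site_mean averages across devices and matches brute force", {
  act <- data.frame(device_id = rep(c("d1", "d2", "d3", "d4"), 2),
                    site_id = "A",
                    hour_start = rep(c(d0 + 10 * 3600, d0 + 11 * 3600), each = 4),
                    buzz_count = 1, recorded_min = 12,
                    buzz_per_hour = c(10, 20, 30, 40, 5, 5, 5, 5))
  expect_equal(hourly_site_mean(act, "A", 10), 25)
  expect_equal(hourly_site_mean(act, "A", 11), 5)
  expect_true(is.na(hourly_site_mean(act, "A", 12)))
  expect_equal(hourly_site_mean(act[1, ], "A", 10), 10)  # single device: identity

  set.seed(8)
  big <- data.frame(device_id = sample(paste0("d", 1:4), 300, TRUE),
                    site_id = sample(c("A", "B"), 300, TRUE),
                    hour_start = d0 + sample(0:71, 300, TRUE) * 3600,
                    buzz_count = 0, recorded_min = 12,
                    buzz_per_hour = runif(300, 0, 50))
  for (h in c(0, 7, 15)) {
    sel <- big$site_id == "A" &
      as.numeric(format(big$hour_start, "%H")) == h
    expect_equal(hourly_site_mean(big, "A", h), mean(big$buzz_per_hour[sel]))
  }
})

test_that("temperature binning: conventions, SE, and linear-scan oracle", {
  temps <- data.frame(site_id = "A", hour_start = d0 + (0:99) * 3600,
                      temperature = seq(10, 35, length.out = 100))
  act <- data.frame(device_id = "d1", site_id = "A",
                    hour_start = d0 + (0:99) * 3600,
                    buzz_count = 1, recorded_min = 12,
                    buzz_per_hour = rep(10, 100))
  out <- bin_by_temperature(act, temps)
  expect_equal(out$bin, c("<15", "15-20", "20-25", "25-30", "30+"))
  expect_equal(sum(out$n), 100)

  # left-closed edges: T = 20 goes to "20-25", T = 22 too
  one <- function(tval) {
    t1 <- data.frame(site_id = "A", hour_start = d0, temperature = tval)
    a1 <- act[1, ]
    o <- bin_by_temperature(a1, t1)
    o$bin[o$n == 1]
  }
  expect_equal(one(22), "20-25")
  expect_equal(one(20), "20-25")
  expect_equal(one(14.9), "<15")
  expect_equal(one(30), "30+")

  # SE = sd/sqrt(n) with n-1 denominator
  act2 <- act[1:4, ]
  act2$buzz_per_hour <- c(1, 2, 3, 4)
  t2 <- temps[1:4, ]; t2$temperature <- 22
  o2 <- bin_by_temperature(act2, t2)
  expect_equal(o2$se[o2$bin == "20-25"], sd(c(1, 2, 3, 4)) / 2)

  # bin assignment equals the linear-scan oracle on 1000 random temperatures
  set.seed(13)
  tt <- runif(1000, 5, 40)
  edges <- c(15, 20, 25, 30)
  got <- findInterval(tt, edges) + 1L
  exp <- vapply(tt, oracle_temp_bin, 1L, edges = edges)
  expect_identical(got, exp)

  # hours without temperature rows are excluded with a warning
  expect_warning(bin_by_temperature(act, temps[1:50, ]), "lack temperature")
})

test_that("pearson_r: exact cases, oracle, and affine invariance", {
  expect_equal(pearson_r(c(1, 2, 3), c(2, 4, 6))$r, 1)
  expect_equal(pearson_r(c(1, 2, 3), c(3, 2, 1))$r, -1)

  x <- c(1, 2, 3, 4); y <- c(2, 4, 5, 4)
  # brute-force covariance formula
  r_exp <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  got <- pearson_r(x, y)
  expect_equal(got$r, r_exp)
  ct <- cor.test(x, y)
  expect_equal(got$r, unname(ct$estimate))
  expect_equal(got$p, ct$p.value)

  set.seed(17)
  for (i in 1:20) {
    x <- rnorm(10); y <- rnorm(10)
    r0 <- pearson_r(x, y)$r
    a <- runif(1, 0.1, 5); b <- rnorm(1); c_ <- runif(1, 0.1, 5); d_ <- rnorm(1)
    expect_equal(pearson_r(a * x + b, c_ * y + d_)$r, r0)
    expect_lte(abs(r0), 1)
  }
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(pearson_r(1:2, 1:2), "n >= 3")
})

test_that("buzz/h is an unbiased rate estimator through the duty cycle", {
  # homogeneous Poisson process at rate lambda/h observed through the
  # default schedule; mean buzz/h over many simulated days must sit within
  # 3 SE of lambda. Event-level simulation (no waveforms).
  sched <- duty_cycle_schedule()
  rec_min <- vapply(0:23, function(h)
    recorded_minutes(sched, d0 + h * 3600, d0 + (h + 1) * 3600), 0)
  set.seed(29)
  for (lambda in c(5, 30, 120)) {
    n_days <- 200
    rates <- numeric(0)
    for (day in seq_len(n_days)) {
      n <- rpois(1, lambda * 24)
      tt <- runif(n, 0, 86400)
      kept <- tt[is_recorded(sched, d0 + tt)]
      hr <- floor(kept / 3600)
      counts <- tabulate(hr + 1L, nbins = 24)
      rates <- c(rates, buzz_per_hour(counts, rec_min))
    }
    m <- mean(rates); se <- sd(rates) / sqrt(length(rates))
    expect_lt(abs(m - lambda), 3 * se)
  }
})

test_that("compare_daytime_vs_24h separates diurnal from uniform activity", {
  hours <- seq(d0, d0 + 14 * 86400 - 3600, by = "1 hour")
  hod <- as.numeric(format(hours, "%H"))
  base <- data.frame(device_id = "d1", site_id = "A", hour_start = hours,
                     buzz_count = 0, recorded_min = 12)
  # all activity at night
  night <- base; night$buzz_per_hour <- ifelse(hod < 6 | hod >= 21, 10, 0)
  out <- compare_daytime_vs_24h(night, "A")
  expect_true(all(out$mean_daytime == 0))
  expect_true(all(out$mean_24h > 0))
  # uniform activity: the two means agree
  unif <- base; unif$buzz_per_hour <- 7
  out2 <- compare_daytime_vs_24h(unif, "A")
  expect_equal(out2$mean_daytime, out2$mean_24h)
  # diurnal excess: daytime mean exceeds the 24 h mean
  diur <- base; diur$buzz_per_hour <- ifelse(hod >= 6 & hod < 21, 12, 10)
  out3 <- compare_daytime_vs_24h(diur, "A")
  expect_true(all(out3$mean_daytime > out3$mean_24h))
})

test_that("site_period_buzz restricts to the survey window and date range", {
  hours <- seq(d0, d0 + 4 * 86400 - 3600, by = "1 hour")
  hod <- as.numeric(format(hours, "%H"))
  act <- data.frame(device_id = "d1", site_id = "A", hour_start = hours,
                    buzz_count = 0, recorded_min = 12,
                    buzz_per_hour = ifelse(hod %in% 10:15, 30, 999))
  periods <- data.frame(period = c("p1", "p2"),
                        start = c("2023-05-01", "2023-05-03"),
                        end = c("2023-05-02", "2023-05-04"))
  spb <- site_period_buzz(act, periods)
  expect_equal(nrow(spb), 2L)
  expect_equal(spb$buzz_per_hour, c(30, 30))  # off-window 999s never included
})

test_that("correlate_surveys joins on site x period and correlates", {
  spb <- data.frame(site_id = rep(c("A", "B", "C", "D"), 2),
                    period = rep(c("apr", "jun"), each = 4),
                    buzz_per_hour = c(10, 8, 6, 2, 12, 9, 7, 3))
  surveys <- standardize_counts(data.frame(
    site_id = rep(c("A", "B", "C", "D"), 2),
    period = rep(c("apr", "jun"), each = 4), method = "pan_trap",
    n_replicates = 4,
    total_abundance = 4 * c(20, 17, 13, 5, 25, 19, 15, 7)))
  res <- correlate_surveys(spb, surveys, method = "pan_trap")
  expect_equal(res$n, 8)
  expect_gt(res$r, 0.95)  # construction is nearly linear
  expect_equal(res$r, cor(res$data$buzz_per_hour, res$data$std_count))
})
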