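# Small hand-made batch tables for the summary and survival contracts.
mini_batch <- function(days, censored, n = 10, ratio = 1, transfer = 50) {
  tibble::tibble(n = n, C = 0.005, lambda1 = 0.25, lambda2 = 0.25,
                 transfer = transfer, ratio = ratio,
                 replicate = seq_along(days), seed = seq_along(days),
                 days = as.integer(days), censored = censored,
                 viable = !censored & days >= 90 & days <= 900)
}

test_that("condition summaries respect the censoring policy", {
  b <- mini_batch(c(5, 5, 5), c(FALSE, FALSE, FALSE))
  s <- summarize_batch(b, "exclude")
  expect_equal(c(s$mean_days, s$min_days, s$max_days), c(5, 5, 5))
  expect_equal(s$fission_fraction, 1)

  b <- mini_batch(c(900, 900), c(TRUE, TRUE))
  s <- summarize_batch(b, "cap_at_max")
  expect_equal(s$mean_days, 900)
  expect_equal(s$fission_fraction, 0)
  s2 <- summarize_batch(b, "exclude")
  expect_true(is.na(s2$mean_days))
  expect_true(s2$all_censored)

  b <- mini_batch(c(3, 7, 900), c(FALSE, FALSE, TRUE))
  s <- summarize_batch(b, "exclude")
  expect_equal(c(s$mean_days, s$min_days, s$max_days), c(5, 3, 7))
  expect_equal(s$fission_fraction, 2 / 3)
})

test_that("summaries are invariant to replicate order and batch concatenation", {
  b1 <- mini_batch(c(3, 7, 900), c(FALSE, FALSE, TRUE))
  b2 <- mini_batch(c(10, 20), c(FALSE, FALSE), ratio = 4, transfer = 80)
  whole <- dplyr::bind_rows(b1, b2)
  shuffled <- whole[c(4, 1, 5, 3, 2), ]
  expect_equal(summarize_batch(whole, "exclude"),
               summarize_batch(shuffled, "exclude"))
  expect_equal(summarize_batch(dplyr::bind_rows(b2, b1), "exclude"),
               summarize_batch(whole, "exclude"))
})

test_that("the transfer regression recovers exact lines and degenerate inputs", {
  perfect <- data.frame(transfer = seq(10, 100, 10),
                        mean_days = seq(900, 0, -100))
  fit <- transfer_linearity(perfect)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$slope, -10)
  expect_equal(fit$intercept, 1000)
  expect_equal(c(fit$df1, fit$df2), c(1L, 8L))

  flat <- data.frame(transfer = seq(10, 100, 10), mean_days = 900)
  fit <- transfer_linearity(flat)
  expect_equal(fit$r_squared, 0)
  expect_equal(fit$F_statistic, 0)

  expect_error(transfer_linearity(perfect[1:2, ]), "at least 3")
})

test_that("the transfer regression slope is sign-equivariant", {
  set.seed(8)
  x <- seq(10, 100, 10)
  falling <- data.frame(transfer = x,
                        mean_days = 900 - 8 * x + rnorm(10, 0, 20))
  rising <- falling
  rising$mean_days <- rev(falling$mean_days)
  expect_lt(transfer_linearity(falling)$slope, 0)
  expect_gt(transfer_linearity(rising)$slope, 0)
})

test_that("Dunn's test separates shifted distributions and merges identical ones", {
  set.seed(12)
  same <- c(rnorm(40, 50, 5), rnorm(40, 50, 5), rnorm(40, 50, 5))
  g <- rep(c("a", "b", "c"), each = 40)
  d <- dunn_test(same, g)
  expect_true(all(d$p_adjusted > 0.05))

  shifted <- c(rnorm(40, 10, 2), rnorm(40, 100, 2), rnorm(40, 1000, 2))
  d <- dunn_test(shifted, g)
  expect_true(all(d$p_adjusted < 0.05))
  # Bonferroni can only raise p-values
  db <- dunn_test(shifted, g, adjust = "bonferroni")
  expect_true(all(db$p_adjusted >= d$p_adjusted))
})

test_that("ratio grouping recovers a constructed three-band structure", {
  set.seed(13)
  days <- function(mu) pmin(900L, as.integer(round(rnorm(120, mu, mu / 20))))
  b <- dplyr::bind_rows(
    mini_batch(days(40), rep(FALSE, 120), ratio = 0.5),
    mini_batch(days(41), rep(FALSE, 120), ratio = 0.6),
    mini_batch(days(300), rep(FALSE, 120), ratio = 1.5),
    mini_batch(days(301), rep(FALSE, 120), ratio = 2),
    mini_batch(days(800), rep(FALSE, 120), ratio = 6),
    mini_batch(days(805), rep(FALSE, 120), ratio = 9))
  b$transfer <- 50   # nothing excluded
  rg <- ratio_groups(b, censor_policy = "cap_at_max")
  expect_lt(rg$kruskal$p.value, 1e-4)
  expect_equal(length(unique(rg$groups$group)), 3)
  # groups are ordered by location and respect the constructed bands
  grp <- rg$groups[order(rg$groups$ratio), ]
  expect_equal(grp$group, c(1, 1, 2, 2, 3, 3))

  # identically distributed levels collapse into one group
  set.seed(14)
  b0 <- dplyr::bind_rows(lapply(1:5, function(r)
    mini_batch(days(200), rep(FALSE, 120), ratio = r)))
  b0$transfer <- 50
  rg0 <- ratio_groups(b0, censor_policy = "cap_at_max")
  expect_equal(length(unique(rg0$groups$group)), 1)
})

test_that("permuted ratio labels lose significance at about the nominal rate", {
  set.seed(15)
  base_days <- as.integer(round(rnorm(240, 300, 60)))
  rejections <- 0L
  for (perm in 1:60) {
    b <- mini_batch(base_days, rep(FALSE, 240),
                    ratio = sample(rep(c(0.5, 1.5, 6), each = 80)))
    b$transfer <- 50
    rg <- ratio_groups(b, censor_policy = "cap_at_max")
    rejections <- rejections + (rg$kruskal$p.value < 0.05)
  }
  expect_lte(rejections / 60, 0.15)
})

test_that("the Poisson model recovers a known transfer effect and drops constants", {
  set.seed(16)
  transfer <- rep(seq(10, 100, 10), each = 50)
  days <- as.integer(round(exp(5 - 0.02 * transfer)))
  b <- tibble::tibble(n = 10L, C = 0.005, lambda1 = 0.25, lambda2 = 0.25,
                      transfer = transfer, ratio = 1, replicate = 1,
                      seed = 1, days = days, censored = FALSE,
                      viable = FALSE)
  expect_warning(pm <- poisson_covariate_model(b), "non-varying")
  co <- pm$coefficients
  expect_equal(co$estimate[co$term == "transfer"], -0.02, tolerance = 0.01)
  expect_false(any(co$term %in% c("n", "ratio")))

  # constant response: near-zero coefficient
  b$days <- 100L
  expect_warning(pm0 <- poisson_covariate_model(b), "non-varying")
  co0 <- pm0$coefficients
  expect_equal(co0$estimate[co0$term == "transfer"], 0, tolerance = 1e-6)
})

test_that("survival curves are proper right-censored step functions", {
  s <- survival_curves(mini_batch(c(5, 5, 5), rep(FALSE, 3)))
  expect_equal(s$day, 5)
  expect_equal(s$survival, 0)

  s <- survival_curves(mini_batch(c(900, 900), c(TRUE, TRUE)))
  expect_equal(s$survival, 1)

  s <- survival_curves(mini_batch(c(3, 7, 900), c(FALSE, FALSE, TRUE)))
  expect_equal(s$survival[s$day == 3], 2 / 3)
  expect_equal(s$survival[s$day == 7], 1 / 3)
  expect_equal(s$survival[s$day == 900], 1 / 3)
  expect_true(all(diff(s$survival) <= 0))
})

test_that("band summaries flag the U-shape and the cohesive low band", {
  b <- dplyr::bind_rows(
    mini_batch(rep(900L, 50), rep(TRUE, 50), ratio = 0.2),
    mini_batch(rep(100L, 50), rep(FALSE, 50), ratio = 1),
    mini_batch(rep(500L, 50), rep(FALSE, 50), ratio = 9))
  b$transfer <- 60
  bs <- ratio_band_summary(b)
  expect_true(bs$u_shape)
  expect_equal(bs$low_fission_fraction, 0)
  expect_equal(sort(bs$bands$band), c("high", "low", "mid"))
})
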