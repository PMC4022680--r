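#' Per-condition summaries of days-to-fission
#'
#' Collapses a batch table to one row per condition (`n`, `C`, `lambda1`,
#' `lambda2`, `transfer`, `ratio`) with the mean, minimum and maximum number
#' of days before irreversible fission and the fraction of replicates in
#' which a fission was observed at all.
#'
#' @param batch A batch tibble as returned by [run_batch()] (or
#'   [read_results()]).
#' @param censor_policy How censored replicates enter the day statistics:
#'   `"exclude"` drops them (a condition where every replicate is censored
#'   keeps its row with `NA` day statistics and `all_censored = TRUE`),
#'   `"cap_at_max"` counts them at the day cap.
#' @return A tibble of condition summaries, one row per condition, with
#'   columns `mean_days`, `min_days`, `max_days`, `fission_fraction`,
#'   `n_reps`, `all_censored` and `censor_policy`.
#' @export
summarize_batch <- function(batch, censor_policy = c("exclude",
                                                     "cap_at_max")) {
  censor_policy <- match.arg(censor_policy)
  if (nrow(batch) == 0L) stop("`batch` is empty", call. = FALSE)
  key <- intersect(c("n", "C", "lambda1", "lambda2", "transfer", "ratio"),
                   names(batch))
  batch |>
    dplyr::group_by(dplyr::across(dplyr::all_of(key))) |>
    dplyr::summarise(
      mean_days = .day_stat(.data$days, .data$censored, censor_policy, mean),
      min_days = .day_stat(.data$days, .data$censored, censor_policy, min),
      max_days = .day_stat(.data$days, .data$censored, censor_policy, max),
      fission_fraction = mean(!.data$censored),
      n_reps = dplyr::n(),
      all_censored = all(.data$censored),
      .groups = "drop") |>
    dplyr::mutate(censor_policy = censor_policy)
}

.day_stat <- function(days, censored, policy, fun) {
  d <- if (policy == "exclude") days[!censored] else days
  if (length(d) == 0L) NA_real_ else as.numeric(fun(d))
}

#' Linearity of mean days-to-fission in the transfer percentage
#'
#' Ordinary least-squares regression of the mean number of days before
#' irreversible fission on the social-relations transfer percentage. Under
#' the model the relation is close to linear with a negative slope: the more
#' grooming time is re-allocated at each temporary fission, the sooner the
#' group splits. The F statistic is on 1 and `levels - 2` degrees of
#' freedom.
#'
#' @param means A data frame with columns `transfer` and `mean_days`, one row
#'   per transfer level — see [mean_days_by_transfer()].
#' @return A list with `slope` (days per percentage point), `intercept`,
#'   `r_squared`, `F_statistic`, `p_value`, `df1`, `df2`.
#' @export
#' @examples
#' perfect <- data.frame(transfer = seq(10, 100, 10),
#'                       mean_days = seq(900, 0, -100))
#' transfer_linearity(perfect)  # r_squared = 1, slope = -10
transfer_linearity <- function(means) {
  if (!all(c("transfer", "mean_days") %in% names(means)))
    stop("`means` needs columns `transfer` and `mean_days`", call. = FALSE)
  means <- means[stats::complete.cases(means[c("transfer", "mean_days")]), ]
  if (nrow(means) < 3L)
    stop("at least 3 transfer levels are required", call. = FALSE)
  fit <- stats::lm(mean_days ~ transfer, data = means)
  sm <- summary(fit)
  tss <- sum((means$mean_days - mean(means$mean_days))^2)
  if (tss < .fissim_tol) {
    # constant response: the regression explains nothing
    return(list(slope = 0, intercept = mean(means$mean_days), r_squared = 0,
                F_statistic = 0, p_value = 1, df1 = 1L,
                df2 = nrow(means) - 2L))
  }
  list(slope = unname(stats::coef(fit)[["transfer"]]),
       intercept = unname(stats::coef(fit)[["(Intercept)"]]),
       r_squared = sm$r.squared,
       F_statistic = unname(sm$fstatistic[["value"]]),
       p_value = unname(stats::pf(sm$fstatistic[["value"]],
                                  sm$fstatistic[["numdf"]],
                                  sm$fstatistic[["dendf"]],
                                  lower.tail = FALSE)),
       df1 = as.integer(sm$fstatistic[["numdf"]]),
       df2 = as.integer(sm$fstatistic[["dendf"]]))
}

#' Mean days per transfer level
#'
#' Pools a batch over its Nutrition/Sociality ratios (for one group size) and
#' returns the mean days-to-fission per transfer percentage, the input of
#' [transfer_linearity()].
#'
#' @inheritParams summarize_batch
#' @param n Optional group size filter.
#' @param censor_policy As in [summarize_batch()]; the default
#'   (`"cap_at_max"`) keeps censored runs at the day cap so that transfer
#'   levels without any fission still contribute a mean.
#' @param include_transfer Transfer levels to keep; default all present.
#' @return Tibble with columns `transfer`, `mean_days`, `n_obs`.
#' @export
mean_days_by_transfer <- function(batch, n = NULL,
                                  censor_policy = c("cap_at_max", "exclude"),
                                  include_transfer = NULL) {
  censor_policy <- match.arg(censor_policy)
  if (!is.null(n)) batch <- batch[batch$n %in% n, , drop = FALSE]
  if (!is.null(include_transfer))
    batch <- batch[batch$transfer %in% include_transfer, , drop = FALSE]
  if (censor_policy == "exclude")
    batch <- batch[!batch$censored, , drop = FALSE]
  batch |>
    dplyr::group_by(.data$transfer) |>
    dplyr::summarise(mean_days = mean(.data$days), n_obs = dplyr::n(),
                     .groups = "drop")
}

#' Dunn's pairwise post-hoc test
#'
#' Rank-based pairwise comparisons between groups after a Kruskal–Wallis
#' test, with the usual tie correction. The z statistic for groups a, b is
#' the difference of mean ranks scaled by
#' `sqrt((N(N+1)/12 - sum(t^3 - t)/(12(N-1))) * (1/n_a + 1/n_b))`.
#'
#' @param x Numeric response values.
#' @param g Grouping vector (coerced to factor).
#' @param adjust Multiple-comparison adjustment of the two-sided p-values:
#'   `"none"` (default, matching common practice for Dunn's test),
#'   `"bonferroni"` or `"holm"`.
#' @return Tibble with one row per unordered pair: `group_a`, `group_b`,
#'   `mean_rank_a`, `mean_rank_b`, `z`, `p_value`, `p_adjusted`.
#' @export
dunn_test <- function(x, g, adjust = c("none", "bonferroni", "holm")) {
  adjust <- match.arg(adjust)
  ok <- !is.na(x) & !is.na(g)
  x <- x[ok]
  g <- factor(g[ok])
  k <- nlevels(g)
  if (k < 2L) stop("at least 2 groups are required", call. = FALSE)
  N <- length(x)
  r <- rank(x)
  mean_rank <- tapply(r, g, mean)
  n_g <- tabulate(g)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  base_var <- N * (N + 1) / 12 - tie_term

  pairs <- utils::combn(seq_len(k), 2)
  z <- p <- numeric(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    v <- base_var * (1 / n_g[a] + 1 / n_g[b])
    z[j] <- if (v <= 0) 0 else (mean_rank[a] - mean_rank[b]) / sqrt(v)
    p[j] <- 2 * stats::pnorm(-abs(z[j]))
  }
  tibble::tibble(
    group_a = levels(g)[pairs[1, ]], group_b = levels(g)[pairs[2, ]],
    mean_rank_a = unname(mean_rank[pairs[1, ]]),
    mean_rank_b = unname(mean_rank[pairs[2, ]]),
    z = z, p_value = p,
    p_adjusted = stats::p.adjust(p, method = adjust))
}

#' Kruskal–Wallis and Dunn grouping of Nutrition/Sociality ratios
#'
#' Tests whether days-to-fission differ across the Nutrition/Sociality ratio
#' levels of a batch (Kruskal–Wallis), runs Dunn's pairwise post-hoc test,
#' and partitions the ratio levels into homogeneity groups by transitive
#' non-significance: two ratios share a group when they are connected by a
#' chain of pairwise-non-significant comparisons at level `alpha`.
#' Simulations at 10% transfer are excluded by default, where no fission is
#' observed before the day cap.
#'
#' @inheritParams summarize_batch
#' @param n Optional group size filter.
#' @param exclude_transfer Transfer levels dropped before testing
#'   (default 10).
#' @param censor_policy `"cap_at_max"` (default) keeps censored replicates at
#'   the day cap so fully cohesive ratio levels remain comparable;
#'   `"exclude"` drops censored replicates, and then drops (with a warning)
#'   any ratio level left without events.
#' @param adjust,alpha Passed to [dunn_test()]; `alpha` is the significance
#'   level used for grouping.
#' @return A list with `kruskal` (the `htest` from [stats::kruskal.test()]),
#'   `dunn` (pairwise tibble), `groups` (tibble `ratio`, `mean_rank`,
#'   `group` with groups numbered by increasing mean rank), and the settings
#'   used.
#' @export
ratio_groups <- function(batch, n = NULL, exclude_transfer = 10,
                         censor_policy = c("cap_at_max", "exclude"),
                         adjust = c("none", "bonferroni", "holm"),
                         alpha = 0.05) {
  censor_policy <- match.arg(censor_policy)
  adjust <- match.arg(adjust)
  if (!is.null(n)) batch <- batch[batch$n %in% n, , drop = FALSE]
  batch <- batch[!batch$transfer %in% exclude_transfer, , drop = FALSE]
  if (censor_policy == "exclude") {
    events_per_ratio <- tapply(!batch$censored, batch$ratio, any)
    dead <- names(events_per_ratio)[!events_per_ratio]
    if (length(dead) > 0)
      warning("dropping ratio level(s) without any fission event: ",
              paste(dead, collapse = ", "), call. = FALSE)
    batch <- batch[!batch$censored, , drop = FALSE]
  }
  if (length(unique(batch$ratio)) < 2L)
    stop("at least 2 ratio levels with data are required", call. = FALSE)

  g <- factor(batch$ratio)
  kw <- stats::kruskal.test(batch$days, g)
  dunn <- dunn_test(batch$days, g, adjust = adjust)

  lev <- levels(g)
  mean_rank <- tapply(rank(batch$days), g, mean)
  # connected components of the non-significance graph
  comp <- seq_along(lev)
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  for (j in seq_len(nrow(dunn))) {
    if (dunn$p_adjusted[j] >= alpha) {
      a <- find(match(dunn$group_a[j], lev))
      b <- find(match(dunn$group_b[j], lev))
      if (a != b) comp[max(a, b)] <- min(a, b)
    }
  }
  roots <- vapply(seq_along(lev), find, integer(1))
  group_rank <- tapply(mean_rank, roots, mean)
  group_id <- match(roots, names(sort(group_rank)))

  list(kruskal = kw, dunn = dunn,
       groups = tibble::tibble(ratio = as.numeric(lev),
                               mean_rank = unname(mean_rank),
                               group = group_id),
       alpha = alpha, adjust = adjust, censor_policy = censor_policy,
       excluded_transfer = exclude_transfer)
}

#' Poisson regression of days-to-fission on the design covariates
#'
#' Generalised linear model with Poisson family and log link for the
#' (discrete) number of days before irreversible fission, with group size,
#' transfer percentage and Nutrition/Sociality ratio as covariates. On
#' sweeps of the standard grid the group size and transfer coefficients are
#' negative (larger groups and stronger transfer speed fission up) and the
#' ratio coefficient is positive.
#'
#' @inheritParams summarize_batch
#' @param censor_policy `"cap_at_max"` (default) enters censored runs at the
#'   day cap; `"exclude"` drops them.
#' @param ratio_as Treat the ratio as a `"numeric"` covariate (default) or as
#'   a `"factor"` (the response is not monotone in the ratio, so a
#'   categorical fit can be preferred for description).
#' @return A list with `model` (the `glm` fit) and `coefficients` (tibble
#'   `term`, `estimate`, `std_error`, `z`, `p_value`). Covariates that do
#'   not vary in the batch are dropped with a warning.
#' @export
poisson_covariate_model <- function(batch,
                                    censor_policy = c("cap_at_max",
                                                      "exclude"),
                                    ratio_as = c("numeric", "factor")) {
  censor_policy <- match.arg(censor_policy)
  ratio_as <- match.arg(ratio_as)
  if (censor_policy == "exclude")
    batch <- batch[!batch$censored, , drop = FALSE]
  if (nrow(batch) == 0L) stop("no data after censoring policy", call. = FALSE)
  dat <- data.frame(days = batch$days, n = batch$n,
                    transfer = batch$transfer, ratio = batch$ratio)
  if (ratio_as == "factor") dat$ratio <- factor(dat$ratio)
  covs <- c("n", "transfer", "ratio")
  varying <- vapply(covs, function(v) length(unique(dat[[v]])) > 1L,
                    logical(1))
  if (!all(varying)) {
    warning("dropping non-varying covariate(s): ",
            paste(covs[!varying], collapse = ", "), call. = FALSE)
    covs <- covs[varying]
  }
  if (length(covs) == 0L)
    stop("no varying covariates to regress on", call. = FALSE)
  fml <- stats::reformulate(covs, response = "days")
  fit <- stats::glm(fml, data = dat, family = stats::poisson())
  co <- summary(fit)$coefficients
  list(model = fit,
       coefficients = tibble::tibble(
         term = rownames(co), estimate = unname(co[, 1]),
         std_error = unname(co[, 2]), z = unname(co[, 3]),
         p_value = unname(co[, 4])))
}

#' Empirical survival curves of the fission time
#'
#' Kaplan–Meier estimate of the probability that a group has not yet split
#' irreversibly by each day, with runs reaching the day cap treated as
#' right-censored. Curves are computed per condition group.
#'
#' @inheritParams summarize_batch
#' @param by Columns of `batch` defining one curve (default
#'   `c("n", "ratio", "transfer")`).
#' @return Tibble with the grouping columns plus `day`, `n_risk`, `n_event`,
#'   `survival`; each curve is monotone non-increasing from 1.
#' @export
survival_curves <- function(batch, by = c("n", "ratio", "transfer")) {
  if (nrow(batch) == 0L) stop("`batch` is empty", call. = FALSE)
  by <- intersect(by, names(batch))
  batch |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::reframe({
      fit <- survival::survfit(
        survival::Surv(days, !censored) ~ 1,
        data = data.frame(days = .data$days, censored = .data$censored))
      tibble::tibble(day = fit$time, n_risk = fit$n.risk,
                     n_event = fit$n.event, survival = fit$surv)
    })
}

#' Classify Nutrition/Sociality ratios into response bands
#'
#' The response of days-to-fission to the Nutrition/Sociality ratio is
#' U-shaped over the fissioning range, with a cohesive low band in which no
#' fission occurs at all: ratios below `low_below` (no fission — cohesion too
#' strong), a middle band up to `high_above` (fast fission), and a high band
#' above it (slow, need-driven fission). The low-band boundary depends on
#' group size (0.43 for groups of 10, 0.25 for groups of 20).
#'
#' @inheritParams summarize_batch
#' @param low_below Ratios strictly below this are the low band (default
#'   0.43, the boundary for groups of 10).
#' @param high_above Ratios strictly above this are the high band
#'   (default 2.33).
#' @param exclude_transfer Transfer levels dropped first (default 10).
#' @return A list with `bands` (tibble `band`, `mean_days`,
#'   `fission_fraction`, `n_obs`, days capped at the maximum) and
#'   `u_shape` (`TRUE` when the middle band's mean days lie strictly below
#'   the high band's).
#' @export
ratio_band_summary <- function(batch, low_below = 0.43, high_above = 2.33,
                               exclude_transfer = 10) {
  batch <- batch[!batch$transfer %in% exclude_transfer, , drop = FALSE]
  band <- ifelse(batch$ratio < low_below, "low",
                 ifelse(batch$ratio > high_above, "high", "mid"))
  bands <- tibble::tibble(band = band, days = batch$days,
                          censored = batch$censored) |>
    dplyr::group_by(.data$band) |>
    dplyr::summarise(mean_days = mean(.data$days),
                     fission_fraction = mean(!.data$censored),
                     n_obs = dplyr::n(), .groups = "drop")
  get <- function(b, col) {
    v <- bands[[col]][bands$band == b]
    if (length(v) == 0L) NA_real_ else v
  }
  list(bands = bands,
       u_shape = isTRUE(get("mid", "mean_days") < get("high", "mean_days")),
       low_fission_fraction = get("low", "fission_fraction"))
}

#' Smallest transfer percentage producing any irreversible fission
#'
#' Over all rows of a (possibly filtered) batch, the smallest transfer
#' percentage at which at least one replicate reached irreversible fission
#' before the day cap; `NA` when no replicate fissioned at all.
#'
#' @inheritParams summarize_batch
#' @return A single number (or `NA`).
#' @export
min_transfer_with_fission <- function(batch) {
  t_ev <- batch$transfer[!batch$censored]
  if (length(t_ev) == 0L) NA_real_ else min(t_ev)
}
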