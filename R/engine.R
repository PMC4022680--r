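#' Nutrition/Sociality ratio
#'
#' The ratio `R = (lambda1 + lambda2) / (C * 100)` scales the strength of
#' intrinsic, nutrition-driven movement against mimetic, cohesion-driven
#' movement. High values describe need-driven, nearly independent movers; low
#' values describe socially viscous groups that move by following each other.
#'
#' @param cond A [condition()] with `C > 0`.
#' @param digits Rounding applied for display; use `NULL` for the raw value.
#'   The default (2) matches the conventional presentation of the
#'   calibration grid.
#' @return The ratio as a single number.
#' @export
#' @examples
#' nutrition_sociality_ratio(condition(10, 0.005, 0.25, 0.25, 50))  # 1
#' nutrition_sociality_ratio(condition(10, 0.003, 0.35, 0.35, 50))  # 2.33
nutrition_sociality_ratio <- function(cond, digits = 2) {
  stopifnot(inherits(cond, "sim_condition"))
  if (cond$C == 0)
    stop("the Nutrition/Sociality ratio is undefined for C = 0",
         call. = FALSE)
  r <- (cond$lambda1 + cond$lambda2) / (cond$C * 100)
  if (is.null(digits)) r else round(r, digits)
}

.ns_ratio <- function(lambda1, lambda2, C) (lambda1 + lambda2) / (C * 100)

#' The standard calibration grid of conditions
#'
#' The nine canonical `(C, lambda1, lambda2)` pairs spanning
#' Nutrition/Sociality ratios from 0.11 to 9 — mimetic coefficients 0.001 to
#' 0.009 in steps of 0.001 with symmetric intrinsic probabilities
#' `lambda1 = lambda2 = 0.5 - 50 * C`, so every pair sits on the feasibility
#' boundary `lambda1 + lambda2 = 1 - C * 100` — crossed with the requested
#' group sizes and transfer percentages.
#'
#' @param n Group sizes to include (default `c(10, 20)`).
#' @param transfer Transfer percentages to include (default 10 to 100 in
#'   steps of 10).
#' @param ratio Optional filter: keep only rows whose 2-decimal ratio is in
#'   this set (e.g. `c(1, 0.67, 0.43, 0.25, 0.11)`).
#' @return A tibble with columns `n`, `C`, `lambda1`, `lambda2`, `transfer`,
#'   `ratio` (2-decimal display value), one row per condition, directly
#'   usable as the grid of [run_batch()].
#' @export
#' @examples
#' standard_conditions(n = 10)
#' standard_conditions(n = 20, ratio = c(0.11, 0.25))
standard_conditions <- function(n = c(10, 20),
                                transfer = seq(10, 100, by = 10),
                                ratio = NULL) {
  C <- seq(0.001, 0.009, by = 0.001)
  lam <- 0.5 - 50 * C
  pairs <- tibble::tibble(C = C, lambda1 = lam, lambda2 = lam,
                          ratio = round(.ns_ratio(lam, lam, C), 2))
  grid <- tidyr_crossing(n = as.integer(n), pairs, transfer = transfer)
  if (!is.null(ratio)) grid <- grid[grid$ratio %in% ratio, , drop = FALSE]
  grid[, c("n", "C", "lambda1", "lambda2", "transfer", "ratio")]
}

# Minimal stand-in for tidyr::crossing() over a vector, a data frame and a
# vector, keeping dependencies to what the package already imports.
tidyr_crossing <- function(n, pairs, transfer) {
  out <- do.call(rbind, lapply(n, function(ni) {
    do.call(rbind, lapply(seq_len(nrow(pairs)), function(j) {
      cbind(n = ni, pairs[rep(j, length(transfer)), , drop = FALSE],
            transfer = transfer)
    }))
  }))
  tibble::as_tibble(out)
}

#' Run one simulation to irreversible fission or censoring
#'
#' Starting from an egalitarian grooming network with everyone in the resting
#' area, each simulated day runs the stochastic assignment
#' ([assign_day()]), applies the link transfer when the day produced a
#' temporary fission ([transfer_update()]), and then tests the
#' irreversible-fission criterion ([check_irreversible()]) on that day's
#' partition and the freshly rewired network. The network state carries over
#' from day to day; all individuals return to the resting area each night.
#' The simulation stops on the first day the criterion holds, or is censored
#' at `max_days`.
#'
#' @param cond A [condition()].
#' @param seed Integer seed; every random draw in the run derives from it.
#' @param max_days Day cap after which the run is censored (default 900).
#' @param threshold,min_subgroup Irreversible-fission criterion parameters,
#'   see [check_irreversible()].
#' @param record_trace Keep a per-day record (areas sizes, temporary-fission
#'   flag, minimal within-subgroup sum, worst row-sum deviation)?
#' @param stop_on_fission Stop at the first irreversible fission (default)?
#'   With `FALSE` the network keeps evolving through `max_days`, which is
#'   useful for studying the rewiring dynamics themselves; the first fission
#'   day is still the one reported.
#' @param engine `"cpp"` (compiled, default) or `"r"` (plain-R replay). Both
#'   consume the random stream identically, so they produce the same result
#'   from the same seed.
#' @param net Optional seed [social_network()]; default egalitarian.
#' @return A `simulation_result`: list with elements `days` (day of fission,
#'   or `max_days` when censored), `censored`, `viable` (event observed in
#'   the 90–900 day window seen in wild fissions), `network`, `assignment`
#'   (partition on the fission day, or the last day when censored), `ratio`,
#'   `condition`, `seed`, and `trace` (tibble, when recorded).
#' @export
#' @examples
#' cond <- condition(10, C = 0.004, lambda1 = 0.3, lambda2 = 0.3,
#'                   transfer = 100)
#' run_simulation(cond, seed = 42)
run_simulation <- function(cond, seed, max_days = 900, threshold = 95,
                           min_subgroup = 4, record_trace = FALSE,
                           stop_on_fission = TRUE,
                           engine = c("cpp", "r"), net = NULL) {
  stopifnot(inherits(cond, "sim_condition"))
  engine <- match.arg(engine)
  if (!is.numeric(max_days) || length(max_days) != 1L || max_days < 1)
    stop("`max_days` must be >= 1", call. = FALSE)
  max_days <- as.integer(max_days)
  if (is.null(net)) net <- init_egalitarian(cond$n)
  stopifnot(inherits(net, "social_network"), nrow(net) == cond$n)

  set.seed(as.integer(seed))
  res <- if (engine == "cpp") {
    .sim_core(unclass(net), cond$C, cond$lambda1, cond$lambda2,
              cond$transfer, max_days, threshold, as.integer(min_subgroup),
              stop_on_fission, record_trace, 10000L)
  } else {
    .sim_core_r(net, cond, max_days, threshold, min_subgroup,
                stop_on_fission, record_trace)
  }

  trace <- NULL
  if (record_trace) {
    tr <- res$trace
    trace <- tibble::tibble(
      day = as.integer(tr[, 1]), n_s1 = as.integer(tr[, 2]),
      n_s2 = as.integer(tr[, 3]), temporary_fission = tr[, 4] == 1,
      min_within_sum = tr[, 5], rowsum_deviation = tr[, 6])
  }
  structure(list(
    days = as.integer(res$days), censored = res$censored,
    viable = !res$censored && res$days >= 90 && res$days <= 900,
    network = social_network(res$network),
    assignment = day_assignment(res$assignment),
    ratio = if (cond$C > 0) nutrition_sociality_ratio(cond) else NA_real_,
    condition = cond, seed = as.integer(seed), max_days = max_days,
    threshold = threshold, min_subgroup = min_subgroup, trace = trace),
    class = "simulation_result")
}

# Plain-R engine: the day loop written directly on the exported network and
# movement operations. Used as the independent replay path in tests.
.sim_core_r <- function(net, cond, max_days, threshold, min_subgroup,
                        stop_on_fission, record_trace) {
  fission_day <- NA_integer_
  final_assign <- NULL
  trace <- if (record_trace) matrix(NA_real_, max_days, 6) else NULL
  days_run <- 0L
  for (day in seq_len(max_days)) {
    a <- assign_day(net, cond)
    temp <- is_temporary_fission(a)
    if (temp) net <- transfer_update(net, a, cond$transfer)
    fission <- temp && check_irreversible(net, a, threshold, min_subgroup)
    if (record_trace) {
      sz <- subgroup_sizes(a)
      trace[day, ] <- c(day, sz[["s1"]], sz[["s2"]], as.numeric(temp),
                        min(within_subgroup_sums(net, a)),
                        max(abs(rowSums(net) - 100)))
    }
    days_run <- day
    if (fission && is.na(fission_day)) {
      fission_day <- day
      final_assign <- a
      if (stop_on_fission) break
    }
    if (day == max_days && is.null(final_assign)) final_assign <- a
  }
  censored <- is.na(fission_day)
  list(days = if (censored) max_days else fission_day, censored = censored,
       network = unclass(net), assignment = as.integer(final_assign),
       days_run = days_run,
       trace = if (record_trace) trace[seq_len(days_run), , drop = FALSE])
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf(
    "<simulation_result: %s, n = %d, R = %.2f, transfer = %g%%, seed = %d>\n",
    if (x$censored) sprintf("censored at %d days", x$max_days)
    else sprintf("irreversible fission on day %d%s", x$days,
                 if (x$viable) " (viable)" else ""),
    x$condition$n, x$ratio, x$condition$transfer, x$seed))
  invisible(x)
}

#' Deterministic per-replicate seeds
#'
#' Derives the seed for replicate `rep` of condition `cond_id` from the batch
#' base seed, so any single run of a batch can be reproduced in isolation.
#' Seeds stay within the 32-bit integer range.
#'
#' @param base_seed Batch-level integer seed.
#' @param cond_id Condition index (row of the grid), 1-based.
#' @param rep Replicate index, 1-based.
#' @return A single integer seed.
#' @export
derive_seed <- function(base_seed, cond_id, rep) {
  as.integer((as.numeric(base_seed) %% 2147483647 +
                as.numeric(cond_id) * 100003 +
                as.numeric(rep) * 7919) %% 2147483647)
}

#' Run a batch of simulations over a parameter grid
#'
#' Runs `reps` independent replicates of [run_simulation()] for every row of
#' a condition grid (such as [standard_conditions()]). Replicate seeds are
#' derived deterministically from `base_seed` via [derive_seed()], so the
#' result table is bit-reproducible and independent of execution order.
#'
#' @param grid Data frame with columns `n`, `C`, `lambda1`, `lambda2`,
#'   `transfer` (extra columns are ignored); one row per condition.
#' @param reps Number of replicates per condition (at least 1).
#' @param base_seed Integer seed for the whole batch.
#' @inheritParams run_simulation
#' @param progress Print a line per condition as the batch advances?
#' @return A tibble with one row per (condition, replicate):
#'   `n, C, lambda1, lambda2, transfer, ratio, replicate, seed, days,
#'   censored, viable`.
#' @export
#' @examples
#' grid <- standard_conditions(n = 10, transfer = 100, ratio = c(1, 1.5))
#' run_batch(grid, reps = 3, base_seed = 7)
run_batch <- function(grid, reps, base_seed, max_days = 900, threshold = 95,
                      min_subgroup = 4, engine = c("cpp", "r"),
                      progress = FALSE) {
  engine <- match.arg(engine)
  grid <- as.data.frame(grid)
  need <- c("n", "C", "lambda1", "lambda2", "transfer")
  if (nrow(grid) == 0L)
    stop("`grid` must contain at least one condition", call. = FALSE)
  if (!all(need %in% names(grid)))
    stop("`grid` must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!is.numeric(reps) || length(reps) != 1L || reps < 1)
    stop("`reps` must be >= 1", call. = FALSE)
  reps <- as.integer(reps)

  rows <- vector("list", nrow(grid))
  for (ci in seq_len(nrow(grid))) {
    g <- grid[ci, ]
    cond <- condition(g$n, g$C, g$lambda1, g$lambda2, g$transfer)
    ratio <- if (cond$C > 0) nutrition_sociality_ratio(cond) else NA_real_
    days <- integer(reps); cens <- logical(reps); seeds <- integer(reps)
    for (r in seq_len(reps)) {
      seeds[r] <- derive_seed(base_seed, ci, r)
      res <- run_simulation(cond, seed = seeds[r], max_days = max_days,
                            threshold = threshold,
                            min_subgroup = min_subgroup, engine = engine)
      days[r] <- res$days
      cens[r] <- res$censored
    }
    rows[[ci]] <- tibble::tibble(
      n = cond$n, C = cond$C, lambda1 = cond$lambda1,
      lambda2 = cond$lambda2, transfer = cond$transfer, ratio = ratio,
      replicate = seq_len(reps), seed = seeds, days = days, censored = cens,
      viable = !cens & days >= 90 & days <= 900)
    if (progress)
      message(sprintf(
        "[fissim] condition %d/%d (n=%d, R=%.2f, T=%g%%): %d/%d fissions",
        ci, nrow(grid), cond$n, ratio, cond$transfer, sum(!cens), reps))
  }
  dplyr::bind_rows(rows)
}
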