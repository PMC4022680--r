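#' Simulation conditions
#'
#' A `condition` bundles one parameter cell of the model: the group size `n`,
#' the mimetic coefficient `C` (probability gained per unit of link weight
#' toward individuals already in an area — a measure of social cohesion or
#' viscosity), the intrinsic per-day probabilities `lambda1` and `lambda2` of
#' moving to resource areas s1 and s2 out of nutritional need alone, and the
#' social-relations transfer percentage `T` applied after each temporary
#' fission.
#'
#' Because every individual's outgoing link weights sum to 100, the mimetic
#' term can contribute at most `C * 100` to the total movement probability,
#' so feasibility (all daily probabilities summing to at most 1) requires
#' `lambda1 + lambda2 <= 1 - C * 100`. The constructor enforces this
#' constraint; it is checked nowhere else.
#'
#' @param n Group size (at least 2).
#' @param C Mimetic coefficient, `>= 0`.
#' @param lambda1,lambda2 Intrinsic movement probabilities toward s1 and s2,
#'   each `>= 0`.
#' @param transfer Transfer percentage in `[0, 100]`.
#' @return An object of class `condition` (a named list).
#' @seealso [nutrition_sociality_ratio()], [standard_conditions()]
#' @export
#' @examples
#' condition(n = 10, C = 0.004, lambda1 = 0.3, lambda2 = 0.3, transfer = 50)
condition <- function(n, C, lambda1, lambda2, transfer) {
  if (!is.numeric(n) || length(n) != 1L || n != round(n) || n < 2)
    stop("`n` must be a single integer >= 2", call. = FALSE)
  for (nm in c("C", "lambda1", "lambda2")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
      stop("`", nm, "` must be a single non-negative number", call. = FALSE)
  }
  if (!is.numeric(transfer) || length(transfer) != 1L || is.na(transfer) ||
      transfer < 0 || transfer > 100)
    stop("`transfer` must be a percentage in [0, 100]", call. = FALSE)
  if (lambda1 + lambda2 > 1 - C * 100 + .fissim_tol)
    stop(sprintf(paste0(
      "infeasible condition (n=%d, C=%g, lambda1=%g, lambda2=%g): ",
      "movement probabilities require (lambda1 + lambda2) <= 1 - C*100"),
      as.integer(n), C, lambda1, lambda2), call. = FALSE)
  structure(list(n = as.integer(n), C = C, lambda1 = lambda1,
                 lambda2 = lambda2, transfer = transfer),
            class = "sim_condition")
}

#' @export
print.sim_condition <- function(x, ...) {
  r <- if (x$C > 0) sprintf("%.2f", nutrition_sociality_ratio(x)) else "Inf"
  cat(sprintf(
    "<condition: n = %d, C = %g, lambda = (%g, %g), transfer = %g%%, R = %s>\n",
    x$n, x$C, x$lambda1, x$lambda2, x$transfer, r))
  invisible(x)
}

#' Daily movement probabilities
#'
#' The probability that individual `i`, still in the resting area, moves to
#' resource area `s` is `p_s = lambda_s + C * sum(w[i, k])` over the
#' individuals `k` already present in area `s`; `p0 = 1 - p1 - p2` is the
#' probability of staying put for this draw. The mimetic term makes movement
#' self-reinforcing: the more grooming time `i` directs at the individuals
#' already in an area, the more likely `i` is to join them.
#'
#' @param net A [social_network()].
#' @param i Index (1-based) of an individual still in the resting area.
#' @param occupancy Integer vector of current locations: 0 = resting area,
#'   1 = area s1, 2 = area s2.
#' @param cond A [condition()].
#' @return A named list with components `p1`, `p2`, `p0` summing to 1.
#' @export
#' @examples
#' net <- init_egalitarian(10)
#' cond <- condition(10, C = 0.005, lambda1 = 0.25, lambda2 = 0.25,
#'                   transfer = 50)
#' move_probabilities(net, 1, rep(0L, 10), cond)      # empty areas: just lambda
#' move_probabilities(net, 1, c(0L, rep(1L, 9)), cond) # strong mimetic pull
move_probabilities <- function(net, i, occupancy, cond) {
  stopifnot(inherits(net, "social_network"), inherits(cond, "sim_condition"))
  occupancy <- as.integer(occupancy)
  if (length(occupancy) != nrow(net))
    stop("`occupancy` must cover all individuals", call. = FALSE)
  if (occupancy[i] != 0L)
    stop("individual `i` has already left the resting area", call. = FALSE)
  p1 <- cond$lambda1 + cond$C * sum(net[i, occupancy == 1L])
  p2 <- cond$lambda2 + cond$C * sum(net[i, occupancy == 2L])
  list(p1 = p1, p2 = p2, p0 = 1 - p1 - p2)
}

#' Resolve one movement draw
#'
#' Applies the threshold rule to a uniform random number `x`: the individual
#' moves to s1 when `p1 >= x`, to s2 when `p1 + p2 >= x > p1`, and stays in
#' the resting area when `x > p1 + p2`. The boundary at `p1` is inclusive
#' toward s1.
#'
#' @param p Probabilities as returned by [move_probabilities()].
#' @param x A number in `[0, 1]`.
#' @return One of `"s1"`, `"s2"`, `"stay"`.
#' @export
#' @examples
#' draw_move(list(p1 = 0.75, p2 = 0.25), 0.75)  # "s1": boundary inclusive
#' draw_move(list(p1 = 0.25, p2 = 0.25), 0.40)  # "s2"
#' draw_move(list(p1 = 0.25, p2 = 0.25), 0.99)  # "stay"
draw_move <- function(p, x) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop("`x` must be a single number in [0, 1]", call. = FALSE)
  if (p$p1 >= x) "s1"
  else if (p$p1 + p$p2 >= x) "s2"
  else "stay"
}

#' Run one day's stochastic assignment
#'
#' All individuals start in the resting area. The process runs in rounds: in
#' each round the individuals still resting are visited in a fresh uniformly
#' random order, and each receives one movement draw with probabilities
#' recomputed from the occupancy at that instant (so an individual that just
#' left already attracts the ones drawn after it). Rounds repeat until the
#' resting area is empty; the day's partition between the two resource areas
#' is returned.
#'
#' Consumes the R random-number stream; seed with [set.seed()] for
#' reproducibility. The round sequence is identical to the one used by the
#' compiled engine, so both produce the same assignment from the same seed.
#'
#' @inheritParams move_probabilities
#' @param max_rounds Safety guard on the number of rounds (default 10000);
#'   only reachable when `lambda1 + lambda2 = 0`, in which case nobody can
#'   make the first move.
#' @return A [day_assignment()].
#' @export
#' @examples
#' net <- init_egalitarian(10)
#' cond <- condition(10, 0.005, 0.25, 0.25, transfer = 50)
#' set.seed(1)
#' assign_day(net, cond)
assign_day <- function(net, cond, max_rounds = 10000L) {
  stopifnot(inherits(net, "social_network"), inherits(cond, "sim_condition"))
  n <- nrow(net)
  occ <- integer(n)
  round <- 0L
  while (length(rest <- which(occ == 0L)) > 0L) {
    round <- round + 1L
    if (round > max_rounds)
      stop("movement round limit (", max_rounds, ") exceeded: with ",
           "lambda1 + lambda2 = 0 and empty resource areas no individual ",
           "can ever leave the resting area", call. = FALSE)
    keys <- stats::runif(length(rest))
    for (i in rest[order(keys)]) {
      p1 <- cond$lambda1 + cond$C * sum(net[i, occ == 1L])
      p2 <- cond$lambda2 + cond$C * sum(net[i, occ == 2L])
      x <- stats::runif(1)
      if (p1 >= x) occ[i] <- 1L
      else if (p1 + p2 >= x) occ[i] <- 2L
    }
  }
  day_assignment(occ)
}
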