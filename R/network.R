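#' Social grooming-time networks
#'
#' A `social_network` is a directed, weighted network over `n` individuals in
#' which the weight `w[i, k]` is the percentage of individual `i`'s social
#' (grooming) time allotted to individual `k`. Each individual has a fixed
#' budget of 100% of its social time, so every row of the weight matrix sums
#' to exactly 100; the diagonal (self-grooming) is structurally zero. Links
#' are directional: `w[i, k]` need not equal `w[k, i]`.
#'
#' @param w Square numeric matrix of link weights with zero diagonal and rows
#'   summing to 100 (within `1e-9`).
#'
#' @return An object of class `social_network`: the validated weight matrix.
#' @seealso [init_egalitarian()], [transfer_update()], [check_irreversible()]
#' @export
#' @examples
#' w <- matrix(c(0, 60, 40,
#'               50, 0, 50,
#'               10, 90, 0), 3, 3, byrow = TRUE)
#' net <- social_network(w)
#' rowSums(net)
social_network <- function(w) {
  if (!is.matrix(w) || !is.numeric(w) || nrow(w) != ncol(w))
    stop("`w` must be a square numeric matrix", call. = FALSE)
  n <- nrow(w)
  if (n < 2L)
    stop("a social network needs at least 2 individuals", call. = FALSE)
  if (any(diag(w) != 0))
    stop("self-links w[i, i] must be zero", call. = FALSE)
  if (any(w < 0))
    stop("link weights must be non-negative", call. = FALSE)
  if (any(abs(rowSums(w) - 100) > .fissim_tol))
    stop("each individual's outgoing weights must sum to 100 ",
         "(% of its social time)", call. = FALSE)
  dimnames(w) <- NULL
  structure(w, class = c("social_network", "matrix", "array"))
}

#' Initialise an egalitarian grooming network
#'
#' Every individual divides its 100% grooming-time budget equally among the
#' other `n - 1` group members, so every off-diagonal weight is
#' `100 / (n - 1)`. This homogeneous network is the seed state of every
#' simulation: group structure only emerges later through link transfer after
#' temporary fissions.
#'
#' @param n Number of individuals (at least 2).
#' @return A [social_network()] with all off-diagonal weights `100 / (n - 1)`.
#' @export
#' @examples
#' net <- init_egalitarian(10)
#' net[1, 2]   # 100/9
#' rowSums(net)
init_egalitarian <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n != round(n) || n < 2)
    stop("`n` must be a single integer >= 2", call. = FALSE)
  n <- as.integer(n)
  w <- matrix(100 / (n - 1), n, n)
  diag(w) <- 0
  social_network(w)
}

#' @export
print.social_network <- function(x, ...) {
  cat(sprintf("<social_network: %d individuals, directed, row sums = 100>\n",
              nrow(x)))
  print(unclass(x), digits = 4)
  invisible(x)
}

#' Daily area assignment
#'
#' Wraps the outcome of one day's movement process: an integer vector giving,
#' for each individual, the resource area (1 or 2) it ended the day in. A day
#' is a *temporary fission* when both areas are non-empty.
#'
#' @param area Integer vector with one entry per individual, each 1 or 2.
#' @return An object of class `day_assignment`.
#' @export
#' @examples
#' a <- day_assignment(c(1, 1, 2, 2, 1))
#' subgroup_sizes(a)
#' is_temporary_fission(a)
day_assignment <- function(area) {
  area <- as.integer(area)
  if (length(area) < 2L || anyNA(area) || !all(area %in% c(1L, 2L)))
    stop("`area` must assign every individual to area 1 or area 2",
         call. = FALSE)
  structure(area, class = "day_assignment")
}

#' @export
print.day_assignment <- function(x, ...) {
  sz <- subgroup_sizes(x)
  cat(sprintf("<day_assignment: %d individuals, areas s1 = %d, s2 = %d%s>\n",
              length(x), sz[["s1"]], sz[["s2"]],
              if (is_temporary_fission(x)) " (temporary fission)" else ""))
  invisible(x)
}

#' @rdname day_assignment
#' @param assign A [day_assignment()] (any 1/2 integer vector is accepted).
#' @return `subgroup_sizes()`: named vector of the two area head-counts;
#'   `is_temporary_fission()`: `TRUE` when both areas are occupied.
#' @export
subgroup_sizes <- function(assign) {
  c(s1 = sum(assign == 1L), s2 = sum(assign == 2L))
}

#' @rdname day_assignment
#' @export
is_temporary_fission <- function(assign) {
  all(subgroup_sizes(assign) > 0L)
}

#' Transfer social relations after a temporary fission
#'
#' After a day on which the group split between the two resource areas, each
#' individual re-allocates part of its grooming time: every link toward an
#' individual in the *other* area shrinks by the transfer percentage `T`, and
#' the total amount removed is redistributed equally among its `N` same-area
#' companions. Two special cases follow from the budget interpretation: an
#' individual alone in its area keeps its own outgoing links frozen (links
#' *toward* it still change), and a day without a temporary fission leaves
#' the network untouched. Each individual's outgoing weights always still sum
#' to 100 afterwards.
#'
#' @param net A [social_network()].
#' @param assign A [day_assignment()] over the same individuals.
#' @param transfer Transfer percentage `T` in `[0, 100]`.
#' @return The rewired [social_network()].
#' @export
#' @examples
#' net <- init_egalitarian(10)
#' a <- day_assignment(rep(c(1, 2), each = 5))
#' net2 <- transfer_update(net, a, transfer = 50)
#' within_subgroup_sums(net2, a)  # cross links halved, within links grown
transfer_update <- function(net, assign, transfer) {
  stopifnot(inherits(net, "social_network"))
  n <- nrow(net)
  if (length(assign) != n)
    stop("`assign` must cover all ", n, " individuals", call. = FALSE)
  if (!is.numeric(transfer) || length(transfer) != 1L || is.na(transfer) ||
      transfer < 0 || transfer > 100)
    stop("`transfer` must be a percentage in [0, 100]", call. = FALSE)
  assign <- as.integer(assign)
  if (!is_temporary_fission(assign)) return(net)

  w <- unclass(net)
  f <- transfer / 100
  for (i in seq_len(n)) {
    same <- which(assign == assign[i])
    same <- same[same != i]
    if (length(same) == 0L) next
    cross <- which(assign != assign[i])
    loss <- sum(w[i, cross]) * f
    w[i, cross] <- w[i, cross] * (1 - f)
    w[i, same] <- w[i, same] + loss / length(same)
  }
  social_network(w)
}

#' Within-subgroup grooming-time sums
#'
#' For each individual, the share of its social time (in %) currently
#' directed at individuals assigned to the same resource area.
#'
#' @inheritParams transfer_update
#' @return Numeric vector of length `n`.
#' @export
within_subgroup_sums <- function(net, assign) {
  stopifnot(inherits(net, "social_network"))
  assign <- as.integer(assign)
  n <- nrow(net)
  vapply(seq_len(n), function(i) {
    same <- which(assign == assign[i])
    sum(net[i, setdiff(same, i)])
  }, numeric(1))
}

#' Test the irreversible-fission criterion
#'
#' The group has split irreversibly when (a) both subgroups hold at least
#' `min_subgroup` individuals — the departure of three or fewer individuals
#' counts as a dispersion, not a fission — and (b) every individual allots at
#' least `threshold` percent of its social time to members of its own
#' subgroup, leaving only insignificant links across the split. A day on
#' which the whole group used a single area is never a fission. The threshold
#' comparison is inclusive (`>=`), with a `1e-9` floating-point allowance.
#'
#' @inheritParams transfer_update
#' @param threshold Within-subgroup social-time threshold in percent
#'   (default 95).
#' @param min_subgroup Minimal viable subgroup size (default 4).
#' @return `TRUE` or `FALSE`.
#' @export
#' @examples
#' net <- init_egalitarian(10)
#' a <- day_assignment(rep(c(1, 2), each = 5))
#' check_irreversible(net, a)                        # FALSE: homogeneous
#' net2 <- transfer_update(net, a, transfer = 100)
#' check_irreversible(net2, a)                       # TRUE: cross links zeroed
check_irreversible <- function(net, assign, threshold = 95, min_subgroup = 4) {
  stopifnot(inherits(net, "social_network"))
  assign <- as.integer(assign)
  sz <- subgroup_sizes(assign)
  if (any(sz == 0L)) return(FALSE)
  if (any(sz < min_subgroup)) return(FALSE)
  all(within_subgroup_sums(net, assign) >= threshold - .fissim_tol)
}
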