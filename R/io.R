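#' Read a sweep configuration file
#'
#' Parses a YAML configuration describing a parameter grid and engine
#' settings. The `grid` section gives group sizes `n`, transfer percentages
#' `transfer`, and either an optional `ratio` filter over the standard
#' calibration pairs (see [standard_conditions()]) or an explicit
#' `conditions` list of `{C, lambda1, lambda2}` entries. The `engine`
#' section may override `max_days` (default 900), `reps` (default 1000),
#' `threshold` (default 95) and `min_subgroup` (default 4); `base_seed` is
#' required. Every condition is validated on load, so an infeasible entry
#' (violating `(lambda1 + lambda2) <= 1 - C*100`) fails immediately with a
#' message naming it.
#'
#' @param path Path to a YAML file.
#' @return A list with elements `grid` (condition tibble), `reps`,
#'   `base_seed`, `max_days`, `threshold`, `min_subgroup`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$grid)) stop("config is missing a `grid` section",
                              call. = FALSE)
  g <- cfg$grid
  # YAML 1.1 treats a bare `n` key as boolean FALSE; accept both spellings
  g_n <- if (!is.null(g$n)) g$n else g[["FALSE"]]
  n <- if (is.null(g_n)) c(10L, 20L) else as.integer(unlist(g_n))
  transfer <- if (is.null(g$transfer)) seq(10, 100, by = 10)
              else as.numeric(unlist(g$transfer))
  if (!is.null(g$conditions)) {
    rows <- lapply(g$conditions, function(cc) {
      tibble::tibble(C = as.numeric(cc$C), lambda1 = as.numeric(cc$lambda1),
                     lambda2 = as.numeric(cc$lambda2))
    })
    pairs <- dplyr::bind_rows(rows)
    pairs$ratio <- ifelse(pairs$C > 0,
                          round(.ns_ratio(pairs$lambda1, pairs$lambda2,
                                          pairs$C), 2), NA_real_)
    grid <- tidyr_crossing(n = n, pairs, transfer = transfer)
    grid <- grid[, c("n", "C", "lambda1", "lambda2", "transfer", "ratio")]
  } else {
    grid <- standard_conditions(
      n = n, transfer = transfer,
      ratio = if (is.null(g$ratio)) NULL else as.numeric(unlist(g$ratio)))
  }
  if (nrow(grid) == 0L)
    stop("configuration produced an empty condition grid", call. = FALSE)
  # validate feasibility row by row, naming the offender
  for (j in seq_len(nrow(grid))) {
    r <- grid[j, ]
    tryCatch(
      condition(r$n, r$C, r$lambda1, r$lambda2, r$transfer),
      error = function(e) stop(
        sprintf("invalid condition in config (row %d): %s", j,
                conditionMessage(e)), call. = FALSE))
  }
  eng <- if (is.null(cfg$engine)) list() else cfg$engine
  if (is.null(cfg$base_seed))
    stop("config is missing `base_seed`", call. = FALSE)
  list(grid = grid,
       reps = if (is.null(eng$reps)) 1000L else as.integer(eng$reps),
       base_seed = as.integer(cfg$base_seed),
       max_days = if (is.null(eng$max_days)) 900L
                  else as.integer(eng$max_days),
       threshold = if (is.null(eng$threshold)) 95
                   else as.numeric(eng$threshold),
       min_subgroup = if (is.null(eng$min_subgroup)) 4L
                      else as.integer(eng$min_subgroup))
}

.batch_cols <- c("n", "C", "lambda1", "lambda2", "transfer", "ratio",
                 "replicate", "seed", "days", "censored")

.fmt_num <- function(x) {
  # 12 significant digits: enough to round-trip weights and re-verify the
  # row-sum budget, stable across writes of the same table
  ifelse(is.na(x), "NA", formatC(x, digits = 12, format = "g"))
}

#' Write and read batch result tables
#'
#' Persists a batch as tidy CSV with the fixed column set
#' `n,C,lambda1,lambda2,transfer,ratio,replicate,seed,days,censored`.
#' Numbers are written with 12 significant digits and rows in table order,
#' so identical batches produce identical bytes. `read_results()` validates
#' the header and every row, reporting the first offending row on a schema
#' mismatch, and recomputes the derived `viable` flag.
#'
#' @param batch A batch tibble from [run_batch()].
#' @param path Output (input) CSV path.
#' @return `write_results()` the path, invisibly; `read_results()` a batch
#'   tibble.
#' @export
write_results <- function(batch, path) {
  miss <- setdiff(.batch_cols, names(batch))
  if (length(miss) > 0)
    stop("batch is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  num <- setdiff(.batch_cols, "censored")
  body <- do.call(paste, c(lapply(num, function(cl) .fmt_num(batch[[cl]])),
                           list(ifelse(batch$censored, "TRUE", "FALSE")),
                           sep = ","))
  writeLines(c(paste(.batch_cols, collapse = ","), body), path)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop("results file not found: ", path,
                               call. = FALSE)
  header <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
  miss <- setdiff(.batch_cols, header)
  if (length(miss) > 0)
    stop("results file is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (cl in setdiff(.batch_cols, c("censored", "ratio"))) {
    bad <- which(!is.finite(df[[cl]]))
    if (length(bad) > 0)
      stop(sprintf("results file %s: non-numeric `%s` at data row %d",
                   path, cl, bad[1]), call. = FALSE)
  }
  if (!is.logical(df$censored))
    stop("results file: `censored` must be TRUE/FALSE", call. = FALSE)
  out <- tibble::as_tibble(df[.batch_cols])
  out$n <- as.integer(out$n)
  out$replicate <- as.integer(out$replicate)
  out$seed <- as.integer(out$seed)
  out$days <- as.integer(out$days)
  out$viable <- !out$censored & out$days >= 90 & out$days <= 900
  out
}

#' Snapshot a grooming network as a weighted edge list
#'
#' Writes all `n * (n - 1)` directed off-diagonal edges as CSV with header
#' `day,source,target,weight`; individuals carry 0-based integer ids and
#' weights are written with 12 significant digits (full effective
#' precision). `read_network()` rebuilds the `social_network`.
#'
#' @param net A [social_network()].
#' @param path CSV path.
#' @param day Day index stamped on every edge row (default 0).
#' @return `write_network()` the path, invisibly; `read_network()` a
#'   [social_network()].
#' @export
write_network <- function(net, path, day = 0L) {
  stopifnot(inherits(net, "social_network"))
  n <- nrow(net)
  src <- rep(seq_len(n), each = n)
  tgt <- rep(seq_len(n), times = n)
  keep <- src != tgt
  src <- src[keep]; tgt <- tgt[keep]
  lines <- paste(as.integer(day), src - 1L, tgt - 1L,
                 .fmt_num(net[cbind(src, tgt)]), sep = ",")
  writeLines(c("day,source,target,weight", lines), path)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  if (!file.exists(path)) stop("network file not found: ", path,
                               call. = FALSE)
  header <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
  need <- c("day", "source", "target", "weight")
  miss <- setdiff(need, header)
  if (length(miss) > 0)
    stop("network file is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  df <- utils::read.csv(path)
  n <- max(df$source, df$target) + 1L
  w <- matrix(0, n, n)
  w[cbind(df$source + 1L, df$target + 1L)] <- df$weight
  social_network(w)
}

#' Export a grooming network to GraphML
#'
#' Writes the network as a directed weighted GraphML file (via igraph) for
#' use in external network tools.
#'
#' @inheritParams write_network
#' @return The path, invisibly.
#' @export
write_network_graphml <- function(net, path) {
  stopifnot(inherits(net, "social_network"))
  if (!requireNamespace("igraph", quietly = TRUE))
    stop("GraphML export requires the `igraph` package", call. = FALSE)
  g <- igraph::graph_from_adjacency_matrix(unclass(net), mode = "directed",
                                           weighted = TRUE, diag = FALSE)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Deterministic test networks
#'
#' Constructs small networks with documented structure for tests and
#' examples:
#' \describe{
#'   \item{`egalitarian`}{identical to [init_egalitarian()].}
#'   \item{`pre_clustered`}{the egalitarian network after `steps` repeated
#'     [transfer_update()] applications with the fixed `split`; with a
#'     balanced split each cross-subgroup link decays geometrically, so the
#'     within-subgroup sum is `100 - m2 * (100 / (n - 1)) * (1 - T/100)^k`
#'     with `m2` the opposite subgroup size.}
#'   \item{`near_fission`}{a network whose within-subgroup sums all equal
#'     `within` (default 92.5, inside `[90, 95)`), straddling the default
#'     irreversible-fission threshold for boundary tests.}
#' }
#'
#' @param kind One of `"egalitarian"`, `"pre_clustered"`, `"near_fission"`.
#' @param n Number of individuals.
#' @param split Integer 1/2 vector assigning individuals to subgroups
#'   (default: first half vs second half); used by the clustered kinds.
#' @param transfer Transfer percentage for `pre_clustered` (default 50).
#' @param steps Number of transfer steps for `pre_clustered` (default 5).
#' @param within Target within-subgroup sum for `near_fission`
#'   (default 92.5).
#' @return A [social_network()].
#' @export
#' @examples
#' make_fixture("pre_clustered", 10, transfer = 50, steps = 5)
make_fixture <- function(kind = c("egalitarian", "pre_clustered",
                                  "near_fission"),
                         n, split = NULL, transfer = 50, steps = 5,
                         within = 92.5) {
  kind <- match.arg(kind)
  if (kind == "egalitarian") return(init_egalitarian(n))
  if (is.null(split)) split <- rep(c(1L, 2L), c(floor(n / 2), ceiling(n / 2)))
  split <- as.integer(split)
  if (length(split) != n || !all(split %in% c(1L, 2L)) ||
      length(unique(split)) != 2L)
    stop("`split` must partition all ", n, " individuals into two subgroups",
         call. = FALSE)
  if (kind == "pre_clustered") {
    net <- init_egalitarian(n)
    a <- day_assignment(split)
    for (k in seq_len(steps)) net <- transfer_update(net, a, transfer)
    return(net)
  }
  # near_fission: every within sum exactly `within`
  if (within < 0 || within > 100)
    stop("`within` must be in [0, 100]", call. = FALSE)
  if (any(tabulate(split, 2L) < 2L))
    stop("`near_fission` needs at least 2 individuals per subgroup",
         call. = FALSE)
  w <- matrix(0, n, n)
  for (i in seq_len(n)) {
    same <- setdiff(which(split == split[i]), i)
    cross <- which(split != split[i])
    w[i, same] <- within / length(same)
    w[i, cross] <- (100 - within) / length(cross)
  }
  social_network(w)
}

#' Build and write a run manifest
#'
#' A manifest records everything required to bit-reproduce a batch: the
#' condition grid, engine settings, base seed, derived first-replicate seed
#' per condition, package version and timestamp.
#'
#' @param grid Condition grid (as passed to [run_batch()]).
#' @param reps,base_seed,max_days,threshold,min_subgroup Batch settings.
#' @return A list of class `run_manifest`.
#' @export
run_manifest <- function(grid, reps, base_seed, max_days = 900,
                         threshold = 95, min_subgroup = 4) {
  grid <- as.data.frame(grid)
  structure(list(
    package = "fissim",
    version = as.character(utils::packageVersion("fissim")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    base_seed = as.integer(base_seed), reps = as.integer(reps),
    max_days = as.integer(max_days), threshold = threshold,
    min_subgroup = as.integer(min_subgroup),
    grid = grid,
    condition_first_seeds = vapply(
      seq_len(nrow(grid)), function(ci) derive_seed(base_seed, ci, 1L),
      integer(1))),
    class = "run_manifest")
}

#' @rdname run_manifest
#' @param manifest A `run_manifest`.
#' @param path Output JSON path.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "run_manifest"))
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Render a plain-markdown analysis report
#'
#' Writes a small markdown report over a batch: per-condition summaries, the
#' transfer-linearity regression and ratio groupings per group size, and the
#' Poisson covariate model.
#'
#' @inheritParams summarize_batch
#' @param path Output markdown path.
#' @return The path, invisibly.
#' @export
analysis_report <- function(batch, path) {
  ln <- character(0)
  add <- function(...) ln <<- c(ln, ...)
  add("# Days-to-fission analysis", "",
      sprintf("Replicate rows: %d; conditions: %d.", nrow(batch),
              nrow(unique(batch[c("n", "ratio", "transfer")]))), "")
  s <- summarize_batch(batch, censor_policy = "cap_at_max")
  add("## Condition summaries (censored capped at the day limit)", "",
      "| n | ratio | transfer | mean | min | max | fission fraction |",
      "|---|-------|----------|------|-----|-----|------------------|")
  for (j in seq_len(nrow(s)))
    add(sprintf("| %d | %.2f | %g | %.1f | %g | %g | %.2f |",
                s$n[j], s$ratio[j], s$transfer[j], s$mean_days[j],
                s$min_days[j], s$max_days[j], s$fission_fraction[j]))
  add("")
  for (nn in sort(unique(batch$n))) {
    md <- mean_days_by_transfer(batch, n = nn)
    if (nrow(md) >= 3) {
      tl <- transfer_linearity(md)
      add(sprintf("## Transfer linearity, n = %d", nn), "",
          sprintf(paste0("slope = %.3f days per percentage point, ",
                         "r^2 = %.3f, F(%d,%d) = %.1f, p = %.3g"),
                  tl$slope, tl$r_squared, tl$df1, tl$df2, tl$F_statistic,
                  tl$p_value), "")
    }
    if (length(unique(batch$ratio[batch$n == nn])) >= 2) {
      rg <- ratio_groups(batch, n = nn)
      add(sprintf("## Ratio groups, n = %d (Kruskal-Wallis K = %.1f, p = %.3g)",
                  nn, unname(rg$kruskal$statistic), rg$kruskal$p.value), "",
          "| ratio | mean rank | group |", "|-------|-----------|-------|")
      for (j in order(rg$groups$ratio))
        add(sprintf("| %.2f | %.1f | %d |", rg$groups$ratio[j],
                    rg$groups$mean_rank[j], rg$groups$group[j]))
      add("")
    }
  }
  can_glm <- sum(vapply(c("n", "transfer", "ratio"),
                        function(v) length(unique(batch[[v]])) > 1L,
                        logical(1)))
  if (can_glm >= 1) {
    pm <- suppressWarnings(poisson_covariate_model(batch))
    add("## Poisson covariate model (log link, censored capped)", "",
        "| term | estimate | z | p |", "|------|----------|---|---|")
    for (j in seq_len(nrow(pm$coefficients)))
      add(sprintf("| %s | %.4g | %.1f | %.3g |", pm$coefficients$term[j],
                  pm$coefficients$estimate[j], pm$coefficients$z[j],
                  pm$coefficients$p_value[j]))
    add("")
  }
  writeLines(ln, path)
  invisible(path)
}
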