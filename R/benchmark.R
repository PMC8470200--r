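# Scalability harness. Task 1 measures ingestion time (building the RDF
# graph) for an increasing number of observations; Task 2 measures rule
# evaluation time and the number of problem objects generated for an
# increasing number of observations in the knowledge base, per rule.
# Wall-clock times depend on hardware and are reported, never asserted;
# object counts are deterministic under a fixed seed, and the Task 2
# datasets are nested day-aligned prefixes so generated counts are
# non-decreasing in the KB size.

elapsed_ms <- function(expr) {
  t <- system.time(force(expr))[["elapsed"]]
  round(1000 * t, 1)
}

#' Task 1: ingestion scaling
#'
#' For each size `n`, generates `n` classified observations and measures the
#' time to build their knowledge graph.
#'
#' @param sizes Positive ascending counts.
#' @param seed Integer seed (drives the observation generator; counts are
#'   reproducible, times are not).
#' @return Data frame: `n_objects_in_kb`, `elapsed_ms`, `n_triples`.
#' @export
run_task1 <- function(sizes, seed = 1) {
  if (!length(sizes)) {
    return(data.frame(n_objects_in_kb = integer(), elapsed_ms = numeric(),
                      n_triples = integer()))
  }
  wkg_stopifnot(all(sizes > 0) && !is.unsorted(sizes),
                "sizes must be positive and ascending")
  rows <- lapply(sizes, function(n) {
    obs <- generate_benchmark_objects(n, seed)
    kg <- NULL
    ms <- elapsed_ms(kg <- build_graph(obs))
    data.frame(n_objects_in_kb = n, elapsed_ms = ms, n_triples = kg_size(kg))
  })
  do.call(rbind, rows)
}

# Per-day observation payload of the synthetic generator (two per-minute
# streams plus the sleep-derived observations).
obs_per_day <- function(day_data) {
  nrow(to_observations(day_data$steps)) + nrow(to_observations(day_data$hr)) +
    nrow(to_observations(day_data$sessions))
}

slice_days <- function(data, dates) {
  keep_s <- wkg_date(data$steps$samples$timestamp) %in% dates
  keep_h <- wkg_date(data$hr$samples$timestamp) %in% dates
  keep_sess <- wkg_date(data$sessions$end) %in% dates
  steps <- data$steps; steps$samples <- steps$samples[keep_s, , drop = FALSE]
  hr <- data$hr; hr$samples <- hr$samples[keep_h, , drop = FALSE]
  sess <- data$sessions[keep_sess, , drop = FALSE]
  class(sess) <- c("sleep_sessions", "data.frame")
  list(steps = steps, hr = hr, sessions = sess)
}

#' Task 2: rule scaling
#'
#' Builds one nested synthetic dataset (problem episodes of every requested
#' rule injected on alternating days), then for each size takes the largest
#' whole-day prefix within the observation budget and, per rule, measures
#' evaluation time and the number of problems generated. Day-aligned
#' prefixes make the generated counts non-decreasing in size.
#'
#' @param sizes Positive ascending observation budgets.
#' @param rule_ids Rules to evaluate (default trio: LackOfMovement,
#'   LowSleepQuality, LackOfSleep).
#' @param seed Integer seed.
#' @return Data frame: `rule_id`, `n_objects_in_kb` (observations actually
#'   in the prefix), `elapsed_ms`, `n_objects_generated`.
#' @export
run_task2 <- function(sizes,
                      rule_ids = c("LackOfMovement", "LowSleepQuality",
                                   "LackOfSleep"),
                      seed = 1) {
  rb <- default_rulebase()
  bad <- setdiff(rule_ids, names(rb$rules))
  wkg_stopifnot(!length(bad), paste0("unknown rule: ", bad[1]))
  if (!length(sizes)) {
    return(data.frame(rule_id = character(), n_objects_in_kb = integer(),
                      elapsed_ms = numeric(), n_objects_generated = integer()))
  }
  wkg_stopifnot(all(sizes > 0) && !is.unsorted(sizes),
                "sizes must be positive and ascending")

  probe <- generate_subject_days(synthetic_profile(), 1, seed)
  per_day <- obs_per_day(probe)
  n_days <- max(2L, ceiling(max(sizes) / per_day))
  data <- generate_subject_days(synthetic_profile(), n_days, seed)
  dates <- sort(unique(wkg_date(data$steps$samples$timestamp)))
  # inject each rule's episode on alternating days so counts grow with size
  for (i in seq_along(dates)) {
    if (i %% 2L == 0L) {
      rid <- rule_ids[((i / 2L - 1L) %% length(rule_ids)) + 1L]
      data <- inject_problem_episode(data, rid, dates[i])
    }
  }
  rows <- list()
  for (n in sizes) {
    take <- max(which(cumsum(rep(per_day, n_days)) <= n), 0L)
    prefix <- slice_days(data, dates[seq_len(take)])
    n_obs <- if (take == 0L) 0L else {
      nrow(to_observations(prefix$steps)) +
        nrow(to_observations(prefix$hr)) +
        nrow(to_observations(prefix$sessions))
    }
    for (rid in rule_ids) {
      one <- structure(list(rules = rb$rules[rid], overrides = list()),
                       class = "rulebase")
      res <- NULL
      ms <- elapsed_ms(
        res <- run_rulebase(prefix$steps, prefix$hr, prefix$sessions,
                            rulebase = one, graph = FALSE))
      rows[[length(rows) + 1L]] <-
        data.frame(rule_id = rid, n_objects_in_kb = n_obs, elapsed_ms = ms,
                   n_objects_generated = length(res$problems))
    }
  }
  do.call(rbind, rows)
}
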