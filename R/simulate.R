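#' Collective initiation probability
#'
#' With every individual carrying the same intrinsic per-second
#' departure probability `lam`, the per-second probability that some
#' individual initiates a movement is `n * lam` (the first-order
#' collective rate; at `lam = 0.00007` and `n = 10` this is 0.0007 per
#' second, an expected initiation latency of about 1429 s).
#'
#' @param config a [sim_config()].
#' @param n group size.
#' @return Probability per second.
#' @export
initiation_probability <- function(config, n) {
  stopifnot(inherits(config, "sim_config"), n >= 1)
  n * config$lam
}

# amplification factor of the mimetic term for j movers in a group of N
kernel_amplification <- function(kernel, j, N) {
  switch(kernel,
         K1 = 1,
         K2 = N - j,
         K3 = j * (N - j),
         stop("unknown kernel '", kernel, "'", call. = FALSE))
}

#' Per-second joining probability of a resting individual
#'
#' The mimetic (allelomimetic) joining rule: a resting individual `i`
#' departs in a given second with probability equal to its intrinsic
#' rate plus a mimetic term proportional to its summed affiliation
#' toward the individuals already moving,
#' `psi_i = lam + M * A(j, N) * sum_k r(i, k)` over moving `k`, where
#' the amplification `A` depends on the kernel variant (see
#' [sim_config()]). Affiliation toward resting individuals contributes
#' nothing. The result is clamped below 1 and never falls below `lam`.
#'
#' @param net a [social_network()].
#' @param moving character vector of labels already moving.
#' @param i label of the resting individual.
#' @param config a [sim_config()].
#' @return Probability per second.
#' @export
#' @examples
#' star <- build_continuum_network(10, 1)
#' joining_probability(star, "C", "c1", sim_config(kernel = "K1"))
joining_probability <- function(net, moving, i, config) {
  stopifnot(inherits(net, "social_network"), inherits(config, "sim_config"))
  if (i %in% moving) {
    stop("individual '", i, "' is already moving", call. = FALSE)
  }
  if (!all(c(i, moving) %in% net$labels)) {
    stop("unknown label(s) in 'moving' or 'i'", call. = FALSE)
  }
  N <- n_individuals(net)
  j <- length(moving)
  if (j == 0) return(config$lam)
  amp <- kernel_amplification(config$kernel, j, N)
  s <- sum(net$weights[i, moving])
  min(config$lam + config$M * amp * s, 1 - 1e-12)
}

# psi vector for all resting individuals (indices), given mover indices
psi_resting <- function(W, resting, moving, config, N) {
  if (length(moving) == 0) return(rep(config$lam, length(resting)))
  amp <- kernel_amplification(config$kernel, length(moving), N)
  s <- rowSums(W[resting, moving, drop = FALSE])
  pmin(config$lam + config$M * amp * s, 1 - 1e-12)
}

new_departure_record <- function(ids, times, n, void = FALSE,
                                 truncated = FALSE) {
  structure(list(
    initiator = if (length(ids)) ids[1L] else NA_character_,
    events = data.frame(id = ids, time = times, stringsAsFactors = FALSE),
    n_departed = length(ids),
    complete = length(ids) == n,
    void = void,
    truncated = truncated), class = "departure_record")
}

#' @export
print.departure_record <- function(x, ...) {
  if (x$void) {
    cat("Void replicate: no initiation before the time cap\n")
    return(invisible(x))
  }
  cat(sprintf("Collective movement: %d departed%s, initiator %s at t = %d s\n",
              x$n_departed, if (x$complete) " (complete)" else "",
              x$initiator, as.integer(x$events$time[1])))
  if (x$n_departed > 1) {
    cat("Departure times (s):",
        paste(sprintf("%s@%d", x$events$id, as.integer(x$events$time)),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Run one replicate of the departure model (per-second loop)
#'
#' The literal formulation of the model: at each one-second time step a
#' uniform number in (0, 1) is attributed to every resting individual,
#' which departs when the number falls below its current departure
#' probability (the intrinsic rate before anyone moves, the mimetic
#' [joining_probability()] afterwards). Several individuals may depart
#' within the same second; they share a timestamp and their rank order
#' within the second is randomized. The replicate ends when all have
#' departed or when `stop_window` seconds pass with no departure after
#' the last one; the stop clock does not run before initiation, which
#' is instead bounded by `max_time` (a replicate that never initiates
#' is flagged void).
#'
#' Seconds in which the state cannot change are evaluated in vectorized
#' blocks of independent per-second draws, which leaves the sampled
#' process identical to the naive loop.
#'
#' Uses the current RNG state; see [run_batch()] for seeded batches.
#'
#' @param net a connected [social_network()].
#' @param config a [sim_config()].
#' @return An object of class `departure_record`: `initiator`, ordered
#'   `events` (label, integer-second time from simulation start),
#'   `n_departed` (initiator included), `complete`, `void`, `truncated`.
#' @export
run_replicate <- function(net, config) {
  stopifnot(inherits(net, "social_network"), inherits(config, "sim_config"))
  W <- net$weights
  N <- n_individuals(net)
  ids <- integer(0)
  times <- numeric(0)
  t <- 0
  # --- initiation phase: everyone rests at rate lam
  repeat {
    block <- min(4096, config$max_time - t)
    if (block <= 0) {
      return(new_departure_record(character(0), numeric(0), N, void = TRUE))
    }
    hit <- matrix(stats::runif(N * block), nrow = N) < config$lam
    col <- first_hit_column(hit)
    if (is.na(col)) {
      t <- t + block
      next
    }
    t <- t + col
    dep <- which(hit[, col])
    if (length(dep) > 1) dep <- sample(dep)
    ids <- dep
    times <- rep(t, length(dep))
    break
  }
  # --- joining phase: mimetic rates, stop clock running
  while (length(ids) < N) {
    resting <- setdiff(seq_len(N), ids)
    psi <- psi_resting(W, resting, ids, config, N)
    window <- config$stop_window
    found <- FALSE
    while (window > 0) {
      block <- min(512, window)
      hit <- matrix(stats::runif(length(resting) * block),
                    nrow = length(resting)) < psi
      col <- first_hit_column(hit)
      if (is.na(col)) {
        window <- window - block
        next
      }
      t <- t + (config$stop_window - window) + col
      dep <- resting[hit[, col]]
      if (length(dep) > 1) dep <- sample(dep)
      ids <- c(ids, dep)
      times <- c(times, rep(t, length(dep)))
      found <- TRUE
      break
    }
    if (!found) break
    if (t > config$max_time) {
      return(new_departure_record(net$labels[ids], times, N,
                                  truncated = TRUE))
    }
  }
  new_departure_record(net$labels[ids], times, N)
}

# index of the first column of a logical matrix containing any TRUE,
# or NA if none does
first_hit_column <- function(hit) {
  cs <- .colSums(hit, nrow(hit), ncol(hit))
  idx <- which(cs > 0L)
  if (length(idx)) idx[1L] else NA_integer_
}

#' Run one replicate by event-driven (geometric waiting time) sampling
#'
#' Distributionally equivalent alternative to [run_replicate()]: between
#' state changes every resting individual's waiting time is geometric
#' with its current per-second probability, so the next departure second
#' is the minimum of independent geometric draws rather than the first
#' success of explicit per-second Bernoulli draws. Serves as an
#' independent route for verifying the per-second loop; batch summary
#' means from the two routes agree within Monte-Carlo error.
#'
#' @inheritParams run_replicate
#' @return A `departure_record`.
#' @export
event_driven_replicate <- function(net, config) {
  stopifnot(inherits(net, "social_network"), inherits(config, "sim_config"))
  W <- net$weights
  N <- n_individuals(net)
  # initiation: minimum of N geometric(lam) waits, capped at max_time
  g <- stats::rgeom(N, config$lam) + 1
  t0 <- min(g)
  if (t0 > config$max_time) {
    return(new_departure_record(character(0), numeric(0), N, void = TRUE))
  }
  dep <- which(g == t0)
  if (length(dep) > 1) dep <- sample(dep)
  ids <- dep
  times <- rep(t0, length(dep))
  t <- t0
  while (length(ids) < N) {
    resting <- setdiff(seq_len(N), ids)
    psi <- psi_resting(W, resting, ids, config, N)
    g <- stats::rgeom(length(resting), psi) + 1
    w <- min(g)
    if (w > config$stop_window) break
    t <- t + w
    dep <- resting[g == w]
    if (length(dep) > 1) dep <- sample(dep)
    ids <- c(ids, dep)
    times <- c(times, rep(t, length(dep)))
    if (t > config$max_time) {
      return(new_departure_record(net$labels[ids], times, N,
                                  truncated = TRUE))
    }
  }
  new_departure_record(net$labels[ids], times, N)
}

#' Run a seeded batch of replicates
#'
#' Replicate `r` runs on an independent RNG substream derived from the
#' base seed, so a batch is bit-reproducible and each replicate's
#' outcome does not depend on execution order. The caller's RNG state
#' is left untouched.
#'
#' @param net a connected [social_network()].
#' @param config a [sim_config()]; `config$replicates` and
#'   `config$seed` control the batch.
#' @param method `"loop"` for the per-second formulation (default) or
#'   `"event"` for the event-driven oracle.
#' @param progress print a progress note every 2000 replicates.
#' @return An object of class `departure_batch`: list with `records`
#'   (list of `departure_record`), `table` (one row per replicate, see
#'   [as.data.frame.departure_batch()]), `config`, `network_name`,
#'   `central`, `labels`, `n_void`, `method`.
#' @export
#' @examples
#' star <- build_continuum_network(10, 1)
#' b <- run_batch(star, sim_config(replicates = 50, seed = 7))
#' summary(b)
run_batch <- function(net, config, method = c("loop", "event"),
                      progress = FALSE) {
  stopifnot(inherits(net, "social_network"), inherits(config, "sim_config"))
  method <- match.arg(method)
  if (!is_connected_weights(net$weights)) {
    stop("network is not connected; the departure model is undefined",
         call. = FALSE)
  }
  one <- if (method == "loop") run_replicate else event_driven_replicate
  records <- with_seed(config$seed, {
    seeds <- sample.int(.Machine$integer.max - 1L, config$replicates)
    lapply(seq_len(config$replicates), function(r) {
      set.seed(seeds[r])
      rec <- one(net, config)
      if (progress && r %% 2000 == 0) {
        message(sprintf("  replicate %d / %d", r, config$replicates))
      }
      rec
    })
  })
  batch <- structure(list(
    records = records,
    config = config,
    network_name = net$name,
    central = net$central,
    labels = net$labels,
    n_void = sum(vapply(records, `[[`, TRUE, "void")),
    method = method), class = "departure_batch")
  batch$table <- batch_table(batch)
  batch
}

batch_table <- function(batch) {
  recs <- batch$records
  n <- length(recs)
  tab <- data.frame(
    replicate = seq_len(n),
    initiator = vapply(recs, `[[`, "", "initiator"),
    n_departed = vapply(recs, `[[`, 0L, "n_departed"),
    t_init = vapply(recs, function(r)
      if (r$n_departed >= 1) r$events$time[1] else NA_real_, 0),
    first_joiner = vapply(recs, function(r)
      if (r$n_departed >= 2) r$events$id[2] else NA_character_, ""),
    dT12 = vapply(recs, function(r)
      if (r$n_departed >= 2) r$events$time[2] - r$events$time[1]
      else NA_real_, 0),
    dT1N = vapply(recs, function(r)
      if (r$complete) r$events$time[r$n_departed] - r$events$time[1]
      else NA_real_, 0),
    complete = vapply(recs, `[[`, TRUE, "complete"),
    void = vapply(recs, `[[`, TRUE, "void"),
    truncated = vapply(recs, `[[`, TRUE, "truncated"),
    stringsAsFactors = FALSE)
  tab
}

#' One row per replicate of a batch
#'
#' Columns: `replicate`, `initiator`, `n_departed` (initiator
#' included), `t_init` (initiation latency from simulation start, s),
#' `first_joiner`, `dT12` (first-joiner latency, s; `NA` without a
#' joiner), `dT1N` (duration of joining, s; `NA` unless complete),
#' `complete`, `void`, `truncated`.
#'
#' @param x a `departure_batch`.
#' @param ... unused.
#' @export
as.data.frame.departure_batch <- function(x, ...) x$table

#' @export
print.departure_batch <- function(x, ...) {
  cat(sprintf("Departure batch: %d replicates on network '%s' (%s kernel, %s)\n",
              length(x$records), x$network_name %||% "?",
              x$config$kernel,
              if (x$method == "loop") "per-second loop" else "event-driven"))
  ok <- !x$table$void
  cat(sprintf("  mean departed %.3f of %d; %d complete; %d void\n",
              mean(x$table$n_departed[ok]), length(x$labels),
              sum(x$table$complete), x$n_void))
  invisible(x)
}

#' Simulate collective movements on a network
#'
#' `simulate()` method: runs a seeded batch of the departure model on
#' the network, a convenience wrapper around [run_batch()].
#'
#' @param object a [social_network()].
#' @param nsim number of replicates.
#' @param seed base seed (overrides `config$seed` when non-NULL).
#' @param config a [sim_config()].
#' @param ... passed to [run_batch()].
#' @return A `departure_batch`.
#' @export
simulate.social_network <- function(object, nsim = 10000, seed = NULL,
                                    config = sim_config(), ...) {
  config$replicates <- as.integer(nsim)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  run_batch(object, config, ...)
}
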