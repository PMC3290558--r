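#' Simulation configuration
#'
#' Parameters of the stochastic departure model. The defaults are the
#' empirically derived constants of the study system: an intrinsic
#' per-individual departure probability `lam = 0.00007` per second
#' (so that the collective initiation probability at group size 10 is
#' 0.0007 per second), a mimetic coefficient `M = 0.002` per unit
#' affiliation per second, a 300-second stop window, and 10,000
#' replicates per network.
#'
#' @param lam intrinsic departure probability per individual per second,
#'   in (0, 1).
#' @param M mimetic coefficient (per unit affiliation per second),
#'   nonnegative.
#' @param kernel mimetic-kernel variant. With `j` individuals moving,
#'   group size `N`, and `S` the resting individual's summed affiliation
#'   toward the movers, the per-second joining probability is
#'   `lam + M*S` (`"K1"`, the literal reading),
#'   `lam + M*(N-j)*S` (`"K2"`), or `lam + M*j*(N-j)*S` (`"K3"`).
#'   The default `"K2"` is the calibrated reference kernel: it is the
#'   variant whose 10,000-replicate star-network summaries come closest
#'   to the benchmark decision statistics (see
#'   [reference_star_summaries()] and [calibrate_kernel()]).
#' @param stop_window seconds without any departure, after the first,
#'   that end a replicate.
#' @param max_time hard cap (s) on the wait for the first departure; a
#'   replicate that never initiates within it is flagged void.
#' @param replicates number of Monte-Carlo replicates in a batch.
#' @param seed base integer seed; each replicate uses an independent
#'   substream derived from it, so batches are reproducible and
#'   replicate results do not depend on execution order.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(lam = 0.00007, M = 0.002,
                       kernel = c("K2", "K1", "K3"),
                       stop_window = 300, max_time = 1e6,
                       replicates = 10000, seed = 1L) {
  kernel <- match.arg(kernel)
  if (!is.numeric(lam) || length(lam) != 1 || lam <= 0 || lam >= 1) {
    stop("'lam' must be a probability in (0, 1)", call. = FALSE)
  }
  if (!is.numeric(M) || length(M) != 1 || M < 0) {
    stop("'M' must be nonnegative", call. = FALSE)
  }
  if (!is.numeric(stop_window) || stop_window <= 0) {
    stop("'stop_window' must be positive", call. = FALSE)
  }
  if (!is.numeric(max_time) || max_time < stop_window) {
    stop("'max_time' must be at least 'stop_window'", call. = FALSE)
  }
  if (!is.numeric(replicates) || replicates < 1) {
    stop("'replicates' must be at least 1", call. = FALSE)
  }
  structure(list(lam = lam, M = M, kernel = kernel,
                 stop_window = as.numeric(stop_window),
                 max_time = as.numeric(max_time),
                 replicates = as.integer(replicates),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "Departure-model configuration: lam = %g /s, M = %g, kernel = %s\n",
    x$lam, x$M, x$kernel))
  cat(sprintf("  stop window %g s, max time %g s, %d replicates, seed %d\n",
              x$stop_window, x$max_time, x$replicates, x$seed))
  invisible(x)
}

#' Read a key-value configuration file
#'
#' Plain-text `key = value` (or `key: value`) lines; `#` starts a
#' comment. Recognized keys are the arguments of [sim_config()] plus
#' `network` (a generator name understood by
#' [make_canonical_networks()] or a file path).
#'
#' @param path file path.
#' @return A list with elements `config` (a [sim_config()]) and
#'   `network` (character or `NULL`).
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*[=:]\\s*")
  bad <- lengths(kv) != 2
  if (any(bad)) {
    stop("cannot parse config line: '", lines[bad][1], "'", call. = FALSE)
  }
  vals <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  args <- list()
  for (key in c("lam", "M", "stop_window", "max_time", "replicates", "seed")) {
    if (key %in% names(vals)) args[[key]] <- as.numeric(vals[[key]])
  }
  if ("kernel" %in% names(vals)) args$kernel <- vals[["kernel"]]
  unknown <- setdiff(names(vals), c("lam", "M", "kernel", "stop_window",
                                    "max_time", "replicates", "seed",
                                    "network"))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  list(config = do.call(sim_config, args),
       network = if ("network" %in% names(vals)) vals[["network"]] else NULL)
}
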