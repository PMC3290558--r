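#' Benchmark star-network decision statistics
#'
#' The canonical star-network summaries the mimetic kernel is
#' calibrated against, from the original 10,000-replicate study of this
#' model at `lam = 0.00007`, `M = 0.002`, 300-s stop window: mean
#' number of departed individuals (initiator included) 9.99 when the
#' central individual initiates and 5.1 when a non-central individual
#' does, and mean first-joiner latencies of 6.75 s and 137.22 s for the
#' same two classes.
#'
#' @return Named numeric vector with elements `mean_joiners_C`,
#'   `mean_joiners_c`, `first_latency_C`, `first_latency_c`.
#' @export
reference_star_summaries <- function() {
  c(mean_joiners_C = 9.99, mean_joiners_c = 5.1,
    first_latency_C = 6.75, first_latency_c = 137.22)
}

# the four class-conditional star summaries of a batch, in the order
# of reference_star_summaries()
star_summary_vector <- function(batch) {
  s <- summary(batch)
  cl <- s$classes
  g <- function(class, var) cl[cl$class == class, var]
  c(mean_joiners_C = g("C_init", "mean_joiners"),
    mean_joiners_c = g("c_init", "mean_joiners"),
    first_latency_C = g("C_init", "mean_first_latency"),
    first_latency_c = g("c_init", "mean_first_latency"))
}

#' Calibrate the mimetic kernel on the star network
#'
#' The mimetic amplification law is not identifiable from the model's
#' defining rates alone, so it is treated as a configurable variant and
#' selected empirically: each candidate kernel is run for `replicates`
#' star-network replicates and scored by its worst (maximum) relative
#' error against the four benchmark class-conditional summaries of
#' [reference_star_summaries()]. The kernel minimising that minimax
#' error is the reference kernel; at full scale (10,000 replicates)
#' this selects `"K2"`, whose four summaries all fall within 10% of the
#' benchmarks, whereas `"K1"` misses the central-initiated first-joiner
#' latency roughly eight-fold and `"K3"` overshoots the non-central-
#' initiated joiner count by about 14%.
#'
#' @param net the star network; defaults to the canonical one.
#' @param kernels candidate kernel names.
#' @param replicates replicates per candidate.
#' @param seed base seed.
#' @param config template [sim_config()] supplying `lam`, `M` and the
#'   stop window.
#' @return List with `kernel` (the selected name), `errors` (matrix of
#'   relative errors, kernels x summaries), `summaries` (matrix of
#'   measured values), `reference`.
#' @export
calibrate_kernel <- function(net = build_continuum_network(10, 1,
                                                           name = "star"),
                             kernels = c("K1", "K2", "K3"),
                             replicates = 10000, seed = 1L,
                             config = sim_config()) {
  ref <- reference_star_summaries()
  sums <- matrix(NA_real_, length(kernels), length(ref),
                 dimnames = list(kernels, names(ref)))
  for (k in kernels) {
    cfg <- config
    cfg$kernel <- k
    cfg$replicates <- as.integer(replicates)
    cfg$seed <- as.integer(seed)
    sums[k, ] <- star_summary_vector(run_batch(net, cfg, method = "loop"))
  }
  errors <- abs(sweep(sums, 2, ref) / matrix(ref, length(kernels),
                                             length(ref), byrow = TRUE))
  worst <- apply(errors, 1, max)
  list(kernel = kernels[which.min(worst)], errors = errors,
       summaries = sums, reference = ref)
}
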