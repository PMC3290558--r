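# shared fixtures: small configs and hand-built batches

quick_config <- function(...) {
  sim_config(replicates = 200, seed = 42, ...)
}

# assemble a departure_batch from hand-specified records:
# each record is list(ids = character, times = numeric)
hand_batch <- function(records, labels, central = NA_character_,
                       name = "hand") {
  n <- length(labels)
  recs <- lapply(records, function(r) {
    mimnet:::new_departure_record(r$ids, r$times, n)
  })
  batch <- structure(list(records = recs,
                          config = sim_config(replicates = length(recs)),
                          network_name = name, central = central,
                          labels = labels, n_void = 0, method = "hand"),
                     class = "departure_batch")
  batch$table <- mimnet:::batch_table(batch)
  batch
}

canonical_star <- function() build_continuum_network(10, 1, name = "star")
canonical_equal <- function() build_continuum_network(10, 1 / 9, name = "equal")

# continuum r(c,C) values of the canonical design
continuum_r <- c(star = 1, highly = 0.75, intermediately = 0.50,
                 low = 0.25, very_low = 0.125, equal = 1 / 9)

# Monte-Carlo standard error of a mean
mc_se <- function(x) stats::sd(x, na.rm = TRUE) / sqrt(sum(!is.na(x)))
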