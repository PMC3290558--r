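#' Summarize a batch of collective movements
#'
#' Reduces a `departure_batch` to the decision variables of the model,
#' split by initiator class: the mean number of departed individuals
#' (initiator included, 0 to N scale), the mean departure latency of
#' the first joiner (`dT12`, over replicates with at least one joiner),
#' and the mean duration of joining (`dT1N`, over complete movements
#' only). Classes are `all`, `C_init` / `c_init` (replicates initiated
#' by the central versus a non-central individual) and `C_first_joiner`
#' / `c_first_joiner` (split by the identity of the first joiner).
#' Absolute central-versus-non-central differences of the three
#' initiator-class means are reported alongside. Void replicates (no
#' initiation before the time cap) are excluded everywhere and counted
#' separately.
#'
#' @param object a `departure_batch`.
#' @param central label of the central individual; defaults to the one
#'   carried by the batch's network. With no central individual only
#'   the `all` class is produced.
#' @param ... unused.
#' @return An object of class `movement_summary`: list with `classes`
#'   (data frame: class, n, mean_joiners, mean_first_latency,
#'   mean_duration, n_with_joiner, n_complete), `diffs` (named numeric:
#'   absolute C-versus-c differences of the three variables), `central`,
#'   `n_void`, `N`.
#' @export
summary.departure_batch <- function(object, central = NULL, ...) {
  central <- central %||% object$central
  tab <- object$table[!object$table$void, , drop = FALSE]
  if (nrow(tab) == 0) {
    stop("batch contains no non-void replicates", call. = FALSE)
  }
  N <- length(object$labels)
  cls <- list(all = rep(TRUE, nrow(tab)))
  if (!is.na(central)) {
    if (!central %in% object$labels) {
      stop("central individual '", central, "' is not in the network",
           call. = FALSE)
    }
    cls$C_init <- tab$initiator == central
    cls$c_init <- tab$initiator != central
    cls$C_first_joiner <- !is.na(tab$first_joiner) &
      tab$first_joiner == central
    cls$c_first_joiner <- !is.na(tab$first_joiner) &
      tab$first_joiner != central
  }
  rows <- lapply(names(cls), function(nm) {
    sel <- tab[cls[[nm]], , drop = FALSE]
    data.frame(
      class = nm,
      n = nrow(sel),
      mean_joiners = if (nrow(sel)) mean(sel$n_departed) else NA_real_,
      mean_first_latency = if (any(!is.na(sel$dT12)))
        mean(sel$dT12, na.rm = TRUE) else NA_real_,
      mean_duration = if (any(!is.na(sel$dT1N)))
        mean(sel$dT1N, na.rm = TRUE) else NA_real_,
      n_with_joiner = sum(!is.na(sel$dT12)),
      n_complete = sum(sel$complete),
      stringsAsFactors = FALSE)
  })
  classes <- do.call(rbind, rows)
  diffs <- c(mean_joiners = NA_real_, mean_first_latency = NA_real_,
             mean_duration = NA_real_)
  if (!is.na(central)) {
    ci <- classes[classes$class == "C_init", ]
    cc <- classes[classes$class == "c_init", ]
    for (v in names(diffs)) diffs[[v]] <- abs(ci[[v]] - cc[[v]])
  }
  structure(list(classes = classes, diffs = diffs,
                 central = central, n_void = object$n_void, N = N,
                 network_name = object$network_name),
            class = "movement_summary")
}

#' @export
print.movement_summary <- function(x, digits = 4, ...) {
  cat("Movement summary",
      if (!is.null(x$network_name)) paste0("for '", x$network_name, "'"),
      sprintf("(N = %d, %d void replicates excluded)\n", x$N, x$n_void))
  out <- x$classes
  for (v in c("mean_joiners", "mean_first_latency", "mean_duration")) {
    out[[v]] <- round(out[[v]], digits)
  }
  print(out, row.names = FALSE)
  if (!all(is.na(x$diffs))) {
    cat("Absolute C-vs-c differences (initiator classes):\n")
    print(round(x$diffs, digits))
  }
  invisible(x)
}

#' Mean joining latency by departure rank
#'
#' For each rank `j = 2..N`, the mean latency between the departures of
#' ranks `j - 1` and `j` over the replicates that reach rank `j`
#' (initiator latencies are excluded: the initiation probability is
#' identical across networks, so rank 1 carries no network signal).
#' Ranks never reached are reported as `NA`, not zero.
#'
#' @param batch a `departure_batch`.
#' @param condition `"all"`, or `"C"` / `"c"` to restrict to replicates
#'   initiated by the central / a non-central individual.
#' @param central central label; defaults to the batch's network value.
#' @return Data frame with columns `rank` (2..N), `mean_latency` (s),
#'   `n` (replicates reaching that rank).
#' @export
rank_latency_profile <- function(batch, condition = c("all", "C", "c"),
                                 central = NULL) {
  condition <- match.arg(condition)
  central <- central %||% batch$central
  if (condition != "all" && is.na(central)) {
    stop("initiator-class profile requested but no central individual set",
         call. = FALSE)
  }
  N <- length(batch$labels)
  keep <- vapply(batch$records, function(r) {
    if (r$void) return(FALSE)
    switch(condition,
           all = TRUE,
           C = r$initiator == central,
           c = r$initiator != central)
  }, TRUE)
  recs <- batch$records[keep]
  sums <- numeric(N)
  cnts <- integer(N)
  for (r in recs) {
    if (r$n_departed < 2) next
    gaps <- diff(r$events$time)
    jj <- seq(2, r$n_departed)
    sums[jj] <- sums[jj] + gaps
    cnts[jj] <- cnts[jj] + 1L
  }
  data.frame(rank = 2:N,
             mean_latency = ifelse(cnts[-1] > 0, sums[-1] / cnts[-1],
                                   NA_real_),
             n = cnts[-1])
}

#' Long-format movement summary table
#'
#' One row per (class, variable) pair, suitable for writing as a
#' delimited file.
#'
#' @param x a `movement_summary`.
#' @param ... unused.
#' @export
as.data.frame.movement_summary <- function(x, ...) {
  vars <- c("mean_joiners", "mean_first_latency", "mean_duration")
  out <- do.call(rbind, lapply(vars, function(v) {
    data.frame(network = x$network_name %||% NA_character_,
               class = x$classes$class,
               variable = v,
               value = x$classes[[v]],
               n = x$classes$n,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
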