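#' Experiment plan
#'
#' A reproducible plan: a named set of networks, one simulation
#' configuration applied to each, and an output directory. All
#' randomness is surfaced in the plan (base seed plus a per-network
#' offset); nothing draws implicit entropy.
#'
#' @param networks named list of [social_network()] objects; defaults
#'   to the six continuum networks of [make_canonical_networks()].
#' @param config a [sim_config()].
#' @param out_dir output directory for the report files.
#' @param continuum_only drop the chain and random networks from the
#'   default set (they have no designated central individual, so the
#'   central-versus-non-central contrasts are undefined for them and
#'   they enter only the network-level tables).
#' @return An object of class `experiment_plan`.
#' @export
experiment_plan <- function(networks = NULL, config = sim_config(),
                            out_dir = "mimnet-report",
                            continuum_only = TRUE) {
  if (is.null(networks)) {
    networks <- make_canonical_networks()
    if (continuum_only) {
      networks <- networks[setdiff(names(networks), c("chain", "random"))]
    }
  }
  if (is.null(names(networks)) || any(!nzchar(names(networks)))) {
    stop("'networks' must be a named list", call. = FALSE)
  }
  structure(list(networks = networks, config = config, out_dir = out_dir),
            class = "experiment_plan")
}

#' Run the full reproduction pipeline
#'
#' For every network in the plan: the centrality table, a seeded batch
#' of simulated movements, its class-conditional summary and
#' latency-by-rank profiles. Across networks: curve fits (all three
#' families) of the three decision variables and of their absolute
#' central-versus-non-central differences against the exact centrality
#' index, and the Spearman correlation matrix of the latency-by-rank
#' profiles. Everything is written as delimited text under the plan's
#' output directory and returned invisibly. Network-level failures are
#' isolated and reported, not fatal.
#'
#' @param plan an [experiment_plan()].
#' @param progress log per-network progress via `message()`.
#' @return Invisibly, a list with `centrality` (data frame),
#'   `summaries` (long data frame), `profiles` (long data frame),
#'   `fits` (data frame of curve fits), `profile_correlations`
#'   (matrix), `batches` (list), `errors` (named character).
#' @export
reproduce <- function(plan, progress = TRUE) {
  stopifnot(inherits(plan, "experiment_plan"))
  dir.create(plan$out_dir, showWarnings = FALSE, recursive = TRUE)
  nets <- plan$networks
  errors <- character(0)
  cent_rows <- list(); sum_rows <- list(); prof_rows <- list()
  batches <- list(); index <- numeric(0)
  for (i in seq_along(nets)) {
    nm <- names(nets)[i]
    net <- nets[[i]]
    res <- tryCatch({
      if (progress) message("network '", nm, "' ...")
      cent <- eigenvector_centrality(net)
      cfg <- plan$config
      cfg$seed <- plan$config$seed + i - 1L
      batch <- run_batch(net, cfg)
      smry <- if (!is.na(net$central)) summary(batch) else
        summary(batch, central = NULL)
      profs <- list(all = rank_latency_profile(batch, "all"))
      if (!is.na(net$central)) {
        profs$C <- rank_latency_profile(batch, "C")
        profs$c <- rank_latency_profile(batch, "c")
      }
      list(cent = cent, batch = batch, smry = smry, profs = profs)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[nm] <- conditionMessage(res)
      next
    }
    cent_rows[[nm]] <- data.frame(network = nm,
                                  as.data.frame(res$cent),
                                  index_exact = res$cent$index_exact,
                                  index_table = res$cent$index_table)
    index[nm] <- if (!is.na(res$cent$index_exact)) res$cent$index_exact
                 else NA_real_
    s <- as.data.frame(res$smry)
    s$network <- nm
    sum_rows[[nm]] <- s
    prof_rows[[nm]] <- do.call(rbind, lapply(names(res$profs), function(cl) {
      data.frame(network = nm, class = cl, res$profs[[cl]])
    }))
    batches[[nm]] <- res$batch
  }
  centrality <- do.call(rbind, cent_rows)
  summaries <- do.call(rbind, sum_rows)
  profiles <- do.call(rbind, prof_rows)
  rownames(centrality) <- rownames(summaries) <- rownames(profiles) <- NULL

  fits <- reproduce_fits(summaries, index)
  prof_cor <- profile_correlation_matrix(profiles)

  wt <- function(obj, file) utils::write.table(
    obj, file.path(plan$out_dir, file), sep = "\t", quote = FALSE,
    row.names = FALSE)
  wt(centrality, "centrality.tsv")
  wt(summaries, "summaries.tsv")
  wt(profiles, "rank_profiles.tsv")
  if (!is.null(fits)) wt(fits, "curve_fits.tsv")
  if (!is.null(prof_cor)) {
    utils::write.table(data.frame(network = rownames(prof_cor),
                                  round(prof_cor, 6), check.names = FALSE),
                       file.path(plan$out_dir, "profile_correlations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  writeLines(c(
    sprintf("lam = %g", plan$config$lam),
    sprintf("M = %g", plan$config$M),
    sprintf("kernel = %s", plan$config$kernel),
    sprintf("stop_window = %g", plan$config$stop_window),
    sprintf("replicates = %d", plan$config$replicates),
    sprintf("seed = %d", plan$config$seed),
    sprintf("networks = %s", paste(names(nets), collapse = ", ")),
    if (length(errors)) paste0("failed: ", paste(names(errors), collapse = ", "))
  ), file.path(plan$out_dir, "provenance.txt"))

  out <- list(centrality = centrality, summaries = summaries,
              profiles = profiles, fits = fits,
              profile_correlations = prof_cor,
              batches = batches, errors = errors)
  invisible(out)
}

# curve fits of the class means and C-vs-c differences against the
# exact centrality index, all three families per variable
reproduce_fits <- function(summaries, index) {
  vars <- c("mean_joiners", "mean_first_latency", "mean_duration")
  nets <- names(index)[!is.na(index)]
  if (length(nets) < 3) return(NULL)
  rows <- list()
  for (v in vars) {
    for (what in c("all", "diff")) {
      y <- vapply(nets, function(nm) {
        s <- summaries[summaries$network == nm & summaries$variable == v, ]
        if (what == "all") {
          s$value[s$class == "all"]
        } else {
          ci <- s$value[s$class == "C_init"]
          cc <- s$value[s$class == "c_init"]
          if (length(ci) && length(cc)) abs(ci - cc) else NA_real_
        }
      }, 0)
      x <- index[nets]
      # centrality indices below numerical tolerance are analytic
      # zeros (the equal network); the logarithmic family must see
      # them as such, not as tiny positive numbers
      x[abs(x) < 1e-9] <- 0
      ok <- !is.na(y)
      if (sum(ok) < 3) next
      for (fam in c("linear", "exponential", "logarithmic")) {
        fit <- tryCatch(curve_estimation(x[ok], y[ok], fam),
                        error = function(e) NULL)
        if (is.null(fit)) next
        rows[[length(rows) + 1]] <- data.frame(
          variable = v, contrast = what, family = fam,
          a = fit$a, b = fit$b, r_squared = fit$r_squared,
          f_stat = fit$f_stat, df1 = fit$df[1], df2 = fit$df[2],
          p_value = fit$p_value, n = fit$n)
      }
    }
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

# Spearman correlations between the all-replicate latency-by-rank
# profiles of every pair of networks
profile_correlation_matrix <- function(profiles) {
  all_prof <- profiles[profiles$class == "all", ]
  nets <- unique(all_prof$network)
  if (length(nets) < 2) return(NULL)
  m <- matrix(NA_real_, length(nets), length(nets),
              dimnames = list(nets, nets))
  diag(m) <- 1
  for (i in seq_along(nets)) for (k in seq_along(nets)) {
    if (k <= i) next
    a <- all_prof$mean_latency[all_prof$network == nets[i]]
    b <- all_prof$mean_latency[all_prof$network == nets[k]]
    ok <- !is.na(a) & !is.na(b)
    if (sum(ok) >= 3) {
      r <- tryCatch(spearman_rho(a[ok], b[ok])$rho,
                    error = function(e) NA_real_)
      m[i, k] <- m[k, i] <- r
    }
  }
  m
}
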