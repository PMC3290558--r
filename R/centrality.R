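#' Eigenvector centrality on received affiliation
#'
#' Scores each individual by the dominant eigenvector of the
#' received-affiliation matrix (entry `(k, i)` equal to `r(i,k)`):
#' an individual is central in proportion to the affiliation it
#' receives, weighted by the centrality of those giving it. Because the
#' given-affiliation matrix is row-stochastic for the constructed
#' families, the dominant eigenvalue is 1. For the continuum family the
#' scores have a closed form: the central-to-non-central score ratio is
#' `(n - 1) * r_cC`, so the star network scores 0.95 (C) versus 0.11
#' (c) and the equal network scores `1/sqrt(n)` for everyone.
#'
#' Computed by power iteration to relative tolerance `tol`, sign-fixed
#' nonnegative and normalized to unit Euclidean norm.
#'
#' @param net a [social_network()]; must be connected through nonzero
#'   weights.
#' @param tol relative convergence tolerance of the power iteration.
#' @param max_iter iteration cap.
#' @return An object of class `centrality_result`: list with `scores`
#'   (named numeric, unit Euclidean norm), `eigenvalue`, `central`
#'   (argmax label, `NA` when not unique), `unique_central` (logical),
#'   `index_exact` and `index_table` (see [centrality_index()]); the
#'   index entries are `NA` when no central individual is identifiable
#'   and none is designated in `net`.
#' @export
#' @examples
#' eigenvector_centrality(build_continuum_network(10, 1))
eigenvector_centrality <- function(net, tol = 1e-12, max_iter = 100000L) {
  stopifnot(inherits(net, "social_network"))
  n <- n_individuals(net)
  A <- t(net$weights)              # received: A[k, i] = r(i, k)
  if (!is_connected_weights(net$weights)) {
    stop("network is not connected through nonzero weights; ",
         "eigenvector centrality is undefined", call. = FALSE)
  }
  x <- rep(1 / sqrt(n), n)
  lambda <- NA_real_
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    y <- drop(A %*% x)
    ny <- sqrt(sum(y^2))
    if (ny == 0) stop("power iteration collapsed to zero", call. = FALSE)
    y <- y / ny
    # bipartite-like structures can alternate in sign pattern; damp
    # only if oscillation is detected
    if (max(abs(y - x)) < tol * max(abs(x))) {
      lambda <- ny
      x <- y
      converged <- TRUE
      break
    }
    if (max(abs(y + x)) < tol * max(abs(x))) {
      # period-2 oscillation: average the two phases
      x <- (abs(y) + abs(x))
      x <- x / sqrt(sum(x^2))
      next
    }
    x <- y
  }
  if (!converged) {
    # fall back to a damped iteration which always converges for
    # primitive-after-shift nonnegative matrices
    x <- rep(1 / sqrt(n), n)
    shift <- max(rowSums(A))
    for (it in seq_len(max_iter)) {
      y <- drop(A %*% x) + shift * x
      y <- y / sqrt(sum(y^2))
      if (max(abs(y - x)) < tol * max(abs(x))) {
        converged <- TRUE
        x <- y
        break
      }
      x <- y
    }
    lambda <- drop(crossprod(x, A %*% x))
    if (!converged) {
      stop("power iteration did not converge in ", max_iter, " steps",
           call. = FALSE)
    }
  }
  scores <- abs(x)
  scores <- scores / sqrt(sum(scores^2))
  names(scores) <- net$labels
  spread <- max(scores) - min(scores)
  unique_central <- spread >= 1e-9 &&
    sum(max(scores) - scores < 1e-9) == 1L
  central <- if (unique_central) net$labels[which.max(scores)] else NA_character_
  idx_central <- if (!is.na(central)) central else net$central
  res <- structure(
    list(scores = scores, eigenvalue = lambda, central = central,
         unique_central = unique_central,
         index_exact = NA_real_, index_table = NA_real_),
    class = "centrality_result")
  if (!is.na(idx_central)) {
    ci <- centrality_index(scores, idx_central)
    res$index_exact <- ci[["index_exact"]]
    res$index_table <- ci[["index_table"]]
  }
  res
}

#' Group centrality (centralization) index
#'
#' The difference between the eigenvector centrality of the central
#' individual `C` and the mean eigenvector centrality of all other
#' individuals: 0 for a fully decentralized group, approaching 1 for a
#' group whose members affiliate only with `C`. Two variants are
#' returned: `index_exact` on the unrounded scores (used as the
#' regression abscissa) and `index_table` on reported scores (the
#' convention of the canonical network table, under which the star
#' network's index is 0.95 - 0.10 = 0.85). Reported scores are the
#' tabulated three-decimal values rounded to two decimals, ties to
#' even: the successive rounding reproduces every printed score of the
#' canonical table, including the star's non-central 0.10 (whose exact
#' value 0.10541 would round directly to 0.11).
#'
#' @param scores named numeric vector of eigenvector centralities.
#' @param central label of the central individual.
#' @return Named numeric vector `c(index_exact, index_table)`.
#' @export
centrality_index <- function(scores, central) {
  if (inherits(scores, "centrality_result")) scores <- scores$scores
  if (length(scores) < 2) {
    stop("centrality index needs at least 2 individuals", call. = FALSE)
  }
  if (!central %in% names(scores)) {
    stop("central individual '", central, "' not among score labels",
         call. = FALSE)
  }
  others <- scores[setdiff(names(scores), central)]
  reported <- round(round(scores, 3), 2)
  c(index_exact = unname(scores[central] - mean(others)),
    index_table = unname(reported[central] -
                           mean(round(round(others, 3), 2))))
}

#' Identify the central individual
#'
#' Returns the label with the maximum eigenvector centrality, or flags
#' the absence of a unique maximum (as in the equal network, where all
#' scores coincide) instead of picking arbitrarily.
#'
#' @param net a [social_network()].
#' @return A character label, or `NA` with attribute
#'   `reason = "no unique central"` when the maximum is tied.
#' @export
identify_central <- function(net) {
  res <- eigenvector_centrality(net)
  if (!res$unique_central) {
    return(structure(NA_character_, reason = "no unique central"))
  }
  res$central
}

#' @export
print.centrality_result <- function(x, digits = 4, ...) {
  cat("Eigenvector centrality (received affiliation), eigenvalue",
      format(x$eigenvalue, digits = 6), "\n")
  print(round(x$scores, digits))
  if (x$unique_central) {
    cat("Central individual:", x$central, "\n")
  } else {
    cat("No unique central individual (scores tied at the maximum)\n")
  }
  if (!is.na(x$index_exact)) {
    cat(sprintf("Centrality index: %.4f exact, %.2f on reported scores\n",
                x$index_exact, x$index_table))
  }
  invisible(x)
}

#' @export
as.data.frame.centrality_result <- function(x, ...) {
  data.frame(label = names(x$scores), score = unname(x$scores),
             row.names = NULL)
}

# reachability of every node from every node through nonzero weights,
# treating an edge in either direction as a connection
is_connected_weights <- function(w) {
  n <- nrow(w)
  if (n == 1) return(TRUE)
  adj <- (w != 0) | (t(w) != 0)
  seen <- logical(n)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue)) {
    v <- queue[1L]
    queue <- queue[-1L]
    nb <- which(adj[v, ] & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  all(seen)
}
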