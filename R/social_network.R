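#' Weighted directed social networks
#'
#' A `social_network` stores the affiliation structure of a group as an
#' N x N matrix of given affiliation `r(i,k)`: row `i` is the giver,
#' column `k` the receiver, and each entry is the (unitless) fraction of
#' individual `i`'s fixed interaction budget directed at `k`. For the
#' constructed network families every row sums to 1 -- each individual
#' has the same total quantity of social interaction to distribute --
#' which makes networks of different shape directly comparable.
#'
#' @param weights numeric N x N matrix of nonnegative affiliation
#'   weights with zero diagonal; dimnames, if present, are used as
#'   individual labels.
#' @param labels optional character vector of individual identifiers;
#'   defaults to the matrix dimnames or `ind1..indN`.
#' @param central optional label of the designated central individual
#'   `C`, or `NA` when the network has no focal individual.
#' @param name optional display name for the network.
#' @param validate logical; check invariants (zero diagonal, weights in
#'   \[0, 1\], row sums). Row sums different from 1 raise a warning, not
#'   an error, so empirically measured matrices can be carried.
#'
#' @return An object of class `social_network`: a list with elements
#'   `weights`, `labels`, `central`, `name`.
#' @seealso [build_continuum_network()], [build_chain_network()],
#'   [build_random_network()], [read_network()]
#' @export
#' @examples
#' w <- matrix(c(0, 1, 1, 0.5, 0, 0.5, 0.5, 0.5, 0), 3, 3, byrow = TRUE)
#' social_network(w, labels = c("a", "b", "c"))
social_network <- function(weights, labels = NULL, central = NA_character_,
                           name = NULL, validate = TRUE) {
  weights <- as.matrix(weights)
  if (nrow(weights) != ncol(weights)) {
    stop("'weights' must be a square matrix, got ", nrow(weights), " x ",
         ncol(weights), call. = FALSE)
  }
  n <- nrow(weights)
  if (is.null(labels)) {
    labels <- rownames(weights)
    if (is.null(labels)) labels <- paste0("ind", seq_len(n))
  }
  labels <- as.character(labels)
  if (length(labels) != n || anyDuplicated(labels)) {
    stop("'labels' must be ", n, " unique identifiers", call. = FALSE)
  }
  storage.mode(weights) <- "double"
  dimnames(weights) <- list(labels, labels)
  if (!is.na(central) && !central %in% labels) {
    stop("central individual '", central, "' is not a network label",
         call. = FALSE)
  }
  if (validate) {
    if (anyNA(weights)) stop("weights contain missing values", call. = FALSE)
    if (any(weights < 0)) {
      bad <- which(weights < 0, arr.ind = TRUE)[1L, ]
      stop("negative weight at row '", labels[bad[1L]], "'", call. = FALSE)
    }
    if (any(weights > 1)) {
      warning("weights above 1 found; constructed networks use fractions of a unit budget")
    }
    if (any(diag(weights) != 0)) {
      stop("diagonal must be zero (no self-affiliation)", call. = FALSE)
    }
    rs <- rowSums(weights)
    if (n > 1 && any(abs(rs - 1) > 1e-8)) {
      warning("row sums differ from 1 for: ",
              paste(labels[abs(rs - 1) > 1e-8], collapse = ", "),
              " (unit-budget convention not met)")
    }
  }
  structure(list(weights = weights, labels = labels,
                 central = central, name = name),
            class = "social_network")
}

#' @export
print.social_network <- function(x, digits = 4, ...) {
  n <- length(x$labels)
  cat("Social network", if (!is.null(x$name)) paste0("'", x$name, "'"),
      "with", n, "individuals\n")
  if (!is.na(x$central)) cat("Central individual:", x$central, "\n")
  cat("Given-affiliation matrix r(i,k) (rows give, columns receive):\n")
  print(round(x$weights, digits))
  invisible(x)
}

#' @export
plot.social_network <- function(x, vertex_scale = 40, edge_scale = 4, ...) {
  g <- igraph::graph_from_adjacency_matrix(x$weights, mode = "directed",
                                           weighted = TRUE, diag = FALSE)
  cent <- tryCatch(eigenvector_centrality(x)$scores,
                   error = function(e) rep(1 / sqrt(length(x$labels)),
                                           length(x$labels)))
  igraph::plot.igraph(
    g,
    vertex.size = vertex_scale * cent / max(cent) * 0.6 + 8,
    edge.width = edge_scale * igraph::E(g)$weight,
    edge.arrow.size = 0.3,
    main = x$name, ...)
  invisible(x)
}

n_individuals <- function(net) length(net$labels)

#' Continuum of centralized social networks
#'
#' Builds the parameterized star-to-equal family of networks: one
#' central individual `C` and `n - 1` non-central individuals `c`. Each
#' non-central individual gives `r_cC` of its unit budget to `C` and
#' splits the remainder equally among the other non-central individuals,
#' `r(c,c') = (1 - r_cC)/(n - 2)`. The central individual always splits
#' its budget equally, `r(C,c) = 1/(n - 1)`. `r_cC = 1` gives the star
#' network (extreme centralization); `r_cC = 1/(n - 1)` gives the equal
#' network (extreme decentralization), where every dyad carries the same
#' weight.
#'
#' @param n group size (at least 3).
#' @param r_cC affiliation of each non-central individual toward the
#'   central one, in `[1/(n - 1), 1]`.
#' @param name optional display name.
#' @return A [social_network()] with labels `C, c1, ..., c<n-1>` and
#'   `central = "C"`.
#' @export
#' @examples
#' build_continuum_network(10, 1)      # star
#' build_continuum_network(10, 1 / 9)  # equal
build_continuum_network <- function(n, r_cC, name = NULL) {
  if (!is.numeric(n) || length(n) != 1 || n < 3 || n != round(n)) {
    stop("'n' must be a single integer >= 3", call. = FALSE)
  }
  n <- as.integer(n)
  lo <- 1 / (n - 1)
  if (!is.numeric(r_cC) || length(r_cC) != 1 ||
      r_cC < lo - 1e-12 || r_cC > 1 + 1e-12) {
    stop("'r_cC' must lie in [1/(n-1), 1] = [", signif(lo, 6), ", 1]",
         call. = FALSE)
  }
  labels <- c("C", paste0("c", seq_len(n - 1)))
  w <- matrix(0, n, n, dimnames = list(labels, labels))
  w[1, -1] <- 1 / (n - 1)                   # r(C,c)
  r_cc <- (1 - r_cC) / (n - 2)
  w[-1, -1] <- r_cc                         # r(c,c')
  w[-1, 1] <- r_cC                          # r(c,C)
  diag(w) <- 0
  social_network(w, labels, central = "C",
                 name = name %||% sprintf("continuum(r_cC=%g)", r_cC))
}

#' Chain (path) social network
#'
#' Individuals are arranged on a path; each endpoint gives its full unit
#' budget to its single neighbour and each interior individual gives 1/2
#' to each of its two neighbours. This is the only weighting of a path
#' topology compatible with the fixed unit interaction budget.
#'
#' @param n group size (at least 2).
#' @return A [social_network()]; no central individual is designated.
#' @export
build_chain_network <- function(n) {
  if (!is.numeric(n) || length(n) != 1 || n < 2 || n != round(n)) {
    stop("'n' must be a single integer >= 2", call. = FALSE)
  }
  n <- as.integer(n)
  labels <- paste0("p", seq_len(n))
  w <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n)) {
    nb <- c(i - 1, i + 1)
    nb <- nb[nb >= 1 & nb <= n]
    w[i, nb] <- 1 / length(nb)
  }
  social_network(w, labels, name = "chain")
}

#' Random (Erdős–Rényi) social network
#'
#' Samples an undirected Erdős–Rényi topology G(n, p), resampling until
#' the graph is connected (the departure model is undefined on
#' disconnected components), then splits each individual's unit budget
#' equally among its graph neighbours, so `r(i,k) = 1/degree(i)` for
#' each neighbour `k`.
#'
#' @param n group size (at least 2).
#' @param p edge probability in (0, 1]. The default 0.5 gives an
#'   expected density halfway to the complete graph while keeping
#'   connectivity attainable at small n.
#' @param seed integer seed; the topology is reproducible from it.
#' @param max_tries resampling attempts before giving up.
#' @return A [social_network()]; no central individual is designated.
#' @export
build_random_network <- function(n, p = 0.5, seed = 1L, max_tries = 10000L) {
  if (!is.numeric(n) || length(n) != 1 || n < 2 || n != round(n)) {
    stop("'n' must be a single integer >= 2", call. = FALSE)
  }
  if (!is.numeric(p) || length(p) != 1 || p <= 0 || p > 1) {
    stop("'p' must be in (0, 1]: a zero edge probability cannot produce a connected graph",
         call. = FALSE)
  }
  n <- as.integer(n)
  adj <- with_seed(as.integer(seed), {
    for (k in seq_len(max_tries)) {
      g <- igraph::sample_gnp(n, p)
      if (igraph::is_connected(g)) break
      g <- NULL
    }
    if (is.null(g)) {
      stop("no connected graph found in ", max_tries,
           " draws at p = ", p, call. = FALSE)
    }
    igraph::as_adjacency_matrix(g, sparse = FALSE)
  })
  labels <- paste0("r", seq_len(n))
  deg <- rowSums(adj)
  w <- adj / deg
  dimnames(w) <- list(labels, labels)
  social_network(w, labels, name = sprintf("random(p=%g, seed=%d)", p, seed))
}

#' Canonical network set
#'
#' The eight networks of the study design at group size `n = 10`: the
#' six continuum networks (star, highly / intermediately / low / very
#' low centralized, equal) with `r(c,C)` equal to 1, 0.75, 0.50, 0.25,
#' 0.125 and 1/9 respectively, plus a chain network and a seeded random
#' network.
#'
#' @param n group size.
#' @param random_seed seed for the random network topology.
#' @return Named list of [social_network()] objects.
#' @export
make_canonical_networks <- function(n = 10, random_seed = 1L) {
  r_values <- c(star = 1, highly = 0.75, intermediately = 0.50,
                low = 0.25, very_low = 0.125, equal = 1 / (n - 1))
  nets <- lapply(seq_along(r_values), function(i) {
    build_continuum_network(n, r_values[[i]], name = names(r_values)[i])
  })
  names(nets) <- names(r_values)
  nets$chain <- build_chain_network(n)
  nets$random <- build_random_network(n, p = 0.5, seed = random_seed)
  nets
}

#' Read / write social networks as plain text
#'
#' Two formats are supported. An adjacency table is a delimited text
#' file whose first row and first column hold the individual labels and
#' whose cell `(i, k)` is the given affiliation `r(i,k)` (row gives,
#' column receives). An edge list has three columns
#' `giver receiver weight`; dyads not listed are read as 0.
#' Validation (zero diagonal, row sums) runs on read with warnings
#' rather than failures so that unnormalized empirical matrices load.
#'
#' @param path file path.
#' @param format `"adjacency"` or `"edgelist"`; `read_network` guesses
#'   from the header when `"auto"`.
#' @param central optional central-individual label to attach on read.
#' @param net a [social_network()].
#' @return `read_network` returns a [social_network()]; `write_network`
#'   returns `path` invisibly.
#' @export
read_network <- function(path, format = c("auto", "adjacency", "edgelist"),
                         central = NA_character_) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- strsplit(readLines(path, n = 1), "[\t ,]+")[[1]]
  if (format == "auto") {
    format <- if (identical(tolower(header[1:3]),
                            c("giver", "receiver", "weight")))
      "edgelist" else "adjacency"
  }
  if (format == "adjacency") {
    tab <- utils::read.table(path, header = TRUE, check.names = FALSE,
                             row.names = 1)
    m <- as.matrix(tab)
    if (nrow(m) != ncol(m)) {
      stop("adjacency table is not square: ", nrow(m), " rows, ",
           ncol(m), " columns", call. = FALSE)
    }
    if (!identical(rownames(m), colnames(m))) {
      stop("row and column labels disagree; first mismatch at row '",
           rownames(m)[which(rownames(m) != colnames(m))[1L]], "'",
           call. = FALSE)
    }
    if (any(m < 0)) {
      bad <- rownames(m)[which(m < 0, arr.ind = TRUE)[1L, 1L]]
      stop("negative weight in row '", bad, "'", call. = FALSE)
    }
    social_network(m, central = central)
  } else {
    el <- utils::read.table(path, header = TRUE,
                            col.names = c("giver", "receiver", "weight"),
                            colClasses = c("character", "character", "numeric"))
    labels <- unique(c(el$giver, el$receiver))
    w <- matrix(0, length(labels), length(labels),
                dimnames = list(labels, labels))
    for (r in seq_len(nrow(el))) {
      if (el$weight[r] < 0) {
        stop("negative weight on edge '", el$giver[r], "' -> '",
             el$receiver[r], "'", call. = FALSE)
      }
      w[el$giver[r], el$receiver[r]] <- el$weight[r]
    }
    social_network(w, central = central)
  }
}

#' @rdname read_network
#' @export
write_network <- function(net, path, format = c("adjacency", "edgelist")) {
  format <- match.arg(format)
  stopifnot(inherits(net, "social_network"))
  if (format == "adjacency") {
    tab <- data.frame(label = net$labels,
                      format(net$weights, digits = 17, trim = TRUE,
                             scientific = FALSE),
                      check.names = FALSE)
    names(tab)[1] <- ""
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    idx <- which(net$weights != 0, arr.ind = TRUE)
    el <- data.frame(giver = net$labels[idx[, 1]],
                     receiver = net$labels[idx[, 2]],
                     weight = format(net$weights[idx], digits = 17,
                                     scientific = FALSE))
    el <- el[order(el$giver, el$receiver), ]
    utils::write.table(el, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# evaluate expr with a temporary RNG state seeded at `seed`,
# restoring the caller's stream afterwards
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
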