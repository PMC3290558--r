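test_that("continuum networks follow the unit-budget construction rules", {
  for (r in continuum_r) {
    net <- build_continuum_network(10, r)
    w <- net$weights
    expect_equal(unname(rowSums(w)), rep(1, 10), tolerance = 1e-12)
    expect_true(all(diag(w) == 0))
    expect_true(all(w >= 0 & w <= 1))
    expect_equal(unname(w["c1", "C"]), r)
    expect_equal(unname(w["C", "c1"]), 1 / 9)
    expect_equal(unname(w["c1", "c2"]), (1 - r) / 8)
    expect_identical(net$central, "C")
  }
  # printed examples of the canonical design
  expect_equal(unname(build_continuum_network(10, 1)$weights["c1", "c2"]), 0)
  expect_equal(unname(build_continuum_network(10, 0.5)$weights["c1", "c2"]),
               0.0625)
})

test_that("the continuum gap r(c,C) - r(c,c) decreases strictly along the design", {
  gaps <- vapply(continuum_r, function(r) {
    w <- build_continuum_network(10, r)$weights
    w["c1", "C"] - w["c1", "c2"]
  }, 0)
  expect_true(all(diff(gaps) < 0))
})

test_that("the equal network is the symmetric fixed point of the family", {
  w <- build_continuum_network(10, 1 / 9)$weights
  expect_equal(w, t(w), tolerance = 1e-15)
  expect_equal(unname(w[w != 0]), rep(1 / 9, 90), tolerance = 1e-15)
})

test_that("continuum constructor rejects invalid sizes and parameters", {
  expect_error(build_continuum_network(2, 1), "integer >= 3")
  expect_error(build_continuum_network(10, 0.05), "must lie in")
  expect_error(build_continuum_network(10, 1.2), "must lie in")
})

test_that("chain network follows the unit-budget path rule", {
  w3 <- build_chain_network(3)$weights
  expect_equal(unname(w3[1, ]), c(0, 1, 0))
  expect_equal(unname(w3[2, ]), c(0.5, 0, 0.5))
  expect_equal(unname(w3[3, ]), c(0, 1, 0))
  w10 <- build_chain_network(10)$weights
  expect_equal(unname(rowSums(w10)), rep(1, 10), tolerance = 1e-12)
  # a path on n nodes has n - 1 undirected edges, hence 2(n - 1)
  # directed nonzero weights
  expect_identical(sum(w10 != 0), 18L)
  expect_error(build_chain_network(1), "integer >= 2")
})

test_that("random network is connected, row-normalized and seed-reproducible", {
  bfs_connected <- function(w) {
    # independent breadth-first-search oracle on the symmetrized support
    adj <- (w != 0) | (t(w) != 0)
    seen <- c(TRUE, rep(FALSE, nrow(w) - 1))
    repeat {
      new <- colSums(adj[seen, , drop = FALSE]) > 0 & !seen
      if (!any(new)) break
      seen <- seen | new
    }
    all(seen)
  }
  a <- build_random_network(10, p = 0.4, seed = 7)
  b <- build_random_network(10, p = 0.4, seed = 7)
  expect_identical(a$weights, b$weights)
  expect_true(bfs_connected(a$weights))
  expect_equal(unname(rowSums(a$weights)), rep(1, 10), tolerance = 1e-12)
  # complete-graph limit coincides with the equal network
  full <- build_random_network(10, p = 1, seed = 1)
  expect_equal(unname(full$weights),
               unname(canonical_equal()$weights), tolerance = 1e-15)
  expect_error(build_random_network(10, p = 0), "connected")
})

test_that("random network generation does not disturb the caller's RNG stream", {
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(build_random_network(10, p = 0.5, seed = 99))
  expect_identical(runif(1), before)
})

test_that("adjacency and edge-list files round-trip losslessly", {
  star <- canonical_star()
  for (fmt in c("adjacency", "edgelist")) {
    path <- withr::local_tempfile(fileext = ".tsv")
    write_network(star, path, format = fmt)
    back <- read_network(path, central = "C")
    expect_equal(back$weights[star$labels, star$labels], star$weights,
                 tolerance = 1e-12)
    expect_identical(back$central, "C")
  }
})

test_that("edge lists treat missing dyads as zero", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("giver\treceiver\tweight", "a\tb\t1", "b\ta\t0.5",
               "b\tc\t0.5", "c\tb\t1"), path)
  net <- read_network(path)
  expect_equal(unname(net$weights["a", "c"]), 0)
  expect_equal(unname(net$weights["b", "a"]), 0.5)
})

test_that("malformed network files fail with a named offender", {
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("\ta\tb", "a\t0\t-0.5", "b\t1\t0"), bad)
  expect_error(read_network(bad), "negative weight.*'a'")
  notsquare <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("\ta\tb", "a\t0\t1"), notsquare)
  expect_error(read_network(notsquare), "not square")
})

test_that("unnormalized matrices load with a warning, not a failure", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("\ta\tb\tc", "a\t0\t0.9\t0.6", "b\t1\t0\t0", "c\t1\t0\t0"),
             path)
  expect_warning(net <- read_network(path), "row sums")
  expect_equal(unname(net$weights["a", "b"]), 0.9)
})
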