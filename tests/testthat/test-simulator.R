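test_that("collective initiation probability is n times the intrinsic rate", {
  cfg <- sim_config()
  expect_equal(initiation_probability(cfg, 10), 7e-4)
  expect_equal(initiation_probability(cfg, 1), 7e-5)
})

test_that("joining probability follows the kernel definitions", {
  star <- canonical_star()
  lam <- 7e-5; M <- 2e-3
  # no movers: intrinsic rate only, for every kernel
  for (k in c("K1", "K2", "K3")) {
    expect_equal(joining_probability(star, character(0), "c1",
                                     sim_config(kernel = k)), lam)
  }
  # C moving, c resting: summed received affiliation is r(c,C) = 1
  expect_equal(joining_probability(star, "C", "c1", sim_config(kernel = "K1")),
               lam + M)
  expect_equal(joining_probability(star, "C", "c1", sim_config(kernel = "K2")),
               lam + M * 9)
  expect_equal(joining_probability(star, "C", "c1", sim_config(kernel = "K3")),
               lam + M * 1 * 9)
  # non-central movers contribute nothing in the star (r(c,c') = 0)
  expect_equal(joining_probability(star, c("c2", "c3"), "c1",
                                   sim_config(kernel = "K1")), lam)
  expect_error(joining_probability(star, c("C", "c1"), "c1", sim_config()),
               "already moving")
})

test_that("K1 joining probability is monotone in the moving set and never below lam", {
  eq <- canonical_equal()
  cfg1 <- sim_config(kernel = "K1")
  movers <- paste0("c", 1:9)
  psis <- vapply(seq_along(movers), function(j) {
    joining_probability(eq, movers[seq_len(j)], "C", cfg1)
  }, 0)
  expect_true(all(diff(psis) > 0))
  for (k in c("K1", "K2", "K3")) {
    cfg <- sim_config(kernel = k)
    expect_true(all(vapply(seq_along(movers), function(j) {
      joining_probability(eq, movers[seq_len(j)], "C", cfg)
    }, 0) >= cfg$lam))
  }
})

test_that("replicates are deterministic under a fixed seed and records are well-formed", {
  star <- canonical_star()
  cfg <- quick_config()
  b1 <- run_batch(star, cfg)
  b2 <- run_batch(star, cfg)
  expect_identical(b1$table, b2$table)
  for (r in b1$records[1:50]) {
    expect_identical(r$initiator, r$events$id[1])
    expect_identical(r$n_departed, nrow(r$events))
    expect_true(all(diff(r$events$time) >= 0))
    expect_identical(r$complete, r$n_departed == 10L)
    # stop rule: no inter-departure gap beyond the window
    if (r$n_departed > 1) {
      expect_true(all(diff(r$events$time) <= cfg$stop_window))
    }
  }
})

test_that("a single individual departs alone at its intrinsic rate", {
  solo <- suppressWarnings(social_network(matrix(0, 1, 1), labels = "only"))
  set.seed(5)
  rec <- run_replicate(solo, sim_config())
  expect_identical(rec$n_departed, 1L)
  expect_true(rec$complete)
  expect_identical(rec$initiator, "only")
})

test_that("replicates that never initiate are flagged void and excluded", {
  star <- canonical_star()
  cfg <- sim_config(lam = 1e-6, max_time = 500, replicates = 50, seed = 1)
  b <- run_batch(star, cfg)
  expect_gt(b$n_void, 0)
  expect_identical(sum(b$table$void), b$n_void)
  s <- summary(b)
  expect_identical(sum(s$classes$n[s$classes$class %in%
                                     c("C_init", "c_init")]),
                   nrow(b$table) - b$n_void)
})

test_that("initiator identity is uniform over individuals", {
  # all intrinsic rates are equal, so the first mover is uniform;
  # chi-square check on a modest batch
  eq <- canonical_equal()
  b <- run_batch(eq, sim_config(replicates = 400, seed = 9,
                                stop_window = 10), method = "event")
  counts <- table(factor(b$table$initiator, levels = eq$labels))
  p <- suppressWarnings(stats::chisq.test(counts)$p.value)
  expect_gt(p, 0.001)
})

test_that("per-second loop and event-driven oracle agree on batch means", {
  star <- canonical_star()
  cfg <- sim_config(replicates = 1200, seed = 31)
  bl <- run_batch(star, cfg, method = "loop")
  be <- run_batch(star, cfg, method = "event")
  for (v in c("n_departed", "dT12", "t_init")) {
    xl <- bl$table[[v]]; xe <- be$table[[v]]
    se <- sqrt(mc_se(xl)^2 + mc_se(xe)^2)
    expect_lt(abs(mean(xl, na.rm = TRUE) - mean(xe, na.rm = TRUE)), 3 * se)
  }
})

test_that("with no mimetism the joining probability reduces to the geometric bound", {
  # M = 0, star: after initiation each of the 9 resting agents departs
  # at rate lam, so P(>= 1 joiner within the 300-s window) is
  # 1 - (1 - lam)^(9 * 300) ~ 0.172
  star <- canonical_star()
  cfg <- sim_config(M = 0, replicates = 1500, seed = 17)
  b <- run_batch(star, cfg, method = "event")
  p_hat <- mean(b$table$n_departed >= 2)
  p_true <- 1 - (1 - cfg$lam)^(9 * 300)
  expect_equal(p_true, 0.172, tolerance = 0.005)
  se <- sqrt(p_true * (1 - p_true) / nrow(b$table))
  expect_lt(abs(p_hat - p_true), 3 * se)
})

test_that("equal-network outcomes are exchangeable across individuals", {
  # relabeling cannot matter: joiner counts conditional on the
  # initiator being any fixed individual share one distribution
  eq <- canonical_equal()
  b <- run_batch(eq, sim_config(replicates = 600, seed = 23),
                 method = "event")
  tab <- b$table
  a <- tab$n_departed[tab$initiator == "C"]
  c_ <- tab$n_departed[tab$initiator != "C"]
  se <- sqrt(mc_se(a)^2 + mc_se(c_)^2)
  expect_lt(abs(mean(a) - mean(c_)), 3 * se)
})

test_that("config validation rejects out-of-range parameters", {
  expect_error(sim_config(lam = 0), "probability")
  expect_error(sim_config(lam = 1.5), "probability")
  expect_error(sim_config(M = -1), "nonnegative")
  expect_error(sim_config(stop_window = 0), "positive")
  expect_error(sim_config(replicates = 0), "at least 1")
  expect_error(sim_config(kernel = "K9"))
})

test_that("key-value config files round-trip into sim_config", {
  path <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("lam = 0.0001", "M = 0.003", "kernel = K1",
               "replicates = 50", "seed = 4", "network = star",
               "# comment"), path)
  got <- read_config(path)
  expect_equal(got$config$lam, 1e-4)
  expect_equal(got$config$M, 3e-3)
  expect_identical(got$config$kernel, "K1")
  expect_identical(got$network, "star")
  bad <- withr::local_tempfile(fileext = ".cfg")
  writeLines("lambda = 1", bad)
  expect_error(read_config(bad), "unknown config key")
})
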