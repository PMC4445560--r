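test_that("prior draws respect bounds, seeds and uniformity", {
  d <- draw_prior_sample(1000, seed = 3)
  expect_equal(names(d), c("N_D", "P", "M_E", "M_L"))
  expect_true(all(d$P >= 0 & d$P <= 1))
  expect_true(all(d$N_D >= 1 & d$N_D <= 1000))
  expect_true(all(d$M_E >= 0 & d$M_E <= 0.01))
  expect_identical(d, draw_prior_sample(1000, seed = 3))
  big <- draw_prior_sample(10000, seed = 4)
  ks <- suppressWarnings(ks.test(big$N_D, "punif", 1, 1000))
  expect_gt(ks$p.value, 0.01)
})

test_that("simulation batches have the contracted shape and reproducibility", {
  sc <- sampling_scheme(c("NE", "EU", "NE", "EU"), c(1500, 1000, 0, 0),
                        n = c(3, 4, 3, 4),
                        group = c("ancient_NE", "ancient_EU", "modern_NE",
                                  "modern_EU"))
  t1 <- run_simulation_batch(10, sc, mutation_model(seq_length = 60), seed = 5)
  expect_equal(dim(t1), c(10, 4 + 1 + 32))
  expect_false(anyNA(t1))
  t2 <- run_simulation_batch(10, sc, mutation_model(seq_length = 60), seed = 5)
  expect_identical(t1, t2)
})

test_that("rejection keeps the exact count with hand-checkable distances", {
  # toy table: 10 rows, 32 stat columns but only two informative ones
  set.seed(1)
  tab <- draw_prior_sample(10, seed = 2)
  tab$sim_seed <- 1:10
  stats <- matrix(0, 10, 32, dimnames = list(NULL, stat_vector_names()))
  stats[, 1] <- c(5, 1, 9, 4, 2, 8, 7, 3, 6, 0)
  stats[, 2] <- c(0, 2, 1, 9, 4, 6, 3, 8, 5, 7)
  tab <- cbind(tab, as.data.frame(stats))
  class(tab) <- c("simulation_table", "data.frame")
  obs <- setNames(numeric(32), stat_vector_names())
  obs[1] <- 5; obs[2] <- 4
  # hand-computed standardized distances identify rows 5 and 1 as closest
  s1 <- sd(stats[, 1]); s2 <- sd(stats[, 2])
  dist <- sqrt(((stats[, 1] - 5) / s1)^2 + ((stats[, 2] - 4) / s2)^2)
  want <- order(dist)[1:2]
  post <- suppressMessages(rejection(obs, tab, tolerance = 0.2))
  expect_equal(nrow(post$accepted), 2)
  expect_equal(as.integer(rownames(post$accepted)), want)

  # tolerance 1 returns everything (posterior = prior)
  all_in <- suppressMessages(rejection(obs, tab, tolerance = 1))
  expect_equal(nrow(all_in$accepted), 10)

  # a row identical to the observation ranks first with zero distance
  obs2 <- unlist(tab[7, stat_vector_names()])
  post2 <- suppressMessages(rejection(obs2, tab, tolerance = 0.1))
  expect_equal(as.integer(rownames(post2$accepted)), 7)
  expect_equal(post2$distance, 0)
})

test_that("rejection is invariant to row permutations of the table", {
  set.seed(9)
  tab <- draw_prior_sample(50, seed = 10)
  tab$sim_seed <- 1:50
  stats <- matrix(rnorm(50 * 32), 50, 32,
                  dimnames = list(NULL, stat_vector_names()))
  tab <- cbind(tab, as.data.frame(stats))
  obs <- setNames(rnorm(32), stat_vector_names())
  a <- rejection(obs, tab, tolerance = 0.1)
  perm <- sample(50)
  b <- rejection(obs, tab[perm, ], tolerance = 0.1)
  expect_equal(sort(a$accepted$N_D), sort(b$accepted$N_D))
})

test_that("1-D KDE modes recover known distributions within bandwidth", {
  set.seed(12)
  x <- pmin(pmax(rnorm(5000, 0.3, 0.01), 0), 1)
  expect_equal(posterior_mode_1d(x, 0, 1)$mode, 0.30, tolerance = 0.01)
  # tight cluster
  y <- rep(0.5, 50) + rnorm(50, 0, 1e-4)
  expect_equal(posterior_mode_1d(y, 0, 1)$mode, 0.5, tolerance = 0.01)
  # bimodal with heavier right cluster
  z <- c(rnorm(400, 0.2, 0.02), rnorm(900, 0.8, 0.02))
  expect_equal(posterior_mode_1d(z, 0, 1)$mode, 0.8, tolerance = 0.05)
  expect_error(posterior_mode_1d(1:5, 0, 1), ">= 10")
})

test_that("2-D KDE finds joint modes; projections can differ from marginals", {
  set.seed(13)
  x <- pmin(pmax(rnorm(3000, 100, 5), 1), 1000)
  y <- pmin(pmax(rnorm(3000, 0.7, 0.02), 0), 1)
  jm <- posterior_mode_2d(x, y, c(1, 1000), c(0, 1))
  expect_equal(jm$mode[1], 100, tolerance = 10)
  expect_equal(jm$mode[2], 0.7, tolerance = 0.05)
  expect_gt(jm$level50, jm$level95)

  # skewed dependent sample: joint mode need not project onto marginals
  u <- runif(4000)
  xs <- 0.1 + 0.8 * u^2
  ys <- ifelse(u > 0.5, 0.9 - 0.6 * u, 0.2 + 0.1 * u) + rnorm(4000, 0, 0.02)
  ys <- pmin(pmax(ys, 0), 1)
  jm2 <- posterior_mode_2d(xs, ys, c(0, 1), c(0, 1))
  mx <- posterior_mode_1d(xs, 0, 1)$mode
  my <- posterior_mode_1d(ys, 0, 1)$mode
  expect_true(is.finite(jm2$mode[1]) && is.finite(jm2$mode[2]))
  # at least one projection differs measurably from the marginal mode
  expect_gt(max(abs(jm2$mode - c(mx, my))), 1e-3)
})

test_that("HPD intervals match a brute-force smallest-window search", {
  set.seed(14)
  # uniform sample: the 95% interval covers ~95% of the support
  u <- runif(4000)
  h <- hpd_interval(u, 0.95, 0, 1)
  expect_equal(diff(h), 0.95, tolerance = 0.05)

  # near point mass: narrow interval
  pm <- rnorm(2000, 0.4, 1e-3)
  expect_lt(diff(hpd_interval(pm, 0.95, 0, 1)), 0.05)

  # exponential-shaped sample: interval is anchored near 0 and agrees with
  # a brute-force smallest-window search over the empirical sample
  ex <- rexp(5000, 10); ex <- ex[ex < 1]
  h2 <- hpd_interval(ex, 0.9, 0, 1)
  s <- sort(ex)
  k <- ceiling(0.9 * length(s))
  widths <- s[k:length(s)] - s[1:(length(s) - k + 1)]
  i <- which.min(widths)
  brute <- c(s[i], s[i + k - 1])
  expect_lt(h2[1], 0.02)
  expect_equal(h2[2], brute[2], tolerance = 0.05)
  # interval contains the KDE mode
  m <- posterior_mode_1d(ex, 0, 1)$mode
  expect_true(h2[1] <= m && m <= h2[2])
})

test_that("accepted-parameter correlations match direct computation", {
  acc <- data.frame(N_D = c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10),
                    P = c(2, 1, 4, 3, 6, 5, 8, 7, 10, 9) / 10,
                    M_E = rep(0.005, 10), M_L = (10:1) / 1000)
  expect_warning(r <- accepted_param_correlation(acc, n_perm = 50, seed = 2),
                 "constant")
  expect_equal(unname(r$r["N_D", "P"]), cor(acc$N_D, acc$P), tolerance = 1e-12)
  expect_equal(unname(r$r["N_D", "M_L"]), -1)
  # independent draws: |r| small, p not extreme
  set.seed(6)
  acc2 <- data.frame(N_D = runif(400), P = runif(400),
                     M_E = runif(400), M_L = runif(400))
  r2 <- accepted_param_correlation(acc2, n_perm = 200, seed = 3)
  expect_lt(abs(r2$r["N_D", "P"]), 3 / sqrt(400))
  expect_gt(r2$p["N_D", "P"], 0.01)
})
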