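# a size-constant single-deme configuration used in several checks
const_model <- function(N) demographic_model(N_D = N, N_NE_modern = N, N_anc = N)

test_that("deme size trajectories hit the model's anchor values", {
  m <- demographic_model(N_D = 100, P = 0.7, M_E = 0.002, M_L = 1e-4)
  expect_equal(deme_size_at(m, "NE", 0), 1007170)
  expect_equal(deme_size_at(m, "NE", 1750), 45000)
  # size approaches N_D at the domestication boundary from below
  expect_equal(deme_size_at(m, "NE", 1750 - 1e-9), 100, tolerance = 1e-6)
  expect_equal(deme_size_at(m, "EU", 0), 7942392)
  # EU founding size is P x NE size at the split
  ne_split <- deme_size_at(m, "NE", 1400)
  expect_equal(deme_size_at(m, "EU", 1400 - 1e-9), 0.7 * ne_split,
               tolerance = 1e-6)
  expect_error(deme_size_at(m, "EU", 1400), "T_split")
  m0 <- demographic_model(N_D = 100, P = 0)
  expect_error(deme_size_at(m0, "EU", 10), "P = 0")
})

test_that("migration epochs switch at 5,000 BCE and the split", {
  m <- demographic_model(N_D = 100, P = 0.7, M_E = 0.002, M_L = 1e-4)
  expect_equal(migration_rate_at(m, 0), 1e-4)
  expect_equal(migration_rate_at(m, 1300), 0.002)
  expect_equal(migration_rate_at(m, 1500), 0)
  expect_equal(migration_rate_at(m, 7000 / 6), 0.002)  # boundary is early
})

test_that("genealogies respect sampling times and parent ordering", {
  m <- demographic_model(N_D = 50, P = 0.6, M_E = 1e-3, M_L = 1e-4)
  sc <- sampling_scheme(c("NE", "NE", "EU", "EU", "EU"),
                        c(1500, 900, 0, 300, 1100))
  g <- simulate_genealogy(m, sc, seed = 42)
  expect_equal(g$time[seq_len(5)], sc$time)
  for (i in seq_len(2 * 5 - 2))
    expect_gt(g$time[g$parent[i] + 1], g$time[i])
  # single sample: trivial genealogy
  g1 <- simulate_genealogy(m, sampling_scheme("NE", 100), seed = 1)
  expect_equal(g1$total_branch_length, 0)
  expect_error(simulate_genealogy(m, sampling_scheme("EU", 1400)), "split")
})

test_that("simulator matches serial-coalescent expectations for pairs", {
  m <- const_model(1000)
  set.seed(8)
  tm <- replicate(4000, simulate_genealogy(m, sampling_scheme("NE", 0, n = 2),
                                           seed = sample.int(1e8, 1))$tmrca)
  se <- sd(tm) / sqrt(length(tm))
  expect_lt(abs(mean(tm) - 1000), 3 * se)

  sc <- sampling_scheme(c("NE", "NE"), c(0, 500))
  tb <- replicate(4000, simulate_genealogy(m, sc,
                                           seed = sample.int(1e8, 1))$total_branch_length)
  se <- sd(tb) / sqrt(length(tb))
  expect_lt(abs(mean(tb) - 2500), 3 * se)
})

test_that("mutation process gives E[pi] = 2 N mu_seq and is length-linear", {
  m <- const_model(1000)
  sc <- sampling_scheme("NE", 0, n = 2)
  mut1 <- mutation_model(seq_length = 240)
  mut2 <- mutation_model(seq_length = 480)
  set.seed(21)
  pis <- replicate(4000, {
    s <- sample.int(1e8, 1)
    g <- simulate_genealogy(m, sc, seed = s)
    c(mean_pairwise_differences(add_mutations(g, mut1, seed = s + 1))$pi,
      mean_pairwise_differences(add_mutations(g, mut2, seed = s + 2))$pi)
  })
  exp1 <- 2 * 1000 * mut1$mu_site_gen * 240
  se1 <- sd(pis[1, ]) / sqrt(ncol(pis))
  expect_lt(abs(mean(pis[1, ]) - exp1), 3 * se1 + 0.02 * exp1)
  # doubling the length doubles pi (same genealogies, paired comparison)
  expect_equal(mean(pis[2, ]) / mean(pis[1, ]), 2, tolerance = 0.1)
  # zero branch length: identical sequences
  g1 <- simulate_genealogy(m, sampling_scheme("NE", 100), seed = 3)
  a1 <- add_mutations(g1, mut1, seed = 4)
  expect_length(a1$seqs, 1)
})

test_that("simulate_dataset is seed-deterministic and group-structured", {
  sc <- sampling_scheme(c("NE", "EU"), c(1450, 100), n = c(5, 6),
                        group = c("ancient_NE", "modern_EU"))
  p <- list(N_D = 200, P = 0.4, M_E = 0.001, M_L = 0)
  d1 <- simulate_dataset(p, sc, seed = 33)
  d2 <- simulate_dataset(p, sc, seed = 33)
  expect_identical(d1, d2)
  d3 <- simulate_dataset(p, sc, seed = 34)
  expect_false(identical(d1, d3))
  expect_equal(sort(names(d1)), c("ancient_NE", "modern_EU"))
  expect_equal(length(d1$ancient_NE), 5)
})

test_that("a full founder (P near 1, no migration) leaves demes undifferentiated", {
  sc <- sampling_scheme(c("NE", "EU"), c(1390, 1390), n = c(12, 12),
                        group = c("a", "b"))
  p <- list(N_D = 100, P = 0.999, M_E = 0, M_L = 0)
  set.seed(55)
  fst <- replicate(80, {
    d <- simulate_dataset(p, sc, seed = sample.int(1e8, 1))
    pairwise_fst(d$a, d$b, n_perm = 0)$fst
  })
  expect_lt(abs(mean(fst)), 0.05)
})

test_that("larger bottlenecks increase ancient Near Eastern diversity", {
  sc <- sampling_scheme("NE", 1500, n = 12, group = "anc")
  mean_pi <- function(nd) {
    set.seed(nd)
    mean(replicate(250, {
      d <- simulate_dataset(list(N_D = nd, P = 0.5, M_E = 0, M_L = 0),
                            sc, seed = sample.int(1e8, 1))
      mean_pairwise_differences(d$anc)$pi
    }))
  }
  expect_lt(mean_pi(20), mean_pi(800))
})

test_that("size-scale multipliers keep the model runnable", {
  for (s in c(0.1, 10)) {
    sc <- sampling_scheme(c("NE", "EU"), c(1500, 0), n = c(3, 3),
                          group = c("a", "b"))
    d <- simulate_dataset(list(N_D = 100, P = 0.5, M_E = 1e-3, M_L = 1e-4),
                          sc, seed = 7,
                          model_constants = list(size_scale_NE = s,
                                                 size_scale_E = s))
    expect_length(d$a, 3)
  }
})
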