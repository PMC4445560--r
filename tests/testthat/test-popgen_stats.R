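test_that("haplotype calling handles identity, wildcards and transitivity", {
  a <- aligned_seqs(c(x = "ACGT", y = "ACGT", z = "ACGA"), c(1L, 4L))
  h <- call_haplotypes(a)
  expect_equal(nrow(h$haplotypes), 2)
  expect_equal(sort(h$haplotypes$n), c(1L, 2L))

  # N matches any base under the wildcard policy
  b <- aligned_seqs(c(x = "ACGT", y = "ACNT"), c(1L, 4L))
  expect_equal(nrow(call_haplotypes(b)$haplotypes), 1)

  # transitive merge: u~v (via N) and v~w (via N) links u and w even though
  # u and w differ at no commonly typed site only through v
  c3 <- aligned_seqs(c(u = "ANGT", v = "ANNT", w = "AGNT"), c(1L, 4L))
  expect_equal(nrow(call_haplotypes(c3)$haplotypes), 1)

  # complete_sites drops N-bearing columns first
  d <- aligned_seqs(c(x = "ACGT", y = "ACNA"), c(1L, 4L))
  expect_equal(nrow(call_haplotypes(d, "complete_sites")$haplotypes), 2)

  # monomorphic fixture collapses to one haplotype
  expect_equal(nrow(call_haplotypes(toys$monomorphic)$haplotypes), 1)

  # per-group counts sum to group sizes
  grp <- c("g1", "g1", "g2")
  h2 <- call_haplotypes(a, groups = grp)
  expect_equal(as.vector(colSums(h2$counts_by_group)), c(2L, 1L))
})

test_that("haplotype diversity matches Nei's estimator and its edge cases", {
  expect_equal(haplotype_diversity(c(2, 2))$H, 4 / 3 * 0.5)
  mono <- haplotype_diversity(8)
  expect_equal(mono$H, 0)
  expect_equal(mono$sd, 0)
  # bounds over random count vectors
  set.seed(42)
  for (i in 1:25) {
    counts <- sample(1:6, sample(2:6, 1), replace = TRUE)
    h <- haplotype_diversity(counts)
    expect_gte(h$H, 0); expect_lte(h$H, 1)
  }
  expect_error(haplotype_diversity(1), "n >= 2")
})

test_that("pi and S behave on toys, with pairwise deletion of missing sites", {
  two <- aligned_seqs(c(a = "AAAA", b = "ATTA"), c(1L, 4L))
  expect_equal(mean_pairwise_differences(two)$pi, 2)
  expect_equal(mean_pairwise_differences(toys$monomorphic)$pi, 0)
  expect_equal(mean_pairwise_differences(toys$tajima_toy)$pi, 7 / 6)

  expect_equal(segregating_sites(toys$tajima_toy), 2)
  expect_equal(segregating_sites(toys$monomorphic), 0)
  # a column with only one non-missing state is not segregating
  mixed <- aligned_seqs(c(a = "AN", b = "A-", c = "AN"), c(1L, 2L))
  expect_equal(segregating_sites(mixed), 0)
  # missing sites are skipped pair by pair: A?T vs AAT compares 2 sites
  pm <- aligned_seqs(c(a = "A?T", b = "AAT"), c(1L, 3L))
  expect_equal(mean_pairwise_differences(pm)$pi, 0)
})

test_that("Tajima's D reproduces the hand-evaluated toy and flags S = 0", {
  td <- tajimas_d(toys$tajima_toy, n_null_sims = 0)
  expect_equal(td$D, 0.5915801, tolerance = 1e-6)

  mono <- tajimas_d(toys$monomorphic, n_null_sims = 0)
  expect_false(mono$defined)
  expect_true(is.na(mono$D))

  # D = 0 when pi equals S/a1 exactly (numerator vanishes)
  expect_equal(cattleabc:::.tajima_d_from(2, 2 / (11 / 6), 4), 0)

  expect_error(tajimas_d(aligned_seqs(c(a = "A"), c(1L, 1L))), "n >= 2")
})

test_that("Fu's Fs equals exhaustive Ewens enumeration for all n <= 8", {
  # frozen worked example: n=4, theta=1, k=3 -> S' = 7/24
  expect_equal(cattleabc:::.fs_from(1, 3, 4), log((7 / 24) / (17 / 24)),
               tolerance = 1e-9)
  for (n in 2:8) for (theta in c(0.5, 1, 5)) {
    pk <- ewens_pr_k(n, 1:n, theta)
    expect_equal(pk, ewens_oracle_pr_k(n, theta), tolerance = 1e-9)
    expect_equal(sum(pk), 1, tolerance = 1e-9)
    for (k in 2:n) {
      want <- fs_oracle(n, theta, k)
      expect_equal(cattleabc:::.fs_from(theta, k, n), want, tolerance = 1e-9)
    }
  }
  # k_obs = 1 gives S' = 1: log-odds diverge, flagged undefined
  expect_true(is.na(cattleabc:::.fs_from(1, 1, 4)))
  expect_false(fus_fs(toys$monomorphic, n_null_sims = 0)$defined)
})

test_that("neutrality p-values are seed-reproducible and sane", {
  aln <- random_aln(12, 60, seed = 5)
  t1 <- tajimas_d(aln, n_null_sims = 400, seed = 9)
  t2 <- tajimas_d(aln, n_null_sims = 400, seed = 9)
  expect_equal(t1$p, t2$p)
  expect_gte(t1$p, 0); expect_lte(t1$p, 1)
  f1 <- fus_fs(aln, n_null_sims = 400, seed = 9)
  expect_gte(f1$p, 0); expect_lte(f1$p, 1)
  # random unrelated sequences are haplotype-rich: Fs far from the neutral
  # lower tail, so its p should not be tiny
  expect_gt(f1$p, 0.01)
})
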