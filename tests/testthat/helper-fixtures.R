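# shared fixtures and small oracles used across the suite

toys <- make_toy_fixtures()

# write a FASTA string to a temp file and return the path
write_tmp_fasta <- function(text) {
  f <- tempfile(fileext = ".fasta")
  writeLines(text, f)
  f
}

# minimal valid metadata row(s)
make_md <- function(n = 1, id = paste0("s", seq_len(n)),
                    region = "IR 7,000-5,000 BCE", epoch = "ancient",
                    lo = 7000, hi = 5000, lat = 34, lon = 48) {
  data.frame(sample_id = id, site = "x", lat = lat, lon = lon,
             region_group = region, age_bce_lo = lo, age_bce_hi = hi,
             epoch = epoch, stringsAsFactors = FALSE)
}

# brute-force two-group AMOVA variance components, written independently of
# the implementation: explicit SSD decomposition from first principles
amova_oracle <- function(d, grp) {
  n <- length(grp)
  lv <- unique(grp)
  ssd_total <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) ssd_total <- ssd_total + d[i, j]
  ssd_total <- ssd_total / n
  ssd_within <- 0
  for (g in lv) {
    idx <- which(grp == g)
    s <- 0
    if (length(idx) > 1) {
      cmb <- combn(idx, 2)
      for (c_ in seq_len(ncol(cmb))) s <- s + d[cmb[1, c_], cmb[2, c_]]
    }
    ssd_within <- ssd_within + s / length(idx)
  }
  ssd_among <- ssd_total - ssd_within
  G <- length(lv)
  sizes <- table(grp)
  ms_among <- ssd_among / (G - 1)
  ms_within <- ssd_within / (n - G)
  n_c <- (n - sum(sizes^2) / n) / (G - 1)
  sigma_a <- (ms_among - ms_within) / n_c
  if (sigma_a + ms_within == 0) return(0)
  sigma_a / (sigma_a + ms_within)
}

# exhaustive Ewens sampling formula by direct product-form enumeration:
# Pr(K = k) = |s(n,k)| theta^k / prod_{i=0}^{n-1}(theta + i), with the
# Stirling numbers built by naive integer recursion (exact for small n)
ewens_oracle_pr_k <- function(n, theta) {
  s <- matrix(0, n + 1, n + 1)
  s[1, 1] <- 1  # |s(0,0)| = 1
  for (m in 1:n) for (k in 1:m)
    s[m + 1, k + 1] <- (m - 1) * s[m, k + 1] + s[m, k]
  num <- s[n + 1, 2:(n + 1)] * theta^(1:n)
  num / prod(theta + 0:(n - 1))
}

fs_oracle <- function(n, theta, k_obs) {
  pk <- ewens_oracle_pr_k(n, theta)
  sp <- sum(pk[k_obs:n])
  if (sp >= 1) return(NA_real_)
  log(sp / (1 - sp))
}

# random small alignment with optional missing data
random_aln <- function(n, L, seed, p_missing = 0) {
  set.seed(seed)
  chars <- c("A", "C", "G", "T")
  seqs <- vapply(seq_len(n), function(i) {
    s <- sample(chars, L, replace = TRUE)
    if (p_missing > 0) {
      miss <- runif(L) < p_missing
      s[miss] <- "N"
    }
    paste(s, collapse = "")
  }, character(1))
  names(seqs) <- paste0("r", seq_len(n))
  aligned_seqs(seqs, c(1L, L))
}

desk_truth <- list(N_D = 100, P = 0.7, M_E = 0.002, M_L = 1e-4)
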