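#' @title Molecular diversity and neutrality statistics
#' @name popgen_stats
#' @description Haplotype calling, haplotype diversity, mean pairwise
#'   differences, segregating sites, Tajima's D and Fu's Fs, with p-values
#'   from constant-size coalescent null simulations.
NULL

.BASE_CODE <- c(A = 0L, C = 1L, G = 2L, T = 3L, N = -1L, "-" = -1L, "?" = -1L)

# integer matrix (rows = samples) with -1 for missing
.encode_aln <- function(aln) {
  chars <- strsplit(aln$seqs, "", fixed = TRUE)
  m <- do.call(rbind, lapply(chars, function(ch) {
    v <- .BASE_CODE[ch]
    v[is.na(v)] <- -1L
    unname(v)
  }))
  rownames(m) <- names(aln$seqs)
  m
}

# transitive closure of the zero-distance (compatibility) graph, via
# union-find; with complete data this reduces to exact identity classes
.hap_assign <- function(d) {
  n <- nrow(d)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }
    i
  }
  zp <- which(d == 0L & upper.tri(d), arr.ind = TRUE)
  for (r in seq_len(nrow(zp))) {
    ri <- find(zp[r, 1L]); rj <- find(zp[r, 2L])
    if (ri != rj) parent[rj] <- ri
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

.pairdiff <- function(aln_or_mat) {
  m <- if (inherits(aln_or_mat, "aligned_seqs")) .encode_aln(aln_or_mat) else aln_or_mat
  storage.mode(m) <- "integer"
  .pair_diff_cpp(m)
}

#' Call haplotypes in an alignment
#'
#' Under the `wildcard` policy (default, mirroring a missing-data-tolerant
#' toolchain setting) two sequences share a haplotype iff they agree at every
#' site at which both are non-missing; compatible sequences are merged
#' transitively. Under `complete_sites` all columns containing any missing
#' symbol are removed first and haplotypes are exact string classes.
#'
#' @param aln [aligned_seqs()].
#' @param missing_policy `"wildcard"` or `"complete_sites"`.
#' @param groups optional factor/character of group labels per sequence, to
#'   tabulate per-group haplotype counts.
#' @return List with `assignment` (integer haplotype index per sequence),
#'   `haplotypes` (data.frame: id, representative, n), and, when `groups` is
#'   given, `counts_by_group` (matrix haplotype x group).
#' @export
call_haplotypes <- function(aln, missing_policy = c("wildcard", "complete_sites"),
                            groups = NULL) {
  missing_policy <- match.arg(missing_policy)
  n <- length(aln$seqs)
  if (n < 1) stop("empty alignment")
  m <- .encode_aln(aln)
  if (missing_policy == "complete_sites") {
    keep <- colSums(m < 0) == 0
    m <- m[, keep, drop = FALSE]
  }
  d <- .pairdiff(m)
  assignment <- .hap_assign(d)
  ids <- seq_len(max(assignment))
  rep_idx <- vapply(ids, function(h) {
    members <- which(assignment == h)
    members[which.min(vapply(members, function(i) sum(m[i, ] < 0), numeric(1)))]
  }, integer(1))
  hap <- data.frame(
    haplotype = paste0("H", ids),
    representative = names(aln$seqs)[rep_idx],
    n = as.integer(tabulate(assignment, length(ids))),
    stringsAsFactors = FALSE)
  out <- list(assignment = assignment, haplotypes = hap,
              policy = missing_policy)
  if (!is.null(groups)) {
    out$counts_by_group <- table(factor(assignment, levels = ids), groups)
  }
  class(out) <- "haplotype_table"
  out
}

#' Haplotype (gene) diversity with standard deviation
#'
#' Nei's unbiased estimator `H = n/(n-1) (1 - sum p_i^2)` with Nei's
#' sampling variance.
#'
#' @param counts vector of haplotype counts.
#' @return List `H`, `sd`, `n`, `k`.
#' @export
haplotype_diversity <- function(counts) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n < 2) stop("need n >= 2")
  p <- counts / n
  s2 <- sum(p^2); s3 <- sum(p^3)
  H <- n / (n - 1) * (1 - s2)
  V <- 2 / (n * (n - 1)) * (2 * (n - 2) * (s3 - s2^2) + s2 - s2^2)
  list(H = H, sd = sqrt(max(V, 0)), n = n, k = length(counts))
}

#' Mean number of pairwise differences
#'
#' Average over all unordered sequence pairs of the number of differing
#' sites, comparing only sites at which both sequences are non-missing
#' (pairwise deletion). The standard deviation uses Tajima's (1983)
#' total variance of pi.
#'
#' @param aln [aligned_seqs()].
#' @return List `pi`, `sd`, `n`.
#' @export
mean_pairwise_differences <- function(aln) {
  n <- length(aln$seqs)
  if (n < 2) stop("need n >= 2")
  d <- .pairdiff(aln)
  pi <- sum(d[upper.tri(d)]) / choose(n, 2)
  V <- (n + 1) / (3 * (n - 1)) * pi +
    2 * (n^2 + n + 3) / (9 * n * (n - 1)) * pi^2
  list(pi = pi, sd = sqrt(max(V, 0)), n = n)
}

#' Number of segregating sites
#'
#' Columns holding at least two distinct non-missing bases.
#'
#' @param aln [aligned_seqs()].
#' @return Integer count.
#' @export
segregating_sites <- function(aln) {
  m <- .encode_aln(aln)
  sum(apply(m, 2, function(col) length(unique(col[col >= 0])) >= 2))
}

# Tajima (1989) constants for sample size n
.tajima_constants <- function(n) {
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

.tajima_d_from <- function(S, pi, n) {
  if (S < 1) return(NA_real_)
  k <- .tajima_constants(n)
  denom <- sqrt(k$e1 * S + k$e2 * S * (S - 1))
  if (denom == 0) return(NA_real_)
  (pi - S / k$a1) / denom
}

.fs_from <- function(pi, K, n) {
  if (pi <= 0 || K <= 1) return(NA_real_)
  lsp <- .log_sprime(n, pi, K)
  if (lsp >= 0) return(NA_real_)  # S' = 1
  # Fs = log(S'/(1-S')) computed stably in log space
  lsp - log1p(-exp(lsp))
}

# log Pr(K >= k_obs) under the Ewens sampling formula at theta
.log_sprime <- function(n, theta, k_obs) {
  ls <- .log_stirling1_row_cpp(n)            # log|s(n,k)|, k = 1..n
  lth <- log(theta)
  lnorm <- sum(log(theta + 0:(n - 1)))
  lp <- ls + (1:n) * lth - lnorm             # log Pr(K = k)
  tail <- lp[k_obs:n]
  mx <- max(tail)
  mx + log(sum(exp(tail - mx)))
}

#' Tajima's D with a coalescent-simulation p-value
#'
#' `D = (pi - S/a1) / sqrt(e1 S + e2 S (S-1))` (Tajima 1989). The p-value is
#' the lower-tail proportion of D values simulated under a constant-size
#' neutral coalescent with theta set to the observed mean pairwise
#' differences; replicates with S = 0 (D undefined) are excluded from the
#' denominator.
#'
#' @param aln [aligned_seqs()].
#' @param n_null_sims number of null coalescent replicates (0 = no p-value).
#' @param seed RNG seed for the null simulations.
#' @return List `D`, `p`, `S`, `pi`, `n`, `defined`, `n_sims`.
#' @export
tajimas_d <- function(aln, n_null_sims = 10000L, seed = 1L) {
  n <- length(aln$seqs)
  if (n < 2) stop("need n >= 2")
  S <- segregating_sites(aln)
  pi <- mean_pairwise_differences(aln)$pi
  D <- .tajima_d_from(S, pi, n)
  if (is.na(D))
    return(list(D = NA_real_, p = NA_real_, S = S, pi = pi, n = n,
                defined = FALSE, n_sims = 0L))
  p <- NA_real_
  if (n_null_sims > 0) {
    null <- .sim_null_cpp(n, max(pi, 1e-8), as.integer(n_null_sims),
                          as.integer(seed))
    Dsim <- mapply(.tajima_d_from, null[, "S"], null[, "pi"],
                   MoreArgs = list(n = n))
    ok <- !is.na(Dsim)
    if (any(ok)) p <- mean(Dsim[ok] <= D)
  }
  list(D = D, p = p, S = S, pi = pi, n = n, defined = TRUE,
       n_sims = as.integer(n_null_sims))
}

#' Fu's Fs with a coalescent-simulation p-value
#'
#' `S' = Pr(K >= k_obs | theta = pi)` under the Ewens sampling formula,
#' `Fs = ln(S'/(1 - S'))` (Fu 1997). Stirling numbers are evaluated in log
#' space. Undefined (flagged) when the sample is monomorphic (`pi = 0` or a
#' single haplotype). The p-value is the lower-tail proportion of Fs in
#' constant-size coalescent null replicates at theta = observed pi, each
#' replicate evaluated at its own simulated pi and K; undefined replicates
#' are excluded.
#'
#' @inheritParams tajimas_d
#' @param missing_policy haplotype-calling policy, see [call_haplotypes()].
#' @return List `Fs`, `p`, `k_obs`, `pi`, `n`, `defined`, `n_sims`.
#' @export
fus_fs <- function(aln, n_null_sims = 10000L, seed = 1L,
                   missing_policy = "wildcard") {
  n <- length(aln$seqs)
  if (n < 2) stop("need n >= 2")
  pi <- mean_pairwise_differences(aln)$pi
  k_obs <- nrow(call_haplotypes(aln, missing_policy)$haplotypes)
  Fs <- .fs_from(pi, k_obs, n)
  if (is.na(Fs))
    return(list(Fs = NA_real_, p = NA_real_, k_obs = k_obs, pi = pi, n = n,
                defined = FALSE, n_sims = 0L))
  p <- NA_real_
  if (n_null_sims > 0) {
    null <- .sim_null_cpp(n, max(pi, 1e-8), as.integer(n_null_sims),
                          as.integer(seed) + 1L)
    Fsim <- mapply(.fs_from, null[, "pi"], null[, "K"],
                   MoreArgs = list(n = n))
    ok <- !is.na(Fsim)
    if (any(ok)) p <- mean(Fsim[ok] <= Fs)
  }
  list(Fs = Fs, p = p, k_obs = k_obs, pi = pi, n = n, defined = TRUE,
       n_sims = as.integer(n_null_sims))
}

#' Ewens sampling probability of k haplotypes (exact)
#'
#' `Pr(K = k | theta, n)` via log-space Stirling numbers of the first kind.
#' Exposed mainly for verification.
#'
#' @param n sample size.
#' @param k number of haplotypes (scalar or vector).
#' @param theta scaled mutation rate.
#' @return Probability vector.
#' @export
ewens_pr_k <- function(n, k, theta) {
  ls <- .log_stirling1_row_cpp(n)
  lnorm <- sum(log(theta + 0:(n - 1)))
  exp(ls[k] + k * log(theta) - lnorm)
}
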