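#' @title Population differentiation (Phi-ST / F-ST)
#' @name fst
#' @description Two-group AMOVA-based Phi-ST on pairwise sequence
#'   differences, a haplotype-frequency analogue, permutation tests, full
#'   pairwise matrices, and Reynolds' linearised distance.
NULL

# two-group AMOVA fixation index from a squared-distance matrix `d`
# (pairwise difference counts, or 0/1 haplotype identity) and a 2-level
# group index. Excoffier-style sums of squared deviations.
.amova_fst <- function(d, grp) {
  n <- length(grp)
  sizes <- tabulate(grp)
  G <- length(sizes)
  ssd_t <- sum(d[upper.tri(d)]) / n
  ssd_w <- 0
  for (g in seq_len(G)) {
    i <- which(grp == g)
    if (length(i) > 1) {
      dg <- d[i, i, drop = FALSE]
      ssd_w <- ssd_w + sum(dg[upper.tri(dg)]) / length(i)
    }
  }
  ssd_a <- ssd_t - ssd_w
  df_a <- G - 1
  df_w <- n - G
  ms_a <- ssd_a / df_a
  ms_w <- ssd_w / df_w
  nprime <- (n - sum(sizes^2) / n) / (G - 1)
  sig_a <- (ms_a - ms_w) / nprime
  tot <- sig_a + ms_w
  if (tot == 0) return(0)
  sig_a / tot
}

#' Pairwise F-ST between two groups with a permutation test
#'
#' `phi_st` (default): AMOVA-based Phi-ST using pairwise difference counts
#' as squared molecular distances. `haplotype_freq`: the same variance
#' decomposition on 0/1 haplotype-identity distances, i.e. a frequency-based
#' (Reynolds/Weir-Cockerham style) index ignoring molecular distance between
#' haplotypes. Negative estimates are reported as computed (clamping is
#' applied only when building ordination distances).
#'
#' @param a,b [aligned_seqs()] for the two groups (same window).
#' @param estimator `"phi_st"` or `"haplotype_freq"`.
#' @param n_perm permutations (individuals reshuffled between the groups,
#'   sizes preserved); 0 disables the test.
#' @param seed RNG seed for permutations.
#' @return List `fst`, `p`, `estimator`, `n_perm`.
#' @export
pairwise_fst <- function(a, b, estimator = c("phi_st", "haplotype_freq"),
                         n_perm = 10000L, seed = 1L) {
  estimator <- match.arg(estimator)
  na <- length(a$seqs); nb <- length(b$seqs)
  if (na < 2 || nb < 2) stop("each group needs n >= 2")
  comb <- aligned_seqs(c(a$seqs, b$seqs), a$window)
  grp <- rep(1:2, c(na, nb))
  d <- .pairdiff(comb)
  if (estimator == "haplotype_freq") {
    hap <- call_haplotypes(comb)$assignment
    d <- (outer(hap, hap, "!=")) * 1
  }
  obs <- .amova_fst(d, grp)
  p <- NA_real_
  if (n_perm > 0) {
    set.seed(seed)
    hits <- 0L
    for (i in seq_len(n_perm)) {
      if (.amova_fst(d, sample(grp)) >= obs) hits <- hits + 1L
    }
    p <- hits / n_perm
  }
  list(fst = obs, p = p, estimator = estimator, n_perm = as.integer(n_perm))
}

#' Pairwise F-ST matrix over several groups
#'
#' @param groups named list of [aligned_seqs()] sharing a window.
#' @param estimator,n_perm,seed as in [pairwise_fst()]; per-pair seeds are
#'   derived from `seed` by the pair's index so the matrix is reproducible.
#' @return List `fst` (symmetric, zero diagonal), `p` (permutation
#'   p-values, `NA` diagonal).
#' @export
fst_matrix <- function(groups, estimator = "phi_st", n_perm = 10000L,
                       seed = 1L) {
  G <- length(groups)
  if (G < 2) stop("need >= 2 groups")
  labs <- names(groups)
  if (is.null(labs)) labs <- paste0("G", seq_len(G))
  f <- matrix(0, G, G, dimnames = list(labs, labs))
  p <- matrix(NA_real_, G, G, dimnames = list(labs, labs))
  idx <- 0L
  for (i in seq_len(G - 1)) for (j in (i + 1):G) {
    idx <- idx + 1L
    r <- pairwise_fst(groups[[i]], groups[[j]], estimator,
                      n_perm = n_perm, seed = derive_seed(seed, idx))
    f[i, j] <- f[j, i] <- r$fst
    p[i, j] <- p[j, i] <- r$p
  }
  list(fst = f, p = p, estimator = estimator)
}

#' Reynolds' linearised genetic distance from F-ST
#'
#' `D = -ln(1 - F_ST)`; negative F-ST is treated as 0 (no differentiation).
#'
#' @param fst scalar or matrix of F-ST values (< 1).
#' @return Distances on the same shape.
#' @export
reynolds_distance <- function(fst) {
  fst <- pmax(fst, 0)
  if (any(fst >= 1)) fst <- pmin(fst, 1 - 1e-12)
  -log(1 - fst)
}

#' Mean between-group pairwise differences
#'
#' Average number of differing sites over all cross-group sequence pairs
#' (pairwise deletion of missing sites).
#'
#' @param a,b [aligned_seqs()] for the two groups.
#' @return Mean count.
#' @export
between_group_pi <- function(a, b) {
  comb <- aligned_seqs(c(a$seqs, b$seqs), a$window)
  d <- .pairdiff(comb)
  na <- length(a$seqs)
  cross <- d[seq_len(na), na + seq_len(length(b$seqs)), drop = FALSE]
  mean(cross)
}
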