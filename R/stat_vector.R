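#' @title ABC summary-statistic vector
#' @name stat_vector
#' @description The 32-element summary vector used for rejection ABC:
#'   5 within-group statistics (haplotype count K, haplotype diversity H,
#'   mean pairwise differences pi, segregating sites S, Tajima's D) for each
#'   of the 4 sample groups, and 2 between-group statistics (Phi-ST and mean
#'   cross-group pairwise differences) for each of the 6 group pairs.
NULL

#' Canonical ABC group order
#' @export
ABC_GROUPS <- c("ancient_NE", "ancient_EU", "modern_NE", "modern_EU")

.WITHIN_STATS <- c("K", "H", "pi", "S", "D")

#' Names of the 32 summary statistics in canonical order
#'
#' Groups in the fixed order ancient_NE, ancient_EU, modern_NE, modern_EU;
#' the 6 pairs follow [utils::combn()] over that order.
#'
#' @return Character vector of length 32.
#' @export
stat_vector_names <- function() {
  within <- as.vector(outer(.WITHIN_STATS, ABC_GROUPS,
                            function(s, g) paste(s, g, sep = ".")))
  pairs <- combn(ABC_GROUPS, 2)
  between <- as.vector(apply(pairs, 2, function(p)
    c(paste0("fst.", p[1], ".", p[2]), paste0("dxy.", p[1], ".", p[2]))))
  c(within, between)
}

# fast path on an encoded integer matrix + group factor (levels = ABC_GROUPS)
.stat_vector_int <- function(m, grp) {
  d <- .pair_diff_cpp(m)
  if (any(m < 0L)) {
    hap <- .hap_assign(d)  # wildcard policy needs transitive merging
  } else {
    # complete data: zero distance is an equivalence relation, so the first
    # zero-distance partner indexes the class
    hap <- apply(d == 0L, 1L, which.max)
  }
  out <- numeric(0)
  idx <- split(seq_len(nrow(m)), grp)
  for (g in ABC_GROUPS) {
    i <- idx[[g]]
    n <- length(i)
    dg <- d[i, i, drop = FALSE]
    pig <- sum(dg[upper.tri(dg)]) / choose(n, 2)
    counts <- tabulate(match(hap[i], unique(hap[i])))
    K <- length(counts)
    H <- n / (n - 1) * (1 - sum((counts / n)^2))
    sub <- m[i, , drop = FALSE]
    S <- sum(apply(sub, 2, function(col) {
      col <- col[col >= 0]
      length(col) && any(col != col[1])
    }))
    D <- .tajima_d_from(S, pig, n)
    if (is.na(D)) D <- 0  # undefined encoded as 0 (flag dropped in ABC)
    out <- c(out, K, H, pig, S, D)
  }
  pairs <- combn(ABC_GROUPS, 2)
  for (c_ in seq_len(ncol(pairs))) {
    i <- idx[[pairs[1, c_]]]; j <- idx[[pairs[2, c_]]]
    grp2 <- rep(1:2, c(length(i), length(j)))
    dd <- d[c(i, j), c(i, j), drop = FALSE]
    fst <- .amova_fst(dd, grp2)
    dxy <- mean(d[i, j, drop = FALSE])
    out <- c(out, fst, dxy)
  }
  names(out) <- stat_vector_names()
  out
}

#' Compute the 32-element ABC summary-statistic vector
#'
#' @param groups named list of [aligned_seqs()] containing exactly the four
#'   groups `ancient_NE, ancient_EU, modern_NE, modern_EU`, each with
#'   n >= 2.
#' @return Named numeric vector of length 32 (see [stat_vector_names()]).
#'   Undefined Tajima's D (monomorphic group) is encoded as 0, identically
#'   for observed and simulated data.
#' @export
abc_stat_vector <- function(groups) {
  miss <- setdiff(ABC_GROUPS, names(groups))
  if (length(miss))
    stop("missing ABC group(s): ", paste(miss, collapse = ", "))
  if (any(vapply(groups, length, integer(1))[ABC_GROUPS] < 2))
    stop("every ABC group needs n >= 2")
  seqs <- unlist(lapply(ABC_GROUPS, function(g) groups[[g]]$seqs))
  grp <- factor(rep(ABC_GROUPS, vapply(groups[ABC_GROUPS], length, integer(1))),
                levels = ABC_GROUPS)
  m <- .encode_aln(aligned_seqs(seqs, groups[[1]]$window))
  .stat_vector_int(m, grp)
}
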