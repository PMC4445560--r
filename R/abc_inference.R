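#' @title Rejection ABC and posterior summaries
#' @name abc_inference
#' @description Uniform prior sampling, batch simulation of the
#'   summary-statistic table, rejection sampling on standardised Euclidean
#'   distance, reflected-kernel density estimates of posterior modes,
#'   highest-posterior-density intervals and accepted-parameter
#'   correlations.
NULL

#' Default parameter priors
#'
#' `N_D ~ U(1, 1000)`, `P ~ U(0, 1)`, `M_E, M_L ~ U(0, 0.01)`.
#'
#' @return data.frame `param, lo, hi`.
#' @export
default_prior <- function() {
  data.frame(param = c("N_D", "P", "M_E", "M_L"),
             lo = c(1, 0, 0, 0),
             hi = c(1000, 1, 0.01, 0.01),
             stringsAsFactors = FALSE)
}

#' Draw parameter sets from the priors
#'
#' @param n number of draws.
#' @param prior prior table, see [default_prior()].
#' @param seed RNG seed.
#' @return data.frame with one column per parameter.
#' @export
draw_prior_sample <- function(n, prior = default_prior(), seed = 1L) {
  stopifnot(n >= 1)
  set.seed(seed)
  out <- as.data.frame(lapply(seq_len(nrow(prior)), function(i)
    runif(n, prior$lo[i], prior$hi[i])))
  names(out) <- prior$param
  out
}

#' Simulate a table of parameters and summary statistics
#'
#' One row per simulation: the drawn parameter 4-tuple, the per-row derived
#' seed (see [derive_seed()]), and the 32 summary statistics. Row results
#' depend only on the master seed and the row index, so the table is
#' reproducible and independent of execution order.
#'
#' @param n_sims number of simulations.
#' @param scheme [sampling_scheme()] (the observed sampling design).
#' @param mut [mutation_model()].
#' @param prior see [default_prior()].
#' @param seed master seed.
#' @param model_constants overrides for [demographic_model()].
#' @param progress print a progress message every `progress` rows (0 = off).
#' @return data.frame of class `simulation_table`.
#' @export
run_simulation_batch <- function(n_sims, scheme, mut = mutation_model(),
                                 prior = default_prior(), seed = 1L,
                                 model_constants = list(), progress = 0L) {
  stopifnot(n_sims >= 1)
  params <- draw_prior_sample(n_sims, prior, seed = seed)
  grp <- factor(scheme$group, levels = ABC_GROUPS)
  if (anyNA(grp))
    stop("scheme groups must be the four ABC groups")
  stats <- matrix(NA_real_, n_sims, 32,
                  dimnames = list(NULL, stat_vector_names()))
  seeds <- integer(n_sims)
  for (i in seq_len(n_sims)) {
    seeds[i] <- derive_seed(seed, i)
    m <- .simulate_ints(params[i, ], scheme, mut, seeds[i], model_constants)
    stats[i, ] <- .stat_vector_int(m, grp)
    if (progress > 0 && i %% progress == 0)
      message("simulated ", i, "/", n_sims)
  }
  out <- cbind(params, sim_seed = seeds, as.data.frame(stats))
  class(out) <- c("simulation_table", "data.frame")
  out
}

.PARAM_COLS <- c("N_D", "P", "M_E", "M_L")

#' Rejection ABC
#'
#' Each statistic is standardised by its standard deviation across the whole
#' table (constant columns are dropped with a message); the distance is
#' Euclidean in standardised space and the `ceiling(tolerance * n)` closest
#' rows are retained, ties broken by row index.
#'
#' @param observed named 32-element statistic vector ([abc_stat_vector()]).
#' @param table [run_simulation_batch()] result.
#' @param tolerance retained proportion, in (0, 1].
#' @param scale `"sd"` (default) or `"mad"` column standardisation.
#' @return `posterior_result` list: `accepted` (data.frame of parameter
#'   rows), `distance`, `tolerance`, `n_total`, `dropped_stats`.
#' @export
rejection <- function(observed, table, tolerance = 0.001, scale = c("sd", "mad")) {
  scale <- match.arg(scale)
  if (!nrow(table)) stop("empty simulation table")
  stopifnot(tolerance > 0, tolerance <= 1)
  statcols <- intersect(stat_vector_names(), names(table))
  sm <- as.matrix(table[, statcols, drop = FALSE])
  obs <- observed[statcols]
  sc <- if (scale == "sd") apply(sm, 2, sd) else apply(sm, 2, stats::mad)
  keep <- is.finite(sc) & sc > 0
  dropped <- statcols[!keep]
  if (length(dropped))
    message("dropping constant statistic(s): ", paste(dropped, collapse = ", "))
  z <- sweep(sm[, keep, drop = FALSE], 2, sc[keep], "/")
  zo <- obs[keep] / sc[keep]
  dist <- sqrt(rowSums(sweep(z, 2, zo, "-")^2))
  n_keep <- ceiling(tolerance * nrow(table))
  ord <- order(dist, seq_along(dist))[seq_len(n_keep)]
  structure(list(
    accepted = table[ord, c(.PARAM_COLS, "sim_seed"), drop = FALSE],
    distance = dist[ord],
    tolerance = tolerance,
    n_total = nrow(table),
    dropped_stats = dropped),
    class = "posterior_result")
}

# reflected-boundary Gaussian KDE on a grid within [lo, hi]
.kde_reflect <- function(x, lo, hi, n_grid = 512L, bw = NULL) {
  if (is.null(bw)) bw <- bw.nrd0(x)
  if (bw <= 0) bw <- max(1e-9, diff(range(x)) / 100, (hi - lo) * 1e-6)
  aug <- c(x, 2 * lo - x, 2 * hi - x)
  d <- density(aug, bw = bw, from = lo, to = hi, n = n_grid)
  d$y <- d$y * 3
  cell <- (hi - lo) / (n_grid - 1)
  d$y <- d$y / (sum(d$y) * cell)  # renormalise on the truncated support
  list(x = d$x, y = d$y, bw = bw)
}

#' Marginal posterior mode via reflected KDE
#'
#' Gaussian KDE with Silverman's bandwidth on a 512-point grid spanning the
#' prior support, with boundary reflection so mass near the prior bounds is
#' not smeared outward.
#'
#' @param values accepted parameter draws (>= 10).
#' @param lo,hi prior support bounds.
#' @param n_grid grid resolution.
#' @return List `mode`, `grid`, `density`, `bw`.
#' @export
posterior_mode_1d <- function(values, lo, hi, n_grid = 512L) {
  if (length(values) < 10) stop("need >= 10 values")
  k <- .kde_reflect(values, lo, hi, n_grid)
  list(mode = k$x[which.max(k$y)], grid = k$x, density = k$y, bw = k$bw)
}

#' Joint posterior mode of two parameters via reflected product-kernel KDE
#'
#' @param x,y accepted draws of the two parameters.
#' @param xlim,ylim prior supports.
#' @param n_grid per-axis grid resolution.
#' @return List `mode` (length-2), `gx`, `gy`, `density` (matrix),
#'   `levels50`, `levels95` (density thresholds enclosing 50%/95% of the
#'   posterior mass, for contouring).
#' @export
posterior_mode_2d <- function(x, y, xlim, ylim, n_grid = 256L) {
  if (length(x) < 10) stop("need >= 10 values")
  stopifnot(length(x) == length(y))
  bwx <- bw.nrd0(x); bwy <- bw.nrd0(y)
  if (bwx <= 0) bwx <- diff(xlim) / 100
  if (bwy <= 0) bwy <- diff(ylim) / 100
  gx <- seq(xlim[1], xlim[2], length.out = n_grid)
  gy <- seq(ylim[1], ylim[2], length.out = n_grid)
  refl <- function(g, v, lo, hi, bw) {
    dnorm(outer(g, v, "-"), sd = bw) +
      dnorm(outer(g, 2 * lo - v, "-"), sd = bw) +
      dnorm(outer(g, 2 * hi - v, "-"), sd = bw)
  }
  Ax <- refl(gx, x, xlim[1], xlim[2], bwx)
  Ay <- refl(gy, y, ylim[1], ylim[2], bwy)
  dens <- (Ax %*% t(Ay)) / length(x)
  cell <- (gx[2] - gx[1]) * (gy[2] - gy[1])
  dens <- dens / (sum(dens) * cell)
  ij <- which(dens == max(dens), arr.ind = TRUE)[1, ]
  ds <- sort(as.vector(dens), decreasing = TRUE)
  cum <- cumsum(ds) * cell
  lev <- function(mass) ds[which(cum >= mass)[1]]
  list(mode = c(gx[ij[1]], gy[ij[2]]), gx = gx, gy = gy, density = dens,
       level50 = lev(0.5), level95 = lev(0.95))
}

#' Highest-posterior-density interval
#'
#' The shortest interval containing the requested mass of the reflected-KDE
#' posterior (grid search over all windows of the cumulative density).
#'
#' @param values accepted draws (>= 10).
#' @param mass credible mass, e.g. 0.95.
#' @param lo,hi prior support bounds.
#' @param n_grid grid resolution.
#' @return Numeric `c(lo, hi)`.
#' @export
hpd_interval <- function(values, mass = 0.95, lo, hi, n_grid = 512L) {
  if (length(values) < 10) stop("need >= 10 values")
  stopifnot(mass > 0, mass < 1)
  k <- .kde_reflect(values, lo, hi, n_grid)
  cell <- k$x[2] - k$x[1]
  cum <- c(0, cumsum(k$y) * cell)    # cum[i+1] = mass up to grid point i
  best <- c(lo, hi); bestw <- hi - lo
  j <- 1L
  for (i in seq_len(n_grid)) {
    if (j < i) j <- i
    while (j <= n_grid && cum[j + 1] - cum[i] < mass) j <- j + 1L
    if (j > n_grid) break
    w <- k$x[j] - k$x[i]
    if (w < bestw) { bestw <- w; best <- c(k$x[i], k$x[j]) }
  }
  best
}

#' Correlations between accepted parameters with permutation p-values
#'
#' @param accepted data.frame of accepted parameter draws (or a
#'   `posterior_result`).
#' @param n_perm permutations of one column per pair.
#' @param seed RNG seed.
#' @return List `r` (Pearson correlation matrix), `p` (two-sided permutation
#'   p-values, `(1+k)/(1+n_perm)`).
#' @export
accepted_param_correlation <- function(accepted, n_perm = 10000L, seed = 1L) {
  if (inherits(accepted, "posterior_result")) accepted <- accepted$accepted
  cols <- intersect(.PARAM_COLS, names(accepted))
  m <- as.matrix(accepted[, cols, drop = FALSE])
  if (nrow(m) < 10) stop("need >= 10 accepted rows")
  const <- apply(m, 2, function(v) sd(v) == 0)
  if (any(const))
    warning("constant parameter column(s): ", paste(cols[const], collapse = ", "))
  r <- suppressWarnings(cor(m))
  p <- matrix(NA_real_, ncol(m), ncol(m), dimnames = dimnames(r))
  set.seed(seed)
  for (i in seq_len(ncol(m) - 1)) for (j in (i + 1):ncol(m)) {
    if (const[i] || const[j]) next
    obs <- abs(r[i, j])
    hits <- 0L
    for (b in seq_len(n_perm))
      if (abs(cor(m[, i], sample(m[, j]))) >= obs) hits <- hits + 1L
    p[i, j] <- p[j, i] <- (1 + hits) / (1 + n_perm)
  }
  list(r = r, p = p)
}

#' Summarise a posterior result
#'
#' Marginal modes and 50%/95% HPD intervals for the four parameters, the
#' joint (N_D, P) mode, and the accepted-parameter correlation matrix.
#'
#' @param result [rejection()] output.
#' @param prior prior table (for KDE supports).
#' @param n_perm permutations for the correlation test.
#' @param seed RNG seed.
#' @return List `modes`, `hpd50`, `hpd95`, `joint_mode_ND_P`, `correlation`.
#' @export
posterior_summary <- function(result, prior = default_prior(),
                              n_perm = 10000L, seed = 1L) {
  acc <- result$accepted
  modes <- hpd50 <- hpd95 <- list()
  for (i in seq_len(nrow(prior))) {
    pm <- prior$param[i]
    v <- acc[[pm]]
    modes[[pm]] <- posterior_mode_1d(v, prior$lo[i], prior$hi[i])$mode
    hpd50[[pm]] <- hpd_interval(v, 0.50, prior$lo[i], prior$hi[i])
    hpd95[[pm]] <- hpd_interval(v, 0.95, prior$lo[i], prior$hi[i])
  }
  jm <- posterior_mode_2d(acc$N_D, acc$P,
                          xlim = c(prior$lo[prior$param == "N_D"],
                                   prior$hi[prior$param == "N_D"]),
                          ylim = c(prior$lo[prior$param == "P"],
                                   prior$hi[prior$param == "P"]))
  list(modes = modes, hpd50 = hpd50, hpd95 = hpd95,
       joint_mode_ND_P = jm$mode,
       correlation = accepted_param_correlation(acc, n_perm = n_perm,
                                                seed = seed))
}
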