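#' @title Isolation by distance and ordination
#' @name spatial_analysis
#' @description Great-circle distances between group centroids, Mantel tests
#'   of genetic against geographic distance, and Kruskal non-metric MDS of
#'   genetic distance matrices.
NULL

#' Great-circle distance between two coordinates
#'
#' Haversine formula on a sphere of radius 6,371 km (via \pkg{geosphere}).
#'
#' @param a,b numeric `c(lat, lon)` in degrees.
#' @return Distance in km.
#' @export
great_circle_km <- function(a, b) {
  chk <- function(p) {
    if (abs(p[1]) > 90 || abs(p[2]) > 180)
      stop("invalid coordinates: lat in [-90,90], lon in [-180,180]")
  }
  chk(a); chk(b)
  geosphere::distHaversine(c(a[2], a[1]), c(b[2], b[1]), r = 6371000) / 1000
}

#' Centroid of a set of coordinates
#'
#' Arithmetic mean of latitudes and longitudes (planar approximation,
#' adequate at the continental scale at which group centres were placed).
#'
#' @param points matrix/data.frame with columns lat, lon.
#' @return Numeric `c(lat, lon)`.
#' @export
group_centroid <- function(points) {
  points <- as.matrix(points)
  if (!nrow(points)) stop("no points")
  c(lat = mean(points[, 1]), lon = mean(points[, 2]))
}

#' Geographic distance matrix between group centroids
#'
#' @param md validated metadata (see [read_metadata()]).
#' @param by grouping column.
#' @return Symmetric matrix of great-circle distances (km) between group
#'   centroids.
#' @export
geo_distance_matrix <- function(md, by = "region_group") {
  cent <- do.call(rbind, lapply(split(md, md[[by]]), function(g)
    group_centroid(cbind(g$lat, g$lon))))
  G <- nrow(cent)
  d <- matrix(0, G, G, dimnames = list(rownames(cent), rownames(cent)))
  for (i in seq_len(G - 1)) for (j in (i + 1):G)
    d[i, j] <- d[j, i] <- great_circle_km(cent[i, ], cent[j, ])
  d
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation over the upper-triangle entries; the null
#' distribution permutes rows and columns of the second matrix jointly.
#' `p = (1 + #\{r_perm >= r_obs\}) / (n_perm + 1)`.
#'
#' @param m1,m2 symmetric matrices with zero diagonals and matching labels.
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @return List `r`, `p`, `r2`, `n_perm`.
#' @export
mantel_test <- function(m1, m2, n_perm = 9999L, seed = 1L) {
  m1 <- as.matrix(m1); m2 <- as.matrix(m2)
  if (!all(dim(m1) == dim(m2))) stop("dimension mismatch")
  if (!is.null(rownames(m1)) && !is.null(rownames(m2)) &&
      !identical(rownames(m1), rownames(m2)))
    stop("matrix labels do not match")
  ut <- upper.tri(m1)
  if (sd(m1[ut]) == 0 || sd(m2[ut]) == 0)
    stop("constant distance matrix: Mantel correlation undefined")
  r_obs <- cor(m1[ut], m2[ut])
  set.seed(seed)
  n <- nrow(m1)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    p_ <- sample(n)
    if (cor(m1[ut], m2[p_, p_][ut]) >= r_obs) hits <- hits + 1L
  }
  p <- (1 + hits) / (n_perm + 1)
  list(r = r_obs, p = p, r2 = r_obs^2, n_perm = as.integer(n_perm))
}

#' Non-metric multidimensional scaling (Kruskal)
#'
#' Wraps [MASS::isoMDS()] with multiple restarts (classical-scaling start
#' plus random starts) keeping the lowest-stress configuration. Negative or
#' zero off-diagonal entries (possible for F-ST estimates) are clamped to a
#' small epsilon, with the clamp count reported.
#'
#' @param d symmetric distance matrix, zero diagonal.
#' @param dims embedding dimension.
#' @param seed RNG seed for random restarts.
#' @param n_restarts number of random restarts after the classical start.
#' @param eps clamp value for non-positive off-diagonal entries.
#' @return List `points` (labelled coordinate matrix), `stress` (Kruskal
#'   stress-1, fraction), `n_clamped`, `restarts`.
#' @export
nmds_embed <- function(d, dims = 2L, seed = 1L, n_restarts = 20L,
                       eps = 1e-6) {
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8)) stop("matrix must be symmetric")
  ut <- upper.tri(d)
  if (all(d[ut] <= 0)) stop("all off-diagonal distances are non-positive")
  n_clamped <- sum(d[ut] <= 0)
  d[d <= 0] <- eps
  diag(d) <- 0
  dd <- stats::as.dist(d)
  best <- NULL
  set.seed(seed)
  init <- cmdscale(dd, k = dims)
  starts <- c(list(init),
              lapply(seq_len(n_restarts), function(i)
                init + matrix(rnorm(length(init), sd = sd(init) + 1e-8),
                              nrow(init))))
  for (s in starts) {
    fit <- tryCatch(
      suppressMessages(MASS::isoMDS(dd, y = s, k = dims, trace = FALSE)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$stress < best$stress))
      best <- fit
  }
  if (is.null(best)) stop("NMDS failed from every start")
  rownames(best$points) <- rownames(d)
  list(points = best$points, stress = best$stress / 100,
       n_clamped = n_clamped, restarts = length(starts))
}
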