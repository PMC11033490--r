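#' Geographic distances between pools
#'
#' `euclidean` is the great-circle (haversine) distance on a spherical Earth
#' of radius 6371 km. `least_cost` is the shortest path through the sea:
#' cells of `seaMask` with a positive, non-missing value are passable, the
#' path moves between 8-connected cell centers, and each step costs the
#' great-circle distance between the two centers (no sqrt(2) approximation
#' on the lon/lat grid). Sites must fall on sea cells; unreachable pairs get
#' `Inf`.
#'
#' @param pools data.frame with `name`, `latitude`, `longitude` (a
#'   [PoolCounts-class] / [PoolFreqs-class] `colData` works after
#'   `as.data.frame`), or one of those objects directly
#' @param metric `"euclidean"` or `"least_cost"`
#' @param seaMask an [EnvGrid-class] mask, required for `least_cost`
#' @return symmetric site x site matrix of distances in km, with attribute
#'   `metric`
#' @export
geoDistances <- function(pools, metric = c("euclidean", "least_cost"),
                         seaMask = NULL) {
  metric <- match.arg(metric)
  if (is(pools, "SummarizedExperiment"))
    pools <- data.frame(name = colnames(pools),
                        latitude = colData(pools)$latitude,
                        longitude = colData(pools)$longitude)
  ll <- cbind(pools$longitude, pools$latitude)
  n <- nrow(ll)
  if (metric == "euclidean") {
    d <- matrix(0, n, n)
    for (i in seq_len(n))
      d[i, ] <- geosphere::distHaversine(ll[i, , drop = FALSE], ll,
                                         r = 6371000) / 1000
    d[cbind(seq_len(n), seq_len(n))] <- 0
  } else {
    if (is.null(seaMask)) stop("least_cost requires a seaMask raster")
    d <- leastCostDistances(seaMask, pools)
  }
  dimnames(d) <- list(pools$name, pools$name)
  attr(d, "metric") <- metric
  d
}

leastCostDistances <- function(mask, pools) {
  g <- mask@grid
  sea <- !is.na(g) & g > 0
  nr <- nrow(g); nc <- ncol(g)
  id <- matrix(NA_integer_, nr, nc)
  id[sea] <- seq_len(sum(sea))
  rc <- which(sea, arr.ind = TRUE)
  lat <- cellCenterLat(mask, rc[, 1]); lon <- cellCenterLon(mask, rc[, 2])
  # 8-neighbour edges, each emitted once (E, SE, S, SW offsets)
  from <- to <- integer(0)
  for (off in list(c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))) {
    r2 <- rc[, 1] + off[1]; c2 <- rc[, 2] + off[2]
    okn <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    nb <- rep(NA_integer_, nrow(rc))
    nb[okn] <- id[cbind(r2[okn], c2[okn])]
    has <- !is.na(nb)
    from <- c(from, id[rc[has, , drop = FALSE]])
    to <- c(to, nb[has])
  }
  w <- geosphere::distHaversine(cbind(lon[from], lat[from]),
                                cbind(lon[to], lat[to]), r = 6371000) / 1000
  gr <- igraph::make_graph(as.vector(rbind(from, to)), n = sum(sea),
                           directed = FALSE)
  cells <- siteCells(mask, pools$latitude, pools$longitude)
  vid <- id[cells]
  if (anyNA(vid))
    stop("sites on land/blocked cells: ",
         paste(pools$name[is.na(vid)], collapse = ", "))
  d <- igraph::distances(gr, v = vid, to = vid, weights = w)
  if (any(is.infinite(d)))
    warning("some site pairs are unreachable through the sea mask (Inf)")
  unname(d)
}

#' Mantel test between two distance matrices
#'
#' `r` is the Pearson correlation of the lower-triangle entries; the
#' one-sided upper-tail p-value is `(1 + #{r_perm >= r}) / (nPerm + 1)`,
#' permuting rows and columns of `d2` jointly.
#'
#' @param d1,d2 symmetric distance matrices over the same sites
#' @param nPerm number of permutations (default 999)
#' @param seed optional integer seed for the permutations
#' @return list: `r`, `p`, `nPerm`
#' @export
mantelTest <- function(d1, d2, nPerm = 999L, seed = NULL) {
  d1 <- as.matrix(d1); d2 <- as.matrix(d2)
  stopifnot(identical(dim(d1), dim(d2)), nPerm >= 1L)
  n <- nrow(d1)
  lt <- lower.tri(d1)
  v1 <- d1[lt]
  if (stats::sd(v1) == 0 || stats::sd(d2[lt]) == 0)
    stop("Mantel r undefined: a matrix is constant over pairs")
  if (!is.null(seed)) set.seed(as.integer(seed))
  r <- stats::cor(v1, d2[lt])
  ge <- 0L
  for (b in seq_len(nPerm)) {
    idx <- sample.int(n)
    rp <- stats::cor(v1, d2[idx, idx][lt])
    if (rp >= r) ge <- ge + 1L
  }
  list(r = r, p = (1 + ge) / (nPerm + 1), nPerm = as.integer(nPerm))
}
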