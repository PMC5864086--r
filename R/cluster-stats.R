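#' Cluster-forming critical t value
#'
#' Inverse CDF of the Student t distribution with df = n - 1 at
#' 1 - alpha / sidedness. For 20 participants and a two-tailed alpha of
#' 0.05 this is 2.093 (the "2.1" cluster-forming threshold).
#'
#' @param n number of participants (>= 2).
#' @param alpha significance level (default 0.05).
#' @param sided 2 for two-tailed (default) or 1 for one-tailed.
#' @return critical t (numeric).
#' @examples
#' criticalT(20)  # 2.093
#' @export
criticalT <- function(n, alpha = 0.05, sided = 2) {
  if (n < 2L) stop("undefined df: need n >= 2")
  stats::qt(1 - alpha / sided, df = n - 1L)
}

#' Dependent-samples t map
#'
#' Elementwise paired t test across participants: t = mean(d) / (sd(d) /
#' sqrt(n)) of the per-participant differences at each grid point. Points
#' with zero difference variance get t = 0 and are flagged.
#'
#' @param mapsA,mapsB numeric matrices, participants x grid points, aligned.
#' @return a \code{\linkS4class{TMap}}.
#' @export
pairedTMap <- function(mapsA, mapsB) {
  if (!all(dim(mapsA) == dim(mapsB)))
    stop("maps must share participants and grid")
  n <- nrow(mapsA)
  if (n < 2L) stop("need >= 2 participants for a paired t map")
  d <- mapsA - mapsB
  m <- colMeans(d)
  s <- sqrt((colSums(d^2) - n * m^2) / (n - 1))
  t <- m / (s / sqrt(n))
  zv <- which(!is.finite(t) | s <= 0)
  if (length(zv)) {
    t[zv] <- 0
    message(length(zv), " grid point(s) had zero difference variance; t set to 0")
  }
  new("TMap", t = as.numeric(t), df = as.integer(n - 1L),
      zeroVar = as.integer(zv))
}

#' Grid adjacency from coordinates
#'
#' Two grid points are neighbours iff their Euclidean distance is at most
#' \code{factor} x \code{spacing} (face adjacency on a regular lattice with
#' the default factor 1.01).
#'
#' @param coords n x 3 coordinate matrix (mm).
#' @param spacing lattice spacing; default: the smallest nonzero
#'   inter-point distance.
#' @param factor multiplicative tolerance on the neighbour radius.
#' @return list of integer neighbour-index vectors, one per grid point.
#' @export
gridAdjacency <- function(coords, spacing = NULL, factor = 1.01) {
  n <- nrow(coords)
  d <- as.matrix(stats::dist(coords))
  if (is.null(spacing)) spacing <- min(d[d > 0])
  lapply(seq_len(n), function(i)
    which(d[i, ] > 0 & d[i, ] <= factor * spacing))
}

# union-find connected components over the subgraph induced by `points`
# (integer indices); adjacency is the full-grid neighbour list.
# Returns a list of integer vectors (components).
.components <- function(points, adjacency) {
  np <- length(points)
  if (np == 0L) return(list())
  pos <- integer(max(points)); pos[points] <- seq_len(np)
  parent <- seq_len(np)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  inSet <- logical(length(adjacency)); inSet[points] <- TRUE
  for (k in seq_len(np)) {
    nb <- adjacency[[points[k]]]
    nb <- nb[inSet[nb]]
    for (j in pos[nb]) {
      rk <- find(k); rj <- find(j)
      if (rk != rj) parent[rk] <- rj
    }
  }
  roots <- vapply(seq_len(np), find, integer(1))
  unname(split(points, roots))
}

#' Connected components of a grid-point set
#'
#' Splits a set of grid points into spatially connected components under
#' the supplied adjacency (see \code{\link{gridAdjacency}}).
#'
#' @param points integer grid-point indices.
#' @param adjacency neighbour list over the full grid.
#' @return list of integer vectors, one per component.
#' @export
connectedComponents <- function(points, adjacency) {
  .components(as.integer(points), adjacency)
}

# summed t per component, given a named structure; returns data.frame rows
.clusterTable <- function(comps, t) {
  if (!length(comps))
    return(data.frame(id = integer(), sign = character(),
                      nPoints = integer(), tSum = numeric()))
  data.frame(id = seq_along(comps),
             sign = vapply(comps, function(m)
               if (sum(t[m]) >= 0) "pos" else "neg", character(1)),
             nPoints = lengths(comps),
             tSum = vapply(comps, function(m) sum(t[m]), numeric(1)))
}

# max cluster statistic of a t map under a threshold (internal, fast path)
.maxClusterStat <- function(t, tCrit, adjacency, sided) {
  if (sided == "two") {
    stat <- 0
    for (sgn in c(1, -1)) {
      pts <- which(sgn * t > tCrit)
      if (length(pts)) {
        comps <- .components(pts, adjacency)
        stat <- max(stat, max(abs(vapply(comps, function(m) sum(t[m]),
                                         numeric(1)))))
      }
    }
    stat
  } else {
    pts <- which(t > tCrit)
    if (!length(pts)) return(0)
    comps <- .components(pts, adjacency)
    max(vapply(comps, function(m) sum(t[m]), numeric(1)))
  }
}

#' Cluster-based permutation test for paired designs
#'
#' Thresholds the observed dependent-t map at +/- \code{tCrit}, forms
#' spatially connected suprathreshold clusters per sign, and compares each
#' cluster's summed t (T_sum) against the Monte-Carlo distribution of the
#' maximal cluster statistic obtained by randomly sign-flipping the
#' per-participant difference maps (the exchangeable null for a dependent
#' t). Two-sided tests use the maximum |T_sum| per permutation; one-sided
#' tests use the maximum positive T_sum. p values use the add-one
#' convention, so they are never exactly zero.
#'
#' @param diffs numeric matrix, participants x grid points, of paired
#'   differences.
#' @param adjacency neighbour list from \code{\link{gridAdjacency}}.
#' @param nPerm number of permutations (default 1000).
#' @param tCrit cluster-forming threshold (default
#'   \code{criticalT(nrow(diffs))}).
#' @param clusterAlpha significance level for accepting clusters (default
#'   0.05).
#' @param sided \code{"two"} (default) or \code{"one"} (positive clusters
#'   only).
#' @param seed RNG seed.
#' @return list with \code{clusters} (data.frame: id, sign, nPoints, tSum,
#'   pCluster, significant), \code{membership} (integer per grid point; 0 =
#'   no cluster), \code{tmap} (\code{\linkS4class{TMap}}), \code{tCrit},
#'   and \code{nullMax} (permutation distribution).
#' @export
clusterPermutation <- function(diffs, adjacency, nPerm = 1000,
                               tCrit = criticalT(nrow(diffs)),
                               clusterAlpha = 0.05,
                               sided = c("two", "one"), seed = NULL) {
  sided <- match.arg(sided)
  if (nPerm < 100L) stop("need at least 100 permutations")
  n <- nrow(diffs); nG <- ncol(diffs)
  if (length(adjacency) != nG)
    stop("adjacency must cover all grid points")
  tmap <- pairedTMap(diffs, matrix(0, n, nG))
  t <- tmap@t
  signs <- if (sided == "two") c(1, -1) else 1
  comps <- list()
  for (sgn in signs) {
    pts <- which(sgn * t > tCrit)
    if (length(pts)) comps <- c(comps, .components(pts, adjacency))
  }
  tab <- .clusterTable(comps, t)

  # permutation null: sign-flip difference maps; column sums of squares are
  # flip-invariant, so permuted t maps are computed in one matrix product
  if (!is.null(seed)) set.seed(seed)
  css <- colSums(diffs^2)
  nullMax <- numeric(nPerm)
  block <- 200L
  done <- 0L
  while (done < nPerm) {
    nb <- min(block, nPerm - done)
    S <- matrix(sample(c(-1, 1), nb * n, replace = TRUE), nb, n)
    M <- (S %*% diffs) / n
    SD <- sqrt(pmax(sweep(-n * M^2, 2L, css, "+") / (n - 1), 0))
    TP <- M / (SD / sqrt(n))
    TP[!is.finite(TP)] <- 0
    for (b in seq_len(nb))
      nullMax[done + b] <- .maxClusterStat(TP[b, ], tCrit, adjacency, sided)
    done <- done + nb
  }
  obs <- if (sided == "two") abs(tab$tSum) else tab$tSum
  tab$pCluster <- vapply(obs, function(o)
    (1 + sum(nullMax >= o)) / (1 + nPerm), numeric(1))
  tab$significant <- tab$pCluster < clusterAlpha
  membership <- integer(nG)
  for (k in seq_along(comps)) membership[comps[[k]]] <- k
  list(clusters = tab, membership = membership, tmap = tmap,
       tCrit = tCrit, nullMax = nullMax)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p values (via \code{p.adjust(method = "BH")}) and the
#' rejection set at level \code{q}.
#'
#' @param p numeric vector of p values in [0, 1].
#' @param q FDR level (default 0.05).
#' @return list with \code{adjusted} (numeric) and \code{rejected}
#'   (integer indices).
#' @examples
#' fdrAdjust(c(0.01, 0.02, 0.03, 0.04))$adjusted  # all 0.04
#' @export
fdrAdjust <- function(p, q = 0.05) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("invalid input: p values must lie in [0, 1]")
  adj <- stats::p.adjust(p, method = "BH")
  list(adjusted = adj, rejected = which(adj < q))
}
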