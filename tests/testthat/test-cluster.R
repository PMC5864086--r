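test_that("the cluster-forming critical t matches the Student t table", {
  expect_equal(round(criticalT(20), 1), 2.1)
  expect_equal(criticalT(20), qt(0.975, 19))
  expect_equal(criticalT(1e6), qnorm(0.975), tolerance = 1e-3)
  expect_equal(criticalT(2), 12.706, tolerance = 1e-3)
  expect_error(criticalT(1), "undefined df")
})

test_that("paired t maps behave like elementwise dependent t tests", {
  set.seed(20)
  a <- matrix(rnorm(20 * 30), 20, 30)
  expect_true(all(tValues(pairedTMap(a, a)) == 0))

  # noncentrality oracle: constant +delta difference with unit noise,
  # n = 20 -> mean t over simulations ~ delta / (sigma / sqrt(20))
  delta <- 0.5
  ts <- replicate(300, {
    d <- matrix(delta + rnorm(20), 20, 1)
    tValues(pairedTMap(d, matrix(0, 20, 1)))
  })
  expect_equal(mean(ts), delta / (1 / sqrt(20)), tolerance = 0.12)

  # cross-check one column against t.test
  b <- a + matrix(rnorm(20 * 30, 0.2), 20, 30)
  tm <- pairedTMap(b, a)
  expect_equal(tm@t[3], unname(t.test(b[, 3], a[, 3], paired = TRUE)$statistic))
  expect_identical(tm@df, 19L)

  expect_error(pairedTMap(a[1, , drop = FALSE], a[1, , drop = FALSE] * 0),
               ">= 2 participants")
})

test_that("connected components match a brute-force flood fill", {
  # BFS oracle, independent of the union-find implementation
  floodFill <- function(points, adj) {
    left <- points; comps <- list()
    while (length(left)) {
      queue <- left[1]; comp <- integer()
      while (length(queue)) {
        v <- queue[1]; queue <- queue[-1]
        if (v %in% comp) next
        comp <- c(comp, v)
        queue <- c(queue, intersect(adj[[v]], setdiff(left, comp)))
      }
      comps[[length(comps) + 1]] <- sort(comp)
      left <- setdiff(left, comp)
    }
    comps
  }
  canon <- function(l) l[order(vapply(l, min, numeric(1)))]

  dims <- c(5, 5, 4)
  adj <- gridAdjacency(gridCoordinates(dims, 6))
  set.seed(21)
  for (rep in 1:25) {
    pts <- sort(sample(prod(dims), sample(3:35, 1)))
    got <- canon(lapply(connectedComponents(pts, adj), sort))
    want <- canon(floodFill(pts, adj))
    expect_identical(got, want)
  }
})

test_that("cluster permutation finds planted clusters and respects geometry", {
  dims <- c(6, 6, 6)
  adj <- gridAdjacency(gridCoordinates(dims, 6))
  nG <- prod(dims)
  set.seed(22)
  n <- 15
  effect <- centralRegion(dims, 2)
  d <- matrix(rnorm(n * nG), n, nG)
  d[, effect] <- d[, effect] + 1.2
  res <- clusterPermutation(d, adj, nPerm = 200, seed = 1)
  sig <- res$clusters[res$clusters$significant, ]
  expect_gte(nrow(sig), 1)
  best <- sig[which.max(abs(sig$tSum)), ]
  members <- which(res$membership == best$id)
  expect_gt(length(intersect(members, effect)) / length(union(members, effect)),
            0.5)
  # T_sum really is the sum of member t values
  expect_equal(best$tSum, sum(res$tmap@t[members]))

  # no suprathreshold points -> no clusters (not an error)
  res0 <- clusterPermutation(matrix(rnorm(n * 27, 0, 1e-2), n, 27),
                             gridAdjacency(gridCoordinates(c(3, 3, 3), 6)),
                             nPerm = 100, tCrit = 50, seed = 1)
  expect_identical(nrow(res0$clusters), 0L)
  expect_true(all(res0$membership == 0))
})

test_that("isolated points form their own clusters and order does not matter", {
  dims <- c(4, 4, 4)
  coords <- gridCoordinates(dims, 6)
  adj <- gridAdjacency(coords)
  set.seed(23)
  n <- 12
  # plant a strong compact cluster plus one distant isolated point
  blob <- c(1, 2, 5)          # corner, face-connected
  lone <- prod(dims)          # opposite corner
  d <- matrix(rnorm(n * prod(dims), 0, 0.5), n, prod(dims))
  d[, blob] <- d[, blob] + 2
  resA <- clusterPermutation(d, adj, nPerm = 100, seed = 5)
  tabA <- resA$clusters
  blobRow <- tabA[vapply(tabA$id, function(id)
    all(blob %in% which(resA$membership == id)), logical(1)), ]

  dLone <- d; dLone[, lone] <- dLone[, lone] + 3
  resB <- clusterPermutation(dLone, adj, nPerm = 100, seed = 5)
  tabB <- resB$clusters
  blobRowB <- tabB[vapply(tabB$id, function(id)
    all(blob %in% which(resB$membership == id)), logical(1)), ]
  # adding a far-away suprathreshold point never changes the blob's T_sum
  expect_equal(blobRow$tSum, blobRowB$tSum)
  loneRow <- tabB[tabB$nPoints == 1 &
                    vapply(tabB$id, function(id)
                      lone %in% which(resB$membership == id), logical(1)), ]
  expect_equal(loneRow$tSum, resB$tmap@t[lone])

  # relabelling grid-point order leaves cluster p values unchanged
  perm <- sample(prod(dims))
  inv <- integer(length(perm)); inv[perm] <- seq_along(perm)
  adjPerm <- lapply(perm, function(i) inv[adj[[i]]])
  resP <- clusterPermutation(d[, perm], adjPerm, nPerm = 100, seed = 5)
  expect_equal(sort(resP$clusters$pCluster), sort(tabA$pCluster))
})

test_that("BH adjustment equals a hand-computed step-up on random inputs", {
  expect_equal(fdrAdjust(0.03)$adjusted, 0.03)
  expect_equal(fdrAdjust(c(0.01, 0.02, 0.03, 0.04))$adjusted, rep(0.04, 4))
  allOnes <- fdrAdjust(rep(1, 6))
  expect_equal(allOnes$adjusted, rep(1, 6))
  expect_length(allOnes$rejected, 0)
  expect_error(fdrAdjust(c(0.5, 1.2)), "invalid input")

  # brute-force step-up oracle
  stepUp <- function(p) {
    m <- length(p); o <- order(p)
    adj <- p[o] * m / seq_len(m)
    adj <- rev(cummin(rev(adj)))
    out <- numeric(m); out[o] <- pmin(adj, 1)
    out
  }
  set.seed(24)
  for (rep in 1:1000) {
    p <- runif(sample(1:12, 1))
    expect_equal(fdrAdjust(p)$adjusted, stepUp(p))
  }
})
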