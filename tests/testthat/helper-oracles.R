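# Independent brute-force oracles for the spatial estimators: plain
# double loops over points, written directly from the estimator
# definitions, deliberately sharing no code with the package internals.

bruteNNDist <- function(xyz) {
  n <- nrow(xyz)
  d <- numeric(n)
  for (i in seq_len(n)) {
    best <- Inf
    for (j in seq_len(n)) {
      if (i == j) next
      dij <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      if (dij < best) best <- dij
    }
    d[i] <- best
  }
  d
}

bruteBorderDist <- function(xyz, win) {
  apply(xyz, 1, function(p)
    min(p[1] - win@xrange[1], win@xrange[2] - p[1],
        p[2] - win@yrange[1], win@yrange[2] - p[2],
        p[3] - win@zrange[1], win@zrange[2] - p[3]))
}

bruteG <- function(xyz, win, r, correction = "border") {
  d <- bruteNNDist(xyz)
  b <- bruteBorderDist(xyz, win)
  sapply(r, function(ri) {
    if (correction == "border") {
      atRisk <- b >= ri
      if (!any(atRisk)) return(NA_real_)
      sum(d[atRisk] <= ri) / sum(atRisk)
    } else {
      mean(d <= ri)
    }
  })
}

bruteF <- function(xyz, win, r, m = 8L, correction = "border") {
  sides <- c(diff(win@xrange), diff(win@yrange), diff(win@zrange))
  lo <- c(win@xrange[1], win@yrange[1], win@zrange[1])
  u <- (seq_len(m) - 0.5) / m
  q <- as.matrix(expand.grid(lo[1] + u * sides[1], lo[2] + u * sides[2],
                             lo[3] + u * sides[3]))
  d <- apply(q, 1, function(p)
    min(sqrt(colSums((t(xyz) - p)^2))))
  b <- bruteBorderDist(q, win)
  sapply(r, function(ri) {
    if (correction == "border") {
      atRisk <- b >= ri
      if (!any(atRisk)) return(NA_real_)
      sum(d[atRisk] <= ri) / sum(atRisk)
    } else {
      mean(d <= ri)
    }
  })
}

bruteK <- function(xyz, win, r, correction = "translation") {
  n <- nrow(xyz)
  sides <- c(diff(win@xrange), diff(win@yrange), diff(win@zrange))
  V <- prod(sides)
  sapply(r, function(ri) {
    acc <- 0
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i == j) next
        dij <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
        if (dij <= ri) {
          if (correction == "translation") {
            ov <- prod(sides - abs(xyz[i, ] - xyz[j, ]))
            acc <- acc + V / ov
          } else {
            acc <- acc + 1
          }
        }
      }
    }
    V * acc / (n * (n - 1))
  })
}

# direct voxelization of a sphere for morphometry oracles
sphereStack <- function(radiusVox, voxNm = c(20, 20, 20), pad = 4L) {
  half <- ceiling(radiusVox) + pad
  n <- 2L * half
  a <- array(0L, dim = c(n, n, n))
  ctr <- half + 0.5
  for (z in seq_len(n)) {
    dz2 <- (z - ctr)^2
    sl <- outer((seq_len(n) - ctr)^2, (seq_len(n) - ctr)^2, "+") + dz2
    a[, , z][sl <= radiusVox^2] <- 1L
  }
  VoxelStack(labels = a,
             geometry = StackGeometry(c(n, n, n), voxelSize = voxNm))
}
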