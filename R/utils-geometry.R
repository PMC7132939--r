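# Internal geometry and RNG helpers shared across modules.

# side lengths of a box, um
.boxSides <- function(box) {
  c(diff(box@xrange), diff(box@yrange), diff(box@zrange))
}

.boxLower <- function(box) c(box@xrange[1], box@yrange[1], box@zrange[1])
.boxUpper <- function(box) c(box@xrange[2], box@yrange[2], box@zrange[2])

# logical vector: rows of xyz inside box (closed on all faces)
.insideBox <- function(xyz, box, tol = 0) {
  xyz[, 1] >= box@xrange[1] - tol & xyz[, 1] <= box@xrange[2] + tol &
  xyz[, 2] >= box@yrange[1] - tol & xyz[, 2] <= box@yrange[2] + tol &
  xyz[, 3] >= box@zrange[1] - tol & xyz[, 3] <= box@zrange[2] + tol
}

# distance from each point to the nearest face of the box
.borderDistance <- function(xyz, box) {
  pmin(xyz[, 1] - box@xrange[1], box@xrange[2] - xyz[, 1],
       xyz[, 2] - box@yrange[1], box@yrange[2] - xyz[, 2],
       xyz[, 3] - box@zrange[1], box@zrange[2] - xyz[, 3])
}

# grow a box by m on every face
.expandBox <- function(box, m) {
  Box3D(box@xrange + c(-m, m), box@yrange + c(-m, m), box@zrange + c(-m, m))
}

# squared Euclidean cross-distances between two point sets (BLAS based);
# a: n x 3, b: m x 3 -> n x m. Negative rounding residue clipped at 0.
.crossDist2 <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

# nearest-neighbour distance of every point within one set
.nnDistance <- function(xyz) {
  n <- nrow(xyz)
  if (n < 2L) return(rep(NA_real_, n))
  d2 <- .crossDist2(xyz, xyz)
  diag(d2) <- Inf
  sqrt(.rowMins(d2))
}

# row minima without apply(): pmin over columns (few hundred at most)
.rowMins <- function(m) {
  out <- m[, 1L]
  nc <- ncol(m)
  j <- 2L
  while (j <= nc) {
    out <- pmin(out, m[, j])
    j <- j + 1L
  }
  out
}

# distance from each query point to the nearest point of a target set
.nearestDistance <- function(query, target) {
  if (nrow(target) == 0L) return(rep(Inf, nrow(query)))
  # chunk queries so the cross matrix stays modest for large lattices
  n <- nrow(query)
  out <- numeric(n)
  step <- max(1L, floor(4e6 / max(1L, nrow(target))))
  i <- 1L
  while (i <= n) {
    j <- min(n, i + step - 1L)
    d2 <- .crossDist2(query[i:j, , drop = FALSE], target)
    out[i:j] <- sqrt(.rowMins(d2))
    i <- j + 1L
  }
  out
}

# deterministic child-seed derivation so multi-stack experiments are
# reproducible from one global seed; arithmetic in doubles (exact below
# 2^53), result kept below 2^31 - 1
.childSeed <- function(seed, k) {
  s <- as.numeric(seed) %% 2147483647
  as.integer((s * 48271 + 9973 * as.numeric(k)) %% 2147483629)
}

.checkSeed <- function(seed) {
  if (is.null(seed) || length(seed) != 1L || !is.finite(seed))
    stop("a single finite integer 'seed' is required", call. = FALSE)
  as.integer(seed)
}
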