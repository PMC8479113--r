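#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded generators do not
#' perturb the global stream.
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic quasi-uniform directions on the unit sphere
# (golden-angle spiral lattice) — seed-free by construction.
golden_spiral_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# Row-wise minimum of (|points - centers_j| - radius_j) over atoms j,
# computed in chunks with BLAS; points m x 3, centers n x 3.
nearest_clearance <- function(points, centers, radii, chunk = 20000L) {
  m <- nrow(points)
  out <- numeric(m)
  cn2 <- rowSums(centers^2)
  # group atoms by radius so the minimum can be taken on squared distances
  rgrp <- split(seq_len(nrow(centers)), radii)
  rvals <- as.numeric(names(rgrp))
  for (lo in seq(1L, m, by = chunk)) {
    hi <- min(lo + chunk - 1L, m)
    p <- points[lo:hi, , drop = FALSE]
    pn2 <- rowSums(p^2)
    best <- rep(Inf, hi - lo + 1L)
    for (gi in seq_along(rgrp)) {
      j <- rgrp[[gi]]
      d2 <- pn2 - 2 * tcrossprod(p, centers[j, , drop = FALSE])
      d2 <- sweep(d2, 2L, -cn2[j])
      mn <- .row_mins(d2)
      mn[mn < 0] <- 0
      best <- pmin(best, sqrt(mn) - rvals[gi])
    }
    out[lo:hi] <- best
  }
  out
}

# Row-wise minimum by pairwise folding (log2(ncol) pmin calls).
.row_mins <- function(m) {
  if (is.null(dim(m))) return(m)
  while (ncol(m) > 1L) {
    k <- ncol(m); h <- k %/% 2L
    m <- pmin(m[, seq_len(h), drop = FALSE],
              m[, k - h + seq_len(h), drop = FALSE])
  }
  m[, 1L]
}
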