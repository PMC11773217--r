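# Delaunay triangulation (Bowyer-Watson) and piecewise-linear barycentric
# interpolation over the triangulation. Used by interpolate_field() to turn
# scattered phonotaxis measurements into a gridded preference field: exact at
# the data points, continuous, and local (each value depends only on the
# enclosing triangle), with nearest-record extension outside the convex hull.

# circumcircle test: is q strictly inside the circumcircle of triangle (a,b,c)?
.circumcircle <- function(a, b, c) {
  ax <- a[1]; ay <- a[2]; bx <- b[1]; by <- b[2]; cx <- c[1]; cy <- c[2]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  if (abs(d) < 1e-14) return(NULL)  # degenerate (collinear) triangle
  ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
           (cx^2 + cy^2) * (ay - by)) / d
  uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
           (cx^2 + cy^2) * (bx - ax)) / d
  c(ux, uy, (ux - ax)^2 + (uy - ay)^2)  # centre and squared radius
}

# Bowyer-Watson incremental Delaunay triangulation.
# pts: n x 2 matrix (already de-duplicated). Returns m x 3 matrix of vertex
# indices, or errors if all points are collinear.
.delaunay_triangulate <- function(pts) {
  n <- nrow(pts)
  if (n < 3) stop("interpolation impossible: need at least 3 records")
  # scale coordinates to unit box for numerical robustness
  lo <- apply(pts, 2, min); hi <- apply(pts, 2, max)
  span <- max(hi - lo, 1e-12)
  p <- sweep(pts, 2, lo) / span
  # robust collinearity: max triangle area over a sample of triples
  amax <- 0
  for (i in 2:(n - 1)) {
    a2 <- abs((p[i, 1] - p[1, 1]) * (p[i + 1, 2] - p[1, 2]) -
                (p[i, 2] - p[1, 2]) * (p[i + 1, 1] - p[1, 1]))
    amax <- max(amax, a2)
  }
  if (amax < 1e-10) {
    # exhaustive check before giving up (sampled triples may be unlucky)
    ok <- FALSE
    for (i in 1:(n - 2)) {
      for (j in (i + 1):(n - 1)) {
        a2 <- abs((p[j, 1] - p[i, 1]) * (p[(j + 1):n, 2] - p[i, 2]) -
                    (p[j, 2] - p[i, 2]) * (p[(j + 1):n, 1] - p[i, 1]))
        if (any(a2 > 1e-10)) { ok <- TRUE; break }
      }
      if (ok) break
    }
    if (!ok) stop("interpolation impossible: records are collinear")
  }
  # super-triangle well outside the unit box
  P <- rbind(p, c(-20, -20), c(40, -20), c(0.5, 40))
  s1 <- n + 1; s2 <- n + 2; s3 <- n + 3
  tris <- list(c(s1, s2, s3))
  circ <- list(.circumcircle(P[s1, ], P[s2, ], P[s3, ]))
  for (i in seq_len(n)) {
    q <- P[i, ]
    bad <- vapply(circ, function(cc) {
      !is.null(cc) && ((q[1] - cc[1])^2 + (q[2] - cc[2])^2 < cc[3] * (1 + 1e-12) + 1e-14)
    }, logical(1))
    bad_idx <- which(bad)
    if (length(bad_idx) == 0) next  # cannot happen for points in the box
    edges <- do.call(rbind, lapply(tris[bad_idx], function(tr)
      rbind(tr[c(1, 2)], tr[c(2, 3)], tr[c(3, 1)])))
    ekey <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    keep <- ekey %in% names(which(table(ekey) == 1))
    boundary <- edges[keep, , drop = FALSE]
    tris <- tris[-bad_idx]
    circ <- circ[-bad_idx]
    for (k in seq_len(nrow(boundary))) {
      tr <- c(boundary[k, ], i)
      cc <- .circumcircle(P[tr[1], ], P[tr[2], ], P[tr[3], ])
      if (is.null(cc)) next  # skip degenerate sliver
      tris <- c(tris, list(tr))
      circ <- c(circ, list(cc))
    }
  }
  tris <- Filter(function(tr) all(tr <= n), tris)
  if (length(tris) == 0)
    stop("interpolation impossible: triangulation empty")
  do.call(rbind, tris)
}

# Piecewise-linear interpolation of values at scattered points, evaluated at
# query points. Queries outside the convex hull get NA (caller decides fill).
.delaunay_interp <- function(pts, values, queries) {
  tri <- .delaunay_triangulate(pts)
  out <- rep(NA_real_, nrow(queries))
  qx <- queries[, 1]; qy <- queries[, 2]
  unassigned <- rep(TRUE, nrow(queries))
  eps <- -1e-9 * max(abs(pts), 1)
  for (k in seq_len(nrow(tri))) {
    if (!any(unassigned)) break
    a <- pts[tri[k, 1], ]; b <- pts[tri[k, 2], ]; c3 <- pts[tri[k, 3], ]
    det <- (b[2] - c3[2]) * (a[1] - c3[1]) + (c3[1] - b[1]) * (a[2] - c3[2])
    if (abs(det) < 1e-12) next
    idx <- which(unassigned)
    l1 <- ((b[2] - c3[2]) * (qx[idx] - c3[1]) +
             (c3[1] - b[1]) * (qy[idx] - c3[2])) / det
    l2 <- ((c3[2] - a[2]) * (qx[idx] - c3[1]) +
             (a[1] - c3[1]) * (qy[idx] - c3[2])) / det
    l3 <- 1 - l1 - l2
    inside <- l1 >= eps & l2 >= eps & l3 >= eps
    if (!any(inside)) next
    hit <- idx[inside]
    out[hit] <- l1[inside] * values[tri[k, 1]] +
      l2[inside] * values[tri[k, 2]] +
      l3[inside] * values[tri[k, 3]]
    unassigned[hit] <- FALSE
  }
  out
}
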