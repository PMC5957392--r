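# Minimum enclosing circle (Welzl's algorithm, deterministic over the given
# point order). Points are reduced to their convex hull first, so the
# recursion stays shallow on raster patches.

.circle2 <- function(p, q) {
  ctr <- (p + q) / 2
  list(c = ctr, r = sqrt(sum((p - ctr)^2)))
}

.circle3 <- function(p, q, r) {
  ax <- p[1]; ay <- p[2]; bx <- q[1]; by <- q[2]; cx <- r[1]; cy <- r[2]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  if (abs(d) < 1e-12) {
    # collinear: fall back to the widest pair
    cands <- list(.circle2(p, q), .circle2(p, r), .circle2(q, r))
    return(cands[[which.max(vapply(cands, `[[`, numeric(1), "r"))]])
  }
  ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
    (cx^2 + cy^2) * (ay - by)) / d
  uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
    (cx^2 + cy^2) * (bx - ax)) / d
  ctr <- c(ux, uy)
  list(c = ctr, r = sqrt(sum((p - ctr)^2)))
}

.in_circle <- function(circ, p, tol = 1e-9) {
  sqrt(sum((p - circ$c)^2)) <= circ$r + tol
}

.welzl <- function(pts, boundary) {
  if (nrow(pts) == 0 || length(boundary) == 3) {
    if (length(boundary) == 0) {
      return(list(c = c(0, 0), r = 0))
    }
    if (length(boundary) == 1) {
      return(list(c = boundary[[1]], r = 0))
    }
    if (length(boundary) == 2) {
      return(.circle2(boundary[[1]], boundary[[2]]))
    }
    return(.circle3(boundary[[1]], boundary[[2]], boundary[[3]]))
  }
  p <- pts[nrow(pts), ]
  circ <- .welzl(pts[-nrow(pts), , drop = FALSE], boundary)
  if (.in_circle(circ, p)) {
    return(circ)
  }
  .welzl(pts[-nrow(pts), , drop = FALSE], c(boundary, list(p)))
}

.min_enclosing_circle <- function(pts) {
  pts <- unique(pts)
  if (nrow(pts) == 1) {
    return(list(c = pts[1, ], r = 0))
  }
  if (nrow(pts) > 3) {
    hull <- grDevices::chull(pts[, 1], pts[, 2])
    pts <- pts[hull, , drop = FALSE]
  }
  .welzl(pts, list())
}
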