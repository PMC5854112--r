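# Independent geometric oracles, implemented separately from the package
# internals they check.

# polygon area by ear-clipping triangulation (simple polygons, any size the
# tests use)
earclip_area <- function(x, y) {
  idx <- seq_along(x)
  # ensure counter-clockwise
  n <- length(x)
  j <- c(2:n, 1)
  if (sum(x * y[j] - x[j] * y) < 0) idx <- rev(idx)
  total <- 0
  guard <- 0
  while (length(idx) > 3) {
    n <- length(idx)
    clipped <- FALSE
    for (k in seq_len(n)) {
      a <- idx[k]
      b <- idx[if (k == n) 1 else k + 1]
      c_ <- idx[if (k >= n - 1) k - n + 2 else k + 2]
      cross <- (x[b] - x[a]) * (y[c_] - y[a]) - (y[b] - y[a]) * (x[c_] - x[a])
      if (cross <= 0) next
      others <- setdiff(idx, c(a, b, c_))
      if (length(others) > 0) {
        # any point inside candidate ear?
        s1 <- (x[b] - x[a]) * (y[others] - y[a]) - (y[b] - y[a]) * (x[others] - x[a])
        s2 <- (x[c_] - x[b]) * (y[others] - y[b]) - (y[c_] - y[b]) * (x[others] - x[b])
        s3 <- (x[a] - x[c_]) * (y[others] - y[c_]) - (y[a] - y[c_]) * (x[others] - x[c_])
        if (any(s1 > 0 & s2 > 0 & s3 > 0)) next
      }
      total <- total + cross / 2
      idx <- idx[-(if (k == n) 1 else k + 1)]
      clipped <- TRUE
      break
    }
    guard <- guard + 1
    if (!clipped || guard > 1e5) stop("ear clipping failed")
  }
  a <- idx[1]; b <- idx[2]; c_ <- idx[3]
  total + ((x[b] - x[a]) * (y[c_] - y[a]) - (y[b] - y[a]) * (x[c_] - x[a])) / 2
}

# convex hull by gift wrapping (Jarvis march); returns vertex indices in
# counter-clockwise order
gift_wrap <- function(x, y) {
  n <- length(x)
  start <- which.min(x + 1e-12 * y)
  hull <- start
  cur <- start
  repeat {
    cand <- setdiff(seq_len(n), cur)
    nxt <- cand[1]
    for (k in cand[-1]) {
      cross <- (x[nxt] - x[cur]) * (y[k] - y[cur]) -
               (y[nxt] - y[cur]) * (x[k] - x[cur])
      if (cross < 0 ||
          (cross == 0 &&
           (x[k] - x[cur])^2 + (y[k] - y[cur])^2 >
           (x[nxt] - x[cur])^2 + (y[nxt] - y[cur])^2)) {
        nxt <- k
      }
    }
    if (nxt == start) break
    hull <- c(hull, nxt)
    cur <- nxt
    if (length(hull) > n) stop("gift wrapping failed")
  }
  rev(hull)  # the march above walks clockwise; return counter-clockwise
}

hull_area_perimeter <- function(x, y) {
  h <- gift_wrap(x, y)
  xs <- x[h]; ys <- y[h]
  n <- length(xs)
  j <- c(2:n, 1)
  list(area = abs(sum(xs * ys[j] - xs[j] * ys) / 2),
       perimeter = sum(sqrt((xs[j] - xs)^2 + (ys[j] - ys)^2)))
}

circum_r <- function(ax, ay, bx, by, cx, cy) {
  la <- sqrt((bx - cx)^2 + (by - cy)^2)
  lb <- sqrt((ax - cx)^2 + (ay - cy)^2)
  lc <- sqrt((ax - bx)^2 + (ay - by)^2)
  K <- abs((bx - ax) * (cy - ay) - (by - ay) * (cx - ax)) / 2
  if (K == 0) return(Inf)
  la * lb * lc / (4 * K)
}

# brute-force alpha-shape area for small n: enumerate all triples, keep the
# Delaunay ones (empty circumcircle) with circumradius <= alpha, sum areas
brute_alpha_area <- function(x, y, alpha) {
  n <- length(x)
  total <- 0
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    K2 <- (x[j] - x[i]) * (y[k] - y[i]) - (y[j] - y[i]) * (x[k] - x[i])
    if (abs(K2) < 1e-12) next
    # circumcentre
    d <- 2 * (x[i] * (y[j] - y[k]) + x[j] * (y[k] - y[i]) + x[k] * (y[i] - y[j]))
    ux <- ((x[i]^2 + y[i]^2) * (y[j] - y[k]) + (x[j]^2 + y[j]^2) * (y[k] - y[i]) +
           (x[k]^2 + y[k]^2) * (y[i] - y[j])) / d
    uy <- ((x[i]^2 + y[i]^2) * (x[k] - x[j]) + (x[j]^2 + y[j]^2) * (x[i] - x[k]) +
           (x[k]^2 + y[k]^2) * (x[j] - x[i])) / d
    r <- sqrt((x[i] - ux)^2 + (y[i] - uy)^2)
    if (r > alpha) next
    others <- setdiff(seq_len(n), c(i, j, k))
    dd <- sqrt((x[others] - ux)^2 + (y[others] - uy)^2)
    if (any(dd < r * (1 - 1e-9))) next
    total <- total + abs(K2) / 2
  }
  total
}

rigid_motion <- function(df, angle, dx = 0, dy = 0) {
  data.frame(x = cos(angle) * df$x - sin(angle) * df$y + dx,
             y = sin(angle) * df$x + cos(angle) * df$y + dy)
}

regular_polygon <- function(n, r = 1) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  data.frame(x = r * cos(th), y = r * sin(th))
}
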