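# Fixtures built in code: small geometric curves and file writers used across
# the test files.

# Triadic Koch curve from (0,0) to (1,0); `levels` subdivision rounds give
# 4^levels + 1 vertices and theoretical dimension log(4)/log(3).
koch_curve <- function(levels) {
  pts <- matrix(c(0, 0, 1, 0), 2, 2, byrow = TRUE)
  rot60 <- matrix(c(cos(pi / 3), sin(pi / 3), -sin(pi / 3), cos(pi / 3)), 2, 2)
  for (l in seq_len(levels)) {
    out <- vector("list", nrow(pts) - 1)
    for (i in seq_len(nrow(pts) - 1)) {
      a <- pts[i, ]; d <- (pts[i + 1, ] - a) / 3
      p1 <- a + d
      p2 <- p1 + as.vector(rot60 %*% d)
      out[[i]] <- rbind(a, p1, p2, a + 2 * d)
    }
    pts <- rbind(do.call(rbind, out), pts[nrow(pts), ])
  }
  unname(pts)
}

# Rigid motion: rotate by theta and translate by shift.
rigid <- function(xy, theta = 0, shift = c(0, 0)) {
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  sweep(xy %*% R, 2, -shift)
}

write_tps_fixture <- function(curves, path) {
  lines <- unlist(lapply(curves, function(cv) {
    c(paste0("LM=", cv$n_points),
      apply(cv$coords, 1, function(p) paste(p[1], p[2])),
      paste0("ID=", cv$specimen_id))
  }))
  writeLines(lines, path)
  path
}

# Dense semicircle of radius r (arc length pi*r, chord 2r).
semicircle <- function(n = 500, r = 1) {
  th <- seq(0, pi, length.out = n)
  cbind(r * cos(th), r * sin(th))
}

expect_equal_tol <- function(object, expected, tol) {
  expect_true(max(abs(object - expected)) < tol)
}
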