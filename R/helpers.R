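# internal geometry helpers shared by builder and analysis code

`%||%` <- function(a, b) if (is.null(a)) b else a

vec_norm <- function(v) sqrt(sum(v * v))

unit_vec <- function(v) {
  n <- vec_norm(v)
  if (n < 1e-12) stop("cannot normalize a zero vector")
  v / n
}

# minimum-image displacement(s) r_i - r_j in a rectangular box.
# a, b: matrices (n x 3) or vectors; box: length-3 edge vector.
min_image <- function(d, box) {
  if (is.null(dim(d))) {
    d - box * round(d / box)
  } else {
    d - sweep(round(sweep(d, 2, box, "/")), 2, box, "*")
  }
}

# place atom D given positions of A, B, C plus bond length |CD|, angle
# B-C-D (deg) and dihedral A-B-C-D (deg). Standard internal-coordinate
# (NERF) construction used by the toy-solute builders.
place_atom <- function(a, b, c, bond, angle, dihedral) {
  ang <- angle * pi / 180
  dih <- dihedral * pi / 180
  bc <- unit_vec(c - b)
  n <- unit_vec(pracma_cross(b - a, bc))
  m <- pracma_cross(n, bc)
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(dih), bond * sin(ang) * sin(dih))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# deterministic quasi-uniform points on the unit sphere (golden-spiral),
# used by the SASA sampler and by water-orientation draws.
sphere_points <- function(n) {
  k <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * k / n)
  theta <- pi * (1 + sqrt(5)) * k
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# random rotation matrix from a seed-controlled RNG stream
random_rotation <- function() {
  repeat {
    q <- rnorm(4)
    nq <- vec_norm(q)
    if (nq > 1e-8) break
  }
  q <- q / nq
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

stopifnot_scalar_pos <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0)
    stop(sprintf("%s must be a single positive number", what), call. = FALSE)
}
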