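# Shared fixture builders; everything is generated in code at test time.

# uniform reflectance image with animal/background masks (left/right halves)
uniform_image <- function(rgb = c(0.2, 0.4, 0.6), h = 8, w = 8,
                          px_per_mm = 20) {
  px <- array(0, dim = c(h, w, 3))
  for (k in 1:3) px[, , k] <- rgb[k]
  left <- matrix(FALSE, h, w); left[, 1:(w %/% 2)] <- TRUE
  reflectance_image(px, px_per_mm,
                    masks = list(animal = left, background = !left))
}

# horizontal sinusoid in R and G around a mean (B constant)
sinusoid_image <- function(wavelength = 16, size = 256, mean_rgb = c(0.5, 0.5, 0.5),
                           amplitude = 0.2, px_per_mm = 20) {
  ph <- outer(rep(1, size), seq_len(size))
  field <- amplitude * sin(2 * pi * ph / wavelength)
  px <- array(0, dim = c(size, size, 3))
  px[, , 1] <- mean_rgb[1] + field
  px[, , 2] <- mean_rgb[2] + field
  px[, , 3] <- mean_rgb[3]
  reflectance_image(px, px_per_mm,
                    masks = list(animal = matrix(TRUE, size, size)))
}

# random bifurcating ultrametric tree with positive branch lengths
random_tree <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rcoal(n)
  tr$edge.length <- tr$edge.length / max(ape::node.depth.edgelength(tr))
  tr
}

# brute-force GLS via explicit matrix inverses (independent oracle)
gls_brute <- function(X, y, V) {
  Vi <- solve(V)
  solve(t(X) %*% Vi %*% X) %*% t(X) %*% Vi %*% y
}

# brute-force through-origin MA slope: minimize perpendicular SS over the
# line angle (independent oracle for the closed-form slope)
ma_brute <- function(u, v) {
  ss <- function(theta) {
    b <- tan(theta)
    sum((v - b * u)^2 / (1 + b^2))
  }
  grid <- seq(-pi / 2 + 1e-6, pi / 2 - 1e-6, length.out = 2001)
  th0 <- grid[which.min(vapply(grid, ss, numeric(1)))]
  opt <- stats::optimize(ss, c(th0 - 0.01, th0 + 0.01), tol = 1e-14)
  tan(opt$minimum)
}
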