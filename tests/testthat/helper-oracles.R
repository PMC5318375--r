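# Shared oracles and generators for the test suite.

# an ensemble realizing given stability parameters (a, b, c):
# x1 = (1, 0) unit, x2 = (b, sqrt(a - b^2)), rho = c / (1 + c)
ensemble_from_abc <- function(a, b, cc) {
  stimulus_ensemble(list(c(1, 0), c(b, sqrt(a - b^2))),
                    probs = c(cc / (1 + cc), 1 / (1 + cc)))
}

# random admissible (a, b, c) draw
random_abc <- function() {
  a <- stats::runif(1, 0.4, 3)
  b <- stats::runif(1, -0.95, 0.95) * sqrt(a)
  cc <- stats::runif(1, 0.2, 4)
  list(a = a, b = b, c = cc)
}

# characteristic coefficients (A0, A1, A2) of a 3x3 matrix:
# p(l) = l^3 + A2 l^2 + A1 l + A0
charpoly3 <- function(J) {
  c(A0 = -det(J),
    A1 = det(J[1:2, 1:2]) + det(J[c(1, 3), c(1, 3)]) + det(J[2:3, 2:3]),
    A2 = -sum(diag(J)))
}

# analytic Jacobian of the averaged equations at z1 = (1/rho, 0, 1/rho)
# (normalization |x1| = 1, tau_w = 1; k = (1-rho)/rho)
analytic_J_z1 <- function(a, b, cc, tau) {
  k <- 1 / cc
  matrix(c(1, b, 2 / tau,
           -b * k, -a * k, 0,
           -1, -b, -1 / tau), 3, 3)
}

# maximum real part of the eigenvalues of the numeric Jacobian
max_re_eig <- function(rhs, y) {
  max(Re(eigen(numeric_jacobian(rhs, y), only.values = TRUE)$values))
}

# rotation matrix in the plane
rot2 <- function(phi) matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2, 2)

# RMS distance between two matrices of states sampled at common times
rms_dist <- function(A, B) sqrt(mean(rowSums((A - B)^2)))

# hybrid responses interpolated onto a regular grid (v columns + theta)
hybrid_on_grid <- function(tr, tgrid) {
  V <- cbind(tr$v, tr$theta)
  out <- sapply(seq_len(ncol(V)), function(j)
    stats::approx(tr$t, V[, j], xout = tgrid, rule = 2)$y)
  out
}
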