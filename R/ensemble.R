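#' Stimulus ensembles
#'
#' A stimulus ensemble is a finite set of input patterns \eqn{x^{(k)} \in
#' R^n} together with the probabilities \eqn{p_k} with which they are
#' presented to the neuron. The averaged response-space dynamics depend on
#' the ensemble only through the Gram matrix of pairwise inner products and
#' the probabilities, so the ensemble object precomputes and carries both.
#'
#' @param vectors stimulus patterns: a list of numeric vectors of common
#'   dimension, or a numeric matrix with one stimulus per row.
#' @param probs presentation probabilities, one per stimulus, summing to 1.
#'   Defaults to the uniform distribution.
#' @return An object of class `"bcm_ensemble"`: a list with elements `X`
#'   (the m-by-n stimulus matrix), `probs`, `gram` (the m-by-m Gram matrix),
#'   `m` and `n`.
#' @examples
#' stimulus_ensemble(list(c(1, 0), c(cos(1), sin(1))))
#' @export
stimulus_ensemble <- function(vectors, probs = NULL) {
  if (is.matrix(vectors)) {
    X <- vectors
  } else {
    lens <- lengths(vectors)
    if (length(unique(lens)) != 1L)
      stop("all stimulus vectors must have the same dimension")
    X <- do.call(rbind, lapply(vectors, as.numeric))
  }
  if (!is.numeric(X) || any(!is.finite(X)))
    stop("stimulus vectors must be finite numeric")
  m <- nrow(X)
  if (is.null(probs)) probs <- rep(1 / m, m)
  probs <- as.numeric(probs)
  if (length(probs) != m)
    stop("need one probability per stimulus (", m, "), got ", length(probs))
  if (any(probs <= 0) || any(probs > 1) || abs(sum(probs) - 1) > 1e-8)
    stop("probs must lie in (0, 1] and sum to 1")
  structure(
    list(X = X, probs = probs, gram = gram_matrix(X), m = m, n = ncol(X)),
    class = "bcm_ensemble"
  )
}

#' Gram matrix of a stimulus set
#'
#' Entry (k, l) is the inner product \eqn{x^{(k)} \cdot x^{(l)}}. The
#' response-space mean field depends on the stimuli only through this matrix,
#' so a common rotation of all stimuli leaves the dynamics unchanged.
#'
#' @param x a `bcm_ensemble`, a stimulus matrix (one stimulus per row), or a
#'   list of stimulus vectors.
#' @return A symmetric positive semidefinite m-by-m matrix.
#' @export
gram_matrix <- function(x) {
  if (inherits(x, "bcm_ensemble")) return(x$gram)
  if (!is.matrix(x)) {
    if (length(unique(lengths(x))) != 1L)
      stop("all stimulus vectors must have the same dimension")
    x <- do.call(rbind, lapply(x, as.numeric))
  }
  tcrossprod(x)
}

#' Conserved linear functionals when stimuli outnumber weights
#'
#' With m stimuli of dimension n < m, the response vector v = Xw is confined
#' to an n-dimensional subspace: any q with \eqn{q^T X = 0} gives a conserved
#' quantity \eqn{q \cdot v(t) = const} along the averaged dynamics. This
#' returns an orthonormal basis of that null space (m - n vectors for X of
#' full column rank; none when m = n).
#'
#' @param X stimulus matrix (m rows of dimension n) or a `bcm_ensemble`.
#' @return An m-by-(m-n) matrix whose columns are orthonormal vectors q with
#'   `t(q) %*% X = 0`; zero columns when m = n.
#' @export
conserved_basis <- function(X) {
  if (inherits(X, "bcm_ensemble")) X <- X$X
  m <- nrow(X); n <- ncol(X)
  if (m < n) stop("need at least as many stimuli as weights (m >= n)")
  sv <- svd(X, nu = m, nv = n)
  rank <- sum(sv$d > max(dim(X)) * max(sv$d) * .Machine$double.eps)
  if (rank < n)
    stop("stimulus matrix is rank deficient (rank ", rank, " < n = ", n,
         "); conserved directions are not well defined")
  sv$u[, seq_len(m - n) + n, drop = FALSE]
}

#' Reduced parameters of a two-stimulus ensemble
#'
#' The stability theory of the two-stimulus mean field uses only three
#' numbers: `a` (squared norm of the second stimulus), `b` (inner product of
#' the two stimuli) and `c` = rho/(1-rho). The first stimulus is assumed to
#' be a unit vector, which can always be arranged by rescaling time.
#'
#' @param a squared norm of the second stimulus; must exceed `b^2`.
#' @param b inner product of the two stimuli.
#' @param c probability ratio rho/(1-rho), positive.
#' @return A list of class `"bcm_two_stimulus_params"`.
#' @export
two_stimulus_params <- function(a, b, c) {
  stopifnot(is.numeric(a), is.numeric(b), is.numeric(c))
  if (c <= 0) stop("c = rho/(1-rho) must be positive")
  if (a <= b^2)
    stop("need a > b^2 (stimuli must not be collinear; Schwartz inequality)")
  structure(list(a = a, b = b, c = c), class = "bcm_two_stimulus_params")
}

#' @export
print.bcm_ensemble <- function(x, ...) {
  cat("BCM stimulus ensemble: m =", x$m, "stimuli of dimension n =", x$n, "\n")
  cat("probs:", format(x$probs, digits = 4), "\n")
  cat("gram matrix:\n")
  print(round(x$gram, 6))
  invisible(x)
}
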