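#' Leroux conditional autoregressive precision structure
#'
#' Builds the precision matrix of the Leroux CAR prior shared by the three
#' discrete-area models. With a binary adjacency matrix `W`, the structure
#' matrix is
#' \deqn{Q(W) = \rho\,(\mathrm{diag}(W\mathbf{1}) - W) + (1-\rho)\,I,}
#' and the areal random effects have \eqn{\phi \sim N(0, \sigma^2_\phi
#' Q^{-1})}. \eqn{\rho = 0} gives independent effects; \eqn{\rho = 1} gives
#' the intrinsic CAR (graph Laplacian, singular on a connected graph).
#'
#' @param W Symmetric binary adjacency matrix with zero diagonal.
#' @param rho Spatial autocorrelation parameter in \[0, 1\].
#' @param sigma2_phi Variance \eqn{\sigma^2_\phi > 0}. If supplied, the
#'   returned matrix is the joint precision \eqn{\sigma^{-2}_\phi Q(W)};
#'   otherwise the structure matrix \eqn{Q(W)} alone.
#' @return A sparse symmetric matrix (class `dsCMatrix`).
#' @export
leroux_precision <- function(W, rho, sigma2_phi = NULL) {
  W <- check_adjacency(W)
  if (!is.numeric(rho) || length(rho) != 1 || rho < 0 || rho > 1)
    stop("rho must be a single value in [0, 1]", call. = FALSE)
  n <- nrow(W)
  L <- diag(rowSums(W)) - W            # graph Laplacian
  Q <- rho * L + (1 - rho) * diag(n)
  if (!is.null(sigma2_phi)) {
    if (sigma2_phi <= 0) stop("sigma2_phi must be > 0", call. = FALSE)
    Q <- Q / sigma2_phi
  }
  methods::as(methods::as(Matrix::Matrix(Q, sparse = TRUE), "symmetricMatrix"),
              "CsparseMatrix")
}

check_adjacency <- function(W) {
  W <- as.matrix(W)
  if (nrow(W) != ncol(W)) stop("adjacency matrix must be square", call. = FALSE)
  if (any(W != t(W))) stop("adjacency matrix must be symmetric", call. = FALSE)
  if (any(diag(W) != 0)) stop("adjacency matrix must have zero diagonal", call. = FALSE)
  if (!all(W %in% c(0, 1))) stop("adjacency entries must be 0/1", call. = FALSE)
  ncomp <- n_components(W)
  if (ncomp > 1)
    warning(sprintf("adjacency graph has %d connected components; districts in different components decouple as rho -> 1", ncomp))
  W
}

n_components <- function(W) {
  n <- nrow(W)
  seen <- rep(FALSE, n)
  ncomp <- 0
  for (i in seq_len(n)) {
    if (seen[i]) next
    ncomp <- ncomp + 1
    queue <- i
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (seen[v]) next
      seen[v] <- TRUE
      queue <- c(queue, which(W[v, ] > 0 & !seen))
    }
  }
  ncomp
}

#' Sample areal effects from the Leroux prior
#'
#' Draws \eqn{\phi \sim N(0, \sigma^2_\phi Q(W)^{-1})} by solving the
#' Cholesky factor of \eqn{Q} against white noise. Requires \eqn{\rho < 1}
#' (the intrinsic model is improper).
#'
#' @inheritParams leroux_precision
#' @param n_samples Number of draws.
#' @param seed Integer seed.
#' @return Matrix `n_samples x n` of draws.
#' @export
sample_leroux <- function(W, rho, sigma2_phi = 1, n_samples = 1, seed = NULL) {
  if (rho >= 1)
    stop("rho must be < 1 to sample (rho = 1 gives a singular, improper prior)",
         call. = FALSE)
  Q <- as.matrix(leroux_precision(W, rho))
  n <- nrow(Q)
  R <- chol(Q)                           # Q = R'R
  if (!is.null(seed)) set.seed(seed)
  z <- matrix(stats::rnorm(n_samples * n), n, n_samples)
  ## phi = sqrt(sigma2) * R^{-1} z  has covariance  sigma2 * Q^{-1}
  t(backsolve(R, z)) * sqrt(sigma2_phi)
}

## log N(phi; 0, (tau Q(rho))^{-1}) up to constants, with logdet
leroux_logdens <- function(phi, W_lap, rho, tau) {
  n <- length(phi)
  Q <- rho * W_lap + (1 - rho) * diag(n)
  R <- tryCatch(chol(Q), error = function(e) NULL)
  if (is.null(R)) return(-Inf)
  logdet_Q <- 2 * sum(log(diag(R)))
  0.5 * n * log(tau) + 0.5 * logdet_Q - 0.5 * tau * sum((R %*% phi)^2)
}
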