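#' Dirichlet eigenvalues of the unit ball
#'
#' Reference spectrum used by the F3 descriptor. The Dirichlet eigenvalues
#' of the unit ball are the squared positive zeros of the spherical Bessel
#' functions j_l (equivalently of J_{l+1/2}), each with multiplicity 2l+1.
#' Zeros are located by a sign-change scan of \code{besselJ} refined with
#' \code{uniroot}, so the reference is analytic, not a digitized sphere.
#' The first value is pi^2 (zero of j_0 at pi). Results are cached for the
#' session.
#'
#' @param n number of eigenvalues (counting multiplicity), ascending.
#' @return numeric vector d_1 <= ... <= d_n with d_1 = pi^2.
#' @export
sphere_reference_spectrum <- function(n = 100L) {
  cache <- get("sphere_spectrum_cache", envir = .shapetriad_env)
  if (length(cache) >= n) return(cache[seq_len(n)])
  # l_max such that even the first zero of j_l exceeds what we need:
  # first zero of J_{l+1/2} is > l, and we need roughly sqrt(d_n) <= some x;
  # grow l until the first zero alone is beyond the current n-th candidate.
  ev <- numeric(0)
  l <- 0L
  repeat {
    zs <- bessel_j_zeros(l + 0.5, n_zeros = ceiling(n / (2 * l + 1)) + 2L)
    ev <- c(ev, rep(zs^2, each = 2L * l + 1L))
    ev <- sort(ev)
    # stop once the first zero of the next order cannot enter the first n:
    # J_{nu} first zero >= nu, so (l+1.5)^2 > ev[n] suffices
    if (length(ev) >= n && (l + 1.5)^2 > ev[n]) break
    l <- l + 1L
  }
  ev <- sort(ev)
  assign("sphere_spectrum_cache", ev, envir = .shapetriad_env)
  ev[seq_len(n)]
}

# first n_zeros positive zeros of J_nu via sign-change scan + uniroot
bessel_j_zeros <- function(nu, n_zeros) {
  f <- function(x) besselJ(x, nu)
  # zeros of J_nu are spaced ~pi apart beyond the first (which is > nu)
  upper <- nu + (n_zeros + 2) * pi + 10
  xs <- seq(max(nu * 0.5, 0.1), upper, by = 0.05)
  v <- f(xs)
  sc <- which(v[-1] * v[-length(v)] < 0)
  zs <- numeric(0)
  for (i in sc) {
    zs <- c(zs, stats::uniroot(f, c(xs[i], xs[i + 1]), tol = 1e-14)$root)
    if (length(zs) >= n_zeros) break
  }
  if (length(zs) < n_zeros) stop("failed to bracket enough Bessel zeros")
  zs
}

.shapetriad_env <- new.env(parent = emptyenv())
assign("sphere_spectrum_cache", numeric(0), envir = .shapetriad_env)

#' Pose- and scale-invariant spectral shape features
#'
#' Builds one of the three eigenvalue-ratio descriptor families from an
#' ascending Dirichlet spectrum. All three are invariant to translation and
#' rotation of the domain (the spectrum is) and to uniform scaling (ratios
#' cancel the 1/s^2 scaling of eigenvalues):
#' \itemize{
#'   \item F1: lambda_1/lambda_i for i = 2..n, in (0, 1].
#'   \item F2: lambda_{i-1}/lambda_i for i = 2..n, in (0, 1] (the default
#'     family, with n = 100).
#'   \item F3: lambda_1/lambda_i - d_1/d_i for i = 2..n, in [-1, 1], where
#'     d_i is the unit-ball reference spectrum; F3 measures deviation of the
#'     shape from a sphere and vanishes identically for a ball.
#' }
#'
#' @param eigenvalues ascending positive eigenvalues, length >= n.
#' @param family one of "F1", "F2", "F3".
#' @param n number of eigenvalues used (default 100); the descriptor has
#'   length n - 1.
#' @return named numeric vector (f_001, f_002, ...) of length n - 1.
#' @export
invariant_features <- function(eigenvalues, family = c("F2", "F1", "F3"),
                               n = 100L) {
  family <- match.arg(family)
  if (length(eigenvalues) < n)
    stop("need at least n = ", n, " eigenvalues, got ", length(eigenvalues))
  lam <- as.numeric(eigenvalues[seq_len(n)])
  if (any(lam <= 0)) stop("eigenvalues must be strictly positive")
  if (is.unsorted(lam)) stop("eigenvalues must be ascending")
  f <- switch(family,
              F1 = lam[1] / lam[2:n],
              F2 = lam[1:(n - 1)] / lam[2:n],
              F3 = lam[1] / lam[2:n] -
                {d <- sphere_reference_spectrum(n); d[1] / d[2:n]})
  names(f) <- sprintf("f_%03d", seq_len(n - 1L))
  f
}

#' Spectral shape descriptor of a binary mask
#'
#' End-to-end extractor: assembles the Dirichlet Laplacian of the mask's
#' largest connected component, computes its n smallest eigenvalues and
#' derives the requested invariant family.
#'
#' @param mask a \code{\link{binary_mask}}.
#' @param n number of eigenvalues (default 100).
#' @param family descriptor family, see \code{\link{invariant_features}}.
#' @param ... further arguments to \code{\link{compute_eigenvalues}}.
#' @return object of class \code{spectral_descriptor}: list with
#'   \code{eigenvalues}, \code{n}, \code{family}, \code{features}.
#' @export
spectral_descriptor <- function(mask, n = 100L, family = "F2", ...) {
  L <- assemble_dirichlet_laplacian(mask)
  lam <- compute_eigenvalues(L$operator, n = n, ...)
  structure(list(eigenvalues = as.numeric(lam), n = n, family = family,
                 features = invariant_features(lam, family = family, n = n),
                 n_voxels = L$n_voxels),
            class = "spectral_descriptor")
}

#' @method print spectral_descriptor
#' @export
print.spectral_descriptor <- function(x, ...) {
  cat(sprintf(paste0("spectral_descriptor: %s on %d eigenvalues ",
                     "(%d voxels), lambda_1 = %.4g mm^-2\n"),
              x$family, x$n, x$n_voxels, x$eigenvalues[1]))
  invisible(x)
}
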