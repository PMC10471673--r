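## Spatial and age discretization.
##
## Space: uniform finite-difference grids on an interval [0, L] or a
## rectangle [0, L1] x [0, L2]. Neumann grids are cell-centered with a
## ghost-node reflection closure (second order); Dirichlet grids eliminate
## the boundary nodes. Age: uniform nodes 0 = a_0 < ... < a_K = a_m.

#' Spatial grid
#'
#' @param nx number of active nodes per dimension (one or two integers).
#' @param L domain extent per dimension.
#' @param delta boundary flag: 0 = Dirichlet, 1 = Neumann.
#' @return A `space_grid` object with node coordinates `X` (matrix, one row
#'   per node), spacings `dx`, quadrature weights `w` (approximating the
#'   L2 inner product), and total node count `nx`.
#' @export
space_grid <- function(nx, L = 1, delta = 1) {
  if (!delta %in% c(0, 1)) stop("delta must be 0 or 1")
  nx <- as.integer(nx)
  if (length(nx) != length(L) || !length(nx) %in% 1:2) {
    stop("nx and L must both have length 1 (interval) or 2 (rectangle)")
  }
  if (any(nx < 3L)) stop("need at least 3 nodes per dimension")
  axes <- lapply(seq_along(nx), function(i) {
    if (delta == 1) {
      h <- L[i] / nx[i]
      list(x = (seq_len(nx[i]) - 0.5) * h, h = h)
    } else {
      h <- L[i] / (nx[i] + 1)
      list(x = seq_len(nx[i]) * h, h = h)
    }
  })
  if (length(nx) == 1L) {
    X <- cbind(axes[[1]]$x)
  } else {
    X <- as.matrix(expand.grid(axes[[1]]$x, axes[[2]]$x))
  }
  colnames(X) <- NULL
  dx <- vapply(axes, `[[`, 0, "h")
  structure(
    list(dim = length(nx), n_axis = nx, nx = prod(nx), L = L, delta = delta,
         X = X, dx = dx, w = rep(prod(dx), prod(nx))),
    class = "space_grid")
}

#' Age grid
#'
#' Uniform discretization of the infection-age interval \[0, a_m\] with
#' `K + 1` nodes; the simulator's time step is tied to the spacing `da`.
#'
#' @param a_m maximal infection age.
#' @param K number of age cells (at least 2).
#' @return An `age_grid` object with nodes `a`, spacing `da` and trapezoid
#'   quadrature weights `wa`.
#' @export
age_grid <- function(a_m, K) {
  stop_if_not_scalar_pos(a_m, "a_m")
  K <- as.integer(K)
  if (K < 2L) stop("K must be at least 2")
  a <- seq(0, a_m, length.out = K + 1L)
  structure(list(a = a, K = K, da = a_m / K, a_m = a_m,
                 wa = trapz_weights(K + 1L, a_m / K)),
            class = "age_grid")
}

#' Build the grid pair for a parameter set
#'
#' @param params a [model_params()] object.
#' @param nx spatial nodes per dimension.
#' @param K age cells.
#' @return A list with components `space` and `age`.
#' @export
model_grids <- function(params, nx = 101L, K = 100L) {
  list(space = space_grid(nx, L = params$L, delta = params$delta),
       age = age_grid(params$a_m, K))
}

lap1d <- function(n, h, delta) {
  main <- rep(-2, n)
  if (delta == 1) main[c(1L, n)] <- -1   # ghost-node reflection closure
  Matrix::bandSparse(n, n, k = c(-1L, 0L, 1L),
                     diagonals = list(rep(1, n - 1L), main, rep(1, n - 1L)),
                     symmetric = FALSE) / h^2
}

#' Discrete Laplacian
#'
#' Second-order central-difference Laplacian `L_h` of the grid, with the
#' grid's boundary closure: Neumann by ghost-node reflection (every row sums
#' to zero, so constants are in the kernel), Dirichlet by elimination of the
#' homogeneous boundary values. The matrix is symmetric and `-L_h` is
#' positive semidefinite (definite for Dirichlet). Rectangles are assembled
#' as Kronecker sums of the one-dimensional operators.
#'
#' @param grid a [space_grid()].
#' @return A sparse symmetric matrix of dimension `grid$nx`.
#' @export
laplacian_matrix <- function(grid) {
  stopifnot(inherits(grid, "space_grid"))
  L1 <- lap1d(grid$n_axis[1], grid$dx[1], grid$delta)
  if (grid$dim == 1L) {
    Lh <- L1
  } else {
    L2 <- lap1d(grid$n_axis[2], grid$dx[2], grid$delta)
    I1 <- Matrix::Diagonal(grid$n_axis[1])
    I2 <- Matrix::Diagonal(grid$n_axis[2])
    ## expand.grid varies the first axis fastest
    Lh <- Matrix::kronecker(I2, L1) + Matrix::kronecker(L2, I1)
  }
  methods::as(Lh, "symmetricMatrix")
}

#' Eigenpairs of the negative Laplacian
#'
#' Eigenvalues `mu_0 <= mu_1 <= ...` of `-L_h` with eigenvectors
#' orthonormal in the grid inner product. Under Neumann conditions
#' `mu_0 = 0` with a constant eigenvector; under Dirichlet conditions
#' `mu_0 > 0`.
#'
#' @param grid a [space_grid()].
#' @param count number of eigenpairs requested (at most `grid$nx`).
#' @return List with `values` (increasing) and `vectors` (columns).
#' @export
laplacian_eigenpairs <- function(grid, count = grid$nx) {
  if (count > grid$nx) stop("count exceeds the number of grid nodes")
  e <- eigen(-as.matrix(laplacian_matrix(grid)), symmetric = TRUE)
  idx <- rev(seq_len(grid$nx))[seq_len(count)]
  vals <- e$values[idx]
  vecs <- e$vectors[, idx, drop = FALSE] / sqrt(grid$w[1])
  ## fix a sign convention: principal component nonnegative on average
  s <- sign(colSums(vecs)); s[s == 0] <- 1
  list(values = vals, vectors = sweep(vecs, 2L, s, `*`))
}

#' Principal eigenvalue of -Laplacian + potential
#'
#' Smallest eigenvalue `lambda_0(q)` of `-L_h + diag(q)` under the grid's
#' boundary condition. It is simple, the associated eigenvector can be
#' chosen strictly positive (Perron root of a shifted M-matrix), the map
#' `q -> lambda_0(q)` is strictly monotone, and `lambda_0(0) = mu_0`.
#'
#' @param grid a [space_grid()].
#' @param q potential, a scalar or a vector over grid nodes.
#' @return List with `value` (the eigenvalue) and `vector` (positive
#'   eigenvector, normalized in the grid inner product).
#' @export
principal_eigenvalue <- function(grid, q = 0) {
  if (length(q) == 1L) q <- rep(q, grid$nx)
  if (length(q) != grid$nx) stop("q must match the number of grid nodes")
  A <- -as.matrix(laplacian_matrix(grid)) + diag(q, grid$nx)
  e <- eigen(A, symmetric = TRUE)
  v <- e$vectors[, grid$nx]
  if (sum(v) < 0) v <- -v
  if (min(v) < -1e-8 * max(abs(v))) {
    warning("principal eigenvector is not numerically positive")
  }
  v <- pmax(v, 0)
  v <- v / grid_norm2(v, grid$w)
  list(value = e$values[grid$nx], vector = v)
}
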