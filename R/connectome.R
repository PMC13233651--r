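#' Sparse global connectome with tract-length delays
#'
#' Container for the long-range coupling structure among field nodes:
#' nonnegative connection weights, tract lengths (mm) on the same sparsity
#' pattern, and the derived conduction delays (ms) `length / speed`.
#'
#' @param weights sparse (or dense) nonnegative square matrix; entry
#'   `weights[i, j]` is the strength of the projection from node `j` onto
#'   node `i`. The diagonal must be zero.
#' @param tract_lengths matrix of tract lengths (mm) on the same sparsity
#'   pattern as `weights`.
#' @param conduction_speed scalar conduction speed in mm/ms (default 3).
#' @return an object of class `sparse_connectome` with elements `weights`,
#'   `tract_lengths`, `delays` (`dgCMatrix`) and `conduction_speed`.
#' @export
sparse_connectome <- function(weights, tract_lengths, conduction_speed = 3) {
  w <- methods::as(Matrix::drop0(Matrix::Matrix(weights, sparse = TRUE)), "generalMatrix")
  l <- methods::as(Matrix::Matrix(tract_lengths, sparse = TRUE), "generalMatrix")
  if (!isTRUE(all.equal(dim(w), dim(l))) || nrow(w) != ncol(w))
    stop("weights and tract_lengths must be square matrices of equal size")
  if (any(w@x < 0)) stop("weights must be nonnegative")
  if (any(Matrix::diag(w) != 0)) stop("weights must have a zero diagonal")
  if (!(conduction_speed > 0)) stop("conduction_speed must be > 0")
  if (any(l[w == 0] != 0))
    stop("tract_lengths has entries outside the sparsity pattern of weights")
  # lengths and delays on exactly the weight pattern (explicit zeros kept)
  wT <- methods::as(w, "TsparseMatrix")
  lv <- l[cbind(wT@i + 1L, wT@j + 1L)]
  if (any(lv < 0)) stop("tract lengths must be nonnegative")
  ln <- Matrix::sparseMatrix(i = wT@i + 1L, j = wT@j + 1L, x = lv,
                             dims = dim(w))
  dl <- Matrix::sparseMatrix(i = wT@i + 1L, j = wT@j + 1L,
                             x = lv / conduction_speed, dims = dim(w))
  structure(list(
    weights = w,
    tract_lengths = ln,
    delays = dl,
    conduction_speed = conduction_speed
  ), class = "sparse_connectome")
}

#' @export
print.sparse_connectome <- function(x, ...) {
  cat("<sparse_connectome> ", nrow(x$weights), " nodes, ",
      length(x$weights@x), " connections, speed ",
      x$conduction_speed, " mm/ms\n", sep = "")
  invisible(x)
}

#' Random sparse connectome for synthetic experiments
#'
#' Erdos-Renyi weights with uniform tract lengths; a stand-in for a
#' tractography-derived matrix at test scale.
#'
#' @param n number of nodes.
#' @param density probability of each off-diagonal connection.
#' @param weight_range,length_range uniform ranges for weights and tract
#'   lengths (mm).
#' @param conduction_speed mm/ms.
#' @param seed integer seed.
#' @return a `sparse_connectome`.
#' @export
random_connectome <- function(n, density = 0.05, weight_range = c(0.5, 1.5),
                              length_range = c(1, 30), conduction_speed = 3,
                              seed = 1L) {
  stopifnot(n >= 2, density >= 0, density <= 1)
  set.seed(as.integer(seed))
  mask <- matrix(runif(n * n) < density, n, n)
  diag(mask) <- FALSE
  w <- matrix(0, n, n); l <- matrix(0, n, n)
  k <- sum(mask)
  w[mask] <- runif(k, weight_range[1], weight_range[2])
  l[mask] <- runif(k, length_range[1], length_range[2])
  sparse_connectome(w, l, conduction_speed)
}

#' Laplace (exponential) local coupling kernel over geodesic neighborhoods
#'
#' `K[i, j] = exp(-d_ij / sigma)` for geodesic distance `0 < d_ij <= cutoff`,
#' zero elsewhere (no self-coupling: the kernel models the influence of a
#' node on its neighbors). Optionally row-normalized.
#'
#' @param geo sparse geodesic distance matrix from [geodesic_distances()].
#' @param sigma kernel length scale in mm (default 2).
#' @param cutoff neighborhood truncation in mm (default 6; must not exceed
#'   the truncation used when computing `geo`).
#' @param normalize logical; divide each row by its sum (default `FALSE`).
#' @return an object of class `local_kernel` with elements `K`
#'   (`dgCMatrix`), `sigma`, `cutoff`.
#' @export
local_kernel <- function(geo, sigma = 2, cutoff = 6, normalize = FALSE) {
  stopifnot(sigma > 0, cutoff > 0)
  g <- methods::as(Matrix::drop0(Matrix::Matrix(geo, sparse = TRUE)), "generalMatrix")
  g@x[g@x > cutoff] <- 0
  g <- Matrix::drop0(g)
  K <- g
  K@x <- exp(-g@x / sigma)
  if (normalize) {
    rs <- Matrix::rowSums(K)
    rs[rs == 0] <- 1
    K <- Matrix::Diagonal(x = 1 / rs) %*% K
    K <- methods::as(K, "generalMatrix")
  }
  structure(list(K = methods::as(K, "CsparseMatrix"), sigma = sigma,
                 cutoff = cutoff), class = "local_kernel")
}

#' @export
print.local_kernel <- function(x, ...) {
  cat("<local_kernel> ", nrow(x$K), " nodes, sigma ", x$sigma,
      " mm, cutoff ", x$cutoff, " mm\n", sep = "")
  invisible(x)
}
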