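# Spatial domains as masked uniform grids.
#
# All geometries are represented as a set of active nodes of a uniform
# Cartesian grid: the full grid for intervals and squares, and the stair-step
# subset of cells whose centres lie inside the circle for discs. Fields are
# stored as vectors over active nodes. Two neighbour tables are precomputed:
# `nb` carries ghost-reflected neighbour indices for the linear Laplacian
# stencils (3-point in 1D, compact 9-point in 2D), and `nbf` carries raw face
# neighbours (NA outside the domain) for the conservative finite-volume form
# of the nonlinear tumour diffusion.

.reflect_coord <- function(c, m) {
  c[c < 1] <- 2 - c[c < 1]
  c[c > m] <- 2 * m - c[c > m]
  c
}

.make_domain <- function(geometry, L, m) {
  if (geometry == "interval") {
    h <- L / (m - 1)
    N <- m
    nb <- cbind(.reflect_coord(seq_len(m) - 1L, m),
                .reflect_coord(seq_len(m) + 1L, m))
    nbf <- cbind(ifelse(seq_len(m) > 1L, seq_len(m) - 1L, NA_integer_),
                 ifelse(seq_len(m) < m, seq_len(m) + 1L, NA_integer_))
    boundary <- seq_len(m) %in% c(1L, m)
    return(structure(list(geometry = geometry, L = L, m = m, h = h,
                          dim = 1L, N = N, x = seq(0, L, length.out = m),
                          nb = nb, nbf = nbf, boundary = boundary),
                     class = "domain_nd"))
  }
  h <- L / (m - 1)
  xg <- seq(0, L, length.out = m)
  grid <- expand.grid(i = seq_len(m), j = seq_len(m))
  if (geometry == "disc") {
    cx <- L / 2
    r2 <- (xg[grid$i] - cx)^2 + (xg[grid$j] - cx)^2
    mask <- r2 <= (L / 2)^2
  } else mask <- rep(TRUE, nrow(grid))
  idx_full <- matrix(NA_integer_, m, m)
  idx_full[cbind(grid$i[mask], grid$j[mask])] <- seq_len(sum(mask))
  gi <- grid$i[mask]; gj <- grid$j[mask]
  N <- length(gi)
  inside <- function(i, j) i >= 1 & i <= m & j >= 1 & j <= m &
    !is.na(idx_full[cbind(pmin(pmax(i, 1L), m), pmin(pmax(j, 1L), m))])
  # neighbour with ghost reflection: reflect each out-of-range coordinate
  # across the grid edge; if the reflected node is still outside the mask
  # (stair-step rim of the disc) fall back to the centre node (zero-gradient)
  refl_nb <- function(di, dj) {
    i2 <- gi + di; j2 <- gj + dj
    ok <- inside(i2, j2)
    i3 <- .reflect_coord(i2, m); j3 <- .reflect_coord(j2, m)
    ok3 <- inside(i3, j3)
    out <- integer(N)
    out[ok] <- idx_full[cbind(i2[ok], j2[ok])]
    sel <- !ok & ok3
    out[sel] <- idx_full[cbind(i3[sel], j3[sel])]
    out[!ok & !ok3] <- which(!ok & !ok3)
    out
  }
  face_nb <- function(di, dj) {
    i2 <- gi + di; j2 <- gj + dj
    ok <- inside(i2, j2)
    out <- rep(NA_integer_, N)
    out[ok] <- idx_full[cbind(i2[ok], j2[ok])]
    out
  }
  nb <- cbind(refl_nb(1L, 0L), refl_nb(-1L, 0L),
              refl_nb(0L, 1L), refl_nb(0L, -1L),
              refl_nb(1L, 1L), refl_nb(1L, -1L),
              refl_nb(-1L, 1L), refl_nb(-1L, -1L))
  nbf <- cbind(face_nb(1L, 0L), face_nb(-1L, 0L),
               face_nb(0L, 1L), face_nb(0L, -1L))
  boundary <- rowSums(is.na(nbf)) > 0L
  structure(list(geometry = geometry, L = L, m = m, h = h, dim = 2L, N = N,
                 x = xg[gi], y = xg[gj], i = gi, j = gj, nb = nb, nbf = nbf,
                 boundary = boundary),
            class = "domain_nd")
}

#' Spatial domains
#'
#' Uniform-grid domains with Neumann closure: an interval of length `L` with
#' `m` nodes, a square of side `L` with `m` nodes per side, or a disc of
#' diameter `L` represented as the stair-step subset of an `m` x `m` grid.
#'
#' @param L domain extent (nondimensional length).
#' @param m number of nodes (per direction in 2D; `m >= 3`).
#' @return A `domain_nd` object.
#' @export
domain_interval <- function(L = 30, m = 256) {
  stopifnot(m >= 3)
  .make_domain("interval", L, as.integer(m))
}

#' @rdname domain_interval
#' @export
domain_square <- function(L = 300, m = 100) {
  stopifnot(m >= 3)
  .make_domain("square", L, as.integer(m))
}

#' @rdname domain_interval
#' @export
domain_disc <- function(L = 300, m = 100) {
  stopifnot(m >= 3)
  .make_domain("disc", L, as.integer(m))
}

#' @export
print.domain_nd <- function(x, ...) {
  cat(sprintf("%s domain, L = %g, %d active nodes, h = %g\n",
              x$geometry, x$L, x$N, x$h))
  invisible(x)
}

#' Discrete Laplacian operator
#'
#' Sparse-matrix form of the Laplacian used throughout: the centred 3-point
#' stencil on intervals and the compact 9-point stencil (edge weight 4,
#' corner weight 1, centre -20, over 6 h^2) on 2D domains, with homogeneous
#' Neumann boundary conditions imposed by ghost reflection. With
#' `bc = "dirichlet"` the rows of rim nodes are zeroed (their values are
#' prescribed externally, e.g. boundary IL-2 dosing).
#'
#' @param dom a `domain_nd` object.
#' @param bc `"neumann"` (default) or `"dirichlet"`.
#' @return A sparse `Matrix::dgCMatrix` of dimension `N` x `N`.
#' @export
build_laplacian <- function(dom, bc = c("neumann", "dirichlet")) {
  bc <- match.arg(bc)
  N <- dom$N
  if (dom$dim == 1L) {
    ii <- rep(seq_len(N), 3L)
    jj <- c(seq_len(N), dom$nb[, 1], dom$nb[, 2])
    xx <- c(rep(-2, N), rep(1, N), rep(1, N)) / dom$h^2
  } else {
    w <- c(rep(4, 4), rep(1, 4)) / 6
    ii <- rep(seq_len(N), 9L)
    jj <- c(seq_len(N), dom$nb[, 1:8])
    xx <- c(rep(-20 / 6, N), rep(w, each = N)) / dom$h^2
  }
  L <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(N, N))
  if (bc == "dirichlet") L[dom$boundary, ] <- 0
  L
}
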