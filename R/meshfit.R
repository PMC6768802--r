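# Least-squares propagation of tensor-product cubic-Hermite meshes to
# tracked material-point displacements.  The mesh interpolant is C^1 across
# shared element faces by construction (shared nodal value/derivative DOFs);
# fitting a frame is a standard linear least-squares solve per spatial
# coordinate.  Derivative DOFs are taken with respect to the unit local
# coordinate of each element (no arc-length scaling).

# cubic Hermite basis on [0,1]: value/derivative at the 0- and 1-end
hermite_h <- function(t, end, kind) {
  if (end == 0L) {
    if (kind == 0L) 1 - 3 * t^2 + 2 * t^3 else t - 2 * t^2 + t^3
  } else {
    if (kind == 0L) 3 * t^2 - 2 * t^3 else t^3 - t^2
  }
}

#' Tensor-product cubic-Hermite mesh
#'
#' A mesh whose nodal degrees of freedom are values plus mixed partial
#' derivatives with respect to the unit local coordinates: 2 DOFs per node
#' per coordinate in 1-D, 4 in 2-D, 8 in 3-D.  Shared element faces reference
#' the same nodal DOFs, which makes the interpolant C^1-continuous across
#' elements by construction.
#'
#' @param n_nodes Number of nodes M.
#' @param elements Integer matrix, one row per element, `2^dim` node ids per
#'   row in tensor-product order (first local direction fastest).
#' @param dim Spatial/parametric dimension d (1, 2 or 3).
#' @return An object of class `hermite_mesh`.  The DOF vector for one
#'   coordinate has length `2^dim * n_nodes`; DOF `2^dim * (node - 1) + k`
#'   holds the derivative type `k` (1 = value, then mixed derivatives with
#'   the first local direction varying fastest).
#' @export
hermite_mesh <- function(n_nodes, elements, dim = 1L) {
  dim <- as.integer(dim)
  if (!dim %in% 1:3) abort_validation("dim must be 1, 2 or 3")
  elements <- as.matrix(elements)
  if (ncol(elements) != 2^dim)
    abort_validation(sprintf("elements must have %d node ids per row", 2^dim))
  if (any(elements < 1L) || any(elements > n_nodes))
    abort_validation("element connectivity references invalid nodes")
  structure(list(n_nodes = as.integer(n_nodes), elements = elements,
                 dim = dim, dof_per_node = 2L^dim,
                 n_dof = 2L^dim * as.integer(n_nodes)),
            class = "hermite_mesh")
}

#' Tracked material points embedded in a Hermite mesh
#'
#' @param element Integer vector of containing-element ids, one per point.
#' @param xi Matrix (N x dim) of local coordinates in `[0, 1]^dim`.
#' @param displacement Optional matrix (N x n_coord) of displacement vectors
#'   from the fitted frame to the target frame, mm.
#' @param mesh The [hermite_mesh()] the points are embedded in (used for
#'   validation).
#' @return A list of class `tracked_points`.
#' @export
tracked_points <- function(element, xi, displacement = NULL, mesh = NULL) {
  xi <- as.matrix(xi)
  if (any(xi < 0) || any(xi > 1))
    abort_validation("local coordinates must lie inside [0, 1]^d (embedding error)")
  if (!is.null(mesh)) {
    if (any(element < 1L) || any(element > nrow(mesh$elements)))
      abort_validation("element ids outside the mesh (embedding error)")
    if (ncol(xi) != mesh$dim)
      abort_validation("local coordinate dimension disagrees with the mesh")
  }
  if (!is.null(displacement)) displacement <- as.matrix(displacement)
  structure(list(element = as.integer(element), xi = xi,
                 displacement = displacement, n = nrow(xi)),
            class = "tracked_points")
}

#' Shape matrix of the cubic-Hermite basis at embedded points
#'
#' Sparse matrix `H` with one row per point and one column per DOF such that
#' `H %*% U` evaluates the Hermite interpolant of the DOF vector `U` at every
#' point; each row touches only the DOFs of the containing element.  The
#' value-type basis columns form a partition of unity.
#'
#' @param mesh A [hermite_mesh()].
#' @param pts A [tracked_points()] object (or anything with `element` and
#'   `xi`).
#' @return A `dgCMatrix` of dimension N x `n_dof`.
#' @export
shape_matrix <- function(mesh, pts) {
  stopifnot(inherits(mesh, "hermite_mesh"))
  d <- mesh$dim
  xi <- as.matrix(pts$xi)
  el <- pts$element
  if (any(xi < 0) || any(xi > 1))
    abort_validation("local coordinates must lie inside [0, 1]^d (embedding error)")
  n_pts <- nrow(xi)
  n_loc <- 2^d          # local nodes per element
  n_kind <- 2^d         # derivative types per node
  # local node corners and derivative-kind multi-indices, first dir fastest
  corners <- as.matrix(expand.grid(rep(list(0:1), d)))
  kinds <- as.matrix(expand.grid(rep(list(0:1), d)))
  ii <- jj <- xx <- vector("list", n_loc * n_kind)
  blk <- 0L
  for (a in seq_len(n_loc)) {
    node_ids <- mesh$elements[el, a]
    for (b in seq_len(n_kind)) {
      blk <- blk + 1L
      val <- rep(1, n_pts)
      for (k in seq_len(d))
        val <- val * hermite_h(xi[, k], corners[a, k], kinds[b, k])
      ii[[blk]] <- seq_len(n_pts)
      jj[[blk]] <- (node_ids - 1L) * mesh$dof_per_node +
        1L + as.integer(kinds[b, , drop = TRUE] %*% 2^(seq_len(d) - 1))
      xx[[blk]] <- val
    }
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(n_pts, mesh$n_dof))
}

#' Propagate mesh DOFs to a new frame by least squares
#'
#' Solves the normal equations of the linear least-squares problem that fits
#' the mesh interpolant to the displaced point positions
#' `z = H U_j + Z`: `U_i = (H' W H + lambda I)^{-1} H' W z`, per spatial
#' coordinate.  Unweighted by default; an optional per-point weight vector
#' gives the diagonally weighted solve.
#'
#' @param U_j DOF matrix (`n_dof` x n_coord) of the source frame.
#' @param Z Displacement matrix (N x n_coord), mm.
#' @param H Shape matrix from [shape_matrix()].
#' @param weights Optional positive per-point weights (length N).
#' @param lambda Optional Tikhonov regularization (default 0); when nonzero
#'   its use is reported via a message.
#' @return DOF matrix (`n_dof` x n_coord) of the fitted frame.
#' @export
propagate_mesh <- function(U_j, Z, H, weights = NULL, lambda = 0) {
  U_j <- as.matrix(U_j)
  Z <- as.matrix(Z)
  if (nrow(Z) != nrow(H) || nrow(U_j) != ncol(H))
    abort_validation("dimension mismatch between DOFs, displacements and shape matrix")
  if (nrow(H) < ncol(H) && lambda == 0)
    stop_df("fewer point equations than DOFs: ill-posed fit; supply more points or set lambda > 0",
            "diastolefit_illposed_fit")
  z <- H %*% U_j + Z
  if (!is.null(weights)) {
    if (length(weights) != nrow(H) || any(weights <= 0))
      abort_validation("weights must be positive, one per point")
    W <- Matrix::Diagonal(x = weights)
    A <- Matrix::crossprod(H, W %*% H)
    b <- Matrix::crossprod(H, W %*% z)
  } else {
    A <- Matrix::crossprod(H)
    b <- Matrix::crossprod(H, z)
  }
  if (lambda > 0) {
    message(sprintf("propagate_mesh: Tikhonov regularization lambda = %g", lambda))
    A <- A + lambda * Matrix::Diagonal(ncol(H))
  }
  U_i <- tryCatch(
    as.matrix(Matrix::solve(A, b)),
    error = function(cnd) stop_df(
      "normal matrix is rank deficient: ill-posed fit; supply more points or set lambda > 0",
      "diastolefit_illposed_fit")
  )
  dimnames(U_i) <- dimnames(U_j)
  U_i
}

#' Residual statistics of a mesh fit
#'
#' Per-point residuals `z - H U_i` of the least-squares fit, their summary
#' statistics, and the normal-equation orthogonality defect
#' `max |H' (z - H U_i)|` (which is ~0 for an unregularized fit).
#'
#' @param U_i Fitted DOF matrix.
#' @param z Target point positions (N x n_coord): `H U_j + Z`.
#' @param H Shape matrix.
#' @return A list with `residuals` (N x n_coord), `mean`, `sd`, `max`
#'   (component-pooled, mm), `norms` (per-point Euclidean norms) and
#'   `orthogonality`.
#' @export
fit_residual <- function(U_i, z, H) {
  z <- as.matrix(z)
  r <- as.matrix(z - H %*% as.matrix(U_i))
  norms <- sqrt(rowSums(r^2))
  list(residuals = r,
       mean = mean(r), sd = stats::sd(as.vector(r)), max = max(abs(r)),
       norms = norms,
       orthogonality = max(abs(as.matrix(Matrix::crossprod(H, r)))))
}

#' DOFs of a 1-D uniform Hermite mesh interpolating a function
#'
#' Convenience constructor for tests and examples: nodal values and unit-xi
#' derivatives of `f` on a uniform 1-D mesh spanning `[a, b]`.
#'
#' @param f Function; `df` its derivative.
#' @param n_elem Number of elements.
#' @param a,b Interval endpoints.
#' @return List with the [hermite_mesh()] and the DOF vector.
#' @export
hermite_mesh_1d <- function(f, df, n_elem, a = 0, b = 1) {
  nodes <- seq(a, b, length.out = n_elem + 1L)
  hx <- (b - a) / n_elem
  mesh <- hermite_mesh(n_elem + 1L, cbind(seq_len(n_elem), seq_len(n_elem) + 1L),
                       dim = 1L)
  U <- numeric(mesh$n_dof)
  U[seq(1, mesh$n_dof, by = 2)] <- f(nodes)
  U[seq(2, mesh$n_dof, by = 2)] <- df(nodes) * hx  # unit-xi derivative DOFs
  list(mesh = mesh, U = U, nodes = nodes, hx = hx)
}

#' Read and write Hermite meshes as JSON
#'
#' The mesh serializes as `{dim, nodes: [{dofs: [...]}, ...], elements:
#' [[node ids], ...]}` where each node carries its DOF block per spatial
#' coordinate (value + mixed unit-coordinate derivatives).
#'
#' @param mesh A [hermite_mesh()].
#' @param U DOF matrix (`n_dof` x n_coord).
#' @param path JSON file path.
#' @return [read_mesh_json()]: a list with `mesh` and `U`.
#' @export
write_mesh_json <- function(mesh, U, path) {
  stopifnot(inherits(mesh, "hermite_mesh"))
  U <- as.matrix(U)
  nodes <- lapply(seq_len(mesh$n_nodes), function(nd) {
    rows <- (nd - 1L) * mesh$dof_per_node + seq_len(mesh$dof_per_node)
    list(dofs = unname(as.list(as.data.frame(U[rows, , drop = FALSE]))))
  })
  payload <- list(
    schema = "diastolefit-mesh/1", dim = mesh$dim, nodes = nodes,
    elements = lapply(seq_len(nrow(mesh$elements)), function(i)
      unname(mesh$elements[i, ]))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mesh_json
#' @export
read_mesh_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(p$schema, "diastolefit-mesh/1"))
    abort_validation("unknown mesh schema")
  dim <- as.integer(p$dim)
  elements <- do.call(rbind, lapply(p$elements, function(e) as.integer(unlist(e))))
  mesh <- hermite_mesh(length(p$nodes), elements, dim = dim)
  U <- do.call(rbind, lapply(p$nodes, function(nd)
    do.call(cbind, lapply(nd$dofs, function(col) as.numeric(unlist(col))))))
  list(mesh = mesh, U = U)
}

#' Read tracked points from CSV
#'
#' Expects columns `element_id`, `xi1` (.. `xid`) and optional displacement
#' columns `dx`, `dy`, `dz`.
#'
#' @param path CSV file path.
#' @param mesh Optional [hermite_mesh()] for validation.
#' @return A [tracked_points()] object.
#' @export
read_tracked_points <- function(path, mesh = NULL) {
  df <- utils::read.csv(path)
  xi_cols <- grep("^xi[0-9]+$", names(df), value = TRUE)
  if (!("element_id" %in% names(df)) || !length(xi_cols))
    abort_validation("tracked points CSV needs element_id and xi1..xid columns")
  disp_cols <- intersect(c("dx", "dy", "dz"), names(df))
  tracked_points(df$element_id, as.matrix(df[xi_cols]),
                 displacement = if (length(disp_cols)) as.matrix(df[disp_cols]),
                 mesh = mesh)
}
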