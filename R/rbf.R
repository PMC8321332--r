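# Scattered-data radial basis function interpolation
#
# The interpolant has the form
#   s(X) = p_m(X) + sum_i lambda_i * phi(||X - X_i||_2)
# with interpolation conditions s(X_j) = f(X_j) and, when a polynomial tail
# of degree m is present, side conditions sum_i lambda_i q(X_i) = 0 for every
# monomial q of degree <= m.  Kernel/tail pairings follow the classical
# conditional positive definiteness requirements: the linear and thin-plate
# spline kernels need a degree-1 tail and nodes not all on one hyperplane;
# the Gaussian and multiquadric kernels are solvable with no tail at all.

rbf_kernels <- c("linear", "thin_plate_spline", "gaussian", "multiquadric")

rbf_kernel_eval <- function(kernel, r, shape_param = NULL) {
  switch(kernel,
    linear = r,
    thin_plate_spline = {
      out <- r^2 * log(r)
      out[r == 0] <- 0
      out
    },
    gaussian = exp(-(r / shape_param)^2),
    multiquadric = sqrt(r^2 + shape_param^2),
    stop(sprintf("unknown kernel '%s'; known: %s", kernel,
                 paste(rbf_kernels, collapse = ", ")))
  )
}

# default polynomial tail degree per kernel (NA = no tail)
rbf_default_degree <- function(kernel) {
  switch(kernel, linear = 1L, thin_plate_spline = 1L,
         gaussian = NA_integer_, multiquadric = NA_integer_)
}

#' Check polynomial unisolvency of a node set
#'
#' A node set is unisolvent for degree \code{m} when no nonzero polynomial
#' of total degree at most \code{m} vanishes at every node — for degree 1,
#' the nodes must not all lie on a single line (2D) or hyperplane.  This is
#' the node condition required by kernels with a degree-1 polynomial tail.
#' Decided by the numerical rank of the monomial-basis matrix.
#'
#' @param nodes numeric matrix, one node per row.
#' @param degree polynomial degree to test.
#' @param tol relative singular-value tolerance for the rank decision.
#' @return \code{TRUE} iff the node set is unisolvent.
#' @export
check_unisolvency <- function(nodes, degree, tol = 1e-10) {
  nodes <- as.matrix(nodes)
  if (nrow(nodes) < 1) stop("empty node set")
  B <- monomial_basis(nodes, degree)
  if (nrow(B) < ncol(B)) return(FALSE)
  qr(B, tol = tol)$rank == ncol(B)
}

#' Fit a radial basis function interpolant
#'
#' Assembles and solves the symmetric saddle-point system
#' \deqn{\left[\begin{array}{cc} A & P \\ P^T & 0 \end{array}\right]
#'       \left[\begin{array}{c} \lambda \\ c \end{array}\right] =
#'       \left[\begin{array}{c} f \\ 0 \end{array}\right]}
#' with \eqn{A_{ij} = \phi(\|X_i - X_j\|_2)} and \eqn{P} the monomial basis
#' of the tail degree, via a pivoted LAPACK QR factorization.  When the node
#' count exceeds \code{max_nodes} a seeded uniform subsample of the nodes is
#' used as centers (annulus masks routinely contain thousands of pixels);
#' the interpolation conditions then hold at the retained centers.
#'
#' @param nodes numeric matrix of distinct points, one per row.
#' @param values function values at the nodes.
#' @param kernel one of \code{"linear"}, \code{"thin_plate_spline"},
#'   \code{"gaussian"}, \code{"multiquadric"}.
#' @param shape_param positive width/offset for the Gaussian and
#'   multiquadric kernels, or \code{"auto"} (mean nearest-neighbour distance
#'   among the retained centers).
#' @param poly_degree polynomial tail degree; \code{NULL} selects the
#'   kernel's conventional pairing (degree 1 for linear and thin-plate
#'   spline, no tail for Gaussian and multiquadric).  Gaussian/multiquadric
#'   fits may opt into a tail by passing a degree.
#' @param max_nodes maximum number of centers retained (default 500).
#' @param seed integer seed controlling the subsample.
#' @param cond_limit condition-number estimate above which the fit is
#'   flagged with a warning.
#' @return an \code{rbf_model} with elements \code{kernel}, \code{centers},
#'   \code{weights}, \code{poly_degree}, \code{tail_coef},
#'   \code{shape_param}, \code{cond_estimate}.
#' @export
fit_rbf <- function(nodes, values, kernel = "thin_plate_spline",
                    shape_param = "auto", poly_degree = NULL,
                    max_nodes = 500L, seed = 1L, cond_limit = 1e12) {
  kernel <- match.arg(kernel, rbf_kernels)
  nodes <- as.matrix(nodes)
  values <- as.numeric(values)
  if (nrow(nodes) != length(values))
    stop("nodes and values length mismatch")
  if (any(!is.finite(values))) stop("values must be finite")
  d <- ncol(nodes)
  if (kernel == "thin_plate_spline" && d != 2)
    stop("thin_plate_spline kernel is defined here for dimension 2")

  if (is.null(poly_degree)) poly_degree <- rbf_default_degree(kernel)
  has_tail <- !is.na(poly_degree)
  if (kernel %in% c("linear", "thin_plate_spline") &&
      (!has_tail || poly_degree < 1))
    stop(sprintf("kernel '%s' requires a polynomial tail of degree >= 1", kernel))

  if (nrow(nodes) > max_nodes) {
    keep <- with_seed(seed, sort(sample.int(nrow(nodes), max_nodes)))
    nodes <- nodes[keep, , drop = FALSE]
    values <- values[keep]
  }
  n <- nrow(nodes)

  D <- cross_dist(nodes, nodes)
  if (n > 1 && min(D[upper.tri(D)]) == 0)
    stop("nodes must be pairwise distinct")

  if (has_tail && !check_unisolvency(nodes, poly_degree))
    stop(sprintf("node set is not unisolvent for tail degree %d (e.g. collinear nodes)",
                 poly_degree))

  rho <- NULL
  if (kernel %in% c("gaussian", "multiquadric")) {
    if (identical(shape_param, "auto")) {
      rho <- if (n > 1) mean(apply(D + diag(Inf, n), 1, min)) else 1
    } else {
      rho <- as.numeric(shape_param)
      if (!(rho > 0)) stop("shape_param must be positive")
    }
  }

  A <- rbf_kernel_eval(kernel, D, rho)
  if (has_tail) {
    P <- monomial_basis(nodes, poly_degree)
    p <- ncol(P)
    M <- rbind(cbind(A, P), cbind(t(P), matrix(0, p, p)))
    rhs <- c(values, rep(0, p))
  } else {
    M <- A
    rhs <- values
  }

  qrM <- qr(M, LAPACK = TRUE)
  if (any(abs(diag(qr.R(qrM))) < 1e-14 * max(abs(diag(qr.R(qrM))))))
    stop(sprintf("interpolation system singular beyond tolerance (condition estimate %.3e)",
                 kappa(M, exact = FALSE)))
  sol <- solve(qrM, rhs)
  cond_est <- kappa(M, exact = FALSE)
  if (cond_est > cond_limit)
    warning(sprintf("ill-conditioned interpolation system (condition estimate %.3e)",
                    cond_est))

  structure(list(kernel = kernel, dimension = d, centers = nodes,
                 weights = sol[seq_len(n)],
                 poly_degree = if (has_tail) as.integer(poly_degree) else NA_integer_,
                 tail_coef = if (has_tail) sol[-seq_len(n)] else NULL,
                 shape_param = rho, cond_estimate = cond_est),
            class = "rbf_model")
}

#' @export
print.rbf_model <- function(x, ...) {
  cat(sprintf("<rbf_model> kernel=%s, %d centers in R^%d, tail degree=%s%s\n",
              x$kernel, nrow(x$centers), x$dimension,
              ifelse(is.na(x$poly_degree), "absent", x$poly_degree),
              if (!is.null(x$shape_param)) sprintf(", rho=%.4g", x$shape_param) else ""))
  invisible(x)
}

#' Evaluate a fitted RBF interpolant
#'
#' @param model an \code{rbf_model} from \code{\link{fit_rbf}}.
#' @param points numeric matrix of evaluation points (one per row) of the
#'   model's dimension.
#' @return numeric vector of interpolant values.
#' @export
evaluate_rbf <- function(model, points) {
  points <- as.matrix(points)
  if (ncol(points) != model$dimension)
    stop(sprintf("points have dimension %d; model expects %d",
                 ncol(points), model$dimension))
  Phi <- rbf_kernel_eval(model$kernel, cross_dist(points, model$centers),
                         model$shape_param)
  v <- drop(Phi %*% model$weights)
  if (!is.na(model$poly_degree))
    v <- v + drop(monomial_basis(points, model$poly_degree) %*% model$tail_coef)
  v
}

#' Weighted least-squares polynomial fit
#'
#' Fits a polynomial of the given total degree over the monomial basis by
#' minimizing \eqn{\sum_j w_j (p(X_j) - f_j)^2}.  The smooth low-order
#' polynomial surface is the classical alternative to the RBF network for
#' referenceless background-phase estimation.
#'
#' @param nodes numeric matrix of points, one per row.
#' @param values function values at the nodes.
#' @param weights nonnegative per-node weights; \code{NULL} for unit weights.
#' @param degree total polynomial degree.
#' @return a \code{poly_model} with coefficients over the monomial basis.
#' @export
fit_polynomial_wls <- function(nodes, values, weights = NULL, degree = 2L) {
  nodes <- as.matrix(nodes)
  values <- as.numeric(values)
  if (nrow(nodes) != length(values)) stop("nodes and values length mismatch")
  if (is.null(weights)) weights <- rep(1, nrow(nodes))
  if (any(weights < 0)) stop("weights must be nonnegative")
  if (all(weights == 0)) stop("weights must not all be zero")
  keep <- weights > 0
  B <- monomial_basis(nodes[keep, , drop = FALSE], degree)
  if (nrow(B) < ncol(B))
    stop(sprintf("rank-deficient design: %d weighted nodes for %d coefficients",
                 nrow(B), ncol(B)))
  sw <- sqrt(weights[keep])
  qrB <- qr(B * sw)
  if (qrB$rank < ncol(B))
    stop(sprintf("rank-deficient design: rank %d < %d coefficients (degenerate node geometry)",
                 qrB$rank, ncol(B)))
  coef <- qr.coef(qrB, values[keep] * sw)
  structure(list(dimension = ncol(nodes), degree = as.integer(degree),
                 coefficients = as.numeric(coef),
                 exponents = monomial_exponents(ncol(nodes), degree)),
            class = "poly_model")
}

#' Evaluate a fitted polynomial model
#'
#' @param model a \code{poly_model}.
#' @param points numeric matrix of evaluation points.
#' @return numeric vector.
#' @export
evaluate_polynomial <- function(model, points) {
  points <- as.matrix(points)
  if (ncol(points) != model$dimension)
    stop(sprintf("points have dimension %d; model expects %d",
                 ncol(points), model$dimension))
  drop(monomial_basis(points, model$degree) %*% model$coefficients)
}

#' Serialize an RBF model to JSON
#'
#' @param model an \code{rbf_model}.
#' @param path optional file path; when omitted the JSON string is returned.
#' @return path (invisibly) or a JSON string.
#' @export
rbf_to_json <- function(model, path = NULL) {
  obj <- list(kernel = model$kernel, dimension = model$dimension,
              centers = model$centers, weights = model$weights,
              poly_degree = if (is.na(model$poly_degree)) NULL else model$poly_degree,
              tail_coef = model$tail_coef, shape_param = model$shape_param)
  if (is.null(path))
    return(as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                                         null = "null")))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Deserialize an RBF model from JSON
#'
#' @param source a file path or JSON string from \code{\link{rbf_to_json}}.
#' @return an \code{rbf_model}.
#' @export
rbf_from_json <- function(source) {
  obj <- jsonlite::fromJSON(source)
  structure(list(kernel = obj$kernel, dimension = obj$dimension,
                 centers = as.matrix(obj$centers),
                 weights = as.numeric(obj$weights),
                 poly_degree = if (is.null(obj$poly_degree)) NA_integer_
                               else as.integer(obj$poly_degree),
                 tail_coef = if (is.null(obj$tail_coef)) NULL
                             else as.numeric(obj$tail_coef),
                 shape_param = obj$shape_param, cond_estimate = NA_real_),
            class = "rbf_model")
}
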