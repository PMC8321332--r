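# shared fixture builders and independent oracles

# seeded random node set in [0, 10]^d
rand_nodes <- function(n, d = 2, seed = 1) {
  set.seed(seed)
  matrix(runif(n * d, 0, 10), n, d)
}

# independent unisolvency oracle: smallest singular value of the
# monomial-basis matrix (null-space test, not QR rank)
svd_unisolvent <- function(nodes, degree, tol = 1e-10) {
  B <- fustherm:::monomial_basis(nodes, degree)
  if (nrow(B) < ncol(B)) return(FALSE)
  s <- svd(B)$d
  s[length(s)] > tol * s[1]
}

# brute-force dense solve of the RBF saddle-point system with base solve()
oracle_rbf_solve <- function(nodes, values, kernel, rho = NULL, degree = NA) {
  n <- nrow(nodes)
  D <- as.matrix(dist(nodes))
  A <- fustherm:::rbf_kernel_eval(kernel, D, rho)
  if (!is.na(degree)) {
    P <- fustherm:::monomial_basis(nodes, degree)
    p <- ncol(P)
    M <- rbind(cbind(A, P), cbind(t(P), matrix(0, p, p)))
    sol <- unname(solve(M, c(values, rep(0, p))))
    list(weights = sol[1:n], tail = sol[-(1:n)])
  } else {
    list(weights = unname(solve(A, values)), tail = NULL)
  }
}

# exhaustive sign-flip signed-rank oracle via bit masks (independent of the
# expand.grid enumeration inside the package)
oracle_signrank_p <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  ge <- le <- 0L
  for (mask in 0:(2^n - 1)) {
    w <- sum(r[bitwAnd(bitwShiftR(mask, 0:(n - 1)), 1L) == 1L])
    if (w >= V - 1e-9) ge <- ge + 1L
    if (w <= V + 1e-9) le <- le + 1L
  }
  min(1, 2 * min(ge, le) / 2^n)
}

# small noiseless phantom fixture (2 mm pixels, 64x64) for fast tests
small_config <- function(...) {
  phantom_config(matrix_size = 64L, pixel_spacing_mm = 2, ...)
}

# hot-spot spec centred on a grid node inside the phantom of small_config
# (phantom centre for small_config sits at (60.5, 63) mm)
small_hotspot <- function(peak = 16, sigma = 6) {
  list(center_mm = c(60, 62), sigma_mm = sigma, peak_deltaT = peak,
       mode = "static")
}

referenceless_kernels <- c("linear", "thin_plate_spline", "multiquadric")
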