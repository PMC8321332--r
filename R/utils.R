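# internal helpers shared across modules

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards so library calls never perturb user randomness.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  code
}

# population (divide-by-N) standard deviation
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

# exponent rows for the monomial basis of total degree <= m in d variables,
# ordered by total degree then lexicographically (deterministic layout)
monomial_exponents <- function(d, m) {
  ex <- as.matrix(expand.grid(rep(list(0:m), d)))
  ex <- ex[rowSums(ex) <= m, , drop = FALSE]
  ord <- do.call(order, c(list(rowSums(ex)), lapply(seq_len(d), function(k) -ex[, k])))
  ex <- ex[ord, , drop = FALSE]
  dimnames(ex) <- NULL
  ex
}

# n x p matrix of monomials evaluated at the rows of X
monomial_basis <- function(X, m) {
  X <- as.matrix(X)
  ex <- monomial_exponents(ncol(X), m)
  B <- matrix(1, nrow(X), nrow(ex))
  for (j in seq_len(nrow(ex))) {
    for (k in seq_len(ncol(X))) {
      if (ex[j, k] > 0) B[, j] <- B[, j] * X[, k]^ex[j, k]
    }
  }
  B
}

# cross Euclidean distance matrix between rows of A (n x d) and B (m x d);
# accumulated per coordinate (no a^2+b^2-2ab cancellation, exact zeros)
cross_dist <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  d2 <- matrix(0, nrow(A), nrow(B))
  for (k in seq_len(ncol(A))) d2 <- d2 + outer(A[, k], B[, k], "-")^2
  sqrt(d2)
}

# positive draws from N(mean, sd) by rejection (exact truncation at 0)
rnorm_pos <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(n, mean, sd)
    out <- c(out, x[x > 0])
  }
  out[seq_len(n)]
}

stage_log <- function(stage, t0 = NULL, verbose = TRUE) {
  if (!verbose) return(invisible(NULL))
  if (is.null(t0)) {
    message(sprintf("[fustherm] %s ...", stage))
  } else {
    message(sprintf("[fustherm] %s done (%.2f s)", stage,
                    as.numeric(proc.time()["elapsed"]) - t0))
  }
  invisible(as.numeric(proc.time()["elapsed"]))
}
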