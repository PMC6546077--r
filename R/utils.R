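#' @keywords internal
"_PACKAGE"

# numerically stable log(sum(exp(x))) over the rows of a matrix
logsumexp_rows <- function(A) {
  mx <- A[, 1L]
  for (j in seq_len(ncol(A))[-1L]) mx <- pmax.int(mx, A[, j])
  mx[!is.finite(mx)] <- 0
  mx + log(rowSums(exp(A - mx)))
}

logsumexp <- function(x) {
  mx <- max(x)
  if (!is.finite(mx)) return(mx)
  mx + log(sum(exp(x - mx)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Bijections between a box-constrained parameter space and R^k, used so that
# all inner optimisations are unconstrained: log for (l, Inf), -log for
# (-Inf, u), scaled logit for finite boxes, identity otherwise. The masks
# are precomputed once per box (hot path: called on every objective eval).
box_transform <- function(lower, upper) {
  lo_only <- is.finite(lower) & !is.finite(upper)
  up_only <- !is.finite(lower) & is.finite(upper)
  both <- is.finite(lower) & is.finite(upper)
  width <- upper - lower
  list(
    to_u = function(x) {
      u <- x
      if (any(lo_only)) u[lo_only] <- log(x[lo_only] - lower[lo_only])
      if (any(up_only)) u[up_only] <- log(upper[up_only] - x[up_only])
      if (any(both)) {
        p <- (x[both] - lower[both]) / width[both]
        p[p < 1e-12] <- 1e-12; p[p > 1 - 1e-12] <- 1 - 1e-12
        u[both] <- log(p / (1 - p))
      }
      u
    },
    to_x = function(u) {
      x <- u
      if (any(lo_only)) x[lo_only] <- lower[lo_only] + exp(pmin.int(u[lo_only], 700))
      if (any(up_only)) x[up_only] <- upper[up_only] - exp(pmin.int(u[up_only], 700))
      if (any(both)) x[both] <- lower[both] + width[both] * stats::plogis(u[both])
      x
    })
}

to_unconstrained <- function(x, lower, upper) box_transform(lower, upper)$to_u(x)
to_constrained <- function(u, lower, upper) box_transform(lower, upper)$to_x(u)

# Run `expr` under a fixed RNG seed without disturbing the caller's stream.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Minimise `fn` from `par` in a box by Nelder-Mead (or BFGS for larger k) in
# the unconstrained reparameterisation; the returned value never exceeds
# fn(par) because optim reports the best point visited.
optim_box <- function(par, fn, lower, upper, maxit = 200L, method = NULL) {
  k <- length(par)
  method <- method %||% if (k == 1L) "Brent" else if (k <= 6L) "Nelder-Mead" else "BFGS"
  tr <- box_transform(lower, upper)
  f_u <- function(u) {
    v <- fn(tr$to_x(u))
    if (!is.finite(v)) 1e300 else v
  }
  if (method == "Brent") {
    lo <- if (is.finite(lower)) lower else par - 1e3 * (abs(par) + 1)
    hi <- if (is.finite(upper)) upper else par + 1e3 * (abs(par) + 1)
    res <- stats::optim(par, function(p) {
      v <- fn(p); if (!is.finite(v)) 1e300 else v
    }, method = "Brent", lower = lo, upper = hi)
    best <- list(par = res$par, value = res$value)
  } else {
    u0 <- tr$to_u(par)
    res <- suppressWarnings(stats::optim(u0, f_u, method = method,
                                         control = list(maxit = maxit)))
    best <- list(par = tr$to_x(res$par), value = res$value)
  }
  v0 <- fn(par)
  if (is.finite(v0) && v0 < best$value) best <- list(par = par, value = v0)
  best
}
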