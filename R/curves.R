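.curve_registry <- new.env(parent = emptyenv())

#' Define a parametric mean-trajectory model
#'
#' A curve model describes the genotype-specific mean of the longitudinal
#' trait as a parametric function of time. Built-in models are registered
#' when the package loads; users may register their own with
#' \code{\link{register_curve}}.
#'
#' @param name Unique model name.
#' @param n_params Number of parameters.
#' @param fun Function \code{(params, times) -> values}, finite for all
#'   in-bounds params.
#' @param lower,upper Per-parameter bounds (length \code{n_params}).
#' @param init Function \code{(times, y_mean) -> params} giving a feasible
#'   starting point.
#' @return A \code{curve_model} object.
#' @export
curve_model <- function(name, n_params, fun, lower, upper, init) {
  stopifnot(is.character(name), length(name) == 1L,
            length(lower) == n_params, length(upper) == n_params)
  structure(list(name = name, n_params = as.integer(n_params), fun = fun,
                 lower = lower, upper = upper, init = init),
            class = "curve_model")
}

#' Register a curve model
#'
#' @param model A \code{curve_model}.
#' @param overwrite Replace an existing entry of the same name.
#' @export
register_curve <- function(model, overwrite = FALSE) {
  stopifnot(inherits(model, "curve_model"))
  if (!overwrite && !is.null(.curve_registry[[model$name]]))
    stop("curve model '", model$name, "' is already registered")
  assign(model$name, model, envir = .curve_registry)
  invisible(model)
}

#' @rdname register_curve
#' @param name Registered model name.
#' @export
get_curve <- function(name) {
  if (inherits(name, "curve_model")) return(name)
  m <- .curve_registry[[name]]
  if (is.null(m)) stop("unknown curve model: ", name,
                       " (registered: ", paste(curve_names(), collapse = ", "), ")")
  m
}

#' @rdname register_curve
#' @export
curve_names <- function() sort(ls(.curve_registry))

#' Logistic growth curve
#'
#' \eqn{g(t) = a / (1 + b e^{-r t})}: \code{a} is the asymptote, \code{b}
#' positions the inflection and \code{r} is the relative growth rate.
#'
#' @param a,b,r Curve parameters.
#' @param t Time point(s).
#' @return Trait value(s).
#' @examples
#' logistic_value(10, 1, 0.5, 0)  # 5: half the asymptote when b e^0 = 1
#' @export
logistic_value <- function(a, b, r, t) {
  den <- 1 + b * exp(-r * t)
  if (any(den == 0)) stop("logistic denominator is zero")
  a / den
}

legendre_basis <- function(times, order, trange = range(times)) {
  # rescale observed times to [-1, 1]; recurrence for P_0..P_order
  if (diff(trange) == 0) x <- rep(0, length(times))
  else x <- 2 * (times - trange[1L]) / diff(trange) - 1
  B <- matrix(0, length(x), order + 1L)
  B[, 1L] <- 1
  if (order >= 1L) B[, 2L] <- x
  if (order >= 2L) for (k in 2L:order)
    B[, k + 1L] <- ((2 * k - 1) * x * B[, k] - (k - 1) * B[, k - 1L]) / k
  B
}

register_builtin_curves <- function() {
  register_curve(curve_model(
    "logistic", 3L,
    fun = function(p, t) p[1L] / (1 + p[2L] * exp(-p[3L] * t)),
    lower = c(-Inf, 0, 0), upper = c(Inf, Inf, Inf),
    init = function(times, y) {
      a <- max(y) * 1.02
      if (a == 0) a <- 1
      b <- max(a / max(y[1L], 1e-6) - 1, 1e-3)
      z <- a / pmax(y, 1e-6) - 1
      ok <- z > 1e-8
      r <- if (sum(ok) >= 2L) {
        sl <- stats::coef(stats::lm(log(z[ok]) ~ times[ok]))[2L]
        max(-sl, 1e-3)
      } else 0.5
      c(a, b, r)
    }), overwrite = TRUE)

  register_curve(curve_model(
    "double_logistic", 6L,
    fun = function(p, t) p[1L] / (1 + p[2L] * exp(-p[3L] * t)) +
                         p[4L] / (1 + p[5L] * exp(-p[6L] * t)),
    lower = c(-Inf, 0, 0, -Inf, 0, 0), upper = rep(Inf, 6L),
    init = function(times, y) {
      base <- get_curve("logistic")$init(times, y)
      c(base[1L] * 0.6, base[2L], base[3L],
        base[1L] * 0.4, base[2L] * 2, base[3L] * 0.5)
    }), overwrite = TRUE)

  register_curve(legendre_curve(4L), overwrite = TRUE)

  # pharmacological (Emax) response curve: E(t) = E0 + Emax * t / (E50 + t)
  register_curve(curve_model(
    "pharmacology", 3L,
    fun = function(p, t) p[1L] + p[2L] * t / (p[3L] + t),
    lower = c(-Inf, -Inf, 1e-6), upper = c(Inf, Inf, Inf),
    init = function(times, y) {
      c(y[1L], y[length(y)] - y[1L], max(stats::median(times), 1e-3))
    }), overwrite = TRUE)
}

#' Legendre polynomial curve of a given order
#'
#' Linear-in-parameters trajectory on times rescaled to \eqn{[-1, 1]} by
#' their observed range. Reproduces any polynomial of degree \code{order}
#' exactly. The default registered instance has order 4 under the name
#' \code{"legendre"}.
#'
#' @param order Polynomial order (>= 0).
#' @param name Registry name.
#' @return A \code{curve_model}.
#' @export
legendre_curve <- function(order = 4L, name = "legendre") {
  order <- as.integer(order)
  stopifnot(order >= 0L)
  curve_model(
    name, order + 1L,
    fun = function(p, t) as.vector(legendre_basis(t, order) %*% p),
    lower = rep(-Inf, order + 1L), upper = rep(Inf, order + 1L),
    init = function(times, y) {
      B <- legendre_basis(times, order)
      as.vector(qr.coef(qr(B), y))
    })
}

#' Least-squares fit of a curve model
#'
#' Minimises \eqn{\sum_i \sum_t (y_{it} - g(\theta, t))^2} over the curve
#' parameters (missing cells excluded), by Nelder-Mead restarts from
#' jittered initial guesses. Linear models converge in one inner step since
#' the initial guess is already the least-squares solution.
#'
#' @param model A \code{curve_model} or registered name.
#' @param times Vector of m time points.
#' @param values \code{n x m} matrix (or length-m vector) of trait values.
#' @param restarts Number of jittered restarts (the unjittered start is
#'   always included).
#' @return A \code{curve_fit}: list with \code{model}, \code{params},
#'   \code{rss}, \code{n_obs}, \code{aic}, \code{bic}, \code{times_range}.
#'   AIC/BIC use the Gaussian concentrated form
#'   \eqn{N \log(rss/N) + penalty \cdot k}.
#' @export
fit_curve_ls <- function(model, times, values, restarts = 5L) {
  model <- get_curve(model)
  if (is.vector(values)) values <- matrix(values, nrow = 1L)
  m <- length(times)
  stopifnot(ncol(values) == m)
  if (m < model$n_params)
    stop("need at least ", model$n_params, " time points to fit ", model$name)
  nt <- colSums(!is.na(values))
  if (any(nt == 0L)) stop("some time points have no observed values")
  ybar <- colMeans(values, na.rm = TRUE)
  sse_within <- sum(sweep(values, 2L, ybar)^2, na.rm = TRUE)
  rss_of <- function(p) {
    g <- model$fun(p, times)
    if (any(!is.finite(g))) return(Inf)
    sse_within + sum(nt * (ybar - g)^2)
  }
  p0 <- pmin(pmax(model$init(times, ybar), model$lower + 1e-9), model$upper - 1e-9)
  best <- optim_box(p0, rss_of, model$lower, model$upper,
                    maxit = 500L * model$n_params)
  if (restarts > 0L) with_local_seed(20240601L, {
    u0 <- to_unconstrained(best$par, model$lower, model$upper)
    for (k in seq_len(restarts)) {
      uk <- u0 + stats::rnorm(length(u0), sd = 0.15)
      cand <- optim_box(to_constrained(uk, model$lower, model$upper), rss_of,
                        model$lower, model$upper,
                        maxit = 300L * model$n_params)
      if (cand$value < best$value) best <- cand
    }
  })
  polish <- optim_box(best$par, rss_of, model$lower, model$upper,
                      maxit = 200L, method = "BFGS")
  if (polish$value < best$value) best <- polish
  N <- sum(nt)
  k <- model$n_params
  rss <- max(best$value, 0)
  sig <- max(rss / N, 1e-300)
  structure(list(model = model, params = best$par, rss = rss, n_obs = N,
                 aic = N * log(sig) + 2 * k, bic = N * log(sig) + k * log(N),
                 times_range = range(times)),
            class = "curve_fit")
}

#' Select the best-fitting curve by information criterion
#'
#' Fits each candidate by least squares and returns the fit minimising AIC
#' or BIC (Gaussian concentrated form). Ties are broken by fewer
#' parameters, then by candidate order.
#'
#' @param candidates List of \code{curve_model}s or registered names.
#' @param times,values As in \code{\link{fit_curve_ls}}.
#' @param criterion \code{"AIC"} or \code{"BIC"}.
#' @return The winning \code{curve_fit}.
#' @export
select_curve <- function(candidates, times, values, criterion = c("AIC", "BIC")) {
  criterion <- match.arg(criterion)
  stopifnot(length(candidates) >= 1L)
  fits <- lapply(candidates, function(cd)
    tryCatch(fit_curve_ls(cd, times, values), error = function(e) NULL))
  ok <- !vapply(fits, is.null, logical(1L))
  if (!any(ok)) stop("all candidate curve fits failed")
  fits <- fits[ok]
  crit <- vapply(fits, function(f) if (criterion == "AIC") f$aic else f$bic, 0)
  np <- vapply(fits, function(f) f$model$n_params, 0L)
  best <- order(crit, np, seq_along(fits))[1L]
  fits[[best]]
}

#' @export
print.curve_fit <- function(x, ...) {
  cat("<curve_fit>", x$model$name, " params:",
      paste(signif(x$params, 5), collapse = ", "),
      " rss:", signif(x$rss, 6), " AIC:", signif(x$aic, 6), "\n")
  invisible(x)
}
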