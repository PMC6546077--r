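.cov_registry <- new.env(parent = emptyenv())

#' Define a structured longitudinal covariance model
#'
#' A covariance model maps a parameter vector to an \code{m x m} symmetric
#' positive-definite matrix over the repeated measures. Bounds may depend
#' on the dimension \code{m} (e.g. compound symmetry), so \code{n_params}
#' and \code{bounds} are functions of \code{m}.
#'
#' @param name Unique model name.
#' @param n_params Integer, or function \code{(m) -> integer}.
#' @param build Function \code{(theta, m, times) -> matrix}.
#' @param bounds Function \code{(m) -> list(lower, upper)}; the matrix must
#'   be positive-definite for every theta strictly inside the box.
#' @param init Function \code{(residuals, times) -> theta}.
#' @return A \code{cov_model}.
#' @export
cov_model <- function(name, n_params, build, bounds, init) {
  stopifnot(is.character(name), length(name) == 1L)
  npf <- if (is.function(n_params)) n_params else function(m) as.integer(n_params)
  structure(list(name = name, n_params = npf, build = build,
                 bounds = bounds, init = init),
            class = "cov_model")
}

#' Register a covariance model
#' @param model A \code{cov_model}.
#' @param overwrite Replace an existing entry of the same name.
#' @export
register_covariance <- function(model, overwrite = FALSE) {
  stopifnot(inherits(model, "cov_model"))
  if (!overwrite && !is.null(.cov_registry[[model$name]]))
    stop("covariance model '", model$name, "' is already registered")
  assign(model$name, model, envir = .cov_registry)
  invisible(model)
}

#' @rdname register_covariance
#' @param name Registered model name.
#' @export
get_covariance <- function(name) {
  if (inherits(name, "cov_model")) return(name)
  m <- .cov_registry[[name]]
  if (is.null(m)) stop("unknown covariance model: ", name,
                       " (registered: ", paste(cov_names(), collapse = ", "), ")")
  m
}

#' @rdname register_covariance
#' @export
cov_names <- function() sort(ls(.cov_registry))

#' Build a structured covariance matrix by name
#'
#' @param name Registered covariance model name.
#' @param theta Parameter vector (within bounds).
#' @param m Number of repeated measures.
#' @param times Measurement times (used by time-distance structures).
#' @return An \code{m x m} symmetric positive-definite matrix.
#' @export
build_covariance <- function(name, theta, m, times = seq_len(m)) {
  model <- get_covariance(name)
  np <- model$n_params(m)
  if (length(theta) != np)
    stop(model$name, " expects ", np, " parameter(s), got ", length(theta))
  b <- model$bounds(m)
  if (any(theta < b$lower) || any(theta > b$upper))
    stop(model$name, " parameters outside bounds")
  S <- model$build(theta, m, times)
  if (max(abs(S - t(S))) > 1e-12) stop(model$name, " produced an asymmetric matrix")
  (S + t(S)) / 2
}

sad1_build <- function(v, phi, m) {
  # antedependence: y_t = phi_t y_{t-1} + e_t, e_t ~ N(0, v_t)
  # Sigma = C diag(v) C' with C[t,s] = prod(phi_{s+1..t}), t >= s
  C <- diag(1, m)
  if (m >= 2L) for (t in 2:m) for (s in 1:(t - 1L))
    C[t, s] <- prod(phi[s:(t - 1L)])   # phi[k] multiplies step k -> k+1
  C %*% (v * t(C))
}

register_builtin_covariances <- function() {
  eps <- 1e-8

  register_covariance(cov_model(
    "vc", 1L,
    build = function(th, m, times) diag(th[1L], m),
    bounds = function(m) list(lower = eps, upper = Inf),
    init = function(R, times) max(mean(R^2, na.rm = TRUE), eps)), overwrite = TRUE)

  register_covariance(cov_model(
    "cs", 2L,
    build = function(th, m, times)
      th[1L] * ((1 - th[2L]) * diag(m) + th[2L] * matrix(1, m, m)),
    bounds = function(m) list(lower = c(eps, -1 / max(m - 1, 1) + 1e-6),
                              upper = c(Inf, 1 - 1e-6)),
    init = function(R, times) {
      s2 <- max(mean(R^2, na.rm = TRUE), eps)
      c(s2, 0.1)
    }), overwrite = TRUE)

  ar1_init <- function(R, times) {
    s2 <- max(mean(R^2, na.rm = TRUE), eps)
    m <- ncol(R)
    rho <- if (m >= 2L) {
      num <- mean(R[, -m] * R[, -1L], na.rm = TRUE)
      min(max(num / s2, -0.9), 0.9)
    } else 0
    c(s2, rho)
  }

  register_covariance(cov_model(
    "ar1", 2L,
    build = function(th, m, times) {
      H <- abs(outer(seq_len(m), seq_len(m), "-"))
      th[1L] * th[2L]^H
    },
    bounds = function(m) list(lower = c(eps, -1 + 1e-6), upper = c(Inf, 1 - 1e-6)),
    init = ar1_init), overwrite = TRUE)

  # continuous-time AR(1): correlation decays with calendar-time distance
  register_covariance(cov_model(
    "ar1_time", 2L,
    build = function(th, m, times) {
      H <- abs(outer(times, times, "-"))
      th[1L] * th[2L]^H
    },
    bounds = function(m) list(lower = c(eps, eps), upper = c(Inf, 1 - 1e-6)),
    init = function(R, times) {
      th <- ar1_init(R, times)
      c(th[1L], max(abs(th[2L]), 0.05)^(1 / max(mean(diff(times)), 1e-6)))
    }), overwrite = TRUE)

  # ARMA(1,1) parameterised by the process parameters (sigma^2, phi, theta),
  # which guarantees positive-definiteness over the whole box; the implied
  # matrix is sigma^2 on the diagonal and sigma^2*gamma*phi^(|s-t|-1) off it,
  # with gamma = (1+phi*theta)(phi+theta)/(1+2*phi*theta+theta^2).
  register_covariance(cov_model(
    "arma11", 3L,
    build = function(th, m, times) {
      s2 <- th[1L]; phi <- th[2L]; tma <- th[3L]
      gam <- (1 + phi * tma) * (phi + tma) / (1 + 2 * phi * tma + tma^2)
      H <- abs(outer(seq_len(m), seq_len(m), "-"))
      S <- s2 * gam * phi^pmax(H - 1, 0)
      diag(S) <- s2
      S
    },
    bounds = function(m) list(lower = c(eps, -1 + 1e-6, -1 + 1e-6),
                              upper = c(Inf, 1 - 1e-6, 1 - 1e-6)),
    init = function(R, times) {
      th <- ar1_init(R, times)
      c(th[1L], th[2L], 0)
    }), overwrite = TRUE)

  # banded Toeplitz with free lag coefficients; strict diagonal dominance
  # (|c_k| < 1/(2*band)) keeps the whole bounds box positive-definite
  register_covariance(toeplitz_banded_covariance(2L), overwrite = TRUE)

  # first-order structured ante-dependence: innovation variances v_1..v_m
  # and lag coefficients phi_2..phi_m (2m-1 parameters)
  register_covariance(cov_model(
    "sad1", function(m) 2L * m - 1L,
    build = function(th, m, times)
      sad1_build(th[seq_len(m)], if (m >= 2L) th[(m + 1L):(2L * m - 1L)] else numeric(0), m),
    bounds = function(m) list(lower = c(rep(eps, m), rep(-5, m - 1L)),
                              upper = c(rep(Inf, m), rep(5, m - 1L))),
    init = function(R, times) {
      m <- ncol(R)
      v <- pmax(apply(R, 2L, stats::var, na.rm = TRUE), eps)
      phi <- numeric(m - 1L)
      for (t in seq_len(m - 1L)) {
        num <- mean(R[, t] * R[, t + 1L], na.rm = TRUE)
        den <- mean(R[, t]^2, na.rm = TRUE)
        phi[t] <- if (den > 0) min(max(num / den, -2), 2) else 0
      }
      c(v, phi)
    }), overwrite = TRUE)
}

#' Banded Toeplitz covariance with free lag coefficients
#'
#' \eqn{\Sigma_{st} = \sigma^2 c_{|s-t|}} for \eqn{|s-t| \le band} (with
#' \eqn{c_0 = 1}) and 0 beyond the band. Lag coefficients are bounded by
#' strict diagonal dominance (\eqn{|c_k| < 1/(2\,band)}) so every in-bounds
#' parameter vector yields a positive-definite matrix.
#'
#' @param band Number of free lags.
#' @param name Registry name.
#' @return A \code{cov_model}.
#' @export
toeplitz_banded_covariance <- function(band = 2L, name = "toeplitz") {
  band <- as.integer(band)
  stopifnot(band >= 1L)
  cmax <- 1 / (2 * band) - 1e-6
  cov_model(
    name, band + 1L,
    build = function(th, m, times) {
      lags <- c(1, th[-1L], rep(0, max(m - band - 1L, 0L)))[seq_len(m)]
      th[1L] * stats::toeplitz(lags)
    },
    bounds = function(m) list(lower = c(1e-8, rep(-cmax, band)),
                              upper = c(Inf, rep(cmax, band))),
    init = function(R, times) {
      s2 <- max(mean(R^2, na.rm = TRUE), 1e-8)
      cc <- numeric(band)
      for (k in seq_len(band)) {
        if (ncol(R) > k) {
          num <- mean(R[, seq_len(ncol(R) - k)] * R[, -seq_len(k)], na.rm = TRUE)
          cc[k] <- min(max(num / s2, -cmax + 1e-6), cmax - 1e-6)
        }
      }
      c(s2, cc)
    })
}

#' Multivariate normal log-density with missing-value marginalisation
#'
#' Evaluates the MVN log-density of \code{y} on its observed coordinates
#' only (rows/columns of \code{Sigma} are subset for missing entries).
#'
#' @param y Length-m observation (NAs allowed).
#' @param mean Length-m mean vector (or scalar).
#' @param Sigma \code{m x m} covariance, symmetric positive-definite on the
#'   observed coordinates.
#' @param id Optional label used in error messages.
#' @return The log-density (scalar).
#' @export
mvn_logpdf <- function(y, mean, Sigma, id = NULL) {
  obs <- !is.na(y)
  k <- sum(obs)
  if (k == 0L) return(0)
  if (length(mean) == 1L) mean <- rep(mean, length(y))
  d <- y[obs] - mean[obs]
  S <- Sigma[obs, obs, drop = FALSE]
  U <- tryCatch(chol(S), error = function(e)
    stop("covariance not positive-definite on observed coordinates",
         if (!is.null(id)) paste0(" for individual ", id) else ""))
  z <- backsolve(U, d, transpose = TRUE)
  -0.5 * (k * log(2 * pi) + 2 * sum(log(diag(U))) + sum(z^2))
}

# log-density of each row of residual matrix R (no missing values) under
# MVN(0, Sigma); one Cholesky shared across rows
mvn_logpdf_rows <- function(R, Sigma) {
  U <- chol(Sigma)
  z <- backsolve(U, t(R), transpose = TRUE)
  -0.5 * (ncol(R) * log(2 * pi) + 2 * sum(log(diag(U))) + colSums(z^2))
}

# ML objective for covariance parameters given a weighted scatter matrix S
# (sum_i w_i r_i r_i' / W): -W/2 * (m log 2pi + logdet Sigma + tr(Sigma^-1 S))
cov_profile_loglik <- function(theta, model, m, times, S, W) {
  Sg <- tryCatch(model$build(theta, m, times), error = function(e) NULL)
  if (is.null(Sg)) return(-Inf)
  U <- tryCatch(chol(Sg), error = function(e) NULL)
  if (is.null(U)) return(-Inf)
  logdet <- 2 * sum(log(diag(U)))
  tr <- sum(chol2inv(U) * S)
  -0.5 * W * (m * log(2 * pi) + logdet + tr)
}

# maximum-likelihood fit of one covariance structure to centred residuals
fit_cov_ml <- function(model, residuals, times, theta0 = NULL, maxit = NULL) {
  model <- get_covariance(model)
  m <- ncol(residuals)
  n <- nrow(residuals)
  b <- model$bounds(m)
  np <- model$n_params(m)
  theta0 <- theta0 %||% pmin(pmax(model$init(residuals, times),
                                  b$lower + 1e-6), b$upper - 1e-6)
  has_na <- anyNA(residuals)
  if (!has_na) {
    S <- crossprod(residuals) / n
    nll <- function(th) -cov_profile_loglik(th, model, m, times, S, n)
  } else {
    nll <- function(th) {
      Sg <- tryCatch(model$build(th, m, times), error = function(e) NULL)
      if (is.null(Sg)) return(Inf)
      v <- tryCatch(sum(vapply(seq_len(n), function(i)
        mvn_logpdf(residuals[i, ], 0, Sg), 0)), error = function(e) -Inf)
      -v
    }
  }
  best <- optim_box(theta0, nll, b$lower, b$upper,
                    maxit = maxit %||% (300L * np),
                    method = if (np > 4L) "BFGS" else NULL)
  ll <- -best$value
  structure(list(model = model, theta = best$par, loglik = ll,
                 aic = -2 * ll + 2 * np, n_params = np),
            class = "cov_fit")
}

#' Select a covariance structure by maximum likelihood
#'
#' Each candidate's parameters are estimated by numerical maximum
#' likelihood on centred residuals; the winner minimises AIC
#' (\code{criterion = "AIC"}) or maximises the log-likelihood outright
#' (\code{criterion = "MLE"}, which ignores parameter count and can
#' overfit). Ties are broken by fewer parameters, then candidate order.
#'
#' @param candidates List of \code{cov_model}s or registered names.
#' @param residuals \code{n x m} matrix of curve-removed residuals.
#' @param times Measurement times.
#' @param criterion \code{"AIC"} or \code{"MLE"}.
#' @return The winning \code{cov_fit} (fields \code{model}, \code{theta},
#'   \code{loglik}, \code{aic}).
#' @export
select_covariance <- function(candidates, residuals, times,
                              criterion = c("AIC", "MLE")) {
  criterion <- match.arg(criterion)
  stopifnot(length(candidates) >= 1L)
  fits <- lapply(candidates, function(cd)
    tryCatch(fit_cov_ml(cd, residuals, times), error = function(e) NULL))
  ok <- !vapply(fits, is.null, logical(1L))
  if (!any(ok)) stop("all candidate covariance fits failed")
  fits <- fits[ok]
  crit <- vapply(fits, function(f)
    if (criterion == "AIC") f$aic else -f$loglik, 0)
  np <- vapply(fits, function(f) f$n_params, 0L)
  fits[[order(crit, np, seq_along(fits))[1L]]]
}

#' @export
print.cov_fit <- function(x, ...) {
  cat("<cov_fit>", x$model$name, " theta:",
      paste(signif(x$theta, 4), collapse = ", "),
      " loglik:", signif(x$loglik, 7), " AIC:", signif(x$aic, 7), "\n")
  invisible(x)
}
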