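## Skew-t distribution (Azzalini location-scale parameterization) and a
## two-component mixture fitted by a generalized EM algorithm. Used to
## separate "guide present" from background in single-cell guide-UMI data.

#' Skew-t density
#'
#' Azzalini skew-t: `2/omega * t_nu(z) * T_{nu+1}(alpha z sqrt((nu+1)/(nu+z^2)))`
#' with `z = (x - xi)/omega`. With `alpha = 0` this reduces exactly to the
#' symmetric location-scale t density.
#'
#' @param x numeric vector
#' @param location location parameter `xi`
#' @param scale scale parameter `omega > 0`
#' @param df degrees of freedom `nu > 1`
#' @param alpha skewness parameter (0 = symmetric)
#' @param log return log-density
#' @return numeric vector of densities
#' @export
dskewt <- function(x, location, scale, df, alpha = 0, log = FALSE) {
  stopifnot(scale > 0, df > 0)
  z <- (x - location) / scale
  ld <- log(2) - log(scale) + dt(z, df, log = TRUE) +
    pt(alpha * z * sqrt((df + 1) / (df + z^2)), df + 1, log.p = TRUE)
  if (log) ld else exp(ld)
}

#' Sample from a skew-t distribution
#'
#' Skew-normal variate divided by the square root of an independent
#' scaled chi-square, then located and scaled.
#'
#' @inheritParams dskewt
#' @param n sample size
#' @return numeric vector
#' @export
rskewt <- function(n, location, scale, df, alpha = 0) {
  delta <- alpha / sqrt(1 + alpha^2)
  u0 <- abs(rnorm(n))
  u1 <- rnorm(n)
  sn <- delta * u0 + sqrt(1 - delta^2) * u1
  w <- rchisq(n, df) / df
  location + scale * sn / sqrt(w)
}

## parameter transform for unconstrained optimization
st_pack <- function(p) c(p$location, log(p$scale), log(p$df - 1), p$alpha)
st_unpack <- function(v) list(location = v[1L], scale = exp(v[2L]),
                              df = 1 + exp(v[3L]), alpha = v[4L])

#' Fit a two-component skew-t mixture by EM
#'
#' Generalized EM: exact E-step (posterior responsibilities) and weight
#' update; per-component location/scale/df/skewness updated by a
#' warm-started Nelder-Mead maximization of the responsibility-weighted
#' log-likelihood, which guarantees a monotone non-decreasing observed
#' log-likelihood. Initialization is quantile-based: observations above the
#' `1 - init_weight` quantile seed the upper ("present") component.
#' Convergence when `|dLL| < tol * (1 + |LL|)`.
#'
#' @param x numeric data vector
#' @param init_weight initial weight of the upper component (default 0.05)
#' @param tol log-likelihood convergence tolerance (default 1e-6)
#' @param max_iter maximum EM iterations (default 500)
#' @param seed optional RNG seed (the fit itself is deterministic; the seed
#'   guards any downstream stochastic use)
#' @return object of class `skewt_mixture`: `components` (data.frame with
#'   `location`, `scale`, `df`, `alpha`, `weight`; row order background
#'   then present, by location), `loglik`, `loglik_trace`, `converged`,
#'   `iterations`
#' @export
fit_skewt_mixture <- function(x, init_weight = 0.05, tol = 1e-6,
                              max_iter = 500L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- as.numeric(x[is.finite(x)])
  n <- length(x)
  if (n < 20L) stop("too few observations to fit a mixture")
  cut <- quantile(x, 1 - init_weight)
  grp <- list(x[x <= cut], x[x > cut])
  if (length(grp[[2L]]) < 5L) grp <- list(x[x <= median(x)], x[x > median(x)])
  comps <- lapply(grp, function(g)
    list(location = median(g), scale = max(sd(g), 1e-3), df = 5, alpha = 0))
  weights <- vapply(grp, length, numeric(1)) / n

  dens <- function(comps) vapply(comps, function(p)
    dskewt(x, p$location, p$scale, p$df, p$alpha), numeric(n))
  mix_ll <- function(d, w) sum(log(pmax(d %*% w, 1e-300)))

  d <- dens(comps)
  ll <- mix_ll(d, weights)
  trace <- ll
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    ## E-step
    wd <- sweep(d, 2L, weights, "*")
    resp <- wd / pmax(rowSums(wd), 1e-300)
    ## M-step
    weights <- pmax(colMeans(resp), 1e-6)
    weights <- weights / sum(weights)
    comps <- lapply(1:2, function(k) {
      r <- resp[, k]
      obj <- function(v) {
        p <- st_unpack(v)
        if (p$df > 200) p$df <- 200
        -sum(r * dskewt(x, p$location, p$scale, p$df, p$alpha, log = TRUE))
      }
      fit <- optim(st_pack(comps[[k]]), obj, method = "Nelder-Mead",
                   control = list(maxit = 60L))
      st_unpack(fit$par)
    })
    d <- dens(comps)
    new_ll <- mix_ll(d, weights)
    trace <- c(trace, new_ll)
    if (abs(new_ll - ll) < tol * (1 + abs(ll))) {
      ll <- new_ll
      converged <- TRUE
      break
    }
    ll <- new_ll
  }
  ord <- order(vapply(comps, `[[`, numeric(1), "location"))
  components <- do.call(rbind, lapply(comps[ord], as.data.frame))
  components$weight <- weights[ord]
  rownames(components) <- c("background", "present")
  structure(list(components = components, loglik = ll, loglik_trace = trace,
                 converged = converged, iterations = it),
            class = "skewt_mixture")
}

#' @export
print.skewt_mixture <- function(x, ...) {
  cat(sprintf("skew-t mixture: logLik %.3f after %d EM iterations (%s)\n",
              x$loglik, x$iterations,
              if (x$converged) "converged" else "NOT converged"))
  print(round(x$components, 4))
  invisible(x)
}

#' Posterior probability of the "present" component
#'
#' @param fit a [fit_skewt_mixture()] object
#' @param x numeric vector
#' @return numeric vector of posterior probabilities in `[0, 1]`
#' @export
posterior_present <- function(fit, x) {
  cmp <- fit$components
  d <- vapply(1:2, function(k)
    cmp$weight[k] * dskewt(x, cmp$location[k], cmp$scale[k], cmp$df[k],
                           cmp$alpha[k]), numeric(length(x)))
  d <- matrix(d, ncol = 2L)
  d[, 2L] / pmax(rowSums(d), 1e-300)
}
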