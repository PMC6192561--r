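# Gaussian mixture deconvolution of chromatogram profiles. Each profile is
# modelled as a sum of 1 to 5 Gaussian components fitted by bounded
# Levenberg-Marquardt least squares; the mixture size is selected by
# corrected AIC. Initialization is deterministic: the first component at the
# global apex, each further component at the largest absolute residual of
# the previous fit.

mixture_predict <- function(par, x) {
  k <- length(par) / 3L
  A <- par[seq(1, by = 3, length.out = k)]
  mu <- par[seq(2, by = 3, length.out = k)]
  sg <- par[seq(3, by = 3, length.out = k)]
  rowSums(vapply(seq_len(k),
                 function(i) A[i] * exp(-(x - mu[i])^2 / (2 * sg[i]^2)),
                 numeric(length(x))))
}

#' Deconvolve a chromatogram profile into a Gaussian mixture
#'
#' Fits `sum_i A_i * exp(-(x - mu_i)^2 / (2 sigma_i^2))` for mixture sizes
#' `k = 1..max_components` by bounded nonlinear least squares
#' (Levenberg-Marquardt) and returns the fit minimizing the corrected AIC.
#' Bounds: `mu` in `[-1, F + 2]`, `sigma` in `[0.5, F]`, `A` in
#' `[0, 2 * max(y)]`. Deterministic given the profile. On failure for every
#' `k`, falls back to a single component at the apex with a warning.
#'
#' @param a Cleaned profile (no missing values), length >= 5.
#' @param max_components Largest mixture size to try (1 to 5).
#' @return A `gaussian_mixture_fit`: list with `components` (data.frame
#'   `A`, `mu`, `sigma`), `k`, `r_squared`, `aicc`.
#' @export
fit_gaussian_mixture <- function(a, max_components = 5L) {
  F <- length(a)
  x <- seq_len(F)
  max_components <- max(1L, min(as.integer(max_components), 5L,
                                (F - 2L) %/% 3L))
  apex <- which.max(a)
  amax <- max(a)
  if (max(a) - min(a) <= 0) {
    warning("constant profile: falling back to a single apex component")
    out <- list(
      components = data.frame(A = max(amax, 0), mu = apex,
                              sigma = max(F / 4, 0.5)),
      k = 1L, r_squared = 0, aicc = NA_real_)
    class(out) <- "gaussian_mixture_fit"
    return(out)
  }
  lower1 <- c(0, -1, 0.5)
  upper1 <- c(max(2 * amax, 1e-6), F + 2, F)

  best <- NULL
  prev_par <- NULL
  worse <- 0L                     # consecutive AICc increases: early stop
  for (k in seq_len(max_components)) {
    init <- if (k == 1L) {
      c(max(amax, 1e-6), apex, 2)
    } else {
      resid <- a - mixture_predict(prev_par, x)
      c(prev_par, max(abs(resid[which.max(abs(resid))]), 1e-6),
        which.max(abs(resid)), 2)
    }
    init <- pmin(pmax(init, rep(lower1, k)), rep(upper1, k))
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nls.lm(
        par = init,
        fn = function(p) a - mixture_predict(p, x),
        lower = rep(lower1, k), upper = rep(upper1, k),
        control = minpack.lm::nls.lm.control(maxiter = 50))),
      error = function(e) NULL)
    if (is.null(fit)) next
    par <- fit$par
    prev_par <- par
    rss <- sum((a - mixture_predict(par, x))^2)
    p <- 3L * k
    if (F - p - 1L < 1L) break
    aicc <- F * log(max(rss, 1e-300) / F) + 2 * p +
      2 * p * (p + 1) / (F - p - 1)
    if (is.null(best) || aicc < best$aicc) {
      best <- list(par = par, k = k, rss = rss, aicc = aicc)
      worse <- 0L
    } else {
      # mixtures are nested, so AICc is near-unimodal in k: stop after two
      # consecutive increases rather than fitting all five sizes
      worse <- worse + 1L
      if (worse >= 2L) break
    }
  }
  if (is.null(best)) {
    warning("Gaussian mixture fit failed; falling back to apex component")
    best <- list(par = c(max(amax, 1e-6), apex, max(F / 4, 0.5)), k = 1L,
                 rss = sum((a - mean(a))^2), aicc = NA_real_)
  }
  tss <- sum((a - mean(a))^2)
  comp <- matrix(best$par, ncol = 3L, byrow = TRUE)
  out <- list(
    components = data.frame(A = comp[, 1], mu = comp[, 2], sigma = comp[, 3]),
    k = best$k,
    r_squared = if (tss > 0) max(0, min(1, 1 - best$rss / tss)) else 0,
    aicc = best$aicc
  )
  class(out) <- "gaussian_mixture_fit"
  out
}

#' Minimum distance between the components of two mixture fits
#'
#' Components are vectorized as `(mu, sigma, A)` triples; the feature is the
#' minimum Euclidean distance between any component of one fit and any
#' component of the other (centers dominate in practice).
#'
#' @param fa,fb `gaussian_mixture_fit` objects.
#' @return Non-negative scalar.
#' @export
min_gaussian_distance <- function(fa, fb) {
  ca <- fa$components; cb <- fb$components
  best <- Inf
  for (i in seq_len(nrow(ca))) {
    d2 <- (ca$mu[i] - cb$mu)^2 + (ca$sigma[i] - cb$sigma)^2 +
      (ca$A[i] - cb$A)^2
    best <- min(best, d2)
  }
  sqrt(best)
}

# Fit mixtures for every row of a cleaned matrix; rows with fewer than 5
# observed raw fractions get a NULL fit (feature missing).
fit_gaussian_mixtures <- function(cleaned, obs, max_components = 5L) {
  n <- nrow(cleaned)
  lapply(seq_len(n), function(i) {
    if (sum(obs[i, ]) < 5L) return(NULL)
    fit_gaussian_mixture(cleaned[i, ], max_components = max_components)
  })
}

# n x n matrix of minimum component distances; NA where either fit is NULL.
# Vectorized over pairs by padding every fit to a fixed component count.
pairwise_min_gaussian_distance <- function(fits) {
  n <- length(fits)
  kmax <- max(1L, vapply(fits, function(f) if (is.null(f)) 1L else nrow(f$components),
                         integer(1)))
  # pad slots get per-protein sentinel centers so pad-vs-pad and pad-vs-real
  # distances are always larger than any real component distance
  big <- 1e9
  pad <- function(idx, col, sentinel) {
    f <- fits[[idx]]
    v <- rep(if (sentinel) big * (1 + idx) else 0, kmax)
    if (!is.null(f)) v[seq_len(nrow(f$components))] <- f$components[[col]]
    v
  }
  pad_matrix <- function(col, sentinel) {
    m <- matrix(vapply(seq_len(n), pad, numeric(kmax), col = col,
                       sentinel = sentinel),
                nrow = kmax)          # explicit dims: kmax may be 1
    t(m)
  }
  MU <- pad_matrix("mu", sentinel = TRUE)
  SG <- pad_matrix("sigma", sentinel = FALSE)
  AA <- pad_matrix("A", sentinel = FALSE)
  out <- matrix(Inf, n, n)
  for (i in seq_len(kmax)) {
    for (j in seq_len(kmax)) {
      d2 <- outer(MU[, i], MU[, j], `-`)^2 +
        outer(SG[, i], SG[, j], `-`)^2 +
        outer(AA[, i], AA[, j], `-`)^2
      out <- pmin(out, d2)
    }
  }
  out <- sqrt(out)
  bad <- vapply(fits, is.null, logical(1))
  out[bad, ] <- NA_real_
  out[, bad] <- NA_real_
  out
}
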