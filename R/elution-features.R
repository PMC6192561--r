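# The six dataset-derived co-elution features computed for every
# co-quantified protein pair: Euclidean distance between cleaned profiles,
# raw-profile Pearson r and its P-value, cleaned-profile Pearson r, co-apex
# distance, and the minimum distance between fitted Gaussian components.

#' Filter an elution matrix
#'
#' Removes proteins quantified in three or fewer fractions (i.e. keeps
#' proteins with at least `min_fractions` non-missing values) and,
#' optionally, protein isoforms (accession-dash-number identifiers).
#'
#' @param matrix Proteins x fractions numeric matrix, `NA` missing.
#' @param min_fractions Minimum number of quantified fractions to retain.
#' @param drop_isoforms Drop identifiers matching `"-<digits>"` suffixes.
#' @return The filtered matrix (warns if empty).
#' @export
filter_proteins <- function(matrix, min_fractions = 4L, drop_isoforms = FALSE) {
  keep <- rowSums(!is.na(matrix)) >= min_fractions
  if (drop_isoforms) keep <- keep & !grepl("-[0-9]+$", rownames(matrix))
  out <- matrix[keep, , drop = FALSE]
  if (nrow(out) == 0L) warning("no proteins left after filtering")
  out
}

#' Euclidean distance between two complete profiles
#' @param a,b Numeric profiles of equal length, no missing values.
#' @return `sqrt(sum((a - b)^2))`.
#' @export
euclidean_distance <- function(a, b) {
  if (length(a) != length(b)) stop("profiles differ in length")
  sqrt(sum((a - b)^2))
}

#' Pearson correlation between raw profiles with its P-value
#'
#' Computed over jointly observed fractions only. The two-sided P-value
#' uses the t transform `t = r * sqrt((n - 2) / (1 - r^2))` with `n - 2`
#' degrees of freedom.
#'
#' @param a,b Numeric profiles of equal length; `NA` allowed.
#' @return `c(r, p)`; both `NA` when fewer than 3 co-observed fractions or
#'   a profile is constant over them.
#' @export
pearson_with_pvalue <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  n <- sum(ok)
  if (n < 3L) return(c(r = NA_real_, p = NA_real_))
  x <- a[ok]; y <- b[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(c(r = NA_real_, p = NA_real_))
  }
  r <- stats::cor(x, y)
  p <- r_to_pvalue(r, n)
  c(r = r, p = p)
}

r_to_pvalue <- function(r, n) {
  r2 <- pmin(r^2, 1 - 1e-15)
  tstat <- r * sqrt((n - 2) / (1 - r2))
  2 * stats::pt(-abs(tstat), df = n - 2)
}

#' Clean a chromatogram profile
#'
#' Isolated single missing values (both neighbors observed) are imputed
#' with the mean of the two flanking values; any remaining missing values
#' are replaced with independent draws from a zero-mean Gaussian whose sd
#' is `noise_floor` — by default 5% of the profile's maximum observed
#' value, i.e. near-zero noise relative to signal. Observed values are
#' never altered.
#'
#' @param a Numeric profile, `NA` missing.
#' @param noise_floor Sd of the replacement noise; default
#'   `0.05 * max(a, na.rm = TRUE)`.
#' @return Profile with no missing values (warns when all-missing).
#' @export
clean_profile <- function(a, noise_floor = NULL) {
  miss <- is.na(a)
  if (all(miss)) {
    warning("all-missing profile: returning pure noise")
    nf <- noise_floor %||% 0
    return(stats::rnorm(length(a), 0, nf))
  }
  nf <- noise_floor %||% max(0, 0.05 * max(a, na.rm = TRUE))
  out <- a
  F <- length(a)
  if (F >= 3L) {
    single <- which(miss[-c(1L, F)] & !miss[-c(F - 1L, F)] & !miss[-c(1L, 2L)]) + 1L
    out[single] <- (a[single - 1L] + a[single + 1L]) / 2
  }
  still <- is.na(out)
  if (any(still)) {
    out[still] <- if (nf > 0) stats::rnorm(sum(still), 0, nf) else 0
  }
  out
}

#' Co-apex distance between two profiles
#'
#' Absolute distance, in fractions, between the positions of the two
#' profiles' maxima. Ties take the earliest maximal fraction.
#'
#' @param a,b Cleaned profiles of equal length.
#' @return Non-negative integer distance.
#' @export
co_apex_distance <- function(a, b) {
  abs(which.max(a) - which.max(b))
}

#' Compute all six co-elution features for every protein pair
#'
#' One row per unordered pair with at least 3 jointly observed raw
#' fractions. Raw-profile Pearson r/P are computed on co-observed fractions;
#' the Euclidean distance, cleaned-profile Pearson r and co-apex distance
#' use the cleaned profiles; the Gaussian feature is the minimum distance
#' between any two fitted mixture components of the pair (missing where a
#' profile has fewer than 5 observed fractions or the fit degenerates).
#' Deterministic given `seed` (profile cleaning draws noise).
#'
#' @param matrix Filtered elution matrix.
#' @param seed RNG seed for profile cleaning.
#' @param max_components Maximum mixture size passed to
#'   [fit_gaussian_mixture()].
#' @return data.frame `(id_a, id_b, euclidean_distance, pearson_r,
#'   pearson_p, cleaned_pearson, coapex_distance, gaussian_min_distance)`,
#'   keyed on the sorted pair and sorted by it.
#' @export
build_pair_features <- function(matrix, seed = 1L, max_components = 5L) {
  empty <- data.frame(id_a = character(0), id_b = character(0),
                      euclidean_distance = numeric(0), pearson_r = numeric(0),
                      pearson_p = numeric(0), cleaned_pearson = numeric(0),
                      coapex_distance = numeric(0),
                      gaussian_min_distance = numeric(0),
                      stringsAsFactors = FALSE)
  if (nrow(matrix) < 2L) return(empty)
  matrix <- matrix[order(rownames(matrix)), , drop = FALSE]
  n <- nrow(matrix)

  obs <- !is.na(matrix)
  n_co <- tcrossprod(obs * 1)           # jointly observed fraction counts

  # raw-profile Pearson over co-observed fractions
  suppressWarnings(r_raw <- stats::cor(t(matrix), use = "pairwise.complete.obs"))

  # per-protein cleaning seeds: the imputation noise is a function of the
  # protein's identity, so reordering proteins permutes rows and nothing else
  cleaned <- t(vapply(rownames(matrix), function(id) {
    with_seed(derive_seed(seed, paste0("clean_", id)),
              clean_profile(matrix[id, ]))
  }, numeric(ncol(matrix))))
  d_euc <- as.matrix(stats::dist(cleaned))
  r_cln <- stats::cor(t(cleaned))
  apex <- apply(cleaned, 1L, which.max)
  d_apex <- abs(outer(apex, apex, `-`))

  fits <- fit_gaussian_mixtures(cleaned, obs, max_components = max_components)
  d_gauss <- pairwise_min_gaussian_distance(fits)

  idx <- utils::combn(n, 2L)
  i <- idx[1L, ]; j <- idx[2L, ]
  keep <- n_co[cbind(i, j)] >= 3L
  i <- i[keep]; j <- j[keep]
  ids <- rownames(matrix)
  r_ij <- r_raw[cbind(i, j)]
  out <- data.frame(
    id_a = ids[i], id_b = ids[j],
    euclidean_distance = d_euc[cbind(i, j)],
    pearson_r = r_ij,
    pearson_p = r_to_pvalue(r_ij, n_co[cbind(i, j)]),
    cleaned_pearson = r_cln[cbind(i, j)],
    coapex_distance = as.numeric(d_apex[cbind(i, j)]),
    gaussian_min_distance = d_gauss[cbind(i, j)],
    stringsAsFactors = FALSE
  )
  # degenerate raw correlations (constant over co-observed window) stay NA
  out$pearson_p[is.na(out$pearson_r)] <- NA_real_
  out[order(out$id_a, out$id_b), , drop = FALSE]
}

#' Names of the six dataset-derived features
#' @export
elution_feature_names <- c(
  "euclidean_distance", "pearson_r", "pearson_p", "cleaned_pearson",
  "coapex_distance", "gaussian_min_distance"
)
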