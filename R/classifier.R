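# Naive Bayes co-complex classifier. Pairs are labeled from a reference
# complex set (intra-complex = positive, inter-complex = negative), the
# classifier is trained in stratified k-fold cross-validation on any
# combination of feature columns, and pairs are ranked by their
# cross-validated posterior scores.

#' Label protein pairs from a reference complex set
#'
#' A pair is `positive` iff the two proteins co-occur in some complex,
#' `negative` iff both appear in the complex set but never together, and
#' `unlabeled` otherwise.
#'
#' @param table Pair feature table with `id_a`, `id_b` columns.
#' @param complexes Named list: complex id -> member vector (each >= 2
#'   members).
#' @return Factor of length `nrow(table)` with levels
#'   `positive, negative, unlabeled`.
#' @export
label_pairs <- function(table, complexes) {
  members <- unique(unlist(complexes, use.names = FALSE))
  intra <- unique(unlist(lapply(complexes, all_pair_keys), use.names = FALSE))
  key <- pair_key(table$id_a, table$id_b)
  lab <- rep("unlabeled", nrow(table))
  in_set <- table$id_a %in% members & table$id_b %in% members
  lab[in_set] <- "negative"
  lab[key %in% intra] <- "positive"
  lab <- factor(lab, levels = c("positive", "negative", "unlabeled"))
  if (sum(lab == "positive") == 0L || sum(lab == "negative") == 0L) {
    stop("training infeasible: need both positive and negative labeled pairs")
  }
  lab
}

# Per-feature class-conditional model. Binary features (values within
# {0, 1}) get Laplace-smoothed Bernoulli likelihoods; continuous features
# get Gaussian kernel densities with Silverman's bandwidth. Returns NULL
# for degenerate features (effectively constant, or too few observed
# values in a class).
fit_feature_model <- function(vpos, vneg) {
  vpos <- vpos[!is.na(vpos)]
  vneg <- vneg[!is.na(vneg)]
  pooled <- c(vpos, vneg)
  if (length(unique(pooled)) < 2L) return(NULL)
  if (all(pooled %in% c(0, 1))) {
    list(type = "binary",
         p_pos = (sum(vpos == 1) + 1) / (length(vpos) + 2),
         p_neg = (sum(vneg == 1) + 1) / (length(vneg) + 2))
  } else {
    if (length(vpos) < 2L || length(vneg) < 2L) return(NULL)
    bw_p <- tryCatch(stats::bw.nrd0(vpos), error = function(e) NA_real_)
    bw_n <- tryCatch(stats::bw.nrd0(vneg), error = function(e) NA_real_)
    fallback <- stats::bw.nrd0(pooled)
    if (!is.finite(bw_p) || bw_p <= 0) bw_p <- fallback
    if (!is.finite(bw_n) || bw_n <= 0) bw_n <- fallback
    if (!is.finite(bw_p) || bw_p <= 0) return(NULL)
    lo <- min(pooled) - 3 * max(bw_p, bw_n)
    hi <- max(pooled) + 3 * max(bw_p, bw_n)
    list(type = "kde",
         den_pos = stats::density(vpos, bw = bw_p, from = lo, to = hi, n = 512),
         den_neg = stats::density(vneg, bw = bw_n, from = lo, to = hi, n = 512))
  }
}

# Log likelihood ratio log f(v | +) - log f(v | -); missing values
# contribute 0 (a unit likelihood ratio: absence of evidence is neutral).
feature_llr <- function(fm, v) {
  out <- numeric(length(v))
  ok <- !is.na(v)
  if (!any(ok)) return(out)
  if (fm$type == "binary") {
    is1 <- ok & v == 1
    out[is1] <- log(fm$p_pos) - log(fm$p_neg)
    out[ok & v != 1] <- log(1 - fm$p_pos) - log(1 - fm$p_neg)
  } else {
    eps <- 1e-12
    fp <- stats::approx(fm$den_pos$x, fm$den_pos$y, xout = v[ok], rule = 2)$y
    fn <- stats::approx(fm$den_neg$x, fm$den_neg$y, xout = v[ok], rule = 2)$y
    out[ok] <- log(pmax(fp, eps)) - log(pmax(fn, eps))
  }
  out
}

#' Fit a naive Bayes co-complex classifier
#'
#' Estimates per-feature class-conditional likelihoods (continuous:
#' Gaussian-kernel density with Silverman bandwidth; binary:
#' Laplace-smoothed Bernoulli) and class priors from training frequencies.
#' Degenerate features are dropped with a warning.
#'
#' @param x data.frame of feature columns for the labeled training pairs
#'   (`NA` allowed; observed values only are used for estimation).
#' @param y Logical or factor: `TRUE`/`"positive"` for intra-complex pairs.
#' @return A `naive_bayes_model`.
#' @export
naive_bayes_fit <- function(x, y) {
  ispos <- if (is.logical(y)) y else y == "positive"
  if (sum(ispos) < 1L || sum(!ispos) < 1L) {
    stop("need both classes to fit")
  }
  models <- list()
  for (col in names(x)) {
    fm <- fit_feature_model(x[[col]][ispos], x[[col]][!ispos])
    if (is.null(fm)) {
      warning(sprintf("dropping degenerate feature '%s'", col))
    } else {
      models[[col]] <- fm
    }
  }
  if (length(models) == 0L) stop("no usable features")
  structure(list(features = models,
                 logit_prior = log(sum(ispos)) - log(sum(!ispos))),
            class = "naive_bayes_model")
}

#' Score pairs with a fitted naive Bayes model
#'
#' Posterior probability of the positive (co-complex) class under
#' conditional independence; missing feature values contribute a unit
#' likelihood ratio.
#'
#' @param model A `naive_bayes_model`.
#' @param newdata data.frame containing the model's feature columns.
#' @return Numeric vector of posterior scores in `(0, 1)`.
#' @export
naive_bayes_score <- function(model, newdata) {
  logit <- rep(model$logit_prior, nrow(newdata))
  for (col in names(model$features)) {
    logit <- logit + feature_llr(model$features[[col]], newdata[[col]])
  }
  stats::plogis(logit)
}

# Stratified fold assignment: within each class, pairs are shuffled and
# dealt round-robin into k folds. Unlabeled pairs get fold NA.
assign_folds <- function(labels, k, seed) {
  npos <- sum(labels == "positive")
  nneg <- sum(labels == "negative")
  if (k > min(npos, nneg)) {
    stop(sprintf("k = %d exceeds smallest class size %d", k, min(npos, nneg)))
  }
  fold <- rep(NA_integer_, length(labels))
  with_seed(seed, {
    for (cls in c("positive", "negative")) {
      idx <- which(labels == cls)
      fold[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
    }
  })
  fold
}

# Precompute, per feature, an n-pairs x k-folds matrix of log likelihood
# ratios, plus the per-fold training priors. The naive Bayes log-odds for
# any feature combination is then prior + the sum of the selected features'
# matrices, so a combination sweep refits nothing.
cv_feature_llr <- function(table, labels, k = 10L, seed = 1L,
                           feature_cols = NULL) {
  feature_cols <- feature_cols %||%
    setdiff(names(table), c("id_a", "id_b"))
  fold <- assign_folds(labels, k, seed)
  n <- nrow(table)
  llr <- lapply(stats::setNames(feature_cols, feature_cols),
                function(col) matrix(0, n, k))
  usable <- matrix(FALSE, length(feature_cols), k,
                   dimnames = list(feature_cols, NULL))
  logit_prior <- numeric(k)
  for (f in seq_len(k)) {
    train <- which(!is.na(fold) & fold != f)
    ispos <- labels[train] == "positive"
    logit_prior[f] <- log(sum(ispos)) - log(sum(!ispos))
    for (col in feature_cols) {
      fm <- fit_feature_model(table[[col]][train][ispos],
                              table[[col]][train][!ispos])
      if (!is.null(fm)) {
        llr[[col]][, f] <- feature_llr(fm, table[[col]])
        usable[col, f] <- TRUE
      }
    }
  }
  structure(list(llr = llr, usable = usable, logit_prior = logit_prior,
                 fold_of = fold, k = k, feature_cols = feature_cols),
            class = "cv_feature_llr")
}

# Combine precomputed per-fold LLRs into cross-validated pair scores for a
# feature combination. Scores are combined on the log-odds scale (the
# median commutes with the monotone logistic map) and returned as both the
# posterior and the log-odds, since posteriors saturate at 1 in double
# precision and would destroy the ranking among high-confidence pairs.
scores_from_llr <- function(pre, combination = NULL, labeled_in_fold = FALSE) {
  cols <- combination %||% pre$feature_cols
  missing_cols <- setdiff(cols, pre$feature_cols)
  if (length(missing_cols) > 0L) {
    stop(sprintf("feature '%s' not precomputed", missing_cols[1]))
  }
  n <- length(pre$fold_of)
  k <- pre$k
  S <- matrix(pre$logit_prior, n, k, byrow = TRUE)
  for (col in cols) S <- S + pre$llr[[col]]
  # row-wise median via a single radix sort of the whole matrix
  sorted <- matrix(S[order(row(S), S)], n, k, byrow = TRUE)
  logit <- if (k %% 2L == 1L) {
    sorted[, (k + 1L) %/% 2L]
  } else {
    (sorted[, k %/% 2L] + sorted[, k %/% 2L + 1L]) / 2
  }
  if (!labeled_in_fold) {
    labeled <- which(!is.na(pre$fold_of))
    logit[labeled] <- S[cbind(labeled, pre$fold_of[labeled])]
  }
  data.frame(score = stats::plogis(logit), logit = logit)
}

#' Cross-validated naive Bayes pair scores
#'
#' Labeled pairs are partitioned into `k` stratified folds; each fold's
#' model is trained on the remaining folds. Unlabeled pairs receive the
#' median of their `k` fold scores; labeled pairs receive, by default, the
#' score from the one model whose training set excluded them (out-of-fold
#' discipline — the literal median over all folds would leak training
#' labels; set `labeled_in_fold = TRUE` for that reading).
#'
#' @param table Pair feature table.
#' @param labels Factor from [label_pairs()].
#' @param k Number of folds.
#' @param seed Fold-assignment seed.
#' @param feature_cols Feature columns to use (default: all non-id columns).
#' @param labeled_in_fold Score labeled pairs by the fold median instead of
#'   out-of-fold.
#' @return data.frame `(id_a, id_b, score, logit, label)`; `score` is the
#'   posterior probability and `logit` the equivalent log-odds (used for
#'   ranking, since posteriors saturate at 1 in double precision).
#' @export
cross_validated_scores <- function(table, labels, k = 10L, seed = 1L,
                                   feature_cols = NULL,
                                   labeled_in_fold = FALSE) {
  pre <- cv_feature_llr(table, labels, k = k, seed = seed,
                        feature_cols = feature_cols)
  s <- scores_from_llr(pre, labeled_in_fold = labeled_in_fold)
  data.frame(id_a = table$id_a, id_b = table$id_b,
             score = s$score, logit = s$logit,
             label = labels, stringsAsFactors = FALSE)
}
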