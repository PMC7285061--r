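#' Ground-truth window labelling
#'
#' Keeps only windows from tasks whose self-report agrees with the
#' intended condition: stress-condition tasks rated strictly above 4 on
#' the 1-7 Likert scale and relaxation-condition tasks rated strictly
#' below 4. Ambiguous tasks (a rating of exactly 4, a low rating on a
#' stress task, an elevated rating on a relaxation task) and tasks with
#' no rating are excluded with a logged reason.
#'
#' @param table A [feature_table()].
#' @param meta A [session_meta()] or a list of them covering every
#'   participant in `table`.
#' @param stress_gt Keep stress tasks rated strictly above this (default 4).
#' @param relax_lt Keep relax tasks rated strictly below this (default 4).
#' @return The filtered [feature_table()] with binary labels.
#' @export
label_windows <- function(table, meta, stress_gt = 4, relax_lt = 4) {
  table <- feature_table(table)
  metas <- if (inherits(meta, "session_meta")) list(meta) else meta
  lut <- do.call(rbind, lapply(metas, function(m) {
    seg <- m$segments[m$segments$condition %in% c("stress", "relax"), ]
    if (!nrow(seg)) return(NULL)
    ratings <- m$ratings
    stress <- if (is.null(ratings)) rep(NA_integer_, nrow(seg)) else
      ratings$stress[match(seg$task_id, ratings$task_id)]
    data.frame(participant_id = m$participant_id, task_id = seg$task_id,
               condition = seg$condition, rating = stress)
  }))
  keep_key <- character(0)
  for (i in seq_len(nrow(lut))) {
    r <- lut[i, ]
    if (is.na(r$rating)) {
      fs_log("task %s/%s excluded: no stress rating", r$participant_id,
             r$task_id)
      next
    }
    ok <- (r$condition == "stress" && r$rating > stress_gt) ||
      (r$condition == "relax" && r$rating < relax_lt)
    if (!ok) {
      fs_log("task %s/%s excluded: %s task rated %d is ambiguous",
             r$participant_id, r$task_id, r$condition, r$rating)
      next
    }
    keep_key <- c(keep_key, paste(r$participant_id, r$task_id))
  }
  out <- table[paste(table$participant_id, table$task_id) %in% keep_key, ,
               drop = FALSE]
  feature_table(out)
}

#' Fit a two-class linear discriminant model
#'
#' Gaussian linear discriminant analysis for stress vs relaxation on a
#' named feature subset: class means, pooled within-class covariance and
#' empirical priors, with features z-scored by training-set statistics
#' first (mixed units - raw pressure, mm, g, Hz - make multi-feature
#' models scale-sensitive otherwise). A singular pooled covariance is
#' ridge-regularised (`1e-6 * mean(diag)`) and logged.
#'
#' @param table A labelled [feature_table()] (labels `stress` / `relax`).
#' @param features Character vector of feature names from `A1..D2`
#'   (no duplicates).
#' @param zscore Standardise features with training statistics.
#' @return A model of class `fs_lda`.
#' @export
fit_lda <- function(table, features, zscore = TRUE) {
  features <- validate_feature_subset(features)
  table <- feature_table(table)
  if (!all(table$label %in% c("stress", "relax")))
    stop("fit_lda needs binary stress/relax labels; run label_windows first")
  cls <- c("stress", "relax")
  counts <- table(factor(table$label, cls))
  if (any(counts < 2)) stop("need at least 2 rows per class")
  x <- as.matrix(table[, features, drop = FALSE])
  center <- if (zscore) colMeans(x) else rep(0, ncol(x))
  scale_ <- if (zscore) apply(x, 2L, stats::sd) else rep(1, ncol(x))
  scale_[!is.finite(scale_) | scale_ == 0] <- 1
  z <- sweep(sweep(x, 2L, center), 2L, scale_, "/")
  mu <- do.call(rbind, lapply(cls, function(k)
    colMeans(z[table$label == k, , drop = FALSE])))
  rownames(mu) <- cls
  ss <- Reduce(`+`, lapply(cls, function(k) {
    zk <- sweep(z[table$label == k, , drop = FALSE], 2L, mu[k, ])
    crossprod(zk)
  }))
  sigma <- ss / (nrow(z) - 2L)
  inv <- tryCatch(solve(sigma), error = function(e) NULL)
  if (is.null(inv) || rcond(sigma) < 1e-12) {
    lambda <- 1e-6 * mean(diag(sigma))
    if (lambda <= 0) lambda <- 1e-6
    fs_log("pooled covariance singular; ridge lambda = %g applied", lambda)
    sigma <- sigma + diag(lambda, ncol(sigma))
    inv <- solve(sigma)
  }
  m <- list(features = features, classes = cls,
            center = center, scale = scale_,
            means = mu, sigma = sigma, sigma_inv = inv,
            priors = as.numeric(counts) / sum(counts), zscore = zscore)
  class(m) <- "fs_lda"
  m
}

validate_feature_subset <- function(features) {
  features <- as.character(features)
  if (!length(features)) stop("feature subset must be non-empty")
  bad <- setdiff(features, FEATURE_NAMES)
  if (length(bad)) stop("unknown feature(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(features))
    stop("duplicate feature(s) in subset: ",
         paste(unique(features[duplicated(features)]), collapse = ", "))
  features
}

#' Predict stress/relaxation labels
#'
#' Applies the fitted discriminant to new feature rows. The score is the
#' difference of the two class discriminants (stress minus relax); a
#' positive score classifies stress, and an exact tie resolves to the
#' conservative `relax`.
#'
#' @param object An `fs_lda` model.
#' @param newdata Data frame containing the model's feature columns.
#' @param ... Unused.
#' @return Data frame with columns `label` and `score`, one row per input.
#' @export
predict.fs_lda <- function(object, newdata, ...) {
  miss <- setdiff(object$features, names(newdata))
  if (length(miss))
    stop("newdata is missing model feature(s): ", paste(miss, collapse = ", "))
  x <- as.matrix(as.data.frame(newdata)[, object$features, drop = FALSE])
  z <- sweep(sweep(x, 2L, object$center), 2L, object$scale, "/")
  delta <- vapply(seq_along(object$classes), function(k) {
    mk <- object$means[k, ]
    drop(z %*% object$sigma_inv %*% mk) -
      0.5 * drop(mk %*% object$sigma_inv %*% mk) + log(object$priors[k])
  }, numeric(nrow(z)))
  if (nrow(z) == 1L) delta <- matrix(delta, nrow = 1L)
  score <- delta[, 1] - delta[, 2]
  data.frame(label = ifelse(score > 0, "stress", "relax"), score = score)
}

#' Save / load a fitted model (JSON)
#'
#' @param model An `fs_lda` model.
#' @param path JSON file path.
#' @return The model for the reader; `path` invisibly for the writer.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "fs_lda"))
  out <- list(features = model$features, classes = model$classes,
              center = unname(model$center), scale = unname(model$scale),
              means = unname(model$means), sigma = unname(model$sigma),
              priors = model$priors, zscore = model$zscore)
  jsonlite::write_json(out, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  d <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- length(d$features)
  sigma <- matrix(as.numeric(d$sigma), p, p,
                  dimnames = list(d$features, d$features))
  m <- list(features = d$features, classes = d$classes,
            center = stats::setNames(as.numeric(d$center), d$features),
            scale = stats::setNames(as.numeric(d$scale), d$features),
            means = matrix(as.numeric(d$means), 2L, p,
                           dimnames = list(d$classes, d$features)),
            sigma = sigma, sigma_inv = solve(sigma),
            priors = as.numeric(d$priors), zscore = isTRUE(d$zscore[1]))
  class(m) <- "fs_lda"
  m
}

#' Assert train/test user disjointness in a cross-validation fold
#'
#' Hard guard used by [leave_one_user_out()] before each fold is fitted:
#' any participant appearing in both the training and the held-out set
#' aborts with an error naming the leaked ids.
#'
#' @param train_ids,test_ids Character vectors of participant ids.
#' @return `TRUE`, invisibly.
#' @export
assert_fold_disjoint <- function(train_ids, test_ids) {
  leaked <- intersect(unique(train_ids), unique(test_ids))
  if (length(leaked))
    stop("leave-one-user-out violation: participant(s) ",
         paste(leaked, collapse = ", "),
         " present in both training and test data")
  invisible(TRUE)
}

#' Leave-one-user-out evaluation
#'
#' One fold per participant: the model is fitted on every other user's
#' windows and tested on the held-out user's windows, with a hard
#' provenance assertion ([assert_fold_disjoint()]) per fold. Reports the
#' per-user window accuracy (percent), its mean and SD across users, an
#' accuracy curve indexed by window position within task (averaged over
#' users and tasks), and the paired separation test between conditions.
#'
#' @param table A labelled [feature_table()] with at least 3 participants.
#' @param features Feature subset to evaluate.
#' @param zscore Standardise per training fold.
#' @return A list of class `fs_louo_report`: `feature_subset`, `per_user`,
#'   `mean_accuracy`, `sd_accuracy`, `curve`, `p_separation`.
#' @export
leave_one_user_out <- function(table, features, zscore = TRUE) {
  features <- validate_feature_subset(features)
  table <- feature_table(table)
  users <- unique(table$participant_id)
  if (length(users) < 3)
    stop("leave-one-user-out needs at least 3 participants, got ",
         length(users))
  # window position within its task, for the accuracy curve
  key <- paste(table$participant_id, table$task_id)
  widx <- stats::ave(table$window_start_s, key, FUN = rank)
  per_user <- list()
  curve_hits <- list()
  sep <- list()
  for (u in users) {
    test <- table$participant_id == u
    if (!any(test)) {
      fs_log("user %s skipped: no labelled windows", u)
      next
    }
    assert_fold_disjoint(table$participant_id[!test],
                         table$participant_id[test])
    model <- fit_lda(table[!test, , drop = FALSE], features, zscore = zscore)
    pred <- predict(model, table[test, , drop = FALSE])
    correct <- pred$label == table$label[test]
    per_user[[u]] <- data.frame(participant_id = u, n_windows = sum(test),
                                accuracy = 100 * mean(correct))
    curve_hits[[u]] <- data.frame(window_index = widx[test],
                                  correct = correct)
    sep[[u]] <- data.frame(
      participant_id = u,
      stress_frac = mean(pred$label[table$label[test] == "stress"] == "stress"),
      relax_frac = mean(pred$label[table$label[test] == "relax"] == "stress"))
  }
  per_user <- do.call(rbind, per_user)
  rownames(per_user) <- NULL
  hits <- do.call(rbind, curve_hits)
  curve <- stats::aggregate(correct ~ window_index, hits,
                            function(v) 100 * mean(v))
  names(curve) <- c("window_index", "accuracy")
  curve$n <- stats::aggregate(correct ~ window_index, hits, length)$correct
  sep <- do.call(rbind, sep)
  p_sep <- separation_test(sep$stress_frac, sep$relax_frac)
  rep <- list(feature_subset = features, per_user = per_user,
              mean_accuracy = mean(per_user$accuracy),
              sd_accuracy = stats::sd(per_user$accuracy),
              curve = curve, p_separation = p_sep)
  class(rep) <- "fs_louo_report"
  rep
}

#' @export
print.fs_louo_report <- function(x, ...) {
  cat(sprintf("<leave-one-user-out: %s | mean accuracy %.1f%% (SD %.1f) over %d users | separation p = %.3g>\n",
              paste(x$feature_subset, collapse = "+"), x$mean_accuracy,
              x$sd_accuracy, nrow(x$per_user), x$p_separation))
  invisible(x)
}

#' Separation-sharpness test
#'
#' Two-sided paired t-test on per-user summaries of the two conditions
#' (typically the fraction of windows classified as stressed under stress
#' vs relaxation tasks). Degenerate cases are resolved explicitly: fewer
#' than 3 complete pairs is undefined (`NA`, flagged); identical paired
#' values give p = 1; a constant nonzero difference (zero variance) gives
#' p = 0, flagged.
#'
#' @param stress,relax Paired numeric vectors, one entry per user.
#' @return The two-sided p-value.
#' @export
separation_test <- function(stress, relax) {
  ok <- stats::complete.cases(stress, relax)
  d <- stress[ok] - relax[ok]
  if (length(d) < 3) {
    fs_log("separation test undefined: only %d complete pairs", length(d))
    return(NA_real_)
  }
  if (all(d == 0)) return(1)
  if (stats::sd(d) == 0) {
    fs_log("separation test: constant nonzero paired difference, p -> 0")
    return(0)
  }
  stats::t.test(stress[ok], relax[ok], paired = TRUE)$p.value
}

#' Evaluate the standard model grid
#'
#' Runs [leave_one_user_out()] for each candidate feature subset - the
#' ten singletons, the four-feature combination A1+B2+C3+D1, the pair
#' C3+A1 and ALL ten features by default - and ranks the models by mean
#' accuracy.
#'
#' @param table A labelled [feature_table()].
#' @param subsets Named list of feature subsets (no duplicates within a
#'   subset).
#' @param zscore Standardise per training fold.
#' @return A list with `summary` (data frame ranked by mean accuracy) and
#'   `reports` (named list of `fs_louo_report`).
#' @export
model_grid <- function(table, subsets = default_model_grid(), zscore = TRUE) {
  stopifnot(is.list(subsets), length(subsets) > 0)
  reports <- lapply(subsets, function(fs)
    leave_one_user_out(table, fs, zscore = zscore))
  summary <- data.frame(
    model = names(subsets),
    mean_accuracy = vapply(reports, `[[`, numeric(1), "mean_accuracy"),
    sd_accuracy = vapply(reports, `[[`, numeric(1), "sd_accuracy"),
    p_separation = vapply(reports, `[[`, numeric(1), "p_separation"))
  summary <- summary[order(-summary$mean_accuracy), ]
  rownames(summary) <- NULL
  list(summary = summary, reports = reports)
}

#' @rdname model_grid
#' @export
default_model_grid <- function() {
  singles <- stats::setNames(as.list(FEATURE_NAMES), FEATURE_NAMES)
  c(singles,
    list("A1+B2+C3+D1" = c("A1", "B2", "C3", "D1"),
         "C3+A1" = c("C3", "A1"),
         "ALL" = FEATURE_NAMES))
}
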