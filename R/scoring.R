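## Logistic-regression dexterity scoring.
##
## Trials are classified success/failure from their movement features (plus
## a final-position covariate when a target is known); the fitted sigmoid
## probability is used as a continuous dexterity score per trial. The fit
## is an L2-penalized Bernoulli maximum likelihood solved by Newton
## iterations — deterministic, no stochastic optimizer.

#' Build a standardized design matrix from features and outcomes
#'
#' One row per trial: the eight movement metrics plus, when `target_mm`
#' and per-trial final positions are supplied, the Euclidean distance from
#' the trajectory endpoint to the target ("final instrument position"
#' covariate). Columns are standardized to mean 0, SD 1; constant columns
#' are dropped with a warning. Labels are 1 for success.
#'
#' @param features data.frame of stacked [summarize_trial()] rows.
#' @param outcomes data.frame with `trial_id` and `success` (logical), one
#'   row per trial.
#' @param final_positions Optional n x 3 matrix of trajectory endpoints, mm.
#' @param target_mm Optional length-3 target position, mm.
#' @return List: `X` (standardized matrix), `y` (0/1), `center`, `scale`,
#'   `feature_names`, `trial_id`.
#' @export
build_design <- function(features, outcomes, final_positions = NULL,
                         target_mm = NULL) {
  ord <- match(features$trial_id, outcomes$trial_id)
  if (any(is.na(ord)))
    stop("missing outcomes for trials: ",
         paste(features$trial_id[is.na(ord)], collapse = ", "))
  outcomes <- outcomes[ord, ]
  cols <- metric_columns()
  raw <- as.matrix(features[, cols])
  if (any(!is.finite(raw))) {
    bad <- features$trial_id[!stats::complete.cases(raw)]
    stop("missing feature values for trials: ", paste(bad, collapse = ", "))
  }
  if (!is.null(final_positions) && !is.null(target_mm)) {
    fp <- matrix(final_positions, ncol = 3)
    dist <- sqrt(rowSums(sweep(fp, 2, as.numeric(target_mm))^2))
    raw <- cbind(raw, final_target_distance_mm = dist)
    cols <- c(cols, "final_target_distance_mm")
  }
  ctr <- colMeans(raw)
  scl <- apply(raw, 2, stats::sd)
  keep <- scl > 1e-12
  if (any(!keep))
    warning("dropping constant feature columns: ",
            paste(cols[!keep], collapse = ", "))
  X <- sweep(sweep(raw[, keep, drop = FALSE], 2, ctr[keep]), 2,
             scl[keep], `/`)
  list(X = X, y = as.integer(outcomes$success),
       center = ctr[keep], scale = scl[keep],
       feature_names = cols[keep], trial_id = features$trial_id)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Fit an L2-penalized logistic regression
#'
#' Maximizes `sum_i [y_i log p_i + (1 - y_i) log(1 - p_i)] -
#' l2_strength/2 * |w|^2` (intercept unpenalized) by damped Newton
#' iterations to a gradient-norm tolerance of 1e-8. Deterministic given
#' its inputs. With `l2_strength = 0` and linearly separable classes the
#' optimum diverges; this is detected and reported as an error advising a
#' penalty.
#'
#' @param design List from [build_design()] (or any list with `X`, `y`,
#'   `center`, `scale`, `feature_names`).
#' @param l2_strength Ridge penalty on the weights, >= 0. Default 1.
#' @param max_iter Newton iteration cap.
#' @return A `dexterity_model`: weights, intercept, standardization,
#'   feature names, training metadata.
#' @export
fit_logistic <- function(design, l2_strength = 1, max_iter = 100) {
  X <- design$X; y <- design$y
  stopifnot(nrow(X) == length(y), l2_strength >= 0)
  if (l2_strength == 0 && length(unique(y)) < 2)
    stop("need at least one example of each class unless l2_strength > 0")
  p <- ncol(X)
  beta <- rep(0, p + 1)            # (intercept, weights)
  Xi <- cbind(1, X)
  pen <- c(0, rep(l2_strength, p))
  for (it in seq_len(max_iter)) {
    eta <- as.numeric(Xi %*% beta)
    mu <- sigmoid(eta)
    grad <- as.numeric(crossprod(Xi, y - mu)) - pen * beta
    if (sqrt(sum(grad^2)) < 1e-8) break
    W <- mu * (1 - mu)
    H <- crossprod(Xi * sqrt(W)) + diag(pen + 1e-12, p + 1)
    step <- tryCatch(solve(H, grad), error = function(e) NULL)
    if (is.null(step)) stop("singular Hessian in logistic fit")
    # backtracking to keep the objective increasing
    obj <- function(b) {
      e <- as.numeric(Xi %*% b)
      sum(y * e - log1p(exp(e))) - sum(pen * b^2) / 2
    }
    f0 <- obj(beta); s <- 1
    while (obj(beta + s * step) < f0 && s > 1e-8) s <- s / 2
    beta <- unname(beta + s * step)
    if (l2_strength == 0 && max(abs(beta)) > 50)
      stop("perfect separation: logistic weights diverge; ",
           "use l2_strength > 0")
  }
  eta <- as.numeric(Xi %*% beta)
  if (l2_strength == 0 && all((eta > 0) == (y == 1)) &&
      max(abs(beta)) > 30)
    # the hyperplane classifies every example correctly with saturated
    # weights: the data are linearly separable and the unpenalized
    # maximum-likelihood weights diverge (the gradient only vanishes
    # because the sigmoid saturates in floating point)
    stop("perfect separation: logistic weights diverge; ",
         "use l2_strength > 0")
  if (sqrt(sum(grad^2)) >= 1e-8)
    warning("logistic fit did not reach gradient tolerance 1e-8")
  structure(list(intercept = beta[1],
                 weights = stats::setNames(beta[-1], design$feature_names),
                 feature_names = design$feature_names,
                 center = design$center, scale = design$scale,
                 l2_strength = l2_strength, n_train = length(y),
                 iterations = it),
            class = "dexterity_model")
}

#' @export
print.dexterity_model <- function(x, ...) {
  cat(sprintf("dexterity_model: %d features, l2=%g, n=%d\n",
              length(x$weights), x$l2_strength, x$n_train))
  invisible(x)
}

#' Score trials and rank by dexterity
#'
#' Applies the model's stored standardization to raw feature rows and
#' returns sigmoid scores in (0, 1), ranked descending; ties broken by
#' trial_id (deterministic).
#'
#' @param model A `dexterity_model`.
#' @param features data.frame of raw feature rows (same columns as used at
#'   fit time; `final_target_distance_mm` supplied via `final_positions` /
#'   `target_mm` as in [build_design()]).
#' @param final_positions,target_mm As in [build_design()].
#' @return data.frame sorted by descending score: trial_id, score, rank.
#' @export
score_and_rank <- function(model, features, final_positions = NULL,
                           target_mm = NULL) {
  cols <- model$feature_names
  raw <- as.matrix(features[, setdiff(cols, "final_target_distance_mm"),
                            drop = FALSE])
  if ("final_target_distance_mm" %in% cols) {
    if (is.null(final_positions) || is.null(target_mm))
      stop("model expects the final-position covariate; ",
           "supply final_positions and target_mm")
    fp <- matrix(final_positions, ncol = 3)
    raw <- cbind(raw, final_target_distance_mm =
                   sqrt(rowSums(sweep(fp, 2, as.numeric(target_mm))^2)))
  }
  if (!identical(colnames(raw), cols)) {
    if (!all(cols %in% colnames(raw)))
      stop("feature mismatch with model: need ",
           paste(cols, collapse = ", "))
    raw <- raw[, cols, drop = FALSE]
  }
  Z <- sweep(sweep(raw, 2, model$center), 2, model$scale, `/`)
  score <- sigmoid(as.numeric(Z %*% model$weights) + model$intercept)
  out <- data.frame(trial_id = features$trial_id, score = score,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$trial_id), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Completion rate for a condition
#'
#' @param outcomes data.frame with `condition` and `success` columns (as
#'   written by [write_outcomes_csv()]).
#' @param condition Condition label, e.g. "palpation" or "radioguided".
#' @return Percentage of successful trials, 0-100.
#' @export
completion_rate <- function(outcomes, condition) {
  sel <- outcomes$condition == condition
  if (!any(sel)) stop("no outcomes for condition ", condition)
  100 * sum(outcomes$success[sel]) / sum(sel)
}

#' Trial outcome table I/O
#'
#' Columns: trial_id, subject, condition, success, time_to_detection_s
#' (NA unless success, and never above the trial time limit).
#'
#' @param outcomes data.frame of outcomes.
#' @param path File path.
#' @export
write_outcomes_csv <- function(outcomes, path) {
  utils::write.csv(outcomes, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_outcomes_csv
#' @param time_limit_s Validation cutoff for detection times.
#' @export
read_outcomes_csv <- function(path, time_limit_s = 40) {
  df <- utils::read.csv(path)
  if (!all(c("condition", "success") %in% names(df)))
    stop("outcomes CSV needs condition and success columns")
  df$success <- as.logical(df$success)
  if ("time_to_detection_s" %in% names(df)) {
    bad <- !is.na(df$time_to_detection_s) &
      (df$time_to_detection_s > time_limit_s | !df$success)
    if (any(bad)) stop("invalid time_to_detection_s rows: ",
                       paste(which(bad), collapse = ", "))
  }
  df
}

#' Dexterity model JSON I/O
#' @param model A `dexterity_model`.
#' @param path File path.
#' @export
write_model_json <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$center <- stats::setNames(as.numeric(obj$center), obj$feature_names)
  obj$scale <- stats::setNames(as.numeric(obj$scale), obj$feature_names)
  structure(obj, class = "dexterity_model")
}

#' Leave-one-out accuracy of the dexterity classifier
#'
#' Refits the model with each trial held out and scores it; accuracy is the
#' fraction of held-out trials classified correctly at the 0.5 threshold.
#' Intended for the tiny-n regime where a train/test split is impossible.
#'
#' @param design List from [build_design()].
#' @param l2_strength Ridge penalty.
#' @return Scalar accuracy in [0, 1].
#' @export
loo_accuracy <- function(design, l2_strength = 1) {
  n <- nrow(design$X)
  correct <- logical(n)
  for (i in seq_len(n)) {
    d <- list(X = design$X[-i, , drop = FALSE], y = design$y[-i],
              center = design$center, scale = design$scale,
              feature_names = design$feature_names)
    m <- fit_logistic(d, l2_strength)
    p <- sigmoid(sum(design$X[i, ] * m$weights) + m$intercept)
    correct[i] <- (p >= 0.5) == (design$y[i] == 1)
  }
  mean(correct)
}
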