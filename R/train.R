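## Model training: weighted SVM backend, k-fold cross-validation, grid
## search, greedy feature-group elimination, holdout discard/reliability
## rules, Platt calibration and the final refit.

#' Kernel specification
#' @param kind `"linear"` or `"rbf"`.
#' @param C cost parameter (> 0).
#' @param gamma RBF width (> 0; `NULL` for linear kernels).
#' @return an `fp_kernel` list.
#' @export
kernel_spec <- function(kind = c("linear", "rbf"), C = 1, gamma = NULL) {
  kind <- match.arg(kind)
  if (C <= 0) stop("C must be positive")
  if (kind == "rbf" && (is.null(gamma) || gamma <= 0))
    stop("rbf kernel needs a positive gamma")
  if (kind == "linear") gamma <- NULL
  structure(list(kind = kind, C = C, gamma = gamma), class = "fp_kernel")
}

#' Default hyper-parameter grid
#'
#' Exhaustive search ranges for the kernel grid: `C` over powers of two
#' from 2^-5 to 2^7 and `gamma` from 2^-9 to 2^1 (both step 2^2).  The
#' expansion order encodes the tie-break rule: linear kernels before RBF,
#' then smaller `C`, then smaller `gamma`.
#'
#' @param linear_C,rbf_C,rbf_gamma numeric vectors of candidate values.
#' @return list of [kernel_spec()]s in tie-break order.
#' @export
default_grid <- function(linear_C = 2^seq(-5, 7, 2),
                         rbf_C = 2^seq(-5, 7, 2),
                         rbf_gamma = 2^seq(-9, 1, 2)) {
  grid <- lapply(sort(linear_C), function(C) kernel_spec("linear", C))
  for (C in sort(rbf_C)) for (g in sort(rbf_gamma))
    grid <- c(grid, list(kernel_spec("rbf", C, g)))
  grid
}

# Weighted binary large-margin fit.  Labels y are +1/-1; errors on the
# positive class are weighted by `weight_pos` (the SVM-Light j rule:
# ratio of negative to positive training examples).  The classifier is
# stored as plain arrays (support vectors, coefficients, offset) so the
# decision function survives JSON round-trips.
.fit_svm <- function(x, y, spec, weight_pos) {
  yf <- factor(ifelse(y > 0, "pos", "neg"), levels = c("pos", "neg"))
  m <- e1071::svm(x, yf, scale = FALSE, cost = spec$C,
                  kernel = if (spec$kind == "rbf") "radial" else "linear",
                  gamma = if (spec$kind == "rbf") spec$gamma else 1 / ncol(x),
                  class.weights = c(pos = weight_pos, neg = 1))
  list(kind = spec$kind,
       gamma = if (spec$kind == "rbf") spec$gamma else NULL,
       sv = unname(as.matrix(m$SV)),
       coefs = as.numeric(m$coefs),
       rho = as.numeric(m$rho))
}

# decision values; positive means predicted positive class
.decision <- function(clf, x) {
  x <- as.matrix(x)
  if (clf$kind == "linear") {
    as.numeric(x %*% crossprod(clf$sv, clf$coefs) - clf$rho)
  } else {
    sq <- outer(rowSums(x^2), rowSums(clf$sv^2), "+") - 2 * tcrossprod(x, clf$sv)
    as.numeric(exp(-clf$gamma * pmax(sq, 0)) %*% clf$coefs - clf$rho)
  }
}

#' k-fold cross-validation of one kernel configuration
#'
#' Rotates over the k homology groups: fold i trains on all other groups
#' (positives and negatives pooled) and tests on group i.  Feature scaling
#' is fit within each training fold only; the class-imbalance weight on
#' positive errors is the ratio of negative to positive training examples.
#' The reported MCC comes from the confusion counts pooled across folds.
#'
#' @param pos_groups,neg_groups lists of k accession vectors.
#' @param features full `fp_features` matrix (unscaled).
#' @param spec an [kernel_spec()].
#' @param retain feature-group names to keep, or `NULL` for all.
#' @return an `fp_cv`: list with `fold_counts`, `pooled`, `mcc`,
#'   `sensitivity`, `specificity`, `precision` and `decisions`
#'   (data.frame `accession`, `f`, `y` of cross-validated decision values).
#' @export
cross_validate <- function(pos_groups, neg_groups, features, spec,
                           retain = NULL) {
  k <- length(pos_groups)
  if (length(neg_groups) != k)
    stop("positive and negative plans must share the same k")
  fm <- if (is.null(retain)) features
        else drop_groups(features, setdiff(.layout(features)$name, retain))
  fold_counts <- vector("list", k)
  dec <- vector("list", k)
  for (i in seq_len(k)) {
    tr_pos <- unlist(pos_groups[-i], use.names = FALSE)
    tr_neg <- unlist(neg_groups[-i], use.names = FALSE)
    te_pos <- pos_groups[[i]]; te_neg <- neg_groups[[i]]
    if (k == 1L) { tr_pos <- te_pos; tr_neg <- te_neg }  # degenerate path
    sc <- fit_scaling(fm[tr_pos_neg <- c(tr_pos, tr_neg), , drop = FALSE])
    xtr <- apply_scaling(sc, fm[tr_pos_neg, , drop = FALSE])
    ytr <- c(rep(1, length(tr_pos)), rep(-1, length(tr_neg)))
    clf <- .fit_svm(xtr, ytr, spec, length(tr_neg) / length(tr_pos))
    te <- c(te_pos, te_neg)
    f <- .decision(clf, apply_scaling(sc, fm[te, , drop = FALSE]))
    yte <- c(rep(1, length(te_pos)), rep(-1, length(te_neg)))
    fold_counts[[i]] <- .count_confusion(yte, f)
    dec[[i]] <- data.frame(accession = te, f = f, y = yte,
                           stringsAsFactors = FALSE)
  }
  pooled <- Reduce(`+`, fold_counts)
  met <- confusion_metrics(pooled)
  structure(c(list(fold_counts = fold_counts, pooled = pooled,
                   decisions = do.call(rbind, dec)), met),
            class = "fp_cv")
}

#' Exhaustive grid search maximising cross-validated MCC
#'
#' Evaluates every configuration in the grid and returns the one with the
#' highest pooled cross-validated MCC.  Ties go to the earlier grid entry
#' (linear before RBF, then smaller C, then smaller gamma).
#'
#' @inheritParams cross_validate
#' @param grid list of [kernel_spec()]s (see [default_grid()]).
#' @return list with `spec` (winning kernel) and `cv` (its `fp_cv`).
#' @export
grid_search <- function(pos_groups, neg_groups, features, grid,
                        retain = NULL) {
  if (!length(grid)) stop("empty grid")
  best <- NULL
  for (spec in grid) {
    cv <- cross_validate(pos_groups, neg_groups, features, spec, retain)
    if (is.null(best) || cv$mcc > best$cv$mcc)
      best <- list(spec = spec, cv = cv)
  }
  best
}

#' Greedy feature-group elimination
#'
#' Starts from the full registry and the best grid configuration, then
#' visits each feature group once in registry order: the full grid is
#' re-run with the group excluded, and the exclusion is kept only when the
#' best cross-validated MCC strictly improves.  The last remaining group is
#' never removed.  The returned MCC is therefore never below the
#' all-groups baseline.
#'
#' @inheritParams grid_search
#' @param groups character vector of feature-group names in elimination
#'   order (defaults to the feature matrix layout order).
#' @return list with `retained` (group names), `spec` and `cv`.
#' @export
greedy_group_elimination <- function(pos_groups, neg_groups, features, grid,
                                     groups = NULL) {
  groups <- groups %||% .layout(features)$name
  retained <- groups
  best <- grid_search(pos_groups, neg_groups, features, grid, retained)
  for (g in groups) {
    if (length(retained) == 1L) break
    cand <- setdiff(retained, g)
    res <- grid_search(pos_groups, neg_groups, features, grid, cand)
    if (res$cv$mcc > best$cv$mcc) {
      retained <- cand
      best <- res
    }
  }
  list(retained = retained, spec = best$spec, cv = best$cv)
}

# train on pooled groups; returns classifier + scaling over retained groups
.train_pooled <- function(pos, neg, features, spec, retain) {
  fm <- drop_groups(features, setdiff(.layout(features)$name, retain))
  rows <- c(pos, neg)
  sc <- fit_scaling(fm[rows, , drop = FALSE])
  x <- apply_scaling(sc, fm[rows, , drop = FALSE])
  y <- c(rep(1, length(pos)), rep(-1, length(neg)))
  clf <- .fit_svm(x, y, spec, length(neg) / length(pos))
  list(clf = clf, scaling = sc, retained = retain)
}

#' Holdout evaluation with discard and reliability rules
#'
#' Scores a trained classifier on the 30\% holdout proteins.  The term is
#' discarded when the holdout MCC falls below `discard_mcc`; otherwise the
#' model is flagged "H" (higher reliability) when MCC, sensitivity,
#' specificity and precision all clear their thresholds (defaults 0.3,
#' 0.3, 0.7, 0.3), else "L".
#'
#' @param fit a pooled fit as produced internally by [train_term()]
#'   (list with `clf`, `scaling`, `retained`).
#' @param pos_holdout,neg_holdout holdout accession vectors.
#' @param features full `fp_features` matrix.
#' @param discard_mcc discard threshold on holdout MCC (default 0.05).
#' @param reliability_thresholds numeric length-4 vector: MCC,
#'   sensitivity, specificity, precision.
#' @return list with `metrics`, `counts`, `discarded`, `reliability`.
#' @export
holdout_evaluate <- function(fit, pos_holdout, neg_holdout, features,
                             discard_mcc = 0.05,
                             reliability_thresholds = c(0.3, 0.3, 0.7, 0.3)) {
  if (!length(pos_holdout) || !length(neg_holdout))
    stop("empty holdout set")
  fm <- drop_groups(features, setdiff(.layout(features)$name, fit$retained))
  rows <- c(pos_holdout, neg_holdout)
  f <- .decision(fit$clf, apply_scaling(fit$scaling, fm[rows, , drop = FALSE]))
  y <- c(rep(1, length(pos_holdout)), rep(-1, length(neg_holdout)))
  counts <- .count_confusion(y, f)
  met <- confusion_metrics(counts)
  vals <- c(met$mcc, met$sensitivity, met$specificity, met$precision)
  list(metrics = met, counts = counts,
       discarded = met$mcc < discard_mcc,
       reliability = if (all(vals > reliability_thresholds)) "H" else "L")
}

#' Platt sigmoid calibration of decision values
#'
#' Fits the sigmoid posterior `P(y = 1 | f) = 1 / (1 + exp(A f + B))` to
#' decision values by maximising the regularised log-likelihood with
#' Platt's smoothed targets `t+ = (N+ + 1)/(N+ + 2)` and
#' `t- = 1/(N- + 2)`, using the numerically robust damped Newton iteration
#' with backtracking line search.  Feed it cross-validated decision
#' values, never resubstitution values, to avoid optimistic bias.
#'
#' @param f numeric decision values.
#' @param y labels (+1/-1 or logical); both classes must be present.
#' @param max_iter,min_step,sigma optimiser controls.
#' @return an `fp_platt`: list with `A` and `B`.
#' @export
platt_fit <- function(f, y, max_iter = 100L, min_step = 1e-10, sigma = 1e-12) {
  y <- ifelse(as.numeric(y) > 0, 1, -1)
  n_pos <- sum(y > 0); n_neg <- sum(y < 0)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
  hi <- (n_pos + 1) / (n_pos + 2)
  lo <- 1 / (n_neg + 2)
  t <- ifelse(y > 0, hi, lo)

  obj <- function(A, B) {
    fApB <- A * f + B
    sum(ifelse(fApB >= 0,
               t * fApB + log1p(exp(-fApB)),
               (t - 1) * fApB + log1p(exp(fApB))))
  }
  A <- 0; B <- log((n_neg + 1) / (n_pos + 1))
  fval <- obj(A, B)
  for (it in seq_len(max_iter)) {
    fApB <- A * f + B
    p <- ifelse(fApB >= 0, exp(-fApB) / (1 + exp(-fApB)), 1 / (1 + exp(fApB)))
    q <- 1 - p
    d1 <- t - p
    d2 <- p * q
    g1 <- sum(f * d1); g2 <- sum(d1)
    if (abs(g1) < 1e-5 && abs(g2) < 1e-5) break
    h11 <- sum(f * f * d2) + sigma
    h22 <- sum(d2) + sigma
    h21 <- sum(f * d2)
    det <- h11 * h22 - h21 * h21
    dA <- -(h22 * g1 - h21 * g2) / det
    dB <- -(-h21 * g1 + h11 * g2) / det
    gd <- g1 * dA + g2 * dB
    step <- 1
    while (step >= min_step) {
      newA <- A + step * dA; newB <- B + step * dB
      newf <- obj(newA, newB)
      if (newf < fval + 1e-4 * step * gd) {
        A <- newA; B <- newB; fval <- newf
        break
      }
      step <- step / 2
    }
    if (step < min_step) break
  }
  structure(list(A = A, B = B), class = "fp_platt")
}

#' Posterior probability from a Platt calibration
#' @param calibration an `fp_platt`.
#' @param f decision value(s).
#' @return posterior probabilities in (0, 1).
#' @export
platt_posterior <- function(calibration, f) {
  fApB <- calibration$A * f + calibration$B
  ifelse(fApB >= 0, exp(-fApB) / (1 + exp(-fApB)), 1 / (1 + exp(fApB)))
}

# parameter-only grid at fixed kernel kind
.param_grid <- function(grid, kind) {
  Filter(function(s) s$kind == kind, grid)
}

#' Train the model for one GO term
#'
#' Runs the complete per-term recipe: 30\% holdout split of the positive
#' and negative sets; maximal-k equal-size homology partition of the
#' remainders (positives and negatives clustered separately on their own
#' distance submatrices, same k); grid search with greedy feature-group
#' elimination maximising pooled cross-validated MCC; holdout evaluation
#' with the discard rule and H/L reliability tier; then — for surviving
#' terms — a refit on all examples (holdout included), re-partitioned into
#' k groups, with kernel parameters re-optimised at fixed kernel kind and
#' feature list, a Platt calibration fit on the decision values of that
#' final k-fold run, and a final classifier trained on every example.
#'
#' @param tset an `fp_term_set`.
#' @param features full `fp_features` matrix covering all accessions.
#' @param distances symmetric distance matrix covering all accessions.
#' @param config an [fp_config()]; supplies holdout fraction, minimum
#'   group size, thresholds, grid and master seed.
#' @return an `fp_term_model` (possibly with `discarded = TRUE`, in which
#'   case no classifier or calibration is attached).
#' @export
train_term <- function(tset, features, distances, config = fp_config()) {
  seed <- derive_seed(config$seed, tset$term)
  grid <- config$grid

  pos_split <- holdout_split(tset$positives, config$holdout, seed)
  neg_split <- holdout_split(tset$negatives, config$holdout, seed + 1L)
  k <- max_k(length(pos_split$remainder), length(neg_split$remainder),
             config$min_group)
  sub <- function(acc) distances[acc, acc, drop = FALSE]
  part <- function(acc, s) if (k == 1L) list(acc)
          else balanced_kmedoids(sub(acc), k, seed = s)
  pos_groups <- part(pos_split$remainder, seed + 2L)
  neg_groups <- part(neg_split$remainder, seed + 3L)

  elim <- greedy_group_elimination(pos_groups, neg_groups, features, grid)

  fit <- .train_pooled(pos_split$remainder, neg_split$remainder,
                       features, elim$spec, elim$retained)
  hold <- holdout_evaluate(fit, pos_split$holdout, neg_split$holdout,
                           features, config$discard_mcc,
                           config$reliability_thresholds)

  model <- structure(list(term = tset$term, kernel = elim$spec,
                          retained_groups = elim$retained,
                          cv_mcc = elim$cv$mcc, k = k, seed = seed,
                          holdout_metrics = hold$metrics,
                          reliability = hold$reliability,
                          discarded = hold$discarded,
                          classifier = NULL, scaling = NULL,
                          calibration = NULL),
                     class = "fp_term_model")
  if (hold$discarded) return(model)

  # final refit on everything, k-fold re-partitioned, params re-optimised
  all_pos <- sort(c(pos_split$remainder, pos_split$holdout))
  all_neg <- sort(c(neg_split$remainder, neg_split$holdout))
  pos_groups2 <- part(all_pos, seed + 4L)
  neg_groups2 <- part(all_neg, seed + 5L)
  refit <- grid_search(pos_groups2, neg_groups2, features,
                       .param_grid(grid, elim$spec$kind), elim$retained)
  calib <- platt_fit(refit$cv$decisions$f, refit$cv$decisions$y)
  final <- .train_pooled(all_pos, all_neg, features, refit$spec, elim$retained)

  model$kernel <- refit$spec
  model$classifier <- final$clf
  model$scaling <- final$scaling
  model$calibration <- calib
  model
}

#' @export
print.fp_term_model <- function(x, ...) {
  cat(sprintf("fp_term_model %s (%s kernel, C=%g%s)\n", x$term,
              x$kernel$kind, x$kernel$C,
              if (!is.null(x$kernel$gamma)) sprintf(", gamma=%g", x$kernel$gamma) else ""))
  cat(sprintf("  retained groups: %d; k=%d; CV MCC=%.3f\n",
              length(x$retained_groups), x$k, x$cv_mcc))
  m <- x$holdout_metrics
  cat(sprintf("  holdout: MCC=%.3f sens=%.3f spec=%.3f prec=%.3f -> %s%s\n",
              m$mcc, m$sensitivity, m$specificity, m$precision,
              x$reliability, if (x$discarded) " (discarded)" else ""))
  invisible(x)
}

#' Train models for a collection of term training sets
#'
#' Applies [train_term()] to every eligible term set; ineligible sets are
#' skipped and discarded terms are retained as stubs so the discard
#' decision is auditable.
#'
#' @param tsets list of `fp_term_set`s.
#' @param features,distances as in [train_term()].
#' @param config an [fp_config()].
#' @return an `fp_library`: list with `models` (kept `fp_term_model`s),
#'   `discarded` (stub models) and `config`.
#' @export
train_library <- function(tsets, features, distances, config = fp_config()) {
  models <- list(); discarded <- list()
  for (tset in tsets) {
    if (!tset$eligible) next
    m <- train_term(tset, features, distances, config)
    if (m$discarded) discarded[[m$term]] <- m else models[[m$term]] <- m
  }
  structure(list(models = models, discarded = discarded, config = config),
            class = "fp_library")
}

#' @export
print.fp_library <- function(x, ...) {
  cat(sprintf("fp_library: %d models (%d H, %d L), %d discarded terms\n",
              length(x$models),
              sum(vapply(x$models, `[[`, "", "reliability") == "H"),
              sum(vapply(x$models, `[[`, "", "reliability") == "L"),
              length(x$discarded)))
  invisible(x)
}

#' @export
summary.fp_library <- function(object, ...) {
  rows <- lapply(object$models, function(m)
    data.frame(term = m$term, kernel = m$kernel$kind, C = m$kernel$C,
               gamma = m$kernel$gamma %||% NA_real_,
               n_groups = length(m$retained_groups), k = m$k,
               cv_mcc = m$cv_mcc, holdout_mcc = m$holdout_metrics$mcc,
               sensitivity = m$holdout_metrics$sensitivity,
               specificity = m$holdout_metrics$specificity,
               precision = m$holdout_metrics$precision,
               reliability = m$reliability, stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Predict GO term posteriors for new proteins
#'
#' Applies every non-discarded model in the library to the feature matrix:
#' features are reduced to the model's retained groups, scaled with the
#' model's training scaling, pushed through the decision function and
#' calibrated into a posterior.  The report carries one row per (protein,
#' term), sorted H-tier first and then by decreasing posterior; the
#' `displayed` flag marks posteriors strictly above the display threshold.
#'
#' @param object an `fp_library`.
#' @param features an `fp_features` matrix for the query proteins.
#' @param threshold display threshold (default 0.5).
#' @param ... unused.
#' @return data.frame `accession`, `term`, `posterior`, `reliability`,
#'   `displayed`.
#' @export
predict.fp_library <- function(object, features, threshold = 0.5, ...) {
  if (!length(object$models)) {
    out <- data.frame(accession = character(0), term = character(0),
                      posterior = numeric(0), reliability = character(0))
    out$displayed <- logical(0)
    return(out)
  }
  out <- lapply(object$models, function(m) {
    miss <- setdiff(m$retained_groups, .layout(features)$name)
    if (length(miss))
      stop(sprintf("feature matrix lacks group(s) %s required by model %s",
                   paste(miss, collapse = ", "), m$term))
    fm <- drop_groups(features, setdiff(.layout(features)$name, m$retained_groups))
    f <- .decision(m$classifier, apply_scaling(m$scaling, fm))
    data.frame(accession = rownames(features), term = m$term,
               posterior = platt_posterior(m$calibration, f),
               reliability = m$reliability, stringsAsFactors = FALSE)
  })
  rep_df <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  rep_df$displayed <- rep_df$posterior > threshold
  rep_df[order(rep_df$accession, rep_df$reliability != "H",
               -rep_df$posterior, rep_df$term), , drop = FALSE]
}
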