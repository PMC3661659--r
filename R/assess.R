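## Assessment: ancestor propagation of scored term sets, CAFA-style
## precision-recall / Fmax, the relaxed ancestor-descendant variant,
## simGIC and COGIC scoring.

# predictions: data.frame(protein, term, confidence)
.check_predictions <- function(pred) {
  need <- c("protein", "term", "confidence")
  if (!all(need %in% names(pred))) stop("predictions need columns ", paste(need, collapse = ", "))
  if (any(pred$confidence < 0 | pred$confidence > 1))
    stop("confidences must lie in [0, 1]")
  pred
}

#' Propagate prediction confidences to ancestor terms
#'
#' Adds every `is_a` ancestor of each scored term (root terms excluded)
#' with confidence equal to the maximum confidence among its scored
#' descendants.  Idempotent.
#'
#' @param pred data.frame with columns `protein`, `term`, `confidence`.
#' @param graph an `fp_ontology`.
#' @param relations relation types to follow (default `"is_a"`).
#' @return a data.frame of the same shape, propagated.
#' @export
propagate_predictions <- function(pred, graph, relations = "is_a") {
  .check_predictions(pred)
  anc <- .ancestor_table(graph, relations)
  roots <- unname(graph$roots)
  out <- lapply(split(pred, pred$protein), function(d) {
    conf <- tapply(d$confidence, d$term, max)
    full <- conf
    for (t in names(conf)) {
      up <- setdiff(anc[[t]] %||% character(0), roots)
      for (a in up) {
        cur <- if (a %in% names(full)) full[[a]] else -Inf
        full[a] <- max(cur, conf[[t]])
      }
    }
    full <- full[!names(full) %in% roots]
    data.frame(protein = d$protein[1], term = names(full),
               confidence = as.numeric(full), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  res <- res[order(res$protein, res$term), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# reference: data.frame(protein, term); propagate (is_a), roots excluded
.propagate_reference <- function(ref, graph, relations = "is_a",
                                 include_roots = FALSE) {
  anc <- .ancestor_table(graph, relations)
  roots <- unname(graph$roots)
  sets <- lapply(split(ref$term, ref$protein), function(terms) {
    full <- unique(c(terms, unlist(anc[unique(terms)], use.names = FALSE)))
    if (!include_roots) full <- setdiff(full, roots)
    full
  })
  sets
}

.sweep_thresholds <- function(pred, thresholds) {
  if (is.null(thresholds))
    thresholds <- sort(unique(c(0, 1, pred$confidence)))
  thresholds
}

.pr_curve <- function(points, fmax) {
  structure(points, class = c("fp_pr_curve", "data.frame"), fmax = fmax)
}

#' @export
print.fp_pr_curve <- function(x, ...) {
  cat(sprintf("fp_pr_curve: %d thresholds, Fmax = %.4f\n",
              nrow(x), attr(x, "fmax")))
  invisible(x)
}

#' Fmax of a precision-recall curve
#' @param curve an `fp_pr_curve`.
#' @return the maximum F-measure over thresholds.
#' @export
fmax <- function(curve) attr(curve, "fmax")

# shared aggregation: per-protein TP/FP/FN functions vary by flavour
.aggregate_pr <- function(pred_sets, ref_sets, thresholds, counter) {
  D <- names(ref_sets)
  if (!length(D)) stop("empty reference set")
  points <- lapply(thresholds, function(v) {
    pr_sum <- 0; n_v <- 0L; rc_sum <- 0
    for (s in D) {
      scored <- pred_sets[[s]]
      sel <- if (is.null(scored)) character(0) else names(scored)[scored >= v]
      cnt <- counter(sel, ref_sets[[s]])
      if (length(sel)) {               # protein has >= 1 assignment scored >= v
        n_v <- n_v + 1L
        pr_sum <- pr_sum + if (cnt["TP"] + cnt["FP"] > 0)
          cnt["TP"] / (cnt["TP"] + cnt["FP"]) else 0
      }
      rc_sum <- rc_sum + if (cnt["TP"] + cnt["FN"] > 0)
        cnt["TP"] / (cnt["TP"] + cnt["FN"]) else 0
    }
    p <- if (n_v > 0) pr_sum / n_v else 0
    r <- rc_sum / length(D)
    data.frame(threshold = v, precision = p, recall = r, n = n_v,
               f = if (p + r > 0) 2 * p * r / (p + r) else 0)
  })
  points <- do.call(rbind, points)
  .pr_curve(points[, c("threshold", "precision", "recall", "n")],
            max(points$f))
}

#' CAFA-style precision-recall analysis
#'
#' Scores a prediction set against reference annotations the way the first
#' CAFA assessment did: both sides are propagated to `is_a` ancestors
#' (roots excluded), and at each confidence threshold v the per-protein
#' precision is averaged over the n_v proteins with at least one
#' prediction scored >= v while the per-protein recall is averaged over
#' the whole reference set D.  The F-measure is maximised over thresholds
#' to give Fmax.
#'
#' @param pred data.frame `protein`, `term`, `confidence`.
#' @param ref data.frame `protein`, `term` (validated annotations).
#' @param graph an `fp_ontology`.
#' @param thresholds numeric vector, or `NULL` to sweep the distinct
#'   confidence values plus 0 and 1.
#' @param propagate propagate both sides before scoring (set `FALSE` when
#'   the inputs are already propagated).
#' @return an `fp_pr_curve` (data.frame `threshold`, `precision`,
#'   `recall`, `n`) with attribute `fmax`.
#' @export
cafa_pr <- function(pred, ref, graph, thresholds = NULL, propagate = TRUE) {
  .check_predictions(pred)
  if (propagate) pred <- propagate_predictions(pred, graph)
  ref_sets <- if (propagate) .propagate_reference(ref, graph)
              else split(ref$term, ref$protein)
  pred_sets <- lapply(split(pred, pred$protein), function(d)
    stats::setNames(d$confidence, d$term))
  thresholds <- .sweep_thresholds(pred, thresholds)
  counter <- function(sel, A) {
    tp <- sum(sel %in% A)
    c(TP = tp, FP = length(sel) - tp, FN = length(A) - tp)
  }
  .aggregate_pr(pred_sets, ref_sets, thresholds, counter)
}

#' Relaxed ancestor/descendant precision-recall analysis
#'
#' Alternative evaluation with no propagation on either side: a predicted
#' term scored >= v counts as a true positive when it equals, or is an
#' `is_a` ancestor or descendant of, some reference annotation; false
#' positives are the remaining predictions scored >= v; a reference
#' annotation counts as missed when no prediction scored >= v equals it or
#' lies on its ancestor/descendant line.  Aggregation across proteins is
#' as in [cafa_pr()].
#'
#' @inheritParams cafa_pr
#' @return an `fp_pr_curve`.
#' @export
relaxed_pr <- function(pred, ref, graph, thresholds = NULL) {
  .check_predictions(pred)
  ref_sets <- split(ref$term, ref$protein)
  pred_sets <- lapply(split(pred, pred$protein), function(d)
    stats::setNames(tapply(d$confidence, d$term, max)[unique(d$term)],
                    unique(d$term)))
  thresholds <- .sweep_thresholds(pred, thresholds)
  anc <- .ancestor_table(graph, "is_a")
  related <- function(p, a)            # p matches a along the is_a line
    p == a || a %in% (anc[[p]] %||% character(0)) ||
      p %in% (anc[[a]] %||% character(0))
  counter <- function(sel, A) {
    tp <- sum(vapply(sel, function(p) any(vapply(A, related, TRUE, p = p)), TRUE))
    fn <- sum(vapply(A, function(a) !any(vapply(sel, related, TRUE, a = a)), TRUE))
    c(TP = tp, FP = length(sel) - tp, FN = fn)
  }
  .aggregate_pr(pred_sets, ref_sets, thresholds, counter)
}

#' simGIC similarity of two propagated GO term sets
#'
#' Information-content weighted Jaccard index: the IC sum over the
#' intersection divided by the IC sum over the union.  Both sets are
#' expected to be propagated (ancestors added; roots may be present, they
#' carry IC 0).  Terms with infinite IC (never annotated in the reference
#' corpus) and terms missing from the table contribute 0.
#'
#' @param A,P character vectors of GO ids.
#' @param ic an `fp_ic` table.
#' @return similarity in [0, 1]; 0 when the union carries no IC mass.
#' @export
simgic <- function(A, P, ic) {
  lut <- .ic_lookup(ic)
  w <- function(terms) {
    v <- lut[unique(terms)]
    sum(v[is.finite(v)], na.rm = TRUE)
  }
  inter <- w(intersect(A, P))
  uni <- w(union(A, P))
  if (uni == 0) 0 else inter / uni
}

#' COGIC: combined simGIC score over confidence strata
#'
#' Splits the predicted terms of one protein into four nested subsets by
#' confidence (>= 0.75, 0.50, 0.25, 0), adds `is_a` ancestors to each
#' subset and to the reference set, computes the simGIC score of each
#' subset against the reference, and combines the four scores with
#' positive decreasing weights summing to one (default `(8, 4, 2, 1)/15`).
#' The score lies in [0, 1]: it is 1 iff all predicted terms are validated
#' with confidence >= 0.75, and 0 iff the prediction shares only the
#' ontology root with the reference.
#'
#' @param pred_s named numeric vector: confidence per predicted term for
#'   one protein.
#' @param A_s character vector of validated terms for the protein.
#' @param ic an `fp_ic` table.
#' @param graph an `fp_ontology`.
#' @param strata confidence cut-offs of the four subsets.
#' @param weights positive decreasing weights, normalised internally.
#' @return list with `S` (the four stratum scores) and `cogic`.
#' @export
cogic <- function(pred_s, A_s, ic, graph,
                  strata = c(0.75, 0.50, 0.25, 0),
                  weights = c(8, 4, 2, 1) / 15) {
  if (length(weights) != length(strata) || any(weights <= 0) ||
      any(diff(weights) >= 0))
    stop("weights must be positive and strictly decreasing")
  weights <- weights / sum(weights)
  anc <- .ancestor_table(graph, "is_a")
  expand <- function(terms)
    unique(c(terms, unlist(anc[unique(terms)], use.names = FALSE)))
  Afull <- expand(A_s)
  S <- vapply(strata, function(v) {
    Pv <- names(pred_s)[pred_s >= v]
    if (!length(Pv)) return(0)
    simgic(Afull, expand(Pv), ic)
  }, numeric(1))
  list(S = S, cogic = sum(weights * S))
}

#' COGIC scores for a whole prediction set
#'
#' Applies [cogic()] per protein in the reference set (proteins without
#' predictions score 0) and attaches a lower-interpolation median and
#' quartile summary.
#'
#' @inheritParams cafa_pr
#' @param evidence_filter evidence codes retained from `ref` when it has
#'   an `evidence` column (default [ASSESSMENT_EVIDENCE]).
#' @param ... passed to [cogic()].
#' @return an `fp_cogic`: data.frame `protein`, `S1`..`S4`, `cogic`, with
#'   attribute `summary` (see [summarize_cogic()]).
#' @export
cogic_report <- function(pred, ref, ic, graph,
                         evidence_filter = ASSESSMENT_EVIDENCE, ...) {
  .check_predictions(pred)
  if ("evidence" %in% names(ref) && !is.null(evidence_filter))
    ref <- ref[ref$evidence %in% evidence_filter, , drop = FALSE]
  if (!nrow(ref)) stop("no reference annotations after evidence filtering")
  ref_sets <- split(ref$term, ref$protein)
  pred_sets <- lapply(split(pred, pred$protein), function(d)
    stats::setNames(tapply(d$confidence, d$term, max)[unique(d$term)],
                    unique(d$term)))
  rows <- lapply(names(ref_sets), function(s) {
    ps <- pred_sets[[s]] %||% stats::setNames(numeric(0), character(0))
    r <- cogic(ps, ref_sets[[s]], ic, graph, ...)
    data.frame(protein = s, S1 = r$S[1], S2 = r$S[2], S3 = r$S[3],
               S4 = r$S[4], cogic = r$cogic, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("fp_cogic", "data.frame"),
            summary = summarize_cogic(out$cogic))
}

#' Median and quartiles with the lower-interpolation convention
#'
#' Order statistics taken by inverse-ECDF (no averaging between ranks), so
#' the reported median is always an observed score.
#'
#' @param values numeric vector of COGIC scores (>= 1 value).
#' @return named numeric: `q1`, `median`, `q3`.
#' @export
summarize_cogic <- function(values) {
  if (!length(values)) stop("no COGIC rows to summarize")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 1, names = FALSE)
  c(q1 = q[1], median = q[2], q3 = q[3])
}
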