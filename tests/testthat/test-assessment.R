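# Propagation, CAFA and relaxed precision-recall, simGIC, COGIC.

# two-branch MF ontology for assessment tests:
# root <- b1 <- {a, b}; root <- c1 <- c2   (flat ids for readability)
assess_graph <- function() {
  parse_obo(c(
    "[Term]", "id: GO:0000001", "name: root", "namespace: molecular_function", "",
    "[Term]", "id: GO:0000002", "name: b1", "namespace: molecular_function",
    "is_a: GO:0000001", "",
    "[Term]", "id: GO:0000003", "name: a", "namespace: molecular_function",
    "is_a: GO:0000002", "",
    "[Term]", "id: GO:0000004", "name: b", "namespace: molecular_function",
    "is_a: GO:0000002", "",
    "[Term]", "id: GO:0000005", "name: c1", "namespace: molecular_function",
    "is_a: GO:0000001", "",
    "[Term]", "id: GO:0000006", "name: c2", "namespace: molecular_function",
    "is_a: GO:0000005"))
}

test_that("prediction propagation takes the max over descendants, skips roots", {
  g <- assess_graph()
  pred <- data.frame(protein = "P1", term = c("GO:0000003", "GO:0000004"),
                     confidence = c(0.3, 0.8))
  out <- propagate_predictions(pred, g)
  lut <- setNames(out$confidence, out$term)
  expect_equal(unname(lut["GO:0000002"]), 0.8)    # max of the two children
  expect_false("GO:0000001" %in% out$term)        # root excluded
  # idempotence
  expect_equal(propagate_predictions(out, g), out)
  # single source: all non-root ancestors inherit its confidence
  one <- propagate_predictions(
    data.frame(protein = "P1", term = "GO:0000006", confidence = 0.9), g)
  expect_equal(sort(one$confidence), c(0.9, 0.9))
})

test_that("CAFA precision-recall reproduces the worked single-protein example", {
  g <- assess_graph()
  # flat references {a-branch disjoint from c-branch}: A = {a, b} under b1;
  # use unpropagated scoring on a flat structure by pre-propagating manually
  ref <- data.frame(protein = "P1", term = c("GO:0000003", "GO:0000004"))
  pred <- data.frame(protein = "P1", term = c("GO:0000003", "GO:0000006"),
                     confidence = c(0.9, 0.4))
  curve <- cafa_pr(pred, ref, g, thresholds = c(0.9, 0.4), propagate = FALSE)
  at <- function(v) curve[curve$threshold == v, ]
  expect_equal(at(0.9)$precision, 1)
  expect_equal(at(0.9)$recall, 0.5)
  expect_equal(at(0.4)$precision, 0.5)
  expect_equal(at(0.4)$recall, 0.5)
  expect_equal(fmax(curve), 2 / 3)
})

test_that("identical predictions and references give Fmax 1", {
  g <- assess_graph()
  ref <- data.frame(protein = c("P1", "P1", "P2"),
                    term = c("GO:0000003", "GO:0000006", "GO:0000004"))
  pred <- cbind(ref, confidence = 1.0)
  names(pred)[2] <- "term"
  curve <- cafa_pr(pred, ref, g)
  expect_equal(fmax(curve), 1)
  expect_true(all(curve$precision[curve$n > 0] == 1))
})

test_that("proteins without predictions above v leave n_v but not recall", {
  g <- assess_graph()
  ref <- data.frame(protein = c("P1", "P2"), term = "GO:0000003")
  pred <- data.frame(protein = "P1", term = "GO:0000003", confidence = 0.9)
  curve <- cafa_pr(pred, ref, g, thresholds = 0.9)
  # P2 contributes nothing to precision (excluded from n_v) but caps recall
  expect_equal(curve$n, 1)
  expect_equal(curve$precision, 1)
  expect_equal(curve$recall, 0.5)
  expect_error(cafa_pr(pred, ref[0, ], g), "empty reference")
})

test_that("CAFA scoring agrees with brute-force enumeration on random instances", {
  g <- random_dag(12, seed = 14)
  anc <- lapply(setNames(g$terms$id, g$terms$id), function(t)
    go_ancestors(g, t, "is_a"))
  root <- unname(g$roots["MF"])
  set.seed(15)
  for (rep in 1:5) {
    prot <- paste0("P", 1:4)
    ref <- data.frame(protein = rep(prot, each = 2),
                      term = sample(setdiff(g$terms$id, root), 8, replace = TRUE))
    pred <- data.frame(protein = sample(prot, 10, replace = TRUE),
                       term = sample(setdiff(g$terms$id, root), 10, replace = TRUE),
                       confidence = round(runif(10), 2))
    pred <- pred[!duplicated(pred[c("protein", "term")]), ]
    curve <- cafa_pr(pred, ref, g)
    # brute force: propagate by hand, enumerate thresholds
    prop_set <- function(terms) setdiff(unique(c(
      terms, unlist(anc[terms], use.names = FALSE))), root)
    A <- lapply(split(ref$term, ref$protein), prop_set)
    P <- lapply(split(pred, pred$protein), function(d) {
      conf <- sapply(split(d$confidence, d$term), max)
      full <- setNames(rep(-Inf, 0), character(0))
      for (t in names(conf)) for (x in setdiff(c(t, anc[[t]]), root))
        full[x] <- max(full[x] %||% -Inf,
                       if (is.na(full[x] %||% NA)) -Inf else full[[x]], conf[[t]],
                       na.rm = TRUE)
      full
    })
    for (v in curve$threshold) {
      prs <- c(); n_v <- 0; rc <- 0
      for (s in names(A)) {
        sel <- if (is.null(P[[s]])) character(0) else names(P[[s]])[P[[s]] >= v]
        tp <- length(intersect(sel, A[[s]]))
        if (length(sel)) { n_v <- n_v + 1; prs <- c(prs, tp / length(sel)) }
        rc <- rc + tp / length(A[[s]])
      }
      row <- curve[abs(curve$threshold - v) < 1e-12, ]
      expect_equal(row$precision, if (n_v) mean(prs) else 0)
      expect_equal(row$recall, rc / length(A))
      expect_equal(row$n, n_v)
    }
  }
})

test_that("relaxed matching credits ancestors and descendants, once per prediction", {
  g <- assess_graph()
  # predicted parent of the sole reference term
  ref <- data.frame(protein = "P1", term = "GO:0000003")
  pred <- data.frame(protein = "P1", term = "GO:0000002", confidence = 0.9)
  curve <- relaxed_pr(pred, ref, g, thresholds = 0.9)
  expect_equal(curve$precision, 1)
  expect_equal(curve$recall, 1)
  # disjoint branch is a plain false positive
  pred2 <- data.frame(protein = "P1", term = "GO:0000006", confidence = 0.9)
  curve2 <- relaxed_pr(pred2, ref, g, thresholds = 0.9)
  expect_equal(curve2$precision, 0)
  expect_equal(curve2$recall, 0)
  # relaxed TP never below exact-match TP on the same unpropagated inputs
  set.seed(16)
  gg <- random_dag(15, seed = 17)
  ref3 <- data.frame(protein = "P1", term = sample(gg$terms$id, 3))
  pred3 <- data.frame(protein = "P1", term = sample(gg$terms$id, 5),
                      confidence = runif(5))
  for (v in pred3$confidence) {
    sel <- pred3$term[pred3$confidence >= v]
    exact_tp <- length(intersect(sel, ref3$term))
    cr <- relaxed_pr(pred3, ref3, gg, thresholds = v)
    relaxed_tp <- cr$precision * length(sel)
    expect_gte(relaxed_tp + 1e-9, exact_tp)
  }
})

test_that("relaxed matching agrees with a pairwise reachability oracle", {
  skip_if_not_installed("igraph")
  g <- random_dag(15, seed = 19)
  set.seed(20)
  ref <- data.frame(protein = "P1", term = sample(g$terms$id, 4))
  pred <- data.frame(protein = "P1", term = sample(g$terms$id, 6),
                     confidence = round(runif(6), 2))
  pred <- pred[!duplicated(pred$term), ]
  curve <- relaxed_pr(pred, ref, g)
  related <- function(p, a)
    p == a || a %in% oracle_reach(g, p, "is_a", "up") ||
      a %in% oracle_reach(g, p, "is_a", "down")
  for (v in curve$threshold) {
    sel <- pred$term[pred$confidence >= v]
    tp <- sum(vapply(sel, function(p) any(vapply(ref$term, related, TRUE, p = p)), TRUE))
    fn <- sum(vapply(ref$term, function(a)
      !any(vapply(sel, related, TRUE, a = a)), TRUE))
    row <- curve[abs(curve$threshold - v) < 1e-12, ]
    expect_equal(row$precision, if (length(sel)) tp / length(sel) else 0)
    expect_equal(row$recall, tp / (tp + fn))
  }
})

test_that("simGIC is an IC-weighted Jaccard with the stated conventions", {
  ic <- structure(data.frame(term = c("R", "A", "B", "C"),
                             ic = c(0, 1, 2, 3)),
                  class = c("fp_ic", "data.frame"))
  expect_equal(simgic(c("R", "A", "B"), c("R", "A", "B"), ic), 1)
  expect_equal(simgic(c("R", "A"), c("R", "B"), ic), 0 / 3)   # only root shared
  expect_equal(simgic(c("R", "A", "B"), c("R", "A", "C"), ic), 1 / 6)
  # hand-built: intersection mass 1, union mass 3
  expect_equal(simgic(c("A", "B"), c("A", "C"), ic[ic$term != "B" | TRUE, ]),
               1 / 6)
  expect_equal(simgic("R", "R", ic), 0)                        # zero union mass
  # symmetry and monotone growth under a shared positive-IC term
  set.seed(22)
  for (rep in 1:20) {
    A <- sample(c("A", "B", "C"), sample(1:3, 1))
    P <- sample(c("A", "B", "C"), sample(1:3, 1))
    expect_equal(simgic(A, P, ic), simgic(P, A, ic))
    s <- simgic(A, P, ic)
    expect_gte(s, 0); expect_lte(s, 1)
    extra <- setdiff(c("A", "B", "C"), union(A, P))
    if (length(extra))
      expect_gte(simgic(c(A, extra[1]), c(P, extra[1]), ic), s)
  }
  # unknown and infinite-IC terms contribute nothing
  ic_inf <- structure(data.frame(term = c("R", "A", "Z"), ic = c(0, 1, Inf)),
                      class = c("fp_ic", "data.frame"))
  expect_equal(simgic(c("A", "Z"), c("A", "Z", "Q"), ic_inf), 1)
})

test_that("COGIC hits its boundary identities and weighted combinations", {
  g <- assess_graph()
  ann <- data.frame(accession = paste0("P", 1:4),
                    term = c("GO:0000003", "GO:0000004", "GO:0000006",
                             "GO:0000006"),
                    evidence = "IDA")
  ic <- information_content(g, tiny_corpus(ann))
  A <- c("GO:0000003", "GO:0000004")
  # exact reproduction at confidence 0.8 >= 0.75: every stratum scores 1
  r1 <- cogic(setNames(c(0.8, 0.8), A), A, ic, g)
  expect_equal(r1$S, rep(1, 4))
  expect_equal(r1$cogic, 1)
  # disjoint branch: only the root is shared after propagation
  r0 <- cogic(setNames(0.9, "GO:0000006"), A, ic, g)
  expect_equal(r0$cogic, 0)
  # half-overlap by strata: S = (1, 1, s, s) combines linearly
  r2 <- cogic(setNames(c(0.8, 0.3), c("GO:0000003", "GO:0000006")),
              A, ic, g)
  w <- c(8, 4, 2, 1) / 15
  expect_equal(r2$cogic, sum(w * r2$S))
  expect_true(all(diff(r2$S) <= 1e-12))   # lower strata add terms, not matches
  expect_error(cogic(setNames(0.8, A[1]), A, ic, g, weights = c(1, 2, 3, 4) / 10),
               "decreasing")
})

test_that("COGIC boundary contracts hold for random positive decreasing weights", {
  g <- assess_graph()
  ann <- data.frame(accession = paste0("P", 1:4),
                    term = c("GO:0000003", "GO:0000004", "GO:0000006", "GO:0000006"),
                    evidence = "IDA")
  ic <- information_content(g, tiny_corpus(ann))
  A <- c("GO:0000003", "GO:0000004")
  set.seed(23)
  for (rep in 1:10) {
    w <- sort(runif(4, 0.05, 1), decreasing = TRUE)
    w <- w / sum(w)
    if (any(diff(w) >= 0)) next
    expect_equal(cogic(setNames(c(0.8, 0.9), A), A, ic, g, weights = w)$cogic, 1)
    expect_equal(cogic(setNames(0.9, "GO:0000006"), A, ic, g, weights = w)$cogic, 0)
  }
})

test_that("cogic_report scores every reference protein and summarizes medians", {
  g <- assess_graph()
  ann <- data.frame(accession = paste0("P", 1:4),
                    term = c("GO:0000003", "GO:0000004", "GO:0000006", "GO:0000006"),
                    evidence = "IDA")
  ic <- information_content(g, tiny_corpus(ann))
  ref <- data.frame(protein = c("P1", "P2", "P3"),
                    term = c("GO:0000003", "GO:0000004", "GO:0000006"),
                    evidence = "IDA")
  pred <- data.frame(protein = c("P1", "P2"),
                     term = c("GO:0000003", "GO:0000006"),
                     confidence = c(0.8, 0.9))
  rep <- cogic_report(pred, ref, ic, g)
  expect_equal(nrow(rep), 3)
  expect_equal(rep$cogic[rep$protein == "P1"], 1)    # exact match
  expect_equal(rep$cogic[rep$protein == "P2"], 0)    # disjoint branch
  expect_equal(rep$cogic[rep$protein == "P3"], 0)    # no prediction at all
  expect_equal(unname(attr(rep, "summary")["median"]), 0)
})

test_that("the COGIC summary uses lower-interpolation order statistics", {
  expect_equal(unname(summarize_cogic(c(0, 0.5, 1))["median"]), 0.5)
  expect_equal(unname(summarize_cogic(0.7)["median"]), 0.7)
  set.seed(24)
  x <- runif(100)
  s <- summarize_cogic(x)
  xs <- sort(x)
  expect_equal(unname(s["median"]), xs[50])    # inverse-ECDF rank, no averaging
  expect_equal(unname(s["q1"]), xs[25])
  expect_equal(unname(s["q3"]), xs[75])
  expect_error(summarize_cogic(numeric(0)), "no COGIC rows")
})
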