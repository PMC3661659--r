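# Shared in-code fixtures for the test suite.

# minimal OBO text: root R, A is_a R, B part_of A (one namespace)
obo_minimal <- function() c(
  "[Term]", "id: GO:0000001", "name: root", "namespace: molecular_function", "",
  "[Term]", "id: GO:0000002", "name: A", "namespace: molecular_function",
  "is_a: GO:0000001", "",
  "[Term]", "id: GO:0000003", "name: B", "namespace: molecular_function",
  "relationship: part_of GO:0000002")

# chain C part_of B, B is_a A, A is_a R
obo_chain <- function() c(
  "[Term]", "id: GO:0000001", "name: R", "namespace: biological_process", "",
  "[Term]", "id: GO:0000002", "name: A", "namespace: biological_process",
  "is_a: GO:0000001", "",
  "[Term]", "id: GO:0000003", "name: B", "namespace: biological_process",
  "is_a: GO:0000002", "",
  "[Term]", "id: GO:0000004", "name: C", "namespace: biological_process",
  "relationship: part_of GO:0000003")

# random rooted DAG on n nodes (single namespace, is_a edges; optional
# part_of extras); returns an fp_ontology built via the public parser
random_dag <- function(n, seed, p_extra = 0.3) {
  set.seed(seed)
  ids <- sprintf("GO:%07d", seq_len(n))
  lines <- c("[Term]", paste0("id: ", ids[1]), "name: root",
             "namespace: molecular_function")
  for (i in 2:n) {
    parents <- unique(c(sample(i - 1L, 1),
                        if (i > 2 && runif(1) < p_extra) sample(i - 1L, 1)))
    stanza <- c("", "[Term]", paste0("id: ", ids[i]), paste0("name: t", i),
                "namespace: molecular_function",
                paste0("is_a: ", ids[parents[1]]))
    if (length(parents) > 1) {
      rel <- if (runif(1) < 0.5) paste0("is_a: ", ids[parents[2]])
             else paste0("relationship: part_of ", ids[parents[2]])
      stanza <- c(stanza, rel)
    }
    lines <- c(lines, stanza)
  }
  parse_obo(lines)
}

# igraph-based reachability oracle over an fp_ontology
oracle_reach <- function(graph, term, relations, direction = c("up", "down")) {
  skip_if_not_installed("igraph")
  direction <- match.arg(direction)
  e <- graph$edges[graph$edges$relation %in% relations, , drop = FALSE]
  if (!nrow(e)) return(character(0))
  ig <- igraph::graph_from_data_frame(e[, c("child", "parent")],
                                      vertices = graph$terms$id)
  mode <- if (direction == "up") "out" else "in"
  res <- igraph::subcomponent(ig, term, mode = mode)
  setdiff(names(res), term)
}

# tiny corpus builder: proteins named P1..Pn with given annotation rows
tiny_corpus <- function(ann, n = NULL, seqs = NULL) {
  acc <- unique(ann$accession)
  if (!is.null(n)) acc <- union(acc, paste0("P", seq_len(n)))
  proteins <- data.frame(accession = acc,
                         sequence = seqs %||% vapply(acc, function(a)
                           paste(rep("ACDEFGHIKL", 3), collapse = ""), ""),
                         stringsAsFactors = FALSE)
  proteins$length <- nchar(proteins$sequence)
  structure(list(proteins = proteins, annotations = ann), class = "fp_corpus")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# block-structured distance matrix with planted equal-size clusters
block_distance <- function(n_per_block, k, seed, within = 0.01, between = 10) {
  set.seed(seed)
  n <- n_per_block * k
  acc <- sprintf("B%03d", seq_len(n))
  blocks <- rep(seq_len(k), each = n_per_block)
  d <- matrix(runif(n * n, between * 0.8, between), n, n,
              dimnames = list(acc, acc))
  same <- outer(blocks, blocks, "==")
  d[same] <- runif(sum(same), 0, within)
  d[lower.tri(d)] <- t(d)[lower.tri(d)]
  diag(d) <- 0
  list(d = d, blocks = split(acc, blocks))
}

# small trainable fixture for grid/elimination tests: n_pos/n_neg proteins,
# g groups of dimension dim, signal planted in group 1
small_training_fixture <- function(n_pos = 20, n_neg = 40, g = 3, dim = 3,
                                   strength = 1, seed = 1) {
  set.seed(seed)
  n <- n_pos + n_neg
  acc <- sprintf("S%03d", seq_len(n))
  mat <- matrix(rnorm(n * g * dim), n, g * dim, dimnames = list(acc, NULL))
  lab <- c(rep(1, n_pos), rep(-1, n_neg))
  mat[, 1:dim] <- (1 - strength) * mat[, 1:dim] + strength * lab
  layout <- data.frame(name = paste0("grp", seq_len(g)),
                       start = seq(1, g * dim, dim), dimension = dim,
                       stringsAsFactors = FALSE)
  colnames(mat) <- unlist(lapply(layout$name, function(nm) paste0(nm, ".", 1:dim)))
  features <- structure(mat, layout = layout, class = c("fp_features", "matrix", "array"))
  d <- matrix(runif(n * n, 1, 2), n, n, dimnames = list(acc, acc))
  d[lower.tri(d)] <- t(d)[lower.tri(d)]
  diag(d) <- 0
  list(features = features, distances = d,
       pos = acc[lab > 0], neg = acc[lab < 0])
}

# split accessions round-robin into k groups (no homology structure needed)
plain_groups <- function(acc, k) split(acc, rep(seq_len(k), length.out = length(acc)))

# reduced grid keeping tests fast
small_grid <- function() default_grid(linear_C = c(0.1, 1), rbf_C = 1, rbf_gamma = 0.1)
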