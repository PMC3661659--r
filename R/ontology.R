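## Ontology core: OBO parsing, typed DAG traversal, obsolete-term mapping,
## and information-content estimation from an annotation corpus.

OBO_NAMESPACES <- c(molecular_function = "MF", biological_process = "BP")

#' Parse a Gene Ontology OBO file
#'
#' Consumes `[Term]` stanzas of an OBO 1.2/1.4 file and returns a typed
#' directed acyclic graph over the molecular function (MF) and biological
#' process (BP) namespaces.  Cellular-component terms are dropped.  Obsolete
#' terms are retained (with their `replaced_by` and `alt_id` fields) so that
#' stale annotations can later be mapped forward, but they carry no edges.
#' Only the tags `id`, `name`, `namespace`, `is_a`, `relationship: part_of`,
#' `is_obsolete`, `replaced_by` and `alt_id` are consumed.
#'
#' @param path path to an OBO file, or a character vector of OBO lines.
#' @return an object of class `fp_ontology`: a list with elements
#'   `terms` (data.frame: `id`, `name`, `namespace`, `obsolete`,
#'   `replaced_by`), `alt` (named character, alt id -> primary id),
#'   `edges` (data.frame: `child`, `parent`, `relation`) and `roots`
#'   (named character, one root id per namespace).
#' @examples
#' obo <- c("[Term]", "id: GO:1", "name: root", "namespace: molecular_function",
#'          "", "[Term]", "id: GO:2", "name: a", "namespace: molecular_function",
#'          "is_a: GO:1")
#' g <- parse_obo(obo)
#' g$roots
#' @export
parse_obo <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path, warn = FALSE) else path
  lines <- sub("\\s*!.*$", "", lines)   # strip OBO comments
  lines <- trimws(lines)

  # split into stanzas
  starts <- grep("^\\[", lines)
  if (!length(starts)) stop("no stanzas found in OBO input")
  bounds <- c(starts, length(lines) + 1L)
  ids <- names <- namespaces <- replaced <- character(0)
  obsolete <- logical(0)
  alt_from <- alt_to <- character(0)
  e_child <- e_parent <- e_rel <- character(0)

  for (i in seq_along(starts)) {
    if (lines[starts[i]] != "[Term]") next
    body <- lines[(starts[i] + 1L):(bounds[i + 1L] - 1L)]
    body <- body[nzchar(body)]
    tagval <- regmatches(body, regexec("^([a-z_]+):\\s*(.*)$", body))
    tags <- vapply(tagval, function(m) if (length(m)) m[2] else "", "")
    vals <- vapply(tagval, function(m) if (length(m)) m[3] else "", "")
    id <- vals[tags == "id"][1]
    if (is.na(id) || !nzchar(id)) stop("OBO [Term] stanza without an id")
    ns_raw <- vals[tags == "namespace"][1]
    obs <- any(tags == "is_obsolete" & vals == "true")
    if (!obs && (is.na(ns_raw) || !nzchar(ns_raw)))
      stop(sprintf("term %s has no namespace", id))
    if (!is.na(ns_raw) && nzchar(ns_raw) &&
        !ns_raw %in% names(OBO_NAMESPACES) && ns_raw != "cellular_component")
      stop(sprintf("term %s has unknown namespace '%s'", id, ns_raw))
    if (identical(ns_raw, "cellular_component")) next
    ns <- if (!is.na(ns_raw) && nzchar(ns_raw)) unname(OBO_NAMESPACES[ns_raw]) else NA_character_

    ids <- c(ids, id)
    names <- c(names, vals[tags == "name"][1] %||% NA_character_)
    namespaces <- c(namespaces, ns)
    obsolete <- c(obsolete, obs)
    rb <- vals[tags == "replaced_by"]
    replaced <- c(replaced, if (length(rb) == 1L) rb else NA_character_)
    av <- vals[tags == "alt_id"]
    if (length(av)) { alt_from <- c(alt_from, av); alt_to <- c(alt_to, rep(id, length(av))) }
    if (!obs) {
      isa <- vals[tags == "is_a"]
      if (length(isa)) {
        e_child <- c(e_child, rep(id, length(isa)))
        e_parent <- c(e_parent, isa)
        e_rel <- c(e_rel, rep("is_a", length(isa)))
      }
      rel <- vals[tags == "relationship"]
      po <- sub("^part_of\\s+", "", rel[grepl("^part_of\\s+", rel)])
      if (length(po)) {
        e_child <- c(e_child, rep(id, length(po)))
        e_parent <- c(e_parent, po)
        e_rel <- c(e_rel, rep("part_of", length(po)))
      }
    }
  }
  if (!length(ids)) stop("no usable [Term] stanzas in OBO input")
  if (anyDuplicated(ids)) stop("duplicate term ids in OBO input")

  terms <- data.frame(id = ids, name = names, namespace = namespaces,
                      obsolete = obsolete, replaced_by = replaced,
                      stringsAsFactors = FALSE)
  keep <- e_parent %in% ids & e_child %in% ids
  edges <- data.frame(child = e_child[keep], parent = e_parent[keep],
                      relation = e_rel[keep], stringsAsFactors = FALSE)

  ns_of <- stats::setNames(terms$namespace, terms$id)
  bad <- edges$relation == "is_a" & ns_of[edges$child] != ns_of[edges$parent]
  if (any(bad)) stop("is_a edge crosses namespaces: ", edges$child[which(bad)[1]])

  g <- structure(list(terms = terms,
                      alt = stats::setNames(alt_to, alt_from),
                      edges = edges, roots = character(0)),
                 class = "fp_ontology")
  cyc <- .find_cycle(g)
  if (!is.null(cyc)) stop("ontology contains a cycle involving term ", cyc)

  live <- terms[!terms$obsolete, , drop = FALSE]
  has_parent <- unique(edges$child)
  roots <- character(0)
  for (ns in unique(live$namespace)) {
    cand <- live$id[live$namespace == ns & !live$id %in% has_parent]
    if (length(cand) != 1L)
      stop(sprintf("namespace %s must have exactly one root, found %d", ns, length(cand)))
    roots[ns] <- cand
  }
  g$roots <- roots
  g
}

# Kahn topological check over all typed edges; returns NULL or a cycle member.
.find_cycle <- function(graph) {
  edges <- graph$edges
  if (!nrow(edges)) return(NULL)
  nodes <- unique(c(edges$child, edges$parent))
  outdeg <- table(factor(edges$child, levels = nodes))
  up <- split(edges$parent, factor(edges$child, levels = nodes))
  indeg_src <- split(edges$child, factor(edges$parent, levels = nodes))
  remaining <- stats::setNames(as.integer(outdeg), nodes)  # unresolved parents
  queue <- nodes[remaining == 0L]
  seen <- 0L
  while (length(queue)) {
    n <- queue[[1]]; queue <- queue[-1]; seen <- seen + 1L
    for (ch in indeg_src[[n]] %||% character(0)) {
      remaining[ch] <- remaining[ch] - 1L
      if (remaining[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen < length(nodes)) names(remaining)[remaining > 0L][1] else NULL
}

#' @export
print.fp_ontology <- function(x, ...) {
  cat(sprintf("fp_ontology: %d terms (%d obsolete), %d edges\n",
              nrow(x$terms), sum(x$terms$obsolete), nrow(x$edges)))
  for (ns in names(x$roots))
    cat(sprintf("  %s root: %s\n", ns, x$roots[[ns]]))
  invisible(x)
}

.check_term <- function(graph, term) {
  if (!term %in% graph$terms$id) stop("unknown term: ", term)
}

# Adjacency list over requested relations; direction "up" (child->parent)
# or "down".  Optionally refuses edges that cross namespaces.
.adjacency <- function(graph, relations, direction, same_namespace_only = FALSE) {
  e <- graph$edges[graph$edges$relation %in% relations, , drop = FALSE]
  if (same_namespace_only && nrow(e)) {
    ns <- stats::setNames(graph$terms$namespace, graph$terms$id)
    e <- e[ns[e$child] == ns[e$parent], , drop = FALSE]
  }
  if (direction == "up") split(e$parent, e$child) else split(e$child, e$parent)
}

.reach <- function(adj, term) {
  seen <- character(0)
  frontier <- adj[[term]] %||% character(0)
  while (length(frontier)) {
    frontier <- unique(frontier[!frontier %in% seen])
    seen <- c(seen, frontier)
    frontier <- unique(unlist(adj[frontier], use.names = FALSE)) %||% character(0)
  }
  seen
}

#' Ancestors of a GO term
#'
#' Transitive closure of a term over the requested relation types, walking
#' child-to-parent.  The query term itself is excluded; the namespace root
#' is included whenever it is reachable.
#'
#' @param graph an `fp_ontology`.
#' @param term GO id present in the graph.
#' @param relations subset of `c("is_a", "part_of")`.
#' @param same_namespace_only if `TRUE`, edges crossing namespaces are not
#'   followed (cross-namespace `part_of` edges are retained in the graph but
#'   skipped here).
#' @return character vector of ancestor ids.
#' @export
go_ancestors <- function(graph, term, relations = c("is_a", "part_of"),
                         same_namespace_only = FALSE) {
  .check_term(graph, term)
  .reach(.adjacency(graph, relations, "up", same_namespace_only), term)
}

#' Descendants of a GO term
#'
#' Mirror of [go_ancestors()] on reversed edges.
#' @inheritParams go_ancestors
#' @return character vector of descendant ids.
#' @export
go_descendants <- function(graph, term, relations = c("is_a", "part_of"),
                           same_namespace_only = FALSE) {
  .check_term(graph, term)
  .reach(.adjacency(graph, relations, "down", same_namespace_only), term)
}

# Ancestor sets for every term at once (memo-free; graphs here are small).
.ancestor_table <- function(graph, relations = "is_a") {
  adj <- .adjacency(graph, relations, "up")
  out <- vector("list", nrow(graph$terms))
  names(out) <- graph$terms$id
  for (id in graph$terms$id) out[[id]] <- .reach(adj, id)
  out
}

#' Map an obsolete term to its unique replacement
#'
#' Returns the term itself when it is current; the `replaced_by` target when
#' exactly one is given; otherwise the unique primary term listing the query
#' as an `alt_id`.  Returns `NA` when no unique replacement exists (callers
#' discard such annotations).
#'
#' @inheritParams go_ancestors
#' @return a GO id or `NA_character_`.
#' @export
map_obsolete <- function(graph, term) {
  tt <- graph$terms
  i <- match(term, tt$id)
  if (!is.na(i) && !tt$obsolete[i]) return(term)
  if (!is.na(i) && !is.na(tt$replaced_by[i])) {
    tgt <- tt$replaced_by[i]
    j <- match(tgt, tt$id)
    if (!is.na(j) && !tt$obsolete[j]) return(tgt)
    return(NA_character_)
  }
  hits <- unname(graph$alt[names(graph$alt) == term])
  hits <- unique(hits[hits %in% tt$id[!tt$obsolete]])
  if (length(hits) == 1L) hits else NA_character_
}

#' Per-term information content from an annotation corpus
#'
#' Estimates, for every term `y`, the frequency `f(y)` of proteins annotated
#' with `y` or any of its descendants among proteins carrying at least one
#' annotation in `y`'s namespace, and reports `ic(y) = -log f(y)` (natural
#' log; the simGIC score is a ratio of IC sums, so the base cancels).  Roots
#' have IC exactly 0; never-annotated terms get `+Inf` and are skipped by
#' [simgic()].
#'
#' @param graph an `fp_ontology`.
#' @param corpus an `fp_corpus` (see [load_corpus()]).
#' @param evidence_filter evidence codes to keep, or `NULL` for all.
#'   The assessment default in the rest of the package is
#'   [ASSESSMENT_EVIDENCE].
#' @param relations relation types used to propagate annotations upward
#'   (default `"is_a"`, matching assessment propagation).
#' @return an `fp_ic`: data.frame with columns `term`, `ic` and attribute
#'   `corpus_size`.
#' @export
information_content <- function(graph, corpus, evidence_filter = NULL,
                                relations = "is_a") {
  ann <- corpus$annotations
  if (!is.null(evidence_filter))
    ann <- ann[ann$evidence %in% evidence_filter, , drop = FALSE]
  ann <- ann[ann$term %in% graph$terms$id, , drop = FALSE]
  if (!nrow(ann)) stop("no annotations left after evidence filtering")

  anc <- .ancestor_table(graph, relations)
  ns_of <- stats::setNames(graph$terms$namespace, graph$terms$id)
  per_prot <- split(ann$term, ann$accession)
  counts <- stats::setNames(numeric(nrow(graph$terms)), graph$terms$id)
  denom <- stats::setNames(numeric(length(graph$roots)), names(graph$roots))
  for (terms in per_prot) {
    full <- unique(c(terms, unlist(anc[terms], use.names = FALSE)))
    counts[full] <- counts[full] + 1
    for (ns in unique(ns_of[full][!is.na(ns_of[full])])) denom[ns] <- denom[ns] + 1
  }
  f <- counts / denom[ns_of[names(counts)]]
  ic <- -log(f)
  ic[counts == 0] <- Inf
  ic[names(ic) %in% graph$roots] <- 0
  out <- data.frame(term = names(ic), ic = unname(ic), stringsAsFactors = FALSE)
  structure(out, class = c("fp_ic", "data.frame"),
            corpus_size = length(per_prot))
}

#' Write / read an information-content table as 2-column TSV
#' @param ic an `fp_ic`.
#' @param path output path.
#' @export
write_ic <- function(ic, path) {
  utils::write.table(ic[, c("term", "ic")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ic
#' @export
read_ic <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  structure(d[, c("term", "ic")], class = c("fp_ic", "data.frame"))
}

# named numeric lookup (Inf for unknown handled by callers)
.ic_lookup <- function(ic) stats::setNames(ic$ic, ic$term)
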