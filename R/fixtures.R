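## Synthetic fixtures: toy two-namespace ontologies, proteomes with planted
## feature signal, annotation tables with a controlled evidence-code mix,
## block-structured homology distances, and writers for every input format
## the rest of the package reads.

#' Specification of a synthetic fixture
#'
#' The defaults describe the standard study conditions used throughout the
#' package's tests: two 12-term namespaces, 700 proteins, three terms with
#' planted feature signal plus one pure-noise term with 150 positives
#' each, three homology blocks, and an evidence mix that leaves a little
#' over 500 qualifying negatives per term so the eligibility rules bind.
#'
#' @param seed master seed.
#' @param n_terms terms per namespace.
#' @param branching maximum branching factor (1 gives a chain).
#' @param n_proteins proteome size.
#' @param n_pos positives planted per signal/noise term.
#' @param n_signal_terms number of terms with planted signal (max 3).
#' @param signal_strength s in [0, 1]: signal channels are
#'   `(1-s) * noise + s * (+/-1)` by label, so s = 1 is linearly separable
#'   by construction and s = 0 carries no label information.
#' @param n_blocks homology block count.
#' @param evidence_mix named probabilities for filler-annotation evidence
#'   codes.
#' @param iea_only_frac fraction of proteins whose filler annotations are
#'   all electronic (IEA), disqualifying them as negatives.
#' @param provider_dim dimension of provider-backed feature groups.
#' @return an `fp_fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1L, n_terms = 12L, branching = 2L,
                         n_proteins = 700L, n_pos = 150L,
                         n_signal_terms = 3L, signal_strength = 0.9,
                         n_blocks = 3L,
                         evidence_mix = c(IDA = 0.45, IMP = 0.2, IPI = 0.1,
                                          IEA = 0.15, TAS = 0.1),
                         iea_only_frac = 0.05, provider_dim = 4L) {
  stopifnot(n_terms >= 1, branching >= 1, n_proteins >= 1, n_pos >= 1,
            signal_strength >= 0, signal_strength <= 1, n_blocks >= 1)
  structure(list(seed = seed, n_terms = n_terms, branching = branching,
                 n_proteins = n_proteins, n_pos = n_pos,
                 n_signal_terms = n_signal_terms,
                 signal_strength = signal_strength, n_blocks = n_blocks,
                 evidence_mix = evidence_mix / sum(evidence_mix),
                 iea_only_frac = iea_only_frac,
                 provider_dim = provider_dim),
            class = "fp_fixture_spec")
}

# term ids: GO:01000nn (MF), GO:02000nn (BP)
.fx_id <- function(ns, i) sprintf("GO:%02d000%02d", if (ns == "MF") 1L else 2L, i)

#' Generate a toy two-namespace ontology
#'
#' Builds, per namespace, a rooted DAG with `is_a` and `part_of` edges and
#' (for 8 or more terms and branching > 1) at least one diamond motif.
#' Layout for the default 12 terms: a root, four branch terms, two
#' children under the first branch closed into a diamond, one leaf under
#' each of branches two and three (the planted-signal/noise slots) and two
#' filler leaves under branch four; extra terms extend a chain under the
#' last filler.  `branching = 1` yields a chain.
#'
#' @param spec an [fixture_spec()].
#' @return an `fp_ontology` with attribute `roles` (list with
#'   `signal_candidates`, `noise_candidate`, `fillers` per namespace).
#' @export
make_ontology <- function(spec = fixture_spec()) {
  n <- spec$n_terms
  terms <- edges <- NULL
  roles <- list(signal_candidates = character(0),
                noise_candidate = character(0), fillers = character(0))
  for (ns in c("MF", "BP")) {
    id <- function(i) .fx_id(ns, i)
    tt <- data.frame(id = id(seq_len(n)),
                     name = paste0(tolower(ns), " term ", seq_len(n)),
                     namespace = ns, obsolete = FALSE,
                     replaced_by = NA_character_, stringsAsFactors = FALSE)
    tt$name[1] <- paste(ns, "root")
    if (spec$branching == 1L || n < 8L) {
      e <- if (n > 1L)
        data.frame(child = id(2:n), parent = id(1:(n - 1L)),
                   relation = "is_a", stringsAsFactors = FALSE)
      else NULL
    } else {
      e <- data.frame(
        child = c(id(2), id(3), id(4), id(5),      # branches B1..B4
                  id(6), id(7),                    # C11, C12 under B1
                  id(8), id(8)),                   # D1: diamond under C11+C12
        parent = c(id(1), id(1), id(1), id(1),
                   id(2), id(2),
                   id(6), id(7)),
        relation = "is_a", stringsAsFactors = FALSE)
      if (n >= 9L)  e <- rbind(e, data.frame(child = id(9), parent = id(3), relation = "is_a"))
      if (n >= 10L) e <- rbind(e, data.frame(child = id(10), parent = id(4), relation = "is_a"))
      if (n >= 11L) e <- rbind(e, data.frame(child = id(11), parent = id(5), relation = "is_a"))
      if (n >= 12L) e <- rbind(e, data.frame(child = id(12), parent = id(5), relation = "is_a"))
      if (n >= 13L) for (i in 13:n)
        e <- rbind(e, data.frame(child = id(i), parent = id(i - 1L), relation = "is_a"))
      # one typed part_of edge: C12 part_of B2
      e <- rbind(e, data.frame(child = id(7), parent = id(3), relation = "part_of"))
      roles$signal_candidates <- c(roles$signal_candidates,
                                   if (n >= 9L) id(9), if (n >= 10L) id(10))
      roles$noise_candidate <- c(roles$noise_candidate, if (n >= 10L) id(10))
      roles$fillers <- c(roles$fillers, if (n >= 11L) id(11), if (n >= 12L) id(12))
    }
    terms <- rbind(terms, tt)
    edges <- rbind(edges, e)
  }
  g <- structure(list(terms = terms, alt = stats::setNames(character(0), character(0)),
                      edges = edges %||% data.frame(child = character(0),
                                                    parent = character(0),
                                                    relation = character(0)),
                      roots = c(MF = .fx_id("MF", 1), BP = .fx_id("BP", 1))),
                 class = "fp_ontology")
  attr(g, "roles") <- roles
  g
}

#' Deterministic hash-seeded mock feature provider
#'
#' Stand-in for the external feature predictors: every (accession, group)
#' pair gets reproducible pseudo-features drawn from a hash-derived seed.
#' Groups named in `signal` get a planted channel instead: positives of
#' the associated term sit at `+s`, all other proteins at `-s`, plus
#' `(1-s)` Gaussian noise, so strength 1 is linearly separable by
#' construction.
#'
#' @param seed integer seed.
#' @param signal named list: group name -> list(positives = accessions,
#'   strength = s).
#' @return a provider function for [assemble_features()].
#' @export
mock_provider <- function(seed = 1L, signal = list()) {
  function(accession, sequence, group, dimension) {
    base <- with_seed(derive_seed(seed, paste0(accession, "::", group)),
                      stats::rnorm(dimension))
    sg <- signal[[group]]
    if (is.null(sg)) return(base)
    lab <- if (accession %in% sg$positives) 1 else -1
    (1 - sg$strength) * base + sg$strength * lab
  }
}

.random_sequences <- function(n, seed) {
  with_seed(seed, vapply(seq_len(n), function(i)
    paste(sample(AA20, sample(80:400, 1), replace = TRUE), collapse = ""), ""))
}

#' Generate a synthetic proteome with planted signal
#'
#' Produces an annotation corpus, a feature matrix, a homology distance
#' matrix and ground-truth labels consistent with the ontology from
#' [make_ontology()].  Signal terms each receive `n_pos` positives whose
#' features in one dedicated provider group are shifted by the signal
#' strength; one extra term receives `n_pos` positives with no feature
#' signal at all (the noise term).  Every protein carries two MF and two
#' BP filler annotations (evidence drawn from the configured mix;
#' a small fraction of proteins is electronic-only and thus fails the
#' negative-example criteria), so eligibility rules are exercised.
#' Proteins fall into equal homology blocks with near-zero within-block
#' distances.
#'
#' @param spec an [fixture_spec()].
#' @param graph ontology from [make_ontology()] (built from `spec` when
#'   omitted).
#' @return list with `corpus` (`fp_corpus`), `features` (`fp_features`),
#'   `distances` (matrix), `truth` (term -> positive accessions),
#'   `signal_terms`, `noise_term`, `vocab`, `blocks` (accession -> block).
#' @export
make_proteome <- function(spec = fixture_spec(), graph = make_ontology(spec)) {
  roles <- attr(graph, "roles")
  if (length(roles$signal_candidates) < 1L)
    stop("ontology too small to host planted-signal terms (need n_terms >= 10, branching > 1)")
  signal_terms <- setdiff(roles$signal_candidates, roles$noise_candidate)
  signal_terms <- c(signal_terms, roles$noise_candidate)[seq_len(spec$n_signal_terms)]
  noise_term <- setdiff(roles$noise_candidate, signal_terms)[1]
  if (is.na(noise_term)) stop("no term left to act as the noise term")
  fillers_mf <- grep("GO:01", roles$fillers, value = TRUE)
  fillers_bp <- grep("GO:02", roles$fillers, value = TRUE)

  n <- spec$n_proteins
  acc <- sprintf("P%05d", seq_len(n))
  sequences <- stats::setNames(.random_sequences(n, derive_seed(spec$seed, "seq")), acc)
  proteins <- data.frame(accession = acc, sequence = unname(sequences),
                         length = nchar(sequences), stringsAsFactors = FALSE)

  # planted positives: signal terms are independent draws (overlaps are
  # allowed); the noise term is stratified over the joint signal-membership
  # cells so it is exactly orthogonal to every planted signal — a pure
  # noise label by construction, not merely in expectation.
  truth <- lapply(seq_along(signal_terms), function(i)
    sort(acc[with_seed(derive_seed(spec$seed, paste0("pos", i)),
                       sample.int(n, spec$n_pos))]))
  names(truth) <- signal_terms
  member <- vapply(truth, function(p) acc %in% p, logical(n))
  cell <- apply(member, 1, paste, collapse = "")
  truth[[noise_term]] <- with_seed(derive_seed(spec$seed, "noise"), {
    cells <- split(acc, cell)
    quota <- spec$n_pos * lengths(cells) / n
    take <- floor(quota)
    rem <- order(quota - take, decreasing = TRUE)
    short <- spec$n_pos - sum(take)
    if (short > 0) take[rem[seq_len(short)]] <- take[rem[seq_len(short)]] + 1L
    sort(unlist(mapply(function(members, t) sample(members, t),
                       cells, take, SIMPLIFY = FALSE), use.names = FALSE))
  })
  all_terms <- c(signal_terms, noise_term)

  # filler annotations: 2 MF + 2 BP per protein
  iea_only <- acc[with_seed(derive_seed(spec$seed, "iea"),
                            sample.int(n, round(spec$iea_only_frac * n)))]
  ev_codes <- names(spec$evidence_mix)
  ann <- with_seed(derive_seed(spec$seed, "ann"), {
    rows <- lapply(acc, function(a) {
      ev <- if (a %in% iea_only) rep("IEA", 4)
            else sample(ev_codes, 4, replace = TRUE, prob = spec$evidence_mix)
      # guarantee the >=2 MF / >=2 BP qualifying annotations for the rest
      if (!a %in% iea_only) {
        bad <- ev %in% EXCLUDED_NEGATIVE_EVIDENCE
        ev[bad] <- sample(setdiff(ev_codes, EXCLUDED_NEGATIVE_EVIDENCE),
                          sum(bad), replace = TRUE)
      }
      data.frame(accession = a,
                 term = c(fillers_mf[1:2], fillers_bp[1:2]),
                 evidence = ev, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  planted <- do.call(rbind, lapply(all_terms, function(t)
    data.frame(accession = truth[[t]], term = t, evidence = "IDA",
               stringsAsFactors = FALSE)))
  ann <- rbind(ann, planted)
  corpus <- structure(list(proteins = proteins, annotations = ann),
                      class = "fp_corpus")

  # features: mock provider with one dedicated signal group per signal term
  registry <- default_registry(spec$provider_dim)
  prov_groups <- registry$name[registry$provider_id == "external"]
  signal <- stats::setNames(lapply(seq_along(signal_terms), function(i)
    list(positives = truth[[signal_terms[i]]], strength = spec$signal_strength)),
    prov_groups[seq_along(signal_terms)])
  providers <- list(native = native_provider(),
                    external = mock_provider(spec$seed, signal))
  features <- assemble_features(proteins, providers, registry)

  # homology blocks: near-zero within, large between
  blocks <- stats::setNames(rep(seq_len(spec$n_blocks), length.out = n), acc)
  d <- with_seed(derive_seed(spec$seed, "dist"), {
    m <- matrix(stats::runif(n * n, 5, 10), n, n, dimnames = list(acc, acc))
    same <- outer(blocks, blocks, "==")
    m[same] <- stats::runif(sum(same), 0, 0.02)
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    diag(m) <- 0
    m
  })

  list(corpus = corpus, features = features, distances = d, truth = truth,
       signal_terms = signal_terms, noise_term = noise_term,
       vocab = graph$terms$id, blocks = blocks)
}

## ------------------------------------------------------------------ writers

#' Write an ontology as an OBO file
#' @param graph an `fp_ontology`.
#' @param path output path.
#' @export
write_obo <- function(graph, path) {
  ns_back <- stats::setNames(names(OBO_NAMESPACES), OBO_NAMESPACES)
  con <- file(path, "w"); on.exit(close(con))
  writeLines("format-version: 1.2", con)
  e <- graph$edges
  for (i in seq_len(nrow(graph$terms))) {
    t <- graph$terms[i, ]
    out <- c("", "[Term]", paste0("id: ", t$id), paste0("name: ", t$name))
    if (!is.na(t$namespace)) out <- c(out, paste0("namespace: ", ns_back[[t$namespace]]))
    alt <- names(graph$alt)[graph$alt == t$id]
    out <- c(out, paste0("alt_id: ", alt))
    isa <- e$parent[e$child == t$id & e$relation == "is_a"]
    out <- c(out, paste0("is_a: ", isa))
    po <- e$parent[e$child == t$id & e$relation == "part_of"]
    out <- c(out, paste0("relationship: part_of ", po))
    if (t$obsolete) out <- c(out, "is_obsolete: true")
    if (!is.na(t$replaced_by)) out <- c(out, paste0("replaced_by: ", t$replaced_by))
    writeLines(out, con)
  }
  invisible(path)
}

#' Write protein sequences as FASTA
#' @param proteins data.frame with `accession` and `sequence`.
#' @param path output path.
#' @export
write_fasta <- function(proteins, path) {
  aa <- Biostrings::AAStringSet(stats::setNames(proteins$sequence,
                                                proteins$accession))
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' Write annotations as a GAF-style TSV (accession, term, evidence)
#' @param annotations data.frame with `accession`, `term`, `evidence`.
#' @param path output path.
#' @export
write_gaf <- function(annotations, path) {
  utils::write.table(annotations[, c("accession", "term", "evidence")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Write a fixture to disk in every input format the pipeline reads
#'
#' Emits OBO, FASTA, GAF TSV, feature TSV, distance TSV and a vocabulary
#' list under `dir`, and returns the file paths.
#'
#' @param spec an [fixture_spec()].
#' @param dir output directory (created if needed).
#' @return named list of paths plus the in-memory fixture (`$fixture`).
#' @export
write_fixture <- function(spec = fixture_spec(), dir = tempfile("fixture")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  graph <- make_ontology(spec)
  fx <- make_proteome(spec, graph)
  paths <- list(ontology = file.path(dir, "ontology.obo"),
                sequences = file.path(dir, "proteins.fasta"),
                annotations = file.path(dir, "annotations.tsv"),
                features = file.path(dir, "features.tsv"),
                distances = file.path(dir, "distances.tsv"),
                vocab = file.path(dir, "vocab.txt"))
  write_obo(graph, paths$ontology)
  write_fasta(fx$corpus$proteins, paths$sequences)
  write_gaf(fx$corpus$annotations, paths$annotations)
  write_features(fx$features, paths$features)
  write_distances(fx$distances, paths$distances)
  writeLines(fx$vocab, paths$vocab)
  c(paths, list(fixture = fx, graph = graph))
}
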