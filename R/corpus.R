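## Dataset builder: annotation corpus loading, length/redundancy filters,
## and per-term positive/negative training-set construction.

#' Load a protein annotation corpus
#'
#' Reads amino-acid sequences (FASTA) and a GAF-style annotation table into
#' a single corpus object.  The annotation table is tab-separated with at
#' least three columns: protein accession, GO term, evidence code; a fourth
#' column, when present, is read as the qualifier and rows containing `NOT`
#' are dropped (negated annotations would poison positive sets).  Comment
#' lines starting with `!` are skipped.  Annotations whose accession has no
#' sequence are dropped (counted and reported via `attr(, "dropped")`).
#'
#' @param fasta path to a FASTA file of protein sequences.
#' @param gaf path to the annotation TSV.
#' @return an `fp_corpus`: list with `proteins` (data.frame `accession`,
#'   `sequence`, `length`) and `annotations` (data.frame `accession`,
#'   `term`, `evidence`).
#' @export
load_corpus <- function(fasta, gaf) {
  aa <- Biostrings::readAAStringSet(fasta)
  proteins <- data.frame(accession = sub("\\s.*$", "", names(aa)),
                         sequence = as.character(aa),
                         stringsAsFactors = FALSE)
  proteins$length <- nchar(proteins$sequence)
  rownames(proteins) <- NULL

  lines <- readLines(gaf, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "!")]
  if (!length(lines)) stop("annotation file has no usable rows")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ok <- lengths(parts) >= 3L
  malformed <- sum(!ok)
  parts <- parts[ok]
  ann <- data.frame(accession = vapply(parts, `[[`, "", 1L),
                    term = vapply(parts, `[[`, "", 2L),
                    evidence = vapply(parts, `[[`, "", 3L),
                    stringsAsFactors = FALSE)
  qual <- vapply(parts, function(p) if (length(p) >= 4L) p[[4L]] else "", "")
  negated <- grepl("NOT", qual, fixed = TRUE)
  ann <- ann[!negated, , drop = FALSE]
  orphan <- !ann$accession %in% proteins$accession
  ann <- ann[!orphan, , drop = FALSE]
  if (!nrow(ann)) stop("no usable annotation rows after filtering")
  log_msg("load_corpus: %d malformed, %d NOT-qualified, %d orphan rows dropped",
          malformed, sum(negated), sum(orphan))
  structure(list(proteins = proteins, annotations = ann),
            class = "fp_corpus",
            dropped = c(malformed = malformed, negated = sum(negated),
                        orphan = sum(orphan)))
}

#' @export
print.fp_corpus <- function(x, ...) {
  cat(sprintf("fp_corpus: %d proteins, %d annotations (%d distinct terms)\n",
              nrow(x$proteins), nrow(x$annotations),
              length(unique(x$annotations$term))))
  invisible(x)
}

#' Greedy k-mer containment redundancy reducer
#'
#' Default implementation of the redundancy-reducer interface: sequences are
#' visited longest-first and joined to an existing representative when the
#' fraction of shared k-mers (relative to the smaller k-mer set) reaches the
#' identity threshold.  Adequate for fixtures and moderate corpora; users
#' with large proteomes plug an external clusterer with the same signature.
#'
#' @param sequences character vector of sequences (named by accession).
#' @param threshold identity fraction in (0, 1].
#' @param k k-mer length.
#' @return integer vector: indices of the retained representatives.
#' @export
kmer_reducer <- function(sequences, threshold, k = 5L) {
  kmers <- lapply(sequences, function(s) {
    if (nchar(s) < k) return(s)
    unique(substring(s, 1:(nchar(s) - k + 1L), k:nchar(s)))
  })
  ord <- order(-nchar(sequences), names(sequences) %||% seq_along(sequences))
  reps <- integer(0)
  for (i in ord) {
    dup <- FALSE
    for (r in reps) {
      shared <- sum(kmers[[i]] %in% kmers[[r]])
      if (shared / min(length(kmers[[i]]), length(kmers[[r]])) >= threshold) {
        dup <- TRUE; break
      }
    }
    if (!dup) reps <- c(reps, i)
  }
  sort(reps)
}

#' Filter a corpus by length and sequence redundancy
#'
#' Removes proteins longer than `max_length` residues, then applies a
#' redundancy reducer at the given identity threshold, keeping one
#' representative per cluster.  Annotations of removed proteins are dropped.
#'
#' @param corpus an `fp_corpus`.
#' @param max_length maximum sequence length in residues (default 1500).
#' @param reducer function `(sequences, threshold) -> representative
#'   indices`; defaults to [kmer_reducer()].
#' @param identity_threshold pairwise identity threshold (default 0.90).
#' @return the filtered `fp_corpus`.
#' @export
filter_proteins <- function(corpus, max_length = 1500,
                            reducer = kmer_reducer,
                            identity_threshold = 0.90) {
  p <- corpus$proteins
  p <- p[p$length <= max_length, , drop = FALSE]
  if (nrow(p)) {
    seqs <- stats::setNames(p$sequence, p$accession)
    keep <- reducer(seqs, identity_threshold)
    p <- p[keep, , drop = FALSE]
  }
  ann <- corpus$annotations
  ann <- ann[ann$accession %in% p$accession, , drop = FALSE]
  log_msg("filter_proteins: %d proteins retained", nrow(p))
  structure(list(proteins = p, annotations = ann), class = "fp_corpus")
}

#' Build the positive/negative training set for one GO term
#'
#' Positives are proteins annotated with the term or any of its descendants
#' (following both `is_a` and `part_of`).  Negatives are proteins that
#' (i) are not annotated with the term, its descendants or its ancestors,
#' and (ii) nonetheless carry at least `min_mf` distinct molecular-function
#' and `min_bp` distinct biological-process direct annotations whose
#' evidence code is not in [EXCLUDED_NEGATIVE_EVIDENCE].  The term is
#' eligible for model training when it occurs in the supplied vocabulary
#' and the positive and negative sets reach `min_pos` and `min_neg`.
#'
#' @param term GO id present in `graph`.
#' @param corpus a filtered `fp_corpus`.
#' @param graph an `fp_ontology`.
#' @param vocab character vector of admissible term ids (e.g. the set of
#'   terms appearing in curated SwissProt annotations), or `NULL` to skip
#'   the vocabulary check.
#' @param min_pos,min_neg eligibility thresholds (defaults 150 / 500).
#' @param min_mf,min_bp per-namespace direct-annotation requirements for
#'   negatives (defaults 2 / 2).
#' @return an `fp_term_set`: list with `term`, `positives`, `negatives`
#'   (accession vectors), `eligible` (flag) and `reason` (string, empty
#'   when eligible).
#' @export
term_training_set <- function(term, corpus, graph, vocab = NULL,
                              min_pos = 150, min_neg = 500,
                              min_mf = 2, min_bp = 2) {
  .check_term(graph, term)
  ann <- corpus$annotations
  desc <- go_descendants(graph, term)
  anc <- go_ancestors(graph, term)

  pos <- unique(ann$accession[ann$term %in% c(term, desc)])
  lineage <- c(term, desc, anc)
  tainted <- unique(ann$accession[ann$term %in% lineage])

  ns_of <- stats::setNames(graph$terms$namespace, graph$terms$id)
  good <- ann[!ann$evidence %in% EXCLUDED_NEGATIVE_EVIDENCE, , drop = FALSE]
  good <- good[good$term %in% names(ns_of), , drop = FALSE]
  good$ns <- ns_of[good$term]
  n_mf <- tapply(good$term[good$ns == "MF"], good$accession[good$ns == "MF"],
                 function(t) length(unique(t)))
  n_bp <- tapply(good$term[good$ns == "BP"], good$accession[good$ns == "BP"],
                 function(t) length(unique(t)))
  well <- intersect(names(n_mf)[n_mf >= min_mf], names(n_bp)[n_bp >= min_bp])
  neg <- sort(setdiff(intersect(well, corpus$proteins$accession), tainted))
  pos <- sort(pos)

  reason <- character(0)
  if (!is.null(vocab) && !term %in% vocab) reason <- c(reason, "not in vocabulary")
  if (length(pos) < min_pos) reason <- c(reason, sprintf("positives<%d", min_pos))
  if (length(neg) < min_neg) reason <- c(reason, sprintf("negatives<%d", min_neg))
  structure(list(term = term, positives = pos, negatives = neg,
                 eligible = !length(reason),
                 reason = paste(reason, collapse = "; ")),
            class = "fp_term_set")
}

#' @export
print.fp_term_set <- function(x, ...) {
  cat(sprintf("fp_term_set %s: %d positives, %d negatives — %s\n",
              x$term, length(x$positives), length(x$negatives),
              if (x$eligible) "eligible" else paste("rejected:", x$reason)))
  invisible(x)
}

#' Serialize a term training set as a 2-column TSV (accession, label)
#' @param tset an `fp_term_set`.
#' @param path output path.
#' @export
write_term_set <- function(tset, path) {
  d <- data.frame(accession = c(tset$positives, tset$negatives),
                  label = c(rep("+", length(tset$positives)),
                            rep("-", length(tset$negatives))))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_term_set
#' @param term the GO id to attach to the read set.
#' @export
read_term_set <- function(path, term) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  structure(list(term = term,
                 positives = d$accession[d$label == "+"],
                 negatives = d$accession[d$label == "-"],
                 eligible = TRUE, reason = ""),
            class = "fp_term_set")
}
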