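## Feature space: the 14-group registry, native sequence-derived features,
## vector assembly from pluggable providers, group dropping, and [0,1]
## min-max scaling.

AA20 <- c("A","R","N","D","C","E","Q","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")

# average residue masses (Da); water added once per chain
AA_MASS <- c(A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886,
             C = 103.1388, E = 129.1155, Q = 128.1307, G = 57.0519,
             H = 137.1411, I = 113.1594, L = 113.1594, K = 128.1741,
             M = 131.1926, F = 147.1766, P = 97.1167, S = 87.0782,
             T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
WATER_MASS <- 18.01528

# Kyte-Doolittle hydropathy
AA_KD <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, E = -3.5,
           Q = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
           M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
           Y = -1.3, V = 4.2)

#' The default 14-group feature registry
#'
#' Feature groups mirror the classic sequence-feature encoding for
#' function prediction: two groups computed natively from the amino-acid
#' sequence (composition and global sequence features) and twelve groups
#' whose values come from external predictor output (transmembrane
#' topology, secondary structure, intrinsic disorder, signal peptides,
#' subcellular localization, PEST regions, low-complexity regions, coiled
#' coils, phosphorylation and glycosylation sites).  The per-group feature
#' lists of the external predictors are provider contracts; their
#' dimensions are configurable and default to `provider_dim`.
#'
#' @param provider_dim dimension used for every provider-backed group.
#' @return data.frame with columns `name`, `dimension`, `provider_id`.
#' @export
default_registry <- function(provider_dim = 4L) {
  prov <- c("transmembrane_segments", "secondary_structure",
            "disordered_regions", "disorder_composition",
            "signal_peptides", "subcellular_localization",
            "pest_regions", "low_complexity_regions", "coiled_coils",
            "phosphorylation_sites", "n_glycosylation_sites",
            "o_glycosylation_sites")
  data.frame(name = c("amino_acid_composition", "sequence_features", prov),
             dimension = c(20L, 5L, rep(as.integer(provider_dim), length(prov))),
             provider_id = c("native", "native", rep("external", length(prov))),
             stringsAsFactors = FALSE)
}

#' Native sequence-derived feature groups
#'
#' Computes the two feature groups that need no external predictor:
#' \describe{
#'   \item{amino_acid_composition}{20 residue fractions.  Non-standard
#'     letters (X, B, Z, U, ...) are excluded from the denominator, so the
#'     fractions over the standard alphabet still sum to 1.}
#'   \item{sequence_features}{sequence length, molecular weight (average
#'     masses, Da), mean Kyte-Doolittle hydropathy, net charge at pH 7
#'     (Henderson-Hasselbalch over ionizable side chains and termini) and
#'     the fraction of charged residues (D, E, K, R, H).}
#' }
#'
#' @param sequence non-empty amino-acid string.
#' @return named list of two numeric vectors, `amino_acid_composition`
#'   (named by residue) and `sequence_features`.
#' @examples
#' native_features("ACDE")$amino_acid_composition[c("A", "C", "D", "E")]
#' @export
native_features <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence))
    stop("sequence must be a non-empty string")
  chars <- strsplit(toupper(sequence), "")[[1]]
  std <- chars[chars %in% AA20]
  if (!length(std)) stop("sequence contains no standard residues")
  comp <- as.numeric(table(factor(std, levels = AA20))) / length(std)
  names(comp) <- AA20

  len <- length(chars)
  mw <- sum(AA_MASS[std]) + WATER_MASS
  hydro <- mean(AA_KD[std])
  counts <- table(factor(std, levels = AA20))
  ph <- 7
  pos <- sum(counts["K"] / (1 + 10^(ph - 10.0)),
             counts["R"] / (1 + 10^(ph - 12.0)),
             counts["H"] / (1 + 10^(ph - 6.0)),
             1 / (1 + 10^(ph - 9.0)))                      # N-terminus
  neg <- sum(counts["D"] / (1 + 10^(4.05 - ph)),
             counts["E"] / (1 + 10^(4.45 - ph)),
             counts["C"] / (1 + 10^(9.0 - ph)),
             counts["Y"] / (1 + 10^(10.0 - ph)),
             1 / (1 + 10^(3.55 - ph)))                     # C-terminus
  charged <- sum(counts[c("D", "E", "K", "R", "H")]) / len
  list(amino_acid_composition = comp,
       sequence_features = c(length = len, mol_weight = mw,
                             mean_hydropathy = hydro,
                             net_charge_ph7 = pos - neg,
                             frac_charged = charged))
}

#' The native feature provider
#'
#' Provider callable for the two natively computed groups, with the
#' signature every provider must honour:
#' `function(accession, sequence, group, dimension) -> numeric(dimension)`.
#' @return a provider function.
#' @export
native_provider <- function() {
  function(accession, sequence, group, dimension) {
    nf <- native_features(sequence)
    if (!group %in% names(nf)) stop("native provider cannot serve group ", group)
    nf[[group]]
  }
}

#' Assemble feature vectors for a set of proteins
#'
#' Concatenates, in registry order, the output of each group's provider.
#' A missing provider or a provider returning the wrong dimension is an
#' error naming the offending group — absent features are never silently
#' defaulted.
#'
#' @param proteins data.frame with columns `accession` and `sequence`
#'   (an `fp_corpus$proteins` works).
#' @param providers named list of provider functions, keyed by the
#'   registry's `provider_id` values.
#' @param registry a registry data.frame (see [default_registry()]).
#' @return numeric matrix (one row per protein, accession rownames) with a
#'   `layout` attribute (data.frame `name`, `start`, `dimension`) and class
#'   `fp_features`.
#' @export
assemble_features <- function(proteins, providers, registry = default_registry()) {
  missing <- setdiff(unique(registry$provider_id), names(providers))
  if (length(missing))
    stop("no provider registered for id(s): ", paste(missing, collapse = ", "))
  total <- sum(registry$dimension)
  mat <- matrix(NA_real_, nrow(proteins), total,
                dimnames = list(proteins$accession, NULL))
  starts <- cumsum(c(1L, registry$dimension))[seq_len(nrow(registry))]
  colnames(mat) <- unlist(lapply(seq_len(nrow(registry)), function(g)
    paste0(registry$name[g], ".", seq_len(registry$dimension[g]))))
  for (g in seq_len(nrow(registry))) {
    fn <- providers[[registry$provider_id[g]]]
    for (i in seq_len(nrow(proteins))) {
      v <- fn(proteins$accession[i], proteins$sequence[i],
              registry$name[g], registry$dimension[g])
      if (length(v) != registry$dimension[g] || anyNA(v))
        stop(sprintf("provider '%s' returned %d values (expected %d) for group %s",
                     registry$provider_id[g], length(v),
                     registry$dimension[g], registry$name[g]))
      mat[i, starts[g]:(starts[g] + registry$dimension[g] - 1L)] <- v
    }
  }
  layout <- data.frame(name = registry$name, start = starts,
                       dimension = registry$dimension, stringsAsFactors = FALSE)
  structure(mat, layout = layout, class = c("fp_features", class(mat)))
}

.layout <- function(matrix) {
  l <- attr(matrix, "layout")
  if (is.null(l)) stop("feature matrix has no group layout")
  l
}

# column indices of a set of groups
.group_cols <- function(matrix, groups) {
  l <- .layout(matrix)
  unknown <- setdiff(groups, l$name)
  if (length(unknown)) stop("unknown feature group(s): ", paste(unknown, collapse = ", "))
  unlist(lapply(match(groups, l$name), function(g)
    l$start[g]:(l$start[g] + l$dimension[g] - 1L)))
}

#' Remove feature groups from a matrix
#'
#' Deletes the columns of the named groups and rebuilds the layout index.
#' Feature groups are all-or-nothing: a group is either fully present or
#' fully discarded.
#'
#' @param matrix an `fp_features` matrix.
#' @param removed character vector of group names (may be empty).
#' @return the reduced `fp_features` matrix.
#' @export
drop_groups <- function(matrix, removed) {
  if (!length(removed)) return(matrix)
  l <- .layout(matrix)
  unknown <- setdiff(removed, l$name)
  if (length(unknown)) stop("unknown feature group(s): ", paste(unknown, collapse = ", "))
  keep <- l[!l$name %in% removed, , drop = FALSE]
  if (!nrow(keep)) stop("cannot remove every feature group")
  cols <- .group_cols(matrix, keep$name)
  out <- matrix[, cols, drop = FALSE]
  keep$start <- cumsum(c(1L, keep$dimension))[seq_len(nrow(keep))]
  rownames(keep) <- NULL
  structure(out, layout = keep, class = class(matrix))
}

# subset rows, preserving layout
.rows <- function(matrix, accessions) {
  out <- matrix[accessions, , drop = FALSE]
  structure(out, layout = attr(matrix, "layout"), class = class(matrix))
}

#' Min-max feature scaling
#'
#' `fit_scaling()` records per-column minima and maxima of a training
#' matrix; `apply_scaling()` maps values into `[0, 1]`, clipping test
#' values that fall outside the training range and sending degenerate
#' (constant) columns to 0.  Fit scaling on training rows only.
#'
#' @param matrix numeric feature matrix.
#' @return `fit_scaling()`: an `fp_scaling` (list `min`, `max`);
#'   `apply_scaling()`: the scaled matrix.
#' @export
fit_scaling <- function(matrix) {
  if (!length(matrix)) stop("cannot fit scaling on an empty matrix")
  structure(list(min = apply(matrix, 2, min), max = apply(matrix, 2, max)),
            class = "fp_scaling")
}

#' @rdname fit_scaling
#' @param model an `fp_scaling`.
#' @export
apply_scaling <- function(model, matrix) {
  rng <- model$max - model$min
  out <- sweep(matrix, 2, model$min, "-")
  out <- sweep(out, 2, ifelse(rng > 0, rng, 1), "/")
  out[, rng == 0] <- 0
  out[out < 0] <- 0
  out[out > 1] <- 1
  structure(out, layout = attr(matrix, "layout"), class = class(matrix))
}

#' Write / read a feature matrix as TSV (accession + named columns)
#'
#' The group layout is rebuilt from the column names (`group.index`).
#' @param matrix an `fp_features` matrix.
#' @param path file path.
#' @export
write_features <- function(matrix, path) {
  d <- data.frame(accession = rownames(matrix), matrix,
                  check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(d[, -1, drop = FALSE])
  rownames(mat) <- d$accession
  grp <- sub("\\.[0-9]+$", "", colnames(mat))
  rle_g <- rle(grp)
  layout <- data.frame(name = rle_g$values,
                       start = cumsum(c(1L, rle_g$lengths))[seq_along(rle_g$values)],
                       dimension = rle_g$lengths, stringsAsFactors = FALSE)
  structure(mat, layout = layout, class = c("fp_features", class(mat)))
}
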