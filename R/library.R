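## Model-library serialization: JSON with per-term kernel, retained groups,
## Platt parameters, metrics, reliability, and the decision-function arrays
## (support vectors, coefficients, offset) plus the scaling model.

#' Write a model library to JSON
#'
#' Serializes every kept model (kernel spec, retained feature groups,
#' calibration A/B, holdout metrics, reliability tier) together with the
#' arrays needed to evaluate the decision function, so a library can be
#' reloaded without refitting.  Discarded terms are recorded with their
#' holdout metrics only.
#'
#' @param library an `fp_library`.
#' @param path output path.
#' @export
write_model_library <- function(library, path) {
  ser_model <- function(m) {
    out <- list(term = m$term,
                kernel = list(kind = m$kernel$kind, C = m$kernel$C,
                              gamma = m$kernel$gamma),
                retained_groups = as.list(m$retained_groups),
                k = m$k, seed = m$seed, cv_mcc = m$cv_mcc,
                holdout_metrics = m$holdout_metrics,
                reliability = m$reliability, discarded = m$discarded)
    if (!m$discarded) {
      out$calibration <- list(A = m$calibration$A, B = m$calibration$B)
      out$classifier <- list(kind = m$classifier$kind,
                             gamma = m$classifier$gamma,
                             sv = m$classifier$sv,
                             coefs = m$classifier$coefs,
                             rho = m$classifier$rho)
      out$scaling <- list(min = as.numeric(m$scaling$min),
                          max = as.numeric(m$scaling$max))
    }
    out
  }
  payload <- list(models = lapply(unname(library$models), ser_model),
                  discarded = lapply(unname(library$discarded), ser_model))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_model_library
#' @export
read_model_library <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE,
                                 simplifyMatrix = TRUE)
  de_model <- function(m) {
    mod <- structure(list(term = m$term,
                          kernel = kernel_spec(m$kernel$kind, m$kernel$C,
                                               m$kernel$gamma),
                          retained_groups = unlist(m$retained_groups),
                          cv_mcc = m$cv_mcc, k = m$k, seed = m$seed,
                          holdout_metrics = m$holdout_metrics,
                          reliability = m$reliability,
                          discarded = isTRUE(m$discarded),
                          classifier = NULL, scaling = NULL,
                          calibration = NULL),
                     class = "fp_term_model")
    if (!mod$discarded) {
      mod$calibration <- structure(list(A = m$calibration$A, B = m$calibration$B),
                                   class = "fp_platt")
      sv <- m$classifier$sv
      if (!is.matrix(sv)) sv <- matrix(unlist(sv), nrow = length(sv), byrow = TRUE)
      mod$classifier <- list(kind = m$classifier$kind,
                             gamma = m$classifier$gamma,
                             sv = sv, coefs = unlist(m$classifier$coefs),
                             rho = m$classifier$rho)
      mod$scaling <- structure(list(min = unlist(m$scaling$min),
                                    max = unlist(m$scaling$max)),
                               class = "fp_scaling")
    }
    mod
  }
  models <- lapply(payload$models, de_model)
  names(models) <- vapply(models, `[[`, "", "term")
  discarded <- lapply(payload$discarded, de_model)
  names(discarded) <- vapply(discarded, `[[`, "", "term")
  structure(list(models = models, discarded = discarded, config = NULL),
            class = "fp_library")
}

#' Write a prediction report as TSV
#'
#' Columns: accession, term, name, namespace, posterior, reliability,
#' displayed — sorted H-tier first, then descending posterior (the default
#' report order).
#'
#' @param report data.frame from [predict.fp_library()].
#' @param path output path.
#' @param graph optional `fp_ontology` used to attach term names and
#'   namespaces.
#' @export
write_report <- function(report, path, graph = NULL) {
  if (!is.null(graph) && nrow(report)) {
    i <- match(report$term, graph$terms$id)
    report$name <- graph$terms$name[i]
    report$namespace <- graph$terms$namespace[i]
    report <- report[, c("accession", "term", "name", "namespace",
                         "posterior", "reliability", "displayed")]
  }
  utils::write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
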