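## Run configuration: every named constant of the training and assessment
## recipes in one place, with a flat key = value file representation.

#' Pipeline run configuration
#'
#' Collects the input/output paths and every tunable constant of the
#' pipeline.  Defaults are the canonical recipe values: 1,500-residue
#' length cap, 90\% identity redundancy threshold, 30\% holdout, minimum
#' cross-validation group size 35, 150/500 positive/negative eligibility
#' thresholds, 0.05 holdout-MCC discard rule, (0.3, 0.3, 0.7, 0.3)
#' reliability thresholds, 0.5 display threshold and (0.75, 0.50, 0.25, 0)
#' COGIC strata.
#'
#' @param paths named list of file paths (`ontology`, `annotations`,
#'   `sequences`, `features`, `distances`, `vocab`, `models`, `out_dir`);
#'   any may be omitted until the command that needs it runs.
#' @param max_length,identity corpus filters.
#' @param holdout holdout fraction.
#' @param min_group minimum cross-validation group size.
#' @param min_pos,min_neg eligibility thresholds.
#' @param discard_mcc holdout-MCC discard threshold.
#' @param reliability_thresholds length-4 numeric (MCC, sens, spec, prec).
#' @param display_threshold posterior display cut-off.
#' @param cogic_strata,cogic_weights COGIC strata and combination weights.
#' @param linear_C,rbf_C,rbf_gamma hyper-parameter grid ranges.
#' @param seed master seed.
#' @return an `fp_config` list (with `$grid` expanded from the ranges).
#' @export
fp_config <- function(paths = list(), max_length = 1500, identity = 0.90,
                      holdout = 0.30, min_group = 35, min_pos = 150,
                      min_neg = 500, discard_mcc = 0.05,
                      reliability_thresholds = c(0.3, 0.3, 0.7, 0.3),
                      display_threshold = 0.5,
                      cogic_strata = c(0.75, 0.50, 0.25, 0),
                      cogic_weights = c(8, 4, 2, 1) / 15,
                      linear_C = 2^seq(-5, 7, 2), rbf_C = 2^seq(-5, 7, 2),
                      rbf_gamma = 2^seq(-9, 1, 2), seed = 1L) {
  stopifnot(holdout > 0, holdout < 1, min_group >= 1,
            length(reliability_thresholds) == 4,
            length(cogic_strata) == length(cogic_weights))
  structure(list(paths = paths, max_length = max_length, identity = identity,
                 holdout = holdout, min_group = min_group, min_pos = min_pos,
                 min_neg = min_neg, discard_mcc = discard_mcc,
                 reliability_thresholds = reliability_thresholds,
                 display_threshold = display_threshold,
                 cogic_strata = cogic_strata, cogic_weights = cogic_weights,
                 linear_C = linear_C, rbf_C = rbf_C, rbf_gamma = rbf_gamma,
                 grid = default_grid(linear_C, rbf_C, rbf_gamma),
                 seed = as.integer(seed)),
            class = "fp_config")
}

#' Write / read a configuration as a flat key = value file
#'
#' Paths are stored as `path.<name>`; numeric vectors as comma-separated
#' lists.  The representation is lossless: `read_config(write_config(x))`
#' reproduces `x`.
#'
#' @param config an `fp_config`.
#' @param path file path.
#' @export
write_config <- function(config, path) {
  num <- function(v) paste(format(v, digits = 17, trim = TRUE,
                                  scientific = FALSE), collapse = ",")
  keys <- c(
    vapply(names(config$paths), function(k)
      paste0("path.", k, " = ", config$paths[[k]]), ""),
    vapply(setdiff(names(config), c("paths", "grid")), function(k)
      paste0(k, " = ", num(config[[k]])), ""))
  writeLines(unname(keys), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- regmatches(lines, regexec("^\\s*([^=]+?)\\s*=\\s*(.*)$", lines))
  keys <- vapply(kv, `[[`, "", 2)
  vals <- vapply(kv, `[[`, "", 3)
  paths <- as.list(vals[startsWith(keys, "path.")])
  names(paths) <- sub("^path\\.", "", keys[startsWith(keys, "path.")])
  args <- list(paths = paths)
  for (i in which(!startsWith(keys, "path."))) {
    v <- as.numeric(strsplit(vals[i], ",")[[1]])
    args[[keys[i]]] <- if (keys[i] == "seed") as.integer(v) else v
  }
  do.call(fp_config, args)
}
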