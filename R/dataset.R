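#' Construct a study-level meta-analysis dataset
#'
#' Builds the container used by every estimator in the package: one row per
#' study, each carrying a design label (`"RCT"` or `"NRS"`) and a log-scale
#' effect `y` with standard error `se`.  Rows that instead provide the four
#' cells of a 2x2 table have `(y, se)` computed from the counts via
#' [log_odds_ratio()] or [log_risk_ratio()] according to `metric`; rows may
#' mix the two representations.  Studies whose table is degenerate (e.g. zero
#' events in both arms) are dropped with a warning, and the number dropped is
#' recorded in the `n_dropped` attribute.
#'
#' All effects are held on the natural-log scale internally; exponentiation
#' to the OR/RR scale happens only in reporting methods.
#'
#' @param studies a data.frame with columns `study_id`, `design`, and either
#'   `y` and `se` or `events_treat`, `total_treat`, `events_ctrl`,
#'   `total_ctrl` (or both; `y`/`se` win when both are present and complete).
#' @param metric `"OR"` or `"RR"`; the scale on which count rows are converted
#'   and on which results are reported.
#' @param label a name for the meta-analysis.
#' @param correction continuity correction passed to the effect-size
#'   functions.
#' @return An object of class `meta_dataset`: a list with elements `label`,
#'   `metric` and `studies` (the validated data.frame).
#' @examples
#' d <- meta_dataset(data.frame(
#'   study_id = c("a", "b", "c"),
#'   design   = c("RCT", "NRS", "NRS"),
#'   y        = c(-0.2, -0.5, -0.4),
#'   se       = c(0.25, 0.15, 0.30)), metric = "OR", label = "toy")
#' d
#' @export
meta_dataset <- function(studies, metric = c("OR", "RR"), label = "",
                         correction = 0.5) {
  metric <- match.arg(metric)
  stopifnot(is.data.frame(studies))
  count_cols <- c("events_treat", "total_treat", "events_ctrl", "total_ctrl")
  has_counts <- all(count_cols %in% names(studies))
  has_effect <- all(c("y", "se") %in% names(studies))
  if (!"study_id" %in% names(studies))
    stop("missing column 'study_id'")
  if (!"design" %in% names(studies))
    stop("missing column 'design'")
  if (!has_counts && !has_effect)
    stop("need columns 'y' and 'se', or the four count columns ",
         paste(count_cols, collapse = ", "))
  studies$study_id <- as.character(studies$study_id)
  studies$design <- as.character(studies$design)
  if (nrow(studies) < 1) stop("dataset must contain at least one study")
  bad <- which(!studies$design %in% c("RCT", "NRS"))
  if (length(bad))
    stop(sprintf("row %d, column 'design': unknown design label '%s' (use RCT or NRS)",
                 bad[1], studies$design[bad[1]]))
  if (anyDuplicated(studies$study_id))
    stop("column 'study_id': duplicated id '",
         studies$study_id[duplicated(studies$study_id)][1], "'")

  if (!has_effect) studies$y <- studies$se <- NA_real_
  if (!has_counts) for (cc in count_cols) studies[[cc]] <- NA_real_

  f <- effect_fun(metric)
  dropped <- logical(nrow(studies))
  for (i in seq_len(nrow(studies))) {
    if (is.finite(studies$y[i]) && is.finite(studies$se[i])) next
    cnt <- as.numeric(studies[i, count_cols])
    if (any(!is.finite(cnt)))
      stop(sprintf("row %d: neither (y, se) nor a complete 2x2 table provided", i))
    res <- tryCatch(f(cnt[1], cnt[2], cnt[3], cnt[4], correction = correction),
                    bfmeta_incomputable_study = function(e) e)
    if (inherits(res, "condition")) {
      warning(sprintf("row %d ('%s') dropped: %s", i, studies$study_id[i],
                      conditionMessage(res)), call. = FALSE)
      dropped[i] <- TRUE
    } else {
      studies$y[i] <- res$y
      studies$se[i] <- res$se
    }
  }
  studies <- studies[!dropped, , drop = FALSE]
  if (nrow(studies) < 1)
    stop("no computable studies remain in the dataset")
  bad_se <- which(!is.finite(studies$se) | studies$se <= 0)
  if (length(bad_se))
    stop(sprintf("row %d, column 'se': standard error must be > 0", bad_se[1]))
  if (any(!is.finite(studies$y)))
    stop("non-finite effect estimate 'y'")
  rownames(studies) <- NULL
  structure(list(label = label, metric = metric, studies = studies),
            n_dropped = sum(dropped), class = "meta_dataset")
}

#' @export
print.meta_dataset <- function(x, ...) {
  cat(sprintf("Meta-analysis dataset '%s' (%s metric): %d studies (%d RCT, %d NRS)\n",
              x$label, x$metric, nrow(x$studies),
              sum(x$studies$design == "RCT"), sum(x$studies$design == "NRS")))
  print(x$studies[, c("study_id", "design", "y", "se")], digits = 4)
  invisible(x)
}

## design subsets keep label/metric; used by the model-comparison machinery
subset_design <- function(dataset, design) {
  keep <- dataset$studies$design == design
  if (!any(keep)) stop("no ", design, " studies in dataset '", dataset$label, "'")
  structure(list(label = paste0(dataset$label, " [", design, "]"),
                 metric = dataset$metric,
                 studies = dataset$studies[keep, , drop = FALSE]),
            class = "meta_dataset")
}

design_counts <- function(dataset) {
  c(k = nrow(dataset$studies),
    k_rct = sum(dataset$studies$design == "RCT"),
    k_nrs = sum(dataset$studies$design == "NRS"))
}

#' Read a study-level CSV file
#'
#' Reads a comma-separated, UTF-8 file with a header row into a
#' [meta_dataset()].  Required columns are `study_id`, `design`, and either
#' `(y, se)` or the four count columns `events_treat`, `total_treat`,
#' `events_ctrl`, `total_ctrl`.  The metric is taken from the `metric`
#' argument, or, when that is `NULL`, from a YAML sidecar file
#' `<path>.yml`/`<path>.yaml` with a `metric` field.
#'
#' @param path path to the CSV file.
#' @param metric `"OR"`, `"RR"`, or `NULL` to consult the sidecar.
#' @param label dataset label; defaults to the file name.
#' @param correction continuity correction for count rows.
#' @return A `meta_dataset`.
#' @seealso [write_meta_csv()] for the inverse operation.
#' @export
read_meta_csv <- function(path, metric = NULL, label = NULL, correction = 0.5) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(metric)) {
    sidecar <- c(paste0(path, ".yml"), paste0(path, ".yaml"),
                 sub("\\.csv$", ".yml", path))
    sidecar <- sidecar[file.exists(sidecar)]
    if (length(sidecar) && requireNamespace("yaml", quietly = TRUE)) {
      metric <- yaml::read_yaml(sidecar[1])$metric
    }
    if (is.null(metric))
      stop("no 'metric' given and no YAML sidecar found for ", path)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  meta_dataset(df, metric = metric,
               label = if (is.null(label)) basename(path) else label,
               correction = correction)
}

#' Write a meta-analysis dataset to CSV
#'
#' Writes all study fields at full double precision, so that
#' `read_meta_csv(write_meta_csv(d, f))` reproduces `d` exactly.
#'
#' @param dataset a `meta_dataset`.
#' @param path output file path.
#' @param sidecar if `TRUE` (default) also write a `<path>.yml` sidecar
#'   recording the metric and label (requires the `yaml` package).
#' @return `path`, invisibly.
#' @export
write_meta_csv <- function(dataset, path, sidecar = TRUE) {
  stopifnot(inherits(dataset, "meta_dataset"))
  df <- dataset$studies
  for (nm in names(df))
    if (is.double(df[[nm]]))
      df[[nm]] <- vapply(df[[nm]], function(v)
        if (is.na(v)) "" else format(v, digits = 17), character(1))
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  if (sidecar && requireNamespace("yaml", quietly = TRUE))
    yaml::write_yaml(list(metric = dataset$metric, label = dataset$label),
                     paste0(path, ".yml"))
  invisible(path)
}
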