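# Corpus TSV reading/writing, model configuration files, report
# serialization. Corpora are TSV (not CSV) so labels containing commas
# survive round trips; everything is UTF-8.

corpus_columns <- c("speaker_id", "group", "object_id", "token")

#' Read a labeling corpus from a TSV file
#'
#' Expects a header `speaker_id  group  object_id  token` and one event
#' per row. Validation failures (missing columns, tokens outside the
#' label space, a speaker labeling one object inconsistently) raise
#' structured errors that name the offending rows.
#'
#' @param path Path to the TSV file.
#' @param space A [label_space()].
#' @param groups Group thetas as accepted by [labeling_corpus()].
#' @return A validated [labeling_corpus()].
#' @export
read_corpus <- function(path, space, groups) {
  if (!file.exists(path)) {
    wt_stop(paste("no such corpus file:", path), "wordtrust_validation_error")
  }
  events <- utils::read.delim(path, colClasses = "character",
                              fileEncoding = "UTF-8")
  missing_cols <- setdiff(corpus_columns, names(events))
  if (length(missing_cols)) {
    wt_stop(paste0(path, " is missing column(s): ",
                   paste(missing_cols, collapse = ", ")),
            "wordtrust_validation_error")
  }
  labeling_corpus(events, space, groups)
}

#' Write a labeling corpus to a TSV file
#'
#' @param corpus A [labeling_corpus()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  stopifnot(inherits(corpus, "labeling_corpus"))
  utils::write.table(as.data.frame(corpus)[, corpus_columns], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a model configuration file
#'
#' YAML (or JSON, which YAML parses) with keys `labels` (list of label
#' strings), `groups` (map group name -> theta), `label_prior`
#' (`"uniform"` or a map label -> probability) and `k_prior` (number in
#' `[0, 1]`). Unknown keys are rejected so typos fail loudly.
#'
#' @param path Path to the config file.
#' @return A list with `space` (a [label_space()]), `thetas`,
#'   `label_prior` (`NULL` for uniform) and `k_prior`.
#' @export
read_model_config <- function(path) {
  if (!file.exists(path)) {
    wt_stop(paste("no such config file:", path), "wordtrust_validation_error")
  }
  cfg <- yaml::read_yaml(path)
  allowed <- c("labels", "groups", "label_prior", "k_prior")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown)) {
    wt_stop(paste("unknown config key(s):", paste(unknown, collapse = ", ")),
            "wordtrust_validation_error")
  }
  if (is.null(cfg$labels) || is.null(cfg$groups)) {
    wt_stop("config must declare 'labels' and 'groups'",
            "wordtrust_validation_error")
  }
  space <- label_space(unlist(cfg$labels))
  thetas <- as_theta_map(unlist(cfg$groups))
  label_prior <- cfg$label_prior
  if (is.null(label_prior) || identical(label_prior, "uniform")) {
    label_prior <- NULL
  } else {
    label_prior <- resolve_label_prior(unlist(label_prior), space)
  }
  k_prior <- if (is.null(cfg$k_prior)) 0.5 else as.numeric(cfg$k_prior)
  if (k_prior < 0 || k_prior > 1) {
    wt_stop("k_prior must lie in [0, 1]", "wordtrust_validation_error")
  }
  list(space = space, thetas = thetas, label_prior = label_prior,
       k_prior = k_prior)
}

report_rows <- function(report) {
  if (inherits(report, "sim1_report")) {
    df <- as.data.frame(report)
    df$kl <- signif(df$kl, 6)
    df
  } else if (inherits(report, "sim2_report")) {
    data.frame(label = names(report$posterior),
               posterior = signif(as.numeric(report$posterior), 6))
  } else {
    wt_stop("write_report handles sim1_report and sim2_report objects",
            "wordtrust_validation_error")
  }
}

report_payload <- function(report) {
  if (inherits(report, "sim1_report")) {
    list(report = "simulation1", parameters = attr(report, "params"),
         cells = as.data.frame(report))
  } else {
    list(report = "simulation2",
         parameters = list(condition = report$condition,
                           method = report$method,
                           habituated = report$habituated,
                           tokens = report$tokens,
                           k_prior = report$k_prior,
                           settings = if (!is.null(report$settings))
                             unclass(report$settings)),
         posterior = as.list(unclass(report$posterior)))
  }
}

#' Serialize a simulation report
#'
#' CSV output carries values at 6 significant digits in the published
#' table layout (four KL cells for simulation 1, one row per label for
#' simulation 2); JSON output keeps full precision plus the parameters
#' needed to regenerate the report.
#'
#' @param report A `sim1_report` or `sim2_report`.
#' @param path Output path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.csv(report_rows(report), path, row.names = FALSE)
  } else {
    jsonlite::write_json(report_payload(report), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}
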