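#' @keywords internal
wt_stop <- function(message, class, call = sys.call(-1)) {
  stop(errorCondition(message, class = c(class, "wordtrust_error"),
                      call = call))
}

#' Define the finite space of candidate labels
#'
#' The model treats labels as atomic, case-sensitive strings; no phonetic
#' structure is represented. Every category, intention and produced token
#' handled by the package must belong to one label space.
#'
#' @param labels Character vector of distinct label strings (length >= 1).
#' @return An object of class `label_space` with elements `labels` and `n`.
#' @examples
#' label_space(c("buk", "puk", "duk"))
#' @export
label_space <- function(labels) {
  labels <- as.character(labels)
  if (length(labels) < 1L || anyNA(labels)) {
    wt_stop("a label space needs at least one non-missing label",
            "wordtrust_validation_error")
  }
  if (anyDuplicated(labels)) {
    wt_stop("labels must be unique", "wordtrust_validation_error")
  }
  structure(list(labels = labels, n = length(labels)), class = "label_space")
}

#' @export
print.label_space <- function(x, ...) {
  cat("<label_space> n =", x$n, ":", paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}

#' Declare a speaker group with characteristic knowledgeability
#'
#' A group (e.g., adult humans vs. inanimate audio speakers) is summarized
#' by `theta`, the probability that one of its members is knowledgeable,
#' i.e. `P(K = 1 | G) = theta`.
#'
#' @param name Group identifier string.
#' @param theta Probability in `[0, 1]` that a member is knowledgeable.
#' @return An object of class `group_spec`.
#' @examples
#' group_spec("audio", 0.15)
#' @export
group_spec <- function(name, theta) {
  if (!is.character(name) || length(name) != 1L || is.na(name)) {
    wt_stop("group name must be a single string", "wordtrust_validation_error")
  }
  theta <- as.numeric(theta)
  if (length(theta) != 1L || is.na(theta) || theta < 0 || theta > 1) {
    wt_stop("theta must be a probability in [0, 1]",
            "wordtrust_validation_error")
  }
  structure(list(name = name, theta = theta), class = "group_spec")
}

#' @export
print.group_spec <- function(x, ...) {
  cat(sprintf("<group_spec> %s: theta = %g\n", x$name, x$theta))
  invisible(x)
}

#' Construct a belief over binary speaker knowledgeability
#'
#' @param p_knowledgeable Probability that `K = 1`.
#' @return A named numeric vector of class `bernoulli_belief` with entries
#'   `knowledgeable` and `unknowledgeable`.
#' @export
bernoulli_belief <- function(p_knowledgeable) {
  p <- as.numeric(p_knowledgeable)
  if (length(p) != 1L || is.na(p) || p < 0 || p > 1) {
    wt_stop("p_knowledgeable must be a probability in [0, 1]",
            "wordtrust_validation_error")
  }
  structure(c(knowledgeable = p, unknowledgeable = 1 - p),
            class = "bernoulli_belief")
}

#' @export
print.bernoulli_belief <- function(x, ...) {
  print(unclass(x), ...)
  invisible(x)
}

#' Construct a categorical distribution over labels or hypotheses
#'
#' @param probs Named numeric vector of nonnegative weights summing to 1
#'   (within 1e-9). Names are the support.
#' @return A named numeric vector of class `categorical_distribution`.
#' @export
categorical_distribution <- function(probs) {
  if (is.null(names(probs)) || anyDuplicated(names(probs))) {
    wt_stop("probs must be named with unique support values",
            "wordtrust_validation_error")
  }
  probs <- vapply(probs, as.numeric, numeric(1))
  if (any(is.na(probs)) || any(probs < 0)) {
    wt_stop("probabilities must be nonnegative", "wordtrust_validation_error")
  }
  if (abs(sum(probs) - 1) > 1e-9) {
    wt_stop(sprintf("probabilities sum to %.12f, not 1", sum(probs)),
            "wordtrust_validation_error")
  }
  structure(probs, class = "categorical_distribution")
}

#' @export
print.categorical_distribution <- function(x, ...) {
  print(unclass(x), ...)
  invisible(x)
}

# coerce a list-of-group_spec or named theta vector to a named theta vector
as_theta_map <- function(groups) {
  if (is.numeric(groups) && !is.null(names(groups))) {
    thetas <- groups
  } else if (inherits(groups, "group_spec")) {
    thetas <- stats::setNames(groups$theta, groups$name)
  } else if (is.list(groups)) {
    thetas <- vapply(groups, function(g) {
      if (!inherits(g, "group_spec")) {
        wt_stop("groups must be group_spec objects or a named theta vector",
                "wordtrust_validation_error")
      }
      g$theta
    }, numeric(1))
    names(thetas) <- vapply(groups, `[[`, character(1), "name")
  } else {
    wt_stop("groups must be group_spec objects or a named theta vector",
            "wordtrust_validation_error")
  }
  if (anyDuplicated(names(thetas))) {
    wt_stop("duplicate group names", "wordtrust_validation_error")
  }
  if (any(thetas < 0 | thetas > 1)) {
    wt_stop("group thetas must lie in [0, 1]", "wordtrust_validation_error")
  }
  thetas
}

#' Assemble and validate a corpus of speaker-attributed labeling events
#'
#' A corpus records who said what about which object. Under the model a
#' speaker commits to one labeling intention per object and repeats it, so
#' a speaker producing two different tokens for the same object is an
#' observation with probability zero; such corpora are rejected here (error
#' class `wordtrust_zero_probability_corpus`) because no posterior is
#' defined over them.
#'
#' @param events Data frame with columns `speaker_id`, `group`, `object_id`
#'   and `token` (one labeling event per row, in order of occurrence).
#' @param space A [label_space()] containing every token.
#' @param groups Group knowledgeability: a named numeric vector of thetas,
#'   a single [group_spec()], or a list of them. Every `group` value in
#'   `events` must be declared here.
#' @return A data frame of class `labeling_corpus` carrying the label
#'   space, the theta map and `m` (number of distinct speakers) as
#'   attributes.
#' @examples
#' sp <- label_space(c("buk", "puk", "duk"))
#' ev <- data.frame(speaker_id = "s1", group = "adult",
#'                  object_id = "obj1", token = rep("buk", 7))
#' labeling_corpus(ev, sp, c(adult = 0.8))
#' @export
labeling_corpus <- function(events, space, groups) {
  stopifnot(inherits(space, "label_space"))
  needed <- c("speaker_id", "group", "object_id", "token")
  missing_cols <- setdiff(needed, names(events))
  if (length(missing_cols)) {
    wt_stop(paste("events is missing column(s):",
                  paste(missing_cols, collapse = ", ")),
            "wordtrust_validation_error")
  }
  events <- as.data.frame(events)[, needed]
  for (col in needed) events[[col]] <- as.character(events[[col]])
  if (nrow(events) < 1L) {
    wt_stop("a corpus needs at least one event", "wordtrust_validation_error")
  }
  thetas <- as_theta_map(groups)

  bad_tok <- which(!(events$token %in% space$labels))
  if (length(bad_tok)) {
    wt_stop(sprintf("token not in label space at row(s): %s",
                    paste(utils::head(bad_tok, 5L), collapse = ", ")),
            "wordtrust_invalid_label")
  }
  bad_grp <- which(!(events$group %in% names(thetas)))
  if (length(bad_grp)) {
    wt_stop(sprintf("undeclared group at row(s): %s",
                    paste(utils::head(bad_grp, 5L), collapse = ", ")),
            "wordtrust_validation_error")
  }
  # a speaker id must map to exactly one group
  grp_per_spk <- tapply(events$group, events$speaker_id,
                        function(g) length(unique(g)))
  if (any(grp_per_spk > 1L)) {
    wt_stop(paste("speaker(s) assigned to more than one group:",
                  paste(names(grp_per_spk)[grp_per_spk > 1L], collapse = ", ")),
            "wordtrust_validation_error")
  }
  # speaker consistency: all tokens identical within a speaker-object pair
  pair <- paste(events$speaker_id, events$object_id, sep = "\r")
  tok_per_pair <- tapply(events$token, pair, function(tt) length(unique(tt)))
  if (any(tok_per_pair > 1L)) {
    bad_pair <- names(tok_per_pair)[tok_per_pair > 1L][1L]
    rows <- which(pair == bad_pair)
    wt_stop(sprintf(
      "speaker '%s' labels object '%s' with different tokens (rows %s): the corpus has probability zero under the consistency model",
      sub("\r.*", "", bad_pair), sub(".*\r", "", bad_pair),
      paste(rows, collapse = ", ")),
      "wordtrust_zero_probability_corpus")
  }

  structure(events,
            class = c("labeling_corpus", "data.frame"),
            label_space = space,
            thetas = thetas,
            m = length(unique(events$speaker_id)))
}

#' @export
print.labeling_corpus <- function(x, ...) {
  cat(sprintf("<labeling_corpus> %d events, %d speaker(s), %d object(s), n = %d labels\n",
              nrow(x), attr(x, "m"), length(unique(x$object_id)),
              attr(x, "label_space")$n))
  print.data.frame(utils::head(as.data.frame(x), 10L), ...)
  if (nrow(x) > 10L) cat("...", nrow(x) - 10L, "more rows\n")
  invisible(x)
}

#' Number of distinct speakers in a corpus
#' @param corpus A [labeling_corpus()].
#' @return Integer speaker count `m`.
#' @export
n_speakers <- function(corpus) {
  stopifnot(inherits(corpus, "labeling_corpus"))
  attr(corpus, "m")
}
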