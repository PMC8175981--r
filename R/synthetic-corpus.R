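# Seeded sampling from the generative model, so every inference path can
# be exercised without external data, plus a label-recovery experiment.

#' Describe a synthetic corpus to be sampled from the generative model
#'
#' @param space A [label_space()].
#' @param true_categories Named character vector: object id -> true label.
#' @param speakers Data frame with columns `speaker_id` and `group`
#'   (unique speaker ids), or a named character vector speaker -> group.
#' @param groups Group thetas as accepted by [labeling_corpus()].
#' @param tokens_per_speaker_object Tokens each speaker produces per
#'   object (default 1).
#' @param seed Integer root seed; all sampling for this design derives
#'   from it.
#' @return A `corpus_design` list.
#' @examples
#' corpus_design(label_space(c("buk", "puk", "duk")),
#'               c(o1 = "buk"),
#'               data.frame(speaker_id = paste0("s", 1:7), group = "adult"),
#'               groups = c(adult = 0.9), seed = 42)
#' @export
corpus_design <- function(space, true_categories, speakers, groups,
                          tokens_per_speaker_object = 1L, seed = 1L) {
  stopifnot(inherits(space, "label_space"))
  if (is.null(names(true_categories)) ||
      !all(true_categories %in% space$labels)) {
    wt_stop("true_categories must be a named vector of labels from the space",
            "wordtrust_invalid_label")
  }
  if (is.character(speakers) && !is.null(names(speakers))) {
    speakers <- data.frame(speaker_id = names(speakers),
                           group = unname(speakers))
  }
  stopifnot(is.data.frame(speakers),
            all(c("speaker_id", "group") %in% names(speakers)))
  if (anyDuplicated(speakers$speaker_id)) {
    wt_stop("speaker ids must be unique", "wordtrust_validation_error")
  }
  thetas <- as_theta_map(groups)
  missing <- setdiff(speakers$group, names(thetas))
  if (length(missing)) {
    wt_stop(paste("undeclared group(s):", paste(missing, collapse = ", ")),
            "wordtrust_validation_error")
  }
  tokens_per_speaker_object <- as.integer(tokens_per_speaker_object)
  if (tokens_per_speaker_object < 1L) {
    wt_stop("tokens_per_speaker_object must be >= 1",
            "wordtrust_validation_error")
  }
  structure(list(space = space,
                 true_categories = true_categories,
                 speakers = speakers[, c("speaker_id", "group")],
                 thetas = thetas,
                 tokens_per_speaker_object = tokens_per_speaker_object,
                 seed = as.integer(seed)),
            class = "corpus_design")
}

# deterministic stream offsets derived from the root seed; the multiplier
# is prime and keeps derived seeds well below 2^31 for realistic indices
derive_seed <- function(root, index) {
  as.integer((as.numeric(root) + as.numeric(index) * 1009) %% 2147483647)
}

#' Sample one speaker's latent state from the generative model
#'
#' Draws `K ~ Bernoulli(theta_g)` and, per object, one fixed labeling
#' intention: the true category when knowledgeable, a uniform draw over
#' the `n` labels otherwise. Uses the current RNG state (seed it, or let
#' [sample_corpus()] manage seeding).
#'
#' @param speaker_id Speaker identifier.
#' @param group A [group_spec()].
#' @param design A [corpus_design()].
#' @return A `speaker_state` list: `speaker_id`, `group`, `k`, and
#'   `intentions` (named by object id).
#' @export
sample_speaker <- function(speaker_id, group, design) {
  stopifnot(inherits(group, "group_spec"), inherits(design, "corpus_design"))
  k <- stats::rbinom(1L, 1L, group$theta)
  objects <- names(design$true_categories)
  intentions <- vapply(objects, function(obj) {
    if (k == 1L) {
      design$true_categories[[obj]]
    } else {
      sample(design$space$labels, 1L)
    }
  }, character(1))
  structure(list(speaker_id = speaker_id, group = group$name, k = k,
                 intentions = intentions),
            class = "speaker_state")
}

#' Sample a labeling corpus from a design
#'
#' Deterministic given the design's seed: each speaker's state is drawn
#' on its own derived stream, then every speaker-object pair contributes
#' `tokens_per_speaker_object` identical tokens (production is noiseless
#' and intentions are fixed, so consistency holds by construction).
#'
#' @param design A [corpus_design()].
#' @return A validated [labeling_corpus()] with
#'   `speakers x objects x tokens_per_speaker_object` events.
#' @export
sample_corpus <- function(design) {
  stopifnot(inherits(design, "corpus_design"))
  objects <- names(design$true_categories)
  rows <- vector("list", nrow(design$speakers))
  for (i in seq_len(nrow(design$speakers))) {
    sid <- design$speakers$speaker_id[i]
    gname <- design$speakers$group[i]
    st <- withr::with_seed(derive_seed(design$seed, i), {
      sample_speaker(sid, group_spec(gname, design$thetas[[gname]]), design)
    })
    rows[[i]] <- data.frame(
      speaker_id = sid, group = gname,
      object_id = rep(objects, each = design$tokens_per_speaker_object),
      token = rep(unname(st$intentions),
                  each = design$tokens_per_speaker_object))
  }
  labeling_corpus(do.call(rbind, rows), design$space, design$thetas)
}

#' Label-recovery experiment over replicate synthetic corpora
#'
#' For each replicate a fresh corpus is sampled from the design and the
#' exact joint posterior is computed per object with priors matched to
#' the generative process (each speaker's knowledgeability prior is its
#' group's theta; uniform label prior). Reports how often the MAP label
#' equals the true category and the average posterior mass on it. MAP
#' ties are broken by label-space declaration order.
#'
#' @param design A [corpus_design()].
#' @param replicates Number of replicate corpora (>= 1).
#' @return A `recovery_report` list: `replicates`, `map_accuracy`,
#'   `mean_posterior_on_truth`.
#' @export
recovery_experiment <- function(design, replicates) {
  stopifnot(inherits(design, "corpus_design"), replicates >= 1)
  objects <- names(design$true_categories)
  hits <- 0L
  mass <- 0
  cells <- 0L
  for (r in seq_len(replicates)) {
    d_r <- design
    d_r$seed <- derive_seed(design$seed, 100000 + r)
    corp <- sample_corpus(d_r)
    k_prior <- stats::setNames(
      design$thetas[design$speakers$group], design$speakers$speaker_id)
    for (obj in objects) {
      sub <- labeling_corpus(
        as.data.frame(corp)[corp$object_id == obj, , drop = FALSE],
        design$space, design$thetas)
      marg <- joint_posterior_exact(sub, k_prior = k_prior)$label_marginal
      map_lab <- design$space$labels[which.max(marg[design$space$labels])]
      truth <- design$true_categories[[obj]]
      hits <- hits + as.integer(map_lab == truth)
      mass <- mass + marg[[truth]]
      cells <- cells + 1L
    }
  }
  structure(list(replicates = as.integer(replicates),
                 map_accuracy = hits / cells,
                 mean_posterior_on_truth = mass / cells),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf(
    "<recovery_report> %d replicates: MAP accuracy %.3f, mean posterior on truth %.3f\n",
    x$replicates, x$map_accuracy, x$mean_posterior_on_truth))
  invisible(x)
}
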