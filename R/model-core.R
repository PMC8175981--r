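# Generative model: group -> knowledgeability -> intention -> data.
# Knowledgeable speakers (K = 1) always intend the correct category;
# unknowledgeable speakers (K = 0) commit to one label drawn uniformly
# from the n candidates. Either way the intention is fixed per
# speaker-object pair and every produced token repeats it.

#' Prior belief about a speaker's knowledgeability given their group
#'
#' `P(K | G) = Bernoulli(theta_g)`: a member of group `G` is knowledgeable
#' with the group's characteristic probability.
#'
#' @param group A [group_spec()].
#' @return A [bernoulli_belief()] `(theta, 1 - theta)`.
#' @examples
#' knowledgeability_prior(group_spec("audio", 0.15))
#' @export
knowledgeability_prior <- function(group) {
  stopifnot(inherits(group, "group_spec"))
  bernoulli_belief(group$theta)
}

#' Distribution of a speaker's labeling intention
#'
#' Knowledgeable speakers intend the true category with certainty (a
#' Kronecker delta on `category`); unknowledgeable speakers pick among the
#' `n` labels uniformly.
#'
#' @param category True label of the object; must belong to `space`.
#' @param k Binary knowledgeability (0 or 1).
#' @param space A [label_space()].
#' @return A [categorical_distribution()] over the labels.
#' @examples
#' sp <- label_space(c("buk", "puk", "duk"))
#' intention_distribution("buk", k = 1, sp)
#' intention_distribution("buk", k = 0, sp)
#' @export
intention_distribution <- function(category, k, space) {
  stopifnot(inherits(space, "label_space"))
  if (!(category %in% space$labels)) {
    wt_stop(sprintf("category '%s' is not in the label space", category),
            "wordtrust_invalid_label")
  }
  if (!(k %in% c(0, 1))) {
    wt_stop("k must be 0 or 1", "wordtrust_validation_error")
  }
  p <- if (k == 1) {
    as.numeric(space$labels == category)
  } else {
    rep(1 / space$n, space$n)
  }
  categorical_distribution(stats::setNames(p, space$labels))
}

#' Distribution of the produced token given the intention
#'
#' In this release production is noiseless: the token `D` equals the
#' intention `I` with certainty. The stage is kept distinct from
#' [intention_distribution()] so production noise can be added later
#' without changing the API.
#'
#' @param intention Intended label; must belong to `space`.
#' @param space A [label_space()].
#' @return A [categorical_distribution()] with a point mass on `intention`.
#' @export
data_distribution <- function(intention, space) {
  stopifnot(inherits(space, "label_space"))
  if (!(intention %in% space$labels)) {
    wt_stop(sprintf("intention '%s' is not in the label space", intention),
            "wordtrust_invalid_label")
  }
  categorical_distribution(
    stats::setNames(as.numeric(space$labels == intention), space$labels))
}

#' Likelihood of a token sequence from one speaker-object pair
#'
#' Because a speaker forms one intention per object and repeats it, `t`
#' identical tokens carry the likelihood of a single intention draw, not
#' `t` independent draws: for `K = 1` the sequence has probability 1 if
#' every token equals `category` (else 0); for `K = 0` any internally
#' consistent sequence has probability `1/n` (the one uniform intention
#' draw), regardless of length. Mixed tokens have probability zero under
#' both values of `K`.
#'
#' @param tokens Nonempty character vector of tokens, all from one
#'   speaker-object pair.
#' @param category Candidate true category.
#' @param k Binary knowledgeability (0 or 1).
#' @param space A [label_space()].
#' @return A probability.
#' @examples
#' sp <- label_space(c("buk", "puk", "duk"))
#' sequence_likelihood(rep("buk", 7), "buk", k = 1, sp)  # 1
#' sequence_likelihood(rep("puk", 5), "buk", k = 0, sp)  # 1/3
#' sequence_likelihood(c("buk", "puk"), "buk", k = 1, sp)  # 0
#' @export
sequence_likelihood <- function(tokens, category, k, space) {
  stopifnot(inherits(space, "label_space"))
  if (length(tokens) < 1L) {
    wt_stop("tokens must be nonempty", "wordtrust_validation_error")
  }
  if (!all(tokens %in% space$labels)) {
    wt_stop("token(s) outside the label space", "wordtrust_invalid_label")
  }
  if (!(category %in% space$labels)) {
    wt_stop(sprintf("category '%s' is not in the label space", category),
            "wordtrust_invalid_label")
  }
  if (!(k %in% c(0, 1))) {
    wt_stop("k must be 0 or 1", "wordtrust_validation_error")
  }
  consistent <- length(unique(tokens)) == 1L
  if (!consistent) return(0)
  if (k == 1) as.numeric(tokens[1L] == category) else 1 / space$n
}
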