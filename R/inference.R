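# Posterior inference: single-event knowledgeability posteriors and their
# KL-divergence informativeness; joint (C, K-vector) posteriors by exact
# enumeration and by Gibbs sampling.

#' Posterior over a speaker's knowledgeability after one labeling event
#'
#' With the category known, Bayes' rule combines the group prior
#' `P(K | G) = Bernoulli(theta)` with the token likelihoods: a correct
#' token has likelihood 1 under `K = 1` and `1/n` under `K = 0`; an
#' incorrect token has likelihood 0 under `K = 1` (knowledgeable speakers
#' never err) and `1/n` under `K = 0`, collapsing the posterior to a point
#' mass on `K = 0`.
#'
#' @param token Produced label.
#' @param group A [group_spec()].
#' @param category True label of the object.
#' @param space A [label_space()].
#' @return A [bernoulli_belief()] `P(K | D, G, C)`.
#' @examples
#' sp <- label_space(c("buk", "puk", "duk"))
#' posterior_knowledgeability("buk", group_spec("adult", 0.8), "buk", sp)
#' @export
posterior_knowledgeability <- function(token, group, category, space) {
  stopifnot(inherits(group, "group_spec"), inherits(space, "label_space"))
  if (!(token %in% space$labels) || !(category %in% space$labels)) {
    wt_stop("token and category must belong to the label space",
            "wordtrust_invalid_label")
  }
  theta <- group$theta
  lik1 <- as.numeric(token == category)
  lik0 <- 1 / space$n
  num1 <- theta * lik1
  num0 <- (1 - theta) * lik0
  total <- num1 + num0
  if (total == 0) {
    wt_stop(sprintf(
      "impossible observation: token '%s' differs from category '%s' but theta = 1 makes every speaker knowledgeable",
      token, category),
      "wordtrust_impossible_observation")
  }
  bernoulli_belief(num1 / total)
}

#' Kullback-Leibler divergence between two knowledgeability beliefs
#'
#' `sum_K p(K) log(p(K) / q(K))` with the convention `0 * log(0/q) = 0`.
#' If `p` places mass where `q` has none the divergence is undefined and
#' an error of class `wordtrust_undefined_divergence` is raised (rather
#' than returning infinity): this is the situation after an incorrect
#' label from a group believed certainly knowledgeable.
#'
#' @param p,q [bernoulli_belief()] objects (or aligned nonnegative numeric
#'   vectors of equal length summing to 1).
#' @param log_base Base of the logarithm; base 2 (the default) gives bits.
#' @return Nonnegative divergence.
#' @examples
#' prior <- bernoulli_belief(0.15)
#' post <- bernoulli_belief(0)   # after an incorrect token
#' kl_divergence(post, prior)    # 0.2345 bits
#' @export
kl_divergence <- function(p, q, log_base = 2) {
  p <- as.numeric(p); q <- as.numeric(q)
  if (length(p) != length(q)) {
    wt_stop("p and q must share a support", "wordtrust_validation_error")
  }
  if (any(p > 0 & q == 0)) {
    wt_stop("KL divergence is undefined: p has mass where q has none",
            "wordtrust_undefined_divergence")
  }
  keep <- p > 0
  sum(p[keep] * log(p[keep] / q[keep], base = log_base))
}

#' Informativeness of one labeling event about speaker knowledgeability
#'
#' The model's looking-time index: the KL divergence between the
#' knowledgeability posterior after hearing one (correct or incorrect)
#' token and the group prior. The scalar is ordinal — larger values
#' predict longer looking — with no calibrated mapping to seconds.
#'
#' @param correct Logical; did the token match the true category?
#' @param group A [group_spec()].
#' @param space A [label_space()]; an incorrect event needs `n >= 2`.
#' @param log_base Logarithm base (2 = bits).
#' @return Nonnegative divergence in `log_base` units.
#' @examples
#' sp <- label_space(c("buk", "puk", "duk"))
#' event_informativeness(FALSE, group_spec("audio", 0.15), sp)  # 0.2345
#' @export
event_informativeness <- function(correct, group, space, log_base = 2) {
  stopifnot(is.logical(correct), length(correct) == 1L,
            inherits(space, "label_space"))
  category <- space$labels[1L]
  token <- if (correct) category else {
    if (space$n < 2L) {
      wt_stop("an incorrect event needs at least two labels",
              "wordtrust_validation_error")
    }
    space$labels[2L]
  }
  post <- posterior_knowledgeability(token, group, category, space)
  kl_divergence(post, knowledgeability_prior(group), log_base = log_base)
}

#' Predicted correctness-by-group interaction in event informativeness
#'
#' The incorrect-minus-correct informativeness gap for a characteristically
#' knowledgeable (human) group minus the same gap for a less knowledgeable
#' (audio) group. Zero when the two thetas coincide; antisymmetric under
#' swapping them; positive when the human group is the more knowledgeable.
#'
#' @param theta_human,theta_audio Group knowledgeability probabilities in
#'   `[0, 1)` (an incorrect event is undefined at theta = 1).
#' @param space A [label_space()].
#' @param log_base Logarithm base.
#' @return A signed number in `log_base` units.
#' @export
interaction_statistic <- function(theta_human, theta_audio, space,
                                  log_base = 2) {
  for (th in c(theta_human, theta_audio)) {
    if (th < 0 || th >= 1) {
      wt_stop("thetas must lie in [0, 1): the incorrect-event divergence is undefined at theta = 1",
              "wordtrust_undefined_divergence")
    }
  }
  gap <- function(theta) {
    g <- group_spec("g", theta)
    event_informativeness(FALSE, g, space, log_base) -
      event_informativeness(TRUE, g, space, log_base)
  }
  gap(theta_human) - gap(theta_audio)
}

#' Interaction statistic over a grid of group parameters
#'
#' @param grid_human,grid_audio Numeric vectors of thetas in `[0, 1)`.
#' @param space A [label_space()].
#' @param log_base Logarithm base.
#' @return Matrix with entry `(i, j)` equal to
#'   `interaction_statistic(grid_human[i], grid_audio[j], ...)`; dimnames
#'   carry the theta values.
#' @export
sweep_interaction <- function(grid_human, grid_audio, space, log_base = 2) {
  out <- outer(seq_along(grid_human), seq_along(grid_audio),
               Vectorize(function(i, j) {
                 interaction_statistic(grid_human[i], grid_audio[j],
                                       space, log_base)
               }))
  dimnames(out) <- list(theta_human = format(grid_human, trim = TRUE),
                        theta_audio = format(grid_audio, trim = TRUE))
  out
}

# per-speaker k prior as a named vector aligned with speaker order
resolve_k_prior <- function(k_prior, speakers) {
  if (length(k_prior) == 1L && is.null(names(k_prior))) {
    k_prior <- stats::setNames(rep(as.numeric(k_prior), length(speakers)),
                               speakers)
  } else {
    missing <- setdiff(speakers, names(k_prior))
    if (length(missing)) {
      wt_stop(paste("k_prior missing speaker(s):",
                    paste(missing, collapse = ", ")),
              "wordtrust_validation_error")
    }
    k_prior <- k_prior[speakers]
  }
  if (any(k_prior < 0 | k_prior > 1)) {
    wt_stop("k_prior values must lie in [0, 1]", "wordtrust_validation_error")
  }
  k_prior
}

resolve_label_prior <- function(label_prior, space) {
  if (is.null(label_prior)) {
    return(categorical_distribution(
      stats::setNames(rep(1 / space$n, space$n), space$labels)))
  }
  label_prior <- categorical_distribution(label_prior)
  if (!setequal(names(label_prior), space$labels)) {
    wt_stop("label_prior support must equal the label space",
            "wordtrust_invalid_label")
  }
  label_prior[space$labels]
}

# per-speaker sequence likelihood array: lik[label, speaker, k + 1]
speaker_likelihoods <- function(corpus) {
  space <- attr(corpus, "label_space")
  if (length(unique(corpus$object_id)) != 1L) {
    wt_stop("joint (C, K) inference is defined for a single object; subset the corpus by object_id first",
            "wordtrust_validation_error")
  }
  speakers <- unique(corpus$speaker_id)
  lik <- array(NA_real_, dim = c(space$n, length(speakers), 2L),
               dimnames = list(space$labels, speakers, c("k0", "k1")))
  for (s in speakers) {
    toks <- corpus$token[corpus$speaker_id == s]
    for (lab in space$labels) {
      lik[lab, s, "k0"] <- sequence_likelihood(toks, lab, 0, space)
      lik[lab, s, "k1"] <- sequence_likelihood(toks, lab, 1, space)
    }
  }
  lik
}

#' Exact joint posterior over category and speaker knowledgeability
#'
#' Enumerates every hypothesis `(C, K_1, ..., K_m)` — `n * 2^m` of them —
#' scores each as prior times the product of per-speaker sequence
#' likelihoods, and normalizes. Above `max_speakers` the hypothesis space
#' is refused (use [gibbs_posterior()] instead).
#'
#' @param corpus A single-object [labeling_corpus()].
#' @param k_prior Per-speaker prior probability of being knowledgeable:
#'   one number shared by all speakers, or a named vector by speaker id.
#' @param label_prior Prior over categories; `NULL` (default) is uniform.
#' @param max_speakers Enumeration cap (default 20).
#' @return An object of class `joint_posterior`: `hypotheses` (data frame
#'   with `category` and one `k_<speaker>` column per speaker), `probs`,
#'   `label_marginal` (a [categorical_distribution()]), plus the speaker
#'   ids and priors used.
#' @examples
#' sp <- label_space(c("buk", "puk", "duk"))
#' ev <- data.frame(speaker_id = "s1", group = "unknown",
#'                  object_id = "o", token = rep("buk", 7))
#' corp <- labeling_corpus(ev, sp, c(unknown = 0.5))
#' joint_posterior_exact(corp, k_prior = 0.5)$label_marginal
#' @export
joint_posterior_exact <- function(corpus, k_prior = 0.5, label_prior = NULL,
                                  max_speakers = 20L) {
  stopifnot(inherits(corpus, "labeling_corpus"))
  space <- attr(corpus, "label_space")
  lik <- speaker_likelihoods(corpus)
  speakers <- dimnames(lik)[[2L]]
  m <- length(speakers)
  if (m > max_speakers) {
    wt_stop(sprintf(
      "%d speakers give %d x 2^%d hypotheses, above the enumeration cap; use gibbs_posterior()",
      m, space$n, m),
      "wordtrust_enumeration_cap")
  }
  k_prior <- resolve_k_prior(k_prior, speakers)
  label_prior <- resolve_label_prior(label_prior, space)

  k_combos <- as.matrix(expand.grid(rep(list(0:1), m), KEEP.OUT.ATTRS = FALSE))
  colnames(k_combos) <- speakers
  n_hyp <- space$n * nrow(k_combos)
  stopifnot(n_hyp == space$n * 2^m)

  category <- rep(space$labels, each = nrow(k_combos))
  kmat <- k_combos[rep(seq_len(nrow(k_combos)), times = space$n), ,
                   drop = FALSE]
  weights <- label_prior[category]
  for (j in seq_len(m)) {
    s <- speakers[j]
    lik_j <- ifelse(kmat[, j] == 1, lik[cbind(category, s, "k1")],
                    lik[cbind(category, s, "k0")])
    prior_j <- ifelse(kmat[, j] == 1, k_prior[s], 1 - k_prior[s])
    weights <- weights * lik_j * prior_j
  }
  total <- sum(weights)
  if (total == 0) {
    wt_stop("the corpus has probability zero under every hypothesis",
            "wordtrust_zero_probability_corpus")
  }
  probs <- as.numeric(weights / total)

  hyp <- data.frame(category = category, kmat, check.names = FALSE)
  names(hyp)[-1L] <- paste0("k_", speakers)
  marg <- vapply(space$labels,
                 function(lab) sum(probs[category == lab]), numeric(1))
  structure(list(hypotheses = hyp, probs = probs,
                 label_marginal = categorical_distribution(marg),
                 speakers = speakers, k_prior = k_prior,
                 label_prior = label_prior, method = "exact",
                 label_space = space),
            class = "joint_posterior")
}

#' @export
print.joint_posterior <- function(x, ...) {
  cat(sprintf("<joint_posterior> (%s) %d hypotheses over (C, K) for %d speaker(s)\n",
              x$method, length(x$probs), length(x$speakers)))
  cat("label marginal:\n")
  print(round(unclass(x$label_marginal), 6))
  invisible(x)
}

#' Marginal posterior over labels from a joint posterior
#'
#' Sums joint probability over the knowledgeability vector per category.
#'
#' @param joint A `joint_posterior`.
#' @return A [categorical_distribution()] `P(C | D)`.
#' @export
marginal_label_posterior <- function(joint) {
  stopifnot(inherits(joint, "joint_posterior"))
  joint$label_marginal
}

#' Gibbs sampler settings
#'
#' @param samples Post-burn-in sweeps to keep (default 20000).
#' @param burn_in Initial sweeps discarded (default 2000).
#' @param seed Integer RNG seed; the run is deterministic given it.
#' @param scan Update order; only `"systematic"` (C, then K_1..K_m) is
#'   implemented.
#' @param rao_blackwell If `TRUE` the label marginal additionally averages
#'   the full conditional `P(C | K, D)` over sweeps instead of raw draw
#'   frequencies. Off by default: raw frequencies mirror the plain sampler.
#' @return A `gibbs_settings` list.
#' @export
gibbs_settings <- function(samples = 20000L, burn_in = 2000L, seed = 1L,
                           scan = c("systematic"), rao_blackwell = FALSE) {
  scan <- match.arg(scan)
  samples <- as.integer(samples); burn_in <- as.integer(burn_in)
  if (samples <= 0L || burn_in < 0L) {
    wt_stop("samples must be > 0 and burn_in >= 0",
            "wordtrust_validation_error")
  }
  structure(list(samples = samples, burn_in = burn_in,
                 seed = as.integer(seed), scan = scan,
                 rao_blackwell = isTRUE(rao_blackwell)),
            class = "gibbs_settings")
}

# effective sample size from the initial monotone positive-autocorrelation
# window of a 0/1 chain
binary_ess <- function(x) {
  n <- length(x)
  if (stats::var(x) == 0) return(n)
  rho <- stats::acf(x, lag.max = min(200L, n - 1L), plot = FALSE)$acf[-1L]
  pos <- which(rho <= 0)
  if (length(pos)) rho <- rho[seq_len(pos[1L] - 1L)]
  n / (1 + 2 * sum(rho))
}

#' Approximate joint posterior by Gibbs sampling
#'
#' Alternates draws from the full conditionals
#' `P(C | K, D) \propto P(C) prod_m P(D_m | C, K_m)` and, per speaker,
#' `P(K_m | C, D) \propto P(K_m) P(D_m | C, K_m)`, in a systematic scan.
#' The chain starts at all `K = 0`, which is in the support of any
#' consistent corpus. Estimates are empirical frequencies after burn-in.
#'
#' @inheritParams joint_posterior_exact
#' @param settings A [gibbs_settings()].
#' @return A `joint_posterior` (method `"gibbs"`) whose `hypotheses`/
#'   `probs` are the observed states with their frequencies, plus
#'   `k_marginals` (per-speaker `P(K = 1 | D)` estimates) and
#'   `diagnostics` (kept sweeps, support repairs at initialization and
#'   per-label effective sample sizes).
#' @examples
#' sp <- label_space(c("buk", "puk", "duk"))
#' ev <- data.frame(speaker_id = paste0("s", 1:7), group = "unknown",
#'                  object_id = "o", token = "buk")
#' corp <- labeling_corpus(ev, sp, c(unknown = 0.5))
#' fit <- gibbs_posterior(corp, settings = gibbs_settings(2000, 200, seed = 7))
#' fit$label_marginal
#' @export
gibbs_posterior <- function(corpus, k_prior = 0.5, label_prior = NULL,
                            settings = gibbs_settings()) {
  stopifnot(inherits(corpus, "labeling_corpus"),
            inherits(settings, "gibbs_settings"))
  space <- attr(corpus, "label_space")
  lik <- speaker_likelihoods(corpus)
  speakers <- dimnames(lik)[[2L]]
  m <- length(speakers)
  k_prior <- resolve_k_prior(k_prior, speakers)
  label_prior <- resolve_label_prior(label_prior, space)

  # lik0[label, speaker], lik1[label, speaker]
  lik0 <- lik[, , "k0", drop = FALSE][, , 1L, drop = TRUE]
  lik1 <- lik[, , "k1", drop = FALSE][, , 1L, drop = TRUE]
  lik0 <- matrix(lik0, nrow = space$n, dimnames = list(space$labels, speakers))
  lik1 <- matrix(lik1, nrow = space$n, dimnames = list(space$labels, speakers))
  if (all(lik0 == 0)) {
    wt_stop("the corpus has probability zero under every hypothesis",
            "wordtrust_zero_probability_corpus")
  }

  total <- settings$burn_in + settings$samples
  withr::with_seed(settings$seed, {
    k <- rep(0L, m)                      # all-unknowledgeable start: in support
    repairs <- 0L
    c_draws <- character(settings$samples)
    k_sums <- numeric(m)
    rb <- numeric(space$n)
    kept <- 0L
    for (it in seq_len(total)) {
      # C | K, D
      w <- as.numeric(label_prior)
      for (j in seq_len(m)) {
        w <- w * (if (k[j] == 1L) lik1[, j] else lik0[, j])
      }
      if (sum(w) == 0) {
        # K outside the support of any category: reset to all-unknowledgeable
        k[] <- 0L
        repairs <- repairs + 1L
        w <- as.numeric(label_prior)
        for (j in seq_len(m)) w <- w * lik0[, j]
      }
      ci <- sample.int(space$n, 1L, prob = w)
      # K_m | C, D
      for (j in seq_len(m)) {
        w1 <- k_prior[j] * lik1[ci, j]
        w0 <- (1 - k_prior[j]) * lik0[ci, j]
        k[j] <- if (stats::runif(1L) < w1 / (w1 + w0)) 1L else 0L
      }
      if (it > settings$burn_in) {
        kept <- kept + 1L
        c_draws[kept] <- space$labels[ci]
        k_sums <- k_sums + k
        if (settings$rao_blackwell) {
          wrb <- as.numeric(label_prior)
          for (j in seq_len(m)) {
            wrb <- wrb * (if (k[j] == 1L) lik1[, j] else lik0[, j])
          }
          rb <- rb + wrb / sum(wrb)
        }
      }
    }
  })

  freq <- table(factor(c_draws, levels = space$labels)) / settings$samples
  label_marginal <- categorical_distribution(
    stats::setNames(as.numeric(freq), space$labels))
  if (settings$rao_blackwell) {
    label_marginal <- categorical_distribution(
      stats::setNames(rb / settings$samples, space$labels))
  }
  ess <- vapply(space$labels, function(lab) {
    binary_ess(as.numeric(c_draws == lab))
  }, numeric(1))

  hyp_tab <- as.data.frame(table(category = c_draws),
                           stringsAsFactors = FALSE)
  structure(list(hypotheses = hyp_tab[, "category", drop = FALSE],
                 probs = hyp_tab$Freq / settings$samples,
                 label_marginal = label_marginal,
                 k_marginals = stats::setNames(k_sums / settings$samples,
                                               speakers),
                 speakers = speakers, k_prior = k_prior,
                 label_prior = label_prior, method = "gibbs",
                 label_space = space, settings = settings,
                 diagnostics = list(kept = settings$samples,
                                    support_repairs = repairs,
                                    ess_per_label = ess)),
            class = "joint_posterior")
}

#' Total variation distance between two label distributions
#'
#' @param p,q Distributions over the same labels (named numerics).
#' @return Half the L1 distance, in `[0, 1]`.
#' @export
total_variation <- function(p, q) {
  p <- unclass(p); q <- unclass(q)
  if (!setequal(names(p), names(q))) {
    wt_stop("distributions must share a support", "wordtrust_validation_error")
  }
  sum(abs(p - q[names(p)])) / 2
}
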