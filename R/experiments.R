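# Turn-key runners for the two simulations: familiar-word recognition
# (single-event KL informativeness by group and correctness) and
# Switch-task novel-word learning (single vs. multiple habituation
# speakers).

#' Familiar-word recognition simulation
#'
#' Computes the KL informativeness of one labeling event about speaker
#' knowledgeability for the four cells: correct/incorrect token crossed
#' with adult (characteristically knowledgeable) and audio-speaker
#' (characteristically unknowledgeable) groups. The default
#' `theta_adult = 0.80` reproduces all four published cells; see the
#' methods vignette for the parameter discussion.
#'
#' @param theta_adult,theta_audio Group knowledgeability priors in
#'   `[0, 1)`.
#' @param n_labels Number of candidate labels (>= 2).
#' @param log_base Logarithm base (2 = bits).
#' @return A `sim1_report`: data frame with columns `group`,
#'   `correctness`, `kl`, carrying the parameters as attributes.
#' @examples
#' run_simulation1()
#' @export
run_simulation1 <- function(theta_adult = 0.80, theta_audio = 0.15,
                            n_labels = 3L, log_base = 2) {
  if (n_labels < 2L) {
    wt_stop("n_labels must be >= 2", "wordtrust_validation_error")
  }
  space <- label_space(paste0("label", seq_len(n_labels)))
  cells <- expand.grid(correctness = c("correct", "incorrect"),
                       group = c("adult", "audio"),
                       stringsAsFactors = FALSE)[, c("group", "correctness")]
  thetas <- c(adult = theta_adult, audio = theta_audio)
  cells$kl <- mapply(function(g, corr) {
    event_informativeness(corr == "correct", group_spec(g, thetas[[g]]),
                          space, log_base)
  }, cells$group, cells$correctness)
  structure(cells,
            class = c("sim1_report", "data.frame"),
            params = list(theta_adult = theta_adult,
                          theta_audio = theta_audio,
                          n_labels = n_labels, log_base = log_base))
}

#' @export
print.sim1_report <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf(
    "<sim1_report> theta_adult = %g, theta_audio = %g, n = %d, log base %g\n",
    p$theta_adult, p$theta_audio, p$n_labels, p$log_base))
  df <- as.data.frame(x)
  df$kl <- sprintf("%.4f", df$kl)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Parameter sweep of the correctness-by-group interaction
#'
#' Evaluates [interaction_statistic()] over a square grid of group
#' thetas, optionally writing the matrix as CSV and a heatmap image. The
#' heatmap uses a diverging palette centered at zero so the equal-theta
#' diagonal reads as neutral; rows index the human group's theta,
#' columns the audio group's.
#'
#' @param grid Numeric vector of thetas in `[0, 1)` shared by both axes.
#' @param n_labels Number of candidate labels.
#' @param log_base Logarithm base.
#' @param csv Optional path for the matrix as CSV (theta grid headers).
#' @param plot_file Optional path for a PNG heatmap.
#' @return The interaction matrix, invisibly carrying the grid.
#' @export
run_simulation1_sweep <- function(grid = seq(0.05, 0.95, length.out = 19),
                                  n_labels = 3L, log_base = 2,
                                  csv = NULL, plot_file = NULL) {
  space <- label_space(paste0("label", seq_len(n_labels)))
  mat <- sweep_interaction(grid, grid, space, log_base)
  if (!is.null(csv)) {
    df <- data.frame(theta_human = grid, mat, check.names = FALSE)
    utils::write.csv(df, csv, row.names = FALSE)
  }
  if (!is.null(plot_file)) {
    grDevices::png(plot_file, width = 640, height = 560)
    on.exit(grDevices::dev.off(), add = TRUE)
    lim <- max(abs(mat))
    pal <- grDevices::colorRampPalette(
      c("#2166AC", "#F7F7F7", "#B2182B"))(101)
    graphics::image(x = grid, y = grid, z = t(mat), zlim = c(-lim, lim),
                    col = pal, xlab = "theta (audio group)",
                    ylab = "theta (human group)",
                    main = "Incorrect-minus-correct KL gap: human minus audio")
  }
  invisible(mat)
}

#' Switch-task habituation simulation
#'
#' Builds the habituation corpus for one condition — `"single"`: one
#' speaker producing `tokens` identical tokens of the habituated label;
#' `"multiple"`: `tokens` distinct speakers producing one each — and
#' returns the marginal posterior over labels after habituation, by exact
#' enumeration or Gibbs sampling.
#'
#' @param condition `"single"` or `"multiple"`.
#' @param tokens Number of tokens (single) or speakers (multiple);
#'   default 7.
#' @param labels Candidate label strings (default buk/puk/duk).
#' @param habituated The label heard during habituation (default "buk").
#' @param k_prior Per-speaker prior probability of knowledgeability
#'   (default 0.5, maximal uncertainty about the speaker's group).
#' @param method `"exact"` or `"gibbs"`.
#' @param settings [gibbs_settings()], used when `method = "gibbs"`.
#' @return A `sim2_report`: the label posterior plus condition, method
#'   and parameters; Gibbs runs also carry the fitted `joint_posterior`.
#' @examples
#' run_simulation2("single")$posterior    # 2/3, 1/6, 1/6
#' @export
run_simulation2 <- function(condition = c("single", "multiple"),
                            tokens = 7L,
                            labels = c("buk", "puk", "duk"),
                            habituated = "buk",
                            k_prior = 0.5,
                            method = c("exact", "gibbs"),
                            settings = gibbs_settings()) {
  condition <- match.arg(condition)
  method <- match.arg(method)
  tokens <- as.integer(tokens)
  if (tokens < 1L) {
    wt_stop("tokens must be >= 1", "wordtrust_validation_error")
  }
  space <- label_space(labels)
  if (!(habituated %in% labels)) {
    wt_stop("habituated label must be one of the candidate labels",
            "wordtrust_invalid_label")
  }
  events <- if (condition == "single") {
    data.frame(speaker_id = "s1", group = "unknown", object_id = "obj",
               token = rep(habituated, tokens))
  } else {
    data.frame(speaker_id = paste0("s", seq_len(tokens)), group = "unknown",
               object_id = "obj", token = habituated)
  }
  corp <- labeling_corpus(events, space, c(unknown = k_prior))
  fit <- if (method == "exact") {
    joint_posterior_exact(corp, k_prior = k_prior)
  } else {
    gibbs_posterior(corp, k_prior = k_prior, settings = settings)
  }
  structure(list(condition = condition, method = method,
                 posterior = fit$label_marginal,
                 habituated = habituated, tokens = tokens,
                 k_prior = k_prior,
                 settings = if (method == "gibbs") settings else NULL,
                 fit = fit),
            class = "sim2_report")
}

#' @export
print.sim2_report <- function(x, ...) {
  cat(sprintf(
    "<sim2_report> %s-speaker condition, %d token(s) of '%s', %s inference\n",
    x$condition, x$tokens, x$habituated, x$method))
  print(round(unclass(x$posterior), 6))
  invisible(x)
}

#' Agreement between exact enumeration and the Gibbs sampler
#'
#' @param corpus A single-object, enumerable [labeling_corpus()].
#' @param k_prior,label_prior Priors as in [joint_posterior_exact()].
#' @param settings A [gibbs_settings()].
#' @return Total variation distance between the two label marginals.
#' @export
compare_exact_gibbs <- function(corpus, k_prior = 0.5, label_prior = NULL,
                                settings = gibbs_settings()) {
  exact <- joint_posterior_exact(corpus, k_prior, label_prior)
  gibbs <- gibbs_posterior(corpus, k_prior, label_prior, settings)
  total_variation(exact$label_marginal, gibbs$label_marginal)
}
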