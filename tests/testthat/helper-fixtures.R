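# Shared fixtures and an independent brute-force oracle for joint
# posteriors, written with raw loops so it shares no code path with the
# package's enumeration.

buk_space <- function() label_space(c("buk", "puk", "duk"))

single_speaker_corpus <- function(tokens = 7L, label = "buk",
                                  k_prior = 0.5) {
  ev <- data.frame(speaker_id = "s1", group = "unknown", object_id = "obj",
                   token = rep(label, tokens))
  labeling_corpus(ev, buk_space(), c(unknown = k_prior))
}

multi_speaker_corpus <- function(m = 7L, label = "buk", k_prior = 0.5) {
  ev <- data.frame(speaker_id = paste0("s", seq_len(m)), group = "unknown",
                   object_id = "obj", token = label)
  labeling_corpus(ev, buk_space(), c(unknown = k_prior))
}

# tokens_by_speaker: list of character vectors, one per speaker.
# Returns the label marginal by summing prior x likelihood over every
# (C, K-vector) combination with plain arithmetic.
brute_label_posterior <- function(tokens_by_speaker, labels,
                                  k_prior = 0.5) {
  n <- length(labels)
  m <- length(tokens_by_speaker)
  marg <- setNames(rep(0, n), labels)
  for (ci in seq_len(n)) {
    C <- labels[ci]
    for (code in 0:(2^m - 1)) {
      w <- 1 / n
      for (j in seq_len(m)) {
        kj <- (code %/% 2^(j - 1)) %% 2
        toks <- tokens_by_speaker[[j]]
        lik <- if (length(unique(toks)) > 1L) {
          0
        } else if (kj == 1) {
          as.numeric(toks[1] == C)
        } else {
          1 / n
        }
        w <- w * (if (kj == 1) k_prior else 1 - k_prior) * lik
      }
      marg[C] <- marg[C] + w
    }
  }
  marg / sum(marg)
}
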