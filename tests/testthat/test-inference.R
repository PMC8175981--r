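test_that("single-event knowledgeability posterior follows Bayes' rule", {
  sp <- buk_space()
  # correct token, theta = 0.8: 0.8 / (0.8 + 0.2/3) = 12/13
  b <- posterior_knowledgeability("buk", group_spec("adult", 0.8), "buk", sp)
  expect_equal(unname(b[["knowledgeable"]]), 12 / 13, tolerance = 1e-12)
  # correct token, theta = 0.15: 0.15 / (0.15 + 0.85/3) = 9/26
  b <- posterior_knowledgeability("buk", group_spec("audio", 0.15), "buk", sp)
  expect_equal(unname(b[["knowledgeable"]]), 9 / 26, tolerance = 1e-12)
  # incorrect token: point mass on K = 0 (knowledgeable speakers never err)
  b <- posterior_knowledgeability("puk", group_spec("audio", 0.15), "buk", sp)
  expect_equal(unname(b[["knowledgeable"]]), 0)
  # incorrect token from a certainly-knowledgeable group is impossible
  expect_error(
    posterior_knowledgeability("puk", group_spec("adult", 1), "buk", sp),
    class = "wordtrust_impossible_observation")
})

test_that("KL divergence matches hand-computed values and conventions", {
  prior_audio <- bernoulli_belief(0.15)
  expect_equal(kl_divergence(bernoulli_belief(0), prior_audio),
               0.2344652536, tolerance = 1e-9)
  expect_equal(kl_divergence(bernoulli_belief(12 / 13),
                             bernoulli_belief(0.8)),
               0.0845306851, tolerance = 1e-9)
  expect_equal(kl_divergence(prior_audio, prior_audio), 0)
  # mass in p where q has none is undefined, not infinite
  expect_error(kl_divergence(bernoulli_belief(0.5), bernoulli_belief(1)),
               class = "wordtrust_undefined_divergence")
  # nats vs bits scale by log(2)
  expect_equal(kl_divergence(bernoulli_belief(0), prior_audio,
                             log_base = exp(1)),
               0.2344652536 * log(2), tolerance = 1e-9)
})

test_that("KL is nonnegative and zero only when posterior equals prior", {
  sp <- buk_space()
  for (theta in seq(0.05, 0.95, by = 0.1)) {
    g <- group_spec("g", theta)
    prior <- knowledgeability_prior(g)
    for (correct in c(TRUE, FALSE)) {
      post <- posterior_knowledgeability(
        if (correct) "buk" else "puk", g, "buk", sp)
      d <- kl_divergence(post, prior)
      expect_gte(d, 0)
      expect_equal(d == 0, isTRUE(all.equal(unclass(post), unclass(prior))))
    }
  }
  # theta = 0: a correct token moves nothing (K = 0 is certain a priori)
  g0 <- group_spec("g", 0)
  expect_equal(event_informativeness(FALSE, g0, sp), 0)
})

test_that("event informativeness reproduces the four published cells", {
  sp <- buk_space()
  adult <- group_spec("adult", 0.8)
  audio <- group_spec("audio", 0.15)
  expect_equal(event_informativeness(FALSE, adult, sp), log2(5),
               tolerance = 1e-12)
  expect_equal(event_informativeness(TRUE, adult, sp), 0.0845306851,
               tolerance = 1e-9)
  expect_equal(event_informativeness(FALSE, audio, sp), 0.2344652536,
               tolerance = 1e-9)
  expect_equal(event_informativeness(TRUE, audio, sp), 0.1701292424,
               tolerance = 1e-9)
})

test_that("interaction statistic is zero on the diagonal, antisymmetric, and matches arithmetic", {
  sp <- buk_space()
  expect_equal(interaction_statistic(0.4, 0.4, sp), 0)
  expect_equal(interaction_statistic(0.8, 0.15, sp),
               (log2(5) - 0.0845306851) - (0.2344652536 - 0.1701292424),
               tolerance = 1e-9)
  expect_equal(interaction_statistic(0.15, 0.8, sp),
               -interaction_statistic(0.8, 0.15, sp))
  expect_error(interaction_statistic(1, 0.5, sp),
               class = "wordtrust_undefined_divergence")
})

test_that("interaction sweep matrix has the diagonal/antisymmetry structure", {
  sp <- buk_space()
  grid <- seq(0.05, 0.95, length.out = 10)
  mat <- sweep_interaction(grid, grid, sp)
  expect_equal(dim(mat), c(10L, 10L))
  expect_equal(diag(mat), rep(0, 10), ignore_attr = TRUE)
  expect_equal(mat, -t(mat), ignore_attr = TRUE)
})

test_that("exact enumeration matches the brute-force oracle and hand cases", {
  sp <- buk_space()
  # single speaker, 7 identical tokens: 2/3 on the heard label
  jp <- joint_posterior_exact(single_speaker_corpus(7))
  expect_equal(nrow(jp$hypotheses), 3 * 2^1)
  expect_equal(unclass(jp$label_marginal),
               c(buk = 2/3, puk = 1/6, duk = 1/6), tolerance = 1e-12)
  expect_equal(unclass(marginal_label_posterior(jp)),
               unclass(jp$label_marginal))

  # two disagreeing speakers: 4/9, 4/9, 1/9 by hand enumeration
  ev <- data.frame(speaker_id = c("a", "b"), group = "u", object_id = "o",
                   token = c("buk", "puk"))
  jp2 <- joint_posterior_exact(labeling_corpus(ev, sp, c(u = 0.5)))
  expect_equal(unclass(jp2$label_marginal),
               c(buk = 4/9, puk = 4/9, duk = 1/9), tolerance = 1e-12)
  expect_equal(unclass(jp2$label_marginal),
               brute_label_posterior(list("buk", "puk"), sp$labels))

  # random mixed corpora against the independent oracle
  set.seed(41)
  for (rep in 1:20) {
    m <- sample(1:4, 1)
    toks <- lapply(seq_len(m), function(j)
      rep(sample(sp$labels, 1), sample(1:3, 1)))
    ev <- do.call(rbind, lapply(seq_len(m), function(j)
      data.frame(speaker_id = paste0("s", j), group = "u",
                 object_id = "o", token = toks[[j]])))
    jp <- joint_posterior_exact(labeling_corpus(ev, sp, c(u = 0.5)))
    expect_equal(length(jp$probs), 3 * 2^m)
    expect_equal(sum(jp$probs), 1, tolerance = 1e-9)
    expect_equal(unclass(jp$label_marginal),
                 brute_label_posterior(toks, sp$labels), tolerance = 1e-12)
  }
})

test_that("label posterior is invariant to repetition count for one speaker", {
  one <- joint_posterior_exact(single_speaker_corpus(1))
  seven <- joint_posterior_exact(single_speaker_corpus(7))
  expect_equal(unclass(one$label_marginal), unclass(seven$label_marginal),
               tolerance = 1e-12)
})

test_that("speaker agreement concentrates belief as 1/(1 + 2 * 4^-m)", {
  for (m in 1:7) {
    jp <- joint_posterior_exact(multi_speaker_corpus(m))
    expect_equal(unname(jp$label_marginal[["buk"]]), 1 / (1 + 2 * 4^(-m)),
                 tolerance = 1e-12)
  }
  pb <- vapply(1:7, function(m) {
    unname(joint_posterior_exact(multi_speaker_corpus(m))$label_marginal[["buk"]])
  }, numeric(1))
  expect_true(all(diff(pb) > 0))
})

test_that("enumeration refuses oversized hypothesis spaces and impossible corpora", {
  expect_error(joint_posterior_exact(multi_speaker_corpus(5), max_speakers = 4),
               class = "wordtrust_enumeration_cap")
  # k_prior 1 with a token the category cannot explain for any C? All C
  # with k=1 mismatched for some speaker: two disagreeing speakers, both
  # certainly knowledgeable, cannot be explained by any single category.
  sp <- buk_space()
  ev <- data.frame(speaker_id = c("a", "b"), group = "u", object_id = "o",
                   token = c("buk", "puk"))
  corp <- labeling_corpus(ev, sp, c(u = 1))
  expect_error(joint_posterior_exact(corp, k_prior = 1),
               class = "wordtrust_zero_probability_corpus")
})

test_that("Gibbs sampler agrees with enumeration and is seed-deterministic", {
  st <- gibbs_settings(samples = 20000, burn_in = 2000, seed = 7)
  g1 <- gibbs_posterior(single_speaker_corpus(7), settings = st)
  exact <- joint_posterior_exact(single_speaker_corpus(7))
  expect_lt(total_variation(g1$label_marginal, exact$label_marginal), 0.02)
  expect_equal(sum(g1$label_marginal), 1, tolerance = 1e-6)

  # same seed reproduces; a different seed moves but stays near the oracle
  g1b <- gibbs_posterior(single_speaker_corpus(7), settings = st)
  expect_identical(unclass(g1$label_marginal), unclass(g1b$label_marginal))
  g2 <- gibbs_posterior(single_speaker_corpus(7),
                        settings = gibbs_settings(20000, 2000, seed = 8))
  expect_false(identical(unclass(g1$label_marginal),
                         unclass(g2$label_marginal)))
  expect_lt(total_variation(g2$label_marginal, exact$label_marginal), 0.02)

  # 7 agreeing speakers: within +/- 0.002 of the exact 0.999878
  g7 <- gibbs_posterior(multi_speaker_corpus(7), settings = st)
  expect_lt(abs(g7$label_marginal[["buk"]] - 1 / (1 + 2 * 4^(-7))), 0.002)
  expect_equal(g7$diagnostics$support_repairs, 0L)
})

test_that("Rao-Blackwellized Gibbs estimate is close to exact with fewer sweeps", {
  st <- gibbs_settings(samples = 5000, burn_in = 500, seed = 3,
                       rao_blackwell = TRUE)
  g <- gibbs_posterior(single_speaker_corpus(7), settings = st)
  exact <- joint_posterior_exact(single_speaker_corpus(7))
  expect_lt(total_variation(g$label_marginal, exact$label_marginal), 0.01)
})

test_that("total variation is a bounded metric on label distributions", {
  p <- c(buk = 0.5, puk = 0.3, duk = 0.2)
  expect_equal(total_variation(p, p), 0)
  q <- c(buk = 1, puk = 0, duk = 0)
  expect_equal(total_variation(p, q), 0.5)
  expect_lte(total_variation(q, c(buk = 0, puk = 0, duk = 1)), 1)
  expect_error(total_variation(p, c(a = 1)),
               class = "wordtrust_validation_error")
})
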