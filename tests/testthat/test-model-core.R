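test_that("knowledgeability prior mirrors the group theta", {
  for (theta in c(0, 0.15, 0.5, 1)) {
    b <- knowledgeability_prior(group_spec("g", theta))
    expect_equal(unname(b[["knowledgeable"]]), theta)
    expect_equal(sum(b), 1, tolerance = 1e-12)
  }
})

test_that("intention distribution is a delta for knowledgeable speakers and uniform otherwise", {
  sp <- buk_space()
  d1 <- intention_distribution("buk", 1, sp)
  expect_equal(unclass(d1), c(buk = 1, puk = 0, duk = 0))
  d0 <- intention_distribution("buk", 0, sp)
  expect_equal(unclass(d0), c(buk = 1/3, puk = 1/3, duk = 1/3))
  # degenerate one-label space
  d <- intention_distribution("buk", 0, label_space("buk"))
  expect_equal(unclass(d), c(buk = 1))
  expect_error(intention_distribution("zug", 1, sp),
               class = "wordtrust_invalid_label")
})

test_that("production is noiseless and composes to a delta on the category", {
  sp <- buk_space()
  expect_equal(unclass(data_distribution("puk", sp)),
               c(buk = 0, puk = 1, duk = 0))
  # knowledgeable intention then production = point mass on the category
  intent <- intention_distribution("duk", 1, sp)
  produced <- data_distribution(names(intent)[which.max(intent)], sp)
  expect_equal(unclass(produced), c(buk = 0, puk = 0, duk = 1))
})

test_that("sequence likelihood treats repetition as one intention draw", {
  sp <- buk_space()
  expect_equal(sequence_likelihood(rep("buk", 7), "buk", 1, sp), 1)
  # unknowledgeable: one uniform intention draw regardless of length
  expect_equal(sequence_likelihood(rep("puk", 5), "buk", 0, sp), 1/3)
  for (t in c(1, 2, 7, 20)) {
    expect_equal(sequence_likelihood(rep("buk", t), "buk", 0, sp), 1/3)
    expect_equal(sequence_likelihood(rep("buk", t), "buk", 1, sp), 1)
    expect_equal(sequence_likelihood(rep("puk", t), "buk", 1, sp), 0)
  }
  # inconsistent tokens are impossible under both values of K
  expect_equal(sequence_likelihood(c("buk", "puk"), "buk", 1, sp), 0)
  expect_equal(sequence_likelihood(c("buk", "puk"), "buk", 0, sp), 0)
  expect_error(sequence_likelihood(character(0), "buk", 1, sp),
               class = "wordtrust_validation_error")
})

test_that("unknowledgeable likelihood of a consistent run is exactly 1/n for any n", {
  for (n in 1:6) {
    sp <- label_space(paste0("w", seq_len(n)))
    expect_equal(sequence_likelihood(rep("w1", 3), "w1", 0, sp), 1 / n)
    expect_equal(sequence_likelihood(rep("w1", 3), "w1", 1, sp), 1)
  }
})

test_that("corpus validation enforces membership, groups and speaker consistency", {
  sp <- buk_space()
  ok <- data.frame(speaker_id = c("a", "a", "b"), group = "adult",
                   object_id = "o1", token = c("buk", "buk", "puk"))
  corp <- labeling_corpus(ok, sp, c(adult = 0.8))
  expect_s3_class(corp, "labeling_corpus")
  expect_equal(n_speakers(corp), 2L)

  bad_tok <- transform(ok, token = c("buk", "zug", "puk"))
  expect_error(labeling_corpus(bad_tok, sp, c(adult = 0.8)),
               class = "wordtrust_invalid_label")
  expect_error(labeling_corpus(ok, sp, c(other = 0.8)),
               class = "wordtrust_validation_error")
  # same speaker, same object, different tokens: probability-zero corpus
  incons <- transform(ok, token = c("buk", "puk", "puk"))
  expect_error(labeling_corpus(incons, sp, c(adult = 0.8)),
               class = "wordtrust_zero_probability_corpus")
  # a speaker may label different objects differently
  two_obj <- data.frame(speaker_id = "a", group = "adult",
                        object_id = c("o1", "o2"), token = c("buk", "puk"))
  expect_s3_class(labeling_corpus(two_obj, sp, c(adult = 0.8)),
                  "labeling_corpus")
})
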