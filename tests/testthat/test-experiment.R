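test_that("trial batches log exact rates and respect bounds", {
  m <- tiny_models()
  log <- run_trials(m, 40, n_known = 4, seed = 1)
  expect_equal(nrow(log), 40)
  expect_true(all(vapply(log$known, length, integer(1)) == 4))
  expect_false(any(mapply(function(k, r, C) any(c(r, C) %in% k),
                          log$known, log$rivals, log$C)))
  pc <- performance_curve(m, grid = c(2, 4), n_trials = 25, seed = 2)
  expect_true(all(pc$rate >= 0 & pc$rate <= 1))
  # one trial per point: rate is 0 or 1
  pc1 <- performance_curve(m, grid = 2, n_trials = 1,
                           tasks = "identification", seed = 3)
  expect_true(pc1$rate %in% c(0, 1))
  expect_error(performance_curve(m, grid = 50, n_trials = 5), "too large")
})

test_that("pipeline results are deterministic given a seed", {
  m <- tiny_models()
  pc1 <- performance_curve(m, grid = c(2, 4), n_trials = 30, seed = 11)
  pc2 <- performance_curve(m, grid = c(2, 4), n_trials = 30, seed = 11)
  expect_identical(pc1, pc2)
  f1 <- withr::local_tempfile()
  f2 <- withr::local_tempfile()
  write_tsv(pc1, f1)
  write_tsv(pc2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("bootstrap interval behaves like a percentile bootstrap", {
  m <- tiny_models()
  log <- run_trials(m, 120, n_known = 4, seed = 4)
  # all-correct log gives the degenerate interval [1, 1]
  log1 <- log
  log1$correct <- TRUE
  ci <- bootstrap_ci(log1, axes = "trials", n_boot = 50, seed = 5)
  expect_equal(c(ci$lower, ci$upper), c(1, 1))
  # trials-only interval close to the binomial normal approximation
  ci2 <- bootstrap_ci(log, axes = "trials", n_boot = 400, seed = 6)
  p <- mean(log$correct)
  normal_width <- 2 * qnorm(0.975) * sqrt(p * (1 - p) / nrow(log))
  expect_lt(abs((ci2$upper - ci2$lower) - normal_width), 0.2 * normal_width)
  # axis order does not matter for a fixed seed
  ci3 <- bootstrap_ci(log, axes = c("trials", "words"), n_boot = 60,
                      seed = 7)
  ci4 <- bootstrap_ci(log, axes = c("words", "trials"), n_boot = 60,
                      seed = 7)
  expect_equal(ci3[c("lower", "upper")], ci4[c("lower", "upper")])
  # image resampling needs the models and runs end to end
  ci5 <- bootstrap_ci(log[1:30, ], axes = "images", n_boot = 8, models = m,
                      seed = 8)
  expect_true(ci5$lower <= ci5$upper)
  expect_error(bootstrap_ci(log, axes = "images", n_boot = 5), "models")
  expect_error(bootstrap_ci(log, n_boot = 1), "n_boot")
})

test_that("permutation baseline sits at chance and recovers the unpermuted rate", {
  m <- tiny_models()
  pb <- permutation_baseline(m, n_perm = 6, n_trials = 150, n_known = 4,
                             seed = 9)
  # 99% Monte-Carlo band around 0.5 for 6 x 2 x 150 Bernoulli trials
  half <- 2.576 * sqrt(0.25 / (6 * 2 * 150))
  expect_gt(pb$mean, 0.5 - half - 0.02)
  expect_lt(pb$mean, 0.5 + half + 0.02)
  expect_length(pb$rates, 6)
  # with shuffling disabled the unpermuted rate comes back
  pb0 <- permutation_baseline(m, n_perm = 2, n_trials = 200, n_known = 4,
                              tasks = "identification", seed = 10,
                              shuffle = FALSE)
  direct <- mean(run_trials(m, 400, n_known = 4, task = "identification",
                            seed = 10)$correct)
  expect_lt(abs(pb0$mean - direct), 0.1)
})

test_that("per-word scores match hand enumeration on a toy world", {
  m <- toy_models(words = letters[1:6], seed = 13)
  pw <- per_word_scores(m, modality = "colour", seed = 14)
  expect_equal(pw$word, letters[1:6])
  # hand enumeration: every other word as rival, both tasks, known = rest
  # (4 known items, so the cross-domain correlations are generically
  # distinct and the decisions tie-free)
  for (C in m$words) {
    hits <- 0
    for (R in setdiff(m$words, C)) {
      known <- setdiff(m$words, c(C, R))
      for (task in c("identification", "naming")) {
        sc <- if (task == "identification")
          c(cor(m$D_word[C, known], m$D_colour[C, known]),
            cor(m$D_word[C, known], m$D_colour[R, known]))
        else
          c(cor(m$D_word[C, known], m$D_colour[C, known]),
            cor(m$D_word[R, known], m$D_colour[C, known]))
        hits <- hits + (which.max(sc) == 1)
      }
    }
    expect_equal(pw$rate[pw$word == C], hits / 10, info = C)
  }
  # degenerate world: identical appearances for everybody -> chance
  m2 <- toy_models(words = letters[1:8], seed = 15)
  m2$D_colour[] <- 1
  diag(m2$D_colour) <- 0
  m2$D_texton <- m2$D_colour
  set.seed(16)
  pw2 <- per_word_scores(m2)
  expect_lt(abs(mean(pw2$rate) - 0.5), 0.25)
  # determinism under a fixed seed
  expect_equal(per_word_scores(m, modality = "colour", seed = 14), pw)
})

test_that("stratified summaries recover exact linear structure", {
  lex <- data.frame(word = sprintf("w%02d", 1:20),
                    category = rep(c("A", "B", "C", "D"), each = 5),
                    depth = rep(1:5, times = 4))
  # exactly linear rates: slope must come back exactly
  pw <- data.frame(word = lex$word, rate = 0.5 + 0.01 * lex$depth)
  s <- suppressWarnings(stratified_summary(pw, lex))
  expect_equal(s$depth_slope, 0.01, tolerance = 1e-12)
  expect_equal(unname(vapply(split(pw$rate, lex$category), mean,
                             numeric(1))),
               s$categories$mean[match(c("A", "B", "C", "D"),
                                       s$categories$category)])
  # all-equal rates: slope 0, no category flagged
  pw0 <- data.frame(word = lex$word, rate = 0.7)
  s0 <- suppressWarnings(stratified_summary(pw0, lex))
  expect_equal(s0$depth_slope, 0)
  expect_true(all(s0$categories$flag %in% c("ns", "undefined")))
  # random rates: slope equals the closed-form OLS estimate
  set.seed(17)
  pwr <- data.frame(word = lex$word, rate = runif(20, 0.4, 0.9))
  sr <- stratified_summary(pwr, lex)
  beta <- cov(lex$depth, pwr$rate) / var(lex$depth)
  expect_equal(sr$depth_slope, beta, tolerance = 1e-12)
  expect_true(sr$depth_ci[1] <= beta && beta <= sr$depth_ci[2])
  # a singleton category is reported but flagged undefined
  lex1 <- lex
  lex1$category[1] <- "LONER"
  s1 <- stratified_summary(pwr, lex1)
  expect_equal(s1$categories$flag[s1$categories$category == "LONER"],
               "undefined")
  expect_error(stratified_summary(data.frame(word = "zz", rate = 1), lex),
               "cover")
})

test_that("multi-rival chance follows 1/(m+1)", {
  m <- tiny_models()
  mr <- multi_rival_curve(m, rival_counts = c(1, 3, 7), n_known = 2,
                          n_trials = 20, seed = 18)
  expect_equal(mr$chance, c(1 / 2, 1 / 4, 1 / 8))
  expect_true(all(mr$rate >= 0 & mr$rate <= 1))
})

test_that("quadruple search finds at least the average quadruple", {
  m <- tiny_models()
  qs <- quadruple_search(m, n_candidates = 8, n_trials = 30, seed = 19)
  expect_length(qs$best_words, 4)
  expect_gte(qs$best_rate, qs$mean_rate)
  qs1 <- quadruple_search(m, n_candidates = 1, n_trials = 10, seed = 20)
  expect_equal(qs1$best_rate, qs1$mean_rate)
  # tiny vocabulary: sampled best can never beat the exhaustive best
  mt <- toy_models(words = letters[1:7], seed = 21)
  all_quads <- combn(mt$words, 4)
  ex_rates <- apply(all_quads, 2, function(q) {
    pool <- setdiff(mt$words, q)
    prs <- t(combn(pool, 2))
    prs <- rbind(prs, prs[, 2:1])
    mean(apply(prs, 1, function(cr) {
      sc <- c(cor(mt$D_word[cr[1], q], mt$D_colour[cr[1], q]),
              cor(mt$D_word[cr[1], q], mt$D_colour[cr[2], q]))
      which.max(sc) == 1
    }))
  })
  qs2 <- quadruple_search(mt, n_candidates = 12, n_trials = 40,
                          modality = "colour", seed = 22)
  expect_lte(qs2$best_rate, max(ex_rates) + 0.25)
})
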