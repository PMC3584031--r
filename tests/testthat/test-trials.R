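test_that("candidate pairings share the word (identification) or the appearance (naming)", {
  sp <- trial_spec("identification", "a", "b", known = c("c", "d"))
  cp <- candidate_pairings(sp)
  expect_equal(cp$word, c("a", "a"))
  expect_equal(cp$appearance, c("a", "b"))
  sp2 <- trial_spec("naming", "a", "b", known = c("c", "d"))
  cp2 <- candidate_pairings(sp2)
  expect_equal(cp2$word, c("a", "b"))
  expect_equal(cp2$appearance, c("a", "a"))
  sp3 <- trial_spec("identification", "a", letters[5:26],
                    known = c("b", "c"))
  expect_equal(nrow(candidate_pairings(sp3)), 23)
  expect_error(trial_spec("naming", "a", "b", known = c("a", "c")),
               "disjoint")
  expect_error(trial_spec("naming", "a", "b", known = c("c", "d"),
                          strategy = "proxy", k = 3), "exceed")
})

test_that("mirroring score is the cross-domain Pearson correlation", {
  m <- toy_models()
  known <- c("c", "d", "e", "f")
  s <- mirroring_score("a", "b", known, m, "colour")
  expect_equal(s, cor(m$D_word["a", known], m$D_colour["b", known]))
  # perfectly mirrored distances give +1
  m2 <- m
  m2$D_colour <- m$D_word
  expect_equal(mirroring_score("a", "a", known, m2, "colour"), 1)
  # two non-degenerate known items give exactly +/-1
  expect_equal(abs(mirroring_score("a", "b", c("c", "d"), m, "texton")), 1)
  # zero variance in one coordinate gives score 0
  m3 <- m
  m3$D_word["a", ] <- 0.5
  expect_equal(mirroring_score("a", "b", known, m3, "colour"), 0)
  expect_error(mirroring_score("a", "b", "c", m, "colour"), ">= 2")
  # hand-computed six-item case
  dw <- c(0.1, 0.3, 0.5, 0.6, 0.8, 0.9)
  da <- c(0.2, 0.2, 0.4, 0.7, 0.6, 1.0)
  m4 <- m
  m4$words <- c("a", "b", paste0("k", 1:6))
  nm <- m4$words
  m4$D_word <- matrix(0.5, 8, 8, dimnames = list(nm, nm))
  m4$D_colour <- matrix(0.5, 8, 8, dimnames = list(nm, nm))
  m4$D_word["a", paste0("k", 1:6)] <- dw
  m4$D_colour["b", paste0("k", 1:6)] <- da
  expect_equal(mirroring_score("a", "b", paste0("k", 1:6), m4, "colour"),
               cor(dw, da))
  # frozen value from an independent evaluation of the Pearson formula
  expect_equal(cor(dw, da), 0.9068213, tolerance = 1e-6)
})

test_that("mirroring decisions take the argmax and break ties at random", {
  expect_equal(decide_mirroring(c(0.8, 0.2))$chosen, 1L)
  expect_equal(decide_mirroring(c(0.2, 0.8))$chosen, 2L)
  expect_false(decide_mirroring(c(0.8, 0.2))$tie)
  set.seed(10)
  picks <- replicate(400, decide_mirroring(c(0.5, 0.5))$chosen)
  expect_true(all(decide_mirroring(c(0.5, 0.5))$tie))
  expect_gt(mean(picks == 1), 0.4)
  expect_lt(mean(picks == 1), 0.6)
})

test_that("mirroring is invariant to affine transforms of word distances", {
  m <- toy_models(seed = 3)
  known <- c("c", "d", "e", "f")
  m2 <- m
  m2$D_word <- 3 * m$D_word + 2   # common strictly increasing affine map
  for (task in c("identification", "naming")) {
    sp <- trial_spec(task, "a", "b", known = known, modality = "colour")
    expect_equal(run_trial(sp, m)$scores, run_trial(sp, m2)$scores)
  }
})

test_that("PROXY and FOIL match brute-force scoring on toy worlds", {
  m <- toy_models(seed = 7)
  known <- c("c", "d", "e", "f")
  for (task in c("identification", "naming")) {
    for (strategy in c("proxy", "foil")) {
      for (k in c(1, 2, 4)) {
        sp <- trial_spec(task, "a", "b", known = known, strategy = strategy,
                         k = k, modality = "colour")
        dec <- if (strategy == "proxy") decide_proxy(sp, m, "colour")
               else decide_foil(sp, m, "colour")
        want <- naive_proxy_foil(m, task, "a", "b", known, k, "colour",
                                 strategy)
        expect_equal(dec$scores, want,
                     info = paste(task, strategy, k))
        expect_equal(dec$chosen, which.max(want))
      }
    }
  }
})

test_that("PROXY with k = 1 follows the nearest proxy's appearance", {
  m <- toy_models(seed = 2)
  # candidate 'a' made identical in appearance to the nearest proxy
  near <- names(which.min(m$D_word["a", c("c", "d", "e", "f")]))
  m$D_colour["a", near] <- m$D_colour[near, "a"] <- 0
  sp <- trial_spec("identification", "a", "b", known = c("c", "d", "e", "f"),
                   strategy = "proxy", k = 1, modality = "colour")
  expect_equal(decide_proxy(sp, m, "colour")$chosen, 1L)
})

test_that("PROXY and FOIL with k = |known| share the reference set with opposite order", {
  m <- toy_models(seed = 5)
  known <- c("c", "d", "e", "f")
  for (task in c("identification", "naming")) {
    sp <- trial_spec(task, "a", "b", known = known, strategy = "proxy",
                     k = 4, modality = "texton")
    sf <- trial_spec(task, "a", "b", known = known, strategy = "foil",
                     k = 4, modality = "texton")
    ps <- decide_proxy(sp, m, "texton")$scores
    fs <- decide_foil(sf, m, "texton")$scores
    expect_equal(ps, -fs)                     # same means, opposite sign
    expect_equal(order(ps), rev(order(fs)))   # opposite preference order
  }
})

test_that("modality combination follows the more unequivocal answer", {
  # the worked example: colour 0.3/0.1 (margin 0.2) beats texton 0.4/0.5
  # (margin 0.1), so colour is followed and candidate 1 chosen
  cmb <- combine_modalities(c(0.3, 0.1), c(0.4, 0.5))
  expect_equal(cmb$modality, "colour")
  expect_equal(cmb$chosen, 1L)
  cmb2 <- combine_modalities(c(0.9, 0.1), c(0.5, 0.5))
  expect_equal(cmb2$modality, "colour")
  expect_equal(cmb2$chosen, 1L)
  # equal margins follow textons
  cmb3 <- combine_modalities(c(0.6, 0.4), c(0.1, 0.3))
  expect_equal(cmb3$modality, "texton")
  expect_equal(cmb3$chosen, 2L)
  # multi-candidate margins are top minus runner-up
  colour <- c(0.5, 0.2, 0.45)
  texton <- c(0.1, 0.8, 0.7)
  ms <- function(s) sort(s, decreasing = TRUE)
  expect_equal(combine_modalities(colour, texton)$modality,
               if ((ms(colour)[1] - ms(colour)[2]) >
                   (ms(texton)[1] - ms(texton)[2])) "colour" else "texton")
})

test_that("run_trial is deterministic and free of positional bias", {
  m <- toy_models(seed = 11)
  sp <- trial_spec("identification", "a", "b", known = c("c", "d", "e", "f"),
                   seed = 99)
  o1 <- run_trial(sp, m)
  o2 <- run_trial(sp, m)
  expect_identical(o1, o2)
  expect_s3_class(o1, "trial_outcome")
  expect_equal(dim(o1$scores), c(2, 2))
  # relabelling candidates permutes the scores identically: swapping the
  # roles of the two appearances swaps the two score rows
  spA <- trial_spec("identification", "a", "b",
                    known = c("c", "d", "e", "f"), modality = "colour")
  sA <- run_trial(spA, m)$scores[, 1]
  swap <- c("a", "b")
  m_sw <- m
  perm <- match(m$words, m$words)
  perm[match(swap, m$words)] <- rev(perm[match(swap, m$words)])
  m_sw <- permute_appearances(m, perm)
  sB <- run_trial(spA, m_sw)$scores[, 1]
  expect_equal(sA, rev(sB))
  expect_error(run_trial(trial_spec("naming", "zz", "b", c("c", "d")), m),
               "zz")
})
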