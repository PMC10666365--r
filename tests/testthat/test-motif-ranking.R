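toy_motifs <- function(ids = c("A|B|C", "A|D|E")) {
  tibble::tibble(
    motif_id = ids,
    n1 = c("A", "A"), n2 = c("B", "D"), n3 = c("C", "E"),
    s12 = 1L, s23 = 1L, s31 = 1L, loop_sign = "positive")[
      seq_along(ids), ]
}

toy_topo <- function() {
  tibble::tibble(id = c("A", "B", "C", "D", "E"),
                 degree = c(2L, 4L, 6L, 1L, 1L),
                 betweenness = c(0.2, 0.4, 0.6, 0.1, 0.0))
}

test_that("motif features aggregate node properties correctly", {
  annot <- tibble::tibble(id = c("A", "B", "C"),
                          dp_member = TRUE, gp_score = c(1, 2, 3))
  fc <- tibble::tibble(id = c("A", "B"), log2fc = c(1.0, -2.0))
  f <- featurize_motifs(toy_motifs("A|B|C"), toy_topo(), annot, fc)
  expect_equal(f$nd, 4)            # mean(2, 4, 6)
  expect_equal(f$dp, 3L)           # all three members
  expect_equal(f$absfc, 1.5)       # mean(|1|, |-2|) over non-missing
  expect_true(f$fc_missing)
  expect_equal(f$gp, 2)            # mean(1, 2, 3)

  sums <- featurize_motifs(toy_motifs("A|B|C"), toy_topo(), annot, fc,
                           aggregate = "sum")
  expect_equal(sums$nd, 12)

  bad <- toy_motifs("A|B|C"); bad$n3 <- "MISSING"
  expect_error(featurize_motifs(bad, toy_topo()), "MISSING")
})

test_that("zero fold changes are treated as sign-free (missing)", {
  fc <- tibble::tibble(id = c("A", "B", "C"), log2fc = c(0, 0, 0))
  f <- featurize_motifs(toy_motifs("A|B|C"), toy_topo(), fc = fc)
  expect_equal(f$absfc, 0)
  expect_true(f$fc_missing)
})

test_that("the score matches the weighted max-normalized form", {
  # a motif attaining every batch maximum scores w1 + w2 + w3 + w4
  feats <- tibble::tibble(
    motif_id = c("M1", "M2"),
    nd = c(6, 3), bc = c(0.5, 0.2), dp = c(3L, 1L), gp = c(4, 1),
    absfc = c(2, 0.5), fc_missing = FALSE)
  s_top <- score_motifs(feats, tibble::tibble(id = "topo", w1 = 1, w2 = 0,
                                              w3 = 0, w4 = 0))
  expect_equal(s_top$score[s_top$motif_id == "M1"], 1.0)
  s_all <- score_motifs(feats, tibble::tibble(id = "all", w1 = 1, w2 = 1,
                                              w3 = 1, w4 = 1))
  expect_equal(s_all$score[s_all$motif_id == "M1"], 4.0)
})

test_that("scores equal an independent per-term arithmetic oracle", {
  set.seed(42)
  feats <- tibble::tibble(
    motif_id = sprintf("M%d", 1:6),
    nd = runif(6, 1, 10), bc = runif(6), dp = sample(0:3, 6, TRUE),
    gp = runif(6, 0, 5), absfc = runif(6, 0, 3), fc_missing = FALSE)
  w <- c(2, 1, 1, 1)
  got <- score_motifs(feats, tibble::tibble(id = "s", w1 = w[1],
                                            w2 = w[2], w3 = w[3],
                                            w4 = w[4]))
  want <- vapply(seq_len(6), function(i) {
    w[1] / 2 * (feats$nd[i] / max(feats$nd) + feats$bc[i] / max(feats$bc)) +
      w[2] * feats$dp[i] / max(feats$dp) +
      w[3] * feats$gp[i] / max(feats$gp) +
      w[4] * feats$absfc[i] / max(feats$absfc)
  }, 0)
  expect_equal(got$score[match(feats$motif_id, got$motif_id)], want,
               tolerance = 1e-12)
})

test_that("zero-max terms contribute zero instead of NaN", {
  feats <- tibble::tibble(motif_id = c("M1", "M2"), nd = c(2, 1),
                          bc = c(0, 0), dp = 0L, gp = 0,
                          absfc = 0, fc_missing = TRUE)
  s <- score_motifs(feats, tibble::tibble(id = "u", w1 = 1, w2 = 1,
                                          w3 = 1, w4 = 1))
  expect_equal(s$score[s$motif_id == "M1"], 0.5)  # only nd term alive
  expect_false(any(is.nan(s$score)))
})

test_that("score is linear in the weights and invariant to feature scaling", {
  set.seed(7)
  feats <- tibble::tibble(
    motif_id = sprintf("M%d", 1:5),
    nd = runif(5, 1, 10), bc = runif(5), dp = sample(0:3, 5, TRUE),
    gp = runif(5, 0, 5), absfc = runif(5, 0, 3), fc_missing = FALSE)
  w <- tibble::tibble(id = "w", w1 = 1.5, w2 = 0.5, w3 = 2, w4 = 1)
  s1 <- score_motifs(feats, w)
  w3x <- dplyr::mutate(w, dplyr::across(w1:w4, ~ 3 * .x))
  s3 <- score_motifs(feats, w3x)
  expect_equal(s3$score, 3 * s1$score, tolerance = 1e-12)

  scaled <- dplyr::mutate(feats, nd = 17 * nd, gp = 0.3 * gp)
  expect_equal(score_motifs(scaled, w)$score, s1$score, tolerance = 1e-12)
})

test_that("a motif dominating every feature ranks first in all scenarios", {
  set.seed(11)
  feats <- tibble::tibble(
    motif_id = c("AAA|BBB|CCC", sprintf("M%d", 1:9)),
    nd = c(10, runif(9, 1, 5)), bc = c(0.9, runif(9, 0, 0.5)),
    dp = c(3L, sample(0:2, 9, TRUE)), gp = c(5, runif(9, 0, 3)),
    absfc = c(4, runif(9, 0, 2)), fc_missing = FALSE)
  scores <- score_motifs(feats, default_weight_scenarios())
  top <- scores |>
    dplyr::group_by(scenario) |>
    dplyr::slice_max(score, n = 1, with_ties = FALSE)
  expect_true(all(top$motif_id == "AAA|BBB|CCC"))
})

test_that("top-k selection is deterministic with documented tie-breaking", {
  feats <- tibble::tibble(motif_id = c("B|C|D", "A|B|C"),
                          nd = c(2, 2), bc = c(0.5, 0.5), dp = 1L,
                          gp = 1, absfc = 1, fc_missing = FALSE)
  s <- score_motifs(feats, default_weight_scenarios())
  sel <- select_top_motifs(s, k = 1)
  expect_true(all(sel$selected$motif_id == "A|B|C"))  # tie -> lower id

  # 13 scenarios x k = 2 over 2 motifs -> 26 selections, 2 unique
  sel2 <- select_top_motifs(s, k = 2)
  expect_equal(nrow(sel2$selected), 26)
  expect_equal(sel2$unique_motifs, c("A|B|C", "B|C|D"))

  expect_warning(sel3 <- select_top_motifs(s, k = 10), "taking all")
  expect_equal(nrow(sel3$selected), 26)
})
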