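test_that("weighted AUROC/AUPRC match direct evaluation on canonical cases", {
  perfect <- weighted_auc(0.9, 0.1, w_neg = 50)
  expect_equal(perfect$auroc, 1)
  expect_equal(perfect$auprc, 1)
  expect_equal(weighted_auc(c(0.8, 0.4), c(0.6, 0.2), w_neg = 7)$auroc, 0.75)
  expect_error(weighted_auc(numeric(0), 1), "non-empty")
  # uniform per-class weights cancel from AUROC
  pos <- runif(50); neg <- runif(60)
  expect_equal(weighted_auc(pos, neg, 1)$auroc,
               weighted_auc(pos, neg, 50)$auroc)
})

test_that("a label-independent scorer has AUPRC 1/(1+w) under equal counts", {
  n <- 20000
  scores <- withr::with_seed(8, runif(2 * n))
  res <- weighted_auc(scores[1:n], scores[(n + 1):(2 * n)], w_neg = 50)
  expect_equal(res$auroc, 0.5, tolerance = 0.02)
  expect_equal(res$auprc, 1 / 51, tolerance = 0.1)
})

test_that("bootstrap AUC summaries are seeded and tighten with resample size", {
  pos <- withr::with_seed(1, rnorm(500, 2))
  neg <- withr::with_seed(2, rnorm(500, 0))
  s1 <- resampled_auc_summary(pos, neg, n_reps = 30, n_pos = 100, n_neg = 100,
                              w_neg = 50, seed = 5)
  s2 <- resampled_auc_summary(pos, neg, n_reps = 30, n_pos = 100, n_neg = 100,
                              w_neg = 50, seed = 5)
  expect_identical(s1, s2)
  s_big <- resampled_auc_summary(pos, neg, n_reps = 30, n_pos = 2000,
                                 n_neg = 2000, w_neg = 50, seed = 5)
  expect_lt(s_big$sd[1], s1$sd[1])
  sep <- resampled_auc_summary(rep(0.9, 50), rep(0.1, 50), n_reps = 5,
                               n_pos = 50, n_neg = 50, seed = 1)
  expect_equal(sep$mean, c(1, 1))
  expect_equal(sep$sd, c(0, 0))
  expect_error(resampled_auc_summary(pos, neg, n_reps = 1, seed = 1), "n_reps")
})

test_that("score agreement reproduces hand-computed correlations", {
  expect_equal(score_agreement(1:5, 1:5)$pcc, 1)
  expect_equal(score_agreement(1:5, -(1:5))$scc, -1)
  x <- c(0.1, 0.4, 0.2, 0.9, 0.6)
  y <- c(0.2, 0.1, 0.5, 0.8, 0.4)
  manual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(score_agreement(x, y)$pcc, manual)
  expect_error(score_agreement(rep(1, 5), 1:5), "constant")
})

test_that("weighted Jaccard follows its definition, with flagged exclusions", {
  expect_equal(weighted_jaccard(c(0.5, 0.2), c(0.5, 0.2)), 1)
  expect_equal(weighted_jaccard(c(1, 0), c(0, 1)), 0)
  expect_equal(weighted_jaccard(c(0.5, 0.2, 0), c(0.25, 0.4, 0.1)), 0.45)
  expect_warning(res <- weighted_jaccard(c(0, 0), c(0, 0)),
                 class = "lecifr_zero_denominator")
  expect_true(is.na(res))
  # symmetry and bounds on random instances, against direct evaluation
  withr::with_seed(4, {
    for (i in 1:25) {
      h <- runif(6); m <- runif(6)
      j <- weighted_jaccard(h, m)
      expect_equal(j, jaccard_oracle(h, m))
      expect_equal(j, weighted_jaccard(m, h))
      expect_true(j >= 0 && j <= 1)
    }
  })
})

test_that("tissue activity fractions count group experiments overlapping each region", {
  mk_peak <- function(id, group, ivs, species = "a") {
    list(track_id = id, species = species, kind = "peak", epigenome = NA,
         group = group,
         data = tibble::tibble(chrom = "chr1", start = ivs[, 1], end = ivs[, 2]))
  }
  pairs <- tibble::tibble(pair_id = c("p1", "p2"),
                          a_chrom = "chr1", a_start = c(100, 900),
                          a_end = c(150, 950),
                          b_chrom = "chr1", b_start = c(100, 900),
                          b_end = c(150, 950))
  liver_a <- list(mk_peak("l1", "liver", cbind(90, 120)),
                  mk_peak("l2", "liver", cbind(0, 10)),
                  mk_peak("l3", "liver", cbind(140, 200)),
                  mk_peak("l4", "liver", cbind(300, 400)))
  liver_b <- list(mk_peak("bl1", "liver", cbind(90, 120), "b"))
  act <- tissue_activity_vectors(pairs, liver_a, liver_b)
  p1 <- act |> dplyr::filter(pair_id == "p1")
  expect_equal(p1$a_fraction, 0.5)   # 2 of 4 liver experiments overlap
  p2 <- act |> dplyr::filter(pair_id == "p2")
  expect_equal(p2$a_fraction, 0)
  expect_equal(p2$b_fraction, 0)
  # order invariance
  act2 <- tissue_activity_vectors(pairs, rev(liver_a), liver_b)
  expect_equal(act2$a_fraction, act$a_fraction)
  brain_only_a <- c(liver_a, list(mk_peak("x", "brain", cbind(0, 10))))
  expect_error(tissue_activity_vectors(pairs, brain_only_a, liver_b),
               "only one species")
  jac <- pairwise_jaccard(act)
  expect_true(is.na(jac$jaccard[jac$pair_id == "p2"]))
})

test_that("state frequency correlation matches the direct formula and its nulls", {
  mk_seg <- function(id, epi, states_by_region, species, regions) {
    list(track_id = id, species = species, kind = "segmentation",
         epigenome = epi, group = NA,
         data = tibble::tibble(chrom = "chr1", start = regions[, 1],
                               end = regions[, 2], state = states_by_region),
         states = sort(unique(states_by_region)))
  }
  regions <- cbind(c(0, 100, 200), c(50, 150, 250))
  pairs <- tibble::tibble(pair_id = paste0("p", 1:3),
                          a_chrom = "chr1", a_start = regions[, 1],
                          a_end = regions[, 2],
                          b_chrom = "chr1", b_start = regions[, 1],
                          b_end = regions[, 2])
  segs_a <- list(mk_seg("a1", "e1", c("E1", "E2", "E1"), "a", regions),
                 mk_seg("a2", "e2", c("E1", "E1", "E2"), "a", regions))
  # identical annotations on both sides: PCC 1 wherever defined
  res <- state_frequency_correlation(pairs, segs_a, segs_a)
  expect_true(all(res$pcc[!is.na(res$pcc)] == 1))
  # hand-computed example against cor()
  segs_b <- list(mk_seg("b1", "e1", c("E2", "E1", "E1"), "b", regions),
                 mk_seg("b2", "e2", c("E1", "E2", "E1"), "b", regions))
  res2 <- state_frequency_correlation(pairs, segs_a, segs_b)
  fa_e1 <- c(1, 0.5, 0.5); fb_e1 <- c(0.5, 0.5, 1)
  expect_equal(res2$pcc[res2$state == "E1"], cor(fa_e1, fb_e1))
})

test_that("state frequency correlation vanishes under cross-species shuffling", {
  pipe <- std_pipeline()
  segs <- function(tracks) tracks[purrr::map_chr(tracks, "kind") == "segmentation"]
  pos <- pipe$labeled |> dplyr::filter(role == "test", label == "positive")
  pos <- pos[1:800, ]
  shuffled <- pos
  perm <- withr::with_seed(7, sample(nrow(pos)))
  shuffled$b_chrom <- pos$b_chrom[perm]
  shuffled$b_start <- pos$b_start[perm]
  shuffled$b_end <- pos$b_end[perm]
  res <- state_frequency_correlation(shuffled, segs(pipe$data$tracks_a),
                                     segs(pipe$data$tracks_b))
  expect_lt(max(abs(res$pcc), na.rm = TRUE), 0.15)
})

test_that("score binning partitions pairs in both modes", {
  x <- tibble::tibble(score = seq(0, 1, length.out = 101))
  ew <- bin_by_score(x, "equal_width", 10)
  expect_equal(attr(ew, "edges"), seq(0, 1, by = 0.1))
  # a partition: every score in exactly one bin, bins ordered with score
  expect_true(all(ew$bin %in% 1:10))
  expect_equal(sum(table(ew$bin)), 101)
  expect_true(all(diff(ew$bin[order(ew$score)]) >= 0))
  y <- tibble::tibble(score = withr::with_seed(1, runif(1000)))
  pr <- bin_by_score(y, "percentile_rank", 10)
  expect_equal(unname(as.numeric(table(pr$bin))), rep(100, 10))
  expect_true(all(!is.na(pr$bin)))
  expect_error(bin_by_score(tibble::tibble(score = rep(1, 5)),
                            "percentile_rank", 3),
               "distinct")
})

test_that("variant enrichment reports ratios and exact binomial tails", {
  # bin 10 overlaps at 10%, background at 5% -> log2 fold 1 in that bin
  regions <- tibble::tibble(
    chrom = "chr1",
    start = seq(0, by = 100, length.out = 200),
    end = seq(0, by = 100, length.out = 200) + 50,
    score = rep(c(0.1, 0.95), each = 100)
  )
  overlap_rows <- which(regions$score == 0.95)[1:10]
  variants <- tibble::tibble(chrom = "chr1",
                             start = regions$start[overlap_rows] + 1,
                             end = regions$start[overlap_rows] + 2)
  enr <- variant_enrichment(regions, variants, k = 10)
  bg <- attr(enr, "background_rate")
  expect_equal(bg, 0.05)
  hi <- enr[enr$bin == 10, ]
  expect_equal(hi$n_regions, 100L)
  expect_equal(hi$log2_fold, 1)
  # exact binomial tail oracle
  p_oracle <- sum(dbinom(hi$n_overlap:hi$n_regions, hi$n_regions, bg))
  expect_equal(hi$p_value, p_oracle)
  # count-weighted mean fold is 1 by construction
  ok <- !is.na(enr$fold)
  expect_equal(sum(enr$fold[ok] * enr$n_regions[ok]) / sum(enr$n_regions[ok]), 1)
  # variants covering every region: fold 1, log2 0 in all non-empty bins
  all_var <- regions |> dplyr::select(chrom, start, end)
  enr_all <- variant_enrichment(regions, all_var, k = 10)
  expect_true(all(abs(enr_all$log2_fold[!is.na(enr_all$log2_fold)]) < 1e-12))
})

test_that("annotation comparison uses a two-sided Mann-Whitney test", {
  track <- tibble::tibble(
    a_chrom = "chr1", a_start = seq(0, by = 50, length.out = 200),
    a_end = seq(0, by = 50, length.out = 200) + 50,
    b_chrom = "chr1", b_start = seq(0, by = 50, length.out = 200),
    b_end = seq(0, by = 50, length.out = 200) + 50,
    score = withr::with_seed(3, runif(200, 0, 0.3))
  )
  # plant clearly higher scores under the annotation
  ann <- tibble::tibble(chrom = "chr1", start = 0, end = 50 * 40)
  track$score[track$a_start < 2000] <- track$score[track$a_start < 2000] + 0.5
  res <- score_by_annotation(track, ann, side = "a")
  expect_lt(res$p_value, 0.05)
  expect_gt(res$summary$mean[res$summary$group == "overlap"],
            res$summary$mean[res$summary$group == "non_overlap"])
  covers_all <- tibble::tibble(chrom = "chr1", start = 0, end = 1e6)
  expect_error(score_by_annotation(track, covers_all), "empty")
})

test_that("the U statistic and exact p match an exhaustive rank oracle", {
  withr::with_seed(11, {
    for (i in 1:10) {
      x <- round(runif(4), 3); y <- round(runif(3), 3)
      if (anyDuplicated(c(x, y))) next
      res <- suppressWarnings(wilcox.test(x, y, alternative = "two.sided",
                                          exact = TRUE))
      oracle <- mwu_oracle(x, y)
      expect_equal(unname(res$statistic), oracle$u)
      expect_equal(res$p.value, oracle$p)
    }
  })
})

test_that("per-state mean scores average in two levels over epigenomes", {
  mk_seg <- function(id, epi, data) {
    list(track_id = id, species = "a", kind = "segmentation", epigenome = epi,
         group = NA, data = data, states = sort(unique(data$state)))
  }
  track <- tibble::tibble(
    a_chrom = "chr1", a_start = c(0, 100, 200), a_end = c(50, 150, 250),
    b_chrom = "chr1", b_start = c(0, 100, 200), b_end = c(50, 150, 250),
    score = c(0.2, 0.4, 0.6)
  )
  seg1 <- mk_seg("s1", "e1", tibble::tibble(chrom = "chr1", start = c(0, 100),
                                            end = c(60, 160), state = "E1"))
  res1 <- mean_score_per_state(track, list(seg1))
  expect_equal(res1$mean_score[res1$state == "E1"], 0.3)
  # second epigenome annotates only the 0.6 region with E1: state mean is
  # the unweighted mean of per-epigenome means (0.3 and 0.6)
  seg2 <- mk_seg("s2", "e2", tibble::tibble(chrom = "chr1", start = 200,
                                            end = 260, state = "E1"))
  res2 <- mean_score_per_state(track, list(seg1, seg2))
  expect_equal(res2$mean_score[res2$state == "E1"], 0.45)
  res_rev <- mean_score_per_state(track[3:1, ], list(seg1, seg2))
  expect_equal(res_rev$mean_score, res2$mean_score)
})

test_that("windowed means enforce the strictly-less-than-half coverage rule", {
  track <- tibble::tibble(
    a_chrom = "chr1", a_start = c(0, 1200), a_end = c(400, 1700),
    b_chrom = "chr1", b_start = c(0, 1200), b_end = c(400, 1700),
    score = c(0.2, 0.6)
  )
  windows <- tibble::tibble(chrom = "chr1", start = c(0, 1000), end = c(1000, 2000))
  res <- windowed_mean_score(track, windows)
  # window 1 has 400 of 1000 bases annotated -> excluded; window 2 has
  # exactly half -> retained with the mean over annotated bases
  expect_equal(nrow(res), 1L)
  expect_equal(res$start, 1000)
  expect_equal(res$covered_bases, 500)
  expect_equal(res$mean_score, 0.6)
  # fully covered constant-score windows return the constant
  full <- tibble::tibble(
    a_chrom = "chr1", a_start = 0, a_end = 1000,
    b_chrom = "chr1", b_start = 0, b_end = 1000, score = 0.37
  )
  res_full <- windowed_mean_score(full, tibble::tibble(chrom = "chr1",
                                                       start = 0, end = 1000))
  expect_equal(res_full$mean_score, 0.37)
})

test_that("windowed track correlation is exact for identical tracks and null for noise", {
  base <- tibble::tibble(
    chrom = "chr1", start = seq(0, by = 50, length.out = 400),
    end = seq(0, by = 50, length.out = 400) + 50
  )
  x <- base |> dplyr::mutate(score = withr::with_seed(1, runif(400)))
  res_same <- windowed_track_correlation(x, x, min_annotated = c(1, 25, 50))
  expect_true(all(res_same$pcc == 1))
  expect_true(all(res_same$scc == 1))
  y <- base |> dplyr::mutate(score = withr::with_seed(2, runif(400)))
  res_null <- windowed_track_correlation(x, y, min_annotated = 50)
  expect_lt(abs(res_null$pcc), 0.1)
  # n = 50 keeps only fully co-annotated windows
  x_gap <- x[-(1:10), ]
  res_gap <- windowed_track_correlation(x_gap, y, min_annotated = 50)
  expect_lt(res_gap$n_windows, res_null$n_windows)
  expect_error(windowed_track_correlation(x[1:1, ], y[1:1, ],
                                          min_annotated = 50),
               "Fewer than 3")
})
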