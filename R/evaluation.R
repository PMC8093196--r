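#' Class-weighted AUROC and AUPRC
#'
#' AUROC is the weighted probability that a positive outscores a negative,
#' with ties counted one half; a uniform per-negative weight cancels from
#' AUROC but not from AUPRC, where each negative contributes `w_neg` to the
#' false-positive mass in the precision denominator. Under equal class
#' counts and label-independent scores the expected AUROC is 0.5 and the
#' expected AUPRC is `1 / (1 + w_neg)`.
#'
#' @param pos_scores,neg_scores Scores for positive and negative examples.
#' @param w_neg Weight per negative example.
#' @return A one-row tibble with `auroc` and `auprc`.
#' @export
weighted_auc <- function(pos_scores, neg_scores, w_neg = 1) {
  if (length(pos_scores) == 0L || length(neg_scores) == 0L) {
    abort("Both score sets must be non-empty.")
  }
  auroc <- fast_auc(pos_scores, neg_scores)
  scores <- c(pos_scores, neg_scores)
  is_pos <- c(rep(TRUE, length(pos_scores)), rep(FALSE, length(neg_scores)))
  ord <- order(scores, decreasing = TRUE)
  scores <- scores[ord]; is_pos <- is_pos[ord]
  # group tied scores so a tie block enters the curve as one step
  grp <- cumsum(c(TRUE, scores[-1] != scores[-length(scores)]))
  tp <- as.numeric(tapply(is_pos, grp, sum))
  fp <- as.numeric(tapply(!is_pos, grp, sum))
  cum_tp <- cumsum(tp)
  cum_fp <- cumsum(fp)
  precision <- cum_tp / (cum_tp + w_neg * cum_fp)
  recall <- cum_tp / sum(is_pos)
  auprc <- sum(diff(c(0, recall)) * precision)
  tibble(auroc = auroc, auprc = auprc)
}

#' Bootstrap summary of weighted AUROC/AUPRC
#'
#' Resamples positives and negatives with replacement `n_reps` times and
#' reports the mean and standard deviation of the weighted AUROC and AUPRC.
#'
#' @param pos_scores,neg_scores Held-out scores per class.
#' @param n_reps Number of bootstrap resamples (at least 2).
#' @param n_pos,n_neg Resample sizes.
#' @param w_neg Weight per negative example.
#' @param seed Integer seed.
#' @return A tibble with one row per metric: `metric`, `mean`, `sd`.
#' @export
resampled_auc_summary <- function(pos_scores, neg_scores, n_reps = 100L,
                                  n_pos = 1e5, n_neg = 1e5, w_neg = 50,
                                  seed = 1L) {
  if (n_reps < 2L) abort("n_reps must be >= 2 for a standard deviation.")
  seed <- check_seed(seed)
  reps <- withr::with_seed(seed, {
    map(seq_len(n_reps), function(i) {
      weighted_auc(sample(pos_scores, n_pos, replace = TRUE),
                   sample(neg_scores, n_neg, replace = TRUE), w_neg)
    }) |> list_rbind()
  })
  tibble(metric = c("auroc", "auprc"),
         mean = c(mean(reps$auroc), mean(reps$auprc)),
         sd = c(sd(reps$auroc), sd(reps$auprc)))
}

#' Agreement between two score vectors
#'
#' @param scores_x,scores_y Scores over the same pairs.
#' @return A one-row tibble with Pearson (`pcc`) and Spearman (`scc`)
#'   correlation coefficients.
#' @export
score_agreement <- function(scores_x, scores_y) {
  stopifnot(length(scores_x) == length(scores_y))
  if (length(scores_x) < 3L) abort("Need at least 3 shared pairs.")
  if (sd(scores_x) == 0 || sd(scores_y) == 0) {
    abort("Correlation undefined for constant scores.")
  }
  tibble(pcc = cor(scores_x, scores_y, method = "pearson"),
         scc = cor(scores_x, scores_y, method = "spearman"))
}

#' Weighted Jaccard similarity of two activity vectors
#'
#' `sum_i min(h_i, m_i) / sum_i max(h_i, m_i)` over tissue-group activity
#' fractions. When the denominator is zero the coefficient is undefined; the
#' pair is flagged for exclusion by returning `NA` with a
#' `lecifr_zero_denominator` warning.
#'
#' @param h,m Numeric activity-fraction vectors of equal length, entries in
#'   `[0, 1]`.
#' @return The coefficient in `[0, 1]`, or `NA` when undefined.
#' @export
weighted_jaccard <- function(h, m) {
  stopifnot(length(h) == length(m))
  denom <- sum(pmax(h, m))
  if (denom == 0) {
    warn("Zero denominator: similarity undefined; pair should be excluded.",
         class = "lecifr_zero_denominator")
    return(NA_real_)
  }
  sum(pmin(h, m)) / denom
}

#' Per-pair tissue-grouped activity vectors
#'
#' For each region pair and tissue group, the fraction of that group's peak
#' experiments (per species) whose peaks overlap the region. Tracks with no
#' group assignment are discarded; every group must be represented in both
#' species. Group metadata is evaluation-only and never enters training
#' features.
#'
#' @param pairs Tibble of region pairs.
#' @param tracks_a,tracks_b Peak track lists carrying `group` tags.
#' @return A long tibble: `pair_id`, `group`, `a_fraction`, `b_fraction`.
#' @export
tissue_activity_vectors <- function(pairs, tracks_a, tracks_b) {
  grouped <- function(tracks) {
    keep <- map_lgl(tracks, function(t) t$kind == "peak" && !is.na(t$group))
    tracks[keep]
  }
  ta <- grouped(tracks_a); tb <- grouped(tracks_b)
  groups_a <- unique(map_chr(ta, "group"))
  groups_b <- unique(map_chr(tb, "group"))
  only_one <- c(setdiff(groups_a, groups_b), setdiff(groups_b, groups_a))
  if (length(only_one) > 0L) {
    abort(sprintf("Tissue group(s) present in only one species: %s",
                  paste(only_one, collapse = ", ")))
  }
  groups <- sort(groups_a)
  frac_side <- function(tracks, chrom_col, start_col, end_col) {
    map(groups, function(g) {
      gt <- tracks[map_chr(tracks, "group") == g]
      hits <- map(gt, function(t) {
        overlaps_any(pairs, t$data,
                     q_cols = c(chrom_col, start_col, end_col))
      })
      Reduce(`+`, map(hits, as.numeric)) / length(gt)
    })
  }
  fa <- frac_side(ta, "a_chrom", "a_start", "a_end")
  fb <- frac_side(tb, "b_chrom", "b_start", "b_end")
  map(seq_along(groups), function(i) {
    tibble(pair_id = pairs$pair_id, group = groups[i],
           a_fraction = fa[[i]], b_fraction = fb[[i]])
  }) |> list_rbind() |> arrange(.data$pair_id, .data$group)
}

#' Per-pair weighted Jaccard similarity from activity vectors
#'
#' @param activity Long tibble from [tissue_activity_vectors()].
#' @return A tibble `pair_id`, `jaccard` (`NA` where the denominator is
#'   zero, i.e. the pair is excluded).
#' @export
pairwise_jaccard <- function(activity) {
  activity |>
    group_by(.data$pair_id) |>
    summarise(
      jaccard = {
        denom <- sum(pmax(.data$a_fraction, .data$b_fraction))
        if (denom == 0) NA_real_ else
          sum(pmin(.data$a_fraction, .data$b_fraction)) / denom
      },
      .groups = "drop"
    )
}

#' Chromatin-state frequency correlation
#'
#' For a set of pairs and jointly learned segmentations (a shared state
#' alphabet across species), computes for each state the Pearson correlation
#' across pairs between the fraction of species-A epigenomes annotating the
#' A region with that state and the same fraction for the B region. States
#' with a constant fraction vector in either species are reported as `NA`
#' (undefined), not 0.
#'
#' @param pairs Tibble of region pairs.
#' @param tracks_a,tracks_b Segmentation track lists sharing one state
#'   alphabet.
#' @return A tibble `state`, `pcc`, `n_pairs`.
#' @export
state_frequency_correlation <- function(pairs, tracks_a, tracks_b) {
  if (nrow(pairs) == 0L) abort("Empty pair set.")
  segs <- function(tracks) tracks[map_chr(tracks, "kind") == "segmentation"]
  sa <- segs(tracks_a); sb <- segs(tracks_b)
  states <- sort_states(unique(c(unlist(map(sa, "states")),
                                 unlist(map(sb, "states")))))
  frac <- function(tracks, chrom_col, start_col, end_col, state) {
    hit <- map(tracks, function(t) {
      overlaps_any(pairs, t$data |> filter(.data$state == !!state),
                   q_cols = c(chrom_col, start_col, end_col))
    })
    Reduce(`+`, map(hit, as.numeric)) / length(tracks)
  }
  map(states, function(s) {
    fa <- frac(sa, "a_chrom", "a_start", "a_end", s)
    fb <- frac(sb, "b_chrom", "b_start", "b_end", s)
    pcc <- if (sd(fa) == 0 || sd(fb) == 0) NA_real_ else cor(fa, fb)
    tibble(state = s, pcc = pcc, n_pairs = nrow(pairs))
  }) |> list_rbind()
}

#' Bin pairs by score
#'
#' Equal-width bins span the observed score range uniformly; percentile-rank
#' bins have near-equal counts with ties resolved by stable rank order.
#'
#' @param x Data frame with a `score` column.
#' @param mode `"equal_width"` or `"percentile_rank"`.
#' @param k Number of bins (>= 2).
#' @return `x` with a `bin` column (integer, 1 = lowest scores); bin edges
#'   (equal-width mode) attached as attribute `"edges"`.
#' @export
bin_by_score <- function(x, mode = c("equal_width", "percentile_rank"),
                         k = 10L) {
  mode <- match.arg(mode)
  stopifnot(k >= 2L)
  s <- x$score
  if (mode == "equal_width") {
    edges <- seq(min(s), max(s), length.out = k + 1L)
    bin <- pmin(pmax(findInterval(s, edges, rightmost.closed = TRUE), 1L), k)
  } else {
    if (length(unique(s)) < k) {
      abort("percentile_rank binning needs at least k distinct scores.")
    }
    r <- rank(s, ties.method = "first")
    bin <- ceiling(r * k / length(s))
    edges <- NULL
  }
  out <- x |> mutate(bin = as.integer(bin))
  attr(out, "edges") <- edges
  attr(out, "mode") <- mode
  class(out) <- c("lecif_binning", class(out))
  out
}

#' Variant enrichment across score bins
#'
#' Regions are placed into `k` equal-width score bins; within each bin the
#' fraction of regions overlapping a variant is compared to the background
#' fraction over all scored regions (a uniform background within aligning
#' regions). Reports log2 fold enrichment and a one-sided binomial p-value
#' for the bin's overlap count at the background rate. Empty bins yield
#' missing folds.
#'
#' @param regions Data frame of scored A regions (`chrom`/`start`/`end` as
#'   `a_chrom` etc. or plain names, plus `score`).
#' @param variants Tibble of variant intervals (`chrom`, `start`, `end`).
#' @param k Number of equal-width bins.
#' @return A `lecif_enrichment` tibble: per bin, `n_regions`, `n_overlap`,
#'   `fold`, `log2_fold`, `p_value`.
#' @export
variant_enrichment <- function(regions, variants, k = 10L) {
  cols <- if ("a_chrom" %in% names(regions)) {
    c("a_chrom", "a_start", "a_end")
  } else {
    c("chrom", "start", "end")
  }
  binned <- bin_by_score(as_tibble(regions), "equal_width", k)
  hit <- overlaps_any(binned, variants, q_cols = cols)
  bg_rate <- mean(hit)
  out <- map(seq_len(k), function(b) {
    in_bin <- binned$bin == b
    n <- sum(in_bin); x <- sum(hit[in_bin])
    if (n == 0L || bg_rate == 0) {
      tibble(bin = b, n_regions = n, n_overlap = x, fold = NA_real_,
             log2_fold = NA_real_, p_value = NA_real_)
    } else {
      fold <- (x / n) / bg_rate
      tibble(bin = b, n_regions = n, n_overlap = x, fold = fold,
             log2_fold = log2(fold),
             p_value = pbinom(x - 1L, n, bg_rate, lower.tail = FALSE))
    }
  }) |> list_rbind()
  attr(out, "edges") <- attr(binned, "edges")
  attr(out, "background_rate") <- bg_rate
  class(out) <- c("lecif_enrichment", class(out))
  out
}

#' Score distributions inside and outside an annotation
#'
#' Splits the score track by whether the chosen side(s) overlap the
#' annotation, summarises each group, and compares them with a two-sided
#' Mann-Whitney U test (exact for small tie-free groups, normal
#' approximation with tie correction otherwise, as in
#' [stats::wilcox.test()]).
#'
#' @param track A score track tibble.
#' @param annotation Tibble of intervals (`chrom`, `start`, `end`) on the
#'   chosen side's genome.
#' @param side `"a"`, `"b"`, or `"both"` (both sides must overlap).
#' @return A list with `summary` (per-group stats tibble), `p_value`, and
#'   `statistic` (the U statistic for the overlap group).
#' @export
score_by_annotation <- function(track, annotation, side = c("a", "b", "both")) {
  side <- match.arg(side)
  ov_a <- overlaps_any(track, annotation, q_cols = c("a_chrom", "a_start", "a_end"))
  ov <- switch(side,
    a = ov_a,
    b = overlaps_any(track, annotation, q_cols = c("b_chrom", "b_start", "b_end")),
    both = ov_a & overlaps_any(track, annotation,
                               q_cols = c("b_chrom", "b_start", "b_end"))
  )
  if (all(ov) || !any(ov)) {
    abort("One of the overlap/non-overlap groups is empty.")
  }
  grp_stats <- function(s, name) {
    q <- quantile(s, c(0.05, 0.25, 0.5, 0.75, 0.95))
    tibble(group = name, n = length(s), mean = mean(s), median = q[[3]],
           q25 = q[[2]], q75 = q[[4]], p5 = q[[1]], p95 = q[[5]])
  }
  wt <- wilcox.test(track$score[ov], track$score[!ov], alternative = "two.sided")
  list(
    summary = bind_rows(grp_stats(track$score[ov], "overlap"),
                        grp_stats(track$score[!ov], "non_overlap")),
    p_value = wt$p.value,
    statistic = unname(wt$statistic)
  )
}

#' Mean score per chromatin state
#'
#' Two-level mean: for every (state, epigenome), the mean score over regions
#' annotated with the state in that epigenome; then, per state, the
#' unweighted mean of those per-epigenome means. Epigenomes lacking a state
#' contribute no term; a state absent from all epigenomes is missing.
#'
#' @param track A score track tibble.
#' @param segmentations Segmentation track list (one entry per epigenome).
#' @param side Which side's coordinates to intersect (`"a"` or `"b"`).
#' @return A tibble `state`, `mean_score`, `n_epigenomes`.
#' @export
mean_score_per_state <- function(track, segmentations, side = c("a", "b")) {
  side <- match.arg(side)
  segs <- segmentations[map_chr(segmentations, "kind") == "segmentation"]
  if (length(segs) == 0L) abort("Need at least one segmentation.")
  cols <- if (side == "a") c("a_chrom", "a_start", "a_end") else
    c("b_chrom", "b_start", "b_end")
  states <- sort_states(unique(unlist(map(segs, "states"))))
  per_epi <- map(segs, function(t) {
    map(states, function(s) {
      ov <- overlaps_any(track, t$data |> filter(.data$state == !!s),
                         q_cols = cols)
      if (!any(ov)) return(NULL)
      tibble(epigenome = t$epigenome, state = s,
             epi_mean = mean(track$score[ov]))
    }) |> list_rbind()
  }) |> list_rbind()
  map(states, function(s) {
    x <- per_epi |> filter(.data$state == !!s)
    tibble(state = s,
           mean_score = if (nrow(x) == 0L) NA_real_ else mean(x$epi_mean),
           n_epigenomes = nrow(x))
  }) |> list_rbind()
}

#' Windowed mean score with a coverage filter
#'
#' Averages the score over the annotated bases of each window (per-base
#' expansion of the 50-bp track); windows with strictly less than
#' `min_coverage` annotated bases are excluded, so exactly-half-covered
#' windows are retained.
#'
#' @param track A score track tibble.
#' @param windows Tibble of windows (`chrom`, `start`, `end`) on the A
#'   genome; if `NULL`, non-overlapping windows of `width` tiling the
#'   track's extent are used.
#' @param width Window width used when `windows` is `NULL` (default 1000).
#' @param min_coverage Minimum annotated bases (default half the window).
#' @return Tibble of retained windows with `covered_bases` and `mean_score`.
#' @export
windowed_mean_score <- function(track, windows = NULL, width = 1000L,
                                min_coverage = NULL) {
  a_track <- tibble(chrom = track$a_chrom, start = track$a_start,
                    end = track$a_end, score = track$score)
  if (is.null(windows)) {
    windows <- a_track |>
      group_by(.data$chrom) |>
      summarise(lo = floor(min(.data$start) / width) * width,
                hi = max(.data$end), .groups = "drop")
    windows <- map(seq_len(nrow(windows)), function(i) {
      starts <- seq(windows$lo[i], windows$hi[i] - 1, by = width)
      tibble(chrom = windows$chrom[i], start = starts, end = starts + width)
    }) |> list_rbind()
  }
  min_coverage <- min_coverage %||% ((windows$end - windows$start) / 2)
  st <- window_overlap_stats(windows, a_track)
  windows |>
    mutate(covered_bases = st$bases,
           mean_score = ifelse(st$bases > 0, st$weighted / st$bases, NA_real_),
           .keep = "all") |>
    filter(.data$covered_bases >= min_coverage)
}

#' Windowed correlation between two score tracks
#'
#' Slides a window of `width` bases in `step`-base increments across the
#' extent of the two tracks' shared genome, computes each track's mean over
#' its annotated bases in the window, and correlates the means across
#' windows with at least `n` annotated bases in each track (the tracks need
#' not annotate the same bases).
#'
#' @param track_x,track_y Tibbles with `chrom`, `start`, `end`, `score`.
#' @param width Window width (default 50).
#' @param step Window step (default 10).
#' @param min_annotated Integer vector of thresholds `n` to report.
#' @return A tibble `n_min`, `pcc`, `scc`, `n_windows`.
#' @export
windowed_track_correlation <- function(track_x, track_y, width = 50L,
                                       step = 10L,
                                       min_annotated = c(1L, width %/% 2L, width)) {
  chroms <- union(unique(track_x$chrom), unique(track_y$chrom))
  windows <- map(chroms, function(ch) {
    xs <- c(track_x$start[track_x$chrom == ch], track_y$start[track_y$chrom == ch])
    xe <- c(track_x$end[track_x$chrom == ch], track_y$end[track_y$chrom == ch])
    if (length(xs) == 0L) return(NULL)
    starts <- seq(min(xs), max(xe) - 1, by = step)
    tibble(chrom = ch, start = starts, end = starts + width)
  }) |> list_rbind()
  sx <- window_overlap_stats(windows, track_x)
  sy <- window_overlap_stats(windows, track_y)
  mx <- ifelse(sx$bases > 0, sx$weighted / sx$bases, NA_real_)
  my <- ifelse(sy$bases > 0, sy$weighted / sy$bases, NA_real_)
  map(as.integer(min_annotated), function(n) {
    ok <- sx$bases >= n & sy$bases >= n
    if (sum(ok) < 3L) {
      abort(sprintf("Fewer than 3 windows qualify at n = %d.", n))
    }
    tibble(n_min = n, pcc = cor(mx[ok], my[ok]),
           scc = cor(mx[ok], my[ok], method = "spearman"),
           n_windows = sum(ok))
  }) |> list_rbind()
}
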