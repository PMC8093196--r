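#' Score every aligning region pair genome-wide
#'
#' Tiles each ungapped alignment block into 50-bp (or truncated) paired
#' windows, featurizes the windows, and scores each with the supplied model
#' (an ensemble, an ensemble pair with split-complementary routing, or any
#' object with a compatible `predict()` method). The score of a window
#' annotates all of its bases.
#'
#' @param model A `lecif_ensemble`, `lecif_ensemble_pair`, or
#'   `lecif_baseline`.
#' @param blocks Tibble of alignment blocks (after
#'   [select_best_partner()], so A intervals are non-overlapping).
#' @param tracks_a,tracks_b,schema_a,schema_b Annotation tracks and schemas.
#' @param width Window width (default 50).
#' @return A `lecif_score_track` tibble: both species' coordinates,
#'   `block_id`, `score`.
#' @export
score_aligning_genome <- function(model, blocks, tracks_a, tracks_b,
                                  schema_a, schema_b, width = 50L) {
  chroms_a <- unique(unlist(map(tracks_a, function(t) unique(t$data$chrom))))
  chroms_b <- unique(unlist(map(tracks_b, function(t) unique(t$data$chrom))))
  bad <- !(blocks$a_chrom %in% chroms_a) | !(blocks$b_chrom %in% chroms_b)
  if (any(bad)) {
    abort(sprintf("No annotation features for block(s): %s",
                  paste(head(blocks$block_id[bad], 10), collapse = ", ")))
  }
  pairs <- tile_pairs(blocks, width = width)
  features <- featurize_pairs(pairs, tracks_a, tracks_b, schema_a, schema_b)
  scores <- predict(model, features)
  track <- features$pairs |>
    mutate(score = as.numeric(scores)) |>
    select(all_of(c("a_chrom", "a_start", "a_end", "b_chrom", "b_start",
                    "b_end", "b_rev", "block_id", "score")))
  structure(track, class = c("lecif_score_track", class(track)))
}

#' Region-neighborhood score: max over nearby B windows
#'
#' For each pair, scores the A region against every 50-bp B window placed at
#' 50-bp steps from the first base of the aligning B region in both
#' directions, within a neighborhood of `W` bases centered on the aligning
#' region, and returns the maximum. `W = 0` reproduces the plain score
#' exactly. Windows extending past a chromosome end are dropped.
#'
#' @param pairs Tibble of aligning region pairs.
#' @param model Model with a `predict()` method.
#' @param tracks_a,tracks_b,schema_a,schema_b Tracks and schemas.
#' @param W Neighborhood width in bases (total extent, centered).
#' @param b_sizes Named vector of B chromosome sizes (for end truncation).
#' @param step Window step (default 50, the tiling convention).
#' @return Numeric vector of neighborhood-max scores, one per pair.
#' @export
neighborhood_max_score <- function(pairs, model, tracks_a, tracks_b,
                                   schema_a, schema_b, W = 0L,
                                   b_sizes = NULL, step = 50L) {
  stopifnot(W >= 0L)
  k_max <- floor((W / 2) / step)
  offsets <- seq(-k_max, k_max) * step
  n <- nrow(pairs)
  if (!"b_rev" %in% names(pairs)) pairs$b_rev <- FALSE
  cand <- map(offsets, function(off) {
    p <- pairs
    p$b_start <- p$b_start + off
    p$b_end <- p$b_end + off
    p$offset <- off
    p$orig <- seq_len(n)
    p
  }) |> list_rbind()
  if (!is.null(b_sizes)) {
    lim <- unname(b_sizes[cand$b_chrom])
    cand <- cand |> filter(.data$b_start >= 0, .data$b_end <= lim)
  } else {
    cand <- cand |> filter(.data$b_start >= 0)
  }
  features <- featurize_pairs(cand, tracks_a, tracks_b, schema_a, schema_b)
  s <- predict(model, features)
  out <- rep(NA_real_, n)
  agg <- tapply(s, cand$orig, max)
  out[as.integer(names(agg))] <- as.numeric(agg)
  out
}

#' Write a score track to bedGraph and paired TSV
#'
#' Emits a bedGraph on the A genome and a TSV carrying both species'
#' coordinates and the score, both sorted by A coordinate, with scores at 6
#' decimal places. Adjacent equal-score windows are not merged, preserving
#' the window resolution.
#'
#' @param track A `lecif_score_track`.
#' @param out_prefix Path prefix; writes `<prefix>.bedGraph` and
#'   `<prefix>.tsv`.
#' @return Invisibly, the paths written.
#' @export
write_score_outputs <- function(track, out_prefix) {
  if (any(!is.finite(track$score))) {
    abort("Score track contains non-finite scores.")
  }
  track <- track |> arrange(.data$a_chrom, .data$a_start)
  bg <- paste0(out_prefix, ".bedGraph")
  writeLines(sprintf("%s\t%d\t%d\t%.6f", track$a_chrom,
                     as.integer(track$a_start), as.integer(track$a_end),
                     track$score), bg)
  tsv <- paste0(out_prefix, ".tsv")
  readr::write_tsv(
    track |>
      mutate(score = sprintf("%.6f", .data$score)) |>
      select(all_of(c("a_chrom", "a_start", "a_end", "b_chrom", "b_start",
                      "b_end", "score"))),
    tsv
  )
  invisible(c(bg, tsv))
}

#' Read a score track written by [write_score_outputs()]
#'
#' @param path Path to the paired `.tsv` output.
#' @return A `lecif_score_track` tibble.
#' @export
read_score_track <- function(path) {
  x <- readr::read_tsv(path, col_types = "cnncnnn", show_col_types = FALSE)
  structure(x, class = c("lecif_score_track", class(x)))
}
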