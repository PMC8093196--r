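#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an ensemble: one row per member
#'
#' @param x A `lecif_ensemble`.
#' @param ... Unused.
#' @return Tibble with `member`, `seed`, `best_epoch`, `epochs_run`,
#'   `val_auroc`.
#' @export
tidy.lecif_ensemble <- function(x, ...) {
  map(seq_along(x$members), function(i) {
    m <- x$members[[i]]
    tibble(member = i, seed = m$seed, best_epoch = m$best_epoch,
           epochs_run = max(m$history$epoch), val_auroc = m$val_auroc)
  }) |> list_rbind()
}

#' One-row ensemble summary
#'
#' @param x A `lecif_ensemble`.
#' @param ... Unused.
#' @export
glance.lecif_ensemble <- function(x, ...) {
  tibble(
    k = length(x$members),
    mean_val_auroc = mean(map_dbl(x$members, "val_auroc")),
    sd_val_auroc = sd(map_dbl(x$members, "val_auroc")),
    w_neg = x$cfg$w_neg,
    n_pos = x$cfg$n_pos, n_neg = x$cfg$n_neg
  )
}

#' Tidy a single network's training history
#'
#' @param x A `lecif_network`.
#' @param ... Unused.
#' @return The per-epoch history tibble (`epoch`, `train_loss`,
#'   `val_auroc`).
#' @export
tidy.lecif_network <- function(x, ...) x$history

#' @export
glance.lecif_network <- function(x, ...) {
  tibble(val_auroc = x$val_auroc, best_epoch = x$best_epoch,
         epochs_run = max(x$history$epoch), d_a = x$d_a, d_b = x$d_b)
}

#' ROC and precision-recall curves for scored examples
#'
#' @param pos_scores,neg_scores Scores per class.
#' @param w_neg Weight per negative example (enters precision).
#' @return A `lecif_curves` tibble with columns `curve` (`roc`/`pr`), `x`,
#'   `y`.
#' @export
roc_pr_curves <- function(pos_scores, neg_scores, w_neg = 1) {
  scores <- c(pos_scores, neg_scores)
  is_pos <- c(rep(TRUE, length(pos_scores)), rep(FALSE, length(neg_scores)))
  ord <- order(scores, decreasing = TRUE)
  scores <- scores[ord]; is_pos <- is_pos[ord]
  grp <- cumsum(c(TRUE, scores[-1] != scores[-length(scores)]))
  tp <- cumsum(as.numeric(tapply(is_pos, grp, sum)))
  fp <- cumsum(as.numeric(tapply(!is_pos, grp, sum)))
  roc <- tibble(curve = "roc", x = c(0, fp / max(fp)), y = c(0, tp / max(tp)))
  pr <- tibble(curve = "pr", x = tp / max(tp),
               y = tp / (tp + w_neg * fp))
  out <- bind_rows(roc, pr)
  class(out) <- c("lecif_curves", class(out))
  out
}

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_step
#'   geom_col labs theme_minimal facet_wrap geom_hline
#' @export
ggplot2::autoplot

#' Plot ROC / precision-recall curves
#'
#' @param object A `lecif_curves` tibble from [roc_pr_curves()].
#' @param ... Unused.
#' @export
autoplot.lecif_curves <- function(object, ...) {
  labels <- c(roc = "ROC", pr = "Precision-recall")
  ggplot(object, aes(x = .data$x, y = .data$y)) +
    geom_line() +
    facet_wrap(~factor(labels[.data$curve], unname(labels)), scales = "free") +
    labs(x = "False-positive rate / recall", y = "True-positive rate / precision") +
    theme_minimal()
}

#' Plot variant enrichment across score bins
#'
#' @param object A `lecif_enrichment` from [variant_enrichment()].
#' @param ... Unused.
#' @export
autoplot.lecif_enrichment <- function(object, ...) {
  ggplot(object, aes(x = .data$bin, y = .data$log2_fold)) +
    geom_hline(yintercept = 0, linetype = "dashed", colour = "grey50") +
    geom_line() + geom_point() +
    labs(x = "Score bin (low to high)", y = "log2 fold enrichment") +
    theme_minimal()
}

#' Plot a score track along one chromosome
#'
#' @param object A `lecif_score_track`.
#' @param chrom Chromosome to display (default: first in the track).
#' @param ... Unused.
#' @export
autoplot.lecif_score_track <- function(object, chrom = NULL, ...) {
  chrom <- chrom %||% object$a_chrom[1]
  d <- object |> filter(.data$a_chrom == !!chrom)
  ggplot(d, aes(x = .data$a_start, y = .data$score)) +
    geom_step() +
    labs(x = sprintf("%s position (bp)", chrom), y = "Conservation score") +
    theme_minimal()
}
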