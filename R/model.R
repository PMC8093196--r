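#' Random hyperparameter search
#'
#' Draws `n_candidates` hyperparameter combinations from the given ranges,
#' trains each candidate on the same fixed training subset, and returns the
#' candidate with the highest validation AUROC. The per-candidate results
#' are attached as attribute `"search"`.
#'
#' @param train,val `lecif_features` objects; `train` is the fixed subset
#'   shared by all candidates.
#' @param space Named list of ranges: `branch_layers` and `final_layers`
#'   (integer candidates), `width` (min/max hidden width), `batch_size`
#'   (candidates), `learning_rate` (min/max, sampled log-uniformly),
#'   `dropout` (min/max).
#' @param n_candidates Number of random candidates.
#' @param cfg A [training_config()].
#' @param seed Integer seed for the candidate draw.
#' @return The winning [hyperparameters()] object.
#' @export
random_hyperparameter_search <- function(train, val,
                                         space = default_search_space(),
                                         n_candidates = cfg$n_candidates,
                                         cfg = training_config(),
                                         seed = cfg$seed) {
  if (length(space) == 0L) abort("Empty hyperparameter space.")
  stopifnot(n_candidates >= 1L)
  seed <- check_seed(seed)
  candidates <- withr::with_seed(seed, {
    map(seq_len(n_candidates), function(i) {
      n_br <- sample(space$branch_layers, 1L)
      n_fin <- sample(space$final_layers, 1L)
      hyperparameters(
        branch_widths_a = sample(space$width[1]:space$width[2], n_br, replace = TRUE),
        branch_widths_b = sample(space$width[1]:space$width[2], n_br, replace = TRUE),
        final_widths = sample(space$width[1]:space$width[2], n_fin, replace = TRUE),
        batch_size = sample(space$batch_size, 1L),
        learning_rate = exp(runif(1, log(space$learning_rate[1]),
                                  log(space$learning_rate[2]))),
        dropout = runif(1, space$dropout[1], space$dropout[2])
      )
    })
  })
  results <- map(seq_along(candidates), function(i) {
    net <- train_network(train, val, candidates[[i]], cfg, seed = seed + i)
    tibble(candidate = i, val_auroc = net$val_auroc)
  }) |> list_rbind()
  best <- results$candidate[which.max(results$val_auroc)]
  structure(candidates[[best]], search = results)
}

#' @rdname random_hyperparameter_search
#' @export
default_search_space <- function() {
  list(branch_layers = 1:2, final_layers = 1:2, width = c(8L, 48L),
       batch_size = c(64L, 128L, 256L), learning_rate = c(1e-4, 1e-2),
       dropout = c(0, 0.3))
}

#' Train an ensemble of two-branch networks
#'
#' Trains `cfg$k` networks, each on its own subset of `cfg$n_pos` positive
#' and `cfg$n_neg` negative examples sampled without replacement from the
#' pool (member seeds derived from `cfg$seed`). The ensemble prediction is
#' the arithmetic mean of the member outputs.
#'
#' @param pool `lecif_features` with all labeled training pairs.
#' @param val `lecif_features` validation set for early stopping.
#' @param hp A [hyperparameters()] object shared by all members.
#' @param cfg A [training_config()].
#' @return A `lecif_ensemble` object.
#' @export
train_ensemble <- function(pool, val, hp = hyperparameters(),
                           cfg = training_config()) {
  y <- feature_labels(pool)
  pos_idx <- which(y == 1)
  neg_idx <- which(y == 0)
  if (length(pos_idx) < cfg$n_pos || length(neg_idx) < cfg$n_neg) {
    abort(sprintf(
      "Training pool too small (%d pos, %d neg) for per-member sizes %g/%g; lower n_pos/n_neg.",
      length(pos_idx), length(neg_idx), cfg$n_pos, cfg$n_neg))
  }
  members <- map(seq_len(cfg$k), function(i) {
    member_seed <- cfg$seed + i
    idx <- withr::with_seed(member_seed, {
      c(sample(pos_idx, cfg$n_pos), sample(neg_idx, cfg$n_neg))
    })
    train_network(subset_features(pool, idx), val, hp, cfg,
                  seed = member_seed)
  })
  structure(
    list(members = members, hp = hp, cfg = cfg,
         schema_a = pool$schema_a, schema_b = pool$schema_b,
         train_chroms = attr(pool, "train_chroms")),
    class = "lecif_ensemble"
  )
}

#' @export
print.lecif_ensemble <- function(x, ...) {
  cat(sprintf("<lecif_ensemble> %d members, mean validation AUROC %.3f\n",
              length(x$members),
              mean(map_dbl(x$members, "val_auroc"))))
  invisible(x)
}

#' Predict conservation scores with an ensemble
#'
#' @param object A `lecif_ensemble`.
#' @param features A `lecif_features` object.
#' @param ... Unused.
#' @return Numeric scores in `[0, 1]`: the mean of the member predictions.
#' @export
predict.lecif_ensemble <- function(object, features, ...) {
  preds <- map(object$members, predict, features = features)
  Reduce(`+`, preds) / length(preds)
}

#' Pair two ensembles trained on complementary chromosome splits
#'
#' For genome-wide prediction, every pair is scored by the ensemble that was
#' *not* trained on its chromosomes, so no region is scored by a model that
#' saw it during training.
#'
#' @param ... Named `lecif_ensemble` objects.
#' @param train_chroms List (same names) of lists with elements `a`, `b`:
#'   the chromosome sets each ensemble was trained on.
#' @return A `lecif_ensemble_pair` object.
#' @export
ensemble_pair <- function(..., train_chroms) {
  ensembles <- list(...)
  stopifnot(length(ensembles) >= 2L,
            identical(sort(names(ensembles)), sort(names(train_chroms))))
  structure(list(ensembles = ensembles, train_chroms = train_chroms),
            class = "lecif_ensemble_pair")
}

#' @export
predict.lecif_ensemble_pair <- function(object, features, ...) {
  pairs <- features$pairs
  scores <- rep(NA_real_, nrow(pairs))
  covered <- rep(FALSE, nrow(pairs))
  for (name in names(object$ensembles)) {
    tc <- object$train_chroms[[name]]
    eligible <- !covered &
      !(pairs$a_chrom %in% tc$a) & !(pairs$b_chrom %in% tc$b)
    if (any(eligible)) {
      scores[eligible] <- predict(object$ensembles[[name]],
                                  subset_features(features, eligible))
      covered[eligible] <- TRUE
    }
  }
  if (!all(covered)) {
    abort(sprintf(
      "%d pair(s) have chromosomes covered by no ensemble in the pair.",
      sum(!covered)))
  }
  scores
}

#' Train a baseline classifier
#'
#' Comparison baselines from the evaluation protocol, behind one predict contract:
#' * `"logistic"` — ridge-penalized logistic regression on the concatenated
#'   (A, B) feature vectors, `w_neg`-weighted, with a grid search over the
#'   penalty selected by validation AUROC.
#' * `"tree_ensemble"` — a random forest on concatenated vectors with
#'   `w_neg` case weights and a small random search over `mtry` and node
#'   size.
#' * `"human_only"` — a fully connected network on species-A features only;
#'   labels must come from the alignment (region aligns / does not align),
#'   supplied as a single-species features object (`b` absent), not as pair
#'   labels.
#'
#' @param kind One of `"logistic"`, `"tree_ensemble"`, `"human_only"`.
#' @param train,val `lecif_features` objects. For `"human_only"`, objects
#'   whose `b` element is `NULL`.
#' @param cfg A [training_config()].
#' @param hp Optional [hyperparameters()] for `"human_only"`.
#' @param seed Integer seed.
#' @return A `lecif_baseline` object with a `predict()` method.
#' @export
train_baseline <- function(kind = c("logistic", "tree_ensemble", "human_only"),
                           train, val = NULL, cfg = training_config(),
                           hp = NULL, seed = cfg$seed) {
  kind <- match.arg(kind)
  seed <- check_seed(seed)
  y <- feature_labels(train)
  w <- ifelse(y == 1, 1, cfg$w_neg)
  if (kind == "human_only") {
    if (!is.null(train$b)) {
      abort("human_only baseline takes single-species features (b must be NULL), with alignment-derived labels.")
    }
    hp <- hp %||% hyperparameters(branch_widths_a = 24L,
                                  branch_widths_b = NULL, final_widths = 24L)
    hp$branch_widths_b <- NULL
    net <- train_network(train, val, hp, cfg, seed = seed)
    return(structure(list(kind = kind, model = net), class = "lecif_baseline"))
  }
  X <- cbind(train$a, train$b)
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  if (kind == "logistic") {
    lambda_grid <- 10^seq(1, -6, length.out = 15)
    fit <- glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                          lambda = lambda_grid, weights = w,
                          standardize = FALSE)
    lambda <- if (!is.null(val)) {
      y_val <- feature_labels(val)
      p_val <- predict(fit, cbind(val$a, val$b), type = "response")
      aucs <- apply(p_val, 2, function(p) {
        fast_auc(p[y_val == 1], p[y_val == 0])
      })
      fit$lambda[which.max(aucs)]
    } else {
      min(fit$lambda)
    }
    model <- list(fit = fit, lambda = lambda)
  } else {
    grids <- withr::with_seed(seed, {
      map(seq_len(max(1L, min(cfg$n_candidates, 5L))), function(i) {
        list(mtry = sample(seq_len(max(1L, floor(sqrt(ncol(X))) * 2L)), 1L),
             min.node.size = sample(c(1L, 5L, 10L), 1L))
      })
    })
    fits <- map(seq_along(grids), function(i) {
      ranger::ranger(
        x = X, y = factor(y, levels = c(0, 1)), probability = TRUE,
        num.trees = 200, mtry = min(grids[[i]]$mtry, ncol(X)),
        min.node.size = grids[[i]]$min.node.size,
        case.weights = w, seed = seed + i, num.threads = 1
      )
    })
    best <- if (!is.null(val)) {
      y_val <- feature_labels(val)
      Xv <- cbind(val$a, val$b)
      colnames(Xv) <- paste0("f", seq_len(ncol(Xv)))
      which.max(map_dbl(fits, function(f) {
        p <- predict(f, data = Xv, num.threads = 1)$predictions[, "1"]
        fast_auc(p[y_val == 1], p[y_val == 0])
      }))
    } else 1L
    model <- list(fit = fits[[best]])
  }
  structure(list(kind = kind, model = model), class = "lecif_baseline")
}

#' @export
predict.lecif_baseline <- function(object, features, ...) {
  if (object$kind == "human_only") {
    return(predict(object$model, features))
  }
  X <- cbind(features$a, features$b)
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  if (object$kind == "logistic") {
    as.numeric(predict(object$model$fit, X, s = object$model$lambda,
                       type = "response"))
  } else {
    predict(object$model$fit, data = X, num.threads = 1)$predictions[, "1"]
  }
}

#' Build a single-species dataset for the human-only baseline
#'
#' Positives are species-A regions that align to species B (the A side of
#' the positive pairs); negatives are random species-A regions that do not
#' overlap any aligning region.
#'
#' @param positives Tibble of aligning region pairs.
#' @param a_genome Tibble with `chrom`, `size` for species A.
#' @param tracks_a,schema_a Annotation tracks and schema for species A.
#' @param seed Integer seed.
#' @param width Negative region width.
#' @return A `lecif_features` object with `b = NULL`.
#' @export
human_only_dataset <- function(positives, a_genome, tracks_a, schema_a,
                               seed, width = 50L) {
  seed <- check_seed(seed)
  n <- nrow(positives)
  neg <- withr::with_seed(seed, {
    out <- list(); got <- 0L
    while (got < n) {
      k <- (n - got) * 2L
      ci <- sample.int(nrow(a_genome), k, replace = TRUE,
                       prob = a_genome$size / sum(a_genome$size))
      start <- floor(runif(k, 0, a_genome$size[ci] - width))
      cand <- tibble(chrom = a_genome$chrom[ci], start = start,
                     end = start + width)
      ok <- !overlaps_any(cand, positives,
                          s_cols = c("a_chrom", "a_start", "a_end"))
      cand <- cand[ok, ]
      out[[length(out) + 1L]] <- cand
      got <- got + nrow(cand)
    }
    bind_rows(out)[seq_len(n), ]
  })
  regions <- bind_rows(
    tibble(pair_id = sprintf("ha%06d", seq_len(n)),
           a_chrom = positives$a_chrom, a_start = positives$a_start,
           a_end = positives$a_end, label = "positive"),
    tibble(pair_id = sprintf("hn%06d", seq_len(n)),
           a_chrom = neg$chrom, a_start = neg$start, a_end = neg$end,
           label = "negative")
  )
  X_a <- featurize_positions(regions$a_chrom, regions$a_start, tracks_a,
                             schema_a)
  structure(list(pairs = regions, a = X_a, b = NULL,
                 schema_a = schema_a, schema_b = NULL),
            class = "lecif_features")
}
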