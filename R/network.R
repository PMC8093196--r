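#' Network hyperparameters
#'
#' Architecture and optimization settings for one two-branch network: the
#' number and width of hidden layers in each species branch and in the final
#' combining subnetwork, the minibatch size, learning rate and dropout rate.
#'
#' @param branch_widths_a,branch_widths_b Integer vectors of hidden-layer
#'   widths for the species A and B branches (one entry per layer).
#' @param final_widths Integer vector of hidden-layer widths for the final
#'   subnetwork that combines the two branch outputs.
#' @param batch_size Minibatch size.
#' @param learning_rate Adam learning rate.
#' @param dropout Dropout rate on hidden activations, in `[0, 1)`.
#' @return A `lecif_hyperparameters` object.
#' @export
hyperparameters <- function(branch_widths_a = 24L, branch_widths_b = 24L,
                            final_widths = 24L, batch_size = 128L,
                            learning_rate = 3e-3, dropout = 0) {
  stopifnot(all(branch_widths_a >= 1L), all(final_widths >= 1L),
            is.null(branch_widths_b) || all(branch_widths_b >= 1L))
  if (dropout < 0 || dropout >= 1) abort("dropout must be in [0, 1).")
  if (learning_rate <= 0) abort("learning_rate must be > 0.")
  if (batch_size < 1) abort("batch_size must be >= 1.")
  structure(
    list(branch_widths_a = as.integer(branch_widths_a),
         branch_widths_b = if (!is.null(branch_widths_b)) as.integer(branch_widths_b),
         final_widths = as.integer(final_widths),
         batch_size = as.integer(batch_size),
         learning_rate = learning_rate, dropout = dropout),
    class = "lecif_hyperparameters"
  )
}

#' Training configuration
#'
#' Defaults follow the reference protocol: negatives weighted 50 times more
#' than positives in the loss, early stopping when validation AUROC has not
#' improved for 3 epochs, at most 100 epochs and 24 h per network, an
#' ensemble of 100 members each trained on 10^6 positive and 10^6 negative
#' examples sampled from the pool. The `"desk"` profile scales the ensemble
#' and sample sizes down for laptop-scale runs.
#'
#' @param w_neg Loss weight for negative examples.
#' @param patience Early-stopping patience in epochs.
#' @param max_epochs Maximum training epochs per network.
#' @param max_hours Wall-time cap per network, in hours.
#' @param k Ensemble size.
#' @param n_pos,n_neg Per-member sample sizes drawn from the training pool.
#' @param n_candidates Candidates for random hyperparameter search.
#' @param seed Integer seed for member subsampling and initialization.
#' @param profile `"reference"` (the defaults above) or `"desk"`
#'   (k = 10, n_pos = n_neg = 2e4, n_candidates = 10, max_epochs = 30).
#' @return A `lecif_training_config` object.
#' @export
training_config <- function(w_neg = 50, patience = 3L, max_epochs = 100L,
                            max_hours = 24, k = 100L, n_pos = 1e6,
                            n_neg = 1e6, n_candidates = 100L, seed = 1L,
                            profile = c("reference", "desk")) {
  profile <- match.arg(profile)
  if (profile == "desk") {
    if (missing(k)) k <- 10L
    if (missing(n_pos)) n_pos <- 2e4
    if (missing(n_neg)) n_neg <- 2e4
    if (missing(n_candidates)) n_candidates <- 10L
    if (missing(max_epochs)) max_epochs <- 30L
  }
  stopifnot(w_neg > 0, patience >= 1L, k >= 1L)
  structure(
    list(w_neg = w_neg, patience = as.integer(patience),
         max_epochs = as.integer(max_epochs), max_hours = max_hours,
         k = as.integer(k), n_pos = n_pos, n_neg = n_neg,
         n_candidates = as.integer(n_candidates),
         seed = check_seed(seed), profile = profile),
    class = "lecif_training_config"
  )
}

#' Class-weighted binary cross-entropy
#'
#' Per-example binary cross-entropy with weight 1 for positives and `w_neg`
#' for negatives. Predictions exactly 0 or 1 are clamped to
#' `[eps, 1 - eps]` before the logarithm.
#'
#' @param prediction Predicted probabilities.
#' @param label 0/1 labels.
#' @param w_neg Weight applied to negative examples.
#' @param eps Clamp width for predictions at the boundary.
#' @return Per-example non-negative losses.
#' @export
weighted_loss <- function(prediction, label, w_neg = 50, eps = 1e-12) {
  p <- pmin(1 - eps, pmax(eps, prediction))
  w <- ifelse(label == 1, 1, w_neg)
  -w * (label * log(p) + (1 - label) * log(1 - p))
}

relu <- function(x) x * (x > 0)

# Unweighted AUROC via average ranks (ties count 1/2).
fast_auc <- function(pos, neg) {
  r <- rank(c(pos, neg), ties.method = "average")
  n_pos <- as.numeric(length(pos)); n_neg <- as.numeric(length(neg))
  (sum(r[seq_len(n_pos)]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# He-initialized dense layer stack for the given input dim and widths; the
# final subnetwork additionally gets a linear output unit.
init_layers <- function(d_in, widths, out_unit = FALSE) {
  dims <- c(d_in, widths, if (out_unit) 1L)
  map(seq_len(length(dims) - 1L), function(i) {
    list(W = matrix(rnorm(dims[i] * dims[i + 1L], sd = sqrt(2 / dims[i])),
                    dims[i], dims[i + 1L]),
         b = rep(0, dims[i + 1L]))
  })
}

net_init <- function(d_a, d_b, hp) {
  a <- init_layers(d_a, hp$branch_widths_a)
  b <- if (!is.null(d_b) && d_b > 0L) init_layers(d_b, hp$branch_widths_b)
  d_comb <- tail(hp$branch_widths_a, 1) +
    (if (!is.null(b)) tail(hp$branch_widths_b, 1) else 0L)
  f <- init_layers(d_comb, hp$final_widths, out_unit = TRUE)
  list(a = a, b = b, f = f)
}

# Forward pass through one stack. Hidden layers are ReLU; the last layer is
# linear when `linear_out`. Inverted dropout on hidden activations when
# training.
stack_forward <- function(layers, X, linear_out, dropout = 0, training = FALSE) {
  n_layer <- length(layers)
  Hs <- vector("list", n_layer + 1L); Hs[[1]] <- X
  Zs <- vector("list", n_layer)
  masks <- vector("list", n_layer)
  H <- X
  for (i in seq_len(n_layer)) {
    Z <- H %*% layers[[i]]$W
    Z <- sweep(Z, 2, layers[[i]]$b, "+")
    Zs[[i]] <- Z
    hidden <- !(linear_out && i == n_layer)
    H <- if (hidden) relu(Z) else Z
    if (hidden && training && dropout > 0) {
      m <- matrix(rbinom(length(H), 1, 1 - dropout), nrow(H)) / (1 - dropout)
      H <- H * m
      masks[[i]] <- m
    }
    Hs[[i + 1L]] <- H
  }
  list(out = H, Hs = Hs, Zs = Zs, masks = masks)
}

# Gradient of a stack given dOut (gradient w.r.t. its output activations).
# Returns per-layer grads and the gradient w.r.t. the stack input.
stack_backward <- function(layers, cache, dOut, linear_out) {
  n_layer <- length(layers)
  grads <- vector("list", n_layer)
  dH <- dOut
  for (i in rev(seq_len(n_layer))) {
    hidden <- !(linear_out && i == n_layer)
    dZ <- dH
    if (hidden) {
      if (!is.null(cache$masks[[i]])) dZ <- dZ * cache$masks[[i]]
      dZ <- dZ * (cache$Zs[[i]] > 0)
    }
    grads[[i]] <- list(W = crossprod(cache$Hs[[i]], dZ), b = colSums(dZ))
    dH <- dZ %*% t(layers[[i]]$W)
  }
  list(grads = grads, dIn = dH)
}

net_forward <- function(params, X_a, X_b, dropout = 0, training = FALSE) {
  fa <- stack_forward(params$a, X_a, linear_out = FALSE, dropout, training)
  fb <- if (!is.null(params$b)) {
    stack_forward(params$b, X_b, linear_out = FALSE, dropout, training)
  }
  comb <- if (!is.null(fb)) cbind(fa$out, fb$out) else fa$out
  ff <- stack_forward(params$f, comb, linear_out = TRUE, dropout, training)
  p <- 1 / (1 + exp(-ff$out))
  list(p = p, fa = fa, fb = fb, ff = ff)
}

net_gradients <- function(params, fwd, y, w) {
  n <- length(y)
  # d(mean weighted BCE)/d(logit)
  dZ <- (fwd$p - y) * w / sum(w)
  bf <- stack_backward(params$f, fwd$ff, dZ, linear_out = TRUE)
  d_a_out <- ncol(fwd$fa$out)
  dCa <- bf$dIn[, seq_len(d_a_out), drop = FALSE]
  ba <- stack_backward(params$a, fwd$fa, dCa, linear_out = FALSE)
  bb <- NULL
  if (!is.null(fwd$fb)) {
    dCb <- bf$dIn[, -seq_len(d_a_out), drop = FALSE]
    bb <- stack_backward(params$b, fwd$fb, dCb, linear_out = FALSE)
  }
  list(a = ba$grads, b = if (!is.null(bb)) bb$grads, f = bf$grads)
}

adam_init <- function(params) {
  zero_like <- function(layers) map(layers, function(l) {
    list(W = l$W * 0, b = l$b * 0)
  })
  list(m = map(params, function(x) if (!is.null(x)) zero_like(x)),
       v = map(params, function(x) if (!is.null(x)) zero_like(x)),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  corr1 <- 1 - beta1^state$t
  corr2 <- 1 - beta2^state$t
  for (part in names(params)) {
    if (is.null(params[[part]])) next
    for (i in seq_along(params[[part]])) {
      for (slot in c("W", "b")) {
        g <- grads[[part]][[i]][[slot]]
        m <- beta1 * state$m[[part]][[i]][[slot]] + (1 - beta1) * g
        v <- beta2 * state$v[[part]][[i]][[slot]] + (1 - beta2) * g^2
        state$m[[part]][[i]][[slot]] <- m
        state$v[[part]][[i]][[slot]] <- v
        params[[part]][[i]][[slot]] <- params[[part]][[i]][[slot]] -
          lr * (m / corr1) / (sqrt(v / corr2) + eps)
      }
    }
  }
  list(params = params, state = state)
}

#' Train a single two-branch network
#'
#' Minimizes class-weighted binary cross-entropy with Adam. After each epoch
#' the unweighted AUROC on the validation set is computed; training stops
#' when it has not improved for `cfg$patience` epochs, at `cfg$max_epochs`,
#' or at the wall-time cap, and the weights from the best-validation-AUROC
#' epoch are returned.
#'
#' @param train,val `lecif_features` objects with labeled pairs.
#' @param hp A [hyperparameters()] object.
#' @param cfg A [training_config()] object.
#' @param seed Integer seed (initialization and minibatch order).
#' @return A `lecif_network` object.
#' @export
train_network <- function(train, val, hp = hyperparameters(),
                          cfg = training_config(), seed = cfg$seed) {
  seed <- check_seed(seed)
  y <- feature_labels(train)
  y_val <- feature_labels(val)
  if (length(y) == 0L || length(y_val) == 0L) {
    abort("Training and validation sets must be non-empty.")
  }
  if (length(unique(y_val)) < 2L) {
    abort("Validation set has a single class; AUROC is undefined.")
  }
  w <- ifelse(y == 1, 1, cfg$w_neg)
  d_b <- if (!is.null(hp$branch_widths_b) && !is.null(train$b) &&
             ncol(train$b) > 0L) ncol(train$b) else 0L
  t0 <- Sys.time()
  fit <- withr::with_seed(seed, {
    params <- net_init(ncol(train$a), d_b, hp)
    state <- adam_init(params)
    best <- list(auroc = -Inf, params = params, epoch = 0L)
    history <- list()
    n <- length(y)
    bs <- min(hp$batch_size, n)
    stall <- 0L
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample.int(n)
      losses <- numeric(0)
      for (start in seq(1L, n, by = bs)) {
        idx <- ord[start:min(start + bs - 1L, n)]
        Xa <- train$a[idx, , drop = FALSE]
        Xb <- if (d_b > 0L) train$b[idx, , drop = FALSE]
        fwd <- net_forward(params, Xa, Xb, hp$dropout, training = TRUE)
        grads <- net_gradients(params, fwd, y[idx], w[idx])
        upd <- adam_step(params, grads, state, hp$learning_rate)
        params <- upd$params; state <- upd$state
        losses <- c(losses, mean(weighted_loss(fwd$p, y[idx], cfg$w_neg)))
      }
      p_val <- net_forward(params, val$a,
                           if (d_b > 0L) val$b, training = FALSE)$p
      auroc <- fast_auc(p_val[y_val == 1], p_val[y_val == 0])
      history[[epoch]] <- tibble(epoch = epoch,
                                 train_loss = mean(losses),
                                 val_auroc = auroc)
      if (auroc > best$auroc) {
        best <- list(auroc = auroc, params = params, epoch = epoch)
        stall <- 0L
      } else {
        stall <- stall + 1L
      }
      if (stall >= cfg$patience) break
      if (difftime(Sys.time(), t0, units = "hours") > cfg$max_hours) break
    }
    list(best = best, history = list_rbind(history))
  })
  structure(
    list(params = fit$best$params, hp = hp, w_neg = cfg$w_neg,
         val_auroc = fit$best$auroc, best_epoch = fit$best$epoch,
         history = fit$history, seed = seed,
         d_a = ncol(train$a), d_b = d_b),
    class = "lecif_network"
  )
}

#' @export
print.lecif_network <- function(x, ...) {
  cat(sprintf(
    "<lecif_network> %d+%d inputs, best validation AUROC %.3f (epoch %d of %d run)\n",
    x$d_a, x$d_b, x$val_auroc, x$best_epoch, max(x$history$epoch)))
  invisible(x)
}

#' Predict with a single network
#'
#' @param object A `lecif_network`.
#' @param features A `lecif_features` object.
#' @param ... Unused.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
predict.lecif_network <- function(object, features, ...) {
  Xb <- if (object$d_b > 0L) features$b
  as.numeric(net_forward(object$params, features$a, Xb, training = FALSE)$p)
}
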