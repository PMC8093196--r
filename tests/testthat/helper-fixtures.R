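# Shared fixtures and independent oracles. Simulated datasets are cached per
# configuration for the duration of the test run.

.fixture_cache <- new.env(parent = emptyenv())

sim_fixture <- function(rho = 0.9, seed = 3, chrom_len = 4e5, n_records = 1000L,
                        n_chrom = 4L, ...) {
  key <- paste(rho, seed, chrom_len, n_records, n_chrom, ...)
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  dir <- file.path(tempdir(), paste0("fx_", gsub("[^0-9a-z]", "_", key)))
  cfg <- lecif_sim_config(n_chrom = n_chrom, chrom_len = chrom_len,
                          n_records = n_records, rho = rho, seed = seed, ...)
  simulate_dataset(cfg, dir)
  out <- list(dir = dir, cfg = cfg)
  .fixture_cache[[key]] <- out
  out
}

# Fixture -> labeled splits -> featurized train/validation/test, cached.
std_pipeline <- function(rho = 0.9, seed = 3, chrom_len = 4e5,
                         n_records = 1000L) {
  key <- paste("pipe", rho, seed, chrom_len, n_records)
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  fx <- sim_fixture(rho, seed, chrom_len, n_records)
  f <- load_fixture(fx$dir)
  blocks <- select_best_partner(f$blocks)
  positives <- tile_pairs(blocks)
  scheme <- split_scheme(paste0("chr", 1:4))
  labeled <- build_labeled_splits(positives, scheme, seed = seed + 100)
  feats <- featurize_pairs(labeled, f$tracks_a, f$tracks_b,
                           f$schema_a, f$schema_b)
  idx <- split(seq_len(nrow(labeled)), labeled$role)
  out <- list(
    fixture = fx, data = f, blocks = blocks, positives = positives,
    scheme = scheme, labeled = labeled, features = feats,
    train = subset_features(feats, idx$train),
    validation = subset_features(feats, idx$validation),
    test = subset_features(feats, idx$test)
  )
  .fixture_cache[[key]] <- out
  out
}

# A features object built directly from matrices, for model tests that do
# not need genomic plumbing.
make_features <- function(a, b, labels) {
  stopifnot(nrow(a) == length(labels))
  structure(
    list(
      pairs = tibble::tibble(
        pair_id = sprintf("x%05d", seq_along(labels)),
        a_chrom = "chr1", a_start = seq_along(labels) * 50,
        a_end = seq_along(labels) * 50 + 50,
        b_chrom = "chr1", b_start = seq_along(labels) * 50,
        b_end = seq_along(labels) * 50 + 50, b_rev = FALSE,
        label = ifelse(labels == 1, "positive", "negative")
      ),
      a = a, b = b, schema_a = NULL, schema_b = NULL
    ),
    class = "lecif_features"
  )
}

# XOR-style cross-species dependence: each class has identical feature
# marginals, only the A/B interaction separates them.
xor_dataset <- function(n, seed, noise_cols = 2L) {
  withr::with_seed(seed, {
    y <- rep(c(1, 0), length.out = n)
    a <- rbinom(n, 1, 0.5)
    b <- ifelse(y == 1, a, 1 - a)
    A <- cbind(a, matrix(runif(n * noise_cols), n))
    B <- cbind(b, matrix(runif(n * noise_cols), n))
    make_features(A, B, y)
  })
}

# Exhaustive weighted pairwise AUROC oracle (ties count 1/2).
auc_oracle <- function(pos, neg, w_neg = 1) {
  w <- rep(w_neg, length(neg))
  num <- 0
  for (p in pos) {
    num <- num + sum(w * ((p > neg) + 0.5 * (p == neg)))
  }
  num / (length(pos) * sum(w))
}

# Exhaustive Mann-Whitney U oracle: U statistic by direct pairwise
# comparison and exact two-sided p by full enumeration of group
# assignments (tie-free inputs).
mwu_oracle <- function(x, y) {
  u_stat <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  u_obs <- u_stat(x, y)
  pooled <- c(x, y)
  n1 <- length(x)
  combs <- utils::combn(length(pooled), n1)
  us <- apply(combs, 2, function(ix) u_stat(pooled[ix], pooled[-ix]))
  mu <- n1 * length(y) / 2
  p <- mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
  list(u = u_obs, p = p)
}

# Direct evaluation of the weighted Jaccard definition.
jaccard_oracle <- function(h, m) {
  if (sum(pmax(h, m)) == 0) return(NA_real_)
  sum(pmin(h, m)) / sum(pmax(h, m))
}

write_axt_text <- function(lines, path = tempfile(fileext = ".axt")) {
  writeLines(lines, path)
  path
}
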