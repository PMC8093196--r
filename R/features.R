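#' Read an annotation manifest
#'
#' The manifest is a TSV with columns `path`, `species`, `kind`
#' (`peak`/`segmentation`/`signal`), and optionally `epigenome` (required
#' for segmentations), `group` (tissue group, used only by evaluation) and
#' `track_id` (defaults to the file name without extension). Relative paths
#' are resolved against the manifest's directory.
#'
#' @param path Path to the manifest TSV.
#' @return A tibble with one row per track.
#' @export
read_annotation_manifest <- function(path) {
  m <- readr::read_tsv(path, show_col_types = FALSE)
  required <- c("path", "species", "kind")
  missing <- setdiff(required, names(m))
  if (length(missing) > 0L) {
    abort(sprintf("Manifest is missing column(s): %s", paste(missing, collapse = ", ")))
  }
  if (!"epigenome" %in% names(m)) m$epigenome <- NA_character_
  if (!"group" %in% names(m)) m$group <- NA_character_
  if (!"track_id" %in% names(m)) {
    m$track_id <- sub("\\.[^.]+$", "", basename(m$path))
  }
  rel <- !grepl("^/", m$path)
  m$path[rel] <- file.path(dirname(path), m$path[rel])
  m
}

#' Load annotation tracks from a manifest
#'
#' Peak calls are read as BED (first three columns used), chromatin-state
#' segmentations as ChromHMM-style dense BED (chrom, start, end, state
#' label), and continuous signal as bedGraph. Segmentation and signal
#' intervals must be non-overlapping within a chromosome.
#'
#' @param manifest A tibble from [read_annotation_manifest()] (or of the
#'   same shape).
#' @return A list of track objects, each a list with `track_id`, `species`,
#'   `kind`, `epigenome`, `group`, `data` (tibble of intervals), and for
#'   segmentations the observed `states`.
#' @export
load_annotations <- function(manifest) {
  if (any(duplicated(manifest$track_id))) {
    abort(sprintf("Duplicate track_id: %s",
                  paste(unique(manifest$track_id[duplicated(manifest$track_id)]),
                        collapse = ", ")))
  }
  bad_kind <- setdiff(unique(manifest$kind), c("peak", "segmentation", "signal"))
  if (length(bad_kind) > 0L) {
    abort(sprintf("Unknown track kind: %s", paste(bad_kind, collapse = ", ")))
  }
  map(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    data <- switch(
      row$kind,
      peak = {
        x <- readr::read_tsv(
          row$path, col_names = FALSE, show_col_types = FALSE,
          col_types = readr::cols(.default = readr::col_guess())
        )
        if (nrow(x) == 0L) {
          tibble(chrom = character(), start = numeric(), end = numeric())
        } else {
          tibble(chrom = as.character(x[[1]]),
                 start = as.numeric(x[[2]]), end = as.numeric(x[[3]]))
        }
      },
      segmentation = readr::read_tsv(
        row$path, col_names = c("chrom", "start", "end", "state"),
        col_types = "cnnc", show_col_types = FALSE
      ),
      signal = {
        x <- readr::read_tsv(row$path, col_names = c("chrom", "start", "end", "value"),
                             col_types = "cnnc", show_col_types = FALSE)
        v <- suppressWarnings(as.numeric(x$value))
        if (anyNA(v)) {
          abort(sprintf("Non-numeric signal value in %s at line %d.",
                        row$path, which(is.na(v))[1]))
        }
        x$value <- v
        x
      }
    )
    if (row$kind %in% c("segmentation", "signal") && nrow(data) > 1L) {
      ovl <- data |>
        arrange(.data$chrom, .data$start) |>
        group_by(.data$chrom) |>
        summarise(bad = any(.data$start[-1] < head(.data$end, -1)), .groups = "drop")
      if (any(ovl$bad)) {
        abort(sprintf("Overlapping intervals in %s track '%s'.", row$kind, row$track_id))
      }
    }
    track <- list(
      track_id = row$track_id, species = row$species, kind = row$kind,
      epigenome = row$epigenome, group = row$group, data = data
    )
    if (row$kind == "segmentation") {
      track$states <- sort_states(unique(data$state))
    }
    track
  })
}

# Deterministic state ordering: numeric suffix order for E1/E2/... labels,
# lexicographic otherwise.
sort_states <- function(states) {
  num <- suppressWarnings(as.integer(sub("^[A-Za-z]+", "", states)))
  if (!anyNA(num)) states[order(num)] else sort(states)
}

#' Build a per-species feature schema
#'
#' One binary feature per peak track, one binary feature per
#' (epigenome, state) combination for segmentations (one-hot encoding of
#' chromatin states), and one continuous feature per signal track, in
#' manifest order (states in deterministic state order). The species-wide
#' signal min/max, computed jointly over all signal tracks, is stored with
#' the schema for normalization.
#'
#' @param tracks Track list from [load_annotations()]; all one species.
#' @param states Optional state alphabet shared by all segmentations;
#'   defaults to the union of observed states.
#' @return A `lecif_schema` tibble with columns `feature`, `track_id`,
#'   `kind`, `epigenome`, `state`; attributes `species`, `signal_min`,
#'   `signal_max`.
#' @export
build_feature_schema <- function(tracks, states = NULL) {
  species <- unique(map_chr(tracks, "species"))
  if (length(species) != 1L) {
    abort("All tracks in a schema must share one species tag.")
  }
  ids <- map_chr(tracks, "track_id")
  if (any(duplicated(ids))) abort("Duplicate track_id in schema input.")
  if (is.null(states)) {
    states <- sort_states(unique(unlist(
      map(tracks, function(t) if (t$kind == "segmentation") t$states)
    )))
  }
  rows <- map(tracks, function(t) {
    switch(t$kind,
      peak = tibble(track_id = t$track_id, kind = "peak",
                    epigenome = NA_character_, state = NA_character_),
      segmentation = tibble(track_id = t$track_id, kind = "segmentation",
                            epigenome = t$epigenome, state = states),
      signal = tibble(track_id = t$track_id, kind = "signal",
                      epigenome = NA_character_, state = NA_character_)
    )
  }) |> list_rbind()
  rows <- rows |> mutate(feature = row_number(), .before = 1)
  sig_vals <- unlist(map(tracks, function(t) {
    if (t$kind == "signal") t$data$value
  }))
  schema <- structure(
    rows,
    species = species,
    signal_min = if (length(sig_vals)) min(sig_vals) else NA_real_,
    signal_max = if (length(sig_vals)) max(sig_vals) else NA_real_,
    class = c("lecif_schema", class(rows))
  )
  schema
}

#' Min-max normalize a signal value
#'
#' Maps `value` to `(value - global_min) / (global_max - global_min)`,
#' clipped to `[0, 1]` so prediction-time values outside the range seen when
#' the schema was built stay valid features.
#'
#' @param value Numeric vector.
#' @param global_min,global_max Species-wide signal extremes (computed once
#'   over all signal tracks jointly).
#' @return Numeric vector in `[0, 1]`.
#' @export
normalize_signal <- function(value, global_min, global_max) {
  if (!is.finite(global_min) || !is.finite(global_max) ||
      global_min >= global_max) {
    abort("Degenerate normalization: global_min must be < global_max.")
  }
  pmin(1, pmax(0, (value - global_min) / (global_max - global_min)))
}

# Feature matrix for one species' side of a set of single-base positions.
featurize_positions <- function(chrom, pos, tracks, schema) {
  n <- length(pos)
  X <- matrix(0, nrow = n, ncol = nrow(schema))
  track_by_id <- setNames(tracks, map_chr(tracks, "track_id"))
  missing <- setdiff(unique(schema$track_id), names(track_by_id))
  if (length(missing) > 0L) {
    abort(sprintf("Schema/track mismatch: no track for %s",
                  paste(missing, collapse = ", ")))
  }
  for (tid in unique(schema$track_id)) {
    t <- track_by_id[[tid]]
    cols <- which(schema$track_id == tid)
    if (t$kind == "peak") {
      hit <- point_lookup(chrom, pos, t$data)
      X[, cols] <- as.numeric(!is.na(hit))
    } else if (t$kind == "segmentation") {
      hit <- point_lookup(chrom, pos, t$data)
      st <- ifelse(is.na(hit), NA_character_, t$data$state[hit])
      for (j in cols) {
        X[, j] <- as.numeric(!is.na(st) & st == schema$state[j])
      }
    } else { # signal
      hit <- point_lookup(chrom, pos, t$data)
      v <- ifelse(is.na(hit), 0, t$data$value[hit])
      X[, cols] <- normalize_signal(v, attr(schema, "signal_min"),
                                    attr(schema, "signal_max"))
    }
  }
  X
}

#' Compute feature vector pairs for region pairs
#'
#' In the default `first_base` resolution, each region is represented by the
#' annotations overlapping its first base (positions within a region share
#' the vector, matching the 50-bp score resolution). In `per_base`
#' resolution one vector pair is emitted per aligned base of each pair,
#' supporting a base-resolution score.
#'
#' @param pairs Tibble of region pairs.
#' @param tracks_a,tracks_b Track lists for species A and B.
#' @param schema_a,schema_b Schemas from [build_feature_schema()].
#' @param resolution `"first_base"` or `"per_base"`.
#' @return A `lecif_features` object: list with `pairs`, feature matrices
#'   `a` and `b`, and the two schemas.
#' @export
featurize_pairs <- function(pairs, tracks_a, tracks_b, schema_a, schema_b,
                            resolution = c("first_base", "per_base")) {
  resolution <- match.arg(resolution)
  if (!"b_rev" %in% names(pairs)) pairs$b_rev <- FALSE
  if (resolution == "per_base") {
    len <- pairs$a_end - pairs$a_start
    idx <- rep(seq_len(nrow(pairs)), len)
    off <- unlist(map(len, seq_len)) - 1L
    pairs <- pairs[idx, ]
    pairs$a_start <- pairs$a_start + off
    pairs$a_end <- pairs$a_start + 1L
    b_first <- ifelse(pairs$b_rev, pairs$b_end - 1L - off, pairs$b_start + off)
    pairs$b_start <- b_first
    pairs$b_end <- b_first + 1L
    pairs$pair_id <- sprintf("%s.%d", pairs$pair_id, off)
  }
  # the "first base" of the B region in alignment orientation
  b_first <- ifelse(pairs$b_rev, pairs$b_end - 1L, pairs$b_start)
  X_a <- featurize_positions(pairs$a_chrom, pairs$a_start, tracks_a, schema_a)
  X_b <- featurize_positions(pairs$b_chrom, b_first, tracks_b, schema_b)
  structure(
    list(pairs = pairs, a = X_a, b = X_b,
         schema_a = schema_a, schema_b = schema_b),
    class = "lecif_features"
  )
}

#' @export
print.lecif_features <- function(x, ...) {
  cat(sprintf("<lecif_features> %d pairs, %d A features, %d B features\n",
              nrow(x$pairs), ncol(x$a), ncol(x$b)))
  invisible(x)
}

#' Subset a features object by row
#'
#' @param features A `lecif_features` object.
#' @param idx Integer or logical row index into the pairs.
#' @return A `lecif_features` with the selected pairs and matrix rows.
#' @export
subset_features <- function(features, idx) {
  structure(
    list(pairs = features$pairs[idx, ], a = features$a[idx, , drop = FALSE],
         b = if (!is.null(features$b)) features$b[idx, , drop = FALSE],
         schema_a = features$schema_a, schema_b = features$schema_b),
    class = "lecif_features"
  )
}

#' 0/1 labels of a features object
#'
#' @param features A `lecif_features` object.
#' @return Numeric vector: 1 for positive pairs, 0 otherwise.
#' @export
feature_labels <- function(features) {
  as.numeric(features$pairs$label == "positive")
}
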