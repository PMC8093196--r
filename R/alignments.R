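#' Read a pairwise alignment in axt format
#'
#' Parses an axt file (optionally gzip-compressed) into one row per alignment
#' record. axt coordinates are 1-based inclusive; they are converted to
#' 0-based half-open on read. For records whose query (species B) side is on
#' the reverse strand, axt reports coordinates on the reverse-complemented
#' query chromosome; these are converted to forward-strand coordinates, which
#' requires the query chromosome sizes.
#'
#' @param path Path to an axt file. May be gzip-compressed.
#' @param b_sizes Named numeric vector of query-species chromosome sizes,
#'   required if any record is on the reverse strand.
#' @return A tibble with one row per record: `record`, `a_chrom`, `a_start`,
#'   `a_end`, `b_chrom`, `b_start`, `b_end` (forward-strand, 0-based
#'   half-open), `b_strand`, `score`, and the gapped sequences `a_seq`,
#'   `b_seq`.
#' @export
read_axt <- function(path, b_sizes = NULL) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) %% 3L != 0L) {
    abort("Malformed axt: number of non-blank lines is not a multiple of 3.")
  }
  idx <- seq(1L, length(lines), by = 3L)
  recs <- map(seq_along(idx), function(i) {
    hdr <- strsplit(trimws(lines[idx[i]]), "\\s+")[[1]]
    if (length(hdr) != 9L) {
      abort(sprintf("Malformed axt header at record %d.", i))
    }
    a_seq <- lines[idx[i] + 1L]
    b_seq <- lines[idx[i] + 2L]
    if (nchar(a_seq) != nchar(b_seq)) {
      abort(sprintf(
        "Gapped sequences differ in length at record %d (%d vs %d).",
        i, nchar(a_seq), nchar(b_seq)
      ))
    }
    tibble(
      record = i,
      a_chrom = hdr[2], a_start = as.numeric(hdr[3]) - 1, a_end = as.numeric(hdr[4]),
      b_chrom = hdr[5], b_start = as.numeric(hdr[6]) - 1, b_end = as.numeric(hdr[7]),
      b_strand = hdr[8], score = as.numeric(hdr[9]),
      a_seq = a_seq, b_seq = b_seq
    )
  })
  out <- list_rbind(recs)
  ungapped_a <- nchar(gsub("-", "", out$a_seq))
  ungapped_b <- nchar(gsub("-", "", out$b_seq))
  bad <- which(ungapped_a != out$a_end - out$a_start |
                 ungapped_b != out$b_end - out$b_start)
  if (length(bad) > 0L) {
    abort(sprintf("Ungapped sequence length disagrees with coordinates at record %d.",
                  bad[1]))
  }
  rev <- out$b_strand == "-"
  if (any(rev)) {
    if (is.null(b_sizes)) {
      abort("Reverse-strand records present: supply `b_sizes` to convert query coordinates.")
    }
    missing <- setdiff(unique(out$b_chrom[rev]), names(b_sizes))
    if (length(missing) > 0L) {
      abort(sprintf("No chromosome size for query chromosome(s): %s",
                    paste(missing, collapse = ", ")))
    }
    sz <- unname(b_sizes[out$b_chrom[rev]])
    new_start <- sz - out$b_end[rev]
    new_end <- sz - out$b_start[rev]
    out$b_start[rev] <- new_start
    out$b_end[rev] <- new_end
  }
  out
}

# Reverse-strand coordinate flip for a 0-based half-open interval; applying
# it twice is the identity.
reverse_coords <- function(start, end, size) {
  list(start = size - end, end = size - start)
}

#' Split alignment records into ungapped blocks
#'
#' Each gapped alignment record is split at every gap column into maximal
#' gap-free blocks. Within a block the two species' segments have equal
#' length and bases correspond 1:1 positionally. Blocks inherit the parent
#' record's alignment score. For reverse-strand records the positional
#' correspondence runs antiparallel: base `i` of the A segment pairs with
#' forward-strand B base `b_end - 1 - i` (flagged by `b_rev`).
#'
#' @param axt A tibble as returned by [read_axt()].
#' @return A tibble of blocks: `block_id`, `record`, `a_chrom`, `a_start`,
#'   `a_end`, `b_chrom`, `b_start`, `b_end`, `b_rev`, `score`.
#' @export
alignment_blocks <- function(axt) {
  blocks <- map(seq_len(nrow(axt)), function(i) {
    a_chars <- strsplit(axt$a_seq[i], "")[[1]]
    b_chars <- strsplit(axt$b_seq[i], "")[[1]]
    gap <- a_chars == "-" | b_chars == "-"
    if (all(gap)) return(NULL)
    r <- rle(!gap)
    col_end <- cumsum(r$lengths)
    col_start <- col_end - r$lengths + 1L
    keep <- which(r$values)
    # ungapped offsets within each species before each column
    a_off <- cumsum(a_chars != "-")
    b_off <- cumsum(b_chars != "-")
    rev <- axt$b_strand[i] == "-"
    map(keep, function(k) {
      cs <- col_start[k]; ce <- col_end[k]
      len <- ce - cs + 1L
      a_s <- axt$a_start[i] + (if (cs == 1L) 0 else a_off[cs - 1L])
      b_off0 <- if (cs == 1L) 0 else b_off[cs - 1L]
      if (!rev) {
        b_s <- axt$b_start[i] + b_off0
        b_e <- b_s + len
      } else {
        # offsets count along the reverse-complement orientation, i.e. from
        # the forward-strand end of the record's B interval
        b_e <- axt$b_end[i] - b_off0
        b_s <- b_e - len
      }
      tibble(
        record = axt$record[i],
        a_chrom = axt$a_chrom[i], a_start = a_s, a_end = a_s + len,
        b_chrom = axt$b_chrom[i], b_start = b_s, b_end = b_e,
        b_rev = rev, score = axt$score[i]
      )
    }) |> list_rbind()
  }) |> list_rbind()
  blocks |> mutate(block_id = row_number(), .before = 1)
}

#' Load ungapped alignment blocks from an axt file
#'
#' Convenience wrapper: [read_axt()] followed by [alignment_blocks()].
#'
#' @inheritParams read_axt
#' @return A tibble of ungapped alignment blocks; see [alignment_blocks()].
#' @export
load_alignment_blocks <- function(path, b_sizes = NULL) {
  alignment_blocks(read_axt(path, b_sizes = b_sizes))
}

#' Resolve multiple query partners per reference segment
#'
#' Where several B segments align to overlapping A segments, keep the one
#' with the highest alignment score, so that retained blocks do not overlap
#' on the A genome. Ties are broken deterministically by lower B chromosome
#' name, then lower B start.
#'
#' @param blocks A tibble of alignment blocks.
#' @return The subset of `blocks` whose A intervals are pairwise
#'   non-overlapping, highest score preferred.
#' @export
select_best_partner <- function(blocks) {
  if (nrow(blocks) == 0L) return(blocks)
  ord <- order(-blocks$score, blocks$b_chrom, blocks$b_start)
  keep <- logical(nrow(blocks))
  kept <- list()
  for (i in ord) {
    chr <- blocks$a_chrom[i]
    prev <- kept[[chr]]
    s <- blocks$a_start[i]; e <- blocks$a_end[i]
    if (is.null(prev) || !any(s < prev$end & e > prev$start)) {
      keep[i] <- TRUE
      kept[[chr]] <- list(start = c(prev$start, s), end = c(prev$end, e))
    }
  }
  blocks[sort(which(keep)), , drop = FALSE]
}

#' Tile alignment blocks into paired fixed-width regions
#'
#' Non-overlapping windows of `width` bases are laid from the first base of
#' each block; the last window is truncated at the block end, so regions can
#' be shorter than `width`. Because blocks are ungapped, the B-side window is
#' the offset-matched segment of the block's B interval (antiparallel for
#' reverse-strand blocks).
#'
#' @param blocks A tibble of alignment blocks.
#' @param width Window width in bases (default 50).
#' @return A tibble of region pairs: `pair_id`, `block_id`, both species'
#'   coordinates, `b_rev`, and `label` (`"positive"`).
#' @export
tile_pairs <- function(blocks, width = 50L) {
  stopifnot(width >= 1L)
  if (nrow(blocks) == 0L) {
    abort("No alignment blocks to tile.")
  }
  len <- blocks$a_end - blocks$a_start
  n_win <- ceiling(len / width)
  idx <- rep(seq_len(nrow(blocks)), n_win)
  off <- unlist(map(n_win, function(k) (seq_len(k) - 1L) * width))
  w_len <- pmin(width, len[idx] - off)
  b_start <- ifelse(blocks$b_rev[idx],
                    blocks$b_end[idx] - off - w_len,
                    blocks$b_start[idx] + off)
  tibble(
    pair_id = sprintf("p%06d", seq_along(idx)),
    block_id = blocks$block_id[idx],
    a_chrom = blocks$a_chrom[idx],
    a_start = blocks$a_start[idx] + off,
    a_end = blocks$a_start[idx] + off + w_len,
    b_chrom = blocks$b_chrom[idx],
    b_start = b_start,
    b_end = b_start + w_len,
    b_rev = blocks$b_rev[idx],
    label = "positive"
  )
}

#' Build labeled training pairs from positive region pairs
#'
#' In `"mismatch"` mode, one negative is produced per positive by permuting
#' the B regions over the A regions such that no A region is re-paired with
#' a B region it truly aligns to (a derangement with respect to the alignment
#' relation). Every region appearing in a negative therefore also appears in
#' some positive, so each feature's marginal distribution is identical
#' between the classes. In `"genome_background"` mode both members are drawn
#' uniformly from their genomes.
#'
#' @param positives Tibble of positive region pairs from [tile_pairs()].
#' @param mode `"mismatch"` or `"genome_background"`.
#' @param seed Integer seed; required.
#' @param a_genome,b_genome For genome-background mode, tibbles with columns
#'   `chrom`, `size`.
#' @param width Region width for genome-background sampling.
#' @return A tibble of positives followed by the same number of labeled
#'   negatives.
#' @export
generate_training_pairs <- function(positives,
                                    mode = c("mismatch", "genome_background"),
                                    seed = NULL,
                                    a_genome = NULL, b_genome = NULL,
                                    width = 50L) {
  mode <- match.arg(mode)
  seed <- check_seed(seed)
  n <- nrow(positives)
  if (mode == "mismatch") {
    if (n < 2L) abort("Mismatch negatives need at least 2 positives (no derangement of size 1).")
    # A region may appear in several positives (it aligns to one partner
    # after best-partner filtering, but be defensive): forbid any (a, b)
    # combination present in the alignment relation.
    a_key <- paste(positives$a_chrom, positives$a_start, positives$a_end)
    b_key <- paste(positives$b_chrom, positives$b_start, positives$b_end)
    true_rel <- paste(a_key, b_key)
    perm <- withr::with_seed(seed, {
      p <- sample.int(n)
      for (iter in 1:100) {
        collide <- which(paste(a_key, b_key[p]) %in% true_rel)
        if (length(collide) == 0L) break
        if (length(collide) >= 2L) {
          # rotate colliding assignments among themselves
          p[collide] <- p[c(collide[-1], collide[1])]
        } else {
          other <- sample(setdiff(seq_len(n), collide), 1L)
          p[c(collide, other)] <- p[c(other, collide)]
        }
      }
      collide <- which(paste(a_key, b_key[p]) %in% true_rel)
      if (length(collide) > 0L) {
        abort("Could not construct a mismatch derangement for this positive set.")
      }
      p
    })
    negatives <- positives |>
      mutate(
        b_chrom = positives$b_chrom[perm],
        b_start = positives$b_start[perm],
        b_end = positives$b_end[perm],
        b_rev = positives$b_rev[perm],
        block_id = NA_integer_,
        label = "negative",
        pair_id = sprintf("n%06d", seq_len(n))
      )
  } else {
    if (is.null(a_genome) || is.null(b_genome)) {
      abort("Genome-background mode needs `a_genome` and `b_genome` (chrom, size).")
    }
    negatives <- withr::with_seed(seed, {
      sample_side <- function(genome, k) {
        ci <- sample.int(nrow(genome), k, replace = TRUE,
                         prob = genome$size / sum(genome$size))
        start <- floor(runif(k, 0, genome$size[ci] - width))
        tibble(chrom = genome$chrom[ci], start = start, end = start + width)
      }
      a <- sample_side(a_genome, n)
      b <- sample_side(b_genome, n)
      tibble(
        pair_id = sprintf("n%06d", seq_len(n)),
        block_id = NA_integer_,
        a_chrom = a$chrom, a_start = a$start, a_end = a$end,
        b_chrom = b$chrom, b_start = b$start, b_end = b$end,
        b_rev = FALSE, label = "negative"
      )
    })
  }
  bind_rows(positives, negatives)
}

#' Define a chromosome-based train/validation/test/predict scheme
#'
#' Training, validation and test sets are defined by disjoint chromosome
#' sets, per species; a pair belongs to a role only if both of its
#' chromosomes are in that role's sets. The default carves the supplied
#' chromosomes by parity: odd chromosomes (minus the last odd one, reserved
#' for validation) train, even chromosomes test, everything predicts.
#'
#' @param a_chroms,b_chroms Character vectors of chromosome names per
#'   species.
#' @param train,validation,test,predict Optional lists with elements `a` and
#'   `b` overriding the parity default.
#' @return A `lecif_split_scheme` object.
#' @export
split_scheme <- function(a_chroms, b_chroms = a_chroms,
                         train = NULL, validation = NULL, test = NULL,
                         predict = NULL) {
  parity_default <- function(chroms) {
    num <- suppressWarnings(as.integer(gsub("^chr", "", chroms)))
    odd <- chroms[!is.na(num) & num %% 2L == 1L]
    even <- chroms[!is.na(num) & num %% 2L == 0L]
    if (length(odd) < 2L) {
      abort("Parity default needs at least two odd chromosomes; supply sets explicitly.")
    }
    list(train = head(odd, -1L), validation = tail(odd, 1L), test = even)
  }
  if (is.null(train) || is.null(validation) || is.null(test)) {
    pa <- parity_default(a_chroms)
    pb <- parity_default(b_chroms)
    train <- train %||% list(a = pa$train, b = pb$train)
    validation <- validation %||% list(a = pa$validation, b = pb$validation)
    test <- test %||% list(a = pa$test, b = pb$test)
  }
  predict <- predict %||% list(a = a_chroms, b = b_chroms)
  scheme <- list(train = train, validation = validation, test = test,
                 predict = predict)
  for (side in c("a", "b")) {
    sets <- list(scheme$train[[side]], scheme$validation[[side]],
                 scheme$test[[side]])
    for (i in 1:2) for (j in (i + 1):3) {
      ov <- intersect(sets[[i]], sets[[j]])
      if (length(ov) > 0L) {
        abort(sprintf("Chromosome set overlap across train/validation/test (%s side): %s",
                      side, paste(ov, collapse = ", ")))
      }
    }
  }
  structure(scheme, class = "lecif_split_scheme")
}

#' Assign region pairs to split roles
#'
#' A pair enters train/validation/test only if both its A and B chromosomes
#' are in that role's sets; pairs matching none of these roles are labeled
#' `"predict"` if covered by the prediction sets and dropped otherwise, so no
#' genomic region is shared between training and evaluation roles.
#'
#' @param pairs Tibble of region pairs.
#' @param scheme A [split_scheme()].
#' @return `pairs` with a `role` column.
#' @export
assign_splits <- function(pairs, scheme) {
  stopifnot(inherits(scheme, "lecif_split_scheme"))
  role <- rep(NA_character_, nrow(pairs))
  for (r in c("train", "validation", "test")) {
    hit <- pairs$a_chrom %in% scheme[[r]]$a & pairs$b_chrom %in% scheme[[r]]$b
    role[is.na(role) & hit] <- r
  }
  in_pred <- pairs$a_chrom %in% scheme$predict$a &
    pairs$b_chrom %in% scheme$predict$b
  role[is.na(role) & in_pred] <- "predict"
  pairs |> mutate(role = role) |> filter(!is.na(role))
}

#' Assign splits and build balanced labeled sets per role
#'
#' Positives are first partitioned by chromosome role with
#' [assign_splits()]; mismatch negatives are then generated separately
#' within each of the train/validation/test roles, so every role is
#' balanced and both members of every example lie on that role's
#' chromosomes. Prediction-role pairs keep positives only.
#'
#' @param positives Tibble of positive region pairs.
#' @param scheme A [split_scheme()].
#' @param seed Integer seed for the per-role derangements.
#' @return A labeled tibble with a `role` column.
#' @export
build_labeled_splits <- function(positives, scheme, seed) {
  seed <- check_seed(seed)
  assigned <- assign_splits(positives, scheme)
  roles <- c("train", "validation", "test")
  out <- map(seq_along(roles), function(i) {
    sub <- assigned |> filter(.data$role == roles[i])
    if (nrow(sub) == 0L) return(NULL)
    generate_training_pairs(sub, "mismatch", seed = seed + i) |>
      mutate(role = roles[i],
             pair_id = sprintf("%s_%s", substr(roles[i], 1, 2), .data$pair_id))
  }) |> list_rbind()
  bind_rows(out, assigned |> filter(.data$role == "predict"))
}

#' Write region pairs as TSV and per-species BED
#'
#' @param pairs Tibble of region pairs.
#' @param out_prefix Output path prefix; writes `<prefix>.pairs.tsv`,
#'   `<prefix>.a.bed`, `<prefix>.b.bed`.
#' @return Invisibly, the paths written.
#' @export
write_pairs <- function(pairs, out_prefix) {
  tsv <- paste0(out_prefix, ".pairs.tsv")
  readr::write_tsv(
    pairs |> select(all_of(c("pair_id", "a_chrom", "a_start", "a_end",
                             "b_chrom", "b_start", "b_end", "label")),
                    any_of("block_id")),
    tsv
  )
  bed_a <- paste0(out_prefix, ".a.bed")
  bed_b <- paste0(out_prefix, ".b.bed")
  readr::write_tsv(
    pairs |> select(all_of(c("a_chrom", "a_start", "a_end", "pair_id"))),
    bed_a, col_names = FALSE
  )
  readr::write_tsv(
    pairs |> select(all_of(c("b_chrom", "b_start", "b_end", "pair_id"))),
    bed_b, col_names = FALSE
  )
  invisible(c(tsv, bed_a, bed_b))
}
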