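#' Configuration for the synthetic two-genome generator
#'
#' The generator emulates the full input surface of the scoring pipeline:
#' two toy genomes, a gapped pairwise alignment in axt format, per-species
#' peak calls, chromatin-state segmentations (shared state alphabet, as in a
#' jointly learned model) and continuous signal tracks, plus a variant set.
#' Cross-species concordance is planted through a latent per-segment
#' activity state: at aligned positions the B-genome segment copies the A
#' segment's latent state (and activity level) with probability `rho`,
#' otherwise it is drawn independently. Observed tracks are noisy emissions
#' of the latent state.
#'
#' @param n_chrom Chromosomes per species.
#' @param chrom_len Chromosome length in bases.
#' @param n_records Number of alignment records.
#' @param record_len Min/max ungapped match length per record.
#' @param gap_events Mean number of gap runs per record (Poisson).
#' @param gap_len Max gap-run length.
#' @param rev_prob Probability a record's query side is reverse-strand.
#' @param synteny Probability the B partner lies on the same-numbered
#'   chromosome (keeps chromosome-parity splits populated).
#' @param segment_len Latent-state segment length.
#' @param states State labels.
#' @param state_freq State frequencies.
#' @param activity_level Mean activity level per state, in `[0, 1]`.
#' @param rho Planted cross-species concordance in `[0, 1]`.
#' @param n_epigenomes Segmentation tracks per species.
#' @param groups Tissue groups for peak tracks.
#' @param peaks_per_group Peak experiments per group per species.
#' @param n_signal Signal tracks per species.
#' @param seg_noise Probability a segmentation mis-labels a segment.
#' @param signal_noise Gaussian sd of the signal emission.
#' @param variant_rate Background variant rate per base.
#' @param variant_fold Variant-rate multiplier in high-activity aligned
#'   segments when `variant_effect` is on.
#' @param variant_effect Plant the variant enrichment effect?
#' @param seed Integer seed.
#' @return A `lecif_sim_config` list.
#' @export
lecif_sim_config <- function(n_chrom = 4L, chrom_len = 1e6, n_records = 2000L,
                             record_len = c(200L, 1200L), gap_events = 1.5,
                             gap_len = 5L, rev_prob = 0.3, synteny = 0.8,
                             segment_len = 200L,
                             states = paste0("E", 1:6),
                             state_freq = c(0.05, 0.08, 0.12, 0.15, 0.15, 0.45),
                             activity_level = c(0.95, 0.8, 0.6, 0.45, 0.25, 0.05),
                             rho = 0.9, n_epigenomes = 3L,
                             groups = c("brain", "heart", "liver"),
                             peaks_per_group = 2L, n_signal = 2L,
                             seg_noise = 0.1, signal_noise = 0.05,
                             variant_rate = 2e-4, variant_fold = 4,
                             variant_effect = TRUE, seed = 1L) {
  stopifnot(rho >= 0, rho <= 1, n_chrom >= 1L, chrom_len > 0,
            length(state_freq) == length(states),
            length(activity_level) == length(states),
            abs(sum(state_freq) - 1) < 1e-8)
  structure(as.list(environment()), class = "lecif_sim_config")
}

# State-specific peak emission probabilities per tissue group; rows follow
# cfg$states. Groups beyond the named three reuse profiles cyclically.
peak_profiles <- function(cfg) {
  base <- list(
    brain = c(0.80, 0.30, 0.70, 0.20, 0.10, 0.03),
    heart = c(0.30, 0.80, 0.60, 0.25, 0.08, 0.03),
    liver = c(0.85, 0.75, 0.35, 0.25, 0.10, 0.03)
  )
  idx <- ((seq_along(cfg$groups) - 1L) %% length(base)) + 1L
  setNames(base[idx], cfg$groups)
}

#' Generate a complete synthetic fixture on disk
#'
#' Writes an axt alignment, chromosome-size tables, annotation tracks with
#' manifests, a variant BED, latent-truth state tracks (files labeled
#' `synthetic`), and the configuration as JSON. All outputs parse with the
#' package's readers.
#'
#' @param cfg A [lecif_sim_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the main paths and the config.
#' @export
simulate_dataset <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "lecif_sim_config"))
  if (cfg$record_len[2] + cfg$gap_events * cfg$gap_len > cfg$chrom_len) {
    abort("Impossible geometry: alignment records longer than chromosomes.")
  }
  dir.create(file.path(out_dir, "tracks"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "truth"), showWarnings = FALSE)
  chroms <- paste0("chr", seq_len(cfg$n_chrom))
  sizes <- setNames(rep(cfg$chrom_len, cfg$n_chrom), chroms)

  withr::with_seed(check_seed(cfg$seed), {
    recs <- sim_alignment(cfg, chroms)
    write_axt(recs, sizes, file.path(out_dir, "alignment.axt"))
    latent_a <- sim_latent(cfg, chroms)
    latent_b <- sim_latent(cfg, chroms)
    blocks <- alignment_blocks(recs)
    latent_b <- couple_latent(cfg, latent_a, latent_b, blocks)
    for (sp in c("a", "b")) {
      latent <- if (sp == "a") latent_a else latent_b
      manifest <- sim_tracks(cfg, latent, sp, out_dir)
      readr::write_tsv(manifest, file.path(out_dir, sprintf("manifest_%s.tsv", sp)))
      readr::write_tsv(
        latent |> select(all_of(c("chrom", "start", "end", "state"))),
        file.path(out_dir, "truth", sprintf("states_%s.synthetic.bed", sp)),
        col_names = FALSE
      )
      readr::write_tsv(tibble(chrom = chroms, size = unname(sizes)),
                       file.path(out_dir, sprintf("genome_%s.sizes", sp)),
                       col_names = FALSE)
    }
    sim_variants(cfg, latent_a, blocks, file.path(out_dir, "variants_a.bed"))
  })
  cfg_json <- cfg
  class(cfg_json) <- NULL
  jsonlite::write_json(cfg_json, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(
    dir = out_dir,
    axt = file.path(out_dir, "alignment.axt"),
    manifest_a = file.path(out_dir, "manifest_a.tsv"),
    manifest_b = file.path(out_dir, "manifest_b.tsv"),
    variants = file.path(out_dir, "variants_a.bed"),
    cfg = cfg
  ))
}

# Alignment records with gapped sequences, in the read_axt() row schema
# (B coordinates forward-strand, 0-based half-open).
sim_alignment <- function(cfg, chroms) {
  n <- cfg$n_records
  n_match <- sample(cfg$record_len[1]:cfg$record_len[2], n, replace = TRUE)
  gaps_a <- rpois(n, cfg$gap_events / 2)  # runs gapped in A (B-only bases)
  gaps_b <- rpois(n, cfg$gap_events / 2)  # runs gapped in B (A-only bases)
  len_a <- n_match + map_int(gaps_b, function(k) {
    if (k == 0L) 0L else sum(sample.int(cfg$gap_len, k, replace = TRUE))
  })
  len_b_extra <- map_int(gaps_a, function(k) {
    if (k == 0L) 0L else sum(sample.int(cfg$gap_len, k, replace = TRUE))
  })
  len_b <- n_match + len_b_extra
  a_chrom_i <- rep(seq_along(chroms), length.out = n)
  b_chrom_i <- ifelse(runif(n) < cfg$synteny, a_chrom_i, {
    shift <- sample.int(length(chroms) - 1L, n, replace = TRUE)
    ((a_chrom_i - 1L + shift) %% length(chroms)) + 1L
  })
  place <- function(chrom_i, lens) {
    start <- integer(length(lens))
    for (ci in unique(chrom_i)) {
      idx <- which(chrom_i == ci)
      total <- sum(lens[idx])
      free <- cfg$chrom_len - total
      if (free < length(idx) + 1L) {
        abort("Impossible geometry: records do not fit on a chromosome.")
      }
      cuts <- runif(length(idx) + 1L)
      gaps <- floor(free * cuts / sum(cuts))
      ord <- sample(idx)  # random order along the chromosome
      start[ord] <- head(cumsum(gaps), -1L) + c(0L, cumsum(head(lens[ord], -1L)))
    }
    start
  }
  a_start <- place(a_chrom_i, len_a)
  b_start <- place(b_chrom_i, len_b)
  strand <- ifelse(runif(n) < cfg$rev_prob, "-", "+")
  seqs <- map(seq_len(n), function(i) {
    m <- n_match[i]
    # column plan: start from matched columns, then splice in gap runs
    cols_a <- rep(TRUE, m)   # A has a base
    cols_b <- rep(TRUE, m)   # B has a base
    total_a_only <- len_a[i] - m
    total_b_only <- len_b[i] - m
    splice <- function(cols_a, cols_b, k_total, into_a) {
      while (k_total > 0L) {
        run <- min(sample.int(cfg$gap_len, 1L), k_total)
        at <- sample.int(length(cols_a) - 1L, 1L)
        ins_a <- rep(into_a, run)
        cols_a <- append(cols_a, ins_a, after = at)
        cols_b <- append(cols_b, !ins_a, after = at)
        k_total <- k_total - run
      }
      list(a = cols_a, b = cols_b)
    }
    sp <- splice(cols_a, cols_b, total_a_only, into_a = TRUE)
    sp <- splice(sp$a, sp$b, total_b_only, into_a = FALSE)
    base <- function(mask) {
      out <- rep("-", length(mask))
      out[mask] <- sample(c("A", "C", "G", "T"), sum(mask), replace = TRUE)
      paste(out, collapse = "")
    }
    list(a = base(sp$a), b = base(sp$b))
  })
  tibble(
    record = seq_len(n),
    a_chrom = chroms[a_chrom_i], a_start = a_start, a_end = a_start + len_a,
    b_chrom = chroms[b_chrom_i], b_start = b_start, b_end = b_start + len_b,
    b_strand = strand,
    score = as.integer(round(n_match * runif(n, 80, 120))),
    a_seq = map_chr(seqs, "a"), b_seq = map_chr(seqs, "b")
  )
}

# Write records (forward-strand b coordinates) as axt, converting
# reverse-strand records to axt's reverse-complement coordinate convention.
write_axt <- function(recs, b_sizes, path) {
  rev <- recs$b_strand == "-"
  b_start1 <- recs$b_start + 1
  b_end1 <- recs$b_end
  sz <- unname(b_sizes[recs$b_chrom])
  b_start1[rev] <- sz[rev] - recs$b_end[rev] + 1
  b_end1[rev] <- sz[rev] - recs$b_start[rev]
  lines <- character(3L * nrow(recs))
  lines[seq(1, length(lines), 3)] <- sprintf(
    "%d %s %d %d %s %d %d %s %d",
    recs$record - 1L, recs$a_chrom, recs$a_start + 1, recs$a_end,
    recs$b_chrom, b_start1, b_end1, recs$b_strand, recs$score
  )
  lines[seq(2, length(lines), 3)] <- recs$a_seq
  lines[seq(3, length(lines), 3)] <- recs$b_seq
  writeLines(paste0(lines, c("", "", "\n")), path, sep = "\n")
  invisible(path)
}

# Latent per-segment activity: categorical state plus a continuous level.
sim_latent <- function(cfg, chroms) {
  n_seg <- ceiling(cfg$chrom_len / cfg$segment_len)
  map(chroms, function(ch) {
    start <- (seq_len(n_seg) - 1L) * cfg$segment_len
    si <- sample.int(length(cfg$states), n_seg, replace = TRUE,
                     prob = cfg$state_freq)
    tibble(
      chrom = ch, start = start,
      end = pmin(start + cfg$segment_len, cfg$chrom_len),
      state = cfg$states[si],
      u = pmin(1, pmax(0, cfg$activity_level[si] + rnorm(n_seg, 0, 0.06)))
    )
  }) |> list_rbind()
}

# Rebuild B's latent intervals so that inside aligned blocks they are exact
# images of A's segments through the alignment: each image copies the A
# segment's latent state (and activity) with probability rho, otherwise it
# is drawn independently. Outside aligned blocks B keeps its own grid, so
# agreement at aligned bases is rho (plus chance) by construction.
couple_latent <- function(cfg, latent_a, latent_b, blocks) {
  hits <- GenomicRanges::findOverlaps(
    as_granges(latent_a),
    as_granges(blocks, "a_chrom", "a_start", "a_end")
  )
  if (length(hits) == 0L) return(latent_b)
  ai <- S4Vectors::queryHits(hits)
  bi <- S4Vectors::subjectHits(hits)
  blk <- blocks[bi, ]
  a_lo <- pmax(latent_a$start[ai], blk$a_start)
  a_hi <- pmin(latent_a$end[ai], blk$a_end)
  len <- a_hi - a_lo
  b_lo <- ifelse(blk$b_rev,
                 blk$b_end - (a_hi - blk$a_start),
                 blk$b_start + (a_lo - blk$a_start))
  copied <- runif(length(ai)) < cfg$rho
  n_fresh <- sum(!copied)
  fresh_state <- sample.int(length(cfg$states), n_fresh, replace = TRUE,
                            prob = cfg$state_freq)
  images <- tibble(
    chrom = blk$b_chrom, start = b_lo, end = b_lo + len,
    state = latent_a$state[ai], u = latent_a$u[ai], copied = copied
  )
  images$state[!copied] <- cfg$states[fresh_state]
  images$u[!copied] <- pmin(1, pmax(0, cfg$activity_level[fresh_state] +
                                      rnorm(n_fresh, 0, 0.06)))
  # B grid restricted to the complement of the aligned B intervals
  grid_gr <- as_granges(latent_b)
  outside <- GenomicRanges::setdiff(
    grid_gr, GenomicRanges::reduce(as_granges(images)))
  piece_gr <- GenomicRanges::intersect(grid_gr, outside)
  src <- GenomicRanges::findOverlaps(piece_gr, grid_gr, select = "first")
  pieces <- tibble(
    chrom = as.character(GenomicRanges::seqnames(piece_gr)),
    start = GenomicRanges::start(piece_gr) - 1L,
    end = GenomicRanges::end(piece_gr),
    state = latent_b$state[src], u = latent_b$u[src], copied = FALSE
  )
  bind_rows(images, pieces) |>
    filter(.data$end > .data$start) |>
    arrange(.data$chrom, .data$start)
}

# Emit observed tracks for one species and write them plus a manifest.
sim_tracks <- function(cfg, latent, sp, out_dir) {
  profiles <- peak_profiles(cfg)
  si <- match(latent$state, cfg$states)
  rows <- list()
  for (g in cfg$groups) {
    for (rep_i in seq_len(cfg$peaks_per_group)) {
      p <- profiles[[g]][si]
      emit <- runif(nrow(latent)) < p
      fn <- sprintf("tracks/%s_peak_%s_%d.bed", sp, g, rep_i)
      readr::write_tsv(latent[emit, c("chrom", "start", "end")],
                       file.path(out_dir, fn), col_names = FALSE)
      rows[[length(rows) + 1L]] <- tibble(
        path = fn, species = sp, kind = "peak", epigenome = NA_character_,
        group = g, track_id = sprintf("%s_peak_%s_%d", sp, g, rep_i))
    }
  }
  for (e in seq_len(cfg$n_epigenomes)) {
    flip <- runif(nrow(latent)) < cfg$seg_noise
    obs <- latent$state
    obs[flip] <- cfg$states[sample.int(length(cfg$states), sum(flip),
                                       replace = TRUE)]
    fn <- sprintf("tracks/%s_seg_epi%d.bed", sp, e)
    readr::write_tsv(
      latent |> mutate(state = obs) |>
        select(all_of(c("chrom", "start", "end", "state"))),
      file.path(out_dir, fn), col_names = FALSE)
    rows[[length(rows) + 1L]] <- tibble(
      path = fn, species = sp, kind = "segmentation",
      epigenome = sprintf("epi%d", e), group = NA_character_,
      track_id = sprintf("%s_seg_epi%d", sp, e))
  }
  for (s in seq_len(cfg$n_signal)) {
    val <- latent$u + rnorm(nrow(latent), 0, cfg$signal_noise)
    fn <- sprintf("tracks/%s_signal_%d.bedGraph", sp, s)
    readr::write_tsv(
      latent |> mutate(value = round(val, 4)) |>
        select(all_of(c("chrom", "start", "end", "value"))),
      file.path(out_dir, fn), col_names = FALSE)
    rows[[length(rows) + 1L]] <- tibble(
      path = fn, species = sp, kind = "signal", epigenome = NA_character_,
      group = NA_character_, track_id = sprintf("%s_signal_%d", sp, s))
  }
  list_rbind(rows)
}

# Variants on the A genome: background rate everywhere, multiplied in
# aligned high-activity segments when the planted effect is on.
sim_variants <- function(cfg, latent_a, blocks, path) {
  aligned <- overlaps_any(latent_a, blocks,
                          s_cols = c("a_chrom", "a_start", "a_end"))
  rate <- rep(cfg$variant_rate, nrow(latent_a))
  if (cfg$variant_effect) {
    rate[aligned & latent_a$u > 0.6] <- cfg$variant_rate * cfg$variant_fold
  }
  len <- latent_a$end - latent_a$start
  k <- rpois(nrow(latent_a), rate * len)
  idx <- rep(seq_len(nrow(latent_a)), k)
  pos <- latent_a$start[idx] + floor(runif(length(idx), 0, len[idx]))
  readr::write_tsv(
    tibble(chrom = latent_a$chrom[idx], start = pos, end = pos + 1L) |>
      arrange(.data$chrom, .data$start),
    path, col_names = FALSE)
  invisible(path)
}

#' Load a simulated fixture
#'
#' Reads back everything [simulate_dataset()] wrote: alignment blocks,
#' annotation tracks, schemas, genomes and variants.
#'
#' @param dir Fixture directory.
#' @return A list with `blocks`, `tracks_a`, `tracks_b`, `schema_a`,
#'   `schema_b`, `a_genome`, `b_genome`, `b_sizes`, `variants`.
#' @export
load_fixture <- function(dir) {
  read_sizes <- function(path) {
    readr::read_tsv(path, col_names = c("chrom", "size"), col_types = "cn",
                    show_col_types = FALSE)
  }
  a_genome <- read_sizes(file.path(dir, "genome_a.sizes"))
  b_genome <- read_sizes(file.path(dir, "genome_b.sizes"))
  b_sizes <- setNames(b_genome$size, b_genome$chrom)
  blocks <- load_alignment_blocks(file.path(dir, "alignment.axt"), b_sizes)
  tracks_a <- load_annotations(read_annotation_manifest(file.path(dir, "manifest_a.tsv")))
  tracks_b <- load_annotations(read_annotation_manifest(file.path(dir, "manifest_b.tsv")))
  variants_path <- file.path(dir, "variants_a.bed")
  variants <- if (file.exists(variants_path) && file.size(variants_path) > 0) {
    readr::read_tsv(variants_path, col_names = c("chrom", "start", "end"),
                    col_types = "cnn", show_col_types = FALSE)
  } else {
    tibble(chrom = character(), start = numeric(), end = numeric())
  }
  list(blocks = blocks, tracks_a = tracks_a, tracks_b = tracks_b,
       schema_a = build_feature_schema(tracks_a),
       schema_b = build_feature_schema(tracks_b),
       a_genome = a_genome, b_genome = b_genome, b_sizes = b_sizes,
       variants = variants)
}

#' Audit the planted concordance of a fixture
#'
#' Samples aligned base positions, compares the latent truth states of the
#' two species there, and converts the raw agreement into a
#' chance-corrected concordance estimate
#' `(agreement - chance) / (1 - chance)`, where `chance` is the expected
#' agreement of independently drawn states given the observed marginal
#' state frequencies at aligned positions.
#'
#' @param dir Fixture directory written by [simulate_dataset()].
#' @param n_sample Number of aligned positions to sample.
#' @param seed Integer seed.
#' @return A one-row tibble: `agreement`, `chance`, `rho_hat`, `n`.
#' @export
concordance_audit <- function(dir, n_sample = 2e4, seed = 1L) {
  seed <- check_seed(seed)
  fx_sizes <- readr::read_tsv(file.path(dir, "genome_b.sizes"),
                              col_names = c("chrom", "size"), col_types = "cn",
                              show_col_types = FALSE)
  blocks <- load_alignment_blocks(file.path(dir, "alignment.axt"),
                                  setNames(fx_sizes$size, fx_sizes$chrom))
  read_truth <- function(sp) {
    readr::read_tsv(file.path(dir, "truth", sprintf("states_%s.synthetic.bed", sp)),
                    col_names = c("chrom", "start", "end", "state"),
                    col_types = "cnnc", show_col_types = FALSE)
  }
  truth_a <- read_truth("a"); truth_b <- read_truth("b")
  len <- blocks$a_end - blocks$a_start
  draw <- withr::with_seed(seed, {
    bi <- sample.int(nrow(blocks), n_sample, replace = TRUE,
                     prob = len / sum(len))
    off <- floor(runif(n_sample, 0, len[bi]))
    list(bi = bi, off = off)
  })
  blk <- blocks[draw$bi, ]
  a_pos <- blk$a_start + draw$off
  b_pos <- ifelse(blk$b_rev, blk$b_end - 1L - draw$off, blk$b_start + draw$off)
  sa <- truth_a$state[point_lookup(blk$a_chrom, a_pos, truth_a)]
  sb <- truth_b$state[point_lookup(blk$b_chrom, b_pos, truth_b)]
  ok <- !is.na(sa) & !is.na(sb)
  agree <- mean(sa[ok] == sb[ok])
  states <- union(unique(sa[ok]), unique(sb[ok]))
  fa <- table(factor(sa[ok], levels = states)) / sum(ok)
  fb <- table(factor(sb[ok], levels = states)) / sum(ok)
  chance <- sum(as.numeric(fa) * as.numeric(fb))
  tibble(agreement = agree, chance = chance,
         rho_hat = (agree - chance) / (1 - chance), n = sum(ok))
}
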