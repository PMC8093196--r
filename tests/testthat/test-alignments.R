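test_that("axt records parse and gap-free records give one block", {
  p <- write_axt_text(c(
    "0 chr1 101 160 chr2 501 560 + 5000",
    strrep("A", 60),
    strrep("C", 60),
    ""
  ))
  axt <- read_axt(p)
  expect_equal(nrow(axt), 1L)
  expect_equal(axt$a_start, 100)
  expect_equal(axt$a_end, 160)
  blocks <- alignment_blocks(axt)
  expect_equal(nrow(blocks), 1L)
  expect_equal(blocks$a_end - blocks$a_start, 60)
  expect_equal(blocks$b_end - blocks$b_start, 60)
})

test_that("a single gap column splits a record into two blocks", {
  # 61 columns, gap in B after the 30th: A is 61 bases, B is 60
  a_seq <- strrep("A", 61)
  b_seq <- paste0(strrep("C", 30), "-", strrep("C", 30))
  p <- write_axt_text(c("0 chr1 1 61 chr2 1 60 + 100", a_seq, b_seq, ""))
  blocks <- alignment_blocks(read_axt(p))
  expect_equal(nrow(blocks), 2L)
  expect_equal(blocks$a_end - blocks$a_start, c(30, 30))
  expect_equal(blocks$b_end - blocks$b_start, c(30, 30))
  # the A base in the gap column belongs to no block, so the second block's
  # A interval starts one base later; B coordinates are contiguous
  expect_equal(blocks$a_start, c(0, 31))
  expect_equal(blocks$b_start, c(0, 30))
})

test_that("malformed axt records are rejected with the record index", {
  p <- write_axt_text(c("0 chr1 1 10 chr2 1 10 + 100",
                        strrep("A", 10), strrep("C", 9), ""))
  expect_error(read_axt(p), "record 1")
  p2 <- write_axt_text(c("0 chr1 1 10 + 100", strrep("A", 10),
                         strrep("C", 10), ""))
  expect_error(read_axt(p2), "header")
})

test_that("reverse-strand query coordinates convert to forward strand", {
  # chr2 has size 1000; axt reverse coordinates 101-160 correspond to
  # forward-strand interval [840, 900)
  p <- write_axt_text(c("0 chr1 1 60 chr2 101 160 - 500",
                        strrep("A", 60), strrep("C", 60), ""))
  expect_error(read_axt(p), "b_sizes")
  axt <- read_axt(p, b_sizes = c(chr2 = 1000))
  expect_equal(axt$b_start, 840)
  expect_equal(axt$b_end, 900)
  rc <- reverse_coords(axt$b_start, axt$b_end, 1000)
  rc2 <- reverse_coords(rc$start, rc$end, 1000)
  expect_identical(rc2$start, axt$b_start)
  expect_identical(rc2$end, axt$b_end)
})

test_that("best-partner selection keeps the top-scoring candidate deterministically", {
  blocks <- tibble::tibble(
    block_id = 1:3,
    record = 1:3,
    a_chrom = "chr1", a_start = c(0, 10, 200), a_end = c(100, 110, 260),
    b_chrom = c("chr5", "chr2", "chr3"),
    b_start = c(0, 0, 0), b_end = c(100, 100, 60),
    b_rev = FALSE, score = c(500, 900, 100)
  )
  kept <- select_best_partner(blocks)
  expect_equal(kept$block_id, c(2L, 3L))
  # equal scores: tie broken by B chromosome then start, stably
  tie <- blocks |> dplyr::mutate(score = c(700, 700, 100))
  kept1 <- select_best_partner(tie)
  kept2 <- select_best_partner(tie)
  expect_identical(kept1, kept2)
  expect_equal(kept1$b_chrom[1], "chr2")
  expect_identical(select_best_partner(blocks[3, ]), blocks[3, ])
})

test_that("tiling covers each block exactly with ordered non-overlapping windows", {
  blk <- function(len) tibble::tibble(
    block_id = 1L, record = 1L, a_chrom = "chr1", a_start = 1000,
    a_end = 1000 + len, b_chrom = "chr2", b_start = 5000, b_end = 5000 + len,
    b_rev = FALSE, score = 1L
  )
  p120 <- tile_pairs(blk(120))
  expect_equal(p120$a_end - p120$a_start, c(50, 50, 20))
  expect_equal(sum(p120$a_end - p120$a_start), 120)
  expect_true(all(p120$a_start[-1] == head(p120$a_end, -1)))
  expect_equal(nrow(tile_pairs(blk(50))), 1L)
  p49 <- tile_pairs(blk(49))
  expect_equal(p49$a_end - p49$a_start, 49)
  # reverse-strand block: B windows run antiparallel but tile the B interval
  rev <- blk(120) |> dplyr::mutate(b_rev = TRUE)
  pr <- tile_pairs(rev)
  expect_equal(sort(pr$b_start), c(5000, 5020, 5070))
  expect_equal(sum(pr$b_end - pr$b_start), 120)
})

test_that("mismatch negatives form a derangement with identical marginals", {
  pos2 <- tibble::tibble(
    pair_id = c("p1", "p2"), block_id = 1:2,
    a_chrom = "chr1", a_start = c(0, 50), a_end = c(50, 100),
    b_chrom = "chr2", b_start = c(0, 50), b_end = c(50, 100),
    b_rev = FALSE, label = "positive"
  )
  out <- generate_training_pairs(pos2, "mismatch", seed = 1)
  neg <- out |> dplyr::filter(label == "negative")
  # only derangement of size 2 is the swap
  expect_equal(neg$b_start, c(50, 0))
  expect_error(generate_training_pairs(pos2[1, ], "mismatch", seed = 1),
               "at least 2")
  expect_error(generate_training_pairs(pos2, "mismatch"), "seed")

  pipe <- std_pipeline()
  pos <- pipe$positives[seq_len(1000), ]
  lab <- generate_training_pairs(pos, "mismatch", seed = 9)
  neg <- lab |> dplyr::filter(label == "negative")
  pos_key <- paste(pos$a_chrom, pos$a_start, pos$b_chrom, pos$b_start)
  neg_key <- paste(neg$a_chrom, neg$a_start, neg$b_chrom, neg$b_start)
  expect_equal(nrow(neg), 1000L)
  expect_length(intersect(pos_key, neg_key), 0L)
  # marginal multisets of each side identical between classes
  expect_identical(sort(paste(pos$b_chrom, pos$b_start)),
                   sort(paste(neg$b_chrom, neg$b_start)))
  expect_identical(sort(paste(pos$a_chrom, pos$a_start)),
                   sort(paste(neg$a_chrom, neg$a_start)))
  lab2 <- generate_training_pairs(pos, "mismatch", seed = 9)
  expect_identical(lab, lab2)
})

test_that("genome-background negatives sample both genomes", {
  pipe <- std_pipeline()
  pos <- pipe$positives[1:200, ]
  out <- generate_training_pairs(pos, "genome_background", seed = 5,
                                 a_genome = pipe$data$a_genome,
                                 b_genome = pipe$data$b_genome)
  neg <- out |> dplyr::filter(label == "negative")
  expect_equal(nrow(neg), 200L)
  expect_true(all(neg$a_end - neg$a_start == 50))
  expect_true(all(neg$a_start >= 0))
})

test_that("split assignment requires both chromosomes in a role and keeps roles disjoint", {
  scheme <- split_scheme(paste0("chr", 1:6))
  # default parity: train {1,3}, validation {5}, test {2,4,6}
  pairs <- tibble::tibble(
    pair_id = c("x1", "x2", "x3"),
    a_chrom = c("chr1", "chr1", "chr5"), a_start = 0, a_end = 50,
    b_chrom = c("chr3", "chr2", "chr5"), b_start = 0, b_end = 50,
    b_rev = FALSE, label = "positive"
  )
  out <- assign_splits(pairs, scheme)
  expect_equal(out$role, c("train", "predict", "validation"))
  expect_error(
    split_scheme(paste0("chr", 1:6), train = list(a = "chr1", b = "chr1"),
                 validation = list(a = "chr1", b = "chr3"),
                 test = list(a = "chr2", b = "chr2")),
    "overlap"
  )
})

test_that("no genomic region is shared between train/validation/test roles", {
  pipe <- std_pipeline()
  lab <- pipe$labeled
  roles <- c("train", "validation", "test")
  for (side in c("a", "b")) {
    cols <- paste0(side, c("_chrom", "_start", "_end"))
    grs <- lapply(roles, function(r) {
      x <- lab[lab$role == r, ]
      GenomicRanges::GRanges(x[[cols[1]]],
                             IRanges::IRanges(x[[cols[2]]] + 1, x[[cols[3]]]))
    })
    for (i in 1:2) for (j in (i + 1):3) {
      # roles live on disjoint chromosome sets, so the seqlevel warning from
      # intersect() is expected
      ov <- suppressWarnings(
        GenomicRanges::intersect(GenomicRanges::reduce(grs[[i]]),
                                 GenomicRanges::reduce(grs[[j]]))
      )
      expect_equal(length(ov), 0L,
                   info = sprintf("%s side, %s vs %s", side, roles[i], roles[j]))
    }
  }
})

test_that("pair tables round-trip through the TSV/BED writers", {
  pipe <- std_pipeline()
  prefix <- file.path(tempdir(), "pairs_out")
  paths <- write_pairs(pipe$labeled[1:20, ], prefix)
  tsv <- readr::read_tsv(paths[1], show_col_types = FALSE)
  expect_equal(nrow(tsv), 20L)
  expect_equal(tsv$a_start, pipe$labeled$a_start[1:20])
  bed <- readr::read_tsv(paths[2], col_names = FALSE, show_col_types = FALSE)
  expect_equal(nrow(bed), 20L)
})
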