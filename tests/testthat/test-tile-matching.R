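test_that("adapter search returns the first exact 0-based occurrence", {
  expect_equal(find_adapter(paste0("AAAA", ADAPTER, "CCGT"), ADAPTER), 4L)
  expect_equal(find_adapter(paste0(ADAPTER, "CCGT"), ADAPTER), 0L)
  expect_true(is.na(find_adapter("ACGTACGTACGT", ADAPTER)))
})

test_that("UMI extraction takes the bases immediately before the adapter", {
  read <- paste0("ACGTACGTAT", ADAPTER, "AAA")
  expect_equal(extract_umi(read, 10L, 10L), "ACGTACGTAT")
  expect_true(is.na(extract_umi(read, 4L, 10L))) # truncated UMI
  expect_equal(extract_umi(read, 10L, 0L), "")
})

test_that("candidate scoring enforces quality, seed and total mismatch rules", {
  cfg <- matcher_config()
  tile <- strrep("ACGT", 10) # 40 nt
  q40 <- rep(40L, 40)

  # identical insert, all Q40
  expect_equal(score_candidate(tile, q40, tile, cfg),
               list(valid = TRUE, seed_mm = 0L, total_mm = 0L))

  mutate_at <- function(seq, pos) {
    for (p in pos) substr(seq, p, p) <- if (substr(seq, p, p) == "A") "C" else "A"
    seq
  }

  # one mismatch at position 3 with Q40
  expect_equal(score_candidate(mutate_at(tile, 3), q40, tile, cfg),
               list(valid = TRUE, seed_mm = 1L, total_mm = 1L))

  # same mismatch but Q30 at that base: mismatch not tolerated
  q <- q40; q[3] <- 30L
  expect_false(score_candidate(mutate_at(tile, 3), q, tile, cfg)$valid)

  # three Q40 mismatches inside the 15-nt seed exceed the seed budget
  expect_false(score_candidate(mutate_at(tile, c(1, 5, 9)), q40, tile, cfg)$valid)

  # five Q40 mismatches beyond the seed exceed the overall budget
  expect_false(
    score_candidate(mutate_at(tile, c(20, 24, 28, 32, 36)), q40, tile, cfg)$valid)

  # empty overlap is invalid
  expect_false(score_candidate("", integer(0), tile, cfg)$valid)
})

test_that("match_read picks the unique minimum-mismatch tile and discards ties", {
  tile_a <- strrep("A", 40)
  tile_b <- paste0(strrep("A", 36), "CCCC")
  lib <- tilefate:::as_tile_library(data.frame(
    tile_id = c("A", "B"), gene = NA, sequence = c(tile_a, tile_b)))

  # insert 1 mismatch from A, 3 from B -> matched to A
  ins <- paste0(strrep("A", 35), "CAAAA")
  expect_equal(match_read(make_read(ins), lib)$status, "matched")
  expect_equal(match_read(make_read(ins), lib)$tile_id, "A")

  # equidistant insert (2 mm from each) -> ambiguous
  tie <- paste0(strrep("A", 36), "CCAA")
  out <- match_read(make_read(tie), lib)
  expect_equal(out$status, "ambiguous")
  expect_true(is.na(out$tile_id))

  # adapter present but no tile within the thresholds
  out <- match_read(make_read(strrep("G", 40)), lib)
  expect_equal(out$status, "unmatched")

  # no adapter at all
  expect_equal(match_read(list(sequence = strrep("A", 60),
                               quality = phred_string(rep(40, 60))),
                          lib)$status, "no_adapter")
})

test_that("matcher agrees with the exhaustive brute-force oracle", {
  set.seed(42)
  lib <- generate_tile_library(20, 50, seed = 43)
  cfg <- matcher_config()
  for (i in 1:200) {
    kind <- sample(3, 1)
    if (kind == 1) { # tile with random errors, random qualities
      ins <- strsplit(sample(lib$sequence, 1), "")[[1]]
      nmm <- sample(0:6, 1)
      pos <- sample(50, nmm)
      ins[pos] <- sample(c("A", "C", "G", "T"), nmm, replace = TRUE)
      read <- make_read(paste(ins, collapse = ""),
                        qual = phred_string(sample(28:41, 80, replace = TRUE)))
    } else if (kind == 2) { # random insert
      read <- make_read(random_dna(50),
                        qual = phred_string(sample(28:41, 80, replace = TRUE)))
    } else { # no adapter
      read <- list(sequence = random_dna(80),
                   quality = phred_string(rep(40, 80)))
    }
    expected <- oracle_match(read, lib, cfg)
    got <- match_read(read, lib, cfg)
    got_str <- if (got$status == "matched") paste0("matched:", got$tile_id)
               else got$status
    expect_equal(got_str, expected)
  }
})

test_that("tile counting tallies constructed reads and deduplicates UMIs", {
  lib <- tilefate:::as_tile_library(data.frame(
    tile_id = c("A", "B"), gene = NA,
    sequence = c(strrep("AC", 20), strrep("GT", 20))))
  umis <- vapply(1:100, function(i) random_dna(10), character(1))
  reads <- data.table::rbindlist(lapply(1:100, function(i) {
    tile <- if (i <= 30) lib$sequence[1] else lib$sequence[2]
    r <- make_read(tile, umi = umis[i])
    data.table::data.table(id = paste0("r", i), sequence = r$sequence,
                           quality = r$quality)
  }))
  cm <- count_tiles(reads, lib, matcher_config(count_mode = "read"))
  expect_equal(unname(cm$counts[c("A", "B")]), c(30L, 70L))

  # 10 reads of tile A sharing one UMI
  one_umi <- data.table::rbindlist(lapply(1:10, function(i) {
    r <- make_read(lib$sequence[1], umi = strrep("A", 10))
    data.table::data.table(id = paste0("r", i), sequence = r$sequence,
                           quality = r$quality)
  }))
  expect_equal(unname(count_tiles(one_umi, lib,
                                  matcher_config(count_mode = "umi"))$counts["A"]),
               1L)
  expect_equal(unname(count_tiles(one_umi, lib,
                                  matcher_config(count_mode = "read"))$counts["A"]),
               10L)
})

test_that("status totals always partition the input reads", {
  set.seed(77)
  lib <- generate_tile_library(10, 40, seed = 78)
  for (rep in 1:20) {
    reads <- data.table::rbindlist(lapply(1:30, function(i) {
      r <- switch(sample(3, 1),
                  make_read(random_dna(40),
                            qual = phred_string(sample(20:41, 70, replace = TRUE))),
                  make_read(sample(lib$sequence, 1)),
                  list(sequence = random_dna(70),
                       quality = phred_string(rep(40, 70))))
      data.table::data.table(id = paste0("r", i), sequence = r$sequence,
                             quality = r$quality)
    }))
    st <- count_tiles(reads, lib)$stats
    expect_equal(st$matched + st$no_adapter + st$unmatched + st$ambiguous,
                 st$total)
    expect_equal(st$total, nrow(reads))
  }
})

test_that("raising quality_min only moves reads out of the matched class", {
  set.seed(99)
  lib <- generate_tile_library(15, 40, seed = 100)
  reads <- lapply(1:100, function(i) {
    ins <- strsplit(sample(lib$sequence, 1), "")[[1]]
    pos <- sample(40, 2)
    ins[pos] <- sample(c("A", "C", "G", "T"), 2, replace = TRUE)
    make_read(paste(ins, collapse = ""),
              qual = phred_string(sample(30:41, 70, replace = TRUE)))
  })
  match_at <- function(qmin) {
    vapply(reads, function(r) {
      m <- match_read(r, lib, matcher_config(quality_min = qmin))
      if (m$status == "matched") m$tile_id else NA_character_
    }, character(1))
  }
  loose <- match_at(30L)
  strict <- match_at(38L)
  still <- !is.na(strict)
  expect_true(all(!is.na(loose[still])))
  expect_equal(strict[still], loose[still])
})
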