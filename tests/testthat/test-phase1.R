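test_that("bin assignment is deterministic and balanced", {
  expect_true(all(assign_file(c(0, 5, 1000), 1) == 0))
  expect_identical(assign_file(123, 512), assign_file(123, 512))
  ids <- assign_file(0:99, 7)
  expect_true(all(ids >= 0 & ids < 7))
  # occupancy over all 4^7 ranks at F = 512
  occ <- tabulate(assign_file(0:(4^7 - 1), 512) + 1L, nbins = 512)
  expect_lte(max(occ) / mean(occ), 1.5)
})

test_that("super-mer records round-trip through the bin format", {
  path <- tempfile(fileext = ".smr")
  write_supermers(path, "CAAGA", rank = 2, append = FALSE)
  got <- read_supermers(path)
  expect_identical(got$supermer, "CAAGA")
  expect_identical(got$rank, 2)
  # n_kmers for k = 4: 5 - 4 + 1 = 2
  expect_identical(nchar(got$supermer) - 4L + 1L, 2L)

  # fuzz round-trip, including lengths not divisible by 4
  withr::with_seed(3, {
    sms <- vapply(1:1000, function(i)
      paste(sample(BASES, sample(4:80, 1), replace = TRUE), collapse = ""),
      character(1))
    ranks <- sample(0:(4^7 - 1), 1000, replace = TRUE)
  })
  p2 <- tempfile(fileext = ".smr")
  write_supermers(p2, sms[1:500], ranks[1:500], append = FALSE)
  write_supermers(p2, sms[501:1000], ranks[501:1000], append = TRUE)
  got2 <- read_supermers(p2)
  expect_identical(got2$supermer, sms)
  expect_identical(got2$rank, as.numeric(ranks))
})

test_that("corrupt bin records are reported with their index", {
  path <- tempfile(fileext = ".smr")
  write_supermers(path, c("ACGTACGT", "CCCCC"), rank = c(1, 2),
                  append = FALSE)
  sz <- file.size(path)
  con <- file(path, "ab")
  writeBin(as.raw(c(9, 0, 1)), con)  # truncated third record
  close(con)
  expect_error(read_supermers(path), "record 3")
})

test_that("phase 1 distributes the worked single-read example", {
  cfg <- phase1_config(k = 4, m = 3, ordering = build_ordering("lex", m = 3),
                       canonical = FALSE, bins = 4,
                       temp_dir = tempfile("p1-"))
  reads <- data.frame(id = "r1", seq = "CAAGAACAGTG")
  res <- run_phase1(reads, cfg)
  expect_identical(sum(res$bins$n_supermers), 5)
  expect_identical(sum(res$bins$n_kmers), 8)   # 11 - 4 + 1 windows
  recs <- do.call(rbind, lapply(res$bins$path[res$bins$n_supermers > 0],
                                read_supermers))
  expect_setequal(recs$supermer, c("CAAGA", "AGAA", "GAACA", "ACAG", "CAGTG"))
  expect_true(file.exists(res$manifest))
  unlink(cfg$temp_dir, recursive = TRUE)
})

test_that("reads shorter than k produce empty bins", {
  cfg <- phase1_config(k = 10, m = 3, ordering = build_ordering("lex", m = 3),
                       bins = 4, temp_dir = tempfile("p1-"))
  res <- run_phase1(data.frame(id = c("a", "b"), seq = c("ACGT", "CCGTAGG")),
                    cfg)
  expect_identical(sum(res$bins$n_kmers), 0)
  expect_identical(sum(res$bins$n_supermers), 0)
  unlink(cfg$temp_dir, recursive = TRUE)
})

test_that("bins conserve and partition the k-mer multiset", {
  reads <- data.frame(
    id = sprintf("r%d", 1:60),
    seq = vapply(1:60, function(i) random_dna(sample(20:90, 1),
                                              seed = 1100 + i), ""))
  for (canon in c(FALSE, TRUE)) {
    cfg <- phase1_config(k = 11, m = 5, canonical = canon, bins = 16,
                         temp_dir = tempfile("p1-"))
    res <- run_phase1(reads, cfg)
    # conservation of total window count
    direct <- oracle_count(reads, 11, canonical = canon)
    expect_identical(sum(res$bins$n_kmers), sum(direct$count))
    # multiset of k-mers across bins equals a direct scan of the reads
    per_bin <- lapply(which(res$bins$n_supermers > 0), function(i) {
      recs <- read_supermers(res$bins$path[i])
      kmers <- unlist(lapply(recs$supermer, function(s)
        substring(s, 1:(nchar(s) - 10), 11:nchar(s))))
      if (canon) kmers <- vapply(kmers, function(x) min(x, rc_chr(x)), "",
                                 USE.NAMES = FALSE)
      kmers
    })
    all_kmers <- sort(unlist(per_bin))
    expect_identical(all_kmers,
                     rep(direct$kmer, times = direct$count))
    # partition property: each distinct k-mer lives in exactly one bin
    homes <- table(unlist(lapply(seq_along(per_bin), function(j)
      paste(unique(per_bin[[j]]), j))))
    seen <- table(vapply(strsplit(names(homes), " "), `[[`, "", 1L))
    expect_true(all(seen == 1))
    unlink(cfg$temp_dir, recursive = TRUE)
  }
})

test_that("phase 1 is byte-deterministic for fixed parameters", {
  reads <- data.frame(id = "r", seq = random_dna(500, seed = 55))
  run <- function() {
    cfg <- phase1_config(k = 15, m = 5, bins = 8,
                         temp_dir = tempfile("p1-"))
    res <- run_phase1(reads, cfg)
    h <- lapply(res$bins$path, function(p) readBin(p, "raw",
                                                   file.size(p) + 1))
    unlink(cfg$temp_dir, recursive = TRUE)
    h
  }
  expect_identical(run(), run())
})
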