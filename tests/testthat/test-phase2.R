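test_that("probe schedule is deterministic and covers a power-of-two table", {
  x <- "ACGTACGTACGTACGTACGTACGTACGT"
  expect_identical(probe_hash(x, 0, 1024), probe_hash(x, 0, 1024))
  slots <- probe_hash(x, 0:1023, 1024)
  expect_true(all(slots >= 0 & slots < 1024))
  # triangular increments visit at least half the table (in fact all of it)
  expect_gte(length(unique(slots)), 512)
})

test_that("near-identical k-mers rarely collide on probe 0", {
  withr::with_seed(5, {
    coll <- 0L
    for (i in 1:2000) {
      a <- sample(BASES, 28, replace = TRUE)
      b <- a
      p <- sample(28, 1)
      b[p] <- sample(setdiff(BASES, a[p]), 1)
      sa <- probe_hash(paste(a, collapse = ""), 0, 2^20)
      sb <- probe_hash(paste(b, collapse = ""), 0, 2^20)
      if (sa == sb) coll <- coll + 1L
    }
    expect_lt(coll / 2000, 0.01)
  })
})

test_that("partition hash is deterministic, bounded, uniform and cheap", {
  expect_identical(part_hash("ACGTACGT"), part_hash("ACGTACGT"))
  kmers <- random_kmers(1e5, 28, seed = 9)
  ph <- part_hash(kmers)
  expect_true(all(ph >= 0 & ph < 2^16))
  buckets <- tabulate(ph %% 256 + 1L, nbins = 256)
  expect_lte(max(buckets) / mean(buckets), 1.3)
  # constant-time contract: only the first 4 blocks of 8 bases matter
  base32 <- strrep("ACGT", 8)
  expect_identical(part_hash(paste0(base32, "AAAA")),
                   part_hash(paste0(base32, "TTTT")))
})

test_that("probing hash and partition hash are independent", {
  kmers <- random_kmers(2e4, 28, seed = 14)
  p0 <- vapply(kmers, probe_hash, numeric(1), i = 0, capacity = 2^20,
               USE.NAMES = FALSE)
  tab <- table(p0 %% 16, part_hash(kmers) %% 16)
  ct <- suppressWarnings(stats::chisq.test(tab))
  expect_gt(ct$p.value, 0.01)
})

test_that("table sizing follows the alpha/beta model", {
  expect_identical(table_size(1000, alpha = 0.15, beta = 0.4), 375)
  expect_identical(table_size(0, alpha = 0.5), 1)
  withr::with_seed(21, {
    for (i in 1:100) {
      n <- sample(0:1e6, 1)
      a <- runif(1, 0.01, 1)
      b <- runif(1, 0.05, 0.95)
      expect_identical(table_size(n, a, b), max(1, ceiling(a * n / b)))
    }
  })
  expect_error(table_size(10, alpha = 0), "alpha")
  expect_error(table_size(10, alpha = 0.5, beta = 1), "beta")
})

test_that("insertion counts duplicates, respects i_max and never corrupts", {
  tb <- new_count_table(4, 16, i_max = 30)
  expect_true(all(table_insert(tb, c("ACGT", "ACGT"))))
  got <- table_counts(tb)
  expect_identical(got$kmer, "ACGT")
  expect_identical(got$count, 2)

  # i_max = 0: every insertion fails, table unchanged
  tb0 <- new_count_table(4, 16, i_max = 0)
  expect_false(any(table_insert(tb0, c("ACGT", "AAAA"))))
  expect_identical(nrow(table_counts(tb0)), 0L)

  # saturated table: a fresh key fails and the table is unchanged
  tbf <- new_count_table(6, 4, i_max = 30)
  kms <- random_kmers(200, 6, seed = 33)
  invisible(table_insert(tbf, kms))         # fills all 4 slots
  before <- table_counts(tbf)
  expect_identical(nrow(before), 4L)
  fresh <- setdiff(random_kmers(50, 6, seed = 34), before$kmer)[1]
  expect_false(table_insert(tbf, fresh))
  after <- table_counts(tbf)
  expect_identical(before[order(before$kmer), ], after[order(after$kmer), ])
})

test_that("filling an exactly sized table reaches the target fill level", {
  kmers <- unique(random_kmers(2.2e4, 24, seed = 44))[1:2e4]
  cap <- table_size(2e4, alpha = 1, beta = 0.4)
  tb <- new_count_table(24, cap, i_max = 30)
  res <- table_insert(tb, kmers)
  expect_true(all(res))
  st <- table_stats(tb)
  expect_lt(abs(st$fill - 0.4), 0.04)
  expect_lt(st$mean_probes, 3)
})

test_that("pass planning matches the ceiling formula and partitions k-mers", {
  expect_identical(plan_passes(10, 4)$p, 3)
  expect_identical(plan_passes(5, 10)$p, 1)
  expect_identical(plan_passes(0, 10)$p, 1)
  withr::with_seed(26, {
    for (i in 1:100) {
      n <- sample(0:1e7, 1)
      tm <- sample(1:1e6, 1)
      expect_identical(plan_passes(n, tm)$p, max(1, ceiling(n / tm)))
    }
  })
  # pass selection by part_hash(x) mod p partitions the k-mers exactly
  kmers <- random_kmers(1e4, 28, seed = 17)
  p <- 3
  sel <- lapply(0:(p - 1), function(i) kmers[part_hash(kmers) %% p == i])
  expect_identical(sort(unlist(sel)), sort(kmers))
  expect_identical(sum(lengths(sel)), length(kmers))
})

test_that("shard routing is deterministic and balanced", {
  expect_true(all(shard_id(random_kmers(20, 12, seed = 1), 1) == 0))
  kmers <- random_kmers(1e5, 28, seed = 13)
  s <- shard_id(kmers, 4)
  expect_identical(s, part_hash(kmers) %% 4L)
  loads <- tabulate(s + 1L, nbins = 4)
  expect_lte(max(loads) / mean(loads), 1.1)
})

test_that("alpha estimator tracks distinct/total per bin", {
  est <- alpha_estimator(0.5)
  est <- update_alpha(est, 150, 1000)
  expect_identical(est$alpha, 0.15)
  expect_identical(est$alpha_prev, 0.5)
  est0 <- update_alpha(est, 0, 0)   # empty bin leaves alpha unchanged
  expect_identical(est0$alpha, 0.15)
  # identical bins converge after one bin
  est2 <- update_alpha(update_alpha(alpha_estimator(), 30, 100), 30, 100)
  expect_identical(est2$alpha, est2$alpha_prev)
})

test_that("bin counting is exact for all i_max/t_max/shard settings", {
  lex <- build_ordering("lex", m = 3)
  # worked example: all 8 windows distinct
  p1 <- tempfile(fileext = ".smr")
  sm <- super_mers("CAAGAACAGTG", 4, lex)
  write_supermers(p1, sm$supermer, sm$rank, append = FALSE)
  res <- count_bin(p1, k = 4, n_kmers = 8, canonical = FALSE)
  expect_identical(nrow(res$counts), 8L)
  expect_true(all(res$counts$count == 1))

  # repeated windows accumulate
  p2 <- tempfile(fileext = ".smr")
  write_supermers(p2, "AAAAA", 0, append = FALSE)
  res2 <- count_bin(p2, k = 4, n_kmers = 2, canonical = FALSE)
  expect_identical(res2$counts$kmer, "AAAA")
  expect_identical(res2$counts$count, 2)

  # oracle equivalence under stress settings, seed 17
  reads <- data.frame(id = "r", seq = random_dna(4000, seed = 17))
  for (canon in c(FALSE, TRUE)) {
    cfg <- phase1_config(k = 9, m = 4, canonical = canon, bins = 1,
                         temp_dir = tempfile("cb-"))
    ph1 <- run_phase1(reads, cfg)
    b <- ph1$bins[1, ]
    want <- oracle_count(reads, 9, canonical = canon)
    for (imax in c(1L, 2L, 30L)) {
      for (tmax in c(2^40, ceiling(b$n_kmers / 3))) {
        for (N in c(1L, 4L)) {
          res <- count_bin(b, k = 9, canonical = canon, i_max = imax,
                           t_max = tmax, n_shards = N)
          got <- res$counts[order(res$counts$kmer, method = "radix"), ]
          rownames(got) <- NULL
          expect_counts_equal(got, want)
          expect_identical(res$stats$passes,
                           as.integer(plan_passes(b$n_kmers, tmax)$p))
        }
      }
    }
    unlink(cfg$temp_dir, recursive = TRUE)
  }
})
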