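all_mmers <- function(m) {
  vapply(0:(4^m - 1), value_mmer, character(1), m = m)
}

test_that("CGAT ordering ranks single bases C<G<A<T", {
  ord <- build_ordering("cgat", m = 1)
  names(ord$rank) <- all_mmers(1)
  expect_identical(ord$rank[c("C", "G", "A", "T")], c(C = 0L, G = 1L,
                                                      A = 2L, T = 3L))
})

test_that("Roberts ordering complements even positions, then C<A<T<G", {
  ord <- build_ordering("roberts", m = 2)
  # independent string-level oracle over all 16 2-mers
  mm <- all_mmers(2)
  transformed <- vapply(mm, function(s) {
    v <- strsplit(s, "")[[1]]
    v[1] <- chartr("ACGT", "TGCA", v[1])  # position 0 is even
    paste(v, collapse = "")
  }, character(1))
  key <- vapply(transformed, function(s)
    chartr("CATG", "ABCD", s), character(1))  # C<A<T<G as A<B<C<D
  expect_identical(as.integer(rank(key)) - 1L, ord$rank)
})

test_that("KMC2 ordering demotes AAA/ACA prefixes after all others", {
  ord <- build_ordering("kmc2", m = 3)
  names(ord$rank) <- all_mmers(3)
  expect_setequal(ord$rank, 0:63)                       # bijection
  expect_setequal(ord$rank[c("AAA", "ACA")], c(62L, 63L))
  expect_lt(max(ord$rank[setdiff(all_mmers(3), c("AAA", "ACA"))]), 62L)
  # demoted class keeps lexicographic order
  expect_lt(ord$rank["AAA"], ord$rank["ACA"])
  # m = 4: demotion applies to all m-mers with those prefixes
  ord4 <- build_ordering("kmc2", m = 4)
  names(ord4$rank) <- all_mmers(4)
  demoted <- grepl("^(AAA|ACA)", all_mmers(4))
  expect_true(min(ord4$rank[demoted]) > max(ord4$rank[!demoted]))
})

test_that("random ordering is a seeded permutation, reproducible", {
  o1 <- build_ordering("random", m = 3, seed = 7)
  o2 <- build_ordering("random", m = 3, seed = 7)
  o3 <- build_ordering("random", m = 3, seed = 8)
  expect_identical(o1$rank, o2$rank)
  expect_false(identical(o1$rank, o3$rank))
  expect_setequal(o1$rank, 0:63)
  expect_error(build_ordering("random", m = 3), "seed")
})

test_that("dfp ordering sorts by frequency then distance from pivot", {
  # m = 1 hand-worked case: frequencies A=10, C=1, G=5, T=2
  # ascending frequency: C(0), T(1), G(2), A(3)
  fr <- c(10, 1, 5, 2)
  # pivot 0: distance = initial position; rank order C,T,G,A
  o0 <- build_ordering("dfp", m = 1, pivot = 0, frequencies = fr)
  names(o0$rank) <- all_mmers(1)
  expect_identical(o0$rank[c("C", "T", "G", "A")],
                   c(C = 0L, T = 1L, G = 2L, A = 3L))
  # pivot 1: pivot position 4; distances A=1,G=2,T=3,C=4
  o1 <- build_ordering("dfp", m = 1, pivot = 1, frequencies = fr)
  names(o1$rank) <- all_mmers(1)
  expect_identical(o1$rank[c("A", "G", "T", "C")],
                   c(A = 0L, G = 1L, T = 2L, C = 3L))
  expect_error(build_ordering("dfp", m = 1, pivot = 0.5), "frequencies")
})

test_that("rank tables are bijections for every strategy", {
  fr <- sample_frequencies(random_dna(5000, seed = 12), m = 5)
  for (m in c(2L, 5L)) {
    for (strat in c("lex", "cgat", "roberts", "kmc2", "random", "dfp")) {
      ord <- build_ordering(strat, m = m,
                            seed = if (strat == "random") 3L else NULL,
                            pivot = if (strat == "dfp") 0.5 else NULL,
                            frequencies = if (strat == "dfp")
                              sample_frequencies(random_dna(5000, seed = 12),
                                                 m = m) else NULL)
      expect_identical(sort(ord$rank), 0:(4^m - 1L))
    }
  }
  expect_error(build_ordering("lex", m = 0), "m must be")
  expect_error(build_ordering("lex", m = 16), "m must be")
})

test_that("m-mer frequency sampling counts every window", {
  fr <- sample_frequencies("AAAA", m = 3)
  expect_identical(fr[mmer_value("AAA") + 1], 2)
  expect_identical(sum(fr), 2)
  expect_identical(sum(sample_frequencies(character(0), m = 3)), 0)
  # conservation: counts sum to the number of windows scanned
  reads <- vapply(1:20, function(i) random_dna(50, seed = 200 + i), "")
  fr2 <- sample_frequencies(reads, m = 4)
  expect_identical(sum(fr2), 20 * (50 - 4 + 1))
  # N splits fragments
  fr3 <- sample_frequencies("AANAA", m = 2)
  expect_identical(sum(fr3), 2)
})

test_that("minimizer of a k-mer is the minimal-rank window", {
  lex <- build_ordering("lex", m = 3)
  expect_identical(minimizer_of("CAAG", lex)$mmer, "AAG")
  expect_identical(minimizer_of("AAAA", lex)$mmer, "AAA")
  expect_identical(minimizer_of("ACAG", lex)$mmer, "ACA")
  # positional tie-break: leftmost occurrence wins
  expect_identical(minimizer_of("AAAA", lex)$pos, 0L)
  # canonical mode takes the min over both strands
  res <- minimizer_of("TTTG", lex, canonical = TRUE)
  expect_identical(res$mmer, "AAA")
  expect_identical(res$strand, "-")
  expect_error(minimizer_of("AC", lex), "smaller than m")
})

test_that("super-mer decomposition conserves and partitions the k-mer windows", {
  lex <- build_ordering("lex", m = 3)
  # fragment of exactly k is a single super-mer
  sm1 <- super_mers("ACGT", 4, lex)
  expect_identical(sm1$supermer, "ACGT")
  expect_identical(sm1$n_kmers, 1L)

  for (i in 1:100) {
    L <- sample(28:150, 1)
    frag <- random_dna(L, seed = 700 + i)
    for (canon in c(FALSE, TRUE)) {
      sm <- super_mers(frag, 28, lex, canonical = canon)
      # conservation of window count
      expect_identical(sum(sm$n_kmers), L - 28L + 1L)
      # windows reconstructed in order equal the direct scan
      windows <- unlist(lapply(seq_len(nrow(sm)), function(j) {
        s <- sm$supermer[j]
        substring(s, 1:(nchar(s) - 27), 28:nchar(s))
      }))
      direct <- substring(frag, 1:(L - 27), 28:L)
      expect_identical(windows, direct)
      # super-mers span from first k-mer start to last k-mer end
      expect_identical(substring(frag, sm$start + 1,
                                 sm$start + nchar(sm$supermer)),
                       sm$supermer)
    }
  }
})

test_that("a super-mer breaks exactly when the minimizer occurrence moves", {
  lex <- build_ordering("lex", m = 3)
  for (i in 1:25) {
    frag <- random_dna(80, seed = 900 + i)
    for (canon in c(FALSE, TRUE)) {
      sm <- super_mers(frag, 10, lex, canonical = canon)
      # occurrence of the minimal m-mer per window, in fragment coordinates
      occ <- vapply(1:(80 - 10 + 1), function(s) {
        w <- substr(frag, s, s + 9)
        mo <- minimizer_of(w, lex, canonical = canon)
        paste0(s - 1 + mo$pos, mo$strand)
      }, character(1))
      # group windows by run of identical occurrences: must match super-mers
      runs <- rle(occ)
      expect_identical(as.integer(runs$lengths), sm$n_kmers)
      # adjacent super-mers have different occurrences by construction of rle
      expect_identical(length(runs$lengths), nrow(sm))
    }
  }
})
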