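test_that("chunk plans partition the loci near-equally", {
  expect_identical(plan_chunks(100, 4)$boundaries, c(0L, 25L, 50L, 75L, 100L))
  expect_identical(plan_chunks(10, 3)$boundaries, c(0L, 4L, 7L, 10L))
  expect_identical(plan_chunks(7, 1)$boundaries, c(0L, 7L))
  for (N in c(5L, 17L, 64L)) for (T in c(1L, 2L, 3L, 5L)) {
    b <- plan_chunks(N, T)$boundaries
    expect_identical(length(b), T + 1L)
    expect_true(all(diff(b) >= 1L))
    expect_lte(max(diff(b)) - min(diff(b)), 1L)
    expect_identical(b[c(1L, T + 1L)], c(0L, N))
  }
  expect_error(plan_chunks(5, 6), "T <= N")
  expect_error(plan_chunks(5, 0), "T <= N")
})

test_that("prefix-array inversion maps ids back to positions", {
  expect_identical(invert_prefix(c(0L, 1L, 2L)), c(0L, 1L, 2L))
  expect_identical(invert_prefix(c(2L, 0L, 1L)), c(1L, 2L, 0L))
  expect_identical(invert_prefix(c(1L, 0L)), c(1L, 0L))
  a <- withr::with_seed(3, sample(0:19))
  ai <- invert_prefix(a)
  expect_identical(ai[a + 1L], 0:19)
  expect_error(invert_prefix(c(0L, 0L, 2L)), "permutation")
})

test_that("group correction restores previous-chunk order and divergences", {
  # group [0, 2) holding haplotypes 0 and 2; previous arrays a=[2,0,1], d=[3,1,2]
  res <- correct_group(a_k = c(0L, 2L, 1L), d_k = c(9L, 5L, 7L),
                       start = 0, stop = 2,
                       a_prev = c(2L, 0L, 1L), d_prev = c(3L, 1L, 2L))
  # positions of (0, 2) in a_prev are (1, 0); sorted -> (0, 1); order (2, 0)
  expect_identical(res$a, c(2L, 0L, 1L))
  # window between positions 0 and 1 (half-open (0, 1]) -> max d_prev[1] = 1
  expect_identical(res$d, c(9L, 1L, 7L))
  expect_identical(res$sort_size, 2L)
  expect_identical(res$scan_work, 1L)
  # group already in previous order with adjacent positions is a fixed point,
  # and each interior divergence is the previous value at its own position
  res <- correct_group(a_k = c(3L, 0L, 1L, 2L), d_k = c(9L, 8L, 4L, 4L),
                       start = 1, stop = 4,
                       a_prev = c(0L, 1L, 2L, 3L), d_prev = c(6L, 3L, 1L, 2L))
  expect_identical(res$a, c(3L, 0L, 1L, 2L))
  expect_identical(res$d, c(9L, 8L, 3L, 1L))
  # size-2 group with one intervening haplotype in the previous chunk: the
  # max-window spans 2 entries
  res <- correct_group(a_k = c(0L, 2L, 1L), d_k = c(9L, 5L, 7L),
                       start = 0, stop = 2,
                       a_prev = c(0L, 1L, 2L), d_prev = c(6L, 1L, 4L))
  expect_identical(res$a, c(0L, 2L, 1L))
  expect_identical(res$d[2L], max(1L, 4L))
  expect_identical(res$scan_work, 2L)
  expect_error(correct_group(0:1, c(0L, 0L), 0, 1, 0:1, c(0L, 0L)),
               "at least 2")
})

test_that("sentinel groups are the maximal runs of chunk-identical haplotypes", {
  # all-distinct chunk: no groups
  pan <- haplotype_panel(rbind(c(1, 0, 0), c(1, 0, 1), c(1, 1, 0)))
  ap <- pbwt_build_chunk(pan, 1, 3)
  expect_identical(nrow(sentinel_groups(ap)), 0L)
  # all-identical chunk: one full group, every d at the sentinel but the first
  pan <- sim_panel(6, 8, dup_groups = list(c(6, 0, 8)), seed = 1)
  ap <- pbwt_build_chunk(pan, 2, 8)
  expect_identical(as.data.frame(sentinel_groups(ap)),
                   data.frame(start = 0L, stop = 6L, size = 6L))
  expect_identical(ap$d[-1L], rep(2L, 5L))
  # planted duplicate pair: some group covers both of its haplotypes
  pan <- sim_panel(8, 16, dup_groups = list(c(2, 0, 16)), seed = 5)
  ap <- pbwt_build_chunk(pan, 8, 16)
  g <- sentinel_groups(ap)
  pos <- match(c(0L, 1L), ap$a) - 1L
  expect_true(any(g$start <= min(pos) & g$stop > max(pos)))
})

test_that("first chunk needs no correction and T = 1 degenerates to the sequential build", {
  pan <- random_panel(11, M = 12, N = 30, rate = 0.5)
  ap <- pbwt_build_chunk(pan, 0, 30)
  expect_true(ap$corrected)
  expect_state_equal(correct_state(ap, pbwt_init(12)), pbwt_build(pan, 30))
  states <- pbwt_build_parallel(pan, 1)
  expect_identical(length(states), 1L)
  expect_state_equal(states[[1L]], pbwt_build(pan, 30))
})

test_that("corrected boundary states equal the sequential build exactly", {
  for (seed in 1:60) {
    pan <- random_panel(200 + seed, mmax = 32L, nmax = 64L, nmin = 2L)
    N <- n_loci(pan)
    for (T in c(2L, 3L, 5L, 8L)) {
      if (T > N) next
      bounds <- plan_chunks(N, T)$boundaries
      states <- pbwt_build_parallel(pan, T)
      for (t in seq_len(T)) {
        tru <- pbwt_build(pan, bounds[t + 1L])
        expect_state_equal(states[[t]], tru)
        expect_true(pbwt_check(pan, states[[t]]))
      }
    }
  }
  # a panel of identical haplotypes: corrected divergences are all 0 past the
  # sentinel position at every boundary
  pan <- sim_panel(6, 20, dup_groups = list(c(6, 0, 20)), seed = 9)
  for (st in pbwt_build_parallel(pan, 4)) expect_identical(st$d[-1L], rep(0L, 5L))
})

test_that("approximation errors are confined to sentinel groups", {
  # d entries above the sentinel are already true; a and d entries outside
  # the sentinel groups (group = leader + flagged run) are already true
  for (seed in 1:25) {
    pan <- random_panel(300 + seed, mmax = 32L, nmax = 64L, nmin = 4L)
    N <- n_loci(pan)
    for (T in c(3L, 6L)) {
      if (T > N) next
      bounds <- plan_chunks(N, T)$boundaries
      for (t in 2:T) {
        ap <- pbwt_build_chunk(pan, bounds[t], bounds[t + 1L])
        tru <- pbwt_build(pan, bounds[t + 1L])
        flagged <- ap$d == ap$chunk_start
        expect_true(all(ap$d[!flagged] == tru$d[!flagged]))
        expect_true(all(ap$d >= ap$chunk_start))
        g <- sentinel_groups(ap)
        in_group <- rep(FALSE, n_hap(pan))
        for (i in seq_len(nrow(g)))
          in_group[(g$start[i] + 1L):g$stop[i]] <- TRUE
        expect_true(all(ap$a[!in_group] == tru$a[!in_group]))
        expect_true(all(ap$d[!in_group] == tru$d[!in_group]))
      }
    }
  }
})

test_that("correction work is bounded: per-group scans and total sort size by M", {
  for (seed in 1:25) {
    pan <- random_panel(400 + seed, mmax = 32L, nmax = 64L, nmin = 2L)
    M <- n_hap(pan)
    N <- n_loci(pan)
    for (T in c(2L, 5L)) {
      if (T > N) next
      states <- pbwt_build_parallel(pan, T)
      for (st in attr(states, "correction_stats")) {
        expect_lte(st$scan_max_group, M)
        expect_lte(st$sort_total, M)
      }
    }
  }
})

test_that("parallel matching equals the sequential run for every chunk count", {
  for (seed in 1:20) {
    pan <- random_panel(500 + seed, mmax = 20L, nmax = 60L, nmin = 8L)
    N <- n_loci(pan)
    long1 <- pbwt_match(pan, "long", 2, n_chunks = 1)
    setmax1 <- pbwt_match(pan, "setmax", n_chunks = 1)
    expect_same_matches(long1, bf_long_matches(pan, 2))
    expect_same_matches(setmax1, bf_set_maximal(pan))
    for (T in c(2L, 3L, 4L, 8L)) {
      if (T > N) next
      expect_identical(pbwt_match(pan, "long", 2, n_chunks = T), long1)
      expect_identical(pbwt_match(pan, "setmax", n_chunks = T), setmax1)
    }
  }
  # a bound longer than the panel yields nothing for any chunk count
  pan <- random_panel(999, M = 8L, N = 16L, rate = 0.5)
  for (T in c(1L, 4L))
    expect_identical(nrow(pbwt_match(pan, "long", 17, n_chunks = T)), 0L)
})

test_that("outputs are identical for any worker count", {
  pan <- random_panel(600, M = 24L, N = 64L, rate = 0.4)
  s1 <- pbwt_build_parallel(pan, 4, workers = 1)
  s2 <- pbwt_build_parallel(pan, 4, workers = 3)
  for (t in 1:4) expect_state_equal(s1[[t]], s2[[t]])
  expect_identical(pbwt_match(pan, "long", 3, n_chunks = 4, workers = 1),
                   pbwt_match(pan, "long", 3, n_chunks = 4, workers = 3))
  expect_identical(pbwt_match(pan, "setmax", n_chunks = 4, workers = 1),
                   pbwt_match(pan, "setmax", n_chunks = 4, workers = 3))
})

test_that("chunk builds and corrections validate their inputs", {
  pan <- random_panel(12, M = 6L, N = 12L, rate = 0)
  expect_error(pbwt_build_chunk(pan, 4, 4), "chunk_start < chunk_end")
  expect_error(pbwt_build_chunk(pan, -1, 4), "chunk_start")
  ap <- pbwt_build_chunk(pan, 4, 8)
  expect_error(correct_state(ap, pbwt_build(pan, 3)), "locus 3")
})
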