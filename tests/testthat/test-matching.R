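test_that("long matches report maximal runs above the length bound", {
  tbl <- pbwt_long_matches(rbind(c(0, 0, 0), c(0, 0, 1)), min_length = 2)
  expect_identical(as.data.frame(tbl),
                   data.frame(hap_i = 0L, hap_j = 1L, start = 0L, end = 2L,
                              length = 2L))
  expect_identical(nrow(pbwt_long_matches(rbind(c(0, 1), c(1, 0)), 1)), 0L)
  tbl <- pbwt_long_matches(rbind(c(0, 0), c(0, 0)), min_length = 2)
  expect_identical(tbl$start, 0L)
  expect_identical(tbl$end, 2L)
  # a bound longer than the panel can never be reached
  expect_identical(nrow(pbwt_long_matches(rbind(c(0, 0), c(0, 0)), 3)), 0L)
})

test_that("set-maximal matches follow the containment definition", {
  tbl <- pbwt_set_maximal(rbind(c(0, 0), c(0, 0), c(1, 0)))
  expect_identical(as.data.frame(tbl),
                   data.frame(hap_i = c(0L, 0L, 1L), hap_j = c(1L, 2L, 2L),
                              start = c(0L, 1L, 1L), end = c(2L, 2L, 2L),
                              length = c(2L, 1L, 1L)))
  expect_identical(nrow(pbwt_set_maximal(rbind(0L, 1L))), 0L)
  # identical haplotypes: containment forces the full interval for all pairs
  tbl <- pbwt_set_maximal(matrix(rep(c(0L, 1L, 1L, 0L), each = 4), nrow = 4))
  expect_identical(nrow(tbl), 6L)
  expect_true(all(tbl$start == 0L & tbl$end == 4L))
})

test_that("brute-force oracles handle the degenerate cases", {
  expect_identical(as.data.frame(bf_long_matches(rbind(c(0, 0, 0), c(0, 0, 1)), 2)),
                   data.frame(hap_i = 0L, hap_j = 1L, start = 0L, end = 2L,
                              length = 2L))
  expect_identical(nrow(bf_long_matches(rbind(c(0, 0), c(0, 0)), 5)), 0L)
  expect_identical(nrow(bf_long_matches(matrix(0L, 1, 4), 1)), 0L)
  # single column with both alleles: same-allele pairs only, span [0, 1)
  tbl <- bf_set_maximal(matrix(c(0L, 0L, 1L, 1L), ncol = 1))
  expect_identical(as.data.frame(tbl),
                   data.frame(hap_i = c(0L, 2L), hap_j = c(1L, 3L),
                              start = 0L, end = 1L, length = 1L))
})

test_that("PBWT sweeps equal the brute-force oracles on random panels", {
  for (seed in 1:60) {
    pan <- random_panel(seed, mmax = 16L, nmax = 60L)
    bf1 <- bf_long_matches(pan, 1)
    for (L in c(1L, 2L, 5L, 20L)) {
      got <- pbwt_long_matches(pan, L)
      expect_same_matches(got, bf1[bf1$length >= L, ])
      if (seed <= 5L) expect_valid_records(got, pan)
    }
    got <- pbwt_set_maximal(pan)
    expect_same_matches(got, bf_set_maximal(pan))
    if (seed <= 5L) expect_valid_records(got, pan)
  }
})

test_that("per-range outputs partition the full-range output", {
  for (seed in 1:20) {
    pan <- random_panel(100 + seed, mmax = 16L, nmax = 60L, nmin = 4L)
    N <- n_loci(pan)
    cuts <- withr::with_seed(seed, sort(sample(1:(N - 1), min(3L, N - 1L))))
    bounds <- unique(c(0L, cuts, N))
    for (mode in c("long", "setmax")) {
      full <- if (mode == "long") pbwt_long_matches(pan, 2) else pbwt_set_maximal(pan)
      parts <- list()
      for (t in seq_len(length(bounds) - 1L)) {
        st <- pbwt_build(pan, bounds[t])
        rng <- c(bounds[t], bounds[t + 1L])
        parts[[t]] <- if (mode == "long") pbwt_long_matches(pan, 2, rng, st)
                      else pbwt_set_maximal(pan, rng, st)
      }
      joined <- do.call(rbind, parts)
      # disjoint union: no duplicates across ranges, nothing missing
      expect_identical(nrow(joined), nrow(unique(joined)))
      expect_same_matches(joined[order(joined$start, joined$hap_i,
                                       joined$hap_j, joined$end), ], full)
    }
  }
})

test_that("matching validates its start state and length bound", {
  pan <- haplotype_panel(rbind(c(0, 0, 0), c(0, 0, 1)))
  st1 <- pbwt_build(pan, 1)
  expect_error(pbwt_long_matches(pan, 1, range = c(2, 3), state = st1),
               "locus 1")
  expect_error(pbwt_long_matches(pan, 0), ">= 1")
  expect_error(pbwt_long_matches(pan, 1, range = c(0, 4)), "within")
})
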