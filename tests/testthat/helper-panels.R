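# Seeded random panels with a controllable share of duplicate haplotypes;
# duplicate groups are the stressor for the chunk-correction path.
random_panel <- function(seed, M = NULL, N = NULL, rate = NULL,
                         mmax = 40L, nmax = 80L, nmin = 1L) {
  withr::with_seed(seed, {
    if (is.null(M)) M <- sample(2:mmax, 1L)
    if (is.null(N)) N <- sample(nmin:nmax, 1L)
    if (is.null(rate)) rate <- sample(c(0, 0.2, 0.8), 1L)
    sim_panel(M, N, dup_groups = sim_dup_spec(M, N, rate),
              group_mut_rate = 0.1, shuffle = TRUE)
  })
}

expect_state_equal <- function(state, ref) {
  expect_identical(state$k, ref$k)
  expect_identical(state$a, ref$a)
  expect_identical(state$d, ref$d)
}

expect_same_matches <- function(x, y) {
  expect_identical(as.data.frame(x), as.data.frame(y))
}

# Literal MatchRecord invariants against the panel: shared alleles over the
# interval, mismatch (or panel edge) on both flanks, canonical pair order.
expect_valid_records <- function(tbl, panel) {
  al <- as_haplotype_panel(panel)$alleles
  N <- ncol(al)
  for (r in seq_len(nrow(tbl))) {
    i <- tbl$hap_i[r] + 1L; j <- tbl$hap_j[r] + 1L
    s <- tbl$start[r]; e <- tbl$end[r]
    expect_true(i < j && s >= 0L && s < e && e <= N)
    expect_true(all(al[i, (s + 1L):e] == al[j, (s + 1L):e]))
    expect_true(s == 0L || al[i, s] != al[j, s])
    expect_true(e == N || al[i, e + 1L] != al[j, e + 1L])
  }
}
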