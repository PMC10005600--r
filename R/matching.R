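#' @importFrom tibble tibble
match_tbl <- function(hap_i = integer(), hap_j = integer(),
                      start = integer(), end = integer()) {
  tibble::tibble(hap_i = as.integer(hap_i), hap_j = as.integer(hap_j),
                 start = as.integer(start), end = as.integer(end),
                 length = as.integer(end) - as.integer(start))
}

# Canonical record order: (start, hap_i, hap_j, end); drop duplicates.
canonicalize_matches <- function(tbl) {
  if (nrow(tbl) == 0L) return(tbl)
  tbl <- unique(tbl)
  tbl[order(tbl$start, tbl$hap_i, tbl$hap_j, tbl$end), , drop = FALSE]
}

check_range_state <- function(panel, range, state) {
  N <- n_loci(panel)
  range <- as.integer(range)
  if (length(range) != 2L || anyNA(range) || range[1L] < 0L ||
      range[2L] > N || range[1L] > range[2L])
    stop("`range` must be a half-open locus interval within [0, N]", call. = FALSE)
  if (is.null(state)) {
    if (range[1L] != 0L)
      stop("a start `state` at locus range[1] is required", call. = FALSE)
    state <- pbwt_init(n_hap(panel))
  }
  stopifnot(inherits(state, "pbwt_state"))
  if (isTRUE(state$corrected == FALSE))
    stop("start state must be corrected before matching", call. = FALSE)
  if (state$k != range[1L])
    stop(sprintf("start state is at locus %d, not at range start %d",
                 state$k, range[1L]), call. = FALSE)
  if (length(state$a) != n_hap(panel))
    stop("start state does not match the panel", call. = FALSE)
  list(range = range, state = state)
}

#' Report all haplotype matches of length at least L
#'
#' Sweeps loci `[range[1], range[2])` maintaining the PBWT arrays and reports
#' every maximal match of length `>= min_length` whose end locus falls in the
#' range (a match terminates where the two haplotypes next disagree; matches
#' still open at the end of the panel are flushed by the range that reaches
#' `N`). With the default full range and initial state this is the sequential
#' long-match algorithm; seeded with a corrected boundary state it is the
#' per-chunk worker of the parallel run.
#'
#' @param panel a [haplotype_panel] (or 0/1 matrix).
#' @param min_length minimum match length `L >= 1` (inclusive bound).
#' @param range half-open locus interval `c(start, end)` owning the reported
#'   match ends; defaults to the whole panel.
#' @param state `pbwt_state` at `range[1]`, correct for the panel; defaults to
#'   the initial state (only valid when `range[1] == 0`).
#' @return a tibble with columns `hap_i`, `hap_j` (0-based ids, `hap_i <
#'   hap_j`), `start`, `end` (0-based half-open), `length`, sorted by
#'   `(start, hap_i, hap_j)`.
#' @examples
#' pbwt_long_matches(rbind(c(0, 0, 0), c(0, 0, 1)), min_length = 2)
#' @export
pbwt_long_matches <- function(panel, min_length,
                              range = c(0L, n_loci(panel)), state = NULL) {
  panel <- as_haplotype_panel(panel)
  min_length <- as.integer(min_length)
  if (length(min_length) != 1L || is.na(min_length) || min_length < 1L)
    stop("`min_length` must be a single integer >= 1", call. = FALSE)
  rs <- check_range_state(panel, range, state)
  flush <- rs$range[2L] == n_loci(panel)
  res <- cpp_match_range(panel$alleles, rs$state$a, rs$state$d,
                         rs$range[1L], rs$range[2L],
                         set_maximal = FALSE, L = min_length, flush = flush)
  canonicalize_matches(match_tbl(res$hap_i, res$hap_j, res$start, res$end))
}

#' Report all set-maximal haplotype matches
#'
#' A match of haplotype `h` is set-maximal when no other match involving `h`
#' covers a strictly larger locus interval containing it. All ties (several
#' partners over the same maximal interval) are reported. As with
#' [pbwt_long_matches()], a record is owned by the range containing its end
#' locus, and the range reaching `N` flushes matches still open at the end.
#'
#' @inheritParams pbwt_long_matches
#' @return a tibble of match records (see [pbwt_long_matches()]).
#' @examples
#' pbwt_set_maximal(rbind(c(0, 0), c(0, 0), c(1, 0)))
#' @export
pbwt_set_maximal <- function(panel, range = c(0L, n_loci(panel)), state = NULL) {
  panel <- as_haplotype_panel(panel)
  rs <- check_range_state(panel, range, state)
  flush <- rs$range[2L] == n_loci(panel)
  res <- cpp_match_range(panel$alleles, rs$state$a, rs$state$d,
                         rs$range[1L], rs$range[2L],
                         set_maximal = TRUE, L = 1L, flush = flush)
  canonicalize_matches(match_tbl(res$hap_i, res$hap_j, res$start, res$end))
}

# Maximal shared runs of one haplotype pair: rle over the agreement vector.
pair_runs <- function(x, y) {
  agree <- x == y
  if (!length(agree)) return(cbind(start = integer(), end = integer()))
  r <- rle(agree)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths           # 0-based starts
  keep <- r$values
  cbind(start = starts[keep], end = ends[keep])
}

#' Brute-force match oracles
#'
#' Direct all-versus-all enumeration (quadratic in the number of haplotypes):
#' `bf_long_matches()` scans every pair for maximal shared runs of length at
#' least `min_length`; `bf_set_maximal()` applies the set-maximal definition
#' per haplotype to the full run list. These are independent oracles for the
#' PBWT sweeps and are only meant for small panels.
#'
#' @inheritParams pbwt_long_matches
#' @return a tibble of match records (see [pbwt_long_matches()]).
#' @export
bf_long_matches <- function(panel, min_length) {
  panel <- as_haplotype_panel(panel)
  al <- panel$alleles
  M <- nrow(al)
  out <- list()
  if (M >= 2L) {
    for (x in 1:(M - 1L)) for (y in (x + 1L):M) {
      runs <- pair_runs(al[x, ], al[y, ])
      runs <- runs[runs[, "end"] - runs[, "start"] >= min_length, , drop = FALSE]
      if (nrow(runs))
        out[[length(out) + 1L]] <- match_tbl(rep(x - 1L, nrow(runs)),
                                             rep(y - 1L, nrow(runs)),
                                             runs[, "start"], runs[, "end"])
    }
  }
  canonicalize_matches(do.call(rbind, c(out, list(match_tbl()))))
}

#' @rdname bf_long_matches
#' @export
bf_set_maximal <- function(panel) {
  panel <- as_haplotype_panel(panel)
  al <- panel$alleles
  M <- nrow(al)
  out <- list()
  if (M >= 2L) {
    for (h in 1:M) {
      # all maximal runs of h with every partner
      recs <- list()
      for (p in setdiff(1:M, h)) {
        runs <- pair_runs(al[h, ], al[p, ])
        if (nrow(runs))
          recs[[length(recs) + 1L]] <- cbind(partner = p, runs)
      }
      if (!length(recs)) next
      recs <- do.call(rbind, recs)
      # keep runs not strictly contained in another run of h
      keep <- vapply(seq_len(nrow(recs)), function(i) {
        s <- recs[i, "start"]; e <- recs[i, "end"]
        !any(recs[, "start"] <= s & recs[, "end"] >= e &
               (recs[, "start"] < s | recs[, "end"] > e))
      }, logical(1L))
      recs <- recs[keep, , drop = FALSE]
      if (nrow(recs))
        out[[length(out) + 1L]] <- match_tbl(pmin(h, recs[, "partner"]) - 1L,
                                             pmax(h, recs[, "partner"]) - 1L,
                                             recs[, "start"], recs[, "end"])
    }
  }
  canonicalize_matches(do.call(rbind, c(out, list(match_tbl()))))
}
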