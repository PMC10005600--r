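#' Partition the locus range into contiguous chunks
#'
#' Splits `[0, N)` into `n_chunks` contiguous chunks of near-equal size
#' (nominal size `b = N / n_chunks`; when `N` is not divisible the remainder
#' is spread one locus each over the leading chunks, so sizes differ by at
#' most 1).
#'
#' @param n_loci number of loci `N`.
#' @param n_chunks number of chunks `T`, `1 <= T <= N`.
#' @return a `chunk_plan`: list with `n_loci`, `n_chunks` and `boundaries`
#'   (integer vector of `T + 1` ascending loci, `boundaries[1] = 0`,
#'   `boundaries[T + 1] = N`).
#' @examples
#' plan_chunks(10, 3)$boundaries
#' @export
plan_chunks <- function(n_loci, n_chunks) {
  N <- as.integer(n_loci); T <- as.integer(n_chunks)
  if (length(T) != 1L || is.na(T) || T < 1L || T > N)
    stop("`n_chunks` must satisfy 1 <= T <= N", call. = FALSE)
  sizes <- rep(N %/% T, T)
  r <- N %% T
  if (r > 0L) sizes[seq_len(r)] <- sizes[seq_len(r)] + 1L
  structure(list(n_loci = N, n_chunks = T,
                 boundaries = c(0L, cumsum(sizes))),
            class = "chunk_plan")
}

#' @export
print.chunk_plan <- function(x, ...) {
  cat(sprintf("<chunk_plan> N = %d, T = %d chunks\n", x$n_loci, x$n_chunks))
  invisible(x)
}

#' Build the approximate PBWT state of one chunk
#'
#' Runs the ordinary column advance over loci `[chunk_start, chunk_end)`, but
#' starting from identity order and a divergence array filled with the
#' sentinel value `chunk_start` instead of the true carry-in arrays. The
#' result is exact everywhere except inside *sentinel groups*: runs of
#' haplotypes identical over the whole chunk, flagged by
#' `d[i] == chunk_start`, whose relative order and true divergences cannot be
#' determined from the chunk alone. The first chunk (`chunk_start == 0`) is
#' already exact because its sentinel array equals the true `d_0`.
#'
#' @param panel a [haplotype_panel] (or 0/1 matrix).
#' @param chunk_start,chunk_end half-open locus interval of the chunk.
#' @return a `pbwt_approx_state`: fields `k` (= `chunk_end`), `chunk_start`,
#'   `a`, `d`, `corrected`.
#' @export
pbwt_build_chunk <- function(panel, chunk_start, chunk_end) {
  panel <- as_haplotype_panel(panel)
  N <- n_loci(panel)
  chunk_start <- as.integer(chunk_start); chunk_end <- as.integer(chunk_end)
  if (anyNA(c(chunk_start, chunk_end)) || chunk_start < 0L ||
      chunk_end > N || chunk_start >= chunk_end)
    stop("need 0 <= chunk_start < chunk_end <= N", call. = FALSE)
  M <- n_hap(panel)
  res <- cpp_build_range(panel$alleles, seq_len(M) - 1L,
                         rep(chunk_start, M), chunk_start, chunk_end)
  structure(list(k = chunk_end, chunk_start = chunk_start,
                 a = res$a, d = res$d, corrected = chunk_start == 0L),
            n_loci = N, class = c("pbwt_approx_state", "pbwt_state"))
}

#' @export
print.pbwt_approx_state <- function(x, ...) {
  cat(sprintf("<pbwt_approx_state> chunk [%d, %d), M = %d, corrected = %s\n",
              x$chunk_start, x$k, length(x$a), x$corrected))
  invisible(x)
}

#' Invert a positional prefix array
#'
#' `a` maps sorted positions to haplotype ids; the inverse maps ids back to
#' positions, which is how the correction step locates a chunk's haplotypes
#' in the previous chunk's ordering.
#'
#' @param a permutation of `0..M-1`.
#' @return integer vector `ainv` with `ainv[a[i] + 1] == i - 1` (0-based
#'   positions).
#' @examples
#' invert_prefix(c(2L, 0L, 1L))
#' @export
invert_prefix <- function(a) {
  a <- as.integer(a)
  M <- length(a)
  if (anyNA(a) || !identical(sort(a), seq_len(M) - 1L))
    stop("`a` must be a permutation of 0..M-1", call. = FALSE)
  ainv <- integer(M)
  ainv[a + 1L] <- seq_len(M) - 1L
  ainv
}

#' Correct one sentinel group of an approximate state
#'
#' Given a maximal group `[start, stop)` (0-based half-open positions in the
#' approximate arrays) of haplotypes identical over the chunk, restores the
#' true order and divergences from the previous boundary's arrays: the
#' group's haplotypes are looked up in the previous ordering, those positions
#' are sorted, the previous order is copied back into `a`, and each interior
#' divergence becomes the maximum of the previous divergence array over the
#' half-open position window between consecutive looked-up positions.
#' `d[start]` is left untouched (it refers to the preceding non-matching
#' haplotype and is already correct).
#'
#' @param a_k,d_k approximate arrays at the chunk end.
#' @param start,stop 0-based half-open group interval, `stop - start >= 2`.
#' @param a_prev,d_prev correct arrays at the chunk start.
#' @param a_prev_inv optional precomputed [invert_prefix()] of `a_prev`.
#' @return list with corrected `a`, `d`, and the instrumentation counters
#'   `sort_size` (group size) and `scan_work` (summed max-window lengths).
#' @export
correct_group <- function(a_k, d_k, start, stop, a_prev, d_prev,
                          a_prev_inv = invert_prefix(a_prev)) {
  start <- as.integer(start); stop <- as.integer(stop)
  if (stop - start < 2L)
    stop("group [start, stop) must contain at least 2 haplotypes", call. = FALSE)
  if (start < 0L || stop > length(a_k))
    stop("group interval out of bounds", call. = FALSE)
  idx <- (start + 1L):stop                  # 1-based positions of the group
  arr <- sort(a_prev_inv[a_k[idx] + 1L])    # previous-chunk positions, ascending
  a_k[idx] <- a_prev[arr + 1L]
  scan_work <- 0L
  for (i in seq_len(stop - start - 1L)) {
    scan_start <- arr[i] + 1L               # half-open window, 0-based
    scan_stop <- arr[i + 1L] + 1L
    d_k[start + i + 1L] <- max(d_prev[(scan_start + 1L):scan_stop])
    scan_work <- scan_work + (scan_stop - scan_start)
  }
  list(a = a_k, d = d_k, sort_size = stop - start, scan_work = scan_work)
}

# Maximal sentinel runs as the correction driver sees them: a group starts at
# the last index whose divergence differs from the sentinel and extends over
# the sentinel-flagged indices that follow (including the trailing run).
find_groups <- function(d, sentinel) {
  M <- length(d)
  groups <- list()
  gi <- 0L
  for (i in seq_len(M) - 1L) {
    if (d[i + 1L] != sentinel) {
      if (i - gi > 1L) groups[[length(groups) + 1L]] <- c(gi, i)
      gi <- i
    }
  }
  if (M - gi > 1L) groups[[length(groups) + 1L]] <- c(gi, M)
  groups
}

#' Sentinel groups of an approximate chunk state
#'
#' The maximal runs (size >= 2) of haplotypes indistinguishable over the
#' chunk — exactly the intervals the correction step fixes. Exposed as a
#' by-product: these are the groups of haplotypes identical over the chunk's
#' genomic span.
#'
#' @param approx a `pbwt_approx_state` from [pbwt_build_chunk()].
#' @return a tibble with 0-based half-open columns `start`, `stop` (positions
#'   in the approximate ordering) and `size`.
#' @export
sentinel_groups <- function(approx) {
  stopifnot(inherits(approx, "pbwt_approx_state"))
  g <- find_groups(approx$d, approx$chunk_start)
  tibble::tibble(start = vapply(g, `[`, integer(1L), 1L),
                 stop = vapply(g, `[`, integer(1L), 2L),
                 size = vapply(g, function(x) x[2L] - x[1L], integer(1L)))
}

#' Correct an approximate chunk state against its predecessor
#'
#' The single correction step per chunk boundary: scans the approximate
#' divergence array for sentinel groups and fixes each one with
#' [correct_group()] using the correct arrays at the chunk start. After
#' correction the state satisfies the full PBWT invariants — identical to the
#' state the sequential build produces at the same locus.
#'
#' @param approx a `pbwt_approx_state` at locus `k`.
#' @param prev correct `pbwt_state` at `approx$chunk_start`.
#' @return a `pbwt_state` at `k`, with attribute `correction_stats`: list
#'   with `n_groups`, `sort_total`, `scan_total`, `scan_max_group`.
#' @export
correct_state <- function(approx, prev) {
  stopifnot(inherits(approx, "pbwt_approx_state"), inherits(prev, "pbwt_state"))
  if (prev$k != approx$chunk_start)
    stop(sprintf("previous state is at locus %d, chunk starts at %d",
                 prev$k, approx$chunk_start), call. = FALSE)
  stats <- list(n_groups = 0L, sort_total = 0L, scan_total = 0L,
                scan_max_group = 0L)
  a <- approx$a; d <- approx$d
  if (!approx$corrected) {
    ainv <- invert_prefix(prev$a)
    groups <- find_groups(d, approx$chunk_start)
    for (g in groups) {
      res <- correct_group(a, d, g[1L], g[2L], prev$a, prev$d, ainv)
      a <- res$a; d <- res$d
      stats$n_groups <- stats$n_groups + 1L
      stats$sort_total <- stats$sort_total + res$sort_size
      stats$scan_total <- stats$scan_total + res$scan_work
      stats$scan_max_group <- max(stats$scan_max_group, res$scan_work)
    }
  }
  out <- new_pbwt_state(approx$k, a, d, attr(approx, "n_loci"))
  attr(out, "correction_stats") <- stats
  out
}

#' Chunk-parallel construction of the PBWT boundary states
#'
#' Part A builds the `T` chunks independently (pure functions of the panel
#' and the chunk range, so they may run concurrently); part B corrects the
#' approximate arrays in a strict left fold over chunk order, one
#' [correct_state()] step per boundary. The result is exact: state `t` equals
#' `pbwt_build(panel, boundaries[t + 1])` elementwise.
#'
#' @param panel a [haplotype_panel] (or 0/1 matrix).
#' @param n_chunks number of chunks `T`.
#' @param workers number of worker processes for the chunk builds (forked via
#'   \pkg{parallel}; `1` runs serially and is always deterministic — results
#'   do not depend on `workers`).
#' @param verbose log per-chunk sentinel-group and correction-work counters
#'   to stderr.
#' @return list of `T` `pbwt_state`s at the chunk-end boundaries
#'   `b, 2b, ..., N`, with attributes `plan` (the [plan_chunks()] result) and
#'   `correction_stats` (per-chunk counters).
#' @export
pbwt_build_parallel <- function(panel, n_chunks, workers = 1L, verbose = FALSE) {
  panel <- as_haplotype_panel(panel)
  N <- n_loci(panel)
  plan <- plan_chunks(N, n_chunks)
  T <- plan$n_chunks
  bounds <- plan$boundaries
  build1 <- function(t) pbwt_build_chunk(panel, bounds[t], bounds[t + 1L])
  approx <- run_workers(seq_len(T), build1, workers)
  states <- vector("list", T)
  stats <- vector("list", T)
  prev <- NULL
  for (t in seq_len(T)) {
    states[[t]] <- if (t == 1L) correct_state(approx[[1L]], pbwt_init(n_hap(panel)))
                   else correct_state(approx[[t]], states[[t - 1L]])
    stats[[t]] <- attr(states[[t]], "correction_stats")
    if (verbose) {
      sg <- sentinel_groups(approx[[t]])
      message(sprintf(
        "chunk %d [%d,%d): sentinel_groups=%d sort_work=%d scan_work=%d",
        t, bounds[t], bounds[t + 1L], nrow(sg),
        stats[[t]]$sort_total, stats[[t]]$scan_total))
    }
  }
  structure(states, plan = plan, correction_stats = stats)
}

run_workers <- function(xs, f, workers) {
  workers <- as.integer(workers)
  if (workers > 1L && .Platform$OS.type == "unix") {
    res <- parallel::mclapply(xs, f, mc.cores = workers, mc.preschedule = TRUE)
    err <- vapply(res, inherits, logical(1L), "try-error")
    if (any(err)) stop(attr(res[[which(err)[1L]]], "condition"))
    res
  } else {
    lapply(xs, f)
  }
}

#' Run haplotype matching in parallel over chunks
#'
#' The full chunk-parallel pipeline: build and correct the boundary states
#' ([pbwt_build_parallel()]), then dispatch the matching sweep over the `T`
#' chunk ranges, each seeded with its corrected boundary state (range 1
#' starts from the initial state). Per-range outputs are disjoint — a match
#' is owned by the range containing its end locus, and the final range
#' flushes matches open at `N` — so their union, canonically sorted, is
#' bit-identical to the `n_chunks = 1` sequential run.
#'
#' @inheritParams pbwt_build_parallel
#' @param mode `"long"` (all matches of length `>= min_length`) or
#'   `"setmax"` (set-maximal matches).
#' @param min_length minimum match length for `mode = "long"`.
#' @return a tibble of match records (see [pbwt_long_matches()]).
#' @examples
#' p <- sim_panel(8, 40, seed = 1)
#' identical(pbwt_match(p, "long", 5, n_chunks = 4),
#'           pbwt_match(p, "long", 5, n_chunks = 1))
#' @export
pbwt_match <- function(panel, mode = c("long", "setmax"), min_length = NULL,
                       n_chunks = 1L, workers = 1L) {
  panel <- as_haplotype_panel(panel)
  mode <- match.arg(mode)
  N <- n_loci(panel)
  if (mode == "long" &&
      (is.null(min_length) || as.integer(min_length) < 1L))
    stop("`min_length` must be >= 1 for mode = \"long\"", call. = FALSE)
  if (N == 0L) return(match_tbl())
  states <- pbwt_build_parallel(panel, n_chunks, workers = workers)
  bounds <- attr(states, "plan")$boundaries
  T <- attr(states, "plan")$n_chunks
  run1 <- function(t) {
    seed <- if (t == 1L) pbwt_init(n_hap(panel)) else states[[t - 1L]]
    rng <- c(bounds[t], bounds[t + 1L])
    if (mode == "long") pbwt_long_matches(panel, min_length, rng, seed)
    else pbwt_set_maximal(panel, rng, seed)
  }
  parts <- run_workers(seq_len(T), run1, workers)
  canonicalize_matches(do.call(rbind, c(parts, list(match_tbl()))))
}
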