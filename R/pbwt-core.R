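#' PBWT state: positional prefix and divergence arrays
#'
#' A PBWT state at locus `k` holds the positional prefix array `a` (the
#' permutation of haplotype ids `0..M-1` in colexicographic order of their
#' reverse prefixes over loci `[0, k)`) and the divergence array `d` (`d[i]`
#' is the smallest locus `j` such that the haplotypes at sorted positions
#' `i` and `i - 1` agree over `[j, k)`; `d[0] = k`, the no-predecessor
#' sentinel). `pbwt_init()` creates the state at `k = 0`: identity order,
#' all-zero divergences.
#'
#' @param M number of haplotypes (>= 1).
#' @return a `pbwt_state` with fields `k`, `a`, `d` (`a` and `d` are integer
#'   vectors of length `M`; ids and loci are 0-based).
#' @examples
#' pbwt_init(3)
#' @export
pbwt_init <- function(M) {
  M <- as.integer(M)
  if (length(M) != 1L || is.na(M) || M < 1L)
    stop("`M` must be a single integer >= 1", call. = FALSE)
  new_pbwt_state(0L, seq_len(M) - 1L, integer(M))
}

new_pbwt_state <- function(k, a, d, n_loci = NA_integer_) {
  structure(list(k = as.integer(k), a = as.integer(a), d = as.integer(d)),
            n_loci = as.integer(n_loci), class = "pbwt_state")
}

#' @export
print.pbwt_state <- function(x, ...) {
  cat(sprintf("<pbwt_state> k = %d, M = %d\n", x$k, length(x$a)))
  invisible(x)
}

#' Advance a PBWT state by one locus
#'
#' Performs the stable radix-sort step: haplotypes carrying allele 0 at locus
#' `k` come before those carrying allele 1, preserving relative order within
#' each class, and divergences are updated with the usual pair of running
#' maxima. The input state is not modified.
#'
#' @param state a `pbwt_state` at locus `k`.
#' @param column length-`M` vector of 0/1 alleles at locus `k`, indexed by
#'   haplotype id (not by sorted position).
#' @return the `pbwt_state` at locus `k + 1`.
#' @examples
#' pbwt_advance(pbwt_init(2), c(1, 0))
#' @export
pbwt_advance <- function(state, column) {
  stopifnot(inherits(state, "pbwt_state"))
  M <- length(state$a)
  column <- as.integer(column)
  if (length(column) != M)
    stop("`column` must have one allele per haplotype", call. = FALSE)
  if (anyNA(column) || !all(column == 0L | column == 1L))
    stop("alleles must all be 0 or 1", call. = FALSE)
  res <- cpp_advance(column, state$a, state$d, state$k)
  new_pbwt_state(state$k + 1L, res$a, res$d, attr(state, "n_loci"))
}

#' Build the PBWT state at a locus by the sequential algorithm
#'
#' Folds [pbwt_advance()] over columns `0..k-1` starting from [pbwt_init()].
#' This is the sequential ground truth that the chunk-parallel construction
#' ([pbwt_build_parallel()]) reproduces exactly.
#'
#' @param panel a [haplotype_panel] (or 0/1 matrix).
#' @param k target locus in `[0, N]`; defaults to `N`.
#' @return the `pbwt_state` at locus `k`.
#' @export
pbwt_build <- function(panel, k = n_loci(panel)) {
  panel <- as_haplotype_panel(panel)
  N <- n_loci(panel)
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 0L || k > N)
    stop("`k` must lie in [0, N]", call. = FALSE)
  init <- pbwt_init(n_hap(panel))
  res <- cpp_build_range(panel$alleles, init$a, init$d, 0L, k)
  new_pbwt_state(k, res$a, res$d, N)
}

# Colexicographic comparison of reverse prefixes over [0, k): the most recent
# locus is the most significant. Returns -1/0/1.
colex_cmp <- function(x, y, k) {
  for (j in rev(seq_len(k))) {
    if (x[j] < y[j]) return(-1L)
    if (x[j] > y[j]) return(1L)
  }
  0L
}

#' Verify a PBWT state against its panel (brute-force oracle)
#'
#' Checks, by direct string comparison of reverse prefixes (quadratic in the
#' worst case), that `a` is a permutation sorted colexicographically over
#' `[0, k)` and that every `d[i]` equals the true start of the match between
#' sorted neighbours. Intended for tests; not for large panels.
#'
#' @param panel a [haplotype_panel] (or 0/1 matrix).
#' @param state a `pbwt_state` with `k <= n_loci(panel)`.
#' @return `TRUE` or `FALSE`.
#' @export
pbwt_check <- function(panel, state) {
  panel <- as_haplotype_panel(panel)
  al <- panel$alleles
  M <- nrow(al)
  k <- state$k
  if (k > ncol(al) || length(state$a) != M || length(state$d) != M) return(FALSE)
  if (!identical(sort(state$a), seq_len(M) - 1L)) return(FALSE)
  if (state$d[1L] != k) return(FALSE)
  if (M == 1L) return(TRUE)
  for (i in 2:M) {
    x <- al[state$a[i - 1L] + 1L, , drop = TRUE]
    y <- al[state$a[i] + 1L, , drop = TRUE]
    if (k > 0L && colex_cmp(x, y, k) > 0L) return(FALSE)
    # smallest j with agreement over [j, k)
    j <- k
    while (j > 0L && x[j] == y[j]) j <- j - 1L
    if (state$d[i] != j) return(FALSE)
  }
  TRUE
}
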