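resample <- function(x, n = 1L) x[sample.int(length(x), n)]

normalize_dup_groups <- function(dup_groups, M, N) {
  gs <- lapply(dup_groups, function(g) {
    if (is.list(g)) g <- c(g$size, g$span)
    g <- as.integer(g)
    if (length(g) != 3L || anyNA(g))
      stop("each dup group must be (size, span_start, span_end)", call. = FALSE)
    if (g[1L] < 2L) stop("dup group size must be >= 2", call. = FALSE)
    if (g[2L] < 0L || g[3L] > N || g[2L] >= g[3L])
      stop("dup group span must be a nonempty interval within [0, N)", call. = FALSE)
    g
  })
  if (sum(vapply(gs, `[`, integer(1L), 1L)) > M)
    stop("dup group sizes exceed the number of haplotypes", call. = FALSE)
  gs
}

#' Generate a seeded synthetic haplotype panel
#'
#' Sites are i.i.d. Bernoulli with per-site alternate-allele frequencies
#' drawn uniformly from `allele_freq` (a range, or a single fixed value).
#' Duplicate groups are planted from the top rows down: each group's members
#' copy the group's first haplotype, are kept identical over the group's
#' locus span, and outside the span are perturbed per-site at
#' `group_mut_rate` (0 keeps them identical everywhere). Duplicate groups are
#' the stressor for the chunk-correction path: a group whose span covers a
#' whole chunk becomes a sentinel group in that chunk's approximate build.
#'
#' @param M,N haplotype and locus counts.
#' @param allele_freq length-2 range (default `c(0.05, 0.5)`) or a single
#'   per-site frequency.
#' @param dup_groups list of groups, each `c(size, span_start, span_end)`
#'   (span 0-based half-open) or `list(size =, span = c(start, end))`.
#' @param group_mut_rate per-site flip probability for group members outside
#'   their span.
#' @param shuffle randomly permute haplotype rows after planting groups (the
#'   returned `dup_rows` attribute maps groups to rows).
#' @param seed optional integer; when given the panel is a deterministic
#'   function of the arguments.
#' @return a [haplotype_panel]; attribute `dup_rows` lists each group's
#'   0-based haplotype ids.
#' @examples
#' p <- sim_panel(8, 32, dup_groups = list(c(4, 0, 32)), seed = 1)
#' @export
sim_panel <- function(M, N, allele_freq = c(0.05, 0.5), dup_groups = list(),
                      group_mut_rate = 0, shuffle = FALSE, seed = NULL) {
  M <- as.integer(M); N <- as.integer(N)
  if (M < 1L || N < 0L) stop("need M >= 1 and N >= 0", call. = FALSE)
  groups <- normalize_dup_groups(dup_groups, M, N)
  gen <- function() {
    f <- if (length(allele_freq) == 1L) rep(allele_freq, N)
         else stats::runif(N, allele_freq[1L], allele_freq[2L])
    al <- matrix(stats::rbinom(M * N, 1L, rep(f, each = M)), nrow = M)
    storage.mode(al) <- "integer"
    row <- 1L
    rows_of <- list()
    for (g in groups) {
      rows <- row:(row + g[1L] - 1L)
      span <- (g[2L] + 1L):g[3L]
      outside <- setdiff(seq_len(N), span)
      for (r in rows[-1L]) {
        al[r, ] <- al[rows[1L], ]
        if (length(outside) && group_mut_rate > 0) {
          flip <- stats::runif(length(outside)) < group_mut_rate
          al[r, outside[flip]] <- 1L - al[r, outside[flip]]
        }
      }
      rows_of[[length(rows_of) + 1L]] <- rows - 1L
      row <- row + g[1L]
    }
    if (shuffle) {
      perm <- sample.int(M)
      al <- al[perm, , drop = FALSE]
      inv <- integer(M); inv[perm] <- seq_len(M)
      rows_of <- lapply(rows_of, function(r) sort(inv[r + 1L] - 1L))
    }
    structure(haplotype_panel(al), dup_rows = rows_of)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Random duplicate-group specification
#'
#' Draws a [sim_panel()] `dup_groups` list covering approximately
#' `rate * M` haplotypes in groups of 2-4, with a mix of full-panel and
#' random partial spans (length >= 2). Consumes the current RNG stream.
#'
#' @param M,N panel dimensions.
#' @param rate target fraction of haplotypes inside duplicate groups.
#' @return a list usable as `dup_groups`.
#' @export
sim_dup_spec <- function(M, N, rate) {
  M <- as.integer(M); N <- as.integer(N)
  target <- as.integer(floor(rate * M))
  groups <- list()
  used <- 0L
  while (used + 2L <= target && N >= 2L) {
    size <- min(resample(2:4), target - used)
    if (size < 2L) break
    span <- if (stats::runif(1L) < 0.5 || N < 4L) c(0L, N) else {
      s <- resample(0:(N - 2L))
      c(s, resample((s + 2L):N))
    }
    groups[[length(groups) + 1L]] <- c(size, span)
    used <- used + size
  }
  groups
}

#' Write a minimal phased VCF realising a panel
#'
#' Emits a synthetic biallelic VCF (CHROM `1`, positions `1..N`, REF `A`,
#' ALT `C` unless the panel carries `site_ids` metadata) with one phased
#' diploid sample per haplotype pair, such that [read_vcf_panel()] inverts it
#' exactly.
#'
#' @param panel a [haplotype_panel] with an even number of haplotypes and at
#'   least one locus.
#' @param path output path (plain text `.vcf`).
#' @return the path, invisibly.
#' @export
write_vcf_fixture <- function(panel, path) {
  panel <- as_haplotype_panel(panel)
  al <- panel$alleles
  M <- nrow(al); N <- ncol(al)
  if (M %% 2L != 0L)
    stop("VCF output needs an even number of haplotypes (diploid samples)",
         call. = FALSE)
  if (N < 1L) stop("VCF output needs at least one locus", call. = FALSE)
  n_s <- M %/% 2L
  samples <- panel$sample_ids
  if (is.null(samples)) samples <- sprintf("S%d", seq_len(n_s))
  sites <- panel$site_ids
  if (!is.data.frame(sites))
    sites <- data.frame(chrom = "1", pos = seq_len(N),
                        id = sprintf("snp%d", seq_len(N)),
                        ref = "A", alt = "C")
  gt <- matrix("", nrow = N, ncol = n_s)
  for (s in seq_len(n_s))
    gt[, s] <- paste0(al[2L * s - 1L, ], "|", al[2L * s, ])
  body <- cbind(sites$chrom, sites$pos, sites$id, sites$ref, sites$alt,
                ".", "PASS", ".", "GT", gt)
  lines <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s>", unique(sites$chrom)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    apply(body, 1L, paste, collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}
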