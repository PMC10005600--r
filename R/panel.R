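#' Create a haplotype panel
#'
#' A haplotype panel holds `M` phased haplotypes over `N` biallelic loci as an
#' `M x N` matrix of 0 (reference allele) and 1 (alternate allele). Rows are
#' haplotypes, columns are loci. Haplotype ids are 0-based throughout the
#' package (row `h + 1` of the matrix is haplotype `h`), as are locus indices;
#' every interval is half-open `[start, end)`.
#'
#' @param alleles integer (or coercible) matrix of 0/1 values, haplotypes in
#'   rows, loci in columns. At least one haplotype; zero loci is allowed.
#' @param site_ids optional per-locus metadata: a data frame with `N` rows
#'   (e.g. `chrom`, `pos`, `id`, `ref`, `alt`) or a length-`N` vector.
#' @param sample_ids optional character vector of `M/2` sample names; sample
#'   `s` (1-based) owns haplotypes `2(s-1)` and `2(s-1)+1` in VCF order.
#' @return an object of class `haplotype_panel`.
#' @examples
#' p <- haplotype_panel(rbind(c(0, 1, 1), c(0, 1, 0)))
#' n_hap(p)
#' n_loci(p)
#' @export
haplotype_panel <- function(alleles, site_ids = NULL, sample_ids = NULL) {
  if (!is.matrix(alleles))
    stop("`alleles` must be a matrix (haplotypes x loci)", call. = FALSE)
  storage.mode(alleles) <- "integer"
  if (nrow(alleles) < 1L)
    stop("a panel needs at least one haplotype", call. = FALSE)
  if (anyNA(alleles) || (length(alleles) && !all(alleles == 0L | alleles == 1L)))
    stop("alleles must all be 0 or 1 (no missing values)", call. = FALSE)
  n_sites <- if (is.data.frame(site_ids)) nrow(site_ids) else length(site_ids)
  if (!is.null(site_ids) && n_sites != ncol(alleles))
    stop("`site_ids` must have one entry per locus", call. = FALSE)
  if (!is.null(sample_ids) && length(sample_ids) * 2L != nrow(alleles))
    stop("`sample_ids` must name M/2 diploid samples", call. = FALSE)
  dimnames(alleles) <- NULL
  structure(list(alleles = alleles, site_ids = site_ids, sample_ids = sample_ids),
            class = "haplotype_panel")
}

#' @export
#' @rdname haplotype_panel
#' @param x object to coerce / a panel.
as_haplotype_panel <- function(x) {
  if (inherits(x, "haplotype_panel")) return(x)
  if (is.matrix(x)) return(haplotype_panel(x))
  stop("cannot coerce to haplotype_panel", call. = FALSE)
}

#' @export
#' @rdname haplotype_panel
n_hap <- function(x) nrow(as_haplotype_panel(x)$alleles)

#' @export
#' @rdname haplotype_panel
n_loci <- function(x) ncol(as_haplotype_panel(x)$alleles)

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("<haplotype_panel> %d haplotypes x %d loci\n",
              n_hap(x), n_loci(x)))
  if (!is.null(x$sample_ids))
    cat(sprintf("  %d diploid samples\n", length(x$sample_ids)))
  invisible(x)
}
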