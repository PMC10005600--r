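#' Read a phased VCF into a haplotype panel
#'
#' Consumes a VCF or VCF.gz with phased GT fields and produces the `M x N`
#' 0/1 panel (`M` = 2 x samples, haplotypes `2(s-1)` and `2(s-1)+1` are
#' sample `s`'s alleles in VCF order). Only biallelic sites with fully
#' phased, non-missing genotypes are usable; in strict mode any other site is
#' an error, in lenient mode such sites are skipped and the count is
#' reported.
#'
#' @param path VCF or VCF.gz file.
#' @param strict reject (TRUE) or skip (FALSE) unusable sites.
#' @return a [haplotype_panel] with `site_ids` (data frame: `chrom`, `pos`,
#'   `id`, `ref`, `alt`) and `sample_ids`.
#' @export
read_vcf_panel <- function(path, strict = TRUE) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(v@fix) == 0L)
    stop("empty panel: VCF has no variant records", call. = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt) || ncol(gt) == 0L)
    stop("VCF has no sample genotypes", call. = FALSE)
  fix <- v@fix
  alt <- fix[, "ALT"]
  biallelic <- !is.na(alt) & !grepl(",", alt, fixed = TRUE)
  ok_gt <- matrix(grepl("^[01]\\|[01]$", gt), nrow = nrow(gt))
  usable <- biallelic & apply(ok_gt, 1L, all)
  if (strict && !all(usable)) {
    bad <- which(!usable)[1L]
    stop(sprintf(
      "site %s:%s is not a phased biallelic 0/1 site (use strict = FALSE to skip)",
      fix[bad, "CHROM"], fix[bad, "POS"]), call. = FALSE)
  }
  if (!all(usable))
    message(sprintf("skipped %d unusable site(s)", sum(!usable)))
  if (!any(usable))
    stop("empty panel: no usable biallelic phased sites", call. = FALSE)
  gt <- gt[usable, , drop = FALSE]
  n_s <- ncol(gt)
  # interleave the two alleles of each sample: rows 2s-1, 2s
  h1 <- substr(t(gt), 1L, 1L)
  h2 <- substr(t(gt), 3L, 3L)
  al <- matrix(0L, nrow = 2L * n_s, ncol = nrow(gt))
  al[seq(1L, 2L * n_s, by = 2L), ] <- as.integer(h1)
  al[seq(2L, 2L * n_s, by = 2L), ] <- as.integer(h2)
  sites <- data.frame(chrom = fix[usable, "CHROM"],
                      pos = as.integer(fix[usable, "POS"]),
                      id = fix[usable, "ID"],
                      ref = fix[usable, "REF"],
                      alt = fix[usable, "ALT"],
                      stringsAsFactors = FALSE)
  haplotype_panel(al, site_ids = sites, sample_ids = colnames(gt))
}

#' Read / write a plain 0/1 matrix panel
#'
#' One haplotype per line, characters `0`/`1`, no separators. Round-trips
#' exactly.
#'
#' @param path text file.
#' @return `read_panel_matrix()`: a [haplotype_panel];
#'   `write_panel_matrix()`: the path, invisibly.
#' @export
read_panel_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    stop("empty panel: no haplotype lines", call. = FALSE)
  if (length(unique(nchar(lines))) != 1L)
    stop("ragged matrix: haplotype lines differ in length", call. = FALSE)
  if (!all(grepl("^[01]*$", lines)))
    stop("matrix lines may only contain characters 0 and 1", call. = FALSE)
  N <- nchar(lines[1L])
  al <- matrix(0L, nrow = length(lines), ncol = N)
  if (N > 0L) {
    chars <- strsplit(lines, "", fixed = TRUE)
    al <- do.call(rbind, lapply(chars, as.integer))
  }
  haplotype_panel(al)
}

#' @rdname read_panel_matrix
#' @param panel a [haplotype_panel] (or 0/1 matrix).
#' @export
write_panel_matrix <- function(panel, path) {
  panel <- as_haplotype_panel(panel)
  lines <- apply(panel$alleles, 1L, paste, collapse = "")
  writeLines(lines, path)
  invisible(path)
}

#' Read / write match reports as TSV
#'
#' Tab-separated columns `hap_i`, `hap_j`, `start`, `end`, `length` with a
#' header line, preceded by a `#` comment stating the coordinate convention
#' (0-based haplotype ids, 0-based half-open locus intervals). Records are
#' written in canonical `(start, hap_i, hap_j)` order so output files are
#' deterministic regardless of worker count.
#'
#' @param matches a tibble of match records (see [pbwt_long_matches()]).
#' @param path TSV file.
#' @return `write_matches()`: the path, invisibly; `read_matches()`: the
#'   match tibble.
#' @export
write_matches <- function(matches, path) {
  stopifnot(all(c("hap_i", "hap_j", "start", "end") %in% names(matches)))
  matches <- canonicalize_matches(match_tbl(matches$hap_i, matches$hap_j,
                                            matches$start, matches$end))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# haplotype ids are 0-based; locus intervals are 0-based, half-open [start, end)",
    paste(c("hap_i", "hap_j", "start", "end", "length"), collapse = "\t")), con)
  if (nrow(matches))
    writeLines(do.call(paste, c(unname(as.list(matches)), sep = "\t")), con)
  invisible(path)
}

#' @rdname write_matches
#' @export
read_matches <- function(path) {
  tbl <- tryCatch(
    utils::read.delim(path, comment.char = "#", sep = "\t",
                      colClasses = "integer"),
    error = function(e) stop("malformed match TSV: ", conditionMessage(e),
                             call. = FALSE))
  if (!identical(names(tbl), c("hap_i", "hap_j", "start", "end", "length")))
    stop("malformed match TSV: unexpected columns", call. = FALSE)
  if (anyNA(tbl) || any(tbl$length != tbl$end - tbl$start))
    stop("malformed match TSV: inconsistent rows", call. = FALSE)
  canonicalize_matches(match_tbl(tbl$hap_i, tbl$hap_j, tbl$start, tbl$end))
}

STATE_MAGIC <- charToRaw("PBWT")
STATE_VERSION <- 1L

#' Save / load a PBWT state checkpoint
#'
#' Binary columnar format: 4-byte magic `"PBWT"`, then version, `M`, `N`
#' (`-1` when unknown) and `k` as little-endian int32, then the `a` and `d`
#' arrays as `M` little-endian int32 each. Round-trips exactly, so matching
#' runs can be seeded from saved boundary states instead of rebuilding them.
#'
#' @param state a `pbwt_state`.
#' @param path checkpoint file.
#' @return `save_state()`: the path, invisibly; `load_state()`: the
#'   `pbwt_state`.
#' @export
save_state <- function(state, path) {
  stopifnot(inherits(state, "pbwt_state"))
  n <- attr(state, "n_loci")
  if (is.null(n) || is.na(n)) n <- -1L
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(STATE_MAGIC, con)
  writeBin(c(STATE_VERSION, length(state$a), as.integer(n), state$k),
           con, size = 4L, endian = "little")
  writeBin(state$a, con, size = 4L, endian = "little")
  writeBin(state$d, con, size = 4L, endian = "little")
  invisible(path)
}

#' @rdname save_state
#' @export
load_state <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 4L)
  if (length(magic) != 4L || !identical(magic, STATE_MAGIC))
    stop("not a PBWT state checkpoint (bad magic)", call. = FALSE)
  hdr <- readBin(con, "integer", n = 4L, size = 4L, endian = "little")
  if (length(hdr) != 4L)
    stop("truncated checkpoint header", call. = FALSE)
  if (hdr[1L] != STATE_VERSION)
    stop(sprintf("unsupported checkpoint version %d", hdr[1L]), call. = FALSE)
  M <- hdr[2L]
  if (M < 1L) stop("corrupt checkpoint: M < 1", call. = FALSE)
  a <- readBin(con, "integer", n = M, size = 4L, endian = "little")
  d <- readBin(con, "integer", n = M, size = 4L, endian = "little")
  if (length(a) != M || length(d) != M)
    stop("truncated checkpoint arrays", call. = FALSE)
  if (length(readBin(con, "raw", n = 1L)))
    stop("trailing bytes after checkpoint payload", call. = FALSE)
  new_pbwt_state(hdr[4L], a, d,
                 if (hdr[3L] >= 0L) hdr[3L] else NA_integer_)
}
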