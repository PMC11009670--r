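# Readers and writers for the on-disk formats: locus-tree files (locus ID +
# newick, tab separated, one per line), locus tables, support tracks (TSV,
# missing as "NA") and outlier regions (BED). Locus table coordinates are
# 1-based inclusive internally; BED output is 0-based half-open.

#' Read per-locus trees
#'
#' Reads a file with one locus per line, `locus_id<TAB>newick`. Trees are
#' returned in file order, leaf labels verbatim, and may contain polytomies.
#' Loci are linked to the locus table by ID, not by order, so the two files
#' can be maintained independently.
#'
#' @param path path to the tree file.
#' @return a named `multiPhylo`, names = locus IDs.
#' @seealso [write_locus_trees()], [read_locus_table()]
#' @export
read_locus_trees <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("no trees in ", path)
  tab <- regexpr("[\t ]", lines)
  if (any(tab < 0L))
    stop("line ", which(tab < 0L)[1L], ": expected 'locus_id<TAB>newick'")
  ids <- substr(lines, 1L, tab - 1L)
  nwk <- trimws(substr(lines, tab + 1L, nchar(lines)))
  if (anyDuplicated(ids))
    stop("duplicate locus ID: ", ids[duplicated(ids)][1L])
  trees <- tryCatch(ape::read.tree(text = paste(nwk, collapse = "\n")),
                    error = function(e) NULL)
  if (inherits(trees, "phylo")) trees <- c(trees)
  if (is.null(trees) || length(trees) != length(ids)) {
    # locate the offending line for the error message
    for (i in seq_along(nwk)) {
      ok <- tryCatch(!is.null(ape::read.tree(text = nwk[i])),
                     error = function(e) FALSE)
      if (!ok) stop("malformed newick on line ", i, " (locus ", ids[i], ")")
    }
    stop("failed to parse trees in ", path)
  }
  names(trees) <- ids
  class(trees) <- "multiPhylo"
  trees
}

#' Write per-locus trees
#'
#' @param trees named list or `multiPhylo` of `"phylo"` objects; names are the
#'   locus IDs.
#' @param path output path.
#' @param digits significant digits for branch lengths.
#' @return `path`, invisibly.
#' @export
write_locus_trees <- function(trees, path, digits = 10) {
  if (is.null(names(trees))) stop("trees must be named by locus ID")
  nwk <- vapply(trees, function(tr) ape::write.tree(tr, digits = digits),
                character(1L))
  writeLines(paste(names(trees), nwk, sep = "\t"), path)
  invisible(path)
}

#' Read a locus table
#'
#' Tab-separated columns `locus_id`, `chrom`, `start`, `end` with 1-based
#' inclusive coordinates. Rows are sorted by (chromosome, start); unsorted
#' input is sorted with a message. A locus appearing in the table but not in
#' a companion tree file is legitimate (it simply yields missing statistics).
#'
#' @param path path to the TSV (with header).
#' @return a data.frame with columns `locus_id`, `chrom`, `start`, `end`.
#' @export
read_locus_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("locus_id", "chrom", "start", "end")
  if (!all(need %in% names(tab)))
    stop("locus table must have columns: ", paste(need, collapse = ", "))
  validate_locus_table(tab[need])
}

#' Validate (and sort) a locus table
#'
#' @param tab data.frame with columns `locus_id`, `chrom`, `start`, `end`.
#' @return the validated table, sorted by (chromosome, start).
#' @export
validate_locus_table <- function(tab) {
  if (anyDuplicated(tab$locus_id))
    stop("duplicate locus_id: ", tab$locus_id[duplicated(tab$locus_id)][1L])
  if (any(tab$start >= tab$end))
    stop("start >= end for locus ",
         tab$locus_id[which(tab$start >= tab$end)[1L]])
  ord <- order(tab$chrom, tab$start)
  if (!identical(ord, seq_len(nrow(tab)))) {
    message("locus table not sorted by (chrom, start); sorting")
    tab <- tab[ord, ]
  }
  ties <- tapply(tab$start, tab$chrom, function(s) any(diff(s) <= 0))
  if (any(unlist(ties)))
    stop("loci on the same chromosome must have strictly increasing starts")
  rownames(tab) <- NULL
  tab
}

#' Write a locus table
#' @param tab a locus table data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_locus_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a support track
#'
#' A support track is a per-locus statistic aligned to the locus table's
#' genome order: columns `locus_id`, `chrom`, `start`, `end`, `value`.
#' Missing values (`NA`) mark loci where the statistic is undefined - they are
#' skipped, never treated as zero, by [moving_average()] and [window_means()].
#'
#' @param table a locus table (see [read_locus_table()]).
#' @param values numeric vector, one value per table row (NA = missing).
#' @return a data.frame of class `c("support_track", "data.frame")`.
#' @export
support_track <- function(table, values) {
  stopifnot(length(values) == nrow(table))
  out <- data.frame(locus_id = table$locus_id, chrom = table$chrom,
                    start = table$start, end = table$end,
                    value = as.numeric(values), stringsAsFactors = FALSE)
  class(out) <- c("support_track", "data.frame")
  out
}

#' Read / write a support track
#'
#' TSV with columns `locus_id`, `chrom`, `start`, `end`, `value`; missing
#' values serialised as `NA`.
#'
#' @param path file path.
#' @return for the reader, a `support_track`; the writer returns `path`
#'   invisibly.
#' @export
read_support_track <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", na.strings = "NA",
                           stringsAsFactors = FALSE)
  support_track(tab, tab$value)
}

#' @rdname read_support_track
#' @param track a `support_track`.
#' @export
write_support_track <- function(track, path) {
  utils::write.table(track, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Write outlier regions as BED
#'
#' Internal coordinates are 1-based inclusive; BED is 0-based half-open, so
#' the exported start is `start - 1` and the end is unchanged. Regions are
#' written sorted by (chromosome, start) with name and score columns (score =
#' smallest BH-adjusted p-value in the region, when present).
#'
#' @param regions data.frame with columns `chrom`, `start`, `end` and
#'   optionally `min_p_adj`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  lines <- "# chrom\tstart\tend\tname\tscore"
  if (nrow(regions) > 0L) {
    regions <- regions[order(regions$chrom, regions$start), ]
    score <- if ("min_p_adj" %in% names(regions)) {
      signif(regions$min_p_adj, 6)
    } else rep(0, nrow(regions))
    lines <- c(lines, paste(regions$chrom,
                            format(regions$start - 1L, scientific = FALSE,
                                   trim = TRUE),
                            format(regions$end, scientific = FALSE,
                                   trim = TRUE),
                            paste0("region_", seq_len(nrow(regions))),
                            score, sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}
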