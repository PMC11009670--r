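# Clade configuration: named taxon groups, the quadripartitions and
# bipartitions to score, and the outgroup set. Outgroup taxa are part of the
# D side of every quadripartition by convention, so a quadripartition
# A.B | C.D effectively asks for the mutual monophyly of A and B.

#' Construct a clade model
#'
#' @param groups named list of character vectors: taxon group name -> taxa.
#' @param outgroup character vector of outgroup taxa (may be empty).
#' @param quadripartitions named list; each element is a list with entries
#'   `A`, `B`, `C`, `D`, each a group name or vector of group names. The
#'   outgroup is appended to the `D` side automatically.
#' @param bipartitions named list; each element a list with entries `X` and
#'   `Y`, each a group name or vector of group names (taxa not referenced are
#'   simply not scored).
#' @return an object of class `"clade_model"`: list with `groups`, `outgroup`,
#'   and resolved `quadripartitions` / `bipartitions` (taxon vectors).
#' @seealso [read_clade_config()]
#' @export
clade_model <- function(groups, outgroup = character(0),
                        quadripartitions = list(), bipartitions = list()) {
  stopifnot(is.list(groups), length(groups) > 0L, !is.null(names(groups)))
  groups <- lapply(groups, as.character)
  if (any(lengths(groups) == 0L))
    stop("empty group: ", names(groups)[lengths(groups) == 0L][1L])
  outgroup <- as.character(outgroup)
  resolve <- function(ref) {
    ref <- as.character(ref)
    bad <- setdiff(ref, names(groups))
    if (length(bad) > 0L) stop("unknown group: ", bad[1L])
    unique(unlist(groups[ref], use.names = FALSE))
  }
  quads <- lapply(quadripartitions, function(qd) {
    if (!all(c("A", "B", "C", "D") %in% names(qd)))
      stop("quadripartition needs A, B, C, D")
    q <- list(A = resolve(qd$A), B = resolve(qd$B),
              C = resolve(qd$C), D = unique(c(resolve(qd$D), outgroup)))
    .check_quad(q)
  })
  bips <- lapply(bipartitions, function(bp) {
    if (!all(c("X", "Y") %in% names(bp)))
      stop("bipartition needs X and Y")
    b <- list(X = resolve(bp$X), Y = resolve(bp$Y))
    if (length(intersect(b$X, b$Y)) > 0L) stop("bipartition sides overlap")
    b
  })
  structure(list(groups = groups, outgroup = outgroup,
                 quadripartitions = quads, bipartitions = bips),
            class = "clade_model")
}

#' Read a clade configuration
#'
#' YAML file with top-level keys `groups` (name -> list of taxa), `outgroup`
#' (list of taxa, optional), `quadripartitions` (name -> \{A, B, C, D\} group
#' references) and `bipartitions` (name -> \{X, Y\} group references).
#' Outgroup taxa are appended to the D side of every quadripartition on load.
#'
#' @param path path to the YAML config.
#' @return a [clade_model()].
#' @export
read_clade_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$groups)) stop("clade config must define 'groups'")
  # YAML 1.1 reads a bare Y/N key as a boolean; map it back
  cfg$bipartitions <- lapply(cfg$bipartitions, function(bp) {
    nm <- names(bp)
    nm[nm %in% c("TRUE", "yes")] <- "Y"
    nm[nm %in% c("FALSE", "no")] <- "N"
    names(bp) <- nm
    bp
  })
  clade_model(groups = cfg$groups,
              outgroup = if (is.null(cfg$outgroup)) character(0)
                         else unlist(cfg$outgroup),
              quadripartitions = if (is.null(cfg$quadripartitions)) list()
                                 else cfg$quadripartitions,
              bipartitions = if (is.null(cfg$bipartitions)) list()
                             else cfg$bipartitions)
}

#' @export
print.clade_model <- function(x, ...) {
  cat("clade model:", length(x$groups), "groups,",
      length(x$quadripartitions), "quadripartitions,",
      length(x$bipartitions), "bipartitions\n")
  invisible(x)
}

#' Per-locus statistic tracks
#'
#' Build genome-ordered support tracks by applying a per-locus statistic to
#' every locus in a table. `qqs_track()` records the normalised main-topology
#' QQS of a quadripartition; `bqs_track()` the BQS of a bipartition;
#' `monophyly_track()` the 0/1 monophyly of the union of the A and B groups of
#' a quadripartition, with the locus qualifying only when it carries at least
#' one taxon from each of A, B, C and D (the quadripartition screening rule).
#' Loci without a tree, or where the statistic is undefined, are missing.
#'
#' @param trees named list / `multiPhylo` of locus trees (names = locus IDs).
#' @param table a locus table.
#' @param quad a quadripartition (list with `A`, `B`, `C`, `D`), e.g. from a
#'   [clade_model()].
#' @return a [support_track()].
#' @export
qqs_track <- function(trees, table, quad) {
  quad <- .check_quad(quad)
  idx <- match(table$locus_id, names(trees))
  trees <- unclass(trees)
  vals <- vapply(idx, function(i) {
    if (is.na(i)) return(NA_real_)
    qqs(trees[[i]], quad)$q[[1L]]
  }, numeric(1L))
  support_track(table, vals)
}

#' @rdname qqs_track
#' @param bip a bipartition (list with `X`, `Y`).
#' @export
bqs_track <- function(trees, table, bip) {
  idx <- match(table$locus_id, names(trees))
  trees <- unclass(trees)
  vals <- vapply(idx, function(i) {
    if (is.na(i)) return(NA_real_)
    bqs(trees[[i]], bip)
  }, numeric(1L))
  support_track(table, vals)
}

#' @rdname qqs_track
#' @param outgroup outgroup taxa passed to [is_monophyletic()]; defaults to
#'   the quadripartition's D side.
#' @export
monophyly_track <- function(trees, table, quad, outgroup = NULL) {
  quad <- .check_quad(quad)
  if (is.null(outgroup)) outgroup <- quad$D
  clade <- c(quad$A, quad$B)
  outgroup <- setdiff(outgroup, clade)
  idx <- match(table$locus_id, names(trees))
  trees <- unclass(trees)
  vals <- vapply(idx, function(i) {
    if (is.na(i)) return(NA_real_)
    tr <- trees[[i]]
    present <- lapply(quad, intersect, y = tr$tip.label)
    if (any(lengths(present) == 0L)) return(NA_real_)
    as.numeric(is_monophyletic(tr, clade, outgroup))
  }, numeric(1L))
  support_track(table, vals)
}

#' Uniting branch lengths of a clade across loci
#'
#' Applies [clade_branch_length()] to every locus tree; loci where the clade
#' is not monophyletic (or does not qualify) are `NA`.
#'
#' @inheritParams qqs_track
#' @param clade,outgroup taxon label vectors.
#' @return a [support_track()] of branch lengths.
#' @export
clade_branch_length_track <- function(trees, table, clade, outgroup) {
  idx <- match(table$locus_id, names(trees))
  trees <- unclass(trees)
  vals <- vapply(idx, function(i) {
    if (is.na(i)) return(NA_real_)
    clade_branch_length(trees[[i]], clade, outgroup)
  }, numeric(1L))
  support_track(table, vals)
}
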