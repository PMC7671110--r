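#' Read a chronogram from a Newick file
#'
#' Reads a single rooted ultrametric tree. Quoted labels and
#' square-bracket comments are accepted; support values stored as internal
#' node labels are ignored. In strict mode any tree whose root-to-tip
#' distances differ by more than `tolerance` (relative to tree height) is
#' rejected; in lenient mode the maximum deviation is reported as a warning
#' and the tree accepted unchanged (no rescaling is attempted).
#'
#' @param path path to a Newick file containing one tree.
#' @param strict reject non-ultrametric trees (default `TRUE`).
#' @param tolerance relative ultrametricity tolerance (default `1e-6`).
#' @return a [Chronogram-class].
#' @examples
#' f <- tempfile(fileext = ".nwk")
#' writeLines("((A:1,B:1):1,C:2);", f)
#' readChronogram(f)
#' @export
readChronogram <- function(path, strict = TRUE, tolerance = 1e-6) {
  if (!file.exists(path)) stop(sprintf("tree file not found: %s", path))
  phy <- tryCatch(suppressWarnings(ape::read.tree(path)),
                  error = function(e)
                    stop(sprintf("failed to parse Newick in '%s': %s",
                                 path, conditionMessage(e))))
  if (is.null(phy)) stop(sprintf("failed to parse Newick in '%s'", path))
  if (inherits(phy, "multiPhylo")) {
    if (length(phy) != 1L)
      stop(sprintf("'%s' contains %d trees; exactly one is expected",
                   path, length(phy)))
    phy <- phy[[1L]]
  }
  if (anyDuplicated(phy$tip.label))
    stop(sprintf("duplicate tip label(s): %s",
                 paste(unique(phy$tip.label[duplicated(phy$tip.label)]),
                       collapse = ", ")))
  if (is.null(phy$edge.length) || any(phy$edge.length < 0))
    stop("tree must have non-negative branch lengths")
  Chronogram(phy, tolerance = tolerance, strict = strict)
}

#' Write a chronogram to a Newick file
#'
#' @param x a [Chronogram-class] or `phylo`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeChronogram <- function(x, path) {
  ape::write.tree(.phy(x), file = path)
  invisible(path)
}

#' Read a taxonomy table (species, description year, optional group/trait)
#'
#' Reads a delimited text file with a header (tab for `.tsv`/`.txt`, comma
#' for `.csv`). Columns are mapped to the canonical names `species`,
#' `year`, `group`, `trait` via the `*Col` arguments. Years must be
#' integers; years before 1758 are accepted with a warning.
#'
#' @param path path to the table.
#' @param speciesCol,yearCol names of the required columns.
#' @param groupCol,traitCol names of the optional columns; ignored when the
#'   file lacks them.
#' @param sep field separator; default guessed from the file extension.
#' @return a [TaxonomyTable-class].
#' @export
readTaxonomy <- function(path, speciesCol = "species", yearCol = "year",
                         groupCol = "group", traitCol = "trait",
                         sep = NULL) {
  if (!file.exists(path)) stop(sprintf("taxonomy file not found: %s", path))
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- read.table(path, header = TRUE, sep = sep, quote = "\"",
                   stringsAsFactors = FALSE, comment.char = "",
                   check.names = FALSE)
  for (col in c(speciesCol, yearCol))
    if (!col %in% names(df))
      stop(sprintf("required column '%s' not found in '%s'", col, path))
  out <- data.frame(species = as.character(df[[speciesCol]]),
                    stringsAsFactors = FALSE)
  yraw <- df[[yearCol]]
  ynum <- suppressWarnings(as.numeric(yraw))
  bad <- !is.finite(ynum) | ynum != round(ynum)
  if (any(bad))
    stop(sprintf("non-integer year '%s' in row %d of '%s'",
                 as.character(yraw[which(bad)[1L]]), which(bad)[1L], path))
  out$year <- as.integer(round(ynum))
  if (groupCol %in% names(df)) out$group <- as.character(df[[groupCol]])
  if (traitCol %in% names(df)) {
    tr <- suppressWarnings(as.numeric(df[[traitCol]]))
    out$trait <- tr
  }
  if (anyDuplicated(out$species))
    stop(sprintf("duplicated species in '%s': %s", path,
                 paste(unique(out$species[duplicated(out$species)]),
                       collapse = ", ")))
  TaxonomyTable(out)
}

#' Write a taxonomy table as TSV
#'
#' @param x a [TaxonomyTable-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeTaxonomy <- function(x, path) {
  .writeTsv(as.data.frame(x), path)
}

.writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Align a chronogram with a taxonomy table
#'
#' Restricts both inputs to their common species set: tree tips lacking a
#' description year are pruned (traversed edges are merged so the tree
#' stays ultrametric) and taxonomy records absent from the tree are
#' removed. Mirrors the usual treatment of described-but-unsampled species
#' in large chronograms, which are simply ignored.
#'
#' @param tree a [Chronogram-class].
#' @param table a [TaxonomyTable-class].
#' @param onDropTip `"warn"` (default) or `"error"` when tree tips lack a
#'   year.
#' @return a list with elements `tree` (pruned [Chronogram-class]), `table`
#'   (restricted [TaxonomyTable-class]) and `report`
#'   ([AlignmentReport-class]).
#' @export
alignTreeTaxonomy <- function(tree, table, onDropTip = c("warn", "error")) {
  onDropTip <- match.arg(onDropTip)
  cg <- .chronogram(tree)
  phy <- cg@tree
  df <- as.data.frame(table)
  common <- intersect(phy$tip.label, df$species)
  if (length(common) < 3L)
    stop(sprintf("only %d species shared between tree and taxonomy (need >= 3)",
                 length(common)))
  droppedTips <- setdiff(phy$tip.label, common)
  droppedRecords <- setdiff(df$species, common)
  if (length(droppedTips)) {
    msg <- sprintf("%d tree tip(s) have no description year and were pruned: %s",
                   length(droppedTips),
                   paste(utils::head(droppedTips, 5L), collapse = ", "))
    if (onDropTip == "error") stop(msg)
    warning(msg)
    phy <- ape::keep.tip(phy, common)
    cg <- new("Chronogram", tree = phy,
              height = mean(.tipDepths(phy)), tolerance = cg@tolerance)
  }
  if (length(droppedRecords))
    df <- df[df$species %in% common, , drop = FALSE]
  rownames(df) <- NULL
  list(tree = cg,
       table = new("TaxonomyTable", data = df),
       report = new("AlignmentReport", droppedTips = droppedTips,
                    droppedRecords = droppedRecords))
}
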