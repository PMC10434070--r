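#' Construct a validated abundance table
#'
#' The package-wide convention is a base integer matrix with taxa as rows
#' and samples as columns (the usual orientation of a denoised amplicon
#' table), with taxon ids as rownames and sample ids as colnames.  This
#' constructor only validates; all analysis functions accept any matrix
#' that passes the same checks.
#'
#' @param counts numeric matrix of non-negative integer counts
#'   (taxa x samples) with row and column names.
#' @return the validated matrix.
#' @examples
#' m <- matrix(0:3, 2, 2, dimnames = list(c("t1", "t2"), c("s1", "s2")))
#' abundance_table(m)
#' @export
abundance_table <- function(counts) {
  storage.mode(counts) <- "double"
  check_table(counts)
  counts
}

#' Read a taxa-by-sample count table from TSV
#'
#' Expects a tab-delimited file whose header row holds sample ids and
#' whose first column holds taxon ids.  Non-integer, negative or missing
#' cells and duplicated ids are rejected.
#'
#' @param path path to a TSV file.
#' @return an abundance matrix (taxa x samples), see [abundance_table()].
#' @seealso [write_abundance_table()]
#' @export
read_abundance_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("abundance table needs a taxon id column plus samples")
  if (anyDuplicated(names(df)[-1])) stop("duplicate sample ids in header")
  taxa <- as.character(df[[1L]])
  if (anyDuplicated(taxa)) stop("duplicate taxon ids")
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric counts in abundance table")
  rownames(m) <- taxa
  abundance_table(m)
}

#' Write a taxa-by-sample count table to TSV
#'
#' @param table abundance matrix (taxa x samples).
#' @param path output path.
#' @export
write_abundance_table <- function(table, path) {
  check_table(table)
  df <- data.frame(taxon_id = rownames(table), table,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Classify salinity into water classes
#'
#' Default cutoffs: freshwater below 1.0 percent, brackish in \[1, 5),
#' subsaline in \[5, 10), saline at or above 10 percent.
#'
#' @param salinity numeric vector of salinities in percent.
#' @param cutoffs increasing 3-vector of class boundaries (percent).
#' @return factor with levels freshwater, brackish, subsalt, salt.
#' @export
water_class <- function(salinity, cutoffs = c(1, 5, 10)) {
  stopifnot(is.numeric(salinity), all(salinity >= 0, na.rm = TRUE),
            length(cutoffs) == 3L, !is.unsorted(cutoffs))
  cut(salinity, breaks = c(-Inf, cutoffs, Inf), right = FALSE,
      labels = c("freshwater", "brackish", "subsalt", "salt"))
}

#' Read a sample metadata table from TSV
#'
#' Requires a `sample_id` column; a `salinity` column (percent) is used to
#' derive `water_class` when the file does not provide one.  All other
#' columns are kept as covariates; empty cells stay missing (`NA`), they
#' are never imputed.
#'
#' @param path path to a TSV file.
#' @param cutoffs water-class salinity cutoffs, see [water_class()].
#' @return data.frame with one row per sample.
#' @export
read_metadata <- function(path, cutoffs = c(1, 5, 10)) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  if (!"sample_id" %in% names(df)) stop("metadata must have a sample_id column")
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in metadata")
  if ("salinity" %in% names(df)) {
    if (any(df$salinity < 0, na.rm = TRUE)) stop("salinity must be >= 0")
    if (!"water_class" %in% names(df))
      df$water_class <- water_class(df$salinity, cutoffs)
  }
  df
}

#' Write sample metadata to TSV
#' @param metadata data.frame with a `sample_id` column.
#' @param path output path.
#' @export
write_metadata <- function(metadata, path) {
  stopifnot(is.data.frame(metadata), "sample_id" %in% names(metadata))
  utils::write.table(metadata, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a rooted phylogenetic tree from newick
#'
#' Validates that the tree is rooted, carries branch lengths, and that tip
#' labels are unique and non-empty; negative branch lengths are rejected.
#'
#' @param path path to a newick file.
#' @return an [ape::phylo] tree.
#' @export
read_tree <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("could not parse newick tree")
  validate_tree(tr)
}

validate_tree <- function(tr) {
  if (!inherits(tr, "phylo")) stop("not a phylo object")
  if (is.null(tr$edge.length)) stop("tree must have branch lengths")
  if (any(tr$edge.length < 0)) stop("negative branch lengths")
  if (is.null(tr$tip.label) || any(!nzchar(tr$tip.label)))
    stop("tree has unlabeled tips")
  if (anyDuplicated(tr$tip.label)) stop("duplicate tip labels")
  if (!ape::is.rooted(tr)) stop("tree must be rooted")
  tr
}

#' Patristic (cophenetic) distances between tree tips
#'
#' @param tree a rooted [ape::phylo] tree with branch lengths.
#' @return symmetric matrix of tip-to-tip path lengths.
#' @export
patristic_distances <- function(tree) {
  validate_tree(tree)
  stats::cophenetic(tree)
}

#' Read a taxon annotation table from TSV
#'
#' Expects `taxon_id` and `trophic_group` columns; trophic groups must be
#' among consumer, saprotroph, parasite, photosynthetic, mixotroph,
#' unclassified.  Additional columns (e.g. `class`, `order`, `taxonomy`)
#' are kept.
#'
#' @param path path to a TSV file.
#' @return data.frame with one row per taxon.
#' @export
read_annotation <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  check_annotation(df)
  df
}

trophic_levels <- function() {
  c("consumer", "saprotroph", "parasite", "photosynthetic", "mixotroph",
    "unclassified")
}

check_annotation <- function(df) {
  if (!is.data.frame(df) || !all(c("taxon_id", "trophic_group") %in% names(df)))
    stop("annotation must have taxon_id and trophic_group columns")
  if (anyDuplicated(df$taxon_id)) stop("duplicate taxon ids in annotation")
  bad <- setdiff(unique(df$trophic_group), trophic_levels())
  if (length(bad)) stop("unknown trophic groups: ", paste(bad, collapse = ", "))
  invisible(df)
}

#' Write a taxon annotation table to TSV
#' @param annotation data.frame as returned by [read_annotation()].
#' @param path output path.
#' @export
write_annotation <- function(annotation, path) {
  check_annotation(annotation)
  utils::write.table(annotation, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a signed co-occurrence network as edge and node TSV files
#'
#' The edge file holds source, target, weight (signed Pearson r) and sign;
#' the node file holds id, degree, and any of the vertex attributes
#' module, zi, pi, role, trophic_group that are present.  The pair of
#' files reconstructs the topology exactly via [read_network()].  An
#' empty network produces header-only files.
#'
#' @param net an [igraph::igraph] network, see [build_network()].
#' @param edge_path,node_path output paths.
#' @export
write_network <- function(net, edge_path, node_path) {
  stopifnot(igraph::is_igraph(net))
  ed <- igraph::as_data_frame(net, what = "edges")
  keep <- intersect(c("from", "to", "weight", "sign"), names(ed))
  ed <- ed[, keep, drop = FALSE]
  names(ed)[names(ed) == "from"] <- "source"
  names(ed)[names(ed) == "to"] <- "target"
  if (nrow(ed) == 0L)
    ed <- data.frame(source = character(), target = character(),
                     weight = numeric(), sign = numeric())
  utils::write.table(ed, edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  nd <- data.frame(id = as.character(igraph::V(net)$name),
                   degree = igraph::degree(net), stringsAsFactors = FALSE)
  for (a in c("module", "zi", "pi", "role", "trophic_group")) {
    if (a %in% igraph::vertex_attr_names(net))
      nd[[a]] <- igraph::vertex_attr(net, a)
  }
  if (nrow(nd) == 0L) nd <- data.frame(id = character(), degree = integer())
  utils::write.table(nd, node_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(edge_path)
}

#' Read a network back from edge and node TSV files
#'
#' @param edge_path,node_path paths written by [write_network()].
#' @return an undirected [igraph::igraph] network.
#' @export
read_network <- function(edge_path, node_path) {
  ed <- utils::read.delim(edge_path, stringsAsFactors = FALSE,
                          colClasses = c(source = "character",
                                         target = "character"))
  nd <- utils::read.delim(node_path, stringsAsFactors = FALSE,
                          colClasses = c(id = "character"))
  igraph::graph_from_data_frame(ed, directed = FALSE, vertices = nd)
}
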