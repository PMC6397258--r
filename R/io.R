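#' Construct and validate an OTU count table
#'
#' An OTU table is a plain numeric matrix of non-negative counts with samples
#' in rows and OTUs in columns; row and column names are the (unique,
#' case-sensitive) sample and OTU identifiers. All functions in this package
#' that take a `table` argument expect this layout.
#'
#' @param counts numeric matrix, samples x OTUs, with dimnames.
#' @return the validated counts matrix.
#' @export
otu_table <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("counts must be a numeric matrix (samples x OTUs)")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry sample ids (rownames) and OTU ids (colnames)")
  if (anyDuplicated(rownames(counts)))
    stop("format error: duplicated sample id: ",
         rownames(counts)[duplicated(rownames(counts))][1L])
  if (anyDuplicated(colnames(counts)))
    stop("format error: duplicated OTU id: ",
         colnames(counts)[duplicated(colnames(counts))][1L])
  if (anyNA(counts) || any(counts < 0))
    stop("counts must be non-negative and free of NA")
  storage.mode(counts) <- "double"
  counts
}

#' Per-sample total read counts
#' @param table OTU table (see [otu_table()]).
#' @return named numeric vector of row sums.
#' @export
total_reads <- function(table) rowSums(table)

#' Read an OTU count table from TSV
#'
#' The file has one header row and one identifier column. Because silently
#' mis-orienting a table is the classic microbiome-pipeline bug, the
#' orientation must be stated explicitly; the returned matrix is always
#' samples x OTUs.
#'
#' @param path path to a tab-separated file.
#' @param orientation `"samples-in-rows"` (rows are samples, header holds OTU
#'   ids) or `"otus-in-rows"` (transposed on read).
#' @return OTU table matrix, samples x OTUs.
#' @export
read_otu_table <- function(path,
                           orientation = c("samples-in-rows", "otus-in-rows")) {
  orientation <- match.arg(orientation)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character")
  if (ncol(raw) < 2L) stop("format error: no data columns in ", path)
  row_ids <- trimws(raw[[1L]])
  col_ids <- trimws(colnames(raw)[-1L])
  if (anyDuplicated(row_ids))
    stop("format error: duplicated identifier '",
         row_ids[duplicated(row_ids)][1L], "' in first column of ", path)
  if (anyDuplicated(col_ids))
    stop("format error: duplicated identifier '",
         col_ids[duplicated(col_ids)][1L], "' in header of ", path)
  body <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop("parse error: non-numeric cell at row '", row_ids[bad[1L]],
         "', column '", col_ids[bad[2L]], "' in ", path)
  }
  dimnames(num) <- list(row_ids, col_ids)
  if (orientation == "otus-in-rows") num <- t(num)
  otu_table(num)
}

#' Write an OTU count table as TSV
#' @param table OTU table.
#' @param path output path.
#' @param orientation layout to write (see [read_otu_table()]).
#' @export
write_otu_table <- function(table, path,
                            orientation = c("samples-in-rows", "otus-in-rows")) {
  orientation <- match.arg(orientation)
  m <- if (orientation == "otus-in-rows") t(table) else table
  id_col <- if (orientation == "otus-in-rows") "otu_id" else "sample_id"
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read sample metadata from TSV
#'
#' Required columns: `sample_id`, `sample_type` (sponge|seawater). Recognised
#' optional columns: `host_species`, `health_status`, `life_stage`,
#' `taxonomic_id_unequivocal`, `read_count`, `temperature`, `depth`,
#' `ecoregion`; absent ones are filled with NA. The NA token is `"NA"`.
#'
#' @param path path to a tab-separated file.
#' @return data.frame, one row per sample.
#' @export
read_sample_metadata <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  sample_metadata(df)
}

#' Validate a sample-metadata data frame
#' @param df data.frame with at least `sample_id` and `sample_type`.
#' @return completed, validated data.frame.
#' @export
sample_metadata <- function(df) {
  need <- c("sample_id", "sample_type")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("metadata lacks required column(s): ",
                         paste(miss, collapse = ", "))
  opt_chr <- c("host_species", "health_status", "life_stage", "ecoregion")
  opt_num <- c("read_count", "temperature", "depth")
  for (cc in opt_chr) if (!cc %in% colnames(df)) df[[cc]] <- NA_character_
  for (cc in opt_num) if (!cc %in% colnames(df)) df[[cc]] <- NA_real_
  if (!"taxonomic_id_unequivocal" %in% colnames(df))
    df$taxonomic_id_unequivocal <- NA
  df$sample_id <- trimws(as.character(df$sample_id))
  if (anyDuplicated(df$sample_id))
    stop("format error: duplicated sample_id in metadata")
  if (anyNA(df$sample_type) ||
      !all(df$sample_type %in% c("sponge", "seawater")))
    stop("sample_type must be 'sponge' or 'seawater' for every sample")
  df$taxonomic_id_unequivocal <- as.logical(df$taxonomic_id_unequivocal)
  rownames(df) <- NULL
  df
}

#' Write sample metadata as TSV
#' @param meta metadata data.frame.
#' @param path output path.
#' @export
write_sample_metadata <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a host-trait table (HMA/LMA classification) from TSV
#' @param path tab-separated file with columns `host_species`, `host_type`.
#' @return data.frame with unique host_species and host_type in HMA/LMA/NA.
#' @export
read_host_traits <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  host_traits(df)
}

#' Validate a host-trait data frame
#' @param df data.frame with `host_species` and `host_type`.
#' @return validated data.frame.
#' @export
host_traits <- function(df) {
  if (!all(c("host_species", "host_type") %in% colnames(df)))
    stop("host traits need columns host_species and host_type")
  df$host_species <- trimws(as.character(df$host_species))
  if (anyDuplicated(df$host_species))
    stop("format error: duplicated host_species in traits")
  ok <- is.na(df$host_type) | df$host_type %in% c("HMA", "LMA")
  if (!all(ok)) stop("host_type must be HMA, LMA or NA")
  rownames(df) <- NULL
  df
}

#' Write a host-trait table as TSV
#' @param traits traits data.frame.
#' @param path output path.
#' @export
write_host_traits <- function(traits, path) {
  utils::write.table(traits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Read a rooted phylogenetic tree from a Newick file
#'
#' Branch lengths absent from the file (topology-only exports, e.g. from
#' taxonomy databases) are replaced by `default_branch_length`, since the
#' UniFrac machinery needs lengths on every edge.
#'
#' @param path Newick file.
#' @param default_branch_length length substituted for missing branch
#'   lengths; default 1.
#' @return an [ape::read.tree()] `phylo` object with complete, non-negative
#'   branch lengths and unique tip labels.
#' @export
read_newick <- function(path, default_branch_length = 1) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  n_open <- lengths(regmatches(txt, gregexpr("(", txt, fixed = TRUE)))
  n_close <- lengths(regmatches(txt, gregexpr(")", txt, fixed = TRUE)))
  if (n_open != n_close)
    stop("parse error: unbalanced parentheses in ", path)
  tree <- tryCatch(ape::read.tree(text = txt),
                   error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tree)) stop("parse error: could not read Newick in ", path)
  if (anyDuplicated(tree$tip.label))
    stop("format error: duplicated tip label '",
         tree$tip.label[duplicated(tree$tip.label)][1L], "'")
  if (is.null(tree$edge.length)) {
    tree$edge.length <- rep(default_branch_length, nrow(tree$edge))
  } else if (anyNA(tree$edge.length)) {
    tree$edge.length[is.na(tree$edge.length)] <- default_branch_length
  }
  if (any(tree$edge.length < 0))
    stop("format error: negative branch length in ", path)
  tree
}

#' Total branch length of a tree
#' @param tree `phylo` object.
#' @return sum of all branch lengths.
#' @export
tree_length <- function(tree) sum(tree$edge.length)

#' Write a module partition as TSV
#'
#' Columns `node_id`, `node_class` (host|otu), `module_id`; round-trips
#' losslessly with [read_partition()].
#'
#' @param partition a `module_partition` (see [find_modules()]).
#' @param path output path.
#' @param net optional `bipartite_network`; when given, every network node
#'   must be covered by the partition.
#' @export
write_partition <- function(partition, path, net = NULL) {
  stopifnot(inherits(partition, "module_partition"))
  if (!is.null(net)) {
    missing_nodes <- setdiff(c(net$hosts, net$otus), names(partition$membership))
    if (length(missing_nodes))
      stop("contract error: partition misses network node(s): ",
           paste(utils::head(missing_nodes, 5L), collapse = ", "))
  }
  df <- data.frame(node_id = names(partition$membership),
                   node_class = partition$node_class,
                   module_id = partition$membership,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a module partition written by [write_partition()]
#' @param path TSV with columns node_id, node_class, module_id.
#' @return a `module_partition` (Q is NA; recompute with [barber_Q()]).
#' @export
read_partition <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("node_id", "node_class", "module_id") %in% colnames(df)))
    stop("format error: partition file needs node_id, node_class, module_id")
  membership <- as.integer(df$module_id)
  names(membership) <- df$node_id
  node_class <- as.character(df$node_class)
  names(node_class) <- df$node_id
  module_partition(membership, node_class, Q = NA_real_)
}

#' Write a distance matrix as TSV
#' @param d symmetric matrix with dimnames.
#' @param path output path.
#' @export
write_distance_matrix <- function(d, path) {
  d <- as_distance_matrix(d)
  df <- data.frame(id = rownames(d), d, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a distance matrix written by [write_distance_matrix()]
#' @param path TSV path.
#' @return validated symmetric matrix.
#' @export
read_distance_matrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  as_distance_matrix(m)
}

#' Validate a distance matrix
#'
#' Checks symmetry (within tolerance), zero diagonal, non-negativity and
#' matching dimnames.
#'
#' @param d square numeric matrix or `dist` object.
#' @return symmetric matrix with ids as dimnames.
#' @export
as_distance_matrix <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) != ncol(d))
    stop("distance matrix must be square")
  if (is.null(rownames(d))) stop("distance matrix must carry ids")
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8,
                        check.attributes = FALSE)))
    stop("distance matrix must be symmetric")
  if (any(abs(diag(d)) > 1e-12)) stop("distance matrix diagonal must be 0")
  if (any(d < -1e-12)) stop("distances must be non-negative")
  d <- (d + t(d)) / 2
  diag(d) <- 0
  colnames(d) <- rownames(d)
  d
}
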