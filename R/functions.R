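#' Assemble a reference functional-profile set
#'
#' Bundles per-reference functional profiles (e.g. KO or pathway
#' abundances inferred from complete genomes), 16S rRNA copy numbers used
#' to normalise them, and the OTU-to-reference identity mapping (supplied
#' as input; typically the product of a 97%-identity alignment).
#'
#' @param profiles non-negative matrix, references x functions, with
#'   dimnames.
#' @param copy_number_16S positive numeric, named by reference id.
#' @param otu_to_reference named character vector: OTU id -> reference id.
#'   OTUs absent from the map are unmapped.
#' @return object of class `function_profile_set`.
#' @export
function_profile_set <- function(profiles, copy_number_16S,
                                 otu_to_reference) {
  if (!is.matrix(profiles) || is.null(rownames(profiles)) ||
      is.null(colnames(profiles)))
    stop("profiles must be a reference x function matrix with dimnames")
  if (any(profiles < 0)) stop("profiles must be non-negative")
  cn <- copy_number_16S[rownames(profiles)]
  if (anyNA(cn) || any(cn <= 0))
    stop("every reference needs a positive 16S copy number")
  bad <- setdiff(unname(otu_to_reference), rownames(profiles))
  if (length(bad))
    stop("otu_to_reference maps to unknown reference(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  x <- list(profiles = profiles,
            copy_number_16S = stats::setNames(as.numeric(cn),
                                              rownames(profiles)),
            otu_to_reference = otu_to_reference)
  class(x) <- "function_profile_set"
  x
}

#' @export
print.function_profile_set <- function(x, ...) {
  cat("function_profile_set:", nrow(x$profiles), "references x",
      ncol(x$profiles), "functions;", length(x$otu_to_reference),
      "OTUs mapped\n")
  invisible(x)
}

#' Read reference profiles from TSV
#'
#' @param profile_path TSV, references in rows, functions in columns, plus
#'   a `copy_number_16S` column.
#' @param mapping_path two-column TSV (`otu_id`, `reference_id`).
#' @return a `function_profile_set`.
#' @export
read_function_profiles <- function(profile_path, mapping_path) {
  df <- utils::read.delim(profile_path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!"copy_number_16S" %in% colnames(df))
    stop("profile table needs a copy_number_16S column")
  refs <- df[[1L]]
  cn <- stats::setNames(df$copy_number_16S, refs)
  body <- as.matrix(df[, setdiff(colnames(df)[-1L], "copy_number_16S"),
                       drop = FALSE])
  rownames(body) <- refs
  mp <- utils::read.delim(mapping_path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  map <- stats::setNames(as.character(mp[[2L]]), mp[[1L]])
  function_profile_set(body, cn, map)
}

#' Write reference profiles and mapping as TSV
#' @param refs `function_profile_set`.
#' @param profile_path,mapping_path output paths.
#' @export
write_function_profiles <- function(refs, profile_path, mapping_path) {
  df <- data.frame(reference_id = rownames(refs$profiles),
                   copy_number_16S = refs$copy_number_16S,
                   refs$profiles, check.names = FALSE)
  utils::write.table(df, profile_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  mp <- data.frame(otu_id = names(refs$otu_to_reference),
                   reference_id = unname(refs$otu_to_reference))
  utils::write.table(mp, mapping_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Predict metagenome function profiles from OTU abundances
#'
#' Each mapped OTU contributes abundance x (reference profile / 16S copy
#' number); contributions are summed per unit and normalised to sum to 1.
#' The fraction of taxonomic units unexplained (FTU) is the abundance mass
#' of unmapped OTUs over the unit's total abundance mass. Output is
#' invariant to rescaling a unit's abundances by a positive constant.
#'
#' @param abundances non-negative matrix, units (samples or host species)
#'   x OTUs.
#' @param refs `function_profile_set`.
#' @return list: `profiles` (units x functions; rows sum to 1, all-NA with
#'   a flag when nothing mapped), `ftu` (named vector), `flagged` (units
#'   with zero mapped abundance).
#' @export
predict_metagenome <- function(abundances, refs) {
  if (any(abundances < 0)) stop("abundances must be non-negative")
  otus <- colnames(abundances)
  mapped <- intersect(otus, names(refs$otu_to_reference))
  # per-OTU profile, already copy-number normalised
  P <- refs$profiles[refs$otu_to_reference[mapped], , drop = FALSE] /
    refs$copy_number_16S[refs$otu_to_reference[mapped]]
  rownames(P) <- mapped
  raw <- abundances[, mapped, drop = FALSE] %*% P
  total_mass <- rowSums(abundances)
  mapped_mass <- rowSums(abundances[, mapped, drop = FALSE])
  ftu <- ifelse(total_mass > 0, 1 - mapped_mass / total_mass, NA_real_)
  rs <- rowSums(raw)
  flagged <- rownames(abundances)[rs == 0]
  out <- raw / ifelse(rs > 0, rs, NA_real_)
  rownames(out) <- rownames(abundances)
  list(profiles = out, ftu = stats::setNames(ftu, rownames(abundances)),
       flagged = flagged)
}

#' Count and fraction of OTUs with a functional reference
#'
#' @param refs `function_profile_set`.
#' @param otu_ids OTU identifiers to assess.
#' @return list with `n_mapped` and `fraction` (0 when no mapping exists).
#' @export
profiled_fraction <- function(refs, otu_ids) {
  if (!length(otu_ids)) return(list(n_mapped = 0L, fraction = 0))
  n <- sum(otu_ids %in% names(refs$otu_to_reference))
  list(n_mapped = n, fraction = n / length(otu_ids))
}

#' Elementwise log2 transform with pseudocount
#'
#' log2(x + pseudocount): monotone, hence rank-preserving per column. The
#' default pseudocount suits sum-to-1 relative-abundance profiles.
#'
#' @param x non-negative matrix.
#' @param pseudocount positive offset (default 1e-6).
#' @return transformed matrix.
#' @export
log2_transform <- function(x, pseudocount = 1e-6) {
  if (pseudocount <= 0) stop("config error: pseudocount must be > 0")
  if (any(x < 0, na.rm = TRUE)) stop("x must be non-negative")
  log2(x + pseudocount)
}

#' Aggregate sample abundances to host species
#'
#' Mean of per-sample relative abundances within each species; the default
#' unit for module-level functional statistics.
#'
#' @param table OTU table (samples x OTUs).
#' @param meta sample metadata.
#' @return species x OTU matrix of mean relative abundances.
#' @export
aggregate_to_species <- function(table, meta) {
  meta <- sample_metadata(meta)
  sp <- meta$host_species[match(rownames(table), meta$sample_id)]
  if (anyNA(sp)) stop("all samples must map to a host species")
  rel <- sweep(table, 1, rowSums(table), "/")
  rowsum(rel, group = sp) / as.vector(table(sp)[sort(unique(sp))])
}
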