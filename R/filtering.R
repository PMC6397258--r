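#' Filter-stage bookkeeping record
#'
#' @param stage name of the filtering stage.
#' @param items_in number of items before filtering.
#' @param removed_ids identifiers removed by the stage.
#' @return object of class `filter_report`; `items_out` is always
#'   `items_in - length(removed_ids)`.
#' @export
filter_report <- function(stage, items_in, removed_ids) {
  r <- list(stage = stage, items_in = as.integer(items_in),
            items_out = as.integer(items_in) - length(removed_ids),
            removed_ids = as.character(removed_ids))
  class(r) <- "filter_report"
  r
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("filter_report [%s]: %d -> %d (%d removed)\n",
              x$stage, x$items_in, x$items_out, length(x$removed_ids)))
  invisible(x)
}

#' Select qualifying sponge samples
#'
#' Keeps sponge samples from healthy adult individuals with unequivocal
#' taxonomic identification and strictly more than `min_reads` sequencing
#' reads, belonging to host species that retain at least `min_samples`
#' qualifying samples. OTUs left with zero total count are dropped.
#'
#' @param table OTU table.
#' @param meta sample metadata covering all samples of `table`.
#' @param min_samples minimum qualifying samples per host species (default 3).
#' @param min_reads read-count threshold; samples must exceed it (default 1e4).
#' @return list with the filtered `table` and a `filter_report` over samples.
#' @export
select_samples <- function(table, meta, min_samples = 3, min_reads = 10000) {
  meta <- sample_metadata(meta)
  miss <- setdiff(rownames(table), meta$sample_id)
  if (length(miss))
    stop("metadata lacks sample(s): ", paste(utils::head(miss, 5L),
                                             collapse = ", "))
  m <- meta[match(rownames(table), meta$sample_id), ]
  reads <- ifelse(is.na(m$read_count), rowSums(table), m$read_count)
  ok <- m$sample_type == "sponge" &
    reads > min_reads &
    !is.na(m$health_status) & m$health_status == "healthy" &
    !is.na(m$life_stage) & m$life_stage == "adult" &
    !is.na(m$taxonomic_id_unequivocal) & m$taxonomic_id_unequivocal &
    !is.na(m$host_species)
  per_species <- table(m$host_species[ok])
  good_species <- names(per_species)[per_species >= min_samples]
  keep <- ok & m$host_species %in% good_species
  if (!any(keep))
    stop("no samples survive sample selection")
  out <- table[keep, , drop = FALSE]
  out <- out[, colSums(out) > 0, drop = FALSE]
  list(table = out,
       report = filter_report("select_samples", nrow(table),
                              rownames(table)[!keep]))
}

#' Remove likely-seawater OTUs from sponge samples
#'
#' An OTU is removed from all sponge samples iff its relative abundance in
#' the reads pooled across all seawater samples strictly exceeds
#' `threshold` (default 0.01%). Seawater samples are dropped from the
#' output; with `mode = "per-sample-mean"` the mean of per-sample relative
#' abundances is compared to the threshold instead of the pooled value.
#'
#' @param table OTU table containing sponge and seawater samples.
#' @param meta sample metadata.
#' @param threshold relative-abundance threshold (default 1e-4, i.e. 0.01%).
#' @param mode `"pooled"` (default) or `"per-sample-mean"`.
#' @return list with the sponge-only `table` (contaminant columns dropped)
#'   and a `filter_report` over OTUs present in sponge samples.
#' @export
remove_seawater_otus <- function(table, meta, threshold = 1e-4,
                                 mode = c("pooled", "per-sample-mean")) {
  mode <- match.arg(mode)
  meta <- sample_metadata(meta)
  sw_ids <- intersect(rownames(table),
                      meta$sample_id[meta$sample_type == "seawater"])
  sp_ids <- intersect(rownames(table),
                      meta$sample_id[meta$sample_type == "sponge"])
  sponge <- table[sp_ids, , drop = FALSE]
  present_sponge <- colnames(sponge)[colSums(sponge) > 0]
  if (!length(sw_ids)) {
    warning("no seawater samples present; table returned unchanged")
    out <- sponge[, present_sponge, drop = FALSE]
    return(list(table = out,
                report = filter_report("remove_seawater_otus",
                                       length(present_sponge), character(0))))
  }
  sw <- table[sw_ids, , drop = FALSE]
  if (mode == "pooled") {
    pooled <- colSums(sw)
    rel <- pooled / sum(pooled)
  } else {
    rel_rows <- sweep(sw, 1, rowSums(sw), "/")
    rel <- colMeans(rel_rows)
  }
  contaminant <- colnames(table)[rel > threshold]
  removed <- intersect(present_sponge, contaminant)
  keep <- setdiff(present_sponge, removed)
  list(table = sponge[, keep, drop = FALSE],
       report = filter_report("remove_seawater_otus",
                              length(present_sponge), removed))
}

#' Flag core host-OTU associations
#'
#' For each host species, an OTU is core iff (i) it occurs in at least
#' `ceil(prevalence * n_samples)` of the species' samples and (ii) its mean
#' relative abundance, computed over the configured scope, strictly exceeds
#' `abundance`. "At least two-thirds" is a lower bound, so fractional sample
#' counts round up.
#'
#' @param table OTU table (sponge samples).
#' @param meta sample metadata.
#' @param prevalence prevalence fraction (default 2/3).
#' @param abundance relative-abundance threshold (default 1e-4).
#' @param abundance_scope `"per-species"` (mean relative abundance over the
#'   species' own samples; default) or `"whole-dataset"` (over all samples).
#' @return list with `core`: a 0/1 species x OTU flag matrix, and a
#'   `filter_report` over OTUs (removed = OTUs core for no species).
#' @export
core_microbiome <- function(table, meta, prevalence = 2 / 3,
                            abundance = 1e-4,
                            abundance_scope = c("per-species",
                                                "whole-dataset")) {
  abundance_scope <- match.arg(abundance_scope)
  meta <- sample_metadata(meta)
  m <- meta[match(rownames(table), meta$sample_id), ]
  if (anyNA(m$host_species))
    stop("all samples must map to a host species")
  rel <- sweep(table, 1, rowSums(table), "/")
  species <- sort(unique(m$host_species))
  pres <- rowsum((table > 0) + 0, group = m$host_species)   # species x OTU
  nsamp <- as.vector(table(m$host_species)[rownames(pres)])
  need <- ceiling(prevalence * nsamp)
  prev_ok <- sweep(pres, 1, need, ">=")
  if (abundance_scope == "per-species") {
    mean_rel <- rowsum(rel, group = m$host_species) / nsamp
    ab_ok <- mean_rel > abundance
  } else {
    global_mean <- colMeans(rel)
    ab_ok <- matrix(rep(global_mean > abundance, each = nrow(pres)),
                    nrow = nrow(pres), dimnames = dimnames(pres))
  }
  core <- (prev_ok & ab_ok) + 0
  removed <- colnames(core)[colSums(core) == 0]
  list(core = core,
       report = filter_report("core_microbiome", ncol(table), removed))
}

#' Rarefy an OTU table to fixed depth
#'
#' Each sample is subsampled without replacement to exactly `depth` reads
#' (via [vegan::rrarefy()]); the same seed reproduces the same table.
#'
#' @param table OTU table with integer counts.
#' @param depth target reads per sample (default 1e4).
#' @param seed integer seed.
#' @return rarefied OTU table; every row sums to `depth`.
#' @export
rarefy <- function(table, depth = 10000, seed = 1) {
  tot <- rowSums(table)
  low <- rownames(table)[tot < depth]
  if (length(low))
    stop("sample(s) below rarefaction depth ", depth, ": ",
         paste(utils::head(low, 5L), collapse = ", "))
  set.seed(seed)
  # vegan heuristically warns when the smallest positive count exceeds 1;
  # legitimate count tables can trip it, so that warning is muffled
  out <- withCallingHandlers(
    vegan::rrarefy(round(table), depth),
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  storage.mode(out) <- "double"
  dimnames(out) <- dimnames(table)
  out
}

#' Robustness of a module partition to rarefaction
#'
#' Repeats: rarefy with an independent substream, aggregate samples to host
#' species (mean relative abundance), compute Bray-Curtis among species,
#' and run pairwise PERMANOVA with module membership as the grouping factor
#' and Benjamini-Yekutieli correction. Summarises per module pair the mean
#' and sd of pseudo-F and adjusted p across replicates.
#'
#' @param table OTU table (sponge samples).
#' @param meta sample metadata.
#' @param partition `module_partition` defined on the host species in
#'   `table`.
#' @param n_reps number of rarefied replicates (default 100; must be >= 2).
#' @param depth rarefaction depth (default 1e4).
#' @param seed integer seed.
#' @param n_perm permutations per PERMANOVA (default 999).
#' @return data.frame per module pair: mean/sd of F and adjusted p.
#' @export
rarefaction_robustness <- function(table, meta, partition, n_reps = 100,
                                   depth = 10000, seed = 1, n_perm = 999) {
  if (n_reps < 2) stop("config error: n_reps must be >= 2")
  meta <- sample_metadata(meta)
  m <- meta[match(rownames(table), meta$sample_id), ]
  host_mod <- partition$membership
  miss <- setdiff(unique(m$host_species), names(host_mod))
  if (length(miss))
    stop("partition misses host species: ", paste(miss, collapse = ", "))
  seeds <- derive_seeds(seed, 2L * n_reps)
  res <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    rar <- rarefy(table, depth = depth, seed = seeds[r])
    rel <- sweep(rar, 1, rowSums(rar), "/")
    agg <- rowsum(rel, group = m$host_species) /
      as.vector(table(m$host_species)[sort(unique(m$host_species))])
    d <- bray_curtis(agg)
    groups <- host_mod[rownames(agg)]
    pw <- pairwise_permanova(d, groups, correction = "BY", n_perm = n_perm,
                             seed = seeds[n_reps + r])
    res[[r]] <- pw
  }
  pairs <- res[[1L]]$comparison
  out <- lapply(pairs, function(p) {
    Fv <- vapply(res, function(x) x$statistic[x$comparison == p], numeric(1))
    pv <- vapply(res, function(x) x$p_adjusted[x$comparison == p], numeric(1))
    data.frame(comparison = p, F_mean = mean(Fv), F_sd = stats::sd(Fv),
               p_adj_mean = mean(pv), p_adj_sd = stats::sd(pv))
  })
  do.call(rbind, out)
}
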