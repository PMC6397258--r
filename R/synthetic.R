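#' Configuration for the synthetic sponge-microbiome generator
#'
#' Defines a dataset with planted host-OTU modules: each module owns a set
#' of host species and a set of OTUs; an OTU occurs in a sample of a host
#' of its own module with probability `p_within` and in other modules'
#' hosts with probability `p_between`. Module structure is mirrored in
#' sample temperatures (per-module Normal means), host HMA/LMA labels,
#' the OTU phylogeny (modules are clades) and per-OTU functional profiles
#' (disjoint enriched function blocks).
#'
#' @param n_modules number of planted modules.
#' @param hosts_per_module integer (recycled) or vector of host counts.
#' @param otus_per_module integer (recycled) or vector of OTU counts.
#' @param samples_per_host samples per host species (>= 3).
#' @param reads_per_sample sequencing depth per sample.
#' @param p_within occurrence probability within the own module.
#' @param p_between occurrence probability across modules
#'   (`p_within > p_between` required for planted structure).
#' @param module_temperature_means per-module mean water temperature, deg C.
#' @param temperature_sd temperature standard deviation, deg C.
#' @param hma_fraction_per_module per-module probability a host is HMA.
#' @param n_seawater_samples seawater samples added by
#'   [generate_seawater()].
#' @param seawater_contaminant_fraction fraction of OTUs designated as
#'   seawater contaminants.
#' @param tree_within_module_depth tip branch length inside a module clade.
#' @param tree_between_module_depth stem length joining module clades.
#' @param n_functions number of functional categories.
#' @param function_signal multiplicative enrichment of a module's function
#'   block (1 = no signal).
#' @param mapped_fraction fraction of OTUs with a functional reference.
#' @param seed integer master seed; one seed drives fixed per-component
#'   substreams, so later components never perturb earlier draws.
#' @return validated config list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_modules = 3,
                             hosts_per_module = 10,
                             otus_per_module = 50,
                             samples_per_host = 3,
                             reads_per_sample = 20000,
                             p_within = 0.9,
                             p_between = 0.01,
                             module_temperature_means = NULL,
                             temperature_sd = 3,
                             hma_fraction_per_module = NULL,
                             n_seawater_samples = 5,
                             seawater_contaminant_fraction = 0.05,
                             tree_within_module_depth = 0.1,
                             tree_between_module_depth = 1,
                             n_functions = 60,
                             function_signal = 4,
                             mapped_fraction = 1,
                             seed = 1) {
  rec <- function(x, what) {
    if (length(x) == 1L) x <- rep(x, n_modules)
    if (length(x) != n_modules)
      stop("config error: ", what, " must have length 1 or n_modules")
    x
  }
  if (is.null(module_temperature_means))
    module_temperature_means <- seq(27, 11, length.out = n_modules)
  if (is.null(hma_fraction_per_module))
    hma_fraction_per_module <- c(0.8, rep(0.2, n_modules - 1L))
  cfg <- list(
    n_modules = as.integer(n_modules),
    hosts_per_module = as.integer(rec(hosts_per_module, "hosts_per_module")),
    otus_per_module = as.integer(rec(otus_per_module, "otus_per_module")),
    samples_per_host = as.integer(samples_per_host),
    reads_per_sample = as.integer(reads_per_sample),
    p_within = p_within, p_between = p_between,
    module_temperature_means = rec(module_temperature_means,
                                   "module_temperature_means"),
    temperature_sd = temperature_sd,
    hma_fraction_per_module = rec(hma_fraction_per_module,
                                  "hma_fraction_per_module"),
    n_seawater_samples = as.integer(n_seawater_samples),
    seawater_contaminant_fraction = seawater_contaminant_fraction,
    tree_within_module_depth = tree_within_module_depth,
    tree_between_module_depth = tree_between_module_depth,
    n_functions = as.integer(n_functions),
    function_signal = function_signal,
    mapped_fraction = mapped_fraction,
    seed = as.integer(seed))
  if (cfg$samples_per_host < 3)
    stop("config error: samples_per_host must be >= 3")
  probs <- c(cfg$p_within, cfg$p_between, cfg$hma_fraction_per_module,
             cfg$seawater_contaminant_fraction, cfg$mapped_fraction)
  if (any(probs < 0 | probs > 1))
    stop("config error: probabilities must lie in [0, 1]")
  if (cfg$p_within <= cfg$p_between)
    stop("config error: p_within must exceed p_between")
  if (cfg$reads_per_sample < sum(cfg$otus_per_module))
    stop("config error: reads_per_sample must be >= total OTU count")
  class(cfg) <- "synthetic_config"
  cfg
}

# Fixed substream indices of the master seed. New components must append,
# never reorder, so earlier draws are stable.
synth_streams <- function(seed) {
  s <- derive_seeds(seed, 8L)
  list(weights = s[1], occurrence = s[2], temperature = s[3], hma = s[4],
       host_tree = s[5], functions = s[6], seawater = s[7], spare = s[8])
}

#' Generate a synthetic dataset with planted module structure
#'
#' Occurrence: OTU j of module M is present in a sample of a host of
#' module M' with probability `p_within` if M = M', else `p_between`.
#' Present OTUs receive one read each (so presence is observable) and the
#' remaining reads are allocated multinomially with lognormal(0, 1)
#' per-OTU relative weights, giving the fat-tailed abundance profile of
#' real 16S tables. Sample temperatures are Normal(module mean, sd). The
#' OTU tree makes modules clades; the host tree is generated independently
#' of module structure. Identical seeds give bit-identical output.
#'
#' @param config `synthetic_config`.
#' @return list: `table` (OTU table), `meta` (sample metadata), `traits`
#'   (HMA/LMA), `otu_tree`, `host_tree` (`phylo`), `functions`
#'   (`function_profile_set`), `truth` (`module_partition` of the planted
#'   structure).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  st <- synth_streams(config$seed)
  nm <- config$n_modules
  host_mod <- rep(seq_len(nm), config$hosts_per_module)
  otu_mod <- rep(seq_len(nm), config$otus_per_module)
  hosts <- sprintf("Host_m%d_%02d", host_mod,
                   unlist(lapply(config$hosts_per_module, seq_len)))
  otus <- sprintf("OTU_m%d_%03d", otu_mod,
                  unlist(lapply(config$otus_per_module, seq_len)))
  n_otus <- length(otus)

  set.seed(st$weights)
  w <- stats::rlnorm(n_otus, meanlog = 0, sdlog = 1)

  set.seed(st$occurrence)
  sample_host <- rep(hosts, each = config$samples_per_host)
  sample_mod <- rep(host_mod, each = config$samples_per_host)
  sample_ids <- sprintf("S_%s_r%d", sample_host,
                        rep(seq_len(config$samples_per_host),
                            times = length(hosts)))
  counts <- matrix(0, length(sample_ids), n_otus,
                   dimnames = list(sample_ids, otus))
  for (i in seq_along(sample_ids)) {
    p <- ifelse(otu_mod == sample_mod[i], config$p_within, config$p_between)
    pres <- stats::runif(n_otus) < p
    if (!any(pres)) next
    base <- as.numeric(pres)            # one guaranteed read per present OTU
    rest <- config$reads_per_sample - sum(base)
    extra <- if (rest > 0)
      as.vector(stats::rmultinom(1, rest, prob = w * pres)) else 0
    counts[i, ] <- base + extra
  }

  set.seed(st$temperature)
  temperature <- stats::rnorm(length(sample_ids),
                              mean = config$module_temperature_means[sample_mod],
                              sd = config$temperature_sd)
  depth_m <- stats::runif(length(sample_ids), 5, 50)
  meta <- sample_metadata(data.frame(
    sample_id = sample_ids, sample_type = "sponge",
    host_species = sample_host, health_status = "healthy",
    life_stage = "adult", taxonomic_id_unequivocal = TRUE,
    read_count = rowSums(counts), temperature = temperature,
    depth = depth_m, ecoregion = NA_character_,
    stringsAsFactors = FALSE))

  set.seed(st$hma)
  is_hma <- stats::runif(length(hosts)) < config$hma_fraction_per_module[host_mod]
  traits <- host_traits(data.frame(
    host_species = hosts, host_type = ifelse(is_hma, "HMA", "LMA"),
    stringsAsFactors = FALSE))

  # OTU tree: module clades, uniform tip depth within, joined at the root
  clades <- vapply(seq_len(nm), function(mmod) {
    tips <- otus[otu_mod == mmod]
    sprintf("(%s):%g",
            paste(sprintf("%s:%g", tips, config$tree_within_module_depth),
                  collapse = ","),
            config$tree_between_module_depth)
  }, character(1))
  otu_tree <- ape::read.tree(text = paste0("(", paste(clades, collapse = ","),
                                           ");"))

  set.seed(st$host_tree)
  host_tree <- ape::rtree(length(hosts), tip.label = sample(hosts))

  set.seed(st$functions)
  mapped <- otus[stats::runif(n_otus) < config$mapped_fraction]
  block <- split(seq_len(config$n_functions),
                 cut(seq_len(config$n_functions), nm, labels = FALSE))
  refs <- paste0("ref_", mapped)
  prof <- matrix(stats::runif(length(refs) * config$n_functions, 0.5, 1.5),
                 nrow = length(refs),
                 dimnames = list(refs, sprintf("K%05d",
                                               seq_len(config$n_functions))))
  for (i in seq_along(mapped)) {
    mmod <- otu_mod[match(mapped[i], otus)]
    prof[i, block[[mmod]]] <- prof[i, block[[mmod]]] * config$function_signal
  }
  cn <- stats::setNames(stats::runif(length(refs), 1, 5), refs)
  fps <- function_profile_set(prof, cn,
                              stats::setNames(refs, mapped))

  membership <- c(stats::setNames(host_mod, hosts),
                  stats::setNames(otu_mod, otus))
  node_class <- c(stats::setNames(rep("host", length(hosts)), hosts),
                  stats::setNames(rep("otu", n_otus), otus))
  truth <- module_partition(membership, node_class, Q = NA_real_)

  list(table = otu_table(counts), meta = meta, traits = traits,
       otu_tree = otu_tree, host_tree = host_tree, functions = fps,
       truth = truth)
}

#' Append synthetic seawater samples with designated contaminants
#'
#' Designates `seawater_contaminant_fraction` of the table's OTUs as
#' seawater contaminants and builds seawater samples in which exactly
#' those OTUs exceed 0.01% pooled relative abundance. A small set of
#' background sponge OTUs is seeded strictly below the threshold, and one
#' synthetic seawater-only filler taxon (`SW_background`, zero in all
#' sponge samples) absorbs enough reads to pin the background fractions
#' down. The contaminant id set is returned as a test oracle.
#'
#' @param config `synthetic_config`.
#' @param table sponge OTU table from [generate_dataset()].
#' @param meta matching sample metadata.
#' @return list: `table` (sponge + seawater rows, plus the filler column),
#'   `meta` (extended), `contaminants` (character vector).
#' @export
generate_seawater <- function(config, table, meta) {
  stopifnot(inherits(config, "synthetic_config"))
  st <- synth_streams(config$seed)
  set.seed(st$seawater)
  n_sw <- config$n_seawater_samples
  if (n_sw < 1) stop("config error: n_seawater_samples must be >= 1")
  otus <- colnames(table)
  n_cont <- floor(config$seawater_contaminant_fraction * length(otus))
  contaminants <- if (n_cont > 0) sort(sample(otus, n_cont)) else character(0)
  rest <- setdiff(otus, contaminants)
  n_bg <- min(length(rest), max(0L, ceiling(0.1 * length(rest))))
  background <- if (n_bg > 0) sample(rest, n_bg) else character(0)

  filler_total <- 20000
  C <- 50
  for (it in 1:3) {   # fixed-point: pooled total depends on C
    total <- filler_total + n_cont * C + n_bg
    C <- max(50, ceiling(2e-4 * total))
  }
  total <- filler_total + n_cont * C + n_bg
  stopifnot(n_cont == 0 || C / total > 1e-4, n_bg == 0 || 1 / total <= 1e-4)

  sw_ids <- sprintf("SW_%02d", seq_len(n_sw))
  sw <- matrix(0, n_sw, length(otus) + 1L,
               dimnames = list(sw_ids, c(otus, "SW_background")))
  spread <- function(x) {  # split pooled count across samples, sum exact
    base <- rep(x %/% n_sw, n_sw)
    if (x %% n_sw > 0) base[seq_len(x %% n_sw)] <- base[seq_len(x %% n_sw)] + 1
    base
  }
  for (o in contaminants) sw[, o] <- spread(C)
  for (o in background) sw[sample(n_sw, 1L), o] <- 1
  sw[, "SW_background"] <- spread(filler_total)

  full <- cbind(table, SW_background = 0)
  combined <- otu_table(rbind(full, sw))
  sw_meta <- sample_metadata(data.frame(
    sample_id = sw_ids, sample_type = "seawater",
    host_species = NA_character_, health_status = NA_character_,
    life_stage = NA_character_, taxonomic_id_unequivocal = NA,
    read_count = rowSums(sw), temperature = NA_real_, depth = NA_real_,
    ecoregion = NA_character_, stringsAsFactors = FALSE))
  list(table = combined, meta = rbind(meta, sw_meta),
       contaminants = contaminants)
}
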