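#' Assemble a pipeline configuration
#'
#' Defaults describe the fully synthetic study: a 200-genome viral
#' reference, 20 vs 10 samples in two groups, 50k reads per sample with 30%
#' host contamination, and the printed analysis thresholds (95% identity,
#' 200 bp presence run, 9999 permutations for factor/vector/Mantel fits,
#' 1000 for the differential-abundance test).  Alternatively a YAML file
#' with the same structure can be loaded via `load_config()`.
#'
#' @param ... Named overrides of the defaults (nested lists are merged at
#'   the top level only).
#' @return A `viromescope_config` list.
#' @export
viromescope_config <- function(...) {
  defaults <- list(
    seed = 1,
    outdir = NULL,
    simulate = list(
      n_genomes = 200, length_range = c(1500, 8000),
      group_sizes = c(smoker = 20, nonsmoker = 10),
      reads_per_sample = 50000, read_length = 150,
      substitution_error_rate = 0.005,
      host_contamination_fraction = 0.3, duplicate_rate = 0.05,
      host_genome_length = 1e5,
      n_metabolites = 83, n_cytokines = 39, n_bacteria = 100
    ),
    paths = list(
      reference_fasta = NULL, host_fasta = NULL, fastq_dir = NULL,
      sam_dir = NULL, metadata = NULL, metabolites = NULL,
      cytokines = NULL, bacteria = NULL
    ),
    thresholds = list(
      min_identity = 95, min_run = 200, phred_min = 10, min_length = 50,
      seed_k = 21, perm_fit = 9999, perm_metastats = 1000
    )
  )
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(defaults[[nm]]) && is.list(over[[nm]])) {
      defaults[[nm]][names(over[[nm]])] <- over[[nm]]
    } else {
      defaults[[nm]] <- over[[nm]]
    }
  }
  cfg <- defaults
  th <- cfg$thresholds
  if (th$min_identity < 0 || th$min_identity > 100 || th$min_run < 1) {
    stop("invalid thresholds", call. = FALSE)
  }
  given <- Filter(Negate(is.null), cfg$paths)
  missing <- names(given)[!vapply(given, file.exists, logical(1))]
  if (length(missing) > 0) {
    stop("configured path(s) do not exist: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  structure(cfg, class = "viromescope_config")
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file whose top-level keys match
#'   [viromescope_config()] arguments.
#' @return A `viromescope_config`.
#' @export
load_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulate$group_sizes)) {
    y$simulate$group_sizes <- unlist(y$simulate$group_sizes)
  }
  do.call(viromescope_config, y)
}

write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a wide sample-by-feature TSV
#'
#' @param path TSV with a `sample_id` column.
#' @return Wide tibble.
#' @export
read_matrix_tsv <- function(path) {
  tibble::as_tibble(read.table(path, header = TRUE, sep = "\t",
                               check.names = FALSE,
                               stringsAsFactors = FALSE))
}

#' Shared and group-unique feature sets from presence calls
#'
#' A feature counts as detected in a group when it is present in at least
#' one of the group's samples.
#'
#' @param presence Long tibble with `sample_id`, `genome_id` (or
#'   `feature_id`) and logical `present`.
#' @param groups Named vector or two-column tibble mapping sample ids to
#'   groups.
#' @return Tibble `feature_id`, `detected_in` (`"both"`, one of the group
#'   names, or `"neither"`); attribute `fractions` gives the shared and
#'   per-group-unique fractions of the detected union.
#' @export
group_feature_sets <- function(presence, groups) {
  feat_col <- if ("feature_id" %in% names(presence)) "feature_id"
              else "genome_id"
  if (is.data.frame(groups)) {
    groups <- setNames(groups$group, groups$sample_id)
  }
  lev <- unique(groups)
  det <- presence %>%
    dplyr::mutate(group = groups[.data$sample_id]) %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(feat_col)), .data$group) %>%
    dplyr::summarise(detected = any(.data$present), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "group", values_from = "detected",
                       values_fill = FALSE)
  in1 <- det[[lev[1]]]; in2 <- det[[lev[2]]]
  out <- tibble::tibble(
    feature_id = det[[feat_col]],
    detected_in = dplyr::case_when(
      in1 & in2 ~ "both",
      in1 ~ lev[1],
      in2 ~ lev[2],
      TRUE ~ "neither"
    )
  )
  union_n <- sum(in1 | in2)
  attr(out, "fractions") <- c(
    shared = if (union_n) sum(in1 & in2) / union_n else NA_real_,
    setNames(c(if (union_n) sum(in1 & !in2) / union_n else NA_real_,
               if (union_n) sum(!in1 & in2) / union_n else NA_real_),
             paste0("unique_", lev))
  )
  out
}

#' Run the full synthetic virome pipeline
#'
#' Executes simulate -> trim/de-duplicate/host-removal -> map -> quantify
#' -> ecology/differential abundance/network with one seed, returning a run
#' report; stages whose external inputs are configured read those instead
#' of simulating.  Re-running with the same configuration reproduces
#' identical artifacts.
#'
#' @param config A [viromescope_config()] (or YAML path).
#' @param verbose Print per-stage progress lines.
#' @return A `run_report` list: `accounting`, `quantification`,
#'   `abundance`, `genus_abundance`, `presence`, `feature_sets`, `alpha`,
#'   `alpha_tests`, `ordination`, `fits`, `differential`, `network`,
#'   `clusters`, `design`, `omics`, `manifest`.
#' @export
run_pipeline <- function(config = viromescope_config(), verbose = TRUE) {
  if (is.character(config)) config <- load_config(config)
  stopifnot(inherits(config, "viromescope_config"))
  th <- config$thresholds
  sim <- config$simulate
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- Sys.time()

  # --- stage: inputs / simulation -----------------------------------------
  if (!is.null(config$paths$reference_fasta)) {
    stop("external reference input requires taxonomy metadata; ",
         "supply it via design objects and the lower-level functions",
         call. = FALSE)
  }
  say("stage simulate: %d genomes, %s samples",
      sim$n_genomes, sum(sim$group_sizes))
  reference <- generate_reference_db(sim$n_genomes, sim$length_range,
                                     seed = derive_seed(config$seed, 1))
  host <- simulate_host_genome(sim$host_genome_length,
                               seed = derive_seed(config$seed, 2))
  design <- design_communities(reference, sim$group_sizes,
                               seed = derive_seed(config$seed, 3))
  rc <- sim_config(reads_per_sample = sim$reads_per_sample,
                   read_length = sim$read_length,
                   substitution_error_rate = sim$substitution_error_rate,
                   host_contamination_fraction =
                     sim$host_contamination_fraction,
                   duplicate_rate = sim$duplicate_rate,
                   seed = derive_seed(config$seed, 4))
  omics <- simulate_omics(design, sim$n_metabolites, sim$n_cytokines,
                          sim$n_bacteria,
                          seed = derive_seed(config$seed, 5))

  # --- stage: reads -> hits -> quantification (streamed per sample) -------
  quants <- list()
  accounting <- list()
  for (sid in design$samples$sample_id) {
    reads <- simulate_reads(design, host, rc, samples = sid)$reads[[sid]]
    pr <- process_reads(reads, host, th$phred_min, th$min_length,
                        th$min_identity, th$seed_k)
    decon <- nrow(pr$reads)
    hits <- map_reads(pr$reads, design$reference, seed_k = th$seed_k,
                      min_identity_pct = th$min_identity)
    q <- quantify_sample(hits, design$reference, decon,
                         th$min_identity, th$min_run)
    q$sample_id <- sid
    quants[[sid]] <- q
    accounting[[sid]] <- dplyr::mutate(pr$accounting, sample_id = sid)
    say("stage quantify: %s, %d decontaminated reads, %d populations",
        sid, decon, sum(q$present))
  }
  quants <- purrr::list_rbind(quants)
  accounting <- purrr::list_rbind(accounting)

  abundance <- build_abundance_matrix(quants)
  genus <- aggregate_by_host(abundance, reference, "genus")
  presence <- dplyr::select(quants, "sample_id", "genome_id", "present")
  feature_sets <- group_feature_sets(presence, design$samples)

  # --- stage: ecology ------------------------------------------------------
  say("stage ecology: diversity, ordination, permutation fits")
  groups <- design$samples$group
  alpha <- alpha_diversity(abundance)
  g1 <- groups == groups[1]
  alpha_tests <- purrr::map(
    c("richness", "shannon", "pielou"),
    function(metric) {
      dplyr::mutate(mann_whitney(alpha[[metric]][g1], alpha[[metric]][!g1]),
                    metric = metric, .before = 1)
    }) %>% purrr::list_rbind()

  d_vir <- bray_curtis(abundance)
  ord <- pcoa(d_vir)
  fits <- list(
    smoking_virome = factor_fit(ord, groups, th$perm_fit,
                                seed = derive_seed(config$seed, 6))
  )

  bact <- omics$bacteria
  d_bact <- bray_curtis(bact)
  fits$smoking_bacteriome <- factor_fit(pcoa(d_bact), groups, th$perm_fit,
                                        seed = derive_seed(config$seed, 7))

  met <- presence_filter(omics$metabolites, 0.5)
  met_scaled <- autoscale(met)
  d_met_bray <- bray_curtis(min_shift_nonneg(met_scaled))
  fits$smoking_metabolome <- factor_fit(pcoa(d_met_bray), groups,
                                        th$perm_fit,
                                        seed = derive_seed(config$seed, 8))
  mantels <- list(
    virome_metabolome = mantel_test(d_vir, euclidean_dist(met_scaled),
                                    n_perm = th$perm_fit,
                                    seed = derive_seed(config$seed, 9)),
    virome_bacteriome = mantel_test(d_vir, d_bact, n_perm = th$perm_fit,
                                    seed = derive_seed(config$seed, 10))
  )
  fits <- adjust_fits(
    purrr::list_rbind(c(fits, mantels), names_to = "term"))

  # --- stage: differential abundance --------------------------------------
  say("stage diffabund: %d host genera", ncol(genus) - 1)
  differential <- metastats_test(genus, groups, th$perm_metastats,
                                 seed = derive_seed(config$seed, 11))

  # --- stage: network ------------------------------------------------------
  say("stage network: CLR + neighborhood selection")
  clr <- clr_transform(abundance)
  net <- mb_network(clr)
  clusters <- detect_clusters(net)

  report <- structure(list(
    accounting = accounting, quantification = quants,
    abundance = abundance, genus_abundance = genus, presence = presence,
    feature_sets = feature_sets, alpha = alpha, alpha_tests = alpha_tests,
    ordination = ord, fits = fits, differential = differential,
    network = net, clusters = clusters, design = design, omics = omics,
    manifest = list(
      seed = config$seed, thresholds = th, simulate = sim,
      elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
      package_version = as.character(utils::packageVersion("viromescope"))
    )
  ), class = "run_report")

  if (!is.null(config$outdir)) write_report(report, config$outdir)
  report
}

#' Write run-report artifacts as plain-text files
#'
#' @param report A `run_report`.
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(report$accounting, file.path(outdir, "read_accounting.tsv"))
  write_tsv(report$quantification, file.path(outdir, "quantification.tsv"))
  write_tsv(report$abundance, file.path(outdir, "abundance.tsv"))
  write_tsv(report$genus_abundance, file.path(outdir, "genus_abundance.tsv"))
  write_tsv(report$presence, file.path(outdir, "presence.tsv"))
  write_tsv(report$alpha, file.path(outdir, "alpha_diversity.tsv"))
  write_tsv(report$alpha_tests, file.path(outdir, "alpha_tests.tsv"))
  write_tsv(dplyr::select(report$fits, -dplyr::any_of("direction")),
            file.path(outdir, "permutation_fits.tsv"))
  write_tsv(report$differential, file.path(outdir, "differential.tsv"))
  write_tsv(tidy(report$network), file.path(outdir, "network_edges.tsv"))
  write_tsv(report$clusters, file.path(outdir, "network_clusters.tsv"))
  write_newick(upgma(bray_curtis(report$abundance)),
               file.path(outdir, "samples_upgma.nwk"))
  jsonlite::write_json(report$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}

#' @export
#' @method print run_report
print.run_report <- function(x, ...) {
  det <- sum(colSums(abund_matrix(x$abundance)) > 0)
  cat("<run_report>\n",
      "  samples: ", nrow(x$alpha), "\n",
      "  detected viral populations: ", det, "\n",
      "  shared fraction: ",
      signif(attr(x$feature_sets, "fractions")[["shared"]], 3), "\n",
      "  smoking factor fit on virome: r2 = ",
      signif(x$fits$effect[x$fits$term == "smoking_virome"], 3),
      ", p = ", signif(x$fits$p_raw[x$fits$term == "smoking_virome"], 3),
      "\n", sep = "")
  invisible(x)
}

#' @export
glance.run_report <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x$alpha),
    n_detected = sum(colSums(abund_matrix(x$abundance)) > 0),
    shared_fraction = attr(x$feature_sets, "fractions")[["shared"]],
    smoking_r2 = x$fits$effect[x$fits$term == "smoking_virome"],
    smoking_p = x$fits$p_raw[x$fits$term == "smoking_virome"],
    n_significant_genera = sum(x$differential$p_value < 0.05, na.rm = TRUE),
    n_network_clusters = attr(x$clusters, "n_clusters")
  )
}
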