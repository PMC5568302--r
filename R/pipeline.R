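#' Default demonstration configuration for the full pipeline
#'
#' Returns the flat key-value configuration used by [run_pipeline()]. All
#' values mirror the module-level defaults; the demo data are fully
#' synthetic with known ground truth.
#'
#' @param seed Master seed; every stage derives its own seed from it.
#' @return Named list of configuration values.
#' @export
default_run_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    # coding-allele simulation
    n_groups = 6L, n_haplotypes_per_group = 6L, codon_count = 120L,
    aa_diffs_between_groups = 2L, syn_diffs_within_group = 1L,
    # two-region polymorphism/divergence simulation (1-based inclusive
    # locus coordinates; lengths follow the opsin locus region sizes)
    region_names = c("up", "gene", "down"),
    region_starts = c(1L, 1933L, 3219L),
    region_ends = c(1932L, 3218L, 5146L),
    theta = 5, divergence_time = 2, n_ingroup = 20L,
    divergence_inflation = c(1, 5, 1),
    alpha = 0.05,
    # tree
    bootstrap_reps = 100L,
    # spectra
    lambda_max_a1 = 544, lambda_max_a2 = 595,
    a2_fractions = c(0.3, 0.7), spectrum_noise_sd = 0.005,
    phi_step = 0.01, smooth_window_nm = 5
  )
}

#' Validate a pipeline configuration
#'
#' @param config Named list (see [default_run_config()]) or path to a YAML
#'   file of the same flat keys.
#' @return The validated configuration list.
#' @export
validate_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    user <- yaml::read_yaml(config)
    config <- utils::modifyList(default_run_config(), user)
  }
  stopifnot(is.list(config))
  config <- utils::modifyList(default_run_config(), config)
  ns <- length(config$region_names)
  if (length(config$region_starts) != ns || length(config$region_ends) != ns) {
    stop("region_names, region_starts and region_ends must have equal length")
  }
  if (any(config$region_starts > config$region_ends)) {
    stop("region start exceeds end for: ",
         paste(config$region_names[config$region_starts > config$region_ends],
               collapse = ", "))
  }
  ord <- order(config$region_starts)
  st <- config$region_starts[ord]; en <- config$region_ends[ord]
  nm <- config$region_names[ord]
  overlap <- which(st[-1L] <= en[-ns])
  if (length(overlap)) {
    stop("overlapping regions: ",
         paste(paste(nm[overlap], nm[overlap + 1L], sep = "/"), collapse = ", "))
  }
  config
}

#' Run the full analysis pipeline on synthetic demonstration data
#'
#' Orchestrates every stage end to end: coding-allele simulation, allele
#' grouping and frequency tables, polymorphic-site tables, mean Ds/Dn, the
#' two-region simulator and HKA panel, the FST screen, the neighbor-joining
#' allele tree with bootstrap supports, and A1/A2 spectral unmixing. All
#' outputs are plain CSV/FASTA/newick files plus a manifest; identical
#' configuration and seed give byte-identical outputs.
#'
#' @param config Configuration list or YAML path (see
#'   [default_run_config()], [validate_run_config()]).
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a named list of output file paths.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir, quiet = FALSE) {
  config <- validate_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  say <- function(...) if (!quiet) message(...)
  wcsv <- function(d, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(d, p, row.names = FALSE)
    paths[[name]] <<- p
  }

  say("stage 1/7: simulating coding alleles")
  cod <- simulate_coding_alleles(
    n_groups = config$n_groups,
    n_haplotypes_per_group = config$n_haplotypes_per_group,
    codon_count = config$codon_count,
    aa_diffs_between_groups = config$aa_diffs_between_groups,
    syn_diffs_within_group = config$syn_diffs_within_group,
    seed = config$seed)
  meta <- cod$truth
  g_idx <- as.integer(sub("G", "", meta$group))
  h_idx <- as.integer(sub(".*_h", "", meta$id))
  # each species is dominated by one allele; the last haplotype of each
  # group samples the neighbouring species to create minority alleles
  sp <- ifelse(h_idx < config$n_haplotypes_per_group, g_idx,
               g_idx %% config$n_groups + 1L)
  meta$species <- sprintf("sp%02d", sp)
  meta$locality <- ifelse(h_idx %% 2L == 0L, "siteA", "siteB")
  meta$depth_m <- 10 * sp
  write_fasta_alignment(cod$alignment, file.path(out_dir, "coding_alleles.fasta"))
  paths[["coding_alleles.fasta"]] <- file.path(out_dir, "coding_alleles.fasta")
  wcsv(meta, "sample_metadata.csv")

  say("stage 2/7: allele grouping, site table, frequencies")
  haps <- data.frame(id = rownames(cod$alignment),
                     sequence = unname(alignment_strings(cod$alignment)))
  haps <- merge(haps, meta[, c("id", "species", "locality", "depth_m")], by = "id")
  grp <- group_alleles(haps)
  wcsv(grp$assignments, "allele_assignments.csv")
  wcsv(site_table(cod$alignment), "site_table.csv")
  wcsv(allele_frequencies(grp, "species"), "allele_frequencies_species.csv")
  wcsv(allele_frequencies(grp, "locality"), "allele_frequencies_locality.csv")

  say("stage 3/7: mean Ds/Dn")
  dd <- mean_ds_dn(cod$alignment)
  wcsv(data.frame(ds = dd$ds, dn = dd$dn, pairs_used = dd$pairs_used,
                  pairs_undefined = dd$pairs_undefined), "ds_dn.csv")

  say("stage 4/7: two-region simulation and HKA panel")
  lens <- config$region_ends - config$region_starts + 1L
  sim <- simulate_two_region_data(sim_sequence_params(
    theta_per_region = config$theta, divergence_time = config$divergence_time,
    n_ingroup = config$n_ingroup, region_lengths = lens,
    divergence_inflation = config$divergence_inflation,
    seed = config$seed + 1000L))
  rcs <- lapply(seq_along(sim$regions), function(r) {
    region_counts(sim$regions[[r]]$ingroup, sim$regions[[r]]$outgroup,
                  config$region_names[r])
  })
  wcsv(data.frame(region = vapply(rcs, `[[`, character(1L), "name"),
                  S = vapply(rcs, `[[`, numeric(1L), "S"),
                  D = vapply(rcs, `[[`, numeric(1L), "D"),
                  n = vapply(rcs, `[[`, numeric(1L), "n"),
                  L_sites = vapply(rcs, `[[`, numeric(1L), "L_sites")),
       "region_counts.csv")
  wcsv(as.data.frame(hka_panel(rcs)), "hka_panel.csv")

  say("stage 5/7: FST screen")
  fst <- fst_matrix(cod$alignment, meta$species)
  p <- file.path(out_dir, "fst_matrix.csv")
  utils::write.csv(as.data.frame(fst), p)
  paths[["fst_matrix.csv"]] <- p
  focal <- sort(unique(meta$species))[1L]
  mp <- min_fst_partner(focal, cod$alignment, meta$species)
  wcsv(data.frame(focal = focal, partner = mp$partner, fst = mp$fst),
       "min_fst_partner.csv")

  say("stage 6/7: neighbor-joining allele tree with bootstrap")
  tree_aln <- sim$regions[[1L]]$ingroup
  keep <- !duplicated(apply(tree_aln, 1L, paste0, collapse = ""))
  tree_aln <- tree_aln[keep, , drop = FALSE]
  tr <- bootstrap_support(tree_aln, reps = config$bootstrap_reps,
                          seed = config$seed + 2000L)
  p <- file.path(out_dir, "allele_tree.nwk")
  ape::write.tree(tr, p)
  paths[["allele_tree.nwk"]] <- p

  say("stage 7/7: spectral templates and A1/A2 unmixing")
  t_a1 <- build_standard_template(lapply(1:4, function(k) {
    simulate_spectrum(sim_spectrum_params(
      lambda_max_a1 = config$lambda_max_a1, lambda_max_a2 = config$lambda_max_a2,
      a2_fraction = 0, noise_sd = config$spectrum_noise_sd,
      seed = config$seed + 3000L + k))
  }), smooth_window_nm = config$smooth_window_nm)
  t_a2 <- build_standard_template(lapply(1:4, function(k) {
    simulate_spectrum(sim_spectrum_params(
      lambda_max_a1 = config$lambda_max_a1, lambda_max_a2 = config$lambda_max_a2,
      a2_fraction = 1, noise_sd = config$spectrum_noise_sd,
      seed = config$seed + 3100L + k))
  }), smooth_window_nm = config$smooth_window_nm)
  grid <- 420:740
  c_a1 <- shift_template(t_a1, config$lambda_max_a1, grid)
  c_a2 <- shift_template(t_a2, config$lambda_max_a2, grid)
  rows <- list()
  for (k in seq_along(config$a2_fractions)) {
    phi <- config$a2_fractions[k]
    obs <- simulate_spectrum(sim_spectrum_params(
      lambda_max_a1 = config$lambda_max_a1, lambda_max_a2 = config$lambda_max_a2,
      a2_fraction = phi, noise_sd = config$spectrum_noise_sd,
      seed = config$seed + 3200L + k))
    write_spectrum_csv(obs, file.path(out_dir, sprintf("msp_observed_%02d.csv", k)))
    paths[[sprintf("msp_observed_%02d.csv", k)]] <-
      file.path(out_dir, sprintf("msp_observed_%02d.csv", k))
    fit_c <- fit_a1_a2_mixture(obs, c_a1, c_a2, mode = "curve-match",
                               phi_step = config$phi_step)
    fit_p <- fit_a1_a2_mixture(obs, c_a1, c_a2, mode = "peak-match",
                               phi_step = config$phi_step)
    rows[[k]] <- data.frame(curve = k, true_phi = phi,
                            phi_curve_match = fit_c$a2_fraction,
                            phi_peak_match = fit_p$a2_fraction,
                            mixture_lambda_max = fit_c$lambda_max)
  }
  wcsv(do.call(rbind, rows), "a1_a2_unmixing.csv")

  manifest <- c(list(package_version = as.character(utils::packageVersion("opsinadapt"))),
                config)
  p <- file.path(out_dir, "manifest.yaml")
  yaml::write_yaml(manifest, p)
  paths[["manifest.yaml"]] <- p
  say("pipeline complete: ", length(paths), " outputs in ", out_dir)
  invisible(paths)
}
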