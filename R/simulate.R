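#' Parameters for the two-region polymorphism/divergence simulator
#'
#' Describes a neutral (or region-wise perturbed) model of two linked genomic
#' regions sampled in an ingroup of `n_ingroup` haplotypes together with a
#' single outgroup sequence. `theta_per_region` is the scaled mutation rate
#' per region (Watterson's theta; the expected number of segregating sites is
#' `theta * a_n` with `a_n = sum(1/(1:(n-1)))`). `divergence_time` is the
#' ingroup/outgroup split time in coalescent units of 2N generations, so the
#' expected ingroup-outgroup divergence per region is `theta * (T + 1)`.
#' `divergence_inflation` multiplies `T` region by region and is the
#' alternative hypothesis knob: values above 1 emulate accelerated divergence
#' of one region, as expected under directional selection.
#'
#' @param theta_per_region Numeric vector (recycled to the number of regions)
#'   of per-region Watterson theta values, each >= 0.
#' @param divergence_time Scaled split time T >= 0 (units of 2N generations).
#' @param n_ingroup Number of ingroup haplotypes, >= 2.
#' @param region_lengths Integer vector of region lengths in bp, all > 0.
#' @param divergence_inflation Per-region multiplier on T, all > 0.
#' @param seed Integer seed; identical parameters and seed give identical
#'   output.
#' @return An object of class `sim_sequence_params`.
#' @export
sim_sequence_params <- function(theta_per_region = 5,
                                divergence_time = 2,
                                n_ingroup = 20,
                                region_lengths = c(1932L, 1286L),
                                divergence_inflation = 1,
                                seed = 1L) {
  n_regions <- length(region_lengths)
  theta <- rep_len(theta_per_region, n_regions)
  infl <- rep_len(divergence_inflation, n_regions)
  if (any(region_lengths <= 0)) stop("region_lengths must all be positive")
  if (any(theta < 0)) stop("theta_per_region must be non-negative")
  if (divergence_time < 0) stop("divergence_time must be non-negative")
  if (any(infl <= 0)) stop("divergence_inflation must all be positive")
  if (n_ingroup < 2) stop("n_ingroup must be at least 2")
  structure(
    list(theta = theta, divergence_time = divergence_time,
         n_ingroup = as.integer(n_ingroup),
         region_lengths = as.integer(region_lengths),
         divergence_inflation = infl, seed = as.integer(seed)),
    class = "sim_sequence_params")
}

# One standard n-sample coalescent: returns branches (list of tip index sets),
# branch lengths (same order) and the time to the most recent common ancestor,
# all in units of 2N generations.
.sim_coalescent <- function(n) {
  lineages <- as.list(seq_len(n))
  lens <- numeric(n)
  branches <- list()
  branch_lens <- numeric(0)
  t_total <- 0
  k <- n
  while (k > 1L) {
    t_k <- stats::rexp(1L, rate = k * (k - 1) / 2)
    t_total <- t_total + t_k
    lens <- lens + t_k
    pair <- sample.int(k, 2L)
    i <- min(pair); j <- max(pair)
    branches <- c(branches, lineages[c(i, j)])
    branch_lens <- c(branch_lens, lens[c(i, j)])
    lineages[[i]] <- c(lineages[[i]], lineages[[j]])
    lens[i] <- 0
    lineages[[j]] <- NULL
    lens <- lens[-j]
    k <- k - 1L
  }
  list(branches = branches, branch_lens = branch_lens, t_mrca = t_total)
}

#' Simulate ingroup polymorphism and outgroup divergence at linked regions
#'
#' For each region, an independent standard coalescent genealogy of the
#' ingroup sample is drawn (exponential waiting times), mutations are placed
#' on branches as a Poisson process with rate theta/2 per unit branch length,
#' and the outgroup is separated from the ingroup by the divergence stem: the
#' residual path `2 * (T * inflation + t_anc) - t_mrca` (with ancestral
#' coalescence time `t_anc ~ Exp(1)`, floored at zero), so that the mean
#' number of differences between an ingroup sequence and the outgroup is
#' `theta * (T * inflation + 1)`. Mutations occupy distinct sites
#' (infinite-sites behaviour on a finite grid); if more mutations are drawn
#' than the region has sites, the simulation fails rather than allowing
#' recurrent hits.
#'
#' @param params A [sim_sequence_params()] object.
#' @return A list of class `two_region_sim` with one element per region, each
#'   containing `ingroup` (alignment matrix) and `outgroup` (character vector
#'   of the outgroup sequence), plus a `truth` data frame of realised mutation
#'   counts.
#' @examples
#' sim <- simulate_two_region_data(sim_sequence_params(theta_per_region = 3, seed = 7))
#' region_counts(sim$regions[[1]]$ingroup, sim$regions[[1]]$outgroup, "up")
#' @export
simulate_two_region_data <- function(params) {
  stopifnot(inherits(params, "sim_sequence_params"))
  set.seed(params$seed)
  bases <- c("A", "C", "G", "T")
  regions <- vector("list", length(params$region_lengths))
  truth <- data.frame(region = seq_along(regions), S_mut = NA_integer_,
                      D_mut = NA_integer_, t_mrca = NA_real_)
  for (r in seq_along(regions)) {
    L <- params$region_lengths[r]
    theta <- params$theta[r]
    gen <- .sim_coalescent(params$n_ingroup)
    n_mut <- stats::rpois(length(gen$branch_lens), theta / 2 * gen$branch_lens)
    t_anc <- stats::rexp(1L, rate = 1)
    stem <- max(0, 2 * (params$divergence_time * params$divergence_inflation[r] + t_anc) -
                  gen$t_mrca)
    n_div <- stats::rpois(1L, theta / 2 * stem)
    total <- sum(n_mut) + n_div
    if (total > L) {
      stop("region ", r, ": ", total, " mutations requested but only ", L,
           " sites available; increase region length or reduce theta/T")
    }
    anc <- sample(bases, L, replace = TRUE)
    aln <- matrix(rep(anc, each = params$n_ingroup), nrow = params$n_ingroup)
    rownames(aln) <- paste0("hap", seq_len(params$n_ingroup))
    sites <- if (total > 0) sample.int(L, total) else integer(0)
    s_idx <- 0L
    for (b in seq_along(gen$branches)) {
      if (n_mut[b] == 0L) next
      for (m in seq_len(n_mut[b])) {
        s_idx <- s_idx + 1L
        site <- sites[s_idx]
        new_base <- sample(setdiff(bases, anc[site]), 1L)
        aln[gen$branches[[b]], site] <- new_base
      }
    }
    outgroup <- anc
    if (n_div > 0L) {
      div_sites <- sites[(s_idx + 1L):(s_idx + n_div)]
      for (site in div_sites) {
        outgroup[site] <- sample(setdiff(bases, anc[site]), 1L)
      }
    }
    regions[[r]] <- list(ingroup = aln, outgroup = outgroup)
    truth$S_mut[r] <- sum(n_mut)
    truth$D_mut[r] <- n_div
    truth$t_mrca[r] <- gen$t_mrca
  }
  structure(list(regions = regions, params = params, truth = truth),
            class = "two_region_sim")
}

#' Simulate a codon alignment structured into amino-acid allele groups
#'
#' Builds `n_groups` allele groups of `n_haplotypes_per_group` haplotypes
#' each. Every group differs from the reference protein at exactly
#' `aa_diffs_between_groups` residues, at codon positions unique to that
#' group (so all groups have distinct proteins). Within a group, every
#' haplotype beyond the first carries `syn_diffs_within_group` synonymous
#' third-position changes at fourfold-degenerate codons, so within-group
#' nucleotide diversity is positive while the translated protein is
#' constant. No stop codons are ever produced.
#'
#' @param n_groups Number of amino-acid allele groups.
#' @param n_haplotypes_per_group Haplotypes per group.
#' @param codon_count Total codons per haplotype.
#' @param aa_diffs_between_groups Amino-acid differences of each non-reference
#'   group from the reference protein.
#' @param syn_diffs_within_group Synonymous differences carried by each
#'   non-founder haplotype within its group.
#' @param seed Integer seed.
#' @return A list of class `coding_sim` with `alignment` (character matrix)
#'   and `truth` (data frame of id and true group label).
#' @export
simulate_coding_alleles <- function(n_groups, n_haplotypes_per_group,
                                    codon_count, aa_diffs_between_groups = 1L,
                                    syn_diffs_within_group = 0L, seed = 1L) {
  set.seed(seed)
  if (n_groups > 1L && aa_diffs_between_groups < 1L) {
    stop("aa_diffs_between_groups must be >= 1 when simulating several groups")
  }
  n_aa_pos <- (n_groups - 1L) * aa_diffs_between_groups
  if (n_aa_pos + max(1L, syn_diffs_within_group) > codon_count) {
    stop("codon_count too small to host ", n_aa_pos,
         " group-defining codons plus ", syn_diffs_within_group,
         " synonymous sites")
  }
  # Filler codons are GCT (Ala, fourfold-degenerate third position); group-
  # defining codons use the GAT family, where every first-position change
  # (GAT/CAT/AAT/TAT = Asp/His/Asn/Tyr) is nonsynonymous and stop-free.
  base <- matrix(rep(c("G", "C", "T"), codon_count), nrow = 3L)
  aa_pos <- if (n_aa_pos > 0) sample.int(codon_count, n_aa_pos) else integer(0)
  for (p in aa_pos) base[, p] <- c("G", "A", "T")
  syn_pool <- setdiff(seq_len(codon_count), aa_pos)
  if (syn_diffs_within_group > length(syn_pool)) {
    stop("not enough fourfold-degenerate codons for the requested ",
         "within-group synonymous differences")
  }
  aa_variant <- c("C", "A", "T")  # replacement first bases for group codons
  aln <- list()
  truth <- data.frame(id = character(0), group = character(0))
  pos_cursor <- 0L
  for (g in seq_len(n_groups)) {
    gseq <- base
    if (g > 1L) {
      own <- aa_pos[(pos_cursor + 1L):(pos_cursor + aa_diffs_between_groups)]
      pos_cursor <- pos_cursor + aa_diffs_between_groups
      for (p in own) gseq[1L, p] <- sample(aa_variant, 1L)
    }
    for (h in seq_len(n_haplotypes_per_group)) {
      hseq <- gseq
      if (h > 1L && syn_diffs_within_group > 0L) {
        syn_at <- sample(syn_pool, syn_diffs_within_group)
        for (p in syn_at) hseq[3L, p] <- sample(c("A", "C", "G"), 1L)
      }
      id <- sprintf("g%d_h%d", g, h)
      aln[[id]] <- as.vector(hseq)
      truth <- rbind(truth, data.frame(id = id, group = sprintf("G%d", g)))
    }
  }
  mat <- do.call(rbind, aln)
  structure(list(alignment = mat, truth = truth,
                 cds_coords = c(1L, 3L * codon_count)),
            class = "coding_sim")
}
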