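#' Polymorphism and divergence counts for one genomic region
#'
#' Counts the inputs of the HKA test: `S`, the number of segregating sites
#' within the ingroup sample, and `D`, the mean number of nucleotide
#' differences between each ingroup sequence and the outgroup sequence.
#' Columns containing a gap, `N`, or ambiguity code in any sequence
#' (including the outgroup) are excluded listwise.
#'
#' @param ingroup Alignment matrix of ingroup haplotypes (>= 2 rows).
#' @param outgroup Single outgroup sequence (string or base vector) aligned
#'   to the ingroup.
#' @param name Region label, e.g. `"up(SWS2A)"`, `"gene"`, `"down"`.
#' @return Object of class `region_counts`: list with `name`, `S`, `D`, `n`,
#'   `L_sites` (columns retained).
#' @export
region_counts <- function(ingroup, outgroup, name = "region") {
  aln <- as_alignment(ingroup)
  if (nrow(aln) < 2L) stop("ingroup must contain at least 2 sequences")
  og <- if (length(outgroup) == 1L) strsplit(toupper(outgroup), "")[[1L]] else toupper(outgroup)
  if (length(og) != ncol(aln)) stop("outgroup not aligned to ingroup")
  plain <- c("A", "C", "G", "T")
  keep <- apply(aln, 2L, function(col) all(col %in% plain)) & og %in% plain
  aln <- aln[, keep, drop = FALSE]
  og <- og[keep]
  S <- sum(apply(aln, 2L, function(col) length(unique(col)) > 1L))
  D <- mean(apply(aln, 1L, function(row) sum(row != og)))
  structure(list(name = name, S = as.integer(S), D = D, n = nrow(aln),
                 L_sites = as.integer(sum(keep))),
            class = "region_counts")
}

#' Construct region counts directly
#'
#' For use when the per-region summaries (e.g. from published tables or
#' external software) are available without the underlying alignments.
#'
#' @param name Region label.
#' @param S Segregating sites within the ingroup (>= 0).
#' @param D Mean ingroup-outgroup differences (>= 0).
#' @param n Ingroup sample size (>= 2).
#' @param L_sites Region length in bp (used only for simulation-based
#'   p-values).
#' @return Object of class `region_counts`.
#' @export
make_region_counts <- function(name, S, D, n, L_sites = 10000L) {
  if (S < 0 || D < 0) stop("S and D must be non-negative")
  if (n < 2) stop("n must be at least 2")
  structure(list(name = name, S = S, D = D, n = as.integer(n),
                 L_sites = as.integer(L_sites)),
            class = "region_counts")
}

# Solve the HKA moment system for two regions. Moment equations under
# neutrality with a single outgroup lineage and equal population sizes:
#   E[S_i] = theta_i * a_n,  E[D_i] = theta_i * (T + 1).
# The estimator matches the total polymorphism, total divergence, and the
# per-region (S + D) totals; the system is exactly identified for two
# regions and is solved in closed form, then polished by bounded
# least-squares on the (symmetric) moment residuals so that boundary cases
# (e.g. S = 0 in one region) go through the same machinery.
.hka_solve <- function(S1, D1, S2, D2, a_n) {
  resid <- function(par) {
    th1 <- par[1L]; th2 <- par[2L]; Tp1 <- par[3L]
    c((S1 + S2) - (th1 + th2) * a_n,
      (D1 + D2) - (th1 + th2) * Tp1,
      (S1 + D1) - th1 * (a_n + Tp1),
      (S2 + D2) - th2 * (a_n + Tp1))
  }
  obj <- function(par) sum(resid(par)^2)
  sumS <- S1 + S2; sumD <- D1 + D2
  starts <- list()
  if (sumS > 0) {
    th <- sumS / a_n
    Tp1 <- max(1, sumD / th)
    th1 <- (S1 + D1) / (a_n + Tp1)
    starts[[1L]] <- c(max(th1, 1e-9), max(th - th1, 1e-9), Tp1)
  }
  starts[[length(starts) + 1L]] <- c(max(S1 / a_n, 0.5), max(S2 / a_n, 0.5),
                                     max(1, sumD / max(sumS / a_n, 0.5)))
  best <- NULL
  for (st in starts) {
    fit <- stats::optim(st, obj, method = "L-BFGS-B",
                        lower = c(1e-9, 1e-9, 1),
                        upper = c(Inf, Inf, Inf),
                        control = list(maxit = 500L, factr = 1e4))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (!is.finite(best$value)) stop("HKA moment solve failed to converge")
  list(theta = best$par[1:2], T = best$par[3L] - 1, residual = best$value)
}

# Goodness-of-fit statistic at given parameter values.
.hka_x2 <- function(S, D, theta, T, a_n, b_n) {
  ES <- theta * a_n
  ED <- theta * (T + 1)
  VarS <- theta * a_n + theta^2 * b_n
  VarD <- ED + theta^2
  x2 <- 0
  for (i in seq_along(S)) {
    if (VarS[i] > 0) x2 <- x2 + (S[i] - ES[i])^2 / VarS[i]
    if (VarD[i] > 0) x2 <- x2 + (D[i] - ED[i])^2 / VarD[i]
  }
  list(X2 = x2, ES = ES, ED = ED, VarS = VarS, VarD = VarD)
}

#' Hudson-Kreitman-Aguade test between two genomic regions
#'
#' Tests heterogeneity in the ratio of within-species polymorphism to
#' between-lineage divergence between two regions. Under neutrality both
#' regions share the divergence time `T`, while each has its own scaled
#' mutation rate `theta_i`; parameters are estimated by the method of
#' moments (see Details) and the goodness-of-fit statistic
#' `X2 = sum_i (S_i - E S_i)^2 / Var S_i + (D_i - E D_i)^2 / Var D_i`
#' is referred to a chi-squared distribution with 1 degree of freedom.
#' With `Var S = theta a_n + theta^2 b_n` and
#' `Var D = theta (T + 1) + theta^2` (single outgroup lineage, equal
#' population sizes).
#'
#' An optional simulation p-value re-simulates null two-region data at the
#' fitted `(theta_1, theta_2, T)` with [simulate_two_region_data()] and
#' reports the fraction of replicate `X2` values at least as large as the
#' observed one.
#'
#' @param region1,region2 `region_counts` objects sharing the ingroup
#'   sample size `n`.
#' @param sim_reps Number of null simulation replicates for `p_sim`
#'   (0 = chi-squared p-value only).
#' @param seed Seed for the simulation p-value.
#' @return Object of class `hka_test`: `theta_hat`, `T_hat`, `X2`, `df`,
#'   `p_chi2`, `p_sim` (NA unless requested), and per-region `expected`
#'   table.
#' @examples
#' hka_test(make_region_counts("up", 10, 20, 20),
#'          make_region_counts("gene", 5, 10, 20))
#' @export
hka_test <- function(region1, region2, sim_reps = 0L, seed = 1L) {
  stopifnot(inherits(region1, "region_counts"), inherits(region2, "region_counts"))
  if (region1$n != region2$n) {
    stop("regions have different ingroup sample sizes (", region1$n, " vs ",
         region2$n, ")")
  }
  n <- region1$n
  a_n <- harmonic_a(n)
  b_n <- harmonic_b(n)
  S <- c(region1$S, region2$S)
  D <- c(region1$D, region2$D)
  if (sum(S) + sum(D) == 0) {
    warning("all counts are zero; test is degenerate")
    fitstat <- list(X2 = 0, ES = c(0, 0), ED = c(0, 0),
                    VarS = c(0, 0), VarD = c(0, 0))
    sol <- list(theta = c(0, 0), T = 0, residual = 0)
  } else {
    sol <- .hka_solve(S[1L], D[1L], S[2L], D[2L], a_n)
    fitstat <- .hka_x2(S, D, sol$theta, sol$T, a_n, b_n)
  }
  p_chi2 <- stats::pchisq(fitstat$X2, df = 1L, lower.tail = FALSE)
  p_sim <- NA_real_
  if (sim_reps > 0L) {
    x2_null <- .hka_null_x2(sol$theta, sol$T, n,
                            c(region1$L_sites, region2$L_sites),
                            sim_reps, seed)
    p_sim <- mean(x2_null >= fitstat$X2 - 1e-12)
  }
  expected <- data.frame(
    region = c(region1$name, region2$name), S = S, D = D,
    E_S = fitstat$ES, E_D = fitstat$ED,
    Var_S = fitstat$VarS, Var_D = fitstat$VarD)
  structure(list(theta_hat = sol$theta, T_hat = sol$T, X2 = fitstat$X2,
                 df = 1L, p_chi2 = p_chi2, p_sim = p_sim,
                 expected = expected, n = n, residual = sol$residual),
            class = "hka_test")
}

# Null distribution of X2 by re-simulation at fitted parameters.
.hka_null_x2 <- function(theta, T, n, L_sites, reps, seed) {
  x2 <- numeric(reps)
  for (r in seq_len(reps)) {
    prm <- sim_sequence_params(theta_per_region = pmax(theta, 1e-6),
                               divergence_time = max(T, 0), n_ingroup = n,
                               region_lengths = L_sites,
                               seed = seed + r)
    sim <- simulate_two_region_data(prm)
    rc1 <- region_counts(sim$regions[[1L]]$ingroup, sim$regions[[1L]]$outgroup, "r1")
    rc2 <- region_counts(sim$regions[[2L]]$ingroup, sim$regions[[2L]]$outgroup, "r2")
    S <- c(rc1$S, rc2$S); D <- c(rc1$D, rc2$D)
    if (sum(S) + sum(D) == 0) {
      x2[r] <- 0
    } else {
      sol <- .hka_solve(S[1L], D[1L], S[2L], D[2L], harmonic_a(n))
      x2[r] <- .hka_x2(S, D, sol$theta, sol$T, harmonic_a(n), harmonic_b(n))$X2
    }
  }
  x2
}

#' @export
print.hka_test <- function(x, ...) {
  cat("HKA test of polymorphism/divergence heterogeneity\n")
  print(x$expected, row.names = FALSE, digits = 4)
  cat(sprintf("theta_hat = (%.4f, %.4f), T_hat = %.4f\n",
              x$theta_hat[1L], x$theta_hat[2L], x$T_hat))
  cat(sprintf("X2 = %.4f, df = %d, p(chi2) = %.4g", x$X2, x$df, x$p_chi2))
  if (!is.na(x$p_sim)) cat(sprintf(", p(sim) = %.4g", x$p_sim))
  cat("\n")
  invisible(x)
}

#' Pairwise HKA tests across a panel of regions
#'
#' Runs [hka_test()] for every unordered pair of regions (e.g. upstream
#' gene, gene body, downstream) and flags significance at the 0.05 and 0.01
#' levels.
#'
#' @param regions List of `region_counts` objects (>= 2) from the same
#'   ingroup sample.
#' @param sim_reps,seed Passed to [hka_test()].
#' @return Data frame of class `hka_panel` with one row per region pair:
#'   `pair`, `X2`, `p_chi2`, `p_sim`, `sig` (`""`, `"*"` for p < 0.05,
#'   `"**"` for p < 0.01).
#' @export
hka_panel <- function(regions, sim_reps = 0L, seed = 1L) {
  if (length(regions) < 2L) stop("need at least two regions")
  out <- list()
  for (i in seq_len(length(regions) - 1L)) {
    for (j in (i + 1L):length(regions)) {
      fit <- hka_test(regions[[i]], regions[[j]], sim_reps = sim_reps, seed = seed)
      p <- fit$p_chi2
      out[[length(out) + 1L]] <- data.frame(
        pair = paste0(regions[[i]]$name, "-", regions[[j]]$name),
        X2 = fit$X2, p_chi2 = p, p_sim = fit$p_sim,
        sig = if (p < 0.01) "**" else if (p < 0.05) "*" else "",
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("hka_panel", class(res))
  res
}
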