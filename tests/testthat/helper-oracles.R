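# Independent oracles used to cross-check the package implementations.
# These deliberately use different machinery (seqinr translation, recursive
# enumeration, generic Nelder-Mead minimisation) from the code under test.

# translate a codon string with seqinr
.oracle_aa <- function(codon) {
  seqinr::translate(strsplit(codon, "")[[1L]])
}

# Recursive enumeration of all minimal substitution pathways between two
# codons; returns the average (syn, nonsyn) step counts over pathways.
oracle_codon_path_counts <- function(c1, c2) {
  pos <- which(strsplit(c1, "")[[1L]] != strsplit(c2, "")[[1L]])
  if (!length(pos)) return(c(syn = 0, nonsyn = 0))
  walk <- function(cur, remaining) {
    if (!length(remaining)) return(list(c(syn = 0, nonsyn = 0)))
    out <- list()
    for (p in remaining) {
      nxt <- strsplit(cur, "")[[1L]]
      nxt[p] <- strsplit(c2, "")[[1L]][p]
      nxt <- paste0(nxt, collapse = "")
      step <- if (.oracle_aa(nxt) == .oracle_aa(cur)) c(1, 0) else c(0, 1)
      for (tail in walk(nxt, setdiff(remaining, p))) {
        out[[length(out) + 1L]] <- c(syn = step[1L] + tail[["syn"]],
                                     nonsyn = step[2L] + tail[["nonsyn"]])
      }
    }
    out
  }
  paths <- walk(c1, pos)
  Reduce(`+`, paths) / length(paths)
}

# Synonymous site count of one codon by explicit neighbour enumeration.
oracle_codon_sites <- function(codon) {
  ch <- strsplit(codon, "")[[1L]]
  syn <- 0
  for (p in 1:3) {
    for (b in setdiff(c("A", "C", "G", "T"), ch[p])) {
      alt <- ch; alt[p] <- b
      if (seqinr::translate(alt) == seqinr::translate(ch)) syn <- syn + 1 / 3
    }
  }
  c(syn = syn, nonsyn = 3 - syn)
}

# Full pairwise Nei-Gojobori oracle on unambiguous, stop-free codon pairs.
oracle_pairwise_ng <- function(s1, s2) {
  n_cod <- nchar(s1) %/% 3L
  S <- N <- Sd <- Nd <- 0
  for (k in seq_len(n_cod)) {
    c1 <- substr(s1, 3 * k - 2, 3 * k)
    c2 <- substr(s2, 3 * k - 2, 3 * k)
    if (.oracle_aa(c1) == "*" || .oracle_aa(c2) == "*") next
    sc1 <- oracle_codon_sites(c1); sc2 <- oracle_codon_sites(c2)
    S <- S + (sc1[["syn"]] + sc2[["syn"]]) / 2
    N <- N + (sc1[["nonsyn"]] + sc2[["nonsyn"]]) / 2
    dd <- oracle_codon_path_counts(c1, c2)
    Sd <- Sd + dd[["syn"]]; Nd <- Nd + dd[["nonsyn"]]
  }
  jc <- function(p) if (p >= 3 / 4) NA_real_ else -3 / 4 * log(1 - 4 * p / 3)
  list(ds = jc(if (S > 0) Sd / S else 0), dn = jc(if (N > 0) Nd / N else 0),
       S = S, N = N, Sd = Sd, Nd = Nd)
}

# Brute-force HKA: minimise the squared residuals of the moment equations
# over (theta1, theta2, T) with generic Nelder-Mead from several starts,
# then evaluate the goodness-of-fit statistic at the optimum.
oracle_hka_x2 <- function(S1, D1, S2, D2, n) {
  a <- sum(1 / (1:(n - 1))); b <- sum(1 / (1:(n - 1))^2)
  obj <- function(p) {
    th1 <- exp(p[1L]); th2 <- exp(p[2L]); Tp1 <- 1 + exp(p[3L])
    ((S1 + S2) - (th1 + th2) * a)^2 +
      ((D1 + D2) - (th1 + th2) * Tp1)^2 +
      ((S1 + D1) - th1 * (a + Tp1))^2
  }
  best <- NULL
  for (s in list(c(0, 0, 0), c(1, 1, 1), c(2, 0, 2), c(0, 2, 2), c(1, 1, 3),
                 c(-1, 1, 0.5))) {
    f <- stats::optim(s, obj, method = "Nelder-Mead",
                      control = list(maxit = 10000, reltol = 1e-15))
    f <- stats::optim(f$par, obj, method = "Nelder-Mead",
                      control = list(maxit = 10000, reltol = 1e-15))
    if (is.null(best) || f$value < best$value) best <- f
  }
  th <- exp(best$par[1:2]); T <- exp(best$par[3L])
  ES <- th * a; ED <- th * (T + 1)
  VS <- th * a + th^2 * b; VD <- ED + th^2
  sum((c(S1, S2) - ES)^2 / VS + (c(D1, D2) - ED)^2 / VD)
}

# Random additive distance matrix from a random binary tree, with the
# generating (unrooted) topology for comparison.
random_additive_matrix <- function(ntaxa, seed) {
  set.seed(seed)
  tr <- ape::rtree(ntaxa, br = function(n) stats::runif(n, 0.05, 0.5))
  list(d = stats::cophenetic(tr), tree = ape::unroot(tr))
}
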