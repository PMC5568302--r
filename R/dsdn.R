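#' Synonymous and nonsynonymous site counts of a codon
#'
#' Nei-Gojobori site counting: at each codon position the fraction of the
#' three possible single-nucleotide changes that are synonymous contributes
#' to the synonymous site count; the complement contributes to the
#' nonsynonymous count, so the two always sum to exactly 3 per codon
#' (changes creating stop codons count as nonsynonymous).
#'
#' @param codon Three-base string or character vector, unambiguous, not a
#'   stop codon.
#' @return Named numeric vector `c(syn = ..., nonsyn = ...)`.
#' @examples
#' count_sites("TTT")  # Phe: 1/3 synonymous site
#' @export
count_sites <- function(codon) {
  codon <- .as_codon(codon)
  code <- Biostrings::GENETIC_CODE
  aa <- code[paste0(codon, collapse = "")]
  if (is.na(aa)) stop("ambiguous codon: ", paste0(codon, collapse = ""))
  if (aa == "*") stop("stop codon has no site counts")
  bases <- c("A", "C", "G", "T")
  syn <- 0
  for (pos in 1:3) {
    for (b in setdiff(bases, codon[pos])) {
      alt <- codon
      alt[pos] <- b
      if (code[paste0(alt, collapse = "")] == aa) syn <- syn + 1 / 3
    }
  }
  c(syn = syn, nonsyn = 3 - syn)
}

.as_codon <- function(codon) {
  if (length(codon) == 1L) codon <- strsplit(toupper(codon), "")[[1L]]
  if (length(codon) != 3L) stop("a codon has exactly 3 bases")
  toupper(codon)
}

# lazy lookup tables: site counts per codon, pathway-averaged difference
# counts per codon pair (64 x 64 entries at most)
.ng_cache <- new.env(parent = emptyenv())

.sites_cached <- function(codon_str) {
  key <- paste0("s_", codon_str)
  v <- .ng_cache[[key]]
  if (is.null(v)) {
    v <- count_sites(codon_str)
    assign(key, v, envir = .ng_cache)
  }
  v
}

.diffs_cached <- function(c1, c2) {
  key <- paste0("d_", paste0(c1, collapse = ""), paste0(c2, collapse = ""))
  v <- .ng_cache[[key]]
  if (is.null(v)) {
    v <- .codon_diffs(c1, c2)
    assign(key, v, envir = .ng_cache)
  }
  v
}

# Average synonymous/nonsynonymous difference counts between two codons over
# all minimal substitution pathways, each ordering weighted equally.
.codon_diffs <- function(c1, c2) {
  code <- Biostrings::GENETIC_CODE
  pos <- which(c1 != c2)
  d <- length(pos)
  if (d == 0L) return(c(syn = 0, nonsyn = 0))
  orders <- .permutations(pos)
  tot <- c(syn = 0, nonsyn = 0)
  for (ord in orders) {
    cur <- c1
    for (p in ord) {
      nxt <- cur
      nxt[p] <- c2[p]
      if (code[paste0(nxt, collapse = "")] == code[paste0(cur, collapse = "")]) {
        tot["syn"] <- tot["syn"] + 1
      } else {
        tot["nonsyn"] <- tot["nonsyn"] + 1
      }
      cur <- nxt
    }
  }
  tot / length(orders)
}

# All orderings of a vector (n <= 3 in practice), without recursion.
.permutations <- function(x) {
  n <- length(x)
  if (n == 1L) return(list(x))
  if (n == 2L) return(list(x, x[2:1]))
  idx <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
              c(3, 1, 2), c(3, 2, 1))
  lapply(idx, function(i) x[i])
}

#' Pairwise Nei-Gojobori synonymous/nonsynonymous distances
#'
#' Counts synonymous and nonsynonymous sites (averaged over the two
#' sequences) and differences (averaged over all equally-weighted minimal
#' substitution pathways for codons differing at more than one position),
#' then applies the Jukes-Cantor correction
#' `d = -(3/4) * log(1 - 4p/3)` to the proportions `ps` and `pn`. Codons
#' containing gaps or ambiguity in either sequence, and stop codons, are
#' skipped pairwise.
#'
#' @param seq1,seq2 Coding sequences (strings or base vectors) of equal
#'   length divisible by 3.
#' @return Object of class `dsdn`: list with `ds`, `dn` (NA and flagged when
#'   `p >= 3/4` makes the correction undefined), `ps`, `pn`, `syn_sites`,
#'   `nonsyn_sites`, `syn_diffs`, `nonsyn_diffs`, `codons_used`.
#' @examples
#' pairwise_ds_dn("GCTGCT", "GCCGCT")
#' @export
pairwise_ds_dn <- function(seq1, seq2) {
  s1 <- if (length(seq1) == 1L) strsplit(toupper(seq1), "")[[1L]] else toupper(seq1)
  s2 <- if (length(seq2) == 1L) strsplit(toupper(seq2), "")[[1L]] else toupper(seq2)
  if (length(s1) != length(s2)) stop("sequences have unequal lengths")
  if (length(s1) %% 3L != 0L) stop("length not divisible by 3")
  code <- Biostrings::GENETIC_CODE
  n_codons <- length(s1) %/% 3L
  S <- N <- Sd <- Nd <- 0
  used <- 0L
  for (k in seq_len(n_codons)) {
    i <- (k - 1L) * 3L + 1:3
    c1 <- s1[i]; c2 <- s2[i]
    if (any(!c(c1, c2) %in% c("A", "C", "G", "T"))) next
    a1 <- code[paste0(c1, collapse = "")]
    a2 <- code[paste0(c2, collapse = "")]
    if (a1 == "*" || a2 == "*") next
    sc1 <- .sites_cached(paste0(c1, collapse = ""))
    sc2 <- .sites_cached(paste0(c2, collapse = ""))
    S <- S + (sc1["syn"] + sc2["syn"]) / 2
    N <- N + (sc1["nonsyn"] + sc2["nonsyn"]) / 2
    dd <- .diffs_cached(c1, c2)
    Sd <- Sd + dd["syn"]
    Nd <- Nd + dd["nonsyn"]
    used <- used + 1L
  }
  if (used == 0L) stop("no usable codons shared by the two sequences")
  ps <- if (S > 0) Sd / S else 0
  pn <- if (N > 0) Nd / N else 0
  jc <- function(p) if (p >= 3 / 4) NA_real_ else -3 / 4 * log(1 - 4 * p / 3)
  structure(list(ds = unname(jc(ps)), dn = unname(jc(pn)),
                 ps = unname(ps), pn = unname(pn),
                 syn_sites = unname(S), nonsyn_sites = unname(N),
                 syn_diffs = unname(Sd), nonsyn_diffs = unname(Nd),
                 codons_used = used,
                 undefined = is.na(jc(ps)) || is.na(jc(pn))),
            class = "dsdn")
}

#' @export
print.dsdn <- function(x, ...) {
  cat(sprintf("Nei-Gojobori distances over %d codons\n", x$codons_used))
  cat(sprintf("  ds = %.5f  (Sd = %.3f over %.2f syn sites)\n",
              x$ds, x$syn_diffs, x$syn_sites))
  cat(sprintf("  dn = %.5f  (Nd = %.3f over %.2f nonsyn sites)\n",
              x$dn, x$nonsyn_diffs, x$nonsyn_sites))
  if (isTRUE(x$undefined)) cat("  note: Jukes-Cantor correction undefined (p >= 3/4)\n")
  invisible(x)
}

#' Mean pairwise Ds and Dn over an alignment
#'
#' Arithmetic mean of synonymous (and nonsynonymous) distances over all
#' unordered sequence pairs; pairs whose Jukes-Cantor correction is
#' undefined are excluded and counted.
#'
#' @param alignment Coding alignment (matrix or named character vector),
#'   length divisible by 3.
#' @param cds_coords Optional coding-region intervals applied to every
#'   sequence before the distance computation.
#' @return List of class `dsdn_mean` with `ds`, `dn`, `pairs_used`,
#'   `pairs_undefined`.
#' @export
mean_ds_dn <- function(alignment, cds_coords = NULL) {
  aln <- as_alignment(alignment)
  if (nrow(aln) < 2L) stop("need at least 2 sequences")
  cols <- cds_columns(cds_coords, ncol(aln))
  aln <- aln[, cols, drop = FALSE]
  ids <- rownames(aln)
  ds <- dn <- c()
  undef <- 0L
  for (i in seq_len(nrow(aln) - 1L)) {
    for (j in (i + 1L):nrow(aln)) {
      r <- pairwise_ds_dn(aln[i, ], aln[j, ])
      if (r$undefined) {
        undef <- undef + 1L
      } else {
        ds <- c(ds, r$ds)
        dn <- c(dn, r$dn)
      }
    }
  }
  if (!length(ds)) stop("all pairwise distances undefined")
  structure(list(ds = mean(ds), dn = mean(dn), pairs_used = length(ds),
                 pairs_undefined = undef),
            class = "dsdn_mean")
}

#' @export
print.dsdn_mean <- function(x, ...) {
  cat(sprintf("Mean Ds = %.5f, mean Dn = %.5f over %d pairs",
              x$ds, x$dn, x$pairs_used))
  if (x$pairs_undefined > 0) cat(sprintf(" (%d undefined)", x$pairs_undefined))
  cat("\n")
  invisible(x)
}
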