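#' Hudson's FST between two populations of haplotypes
#'
#' Estimator `FST = 1 - Hw / Hb`, where `Hw` is the average of the two
#' within-population mean pairwise difference counts and `Hb` the mean
#' pairwise difference count between populations. Columns with gaps or
#' ambiguity are handled by pairwise deletion. Negative estimates are
#' reported as computed, with a flag.
#'
#' @param pop1,pop2 Alignment matrices (>= 2 sequences each) on the same
#'   coordinate system.
#' @param labels Length-2 character vector of population labels.
#' @return Object of class `population_pair`: `fst`, `hw`, `hb`,
#'   `undefined` (TRUE when `Hb = 0`), `negative`, `labels`.
#' @export
pairwise_fst <- function(pop1, pop2, labels = c("pop1", "pop2")) {
  p1 <- as_alignment(pop1)
  p2 <- as_alignment(pop2)
  if (nrow(p1) < 2L || nrow(p2) < 2L) stop("each population needs >= 2 sequences")
  if (ncol(p1) != ncol(p2)) stop("populations are not aligned")
  hw1 <- .mean_within(p1)
  hw2 <- .mean_within(p2)
  hb <- .mean_between(p1, p2)
  hw <- (hw1 + hw2) / 2
  if (hb == 0) {
    warning("populations indistinguishable (Hb = 0); FST undefined")
    fst <- NA_real_
  } else {
    fst <- 1 - hw / hb
  }
  structure(list(fst = fst, hw = hw, hb = hb,
                 undefined = is.na(fst),
                 negative = !is.na(fst) && fst < 0, labels = labels),
            class = "population_pair")
}

.mean_within <- function(aln) {
  n <- nrow(aln)
  tot <- 0
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) tot <- tot + .count_diffs(aln[i, ], aln[j, ])
  }
  tot / (n * (n - 1L) / 2)
}

.mean_between <- function(a, b) {
  tot <- 0
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) tot <- tot + .count_diffs(a[i, ], b[j, ])
  }
  tot / (nrow(a) * nrow(b))
}

#' @export
print.population_pair <- function(x, ...) {
  cat(sprintf("FST(%s, %s) = %s  (Hw = %.3f, Hb = %.3f)\n",
              x$labels[1L], x$labels[2L],
              if (x$undefined) "undefined" else sprintf("%.4f", x$fst),
              x$hw, x$hb))
  invisible(x)
}

#' Full pairwise FST matrix over labelled populations
#'
#' @param alignment Alignment matrix of all haplotypes.
#' @param populations Character vector (or factor) of population labels,
#'   one per alignment row.
#' @return Symmetric numeric matrix of FST values (NA where undefined).
#' @export
fst_matrix <- function(alignment, populations) {
  aln <- as_alignment(alignment)
  populations <- as.character(populations)
  stopifnot(length(populations) == nrow(aln))
  pops <- sort(unique(populations))
  m <- matrix(NA_real_, length(pops), length(pops), dimnames = list(pops, pops))
  diag(m) <- 0
  for (i in seq_len(length(pops) - 1L)) {
    for (j in (i + 1L):length(pops)) {
      r <- suppressWarnings(
        pairwise_fst(aln[populations == pops[i], , drop = FALSE],
                     aln[populations == pops[j], , drop = FALSE],
                     labels = pops[c(i, j)]))
      m[i, j] <- m[j, i] <- r$fst
    }
  }
  m
}

#' Minimum-FST partner of a focal population
#'
#' Identifies, among all candidate populations, the one least
#' differentiated from the focal population (smallest defined FST); ties
#' are broken deterministically by lexicographic label order.
#'
#' @param focal Label of the focal population.
#' @param alignment Alignment matrix of all haplotypes.
#' @param populations Population label per alignment row.
#' @return List with `partner` and `fst`.
#' @export
min_fst_partner <- function(focal, alignment, populations) {
  m <- fst_matrix(alignment, populations)
  if (!focal %in% rownames(m)) stop("unknown focal population: ", focal)
  cand <- setdiff(rownames(m), focal)
  if (!length(cand)) stop("no candidate partner populations")
  vals <- m[focal, cand]
  if (all(is.na(vals))) stop("all pairwise FST values undefined")
  vals <- vals[!is.na(vals)]
  cand <- sort(names(vals)[vals == min(vals)])
  list(partner = cand[1L], fst = unname(min(vals)))
}
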