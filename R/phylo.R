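#' Expand a heterozygous (IUPAC-coded) sequence into two allele sequences
#'
#' Direct sequencing of a diploid yields one read with biallelic IUPAC
#' codes at heterozygous positions. This splits such a sequence into two
#' allele sequences using a declared convention: at every ambiguous site
#' the first-listed base of the IUPAC code goes to allele 1 and the second
#' to allele 2. Phase between sites is NOT inferred; with more than one
#' heterozygous site the assignment is arbitrary and flagged.
#'
#' @param sequence Nucleotide string possibly containing the biallelic
#'   codes R, Y, S, W, K, M.
#' @param id Base identifier; alleles are named `<id>_1` and `<id>_2`.
#' @return Named character vector of the two allele sequences, with
#'   attributes `het_sites` (positions expanded) and `phase_arbitrary`.
#' @export
expand_heterozygotes <- function(sequence, id = "seq") {
  chars <- if (length(sequence) == 1L) strsplit(toupper(sequence), "")[[1L]] else toupper(sequence)
  iupac <- Biostrings::IUPAC_CODE_MAP
  biallelic <- c("R", "Y", "S", "W", "K", "M")
  bad <- which(!chars %in% c("A", "C", "G", "T", "-", biallelic))
  if (length(bad)) {
    stop("non-biallelic ambiguity at site(s): ", paste(bad, collapse = ", "))
  }
  het <- which(chars %in% biallelic)
  a1 <- a2 <- chars
  for (p in het) {
    alleles <- strsplit(iupac[[chars[p]]], "")[[1L]]
    a1[p] <- alleles[1L]
    a2[p] <- alleles[2L]
  }
  out <- stats::setNames(c(paste0(a1, collapse = ""), paste0(a2, collapse = "")),
                         paste0(id, c("_1", "_2")))
  attr(out, "het_sites") <- het
  attr(out, "phase_arbitrary") <- length(het) > 1L
  out
}

#' Concatenate per-region allele sequences
#'
#' Expands heterozygous sites region by region and concatenates each
#' individual's two allele sequences across regions (e.g. upstream flank,
#' intron-only gene body, downstream flank), preserving heterozygous-site
#' information for tree building.
#'
#' @param regions List of named character vectors, one per region, each
#'   holding one sequence per individual (same names across regions).
#' @return Alignment matrix with two rows per individual (`<id>_1`,
#'   `<id>_2`) and total width equal to the summed region lengths.
#' @export
concatenate_alleles <- function(regions) {
  ids <- names(regions[[1L]])
  if (is.null(ids)) stop("sequences must be named by individual")
  for (r in regions) {
    if (!identical(sort(names(r)), sort(ids))) {
      stop("all regions must cover the same individuals")
    }
  }
  out <- lapply(ids, function(id) {
    parts <- lapply(regions, function(r) expand_heterozygotes(r[[id]], id))
    c(paste0(vapply(parts, `[`, character(1L), 1L), collapse = ""),
      paste0(vapply(parts, `[`, character(1L), 2L), collapse = ""))
  })
  seqs <- unlist(out)
  names(seqs) <- unlist(lapply(ids, function(id) paste0(id, c("_1", "_2"))))
  as_alignment(seqs)
}

#' Jukes-Cantor distance matrix
#'
#' Pairwise `d = -(3/4) * log(1 - 4p/3)` with `p` the proportion of
#' differing sites after pairwise deletion of columns with gaps or
#' ambiguity.
#'
#' @param alignment Alignment matrix.
#' @return Symmetric numeric matrix (NA where `p >= 3/4` makes the
#'   distance undefined).
#' @export
jc_distance_matrix <- function(alignment) {
  aln <- as_alignment(alignment)
  n <- nrow(aln)
  m <- matrix(0, n, n, dimnames = list(rownames(aln), rownames(aln)))
  plain <- c("A", "C", "G", "T")
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- aln[i, ] %in% plain & aln[j, ] %in% plain
      L <- sum(ok)
      if (L == 0L) { m[i, j] <- m[j, i] <- NA_real_; next }
      p <- sum(aln[i, ok] != aln[j, ok]) / L
      m[i, j] <- m[j, i] <- if (p >= 3 / 4) NA_real_ else -3 / 4 * log(1 - 4 * p / 3)
    }
  }
  m
}

#' Neighbor-joining tree
#'
#' Saitou-Nei agglomeration from a distance matrix. Ties in the
#' rate-corrected criterion are broken deterministically by joining the
#' pair whose representative (smallest contained) taxon labels sort first;
#' negative branch lengths are clamped to zero with the excess transferred
#' to the sister branch. Results are returned as an `ape::phylo` object.
#'
#' @param distances Symmetric numeric matrix with taxon labels as
#'   dimnames; all entries must be finite.
#' @return An unrooted `phylo` tree.
#' @export
neighbor_joining <- function(distances) {
  d <- as.matrix(distances)
  if (any(!is.finite(d))) stop("distance matrix contains undefined entries")
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(nrow(d)))
  n <- nrow(d)
  if (n < 3L) stop("need at least 3 taxa")
  # active nodes: newick fragment, representative label for tie-breaking
  nwk <- labels
  rep_lab <- labels
  active <- seq_len(n)
  D <- d
  while (length(active) > 3L) {
    N <- length(active)
    r <- rowSums(D)
    Q <- (N - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    keys <- apply(cand, 1L, function(ij) {
      paste(sort(rep_lab[ij]), collapse = "\r")
    })
    pick <- cand[order(keys)[1L], ]
    i <- pick[1L]; j <- pick[2L]
    vi <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (N - 2))
    vj <- D[i, j] - vi
    if (vi < 0) { vj <- vj + vi; vi <- 0 }
    if (vj < 0) { vi <- vi + vj; vj <- 0 }
    new_nwk <- sprintf("(%s:%.10g,%s:%.10g)", nwk[i], vi, nwk[j], vj)
    new_rep <- min(rep_lab[i], rep_lab[j])
    new_d <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(N), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], new_d[keep]),
               c(new_d[keep], 0))
    nwk <- c(nwk[keep], new_nwk)
    rep_lab <- c(rep_lab[keep], new_rep)
    active <- seq_len(N - 1L)
  }
  # resolve the final three nodes around the central vertex
  va <- (D[1L, 2L] + D[1L, 3L] - D[2L, 3L]) / 2
  vb <- (D[1L, 2L] + D[2L, 3L] - D[1L, 3L]) / 2
  vc <- (D[1L, 3L] + D[2L, 3L] - D[1L, 2L]) / 2
  va <- max(va, 0); vb <- max(vb, 0); vc <- max(vc, 0)
  txt <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);", nwk[1L], va, nwk[2L], vb,
                 nwk[3L], vc)
  ape::read.tree(text = txt)
}

# Canonical bipartitions (internal edges only) of an unrooted tree: each
# split is represented by the sorted tip labels on the side NOT containing
# the alphabetically first tip.
.tree_splits <- function(tree) {
  tips <- sort(tree$tip.label)
  anchor <- tips[1L]
  n <- length(tree$tip.label)
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  out <- character(0)
  for (k in seq_along(pp)) {
    below <- labs[pp[[k]]]
    side <- if (anchor %in% below) setdiff(tips, below) else below
    if (length(side) >= 2L && length(side) <= n - 2L) {
      out <- c(out, paste(sort(side), collapse = "\r"))
    }
  }
  unique(out)
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree for
#' each replicate, and reports for each internal bipartition of the
#' point-estimate tree the percentage of replicates containing it.
#'
#' @param alignment Alignment matrix.
#' @param reps Number of bootstrap replicates.
#' @param seed Integer seed (fixed seed gives identical supports).
#' @param dist_fun Function mapping an alignment to a distance matrix.
#' @return The point-estimate `phylo` tree with `node.label` holding
#'   support percentages (root label empty) and attribute `supports`, a
#'   named vector keyed by bipartition.
#' @export
bootstrap_support <- function(alignment, reps = 1000L, seed = 1L,
                              dist_fun = jc_distance_matrix) {
  if (reps < 1L) stop("reps must be at least 1")
  aln <- as_alignment(alignment)
  point <- neighbor_joining(dist_fun(aln))
  target <- .tree_splits(point)
  hits <- stats::setNames(numeric(length(target)), target)
  set.seed(seed)
  for (r in seq_len(reps)) {
    cols <- sample.int(ncol(aln), ncol(aln), replace = TRUE)
    rep_tree <- neighbor_joining(dist_fun(aln[, cols, drop = FALSE]))
    sp <- .tree_splits(rep_tree)
    hits[target %in% sp] <- hits[target %in% sp] + 1
  }
  support <- 100 * hits / reps
  # attach supports as node labels on the point tree
  n <- length(point$tip.label)
  labs <- character(point$Nnode)
  tips <- sort(point$tip.label)
  anchor <- tips[1L]
  for (k in seq_len(point$Nnode)) {
    node <- n + k
    below <- ape::extract.clade(point, node)$tip.label
    side <- if (anchor %in% below) setdiff(tips, below) else below
    key <- paste(sort(side), collapse = "\r")
    labs[k] <- if (key %in% names(support)) sprintf("%g", support[key]) else ""
  }
  point$node.label <- labs
  attr(point, "supports") <- support
  point
}
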