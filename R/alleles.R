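#' Translate a coding nucleotide sequence
#'
#' Translates the concatenated coding region of a haplotype using the
#' standard genetic code. Codons containing `N`, IUPAC ambiguity codes, or
#' gaps are expanded over all compatible bases: if every expansion yields
#' the same residue the codon translates to that residue, otherwise to `X`.
#' An internal stop codon raises a warning but the translation (with `*`)
#' is still returned, so that premature stops can be inspected.
#'
#' @param sequence Nucleotide string or character vector of single bases.
#' @param cds_coords 1-based inclusive (start, end) intervals of the coding
#'   region in the supplied sequence; `NULL` means the whole sequence.
#' @param genetic_code Named character vector mapping codons to residues;
#'   defaults to the standard code.
#' @return Single amino-acid string (one residue per codon).
#' @examples
#' translate_cds("ATGGCT")
#' @export
translate_cds <- function(sequence, cds_coords = NULL,
                          genetic_code = Biostrings::GENETIC_CODE) {
  chars <- if (length(sequence) == 1L && nchar(sequence[1L]) != 1L) {
    strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  } else {
    toupper(as.character(sequence))
  }
  cols <- cds_columns(cds_coords, length(chars))
  cds <- chars[cols]
  if (length(cds) %% 3L != 0L) {
    stop("CDS length ", length(cds), " is not divisible by 3")
  }
  if (length(cds) == 0L) return("")
  codons <- matrix(cds, nrow = 3L)
  aa <- vapply(seq_len(ncol(codons)), function(i) {
    .translate_codon(codons[, i], genetic_code)
  }, character(1L))
  n_codons <- length(aa)
  if (n_codons > 1L && any(aa[-n_codons] == "*")) {
    warning("internal stop codon in translation")
  }
  paste0(aa, collapse = "")
}

# Translate one codon, resolving IUPAC ambiguity by expansion. Gaps and
# unknown symbols are unresolvable and give "X".
.translate_codon <- function(codon, genetic_code = Biostrings::GENETIC_CODE) {
  iupac <- Biostrings::IUPAC_CODE_MAP
  expand <- lapply(codon, function(b) {
    if (b %in% c("A", "C", "G", "T")) return(b)
    if (b %in% names(iupac)) return(strsplit(iupac[[b]], "", fixed = TRUE)[[1L]])
    NULL
  })
  if (any(vapply(expand, is.null, logical(1L)))) return("X")
  combos <- expand.grid(expand[[1L]], expand[[2L]], expand[[3L]],
                        stringsAsFactors = FALSE)
  aas <- unique(genetic_code[paste0(combos[[1L]], combos[[2L]], combos[[3L]])])
  if (length(aas) == 1L && !is.na(aas)) aas else "X"
}

#' Partition haplotypes into amino-acid allele groups
#'
#' Haplotypes whose coding regions translate to the same protein belong to
#' one allele group (synonymous variants are functionally identical and are
#' collapsed). Translations containing `X` (from ambiguity codes) are
#' assigned to a group only if exactly one group protein is compatible at
#' every unambiguous position; otherwise they are reported as unresolved.
#' Haplotypes that fail translation are reported separately.
#'
#' @param haplotypes Data frame with columns `id` and `sequence` (additional
#'   metadata columns are kept and available to [allele_frequencies()]), or
#'   an alignment matrix.
#' @param cds_coords Coding-region intervals passed to [translate_cds()].
#' @param reference_proteins Optional named character vector of known allele
#'   proteins used to assign the field's allele labels (e.g. `"M3"`, `"D"`);
#'   groups not matching any reference get labels `A1`, `A2`, ... in order
#'   of first occurrence.
#' @return An object of class `allele_groups`: list with `groups` (each with
#'   `label`, `protein`, `member_ids`), `unresolved`, `failed`, and an
#'   `assignments` data frame.
#' @export
group_alleles <- function(haplotypes, cds_coords = NULL,
                          reference_proteins = NULL) {
  if (is.matrix(haplotypes)) {
    haplotypes <- data.frame(id = rownames(haplotypes),
                             sequence = unname(alignment_strings(haplotypes)),
                             stringsAsFactors = FALSE)
  }
  stopifnot(all(c("id", "sequence") %in% names(haplotypes)))
  proteins <- character(nrow(haplotypes))
  failed <- character(0)
  for (i in seq_len(nrow(haplotypes))) {
    p <- tryCatch(translate_cds(haplotypes$sequence[i], cds_coords),
                  error = function(e) NA_character_)
    if (is.na(p)) failed <- c(failed, haplotypes$id[i])
    proteins[i] <- p
  }
  clean <- !is.na(proteins) & !grepl("X", proteins, fixed = TRUE)
  group_prots <- unique(proteins[clean])
  # Resolve ambiguous translations against clean group proteins (and any
  # supplied references) at their unambiguous positions.
  unresolved <- character(0)
  assigned_prot <- proteins
  candidates <- unique(c(group_prots, unname(reference_proteins)))
  for (i in which(!is.na(proteins) & !clean)) {
    compat <- candidates[vapply(candidates, .protein_compatible,
                                logical(1L), ambiguous = proteins[i])]
    if (length(compat) == 1L) {
      assigned_prot[i] <- compat
    } else {
      assigned_prot[i] <- NA_character_
      unresolved <- c(unresolved, haplotypes$id[i])
    }
  }
  ok <- !is.na(assigned_prot)
  prots_in_order <- unique(assigned_prot[ok])
  labels <- character(length(prots_in_order))
  auto <- 0L
  for (k in seq_along(prots_in_order)) {
    hit <- if (!is.null(reference_proteins)) {
      names(reference_proteins)[reference_proteins == prots_in_order[k]]
    } else character(0)
    if (length(hit) >= 1L) {
      labels[k] <- hit[1L]
    } else {
      auto <- auto + 1L
      labels[k] <- paste0("A", auto)
    }
  }
  groups <- lapply(seq_along(prots_in_order), function(k) {
    members <- haplotypes$id[ok & assigned_prot == prots_in_order[k]]
    list(label = labels[k], protein = prots_in_order[k], member_ids = members)
  })
  names(groups) <- labels
  assignments <- data.frame(
    id = haplotypes$id,
    allele = vapply(seq_len(nrow(haplotypes)), function(i) {
      if (!ok[i]) NA_character_ else labels[match(assigned_prot[i], prots_in_order)]
    }, character(1L)),
    stringsAsFactors = FALSE)
  meta_cols <- setdiff(names(haplotypes), c("sequence"))
  assignments <- merge(assignments, haplotypes[, meta_cols, drop = FALSE],
                       by = "id", sort = FALSE)
  structure(list(groups = groups, unresolved = unresolved, failed = failed,
                 assignments = assignments),
            class = "allele_groups")
}

# TRUE if `ambiguous` (protein with X wildcards) matches `candidate` at all
# non-X positions.
.protein_compatible <- function(candidate, ambiguous) {
  if (nchar(candidate) != nchar(ambiguous)) return(FALSE)
  a <- strsplit(ambiguous, "", fixed = TRUE)[[1L]]
  b <- strsplit(candidate, "", fixed = TRUE)[[1L]]
  all(a == "X" | a == b)
}

#' @export
print.allele_groups <- function(x, ...) {
  cat("Amino-acid allele groups:", length(x$groups), "\n")
  for (g in x$groups) {
    cat(sprintf("  %-6s %3d haplotype(s)\n", g$label, length(g$member_ids)))
  }
  if (length(x$unresolved)) {
    cat("Unresolved (ambiguous translation):", length(x$unresolved), "\n")
  }
  if (length(x$failed)) cat("Failed translation:", length(x$failed), "\n")
  invisible(x)
}

#' Tabulate polymorphic sites with synonymous/nonsynonymous labels
#'
#' Emits one row per polymorphic alignment column. Columns inside the coding
#' region are labelled `"s"` when every observed variant base leaves the
#' translation of every observed codon background unchanged, `"n"`
#' otherwise; columns outside the coding region are labelled `"noncoding"`.
#'
#' @param alignment Alignment matrix of equal-length sequences.
#' @param cds_coords Coding-region intervals (1-based inclusive).
#' @return Data frame with `position`, `class`, and one column per sequence
#'   giving its base at the site.
#' @export
site_table <- function(alignment, cds_coords = NULL) {
  aln <- as_alignment(alignment)
  L <- ncol(aln)
  cols <- cds_columns(cds_coords, L)
  codon_idx <- match(seq_len(L), cols)       # position within CDS, NA outside
  rows <- list()
  for (j in seq_len(L)) {
    obs <- aln[, j]
    variants <- unique(obs[obs %in% c("A", "C", "G", "T")])
    if (length(variants) < 2L) next
    if (is.na(codon_idx[j])) {
      cls <- "noncoding"
    } else {
      k <- codon_idx[j]
      codon_number <- (k - 1L) %/% 3L
      offset <- (k - 1L) %% 3L + 1L
      codon_cols <- cols[codon_number * 3L + 1:3]
      backgrounds <- unique(apply(aln[, codon_cols, drop = FALSE], 1L,
                                  paste0, collapse = ""))
      backgrounds <- backgrounds[!grepl("[^ACGT]", backgrounds)]
      cls <- "s"
      for (bg in backgrounds) {
        ref_aa <- .translate_codon(strsplit(bg, "")[[1L]])
        for (v in variants) {
          alt <- strsplit(bg, "")[[1L]]
          alt[offset] <- v
          if (.translate_codon(alt) != ref_aa) {
            cls <- "n"
            break
          }
        }
        if (cls == "n") break
      }
    }
    row <- data.frame(position = j, class = cls, stringsAsFactors = FALSE)
    for (id in rownames(aln)) row[[id]] <- aln[id, j]
    rows[[length(rows) + 1L]] <- row
  }
  if (!length(rows)) {
    out <- data.frame(position = integer(0), class = character(0))
    for (id in rownames(aln)) out[[id]] <- character(0)
    return(out)
  }
  do.call(rbind, rows)
}

#' Allele frequencies stratified by sample metadata
#'
#' Counts allele-group membership per stratum (species, locality, or any
#' metadata column) and reports proportions and the dominant allele of each
#' stratum.
#'
#' @param groups An `allele_groups` object from [group_alleles()].
#' @param metadata Optional data frame with column `id` plus metadata; if
#'   omitted, the metadata carried in `groups$assignments` is used.
#' @param stratify_by Name of the metadata column to stratify on.
#' @return Data frame with `stratum`, `allele`, `count`, `proportion`, and
#'   logical `dominant`.
#' @export
allele_frequencies <- function(groups, stratify_by = "species",
                               metadata = NULL) {
  stopifnot(inherits(groups, "allele_groups"))
  tab <- groups$assignments
  if (!is.null(metadata)) {
    tab <- merge(tab[, c("id", "allele")], metadata, by = "id", sort = FALSE)
  }
  if (!stratify_by %in% names(tab)) {
    stop("metadata column '", stratify_by, "' not found")
  }
  tab <- tab[!is.na(tab$allele), , drop = FALSE]
  strat <- as.character(tab[[stratify_by]])
  strat[is.na(strat) | strat == ""] <- "unknown"
  counts <- as.data.frame(table(stratum = strat, allele = tab$allele),
                          stringsAsFactors = FALSE)
  counts <- counts[counts$Freq > 0L, , drop = FALSE]
  names(counts)[names(counts) == "Freq"] <- "count"
  out <- do.call(rbind, lapply(split(counts, counts$stratum), function(d) {
    d$proportion <- d$count / sum(d$count)
    d$dominant <- d$count == max(d$count)
    d
  }))
  rownames(out) <- NULL
  out[order(out$stratum, -out$count, out$allele), , drop = FALSE]
}
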