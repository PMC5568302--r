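test_that("translation handles the standard code, ambiguity, and errors", {
  expect_identical(translate_cds("ATGGCT"), "MA")
  # fourfold-degenerate ambiguity resolves; two-residue ambiguity does not
  expect_identical(translate_cds("GCN"), "A")
  expect_identical(translate_cds("GCW"), "A")
  expect_identical(translate_cds("RAT"), "X")  # AAT (N) vs GAT (D)
  expect_identical(translate_cds("GCNAAY"), "AN")
  # N and gaps are unresolvable unless degenerate
  expect_identical(translate_cds("A-G"), "X")
  # empty CDS
  expect_identical(translate_cds("ACGTTT", cds_coords = matrix(numeric(0), 0, 2)), "")
  expect_error(translate_cds("ATGGC"), "divisible by 3")
  expect_warning(translate_cds("ATGTAAGCT"), "stop codon")
})

test_that("allele grouping partitions by protein identity", {
  haps <- data.frame(
    id = c("a", "b", "c", "d"),
    sequence = c("GCTGAT",   # AD
                 "GCCGAT",   # AD via synonymous change -> same group
                 "GCTCAT",   # AH
                 "TCTGAT"))  # SD
  grp <- group_alleles(haps)
  expect_length(grp$groups, 3L)
  g_of <- setNames(grp$assignments$allele, grp$assignments$id)
  expect_identical(g_of[["a"]], g_of[["b"]])
  expect_false(g_of[["a"]] == g_of[["c"]])
  # single haplotype forms its own singleton group
  solo <- group_alleles(data.frame(id = "x", sequence = "ATGGCT"))
  expect_length(solo$groups, 1L)
  expect_identical(solo$groups[[1L]]$member_ids, "x")
})

test_that("grouping recovers simulated ground truth and ignores input order", {
  sim <- simulate_coding_alleles(6, 5, 80, 2, 1, seed = 21)
  haps <- data.frame(id = rownames(sim$alignment),
                     sequence = unname(alignment_strings(sim$alignment)))
  grp <- group_alleles(haps)
  expect_length(grp$groups, 6L)
  found <- setNames(grp$assignments$allele, grp$assignments$id)
  truth <- setNames(sim$truth$group, sim$truth$id)
  # same partition: the map truth -> found labels is a bijection
  expect_true(all(tapply(found, truth, function(v) length(unique(v))) == 1L))
  expect_length(unique(tapply(found, truth, `[`, 1L)), 6L)
  # permuting input rows changes labels at most, not the partition
  perm <- haps[rev(seq_len(nrow(haps))), ]
  grp2 <- group_alleles(perm)
  found2 <- setNames(grp2$assignments$allele, grp2$assignments$id)
  cross <- table(found[names(found2)], found2)
  expect_true(all(rowSums(cross > 0) == 1L))
})

test_that("reference proteins name the groups and ambiguity follows the rule", {
  refs <- c(M3 = "AD", H = "SH")
  haps <- data.frame(id = c("a", "b", "c"),
                     sequence = c("GCTGAT", "TCTCAT", "GCTRAT"))
  # "GCTRAT" translates to "AX": among the known proteins only AD (M3)
  # matches at the unambiguous first residue, so it is assigned there
  grp <- group_alleles(haps, reference_proteins = refs)
  expect_setequal(names(grp$groups), c("M3", "H"))
  expect_true("c" %in% grp$groups[["M3"]]$member_ids)
  # when two known proteins are compatible the haplotype stays unresolved
  haps2 <- data.frame(id = c("a", "b", "c"),
                      sequence = c("GCTAAT", "GCTGAT", "GCTRAT"))
  grp2 <- group_alleles(haps2)
  expect_identical(grp2$unresolved, "c")
  # untranslatable haplotypes are reported as failed, not grouped
  haps3 <- data.frame(id = c("a", "b"), sequence = c("GCTGA", "GCTGAT"))
  grp3 <- group_alleles(haps3)
  expect_identical(grp3$failed, "a")
  expect_length(grp3$groups, 1L)
})

test_that("site table labels synonymous/nonsynonymous/noncoding correctly", {
  # invariant alignment -> empty table
  inv <- as_alignment(c(a = "GCTGCT", b = "GCTGCT"))
  expect_identical(nrow(site_table(inv)), 0L)
  # third-position GCT<->GCC is synonymous; first-position GCT<->TCT is not
  aln <- as_alignment(c(a = "GCTGCTA", b = "GCCGCTA", c = "GCTTCTC"))
  st <- site_table(aln, cds_coords = c(1, 6))
  expect_identical(st$class[st$position == 3L], "s")
  expect_identical(st$class[st$position == 4L], "n")
  expect_identical(st$class[st$position == 7L], "noncoding")
  expect_identical(sort(st$position), c(3L, 4L, 7L))
  # per-sequence bases are carried in the table
  expect_identical(st[st$position == 3L, "b"], "C")
})

test_that("site table agrees with planted truth from the generator", {
  sim <- simulate_coding_alleles(4, 4, 60, 2, 2, seed = 31)
  st <- site_table(sim$alignment)
  expect_gt(nrow(st), 0L)
  # by construction: group-defining changes sit at codon position 1 ("n"),
  # synonymous within-group changes at fourfold-degenerate position 3 ("s")
  expected <- ifelse(st$position %% 3L == 1L, "n", "s")
  expect_identical(st$class, expected)
})

test_that("allele frequencies stratify, normalise, and flag dominance", {
  haps <- data.frame(
    id = sprintf("h%d", 1:8),
    sequence = c(rep("GCTGAT", 3), "GCTCAT", rep("GCTCAT", 3), "TCTGAT"),
    species = c(rep("sp1", 4), rep("sp2", 3), NA))
  grp <- group_alleles(haps)
  freq <- allele_frequencies(grp, "species")
  sp1 <- freq[freq$stratum == "sp1", ]
  expect_identical(sp1$proportion[order(-sp1$count)], c(0.75, 0.25))
  expect_identical(sp1$dominant[order(-sp1$count)], c(TRUE, FALSE))
  for (s in unique(freq$stratum)) {
    expect_equal(sum(freq$proportion[freq$stratum == s]), 1)
  }
  expect_true("unknown" %in% freq$stratum)
  # single species, single allele -> frequency exactly 1
  one <- group_alleles(data.frame(id = "z", sequence = "GCTGAT", species = "sp9"))
  f1 <- allele_frequencies(one, "species")
  expect_identical(f1$proportion, 1)
  expect_error(allele_frequencies(grp, "no_such_column"), "not found")
})
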