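test_that("transition/transversion typing is exhaustive and correct", {
  bases <- c("A", "C", "G", "T")
  pairs <- expand.grid(ref = bases, alt = bases,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$ref != pairs$alt, ]
  types <- classify_substitution(pairs$ref, pairs$alt)
  expect_equal(sum(types == "transition"), 4L)
  expect_equal(sum(types == "transversion"), 8L)
  expect_equal(classify_substitution("A", "G"), "transition")
  expect_equal(classify_substitution("G", "T"), "transversion")
  expect_equal(classify_substitution("C", "G"), "transversion")
  expect_error(classify_substitution("A", "A"), "Identical")
  expect_error(classify_substitution("-", "A"), "A, C, G, T")
})

test_that("A/T effect labels derive from the (ref, derived) pair only", {
  expect_equal(ta_effect("A", "T"), "loses_A,gains_T")
  expect_equal(ta_effect("T", "C"), "loses_T")
  expect_equal(ta_effect("C", "G"), "")
  expect_equal(ta_effect("G", "A"), "gains_A")
  expect_error(ta_effect("A", "A"), "Identical")
})

test_that("A/T effect is antisymmetric under polarity reversal", {
  bases <- c("A", "C", "G", "T")
  flip <- function(lbl) {
    if (lbl == "") return("")
    parts <- vapply(strsplit(lbl, ",", fixed = TRUE)[[1]], function(p) {
      if (startsWith(p, "loses_")) sub("loses_", "gains_", p)
      else sub("gains_", "loses_", p)
    }, character(1))
    paste(sort(parts), collapse = ",")
  }
  for (r in bases) {
    for (a in setdiff(bases, r)) {
      fwd <- ta_effect(r, a)
      rev <- ta_effect(a, r)
      expect_equal(paste(sort(strsplit(rev, ",")[[1]]), collapse = ","),
                   flip(fwd))
    }
  }
})

test_that("the rpl22 fixture yields the published SNP table", {
  fx <- rpl22_alignment()
  expect_equal(nchar(fx$alignment$sequence), rep(426L, 4))
  snps <- call_snps(fx$alignment, reference = "E_drupifera")
  expect_equal(snps$position,
               c(223L, 385L, 390L, 391L, 392L, 394L, 396L, 397L, 405L, 409L))
  expect_equal(sum(snps$change_type == "transition"), 5L)
  expect_equal(sum(snps$change_type == "transversion"), 5L)
  expect_equal(snps$change,
               c("A>G", "A>G", "A>G", "T>C", "A>T", "G>T", "A>T", "G>A",
                 "T>G", "C>A"))
  expect_equal(snps$ta_effect,
               c("loses_A", "loses_A", "loses_A", "loses_T",
                 "loses_A,gains_T", "gains_T", "loses_A,gains_T",
                 "gains_A", "loses_T", "gains_A"))
})

test_that("SNP calling handles invariant, multiallelic and ref-gap columns", {
  invariant <- tibble::tibble(taxon = c("a", "b"),
                              sequence = c("ACGT", "ACGT"))
  expect_equal(nrow(call_snps(invariant)), 0L)

  multi <- tibble::tibble(taxon = c("a", "b", "c"),
                          sequence = c("AAAA", "ACAA", "AGTA"))
  got <- call_snps(multi, reference = "a")
  expect_equal(got$change_type[got$position == 2L], "multiallelic")
  expect_equal(got$change_type[got$position == 3L], "transversion")

  refgap <- tibble::tibble(taxon = c("a", "b", "c"),
                           sequence = c("A-GT", "ACGT", "AGGT"))
  expect_warning(rg <- call_snps(refgap, reference = "a"), "gapped")
  expect_equal(rg$change_type, "multiallelic")
  expect_true(rg$ref_gap)

  expect_error(call_snps(invariant, reference = "nope"), "not in")
})

test_that("planted biallelic sites are recovered exactly at zero noise", {
  for (seed in 1:10) {
    set.seed(seed + 900)
    positions <- sort(sample(10:490, 8))
    refs <- sample(c("A", "C", "G", "T"), 8, TRUE)
    alts <- vapply(refs, function(r) {
      sample(setdiff(c("A", "C", "G", "T"), r), 1)
    }, character(1))
    carriers <- vapply(1:8, function(i) {
      paste(sample(paste0("t", 1:6), sample(1:5, 1)), collapse = ",")
    }, character(1))
    spec <- alignment_spec(n_taxa = 6, length = 500, theta = 0,
                           snps = tibble::tibble(position = positions,
                                                 ref = refs, alt = alts,
                                                 carriers = carriers))
    a <- synth_alignment(spec, seed = seed)
    got <- call_snps(a$alignment)
    expect_equal(got$position, positions)
    # precision and recall are both 1 on the planted truth
    expect_setequal(paste(got$position,
                          pmin(got$reference_base, got$derived_base),
                          pmax(got$reference_base, got$derived_base)),
                    paste(positions, pmin(refs, alts), pmax(refs, alts)))
  }
})

test_that("pairwise identity counts matches over gap-free pair columns", {
  a <- strrep("A", 423)
  b <- paste0(strrep("A", 422), "G")
  got <- pairwise_identity(a, b)
  expect_equal(got$percent, 99.76)
  expect_equal(got$compared_length, 423L)
  expect_equal(pairwise_identity(a, a)$percent, 100)
  expect_equal(pairwise_identity("AAAA", "TTTT")$percent, 0)
  gapped <- paste0("--", strrep("A", 50))
  expect_equal(pairwise_identity(gapped, gapped)$percent, 100)
  expect_equal(pairwise_identity(gapped, gapped)$compared_length, 50L)
  expect_error(pairwise_identity("A-", "-A"), "comparable")
  expect_error(pairwise_identity("AC", "ACG"), "length")
})

test_that("the fixture identity matrix mirrors the published comparisons", {
  fx <- rpl22_alignment()
  im <- identity_matrix(fx$alignment)
  expect_equal(im$percent["E_resinifera", "E_ampliphylla"], 100)
  expect_equal(im$percent["E_resinifera", "E_royleana"], 99.76)
  expect_equal(im$compared_length["E_resinifera", "E_royleana"], 423L)
  # drupifera differs from resinifera/ampliphylla at 9 columns and from
  # royleana at 10 (adding the 405 marker): the published 97.41-97.87% band
  expect_equal(im$percent["E_drupifera", "E_resinifera"], 97.87)
  expect_equal(im$percent["E_drupifera", "E_royleana"], 97.64)
  expect_true(isSymmetric(im$percent))
  expect_equal(diag(im$percent), setNames(rep(100, 4), fx$alignment$taxon))
  td <- tidy(im)
  expect_equal(nrow(td), 6L)
})

test_that("diagnostic and private sites separate the cactiform trio", {
  fx <- rpl22_alignment()
  cactiform <- fx$groups$taxon[fx$groups$group == "cactiform"]
  ds <- diagnostic_sites(fx$alignment, cactiform)
  expect_equal(ds$shared_diagnostic,
               c(223L, 385L, 390L, 391L, 392L, 394L, 396L, 397L, 409L))
  roy <- ds$private_alleles[ds$private_alleles$taxon == "E_royleana", ]
  expect_equal(roy$position, 405L)

  flat <- tibble::tibble(taxon = c("a", "b", "c"),
                         sequence = rep("ACGT", 3))
  none <- diagnostic_sites(flat, "a")
  expect_equal(none$shared_diagnostic, integer())
  expect_equal(nrow(none$private_alleles), 0L)
  expect_error(diagnostic_sites(flat, c("a", "b", "c")), "proper subset")
})

test_that("indels are maximal gap blocks grouped by carrier set", {
  fx <- rpl22_alignment()
  ind <- find_indels(fx$alignment)
  expect_equal(nrow(ind), 1L)
  expect_equal(c(ind$start, ind$end, ind$length), c(150L, 152L, 3L))
  expect_equal(ind$inserted_or_deleted, "AGC")

  gapless <- tibble::tibble(taxon = c("a", "b"),
                            sequence = c("ACGT", "ACGA"))
  expect_equal(nrow(find_indels(gapless)), 0L)

  allgap <- tibble::tibble(taxon = c("a", "b"),
                           sequence = c("A-GT", "A-GA"))
  expect_error(find_indels(allgap), "every taxon")
})

test_that("planted indels of lengths 1-6 are recovered with exact coordinates", {
  starts <- c(20L, 60L, 110L, 170L, 240L, 320L)
  lens <- 1:6
  spec <- alignment_spec(
    n_taxa = 4, length = 400, theta = 0,
    indels = tibble::tibble(position = starts, length = lens,
                            carriers = rep(c("t1", "t2,t3"), 3)))
  a <- synth_alignment(spec, seed = 14)
  got <- find_indels(a$alignment)
  expect_equal(got$start, starts)
  expect_equal(got$length, lens)
  expect_equal(got$end, starts + lens - 1L)
})
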