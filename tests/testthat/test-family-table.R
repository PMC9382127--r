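test_that("family table loads, validates and round-trips", {
  tab <- acprx_table()
  expect_s3_class(tab, "family_table")
  expect_equal(nrow(tab), 78)
  # thousands separators and en-dash locations parsed
  expect_equal(tab$start[tab$gene_name == "AcPRX1"], 22942404)
  expect_equal(tab$end[tab$gene_name == "AcPRX1"], 22945339)
  expect_equal(tab$aa_len[tab$gene_name == "AcPRX64"], 100)
  expect_equal(tab$mw[tab$gene_name == "AcPRX64"], 11.33)

  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_family_table(tab, tmp)
  expect_equal(as.data.frame(load_family_table(tmp)), as.data.frame(tab))

  bad <- as.data.frame(tab)
  bad$start[3] <- bad$end[3] + 1
  expect_error(family_table(bad), "start > end.*row 3")
  dup <- as.data.frame(tab)
  dup$gene_name[2] <- dup$gene_name[1]
  expect_error(family_table(dup), "duplicate gene_name")

  t2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_name\taccession\tchromosome\tgenomic_location\torf\texon\taa\tmw\tpi",
               "g1\ta1\tchr1\t500-100\t300\t2\t99\t11\t6"), t2)
  expect_error(load_family_table(t2), "start > end")
  t3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_name\taccession\tchromosome\tgenomic_location\torf\texon\taa\tmw\tpi",
               "g1\ta1\tchr1\t100-500\tNOTANUMBER\t2\t99\t11\t6"), t3)
  expect_error(load_family_table(t3), "unparseable numeric.*orf.*row 1")
})

test_that("candidate screening applies the printed thresholds literally", {
  hits <- data.frame(
    query_id = "q", subject_id = c("s1", "s2", "s3", "s4", "s4", "s5"),
    evalue = c(1e-6, 1e-4, 1e-5, 1e-8, 0, 1e-9),
    identity_pct = c(60, 60, 50.1, 40, 0, 90),
    source = c("homology_search", "homology_search", "homology_search",
               "homology_search", "keyword", "keyword"),
    stringsAsFactors = FALSE)
  kept <- filter_candidates(hits)
  expect_true("s1" %in% kept)          # passes both
  expect_false("s2" %in% kept)         # fails E-value (inclusive bound)
  expect_true("s3" %in% kept)          # E-value boundary kept, identity strict
  expect_true("s4" %in% kept)          # keyword bypasses numeric filter
  expect_true("s5" %in% kept)
  expect_equal(sum(kept == "s4"), 1)   # deduplicated
  # strictly >50: an exact 50 homology hit is dropped
  h50 <- data.frame(query_id = "q", subject_id = "x", evalue = 1e-9,
                    identity_pct = 50, source = "homology_search")
  expect_length(filter_candidates(h50), 0)
  expect_length(filter_candidates(hits[0, ]), 0)
  # order/duplication invariance
  shuf <- hits[c(6, 1, 5, 2, 4, 3, 1, 1), ]
  expect_identical(filter_candidates(shuf), kept)
})

test_that("exon histogram matches the published structure counts", {
  tab <- acprx_table()
  h <- exon_histogram(tab)
  expect_equal(unname(h$counts[c("2", "3", "4", "5")]), c(9L, 14L, 35L, 5L))
  expect_equal(unname(h$intron_counts["1"]), 9L)
  expect_equal(h$total, 78)
  expect_equal(sum(h$counts), nrow(tab))
  expect_equal(unname(h$percentages["2"]), 11.54)
  expect_lt(abs(sum(h$percentages) - 100), 0.05)
  expect_equal(round_half_away(sum(h$percentages[c("2", "3", "4", "5")]), 2),
               80.77)
  one <- family_table(as.data.frame(tab)[1, ])
  h1 <- exon_histogram(one)
  expect_equal(unname(h1$counts[as.character(tab$exon_count[1])]), 1L)
  expect_error(exon_histogram(tab[0, ]), "empty")
})

test_that("protein MW is additive and matches the alanine-dipeptide value", {
  expect_equal(protein_mw("AA"), 0.1601729, tolerance = 1e-6)
  expect_error(protein_mw(""), "empty")
  expect_error(protein_mw("AB2"), "illegal.*position 2")
  set.seed(1)
  aas <- paste(sample(names(famdup:::.aa_masses), 30, TRUE), collapse = "")
  s1 <- substr(aas, 1, 12); s2 <- substr(aas, 13, 30)
  water <- 18.01524 / 1000
  expect_equal(protein_mw(aas), protein_mw(s1) + protein_mw(s2) - water,
               tolerance = 1e-9)
})

test_that("isoelectric point solves the net-charge root", {
  pka <- pka_table()
  pka[c("Nterm", "Cterm")] <- c(9.6, 2.34)
  expect_equal(isoelectric_point("GG", pka = pka), 5.97, tolerance = 2e-3)
  # net charge at the root is ~0
  seqs <- c("GG", "DDDDDDDDDD", "KRKRHH", "ACDEFGHIKLMNPQRSTVWY")
  for (s in seqs) {
    pI <- isoelectric_point(s)
    aa <- strsplit(s, "")[[1]]
    counts <- c(Nterm = 1, Cterm = 1,
                vapply(c("C", "D", "E", "H", "K", "R", "Y"),
                       function(g) sum(aa == g), numeric(1)))
    expect_lt(abs(famdup:::.net_charge(pI, counts, pka_table())), 2e-3)
  }
  expect_lt(isoelectric_point("DDDDDDDDDD"), 7)   # poly-acidic
  # appending an acidic residue lowers pI, a basic one raises it
  base <- "ACGTMS"
  expect_lt(isoelectric_point(paste0(base, "D")), isoelectric_point(base))
  expect_gt(isoelectric_point(paste0(base, "K")), isoelectric_point(base))
})

test_that("range summaries reproduce the published extrema", {
  tab <- acprx_table()
  aa <- range_summary(tab, "aa_len")
  expect_equal(aa[c("min", "min_gene", "max", "max_gene")],
               list(min = 100L, min_gene = "AcPRX64",
                    max = 1057L, max_gene = "AcPRX66"))
  mw <- range_summary(tab, "mw")
  expect_equal(mw$min, 11.33); expect_equal(mw$max, 118.18)
  pi <- range_summary(tab, "pi")
  expect_equal(pi$min, 4.52); expect_equal(pi$min_gene, "AcPRX59")
  expect_equal(pi$max, 10.28); expect_equal(pi$max_gene, "AcPRX78")
  one <- family_table(as.data.frame(tab)[5, ])
  r <- range_summary(one, "mw")
  expect_equal(r$min, r$max)
})

test_that("physchem table computes per-sequence descriptors", {
  pt <- physchem_table(c(p1 = "AA", p2 = "ACDEFGHIKLMNPQRSTVWY"))
  expect_equal(pt$aa_len, c(2L, 20L))
  expect_equal(pt$mw[1], 0.1601729, tolerance = 1e-6)
  expect_true(all(pt$pi > 0 & pt$pi < 14))
})
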