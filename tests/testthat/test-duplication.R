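test_that("global identity counts matches over the shorter sequence", {
  expect_equal(global_identity("HDCFV", "HDCYV"), 0.8)
  expect_equal(global_identity("MKVLT", "MKVLT"), 1.0)
  set.seed(2)
  s <- paste(sample(c("A", "C", "D", "K", "L", "M"), 40, TRUE), collapse = "")
  expect_equal(global_identity(s, s), 1.0)
  expect_error(global_identity("ACD", ""), "empty")
  # symmetric
  expect_equal(global_identity("HDCFV", "HDCYV"),
               global_identity("HDCYV", "HDCFV"))
})

test_that("duplicate detection applies both strict criteria", {
  # three similar proteins + one unrelated, lengths tuned around the ratio
  base <- "MKVLTAGHEDWCRPQSYFNIKLMVATGHEDWCRPQSYFNI"  # 40 aa
  tab <- family_table(data.frame(
    gene_name = c("g1", "g2", "g3", "g4"),
    accession = paste0("a", 1:4), chromosome = "chr1",
    start = c(1, 100, 200, 300) * 1000,
    end = c(1, 100, 200, 300) * 1000 + 500,
    orf_len = 120, exon_count = 2,
    aa_len = c(40, 40, 25, 40), mw = 5, pi = 7,
    stringsAsFactors = FALSE))
  prot <- c(
    g1 = base,
    g2 = sub("AGH", "AGY", base),              # ~97% identical, ratio 1
    g3 = substr(base, 1, 25),                  # ratio 0.625 -> excluded
    g4 = "WWWWWYYYYYWWWWWYYYYYWWWWWYYYYYWWWWWYYYYY")
  pairs <- find_duplicate_pairs(tab, prot)
  expect_equal(pair_key(pairs), "g1 g2")
  expect_gt(pairs$identity, 0.9)
  # strictness: identity exactly at the threshold is excluded
  p2 <- find_duplicate_pairs(tab, prot, identity_min = 0.999)
  expect_false("g1 g2" %in% pair_key(p2))
  # monotonicity: raising identity_min never grows the set
  p_lo <- find_duplicate_pairs(tab, prot, identity_min = 0.3)
  expect_true(all(pair_key(pairs) %in% pair_key(p_lo)))
  expect_error(find_duplicate_pairs(tab, prot[-1]), "missing protein.*g1")
})

test_that("tandem classification follows the span rule", {
  tab <- toy_table()  # g1/g2 149 kb apart on chr1; g3 far; g4 on chr2
  pairs <- duplicate_pairs(c("g1", "g1", "g2"), c("g2", "g4", "g3"))
  cl <- classify_tandem(pairs, tab, "span_200kb")
  got <- setNames(cl$classification, pair_key(cl))
  expect_equal(got[["g1 g2"]], "tandem")
  expect_equal(got[["g1 g4"]], "unclassified")  # different chromosome
  expect_equal(got[["g2 g3"]], "unclassified")  # 1.15 Mb apart
  # boundary: exactly 200 kb is not tandem (strict <)
  t2 <- toy_table()
  t2$start[2] <- t2$start[1] + 200000
  cl2 <- classify_tandem(duplicate_pairs("g1", "g2"), t2, "span_200kb")
  expect_equal(cl2$classification, "unclassified")
  t2$start[2] <- t2$start[1] + 199999
  cl3 <- classify_tandem(duplicate_pairs("g1", "g2"), t2, "span_200kb")
  expect_equal(cl3$classification, "tandem")
})

test_that("window rule needs gene order and counts intervening genes", {
  tab <- toy_table()
  tab$start <- c(1000, 60000, 90000, 5000)
  tab$end <- tab$start + 1000
  pairs <- duplicate_pairs("g1", "g3")
  expect_error(classify_tandem(pairs, tab, "window_100kb_5genes"),
               "requires all_genes")
  mk_order <- function(n_between) {
    data.frame(
      gene_name = c("g1", paste0("x", seq_len(n_between)), "g3"),
      chromosome = "chr1",
      start = seq(1000, 90000, length.out = n_between + 2),
      stringsAsFactors = FALSE)
  }
  cl <- classify_tandem(pairs, tab, "window_100kb_5genes",
                        all_genes = mk_order(3))
  expect_equal(cl$classification, "tandem")
  cl6 <- classify_tandem(pairs, tab, "window_100kb_5genes",
                         all_genes = mk_order(6))
  expect_equal(cl6$classification, "unclassified")
  # outside the 100-kb fragment even with few intervening genes
  tab$start[3] <- 150000; tab$end[3] <- 151000
  ord <- mk_order(2); ord$start[4] <- 150000
  cl_far <- classify_tandem(pairs, tab, "window_100kb_5genes",
                            all_genes = ord)
  expect_equal(cl_far$classification, "unclassified")
})

test_that("segmental classification uses blocks with tandem precedence", {
  tab <- toy_table()
  pairs <- duplicate_pairs(c("g1", "g2"), c("g2", "g4"))
  pairs <- classify_tandem(pairs, tab, "span_200kb")  # g1/g2 tandem
  blocks <- data.frame(block_id = c("b1", "b2"),
                       chrom_a = "chr1", start_a = 1, end_a = 2e6,
                       chrom_b = "chr2", start_b = 1, end_b = 1e6,
                       gene_a = c("g2", "g1"), gene_b = c("g4", "g2"),
                       stringsAsFactors = FALSE)
  cl <- classify_segmental(pairs, blocks, tab)
  got <- setNames(cl$classification, pair_key(cl))
  expect_equal(got[["g2 g4"]], "segmental")
  expect_equal(got[["g1 g2"]], "tandem")  # precedence kept
  # span containment route (pair in no member list)
  p2 <- classify_segmental(duplicate_pairs("g3", "g4"), blocks, tab)
  expect_equal(p2$classification, "segmental")  # g3 in span_a, g4 in span_b
  # no blocks: unchanged
  expect_equal(classify_segmental(pairs, blocks[0, ], tab)$classification,
               pairs$classification)
})

test_that("operations are symmetric in pair order and input order", {
  tab <- toy_table()
  p_ab <- classify_tandem(duplicate_pairs("g1", "g2"), tab)
  p_ba <- classify_tandem(duplicate_pairs("g2", "g1"), tab)
  expect_identical(p_ab, p_ba)
  expect_error(duplicate_pairs("g1", "g1"), "self-pairing")
})

test_that("summaries count pairs, genes and chromosomes", {
  tab <- acprx_table()
  tp <- acprx_pairs("tandem")
  sp <- acprx_pairs("segmental")
  tand <- classify_tandem(duplicate_pairs(tp$gene_a, tp$gene_b), tab)
  expect_true(all(tand$classification == "tandem"))
  s <- summarize_duplications(tand, tab)
  expect_equal(s$tandem_pairs, 17)
  expect_equal(s$tandem_genes, 22)
  expect_equal(s$tandem_chromosomes, 8)
  seg <- duplicate_pairs(sp$gene_a, sp$gene_b)
  seg$classification <- "segmental"
  s2 <- summarize_duplications(seg)
  expect_equal(s2$segmental_pairs, 15)
  expect_equal(s2$segmental_genes, 24)
  empty <- summarize_duplications(duplicate_pairs(character(0), character(0)))
  expect_equal(empty$tandem_pairs, 0)
  expect_equal(empty$segmental_genes, 0)
})
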