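test_that("simulated genomes are deterministic with complete truth tables", {
  sim <- cached_sim_genome(7)
  cfg <- sim$config
  expect_identical(simulate_genome(sim_config(seed = 7))[c("table", "cds")],
                   sim[c("table", "cds")])
  # truth completeness: every planted cluster yields all C(k,2) pairs
  n_t <- cfg$tandem$count * choose(cfg$tandem$size, 2)
  expect_equal(nrow(sim$truth$tandem_pairs), n_t)
  n_s <- cfg$segmental$count * cfg$segmental$pairs_per_block
  expect_equal(nrow(sim$truth$segmental_pairs), n_s)
  expect_equal(nrow(sim$table), cfg$family_size)
  # no pair is listed twice or in both classes
  keys <- c(pair_key(sim$truth$tandem_pairs),
            pair_key(sim$truth$segmental_pairs))
  expect_equal(anyDuplicated(keys), 0)
  # tandem members share a chromosome within the spacing budget
  for (i in seq_len(nrow(sim$truth$tandem_pairs))) {
    a <- sim$table[sim$table$gene_name == sim$truth$tandem_pairs$gene_a[i], ]
    b <- sim$table[sim$table$gene_name == sim$truth$tandem_pairs$gene_b[i], ]
    expect_equal(a$chromosome, b$chromosome)
    expect_lt(abs(a$start - b$start), 200000)
  }
  # segmental partners sit on different chromosomes, inside block spans
  for (i in seq_len(nrow(sim$truth$segmental_pairs))) {
    a <- sim$table[sim$table$gene_name == sim$truth$segmental_pairs$gene_a[i], ]
    b <- sim$table[sim$table$gene_name == sim$truth$segmental_pairs$gene_b[i], ]
    expect_false(a$chromosome == b$chromosome)
  }
  # CDS translate cleanly and physchem columns are self-consistent
  expect_identical(unname(vapply(sim$cds, translate_cds, "")),
                   unname(sim$proteins))
  expect_false(any(grepl("\\*", sim$proteins)))
  expect_equal(sim$table$aa_len, unname(nchar(sim$proteins)))
})

test_that("infeasible placements and invalid configs error", {
  cfg <- sim_config(seed = 1,
                    chromosomes = stats::setNames(rep(2000, 3),
                                                  paste0("chr", 1:3)))
  expect_error(simulate_genome(cfg), "infeasible placement")
  cfg2 <- sim_config(seed = 1, family_size = 5)
  expect_error(simulate_genome(cfg2), "family_size too small")
})

test_that("evolve_pair honours target_ks boundaries and determinism", {
  anc <- random_sense_cds(150)
  same <- evolve_pair(anc, omega = 0.5, target_ks = 0, seed = 3)
  expect_identical(same$cds_a, anc)
  expect_identical(same$cds_b, anc)
  ev1 <- evolve_pair(anc, omega = 0.5, target_ks = 0.3, seed = 3)
  ev2 <- evolve_pair(anc, omega = 0.5, target_ks = 0.3, seed = 3)
  expect_identical(ev1, ev2)
  expect_error(evolve_pair(anc, omega = 0.5, target_ks = -1), "target_ks")
  # no stops ever introduced
  expect_false(grepl("\\*", translate_cds(ev1$cds_a)))
  expect_false(grepl("\\*", translate_cds(ev1$cds_b)))
})

test_that("background-only genomes yield no duplicate pairs", {
  cfg <- sim_config(seed = 5,
                    tandem = list(count = 0, size = 3, target_ks = 0.15,
                                  max_spacing = 20000),
                    segmental = list(count = 0, pairs_per_block = 2,
                                     target_ks = 0.5),
                    family_size = 12)
  sim <- simulate_genome(cfg)
  pairs <- find_duplicate_pairs(sim$table, sim$proteins)
  expect_equal(nrow(pairs), 0)
})

test_that("simulated cohorts follow their generating distributions", {
  co <- simulate_cohorts(sim_config(seed = 5))
  expect_named(co, c("control:3", "control:6", "control:9",
                     "treated:3", "treated:6", "treated:9"))
  expect_true(all(vapply(co, function(x) x$n_total, 1) == 30))
  # all-mass-on-a-grade corners
  cfg <- sim_config(seed = 2)
  cfg$cohorts$groups <- list(g = list(`1` = c(`0` = 1), `2` = c(`5` = 1)))
  corners <- simulate_cohorts(cfg)
  expect_equal(ib_index(corners[["g:1"]]), 0)
  expect_equal(ib_index(corners[["g:2"]]), 100)
  # law of large numbers on the multinomial mean (expected index 30)
  cfg2 <- sim_config(seed = 2)
  cfg2$cohorts$n <- 30
  cfg2$cohorts$groups <- list(g = list(`1` = c(`0` = 0.4, `1` = 0.2,
                                               `2` = 0.2, `3` = 0.1,
                                               `4` = 0.06, `5` = 0.04)))
  expected <- (0.2 + 0.4 + 0.3 + 0.24 + 0.2) / 5 * 100  # 26.8
  idx <- vapply(1:400, function(i) {
    cfg2$seed <- i
    ib_index(simulate_cohorts(cfg2)[["g:1"]])
  }, 1)
  expect_lt(abs(mean(idx) - expected), 2)
  # invalid distribution
  bad <- sim_config(seed = 2)
  bad$cohorts$groups <- list(g = list(`1` = c(`0` = 0.5)))
  expect_error(simulate_cohorts(bad), "sum to 1")
})

test_that("written simulation files are readable by the parsers", {
  sim <- cached_sim_genome(7)
  dir <- withr::local_tempdir()
  paths <- write_sim_genome(sim, dir)
  expect_true(all(file.exists(paths)))
  t2 <- load_family_table(paths[["table"]])
  expect_equal(as.data.frame(t2), as.data.frame(sim$table), tolerance = 1e-9)
  gm <- read_gene_models(paths[["gff"]])
  m <- match(sim$table$gene_name, gm$gene_id)
  expect_equal(gm$start[m], sim$table$start)
  expect_equal(gm$exon_count[m], sim$table$exon_count)
  blocks <- read_synteny_blocks(paths[["blocks"]])
  expect_equal(nrow(blocks), nrow(sim$blocks))
  cds <- Biostrings::readDNAStringSet(paths[["cds"]])
  expect_equal(stats::setNames(as.character(cds), names(cds)), sim$cds)
  # spliced CDS really is embedded in the genome sequence
  g1 <- sim$gene_models[sim$gene_models$gene_id == "SimPRX1", ]
  chrom <- sim$genome[[g1$chromosome[1]]]
  spliced <- paste(vapply(seq_len(nrow(g1)), function(e)
    substr(chrom, g1$exon_start[e], g1$exon_end[e]), ""), collapse = "")
  expect_identical(spliced, unname(sim$cds[["SimPRX1"]]))
})
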