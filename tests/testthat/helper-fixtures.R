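# Shared fixtures: the in-repo family characteristics table and printed
# duplicate-pair lists, plus a memoised default synthetic genome so heavy
# simulation runs once per test session.

acprx_table <- function() {
  load_family_table(system.file("extdata", "acprx_family.tsv",
                                package = "famdup"))
}

acprx_pairs <- function(which = c("tandem", "segmental")) {
  which <- match.arg(which)
  utils::read.delim(system.file("extdata",
                                paste0("acprx_", which, "_pairs.tsv"),
                                package = "famdup"),
                    stringsAsFactors = FALSE)
}

.sim_cache <- new.env(parent = emptyenv())

cached_sim_genome <- function(seed = 7) {
  key <- as.character(seed)
  if (is.null(.sim_cache[[key]]))
    .sim_cache[[key]] <- simulate_genome(sim_config(seed = seed))
  .sim_cache[[key]]
}

# small hand-built family table for unit cases
toy_table <- function() {
  family_table(data.frame(
    gene_name = c("g1", "g2", "g3", "g4"),
    accession = c("a1", "a2", "a3", "a4"),
    chromosome = c("chr1", "chr1", "chr1", "chr2"),
    start = c(1000, 150000, 1300000, 5000),
    end = c(2000, 151000, 1301000, 6000),
    orf_len = c(300, 300, 300, 300),
    exon_count = c(2, 3, 2, 4),
    aa_len = c(99, 99, 99, 99),
    mw = c(11, 11, 11, 11),
    pi = c(6, 6, 6, 6),
    stringsAsFactors = FALSE))
}

pair_key <- function(df) paste(df$gene_a, df$gene_b)
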