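# Independent NG86 oracle: recursive pathway enumeration, written without
# the package's precomputed codon tables so the two routes stay separate.

oracle_gc <- Biostrings::GENETIC_CODE

# synonymous sites of one codon, out of 3: fraction of the nine possible
# single-nucleotide changes that are synonymous (stop targets count as
# nonsynonymous opportunities)
oracle_syn_sites <- function(codon) {
  nts <- c("A", "C", "G", "T")
  ch <- strsplit(codon, "")[[1]]
  syn <- 0
  for (pos in 1:3) {
    for (alt in setdiff(nts, ch[pos])) {
      mut <- ch
      mut[pos] <- alt
      if (oracle_gc[[paste(mut, collapse = "")]] == oracle_gc[[codon]] &&
          oracle_gc[[paste(mut, collapse = "")]] != "*")
        syn <- syn + 1
    }
  }
  syn / 3
}

# all single-step mutation paths from codon a to codon b, as (syn, nonsyn)
# step counts; paths through stop codons dropped (unless all are, in which
# case every path is kept)
oracle_paths <- function(a, b, allow_stop = FALSE) {
  if (a == b) return(list(c(0, 0)))
  ch_a <- strsplit(a, "")[[1]]
  ch_b <- strsplit(b, "")[[1]]
  res <- list()
  for (pos in which(ch_a != ch_b)) {
    nxt <- ch_a
    nxt[pos] <- ch_b[pos]
    nxt_codon <- paste(nxt, collapse = "")
    if (oracle_gc[[nxt_codon]] == "*" && !allow_stop) next
    step <- if (oracle_gc[[nxt_codon]] == oracle_gc[[a]]) c(1, 0) else c(0, 1)
    for (tail in oracle_paths(nxt_codon, b, allow_stop))
      res[[length(res) + 1]] <- step + tail
  }
  res
}

oracle_pair_diffs <- function(a, b) {
  paths <- oracle_paths(a, b, allow_stop = FALSE)
  if (!length(paths)) paths <- oracle_paths(a, b, allow_stop = TRUE)
  m <- do.call(rbind, paths)
  c(sd = mean(m[, 1]), nd = mean(m[, 2]))
}

# full oracle NG86 counts for two equal-length ungapped CDS
oracle_ng86_counts <- function(cds_a, cds_b) {
  split3 <- function(x) substring(x, seq(1, nchar(x), 3), seq(3, nchar(x), 3))
  ca <- split3(cds_a); cb <- split3(cds_b)
  s <- (sum(vapply(ca, oracle_syn_sites, 1)) +
          sum(vapply(cb, oracle_syn_sites, 1))) / 2
  d <- rowSums(vapply(seq_along(ca),
                      function(i) oracle_pair_diffs(ca[i], cb[i]),
                      c(sd = 0, nd = 0)))
  list(s_sites = s, n_sites = 3 * length(ca) - s, sd = d[["sd"]], nd = d[["nd"]])
}

sense_codons <- names(oracle_gc)[oracle_gc != "*"]

random_sense_cds <- function(n_codons) {
  paste(sample(sense_codons, n_codons, replace = TRUE), collapse = "")
}
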