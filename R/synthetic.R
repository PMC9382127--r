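# Seeded synthetic inputs with the statistical structure the analysis
# stages assume: a toy multi-chromosome genome carrying a gene family with
# planted tandem clusters and segmental block pairs, codon sequences
# diverged at a chosen omega, FPKM matrices with planted fold changes, and
# graded fruit cohorts. Every generator is deterministic under a fixed
# seed; sub-seeds are derived per component so adding one component never
# perturbs another's draws.

.derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% 2147483629)
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

#' Default synthetic-world configuration
#'
#' The defaults describe the toy scale used throughout the test suite:
#' 3 chromosomes of 1 Mb; a 40-gene family of 300-codon genes comprising 2
#' planted tandem clusters of 3 genes (members diverged to pairwise
#' synonymous distance ~0.15, i.e. >= 85% protein identity), 2 segmental
#' blocks of 2 gene pairs each (pairwise Ks ~0.5) and independent
#' background members; purifying selection at omega 0.2; an expression
#' design with 3 storage timepoints, 3 replicates, 5 genes planted 4-fold
#' up and 5 down, and 20% of genes silent; graded cohorts of 30 fruits
#' emulating a control and a treated group over storage days 3/6/9.
#'
#' @param seed root integer seed.
#' @param ... overrides for any top-level element.
#' @return Config list of class `sim_config`.
#' @export
sim_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = seed,
    chromosomes = stats::setNames(rep(1e6, 3), paste0("chr", 1:3)),
    gene_codons = 300,
    family_size = 40,
    tandem = list(count = 2, size = 3, target_ks = 0.15, max_spacing = 20000),
    segmental = list(count = 2, pairs_per_block = 2, target_ks = 0.5),
    omega = 0.2,
    intergenic = c(min = 5000, max = 40000),
    exon_count_probs = c(`2` = 0.30, `3` = 0.25, `4` = 0.35, `5` = 0.10),
    intron_len = c(min = 80, max = 500),
    expression = list(conditions = c("day0", "day4", "day6"),
                      baseline = "day0", replicates = 3,
                      n_up = 5, n_down = 5, planted_lfc = 2,
                      dropout = 0.2, meanlog = 3, sdlog = 1,
                      noise_sdlog = 0),
    cohorts = list(
      n = 30,
      groups = list(
        control = list(
          `3` = c(`0` = 0.60, `1` = 0.30, `2` = 0.10),
          `6` = c(`1` = 0.20, `2` = 0.40, `3` = 0.30, `4` = 0.10),
          `9` = c(`2` = 0.05, `3` = 0.15, `4` = 0.35, `5` = 0.45)),
        treated = list(
          `3` = c(`0` = 0.85, `1` = 0.15),
          `6` = c(`0` = 0.4667, `1` = 0.3333, `2` = 0.20),
          `9` = c(`0` = 0.20, `1` = 0.30, `2` = 0.30, `3` = 0.12,
                  `4` = 0.05, `5` = 0.03))))
  )
  over <- list(...)
  for (nm in names(over)) cfg[[nm]] <- over[[nm]]
  structure(cfg, class = "sim_config")
}

# random CDS of n codons with no internal stop and a fixed ATG start
.random_cds <- function(n_codons) {
  tb <- .codon_tables()
  sense <- tb$codons[!tb$is_stop]
  paste(c("ATG", sample(sense, n_codons - 1, replace = TRUE)), collapse = "")
}

#' Evolve a diverged CDS pair from an ancestor at a chosen omega
#'
#' Each copy accumulates accepted point substitutions under a uniform
#' proposal process (site and target nucleotide uniform): proposals
#' creating a stop codon are rejected, synonymous changes are accepted with
#' probability 1 and nonsynonymous changes with probability `omega`. A copy
#' stops once its accepted synonymous substitutions reach
#' `target_ks / 2 * S` (S = NG86 synonymous sites of the ancestor), so the
#' pair's expected synonymous divergence is `target_ks`.
#'
#' @param ancestor_cds ungapped CDS without internal stops.
#' @param omega nonsynonymous acceptance probability (> 0).
#' @param target_ks desired pairwise synonymous divergence (>= 0).
#' @param seed integer seed.
#' @return list with `cds_a`, `cds_b` and `truth` (realized synonymous and
#'   nonsynonymous substitution counts per copy).
#' @export
evolve_pair <- function(ancestor_cds, omega, target_ks, seed = 1) {
  if (target_ks < 0) stop("target_ks must be >= 0")
  stopifnot(omega > 0)
  .with_seed(seed, {
    a <- .evolve_copy(ancestor_cds, omega, target_ks / 2)
    b <- .evolve_copy(ancestor_cds, omega, target_ks / 2)
    list(cds_a = a$cds, cds_b = b$cds,
         truth = list(syn_a = a$syn, nonsyn_a = a$nonsyn,
                      syn_b = b$syn, nonsyn_b = b$nonsyn))
  })
}

.evolve_copy <- function(cds, omega, ks_branch) {
  tb <- .codon_tables()
  gc <- Biostrings::GENETIC_CODE
  chars <- strsplit(toupper(cds), "")[[1]]
  L <- length(chars)
  if (L %% 3 != 0) stop("CDS length not a multiple of 3")
  s_sites <- sum(tb$syn_sites[match(
    .split_codons(paste(chars, collapse = "")), tb$codons)])
  target_syn <- round(ks_branch * s_sites)
  syn <- 0L; nonsyn <- 0L
  guard <- 0L
  while (syn < target_syn) {
    guard <- guard + 1L
    if (guard > 1e7) stop("evolve_pair failed to reach target_ks")
    pos <- sample.int(L, 1)
    alt <- sample(setdiff(.nt, chars[pos]), 1)
    ci <- (pos - 1) %/% 3
    old_codon <- paste(chars[(ci * 3 + 1):(ci * 3 + 3)], collapse = "")
    new <- chars[(ci * 3 + 1):(ci * 3 + 3)]
    new[(pos - 1) %% 3 + 1] <- alt
    new_codon <- paste(new, collapse = "")
    aa_old <- gc[[old_codon]]
    aa_new <- gc[[new_codon]]
    if (aa_new == "*") next
    if (aa_old == aa_new) {
      chars[pos] <- alt
      syn <- syn + 1L
    } else if (stats::runif(1) < omega) {
      chars[pos] <- alt
      nonsyn <- nonsyn + 1L
    }
  }
  list(cds = paste(chars, collapse = ""), syn = syn, nonsyn = nonsyn)
}

#' Simulate a toy genome with planted duplications
#'
#' Generates family and truth structures per the configuration: tandem
#' cluster members are placed consecutively on one chromosome within the
#' configured spacing; segmental block pairs on two distinct chromosomes
#' with a matching synteny block record; remaining family members are
#' independent background genes. Gene models get 2-5 exons and the spliced
#' CDS is embedded in the chromosome sequence. Genes are named `SimPRX1..n`
#' by chromosome and position.
#'
#' @param cfg a [sim_config].
#' @return list of class `sim_genome`: `table` ([family_table] with
#'   computed physicochemical columns), `cds`, `proteins` (named vectors),
#'   `genome` (named chromosome sequences), `gene_models` (exon-level
#'   frame), `blocks` (synteny block table), and `truth` (`tandem_pairs`,
#'   `segmental_pairs` frames listing every planted pair).
#' @export
simulate_genome <- function(cfg = sim_config()) {
  .with_seed(.derive_seed(cfg$seed, 1), .simulate_genome_impl(cfg))
}

.simulate_genome_impl <- function(cfg) {
  n_codons <- cfg$gene_codons
  tand <- cfg$tandem; seg <- cfg$segmental
  n_tandem <- tand$count * tand$size
  n_segmental <- seg$count * seg$pairs_per_block * 2
  n_background <- cfg$family_size - n_tandem - n_segmental
  if (n_background < 0)
    stop("family_size too small for the planted structures")

  # --- sequences ------------------------------------------------------
  units <- list()   # placement units: list(genes = named cds, tandem = bool)
  truth_tandem <- list()
  truth_seg <- list()
  useed <- 0L
  for (ci in seq_len(tand$count)) {
    anc <- .random_cds(n_codons)
    members <- character(tand$size)
    for (m in seq_len(tand$size)) {
      useed <- useed + 1L
      members[m] <- .evolve_copy(anc, cfg$omega, tand$target_ks / 2)$cds
    }
    names(members) <- paste0("tclust", ci, "_", seq_len(tand$size))
    units[[length(units) + 1L]] <- list(genes = members, kind = "tandem",
                                        cluster = ci)
    cmb <- utils::combn(names(members), 2)
    truth_tandem[[ci]] <- data.frame(tmp_a = cmb[1, ], tmp_b = cmb[2, ],
                                     stringsAsFactors = FALSE)
  }
  seg_units <- list()
  for (bi in seq_len(seg$count)) {
    pr <- list()
    for (pi in seq_len(seg$pairs_per_block)) {
      anc <- .random_cds(n_codons)
      ev <- list(cds_a = .evolve_copy(anc, cfg$omega, seg$target_ks / 2)$cds,
                 cds_b = .evolve_copy(anc, cfg$omega, seg$target_ks / 2)$cds)
      pr[[pi]] <- ev
    }
    seg_units[[bi]] <- pr
  }
  background <- stats::setNames(
    replicate(n_background, .random_cds(n_codons)),
    paste0("bg", seq_len(max(n_background, 0))))

  # --- placement ------------------------------------------------------
  chroms <- names(cfg$chromosomes)
  cursor <- stats::setNames(rep(1, length(chroms)), chroms)
  placements <- list()  # tmp_name, chrom, start, end, cds, exon structure
  place_gene <- function(tmp_name, cds, chrom, gap) {
    exon_n <- as.integer(sample(names(cfg$exon_count_probs), 1,
                                prob = cfg$exon_count_probs))
    introns <- if (exon_n > 1)
      round(stats::runif(exon_n - 1, cfg$intron_len["min"],
                         cfg$intron_len["max"])) else integer(0)
    span <- nchar(cds) + sum(introns)
    start <- unname(cursor[chrom]) + gap
    end <- start + span - 1
    if (end > cfg$chromosomes[chrom])
      stop("infeasible placement: chromosome ", chrom, " too short")
    cursor[chrom] <<- end + 1
    # split CDS into exon_n pieces (codon-boundary cuts)
    if (exon_n > 1) {
      ncod <- nchar(cds) / 3
      cuts <- sort(sample(seq_len(ncod - 1), exon_n - 1)) * 3
    } else cuts <- integer(0)
    piece_bounds <- cbind(c(1, cuts + 1), c(cuts, nchar(cds)))
    exon_starts <- numeric(exon_n); exon_ends <- numeric(exon_n)
    off <- start
    for (e in seq_len(exon_n)) {
      len <- piece_bounds[e, 2] - piece_bounds[e, 1] + 1
      exon_starts[e] <- off
      exon_ends[e] <- off + len - 1
      off <- exon_ends[e] + 1 + if (e < exon_n) introns[e] else 0
    }
    placements[[length(placements) + 1L]] <<- list(
      tmp_name = tmp_name, chrom = chrom, start = start, end = end,
      cds = cds, exon_starts = exon_starts, exon_ends = exon_ends)
  }
  rand_gap <- function() round(stats::runif(1, cfg$intergenic["min"],
                                            cfg$intergenic["max"]))

  # tandem clusters: all members consecutive within max_spacing
  for (u in units) {
    chrom <- sample(chroms, 1)
    first <- TRUE
    for (g in names(u$genes)) {
      # keep start-to-start distances inside the cluster spacing budget
      # (gene span is ~3*codons + up to 4 introns)
      gap <- if (first) rand_gap() else
        round(stats::runif(1, 200,
                           max(300, tand$max_spacing - 3 * n_codons - 2500)))
      place_gene(g, u$genes[[g]], chrom, gap)
      first <- FALSE
    }
  }
  # segmental blocks: a-side genes consecutive on one chromosome, b-side on
  # another
  block_rows <- list()
  for (bi in seq_along(seg_units)) {
    two <- sample(chroms, 2)
    a_names <- paste0("seg", bi, "a", seq_along(seg_units[[bi]]))
    b_names <- paste0("seg", bi, "b", seq_along(seg_units[[bi]]))
    for (pi in seq_along(seg_units[[bi]]))
      place_gene(a_names[pi], seg_units[[bi]][[pi]]$cds_a, two[1], rand_gap())
    for (pi in seq_along(seg_units[[bi]]))
      place_gene(b_names[pi], seg_units[[bi]][[pi]]$cds_b, two[2], rand_gap())
    block_rows[[bi]] <- data.frame(block_id = paste0("blk", bi),
                                   tmp_a = a_names, tmp_b = b_names,
                                   stringsAsFactors = FALSE)
    truth_seg[[bi]] <- data.frame(tmp_a = a_names, tmp_b = b_names,
                                  stringsAsFactors = FALSE)
  }
  # background genes scattered across chromosomes
  for (g in names(background))
    place_gene(g, background[[g]], sample(chroms, 1), rand_gap())

  # --- naming by chromosomal location, family table, genome -----------
  pl <- placements[order(vapply(placements, `[[`, "", "chrom"),
                         vapply(placements, `[[`, 1, "start"))]
  tmp_names <- vapply(pl, `[[`, "", "tmp_name")
  final <- stats::setNames(paste0("SimPRX", seq_along(pl)), tmp_names)
  cds <- stats::setNames(vapply(pl, `[[`, "", "cds"), final[tmp_names])
  proteins <- vapply(cds, translate_cds, "")
  genome <- lapply(stats::setNames(nm = chroms), function(ch)
    sample(.nt, cfg$chromosomes[ch], replace = TRUE))
  gm_rows <- list()
  tab_rows <- list()
  for (i in seq_along(pl)) {
    p <- pl[[i]]
    nm <- final[[p$tmp_name]]
    # embed spliced CDS into the chromosome
    cdsch <- strsplit(p$cds, "")[[1]]
    off <- 1
    for (e in seq_along(p$exon_starts)) {
      len <- p$exon_ends[e] - p$exon_starts[e] + 1
      genome[[p$chrom]][p$exon_starts[e]:p$exon_ends[e]] <-
        cdsch[off:(off + len - 1)]
      off <- off + len
    }
    gm_rows[[i]] <- data.frame(
      gene_id = nm, chromosome = p$chrom,
      start = p$start, end = p$end, strand = "+",
      exon_start = p$exon_starts, exon_end = p$exon_ends,
      stringsAsFactors = FALSE)
    tab_rows[[i]] <- data.frame(
      gene_name = nm, accession = sprintf("g%04d", i),
      chromosome = p$chrom, start = p$start, end = p$end,
      orf_len = nchar(p$cds), exon_count = length(p$exon_starts),
      aa_len = nchar(proteins[[nm]]),
      mw = protein_mw(proteins[[nm]]),
      pi = isoelectric_point(proteins[[nm]]),
      stringsAsFactors = FALSE)
  }
  table <- family_table(do.call(rbind, tab_rows))
  gene_models <- do.call(rbind, gm_rows)
  genome <- vapply(genome, paste, "", collapse = "")

  rename_pairs <- function(lst) {
    if (!length(lst)) return(duplicate_pairs(character(0), character(0))[0, ])
    df <- do.call(rbind, lst)
    duplicate_pairs(unname(final[df$tmp_a]), unname(final[df$tmp_b]))
  }
  tt <- rename_pairs(truth_tandem)
  if (nrow(tt)) tt$classification <- "tandem"
  ts <- rename_pairs(truth_seg)
  if (nrow(ts)) ts$classification <- "segmental"
  blocks <- do.call(rbind, block_rows)
  gi <- function(nm) match(nm, table$gene_name)
  blocks_tbl <- data.frame(
    block_id = blocks$block_id,
    chrom_a = table$chromosome[gi(final[blocks$tmp_a])],
    start_a = table$start[gi(final[blocks$tmp_a])],
    end_a = table$end[gi(final[blocks$tmp_a])],
    chrom_b = table$chromosome[gi(final[blocks$tmp_b])],
    start_b = table$start[gi(final[blocks$tmp_b])],
    end_b = table$end[gi(final[blocks$tmp_b])],
    gene_a = unname(final[blocks$tmp_a]),
    gene_b = unname(final[blocks$tmp_b]),
    stringsAsFactors = FALSE)
  structure(list(table = table, cds = cds, proteins = proteins,
                 genome = genome, gene_models = gene_models,
                 blocks = blocks_tbl,
                 truth = list(tandem_pairs = tt, segmental_pairs = ts),
                 config = cfg),
            class = "sim_genome")
}

#' Simulate an FPKM expression matrix with planted fold changes
#'
#' Baseline FPKM is drawn log-normally per gene; planted genes get the
#' configured log2 fold change in every non-baseline condition; a
#' configured fraction of genes is silent (FPKM 0 everywhere). With
#' `noise_sdlog = 0` (default) replicates are exact copies, so planted
#' calls are recovered exactly.
#'
#' @param cfg a [sim_config]; `cfg$expression` holds the design.
#' @param genes optional gene names (default `SimPRX1..family_size`).
#' @return list of class `sim_expression`: `matrix` (an
#'   [expression_matrix]) and `truth` (per-gene intended call and planted
#'   log2 fold change).
#' @export
simulate_expression <- function(cfg = sim_config(), genes = NULL) {
  ex <- cfg$expression
  if (is.null(genes)) genes <- paste0("SimPRX", seq_len(cfg$family_size))
  .with_seed(.derive_seed(cfg$seed, 2), {
    ng <- length(genes)
    base <- stats::rlnorm(ng, ex$meanlog, ex$sdlog)
    lfc <- stats::setNames(rep(0, ng), genes)
    free <- seq_len(ng)
    silent <- sort(sample(free, round(ex$dropout * ng)))
    free <- setdiff(free, silent)
    up <- sort(sample(free, min(ex$n_up, length(free))))
    free <- setdiff(free, up)
    down <- sort(sample(free, min(ex$n_down, length(free))))
    lfc[up] <- ex$planted_lfc
    lfc[down] <- -ex$planted_lfc
    conds <- ex$conditions
    cols <- list(); meta <- list()
    for (cc in conds) for (r in seq_len(ex$replicates)) {
      v <- base
      if (cc != ex$baseline) v <- base * 2^lfc
      if (ex$noise_sdlog > 0) v <- v * stats::rlnorm(ng, 0, ex$noise_sdlog)
      v[silent] <- 0
      snm <- paste0(cc, "_r", r)
      cols[[snm]] <- v
      meta[[snm]] <- data.frame(sample = snm, condition = cc, replicate = r,
                                stringsAsFactors = FALSE)
    }
    m <- do.call(cbind, cols)
    rownames(m) <- genes
    truth <- data.frame(
      gene = genes,
      call = ifelse(seq_len(ng) %in% silent, "not_expressed",
             ifelse(lfc > 0, "up", ifelse(lfc < 0, "down", "unchanged"))),
      planted_lfc = unname(lfc),
      stringsAsFactors = FALSE)
    structure(list(matrix = expression_matrix(m, do.call(rbind, meta)),
                   truth = truth, config = cfg),
              class = "sim_expression")
  })
}

#' Simulate graded internal-browning cohorts
#'
#' Draws multinomial per-grade fruit counts for every group x day in the
#' configuration.
#'
#' @param cfg a [sim_config]; `cfg$cohorts` holds cohort size and the
#'   grade distribution per group and day (each must sum to 1).
#' @return list of [ib_cohort] objects named `group:day`, with the
#'   expected index of each generating distribution in attribute
#'   `expected_index`.
#' @export
simulate_cohorts <- function(cfg = sim_config()) {
  co <- cfg$cohorts
  .with_seed(.derive_seed(cfg$seed, 3), {
    out <- list(); expected <- numeric(0)
    for (grp in names(co$groups)) for (dy in names(co$groups[[grp]])) {
      p <- co$groups[[grp]][[dy]]
      if (abs(sum(p) - 1) > 1e-6)
        stop("grade distribution for ", grp, " day ", dy, " must sum to 1")
      grades <- as.integer(names(p))
      if (any(grades < 0 | grades > 5)) stop("grades must be 0-5")
      draw <- stats::rmultinom(1, co$n, p)[, 1]
      key <- paste(grp, dy, sep = ":")
      out[[key]] <- ib_cohort(stats::setNames(draw, names(p)),
                              group = grp, day = as.numeric(dy))
      expected[key] <- sum(grades * p) / 5 * 100
    }
    attr(out, "expected_index") <- expected
    out
  })
}

#' Write simulated genome outputs to standard-format files
#'
#' Writes the family table (TSV), CDS and protein FASTA, genome FASTA,
#' GFF3 gene models, synteny block table and truth tables into `dir`.
#'
#' @param sim a `sim_genome` from [simulate_genome()].
#' @param dir output directory (created if needed).
#' @return Named vector of file paths, invisibly.
#' @export
write_sim_genome <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(table = file.path(dir, "family.tsv"),
             cds = file.path(dir, "cds.fa"),
             proteins = file.path(dir, "proteins.fa"),
             genome = file.path(dir, "genome.fa"),
             gff = file.path(dir, "genes.gff3"),
             blocks = file.path(dir, "blocks.tsv"),
             truth_tandem = file.path(dir, "truth_tandem.tsv"),
             truth_segmental = file.path(dir, "truth_segmental.tsv"))
  write_family_table(sim$table, paths["table"])
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sim$cds), paths["cds"])
  Biostrings::writeXStringSet(Biostrings::AAStringSet(sim$proteins),
                              paths["proteins"])
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sim$genome),
                              paths["genome"])
  write_gene_models_gff3(sim$gene_models, paths["gff"])
  utils::write.table(sim$blocks, paths["blocks"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sim$truth$tandem_pairs, paths["truth_tandem"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$segmental_pairs, paths["truth_segmental"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Write gene models to GFF3
#'
#' Emits gene, mRNA and exon features (one mRNA per gene) via rtracklayer.
#'
#' @param gene_models exon-level frame with `gene_id`, `chromosome`,
#'   `start`, `end`, `strand`, `exon_start`, `exon_end`.
#' @param path output GFF3 path.
#' @return `path`, invisibly.
#' @export
write_gene_models_gff3 <- function(gene_models, path) {
  genes <- unique(gene_models[, c("gene_id", "chromosome", "start", "end",
                                  "strand")])
  feats <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    ex <- gene_models[gene_models$gene_id == g$gene_id, , drop = FALSE]
    feats[[length(feats) + 1L]] <- data.frame(
      seqnames = g$chromosome, start = g$start, end = g$end,
      strand = g$strand, type = "gene", ID = g$gene_id, Parent = NA,
      stringsAsFactors = FALSE)
    mrna_id <- paste0(g$gene_id, ".t1")
    feats[[length(feats) + 1L]] <- data.frame(
      seqnames = g$chromosome, start = g$start, end = g$end,
      strand = g$strand, type = "mRNA", ID = mrna_id, Parent = g$gene_id,
      stringsAsFactors = FALSE)
    for (e in seq_len(nrow(ex)))
      feats[[length(feats) + 1L]] <- data.frame(
        seqnames = g$chromosome, start = ex$exon_start[e],
        end = ex$exon_end[e], strand = g$strand, type = "exon",
        ID = paste0(mrna_id, ".exon", e), Parent = mrna_id,
        stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, feats)
  gr <- GenomicRanges::GRanges(
    seqnames = df$seqnames,
    ranges = IRanges::IRanges(df$start, df$end),
    strand = df$strand, type = df$type, ID = df$ID)
  gr$Parent <- IRanges::CharacterList(
    lapply(df$Parent, function(p) if (is.na(p)) character(0) else p))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
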