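# Canonical column set of a family table. Coordinates are 1-based inclusive
# throughout the package, the convention shared by GFF3, IRanges/GRanges and
# the published characteristics tables this loader consumes.
.family_cols <- c("gene_name", "accession", "chromosome", "start", "end",
                  "orf_len", "exon_count", "aa_len", "mw", "pi")

# Header aliases accepted on input (lower-cased, punctuation stripped).
.family_aliases <- list(
  gene_name  = c("gene_name", "name", "gene"),
  accession  = c("accession", "gene_id", "geneid", "id"),
  chromosome = c("chromosome", "chr", "chrom", "lg"),
  orf_len    = c("orf_len", "orf", "orflength"),
  exon_count = c("exon_count", "exon", "exons"),
  aa_len     = c("aa_len", "aa", "aalength", "length"),
  mw         = c("mw", "mwkda", "molecularweight"),
  pi         = c("pi", "theoreticalpi", "isoelectricpoint")
)

.norm_header <- function(x) gsub("[^a-z0-9_]", "", tolower(x))

# Strip thousands separators and parse a numeric cell, erroring with the
# row/column location on failure.
.parse_num <- function(x, row, col, integer = FALSE) {
  v <- gsub("[, ]", "", as.character(x))
  out <- suppressWarnings(as.numeric(v))
  bad <- which(is.na(out) & !is.na(v) & nzchar(v))
  if (length(bad) || anyNA(out))
    stop(sprintf("unparseable numeric value '%s' in column '%s', row %d",
                 as.character(x)[c(bad, which(is.na(out)))[1]], col,
                 row[c(bad, which(is.na(out)))[1]]), call. = FALSE)
  if (integer) out <- as.integer(round(out))
  out
}

#' Construct and validate a gene-family characteristics table
#'
#' A family table holds one row per family member with its genomic
#' coordinates, gene-model structure and protein physicochemical
#' descriptors: `gene_name` (short family label, e.g. `AcPRX1`),
#' `accession` (genome gene id, e.g. `Aco006655`), `chromosome`,
#' `start`/`end` (1-based inclusive bp), `orf_len` (nt), `exon_count`,
#' `aa_len` (residues), `mw` (kDa) and `pi`.
#'
#' @param df data.frame carrying the columns above.
#' @return The validated data.frame with class `family_table`.
#' @export
family_table <- function(df) {
  stopifnot(is.data.frame(df))
  missing <- setdiff(.family_cols, names(df))
  if (length(missing))
    stop("family table is missing column(s): ", paste(missing, collapse = ", "))
  df <- df[, .family_cols]
  if (anyDuplicated(df$gene_name))
    stop("duplicate gene_name: ",
         paste(unique(df$gene_name[duplicated(df$gene_name)]), collapse = ", "))
  if (anyDuplicated(df$accession))
    stop("duplicate accession: ",
         paste(unique(df$accession[duplicated(df$accession)]), collapse = ", "))
  bad <- which(df$start > df$end)
  if (length(bad))
    stop(sprintf("start > end for gene %s (row %d)", df$gene_name[bad[1]], bad[1]))
  if (any(df$exon_count < 1)) stop("exon_count must be >= 1")
  if (any(df$aa_len < 1)) stop("aa_len must be >= 1")
  if (any(df$mw <= 0)) stop("mw must be positive")
  if (any(df$pi <= 0 | df$pi >= 14)) stop("pi must lie in (0, 14)")
  rownames(df) <- NULL
  class(df) <- c("family_table", "data.frame")
  df
}

#' Load a family characteristics table from a delimited file
#'
#' Reads a tab-separated table with one row per gene. Coordinates may be
#' given either as `start`/`end` columns or as a single `genomic_location`
#' column written `start-end` (hyphen or en dash); thousands separators in
#' numeric cells are accepted.
#'
#' @param path path to a tab-separated file with a header row.
#' @return A [family_table] data.frame.
#' @examples
#' tab <- load_family_table(system.file("extdata", "acprx_family.tsv",
#'                                      package = "famdup"))
#' nrow(tab)  # 78
#' @export
load_family_table <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  names(raw) <- .norm_header(names(raw))
  out <- list()
  for (col in names(.family_aliases)) {
    hit <- intersect(.family_aliases[[col]], names(raw))
    if (length(hit)) out[[col]] <- raw[[hit[1]]]
  }
  n <- nrow(raw)
  rows <- seq_len(n)
  if (all(c("start", "end") %in% names(raw))) {
    start <- .parse_num(raw$start, rows, "start", integer = TRUE)
    end <- .parse_num(raw$end, rows, "end", integer = TRUE)
  } else {
    loc <- intersect(c("genomic_location", "genomiclocation", "location"),
                     names(raw))
    if (!length(loc))
      stop("no coordinate columns found (need start/end or genomic_location)")
    parts <- strsplit(raw[[loc[1]]], "–|—|-")
    if (any(lengths(parts) != 2))
      stop(sprintf("unparseable genomic location '%s' in row %d",
                   raw[[loc[1]]][which(lengths(parts) != 2)[1]],
                   which(lengths(parts) != 2)[1]))
    start <- .parse_num(vapply(parts, `[`, "", 1), rows, "genomic_location",
                        integer = TRUE)
    end <- .parse_num(vapply(parts, `[`, "", 2), rows, "genomic_location",
                      integer = TRUE)
  }
  req <- c("gene_name", "accession", "chromosome")
  miss <- setdiff(req, names(out))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  df <- data.frame(
    gene_name = out$gene_name,
    accession = out$accession,
    chromosome = out$chromosome,
    start = start,
    end = end,
    orf_len = .parse_num(out$orf_len, rows, "orf", integer = TRUE),
    exon_count = .parse_num(out$exon_count, rows, "exon", integer = TRUE),
    aa_len = .parse_num(out$aa_len, rows, "aa", integer = TRUE),
    mw = .parse_num(out$mw, rows, "mw"),
    pi = .parse_num(out$pi, rows, "pi"),
    stringsAsFactors = FALSE
  )
  family_table(df)
}

#' Write a family table to a tab-separated file
#'
#' Round-trips with [load_family_table()]: the written file parses back to
#' an identical record set.
#'
#' @param table a [family_table].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_family_table <- function(table, path) {
  table <- family_table(as.data.frame(table))
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Screen candidate homolog hits by E-value and percent identity
#'
#' Applies the family-identification screen: homology-search hits are kept
#' when `evalue <= evalue_max` (inclusive) and `identity_pct >
#' identity_min_pct` (strict, matching the published ">50% identity"
#' wording); keyword-search hits bypass the numeric filter. The union is
#' deduplicated by subject id, emulating the removal of redundant sequences
#' before domain verification.
#'
#' @param hits data.frame with columns `query_id`, `subject_id`, `evalue`,
#'   `identity_pct` and `source` (`"homology_search"` or `"keyword"`).
#' @param evalue_max inclusive E-value ceiling (default `1e-5`).
#' @param identity_min_pct exclusive identity floor in percent (default 50).
#' @return Sorted character vector of unique retained subject ids.
#' @export
filter_candidates <- function(hits, evalue_max = 1e-5, identity_min_pct = 50) {
  stopifnot(evalue_max > 0, identity_min_pct > 0)
  if (is.null(hits) || nrow(hits) == 0) return(character(0))
  req <- c("subject_id", "evalue", "identity_pct", "source")
  miss <- setdiff(req, names(hits))
  if (length(miss)) stop("hits missing column(s): ", paste(miss, collapse = ", "))
  if (any(hits$evalue < 0)) stop("negative evalue")
  if (any(hits$identity_pct < 0 | hits$identity_pct > 100))
    stop("identity_pct outside [0, 100]")
  keep_hom <- hits$source == "homology_search" &
    hits$evalue <= evalue_max & hits$identity_pct > identity_min_pct
  keep_kw <- hits$source == "keyword"
  sort(unique(hits$subject_id[keep_hom | keep_kw]))
}

#' Read a 12-column BLAST tabular hit file
#'
#' Parses the standard `-outfmt 6` dialect (qseqid sseqid pident length
#' mismatch gapopen qstart qend sstart send evalue bitscore) into the
#' candidate-hit frame consumed by [filter_candidates()].
#'
#' @param path path to the tabular file (no header).
#' @param source hit provenance label, default `"homology_search"`.
#' @return data.frame with columns `query_id`, `subject_id`, `evalue`,
#'   `identity_pct`, `source`.
#' @export
read_blast_tab <- function(path, source = "homology_search") {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  x <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(x) < 12) stop("expected 12 BLAST tabular columns, got ", ncol(x))
  names(x)[1:12] <- cols
  data.frame(query_id = x$qseqid, subject_id = x$sseqid,
             evalue = as.numeric(x$evalue), identity_pct = as.numeric(x$pident),
             source = source, stringsAsFactors = FALSE)
}

#' Round half away from zero
#'
#' The rounding convention behind printed percentages such as `11.54%`
#' (base R's `round()` rounds half to even).
#'
#' @param x numeric vector.
#' @param digits decimal places (default 2).
#' @return Rounded vector.
#' @export
round_half_away <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Exon-count histogram of a family table
#'
#' Tabulates genes by exon count, with a companion view keyed by intron
#' count (`exon_count - 1`) and percentages of the family total rounded to
#' two decimals (half away from zero).
#'
#' @param table a [family_table].
#' @return list with `counts` (named by exon count), `intron_counts`,
#'   `total`, and `percentages`.
#' @export
exon_histogram <- function(table) {
  if (nrow(table) == 0) stop("empty family table")
  if (any(table$exon_count < 1)) stop("exon_count must be >= 1")
  tab <- table(table$exon_count)
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  intron <- counts
  names(intron) <- as.character(as.integer(names(tab)) - 1L)
  list(counts = counts,
       intron_counts = intron,
       total = nrow(table),
       percentages = round_half_away(100 * counts / nrow(table), 2))
}

# ExPASy-style average residue masses (Da) for the 20 standard amino acids.
.aa_masses <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
.water_mass <- 18.01524

#' Protein molecular weight from sequence
#'
#' Sum of average (not monoisotopic) residue masses plus one water, in
#' kilodaltons, for an unmodified chain. `X` is tolerated and assigned the
#' unweighted mean of the 20 standard residue masses.
#'
#' @param sequence amino-acid string (single-letter codes).
#' @return Mass in kDa.
#' @examples
#' protein_mw("AA")  # 0.1601729
#' @export
protein_mw <- function(sequence) {
  if (length(sequence) != 1 || is.na(sequence) || !nzchar(sequence))
    stop("empty protein sequence")
  aa <- strsplit(toupper(sequence), "")[[1]]
  masses <- c(.aa_masses, X = mean(.aa_masses))
  bad <- which(!aa %in% names(masses))
  if (length(bad))
    stop(sprintf("illegal amino-acid character '%s' at position %d",
                 aa[bad[1]], bad[1]))
  (sum(masses[aa]) + .water_mass) / 1000
}

#' EMBOSS-style pKa table for isoelectric-point calculation
#'
#' Named vector of pKa values for the ionizable groups used by
#' [isoelectric_point()]: the termini plus C, D, E, H, K, R, Y side chains.
#'
#' @return Named numeric vector.
#' @export
pka_table <- function() {
  c(Nterm = 8.6, Cterm = 3.6, C = 8.5, D = 3.9, E = 4.1,
    H = 6.5, K = 10.8, R = 12.5, Y = 10.1)
}

# Net protein charge at a given pH under Henderson-Hasselbalch.
.net_charge <- function(pH, counts, pka) {
  pos_groups <- c("Nterm", "H", "K", "R")
  neg_groups <- c("Cterm", "C", "D", "E", "Y")
  pos <- sum(counts[pos_groups] / (1 + 10^(pH - pka[pos_groups])))
  neg <- sum(counts[neg_groups] / (1 + 10^(pka[neg_groups] - pH)))
  pos - neg
}

#' Theoretical isoelectric point of a protein
#'
#' Finds the pH at which the Henderson-Hasselbalch net charge over the
#' N-terminus, C-terminus and D/E/C/Y/H/K/R side chains is zero, by
#' bisection on \[0, 14\] to within `tol`. The net-charge function is
#' strictly decreasing in pH, so the root is unique.
#'
#' @param sequence amino-acid string.
#' @param pka named pKa vector as returned by [pka_table()]; entries may be
#'   overridden to emulate other published sets.
#' @param tol bisection tolerance in pH units (default `1e-3`).
#' @return pH of zero net charge.
#' @export
isoelectric_point <- function(sequence, pka = pka_table(), tol = 1e-3) {
  if (length(sequence) != 1 || is.na(sequence) || !nzchar(sequence))
    stop("empty protein sequence")
  aa <- strsplit(toupper(sequence), "")[[1]]
  bad <- which(!aa %in% c(names(.aa_masses), "X"))
  if (length(bad))
    stop(sprintf("illegal amino-acid character '%s' at position %d",
                 aa[bad[1]], bad[1]))
  counts <- c(Nterm = 1, Cterm = 1,
              vapply(c("C", "D", "E", "H", "K", "R", "Y"),
                     function(g) sum(aa == g), numeric(1)))
  lo <- 0; hi <- 14
  while (hi - lo > tol / 2) {
    mid <- (lo + hi) / 2
    if (.net_charge(mid, counts, pka) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Extremes of a family-table column with the genes attaining them
#'
#' @param table a [family_table].
#' @param column one of `"aa_len"`, `"mw"`, `"pi"`.
#' @return list with `min`, `min_gene`, `max`, `max_gene`; ties broken by
#'   first occurrence in table order.
#' @export
range_summary <- function(table, column = c("aa_len", "mw", "pi")) {
  column <- match.arg(column)
  if (nrow(table) == 0) stop("empty family table")
  v <- table[[column]]
  i_min <- which.min(v)
  i_max <- which.max(v)
  list(min = v[i_min], min_gene = table$gene_name[i_min],
       max = v[i_max], max_gene = table$gene_name[i_max])
}

#' Read gene models from a GFF3 file
#'
#' Imports gene/mRNA/exon/CDS features via rtracklayer and summarizes one
#' row per gene: chromosome, genomic span (1-based inclusive), strand and
#' exon count.
#'
#' @param path GFF3 file path.
#' @return data.frame with columns `gene_id`, `chromosome`, `start`, `end`,
#'   `strand`, `exon_count`, sorted by chromosome then start.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  genes <- gr[gr$type == "gene"]
  if (!length(genes)) stop("no gene features in ", path)
  exons <- gr[gr$type == "exon"]
  gid <- as.character(genes$ID)
  # exon Parent points at the mRNA; mRNA Parent at the gene
  mrna <- gr[gr$type == "mRNA"]
  mrna_parent <- vapply(mrna$Parent, function(p) as.character(p)[1], "")
  names(mrna_parent) <- as.character(mrna$ID)
  exon_parent <- vapply(exons$Parent, function(p) as.character(p)[1], "")
  exon_gene <- ifelse(exon_parent %in% names(mrna_parent),
                      mrna_parent[exon_parent], exon_parent)
  exon_n <- table(factor(exon_gene, levels = gid))
  out <- data.frame(
    gene_id = gid,
    chromosome = as.character(GenomicRanges::seqnames(genes)),
    start = GenomicRanges::start(genes),
    end = GenomicRanges::end(genes),
    strand = as.character(GenomicRanges::strand(genes)),
    exon_count = as.integer(exon_n),
    stringsAsFactors = FALSE
  )
  out[order(out$chromosome, out$start), , drop = FALSE]
}

#' Physicochemical property table for a set of protein sequences
#'
#' @param proteins named character vector or `Biostrings::AAStringSet`.
#' @return data.frame with `gene_name`, `aa_len`, `mw` (kDa), `pi`.
#' @export
physchem_table <- function(proteins) {
  proteins <- as_protein_vector(proteins)
  data.frame(
    gene_name = names(proteins),
    aa_len = nchar(proteins),
    mw = vapply(proteins, protein_mw, numeric(1)),
    pi = vapply(proteins, isoelectric_point, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

# Accept either a named character vector or an (AA)StringSet.
as_protein_vector <- function(x) {
  if (methods::is(x, "XStringSet")) x <- as.character(x)
  if (!is.character(x) || is.null(names(x)) || any(!nzchar(names(x))))
    stop("proteins must be a named character vector or named AAStringSet")
  x
}
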