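# Duplicate-pair detection and tandem/segmental classification.
#
# A pair of family members counts as a duplication event when (1) the
# global-alignment similarity between the longer and the shorter protein
# exceeds 70% and (2) the shorter protein is more than 70% of the longer
# protein's length. Tandem status is decided by chromosomal proximity,
# segmental status by membership in synteny/collinearity blocks; tandem
# takes precedence so the classes stay disjoint.

# Canonical unordered pair ordering: gene_a < gene_b lexicographically.
.canon_pairs <- function(a, b) {
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  data.frame(gene_a = a, gene_b = b, stringsAsFactors = FALSE)
}

#' Global-alignment identity between two protein sequences
#'
#' Needleman-Wunsch global alignment (Biostrings, BLOSUM62, affine gaps)
#' with identity defined as exact matches divided by the length of the
#' shorter input sequence, mirroring "similarity between the longer and the
#' shorter sequence".
#'
#' @param seq_a,seq_b amino-acid strings.
#' @param substitution_matrix scoring matrix name (default `"BLOSUM62"`).
#' @param gap_opening,gap_extension affine gap penalties (defaults 10, 0.5).
#' @return Identity fraction in \[0, 1\].
#' @export
global_identity <- function(seq_a, seq_b, substitution_matrix = "BLOSUM62",
                            gap_opening = 10, gap_extension = 0.5) {
  if (!nzchar(seq_a) || !nzchar(seq_b)) stop("empty sequence")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    type = "global", substitutionMatrix = substitution_matrix,
    gapOpening = gap_opening, gapExtension = gap_extension)
  Biostrings::nmatch(aln) / min(nchar(seq_a), nchar(seq_b))
}

#' Detect duplicate gene pairs in a family
#'
#' Scans all unordered pairs and keeps those satisfying both strict
#' criteria: alignment identity > `identity_min` and length ratio
#' (shorter aa length / longer aa length) > `ratio_min`. The cheap length
#' filter runs first so only surviving pairs are aligned.
#'
#' @param table a [family_table]; only `gene_name` and `aa_len` are used.
#' @param proteins named protein sequences covering every `gene_name`.
#' @param identity_min strict identity floor as a fraction (default 0.70).
#' @param ratio_min strict length-ratio floor (default 0.70).
#' @param ... passed to [global_identity()].
#' @return data.frame of class `duplicate_pairs` with columns `gene_a`,
#'   `gene_b` (canonically ordered), `identity`, `length_ratio`,
#'   `classification` (initially `"unclassified"`).
#' @export
find_duplicate_pairs <- function(table, proteins, identity_min = 0.70,
                                 ratio_min = 0.70, ...) {
  proteins <- as_protein_vector(proteins)
  missing <- setdiff(table$gene_name, names(proteins))
  if (length(missing))
    stop("missing protein sequence for: ", paste(missing, collapse = ", "))
  genes <- table$gene_name
  lens <- nchar(proteins[genes])
  out <- list()
  if (length(genes) >= 2) {
    idx <- utils::combn(seq_along(genes), 2)
    ratio <- pmin(lens[idx[1, ]], lens[idx[2, ]]) /
      pmax(lens[idx[1, ]], lens[idx[2, ]])
    cand <- which(ratio > ratio_min)
    # batch alignments: all partners of gene j in one vectorized call
    extra <- list(...)
    sm <- if (!is.null(extra$substitution_matrix)) extra$substitution_matrix
      else "BLOSUM62"
    go <- if (!is.null(extra$gap_opening)) extra$gap_opening else 10
    ge <- if (!is.null(extra$gap_extension)) extra$gap_extension else 0.5
    for (j in unique(idx[2, cand])) {
      ii <- idx[1, cand[idx[2, cand] == j]]
      pats <- Biostrings::AAStringSet(unname(proteins[genes[ii]]))
      aln <- Biostrings::pairwiseAlignment(
        pats, Biostrings::AAString(proteins[[genes[j]]]), type = "global",
        substitutionMatrix = sm, gapOpening = go, gapExtension = ge)
      ident <- Biostrings::nmatch(aln) / pmin(lens[genes[ii]], lens[genes[j]])
      sel <- ident > identity_min
      if (any(sel))
        out[[length(out) + 1L]] <- data.frame(
          gene_a = genes[ii[sel]], gene_b = genes[j],
          identity = unname(ident[sel]),
          length_ratio = unname(pmin(lens[genes[ii[sel]]], lens[genes[j]]) /
                                  pmax(lens[genes[ii[sel]]], lens[genes[j]])),
          stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    res <- data.frame(gene_a = character(0), gene_b = character(0),
                      identity = numeric(0), length_ratio = numeric(0),
                      stringsAsFactors = FALSE)
  } else {
    res <- do.call(rbind, out)
    cp <- .canon_pairs(res$gene_a, res$gene_b)
    res$gene_a <- cp$gene_a; res$gene_b <- cp$gene_b
    res <- res[order(res$gene_a, res$gene_b), , drop = FALSE]
  }
  res$classification <- rep("unclassified", nrow(res))
  rownames(res) <- NULL
  class(res) <- c("duplicate_pairs", "data.frame")
  res
}

#' Assemble a duplicate-pair frame from an explicit pair list
#'
#' Convenience constructor for pair lists given directly (for instance a
#' published table of duplication events) rather than detected from
#' sequences.
#'
#' @param gene_a,gene_b character vectors of gene names.
#' @param identity,length_ratio optional numeric vectors (default `NA`).
#' @return A `duplicate_pairs` data.frame with canonical pair ordering.
#' @export
duplicate_pairs <- function(gene_a, gene_b, identity = NA_real_,
                            length_ratio = NA_real_) {
  if (any(gene_a == gene_b)) stop("self-pairing is not allowed")
  cp <- .canon_pairs(gene_a, gene_b)
  n <- nrow(cp)
  res <- data.frame(cp, identity = rep_len(identity, n),
                    length_ratio = rep_len(length_ratio, n),
                    classification = rep_len("unclassified", n),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(paste(res$gene_a, res$gene_b)))
    stop("duplicated pairs in input")
  res <- res[order(res$gene_a, res$gene_b), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("duplicate_pairs", "data.frame")
  res
}

.pair_coords <- function(pairs, table, cols = c("chromosome", "start")) {
  m_a <- match(pairs$gene_a, table$gene_name)
  m_b <- match(pairs$gene_b, table$gene_name)
  bad <- c(pairs$gene_a[is.na(m_a)], pairs$gene_b[is.na(m_b)])
  if (length(bad))
    stop("pair gene(s) missing from family table: ",
         paste(unique(bad), collapse = ", "))
  list(a = table[m_a, , drop = FALSE], b = table[m_b, , drop = FALSE])
}

#' Classify duplicate pairs as tandem duplications
#'
#' Two proximity rules are provided. `span_200kb` (default): tandem iff the
#' genes share a chromosome and their start-to-start distance is strictly
#' below 200,000 bp. `window_100kb_5genes`: tandem iff same chromosome, at
#' most five intervening genes in the full chromosome gene order, and
#' start-to-start distance strictly below 100,000 bp; this rule requires
#' `all_genes`, the complete gene order of the genome (e.g. from
#' [read_gene_models()], matched by `gene_id` against the table's
#' `accession`, or any frame with `gene_name`/`chromosome`/`start`).
#'
#' @param pairs a `duplicate_pairs` frame.
#' @param table a [family_table] supplying coordinates.
#' @param rule `"span_200kb"` or `"window_100kb_5genes"`.
#' @param all_genes full gene order (required for the window rule).
#' @param max_span window size in bp; defaults to the rule's published value.
#' @param max_intervening maximum intervening genes for the window rule.
#' @return `pairs` with `classification` set to `"tandem"` where the rule
#'   holds; other rows keep their previous classification.
#' @export
classify_tandem <- function(pairs, table,
                            rule = c("span_200kb", "window_100kb_5genes"),
                            all_genes = NULL, max_span = NULL,
                            max_intervening = 5) {
  rule <- match.arg(rule)
  if (!nrow(pairs)) return(pairs)
  if (is.null(max_span))
    max_span <- if (rule == "span_200kb") 200000 else 100000
  cc <- .pair_coords(pairs, table)
  same_chr <- cc$a$chromosome == cc$b$chromosome
  dist <- abs(cc$a$start - cc$b$start)
  tandem <- same_chr & dist < max_span
  if (rule == "window_100kb_5genes") {
    if (is.null(all_genes))
      stop("rule 'window_100kb_5genes' requires all_genes (full gene order)")
    key <- if ("gene_name" %in% names(all_genes)) "gene_name" else "gene_id"
    ord <- all_genes[order(all_genes$chromosome, all_genes$start), ,
                     drop = FALSE]
    rank <- seq_len(nrow(ord))
    names(rank) <- ord[[key]]
    # match family gene_name via accession when the order uses genome ids
    nm_a <- if (all(pairs$gene_a %in% names(rank))) pairs$gene_a else
      cc$a$accession
    nm_b <- if (all(pairs$gene_b %in% names(rank))) pairs$gene_b else
      cc$b$accession
    if (any(!c(nm_a, nm_b) %in% names(rank)))
      stop("pair gene(s) missing from all_genes gene order")
    interv <- abs(rank[nm_a] - rank[nm_b]) - 1L
    tandem <- tandem & interv <= max_intervening
  }
  pairs$classification[tandem] <- "tandem"
  pairs
}

#' Read a synteny/collinearity block table
#'
#' Tab-separated with header columns `block_id`, `chrom_a`, `start_a`,
#' `end_a`, `chrom_b`, `start_b`, `end_b`, `gene_a`, `gene_b`; one row per
#' recorded member pair of a block.
#'
#' @param path file path.
#' @return data.frame of block records.
#' @export
read_synteny_blocks <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("block_id", "chrom_a", "start_a", "end_a", "chrom_b", "start_b",
           "end_b", "gene_a", "gene_b")
  miss <- setdiff(req, names(x))
  if (length(miss)) stop("block table missing: ", paste(miss, collapse = ", "))
  bad <- which(x$start_a > x$end_a | x$start_b > x$end_b)
  if (length(bad)) stop("malformed block span in row ", bad[1])
  x
}

#' Classify non-tandem duplicate pairs as segmental duplications
#'
#' A duplicate pair not already classified tandem becomes segmental when it
#' is recorded as a member pair of a synteny block (either orientation), or
#' when its two genes fall inside the paired spans of one block. Tandem
#' classifications are never overwritten, keeping the classes disjoint.
#'
#' @param pairs a `duplicate_pairs` frame (tandem already assigned).
#' @param blocks block table as from [read_synteny_blocks()]; may have zero
#'   rows.
#' @param table optional [family_table] with coordinates, needed only for
#'   the span-containment route.
#' @return `pairs` with `classification` updated to `"segmental"` where a
#'   block supports the pair.
#' @export
classify_segmental <- function(pairs, blocks, table = NULL) {
  if (!nrow(pairs) || is.null(blocks) || !nrow(blocks)) return(pairs)
  key <- paste(pairs$gene_a, pairs$gene_b)
  bk1 <- paste(blocks$gene_a, blocks$gene_b)
  bk2 <- paste(blocks$gene_b, blocks$gene_a)
  hit <- key %in% c(bk1, bk2)
  if (!is.null(table)) {
    cc <- .pair_coords(pairs, table)
    for (i in which(!hit)) {
      in_a <- cc$a$chromosome[i] == blocks$chrom_a &
        cc$a$start[i] >= blocks$start_a & cc$a$end[i] <= blocks$end_a
      in_b <- cc$b$chromosome[i] == blocks$chrom_b &
        cc$b$start[i] >= blocks$start_b & cc$b$end[i] <= blocks$end_b
      in_a2 <- cc$b$chromosome[i] == blocks$chrom_a &
        cc$b$start[i] >= blocks$start_a & cc$b$end[i] <= blocks$end_a
      in_b2 <- cc$a$chromosome[i] == blocks$chrom_b &
        cc$a$start[i] >= blocks$start_b & cc$a$end[i] <= blocks$end_b
      hit[i] <- any((in_a & in_b) | (in_a2 & in_b2))
    }
  }
  upd <- hit & pairs$classification != "tandem"
  pairs$classification[upd] <- "segmental"
  pairs
}

#' Summarize classified duplication events
#'
#' @param pairs a classified `duplicate_pairs` frame.
#' @param table optional [family_table]; when given, the number of distinct
#'   chromosomes bearing at least one tandem pair is reported.
#' @return list with `tandem_pairs`, `segmental_pairs`, `tandem_genes`,
#'   `segmental_genes`, and `tandem_chromosomes` (NA without `table`).
#' @export
summarize_duplications <- function(pairs, table = NULL) {
  tand <- pairs[pairs$classification == "tandem", , drop = FALSE]
  seg <- pairs[pairs$classification == "segmental", , drop = FALSE]
  tchr <- NA_integer_
  if (!is.null(table) && nrow(tand)) {
    cc <- .pair_coords(tand, table)
    tchr <- length(unique(c(cc$a$chromosome)))
  } else if (!is.null(table)) tchr <- 0L
  list(
    tandem_pairs = nrow(tand),
    segmental_pairs = nrow(seg),
    tandem_genes = length(unique(c(tand$gene_a, tand$gene_b))),
    segmental_genes = length(unique(c(seg$gene_a, seg$gene_b))),
    tandem_chromosomes = tchr
  )
}
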