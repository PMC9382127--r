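# Nei-Gojobori (1986) Ka/Ks estimation with Jukes-Cantor correction, and
# the divergence-time formula T = Ks / (2 * lambda), lambda the synonymous
# substitution rate per site per year.
#
# Conventions (they differ between published implementations):
#   * sites are counted out of 3 per codon position: the synonymous-site
#     fraction of a codon is (# synonymous one-step changes) / 9 * 3, with
#     changes creating a stop codon counted as nonsynonymous opportunities;
#   * multi-nucleotide codon differences are averaged uniformly over all
#     orderings of single steps, but orderings passing through a stop codon
#     are excluded; if every ordering is blocked (rare), all orderings are
#     used as a documented fallback;
#   * gapped codon columns are dropped pairwise before counting.

.nt <- c("A", "C", "G", "T")

.codon_env <- new.env(parent = emptyenv())

# Codon table keyed by the 64 codons in Biostrings' GENETIC_CODE order.
.codon_tables <- function() {
  if (!is.null(.codon_env$tables)) return(.codon_env$tables)
  gc <- Biostrings::GENETIC_CODE
  codons <- names(gc)
  aa <- unname(gc)
  n <- length(codons)
  is_stop <- aa == "*"
  # per-codon synonymous site counts (out of 3)
  split3 <- do.call(rbind, strsplit(codons, ""))
  syn_sites <- numeric(n)
  for (i in seq_len(n)) {
    if (is_stop[i]) { syn_sites[i] <- NA_real_; next }
    syn <- 0L
    for (pos in 1:3) for (alt in setdiff(.nt, split3[i, pos])) {
      mut <- split3[i, ]
      mut[pos] <- alt
      mc <- paste(mut, collapse = "")
      if (gc[[mc]] == aa[i]) syn <- syn + 1L  # stop targets count nonsyn
    }
    syn_sites[i] <- syn / 3
  }
  names(syn_sites) <- codons
  # pairwise average synonymous / nonsynonymous differences
  sd_mat <- matrix(NA_real_, n, n, dimnames = list(codons, codons))
  nd_mat <- sd_mat
  perms <- list(`1` = matrix(1, 1, 1),
                `2` = rbind(c(1, 2), c(2, 1)),
                `3` = rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                            c(2, 3, 1), c(3, 1, 2), c(3, 2, 1)))
  for (i in seq_len(n)) {
    if (is_stop[i]) next
    for (j in seq_len(n)) {
      if (is_stop[j]) next
      if (i == j) { sd_mat[i, j] <- 0; nd_mat[i, j] <- 0; next }
      diffpos <- which(split3[i, ] != split3[j, ])
      k <- length(diffpos)
      ords <- perms[[as.character(k)]]
      count_path <- function(ord, allow_stop) {
        cur <- split3[i, ]
        s <- 0; d <- 0
        for (p in diffpos[ord]) {
          nxt <- cur
          nxt[p] <- split3[j, p]
          aa_from <- gc[[paste(cur, collapse = "")]]
          aa_to <- gc[[paste(nxt, collapse = "")]]
          if (aa_to == "*" && !allow_stop) return(NULL)
          if (aa_from == aa_to) s <- s + 1 else d <- d + 1
          cur <- nxt
        }
        c(s, d)
      }
      paths <- lapply(seq_len(nrow(ords)),
                      function(r) count_path(ords[r, ], FALSE))
      paths <- paths[!vapply(paths, is.null, TRUE)]
      if (!length(paths))  # all orderings pass through a stop: fallback
        paths <- lapply(seq_len(nrow(ords)),
                        function(r) count_path(ords[r, ], TRUE))
      m <- do.call(rbind, paths)
      sd_mat[i, j] <- mean(m[, 1])
      nd_mat[i, j] <- mean(m[, 2])
    }
  }
  .codon_env$tables <- list(codons = codons, aa = aa, is_stop = is_stop,
                            syn_sites = syn_sites, sd = sd_mat, nd = nd_mat)
  .codon_env$tables
}

.split_codons <- function(x) {
  if (nchar(x) %% 3 != 0) stop("sequence length not a multiple of 3")
  substring(x, seq(1, nchar(x), 3), seq(3, nchar(x), 3))
}

# Translate an ungapped CDS with the standard code; stop -> "*".
translate_cds <- function(cds) {
  gc <- Biostrings::GENETIC_CODE
  codons <- .split_codons(toupper(cds))
  bad <- which(!codons %in% names(gc))
  if (length(bad)) stop("unrecognized codon '", codons[bad[1]], "' at codon ",
                        bad[1])
  paste(gc[codons], collapse = "")
}

#' Construct a codon alignment from two aligned CDS strings
#'
#' Validates the invariants: equal lengths, multiple of 3, gaps only in
#' whole-codon units, no internal stop codons in either ungapped sequence.
#'
#' @param cds_a,cds_b aligned nucleotide strings (`-` for gaps).
#' @return list of class `codon_alignment`.
#' @export
codon_alignment <- function(cds_a, cds_b) {
  cds_a <- toupper(cds_a); cds_b <- toupper(cds_b)
  if (nchar(cds_a) != nchar(cds_b)) stop("aligned CDS lengths differ")
  ca <- .split_codons(cds_a); cb <- .split_codons(cds_b)
  chk_gaps <- function(codons) {
    g <- grepl("-", codons)
    if (any(codons[g] != "---")) stop("gaps must come in whole-codon units")
  }
  chk_gaps(ca); chk_gaps(cb)
  gc <- Biostrings::GENETIC_CODE
  chk_stop <- function(codons, label) {
    cc <- codons[codons != "---"]
    if (any(gc[cc] == "*"))
      stop("internal stop codon in sequence ", label)
  }
  chk_stop(ca, "a"); chk_stop(cb, "b")
  structure(list(cds_a = cds_a, cds_b = cds_b), class = "codon_alignment")
}

#' Back-translate a protein alignment onto its coding sequences
#'
#' Expands each protein-alignment gap to a `---` codon gap and checks that
#' every CDS translates to its ungapped protein row; a terminal stop codon
#' on a CDS is stripped.
#'
#' @param prot_a,prot_b aligned protein rows (equal length, `-` gaps).
#' @param cds_a,cds_b ungapped coding sequences.
#' @return A [codon_alignment].
#' @export
back_translate_alignment <- function(prot_a, prot_b, cds_a, cds_b) {
  expand_one <- function(prot, cds, label) {
    cds <- toupper(cds)
    aa_seq <- gsub("-", "", prot)
    codons <- .split_codons(cds)
    gc <- Biostrings::GENETIC_CODE
    if (length(codons) == nchar(aa_seq) + 1 &&
        gc[[codons[length(codons)]]] == "*")
      codons <- codons[-length(codons)]
    if (length(codons) != nchar(aa_seq))
      stop("CDS ", label, " length does not match its protein row")
    tr <- gc[codons]
    aa_chars <- strsplit(aa_seq, "")[[1]]
    mism <- which(tr != aa_chars)
    if (length(mism))
      stop(sprintf("CDS %s codon %d (%s -> %s) does not translate to protein residue '%s'",
                   label, mism[1], codons[mism[1]], tr[mism[1]],
                   aa_chars[mism[1]]))
    cols <- strsplit(prot, "")[[1]]
    out <- character(length(cols))
    k <- 0L
    for (i in seq_along(cols)) {
      if (cols[i] == "-") out[i] <- "---"
      else { k <- k + 1L; out[i] <- codons[k] }
    }
    paste(out, collapse = "")
  }
  if (nchar(prot_a) != nchar(prot_b)) stop("protein alignment rows differ in length")
  codon_alignment(expand_one(prot_a, cds_a, "a"), expand_one(prot_b, cds_b, "b"))
}

#' NG86 Ka/Ks estimate for a codon alignment
#'
#' Counts synonymous/nonsynonymous sites and differences per the
#' Nei-Gojobori (1986) method (see the conventions documented at the top of
#' this file), applies the Jukes-Cantor multiple-hit correction
#' `K = -(3/4) ln(1 - (4/3) p)`, and dates the event with
#' [divergence_time()].
#'
#' @param aln a [codon_alignment] (or two aligned CDS strings via `cds_b`).
#' @param cds_b optional second aligned CDS when `aln` is a plain string.
#' @param lambda synonymous substitution rate per site per year used for
#'   dating (default `6.1e-9`).
#' @return list of class `kaks_result` with `ka`, `ks`, `omega`, `s_sites`,
#'   `n_sites`, `sd`, `nd`, `ps`, `pn`, `t_mya`, `status` (`"ok"`,
#'   `"saturated"` or `"undefined_omega"`).
#' @export
ng86 <- function(aln, cds_b = NULL, lambda = 6.1e-9) {
  if (is.character(aln) && !is.null(cds_b)) aln <- codon_alignment(aln, cds_b)
  stopifnot(inherits(aln, "codon_alignment"))
  tb <- .codon_tables()
  ca <- .split_codons(aln$cds_a)
  cb <- .split_codons(aln$cds_b)
  keep <- ca != "---" & cb != "---"
  if (!any(keep)) stop("alignment has no ungapped codon pair")
  ia <- match(ca[keep], tb$codons)
  ib <- match(cb[keep], tb$codons)
  s_a <- sum(tb$syn_sites[ia])
  s_b <- sum(tb$syn_sites[ib])
  s_sites <- (s_a + s_b) / 2
  n_sites <- 3 * sum(keep) - s_sites
  sd <- sum(tb$sd[cbind(ia, ib)])
  nd <- sum(tb$nd[cbind(ia, ib)])
  ps <- if (s_sites > 0) sd / s_sites else 0
  pn <- if (n_sites > 0) nd / n_sites else 0
  jc <- function(p) -0.75 * log(1 - 4 * p / 3) + 0  # +0 clears IEEE -0
  saturated <- ps >= 0.75 || pn >= 0.75
  ks <- if (ps >= 0.75) NA_real_ else jc(ps)
  ka <- if (pn >= 0.75) NA_real_ else jc(pn)
  omega <- if (!is.na(ka) && !is.na(ks) && ks > 0) ka / ks else NA_real_
  status <- if (saturated) "saturated"
  else if (!is.na(ks) && ks == 0 && !is.na(ka) && ka > 0) "undefined_omega"
  else "ok"
  t_mya <- if (!is.na(ks)) divergence_time(ks, lambda) else NA_real_
  structure(list(ka = ka, ks = ks, omega = omega,
                 s_sites = s_sites, n_sites = n_sites, sd = sd, nd = nd,
                 ps = ps, pn = pn, t_mya = t_mya, status = status),
            class = "kaks_result")
}

#' Date a duplication event from its synonymous divergence
#'
#' `T = Ks / (2 * lambda) * 1e-6` million years, with `lambda` the
#' synonymous substitution rate per site per year (default `6.1e-9`).
#'
#' @param ks synonymous substitutions per synonymous site (>= 0).
#' @param lambda rate in substitutions/site/year.
#' @return Time in million years ago (mya).
#' @examples
#' divergence_time(1.0)  # 81.96721
#' @export
divergence_time <- function(ks, lambda = 6.1e-9) {
  if (any(ks < 0, na.rm = TRUE)) stop("negative ks")
  stopifnot(lambda > 0)
  ks / (2 * lambda) * 1e-6
}

#' Ka/Ks table for a set of duplicate pairs
#'
#' Runs [ng86()] on each pair's coding sequences (aligned via their protein
#' global alignment when lengths differ) and returns one row per pair in
#' the layout gene_a, gene_b, ka, ks, omega, s_sites, n_sites, sd, nd,
#' t_mya, status.
#'
#' @param pairs `duplicate_pairs` frame (or any frame with `gene_a`,
#'   `gene_b`).
#' @param cds named ungapped CDS vector covering all pair members.
#' @param lambda dating rate, default `6.1e-9`.
#' @return data.frame, one row per pair.
#' @export
kaks_table <- function(pairs, cds, lambda = 6.1e-9) {
  cds <- as_protein_vector(cds)  # named character check
  if (!nrow(pairs))
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      ka = numeric(0), ks = numeric(0), omega = numeric(0),
                      s_sites = numeric(0), n_sites = numeric(0),
                      sd = numeric(0), nd = numeric(0), t_mya = numeric(0),
                      status = character(0), stringsAsFactors = FALSE))
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    ga <- pairs$gene_a[i]; gb <- pairs$gene_b[i]
    if (!ga %in% names(cds) || !gb %in% names(cds))
      stop("missing CDS for pair ", ga, "/", gb)
    aln <- align_cds_pair(cds[[ga]], cds[[gb]])
    r <- ng86(aln, lambda = lambda)
    data.frame(gene_a = ga, gene_b = gb, ka = r$ka, ks = r$ks,
               omega = r$omega, s_sites = r$s_sites, n_sites = r$n_sites,
               sd = r$sd, nd = r$nd, t_mya = r$t_mya, status = r$status,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(stringsAsFactors = FALSE)))
}

# Align a CDS pair through their translated proteins (global alignment,
# BLOSUM62) and back-translate; equal-length pairs that already translate
# cleanly skip the alignment.
align_cds_pair <- function(cds_a, cds_b) {
  strip_stop <- function(cds) {
    codons <- .split_codons(toupper(cds))
    if (Biostrings::GENETIC_CODE[[codons[length(codons)]]] == "*")
      codons <- codons[-length(codons)]
    paste(codons, collapse = "")
  }
  cds_a <- strip_stop(cds_a); cds_b <- strip_stop(cds_b)
  pa <- translate_cds(cds_a); pb <- translate_cds(cds_b)
  if (nchar(cds_a) == nchar(cds_b) && !grepl("\\*", pa) && !grepl("\\*", pb) &&
      identical(nchar(pa), nchar(pb)))
    return(codon_alignment(cds_a, cds_b))
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(pa), Biostrings::AAString(pb), type = "global",
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5)
  back_translate_alignment(as.character(Biostrings::pattern(aln)),
                           as.character(Biostrings::subject(aln)),
                           cds_a, cds_b)
}
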