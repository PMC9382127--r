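# Expression-level and fold-change classification of FPKM matrices.
#
# The high-expression rule is applied literally: a gene is "high" in a
# condition when |log2(FPKM)| >= threshold (so both FPKM >= 2 and
# 0 < FPKM <= 0.5 qualify at the default threshold 1); FPKM = 0 is
# "not_expressed" and no pseudocount is used. The alternative reading
# (log2 >= threshold only, i.e. FPKM >= 2) is selectable.

#' Build an expression matrix with sample metadata
#'
#' @param values genes x samples numeric matrix of FPKM values (>= 0),
#'   with row and column names.
#' @param metadata data.frame with one row per column of `values`; must
#'   contain a `sample` column matching `colnames(values)` and a
#'   `condition` column; a `replicate` column is optional.
#' @return list of class `expression_matrix`.
#' @export
expression_matrix <- function(values, metadata = NULL) {
  stopifnot(is.matrix(values))
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(values))) stop("duplicate gene names")
  if (any(values < 0)) stop("negative FPKM")
  if (is.null(metadata))
    metadata <- data.frame(sample = colnames(values),
                           condition = colnames(values),
                           stringsAsFactors = FALSE)
  if (!all(c("sample", "condition") %in% names(metadata)))
    stop("metadata needs 'sample' and 'condition' columns")
  if (!setequal(metadata$sample, colnames(values)))
    stop("metadata does not cover every sample column")
  metadata <- metadata[match(colnames(values), metadata$sample), , drop = FALSE]
  structure(list(values = values, metadata = metadata),
            class = "expression_matrix")
}

#' Read an FPKM matrix from a TSV file
#'
#' First column gene names, remaining columns samples. Sample metadata may
#' be supplied as a sidecar TSV (`sample`, `condition`, optional
#' `replicate`); without one, each column is its own condition.
#'
#' @param path matrix TSV path.
#' @param meta_path optional metadata TSV path.
#' @return An [expression_matrix].
#' @export
read_expression_tsv <- function(path, meta_path = NULL) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  genes <- x[[1]]
  m <- as.matrix(x[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- genes
  meta <- if (!is.null(meta_path))
    utils::read.delim(meta_path, stringsAsFactors = FALSE) else NULL
  expression_matrix(m, meta)
}

# mean FPKM per gene per condition (replicates averaged arithmetically
# before any log transform)
.condition_means <- function(em) {
  conds <- unique(em$metadata$condition)
  out <- sapply(conds, function(cc) {
    cols <- em$metadata$sample[em$metadata$condition == cc]
    rowMeans(em$values[, cols, drop = FALSE])
  })
  out <- matrix(out, nrow = nrow(em$values),
                dimnames = list(rownames(em$values), conds))
  out
}

#' Classify expression level per gene per condition
#'
#' Replicates are averaged per condition; FPKM = 0 is `not_expressed`,
#' otherwise log2(FPKM) is computed with no pseudocount and the gene is
#' `high` when the rule holds (`abs_log2`, the default: |log2| >=
#' `high_threshold`; `log2_up`: log2 >= `high_threshold`), else `low`.
#'
#' @param em an [expression_matrix].
#' @param high_threshold positive threshold on the log2 scale (default 1).
#' @param rule `"abs_log2"` (literal |log2|) or `"log2_up"`.
#' @return list of class `expression_calls`: `status` (genes x conditions
#'   character matrix), `log2` (log2 mean FPKM, `NA` where not expressed),
#'   and `summary` (per condition: expressed count, high count, high
#'   percentage to 2 decimals).
#' @export
call_expression <- function(em, high_threshold = 1,
                            rule = c("abs_log2", "log2_up")) {
  rule <- match.arg(rule)
  stopifnot(high_threshold > 0)
  mm <- .condition_means(em)
  if (any(mm < 0)) stop("negative FPKM")
  lg <- ifelse(mm > 0, log2(mm), NA_real_)
  high <- if (rule == "abs_log2") abs(lg) >= high_threshold
  else lg >= high_threshold
  status <- ifelse(mm == 0, "not_expressed",
                   ifelse(high, "high", "low"))
  summ <- do.call(rbind, lapply(colnames(mm), function(cc) {
    expressed <- sum(status[, cc] != "not_expressed")
    nhigh <- sum(status[, cc] == "high")
    data.frame(condition = cc, expressed = expressed, high = nhigh,
               high_pct = if (expressed > 0)
                 round_half_away(100 * nhigh / expressed, 2) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  structure(list(status = status, log2 = lg, summary = summ),
            class = "expression_calls")
}

#' Fold-change direction calls against a baseline condition
#'
#' Replicates are averaged per condition, then log2(condition/baseline) is
#' taken per gene. Zero handling: condition 0 with baseline > 0 is a `down`
#' call with log2FC capped at `-zero_floor`; baseline 0 with condition > 0
#' is newly expressed, called `up` (log2FC capped at `+zero_floor`); both
#' zero in all conditions makes the gene `not_expressed`. Direction is set
#' when |log2FC| >= `fc_threshold`, else `unchanged`.
#'
#' @param em an [expression_matrix].
#' @param baseline baseline condition name.
#' @param fc_threshold log2 fold-change threshold (default 1).
#' @param zero_floor magnitude cap replacing infinite ratios (default 10).
#' @return list of class `fold_change_calls`: `direction` (genes x
#'   non-baseline conditions), `log2fc`, and `summary` with percentages of
#'   up/down genes among expressed genes (a gene counts once, as `up` if up
#'   at any timepoint, else `down` if down at any, else unchanged).
#' @export
fold_change_calls <- function(em, baseline, fc_threshold = 1,
                              zero_floor = 10) {
  mm <- .condition_means(em)
  if (!baseline %in% colnames(mm))
    stop("baseline condition '", baseline, "' not found")
  conds <- setdiff(colnames(mm), baseline)
  base <- mm[, baseline]
  never <- rowSums(mm > 0) == 0
  lfc <- matrix(NA_real_, nrow(mm), length(conds),
                dimnames = list(rownames(mm), conds))
  dir <- matrix("not_expressed", nrow(mm), length(conds),
                dimnames = list(rownames(mm), conds))
  for (cc in conds) {
    v <- mm[, cc]
    both0 <- v == 0 & base == 0
    lfc[, cc] <- ifelse(v > 0 & base > 0, log2(v / base),
                 ifelse(v == 0 & base > 0, -zero_floor,
                 ifelse(v > 0 & base == 0, zero_floor, NA_real_)))
    d <- ifelse(both0, "not_expressed",
         ifelse(lfc[, cc] >= fc_threshold, "up",
         ifelse(lfc[, cc] <= -fc_threshold, "down", "unchanged")))
    dir[, cc] <- d
  }
  expressed <- !never
  any_up <- expressed & apply(dir == "up", 1, any)
  any_down <- expressed & !any_up & apply(dir == "down", 1, any)
  n_expr <- sum(expressed)
  summ <- data.frame(
    expressed = n_expr,
    up = sum(any_up), down = sum(any_down),
    up_pct = if (n_expr) round_half_away(100 * sum(any_up) / n_expr, 2) else NA,
    down_pct = if (n_expr) round_half_away(100 * sum(any_down) / n_expr, 2) else NA)
  structure(list(direction = dir, log2fc = lfc, summary = summ),
            class = "fold_change_calls")
}

#' Reorder an expression matrix by a phylogeny-derived gene order
#'
#' @param values numeric matrix (or `log2` slot of calls) with gene rows.
#' @param gene_order character permutation of `rownames(values)`, e.g.
#'   taxa grouped by [cut_subgroups()] ids.
#' @return The row-permuted matrix.
#' @export
heatmap_matrix <- function(values, gene_order) {
  if (!setequal(gene_order, rownames(values)) ||
      length(gene_order) != nrow(values))
    stop("gene_order must be a permutation of the matrix genes")
  values[gene_order, , drop = FALSE]
}
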