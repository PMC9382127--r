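# Internal-browning (IB) phenotype statistics for graded fruit cohorts.
#
# Severity is graded 0-5 on the fraction of browned cross-sectional area
# (0: none ... 5: more than 50%). The cohort severity index is
#   IB index = [ sum_i(S_i * N_i) / (5 N) ] * 100
# with S_i the grade, N_i the fruit count at that grade and N the cohort
# total; incidence is the percentage of fruits with any IB spots
# (grade >= 1).

#' Construct an IB cohort from per-grade fruit counts
#'
#' @param grade_counts named numeric vector; names are grades `0`-`5`,
#'   values are fruit counts. Missing grades count as zero; any ungraded
#'   remainder of `n_total` is treated as grade 0.
#' @param n_total total fruits investigated; defaults to
#'   `sum(grade_counts)`.
#' @param group optional group label (e.g. `"control"`, `"AsA"`).
#' @param day optional storage day.
#' @return list of class `ib_cohort`.
#' @export
ib_cohort <- function(grade_counts, n_total = NULL, group = NA_character_,
                      day = NA_real_) {
  if (is.null(names(grade_counts)))
    stop("grade_counts must be named by grade (0-5)")
  g <- suppressWarnings(as.integer(names(grade_counts)))
  if (anyNA(g) || any(g < 0 | g > 5)) stop("grades must be integers 0-5")
  if (any(grade_counts < 0)) stop("negative fruit count")
  counts <- stats::setNames(numeric(6), as.character(0:5))
  counts[as.character(g)] <- counts[as.character(g)] + grade_counts
  if (is.null(n_total)) n_total <- sum(counts)
  if (sum(counts) > n_total)
    stop("graded fruits exceed n_total")
  counts["0"] <- counts["0"] + (n_total - sum(counts))
  structure(list(grade_counts = counts, n_total = n_total,
                 group = group, day = day), class = "ib_cohort")
}

#' IB severity index of a cohort
#'
#' `[sum(S_i * N_i) / (5 N)] * 100`, in `[0, 100]`.
#'
#' @param cohort an [ib_cohort] (or a named grade-count vector).
#' @return Index value; use [round_half_away()] with 2 digits for printed
#'   reporting.
#' @examples
#' ib_index(ib_cohort(c(`0` = 5, `1` = 1, `2` = 1, `3` = 1, `4` = 1,
#'                      `5` = 1)))  # 30
#' @export
ib_index <- function(cohort) {
  if (!inherits(cohort, "ib_cohort")) cohort <- ib_cohort(cohort)
  if (cohort$n_total <= 0) stop("n_total must be positive")
  s <- as.integer(names(cohort$grade_counts))
  sum(s * cohort$grade_counts) / (5 * cohort$n_total) * 100
}

#' IB incidence percentage
#'
#' Proportion of fruits with IB spots (grade >= 1), as a percentage.
#'
#' @param n_affected affected fruit count, or an [ib_cohort] from which
#'   the count of grade >= 1 fruits is taken.
#' @param n_total total fruits (ignored when a cohort is given).
#' @return Percentage in `[0, 100]`.
#' @examples
#' ib_incidence(16, 30)  # 53.33333
#' @export
ib_incidence <- function(n_affected, n_total = NULL) {
  if (inherits(n_affected, "ib_cohort")) {
    cohort <- n_affected
    n_total <- cohort$n_total
    n_affected <- sum(cohort$grade_counts[-1])
  }
  if (is.null(n_total) || n_total <= 0) stop("n_total must be positive")
  if (n_affected < 0 || n_affected > n_total)
    stop("n_affected must lie in [0, n_total]")
  100 * n_affected / n_total
}

#' Read graded cohorts from a TSV file
#'
#' Long format with header `group`, `day`, `grade`, `count`; one cohort
#' per group x day.
#'
#' @param path file path.
#' @return list of [ib_cohort] objects named `group:day`.
#' @export
read_cohorts <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("group", "day", "grade", "count")
  miss <- setdiff(req, names(x))
  if (length(miss)) stop("cohort table missing: ", paste(miss, collapse = ", "))
  keys <- unique(x[, c("group", "day")])
  out <- lapply(seq_len(nrow(keys)), function(i) {
    sel <- x$group == keys$group[i] & x$day == keys$day[i]
    ib_cohort(stats::setNames(x$count[sel], x$grade[sel]),
              group = keys$group[i], day = keys$day[i])
  })
  names(out) <- paste(keys$group, keys$day, sep = ":")
  out
}

#' Per-cohort IB report table
#'
#' @param cohorts list of [ib_cohort] objects (e.g. from [read_cohorts()]).
#' @return data.frame with group, day, n, index and incidence (2-decimal
#'   reporting convention applied).
#' @export
ib_report <- function(cohorts) {
  do.call(rbind, lapply(cohorts, function(co) {
    data.frame(group = co$group, day = co$day, n = co$n_total,
               ib_index = round_half_away(ib_index(co), 2),
               ib_incidence = round_half_away(ib_incidence(co), 2),
               stringsAsFactors = FALSE)
  }))
}
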