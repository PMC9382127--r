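# End-to-end orchestration: a single declarative JSON config drives table
# loading -> physchem -> duplication -> Ka/Ks dating -> phylogeny ->
# expression -> phenotype, each stage skippable, with per-stage TSV/JSON/
# Newick outputs plus a summary JSON of the headline counts.

#' Default run configuration
#'
#' Every published analysis parameter surfaces as a named key with its
#' printed value as default: candidate screening at E-value <= 1e-5 and
#' identity > 50%; duplicate criteria 0.70/0.70; tandem rule
#' `span_200kb`; synonymous rate lambda 6.1e-9/site/year; expression
#' thresholds 1 on the log2 scale; 1000 bootstrap replicates.
#'
#' @param ... overrides (input paths under `inputs`, or any threshold).
#' @return list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    inputs = list(table = NULL, proteins = NULL, cds = NULL, blocks = NULL,
                  alignment = NULL, expression = NULL, expression_meta = NULL,
                  expression_baseline = NULL, cohorts = NULL),
    evalue_max = 1e-5,
    identity_min_pct = 50,
    dup_identity_min = 0.70,
    dup_ratio_min = 0.70,
    tandem_rule = "span_200kb",
    lambda = 6.1e-9,
    high_threshold = 1,
    fc_threshold = 1,
    bootstrap_replicates = 1000,
    subgroups = 5,
    seed = 42,
    out_dir = NULL
  )
  over <- list(...)
  for (nm in names(over)) {
    if (nm == "inputs") for (k in names(over$inputs))
      cfg$inputs[[k]] <- over$inputs[[k]]
    else cfg[[nm]] <- over[[nm]]
  }
  structure(cfg, class = "run_config")
}

#' Load a run configuration from a JSON file
#'
#' @param path JSON file whose keys mirror [run_config()].
#' @return A validated `run_config`.
#' @export
load_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, x)
}

.validate_run_config <- function(cfg) {
  errs <- character(0)
  chk <- function(cond, msg) if (!cond) errs <<- c(errs, msg)
  chk(cfg$evalue_max > 0, "evalue_max must be positive")
  chk(cfg$identity_min_pct > 0 && cfg$identity_min_pct < 100,
      "identity_min_pct must be in (0, 100)")
  chk(cfg$dup_identity_min > 0 && cfg$dup_identity_min <= 1,
      "dup_identity_min must be in (0, 1]")
  chk(cfg$dup_ratio_min > 0 && cfg$dup_ratio_min <= 1,
      "dup_ratio_min must be in (0, 1]")
  chk(cfg$tandem_rule %in% c("span_200kb", "window_100kb_5genes"),
      "unknown tandem_rule")
  chk(cfg$lambda > 0, "lambda must be positive")
  chk(cfg$bootstrap_replicates >= 1, "bootstrap_replicates must be >= 1")
  for (nm in names(cfg$inputs)) {
    p <- cfg$inputs[[nm]]
    if (!is.null(p) && nm != "expression_baseline" && !file.exists(p))
      errs <- c(errs, paste0("input '", nm, "' does not exist: ", p))
  }
  if (is.null(cfg$inputs$table)) errs <- c(errs, "inputs$table is required")
  errs
}

#' Run the full pipeline from a configuration
#'
#' Stages with missing inputs are skipped and recorded as such. When
#' `cfg$out_dir` is set, per-stage TSV/Newick files and `summary.json`
#' (including the seed and a config hash for provenance) are written.
#'
#' @param cfg a `run_config` (or path to a JSON config).
#' @return list with per-stage results and `summary`.
#' @export
run_all <- function(cfg) {
  if (is.character(cfg)) cfg <- load_run_config(cfg)
  errs <- .validate_run_config(cfg)
  if (length(errs))
    stop("config validation failed:\n  - ", paste(errs, collapse = "\n  - "))
  out <- list(config = cfg)
  summary <- list(seed = cfg$seed,
                  config_hash = .config_hash(cfg))
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  # family table
  tab <- run_stage("table", load_family_table(cfg$inputs$table))
  out$table <- tab
  hist <- exon_histogram(tab)
  summary$family_size <- nrow(tab)
  summary$exon_histogram <- as.list(hist$counts)
  summary$aa_range <- range_summary(tab, "aa_len")
  summary$mw_range <- range_summary(tab, "mw")
  summary$pi_range <- range_summary(tab, "pi")

  proteins <- NULL
  if (!is.null(cfg$inputs$proteins)) {
    proteins <- run_stage("physchem", {
      p <- Biostrings::readAAStringSet(cfg$inputs$proteins)
      stats::setNames(as.character(p), names(p))
    })
    out$physchem <- physchem_table(proteins)
  }

  if (!is.null(proteins)) {
    out$duplicates <- run_stage("duplication", {
      pairs <- find_duplicate_pairs(tab, proteins, cfg$dup_identity_min,
                                    cfg$dup_ratio_min)
      pairs <- classify_tandem(pairs, tab, cfg$tandem_rule)
      blocks <- if (!is.null(cfg$inputs$blocks))
        read_synteny_blocks(cfg$inputs$blocks) else NULL
      if (!is.null(blocks))
        pairs <- classify_segmental(pairs, blocks, tab)
      pairs
    })
    summary$duplication <- summarize_duplications(out$duplicates, tab)
  }

  if (!is.null(cfg$inputs$cds) && !is.null(out$duplicates) &&
      nrow(out$duplicates)) {
    out$kaks <- run_stage("kaks", {
      cdss <- Biostrings::readDNAStringSet(cfg$inputs$cds)
      kaks_table(out$duplicates, stats::setNames(as.character(cdss),
                                                 names(cdss)),
                 lambda = cfg$lambda)
    })
    ok <- out$kaks$status != "saturated" & !is.na(out$kaks$t_mya)
    if (any(ok))
      summary$divergence_time_mya <- list(min = min(out$kaks$t_mya[ok]),
                                          max = max(out$kaks$t_mya[ok]))
  }

  if (!is.null(cfg$inputs$alignment)) {
    out$tree <- run_stage("phylogeny", {
      aln <- Biostrings::readAAStringSet(cfg$inputs$alignment)
      nj_bootstrap(stats::setNames(as.character(aln), names(aln)),
                   replicates = cfg$bootstrap_replicates, seed = cfg$seed)
    })
    out$subgroups <- cut_subgroups(out$tree$tree,
                                   min(cfg$subgroups,
                                       length(out$tree$tree$tip.label)))
    summary$subgroup_sizes <- as.list(table(out$subgroups))
  }

  if (!is.null(cfg$inputs$expression)) {
    out$expression <- run_stage("expression", {
      em <- read_expression_tsv(cfg$inputs$expression,
                                cfg$inputs$expression_meta)
      calls <- call_expression(em, cfg$high_threshold)
      fc <- if (!is.null(cfg$inputs$expression_baseline))
        fold_change_calls(em, cfg$inputs$expression_baseline,
                          cfg$fc_threshold) else NULL
      list(matrix = em, calls = calls, fold_change = fc)
    })
    summary$expression <- out$expression$calls$summary
    if (!is.null(out$expression$fold_change))
      summary$fold_change <- out$expression$fold_change$summary
  }

  if (!is.null(cfg$inputs$cohorts)) {
    out$ib <- run_stage("phenotype", ib_report(read_cohorts(cfg$inputs$cohorts)))
    summary$ib <- out$ib
  }

  out$summary <- summary
  if (!is.null(cfg$out_dir)) .write_run_outputs(out, cfg$out_dir)
  out
}

.config_hash <- function(cfg) {
  cfg <- unclass(cfg)
  cfg$out_dir <- NULL  # hash covers the analysis parameters, not the sink
  s <- jsonlite::toJSON(cfg, auto_unbox = TRUE, null = "null",
                        digits = NA)
  # small rolling hash; provenance marker, not cryptographic
  v <- utf8ToInt(as.character(s))
  sprintf("%08x", Reduce(function(h, c)
    bitwXor(as.integer((h * 31) %% 2147483647), as.integer(c)), v, 17L))
}

.write_run_outputs <- function(out, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_family_table(out$table, file.path(dir, "family_table.tsv"))
  if (!is.null(out$physchem))
    utils::write.table(out$physchem, file.path(dir, "physchem.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(out$duplicates))
    utils::write.table(out$duplicates, file.path(dir, "duplicates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(out$kaks))
    utils::write.table(out$kaks, file.path(dir, "kaks.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(out$tree))
    write_tree_newick(out$tree$tree, file.path(dir, "tree.nwk"))
  if (!is.null(out$ib))
    utils::write.table(out$ib, file.path(dir, "ib_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(out$summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(dir)
}

# ---------------------------------------------------------------------
# Command-line entry point (used by inst/scripts/famdup)

.parse_cli <- function(args) {
  opts <- list(); positional <- character(0)
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      key <- sub("^--", "", a)
      if (i == length(args) || startsWith(args[i + 1], "--")) {
        opts[[key]] <- TRUE; i <- i + 1
      } else { opts[[key]] <- args[i + 1]; i <- i + 2 }
    } else { positional <- c(positional, a); i <- i + 1 }
  }
  list(opts = opts, positional = positional)
}

#' Command-line dispatcher
#'
#' Subcommands: `table` (family-table summary JSON), `physchem`
#' (MW/pI table from a protein FASTA), `duplication`, `kaks`, `tree`,
#' `expr`, `ib`, `simulate` and `run`. Invoked by the `famdup` script in
#' `inst/scripts/`; see the script for usage lines. Returns the exit code
#' rather than calling `quit()`, so it is testable in-process: 0 on
#' success, 2 on validation errors, 1 on runtime failure.
#'
#' @param args character vector of command-line arguments.
#' @return Integer exit code.
#' @export
famdup_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    message("usage: famdup <table|physchem|duplication|kaks|tree|expr|ib|simulate|run> [--opts]")
    return(2L)
  }
  cmd <- args[1]
  p <- .parse_cli(args[-1])
  o <- p$opts
  need <- function(key) {
    if (is.null(o[[key]])) stop("missing required option --", key, call. = FALSE)
    o[[key]]
  }
  code <- tryCatch({
    switch(cmd,
      table = {
        tab <- load_family_table(need("in"))
        h <- exon_histogram(tab)
        res <- list(family_size = nrow(tab), exon_histogram = as.list(h$counts),
                    aa = range_summary(tab, "aa_len"),
                    mw = range_summary(tab, "mw"),
                    pi = range_summary(tab, "pi"))
        jsonlite::write_json(res, need("summary"), auto_unbox = TRUE,
                             pretty = TRUE, digits = NA)
        0L
      },
      physchem = {
        pr <- Biostrings::readAAStringSet(need("fasta"))
        tabp <- physchem_table(stats::setNames(as.character(pr), names(pr)))
        utils::write.table(tabp, need("out"), sep = "\t", quote = FALSE,
                           row.names = FALSE)
        0L
      },
      duplication = {
        tab <- load_family_table(need("table"))
        pr <- Biostrings::readAAStringSet(need("fasta"))
        pairs <- find_duplicate_pairs(tab, stats::setNames(as.character(pr),
                                                           names(pr)))
        rule <- if (!is.null(o$rule)) o$rule else "span_200kb"
        pairs <- classify_tandem(pairs, tab, rule)
        if (!is.null(o$blocks))
          pairs <- classify_segmental(pairs, read_synteny_blocks(o$blocks), tab)
        utils::write.table(pairs, if (!is.null(o$out)) o$out else stdout(),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        0L
      },
      kaks = {
        pairs <- utils::read.delim(need("pairs"), stringsAsFactors = FALSE)
        cdss <- Biostrings::readDNAStringSet(need("cds"))
        lambda <- if (!is.null(o$lambda)) as.numeric(o$lambda) else 6.1e-9
        kk <- kaks_table(pairs, stats::setNames(as.character(cdss),
                                                names(cdss)), lambda)
        utils::write.table(kk, if (!is.null(o$out)) o$out else stdout(),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        0L
      },
      tree = {
        aln <- Biostrings::readAAStringSet(need("aln"))
        reps <- if (!is.null(o$bootstrap)) as.integer(o$bootstrap) else 1000L
        seed <- if (!is.null(o$seed)) as.integer(o$seed) else 42L
        bt <- nj_bootstrap(stats::setNames(as.character(aln), names(aln)),
                           replicates = reps, seed = seed)
        write_tree_newick(bt$tree, need("out"))
        if (!is.null(o$subgroups)) {
          sg <- cut_subgroups(bt$tree, as.integer(o$subgroups))
          utils::write.table(data.frame(taxon = names(sg), subgroup = sg),
                             paste0(need("out"), ".subgroups.tsv"),
                             sep = "\t", quote = FALSE, row.names = FALSE)
        }
        0L
      },
      expr = {
        em <- read_expression_tsv(need("matrix"), o$meta)
        calls <- call_expression(em)
        utils::write.table(calls$summary,
                           if (!is.null(o$out)) o$out else stdout(),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        if (!is.null(o$baseline)) {
          fc <- fold_change_calls(em, o$baseline)
          utils::write.table(fc$summary,
                             if (!is.null(o$out)) paste0(o$out, ".fc.tsv")
                             else stdout(),
                             sep = "\t", quote = FALSE, row.names = FALSE)
        }
        0L
      },
      ib = {
        rep <- ib_report(read_cohorts(need("cohorts")))
        utils::write.table(rep, if (!is.null(o$out)) o$out else stdout(),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        0L
      },
      simulate = {
        seed <- if (!is.null(o$seed)) as.integer(o$seed) else 1L
        cfg <- sim_config(seed = seed)
        write_sim_genome(simulate_genome(cfg), need("out"))
        0L
      },
      run = {
        run_all(need("config"))
        0L
      },
      {
        message("unknown subcommand: ", cmd)
        2L
      })
  }, error = function(e) {
    message("famdup ", cmd, ": ", conditionMessage(e))
    if (grepl("validation failed|missing required option", conditionMessage(e)))
      2L else 1L
  })
  code
}
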