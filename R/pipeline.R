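# Orchestration: simulate -> run -> report as composable subcommands.
# Single-process, per-sample isolation; per-stage read counts are logged
# to standard error so the conservation invariant is auditable from logs.

msg <- function(...) message(sprintf(...))

#' Load and validate a run configuration (JSON or YAML)
#'
#' The configuration holds a sample manifest (`sample_id`, `subject`,
#' `timepoint`, `isotype`, optional `fastq`, optional per-sample `n_reads`
#' / `seed` overrides), optional `sim`, `rslb` and `thresholds` sections,
#' a `germline` entry ("builtin-toy" or a FASTA path) and an `outdir`.
#' Relative paths resolve against the configuration file's directory.
#'
#' @param path configuration file (`.json`, `.yml`, `.yaml`).
#' @return object of class `run_config`.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML configuration requires the 'yaml' package; use JSON instead")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  cfg$config_dir <- dirname(normalizePath(path))
  validate_run_config(cfg)
}

#' Build a run configuration from an R list
#'
#' @param cfg list with the fields described in [load_run_config()].
#' @return object of class `run_config`.
#' @export
run_config <- function(cfg) {
  if (is.null(cfg$config_dir)) cfg$config_dir <- getwd()
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  samples <- cfg$samples
  if (is.null(samples)) stop("config must contain a 'samples' manifest")
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  need <- c("sample_id", "subject", "timepoint", "isotype")
  if (!all(need %in% names(samples)))
    stop("sample manifest needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(samples$sample_id))
    stop("sample_ids must be unique")
  if (!all(samples$isotype %in% c("IgM", "IgG")))
    stop("isotype must be IgM or IgG")
  cfg$samples <- samples
  if (is.null(cfg$seed)) cfg$seed <- 1L
  if (is.null(cfg$outdir)) cfg$outdir <- "bovcdr3_out"
  if (is.null(cfg$germline)) cfg$germline <- "builtin-toy"
  structure(cfg, class = "run_config")
}

resolve_path <- function(path, config) {
  if (grepl("^(/|[A-Za-z]:)", path)) path
  else file.path(config$config_dir, path)
}

config_db <- function(config) {
  if (identical(config$germline, "builtin-toy")) germline_db()
  else read_germline_fasta(resolve_path(config$germline, config))
}

config_thresholds <- function(config) {
  th <- config$thresholds
  if (is.null(th)) class_thresholds()
  else do.call(class_thresholds, th)
}

sample_sim_config <- function(config, i, seed) {
  s <- config$samples[i, ]
  args <- if (is.null(config$sim)) list() else config$sim
  if (!is.null(s$n_reads) && !is.na(s$n_reads)) args$n_reads <- s$n_reads
  if (!is.null(args$class_probs)) args$class_probs <- unlist(args$class_probs)
  args$isotype <- s$isotype
  args$seed <- (seed + i) %% .Machine$integer.max
  args$id_prefix <- paste0(s$sample_id, "_")
  do.call(sim_config, args)
}

sample_rslb_config <- function(config, isotype) {
  args <- if (is.null(config$rslb)) list() else config$rslb
  keep <- intersect(names(args), c("imgt_length"))
  rc <- list(isotype = isotype)
  rc[keep] <- args[keep]
  if (!is.null(args$max_mismatch))
    rc$primers <- primer_set(max_mismatch = args$max_mismatch)
  if (!is.null(args$window))
    rc$window <- length_window(isotype, args$window$min_len,
                               args$window$max_len)
  if (!is.null(args$quality))
    rc$gate <- do.call(quality_gate, args$quality)
  do.call(rslb_config, rc)
}

#' Simulate FASTQ + truth files for every manifest sample
#'
#' @param config a `run_config`.
#' @param outdir output directory (default from the config).
#' @param seed base seed; per-sample seeds derive from it deterministically.
#' @return data.frame manifest with `fastq` and `truth` paths added,
#'   invisibly (also written to `<outdir>/manifest.tsv`).
#' @export
cmd_simulate <- function(config, outdir = config$outdir,
                         seed = config$seed) {
  # validate everything before writing anything
  db <- config_db(config)
  sims <- lapply(seq_len(nrow(config$samples)), function(i)
    sample_sim_config(config, i, seed))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("cannot create output directory: ", outdir)
  manifest <- config$samples
  manifest$fastq <- file.path(outdir, paste0(manifest$sample_id, ".fastq"))
  manifest$truth <- file.path(outdir,
                              paste0(manifest$sample_id, ".truth.tsv"))
  for (i in seq_len(nrow(manifest))) {
    sim <- simulate_sample(sims[[i]], db = db)
    write_fastq(sim$reads, manifest$fastq[i])
    write_table(sim$truth, manifest$truth[i])
    msg("simulate: %s -> %d reads (%s)", manifest$sample_id[i],
        nrow(sim$reads), manifest$fastq[i])
  }
  write_table(manifest, file.path(outdir, "manifest.tsv"))
  invisible(manifest)
}

#' Run the filtering/extraction cascade for every manifest sample
#'
#' Each sample is processed in isolation: a missing or corrupt FASTQ fails
#' that sample (recorded in the returned status) while the others proceed.
#' Outputs per sample: `<id>.extraction.tsv` and `<id>.outcomes.json`;
#' plus a combined `productive_all.tsv` holding every extracted,
#' stop-codon-free junction across samples.
#'
#' @param config a `run_config`.
#' @param outdir output directory.
#' @return list with `status` (data.frame `sample_id`, `ok`, `error`) and
#'   `n_failed`; callers should exit nonzero when `n_failed > 0`.
#' @export
cmd_run <- function(config, outdir = config$outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  samples <- config$samples
  if (is.null(samples$fastq)) {
    samples$fastq <- file.path(outdir, paste0(samples$sample_id, ".fastq"))
  } else {
    samples$fastq <- vapply(samples$fastq, resolve_path, character(1),
                            config = config)
  }
  status <- data.frame(sample_id = samples$sample_id, ok = FALSE,
                       error = NA_character_, stringsAsFactors = FALSE)
  productive <- list()
  for (i in seq_len(nrow(samples))) {
    sid <- samples$sample_id[i]
    res <- tryCatch({
      reads <- read_fastq(samples$fastq[i])
      rc <- sample_rslb_config(config, samples$isotype[i])
      out <- run_rslb(reads, rc)
      write_table(out$records,
                  file.path(outdir, paste0(sid, ".extraction.tsv")))
      jsonlite::write_json(as.list(out$counts),
                           file.path(outdir, paste0(sid, ".outcomes.json")),
                           auto_unbox = TRUE)
      msg("run: %s -> %s", sid,
          paste(names(out$counts), out$counts, sep = "=", collapse = " "))
      ex <- out$records[out$records$outcome == "extracted" &
                          is_productive(out$records$junction_aa), ,
                        drop = FALSE]
      if (nrow(ex)) ex$sample_id <- sid
      productive[[sid]] <- ex
      TRUE
    }, error = function(e) {
      msg("run: %s FAILED: %s", sid, conditionMessage(e))
      status$error[i] <<- conditionMessage(e)
      FALSE
    })
    status$ok[i] <- res
  }
  combined <- do.call(rbind, productive[!vapply(productive, is.null,
                                                logical(1))])
  if (is.null(combined) || !nrow(combined)) {
    combined <- data.frame(read_id = character(0), isotype = character(0),
                           orientation = character(0), outcome = character(0),
                           junction_nt = character(0),
                           junction_aa = character(0),
                           length_aa = integer(0),
                           pre_motif_used = character(0),
                           post_motif_used = character(0),
                           sample_id = character(0), stringsAsFactors = FALSE)
  }
  write_table(combined, file.path(outdir, "productive_all.tsv"))
  list(status = status, n_failed = sum(!status$ok))
}

#' Summarise extractions and run the planned paired comparisons
#'
#' Produces, per isotype: a per-timepoint mean (SEM) table for the
#' ultralong percentages (both denominators) and the planned-comparison
#' results; human-readable TSVs plus a full-precision `report.json`.
#' Contrasts with fewer than 2 complete subject pairs are skipped with a
#' warning.
#'
#' @param config a `run_config`.
#' @param outdir directory holding `cmd_run` outputs; report files are
#'   written next to them.
#' @param metrics summary fields to compare across timepoints.
#' @return list (per isotype) with `per_sample`, `summary`, `comparisons`,
#'   invisibly.
#' @export
cmd_report <- function(config, outdir = config$outdir,
                       metrics = c("pct_ultralong_productive",
                                   "pct_ultralong_total")) {
  samples <- config$samples
  th <- config_thresholds(config)
  per_sample <- lapply(seq_len(nrow(samples)), function(i) {
    path <- file.path(outdir, paste0(samples$sample_id[i], ".extraction.tsv"))
    if (!file.exists(path)) return(NULL)
    rec <- read_table_tsv(path)
    s <- summarize_sample(rec, th, sample_id = samples$sample_id[i],
                          isotype = samples$isotype[i])
    cbind(samples[i, c("sample_id", "subject", "timepoint", "isotype")],
          as.data.frame(s)[setdiff(names(as.data.frame(s)),
                                   c("sample_id", "isotype"))])
  })
  per_sample <- do.call(rbind, per_sample[!vapply(per_sample, is.null,
                                                  logical(1))])
  if (is.null(per_sample) || !nrow(per_sample))
    stop("no extraction outputs found under ", outdir)

  report <- list()
  for (iso in unique(per_sample$isotype)) {
    d <- per_sample[per_sample$isotype == iso, ]
    summary_rows <- list()
    comparison_rows <- list()
    for (metric in metrics) {
      for (tp in sort(unique(d$timepoint))) {
        ms <- mean_sem(d[[metric]][d$timepoint == tp], na.rm = TRUE)
        summary_rows[[length(summary_rows) + 1L]] <- data.frame(
          metric = metric, timepoint = tp, mean = ms$mean, sem = ms$sem,
          n = ms$n,
          formatted = if (is.na(ms$sem)) sprintf("%.2f (NA)", ms$mean)
                      else sprintf("%.2f (%.2f)", ms$mean, ms$sem),
          stringsAsFactors = FALSE)
      }
      long <- data.frame(subject = d$subject, timepoint = d$timepoint,
                         value = d[[metric]], stringsAsFactors = FALSE)
      contrasts <- Filter(function(ct)
        all(ct %in% long$timepoint), default_contrasts())
      contrasts <- Filter(function(ct) {
        n_pairs <- length(intersect(long$subject[long$timepoint == ct[1]],
                                    long$subject[long$timepoint == ct[2]]))
        if (n_pairs < 2) {
          warning(sprintf("%s: contrast day %s vs day %s skipped (%d pair)",
                          iso, ct[1], ct[2], n_pairs))
          FALSE
        } else TRUE
      }, contrasts)
      if (length(contrasts)) {
        cmp <- planned_comparisons(long, contrasts)
        cmp$metric <- metric
        cmp$p_formatted <- sprintf("%.2f", cmp$p_two_sided)
        comparison_rows[[length(comparison_rows) + 1L]] <- cmp
      }
    }
    summary_tab <- do.call(rbind, summary_rows)
    comparison_tab <- if (length(comparison_rows))
      do.call(rbind, comparison_rows) else NULL
    write_table(summary_tab,
                file.path(outdir, paste0("summary_", iso, ".tsv")))
    if (!is.null(comparison_tab))
      write_table(comparison_tab,
                  file.path(outdir, paste0("comparisons_", iso, ".tsv")))
    report[[iso]] <- list(per_sample = d, summary = summary_tab,
                          comparisons = comparison_tab)
  }
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       dataframe = "rows")
  invisible(report)
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `run`, `report`, `all`.  Flags: `--config
#' PATH` (required), `--outdir PATH`, `--seed INT`, `--isotype {IgM,IgG}`
#' (restricts the manifest).
#'
#' @param args character vector of command-line arguments.
#' @return integer exit code (0 on full success).
#' @export
rslb_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: bovcdr3 <simulate|run|report|all> --config PATH",
    "[--outdir PATH] [--seed INT] [--isotype IgM|IgG]")
  if (!length(args) || args[1] %in% c("-h", "--help")) {
    message(usage)
    return(0L)
  }
  cmd <- args[1]
  if (!cmd %in% c("simulate", "run", "report", "all")) {
    message("unknown subcommand: ", cmd, "\n", usage)
    return(2L)
  }
  opts <- list()
  rest <- args[-1]
  i <- 1L
  while (i <= length(rest)) {
    key <- rest[i]
    if (!startsWith(key, "--") || i == length(rest)) {
      message("malformed arguments near '", key, "'\n", usage)
      return(2L)
    }
    opts[[substring(key, 3)]] <- rest[i + 1L]
    i <- i + 2L
  }
  if (is.null(opts$config)) {
    message("--config is required\n", usage)
    return(2L)
  }
  code <- tryCatch({
    config <- load_run_config(opts$config)
    if (!is.null(opts$outdir)) config$outdir <- opts$outdir
    if (!is.null(opts$seed)) config$seed <- as.integer(opts$seed)
    if (!is.null(opts$isotype)) {
      config$samples <- config$samples[config$samples$isotype ==
                                         opts$isotype, , drop = FALSE]
      if (!nrow(config$samples)) stop("no samples for isotype ", opts$isotype)
    }
    failed <- 0L
    if (cmd %in% c("simulate", "all")) cmd_simulate(config)
    if (cmd %in% c("run", "all")) {
      failed <- cmd_run(config)$n_failed
    }
    if (cmd %in% c("report", "all")) cmd_report(config)
    if (failed > 0L) 1L else 0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  code
}
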