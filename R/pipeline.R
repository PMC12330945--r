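#' Assemble a pipeline run configuration
#'
#' A run configuration carries every tunable of the pipeline: either an
#' input abundance table path or a simulator block, the fit settings, the
#' shift-classification knobs, the DEP cutoff, optional CETSA input, the
#' output directory and the global seed. It can come from
#' [read_run_config()] (YAML) or be built in code; [run_pipeline()]
#' writes the fully resolved copy next to its outputs so a run is
#' reproducible from its artifacts alone.
#'
#' @param input optional path to a long-format abundance TSV/CSV.
#' @param simulator optional list of [sim_config()] arguments (ignored
#'   fields error); used when \code{input} is \code{NULL}.
#' @param fit list of [fit_settings()] arguments.
#' @param shifts list with \code{delta_threshold}, \code{q_cutoff},
#'   \code{mode}.
#' @param dep list with \code{q_cutoff}.
#' @param cetsa optional list with \code{input} (path to a densitometry
#'   TSV) and \code{method}.
#' @param output_dir directory for artifacts (created if needed).
#' @param seed global integer seed, fanned out deterministically to named
#'   per-stage substreams.
#' @param dialect table dialect, \code{"tab"} or \code{"comma"}.
#' @param log_level \code{"quiet"}, \code{"info"} or \code{"debug"}.
#' @param top_k number of top-ranked candidates echoed in the report.
#' @return a list of class \code{"run_config"}.
#' @export
run_config <- function(input = NULL, simulator = NULL, fit = list(),
                       shifts = list(), dep = list(), cetsa = NULL,
                       output_dir = "meltshift_out", seed = 1L,
                       dialect = c("tab", "comma"),
                       log_level = c("info", "quiet", "debug"),
                       top_k = 10L) {
  dialect <- match.arg(dialect)
  log_level <- match.arg(log_level)
  if (is.null(input) && is.null(simulator)) {
    stop("validation error: config needs either `input` or a `simulator` ",
         "block", call. = FALSE)
  }
  shifts <- utils::modifyList(list(delta_threshold = 2.0, q_cutoff = 0.05,
                                   mode = "proteome_null"), shifts)
  dep <- utils::modifyList(list(q_cutoff = 0.05), dep)
  structure(list(input = input, simulator = simulator, fit = fit,
                 shifts = shifts, dep = dep, cetsa = cetsa,
                 output_dir = output_dir, seed = as.integer(seed),
                 dialect = dialect, log_level = log_level,
                 top_k = as.integer(top_k)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file with the fields of [run_config()].
#' @return a \code{run_config}.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

# Deterministic per-stage substream seed derived from the global seed and
# the stage name; kept within the 32-bit integer range.
substream_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

pipeline_log <- function(config, level, ...) {
  levels <- c(quiet = 0, info = 1, debug = 2)
  if (levels[[config$log_level]] >= levels[[level]]) {
    message("[meltshift] ", sprintf(...))
  }
}

#' Run the full melting-shift pipeline
#'
#' Executes simulate (or load) -> validate -> normalize/fit -> shift
#' classification -> DEP -> optional CETSA -> report, persisting every
#' intermediate under the configured output directory: the resolved
#' configuration (\code{config.yaml}), the abundance table and ground
#' truth when simulated, the shift table (\code{shifts.tsv}), the DEP
#' table (\code{dep.tsv}), the CETSA results (\code{cetsa.tsv}) and the
#' run report (\code{report.yaml}). Fully deterministic given the seed.
#' Stage failures abort with the stage name in the error.
#'
#' @param config a [run_config()], or a path to a YAML file for
#'   [read_run_config()].
#' @return a \code{run_report} list (see [make_report()]), invisibly
#'   carrying the shift and DEP tables as attributes.
#' @examples
#' \donttest{
#' cfg <- run_config(simulator = list(n_proteins = 40, seed = 5),
#'                   output_dir = tempfile("run"), log_level = "quiet")
#' rep <- run_pipeline(cfg)
#' rep$counts
#' }
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage `%s` failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  # -- acquire ---------------------------------------------------------
  truth <- NULL
  tab <- stage("input", {
    if (!is.null(config$input)) {
      pipeline_log(config, "info", "reading %s", config$input)
      read_abundance_table(config$input, dialect = config$dialect)
    } else {
      sim_args <- config$simulator
      sim_args$seed <- substream_seed(config$seed, "simulate")
      pipeline_log(config, "info",
                   "simulating dataset (substream seed %d)", sim_args$seed)
      sim <- simulate_dataset(do.call(sim_config, sim_args))
      truth <<- sim$truth
      write_abundance_table(sim$table,
                            file.path(config$output_dir, "abundance.tsv"))
      utils::write.table(sim$truth,
                         file.path(config$output_dir, "truth.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      sim$table
    }
  })

  # -- fit + shifts ----------------------------------------------------
  fitset <- do.call(fit_settings, config$fit)
  pipeline_log(config, "info",
               "fit: min_points=%d r2_min=%g plateau_max=%g; shifts: |dTm|>=%g q<=%g mode=%s",
               fitset$min_points, fitset$r2_min, fitset$plateau_max,
               config$shifts$delta_threshold, config$shifts$q_cutoff,
               config$shifts$mode)
  shift_tab <- stage("shifts", {
    tpp_shifts(tab, settings = fitset,
               delta_threshold = config$shifts$delta_threshold,
               q_cutoff = config$shifts$q_cutoff,
               mode = config$shifts$mode)
  })
  write_shift_table(shift_tab, file.path(config$output_dir, "shifts.tsv"))

  # -- differential expression ----------------------------------------
  dep_tab <- stage("dep", {
    classify_dep(tab, q_cutoff = config$dep$q_cutoff)
  })
  utils::write.table(
    within(dep_tab, {
      log2_fold_change <- signif(log2_fold_change, 6)
      p_value <- signif(p_value, 6)
      q_value <- signif(q_value, 6)
    }),
    file.path(config$output_dir, "dep.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE, na = "")

  # -- CETSA (optional) ------------------------------------------------
  cetsa_res <- NULL
  if (!is.null(config$cetsa) && !is.null(config$cetsa$input)) {
    cetsa_res <- stage("cetsa", {
      ct <- read_cetsa_table(config$cetsa$input, dialect = config$dialect)
      method <- if (is.null(config$cetsa$method)) "auto" else config$cetsa$method
      out <- lapply(split(ct, ct$target_name), function(d) {
        r <- cetsa_delta_tm(d[d$condition == "vehicle", , drop = FALSE],
                            d[d$condition == "treated", , drop = FALSE],
                            method = method)
        data.frame(target_name = d$target_name[1],
                   tm_control = r$tm_control, tm_treated = r$tm_treated,
                   delta_tm = r$delta_tm, p_value = r$p_value,
                   n_replicate_pairs = r$n_replicate_pairs,
                   stringsAsFactors = FALSE)
      })
      do.call(rbind, out)
    })
    utils::write.table(cetsa_res, file.path(config$output_dir, "cetsa.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  }

  # -- resolved config + report ---------------------------------------
  resolved <- config
  resolved$fit <- unclass(do.call(fit_settings, config$fit))
  cfg_path <- file.path(config$output_dir, "config.yaml")
  yaml::write_yaml(lapply(unclass(resolved), function(x) {
    if (is.function(x)) "<function>" else x
  }), cfg_path)

  report <- make_report(config$output_dir, top_k = config$top_k)
  pipeline_log(config, "info",
               "done: %d proteins, %d QC pass, %d stabilized, %d destabilized",
               report$counts$proteins_in, report$counts$qc_pass,
               report$counts$stabilized, report$counts$destabilized)
  attr(report, "shift_table") <- shift_tab
  attr(report, "dep_table") <- dep_tab
  attr(report, "truth") <- truth
  attr(report, "cetsa") <- cetsa_res
  invisible(report)
}

#' Build a run report from persisted intermediates
#'
#' Reads the artifacts a pipeline run left in \code{output_dir}
#' (\code{shifts.tsv}, \code{dep.tsv}, \code{config.yaml}) and assembles
#' the deterministic summary: class counts satisfying the partition
#' invariant, the top-k candidate table ordered by rank, DEP counts, the
#' package version, the MD5 hash of the resolved configuration and the
#' seed. Rerunning on the same intermediates gives an identical report.
#'
#' @param output_dir directory holding the intermediates.
#' @param top_k rows of the candidate table to include (truncated to the
#'   table size).
#' @return a list of class \code{"run_report"}.
#' @export
make_report <- function(output_dir, top_k = 10L) {
  shifts_path <- file.path(output_dir, "shifts.tsv")
  if (!file.exists(shifts_path)) {
    stop("missing intermediate: ", shifts_path, call. = FALSE)
  }
  st <- utils::read.table(shifts_path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (nrow(st) == 0) stop("empty shift table: ", shifts_path, call. = FALSE)
  cfg_path <- file.path(output_dir, "config.yaml")
  cfg <- if (file.exists(cfg_path)) yaml::read_yaml(cfg_path) else list()
  counts <- list(
    proteins_in = nrow(st),
    qc_pass = sum(st$stability_class != "qc_failed"),
    stabilized = sum(st$stability_class == "stabilized"),
    destabilized = sum(st$stability_class == "destabilized"),
    unchanged = sum(st$stability_class == "unchanged"),
    qc_failed = sum(st$stability_class == "qc_failed"))
  top <- st[order(is.na(st$rank), st$rank), , drop = FALSE]
  top <- utils::head(top[c("protein_id", "tm_control", "tm_treated",
                           "delta_tm", "q_value", "stability_class",
                           "rank")], min(top_k, nrow(top)))
  rownames(top) <- NULL
  dep_path <- file.path(output_dir, "dep.tsv")
  dep_counts <- NULL
  if (file.exists(dep_path)) {
    dp <- utils::read.table(dep_path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    dep_counts <- list(up = sum(dp$dep_class == "up"),
                       down = sum(dp$dep_class == "down"),
                       unchanged = sum(dp$dep_class == "unchanged"),
                       undefined = sum(dp$dep_class == "undefined"))
  }
  report <- list(
    counts = counts, top_candidates = top, dep_counts = dep_counts,
    version = as.character(utils::packageVersion("meltshift")),
    config_hash = if (file.exists(cfg_path)) {
      unname(tools::md5sum(cfg_path))
    } else {
      NA_character_
    },
    seed = cfg$seed,
    thresholds = cfg$shifts)
  class(report) <- "run_report"
  yaml::write_yaml(lapply(unclass(report), function(x) {
    if (is.data.frame(x)) as.list(x) else x
  }), file.path(output_dir, "report.yaml"))
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("meltshift run report (v", x$version, ")\n", sep = "")
  if (!is.null(x$seed)) cat("  seed:", x$seed, "\n")
  cat("  config hash:", x$config_hash, "\n")
  c <- x$counts
  cat(sprintf("  proteins: %d in, %d QC pass\n", c$proteins_in, c$qc_pass))
  cat(sprintf("  stabilized %d | destabilized %d | unchanged %d | qc_failed %d\n",
              c$stabilized, c$destabilized, c$unchanged, c$qc_failed))
  if (!is.null(x$dep_counts)) {
    cat(sprintf("  DEP: %d up, %d down\n", x$dep_counts$up,
                x$dep_counts$down))
  }
  cat("  top candidates:\n")
  print.data.frame(x$top_candidates, row.names = FALSE, digits = 4)
  invisible(x)
}
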