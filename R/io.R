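#' Read and validate a long-format abundance table
#'
#' Reads a TSV or CSV protein quantification table with mandatory header
#' and columns \code{protein_id}, \code{condition}, \code{replicate},
#' \code{temperature_c}, \code{intensity} (\code{gene_symbol} optional).
#' \code{condition} must be \code{"treated"} or \code{"vehicle"};
#' intensities must be non-negative (zero is valid: fully denatured or
#' undetected); missing observations are represented by row absence, not
#' sentinels. Rows with non-parseable numerics are rejected with their
#' line numbers (an error under \code{strict}, a warning plus drop
#' otherwise). Duplicate \code{(protein_id, condition, replicate,
#' temperature_c)} tuples are an integrity error.
#'
#' @param path file path.
#' @param dialect \code{"tab"} (default) or \code{"comma"}.
#' @param strict if \code{TRUE}, any malformed row is an error.
#' @return the validated data frame, with a \code{"load_report"} attribute
#'   (record count, distinct proteins/conditions/temperatures, rows
#'   dropped).
#' @export
read_abundance_table <- function(path, dialect = c("tab", "comma"),
                                 strict = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  sep <- if (dialect == "tab") "\t" else ","
  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           colClasses = "character", quote = "\"",
                           comment.char = "", fileEncoding = "UTF-8",
                           check.names = TRUE, stringsAsFactors = FALSE)
  required <- c("protein_id", "condition", "replicate", "temperature_c",
                "intensity")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop("schema error: missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(raw) == 0) stop("empty table: ", path, call. = FALSE)

  replicate <- suppressWarnings(as.integer(raw$replicate))
  temperature <- suppressWarnings(as.numeric(raw$temperature_c))
  intensity <- suppressWarnings(as.numeric(raw$intensity))
  bad <- !is.finite(replicate) | !is.finite(temperature) |
    !is.finite(intensity) | !nzchar(raw$protein_id)
  if (any(bad)) {
    lines <- which(bad) + 1L  # header is line 1
    msg <- sprintf("%d malformed row(s) at line(s): %s", sum(bad),
                   paste(utils::head(lines, 20), collapse = ", "))
    if (strict) stop(msg, call. = FALSE)
    warning(msg, "; rows dropped", call. = FALSE)
  }
  tab <- data.frame(
    protein_id = raw$protein_id,
    gene_symbol = if ("gene_symbol" %in% names(raw)) raw$gene_symbol else NA_character_,
    condition = raw$condition,
    replicate = replicate,
    temperature_c = temperature,
    intensity = intensity,
    stringsAsFactors = FALSE)[!bad, , drop = FALSE]
  rownames(tab) <- NULL

  bad_cond <- !tab$condition %in% c("treated", "vehicle")
  if (any(bad_cond)) {
    stop("schema error: `condition` must be 'treated' or 'vehicle'; found: ",
         paste(unique(tab$condition[bad_cond]), collapse = ", "),
         call. = FALSE)
  }
  if (any(tab$intensity < 0)) {
    stop("integrity error: negative intensity values present", call. = FALSE)
  }
  if (any(tab$replicate < 1)) {
    stop("integrity error: `replicate` must be a positive integer",
         call. = FALSE)
  }
  key <- paste(tab$protein_id, tab$condition, tab$replicate,
               tab$temperature_c, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    first <- tab[which(dup)[1], ]
    stop(sprintf(paste0("integrity error: duplicate (protein_id, condition, ",
                        "replicate, temperature_c) tuple: (%s, %s, %d, %g)"),
                 first$protein_id, first$condition, first$replicate,
                 first$temperature_c), call. = FALSE)
  }
  attr(tab, "load_report") <- list(
    n_records = nrow(tab),
    n_dropped = sum(bad),
    n_proteins = length(unique(tab$protein_id)),
    conditions = sort(unique(tab$condition)),
    temperatures = sort(unique(tab$temperature_c)),
    n_replicates = max(tab$replicate))
  tab
}

#' Write an abundance table
#'
#' Deterministic serialization of a long-format abundance table in the
#' schema read by [read_abundance_table()].
#'
#' @param table the abundance data frame.
#' @param path output path.
#' @param dialect \code{"tab"} or \code{"comma"}.
#' @return \code{path}, invisibly.
#' @export
write_abundance_table <- function(table, path, dialect = c("tab", "comma")) {
  dialect <- match.arg(dialect)
  cols <- c("protein_id", "gene_symbol", "condition", "replicate",
            "temperature_c", "intensity")
  cols <- intersect(cols, names(table))
  utils::write.table(table[cols], path,
                     sep = if (dialect == "tab") "\t" else ",",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Convert a wide per-temperature table to the long format
#'
#' Accepts tables with one row per protein/condition/replicate and one
#' intensity column per temperature. Temperature columns are recognized by
#' a numeric-parseable name, optionally prefixed with \code{"T"} or
#' \code{"X"} (e.g. \code{"43"}, \code{"T46.4"}, \code{"X49.8"}).
#'
#' @param wide the wide data frame; must contain \code{protein_id},
#'   \code{condition} and \code{replicate} columns.
#' @return a long-format data frame in the [read_abundance_table()] schema.
#'   \code{NA} intensities become absent rows.
#' @export
wide_to_long <- function(wide) {
  stopifnot(all(c("protein_id", "condition", "replicate") %in% names(wide)))
  id_cols <- intersect(c("protein_id", "gene_symbol", "condition",
                         "replicate"), names(wide))
  temp_cols <- setdiff(names(wide), id_cols)
  temps <- suppressWarnings(as.numeric(sub("^[TX]", "", temp_cols)))
  if (any(is.na(temps))) {
    stop("schema error: non-temperature column(s): ",
         paste(temp_cols[is.na(temps)], collapse = ", "), call. = FALSE)
  }
  out <- do.call(rbind, lapply(seq_along(temp_cols), function(j) {
    d <- wide[id_cols]
    d$temperature_c <- temps[j]
    d$intensity <- as.numeric(wide[[temp_cols[j]]])
    d
  }))
  out <- out[is.finite(out$intensity), , drop = FALSE]
  out <- out[order(out$protein_id, out$condition, out$replicate,
                   out$temperature_c), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a CETSA densitometry table
#'
#' Columns: \code{target_name}, \code{condition} (treated/vehicle),
#' \code{replicate}, \code{temperature_c}, \code{band_intensity}.
#'
#' @inheritParams read_abundance_table
#' @return validated data frame.
#' @export
read_cetsa_table <- function(path, dialect = c("tab", "comma")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.table(path, sep = if (dialect == "tab") "\t" else ",",
                           header = TRUE, stringsAsFactors = FALSE,
                           fileEncoding = "UTF-8")
  required <- c("target_name", "condition", "replicate", "temperature_c",
                "band_intensity")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols)) {
    stop("schema error: missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (any(!tab$condition %in% c("treated", "vehicle"))) {
    stop("schema error: `condition` must be 'treated' or 'vehicle'",
         call. = FALSE)
  }
  if (any(tab$band_intensity < 0)) {
    stop("integrity error: negative band intensities", call. = FALSE)
  }
  tab
}

#' Write a melting-point shift table
#'
#' Serializes a [tpp_shifts()] result with a fixed column order, rows
#' ordered by rank (QC-failed rows last, by protein id), and floating
#' values at 6 significant digits, so identical results always produce
#' byte-identical files. QC-failed proteins keep their row, with
#' \code{qc_flags} populated and an empty rank.
#'
#' @param results a shift table data frame (class \code{"shift_table"}).
#' @param path output path.
#' @param dialect \code{"tab"} or \code{"comma"}.
#' @return \code{path}, invisibly.
#' @export
write_shift_table <- function(results, path, dialect = c("tab", "comma")) {
  dialect <- match.arg(dialect)
  if (is.null(results) || nrow(results) == 0) {
    stop("write_shift_table: empty results", call. = FALSE)
  }
  cols <- c("protein_id", "tm_control", "tm_treated", "delta_tm",
            "z_score", "p_value", "q_value", "stability_class", "rank",
            "r_squared_control", "r_squared_treated",
            "plateau_control", "plateau_treated",
            "rmse_control", "rmse_treated",
            "n_points_control", "n_points_treated",
            "converged_control", "converged_treated", "qc_flags")
  cols <- intersect(cols, names(results))
  out <- results[cols]
  o <- order(is.na(out$rank), out$rank, out$protein_id)
  out <- out[o, , drop = FALSE]
  for (nm in names(out)) {
    if (is.double(out[[nm]])) out[[nm]] <- signif(out[[nm]], 6)
  }
  utils::write.table(out, path, sep = if (dialect == "tab") "\t" else ",",
                     quote = FALSE, row.names = FALSE, na = "",
                     fileEncoding = "UTF-8")
  invisible(path)
}
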