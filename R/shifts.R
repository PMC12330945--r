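#' Melting-point shift between two fits
#'
#' The treated-minus-control melting-point difference; positive means the
#' ligand stabilized the protein against heat denaturation, negative means
#' destabilization. Antisymmetric under swapping the conditions.
#'
#' @param fit_control,fit_treated \code{unfolding_fit} objects.
#' @return delta Tm in degrees Celsius, or \code{NA_real_} when either
#'   melting point is undefined.
#' @export
compute_shift <- function(fit_control, fit_treated) {
  if (is.na(fit_control$tm) || is.na(fit_treated$tm)) return(NA_real_)
  fit_treated$tm - fit_control$tm
}

#' Significance scores for melting-point shifts
#'
#' Two modes. \code{proteome_null} (default; needs no replicate
#' structure): each protein's shift is standardized against the proteome
#' itself, \eqn{z = (\Delta T_m - \mathrm{median}) / (1.4826 \cdot
#' \mathrm{MAD})} over all QC-passing proteins, with a two-sided normal
#' p-value; the robust location/scale make the null estimate insensitive
#' to the minority of true binders. A floor of 1e-6 degrees on the scale
#' guards degenerate (all-identical) nulls, where every z is 0.
#' \code{replicate}: per protein, a one-sample two-sided t-test of the
#' replicate-wise shifts against 0 (at least 2 values required; proteins
#' with fewer get \code{NA}). Both modes are followed by
#' Benjamini-Hochberg adjustment across proteins.
#'
#' @param shifts for \code{proteome_null}: a named numeric vector of per-
#'   protein delta Tm values. For \code{replicate}: a named list of
#'   numeric vectors (replicate-wise delta Tm values per protein).
#' @param mode \code{"proteome_null"} or \code{"replicate"}.
#' @return data frame with columns \code{protein_id}, \code{z_score},
#'   \code{p_value}, \code{q_value}.
#' @export
significance_scores <- function(shifts, mode = c("proteome_null",
                                                 "replicate")) {
  mode <- match.arg(mode)
  if (mode == "proteome_null") {
    stopifnot(is.numeric(shifts))
    ok <- is.finite(shifts)
    if (sum(ok) < 3) {
      stop("proteome_null mode needs at least 3 QC-passing proteins",
           call. = FALSE)
    }
    center <- stats::median(shifts[ok])
    scale <- max(stats::mad(shifts[ok]), 1e-6)  # 1.4826 * MAD, floored
    z <- (shifts - center) / scale
    p <- 2 * stats::pnorm(-abs(z))
    ids <- names(shifts)
  } else {
    stopifnot(is.list(shifts))
    z <- p <- rep(NA_real_, length(shifts))
    for (i in seq_along(shifts)) {
      d <- shifts[[i]][is.finite(shifts[[i]])]
      if (length(d) < 2) next
      if (stats::sd(d) == 0) {
        # degenerate: identical replicate shifts
        z[i] <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
        p[i] <- if (mean(d) == 0) 1 else 0
      } else {
        tt <- stats::t.test(d, mu = 0)
        z[i] <- unname(tt$statistic)
        p[i] <- tt$p.value
      }
    }
    ids <- names(shifts)
  }
  q <- rep(NA_real_, length(p))
  q[is.finite(p)] <- stats::p.adjust(p[is.finite(p)], method = "BH")
  data.frame(protein_id = if (is.null(ids)) as.character(seq_along(p)) else ids,
             z_score = as.numeric(z), p_value = p, q_value = q,
             stringsAsFactors = FALSE)
}

#' Classify and rank melting-point shifts
#'
#' Applies the stability calls: \code{stabilized} when delta Tm is at
#' least \code{+delta_threshold} with \code{q_value <= q_cutoff};
#' \code{destabilized} symmetric at \code{-delta_threshold};
#' \code{unchanged} otherwise; rows flagged by QC stay
#' \code{qc_failed}. QC-passing proteins are ranked by descending
#' |delta Tm|, ties broken by ascending q-value then lexicographic
#' protein id, so ranking is fully deterministic.
#'
#' @param results data frame with at least \code{protein_id},
#'   \code{delta_tm}, \code{q_value} and \code{qc_pass} (logical)
#'   columns, one row per protein.
#' @param delta_threshold minimum |delta Tm| (degrees Celsius) to call a
#'   shift.
#' @param q_cutoff FDR cutoff.
#' @return the input with \code{stability_class} and \code{rank} columns
#'   added (rank \code{NA} for QC-failed rows), of class
#'   \code{"shift_table"}. Classification thresholds are attached as
#'   attributes.
#' @export
classify_and_rank <- function(results, delta_threshold = 2.0,
                              q_cutoff = 0.05) {
  if (is.null(results) || nrow(results) == 0) {
    stop("classify_and_rank: empty input", call. = FALSE)
  }
  stopifnot(all(c("protein_id", "delta_tm", "q_value", "qc_pass") %in%
                  names(results)))
  cls <- rep("unchanged", nrow(results))
  sig <- !is.na(results$q_value) & results$q_value <= q_cutoff &
    !is.na(results$delta_tm)
  cls[sig & results$delta_tm >= delta_threshold] <- "stabilized"
  cls[sig & results$delta_tm <= -delta_threshold] <- "destabilized"
  cls[!results$qc_pass] <- "qc_failed"
  results$stability_class <- cls

  results$rank <- NA_integer_
  pass <- which(results$qc_pass)
  if (length(pass)) {
    o <- order(-abs(results$delta_tm[pass]), results$q_value[pass],
               results$protein_id[pass])
    results$rank[pass[o]] <- seq_along(pass)
  }
  structure(results, class = c("shift_table", "data.frame"),
            delta_threshold = delta_threshold, q_cutoff = q_cutoff)
}

#' Proteome-wide melting-point shift analysis
#'
#' The main driver: normalizes a long-format abundance table to the
#' lowest-temperature reference ([normalize_to_reference()]), fits the
#' unfolding model per protein and condition pooling replicates
#' ([fit_unfolding()]), applies the QC filter ([qc_filter()]), computes
#' delta Tm with significance scores ([significance_scores()]) and
#' classifies and ranks candidates ([classify_and_rank()]).
#'
#' @param table abundance data frame (schema of
#'   [read_abundance_table()]).
#' @param settings a [fit_settings()].
#' @param delta_threshold,q_cutoff classification knobs, see
#'   [classify_and_rank()].
#' @param mode significance mode, see [significance_scores()]. In
#'   \code{"replicate"} mode each replicate pair is additionally fit
#'   separately to obtain replicate-wise shifts.
#' @return a \code{shift_table} data frame, one row per protein, with Tm
#'   values, delta Tm, significance, class, rank, per-condition fit
#'   diagnostics and accumulated \code{qc_flags}.
#' @examples
#' sim <- simulate_dataset(sim_config(n_proteins = 30, seed = 1))
#' st <- tpp_shifts(sim$table)
#' summary(st)
#' @export
tpp_shifts <- function(table, settings = fit_settings(),
                       delta_threshold = 2.0, q_cutoff = 0.05,
                       mode = c("proteome_null", "replicate")) {
  mode <- match.arg(mode)
  norm <- normalize_to_reference(table)
  fits <- fit_all_curves(norm$curves, settings)

  ids <- sort(unique(table$protein_id))
  rows <- vector("list", length(ids))
  rep_shifts <- if (mode == "replicate") vector("list", length(ids)) else NULL
  empty_fit <- fit_unfolding(data.frame(temperature_c = numeric(),
                                        rel_abundance = numeric()),
                             settings = settings)
  for (k in seq_along(ids)) {
    pid <- ids[k]
    fc <- fits[[pid]][["vehicle"]]
    ft <- fits[[pid]][["treated"]]
    if (is.null(fc)) fc <- empty_fit
    if (is.null(ft)) ft <- empty_fit
    qc <- qc_filter(fc, ft, settings)
    flags <- qc$reasons
    ex <- norm$excluded
    if (nrow(ex) && any(ex$protein_id == pid)) {
      flags <- c(flags, "no_reference")
    }
    rows[[k]] <- data.frame(
      protein_id = pid,
      tm_control = fc$tm, tm_treated = ft$tm,
      delta_tm = compute_shift(fc, ft),
      qc_pass = qc$pass,
      r_squared_control = fc$r_squared, r_squared_treated = ft$r_squared,
      plateau_control = unname(fc$coefficients["p"]),
      plateau_treated = unname(ft$coefficients["p"]),
      rmse_control = fc$rmse, rmse_treated = ft$rmse,
      n_points_control = fc$n_points, n_points_treated = ft$n_points,
      converged_control = fc$converged, converged_treated = ft$converged,
      qc_flags = paste(unique(flags), collapse = ";"),
      stringsAsFactors = FALSE)
    if (mode == "replicate") {
      rep_shifts[[k]] <- replicate_shifts(norm$curves, pid, settings)
    }
  }
  res <- do.call(rbind, rows)

  if (mode == "proteome_null") {
    pass <- res$qc_pass & is.finite(res$delta_tm)
    if (sum(pass) < 3) {
      stop("proteome_null mode needs at least 3 QC-passing proteins",
           call. = FALSE)
    }
    d <- res$delta_tm
    names(d) <- res$protein_id
    # null estimated from QC-passing proteins only
    center <- stats::median(d[pass])
    scale <- max(stats::mad(d[pass]), 1e-6)
    z <- (d - center) / scale
    p <- 2 * stats::pnorm(-abs(z))
    p[!pass] <- NA_real_
    sc <- data.frame(protein_id = res$protein_id, z_score = as.numeric(z),
                     p_value = p, q_value = NA_real_,
                     stringsAsFactors = FALSE)
    sc$q_value[pass] <- stats::p.adjust(p[pass], method = "BH")
    sc$z_score[!pass] <- NA_real_
  } else {
    names(rep_shifts) <- ids
    sc <- significance_scores(rep_shifts, mode = "replicate")
  }
  res <- merge(res, sc, by = "protein_id", sort = TRUE)
  res <- classify_and_rank(res, delta_threshold = delta_threshold,
                           q_cutoff = q_cutoff)
  attr(res, "mode") <- mode
  res
}

# Replicate-wise delta Tm values for one protein: fit each replicate's
# control and treated series separately (min_points relaxed to the grid
# available) and pair by replicate index.
replicate_shifts <- function(curves, pid, settings) {
  d <- curves[curves$protein_id == pid, , drop = FALSE]
  reps <- sort(unique(d$replicate))
  out <- numeric(0)
  for (r in reps) {
    dc <- d[d$replicate == r & d$condition == "vehicle", , drop = FALSE]
    dt <- d[d$replicate == r & d$condition == "treated", , drop = FALSE]
    if (!nrow(dc) || !nrow(dt)) next
    fc <- fit_unfolding(dc, settings = settings)
    ft <- fit_unfolding(dt, settings = settings)
    s <- compute_shift(fc, ft)
    if (is.finite(s)) out <- c(out, s)
  }
  out
}

#' @export
print.shift_table <- function(x, n = 10, ...) {
  cat(sprintf("Melting-point shift table: %d proteins (|dTm| >= %g degC, q <= %g)\n",
              nrow(x), attr(x, "delta_threshold"), attr(x, "q_cutoff")))
  counts <- table(factor(x$stability_class,
                         levels = c("stabilized", "destabilized",
                                    "unchanged", "qc_failed")))
  cat(sprintf("  stabilized %d | destabilized %d | unchanged %d | qc_failed %d\n",
              counts[["stabilized"]], counts[["destabilized"]],
              counts[["unchanged"]], counts[["qc_failed"]]))
  top <- x[order(is.na(x$rank), x$rank), , drop = FALSE]
  top <- utils::head(top[c("protein_id", "tm_control", "tm_treated",
                           "delta_tm", "q_value", "stability_class",
                           "rank")], n)
  print.data.frame(top, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
summary.shift_table <- function(object, ...) {
  counts <- table(factor(object$stability_class,
                         levels = c("stabilized", "destabilized",
                                    "unchanged", "qc_failed")))
  out <- list(n = nrow(object), counts = as.list(counts),
              delta_threshold = attr(object, "delta_threshold"),
              q_cutoff = attr(object, "q_cutoff"),
              mode = attr(object, "mode"))
  class(out) <- "summary.shift_table"
  out
}

#' @export
print.summary.shift_table <- function(x, ...) {
  cat(sprintf("%d proteins; thresholds |dTm| >= %g degC, q <= %g (mode %s)\n",
              x$n, x$delta_threshold, x$q_cutoff,
              if (is.null(x$mode)) "?" else x$mode))
  cat(sprintf("stabilized %d, destabilized %d, unchanged %d, qc_failed %d\n",
              x$counts$stabilized, x$counts$destabilized,
              x$counts$unchanged, x$counts$qc_failed))
  invisible(x)
}

#' Two-fold differential-expression classifier
#'
#' Compares treated and vehicle abundances at the lowest (non-denaturing)
#' temperature. Per protein: the fold change of replicate-mean
#' intensities, a Welch two-sample t-test on log intensities, and
#' Benjamini-Hochberg adjustment across proteins. A protein is called
#' \code{up} when its fold change is two or more ("twice or more" is
#' inclusive) with \code{q <= q_cutoff}, \code{down} when the fold change
#' is 0.5 or less with \code{q <= q_cutoff}, else \code{unchanged}.
#' Proteins with a zero control mean have an undefined fold change and are
#' flagged.
#'
#' @param table abundance data frame (schema of
#'   [read_abundance_table()]).
#' @param q_cutoff FDR cutoff.
#' @param reference_temperature temperature at which to compare; defaults
#'   to the lowest in the table.
#' @return data frame with columns \code{protein_id},
#'   \code{log2_fold_change}, \code{p_value}, \code{q_value},
#'   \code{dep_class} (\code{up}/\code{down}/\code{unchanged}/
#'   \code{undefined}).
#' @export
classify_dep <- function(table, q_cutoff = 0.05,
                         reference_temperature = NULL) {
  if (is.null(reference_temperature)) {
    reference_temperature <- min(table$temperature_c)
  }
  d <- table[table$temperature_c == reference_temperature, , drop = FALSE]
  ids <- sort(unique(d$protein_id))
  fc <- p <- rep(NA_real_, length(ids))
  flag <- rep(FALSE, length(ids))
  for (k in seq_along(ids)) {
    dd <- d[d$protein_id == ids[k], , drop = FALSE]
    xt <- dd$intensity[dd$condition == "treated"]
    xc <- dd$intensity[dd$condition == "vehicle"]
    if (length(xt) < 2 || length(xc) < 2) { flag[k] <- TRUE; next }
    if (mean(xc) == 0) { flag[k] <- TRUE; next }
    fc[k] <- mean(xt) / mean(xc)
    lt <- log(xt[xt > 0]); lc <- log(xc[xc > 0])
    if (length(lt) >= 2 && length(lc) >= 2 &&
        (stats::sd(lt) > 0 || stats::sd(lc) > 0)) {
      p[k] <- stats::t.test(lt, lc)$p.value
    } else {
      p[k] <- if (isTRUE(all.equal(mean(lt), mean(lc)))) 1 else NA_real_
    }
  }
  q <- rep(NA_real_, length(p))
  q[is.finite(p)] <- stats::p.adjust(p[is.finite(p)], method = "BH")
  cls <- rep("unchanged", length(ids))
  cls[!is.na(fc) & fc >= 2 & !is.na(q) & q <= q_cutoff] <- "up"
  cls[!is.na(fc) & fc <= 0.5 & !is.na(q) & q <= q_cutoff] <- "down"
  cls[flag] <- "undefined"
  data.frame(protein_id = ids, log2_fold_change = log2(fc), p_value = p,
             q_value = q, dep_class = cls, stringsAsFactors = FALSE)
}
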