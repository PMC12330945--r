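#' Normalize abundances to the lowest-temperature reference
#'
#' Converts raw per-protein intensities into relative (fraction-folded
#' scale) melting curves: within each protein, condition and replicate,
#' every intensity is divided by that replicate's intensity at its lowest
#' available temperature, so the reference point becomes exactly 1.
#' Replicates whose reference intensity is zero or missing cannot be
#' normalized and are excluded with reason code \code{"no_reference"}.
#'
#' The operation is idempotent: normalizing an already-normalized curve
#' leaves it unchanged.
#'
#' @param table a long-format abundance table with columns
#'   \code{protein_id}, \code{condition}, \code{replicate},
#'   \code{temperature_c}, \code{intensity} (see
#'   [read_abundance_table()]).
#' @return list with \code{curves}: a data frame with columns
#'   \code{protein_id}, \code{condition}, \code{replicate},
#'   \code{temperature_c}, \code{rel_abundance}; and \code{excluded}: a
#'   data frame (\code{protein_id}, \code{condition}, \code{replicate},
#'   \code{reason}) of dropped replicate series.
#' @examples
#' tab <- data.frame(protein_id = "P1", condition = "vehicle", replicate = 1,
#'                   temperature_c = c(43, 46.4, 49.8, 53.2, 56.6, 60),
#'                   intensity = c(1000, 900, 600, 300, 120, 60))
#' normalize_to_reference(tab)$curves$rel_abundance
#' @export
normalize_to_reference <- function(table) {
  req <- c("protein_id", "condition", "replicate", "temperature_c",
           "intensity")
  stopifnot(all(req %in% names(table)))
  key <- interaction(table$protein_id, table$condition, table$replicate,
                     drop = TRUE, lex.order = TRUE)
  pieces <- split(table[req], key)
  curves <- vector("list", length(pieces))
  excl <- vector("list", length(pieces))
  for (i in seq_along(pieces)) {
    d <- pieces[[i]]
    ref <- d$intensity[which.min(d$temperature_c)]
    if (!is.finite(ref) || ref <= 0) {
      excl[[i]] <- data.frame(protein_id = d$protein_id[1],
                              condition = d$condition[1],
                              replicate = d$replicate[1],
                              reason = "no_reference")
      next
    }
    d$rel_abundance <- d$intensity / ref
    d$intensity <- NULL
    curves[[i]] <- d
  }
  curves <- do.call(rbind, curves[!vapply(curves, is.null, logical(1))])
  excl <- do.call(rbind, excl[!vapply(excl, is.null, logical(1))])
  if (is.null(curves)) {
    curves <- data.frame(protein_id = character(), condition = character(),
                         replicate = integer(), temperature_c = numeric(),
                         rel_abundance = numeric())
  }
  if (is.null(excl)) {
    excl <- data.frame(protein_id = character(), condition = character(),
                       replicate = integer(), reason = character())
  }
  rownames(curves) <- NULL
  rownames(excl) <- NULL
  list(curves = curves, excluded = excl)
}

# Pooled per-protein/condition fits over normalized curves.
# Returns a named list fits[[protein]][[condition]] of unfolding_fit.
fit_all_curves <- function(curves, settings = fit_settings()) {
  by_protein <- split(curves, curves$protein_id)
  lapply(by_protein, function(dp) {
    by_cond <- split(dp, dp$condition, drop = TRUE)
    mapply(function(dc, cond) {
      attr(dc, "protein_id") <- dp$protein_id[1]
      attr(dc, "condition") <- cond
      fit_unfolding(dc, settings = settings)
    }, by_cond, names(by_cond), SIMPLIFY = FALSE)
  })
}
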