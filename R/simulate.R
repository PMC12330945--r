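#' Configuration for the synthetic thermal-proteome generator
#'
#' Bundles and validates all parameters of [simulate_dataset()]. The
#' defaults emulate the structure of a proteome-wide thermal profiling
#' (TPP-TR) experiment on a drug-treated cancer cell line: about 3000
#' proteins quantified at six temperatures evenly spaced from 43 to 60
#' degrees Celsius (step 3.4), treated versus vehicle conditions, three
#' replicates, sigmoidal denaturation with a low-plateau tail,
#' multiplicative label-free quantification noise, a small spiked-in
#' fraction of ligand-stabilized (81/3000) and destabilized (89/3000)
#' targets, and missing values.
#'
#' @param n_proteins number of proteins.
#' @param fraction_stabilized,fraction_destabilized proportions of proteins
#'   spiked with a positive / negative melting-point shift; their sum must
#'   not exceed 1. Spiked counts are \code{round(fraction * n_proteins)}.
#' @param temperatures strictly increasing vector of at least 4
#'   temperatures (degrees Celsius).
#' @param n_replicates replicates per condition.
#' @param slope_range interval (entirely negative) for the slope \code{a}.
#' @param tm_range interval for the control inflection temperature
#'   \code{b} (degrees Celsius).
#' @param plateau_range interval within \code{[0, 0.5)} for the plateau
#'   \code{p}.
#' @param effect_distribution distribution of true |delta Tm| magnitudes
#'   for spiked targets: a single number (constant magnitude), a length-2
#'   interval (uniform draw), or a \code{function(n)} returning \code{n}
#'   positive magnitudes.
#' @param noise_cv linear-scale coefficient of variation of the
#'   multiplicative log-normal quantification noise.
#' @param missing_rate per-observation probability of a missing value
#'   (missing completely at random, in \code{[0, 1)}).
#' @param base_intensity_range interval for the per-protein raw intensity
#'   scale (arbitrary units; drawn log-uniformly).
#' @param seed integer random seed; identical configurations give
#'   bit-identical output.
#' @return a validated list of class \code{"sim_config"}.
#' @export
sim_config <- function(n_proteins = 3000,
                       fraction_stabilized = 81 / 3000,
                       fraction_destabilized = 89 / 3000,
                       temperatures = seq(43, 60, length.out = 6),
                       n_replicates = 3,
                       slope_range = c(-1.5, -0.3),
                       tm_range = c(46, 52),
                       plateau_range = c(0, 0.2),
                       effect_distribution = c(2, 8),
                       noise_cv = 0.1,
                       missing_rate = 0.05,
                       base_intensity_range = c(1e6, 1e9),
                       seed = 1L) {
  bad <- function(field, why) {
    stop(sprintf("invalid `%s`: %s", field, why), call. = FALSE)
  }
  if (!is.numeric(n_proteins) || length(n_proteins) != 1 || n_proteins < 1) {
    bad("n_proteins", "must be a positive count")
  }
  for (f in c("fraction_stabilized", "fraction_destabilized")) {
    v <- get(f)
    if (!is.numeric(v) || length(v) != 1 || v < 0 || v > 1) {
      bad(f, "must be a proportion in [0, 1]")
    }
  }
  if (fraction_stabilized + fraction_destabilized > 1) {
    bad("fraction_stabilized", "spiked fractions must sum to at most 1")
  }
  if (length(temperatures) < 4 || any(diff(temperatures) <= 0)) {
    bad("temperatures", "must be strictly increasing with length >= 4")
  }
  if (n_replicates < 1) bad("n_replicates", "must be at least 1")
  if (length(slope_range) != 2 || any(slope_range >= 0) ||
      slope_range[1] > slope_range[2]) {
    bad("slope_range", "must be an entirely negative interval")
  }
  if (length(tm_range) != 2 || tm_range[1] > tm_range[2]) {
    bad("tm_range", "must be an interval")
  }
  if (length(plateau_range) != 2 || plateau_range[1] < 0 ||
      plateau_range[2] >= 0.5 || plateau_range[1] > plateau_range[2]) {
    bad("plateau_range", "must be an interval within [0, 0.5)")
  }
  if (!is.numeric(noise_cv) || noise_cv < 0) {
    bad("noise_cv", "must be non-negative")
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    bad("missing_rate", "must be in [0, 1)")
  }
  if (length(base_intensity_range) != 2 || any(base_intensity_range <= 0) ||
      base_intensity_range[1] > base_intensity_range[2]) {
    bad("base_intensity_range", "must be a positive interval")
  }
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed)) {
    bad("seed", "must be a finite integer")
  }
  structure(list(n_proteins = as.integer(n_proteins),
                 fraction_stabilized = fraction_stabilized,
                 fraction_destabilized = fraction_destabilized,
                 temperatures = as.numeric(temperatures),
                 n_replicates = as.integer(n_replicates),
                 slope_range = slope_range, tm_range = tm_range,
                 plateau_range = plateau_range,
                 effect_distribution = effect_distribution,
                 noise_cv = noise_cv, missing_rate = missing_rate,
                 base_intensity_range = base_intensity_range,
                 seed = as.integer(seed)),
            class = "sim_config")
}

draw_effect_magnitudes <- function(dist, n) {
  if (n == 0) return(numeric(0))
  mags <- if (is.function(dist)) {
    dist(n)
  } else if (is.numeric(dist) && length(dist) == 1) {
    rep(dist, n)
  } else if (is.numeric(dist) && length(dist) == 2) {
    stats::runif(n, dist[1], dist[2])
  } else {
    stop("invalid `effect_distribution`: must be a number, an interval, ",
         "or a function(n)", call. = FALSE)
  }
  if (any(mags <= 0)) {
    stop("invalid `effect_distribution`: magnitudes must be positive",
         call. = FALSE)
  }
  mags
}

#' Simulate a thermal proteome profiling dataset with known ground truth
#'
#' Draws per-protein unfolding parameters from the configured ranges,
#' spikes the configured fractions of proteins with positive (stabilized)
#' or negative (destabilized) melting-point shifts -- the treated condition
#' shares the control slope and plateau, only the inflection moves by the
#' true delta Tm -- evaluates the noise-free fraction folded on the
#' temperature grid, scales by a per-protein base intensity, applies
#' multiplicative log-normal noise independently per replicate and
#' temperature (sigma chosen so the linear-scale CV equals
#' \code{noise_cv}; the log-noise has mean 0), and finally drops
#' observations completely at random at \code{missing_rate}.
#'
#' @param config a [sim_config()].
#' @return list with \code{table}: a long-format abundance data frame
#'   (columns \code{protein_id}, \code{gene_symbol}, \code{condition},
#'   \code{replicate}, \code{temperature_c}, \code{intensity}) and
#'   \code{truth}: one row per protein (\code{protein_id},
#'   \code{a_control}, \code{b_control}, \code{p_control},
#'   \code{true_delta_tm}, \code{true_class}, plus the drawn
#'   \code{base_intensity}). The config (including the seed) is attached
#'   as attribute \code{"config"}.
#' @examples
#' sim <- simulate_dataset(sim_config(n_proteins = 20, seed = 7))
#' table(sim$truth$true_class)
#' @export
simulate_dataset <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) {
    config <- do.call(sim_config, config)
  }
  set.seed(config$seed)
  n <- config$n_proteins
  n_stab <- round(config$fraction_stabilized * n)
  n_dest <- round(config$fraction_destabilized * n)

  a <- stats::runif(n, config$slope_range[1], config$slope_range[2])
  b <- stats::runif(n, config$tm_range[1], config$tm_range[2])
  p <- stats::runif(n, config$plateau_range[1], config$plateau_range[2])
  base <- 10^stats::runif(n, log10(config$base_intensity_range[1]),
                          log10(config$base_intensity_range[2]))

  cls <- rep("unchanged", n)
  spiked <- sample.int(n, n_stab + n_dest)
  cls[spiked[seq_len(n_stab)]] <- "stabilized"
  if (n_dest > 0) cls[spiked[n_stab + seq_len(n_dest)]] <- "destabilized"
  delta <- numeric(n)
  delta[cls == "stabilized"] <- draw_effect_magnitudes(
    config$effect_distribution, n_stab)
  delta[cls == "destabilized"] <- -draw_effect_magnitudes(
    config$effect_distribution, n_dest)

  ids <- sprintf("P%0*d", nchar(n), seq_len(n))
  truth <- data.frame(protein_id = ids, a_control = a, b_control = b,
                      p_control = p, true_delta_tm = delta,
                      true_class = cls, base_intensity = base,
                      stringsAsFactors = FALSE)

  tt <- config$temperatures
  nt <- length(tt)
  nr <- config$n_replicates
  sigma <- sqrt(log(1 + config$noise_cv^2))

  grid <- expand.grid(temperature_c = tt, replicate = seq_len(nr),
                      condition = c("vehicle", "treated"),
                      protein = seq_len(n), KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  i <- grid$protein
  b_eff <- ifelse(grid$condition == "treated", b[i] + delta[i], b[i])
  mu <- base[i] * eval_unfolding(grid$temperature_c, a[i], b_eff, p[i])
  noise <- if (config$noise_cv > 0) {
    exp(stats::rnorm(nrow(grid), 0, sigma))
  } else {
    rep(1, nrow(grid))
  }
  tab <- data.frame(protein_id = ids[i],
                    gene_symbol = sub("^P", "G", ids[i]),
                    condition = grid$condition,
                    replicate = grid$replicate,
                    temperature_c = grid$temperature_c,
                    intensity = mu * noise,
                    stringsAsFactors = FALSE)
  if (config$missing_rate > 0) {
    tab <- tab[stats::runif(nrow(tab)) >= config$missing_rate, , drop = FALSE]
    rownames(tab) <- NULL
  }
  structure(list(table = tab, truth = truth), config = config)
}

#' Simulate a CETSA densitometry curve pair
#'
#' Generates immunoblot band-intensity series for one target under vehicle
#' and treated conditions. Band intensities are proportional to the
#' unfolding curve's fraction folded, with the treated inflection shifted
#' by \code{delta_tm}, normalized so the intensity at the lowest
#' temperature is (up to noise) 1, and perturbed by multiplicative
#' log-normal noise.
#'
#' @param tm_control control-condition inflection temperature (degrees
#'   Celsius). With the default \code{p = 0} this is exactly the control
#'   Tm50.
#' @param delta_tm true treated-minus-control shift (degrees Celsius).
#' @param a slope parameter (negative).
#' @param p plateau, must be below 0.5 (otherwise the 50% crossing does
#'   not exist).
#' @param temperatures strictly increasing grid (degrees Celsius).
#' @param noise_cv linear-scale CV of the multiplicative noise.
#' @param n_replicates replicate curve pairs.
#' @param target_name identifier carried in the output.
#' @param seed optional integer seed.
#' @return data frame with columns \code{target_name}, \code{condition}
#'   (\code{"vehicle"}/\code{"treated"}), \code{replicate},
#'   \code{temperature_c}, \code{band_intensity}.
#' @examples
#' cc <- simulate_cetsa(tm_control = 50, delta_tm = 5, noise_cv = 0,
#'                      temperatures = seq(40, 70, by = 1))
#' cetsa_delta_tm(cc[cc$condition == "vehicle", ],
#'                cc[cc$condition == "treated", ])$delta_tm
#' @export
simulate_cetsa <- function(tm_control, delta_tm, a = -0.8, p = 0,
                           temperatures = seq(40, 70, by = 2),
                           noise_cv = 0, n_replicates = 1,
                           target_name = "target", seed = NULL) {
  if (any(diff(temperatures) <= 0)) {
    stop("invalid `temperatures`: must be strictly increasing",
         call. = FALSE)
  }
  if (p >= 0.5) {
    stop("invalid `p`: plateau must be below 0.5 (0.5 crossing undefined)",
         call. = FALSE)
  }
  if (a >= 0) stop("invalid `a`: slope must be negative", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  sigma <- sqrt(log(1 + noise_cv^2))
  out <- list()
  for (cond in c("vehicle", "treated")) {
    b <- if (cond == "treated") tm_control + delta_tm else tm_control
    f <- eval_unfolding(temperatures, a, b, p)
    f <- f / f[1]
    for (r in seq_len(n_replicates)) {
      noise <- if (noise_cv > 0) {
        exp(stats::rnorm(length(f), 0, sigma))
      } else {
        rep(1, length(f))
      }
      out[[length(out) + 1L]] <- data.frame(
        target_name = target_name, condition = cond, replicate = r,
        temperature_c = temperatures, band_intensity = f * noise,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
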