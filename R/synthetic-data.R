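#' @include AllClasses.R
NULL

# Canonical property names, in reporting order. Analytes are % w/w, moisture
# is % of fresh weight.
PROPERTIES <- c("gastrodin", "p_hydroxybenzyl_alcohol", "parishin_b",
                "parishin_a", "moisture")

#' Properties monitored during steaming
#' @return character vector: the four phenolic analytes and moisture
#' @export
monitoredProperties <- function() PROPERTIES

#' Component band specification
#'
#' A pure-component NIR signature as a sum of Gaussian bands:
#' `s(nu) = sum_b height_b * exp(-(nu - center_b)^2 / (2 sigma_b^2))`,
#' with heights in absorbance units per unit concentration.
#'
#' @param name component name
#' @param bands numeric matrix with columns `center` (cm-1), `sigma` (cm-1)
#'   and `height` (AU per unit concentration); may have zero rows
#' @export
componentSpec <- function(name, bands) {
  bands <- matrix(as.numeric(bands), ncol = 3,
                  dimnames = list(NULL, c("center", "sigma", "height")))
  if (nrow(bands) && any(bands[, "sigma"] <= 0)) stop("band widths must be > 0")
  if (nrow(bands) && any(bands[, "height"] < 0)) stop("band heights must be >= 0")
  structure(list(name = name, bands = bands), class = "componentSpec")
}

#' Default component band library
#'
#' Analyte bands sit in the 4,200-5,000 cm-1 phenyl C-H/O-H combination
#' region with one minor band each between 5,500 and 6,100 cm-1; water has a
#' strong band at 5,155 cm-1 and a weaker one at 6,944 cm-1 (first overtone
#' and deformation of O-H). A `dry_matter` component with broad carbohydrate
#' bands represents the structural (insoluble) matrix of the homogenate; its
#' concentration is the mass-balance remainder (100 minus moisture and all
#' dissolved constituents) and gives scatter correction a stable backbone, as
#' in real diffuse-reflectance spectra.
#'
#' Two nuisance constituents model the fact that only four of the rhizome's
#' several dozen phenolic compounds are monitored: an aggregate
#' `unmonitored_phenolics` component sharing the phenyl combination region
#' (plus aromatic overtone bands at higher wavenumbers) and a
#' `soluble_solids` component. Both vary batch-to-batch and over steaming but
#' never appear in the reference table, so every calibration has to contend
#' with unmodelled spectral variation, as on real process spectra.
#'
#' Heights are scaled to the working units: % w/w for analytes and
#' unmonitored phenolics, % for moisture, dry matter and soluble solids.
#'
#' @return named list of [componentSpec()] objects, one per monitored property
#' @export
defaultComponents <- function() {
  list(
    gastrodin = componentSpec("gastrodin", rbind(
      c(4310, 40, 0.55), c(4750, 55, 0.35), c(5620, 60, 0.12))),
    p_hydroxybenzyl_alcohol = componentSpec("p_hydroxybenzyl_alcohol", rbind(
      c(4460, 45, 0.60), c(4920, 50, 0.30), c(5780, 60, 0.12))),
    parishin_b = componentSpec("parishin_b", rbind(
      c(4230, 35, 0.50), c(4610, 50, 0.45), c(5920, 55, 0.15))),
    parishin_a = componentSpec("parishin_a", rbind(
      c(4390, 40, 0.50), c(5050, 55, 0.35), c(6070, 60, 0.12))),
    moisture = componentSpec("moisture", rbind(
      c(5155, 180, 0.012), c(6944, 160, 0.006))),
    dry_matter = componentSpec("dry_matter", rbind(
      c(4350, 150, 0.008), c(4800, 180, 0.006), c(5600, 250, 0.005),
      c(6100, 220, 0.004), c(8300, 500, 0.002))),
    unmonitored_phenolics = componentSpec("unmonitored_phenolics", rbind(
      c(4520, 55, 0.45), c(4960, 60, 0.30), c(7800, 130, 0.30),
      c(9050, 160, 0.18))),
    soluble_solids = componentSpec("soluble_solids", rbind(
      c(5230, 150, 0.0075), c(6550, 180, 0.010), c(8800, 250, 0.006))))
}

#' Default steaming trajectories
#'
#' First-order kinetics: the parishins hydrolyse during steaming, so parishin
#' A and B decay exponentially from batch-specific initial levels while
#' gastrodin and p-hydroxybenzyl alcohol rise with saturating kinetics;
#' moisture rises towards a plateau as steam condenses into the homogenate.
#' `bounds` are the admissible per-sample ranges (% units) to which generated
#' values are clipped; `batch_sd` is the SD of the per-batch multiplicative
#' offsets applied independently to initial and final levels.
#'
#' @return list with per-property `initial`, `final`, `rate` (s-1), `bounds`
#'   and `batch_sd`
#' @export
defaultTrajectories <- function() {
  list(
    gastrodin = list(initial = 0.030, final = 0.580, rate = 1 / 180,
                     bounds = c(0.01098, 0.66611), batch_sd = 0.06),
    p_hydroxybenzyl_alcohol = list(initial = 0.048, final = 0.330,
                                   rate = 1 / 220,
                                   bounds = c(0.04013, 0.36677),
                                   batch_sd = 0.06),
    parishin_b = list(initial = 0.152, final = 0.0125, rate = 1 / 250,
                      bounds = c(0.01019, 0.16023), batch_sd = 0.06),
    parishin_a = list(initial = 0.560, final = 0.0140, rate = 1 / 160,
                      bounds = c(0.01098, 0.59755), batch_sd = 0.06),
    moisture = list(initial = 67.0, final = 86.5, rate = 1 / 240,
                    bounds = c(65.43, 89.12), batch_sd = 0.03),
    # nuisance constituents: present in the spectra, absent from the
    # reference table. Large batch-to-batch spread reflects raw-material
    # variability of the unmonitored fraction; sample_sd adds per-grab-sample
    # heterogeneity of the homogenate (the slurry is not perfectly mixed), a
    # source of spectral variation no smooth kinetic model can absorb
    unmonitored_phenolics = list(initial = 0.45, final = 0.18, rate = 1 / 300,
                                 bounds = c(0.05, 0.90), batch_sd = 0.20,
                                 sample_sd = 0.10),
    soluble_solids = list(initial = 3.5, final = 2.2, rate = 1 / 500,
                          bounds = c(1.0, 6.0), batch_sd = 0.10,
                          sample_sd = 0.05))
}

#' Default noise specification
#'
#' Additive detector noise, per-spectrum multiplicative scatter gain and
#' additive baseline offset/slope on the spectra; multiplicative reference
#' noise on the analyte assays at the repeatability RSDs of the HPLC
#' reference method (0.23, 0.15, 0.09 and 0.12 % RSD for gastrodin,
#' p-hydroxybenzyl alcohol, parishin B and parishin A) and absolute noise of
#' 0.5 % on the gravimetric moisture assay.
#'
#' @return list of noise parameters, all >= 0
#' @export
defaultNoise <- function() {
  list(additive_sd = 1e-3,          # AU, i.i.d. per grid point
       scatter_gain_sd = 0.05,      # unitless multiplicative gain
       baseline_offset_sd = 0.02,   # AU
       baseline_slope_sd = 0.01,    # AU across the full grid span
       reference_rsd = c(gastrodin = 0.0023,
                         p_hydroxybenzyl_alcohol = 0.0015,
                         parishin_b = 0.0009,
                         parishin_a = 0.0012),
       moisture_ref_sd = 0.5)       # absolute %
}

#' Synthetic steaming-process configuration
#'
#' Defaults emulate the study design: 10 batches sampled every 30 s over a
#' 600 s steaming run (21 time points per batch, 210 samples) on the
#' 4,000-12,000 cm-1 / 8 cm-1 grid.
#'
#' @param components band library, see [defaultComponents()]
#' @param trajectories kinetics, see [defaultTrajectories()]
#' @param noise noise levels, see [defaultNoise()]
#' @param nBatches number of steaming batches
#' @param sampleInterval sampling interval (s)
#' @param duration steaming duration (s)
#' @param grid a [WavenumberGrid-class]
#' @param seed integer seed controlling every random draw
#' @return a list of class `syntheticConfig`
#' @export
syntheticConfig <- function(components = defaultComponents(),
                            trajectories = defaultTrajectories(),
                            noise = defaultNoise(),
                            nBatches = 10L, sampleInterval = 30,
                            duration = 600, grid = wavenumberGrid(),
                            seed = 1L) {
  stopifnot(nBatches >= 1, sampleInterval > 0, duration > 0)
  if (any(unlist(noise[c("additive_sd", "scatter_gain_sd",
                         "baseline_offset_sd", "baseline_slope_sd",
                         "moisture_ref_sd")]) < 0) ||
      any(noise$reference_rsd < 0))
    stop("noise parameters must be >= 0")
  structure(list(components = components, trajectories = trajectories,
                 noise = noise, nBatches = as.integer(nBatches),
                 sampleInterval = sampleInterval, duration = duration,
                 grid = grid, seed = as.integer(seed)),
            class = "syntheticConfig")
}

#' Pure-component spectrum on a grid
#'
#' @param spec a [componentSpec()]
#' @param grid a [WavenumberGrid-class]
#' @return non-negative absorbance vector, one value per grid point
#' @examples
#' s <- pureSpectrum(componentSpec("w", rbind(c(5155, 50, 1))),
#'                   wavenumberGrid())
#' max(s)  # 1 at 5155 cm-1
#' @export
pureSpectrum <- function(spec, grid) {
  nu <- gridSeq(grid)
  b <- spec$bands
  if (nrow(b) &&
      (any(b[, "center"] < grid@start) || any(b[, "center"] > grid@end)))
    stop(sprintf("band center outside the grid for component '%s'", spec$name))
  out <- numeric(length(nu))
  for (i in seq_len(nrow(b)))
    out <- out + b[i, "height"] *
      exp(-(nu - b[i, "center"])^2 / (2 * b[i, "sigma"]^2))
  out
}

#' Simulate per-sample true concentrations
#'
#' Exponential (first-order) trajectories per constituent with per-batch
#' multiplicative offsets on the initial and final levels, evaluated at every
#' sampling time, then clipped to the configured bounds. A trajectory may
#' additionally declare `sample_sd`, a relative per-sample jitter modelling
#' grab-sample heterogeneity (used for the unmonitored nuisance
#' constituents). Deterministic given the seed.
#'
#' @param config a [syntheticConfig()]
#' @return list: `truth` (samples x properties matrix), `batch`, `time`
#'   annotations, and `n_clipped` (count of bound-clipped values)
#' @export
simulateTrajectories <- function(config) {
  times <- seq(0, config$duration, by = config$sampleInterval)
  nb <- config$nBatches
  n <- nb * length(times)
  props <- names(config$trajectories)
  truth <- matrix(NA_real_, n, length(props), dimnames = list(NULL, props))
  set.seed(config$seed)
  clipped <- 0L
  for (j in seq_along(props)) {
    tr <- config$trajectories[[j]]
    # batch-specific initial/final levels (independent multiplicative offsets)
    ini <- tr$initial * (1 + rnorm(nb, 0, tr$batch_sd))
    fin <- tr$final * (1 + rnorm(nb, 0, tr$batch_sd))
    ssd <- if (is.null(tr$sample_sd)) 0 else tr$sample_sd
    for (b in seq_len(nb)) {
      ct <- fin[b] + (ini[b] - fin[b]) * exp(-tr$rate * times)
      if (ssd > 0) ct <- ct * (1 + rnorm(length(times), 0, ssd))
      truth[(b - 1) * length(times) + seq_along(times), j] <- ct
    }
    lo <- tr$bounds[1]; hi <- tr$bounds[2]
    clipped <- clipped + sum(truth[, j] < lo | truth[, j] > hi)
    truth[, j] <- pmin(pmax(truth[, j], lo), hi)
  }
  if (clipped > 0)
    message(sprintf("simulateTrajectories: %d values clipped to bounds", clipped))
  list(truth = truth,
       batch = rep(sprintf("batch%02d", seq_len(nb)), each = length(times)),
       time = rep(times, nb), n_clipped = clipped)
}

#' Noise-free Beer-Lambert mixture spectra
#'
#' The exact linear mixing map used by the generator: component
#' concentrations times pure-component spectra, `C %*% S`. Concentrations are
#' taken column-wise from `truth` by component name; a `dry_matter` component,
#' if present in the library, receives the mass-balance remainder
#' `100 - moisture - sum(dissolved constituents)`, i.e. it stands for the
#' structural (insoluble) matrix.
#'
#' @param truth samples x properties concentration matrix (named columns)
#' @param components band library, see [defaultComponents()]
#' @param grid a [WavenumberGrid-class]
#' @return samples x grid-points absorbance matrix
#' @export
mixtureSpectra <- function(truth, components, grid) {
  conc <- vapply(names(components), function(nm) {
    if (nm == "dry_matter") {
      others <- intersect(colnames(truth),
                          setdiff(names(components), "dry_matter"))
      100 - rowSums(truth[, others, drop = FALSE])
    } else if (nm %in% colnames(truth)) truth[, nm]
    else stop(sprintf("no concentration available for component '%s'", nm))
  }, numeric(nrow(truth)))
  conc <- matrix(conc, nrow = nrow(truth))
  S <- t(vapply(components, pureSpectrum, numeric(grid@points), grid = grid))
  conc %*% S
}

#' Generate a synthetic steaming-process dataset
#'
#' Spectra follow a Beer-Lambert mixture with per-spectrum distortions:
#' `x = gain * (C %*% S) + offset + slope * nu_scaled + eps`, where `gain ~
#' 1 + N(0, scatter_gain_sd)`, the baseline offset and slope are per-spectrum
#' Gaussian draws, and `eps` is i.i.d. additive noise. Reference values are
#' the true concentrations perturbed multiplicatively (analytes, at the
#' reference-assay RSDs) or additively (moisture), then clipped to the
#' trajectory bounds. The unperturbed truth matrix is returned for recovery
#' tests.
#'
#' @param config a [syntheticConfig()]
#' @return list: `spectra` ([SpectraSet-class]), `reference` (data.frame with
#'   `sample_id` and the five monitored properties), `truth` (matrix over all
#'   simulated constituents, including any nuisance components)
#' @examples
#' d <- generateDataset(syntheticConfig(nBatches = 2, duration = 120, seed = 7))
#' dim(absorbance(d$spectra))
#' @export
generateDataset <- function(config) {
  traj <- simulateTrajectories(config)   # seeds the stream with config$seed
  truth <- traj$truth
  n <- nrow(truth)
  nu <- gridSeq(config$grid)
  p <- length(nu)
  clean <- mixtureSpectra(truth, config$components, config$grid)
  props <- intersect(PROPERTIES, colnames(truth))  # reference-table columns
  ns <- config$noise
  gain <- 1 + rnorm(n, 0, ns$scatter_gain_sd)
  offset <- rnorm(n, 0, ns$baseline_offset_sd)
  slope <- rnorm(n, 0, ns$baseline_slope_sd)
  nu01 <- (nu - nu[1]) / (nu[p] - nu[1])
  eps <- if (ns$additive_sd > 0)
    matrix(rnorm(n * p, 0, ns$additive_sd), n, p) else 0
  X <- clean * gain + outer(offset, rep(1, p)) + outer(slope, nu01) + eps
  if (!all(is.finite(X)))
    stop("internal error: non-finite absorbance generated")
  # reference assay noise; nuisance constituents never reach the reference
  ref <- truth[, props, drop = FALSE]
  for (nm in setdiff(props, "moisture")) {
    rsd <- ns$reference_rsd[[nm]]
    if (rsd > 0) ref[, nm] <- ref[, nm] * (1 + rnorm(n, 0, rsd))
  }
  if (ns$moisture_ref_sd > 0)
    ref[, "moisture"] <- ref[, "moisture"] + rnorm(n, 0, ns$moisture_ref_sd)
  for (nm in props) {
    b <- config$trajectories[[nm]]$bounds
    ref[, nm] <- pmin(pmax(ref[, nm], b[1]), b[2])
  }
  ids <- sprintf("%s_t%03d", traj$batch, as.integer(traj$time))
  spectra <- SpectraSet(X, nu, sampleId = ids, batchId = traj$batch,
                        steamTime = traj$time)
  reference <- data.frame(sample_id = ids, as.data.frame(ref),
                          stringsAsFactors = FALSE)
  list(spectra = spectra, reference = reference, truth = truth)
}
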