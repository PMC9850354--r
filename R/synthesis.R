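# Synthetic experimental spectra for known mixtures.
#
# The generator places a peak at every theoretical fragment m/z of
# every component, scales intensities by the molar ratio times a
# lognormal draw (positive, heavy-tailed), sums shared m/z across
# components, and sprinkles spurious peaks as a seeded Poisson process
# along the m/z axis. Spurious peaks are capped below the MS3
# precursor-selection threshold by default so that acquisition logic
# is driven by signal, not noise. Everything is deterministic given
# the seed.

#' Specify a synthetic mixture
#'
#' @param components List of `glycan` objects (isomeric components).
#' @param ratios Positive molar ratios, recycled and normalized to sum
#'   to 1 (default equimolar).
#' @param noise_rate Spurious-peak rate per 100 Th of m/z range
#'   (default 2).
#' @param sigma Lognormal intensity spread (sdlog; default 0.5; 0
#'   makes intensities exactly proportional to the ratios).
#' @param noise_cap Upper bound on spurious-peak intensity as a
#'   fraction of the base peak (default 0.08, below the 10% MS3
#'   selection threshold; raise for stress testing).
#' @param seed Integer seed; all simulated scans derive their streams
#'   from it.
#' @return A `mixture_spec`.
#' @export
mixture_spec <- function(components, ratios = NULL, noise_rate = 2,
                         sigma = 0.5, noise_cap = 0.08, seed = 1L) {
  stopifnot(is.list(components), length(components) >= 1L,
            all(vapply(components, inherits, logical(1), "glycan")))
  if (is.null(ratios)) ratios <- rep(1, length(components))
  ratios <- rep_len(as.numeric(ratios), length(components))
  stopifnot(all(ratios > 0), noise_rate >= 0, sigma >= 0, noise_cap >= 0)
  structure(list(components = components, ratios = ratios / sum(ratios),
                 noise_rate = noise_rate, sigma = sigma,
                 noise_cap = noise_cap, seed = as.integer(seed)),
            class = "mixture_spec")
}

# scan-specific deterministic seed below 2^31
.scan_seed <- function(mix, level, precursor_chain) {
  h <- sum(round(precursor_chain * 97)) + level * 131
  as.integer((abs(mix$seed) * 48271 + h) %% 2147483647)
}

#' Simulate one spectrum of a mixture
#'
#' @param mix A `mixture_spec`.
#' @param level 2 for the product-ion spectrum of the molecular ion,
#'   3 or deeper for further product-ion scans.
#' @param precursor_chain Precursor chain (molecular ion m/z first);
#'   defaults to the components' molecular ion for level 2.
#' @param cfg A `scoring_config` (fragmentation settings and
#'   tolerance).
#' @return An `ms_spectrum`, deterministic given `mix$seed` and the
#'   arguments.
#' @export
simulate_spectrum <- function(mix, level = 2L, precursor_chain = NULL,
                              cfg = scoring_config()) {
  stopifnot(inherits(mix, "mixture_spec"), level >= 2L)
  mol_mz <- permethylated_mz(glycan_composition_of(mix$components[[1]]))
  if (is.null(precursor_chain)) {
    stopifnot(level == 2L)
    precursor_chain <- mol_mz
  }
  stopifnot(length(precursor_chain) == level - 1L)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()), add = TRUE)
  set.seed(.scan_seed(mix, level, precursor_chain))

  mz <- numeric(0); int <- numeric(0)
  for (i in seq_along(mix$components)) {
    ts <- if (level == 2L) {
      theoretical_ms2(mix$components[[i]], max_cleavages = cfg$max_cleavages,
                      scar = cfg$scar)
    } else {
      theoretical_msn(mix$components[[i]], precursor_chain[-1],
                      tol = cfg$tol, max_cleavages = cfg$max_cleavages,
                      scar = cfg$scar)
    }
    mzs <- theo_mz(ts)
    if (!length(mzs)) next  # no fragment at this precursor chain
    draws <- if (mix$sigma > 0) stats::rlnorm(length(mzs), 0, mix$sigma)
             else rep(1, length(mzs))
    mz <- c(mz, mzs)
    int <- c(int, 1000 * mix$ratios[i] * draws)
  }
  if (length(mz)) {
    agg <- tapply(int, sprintf("%.4f", mz), sum)
    mz <- as.numeric(names(agg)); int <- as.numeric(agg)
  }
  if (mix$noise_rate > 0 && length(mz)) {
    lo <- 200
    hi <- max(precursor_chain[length(precursor_chain)], lo + 1)
    n_noise <- stats::rpois(1, mix$noise_rate * (hi - lo) / 100)
    if (n_noise > 0) {
      nmz <- stats::runif(n_noise, lo, hi)
      nint <- stats::runif(n_noise, 0, mix$noise_cap * max(int))
      # keep spurious peaks off real centroids so they stay sub-threshold
      clear <- vapply(nmz, function(m) all(abs(m - mz) > 0.05), logical(1))
      mz <- c(mz, nmz[clear]); int <- c(int, nint[clear])
    }
  }
  ms_spectrum(mz, int, level = level, precursor_chain = precursor_chain)
}

#' Simulate the full spectra tree of a mixture
#'
#' MS1 with the components' molecular ions (intensity proportional to
#' the ratios), the MS2 product-ion spectrum, and an MS3 spectrum for
#' every MS2 peak above the precursor-selection threshold.
#'
#' @param mix A `mixture_spec`.
#' @param cfg A `scoring_config`.
#' @return A `spectra_tree`.
#' @export
simulate_spectra_tree <- function(mix, cfg = scoring_config()) {
  mol_mz <- vapply(mix$components, function(g) {
    permethylated_mz(glycan_composition_of(g))
  }, numeric(1))
  ms1 <- ms_spectrum(unique(mol_mz),
                     vapply(unique(mol_mz), function(m) {
                       sum(1000 * mix$ratios[abs(mol_mz - m) < 1e-6])
                     }, numeric(1)),
                     level = 1L)
  ms2 <- simulate_spectrum(mix, 2L, cfg = cfg)
  tree <- spectra_tree(ms2, ms1 = ms1)
  for (p in select_ms3_precursors(ms2, cfg$ms3_threshold, cfg$tol)) {
    sp <- simulate_spectrum(mix, 3L, c(ms2$precursor_chain, p), cfg = cfg)
    if (nrow(sp$peaks)) tree <- suppressWarnings(add_spectrum(tree, sp))
  }
  tree
}

#' Virtual instrument for closed-loop sessions
#'
#' Wraps a mixture as a scan provider honouring the [run_session()]
#' callback contract: on request it simulates the product-ion spectrum
#' of the given precursor chain, recording every request for audit.
#'
#' @param mix A `mixture_spec`.
#' @param cfg A `scoring_config`.
#' @return A function `(level, precursor_chain) -> ms_spectrum` of
#'   class `virtual_instrument`; see [instrument_log()].
#' @export
virtual_instrument <- function(mix, cfg = scoring_config()) {
  requests <- list()
  f <- function(level, precursor_chain) {
    requests[[length(requests) + 1L]] <<-
      list(level = level, precursor_chain = precursor_chain)
    simulate_spectrum(mix, level, precursor_chain, cfg = cfg)
  }
  class(f) <- c("virtual_instrument", class(f))
  f
}

#' Scan requests recorded by a virtual instrument
#'
#' @param instrument A `virtual_instrument`.
#' @return List of requests (`level`, `precursor_chain`), in order.
#' @export
instrument_log <- function(instrument) {
  stopifnot(inherits(instrument, "virtual_instrument"))
  get("requests", environment(instrument))
}
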