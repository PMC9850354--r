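# Experimental spectra: peak lists, the MSn spectra tree, precursor
# selection and peak matching.

#' Construct a centroided spectrum
#'
#' Peaks are sorted by m/z; peaks closer than `merge_tol` are merged
#' (intensity-weighted mean m/z, summed intensity) so that the peak
#' list is strictly ascending. Relative intensities are percentages of
#' the base peak.
#'
#' @param mz,intensity Numeric vectors of equal length.
#' @param level MS level (1 for a survey scan, 2, 3, ...).
#' @param precursor_chain Numeric vector of precursor m/z values from
#'   MS2 down to this spectrum's own precursor; empty for MS1. Its
#'   length must be `level - 1`.
#' @param merge_tol Centroid merge tolerance in Da.
#' @return An `ms_spectrum`: list with `level`, `precursor_chain` and a
#'   `peaks` data frame (`mz`, `intensity`, `rel_intensity`).
#' @export
ms_spectrum <- function(mz, intensity, level = 2L,
                        precursor_chain = numeric(0), merge_tol = 0.01) {
  stopifnot(length(mz) == length(intensity), all(intensity >= 0))
  level <- as.integer(level)
  if (level != length(precursor_chain) + 1L) {
    stop("level must equal length(precursor_chain) + 1", call. = FALSE)
  }
  if (length(mz)) {
    if (any(mz <= 0)) stop("peak m/z must be positive", call. = FALSE)
    o <- order(mz)
    mz <- mz[o]; intensity <- intensity[o]
    # merge near-coincident centroids
    grp <- cumsum(c(TRUE, diff(mz) > merge_tol))
    if (max(grp) < length(mz)) {
      w <- intensity
      w[w == 0] <- 1e-12
      mzm <- tapply(mz * w, grp, sum) / tapply(w, grp, sum)
      intm <- tapply(intensity, grp, sum)
      mz <- as.numeric(mzm); intensity <- as.numeric(intm)
    }
  }
  rel <- if (length(mz) && max(intensity) > 0) {
    100 * intensity / max(intensity)
  } else {
    rep(0, length(mz))
  }
  structure(
    list(level = level,
         precursor_chain = as.numeric(precursor_chain),
         peaks = data.frame(mz = mz, intensity = intensity,
                            rel_intensity = rel)),
    class = "ms_spectrum"
  )
}

#' @export
print.ms_spectrum <- function(x, ...) {
  chain <- if (length(x$precursor_chain)) {
    paste(sprintf("%.2f", x$precursor_chain), collapse = " > ")
  } else "-"
  cat("<ms_spectrum> MS", x$level, ", precursor chain: ", chain, ", ",
      nrow(x$peaks), " peaks\n", sep = "")
  invisible(x)
}

# key for the msn map: precursor chain below the MS2 precursor
.chain_key <- function(precursor_chain) {
  paste(sprintf("%.4f", precursor_chain[-1]), collapse = "/")
}

#' Assemble an MSn spectra tree
#'
#' The spectra tree of one sample: the MS1 survey scan, the MS2
#' product-ion spectrum of the molecular ion, and any deeper spectra
#' keyed by their precursor chain (for an MS3 spectrum, its precursor
#' m/z).
#'
#' @param ms2 `ms_spectrum` of level 2.
#' @param ms1 Optional `ms_spectrum` of level 1.
#' @param msn List of `ms_spectrum` objects of level 3 or deeper.
#' @return A `spectra_tree`.
#' @export
spectra_tree <- function(ms2, ms1 = NULL, msn = list()) {
  stopifnot(inherits(ms2, "ms_spectrum"), ms2$level == 2L)
  if (!is.null(ms1)) stopifnot(inherits(ms1, "ms_spectrum"), ms1$level == 1L)
  tree <- structure(list(ms1 = ms1, ms2 = ms2, msn = list()),
                    class = "spectra_tree")
  for (s in msn) tree <- add_spectrum(tree, s)
  tree
}

#' Add a product-ion spectrum to a spectra tree
#'
#' Spectra with an already-present precursor chain are merged by
#' summing intensities (replicate scans).
#'
#' @param tree A `spectra_tree`.
#' @param spectrum An `ms_spectrum` of level 3 or deeper whose
#'   precursor chain starts at the MS2 precursor.
#' @param tol Tolerance used to check that the spectrum's precursor is
#'   a peak of its parent spectrum.
#' @return The updated `spectra_tree`.
#' @export
add_spectrum <- function(tree, spectrum, tol = 0.5) {
  stopifnot(inherits(tree, "spectra_tree"), inherits(spectrum, "ms_spectrum"),
            spectrum$level >= 3L)
  prec <- spectrum$precursor_chain[length(spectrum$precursor_chain)]
  parent_peaks <- if (spectrum$level == 3L) tree$ms2$peaks$mz else {
    parent_key <- .chain_key(spectrum$precursor_chain[-length(spectrum$precursor_chain)] )
    if (!is.null(tree$msn[[parent_key]])) tree$msn[[parent_key]]$peaks$mz else numeric(0)
  }
  if (length(parent_peaks) && !any(abs(parent_peaks - prec) <= tol)) {
    warning("precursor ", sprintf("%.4f", prec),
            " is not a peak of its parent spectrum")
  }
  key <- .chain_key(spectrum$precursor_chain)
  old <- tree$msn[[key]]
  if (!is.null(old)) {
    spectrum <- ms_spectrum(c(old$peaks$mz, spectrum$peaks$mz),
                            c(old$peaks$intensity, spectrum$peaks$intensity),
                            level = spectrum$level,
                            precursor_chain = spectrum$precursor_chain)
  }
  tree$msn[[key]] <- spectrum
  tree
}

#' @export
print.spectra_tree <- function(x, ...) {
  cat("<spectra_tree>\n")
  if (!is.null(x$ms1)) cat("  MS1: ", nrow(x$ms1$peaks), " peaks\n", sep = "")
  cat("  MS2 (precursor ", sprintf("%.4f", x$ms2$precursor_chain[1]), "): ",
      nrow(x$ms2$peaks), " peaks\n", sep = "")
  for (k in names(x$msn)) {
    cat("  MS", x$msn[[k]]$level, " @ ", k, ": ", nrow(x$msn[[k]]$peaks),
        " peaks\n", sep = "")
  }
  invisible(x)
}

#' Select MS3 precursors from an MS2 spectrum
#'
#' Fragment ions with relative intensity above the threshold are
#' selected as precursors for further product-ion scanning, in
#' descending intensity order. The spectrum's own (residual) precursor
#' ion is excluded.
#'
#' @param spectrum An `ms_spectrum`.
#' @param threshold_pct Relative-intensity threshold in percent
#'   (default 10: peaks strictly above 10% are selected).
#' @param tol Tolerance for recognizing the residual precursor peak.
#' @return Numeric vector of precursor m/z values.
#' @export
select_ms3_precursors <- function(spectrum, threshold_pct = 10, tol = 0.5) {
  stopifnot(inherits(spectrum, "ms_spectrum"))
  pk <- spectrum$peaks
  keep <- pk$rel_intensity > threshold_pct
  if (length(spectrum$precursor_chain)) {
    own <- spectrum$precursor_chain[length(spectrum$precursor_chain)]
    keep <- keep & abs(pk$mz - own) > tol
  }
  sel <- pk[keep, , drop = FALSE]
  sel$mz[order(sel$intensity, decreasing = TRUE)]
}

#' Match experimental peaks to theoretical m/z values
#'
#' Each experimental peak is assigned to its nearest theoretical m/z
#' within the tolerance; exact-distance ties go to the lower
#' theoretical m/z. Unmatched peaks are omitted.
#'
#' @param spectrum An `ms_spectrum`, or a data frame with columns `mz`,
#'   `intensity`, `rel_intensity`.
#' @param theo_mz Numeric vector of theoretical m/z values.
#' @param tol Matching tolerance in Da.
#' @return Data frame with one row per matched experimental peak:
#'   `mz`, `intensity`, `rel_intensity`, `theo_mz`.
#' @export
match_peaks <- function(spectrum, theo_mz, tol = 0.5) {
  stopifnot(tol > 0)
  pk <- if (inherits(spectrum, "ms_spectrum")) spectrum$peaks else spectrum
  theo_mz <- sort(unique(as.numeric(theo_mz)))
  if (!nrow(pk) || !length(theo_mz)) {
    return(data.frame(mz = numeric(0), intensity = numeric(0),
                      rel_intensity = numeric(0), theo_mz = numeric(0)))
  }
  # nearest theoretical value; ties resolved to the lower m/z because
  # findInterval brackets from the left
  idx <- findInterval(pk$mz, theo_mz)
  lo <- pmax(idx, 1L)
  hi <- pmin(idx + 1L, length(theo_mz))
  d_lo <- abs(pk$mz - theo_mz[lo])
  d_hi <- abs(pk$mz - theo_mz[hi])
  best <- ifelse(d_lo <= d_hi, lo, hi)
  dist <- pmin(d_lo, d_hi)
  keep <- dist <= tol
  out <- pk[keep, c("mz", "intensity", "rel_intensity"), drop = FALSE]
  out$theo_mz <- theo_mz[best[keep]]
  rownames(out) <- NULL
  out
}
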