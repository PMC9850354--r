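# Shared fixtures and independent oracles. All structures are built in
# code via the parser; the three difucohexaose branching patterns are
# the isomer family used throughout (Lewis-b type, blood-group-H +
# core-fucose type, Lewis-x + core-fucose type).

gly <- function(s) parse_glycan(s)

pat_lewis_b <- function() gly("Fuc(a1-2)Gal(b1-3)[Fuc(a1-4)]GlcNAc(b1-3)Gal(b1-4)Glc")
pat_h_core  <- function() gly("Fuc(a1-2)Gal(b1-3)GlcNAc(b1-3)Gal(b1-4)[Fuc(a1-3)]Glc")
pat_lewis_x <- function() gly("Gal(b1-4)[Fuc(a1-3)]GlcNAc(b1-3)Gal(b1-4)[Fuc(a1-3)]Glc")
gly_lnt     <- function() gly("Gal(b1-3)GlcNAc(b1-3)Gal(b1-4)Glc")
gly_lnh     <- function() gly("Gal(b1-3)GlcNAc(b1-3)[Gal(b1-4)GlcNAc(b1-6)]Gal(b1-4)Glc")
gly_plnh    <- function() gly("Gal(b1-3)GlcNAc(b1-3)Gal(b1-4)GlcNAc(b1-3)Gal(b1-4)Glc")

# brute-force nearest-neighbour peak assignment (ties to lower m/z)
oracle_match <- function(peaks, theo_mz, tol) {
  theo_mz <- sort(unique(theo_mz))
  out <- NULL
  for (i in seq_len(nrow(peaks))) {
    d <- abs(peaks$mz[i] - theo_mz)
    j <- which(d == min(d))[1]  # sorted, so first minimum = lower m/z
    if (d[j] <= tol) {
      out <- rbind(out, cbind(peaks[i, c("mz", "intensity", "rel_intensity")],
                              theo_mz = theo_mz[j]))
    }
  }
  if (is.null(out)) {
    out <- data.frame(mz = numeric(0), intensity = numeric(0),
                      rel_intensity = numeric(0), theo_mz = numeric(0))
  }
  rownames(out) <- NULL
  out
}

# independent recomputation of the group similarity: plain loops over
# spectra and peaks, nearest-within-tol matching, tanh weighting,
# group-size penalty
oracle_similarity <- function(group_members, tree, cfg) {
  theo_for <- function(chain) {
    mzs <- unlist(lapply(group_members, function(g) {
      if (length(chain) <= 1L) {
        theo_mz(theoretical_ms2(g, cfg$max_cleavages, cfg$scar))
      } else {
        theo_mz(theoretical_msn(g, chain[-1], cfg$tol, cfg$max_cleavages,
                                cfg$scar))
      }
    }))
    sort(unique(mzs))
  }
  total <- 0
  specs <- c(list(tree$ms2), unname(tree$msn))
  for (sp in specs) {
    mzs <- theo_for(sp$precursor_chain)
    own <- sp$precursor_chain[length(sp$precursor_chain)]
    for (i in seq_len(nrow(sp$peaks))) {
      p <- sp$peaks[i, ]
      if (abs(p$mz - own) <= cfg$tol) next  # residual precursor ion
      if (length(mzs) && min(abs(p$mz - mzs)) <= cfg$tol) {
        total <- total + tanh(cfg$beta * p$rel_intensity)
      }
    }
  }
  total - cfg$alpha * length(group_members)
}

# spectra tree with chosen peaks, no file round trip
toy_tree <- function(ms2_mz, ms2_int, precursor, msn = list()) {
  suppressWarnings(
    spectra_tree(ms_spectrum(ms2_mz, ms2_int, level = 2L,
                             precursor_chain = precursor),
                 msn = msn))
}
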