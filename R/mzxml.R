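# mzXML input/output. Reading goes through mzR (which also accepts
# mzML); writing emits plain uncompressed mzXML 3.2 with base64,
# network-byte-order 64-bit peak arrays, sufficient for round-tripping
# synthetic spectra through the real reader.

#' Read an MSn spectra tree from mzXML
#'
#' Scans are grouped by MS level and precursor m/z (4 decimals);
#' replicate scans of the same level and precursor are merged by
#' summing intensities and re-centroiding. Relative intensities are
#' computed per merged spectrum. mzML files are accepted as a
#' convenience.
#'
#' @param path Path to an mzXML (or mzML) file.
#' @param merge_tol Centroid merge tolerance in Da.
#' @return A `spectra_tree`.
#' @export
read_mzxml <- function(path, merge_tol = 0.01) {
  handle <- mzR::openMSfile(path)
  on.exit(mzR::close(handle), add = TRUE)
  hd <- mzR::header(handle)
  if (!nrow(hd)) stop("no scans in ", path, call. = FALSE)
  if (any(hd$msLevel >= 2L & (is.na(hd$precursorMZ) | hd$precursorMZ <= 0))) {
    stop("format error: scan of level >= 2 without precursorMz in ", path,
         call. = FALSE)
  }

  merge_scans <- function(rows, level, chain) {
    mz <- numeric(0); int <- numeric(0)
    for (r in rows) {
      p <- mzR::peaks(handle, r)
      mz <- c(mz, p[, 1]); int <- c(int, p[, 2])
    }
    ms_spectrum(mz, int, level = level, precursor_chain = chain,
                merge_tol = merge_tol)
  }

  ms1 <- NULL
  ms1_rows <- which(hd$msLevel == 1L)
  if (length(ms1_rows)) {
    ms1 <- merge_scans(hd$seqNum[ms1_rows], 1L, numeric(0))
  } else {
    warning("no MS1 scan in ", path, "; tree built from MS2 down")
  }

  ms2_rows <- which(hd$msLevel == 2L)
  if (!length(ms2_rows)) stop("no MS2 scan in ", path, call. = FALSE)
  prec2 <- round(hd$precursorMZ[ms2_rows], 4)
  main_prec <- prec2[1]
  if (length(unique(prec2)) > 1L) {
    tot <- tapply(hd$totIonCurrent[ms2_rows], prec2, sum)
    main_prec <- as.numeric(names(tot)[which.max(tot)])
    warning("multiple MS2 precursors in ", path, "; using ",
            sprintf("%.4f", main_prec))
  }
  use2 <- ms2_rows[prec2 == main_prec]
  ms2 <- merge_scans(hd$seqNum[use2], 2L, main_prec)

  tree <- spectra_tree(ms2, ms1 = ms1)
  deep <- which(hd$msLevel >= 3L)
  if (length(deep)) {
    # mzXML stores only the immediate precursor; the chain is rebuilt
    # as MS2 precursor followed by this scan's own precursor(s)
    keyv <- paste(hd$msLevel[deep], round(hd$precursorMZ[deep], 4))
    for (k in unique(keyv)) {
      rows <- deep[keyv == k]
      level <- hd$msLevel[rows[1]]
      own <- round(hd$precursorMZ[rows[1]], 4)
      chain <- c(main_prec, rep(NA_real_, max(0L, level - 3L)), own)
      chain <- chain[!is.na(chain)]
      if (length(chain) != level - 1L) chain <- c(main_prec, own)
      sp <- merge_scans(hd$seqNum[rows], level, chain)
      tree <- add_spectrum(tree, sp)
    }
  }
  tree
}

.b64_peaks <- function(mz, intensity) {
  if (!length(mz)) return("")
  v <- as.numeric(rbind(mz, intensity))
  enc <- jsonlite::base64_enc(writeBin(v, raw(), size = 8L, endian = "big"))
  gsub("[\r\n]", "", enc)  # parsers reject wrapped base64
}

.scan_xml <- function(num, spectrum) {
  pk <- spectrum$peaks
  prec <- ""
  if (length(spectrum$precursor_chain)) {
    own <- spectrum$precursor_chain[length(spectrum$precursor_chain)]
    prec <- sprintf('\n  <precursorMz precursorIntensity="1">%.6f</precursorMz>',
                    own)
  }
  base_i <- if (nrow(pk)) which.max(pk$intensity) else NA_integer_
  sprintf(paste0(
    ' <scan num="%d" msLevel="%d" peaksCount="%d" lowMz="%.4f"',
    ' highMz="%.4f" basePeakMz="%.4f" basePeakIntensity="%.4f"',
    ' totIonCurrent="%.4f">%s\n  <peaks precision="64" byteOrder="network"',
    ' contentType="m/z-int" compressionType="none" compressedLen="0">%s',
    '</peaks>\n </scan>'),
    num, spectrum$level, nrow(pk),
    if (nrow(pk)) min(pk$mz) else 0, if (nrow(pk)) max(pk$mz) else 0,
    if (nrow(pk)) pk$mz[base_i] else 0,
    if (nrow(pk)) pk$intensity[base_i] else 0,
    sum(pk$intensity), prec, .b64_peaks(pk$mz, pk$intensity))
}

#' Write a spectra tree to mzXML
#'
#' Emits uncompressed mzXML 3.2 (64-bit network-byte-order peaks)
#' readable by standard mzXML parsers, including [read_mzxml()].
#'
#' @param tree A `spectra_tree`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mzxml <- function(tree, path) {
  stopifnot(inherits(tree, "spectra_tree"))
  spectra <- c(if (!is.null(tree$ms1)) list(tree$ms1), list(tree$ms2),
               unname(tree$msn))
  scans <- vapply(seq_along(spectra), function(i) .scan_xml(i, spectra[[i]]),
                  character(1))
  doc <- paste0(
    '<?xml version="1.0" encoding="ISO-8859-1"?>\n',
    '<mzXML xmlns="http://sashimi.sourceforge.net/schema_revision/mzXML_3.2"',
    ' xmlns:xsi="http://www.w3.org/2001/XMLSchema-instance"',
    ' xsi:schemaLocation="http://sashimi.sourceforge.net/schema_revision/mzXML_3.2',
    ' http://sashimi.sourceforge.net/schema_revision/mzXML_3.2/mzXML_idx_3.2.xsd">\n',
    '<msRun scanCount="', length(spectra), '">\n',
    paste(scans, collapse = "\n"),
    '\n</msRun>\n</mzXML>\n')
  writeLines(doc, path)
  invisible(path)
}
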