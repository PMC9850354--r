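# Monoisotopic mass model for free and permethylated, sodiated glycans.
#
# All masses are assembled from an elemental mass table so that residue
# masses, adduct masses and cleavage offsets stay mutually consistent.

# monoisotopic atomic masses (Da), CODATA/IUPAC 2021
.ATOMIC_MASS <- c(
  C  = 12.0,
  H  = 1.00782503207,
  N  = 14.0030740048,
  O  = 15.9949146196,
  Na = 22.9897692809
)

#' Monoisotopic mass of a molecular formula
#'
#' Computes the monoisotopic mass of a simple molecular formula such as
#' `"C6H10O5"` from the package's elemental mass table (C, H, N, O, Na).
#'
#' @param formula Character scalar, e.g. `"C8H13NO5"`. Element symbols
#'   followed by optional counts; no parentheses or isotopes.
#' @return Monoisotopic mass in Da.
#' @examples
#' formula_mass("H2O")     # water, 18.0106
#' formula_mass("C6H10O5") # hexose residue, 162.0528
#' @export
formula_mass <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L, nzchar(formula))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  parts <- regmatches(formula, list(m))[[1]]
  parts <- parts[nzchar(parts)]
  if (sum(nchar(parts)) != nchar(formula)) {
    stop("malformed formula: ", formula, call. = FALSE)
  }
  total <- 0
  for (p in parts) {
    sym <- sub("[0-9]*$", "", p)
    cnt <- sub("^[A-Za-z]+", "", p)
    cnt <- if (nzchar(cnt)) as.integer(cnt) else 1L
    if (!sym %in% names(.ATOMIC_MASS)) {
      stop("unknown element '", sym, "' in formula ", formula, call. = FALSE)
    }
    total <- total + .ATOMIC_MASS[[sym]] * cnt
  }
  total
}

# fixed small-molecule constants used throughout
.MASS <- list(
  water    = NA_real_,  # filled in .onLoad-free init below
  sodium   = NA_real_,
  ch2      = NA_real_,  # one methylene: difference methylated vs free hydroxyl
  red_end  = NA_real_,  # fully methylated terminal groups of an intact glycan
  b_offset = NA_real_,  # reducing-side terminus of a B-type fragment
  c_offset = NA_real_   # reducing-side terminus of a C-type fragment
)
.MASS$water    <- formula_mass("H2O")
.MASS$sodium   <- .ATOMIC_MASS[["Na"]]
.MASS$ch2      <- formula_mass("CH2")
.MASS$red_end  <- formula_mass("C2H6O")  # 46.0419
.MASS$b_offset <- formula_mass("CH2")    # 14.0157
.MASS$c_offset <- formula_mass("CH4O")   # 32.0262

#' Monosaccharide class registry
#'
#' The default registry covers the neutral residue classes found in human
#' milk oligosaccharides and related standards: hexose (`Hex`),
#' N-acetylhexosamine (`HexNAc`) and deoxyhexose (`dHex`, i.e. fucose).
#' Native and permethylated residue masses are derived from molecular
#' formulae. The registry is extensible: supply additional rows via
#' `extra` (sialylated or anionic residues, for instance).
#'
#' @param extra Optional `data.frame` with columns `label`,
#'   `native_formula`, `permethyl_formula` to append to the defaults.
#' @return A `data.frame` with columns `label`, `native_formula`,
#'   `permethyl_formula`, `native_mass`, `permethyl_mass`.
#' @examples
#' monosaccharide_registry()
#' @export
monosaccharide_registry <- function(extra = NULL) {
  reg <- data.frame(
    label             = c("Hex", "HexNAc", "dHex"),
    native_formula    = c("C6H10O5", "C8H13NO5", "C6H10O4"),
    permethyl_formula = c("C9H16O5", "C11H19NO5", "C8H14O4"),
    stringsAsFactors  = FALSE
  )
  if (!is.null(extra)) {
    stopifnot(all(c("label", "native_formula", "permethyl_formula") %in%
                    names(extra)))
    reg <- rbind(reg, extra[, c("label", "native_formula",
                                "permethyl_formula")])
  }
  if (anyDuplicated(reg$label)) {
    stop("duplicate monosaccharide labels in registry", call. = FALSE)
  }
  reg$native_mass    <- vapply(reg$native_formula, formula_mass, numeric(1))
  reg$permethyl_mass <- vapply(reg$permethyl_formula, formula_mass, numeric(1))
  if (any(reg$native_mass <= 0) || any(reg$permethyl_mass <= 0)) {
    stop("registry masses must be strictly positive", call. = FALSE)
  }
  rownames(reg) <- reg$label
  reg
}

# residue name (condensed notation) -> monosaccharide class
.RESIDUE_CLASS <- c(
  Glc = "Hex", Gal = "Hex", Man = "Hex",
  GlcNAc = "HexNAc", GalNAc = "HexNAc",
  Fuc = "dHex", Rha = "dHex"
)

#' Construct a glycan composition
#'
#' A composition is a named count vector over monosaccharide classes,
#' e.g. `glycan_composition(Hex = 3, HexNAc = 1)`. Compositions support
#' `+` and `-`; subtraction that would yield a negative count is an
#' error.
#'
#' @param ... Named non-negative integer counts, names being class
#'   labels present in the registry.
#' @param registry Monosaccharide registry (see
#'   [monosaccharide_registry()]).
#' @return An integer vector of class `glycan_composition`, one entry
#'   per registry class (zeros kept).
#' @examples
#' glycan_composition(Hex = 3, HexNAc = 1)
#' glycan_composition(dHex = 2, Hex = 3, HexNAc = 1)
#' @export
glycan_composition <- function(..., registry = monosaccharide_registry()) {
  counts <- c(...)
  if (length(counts) == 0L) {
    counts <- integer(0)
  }
  if (length(counts) && (is.null(names(counts)) || any(!nzchar(names(counts))))) {
    stop("composition counts must be named by class label", call. = FALSE)
  }
  unknown <- setdiff(names(counts), registry$label)
  if (length(unknown)) {
    stop("unknown monosaccharide class: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (any(counts < 0)) stop("composition counts must be non-negative",
                            call. = FALSE)
  out <- stats::setNames(integer(length(registry$label)), registry$label)
  out[names(counts)] <- as.integer(counts)
  structure(out, class = "glycan_composition")
}

#' @export
`+.glycan_composition` <- function(e1, e2) {
  stopifnot(identical(names(e1), names(e2)))
  structure(stats::setNames(as.integer(unclass(e1) + unclass(e2)), names(e1)),
            class = "glycan_composition")
}

#' @export
`-.glycan_composition` <- function(e1, e2) {
  stopifnot(identical(names(e1), names(e2)))
  d <- unclass(e1) - unclass(e2)
  if (any(d < 0)) stop("composition subtraction yields negative counts",
                       call. = FALSE)
  structure(stats::setNames(as.integer(d), names(e1)),
            class = "glycan_composition")
}

#' @export
format.glycan_composition <- function(x, ...) {
  nz <- x[x > 0]
  if (!length(nz)) return("(empty)")
  paste0(names(nz), unclass(nz), collapse = ".")
}

#' @export
print.glycan_composition <- function(x, ...) {
  cat("<composition> ", format(x), "\n", sep = "")
  invisible(x)
}

.as_composition <- function(x, registry = monosaccharide_registry()) {
  if (inherits(x, "glycan_composition")) return(x)
  if (inherits(x, "glycan")) return(glycan_composition_of(x, registry))
  stop("cannot interpret object of class ", paste(class(x), collapse = "/"),
       " as a composition", call. = FALSE)
}

#' Native monoisotopic mass of a free reducing glycan
#'
#' Sum of native residue masses plus one water. The empty composition
#' gives the mass of water.
#'
#' @param x A `glycan_composition` or a `glycan` tree.
#' @param registry Monosaccharide registry.
#' @return Monoisotopic mass in Da.
#' @examples
#' native_mass(glycan_composition(dHex = 2, Hex = 3, HexNAc = 1)) # 999.364
#' @export
native_mass <- function(x, registry = monosaccharide_registry()) {
  comp <- .as_composition(x, registry)
  sum(unclass(comp) * registry[names(comp), "native_mass"]) + .MASS$water
}

#' Permethylated, sodiated m/z of an intact glycan
#'
#' Monoisotopic m/z of the singly sodiated, fully permethylated glycan
#' (MNa+): sum of permethylated residue masses, plus the fully
#' methylated terminal groups (C2H6O equivalent), plus Na.
#'
#' @inheritParams native_mass
#' @return Monoisotopic m/z (Th).
#' @examples
#' permethylated_mz(glycan_composition(Hex = 3, HexNAc = 1))          # 926.46
#' permethylated_mz(glycan_composition(dHex = 2, Hex = 3, HexNAc = 1)) # 1274.64
#' @export
permethylated_mz <- function(x, registry = monosaccharide_registry()) {
  comp <- .as_composition(x, registry)
  if (sum(comp) < 1L) {
    stop("permethylated m/z is undefined for an empty composition",
         call. = FALSE)
  }
  sum(unclass(comp) * registry[names(comp), "permethyl_mass"]) +
    .MASS$red_end + .MASS$sodium
}
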