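# Theoretical glycosidic fragmentation of permethylated, sodiated
# glycans.
#
# Cleaving one glycosidic bond splits the tree into a nonreducing-side
# piece, observed as a B- or C-type ion, and a reducing-side piece that
# keeps the intact methylated reducing end and carries one cleavage
# scar. Double cleavage additionally yields internal pieces (between
# two nested cleavage sites) and reducing pieces with two scars. Scars
# are free hydroxyls by default (-CH2 relative to full methylation); a
# methylated-scar convention (methyl migration, delta 0) and the union
# of both are available. Cross-ring fragments are not modelled.

.TERMINUS_OFFSET <- function(terminus) {
  switch(terminus,
         M = .MASS$red_end,
         B = .MASS$b_offset,
         C = .MASS$c_offset,
         stop("unknown terminus '", terminus, "'", call. = FALSE))
}

#' m/z of a glycosidic fragment ion
#'
#' Sum of permethylated residue masses plus the sodium adduct, a
#' reducing-side terminus offset (intact methylated reducing end for
#' Y/Z-equivalent pieces, B-cut or C-cut otherwise) and `-CH2` per
#' free-hydroxyl scar.
#'
#' @param composition A `glycan_composition` (non-empty).
#' @param terminus `"M"` (intact reducing end), `"B"` or `"C"`.
#' @param n_free_scars Number of cleavage scars left as free hydroxyls.
#' @param registry Monosaccharide registry.
#' @return Monoisotopic m/z.
#' @examples
#' fragment_mz(glycan_composition(Hex = 1), "B") # 241.11
#' fragment_mz(glycan_composition(Hex = 1), "C") # 259.12
#' @export
fragment_mz <- function(composition, terminus = "B", n_free_scars = 0L,
                        registry = monosaccharide_registry()) {
  comp <- .as_composition(composition, registry)
  if (sum(comp) < 1L) stop("fragment composition is empty", call. = FALSE)
  sum(unclass(comp) * registry[names(comp), "permethyl_mass"]) +
    .MASS$sodium + .TERMINUS_OFFSET(terminus) - n_free_scars * .MASS$ch2
}

# ---- structural piece enumeration ---------------------------------------

.tree_index <- function(g) {
  kids <- .glycan_children(g)
  n <- length(g$residue)
  subtree <- vector("list", n)
  walk <- function(i) {
    out <- i
    for (c in kids[[i]]) out <- c(out, walk(c))
    subtree[[i]] <<- out
    out
  }
  walk(.glycan_root(g))
  list(kids = kids, subtree = subtree)
}

.initial_state <- function(g) {
  list(nodes = seq_along(g$residue), root = .glycan_root(g),
       terminus = "M", scars = integer(0))
}

# all pieces reachable from `state` by up to `max_cleavages` glycosidic
# cleavages, the intact state included. terminus field: "inherit" keeps
# the state terminus, "cut" expands to B and C.
.enumerate_pieces <- function(g, idx, state, max_cleavages = 2L) {
  nodes <- state$nodes
  in_piece <- logical(length(g$residue))
  in_piece[nodes] <- TRUE
  edges <- nodes[!is.na(g$parent[nodes]) & in_piece[pmax(g$parent[nodes], 1L)] &
                   !is.na(g$parent[nodes])]
  edges <- setdiff(edges, state$root)
  pieces <- list(list(nodes = nodes, root = state$root, terminus = "inherit",
                      scars = state$scars, cleaved = integer(0)))
  sub_in <- function(c) intersect(idx$subtree[[c]], nodes)
  for (c in edges) {
    sub <- sub_in(c)
    keep <- setdiff(nodes, sub)
    pieces[[length(pieces) + 1L]] <-
      list(nodes = sub, root = c, terminus = "cut",
           scars = intersect(state$scars, sub), cleaved = c)
    pieces[[length(pieces) + 1L]] <-
      list(nodes = keep, root = state$root, terminus = "inherit",
           scars = c(state$scars[state$scars %in% keep], g$parent[c]),
           cleaved = c)
  }
  if (max_cleavages >= 2L && length(edges) >= 2L) {
    for (a in seq_along(edges)[-length(edges)]) {
      for (b in (a + 1L):length(edges)) {
        c1 <- edges[a]; c2 <- edges[b]
        s1 <- idx$subtree[[c1]]; s2 <- idx$subtree[[c2]]
        if (c2 %in% s1 || c1 %in% s2) {
          if (c1 %in% s2) { tmp <- c1; c1 <- c2; c2 <- tmp }
          # c2 nested below c1: internal piece between the two cuts
          inner <- setdiff(sub_in(c1), intersect(idx$subtree[[c2]], nodes))
          pieces[[length(pieces) + 1L]] <-
            list(nodes = inner, root = c1, terminus = "cut",
                 scars = c(state$scars[state$scars %in% inner], g$parent[c2]),
                 cleaved = c(c1, c2))
        } else {
          keep <- setdiff(nodes, c(sub_in(c1), sub_in(c2)))
          pieces[[length(pieces) + 1L]] <-
            list(nodes = keep, root = state$root, terminus = "inherit",
                 scars = c(state$scars[state$scars %in% keep],
                           g$parent[c1], g$parent[c2]),
                 cleaved = c(c1, c2))
        }
      }
    }
  }
  # deduplicate structurally identical pieces, merging provenance
  key <- vapply(pieces, function(p) {
    paste(p$terminus, p$root, paste(sort(p$nodes), collapse = ","),
          paste(sort(p$scars), collapse = ","), sep = "|")
  }, character(1))
  out <- list()
  for (i in seq_along(pieces)) {
    k <- key[i]
    if (is.null(out[[k]])) {
      out[[k]] <- pieces[[i]]
      out[[k]]$cleaved <- list(pieces[[i]]$cleaved)
    } else {
      out[[k]]$cleaved <- c(out[[k]]$cleaved, list(pieces[[i]]$cleaved))
    }
  }
  unname(out)
}

.scar_expansion <- function(n_scars, scar_rule) {
  switch(scar_rule,
         free = n_scars,
         methylated = 0L,
         both = 0L:n_scars,
         stop("scar rule must be 'free', 'methylated' or 'both'",
              call. = FALSE))
}

.piece_comp_mass <- function(g, nodes, registry) {
  sum(registry[g$class[nodes], "permethyl_mass"])
}

.comp_string <- function(g, nodes, registry) {
  tab <- table(factor(g$class[nodes], levels = registry$label))
  nz <- tab[tab > 0]
  paste0(names(nz), as.integer(nz), collapse = ".")
}

# expand structural pieces into fragment-ion rows
.expand_pieces <- function(g, pieces, state_terminus, scar_rule, registry) {
  rows <- list()
  for (p in pieces) {
    termini <- if (identical(p$terminus, "inherit")) state_terminus
               else c("B", "C")
    base <- .piece_comp_mass(g, p$nodes, registry) + .MASS$sodium
    ns <- length(p$scars)
    comp <- .comp_string(g, p$nodes, registry)
    prov <- paste(vapply(p$cleaved, function(e) paste(e, collapse = "+"),
                         character(1)), collapse = ";")
    for (term in termini) {
      for (nf in .scar_expansion(ns, scar_rule)) {
        rows[[length(rows) + 1L]] <- data.frame(
          mz = base + .TERMINUS_OFFSET(term) - nf * .MASS$ch2,
          terminus = term, composition = comp, n_scars = ns, n_free = nf,
          root = p$root, provenance = prov, stringsAsFactors = FALSE)
      }
    }
  }
  df <- do.call(rbind, rows)
  df[!duplicated(df[, c("mz", "terminus", "composition", "n_scars",
                        "n_free")]), , drop = FALSE]
}

#' Enumerate glycosidic fragment ions of a glycan
#'
#' All fragment ions reachable by up to `max_cleavages` glycosidic
#' cleavages (1 or 2), under the selected scar convention. The intact
#' molecular ion is included.
#'
#' @param g A `glycan`.
#' @param max_cleavages 1 or 2.
#' @param scar Scar convention: `"free"` (free hydroxyl, -CH2 per
#'   scar; default), `"methylated"` (methyl migration, no shift) or
#'   `"both"` (union over the number of free scars).
#' @param registry Monosaccharide registry.
#' @return Data frame with columns `mz`, `terminus` (`M`/`B`/`C`),
#'   `composition`, `n_scars`, `n_free`, `root`, `provenance`.
#' @export
enumerate_fragments <- function(g, max_cleavages = 2L,
                                scar = c("free", "methylated", "both"),
                                registry = monosaccharide_registry()) {
  stopifnot(inherits(g, "glycan"), max_cleavages %in% 1:2)
  scar <- match.arg(scar)
  idx <- .tree_index(g)
  pieces <- .enumerate_pieces(g, idx, .initial_state(g), max_cleavages)
  out <- .expand_pieces(g, pieces, "M", scar, registry)
  rownames(out) <- NULL
  out
}

# ---- theoretical spectra -------------------------------------------------

.new_theo_spectrum <- function(ions, level, precursor_chain, origin) {
  ions$mz <- round(ions$mz, 4)
  ions <- ions[order(ions$mz, ions$terminus), , drop = FALSE]
  ions <- ions[!duplicated(ions), , drop = FALSE]
  rownames(ions) <- NULL
  structure(list(level = level, precursor_chain = precursor_chain,
                 origin = origin, ions = ions),
            class = "theo_spectrum")
}

#' @export
print.theo_spectrum <- function(x, ...) {
  cat("<theo_spectrum> MS", x$level, ", ", length(theo_mz(x)),
      " distinct m/z (", nrow(x$ions), " annotations), origin: ",
      paste(x$origin, collapse = "+"), "\n", sep = "")
  invisible(x)
}

#' Distinct m/z values of a theoretical spectrum
#'
#' @param ts A `theo_spectrum`.
#' @return Sorted numeric vector of m/z values.
#' @export
theo_mz <- function(ts) {
  stopifnot(inherits(ts, "theo_spectrum"))
  sort(unique(ts$ions$mz))
}

#' Union of theoretical spectra
#'
#' Set semantics: m/z entries are pooled and annotation sets merged;
#' a fragment shared by several origins keeps one entry per distinct
#' annotation. The union with itself is idempotent.
#'
#' @param ... `theo_spectrum` objects of identical level and precursor
#'   chain.
#' @return A `theo_spectrum`.
#' @export
union_spectra <- function(...) {
  xs <- list(...)
  if (length(xs) == 1L && is.list(xs[[1]]) &&
      !inherits(xs[[1]], "theo_spectrum")) {
    xs <- xs[[1]]
  }
  stopifnot(length(xs) >= 1L)
  lev <- xs[[1]]$level
  chain <- xs[[1]]$precursor_chain
  ions <- do.call(rbind, lapply(xs, function(x) {
    cbind(x$ions, origin = rep(paste(x$origin, collapse = "+"),
                               nrow(x$ions)))
  }))
  .new_theo_spectrum(ions, lev, chain,
                     unique(unlist(lapply(xs, `[[`, "origin"))))
}

#' Theoretical MS2 spectrum of a glycan
#'
#' Fragment m/z values from single and double glycosidic cleavage of
#' the intact permethylated, sodiated glycan, with uniform nominal
#' intensity and provenance annotations.
#'
#' @inheritParams enumerate_fragments
#' @param origin Identifier recorded as the spectrum origin.
#' @return A `theo_spectrum` of level 2.
#' @export
theoretical_ms2 <- function(g, max_cleavages = 2L,
                            scar = c("free", "methylated", "both"),
                            registry = monosaccharide_registry(),
                            origin = NULL) {
  scar <- match.arg(scar)
  frags <- enumerate_fragments(g, max_cleavages, scar, registry)
  if (is.null(origin)) origin <- serialize_glycan(g)
  frags$origin <- origin
  .new_theo_spectrum(frags, 2L, permethylated_mz(glycan_composition_of(g)),
                     origin)
}

#' Theoretical MSn spectrum of a glycan along a precursor chain
#'
#' Walks the chain of product-ion selections: at each stage every
#' fragment of the surviving pieces whose m/z lies within `tol` of the
#' stage precursor is isolated (inheriting its terminus and scars) and
#' re-fragmented by single and double glycosidic cleavage. The result
#' is the union over all matching isolation paths; an empty spectrum
#' means no fragment matched the chain.
#'
#' @param g A `glycan`.
#' @param precursors Numeric vector of precursor m/z values below the
#'   molecular ion (for MS3, a single value).
#' @param tol Precursor matching tolerance in Da.
#' @inheritParams enumerate_fragments
#' @param origin Identifier recorded as the spectrum origin.
#' @return A `theo_spectrum` of level `length(precursors) + 2`.
#' @export
theoretical_msn <- function(g, precursors, tol = 0.5, max_cleavages = 2L,
                            scar = c("free", "methylated", "both"),
                            registry = monosaccharide_registry(),
                            origin = NULL) {
  stopifnot(inherits(g, "glycan"), length(precursors) >= 1L, tol > 0)
  scar <- match.arg(scar)
  idx <- .tree_index(g)
  if (is.null(origin)) origin <- serialize_glycan(g)
  states <- list(.initial_state(g))
  for (p in precursors) {
    nxt <- list()
    for (st in states) {
      pieces <- .enumerate_pieces(g, idx, st, max_cleavages)
      for (pc in pieces) {
        termini <- if (identical(pc$terminus, "inherit")) st$terminus
                   else c("B", "C")
        base <- .piece_comp_mass(g, pc$nodes, registry) + .MASS$sodium
        ns <- length(pc$scars)
        for (term in termini) {
          for (nf in .scar_expansion(ns, scar)) {
            if (abs(base + .TERMINUS_OFFSET(term) - nf * .MASS$ch2 - p) <= tol) {
              key <- paste(term, pc$root,
                           paste(sort(pc$nodes), collapse = ","),
                           paste(sort(pc$scars), collapse = ","), sep = "|")
              nxt[[key]] <- list(nodes = pc$nodes, root = pc$root,
                                 terminus = term, scars = pc$scars)
            }
          }
        }
      }
    }
    states <- unname(nxt)
    if (!length(states)) break
  }
  level <- length(precursors) + 2L
  chain <- c(permethylated_mz(glycan_composition_of(g)), precursors)
  if (!length(states)) {
    empty <- data.frame(mz = numeric(0), terminus = character(0),
                        composition = character(0), n_scars = integer(0),
                        n_free = integer(0), root = integer(0),
                        provenance = character(0), origin = character(0),
                        stringsAsFactors = FALSE)
    return(.new_theo_spectrum(empty, level, chain, origin))
  }
  parts <- lapply(states, function(st) {
    pieces <- .enumerate_pieces(g, idx, st, max_cleavages)
    .expand_pieces(g, pieces, st$terminus, scar, registry)
  })
  ions <- do.call(rbind, parts)
  ions <- ions[!duplicated(ions), , drop = FALSE]
  ions$origin <- origin
  .new_theo_spectrum(ions, level, chain, origin)
}

#' Theoretical MS3 spectrum of a glycan
#'
#' Convenience wrapper around [theoretical_msn()] for a single
#' product-ion selection.
#'
#' @inheritParams theoretical_msn
#' @param precursor_mz The MS3 precursor m/z.
#' @return A `theo_spectrum` of level 3.
#' @export
theoretical_ms3 <- function(g, precursor_mz, tol = 0.5, max_cleavages = 2L,
                            scar = c("free", "methylated", "both"),
                            registry = monosaccharide_registry(),
                            origin = NULL) {
  theoretical_msn(g, precursor_mz, tol = tol, max_cleavages = max_cleavages,
                  scar = match.arg(scar), registry = registry, origin = origin)
}

#' Export an annotated theoretical spectrum
#'
#' @param ts A `theo_spectrum`.
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
export_theo_spectrum <- function(ts, path, format = c("tsv", "json")) {
  stopifnot(inherits(ts, "theo_spectrum"))
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(ts$ions, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    jsonlite::write_json(
      list(level = ts$level, precursor_chain = ts$precursor_chain,
           origin = ts$origin, ions = ts$ions),
      path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  invisible(path)
}
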