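# Glycan structures as rooted trees of monosaccharide residues.
#
# A glycan is stored as parallel node vectors (residue name, class,
# parent index, linkage string); node 1 is the reducing end (root) and
# nodes are kept in canonical preorder so that isomorphic inputs parse
# to identical objects. Linkage annotations (anomericity, positions)
# are carried for display and round-tripping but are ignored by every
# mass and isomorphism computation: the unit of identity is the
# branching pattern.

new_glycan <- function(residue, parent, linkage,
                       registry = monosaccharide_registry()) {
  n <- length(residue)
  stopifnot(n >= 1L, length(parent) == n, length(linkage) == n)
  cls <- .RESIDUE_CLASS[residue]
  if (anyNA(cls)) {
    bad <- residue[is.na(cls)][1]
    stop("unknown residue name '", bad, "'", call. = FALSE)
  }
  if (!all(cls %in% registry$label)) {
    stop("residue class missing from registry", call. = FALSE)
  }
  g <- structure(
    list(residue = as.character(residue),
         class   = as.character(cls),
         parent  = as.integer(parent),
         linkage = as.character(linkage)),
    class = "glycan"
  )
  .validate_glycan(g)
  .canonicalize_glycan(g)
}

.validate_glycan <- function(g) {
  n <- length(g$residue)
  roots <- which(is.na(g$parent))
  if (length(roots) != 1L) {
    stop("glycan must have exactly one root (reducing end)", call. = FALSE)
  }
  # reachability from root guarantees connected + acyclic for n-1 edges
  seen <- rep(FALSE, n)
  seen[roots] <- TRUE
  repeat {
    new <- !seen & !is.na(g$parent) & seen[pmax(g$parent, 1L)] &
      !is.na(g$parent)
    new[is.na(new)] <- FALSE
    if (!any(new)) break
    seen[new] <- TRUE
  }
  if (!all(seen)) stop("glycan tree is not connected", call. = FALSE)
  invisible(g)
}

.glycan_children <- function(g) {
  n <- length(g$residue)
  kids <- vector("list", n)
  for (i in seq_len(n)) kids[[i]] <- which(!is.na(g$parent) & g$parent == i)
  kids
}

.glycan_root <- function(g) which(is.na(g$parent))

# subtree signature: residue class plus sorted child signatures;
# linkage deliberately excluded
.node_signature <- function(g, i, kids) {
  ch <- kids[[i]]
  if (!length(ch)) return(g$class[i])
  sub <- sort(vapply(ch, .node_signature, character(1), g = g, kids = kids))
  paste0(g$class[i], "(", paste(sub, collapse = ","), ")")
}

#' Branching-pattern signature of a glycan
#'
#' Canonical string encoding the rooted tree of monosaccharide classes,
#' ignoring linkage annotations. Two glycans have equal signatures if
#' and only if they share the same branching pattern.
#'
#' @param g A `glycan`.
#' @return Character scalar.
#' @export
glycan_signature <- function(g) {
  stopifnot(inherits(g, "glycan"))
  kids <- .glycan_children(g)
  .node_signature(g, .glycan_root(g), kids)
}

# reorder nodes into canonical preorder: children sorted by subtree
# signature, ties broken by linkage then residue for stable serialization
.canonicalize_glycan <- function(g) {
  kids <- .glycan_children(g)
  sig <- vapply(seq_along(g$residue), .node_signature, character(1),
                g = g, kids = kids)
  order_new <- integer(0)
  walk <- function(i) {
    order_new[[length(order_new) + 1L]] <<- i
    ch <- kids[[i]]
    if (length(ch)) {
      ch <- ch[order(sig[ch], g$linkage[ch], g$residue[ch])]
      for (c in ch) walk(c)
    }
  }
  walk(.glycan_root(g))
  order_new <- unlist(order_new)
  remap <- integer(length(order_new))
  remap[order_new] <- seq_along(order_new)
  structure(
    list(residue = g$residue[order_new],
         class   = g$class[order_new],
         parent  = ifelse(is.na(g$parent[order_new]), NA_integer_,
                          remap[g$parent[order_new]]),
         linkage = g$linkage[order_new]),
    class = "glycan"
  )
}

#' Composition of a glycan tree
#'
#' @param g A `glycan`.
#' @param registry Monosaccharide registry.
#' @return A `glycan_composition` counting the residue classes.
#' @export
glycan_composition_of <- function(g, registry = monosaccharide_registry()) {
  stopifnot(inherits(g, "glycan"))
  tab <- table(factor(g$class, levels = registry$label))
  structure(stats::setNames(as.integer(tab), registry$label),
            class = "glycan_composition")
}

## ---- condensed-notation parser ------------------------------------------

.tokenize_glycan <- function(text) {
  tokens <- list()
  i <- 1L
  n <- nchar(text)
  while (i <= n) {
    ch <- substr(text, i, i)
    if (ch == "[") {
      tokens[[length(tokens) + 1L]] <- list(type = "open", pos = i)
      i <- i + 1L
    } else if (ch == "]") {
      tokens[[length(tokens) + 1L]] <- list(type = "close", pos = i)
      i <- i + 1L
    } else if (grepl("^[A-Za-z]$", ch)) {
      m <- regexpr("^[A-Za-z][A-Za-z0-9]*", substr(text, i, n))
      name <- regmatches(substr(text, i, n), m)
      j <- i + attr(m, "match.length")
      linkage <- NA_character_
      if (j <= n && substr(text, j, j) == "(") {
        lm <- regexpr("^\\([^()]*\\)", substr(text, j, n))
        if (lm == -1L) {
          stop("glycan parse error at position ", j,
               ": unterminated linkage", call. = FALSE)
        }
        lk <- regmatches(substr(text, j, n), lm)
        linkage <- substr(lk, 2L, nchar(lk) - 1L)
        j <- j + attr(lm, "match.length")
      }
      tokens[[length(tokens) + 1L]] <-
        list(type = "res", name = name, linkage = linkage, pos = i)
      i <- j
    } else {
      stop("glycan parse error at position ", i, ": unexpected character '",
           ch, "'", call. = FALSE)
    }
  }
  tokens
}

# group tokens into nested element lists
.group_tokens <- function(tokens, pos0 = 1L) {
  parse_elems <- function(i, depth) {
    elems <- list()
    while (i <= length(tokens)) {
      tk <- tokens[[i]]
      if (tk$type == "res") {
        elems[[length(elems) + 1L]] <- tk
        i <- i + 1L
      } else if (tk$type == "open") {
        sub <- parse_elems(i + 1L, depth + 1L)
        if (sub$end > length(tokens) || tokens[[sub$end]]$type != "close") {
          stop("glycan parse error at position ", tk$pos,
               ": unbalanced '['", call. = FALSE)
        }
        elems[[length(elems) + 1L]] <-
          list(type = "branch", elements = sub$elements, pos = tk$pos)
        i <- sub$end + 1L
      } else { # close
        if (depth == 0L) {
          stop("glycan parse error at position ", tk$pos,
               ": unbalanced ']'", call. = FALSE)
        }
        return(list(elements = elems, end = i))
      }
    }
    if (depth > 0L) {
      stop("glycan parse error: unbalanced '[' (missing ']')", call. = FALSE)
    }
    list(elements = elems, end = i)
  }
  parse_elems(pos0, 0L)$elements
}

#' Parse a glycan from condensed notation
#'
#' Parses strings such as
#' `"Fuc(a1-2)Gal(b1-3)[Fuc(a1-4)]GlcNAc(b1-3)Gal(b1-4)Glc"`. The
#' rightmost residue is the reducing end (tree root); each residue
#' attaches to the next residue on its right at the same bracket level,
#' and a bracketed branch attaches to the residue immediately following
#' it. Linkage tokens like `(b1-4)` are stored verbatim but do not
#' affect masses or isomorphism.
#'
#' @param text Character scalar in condensed notation.
#' @param registry Monosaccharide registry.
#' @return A `glycan` in canonical node order.
#' @examples
#' lnt <- parse_glycan("Gal(b1-3)GlcNAc(b1-3)Gal(b1-4)Glc")
#' glycan_composition_of(lnt)
#' @export
parse_glycan <- function(text, registry = monosaccharide_registry()) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  if (!nzchar(text)) stop("glycan parse error: empty input", call. = FALSE)
  tokens <- .tokenize_glycan(text)
  elems <- .group_tokens(tokens)

  env <- new.env(parent = emptyenv())
  env$residue <- character(0)
  env$parent  <- integer(0)
  env$linkage <- character(0)
  add_node <- function(tk, parent_id) {
    if (!tk$name %in% names(.RESIDUE_CLASS)) {
      stop("glycan parse error at position ", tk$pos,
           ": unknown residue name '", tk$name, "'", call. = FALSE)
    }
    env$residue <- c(env$residue, tk$name)
    env$parent  <- c(env$parent, parent_id)
    env$linkage <- c(env$linkage, tk$linkage)
    length(env$residue)
  }
  build_chain <- function(elements, parent_id) {
    k <- length(elements)
    last <- elements[[k]]
    if (!identical(last$type, "res")) {
      stop("glycan parse error at position ", last$pos,
           ": a chain must end in a residue", call. = FALSE)
    }
    attach_point <- add_node(last, parent_id)
    if (k >= 2L) {
      for (j in (k - 1L):1L) {
        el <- elements[[j]]
        if (identical(el$type, "res")) {
          attach_point <- add_node(el, attach_point)
        } else {
          if (!length(el$elements)) {
            stop("glycan parse error at position ", el$pos,
                 ": empty branch", call. = FALSE)
          }
          build_chain(el$elements, attach_point)
        }
      }
    }
    invisible(NULL)
  }
  if (!length(elems)) stop("glycan parse error: empty input", call. = FALSE)
  build_chain(elems, NA_integer_)
  new_glycan(env$residue, env$parent, env$linkage, registry = registry)
}

#' Serialize a glycan to condensed notation
#'
#' Inverse of [parse_glycan()] on canonical forms: the first child of a
#' node continues the chain to the left and every further child is
#' bracketed.
#'
#' @param g A `glycan`.
#' @return Character scalar.
#' @export
serialize_glycan <- function(g) {
  stopifnot(inherits(g, "glycan"))
  kids <- .glycan_children(g)
  lk <- function(i) if (is.na(g$linkage[i])) "" else paste0("(", g$linkage[i], ")")
  ser <- function(i) {
    ch <- kids[[i]]
    if (!length(ch)) return(g$residue[i])
    out <- paste0(ser(ch[1]), lk(ch[1]))
    if (length(ch) > 1L) {
      for (c in ch[-1]) out <- paste0(out, "[", ser(c), lk(c), "]")
    }
    paste0(out, g$residue[i])
  }
  ser(.glycan_root(g))
}

#' Test two glycans for branching-pattern equality
#'
#' Rooted-tree isomorphism over monosaccharide classes, ignoring
#' linkage annotations.
#'
#' @param a,b `glycan` objects.
#' @return Logical scalar.
#' @export
glycan_isomorphic <- function(a, b) {
  identical(glycan_signature(a), glycan_signature(b))
}

#' @export
format.glycan <- function(x, ...) serialize_glycan(x)

#' @export
print.glycan <- function(x, ...) {
  cat("<glycan> ", serialize_glycan(x), "\n  composition: ",
      format(glycan_composition_of(x)), "  (", length(x$residue),
      " residues)\n", sep = "")
  invisible(x)
}
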