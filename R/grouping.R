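# Candidate-group enumeration and similarity scoring.
#
# A candidate group is a non-empty subset of the representative
# branching patterns at the observed molecular mass. Each group is
# scored against the experimental spectra tree by summing
# tanh(beta * I_p) over experimental peaks matched by the group's
# theoretical spectra (MS2 and every MS3 weighted identically) and
# subtracting alpha times the group size, which biases the choice
# toward the fewest components that explain the spectra.

#' Scoring configuration
#'
#' @param alpha Group-size penalty weight (default 1).
#' @param beta Intensity squash rate inside `tanh(beta * I_p)` with
#'   `I_p` the relative intensity in percent (default 0.2: an 80%
#'   peak and an 8% peak contribute tanh(16) ~ 1.00 and
#'   tanh(1.6) ~ 0.92 rather than differing tenfold).
#' @param tol Peak/precursor matching tolerance in Da (default 0.5,
#'   consistent with nominal MALDI ion-trap labelling).
#' @param tie_epsilon Scores within this margin of the maximum count
#'   as tied (default 0.01).
#' @param prob_threshold Posterior probability at which a single group
#'   is accepted and the session terminates (default 0.9).
#' @param max_candidates Combinatorial guard on group enumeration
#'   (default 12).
#' @param min_precursor_mz Peaks below this m/z are never recommended
#'   as tie-breaking precursors (default 200).
#' @param max_cleavages Glycosidic cleavages per fragmentation stage
#'   (1 or 2; default 2).
#' @param scar Scar convention for fragment simulation (`"free"`,
#'   `"methylated"` or `"both"`; see [enumerate_fragments()]).
#' @param ms3_threshold Relative-intensity threshold (percent) for MS3
#'   precursor selection (default 10).
#' @return A `scoring_config` list.
#' @export
scoring_config <- function(alpha = 1, beta = 0.2, tol = 0.5,
                           tie_epsilon = 0.01, prob_threshold = 0.9,
                           max_candidates = 12L, min_precursor_mz = 200,
                           max_cleavages = 2L,
                           scar = c("free", "methylated", "both"),
                           ms3_threshold = 10) {
  stopifnot(alpha >= 0, beta > 0, tol > 0, tie_epsilon >= 0,
            prob_threshold > 0, prob_threshold < 1,
            max_candidates >= 1, max_cleavages %in% 1:2)
  structure(list(alpha = alpha, beta = beta, tol = tol,
                 tie_epsilon = tie_epsilon, prob_threshold = prob_threshold,
                 max_candidates = as.integer(max_candidates),
                 min_precursor_mz = min_precursor_mz,
                 max_cleavages = as.integer(max_cleavages),
                 scar = match.arg(scar), ms3_threshold = ms3_threshold),
            class = "scoring_config")
}

#' Enumerate all candidate groups
#'
#' All 2^n - 1 non-empty subsets of the candidate glycans, ordered by
#' size and then lexicographically by member index.
#'
#' @param candidates List of `glycan` objects (the branching-pattern
#'   representatives).
#' @param max_candidates Guard against combinatorial blow-up; exceeding
#'   it is an error advising pre-filtering.
#' @return List of `candidate_group` objects, each with `idx` (member
#'   indices), `members` (glycans), `n` and a `label`.
#' @export
enumerate_groups <- function(candidates, max_candidates = 12L) {
  stopifnot(is.list(candidates), length(candidates) >= 1L)
  n <- length(candidates)
  if (n > max_candidates) {
    stop("too many candidates (", n, " > ", max_candidates,
         "): pre-filter the candidate list (e.g. collapse to branching ",
         "patterns) before grouping", call. = FALSE)
  }
  groups <- list()
  for (k in seq_len(n)) {
    for (idx in asplit(utils::combn(n, k), 2)) {
      idx <- as.integer(idx)
      groups[[length(groups) + 1L]] <- structure(
        list(idx = idx, members = candidates[idx], n = k,
             label = paste0("{g", paste(idx, collapse = ",g"), "}")),
        class = "candidate_group")
    }
  }
  groups
}

#' @export
print.candidate_group <- function(x, ...) {
  cat("<candidate_group> ", x$label, " (", x$n, " members)\n", sep = "")
  invisible(x)
}

# cache of per-member theoretical spectra keyed by precursor chain;
# avoids re-simulating fragments for every group that shares a member
.theo_cache <- function(candidates, cfg) {
  env <- new.env(parent = emptyenv())
  env$candidates <- candidates
  env$cfg <- cfg
  env$store <- new.env(parent = emptyenv())
  env
}

.member_theo <- function(cache, i, precursors = numeric(0)) {
  key <- paste0(i, "|", paste(sprintf("%.4f", precursors), collapse = "/"))
  got <- cache$store[[key]]
  if (!is.null(got)) return(got)
  g <- cache$candidates[[i]]
  cfg <- cache$cfg
  ts <- if (!length(precursors)) {
    theoretical_ms2(g, max_cleavages = cfg$max_cleavages, scar = cfg$scar,
                    origin = paste0("g", i))
  } else {
    theoretical_msn(g, precursors, tol = cfg$tol,
                    max_cleavages = cfg$max_cleavages, scar = cfg$scar,
                    origin = paste0("g", i))
  }
  cache$store[[key]] <- ts
  ts
}

#' Theoretical spectra of a candidate group
#'
#' The group's theoretical MS2 spectrum is the union of its members'
#' theoretical MS2 spectra; for every experimental product-ion
#' spectrum in the tree, the counterpart is the union of the members'
#' theoretical spectra simulated along that precursor chain.
#'
#' @param group A `candidate_group`.
#' @param tree A `spectra_tree`.
#' @param cfg A `scoring_config`.
#' @param cache Optional internal spectra cache (created when missing).
#' @return Named list of `theo_spectrum`: `ms2` plus one entry per
#'   product-ion spectrum key.
#' @export
group_theoretical_spectra <- function(group, tree, cfg = scoring_config(),
                                      cache = NULL) {
  stopifnot(inherits(group, "candidate_group"), inherits(tree, "spectra_tree"))
  if (is.null(cache)) {
    cand <- vector("list", max(group$idx))
    cand[group$idx] <- group$members
    cache <- .theo_cache(cand, cfg)
  }
  out <- list(ms2 = union_spectra(lapply(group$idx, function(i) {
    .member_theo(cache, i)
  })))
  for (key in names(tree$msn)) {
    chain <- tree$msn[[key]]$precursor_chain
    out[[key]] <- union_spectra(lapply(group$idx, function(i) {
      .member_theo(cache, i, chain[-1])
    }))
  }
  out
}

# tanh-weighted matched-intensity contribution of one spectrum,
# excluding the residual precursor ion of the spectrum itself
.spectrum_contrib <- function(spectrum, mzs, cfg) {
  pk <- spectrum$peaks
  if (length(spectrum$precursor_chain)) {
    own <- spectrum$precursor_chain[length(spectrum$precursor_chain)]
    pk <- pk[abs(pk$mz - own) > cfg$tol, , drop = FALSE]
  }
  m <- match_peaks(pk, mzs, cfg$tol)
  list(contrib = sum(tanh(cfg$beta * m$rel_intensity)), n_matched = nrow(m))
}

#' Similarity between a candidate group and the experimental spectra
#'
#' Sum over all experimental spectra (MS2 and every acquired MS3, with
#' identical weights) of `tanh(beta * I_p)` over the peaks matched by
#' the group's theoretical counterpart spectra, minus `alpha` times
#' the group size. Each experimental peak contributes at most once per
#' spectrum. Intensities `I_p` are relative intensities in percent.
#'
#' @inheritParams group_theoretical_spectra
#' @return A `group_score`: list with `group`, `similarity`,
#'   `per_spectrum` (named contributions) and `n_matched`.
#' @export
similarity_score <- function(group, tree, cfg = scoring_config(),
                             cache = NULL) {
  theo <- group_theoretical_spectra(group, tree, cfg, cache)
  contrib <- c(ms2 = NA_real_)
  nm <- c(ms2 = NA_real_)
  s2 <- .spectrum_contrib(tree$ms2, theo_mz(theo$ms2), cfg)
  contrib["ms2"] <- s2$contrib; nm["ms2"] <- s2$n_matched
  for (key in names(tree$msn)) {
    s3 <- .spectrum_contrib(tree$msn[[key]], theo_mz(theo[[key]]), cfg)
    contrib[key] <- s3$contrib; nm[key] <- s3$n_matched
  }
  structure(list(group = group,
                 similarity = sum(contrib) - cfg$alpha * group$n,
                 per_spectrum = contrib, n_matched = nm),
            class = "group_score")
}

#' @export
print.group_score <- function(x, ...) {
  cat("<group_score> ", x$group$label, ": ",
      sprintf("%.4f", x$similarity), "\n", sep = "")
  invisible(x)
}

#' Score every candidate group
#'
#' @param groups List of `candidate_group`s (see [enumerate_groups()]).
#' @param tree A `spectra_tree`.
#' @param cfg A `scoring_config`.
#' @param candidates Optional full candidate list for the spectra
#'   cache; inferred from the groups when missing.
#' @return List of `group_score`s in group order.
#' @export
score_groups <- function(groups, tree, cfg = scoring_config(),
                         candidates = NULL) {
  stopifnot(length(groups) >= 1L)
  if (is.null(candidates)) {
    nmax <- max(vapply(groups, function(g) max(g$idx), integer(1)))
    candidates <- vector("list", nmax)
    for (g in groups) candidates[g$idx] <- g$members
  }
  cache <- .theo_cache(candidates, cfg)
  lapply(groups, similarity_score, tree = tree, cfg = cfg, cache = cache)
}

#' Opt in the best-matched candidate group(s)
#'
#' Keeps every group whose similarity is within `tie_epsilon` of the
#' maximum, ordered by similarity (descending) and then by group size
#' (ascending). A result of length one is a unique solution.
#'
#' @param scores List of `group_score`s.
#' @param cfg A `scoring_config`.
#' @return List of `group_score`s (the surviving groups with their
#'   scores).
#' @export
rank_and_opt <- function(scores, cfg = scoring_config()) {
  stopifnot(length(scores) >= 1L)
  sim <- vapply(scores, `[[`, numeric(1), "similarity")
  keep <- which(sim >= max(sim) - cfg$tie_epsilon)
  sizes <- vapply(scores[keep], function(s) s$group$n, integer(1))
  keep <- keep[order(-sim[keep], sizes)]
  scores[keep]
}

#' Write a score report
#'
#' @param scores List of `group_score`s.
#' @param path Optional TSV output path.
#' @return Data frame with group label, size, similarity and matched
#'   peak counts per spectrum (invisibly written to `path` if given).
#' @export
score_report <- function(scores, path = NULL) {
  df <- data.frame(
    group = vapply(scores, function(s) s$group$label, character(1)),
    n = vapply(scores, function(s) s$group$n, integer(1)),
    similarity = vapply(scores, `[[`, numeric(1), "similarity"),
    matched = vapply(scores, function(s) paste(names(s$n_matched),
                                               s$n_matched, sep = "=",
                                               collapse = ";"), character(1))
  )
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  df
}
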