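# Tie breaking: group posteriors, entropy, distinguishing power values
# (DPv) and the iterative identification session.
#
# When several candidate groups tie on similarity, each group is given
# a probability proportional to an indicator-weighted score f: the sum
# of tanh(beta * I_p) over every experimental peak that the group's
# theoretical spectra can explain. The DPv of a fragment ion is the
# expected reduction in posterior entropy if that ion were isolated
# for a further product-ion scan, under the hypothesis that each group
# in turn is the true one and would produce its own theoretical
# product spectrum.

.as_group_list <- function(groups) {
  lapply(groups, function(g) if (inherits(g, "group_score")) g$group else g)
}

#' Posterior probabilities of candidate groups
#'
#' Raw score `f(G_i)` is the sum over all peaks of all spectra (MS2
#' and every acquired product-ion spectrum) of `tanh(beta * I_p)` for
#' peaks explainable by any glycan in the group (matched within
#' `cfg$tol` by the group's theoretical counterpart). Probabilities
#' are `f_i / sum(f)`; when every `f` is zero the posterior is
#' uniform.
#'
#' @param groups List of `candidate_group`s (or `group_score`s).
#' @param tree A `spectra_tree`.
#' @param cfg A `scoring_config`.
#' @param cache Optional internal theoretical-spectra cache.
#' @return A `group_posterior`: list with `groups`, `p` (probabilities
#'   summing to 1) and `labels`.
#' @export
group_probability <- function(groups, tree, cfg = scoring_config(),
                              cache = NULL) {
  groups <- .as_group_list(groups)
  stopifnot(length(groups) >= 1L)
  if (is.null(cache)) {
    nmax <- max(vapply(groups, function(g) max(g$idx), integer(1)))
    cand <- vector("list", nmax)
    for (g in groups) cand[g$idx] <- g$members
    cache <- .theo_cache(cand, cfg)
  }
  f <- vapply(groups, function(g) {
    s <- similarity_score(g, tree, cfg, cache)
    s$similarity + cfg$alpha * g$n  # matched contribution without penalty
  }, numeric(1))
  p <- if (sum(f) > 0) f / sum(f) else rep(1 / length(f), length(f))
  structure(list(groups = groups, p = p,
                 labels = vapply(groups, `[[`, character(1), "label")),
            class = "group_posterior")
}

#' @export
print.group_posterior <- function(x, ...) {
  cat("<group_posterior>\n")
  print(data.frame(group = x$labels, p = round(x$p, 4)), row.names = FALSE)
  invisible(x)
}

#' Shannon entropy of a posterior, in bits
#'
#' @param p A `group_posterior` or a probability vector.
#' @return Entropy in bits (`0 * log 0` taken as 0).
#' @export
entropy_bits <- function(p) {
  if (inherits(p, "group_posterior")) p <- p$p
  stopifnot(all(p >= -1e-12), abs(sum(p) - 1) < 1e-6)
  p <- p[p > 0]
  -sum(p * log2(p))
}

# hypothetical product-ion spectrum predicted for a group: every
# theoretical fragment of the group at the given chain, at 50%
# relative intensity (theoretical intensities are unknown)
.hypothetical_spectrum <- function(group, chain, cfg, cache) {
  mzs <- sort(unique(unlist(lapply(group$idx, function(i) {
    theo_mz(.member_theo(cache, i, chain[-1]))
  }))))
  if (!length(mzs)) return(NULL)
  sp <- ms_spectrum(mzs, rep(1, length(mzs)),
                    level = length(chain) + 1L, precursor_chain = chain)
  sp$peaks$rel_intensity <- rep(50, nrow(sp$peaks))
  sp
}

#' Distinguishing power value of a fragment ion
#'
#' Expected information gain (bits) of acquiring a product-ion scan of
#' `peak_mz`: current posterior entropy minus the expectation, over
#' groups weighted by their posterior probability, of the posterior
#' entropy after ingesting the product spectrum that each group would
#' hypothetically produce at that precursor. Clamped at zero; a peak
#' whose hypothetical spectra are empty for every group has DPv 0.
#'
#' @param peak_mz Candidate precursor m/z (a peak of an acquired
#'   spectrum).
#' @param groups List of `candidate_group`s under consideration (at
#'   least 2).
#' @param posterior Their current `group_posterior`.
#' @param tree A `spectra_tree`.
#' @param cfg A `scoring_config`.
#' @param source_chain Precursor chain of the spectrum the peak was
#'   observed in (default: the MS2 chain), used to form the
#'   hypothetical scan's chain.
#' @param cache Optional theoretical-spectra cache.
#' @return Non-negative number of bits.
#' @export
dpv <- function(peak_mz, groups, posterior, tree, cfg = scoring_config(),
                source_chain = NULL, cache = NULL) {
  groups <- .as_group_list(groups)
  stopifnot(length(groups) >= 2L)
  if (is.null(source_chain)) source_chain <- tree$ms2$precursor_chain
  if (is.null(cache)) {
    nmax <- max(vapply(groups, function(g) max(g$idx), integer(1)))
    cand <- vector("list", nmax)
    for (g in groups) cand[g$idx] <- g$members
    cache <- .theo_cache(cand, cfg)
  }
  chain <- c(source_chain, peak_mz)
  hyp <- lapply(groups, .hypothetical_spectrum, chain = chain, cfg = cfg,
                cache = cache)
  if (all(vapply(hyp, is.null, logical(1)))) return(0)
  h0 <- entropy_bits(posterior$p)
  h_exp <- 0
  for (i in seq_along(groups)) {
    if (posterior$p[i] == 0) next
    aug <- tree
    if (!is.null(hyp[[i]])) {
      aug <- suppressWarnings(add_spectrum(aug, hyp[[i]], tol = cfg$tol))
    }
    post_i <- group_probability(groups, aug, cfg, cache)
    h_exp <- h_exp + posterior$p[i] * entropy_bits(post_i$p)
  }
  max(0, h0 - h_exp)
}

#' Rank candidate precursors for tie breaking
#'
#' Collects the peaks of all acquired spectra (MS2 and deeper) that
#' are above `cfg$min_precursor_mz`, are not a spectrum's own residual
#' precursor and have not been consumed already, computes the DPv of
#' each, and returns the full ranked list (highest DPv first, ties by
#' intensity). Peaks with zero DPv are dropped; an empty result means
#' no informative precursor remains.
#'
#' @param tree A `spectra_tree`.
#' @param groups Surviving `candidate_group`s (at least 2).
#' @param posterior Their `group_posterior`.
#' @param cfg A `scoring_config`.
#' @param used Numeric vector of already-consumed precursor m/z.
#' @param cache Optional theoretical-spectra cache.
#' @return Data frame with columns `mz`, `dpv`, `intensity`, `level`,
#'   `rank`; attribute `chains` holds each row's source precursor
#'   chain.
#' @export
recommend_precursor <- function(tree, groups, posterior,
                                cfg = scoring_config(), used = numeric(0),
                                cache = NULL) {
  groups <- .as_group_list(groups)
  stopifnot(length(groups) >= 2L)
  if (is.null(cache)) {
    nmax <- max(vapply(groups, function(g) max(g$idx), integer(1)))
    cand <- vector("list", nmax)
    for (g in groups) cand[g$idx] <- g$members
    cache <- .theo_cache(cand, cfg)
  }
  specs <- c(list(tree$ms2), unname(tree$msn))
  rows <- list()
  for (sp in specs) {
    pk <- sp$peaks
    own <- sp$precursor_chain[length(sp$precursor_chain)]
    keep <- pk$mz >= cfg$min_precursor_mz & abs(pk$mz - own) > cfg$tol
    if (length(used)) {
      keep <- keep & vapply(pk$mz, function(m) all(abs(m - used) > cfg$tol),
                            logical(1))
    }
    if (any(keep)) {
      rows[[length(rows) + 1L]] <-
        data.frame(mz = pk$mz[keep], intensity = pk$intensity[keep],
                   level = sp$level,
                   chain = I(replicate(sum(keep), sp$precursor_chain,
                                       simplify = FALSE)))
    }
  }
  empty <- data.frame(mz = numeric(0), dpv = numeric(0),
                      intensity = numeric(0), level = integer(0),
                      rank = integer(0))
  if (!length(rows)) return(empty)
  cand <- do.call(rbind, rows)
  # deduplicate near-coincident peaks across spectra: keep the
  # shallowest, most intense occurrence
  cand <- cand[order(cand$level, -cand$intensity), , drop = FALSE]
  dup <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (i > 1L) dup[i] <- any(abs(cand$mz[seq_len(i - 1L)][!dup[seq_len(i - 1L)]] -
                                    cand$mz[i]) <= cfg$tol)
  }
  cand <- cand[!dup, , drop = FALSE]
  cand$dpv <- vapply(seq_len(nrow(cand)), function(i) {
    dpv(cand$mz[i], groups, posterior, tree, cfg,
        source_chain = cand$chain[[i]], cache = cache)
  }, numeric(1))
  cand <- cand[cand$dpv > 1e-12, , drop = FALSE]
  if (!nrow(cand)) return(empty)
  cand <- cand[order(-cand$dpv, -cand$intensity), , drop = FALSE]
  out <- data.frame(mz = cand$mz, dpv = cand$dpv,
                    intensity = cand$intensity, level = cand$level,
                    rank = seq_len(nrow(cand)))
  attr(out, "chains") <- cand$chain
  out
}

#' Run an identification session
#'
#' Full pipeline on one sample: candidate lookup at the observed
#' molecular ion, collapse to branching patterns, group enumeration,
#' similarity scoring and opting; when several groups tie, posterior
#' probabilities are computed and, if no group clears
#' `cfg$prob_threshold`, the most informative precursor is
#' recommended. With an instrument callback the recommended scan is
#' acquired (virtually or scripted), ingested and the analysis
#' iterated; without one the session halts with the recommendation.
#'
#' @param tree A `spectra_tree` with at least an MS2 spectrum.
#' @param db A `glycan_db` of candidate structures.
#' @param cfg A `scoring_config`.
#' @param instrument Optional scan provider: a
#'   `function(level, precursor_chain)` returning an `ms_spectrum`
#'   (see [virtual_instrument()]).
#' @param precursor_mz Molecular-ion m/z; defaults to the MS2
#'   precursor.
#' @param max_iter Safety cap on tie-breaking iterations.
#' @return A `gips_session`: list with `status` (`resolved`, `tied` or
#'   `exhausted`), `opted` (list of `group_score`s), `posterior`,
#'   `scores`, `representatives`, `candidates`, `recommendation`,
#'   `tree` (final spectra tree) and `log` (audit data frame).
#' @export
run_session <- function(tree, db, cfg = scoring_config(), instrument = NULL,
                        precursor_mz = NULL, max_iter = 25L) {
  stopifnot(inherits(tree, "spectra_tree"), inherits(db, "glycan_db"))
  if (is.null(precursor_mz)) precursor_mz <- tree$ms2$precursor_chain[1]
  candidates <- find_candidates(db, precursor_mz, cfg$tol)
  if (!length(candidates)) {
    near <- sort(unique(round(db$permethylated_mz, 2)))
    near <- near[order(abs(near - precursor_mz))][seq_len(min(3, length(near)))]
    stop("no candidate structures at m/z ", sprintf("%.4f", precursor_mz),
         "; nearest database m/z: ", paste(near, collapse = ", "),
         call. = FALSE)
  }
  reps <- branching_pattern_classes(candidates)
  groups <- enumerate_groups(reps, cfg$max_candidates)
  cache <- .theo_cache(reps, cfg)
  used <- vapply(tree$msn, function(s) {
    s$precursor_chain[length(s$precursor_chain)]
  }, numeric(1))
  used <- as.numeric(used)
  log <- data.frame(iteration = integer(0), action = character(0),
                    detail = character(0))
  note <- function(it, action, detail) {
    log[nrow(log) + 1L, ] <<- list(it, action, detail)
  }
  result <- function(status, opted, posterior, scores, recommendation) {
    structure(list(status = status, opted = opted, posterior = posterior,
                   scores = scores, representatives = reps,
                   candidates = candidates,
                   recommendation = recommendation, tree = tree, log = log),
              class = "gips_session")
  }

  for (it in seq_len(max_iter)) {
    scores <- lapply(groups, similarity_score, tree = tree, cfg = cfg,
                     cache = cache)
    survivors <- rank_and_opt(scores, cfg)
    note(it, "score", paste0(length(survivors), " group(s) at max similarity ",
                             sprintf("%.4f", survivors[[1]]$similarity)))
    if (length(survivors) == 1L) {
      posterior <- group_probability(survivors, tree, cfg, cache)
      return(result("resolved", survivors, posterior, scores, NULL))
    }
    posterior <- group_probability(survivors, tree, cfg, cache)
    if (max(posterior$p) >= cfg$prob_threshold) {
      top <- which.max(posterior$p)
      note(it, "posterior", paste0(posterior$labels[top], " at p=",
                                   sprintf("%.3f", max(posterior$p))))
      return(result("resolved", survivors[top], posterior, scores, NULL))
    }
    recs <- recommend_precursor(tree, survivors, posterior, cfg,
                                used = used, cache = cache)
    if (!nrow(recs)) {
      note(it, "exhausted", "no informative precursor remains")
      return(result("exhausted", survivors, posterior, scores, NULL))
    }
    if (is.null(instrument)) {
      note(it, "recommend", sprintf("m/z %.4f (DPv %.4f)", recs$mz[1],
                                    recs$dpv[1]))
      return(result("tied", survivors, posterior, scores, recs))
    }
    chain <- c(attr(recs, "chains")[[1]], recs$mz[1])
    note(it, "scan", sprintf("MS%d @ m/z %.4f (DPv %.4f)", length(chain) + 1L,
                             recs$mz[1], recs$dpv[1]))
    newspec <- instrument(length(chain) + 1L, chain)
    stopifnot(inherits(newspec, "ms_spectrum"))
    tree <- suppressWarnings(add_spectrum(tree, newspec, tol = cfg$tol))
    used <- c(used, recs$mz[1])
  }
  scores <- lapply(groups, similarity_score, tree = tree, cfg = cfg,
                   cache = cache)
  survivors <- rank_and_opt(scores, cfg)
  posterior <- group_probability(survivors, tree, cfg, cache)
  note(max_iter, "exhausted", "iteration cap reached")
  result("exhausted", survivors, posterior, scores, NULL)
}

#' @export
print.gips_session <- function(x, ...) {
  cat("<gips_session> status: ", x$status, "\n", sep = "")
  cat("  candidates: ", length(x$candidates), " (",
      length(x$representatives), " branching patterns)\n", sep = "")
  for (s in x$opted) {
    cat("  opted ", s$group$label, "  similarity ",
        sprintf("%.4f", s$similarity), "\n", sep = "")
  }
  if (!is.null(x$posterior)) {
    cat("  max posterior: ", sprintf("%.3f", max(x$posterior$p)), "\n",
        sep = "")
  }
  if (!is.null(x$recommendation) && nrow(x$recommendation)) {
    cat("  next precursor: m/z ",
        sprintf("%.4f", x$recommendation$mz[1]), " (DPv ",
        sprintf("%.4f", x$recommendation$dpv[1]), ")\n", sep = "")
  }
  invisible(x)
}
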