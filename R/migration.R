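#' Combine per-tissue locality calls into per-bat classifications
#'
#' A bat is classified non-local when at least one of its tissue samples is
#' called non-local; a missing tissue is recorded as \code{"missing"} and
#' never makes a bat local on its own.
#'
#' @param calls data.frame of per-sample calls as returned by
#'   [locality_calls()] (columns \code{bat_id}, \code{tissue}, \code{call};
#'   \code{site_id}/\code{season}/\code{sex} are carried through when
#'   present).
#' @return data.frame with one row per bat: \code{bat_id},
#'   \code{fur_call}, \code{wing_call} (\code{"local"}, \code{"non-local"}
#'   or \code{"missing"}) and \code{combined}.
#' @export
combine_tissues <- function(calls) {
  if (!nrow(calls)) stop("no locality calls to combine", call. = FALSE)
  bad <- setdiff(unique(calls$call), c("local", "non-local"))
  if (length(bad))
    stop("unknown call value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  ids <- unique(calls$bat_id)
  pick <- function(id, tiss) {
    v <- calls$call[calls$bat_id == id & calls$tissue == tiss]
    if (!length(v)) "missing" else v[1]
  }
  fur_call <- vapply(ids, pick, character(1), tiss = "fur")
  wing_call <- vapply(ids, pick, character(1), tiss = "wing")
  out <- data.frame(
    bat_id = ids, fur_call = fur_call, wing_call = wing_call,
    combined = ifelse(fur_call == "non-local" | wing_call == "non-local",
                      "non-local", "local"),
    stringsAsFactors = FALSE
  )
  extra <- intersect(c("site_id", "season", "sex"), names(calls))
  if (length(extra)) {
    first <- calls[!duplicated(calls$bat_id), c("bat_id", extra)]
    out <- merge(out, first, by = "bat_id", sort = FALSE)
    out <- out[match(ids, out$bat_id), ]
  }
  rownames(out) <- NULL
  out
}

#' Site-by-season migration summaries
#'
#' Counts classified bats and non-local bats per (site, season) cell; the
#' per-cell totals partition the classified bats.
#'
#' @param classifications output of [combine_tissues()].
#' @param bats long-format bat table supplying \code{site_id} and
#'   \code{season} when the classifications do not carry them.
#' @return data.frame with columns \code{site_id}, \code{season},
#'   \code{n_bats}, \code{n_nonlocal}, \code{prop_nonlocal}.
#' @export
summarize_sites <- function(classifications, bats = NULL) {
  cl <- classifications
  if (!nrow(cl))
    return(data.frame(site_id = character(), season = character(),
                      n_bats = integer(), n_nonlocal = integer(),
                      prop_nonlocal = numeric()))
  if (!all(c("site_id", "season") %in% names(cl))) {
    if (is.null(bats))
      stop("classifications lack site/season; supply the bats table",
           call. = FALSE)
    first <- bats[!duplicated(bats$bat_id),
                  c("bat_id", "site_id", "season")]
    cl <- merge(cl, first, by = "bat_id", sort = FALSE)
  }
  orphan <- setdiff(classifications$bat_id, cl$bat_id)
  if (length(orphan))
    stop("referential-integrity error: classified bat(s) with no bat record: ",
         paste(utils::head(orphan, 5), collapse = ", "), call. = FALSE)
  agg <- aggregate(cbind(n_bats = rep(1L, nrow(cl)),
                         n_nonlocal = as.integer(cl$combined == "non-local"))
                   ~ site_id + season, data = cl, FUN = sum)
  agg$prop_nonlocal <- agg$n_nonlocal / agg$n_bats
  agg[order(agg$site_id, agg$season), , drop = FALSE]
}

#' Fur-wing agreement among non-local wing samples
#'
#' Over bats with both tissues classified, counts how many were called
#' non-local from the wing sample, how many of those were also non-local
#' from fur, and the per-season breakdown of the agreeing bats.
#'
#' @param classifications output of [combine_tissues()], carrying a
#'   \code{season} column.
#' @return list with \code{n_wing_nonlocal}, \code{n_both_nonlocal} and
#'   \code{by_season} (data.frame season / n_both_nonlocal).
#' @export
tissue_agreement <- function(classifications) {
  cl <- classifications
  both <- cl$fur_call != "missing" & cl$wing_call != "missing"
  cl <- cl[both, , drop = FALSE]
  wing_nl <- cl$wing_call == "non-local"
  both_nl <- wing_nl & cl$fur_call == "non-local"
  by_season <- if ("season" %in% names(cl) && any(both_nl)) {
    t <- table(cl$season[both_nl])
    data.frame(season = names(t), n_both_nonlocal = as.integer(t),
               stringsAsFactors = FALSE)
  } else {
    data.frame(season = character(), n_both_nonlocal = integer())
  }
  list(n_wing_nonlocal = sum(wing_nl), n_both_nonlocal = sum(both_nl),
       by_season = by_season)
}

# Shared LRT machinery: full vs reduced lme4 fit by ML, chi-square test.
.lrt <- function(full_formula, reduced_formula, data, term) {
  warnings <- character()
  fit_one <- function(f) {
    withCallingHandlers(
      suppressMessages(lme4::lmer(f, data = data, REML = FALSE)),
      warning = function(w) {
        warnings <<- c(warnings, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
  }
  full <- fit_one(full_formula)
  reduced <- fit_one(reduced_formula)
  if (lme4::isSingular(full) || lme4::isSingular(reduced))
    warnings <- c(warnings, "singular random-effects fit")
  chisq <- 2 * (as.numeric(logLik(full)) - as.numeric(logLik(reduced)))
  if (!is.finite(chisq)) chisq <- 0   # e.g. constant response: both saturate
  chisq <- max(0, chisq)
  df <- length(lme4::fixef(full)) - length(lme4::fixef(reduced))
  out <- list(term = term, chisq = chisq, df = df,
              p = if (df > 0) pchisq(chisq, df, lower.tail = FALSE) else 1,
              warnings = unique(warnings))
  class(out) <- "lmm_lrt"
  out
}

#' @export
print.lmm_lrt <- function(x, ...) {
  cat(sprintf("LRT for '%s': chisq(%d) = %.3f, p = %.4g\n",
              x$term, x$df, x$chisq, x$p))
  if (length(x$warnings))
    cat("  notes:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' Likelihood-ratio test of a fixed effect on tissue delta-2H
#'
#' Fits the linear mixed model \code{d2h ~ tissue + season + sex +
#' (1 | site_id) + (1 | bat_id)} by maximum likelihood (not REML, so that
#' likelihoods are comparable across fixed-effect structures), refits
#' without the tested term, and compares the two by a likelihood-ratio
#' chi-square test.
#'
#' @param long_table data.frame with columns \code{bat_id}, \code{site_id},
#'   \code{tissue}, \code{season}, \code{sex}, \code{d2h}; bats with both
#'   tissues contribute two rows.
#' @param tested_term one of \code{"tissue"}, \code{"season"}, \code{"sex"}.
#' @param dual_tissue_only restrict to bats carrying both tissues (default
#'   \code{TRUE}, matching a paired-tissue comparison).
#' @return object of class \code{"lmm_lrt"}: \code{term}, \code{chisq},
#'   \code{df}, \code{p}, \code{warnings}.
#' @export
lmm_lrt <- function(long_table, tested_term = c("tissue", "season", "sex"),
                    dual_tissue_only = TRUE) {
  tested_term <- match.arg(tested_term)
  lt <- long_table
  lt$d2h <- parse_permil(lt$d2h)
  if (dual_tissue_only) {
    tab <- table(lt$bat_id)
    lt <- lt[lt$bat_id %in% names(tab)[tab == 2], , drop = FALSE]
  }
  if (length(unique(lt[[tested_term]])) < 2)
    stop("tested term '", tested_term, "' has fewer than 2 levels",
         call. = FALSE)
  fixed <- c("tissue", "season", "sex")
  full <- reformulate(c(fixed, "(1 | site_id)", "(1 | bat_id)"),
                      response = "d2h")
  reduced <- reformulate(c(setdiff(fixed, tested_term),
                           "(1 | site_id)", "(1 | bat_id)"),
                         response = "d2h")
  .lrt(full, reduced, lt, tested_term)
}

#' Likelihood-ratio test of season or sex on the fur-wing difference
#'
#' Models the per-bat absolute fur-wing difference as \code{delta_d2h ~
#' season + sex + (1 | site_id)} by maximum likelihood. With one row per
#' bat an individual-level random intercept is unidentifiable (it is
#' confounded with the residual) and is therefore omitted.
#'
#' @param diff_table data.frame with columns \code{bat_id}, \code{site_id},
#'   \code{season}, \code{sex}, \code{delta_d2h} (one row per dual-tissue
#'   bat; see [delta_diff()]).
#' @param tested_term \code{"season"} or \code{"sex"}.
#' @return object of class \code{"lmm_lrt"}.
#' @export
delta_lmm_lrt <- function(diff_table, tested_term = c("season", "sex")) {
  tested_term <- match.arg(tested_term)
  if (anyDuplicated(diff_table$bat_id))
    stop("diff_table must have one row per bat", call. = FALSE)
  if (length(unique(diff_table[[tested_term]])) < 2)
    stop("tested term '", tested_term, "' has fewer than 2 levels",
         call. = FALSE)
  fixed <- c("season", "sex")
  full <- reformulate(c(fixed, "(1 | site_id)"), response = "delta_d2h")
  reduced <- reformulate(c(setdiff(fixed, tested_term), "(1 | site_id)"),
                         response = "delta_d2h")
  .lrt(full, reduced, diff_table, tested_term)
}
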