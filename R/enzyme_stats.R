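## enzyme_stats: enzyme-level clash scores, ensemble Z-scores and tail
## probabilities, and the RNA/DNA-cleavage prediction rule.

#' Enzyme-level maximal clash score over the recognition site
#'
#' The score is the maximum, over the site's nucleotides on both strands
#' (individual grafts, before any strand averaging), of the per-graft
#' maximal clash.  The `exclude_outermost` variant drops the first and last
#' site base pair before taking the maximum (relevant for enzymes whose
#' conflicts are driven by the flanking pairs of the target).
#'
#' @param clash_table per-position table from [score_duplex()].
#' @param site_span integer c(from, to); defaults to the span recorded on
#'   the table.
#' @param variant `"include_outermost"` or `"exclude_outermost"`.
#' @return list of class `enzyme_score`: `max_clash_site`, `variant`,
#'   `site_span`, `n_site_positions`, `n_missing`.
#' @export
enzyme_score <- function(clash_table,
                         site_span = attr(clash_table, "site_span"),
                         variant = c("include_outermost",
                                     "exclude_outermost")) {
  variant <- match.arg(variant)
  if (is.null(site_span)) stop("no site: site_span is not set")
  lv <- site_span[1L]:site_span[2L]
  if (variant == "exclude_outermost") {
    lv <- lv[-c(1L, length(lv))]
    if (!length(lv)) stop("no site: nothing left after dropping outermost pairs")
  }
  sel <- clash_table$pos %in% lv
  if (!any(sel)) stop("no site: span outside the table")
  vals <- c(clash_table$max_1[sel], clash_table$max_2[sel])
  structure(list(max_clash_site = if (all(is.na(vals))) NA_real_
                                  else max(vals, na.rm = TRUE),
                 variant = variant, site_span = site_span,
                 n_site_positions = length(lv), n_missing = sum(is.na(vals))),
            class = "enzyme_score")
}

#' Ensemble Z-scores and tail probabilities
#'
#' Standardizes enzyme-level scores by subtracting the ensemble average and
#' dividing by the sample standard deviation (n - 1).  Normal-theory tail
#' probabilities are reported (one-sided lower tail and two-sided), along
#' with empirical ranks and the rank-based probability r / (n + 1).
#'
#' @param scores numeric vector (optionally named by enzyme), length >= 2.
#' @return data.frame: enzyme, score, z, p_one_sided, p_two_sided, rank,
#'   p_empirical.
#' @export
zscores <- function(scores) {
  x <- as.numeric(scores)
  if (length(x) < 2L) stop("need at least 2 scores")
  s <- stats::sd(x)
  if (!is.finite(s) || s < 1e-12) {
    stop("degenerate ensemble: zero standard deviation")
  }
  z <- (x - mean(x)) / s
  r <- rank(x, ties.method = "average")
  data.frame(enzyme = if (!is.null(names(scores))) names(scores)
                      else as.character(seq_along(x)),
             score = x, z = z,
             p_one_sided = stats::pnorm(z),
             p_two_sided = 2 * stats::pnorm(-abs(z)),
             rank = r, p_empirical = r / (length(x) + 1),
             stringsAsFactors = FALSE)
}

#' Predict RNA/DNA heteroduplex cleavage competence
#'
#' An enzyme is predicted to cleave RNA/DNA heteroduplexes when it binds its
#' dsDNA target with a sufficient fraction of A-like steps AND the grafted
#' 2'-OH groups in the recognition site cause no clash beyond the
#' compensable threshold.
#'
#' @param n_A_steps number of A-classified recognition-site steps.
#' @param n_site_steps total recognition-site steps.
#' @param max_clash_site enzyme-level maximal site clash (Angstrom); an
#'   `enzyme_score` object is also accepted.
#' @param a_fraction_min minimum A-like step fraction (default 0.5).
#' @param clash_threshold maximal compensable clash (default 1.1 Angstrom).
#' @return logical flag.
#' @export
predict_cleaver <- function(n_A_steps, n_site_steps, max_clash_site,
                            a_fraction_min = 0.5, clash_threshold = 1.1) {
  if (inherits(max_clash_site, "enzyme_score")) {
    max_clash_site <- max_clash_site$max_clash_site
  }
  if (n_site_steps <= 0) return(FALSE)
  (n_A_steps / n_site_steps >= a_fraction_min) &&
    (max_clash_site <= clash_threshold)
}
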