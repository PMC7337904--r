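## pipeline: per-structure orchestration (read -> pair -> site -> geometry
## -> grooves -> graft -> clash -> score -> predict) and ensemble reports.

#' Full analysis of one protein-nucleic-acid complex (or naked duplex)
#'
#' Runs every stage of the pipeline and collects the evidence into an
#' `enzyme_report`: per-step parameters with A/B classification, groove
#' summary, per-position grafted-O2' clash table, the enzyme-level maximal
#' site clash, and the cleavage-competence prediction.  Stage failures that
#' leave later independent stages runnable (e.g. an unmatched site pattern)
#' produce partial reports with warnings rather than errors.
#'
#' @param input a file path, a `structure_model`, or a `duplex`.
#' @param site_pattern IUPAC recognition pattern (e.g. `"GGWCC"`), or NA to
#'   skip site-dependent stages.
#' @param enzyme_id identifier used in reports.
#' @param chain_pair optional chain restriction for pairing.
#' @param variant enzyme-score variant (see [enzyme_score()]).
#' @param zp_A,zp_B step-classification thresholds (Angstrom).
#' @param clash_threshold compensable-clash threshold (Angstrom).
#' @param a_fraction_min minimum A-like step fraction for the prediction.
#' @param groove_def a [groove_definition()].
#' @param radius_set radii table for [assign_radii()].
#' @return object of class `enzyme_report`.
#' @export
analyze_structure <- function(input, site_pattern = NA, enzyme_id = NULL,
                              chain_pair = NULL,
                              variant = "include_outermost",
                              zp_A = 1.5, zp_B = 0.5,
                              clash_threshold = 1.1, a_fraction_min = 0.5,
                              groove_def = groove_definition(),
                              radius_set = bondi_radii()) {
  if (is.character(input)) {
    model <- read_structure(input)
    if (is.null(enzyme_id)) enzyme_id <- basename(input)
  } else if (inherits(input, "structure_model")) {
    model <- input
    if (is.null(enzyme_id)) enzyme_id <- model$source_id
  } else if (inherits(input, "duplex")) {
    model <- input$model
    if (is.null(enzyme_id)) enzyme_id <- model$source_id
  } else stop("input must be a path, structure_model or duplex")
  model <- assign_radii(model, radius_set)
  duplex <- if (inherits(input, "duplex")) { input$model <- model; input }
            else pair_bases(model, chain_pair = chain_pair)
  if (!is.na(site_pattern)) duplex <- annotate_site(duplex, site_pattern)
  geom <- duplex_geometry(duplex, model, zp_A = zp_A, zp_B = zp_B)
  grooves <- tryCatch(groove_profile(duplex, model, groove_def),
                      error = function(e) { warning(conditionMessage(e)); NULL })
  clash_tab <- score_duplex(duplex, model, threshold = clash_threshold)
  ## site-step classification counts
  site_steps <- NULL; score <- NULL; prediction <- NA
  if (!is.null(duplex$site_span)) {
    sp <- duplex$site_span
    site_steps <- geom$steps[geom$steps$step >= sp[1L] &
                               geom$steps$step <= sp[2L] - 1L, , drop = FALSE]
    score <- enzyme_score(clash_tab, site_span = sp, variant = variant)
    prediction <- predict_cleaver(
      n_A_steps = sum(site_steps$classification == "A", na.rm = TRUE),
      n_site_steps = nrow(site_steps),
      max_clash_site = score,
      a_fraction_min = a_fraction_min, clash_threshold = clash_threshold)
  } else if (!is.na(site_pattern)) {
    warning("no enzyme score: site pattern did not match")
  }
  groove_sum <- if (!is.null(grooves)) {
    tryCatch(groove_summary(grooves, span = duplex$site_span),
             error = function(e) NULL)
  }
  structure(list(
    enzyme_id = enzyme_id,
    site_pattern = if (is.na(site_pattern)) NA_character_
                   else toupper(site_pattern),
    duplex = duplex, geometry = geom, grooves = grooves,
    groove_summary = groove_sum, clash_table = clash_tab,
    site_steps = site_steps, enzyme_score = score,
    n_A_steps = if (!is.null(site_steps))
      sum(site_steps$classification == "A", na.rm = TRUE) else NA_integer_,
    n_site_steps = if (!is.null(site_steps)) nrow(site_steps)
                   else NA_integer_,
    displacement = duplex_displacement(geom),
    predicted_cleaver = prediction,
    provenance = list(
      package_version = as.character(utils::packageVersion("agraft")),
      displacement_definition = DISPLACEMENT_DEFAULT,
      groove_definition = groove_def$id,
      zp_A = zp_A, zp_B = zp_B, clash_threshold = clash_threshold,
      a_fraction_min = a_fraction_min, variant = variant)),
    class = "enzyme_report")
}

#' @export
print.enzyme_report <- function(x, ...) {
  cat("<enzyme_report> ", x$enzyme_id, "\n", sep = "")
  cat("  duplex: ", nrow(x$duplex$pairs), " bp, sequence 5'-",
      paste(x$duplex$pairs$base_i, collapse = ""), "-3'\n", sep = "")
  if (!is.null(x$site_steps)) {
    cat(sprintf("  site %s at %d-%d: %d/%d steps A-like\n",
                x$site_pattern, x$duplex$site_span[1L],
                x$duplex$site_span[2L], x$n_A_steps, x$n_site_steps))
  }
  if (!is.null(x$enzyme_score)) {
    cat(sprintf("  max site clash: %.3f A (%s)\n",
                x$enzyme_score$max_clash_site, x$enzyme_score$variant))
  }
  cat(sprintf("  mean displacement from helix axis: %.2f A\n",
              x$displacement))
  if (!is.null(x$groove_summary)) {
    cat(sprintf("  grooves (site mean): minor depth %.1f, major depth %.1f A\n",
                x$groove_summary[["minor_depth"]],
                x$groove_summary[["major_depth"]]))
  }
  if (!is.na(x$predicted_cleaver)) {
    cat("  predicted RNA/DNA cleaver:", if (x$predicted_cleaver) "YES"
        else "no", "\n")
  }
  invisible(x)
}

#' @export
summary.enzyme_report <- function(object, ...) {
  print(object)
  cat("\nstep parameters:\n")
  print(object$geometry$steps[, c("step", "dinucleotide", "twist", "rise",
                                  "x_displacement", "zp", "classification")],
        digits = 3)
  invisible(object)
}

#' Ensemble analysis over several enzyme reports or scores
#'
#' Pools enzyme-level maximal clash scores, computes Z-scores and tail
#' probabilities, a cumulative distribution table, and a ranked listing.
#' Output is independent of input order.
#'
#' @param x list of `enzyme_report` objects, or a named numeric vector of
#'   enzyme-level scores.
#' @return list of class `ensemble_report`: `table` (per-enzyme statistics,
#'   ranked), `cumulative` (score vs fraction of enzymes at or below it).
#' @export
analyze_ensemble <- function(x) {
  if (is.numeric(x)) {
    scores <- x
  } else {
    ok <- vapply(x, function(r) inherits(r, "enzyme_report") &&
                   !is.null(r$enzyme_score), logical(1L))
    if (sum(ok) < 2L) stop("ensemble error: fewer than 2 usable reports")
    scores <- vapply(x[ok], function(r) r$enzyme_score$max_clash_site,
                     numeric(1L))
    names(scores) <- vapply(x[ok], `[[`, character(1L), "enzyme_id")
  }
  if (length(scores) < 2L) stop("ensemble error: fewer than 2 scores")
  tab <- zscores(scores)
  tab <- tab[order(tab$score, tab$enzyme), , drop = FALSE]
  rownames(tab) <- NULL
  cum <- data.frame(score = tab$score,
                    fraction = seq_len(nrow(tab)) / nrow(tab))
  structure(list(table = tab, cumulative = cum, n = nrow(tab)),
            class = "ensemble_report")
}

#' @export
print.ensemble_report <- function(x, ...) {
  cat("<ensemble_report> ", x$n, " enzymes\n", sep = "")
  print(utils::head(x$table, 10L), digits = 3)
  invisible(x)
}

#' Write an enzyme report as JSON (+ optional TSV tables)
#'
#' @param report an `enzyme_report`.
#' @param path JSON output file.
#' @param tables also write the per-step and per-position TSV tables next
#'   to it.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, tables = FALSE) {
  payload <- list(
    enzyme_id = report$enzyme_id, site_pattern = report$site_pattern,
    n_pairs = nrow(report$duplex$pairs),
    n_A_steps = report$n_A_steps, n_site_steps = report$n_site_steps,
    max_clash_site = if (!is.null(report$enzyme_score))
      report$enzyme_score$max_clash_site else NA,
    displacement = report$displacement,
    groove_summary = as.list(report$groove_summary),
    predicted_cleaver = report$predicted_cleaver,
    provenance = report$provenance)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  if (tables) {
    base <- sub("\\.json$", "", path)
    write_step_table(report$geometry, paste0(base, "_steps.tsv"))
    write_clash_table(report$clash_table, paste0(base, "_clashes.tsv"))
  }
  invisible(path)
}
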