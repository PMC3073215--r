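#' Assign detected dots to nuclei
#'
#' Each dot receives the nucleus label found at its centroid pixel; dots
#' whose centroid lies on background get `NA` and are excluded from scoring.
#' Dots are never attributed to a nucleus they merely touch.
#'
#' @param dots Dot-record data frame (`row`/`col` are 0-based centroids).
#' @param nuclei A `nucleus_map`.
#' @return The dot records with `nucleus_id` filled in.
#' @export
assign_dots <- function(dots, nuclei) {
  stopifnot(inherits(nuclei, "nucleus_map"))
  if (nrow(dots) == 0L) return(dots)
  r <- floor(dots$row + 0.5) + 1L
  c <- floor(dots$col + 0.5) + 1L
  nr <- nrow(nuclei$labels); nc <- ncol(nuclei$labels)
  if (any(r < 1L | r > nr | c < 1L | c > nc)) {
    stop("dot centroid outside image bounds")
  }
  lab <- nuclei$labels[cbind(r, c)]
  dots$nucleus_id <- ifelse(lab > 0L, lab, NA_integer_)
  dots
}

#' Per-nucleus HER2 and CEP17 dot counts and ratios
#'
#' Sums the estimated copy counts per channel within each nucleus and forms
#' the HER2/CEP17 ratio `red_count / green_count`. Nuclei without any green
#' (CEP17) signal have an undefined ratio and are marked excluded: at least
#' one centromere-17 copy per nucleus is biologically expected, so a missing
#' green count indicates a detection failure rather than a zero denominator
#' worth scoring.
#'
#' @param dots Assigned dot records (dots with `NA` `nucleus_id` are
#'   ignored).
#' @param nuclei A `nucleus_map`.
#' @return Data frame with one row per nucleus: `nucleus_id`, `red_count`,
#'   `green_count`, `ratio` (`NA` when excluded), `excluded`.
#' @export
nucleus_scores <- function(dots, nuclei) {
  stopifnot(inherits(nuclei, "nucleus_map"))
  ids <- nuclei$features$label_id
  count_for <- function(ch) {
    vapply(ids, function(id) {
      sel <- !is.na(dots$nucleus_id) & dots$nucleus_id == id &
        dots$channel == ch
      sum(dots$est_count[sel])
    }, numeric(1))
  }
  red <- if (nrow(dots)) count_for("red") else numeric(length(ids))
  green <- if (nrow(dots)) count_for("green") else numeric(length(ids))
  data.frame(
    nucleus_id = ids,
    red_count = as.integer(red),
    green_count = as.integer(green),
    ratio = ifelse(green >= 1, red / pmax(green, 1), NA_real_),
    excluded = green < 1
  )
}

#' Classify a HER2/CEP17 ratio against the decision bands
#'
#' Ratios above 2.2 denote amplification, ratios below 1.8 the normal
#' (non-amplified) state, and the inclusive band `[1.8, 2.2]` is equivocal
#' and needs additional investigation.
#'
#' @param ratio Non-negative ratio(s).
#' @return Character vector: `"amplified"`, `"equivocal"` or
#'   `"non_amplified"`.
#' @export
classify_ratio <- function(ratio) {
  if (any(is.na(ratio)) || any(ratio < 0)) {
    stop("ratio must be non-negative")
  }
  ifelse(ratio > 2.2, "amplified",
         ifelse(ratio < 1.8, "non_amplified", "equivocal"))
}

#' Naive copy-count estimate for merged dots
#'
#' Overlapping probe signals (common in the red channel of amplified cases)
#' merge into a single connected component and are undercounted. This
#' estimator divides the component area by a reference single-dot area and
#' rounds, flooring at 1. It is a crude area heuristic — resolving merged
#' signals properly needs dedicated post-processing — and is therefore
#' disabled by default (`est_count = 1` for every dot).
#'
#' @param dot_area Component area(s) in pixels.
#' @param reference_area Typical single-dot area, by default the median area
#'   of green-channel dots in the case.
#' @return Integer copy count(s), each >= 1.
#' @export
estimate_count <- function(dot_area, reference_area) {
  if (any(reference_area <= 0)) stop("reference_area must be positive")
  pmax(1L, as.integer(floor(dot_area / reference_area + 0.5)))
}

unscorable_error <- function(message, qc_warnings = character()) {
  structure(
    class = c("fishdots_unscorable", "error", "condition"),
    list(message = message, call = sys.call(-1), qc_warnings = qc_warnings)
  )
}

#' Case-level HER2/CEP17 score
#'
#' Averages the per-nucleus ratios over the first `max_cells` scorable
#' nuclei (in nucleus index order) and classifies the mean against the
#' 1.8/2.2 bands. The protocol scores 60 cells per case; when fewer are
#' available all are used and the shortfall is recorded as a QC note.
#'
#' @param scores Output of [nucleus_scores()] (rows from several images may
#'   be pooled).
#' @param max_cells Maximum number of nuclei entering the average.
#' @param qc_warnings Character vector of QC notes carried into the score.
#' @param mode `"mean_of_ratios"` (the protocol's "averaging the scores";
#'   default) or `"ratio_of_sums"` (total red over total green in the used
#'   nuclei); the two differ when copy numbers vary between nuclei.
#' @return A `case_score` object: `mean_ratio`, `n_nuclei_used`,
#'   `max_cells`, `status`, `qc_warnings`, `method` (filled by the
#'   pipeline).
#' @export
case_score <- function(scores, max_cells = 60L, qc_warnings = character(),
                       mode = c("mean_of_ratios", "ratio_of_sums")) {
  mode <- match.arg(mode)
  eligible <- scores[!scores$excluded, , drop = FALSE]
  if (nrow(eligible) == 0L) {
    stop(unscorable_error(
      "unscorable case: no nucleus with at least one CEP17 (green) signal",
      qc_warnings
    ))
  }
  eligible <- eligible[order(eligible$nucleus_id), , drop = FALSE]
  used <- head(eligible, max_cells)
  mean_ratio <- if (mode == "mean_of_ratios") {
    mean(used$ratio)
  } else {
    sum(used$red_count) / sum(used$green_count)
  }
  if (nrow(eligible) < max_cells) {
    qc_warnings <- c(qc_warnings, sprintf(
      "only %d scorable nuclei available (target %d)",
      nrow(eligible), max_cells
    ))
  }
  structure(
    list(mean_ratio = mean_ratio,
         n_nuclei_used = nrow(used),
         max_cells = as.integer(max_cells),
         status = classify_ratio(mean_ratio),
         qc_warnings = qc_warnings,
         method = NA_character_),
    class = "case_score"
  )
}

#' @export
print.case_score <- function(x, ...) {
  cat("HER2/CEP17 case score", if (!is.na(x$method)) paste0(" [", x$method, "]"),
      "\n  mean ratio: ", format(x$mean_ratio, digits = 4),
      " over ", x$n_nuclei_used, " nuclei -> ", x$status, "\n", sep = "")
  if (length(x$qc_warnings)) {
    cat("  QC:", paste(x$qc_warnings, collapse = "; "), "\n")
  }
  invisible(x)
}
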