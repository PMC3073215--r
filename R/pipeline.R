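#' Pipeline configuration
#'
#' Bundles every tunable of the scoring pipeline under one object. A flat
#' YAML file with namespaced keys (`seg.*`, `mm.*`, `mf.*`, plus the
#' top-level keys) can be loaded with [config_from_yaml()]; unknown keys
#' are rejected.
#'
#' @param method Dot-detection engine(s): `"both"` (default), `"mm"` or
#'   `"imf"`. In `"both"` mode the two engines share one segmentation per
#'   image, so their scores are paired at the nucleus level.
#' @param seg [segmentation_params()].
#' @param mm [mm_detect_params()].
#' @param mf [mf_params()].
#' @param max_cells Nuclei entering the case average (protocol: 60).
#' @param estimate_counts Enable the naive area-based copy-count estimate
#'   ([estimate_count()]) for merged dots; off by default.
#' @param ratio_mode See [case_score()].
#' @param debug Write intermediate images (enhanced channels, alpha image)
#'   when the pipeline is given an output directory.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(method = c("both", "mm", "imf"),
                            seg = segmentation_params(),
                            mm = mm_detect_params(),
                            mf = mf_params(),
                            max_cells = 60L,
                            estimate_counts = FALSE,
                            ratio_mode = c("mean_of_ratios", "ratio_of_sums"),
                            debug = FALSE) {
  method <- match.arg(method)
  ratio_mode <- match.arg(ratio_mode)
  structure(
    list(method = method, seg = seg, mm = mm, mf = mf,
         max_cells = as.integer(max_cells),
         estimate_counts = isTRUE(estimate_counts),
         ratio_mode = ratio_mode, debug = isTRUE(debug)),
    class = "pipeline_config"
  )
}

#' Load a pipeline configuration from a flat YAML file
#'
#' Keys are namespaced with dots (`seg.min_area`, `mm.se_radius`,
#' `mf.alpha_percentile`, ...) or nested under `seg:`/`mm:`/`mf:` blocks;
#' both spellings are accepted. Any key that does not correspond to a known
#' parameter raises an error, so typos cannot silently fall back to
#' defaults.
#'
#' @param path YAML file path.
#' @return A [pipeline_config()].
#' @export
config_from_yaml <- function(path) {
  raw <- yaml::yaml.load_file(path)
  if (is.null(raw)) raw <- list()
  flat <- list()
  for (k in names(raw)) {
    v <- raw[[k]]
    if (is.list(v)) {
      for (k2 in names(v)) flat[[paste(k, k2, sep = ".")]] <- v[[k2]]
    } else {
      flat[[k]] <- v
    }
  }
  groups <- list(
    seg = formals(segmentation_params),
    mm = formals(mm_detect_params),
    mf = formals(mf_params)
  )
  top_known <- c("method", "max_cells", "estimate_counts", "ratio_mode", "debug")
  args <- list(seg = list(), mm = list(), mf = list(), top = list())
  for (k in names(flat)) {
    if (grepl("\\.", k)) {
      parts <- strsplit(k, ".", fixed = TRUE)[[1]]
      g <- parts[1]; f <- paste(parts[-1], collapse = ".")
      if (!g %in% names(groups) || !f %in% names(groups[[g]])) {
        stop("unknown configuration key: ", k)
      }
      args[[g]][[f]] <- flat[[k]]
    } else {
      if (!k %in% top_known) stop("unknown configuration key: ", k)
      args$top[[k]] <- flat[[k]]
    }
  }
  do.call(pipeline_config, c(
    args$top,
    list(seg = do.call(segmentation_params, args$seg),
         mm = do.call(mm_detect_params, args$mm),
         mf = do.call(mf_params, args$mf))
  ))
}

detect_for_method <- function(method, channel, nuclei, config, channel_name) {
  if (method == "mm") {
    detect_dots_mm(channel, nuclei, config$mm, channel_name = channel_name)
  } else {
    detect_dots_imf(channel, nuclei, config$mf, channel_name = channel_name)
  }
}

#' Run the full scoring pipeline over one or more images of a case
#'
#' Per image: read, split channels, segment nuclei from the blue channel,
#' run DAPI quality control, detect red and green dots with the configured
#' engine(s) and assign them to nuclei. Nuclei are pooled across images
#' (several fields of view are usually needed to reach the target cell
#' count), then one case score is computed per engine. In `"both"` mode the
#' engines share the same segmentation, so their results are directly
#' comparable.
#'
#' @param images Character vector of image paths, a single [rgb_image()],
#'   or a list of `rgb_image` objects.
#' @param config A [pipeline_config()].
#' @return A `case_report`: list with `cases` (named list of `case_score`
#'   per method), `nucleus_scores` (named list of data frames, with pooled
#'   `nucleus_id`), `images` (per-image log data frame) and `qc_warnings`.
#'   An unscorable case (e.g. no DAPI, hence no nuclei) raises a classed
#'   error (`fishdots_unscorable`) carrying the QC context.
#' @export
run_pipeline <- function(images, config = pipeline_config()) {
  if (inherits(images, "rgb_image")) images <- list(images)
  if (length(images) == 0L) stop("at least one image is required")
  methods <- if (config$method == "both") c("mm", "imf") else config$method

  qc_warnings <- character()
  img_log <- list()
  pooled_scores <- setNames(vector("list", length(methods)), methods)
  pooled_dots <- setNames(vector("list", length(methods)), methods)
  offset <- 0L

  for (i in seq_along(images)) {
    img <- images[[i]]
    name <- if (is.character(img)) basename(img) else sprintf("image_%d", i)
    if (is.character(img)) img <- read_rgb(img)
    ch <- split_channels(img)
    nuclei <- segment_nuclei(ch$blue, config$seg)
    qc <- qc_dapi(ch$blue, nuclei)
    if (qc$no_dapi_suspected) {
      qc_warnings <- c(qc_warnings, sprintf(
        "%s: no DAPI suspected (nuclear area fraction %.4f)",
        name, qc$nuclear_area_fraction
      ))
    }
    n_red <- n_green <- 0L
    for (m in methods) {
      red <- detect_for_method(m, ch$red, nuclei, config, "red")
      green <- detect_for_method(m, ch$green, nuclei, config, "green")
      dots <- assign_dots(rbind(red, green), nuclei)
      dots <- dots[!is.na(dots$nucleus_id), , drop = FALSE]
      dots$nucleus_id <- dots$nucleus_id + offset
      pooled_dots[[m]] <- rbind(pooled_dots[[m]], dots)
      n_red <- max(n_red, sum(dots$channel == "red"))
      n_green <- max(n_green, sum(dots$channel == "green"))
    }
    # keep per-image nucleus features for pooled scoring
    feats <- nuclei$features
    if (nrow(feats)) feats$label_id <- feats$label_id + offset
    img_log[[i]] <- data.frame(
      image = name, n_nuclei = nrow(nuclei$features),
      n_red_dots = n_red, n_green_dots = n_green,
      no_dapi_suspected = qc$no_dapi_suspected
    )
    attr(img_log[[i]], "features") <- feats
    offset <- offset + nrow(nuclei$features)
  }

  all_features <- do.call(rbind, lapply(img_log, attr, "features"))
  pooled_map <- new_nucleus_map(matrix(0L, 1, 1), all_features)

  cases <- list()
  nscore_tabs <- list()
  for (m in methods) {
    dots <- pooled_dots[[m]]
    if (is.null(dots)) dots <- dot_records()
    if (config$estimate_counts && nrow(dots)) {
      ref <- median(dots$area[dots$channel == "green"])
      if (is.finite(ref) && ref > 0) {
        dots$est_count <- estimate_count(dots$area, ref)
      }
    }
    scores <- nucleus_scores(dots, pooled_map)
    cs <- case_score(scores, max_cells = config$max_cells,
                     qc_warnings = qc_warnings, mode = config$ratio_mode)
    cs$method <- toupper(m)
    cases[[m]] <- cs
    nscore_tabs[[m]] <- scores
  }

  structure(
    list(cases = cases, nucleus_scores = nscore_tabs,
         images = do.call(rbind, lapply(img_log, function(x) {
           attr(x, "features") <- NULL; x
         })),
         qc_warnings = qc_warnings),
    class = "case_report"
  )
}

#' @export
print.case_report <- function(x, ...) {
  cat("FISH case report over", nrow(x$images), "image(s)\n")
  for (cs in x$cases) print(cs)
  invisible(x)
}

#' Write case reports to disk
#'
#' For each engine writes `nuclei_<method>.csv` (per-nucleus counts and
#' ratios) and `case_<method>.json` (mean ratio, nuclei used, status, QC
#' warnings). Overwrites existing files, so re-running a case is
#' idempotent.
#'
#' @param report A `case_report` from [run_pipeline()].
#' @param outdir Output directory (created if missing).
#' @param case_id Identifier written into the per-nucleus tables.
#' @return Character vector of the files written, invisibly.
#' @export
write_report <- function(report, outdir, case_id = "case") {
  stopifnot(inherits(report, "case_report"))
  if (!dir.exists(outdir)) {
    ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", outdir)
  }
  written <- character()
  for (m in names(report$cases)) {
    cs <- report$cases[[m]]
    tab <- report$nucleus_scores[[m]]
    tab <- cbind(case_id = case_id, tab)
    csv <- file.path(outdir, paste0("nuclei_", m, ".csv"))
    write.csv(tab, csv, row.names = FALSE)
    js <- file.path(outdir, paste0("case_", m, ".json"))
    jsonlite::write_json(
      list(case_id = case_id, method = cs$method,
           mean_ratio = cs$mean_ratio, n_nuclei_used = cs$n_nuclei_used,
           status = cs$status, qc_warnings = as.list(cs$qc_warnings)),
      js, auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
    written <- c(written, csv, js)
  }
  invisible(written)
}
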