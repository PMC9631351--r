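# Run configuration, extraction driver and the static HTML report.

#' Run configuration
#'
#' Bundles every processing choice so a report can embed the exact
#' configuration it was produced with. Serializable to JSON.
#'
#' @param instrument An [instrument_model()].
#' @param criteria A [scan_criteria()].
#' @param species Character vector of registry species to extract.
#' @param standards A [standard_ratios()].
#' @param solvent_ppm Solvent 2H/1H (ppm) for the exchangeable correction.
#' @param mad_k Outlier-trim width (MAD units) before aggregation.
#' @param seed Seed for the stochastic diagnostics (subsampling).
#' @return List with class `run_config`.
#' @export
run_config <- function(instrument = instrument_model(),
                       criteria = scan_criteria(),
                       species = names(immonium_registry()),
                       standards = standard_ratios(),
                       solvent_ppm = 150, mad_k = 5, seed = 1) {
  stopifnot(inherits(instrument, "instrument_model"),
            inherits(criteria, "scan_criteria"),
            solvent_ppm > 0, mad_k > 0)
  structure(list(instrument = instrument, criteria = criteria,
                 species = species, standards = standards,
                 solvent_ppm = solvent_ppm, mad_k = mad_k, seed = seed,
                 version = as.character(utils::packageVersion("isofine"))),
            class = "run_config")
}

config_json <- function(config) {
  jsonlite::toJSON(lapply(unclass(config), unclass), auto_unbox = TRUE,
                   pretty = TRUE, digits = NA)
}

#' Extract one mzML run to a ratio-record CSV
#'
#' The extract step of the workflow: read the mzML, select the isoMS
#' scans, recalibrate, fit fine-structure components for every configured
#' species, and write one CSV row per (scan, species). A JSON sidecar with
#' kept/dropped scan counts and per-species yields is written next to the
#' CSV.
#'
#' @param mzml_path Input mzML file.
#' @param out_csv Output CSV path.
#' @param config A [run_config()].
#' @return The records tibble, invisibly. Errors if no scan passes the
#'   isoMS selection.
#' @export
extract_to_csv <- function(mzml_path, out_csv, config = run_config()) {
  run <- read_run(mzml_path)
  scans <- select_isoms_scans(run, config$criteria)
  counts <- attr(scans, "selection_counts")
  if (length(scans) == 0) {
    stop("no scans in ", mzml_path, " match the isoMS criteria (",
         paste(names(counts), counts, sep = "=", collapse = ", "), ")")
  }
  registry <- immonium_registry(config$species,
                                mz_range = config$criteria$mz_range)
  rec <- extract_run(scans, registry, config$instrument, criteria = NULL)
  write_records_csv(rec, out_csv)
  sidecar <- list(
    input = mzml_path, output = out_csv,
    scans = as.list(counts),
    records = nrow(rec),
    skipped_species_scans = attr(rec, "skipped"),
    mz_offset_ppm = attr(rec, "mz_offset_ppm"),
    species_found = as.list(table(rec$species)),
    version = config$version
  )
  jsonlite::write_json(sidecar, paste0(out_csv, ".log.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(rec)
}

# ggplot -> base64 <img>; falls back to a notice if no graphics device works
.plot_b64 <- function(p, width = 6.5, height = 4) {
  tf <- tempfile(fileext = ".png")
  ok <- tryCatch({
    grDevices::png(tf, width = width * 100, height = height * 100, res = 100)
    print(p)
    grDevices::dev.off()
    TRUE
  }, error = function(e) {
    try(grDevices::dev.off(), silent = TRUE)
    FALSE
  })
  if (!ok || !file.exists(tf)) {
    return("<p class='notice'>figure unavailable (no PNG device)</p>")
  }
  raw <- readBin(tf, "raw", file.info(tf)$size)
  unlink(tf)
  sprintf("<img src='data:image/png;base64,%s' alt='figure'/>",
          jsonlite::base64_enc(raw))
}

.html_table <- function(df, digits = 6) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], signif, digits = digits)
  head_row <- paste0("<tr>", paste0("<th>", names(df), "</th>", collapse = ""), "</tr>")
  body <- apply(df, 1, function(r) {
    paste0("<tr>", paste0("<td>", r, "</td>", collapse = ""), "</tr>")
  })
  paste0("<table>", head_row, paste(body, collapse = "\n"), "</table>")
}

#' Build the HTML report
#'
#' A single static HTML file summarising an experiment: per-sample ratio
#' density distributions, delta-value tables, between-replicate CV tables,
#' TIC-independence diagnostics, a datapoint-subsampling precision curve,
#' species contributions, and (when the design has `media_ppm` levels) the
#' deuterium-incorporation regression. The exact configuration and package
#' version are embedded. Regeneration with the same inputs and seed is
#' deterministic.
#'
#' @param design An [read_design()] tibble; its `file` column names
#'   record CSVs produced by [extract_to_csv()].
#' @param out_html Output path.
#' @param config A [run_config()].
#' @return `out_html`, invisibly.
#' @export
build_report <- function(design, out_html, config = run_config()) {
  missing <- !file.exists(design$file)
  if (any(missing)) {
    stop("design rows reference missing record CSVs: ",
         paste(design$file[missing], collapse = ", "))
  }
  recs <- dplyr::bind_rows(lapply(seq_len(nrow(design)), function(i) {
    r <- read_records_csv(design$file[i])
    for (cn in setdiff(names(design), "file")) r[[cn]] <- design[[cn]][i]
    r
  }))
  registry <- immonium_registry(intersect(config$species, unique(recs$species)),
                                mz_range = NULL)
  solvent <- if ("solvent_ppm" %in% names(recs)) recs$solvent_ppm[1] else config$solvent_ppm
  summ <- aggregate_replicates(recs, registry = registry,
                               solvent_ppm = solvent, mad_k = config$mad_k,
                               standards = config$standards)
  long <- .records_long(recs[recs$qc_pass, ], registry, solvent)

  sec <- character(0)
  add <- function(...) sec <<- c(sec, ...)

  add("<h2>Samples</h2>", .html_table(as.data.frame(design)))

  add("<h2>Ratio distributions</h2>")
  for (el in intersect(c("C", "H"), unique(long$element))) {
    dat <- long[long$element == el, ]
    p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$ratio,
                                           colour = .data$sample)) +
      ggplot2::geom_density() +
      ggplot2::facet_wrap(~species, scales = "free") +
      ggplot2::labs(title = paste0("Per-scan ", el, " ratio distributions"),
                    x = "isotope ratio", y = "density") +
      ggplot2::theme_minimal()
    add(.plot_b64(p))
  }

  add("<h2>Replicate summaries and &delta; values</h2>",
      .html_table(as.data.frame(summ)))

  n_reps <- tapply(design$replicate, design$sample,
                   function(r) length(unique(r)))
  if (all(n_reps < 2)) {
    add("<p class='notice'>n &lt; 2 replicates per sample: between-replicate CVs not computable.</p>")
  } else {
    cvs <- suppressWarnings(cv_between_replicates(summ))
    add("<h2>Between-replicate CVs</h2>", .html_table(as.data.frame(cvs)))
  }

  add("<h2>TIC-independence</h2>")
  tics <- dplyr::bind_rows(lapply(unique(recs$species), function(sp) {
    tt <- tryCatch(suppressWarnings(tic_trend(recs, sp, "C")),
                   error = function(e) NULL)
    if (is.null(tt)) return(NULL)
    tibble::tibble(species = sp, element = "C", slope = tt$slope,
                   correlation = tt$correlation, p_value = tt$p_value,
                   n = tt$n)
  }))
  if (nrow(tics) > 0) {
    add(.html_table(as.data.frame(tics)))
    p <- ggplot2::ggplot(recs[!is.na(recs$r_C), ],
                         ggplot2::aes(x = log10(.data$tic), y = .data$r_C,
                                      colour = .data$species)) +
      ggplot2::geom_point(alpha = 0.3, size = 0.6) +
      ggplot2::labs(title = "13C/12C ratio vs TIC", x = "log10 TIC",
                    y = "r_C") +
      ggplot2::theme_minimal()
    add(.plot_b64(p))
  } else {
    add("<p class='notice'>TIC trend not computable.</p>")
  }

  if (length(unique(recs$replicate)) >= 2) {
    n_min <- min(table(recs$replicate[recs$qc_pass], recs$species[recs$qc_pass]))
    ks <- unique(pmin(n_min, c(25, 50, 100, 200, 500)))
    ks <- ks[ks >= 10]
    if (length(ks) >= 2) {
      pcur <- subsample_precision(recs, ks = ks, n_draws = 10,
                                  seed = config$seed, registry = registry,
                                  solvent_ppm = solvent)
      add("<h2>Precision vs number of datapoints</h2>",
          .html_table(as.data.frame(pcur)))
      p <- ggplot2::ggplot(tidyr::pivot_longer(pcur, c("cv_mean_pct", "cv_median_pct"),
                                               names_to = "statistic",
                                               values_to = "cv"),
                           ggplot2::aes(x = .data$k, y = .data$cv,
                                        colour = .data$statistic)) +
        ggplot2::geom_line() + ggplot2::geom_point() +
        ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
        ggplot2::labs(title = "Average between-replicate CV vs datapoints",
                      x = "datapoints per replicate", y = "CV (%)") +
        ggplot2::theme_minimal()
      add(.plot_b64(p))
    }
  }

  add("<h2>Species contributions</h2>",
      .html_table(as.data.frame(species_contributions(recs))))

  if ("media_ppm" %in% names(recs) && length(unique(stats::na.omit(recs$media_ppm))) >= 3) {
    add("<h2>Deuterium incorporation</h2>")
    hsum <- summ[summ$element == "H", ]
    fits <- dplyr::bind_rows(lapply(unique(hsum$species), function(sp) {
      f <- incorporation_regression(hsum[hsum$species == sp, ])
      tibble::tibble(species = sp, slope = f$slope,
                     incorporation_pct = f$incorporation_pct,
                     r_squared = f$r_squared, slope_se = f$slope_se)
    }))
    add(.html_table(as.data.frame(fits)))
    p <- ggplot2::ggplot(hsum, ggplot2::aes(x = .data$media_ppm,
                                            y = .data$mean * 1e6,
                                            colour = .data$species)) +
      ggplot2::geom_point() +
      ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                           linewidth = 0.4) +
      ggplot2::labs(title = "C-bonded 2H/1H vs media 2H",
                    x = "media 2H (ppm)", y = "measured 2H/1H (ppm)") +
      ggplot2::theme_minimal()
    add(.plot_b64(p))
  }

  add("<h2>Configuration</h2>",
      "<pre>", as.character(config_json(config)), "</pre>")

  html <- paste0(
    "<!DOCTYPE html>\n<html><head><meta charset='utf-8'/>",
    "<title>isofine report</title><style>",
    "body{font-family:sans-serif;max-width:70em;margin:2em auto;padding:0 1em;}",
    "table{border-collapse:collapse;font-size:0.85em;margin:1em 0;}",
    "th,td{border:1px solid #bbb;padding:0.25em 0.6em;text-align:right;}",
    "th{background:#eee;} img{max-width:100%;} .notice{color:#a40;}",
    "</style></head><body><h1>isofine isotope-ratio report</h1>",
    sprintf("<p>isofine %s &mdash; %d record file(s), %d records.</p>",
            config$version, nrow(design), nrow(recs)),
    paste(sec, collapse = "\n"),
    "</body></html>")
  writeLines(html, out_html)
  invisible(out_html)
}
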