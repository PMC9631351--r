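# Corrected ratios, delta values, replicate statistics and diagnostics.

#' Exchangeable-hydrogen solvent correction
#'
#' The raw 2H/1H ratio of an immonium ion averages over all hydrogens, but
#' the ionizing proton and the hydrogens bonded to heteroatoms equilibrate
#' with the solvent (natural deuterium content about 140-150 ppm) and carry
#' no sample information. Removing that contribution gives the C-bonded
#' ratio:
#' r_cb = (h_total * r_raw - h_exch * r_solvent) / (h_total - h_exch).
#'
#' @param r_raw Measured all-hydrogen 2H/1H ratio(s).
#' @param h_total Total hydrogen count of the ion.
#' @param h_exch Exchangeable hydrogen count, `0 <= h_exch < h_total`.
#' @param r_solvent Solvent 2H/1H (dimensionless; 150 ppm = 150e-6).
#' @return C-bonded 2H/1H ratio(s); exceeds `r_raw` when `r_raw > r_solvent`.
#' @export
#' @examples
#' correct_exchangeable_h(200e-6, h_total = 8, h_exch = 1, r_solvent = 150e-6)
correct_exchangeable_h <- function(r_raw, h_total, h_exch, r_solvent = 150e-6) {
  if (h_exch < 0 || h_exch >= h_total) {
    stop("need 0 <= h_exch < h_total (got ", h_exch, " of ", h_total, ")")
  }
  if (any(r_solvent <= 0)) stop("r_solvent must be > 0")
  (h_total * r_raw - h_exch * r_solvent) / (h_total - h_exch)
}

#' Delta notation
#'
#' Per-mil deviation of a sample ratio from a reference standard:
#' delta = (r_sample / r_standard - 1) * 1000.
#'
#' @param r_sample,r_standard Isotope ratios; `r_standard > 0`.
#' @return Delta value(s) in per mil.
#' @export
#' @examples
#' delta_value(2 * 1.5576e-4, 1.5576e-4)  # +1000 per mil
delta_value <- function(r_sample, r_standard) {
  if (any(r_standard <= 0)) stop("r_standard must be > 0")
  (r_sample / r_standard - 1) * 1000
}

#' @rdname delta_value
#' @param delta Delta value(s) in per mil.
#' @export
delta_to_ratio <- function(delta, r_standard) {
  if (any(r_standard <= 0)) stop("r_standard must be > 0")
  (delta / 1000 + 1) * r_standard
}

# long form of ratio records: one row per (record, element), with the
# C-bonded hydrogen ratio computed per record. Elements: C, N, O, H
# (corrected C-bonded) and H_raw.
.records_long <- function(records, registry = immonium_registry(),
                          solvent_ppm = 150) {
  h_tab <- registry_table(registry)
  rec <- dplyr::left_join(records, h_tab[, c("name", "h_exch", "h_cb")],
                          by = c(species = "name"))
  if (anyNA(rec$h_exch)) {
    stop("records contain species absent from the registry: ",
         paste(unique(rec$species[is.na(rec$h_exch)]), collapse = ", "))
  }
  h_total <- rec$h_exch + rec$h_cb
  rec$r_H <- ifelse(
    rec$h_exch == 0, rec$r_H_raw,
    (h_total * rec$r_H_raw - rec$h_exch * solvent_ppm * 1e-6) /
      (h_total - rec$h_exch))
  keep <- setdiff(names(rec), c("r_C", "r_H_raw", "r_H", "r_N", "r_O",
                                "h_exch", "h_cb"))
  long <- tidyr::pivot_longer(
    rec[, c(keep, "r_C", "r_N", "r_O", "r_H", "r_H_raw")],
    cols = c("r_C", "r_N", "r_O", "r_H", "r_H_raw"),
    names_to = "element", values_to = "ratio", names_prefix = "r_")
  long[!is.na(long$ratio), ]
}

#' Aggregate ratio records into replicate summaries
#'
#' Converts per-scan records to one row per grouping x species x element
#' with n, mean, median, SD and SEM. The exchangeable-hydrogen correction is
#' applied per record (element `"H"` is the corrected C-bonded ratio;
#' `"H_raw"` is also kept). QC-failing records are dropped, and an outlier
#' trim discards records outside `median +/- mad_k * MAD` within each group
#' and element before the moments are computed (full-profile acquisition
#' retains noise spikes; the trim is configurable and `mad_k = Inf`
#' disables it).
#'
#' @param records Ratio-record tibble; may carry grouping columns such as
#'   `sample`, `replicate`, `media_ppm`.
#' @param by Character vector of grouping columns present in `records`
#'   (plus `species`, always used).
#' @param registry Species registry supplying hydrogen splits.
#' @param solvent_ppm Solvent 2H/1H in ppm for the correction.
#' @param mad_k Outlier trim width in MAD units.
#' @param standards [standard_ratios()] for delta values.
#' @param element_correction Optional named multiplicative factors (e.g.
#'   `c(C = 1.002, H = 0.99)`) applied to the per-record ratios of each
#'   element before aggregation — the interim-standard calibration: the
#'   factor that maps the measured ratio of a co-analysed standard to its
#'   known value.
#' @return Tibble with class `replicate_summary`: grouping columns,
#'   `species`, `element`, `n`, `mean`, `median`, `sd`, `sem`, `delta`
#'   (per mil, NA for `H_raw`).
#' @export
aggregate_replicates <- function(records, by = intersect(c("sample", "group", "replicate", "media_ppm"), names(records)),
                                 registry = immonium_registry(),
                                 solvent_ppm = 150, mad_k = 5,
                                 standards = standard_ratios(),
                                 element_correction = NULL) {
  if (nrow(records) == 0) stop("no records to aggregate")
  if ("qc_pass" %in% names(records)) records <- records[records$qc_pass, ]
  if (nrow(records) == 0) stop("no QC-passing records to aggregate")
  long <- .records_long(records, registry, solvent_ppm)
  if (!is.null(element_correction)) {
    m <- match(long$element, names(element_correction))
    long$ratio <- long$ratio * ifelse(is.na(m), 1, element_correction[m])
  }
  grp <- c(by, "species", "element")
  long <- dplyr::group_by(long, dplyr::across(dplyr::all_of(grp)))
  if (is.finite(mad_k)) {
    long <- dplyr::filter(
      long,
      abs(.data$ratio - stats::median(.data$ratio)) <=
        mad_k * stats::mad(.data$ratio) | stats::mad(.data$ratio) == 0)
  }
  out <- dplyr::summarise(
    long, n = dplyr::n(), mean = mean(.data$ratio),
    median = stats::median(.data$ratio), sd = stats::sd(.data$ratio),
    .groups = "drop")
  out$sd[is.na(out$sd)] <- 0
  out$sem <- out$sd / sqrt(out$n)
  std <- unlist(standards[c("C", "N", "O", "H")])
  m <- match(out$element, names(std))
  out$delta <- NA_real_
  out$delta[!is.na(m)] <- delta_value(out$mean[!is.na(m)], std[m[!is.na(m)]])
  class(out) <- c("replicate_summary", class(out))
  out
}

#' Between-replicate coefficients of variation
#'
#' CV = SD(replicate means) / mean(replicate means) * 100, per
#' (grouping, species, element); computed on replicate means and medians.
#'
#' @param summaries A [aggregate_replicates()] result containing a
#'   `replicate` column.
#' @param by Grouping columns beside species and element (replicate is
#'   consumed).
#' @return Tibble: grouping, `species`, `element`, `n_replicates`,
#'   `cv_mean_pct`, `cv_median_pct`. Groups with fewer than 2 replicates are
#'   dropped with a warning; an error is raised if nothing remains.
#' @export
cv_between_replicates <- function(summaries, by = intersect(c("sample", "group", "media_ppm"), names(summaries))) {
  grp <- c(by, "species", "element")
  out <- dplyr::summarise(
    dplyr::group_by(summaries, dplyr::across(dplyr::all_of(grp))),
    n_replicates = dplyr::n(),
    cv_mean_pct = stats::sd(.data$mean) / base::mean(.data$mean) * 100,
    cv_median_pct = stats::sd(.data$median) / base::mean(.data$median) * 100,
    .groups = "drop")
  if (any(out$n_replicates < 2)) {
    out <- out[out$n_replicates >= 2, ]
    warning("dropped groups with fewer than 2 replicates")
  }
  if (nrow(out) == 0) stop("no group has >= 2 replicates")
  out
}

#' TIC-independence diagnostic
#'
#' With automatic gain control the number of ions per spectrum — and hence
#' the measured ratio — should not depend on the ion current. This fits
#' ordinary least squares of the per-scan ratio on log10(TIC) and reports
#' the slope, the Pearson correlation and the two-sided p-value of the
#' slope.
#'
#' @param records Ratio records.
#' @param species,element Which per-scan ratio to test (element one of
#'   `"C"`, `"N"`, `"O"`, `"H_raw"`).
#' @return List: `slope`, `intercept`, `correlation`, `p_value`, `n`.
#' @export
tic_trend <- function(records, species, element = "C") {
  col <- switch(element, C = "r_C", N = "r_N", O = "r_O", H_raw = "r_H_raw",
                stop("element must be one of C, N, O, H_raw"))
  rec <- records[records$species == species & !is.na(records[[col]]), ]
  if (nrow(rec) < 3) stop("need at least 3 records with ", col)
  lt <- log10(rec$tic)
  if (stats::sd(lt) == 0) stop("degenerate TIC spread: all TIC values equal")
  if (diff(range(lt)) < 0.5 || nrow(rec) < 10) {
    warning("TIC trend is underpowered: fewer than 10 records or < 0.5 decades of TIC")
  }
  y <- rec[[col]]
  if (stats::sd(y) == 0) {
    return(list(slope = 0, intercept = y[1], correlation = 0, p_value = 1,
                n = nrow(rec)))
  }
  fit <- stats::lm(y ~ lt)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       correlation = unname(stats::cor(lt, y)),
       p_value = sm$coefficients[2, 4],
       n = nrow(rec))
}

#' Precision versus number of datapoints
#'
#' Emulates shortening the acquisition: for each k in `ks`, draw k records
#' (datapoints = per-scan, per-species ratios) without replacement from
#' every replicate, compute replicate means and medians per element and
#' species, the CV across replicates, and average over draws, species and
#' the elements C, N, H. Shot-noise-limited data follow CV proportional to
#' k^(-1/2).
#'
#' @param records Ratio records with a `replicate` column.
#' @param ks Increasing vector of datapoint counts.
#' @param n_draws Random draws per k.
#' @param seed Integer seed (the curve is reproducible given the seed).
#' @param elements Elements entering the average.
#' @param registry,solvent_ppm Passed to the aggregation.
#' @return Tibble with class `precision_curve`: `k`, `cv_mean_pct`,
#'   `cv_median_pct`, `n_draws`, `seed`.
#' @export
subsample_precision <- function(records, ks, n_draws = 20, seed = 1,
                                elements = c("C", "N", "H"),
                                registry = immonium_registry(),
                                solvent_ppm = 150) {
  if (is.unsorted(ks, strictly = TRUE)) stop("ks must be strictly increasing")
  if (!"replicate" %in% names(records)) stop("records need a replicate column")
  long <- .records_long(records[records$qc_pass, ], registry, solvent_ppm)
  long <- long[long$element %in% elements, ]
  groups <- split(long$ratio,
                  list(long$replicate, long$species, long$element), drop = TRUE)
  sizes <- vapply(groups, length, integer(1))
  # group sizes differ only by element availability; k applies to datapoints
  # per (replicate, species)
  n_avail <- min(sizes)
  if (max(ks) > n_avail) {
    small <- names(sizes)[which.min(sizes)]
    stop("k = ", max(ks), " exceeds the ", n_avail,
         " records available in group ", small)
  }
  set.seed(seed)
  rows <- lapply(ks, function(k) {
    cvs_mean <- numeric(n_draws); cvs_median <- numeric(n_draws)
    key <- sub("^[^.]*\\.", "", names(groups))  # species.element
    cv <- function(v) {
      per <- tapply(v, key, function(x) stats::sd(x) / mean(x) * 100)
      mean(per)
    }
    for (d in seq_len(n_draws)) {
      draws <- lapply(groups, function(g) g[sample.int(length(g), k)])
      cvs_mean[d] <- cv(vapply(draws, mean, numeric(1)))
      cvs_median[d] <- cv(vapply(draws, stats::median, numeric(1)))
    }
    tibble::tibble(k = k, cv_mean_pct = mean(cvs_mean),
                   cv_median_pct = mean(cvs_median))
  })
  out <- dplyr::bind_rows(rows)
  out$n_draws <- n_draws; out$seed <- seed
  class(out) <- c("precision_curve", class(out))
  out
}

#' Deuterium-incorporation regression
#'
#' Regresses the measured C-bonded 2H/1H ratio (ppm) on the growth-media 2H
#' level (ppm). The incorporation degree is 100 times the slope.
#'
#' @param summaries Tibble with columns `media_ppm` and `mean` (element "H"
#'   rows of a [aggregate_replicates()] result), or any tibble with
#'   `media_ppm` and a ratio column named by `value`.
#' @param value Name of the response column (dimensionless ratio or ppm; the
#'   slope is scale-free in the response units per media ppm when the
#'   response is in ppm).
#' @return List: `slope`, `intercept_ppm`, `r_squared`, `incorporation_pct`,
#'   `slope_se`, `n_levels`.
#' @export
incorporation_regression <- function(summaries, value = "mean") {
  if (!all(c("media_ppm", value) %in% names(summaries))) {
    stop("need columns media_ppm and ", value)
  }
  x <- summaries$media_ppm
  y <- summaries[[value]]
  if (max(y, na.rm = TRUE) < 0.01) y <- y * 1e6  # dimensionless -> ppm
  if (length(unique(x)) < 3) stop("need at least 3 distinct media levels")
  fit <- stats::lm(y ~ x)
  # summary.lm warns on exactly collinear (noise-free) input; harmless here
  sm <- suppressWarnings(summary(fit))
  list(slope = unname(stats::coef(fit)[2]),
       intercept_ppm = unname(stats::coef(fit)[1]),
       r_squared = sm$r.squared,
       incorporation_pct = 100 * unname(stats::coef(fit)[2]),
       slope_se = sm$coefficients[2, 2],
       n_levels = length(unique(x)))
}

#' Relative amino-acid contributions
#'
#' The share of the summed monoisotopic signal contributed by each species —
#' a composition fingerprint usable for verifying sample identity against a
#' known amino-acid composition.
#'
#' @param records Ratio records.
#' @param reference Optional named numeric vector of reference contributions
#'   (%); the squared Pearson correlation with the measured contributions is
#'   reported for the shared species.
#' @return Tibble `species`, `contribution_pct`; attribute `r_squared` when
#'   a reference was given.
#' @export
species_contributions <- function(records, reference = NULL) {
  if (nrow(records) == 0) stop("no records")
  tot <- tapply(records$area_M, records$species, sum)
  out <- tibble::tibble(species = names(tot),
                        contribution_pct = 100 * as.numeric(tot) / sum(tot))
  r2 <- NULL
  if (!is.null(reference)) {
    shared <- intersect(out$species, names(reference))
    if (length(shared) < 3) stop("need >= 3 shared species for the R^2 check")
    r2 <- stats::cor(out$contribution_pct[match(shared, out$species)],
                     reference[shared])^2
  }
  structure(out, r_squared = r2)
}
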