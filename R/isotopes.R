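# Isotope reference data and abundance sets.
#
# Masses in Da (unified atomic mass units); abundances as mole fractions.
# Values follow the IUPAC/CIAAW compilation. The table is stored as data
# (inst/extdata/isotopes.tsv mirrors it as editable text), not hard-coded in
# the combinatorics.

#' Physical constants used for ion mass arithmetic
#'
#' @return Named list with `electron` (electron mass, Da), `proton`
#'   (proton mass, Da) and `h_atom` (hydrogen-atom mass, Da).
#' @export
#' @examples
#' physical_constants()$electron
physical_constants <- function() {
  list(
    electron = 5.48579909065e-4,
    proton   = 1.007276466621,
    h_atom   = 1.00782503207
  )
}

.isotope_data <- function() {
  tibble::tribble(
    ~element, ~isotope, ~mass,          ~abundance,
    "H",      "1H",     1.00782503207,  0.999885,
    "H",      "2H",     2.01410177785,  0.000115,
    "C",      "12C",    12.0,           0.9893,
    "C",      "13C",    13.00335483507, 0.0107,
    "N",      "14N",    14.00307400443, 0.99636,
    "N",      "15N",    15.00010889888, 0.00364,
    "O",      "16O",    15.99491461957, 0.99757,
    "O",      "17O",    16.99913175650, 0.00038,
    "O",      "18O",    17.99915961286, 0.00205,
    "S",      "32S",    31.9720711744,  0.9499,
    "S",      "33S",    32.9714589098,  0.0075,
    "S",      "34S",    33.967867004,   0.0425,
    "S",      "36S",    35.96708071,    0.0001
  )
}

# Heavy isotope used by the two-isotope ratio model, per element. 17O (0.038%)
# and the minor S isotopes are carried in the table for completeness but are
# not part of the fine-structure estimator (see the methods vignette).
.heavy_isotope <- c(C = "13C", H = "2H", N = "15N", O = "18O")
.ratio_elements <- c("C", "H", "N", "O")

#' Isotope reference table
#'
#' Per element, the stable isotopes with their exact masses and natural
#' abundances, ordered by mass. Abundances within an element sum to 1.
#'
#' @param path Optional path to a TSV file with columns
#'   `element`, `isotope`, `mass`, `abundance` overriding the built-in table.
#' @return A tibble with class `isotope_table`.
#' @export
#' @examples
#' isotope_table()
isotope_table <- function(path = NULL) {
  tab <- if (is.null(path)) {
    .isotope_data()
  } else {
    readr::read_tsv(path, show_col_types = FALSE)
  }
  validate_isotope_table(tab)
}

#' @rdname isotope_table
#' @param tab A candidate isotope table.
#' @export
validate_isotope_table <- function(tab) {
  need <- c("element", "isotope", "mass", "abundance")
  if (!all(need %in% names(tab))) {
    stop("isotope table must have columns: ", paste(need, collapse = ", "))
  }
  split_tab <- split(tab, tab$element)
  for (el in names(split_tab)) {
    x <- split_tab[[el]]
    if (any(diff(x$mass) <= 0)) {
      stop("isotope masses not strictly increasing for element ", el)
    }
    if (abs(sum(x$abundance) - 1) > 1e-9) {
      stop("isotope abundances for element ", el, " do not sum to 1")
    }
  }
  structure(tibble::as_tibble(tab), class = c("isotope_table", class(tibble::tibble())))
}

# lightest-isotope mass per element, as a named vector
.light_masses <- function(isotopes = isotope_table()) {
  light <- isotopes[!duplicated(isotopes$element), ]
  stats::setNames(light$mass, light$element)
}

# mass difference heavy - light for the ratio-model isotope of each element
.heavy_mass_shifts <- function(isotopes = isotope_table()) {
  light <- .light_masses(isotopes)
  out <- vapply(.ratio_elements, function(el) {
    row <- isotopes[isotopes$element == el & isotopes$isotope == .heavy_isotope[[el]], ]
    row$mass - light[[el]]
  }, numeric(1))
  stats::setNames(out, .ratio_elements)
}

# nominal mass shift (shell) of the heavy isotope per element
.heavy_nominal_shift <- c(C = 1L, H = 1L, N = 1L, O = 2L)

#' Heavy/light isotope ratio set
#'
#' An abundance set holds the heavy-to-light isotope ratio r_X for each
#' element the method measures: r_C = [13C]/[12C], r_H = [2H]/[1H],
#' r_N = [15N]/[14N], r_O = [18O]/[16O]. All ratios are dimensionless;
#' 2H/1H is conventionally quoted in ppm (multiply by 1e6).
#'
#' @param r_C,r_H,r_N,r_O Heavy/light ratios, each in (0, 1).
#' @return Named list with class `abundance_set`.
#' @export
#' @examples
#' abundance_set(r_C = 0.011, r_H = 150e-6, r_N = 0.0037, r_O = 0.002)
abundance_set <- function(r_C, r_H, r_N, r_O) {
  r <- list(C = r_C, H = r_H, N = r_N, O = r_O)
  for (el in names(r)) {
    v <- r[[el]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0 || v >= 1) {
      stop("abundance ratio for ", el, " must be a single number in (0, 1)")
    }
  }
  structure(r, class = "abundance_set")
}

#' @export
print.abundance_set <- function(x, ...) {
  cat("<abundance_set>\n")
  cat(sprintf("  13C/12C: %.6g\n  2H/1H:   %.6g (%.1f ppm)\n  15N/14N: %.6g\n  18O/16O: %.6g\n",
              x$C, x$H, x$H * 1e6, x$N, x$O))
  invisible(x)
}

#' Natural-abundance ratio sets
#'
#' `"iupac"` derives r_X from the isotope reference table
#' (e.g. r_C = 0.0107/0.9893). `"nominal"` is the rounded set commonly quoted
#' for back-of-envelope work and used as the simulator's default natural
#' baseline: 13C 1.1%, 15N 0.37%, 2H 150 ppm, 18O 0.2%.
#'
#' @param source `"nominal"` (default) or `"iupac"`.
#' @param isotopes Isotope table used for the `"iupac"` source.
#' @return An [abundance_set()].
#' @export
#' @examples
#' natural_abundances()
#' natural_abundances("iupac")
natural_abundances <- function(source = c("nominal", "iupac"),
                               isotopes = isotope_table()) {
  source <- match.arg(source)
  if (source == "nominal") {
    return(abundance_set(r_C = 0.011, r_H = 150e-6, r_N = 0.0037, r_O = 0.002))
  }
  r <- vapply(.ratio_elements, function(el) {
    x <- isotopes[isotopes$element == el, ]
    heavy <- x$abundance[x$isotope == .heavy_isotope[[el]]]
    heavy / x$abundance[[1]]
  }, numeric(1))
  abundance_set(r_C = r[["C"]], r_H = r[["H"]], r_N = r[["N"]], r_O = r[["O"]])
}

#' International reference standards for delta notation
#'
#' Literature consensus ratios of the standards used for per-mil delta
#' values: VSMOW for 2H/1H and 18O/16O, VPDB for 13C/12C, atmospheric N2
#' (AIR) for 15N/14N. Any entry can be overridden.
#'
#' @param H,C,N,O Optional replacement ratios.
#' @return Named list with class `standard_set`.
#' @export
#' @examples
#' standard_ratios()
standard_ratios <- function(H = 1.5576e-4, C = 1.11802e-2,
                            N = 3.6765e-3, O = 2.0052e-3) {
  r <- list(H = H, C = C, N = N, O = O)
  if (any(vapply(r, function(v) !is.numeric(v) || v <= 0, logical(1)))) {
    stop("standard ratios must all be positive numbers")
  }
  structure(r, class = "standard_set",
            names_long = c(H = "VSMOW", C = "VPDB", N = "AIR", O = "VSMOW"))
}
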