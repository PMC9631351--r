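# Elemental compositions and exact ion mass arithmetic.

#' Elemental composition of an ion or neutral species
#'
#' @param formula A Hill-style formula string such as `"C5H9NO2"`, or omitted
#'   when counts are given directly.
#' @param ... Named atom counts, e.g. `composition(C = 4, H = 8, N = 1)`.
#' @return Named integer vector with class `elemental_composition`.
#' @export
#' @examples
#' composition("C5H9NO2")
#' composition(C = 4, H = 8, N = 1)
composition <- function(formula = NULL, ...) {
  counts <- if (!is.null(formula)) parse_formula(formula) else unlist(list(...))
  if (length(counts) == 0) {
    return(structure(integer(0), class = "elemental_composition"))
  }
  if (is.null(names(counts)) || any(names(counts) == "")) {
    stop("atom counts must be named by element symbol")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("atom counts must be non-negative integers")
  }
  structure(stats::setNames(as.integer(counts), names(counts)),
            class = "elemental_composition")
}

#' @rdname composition
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1)
  if (!grepl("^([A-Z][a-z]?[0-9]*)*$", formula)) {
    stop("cannot parse formula: ", formula)
  }
  m <- gregexpr("[A-Z][a-z]?[0-9]*", formula)[[1]]
  parts <- regmatches(formula, list(m))[[1]]
  els <- sub("[0-9]*$", "", parts)
  ns <- as.integer(ifelse(grepl("[0-9]+$", parts),
                          sub("^[A-Za-z]+", "", parts), "1"))
  counts <- tapply(ns, els, sum)
  stats::setNames(as.integer(counts), names(counts))
}

#' @export
format.elemental_composition <- function(x, ...) {
  if (length(x) == 0) return("(empty)")
  ord <- c(intersect(c("C", "H"), names(x)), sort(setdiff(names(x), c("C", "H"))))
  paste0(ord, ifelse(x[ord] > 1, x[ord], ""), collapse = "")
}

#' @export
print.elemental_composition <- function(x, ...) {
  cat("<elemental_composition> ", format(x), "\n", sep = "")
  invisible(x)
}

#' Monoisotopic mass of a composition
#'
#' Sum over elements of atom count times the lightest-isotope mass.
#'
#' @param comp An [composition()] (or formula string).
#' @param isotopes Isotope reference table.
#' @return Mass in Da.
#' @export
#' @examples
#' monoisotopic_mass("C5H9NO2") # proline, 115.06333
monoisotopic_mass <- function(comp, isotopes = isotope_table()) {
  if (is.character(comp)) comp <- composition(comp)
  if (length(comp) == 0) return(0)
  light <- .light_masses(isotopes)
  unknown <- setdiff(names(comp), names(light))
  if (length(unknown) > 0) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  }
  sum(comp * light[names(comp)])
}

#' Theoretical m/z of an ion
#'
#' Two mass conventions are supported. Under `"h_atom"` the compiled
#' composition is treated with hydrogen-atom arithmetic: a protonated species
#' adds whole hydrogen *atoms* (`extra_h`) and no electron correction is
#' applied. This is the convention that reproduces the immonium and MH+
#' values commonly printed in the proteomics literature (e.g. Pro immonium
#' C4H8N at m/z 70.0656). Under `"cation_physical"` one electron mass per
#' charge is subtracted, giving the physically exact cation m/z
#' (70.0651 for the same ion).
#'
#' @param comp Composition of the ion *including* all hydrogens of the
#'   radical/neutral formula (immonium ions are conventionally written this
#'   way, e.g. C4H8N for Pro).
#' @param convention `"h_atom"` (default) or `"cation_physical"`.
#' @param charge Positive integer charge.
#' @param extra_h Number of hydrogen atoms to add (use 1 for MH+ of a
#'   neutral-molecule composition).
#' @param isotopes Isotope reference table.
#' @return m/z in Th.
#' @export
#' @examples
#' theoretical_mz("C5H9NO2", extra_h = 1)  # MH+ of Pro: 116.0712
#' theoretical_mz("C4H8N")                 # Pro immonium: 70.0657
#' theoretical_mz("C4H8N", convention = "cation_physical")
theoretical_mz <- function(comp, convention = c("h_atom", "cation_physical"),
                           charge = 1L, extra_h = 0L,
                           isotopes = isotope_table()) {
  convention <- match.arg(convention)
  if (charge < 1) stop("charge must be >= 1")
  k <- physical_constants()
  m <- monoisotopic_mass(comp, isotopes) + extra_h * k$h_atom
  mz <- m / charge
  if (convention == "cation_physical") mz <- mz - k$electron
  mz
}
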