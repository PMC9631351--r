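# Immonium-ion species registry.
#
# Immonium ions (H2N+=CHR, the protonated residue minus the carbonyl) are
# written here with the neutral-radical formula that already includes the
# ionizing proton, the convention under which the familiar printed m/z
# values (Pro 70.0656, Hyp 86.0606, Val 72.0813, ...) arise.

#' Construct an immonium-ion species
#'
#' @param name Short species key, e.g. `"Pro"` or `"Leu/Ile"`.
#' @param formula Radical formula of the cation, e.g. `"C4H8N"`.
#' @param h_exch Number of exchangeable hydrogens (N-H, O-H plus the
#'   ionizing proton), equilibrated with the solvent.
#' @param residues Residue label(s) the ion reports on (defaults to `name`).
#' @param note Free-text note.
#' @param isotopes Isotope reference table.
#' @return List with class `immonium_species`: composition, hydrogen split
#'   (`h_exch` + `h_cb` = total H), and theoretical m/z under both mass
#'   conventions.
#' @export
#' @examples
#' immonium_species("Pro", "C4H8N", h_exch = 1)
immonium_species <- function(name, formula, h_exch, residues = name,
                             note = "", isotopes = isotope_table()) {
  comp <- composition(formula)
  h_total <- if ("H" %in% names(comp)) comp[["H"]] else 0L
  if (h_exch < 0 || h_exch > h_total) {
    stop("h_exch must be between 0 and the total hydrogen count (", h_total, ")")
  }
  structure(list(
    name = name,
    residues = residues,
    composition = comp,
    h_total = h_total,
    h_exch = as.integer(h_exch),
    h_cb = h_total - as.integer(h_exch),
    mz = theoretical_mz(comp, "h_atom", isotopes = isotopes),
    mz_cation = theoretical_mz(comp, "cation_physical", isotopes = isotopes),
    note = note
  ), class = "immonium_species")
}

#' @export
print.immonium_species <- function(x, ...) {
  cat(sprintf("<immonium_species> %s (%s)  m/z %.4f (H-atom) / %.4f (cation)  H: %d exch + %d C-bonded\n",
              x$name, format(x$composition), x$mz, x$mz_cation, x$h_exch, x$h_cb))
  invisible(x)
}

.registry_data <- function() {
  tibble::tribble(
    ~name,      ~residues,  ~formula, ~h_exch, ~note,
    "Pro",      "Pro",      "C4H8N",  1L,      "",
    "Hyp",      "Hyp",      "C4H8NO", 2L,      "N-H and O-H exchangeable",
    "Val",      "Val",      "C4H10N", 2L,      "",
    "Leu/Ile",  "Leu/Ile",  "C5H12N", 2L,      "Leu and Ile are isomeric; one species",
    "Phe",      "Phe",      "C8H10N", 2L,      "",
    "Gly",      "Gly",      "CH4N",   2L,      "m/z 30, below the usual m/z 50 low cutoff",
    "Ala",      "Ala",      "C2H6N",  2L,      "m/z 44, below the usual m/z 50 low cutoff"
  )
}

#' Registry of immonium-ion species
#'
#' The default registry covers the residues with abundant, well-separated
#' immonium ions in the m/z 50-200 detection window (Pro, Hyp, Val, Leu/Ile,
#' Phe). Gly and Ala are included but fall below the m/z 50 cutoff of most
#' Orbitrap instruments and are excluded by the default `mz_range`.
#' Exchangeable-hydrogen counts derive from the H2N+=CHR structure (ring N-H
#' for Pro; N-H + O-H for Hyp) and are editable via the TSV interface.
#'
#' @param species Optional character vector restricting the registry.
#' @param mz_range Detected m/z window; species outside it are dropped with a
#'   message. Use `NULL` to keep everything.
#' @param path Optional TSV (columns `name`, `residues`, `formula`, `h_exch`,
#'   `note`) replacing the built-in table; a template ships in
#'   `system.file("extdata", "immonium_species.tsv", package = "isofine")`.
#' @return Named list of [immonium_species()] objects.
#' @export
#' @examples
#' names(immonium_registry())
#' immonium_registry("Pro")[["Pro"]]
immonium_registry <- function(species = NULL, mz_range = c(50, 200), path = NULL) {
  tab <- if (is.null(path)) {
    .registry_data()
  } else {
    readr::read_tsv(path, show_col_types = FALSE)
  }
  need <- c("name", "formula", "h_exch")
  if (!all(need %in% names(tab))) {
    stop("species registry must have columns: ", paste(need, collapse = ", "))
  }
  if (!"residues" %in% names(tab)) tab$residues <- tab$name
  if (!"note" %in% names(tab)) tab$note <- ""
  tab$note[is.na(tab$note)] <- ""
  if (!is.null(species)) {
    missing <- setdiff(species, tab$name)
    if (length(missing) > 0) {
      stop("unknown species: ", paste(missing, collapse = ", "))
    }
    tab <- tab[tab$name %in% species, ]
  }
  out <- lapply(seq_len(nrow(tab)), function(i) {
    immonium_species(tab$name[i], tab$formula[i], tab$h_exch[i],
                     residues = tab$residues[i], note = tab$note[i])
  })
  names(out) <- tab$name
  if (!is.null(mz_range)) {
    mzs <- vapply(out, `[[`, numeric(1), "mz")
    below <- mzs < mz_range[1] | mzs > mz_range[2]
    if (any(below)) {
      message("dropping species outside m/z range ", mz_range[1], "-",
              mz_range[2], ": ", paste(names(out)[below], collapse = ", "))
      out <- out[!below]
    }
  }
  out
}

#' Registry overview table
#'
#' @param registry A list of [immonium_species()].
#' @return A tibble, one row per species.
#' @export
registry_table <- function(registry = immonium_registry()) {
  tibble::tibble(
    name = vapply(registry, `[[`, character(1), "name"),
    residues = vapply(registry, `[[`, character(1), "residues"),
    formula = vapply(registry, function(s) format(s$composition), character(1)),
    mz = vapply(registry, `[[`, numeric(1), "mz"),
    mz_cation = vapply(registry, `[[`, numeric(1), "mz_cation"),
    h_exch = vapply(registry, `[[`, integer(1), "h_exch"),
    h_cb = vapply(registry, `[[`, integer(1), "h_cb")
  )
}

#' Write a species registry to its editable TSV form
#'
#' @param registry A list of [immonium_species()].
#' @param path Output TSV path.
#' @export
write_species_registry <- function(registry, path) {
  tab <- tibble::tibble(
    name = vapply(registry, `[[`, character(1), "name"),
    residues = vapply(registry, `[[`, character(1), "residues"),
    formula = vapply(registry, function(s) format(s$composition), character(1)),
    h_exch = vapply(registry, `[[`, integer(1), "h_exch"),
    note = vapply(registry, `[[`, character(1), "note")
  )
  readr::write_tsv(tab, path)
  invisible(path)
}

# atom count of one element in a species (0 when absent)
.n_atoms <- function(species, element) {
  if (element %in% names(species$composition)) species$composition[[element]] else 0L
}
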