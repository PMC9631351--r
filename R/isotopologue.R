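# Isotopologue fine-structure combinatorics.
#
# Model: independent substitution sites, one heavy isotope per element
# (13C, 2H, 15N, 18O). A substitution multiset with k_X heavy atoms of
# element X (n_X sites, site probability a_X = r_X/(1+r_X)) has probability
#   prod_X C(n_X, k_X) a_X^k_X (1-a_X)^(n_X-k_X),
# and its abundance ratio to the all-light (monoisotopic) line is exactly
#   prod_X C(n_X, k_X) r_X^k_X,
# hence the single-substitution identity A(M+1, X)/A(M) = n_X * r_X that the
# whole ratio estimator rests on.

# site classes: one row per independent site group. Splitting hydrogen into
# C-bonded and exchangeable classes (different r, same isotope label) is how
# the simulator models solvent-equilibrated hydrogens.
.site_classes <- function(comp, abundances, isotopes = isotope_table(),
                          h_split = NULL) {
  if (is.character(comp)) comp <- composition(comp)
  shifts <- .heavy_mass_shifts(isotopes)
  els <- intersect(names(comp), .ratio_elements)
  unknown <- setdiff(names(comp), names(.light_masses(isotopes)))
  if (length(unknown) > 0) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  }
  cls <- tibble::tibble(
    iso = unname(.heavy_isotope[els]),
    element = els,
    n = as.integer(comp[els]),
    r = vapply(els, function(e) abundances[[e]], numeric(1)),
    dm = unname(shifts[els]),
    shell = unname(.heavy_nominal_shift[els])
  )
  cls <- cls[cls$n > 0, ]
  if (!is.null(h_split) && "H" %in% cls$element) {
    h <- cls[cls$element == "H", ]
    cls <- cls[cls$element != "H", ]
    stopifnot(h_split$h_cb + h_split$h_exch == h$n)
    extra <- tibble::tibble(
      iso = "2H", element = c("H", "H"),
      n = c(h_split$h_cb, h_split$h_exch),
      r = c(h_split$r_cb, h_split$r_exch),
      dm = h$dm, shell = 1L
    )
    cls <- rbind(cls, extra[extra$n > 0, ])
  }
  cls
}

# enumerate substitution multisets with total nominal shift <= max_shell
.enumerate_lines <- function(classes, max_shell) {
  if (max_shell < 0) stop("max_shell must be >= 0")
  nc <- nrow(classes)
  if (nc == 0) {
    return(tibble::tibble(shell = 0L, label = "M", dm = 0, ratio = 1,
                          prob = 1, subs = ""))
  }
  kmax <- pmin(classes$n, max_shell %/% classes$shell)
  grid <- do.call(expand.grid, lapply(kmax, function(k) 0:k))
  shell_tot <- as.integer(as.matrix(grid) %*% classes$shell)
  grid <- grid[shell_tot <= max_shell, , drop = FALSE]
  shell_tot <- shell_tot[shell_tot <= max_shell]

  km <- as.matrix(grid)
  ratio <- apply(km, 1, function(k) prod(choose(classes$n, k) * classes$r^k))
  p_light <- prod((1 / (1 + classes$r))^classes$n)
  dm <- as.numeric(km %*% classes$dm)

  sig <- apply(km, 1, function(k) {
    on <- k > 0
    if (!any(on)) return("")
    # merge classes sharing an isotope label (e.g. the two hydrogen pools)
    counts <- tapply(k[on], classes$iso[on], sum)
    counts <- counts[order(classes$dm[match(names(counts), classes$iso)])]
    paste0(names(counts), ifelse(counts > 1, counts, ""), collapse = ".")
  })
  out <- tibble::tibble(shell = shell_tot, dm = dm, ratio = ratio,
                        prob = ratio * p_light, subs = sig)
  out <- stats::aggregate(cbind(ratio, prob) ~ shell + dm + subs, data = out, FUN = sum)
  out$label <- ifelse(out$shell == 0, "M", paste0("M", out$shell, "_", out$subs))
  out <- out[order(out$shell, out$dm), ]
  tibble::as_tibble(out[, c("shell", "label", "dm", "ratio", "prob", "subs")])
}

#' Isotopologue distribution of a composition
#'
#' Enumerates all heavy-isotope substitution multisets up to a nominal mass
#' shift of `max_shell`, with exact abundance ratios relative to the
#' monoisotopic line.
#'
#' @param comp [composition()] or formula string.
#' @param abundances [abundance_set()] of heavy/light ratios.
#' @param max_shell Highest nominal shell (default 2: M, M+1, M+2).
#' @param h_split Optional list `(h_cb, h_exch, r_cb, r_exch)` splitting the
#'   hydrogen sites into two pools with different 2H levels (simulator use).
#' @return Tibble of fine lines: `shell`, `label`, `dm` (Da from M), `ratio`
#'   (to M), `prob` (absolute isotopologue probability), `subs`.
#' @export
#' @examples
#' isotopologue_distribution("C4H8N", natural_abundances())
isotopologue_distribution <- function(comp, abundances = natural_abundances(),
                                      max_shell = 2L, h_split = NULL) {
  classes <- .site_classes(comp, abundances, h_split = h_split)
  .enumerate_lines(classes, max_shell)
}

#' Fine-structure line positions for an immonium species
#'
#' Places the isotopologue lines of shells M+1 (and M+2 when requested) at
#' absolute m/z using exact isotope mass differences (13C-12C 1.0033548,
#' 15N-14N 0.9970349, 2H-1H 1.0062768, 18O-16O 2.0042464 Da). Within M+1 the
#' m/z order is always 15N < 13C < 2H.
#'
#' @param species An [immonium_species()].
#' @param abundances [abundance_set()] used for expected ratios.
#' @param shell 1 or 2: include shells up to this nominal shift.
#' @param h_split Optional hydrogen-pool split (see
#'   [isotopologue_distribution()]).
#' @return Tibble of lines with columns of [isotopologue_distribution()] plus
#'   `mz`. When shell 2 is requested for an oxygen-free species the 13C2 /
#'   13C.15N / 2H-combination lines are still returned and the result carries
#'   `attr(, "o_line_missing") = TRUE`.
#' @export
#' @examples
#' sp <- immonium_registry("Pro")[["Pro"]]
#' fine_structure_lines(sp, shell = 1)
fine_structure_lines <- function(species, abundances = natural_abundances(),
                                 shell = 2L, h_split = NULL) {
  if (!shell %in% 1:2) stop("shell must be 1 or 2")
  lines <- isotopologue_distribution(species$composition, abundances,
                                     max_shell = shell, h_split = h_split)
  lines$mz <- species$mz + lines$dm
  o_missing <- shell == 2 && .n_atoms(species, "O") == 0
  if (o_missing) {
    message("species ", species$name, " contains no oxygen: no 18O line in M+2")
  }
  structure(lines, o_line_missing = o_missing)
}
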