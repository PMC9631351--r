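# Independent brute-force oracle for isotopologue distributions: enumerate
# every per-atom isotope assignment (2^n for n atoms), accumulate exact
# probabilities per substitution multiset. Feasible for molecules with up to
# ~13 atoms; deliberately naive and independent of the package's closed-form
# combinatorics.
bf_isotopologues <- function(formula, ab) {
  comp <- isofine::composition(formula)
  els <- rep(names(comp), comp)
  n <- length(els)
  stopifnot(n <= 14)
  a <- vapply(els, function(e) ab[[e]] / (1 + ab[[e]]), numeric(1))
  acc <- new.env(parent = emptyenv())
  for (mask in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(mask))[seq_len(n)]
    p <- prod(ifelse(bits == 1L, a, 1 - a))
    k <- tapply(bits, els, sum)
    key <- paste(names(k), k, sep = ":", collapse = ",")
    acc[[key]] <- (if (is.null(acc[[key]])) 0 else acc[[key]]) + p
  }
  keys <- ls(acc)
  counts <- do.call(rbind, lapply(strsplit(keys, ","), function(parts) {
    kv <- do.call(rbind, strsplit(parts, ":"))
    stats::setNames(as.integer(kv[, 2]), kv[, 1])
  }))
  data.frame(counts, prob = vapply(keys, function(k) acc[[k]], numeric(1)),
             row.names = NULL)
}

# substitution counts per element from the package's line signature
# (e.g. "15N.13C2" -> C 2, N 1)
parse_subs <- function(subs) {
  iso2el <- c("13C" = "C", "2H" = "H", "15N" = "N", "18O" = "O")
  out <- c(C = 0L, H = 0L, N = 0L, O = 0L)
  if (subs == "") return(out)
  for (part in strsplit(subs, ".", fixed = TRUE)[[1]]) {
    iso <- sub("([0-9]*)$", "", part)
    k <- sub("^.*[A-Za-z]", "", part)
    out[iso2el[[iso]]] <- out[iso2el[[iso]]] + if (k == "") 1L else as.integer(k)
  }
  out
}

# noiseless, perfectly calibrated simulated instrument used as the oracle
# configuration in recovery tests
noiseless_instrument <- function(agc = 1e7, microscans = 1, resolution = 60000) {
  isofine::sim_instrument(resolution = resolution, agc_target = agc,
                          microscans = microscans, cal_offset_ppm = 0,
                          jitter_ppm = 0, baseline_sd = 0)
}

# per-scan ratio records drawn from a Gaussian - the sampling-theory oracle
# for aggregation and subsampling operations
gaussian_records <- function(n_per_rep, replicates = 3, mu = 0.011,
                             sigma = 1e-4, species = "Pro", seed = 1) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(replicates), function(r) {
    tibble::tibble(
      scan = seq_len(n_per_rep), rt = seq_len(n_per_rep), tic = 1e6,
      species = species, area_M = 1000,
      r_C = stats::rnorm(n_per_rep, mu, sigma),
      r_H_raw = stats::rnorm(n_per_rep, 150e-6, 5e-6),
      r_N = stats::rnorm(n_per_rep, 0.0037, 5e-5),
      r_O = NA_real_, mass_error_ppm = 0, qc_pass = TRUE, flags = "",
      replicate = r, sample = "S1", group = "G"
    )
  }))
}
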