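# Most-abundant-isotope masses, Da (CODATA/AME2020, 6 decimals).
# Element set of the bundled compound library.
ATOMIC_MASSES <- c(C = 12.000000, H = 1.007825, N = 14.003074,
                   O = 15.994915, S = 31.972071, Br = 78.918338)

H_ATOM_MASS <- 1.00783  # hydrogen-atom convention for [M-H]- (see docs)

#' Parse an elemental formula
#'
#' Accepts Hill-style composition strings over the elements C, H, N, O,
#' S and Br (e.g. `"C9H8O7S"`); counts default to 1 when omitted.
#'
#' @param formula Formula string, or an already-named count vector
#'   (returned unchanged after validation).
#' @return Named integer vector of element counts.
#' @examples
#' parse_formula("C5H9NO2")
#' @export
parse_formula <- function(formula) {
  if (is.numeric(formula)) {
    if (is.null(names(formula)) ||
        !all(names(formula) %in% names(ATOMIC_MASSES)))
      stop("numeric formula must be named by known element symbols")
    return(formula)
  }
  stopifnot(is.character(formula), length(formula) == 1L)
  if (formula == "") return(stats::setNames(numeric(0), character(0)))
  tokens <- gregexpr("[A-Z][a-z]?[0-9]*", formula)[[1]]
  parts <- regmatches(formula, gregexpr("[A-Z][a-z]?[0-9]*", formula))[[1]]
  if (sum(nchar(parts)) != nchar(formula))
    stop("cannot parse formula: '", formula, "'")
  el <- sub("[0-9]*$", "", parts)
  n <- as.numeric(ifelse(grepl("[0-9]+$", parts),
                         sub("^[A-Za-z]+", "", parts), "1"))
  unknown <- setdiff(el, names(ATOMIC_MASSES))
  if (length(unknown))
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  counts <- tapply(n, el, sum)
  stats::setNames(as.numeric(counts), names(counts))
}

#' Monoisotopic mass of a neutral formula
#'
#' Sum of most-abundant-isotope masses over the elemental composition.
#'
#' @param formula Formula string or named count vector
#'   (see [parse_formula()]).
#' @return Mass in Da.
#' @examples
#' monoisotopic_mass("H2O")  # 18.0106
#' @export
monoisotopic_mass <- function(formula) {
  counts <- parse_formula(formula)
  if (!length(counts)) return(0)
  sum(counts * ATOMIC_MASSES[names(counts)])
}

#' Theoretical deprotonated ion m/z
#'
#' m/z of the `[M-H]-` ion observed in negative-mode electrospray:
#' neutral monoisotopic mass minus one hydrogen atom (1.00783 Da; the
#' electron mass is neglected, which reproduces the library's observed
#' masses to 4 decimals).
#'
#' @param formula Formula string or named count vector; must contain
#'   hydrogen.
#' @return m/z in Da.
#' @examples
#' deprotonated_mz("C5H9NO2")  # 114.0555 (proline)
#' @export
deprotonated_mz <- function(formula) {
  counts <- parse_formula(formula)
  if (!("H" %in% names(counts)) || counts[["H"]] < 1)
    stop("no hydrogen to remove: cannot form [M-H]- from '",
         if (is.character(formula)) formula else "formula", "'")
  monoisotopic_mass(counts) - H_ATOM_MASS
}

#' Load a compound annotation library
#'
#' Reads a library CSV (columns: index, name, class, formula, calc_mz,
#' obs_mz, semicolon-separated fragments, first_in_sf, formula_suspect)
#' and augments it with the theoretical `[M-H]-` m/z of each formula.
#' Printed calculated/observed masses that disagree with the exact-mass
#' arithmetic are surfaced by [library_discrepancies()], never silently
#' corrected; formulas that fail to parse would error here, which is why
#' chemically suspect but parseable formulas are only flagged.
#'
#' @param path CSV path; default the bundled 79-compound seaweed-extract
#'   library.
#' @return A data frame of class `compound_library` with list-column
#'   `fragments` and numeric `theory_mz`.
#' @examples
#' nrow(sf_compounds())  # 79
#' @export
load_compound_library <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "compound_library_sf.csv",
                        package = "maeopt", mustWork = TRUE)
  x <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("index", "name", "class", "formula", "calc_mz", "obs_mz",
            "fragments", "first_in_sf", "formula_suspect")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols))
    stop("library CSV missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (any(x$obs_mz <= 0)) stop("observed m/z must be positive")
  x$fragments <- lapply(strsplit(x$fragments, ";", fixed = TRUE),
                        function(f) as.numeric(f[nzchar(f)]))
  bad <- vapply(seq_len(nrow(x)), function(i)
    any(x$fragments[[i]] >= x$obs_mz[i] + 1), logical(1))
  if (any(bad))
    warning("fragments above precursor+1 for index ",
            paste(x$index[bad], collapse = ", "))
  x$theory_mz <- vapply(x$formula, deprotonated_mz, numeric(1),
                        USE.NAMES = FALSE)
  class(x) <- c("compound_library", "data.frame")
  x
}

#' @rdname load_compound_library
#' @export
sf_compounds <- function() load_compound_library()

#' Report printed-mass inconsistencies in a compound library
#'
#' For every record, the difference between the theoretical `[M-H]-`
#' m/z computed from the formula and (a) the printed calculated mass,
#' (b) the printed observed mass, in mDa and ppm. Records exceeding
#' `ppm_flag` against the printed calculated mass are marked; several
#' printed entries of the bundled library are internally inconsistent
#' and this report is how they surface.
#'
#' @param library A `compound_library`.
#' @param ppm_flag Flagging threshold in ppm (default 20).
#' @return Data frame with one row per compound.
#' @export
library_discrepancies <- function(library = sf_compounds(), ppm_flag = 20) {
  th <- library$theory_mz
  data.frame(
    index = library$index, name = library$name, formula = library$formula,
    theory_mz = th,
    calc_delta_mda = 1000 * (library$calc_mz - th),
    calc_ppm = 1e6 * (library$calc_mz - th) / th,
    obs_delta_mda = 1000 * (library$obs_mz - th),
    obs_ppm = 1e6 * (library$obs_mz - th) / th,
    formula_suspect = library$formula_suspect,
    flagged = abs(1e6 * (library$calc_mz - th) / th) > ppm_flag |
      library$formula_suspect,
    stringsAsFactors = FALSE)
}

#' Match an observed peak against a compound library
#'
#' Candidates are library records whose theoretical `[M-H]-` m/z lies
#' within `ppm_tol` of the query, with the theoretical value as the ppm
#' denominator; results are sorted by absolute ppm error.
#'
#' @param mz Observed m/z.
#' @param library A `compound_library`.
#' @param ppm_tol Tolerance in ppm (default 5, typical Orbitrap practice).
#' @return Data frame of candidates (possibly empty) with `ppm_error`.
#' @examples
#' match_peak(114.0555, sf_compounds())$name[1]  # L-Proline
#' @export
match_peak <- function(mz, library = sf_compounds(), ppm_tol = 5) {
  if (ppm_tol <= 0) stop("ppm_tol must be > 0")
  if (!is.finite(mz) || mz <= 0) stop("mz must be a positive number")
  ppm <- 1e6 * (mz - library$theory_mz) / library$theory_mz
  hit <- abs(ppm) <= ppm_tol
  out <- data.frame(index = library$index[hit], name = library$name[hit],
                    class = library$class[hit],
                    formula = library$formula[hit],
                    theory_mz = library$theory_mz[hit],
                    ppm_error = ppm[hit], stringsAsFactors = FALSE)
  out[order(abs(out$ppm_error)), , drop = FALSE]
}

#' Catalog of characteristic neutral losses
#'
#' Exact monoisotopic masses (Da) of the fragmentation losses used to
#' interpret MS/MS spectra of seaweed polyphenols: methyl, water,
#' carbonyl, carboxyl, sulfo and hexose departures.
#'
#' @return Named numeric vector.
#' @export
neutral_loss_catalog <- function() {
  c(CH3 = 15.0235, H2O = 18.0106, CO = 27.9949, CO2 = 43.9898,
    SO3 = 79.9568, hexose = 162.0528)
}

#' Label fragment losses against a neutral-loss catalog
#'
#' Forms every positive single-step mass difference -- precursor to each
#' fragment, and each fragment to every smaller fragment -- and assigns
#' the catalog loss closest in mass when within `tol_da`; unmatched
#' differences are labelled `"unknown"`. Zero differences are skipped.
#'
#' @param precursor_mz Precursor ion m/z.
#' @param fragment_mzs Numeric vector of fragment m/z values (all below
#'   `precursor_mz`).
#' @param catalog Named loss-mass vector (default
#'   [neutral_loss_catalog()]).
#' @param tol_da Match tolerance in Da (default 0.02).
#' @return Data frame with columns `from_mz`, `to_mz`, `loss_mass`,
#'   `label`, `catalog_mass`, `delta_da`.
#' @examples
#' annotate_losses(309.0974, c(147.04))$label  # "hexose"
#' @export
annotate_losses <- function(precursor_mz, fragment_mzs,
                            catalog = neutral_loss_catalog(),
                            tol_da = 0.02) {
  if (tol_da <= 0) stop("tol_da must be > 0")
  if (any(fragment_mzs > precursor_mz))
    stop("fragments must not exceed the precursor m/z")
  ions <- c(precursor_mz, sort(fragment_mzs, decreasing = TRUE))
  rows <- list()
  for (i in seq_along(ions)) {
    for (j in seq_along(ions)) {
      if (j <= i) next
      loss <- ions[i] - ions[j]
      if (loss <= 0) next
      d <- abs(catalog - loss)
      best <- which.min(d)
      matched <- d[best] <= tol_da
      rows[[length(rows) + 1L]] <- data.frame(
        from_mz = ions[i], to_mz = ions[j], loss_mass = loss,
        label = if (matched) names(catalog)[best] else "unknown",
        catalog_mass = if (matched) unname(catalog[best]) else NA_real_,
        delta_da = if (matched) unname(loss - catalog[best]) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(from_mz = numeric(0), to_mz = numeric(0),
                      loss_mass = numeric(0), label = character(0),
                      catalog_mass = numeric(0), delta_da = numeric(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
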