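#' Read native-MS peak tables from CSV
#'
#' Canonical columns: `species`, `concentration_uM`, `n_bound`, `intensity`,
#' and optionally `charge`. Rows are grouped into one [peak_set()] per
#' (species, concentration); when a `charge` column is present and
#' `max_charge` is set, the charge-state filter of [filter_charge_states()]
#' is applied per group. Duplicate (species, concentration, n_bound) rows are
#' summed with a warning. Malformed input is rejected with the offending row
#' named, never silently coerced.
#'
#' @param path CSV file path.
#' @param max_charge Optional charge-state cap (applied only when a `charge`
#'   column is present).
#' @return List of [peak_set()] objects.
#' @export
read_peaks_csv <- function(path, max_charge = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "concentration_uM", "n_bound", "intensity")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop(sprintf("schema error: missing column(s) %s", paste(miss, collapse = ", ")))
  bad <- which(!is.finite(df$intensity) | df$intensity < 0)
  if (length(bad) > 0L)
    stop(sprintf("schema error: negative or non-finite intensity at row %d", bad[1]))
  bad <- which(!is.finite(df$n_bound) | df$n_bound < 0 |
                 df$n_bound != round(df$n_bound))
  if (length(bad) > 0L)
    stop(sprintf("schema error: invalid n_bound at row %d", bad[1]))
  groups <- split(df, list(df$species, df$concentration_uM), drop = TRUE)
  lapply(unname(groups), function(g) {
    sp <- g$species[1]; cc <- g$concentration_uM[1]
    if ("charge" %in% names(g) && !is.null(max_charge))
      return(filter_charge_states(g, max_charge = max_charge,
                                  species = sp, concentration = cc))
    if (anyDuplicated(g$n_bound)) {
      warning(sprintf("duplicated (species, concentration, n_bound) rows for %s at %g uM: intensities summed",
                      sp, cc))
      g <- stats::aggregate(intensity ~ n_bound, data = g, FUN = sum)
    }
    g <- g[order(g$n_bound), ]
    peak_set(sp, cc, g$n_bound, g$intensity)
  })
}

#' Write peak sets to CSV
#'
#' Inverse of [read_peaks_csv()] (modulo float formatting).
#'
#' @param peaksets List of [peak_set()] objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_peaks_csv <- function(peaksets, path) {
  if (inherits(peaksets, "peak_set")) peaksets <- list(peaksets)
  rows <- lapply(peaksets, function(ps)
    data.frame(species = ps$species$name,
               concentration_uM = ps$concentration,
               n_bound = ps$n_bound, intensity = ps$intensity))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read a coarse-grained GRO coordinate file as a membrane frame
#'
#' Parses the fixed-column GRO record layout (residue id/name, atom name,
#' atom number, x/y/z in nm) and converts to Angstrom. Residue names listed
#' in `species_map` become lipids of the mapped species, with the bead named
#' `phosphate_bead_name` as the phosphate; residue names in
#' `protein_resnames` become protein beads (flagged TMD). Any other residue
#' is ignored with a count warning.
#'
#' @param path GRO file path.
#' @param species_map Named character vector, residue name -> species label,
#'   e.g. `c(POPG = "POPG", POPC = "POPC")`.
#' @param protein_resnames Residue names treated as protein TMD beads.
#' @param phosphate_bead_name Phosphate bead name (default "PO4").
#' @param time Frame time in microseconds (optional).
#' @return A [membrane_frame()].
#' @export
read_gro_frame <- function(path, species_map, protein_resnames,
                           phosphate_bead_name = "PO4", time = NA_real_) {
  lines <- readLines(path)
  if (length(lines) < 3L) stop("parse error: truncated GRO file (no box line)")
  n_atoms <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(n_atoms)) stop("parse error: line 2 is not an atom count")
  if (length(lines) < 3L + n_atoms)
    stop("parse error: fewer atom lines than the declared count (missing box line?)")
  box_fields <- suppressWarnings(as.numeric(strsplit(trimws(lines[3L + n_atoms]),
                                                     "\\s+")[[1]]))
  if (length(box_fields) < 3L || any(is.na(box_fields[1:3])))
    stop("parse error: malformed or missing box line")
  box <- box_fields[1:3] * 10  # nm -> Angstrom
  at <- lines[3:(2 + n_atoms)]
  parse_num <- function(s, i, ln) {
    v <- suppressWarnings(as.numeric(s))
    if (any(is.na(v)))
      stop(sprintf("parse error: malformed fixed-width field at line %d",
                   ln[which(is.na(v))[1]]))
    v
  }
  lnum <- 2L + seq_len(n_atoms)
  resid <- trimws(substr(at, 1, 5))
  resname <- trimws(substr(at, 6, 10))
  atomname <- trimws(substr(at, 11, 15))
  x <- parse_num(substr(at, 21, 28), 1, lnum) * 10
  y <- parse_num(substr(at, 29, 36), 2, lnum) * 10
  z <- parse_num(substr(at, 37, 44), 3, lnum) * 10

  is_prot <- resname %in% protein_resnames
  is_lip <- resname %in% names(species_map)
  n_other <- sum(!is_prot & !is_lip)
  if (n_other > 0L)
    warning(sprintf("%d bead(s) with unmapped residue names ignored", n_other))
  if (!any(is_prot)) stop("configuration error: no protein beads found")
  if (!any(is_lip)) stop("no lipid beads found for the supplied species_map")
  protein <- data.frame(x = x[is_prot], y = y[is_prot], z = z[is_prot],
                        tmd = TRUE)
  lip_id <- paste0(resname[is_lip], "_", resid[is_lip])
  lipids <- data.frame(lipid_id = lip_id,
                       species = unname(species_map[resname[is_lip]]),
                       bead = atomname[is_lip],
                       x = x[is_lip], y = y[is_lip], z = z[is_lip],
                       phosphate = atomname[is_lip] == phosphate_bead_name)
  membrane_frame(protein, lipids, box = box, time = time)
}

#' Read thermal-stability measurements from CSV
#'
#' Columns: `concentration_uM`, `effect`, and optionally `replicate`.
#'
#' @param path CSV file path.
#' @return Data frame with columns `concentration`, `effect`, `replicate`.
#' @export
read_stability_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("concentration_uM", "effect")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop(sprintf("schema error: missing column(s) %s", paste(miss, collapse = ", ")))
  if (any(!is.finite(df$effect)))
    stop(sprintf("schema error: non-finite effect at row %d",
                 which(!is.finite(df$effect))[1]))
  data.frame(concentration = df$concentration_uM, effect = df$effect,
             replicate = if ("replicate" %in% names(df)) df$replicate else 1L)
}

#' Read stopped-flow quench traces from CSV
#'
#' Columns: `condition`, `delay_s`, `rep`, `time_s`, `fluorescence`.
#'
#' @param path CSV file path.
#' @return Validated data frame in the layout [aggregate_rates()] consumes.
#' @export
read_flux_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("condition", "delay_s", "rep", "time_s", "fluorescence")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop(sprintf("schema error: missing column(s) %s", paste(miss, collapse = ", ")))
  if (any(!is.finite(df$fluorescence)))
    stop("schema error: non-finite fluorescence values")
  df
}

#' Read patch-clamp current traces from CSV
#'
#' Columns: `condition`, `patch_id`, `concentration_mM`, `time_s`,
#' `current_pA`.
#'
#' @param path CSV file path.
#' @return Validated data frame.
#' @export
read_currents_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("condition", "patch_id", "concentration_mM", "time_s", "current_pA")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop(sprintf("schema error: missing column(s) %s", paste(miss, collapse = ", ")))
  if (any(!is.finite(df$current_pA)))
    stop("schema error: non-finite current values")
  df
}
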