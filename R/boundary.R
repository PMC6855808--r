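#' Coarse-grained membrane frame
#'
#' One snapshot of a protein embedded in a lipid bilayer: protein bead
#' coordinates with a transmembrane-domain (TMD) flag, per-lipid bead records
#' with species labels and a phosphate-bead flag, and the periodic box.
#' All coordinates are in Angstrom.
#'
#' @param protein Data frame with columns `x`, `y`, `z` and logical `tmd`
#'   (at least one TMD bead); an optional `helix` column is carried along.
#' @param lipids Data frame with columns `lipid_id`, `species`, `x`, `y`, `z`
#'   and logical `phosphate`; every lipid must have at least one bead and
#'   exactly one phosphate bead.
#' @param box Periodic box lengths in Angstrom: length 2 (periodic in x, y)
#'   or 3 (fully periodic).
#' @param time Frame time in microseconds (optional).
#' @return An object of class `membrane_frame`.
#' @export
membrane_frame <- function(protein, lipids, box, time = NA_real_) {
  stopifnot(is.data.frame(protein), is.data.frame(lipids))
  if (!all(c("x", "y", "z", "tmd") %in% names(protein)))
    stop("'protein' needs columns x, y, z, tmd")
  if (!any(protein$tmd)) stop("configuration error: no TMD-flagged protein beads")
  if (!all(c("lipid_id", "species", "x", "y", "z", "phosphate") %in% names(lipids)))
    stop("'lipids' needs columns lipid_id, species, x, y, z, phosphate")
  if (nrow(lipids) == 0L) stop("no lipid beads")
  nph <- tapply(lipids$phosphate, lipids$lipid_id, sum)
  if (any(nph != 1L))
    stop("each lipid must have exactly one phosphate bead")
  co <- c(protein$x, protein$y, protein$z, lipids$x, lipids$y, lipids$z)
  if (any(!is.finite(co))) stop("coordinates must be finite")
  box <- as.numeric(box)
  if (!length(box) %in% c(2L, 3L) || any(box <= 0))
    stop("'box' must be 2 or 3 positive lengths (Angstrom)")
  structure(list(protein = protein, lipids = lipids, box = box, time = time),
            class = "membrane_frame")
}

#' @export
print.membrane_frame <- function(x, ...) {
  cat(sprintf("<membrane_frame> %d protein beads (%d TMD), %d lipids (%s), box %s A\n",
              nrow(x$protein), sum(x$protein$tmd),
              length(unique(x$lipids$lipid_id)),
              paste(names(table(x$lipids$species[x$lipids$phosphate])),
                    collapse = "/"),
              paste(signif(x$box, 4), collapse = " x ")))
  invisible(x)
}

# Minimum-image squared distances between two coordinate matrices (n x 3).
# 'box' gives periodic lengths for the first length(box) dimensions.
.min_image_dist2 <- function(a, b, box) {
  d2 <- matrix(0, nrow(a), nrow(b))
  for (k in 1:3) {
    dk <- outer(a[, k], b[, k], "-")
    if (k <= length(box)) dk <- dk - box[k] * round(dk / box[k])
    d2 <- d2 + dk * dk
  }
  d2
}

#' Assign lipids to leaflets
#'
#' Labels each lipid `outer` or `inner` by the z coordinate of its phosphate
#' bead relative to the instantaneous median phosphate z of the frame.
#'
#' @param frame A [membrane_frame()].
#' @return Named character vector (`outer`/`inner`), one entry per lipid,
#'   named by `lipid_id`.
#' @export
assign_leaflets <- function(frame) {
  stopifnot(inherits(frame, "membrane_frame"))
  ph <- frame$lipids[frame$lipids$phosphate, ]
  if (nrow(ph) < 2L) stop("need >= 2 lipids to assign leaflets")
  if (diff(range(ph$z)) < 1e-9)
    stop("degenerate input: all phosphate beads are coplanar")
  mid <- stats::median(ph$z)
  lab <- ifelse(ph$z > mid, "outer", "inner")
  names(lab) <- ph$lipid_id
  lab
}

#' Classify boundary (annular) lipids
#'
#' A lipid is a boundary lipid iff the minimum distance between any of its
#' beads and any TMD protein bead is at most `cutoff`, under the
#' minimum-image convention in the periodic dimensions of the box.
#'
#' @param frame A [membrane_frame()].
#' @param cutoff Distance cutoff in Angstrom (default 6).
#' @return An object of class `boundary_count`: list with `per_species`
#'   (named counts), `b_tot`, `boundary_ids` (lipid ids), and `time`.
#' @export
find_boundary <- function(frame, cutoff = 6) {
  stopifnot(inherits(frame, "membrane_frame"))
  if (!is.numeric(cutoff) || cutoff <= 0) stop("'cutoff' must be > 0")
  tmd <- frame$protein[frame$protein$tmd, c("x", "y", "z"), drop = FALSE]
  if (nrow(tmd) == 0L) stop("configuration error: no TMD-flagged protein beads")
  lb <- frame$lipids
  d2 <- .min_image_dist2(as.matrix(lb[, c("x", "y", "z")]), as.matrix(tmd),
                         frame$box)
  near_bead <- apply(d2, 1L, min) <= cutoff^2
  is_boundary <- tapply(near_bead, lb$lipid_id, any)
  species_of <- tapply(as.character(lb$species), lb$lipid_id, `[`, 1L)
  all_species <- sort(unique(as.character(lb$species)))
  bids <- names(is_boundary)[is_boundary]
  per_species <- table(factor(species_of[bids], levels = all_species))
  structure(list(per_species = as.vector(per_species),
                 species = all_species,
                 b_tot = length(bids), boundary_ids = bids,
                 time = frame$time),
            class = "boundary_count")
}

#' @export
print.boundary_count <- function(x, ...) {
  cat(sprintf("<boundary_count> b_tot = %d (%s)\n", x$b_tot,
              paste(sprintf("%s: %d", x$species, x$per_species), collapse = ", ")))
  invisible(x)
}

# Full-census bulk mole fractions and boundary fraction of one species in one frame.
.frame_fractions <- function(frame, species, cutoff) {
  bc <- find_boundary(frame, cutoff)
  species_of <- tapply(as.character(frame$lipids$species),
                       frame$lipids$lipid_id, `[`, 1L)
  x_i <- mean(species_of == species)
  list(bc = bc, x_i = x_i)
}

#' Boundary-lipid enrichment metric B
#'
#' For each frame, the fraction of boundary lipids that are of the requested
#' species is divided by the species' bulk mole fraction (full lipid census of
#' that frame) and 1 is subtracted; the result is averaged over frames (and
#' replicas, when frames from several runs are pooled). B > 0 indicates
#' enrichment among boundary lipids, B < 0 depletion, and B = 0 random
#' mixing. Frames with no boundary lipids are skipped with a warning.
#'
#' @param frames List of [membrane_frame()] objects.
#' @param species Species label.
#' @param cutoff Boundary cutoff in Angstrom (default 6).
#' @return An object of class `enrichment_result`: list with `species`, `B`
#'   (mean over frames), `sd`, `n_frames`, `bulk_fraction` (mean x_i) and
#'   `per_frame` (per-frame B values).
#' @export
enrichment <- function(frames, species, cutoff = 6) {
  if (inherits(frames, "membrane_frame")) frames <- list(frames)
  stopifnot(length(frames) >= 1L)
  vals <- numeric(0); xs <- numeric(0); skipped <- 0L
  for (fr in frames) {
    ff <- .frame_fractions(fr, species, cutoff)
    if (ff$x_i <= 0)
      stop(sprintf("species '%s' absent from the lipid census (x_i = 0)", species))
    if (ff$bc$b_tot == 0L) { skipped <- skipped + 1L; next }
    b_i <- ff$bc$per_species[match(species, ff$bc$species)]
    if (is.na(b_i)) b_i <- 0
    vals <- c(vals, (b_i / ff$bc$b_tot) / ff$x_i - 1)
    xs <- c(xs, ff$x_i)
  }
  if (skipped > 0L)
    warning(sprintf("%d frame(s) with no boundary lipids were skipped", skipped))
  if (length(vals) == 0L) stop("no frames with boundary lipids")
  structure(list(species = species, B = mean(vals),
                 sd = if (length(vals) > 1L) stats::sd(vals) else 0,
                 n_frames = length(vals), bulk_fraction = mean(xs),
                 per_frame = vals),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("<enrichment_result> %s: B = %.3f +/- %.3f (n = %d frames, x_i = %.3f)\n",
              x$species, x$B, x$sd, x$n_frames, x$bulk_fraction))
  invisible(x)
}

#' Mean total boundary-lipid count over frames
#'
#' @param frames List of [membrane_frame()] objects (>= 2).
#' @param cutoff Boundary cutoff in Angstrom (default 6).
#' @return List with `mean`, `sd` and `per_frame` total boundary counts.
#' @export
boundary_census <- function(frames, cutoff = 6) {
  stopifnot(is.list(frames), length(frames) >= 2L)
  btot <- vapply(frames, function(fr) find_boundary(fr, cutoff)$b_tot, numeric(1))
  list(mean = mean(btot), sd = stats::sd(btot), per_frame = btot)
}

#' Leaflet-resolved polar density map of phosphate beads
#'
#' Bins the phosphate beads of one species, in one leaflet, into polar bins
#' around the protein center (TMD center of mass projected onto the membrane
#' plane) and reports the mean per-bin area density over the chosen frame
#' window.
#'
#' @param frames List of [membrane_frame()] objects.
#' @param species Species label.
#' @param leaflet `"outer"` or `"inner"`.
#' @param r_max Map extent in Angstrom (default 40).
#' @param dr Radial bin width in Angstrom (default 4); `r_max/dr` must be an
#'   integer.
#' @param dtheta Angular bin width in radians (default pi/15, i.e. 30 bins).
#' @param frame_window `"last_half"` (default, the analysis window used for
#'   density maps) or `"all"`.
#' @return An object of class `polar_density_map`: list with `values`
#'   (radial x angular matrix of mean area densities, per Angstrom^2),
#'   `counts` (mean per-bin counts), `r_edges`, `theta_edges`, `leaflet`,
#'   `species`, `n_frames`.
#' @export
polar_density <- function(frames, species, leaflet = c("outer", "inner"),
                          r_max = 40, dr = 4, dtheta = pi / 15,
                          frame_window = c("last_half", "all")) {
  leaflet <- match.arg(leaflet)
  frame_window <- match.arg(frame_window)
  if (inherits(frames, "membrane_frame")) frames <- list(frames)
  n_r <- r_max / dr
  if (abs(n_r - round(n_r)) > 1e-9)
    stop("binning error: r_max/dr must be an integer")
  n_r <- as.integer(round(n_r))
  n_th <- as.integer(round(2 * pi / dtheta))
  if (abs(n_th * dtheta - 2 * pi) > 1e-6)
    stop("binning error: dtheta must divide 2*pi")
  if (frame_window == "last_half") {
    tt <- vapply(frames, function(fr) fr$time, numeric(1))
    ord <- if (all(is.finite(tt))) order(tt) else seq_along(frames)
    n <- length(frames)
    frames <- frames[ord][(floor(n / 2) + 1L):n]
  }
  acc <- matrix(0, n_r, n_th)
  for (fr in frames) {
    tmd <- fr$protein[fr$protein$tmd, ]
    ctr <- c(mean(tmd$x), mean(tmd$y))
    leaf <- assign_leaflets(fr)
    ph <- fr$lipids[fr$lipids$phosphate, ]
    keep <- as.character(ph$species) == species &
      leaf[as.character(ph$lipid_id)] == leaflet
    ph <- ph[keep, , drop = FALSE]
    if (nrow(ph) == 0L) next
    dx <- ph$x - ctr[1]; dy <- ph$y - ctr[2]
    dx <- dx - fr$box[1] * round(dx / fr$box[1])
    dy <- dy - fr$box[2] * round(dy / fr$box[2])
    r <- sqrt(dx^2 + dy^2)
    th <- atan2(dy, dx) %% (2 * pi)
    inr <- r < r_max
    if (!any(inr)) next
    ri <- pmin(floor(r[inr] / dr), n_r - 1L) + 1L
    ti <- pmin(floor(th[inr] / dtheta), n_th - 1L) + 1L
    for (j in seq_along(ri)) acc[ri[j], ti[j]] <- acc[ri[j], ti[j]] + 1
  }
  counts <- acc / length(frames)
  r_edges <- seq(0, r_max, by = dr)
  areas <- outer(diff(r_edges^2) / 2, rep(dtheta, n_th))  # (r2^2-r1^2)/2 * dtheta
  structure(list(values = counts / areas, counts = counts,
                 r_edges = r_edges,
                 theta_edges = seq(0, 2 * pi, length.out = n_th + 1L),
                 leaflet = leaflet, species = species,
                 n_frames = length(frames)),
            class = "polar_density_map")
}

#' @export
print.polar_density_map <- function(x, ...) {
  cat(sprintf("<polar_density_map> %s, %s leaflet: %d x %d bins, mean in-range count %.2f (n = %d frames)\n",
              x$species, x$leaflet, nrow(x$values), ncol(x$values),
              sum(x$counts), x$n_frames))
  invisible(x)
}
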