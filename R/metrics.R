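# RMSD series per substructure and RMSF fluctuation profiles.

#' Per-frame RMSD of a substructure
#'
#' For each frame, the region's heavy atoms are superposed onto the reference
#' ("fitting to their respective parts") and the heavy-atom RMSD over the same
#' region is computed. The default reference is the first frame of the
#' trajectory, i.e. the initial structure of the production run. A different
#' fit region can be requested (e.g. fitting a ligand's RMSD on the RNA heavy
#' atoms) via `fit_region`.
#'
#' @param trajectory a trajectory object.
#' @param annotation a `substructure_annotation`.
#' @param region region name to measure.
#' @param reference reference coordinates: a structure, frame index or xyz
#'   vector (default first frame).
#' @param fit_region region whose heavy atoms are used for the fit
#'   (default: `region` itself).
#' @return an `rmsd_series`: region, per-frame values (Angstrom), mean, sd
#'   (sample SD), reference descriptor.
#' @export
rmsd_series <- function(trajectory, annotation, region,
                        reference = 1L, fit_region = region) {
  sel  <- region_selection(trajectory$topology, annotation, region, heavy = TRUE)
  fsel <- region_selection(trajectory$topology, annotation, fit_region, heavy = TRUE)
  ref_xyz <- resolve_reference(trajectory, reference)
  refm <- vec2mat(ref_xyz)

  vals <- vapply(seq_len(n_frames(trajectory)), function(f) {
    fit <- kabsch_superpose(frame_coords(trajectory, f), refm,
                            fit_indices = fsel$atom)
    coord_rmsd(fit$xyz, refm, sel$atom)
  }, numeric(1))

  structure(
    list(region = region, values = vals,
         mean = mean(vals), sd = if (length(vals) > 1) stats::sd(vals) else 0,
         reference = if (is.numeric(reference) && length(reference) == 1)
           sprintf("frame %d", reference) else "structure",
         fit_region = fit_region),
    class = "rmsd_series"
  )
}

#' @export
print.rmsd_series <- function(x, ...) {
  cat(sprintf("<rmsd series> %s: %.2f (%.2f) A over %d frames [ref: %s]\n",
              x$region, x$mean, x$sd, length(x$values), x$reference))
  invisible(x)
}

#' Table-style RMSD summary over all annotated regions
#'
#' One row per region with mean and standard deviation, mirroring the usual
#' "mean (sd)" presentation of substructure RMSD tables.
#'
#' @inheritParams rmsd_series
#' @param regions character vector of region names (default: all).
#' @return data.frame with columns region, mean_rmsd, sd_rmsd, n_frames.
#' @export
rmsd_table <- function(trajectory, annotation, regions = names(annotation),
                       reference = 1L) {
  rows <- lapply(regions, function(r) {
    s <- rmsd_series(trajectory, annotation, r, reference = reference)
    data.frame(region = r, mean_rmsd = s$mean, sd_rmsd = s$sd,
               n_frames = length(s$values))
  })
  do.call(rbind, rows)
}

#' Root-mean-square fluctuation profile
#'
#' Frames are superposed onto the average structure over `fit_selection`
#' (a single fit-to-mean pass followed by recomputation of the mean; set
#' `iterate = TRUE` for full convergence), then
#' `RMSF_i = sqrt(mean_f |r_i(f) - <r_i>|^2)` is evaluated over
#' `measure_selection`. Pass `fit_selection = NULL` to skip superposition
#' (coordinates are then taken as already aligned).
#'
#' @param trajectory a trajectory object with at least 2 frames.
#' @param fit_selection `atom_selection` used for superposition, or NULL.
#' @param measure_selection `atom_selection` to report (default: fit selection,
#'   or all atoms when `fit_selection` is NULL).
#' @param per_residue if TRUE, average the per-atom values within each residue.
#' @param iterate if TRUE, repeat fit-to-mean until the mean structure is
#'   stable (tolerance 1e-8 A).
#' @return an `rmsf_profile`: values (Angstrom), atom indices (or residue
#'   numbers when `per_residue`), selection descriptor.
#' @export
rmsf_profile <- function(trajectory, fit_selection,
                         measure_selection = NULL, per_residue = FALSE,
                         iterate = FALSE) {
  if (n_frames(trajectory) < 2)
    stopf("insufficient frames: RMSF requires at least 2 frames")
  msel <- measure_selection %||% fit_selection %||%
    select_atoms(trajectory$topology, "all")

  xyz <- trajectory$xyz
  if (!is.null(fit_selection)) {
    mean_xyz <- colMeans(xyz)
    repeat {
      xyz_fit <- superpose_frames(trajectory$xyz, mean_xyz, fit_selection$atom)
      new_mean <- colMeans(xyz_fit)
      done <- !iterate || max(abs(new_mean - mean_xyz)) < 1e-8
      mean_xyz <- new_mean
      xyz <- xyz_fit
      if (done) break
    }
  } else {
    mean_xyz <- colMeans(xyz)
  }

  dev2 <- sweep(xyz, 2, mean_xyz)^2
  # per-atom mean squared displacement over frames
  msd <- colMeans(dev2)
  per_atom <- sqrt(msd[seq(1, length(msd), 3)] +
                   msd[seq(2, length(msd), 3)] +
                   msd[seq(3, length(msd), 3)])
  vals <- per_atom[msel$atom]
  ids <- msel$atom

  if (per_residue) {
    res <- trajectory$topology$atom$resno[msel$atom]
    vals <- tapply(vals, res, mean)
    ids <- as.integer(names(vals))
    o <- order(ids)
    vals <- as.numeric(vals[o]); ids <- ids[o]
  }

  structure(
    list(values = as.numeric(vals), ids = ids, per_residue = per_residue,
         selection = msel$descriptor),
    class = "rmsf_profile"
  )
}

#' @export
print.rmsf_profile <- function(x, ...) {
  cat(sprintf("<rmsf profile> %d %s, mean %.3f A (selection: %s)\n",
              length(x$values), if (x$per_residue) "residues" else "atoms",
              mean(x$values), x$selection))
  invisible(x)
}
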