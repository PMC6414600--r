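# Seeded synthetic-trajectory generator with planted statistical structure.
#
# This is a statistical emulator, not a physics simulator: frames fluctuate
# around an idealized reference with a prescribed residue-residue correlation
# structure (one shared latent factor per correlated block), optional
# rigid-body drift, and hydrogen-bond geometries planted at known occupancy.
# Every planted quantity is recoverable by the corresponding analysis module,
# which is what makes the pipeline verifiable at desk scale.

default_template <- function() {
  data.frame(
    elety = c("P", "O5'", "C5'", "C4'", "C1'", "N1", "H1", "O2"),
    elesy = c("P", "O",   "C",   "C",   "C",   "N",  "H",  "O"),
    dx = c(-1.8, -1.2, 0.0, 0.9, 2.2, 3.4, 3.9, 3.8),
    dy = c( 0.6,  0.3, 0.0, 0.8, 0.4, 0.0, 0.8, -1.2),
    dz = c(-1.5, -0.7, 0.0, 0.6, 0.9, 0.2, 0.2,  0.0),
    stringsAsFactors = FALSE
  )
}

#' Specification for a synthetic trajectory
#'
#' Defines the ground truth a generated trajectory realises: residue count
#' and fold geometry, per-residue fluctuation scale, correlated residue
#' blocks (one shared latent Gaussian factor per block, loading chosen so the
#' pairwise correlation equals the target), planted hydrogen-bond schedules,
#' optional rigid-body drift, and the seed all randomness flows from.
#'
#' @param n_residues number of residues (>= 2); default 76, the size of a
#'   typical TPP-aptamer chain.
#' @param n_frames number of frames (>= 1).
#' @param sigma per-residue displacement scale in Angstrom (scalar or length
#'   `n_residues`); default 0.5.
#' @param jitter independent per-atom jitter SD in Angstrom. Default 0.05,
#'   or 0 when `modes` is given (mode planting is exact low-rank motion).
#' @param correlation_blocks list of `list(residues = ..., rho = ...)` with
#'   target pairwise correlation `rho` in (-1, 1). Blocks must be disjoint;
#'   negative `rho` is representable only for 2-residue blocks (one-factor
#'   model) and must satisfy `rho >= -1/(m-1)` for positive semi-definiteness.
#' @param hbonds list of `list(donor = resno, acceptor = resno,
#'   occupancy = fraction)` planted donor(N1/H1)->acceptor(O2) geometries:
#'   in-criterion frames place the acceptor 2.9 A from the donor along the
#'   D-H direction (D-H-A = 180 deg), out-of-criterion frames at 5.0 A.
#' @param drift rigid-body drift amplitude in Angstrom (per-frame random
#'   translation of that magnitude; default 0).
#' @param fold `"hairpin"` (default; two antiparallel strands with inward
#'   bases giving a contact band plus long-range cross-strand contacts) or
#'   `"helix"`.
#' @param anchors residue numbers held nearly rigid so superposition is well
#'   conditioned (default: two at each end); their sigma is `anchor_sigma`.
#' @param anchor_sigma fluctuation scale of anchor residues (default 0.15 A).
#'   Deliberately kept above the superposition fit-residual scale
#'   (~`sigma/sqrt(n_residues)`): residues fluctuating much less than that
#'   inherit the common fit noise and acquire spurious mutual correlation,
#'   a known artifact of correlation analysis on rigidly fitted ensembles.
#' @param modes optional numeric vector of planted mode variances (A^2):
#'   instead of the block model, displacements are a sum of orthonormal
#'   residue-level directions (orthogonal to rigid-body motion) with these
#'   variances — the ground truth for PCA eigenvalue recovery.
#' @param seed integer random seed recorded in all outputs.
#' @param template atom template per residue (data.frame with elety, elesy,
#'   dx, dy, dz); must contain a C5' atom.
#' @return a validated `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_residues = 76, n_frames = 1000, sigma = 0.5,
                           jitter = NULL, correlation_blocks = list(),
                           hbonds = list(), drift = 0,
                           fold = c("hairpin", "helix"),
                           anchors = NULL, anchor_sigma = 0.15,
                           modes = NULL, seed = 1,
                           template = default_template()) {
  fold <- match.arg(fold)
  if (n_residues < 2) stopf("need at least 2 residues")
  if (n_frames < 1) stopf("need at least 1 frame")
  if (length(modes) == 0) modes <- NULL
  modes <- if (!is.null(modes)) as.numeric(modes)
  if (!"C5'" %in% template$elety)
    stopf("atom template must contain a C5' atom")
  if (length(sigma) == 1) sigma <- rep(sigma, n_residues)
  if (length(sigma) != n_residues) stopf("sigma must be scalar or per-residue")
  jitter <- jitter %||% (if (is.null(modes)) 0.05 else 0)

  seen <- integer(0)
  for (b in correlation_blocks) {
    r <- b$residues; rho <- b$rho
    if (is.null(r) || is.null(rho)) stopf("each block needs residues and rho")
    if (any(r < 1 | r > n_residues)) stopf("block residue out of range")
    if (length(intersect(r, seen)) > 0) stopf("correlation blocks must be disjoint")
    seen <- c(seen, r)
    m <- length(r)
    if (abs(rho) >= 1) stopf("target correlation must lie in (-1, 1)")
    if (rho < -1 / (m - 1))
      stopf("infeasible correlation structure: rho = %.3f < -1/(m-1) is not positive semi-definite", rho)
    if (rho < 0 && m > 2)
      stopf("negative block correlation is only representable for 2-residue blocks")
  }
  for (h in hbonds) {
    if (is.null(h$donor) || is.null(h$acceptor) || is.null(h$occupancy))
      stopf("each hbond needs donor, acceptor, occupancy")
    if (h$occupancy < 0 || h$occupancy > 1)
      stopf("occupancy fraction must be in [0, 1]")
  }
  if (!is.null(modes) && any(modes <= 0)) stopf("mode variances must be positive")
  if (is.null(anchors))
    anchors <- unique(c(1, 2, n_residues - 1, n_residues))
  if (is.null(seed) || is.na(seed)) stopf("a seed is required")

  structure(
    list(n_residues = as.integer(n_residues), n_frames = as.integer(n_frames),
         sigma = sigma, jitter = jitter,
         correlation_blocks = correlation_blocks, hbonds = hbonds,
         drift = drift, fold = fold, anchors = as.integer(anchors),
         anchor_sigma = anchor_sigma, modes = modes,
         seed = as.integer(seed), template = template),
    class = "synthetic_spec"
  )
}

#' Build the idealized reference structure of a spec
#'
#' Residues are instantiated from the atom template along the requested fold:
#' the hairpin places residues 1..m up one strand and m+1..n back down an
#' adjacent antiparallel strand 10 A away with base atoms facing inward
#' (residue i pairs spatially with n+1-i); the helix winds a single A-form
#' like coil. Deterministic; no randomness is consumed.
#'
#' @param spec a `synthetic_spec`.
#' @return a structure object with one C5' per residue.
#' @export
make_reference <- function(spec) {
  tmpl <- spec$template
  n <- spec$n_residues
  rise <- 4.0; strand_sep <- 10.0
  m <- ceiling(n / 2)
  resid_names <- rep(c("G", "A", "C", "U"), length.out = n)

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    if (spec$fold == "hairpin") {
      if (i <= m) { base <- c(0, 0, i * rise); sgn <- 1 }
      else        { base <- c(strand_sep, 0, (n - i + 1) * rise); sgn <- -1 }
      pos <- cbind(base[1] + sgn * tmpl$dx, base[2] + tmpl$dy, base[3] + tmpl$dz)
    } else {
      theta <- (i - 1) * 32.7 * pi / 180
      base <- c(9.4 * cos(theta), 9.4 * sin(theta), i * 2.81)
      ct <- cos(theta); st <- sin(theta)
      # rotate local offsets with the helical frame
      lx <- ct * tmpl$dx - st * tmpl$dy
      ly <- st * tmpl$dx + ct * tmpl$dy
      pos <- cbind(base[1] + lx, base[2] + ly, base[3] + tmpl$dz)
    }
    rows[[i]] <- data.frame(
      type = "ATOM", eleno = 0L, elety = tmpl$elety, resid = resid_names[i],
      chain = "A", resno = i, insert = "",
      x = pos[, 1], y = pos[, 2], z = pos[, 3],
      elesy = tmpl$elesy, stringsAsFactors = FALSE)
  }
  atom <- do.call(rbind, rows)
  atom$eleno <- seq_len(nrow(atom))
  new_structure(atom)
}

# orthonormal residue-level mode directions (3*n_res each), orthogonal to the
# 6 rigid-body motions of the C5' reference positions
make_mode_directions <- function(ref_c5, k) {
  n <- nrow(ref_c5)
  ctr <- colMeans(ref_c5)
  rc <- sweep(ref_c5, 2, ctr)
  rigid <- matrix(0, 3 * n, 6)
  rigid[seq(1, 3 * n, 3), 1] <- 1
  rigid[seq(2, 3 * n, 3), 2] <- 1
  rigid[seq(3, 3 * n, 3), 3] <- 1
  # infinitesimal rotations about x, y, z
  for (a in 1:3) {
    ax <- c(0, 0, 0); ax[a] <- 1
    disp <- t(apply(rc, 1, function(r) c(ax[2] * r[3] - ax[3] * r[2],
                                         ax[3] * r[1] - ax[1] * r[3],
                                         ax[1] * r[2] - ax[2] * r[1])))
    rigid[, 3 + a] <- as.numeric(t(disp))
  }
  basis <- qr.Q(qr(rigid))
  U <- matrix(0, 3 * n, k)
  for (j in seq_len(k)) {
    v <- stats::rnorm(3 * n)
    v <- v - basis %*% crossprod(basis, v)
    if (j > 1) v <- v - U[, 1:(j - 1), drop = FALSE] %*%
        crossprod(U[, 1:(j - 1), drop = FALSE], v)
    U[, j] <- v / sqrt(sum(v^2))
  }
  U
}

#' Generate a synthetic trajectory
#'
#' Frames are the reference plus zero-mean Gaussian displacements whose
#' residue-level covariance realises the spec's correlation blocks (shared
#' latent factor per block), plus independent per-atom jitter, plus optional
#' per-frame rigid drift; all atoms of a residue move rigidly with it.
#' Planted hydrogen-bond acceptors are positioned inside or outside the
#' geometric criterion according to seeded Bernoulli draws at the scheduled
#' occupancy. All randomness flows from `spec$seed`.
#'
#' @param reference the structure from [make_reference()] (or compatible).
#' @param spec the `synthetic_spec`.
#' @return a trajectory object of `spec$n_frames` frames.
#' @export
make_trajectory <- function(reference, spec) {
  n <- spec$n_residues
  if (n_residues(reference) != n)
    stopf("reference has %d residues, spec expects %d", n_residues(reference), n)
  atom <- reference$atom
  natom <- nrow(atom)
  nf <- spec$n_frames
  set.seed(spec$seed)

  sigma <- spec$sigma
  sigma[spec$anchors] <- spec$anchor_sigma

  # residue-level displacements, frames x 3n
  res_disp <- matrix(0, nf, 3 * n)
  if (!is.null(spec$modes)) {
    sel_c5 <- which(trimws(atom$elety) == "C5'")
    U <- make_mode_directions(as.matrix(atom[sel_c5, c("x", "y", "z")]),
                              length(spec$modes))
    Zm <- matrix(stats::rnorm(nf * length(spec$modes)), nf)
    for (k in seq_along(spec$modes))
      res_disp <- res_disp + sqrt(spec$modes[k]) * tcrossprod(Zm[, k], U[, k])
  } else {
    in_block <- rep(FALSE, n)
    eps <- matrix(stats::rnorm(nf * 3 * n), nf)
    for (b in spec$correlation_blocks) {
      r <- b$residues; rho <- b$rho
      in_block[r] <- TRUE
      Z <- matrix(stats::rnorm(nf * 3), nf)
      signs <- if (rho < 0) c(1, -1) else rep(1, length(r))
      for (j in seq_along(r)) {
        i <- r[j]
        cols <- (3 * i - 2):(3 * i)
        res_disp[, cols] <- sigma[i] *
          (signs[j] * sqrt(abs(rho)) * Z + sqrt(1 - abs(rho)) * eps[, cols])
      }
    }
    for (i in which(!in_block)) {
      cols <- (3 * i - 2):(3 * i)
      res_disp[, cols] <- sigma[i] * eps[, cols]
    }
  }

  # map residue displacements onto atoms (rigid within residue) + jitter
  ref_vec <- reference$xyz
  colmap <- as.integer(rbind(3L * atom$res_index - 2L,
                             3L * atom$res_index - 1L,
                             3L * atom$res_index))
  xyz <- matrix(ref_vec, nf, 3 * natom, byrow = TRUE) + res_disp[, colmap]
  if (spec$jitter > 0)
    xyz <- xyz + spec$jitter * matrix(stats::rnorm(nf * 3 * natom), nf)

  # planted hydrogen-bond geometry
  for (h in spec$hbonds) {
    d_atom <- h$donor_atom %||% "N1"
    h_atom <- h$h_atom %||% "H1"
    a_atom <- h$acceptor_atom %||% "O2"
    di <- which(atom$resno == h$donor & trimws(atom$elety) == d_atom)[1]
    hi <- which(atom$resno == h$donor & trimws(atom$elety) == h_atom)[1]
    ai <- which(atom$resno == h$acceptor & trimws(atom$elety) == a_atom)[1]
    if (any(is.na(c(di, hi, ai))))
      stopf("cannot plant hbond %s->%s: atoms missing from template",
            h$donor, h$acceptor)
    hit <- stats::runif(nf) < h$occupancy
    target <- ifelse(hit, 2.9, 5.0)
    Dm <- xyz[, (3 * di - 2):(3 * di)]
    Hm <- xyz[, (3 * hi - 2):(3 * hi)]
    dirm <- Hm - Dm
    dirm <- dirm / sqrt(rowSums(dirm^2))
    xyz[, (3 * ai - 2):(3 * ai)] <- Dm + target * dirm
  }

  if (spec$drift > 0) {
    tr <- matrix(stats::rnorm(nf * 3), nf)
    tr <- spec$drift * tr / sqrt(rowSums(tr^2))
    xyz <- xyz + tr[, rep(1:3, natom)]
  }

  new_trajectory(reference, xyz)
}

#' Apply a random rigid-body motion to every frame
#'
#' Rotates and translates each frame by an independent seeded random proper
#' rotation and translation — the canonical perturbation for invariance
#' checks (RMSD/DCCM/PCA/contact masks must not change after superposition).
#'
#' @param trajectory a trajectory object.
#' @param seed integer seed.
#' @param max_shift maximum translation magnitude per axis (default 10 A).
#' @return a trajectory object.
#' @export
perturb_rigid <- function(trajectory, seed = 1, max_shift = 10) {
  set.seed(seed)
  xyz <- trajectory$xyz
  for (f in seq_len(nrow(xyz))) {
    Q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
    if (det(Q) < 0) Q[, 1] <- -Q[, 1]
    shift <- stats::runif(3, -max_shift, max_shift)
    m <- vec2mat(xyz[f, ]) %*% Q
    xyz[f, ] <- mat2vec(sweep(m, 2, shift, "+"))
  }
  new_trajectory(trajectory$topology, xyz, trajectory$frame_labels)
}

#' Default substructure annotation for a synthetic spec
#'
#' Names follow riboswitch convention: a closing stem (P1) made of both chain
#' ends, arm and loop regions along the fold, plus `whole`. Regions may
#' overlap ("P3-L3" spans "P3" and "L3").
#'
#' @param spec a `synthetic_spec`.
#' @return a `substructure_annotation`.
#' @export
default_annotation <- function(spec) {
  n <- spec$n_residues
  m <- ceiling(n / 2)
  regions <- list(
    whole = seq_len(n),
    P1 = c(seq_len(min(3, n)), seq(max(1, n - 2), n)),
    P3 = seq(4, max(4, m - 2)),
    L3 = seq(max(1, m - 1), min(n, m + 2)),
    P5 = seq(min(n, m + 3), max(1, n - 3))
  )
  regions[["P3-L3"]] <- sort(unique(c(regions$P3, regions$L3)))
  regions <- lapply(regions, function(r) r[r >= 1 & r <= n])
  regions <- regions[vapply(regions, length, integer(1)) > 0]
  annotation(regions)
}

#' Default monitored-pair table for a synthetic spec
#'
#' One row per planted hydrogen bond (donor N1 -> acceptor O2); if none are
#' planted, a single cross-strand pair is monitored.
#'
#' @param spec a `synthetic_spec`.
#' @return data.frame usable with [hbond_occupancy()].
#' @export
default_pairs <- function(spec) {
  if (length(spec$hbonds) > 0) {
    do.call(rbind, lapply(spec$hbonds, function(h)
      data.frame(donor_resno = h$donor, donor_name = h$donor_atom %||% "N1",
                 acceptor_resno = h$acceptor,
                 acceptor_name = h$acceptor_atom %||% "O2")))
  } else {
    data.frame(donor_resno = 3, donor_name = "N1",
               acceptor_resno = spec$n_residues - 2, acceptor_name = "O2")
  }
}

#' Write a regenerable fixture bundle
#'
#' Writes the reference PDB, multi-model trajectory PDB, annotation file,
#' monitored-pair CSV and a JSON manifest holding the full spec (seed
#' included) — sufficient to regenerate every file bit-identically.
#'
#' @param spec a `synthetic_spec`.
#' @param directory output directory (created if needed).
#' @return invisibly, the manifest as a list (with file paths and MD5 sums).
#' @export
write_fixture_bundle <- function(spec, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  ref <- make_reference(spec)
  trj <- make_trajectory(ref, spec)
  ann <- default_annotation(spec)
  prs <- default_pairs(spec)

  paths <- file.path(directory, c("reference.pdb", "trajectory.pdb",
                                  "annotation.txt", "pairs.csv"))
  names(paths) <- c("reference", "trajectory", "annotation", "pairs")
  write_structure_pdb(ref, paths["reference"])
  write_trajectory_pdb(trj, paths["trajectory"])
  writeLines(vapply(names(ann), function(nm)
    sprintf("%s: %s", nm, paste(ann[[nm]], collapse = ",")), character(1)),
    paths["annotation"])
  utils::write.csv(prs, paths["pairs"], row.names = FALSE)

  manifest <- list(
    generator = "ribonet", seed = spec$seed,
    spec = unclass(spec),
    files = as.list(stats::setNames(unname(tools::md5sum(paths)), names(paths)))
  )
  jsonlite::write_json(manifest, file.path(directory, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Rebuild a spec from a fixture-bundle manifest
#'
#' Refuses to regenerate when the manifest lacks the seed (the bundle would
#' not be reproducible).
#'
#' @param path path to a `manifest.json` written by [write_fixture_bundle()].
#' @return a `synthetic_spec`.
#' @export
spec_from_manifest <- function(path) {
  man <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(man$seed) || is.null(man$spec$seed))
    stopf("manifest lacks a seed; refusing to regenerate")
  s <- man$spec
  blocks <- s$correlation_blocks
  if (is.data.frame(blocks))
    blocks <- lapply(seq_len(nrow(blocks)), function(i)
      list(residues = unlist(blocks$residues[i]), rho = blocks$rho[i]))
  hb <- s$hbonds
  if (is.data.frame(hb))
    hb <- lapply(seq_len(nrow(hb)), function(i) as.list(hb[i, ]))
  synthetic_spec(
    n_residues = s$n_residues, n_frames = s$n_frames, sigma = s$sigma,
    jitter = s$jitter, correlation_blocks = blocks %||% list(),
    hbonds = hb %||% list(), drift = s$drift, fold = s$fold,
    anchors = s$anchors, anchor_sigma = s$anchor_sigma,
    modes = s$modes, seed = s$seed,
    template = as.data.frame(s$template, stringsAsFactors = FALSE)
  )
}
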