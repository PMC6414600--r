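# Geometric hydrogen-bond detection, occupancy, and pair distance statistics.

#' Geometric hydrogen-bond criterion
#'
#' A donor-acceptor pair is a hit in a frame when the distance between the two
#' polar heavy atoms is below `distance` AND the D-H...A arrangement deviates
#' from linearity by at most `angle` degrees (i.e. the D-H-A angle is at least
#' 180 - `angle`; at the defaults, >= 150 degrees). The distance cutoff
#' applies to the donor-acceptor heavy-atom distance, not H...A.
#'
#' @param distance heavy-atom distance cutoff in Angstrom (default 3.5).
#' @param angle maximum deviation from D-H-A linearity in degrees (default 30).
#' @return an `hbond_criterion` list.
#' @export
hbond_criterion <- function(distance = 3.5, angle = 30) {
  if (distance <= 0 || angle <= 0) stopf("H-bond cutoffs must be positive")
  structure(list(distance = distance, angle = angle), class = "hbond_criterion")
}

# Hydrogens covalently attached to a donor heavy atom: same residue, within
# `max_dh` Angstrom in the given coordinates (name-distance heuristic; PDB
# fixtures rarely carry explicit bonds).
donor_hydrogens <- function(structure, donor_idx, coords = NULL, max_dh = 1.25) {
  atom <- structure$atom
  m <- coords %||% vec2mat(structure$xyz)
  same_res <- which(atom$res_index == atom$res_index[donor_idx] &
                    is_hydrogen(atom))
  if (length(same_res) == 0) return(integer(0))
  d <- sqrt(rowSums((m[same_res, , drop = FALSE] -
                     matrix(m[donor_idx, ], length(same_res), 3, byrow = TRUE))^2))
  same_res[d <= max_dh]
}

#' Detect hydrogen bonds in a single frame
#'
#' @param coords n x 3 coordinate matrix for one frame.
#' @param donors data.frame with integer columns `d` (donor heavy atom index)
#'   and `h` (attached hydrogen index).
#' @param acceptors integer vector of acceptor atom indices.
#' @param criterion an [hbond_criterion()].
#' @return data.frame of hits with columns `donor`, `acceptor`.
#' @export
detect_hbonds_frame <- function(coords, donors, acceptors,
                                criterion = hbond_criterion()) {
  stopifnot(is.data.frame(donors), all(c("d", "h") %in% names(donors)))
  min_angle <- 180 - criterion$angle
  hits_d <- integer(0); hits_a <- integer(0)
  for (r in seq_len(nrow(donors))) {
    D <- coords[donors$d[r], ]; H <- coords[donors$h[r], ]
    for (a in acceptors) {
      if (a == donors$d[r] || a == donors$h[r]) next
      A <- coords[a, ]
      if (dist3(D, A) >= criterion$distance) next
      u <- D - H; v <- A - H
      ang <- acos(pmin(1, pmax(-1, sum(u * v) /
                               (sqrt(sum(u^2)) * sqrt(sum(v^2)))))) * 180 / pi
      if (ang >= min_angle) {
        hits_d <- c(hits_d, donors$d[r]); hits_a <- c(hits_a, a)
      }
    }
  }
  data.frame(donor = hits_d, acceptor = hits_a)
}

# Resolve a user pair table (donor_resno, donor_name, acceptor_resno,
# acceptor_name) to atom indices plus attached hydrogens.
resolve_pairs <- function(structure, pairs) {
  stopifnot(is.data.frame(pairs),
            all(c("donor_resno", "donor_name", "acceptor_resno",
                  "acceptor_name") %in% names(pairs)))
  atom <- structure$atom
  find1 <- function(resno, name, what, row) {
    i <- which(atom$resno == resno & trimws(atom$elety) == name)
    if (length(i) == 0)
      stopf("pair %d: cannot resolve %s atom %s of residue %s", row, what, name, resno)
    i[1]
  }
  out <- lapply(seq_len(nrow(pairs)), function(r) {
    d <- find1(pairs$donor_resno[r], pairs$donor_name[r], "donor", r)
    a <- find1(pairs$acceptor_resno[r], pairs$acceptor_name[r], "acceptor", r)
    h <- donor_hydrogens(structure, d)
    list(d = d, a = a, h = h,
         label = sprintf("%s%s:%s-%s%s:%s",
                         atom$resid[d], pairs$donor_resno[r], pairs$donor_name[r],
                         atom$resid[a], pairs$acceptor_resno[r], pairs$acceptor_name[r]))
  })
  out
}

#' Hydrogen-bond occupancy over a trajectory
#'
#' For each monitored donor/acceptor pair, the fraction of frames satisfying
#' the geometric criterion is reported as a percentage. A pair counts as a hit
#' in a frame if ANY hydrogen attached to the donor satisfies the angular
#' condition. Donors without an attached hydrogen are a definition error.
#'
#' @param trajectory a trajectory object.
#' @param pairs data.frame with columns donor_resno, donor_name,
#'   acceptor_resno, acceptor_name.
#' @param criterion an [hbond_criterion()].
#' @return data.frame with pair, frames_observed, occupancy (percent).
#' @export
hbond_occupancy <- function(trajectory, pairs, criterion = hbond_criterion()) {
  res <- resolve_pairs(trajectory$topology, pairs)
  xyz <- trajectory$xyz
  nf <- nrow(xyz)
  min_angle <- 180 - criterion$angle

  rows <- lapply(res, function(p) {
    if (length(p$h) == 0)
      stopf("donor atom of pair %s has no attached hydrogen", p$label)
    Dx <- xyz[, 3 * p$d - 2]; Dy <- xyz[, 3 * p$d - 1]; Dz <- xyz[, 3 * p$d]
    Ax <- xyz[, 3 * p$a - 2]; Ay <- xyz[, 3 * p$a - 1]; Az <- xyz[, 3 * p$a]
    dist_ok <- sqrt((Dx - Ax)^2 + (Dy - Ay)^2 + (Dz - Az)^2) < criterion$distance
    ang_ok <- rep(FALSE, nf)
    for (h in p$h) {
      Hx <- xyz[, 3 * h - 2]; Hy <- xyz[, 3 * h - 1]; Hz <- xyz[, 3 * h]
      ux <- Dx - Hx; uy <- Dy - Hy; uz <- Dz - Hz
      vx <- Ax - Hx; vy <- Ay - Hy; vz <- Az - Hz
      cosang <- (ux * vx + uy * vy + uz * vz) /
        (sqrt(ux^2 + uy^2 + uz^2) * sqrt(vx^2 + vy^2 + vz^2))
      ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
      ang_ok <- ang_ok | (ang >= min_angle)
    }
    hits <- sum(dist_ok & ang_ok)
    data.frame(pair = p$label, frames_observed = hits,
               occupancy = 100 * hits / nf)
  })
  do.call(rbind, rows)
}

#' Mean and SD of atom-pair distances over a trajectory
#'
#' @param trajectory a trajectory object.
#' @param pairs data.frame with columns a_resno, a_name, b_resno, b_name
#'   (any two atoms; no donor/acceptor role implied).
#' @return data.frame with pair, mean_dist, sd_dist (sample SD, Angstrom).
#' @export
distance_stats <- function(trajectory, pairs) {
  stopifnot(all(c("a_resno", "a_name", "b_resno", "b_name") %in% names(pairs)))
  atom <- trajectory$topology$atom
  xyz <- trajectory$xyz
  find1 <- function(resno, name, row) {
    i <- which(atom$resno == resno & trimws(atom$elety) == name)
    if (length(i) == 0)
      stopf("pair %d: cannot resolve atom %s of residue %s", row, name, resno)
    i[1]
  }
  rows <- lapply(seq_len(nrow(pairs)), function(r) {
    i <- find1(pairs$a_resno[r], pairs$a_name[r], r)
    j <- find1(pairs$b_resno[r], pairs$b_name[r], r)
    d <- sqrt((xyz[, 3 * i - 2] - xyz[, 3 * j - 2])^2 +
              (xyz[, 3 * i - 1] - xyz[, 3 * j - 1])^2 +
              (xyz[, 3 * i]     - xyz[, 3 * j])^2)
    data.frame(pair = sprintf("%s%s:%s-%s%s:%s",
                              atom$resid[i], pairs$a_resno[r], pairs$a_name[r],
                              atom$resid[j], pairs$b_resno[r], pairs$b_name[r]),
               mean_dist = mean(d),
               sd_dist = if (length(d) > 1) stats::sd(d) else 0)
  })
  do.call(rbind, rows)
}
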