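combine_models <- function(...) {
  atoms <- do.call(rbind, lapply(list(...), function(m) m$atoms))
  rownames(atoms) <- NULL
  structure_model(atoms, label = "complex", provenance = list(source = "memory"))
}

#' Buried interface area between a subunit and its N-k neighbour
#'
#' Computes the buried surface area of the N:N-k interface as the
#' half-difference `(SASA(A) + SASA(B) - SASA(A+B)) / 2` on the isolated pair
#' - the convention under which PISA-style "interface areas" are reported -
#' along with the unhalved difference (`buried_area_full`), since published
#' totals do not always state their convention. By default the pair is
#' evaluated context-free (no other subunits present); `context = TRUE`
#' evaluates both terms with all remaining filament subunits present.
#'
#' @param filament a `FilamentModel` containing subunits 0 and -offset_k, with
#'   radii assigned.
#' @param offset_k positive integer neighbour offset (interface N:N-k).
#' @param probe probe radius (Angstrom).
#' @param n_points sphere points per atom.
#' @param contact_cutoff heavy-atom distance (Angstrom) below which a residue
#'   pair is listed as contacting.
#' @param context include all other subunits as environment (default FALSE).
#' @param central index of the subunit taken as N (default 0). The pair is
#'   mapped back into the frame of subunit 0 before any area is computed, so
#'   results are exactly independent of which subunit is central.
#' @return An `InterfaceReport`: list with `offset_k`, `buried_area`,
#'   `buried_area_full`, `residue_pairs` (data frame), `n_points`, `probe`.
#' @export
buried_interface_area <- function(filament, offset_k, probe = 1.4,
                                  n_points = 960, contact_cutoff = 4.0,
                                  context = FALSE, central = 0) {
  stopifnot(inherits(filament, "FilamentModel"), offset_k >= 1)
  A <- get_subunit(filament, central)
  B <- get_subunit(filament, central - offset_k)
  if (central != 0) {
    back <- symmetry_operator(filament$params, -central)
    A <- apply_transform(A, back)
    B <- apply_transform(B, back)
  }
  if (context) {
    rest <- filament$subunits[!(names(filament$subunits) %in%
                                  as.character(c(central, central - offset_k)))]
    if (central != 0) {
      back <- symmetry_operator(filament$params, -central)
      rest <- lapply(rest, apply_transform, t = back)
    }
    env <- do.call(combine_models, rest)
    sa <- compute_sasa(combine_models(A, env), probe, n_points)
    sb <- compute_sasa(combine_models(B, env), probe, n_points)
    sab <- compute_sasa(combine_models(A, B, env), probe, n_points)
    na_ <- n_atoms(A); nb <- n_atoms(B)
    # restrict to the pair's own atoms so the environment cancels
    a_alone <- sum(sa$per_atom[seq_len(na_)])
    b_alone <- sum(sb$per_atom[seq_len(nb)])
    ab <- sum(sab$per_atom[seq_len(na_ + nb)])
    full <- a_alone + b_alone - ab
  } else {
    a_alone <- compute_sasa(A, probe, n_points)$total
    b_alone <- compute_sasa(B, probe, n_points)$total
    ab <- compute_sasa(combine_models(A, B), probe, n_points)$total
    full <- a_alone + b_alone - ab
  }
  full <- max(full, 0)
  pairs <- contacting_residue_pairs(A, B, contact_cutoff)
  structure(list(offset_k = as.integer(offset_k),
                 buried_area = full / 2, buried_area_full = full,
                 residue_pairs = pairs,
                 probe = probe, n_points = as.integer(n_points),
                 context = context),
            class = "InterfaceReport")
}

contacting_residue_pairs <- function(A, B, cutoff) {
  a <- A$atoms[A$atoms$element != "H", , drop = FALSE]
  b <- B$atoms[B$atoms$element != "H", , drop = FALSE]
  empty <- data.frame(res_a = character(0), res_b = character(0),
                      min_dist = numeric(0), stringsAsFactors = FALSE)
  if (nrow(a) == 0 || nrow(b) == 0) return(empty)
  d2 <- outer(a$x, b$x, "-")^2 + outer(a$y, b$y, "-")^2 + outer(a$z, b$z, "-")^2
  hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
  if (nrow(hit) == 0) return(empty)
  res_a <- paste0(a$res_name[hit[, 1]], a$res_seq[hit[, 1]])
  res_b <- paste0(b$res_name[hit[, 2]], b$res_seq[hit[, 2]])
  key <- paste(res_a, res_b)
  dmin <- sqrt(vapply(split(d2[hit], key), min, 0))
  first <- !duplicated(key)
  out <- data.frame(res_a = res_a[first], res_b = res_b[first],
                    min_dist = unname(dmin[key[first]]),
                    stringsAsFactors = FALSE)
  out[order(out$min_dist), , drop = FALSE]
}

#' Enumerate all subunit-subunit interfaces of a filament
#'
#' Evaluates the buried area for every neighbour offset `1..max_offset` and
#' keeps interfaces with at least `min_area` (a numerical-dust threshold,
#' surfaced in the report). Because a subunit contacts partners both above and
#' below, the per-pilin total is exactly twice the per-subunit total and the
#' partner count is twice the number of distinct interface classes.
#'
#' @param filament a `FilamentModel` spanning at least `-max_offset..max_offset`.
#' @param max_offset largest neighbour offset to test (default 9).
#' @param min_area minimum buried area (Angstrom^2) to call an interface
#'   present (default 10).
#' @param probe,n_points,contact_cutoff passed to [buried_interface_area()].
#' @return An `InterfaceSummary`: list with `interfaces` (list of
#'   `InterfaceReport`, sorted by descending area), `table` (data frame),
#'   `total_per_subunit`, `total_per_pilin`, `n_partners`, `min_area`.
#' @export
enumerate_interfaces <- function(filament, max_offset = 9, min_area = 10,
                                 probe = 1.4, n_points = 960,
                                 contact_cutoff = 4.0) {
  if (filament$k_range[1] > -max_offset || filament$k_range[2] < max_offset) {
    stop(sprintf("filament spans [%d, %d] but offsets through +/-%d are required",
                 filament$k_range[1], filament$k_range[2], max_offset))
  }
  reports <- lapply(seq_len(max_offset), function(k) {
    buried_interface_area(filament, k, probe, n_points, contact_cutoff)
  })
  areas <- vapply(reports, function(r) r$buried_area, 0)
  keep <- which(areas >= min_area)
  keep <- keep[order(areas[keep], decreasing = TRUE)]
  reports <- reports[keep]
  tab <- data.frame(
    offset_k = vapply(reports, function(r) r$offset_k, 0L),
    buried_area = vapply(reports, function(r) r$buried_area, 0),
    buried_area_full = vapply(reports, function(r) r$buried_area_full, 0),
    n_residue_pairs = vapply(reports, function(r) nrow(r$residue_pairs), 0L)
  )
  total <- sum(tab$buried_area)
  structure(list(interfaces = reports, table = tab,
                 total_per_subunit = total, total_per_pilin = 2 * total,
                 n_partners = 2L * nrow(tab), min_area = min_area),
            class = "InterfaceSummary")
}

#' @export
print.InterfaceSummary <- function(x, ...) {
  cat(sprintf("InterfaceSummary: %d interface classes, %.0f A^2 per subunit, %.0f A^2 per pilin, %d partners\n",
              nrow(x$table), x$total_per_subunit, x$total_per_pilin, x$n_partners))
  if (nrow(x$table) > 0) print(x$table, row.names = FALSE)
  invisible(x)
}

BASIC_N_ATOMS <- list(ARG = c("NE", "NH1", "NH2"), LYS = "NZ",
                      HIS = c("ND1", "NE2"))
ACIDIC_O_ATOMS <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))

#' Cross-subunit salt bridges at the N:N-k interface
#'
#' Reports every (Arg/Lys/His side-chain nitrogen) to (Asp/Glu carboxylate
#' oxygen) pair across the interface with a minimum N-O distance at or below
#' `cutoff` (default 4.0 Angstrom, a common convention; His is counted as
#' basic). Pairs are deduplicated to residue pairs keeping the minimal
#' distance; bridges are reported in both charge orientations (basic on
#' either subunit).
#'
#' @param filament a `FilamentModel`.
#' @param offset_k positive neighbour offset.
#' @param cutoff N-O distance cutoff (Angstrom).
#' @return data frame with `basic`, `acidic`, `basic_subunit`,
#'   `acidic_subunit`, `distance`, sorted by distance.
#' @export
find_salt_bridges <- function(filament, offset_k, cutoff = 4.0) {
  A <- get_subunit(filament, 0)
  B <- get_subunit(filament, -offset_k)
  one_dir <- function(basic_m, acidic_m, basic_lab, acidic_lab) {
    ba <- basic_m$atoms
    bi <- which(ba$res_name %in% names(BASIC_N_ATOMS) &
                  mapply(function(rn, an) an %in% BASIC_N_ATOMS[[rn]],
                         ba$res_name, ba$name))
    aa <- acidic_m$atoms
    ai <- which(aa$res_name %in% names(ACIDIC_O_ATOMS) &
                  mapply(function(rn, an) an %in% ACIDIC_O_ATOMS[[rn]],
                         aa$res_name, aa$name))
    if (length(bi) == 0 || length(ai) == 0) return(NULL)
    b <- ba[bi, ]; c_ <- aa[ai, ]
    d <- sqrt(outer(b$x, c_$x, "-")^2 + outer(b$y, c_$y, "-")^2 +
                outer(b$z, c_$z, "-")^2)
    hit <- which(d <= cutoff, arr.ind = TRUE)
    if (nrow(hit) == 0) return(NULL)
    data.frame(
      basic = paste0(b$res_name[hit[, 1]], b$res_seq[hit[, 1]]),
      acidic = paste0(c_$res_name[hit[, 2]], c_$res_seq[hit[, 2]]),
      basic_subunit = basic_lab, acidic_subunit = acidic_lab,
      distance = d[hit], stringsAsFactors = FALSE
    )
  }
  lab_n <- "N"; lab_nk <- sprintf("N-%d", offset_k)
  out <- rbind(one_dir(A, B, lab_n, lab_nk), one_dir(B, A, lab_nk, lab_n))
  if (is.null(out) || nrow(out) == 0) {
    return(data.frame(basic = character(0), acidic = character(0),
                      basic_subunit = character(0), acidic_subunit = character(0),
                      distance = numeric(0), stringsAsFactors = FALSE))
  }
  key <- paste(out$basic, out$basic_subunit, out$acidic, out$acidic_subunit)
  out <- out[order(out$distance), , drop = FALSE]
  out <- out[!duplicated(paste(out$basic, out$basic_subunit, out$acidic,
                               out$acidic_subunit)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

#' Backbone phi/psi dihedrals of a chain
#'
#' @param chain a single-chain `StructureModel` with backbone N, CA, C atoms.
#' @return data frame with `res_seq`, `res_name`, `phi`, `psi` (degrees; NA at
#'   termini or where backbone atoms are missing).
#' @export
backbone_dihedrals <- function(chain) {
  a <- chain$atoms
  if (length(unique(a$chain_id)) != 1) stop("expected a single chain")
  res_ids <- unique(a$res_seq)
  getat <- function(rs, nm) {
    i <- which(a$res_seq == rs & a$name == nm)
    if (length(i) == 0) return(NULL)
    c(a$x[i[1]], a$y[i[1]], a$z[i[1]])
  }
  n <- length(res_ids)
  phi <- psi <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    N <- getat(res_ids[i], "N"); CA <- getat(res_ids[i], "CA")
    C <- getat(res_ids[i], "C")
    if (is.null(N) || is.null(CA) || is.null(C)) next
    if (i > 1 && res_ids[i - 1] == res_ids[i] - 1) {
      Cp <- getat(res_ids[i - 1], "C")
      if (!is.null(Cp)) phi[i] <- dihedral_angle(Cp, N, CA, C)
    }
    if (i < n && res_ids[i + 1] == res_ids[i] + 1) {
      Nn <- getat(res_ids[i + 1], "N")
      if (!is.null(Nn)) psi[i] <- dihedral_angle(N, CA, C, Nn)
    }
  }
  first <- !duplicated(a$res_seq)
  data.frame(res_seq = res_ids,
             res_name = a$res_name[first][match(res_ids, a$res_seq[first])],
             phi = phi, psi = psi)
}

#' Helix/coil segmentation of a pilin chain
#'
#' Residues are classified helical when their backbone dihedrals fall in the
#' alpha window (phi in \[-100, -30\], psi in \[-80, -5\] degrees) in runs of
#' at least `min_run` residues - a dihedral-window assignment chosen over
#' hydrogen-bond (DSSP-style) assignment so no hydrogens are required.
#' The first helical run is reported as alpha1-N, the second as alpha1-C, and
#' the gap between them as the melted stretch (around the conserved Pro22 in
#' assembled major pilins).
#'
#' @param chain a single-chain `StructureModel` (>= 5 residues with backbone).
#' @param phi_window,psi_window numeric length-2 dihedral windows (degrees).
#' @param min_run minimum helical run length (residues).
#' @return A `HelixSegmentation`: list with `segments` (data frame start, end,
#'   class), `alpha1N`, `melted`, `alpha1C` (length-2 residue ranges or NULL).
#' @export
segment_helices <- function(chain, phi_window = c(-100, -30),
                            psi_window = c(-80, -5), min_run = 4) {
  dih <- backbone_dihedrals(chain)
  if (nrow(dih) < 5) stop("chain has fewer than 5 residues with backbone atoms")
  is_helix_res <- !is.na(dih$phi) & !is.na(dih$psi) &
    dih$phi >= phi_window[1] & dih$phi <= phi_window[2] &
    dih$psi >= psi_window[1] & dih$psi <= psi_window[2]
  r <- rle(is_helix_res)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  helical <- rep(FALSE, nrow(dih))
  for (j in seq_along(r$lengths)) {
    if (r$values[j] && r$lengths[j] >= min_run) {
      helical[starts[j]:ends[j]] <- TRUE
    }
  }
  r2 <- rle(helical)
  ends <- cumsum(r2$lengths); starts <- ends - r2$lengths + 1
  segments <- data.frame(
    start = dih$res_seq[starts], end = dih$res_seq[ends],
    class = ifelse(r2$values, "helix", "coil"), stringsAsFactors = FALSE
  )
  hseg <- segments[segments$class == "helix", , drop = FALSE]
  alpha1N <- if (nrow(hseg) >= 1) c(hseg$start[1], hseg$end[1]) else NULL
  alpha1C <- if (nrow(hseg) >= 2) c(hseg$start[2], hseg$end[2]) else NULL
  melted <- if (!is.null(alpha1N) && !is.null(alpha1C)) {
    c(alpha1N[2] + 1, alpha1C[1] - 1)
  } else NULL
  structure(list(segments = segments, alpha1N = alpha1N, melted = melted,
                 alpha1C = alpha1C, dihedrals = dih),
            class = "HelixSegmentation")
}
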