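#' Deterministic quasi-uniform sphere point set
#'
#' Fibonacci (golden-spiral) lattice on the unit sphere. Deterministic by
#' construction, so SASA values are exactly reproducible across runs and
#' platforms - a design choice over Monte Carlo point sets.
#'
#' @param n number of points (>= 1).
#' @return n x 3 matrix of unit vectors.
#' @export
fibonacci_sphere <- function(n) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 1
  z <- 1 - 2 * (i + 0.5) / n
  phi <- i * pi * (3 - sqrt(5))
  rho <- sqrt(pmax(0, 1 - z^2))
  cbind(x = rho * cos(phi), y = rho * sin(phi), z = z)
}

# neighbour candidate lists: for each atom, indices j with
# d_ij < (r_i + probe) + (r_j + probe). method "grid" bins atoms into a
# uniform spatial grid with cell edge 2 * (max radius + probe) and scans the
# 27 surrounding cells; contract: identical result to the all-pairs scan.
sasa_neighbours <- function(xyz, R, method = c("grid", "allpairs")) {
  method <- match.arg(method)
  n <- nrow(xyz)
  if (method == "allpairs" || n < 64) {
    return(lapply(seq_len(n), function(i) {
      d2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 +
        (xyz[, 3] - xyz[i, 3])^2
      j <- which(d2 < (R[i] + R)^2)
      j[j != i]
    }))
  }
  edge <- 2 * max(R)
  cell <- floor(sweep(xyz, 2, apply(xyz, 2, min)) / edge)
  key <- paste(cell[, 1], cell[, 2], cell[, 3])
  bykey <- split(seq_len(n), key)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  lapply(seq_len(n), function(i) {
    cand <- integer(0)
    for (o in seq_len(27)) {
      k <- paste(cell[i, 1] + offs[o, 1], cell[i, 2] + offs[o, 2],
                 cell[i, 3] + offs[o, 3])
      cand <- c(cand, bykey[[k]])
    }
    cand <- cand[cand != i]
    if (length(cand) == 0) return(integer(0))
    d2 <- (xyz[cand, 1] - xyz[i, 1])^2 + (xyz[cand, 2] - xyz[i, 2])^2 +
      (xyz[cand, 3] - xyz[i, 3])^2
    cand[d2 < (R[i] + R[cand])^2]
  })
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Numeric SASA: for every atom, the fraction of quasi-uniform points on its
#' probe-inflated sphere not inside any other inflated sphere, times
#' `4 * pi * (r + probe)^2`. The point set is a deterministic Fibonacci
#' lattice, so repeated runs agree bit for bit.
#'
#' @param model a `StructureModel` with radii assigned ([assign_radii()]).
#' @param probe probe radius in Angstrom (water: 1.4).
#' @param n_points sphere points per atom (>= 92; default 960).
#' @param method neighbour search, `"grid"` (default) or `"allpairs"`; both
#'   give identical areas.
#' @return An object of class `SasaResult`: list with `per_atom` (Angstrom^2
#'   vector), `per_residue` (data frame chain/res_seq/res_name/area), `total`,
#'   `probe_radius`, `n_points`.
#' @export
compute_sasa <- function(model, probe = 1.4, n_points = 960,
                         method = c("grid", "allpairs")) {
  method <- match.arg(method)
  stopifnot(inherits(model, "StructureModel"), probe >= 0, n_points >= 92)
  a <- model$atoms
  if (nrow(a) == 0) stop("empty model")
  if (anyNA(a$vdw_radius)) {
    stop("missing vdW radii for atoms ",
         paste(head(which(is.na(a$vdw_radius)), 5), collapse = ", "),
         "; run assign_radii() first")
  }
  xyz <- as.matrix(a[, c("x", "y", "z")])
  R <- a$vdw_radius + probe
  pts <- fibonacci_sphere(n_points)
  nbrs <- sasa_neighbours(xyz, R, method)
  per_atom <- vapply(seq_len(nrow(a)), function(i) {
    js <- nbrs[[i]]
    area_i <- 4 * pi * R[i]^2
    if (length(js) == 0) return(area_i)
    p <- pts * R[i]
    p[, 1] <- p[, 1] + xyz[i, 1]
    p[, 2] <- p[, 2] + xyz[i, 2]
    p[, 3] <- p[, 3] + xyz[i, 3]
    alive <- rep(TRUE, n_points)
    for (j in js) {
      if (!any(alive)) break
      d2 <- (p[alive, 1] - xyz[j, 1])^2 + (p[alive, 2] - xyz[j, 2])^2 +
        (p[alive, 3] - xyz[j, 3])^2
      alive[alive] <- d2 >= R[j]^2
    }
    area_i * sum(alive) / n_points
  }, 0)
  res_key <- paste(a$chain_id, a$res_seq, a$ins_code)
  agg <- rowsum(per_atom, res_key, reorder = FALSE)
  first <- !duplicated(res_key)
  per_residue <- data.frame(
    chain_id = a$chain_id[first], res_seq = a$res_seq[first],
    res_name = a$res_name[first], area = agg[, 1],
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(list(per_atom = per_atom, per_residue = per_residue,
                 total = sum(per_atom), probe_radius = probe,
                 n_points = as.integer(n_points)),
            class = "SasaResult")
}

#' @export
print.SasaResult <- function(x, ...) {
  cat(sprintf("SasaResult: total %.1f A^2 over %d atoms (probe %.2f A, %d points)\n",
              x$total, length(x$per_atom), x$probe_radius, x$n_points))
  invisible(x)
}
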