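#' Counter-based sub-seed derivation
#'
#' One root seed fans out to per-item sub-seeds so that changing the number
#' of generated items never reshuffles earlier ones. Values stay below 2^31.
#'
#' @param seed root integer seed.
#' @param i item counter (>= 1).
#' @return integer sub-seed.
#' @export
sub_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(i) * 7919) %% 2147483647)
}

#' Generate a toy pilin-like subunit
#'
#' A pseudo-pilin stand-in for structural tests: an ideal alpha-helix
#' (1.5 Angstrom rise and 100 degrees per residue, C-alpha plus one dummy
#' side-chain sphere per residue) whose axis runs along +z but drifts
#' radially outward with height, plus a globular cluster of pseudo-atoms at
#' a stated radial offset near the top - mimicking the core alpha1-helix /
#' surface globular-domain layout of a major pilin. Posed so that copies
#' under (twist 100.7 deg, rise 10 A) form contacting interfaces at several
#' neighbour offsets.
#'
#' @param seed integer seed (geometry is deterministic; the seed only
#'   perturbs nothing by default and is kept for interface uniformity).
#' @param helix_len helix length in residues (default 52).
#' @param globule_radius radius of the globular cluster (Angstrom; 0 for a
#'   helix-only subunit).
#' @param radial_offset radial distance of the globule centre from the
#'   filament axis (Angstrom).
#' @return A `StructureModel` with radii assigned.
#' @export
make_toy_subunit <- function(seed = 1, helix_len = 52, globule_radius = 8,
                             radial_offset = 11.5) {
  stopifnot(helix_len >= 5, globule_radius >= 0, radial_offset >= 0)
  j <- seq_len(helix_len)
  phi <- j * 100 * pi / 180
  zax <- (j - 1) * 1.5
  # helix column parallel to the filament axis at radius 7.5: close enough
  # that symmetry copies pack against each other at several offsets, far
  # enough that some offsets are reachable only through the globule
  rax <- 7.5
  ca <- data.frame(
    name = "CA", res_name = "ALA", chain_id = "A", res_seq = j,
    x = rax + 2.3 * cos(phi), y = 2.3 * sin(phi), z = zax,
    element = "C", stringsAsFactors = FALSE
  )
  cb <- data.frame(
    name = "CB", res_name = "ALA", chain_id = "A", res_seq = j,
    x = rax + 3.0 * cos(phi), y = 3.0 * sin(phi), z = zax + 0.8,
    element = "C", stringsAsFactors = FALSE
  )
  atoms <- rbind(ca, cb)
  if (globule_radius > 0) {
    centre <- c(radial_offset, 0, 1.5 * (helix_len - 1) - 10)
    shell <- fibonacci_sphere(42) * globule_radius
    inner <- fibonacci_sphere(12) * (globule_radius / 2)
    g <- rbind(shell, inner, c(0, 0, 0))
    gx <- centre[1] + g[, 1]; gy <- centre[2] + g[, 2]; gz <- centre[3] + g[, 3]
    # carve out globule pseudo-atoms that would interpenetrate the helix: the
    # globular domain decorates the helix top, it does not pass through it
    keep <- vapply(seq_along(gx), function(q) {
      min((atoms$x - gx[q])^2 + (atoms$y - gy[q])^2 + (atoms$z - gz[q])^2) > 2.0^2
    }, TRUE)
    if (any(keep)) {
      glob <- data.frame(
        name = "GC", res_name = "GLB", chain_id = "A",
        res_seq = helix_len + seq_len(sum(keep)),
        x = gx[keep], y = gy[keep], z = gz[keep],
        element = "C", stringsAsFactors = FALSE
      )
      atoms <- rbind(atoms, glob)
    }
  }
  m <- assign_radii(structure_model(atoms, label = "toy_subunit",
                                    provenance = list(source = "make_toy_subunit",
                                                      seed = seed)))
  d <- as.matrix(dist(m$atoms[, c("x", "y", "z")]))
  diag(d) <- Inf
  if (min(d) < 0.8) {
    stop("toy subunit parameters produce self-intersecting atoms (min distance ",
         round(min(d), 2), " A)")
  }
  m
}

#' Simulate 2D-equilibrium worm-like-chain traces
#'
#' The tangent angle performs a Gaussian random walk with per-step variance
#' `ds / Lp` (the planar-equilibrium convention, giving
#' `<cos theta(s)> = exp(-s / (2 Lp))`); positions follow by cumulative sum.
#' Each trace draws an independent sub-seed from the root seed.
#'
#' @param seed root integer seed.
#' @param lp_um true persistence length (micrometres).
#' @param contour_um contour length per trace (micrometres).
#' @param ds_nm discretization step (nm), must be < Lp.
#' @param n_traces number of traces.
#' @return list of `Trace2D`.
#' @export
simulate_wlc_traces <- function(seed, lp_um = 21, contour_um = 4, ds_nm = 10,
                                n_traces = 200) {
  lp_nm <- lp_um * 1000
  if (ds_nm >= lp_nm) stop("ds must be smaller than Lp for a valid discretization")
  stopifnot(contour_um > 0, n_traces >= 1)
  n_steps <- round(contour_um * 1000 / ds_nm)
  lapply(seq_len(n_traces), function(i) {
    set.seed(sub_seed(seed, i))
    theta0 <- runif(1, 0, 2 * pi)
    theta <- theta0 + cumsum(c(0, rnorm(n_steps - 1, 0, sqrt(ds_nm / lp_nm))))
    x <- c(0, cumsum(ds_nm * cos(theta)))
    y <- c(0, cumsum(ds_nm * sin(theta)))
    trace2d(x, y, pixel_size = ds_nm, label = sprintf("wlc%04d", i))
  })
}

#' Simulate AFM retraction force-distance curves
#'
#' Labelled synthetic curves of three kinds. `nanospring`: force rises
#' linearly with slope k from a contact point until rupture at F_adh, then
#' returns instantaneously to baseline. `plateau`: a steep grab is followed
#' by a constant-force plateau of the stated length, then rupture. `none`:
#' baseline only. Gaussian noise, a constant baseline offset and a linear
#' drift are superimposed; ground truth is attached to each curve as the
#' `truth` attribute. Defaults mirror the nanospring spring constant
#' (~5.5 pN/nm), spring rupture force (~120 pN) and plateau force (~220 pN)
#' characteristic of tightly packed T4aP measured at 1 um/s.
#'
#' @param seed root integer seed.
#' @param n number of curves.
#' @param mix named kind probabilities (`nanospring`, `plateau`, `none`).
#' @param k_mean,k_sd nanospring spring constant distribution (pN/nm).
#' @param f_adh_mean,f_adh_sd spring rupture force distribution (pN).
#' @param plateau_mean,plateau_sd plateau force distribution (pN).
#' @param plateau_len_mean,plateau_len_sd plateau length distribution (nm).
#' @param noise_sd Gaussian force noise (pN).
#' @param baseline_sd SD of the constant baseline offset (pN).
#' @param drift_max maximal |linear drift| (pN/nm).
#' @param ds distance sampling step (nm).
#' @param d_max curve length (nm).
#' @return list of `FDCurve`, each with a `truth` attribute list
#'   (`kind`, `k`, `f_adh`, `plateau_force`).
#' @export
simulate_fd_curves <- function(seed, n = 500,
                               mix = c(nanospring = 0.4, plateau = 0.3, none = 0.3),
                               k_mean = 5.5, k_sd = 0.5,
                               f_adh_mean = 120, f_adh_sd = 12,
                               plateau_mean = 220, plateau_sd = 20,
                               plateau_len_mean = 120, plateau_len_sd = 25,
                               noise_sd = 5, baseline_sd = 10,
                               drift_max = 0.005, ds = 1, d_max = 600) {
  params <- c(k_mean, k_sd, f_adh_mean, f_adh_sd, plateau_mean, plateau_sd,
              plateau_len_mean, plateau_len_sd, noise_sd, baseline_sd, drift_max,
              ds, d_max)
  if (any(params < 0)) stop("negative generator parameters are invalid")
  stopifnot(abs(sum(mix) - 1) < 1e-9, n >= 1)
  kinds <- names(mix)
  lapply(seq_len(n), function(i) {
    set.seed(sub_seed(seed, i))
    kind <- sample(kinds, 1, prob = mix)
    d <- seq(0, d_max, by = ds)
    sig <- numeric(length(d))
    truth <- list(kind = kind, k = NA_real_, f_adh = NA_real_,
                  plateau_force = NA_real_)
    if (kind == "nanospring") {
      k <- max(0.5, rnorm(1, k_mean, k_sd))
      fa <- max(40, rnorm(1, f_adh_mean, f_adh_sd))
      d0 <- round(runif(1, 30, 80) / ds) * ds
      # snap the rupture to the sampling grid so the drawn rupture force is
      # actually realized on the curve (otherwise truth would sit between
      # samples and be unrecoverable by construction)
      n_ext <- max(1, round(fa / k / ds))
      fa <- k * n_ext * ds
      on <- d >= d0 & d <= d0 + n_ext * ds
      sig[on] <- k * (d[on] - d0)
      truth$k <- k; truth$f_adh <- fa
    } else if (kind == "plateau") {
      fp <- max(60, rnorm(1, plateau_mean, plateau_sd))
      len <- max(60, rnorm(1, plateau_len_mean, plateau_len_sd))
      d0 <- runif(1, 30, 80)
      grab <- 30  # steep grab slope, pN/nm
      d1 <- d0 + fp / grab
      rise <- d >= d0 & d < d1
      sig[rise] <- grab * (d[rise] - d0)
      flat <- d >= d1 & d <= d1 + len
      sig[flat] <- fp
      truth$plateau_force <- fp
      truth$f_adh <- fp
    }
    offset <- rnorm(1, 0, baseline_sd)
    drift <- runif(1, -drift_max, drift_max)
    f <- sig + rnorm(length(d), 0, noise_sd) + offset + drift * d
    cv <- fd_curve(d, f, retract_speed = 1, label = sprintf("fd%04d", i))
    attr(cv, "truth") <- truth
    cv
  })
}

random_aa <- function(n, exclude = character(0)) {
  pool <- setdiff(setdiff(AA_ALPHABET, "X"), exclude)
  sample(pool, n, replace = TRUE)
}

rtrunc_norm_int <- function(n, mean, sd, lo, hi) {
  out <- integer(0)
  while (length(out) < n) {
    x <- round(rnorm(n, mean, sd))
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

#' Simulate a prepilin sequence set with taxonomy
#'
#' Each prepilin is a random signal peptide (5-30 aa ending in the Gly of
#' the cleavage motif) followed by a mature sequence
#' `F-x-x-x-E-...` of a target length drawn from a truncated normal
#' distribution (default mean 141, SD 25, range 42-297 aa). The conserved
#' Glu at mature position 5 is always present (it is part of the detection
#' motif); a conserved Pro at mature position 22 is planted at a
#' configurable frequency. Signal peptides are redrawn until the planted
#' motif is the first match, so every sequence cleaves at the planted index.
#' Optional near-duplicates (~97% identity) exercise the redundancy filter.
#'
#' @param seed root integer seed.
#' @param taxa data frame with columns `phylum`, `class`, `n` and optional
#'   `frac_large` (NA = natural fraction from the length distribution).
#' @param length_mean,length_sd,length_range mature-length distribution (aa).
#' @param large_threshold boundary used when `frac_large` is specified.
#' @param p22_freq planted frequency of Pro at mature position 22.
#' @param dup_rate fraction of extra near-duplicate sequences to append.
#' @return list with `records` (id, sequence, phylum, class), `taxonomy`
#'   (id, phylum, class), `truth` (planted cleavage index and mature length
#'   per id).
#' @export
simulate_prepilin_set <- function(seed,
                                  taxa = data.frame(
                                    phylum = c("Pseudomonadota", "Pseudomonadota",
                                               "Cyanobacteria", "Myxococcota"),
                                    class = c("Gammaproteobacteria",
                                              "Betaproteobacteria",
                                              "Cyanophyceae", "Myxococcia"),
                                    n = c(80, 40, 40, 40),
                                    frac_large = c(NA, 0.2, 0.23, 0.93)),
                                  length_mean = 141, length_sd = 25,
                                  length_range = c(42, 297),
                                  large_threshold = 166,
                                  p22_freq = 0.8, dup_rate = 0) {
  stopifnot(all(taxa$n >= 1), length_range[1] >= 30,
            length_range[2] > length_range[1])
  if (length_range[1] > length_range[2]) stop("infeasible length range")
  counter <- 0
  records <- list()
  truth <- list()
  make_one <- function(id, phylum, class_, want_large) {
    counter <<- counter + 1
    set.seed(sub_seed(seed, counter))
    L <- if (is.na(want_large)) {
      rtrunc_norm_int(1, length_mean, length_sd, length_range[1], length_range[2])
    } else if (want_large) {
      rtrunc_norm_int(1, max(length_mean, large_threshold + 10), length_sd,
                      large_threshold, length_range[2])
    } else {
      rtrunc_norm_int(1, min(length_mean, large_threshold - 20), length_sd,
                      length_range[1], large_threshold - 1)
    }
    for (attempt in 1:100) {
      sp_body <- paste(random_aa(sample(4:29, 1)), collapse = "")
      tail_len <- L - 5
      tail_res <- random_aa(tail_len)
      # mature position 22 = tail position 17 (after F x x x E)
      if (L >= 22 && runif(1) < p22_freq) tail_res[17] <- "P"
      mature <- paste0("F", paste(random_aa(3), collapse = ""), "E",
                       paste(tail_res, collapse = ""))
      seqn <- paste0(sp_body, "G", mature)
      hit <- detect_spiii(seqn)
      if (!is.null(hit) && hit$index == nchar(sp_body)) {
        return(list(seq = seqn, index = nchar(sp_body), mature_length = L))
      }
    }
    stop("could not place a unique cleavage motif; infeasible parameters")
  }
  for (t in seq_len(nrow(taxa))) {
    fl <- if (is.null(taxa$frac_large)) NA else taxa$frac_large[t]
    for (j in seq_len(taxa$n[t])) {
      id <- sprintf("%s_%03d", substr(taxa$class[t], 1, 4), j)
      want_large <- if (is.na(fl)) NA else {
        counter <- counter + 1
        set.seed(sub_seed(seed, counter))
        runif(1) < fl
      }
      one <- make_one(id, taxa$phylum[t], taxa$class[t], want_large)
      records[[id]] <- data.frame(id = id, sequence = one$seq,
                                  phylum = taxa$phylum[t], class = taxa$class[t],
                                  stringsAsFactors = FALSE)
      truth[[id]] <- list(index = one$index, mature_length = one$mature_length)
    }
  }
  rec <- do.call(rbind, records)
  rownames(rec) <- NULL
  if (dup_rate > 0) {
    n_dup <- round(dup_rate * nrow(rec))
    dups <- lapply(seq_len(n_dup), function(j) {
      counter <<- counter + 1
      set.seed(sub_seed(seed, counter))
      src <- rec[sample.int(nrow(rec), 1), ]
      chars <- strsplit(src$sequence, "")[[1]]
      hit <- detect_spiii(src$sequence)
      # mutate ~3% of positions well downstream of the motif
      mutable <- (hit$index + 8):length(chars)
      k <- max(1, round(0.03 * length(chars)))
      pos <- sample(mutable, min(k, length(mutable)))
      chars[pos] <- random_aa(length(pos))
      out <- src
      out$id <- paste0(src$id, "_dup", j)
      out$sequence <- paste(chars, collapse = "")
      truth[[out$id]] <<- list(index = hit$index,
                               mature_length = nchar(out$sequence) - hit$index - 1,
                               duplicate_of = src$id)
      out
    })
    rec <- rbind(rec, do.call(rbind, dups))
  }
  list(records = rec,
       taxonomy = rec[, c("id", "phylum", "class")],
       truth = truth)
}
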