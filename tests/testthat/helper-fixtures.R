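# Shared fixtures and independent oracles for the test suite.

# --- internal-coordinate (NeRF) backbone builder ---------------------------
# Places atom D given three predecessors A-B-C, the C-D bond length, the
# B-C-D angle (deg) and the A-B-C-D dihedral (deg). Used to build chains with
# exact phi/psi values, independently of any package geometry code.
place_atom <- function(A, B, C, bond, angle, dihedral) {
  ang <- angle * pi / 180
  dih <- -dihedral * pi / 180  # sign flip matches the IUPAC convention used
                               # by the package's dihedral measurement
  bc <- C - B
  bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(dih), bond * sin(ang) * sin(dih))
  C + d2[1] * bc + d2[2] * m + d2[3] * n
}

# Build an all-backbone (N, CA, C) chain with per-residue phi/psi (omega 180).
# Returns a StructureModel with author numbering starting at `first_res`.
build_backbone_chain <- function(phi, psi, first_res = 1, res_name = "ALA") {
  n_res <- length(phi)
  stopifnot(length(psi) == n_res)
  # standard backbone internal coordinates
  bN_CA <- 1.458; bCA_C <- 1.525; bC_N <- 1.329
  aN_CA_C <- 111.2; aCA_C_N <- 116.2; aC_N_CA <- 121.7
  coords <- list()
  # seed the first three atoms arbitrarily but consistently
  N1 <- c(0, 0, 0)
  CA1 <- c(bN_CA, 0, 0)
  C1 <- CA1 + c(-bCA_C * cos(aN_CA_C * pi / 180),
                bCA_C * sin(aN_CA_C * pi / 180), 0)
  coords[[1]] <- list(N = N1, CA = CA1, C = C1)
  for (i in 2:n_res) {
    prev <- coords[[i - 1]]
    Ni <- place_atom(prev$N, prev$CA, prev$C, bC_N, aCA_C_N, psi[i - 1])
    CAi <- place_atom(prev$CA, prev$C, Ni, bN_CA, aC_N_CA, 180)  # omega
    Ci <- place_atom(prev$C, Ni, CAi, bCA_C, aN_CA_C, phi[i])
    coords[[i]] <- list(N = Ni, CA = CAi, C = Ci)
  }
  rows <- do.call(rbind, lapply(seq_len(n_res), function(i) {
    at <- coords[[i]]
    data.frame(name = c("N", "CA", "C"),
               res_name = res_name, chain_id = "A",
               res_seq = first_res + i - 1,
               x = c(at$N[1], at$CA[1], at$C[1]),
               y = c(at$N[2], at$CA[2], at$C[2]),
               z = c(at$N[3], at$CA[3], at$C[3]),
               element = c("N", "C", "C"), stringsAsFactors = FALSE)
  }))
  structure_model(rows, label = "synthetic backbone")
}

# --- brute-force global-alignment identity oracle --------------------------
# Plain Needleman-Wunsch with linear gap penalty; returns
# matches / alignment columns via traceback. Independent of Biostrings.
nw_identity <- function(a, b, match = 1, mismatch = 0, gap = -1) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  S <- matrix(0, n + 1, m + 1)
  S[, 1] <- gap * (0:n)
  S[1, ] <- gap * (0:m)
  for (i in 1:n) {
    for (j in 1:m) {
      sub <- S[i, j] + if (A[i] == B[j]) match else mismatch
      S[i + 1, j + 1] <- max(sub, S[i, j + 1] + gap, S[i + 1, j] + gap)
    }
  }
  i <- n; j <- m; matches <- 0; cols <- 0
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        S[i + 1, j + 1] == S[i, j] + (if (A[i] == B[j]) match else mismatch)) {
      matches <- matches + (A[i] == B[j])
      i <- i - 1; j <- j - 1
    } else if (i > 0 && S[i + 1, j + 1] == S[i, j + 1] + gap) {
      i <- i - 1
    } else {
      j <- j - 1
    }
    cols <- cols + 1
  }
  matches / cols
}

# random rigid rotation from a seed (QR of a Gaussian matrix, det +1)
random_rotation <- function(seed) {
  set.seed(seed)
  qr_dec <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_dec)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# small all-carbon model from explicit coordinates
point_model <- function(xyz, chain_id = "A") {
  structure_model(data.frame(
    name = "C", res_name = "PNT", chain_id = chain_id,
    res_seq = seq_len(nrow(xyz)),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    element = "C", stringsAsFactors = FALSE
  ))
}

minimal_pdb_lines <- function() {
  c("HEADER    TEST",
    "ATOM      1  CA  ALA A   1      11.104  13.207   2.100  1.00  0.00           C",
    "END")
}
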