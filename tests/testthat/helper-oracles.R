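# Independent brute-force oracles and fixture builders shared by the unit
# and acceptance tests. Everything here is deliberately written from the
# rules themselves (position-by-position, all-pairs, grid search), not by
# calling the package's implementations.

AA20 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL")
AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
         "F", "P", "S", "T", "W", "Y", "V")

BACKBONE_NAMES <- c("N", "CA", "C", "O", "OXT")
APOLAR_SET <- c("ALA", "VAL", "LEU", "ILE", "PRO", "PHE", "MET", "TRP", "TYR")
RING_SETS <- list(
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2"),
  TRP = c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2")
)

# ---- structure builders ----------------------------------------------------

# build a papp_structure from a data.frame with columns
# res, resn, name, elem, x, y, z (chain A, one model)
build_toy <- function(df, chain = "A") {
  atoms <- data.frame(
    chain = chain, res_index = df$res, res_name = df$resn,
    atom_name = df$name, element = df$elem,
    het = df$resn %in% c("HOH", "ZN"), stringsAsFactors = FALSE)
  new_structure(atoms, as.matrix(df[, c("x", "y", "z")]),
                source_id = "toy")
}

atom_df <- function(res, resn, name, elem, x, y, z) {
  data.frame(res = res, resn = resn, name = name, elem = elem,
             x = x, y = y, z = z, stringsAsFactors = FALSE)
}

# random toy structure exercising all three detectors: clustered backbone
# plus side-chain atoms (apolar carbons, polar N/O, full aromatic rings)
random_toy_structure <- function(n_res = 25, seed = 1, box = 18) {
  set.seed(seed)
  rows <- NULL
  for (i in seq_len(n_res)) {
    resn <- sample(AA20, 1)
    c0 <- runif(3, 0, box)
    jit <- function() c0 + runif(3, -0.8, 0.8)
    for (nm in c("N", "CA", "C", "O")) {
      el <- substr(nm, 1, 1)
      p <- jit()
      rows <- rbind(rows, atom_df(i, resn, nm, el, p[1], p[2], p[3]))
    }
    if (resn %in% names(RING_SETS)) {
      ring <- RING_SETS[[resn]]
      cen <- c0 + runif(3, -1.5, 1.5)
      u <- rnorm(3); u <- u / sqrt(sum(u^2))
      v <- c(-u[2], u[1], 0)
      if (sqrt(sum(v^2)) < 1e-6) v <- c(1, 0, 0)
      v <- v / sqrt(sum(v^2))
      w <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
             u[1] * v[2] - u[2] * v[1])
      th <- 2 * pi * (seq_along(ring) - 1) / length(ring)
      for (q in seq_along(ring)) {
        p <- cen + 1.39 * (cos(th[q]) * v + sin(th[q]) * w)
        rows <- rbind(rows, atom_df(i, resn, ring[q],
                                    substr(ring[q], 1, 1), p[1], p[2], p[3]))
      }
    } else if (resn %in% c(APOLAR_SET, "LYS")) {
      p <- jit()
      rows <- rbind(rows, atom_df(i, resn, "CB", "C", p[1], p[2], p[3]))
    } else if (resn %in% c("SER", "THR", "ASN", "ASP", "GLN", "GLU", "ARG")) {
      p <- jit()
      nm <- sample(c("OG", "OD1", "ND2", "NE"), 1)
      rows <- rbind(rows, atom_df(i, resn, nm, substr(nm, 1, 1),
                                  p[1], p[2], p[3]))
    }
  }
  build_toy(rows)
}

# ---- rotations -------------------------------------------------------------

rot_z <- function(a) matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0,
                              0, 0, 1), 3, 3, byrow = TRUE)
rot_y <- function(b) matrix(c(cos(b), 0, sin(b), 0, 1, 0,
                              -sin(b), 0, cos(b)), 3, 3, byrow = TRUE)
euler_rot <- function(a, b, c) rot_z(a) %*% rot_y(b) %*% rot_z(c)

random_rigid <- function() {
  list(R = euler_rot(runif(1, 0, 2 * pi), runif(1, 0, pi),
                     runif(1, 0, 2 * pi)),
       t = runif(3, -30, 30))
}

# ---- motif oracle ----------------------------------------------------------

# greedy left-to-right position-by-position check of H-[EQ]-x-x-H-x-x-G-x-x-H
oracle_motif_starts <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  if (n < 11) return(integer(0))
  i <- seq_len(n - 10)
  cand <- ch[i] == "H" & (ch[i + 1] == "E" | ch[i + 1] == "Q") &
    ch[i + 4] == "H" & ch[i + 7] == "G" & ch[i + 10] == "H"
  starts <- integer(0)
  nxt <- 1
  for (s in which(cand)) {
    if (s >= nxt) {
      starts <- c(starts, s)
      nxt <- s + 11
    }
  }
  starts
}

# ---- detector oracles (all-pairs double loops) -----------------------------

edge_key <- function(df) {
  if (is.null(df) || nrow(df) == 0) return(character(0))
  sort(sprintf("%s|%s|%s|%.5f", df$res_a, df$res_b, df$kind, df$distance))
}

oracle_hbonds <- function(s, cutoff = 3.5) {
  a <- s$atoms
  x <- s$coords[, , 1]
  keep <- which(!a$het & a$element %in% c("N", "O"))
  out <- NULL
  for (ii in seq_along(keep)) {
    for (jj in seq_len(ii - 1)) {
      i <- keep[ii]; j <- keep[jj]
      if (a$res_index[i] == a$res_index[j]) next
      d <- sqrt(sum((x[i, ] - x[j, ])^2))
      if (d > cutoff) next
      if (abs(a$res_index[i] - a$res_index[j]) <= 1 &&
          a$atom_name[i] %in% BACKBONE_NAMES &&
          a$atom_name[j] %in% BACKBONE_NAMES) next
      out <- rbind(out, data.frame(
        res_a = min(a$res_index[i], a$res_index[j]),
        res_b = max(a$res_index[i], a$res_index[j]),
        kind = "hbond", distance = d))
    }
  }
  out
}

oracle_hydrophobic <- function(s, cutoff = 4.5) {
  a <- s$atoms
  x <- s$coords[, , 1]
  is_apolar <- (!a$het) & a$element == "C" &
    !(a$atom_name %in% BACKBONE_NAMES) &
    (a$res_name %in% APOLAR_SET |
       (a$res_name == "LYS" & a$atom_name %in% c("CB", "CG", "CD")))
  keep <- which(is_apolar)
  out <- NULL
  for (ii in seq_along(keep)) {
    for (jj in seq_len(ii - 1)) {
      i <- keep[ii]; j <- keep[jj]
      if (abs(a$res_index[i] - a$res_index[j]) <= 1) next
      d <- sqrt(sum((x[i, ] - x[j, ])^2))
      if (d > cutoff) next
      out <- rbind(out, data.frame(
        res_a = min(a$res_index[i], a$res_index[j]),
        res_b = max(a$res_index[i], a$res_index[j]),
        kind = "hydrophobic", distance = d))
    }
  }
  out
}

oracle_pipi <- function(s, cutoff = 6.0) {
  a <- s$atoms
  x <- s$coords[, , 1]
  cents <- NULL
  for (rn in names(RING_SETS)) {
    for (r in unique(a$res_index[a$res_name == rn & !a$het])) {
      rows <- which(a$res_index == r & a$res_name == rn &
                      a$atom_name %in% RING_SETS[[rn]])
      if (length(rows) < length(RING_SETS[[rn]]) - 1) next
      cents <- rbind(cents, data.frame(res = r,
                                       t(colMeans(x[rows, , drop = FALSE]))))
    }
  }
  out <- NULL
  if (is.null(cents) || nrow(cents) < 2) return(out)
  for (ii in seq_len(nrow(cents) - 1)) {
    for (jj in seq(ii + 1, nrow(cents))) {
      if (cents$res[ii] == cents$res[jj]) next
      d <- sqrt(sum((as.numeric(cents[ii, -1]) -
                       as.numeric(cents[jj, -1]))^2))
      if (d > cutoff) next
      out <- rbind(out, data.frame(
        res_a = min(cents$res[ii], cents$res[jj]),
        res_b = max(cents$res[ii], cents$res[jj]),
        kind = "pipi", distance = d))
    }
  }
  out
}

# ---- superposition oracle --------------------------------------------------

# minimum RMSD over proper rotations: coarse Euler grid + Nelder-Mead polish
oracle_min_rmsd <- function(P, Q, n_grid = 14) {
  Pc <- sweep(P, 2, colMeans(P))
  Qc <- sweep(Q, 2, colMeans(Q))
  f <- function(ang) {
    R <- euler_rot(ang[1], ang[2], ang[3])
    sqrt(mean(rowSums((Pc %*% t(R) - Qc)^2)))
  }
  best <- c(0, 0, 0); bv <- f(best)
  for (a in seq(0, 2 * pi, length.out = n_grid)) {
    for (b in seq(0, pi, length.out = ceiling(n_grid / 2))) {
      for (cc in seq(0, 2 * pi, length.out = n_grid)) {
        v <- f(c(a, b, cc))
        if (v < bv) { bv <- v; best <- c(a, b, cc) }
      }
    }
  }
  opt <- stats::optim(best, f, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 2000))
  min(bv, opt$value)
}
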