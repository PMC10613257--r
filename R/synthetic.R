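# Synthetic fixtures with known ground truth: toy metzincin enzymes with a
# planted active site and interaction path, and two-domain "dumbbell"
# trajectories driven by a hidden two-state Markov chain.
#
# The structures are geometric, not stereochemically valid: side-chain atoms
# are placed wherever the planted interaction requires, since every detector
# in this package uses distances only. They must not be mistaken for
# physically realistic models.

#' Default planted interaction path
#'
#' A five-link residue chain (hydrophobic, H-bond, pi-pi stack, hydrophobic,
#' H-bond) ending on the motif's first histidine, which coordinates the
#' zinc - six edges distal-residue-to-zinc in total, emulating the patch
#' architecture that couples a distal mutation site to the active site.
#'
#' @param motif_start mature index of the motif's first His.
#' @param distal_start index of the distal residue the path starts from.
#' @return data.frame with columns `res_a`, `res_b`, `kind`.
#' @export
default_path_spec <- function(motif_start = 10, distal_start = 30) {
  r <- distal_start + c(0, 2, 4, 6, 8)
  data.frame(
    res_a = r,
    res_b = c(r[-1], motif_start),
    kind = c("hydrophobic", "hbond", "pipi", "hydrophobic", "hbond"),
    stringsAsFactors = FALSE
  )
}

#' Specification for a synthetic toy enzyme
#'
#' @param n_residues chain length (default 40).
#' @param motif_start index of the motif's first His (default 10).
#' @param plant_water place a catalytic water 2.3 A from the zinc plus a
#'   tyrosine hydroxyl 2.9 A from the water.
#' @param plant_met_turn place a Met side-chain sulfur 5 A from the zinc
#'   inside the downstream search window.
#' @param catalytic_mutant use Gln instead of Glu at the motif's second
#'   position (an E-to-Q dead mutant).
#' @param path_spec data.frame of planted interactions (`res_a`, `res_b`,
#'   `kind` in hbond/hydrophobic/pipi); the last `res_b` must be a motif
#'   histidine so the path reaches the zinc. `NULL` for no path.
#' @param seed integer seed (outputs are byte-identical given the seed).
#' @return An object of class `enzyme_spec`.
#' @export
enzyme_spec <- function(n_residues = 40, motif_start = 10,
                        plant_water = TRUE, plant_met_turn = TRUE,
                        catalytic_mutant = FALSE,
                        path_spec = default_path_spec(motif_start),
                        seed = 1) {
  if (motif_start < 1 || motif_start + 10 > n_residues) {
    stop("motif does not fit inside the sequence")
  }
  his_res <- motif_start + c(0L, 4L, 10L)
  tyr_res <- motif_start + 12L
  met_res <- motif_start + 15L
  if (plant_met_turn && met_res > n_residues) {
    stop("no room for the Met-turn residue")
  }
  if (plant_water && tyr_res > n_residues) {
    stop("no room for the water-bonded tyrosine")
  }
  if (!is.null(path_spec) && nrow(path_spec) > 0) {
    stopifnot(all(c("res_a", "res_b", "kind") %in% names(path_spec)))
    if (!all(path_spec$kind %in% c("hbond", "hydrophobic", "pipi"))) {
      stop("path kinds must be hbond, hydrophobic or pipi")
    }
    pr <- unique(c(path_spec$res_a, path_spec$res_b))
    if (any(pr < 1 | pr > n_residues)) stop("path residues outside sequence")
    if (!path_spec$res_b[nrow(path_spec)] %in% his_res) {
      stop("the path must end on a motif histidine to reach the zinc")
    }
    inner <- setdiff(pr, his_res)
    clash <- intersect(inner, c(motif_start + 0:10,
                                if (plant_water) tyr_res,
                                if (plant_met_turn) met_res))
    if (length(clash) > 0) {
      stop("path residues collide with motif/water/Met-turn residues: ",
           paste(clash, collapse = ","))
    }
  }
  structure(
    list(n_residues = as.integer(n_residues),
         motif_start = as.integer(motif_start),
         his_res = his_res, tyr_res = tyr_res, met_res = met_res,
         plant_water = plant_water, plant_met_turn = plant_met_turn,
         catalytic_mutant = catalytic_mutant,
         path_spec = path_spec, seed = as.integer(seed)),
    class = "enzyme_spec"
  )
}

# hexagon / pentagon of ring atoms around a centroid in the z = const plane
.ring_coords <- function(center, n_atoms, radius) {
  th <- 2 * pi * (seq_len(n_atoms) - 1) / n_atoms
  cbind(center[1] + radius * cos(th), center[2] + radius * sin(th),
        center[3])
}

#' Generate a toy metzincin enzyme with known ground truth
#'
#' Builds a chemically naive but geometrically exact single-chain structure:
#' a spaced backbone trace, the HEXXHXXGXXH motif with the three His
#' side-chain nitrogens 2.1 A from a planted zinc, an optional catalytic
#' water (2.3 A from Zn, 2.9 A from a Tyr hydroxyl), an optional Met-turn
#' sulfur 5 A from the zinc, and one explicitly placed atom pair (or ring
#' pair) per planted interaction, each satisfying exactly its intended
#' detector at default cutoffs. The construction is verified internally:
#' generation fails if any detector sees more or fewer edges than planted,
#' or if atoms from different residues clash below 1.5 A.
#'
#' @param spec an [enzyme_spec()].
#' @return list with `structure` (a `papp_structure`) and `truth` (motif
#'   position, His residues, zinc coordinates, water/Met-turn records,
#'   planted edges and the planted path node sequence ending in `"zinc"`).
#' @export
make_enzyme <- function(spec = enzyme_spec()) {
  stopifnot(inherits(spec, "enzyme_spec"))
  set.seed(spec$seed)
  n <- spec$n_residues
  m <- spec$motif_start

  res_names <- rep("GLY", n)
  res_names[m + 0:10] <- c("HIS", if (spec$catalytic_mutant) "GLN" else "GLU",
                           "ALA", "ALA", "HIS", "ALA", "ALA", "GLY",
                           "ALA", "ALA", "HIS")
  if (spec$plant_water) res_names[spec$tyr_res] <- "TYR"
  if (spec$plant_met_turn) res_names[spec$met_res] <- "MET"

  rows <- list()
  used <- vector("list", n)  # atom names consumed per residue
  add_atom <- function(res, name, element, xyz, res_name = NULL,
                       het = FALSE) {
    if (res <= n && name %in% used[[res]]) {
      stop("infeasible placement: atom ", name, " of residue ", res,
           " needed twice")
    }
    if (res <= n) used[[res]] <<- c(used[[res]], name)
    rows[[length(rows) + 1]] <<- list(
      chain = "A", res_index = res,
      res_name = if (is.null(res_name)) res_names[res] else res_name,
      atom_name = name, element = element, het = het,
      x = xyz[1], y = xyz[2], z = xyz[3])
  }

  # backbone trace: 6 A CA spacing keeps non-planted residues out of every
  # detector's reach (i/i+1 backbone contacts are excluded by rule)
  for (i in seq_len(n)) {
    ca <- c(6 * (i - 1), 0, 0)
    add_atom(i, "N", "N", ca + c(-1.4, 0.8, 0))
    add_atom(i, "CA", "C", ca)
    add_atom(i, "C", "C", ca + c(1.4, 0.8, 0))
    add_atom(i, "O", "O", ca + c(1.4, 2.0, 0))
  }

  # zinc site below the motif's middle His
  zn <- c(6 * (m + 3), -25, 0)
  dirs <- rbind(c(0, 1, 0),
                c(-sqrt(3) / 2, -0.5, 0),
                c(sqrt(3) / 2, -0.5, 0))
  for (k in 1:3) {
    add_atom(spec$his_res[k], "NE2", "N", zn + 2.1 * dirs[k, ])
    add_atom(spec$his_res[k], "CB", "C", zn + 4.5 * dirs[k, ])
  }
  add_atom(n + 1L, "ZN", "ZN", zn, res_name = "ZN", het = TRUE)
  if (spec$plant_water) {
    w <- zn + c(0, 0, 2.3)
    add_atom(n + 2L, "O", "O", w, res_name = "HOH", het = TRUE)
    add_atom(spec$tyr_res, "OH", "O", w + c(0, 0, 2.9))
  }
  if (spec$plant_met_turn) {
    add_atom(spec$met_res, "SD", "S", zn + c(0, -5, 0))
  }

  # planted interactions: one well-separated site per edge, atoms placed to
  # satisfy the intended detector's default cutoff and no other
  planted <- NULL
  ps <- spec$path_spec
  if (!is.null(ps) && nrow(ps) > 0) {
    o_pool <- c("OD1", "OE1", "OG", "OD2")
    n_pool <- c("ND2", "NZ", "NH1", "NH2")
    c_pool <- c("CB", "CG1", "CG2", "CE")
    lys_pool <- c("CB", "CG", "CD")
    pick <- function(res, pool) {
      free <- setdiff(pool, used[[res]])
      if (length(free) == 0) {
        stop("infeasible placement: no free atom name for residue ", res)
      }
      free[1]
    }
    need_name <- function(res, ok_names, fallback) {
      if (!res_names[res] %in% ok_names) {
        if (res_names[res] %in% c("GLY", "ALA")) {
          res_names[res] <<- fallback
        } else {
          stop("infeasible placement: residue ", res, " is ",
               res_names[res], " but the edge needs one of ",
               paste(ok_names, collapse = "/"))
        }
      }
    }
    for (k in seq_len(nrow(ps))) {
      a <- ps$res_a[k]; b <- ps$res_b[k]; kind <- ps$kind[k]
      site <- c(15 * k, 25, 0)
      if (kind == "hbond") {
        add_atom(a, pick(a, o_pool), "O", site + c(-1.45, 0, 0))
        add_atom(b, pick(b, n_pool), "N", site + c(1.45, 0, 0))
        d <- 2.9
      } else if (kind == "hydrophobic") {
        if (abs(a - b) <= 1) {
          stop("hydrophobic edges between sequence neighbours are excluded")
        }
        need_name(a, c(.APOLAR_RES, "LYS"), "ALA")
        need_name(b, c(.APOLAR_RES, "LYS"), "ALA")
        pa <- if (res_names[a] == "LYS") lys_pool else c_pool
        pb <- if (res_names[b] == "LYS") lys_pool else c_pool
        add_atom(a, pick(a, pa), "C", site + c(-2, 0, 0))
        add_atom(b, pick(b, pb), "C", site + c(2, 0, 0))
        d <- 4.0
      } else {  # pipi
        need_name(a, c("PHE", "TYR", "TRP"), "PHE")
        need_name(b, c("PHE", "TYR", "TRP"), "PHE")
        for (side in 1:2) {
          r <- c(a, b)[side]
          cen <- site + c(0, 0, c(-2.4, 2.4)[side])
          ring <- .RING_ATOMS[[res_names[r]]]
          xyz <- .ring_coords(cen, length(ring), 1.39)
          for (q in seq_along(ring)) {
            add_atom(r, ring[q], substr(ring[q], 1, 1), xyz[q, ])
          }
        }
        d <- 4.8
      }
      planted <- rbind(planted, data.frame(
        res_a = min(a, b), res_b = max(a, b), kind = kind, distance = d,
        stringsAsFactors = FALSE))
    }
  }

  tab <- do.call(rbind, lapply(rows, as.data.frame))
  # res_name may have been upgraded (GLY -> ALA/PHE) after backbone placement
  poly <- tab$res_index <= n
  tab$res_name[poly] <- res_names[tab$res_index[poly]]
  atoms <- tab[, c("chain", "res_index", "res_name", "atom_name", "element",
                   "het")]
  coords <- as.matrix(tab[, c("x", "y", "z")])
  s <- new_structure(atoms, coords, source_id = "synthetic toy enzyme")

  # ---- internal verification: planted geometry is exactly what detectors see
  dm <- as.matrix(stats::dist(coords))
  diag(dm) <- Inf
  same_res <- outer(tab$res_index, tab$res_index, "==")
  if (min(dm[!same_res]) < 1.5) {
    stop("infeasible placement: cross-residue clash below 1.5 A")
  }
  seq <- extract_sequence(s, "A")
  hits <- scan_metzincin_motif(seq)
  if (nrow(hits) != 1 || hits$start != m) {
    stop("generation self-check failed: motif not unique at ", m)
  }
  detected <- rbind(detect_hbonds(s), detect_hydrophobic(s), detect_pipi(s))
  key <- function(df) {
    if (is.null(df) || nrow(df) == 0) return(character(0))
    sort(paste(df$res_a, df$res_b, df$kind))
  }
  if (!identical(key(detected), key(planted))) {
    stop("generation self-check failed: detected edges differ from planted\n",
         "detected: ", paste(key(detected), collapse = " "), "\n",
         "planted:  ", paste(key(planted), collapse = " "))
  }
  site <- validate_zinc_site(s, hits[1, ])
  if (!site$validated) stop("generation self-check failed: zinc site invalid")
  if (spec$plant_water != !is.null(site$catalytic_water)) {
    stop("generation self-check failed: water presence mismatch")
  }

  path_nodes <- NULL
  if (!is.null(ps) && nrow(ps) > 0) {
    path_nodes <- c(as.character(c(ps$res_a[1], ps$res_b)), "zinc")
  }
  truth <- list(
    motif_start = m, his_res = spec$his_res, glu_res = m + 1L,
    zinc_coord = zn,
    catalytic_water = spec$plant_water,
    tyr_res = if (spec$plant_water) spec$tyr_res else NULL,
    met_turn = if (spec$plant_met_turn) {
      list(res_index = spec$met_res, distance = 5.0)
    } else NULL,
    planted_edges = planted,
    path_nodes = path_nodes,
    sequence = as.character(seq)
  )
  list(structure = s, truth = truth)
}

#' Specification for a synthetic two-domain dumbbell trajectory
#'
#' The inter-domain separation follows a hidden two-state (closed/open)
#' Markov chain with Gaussian jitter; default parameters mirror the
#' M1-M2 regime: closed 54 A, open 63 A, 2 A jitter, stationary open
#' occupancy 0.8, frames 0.1 ns apart.
#'
#' @param atoms_per_domain C-alpha count per rigid domain (default 30).
#' @param closed_mean,open_mean state separations in Angstrom
#'   (`open_mean > closed_mean > 0`).
#' @param jitter_sd Gaussian jitter of the separation, Angstrom.
#' @param transition_probs 2 x 2 row-stochastic matrix, rows/cols ordered
#'   (closed, open).
#' @param n_frames frame count.
#' @param frame_spacing ns between frames.
#' @param start_state `"closed"` or `"open"`.
#' @param random_rigid apply an independent random rigid-body transform to
#'   every frame (on by default so invariance bugs surface in routine
#'   tests).
#' @param seed integer seed.
#' @return An object of class `dumbbell_spec`.
#' @export
dumbbell_spec <- function(atoms_per_domain = 30, closed_mean = 54,
                          open_mean = 63, jitter_sd = 2,
                          transition_probs = matrix(c(0.96, 0.04, 0.01, 0.99),
                                                    2, 2, byrow = TRUE),
                          n_frames = 5000, frame_spacing = 0.1,
                          start_state = c("closed", "open"),
                          random_rigid = TRUE, seed = 1) {
  start_state <- match.arg(start_state)
  if (!(open_mean > closed_mean && closed_mean > 0)) {
    stop("need open_mean > closed_mean > 0")
  }
  if (jitter_sd < 0) stop("jitter_sd must be >= 0")
  transition_probs <- as.matrix(transition_probs)
  if (!all(dim(transition_probs) == c(2, 2)) ||
      any(transition_probs < 0) ||
      any(abs(rowSums(transition_probs) - 1) > 1e-9)) {
    stop("transition_probs must be 2 x 2 row-stochastic")
  }
  structure(
    list(atoms_per_domain = as.integer(atoms_per_domain),
         closed_mean = closed_mean, open_mean = open_mean,
         jitter_sd = jitter_sd, transition_probs = transition_probs,
         n_frames = as.integer(n_frames), frame_spacing = frame_spacing,
         start_state = start_state, random_rigid = random_rigid,
         seed = as.integer(seed)),
    class = "dumbbell_spec"
  )
}

# uniform-ish random rotation from a normalised Gaussian quaternion
.random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - z * w), 2 * (x * z + y * w),
    2 * (x * y + z * w), 1 - 2 * (x^2 + z^2), 2 * (y * z - x * w),
    2 * (x * z - y * w), 2 * (y * z + x * w), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

#' Generate a two-domain dumbbell trajectory with known ground truth
#'
#' Two rigid C-alpha blobs (chains A and B, centroid exactly at the domain
#' origin) separated per frame by `state mean + Gaussian(0, jitter_sd)`,
#' where the state follows the hidden Markov chain of the spec. Each frame
#' then receives an independent random rigid-body transform (unless
#' disabled), so any analysis that is not rigid-motion invariant will fail
#' on this data. The ground truth records the hidden state path and the
#' exact per-frame separations.
#'
#' @param spec a [dumbbell_spec()].
#' @return list with `trajectory` (a `papp_trajectory`), `truth` (`states`,
#'   `separations`, `domain_a`, `domain_b`, `stationary_open`) and `spec`.
#' @export
make_dumbbell_trajectory <- function(spec = dumbbell_spec()) {
  stopifnot(inherits(spec, "dumbbell_spec"))
  set.seed(spec$seed)
  napd <- spec$atoms_per_domain
  nf <- spec$n_frames
  center0 <- function(x) sweep(x, 2, colMeans(x))
  templ_a <- center0(matrix(stats::runif(3 * napd, -3, 3), ncol = 3))
  templ_b <- center0(matrix(stats::runif(3 * napd, -3, 3), ncol = 3))

  P <- spec$transition_probs
  states <- integer(nf)  # 1 = closed, 2 = open
  states[1] <- if (spec$start_state == "closed") 1L else 2L
  if (nf > 1) {
    u <- stats::runif(nf - 1)
    for (i in 2:nf) {
      states[i] <- if (u[i - 1] <= P[states[i - 1], 1]) 1L else 2L
    }
  }
  means <- c(spec$closed_mean, spec$open_mean)
  sep <- means[states] + stats::rnorm(nf, 0, spec$jitter_sd)
  if (any(sep <= 0)) stop("separation went non-positive; reduce jitter_sd")

  coords <- array(NA_real_, dim = c(2 * napd, 3, nf))
  for (f in seq_len(nf)) {
    X <- rbind(templ_a, sweep(templ_b, 2, c(sep[f], 0, 0), "+"))
    if (spec$random_rigid) {
      R <- .random_rotation()
      tr <- stats::runif(3, -50, 50)
      X <- sweep(X %*% t(R), 2, tr, "+")
    }
    coords[, , f] <- X
  }

  atoms <- data.frame(
    chain = rep(c("A", "B"), each = napd),
    res_index = rep(seq_len(napd), 2),
    res_name = "GLY", atom_name = "CA", element = "C", het = FALSE,
    stringsAsFactors = FALSE
  )
  s <- new_structure(atoms, coords, source_id = "synthetic dumbbell")
  traj <- as_trajectory(s, frame_spacing = spec$frame_spacing)

  p_co <- P[1, 2]; p_oc <- P[2, 1]
  truth <- list(
    states = c("closed", "open")[states],
    separations = sep,
    domain_a = domain_definition("domainA", c(1, napd), chain = "A"),
    domain_b = domain_definition("domainB", c(1, napd), chain = "B"),
    stationary_open = if (p_co + p_oc > 0) p_co / (p_co + p_oc) else
      as.numeric(states[1] == 2L)
  )
  list(trajectory = traj, truth = truth, spec = spec)
}
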