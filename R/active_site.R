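# Metzincin active-site detection: HEXXHXXGXXH motif, zinc coordination,
# catalytic water and Met-turn.

#' Scan a sequence for the metzincin zinc-binding motif
#'
#' Finds all non-overlapping matches of `H-[EQ]-x-x-H-x-x-G-x-x-H`, the
#' metzincin signature whose three histidines coordinate the catalytic zinc.
#' Glutamine is accepted at the glutamate position so catalytically dead
#' E-to-Q constructs still match; such hits are flagged as possible catalytic
#' mutants.
#'
#' @param seq uppercase one-letter amino-acid string.
#' @return data.frame with one row per hit: `start`, `his1`, `his2`, `his3`
#'   (`start`, `start+4`, `start+10`), `glu_position` (`start+1`), `pattern`
#'   (matched text) and `catalytic_mutant` (TRUE when Q occupies the
#'   glutamate position). Positions are 1-based on the input sequence.
#'   Zero rows when there is no match.
#' @export
scan_metzincin_motif <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1)
  seq <- as.character(seq)
  m <- gregexpr("H[EQ][A-Z]{2}H[A-Z]{2}G[A-Z]{2}H", seq)[[1]]
  empty <- data.frame(start = integer(), his1 = integer(), his2 = integer(),
                      his3 = integer(), glu_position = integer(),
                      pattern = character(), catalytic_mutant = logical(),
                      stringsAsFactors = FALSE)
  if (m[1] == -1) return(empty)
  start <- as.integer(m)
  data.frame(
    start = start, his1 = start, his2 = start + 4L, his3 = start + 10L,
    glu_position = start + 1L,
    pattern = substring(seq, start, start + 10L),
    catalytic_mutant = substring(seq, start + 1L, start + 1L) == "Q",
    stringsAsFactors = FALSE
  )
}

.coords1 <- function(s, model) {
  x <- s$coords[, , model, drop = FALSE]
  dim(x) <- c(dim(s$coords)[1], 3)
  x
}

.dist_to <- function(x, p) sqrt(rowSums(sweep(x, 2, p)^2))

# map sequence positions of a motif hit to residue indices on a chain;
# picks the chain automatically when not given
.motif_residues <- function(s, hit, chain) {
  chains <- unique(s$atoms$chain[!s$atoms$het])
  if (is.null(chain)) {
    for (ch in chains) {
      sq <- extract_sequence(s, ch)
      ri <- attr(sq, "res_index")
      pos <- c(hit$his1, hit$his2, hit$his3)
      if (max(pos) <= length(ri) &&
          all(s$atoms$res_name[match(paste(ch, ri[pos]),
              paste(s$atoms$chain, s$atoms$res_index))] == "HIS")) {
        chain <- ch
        break
      }
    }
    if (is.null(chain)) stop("motif residues absent from structure: ",
                             "no chain carries HIS at the hit positions")
  }
  sq <- extract_sequence(s, chain)
  ri <- attr(sq, "res_index")
  pos <- c(hit$his1, hit$his2, hit$his3)
  if (max(pos) > length(ri)) {
    stop("motif positions extend past chain '", chain, "'")
  }
  his_res <- ri[pos]
  nm <- s$atoms$res_name[match(paste(chain, his_res),
                               paste(s$atoms$chain, s$atoms$res_index))]
  if (any(nm != "HIS")) {
    stop("motif residues absent from structure: expected HIS at ",
         paste(his_res[nm != "HIS"], collapse = ","))
  }
  list(chain = chain, his_res = his_res,
       glu_res = ri[min(hit$glu_position, length(ri))])
}

#' Geometrically validate a zinc site implied by a motif hit
#'
#' Selects the zinc nearest the centroid of the motif histidines' C-beta
#' atoms, lists every residue atom within the coordination cutoff of that
#' zinc, and declares the site validated when all three motif histidines
#' contribute a side-chain nitrogen within the cutoff. A catalytic water is a
#' water oxygen within `water_cutoff` of the zinc; its distance to the
#' nearest tyrosine hydroxyl oxygen is recorded and a heavy-atom hydrogen
#' bond (<= 3.5 Angstrom) to that tyrosine flagged. The check degrades
#' gracefully to "absent" when the file deposits no water.
#'
#' @param s a `papp_structure` containing at least one ZN hetero atom.
#' @param hit one row of [scan_metzincin_motif()] output.
#' @param coordination_cutoff Zn-ligand heavy-atom cutoff in Angstrom
#'   (default 2.8: typical Zn-N bonds are 2.0-2.2, with slack for model
#'   error).
#' @param water_cutoff Zn-water oxygen cutoff in Angstrom (default 2.8).
#' @param chain chain carrying the motif; auto-detected when `NULL`.
#' @param model model index.
#' @return An object of class `zinc_site`: zinc coordinates, the
#'   coordinating-atom table (residue, atom, distance), `validated` flag,
#'   optional `catalytic_water` record, and the motif residue indices.
#' @export
validate_zinc_site <- function(s, hit, coordination_cutoff = 2.8,
                               water_cutoff = 2.8, chain = NULL, model = 1) {
  stopifnot(inherits(s, "papp_structure"))
  if (is.data.frame(hit)) {
    if (nrow(hit) < 1) stop("empty motif hit")
    hit <- hit[1, ]
  }
  a <- s$atoms
  x <- .coords1(s, model)
  zn_rows <- which(a$element == "ZN" | a$res_name == "ZN")
  if (length(zn_rows) == 0) stop("no zinc (ZN) atom in structure")

  mot <- .motif_residues(s, hit, chain)
  chain <- mot$chain
  his_res <- mot$his_res

  anchor_rows <- which(a$chain == chain & a$res_index %in% his_res &
                         a$atom_name %in% c("CB", "CA"))
  # prefer CB, fall back to CA per residue
  pick <- vapply(his_res, function(r) {
    rws <- anchor_rows[a$res_index[anchor_rows] == r]
    if (length(rws) == 0) return(NA_integer_)
    cb <- rws[a$atom_name[rws] == "CB"]
    if (length(cb) > 0) cb[1] else rws[1]
  }, integer(1))
  pick <- pick[!is.na(pick)]
  if (length(pick) == 0) stop("motif residues lack CB/CA anchors")
  centroid <- colMeans(x[pick, , drop = FALSE])

  zi <- zn_rows[which.min(.dist_to(x[zn_rows, , drop = FALSE], centroid))]
  zn_coord <- x[zi, ]

  cand <- which(!a$res_name %in% .WATER_NAMES & a$element != "ZN")
  d <- .dist_to(x[cand, , drop = FALSE], zn_coord)
  keep <- d <= coordination_cutoff
  coordinating <- data.frame(
    res_index = a$res_index[cand[keep]],
    res_name = a$res_name[cand[keep]],
    atom_name = a$atom_name[cand[keep]],
    element = a$element[cand[keep]],
    chain = a$chain[cand[keep]],
    distance = d[keep],
    stringsAsFactors = FALSE
  )
  coordinating <- coordinating[order(coordinating$distance), , drop = FALSE]
  rownames(coordinating) <- NULL

  side_n <- coordinating$element == "N" & coordinating$atom_name != "N"
  validated <- all(his_res %in% coordinating$res_index[side_n &
                     coordinating$chain == chain])

  catalytic_water <- NULL
  w_rows <- which(a$res_name %in% .WATER_NAMES & a$element == "O")
  if (length(w_rows) > 0) {
    dw <- .dist_to(x[w_rows, , drop = FALSE], zn_coord)
    if (any(dw <= water_cutoff)) {
      wi <- w_rows[which.min(dw)]
      tyr_rows <- which(a$res_name == "TYR" & a$atom_name == "OH")
      tyr_d <- if (length(tyr_rows) > 0) {
        min(.dist_to(x[tyr_rows, , drop = FALSE], x[wi, ]))
      } else NA_real_
      catalytic_water <- list(
        res_index = a$res_index[wi],
        zn_distance = min(dw),
        tyr_oh_distance = tyr_d,
        hbond_to_tyr = isTRUE(tyr_d <= 3.5)
      )
    }
  }

  structure(
    list(zinc_coord = zn_coord, zinc_res_index = a$res_index[zi],
         coordinating = coordinating, validated = validated,
         catalytic_water = catalytic_water, his_res = his_res,
         glu_res = mot$glu_res, chain = chain, model = model,
         coordination_cutoff = coordination_cutoff,
         water_cutoff = water_cutoff,
         catalytic_mutant = isTRUE(hit$catalytic_mutant)),
    class = "zinc_site"
  )
}

#' @export
print.zinc_site <- function(x, ...) {
  cat("zinc_site:", if (x$validated) "validated" else "NOT validated",
      "| motif His", paste(x$his_res, collapse = "/"),
      "| chain", x$chain, "\n")
  cat("  coordinating atoms (<=", x$coordination_cutoff, "A):",
      nrow(x$coordinating), "\n")
  if (is.null(x$catalytic_water)) {
    cat("  catalytic water: absent\n")
  } else {
    cat(sprintf("  catalytic water: Zn-O %.2f A, Tyr OH %.2f A (%s)\n",
                x$catalytic_water$zn_distance,
                x$catalytic_water$tyr_oh_distance,
                if (x$catalytic_water$hbond_to_tyr) "H-bonded" else "no H-bond"))
  }
  invisible(x)
}

#' Locate the Met-turn methionine
#'
#' The Met-turn is the conserved methionine packed beneath the catalytic zinc
#' of metzincins (M573 in mature PAPP-A2). Defined operationally: the Met
#' whose side-chain sulfur lies nearest the zinc, among Met residues within
#' `search_window` residues downstream of the motif's third histidine.
#'
#' @param s a `papp_structure`.
#' @param site a validated [validate_zinc_site()] result.
#' @param search_window residue count downstream of the third motif His to
#'   search (default 100).
#' @param model model index.
#' @return list with `res_index` of the Met-turn and `distance` (SD-to-zinc,
#'   Angstrom).
#' @export
find_met_turn <- function(s, site, search_window = 100, model = 1) {
  stopifnot(inherits(s, "papp_structure"), inherits(site, "zinc_site"))
  if (!site$validated) stop("zinc site is not validated")
  a <- s$atoms
  h3 <- max(site$his_res)
  rows <- which(a$chain == site$chain & a$res_name == "MET" &
                  a$atom_name == "SD" &
                  a$res_index > h3 & a$res_index <= h3 + search_window)
  if (length(rows) == 0) {
    stop("no Met side-chain sulfur within ", search_window,
         " residues downstream of His", h3)
  }
  x <- .coords1(s, model)
  d <- .dist_to(x[rows, , drop = FALSE], site$zinc_coord)
  i <- which.min(d)
  list(res_index = a$res_index[rows[i]], distance = d[i])
}
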