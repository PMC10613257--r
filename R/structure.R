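# Structure container, numbering schemes, domain definitions and selections.

.AA321 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V"
)

.WATER_NAMES <- c("HOH", "WAT", "H2O")

#' Construct a structure object
#'
#' A `papp_structure` holds an ordered atom table plus one coordinate set per
#' model (frame). All models share the same atom identity list, which is what
#' makes multi-model files usable as trajectories.
#'
#' @param atoms data.frame with columns `chain`, `res_index` (1-based integer),
#'   `res_name` (3-letter code, `HOH`/`ZN` for hetero), `atom_name`, `element`,
#'   and logical `het`.
#' @param coords numeric n x 3 matrix (single model) or n x 3 x m array, in
#'   Angstrom.
#' @param source_id free-text provenance label.
#' @param numbering a [numbering_scheme()] describing how `res_index` is to be
#'   interpreted.
#' @return An object of class `papp_structure`.
#' @export
new_structure <- function(atoms, coords, source_id = "",
                          numbering = numbering_scheme("mature", 0L)) {
  stopifnot(is.data.frame(atoms))
  need <- c("chain", "res_index", "res_name", "atom_name", "element")
  miss <- setdiff(need, names(atoms))
  if (length(miss) > 0) {
    stop("atom table lacks column(s): ", paste(miss, collapse = ", "))
  }
  if (is.null(atoms$het)) atoms$het <- atoms$res_name %in% c(.WATER_NAMES, "ZN")
  atoms$res_index <- as.integer(atoms$res_index)
  if (nrow(atoms) == 0) stop("empty structure: no atoms")
  if (any(atoms$res_index < 1)) stop("res_index must be >= 1")
  if (any(is.na(atoms$element) | !nzchar(atoms$element))) {
    stop("every atom needs a non-empty element symbol")
  }
  if (is.matrix(coords)) coords <- array(coords, dim = c(nrow(coords), 3, 1))
  stopifnot(length(dim(coords)) == 3, dim(coords)[2] == 3)
  if (dim(coords)[1] != nrow(atoms)) {
    stop("coordinate rows (", dim(coords)[1], ") != atoms (", nrow(atoms), ")")
  }
  if (!all(is.finite(coords))) stop("non-finite coordinates")
  key <- paste(atoms$chain, atoms$res_index, atoms$atom_name)
  if (anyDuplicated(key)) {
    stop("duplicate (chain, res_index, atom_name) triple: ",
         key[anyDuplicated(key)])
  }
  structure(
    list(atoms = atoms, coords = coords, n_models = dim(coords)[3],
         source_id = source_id, numbering = numbering),
    class = "papp_structure"
  )
}

#' @export
print.papp_structure <- function(x, ...) {
  res <- unique(paste(x$atoms$chain, x$atoms$res_index))
  cat("papp_structure:", nrow(x$atoms), "atoms,", length(res), "residues,",
      length(unique(x$atoms$chain)), "chain(s),", x$n_models, "model(s)\n")
  cat("  numbering:", x$numbering$kind,
      "(propeptide offset", x$numbering$propeptide_offset, ")\n")
  if (nzchar(x$source_id)) cat("  source:", x$source_id, "\n")
  invisible(x)
}

#' Residue numbering scheme
#'
#' Pappalysins are deposited either in precursor numbering (signal peptide and
#' pro-peptide included) or mature numbering (after their removal). The two
#' differ by a constant propeptide offset (234 residues for PAPP-A2), so the
#' patient mutation A1033V (precursor) is A799V (mature).
#'
#' @param kind `"precursor"` or `"mature"`.
#' @param propeptide_offset non-negative integer count of residues removed
#'   during maturation.
#' @return An object of class `numbering_scheme`.
#' @export
numbering_scheme <- function(kind = c("mature", "precursor"),
                             propeptide_offset = 0L) {
  kind <- match.arg(kind)
  propeptide_offset <- as.integer(propeptide_offset)
  if (is.na(propeptide_offset) || propeptide_offset < 0) {
    stop("propeptide_offset must be a non-negative integer")
  }
  structure(list(kind = kind, propeptide_offset = propeptide_offset),
            class = "numbering_scheme")
}

#' Convert residue indices between numbering schemes
#'
#' @param index integer vector of residue indices valid under `scheme_from`.
#' @param scheme_from,scheme_to [numbering_scheme()] objects sharing the same
#'   propeptide offset.
#' @return Integer vector of converted indices. Precursor to mature subtracts
#'   the offset; mature to precursor adds it; the round trip is the identity.
#' @examples
#' m <- numbering_scheme("mature", 234)
#' p <- numbering_scheme("precursor", 234)
#' convert_numbering(1033, p, m)  # 799, the A799V site
#' @export
convert_numbering <- function(index, scheme_from, scheme_to) {
  stopifnot(inherits(scheme_from, "numbering_scheme"),
            inherits(scheme_to, "numbering_scheme"))
  if (scheme_from$propeptide_offset != scheme_to$propeptide_offset) {
    stop("schemes disagree on propeptide_offset (",
         scheme_from$propeptide_offset, " vs ", scheme_to$propeptide_offset, ")")
  }
  index <- as.integer(index)
  if (any(is.na(index)) || any(index < 1)) stop("indices must be >= 1")
  off <- scheme_from$propeptide_offset
  if (scheme_from$kind == scheme_to$kind) return(index)
  if (scheme_from$kind == "precursor") {
    out <- index - off
    if (any(out < 1)) {
      stop("precursor index ", paste(index[out < 1], collapse = ","),
           " lies inside the pro-peptide: outside the mature range")
    }
    out
  } else {
    index + off
  }
}

#' Shift a structure between precursor and mature numbering
#'
#' @param s a `papp_structure`.
#' @param to target kind, `"mature"` or `"precursor"`.
#' @return The structure with `res_index` and numbering metadata converted.
#' @export
apply_numbering <- function(s, to = c("mature", "precursor")) {
  to <- match.arg(to)
  stopifnot(inherits(s, "papp_structure"))
  if (s$numbering$kind == to) return(s)
  off <- s$numbering$propeptide_offset
  target <- numbering_scheme(to, off)
  s$atoms$res_index <- convert_numbering(s$atoms$res_index, s$numbering, target)
  s$numbering <- target
  s
}

#' Named residue-range selection
#'
#' Domain definitions follow the convention of the M1/M2 center-of-mass
#' analysis: 1-based residue intervals, inclusive on both ends (M1 = 610-927,
#' M2 = 953-1160, IGFBP5 anchor peptide = 120-143 in its own numbering).
#'
#' @param name label used in error messages and reports.
#' @param ranges numeric vector `c(start, end)`, or a list of such vectors, or
#'   a 2-column matrix of inclusive intervals.
#' @param chain chain identifier the ranges refer to.
#' @return An object of class `domain_definition`.
#' @export
domain_definition <- function(name, ranges, chain = "A") {
  if (is.numeric(ranges) && is.null(dim(ranges))) {
    if (length(ranges) != 2) stop("a single range needs exactly c(start, end)")
    ranges <- matrix(ranges, ncol = 2, byrow = TRUE)
  } else if (is.list(ranges)) {
    ranges <- do.call(rbind, lapply(ranges, function(r) {
      if (length(r) != 2) stop("each range needs exactly c(start, end)")
      r
    }))
  }
  ranges <- matrix(as.integer(ranges), ncol = 2)
  colnames(ranges) <- c("start", "end")
  if (any(ranges[, 1] > ranges[, 2])) stop("range start > end in '", name, "'")
  if (any(ranges < 1)) stop("ranges are 1-based")
  if (nrow(ranges) > 1) {
    o <- order(ranges[, 1])
    r <- ranges[o, , drop = FALSE]
    if (any(r[-1, 1] <= r[-nrow(r), 2])) {
      stop("overlapping ranges in domain '", name, "'")
    }
  }
  structure(list(name = name, ranges = ranges, chain = chain),
            class = "domain_definition")
}

# membership of residue indices in a domain definition
.in_ranges <- function(idx, d) {
  hit <- rep(FALSE, length(idx))
  for (k in seq_len(nrow(d$ranges))) {
    hit <- hit | (idx >= d$ranges[k, 1] & idx <= d$ranges[k, 2])
  }
  hit
}

.guess_element <- function(atom_name) {
  e <- sub("^[0-9']*", "", atom_name)
  e <- substr(e, 1, 1)
  ifelse(nzchar(e), toupper(e), "X")
}

#' Read a structure from PDB or mmCIF
#'
#' Reads all models; hetero atoms (zinc, waters) are retained. Structures with
#' insertion codes are rejected. Alternate locations are resolved by keeping
#' the highest-occupancy conformer (ties broken by altloc letter order).
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"pdb"` or `"mmcif"`.
#' @param numbering [numbering_scheme()] the file's residue numbers follow.
#' @param source_id provenance label, defaults to the file name.
#' @return A `papp_structure`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                           numbering = numbering_scheme("mature", 0L),
                           source_id = basename(path)) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  }
  pdb <- tryCatch(
    suppressWarnings(
      if (format == "pdb") {
        bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE)
      } else {
        bio3d::read.cif(path, rm.alt = FALSE, verbose = FALSE)
      }
    ),
    error = function(e) stop("parse error reading ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0) stop("empty structure: no atoms in ", path)
  if (!is.null(at$insert) && any(!is.na(at$insert) & nzchar(at$insert))) {
    stop("insertion codes present (e.g. residue ",
         at$resno[which(!is.na(at$insert) & nzchar(at$insert))[1]],
         "); renumber the file first")
  }
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  keep <- seq_len(nrow(at))
  # altloc: highest occupancy wins, ties by letter order
  if (!is.null(at$alt) && any(!is.na(at$alt) & nzchar(at$alt))) {
    occ <- if (is.null(at$o)) rep(1, nrow(at)) else ifelse(is.na(at$o), 1, at$o)
    alt <- ifelse(is.na(at$alt), "", at$alt)
    grp <- paste(at$chain, at$resno, at$elety)
    ord <- order(grp, -occ, alt)
    keep <- sort(ord[!duplicated(grp[ord])])
  }
  n_models <- nrow(xyz)
  if (ncol(xyz) != 3 * nrow(at) || !all(is.finite(xyz))) {
    stop("model atom mismatch in ", path,
         ": models do not contain identical atom lists")
  }
  at <- at[keep, , drop = FALSE]
  cols <- as.vector(rbind(3 * keep - 2, 3 * keep - 1, 3 * keep))
  xyz <- xyz[, cols, drop = FALSE]
  n <- nrow(at)
  coords <- array(NA_real_, dim = c(n, 3, n_models))
  for (m in seq_len(n_models)) {
    coords[, , m] <- matrix(xyz[m, ], ncol = 3, byrow = TRUE)
  }
  elesy <- at$elesy
  if (is.null(elesy)) elesy <- rep(NA_character_, n)
  elesy <- ifelse(is.na(elesy) | !nzchar(elesy),
                  .guess_element(at$elety), toupper(elesy))
  atoms <- data.frame(
    chain = ifelse(is.na(at$chain), "A", at$chain),
    res_index = at$resno,
    res_name = at$resid,
    atom_name = at$elety,
    element = elesy,
    het = at$type == "HETATM",
    stringsAsFactors = FALSE
  )
  new_structure(atoms, coords, source_id = source_id, numbering = numbering)
}

#' Write a structure to PDB
#'
#' Multi-model structures are written as MODEL/ENDMDL blocks, so trajectories
#' round-trip through the standard format.
#'
#' @param s a `papp_structure`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(s, path) {
  stopifnot(inherits(s, "papp_structure"))
  n <- nrow(s$atoms)
  xyz <- t(apply(s$coords, 3, function(m) as.vector(t(m))))
  if (s$n_models == 1) xyz <- matrix(xyz, nrow = 1)
  bio3d::write.pdb(
    file = path, xyz = xyz,
    type = ifelse(s$atoms$het, "HETATM", "ATOM"),
    eleno = seq_len(n), elety = s$atoms$atom_name,
    resid = s$atoms$res_name, chain = s$atoms$chain,
    resno = s$atoms$res_index, elesy = s$atoms$element,
    o = rep(1, n), b = rep(0, n)
  )
  invisible(path)
}

#' Extract the one-letter sequence of a chain
#'
#' Water, metal ions and other hetero records are excluded. Non-standard
#' residues map to `"X"`. Gaps in the residue numbering are recorded in the
#' `"gaps"` attribute, and the residue index of every sequence position in the
#' `"res_index"` attribute (needed to map alignment positions back onto the
#' structure).
#'
#' @param s a `papp_structure`.
#' @param chain chain identifier.
#' @return Character scalar with attributes `res_index` and `gaps`.
#' @export
extract_sequence <- function(s, chain) {
  stopifnot(inherits(s, "papp_structure"))
  chains <- unique(s$atoms$chain)
  if (length(chain) != 1 || is.na(chain) || !nzchar(chain) ||
      !chain %in% chains) {
    stop("unknown chain '", chain, "'; available: ",
         paste(chains, collapse = ", "))
  }
  a <- s$atoms[s$atoms$chain == chain & !s$atoms$het, , drop = FALSE]
  a <- a[!a$res_name %in% c(.WATER_NAMES, "ZN"), , drop = FALSE]
  if (nrow(a) == 0) stop("chain '", chain, "' has no polymer residues")
  a <- a[!duplicated(a$res_index), , drop = FALSE]
  a <- a[order(a$res_index), , drop = FALSE]
  letters1 <- unname(.AA321[a$res_name])
  letters1[is.na(letters1)] <- "X"
  seq <- paste(letters1, collapse = "")
  attr(seq, "res_index") <- a$res_index
  attr(seq, "gaps") <- setdiff(seq(min(a$res_index), max(a$res_index)),
                               a$res_index)
  seq
}

# CA atom row numbers for a domain selection, ordered by residue index
.calpha_rows <- function(s, d) {
  a <- s$atoms
  sel <- which(a$chain == d$chain & a$atom_name == "CA" &
                 .in_ranges(a$res_index, d))
  sel[order(a$res_index[sel])]
}

#' Select C-alpha coordinates of a domain
#'
#' @param s a `papp_structure`.
#' @param d a [domain_definition()].
#' @param model model (frame) index, 1-based.
#' @return N x 3 coordinate matrix ordered by residue index, with attributes
#'   `res_index` (selected residues) and `n_missing` (in-range residues of the
#'   chain lacking a C-alpha, which are skipped).
#' @export
select_calpha <- function(s, d, model = 1) {
  stopifnot(inherits(s, "papp_structure"), inherits(d, "domain_definition"))
  if (model < 1 || model > s$n_models) {
    stop("model ", model, " out of range (structure has ", s$n_models, ")")
  }
  rows <- .calpha_rows(s, d)
  if (length(rows) == 0) {
    stop("empty selection for domain '", d$name, "' (chain ", d$chain, ")")
  }
  a <- s$atoms
  in_chain <- unique(a$res_index[a$chain == d$chain & !a$het])
  n_missing <- sum(.in_ranges(in_chain, d)) - length(rows)
  m <- s$coords[rows, , model, drop = FALSE]
  dim(m) <- c(length(rows), 3)
  attr(m, "res_index") <- a$res_index[rows]
  attr(m, "n_missing") <- n_missing
  m
}

#' Apply a rigid-body transform to every model of a structure
#'
#' @param s a `papp_structure`.
#' @param rotation 3 x 3 proper rotation matrix.
#' @param translation length-3 vector in Angstrom.
#' @return The transformed structure.
#' @export
transform_structure <- function(s, rotation = diag(3), translation = c(0, 0, 0)) {
  stopifnot(inherits(s, "papp_structure"))
  for (m in seq_len(s$n_models)) {
    x <- s$coords[, , m, drop = FALSE]
    dim(x) <- c(dim(s$coords)[1], 3)
    s$coords[, , m] <- sweep(x %*% t(rotation), 2, translation, "+")
  }
  s
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA file path.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- names(x)
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
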