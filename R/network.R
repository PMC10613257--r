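# Typed residue-interaction graph and long-range path analysis.
#
# Detectors use heavy-atom distance criteria only (deposited and synthetic
# structures carry no hydrogens) and operate on one chain at a time: the
# analysis they exist for - tracing how a distal mutation site couples to the
# catalytic zinc - is intra-chain.

.BACKBONE <- c("N", "CA", "C", "O", "OXT")
.APOLAR_RES <- c("ALA", "VAL", "LEU", "ILE", "PRO", "PHE", "MET", "TRP", "TYR")
.RING_ATOMS <- list(
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2"),
  TRP = c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2")  # 6-membered ring
)

.pick_chain <- function(s, chain) {
  chains <- unique(s$atoms$chain[!s$atoms$het])
  if (!is.null(chain)) {
    if (!chain %in% chains) {
      stop("unknown chain '", chain, "'; available: ",
           paste(chains, collapse = ", "))
    }
    return(chain)
  }
  if (length(chains) != 1) {
    stop("structure has chains ", paste(chains, collapse = ", "),
         "; specify one")
  }
  chains
}

# polymer atoms of one chain with coordinates attached
.chain_atoms <- function(s, chain, model) {
  a <- s$atoms
  x <- .coords1(s, model)
  rows <- which(a$chain == chain & !a$het &
                  !a$res_name %in% c(.WATER_NAMES, "ZN"))
  cbind(a[rows, , drop = FALSE],
        data.frame(x = x[rows, 1], y = x[rows, 2], z = x[rows, 3]))
}

.empty_edges <- function() {
  data.frame(res_a = integer(), res_b = integer(), kind = character(),
             distance = numeric(), detail = character(), angle = numeric(),
             stringsAsFactors = FALSE)
}

# assemble an edge table from candidate atoms and a distance cutoff
.pairs_within <- function(tab, cutoff) {
  n <- nrow(tab)
  if (n < 2) return(NULL)
  dm <- as.matrix(stats::dist(tab[, c("x", "y", "z")]))
  idx <- which(upper.tri(dm) & dm <= cutoff, arr.ind = TRUE)
  if (nrow(idx) == 0) return(NULL)
  cbind(idx, dist = dm[idx])
}

#' Detect hydrogen bonds (heavy-atom criterion)
#'
#' An edge for every nitrogen/oxygen heavy-atom pair within the cutoff
#' between non-identical residues. Backbone-backbone contacts between
#' sequence-adjacent residues are excluded (they are covalent-geometry
#' trivia, not interactions). Backbone vs side-chain participation is
#' recorded in `detail`.
#'
#' @param s a `papp_structure`.
#' @param heavy_cutoff donor-acceptor N/O distance cutoff in Angstrom
#'   (default 3.5, the standard heavy-atom convention).
#' @param chain chain to analyse (auto when the structure has one chain).
#' @param model model index.
#' @return data.frame of edges: `res_a`, `res_b` (residue indices,
#'   `res_a < res_b`), `kind`, `distance`, `detail`, `angle` (NA here).
#' @export
detect_hbonds <- function(s, heavy_cutoff = 3.5, chain = NULL, model = 1) {
  chain <- .pick_chain(s, chain)
  tab <- .chain_atoms(s, chain, model)
  tab <- tab[tab$element %in% c("N", "O"), , drop = FALSE]
  hits <- .pairs_within(tab, heavy_cutoff)
  if (is.null(hits)) return(.empty_edges())
  i <- hits[, 1]; j <- hits[, 2]
  ri <- tab$res_index[i]; rj <- tab$res_index[j]
  bb_i <- tab$atom_name[i] %in% .BACKBONE
  bb_j <- tab$atom_name[j] %in% .BACKBONE
  keep <- ri != rj & !(abs(ri - rj) <= 1 & bb_i & bb_j)
  if (!any(keep)) return(.empty_edges())
  i <- i[keep]; j <- j[keep]
  part <- function(bb) ifelse(bb, "bb", "sc")
  detail <- sprintf("%s(%s)-%s(%s)", tab$atom_name[i], part(bb_i[keep]),
                    tab$atom_name[j], part(bb_j[keep]))
  ra <- pmin(tab$res_index[i], tab$res_index[j])
  rb <- pmax(tab$res_index[i], tab$res_index[j])
  data.frame(res_a = ra, res_b = rb, kind = "hbond",
             distance = hits[keep, 3], detail = detail, angle = NA_real_,
             stringsAsFactors = FALSE)
}

#' Detect hydrophobic contacts
#'
#' An edge when any pair of apolar side-chain carbons (Ala, Val, Leu, Ile,
#' Pro, Phe, Met, Trp, Tyr side chains, plus the Lys CB/CG/CD aliphatic
#' stem) lies within the cutoff. Sequence-adjacent residue pairs are
#' excluded to avoid trivial neighbours.
#'
#' @inheritParams detect_hbonds
#' @param carbon_cutoff carbon-carbon cutoff in Angstrom (default 4.5).
#' @return data.frame of edges (see [detect_hbonds()]).
#' @export
detect_hydrophobic <- function(s, carbon_cutoff = 4.5, chain = NULL,
                               model = 1) {
  chain <- .pick_chain(s, chain)
  tab <- .chain_atoms(s, chain, model)
  side_c <- tab$element == "C" & !tab$atom_name %in% .BACKBONE
  apolar <- (tab$res_name %in% .APOLAR_RES & side_c) |
    (tab$res_name == "LYS" & tab$atom_name %in% c("CB", "CG", "CD"))
  tab <- tab[apolar, , drop = FALSE]
  hits <- .pairs_within(tab, carbon_cutoff)
  if (is.null(hits)) return(.empty_edges())
  i <- hits[, 1]; j <- hits[, 2]
  keep <- abs(tab$res_index[i] - tab$res_index[j]) > 1
  if (!any(keep)) return(.empty_edges())
  i <- i[keep]; j <- j[keep]
  data.frame(res_a = pmin(tab$res_index[i], tab$res_index[j]),
             res_b = pmax(tab$res_index[i], tab$res_index[j]),
             kind = "hydrophobic", distance = hits[keep, 3],
             detail = sprintf("%s-%s", tab$atom_name[i], tab$atom_name[j]),
             angle = NA_real_, stringsAsFactors = FALSE)
}

# ring centroids and plane normals for aromatic residues of one chain
.ring_table <- function(tab) {
  out <- list()
  for (rn in names(.RING_ATOMS)) {
    rt <- tab[tab$res_name == rn & tab$atom_name %in% .RING_ATOMS[[rn]], ,
              drop = FALSE]
    if (nrow(rt) == 0) next
    for (r in unique(rt$res_index)) {
      xyz <- as.matrix(rt[rt$res_index == r, c("x", "y", "z")])
      # a centroid is meaningful only for an essentially complete ring
      if (nrow(xyz) < length(.RING_ATOMS[[rn]]) - 1) next
      cen <- colMeans(xyz)
      sv <- svd(sweep(xyz, 2, cen))
      out[[length(out) + 1]] <- list(res_index = r, centroid = cen,
                                     normal = sv$v[, 3])
    }
  }
  out
}

#' Detect pi-pi stacking between aromatic rings
#'
#' An edge when two aromatic ring centroids (Phe, Tyr, His; the six-membered
#' ring for Trp) lie within the cutoff. No plane-angle filter is applied -
#' both parallel and T-shaped geometries count as stacks - but the
#' inter-plane angle is recorded for inspection.
#'
#' @inheritParams detect_hbonds
#' @param centroid_cutoff inter-centroid cutoff in Angstrom (default 6.0).
#' @return data.frame of edges; `angle` holds the inter-plane angle in
#'   degrees.
#' @export
detect_pipi <- function(s, centroid_cutoff = 6.0, chain = NULL, model = 1) {
  chain <- .pick_chain(s, chain)
  tab <- .chain_atoms(s, chain, model)
  rings <- .ring_table(tab)
  n <- length(rings)
  if (n < 2) return(.empty_edges())
  out <- .empty_edges()
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (rings[[i]]$res_index == rings[[j]]$res_index) next
      d <- sqrt(sum((rings[[i]]$centroid - rings[[j]]$centroid)^2))
      if (d > centroid_cutoff) next
      ang <- acos(pmin(1, abs(sum(rings[[i]]$normal * rings[[j]]$normal)))) *
        180 / pi
      out <- rbind(out, data.frame(
        res_a = min(rings[[i]]$res_index, rings[[j]]$res_index),
        res_b = max(rings[[i]]$res_index, rings[[j]]$res_index),
        kind = "pipi", distance = d, detail = "ring-ring", angle = ang,
        stringsAsFactors = FALSE))
    }
  }
  out
}

#' Build the typed residue-interaction graph
#'
#' Union of hydrogen-bond, hydrophobic and pi-pi edges; duplicate
#' (pair, kind) detections are merged keeping the shortest distance. When
#' `include_zinc` is TRUE and the chain carries both the metzincin motif and
#' a zinc atom, metal-coordination edges connect the coordinating residues
#' to a `"zinc"` pseudo-node.
#'
#' @param s a `papp_structure`.
#' @param include_zinc add the zinc node and metal edges when possible.
#' @param chain chain to analyse (auto when single-chain).
#' @param model model index.
#' @param hbond_cutoff,hydrophobic_cutoff,pipi_cutoff,coordination_cutoff
#'   detector cutoffs in Angstrom.
#' @return An object of class `interaction_graph`: `nodes` (residue indices
#'   as character, plus `"zinc"` when present) and `edges` (res_a, res_b,
#'   kind, distance, detail, angle).
#' @export
build_graph <- function(s, include_zinc = TRUE, chain = NULL, model = 1,
                        hbond_cutoff = 3.5, hydrophobic_cutoff = 4.5,
                        pipi_cutoff = 6.0, coordination_cutoff = 2.8) {
  chain <- .pick_chain(s, chain)
  edges <- rbind(
    detect_hbonds(s, hbond_cutoff, chain, model),
    detect_hydrophobic(s, hydrophobic_cutoff, chain, model),
    detect_pipi(s, pipi_cutoff, chain, model)
  )
  edges$res_a <- as.character(edges$res_a)
  edges$res_b <- as.character(edges$res_b)

  nodes <- as.character(sort(unique(
    s$atoms$res_index[s$atoms$chain == chain & !s$atoms$het &
                        !s$atoms$res_name %in% c(.WATER_NAMES, "ZN")])))

  zinc_site <- NULL
  if (include_zinc && any(s$atoms$element == "ZN" | s$atoms$res_name == "ZN")) {
    sq <- extract_sequence(s, chain)
    hits <- scan_metzincin_motif(sq)
    if (nrow(hits) > 0) {
      zinc_site <- validate_zinc_site(s, hits[1, ],
                                      coordination_cutoff = coordination_cutoff,
                                      chain = chain, model = model)
      co <- zinc_site$coordinating
      co <- co[co$element %in% c("N", "O", "S") & co$chain == chain, ,
               drop = FALSE]
      if (nrow(co) > 0) {
        agg <- stats::aggregate(distance ~ res_index, data = co, FUN = min)
        edges <- rbind(edges, data.frame(
          res_a = as.character(agg$res_index), res_b = "zinc",
          kind = "metal", distance = agg$distance, detail = "coordination",
          angle = NA_real_, stringsAsFactors = FALSE))
        nodes <- c(nodes, "zinc")
      }
    }
  }

  if (nrow(edges) > 0) {
    edges <- edges[order(edges$distance), , drop = FALSE]
    edges <- edges[!duplicated(edges[, c("res_a", "res_b", "kind")]), ,
                   drop = FALSE]
    o <- order(as.numeric(ifelse(edges$res_a == "zinc", Inf, edges$res_a)),
               as.numeric(ifelse(edges$res_b == "zinc", Inf, edges$res_b)),
               edges$kind)
    edges <- edges[o, , drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(list(nodes = nodes, edges = edges, chain = chain,
                 zinc_site = zinc_site,
                 cutoffs = c(hbond = hbond_cutoff,
                             hydrophobic = hydrophobic_cutoff,
                             pipi = pipi_cutoff,
                             coordination = coordination_cutoff)),
            class = "interaction_graph")
}

#' @export
print.interaction_graph <- function(x, ...) {
  cat("interaction_graph: chain", x$chain, "|", length(x$nodes), "nodes,",
      nrow(x$edges), "edges\n")
  if (nrow(x$edges) > 0) print(table(x$edges$kind))
  invisible(x)
}

# lexicographically smallest numeric-key path among a list of paths
.lex_min_path <- function(paths) {
  keys <- lapply(paths, function(p) {
    as.numeric(ifelse(p == "zinc", Inf, p))
  })
  best <- 1
  for (k in seq_along(keys)[-1]) {
    a <- keys[[k]]; b <- keys[[best]]
    n <- min(length(a), length(b))
    cmp <- 0
    for (i in seq_len(n)) {
      if (a[i] != b[i]) { cmp <- sign(a[i] - b[i]); break }
    }
    if (cmp == 0) cmp <- sign(length(a) - length(b))
    if (cmp < 0) best <- k
  }
  paths[[best]]
}

#' Minimum-hop path through the interaction graph
#'
#' Finds the shortest path (in hops) from a source residue to a target node,
#' typically `"zinc"`. Ties between equal-length paths are broken by the
#' lexicographically smallest residue-index sequence, so reports are
#' reproducible. A disconnected pair yields an explicit no-path result, not
#' an error.
#'
#' @param g an [build_graph()] result.
#' @param source residue index (or node name) of the start.
#' @param target node name, default `"zinc"`.
#' @return An object of class `network_path`: `found`, `path` (ordered node
#'   names) and `n_hops`.
#' @export
shortest_path <- function(g, source, target = "zinc") {
  stopifnot(inherits(g, "interaction_graph"))
  source <- as.character(source)
  target <- as.character(target)
  if (!source %in% g$nodes) {
    stop("source node '", source, "' not in graph")
  }
  no_path <- structure(list(found = FALSE, path = NULL, n_hops = NA_integer_,
                            source = source, target = target),
                       class = "network_path")
  if (!target %in% g$nodes) return(no_path)
  ig <- igraph::graph_from_data_frame(
    g$edges[, c("res_a", "res_b")], directed = FALSE,
    vertices = data.frame(name = g$nodes))
  res <- suppressWarnings(
    igraph::all_shortest_paths(ig, from = source, to = target))
  vp <- if (!is.null(res$vpaths)) res$vpaths else res$res
  if (length(vp) == 0) return(no_path)
  paths <- lapply(vp, function(p) names(igraph::V(ig))[as.integer(p)])
  best <- .lex_min_path(paths)
  structure(list(found = TRUE, path = best, n_hops = length(best) - 1L,
                 source = source, target = target),
            class = "network_path")
}

#' @export
print.network_path <- function(x, ...) {
  if (!x$found) {
    cat("network_path: no path from", x$source, "to", x$target, "\n")
  } else {
    cat("network_path:", paste(x$path, collapse = " -> "),
        sprintf("(%d hops)\n", x$n_hops))
  }
  invisible(x)
}

#' Distance from a residue atom to an arbitrary point
#'
#' Used e.g. to measure how far a mutation site's C-alpha sits from the
#' catalytic zinc.
#'
#' @param s a `papp_structure`.
#' @param residue residue index.
#' @param atom atom name (e.g. `"CA"`).
#' @param node_coord length-3 coordinate vector in Angstrom.
#' @param chain chain (auto when single-chain).
#' @param model model index.
#' @return Euclidean distance in Angstrom.
#' @export
distance_to_node <- function(s, residue, atom, node_coord, chain = NULL,
                             model = 1) {
  chain <- .pick_chain(s, chain)
  a <- s$atoms
  row <- which(a$chain == chain & a$res_index == residue &
                 a$atom_name == atom)
  if (length(row) == 0) {
    stop("atom ", atom, " of residue ", residue, " (chain ", chain,
         ") not found")
  }
  x <- .coords1(s, model)
  sqrt(sum((x[row[1], ] - node_coord)^2))
}

#' Export graph edges as TSV
#'
#' @param g an `interaction_graph`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_edges_tsv <- function(g, path) {
  stopifnot(inherits(g, "interaction_graph"))
  utils::write.table(
    g$edges[, c("res_a", "res_b", "kind", "distance")], path,
    sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
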