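# Optimal rigid-body superposition (Kabsch) and domain RMSD.

#' Kabsch superposition
#'
#' Finds the proper rotation and translation minimising the RMSD between two
#' paired coordinate sets. The reflection branch of the SVD solution is
#' corrected, so mirror images are never superposed onto each other.
#'
#' @param P,Q N x 3 coordinate matrices (Angstrom), row i of P paired with
#'   row i of Q. N >= 3 and the points must not be collinear.
#' @return An object of class `superposition`: `rotation` (3 x 3, det +1,
#'   acting on column vectors q = R p), `translation`, `rmsd`, `n_atoms`.
#'   Applying `rotation`/`translation` to P superposes it onto Q.
#' @export
kabsch <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  storage.mode(P) <- "double"; storage.mode(Q) <- "double"
  if (ncol(P) != 3 || ncol(Q) != 3) stop("coordinates must be N x 3")
  if (nrow(P) != nrow(Q)) stop("paired sets differ in length")
  if (nrow(P) < 3) stop("under-determined: need at least 3 paired atoms")
  if (!all(is.finite(P)) || !all(is.finite(Q))) stop("non-finite coordinates")
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  for (M in list(Pc, Qc)) {
    d <- svd(M, nu = 0, nv = 0)$d
    if (d[2] <= 1e-8 * max(d[1], 1)) {
      stop("under-determined: collinear (degenerate) point set")
    }
  }
  H <- crossprod(Pc, Qc)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  rmsd <- sqrt(mean(rowSums((Pc %*% t(R) - Qc)^2)))
  structure(
    list(rotation = R, translation = as.vector(cq - R %*% cp),
         rmsd = rmsd, n_atoms = nrow(P), pairing = NULL),
    class = "superposition"
  )
}

#' Apply a superposition to coordinates
#'
#' @param fit a [kabsch()] result.
#' @param X N x 3 coordinate matrix.
#' @return The transformed N x 3 matrix.
#' @export
apply_superposition <- function(fit, X) {
  stopifnot(inherits(fit, "superposition"))
  sweep(as.matrix(X) %*% t(fit$rotation), 2, fit$translation, "+")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("superposition: rmsd %.3f A over %d atoms\n", x$rmsd, x$n_atoms))
  if (!is.null(x$cycles_used)) {
    cat(sprintf("  outlier rejection: %d cycle(s), %d pair(s) dropped, ",
                x$cycles_used, x$n_dropped),
        sprintf("all-pair rmsd %.3f A\n", x$rmsd_all))
  }
  invisible(x)
}

#' Pair sequence positions by global alignment
#'
#' Global (Needleman-Wunsch) alignment with an identity substitution matrix
#' and linear gap penalty 1 - adequate and deterministic for pairing
#' paralogous pappalysin domains. Returns the aligned, non-gap position
#' pairs.
#'
#' @param sa,sb uppercase one-letter sequences (non-empty).
#' @param gap_penalty linear gap cost (default 1).
#' @return data.frame with columns `pos_a`, `pos_b` (1-based positions in
#'   each input).
#' @export
pair_by_alignment <- function(sa, sb, gap_penalty = 1) {
  sa <- as.character(sa); sb <- as.character(sb)
  if (!nzchar(sa) || !nzchar(sb)) stop("sequences must be non-empty")
  sm <- diag(1, 26)
  dimnames(sm) <- list(LETTERS, LETTERS)
  aln <- Biostrings::pairwiseAlignment(
    sa, sb, type = "global", substitutionMatrix = sm,
    gapOpening = 0, gapExtension = gap_penalty)
  pa <- strsplit(as.character(Biostrings::pattern(aln)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::subject(aln)), "")[[1]]
  ia <- 0L; ib <- 0L
  pos_a <- integer(0); pos_b <- integer(0)
  for (k in seq_along(pa)) {
    ga <- pa[k] == "-"; gb <- pb[k] == "-"
    if (!ga) ia <- ia + 1L
    if (!gb) ib <- ib + 1L
    if (!ga && !gb) {
      pos_a <- c(pos_a, ia)
      pos_b <- c(pos_b, ib)
    }
  }
  data.frame(pos_a = pos_a, pos_b = pos_b)
}

#' Map aligned sequence positions to residue indices
#'
#' Converts [pair_by_alignment()] output (positions in the extracted
#' sequences) into residue-index pairs on the structures, via the
#' `res_index` attribute that [extract_sequence()] records.
#'
#' @param pairs data.frame from [pair_by_alignment()].
#' @param seq_a,seq_b sequences returned by [extract_sequence()].
#' @return data.frame with columns `res_a`, `res_b`.
#' @export
residue_pairing <- function(pairs, seq_a, seq_b) {
  ria <- attr(seq_a, "res_index")
  rib <- attr(seq_b, "res_index")
  if (is.null(ria) || is.null(rib)) {
    stop("sequences must carry a res_index attribute (see extract_sequence)")
  }
  data.frame(res_a = ria[pairs$pos_a], res_b = rib[pairs$pos_b])
}

#' Superpose paired domains and report the C-alpha RMSD
#'
#' Runs [kabsch()] on the paired C-alpha atoms of two domain selections. By
#' default a single pass over all pairs is used; optional outlier-rejection
#' cycles (iteratively dropping pairs deviating more than `sd_factor`
#' standard deviations above the mean, at most `max_cycles` times) mirror
#' what interactive viewers' align commands do, and both the all-pair and
#' final RMSD are reported.
#'
#' @param sa,sb `papp_structure` objects.
#' @param da,db [domain_definition()] selections in each structure.
#' @param pairing data.frame of residue-index pairs (`res_a`, `res_b`),
#'   e.g. from [residue_pairing()].
#' @param max_cycles outlier-rejection cycles (0 = single pass, the default).
#' @param sd_factor rejection threshold in standard deviations (default 2).
#' @param model_a,model_b model indices.
#' @return A `superposition` whose `pairing` records the pairs used; with
#'   rejection, also `rmsd_all`, `cycles_used`, `n_dropped`.
#' @export
domain_rmsd <- function(sa, sb, da, db, pairing, max_cycles = 0,
                        sd_factor = 2, model_a = 1, model_b = 1) {
  stopifnot(inherits(sa, "papp_structure"), inherits(sb, "papp_structure"))
  ca_a <- select_calpha(sa, domain_definition(da$name,
            cbind(1, max(sa$atoms$res_index)), da$chain), model_a)
  ca_b <- select_calpha(sb, domain_definition(db$name,
            cbind(1, max(sb$atoms$res_index)), db$chain), model_b)
  ria <- attr(ca_a, "res_index"); rib <- attr(ca_b, "res_index")
  keep <- .in_ranges(pairing$res_a, da) & .in_ranges(pairing$res_b, db) &
    pairing$res_a %in% ria & pairing$res_b %in% rib
  pairs <- pairing[keep, , drop = FALSE]
  if (nrow(pairs) < 3) {
    stop("under-determined: fewer than 3 usable C-alpha pairs between '",
         da$name, "' and '", db$name, "'")
  }
  P <- ca_a[match(pairs$res_a, ria), , drop = FALSE]
  Q <- ca_b[match(pairs$res_b, rib), , drop = FALSE]
  fit <- kabsch(P, Q)
  fit$rmsd_all <- fit$rmsd
  cycles <- 0L
  if (max_cycles > 0) {
    repeat {
      dev <- sqrt(rowSums((apply_superposition(fit, P) - Q)^2))
      bad <- dev > mean(dev) + sd_factor * stats::sd(dev)
      if (!any(bad) || cycles >= max_cycles || sum(!bad) < 3) break
      P <- P[!bad, , drop = FALSE]
      Q <- Q[!bad, , drop = FALSE]
      pairs <- pairs[!bad, , drop = FALSE]
      rmsd_all <- fit$rmsd_all
      fit <- kabsch(P, Q)
      fit$rmsd_all <- rmsd_all
      cycles <- cycles + 1L
    }
  }
  fit$pairing <- pairs
  fit$cycles_used <- cycles
  fit$n_dropped <- nrow(pairing[keep, , drop = FALSE]) - nrow(pairs)
  fit
}
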