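# Multi-model PDB reading and backbone dihedral computation.
#
# Conformational-ensemble entries (NMR / ensemble-restrained MD, as deposited
# in ensemble databases) come as one PDB file with MODEL/ENDMDL blocks sharing
# one chain. Only backbone N/CA/C atoms are needed downstream.

# PDB fixed columns (v3.3): name 13-16, altLoc 17, resName 18-20, chain 22,
# resSeq 23-26, iCode 27, x/y/z 31-54, occupancy 55-60.
parse_atom_lines <- function(lines) {
  data.frame(
    name    = trimws(substr(lines, 13L, 16L)),
    altloc  = substr(lines, 17L, 17L),
    resname = trimws(substr(lines, 18L, 20L)),
    chain   = substr(lines, 22L, 22L),
    resno   = as.integer(substr(lines, 23L, 26L)),
    icode   = substr(lines, 27L, 27L),
    x = as.numeric(substr(lines, 31L, 38L)),
    y = as.numeric(substr(lines, 39L, 46L)),
    z = as.numeric(substr(lines, 47L, 54L)),
    occ = suppressWarnings(as.numeric(substr(lines, 55L, 60L))),
    stringsAsFactors = FALSE
  )
}

#' Read a multi-model PDB ensemble
#'
#' Parses `ATOM` records of every `MODEL`/`ENDMDL` block (a file without
#' `MODEL` records is treated as a single implicit model), keeps the backbone
#' N/CA/C atoms of one chain, resolves alternate locations by highest
#' occupancy (then first seen) and reconciles the models onto the union of
#' residues seen in any model. Residues missing any backbone atom in a model
#' are flagged incomplete in that model only.
#'
#' @param pdb Path to a PDB file, or a character vector of PDB lines.
#' @param chain Chain identifier; default: the first chain encountered.
#' @return An object of class `backbone_ensemble`: a list with
#'   \describe{
#'     \item{residues}{data.frame of the union residue map: `position`
#'       (1-based), `resno`, `icode`, `resname`.}
#'     \item{models}{list of per-model lists: `model_id`, `complete` (logical
#'       per position), and `n`, `ca`, `c` (L x 3 coordinate matrices, `NA`
#'       rows where absent).}
#'     \item{chain}{the chain id used.}
#'   }
#' @export
read_ensemble <- function(pdb, chain = NULL) {
  lines <- if (length(pdb) == 1L && !grepl("\n", pdb) && file.exists(pdb)) {
    readLines(pdb, warn = FALSE)
  } else {
    unlist(strsplit(pdb, "\n", fixed = TRUE), use.names = FALSE)
  }
  rec <- substr(lines, 1L, 6L)
  model_starts <- which(trimws(rec) == "MODEL")
  model_ends <- which(trimws(rec) == "ENDMDL")
  atom_idx <- which(rec == "ATOM  ")
  if (!length(atom_idx)) stop("read_ensemble: no ATOM records found", call. = FALSE)

  if (length(model_starts)) {
    if (length(model_ends) != length(model_starts)) {
      stop("read_ensemble: unbalanced MODEL/ENDMDL records", call. = FALSE)
    }
    blocks <- mapply(function(s, e) atom_idx[atom_idx > s & atom_idx < e],
                     model_starts, model_ends, SIMPLIFY = FALSE)
    ids <- as.integer(trimws(substr(lines[model_starts], 7L, 80L)))
    if (any(is.na(ids))) ids <- seq_along(blocks)
  } else {
    blocks <- list(atom_idx)
    ids <- 1L
  }
  blocks <- Filter(length, blocks)
  if (!length(blocks)) stop("read_ensemble: no ATOM records inside models", call. = FALSE)

  atoms <- lapply(blocks, function(ix) parse_atom_lines(lines[ix]))
  if (is.null(chain)) chain <- atoms[[1L]]$chain[1L]

  per_model <- lapply(atoms, function(a) {
    a <- a[a$chain == chain & a$name %in% c("N", "CA", "C"), , drop = FALSE]
    if (!nrow(a)) return(a)
    # altloc: highest occupancy wins, then first seen
    a$occ[is.na(a$occ)] <- 1
    key <- paste(a$resno, a$icode, a$name, sep = "\r")
    ord <- order(key, -a$occ, seq_len(nrow(a)))
    a <- a[ord, , drop = FALSE]
    a <- a[!duplicated(paste(a$resno, a$icode, a$name, sep = "\r")), , drop = FALSE]
    a[order(a$resno, a$icode), , drop = FALSE]
  })
  if (all(vapply(per_model, nrow, 0L) == 0L)) {
    stop("read_ensemble: chain '", chain, "' has no backbone atoms", call. = FALSE)
  }

  # union residue map, ordered by resno then insertion code
  res_all <- unique(do.call(rbind, lapply(per_model, function(a)
    a[, c("resno", "icode", "resname")])))
  res_all <- res_all[order(res_all$resno, res_all$icode), , drop = FALSE]
  res_all <- res_all[!duplicated(paste(res_all$resno, res_all$icode, sep = "\r")), ,
                     drop = FALSE]
  rkey <- paste(res_all$resno, res_all$icode, sep = "\r")
  L <- nrow(res_all)

  ranges_differ <- length(unique(vapply(per_model, function(a)
    paste(unique(paste(a$resno, a$icode, sep = "\r")), collapse = ";"), ""))) > 1L
  if (ranges_differ) {
    warning("read_ensemble: models cover different residue sets; ",
            "reconciled to their union with per-model gaps", call. = FALSE)
  }

  models <- vector("list", length(per_model))
  for (m in seq_along(per_model)) {
    a <- per_model[[m]]
    coords <- list(
      n  = matrix(NA_real_, L, 3L),
      ca = matrix(NA_real_, L, 3L),
      c  = matrix(NA_real_, L, 3L)
    )
    pos <- match(paste(a$resno, a$icode, sep = "\r"), rkey)
    for (at in c("N", "CA", "C")) {
      sel <- a$name == at
      slot <- tolower(at)
      coords[[slot]][pos[sel], ] <- as.matrix(a[sel, c("x", "y", "z")])
    }
    complete <- !apply(is.na(coords$n) | is.na(coords$ca) | is.na(coords$c), 1L, any)
    models[[m]] <- list(model_id = ids[m], complete = complete,
                        n = coords$n, ca = coords$ca, c = coords$c)
  }

  structure(
    list(residues = data.frame(position = seq_len(L), resno = res_all$resno,
                               icode = res_all$icode, resname = res_all$resname,
                               stringsAsFactors = FALSE),
         models = models, chain = chain),
    class = "backbone_ensemble"
  )
}

#' @export
print.backbone_ensemble <- function(x, ...) {
  cat("backbone_ensemble: ", length(x$models), " model(s), ",
      nrow(x$residues), " residue(s), chain '", x$chain, "'\n", sep = "")
  invisible(x)
}

#' Signed torsion angle of four points
#'
#' Standard atan2 construction on the two plane normals of the three bond
#' vectors. Degenerate geometry (zero-length or collinear bond vectors)
#' yields `NA`, which propagates to an invalid PB window.
#'
#' @param p1,p2,p3,p4 Numeric length-3 coordinate vectors (Angstrom).
#' @return Torsion in degrees in (-180, 180], or `NA` if degenerate.
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  nb2 <- sqrt(sum(b2^2))
  if (!is.finite(nb2) || nb2 == 0 || sum(n1^2) == 0 || sum(n2^2) == 0) {
    return(NA_real_)
  }
  x <- sum(n1 * n2)
  y <- sum(b1 * n2) * nb2
  ang <- atan2(y, x) * 180 / pi
  wrap_angle(ang)
}

# chain break between consecutive union positions i, i+1 within one model:
# non-consecutive residue numbering (unless insertion codes intervene) or
# C(i)-N(i+1) distance above 2.5 A, or either residue incomplete.
peptide_bond_ok <- function(resno_i, resno_j, icode_i, icode_j, c_i, n_j,
                            max_cn = 2.5) {
  if (any(is.na(c_i)) || any(is.na(n_j))) return(FALSE)
  numbering_ok <- (resno_j == resno_i + 1L) ||
    (resno_j == resno_i && icode_j != icode_i)
  if (!numbering_ok) return(FALSE)
  sqrt(sum((n_j - c_i)^2)) <= max_cn
}

#' Backbone dihedrals of every model in an ensemble
#'
#' \eqn{\phi(i)} is the torsion C(i-1)-N(i)-CA(i)-C(i) and \eqn{\psi(i)} the
#' torsion N(i)-CA(i)-C(i)-N(i+1). Angles are undefined (`NA`) at chain ends,
#' at incomplete residues and across chain breaks (non-consecutive numbering
#' or a C--N distance above `max_cn` Angstrom -- missing residues must not
#' produce spurious dihedrals).
#'
#' @param ensemble A `backbone_ensemble` from [read_ensemble()].
#' @param max_cn Maximum C(i)-N(i+1) peptide-bond length in Angstrom
#'   (default 2.5).
#' @return An object of class `ensemble_dihedrals`: list with `phi` and `psi`
#'   (L x M matrices, degrees, `NA` = undefined) and the `residues` map.
#' @export
compute_dihedrals <- function(ensemble, max_cn = 2.5) {
  stopifnot(inherits(ensemble, "backbone_ensemble"))
  L <- nrow(ensemble$residues)
  M <- length(ensemble$models)
  phi <- matrix(NA_real_, L, M)
  psi <- matrix(NA_real_, L, M)
  rn <- ensemble$residues$resno
  ic <- ensemble$residues$icode
  for (m in seq_len(M)) {
    mod <- ensemble$models[[m]]
    if (L < 2L) next
    bond <- vapply(seq_len(L - 1L), function(i) {
      mod$complete[i] && mod$complete[i + 1L] &&
        peptide_bond_ok(rn[i], rn[i + 1L], ic[i], ic[i + 1L],
                        mod$c[i, ], mod$n[i + 1L, ], max_cn)
    }, logical(1L))
    for (i in seq_len(L)) {
      if (!mod$complete[i]) next
      if (i > 1L && bond[i - 1L]) {
        phi[i, m] <- dihedral(mod$c[i - 1L, ], mod$n[i, ], mod$ca[i, ], mod$c[i, ])
      }
      if (i < L && bond[i]) {
        psi[i, m] <- dihedral(mod$n[i, ], mod$ca[i, ], mod$c[i, ], mod$n[i + 1L, ])
      }
    }
  }
  structure(list(phi = phi, psi = psi, residues = ensemble$residues),
            class = "ensemble_dihedrals")
}

#' Assign protein blocks to every model of an ensemble
#'
#' Runs [assign_sequence()] down each model's dihedral series, yielding the
#' positions x models PB label matrix that underlies the Neq profile.
#'
#' @param dihedrals An `ensemble_dihedrals` from [compute_dihedrals()].
#' @param prototypes Prototype matrix, see [pb_prototypes()].
#' @return A positions x models character matrix of labels in
#'   `{a..p, Z}`, class `pb_matrix`, with the residue map as attribute
#'   `residues`.
#' @export
assign_ensemble <- function(dihedrals, prototypes = pb_prototypes()) {
  stopifnot(inherits(dihedrals, "ensemble_dihedrals"))
  M <- ncol(dihedrals$phi)
  labels <- vapply(seq_len(M), function(m) {
    assign_sequence(dihedrals$phi[, m], dihedrals$psi[, m], prototypes)
  }, character(nrow(dihedrals$phi)))
  labels <- matrix(labels, nrow = nrow(dihedrals$phi), ncol = M)
  structure(labels, class = c("pb_matrix", "matrix"),
            residues = dihedrals$residues)
}
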