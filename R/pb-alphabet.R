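#' @keywords internal
"_PACKAGE"

# Package-level cache (prototype table is read from extdata once per session)
.pbneq <- new.env(parent = emptyenv())

#' The 16 protein block labels
#'
#' @return Character vector `c("a", ..., "p")` in canonical order.
#' @export
pb_labels <- function() letters[1:16]

#' Undefined protein block symbol
#'
#' Used for positions without a complete five-residue dihedral window
#' (chain termini, chain breaks, missing backbone atoms).
#' @export
PB_UNDEFINED <- "Z"

#' Wrap angles into (-180, 180]
#'
#' @param x Numeric vector of angles in degrees.
#' @return Angles reduced modulo 360 into the half-open interval (-180, 180].
#' @export
wrap_angle <- function(x) {
  y <- x %% 360
  y[!is.na(y) & y > 180] <- y[!is.na(y) & y > 180] - 360
  y
}

#' Circular distance between two angles
#'
#' The shortest arc between two angles on the circle, in degrees.
#'
#' @param x,y Angles in degrees (vectors recycle).
#' @return Nonnegative distances in `[0, 180]`.
#' @examples
#' angular_distance(10, 10)     # 0
#' angular_distance(-170, 170)  # 20
#' @export
angular_distance <- function(x, y) {
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("angular_distance: non-finite angle", call. = FALSE)
  }
  d <- abs(x - y) %% 360
  pmin(d, 360 - d)
}

#' Root-mean-square deviation over angular differences (RMSDA)
#'
#' The distance used to match an eight-dihedral window against a PB
#' prototype: the root of the mean squared circular difference over the
#' eight coordinates.
#'
#' @param window Numeric vector of 8 dihedral angles (degrees); `NA` marks an
#'   undefined window.
#' @param prototype Numeric vector of 8 prototype angles.
#' @return Nonnegative RMSDA in degrees.
#' @export
rmsda <- function(window, prototype) {
  if (length(window) != 8L || length(prototype) != 8L) {
    stop("rmsda: window and prototype must have 8 angles", call. = FALSE)
  }
  if (any(is.na(window))) stop("rmsda: undefined window", call. = FALSE)
  sqrt(mean(angular_distance(window, prototype)^2))
}

#' The protein block prototype table
#'
#' Returns the canonical 16-prototype dihedral table of the PB structural
#' alphabet. Each prototype is an 8-dimensional dihedral vector over five
#' consecutive residues in the order
#' \eqn{\psi(i-2), \phi(i-1), \psi(i-1), \phi(i), \psi(i), \phi(i+1),
#' \psi(i+1), \phi(i+2)}.
#'
#' The table ships as a plain-text file
#' (`system.file("extdata", "pb_prototypes.tsv", package = "pbneq")`);
#' users may substitute an alternative alphabet of any size n through the
#' `file` argument, in which case Neq ranges over `[1, n]`.
#'
#' @param file Optional path to an alternative prototype table (TSV with a
#'   header line and columns label + 8 angles).
#' @return A matrix with one row per prototype (rownames = labels) and 8
#'   angle columns, degrees in (-180, 180].
#' @export
pb_prototypes <- function(file = NULL) {
  if (is.null(file)) {
    if (!is.null(.pbneq$prototypes)) return(.pbneq$prototypes)
    file <- system.file("extdata", "pb_prototypes.tsv", package = "pbneq")
    cache <- TRUE
  } else {
    cache <- FALSE
  }
  tab <- utils::read.delim(file, header = TRUE, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  storage.mode(m) <- "double"
  validate_prototypes(m)
  if (cache) .pbneq$prototypes <- m
  m
}

validate_prototypes <- function(m) {
  if (nrow(m) < 2L) stop("prototype table needs at least 2 prototypes")
  if (ncol(m) != 8L) stop("prototype table must have 8 angle columns")
  if (anyDuplicated(rownames(m))) stop("duplicate prototype labels")
  if (any(!is.finite(m)) || any(m <= -180) || any(m > 180)) {
    stop("prototype angles must be finite and in (-180, 180]")
  }
  invisible(m)
}

#' Assign a protein block to one dihedral window
#'
#' Matches an eight-dihedral window against every prototype by RMSDA and
#' returns the label of the closest one. Windows containing any undefined
#' angle get the undefined symbol `Z`. Ties (measure-zero on real data) are
#' broken toward the alphabetically first label.
#'
#' @param window Numeric vector of 8 dihedrals in degrees; `NA` = undefined.
#' @param prototypes Prototype matrix, see [pb_prototypes()].
#' @return A single-character PB label (`"a"`--`"p"` or `"Z"`).
#' @export
assign_pb <- function(window, prototypes = pb_prototypes()) {
  if (length(window) != 8L || any(is.na(window))) return(PB_UNDEFINED)
  w <- wrap_angle(window)
  d <- apply(prototypes, 1L, function(p) sum(angular_distance(w, p)^2))
  rownames(prototypes)[which.min(d)]
}

# Build the L x 8 window matrix from per-residue phi/psi vectors.
# Window of position i: psi(i-2), phi(i-1), psi(i-1), phi(i), psi(i),
# phi(i+1), psi(i+1), phi(i+2). Rows with any NA are invalid windows.
dihedral_windows <- function(phi, psi) {
  L <- length(phi)
  stopifnot(length(psi) == L)
  w <- matrix(NA_real_, nrow = L, ncol = 8L)
  if (L >= 5L) {
    idx <- 3L:(L - 2L)
    w[idx, 1L] <- psi[idx - 2L]
    w[idx, 2L] <- phi[idx - 1L]
    w[idx, 3L] <- psi[idx - 1L]
    w[idx, 4L] <- phi[idx]
    w[idx, 5L] <- psi[idx]
    w[idx, 6L] <- phi[idx + 1L]
    w[idx, 7L] <- psi[idx + 1L]
    w[idx, 8L] <- phi[idx + 2L]
  }
  w
}

#' Assign protein blocks along a chain
#'
#' Slides the five-residue window over a chain's per-residue \eqn{(\phi,
#' \psi)} series and assigns a PB to every position. The first two and last
#' two positions, and any position whose window spans an undefined dihedral
#' (chain break, missing atoms), receive `Z`.
#'
#' @param phi,psi Numeric vectors of per-residue dihedrals in degrees
#'   (`NA` = undefined). Equal length L.
#' @param prototypes Prototype matrix, see [pb_prototypes()].
#' @return Character vector of L PB labels.
#' @examples
#' helix <- assign_sequence(rep(-57, 7), rep(-47, 7))
#' # "Z" "Z" "m" "m" "m" "Z" "Z"
#' @export
assign_sequence <- function(phi, psi, prototypes = pb_prototypes()) {
  L <- length(phi)
  if (L == 0L) return(character(0))
  w <- dihedral_windows(wrap_angle(phi), wrap_angle(psi))
  labels <- rep(PB_UNDEFINED, L)
  ok <- which(rowSums(is.na(w)) == 0L)
  if (length(ok)) {
    d2 <- matrix(0, nrow = length(ok), ncol = nrow(prototypes))
    for (k in seq_len(nrow(prototypes))) {
      diffs <- sweep(w[ok, , drop = FALSE], 2L, prototypes[k, ])
      a <- abs(diffs) %% 360
      a <- pmin(a, 360 - a)
      d2[, k] <- rowSums(a * a)
    }
    labels[ok] <- rownames(prototypes)[max.col(-d2, ties.method = "first")]
  }
  labels
}
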