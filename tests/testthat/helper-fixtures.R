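# Shared fixture builders. All fixtures are generated in code.

# Independent circular distance for oracle use: shortest arc via the
# complex-argument construction (distinct from the package's modulo form).
oracle_angdist <- function(x, y) {
  abs(Arg(exp(1i * (x - y) * pi / 180))) * 180 / pi
}

# Independent RMSDA oracle.
oracle_rmsda <- function(w, p) sqrt(mean(oracle_angdist(w, p)^2))

# Brute-force nearest-prototype oracle reading the shipped table directly.
oracle_assign <- function(window) {
  tab <- utils::read.delim(
    system.file("extdata", "pb_prototypes.tsv", package = "pbneq"))
  d <- apply(as.matrix(tab[, -1]), 1L, function(p) oracle_rmsda(window, p))
  as.character(tab$label[which.min(d)])
}

# A minimal hand-written two-model PDB: 5-residue chain A with exactly
# N/CA/C per residue, coordinates from the package chain builder frozen as
# text. `mutate` lets tests drop/duplicate lines.
toy_pdb <- function(n_res = 10, n_models = 3, sigma = 0, seed = 1,
                    mixture = pb_mixture(m = 1)) {
  spec <- ensemble_spec(max(n_res, 7), max(n_models, 2), mixture,
                        sigma = sigma, seed = seed)
  sim <- simulate_ensemble(spec)
  pdb <- sim$pdb
  if (n_models < 2) {   # keep only the first MODEL block
    ends <- grep("^ENDMDL", pdb)
    pdb <- c(pdb[seq_len(ends[n_models])], "END")
  }
  pdb
}

# Select the ATOM lines of one model block from PDB lines.
model_block_idx <- function(lines, model) {
  starts <- grep("^MODEL", lines)
  ends <- grep("^ENDMDL", lines)
  seq(starts[model] + 1L, ends[model] - 1L)
}

disopred_text <- function(scores, marks, residues = NULL) {
  n <- length(scores)
  if (is.null(residues)) residues <- rep("M", n)
  c("#         ----- DISOPRED version 3.1 -----",
    "# Disordered residues are marked with asterisks (*)",
    sprintf("%5d %s %s %5.2f", seq_len(n), residues, marks, scores))
}

prdos_text <- function(scores, states = NULL, residues = NULL) {
  n <- length(scores)
  if (is.null(residues)) residues <- rep("M", n)
  rows <- if (is.null(states)) {
    sprintf("%d,%s,%.3f", seq_len(n), residues, scores)
  } else {
    sprintf("%d,%s,%.3f,%s", seq_len(n), residues, scores, states)
  }
  c("residue_no,residue,disorder_probability", rows)
}

iupred_text <- function(scores, residues = NULL) {
  n <- length(scores)
  if (is.null(residues)) residues <- rep("M", n)
  c("# IUPred2A: context-dependent prediction of protein disorder",
    "# POS\tRES\tIUPRED2",
    sprintf("%d\t%s\t%.4f", seq_len(n), residues, scores))
}

anchor_text <- function(iupred_scores, anchor_scores, residues = NULL) {
  n <- length(anchor_scores)
  if (is.null(residues)) residues <- rep("M", n)
  c("# ANCHOR2 output",
    "# POS\tRES\tIUPRED2\tANCHOR2",
    sprintf("%d\t%s\t%.4f\t%.4f", seq_len(n), residues, iupred_scores,
            anchor_scores))
}

# neq_profile-shaped data.frame from bare Neq values (for comparison tests).
profile_from_neq <- function(neq_values, positions = seq_along(neq_values)) {
  structure(data.frame(position = positions, neq = neq_values),
            class = c("neq_profile", "data.frame"))
}

# Score track built directly from vectors.
track_from_scores <- function(scores, positions = seq_along(scores),
                              states = NA_character_, predictor = "test") {
  structure(
    data.frame(position = positions, residue = "A", score = scores,
               state = states, stringsAsFactors = FALSE),
    predictor = predictor, class = c("score_track", "data.frame"))
}

# Synthetic Neq values spanning the whole 1..16 continuum with a rigid mode
# at 1, loosely emulating an IDP-ensemble Neq distribution.
synth_neq_values <- function(n, seed = 1, frac_rigid = 0.4) {
  set.seed(seed)
  rigid <- stats::runif(n) < frac_rigid
  v <- 1 + stats::rexp(n, rate = 1 / 4)
  v[v > 16] <- 16
  v[rigid] <- 1
  v
}
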