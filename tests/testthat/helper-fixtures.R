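# Shared fixtures: toy file writers and independent metric oracles.

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# Minimal valid PDB ATOM line with the temperature factor carrying pLDDT.
pdb_atom_line <- function(serial, name, resn, chain, resno, b,
                          record = "ATOM", element = "C") {
  sprintf("%-6s%5d  %-3s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           %s",
          record, serial, name, resn, chain, resno,
          resno * 1.5, 0, 0, 1.00, b, element)
}

write_toy_pdb <- function(residues, path = tempfile(fileext = ".pdb"),
                          chain = "A") {
  # residues: list of lists(resno, atoms = named numeric of b per atom name)
  lines <- character()
  serial <- 0L
  for (r in residues) {
    for (atom in names(r$atoms)) {
      serial <- serial + 1L
      lines <- c(lines, pdb_atom_line(serial, atom, "ALA", chain, r$resno,
                                      r$atoms[[atom]]))
    }
  }
  writeLines(c(lines, "END"), path)
  path
}

# Brute-force ROC AUC: enumerate every positive-negative pair, ties count 1/2.
auc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# Independent MCC: Pearson correlation of the two 0/1 vectors.
mcc_cor_oracle <- function(tp, tn, fp, fn) {
  pred <- c(rep(1, tp), rep(0, tn), rep(1, fp), rep(0, fn))
  act  <- c(rep(1, tp), rep(0, tn), rep(0, fp), rep(1, fn))
  suppressWarnings(stats::cor(pred, act))
}

small_cohort <- function(n = 40, seed = 11, ...) {
  gen_reference(gen_config(n_proteins = n, length_meanlog = log(120),
                           length_sdlog = 0.5, mean_run_ordered = 60,
                           mean_run_disordered = 20, seed = seed, ...))
}
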