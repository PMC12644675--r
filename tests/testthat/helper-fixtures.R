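# Independent brute-force contact counter: plain nested loops over all atom
# pairs, re-stating the classification rules without sharing any code with
# classify_contacts().
brute_force_contacts <- function(model, cutoff, elements = "C") {
  n <- nrow(model)
  intra <- 0L; inter <- 0L
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (!(model$elesy[i] %in% elements) || !(model$elesy[j] %in% elements)) next
      same_chain <- model$chain[i] == model$chain[j]
      if (same_chain && abs(model$resno[i] - model$resno[j]) <= 1) next
      d <- sqrt((model$x[i] - model$x[j])^2 + (model$y[i] - model$y[j])^2 +
                  (model$z[i] - model$z[j])^2)
      if (d <= cutoff) {
        if (same_chain) intra <- intra + 1L else inter <- inter + 1L
      }
    }
  }
  list(intra = intra, inter = inter, total = intra + inter)
}

# Write a structure_model to a minimal standards-conforming PDB file.
write_pdb_fixture <- function(model, path) {
  lines <- vapply(seq_len(nrow(model)), function(i) {
    sprintf("ATOM  %5d  %-3s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            i, model$elety[i], model$resid[i], model$chain[i], model$resno[i],
            model$x[i], model$y[i], model$z[i], 1.0, 0.0, model$elesy[i])
  }, character(1))
  writeLines(c(lines, "END"), path)
  path
}

# One-line atom table constructor for hand-built fixtures.
atom_row <- function(chain, resno, resid, elety, elesy, x, y, z) {
  data.frame(chain = chain, resno = resno, resid = resid, elety = elety,
             elesy = elesy, x = x, y = y, z = z, stringsAsFactors = FALSE)
}

# Published sequence-characterization values for the seven engineered
# trimerization-domain variants (calculated trimer 5+ m/z and trimer atom
# counts) used as frozen references.
published_trimer_table <- function() {
  data.frame(
    name = paste0("foldon", 0:6),
    mz = c(1848.75, 1875.80, 1875.80, 1841.58, 1841.58, 1862.00, 1877.61),
    atoms = c(1299, 1332, 1332, 1311, 1311, 1326, 1338))
}

# Published ambient-temperature pseudo-thermodynamic triples
# (dG, dH, T_amb*dS in kJ/mol) for the seven variants.
published_thermo_triples <- function() {
  data.frame(
    name = paste0("foldon", 0:6),
    dG = c(23.9, 16.5, 18.5, 19.1, 21.2, 21.1, 24.6),
    dH = c(63.9, 51.8, 56.3, 56.7, 60.0, 61.1, 66.8),
    TdS = c(40.0, 35.3, 37.8, 37.6, 38.8, 40.0, 42.2))
}
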