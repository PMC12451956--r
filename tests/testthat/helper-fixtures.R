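# Hand-written minimal PDB fixture lines (fixed-column format) so parser
# rules (altlocs, numbering gaps, chains, HETATM) can be forced exactly.
pdb_atom_line <- function(serial, name, altloc, resname, chain, resno,
                          x, y, z, occ = 1.00, b = 0.00, record = "ATOM") {
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
          record, serial, paste0(" ", name), altloc, resname, chain, resno,
          x, y, z, occ, b)
}

write_mini_pdb <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

# bare trace-shaped tibble (write_trace_pdb only needs the columns)
new_trace_for_test <- function(xyz) {
  xyz <- matrix(xyz, ncol = 3, byrow = TRUE)
  tibble::tibble(residue_number = seq_len(nrow(xyz)),
                 aa = rep("A", nrow(xyz)),
                 x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
}

# three-residue fixture with known coordinates
mini_pdb_3res <- function() {
  write_mini_pdb(c(
    pdb_atom_line(1, "CA", " ", "ALA", "A", 1, 1.000, 2.000, 3.000),
    pdb_atom_line(2, "CA", " ", "GLY", "A", 2, 4.500, 2.000, 3.000),
    pdb_atom_line(3, "CA", " ", "MET", "A", 3, 4.500, 5.500, 3.000)
  ))
}
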